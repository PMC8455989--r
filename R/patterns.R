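# The p10 anchor-pattern language and three-anchor search.
#
# Diatom type III metacaspases carry a small p10 domain that public
# profile databases often miss; it is instead located by three short
# anchors — Dx[QE]TSAD near the start, GGAX[ST] in the middle and QxPQL
# at the end. The pattern grammar: an uppercase amino-acid letter is a
# literal, 'x'/'X' is a wildcard, '[...]' is a class of allowed residues.
# A wildcard matches any residue including the unknown residue X, so
# truncated transcripts are not silently dropped.

#' Parse a PROSITE-style anchor pattern
#'
#' @param text Pattern string, e.g. `"Dx[QE]TSAD"`. Uppercase letters are
#'   literals, `x` or `X` a wildcard, `[...]` a residue class.
#' @return An object of class `mc_pattern`: a list with `text` and
#'   `tokens`, where each token is either `NULL` (wildcard) or a character
#'   vector of allowed residues.
#' @export
#' @examples
#' parse_pattern("Dx[QE]TSAD")
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  cc <- chars(text)
  tokens <- list()
  i <- 1L
  while (i <= length(cc)) {
    ch <- cc[[i]]
    if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (j <= length(cc) && cc[[j]] != "]") {
        if (!cc[[j]] %in% AA20) {
          stop("parse_pattern: non-amino-acid '", cc[[j]], "' in class at position ", j)
        }
        cls <- c(cls, cc[[j]])
        j <- j + 1L
      }
      if (j > length(cc)) stop("parse_pattern: unbalanced '[' at position ", i)
      if (length(cls) == 0L) stop("parse_pattern: empty class at position ", i)
      tokens <- c(tokens, list(unique(cls)))
      i <- j + 1L
    } else if (ch == "]") {
      stop("parse_pattern: unmatched ']' at position ", i)
    } else if (ch %in% c("x", "X")) {
      tokens <- c(tokens, list(NULL))
      i <- i + 1L
    } else if (ch %in% AA20) {
      tokens <- c(tokens, list(ch))
      i <- i + 1L
    } else {
      stop("parse_pattern: illegal character '", ch, "' at position ", i)
    }
  }
  structure(list(text = text, tokens = tokens), class = "mc_pattern")
}

#' @export
print.mc_pattern <- function(x, ...) {
  cat("<mc_pattern> ", x$text, " (", length(x$tokens), " tokens)\n", sep = "")
  invisible(x)
}

pattern_length <- function(pat) length(pat$tokens)

#' Find all occurrences of an anchor pattern in a protein sequence
#'
#' Reports every match position left to right; overlapping matches are
#' allowed. A wildcard token matches any residue including `X`; literal
#' and class tokens do not match `X`.
#'
#' @param seq Protein sequence string.
#' @param pat An `mc_pattern` from [parse_pattern()] (or a pattern string,
#'   parsed on the fly).
#' @return Tibble with 0-based half-open columns `start`, `end`.
#' @export
find_pattern <- function(seq, pat) {
  if (is.character(pat)) pat <- parse_pattern(pat)
  stopifnot(inherits(pat, "mc_pattern"))
  s <- chars(seq)
  n <- length(s)
  m <- pattern_length(pat)
  if (n < m) return(tibble::tibble(start = integer(), end = integer()))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    tok <- pat$tokens[[j]]
    if (is.null(tok)) next  # wildcard
    ok <- ok & s[j:(n - m + j)] %in% tok
  }
  starts <- which(ok) - 1L
  tibble::tibble(start = starts, end = starts + m)
}

#' Default and alternative p10 anchor pattern sets
#'
#' The refined three-anchor set is the default. The earlier two-anchor
#' "basis" set (no end anchor) is shipped as a named alternative and is
#' off unless requested.
#'
#' @param set `"refined"` (default) or `"basis"`.
#' @return Named list of `mc_pattern`s (`start`, `middle`, `end`; `end`
#'   is `NULL` for the basis set).
#' @export
p10_patterns <- function(set = c("refined", "basis")) {
  set <- match.arg(set)
  if (set == "refined") {
    list(start = parse_pattern("Dx[QE]TSAD"),
         middle = parse_pattern("GGAX[ST]"),
         end = parse_pattern("QxPQL"))
  } else {
    list(start = parse_pattern("[QE]TSAD"),
         middle = parse_pattern("GAX[ST]XXXXXX[IVLA]"),
         end = NULL)
  }
}

#' p10 search configuration
#'
#' The three p10 anchors with configurable inter-anchor gap windows.
#' The gap windows are a package convention (p10 domains run roughly
#' 70-120 residues): gap1 is the allowed residue gap between the end of
#' the start anchor and the start of the middle anchor, gap2 between the
#' middle anchor end and the end anchor start; both inclusive.
#'
#' @param patterns Named list as from [p10_patterns()], or pattern strings
#'   `list(start=, middle=, end=)`.
#' @param gap1,gap2 Length-2 integer vectors `c(lo, hi)`, `0 <= lo <= hi`.
#' @return An object of class `p10_config`.
#' @export
p10_config <- function(patterns = p10_patterns("refined"),
                       gap1 = c(0L, 40L), gap2 = c(0L, 60L)) {
  patterns <- lapply(patterns, function(p) {
    if (is.null(p) || inherits(p, "mc_pattern")) p else parse_pattern(p)
  })
  stopifnot(all(c("start", "middle") %in% names(patterns)))
  check_gap <- function(g) {
    stopifnot(length(g) == 2L, g[1] >= 0, g[1] <= g[2])
  }
  check_gap(gap1); check_gap(gap2)
  structure(list(patterns = patterns, gap1 = as.integer(gap1),
                 gap2 = as.integer(gap2)), class = "p10_config")
}

#' Locate p10 domains by the three-anchor search
#'
#' For each start-anchor match (left to right), accept the leftmost
#' middle-anchor match whose offset from the start-anchor end lies inside
#' `gap1`, then the leftmost end-anchor match within `gap2` of the middle
#' anchor end; the hit spans start-anchor start to end-anchor end. Hits
#' are reported non-overlapping, greedily left to right; an anchor
#' consumed by one hit cannot seed another. With a `NULL` end pattern
#' (the "basis" set) the hit ends at the middle anchor.
#'
#' @param seq Protein sequence string.
#' @param cfg A [p10_config()].
#' @return Tibble of domain hits (`kind = "p10"`, 0-based half-open
#'   `start`/`end`, `score` = number of anchors matched, `method`).
#' @export
find_p10 <- function(seq, cfg = p10_config()) {
  stopifnot(inherits(cfg, "p10_config"))
  p <- cfg$patterns
  m_start <- find_pattern(seq, p$start)
  m_mid <- find_pattern(seq, p$middle)
  m_end <- if (!is.null(p$end)) find_pattern(seq, p$end) else NULL

  hits <- empty_hits()
  cursor <- 0L
  for (i in seq_len(nrow(m_start))) {
    s0 <- m_start$start[[i]]
    if (s0 < cursor) next
    s1 <- m_start$end[[i]]
    mid_ok <- m_mid[m_mid$start - s1 >= cfg$gap1[1] &
                    m_mid$start - s1 <= cfg$gap1[2], , drop = FALSE]
    if (nrow(mid_ok) == 0L) next
    g1 <- mid_ok[1, ]  # leftmost
    if (is.null(m_end)) {
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        kind = "p10", start = s0, end = g1$end, score = 2,
        method = "anchor_pattern"))
      cursor <- g1$end
      next
    }
    end_ok <- m_end[m_end$start - g1$end >= cfg$gap2[1] &
                    m_end$start - g1$end <= cfg$gap2[2], , drop = FALSE]
    if (nrow(end_ok) == 0L) next
    g2 <- end_ok[1, ]  # leftmost
    hits <- dplyr::bind_rows(hits, tibble::tibble(
      kind = "p10", start = s0, end = g2$end, score = 3,
      method = "anchor_pattern"))
    cursor <- g2$end
  }
  hits
}
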