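# Independent oracles and fixture builders used across test files.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, with_x = FALSE) {
  pool <- if (with_x) c(AA, "X") else AA
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Regex translation of the anchor-pattern grammar: an independently
# written matcher used as the oracle for find_pattern. Overlapping
# matches found with a lookahead capture.
pattern_regex_matches <- function(seq, text) {
  cc <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(cc)) {
    if (cc[i] == "[") {
      j <- i + 1
      while (cc[j] != "]") j <- j + 1
      out <- c(out, paste0("[", paste(cc[(i + 1):(j - 1)], collapse = ""), "]"))
      i <- j + 1
    } else if (cc[i] %in% c("x", "X")) {
      out <- c(out, ".")  # wildcard matches anything incl. X
      i <- i + 1
    } else {
      out <- c(out, cc[i])
      i <- i + 1
    }
  }
  m <- length(out)
  rx <- paste0("(?=(", paste(out, collapse = ""), "))")
  g <- gregexpr(rx, seq, perl = TRUE)[[1]]
  starts <- as.integer(g)
  if (length(starts) == 1 && starts == -1) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = starts - 1L, end = starts - 1L + m)
}

# Brute-force all-windows PSSM scorer: score every window, threshold,
# then resolve overlaps by score (ties leftmost) — written directly
# from the definitions, no shared code with scan_pssm internals.
brute_pssm_hits <- function(seq, pssm, threshold = pssm$score_threshold) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  w <- pssm$width
  n <- length(s)
  if (n < w) return(NULL)
  scores <- vapply(0:(n - w), function(off) {
    sum(vapply(seq_len(w), function(j) {
      r <- s[off + j]
      if (r %in% rownames(pssm$scores)) pssm$scores[r, j] else 0
    }, double(1)))
  }, double(1))
  cand <- which(scores >= threshold) - 1L
  cand <- cand[order(-scores[cand + 1L], cand)]
  sel <- integer(0)
  for (p in cand) {
    if (!any(abs(sel - p) < w)) sel <- c(sel, p)
  }
  sel <- sort(sel)
  tibble::tibble(start = sel, end = sel + w, score = scores[sel + 1L])
}

# Random additive (tree-realizable) distance matrix: build a random
# binary tree shape with positive branch lengths, return its
# path-length metric and the generating tree.
random_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  dm <- cophenetic(tr)
  dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
  list(tree = tr, dm = dm)
}

# Unrooted topology comparison via Robinson-Foulds distance.
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Exhaustive off-target oracle: slide a 23-nt window over both strands,
# demand NGG, exact 12-nt PAM-proximal seed, <= max mm in the 8-nt
# PAM-distal block (N mismatches), exclude the on-target locus.
brute_off_targets <- function(guide, genome, max_mm = 3) {
  seq <- toupper(genome$sequence)
  n <- nchar(seq)
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  g <- strsplit(guide$protospacer, "", fixed = TRUE)[[1]]
  res <- list()
  for (p in 0:(n - 23L)) {
    win <- substr(seq, p + 1L, p + 23L)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rc(win)
      if (substr(w, 22, 23) != "GG") next
      proto <- substr(w, 1, 20)
      st <- if (strand == "+") p else p + 3L
      en <- st + 20L
      if (st == guide$start && strand == guide$strand) next
      t <- strsplit(proto, "", fixed = TRUE)[[1]]
      mm <- t != g | t == "N"
      if (any(mm[9:20])) next
      if (sum(mm[1:8]) > max_mm) next
      res[[length(res) + 1L]] <- tibble::tibble(
        start = st, end = en, strand = strand,
        nonseed_mismatches = sum(mm[1:8]))
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), nonseed_mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(res), start, strand)
}
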