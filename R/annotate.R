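# Metacaspase typing and the 2-Cys regulatory-pair call.
#
# Domain hits are assembled into an architecture call: type III
# metacaspases are the only type in which the p10 domain precedes the
# p20 domain; p20-only proteins are metacaspase-like proteases (MCPs);
# p20-then-p10 splits into type I vs type II by inter-domain linker
# length. The 2-Cys call maps the PtMCA-IIIc regulatory cysteine pair
# (reference positions 202 and 259; catalytic Cys 264) onto a query via
# global pairwise alignment and asks whether both mapped query residues
# are cysteines.

get_submat <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch with affine gap penalties (via Biostrings). Returns
#' the column-by-column map between query and reference positions.
#'
#' @param query,reference Protein sequence strings (non-empty).
#' @param submat Substitution matrix name (e.g. `"BLOSUM62"`, the
#'   default) or a matrix.
#' @param gap_open,gap_extend Positive gap penalties (default 10 / 0.5).
#' @return A list of class `alignment_map`: `map`, a tibble with
#'   1-based residue columns `query_pos` / `ref_pos` (`NA` against a
#'   gap), and `score`.
#' @export
align_global <- function(query, reference, submat = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(query) || !nzchar(reference)) {
    stop("align_global: sequences must be non-empty")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = get_submat(submat),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  qa <- chars(as.character(Biostrings::alignedPattern(pa)))
  ra <- chars(as.character(Biostrings::alignedSubject(pa)))
  qpos <- ifelse(qa == "-", NA_integer_, cumsum(qa != "-"))
  rpos <- ifelse(ra == "-", NA_integer_, cumsum(ra != "-"))
  structure(list(map = tibble::tibble(query_pos = qpos, ref_pos = rpos),
                 score = Biostrings::score(pa)),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("<alignment_map> ", nrow(x$map), " columns, score ",
      sprintf("%.1f", x$score), "\n", sep = "")
  invisible(x)
}

#' Define a 2-Cys reference protein
#'
#' Named positions are 1-based on the full reference protein, as printed
#' for PtMCA-IIIc (C202, C259, catalytic C264). All named cysteine
#' positions must hold `C` in the reference.
#'
#' @param sequence Reference protein sequence.
#' @param cys_pair Length-2 integer vector, the regulatory pair.
#' @param catalytic_cys Catalytic cysteine position.
#' @param catalytic_his Optional catalytic histidine position.
#' @param ca_aspartates Optional integer vector of calcium-site
#'   aspartate positions.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(sequence, cys_pair = c(202L, 259L),
                           catalytic_cys = 264L, catalytic_his = NULL,
                           ca_aspartates = NULL) {
  n <- nchar(sequence)
  pos <- c(cys_pair, catalytic_cys, catalytic_his, ca_aspartates)
  if (any(pos < 1 | pos > n)) stop("reference_spec: position outside reference")
  s <- chars(sequence)
  cys_at <- c(cys_pair, catalytic_cys)
  if (any(s[cys_at] != "C")) {
    stop("reference_spec: named Cys position(s) do not hold 'C': ",
         paste(cys_at[s[cys_at] != "C"], collapse = ", "))
  }
  structure(list(sequence = sequence, cys_pair = as.integer(cys_pair),
                 catalytic_cys = as.integer(catalytic_cys),
                 catalytic_his = catalytic_his,
                 ca_aspartates = ca_aspartates), class = "reference_spec")
}

#' Call 2-Cys status for a query protein
#'
#' Maps the reference regulatory pair through a global alignment of the
#' query to the reference. `both` requires both mapped query residues to
#' be cysteine; `first_only`/`second_only`/`none` accordingly; `unmapped`
#' when either reference position aligns to a gap. Mapped query positions
#' are reported 1-based.
#'
#' @param query Query protein sequence.
#' @param ref A [reference_spec()].
#' @inheritParams align_global
#' @return One-row tibble: `two_cys_status`, `two_cys_pos1`,
#'   `two_cys_pos2` (1-based query positions or `NA`).
#' @export
call_two_cys <- function(query, ref, submat = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(ref, "reference_spec"))
  al <- align_global(query, ref$sequence, submat, gap_open, gap_extend)
  qs <- chars(query)
  mapped <- vapply(ref$cys_pair, function(p) {
    q <- al$map$query_pos[match(p, al$map$ref_pos)]
    if (length(q) == 0L) NA_integer_ else q
  }, integer(1))
  if (anyNA(mapped)) {
    status <- "unmapped"
  } else {
    is_c <- qs[mapped] == "C"
    status <- if (all(is_c)) "both"
      else if (is_c[1]) "first_only"
      else if (is_c[2]) "second_only"
      else "none"
  }
  tibble::tibble(two_cys_status = status,
                 two_cys_pos1 = mapped[1], two_cys_pos2 = mapped[2])
}

#' Classify metacaspase architecture from domain hits
#'
#' Decision table over one protein's hits: no p20 is `unclassified`; p20
#' without p10 is `MCP`; p10 entirely before the best p20 is `type_III`;
#' p20 before p10 is `type_I` when the inter-domain linker is shorter
#' than `linker_threshold` residues, else `type_II`; overlapping p10/p20
#' is `unclassified` with a warning. The best p20 is the highest-scoring
#' hit; the first p10 hit is used.
#'
#' @param hits Tibble of domain hits for one protein (columns `kind`,
#'   `start`, `end`, `score`).
#' @param linker_threshold Type I vs type II linker cutoff in residues
#'   (default 50; the distinction is pictorial in the source biology, the
#'   number is a package convention).
#' @return A single string, one of `type_I`, `type_II`, `type_III`,
#'   `MCP`, `unclassified`.
#' @export
classify_mc <- function(hits, linker_threshold = 50) {
  p20 <- hits[hits$kind == "p20", , drop = FALSE]
  p10 <- hits[hits$kind == "p10", , drop = FALSE]
  if (nrow(p20) == 0L) return("unclassified")
  p20 <- p20[order(-p20$score, p20$start), ][1, ]
  if (nrow(p10) == 0L) return("MCP")
  p10 <- p10[1, ]
  if (p10$end <= p20$start) return("type_III")
  if (p20$end <= p10$start) {
    linker <- p10$start - p20$end
    return(if (linker < linker_threshold) "type_I" else "type_II")
  }
  warning("classify_mc: overlapping p10/p20 hits")
  "unclassified"
}

#' Annotate a set of proteins end to end
#'
#' Runs the p20 profile scan (with dyad verification), the p10 anchor
#' search, architecture classification, and the 2-Cys call for each
#' record.
#'
#' @param records Tibble of protein records (`id`, `species`,
#'   `sequence`), as from [read_fasta()] or [synth_proteome()].
#' @param pssm p20 profile ([build_pssm()]); default [default_pssm()].
#' @param dyad Dyad columns ([dyad_spec()]); default [default_dyad()].
#' @param p10_cfg p10 search configuration ([p10_config()]).
#' @param ref 2-Cys reference ([reference_spec()]); default
#'   [default_reference()].
#' @param linker_threshold Passed to [classify_mc()].
#' @return Tibble, one row per protein: `id`, `species`, `mc_type`,
#'   `p20_start`, `p20_end`, `p20_score`, `dyad_status`, `p10_start`,
#'   `p10_end`, `two_cys_status`, `two_cys_pos1`, `two_cys_pos2`.
#'   Intervals are 0-based half-open.
#' @export
annotate_proteins <- function(records, pssm = default_pssm(),
                              dyad = default_dyad(),
                              p10_cfg = p10_config(),
                              ref = default_reference(),
                              linker_threshold = 50) {
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[[i]]
    p20 <- find_p20(seq, pssm, dyad)
    p10 <- find_p10(seq, p10_cfg)
    hits <- dplyr::bind_rows(p20, p10)
    mc_type <- classify_mc(hits, linker_threshold)
    best20 <- if (nrow(p20)) p20[order(-p20$score, p20$start), ][1, ] else NULL
    first10 <- if (nrow(p10)) p10[1, ] else NULL
    two <- call_two_cys(seq, ref)
    tibble::tibble(
      id = records$id[[i]],
      species = records$species[[i]] %||% "",
      mc_type = mc_type,
      p20_start = if (is.null(best20)) NA_integer_ else best20$start,
      p20_end = if (is.null(best20)) NA_integer_ else best20$end,
      p20_score = if (is.null(best20)) NA_real_ else best20$score,
      dyad_status = if (is.null(best20)) NA_character_ else best20$dyad_status,
      p10_start = if (is.null(first10)) NA_integer_ else first10$start,
      p10_end = if (is.null(first10)) NA_integer_ else first10$end
    ) |>
      dplyr::bind_cols(two)
  })
}

#' Summarize metacaspase annotations per species
#'
#' Mirrors a per-species abundance table: metacaspase count, presence of
#' type III and of 2-Cys metacaspases (`+`/`-`), plus raw counts. The
#' returned tibble carries the dataset-level fraction of species with at
#' least one 2-Cys metacaspase as attribute `two_cys_species_fraction`
#' (also available via [two_cys_species_fraction()]).
#'
#' @param annotations Tibble from [annotate_proteins()].
#' @return Per-species tibble: `species`, `n_mc`, `n_type_iii`,
#'   `n_two_cys`, `type_iii` (`+`/`-`), `two_cys` (`+`/`-`).
#' @export
summarize_species <- function(annotations) {
  stopifnot("species" %in% names(annotations))
  out <- annotations |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_mc = dplyr::n(),
      n_type_iii = sum(.data$mc_type == "type_III"),
      n_two_cys = sum(.data$mc_type == "type_III" &
                        .data$two_cys_status == "both"),
      .groups = "drop") |>
    dplyr::mutate(
      type_iii = ifelse(.data$n_type_iii > 0, "+", "-"),
      two_cys = ifelse(.data$n_two_cys > 0, "+", "-"))
  attr(out, "two_cys_species_fraction") <- mean(out$n_two_cys > 0)
  out
}

#' Fraction of species carrying at least one 2-Cys metacaspase
#'
#' @param annotations Tibble from [annotate_proteins()].
#' @return A number in `[0, 1]`.
#' @export
two_cys_species_fraction <- function(annotations) {
  s <- summarize_species(annotations)
  mean(s$n_two_cys > 0)
}
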