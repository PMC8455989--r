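# Paired-guide CRISPR excision design with seed-sequence off-target
# screening.
#
# Conventions: SpCas9 NGG PAM only; the protospacer is the 20 nt
# immediately 5' of the PAM; the blunt cut falls 3 bp 5' of the PAM
# (between protospacer positions 17 and 18). `cut_site` is a 0-based
# phosphodiester bond index: the cut lies between genome positions
# cut_site - 1 and cut_site. The off-target rule is the one used for
# guide selection in diatom knockout work: the 3' 12-nt seed must match
# exactly, an NGG PAM must be present, and at most three mismatches are
# allowed in the 8 nt outside the seed. An exhaustive within-genome scan
# replaces the original BLAST heuristic and subsumes it at gene scale.

#' Enumerate candidate CRISPR targets (20 nt + NGG) in a genome
#'
#' Scans both strands; candidates whose protospacer or PAM contains `N`
#' are excluded. Coordinates are 0-based half-open on the + strand.
#'
#' @param genome A list or one-row tibble with `id` and `sequence`
#'   (A/C/G/T/N), e.g. a row of [read_fasta()] output or
#'   [synth_genome()]'s record.
#' @param region Optional length-2 vector `c(start, end)`, 0-based
#'   half-open; only candidates whose protospacer+PAM lie inside are
#'   returned.
#' @return Tibble: `protospacer`, `pam`, `strand`, `start`, `end`
#'   (protospacer interval, + strand coords), `cut_site`.
#' @export
enumerate_targets <- function(genome, region = NULL) {
  seq <- toupper(genome$sequence)
  n <- nchar(seq)
  lo <- 0L; hi <- n
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 0, region[2] <= n)
    lo <- as.integer(region[1]); hi <- as.integer(region[2])
  }
  if (hi - lo < 23L) return(empty_guides())
  res <- pam_sites(seq, lo, hi)
  if (nrow(res) == 0L) return(empty_guides())
  res <- res[!grepl("N", res$protospacer, fixed = TRUE) &
               !grepl("N", res$pam, fixed = TRUE), , drop = FALSE]
  dplyr::arrange(res, .data$start, .data$strand)
}

# All 23-mer windows with an NGG PAM on either strand, N-containing
# protospacers included (the candidate filter lives in
# enumerate_targets; off-target comparison treats N as mismatch).
pam_sites <- function(seq, lo = 0L, hi = nchar(seq)) {
  s <- chars(seq)
  out <- list()
  # forward: protospacer [p, p+20), PAM [p+20, p+23) with GG at p+21,p+22
  p <- lo:(hi - 23L)
  fwd <- p[s[p + 22L] == "G" & s[p + 23L] == "G"]
  if (length(fwd)) {
    out$fwd <- tibble::tibble(
      protospacer = substring(seq, fwd + 1L, fwd + 20L),
      pam = substring(seq, fwd + 21L, fwd + 23L), strand = "+",
      start = fwd, end = fwd + 20L, cut_site = fwd + 17L)
  }
  # reverse: PAM CCN at + interval [q, q+3), protospacer [q+3, q+23)
  q <- lo:(hi - 23L)
  rev <- q[s[q + 1L] == "C" & s[q + 2L] == "C"]
  if (length(rev)) {
    out$rev <- tibble::tibble(
      protospacer = vapply(substring(seq, rev + 4L, rev + 23L), revcomp,
                           character(1), USE.NAMES = FALSE),
      pam = vapply(substring(seq, rev + 1L, rev + 3L), revcomp,
                   character(1), USE.NAMES = FALSE),
      strand = "-", start = rev + 3L, end = rev + 23L, cut_site = rev + 6L)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty_guides() else res
}

empty_guides <- function() {
  tibble::tibble(protospacer = character(), pam = character(),
                 strand = character(), start = integer(), end = integer(),
                 cut_site = integer())
}

#' Screen a guide for off-target sites in a genome
#'
#' Scans both strands for 23-mers with an NGG PAM; a site is reported
#' when the 12 PAM-proximal protospacer nucleotides (the seed) match
#' exactly and the remaining 8 PAM-distal nucleotides carry at most
#' `max_nonseed_mismatches` mismatches. `N` counts as a mismatch. The
#' on-target locus (same interval and strand) is excluded.
#'
#' @param guide One row of [enumerate_targets()] output (needs
#'   `protospacer`, `start`, `end`, `strand`).
#' @param genome As in [enumerate_targets()].
#' @param seed_length Seed length in nt (default 12, PAM-proximal).
#' @param max_nonseed_mismatches Maximum mismatches outside the seed
#'   (default 3).
#' @return Tibble: `start`, `end`, `strand`, `seed_identical`,
#'   `nonseed_mismatches`.
#' @export
off_target_scan <- function(guide, genome, seed_length = 12,
                            max_nonseed_mismatches = 3) {
  stopifnot(nchar(guide$protospacer) == 20L)
  sites <- pam_sites(toupper(genome$sequence))
  g <- chars(guide$protospacer)
  nonseed_idx <- seq_len(20L - seed_length)
  seed_idx <- (20L - seed_length + 1L):20L
  hits <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    if (site$start == guide$start && site$strand == guide$strand) return(NULL)
    t <- chars(site$protospacer)
    mm <- t != g | t == "N"
    if (any(mm[seed_idx])) return(NULL)
    nmm <- sum(mm[nonseed_idx])
    if (nmm > max_nonseed_mismatches) return(NULL)
    tibble::tibble(start = site$start, end = site$end, strand = site$strand,
                   seed_identical = TRUE, nonseed_mismatches = nmm)
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), seed_identical = logical(),
                          nonseed_mismatches = integer()))
  }
  hits
}

# Map 0-based CDS nucleotide positions to 0-based genomic positions
# through an exon model (tibble start/end, 0-based half-open, ascending).
cds_to_genomic <- function(exons, cds_pos) {
  widths <- exons$end - exons$start
  offsets <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  vapply(cds_pos, function(p) {
    k <- findInterval(p, offsets)
    if (k < 1L || p >= offsets[k] + widths[k]) {
      stop("cds_to_genomic: CDS position ", p, " outside CDS")
    }
    exons$start[k] + (p - offsets[k])
  }, double(1)) |> as.integer()
}

#' Design a paired-guide excision and predict its consequences
#'
#' The deletion interval spans the two cut sites. The deleted CDS length
#' is the intersection of the deletion with the exons; a frameshift is
#' predicted when the deleted CDS length is not a multiple of 3. The
#' catalytic-Cys flag is set when all three genomic positions of the
#' catalytic codon fall inside the deletion.
#'
#' @param genome A record with `sequence` and an exon model `exons`
#'   (tibble `start`/`end`, 0-based half-open, ascending,
#'   non-overlapping), e.g. from [synth_genome()].
#' @param guide1,guide2 Rows of [enumerate_targets()] output with
#'   distinct `cut_site`s.
#' @param catalytic_codon 1-based codon index of the catalytic Cys in
#'   the spliced CDS.
#' @return One-row tibble: `cut1`, `cut2`, `deletion_start`,
#'   `deletion_end`, `deletion_length`, `deleted_cds_nt`, `frameshift`,
#'   `removes_catalytic_cys`.
#' @export
design_excision <- function(genome, guide1, guide2, catalytic_codon) {
  exons <- genome$exons
  stopifnot(!is.null(exons), all(exons$end > exons$start))
  c1 <- guide1$cut_site; c2 <- guide2$cut_site
  if (c1 == c2) stop("design_excision: cut sites must be distinct")
  del <- c(min(c1, c2), max(c1, c2))  # [min cut, max cut)
  deleted_cds <- sum(pmax(0L, pmin(exons$end, del[2]) - pmax(exons$start, del[1])))
  codon_g <- cds_to_genomic(exons, (catalytic_codon - 1L) * 3L + 0:2)
  tibble::tibble(
    cut1 = c1, cut2 = c2,
    deletion_start = del[1], deletion_end = del[2],
    deletion_length = del[2] - del[1],
    deleted_cds_nt = deleted_cds,
    frameshift = (deleted_cds %% 3L) != 0L,
    removes_catalytic_cys = all(codon_g >= del[1] & codon_g < del[2]))
}
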