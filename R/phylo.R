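# p20-domain phylogeny: trimming, center-star alignment, protein
# distances, neighbor-joining, and bootstrap supports.
#
# Neighbor joining is implemented in-package because the pipeline
# specifies behavior beyond a stock NJ: negative branch lengths are
# clipped to zero with the deficit moved to the sister edge, and
# Q-matrix ties break deterministically on the lowest taxon-index pair.
# The unrooted tree is represented with a trifurcating root (ape phylo).

#' Extract p20 subsequences for tree building
#'
#' Proteins without a p20 hit are excluded with a warning (the count is
#' reported).
#'
#' @param annotations Tibble from [annotate_proteins()].
#' @param records Tibble of protein records (`id`, `sequence`).
#' @return Tibble of p20-domain records (`id`, `species`, `sequence`).
#' @export
trim_p20 <- function(annotations, records) {
  ann <- dplyr::inner_join(annotations, records[, c("id", "sequence")], by = "id")
  no20 <- is.na(ann$p20_start)
  if (any(no20)) {
    warning("trim_p20: excluded ", sum(no20), " protein(s) without a p20 hit")
    ann <- ann[!no20, , drop = FALSE]
  }
  tibble::tibble(
    id = ann$id,
    species = if ("species" %in% names(ann)) ann$species else "",
    sequence = substr(ann$sequence, ann$p20_start + 1L, ann$p20_end))
}

# Insertion-run profile of the center row of one pairwise alignment:
# ins[j] = number of inserted columns before center residue j (1..L),
# ins[L+1] = trailing insertions.
center_ins_profile <- function(center_aln) {
  cc <- chars(center_aln)
  L <- sum(cc != "-")
  ins <- integer(L + 1L)
  j <- 1L
  run <- 0L
  for (ch in cc) {
    if (ch == "-") run <- run + 1L
    else { ins[j] <- run; run <- 0L; j <- j + 1L }
  }
  ins[L + 1L] <- run
  ins
}

# Re-emit one aligned row under the merged insertion profile M.
expand_to_master <- function(center_aln, other_aln, M) {
  cc <- chars(center_aln)
  oo <- chars(other_aln)
  out <- character(0)
  pending <- character(0)
  j <- 1L
  for (k in seq_along(cc)) {
    if (cc[k] == "-") {
      pending <- c(pending, oo[k])
    } else {
      out <- c(out, rep("-", M[j] - length(pending)), pending, oo[k])
      pending <- character(0)
      j <- j + 1L
    }
  }
  out <- c(out, rep("-", M[j] - length(pending)), pending)
  paste(out, collapse = "")
}

#' Center-star multiple sequence alignment
#'
#' A built-in progressive alignment: the center is the record maximizing
#' the summed pairwise global alignment score; every other record is
#' aligned to the center pairwise and gaps are merged under "once a gap,
#' always a gap". External alignments (ClustalW, MAFFT) can be imported
#' with [read_alignment()] instead.
#'
#' @param records Tibble with `id` and `sequence` (>= 2 rows).
#' @inheritParams align_global
#' @return A named character vector of aligned rows (see [as_msa()]),
#'   in input record order.
#' @export
center_star_msa <- function(records, submat = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  n <- nrow(records)
  if (n < 2L) stop("center_star_msa: need >= 2 records")
  sm <- get_submat(submat)
  seqs <- records$sequence
  ids <- records$id
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        substitutionMatrix = sm, gapOpening = gap_open,
        gapExtension = gap_extend, type = "global")
      score[i, j] <- score[j, i] <- Biostrings::score(pa)
    }
  }
  center <- which.max(rowSums(score))
  others <- setdiff(seq_len(n), center)
  alns <- lapply(others, function(j) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[center]]), Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = sm, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    list(center = as.character(Biostrings::alignedPattern(pa)),
         other = as.character(Biostrings::alignedSubject(pa)))
  })
  L <- nchar(seqs[[center]])
  M <- integer(L + 1L)
  for (a in alns) M <- pmax(M, center_ins_profile(a$center))

  rows <- character(n)
  cc <- chars(seqs[[center]])
  rows[center] <- paste(
    unlist(lapply(seq_len(L), function(j) c(rep("-", M[j]), cc[j]))),
    collapse = "")
  rows[center] <- paste0(rows[center], strrep("-", M[L + 1L]))
  for (k in seq_along(others)) {
    rows[others[k]] <- expand_to_master(alns[[k]]$center, alns[[k]]$other, M)
  }
  as_msa(stats::setNames(rows, ids))
}

#' Pairwise distances from a protein alignment
#'
#' For each pair, over columns where neither row has a gap:
#' `p = mismatches / compared`. `p_distance` returns `p`;
#' `kimura_protein` returns `-ln(1 - p - 0.2 p^2)` (errors at the
#' singularity). Pairs with zero comparable columns are an error.
#'
#' @param msa Named character vector of aligned rows.
#' @param model `"p_distance"` (default) or `"kimura_protein"`.
#' @return Symmetric numeric matrix with taxa dimnames, zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("p_distance", "kimura_protein")) {
  model <- match.arg(model)
  msa <- as_msa(msa)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(mat)
  taxa <- names(msa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(comp)) {
        stop("distance_matrix: no comparable columns for pair ",
             taxa[i], " / ", taxa[j])
      }
      p <- mean(mat[i, comp] != mat[j, comp])
      dij <- if (model == "p_distance") p else {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0) {
          stop("distance_matrix: Kimura correction undefined for pair ",
               taxa[i], " / ", taxa[j], " (p = ", round(p, 3), ")")
        }
        -log(arg)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing
#' `Q_ij = (n-2) d_ij - r_i - r_j`, with branch lengths from the
#' standard two-point formulas. Negative branch lengths are clipped to
#' zero with the deficit moved to the sister edge; Q ties break on the
#' lowest taxon-index pair. The result is unrooted, represented with a
#' trifurcating root.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (or `dist`),
#'   size >= 3.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("nj_tree: need >= 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("nj_tree: matrix must be symmetric with zero diagonal")
  }
  taxa <- rownames(dm) %||% paste0("t", seq_len(nrow(dm)))

  # Subtree newick fragments, grown bottom-up.
  sub <- as.list(taxa)
  D <- dm
  act <- seq_len(nrow(dm))  # original taxon indices, for tie-breaking
  fmt <- function(x) sprintf("%.12g", x)

  while (length(sub) > 3L) {
    na <- length(sub)
    r <- rowSums(D)
    Q <- (na - 2) * D - outer(r, r, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(act[hit[, 1]], act[hit[, 2]]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (na - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    merged <- paste0("(", sub[[i]], ":", fmt(li), ",",
                     sub[[j]], ":", fmt(lj), ")")
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    sub <- c(sub[keep], merged)
    act <- c(act[keep], min(act[c(i, j)]))
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[[1]], ":", fmt(max(la, 0)), ",",
                sub[[2]], ":", fmt(max(lb, 0)), ",",
                sub[[3]], ":", fmt(max(lc, 0)), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of a tree's internal nodes, in node order
# (root first). The side not containing the alphabetically first taxon
# is the key; the root's key is "" (trivial split).
tree_splits <- function(phy, taxa = sort(phy$tip.label)) {
  anchor <- taxa[1]
  pp <- ape::prop.part(phy)
  vapply(pp, function(ix) {
    side <- phy$tip.label[ix]
    if (anchor %in% side) side <- setdiff(taxa, side)
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement (same column count) for each
#' replicate, rebuilds the NJ tree, and records bipartitions. Each
#' internal edge of the reference tree gets support = 100 x (replicates
#' containing that bipartition) / n, rounded to the nearest integer and
#' stored in `node.label`. Replicate RNG streams are split by counter
#' (`seed + replicate`), so results are reproducible and independent of
#' evaluation order. Defaults honor the study settings: 1,000 replicates,
#' seed 111.
#'
#' @param msa Named character vector of aligned rows.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param model Distance model, see [distance_matrix()].
#' @return An `ape::phylo` tree; with fewer than 4 rows the plain NJ
#'   tree is returned without supports (no informative internal edge).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 111,
                              model = "p_distance") {
  stopifnot(n_replicates >= 1)
  msa <- as_msa(msa)
  ref <- nj_tree(distance_matrix(msa, model))
  if (length(msa) < 4L) return(ref)

  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(mat) <- names(msa)
  L <- ncol(mat)
  taxa <- sort(names(msa))
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- stats::setNames(
      apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""), names(msa))
    rep_tree <- nj_tree(distance_matrix(rep_msa, model))
    for (k in unique(tree_splits(rep_tree, taxa))) {
      if (!nzchar(k)) next
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  keys <- tree_splits(ref, taxa)
  ref$node.label <- vapply(keys, function(k) {
    if (!nzchar(k)) return("")
    as.character(as.integer(round(100 * (counts[[k]] %||% 0L) / n_replicates)))
  }, character(1), USE.NAMES = FALSE)
  ref
}
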