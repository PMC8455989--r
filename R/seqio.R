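# Sequence and tree input/output. Single home for format conventions:
# FASTA (plain and aligned), Newick, and the species-tag header dialect
# "Genus_species|id". '*' stop characters and lowercase are tolerated on
# input, never emitted on output.

#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased, `*` stop characters are stripped with a
#' warning, and each residue is validated against the chosen alphabet
#' (the 20 standard amino acids plus `X`, or `A/C/G/T/N`). When a header's
#' first whitespace-delimited token contains a `|`, the part before the
#' first `|` is taken as a species tag (e.g. `Skeletonema_marinoi|mc01`);
#' otherwise the species field is empty and the token is the id.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A tibble with columns `id`, `species`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("read_fasta: not valid FASTA: ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("read_fasta: no records in ", path)

  headers <- names(set)
  token <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  species <- ifelse(grepl("|", token, fixed = TRUE),
                    sub("\\|.*$", "", token), "")
  id <- token

  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("read_fasta: stripped '*' stop characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " record(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  seqs <- gsub("[ \t\r]", "", seqs)

  allowed <- if (alphabet == "protein") c(AA20, "X") else NUC5
  for (i in seq_along(seqs)) {
    cc <- chars(seqs[[i]])
    if (length(cc) == 0L) stop("read_fasta: empty sequence for record ", id[[i]])
    bad <- which(!cc %in% allowed)
    if (length(bad) > 0L) {
      stop("read_fasta: illegal character '", cc[bad[1]], "' in record ",
           id[[i]], " at position ", bad[1])
    }
  }
  if (anyDuplicated(id)) {
    stop("read_fasta: duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  tibble::tibble(id = id, species = species,
                 description = description, sequence = unname(seqs))
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with at least `id` and `sequence`; a non-empty
#'   `description` is appended to the header after a space.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  desc <- if ("description" %in% names(records)) records$description else ""
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[[i]]
    if (length(desc) > 1 && nzchar(desc[[i]])) hdr <- paste(hdr, desc[[i]])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as a multiple sequence alignment
#'
#' Stands in for importing an externally computed alignment (e.g. ClustalW
#' or MAFFT output). All rows must have equal length and there must be at
#' least two rows.
#'
#' @param path Path to aligned FASTA.
#' @return A named character vector (names = taxa, values = aligned rows
#'   over residues and `-`).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("read_alignment: need >= 2 aligned rows")
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  as_msa(rows)
}

#' Validate a named character vector as an alignment
#'
#' @param rows Named character vector of equal-length aligned strings.
#' @return `rows`, validated.
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("as_msa: rows must be named by taxon")
  }
  if (anyDuplicated(names(rows))) stop("as_msa: duplicate taxon ids")
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    bad <- names(rows)[w != stats::median(w)]
    stop("read_alignment: ragged rows for taxa: ", paste(bad, collapse = ", "))
  }
  if (w[[1]] < 1L) stop("as_msa: zero-column alignment")
  rows
}

#' Serialize a phylogenetic tree to Newick text
#'
#' Branch lengths are printed with six decimals and internal bootstrap
#' supports (from `node.label`) as integer internal node labels, the
#' format iTOL and standard parsers consume. The output always ends in
#' `;`.
#'
#' @param tree An `ape::phylo` object (branch lengths >= 0).
#' @param path Optional output file.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("write_newick: tree has no branch lengths")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- ntip + 1L
  seen <- integer(0)

  fmt <- function(x) sprintf("%.6f", x)
  build <- function(node) {
    if (node %in% seen) stop("write_newick: cyclic node structure")
    seen <<- c(seen, node)
    if (node <= ntip) return(tree$tip.label[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      paste0(build(child), ":", fmt(tree$edge.length[r]))
    }, character(1))
    lab <- ""
    if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (!is.na(l) && nzchar(l)) lab <- as.character(as.integer(round(as.numeric(l))))
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  out <- paste0(build(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse Newick text to a tree
#'
#' Thin wrapper over [ape::read.tree()]; the round-trip partner of
#' [write_newick()].
#'
#' @param text Newick string.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}
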