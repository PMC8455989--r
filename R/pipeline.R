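# End-to-end orchestration with config validation and stable report
# formats. Reports are TSV with '#'-prefixed metadata header lines
# (tool version and a config hash); intervals in reports are 1-based
# inclusive, per the package-wide convention.

pipeline_version <- function() {
  as.character(utils::packageVersion("twocys"))
}

report_header <- function(config) {
  c(paste0("# twocys ", pipeline_version()),
    paste0("# config_hash ", rlang::hash(config)))
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(report_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_config <- function(config, allowed) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  config
}

resolve_records <- function(config) {
  if (!is.null(config$records)) return(config$records)
  if (is.null(config$proteins)) stop("config: 'proteins' (FASTA path) or 'records' required")
  read_fasta(config$proteins, alphabet = "protein")
}

#' Run the annotation stage end to end
#'
#' Reads (or receives) protein records, annotates every protein
#' (p20/p10 domains, dyad, type, 2-Cys call), and summarizes per
#' species. With an `out_dir`, writes `annotations.tsv` and
#' `species_summary.tsv` (intervals 1-based inclusive, '#' metadata
#' header).
#'
#' @param config A list or YAML file path. Keys: `proteins` (FASTA
#'   path) or `records` (tibble, programmatic use); optional
#'   `reference` (FASTA path, first record used), `linker_threshold`,
#'   `p10_gap1` / `p10_gap2` (length-2), `p10_set`
#'   (`"refined"`/`"basis"`), `pssm_threshold_frac`, `seed_alignment`
#'   (aligned FASTA for the p20 profile), `dyad` (list `his`, `cys`,
#'   0-based profile columns), `out_dir`.
#' @return A list: `annotations`, `summary`,
#'   `two_cys_species_fraction`, invisibly the written paths in
#'   `paths`.
#' @export
run_annotate <- function(config) {
  config <- load_config(config, c(
    "proteins", "records", "reference", "linker_threshold", "p10_gap1",
    "p10_gap2", "p10_set", "pssm_threshold_frac", "seed_alignment",
    "dyad", "out_dir"))
  records <- resolve_records(config)
  if (nrow(records) == 0L) stop("run_annotate: no records")

  seed <- if (!is.null(config$seed_alignment)) {
    read_alignment(config$seed_alignment)
  } else p20_seed_msa()
  pssm <- build_pssm(seed,
                     threshold_frac = config$pssm_threshold_frac %||% 0.6)
  dyad <- if (!is.null(config$dyad)) {
    dyad_spec(config$dyad$his, config$dyad$cys)
  } else default_dyad()
  ref <- if (!is.null(config$reference)) {
    r <- read_fasta(config$reference, "protein")
    reference_spec(r$sequence[[1]])
  } else default_reference()
  p10_cfg <- p10_config(patterns = p10_patterns(config$p10_set %||% "refined"),
                        gap1 = config$p10_gap1 %||% c(0L, 40L),
                        gap2 = config$p10_gap2 %||% c(0L, 60L))

  ann <- annotate_proteins(records, pssm, dyad, p10_cfg, ref,
                           linker_threshold = config$linker_threshold %||% 50)
  summ <- summarize_species(ann)
  message("run_annotate: ", nrow(records), " proteins, ",
          sum(!is.na(ann$p20_start)), " with p20, ",
          sum(!is.na(ann$p10_start)), " with p10, ",
          sum(ann$two_cys_status == "both"), " 2-Cys")

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    rep_ann <- dplyr::mutate(ann,
      p20_start = .data$p20_start + 1L, p10_start = .data$p10_start + 1L)
    paths <- c(
      annotations = write_report_tsv(
        rep_ann, file.path(config$out_dir, "annotations.tsv"), config),
      summary = write_report_tsv(
        summ, file.path(config$out_dir, "species_summary.tsv"), config))
  }
  list(annotations = ann, summary = summ,
       two_cys_species_fraction = attr(summ, "two_cys_species_fraction"),
       paths = paths)
}

#' Run the phylogeny stage end to end
#'
#' Trims p20 domains from annotated proteins, aligns them (center-star,
#' or an imported alignment), computes distances, builds the
#' neighbor-joining tree, attaches bootstrap supports, and optionally
#' writes Newick.
#'
#' @param config A list or YAML file path. Keys: `records` +
#'   `annotations` (tibbles) or `proteins` (FASTA path, annotated with
#'   defaults); optional `alignment` (aligned FASTA path, skips
#'   trimming/alignment), `model` (`"p_distance"`/`"kimura_protein"`),
#'   `bootstrap` (default 1000), `seed` (default 111), `out` (Newick
#'   path).
#' @return The `ape::phylo` tree with `node.label` supports.
#' @export
run_tree <- function(config) {
  config <- load_config(config, c(
    "proteins", "records", "annotations", "alignment", "model",
    "bootstrap", "seed", "out"))
  model <- config$model %||% "p_distance"
  if (!is.null(config$alignment)) {
    msa <- read_alignment(config$alignment)
  } else {
    records <- resolve_records(config)
    ann <- config$annotations %||% annotate_proteins(records)
    p20 <- trim_p20(ann, records)
    if (nrow(p20) < 4L) stop("run_tree: need >= 4 annotated proteins with p20")
    msa <- center_star_msa(p20)
  }
  tree <- bootstrap_support(msa, n_replicates = config$bootstrap %||% 1000,
                            seed = config$seed %||% 111, model = model)
  if (!is.null(config$out)) {
    # Newick must stay parseable: metadata goes in a sidecar, not the tree.
    write_newick(tree, config$out)
    writeLines(report_header(config), paste0(config$out, ".meta"))
  }
  tree
}
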