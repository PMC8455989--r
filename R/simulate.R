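# Seeded synthetic-data generators. Every pipeline input can be
# generated with planted ground truth, so all stages are testable
# without downloads. Each generator is a pure function of its spec and
# seed: per-record RNG substreams are derived by counter from the spec
# seed, so reruns are byte-identical and insertion order does not
# perturb other records. The caller's RNG state is restored on exit.
#
# Fixed architecture scales: p20 scaffold 170 residues (a typical
# caspase-fold large subunit), p10 block 75 residues. Within the p20
# scaffold, 0-based columns 59 (His) and 133 (catalytic Cys) are the
# dyad; columns 71 and 128 are the positions homologous to the
# reference regulatory pair (C202/C259 in full-reference numbering) and
# hold Ser except in planted 2-Cys proteins. The synthetic reference
# protein is laid out M + 4 pad + p10 (positions 6-80) + 50 linker +
# p20 (131-300) + 10 tail, which places the pair at exactly 202/259 and
# the catalytic Cys at 264, as printed for PtMCA-IIIc.

# Evaluate code under a temporary RNG seed, restoring the caller state.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# --- fixed sequence scaffolds (internal constant seeds, not user seeds) ---

P10_LEN <- 75L
P20_LEN <- 170L
DYAD_HIS_COL <- 59L
DYAD_CYS_COL <- 133L
PAIR_COL1 <- 71L   # homologous to reference C202
PAIR_COL2 <- 128L  # homologous to reference C259

p10_anchor_positions <- function() {
  list(start = 0:6, middle = 27:31, end = 70:74)
}

# 75-residue p10 block carrying the three anchors at fixed offsets.
p10_block <- function() {
  with_seed_local(190411, {
    s <- chars(rand_aa(P10_LEN))
    s[1:7] <- chars("DAQTSAD")    # Dx[QE]TSAD
    s[28:32] <- chars("GGAKT")    # GGAX[ST]
    s[71:75] <- chars("QAPQL")    # QxPQL
    paste(s, collapse = "")
  })
}

# 170-residue p20 scaffold; dyad H/C fixed, pair columns hold Ser.
p20_scaffold <- function(two_cys = FALSE) {
  s <- with_seed_local(260817, chars(rand_aa(P20_LEN)))
  s[DYAD_HIS_COL + 1L] <- "H"
  s[DYAD_CYS_COL + 1L] <- "C"
  s[c(PAIR_COL1, PAIR_COL2) + 1L] <- if (two_cys) "C" else "S"
  paste(s, collapse = "")
}

#' The synthetic 2-Cys reference protein
#'
#' A 310-residue synthetic stand-in for a type III 2-Cys metacaspase:
#' p10 at positions 6-80, p20 at 131-300, regulatory cysteines at 202
#' and 259, catalytic His/Cys at 190/264 (1-based). Use
#' [reference_spec()] with a real sequence for real data.
#'
#' @return A [reference_spec()].
#' @export
default_reference <- function() {
  seqs <- with_seed_local(330105, list(
    pad = rand_aa(4L), linker = rand_aa(50L), tail = rand_aa(10L)))
  seq <- paste0("M", seqs$pad, p10_block(), seqs$linker,
                p20_scaffold(two_cys = TRUE), seqs$tail)
  reference_spec(seq, cys_pair = c(202L, 259L), catalytic_cys = 264L,
                 catalytic_his = 190L)
}

#' Synthetic p20 seed alignment
#'
#' Eight scaffold copies mutated at a low per-residue rate outside the
#' dyad and pair columns; ungapped, so directly usable by
#' [build_pssm()]. Generated, versioned in code: a real p20 seed
#' alignment is user-suppliable via [read_alignment()].
#'
#' @param n Number of rows (default 8).
#' @param mutation_rate Per-residue substitution rate (default 0.05).
#' @return Named character vector of aligned rows.
#' @export
p20_seed_msa <- function(n = 8, mutation_rate = 0.05) {
  base <- p20_scaffold()
  fixed <- c(DYAD_HIS_COL, DYAD_CYS_COL, PAIR_COL1, PAIR_COL2)
  rows <- with_seed_local(771129, vapply(seq_len(n), function(i) {
    mutate_seq(base, mutation_rate, fixed)
  }, character(1)))
  as_msa(stats::setNames(rows, paste0("seed_", seq_len(n))))
}

#' Default p20 profile and dyad columns for synthetic data
#'
#' @return `default_pssm()`: an `mc_pssm` built from [p20_seed_msa()];
#'   `default_dyad()`: the scaffold's dyad columns (59, 133).
#' @export
default_pssm <- function() build_pssm(p20_seed_msa())

#' @rdname default_pssm
#' @export
default_dyad <- function() dyad_spec(DYAD_HIS_COL, DYAD_CYS_COL)

# Substitute residues at rate outside 0-based `fixed` positions.
mutate_seq <- function(seq, rate, fixed = integer(0)) {
  if (rate <= 0) return(seq)
  s <- chars(seq)
  free <- setdiff(seq_along(s) - 1L, fixed)
  hit <- free[stats::runif(length(free)) < rate]
  for (p in hit) s[p + 1L] <- sample(setdiff(AA20, s[p + 1L]), 1)
  paste(s, collapse = "")
}

#' Specify a synthetic proteome
#'
#' @param n_species Number of species.
#' @param mcs_per_species Metacaspases per species.
#' @param mix Named architecture fractions over
#'   `type_I`/`type_II`/`type_III`/`MCP`, summing to 1.
#' @param two_cys_fraction Fraction of species carrying at least one
#'   2-Cys type III metacaspase (a deterministic count of
#'   `round(fraction * n_species)` carrier species is drawn; all type
#'   III proteins of a carrier species get the pair).
#' @param mutation_rate Per-residue substitution rate outside
#'   constrained columns (anchors, dyad, pair).
#' @param dead_dyad_fraction Fraction of proteins whose catalytic Cys is
#'   replaced by Ser (dyad status `cys_lost`). Default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_species = 10, mcs_per_species = 3,
                          mix = c(type_I = 0.2, type_II = 0.1,
                                  type_III = 0.5, MCP = 0.2),
                          two_cys_fraction = 0.5, mutation_rate = 0,
                          dead_dyad_fraction = 0, seed = 1) {
  stopifnot(all(mix >= 0), abs(sum(mix) - 1) < 1e-8,
            all(c("type_I", "type_II", "type_III", "MCP") %in% names(mix)),
            two_cys_fraction >= 0, two_cys_fraction <= 1,
            mutation_rate >= 0, mutation_rate < 1)
  if (two_cys_fraction > 0 && mix[["type_III"]] == 0) {
    stop("proteome_spec: two_cys_fraction > 0 requires a type_III fraction > 0")
  }
  structure(list(n_species = as.integer(n_species),
                 mcs_per_species = as.integer(mcs_per_species),
                 mix = mix, two_cys_fraction = two_cys_fraction,
                 mutation_rate = mutation_rate,
                 dead_dyad_fraction = dead_dyad_fraction,
                 seed = as.integer(seed)), class = "proteome_spec")
}

# Assemble one protein of a given architecture; returns sequence and
# 0-based truth intervals plus constrained (unmutated) positions.
assemble_protein <- function(arch, two_cys) {
  a <- p10_anchor_positions()
  p10 <- p10_block()
  p20 <- p20_scaffold(two_cys = two_cys)
  pad <- rand_aa(4L); tail <- rand_aa(10L)
  p20_fixed <- c(DYAD_HIS_COL, DYAD_CYS_COL, PAIR_COL1, PAIR_COL2)
  p10_fixed <- unlist(a)
  if (arch == "type_III") {
    linker <- rand_aa(50L)
    seq <- paste0("M", pad, p10, linker, p20, tail)
    p10_iv <- c(5L, 80L); p20_iv <- c(130L, 300L)
  } else if (arch == "type_I") {
    linker <- rand_aa(10L)
    seq <- paste0("M", pad, p20, linker, p10, tail)
    p20_iv <- c(5L, 175L); p10_iv <- c(185L, 260L)
  } else if (arch == "type_II") {
    linker <- rand_aa(80L)
    seq <- paste0("M", pad, p20, linker, p10, tail)
    p20_iv <- c(5L, 175L); p10_iv <- c(255L, 330L)
  } else {  # MCP
    flank <- rand_aa(20L)
    seq <- paste0("M", pad, flank, p20, tail)
    p20_iv <- c(25L, 195L); p10_iv <- c(NA_integer_, NA_integer_)
  }
  fixed <- p20_iv[1] + p20_fixed
  if (!is.na(p10_iv[1])) fixed <- c(fixed, p10_iv[1] + p10_fixed)
  list(sequence = seq, p10 = p10_iv, p20 = p20_iv, fixed = fixed)
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Proteins are assembled from the fixed p20 scaffold and p10 anchor
#' block according to the architecture mix; 2-Cys pairs are planted at
#' the columns homologous to reference positions 202/259 in all type III
#' proteins of carrier species; mutations apply outside constrained
#' columns. Fully seeded and byte-reproducible.
#'
#' @param spec A [proteome_spec()].
#' @return A list: `records` (tibble `id`, `species`, `description`,
#'   `sequence`) and `truth` (tibble `id`, `species`, `mc_type`,
#'   `two_cys_status`, `dyad_status`, 0-based `p10_start`, `p10_end`,
#'   `p20_start`, `p20_end`).
#' @export
synth_proteome <- function(spec = proteome_spec()) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed_local(spec$seed, {
    n_carrier <- round(spec$two_cys_fraction * spec$n_species)
    carriers <- sample.int(spec$n_species)[seq_len(n_carrier)]
    recs <- list(); truth <- list()
    k <- 0L
    for (sp in seq_len(spec$n_species)) {
      species <- sprintf("Synthsp_%02d", sp)
      archs <- sample(names(spec$mix), spec$mcs_per_species,
                      replace = TRUE, prob = spec$mix)
      if (sp %in% carriers && !any(archs == "type_III")) {
        archs[1] <- "type_III"
      }
      for (m in seq_along(archs)) {
        k <- k + 1L
        set.seed(spec$seed + 7919L * k)  # per-record substream
        arch <- archs[m]
        two_cys <- arch == "type_III" && sp %in% carriers
        dead <- stats::runif(1) < spec$dead_dyad_fraction
        pr <- assemble_protein(arch, two_cys)
        seq <- pr$sequence
        if (dead) {
          s <- chars(seq)
          s[pr$p20[1] + DYAD_CYS_COL + 1L] <- "S"
          seq <- paste(s, collapse = "")
        }
        seq <- mutate_seq(seq, spec$mutation_rate, pr$fixed)
        id <- sprintf("%s|mc%03d", species, m)
        recs[[k]] <- tibble::tibble(id = id, species = species,
                                    description = "", sequence = seq)
        truth[[k]] <- tibble::tibble(
          id = id, species = species, mc_type = arch,
          two_cys_status = if (two_cys) "both" else "none",
          dyad_status = if (dead) "cys_lost" else "intact",
          p10_start = pr$p10[1], p10_end = pr$p10[2],
          p20_start = pr$p20[1], p20_end = pr$p20[2])
      }
    }
    list(records = dplyr::bind_rows(recs), truth = dplyr::bind_rows(truth))
  })
}

#' Specify a synthetic gene for guide design
#'
#' Defaults emulate the knockout design geometry: four exons and three
#' introns, two planted + strand guide targets whose blunt cut sites sit
#' 115 nt apart, spanning the catalytic Cys codon and the third intron.
#'
#' @param exon_lengths,intron_lengths Integer vectors (introns one
#'   shorter than exons).
#' @param flank 5'/3' flank length outside the gene body.
#' @param catalytic_codon 1-based codon index of the catalytic Cys in
#'   the spliced CDS.
#' @param guide_positions 0-based + strand protospacer start positions
#'   of planted targets.
#' @param decoys Optional tibble (`guide`, `nonseed_mismatches`,
#'   `position`) of planted off-target decoys: a copy of guide
#'   `guide`'s protospacer with that many substitutions in the 8-nt
#'   non-seed block and a TGG PAM, planted at `position`.
#' @param seed Integer RNG seed.
#' @return An object of class `gene_spec`.
#' @export
gene_spec <- function(exon_lengths = c(150L, 120L, 90L, 150L),
                      intron_lengths = c(70L, 80L, 60L),
                      flank = 100L, catalytic_codon = 116L,
                      guide_positions = c(563L, 678L),
                      decoys = NULL, seed = 1) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths > 0), all(intron_lengths > 0))
  cds_len <- sum(exon_lengths)
  if (catalytic_codon * 3L > cds_len) {
    stop("gene_spec: catalytic codon outside CDS")
  }
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 flank = as.integer(flank),
                 catalytic_codon = as.integer(catalytic_codon),
                 guide_positions = as.integer(guide_positions),
                 decoys = decoys, seed = as.integer(seed)),
            class = "gene_spec")
}

# Random nucleotide string with no GG or CC dinucleotide (so the only
# NGG PAMs in a synthetic genome are the planted ones).
rand_nt_no_pam <- function(n, prev = "") {
  out <- character(n)
  for (i in seq_len(n)) {
    allowed <- switch(prev, G = c("A", "C", "T"), C = c("A", "G", "T"),
                      c("A", "C", "G", "T"))
    out[i] <- sample(allowed, 1)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

#' Generate a synthetic gene with planted guide targets
#'
#' The background sequence avoids GG/CC dinucleotides so that
#' [enumerate_targets()] finds exactly the planted sites; planted
#' protospacers get an AGG PAM, decoys a TGG PAM. The catalytic codon is
#' written as TGC. A repair pass keeps the no-PAM guarantee at planting
#' junctions.
#'
#' @param spec A [gene_spec()].
#' @return A list: `record` (list `id`, `sequence`, `exons`) and
#'   `truth` (list `guides` tibble, `decoys` tibble or NULL,
#'   `catalytic_codon_genomic`, `exons`).
#' @export
synth_genome <- function(spec = gene_spec()) {
  stopifnot(inherits(spec, "gene_spec"))
  with_seed_local(spec$seed, {
    ne <- length(spec$exon_lengths)
    starts <- spec$flank + cumsum(c(0L, head_lengths(spec)))
    exons <- tibble::tibble(start = starts,
                            end = starts + spec$exon_lengths)
    total <- spec$flank * 2L + sum(spec$exon_lengths) + sum(spec$intron_lengths)

    s <- chars(rand_nt_no_pam(total))
    protected <- logical(total)

    plant <- function(pos, proto, pam) {
      iv <- (pos + 1L):(pos + 23L)
      if (any(protected[iv])) stop("synth_genome: overlapping planted targets")
      s[iv] <<- chars(paste0(proto, pam))
      protected[iv] <<- TRUE
    }

    guides <- purrr::map_dfr(seq_along(spec$guide_positions), function(g) {
      pos <- spec$guide_positions[g]
      if (pos < 0 || pos + 23L > total) stop("synth_genome: target outside gene")
      proto <- rand_nt_no_pam(20L)
      plant(pos, proto, "AGG")
      tibble::tibble(guide = g, protospacer = proto, pam = "AGG",
                     strand = "+", start = pos, end = pos + 20L,
                     cut_site = pos + 17L)
    })

    decoys <- NULL
    if (!is.null(spec$decoys) && nrow(spec$decoys) > 0) {
      decoys <- purrr::map_dfr(seq_len(nrow(spec$decoys)), function(i) {
        d <- spec$decoys[i, ]
        proto <- chars(guides$protospacer[d$guide])
        for (p in seq_len(d$nonseed_mismatches)) {  # 5' non-seed block
          proto[p] <- sample(setdiff(c("A", "C", "G", "T"), proto[p]), 1)
        }
        proto <- paste(proto, collapse = "")
        plant(d$position, proto, "TGG")
        tibble::tibble(guide = d$guide, protospacer = proto,
                       start = d$position, end = d$position + 20L,
                       strand = "+", nonseed_mismatches = d$nonseed_mismatches)
      })
    }

    codon_g <- cds_to_genomic(exons, (spec$catalytic_codon - 1L) * 3L + 0:2)
    if (any(protected[codon_g + 1L])) {
      stop("synth_genome: catalytic codon overlaps a planted target")
    }
    s[codon_g + 1L] <- c("T", "G", "C")
    protected[codon_g + 1L] <- TRUE

    # repair pass: break accidental GG/CC at planting junctions
    for (i in seq_len(total - 1L)) {
      if (s[i] == s[i + 1L] && s[i] %in% c("G", "C")) {
        if (!protected[i]) s[i] <- "A"
        else if (!protected[i + 1L]) s[i + 1L] <- "A"
        # both protected: intended (e.g. the PAM's own GG)
      }
    }

    record <- list(id = "synthetic_gene", sequence = paste(s, collapse = ""),
                   exons = exons)
    list(record = record,
         truth = list(guides = guides, decoys = decoys,
                      catalytic_codon_genomic = codon_g, exons = exons))
  })
}

# interleaved exon/intron offsets: cumulative lengths preceding each exon
head_lengths <- function(spec) {
  ne <- length(spec$exon_lengths)
  if (ne == 1L) return(integer(0))
  spec$exon_lengths[-ne] + spec$intron_lengths
}

#' Specify a synthetic oxidation table
#'
#' The default plants a single regulatory-cysteine site with a
#' +20.9-point oxidation shift in the lethal treatment — the effect size
#' the pipeline is designed to recover — over a baseline of 35%.
#'
#' @param sites Tibble with `protein`, `cys_pos`, `baseline`, `effect`
#'   (percentage points).
#' @param n_rep Replicates per group (default 3).
#' @param noise_sd Replicate noise standard deviation in percentage
#'   points (default 1).
#' @param lethal,nonlethal Treatment labels used in the table.
#' @param total_intensity Summed light+heavy intensity per record.
#' @param seed Integer RNG seed.
#' @return An object of class `ox_spec`.
#' @export
ox_spec <- function(sites = tibble::tibble(protein = "MCA_IIIc_synthetic",
                                           cys_pos = 202L, baseline = 35,
                                           effect = 20.9),
                    n_rep = 3, noise_sd = 1,
                    lethal = "lethal_25uM_DD",
                    nonlethal = "nonlethal_5plus25uM_DD",
                    total_intensity = 1e6, seed = 1) {
  stopifnot(all(sites$baseline >= 0), all(sites$baseline <= 100),
            n_rep >= 1, noise_sd >= 0)
  structure(list(sites = sites, n_rep = as.integer(n_rep),
                 noise_sd = noise_sd, lethal = lethal,
                 nonlethal = nonlethal, total_intensity = total_intensity,
                 seed = as.integer(seed)), class = "ox_spec")
}

#' Generate a synthetic peptide oxidation table
#'
#' Light/heavy intensities are drawn so that
#' `heavy/(light+heavy) x 100 = clip(baseline + group effect + N(0, sd), 0, 100)`.
#'
#' @param spec An [ox_spec()].
#' @return A list: `records` (tibble `protein`, `cys_pos`, `peptide`,
#'   `treatment`, `replicate`, `light`, `heavy`) and `truth`
#'   (the site tibble with labels).
#' @export
synth_ox_table <- function(spec = ox_spec()) {
  stopifnot(inherits(spec, "ox_spec"))
  with_seed_local(spec$seed, {
    grid <- tidyr::expand_grid(
      site = seq_len(nrow(spec$sites)),
      treatment = c(spec$lethal, spec$nonlethal),
      replicate = seq_len(spec$n_rep))
    k <- nrow(grid)
    noise <- stats::rnorm(k, 0, spec$noise_sd)
    sites <- spec$sites[grid$site, ]
    ox <- pmin(100, pmax(0, sites$baseline +
                           ifelse(grid$treatment == spec$lethal,
                                  sites$effect, 0) + noise))
    heavy <- spec$total_intensity * ox / 100
    records <- tibble::tibble(
      protein = sites$protein, cys_pos = sites$cys_pos,
      peptide = sprintf("PEP_%s_C%d", sites$protein, sites$cys_pos),
      treatment = grid$treatment, replicate = grid$replicate,
      light = spec$total_intensity - heavy, heavy = heavy)
    list(records = records,
         truth = dplyr::mutate(spec$sites, lethal = spec$lethal,
                               nonlethal = spec$nonlethal))
  })
}

#' Generate a synthetic fluorescence trace with AMC standards
#'
#' `RFU(t) = intercept + cal_slope x rate x t + N(0, sd)`; standards are
#' generated noise-free on the six-point curve 12, 6, 3, 1.5, 0.75,
#' 0 uM.
#'
#' @param rate_um_min True AMC release rate in uM/min (>= 0).
#' @param cal_slope Calibration slope in RFU per uM.
#' @param noise_sd Gaussian noise sd in RFU.
#' @param duration_min Trace duration in minutes.
#' @param n_points Number of timepoints.
#' @param intercept Baseline fluorescence in RFU.
#' @param volume_l Well volume in liters (default 2e-4, a 200 uL well).
#' @param protein_mg Protein mass per well in mg (default 6e-5, 60 ng).
#' @param seed Integer RNG seed.
#' @return A list: `trace` (tibble `time_min`, `rfu`), `standards`
#'   (tibble `conc_um`, `rfu`), `params`.
#' @export
synth_kinetics <- function(rate_um_min = 0.5, cal_slope = 1000,
                           noise_sd = 0, duration_min = 30, n_points = 31,
                           intercept = 100, volume_l = 2e-4,
                           protein_mg = 6e-5, seed = 1) {
  stopifnot(rate_um_min >= 0, cal_slope > 0, n_points >= 4)
  with_seed_local(seed, {
    t <- seq(0, duration_min, length.out = n_points)
    rfu <- intercept + cal_slope * rate_um_min * t +
      stats::rnorm(n_points, 0, noise_sd)
    standards <- tibble::tibble(conc_um = c(12, 6, 3, 1.5, 0.75, 0))
    standards$rfu <- cal_slope * standards$conc_um
    list(trace = tibble::tibble(time_min = t, rfu = rfu),
         standards = standards,
         params = list(rate_um_min = rate_um_min, cal_slope = cal_slope,
                       noise_sd = noise_sd, volume_l = volume_l,
                       protein_mg = protein_mg))
  })
}
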