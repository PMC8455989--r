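test_that("synth_proteome is a pure function of spec and seed", {
  spec <- proteome_spec(n_species = 4, mcs_per_species = 2, seed = 99)
  a <- synth_proteome(spec)
  b <- synth_proteome(spec)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$records, f1); write_fasta(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
  c <- synth_proteome(proteome_spec(n_species = 4, mcs_per_species = 2, seed = 100))
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("generators restore the caller's RNG state", {
  set.seed(1234)
  before <- .Random.seed
  invisible(synth_proteome(proteome_spec(n_species = 2, seed = 5)))
  invisible(synth_genome(gene_spec(seed = 5)))
  invisible(synth_ox_table(ox_spec(seed = 5)))
  invisible(synth_kinetics(seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("proteome spec validation catches impossible mixes", {
  expect_error(proteome_spec(mix = c(type_I = 0.5, type_II = 0.5,
                                     type_III = 0, MCP = 0),
                             two_cys_fraction = 0.5),
               "type_III")
  expect_error(proteome_spec(mix = c(type_I = 0.5, type_II = 0.6,
                                     type_III = 0, MCP = 0)))
})

test_that("planted truth intervals are exact at zero noise", {
  sim <- synth_proteome(proteome_spec(
    n_species = 6, mcs_per_species = 3,
    mix = c(type_I = 0.25, type_II = 0.25, type_III = 0.25, MCP = 0.25),
    two_cys_fraction = 0.5, mutation_rate = 0, seed = 21))
  for (i in seq_len(nrow(sim$records))) {
    tr <- sim$truth[i, ]
    seq <- sim$records$sequence[[i]]
    p20 <- find_p20(seq, default_pssm(), default_dyad())
    expect_equal(p20$start, tr$p20_start)
    expect_equal(p20$dyad_status, tr$dyad_status)
    p10 <- find_p10(seq)
    if (is.na(tr$p10_start)) {
      expect_equal(nrow(p10), 0L)
    } else {
      expect_equal(c(p10$start, p10$end), c(tr$p10_start, tr$p10_end))
    }
  }
})

test_that("carrier species fraction is planted deterministically", {
  spec <- proteome_spec(n_species = 50, mcs_per_species = 2,
                        two_cys_fraction = 0.62, seed = 3)
  sim <- synth_proteome(spec)
  carriers <- sim$truth |>
    dplyr::group_by(species) |>
    dplyr::summarise(has = any(two_cys_status == "both"))
  expect_equal(sum(carriers$has), round(0.62 * 50))
})

test_that("p20/p10 recall holds at 10% mutation across seeds", {
  p10_recalled <- 0L; p10_total <- 0L
  for (s in 1:5) {
    sim <- synth_proteome(proteome_spec(
      n_species = 4, mcs_per_species = 3,
      mix = c(type_I = 0.2, type_II = 0.2, type_III = 0.4, MCP = 0.2),
      two_cys_fraction = 0.5, mutation_rate = 0.10, seed = 1000 + s))
    for (i in seq_len(nrow(sim$records))) {
      tr <- sim$truth[i, ]
      seq <- sim$records$sequence[[i]]
      p20 <- find_p20(seq, default_pssm(), default_dyad())
      expect_true(any(p20$start == tr$p20_start))  # p20 recall 1.0
      if (!is.na(tr$p10_start)) {
        p10_total <- p10_total + 1L
        hits <- find_p10(seq)
        if (nrow(hits) > 0 && any(hits$start == tr$p10_start)) {
          p10_recalled <- p10_recalled + 1L
        }
      }
    }
  }
  expect_gte(p10_recalled / p10_total, 0.95)
})

test_that("synth_genome plants exactly the configured targets", {
  sg <- synth_genome(gene_spec(seed = 8))
  hits <- enumerate_targets(sg$record)
  expect_equal(hits$start, sg$truth$guides$start)
  expect_equal(hits$protospacer, sg$truth$guides$protospacer)
  expect_equal(hits$cut_site, sg$truth$guides$cut_site)
  # background is PAM-free by construction: no GG/CC outside planted sites
  expect_identical(synth_genome(gene_spec(seed = 8))$record$sequence,
                   sg$record$sequence)
  expect_error(synth_genome(gene_spec(guide_positions = c(100L, 110L))),
               "overlapping")
})

test_that("the default gene geometry encodes the excision design", {
  sg <- synth_genome(gene_spec())
  g <- sg$truth$guides
  expect_equal(diff(g$cut_site), 115L)
  de <- design_excision(sg$record, g[1, ], g[2, ], 116)
  expect_true(de$removes_catalytic_cys)
  # catalytic codon is written as TGC (Cys) at its genomic span
  cg <- sg$truth$catalytic_codon_genomic
  expect_equal(substr(sg$record$sequence, cg[1] + 1, cg[3] + 1), "TGC")
  # the third intron lies inside the deletion
  i3 <- c(sg$truth$exons$end[3], sg$truth$exons$start[4])
  expect_true(i3[1] >= de$deletion_start && i3[2] <= de$deletion_end)
})

test_that("synth_ox_table at zero noise yields the planted effect exactly", {
  ox <- synth_ox_table(ox_spec(noise_sd = 0))
  d <- delta_oxidation(ox$records, ox$truth$lethal[1], ox$truth$nonlethal[1])
  expect_equal(d$delta_ox, 20.9)
  expect_equal(d$mean_nonlethal, 35)
  expect_identical(synth_ox_table(ox_spec(noise_sd = 0))$records, ox$records)
})

test_that("null oxidation tables give a calibrated false-positive rate", {
  sites <- tibble::tibble(protein = sprintf("p%04d", 1:800),
                          cys_pos = 1L, baseline = 50, effect = 0)
  ox <- synth_ox_table(ox_spec(sites = sites, noise_sd = 2, seed = 77))
  d <- delta_oxidation(ox$records, ox$truth$lethal[1], ox$truth$nonlethal[1])
  rate <- mean(d$p_value < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("synth_kinetics traces recover the planted rate", {
  kin <- synth_kinetics(rate_um_min = 0.5, noise_sd = 0)
  cal <- fit_calibration(kin$standards)
  act <- compute_activity(kin$trace, cal, kin$params$volume_l,
                          kin$params$protein_mg)
  expect_equal(act$rate_um_min, 0.5, tolerance = 1e-12)
  # inhibited (rate 0) vs uninhibited: 100% inhibition
  k0 <- synth_kinetics(rate_um_min = 0, noise_sd = 0)
  a0 <- compute_activity(k0$trace, cal, 2e-4, 6e-5)
  expect_equal(inhibition_percent(a0$activity_umol_min_mg,
                                  act$activity_umol_min_mg), 100)
  expect_identical(synth_kinetics(seed = 2)$trace, synth_kinetics(seed = 2)$trace)
})
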