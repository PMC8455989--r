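test_that("trim_p20 extracts the p20 interval and excludes p20-less proteins", {
  records <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c(random_protein(400), random_protein(100), random_protein(200)))
  ann <- tibble::tibble(
    id = c("a", "b", "c"), species = "s",
    p20_start = c(130L, NA, 30L), p20_end = c(330L, NA, 200L))
  expect_warning(out <- trim_p20(ann, records), "excluded 1")
  expect_equal(out$id, c("a", "c"))
  expect_equal(nchar(out$sequence), c(200L, 170L))
  expect_equal(out$sequence[1], substr(records$sequence[1], 131, 330))
  # interval reaching the sequence end
  ann2 <- tibble::tibble(id = "b", species = "s",
                         p20_start = 50L, p20_end = 100L)
  out2 <- trim_p20(ann2, records)
  expect_equal(out2$sequence, substr(records$sequence[2], 51, 100))
})

test_that("center_star_msa picks the max-sum center and merges gaps", {
  recs <- tibble::tibble(id = c("r1", "r2", "r3"),
                         sequence = c("ACDE", "ACE", "ACDE"))
  msa <- center_star_msa(recs)
  expect_equal(unname(msa), c("ACDE", "AC-E", "ACDE"))
  # identical records: no gaps
  same <- tibble::tibble(id = c("a", "b"), sequence = rep("MKVLW", 2))
  expect_equal(unname(center_star_msa(same)), c("MKVLW", "MKVLW"))
  expect_error(center_star_msa(same[1, ]), ">= 2")
})

test_that("center-star column count is at least the longest record", {
  set.seed(9)
  for (i in 1:5) {
    recs <- tibble::tibble(
      id = paste0("r", 1:4),
      sequence = vapply(1:4, function(j) random_protein(sample(30:60, 1)),
                        character(1)))
    msa <- center_star_msa(recs)
    expect_true(all(nchar(msa) == nchar(msa[1])))
    expect_gte(nchar(msa[1]), max(nchar(recs$sequence)))
  }
})

test_that("distance_matrix computes p and Kimura distances", {
  msa <- as_msa(c(a = "AAAA", b = "AATA"))
  expect_equal(unname(distance_matrix(msa)["a", "b"]), 0.25)
  expect_equal(unname(distance_matrix(msa, "kimura_protein")["a", "b"]),
               -log(1 - 0.25 - 0.2 * 0.25^2), tolerance = 1e-12)
  expect_equal(-log(1 - 0.25 - 0.2 * 0.25^2), 0.30449, tolerance = 1e-4)
  # identical rows: zero under both models
  two <- as_msa(c(a = "MKV", b = "MKV"))
  expect_equal(unname(distance_matrix(two)["a", "b"]), 0)
  expect_equal(unname(distance_matrix(two, "kimura_protein")["a", "b"]), 0)
  # gapped columns are skipped pairwise
  g <- as_msa(c(a = "A-CD", b = "AACA"))
  expect_equal(unname(distance_matrix(g)["a", "b"]), 1 / 3)
  # zero comparable columns / singularity errors name the pair
  bad <- as_msa(c(a = "A--", b = "-AA", c = "AAA"))
  expect_error(distance_matrix(bad), "a / b")
  far <- as_msa(c(a = "AAAA", b = "CCCC"))
  expect_error(distance_matrix(far, "kimura_protein"), "Kimura")
})

test_that("nj_tree reproduces the 3-taxon closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  expect_equal(write_newick(tr), "(A:1.000000,B:1.000000,C:3.000000);")
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3")
})

test_that("nj_tree recovers the 4-taxon additive tree exactly", {
  taxa <- c("A", "B", "C", "D")
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  dm["A", "B"] <- 3; dm["A", "C"] <- 5; dm["A", "D"] <- 6
  dm["B", "C"] <- 6; dm["B", "D"] <- 7; dm["C", "D"] <- 7
  dm <- dm + t(dm)
  tr <- nj_tree(dm)
  # split AB|CD with internal edge 1 and leaf edges 1,2,3,4
  expect_true(same_topology(tr, ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")))
  pm <- cophenetic(tr)[taxa, taxa]
  expect_equal(pm, dm, tolerance = 1e-12)
})

test_that("nj_tree is consistent on random additive matrices", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    gen <- random_additive(n)
    tr <- nj_tree(gen$dm)
    expect_true(same_topology(tr, gen$tree), label = paste("case", i))
    pm <- cophenetic(tr)[rownames(gen$dm), colnames(gen$dm)]
    expect_lt(max(abs(pm - gen$dm)), 1e-9)
  }
})

test_that("nj_tree agrees in topology with the ape reference implementation", {
  set.seed(78)
  for (i in 1:10) {
    gen <- random_additive(sample(5:10, 1))
    expect_true(same_topology(nj_tree(gen$dm), ape::nj(gen$dm)))
  }
})

test_that("negative branch estimates are clipped with deficit to the sister", {
  # a strongly non-additive matrix known to produce negative NJ limbs
  taxa <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 1, 6, 6,
                 1, 0, 6, 6,
                 6, 6, 0, 1,
                 6, 6, 1, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is 100 for a conflict-free clade", {
  msa <- as_msa(c(
    A = paste0(strrep("A", 10), strrep("C", 10)),
    B = paste0(strrep("A", 10), strrep("C", 10)),
    C = paste0(strrep("A", 10), strrep("G", 10)),
    D = paste0(strrep("A", 10), strrep("T", 10))))
  tr <- bootstrap_support(msa, n_replicates = 50, seed = 111)
  labs <- tr$node.label[nzchar(tr$node.label)]
  expect_equal(labs, "100")
})

test_that("single-replicate supports are 0 or 100; same seed reproduces", {
  set.seed(55)
  rows <- vapply(1:6, function(i) random_protein(40), character(1))
  # relate rows so the tree has internal structure
  rows[2] <- rows[1]; rows[4] <- rows[3]
  msa <- as_msa(stats::setNames(
    vapply(rows, function(r) chartr("X", "A", r), character(1), USE.NAMES = FALSE),
    paste0("t", 1:6)))
  t1 <- bootstrap_support(msa, n_replicates = 1, seed = 111)
  expect_true(all(t1$node.label[nzchar(t1$node.label)] %in% c("0", "100")))
  t2 <- bootstrap_support(msa, n_replicates = 25, seed = 111)
  t3 <- bootstrap_support(msa, n_replicates = 25, seed = 111)
  expect_identical(t2$node.label, t3$node.label)
  expect_identical(write_newick(t2), write_newick(t3))
})

test_that("supports lie in [0,100] and output Newick round-trips", {
  set.seed(91)
  msa <- as_msa(stats::setNames(
    vapply(1:5, function(i) random_protein(60), character(1)), paste0("t", 1:5)))
  tr <- bootstrap_support(msa, n_replicates = 20, seed = 7)
  sup <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(sup >= 0 & sup <= 100))
  back <- read_newick(write_newick(tr))
  expect_true(same_topology(tr, back))
})

test_that("adding clade-private columns never decreases that clade's support", {
  set.seed(13)
  base <- random_protein(30)
  mk <- function(k_private) {
    rows <- c(A = base, B = base, C = base, D = base)
    s <- strsplit(base, "")[[1]]
    # diverge C and D everywhere to create noise
    rows["C"] <- random_protein(30)
    rows["D"] <- random_protein(30)
    # k private identical columns for {A,B}
    rows <- vapply(rows, function(r) {
      paste0(r, strrep("W", k_private))
    }, character(1))
    rows["C"] <- paste0(substr(rows["C"], 1, 30), strrep("P", k_private))
    rows["D"] <- paste0(substr(rows["D"], 1, 30), strrep("G", k_private))
    as_msa(rows)
  }
  sup_of <- function(msa) {
    tr <- bootstrap_support(msa, n_replicates = 30, seed = 111)
    sp <- tr$node.label[nzchar(tr$node.label)]
    if (length(sp) == 0) 0 else max(as.numeric(sp))
  }
  sups <- vapply(c(2, 8, 20), function(k) sup_of(mk(k)), double(1))
  expect_true(all(diff(sups) >= 0))
})
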