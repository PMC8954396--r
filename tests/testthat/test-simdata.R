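test_that("simulate_reference honors sizes and is deterministic", {
  p <- sim_params(n_contigs = 19L, total_ref_len = 906223L, rng_seed = 3)
  a <- simulate_reference(p, seed = 3)
  expect_equal(nrow(a$index$contigs), 19L)
  expect_equal(ref_total_length(a$index), 906223L)
  expect_true(all(a$index$contigs$length >= 200L))
  b <- simulate_reference(p, seed = 3)
  expect_identical(a$seqs, b$seqs)
  expect_error(simulate_reference(sim_params(n_contigs = 10L,
                                             total_ref_len = 1000L)),
               "infeasible")
})

test_that("zero-length branches copy the reference; no indels, no gaps", {
  tr <- read_newick(text = "((a:0,b:0):0,c:0);")
  p <- sim_params(n_contigs = 1L, total_ref_len = 2000L, tree = tr,
                  rng_seed = 5, indel_rate = 0)
  refobj <- simulate_reference(p, seed = 5)
  sim <- evolve_alignment(refobj, tr, p, seed = 6)
  for (t in c("a", "b", "c")) {
    expect_identical(unname(sim$leaf_calls[t, ]), refobj$concat)
  }
  expect_equal(nrow(sim$indels$events), 0L)
  expect_equal(ncol(sim$aln$mat), 2000L)
})

test_that("per-branch substitution counts follow the Poisson mean", {
  tr <- read_newick(text = "(a:0.01,b:0);")
  p <- sim_params(n_contigs = 1L, total_ref_len = 100000L, tree = tr,
                  rng_seed = 1, indel_rate = 0)
  refobj <- simulate_reference(p, seed = 1)
  counts <- vapply(1:6, function(s) {
    sim <- evolve_alignment(refobj, tr, p, seed = s)
    sum(sim$leaf_calls["a", ] != refobj$concat)
  }, 0)
  # mean of 6 draws from Pois(1000): sd = sqrt(1000/6) ~ 12.9
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 6))
})

test_that("indel_rate = 0 yields a gap-free alignment", {
  res <- quick_capture(8, indel_rate = 0)
  expect_false(any(res$sim$aln$mat == "-"))
  expect_equal(ncol(res$sim$aln$mat), 6000L)
})

test_that("capture mask: no dropout means fully scored; seeds reproduce", {
  res <- quick_capture(9)
  samples <- lapply(res$samples, mask_low_coverage, threshold = 20)
  built <- build_alignment(samples, res$refobj$index)
  sf <- vapply(aln_taxa(built$aln), function(t) scored_fraction(built$aln, t),
               0)
  expect_true(all(sf == 1))
  res2 <- quick_capture(9)
  expect_identical(res$sim$aln$mat, res2$sim$aln$mat)
  expect_identical(lapply(res$samples, `[[`, "coverage"),
                   lapply(res2$samples, `[[`, "coverage"))
})

test_that("scored fraction decreases with divergence from the reference", {
  # a non-clock tree so root-to-tip divergences actually vary (on an
  # ultrametric tree every taxon is equidistant from the reference); a
  # pooled rank test over >= 20 taxa and 10 seeds must come out negative
  div_all <- c(); sf_all <- c()
  for (s in 1:10) {
    set.seed(s + 20)
    tr <- ape::rtree(20)
    tr$edge.length <- tr$edge.length * 0.06 /
      max(ape::node.depth.edgelength(tr))
    res <- quick_capture(s + 20, tree = tr, len = 8000L,
                         dropout_base = 0.05, dropout_slope = 10,
                         indel_rate = 0.1)
    samples <- lapply(res$samples, mask_low_coverage, threshold = 20)
    built <- build_alignment(samples, res$refobj$index)
    taxa <- setdiff(aln_taxa(built$aln), "REF")
    sf <- vapply(taxa, function(t) scored_fraction(built$aln, t), 0)
    div_all <- c(div_all, res$sim$divergence[taxa])
    sf_all <- c(sf_all, sf)
  }
  ct <- suppressWarnings(cor.test(div_all, sf_all, method = "spearman",
                                  alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("expected scored fraction tracks the dropout model within 5 pp", {
  # expectation, not a single realization: with ~60 windows per sample the
  # per-sample dropout fraction still varies, so average across samples
  res <- quick_capture(31, n_taxa = 8L, len = 60000L, depth = 0.04,
                       dropout_base = 0.2, dropout_slope = 0,
                       indel_rate = 0, dropout_window_mean = 1000)
  samples <- lapply(res$samples, mask_low_coverage, threshold = 20)
  built <- build_alignment(samples, res$refobj$index)
  taxa <- setdiff(aln_taxa(built$aln), "REF")
  sf <- vapply(taxa, function(t) scored_fraction(built$aln, t), 0)
  expect_lt(abs(mean(sf) - 0.8), 0.05)
})

test_that("introgression: f = 0 is a no-op; f = 1 copies the donor", {
  res <- quick_capture(12, tree = abba_tree(), len = 8000L)
  sim0 <- inject_introgression(res$sim, list(list(
    donor = c("c1", "c2"), recipient = c("a1", "a2"), f = 0)))
  expect_identical(sim0$aln$mat, res$sim$aln$mat)
  expect_length(sim0$introgressed_cols, 0L)
  sim1 <- inject_introgression(res$sim, list(list(
    donor = c("c1", "c2"), recipient = c("a1", "a2"), f = 1)), seed = 1)
  cols <- sim1$introgressed_cols
  expect_gt(length(cols), 0L)
  for (t in c("a1", "a2")) {
    expect_identical(sim1$aln$mat[t, cols], sim1$aln$mat["c1", cols])
  }
  expect_error(inject_introgression(res$sim, list(list(
    donor = c("a1", "c1"), recipient = c("a1", "a2"), f = 0.5))),
    "overlap")
})

test_that("transferred column fraction matches binomial expectation", {
  hits <- 0L; total <- 0L
  for (s in 1:8) {
    res <- quick_capture(40 + s, tree = abba_tree(), len = 8000L)
    all_elig <- length(inject_introgression(
      res$sim, list(list(donor = c("c1", "c2"),
                         recipient = c("a1", "a2"), f = 1)),
      seed = 1)$introgressed_cols)
    got <- length(inject_introgression(
      res$sim, list(list(donor = c("c1", "c2"),
                         recipient = c("a1", "a2"), f = 0.3)),
      seed = 1)$introgressed_cols)
    hits <- hits + got; total <- total + all_elig
  }
  # 99% binomial interval around 0.3
  p_hat <- hits / total
  expect_lt(abs(p_hat - 0.3), 2.58 * sqrt(0.3 * 0.7 / total) + 1e-9)
})

test_that("segregating sites grow with total tree length", {
  snps <- vapply(c(0.01, 0.04, 0.12), function(depth) {
    mean(vapply(1:3, function(s) {
      res <- quick_capture(60 + s, n_taxa = 6L, len = 5000L, depth = depth,
                           indel_rate = 0)
      count_snps(res$sim$aln)
    }, 0))
  }, 0)
  expect_true(all(diff(snps) > 0))
})
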