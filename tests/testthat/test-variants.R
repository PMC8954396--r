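# independent naive oracle: explicit per-column scan
naive_count_snps <- function(aln, taxa) {
  n <- 0L
  for (j in seq_len(ncol(aln$mat))) {
    states <- unique(aln$mat[taxa, j])
    states <- states[states %in% c("A", "C", "G", "T")]
    if (length(states) >= 2L) n <- n + 1L
  }
  n
}

naive_pair_dist <- function(aln, m, a, b) {
  nd <- 0L; id <- 0L
  for (j in seq_len(ncol(aln$mat))) {
    x <- aln$mat[a, j]; y <- aln$mat[b, j]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T") &&
        x != y) nd <- nd + 1L
  }
  for (k in seq_len(ncol(m$states))) {
    x <- m$states[a, k]; y <- m$states[b, k]
    if (x != "?" && y != "?" && x != y) id <- id + 1L
  }
  c(nd, id)
}

test_that("count_snps matches hand cases and the naive oracle", {
  aln <- mk_aln(a = "ACGT", b = "ACGA", c = "?CGA")
  expect_equal(count_snps(aln), 1L)
  expect_equal(count_snps(mk_aln(a = "ACGT", b = "ACGT")), 0L)
  expect_error(count_snps(aln, character(0)), "empty")
  for (s in 1:3) {
    res <- quick_capture(80 + s, n_taxa = 10L, len = 4000L, depth = 0.05)
    taxa <- sample(aln_taxa(res$sim$aln), 6L)
    expect_equal(count_snps(res$sim$aln, taxa),
                 naive_count_snps(res$sim$aln, taxa))
  }
})

test_that("count_indel_events needs both states in the subset", {
  m <- mk_indels(c(a = "110", b = "11?", c = "100"))
  expect_equal(count_indel_events(m, c("a", "b")), 0L)       # 11, 11, 0?
  expect_equal(count_indel_events(m, c("a", "c")), 1L)
  expect_equal(count_indel_events(m), 1L)
  empty <- indel_matrix(
    data.frame(contig = character(), start = integer(), end = integer(),
               type = character(), seq = character()),
    matrix(character(), 2L, 0L, dimnames = list(c("a", "b"), NULL)))
  expect_equal(count_indel_events(empty, c("a", "b")), 0L)
})

test_that("intraspecific polymorphisms pool SNPs and indel events", {
  aln <- mk_aln(a = "ACGTACGT", b = "ACGAAGCT")  # 3 nucleotide diffs
  m <- mk_indels(c(a = "1", b = "0"))            # 1 shared-vs-absent indel
  expect_equal(intraspecific_polymorphisms(aln, m, c("a", "b")), 4L)
  expect_equal(intraspecific_polymorphisms(
    mk_aln(a = "ACGT", b = "ACGT"), mk_indels(c(a = "1", b = "1")),
    c("a", "b")), 0L)
  expect_error(intraspecific_polymorphisms(aln, m, "a"), "at least 2")
})

test_that("sibling-pair polymorphism count equals the truth path count", {
  # two leaves joined at a shallow node; with no dropout the pairwise
  # mutation count equals the substitutions + indels on the connecting path
  tr <- read_newick(text = "((s1:0.004,s2:0.004):0.02,out:0.024);")
  res <- quick_capture(91, tree = tr, len = 10000L, indel_rate = 0.2)
  sim <- res$sim
  e <- sim$tree$edge
  tips <- match(c("s1", "s2"), sim$tree$tip.label)
  path_edges <- which(e[, 2L] %in% tips)
  n_sub <- sum(sim$branch_subs[path_edges])
  n_ind <- sum(vapply(sim$events, function(ev) {
    setequal(intersect(ev$clade, c("s1", "s2")), "s1") ||
      setequal(intersect(ev$clade, c("s1", "s2")), "s2")
  }, TRUE))
  got <- intraspecific_polymorphisms(sim$aln, sim$indels, c("s1", "s2"))
  # back substitutions can only reduce the observed count
  expect_lte(got, n_sub + n_ind)
  expect_gte(got, round(0.9 * (n_sub + n_ind)))
})

test_that("group_distances: hand example, singleton diagonal, oracle", {
  aln <- mk_aln(a1 = "AAAA", a2 = "GGCC", b1 = "AATT")
  m <- mk_indels(c(a1 = "0", a2 = "0", b1 = "0"))
  gd <- group_distances(aln, m, list(A = c("a1", "a2"), B = "b1"))
  expect_equal(gd$nuc["A", "B"], 3)      # a1-b1 = 2, a2-b1 = 4
  expect_equal(gd$nuc["B", "B"], 0)
  expect_equal(gd$nuc["A", "A"], 4)
  expect_true(isSymmetric(gd$nuc))
  expect_error(group_distances(aln, m, list(A = c("a1", "b1"), B = "b1")),
               "overlapping")
  res <- quick_capture(92, n_taxa = 9L, len = 4000L)
  taxa <- aln_taxa(res$sim$aln)
  groups <- list(g1 = taxa[1:3], g2 = taxa[4:6], g3 = taxa[7:8])
  gd2 <- group_distances(res$sim$aln, res$sim$indels, groups)
  for (gi in names(groups)) for (gj in names(groups)) {
    pairs <- if (gi == gj) combn(groups[[gi]], 2, simplify = FALSE) else
      unlist(lapply(groups[[gi]], function(a) lapply(groups[[gj]],
                                                     function(b) c(a, b))),
             recursive = FALSE)
    d <- vapply(pairs, function(p) naive_pair_dist(res$sim$aln,
                                                   res$sim$indels,
                                                   p[1], p[2]), numeric(2))
    expect_equal(gd2$nuc[gi, gj], mean(d[1, ]))
    expect_equal(gd2$indel[gi, gj], mean(d[2, ]))
  }
})

test_that("count_snps invariant to row order and fully-missing taxa", {
  res <- quick_capture(93, n_taxa = 6L, len = 3000L)
  aln <- res$sim$aln
  taxa <- aln_taxa(aln)
  base <- count_snps(aln, taxa)
  expect_equal(count_snps(aln, rev(taxa)), base)
  aln2 <- aln
  aln2$mat <- rbind(aln$mat, ghost = rep("?", ncol(aln$mat)))
  expect_equal(count_snps(aln2, c(taxa, "ghost")), base)
})

test_that("raw mean differences dominate normalized x comparable count", {
  res <- quick_capture(94, n_taxa = 6L, len = 4000L, dropout_base = 0.3,
                       dropout_slope = 0)
  samples <- lapply(res$samples, mask_low_coverage, 20)
  built <- build_alignment(samples, res$refobj$index)
  taxa <- aln_taxa(built$aln)
  gd <- group_distances(built$aln, built$indels,
                        list(g1 = taxa[1:3], g2 = taxa[4:6]))
  n_min <- min(vapply(taxa[1:3], function(a) {
    min(vapply(taxa[4:6], function(b) {
      sum(built$aln$mat[a, ] %in% c("A", "C", "G", "T") &
            built$aln$mat[b, ] %in% c("A", "C", "G", "T"))
    }, 0))
  }, 0))
  expect_gte(gd$nuc["g1", "g2"] + 1e-9,
             gd$nuc_per_site["g1", "g2"] * n_min)
})

test_that("variant_summary aggregates consistently", {
  res <- quick_capture(95)
  vs <- variant_summary(res$sim$aln, res$sim$indels)
  expect_equal(vs$n_snp_sites, count_snps(res$sim$aln))
  expect_equal(vs$n_indel_events, count_indel_events(res$sim$indels))
  expect_equal(vs$alignment_length, ncol(res$sim$aln$mat))
  expect_true(all(vs$scored_fraction >= 0 & vs$scored_fraction <= 1))
})
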