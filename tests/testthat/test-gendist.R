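# Haplotype distances, AMOVA Phi-st, permutation tests and distance-matrix
# comparison.

test_that("haplotype distance kernels match hand values", {
  p <- marker_panel("p", c("A", "B"))
  spec <- hap_dist_spec(panel = p)
  h1 <- c(A = 14, B = 10)
  expect_equal(haplotype_distance(h1, h1, spec), 0)
  expect_equal(haplotype_distance(h1, c(A = 16, B = 10), spec), 4)
  expect_equal(haplotype_distance(h1, c(A = 15, B = 13), spec), 10)  # 1 + 9
  ham <- hap_dist_spec("hamming", p)
  expect_equal(haplotype_distance(h1, c(A = 16, B = 10), ham), 1)
  expect_error(haplotype_distance(h1, c(A = 16), spec), "missing")
})

test_that("Phi-st equals the brute-force AMOVA oracle on toy instances", {
  for (seed in 1:8) {
    set.seed(300 + seed)
    nA <- sample(3:10, 1); nB <- sample(3:10, 1)
    tb <- make_table(list(
      A = data.frame(L1 = sample(10:14, nA, TRUE),
                     L2 = sample(10:14, nA, TRUE)),
      B = data.frame(L1 = sample(12:16, nB, TRUE),
                     L2 = sample(12:16, nB, TRUE))))
    got <- pairwise_phist(tb, "A", "B")
    mat <- as.matrix(as.data.frame(tb)[, c("L1", "L2")])
    want <- oracle_phist(mat, tb$population)
    expect_equal(got, want, tolerance = 1e-10)
    # symmetric in the pair
    expect_equal(pairwise_phist(tb, "B", "A"), got)
    expect_lte(got, 1)
  }
})

test_that("Phi-st limits: identical populations <= 0, monomorphic-disjoint
           populations = 1", {
  block <- data.frame(L1 = c(12L, 13L, 14L, 12L), L2 = c(10L, 11L, 10L, 12L))
  same <- make_table(list(A = block, B = block))
  expect_lte(pairwise_phist(same, "A", "B"), 0)

  mono <- make_table(list(
    A = data.frame(L1 = rep(12L, 4), L2 = rep(10L, 4)),
    B = data.frame(L1 = rep(15L, 4), L2 = rep(13L, 4))))
  expect_equal(pairwise_phist(mono, "A", "B"), 1)

  tiny <- make_table(list(A = data.frame(L1 = 12L),
                          B = data.frame(L1 = c(13L, 14L))))
  expect_error(pairwise_phist(tiny, "A", "B"), ">= 2 haplotypes")
})

test_that("permutation test is seeded, pair-order invariant, and bounded
           below by 1/(n_perm+1)", {
  tb <- make_table(list(
    A = data.frame(L1 = rep(12L, 6), L2 = rep(10L, 6)),
    B = data.frame(L1 = rep(18L, 6), L2 = rep(16L, 6))))
  r1 <- permutation_test(tb, "A", "B", n_perm = 200, seed = 42)
  r2 <- permutation_test(tb, "A", "B", n_perm = 200, seed = 42)
  expect_identical(r1, r2)
  # strongly diverged: p at the attainable minimum
  expect_equal(r1$p_value, 1 / 201)
  # stream depends on the sorted pair, not the argument order
  r3 <- permutation_test(tb, "B", "A", n_perm = 200, seed = 42)
  expect_identical(r1, r3)
  # different seed gives a different stream but the same observed statistic
  r4 <- permutation_test(tb, "A", "B", n_perm = 200, seed = 43)
  expect_equal(r4$phist, r1$phist)
})

test_that("distance matrices are symmetric, zero-diagonal and consistent
           with one-at-a-time calls", {
  tb <- random_table(npop = 4, n = 8, nloc = 3, seed = 77)
  panel <- marker_panel("p", c("L1", "L2", "L3"))
  dm <- distance_matrix(tb, panel, n_perm = 50, seed = 5)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 4))
  expect_true(all(dm$p[upper.tri(dm$p)] >= 0 & dm$p[upper.tri(dm$p)] <= 1))
  spec <- hap_dist_spec(panel = panel)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dm$d[i, j],
                 pairwise_phist(tb, dm$populations[i], dm$populations[j],
                                spec))
  # deterministic under a fixed seed
  dm2 <- distance_matrix(tb, panel, n_perm = 50, seed = 5)
  expect_identical(dm, dm2)
})

test_that("three identical populations give no differentiation signal", {
  block <- data.frame(L1 = c(12L, 13L, 14L, 15L, 12L, 13L),
                      L2 = c(10L, 10L, 11L, 12L, 11L, 10L))
  tb <- make_table(list(A = block, B = block, C = block))
  dm <- distance_matrix(tb, marker_panel("p", c("L1", "L2")),
                        n_perm = 100, seed = 3)
  expect_true(all(dm$d[upper.tri(dm$d)] <= 0))
})

test_that("matrix comparison fractions match a hand count and order pairs by
           ascending reference distance", {
  tb <- random_table(npop = 5, n = 10, nloc = 4, seed = 12)
  pA <- marker_panel("big", c("L1", "L2", "L3", "L4"))
  pB <- marker_panel("small", c("L1", "L2"))
  ref <- distance_matrix(tb, pB, n_perm = 0, seed = 1)
  alt <- distance_matrix(tb, pA, n_perm = 0, seed = 1)
  cm <- compare_distance_matrices(ref, alt)
  expect_equal(cm$frac_increased + cm$frac_decreased + cm$frac_tied, 1)
  expect_true(!is.unsorted(cm$pairs$d_ref))
  # brute-force count over aligned pairs
  inc <- 0; dec <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    dlt <- alt$d[i, j] - ref$d[i, j]
    if (dlt > 1e-12) inc <- inc + 1 else if (dlt < -1e-12) dec <- dec + 1
  }
  expect_equal(cm$frac_increased, inc / 10)
  expect_equal(cm$frac_decreased, dec / 10)

  # trivial cases
  expect_equal(compare_distance_matrices(ref, ref)$frac_tied, 1)
  shifted <- ref
  shifted$d <- ref$d + 0.01
  diag(shifted$d) <- 0
  expect_equal(compare_distance_matrices(ref, shifted)$frac_increased, 1)
  # population mismatch rejected
  sub <- distance_matrix(make_table(list(
    X = data.frame(L1 = c(12L, 13L, 12L)),
    Y = data.frame(L1 = c(14L, 15L, 15L)))),
    marker_panel("p", "L1"), n_perm = 0)
  expect_error(compare_distance_matrices(ref, sub), "different population")
})

test_that("distance matrices serialize to PHYLIP and long TSV", {
  tb <- random_table(npop = 3, n = 6, nloc = 2, seed = 4)
  dm <- distance_matrix(tb, marker_panel("p", c("L1", "L2")),
                        n_perm = 20, seed = 2)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(dm, phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(dm, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 3)  # C(3,2)
  expect_equal(back$distance, as.data.frame(dm)$distance)
})
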