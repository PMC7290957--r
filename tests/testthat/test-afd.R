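# Allele frequencies, the AFD statistic, mAFD ranking, sliding panels and
# the mAFD / mutation-rate correlation.

spec_of <- function(freqs, locus = "L", pop = "A") {
  structure(list(locus = locus, population = pop, freqs = freqs,
                 n_samples = 100L), class = "afd_spectrum")
}

test_that("allele frequencies are empirical relative frequencies", {
  tbl <- make_table(list(P1 = data.frame(DYS392 = c(13L, 13L, 14L, 15L))))
  sp <- allele_frequencies(tbl, "DYS392", "P1")
  expect_equal(sp$freqs, c(`13` = 0.5, `14` = 0.25, `15` = 0.25))
  expect_equal(sp$n_samples, 4)

  one <- make_table(list(P1 = data.frame(DYS392 = 14L)))
  expect_equal(allele_frequencies(one, "DYS392", "P1")$freqs, c(`14` = 1))

  set.seed(11)
  rt <- random_table(npop = 2, n = 17, nloc = 2, seed = 11)
  for (p in c("P1", "P2"))
    expect_equal(sum(allele_frequencies(rt, "L1", p)$freqs), 1)

  expect_error(allele_frequencies(tbl, "DYS392", "nope"), "empty")
  expect_error(allele_frequencies(tbl, "bogus", "P1"), "unknown locus")
})

test_that("AFD matches hand evaluations and rejects locus mismatch", {
  s <- spec_of(c(`13` = 0.5, `14` = 0.5))
  expect_equal(afd(s, s), 0)
  # disjoint allele sets
  expect_equal(afd(spec_of(c(`13` = 1)), spec_of(c(`15` = 1), pop = "B")), 1)
  # half-overlap case: 0.5*(|1-0.5| + |0-0.5|)
  expect_equal(afd(spec_of(c(`14` = 1)),
                   spec_of(c(`14` = 0.5, `15` = 0.5), pop = "B")), 0.5)
  expect_error(afd(spec_of(c(`14` = 1), locus = "L1"),
                   spec_of(c(`14` = 1), locus = "L2")), "different loci")
})

test_that("AFD bounds, symmetry and the L1 triangle inequality hold on
           random spectra (property)", {
  set.seed(202)
  for (i in 1:200) {
    a <- random_spectrum("L", "A")
    b <- random_spectrum("L", "B")
    c_ <- random_spectrum("L", "C")
    ab <- afd(a, b)
    expect_gte(ab, 0)
    expect_lte(ab, 1)
    expect_equal(ab, afd(b, a))
    expect_equal(ab, oracle_afd(as.list(a$freqs), as.list(b$freqs)))
    expect_lte(afd(a, c_), afd(a, b) + afd(b, c_) + 1e-12)
  }
})

test_that("mAFD equals the brute-force double loop and is invariant to
           relabeling (property)", {
  # 2 populations: mean of one pair
  t2 <- random_table(npop = 2, n = 10, seed = 5)
  m2 <- mafd(t2, "L1")
  expect_equal(m2$n_pairs, 1)
  expect_equal(m2$mafd, oracle_mafd(as.data.frame(t2), "L1"))

  # 3 identical populations: mAFD 0
  block <- data.frame(L1 = c(12L, 13L, 13L, 14L))
  t3 <- make_table(list(A = block, B = block, C = block))
  expect_equal(mafd(t3, "L1")$mafd, 0)

  # up to 5 populations vs the oracle
  for (seed in 1:6) {
    npop <- 2 + (seed %% 4)
    tb <- random_table(npop = npop, n = 6 + seed, nloc = 3, seed = 100 + seed)
    for (l in c("L1", "L3")) {
      got <- mafd(tb, l)
      expect_equal(got$n_pairs, choose(npop, 2))
      expect_equal(got$mafd, oracle_mafd(as.data.frame(tb), l),
                   tolerance = 1e-12)
    }
    # relabeling populations and permuting locus columns changes nothing
    df <- as.data.frame(tb)
    df$population <- paste0("X", match(df$population, unique(df$population)))
    relab <- haplotype_table(df[, c("sample", "population",
                                    rev(table_loci(tb)))])
    expect_equal(mafd(relab, "L1")$mafd, mafd(tb, "L1")$mafd)
  }
  expect_error(mafd(make_table(list(A = data.frame(L1 = 1:3))), "L1"),
               "2 populations")
})

test_that("mafd_table ranks descending with deterministic tie-breaks and
           cross-checks per-locus mafd", {
  tb <- random_table(npop = 3, n = 12, nloc = 4, seed = 9)
  panel <- marker_panel("p", c("L1", "L2", "L3", "L4"))
  mt <- mafd_table(tb, panel)
  expect_equal(nrow(mt$rows), 4)
  expect_true(all(diff(mt$rows$mafd) <= 0))
  for (k in seq_len(4))
    expect_equal(mt$rows$mafd[k], mafd(tb, mt$rows$locus[k])$mafd)
  # ties break lexicographically by locus name
  block <- data.frame(Lb = c(12L, 13L), La = c(12L, 13L))
  tt <- make_table(list(A = block, B = block))
  mtt <- mafd_table(tt, marker_panel("t", c("Lb", "La")))
  expect_equal(mtt$rows$locus, c("La", "Lb"))
})

test_that("packaged reference ranking has the published extremes", {
  ref <- reference_mafd()
  expect_equal(nrow(ref$rows), 23)
  expect_equal(ref$rows$locus[1], "DYS392")
  expect_equal(ref$rows$mafd[1], 0.3802)
  expect_equal(ref$rows$locus[23], "YGATAH4")
  expect_equal(ref$rows$mafd[23], 0.1845)
  expect_true(all(ref$rows$mutation_rate > 0 & ref$rows$mutation_rate < 1))
})

test_that("sliding panels window the descending ranking", {
  ref <- reference_mafd()
  sp <- sliding_panels(ref, window = 15, step = 1)
  expect_equal(length(sp$panels), 9)  # 23 - 15 + 1
  expect_equal(sp$panels[[1]]$loci, ref$rows$locus[1:15])
  expect_equal(sp$panels[[9]]$loci, ref$rows$locus[9:23])
  expect_equal(names(sp$panels)[c(1, 9)], c("top_15", "min_15"))
  # every panel is the previous one shifted by the step
  for (k in 2:9)
    expect_equal(sp$panels[[k]]$loci, sp$ranking[k:(k + 14)])
  # degenerate window = all loci
  sp1 <- sliding_panels(ref, window = 23)
  expect_equal(length(sp1$panels), 1)
  expect_equal(sp1$panels[[1]]$loci, ref$rows$locus)
  expect_error(sliding_panels(ref, window = 24), "exceeds")
})

test_that("the top-15 reference panel contains exactly 9 Yfiler loci", {
  sp <- sliding_panels(reference_mafd(), window = 15)
  yf <- builtin_panels()$yfiler$loci
  expect_equal(sum(sp$panels$top_15$loci %in% yf), 9)
  expect_equal(sum(!sp$panels$top_15$loci %in% yf), 6)
})

test_that("mAFD/mutation-rate correlation matches first-principles formulas
           and flags degenerate input", {
  ref <- reference_mafd()
  res <- mafd_rate_correlation(ref)
  x <- ref$rows$mafd; y <- ref$rows$mutation_rate
  expect_equal(res$pearson_r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(res$spearman_rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_false(res$degenerate)

  # rates proportional to mAFD: r = 1
  prop <- ref
  prop$rows$mutation_rate <- 0.01 * prop$rows$mafd
  expect_equal(mafd_rate_correlation(prop)$pearson_r, 1)

  # constant rates: zero variance, flagged
  const <- ref
  const$rows$mutation_rate <- 0.003
  degen <- mafd_rate_correlation(const)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$pearson_r))
})
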