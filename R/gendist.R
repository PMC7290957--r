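# AMOVA-based pairwise genetic distances between populations with
# permutation p-values, and distance-matrix comparison across marker panels.

#' Haplotype distance specification
#'
#' Controls the inter-haplotype distance underlying the AMOVA. The default
#' `sum_squared_size_diff` sums squared repeat-count differences over the
#' panel loci, giving an Rst-analogue Phi-st appropriate for STRs under the
#' stepwise mutation model. `hamming` counts differing loci, giving an
#' Fst-analogue.
#'
#' @param metric `"sum_squared_size_diff"` (default) or `"hamming"`.
#' @param panel A [marker_panel] restricting the loci used.
#' @return An object of class `hap_dist_spec`.
#' @export
hap_dist_spec <- function(metric = c("sum_squared_size_diff", "hamming"),
                          panel) {
  metric <- match.arg(metric)
  stopifnot(inherits(panel, "marker_panel"))
  structure(list(metric = metric, panel = panel), class = "hap_dist_spec")
}

#' Distance between two haplotypes
#'
#' @param h1,h2 Named numeric vectors of integer allele calls (names are
#'   locus names) covering all panel loci.
#' @param spec A [hap_dist_spec].
#' @return Non-negative scalar; 0 iff the haplotypes agree on every panel
#'   locus.
#' @export
#' @examples
#' p <- marker_panel("p", c("DYS392", "DYS391"))
#' haplotype_distance(c(DYS392 = 14, DYS391 = 10),
#'                    c(DYS392 = 16, DYS391 = 10),
#'                    hap_dist_spec(panel = p))  # 4
haplotype_distance <- function(h1, h2, spec) {
  stopifnot(inherits(spec, "hap_dist_spec"))
  loci <- spec$panel$loci
  if (!all(loci %in% names(h1)) || !all(loci %in% names(h2)))
    stop("haplotypes missing panel loci")
  a <- as.numeric(h1[loci]); b <- as.numeric(h2[loci])
  if (anyNA(a) || anyNA(b)) stop("haplotypes must be integer-valued")
  switch(spec$metric,
         sum_squared_size_diff = sum((a - b)^2),
         hamming = sum(a != b))
}

# All-pairs squared-difference matrix of haplotypes (rows = samples,
# columns = panel loci). AMOVA consumes these entries directly as the
# squared inter-haplotype deviations.
.hap_dist_matrix <- function(mat, metric) {
  n <- nrow(mat)
  D <- matrix(0, n, n)
  if (metric == "sum_squared_size_diff") {
    for (l in seq_len(ncol(mat))) {
      d <- outer(mat[, l], mat[, l], "-")
      D <- D + d * d
    }
  } else {
    for (l in seq_len(ncol(mat)))
      D <- D + (outer(mat[, l], mat[, l], "!=") * 1)
  }
  D
}

# Two-level AMOVA Phi-st from a squared-distance matrix D and a list of
# index vectors (one per population). Standard variance-component
# estimators: SSD(T) from all pairs, SSD(W) within populations,
# sigma2_w = SSD(W)/(N-P), sigma2_a = (MSD(A) - sigma2_w)/n_c.
.phist_from_D <- function(D, groups) {
  N <- sum(lengths(groups))
  P <- length(groups)
  ssd_t <- sum(D) / (2 * N)
  ssd_w <- 0
  for (idx in groups)
    ssd_w <- ssd_w + sum(D[idx, idx, drop = FALSE]) / (2 * length(idx))
  ssd_a <- ssd_t - ssd_w
  df_a <- P - 1L
  df_w <- N - P
  if (df_w <= 0L) stop("AMOVA needs more haplotypes than populations")
  sigma_w <- ssd_w / df_w
  n_c <- (N - sum(lengths(groups)^2) / N) / df_a
  sigma_a <- (ssd_a / df_a - sigma_w) / n_c
  denom <- sigma_a + sigma_w
  if (denom == 0) return(0)
  sigma_a / denom
}

#' Pairwise Phi-st between two populations
#'
#' Two-level analysis of molecular variance (AMOVA) on the inter-haplotype
#' distance matrix of the pooled samples:
#' \deqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}
#' with among- and within-population variance components from the standard
#' sum-of-squared-deviation estimators. With the default squared
#' repeat-count distance this is the Rst-analogue commonly reported for STR
#' haplotype data. Estimates can be slightly negative when the among-
#' population component estimate is negative; they are returned as computed.
#'
#' @param table A QC'd [haplotype_table].
#' @param popA,popB Population ids, each with at least 2 haplotypes.
#' @param spec A [hap_dist_spec]; defaults to squared-size-difference over
#'   all table loci.
#' @return Phi-st estimate (<= 1, possibly slightly negative).
#' @export
pairwise_phist <- function(table, popA, popB, spec = NULL) {
  pd <- .pair_setup(table, popA, popB, spec)
  .phist_from_D(pd$D, pd$groups)
}

# shared setup: pooled allele matrix, distances, group index vectors
.pair_setup <- function(table, popA, popB, spec) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(spec))
    spec <- hap_dist_spec(panel = marker_panel("all", table_loci(table)))
  sel <- table$population %in% c(popA, popB)
  pop <- table$population[sel]
  nA <- sum(pop == popA); nB <- sum(pop == popB)
  if (nA < 2L || nB < 2L)
    stop("both populations need >= 2 haplotypes (", popA, ": ", nA, ", ",
         popB, ": ", nB, ")")
  loci <- spec$panel$loci
  missing <- setdiff(loci, table_loci(table))
  if (length(missing))
    stop("panel loci absent from table: ", paste(missing, collapse = ", "))
  mat <- as.matrix(as.data.frame(table)[sel, loci, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("allele calls must be complete; run qc_filter()")
  D <- .hap_dist_matrix(mat, spec$metric)
  list(D = D, groups = list(which(pop == popA), which(pop == popB)),
       nA = nA, nB = nB)
}

#' Permutation test of population differentiation
#'
#' Builds the null distribution of Phi-st by randomly reassigning the pooled
#' haplotypes to the two populations (keeping sample sizes) `n_perm` times.
#' The p-value uses the add-one estimator
#' `p = (#{perm >= observed} + 1) / (n_perm + 1)`, so the attainable minimum
#' is `1/(n_perm + 1)`. The random stream is derived from `seed` and the
#' sorted pair of population ids, making matrices reproducible regardless of
#' the order in which pairs are computed.
#'
#' @inheritParams pairwise_phist
#' @param n_perm Number of permutations (>= 1); analyses of record
#'   typically use 10,000.
#' @param seed Integer seed.
#' @return List with `phist` (observed) and `p_value`.
#' @export
permutation_test <- function(table, popA, popB, spec = NULL,
                             n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pd <- .pair_setup(table, popA, popB, spec)
  obs <- .phist_from_D(pd$D, pd$groups)
  n <- pd$nA + pd$nB
  old <- .pair_rng(seed, popA, popB)
  on.exit(.restore_rng(old))
  count <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    g <- list(idx[seq_len(pd$nA)], idx[pd$nA + seq_len(pd$nB)])
    if (.phist_from_D(pd$D, g) >= obs - 1e-12) count <- count + 1L
  }
  list(phist = obs, p_value = (count + 1) / (n_perm + 1))
}

# Deterministic per-pair RNG stream: seed the global RNG from a hash of
# (seed, sorted pair ids); returns the previous RNG state for restoration.
.pair_rng <- function(seed, popA, popB) {
  pair <- paste(sort(c(as.character(popA), as.character(popB))),
                collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(pair)) h <- (h * 131 + code) %% 2147483647
  derived <- as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %%
                          2147483647)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(derived)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' All-pairs Phi-st distance matrix with permutation p-values
#'
#' @param table A QC'd [haplotype_table] with >= 2 populations.
#' @param panel A [marker_panel] (loci used for the distances).
#' @param n_perm Permutations per pair; 0 skips testing (p = NA).
#' @param seed Integer seed; each pair gets its own derived stream.
#' @param metric Haplotype distance metric, see [hap_dist_spec()].
#' @return An object of class `phist_matrix`: list with `populations`, `d`
#'   (symmetric Phi-st matrix, zero diagonal), `p` (permutation p-values),
#'   `n_perm`, `panel` (name), `metric`.
#' @export
distance_matrix <- function(table, panel, n_perm = 10000L, seed = 1L,
                            metric = "sum_squared_size_diff") {
  stopifnot(inherits(table, "haplotype_table"),
            inherits(panel, "marker_panel"))
  spec <- hap_dist_spec(metric = metric, panel = panel)
  pops <- sort(unique(table$population))
  P <- length(pops)
  if (P < 2L) stop("need >= 2 populations")
  d <- matrix(0, P, P, dimnames = list(pops, pops))
  p <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(p) <- NA_real_
  for (i in seq_len(P - 1L)) for (j in seq(i + 1L, P)) {
    if (n_perm > 0L) {
      res <- permutation_test(table, pops[i], pops[j], spec,
                              n_perm = n_perm, seed = seed)
      d[i, j] <- d[j, i] <- res$phist
      p[i, j] <- p[j, i] <- res$p_value
    } else {
      d[i, j] <- d[j, i] <- pairwise_phist(table, pops[i], pops[j], spec)
    }
  }
  structure(list(populations = pops, d = d, p = p,
                 n_perm = as.integer(n_perm), panel = panel$name,
                 metric = spec$metric),
            class = "phist_matrix")
}

#' @export
print.phist_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise Phi-st matrix (panel '", x$panel, "', metric ", x$metric,
      ", ", x$n_perm, " permutations)\n", sep = "")
  print(round(x$d, digits))
  invisible(x)
}

#' Long-form view of a distance matrix
#' @param x A `phist_matrix`.
#' @param ... Unused.
#' @return Data frame with one row per unordered population pair: `popA`,
#'   `popB`, `distance`, `p_value`.
#' @export
as.data.frame.phist_matrix <- function(x, ...) {
  P <- length(x$populations)
  ij <- which(upper.tri(x$d), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  data.frame(popA = x$populations[ij[, "row"]],
             popB = x$populations[ij[, "col"]],
             distance = x$d[ij],
             p_value = x$p[ij],
             stringsAsFactors = FALSE)
}

#' Write a distance matrix in square PHYLIP format and as long TSV
#'
#' @param x A `phist_matrix`.
#' @param path Output path; `write_phylip()` writes the square matrix,
#'   `write_distance_tsv()` the long form (popA, popB, distance, p).
#' @return `path`, invisibly.
#' @export
write_phylip <- function(x, path) {
  stopifnot(inherits(x, "phist_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(x$populations)), con)
  for (i in seq_along(x$populations)) {
    nm <- formatC(substr(x$populations[i], 1, 10), width = -10)
    writeLines(paste0(nm, "  ",
                      paste(sprintf("%.6f", x$d[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' @rdname write_phylip
#' @export
write_distance_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare two distance matrices over the same populations
#'
#' Aligns the unordered population pairs of a reference and an alternative
#' matrix, orders them by ascending reference distance (the line-chart
#' convention for panel comparisons), and reports the fractions of pairs
#' whose distance increased, decreased, or is tied under the alternative
#' panel.
#'
#' @param ref,alt Two `phist_matrix` objects over the same population set.
#' @param tie_tol Absolute tolerance below which a difference counts as a
#'   tie.
#' @return An object of class `dist_comparison`: list with `pairs` (data
#'   frame popA, popB, d_ref, d_alt, ordered ascending by d_ref),
#'   `frac_increased`, `frac_decreased`, `frac_tied`, and the two panel
#'   names.
#' @export
compare_distance_matrices <- function(ref, alt, tie_tol = 1e-12) {
  stopifnot(inherits(ref, "phist_matrix"), inherits(alt, "phist_matrix"))
  if (!identical(ref$populations, alt$populations))
    stop("distance matrices cover different population sets")
  dr <- as.data.frame(ref)
  da <- as.data.frame(alt)
  pairs <- data.frame(popA = dr$popA, popB = dr$popB,
                      d_ref = dr$distance, d_alt = da$distance,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$d_ref, pairs$popA, pairs$popB), , drop = FALSE]
  rownames(pairs) <- NULL
  delta <- pairs$d_alt - pairs$d_ref
  n <- nrow(pairs)
  structure(list(pairs = pairs,
                 frac_increased = sum(delta > tie_tol) / n,
                 frac_decreased = sum(delta < -tie_tol) / n,
                 frac_tied = sum(abs(delta) <= tie_tol) / n,
                 ref_panel = ref$panel, alt_panel = alt$panel),
            class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat("Distance comparison: '", x$alt_panel, "' vs reference '",
      x$ref_panel, "' (", nrow(x$pairs), " population pairs)\n", sep = "")
  cat(sprintf("  increased: %.1f%%  decreased: %.1f%%  tied: %.1f%%\n",
              100 * x$frac_increased, 100 * x$frac_decreased,
              100 * x$frac_tied))
  invisible(x)
}

#' @export
plot.dist_comparison <- function(x, ...) {
  n <- nrow(x$pairs)
  ylim <- range(c(x$pairs$d_ref, x$pairs$d_alt))
  graphics::plot(seq_len(n), x$pairs$d_ref, type = "l", col = "blue",
                 lwd = 1.5, xlab = "population pairs (ascending reference distance)",
                 ylab = expression(Phi[ST]), ylim = ylim, ...)
  graphics::lines(seq_len(n), x$pairs$d_alt, col = "darkorange", lwd = 1.5)
  graphics::legend("topleft", c(x$ref_panel, x$alt_panel),
                   col = c("blue", "darkorange"), lty = 1, bty = "n")
  invisible(x)
}
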