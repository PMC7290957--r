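# Allele-frequency spectra, the AFD statistic, mAFD ranking and sliding
# marker panels.

#' Per-locus allele frequency spectrum of one population
#'
#' @param table A QC'd [haplotype_table] (integer allele calls).
#' @param locus Locus name.
#' @param population Population id.
#' @return An object of class `afd_spectrum`: list with `locus`,
#'   `population`, `freqs` (named numeric vector, names are allele repeat
#'   counts, values are relative frequencies summing to 1) and `n_samples`.
#' @export
#' @examples
#' df <- data.frame(sample = paste0("s", 1:4), population = "P1",
#'                  DYS392 = c(13L, 13L, 14L, 15L))
#' allele_frequencies(haplotype_table(df), "DYS392", "P1")$freqs
allele_frequencies <- function(table, locus, population) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!locus %in% table_loci(table)) stop("unknown locus: ", locus)
  calls <- table[[locus]][table$population == population]
  if (length(calls) == 0L)
    stop("population '", population, "' is empty at ", locus)
  if (!is.numeric(calls) || anyNA(calls))
    stop("allele calls must be numeric and complete; run qc_filter() first")
  tab <- base::table(calls)
  freqs <- as.numeric(tab) / length(calls)
  names(freqs) <- names(tab)
  structure(list(locus = locus, population = as.character(population),
                 freqs = freqs, n_samples = length(calls)),
            class = "afd_spectrum")
}

#' @export
print.afd_spectrum <- function(x, ...) {
  cat("Allele spectrum ", x$locus, " / ", x$population,
      " (n = ", x$n_samples, ")\n", sep = "")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Allele frequency difference (AFD) between two populations at one locus
#'
#' AFD is half the L1 distance between the two allele-frequency vectors,
#' summed over the union of alleles observed in either population (alleles
#' absent from one population contribute frequency 0 there):
#' \deqn{AFD = \frac{1}{2}\sum_i |f_{i1} - f_{i2}|.}
#' It ranges from 0 (identical spectra) to 1 (disjoint allele sets) and is
#' symmetric in its arguments.
#'
#' @param spec1,spec2 Two [allele_frequencies()] spectra for the same locus.
#' @return AFD statistic in `[0, 1]`.
#' @export
#' @examples
#' s1 <- structure(list(locus = "L", population = "A",
#'                      freqs = c(`14` = 1), n_samples = 4),
#'                 class = "afd_spectrum")
#' s2 <- structure(list(locus = "L", population = "B",
#'                      freqs = c(`14` = 0.5, `15` = 0.5), n_samples = 4),
#'                 class = "afd_spectrum")
#' afd(s1, s2)  # 0.5
afd <- function(spec1, spec2) {
  stopifnot(inherits(spec1, "afd_spectrum"), inherits(spec2, "afd_spectrum"))
  if (!identical(spec1$locus, spec2$locus))
    stop("spectra are for different loci: ", spec1$locus, " vs ",
         spec2$locus)
  alleles <- union(names(spec1$freqs), names(spec2$freqs))
  f1 <- spec1$freqs[alleles]; f1[is.na(f1)] <- 0
  f2 <- spec2$freqs[alleles]; f2[is.na(f2)] <- 0
  0.5 * sum(abs(f1 - f2))
}

#' Mean AFD of one locus over all population pairs
#'
#' The unweighted arithmetic mean of [afd()] over all C(P, 2) unordered
#' pairs of populations in the table; the per-locus population
#' differentiation score driving the locus ranking.
#'
#' @param table A QC'd [haplotype_table] with at least two populations.
#' @param locus Locus name.
#' @return List with `mafd` (statistic in `[0, 1]`) and `n_pairs`.
#' @export
mafd <- function(table, locus) {
  stopifnot(inherits(table, "haplotype_table"))
  pops <- sort(unique(table$population))
  if (length(pops) < 2L)
    stop("mAFD requires at least 2 populations")
  specs <- lapply(pops, function(p) allele_frequencies(table, locus, p))
  vals <- numeric(0)
  for (i in seq_len(length(pops) - 1L))
    for (j in seq(i + 1L, length(pops)))
      vals <- c(vals, afd(specs[[i]], specs[[j]]))
  list(mafd = mean(vals), n_pairs = length(vals))
}

#' Rank panel loci by mAFD
#'
#' Computes [mafd()] for every locus of `panel` and returns the ranking,
#' sorted by descending mAFD (ties broken by locus name so the ranking is
#' deterministic). Per-locus mutation rates, when supplied, are carried
#' along for downstream correlation analysis and plotting.
#'
#' @param table A QC'd, DYS389-adjusted [haplotype_table].
#' @param panel A [marker_panel].
#' @param rates Optional named numeric vector of per-generation mutation
#'   rates, names matching locus names.
#' @return An object of class `mafd_table`: list with `rows` (data frame
#'   `locus`, `mafd`, `n_pairs`, `mutation_rate`) and `populations_used`.
#' @export
mafd_table <- function(table, panel, rates = NULL) {
  stopifnot(inherits(table, "haplotype_table"),
            inherits(panel, "marker_panel"))
  missing <- setdiff(panel$loci, table_loci(table))
  if (length(missing))
    stop("panel loci absent from table: ", paste(missing, collapse = ", "))
  res <- lapply(panel$loci, function(l) mafd(table, l))
  rows <- data.frame(
    locus = panel$loci,
    mafd = vapply(res, `[[`, numeric(1), "mafd"),
    n_pairs = vapply(res, `[[`, integer(1), "n_pairs"),
    mutation_rate = if (is.null(rates)) NA_real_ else
      unname(rates[panel$loci]),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(-rows$mafd, rows$locus), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 populations_used = sort(unique(table$population))),
            class = "mafd_table")
}

#' @export
print.mafd_table <- function(x, digits = 4, ...) {
  cat("mAFD locus ranking (", nrow(x$rows), " loci",
      if (length(x$populations_used))
        paste0(", ", length(x$populations_used), " populations") else "",
      ")\n", sep = "")
  df <- x$rows
  df$mafd <- round(df$mafd, digits)
  print(df)
  invisible(x)
}

#' @export
as.data.frame.mafd_table <- function(x, ...) x$rows

#' Write an mAFD ranking as TSV
#' @param x A [mafd_table].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mafd_table <- function(x, path) {
  stopifnot(inherits(x, "mafd_table"))
  df <- cbind(rank = seq_len(nrow(x$rows)), x$rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.mafd_table <- function(x, ...) {
  df <- x$rows
  n <- nrow(df)
  op <- graphics::par(mar = c(7, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(n), df$mafd, type = "o", pch = 16, col = "blue",
                 xaxt = "n", xlab = "", ylab = "mAFD",
                 ylim = c(0, max(df$mafd) * 1.1), ...)
  graphics::axis(1, at = seq_len(n), labels = df$locus, las = 2,
                 cex.axis = 0.7)
  if (!all(is.na(df$mutation_rate))) {
    graphics::par(new = TRUE)
    graphics::plot(seq_len(n), df$mutation_rate, type = "o", pch = 17,
                   col = "darkorange", axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "darkorange")
    graphics::mtext("mutation rate / generation", side = 4, line = 2.5,
                    col = "darkorange", cex = 0.9)
    graphics::legend("topright", c("mAFD", "mutation rate"),
                     col = c("blue", "darkorange"), pch = c(16, 17),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Sliding marker panels along an mAFD ranking
#'
#' Slides a window of `window` loci down the descending mAFD ranking with
#' the given step, so the first panel holds the top-`window` loci and the
#' last panel the minimum-`window` loci. With 23 ranked loci, a window of 15
#' and step 1 this yields 9 panels.
#'
#' @param ranking A [mafd_table] (or [reference_mafd()]).
#' @param window Panel size (default 15).
#' @param step Slide step in loci (default 1).
#' @return An object of class `sliding_panels`: list with `panels` (list of
#'   [marker_panel], named `top_15`, `rank02_16`, ..., `min_15` style),
#'   `window`, `step` and `ranking` (locus names, descending mAFD).
#' @export
#' @examples
#' sp <- sliding_panels(reference_mafd())
#' length(sp$panels)  # 9
sliding_panels <- function(ranking, window = 15L, step = 1L) {
  stopifnot(inherits(ranking, "mafd_table"))
  loci <- ranking$rows$locus
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (window > length(loci))
    stop("window (", window, ") exceeds number of ranked loci (",
         length(loci), ")")
  starts <- seq(1L, length(loci) - window + 1L, by = step)
  panels <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    nm <- if (s == 1L) sprintf("top_%d", window)
      else if (s == max(starts) && s + window - 1L == length(loci))
        sprintf("min_%d", window)
      else sprintf("rank%02d_%02d", s, s + window - 1L)
    marker_panel(nm, loci[s:(s + window - 1L)])
  })
  names(panels) <- vapply(panels, `[[`, character(1), "name")
  structure(list(panels = panels, window = window, step = step,
                 ranking = loci),
            class = "sliding_panels")
}

#' @export
print.sliding_panels <- function(x, ...) {
  cat("Sliding panels: ", length(x$panels), " windows of ", x$window,
      " loci (step ", x$step, ") over ", length(x$ranking),
      " ranked loci\n", sep = "")
  for (p in x$panels)
    cat("  ", format(p$name, width = 12), paste(p$loci, collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Correlation between mAFD and locus mutation rate
#'
#' Tests whether locus differentiation (mAFD) tracks the locus mutation
#' rate, reporting both Pearson product-moment and Spearman rank
#' correlations with their p-values. A near-zero correlation indicates that
#' drift and founder effects, not mutation pressure, dominate between-
#' population allele-frequency differences.
#'
#' @param mafd_tbl A [mafd_table] whose rows carry mutation rates.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`, and `degenerate` (TRUE when either variable has zero variance, in
#'   which case the coefficients are `NA`).
#' @export
mafd_rate_correlation <- function(mafd_tbl) {
  stopifnot(inherits(mafd_tbl, "mafd_table"))
  df <- mafd_tbl$rows
  ok <- !is.na(df$mutation_rate) & !is.na(df$mafd)
  if (sum(ok) < 3L)
    stop("need at least 3 loci with mutation rates")
  x <- df$mafd[ok]; y <- df$mutation_rate[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                n = sum(ok), degenerate = TRUE))
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = sum(ok), degenerate = FALSE)
}
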