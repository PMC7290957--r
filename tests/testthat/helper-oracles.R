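# Independent brute-force oracles, coded without reference to the package
# internals, plus small fixture builders.

# AFD from two named frequency vectors: half L1 over the allele union.
oracle_afd <- function(f1, f2) {
  alleles <- union(names(f1), names(f2))
  tot <- 0
  for (a in alleles) {
    p <- if (a %in% names(f1)) f1[[a]] else 0
    q <- if (a %in% names(f2)) f2[[a]] else 0
    tot <- tot + abs(p - q)
  }
  tot / 2
}

# mAFD by an explicit double loop over population pairs and alleles,
# counting frequencies with plain table()/length().
oracle_mafd <- function(df, locus) {
  pops <- sort(unique(df$population))
  vals <- c()
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i >= j) next
    x <- df[[locus]][df$population == pops[i]]
    y <- df[[locus]][df$population == pops[j]]
    f1 <- table(x) / length(x)
    f2 <- table(y) / length(y)
    vals <- c(vals, oracle_afd(as.list(f1), as.list(f2)))
  }
  mean(vals)
}

# Two-level AMOVA Phi-st by explicit sums of squared deviations. `mat` is
# the pooled haplotype matrix (rows = samples, cols = loci), `pop` the
# population label per row. Squared inter-haplotype distance = sum of
# squared repeat differences.
oracle_phist <- function(mat, pop) {
  d2 <- function(i, j) sum((mat[i, ] - mat[j, ])^2)
  N <- nrow(mat)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_total <- ss_total + d2(i, j)
  ss_total <- ss_total / N
  ss_within <- 0
  for (p in pops) {
    idx <- which(pop == p)
    s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d2(idx[a], idx[b])
    ss_within <- ss_within + s / length(idx)
  }
  ss_among <- ss_total - ss_within
  sigma_w <- ss_within / (N - P)
  n_c <- (N - sum(table(pop)^2) / N) / (P - 1)
  sigma_a <- (ss_among / (P - 1) - sigma_w) / n_c
  sigma_a / (sigma_a + sigma_w)
}

# Pearson r and Spearman rho from first principles.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Tiny haplotype table from per-population allele-call lists.
# calls: named list population -> data.frame of locus columns.
make_table <- function(calls) {
  dfs <- lapply(names(calls), function(p) {
    d <- as.data.frame(calls[[p]])
    cbind(data.frame(sample = paste0(p, "_", seq_len(nrow(d))),
                     population = p, stringsAsFactors = FALSE), d)
  })
  haplotype_table(do.call(rbind, dfs))
}

# Random QC-clean table: npop populations, n samples each, nloc loci.
random_table <- function(npop = 3, n = 8, nloc = 4, seed = 1) {
  set.seed(seed)
  pops <- paste0("P", seq_len(npop))
  df <- data.frame(sample = paste0("s", seq_len(npop * n)),
                   population = rep(pops, each = n),
                   stringsAsFactors = FALSE)
  for (l in seq_len(nloc))
    df[[paste0("L", l)]] <- sample(10:16, npop * n, replace = TRUE)
  haplotype_table(df)
}

# Random normalized allele spectrum over the given allele labels.
random_spectrum <- function(locus, population, alleles = 10:16) {
  k <- sample(2:length(alleles), 1)
  a <- sort(sample(alleles, k))
  w <- stats::runif(k)
  structure(list(locus = locus, population = population,
                 freqs = stats::setNames(w / sum(w), a), n_samples = 100L),
            class = "afd_spectrum")
}
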