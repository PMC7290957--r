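# Seeded forward simulator of multi-population Y-STR haplotypes: star-split
# Wright-Fisher model with per-locus stepwise mutation, founder bottlenecks
# and optional QC-noise injection.

#' Simulation configuration
#'
#' Describes a star-shaped population history: one ancestral haploid
#' population accumulates standing variation for `burn_in` Wright-Fisher
#' generations, then each daughter population is founded by a bottleneck of
#' `founder_size` haplotypes drawn from the ancestral pool, expands to
#' `pop_size`, and drifts independently for its `generations_since_split`.
#' Mutation follows the strict stepwise model: each locus mutates with its
#' per-generation rate, moving one repeat up or down with equal probability,
#' reflecting at the lower bound of 1 repeat.
#'
#' Defaults use the 23 packaged single-copy loci with their reference
#' point mutation rates (order 1e-4 to 1e-2 per generation), so synthetic
#' panels are nominally comparable to the standard 23-locus set.
#'
#' @param n_populations Number of daughter populations.
#' @param pop_size Haplotypes per population (also the ancestral pool size).
#' @param founder_size Bottleneck size at each population split.
#' @param generations_since_split Generations of independent drift per
#'   population; scalar or vector of length `n_populations`.
#' @param mutation_rates Named numeric vector, locus -> per-generation
#'   mutation probability in `[0, 1)`.
#' @param burn_in Ancestral generations before the split.
#' @param qc_noise Named rates `c(null=, intermediate=, multi=)` of
#'   QC-problem injection per haplotype (see [inject_qc_noise()]).
#' @param seed Integer seed; the entire simulation is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_populations = 5L,
                              pop_size = 100L,
                              founder_size = 50L,
                              generations_since_split = 50L,
                              mutation_rates = NULL,
                              burn_in = 300L,
                              qc_noise = c(null = 0, intermediate = 0,
                                           multi = 0),
                              seed = 1L) {
  if (is.null(mutation_rates)) {
    ref <- reference_mafd()$rows
    mutation_rates <- stats::setNames(ref$mutation_rate, ref$locus)
  }
  if (length(mutation_rates) == 0L || is.null(names(mutation_rates)))
    stop("mutation_rates must be a named vector with >= 1 locus")
  if (any(mutation_rates < 0 | mutation_rates >= 1))
    stop("mutation rates must lie in [0, 1)")
  gens <- rep_len(as.integer(generations_since_split), n_populations)
  stopifnot(n_populations >= 1L, pop_size >= 1L, founder_size >= 1L,
            all(gens >= 0L), burn_in >= 0L)
  qn <- c(null = 0, intermediate = 0, multi = 0)
  qn[names(qc_noise)] <- qc_noise
  if (any(qn < 0 | qn >= 1)) stop("qc_noise rates must lie in [0, 1)")
  structure(list(n_populations = as.integer(n_populations),
                 pop_size = as.integer(pop_size),
                 founder_size = as.integer(founder_size),
                 generations_since_split = gens,
                 mutation_rates = mutation_rates,
                 burn_in = as.integer(burn_in),
                 qc_noise = qn,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One round of stepwise mutation over an N x L allele matrix; returns the
# matrix and the per-locus count of realized mutation events. Steps are +/-1
# with probability 1/2 each; values reflect at the lower bound of 1.
.mutate_step <- function(mat, rates) {
  counts <- integer(ncol(mat))
  for (l in seq_len(ncol(mat))) {
    hit <- which(stats::runif(nrow(mat)) < rates[l])
    if (length(hit)) {
      step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
      v <- mat[hit, l] + step
      v[v < 1L] <- 2L - v[v < 1L]  # reflect at 1
      mat[hit, l] <- v
      counts[l] <- length(hit)
    }
  }
  list(mat = mat, counts = counts)
}

#' Simulate multi-population Y-STR haplotype tables
#'
#' Runs the star-split Wright-Fisher forward simulation described in
#' [simulation_config()] and emits a [haplotype_table] in the same layout
#' [read_haplotype_table()] accepts, together with a truth record
#' documenting the ancestral haplotype and realized per-locus mutation
#' counts. With `qc_noise` rates above zero, QC-problem records (null,
#' intermediate, duplicated calls) are injected after simulation so the
#' table exercises [qc_filter()].
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [haplotype_table]; character allele columns
#'   when noise was injected, integer otherwise) and `truth` (list:
#'   `ancestral_haplotype`, `split_topology`, `realized_mutation_counts`
#'   per population x locus, `burn_in_mutation_counts`).
#' @export
#' @examples
#' sim <- simulate_populations(simulation_config(n_populations = 3,
#'   pop_size = 30, generations_since_split = 50, seed = 42))
#' table(sim$table$population)
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .seed_rng(config$seed)
  on.exit(.restore_rng(old))

  rates <- config$mutation_rates
  loci <- names(rates)
  L <- length(loci)
  N <- config$pop_size

  # ancestral haplotype: typical Y-STR modal repeat counts. DYS389II is the
  # full nested amplicon and sits well above DYS389I, so its decomposition
  # (DYS389II - DYS389I) stays positive under drift.
  anc <- sample(10:17, L, replace = TRUE)
  names(anc) <- loci
  if (all(c("DYS389I", "DYS389II") %in% loci))
    anc["DYS389II"] <- anc["DYS389I"] + sample(14:18, 1L)
  pool <- matrix(rep(anc, each = N), nrow = N)
  burn_counts <- integer(L)
  for (g in seq_len(config$burn_in)) {
    pool <- pool[sample.int(N, N, replace = TRUE), , drop = FALSE]
    st <- .mutate_step(pool, rates)
    pool <- st$mat
    burn_counts <- burn_counts + st$counts
  }

  pop_names <- sprintf("pop%02d", seq_len(config$n_populations))
  mut_counts <- matrix(0L, config$n_populations, L,
                       dimnames = list(pop_names, loci))
  rows <- vector("list", config$n_populations)
  for (k in seq_len(config$n_populations)) {
    founders <- pool[sample.int(N, config$founder_size, replace = TRUE), ,
                     drop = FALSE]
    cur <- founders[sample.int(config$founder_size, N, replace = TRUE), ,
                    drop = FALSE]
    for (g in seq_len(config$generations_since_split[k])) {
      cur <- cur[sample.int(N, N, replace = TRUE), , drop = FALSE]
      st <- .mutate_step(cur, rates)
      cur <- st$mat
      mut_counts[k, ] <- mut_counts[k, ] + st$counts
    }
    rows[[k]] <- cur
  }

  mat <- do.call(rbind, rows)
  df <- data.frame(
    sample = sprintf("%s_%04d", rep(pop_names, each = N), seq_len(N)),
    population = rep(pop_names, each = N),
    stringsAsFactors = FALSE)
  for (l in seq_len(L)) df[[loci[l]]] <- as.integer(mat[, l])
  tbl <- haplotype_table(df, loci = loci)

  if (any(config$qc_noise > 0))
    tbl <- .inject_qc_noise_impl(tbl, config$qc_noise)

  truth <- list(ancestral_haplotype = stats::setNames(anc, loci),
                split_topology = "star",
                realized_mutation_counts = mut_counts,
                burn_in_mutation_counts = stats::setNames(burn_counts, loci))
  list(table = tbl, truth = truth)
}

# seed the global RNG and return the previous state for restoration
.seed_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

#' Sample haplotype tables from prescribed allele spectra
#'
#' Draws haplotypes locus-by-locus (loci independent) from explicitly given
#' allele-frequency spectra, one spectrum set per population. Useful for
#' calibration studies: the analytic AFD of the generating spectra is known,
#' and panmictic data are obtained by reusing one spectrum set for several
#' population labels.
#'
#' @param spectra Named list (one element per population) of named lists
#'   (one per locus) of named numeric frequency vectors; each must sum to 1
#'   within 1e-8.
#' @param n Haplotypes per population.
#' @param seed Integer seed.
#' @return A [haplotype_table] with integer allele columns.
#' @export
#' @examples
#' sp <- list(A = list(DYS392 = c(`13` = 0.5, `14` = 0.5)),
#'            B = list(DYS392 = c(`14` = 1)))
#' sample_from_spectra(sp, n = 5, seed = 1)
sample_from_spectra <- function(spectra, n, seed = 1L) {
  if (is.null(names(spectra))) stop("spectra must be named by population")
  loci <- names(spectra[[1L]])
  for (p in names(spectra)) {
    if (!identical(names(spectra[[p]]), loci))
      stop("all populations must share the same locus set, in order")
    for (l in loci) {
      f <- spectra[[p]][[l]]
      if (abs(sum(f) - 1) > 1e-8)
        stop("spectrum ", p, "/", l, " is not normalized (sum = ", sum(f),
             ")")
    }
  }
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  dfs <- lapply(names(spectra), function(p) {
    df <- data.frame(sample = sprintf("%s_%04d", p, seq_len(n)),
                     population = p, stringsAsFactors = FALSE)
    for (l in loci) {
      f <- spectra[[p]][[l]]
      alleles <- as.numeric(names(f))
      df[[l]] <- as.integer(alleles[sample.int(length(f), n, replace = TRUE,
                                               prob = f)])
    }
    df
  })
  haplotype_table(do.call(rbind, dfs), loci = loci)
}

#' Inject QC-problem records into a haplotype table
#'
#' Randomly selects haplotypes to receive a null call (empty cell), an
#' intermediate allele (+0.2 microvariant) or a duplicated call
#' (`"a,a+1"`) at one randomly chosen locus, at the given per-haplotype
#' rates. The expected number of affected records per reason is
#' `rate * nrow(table)`. Allele columns are returned as character, exactly
#' as a raw input file would present them.
#'
#' @param table A [haplotype_table].
#' @param rates Named rates `c(null=, intermediate=, multi=)` in `[0, 1)`.
#' @param seed Integer seed.
#' @return The noised [haplotype_table].
#' @export
inject_qc_noise <- function(table, rates, seed = 1L) {
  stopifnot(inherits(table, "haplotype_table"))
  qn <- c(null = 0, intermediate = 0, multi = 0)
  qn[names(rates)] <- rates
  if (any(qn < 0 | qn >= 1)) stop("rates must lie in [0, 1)")
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  .inject_qc_noise_impl(table, qn)
}

.inject_qc_noise_impl <- function(table, qn) {
  if (all(qn == 0)) return(table)
  loci <- table_loci(table)
  df <- as.data.frame(table)
  for (l in loci) df[[l]] <- as.character(df[[l]])
  n <- nrow(df)
  for (reason in c("null", "intermediate", "multi")) {
    rate <- qn[[reason]]
    if (rate == 0) next
    hit <- which(stats::runif(n) < rate)
    for (i in hit) {
      l <- loci[sample.int(length(loci), 1L)]
      v <- suppressWarnings(as.numeric(df[[l]][i]))
      df[[l]][i] <- switch(reason,
        null = "",
        intermediate = if (is.na(v)) "13.2" else
          format(v + 0.2, nsmall = 1),
        multi = if (is.na(v)) "17,18" else paste0(v, ",", v + 1))
    }
  }
  haplotype_table(df, loci = loci,
                  adjusted = attr(table, "dys389_adjusted"))
}
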