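# End-to-end orchestration: ingest -> QC -> mAFD ranking -> sliding panels
# -> distance matrices -> comparison -> MDS, behind one configuration.

#' Pipeline configuration
#'
#' @param input Path to a delimited haplotype file, or a
#'   [simulation_config()] to generate the input.
#' @param panel Optional [marker_panel] of analysis loci; default uses every
#'   single-copy locus present in the table (multi-copy DYS385a/b and
#'   DYF387S1a/b are excluded from analysis).
#' @param window,step Sliding-panel window and step (defaults 15 and 1).
#' @param n_perm Permutations per population pair (default 10,000).
#' @param alpha Significance level for permutation tests (default 0.05).
#' @param mds_method `"classical"` or `"smacof"`.
#' @param metric Haplotype distance metric, see [hap_dist_spec()].
#' @param clamp_negative Clamp negative Phi-st at MDS input (default TRUE).
#' @param mutation_rates Optional named rates attached to the mAFD ranking;
#'   defaults to the packaged reference rates for loci that have one, or the
#'   simulator's rates for simulated input.
#' @param seed Integer seed governing simulation and permutation streams.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, panel = NULL, window = 15L, step = 1L,
                       n_perm = 10000L, alpha = 0.05,
                       mds_method = c("classical", "smacof"),
                       metric = "sum_squared_size_diff",
                       clamp_negative = TRUE, mutation_rates = NULL,
                       seed = 1L) {
  mds_method <- match.arg(mds_method)
  if (!(is.character(input) || inherits(input, "sim_config")))
    stop("input must be a file path or a simulation_config()")
  structure(list(input = input, panel = panel, window = as.integer(window),
                 step = as.integer(step), n_perm = as.integer(n_perm),
                 alpha = alpha, mds_method = mds_method, metric = metric,
                 clamp_negative = clamp_negative,
                 mutation_rates = mutation_rates, seed = as.integer(seed)),
            class = "run_config")
}

.MULTI_COPY <- c("DYS385a", "DYS385b", "DYF387S1a", "DYF387S1b")

# md5 of the deparsed config, for provenance
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full locus-characterization pipeline
#'
#' Executes all stages in order: input (file or simulation), QC filtering,
#' DYS389 decomposition (when both components are present), per-locus mAFD
#' ranking, sliding 15-marker panels, AMOVA Phi-st distance matrices with
#' permutation p-values for the top- and minimum-mAFD panels, a
#' distance-matrix comparison ordered by ascending minimum-panel distance,
#' and an MDS embedding per distance matrix. All randomness derives from the
#' configured seed, so repeated runs are byte-identical.
#'
#' @param config A [run_config()].
#' @return An object of class `ystr_run`: list with `qc` (QC report),
#'   `table` (QC'd, adjusted haplotype table), `mafd` ([mafd_table]),
#'   `panels` ([sliding_panels]), `distances` (named list of
#'   `phist_matrix`), `comparisons` (named list of `dist_comparison`),
#'   `mds` (named list of `mds_embedding`), `truth` (for simulated input),
#'   `provenance` (version, seed, config hash) and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(simulation_config(n_populations = 4, pop_size = 40,
#'                                     seed = 7), n_perm = 100, seed = 7)
#' run <- run_characterization(cfg)
#' summary(run)
#' }
run_characterization <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  rates <- config$mutation_rates
  tbl <- stage("input", {
    if (inherits(config$input, "sim_config")) {
      sim <- simulate_populations(config$input)
      truth <- sim$truth
      if (is.null(rates)) rates <- config$input$mutation_rates
      sim$table
    } else read_haplotype_table(config$input)
  })

  panel <- config$panel
  if (is.null(panel)) {
    loci <- setdiff(table_loci(tbl), .MULTI_COPY)
    panel <- marker_panel("analysis", loci)
  }
  if (is.null(rates)) {
    ref <- reference_mafd()$rows
    have <- panel$loci %in% ref$locus
    if (any(have))
      rates <- stats::setNames(
        ref$mutation_rate[match(panel$loci, ref$locus)], panel$loci)
  }

  qc <- stage("qc", qc_filter(tbl, panel))
  tbl <- qc$table
  if (all(c("DYS389I", "DYS389II") %in% panel$loci) &&
      !isTRUE(attr(tbl, "dys389_adjusted")))
    tbl <- stage("dys389", adjust_dys389(tbl))

  ranking <- stage("mafd", mafd_table(tbl, panel, rates = rates))
  window <- min(config$window, nrow(ranking$rows))
  panels <- stage("panels", sliding_panels(ranking, window = window,
                                           step = config$step))

  # the first (top-mAFD) and last (minimum-mAFD) panels always get full
  # distance + MDS treatment
  eval_panels <- panels$panels[unique(c(1L, length(panels$panels)))]
  distances <- stage("distances", lapply(eval_panels, function(p)
    distance_matrix(tbl, p, n_perm = config$n_perm, seed = config$seed,
                    metric = config$metric)))

  comparisons <- list()
  if (length(distances) == 2L)
    comparisons[[paste0(names(distances)[1L], "_vs_",
                        names(distances)[2L])]] <-
      stage("compare", compare_distance_matrices(distances[[2L]],
                                                 distances[[1L]]))

  mds <- stage("mds", lapply(distances, function(dm) {
    emb <- classical_mds(dm, dims = 2L,
                         clamp_negative = config$clamp_negative)
    if (config$mds_method == "smacof")
      emb <- smacof_refine(emb, dm, clamp_negative = config$clamp_negative)
    emb
  }))

  structure(list(qc = qc$report, table = tbl, mafd = ranking,
                 panels = panels, distances = distances,
                 comparisons = comparisons, mds = mds, truth = truth,
                 provenance = list(
                   package_version =
                     as.character(utils::packageVersion("ystrdiff")),
                   seed = config$seed,
                   config_hash = .config_hash(config)),
                 config = config),
            class = "ystr_run")
}

#' @export
print.ystr_run <- function(x, ...) {
  cat("Y-STR characterization run (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  cat("  haplotypes retained: ", x$qc$n_retained, "/", x$qc$n_input,
      "; populations: ", length(x$mafd$populations_used),
      "; loci ranked: ", nrow(x$mafd$rows), "\n", sep = "")
  cat("  panels: ", length(x$panels$panels), " (window ", x$panels$window,
      ", step ", x$panels$step, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ystr_run <- function(object, ...) {
  x <- object
  print(x)
  top <- x$mafd$rows[1L, ]
  bot <- x$mafd$rows[nrow(x$mafd$rows), ]
  cat(sprintf("  mAFD range: %s %.4f (max) ... %s %.4f (min)\n",
              top$locus, top$mafd, bot$locus, bot$mafd))
  for (nm in names(x$distances)) {
    d <- x$distances[[nm]]$d
    cat(sprintf("  panel %-10s mean Phi-st %.4f, MDS stress-1 %.4f\n",
                nm, mean(d[upper.tri(d)]), x$mds[[nm]]$stress))
  }
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    cat(sprintf("  comparison %s: %.1f%% of pairs increased\n",
                nm, 100 * cm$frac_increased))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the QC report (JSON), the mAFD ranking (TSV), every sliding panel
#' (plain-text locus lists), distance matrices (square PHYLIP plus long
#' TSV), comparison tables (TSV + JSON summary), MDS embeddings (TSV + JSON)
#' and a provenance record. Output is deterministic: rerunning the same
#' seeded configuration reproduces every file byte-for-byte.
#'
#' @param run A `ystr_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "ystr_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "panels"), showWarnings = FALSE)
  write_qc_report(run$qc, file.path(dir, "qc_report.json"))
  write_mafd_table(run$mafd, file.path(dir, "mafd_ranking.tsv"))
  for (p in run$panels$panels)
    write_panel(p, file.path(dir, "panels", paste0(p$name, ".txt")))
  for (nm in names(run$distances)) {
    write_phylip(run$distances[[nm]],
                 file.path(dir, paste0("phist_", nm, ".phy")))
    write_distance_tsv(run$distances[[nm]],
                       file.path(dir, paste0("phist_", nm, ".tsv")))
  }
  for (nm in names(run$comparisons)) {
    cm <- run$comparisons[[nm]]
    utils::write.table(cm$pairs,
                       file.path(dir, paste0("compare_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(ref_panel = cm$ref_panel, alt_panel = cm$alt_panel,
           frac_increased = cm$frac_increased,
           frac_decreased = cm$frac_decreased, frac_tied = cm$frac_tied),
      file.path(dir, paste0("compare_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(run$mds))
    write_mds(run$mds[[nm]], file.path(dir, paste0("mds_", nm, ".tsv")))
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Render the standard figure set for a run
#'
#' Produces, as PNG (default) or SVG: the dual-series chart of mAFD and
#' mutation rate over the ranked loci; one ascending-rank line chart per
#' distance comparison; and one labeled scatter per MDS embedding.
#'
#' @param run A `ystr_run`.
#' @param dir Output directory.
#' @param format `"png"` or `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
render_figures <- function(run, dir, format = c("png", "svg")) {
  stopifnot(inherits(run, "ystr_run"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dev_open <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::svg(path, width = 9, height = 6)
  }
  files <- character(0)
  emit <- function(name, plot_fun) {
    path <- file.path(dir, paste0(name, ".", format))
    dev_open(path)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_fun()
    files <<- c(files, path)
  }
  emit("mafd_vs_mutation_rate", function() plot(run$mafd))
  if (length(run$comparisons) == 0L)
    message("no distance comparisons in report; comparison figure skipped")
  for (nm in names(run$comparisons))
    emit(paste0("compare_", nm),
         local({ n <- nm; function() plot(run$comparisons[[n]]) }))
  for (nm in names(run$mds))
    emit(paste0("mds_", nm),
         local({ n <- nm; function() plot(run$mds[[n]],
                                          main = paste("MDS:", n)) }))
  invisible(files)
}
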