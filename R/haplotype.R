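# Haplotype tables: reading, allele-call classification, QC filtering and
# the DYS389 decomposition.

.NULL_SENTINELS <- c("", "NA", "na", "null", "-", ".")

#' Classify raw allele-call tokens
#'
#' Each cell of a Y-STR haplotype table is in exactly one of four states:
#' a valid integer repeat count (>= 1), a null call, an intermediate
#' (microvariant) allele such as `"13.2"`, or a multi-valued call such as
#' `"17,18"` (a duplicated or triplicated allele at a nominally single-copy
#' locus). Tokens that parse as none of these (including non-positive
#' integers) are classified as null.
#'
#' @param x Character vector of raw tokens.
#' @param null_sentinels Tokens treated as null calls.
#' @return Character vector over `{"integer","null","intermediate","multi"}`.
#' @export
#' @examples
#' classify_call(c("14", "13.2", "17,18", "", "bad"))
classify_call <- function(x, null_sentinels = .NULL_SENTINELS) {
  x <- trimws(as.character(x))
  out <- rep("null", length(x))
  is_sent <- is.na(x) | x %in% null_sentinels
  has_comma <- !is_sent & grepl(",", x, fixed = TRUE)
  out[has_comma] <- "multi"
  rest <- !is_sent & !has_comma
  val <- suppressWarnings(as.numeric(x[rest]))
  ok <- !is.na(val)
  whole <- ok & abs(val - round(val)) < 1e-9
  out[rest][whole & val >= 1] <- "integer"
  out[rest][ok & !whole] <- "intermediate"
  out
}

#' Construct a haplotype table
#'
#' A haplotype table holds one row per male sample: a sample identifier, a
#' population identifier, and one raw allele call per locus. Locus columns
#' are kept as character until [qc_filter()] validates them.
#'
#' @param df Data frame with columns `sample`, `population` and one column
#'   per locus.
#' @param loci Character vector naming the locus columns; defaults to every
#'   column other than `sample` and `population`.
#' @param adjusted Logical; whether the DYS389 decomposition has already
#'   been applied (see [adjust_dys389()]).
#' @return An object of class `haplotype_table` (a data frame with
#'   attributes `loci` and `dys389_adjusted`).
#' @export
haplotype_table <- function(df, loci = NULL, adjusted = FALSE) {
  stopifnot(is.data.frame(df))
  names(df)[names(df) %in% c("Sample", "SAMPLE")] <- "sample"
  names(df)[names(df) %in% c("Population", "POPULATION")] <- "population"
  if (!all(c("sample", "population") %in% names(df)))
    stop("haplotype table requires 'sample' and 'population' columns")
  if (is.null(loci))
    loci <- setdiff(names(df), c("sample", "population"))
  if (length(loci) == 0L) stop("haplotype table has no locus columns")
  if (!all(loci %in% names(df)))
    stop("loci not present in table: ",
         paste(setdiff(loci, names(df)), collapse = ", "))
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  if (anyDuplicated(df$sample))
    stop("duplicate sample_id: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (nrow(df) > 0L && length(unique(df$population)) < 1L)
    stop("haplotype table requires at least one population")
  df <- df[, c("sample", "population", loci), drop = FALSE]
  rownames(df) <- NULL
  structure(df, loci = loci, dys389_adjusted = isTRUE(adjusted),
            class = c("haplotype_table", "data.frame"))
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Y-STR haplotype table: ", nrow(x), " haplotypes, ",
      length(attr(x, "loci")), " loci, ",
      length(unique(x$population)), " populations",
      if (isTRUE(attr(x, "dys389_adjusted"))) " (DYS389 adjusted)" else "",
      "\n", sep = "")
  NextMethod()
}

#' Loci of a haplotype table
#' @param table A `haplotype_table`.
#' @return Character vector of locus column names.
#' @export
table_loci <- function(table) attr(table, "loci")

#' Read a delimited Y-STR haplotype file
#'
#' Expects a header row naming `sample`, `population` and one column per
#' locus. Tab-delimited by default; comma-delimited files are detected from
#' the extension or can be forced with `delim`. Cells that parse as none of
#' integer / intermediate / multi-valued are kept as null calls with a
#' warning.
#'
#' @param path Input file.
#' @param delim Field delimiter; `NULL` (default) picks `","` for `.csv`
#'   files and `"\t"` otherwise.
#' @return A [haplotype_table].
#' @export
read_haplotype_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  names(df) <- trimws(names(df))
  tbl <- haplotype_table(df)
  loci <- table_loci(tbl)
  raw <- unlist(lapply(loci, function(l) tbl[[l]]), use.names = FALSE)
  bad <- classify_call(raw) == "null" &
    !(trimws(raw) %in% .NULL_SENTINELS | is.na(raw))
  if (any(bad))
    warning(sum(bad), " unparseable allele call(s) treated as null",
            call. = FALSE)
  tbl
}

#' Write a haplotype table as TSV
#'
#' @param table A [haplotype_table].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-filter a haplotype table
#'
#' Removes whole haplotypes that carry a null, intermediate (microvariant)
#' or multi-valued (duplicated/triplicated) allele call at any locus of the
#' analysis panel. Removal is per haplotype, never per locus: one offending
#' call discards the record. A record with several problems is counted once,
#' under the first applicable reason in the order
#' null -> intermediate -> multi_allele. Loci outside the panel (e.g. the
#' multi-copy DYS385a/b) are ignored.
#'
#' @param table A [haplotype_table].
#' @param panel A [marker_panel] naming the loci that must be clean; all
#'   panel loci must be columns of `table`.
#' @param null_sentinels Tokens treated as null calls.
#' @return List with elements `table` (retained haplotypes; panel locus
#'   columns converted to integer) and `report` (a `qc_report`: counts in,
#'   retained, removed by reason, plus a per-population breakdown).
#' @export
#' @examples
#' df <- data.frame(sample = c("s1", "s2"), population = "P1",
#'                  DYS392 = c("13", ""), DYS391 = c("10", "11"))
#' qc <- qc_filter(haplotype_table(df), marker_panel("p", c("DYS392", "DYS391")))
#' qc$report$removed_by_reason
qc_filter <- function(table, panel, null_sentinels = .NULL_SENTINELS) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!inherits(panel, "marker_panel")) stop("panel must be a marker_panel")
  loci <- panel$loci
  missing <- setdiff(loci, table_loci(table))
  if (length(missing))
    stop("panel loci absent from table: ", paste(missing, collapse = ", "))

  n <- nrow(table)
  # per-record first offending reason, in fixed precedence order
  reason <- rep(NA_character_, n)
  for (state in c("null", "intermediate", "multi")) {
    hit <- rep(FALSE, n)
    for (l in loci)
      hit <- hit | classify_call(table[[l]], null_sentinels) == state
    reason[is.na(reason) & hit] <- state
  }
  keep <- is.na(reason)

  out <- as.data.frame(table)[keep, , drop = FALSE]
  for (l in loci)
    out[[l]] <- as.integer(round(as.numeric(out[[l]])))
  out <- out[, c("sample", "population", loci), drop = FALSE]
  kept <- haplotype_table(out, loci = loci,
                          adjusted = attr(table, "dys389_adjusted"))

  reason_levels <- c("null", "intermediate", "multi_allele")
  reason[reason == "multi"] <- "multi_allele"
  removed <- base::table(factor(reason, levels = reason_levels))
  # per-population breakdown of removals
  all_pop <- as.data.frame(table)$population
  pops <- sort(unique(all_pop))
  by_pop <- data.frame(
    population = pops,
    n_input = as.integer(base::table(factor(all_pop, levels = pops))),
    stringsAsFactors = FALSE)
  rem_pop <- all_pop[!keep]
  rem_rea <- reason[!keep]
  for (rl in reason_levels)
    by_pop[[rl]] <- as.integer(base::table(factor(
      rem_pop[rem_rea == rl], levels = pops)))
  by_pop$n_retained <- by_pop$n_input -
    rowSums(by_pop[, reason_levels, drop = FALSE])

  report <- structure(list(
    n_input = n,
    n_retained = sum(keep),
    removed_by_reason = as.list(as.integer(removed)) |>
      stats::setNames(reason_levels),
    dys389_adjusted = isTRUE(attr(table, "dys389_adjusted")),
    by_population = by_pop
  ), class = "qc_report")
  list(table = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: ", x$n_input, " haplotypes in, ", x$n_retained,
      " retained\n", sep = "")
  r <- x$removed_by_reason
  cat("  removed: null=", r$null, ", intermediate=", r$intermediate,
      ", multi_allele=", r$multi_allele, "\n", sep = "")
  invisible(x)
}

#' Serialize a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Decompose DYS389II into its independent component
#'
#' The DYS389II amplicon physically contains DYS389I, so the raw DYS389II
#' repeat count double-counts DYS389I. This replaces each DYS389II call by
#' DYS389II - DYS389I, leaving DYS389I untouched, and flags the table so the
#' adjustment cannot be applied twice. Apply after [qc_filter()] so both
#' columns are integer-valued.
#'
#' @param table A QC'd [haplotype_table] containing integer `DYS389I` and
#'   `DYS389II` columns.
#' @return The adjusted [haplotype_table] with `dys389_adjusted = TRUE`.
#' @export
adjust_dys389 <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (isTRUE(attr(table, "dys389_adjusted")))
    stop("table is already DYS389-adjusted; refusing to adjust twice")
  loci <- table_loci(table)
  if (!all(c("DYS389I", "DYS389II") %in% loci))
    stop("both DYS389I and DYS389II must be present")
  a <- table[["DYS389I"]]
  b <- table[["DYS389II"]]
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b) ||
      any(a != round(a)) || any(b != round(b)))
    stop("DYS389I/DYS389II must be integer-valued; run qc_filter() first")
  diff <- b - a
  if (any(diff <= 0) || any(a <= 0)) {
    bad <- table$sample[diff <= 0 | a <= 0][1L]
    stop("non-positive DYS389II - DYS389I difference for sample '",
         bad, "'")
  }
  out <- as.data.frame(table)
  out[["DYS389II"]] <- as.integer(diff)
  haplotype_table(out, loci = loci, adjusted = TRUE)
}
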