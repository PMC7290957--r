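# Marker panel definitions and the packaged 23-locus reference table.

# The 15 single-copy loci shared by the 17-locus Yfiler kit and the 23
# single-copy loci of the 27-locus Yfiler Plus kit.
.YFILER_SINGLE_COPY <- c(
  "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
  "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458", "DYS635",
  "YGATAH4"
)

# The 8 single-copy loci added by Yfiler Plus (DYF387S1 is multi-copy).
.YFILER_PLUS_NEW_SINGLE_COPY <- c(
  "DYS449", "DYS460", "DYS481", "DYS518", "DYS533", "DYS570", "DYS576",
  "DYS627"
)

#' Create a marker panel
#'
#' A marker panel is an ordered, duplicate-free set of locus names used to
#' restrict an analysis to a subset of typed Y-STRs.
#'
#' @param name Panel label, e.g. `"yfiler"`.
#' @param loci Character vector of locus names, no duplicates.
#' @return An object of class `marker_panel` with elements `name` and
#'   `loci`.
#' @export
#' @examples
#' marker_panel("mini", c("DYS392", "DYS391"))
marker_panel <- function(name, loci) {
  loci <- as.character(loci)
  if (length(loci) == 0L) stop("panel must contain at least one locus")
  if (anyDuplicated(loci)) stop("panel loci must be unique")
  structure(list(name = as.character(name)[1L], loci = loci),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel '", x$name, "': ", length(x$loci), " loci\n", sep = "")
  cat(" ", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.marker_panel <- function(x) length(x$loci)

#' Built-in Y-STR marker panels
#'
#' Returns the standard forensic panels used throughout the package:
#' \describe{
#'   \item{`yfiler`}{17 loci of the Yfiler kit (includes the multi-copy
#'     DYS385a/b).}
#'   \item{`yfiler_plus`}{27 loci of the Yfiler Plus kit (adds 8 new
#'     single-copy loci plus the multi-copy DYF387S1a/b).}
#'   \item{`single_copy_23`}{the 23 single-copy Yfiler Plus loci on which
#'     per-locus differentiation statistics are computed.}
#' }
#'
#' @return Named list of [marker_panel] objects.
#' @export
#' @examples
#' p <- builtin_panels()
#' length(p$single_copy_23$loci)  # 23
builtin_panels <- function() {
  yfiler <- c(.YFILER_SINGLE_COPY, "DYS385a", "DYS385b")
  yfiler_plus <- c(yfiler, .YFILER_PLUS_NEW_SINGLE_COPY,
                   "DYF387S1a", "DYF387S1b")
  single23 <- c(.YFILER_SINGLE_COPY, .YFILER_PLUS_NEW_SINGLE_COPY)
  list(
    yfiler = marker_panel("yfiler", yfiler),
    yfiler_plus = marker_panel("yfiler_plus", yfiler_plus),
    single_copy_23 = marker_panel("single_copy_23", single23)
  )
}

#' Packaged per-locus reference mAFD table
#'
#' Loads the packaged reference table of mAFD values and locus mutation
#' rates for the 23 single-copy Yfiler Plus loci, as estimated from a
#' 41-population compilation of 20,927 quality-filtered haplotypes. Mutation
#' rates are per-locus, per-generation point estimates with binomial 95%
#' confidence bounds.
#'
#' @return A [mafd_table] object with a `mutation_rate` column and the
#'   `in_yfiler` flag attached to each row.
#' @export
#' @examples
#' ref <- reference_mafd()
#' head(as.data.frame(ref))
reference_mafd <- function() {
  path <- system.file("extdata", "reference_mafd_23.tsv",
                      package = "ystrdiff", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rows <- data.frame(
    locus = df$locus,
    mafd = df$mafd,
    n_pairs = NA_integer_,
    mutation_rate = df$mutation_rate,
    in_yfiler = df$in_yfiler,
    stringsAsFactors = FALSE
  )
  rows <- rows[order(-rows$mafd, rows$locus), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, populations_used = character(0)),
            class = "mafd_table")
}

#' Read/write plain-text panel files
#'
#' Panels are stored as one locus name per line; the file name (minus
#' extension) becomes the panel name on read.
#'
#' @param path File path.
#' @param panel A [marker_panel].
#' @return `read_panel()` returns a [marker_panel]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  loci <- readLines(path)
  loci <- trimws(loci)
  loci <- loci[nzchar(loci) & !startsWith(loci, "#")]
  name <- sub("\\.[^.]*$", "", basename(path))
  marker_panel(name, loci)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  writeLines(panel$loci, path)
  invisible(path)
}
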