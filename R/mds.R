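# Multidimensional scaling of population distance matrices: classical
# (Torgerson) embedding, Kruskal stress-1, and SMACOF stress refinement.

# Coerce input to a plain symmetric dissimilarity matrix. Negative Phi-st
# estimates (possible from the variance-component estimators) are clamped
# to 0 by default before embedding.
.as_dissim <- function(dm, clamp_negative = TRUE) {
  d <- if (inherits(dm, "phist_matrix")) dm$d else as.matrix(dm)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  d <- (d + t(d)) / 2
  if (clamp_negative) d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Fixed sign convention: the first nonzero coordinate of each axis is made
# positive, so embeddings are bit-reproducible.
.fix_signs <- function(X) {
  for (k in seq_len(ncol(X))) {
    col <- X[, k]
    nz <- which(abs(col) > 1e-12)
    if (length(nz) && col[nz[1L]] < 0) X[, k] <- -col
  }
  X
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a population-by-population dissimilarity matrix into `dims`
#' dimensions by double-centering the squared dissimilarities and taking the
#' top eigenvectors (the standard metric MDS used to visualize population
#' differentiation). Exact when the input distances are Euclidean; the
#' Kruskal stress-1 of the embedding is attached as a misfit diagnostic.
#'
#' Axes are ordered by eigenvalue, the configuration is centered at the
#' origin, and each axis is given a fixed sign (first nonzero coordinate
#' positive) so output is reproducible bit-for-bit.
#'
#' @param dm A `phist_matrix` from [distance_matrix()], or a plain symmetric
#'   matrix.
#' @param dims Embedding dimension (default 2, for the usual scatter plot).
#' @param clamp_negative Replace negative distances by 0 before embedding
#'   (default TRUE; Phi-st estimates can be slightly negative).
#' @return An object of class `mds_embedding`: list with `populations`,
#'   `coords` (P x dims matrix), `stress` (Kruskal stress-1), `method`.
#' @export
classical_mds <- function(dm, dims = 2L, clamp_negative = TRUE) {
  d <- .as_dissim(dm, clamp_negative)
  pops <- rownames(d)
  if (is.null(pops)) pops <- paste0("pop", seq_len(nrow(d)))
  dims <- as.integer(dims)
  if (all(d == 0)) {
    coords <- matrix(0, nrow(d), dims,
                     dimnames = list(pops, paste0("dim", seq_len(dims))))
    return(structure(list(populations = pops, coords = coords, stress = 0,
                          method = "classical"), class = "mds_embedding"))
  }
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  X <- fit$points
  if (ncol(X) < dims)  # rank-deficient input: pad with zero axes
    X <- cbind(X, matrix(0, nrow(X), dims - ncol(X)))
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  X <- .fix_signs(X)
  dimnames(X) <- list(pops, paste0("dim", seq_len(dims)))
  structure(list(populations = pops, coords = X,
                 stress = stress1(X, d), method = "classical"),
            class = "mds_embedding")
}

#' Kruskal stress-1 of a configuration
#'
#' \deqn{stress_1 = \sqrt{\sum_{i<j} (\hat d_{ij} - d_{ij})^2 /
#'   \sum_{i<j} d_{ij}^2}}
#' where \eqn{\hat d} are the Euclidean distances of the configuration and
#' \eqn{d} the target dissimilarities. 0 iff the configuration reproduces
#' the dissimilarities exactly; defined as 0 for an all-zero target.
#'
#' @param coords P x k coordinate matrix.
#' @param dm Target dissimilarities (`phist_matrix` or symmetric matrix).
#' @param clamp_negative See [classical_mds()].
#' @return Non-negative scalar.
#' @export
stress1 <- function(coords, dm, clamp_negative = TRUE) {
  d <- .as_dissim(dm, clamp_negative)
  if (nrow(coords) != nrow(d)) stop("coords and dm shapes disagree")
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((dhat[upper.tri(d)] - d[upper.tri(d)])^2)
  den <- sum(d[upper.tri(d)]^2)
  if (den == 0) return(0)
  sqrt(num / den)
}

#' SMACOF stress-majorization refinement of an embedding
#'
#' Iteratively improves a configuration by the Guttman transform
#' (scaling-by-majorizing-a-complicated-function), which guarantees a
#' monotone non-increasing stress sequence. Useful when Phi-st matrices are
#' far from Euclidean and the classical solution is a rough start.
#'
#' @param embedding An `mds_embedding` (typically from [classical_mds()]).
#' @param dm The target dissimilarities the embedding was built from.
#' @param max_iter Iteration cap.
#' @param tol Stop when the stress decrease falls below `tol`.
#' @param clamp_negative See [classical_mds()].
#' @return A refined `mds_embedding` (method `"smacof"`) with an added
#'   `stress_trace` of the per-iteration stress values.
#' @export
smacof_refine <- function(embedding, dm, max_iter = 300L, tol = 1e-10,
                          clamp_negative = TRUE) {
  stopifnot(inherits(embedding, "mds_embedding"))
  d <- .as_dissim(dm, clamp_negative)
  X <- embedding$coords
  if (nrow(X) != nrow(d)) stop("embedding and dm shapes disagree")
  n <- nrow(X)
  trace <- stress1(X, d)
  if (all(d == 0) || trace == 0) {
    out <- embedding
    out$method <- "smacof"
    out$stress_trace <- trace
    return(out)
  }
  for (it in seq_len(max_iter)) {
    dhat <- as.matrix(stats::dist(X))
    ratio <- ifelse(dhat > 1e-12, d / dhat, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- (B %*% X) / n
    s <- stress1(Xn, d)
    if (s > trace[length(trace)] + 1e-12) break  # numerical floor reached
    X <- Xn
    trace <- c(trace, s)
    if (length(trace) > 1L &&
        trace[length(trace) - 1L] - s < tol) break
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  X <- .fix_signs(X)
  dimnames(X) <- dimnames(embedding$coords)
  structure(list(populations = embedding$populations, coords = X,
                 stress = stress1(X, d), method = "smacof",
                 stress_trace = trace),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, digits = 4, ...) {
  cat("MDS embedding (", x$method, "): ", length(x$populations),
      " populations, stress-1 = ", signif(x$stress, 4), "\n", sep = "")
  print(round(x$coords, digits))
  invisible(x)
}

#' @export
plot.mds_embedding <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("MDS (%s), stress-1 = %.3f", x$method, x$stress)
  graphics::plot(x$coords[, 1], x$coords[, 2], pch = 16,
                 xlab = "dimension 1", ylab = "dimension 2",
                 main = main, ...)
  graphics::text(x$coords[, 1], x$coords[, 2], labels = x$populations,
                 pos = 3, cex = 0.7)
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  invisible(x)
}

#' Write an MDS embedding as TSV with JSON metadata
#' @param x An `mds_embedding`.
#' @param path Output TSV (population, dim1, dim2, ...); metadata (stress,
#'   method) is written alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mds <- function(x, path) {
  stopifnot(inherits(x, "mds_embedding"))
  df <- data.frame(population = x$populations, x$coords,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = x$method, stress = x$stress),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
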