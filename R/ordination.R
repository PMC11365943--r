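#' Gower dissimilarity matrix
#'
#' For all-quantitative variables the Gower dissimilarity between rows i and
#' j is the mean over variables of `|x_iv - x_jv| / range_v`, with the range
#' taken over the rows of this matrix. Variables with zero range contribute
#' 0 to the numerator but still count in the mean, so distances stay in
#' \[0, 1\].
#'
#' @param values numeric matrix (rows = vertebrae, columns = variables),
#'   no missing values.
#' @param provenance optional data frame (one row per matrix row) recording
#'   specimen and position.
#' @return Object of class `gower_dist`: list with `d` (an n x n symmetric
#'   matrix, zero diagonal) and `provenance`.
#' @export
gower_matrix <- function(values, provenance = NULL) {
  x <- as.matrix(values)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (anyNA(x)) stop("missing values: clean the data first")
  rng <- apply(x, 2, function(v) diff(range(v)))
  w <- ifelse(rng > 0, 1 / rng, 0)
  xs <- sweep(x, 2, w, `*`)
  d <- as.matrix(stats::dist(xs, method = "manhattan")) / ncol(x)
  dimnames(d) <- NULL
  structure(list(d = d, provenance = provenance), class = "gower_dist")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix, eigendecomposes, and keeps
#' axes with eigenvalue above `1e-10` times the leading eigenvalue (negative
#' eigenvalues, which a Gower matrix may produce, are dropped). Scores are
#' eigenvectors scaled by the square root of their eigenvalue; the variance
#' fraction of an axis is its eigenvalue over the sum of kept eigenvalues.
#' Eigenvector signs are fixed deterministically (the largest-magnitude
#' loading of each axis is made positive) so repeated runs are
#' bit-comparable.
#'
#' @param dist a [gower_matrix()] result, or a plain symmetric matrix.
#' @return Object of class `morphospace`: list with `scores` (n x m),
#'   `eigenvalues`, `varfrac`, `provenance`.
#' @export
pco <- function(dist) {
  prov <- NULL
  if (inherits(dist, "gower_dist")) {
    prov <- dist$provenance
    d <- dist$d
  } else d <- as.matrix(dist)
  n <- nrow(d)
  cs <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  if (max(cs$eig) <= 0) stop("no positive eigenvalue: degenerate distances")
  keep <- which(cs$eig > 1e-10 * max(cs$eig))
  ev <- cs$eig[keep]
  scores <- cs$points[, keep, drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- NULL
  structure(list(scores = scores, eigenvalues = ev,
                 varfrac = ev / sum(ev), provenance = prov),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d items, %d positive axes\n",
              nrow(x$scores), ncol(x$scores)))
  k <- min(5L, length(x$varfrac))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$varfrac[seq_len(k)]), collapse = " "),
      if (length(x$varfrac) > k) "..." else "", "\n")
  invisible(x)
}

#' Select ordination axes above a variance threshold
#'
#' Axes carrying more than `threshold` of the total (positive-axis) variance
#' are retained for the segmented regressions; axis 1 is always returned so
#' the fit is never empty.
#'
#' @param space a [pco()] morphospace.
#' @param threshold variance fraction cutoff (default 0.05).
#' @return Integer vector of axis indices (a prefix of `1:m`).
#' @export
select_axes <- function(space, threshold = 0.05) {
  idx <- which(space$varfrac > threshold)
  if (length(idx) == 0) {
    warning("no axis exceeds the variance threshold; keeping axis 1")
    return(1L)
  }
  seq_len(max(idx))
}

#' Per-specimen morphospace
#'
#' Gower distances and PCO on one specimen's scaled measurements.
#'
#' @param column a cleaned, z-scored [specimen_column()].
#' @param rows optional subset of vertebra positions (e.g. the equidistant
#'   subsample); ranges are computed within the subset.
#' @return A [pco()] morphospace with provenance.
#' @export
specimen_morphospace <- function(column, rows = NULL) {
  if (is.null(rows)) rows <- column$position
  prov <- data.frame(species = column$species, specimen = column$specimen,
                     position = rows, stringsAsFactors = FALSE)
  pco(gower_matrix(column$values[rows, , drop = FALSE], prov))
}

#' Common morphospace of all vertebrae from all specimens
#'
#' Pools every vertebra of every specimen into one Gower + PCO ordination.
#' Provenance (species, specimen, position) is retained so per-specimen
#' trajectories can be extracted; the first three axes are the ones used for
#' module homology and serial disparity.
#'
#' @param columns list of cleaned, z-scored [specimen_column()].
#' @return A [pco()] morphospace with provenance.
#' @export
common_morphospace <- function(columns) {
  nm <- lapply(columns, function(c) colnames(c$values))
  if (!all(vapply(nm, identical, logical(1), nm[[1]])))
    stop("measurement schema differs across columns")
  values <- do.call(rbind, lapply(columns, function(c) c$values))
  prov <- do.call(rbind, lapply(columns, function(c)
    data.frame(species = c$species, specimen = c$specimen,
               position = c$position, stringsAsFactors = FALSE)))
  pco(gower_matrix(values, prov))
}
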