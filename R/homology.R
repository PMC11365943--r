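#' Spectral clustering with automatic cluster-number selection
#'
#' Classifies observations into clusters without a priori information on
#' the final number. The affinity is a self-tuning Gaussian kernel
#' `A_ij = exp(-d_ij^2 / (s_i s_j))` with local scales `s_i` equal to the
#' distance to the `local_k`-th neighbour, robust to unequal cluster
#' densities. The number of clusters `K` is chosen by the largest eigengap
#' of the normalized Laplacian within `k_range`, and points are partitioned
#' by k-means on the row-normalized leading `K` eigenvectors with a
#' deterministic farthest-point initialization.
#'
#' @param scores numeric matrix of observations (rows) in ordination space;
#'   for module homology, the first three axes of the common morphospace.
#' @param k_range candidate cluster numbers (default `2:15`).
#' @param seed integer seed (the initialization is deterministic; the seed
#'   is set for reproducibility of any k-means tie-breaking).
#' @param local_k neighbour index for the local scale (default 7).
#' @return Object of class `module_clustering`: list with `labels`
#'   (integer cluster per row), `K`, `laplacian_eigenvalues` (ascending)
#'   and `eigengaps`.
#' @export
spectral_cluster <- function(scores, k_range = 2:15, seed = 1L,
                             local_k = 7L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (n < max(k_range) + 1)
    stop("need more observations than the largest candidate cluster number")
  d <- as.matrix(stats::dist(x))
  if (max(d) == 0) stop("degenerate affinity: all points identical")
  scale_k <- min(local_k, n - 1L)
  s <- apply(d, 1, function(row) sort(row)[scale_k + 1L])
  s[s == 0] <- min(d[d > 0])
  a <- exp(-(d^2) / outer(s, s))
  diag(a) <- 0
  deg <- rowSums(a)
  if (any(deg == 0)) stop("degenerate affinity: isolated observation")
  isq <- 1 / sqrt(deg)
  lsym <- diag(n) - (isq * a) %*% diag(isq)
  lsym <- (lsym + t(lsym)) / 2
  e <- eigen(lsym, symmetric = TRUE)
  lambda <- rev(e$values)            # ascending
  vecs <- e$vectors[, n:1, drop = FALSE]
  k_range <- k_range[k_range < n]
  gaps <- lambda[k_range + 1L] - lambda[k_range]
  K <- k_range[which.max(gaps)]
  emb <- vecs[, seq_len(K), drop = FALSE]
  for (j in seq_len(K)) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  norms <- sqrt(rowSums(emb^2))
  norms[norms == 0] <- 1
  emb <- emb / norms
  centers <- .farthest_point_init(emb, K)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  km <- stats::kmeans(emb, centers = centers, iter.max = 100L)
  structure(list(labels = km$cluster, K = K,
                 laplacian_eigenvalues = lambda,
                 eigengaps = stats::setNames(gaps, k_range)),
            class = "module_clustering")
}

# deterministic farthest-point (maximin) seeding: start from the point
# farthest from the centroid, then add the point farthest from the chosen set
.farthest_point_init <- function(x, k) {
  ctr <- colMeans(x)
  first <- which.max(rowSums(sweep(x, 2, ctr)^2))
  chosen <- first
  mind <- rowSums(sweep(x, 2, x[first, ])^2)
  while (length(chosen) < k) {
    cand <- which.max(mind)
    if (mind[cand] == 0)
      stop("fewer distinct points than clusters")
    chosen <- c(chosen, cand)
    mind <- pmin(mind, rowSums(sweep(x, 2, x[cand, ])^2))
  }
  x[chosen, , drop = FALSE]
}

#' @export
print.module_clustering <- function(x, ...) {
  cat(sprintf("<module_clustering> K=%d over %d observations\n",
              x$K, length(x$labels)))
  invisible(x)
}

#' Smooth a cranio-caudal label sequence
#'
#' Vertebrae are serially ordered, so module labels along one column should
#' form contiguous runs. Isolated runs shorter than 2 vertebrae are
#' absorbed into the flanking module with the longer adjacent run (ties go
#' to the anterior flank), repeating until stable.
#'
#' @param labels vector of module labels in cranio-caudal order.
#' @return Smoothed label vector of the same length.
#' @export
smooth_labels <- function(labels) {
  repeat {
    r <- rle(as.vector(labels))
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < 2)
    short <- short[!(short %in% c(0))]
    if (length(short) == 0) break
    i <- short[1]
    left <- if (i > 1) r$lengths[i - 1] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
    r$values[i] <- if (left >= right) r$values[i - 1] else r$values[i + 1]
    labels <- inverse.rle(r)
  }
  as.vector(labels)
}

#' Species module map from per-specimen assignments
#'
#' Only modules identified in at least half of the species' specimens are
#' conserved. Modules are ordered cranio-caudally by the mean relative
#' position of their vertebrae, and each inter-module boundary is averaged
#' across the specimens possessing both modules on the relative scale
#' (boundary position / column length) before rescaling to the species'
#' retained vertebral count — specimens of one species can differ in count.
#'
#' @param assignments list of smoothed label vectors, one per specimen of
#'   the species, each in cranio-caudal order.
#' @param retained_count species-level vertebral count the boundaries are
#'   expressed in; defaults to the largest column length.
#' @return Object of class `species_module_map`: list with `modules`
#'   (retained labels in cranio-caudal order), `boundaries` (start
#'   positions, in vertebra units, of every module after the first) and
#'   `retained_count`.
#' @export
species_module_map <- function(assignments, retained_count = NULL) {
  stopifnot(length(assignments) >= 1)
  lens <- lengths(assignments)
  if (is.null(retained_count)) retained_count <- max(lens)
  n_spec <- length(assignments)
  mods <- sort(unique(unlist(lapply(assignments, unique))))
  presence <- vapply(mods, function(m)
    sum(vapply(assignments, function(a) m %in% a, logical(1))), numeric(1))
  keep <- mods[presence >= n_spec / 2]
  if (length(keep) == 0)
    stop("no module shared by at least half of the specimens")
  relpos <- vapply(keep, function(m)
    mean(unlist(lapply(assignments, function(a) {
      i <- which(a == m)
      if (length(i) == 0) return(NULL)
      (i - 0.5) / length(a)
    }))), numeric(1))
  ord <- order(relpos)
  keep <- keep[ord]
  bounds <- numeric(0)
  if (length(keep) > 1) {
    # a boundary is the last vertebra of the anterior module, averaged on
    # the relative scale across the specimens possessing the module
    bounds <- vapply(keep[-1], function(m) {
      ends <- unlist(lapply(assignments, function(a) {
        i <- which(a == m)
        if (length(i) == 0) return(NULL)
        (min(i) - 1) / length(a)
      }))
      mean(ends) * retained_count
    }, numeric(1))
    bounds <- sort(bounds)
  }
  structure(list(modules = keep, boundaries = unname(bounds),
                 retained_count = retained_count),
            class = "species_module_map")
}

#' @export
print.species_module_map <- function(x, ...) {
  cat(sprintf("<species_module_map> %d modules over %d vertebrae\n",
              length(x$modules), x$retained_count))
  cat("  order:", paste(x$modules, collapse = " -> "), "\n")
  if (length(x$boundaries) > 0)
    cat("  boundaries:", paste(sprintf("%.1f", x$boundaries), collapse = ", "),
        "\n")
  invisible(x)
}

#' Map fitted regions onto homologous modules
#'
#' Each region is assigned to the module to which most of its vertebrae
#' belong; ties go to the anterior (earlier-starting) module with a
#' warning.
#'
#' @param ranges a [region_ranges()] data frame tiling the column.
#' @param labels smoothed per-vertebra module labels for the same column.
#' @return Vector of module labels, one per region.
#' @export
regions_to_modules <- function(ranges, labels) {
  vapply(seq_len(nrow(ranges)), function(i) {
    seg <- labels[ranges$start[i]:ranges$end[i]]
    tb <- table(seg)
    winners <- names(tb)[tb == max(tb)]
    if (length(winners) > 1) {
      warning(sprintf("region %d: tie between modules; anterior module used",
                      ranges$region[i]))
      firsts <- vapply(winners, function(m) min(which(seg == m)), numeric(1))
      winners <- winners[which.min(firsts)]
    }
    winners
  }, character(1))
}

#' Offsets of module boundaries from anatomical landmarks
#'
#' Signed vertebra offsets between each module boundary and (a) the
#' double-headed to single-headed rib transition (position of the last
#' double-headed rib), (b) the last rib-bearing vertebra, and (c) the first
#' chevron-bearing vertebra. A missing landmark yields `NA` offsets rather
#' than an error.
#'
#' @param boundaries numeric boundary positions (vertebra units of the
#'   column supplied).
#' @param column a [specimen_column()] with flags.
#' @return Data frame with one row per boundary: `boundary`, `position`,
#'   `rib_transition`, `last_rib`, `first_chevron` offsets.
#' @export
landmark_offsets <- function(boundaries, column) {
  fl <- column$flags
  dbl <- which(fl$rib_bearing & fl$rib_head == "double")
  sgl <- which(fl$rib_bearing & fl$rib_head == "single")
  rib_trans <- if (length(dbl) > 0 && length(sgl) > 0) max(dbl) else NA_real_
  last_rib <- if (any(fl$rib_bearing)) max(which(fl$rib_bearing)) else NA_real_
  first_chev <- if (any(fl$chevron_bearing)) min(which(fl$chevron_bearing)) else NA_real_
  data.frame(boundary = seq_along(boundaries),
             position = as.numeric(boundaries),
             rib_transition = as.numeric(boundaries) - rib_trans,
             last_rib = as.numeric(boundaries) - last_rib,
             first_chevron = as.numeric(boundaries) - first_chev)
}

#' Centrum height/width ratio profile
#'
#' The ratio of centrum height to centrum width (`Hc / Wc`, on raw,
#' unscaled measurements) distinguishes laterally compressed peduncle
#' vertebrae (ratio above 1) from dorso-ventrally flattened fluke vertebrae
#' (ratio below 1).
#'
#' @param column a [specimen_column()] with raw (unscaled) values.
#' @param labels optional per-vertebra module labels; when given,
#'   per-module mean ratios are reported.
#' @return List with `ratio` (per vertebra), `shape`
#'   (`"laterally_compressed"`, `"flattened"` or `"circular"`), and
#'   `module_means` (data frame, or NULL without labels).
#' @export
centrum_ratio_profile <- function(column, labels = NULL) {
  hc <- column$values[, "Hc"]
  wc <- column$values[, "Wc"]
  if (any(wc == 0)) stop("centrum width is zero; ratio undefined")
  ratio <- hc / wc
  shape <- ifelse(ratio > 1, "laterally_compressed",
                  ifelse(ratio < 1, "flattened", "circular"))
  module_means <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(ratio))
    mm <- tapply(ratio, labels, mean)
    module_means <- data.frame(module = names(mm), mean_ratio = as.numeric(mm),
                               stringsAsFactors = FALSE)
  }
  list(ratio = ratio, shape = shape, module_means = module_means)
}

#' Cluster all vertebrae of a common morphospace into modules
#'
#' Convenience wrapper: spectral clustering on the first three axes of the
#' common morphospace, followed by per-specimen label smoothing.
#'
#' @param space a [common_morphospace()] with provenance.
#' @param k_range,seed,local_k passed to [spectral_cluster()].
#' @param axes ordination axes used (default `1:3`).
#' @return List with `K`, `clustering` and `assignments` — a named list of
#'   smoothed label vectors per specimen, in cranio-caudal order.
#' @export
cluster_modules <- function(space, k_range = 2:15, seed = 1L, local_k = 7L,
                            axes = 1:3) {
  if (is.null(space$provenance))
    stop("common morphospace must carry provenance")
  cl <- spectral_cluster(space$scores[, axes, drop = FALSE],
                         k_range = k_range, seed = seed, local_k = local_k)
  prov <- space$provenance
  assignments <- lapply(split(seq_len(nrow(prov)), prov$specimen),
                        function(rows) {
                          rows <- rows[order(prov$position[rows])]
                          smooth_labels(cl$labels[rows])
                        })
  list(K = cl$K, clustering = cl, assignments = assignments,
       species = vapply(split(prov$species, prov$specimen),
                        `[`, character(1), 1))
}
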