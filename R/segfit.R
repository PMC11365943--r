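#' Equidistant subsample of vertebral positions
#'
#' Vertebral counts vary widely across species and the number of regions
#' recovered by segmented regressions is sensitive to the number of points,
#' so the region-number search is run on a fixed, reduced number of
#' vertebrae: `n_target` positions on the rounded arithmetic progression
#' from 1 to `n_total`, always including both ends.
#'
#' @param n_total number of vertebrae in the column.
#' @param n_target number of retained vertebrae (default 33).
#' @return Sorted unique integer positions of length `n_target`.
#' @export
equidistant_subsample <- function(n_total, n_target = 33) {
  if (n_total < n_target)
    stop(sprintf("column has %d vertebrae; %d required for the fixed-count protocol",
                 n_total, n_target))
  idx <- as.integer(round(seq(1, n_total, length.out = n_target)))
  stopifnot(!anyDuplicated(idx), idx[1] == 1L, idx[n_target] == n_total)
  idx
}

# linear-spline design matrix: intercept, position, one hinge per knot.
# A breakpoint value t means "the region ends at vertebra t"; the spline
# knot sits at t itself, so a slope change occurring exactly at a vertebra
# is representable and noiseless kinked data are fitted exactly. Region
# membership for the minimum-segment rule assigns vertebra t to the region
# it ends.
.seg_basis <- function(x, breakpoints) {
  if (length(breakpoints) == 0) return(cbind(1, x))
  h <- outer(x, breakpoints, function(a, b) pmax(a - b, 0))
  cbind(1, x, h)
}

# residual sum of squares of the continuous segmented fit, summed over axes
.seg_rss <- function(scores, positions, breakpoints) {
  fit <- stats::lm.fit(.seg_basis(positions, breakpoints), scores)
  sum(fit$residuals^2)
}

# fast closure over precomputed hinge columns: rss for a configuration of
# observation indices
.make_rss_fun <- function(scores, positions) {
  n <- length(positions)
  hall <- outer(positions, positions, function(a, b) pmax(a - b, 0))
  base <- cbind(1, positions)
  y <- as.matrix(scores)
  function(idx) {
    x <- cbind(base, hall[, idx, drop = FALSE])
    sum(.lm.fit(x, y)$residuals^2)
  }
}

#' Fit one continuous segmented linear regression
#'
#' Ordinary least squares on the continuous linear-spline basis, fitted to
#' every ordination axis with a common set of breakpoints. Successive
#' segments are forced to be continuous, modelling gradational variation
#' without jumps. The fit is scored by the Bayesian information criterion
#' `BIC = n ln(s/n) + k ln(n)` with `n` the number of data points
#' (observations times axes), `s` the total residual sum of squares across
#' axes, and `k = r p + p + r - 1` parameters (one slope per region per
#' axis, one first-segment intercept per axis, one position per breakpoint).
#'
#' @param scores numeric matrix, observations x axes.
#' @param positions vertebral positions of the observations (sorted).
#' @param breakpoints sorted vector of breakpoint positions (possibly
#'   empty); each must leave at least `min_seg` observations per region.
#' @param min_seg minimum observations per region (default 3).
#' @return Object of class `segmented_model` with elements `r`,
#'   `breakpoints`, `coefficients` (basis coefficients per axis), `s`, `n`,
#'   `k`, `p`, `bic`, `saturated`, `fitted`.
#' @export
fit_segmented <- function(scores, positions, breakpoints = numeric(0),
                          min_seg = 3) {
  scores <- as.matrix(scores)
  stopifnot(length(positions) == nrow(scores))
  breakpoints <- as.numeric(breakpoints)
  if (anyDuplicated(breakpoints)) stop("duplicate breakpoints")
  if (is.unsorted(breakpoints)) stop("breakpoints must be sorted")
  region <- findInterval(positions, breakpoints + 0.5) + 1L
  cnt <- tabulate(region, nbins = length(breakpoints) + 1L)
  if (any(cnt < min_seg))
    stop(sprintf("region with fewer than %d observations", min_seg))
  r <- length(breakpoints) + 1L
  p <- ncol(scores)
  fit <- stats::lm.fit(.seg_basis(positions, breakpoints), scores)
  s <- sum(fit$residuals^2)
  n <- nrow(scores) * p
  k <- r * p + p + r - 1
  floor_s <- 1e-12 * n
  saturated <- s < floor_s
  bic <- n * log(max(s, floor_s) / n) + k * log(n)
  structure(list(r = r, breakpoints = breakpoints,
                 coefficients = as.matrix(fit$coefficients),
                 s = s, n = n, k = k, p = p, bic = bic,
                 saturated = saturated,
                 fitted = scores - as.matrix(fit$residuals)),
            class = "segmented_model")
}

#' @export
print.segmented_model <- function(x, ...) {
  cat(sprintf("<segmented_model> r=%d, p=%d, s=%.6g, BIC=%.4f\n",
              x$r, x$p, x$s, x$bic))
  if (x$r > 1)
    cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Number of admissible breakpoint configurations
#'
#' Closed-form count of ways to split `n_obs` ordered observations into `r`
#' contiguous regions of at least `min_seg` observations each.
#'
#' @param n_obs observation count.
#' @param r region count.
#' @param min_seg minimum observations per region.
#' @return A count (0 when infeasible).
#' @export
n_breakpoint_configs <- function(n_obs, r, min_seg = 3) {
  if (n_obs < r * min_seg) return(0)
  choose(n_obs - r * min_seg + r - 1, r - 1)
}

# all admissible configs as a matrix of observation indices (rows = configs)
.enumerate_configs <- function(n_obs, r, min_seg = 3) {
  if (r == 1) return(matrix(integer(0), nrow = 1, ncol = 0))
  m <- n_obs - r * min_seg + r - 1
  if (m < r - 1) stop("no admissible configuration: too few observations")
  cmb <- utils::combn(m, r - 1)
  t(cmb + (min_seg - 1) * seq_len(r - 1))
}

.config_key <- function(idx) paste(idx, collapse = ",")

#' Search breakpoint configurations for a given region count
#'
#' Exhaustive mode enumerates every admissible configuration under the
#' minimum-segment rule. Heuristic mode (for counts where enumeration is
#' combinatorially infeasible) seeds starting configurations from the best
#' model with one fewer region plus each admissible extra breakpoint and
#' from seeded random draws, then runs coordinate-wise 1-D scans over each
#' breakpoint until no improvement, restarting from the best few seeds. All
#' evaluated models are archived for breakpoint-uncertainty estimation.
#' `"auto"` picks exhaustive whenever the configuration count is at most
#' `max_exhaustive`.
#'
#' @param scores observations x axes score matrix.
#' @param positions vertebral positions (sorted).
#' @param r region count (1 to 11 in the standard protocol).
#' @param min_seg minimum observations per region.
#' @param mode `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param seed integer seed for the heuristic's random restarts.
#' @param init optional matrix of observation-index configurations used to
#'   seed the heuristic (typically the best configuration at `r - 1`).
#' @param max_exhaustive configuration-count threshold for `"auto"`.
#' @return Object of class `model_set`: list with `best` (a
#'   [fit_segmented()] model), `configs` (observation-index matrix of all
#'   evaluated configurations), `s` (their residual sums of squares), `r`,
#'   `mode`.
#' @export
search_models <- function(scores, positions, r, min_seg = 3,
                          mode = c("auto", "exhaustive", "heuristic"),
                          seed = 1L, init = NULL, max_exhaustive = 50000) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  n_obs <- length(positions)
  total <- n_breakpoint_configs(n_obs, r, min_seg)
  if (total == 0)
    stop(sprintf("no admissible configuration for r=%d with %d observations",
                 r, n_obs))
  if (r == 1) {
    best <- fit_segmented(scores, positions, numeric(0), min_seg)
    return(structure(list(best = best,
                          configs = matrix(integer(0), 1, 0),
                          s = best$s, r = 1L, mode = "exhaustive",
                          positions = positions),
                     class = "model_set"))
  }
  if (mode == "auto")
    mode <- if (total <= max_exhaustive) "exhaustive" else "heuristic"
  rss_fun <- .make_rss_fun(scores, positions)
  if (mode == "exhaustive") {
    configs <- .enumerate_configs(n_obs, r, min_seg)
    s <- vapply(seq_len(nrow(configs)),
                function(i) rss_fun(configs[i, ]), numeric(1))
  } else {
    res <- .heuristic_search(rss_fun, n_obs, r, min_seg, seed, init)
    configs <- res$configs
    s <- res$s
  }
  ib <- which.min(s)
  best <- fit_segmented(scores, positions, positions[configs[ib, ]], min_seg)
  structure(list(best = best, configs = configs, s = s, r = as.integer(r),
                 mode = mode, positions = positions),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> r=%d (%s): %d models evaluated, best s=%.6g\n",
              x$r, x$mode, length(x$s), min(x$s)))
  invisible(x)
}

# feasible range of breakpoint j given the others fixed
.coord_range <- function(idx, j, n_obs, min_seg) {
  lo <- if (j == 1) min_seg else idx[j - 1] + min_seg
  hi <- if (j == length(idx)) n_obs - min_seg else idx[j + 1] - min_seg
  if (lo > hi) integer(0) else lo:hi
}

.random_config <- function(n_obs, r, min_seg) {
  m <- n_obs - r * min_seg + r - 1
  sort(sample.int(m, r - 1)) + (min_seg - 1) * seq_len(r - 1)
}

.heuristic_search <- function(rss_fun, n_obs, r, min_seg, seed, init,
                              n_random = 40, n_keep = 10) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  seeds <- list()
  if (!is.null(init) && ncol(init) == r - 2) {
    # extend each (r-1)-region configuration by one extra breakpoint
    for (row in seq_len(nrow(init))) {
      base <- init[row, ]
      for (cand in setdiff(min_seg:(n_obs - min_seg), base)) {
        new <- sort(c(base, cand))
        gaps <- diff(c(0L, new, n_obs))
        if (all(gaps >= min_seg)) seeds[[length(seeds) + 1L]] <- new
      }
    }
  } else if (!is.null(init) && ncol(init) == r - 1) {
    # full-size configurations used directly as starting points
    for (row in seq_len(nrow(init))) {
      idx <- as.integer(init[row, ])
      gaps <- diff(c(0L, idx, n_obs))
      if (all(gaps >= min_seg)) seeds[[length(seeds) + 1L]] <- idx
    }
  }
  for (i in seq_len(n_random))
    seeds[[length(seeds) + 1L]] <- .random_config(n_obs, r, min_seg)
  seeds <- unique(seeds)
  archive <- new.env(parent = emptyenv())
  eval1 <- function(idx) {
    key <- .config_key(idx)
    hit <- archive[[key]]
    if (!is.null(hit)) return(hit)
    s <- rss_fun(idx)
    archive[[key]] <- s
    s
  }
  local_search <- function(idx) {
    cur <- eval1(idx)
    repeat {
      improved <- FALSE
      for (j in seq_along(idx)) {
        rng <- .coord_range(idx, j, n_obs, min_seg)
        for (v in rng) {
          if (v == idx[j]) next
          cand <- idx
          cand[j] <- v
          s <- eval1(cand)
          if (s < cur - 1e-12) {
            cur <- s
            idx <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    idx
  }
  seed_s <- vapply(seeds, eval1, numeric(1))
  starts <- seeds[order(seed_s)][seq_len(min(n_keep, length(seeds)))]
  best_idx <- starts[[1]]
  best_s <- Inf
  for (start in starts) {
    idx <- local_search(start)
    s <- eval1(idx)
    if (s < best_s) {
      best_s <- s
      best_idx <- idx
    }
  }
  # kick restarts: re-randomize one breakpoint of the incumbent at a time
  # and re-descend, to escape single-coordinate traps
  for (j in seq_along(best_idx)) {
    for (rep in 1:2) {
      kick <- best_idx
      kick[j] <- 0L
      lo <- if (j == 1) min_seg else kick[j - 1] + min_seg
      hi <- if (j == length(kick)) n_obs - min_seg else kick[j + 1] - min_seg
      if (lo > hi) next
      kick[j] <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
      local_search(kick)
    }
  }
  keys <- ls(archive)
  configs <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  list(configs = configs, s = vapply(keys, function(k) archive[[k]],
                                     numeric(1), USE.NAMES = FALSE))
}

#' Fit and search models for 1 to `max_regions` regions
#'
#' Runs [search_models()] for each candidate region count, feeding the best
#' configuration at `r - 1` as a heuristic seed for `r`.
#'
#' @inheritParams search_models
#' @param max_regions largest region count considered (default 11).
#' @return List of `model_set`, one per region count.
#' @export
fit_region_models <- function(scores, positions, max_regions = 11,
                              min_seg = 3, mode = "auto", seed = 1L,
                              max_exhaustive = 50000) {
  out <- vector("list", max_regions)
  prev <- NULL
  for (r in seq_len(max_regions)) {
    if (n_breakpoint_configs(length(positions), r, min_seg) == 0) {
      out <- out[seq_len(r - 1)]
      break
    }
    out[[r]] <- search_models(scores, positions, r, min_seg, mode,
                              seed = seed + r, init = prev,
                              max_exhaustive = max_exhaustive)
    ib <- which.min(out[[r]]$s)
    prev <- out[[r]]$configs[ib, , drop = FALSE]
  }
  out
}

#' Compare the best models across region counts by BIC weight
#'
#' Computes delta-BIC and BIC weights
#' `w_i = exp(-0.5 dBIC_i) / sum_j exp(-0.5 dBIC_j)` over the best model per
#' region count, and the region score — the weight-averaged number of
#' regions, a continuous regionalization level that accounts for model
#' uncertainty.
#'
#' @param models list of [fit_segmented()] models (or `model_set`s), the
#'   best per region count, in order r = 1, 2, ...
#' @return Object of class `model_comparison`: list with `table`
#'   (data frame r, s, k, bic, dbic, weight), `weights`, `best_r`
#'   (highest-weight region count) and `region_score`.
#' @export
compare_models <- function(models) {
  models <- lapply(models, function(m) if (inherits(m, "model_set")) m$best else m)
  r <- vapply(models, function(m) m$r, numeric(1))
  stopifnot(identical(r, as.numeric(seq_along(models))))
  bic <- vapply(models, function(m) m$bic, numeric(1))
  dbic <- bic - min(bic)
  w <- exp(-0.5 * dbic)
  w <- w / sum(w)
  structure(list(
    table = data.frame(r = r,
                       s = vapply(models, function(m) m$s, numeric(1)),
                       k = vapply(models, function(m) m$k, numeric(1)),
                       bic = bic, dbic = dbic, weight = w),
    weights = w, best_r = as.integer(which.max(w)),
    region_score = region_score(w)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> best r=%d, region score=%.3f\n",
              x$best_r, x$region_score))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Region score from BIC weights
#'
#' `RS = sum_i i * w_i` over models with i regions: the number of regions in
#' each candidate model scaled by its BIC weight. A species with weights 0.4
#' at seven regions and 0.6 at eight has a region score of 7.6.
#'
#' @param weights numeric vector of BIC weights for r = 1, 2, ...,
#'   summing to 1.
#' @return The region score, in `[1, length(weights)]`.
#' @export
region_score <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("BIC weights must sum to 1")
  sum(seq_along(weights) * weights)
}

#' Breakpoint position estimates from the top models
#'
#' Takes the top fraction of archived models by ascending residual sum of
#' squares (at least one) and reports, for each breakpoint index, the
#' weighted mean position and weighted standard deviation, with weights
#' proportional to the models' likelihoods, `exp(-n/2 ln(s/n))`,
#' renormalized within the retained set.
#'
#' @param set a `model_set` from [search_models()].
#' @param n data-point count for the likelihood transform (observations
#'   times axes); defaults to the set's best-model `n`.
#' @param top_frac fraction of models retained (default 0.05), rounded up.
#' @return Data frame with columns `index`, `mean`, `sd`, one row per
#'   breakpoint; attribute `n_models` gives the retained count.
#' @export
estimate_breakpoints <- function(set, n = NULL, top_frac = 0.05) {
  stopifnot(inherits(set, "model_set"))
  if (set$r == 1)
    return(structure(data.frame(index = integer(0), mean = numeric(0),
                                sd = numeric(0)), n_models = 0L))
  if (is.null(n)) n <- set$best$n
  m <- max(1L, as.integer(ceiling(top_frac * length(set$s))))
  ord <- order(set$s)[seq_len(m)]
  s_top <- set$s[ord]
  bp <- matrix(set$positions[set$configs[ord, , drop = FALSE]],
               nrow = m, ncol = set$r - 1L)
  s_floor <- pmax(s_top, 1e-12 * n)
  logw <- -(n / 2) * log(s_floor / n)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  mu <- colSums(bp * w)
  sd <- sqrt(colSums(w * sweep(bp, 2, mu)^2))
  structure(data.frame(index = seq_len(set$r - 1L), mean = mu, sd = sd),
            n_models = m)
}
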