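#' Region ranges implied by a set of breakpoints
#'
#' @param breakpoints sorted breakpoint positions (region-end convention).
#' @param n_total number of vertebrae.
#' @return Data frame with columns `region`, `start`, `end` tiling
#'   `1..n_total`.
#' @export
region_ranges <- function(breakpoints, n_total) {
  bp <- as.integer(round(breakpoints))
  data.frame(region = seq_len(length(bp) + 1L),
             start = c(1L, bp + 1L),
             end = c(bp, as.integer(n_total)))
}

#' Fractional region counts per backbone segment
#'
#' Every region lying wholly within the precaudal or caudal segment counts
#' 1 toward that segment; a region spanning the boundary contributes the
#' fraction of its vertebrae falling in each segment. A specimen with two
#' complete precaudal regions, three complete caudal regions, and an
#' eight-vertebra region spanning the boundary with five vertebrae
#' precaudal therefore has 2.625 precaudal and 3.375 caudal regions.
#'
#' @param ranges a [region_ranges()] data frame tiling the column.
#' @param boundary last precaudal vertebral position.
#' @return Named numeric vector `c(precaudal, caudal)`; the two values sum
#'   to the number of regions.
#' @export
segment_region_counts <- function(ranges, boundary) {
  n_total <- max(ranges$end)
  if (boundary < 0 || boundary > n_total)
    stop("boundary outside the column")
  if (!identical(as.integer(ranges$start),
                 as.integer(c(1L, ranges$end[-nrow(ranges)] + 1L))))
    stop("region ranges must tile the column")
  pre <- 0
  cau <- 0
  for (i in seq_len(nrow(ranges))) {
    a <- ranges$start[i]
    b <- ranges$end[i]
    if (b <= boundary) {
      pre <- pre + 1
    } else if (a > boundary) {
      cau <- cau + 1
    } else {
      len <- b - a + 1
      pre <- pre + (boundary - a + 1) / len
      cau <- cau + (b - boundary) / len
    }
  }
  c(precaudal = pre, caudal = cau)
}

#' Fit the regionalization model to one specimen
#'
#' Two-stage protocol. Stage 1 defines the best number of regions on a
#' fixed, reduced number of vertebrae (33 equidistant positions), removing
#' the bias of vertebral count on the recovered region number: a PCO is run
#' on the subsampled vertebrae, axes above the variance threshold are kept,
#' and models with 1 to `max_regions` regions are searched and compared by
#' BIC weight. Stage 2 refits on all vertebrae — with the PCO recomputed on
#' the full column — keeping only models with the predefined optimal region
#' count (the species-level optimum when supplied), and estimates each
#' breakpoint's position and uncertainty from the top 5% of models by
#' residual sum of squares.
#'
#' @param column a cleaned, z-scored [specimen_column()].
#' @param species_r region count imposed in stage 2 (the species-level
#'   optimum); defaults to the specimen's own stage-1 optimum.
#' @param max_regions largest region count considered (default 11).
#' @param min_seg minimum vertebrae per region (default 3).
#' @param n_fixed fixed vertebra count for stage 1 (default 33).
#' @param axis_threshold variance fraction for axis retention (default
#'   0.05).
#' @param mode search mode passed to [search_models()].
#' @param seed integer seed for heuristic searches.
#' @param top_frac top-model fraction for breakpoint estimation.
#' @return Object of class `specimen_region_fit` with the stage-1
#'   [compare_models()] comparison, the stage-2 `model_set`, breakpoint
#'   estimates, region ranges and fractional per-segment counts.
#' @export
fit_specimen <- function(column, species_r = NULL, max_regions = 11,
                         min_seg = 3, n_fixed = 33, axis_threshold = 0.05,
                         mode = "auto", seed = 1L, top_frac = 0.05) {
  if (is.null(column$segments)) column <- label_segments(column)
  n <- n_vertebrae(column)
  idx <- equidistant_subsample(n, n_fixed)
  ms1 <- specimen_morphospace(column, idx)
  ax1 <- select_axes(ms1, axis_threshold)
  sets1 <- fit_region_models(ms1$scores[, ax1, drop = FALSE], idx,
                             max_regions = max_regions, min_seg = min_seg,
                             mode = mode, seed = seed)
  cmp <- compare_models(sets1)
  r_star <- if (is.null(species_r)) cmp$best_r else as.integer(species_r)

  ms2 <- specimen_morphospace(column)
  ax2 <- select_axes(ms2, axis_threshold)
  init <- matrix(sets1[[r_star]]$best$breakpoints, nrow = 1)
  set2 <- search_models(ms2$scores[, ax2, drop = FALSE], column$position,
                        r_star, min_seg = min_seg, mode = mode,
                        seed = seed, init = if (r_star > 1) init)
  bp <- estimate_breakpoints(set2, top_frac = top_frac)
  ranges <- region_ranges(set2$best$breakpoints, n)
  counts <- segment_region_counts(ranges, column$precaudal_boundary)
  structure(list(species = column$species, specimen = column$specimen,
                 n_vertebrae = n, comparison = cmp, r_star = r_star,
                 p_fixed = length(ax1), p_full = length(ax2),
                 stage2 = set2, breakpoints = bp, ranges = ranges,
                 segment_counts = counts,
                 boundary = column$precaudal_boundary),
            class = "specimen_region_fit")
}

#' @export
print.specimen_region_fit <- function(x, ...) {
  cat(sprintf("<specimen_region_fit> %s / %s: r*=%d, RS=%.3f\n",
              x$species, x$specimen, x$r_star, x$comparison$region_score))
  cat(sprintf("  segment counts: precaudal=%.3f caudal=%.3f\n",
              x$segment_counts["precaudal"], x$segment_counts["caudal"]))
  invisible(x)
}

# combined mean/SD of each breakpoint across specimens: law of total
# variance — mean within-specimen variance plus variance of specimen means
.combine_breakpoints <- function(mus, sds) {
  mu <- colMeans(mus)
  va <- colMeans(sds^2) + colMeans(sweep(mus, 2, mu)^2)
  data.frame(index = seq_len(ncol(mus)), mean = mu, sd = sqrt(va))
}

#' Species-level region profile
#'
#' Stage 1 is run for every specimen; the mean BIC weight across specimens
#' is computed for each region count and the count with the highest mean
#' weight becomes the species optimum, which is then imposed on every
#' specimen's stage-2 fit. Breakpoint means and standard deviations are
#' combined across specimens by the law of total variance (mean of
#' within-specimen variances plus variance of specimen means); fractional
#' segment counts are averaged.
#'
#' @param group a `species_group` from [species_groups()], or a list of
#'   cleaned, z-scored [specimen_column()] of one species.
#' @param ... passed to [fit_specimen()].
#' @return Object of class `species_region_profile` with mean weights,
#'   species `r_star`, `region_score`, combined `breakpoints`, mean
#'   `segment_counts`, and the per-specimen fits.
#' @export
species_profile <- function(group, ...) {
  cols <- if (inherits(group, "species_group")) group$columns else group
  stopifnot(length(cols) >= 1)
  stage1 <- lapply(cols, fit_specimen, ...)
  wmat <- do.call(rbind, lapply(stage1, function(f) f$comparison$weights))
  wbar <- colMeans(wmat)
  wbar <- wbar / sum(wbar)
  r_star <- which.max(wbar)
  fits <- lapply(seq_along(cols), function(i) {
    if (stage1[[i]]$r_star == r_star) return(stage1[[i]])
    fit_specimen(cols[[i]], species_r = r_star, ...)
  })
  mismatch <- vapply(stage1, function(f) f$r_star, integer(1)) != r_star
  if (any(mismatch))
    warning(sprintf("%d specimen(s) preferred a different region count; species optimum %d used",
                    sum(mismatch), r_star))
  bp <- NULL
  if (r_star > 1) {
    mus <- do.call(rbind, lapply(fits, function(f) f$breakpoints$mean))
    sds <- do.call(rbind, lapply(fits, function(f) f$breakpoints$sd))
    bp <- .combine_breakpoints(mus, sds)
  } else {
    bp <- data.frame(index = integer(0), mean = numeric(0), sd = numeric(0))
  }
  counts <- colMeans(do.call(rbind, lapply(fits, function(f) f$segment_counts)))
  structure(list(species = cols[[1]]$species,
                 n_specimens = length(cols),
                 weights = wbar, r_star = as.integer(r_star),
                 region_score = region_score(wbar),
                 breakpoints = bp, segment_counts = counts,
                 specimen_fits = fits),
            class = "species_region_profile")
}

#' @export
print.species_region_profile <- function(x, ...) {
  cat(sprintf("<species_region_profile> %s (%d specimens): r*=%d, RS=%.3f\n",
              x$species, x$n_specimens, x$r_star, x$region_score))
  cat(sprintf("  segment counts: precaudal=%.3f caudal=%.3f\n",
              x$segment_counts["precaudal"], x$segment_counts["caudal"]))
  if (nrow(x$breakpoints) > 0) {
    cat("  breakpoints:",
        paste(sprintf("%.1f±%.2f", x$breakpoints$mean, x$breakpoints$sd),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Fit the whole regionalization pipeline for many specimens
#'
#' Groups columns by species and computes a [species_profile()] for each.
#'
#' @param columns list of cleaned, z-scored [specimen_column()].
#' @param ... passed to [fit_specimen()].
#' @return Named list of `species_region_profile`.
#' @export
fit_backbone <- function(columns, ...) {
  lapply(species_groups(columns), species_profile, ...)
}
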