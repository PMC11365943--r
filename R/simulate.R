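#' Blueprint for one synthetic vertebral column
#'
#' Defines the ground truth a simulated specimen is generated from.
#' Vertebral measurements covary strongly along the column, so the planted
#' signal is built from a small number of latent cranio-caudal gradient
#' profiles — each piecewise-linear with the same breakpoints — mixed into
#' the measurements by random loadings, plus Gaussian noise and an
#' anatomical flag plan (rib run with a double-to-single transition,
#' chevron start, terminal fluke run). Because every measurement (and
#' hence every ordination axis) is a linear mixture of the latents, each
#' retained axis is itself piecewise-linear with the full set of planted
#' breakpoints. The dominant latent is monotone — its slope alternates
#' between a low and a high band at each breakpoint without changing sign,
#' like overall vertebral size along real columns — while minor latents
#' change slope by at least `slope_jump` with random sign, so the planted
#' effect size scales with `slope_jump / noise_sd`.
#'
#' @param n number of vertebrae.
#' @param breakpoints planted region-end positions; default `r` evenly
#'   spaced interior positions.
#' @param r planted region count (used when `breakpoints` is NULL).
#' @param noise_sd Gaussian noise SD per measurement (default 0.25).
#' @param noise_cor fraction of the noise variance carried by a
#'   per-vertebra deviation shared across measurements (anatomical
#'   irregularity of a whole vertebra, default 0.5); the remainder is
#'   independent per measurement.
#' @param pos_jitter SD, in vertebra units, of an optional serial jitter
#'   of each vertebra along the cranio-caudal gradient (default 0, no
#'   jitter).
#' @param n_latents number of latent gradient profiles (default 3).
#' @param latent_sd relative amplitudes of the latent profiles; the
#'   defaults give three ordination axes above the 5% variance rule.
#' @param effect_size planted effect of each breakpoint, in noise-SD
#'   units, measured as the deflection a slope change accumulates over one
#'   mean region length. The default 8 sits well above the detectability
#'   floor of about 4, below which adjacent region counts can no longer be
#'   separated reliably at 33 observations.
#' @param slope_jump magnitude of the slope change at each breakpoint; by
#'   default derived from `effect_size`:
#'   `effect_size * noise_sd / (n / n_regions)`.
#' @param schema a [measurement_schema()].
#' @param n_rib number of rib-bearing vertebrae (default 30% of `n`).
#' @param rib_double number of double-headed ribs (default half the ribs).
#' @param chevron_start first chevron-bearing position (default ~60% of
#'   `n`).
#' @param n_fluke terminal fluke vertebrae without chevrons (default 3).
#' @param module_offsets optional list `list(boundaries =, offsets =)`
#'   planting cluster structure: `boundaries` are module-end positions and
#'   `offsets` an (n_modules x n_measurements) matrix of mean shifts.
#' @param absence optional data frame `measurement`, `start`, `end` of
#'   naturally absent runs.
#' @param seed integer seed for the slope draw.
#' @return Object of class `column_blueprint`.
#' @export
column_blueprint <- function(n, breakpoints = NULL, r = 5,
                             noise_sd = 0.25, noise_cor = 0.5,
                             pos_jitter = 0, effect_size = 8,
                             slope_jump = NULL,
                             n_latents = 3, latent_sd = c(1, 0.45, 0.3),
                             schema = default_schema(),
                             n_rib = max(3L, round(0.3 * n)),
                             rib_double = max(1L, round(n_rib / 2)),
                             chevron_start = round(0.6 * n) + 1L,
                             n_fluke = 3L, module_offsets = NULL,
                             absence = NULL, seed = 1L) {
  if (is.null(breakpoints)) {
    stopifnot(r >= 1, n >= 3 * r)
    breakpoints <- if (r == 1) integer(0) else
      round(seq(0, n, length.out = r + 1))[2:r]
    if (n > 33 && length(breakpoints) > 0) {
      # place planted breaks on the fixed-count subsample grid, so the
      # planted region count is representable at the resolution of the
      # region-number search
      grid <- equidistant_subsample(n, 33)
      breakpoints <- vapply(breakpoints, function(b)
        grid[which.min(abs(grid - b))], integer(1))
    }
  }
  breakpoints <- as.integer(breakpoints)
  if (any(diff(c(0L, breakpoints, n)) < 3))
    stop("planted breakpoints violate the minimum 3-vertebra spacing")
  if (chevron_start <= n_rib)
    stop("chevron start must be caudal to the rib-bearing run")
  nr <- length(breakpoints) + 1L
  nm <- nrow(schema)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  nl <- n_latents
  latent_sd <- rep_len(latent_sd, nl)
  if (is.null(slope_jump))
    slope_jump <- effect_size * noise_sd / (n / (length(breakpoints) + 1))
  x <- seq_len(n)
  basis <- .seg_basis(x, breakpoints)
  # dominant latent: a monotone cranio-caudal gradient whose slope
  # alternates between a low and a high band at each breakpoint (vertebral
  # size and process development change rate, never direction); minor
  # latents: free piecewise profiles with random-sign slope changes.
  # Monotonicity of the dominant gradient keeps the pooled dissimilarities
  # close to additive along the column.
  dir1 <- sample(c(-1, 1), 1)
  lowhigh <- function(r) if (r %% 2 == 1) stats::runif(1, 0.5, 0.8)
    else stats::runif(1, 1.7, 2.0)
  slopes1 <- dir1 * slope_jump * vapply(seq_len(nr), lowhigh, numeric(1))
  first_slope <- numeric(nl)
  first_slope[1] <- slopes1[1]
  jumps <- if (nr > 1) matrix(0, nr - 1, nl)
  if (nr > 1) jumps[, 1] <- diff(slopes1)
  dom <- drop(basis %*% c(0, slopes1[1], if (nr > 1) diff(slopes1)))
  base_amp <- stats::sd(dom)
  lat_signal <- matrix(0, n, nl)
  lat_signal[, 1] <- (dom - mean(dom)) / base_amp * latent_sd[1] * base_amp
  # minor latents: free piecewise profiles, slope changes of random sign
  # and magnitude in [1, 1.5] x slope_jump so every breakpoint is visible;
  # decorrelated from the earlier latents by projection, redrawing any
  # profile whose independent part is less than half its size (rescaling
  # a near-collinear residual would plant slopes the truth doesn't own)
  if (nl > 1) {
    for (k in 2:nl) {
      for (try in 1:50) {
        fs <- stats::runif(1, -slope_jump, slope_jump)
        jk <- if (nr > 1) sample(c(-1, 1), nr - 1, TRUE) *
          stats::runif(nr - 1, slope_jump, 1.5 * slope_jump) else numeric(0)
        raw <- drop(basis %*% c(0, fs, jk))
        q <- stats::lsfit(cbind(1, lat_signal[, seq_len(k - 1)]), raw,
                          intercept = FALSE)$residuals
        if (stats::sd(q) >= 0.5 * stats::sd(raw)) break
      }
      first_slope[k] <- fs
      if (nr > 1) jumps[, k] <- jk
      lat_signal[, k] <- q * latent_sd[k] * base_amp / stats::sd(q)
    }
  }
  # measurement loadings sample the latent gradients evenly (a measurement
  # suite is designed to cover distinct aspects of vertebral shape): for
  # three latents, a randomly rotated Fibonacci-sphere set of directions;
  # otherwise random unit directions
  if (nl == 3) {
    i <- seq_len(nm)
    z <- 1 - 2 * (i - 0.5) / nm
    phi <- i * pi * (3 - sqrt(5))
    dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    loadings <- dirs %*% rot
  } else {
    loadings <- matrix(stats::rnorm(nm * nl), nm, nl)
    loadings <- loadings / sqrt(rowSums(loadings^2))
  }
  structure(list(n = as.integer(n), breakpoints = breakpoints,
                 first_slope = first_slope, jumps = jumps,
                 lat_signal = lat_signal,
                 loadings = loadings, latent_sd = latent_sd,
                 intercept = stats::runif(nm, -1, 1),
                 noise_sd = rep_len(noise_sd, nm), noise_cor = noise_cor,
                 pos_jitter = pos_jitter, schema = schema,
                 n_rib = as.integer(n_rib),
                 rib_double = as.integer(min(rib_double, n_rib)),
                 chevron_start = as.integer(chevron_start),
                 n_fluke = as.integer(n_fluke),
                 module_offsets = module_offsets, absence = absence,
                 seed = as.integer(seed)),
            class = "column_blueprint")
}

#' Simulate one specimen column from a blueprint
#'
#' Each measurement follows `intercept + slope * x` within regions, chained
#' so the noiseless signal is continuous at every planted knot (mirroring
#' the continuous-fit assumption), plus Gaussian noise. Set
#' `discontinuous = TRUE` to add per-region jumps for negative-control
#' experiments.
#'
#' @param bp a [column_blueprint()].
#' @param species,specimen identifiers for the generated column.
#' @param seed noise seed (distinct specimens of one blueprint share the
#'   signal, not the noise).
#' @param discontinuous break continuity at the knots (default FALSE).
#' @return List with `column` (a [specimen_column()], segments labelled)
#'   and `truth` (planted breakpoints, coefficients, flags, module labels).
#' @export
simulate_column <- function(bp, species = "sp1", specimen = "sp1_a",
                            seed = bp$seed, discontinuous = FALSE) {
  n <- bp$n
  x <- seq_len(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  nm <- nrow(bp$schema)
  nl <- length(bp$first_slope)
  latents <- bp$lat_signal
  if (bp$pos_jitter > 0) {
    # serial jitter: a vertebra sits slightly ahead of or behind its
    # nominal position along the gradient, displacing all measurements
    # coherently
    x_eff <- pmin(pmax(x + stats::rnorm(n, 0, bp$pos_jitter), 1), n)
    latents <- apply(latents, 2, function(l)
      stats::approx(x, l, xout = x_eff)$y)
  }
  # serial deviation of each gradient profile: independent per vertebra
  # and per latent, so it reaches the ordination axes undiluted
  latents <- latents + matrix(stats::rnorm(n * nl, 0, bp$noise_sd[1]), n, nl)
  if (discontinuous && length(bp$breakpoints) > 0) {
    region <- findInterval(x, bp$breakpoints + 0.001) + 1L
    shifts <- matrix(stats::rnorm(length(unique(region)) * nl, 0, 1),
                     ncol = nl)
    latents <- latents + shifts[region, ]
  }
  signal <- rep(1, n) %o% bp$intercept + latents %*% t(bp$loadings)
  module_labels <- NULL
  if (!is.null(bp$module_offsets)) {
    mb <- bp$module_offsets$boundaries
    module_labels <- findInterval(x, mb + 0.5) + 1L
    signal <- signal + bp$module_offsets$offsets[module_labels, , drop = FALSE]
  }
  # total per-measurement noise SD is noise_sd; a fraction of its variance
  # is a per-vertebra deviation shared across measurements (an irregular
  # vertebra is irregular in several measurements at once), which, unlike
  # independent noise, is not filtered into the tail ordination axes
  cor_frac <- bp$noise_cor
  iid <- matrix(stats::rnorm(n * nm), n, nm)
  shared <- stats::rnorm(n) %o% sample(c(-1, 1), nm, replace = TRUE)
  noise <- sweep(sqrt(1 - cor_frac) * iid + sqrt(cor_frac) * shared,
                 2, bp$noise_sd, `*`)
  values <- signal + noise
  colnames(values) <- bp$schema$name
  flags <- data.frame(
    rib_bearing = x <= bp$n_rib,
    rib_head = ifelse(x <= bp$rib_double, "double",
                      ifelse(x <= bp$n_rib, "single", "none")),
    chevron_bearing = x >= bp$chevron_start & x <= n - bp$n_fluke,
    fluke = x > n - bp$n_fluke)
  status <- matrix("measured", n, nm,
                   dimnames = list(NULL, bp$schema$name))
  if (!is.null(bp$absence)) {
    for (i in seq_len(nrow(bp$absence)))
      status[bp$absence$start[i]:bp$absence$end[i],
             bp$absence$measurement[i]] <- "absent"
  }
  col <- label_segments(specimen_column(species, specimen, values, flags,
                                        status, bp$schema))
  list(column = col,
       truth = list(breakpoints = bp$breakpoints, r = length(bp$breakpoints) + 1L,
                    intercept = bp$intercept, first_slope = bp$first_slope,
                    jumps = bp$jumps, loadings = bp$loadings,
                    noise_sd = bp$noise_sd,
                    module_labels = module_labels,
                    precaudal_boundary = col$precaudal_boundary,
                    seed = seed))
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree rescaled to unit depth.
#'
#' @param n_taxa number of tips (at least 3).
#' @param birth speciation rate (default 1).
#' @param seed integer seed.
#' @return An [ape::phylo] tree with tips `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_taxa, birth = 1, seed = 1L) {
  stopifnot(n_taxa >= 3)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tr
}

#' Evolve a continuous trait with known phylogenetic signal
#'
#' One multivariate-normal draw with lambda-scaled Brownian covariance:
#' tips covary by `sigma2 * lambda * shared path length` with variances
#' `sigma2 * depth`. At lambda 0 tip values are independent; at `sigma2 =
#' 0` all tips equal the root value.
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma2 Brownian rate (non-negative).
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param root root state (default 0).
#' @param seed integer seed.
#' @return Named numeric vector of tip values.
#' @export
evolve_trait <- function(tree, sigma2, lambda = 1, root = 0, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  n <- length(tree$tip.label)
  if (sigma2 == 0)
    return(stats::setNames(rep(root, n), tree$tip.label))
  V <- .pagel_cov(ape::vcv(tree), lambda)
  U <- chol(sigma2 * V)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  stats::setNames(root + drop(t(U) %*% stats::rnorm(n)), tree$tip.label)
}

#' Blueprint for a whole synthetic comparative study
#'
#' Defaults emulate the structure of a comparative cetacean dataset:
#' 62 species with 1-3 specimens each, 33-90 post-cervical vertebrae,
#' habitat frequencies 7 rivers-bays : 11 coastal : 8 mixed : 36 offshore,
#' region number increasing with vertebral count (6 to 9 regions), serial
#' disparity decreasing with count, riverine species drawing the low
#' counts, and burst swimming speed following a planted linear model on
#' region score with Brownian residuals of known lambda.
#'
#' @param n_species number of species.
#' @param count_range vertebral count bounds.
#' @param habitat_probs named habitat sampling probabilities.
#' @param lambda planted Pagel's lambda of trait residuals.
#' @param rs_noise_sd Brownian SD of region score around its count trend.
#' @param disp_intercept,disp_slope planted disparity ~ count line.
#' @param disp_noise_sd Brownian SD of disparity residuals.
#' @param burst_intercept,burst_slope planted size-corrected burst speed ~
#'   region score line.
#' @param burst_noise_sd Brownian SD of burst-speed residuals.
#' @param column_noise_sd measurement noise for the generated columns.
#' @param seed master seed.
#' @return Object of class `study_blueprint` (a list of the above).
#' @export
study_blueprint <- function(n_species = 62, count_range = c(33L, 90L),
                            habitat_probs = c(rivers_bays = 7, coastal = 11,
                                              mixed = 8, offshore = 36) / 62,
                            lambda = 1, rs_noise_sd = 0.3,
                            disp_intercept = 1.3, disp_slope = -0.008,
                            disp_noise_sd = 0.05,
                            burst_intercept = 0.5, burst_slope = 0.25,
                            burst_noise_sd = 0.15,
                            column_noise_sd = 0.25, seed = 1L) {
  structure(as.list(environment()), class = "study_blueprint")
}

#' Simulate a complete comparative study with known truth
#'
#' Generates a phylogeny, per-species ecology and vertebral counts,
#' specimen columns with planted region structure, and a species trait
#' table in which every headline relationship (region score and disparity
#' versus count, habitat effects, burst speed versus region score) has
#' known planted coefficients recorded in the `truth` element.
#'
#' @param bp a [study_blueprint()].
#' @return List with `columns` (all specimens), `tree`, `traits` (species
#'   trait table, row names = species), and `truth`.
#' @export
simulate_study <- function(bp = study_blueprint()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(bp$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  ns <- bp$n_species
  tree <- simulate_tree(ns, seed = bp$seed + 1L)
  species <- tree$tip.label
  habitat <- sample(names(bp$habitat_probs), ns, replace = TRUE,
                    prob = bp$habitat_probs)
  lo <- bp$count_range[1]
  hi <- bp$count_range[2]
  span <- hi - lo
  count_window <- list(
    rivers_bays = c(0, 0.25), coastal = c(0.2, 0.55),
    mixed = c(0.3, 0.7), offshore = c(0.4, 1))
  count <- vapply(habitat, function(h) {
    w <- count_window[[h]]
    as.integer(round(stats::runif(1, lo + w[1] * span, lo + w[2] * span)))
  }, integer(1))
  rs_trend <- 6 + 3 * (count - lo) / span
  rs <- rs_trend + bp$rs_noise_sd *
    evolve_trait(tree, 1, bp$lambda, 0, seed = bp$seed + 2L)
  rs <- pmin(pmax(rs, 1), 11)
  r_int <- pmin(pmax(as.integer(round(rs)), 3L), 11L)
  disp <- bp$disp_intercept + bp$disp_slope * count + bp$disp_noise_sd *
    evolve_trait(tree, 1, bp$lambda, 0, seed = bp$seed + 3L)
  body_size <- stats::runif(ns, 2, 4) +
    ifelse(habitat == "offshore", stats::runif(ns, 0, 6), 0)
  sustained_sc <- 1.5 + 0.1 *
    evolve_trait(tree, 1, bp$lambda, 0, seed = bp$seed + 4L)
  burst_sc <- bp$burst_intercept + bp$burst_slope * rs + bp$burst_noise_sd *
    evolve_trait(tree, 1, bp$lambda, 0, seed = bp$seed + 5L)
  # mirror the study's availability: ~34/62 sustained, ~26/62 burst
  has_sust <- seq_len(ns) %in% sample.int(ns, round(ns * 34 / 62))
  has_burst <- seq_len(ns) %in% sample.int(ns, round(ns * 26 / 62))
  sustained_sc[!has_sust] <- NA
  burst_sc[!has_burst] <- NA
  chevron_start <- pmax(as.integer(round(0.55 * count)), 5L)
  n_specimens <- sample(1:3, ns, replace = TRUE)
  columns <- list()
  col_truth <- list()
  for (i in seq_len(ns)) {
    cb <- column_blueprint(
      n = count[i], r = r_int[i], noise_sd = bp$column_noise_sd,
      n_rib = max(3L, round(0.3 * count[i])),
      chevron_start = chevron_start[i],
      seed = bp$seed + 10L + i)
    for (j in seq_len(n_specimens[i])) {
      id <- sprintf("%s_%d", species[i], j)
      sim <- simulate_column(cb, species = species[i], specimen = id,
                             seed = bp$seed + 1000L + 10L * i + j)
      columns[[id]] <- sim$column
      col_truth[[id]] <- sim$truth
    }
  }
  traits <- data.frame(
    species = species, habitat = habitat, count = count,
    precaudal_count = chevron_start - 1L,
    caudal_count = count - chevron_start + 1L,
    region_score = as.numeric(rs), r = r_int,
    disparity = as.numeric(disp), body_size = body_size,
    sustained_speed = as.numeric(sustained_sc) * body_size,
    burst_speed = as.numeric(burst_sc) * body_size,
    sustained_sc = as.numeric(sustained_sc),
    burst_sc = as.numeric(burst_sc),
    row.names = species, stringsAsFactors = FALSE)
  truth <- list(
    seed = bp$seed, lambda = bp$lambda,
    rs_per_count = 3 / span,
    disp_slope = bp$disp_slope, disp_intercept = bp$disp_intercept,
    burst_slope = bp$burst_slope, burst_intercept = bp$burst_intercept,
    habitat_count_windows = count_window,
    columns = col_truth)
  list(columns = columns, tree = tree, traits = traits, truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits the measurement CSV dialect of [read_columns()], a Newick tree, a
#' trait CSV and a truth JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_columns(study$columns, file.path(dir, "measurements.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(study$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$truth[setdiff(names(study$truth), "columns")],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
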