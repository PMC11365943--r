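#' Ordered vertebral column of one specimen
#'
#' A `specimen_column` holds the post-cervical vertebrae of one specimen in
#' cranio-caudal order, with one row per vertebra: the measurement values, a
#' per-measurement status (`measured`, `absent` for naturally missing
#' apophyses, `broken` for damaged ones), and the anatomical flags used to
#' delimit segments (rib-bearing, rib-head type, chevron-bearing, fluke).
#'
#' @param species species identifier.
#' @param specimen specimen identifier.
#' @param measurements numeric data frame or matrix, one column per schema
#'   measurement, one row per vertebra in cranio-caudal order.
#' @param flags data frame with logical columns `rib_bearing`,
#'   `chevron_bearing`, `fluke` and character `rib_head`
#'   (`"double"`, `"single"` or `"none"`).
#' @param status character matrix of the same shape as `measurements` with
#'   entries `measured`, `absent` or `broken`; defaults to all `measured`.
#' @param schema a [measurement_schema()]; defaults to [default_schema()].
#' @return An object of class `specimen_column`.
#' @export
specimen_column <- function(species, specimen, measurements, flags,
                            status = NULL, schema = default_schema()) {
  m <- as.matrix(measurements)
  if (!is.numeric(m)) stop("measurements must be numeric")
  if (ncol(m) != nrow(schema))
    stop(sprintf("expected %d measurement columns, got %d",
                 nrow(schema), ncol(m)))
  colnames(m) <- schema$name
  n <- nrow(m)
  if (n < 1L) stop("a column needs at least one vertebra")
  if (is.null(status)) {
    status <- matrix("measured", n, ncol(m), dimnames = dimnames(m))
  } else {
    status <- as.matrix(status)
    dimnames(status) <- dimnames(m)
  }
  if (!all(status %in% c("measured", "absent", "broken")))
    stop("unknown status code: statuses must be measured/absent/broken")
  flags <- as.data.frame(flags)
  need <- c("rib_bearing", "rib_head", "chevron_bearing", "fluke")
  if (!all(need %in% names(flags)))
    stop("flags must contain rib_bearing, rib_head, chevron_bearing, fluke")
  flags$rib_bearing <- as.logical(flags$rib_bearing)
  flags$chevron_bearing <- as.logical(flags$chevron_bearing)
  flags$fluke <- as.logical(flags$fluke)
  flags$rib_head <- as.character(flags$rib_head)
  if (!all(flags$rib_head %in% c("double", "single", "none")))
    stop("rib_head must be double/single/none")
  if (any(flags$rib_bearing == (flags$rib_head == "none")))
    stop("rib_head must be 'none' exactly on non rib-bearing vertebrae")
  if (any(flags$fluke & flags$rib_bearing))
    stop("fluke vertebrae cannot be rib-bearing")
  structure(
    list(species = as.character(species), specimen = as.character(specimen),
         position = seq_len(n), values = m, status = status,
         flags = flags[need], segments = NULL, schema = schema),
    class = "specimen_column")
}

#' @export
print.specimen_column <- function(x, ...) {
  cat(sprintf("<specimen_column> %s / %s: %d vertebrae, %d measurements\n",
              x$species, x$specimen, nrow(x$values), ncol(x$values)))
  if (!is.null(x$segments)) {
    tb <- table(factor(x$segments,
                       levels = c("thoracic", "lumbar", "caudal", "fluke")))
    cat("  segments:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
        "\n")
  }
  ns <- sum(x$status != "measured")
  if (ns > 0) cat(sprintf("  %d non-measured entries (absent/broken)\n", ns))
  invisible(x)
}

#' Number of vertebrae in a column
#' @param column a [specimen_column()].
#' @return integer count.
#' @export
n_vertebrae <- function(column) nrow(column$values)

#' Label anatomical segments of a column
#'
#' Thoracic vertebrae are the rib-bearing ones; the caudal segment starts at
#' the first chevron-bearing vertebra and comprises all chevron-bearing plus
#' the terminal fluke vertebrae; lumbars are the remainder between the last
#' rib and the first chevron. The precaudal segment is thoracic plus lumbar.
#'
#' @param column a [specimen_column()].
#' @return The column with `$segments` filled (values `thoracic`, `lumbar`,
#'   `caudal`, `fluke`) and `$precaudal_boundary`, the last precaudal
#'   position.
#' @export
label_segments <- function(column) {
  fl <- column$flags
  n <- nrow(column$values)
  ribs <- which(fl$rib_bearing)
  chev <- which(fl$chevron_bearing)
  if (length(chev) > 0 && length(ribs) > 0 && min(chev) < max(ribs))
    stop(sprintf("chevron-bearing vertebra at position %d anterior to rib-bearing vertebra at %d",
                 min(chev), max(ribs)))
  first_caudal <- if (length(chev) > 0) min(chev) else n + 1L
  seg <- rep("lumbar", n)
  seg[fl$rib_bearing] <- "thoracic"
  seg[seq_len(n) >= first_caudal] <- "caudal"
  seg[fl$fluke] <- "fluke"
  column$segments <- seg
  column$precaudal_boundary <- first_caudal - 1L
  column
}

#' Precaudal/caudal segment of every vertebra
#' @param column a labelled [specimen_column()].
#' @return character vector, `"precaudal"` or `"caudal"` per vertebra.
#' @export
segment_side <- function(column) {
  if (is.null(column$segments)) column <- label_segments(column)
  ifelse(column$segments %in% c("thoracic", "lumbar"), "precaudal", "caudal")
}

# runs of TRUE in a logical vector -> data.frame(start, end)
.runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start[r$values], end = end[r$values])
}

#' Resolve naturally absent apophyses
#'
#' Linear measurements of an absent apophysis are coded zero, with one
#' exception: metapophysis height (`Hm`) on a run of lumbar vertebrae that
#' is flanked on both sides by metapophysis-bearing vertebrae is set to the
#' mean `Hm` of the two flanking vertebrae (metapophyses in the lumbar
#' region are generally well developed, so zeroing would fabricate an
#' anatomical change). Angular measurements of absent apophyses are never
#' zeroed: a terminal run copies the value of the closest vertebra still
#' bearing the apophysis, an interior run takes the mean of the two flanking
#' bearing vertebrae. Statuses are preserved for audit.
#'
#' @param column a [specimen_column()] with statuses set; segments are
#'   labelled on the fly if missing.
#' @return The column with absent-apophysis values resolved.
#' @export
apply_absence_rules <- function(column) {
  if (is.null(column$segments)) column <- label_segments(column)
  sch <- column$schema
  v <- column$values
  st <- column$status
  n <- nrow(v)
  for (j in seq_len(nrow(sch))) {
    nm <- sch$name[j]
    abs_j <- st[, nm] == "absent"
    if (!any(abs_j)) next
    meas_j <- which(st[, nm] == "measured")
    if (sch$kind[j] == "angular") {
      if (length(meas_j) == 0)
        stop(sprintf("angular measurement %s absent on every vertebra", nm))
      runs <- .runs(abs_j)
      for (i in seq_len(nrow(runs))) {
        lo <- meas_j[meas_j < runs$start[i]]
        hi <- meas_j[meas_j > runs$end[i]]
        fill <- if (length(lo) > 0 && length(hi) > 0) {
          mean(c(v[max(lo), nm], v[min(hi), nm]))
        } else if (length(lo) > 0) {
          v[max(lo), nm]
        } else {
          v[min(hi), nm]
        }
        v[runs$start[i]:runs$end[i], nm] <- fill
      }
    } else {
      v[abs_j, nm] <- 0
      if (nm == "Hm") {
        runs <- .runs(abs_j)
        for (i in seq_len(nrow(runs))) {
          idx <- runs$start[i]:runs$end[i]
          if (!all(column$segments[idx] == "lumbar")) next
          lo <- meas_j[meas_j < runs$start[i]]
          hi <- meas_j[meas_j > runs$end[i]]
          if (length(lo) > 0 && length(hi) > 0)
            v[idx, nm] <- mean(c(v[max(lo), nm], v[min(hi), nm]))
        }
      }
    }
  }
  column$values <- v
  column
}

#' Interpolate broken measurements
#'
#' Each measurement with status `broken` is replaced by the mean of the same
#' measurement on the nearest non-broken vertebra on each side; at the ends
#' of the column the single nearest non-broken value is copied. Absence
#' rules must be applied first so neighbour values are always defined.
#'
#' @param column a [specimen_column()] after [apply_absence_rules()].
#' @return The column with broken values interpolated; statuses preserved.
#' @export
impute_broken <- function(column) {
  v <- column$values
  st <- column$status
  for (nm in colnames(v)) {
    brk <- which(st[, nm] == "broken")
    if (length(brk) == 0) next
    ok <- which(st[, nm] != "broken")
    if (length(ok) == 0)
      stop(sprintf("measurement %s broken on every vertebra", nm))
    for (i in brk) {
      lo <- ok[ok < i]
      hi <- ok[ok > i]
      v[i, nm] <- if (length(lo) > 0 && length(hi) > 0) {
        mean(c(v[max(lo), nm], v[min(hi), nm]))
      } else if (length(lo) > 0) v[max(lo), nm] else v[min(hi), nm]
    }
  }
  column$values <- v
  column
}

#' Z-transform measurements within a specimen
#'
#' Each of the measurement variables is centred and scaled to unit sample
#' standard deviation (n - 1 denominator) across the specimen's vertebrae.
#' A constant variable carries no serial information and is set to all-zero
#' with a warning.
#'
#' @param column a cleaned [specimen_column()].
#' @return The column with scaled values.
#' @export
zscore_column <- function(column) {
  v <- column$values
  if (nrow(v) < 2) stop("z-scoring needs at least 2 vertebrae")
  for (nm in colnames(v)) {
    s <- stats::sd(v[, nm])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("variable %s is constant within specimen %s; set to zero",
                      nm, column$specimen))
      v[, nm] <- 0
    } else {
      v[, nm] <- (v[, nm] - mean(v[, nm])) / s
    }
  }
  column$values <- v
  column$scaled <- TRUE
  column
}

#' Full cleaning pipeline for one column
#'
#' Labels segments, resolves absent apophyses, interpolates broken
#' measurements, and (optionally) z-transforms, in that order.
#'
#' @param column a [specimen_column()].
#' @param scale z-transform after cleaning (default TRUE).
#' @return The cleaned column.
#' @export
clean_column <- function(column, scale = TRUE) {
  column <- impute_broken(apply_absence_rules(label_segments(column)))
  if (scale) column <- zscore_column(column)
  column
}

#' Group specimen columns by species
#'
#' When vertebral counts differ across specimens of a species, the highest
#' count is the one retained for species-level analyses.
#'
#' @param columns list of [specimen_column()].
#' @return Named list of `species_group` objects, each with elements
#'   `species`, `columns`, `retained_count`.
#' @export
species_groups <- function(columns) {
  if (length(columns) == 0) stop("no columns supplied")
  sp <- vapply(columns, function(c) c$species, character(1))
  lapply(split(columns, sp), function(cols) {
    structure(list(species = cols[[1]]$species, columns = cols,
                   retained_count = max(vapply(cols, n_vertebrae, integer(1)))),
              class = "species_group")
  })
}

#' @export
print.species_group <- function(x, ...) {
  cat(sprintf("<species_group> %s: %d specimen(s), retained count %d\n",
              x$species, length(x$columns), x$retained_count))
  invisible(x)
}
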