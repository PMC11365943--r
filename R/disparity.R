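#' Euclidean distances between successive vertebrae
#'
#' Serial disparity is built from the Euclidean distance between each pair
#' of successive vertebrae of one specimen in the common morphospace,
#' using ordination axes 1 to 3.
#'
#' @param scores numeric matrix of the specimen's vertebrae (rows in
#'   cranio-caudal order) in the common morphospace.
#' @param axes axes used (default `1:3`).
#' @return Numeric vector of `N - 1` distances in position order.
#' @export
successive_distances <- function(scores, axes = 1:3) {
  x <- as.matrix(scores)[, axes, drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 vertebrae")
  sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
}

#' Serial disparity summary for one specimen
#'
#' Mean successive-vertebra distance for the whole backbone and for the
#' precaudal and caudal segments. A pair belongs to a segment only when
#' both of its vertebrae do; the single pair straddling the
#' precaudal/caudal boundary contributes to the whole-column mean only, so
#' segment means stay pure. A segment with fewer than two vertebrae has an
#' undefined (NA) mean.
#'
#' @param distances successive distances from [successive_distances()].
#' @param side per-vertebra segment side (`"precaudal"`/`"caudal"`), e.g.
#'   from [segment_side()]; length one more than `distances`.
#' @return Named numeric vector `c(whole, precaudal, caudal)`.
#' @export
disparity_summary <- function(distances, side) {
  stopifnot(length(side) == length(distances) + 1)
  a <- side[-length(side)]
  b <- side[-1]
  pre <- a == "precaudal" & b == "precaudal"
  cau <- a == "caudal" & b == "caudal"
  c(whole = mean(distances),
    precaudal = if (any(pre)) mean(distances[pre]) else NA_real_,
    caudal = if (any(cau)) mean(distances[cau]) else NA_real_)
}

#' Serial disparity for every specimen and species
#'
#' Extracts each specimen's trajectory from the common morphospace,
#' computes successive distances on axes 1-3 and the per-segment means,
#' then averages specimens within species.
#'
#' @param space a [common_morphospace()] with provenance.
#' @param columns the list of labelled [specimen_column()] the space was
#'   built from (provides segment sides).
#' @param axes ordination axes (default `1:3`).
#' @return List with `specimens` and `species` data frames of whole /
#'   precaudal / caudal disparity.
#' @export
disparity_profile <- function(space, columns, axes = 1:3) {
  prov <- space$provenance
  names(columns) <- vapply(columns, function(c) c$specimen, character(1))
  rows_by_spec <- split(seq_len(nrow(prov)), prov$specimen)
  spec_df <- do.call(rbind, lapply(names(rows_by_spec), function(sp) {
    rows <- rows_by_spec[[sp]]
    rows <- rows[order(prov$position[rows])]
    col <- columns[[sp]]
    d <- successive_distances(space$scores[rows, , drop = FALSE], axes)
    s <- disparity_summary(d, segment_side(col))
    data.frame(species = col$species, specimen = sp,
               whole = s["whole"], precaudal = s["precaudal"],
               caudal = s["caudal"], row.names = NULL)
  }))
  sp_df <- do.call(rbind, lapply(split(spec_df, spec_df$species), function(d)
    data.frame(species = d$species[1],
               whole = mean(d$whole), precaudal = mean(d$precaudal),
               caudal = mean(d$caudal), row.names = NULL)))
  rownames(sp_df) <- NULL
  list(specimens = spec_df, species = sp_df)
}
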