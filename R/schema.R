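#' Measurement schema for per-vertebra morphometrics
#'
#' A schema lists the measurements taken on every vertebra, whether each is
#' linear (taken in mm) or angular (degrees), and which apophysis or element
#' of the vertebra it describes. The apophysis group drives the cleaning
#' rules: when an apophysis is naturally absent, all of its linear
#' measurements are zeroed while its angular measurements are interpolated
#' from neighbouring vertebrae that still bear the apophysis.
#'
#' @param names character vector of unique measurement identifiers.
#' @param kind character vector, one of `"linear"` or `"angular"` per name.
#' @param group character vector giving the apophysis/element each
#'   measurement describes (e.g. `"neural_spine"`, `"centrum"`).
#' @return An object of class `measurement_schema`: a data frame with
#'   columns `name`, `kind`, `group`.
#' @export
measurement_schema <- function(names, kind, group) {
  if (anyDuplicated(names)) stop("measurement names must be unique")
  if (length(kind) != length(names) || length(group) != length(names))
    stop("names, kind and group must have equal length")
  if (!all(kind %in% c("linear", "angular")))
    stop("kind must be 'linear' or 'angular'")
  out <- data.frame(name = as.character(names), kind = as.character(kind),
                    group = as.character(group), stringsAsFactors = FALSE)
  class(out) <- c("measurement_schema", "data.frame")
  out
}

#' Default 16-measurement vertebral schema
#'
#' Fourteen linear and two angular measurements. The named core comprises
#' centrum height (`Hc`), centrum width (`Wc`), metapophysis height (`Hm`)
#' and the antero-posterior inclinations of the neural spine (`Inp`) and
#' transverse process (`Itp`); the remaining eleven linear slots cover the
#' other apophyses (centrum length, neural-spine and transverse-process
#' extents, zygapophyses, metapophysis width, chevron height) and can be
#' renamed or replaced by the user — downstream computation depends only on
#' the count and the linear/angular kind.
#'
#' @return A [measurement_schema()] with 16 rows.
#' @export
default_schema <- function() {
  measurement_schema(
    names = c("Lc", "Hc", "Wc",
              "Hns", "Wns", "Inp",
              "Wtp", "Htp", "Itp",
              "Hm", "Wm",
              "Hprz", "Wprz",
              "Hpoz", "Wpoz",
              "Hch"),
    kind = c("linear", "linear", "linear",
             "linear", "linear", "angular",
             "linear", "linear", "angular",
             "linear", "linear",
             "linear", "linear",
             "linear", "linear",
             "linear"),
    group = c("centrum", "centrum", "centrum",
              "neural_spine", "neural_spine", "neural_spine",
              "transverse_process", "transverse_process", "transverse_process",
              "metapophysis", "metapophysis",
              "prezygapophysis", "prezygapophysis",
              "postzygapophysis", "postzygapophysis",
              "chevron")
  )
}

#' @export
print.measurement_schema <- function(x, ...) {
  cat(sprintf("Measurement schema: %d measurements (%d linear, %d angular)\n",
              nrow(x), sum(x$kind == "linear"), sum(x$kind == "angular")))
  print.data.frame(x)
  invisible(x)
}
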