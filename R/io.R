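#' Read per-vertebra measurement tables
#'
#' Long-format CSV, one row per vertebra, UTF-8, header required:
#' `species`, `specimen`, `position`, one column per schema measurement,
#' then `rib_bearing` (0/1), `rib_head` (`double`/`single`/`none`),
#' `chevron` (0/1), `fluke` (0/1), and optional `<measurement>_status`
#' columns with `measured`/`absent`/`broken` (default `measured`).
#'
#' @param path CSV file path (or connection).
#' @param schema a [measurement_schema()].
#' @return List of [specimen_column()], one per specimen, rows ordered by
#'   position and segments labelled.
#' @export
read_columns <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("species", "specimen", "position", schema$name,
            "rib_bearing", "rib_head", "chevron", "fluke")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  stat_cols <- paste0(schema$name, "_status")
  for (sc in stat_cols) {
    if (!sc %in% names(df)) df[[sc]] <- "measured"
    bad <- which(!df[[sc]] %in% c("measured", "absent", "broken"))
    if (length(bad) > 0)
      stop(sprintf("unknown status code '%s' in column %s (row %d)",
                   df[[sc]][bad[1]], sc, bad[1]))
  }
  out <- list()
  for (spec in unique(df$specimen)) {
    sub <- df[df$specimen == spec, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    dup <- duplicated(sub$position)
    if (any(dup))
      stop(sprintf("duplicate (specimen, position): (%s, %d)",
                   spec, sub$position[dup][1]))
    expected <- seq_len(nrow(sub))
    if (!identical(as.integer(sub$position), as.integer(expected))) {
      gap <- setdiff(expected, sub$position)[1]
      stop(sprintf("specimen %s: positions not consecutive from 1 (missing %d)",
                   spec, gap))
    }
    col <- specimen_column(
      species = sub$species[1], specimen = spec,
      measurements = sub[, schema$name, drop = FALSE],
      flags = data.frame(rib_bearing = sub$rib_bearing == 1,
                         rib_head = sub$rib_head,
                         chevron_bearing = sub$chevron == 1,
                         fluke = sub$fluke == 1),
      status = as.matrix(sub[, stat_cols, drop = FALSE]),
      schema = schema)
    out[[spec]] <- label_segments(col)
  }
  out
}

#' Write specimen columns in the long CSV dialect
#'
#' Emits the same dialect [read_columns()] accepts, so cleaned/scaled tables
#' round-trip.
#'
#' @param columns list of [specimen_column()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_columns <- function(columns, path) {
  rows <- lapply(columns, function(col) {
    df <- data.frame(species = col$species, specimen = col$specimen,
                     position = col$position, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(col$values))
    df$rib_bearing <- as.integer(col$flags$rib_bearing)
    df$rib_head <- col$flags$rib_head
    df$chevron <- as.integer(col$flags$chevron_bearing)
    df$fluke <- as.integer(col$flags$fluke)
    st <- as.data.frame(col$status)
    names(st) <- paste0(colnames(col$values), "_status")
    cbind(df, st)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
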