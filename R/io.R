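#' Read a tide-gauge style 6-minute water-level CSV
#'
#' Parses the verified-water-level CSV dialect used by US tide-gauge
#' exports: columns `Date Time` (`YYYY-MM-DD HH:MM`) and `Water Level`
#' (metres), with any further columns (sigma, quality flags) ignored.
#' Files written by [write_coops_water_level()] carry `#`-prefixed metadata
#' lines (`Station`, `Datum`, `Interval`, `Start`, `Samples`) that make the
#' reader an exact inverse of the writer; for third-party files the datum
#' (and optionally interval) must be supplied by the caller.
#'
#' Rows absent from the file become explicit missing markers on the regular
#' grid; rows are never silently dropped. Duplicate, non-monotone or
#' off-grid timestamps are parse errors naming the first offending row.
#'
#' @param path Path to the CSV file.
#' @param datum Vertical datum label; required unless the file metadata
#'   records one.
#' @param station Station label; optional, overrides file metadata.
#' @param interval Sampling interval in minutes; inferred from metadata or
#'   from the smallest timestamp difference when omitted.
#' @return A [water_level_series()].
#' @export
read_coops_water_level <- function(path, datum = NULL, station = NULL,
                                   interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_hash_metadata(path)
  df <- read_csv_exact(path)
  need <- c("Date Time", "Water Level")
  if (!all(need %in% names(df))) {
    stop("water-level CSV must have columns 'Date Time' and 'Water Level'")
  }
  df[["Water Level"]] <- exact_num(df[["Water Level"]])
  t <- as.POSIXct(df[["Date Time"]], tz = "UTC", format = "%Y-%m-%d %H:%M")
  if (any(is.na(t))) {
    stop("unparseable timestamp at data row ", which(is.na(t))[1])
  }
  if (anyDuplicated(t)) {
    i <- which(duplicated(t))[1]
    stop("duplicated timestamp at data row ", i, ": ",
         format(t[i], "%Y-%m-%d %H:%M"))
  }
  if (is.unsorted(t)) {
    i <- which(diff(as.numeric(t)) < 0)[1] + 1L
    stop("non-monotone timestamp at data row ", i, ": ",
         format(t[i], "%Y-%m-%d %H:%M"))
  }
  interval <- interval %||% as_num(meta[["Interval"]])
  if (is.null(interval)) {
    if (length(t) < 2) stop("cannot infer interval from a single row; supply it")
    interval <- min(diff(as.numeric(t))) / 60
  }
  start <- if (!is.null(meta[["Start"]])) as_wl_time(meta[["Start"]]) else t[1]
  step_s <- interval * 60
  off <- as.numeric(difftime(t, start, units = "secs")) / step_s
  bad <- which(abs(off - round(off)) > 1e-6 | off < 0)
  if (length(bad)) {
    stop("timestamp not aligned to the ", interval, "-minute grid at data row ",
         bad[1], ": ", format(t[bad[1]], "%Y-%m-%d %H:%M"))
  }
  n <- if (!is.null(meta[["Samples"]])) as.integer(as_num(meta[["Samples"]]))
       else as.integer(round(off[length(off)])) + 1L
  levels <- rep(NA_real_, n)
  levels[round(off) + 1L] <- df[["Water Level"]]
  datum <- datum %||% meta[["Datum"]] %||%
    stop("no datum in file metadata; supply one via the 'datum' argument")
  water_level_series(levels, start, interval, datum = datum,
                     station = station %||% meta[["Station"]] %||% "unknown")
}

#' Write a water-level series as a tide-gauge style CSV
#'
#' Missing samples are written as absent rows (the gauge-export convention);
#' `#`-prefixed metadata lines record station, datum, interval, grid start
#' and sample count so that [read_coops_water_level()] round-trips the
#' series bit-identically.
#'
#' @param series A [water_level_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coops_water_level <- function(series, path) {
  stopifnot(inherits(series, "water_level_series"))
  ok <- !is.na(series$levels)
  df <- tibble::tibble(
    `Date Time` = format(wl_timestamps(series)[ok], "%Y-%m-%d %H:%M", tz = "UTC"),
    `Water Level` = series$levels[ok],
    Sigma = 0,
    Quality = "v"
  )
  writeLines(c(
    paste0("# Station: ", series$station),
    paste0("# Datum: ", series$datum),
    paste0("# Interval: ", series$interval),
    paste0("# Start: ", format(series$start, "%Y-%m-%d %H:%M", tz = "UTC")),
    paste0("# Samples: ", length(series$levels))
  ), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# Read a CSV with every column as character, so numeric conversion can go
# through base R's correctly rounded strtod; the fast float parser used by
# the CSV reader can be one ulp off, which would break the exact
# reader/writer inverse guarantee.
read_csv_exact <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, col_types = readr::cols(.default = "c"),
                  na = character())
}

exact_num <- function(x) {
  x[!nzchar(x) | x == "NA"] <- NA_character_
  as.numeric(x)
}

exact_int <- function(x) {
  x[!nzchar(x) | x == "NA"] <- NA_character_
  as.integer(x)
}

read_hash_metadata <- function(path) {
  head_lines <- readLines(path, n = 50L)
  head_lines <- head_lines[startsWith(head_lines, "#")]
  out <- list()
  for (ln in head_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

as_num <- function(x) if (is.null(x)) NULL else as.numeric(x)

plot_table_cols <- c(
  plot_id = "plot_id", segment = "segment", transect = "transect",
  position_index = "position_index",
  distance_from_forest = "distance_from_forest_m",
  elevation = "elevation_m_navd88", zone = "zone", vegetation = "vegetation"
)

#' Read / write the plot table
#'
#' One row per permanent monitoring plot, with unit-suffixed column headers
#' (`distance_from_forest_m`, `elevation_m_navd88`). Units are fixed: metres
#' for distance and elevation (NAVD88); no unit inference is performed.
#' Validation rejects duplicate plot ids, unknown zone labels and
#' non-finite elevations, listing the offenders.
#'
#' @param path Path to the CSV file.
#' @return `read_plot_table()` returns a tibble with the same columns as
#'   [simulate_marsh()]; an empty data section with a valid header yields an
#'   empty tibble.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_csv_exact(path)
  miss <- setdiff(unname(plot_table_cols), names(df))
  if (length(miss)) stop("plot table missing column(s): ", paste(miss, collapse = ", "))
  names(df)[match(unname(plot_table_cols), names(df))] <- names(plot_table_cols)
  df$transect <- exact_int(df$transect)
  df$position_index <- exact_int(df$position_index)
  df$distance_from_forest <- exact_num(df$distance_from_forest)
  df$elevation <- exact_num(df$elevation)
  if (nrow(df) == 0) return(tibble::as_tibble(df))
  dup <- unique(df$plot_id[duplicated(df$plot_id)])
  if (length(dup)) stop("duplicate plot_id: ", paste(dup, collapse = ", "))
  bad_zone <- unique(df$zone[!df$zone %in% c("high", "mid", "low")])
  if (length(bad_zone)) stop("unknown zone label(s): ", paste(bad_zone, collapse = ", "))
  if (any(!is.finite(df$elevation))) {
    stop("non-finite elevation for plot(s): ",
         paste(df$plot_id[!is.finite(df$elevation)], collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_plot_table
#' @param plots Plot table (as from [simulate_marsh()]).
#' @export
write_plot_table <- function(plots, path) {
  stopifnot(is.data.frame(plots))
  out <- plots[, names(plot_table_cols)]
  names(out) <- unname(plot_table_cols)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

porewater_table_cols <- c(
  plot_id = "plot_id", year = "year", month = "month",
  replicate = "replicate", nh4 = "nh4_um", po4 = "po4_um",
  salinity = "salinity_psu"
)

#' Read / write the long-format porewater sample table
#'
#' One row per replicate measurement, with unit-suffixed concentration
#' headers (`nh4_um`, `po4_um`, `salinity_psu`). Validation rejects
#' duplicate (plot, year, month, replicate) keys, months outside the
#' growing season (May--August) and negative concentrations, listing the
#' offending rows; missing measurements are permitted as empty cells.
#'
#' @param path Path to the CSV file.
#' @return `read_porewater_table()` returns a tibble with the same columns
#'   as [simulate_porewater()].
#' @export
read_porewater_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_csv_exact(path)
  miss <- setdiff(unname(porewater_table_cols), names(df))
  if (length(miss)) stop("porewater table missing column(s): ", paste(miss, collapse = ", "))
  names(df)[match(unname(porewater_table_cols), names(df))] <- names(porewater_table_cols)
  for (v in c("year", "month", "replicate")) df[[v]] <- exact_int(df[[v]])
  for (v in c("nh4", "po4", "salinity")) df[[v]] <- exact_num(df[[v]])
  if (nrow(df) == 0) return(tibble::as_tibble(df))
  key <- paste(df$plot_id, df$year, df$month, df$replicate)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate sample key(s) (plot year month replicate): ",
         paste(dup, collapse = "; "))
  }
  if (any(!df$month %in% 5:8)) {
    stop("month outside the growing season (5-8) at row(s): ",
         paste(which(!df$month %in% 5:8), collapse = ", "))
  }
  for (v in c("nh4", "po4", "salinity")) {
    neg <- which(!is.na(df[[v]]) & df[[v]] < 0)
    if (length(neg)) {
      stop("negative ", v, " at row(s): ", paste(neg, collapse = ", "))
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_porewater_table
#' @param samples Porewater sample table (as from [simulate_porewater()]).
#' @export
write_porewater_table <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  out <- samples[, names(porewater_table_cols)]
  names(out) <- unname(porewater_table_cols)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
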