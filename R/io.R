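#' Column mappings for raw sensor CSVs
#'
#' The recording app's CSV dialects are not standardised, so every reader
#' takes a column map linking the fields the pipeline needs to the column
#' names in the file at hand. These helpers return the default maps; pass a
#' modified copy to the readers for other dialects.
#'
#' @param ... Named overrides, e.g. `gps_column_map(lat = "latitude")`.
#' @return A named list of column names.
#' @export
#' @examples
#' gps_column_map(timestamp = "time", lat = "latitude", lon = "longitude")
gps_column_map <- function(...) {
  utils::modifyList(
    list(timestamp = "timestamp", lat = "lat", lon = "lon",
         accuracy = "accuracy", device_status = "device_status"),
    list(...)
  )
}

#' @rdname gps_column_map
#' @export
accel_column_map <- function(...) {
  utils::modifyList(
    list(timestamp = "timestamp", ax = "acc_x", ay = "acc_y", az = "acc_z"),
    list(...)
  )
}

#' @rdname gps_column_map
#' @export
diary_column_map <- function(...) {
  utils::modifyList(
    list(begin = "begin", end = "end", lat = "lat", lon = "lon",
         address = "address"),
    list(...)
  )
}

read_mapped_csv <- function(source, column_map, mandatory) {
  if (is.character(source) && !file.exists(source)) {
    abort(paste0("input file does not exist: ", source), class = "mobitrace_io_error")
  }
  raw <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unlist(column_map[mandatory]), names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("mandatory column(s) not found: ", paste(missing, collapse = ", ")),
      class = "mobitrace_config_error"
    )
  }
  raw
}

#' Read timestamped GPS fixes from CSV
#'
#' Reads a CSV of raw GPS fixes, parses timestamps to UTC
#' ([parse_timestamps()]), validates coordinates (latitude in \[-90, 90\],
#' longitude in \[-180, 180\]) and returns the fixes sorted ascending in
#' time. Rows with unparseable timestamps or out-of-range coordinates are
#' dropped; the number of dropped rows is reported via a message and stored
#' in the `"skipped"` attribute of the result.
#'
#' @param source Path to a CSV file (or a connection `readr::read_csv()`
#'   accepts).
#' @param column_map Named list mapping the fields `timestamp`, `lat`, `lon`
#'   (mandatory) and `accuracy`, `device_status` (optional) to column names;
#'   see [gps_column_map()].
#' @return A tibble with columns `timestamp` (POSIXct, UTC), `lat`, `lon`
#'   (degrees, WGS84) and, when present in the file, `accuracy` (metres) and
#'   `device_status`.
#' @export
read_gps_records <- function(source, column_map = gps_column_map()) {
  raw <- read_mapped_csv(source, column_map, c("timestamp", "lat", "lon"))
  out <- tibble(
    timestamp = parse_timestamps(raw[[column_map$timestamp]]),
    lat = as.numeric(raw[[column_map$lat]]),
    lon = as.numeric(raw[[column_map$lon]])
  )
  if (!is.null(column_map$accuracy) && column_map$accuracy %in% names(raw)) {
    out$accuracy <- as.numeric(raw[[column_map$accuracy]])
  }
  if (!is.null(column_map$device_status) && column_map$device_status %in% names(raw)) {
    out$device_status <- as.character(raw[[column_map$device_status]])
  }
  ok <- !is.na(out$timestamp) & !is.na(out$lat) & !is.na(out$lon) &
    out$lat >= -90 & out$lat <= 90 & out$lon >= -180 & out$lon <= 180
  skipped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no valid GPS rows in input", class = "mobitrace_empty_input")
  }
  if (skipped > 0) {
    inform(paste0("read_gps_records: skipped ", skipped, " invalid row(s)"))
  }
  out <- arrange(out, .data$timestamp)
  attr(out, "skipped") <- skipped
  out
}

#' Read 3-axis accelerometer records from CSV
#'
#' Reads 1 Hz (or faster) accelerometer samples. Rows are sorted ascending
#' in time; duplicate timestamps are retained (de-duplication is a
#' preprocessing concern, not an ingest concern).
#'
#' @inheritParams read_gps_records
#' @param column_map Named list mapping `timestamp`, `ax`, `ay`, `az`
#'   (all mandatory) to column names; see [accel_column_map()].
#' @return A tibble with columns `timestamp` (POSIXct, UTC) and `ax`, `ay`,
#'   `az` (device acceleration units).
#' @export
read_accel_records <- function(source, column_map = accel_column_map()) {
  raw <- read_mapped_csv(source, column_map, c("timestamp", "ax", "ay", "az"))
  out <- tibble(
    timestamp = parse_timestamps(raw[[column_map$timestamp]]),
    ax = as.numeric(raw[[column_map$ax]]),
    ay = as.numeric(raw[[column_map$ay]]),
    az = as.numeric(raw[[column_map$az]])
  )
  ok <- !is.na(out$timestamp) & is.finite(out$ax) & is.finite(out$ay) & is.finite(out$az)
  skipped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no valid accelerometer rows in input", class = "mobitrace_empty_input")
  }
  if (skipped > 0) {
    inform(paste0("read_accel_records: skipped ", skipped, " invalid row(s)"))
  }
  out <- arrange(out, .data$timestamp)
  attr(out, "skipped") <- skipped
  out
}

#' Read a diary of ground-truth stops
#'
#' A mobility diary logs, for every stay, the begin and end instants, the
#' coordinates of the location and optionally a reverse-geocoded address.
#' Stops are validated (begin strictly before end, no temporal overlap
#' between stops) and returned sorted by begin time.
#'
#' @inheritParams read_gps_records
#' @param column_map See [diary_column_map()].
#' @return A tibble with columns `begin`, `end` (POSIXct, UTC), `lat`,
#'   `lon` and optionally `address`.
#' @export
read_diary <- function(source, column_map = diary_column_map()) {
  raw <- read_mapped_csv(source, column_map, c("begin", "end", "lat", "lon"))
  out <- tibble(
    begin = parse_timestamps(raw[[column_map$begin]]),
    end = parse_timestamps(raw[[column_map$end]]),
    lat = as.numeric(raw[[column_map$lat]]),
    lon = as.numeric(raw[[column_map$lon]])
  )
  if (!is.null(column_map$address) && column_map$address %in% names(raw)) {
    out$address <- as.character(raw[[column_map$address]])
  }
  validate_diary(out)
}

validate_diary <- function(diary) {
  bad <- which(!(diary$begin < diary$end))
  if (length(bad) > 0) {
    abort(
      paste0("diary stop must have begin < end; offending row(s): ",
             paste(bad, collapse = ", ")),
      class = "mobitrace_validation_error"
    )
  }
  diary <- arrange(diary, .data$begin)
  if (nrow(diary) > 1) {
    overlap <- which(ts_num(diary$begin[-1]) < ts_num(diary$end[-nrow(diary)]))
    if (length(overlap) > 0) {
      abort(
        paste0("diary stops overlap in time at sorted row(s): ",
               paste(overlap + 1, collapse = ", ")),
        class = "mobitrace_validation_error"
      )
    }
  }
  diary
}

#' Trim records to the study window
#'
#' Study phones are shipped by post and often record the shipping route;
#' analysis therefore starts by clipping all records to the participant's
#' actual study interval. The window is closed on both ends; bounds given at
#' day granularity (a `Date` or `"YYYY-MM-DD"` string) expand to the full
#' day (00:00:00 to 23:59:59 UTC).
#'
#' @param records A tibble with a `timestamp` column (GPS or accelerometer
#'   records), sorted ascending.
#' @param start,end Window bounds: POSIXct, `Date` or strings.
#' @return The input tibble restricted to `start <= timestamp <= end`;
#'   row order preserved. May be empty.
#' @export
trim_to_study_window <- function(records, start, end) {
  t0 <- window_bound(start, "start")
  t1 <- window_bound(end, "end")
  if (t0 > t1) abort("study window start is after its end",
                     class = "mobitrace_validation_error")
  records[records$timestamp >= t0 & records$timestamp <= t1, , drop = FALSE]
}

#' Export GPS fixes as a GPX 1.1 track
#'
#' Writes one `<trk>` with a single `<trkseg>`; coordinates are stored at
#' 7 decimal places and timestamps as ISO-8601 UTC. A reported accuracy, if
#' present, is carried in a `<extensions><accuracy>` element per trackpoint.
#'
#' @param gps A non-empty tibble of GPS fixes (see [read_gps_records()]).
#' @param dest Output file path.
#' @return `dest`, invisibly.
#' @export
export_gpx <- function(gps, dest) {
  if (is.null(gps) || nrow(gps) == 0) {
    abort("cannot export an empty track", class = "mobitrace_empty_input")
  }
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "mobitrace",
    xmlns = "http://www.topografix.com/GPX/1/1"
  )
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  has_acc <- "accuracy" %in% names(gps)
  for (i in seq_len(nrow(gps))) {
    pt <- xml2::xml_add_child(
      seg, "trkpt",
      lat = sprintf("%.7f", gps$lat[i]),
      lon = sprintf("%.7f", gps$lon[i])
    )
    xml2::xml_add_child(
      pt, "time",
      format(gps$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    )
    if (has_acc && !is.na(gps$accuracy[i])) {
      ext <- xml2::xml_add_child(pt, "extensions")
      xml2::xml_add_child(ext, "accuracy", sprintf("%.2f", gps$accuracy[i]))
    }
  }
  xml2::write_xml(doc, dest)
  invisible(dest)
}

#' Read a GPX 1.1 track back into a fix tibble
#'
#' Companion to [export_gpx()]; also accepts third-party GPX tracks.
#'
#' @param source Path to a GPX file.
#' @return A tibble with `timestamp`, `lat`, `lon` and `accuracy` (NA when
#'   the file carries none).
#' @export
read_gpx <- function(source) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) {
    abort("GPX file contains no trackpoints", class = "mobitrace_empty_input")
  }
  acc <- map_dbl(pts, function(p) {
    a <- xml2::xml_find_first(p, "./extensions/accuracy")
    if (inherits(a, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(a))
  })
  tibble(
    timestamp = parse_timestamps(xml2::xml_text(xml2::xml_find_all(pts, "./time"))),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    accuracy = acc
  )
}

#' Write the pipeline's result tables
#'
#' Writes `stops.csv` (one row per stop interval) and `daily_features.csv`
#' (one row per participant-day, one column per mobility variable) with a
#' fixed column order so re-runs are byte-identical.
#'
#' @param stops Stop-interval tibble (see [run_stop_go()]).
#' @param daily Daily feature tibble (see [daily_features()]).
#' @param dest Output directory (created if absent).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_results <- function(stops, daily, dest) {
  if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
  stop_cols <- c("stop_id", "start", "end", "duration_s", "centroid_lat",
                 "centroid_lon", "member_count", "location_id", "is_home")
  for (col in setdiff(stop_cols, names(stops))) stops[[col]] <- NA
  stops_path <- file.path(dest, "stops.csv")
  readr::write_csv(stops[, stop_cols], stops_path, progress = FALSE)
  daily_path <- file.path(dest, "daily_features.csv")
  readr::write_csv(daily, daily_path, progress = FALSE, na = "NA")
  invisible(c(stops = stops_path, daily_features = daily_path))
}
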