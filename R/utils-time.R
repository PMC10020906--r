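#' Parse heterogeneous timestamp columns to UTC
#'
#' Mobility CSVs in the wild carry timestamps as ISO-8601 strings, epoch
#' seconds or epoch milliseconds; recordings are shipped across time zones,
#' so everything is normalised to UTC on ingest. The format is auto-detected
#' per column: numeric values above 1e11 are treated as epoch milliseconds,
#' other numerics as epoch seconds, and character input is parsed as
#' ISO-8601 (date or date-time).
#'
#' @param x A character, numeric or POSIXct vector.
#' @return A POSIXct vector in UTC; elements that cannot be parsed are `NA`.
#' @export
#' @examples
#' parse_timestamps(c("2022-03-01T08:00:00Z", "2022-03-01 08:00:10"))
#' parse_timestamps(1646121600)
parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::with_tz(x, "UTC"))
  }
  if (is.numeric(x)) {
    secs <- ifelse(abs(x) > 1e11, x / 1000, x)
    return(lubridate::as_datetime(secs, tz = "UTC"))
  }
  x <- as.character(x)
  # numeric-looking strings are epochs
  num <- suppressWarnings(as.numeric(x))
  if (all(is.na(num) == is.na(x)) && any(!is.na(num))) {
    return(parse_timestamps(num))
  }
  out <- suppressWarnings(lubridate::parse_date_time(
    x,
    orders = c("Ymd HMS", "Ymd HMOS", "Ymd HM", "Ymd", "mdY HMS", "dmY HMS"),
    tz = "UTC", quiet = TRUE
  ))
  lubridate::as_datetime(out, tz = "UTC")
}

# numeric seconds since epoch (double), convenient for interval arithmetic
ts_num <- function(x) as.numeric(x)

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  parse_timestamps(x)
}

# expand a date-granularity bound to a closed day interval endpoint
window_bound <- function(x, side = c("start", "end")) {
  side <- match.arg(side)
  if (inherits(x, "Date")) {
    t0 <- lubridate::as_datetime(x, tz = "UTC")
    return(if (side == "start") t0 else t0 + (86400 - 1))
  }
  if (is.character(x) && grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    return(window_bound(as.Date(x), side))
  }
  as_utc(x)
}

secs_of_day <- function(t, tz = "UTC") {
  lt <- lubridate::with_tz(t, tz)
  3600 * lubridate::hour(lt) + 60 * lubridate::minute(lt) + lubridate::second(lt)
}
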