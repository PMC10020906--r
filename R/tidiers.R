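#' Tidy a stop/trip segmentation
#'
#' Returns one row per detected interval (stops and trips interleaved in
#' time), in broom's tidy-output style.
#'
#' @param x A `stop_go` object from [run_stop_go()].
#' @param ... Unused.
#' @return A tibble with `type`, `start`, `end`, `duration_s`, interval
#'   geometry (`centroid_lat`/`centroid_lon` for stops, `length_m` and
#'   `median_speed_kmh` for trips) and `segment`.
#' @export
tidy.stop_go <- function(x, ...) {
  stops <- mutate(x$stops, type = "stop", .before = 1)
  trips <- mutate(select(x$trips, -"path"), type = "trip", .before = 1)
  arrange(bind_rows(stops, trips), .data$start)
}

#' One-row summary of a stop/trip segmentation
#'
#' @param x A `stop_go` object.
#' @param ... Unused.
#' @return A one-row tibble: sample and interval counts, total stop and
#'   trip time, total trip distance and the fraction of samples labeled
#'   stop.
#' @export
glance.stop_go <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_stops = nrow(x$stops),
    n_trips = nrow(x$trips),
    stop_time_s = sum(x$stops$duration_s),
    trip_time_s = sum(x$trips$duration_s),
    trip_length_m = sum(x$trips$length_m),
    frac_stop_samples = mean(x$samples$label == "stop")
  )
}

#' Tidy a diary evaluation
#'
#' @param x A `stop_go_eval` object from [benchmark_report()].
#' @param ... Unused.
#' @return The long comparison tibble: one row per metric with
#'   `with_motion` and `without_motion` values.
#' @export
tidy.stop_go_eval <- function(x, ...) x$comparison

#' One-row summary of a diary evaluation (with-motion configuration)
#'
#' @param x A `stop_go_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline sample- and interval-level
#'   metrics of the with-motion run.
#' @export
glance.stop_go_eval <- function(x, ...) {
  bind_cols(x$with_motion$metrics, x$with_motion$intervals)
}

#' Plot a stop/trip segmentation
#'
#' Trajectory coloured by label, with detected stop centroids overlaid and
#' sized by dwell duration.
#'
#' @param object A `stop_go` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stop_go <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_path(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.6) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = NULL,
                  title = "Stop/trip segmentation")
  if (nrow(object$stops) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$stops,
      ggplot2::aes(x = .data$centroid_lon, y = .data$centroid_lat,
                   size = .data$duration_s / 60),
      shape = 21, fill = NA, colour = "black", stroke = 0.8
    ) +
      ggplot2::labs(size = "dwell (min)")
  }
  p
}

#' Plot daily mobility features over the study
#'
#' Small-multiple time series of selected daily variables.
#'
#' @param daily A [daily_features()] tibble.
#' @param vars Character vector of columns to plot (defaults to a
#'   representative set).
#' @return A ggplot object.
#' @export
plot_daily_features <- function(daily,
                                vars = c("time_out_of_home_s",
                                         "hull_area_m2",
                                         "n_unique_locations",
                                         "location_entropy")) {
  vars <- intersect(vars, names(daily))
  long <- tidyr::pivot_longer(daily[, c("date", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Daily mobility features")
}
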