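# shared fixture builders and independent oracles

UTC0 <- as.POSIXct("2022-03-01 08:00:00", tz = "UTC")

# lat/lon at planar offsets (metres) from a centre, via exact spherical
# geodesics consistent with the package's projection radius
ll_at <- function(x_m, y_m, center = c(48, 11)) {
  d <- sqrt(x_m^2 + y_m^2)
  brg <- atan2(x_m, y_m) * 180 / pi
  p <- geosphere::destPoint(cbind(center[2], center[1]), brg, d,
                            a = 6371008.8, f = 0)
  tibble::tibble(lat = p[, 2], lon = p[, 1])
}

# GPS fix tibble at planar offsets, sampled every `dt` seconds
make_gps <- function(x_m, y_m, t0 = UTC0, dt = 10) {
  ll <- ll_at(x_m, y_m)
  tibble::tibble(
    timestamp = t0 + dt * (seq_along(x_m) - 1),
    lat = ll$lat, lon = ll$lon
  )
}

# accelerometer tibble with given magnitude sequence along z
make_accel <- function(mag, t0 = UTC0, dt = 1) {
  tibble::tibble(
    timestamp = t0 + dt * (seq_along(mag) - 1),
    ax = 0, ay = 0, az = mag
  )
}

write_temp_csv <- function(df, name = "fixture.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}

# independent great-circle oracle: spherical law of cosines
slc_distance_m <- function(lat1, lon1, lat2, lon2, r = 6371008.8) {
  rad <- pi / 180
  r * acos(pmin(1, sin(lat1 * rad) * sin(lat2 * rad) +
                  cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)))
}

# brute-force minimum-area covering ellipse (Khachiyan's algorithm)
khachiyan_area <- function(P, tol = 1e-7, max_iter = 20000) {
  n <- nrow(P); d <- ncol(P)
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    nu <- (1 - step) * u
    nu[j] <- nu[j] + step
    if (max(abs(nu - u)) < tol) { u <- nu; break }
    u <- nu
  }
  ctr <- as.numeric(t(P) %*% u)
  A <- solve(t(P) %*% (u * P) - ctr %*% t(ctr)) / d
  pi / sqrt(det(A))
}

# conservation / partition checks for a stop_go fit, per recording segment
expect_tiling <- function(fit) {
  iv <- dplyr::arrange(
    dplyr::bind_rows(
      dplyr::select(fit$stops, "start", "end", "segment"),
      dplyr::select(fit$trips, "start", "end", "segment")
    ),
    .data$start
  )
  for (s in unique(iv$segment)) {
    sub <- iv[iv$segment == s, ]
    seg_samples <- fit$samples[fit$samples$segment == s, ]
    span <- as.numeric(max(seg_samples$timestamp)) -
      as.numeric(min(seg_samples$timestamp))
    expect_equal(sum(as.numeric(sub$end) - as.numeric(sub$start)), span,
                 tolerance = 1e-9)
    if (nrow(sub) > 1) {
      expect_equal(as.numeric(sub$start[-1]), as.numeric(sub$end[-nrow(sub)]),
                   tolerance = 1e-9) # abutting: no gap, no overlap
    }
  }
  invisible(iv)
}
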