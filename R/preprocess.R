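# Cleaning and regularization rules for artisanal-fleet GPS tracks, and the
# derivation of the HMM observation series (step lengths, turning angles).

#' Remove fixes near landing sites
#'
#' Drops every fix whose great-circle distance to the nearest landing site is
#' strictly less than `radius_km` (fishing is prohibited there and positions
#' close to port are transit). A fix exactly at the radius is retained; set
#' `inclusive = TRUE` for the `<=` reading.
#'
#' @param trip A trip.
#' @param sites data.frame of landing sites (`site_id`, `lat`, `lon`).
#' @param radius_km Buffer radius, km (default 3).
#' @param inclusive Treat the boundary as removed too (default `FALSE`).
#' @return The trimmed trip, or `NULL` (with a warning) if fewer than 2 fixes
#'   survive — the caller should drop such trips.
#' @export
trim_landing_buffer <- function(trip, sites, radius_km = 3,
                                inclusive = FALSE) {
  stopifnot(nrow(sites) >= 1)
  f <- trip$fixes
  dmin <- rep(Inf, nrow(f))
  for (s in seq_len(nrow(sites))) {
    d <- haversine_m(f$lat, f$lon, sites$lat[s], sites$lon[s]) / 1000
    dmin <- pmin(dmin, d)
  }
  keep <- if (inclusive) dmin > radius_km else dmin >= radius_km
  if (sum(keep) < 2L) {
    warning("trip '", trip$trip_id,
            "': fewer than 2 fixes outside the landing buffer; dropping")
    return(NULL)
  }
  replace_fixes(trip, f[keep, , drop = FALSE],
                fix_labels = trip$fix_labels[keep])
}

#' Remove implausibly fast fixes
#'
#' Forward sweep anchored on the first fix: a fix whose implied arrival speed
#' from the previous *retained* fix exceeds `vmax_kmh` is removed and the next
#' fix is re-evaluated against the last retained one. This keeps a single
#' position spike from poisoning two consecutive speeds.
#'
#' @param trip A trip with at least 2 fixes.
#' @param vmax_kmh Maximum plausible speed, km/h (default 50, the top speed of
#'   the 40 HP outboards typical of the fleet).
#' @return The filtered trip.
#' @export
speed_filter <- function(trip, vmax_kmh = 50) {
  f <- trip$fixes
  n <- nrow(f)
  tnum <- as.numeric(f$time)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    d_km <- haversine_m(f$lat[last], f$lon[last], f$lat[i], f$lon[i]) / 1000
    dt_h <- (tnum[i] - tnum[last]) / 3600
    if (d_km / dt_h <= vmax_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  if (sum(keep) < 2L) {
    warning("trip '", trip$trip_id, "': speed filter left < 2 fixes")
    return(NULL)
  }
  replace_fixes(trip, f[keep, , drop = FALSE],
                fix_labels = trip$fix_labels[keep])
}

#' Regularize a trip to a constant time interval
#'
#' Resamples the track onto the grid `t0, t0 + interval_s, ...` up to the last
#' original fix time. Each grid position is interpolated along the great
#' circle between the bracketing original fixes with along-segment fraction
#' equal to the elapsed-time fraction (constant speed within each original
#' segment) — "speed-based linear interpolation". Grid points falling inside a
#' recording gap longer than `max_gap_s` are emitted with missing coordinates
#' rather than interpolated, so dropouts do not fabricate straight transits.
#'
#' @param trip A trip (irregular allowed).
#' @param interval_s Target interval, seconds (the loggers' native rate is
#'   5 s).
#' @param max_gap_s Largest original gap to interpolate across; default
#'   `10 * interval_s`.
#' @return A regular trip (attribute `interval_s` set) possibly containing
#'   missing positions.
#' @export
regularize <- function(trip, interval_s, max_gap_s = 10 * interval_s) {
  stopifnot(interval_s > 0)
  f <- trip$fixes
  tnum <- as.numeric(f$time)
  grid <- seq(tnum[1], tnum[length(tnum)], by = interval_s)
  seg <- findInterval(grid, tnum, rightmost.closed = FALSE)
  seg <- pmin(seg, length(tnum) - 1L)  # last grid point may equal last time
  lat <- lon <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    i <- seg[g]
    t0 <- tnum[i]; t1 <- tnum[i + 1]
    if (grid[g] == t0) {           # exactly on an original fix
      lat[g] <- f$lat[i]; lon[g] <- f$lon[i]
    } else if (grid[g] == t1) {
      lat[g] <- f$lat[i + 1]; lon[g] <- f$lon[i + 1]
    } else if ((t1 - t0) <= max_gap_s) {
      fr <- (grid[g] - t0) / (t1 - t0)
      p <- slerp_point(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1], fr)
      lat[g] <- p$lat; lon[g] <- p$lon
    }                              # else: inside a long gap -> missing
  }
  new_trip(trip$trip_id, as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
           lat, lon, gear = trip$gear,
           landing_site_id = trip$landing_site_id,
           interval_s = interval_s, allow_missing = TRUE)
}

# Spacing of a regular trip, or an informative error.
regular_interval <- function(trip) {
  iv <- attr(trip, "interval_s")
  if (is.null(iv)) {
    d <- diff(as.numeric(trip$fixes$time))
    if (length(unique(d)) != 1L)
      stop("trip '", trip$trip_id,
           "' is not on a regular grid; run regularize() first")
    iv <- d[1]
  }
  iv
}

#' Decimate a regular trip
#'
#' Keeps every `factor`-th fix starting at the first, emulating a logger
#' programmed at a coarser sampling interval.
#'
#' @param trip A regular trip (from [regularize()] or the simulator).
#' @param factor Integer subsampling factor, >= 1.
#' @return A regular trip at `factor` times the input interval.
#' @export
decimate <- function(trip, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  iv <- regular_interval(trip)
  if (factor == 1) return(trip)
  idx <- seq(1L, n_fixes(trip), by = factor)
  if (length(idx) < 2L) {
    warning("trip '", trip$trip_id,
            "': decimation left < 2 fixes; dropping (empty-series signal)")
    return(NULL)
  }
  replace_fixes(trip, trip$fixes[idx, , drop = FALSE],
                fix_labels = trip$fix_labels[idx],
                interval_s = iv * factor, allow_missing = TRUE)
}

#' Derive step lengths and turning angles
#'
#' For a regular trip of M fixes: `step[i]` is the great-circle distance from
#' fix i to fix i+1 (meters, length M-1); `angle[i]` is the signed change of
#' bearing at interior fix i+1, wrapped to `(-pi, pi]` with left
#' (counterclockwise) turns positive (length M-2). Angles are missing where
#' either adjacent step has zero length (heading undefined — stationary jitter
#' must not masquerade as straight travel) or where a position is missing.
#'
#' @param trip A regular trip with at least 2 fixes (3 for angles).
#' @return A `"step_series"` object: list with `trip_id`, `gear`,
#'   `interval_s`, `times` (grid), `step`, `angle`.
#' @export
steps_and_angles <- function(trip) {
  iv <- regular_interval(trip)
  f <- trip$fixes
  m <- nrow(f)
  if (m < 2L) stop("trip '", trip$trip_id, "': need >= 2 fixes")
  step <- haversine_m(f$lat[-m], f$lon[-m], f$lat[-1], f$lon[-1])
  brg <- bearing_rad(f$lat[-m], f$lon[-m], f$lat[-1], f$lon[-1])
  angle <- if (m >= 3) {
    a <- wrap_angle(brg[-(m - 1)] - brg[-1])  # bearing_in - bearing_out
    a[is.na(brg[-(m - 1)]) | is.na(brg[-1])] <- NA_real_
    a
  } else numeric(0)
  structure(list(trip_id = trip$trip_id, gear = trip$gear, interval_s = iv,
                 times = f$time, step = step, angle = angle),
            class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("<step_series> %s  gear=%s  %d intervals at %g s (%d%% missing)\n",
              x$trip_id, x$gear, length(x$step), x$interval_s,
              round(100 * mean(is.na(x$step)))))
  invisible(x)
}

#' Speeds from a step series
#'
#' @param series A [steps_and_angles()] result.
#' @return Speeds in km/h, one per interval (`step / interval * 3.6`).
#' @export
speed_series <- function(series) {
  series$step / series$interval_s * 3.6
}
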