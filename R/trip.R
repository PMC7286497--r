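#' Construct a fishing trip
#'
#' A trip is an ordered sequence of timestamped WGS84 positions recorded by a
#' GPS logger over one fishing trip, plus gear and landing-site metadata. All
#' times are UTC. Fixes must be strictly increasing in time and at least two
#' are required. A regularized trip (see [regularize()]) may contain missing
#' positions (NA lat/lon) at grid times that fall inside recording gaps.
#'
#' @param trip_id Character scalar identifying the trip.
#' @param time `POSIXct` vector (converted to UTC) or something coercible.
#' @param lat,lon Numeric vectors, WGS84 decimal degrees.
#' @param gear Optional gear code, one of `"SCG"`, `"SG"`, `"MCG"`, `"PS"`,
#'   `"HL"`, `"LL"`, `"BG"` (sardine circling gillnet, surface drifting
#'   gillnet, mullet circling gillnet, purse seine, handline, longline,
#'   bottom gillnet), or `NA`.
#' @param landing_site_id Optional landing-site identifier.
#' @param fix_labels Optional character vector of per-fix reference states
#'   (`"fishing"` / `"non_fishing"`), aligned 1:1 with fixes.
#' @param interval_s Optional: if the fixes lie on a strictly regular grid,
#'   its spacing in seconds (set by [regularize()] and [decimate()]).
#' @param allow_missing Permit NA positions (regularized trips only).
#' @return An object of class `"fish_trip"`: a list with elements `trip_id`,
#'   `gear`, `landing_site_id`, `fixes` (data.frame `time`, `lat`, `lon`) and
#'   optionally `fix_labels`.
#' @export
new_trip <- function(trip_id, time, lat, lon, gear = NA_character_,
                     landing_site_id = NA_character_, fix_labels = NULL,
                     interval_s = NULL, allow_missing = FALSE) {
  if (inherits(time, "POSIXct")) {
    attr(time, "tzone") <- "UTC"
  } else {
    time <- as.POSIXct(time, tz = "UTC")
  }
  n <- length(time)
  if (n < 2L) stop("trip '", trip_id, "': a trip needs at least 2 fixes")
  if (length(lat) != n || length(lon) != n)
    stop("trip '", trip_id, "': time, lat, lon lengths differ")
  if (anyNA(time)) stop("trip '", trip_id, "': non-finite timestamps")
  if (any(diff(as.numeric(time)) <= 0))
    stop("trip '", trip_id, "': fixes must be strictly increasing in time")
  ok <- !(is.na(lat) | is.na(lon))
  if (!allow_missing && !all(ok))
    stop("trip '", trip_id, "': missing coordinates")
  if (any(abs(lat[ok]) > 90))
    stop("trip '", trip_id, "': latitude out of range [-90, 90]")
  if (any(abs(lon[ok]) > 180))
    stop("trip '", trip_id, "': longitude out of range [-180, 180]")
  if (!is.na(gear) && !gear %in% GEAR_CODES)
    stop("trip '", trip_id, "': unknown gear '", gear, "' (expected one of ",
         paste(GEAR_CODES, collapse = ", "), ")")
  if (!is.null(fix_labels) && length(fix_labels) != n)
    stop("trip '", trip_id, "': fix_labels must align 1:1 with fixes")
  out <- structure(
    list(trip_id = as.character(trip_id), gear = gear,
         landing_site_id = landing_site_id,
         fixes = data.frame(time = time, lat = as.numeric(lat),
                            lon = as.numeric(lon))),
    class = "fish_trip")
  if (!is.null(fix_labels)) out$fix_labels <- as.character(fix_labels)
  if (!is.null(interval_s)) attr(out, "interval_s") <- interval_s
  out
}

#' @export
print.fish_trip <- function(x, ...) {
  f <- x$fixes
  cat(sprintf("<fish_trip> %s  gear=%s  %d fixes  %s .. %s\n",
              x$trip_id, x$gear, nrow(f),
              format(f$time[1], "%Y-%m-%d %H:%M:%S"),
              format(f$time[nrow(f)], "%H:%M:%S")))
  if (!is.null(attr(x, "interval_s")))
    cat(sprintf("  regular at %g s\n", attr(x, "interval_s")))
  invisible(x)
}

n_fixes <- function(trip) nrow(trip$fixes)

# Rebuild a trip from a subset/replacement of its fixes, keeping metadata.
replace_fixes <- function(trip, fixes, fix_labels = NULL, interval_s = NULL,
                          allow_missing = FALSE) {
  new_trip(trip$trip_id, fixes$time, fixes$lat, fixes$lon, gear = trip$gear,
           landing_site_id = trip$landing_site_id, fix_labels = fix_labels,
           interval_s = interval_s, allow_missing = allow_missing)
}

#' Construct a landing site
#'
#' @param site_id Character identifier.
#' @param lat,lon WGS84 decimal degrees.
#' @return A one-row data.frame with columns `site_id`, `lat`, `lon`.
#' @export
landing_site <- function(site_id, lat, lon) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180, is.finite(lat), is.finite(lon))
  data.frame(site_id = as.character(site_id), lat = lat, lon = lon)
}

#' Per-trip summary statistics
#'
#' Duration (hours, last minus first fix time) and total distance (km, sum of
#' great-circle step lengths between consecutive fixes; pairs with a missing
#' position contribute nothing).
#'
#' @param trip A [new_trip()] object.
#' @return A one-row data.frame: `trip_id`, `gear`, `duration_h`,
#'   `total_distance_km`, `n_fixes`.
#' @export
trip_summary <- function(trip) {
  f <- trip$fixes
  m <- nrow(f)
  dur <- as.numeric(difftime(f$time[m], f$time[1], units = "hours"))
  d <- haversine_m(f$lat[-m], f$lon[-m], f$lat[-1], f$lon[-1])
  data.frame(trip_id = trip$trip_id, gear = trip$gear,
             duration_h = dur,
             total_distance_km = sum(d, na.rm = TRUE) / 1000,
             n_fixes = m)
}
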