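# Track ingestion: GPX 1.1 from consumer GPS loggers, and a plain CSV
# interchange schema (trip_id, time, lat, lon [, gear, state]).

parse_utc_time <- function(x) {
  # ISO-8601, with or without 'T'/'Z'; naive timestamps are assumed UTC.
  # Unparseable elements come back NA (callers report the offending row).
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y/%m/%d %H:%M:%OS")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read trips from a GPX 1.1 file
#'
#' One trip per `<trk>`; multiple `<trkseg>` within a track are concatenated
#' (segments mark receiver power cycles, not trip boundaries). Track points
#' must carry `<time>`; fixes are sorted by time and exact duplicate
#' timestamps are collapsed to the first occurrence. Naive timestamps are
#' taken as UTC.
#'
#' @param path Path to a GPX file.
#' @param gear Optional gear code applied to all tracks in the file.
#' @return A list of [new_trip()] objects. Tracks with no points are skipped
#'   with a warning; a track point lacking a timestamp aborts with a message
#'   naming the point.
#' @export
read_gpx <- function(path, gear = NA_character_) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in ", path)
  stem <- sub("\\.[^.]*$", "", basename(path))
  trips <- list()
  for (k in seq_along(trks)) {
    trk <- trks[[k]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    trip_id <- if (!is.na(nm) && nzchar(nm)) nm else sprintf("%s_trk%d", stem, k)
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) == 0) {
      warning("track '", trip_id, "' has no points; skipped")
      next
    }
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    bad <- which(is.na(tstr) | !nzchar(tstr))
    if (length(bad) > 0)
      stop("track '", trip_id, "': point ", bad[1], " (lat=", lat[bad[1]],
           ", lon=", lon[bad[1]], ") has no <time>")
    tm <- parse_utc_time(tstr)
    if (anyNA(tm))
      stop("track '", trip_id, "': unparseable <time> at point ",
           which(is.na(tm))[1])
    o <- order(tm)
    tm <- tm[o]; lat <- lat[o]; lon <- lon[o]
    keep <- !duplicated(as.numeric(tm))
    trips[[length(trips) + 1L]] <-
      new_trip(trip_id, tm[keep], lat[keep], lon[keep], gear = gear)
  }
  trips
}

#' Read trips from a CSV file
#'
#' Expected columns (renameable through `column_map`): `trip_id`, `time`
#' (ISO-8601, UTC assumed), `lat`, `lon`, and optionally `gear` and `state`
#' (per-fix reference labels, `"fishing"`/`"non_fishing"`). Rows are grouped
#' by `trip_id`; within a trip, fixes are sorted by time and duplicate
#' timestamps collapsed to the first.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping the canonical names to the
#'   file's column names, e.g. `c(time = "timestamp")`.
#' @return List of trips (possibly empty, with a warning, for an empty file).
#' @export
read_track_csv <- function(path, column_map = character()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no rows in ", path)
    return(list())
  }
  cols <- c(trip_id = "trip_id", time = "time", lat = "lat", lon = "lon",
            gear = "gear", state = "state")
  cols[names(column_map)] <- column_map
  for (need in c("trip_id", "time", "lat", "lon"))
    if (!cols[[need]] %in% names(df))
      stop("column '", cols[[need]], "' (", need, ") not found in ", path)
  tm <- parse_utc_time(df[[cols["time"]]])
  if (anyNA(tm))
    stop("unparseable timestamp at row ", which(is.na(tm))[1], " of ", path)
  lat <- suppressWarnings(as.numeric(df[[cols["lat"]]]))
  lon <- suppressWarnings(as.numeric(df[[cols["lon"]]]))
  if (anyNA(lat) || anyNA(lon))
    stop("unparseable coordinate at row ",
         which(is.na(lat) | is.na(lon))[1], " of ", path)
  if (any(abs(lat) > 90))
    stop("latitude out of range at row ", which(abs(lat) > 90)[1], " of ", path)
  if (any(abs(lon) > 180))
    stop("longitude out of range at row ", which(abs(lon) > 180)[1], " of ", path)
  gear <- if (cols["gear"] %in% names(df)) df[[cols["gear"]]] else NA_character_
  state <- if (cols["state"] %in% names(df)) df[[cols["state"]]] else NULL
  ids <- as.character(df[[cols["trip_id"]]])
  lapply(unique(ids), function(id) {
    i <- which(ids == id)
    i <- i[order(tm[i])]
    i <- i[!duplicated(as.numeric(tm[i]))]
    g <- if (all(is.na(gear))) NA_character_ else gear[i][1]
    new_trip(id, tm[i], lat[i], lon[i], gear = g,
             fix_labels = if (!is.null(state)) state[i])
  })
}

#' Write trips to CSV
#'
#' Writes the canonical schema `trip_id, time, lat, lon, gear[, state]` with
#' 1-second time resolution and 1e-6-degree coordinate precision, so that
#' `read_track_csv()` round-trips losslessly at that precision.
#'
#' @param trips List of trips.
#' @param path Output file.
#' @param labels Optional list of per-fix label vectors aligned 1:1 with each
#'   trip's fixes (defaults to each trip's own `fix_labels` if present).
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(trips, path, labels = NULL) {
  if (inherits(trips, "fish_trip")) trips <- list(trips)
  if (!is.null(labels) && length(labels) != length(trips))
    stop("labels must be one vector per trip")
  rows <- lapply(seq_along(trips), function(k) {
    tr <- trips[[k]]
    lab <- if (!is.null(labels)) labels[[k]] else tr$fix_labels
    if (!is.null(lab) && length(lab) != n_fixes(tr))
      stop("trip '", tr$trip_id, "': labels not aligned with fixes (",
           length(lab), " vs ", n_fixes(tr), ")")
    out <- data.frame(trip_id = tr$trip_id,
                      time = format(tr$fixes$time, "%Y-%m-%dT%H:%M:%SZ"),
                      lat = sprintf("%.6f", tr$fixes$lat),
                      lon = sprintf("%.6f", tr$fixes$lon),
                      gear = tr$gear)
    if (!is.null(lab)) out$state <- lab
    out
  })
  has_state <- vapply(rows, function(r) "state" %in% names(r), logical(1))
  if (any(has_state))
    rows <- lapply(rows, function(r) {
      if (!"state" %in% names(r)) r$state <- NA_character_
      r
    })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landing sites from CSV
#'
#' @param path CSV with columns `site_id`, `lat`, `lon`.
#' @return data.frame of landing sites.
#' @export
read_landing_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (need in c("site_id", "lat", "lon"))
    if (!need %in% names(df)) stop("column '", need, "' not found in ", path)
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("landing site coordinate out of range in ", path)
  df[c("site_id", "lat", "lon")]
}
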