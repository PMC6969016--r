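# Readers and writers for every external format the pipeline touches.
# Readers validate and reject rather than silently repair; all formats
# round-trip losslessly.

STANDARD_GRAVITY <- 9.80665          # m/s^2 per g
EARTH_RADIUS_M <- 6371008.8          # mean Earth radius
M_PER_DEG <- pi / 180 * EARTH_RADIUS_M

find_col <- function(df, candidates, what, path) {
  hit <- which(tolower(names(df)) %in% candidates)
  if (!length(hit)) {
    stop(sprintf("%s: missing column for %s (accepted names: %s)",
                 path, what, paste(candidates, collapse = ", ")))
  }
  hit[1]
}

#' Read an accelerometer CSV
#'
#' Expects a header with a time column (`epoch_s`, `t`, `time` or
#' `timestamp`) and three axis columns (`x`/`x_g`, `y`/`y_g`, `z`/`z_g`).
#' Values in m/s^2 are normalised to g when `units = "ms2"`. Gaps longer than
#' two nominal sample intervals are recorded in a gap log attached as
#' attribute `gaps` (columns `after_sample`, `t_before`, `t_after`,
#' `n_missing`).
#'
#' @param path CSV file path.
#' @param rate_hz nominal sample rate.
#' @param units `"g"` (default) or `"ms2"`.
#' @return An [accel_trace()] with a `gaps` attribute.
#' @export
read_accel_csv <- function(path, rate_hz = 50, units = c("g", "ms2")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  it <- find_col(df, c("epoch_s", "t", "time", "timestamp"), "time", path)
  ix <- find_col(df, c("x", "x_g"), "x axis", path)
  iy <- find_col(df, c("y", "y_g"), "y axis", path)
  iz <- find_col(df, c("z", "z_g"), "z axis", path)
  t <- as.numeric(df[[it]])
  x <- as.numeric(df[[ix]]); y <- as.numeric(df[[iy]]); z <- as.numeric(df[[iz]])
  for (v in list(t = t, x = x, y = y, z = z)) {
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s: non-finite value at line %d", path, bad[1] + 1L))
    }
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop(sprintf("%s: time not strictly increasing at line %d",
                 path, which(diff(t) <= 0)[1] + 2L))
  }
  if (units == "ms2") {
    x <- x / STANDARD_GRAVITY; y <- y / STANDARD_GRAVITY; z <- z / STANDARD_GRAVITY
  }
  gaps <- data.frame(after_sample = integer(0), t_before = numeric(0),
                     t_after = numeric(0), n_missing = integer(0))
  if (length(t) > 1) {
    dt <- diff(t)
    gi <- which(dt > 2 / rate_hz)
    if (length(gi)) {
      gaps <- data.frame(after_sample = gi, t_before = t[gi], t_after = t[gi + 1],
                         n_missing = as.integer(round(dt[gi] * rate_hz) - 1L))
    }
  }
  # a gappy file can shift the median interval; validate on the gap-free part
  tr <- accel_trace_allow_gaps(t, x, y, z, rate_hz, gaps)
  attr(tr, "gaps") <- gaps
  tr
}

accel_trace_allow_gaps <- function(t, x, y, z, rate_hz, gaps) {
  if (nrow(gaps) == 0) return(accel_trace(t, x, y, z, rate_hz))
  tr <- structure(list(t = t, x = x, y = y, z = z, rate_hz = rate_hz),
                  class = "accel_trace")
  if (any(diff(t) <= 0)) stop("timestamps not strictly increasing")
  tr
}

#' Write an accelerometer trace to CSV
#'
#' Columns `epoch_s, x_g, y_g, z_g`; full double precision so that
#' write-then-read is the identity.
#'
#' @param trace an [accel_trace()].
#' @param path output path.
#' @export
write_accel_csv <- function(trace, path) {
  df <- data.frame(epoch_s = fmt_num(trace$t), x_g = fmt_num(trace$x),
                   y_g = fmt_num(trace$y), z_g = fmt_num(trace$z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(v) formatC(v, format = "g", digits = 17)

#' Read a behaviour annotation CSV
#'
#' Interval annotations `start_s, end_s, class` (half-open seconds), in the
#' spirit of ELAN interval exports. Overlapping intervals are an error naming
#' the offending pairs.
#'
#' @param path CSV file path.
#' @param collapse fold fine "other" labels (walk, run, ...) into `"other"`.
#' @return A [label_track()].
#' @export
read_labels <- function(path, collapse = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_ <- find_col(df, c("start_s", "start"), "interval start", path)
  ie <- find_col(df, c("end_s", "end"), "interval end", path)
  ic <- find_col(df, c("class", "label", "behaviour", "behavior"), "class", path)
  cl <- as.character(df[[ic]])
  if (collapse) cl <- collapse_other(cl)
  label_track(as.numeric(df[[is_]]), as.numeric(df[[ie]]), cl)
}

#' @rdname read_labels
#' @param labels a [label_track()].
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(start_s = fmt_num(labels$start_s),
                   end_s = fmt_num(labels$end_s), class = labels$class)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_time <- function(v, path) {
  if (is.numeric(v)) return(as.numeric(v))
  suppressWarnings(num <- as.numeric(v))
  if (!any(is.na(num))) return(num)
  tt <- as.POSIXct(v, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  bad <- which(is.na(tt))
  if (length(bad)) {
    stop(sprintf("%s: unparseable timestamp '%s' at record %d",
                 path, v[bad[1]], bad[1]))
  }
  as.numeric(tt)
}

#' Read a GPS track (CSV or GPX)
#'
#' Format is chosen by extension: `.gpx` files are parsed as GPX 1.1 track
#' points, anything else as CSV with columns `time`/`t`/`epoch_s`, `lat`,
#' `lon`. ISO-8601 timestamps are converted to UTC epoch seconds.
#'
#' @param path file path.
#' @return A [gps_track()].
#' @export
read_gps <- function(path) {
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) return(read_gpx(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  it <- find_col(df, c("time", "t", "epoch_s", "timestamp"), "time", path)
  ila <- find_col(df, c("lat", "latitude"), "latitude", path)
  ilo <- find_col(df, c("lon", "longitude", "lng"), "longitude", path)
  gps_track(parse_time(df[[it]], path),
            as.numeric(df[[ilo]]), as.numeric(df[[ila]]))
}

read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (!length(pts)) stop(path, ": no <trkpt> elements found")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  gps_track(parse_time(tstr, path), lon, lat)
}

#' Write a GPS track as GPX 1.1
#'
#' @param track a [gps_track()].
#' @param path output path.
#' @export
write_gpx <- function(track, path) {
  tstr <- strftime(as.POSIXct(track$t, origin = "1970-01-01", tz = "UTC"),
                   "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pts <- sprintf('      <trkpt lat="%s" lon="%s"><time>%s</time></trkpt>',
                 fmt_num(track$lat), fmt_num(track$lon), tstr)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gpx version="1.1" creator="scentmark" xmlns="http://www.topografix.com/GPX/1/1">',
             '  <trk>', '    <trkseg>', pts, '    </trkseg>', '  </trk>', '</gpx>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a GPS track as CSV (epoch seconds)
#' @rdname write_gpx
#' @export
write_gps_csv <- function(track, path) {
  df <- data.frame(time = fmt_num(track$t), lat = fmt_num(track$lat),
                   lon = fmt_num(track$lon))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project a GPS track into a local planar frame
#'
#' Equirectangular projection about the track centroid: adequate at pasture
#' scale (inverse error < 0.1 m for tracks spanning < 20 km) and
#' dependency-free. Adds columns `x_m`, `y_m` and attributes `ref_lon`,
#' `ref_lat`, `projection = "equirectangular"`.
#'
#' @param track a [gps_track()] with at least one fix.
#' @return The projected track.
#' @export
project_track <- function(track) {
  if (nrow(track) == 0) stop("cannot project an empty track")
  ref_lon <- mean(track$lon)
  ref_lat <- mean(track$lat)
  xy <- lonlat_to_local(track$lon, track$lat, ref_lon, ref_lat)
  track$x_m <- xy$x
  track$y_m <- xy$y
  attr(track, "ref_lon") <- ref_lon
  attr(track, "ref_lat") <- ref_lat
  attr(track, "projection") <- "equirectangular"
  track
}

#' @rdname project_track
#' @param lon,lat WGS84 degrees.
#' @param ref_lon,ref_lat projection reference point, degrees.
#' @export
lonlat_to_local <- function(lon, lat, ref_lon, ref_lat) {
  list(x = (lon - ref_lon) * M_PER_DEG * cos(ref_lat * pi / 180),
       y = (lat - ref_lat) * M_PER_DEG)
}

#' @rdname project_track
#' @param x,y planar metres in the local frame.
#' @export
local_to_lonlat <- function(x, y, ref_lon, ref_lat) {
  list(lon = ref_lon + x / (M_PER_DEG * cos(ref_lat * pi / 180)),
       lat = ref_lat + y / M_PER_DEG)
}

#' Write scent-mark events as GeoJSON points
#'
#' Unlocated events (no GPS fix within tolerance) are written with a `null`
#' geometry and `located = false`.
#'
#' @param events a scent-mark event data.frame (see [extract_events()],
#'   [georeference()]).
#' @param path output path.
#' @export
write_events_geojson <- function(events, path) {
  feats <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    geom <- if (isTRUE(e$located)) {
      list(type = "Point", coordinates = c(e$lon, e$lat))
    } else NULL
    list(type = "Feature", geometry = geom,
         properties = list(class = e$class, start_s = e$start_s,
                           end_s = e$end_s,
                           located = isTRUE(e$located)))
  })
  doc <- list(type = "FeatureCollection",
              metadata = list(projection = "equirectangular",
                              crs = "WGS84"),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a per-sample or per-bin prediction series to CSV
#'
#' @param series data.frame with a time column and a `class` column.
#' @param path output path.
#' @export
write_predictions_csv <- function(series, path) {
  out <- series
  for (nm in names(out)) if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a convex polygon as a GeoJSON Polygon
#'
#' @param poly an `mcp_result` or a 2-column matrix of planar vertices.
#' @param ref_lon,ref_lat local-frame reference for converting metres back to
#'   WGS84.
#' @param path output path.
#' @param properties named list of extra properties.
#' @export
write_polygon_geojson <- function(poly, ref_lon, ref_lat, path,
                                  properties = list()) {
  ring <- if (inherits(poly, "mcp_result")) poly$polygon else poly
  ll <- local_to_lonlat(ring[, 1], ring[, 2], ref_lon, ref_lat)
  coords <- cbind(ll$lon, ll$lat)
  coords <- rbind(coords, coords[1, ])   # closed ring
  feat <- list(type = "Feature",
               geometry = list(type = "Polygon",
                               coordinates = list(unname(split_rows(coords)))),
               properties = properties)
  doc <- list(type = "FeatureCollection", features = list(feat))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
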