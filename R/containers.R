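# Core data containers: accel_trace, label_track, gps_track.
# All times are UTC epoch seconds internally; label intervals are half-open
# [start, end).

#' Tri-axial acceleration trace
#'
#' A uniformly sampled tri-axial accelerometer record in units of g with epoch
#' timestamps. Axis convention: x = surge (anterior-posterior), y = sway
#' (lateral), z = heave (dorso-ventral); at rest in the baseline standing
#' orientation a pelvis-mounted device reads approximately (0, 0, -1) g.
#'
#' @param t numeric vector of epoch seconds, strictly increasing.
#' @param x,y,z numeric vectors of acceleration in g, finite.
#' @param rate_hz nominal sample rate (samples per second).
#' @return An object of class `accel_trace`: a list with elements `t`, `x`,
#'   `y`, `z`, `rate_hz`.
#' @export
accel_trace <- function(t, x, y, z, rate_hz = 50) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(z) == n, rate_hz > 0)
  if (n == 0) stop("accel_trace must contain at least one sample")
  if (!all(is.finite(t))) stop("non-finite timestamps in accel trace")
  for (ax in list(x = x, y = y, z = z)) {
    if (!all(is.finite(ax))) stop("non-finite acceleration values in accel trace")
  }
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop("timestamps not strictly increasing at sample ",
           which(dt <= 0)[1] + 1L)
    }
    med <- stats::median(dt)
    if (abs(med - 1 / rate_hz) > 0.1 / rate_hz) {
      stop(sprintf(
        "median sample interval %.6f s inconsistent with rate_hz = %g", med, rate_hz))
    }
  }
  structure(list(t = t, x = x, y = y, z = z, rate_hz = rate_hz),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz, %.1f s span\n",
              length(x$t), x$rate_hz, diff(range(x$t))))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$t)

#' Behaviour label track
#'
#' Time intervals tagged with behaviour classes, half-open `[start, end)`,
#' sorted and non-overlapping. Used both for ground-truth annotation (in the
#' spirit of ELAN interval exports) and for predictions.
#'
#' @param start_s,end_s numeric interval bounds in epoch seconds.
#' @param class character behaviour labels (fine "other" labels allowed).
#' @return A `label_track`: a data.frame with columns `start_s`, `end_s`,
#'   `class`, sorted by `start_s`.
#' @export
label_track <- function(start_s, end_s, class) {
  n <- length(start_s)
  stopifnot(length(end_s) == n, length(class) == n)
  if (n == 0) {
    df <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     class = character(0), stringsAsFactors = FALSE)
    class(df) <- c("label_track", "data.frame")
    return(df)
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("non-finite label interval bounds")
  }
  bad <- which(start_s >= end_s)
  if (length(bad)) {
    stop("label interval(s) with start >= end at row(s): ",
         paste(bad, collapse = ", "))
  }
  ord <- order(start_s, end_s)
  df <- data.frame(start_s = start_s[ord], end_s = end_s[ord],
                   class = as.character(class)[ord], stringsAsFactors = FALSE)
  # half-open intervals: end == next start is fine
  ov <- which(df$end_s[-n] > df$start_s[-1] + 1e-9)
  if (length(ov)) {
    pairs <- vapply(ov, function(i) {
      sprintf("[%g, %g) '%s' overlaps [%g, %g) '%s'",
              df$start_s[i], df$end_s[i], df$class[i],
              df$start_s[i + 1], df$end_s[i + 1], df$class[i + 1])
    }, character(1))
    stop("overlapping label intervals:\n  ", paste(pairs, collapse = "\n  "))
  }
  class(df) <- c("label_track", "data.frame")
  df
}

#' Look up the behaviour class at given times
#'
#' @param labels a [label_track()].
#' @param t numeric vector of epoch seconds.
#' @param default class returned for times not covered by any interval.
#' @return Character vector of classes, one per element of `t`.
#' @export
labels_at <- function(labels, t, default = NA_character_) {
  if (nrow(labels) == 0) return(rep(default, length(t)))
  idx <- findInterval(t, labels$start_s)
  out <- rep(default, length(t))
  hit <- idx >= 1
  hit[hit] <- t[hit] < labels$end_s[idx[hit]]
  out[hit] <- labels$class[idx[hit]]
  out
}

#' GPS track
#'
#' A sequence of GPS fixes (epoch seconds, WGS84 lon/lat). Planar metre
#' coordinates `x_m`, `y_m` are added by [project_track()].
#'
#' @param t numeric epoch seconds, strictly increasing.
#' @param lon,lat WGS84 degrees.
#' @return A `gps_track`: a data.frame with columns `t`, `lon`, `lat` (and
#'   after projection `x_m`, `y_m` plus reference attributes `ref_lon`,
#'   `ref_lat`).
#' @export
gps_track <- function(t, lon, lat) {
  n <- length(t)
  stopifnot(length(lon) == n, length(lat) == n)
  if (n > 0) {
    if (any(!is.finite(t)) || any(!is.finite(lon)) || any(!is.finite(lat))) {
      stop("non-finite GPS fix fields")
    }
    if (n > 1 && any(diff(t) <= 0)) {
      stop("GPS timestamps not strictly increasing at fix ",
           which(diff(t) <= 0)[1] + 1L)
    }
    if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
    if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  }
  df <- data.frame(t = t, lon = lon, lat = lat)
  class(df) <- c("gps_track", "data.frame")
  df
}

#' @export
print.gps_track <- function(x, ...) {
  cat(sprintf("<gps_track> %d fixes%s\n", nrow(x),
              if (!is.null(x$x_m)) ", projected" else ""))
  if (nrow(x)) cat(sprintf("  span %.1f s\n", diff(range(x$t))))
  invisible(x)
}
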