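# From 50 Hz per-sample predictions to a 1 Hz behaviour series, discrete
# scent-mark events, and GPS-georeferenced marks.

#' Modal smoothing to 1 s bins
#'
#' Segments per-sample predictions into contiguous 1 s bins and takes the
#' modal class per bin, reducing data volume and matching the GPS fix
#' cadence. Tie-break: scent classes outrank "other" (biasing toward
#' detection of the rare classes of interest); among tied scent classes the
#' one with the longest consecutive sample run in the bin wins, then
#' lexicographic order. A partial trailing bin is kept if at least half full.
#'
#' @param pred character vector of per-sample predicted classes.
#' @param t numeric sample times (epoch seconds), same length as `pred`.
#' @param t0 bin origin; defaults to `floor(min(t))`.
#' @return A `smoothed_series`: data.frame with columns `bin_start_s`,
#'   `class`.
#' @export
smooth_modal <- function(pred, t, t0 = NULL) {
  if (length(pred) == 0) stop("empty prediction vector")
  if (length(pred) != length(t)) stop("pred and t must have equal length")
  if (is.null(t0)) t0 <- floor(min(t))
  bin <- floor(t - t0)                      # 1 s bins [t0+i, t0+i+1)
  bins <- sort(unique(bin))
  counts <- table(bin)
  full <- stats::median(counts)
  out_start <- numeric(0)
  out_class <- character(0)
  for (b in bins) {
    sel <- which(bin == b)
    if (b == bins[length(bins)] && length(sel) < full / 2 && length(bins) > 1) {
      next                                  # drop a <half-full trailing bin
    }
    out_start <- c(out_start, t0 + b)
    out_class <- c(out_class, modal_class(pred[sel]))
  }
  df <- data.frame(bin_start_s = out_start, class = out_class,
                   stringsAsFactors = FALSE)
  class(df) <- c("smoothed_series", "data.frame")
  df
}

modal_class <- function(cl) {
  tab <- table(cl)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  scent <- top[is_scent_class(top)]
  if (length(scent) == 1) return(scent)
  if (length(scent) == 0) return(sort(top)[1])
  # several scent classes tied: longest consecutive run, then lexicographic
  runs <- rle(cl)
  best_run <- vapply(scent, function(s) {
    r <- runs$lengths[runs$values == s]
    if (length(r)) max(r) else 0L
  }, numeric(1))
  scent <- scent[best_run == max(best_run)]
  sort(scent)[1]
}

#' Extract discrete scent-mark events from a smoothed series
#'
#' Maximal runs of the same scent class become one event; runs shorter than
#' `min_duration_s` are discarded (postures are typically held for a few
#' seconds, so 1 s blips are classifier noise). "other" never yields events.
#'
#' @param series a [smooth_modal()] result.
#' @param min_duration_s minimum event duration in seconds (default 2).
#' @return data.frame with columns `start_s`, `end_s`, `class`,
#'   `duration_s`.
#' @export
extract_events <- function(series, min_duration_s = 2) {
  if (nrow(series) == 0) {
    return(empty_events())
  }
  r <- rle(series$class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- is_scent_class(r$values) & r$lengths >= min_duration_s
  if (!any(keep)) return(empty_events())
  ev <- data.frame(
    start_s = series$bin_start_s[starts[keep]],
    end_s = series$bin_start_s[ends[keep]] + 1,   # bins are 1 s wide
    class = r$values[keep], stringsAsFactors = FALSE)
  ev$duration_s <- ev$end_s - ev$start_s
  ev
}

empty_events <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), class = character(0),
             duration_s = numeric(0), stringsAsFactors = FALSE)
}

#' Assign GPS locations to scent-mark events
#'
#' Each event receives the fix nearest in time to its start (a posture's
#' onset best marks the deposition point). Events with no fix within
#' `tolerance_s` remain unlocated and are flagged.
#'
#' @param events an [extract_events()] data.frame.
#' @param track a projected [gps_track()] (see [project_track()]).
#' @param tolerance_s maximum |fix time - event start| for assignment.
#' @return `events` with added columns `located`, `x_m`, `y_m`, `lon`,
#'   `lat`, `source_fix_t`.
#' @export
georeference <- function(events, track, tolerance_s = 10) {
  events$located <- FALSE
  events$x_m <- NA_real_; events$y_m <- NA_real_
  events$lon <- NA_real_; events$lat <- NA_real_
  events$source_fix_t <- NA_real_
  if (nrow(events) == 0) return(events)
  if (nrow(track) == 0) {
    warning("empty GPS track: all ", nrow(events), " events left unlocated")
    return(events)
  }
  if (is.null(track$x_m)) stop("track must be projected first (project_track)")
  for (i in seq_len(nrow(events))) {
    j <- which.min(abs(track$t - events$start_s[i]))
    if (abs(track$t[j] - events$start_s[i]) <= tolerance_s) {
      events$located[i] <- TRUE
      events$x_m[i] <- track$x_m[j]; events$y_m[i] <- track$y_m[j]
      events$lon[i] <- track$lon[j]; events$lat[i] <- track$lat[j]
      events$source_fix_t[i] <- track$t[j]
    }
  }
  n_un <- sum(!events$located)
  if (n_un > 0) warning(n_un, " event(s) had no GPS fix within tolerance")
  events
}

#' Behaviour-specific accuracy at 1 Hz
#'
#' Compares a smoothed prediction series to a smoothed ground-truth series on
#' the same 1 s bins, reporting the full metrics plus per-scent-class
#' detection fractions ("7/7"-style: seconds in the posture that were
#' detected), so that performance on rare scent classes is not masked by
#' abundant "other" behaviour.
#'
#' @param pred,truth two aligned `smoothed_series`.
#' @return List with `metrics` (a [evaluate()] report) and `detections`
#'   (data.frame `class`, `detected_s`, `total_s`, `fraction`, `shown`).
#' @export
behaviour_specific_accuracy <- function(pred, truth) {
  common <- intersect(pred$bin_start_s, truth$bin_start_s)
  if (length(common) < max(nrow(pred), nrow(truth)) ||
      length(common) == 0) {
    stop("prediction and truth series are misaligned (bin starts differ)")
  }
  p <- pred$class[match(common, pred$bin_start_s)]
  g <- truth$class[match(common, truth$bin_start_s)]
  metrics <- suppressWarnings(evaluate(g, p))
  scls <- intersect(scent_classes(), unique(g))
  det <- data.frame(class = scls,
                    detected_s = vapply(scls, function(s) sum(g == s & p == s), numeric(1)),
                    total_s = vapply(scls, function(s) sum(g == s), numeric(1)),
                    stringsAsFactors = FALSE)
  det$fraction <- ifelse(det$total_s > 0, det$detected_s / det$total_s, NA)
  det$shown <- sprintf("%d/%d", det$detected_s, det$total_s)
  list(metrics = metrics, detections = det)
}
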