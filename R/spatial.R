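# Home-range and territory geometry in a local planar frame: percentage
# minimum convex polygons, convex overlap, overmark revisits within a buffer,
# and extra-territorial foray segmentation.

#' Percentage minimum convex polygon
#'
#' Removes the `ceiling((1 - percent/100) * n)` points farthest from the
#' arithmetic centroid (ties peeled by larger distance then later index),
#' then takes the convex hull of the remainder — the convention of the
#' classical home-range MCP estimators.
#'
#' @param points 2-column matrix or data.frame of planar coordinates
#'   (metres); data.frames may use columns `x_m`/`y_m` or `x`/`y`.
#' @param percent retention percentage (default 95).
#' @return An `mcp_result`: list with `polygon` (counter-clockwise open
#'   vertex ring), `area_m2`, `percent`, `n_points_in`, `n_points_total`.
#' @export
mcp <- function(points, percent = 95) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  stopifnot(percent > 0, percent <= 100)
  n_peel <- ceiling((1 - percent / 100) * n)
  if (n - n_peel < 3) stop("fewer than 3 points remain after peeling")
  if (n_peel > 0) {
    ctr <- colMeans(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    peel <- order(-d, -seq_len(n))[seq_len(n_peel)]
    kept <- pts[-peel, , drop = FALSE]
  } else {
    kept <- pts
  }
  hull_idx <- grDevices::chull(kept[, 1], kept[, 2])
  if (length(hull_idx) < 3) stop("degenerate geometry: kept points are collinear")
  ring <- kept[rev(hull_idx), , drop = FALSE]   # chull is clockwise; flip to CCW
  res <- list(polygon = unname(ring), area_m2 = polygon_area(ring),
              percent = percent, n_points_in = nrow(kept), n_points_total = n)
  class(res) <- "mcp_result"
  res
}

#' @export
print.mcp_result <- function(x, ...) {
  cat(sprintf("<mcp_result> %g%% MCP: %d/%d points, area %.1f m^2, %d vertices\n",
              x$percent, x$n_points_in, x$n_points_total, x$area_m2,
              nrow(x$polygon)))
  invisible(x)
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    nm <- names(points)
    xc <- intersect(c("x_m", "x"), nm)[1]
    yc <- intersect(c("y_m", "y"), nm)[1]
    if (is.na(xc) || is.na(yc)) stop("points must have x/y (or x_m/y_m) columns")
    points <- cbind(points[[xc]], points[[yc]])
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must be 2-column")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points")
  storage.mode(pts) <- "double"
  pts
}

# Shoelace area of a simple (open) ring.
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

ring_of <- function(poly) {
  if (inherits(poly, "mcp_result")) poly$polygon else as.matrix(poly)
}

ensure_ccw <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  if (sum(x * y[j] - x[j] * y) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# Sutherland-Hodgman clipping of convex polygon P by convex polygon Q.
convex_intersection <- function(P, Q) {
  P <- ensure_ccw(ring_of(P)); Q <- ensure_ccw(ring_of(Q))
  out <- P
  nq <- nrow(Q)
  for (i in seq_len(nq)) {
    if (nrow(out) == 0) break
    a <- Q[i, ]; b <- Q[if (i == nq) 1L else i + 1L, ]
    out <- clip_halfplane(out, a, b)
  }
  out
}

# Keep the part of ring on the left of (inclusive) directed edge a -> b.
clip_halfplane <- function(ring, a, b) {
  n <- nrow(ring)
  side <- (b[1] - a[1]) * (ring[, 2] - a[2]) - (b[2] - a[2]) * (ring[, 1] - a[1])
  res <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i] >= -1e-12; cj <- side[j] >= -1e-12
    if (ci) res <- rbind(res, ring[i, ])
    if (ci != cj) {
      t <- side[i] / (side[i] - side[j])
      res <- rbind(res, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  res
}

#' Proportion of the home range covered by the territory
#'
#' area(all ∩ scent) / area(all): the proportion of the all-locations MCP
#' that is also included in the scent-mark-only MCP.
#'
#' @param all_mcp MCP over all GPS fixes (home range).
#' @param scent_mcp MCP over scent-mark locations (territory).
#' @return Overlap proportion in `[0, 1]`.
#' @export
overlap_proportion <- function(all_mcp, scent_mcp) {
  a_all <- if (inherits(all_mcp, "mcp_result")) all_mcp$area_m2
           else polygon_area(ring_of(all_mcp))
  if (a_all <= 0) stop("zero-area home-range polygon")
  inter <- convex_intersection(all_mcp, scent_mcp)
  if (nrow(inter) < 3) return(0)
  polygon_area(inter) / a_all
}

# TRUE where (x, y) lies inside or on the boundary of a convex CCW ring.
point_in_convex <- function(x, y, ring, eps = 1e-9) {
  ring <- ensure_ccw(ring)
  n <- nrow(ring)
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (ring[j, 1] - ring[i, 1]) * (y - ring[i, 2]) -
          (ring[j, 2] - ring[i, 2]) * (x - ring[i, 1])
    inside <- inside & (cr >= -eps)
  }
  inside
}

#' Detect overmark revisits
#'
#' A revisit is a scent mark placed within `buffer_m` of a previous mark
#' (the buffer matches typical GPS accuracy). Each mark is paired with the
#' most recent earlier mark within the buffer, so "time between visits" is
#' unambiguous; set `all_pairs = TRUE` to enumerate every qualifying earlier
#' mark instead.
#'
#' @param events located scent-mark events (see [georeference()]), time
#'   sorted.
#' @param buffer_m distance buffer in metres (default 10).
#' @param all_pairs pair with every earlier mark within the buffer.
#' @return List with `revisits` (data.frame `earlier`, `later`,
#'   `distance_m`, `interval_h`) and `mean_interval_h`.
#' @export
detect_revisits <- function(events, buffer_m = 10, all_pairs = FALSE) {
  ev <- events[isTRUE_vec(events$located), , drop = FALSE]
  ev <- ev[order(ev$start_s), , drop = FALSE]
  out <- data.frame(earlier = integer(0), later = integer(0),
                    distance_m = numeric(0), interval_h = numeric(0))
  n <- nrow(ev)
  if (n >= 2) {
    for (i in 2:n) {
      d <- sqrt((ev$x_m[seq_len(i - 1)] - ev$x_m[i])^2 +
                (ev$y_m[seq_len(i - 1)] - ev$y_m[i])^2)
      hit <- which(d <= buffer_m)
      if (!length(hit)) next
      if (!all_pairs) hit <- hit[length(hit)]   # most recent prior mark
      out <- rbind(out, data.frame(
        earlier = hit, later = i, distance_m = d[hit],
        interval_h = (ev$start_s[i] - ev$start_s[hit]) / 3600))
    }
  }
  rownames(out) <- NULL
  list(revisits = out,
       mean_interval_h = if (nrow(out)) mean(out$interval_h) else NA_real_)
}

isTRUE_vec <- function(v) if (is.null(v)) TRUE else !is.na(v) & v

#' Segment extra-territorial forays
#'
#' Each maximal run of fixes strictly outside the territory polygon (the
#' boundary counts as inside) is one foray: the first outside fix is the
#' start, the last fix before re-entry the end. Durations are split at
#' `split_min` minutes (a foray of exactly `split_min` counts as "over").
#'
#' @param track projected [gps_track()].
#' @param territory an `mcp_result` (or convex vertex ring) delineated by
#'   scent-mark locations.
#' @param split_min duration split in minutes (default 10).
#' @return List with `forays` (data.frame `start_t`, `end_t`,
#'   `duration_min`, `n_fixes`, `max_displacement_m`, `over_split`) and
#'   `summary` (a `foray_summary`: `n_forays`, `n_under_split`,
#'   `n_over_split`, `mean_min`, `sd_min`, `total_min`,
#'   `percent_extraterritorial`, `frequency_per_min`, plus the definitions
#'   used).
#' @export
detect_forays <- function(track, territory, split_min = 10) {
  if (is.null(track$x_m)) stop("track must be projected first (project_track)")
  ring <- ensure_ccw(ring_of(territory))
  inside <- point_in_convex(track$x_m, track$y_m, ring)
  if (!any(inside)) {
    warning("track lies entirely outside the territory polygon")
  }
  ctr <- colMeans(ring)
  r <- rle(!inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  forays <- data.frame(start_t = numeric(0), end_t = numeric(0),
                       duration_min = numeric(0), n_fixes = integer(0),
                       max_displacement_m = numeric(0), over_split = logical(0))
  for (ri in runs) {
    sel <- starts[ri]:ends[ri]
    st <- track$t[sel[1]]; en <- track$t[sel[length(sel)]]
    disp <- max(sqrt((track$x_m[sel] - ctr[1])^2 + (track$y_m[sel] - ctr[2])^2))
    forays <- rbind(forays, data.frame(
      start_t = st, end_t = en, duration_min = (en - st) / 60,
      n_fixes = length(sel), max_displacement_m = disp,
      over_split = (en - st) / 60 >= split_min))
  }
  rownames(forays) <- NULL
  deployment_min <- if (nrow(track) > 1) diff(range(track$t)) / 60 else 0
  total_min <- sum(forays$duration_min)
  summary <- list(
    n_forays = nrow(forays),
    n_under_split = sum(!forays$over_split),
    n_over_split = sum(forays$over_split),
    split_min = split_min,
    mean_min = if (nrow(forays)) mean(forays$duration_min) else NA_real_,
    sd_min = if (nrow(forays) > 1) stats::sd(forays$duration_min) else NA_real_,
    total_min = total_min,
    percent_extraterritorial = if (deployment_min > 0) 100 * total_min / deployment_min else NA_real_,
    frequency_per_min = if (deployment_min > 0) nrow(forays) / deployment_min else NA_real_,
    definitions = paste("percent = 100 * total foray min / deployment span min;",
                        "frequency = N forays / deployment span min"))
  class(summary) <- "foray_summary"
  list(forays = forays, summary = summary)
}

#' @export
print.foray_summary <- function(x, ...) {
  cat(sprintf("<foray_summary> %d forays (%d under / %d over %g min)\n",
              x$n_forays, x$n_under_split, x$n_over_split, x$split_min))
  if (x$n_forays) {
    cat(sprintf("  mean %.1f min (sd %s), total %.1f min, %.1f%% of deployment\n",
                x$mean_min, if (is.na(x$sd_min)) "NA" else sprintf("%.1f", x$sd_min),
                x$total_min, x$percent_extraterritorial))
  }
  invisible(x)
}
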