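# Shared fixture builders. Everything is generated in code; nothing binary.

# Constant-valued trace: n samples at rate_hz with fixed (x, y, z).
const_trace <- function(n, xyz = c(0, 0, -1), rate_hz = 50, t0 = 0) {
  t <- t0 + (seq_len(n) - 1) / rate_hz
  accel_trace(t, rep(xyz[1], n), rep(xyz[2], n), rep(xyz[3], n), rate_hz)
}

# Toy annotated trace: one interval per class, each `per_class` samples of the
# class's signature point plus optional jitter. Classes sit far apart.
toy_labelled_trace <- function(per_class = 20,
                               classes = c("left_leg", "right_leg", "other"),
                               jitter = 0, rate_hz = 50, seed = 42) {
  sig <- list(left_leg = c(0, -1, 0), right_leg = c(0, 1, 0),
              squat_urinate = c(-1, 0, 0), squat_defaecate = c(-0.92, 0, 0),
              other = c(0, 0, -1))
  set.seed(seed)
  n <- per_class * length(classes)
  t <- (seq_len(n) - 1) / rate_hz
  x <- y <- z <- numeric(n)
  starts <- ends <- numeric(length(classes))
  for (i in seq_along(classes)) {
    idx <- ((i - 1) * per_class + 1):(i * per_class)
    s <- sig[[classes[i]]]
    x[idx] <- s[1] + stats::rnorm(per_class, 0, jitter)
    y[idx] <- s[2] + stats::rnorm(per_class, 0, jitter)
    z[idx] <- s[3] + stats::rnorm(per_class, 0, jitter)
    starts[i] <- t[idx[1]]
    ends[i] <- t[idx[per_class]] + 1 / rate_hz
  }
  list(trace = accel_trace(t, x, y, z, rate_hz),
       labels = label_track(starts, ends, classes))
}

# GPS track with prescribed planar coordinates (project_track would re-centre
# on the centroid; fixtures need the frame pinned).
toy_track <- function(x_m, y_m, t = NULL, ref_lon = -123.083, ref_lat = 39) {
  if (is.null(t)) t <- seq_along(x_m) * 5
  ll <- local_to_lonlat(x_m, y_m, ref_lon, ref_lat)
  track <- gps_track(t, ll$lon, ll$lat)
  track$x_m <- x_m
  track$y_m <- y_m
  attr(track, "ref_lon") <- ref_lon
  attr(track, "ref_lat") <- ref_lat
  attr(track, "projection") <- "equirectangular"
  track
}

# Brute-force KNN oracle implementing the declared semantics independently:
# exhaustive pairwise distances, full sort (stable in index), majority vote,
# deadlock broken by the tied class whose representative appears first.
knn_oracle <- function(training, k, queries, vote = "majority") {
  q <- as.matrix(as.data.frame(queries)[, c("x", "y", "z")])
  vapply(seq_len(nrow(q)), function(i) {
    d <- sqrt((training$x - q[i, 1])^2 + (training$y - q[i, 2])^2 +
              (training$z - q[i, 3])^2)
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(k)]
    cls <- training$class[nn]
    if (vote == "distance_weighted") {
      if (any(d[nn] == 0)) return(cls[which(d[nn] == 0)[1]])
      w <- tapply(1 / d[nn], cls, sum)
    } else {
      w <- table(cls)
    }
    top <- names(w)[w == max(w)]
    if (length(top) == 1) return(top)
    top[which.min(vapply(top, function(cl) match(cl, cls), integer(1)))]
  }, character(1))
}

# Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 P(equal), by
# exhaustive comparison.
auc_oracle <- function(score, positive) {
  sp <- score[positive]; sn <- score[!positive]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Events table of located scent marks at given times/positions.
located_events <- function(t, x, y, class = "left_leg") {
  data.frame(start_s = t, end_s = t + 3, class = class, duration_s = 3,
             located = TRUE, x_m = x, y_m = y,
             lon = NA_real_, lat = NA_real_, source_fix_t = t,
             stringsAsFactors = FALSE)
}

unit_square_points <- function(reps = 25) {
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  corners[rep(1:4, each = reps), ]
}
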