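# Labelled synthetic accelerometer traces and GPS tracks.
#
# Generative model: scent-marking postures are quasi-static gravity
# projections held for a few seconds. A pelvis-mounted device in the baseline
# standing orientation reads (0, 0, -1) g; a left-leg-raised posture rolls the
# lateral axis toward gravity (y = -1 g), right-leg gives y = +1 g, and both
# squat postures pitch the longitudinal axis down (x = -1 g), the defaecation
# squat being slightly shallower by a configurable offset. "Other" behaviour
# is modelled as the baseline orientation plus a zero-mean locomotion sinusoid
# on the heave axis and i.i.d. Gaussian sensor noise on all three axes.

#' Simulation configuration
#'
#' Defaults state the world the method assumes: 50 Hz tri-axial acceleration,
#' one GPS fix per 5 s, postures held 2-5 s, sensor noise sd 0.1 g, six marks
#' per hour per scent class (validation sessions required at least five marks
#' within 50 minutes), a 300 m territory with occasional extra-territorial
#' forays, and 5 m GPS jitter.
#'
#' @param seed integer seed driving all randomness in the simulation.
#' @param duration_s simulated deployment duration, seconds.
#' @param accel_rate_hz accelerometer sample rate, samples/s.
#' @param gps_interval_s GPS fix interval, seconds.
#' @param noise_sd_g Gaussian sensor-noise standard deviation, g.
#' @param posture_hold_s length-2 range (min, max) of posture hold time, s.
#' @param marks_per_hour expected scent-mark events per hour per scent class.
#' @param territory_radius_m radius of the simulated territory, metres.
#' @param foray_prob_per_min per-minute probability of starting a foray.
#' @param foray_mean_duration_s mean foray duration (exponential), seconds.
#' @param sex `"male"` (left/right raised-leg classes) or `"female"`
#'   (squat urination and defaecation classes).
#' @param squat_defaecate_offset_g x-axis offset distinguishing the
#'   defaecation squat from the urination squat, g.
#' @param gps_jitter_sd_m Gaussian GPS position error sd, metres.
#' @param anchor_lon,anchor_lat WGS84 anchor of the local planar frame.
#' @param locomotion_amp_g,locomotion_hz amplitude (g) and frequency (Hz) of
#'   the heave-axis locomotion sinusoid during "other" behaviour.
#' @param mount_roll_deg per-individual device mounting roll about the surge
#'   axis, degrees (for surrogate-transfer experiments).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 3600,
                       accel_rate_hz = 50,
                       gps_interval_s = 5,
                       noise_sd_g = 0.1,
                       posture_hold_s = c(2, 5),
                       marks_per_hour = 6,
                       territory_radius_m = 300,
                       foray_prob_per_min = 0.02,
                       foray_mean_duration_s = 600,
                       sex = c("male", "female"),
                       squat_defaecate_offset_g = 0.08,
                       gps_jitter_sd_m = 5,
                       anchor_lon = -123.083,
                       anchor_lat = 39.0,
                       locomotion_amp_g = 0.25,
                       locomotion_hz = 2,
                       mount_roll_deg = 0) {
  sex <- match.arg(sex)
  stopifnot(accel_rate_hz > 0, gps_interval_s > 0, noise_sd_g >= 0,
            duration_s > 0, length(posture_hold_s) == 2,
            posture_hold_s[1] > 0, posture_hold_s[2] >= posture_hold_s[1],
            marks_per_hour >= 0, territory_radius_m > 0,
            foray_prob_per_min >= 0, foray_prob_per_min <= 1,
            foray_mean_duration_s > 0, gps_jitter_sd_m >= 0)
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              accel_rate_hz = accel_rate_hz, gps_interval_s = gps_interval_s,
              noise_sd_g = noise_sd_g, posture_hold_s = posture_hold_s,
              marks_per_hour = marks_per_hour,
              territory_radius_m = territory_radius_m,
              foray_prob_per_min = foray_prob_per_min,
              foray_mean_duration_s = foray_mean_duration_s, sex = sex,
              squat_defaecate_offset_g = squat_defaecate_offset_g,
              gps_jitter_sd_m = gps_jitter_sd_m,
              anchor_lon = anchor_lon, anchor_lat = anchor_lat,
              locomotion_amp_g = locomotion_amp_g,
              locomotion_hz = locomotion_hz,
              mount_roll_deg = mount_roll_deg)
  class(cfg) <- "sim_config"
  cfg
}

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gravity signature (x, y, z) in g for each scent posture.
posture_signature <- function(class, cfg) {
  sig <- switch(class,
    left_leg        = c(0, -1, 0),
    right_leg       = c(0,  1, 0),
    squat_urinate   = c(-1, 0, 0),
    squat_defaecate = c(-1 + cfg$squat_defaecate_offset_g, 0, 0),
    stop("no signature for class ", class))
  rotate_roll(sig, cfg$mount_roll_deg)
}

# Roll the gravity vector about the surge (x) axis, emulating an imperfect
# device mounting angle that differs between individuals.
rotate_roll <- function(v, deg) {
  if (deg == 0) return(v)
  th <- deg * pi / 180
  c(v[1], cos(th) * v[2] - sin(th) * v[3], sin(th) * v[2] + cos(th) * v[3])
}

scent_classes_for_sex <- function(sex) {
  if (sex == "male") c("left_leg", "right_leg")
  else c("squat_urinate", "squat_defaecate")
}

# Draw homogeneous-Poisson scent-mark events per class, thinned so no two
# events overlap (1 s guard between postures).
draw_mark_events <- function(cfg) {
  classes <- scent_classes_for_sex(cfg$sex)
  max_hold <- cfg$posture_hold_s[2]
  if (cfg$marks_per_hour > 0 && cfg$duration_s < max_hold + 2) {
    stop(sprintf("duration_s = %g too short to place scent-mark events (max hold %g s)",
                 cfg$duration_s, max_hold))
  }
  ev <- list()
  for (cl in classes) {
    n <- stats::rpois(1, cfg$marks_per_hour * cfg$duration_s / 3600)
    if (n == 0) next
    start <- stats::runif(n, 1, cfg$duration_s - max_hold - 1)
    hold <- stats::runif(n, cfg$posture_hold_s[1], cfg$posture_hold_s[2])
    ev[[cl]] <- data.frame(start_s = start, end_s = start + hold, class = cl,
                           stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$start_s), , drop = FALSE]
  keep <- logical(nrow(ev))
  last_end <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$start_s[i] >= last_end + 1) {   # 1 s guard: postures never abut
      keep[i] <- TRUE
      last_end <- ev$end_s[i]
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Simulate a labelled accelerometer trace
#'
#' Generates `duration_s * accel_rate_hz` samples. Within scent-posture
#' intervals the signal is the static gravity signature of the posture plus
#' Gaussian noise; elsewhere it is the baseline standing orientation
#' (z = -1 g) plus a heave-axis locomotion sinusoid and Gaussian noise.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `trace` ([accel_trace()]), `labels`
#'   ([label_track()] covering the full duration, scent intervals interleaved
#'   with `"other"`), and `events` (data.frame of the scent intervals only).
#' @export
simulate_accel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    events <- draw_mark_events(cfg)
    n <- round(cfg$duration_s * cfg$accel_rate_hz)
    t <- (seq_len(n) - 1) / cfg$accel_rate_hz
    base <- rotate_roll(c(0, 0, -1), cfg$mount_roll_deg)
    x <- rep(base[1], n)
    y <- rep(base[2], n)
    z <- base[3] + cfg$locomotion_amp_g * sin(2 * pi * cfg$locomotion_hz * t)
    for (i in seq_len(nrow(events))) {
      sel <- t >= events$start_s[i] & t < events$end_s[i]
      sig <- posture_signature(events$class[i], cfg)
      x[sel] <- sig[1]; y[sel] <- sig[2]; z[sel] <- sig[3]
    }
    if (cfg$noise_sd_g > 0) {
      x <- x + stats::rnorm(n, 0, cfg$noise_sd_g)
      y <- y + stats::rnorm(n, 0, cfg$noise_sd_g)
      z <- z + stats::rnorm(n, 0, cfg$noise_sd_g)
    }
    labels <- interleave_other(events, cfg$duration_s)
    list(trace = accel_trace(t, x, y, z, cfg$accel_rate_hz),
         labels = labels, events = events)
  })
}

# Full-coverage label track: scent intervals plus the "other" gaps between.
interleave_other <- function(events, duration_s) {
  starts <- c(0, events$end_s)
  ends <- c(events$start_s, duration_s)
  keep <- starts < ends - 1e-12
  other <- data.frame(start_s = starts[keep], end_s = ends[keep],
                      class = "other", stringsAsFactors = FALSE)
  all <- rbind(events, other)
  label_track(all$start_s, all$end_s, all$class)
}

# Bernoulli-per-minute foray onsets with exponential durations, thinned to
# non-overlapping windows; durations floored at 3 GPS intervals so every
# window contains fixes.
draw_foray_windows <- function(cfg) {
  onsets <- which(stats::runif(max(0, floor(cfg$duration_s / 60))) <
                    cfg$foray_prob_per_min)
  if (!length(onsets)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  start <- (onsets - 1) * 60
  dur <- pmax(3 * cfg$gps_interval_s,
              stats::rexp(length(start), 1 / cfg$foray_mean_duration_s))
  end <- pmin(start + dur, cfg$duration_s - cfg$gps_interval_s)
  keep <- logical(length(start))
  last_end <- -Inf
  for (i in seq_along(start)) {
    if (start[i] > last_end + 2 * cfg$gps_interval_s && end[i] > start[i]) {
      keep[i] <- TRUE
      last_end <- end[i]
    }
  }
  data.frame(start_s = start[keep], end_s = end[keep])
}

#' Simulate a GPS track consistent with a ground truth
#'
#' A correlated random walk (discrete Ornstein-Uhlenbeck) attracted to the
#' territory centre; during foray windows the attractor is displaced beyond
#' the territory radius. To keep foray recovery well-posed, positions are
#' clamped inside 0.95 r outside foray windows and outside 1.05 r within them.
#' Scent-mark locations are the (unjittered) walk positions at mark times;
#' reported fixes carry Gaussian jitter of sd `gps_jitter_sd_m`.
#'
#' @param cfg a [sim_config()].
#' @param truth a ground-truth list with at least `events` (scent intervals)
#'   and `foray_windows`, as produced by [simulate_scenario()] internals.
#' @return A [gps_track()] with attribute `mark_locations` (data.frame
#'   `t, x_m, y_m, class` in the local planar frame) and attribute
#'   `sim_frame` giving the anchor lon/lat of that frame.
#' @export
simulate_gps <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed + 777L, {
    r <- cfg$territory_radius_m
    fix_t <- seq(0, cfg$duration_s, by = cfg$gps_interval_s)
    nf <- length(fix_t)
    fw <- truth$foray_windows
    in_foray <- rep(FALSE, nf)
    attractor <- matrix(0, nf, 2)
    for (i in seq_len(nrow(fw))) {
      sel <- fix_t >= fw$start_s[i] & fix_t <= fw$end_s[i]
      in_foray[sel] <- TRUE
      th <- stats::runif(1, 0, 2 * pi)
      attractor[sel, ] <- matrix(1.6 * r * c(cos(th), sin(th)),
                                 sum(sel), 2, byrow = TRUE)
    }
    theta <- 0.2
    step_sd <- 1.0 * cfg$gps_interval_s   # ~1 m/s wandering speed
    pos <- matrix(0, nf, 2)
    for (i in seq_len(nf)[-1]) {
      p <- pos[i - 1, ] + theta * (attractor[i, ] - pos[i - 1, ]) +
        stats::rnorm(2, 0, step_sd)
      d <- sqrt(sum(p^2))
      if (in_foray[i]) {
        if (d < 1.05 * r) p <- p * (1.05 * r) / max(d, 1e-9)
      } else if (d > 0.95 * r) {
        p <- p * (0.95 * r) / d
      }
      pos[i, ] <- p
    }
    # true walk position at each scent-mark onset (linear interpolation)
    ev <- truth$events
    if (nrow(ev)) {
      mx <- stats::approx(fix_t, pos[, 1], xout = ev$start_s, rule = 2)$y
      my <- stats::approx(fix_t, pos[, 2], xout = ev$start_s, rule = 2)$y
      marks <- data.frame(t = ev$start_s, x_m = mx, y_m = my,
                          class = ev$class, stringsAsFactors = FALSE)
    } else {
      marks <- data.frame(t = numeric(0), x_m = numeric(0), y_m = numeric(0),
                          class = character(0), stringsAsFactors = FALSE)
    }
    obs <- pos
    if (cfg$gps_jitter_sd_m > 0) {
      obs <- obs + matrix(stats::rnorm(2 * nf, 0, cfg$gps_jitter_sd_m), nf, 2)
    }
    ll <- local_to_lonlat(obs[, 1], obs[, 2], cfg$anchor_lon, cfg$anchor_lat)
    track <- gps_track(fix_t, ll$lon, ll$lat)
    attr(track, "mark_locations") <- marks
    attr(track, "sim_frame") <- c(lon = cfg$anchor_lon, lat = cfg$anchor_lat)
    track
  })
}

#' Simulate a complete deployment
#'
#' One call generating the full (trace, labels, track, ground truth) world for
#' a single animal: accelerometer signal with scent-posture intervals, the
#' foray windows, the GPS walk, and the true mark locations.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `trace`, `labels`, `track`, and `truth`
#'   (list: `label_track`, `events`, `mark_locations`, `foray_windows`).
#' @export
simulate_scenario <- function(cfg) {
  acc <- simulate_accel(cfg)
  foray_windows <- with_sim_seed(cfg$seed + 555L, draw_foray_windows(cfg))
  truth <- list(label_track = acc$labels, events = acc$events,
                foray_windows = foray_windows)
  track <- simulate_gps(cfg, truth)
  truth$mark_locations <- attr(track, "mark_locations")
  list(trace = acc$trace, labels = acc$labels, track = track, truth = truth)
}
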