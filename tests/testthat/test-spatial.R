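test_that("MCP at 100% is the convex hull; peeling removes distant outliers", {
  pts <- unit_square_points(25)
  full <- mcp(pts, percent = 100)
  expect_equal(full$area_m2, 1.0)
  expect_equal(full$n_points_in, 100)

  # 100 square points + 1 outlier, percent 95: peel ceil(0.05 * 101) = 6
  with_out <- rbind(pts, c(100, 100))
  p95 <- mcp(with_out, percent = 95)
  expect_equal(p95$n_points_total - p95$n_points_in, 6)
  expect_equal(p95$area_m2, 1.0)

  expect_error(mcp(rbind(c(0, 0), c(1, 1))), "at least 3")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(mcp(coll, 100), "collinear")
})

test_that("100% hull contains every input point and retention bound holds", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    pts <- cbind(rnorm(n, 0, 50), rnorm(n, 0, 50))
    full <- mcp(pts, percent = 100)
    expect_true(all(scentmark:::point_in_convex(pts[, 1], pts[, 2],
                                                full$polygon, eps = 1e-6)))
    p95 <- mcp(pts, percent = 95)
    expect_gte(p95$n_points_in / n, 0.95 - 1 / n)
    expect_gte(full$area_m2, p95$area_m2)
  }
})

test_that("overlap proportion covers identical, disjoint, and half overlap", {
  sq <- function(x0, y0, w, h) {
    mcp(rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h)),
        percent = 100)
  }
  a <- sq(0, 0, 1, 1)
  expect_equal(overlap_proportion(a, sq(0, 0, 1, 1)), 1.0)
  expect_equal(overlap_proportion(a, sq(5, 5, 1, 1)), 0.0)
  expect_equal(overlap_proportion(a, sq(0, 0, 0.5, 1)), 0.5)
  expect_error(overlap_proportion(structure(list(polygon = rbind(c(0, 0), c(1, 1), c(2, 2)),
                                                 area_m2 = 0),
                                            class = "mcp_result"), a),
               "zero-area")
})

test_that("overlap proportion is invariant under rigid motion of both polygons", {
  set.seed(71)
  p1 <- mcp(cbind(rnorm(40), rnorm(40)), 100)
  p2 <- mcp(cbind(rnorm(40, 0.5), rnorm(40, 0.5)), 100)
  base <- overlap_proportion(p1, p2)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(p) {
    ring <- p$polygon %*% R + matrix(c(100, -50), nrow(p$polygon), 2, TRUE)
    list(polygon = ring, area_m2 = scentmark:::polygon_area(ring))
  }
  m1 <- move(p1); m2 <- move(p2)
  expect_equal(overlap_proportion(m1$polygon, m2$polygon), base,
               tolerance = 1e-9)
})

test_that("revisits pair each mark with the most recent prior within 10 m", {
  # two marks 5 m and 3 h apart
  ev <- located_events(c(0, 3 * 3600), c(0, 5), c(0, 0))
  rv <- detect_revisits(ev, buffer_m = 10)
  expect_equal(nrow(rv$revisits), 1)
  expect_equal(rv$revisits$interval_h, 3.0)
  expect_equal(rv$mean_interval_h, 3.0)

  # all pairwise distances > 10 m -> none
  far <- located_events(c(0, 3600, 7200), c(0, 50, 100), c(0, 0, 0))
  expect_equal(nrow(detect_revisits(far)$revisits), 0)

  # 4 co-located marks -> 3 revisits chained to the most recent prior
  co <- located_events(c(0, 1, 2, 3) * 3600, rep(0, 4), rep(0, 4))
  rv <- detect_revisits(co)
  expect_equal(nrow(rv$revisits), 3)
  expect_equal(rv$revisits$earlier, 1:3)
  expect_equal(rv$revisits$later, 2:4)
  expect_true(all(rv$revisits$interval_h == 1))
})

test_that("revisit chaining matches an exhaustive pairing oracle", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    ev <- located_events(sort(runif(n, 0, 1e5)),
                         runif(n, 0, 60), runif(n, 0, 60))
    got <- detect_revisits(ev, buffer_m = 10)$revisits
    # oracle: for each i the largest j < i with distance <= 10
    oracle <- do.call(rbind, lapply(2:n, function(i) {
      d <- sqrt((ev$x_m[1:(i - 1)] - ev$x_m[i])^2 +
                (ev$y_m[1:(i - 1)] - ev$y_m[i])^2)
      j <- which(d <= 10)
      if (!length(j)) return(NULL)
      j <- max(j)
      data.frame(earlier = j, later = i,
                 interval_h = (ev$start_s[i] - ev$start_s[j]) / 3600)
    }))
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("earlier", "later", "interval_h")], oracle,
                   ignore_attr = TRUE)
    }
    # all-pairs mode returns a superset
    ap <- detect_revisits(ev, buffer_m = 10, all_pairs = TRUE)$revisits
    expect_gte(nrow(ap), nrow(got))
  }
})

test_that("foray segmentation follows the first-out/last-before-re-entry rule", {
  square <- mcp(rbind(c(-100, -100), c(100, -100), c(100, 100), c(-100, 100)),
                100)
  # fully inside -> no forays
  inside <- toy_track(seq(-50, 50, 10), rep(0, 11))
  fo <- detect_forays(inside, square)
  expect_equal(fo$summary$n_forays, 0)
  expect_equal(fo$summary$percent_extraterritorial, 0)

  # one excursion of 5 outside fixes at 5 s spacing -> 20 s = 1/3 min, under
  x <- c(0, 50, 150, 160, 170, 160, 150, 50, 0)
  tr <- toy_track(x, rep(0, 9), t = seq(0, 40, 5))
  fo <- detect_forays(tr, square, split_min = 10)
  expect_equal(fo$summary$n_forays, 1)
  expect_equal(fo$forays$n_fixes, 5)
  expect_equal(fo$forays$duration_min, 20 / 60, tolerance = 1e-9)
  expect_equal(fo$summary$n_under_split, 1)
  expect_equal(fo$summary$n_over_split, 0)
  # boundary counts as inside
  expect_equal(fo$forays$start_t, 10)
  expect_equal(fo$forays$end_t, 30)

  # entirely outside -> single foray spanning the track, with a warning
  out <- toy_track(seq(500, 580, 10), rep(0, 9))
  expect_warning(fo <- detect_forays(out, square), "entirely outside")
  expect_equal(fo$summary$n_forays, 1)
  expect_equal(fo$forays$n_fixes, 9)
})

test_that("foray summary identities hold on random tracks", {
  square <- mcp(rbind(c(-40, -40), c(40, -40), c(40, 40), c(-40, 40)), 100)
  set.seed(91)
  for (rep in 1:5) {
    x <- cumsum(rnorm(300, 0, 15))
    tr <- toy_track(x, rep(0, 300))
    fo <- suppressWarnings(detect_forays(tr, square))
    expect_equal(fo$summary$n_under_split + fo$summary$n_over_split,
                 fo$summary$n_forays)
    expect_equal(fo$summary$total_min, sum(fo$forays$duration_min))
    # foray runs partition the outside fixes
    outside <- !scentmark:::point_in_convex(tr$x_m, tr$y_m, square$polygon)
    expect_equal(sum(fo$forays$n_fixes), sum(outside))
  }
})

test_that("forays and revisits are recovered exactly from simulator truth", {
  cfg <- sim_config(seed = 37, duration_s = 7200, foray_prob_per_min = 0.05,
                    gps_jitter_sd_m = 0, marks_per_hour = 8)
  sc <- simulate_scenario(cfg)
  fw <- sc$truth$foray_windows
  expect_gt(nrow(fw), 0)

  track <- project_track(sc$track)
  # ground-truth territory: the simulation's radius-r disc, re-expressed in
  # the projection frame as a fine regular polygon
  ctr_ll <- local_to_lonlat(0, 0, cfg$anchor_lon, cfg$anchor_lat)
  ctr <- lonlat_to_local(ctr_ll$lon, ctr_ll$lat,
                         attr(track, "ref_lon"), attr(track, "ref_lat"))
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  disc <- cbind(ctr$x + cfg$territory_radius_m * cos(th),
                ctr$y + cfg$territory_radius_m * sin(th))
  fo <- detect_forays(track, disc, split_min = 10)
  expect_equal(fo$summary$n_forays, nrow(fw))
  # recovered durations equal the fix-grid span of each truth window
  for (i in seq_len(nrow(fw))) {
    fix_in <- sc$track$t[sc$track$t >= fw$start_s[i] & sc$track$t <= fw$end_s[i]]
    expect_equal(fo$forays$start_t[i], min(fix_in))
    expect_equal(fo$forays$end_t[i], max(fix_in))
  }

  # revisits computed from true mark locations match the oracle pairing
  truth <- sc$truth$mark_locations
  ev <- located_events(truth$t, truth$x_m, truth$y_m, truth$class)
  got <- detect_revisits(ev, buffer_m = 10)$revisits
  expected <- 0L
  for (i in seq_len(nrow(truth))[-1]) {
    d <- sqrt((truth$x_m[1:(i - 1)] - truth$x_m[i])^2 +
              (truth$y_m[1:(i - 1)] - truth$y_m[i])^2)
    if (any(d <= 10)) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
})
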