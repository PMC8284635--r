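mk_track <- function(lat, lon, dt_s = 5,
                     t0 = as.POSIXct("2018-08-20 00:00:00", tz = "UTC")) {
  gps_track(data.frame(time = t0 + (seq_along(lat) - 1) * dt_s,
                       lat = lat, lon = lon))
}

test_that("moving-window speeds: stationary zero, meridian track ~72 kph", {
  g <- mk_track(rep(39.4, 10), rep(141.99, 10))
  expect_true(all(compute_speeds(g)$speed_kph == 0))

  # 100 m steps along a meridian every 5 s => 72 km/h
  step_deg <- 100 / geosphere::distGeo(c(0, 39), c(0, 40)) # 1 deg of lat
  g2 <- mk_track(39 + (0:19) * step_deg, rep(142, 20))
  sp <- compute_speeds(g2)$speed_kph
  expect_equal(sp[10], 72, tolerance = 0.01)
  expect_true(all(abs(sp - 72) < 1))
})

test_that("5-fix windows damp jitter below consecutive-fix speeds", {
  set.seed(32)
  jit <- 20 / 111320  # ~20 m jitter
  g <- mk_track(39.4 + rnorm(100, 0, jit), 141.99 + rnorm(100, 0, jit))
  s5 <- compute_speeds(g, window_fixes = 5)$speed_kph
  s2 <- compute_speeds(g, window_fixes = 2)$speed_kph
  expect_lt(mean(s5), mean(s2))
})

test_that("colony and speed filters drop the right fixes and commute", {
  colony <- c(39.40, 141.99)
  km <- 1 / 111.32  # deg lat per km
  g <- mk_track(39.40 + c(0.5, 1.0, 2.0, 5.0, 10.0) * km,
                rep(141.99, 5))
  g$speed_kph <- c(10, 10, 85, 10, 10)
  out <- filter_fixes(g, colony)
  expect_equal(nrow(out), 2)   # 0.5 and 1.0 km inside radius; 85 kph fast
  expect_equal(out$speed_kph, c(10, 10))

  set.seed(33)
  g2 <- mk_track(39.40 + runif(200, 0, 0.2), 141.99 + runif(200, 0, 0.2))
  g2$speed_kph <- runif(200, 0, 120)
  a <- filter_fixes(filter_fixes(g2, colony, max_speed_kph = Inf),
                    colony, radius_km = 0)
  # oracle: brute-force row filter
  d_km <- geosphere::distGeo(cbind(g2$lon, g2$lat),
                             c(colony[2], colony[1])) / 1000
  keep <- d_km >= 1.5 & g2$speed_kph <= 80
  expect_equal(nrow(filter_fixes(g2, colony)), sum(keep))
})

test_that("foraging behaviours attach to fixes within 30 s, dives win ties", {
  t0 <- as.POSIXct("2018-08-20 00:00:00", tz = "UTC")
  g <- mk_track(rep(39.5, 3), rep(142, 3), dt_s = 60, t0 = t0)  # 0, 60, 120 s
  eth <- ethogram(c(45, 100), c(50, 110),
                  c("foraging_dive", "surface_seizing"))
  out <- assign_behaviour(g, eth, t0 = t0)
  expect_equal(out$behaviour, c(NA, "foraging_dive", "surface_seizing"))

  # nearest interval 45 s away -> unlabelled
  eth2 <- ethogram(165, 170, "foraging_dive")
  expect_true(all(is.na(assign_behaviour(g, eth2, t0 = t0)$behaviour)))

  # exact tie between a dive and a seizing -> dive
  eth3 <- ethogram(c(40, 70), c(50, 80),
                   c("foraging_dive", "surface_seizing"))
  out3 <- assign_behaviour(g, eth3, t0 = t0)
  expect_equal(out3$behaviour[2], "foraging_dive")  # both 10 s from fix at 60
})

test_that("random layouts assign like a brute-force nearest-interval oracle", {
  set.seed(34)
  t0 <- as.POSIXct("2018-08-20 00:00:00", tz = "UTC")
  for (rep in 1:20) {
    ft <- sort(sample(0:2000, 30))
    g <- mk_track(rep(39.5, 30), rep(142, 30), dt_s = 1, t0 = t0)
    g$time <- t0 + ft
    st <- sort(sample(seq(0, 1950, by = 50), 8))
    eth <- ethogram(st, st + runif(8, 2, 40),
                    sample(c("foraging_dive", "surface_seizing"), 8, TRUE))
    out <- assign_behaviour(g, eth, t0 = t0)
    for (i in seq_len(30)) {
      dist_i <- pmax(eth$start_s - ft[i], ft[i] - eth$end_s, 0)
      near <- dist_i <= 30
      if (!any(near)) {
        expect_true(is.na(out$behaviour[i]))
      } else {
        dmin <- min(dist_i[near])
        cand <- eth$label[near & dist_i <= dmin]
        want <- if ("foraging_dive" %in% cand) "foraging_dive" else
          cand[1]
        expect_equal(out$behaviour[i], want)
      }
    }
  }
})

test_that("fast foraging fixes reclassify to flight strictly above 15 kph", {
  g <- mk_track(rep(39.5, 3), rep(142, 3))
  g$behaviour <- c("foraging_dive", "surface_seizing", "foraging_dive")
  g$speed_kph <- c(20, 10, 15)
  out <- reclassify_fast_foraging(g)
  expect_equal(out$behaviour,
               c("flight", "surface_seizing", "foraging_dive"))
})

test_that("short flight/unknown slivers are pruned, partition preserved", {
  eth <- ethogram(c(0, 10, 13, 40, 44.9),
                  c(10, 13, 40, 44.9, 60),
                  c("rest", "flight", "surface_seizing", "unknown", "rest"))
  out <- prune_short_behaviours(eth)
  expect_false(any(out$label == "flight" & (out$end_s - out$start_s) < 5))
  expect_false(any(out$label == "unknown"))
  expect_equal(sum(out$end_s - out$start_s), 60)  # still a partition

  keep5 <- ethogram(c(0, 10), c(10, 15), c("rest", "flight"))
  expect_equal(nrow(prune_short_behaviours(keep5)), 2)  # 5.0 s kept

  set.seed(35)
  for (rep in 1:10) {
    b <- sort(c(0, runif(12, 0, 100), 100))
    e <- ethogram(b[-length(b)], b[-1],
                  sample(behaviour_levels(), length(b) - 1, TRUE))
    out <- prune_short_behaviours(e)
    expect_equal(sum(out$end_s - out$start_s), 100)
    expect_false(any(out$label %in% c("flight", "unknown") &
                       (out$end_s - out$start_s) < 5 - 1e-9))
  }
})

test_that("trip segmentation uses ceiling days and the 2-day category split", {
  colony <- c(39.40, 141.99)
  km <- 1 / 111.32
  t0 <- as.POSIXct("2018-08-20 06:00:00", tz = "UTC")
  # 26-hour excursion: out at 10 km, then home
  n <- 26 * 60
  lat <- c(39.40, rep(39.40 + 10 * km, n), 39.40)
  g <- mk_track(lat, rep(141.99, n + 2), dt_s = 60, t0 = t0)
  tr <- segment_trips(g, colony)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$duration_days, 2)       # ceiling(26 h)
  expect_equal(tr$category, "short")      # <= 2 days

  n3 <- 3 * 24 * 60
  g3 <- mk_track(c(39.40, rep(39.40 + 10 * km, n3), 39.40),
                 rep(141.99, n3 + 2), dt_s = 60, t0 = t0)
  expect_equal(segment_trips(g3, colony)$category, "long")
})

test_that("daily budgets conserve day length and fractions sum to one", {
  eth <- ethogram(0, 86400, "rest")
  b <- daily_budget(eth)
  expect_equal(b$rest_frac, 1)
  expect_equal(b$rest_s, 86400)

  eth2 <- ethogram(c(0, 40000, 50000, 50030, 86400, 150000),
                   c(40000, 50000, 50030, 86400, 150000, 172800),
                   c("rest", "flight", "surface_seizing", "rest",
                     "flight", "rest"))
  b2 <- daily_budget(eth2)
  expect_equal(nrow(b2), 2)
  tot <- b2$forage_s + b2$transit_s + b2$rest_s + b2$unknown_s
  expect_equal(tot, c(86400, 86400))
  expect_equal(b2$forage_frac + b2$transit_frac + b2$rest_frac +
                 b2$unknown_frac, c(1, 1), tolerance = 1e-9)
  expect_equal(b2$n_seizing, c(1, 0))
  # interval crossing midnight is split between the days
  expect_equal(b2$transit_s, c(10000, 63600))
})
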