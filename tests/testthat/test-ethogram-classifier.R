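test_that("flap detection: glides yield nothing, threshold is inclusive", {
  set.seed(20)
  glide <- fake_decomposed(rnorm(200, 0, 0.02))
  expect_equal(nrow(detect_flaps(glide, fake_profile(0.3))), 0)

  # triangle wave with peak-trough difference exactly at the threshold
  zig <- fake_decomposed(rep(c(0, 0.5), 10))
  fl <- detect_flaps(zig, fake_profile(flap_threshold_g = 0.5))
  expect_gt(nrow(fl), 0)
  expect_true(all(fl$amplitude_g >= 0.5))
})

test_that("a 4 Hz flapping segment yields one flap per wingbeat cycle", {
  cfg <- generator_config(flap_bout_s = 10, glide_s = 0.05)
  sa <- synth_accel(data.frame(label = "flight", duration_s = 10), cfg,
                    seed = 21)
  dec <- decompose_accel(sa$series)
  fl <- detect_flaps(dec, fake_profile(0.3))
  expect_true(abs(nrow(fl) - 40) <= 2)  # 10 s x 4 Hz, edge effects
})

test_that("flap grouping follows the 0.5 s / 30 s two-level rule", {
  mk <- function(t) data.frame(peak_index = 1, trough_index = 2,
                               amplitude_g = 1, start_s = t, end_s = t + 0.1)
  flaps <- do.call(rbind, lapply(c(0, 0.4, 0.8), mk))
  expect_equal(nrow(group_flight(flaps)), 1)

  flaps2 <- do.call(rbind, lapply(c(0, 10, 45), mk))
  fi <- group_flight(flaps2)
  expect_equal(nrow(fi), 2)       # 45 - 10.1 = 34.9 s gap > 30 s
  expect_equal(fi$start_s, c(0, 45))
})

test_that("random flap trains group like a transitive-closure oracle", {
  set.seed(22)
  for (rep in 1:20) {
    t <- sort(runif(40, 0, 300))
    flaps <- data.frame(peak_index = 1, trough_index = 2, amplitude_g = 1,
                        start_s = t, end_s = t + 0.05)
    got <- group_flight(flaps)
    # oracle: repeatedly merge any two intervals violating the gap rules
    merge_pass <- function(ints, gap, inclusive) {
      repeat {
        done <- TRUE
        i <- 1
        while (i < nrow(ints)) {
          g <- ints$start_s[i + 1] - ints$end_s[i]
          if ((inclusive && g <= gap) || (!inclusive && g < gap)) {
            ints$end_s[i] <- max(ints$end_s[i], ints$end_s[i + 1])
            ints <- ints[-(i + 1), , drop = FALSE]
            done <- FALSE
          } else i <- i + 1
        }
        if (done) return(ints)
      }
    }
    bouts <- merge_pass(data.frame(start_s = t, end_s = t + 0.05), 0.5, FALSE)
    flights <- merge_pass(bouts, 30, TRUE)
    rownames(flights) <- NULL
    expect_equal(got, flights)
  }
})

test_that("take-offs need an upward pitch event near the flight onset", {
  prof <- fake_profile(large_pitch_change_deg = 10)
  flights <- data.frame(start_s = 100, end_s = 400)
  up <- data.frame(time_s = 99.5, end_s = 100.5, magnitude_deg = 12,
                   direction = "up", origin_pitch_deg = -5)
  down <- transform(up, direction = "down")
  expect_equal(nrow(detect_takeoffs(flights, up, prof)), 1)
  expect_equal(nrow(detect_takeoffs(flights, down, prof)), 0)
  far <- transform(up, time_s = 95, end_s = 96)
  expect_equal(nrow(detect_takeoffs(flights, far, prof)), 0)
})

test_that("back-mounted tags drop upward events originating at high pitch", {
  prof <- fake_profile(pfm_pitch_min_med_deg = -4,
                       tag_kind = "back_mounted")
  flights <- data.frame(start_s = 100, end_s = 400)
  hi <- data.frame(time_s = 99.5, end_s = 100.5, magnitude_deg = 12,
                   direction = "up", origin_pitch_deg = 10)  # above -4
  lo <- transform(hi, origin_pitch_deg = -8)
  expect_equal(nrow(detect_takeoffs(flights, hi, prof)), 0)
  expect_equal(nrow(detect_takeoffs(flights, lo, prof)), 1)
  # same events pass on a chest-mounted tag
  chest <- fake_profile(pfm_pitch_min_med_deg = -4)
  expect_equal(nrow(detect_takeoffs(flights, hi, chest)), 1)
})

test_that("pitch events chain into groups at the 23.3 s window", {
  mk <- function(t) data.frame(time_s = t, end_s = t + 0.5,
                               magnitude_deg = 20, direction = "up",
                               origin_pitch_deg = 0)
  g1 <- group_pitch_events(do.call(rbind, lapply(c(0, 20, 40), mk)))
  expect_length(g1, 1)
  g2 <- group_pitch_events(do.call(rbind, lapply(c(0, 30), mk)))
  expect_length(g2, 2)
})

test_that("random event sets group like a single-linkage oracle", {
  set.seed(23)
  for (rep in 1:20) {
    t <- sort(runif(15, 0, 400))
    ev <- data.frame(time_s = t, end_s = t + 0.5, magnitude_deg = 20,
                     direction = "up", origin_pitch_deg = 0)
    got <- group_pitch_events(ev, 23.3)
    # oracle: single-linkage clusters cut at distance 23.3 on 1-D points
    cl <- cutree(hclust(dist(t), method = "single"), h = 23.3)
    sizes_got <- sort(vapply(got, nrow, integer(1)))
    expect_equal(sizes_got, sort(unname(table(cl))),
                 ignore_attr = TRUE)
    expect_length(got, length(unique(cl)))
  }
})

test_that("dive rule: descent below threshold then timely ascent recovery", {
  fs <- 20
  prof <- fake_profile(pfm_pitch_min_med_deg = -20,
                       pfm_pitch_mean_med_deg = 0,
                       pfm_pitch_var_med_deg2 = 5)
  # thresholds: descent < -50, ascent > 10
  t <- seq_len(30 * fs) / fs
  pitch <- rep(0, length(t))
  pitch[t >= 10 & t < 12] <- -70   # dip
  pitch[t >= 12 & t < 14] <- 20    # recovery within 4 s
  ev <- data.frame(time_s = c(10, 12), end_s = c(10.5, 12.5),
                   magnitude_deg = 90, direction = c("down", "up"),
                   origin_pitch_deg = 0)
  dv <- classify_dives(ev, fake_pitch(pitch, fs), prof)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$start_s, 10, tolerance = 0.01)
  expect_true(dv$end_s >= 11.9 && dv$end_s <= 12.1)

  # no recovery within 10 s -> no dive
  pitch2 <- rep(0, length(t)); pitch2[t >= 10 & t < 25] <- -70
  expect_equal(nrow(classify_dives(ev, fake_pitch(pitch2, fs), prof)), 0)
})

test_that("surface seizing needs three chained events within 2 s gaps", {
  mk <- function(tt) data.frame(time_s = tt, end_s = tt + 0.3,
                                magnitude_deg = 30, direction = "up",
                                origin_pitch_deg = 0)
  yes <- classify_surface_seizing(mk(c(0, 1.5, 3.0)))
  expect_equal(nrow(yes), 1)
  expect_equal(yes$start_s, 0)
  no <- classify_surface_seizing(mk(c(0, 3, 6)))
  expect_equal(nrow(no), 0)
  # all-pairs variant is stricter: 0..3.0 span fails, a tight burst passes
  expect_equal(nrow(classify_surface_seizing(mk(c(0, 1.5, 3.0)),
                                             rule = "all_pairs")), 0)
  expect_equal(nrow(classify_surface_seizing(mk(c(0, 0.8, 1.6)),
                                             rule = "all_pairs")), 1)
  # events inside an already-extracted dive are discarded first
  ev <- mk(c(0, 1.5, 3.0))
  dives <- data.frame(start_s = 1, end_s = 2)
  expect_equal(nrow(classify_surface_seizing(ev, dives)), 0)
})

test_that("rest is assigned where the ODBA moving average is quiet", {
  still <- fake_decomposed(numeric(600))
  r <- classify_rest(odba(still))
  expect_equal(nrow(r), 1)
  expect_equal(r$start_s, 0)
  expect_equal(r$end_s, 30)

  set.seed(24)
  loud <- fake_decomposed(rnorm(600, 0, 1))  # flight-level ODBA ~1 g
  expect_equal(nrow(classify_rest(odba(loud))), 0)
})

test_that("assembly partitions the record with dive-first precedence", {
  eth <- assemble_ethogram(200, 20,
                           flights = data.frame(start_s = 0, end_s = 8),
                           dives = data.frame(start_s = 2, end_s = 4),
                           rests = data.frame(start_s = 8, end_s = 10))
  expect_equal(sum(eth$end_s - eth$start_s), 10)  # exact partition
  lab_at <- function(t) eth$label[findInterval(t + 1e-9, eth$start_s)]
  expect_equal(lab_at(3), "foraging_dive")  # dive wins over flight
  expect_equal(lab_at(1), "flight")
  expect_equal(lab_at(9), "rest")

  empty <- assemble_ethogram(100, 20)
  expect_equal(empty$label, "unknown")
  expect_equal(sum(empty$end_s - empty$start_s), 5)
})

test_that("raising the flap threshold never increases flight duration", {
  set.seed(25)
  scr <- synth_validation_script(1200, generator_config(), seed = 26)
  sa <- synth_accel(scr, generator_config(), seed = 27)
  dec <- decompose_accel(sa$series)
  dur_at <- function(thr) {
    fl <- group_flight(detect_flaps(dec, fake_profile(thr)))
    sum(fl$end_s - fl$start_s)
  }
  durs <- vapply(c(0.1, 0.3, 0.5, 0.7, 1.0), dur_at, numeric(1))
  expect_true(all(diff(durs) <= 1e-9))
})

test_that("raising the rest threshold never decreases rest duration", {
  set.seed(28)
  dec <- fake_decomposed(rnorm(2000, 0, 0.15))
  od <- odba(dec)
  dur_at <- function(thr) {
    r <- classify_rest(od, thr)
    if (!nrow(r)) 0 else sum(r$end_s - r$start_s)
  }
  durs <- vapply(c(0.1, 0.2, 0.3, 0.5), dur_at, numeric(1))
  expect_true(all(diff(durs) >= -1e-9))
})

test_that("the full classifier labels every sample exactly once", {
  scr <- synth_validation_script(1800, generator_config(), seed = 29)
  sa <- synth_accel(scr, generator_config(), seed = 30)
  # a half-hour record cannot host the full 10 PFMs 5 min apart; the
  # calibration proceeds on fewer with a warning
  cl <- suppressWarnings(classify_behaviour(sa$series))
  eth <- cl$ethogram
  expect_equal(sum(eth$end_s - eth$start_s), duration_s(sa$series))
  expect_false(is.unsorted(eth$start_s))
  expect_true(all(eth$start_s[-1] >= eth$end_s[-nrow(eth)] - 1e-9))
})
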