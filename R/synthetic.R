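#' Generator configuration for synthetic deployments
#'
#' Parameters of the synthetic labelled-signal generator. Behaviour
#' durations are drawn from normal distributions with the field-observed
#' means and standard deviations (dives 3.2 +/- 1.2 s, surface-seizing
#' landings 1.5 +/- 1.4 s and take-offs 0.6 +/- 1.6 s, pre-flight take-offs
#' 3.0 +/- 1.3 s), truncated to positive, physically plausible ranges.
#' Cruising flapping runs at 4 Hz (inside the flap band), take-off flapping
#' at 5.5 Hz (inside the take-off band).
#'
#' @param ... Named overrides of any default listed below.
#' @return Named list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    fs = 20,                      # Hz
    tag_kind = "chest_mounted",
    flight_flap_hz = 4,
    takeoff_flap_hz = 5.5,
    flap_amp_g = 0.4,             # z_D sinusoid amplitude during flaps
    flap_x_amp_g = 0.2,
    flap_y_amp_g = 0.15,
    glide_noise_g = 0.02,         # per-axis dynamic noise outside flaps
    rest_noise_g = 0.01,          # per-axis dynamic noise at rest
    water_noise_g = 0.05,         # per-axis dynamic noise in water contact
    flap_bout_s = 8,              # flap run length within flight
    glide_s = 2,                  # glide length between flap runs
    flight_pitch_amp_deg = 3,     # slow pitch oscillation during flight
    flight_pitch_hz = 0.3,
    rest_pitch_amp_deg = 0.5,
    takeoff_amp_g = 0.5,          # z_D amplitude of take-off flapping
    takeoff_pitch_deg = 40,       # upward excursion at take-off
    preflight_takeoff_s = c(mean = 3.0, sd = 1.3, lo = 1.0, hi = 6.0),
    dive_duration_s = c(mean = 3.2, sd = 1.2, lo = 1.2, hi = 6.0),
    dive_pitch_deg = -70,
    dive_recovery_pitch_deg = 35,
    landing_s = c(mean = 1.5, sd = 1.4, lo = 0.3, hi = 4.0),
    landing_pitch_deg = -25,
    landing_amp_g = 0.3,          # z_D splash amplitude at landing
    seize_takeoff_s = c(mean = 0.6, sd = 1.6, lo = 0.2, hi = 2.0),
    seize_takeoff_pitch_deg = 45,
    mount_pitch_offset_deg = 0
  )
  user <- list(...)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown generator parameter(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  if (cfg$flight_flap_hz >= cfg$fs / 2)
    stop("config error: flight_flap_hz must be below the Nyquist frequency")
  structure(cfg, class = c("generator_config", "list"))
}

# truncated-normal draw (rejection with clamping fallback)
.rtnorm <- function(n, spec) {
  x <- stats::rnorm(n, spec[["mean"]], spec[["sd"]])
  for (i in 1:50) {
    bad <- x < spec[["lo"]] | x > spec[["hi"]]
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), spec[["mean"]], spec[["sd"]])
  }
  pmin(spec[["hi"]], pmax(spec[["lo"]], x))
}

# piecewise-linear profile over n samples; breaks are fractions of [0, 1]
.pw_linear <- function(n, breaks, values) {
  stats::approx(breaks, values, xout = seq(0, 1, length.out = n))$y
}

# ---- per-behaviour signal templates -----------------------------------
# each returns list(pitch_deg, xd, yd, zd) of length n

.seg_rest <- function(n, cfg) {
  t <- seq_len(n) / cfg$fs
  list(pitch_deg = cfg$rest_pitch_amp_deg *
         sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi)),
       xd = stats::rnorm(n, 0, cfg$rest_noise_g),
       yd = stats::rnorm(n, 0, cfg$rest_noise_g),
       zd = stats::rnorm(n, 0, cfg$rest_noise_g))
}

.seg_flight <- function(n, cfg) {
  fs <- cfg$fs
  t <- seq_len(n) / fs
  nf <- max(1L, round(cfg$flap_bout_s * fs))
  ng <- max(1L, round(cfg$glide_s * fs))
  is_flap <- rep_len(rep(c(TRUE, FALSE), c(nf, ng)), n)
  carrier <- sin(2 * pi * cfg$flight_flap_hz * t)
  list(pitch_deg = cfg$flight_pitch_amp_deg *
         sin(2 * pi * cfg$flight_pitch_hz * t + stats::runif(1, 0, 2 * pi)),
       xd = is_flap * cfg$flap_x_amp_g *
         sin(2 * pi * cfg$flight_flap_hz * t + 1) +
         stats::rnorm(n, 0, cfg$glide_noise_g),
       yd = is_flap * cfg$flap_y_amp_g *
         sin(2 * pi * cfg$flight_flap_hz * t + 2) +
         stats::rnorm(n, 0, cfg$glide_noise_g),
       zd = is_flap * cfg$flap_amp_g * carrier +
         stats::rnorm(n, 0, cfg$glide_noise_g))
}

.seg_takeoff <- function(n, cfg, peak_deg = cfg$takeoff_pitch_deg) {
  t <- seq_len(n) / cfg$fs
  amp <- cfg$takeoff_amp_g
  list(pitch_deg = .pw_linear(n, c(0, 0.4, 1), c(0, peak_deg, 0)),
       xd = 0.4 * amp * sin(2 * pi * cfg$takeoff_flap_hz * t + 1) +
         stats::rnorm(n, 0, cfg$glide_noise_g),
       yd = 0.3 * amp * sin(2 * pi * cfg$takeoff_flap_hz * t + 2) +
         stats::rnorm(n, 0, cfg$glide_noise_g),
       zd = amp * sin(2 * pi * cfg$takeoff_flap_hz * t) +
         stats::rnorm(n, 0, cfg$glide_noise_g))
}

.seg_dive <- function(n, cfg) {
  # plunge profile: fast descent, bottom phase, rapid exit held at the
  # recovery angle (the return to level flight is smoothed into the next
  # segment)
  fs <- cfg$fs
  t <- seq_len(n) / fs
  pitch <- .pw_linear(n, c(0, 0.12, 0.60, 0.90, 1),
                      c(0, cfg$dive_pitch_deg, cfg$dive_pitch_deg,
                        cfg$dive_recovery_pitch_deg,
                        cfg$dive_recovery_pitch_deg))
  burst <- as.numeric(t <= 0.4) * 0.8 * sin(2 * pi * 8 * t)  # entry splash
  list(pitch_deg = pitch,
       xd = stats::rnorm(n, 0, cfg$water_noise_g),
       yd = stats::rnorm(n, 0, cfg$water_noise_g),
       zd = burst + stats::rnorm(n, 0, cfg$water_noise_g))
}

.seg_landing <- function(n, cfg) {
  t <- seq_len(n) / cfg$fs
  list(pitch_deg = .pw_linear(n, c(0, 0.5, 1),
                              c(0, cfg$landing_pitch_deg, 0)),
       xd = stats::rnorm(n, 0, cfg$water_noise_g),
       yd = stats::rnorm(n, 0, cfg$water_noise_g),
       zd = cfg$landing_amp_g * sin(2 * pi * 6 * t) +
         stats::rnorm(n, 0, cfg$water_noise_g))
}

.seg_seize_takeoff <- function(n, cfg) {
  .seg_takeoff(n, cfg, peak_deg = cfg$seize_takeoff_pitch_deg)
}

# surface seizing: alternating landings and very short take-offs
.seg_surface_seizing <- function(n, cfg) {
  fs <- cfg$fs
  out_p <- numeric(0); out_x <- numeric(0); out_y <- numeric(0)
  out_z <- numeric(0)
  landing <- TRUE
  while (length(out_p) < n) {
    d <- if (landing) .rtnorm(1L, cfg$landing_s) else
      .rtnorm(1L, cfg$seize_takeoff_s)
    m <- max(2L, round(d * fs))
    sub <- if (landing) .seg_landing(m, cfg) else .seg_seize_takeoff(m, cfg)
    out_p <- c(out_p, sub$pitch_deg); out_x <- c(out_x, sub$xd)
    out_y <- c(out_y, sub$yd); out_z <- c(out_z, sub$zd)
    landing <- !landing
  }
  list(pitch_deg = out_p[seq_len(n)], xd = out_x[seq_len(n)],
       yd = out_y[seq_len(n)], zd = out_z[seq_len(n)])
}

#' Generate a labelled tri-axial acceleration record from a script
#'
#' Renders each scripted behaviour segment with its signal template (4 Hz
#' flapping with interleaved glides for flight, >5 Hz flapping with an
#' upward pitch ramp for take-off, steep down-then-up pitch for dives,
#' alternating landing/take-off pitch oscillations for surface seizing,
#' low-motion noise for rest), keeps the static channel consistent with
#' pitch (`x_S = sin(pitch)`, `z_S = cos(pitch)`), and returns the signal
#' together with the exact ground-truth ethogram. Deterministic for a fixed
#' seed.
#'
#' @param script Data frame with columns `label` and `duration_s`.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return List with `series` (an [accel_series()]) and `ethogram` (the
#'   ground truth, boundaries snapped to the sample grid).
#' @export
synth_accel <- function(script, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("label", "duration_s") %in% names(script)),
            all(script$duration_s > 0),
            all(script$label %in% behaviour_levels()))
  fs <- config$fs
  bounds <- round(cumsum(c(0, script$duration_s)) * fs)
  ns <- diff(bounds)
  pieces <- vector("list", nrow(script))
  for (i in seq_len(nrow(script))) {
    n <- ns[i]
    if (n < 2L) n <- 2L
    pieces[[i]] <- switch(script$label[i],
      rest = .seg_rest(n, config),
      flight = .seg_flight(n, config),
      take_off = .seg_takeoff(n, config),
      foraging_dive = .seg_dive(n, config),
      surface_seizing = .seg_surface_seizing(n, config),
      unknown = .seg_rest(n, config))
    if (ns[i] < 2L)  # degenerate sliver: trim back to scripted length
      pieces[[i]] <- lapply(pieces[[i]], function(v) v[seq_len(ns[i])])
  }
  pitch <- unlist(lapply(pieces, `[[`, "pitch_deg"), use.names = FALSE) +
    config$mount_pitch_offset_deg
  xd <- unlist(lapply(pieces, `[[`, "xd"), use.names = FALSE)
  yd <- unlist(lapply(pieces, `[[`, "yd"), use.names = FALSE)
  zd <- unlist(lapply(pieces, `[[`, "zd"), use.names = FALSE)
  pr <- pitch * pi / 180
  series <- accel_series(x = sin(pr) + xd, y = yd, z = cos(pr) + zd,
                         fs = fs, tag_kind = config$tag_kind)
  keep <- ns > 0
  eth <- ethogram(bounds[-length(bounds)][keep] / fs,
                  bounds[-1L][keep] / fs, script$label[keep], sort = FALSE)
  list(series = series, ethogram = eth)
}

#' Build a two-hour validation-style behaviour script
#'
#' Emulates the structure of a chest-mounted video-tag recording: repeated
#' blocks of rest, a pre-flight take-off, long flight with interleaved
#' glides, a surface-seizing bout, a short flight, a foraging dive and more
#' flight. Block lengths are drawn from the generator's duration
#' distributions; the script fills `duration_s` exactly.
#'
#' @param duration_s Total script length in seconds (default 7200).
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return Data frame (`label`, `duration_s`) suitable for [synth_accel()].
#' @export
synth_validation_script <- function(duration_s = 7200,
                                    config = generator_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- character(); dur <- numeric()
  add <- function(l, d) { lab <<- c(lab, l); dur <<- c(dur, d) }
  total <- function() sum(dur)
  add("rest", stats::runif(1, 120, 240))
  while (total() < duration_s) {
    add("take_off", .rtnorm(1L, config$preflight_takeoff_s))
    add("flight", stats::runif(1, 480, 660))
    add("surface_seizing", stats::runif(1, 15, 40))
    add("flight", stats::runif(1, 10, 20))
    add("foraging_dive", .rtnorm(1L, config$dive_duration_s))
    add("flight", stats::runif(1, 120, 240))
    add("rest", stats::runif(1, 180, 300))
  }
  # trim the overshoot off the final segments
  over <- total() - duration_s
  while (over > 0 && length(dur)) {
    excess <- min(over, dur[length(dur)] - 1)
    if (dur[length(dur)] - over < 1) {
      over <- over - dur[length(dur)]
      dur <- dur[-length(dur)]; lab <- lab[-length(lab)]
    } else {
      dur[length(dur)] <- dur[length(dur)] - over
      over <- 0
    }
  }
  if (total() < duration_s) add("rest", duration_s - total())
  data.frame(label = lab, duration_s = dur, stringsAsFactors = FALSE)
}

# one at-sea activity cycle for deployment days; foraging is flanked by
# on-water rest (birds land, sit-and-wait, forage, then rest before the
# next take-off), which also keeps foraging-time track speeds low
.deployment_cycle <- function(config) {
  data.frame(
    label = c("take_off", "flight", "rest", "surface_seizing", "rest",
              "foraging_dive", "rest", "take_off", "flight", "rest"),
    duration_s = c(.rtnorm(1L, config$preflight_takeoff_s),
                   stats::runif(1, 800, 1000),
                   stats::runif(1, 35, 50),
                   stats::runif(1, 15, 40),
                   stats::runif(1, 35, 50),
                   .rtnorm(1L, config$dive_duration_s),
                   stats::runif(1, 35, 50),
                   .rtnorm(1L, config$preflight_takeoff_s),
                   stats::runif(1, 700, 900),
                   stats::runif(1, 1300, 1700)),
    stringsAsFactors = FALSE)
}

# fill [0, len_s) with at-sea cycles, trimming the last segment
.fill_cycles <- function(len_s, config) {
  lab <- character(); dur <- numeric()
  while (sum(dur) < len_s) {
    cyc <- .deployment_cycle(config)
    for (i in seq_len(nrow(cyc))) {
      remaining <- len_s - sum(dur)
      if (remaining <= 0) break
      lab <- c(lab, cyc$label[i])
      dur <- c(dur, min(cyc$duration_s[i], remaining))
    }
  }
  data.frame(label = lab, duration_s = dur, stringsAsFactors = FALSE)
}

#' Generate a multi-day labelled deployment with a GPS track
#'
#' Builds a day-resolved behaviour script (departures at 06:00, returns at
#' 22:00 local, rest at the colony between trips), a ground-truth ethogram,
#' and a GPS track with one fix every `fix_interval_s` seconds whose speeds
#' are consistent with behaviour (transit ~40 km/h, foraging ~5 km/h, rest
#' ~1 km/h drift). Each foraging trip heads out along a random bearing and
#' retraces to the colony, so trip segmentation can recover the scripted
#' trips exactly. Record start is local midnight (UTC+9).
#'
#' @param trip_days Integer vector of scripted trip durations in days;
#'   trips run on consecutive days (deployment length is `sum(trip_days)`
#'   days).
#' @param config A [generator_config()].
#' @param seed Optional integer seed (one RNG stream drives script, signal
#'   and track).
#' @param fix_interval_s GPS fix interval in seconds (default 5).
#' @param colony `c(lat, lon)` of the nest colony (default Sanriku-coast
#'   study site).
#' @param generate_accel Also render the acceleration signal (default
#'   `FALSE`; multi-day records are large).
#' @return List with `script` (including an `at_sea` flag), `ethogram`,
#'   `gps` (a `gps_track`), `trips` (scripted trip table with
#'   `duration_days` and `category`), `target_budget` (scripted per-day
#'   seconds and fractions per functional category, plus scripted event
#'   counts), `t0`, `colony`, and `series` (`NULL` unless
#'   `generate_accel`).
#' @export
synth_deployment <- function(trip_days = c(1, 4, 2, 3),
                             config = generator_config(), seed = NULL,
                             fix_interval_s = 5,
                             colony = c(39.40, 141.99),
                             generate_accel = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(trip_days >= 1))
  n_days <- sum(trip_days)
  depart_s <- 6 * 3600; return_s <- 22 * 3600
  # assign each calendar day to a trip (consecutive)
  trip_of_day <- rep(seq_along(trip_days), trip_days)
  day_in_trip <- unlist(lapply(trip_days, seq_len))
  lab <- character(); dur <- numeric(); at_sea <- logical()
  add <- function(df, sea) {
    lab <<- c(lab, df$label); dur <<- c(dur, df$duration_s)
    at_sea <<- c(at_sea, rep(sea, nrow(df)))
  }
  for (d in seq_len(n_days)) {
    first <- day_in_trip[d] == 1L
    last <- day_in_trip[d] == trip_days[trip_of_day[d]]
    sea_from <- if (first) depart_s else 0
    sea_to <- if (last) return_s else 86400
    if (sea_from > 0)
      add(data.frame(label = "rest", duration_s = sea_from), FALSE)
    add(.fill_cycles(sea_to - sea_from, config), TRUE)
    if (sea_to < 86400)
      add(data.frame(label = "rest", duration_s = 86400 - sea_to), FALSE)
  }
  script <- data.frame(label = lab, duration_s = dur, at_sea = at_sea,
                       stringsAsFactors = FALSE)
  bounds <- cumsum(c(0, script$duration_s))
  eth <- ethogram(bounds[-length(bounds)], bounds[-1L], script$label,
                  sort = FALSE)
  t0 <- as.POSIXct("2018-08-19 15:00:00", tz = "UTC")  # local midnight UTC+9

  # scripted per-day budget (segments never cross midnight by construction)
  cat_of <- c(flight = "transit", take_off = "transit",
              surface_seizing = "forage", foraging_dive = "forage",
              rest = "rest", unknown = "unknown")
  seg_day <- findInterval(bounds[-length(bounds)], (0:n_days) * 86400)
  tb <- lapply(seq_len(n_days), function(d) {
    sel <- seg_day == d
    secs <- vapply(c("forage", "transit", "rest", "unknown"), function(cc)
      sum(script$duration_s[sel][cat_of[script$label[sel]] == cc]),
      numeric(1))
    data.frame(day = d, forage_s = secs[["forage"]],
               transit_s = secs[["transit"]], rest_s = secs[["rest"]],
               unknown_s = secs[["unknown"]],
               forage_frac = secs[["forage"]] / 86400,
               transit_frac = secs[["transit"]] / 86400,
               rest_frac = secs[["rest"]] / 86400,
               unknown_frac = secs[["unknown"]] / 86400,
               n_seizing = sum(sel & script$label == "surface_seizing"),
               n_dives = sum(sel & script$label == "foraging_dive"))
  })
  target_budget <- do.call(rbind, tb)

  # ---- GPS track -------------------------------------------------------
  fix_t <- seq(0, n_days * 86400 - fix_interval_s, by = fix_interval_s)
  seg_ix <- findInterval(fix_t + 1e-9, bounds[-length(bounds)])
  fix_lab <- script$label[seg_ix]
  fix_sea <- script$at_sea[seg_ix]
  speed_map <- c(flight = 40, take_off = 40, surface_seizing = 5,
                 foraging_dive = 5, rest = 1, unknown = 1)
  step_m <- speed_map[fix_lab] / 3.6 * fix_interval_s
  dx <- numeric(length(fix_t)); dy <- numeric(length(fix_t))
  # at-sea spans, one per trip: head out, retrace home along one bearing
  sea_r <- rle(fix_sea)
  ends <- cumsum(sea_r$lengths); starts <- ends - sea_r$lengths + 1L
  for (k in which(sea_r$values)) {
    ix <- starts[k]:ends[k]
    mid_t <- (fix_t[ix[1L]] + fix_t[ix[length(ix)]]) / 2
    sign_k <- ifelse(fix_t[ix] < mid_t, 1, -1)
    s_out <- sum(step_m[ix][sign_k > 0]); s_in <- sum(step_m[ix][sign_k < 0])
    scale_in <- if (s_in > 0) s_out / s_in else 1
    steps <- step_m[ix] * ifelse(sign_k > 0, 1, -scale_in)
    dist <- cumsum(steps)
    theta <- stats::runif(1, 0, 2 * pi)
    dx[ix] <- dist * sin(theta)
    dy[ix] <- dist * cos(theta)
  }
  dx <- dx + stats::rnorm(length(fix_t), 0, 3)
  dy <- dy + stats::rnorm(length(fix_t), 0, 3)
  lat <- colony[1L] + dy / 111320
  lon <- colony[2L] + dx / (111320 * cos(colony[1L] * pi / 180))
  gps <- gps_track(data.frame(time = t0 + fix_t, lat = lat, lon = lon))
  gps$true_behaviour <- fix_lab

  series <- NULL
  if (generate_accel) {
    sa <- synth_accel(script[, c("label", "duration_s")], config)
    series <- sa$series
    eth <- sa$ethogram
  }
  trips <- data.frame(trip = seq_along(trip_days),
                      duration_days = as.integer(trip_days),
                      category = ifelse(trip_days > 2, "long", "short"))
  list(script = script, ethogram = eth, gps = gps, trips = trips,
       target_budget = target_budget, t0 = t0, colony = colony,
       series = series)
}
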