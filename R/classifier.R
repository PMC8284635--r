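#' Detect individual flaps
#'
#' A flap is a local maximum of dynamic dorsoventral acceleration followed
#' by a local minimum whose peak-trough difference is at least the
#' calibrated flap threshold (boundary inclusive).
#'
#' @param decomposed An `accel_decomposed`.
#' @param profile A `calibration_profile` (only `flap_threshold_g` is used),
#'   or a single numeric threshold in g.
#' @return Data frame of flap events: `peak_index`, `trough_index`,
#'   `amplitude_g`, `start_s`, `end_s`.
#' @export
detect_flaps <- function(decomposed, profile) {
  stopifnot(inherits(decomposed, "accel_decomposed"))
  thr <- if (is.numeric(profile)) profile else profile$flap_threshold_g
  fs <- decomposed$fs
  dd <- extremum_diffs(decomposed$dynamic$z)
  dd <- dd[dd$kind1 == "max" & dd$diff >= thr, , drop = FALSE]
  data.frame(peak_index = dd$i1, trough_index = dd$i2,
             amplitude_g = dd$diff, start_s = (dd$i1 - 1L) / fs,
             end_s = (dd$i2 - 1L) / fs)
}

#' Group flaps into flapping bouts and flight intervals
#'
#' Two-level agglomeration: flaps separated by less than `intra_bout_gap_s`
#' form a flapping bout; bouts separated by at most `inter_bout_gap_s` form
#' one flight interval, so glides between bouts are counted as flight.
#'
#' @param flaps Flap events from [detect_flaps()] (time-sorted).
#' @param intra_bout_gap_s Maximum gap within a bout, exclusive (default
#'   0.5 s).
#' @param inter_bout_gap_s Maximum gap between bouts within one flight,
#'   inclusive (default 30 s).
#' @return Data frame of flight intervals (`start_s`, `end_s`).
#' @export
group_flight <- function(flaps, intra_bout_gap_s = 0.5,
                         inter_bout_gap_s = 30) {
  if (!nrow(flaps))
    return(data.frame(start_s = numeric(), end_s = numeric()))
  bouts <- .chain_intervals(flaps$start_s, flaps$end_s,
                            gap = intra_bout_gap_s, inclusive = FALSE)
  .chain_intervals(bouts$start_s, bouts$end_s, gap = inter_bout_gap_s,
                   inclusive = TRUE)
}

#' Large pitch-change events
#'
#' Successive local pitch extrema whose absolute difference reaches the
#' calibrated large-pitch-change threshold. An event's time is the time of
#' the first extremum of the pair, its origin pitch the value there, and
#' its direction `"up"` when pitch increases across the pair.
#'
#' @param pitchseries A `pitch_series`.
#' @param profile A `calibration_profile` (uses `large_pitch_change_deg`) or
#'   a single numeric threshold in degrees.
#' @return Data frame of events: `time_s`, `end_s`, `magnitude_deg`,
#'   `direction`, `origin_pitch_deg`.
#' @export
pitch_change_events <- function(pitchseries, profile) {
  stopifnot(inherits(pitchseries, "pitch_series"))
  thr <- if (is.numeric(profile)) profile else profile$large_pitch_change_deg
  fs <- pitchseries$fs
  dd <- extremum_diffs(pitchseries$pitch_deg)
  dd <- dd[dd$diff >= thr, , drop = FALSE]
  data.frame(time_s = (dd$i1 - 1L) / fs, end_s = (dd$i2 - 1L) / fs,
             magnitude_deg = dd$diff,
             direction = ifelse(dd$v2 > dd$v1, "up", "down"),
             origin_pitch_deg = dd$v1)
}

#' Detect take-offs at flight-interval onsets
#'
#' Flight onsets coinciding (within `search_window_s`) with a large upward
#' pitch change are marked as take-offs. For back-mounted tags, upward
#' events originating above the median of the per-PFM minimum pitch values
#' are discarded first: a back-mounted tag rides higher on the body, and
#' such events reflect posture changes rather than take-off rotations.
#'
#' @param flights Flight intervals from [group_flight()].
#' @param events Pitch-change events from [pitch_change_events()].
#' @param profile A `calibration_profile` (`tag_kind`,
#'   `pfm_pitch_min_med_deg`).
#' @param search_window_s Half-width of the onset search window (default 2).
#' @param pitchseries Optional `pitch_series`; when supplied, a take-off
#'   runs until the first pitch extremum after the upward event (the bird
#'   levelling off into cruising flight), otherwise until the event end or
#'   the flight onset, whichever is later.
#' @return Data frame of take-off intervals (`start_s`, `end_s`), one at
#'   most per flight onset.
#' @export
detect_takeoffs <- function(flights, events, profile,
                            search_window_s = 2, pitchseries = NULL) {
  up <- events[events$direction == "up", , drop = FALSE]
  if (identical(profile$tag_kind, "back_mounted"))
    up <- up[up$origin_pitch_deg <= profile$pfm_pitch_min_med_deg, ,
             drop = FALSE]
  ex_t <- NULL
  if (!is.null(pitchseries)) {
    ex <- local_extrema(pitchseries$pitch_deg)
    ex_t <- (ex$index - 1L) / pitchseries$fs
  }
  out <- list(); k <- 0L
  for (i in seq_len(nrow(flights))) {
    t0 <- flights$start_s[i]
    hit <- which(abs(up$time_s - t0) <= search_window_s)
    if (length(hit)) {
      ev <- up[hit[1L], ]
      end <- max(ev$end_s, t0)
      if (!is.null(ex_t)) {
        nxt <- ex_t[ex_t > ev$end_s + 1e-9]
        if (length(nxt)) end <- max(end, nxt[1L])
      }
      k <- k + 1L
      out[[k]] <- data.frame(start_s = min(ev$time_s, t0), end_s = end)
    }
  }
  if (!k) return(data.frame(start_s = numeric(), end_s = numeric()))
  do.call(rbind, out)
}

#' Group pitch-change events into candidate foraging bouts
#'
#' Chain grouping: successive events no more than `group_window_s` apart
#' (start-to-start) share a group. The default window is the mean foraging
#' bout duration observed on video (23.3 s).
#'
#' @param events Pitch-change events, time-sorted.
#' @param group_window_s Chaining window in seconds (default 23.3).
#' @return List of data frames, one per group (subsets of `events`).
#' @export
group_pitch_events <- function(events, group_window_s = 23.3) {
  if (!nrow(events)) return(list())
  gid <- cumsum(c(1, as.integer(diff(events$time_s) > group_window_s)))
  unname(split(events, gid))
}

#' Detect foraging dives within an event group
#'
#' A dive requires pitch to drop below the descent threshold (median of
#' per-PFM minimum pitch minus `descent_offset_deg`), followed within
#' `ascent_window_s` by pitch exceeding the ascent threshold (median of
#' per-PFM mean pitch plus twice the median per-PFM pitch variance). The
#' dive interval spans the descent crossing to the ascent crossing.
#'
#' @param group Data frame of pitch-change events forming one group.
#' @param pitchseries A `pitch_series`.
#' @param profile A `calibration_profile`.
#' @param ascent_window_s Maximum descent-to-ascent delay (default 10 s).
#' @param descent_offset_deg Offset below the PFM minimum-pitch median
#'   (default 30).
#' @return Data frame of dive intervals (`start_s`, `end_s`).
#' @export
classify_dives <- function(group, pitchseries, profile,
                           ascent_window_s = 10, descent_offset_deg = 30) {
  stopifnot(inherits(pitchseries, "pitch_series"))
  fs <- pitchseries$fs
  p <- pitchseries$pitch_deg
  n <- length(p)
  desc_thr <- profile$pfm_pitch_min_med_deg - descent_offset_deg
  asc_thr <- profile$pfm_pitch_mean_med_deg +
    2 * profile$pfm_pitch_var_med_deg2
  lo <- max(1L, floor(min(group$time_s) * fs) + 1L)
  hi <- min(n, ceiling((max(group$end_s) + ascent_window_s) * fs) + 1L)
  win <- max(1L, round(ascent_window_s * fs))
  out <- list(); k <- 0L
  i <- lo
  while (i <= hi) {
    if (p[i] < desc_thr) {
      jmax <- min(n, i + win)
      above <- which(p[(i + 1L):jmax] > asc_thr)
      if (length(above)) {
        j <- i + above[1L]
        k <- k + 1L
        out[[k]] <- data.frame(start_s = (i - 1L) / fs,
                               end_s = (j - 1L) / fs)
        i <- j + 1L
        next
      }
      # skip past this sub-threshold run: no qualifying ascent
      run_end <- i
      while (run_end < hi && p[run_end + 1L] < desc_thr)
        run_end <- run_end + 1L
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!k) return(data.frame(start_s = numeric(), end_s = numeric()))
  do.call(rbind, out)
}

#' Detect surface seizing within an event group
#'
#' After dives are removed, a run of at least `min_events` large pitch
#' changes with successive gaps of at most `burst_gap_s` marks surface
#' seizing — the rapid alternation of landings and take-offs at the water
#' surface. Groups without such a run remain unknown. The default reads
#' "within 2 seconds of one another" as a successive-gap chain; set
#' `rule = "all_pairs"` to require every pair of the run within the gap.
#'
#' @param group Data frame of pitch-change events forming one group.
#' @param dives Dive intervals already extracted from this group (their
#'   events are discarded before the chain is re-evaluated).
#' @param burst_gap_s Maximum successive gap (default 2 s).
#' @param min_events Minimum run length (default 3).
#' @param rule `"chain"` (default) or `"all_pairs"`.
#' @return Data frame of surface-seizing intervals (`start_s`, `end_s`);
#'   zero rows when the group holds no qualifying run.
#' @export
classify_surface_seizing <- function(group, dives = NULL, burst_gap_s = 2,
                                     min_events = 3, rule = c("chain", "all_pairs")) {
  rule <- match.arg(rule)
  ev <- group
  if (!is.null(dives) && nrow(dives)) {
    in_dive <- vapply(ev$time_s, function(t)
      any(t >= dives$start_s & t < dives$end_s), logical(1))
    ev <- ev[!in_dive, , drop = FALSE]
  }
  if (nrow(ev) < min_events)
    return(data.frame(start_s = numeric(), end_s = numeric()))
  gid <- cumsum(c(1, as.integer(diff(ev$time_s) > burst_gap_s)))
  out <- list(); k <- 0L
  for (g in split(ev, gid)) {
    ok <- nrow(g) >= min_events
    if (ok && rule == "all_pairs")
      ok <- (max(g$time_s) - min(g$time_s)) <= burst_gap_s
    if (ok) {
      k <- k + 1L
      out[[k]] <- data.frame(start_s = min(g$time_s), end_s = max(g$end_s))
    }
  }
  if (!k) return(data.frame(start_s = numeric(), end_s = numeric()))
  do.call(rbind, out)
}

#' Detect rest from the ODBA moving average
#'
#' Maximal runs where the 10-second ODBA moving average stays below the
#' rest threshold. Samples claimed by flight or foraging take precedence at
#' assembly.
#'
#' @param odbaseries An `odba_series` from [odba()].
#' @param threshold_g Rest threshold in g (default 0.2, strict `<`).
#' @return Data frame of rest intervals (`start_s`, `end_s`).
#' @export
classify_rest <- function(odbaseries, threshold_g = 0.2) {
  stopifnot(inherits(odbaseries, "odba_series"))
  fs <- odbaseries$fs
  below <- odbaseries$odmn < threshold_g
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}

#' Assemble detections into a single ethogram
#'
#' Paints all detections onto a per-sample timeline with precedence
#' `foraging_dive > surface_seizing > take_off > flight > rest > unknown`
#' (foraging dives are identified first and always win), then collapses
#' runs into half-open intervals. Every sample receives a label, so the
#' result partitions the record exactly.
#'
#' @param n_samples Record length in samples.
#' @param fs Sampling rate in Hz.
#' @param flights,takeoffs,seizings,dives,rests Interval data frames
#'   (`start_s`, `end_s`); any may be `NULL` or empty.
#' @return An `ethogram` covering `[0, n_samples / fs)`.
#' @export
assemble_ethogram <- function(n_samples, fs, flights = NULL,
                              takeoffs = NULL, seizings = NULL,
                              dives = NULL, rests = NULL) {
  lab <- rep.int(1L, n_samples)  # unknown
  paint <- function(lab, ints, code) {
    if (is.null(ints) || !nrow(ints)) return(lab)
    for (i in seq_len(nrow(ints))) {
      i1 <- max(1L, floor(ints$start_s[i] * fs + 1e-9) + 1L)
      i2 <- min(n_samples, ceiling(ints$end_s[i] * fs - 1e-9))
      if (i2 >= i1) lab[i1:i2] <- code
    }
    lab
  }
  lv <- behaviour_levels()
  lab <- paint(lab, rests, match("rest", lv))
  lab <- paint(lab, flights, match("flight", lv))
  lab <- paint(lab, takeoffs, match("take_off", lv))
  lab <- paint(lab, seizings, match("surface_seizing", lv))
  lab <- paint(lab, dives, match("foraging_dive", lv))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ethogram((starts - 1L) / fs, ends / fs, lv[r$values], sort = FALSE)
}

#' Classify behaviour from a tri-axial acceleration record
#'
#' Full pipeline: static/dynamic decomposition, pitch and ODBA derivation,
#' per-tag calibration (unless a profile is supplied), flap and
#' pitch-change event detection, flight/take-off/dive/surface-seizing/rest
#' classification, and assembly into one non-overlapping ethogram.
#'
#' @param series An [accel_series()].
#' @param profile Optional pre-computed `calibration_profile`; when `NULL`
#'   the tag is calibrated from its own record via [calibrate_tag()].
#' @param config Configuration list, see [default_config()].
#' @return List of class `behaviour_classification`: `ethogram`, `profile`,
#'   and `details` (flights, take-offs, dives, seizings, rests, events).
#' @export
classify_behaviour <- function(series, profile = NULL,
                               config = default_config()) {
  stopifnot(inherits(series, "accel_series"))
  dec <- decompose_accel(series, config$lowpass_cutoff_hz,
                         config$filter_order, config$zero_phase)
  if (is.null(profile)) profile <- calibrate_tag(series, config = config)
  pit <- pitch_angle(dec)
  od <- odba(dec, config$odba_window_s)

  flaps <- detect_flaps(dec, profile)
  flights <- group_flight(flaps, config$intra_bout_gap_s,
                          config$inter_bout_gap_s)
  events <- pitch_change_events(pit, profile)
  takeoffs <- detect_takeoffs(flights, events, profile,
                              config$takeoff_search_window_s, pit)
  groups <- group_pitch_events(events, config$pitch_group_window_s)
  dives <- list(); seizes <- list()
  for (g in groups) {
    d <- classify_dives(g, pit, profile, config$dive_ascent_window_s,
                        config$dive_descent_offset_deg)
    s <- classify_surface_seizing(g, d, config$seize_burst_gap_s,
                                  config$seize_min_events,
                                  config$seize_chain_rule)
    dives[[length(dives) + 1L]] <- d
    seizes[[length(seizes) + 1L]] <- s
  }
  dives <- if (length(dives)) do.call(rbind, dives) else NULL
  seizes <- if (length(seizes)) do.call(rbind, seizes) else NULL
  rests <- classify_rest(od, config$rest_threshold_g)
  eth <- assemble_ethogram(length(series$x), series$fs, flights, takeoffs,
                           seizes, dives, rests)
  structure(list(ethogram = eth, profile = profile,
                 details = list(flaps = flaps, flights = flights,
                                takeoffs = takeoffs, dives = dives,
                                seizings = seizes, rests = rests,
                                pitch_events = events)),
            class = "behaviour_classification")
}

#' @export
print.behaviour_classification <- function(x, ...) {
  d <- label_durations(x$ethogram)
  cat("<behaviour_classification>\n")
  for (b in names(d))
    cat(sprintf("  %-16s %8.1f s\n", b, d[[b]]))
  invisible(x)
}

# internal: chain intervals whose gap to the previous end is < gap
# (inclusive = FALSE) or <= gap (inclusive = TRUE)
.chain_intervals <- function(start_s, end_s, gap, inclusive) {
  n <- length(start_s)
  if (!n) return(data.frame(start_s = numeric(), end_s = numeric()))
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  gs <- start_s[1L]; cur_end <- end_s[1L]
  out <- list(); k <- 0L
  for (i in seq_len(n)[-1L]) {
    gap_i <- start_s[i] - cur_end
    joined <- if (inclusive) gap_i <= gap else gap_i < gap
    if (joined) {
      cur_end <- max(cur_end, end_s[i])
    } else {
      k <- k + 1L
      out[[k]] <- c(gs, cur_end)
      gs <- start_s[i]; cur_end <- end_s[i]
    }
  }
  out[[k + 1L]] <- c(gs, cur_end)
  m <- do.call(rbind, out)
  data.frame(start_s = m[, 1L], end_s = m[, 2L])
}
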