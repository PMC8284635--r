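#' Moving-window speeds from GPS fixes
#'
#' Speed at each fix is the geodesic (WGS84 ellipsoid) distance between the
#' first and last fix of a centred `window_fixes`-fix window divided by the
#' window's time span, in km/h. Windows shrink at the track edges. Using a
#' window rather than consecutive fixes damps GPS jitter.
#'
#' @param fixes A `gps_track` (time-sorted).
#' @param window_fixes Window size in fixes (default 5).
#' @return The track with a `speed_kph` column added/replaced.
#' @export
compute_speeds <- function(fixes, window_fixes = 5) {
  n <- nrow(fixes)
  if (n < 2L) stop("need at least 2 fixes to compute speeds")
  h1 <- (window_fixes - 1L) %/% 2L
  h2 <- window_fixes - 1L - h1
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  # keep a genuine span at the edges
  same <- lo == hi
  lo[same & lo > 1L] <- lo[same & lo > 1L] - 1L
  hi[same & hi < n] <- hi[same & hi < n] + 1L
  d <- geosphere::distGeo(cbind(fixes$lon[lo], fixes$lat[lo]),
                          cbind(fixes$lon[hi], fixes$lat[hi]))
  dt <- as.numeric(fixes$time[hi]) - as.numeric(fixes$time[lo])
  fixes$speed_kph <- ifelse(dt > 0, d / dt * 3.6, 0)
  fixes
}

#' Filter fixes near the colony or at unrealistic speeds
#'
#' Drops fixes within `radius_km` of the nest colony and fixes moving
#' faster than `max_speed_kph`. The two filters commute.
#'
#' @param fixes A `gps_track` with `speed_kph` (see [compute_speeds()]).
#' @param colony Numeric `c(lat, lon)` of the colony.
#' @param radius_km Colony exclusion radius in km (default 1.5, strict
#'   `<`).
#' @param max_speed_kph Speed ceiling in km/h (default 80, strict `>`
#'   removed).
#' @return The filtered track; an empty result raises a warning.
#' @export
filter_fixes <- function(fixes, colony, radius_km = 1.5,
                         max_speed_kph = 80) {
  d_km <- geosphere::distGeo(cbind(fixes$lon, fixes$lat),
                             c(colony[2L], colony[1L])) / 1000
  keep <- d_km >= radius_km
  if (!is.null(fixes$speed_kph))
    keep <- keep & !(fixes$speed_kph > max_speed_kph)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("empty track: all fixes filtered out")
  out
}

#' Assign foraging behaviours to GPS fixes
#'
#' A fix is labelled `surface_seizing` or `foraging_dive` when such an
#' ethogram interval lies within `window_s` of the fix time; the nearer
#' interval wins and dives win exact ties.
#'
#' @param fixes A `gps_track`.
#' @param eth An `ethogram` on the same clock (seconds relative to `t0`).
#' @param t0 Time of ethogram second 0; defaults to the first fix time.
#' @param window_s Assignment window in seconds (default 30).
#' @return The track with a `behaviour` column (`NA` where no foraging
#'   interval is near).
#' @export
assign_behaviour <- function(fixes, eth, t0 = NULL, window_s = 30) {
  if (is.null(t0)) t0 <- fixes$time[1L]
  ts <- as.numeric(fixes$time) - as.numeric(t0)
  dist_to <- function(ints) {
    if (!nrow(ints)) return(rep(Inf, length(ts)))
    vapply(ts, function(t)
      min(pmax(ints$start_s - t, t - ints$end_s, 0)), numeric(1))
  }
  d_dive <- dist_to(eth[eth$label == "foraging_dive", , drop = FALSE])
  d_seiz <- dist_to(eth[eth$label == "surface_seizing", , drop = FALSE])
  beh <- rep(NA_character_, length(ts))
  beh[d_seiz <= window_s] <- "surface_seizing"
  beh[d_dive <= window_s & d_dive <= d_seiz] <- "foraging_dive"
  fixes$behaviour <- beh
  fixes
}

#' Reclassify fast foraging fixes as flight
#'
#' Foraging-labelled fixes moving faster than `max_forage_speed_kph`
#' (strictly greater) are relabelled `flight`: a bird at such speeds is
#' airborne regardless of nearby foraging detections.
#'
#' @param fixes A `gps_track` with `behaviour` and `speed_kph`.
#' @param max_forage_speed_kph Threshold in km/h (default 15).
#' @return The track with `behaviour` updated.
#' @export
reclassify_fast_foraging <- function(fixes, max_forage_speed_kph = 15) {
  fast <- !is.na(fixes$behaviour) &
    fixes$behaviour %in% c("surface_seizing", "foraging_dive") &
    fixes$speed_kph > max_forage_speed_kph
  fixes$behaviour[fast] <- "flight"
  fixes
}

#' Remove implausibly short flight/unknown intervals
#'
#' Flight and unknown intervals shorter than `min_s` (strictly less) are
#' deleted; the freed time is absorbed into the preceding interval (the
#' following one at the record start) so the ethogram still partitions the
#' record.
#'
#' @param eth An `ethogram`.
#' @param min_s Minimum duration in seconds (default 5).
#' @return The pruned `ethogram`.
#' @export
prune_short_behaviours <- function(eth, min_s = 5) {
  stopifnot(inherits(eth, "ethogram"))
  repeat {
    short <- which(eth$label %in% c("flight", "unknown") &
                     (eth$end_s - eth$start_s) < min_s)
    if (!length(short) || nrow(eth) == 1L) break
    i <- short[1L]
    if (i > 1L) {
      eth$end_s[i - 1L] <- eth$end_s[i]
    } else {
      eth$start_s[i + 1L] <- eth$start_s[i]
    }
    eth <- eth[-i, , drop = FALSE]
    eth <- .merge_adjacent(ethogram(eth$start_s, eth$end_s, eth$label,
                                    sort = FALSE))
  }
  eth
}

#' Segment a track into foraging trips
#'
#' A trip is a maximal run of consecutive fixes outside the colony radius.
#' Trip duration is the ceiling of the elapsed time in days; trips longer
#' than 2 days are `long`, others `short`.
#'
#' @param fixes A `gps_track`.
#' @param colony Numeric `c(lat, lon)`.
#' @param radius_km Colony radius in km (default 1.5).
#' @return Data frame of trips: `start`, `end`, `duration_days`,
#'   `category`, `n_fixes`.
#' @export
segment_trips <- function(fixes, colony, radius_km = 1.5) {
  d_km <- geosphere::distGeo(cbind(fixes$lon, fixes$lat),
                             c(colony[2L], colony[1L])) / 1000
  out_col <- d_km >= radius_km
  r <- rle(out_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = fixes$time[0], end = fixes$time[0],
                      duration_days = integer(), category = character(),
                      n_fixes = integer()))
  st <- fixes$time[starts[keep]]
  en <- fixes$time[ends[keep]]
  days <- pmax(1L, ceiling((as.numeric(en) - as.numeric(st)) / 86400))
  data.frame(start = st, end = en, duration_days = as.integer(days),
             category = ifelse(days > 2, "long", "short"),
             n_fixes = ends[keep] - starts[keep] + 1L)
}

#' Daily activity budget from a classified ethogram
#'
#' Splits the ethogram at local midnights (configurable UTC offset) and
#' accumulates per-day durations and fractions of the functional
#' categories: foraging (surface seizing + dives), transit (flight +
#' take-offs), rest, and unknown, plus counts of surface-seizing events and
#' dives starting that day.
#'
#' @param eth An `ethogram`.
#' @param t0 Absolute time of ethogram second 0 (`POSIXct`); with the
#'   default `NULL` day boundaries fall at multiples of 86400 s from record
#'   start.
#' @param tz_offset_h Local-midnight offset from UTC in hours (default 9).
#' @return Data frame of class `activity_budget`: one row per day with
#'   `day`, seconds and fractions per category (`forage_s`, `transit_s`,
#'   `rest_s`, `unknown_s`, `forage_frac`, ...), `n_seizing`, `n_dives`.
#'   Fractions are of the labelled time in that day and sum to 1.
#' @export
daily_budget <- function(eth, t0 = NULL, tz_offset_h = 9) {
  stopifnot(inherits(eth, "ethogram"))
  cat_of <- c(flight = "transit", take_off = "transit",
              surface_seizing = "forage", foraging_dive = "forage",
              rest = "rest", unknown = "unknown")
  shift <- if (is.null(t0)) 0 else as.numeric(t0) + tz_offset_h * 3600
  # split every interval at day boundaries
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(eth))) {
    s <- eth$start_s[i]; e <- eth$end_s[i]
    d1 <- floor((s + shift) / 86400); d2 <- floor((e - 1e-9 + shift) / 86400)
    for (d in d1:d2) {
      cs <- max(s, d * 86400 - shift)
      ce <- min(e, (d + 1) * 86400 - shift)
      if (ce <= cs) next
      k <- k + 1L
      rows[[k]] <- data.frame(day = d, dur = ce - cs,
                              category = cat_of[[eth$label[i]]],
                              label = eth$label[i], start_day = d1)
    }
  }
  pieces <- do.call(rbind, rows)
  day0 <- min(pieces$day)
  pieces$day <- pieces$day - day0 + 1L
  pieces$start_day <- pieces$start_day - day0 + 1L
  days <- sort(unique(pieces$day))
  cats <- c("forage", "transit", "rest", "unknown")
  out <- lapply(days, function(d) {
    p <- pieces[pieces$day == d, , drop = FALSE]
    secs <- vapply(cats, function(cc) sum(p$dur[p$category == cc]),
                   numeric(1))
    tot <- sum(secs)
    # event counts: intervals of the behaviour that start on this day
    first <- pieces[pieces$start_day == d & pieces$day == d, , drop = FALSE]
    cbind(data.frame(day = d),
          as.data.frame(as.list(stats::setNames(secs, paste0(cats, "_s")))),
          as.data.frame(as.list(stats::setNames(secs / tot,
                                                paste0(cats, "_frac")))),
          data.frame(n_seizing = sum(first$label == "surface_seizing"),
                     n_dives = sum(first$label == "foraging_dive")))
  })
  out <- do.call(rbind, out)
  class(out) <- c("activity_budget", "data.frame")
  out
}
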