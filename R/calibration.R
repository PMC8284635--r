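#' Select predicted flight minutes (PFMs)
#'
#' Sums the per-frame flap-minus-takeoff band-energy difference in
#' one-minute moving windows (hop of one spectrogram frame) and greedily
#' picks the `n_pfm` windows with the greatest positive summed difference,
#' rejecting any candidate whose start lies within `min_separation_s` of an
#' already selected start. Ties are broken toward the earliest start, so the
#' selection is deterministic.
#'
#' @param bands A `band_energy_series` from [band_energy()].
#' @param n_pfm Number of windows to select.
#' @param min_separation_s Minimum start-to-start separation (default 300).
#' @param window_s Window length in seconds (default 60).
#' @return Data frame with columns `start_s`, `end_s` and `score` (summed
#'   band-energy difference), sorted by start time. If fewer than `n_pfm`
#'   eligible windows exist, the result carries attribute
#'   `insufficient = TRUE` and a warning is raised.
#' @export
select_pfms <- function(bands, n_pfm, min_separation_s = 300,
                        window_s = 60) {
  stopifnot(inherits(bands, "band_energy_series"))
  ft <- bands$frame_times
  record_end <- ft[length(ft)] + bands$frame_step_s
  cand <- which(ft + window_s <= record_end + 1e-9)
  if (!length(cand)) stop("record shorter than one PFM window")
  # windowed sums of frame diffs via cumulative sums
  cs <- c(0, cumsum(bands$diff))
  hi <- findInterval(ft[cand] + window_s - 1e-9, ft)
  score <- cs[hi + 1L] - cs[cand]
  o <- cand[order(-score, ft[cand])]
  sel <- integer()
  for (i in o) {
    if (length(sel) >= n_pfm) break
    if (all(abs(ft[i] - ft[sel]) >= min_separation_s)) sel <- c(sel, i)
  }
  insufficient <- length(sel) < n_pfm
  if (insufficient)
    warning("only ", length(sel), " of ", n_pfm,
            " PFM windows could be selected")
  sel <- sel[order(ft[sel])]
  out <- data.frame(start_s = ft[sel], end_s = ft[sel] + window_s,
                    score = (cs[findInterval(ft[sel] + window_s - 1e-9, ft) + 1L] -
                               cs[sel]))
  attr(out, "insufficient") <- insufficient
  out
}

#' Trough of a bimodal kernel density estimate
#'
#' Fits a Gaussian KDE (normal-reference bandwidth) to a sample, locates its
#' modes, and returns the abscissa of the density minimum between the two
#' largest modes. Used to split flap from glide peak-trough amplitudes,
#' whose distribution during flight is strongly bimodal.
#'
#' @param values Numeric sample (length >= 5).
#' @param n_grid KDE evaluation grid size (default 512).
#' @return List with `trough` (abscissa of the inter-mode density minimum),
#'   `modes` (data frame of mode abscissae/heights, tallest first) and
#'   `n_modes`. `trough` is `NA` when the density is unimodal. More than two
#'   modes raises a warning; the trough is still taken between the two
#'   tallest.
#' @export
kde_trough <- function(values, n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 values for a KDE")
  d <- stats::density(values, bw = "nrd0", n = n_grid)
  y <- d$y
  m <- length(y)
  is_mode <- c(FALSE, y[2:(m - 1L)] > y[1:(m - 2L)] &
                 y[2:(m - 1L)] >= y[3:m], FALSE)
  mi <- which(is_mode)
  modes <- data.frame(x = d$x[mi], height = y[mi])
  modes <- modes[order(-modes$height), , drop = FALSE]
  if (nrow(modes) < 2L)
    return(list(trough = NA_real_, modes = modes, n_modes = nrow(modes)))
  if (nrow(modes) > 2L)
    warning("density has ", nrow(modes), " modes; using the two largest")
  lo <- min(modes$x[1:2]); hi <- max(modes$x[1:2])
  between <- which(d$x > lo & d$x < hi)
  trough <- d$x[between[which.min(y[between])]]  # which.min: lowest abscissa on ties
  list(trough = trough, modes = modes, n_modes = nrow(modes))
}

#' Flap-amplitude threshold from PFMs
#'
#' Within each predicted flight minute, computes the absolute differences
#' between successive local extrema of dynamic dorsoventral acceleration,
#' fits a KDE, and takes the trough between the flap and glide modes; the
#' per-tag threshold is the median of the per-PFM troughs. PFMs whose
#' amplitude distribution is unimodal are skipped.
#'
#' @param decomposed An `accel_decomposed`.
#' @param pfms Data frame of PFM windows (`start_s`, `end_s`).
#' @return Threshold in g (`flap_threshold_g`).
#' @export
flap_threshold <- function(decomposed, pfms) {
  stopifnot(inherits(decomposed, "accel_decomposed"))
  fs <- decomposed$fs
  troughs <- numeric()
  for (i in seq_len(nrow(pfms))) {
    seg <- .window_slice(decomposed$dynamic$z, pfms$start_s[i],
                         pfms$end_s[i], fs)
    if (length(seg) < 3L) next
    dd <- extremum_diffs(seg)
    if (nrow(dd) < 5L) next
    kt <- suppressWarnings(kde_trough(dd$diff))
    if (!is.na(kt$trough)) troughs <- c(troughs, kt$trough)
  }
  if (!length(troughs))
    stop("calibration error: no PFM produced a bimodal amplitude density")
  stats::median(troughs)
}

#' PFM pitch statistics and large-pitch-change threshold
#'
#' Per PFM computes (a) the maximum absolute difference between successive
#' local pitch extrema, (b) the minimum pitch, (c) the mean pitch, and
#' (d) the population pitch variance. Returns `1.5 x median(a)` as the
#' large-pitch-change threshold together with the medians of (b)-(d), which
#' parameterise the dive rules.
#'
#' @param pitchseries A `pitch_series` from [pitch_angle()].
#' @param pfms Data frame of PFM windows (`start_s`, `end_s`).
#' @return List with `large_pitch_change_deg`, `pfm_pitch_min_med_deg`,
#'   `pfm_pitch_mean_med_deg`, `pfm_pitch_var_med_deg2`.
#' @export
pitch_statistics <- function(pitchseries, pfms) {
  stopifnot(inherits(pitchseries, "pitch_series"))
  if (!nrow(pfms)) stop("calibration error: no PFM windows supplied")
  fs <- pitchseries$fs
  maxdiff <- numeric(); pmin_ <- numeric(); pmean <- numeric()
  pvar <- numeric()
  for (i in seq_len(nrow(pfms))) {
    seg <- .window_slice(pitchseries$pitch_deg, pfms$start_s[i],
                         pfms$end_s[i], fs)
    if (!length(seg)) next
    n <- length(seg)
    pmin_ <- c(pmin_, min(seg))
    pmean <- c(pmean, mean(seg))
    pvar <- c(pvar, sum((seg - mean(seg))^2) / n)  # population variance
    dd <- if (n >= 3L) extremum_diffs(seg) else NULL
    if (!is.null(dd) && nrow(dd) >= 1L) {
      maxdiff <- c(maxdiff, max(dd$diff))
    } else {
      warning("PFM ", i, " has fewer than 2 pitch extrema; skipped for the ",
              "pitch-change threshold")
    }
  }
  if (!length(maxdiff))
    stop("calibration error: no PFM contained 2+ pitch extrema; ",
         "large pitch change threshold undefined")
  list(large_pitch_change_deg = 1.5 * stats::median(maxdiff),
       pfm_pitch_min_med_deg = stats::median(pmin_),
       pfm_pitch_mean_med_deg = stats::median(pmean),
       pfm_pitch_var_med_deg2 = stats::median(pvar))
}

#' Pool large-pitch-change thresholds across chest-mounted tags
#'
#' Chest-mounted video tags record for only a couple of hours each, so the
#' per-tag pitch-change threshold is replaced by the median across all
#' chest-mounted calibration profiles.
#'
#' @param profiles List of `calibration_profile` objects.
#' @return Pooled threshold in degrees (median; even counts use the mean of
#'   the central pair, the standard median convention).
#' @export
pool_dvl_pitch_threshold <- function(profiles) {
  if (!length(profiles)) stop("no calibration profiles supplied")
  th <- vapply(profiles, function(p) p$large_pitch_change_deg, numeric(1))
  stats::median(th)
}

#' Calibrate a tag from its acceleration record
#'
#' Runs the full per-tag calibration: spectrogram band energies, PFM
#' selection, flap-amplitude threshold and PFM pitch statistics.
#'
#' @param series An [accel_series()].
#' @param n_pfm Number of PFMs; `NULL` (default) uses 10 for chest-mounted
#'   tags and 20 per recorded calendar day (proportionally fewer, rounded
#'   up, for a final partial day) for back-mounted tags.
#' @param config Configuration list, see [default_config()].
#' @return Object of class `calibration_profile`: list with `pfm_windows`,
#'   `flap_threshold_g`, `large_pitch_change_deg`, `pfm_pitch_min_med_deg`,
#'   `pfm_pitch_mean_med_deg`, `pfm_pitch_var_med_deg2`, `tag_kind`.
#' @export
calibrate_tag <- function(series, n_pfm = NULL, config = default_config()) {
  stopifnot(inherits(series, "accel_series"))
  dec <- decompose_accel(series, config$lowpass_cutoff_hz,
                         config$filter_order, config$zero_phase)
  bands <- band_energy(dec, config$spec_window_s, config$spec_overlap_frac,
                       config$flap_band_hz, config$takeoff_band_hz)
  if (is.null(n_pfm)) {
    if (series$tag_kind == "chest_mounted") {
      n_pfm <- config$n_pfm_dvl
    } else {
      days <- duration_s(series) / 86400
      full <- floor(days)
      n_pfm <- config$n_pfm_per_day * full +
        max(1L, ceiling(config$n_pfm_per_day * (days - full)))
    }
  }
  pfms <- select_pfms(bands, n_pfm, config$pfm_min_separation_s,
                      config$pfm_window_s)
  pit <- pitch_angle(dec)
  ps <- pitch_statistics(pit, pfms)
  structure(c(list(pfm_windows = pfms[, c("start_s", "end_s")],
                   flap_threshold_g = flap_threshold(dec, pfms)),
              ps, list(tag_kind = series$tag_kind)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(paste0("<calibration_profile> %s\n",
                     "  PFMs: %d  flap threshold: %.3f g\n",
                     "  large pitch change: %.1f deg\n",
                     "  PFM pitch min/mean med: %.1f / %.1f deg, var med: %.1f deg^2\n"),
              x$tag_kind, nrow(x$pfm_windows), x$flap_threshold_g,
              x$large_pitch_change_deg, x$pfm_pitch_min_med_deg,
              x$pfm_pitch_mean_med_deg, x$pfm_pitch_var_med_deg2))
  invisible(x)
}

#' Read / write a calibration profile JSON sidecar
#'
#' @param profile A `calibration_profile`.
#' @param path Path to a JSON file.
#' @return [write_calibration()]: `path`, invisibly. [read_calibration()]:
#'   the `calibration_profile`.
#' @export
write_calibration <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$pfm_windows <- as.data.frame(p$pfm_windows)
  structure(p, class = "calibration_profile")
}

# internal: samples whose instants fall in [start_s, end_s)
.window_slice <- function(v, start_s, end_s, fs) {
  i1 <- max(1L, floor(start_s * fs + 1e-9) + 1L)
  i2 <- min(length(v), ceiling(end_s * fs - 1e-9))
  if (i2 < i1) return(numeric())
  v[i1:i2]
}
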