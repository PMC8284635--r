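#' Read a tri-axial acceleration export
#'
#' Reads a comma-delimited tag export (header row required) with a time or
#' sample-index column and three acceleration columns in g, and returns a
#' validated [accel_series()]. Sampling is verified uniform at the declared
#' rate; records with gaps are either rejected (default) or split into
#' contiguous segments.
#'
#' @param path Path to a CSV file.
#' @param fs Declared sampling rate in Hz.
#' @param tag_kind Tag mounting, see [accel_series()].
#' @param column_map Named character vector mapping the canonical names
#'   `time`, `x`, `y`, `z` to the column names of the export. `time` may
#'   name either a numeric seconds / sample-index column or an ISO-8601
#'   timestamp column.
#' @param gap_policy `"reject"` (default): any sampling gap is an error
#'   listing the gap positions; `"split"`: return a list of contiguous
#'   `accel_series` segments.
#' @param tol Fraction of the sample interval by which successive timestamps
#'   may deviate from `1/fs` before being counted as a gap (default 0.25).
#' @return An `accel_series`, or a list of them when `gap_policy = "split"`
#'   and gaps are present.
#' @export
read_accel <- function(path, fs,
                       tag_kind = c("chest_mounted", "back_mounted"),
                       column_map = c(time = "time", x = "x", y = "y",
                                      z = "z"),
                       gap_policy = c("reject", "split"), tol = 0.25) {
  tag_kind <- match.arg(tag_kind)
  gap_policy <- match.arg(gap_policy)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "x", "y", "z")
  if (is.null(names(column_map)) || !all(need %in% names(column_map)))
    stop("`column_map` must name all of: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(unname(column_map[need]), names(df))
  if (length(missing_cols))
    stop("schema error: column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  tcol <- df[[column_map[["time"]]]]
  t0 <- NA
  if (is.character(tcol)) {
    tt <- as.POSIXct(tcol, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt)) stop("schema error: unparseable timestamps")
    t0 <- tt[1L]
    tsec <- as.numeric(tt) - as.numeric(tt[1L])
  } else {
    tsec <- as.numeric(tcol)
    tsec <- tsec - tsec[1L]
    # a sample-index column counts in samples, not seconds
    if (length(tsec) > 1L && fs != 1 &&
        isTRUE(all.equal(stats::median(diff(tsec)), 1, tolerance = 1e-9)))
      tsec <- tsec / fs
  }
  n <- length(tsec)
  if (n > 1L) {
    dt <- diff(tsec)
    gaps <- which(abs(dt - 1 / fs) > tol / fs)
    if (length(gaps)) {
      if (gap_policy == "reject")
        stop("gap error: non-uniform sampling at row(s) ",
             paste(utils::head(gaps + 1L, 10L), collapse = ", "),
             if (length(gaps) > 10L) " ..." else "")
      # split into contiguous segments at the gaps
      seg_id <- cumsum(c(0L, as.integer(seq_len(n - 1L) %in% gaps))) + 1L
      return(lapply(split(seq_len(n), seg_id), function(ix) {
        accel_series(df[[column_map[["x"]]]][ix],
                     df[[column_map[["y"]]]][ix],
                     df[[column_map[["z"]]]][ix],
                     fs = fs, t0 = t0, tag_kind = tag_kind)
      }))
    }
  }
  accel_series(df[[column_map[["x"]]]], df[[column_map[["y"]]]],
               df[[column_map[["z"]]]], fs = fs, t0 = t0,
               tag_kind = tag_kind)
}

#' Read / write an ethogram CSV
#'
#' The on-disk format is a CSV with columns `start_s`, `end_s`, `label`.
#' Reading sorts and validates; overlapping intervals or labels outside the
#' vocabulary are errors.
#'
#' @param path Path to a CSV file.
#' @return [read_ethogram()]: an `ethogram`. [write_ethogram()]: `path`,
#'   invisibly.
#' @export
read_ethogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("schema error: ethogram CSV needs columns ",
         paste(need, collapse = ", "))
  ethogram(df$start_s, df$end_s, df$label, sort = TRUE)
}

#' @rdname read_ethogram
#' @param eth An `ethogram`.
#' @export
write_ethogram <- function(eth, path) {
  stopifnot(inherits(eth, "ethogram"))
  utils::write.csv(as.data.frame(eth), path, row.names = FALSE)
  invisible(path)
}

#' Read / write GPS fixes
#'
#' Fix files are CSVs with columns `time` (ISO-8601 UTC or numeric seconds),
#' `lat`, `lon` (decimal degrees, WGS84) and optionally `speed_kph` and
#' `behaviour`. Fixes are returned time-sorted; coordinates outside valid
#' ranges are an error.
#'
#' @param path Path to a CSV file.
#' @param dedup How to treat duplicated timestamps: keep the `"first"` fix
#'   (default) or raise an `"error"`.
#' @return A `data.frame` of class `gps_track` with `time` (`POSIXct` UTC or
#'   numeric seconds), `lat`, `lon`, plus any optional columns present.
#' @export
read_gps <- function(path, dedup = c("first", "error")) {
  dedup <- match.arg(dedup)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("schema error: GPS CSV needs columns ",
         paste(need, collapse = ", "))
  if (is.character(df$time)) {
    df$time <- as.POSIXct(df$time, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(df$time)) stop("schema error: unparseable timestamps")
  }
  gps_track(df, dedup = dedup)
}

#' @rdname read_gps
#' @param fixes A `gps_track` data frame.
#' @export
write_gps <- function(fixes, path) {
  out <- as.data.frame(fixes)
  if (inherits(out$time, "POSIXct"))
    out$time <- format(out$time, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Validate a data frame of GPS fixes
#'
#' @param df Data frame with at least `time`, `lat`, `lon`.
#' @param dedup Duplicate-timestamp policy, see [read_gps()].
#' @return The validated, time-sorted `gps_track`.
#' @export
gps_track <- function(df, dedup = c("first", "error")) {
  dedup <- match.arg(dedup)
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("validation error: coordinates out of range")
  o <- order(df$time)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df$time)
  if (any(dup)) {
    if (dedup == "error") stop("validation error: duplicated timestamps")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("gps_track", "data.frame")
  df
}

#' Default analysis configuration
#'
#' Every constant of the detection method, exposed in one place so that a
#' YAML run configuration (see [read_config()]) or a function argument can
#' override it. Units are given in the names where they are not obvious.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    lowpass_cutoff_hz   = 1.5,   # static/dynamic split
    filter_order        = 100,
    zero_phase          = TRUE,
    spec_window_s       = 4,     # spectrogram window
    spec_overlap_frac   = 0.85,
    flap_band_hz        = c(3.5, 5),
    takeoff_band_hz     = NULL,  # NULL = (5, Nyquist]
    pfm_window_s        = 60,
    pfm_min_separation_s = 300,
    n_pfm_dvl           = 10,
    n_pfm_per_day       = 20,
    odba_window_s       = 10,
    rest_threshold_g    = 0.2,
    intra_bout_gap_s    = 0.5,
    inter_bout_gap_s    = 30,
    takeoff_search_window_s = 2,
    pitch_group_window_s = 23.3,
    dive_descent_offset_deg = 30,
    dive_ascent_window_s = 10,
    seize_burst_gap_s   = 2,
    seize_min_events    = 3,
    seize_chain_rule    = "chain",  # or "all_pairs"
    colony_radius_km    = 1.5,
    max_speed_kph       = 80,
    max_forage_speed_kph = 15,
    speed_window_fixes  = 5,
    assign_window_s     = 30,
    min_behaviour_s     = 5,
    day_tz_offset_h     = 9,
    clock_offset_s      = 0      # video-to-acceleration clock offset
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file of configuration overrides and merges it over
#' [default_config()]. Unknown keys are an error, so typos fail loudly.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Named list with the same shape as [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, user)
}
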