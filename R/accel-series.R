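#' Construct a tri-axial acceleration series
#'
#' Container for a uniformly sampled tri-axial acceleration record in units
#' of g. Axes follow the tag convention: `x` longitudinal (surge), `y`
#' lateral (sway), `z` dorsoventral (heave).
#'
#' @param x,y,z Numeric vectors of equal length: per-sample acceleration in g
#'   along the longitudinal, lateral and dorsoventral axes.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Absolute start time (`POSIXct`, UTC) or `NA` when unknown; all
#'   analyses run on seconds from series start, `t0` is metadata only.
#' @param tag_kind `"chest_mounted"` (video + acceleration loggers) or
#'   `"back_mounted"` (GPS + acceleration loggers). Mounting changes which
#'   pitch-event suppression rules apply during classification.
#' @return An object of class `accel_series`: a list with elements `x`, `y`,
#'   `z`, `fs`, `t0`, `tag_kind`.
#' @examples
#' acc <- accel_series(x = rnorm(100, 0, 0.01), y = rnorm(100, 0, 0.01),
#'                     z = 1 + rnorm(100, 0, 0.01), fs = 20)
#' duration_s(acc)
#' @export
accel_series <- function(x, y, z, fs, t0 = NA,
                         tag_kind = c("chest_mounted", "back_mounted")) {
  tag_kind <- match.arg(tag_kind)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  n <- length(x)
  if (n < 1L) stop("acceleration series must contain at least one sample")
  if (length(y) != n || length(z) != n)
    stop("`x`, `y`, `z` must have equal length")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("acceleration series must not contain missing samples")
  structure(list(x = x, y = y, z = z, fs = fs, t0 = t0, tag_kind = tag_kind),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples at %g Hz (%.1f s), %s\n",
              length(x$x), x$fs, length(x$x) / x$fs, x$tag_kind))
  invisible(x)
}

#' Duration of a series or ethogram in seconds
#'
#' @param x An `accel_series` or `ethogram`.
#' @return Length of the record in seconds (for an ethogram, the end of the
#'   last interval).
#' @export
duration_s <- function(x) {
  if (inherits(x, "accel_series")) return(length(x$x) / x$fs)
  if (inherits(x, "ethogram")) {
    if (nrow(x) == 0L) return(0)
    return(max(x$end_s))
  }
  stop("unsupported type")
}

#' Construct an ethogram (labelled behaviour intervals)
#'
#' An ethogram is an ordered set of non-overlapping, half-open intervals
#' `[start_s, end_s)` in seconds from record start, each carrying one label
#' from [behaviour_levels()].
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds;
#'   `end_s > start_s` elementwise.
#' @param label Character vector of behaviour labels.
#' @param sort Sort intervals by start time before validation (default
#'   `TRUE`). With `sort = FALSE` unordered input is an error.
#' @return A `data.frame` of class `ethogram` with columns `start_s`,
#'   `end_s`, `label`.
#' @examples
#' ethogram(c(0, 10), c(10, 25), c("flight", "rest"))
#' @export
ethogram <- function(start_s = numeric(), end_s = numeric(),
                     label = character(), sort = TRUE) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  label <- as.character(label)
  n <- length(start_s)
  if (length(end_s) != n || length(label) != n)
    stop("`start_s`, `end_s`, `label` must have equal length")
  bad <- setdiff(unique(label), behaviour_levels())
  if (length(bad))
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "))
  if (any(end_s <= start_s))
    stop("every interval must satisfy end_s > start_s")
  if (sort && n > 1L) {
    o <- order(start_s, end_s)
    start_s <- start_s[o]; end_s <- end_s[o]; label <- label[o]
  }
  if (n > 1L) {
    if (is.unsorted(start_s)) stop("intervals must be sorted by start time")
    if (any(start_s[-1L] < end_s[-n] - 1e-9))
      stop("intervals must not overlap")
  }
  structure(data.frame(start_s = start_s, end_s = end_s, label = label,
                       stringsAsFactors = FALSE),
            class = c("ethogram", "data.frame"))
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d intervals covering %.1f s\n",
              nrow(x), sum(x$end_s - x$start_s)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Total duration per behaviour label
#'
#' @param eth An `ethogram`.
#' @return Named numeric vector of summed interval durations (s), one entry
#'   per label in [behaviour_levels()] (zero when absent).
#' @export
label_durations <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  out <- stats::setNames(numeric(length(behaviour_levels())),
                         behaviour_levels())
  if (nrow(eth)) {
    d <- tapply(eth$end_s - eth$start_s, eth$label, sum)
    out[names(d)] <- d
  }
  out
}

# internal: merge adjacent intervals sharing a label (within tol)
.merge_adjacent <- function(eth, tol = 1e-9) {
  if (nrow(eth) < 2L) return(eth)
  keep_start <- eth$start_s[1L]; out <- list(); k <- 0L
  cur <- eth[1L, ]
  for (i in seq_len(nrow(eth))[-1L]) {
    if (eth$label[i] == cur$label && eth$start_s[i] <= cur$end_s + tol) {
      cur$end_s <- max(cur$end_s, eth$end_s[i])
    } else {
      k <- k + 1L; out[[k]] <- cur
      cur <- eth[i, ]
    }
  }
  out[[k + 1L]] <- cur
  merged <- do.call(rbind, out)
  ethogram(merged$start_s, merged$end_s, merged$label, sort = FALSE)
}
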