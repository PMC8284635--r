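#' Sample an ethogram at a fixed rate
#'
#' Produces the per-sample label sequence at sampling rate `fs`: the label
#' at instant `t = (k - 1) / fs` is that of the interval containing `t`
#' under the half-open convention (`start <= t < end`); instants outside
#' any interval are `"unknown"`.
#'
#' @param eth An `ethogram`.
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration; defaults to the ethogram's end.
#' @return Character vector of length `round(duration_s * fs)`.
#' @export
sample_ethogram <- function(eth, fs, duration_s = NULL) {
  stopifnot(inherits(eth, "ethogram"), fs > 0)
  if (is.null(duration_s)) duration_s <- duration_s(eth)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  out <- rep.int("unknown", n)
  if (nrow(eth)) {
    tq <- t + 1e-9  # nudge instants sitting on a boundary into the right interval
    ix <- findInterval(tq, eth$start_s)
    inside <- ix >= 1L
    inside[inside] <- tq[inside] < eth$end_s[ix[inside]]
    out[inside] <- eth$label[ix[inside]]
  }
  out
}

#' Duration-based confusion rates for one behaviour
#'
#' True positive rate is the correctly identified duration over the
#' reference duration of the behaviour; false positive rate is the duration
#' incorrectly labelled as the behaviour over the reference duration of all
#' *other* behaviours. Durations are counted sample-wise and reported in
#' seconds.
#'
#' @param predicted,reference Equal-length per-sample label vectors on the
#'   same clock (see [sample_ethogram()]).
#' @param behaviour Behaviour label to score.
#' @param fs Sampling rate in Hz used to convert counts to seconds.
#' @return List with `tpr`, `fpr` (NA when the respective reference
#'   duration is zero), `PF_c`, `PF_i`, `V_F`, `V_O` (seconds).
#' @export
confusion_rates <- function(predicted, reference, behaviour, fs = 1) {
  if (length(predicted) != length(reference))
    stop("predicted and reference sequences must have equal length")
  is_ref <- reference == behaviour
  is_pred <- predicted == behaviour
  PF_c <- sum(is_pred & is_ref) / fs
  PF_i <- sum(is_pred & !is_ref) / fs
  V_F <- sum(is_ref) / fs
  V_O <- sum(!is_ref) / fs
  list(tpr = if (V_F > 0) PF_c / V_F else NA_real_,
       fpr = if (V_O > 0) PF_i / V_O else NA_real_,
       PF_c = PF_c, PF_i = PF_i, V_F = V_F, V_O = V_O)
}

#' Drop masked samples from a label sequence
#'
#' Removes the samples whose instants fall inside any of the mask
#' intervals; used to exclude periods that cannot be scored (e.g. obscured
#' video) from both sequences before rate computation.
#'
#' @param labels Per-sample label vector.
#' @param mask Data frame of intervals (`start_s`, `end_s`) to drop, or
#'   `NULL`/empty for the identity.
#' @param fs Sampling rate in Hz.
#' @return The label vector with masked samples removed.
#' @export
exclude_periods <- function(labels, mask, fs) {
  if (is.null(mask) || !nrow(mask)) return(labels)
  t <- (seq_along(labels) - 1L) / fs
  drop <- rep.int(FALSE, length(labels))
  for (i in seq_len(nrow(mask)))
    drop <- drop | (t >= mask$start_s[i] - 1e-12 &
                      t < mask$end_s[i] - 1e-12)
  labels[!drop]
}

#' Validate a predicted ethogram against a reference
#'
#' Samples both ethograms on a common clock, optionally excludes masked
#' periods, and computes per-behaviour duration-based TPR/FPR.
#'
#' @param predicted,reference `ethogram` objects on the same clock.
#' @param fs Validation sampling rate in Hz (use the acceleration rate to
#'   score every acceleration sample, e.g. 20 Hz = one label per 0.05 s).
#' @param mask Optional data frame of excluded intervals (`start_s`,
#'   `end_s`).
#' @param behaviours Labels to score (default: all labels present in the
#'   reference, ordered as [behaviour_levels()]).
#' @return Data frame of class `validation_report`: one row per behaviour
#'   with `behaviour`, `tpr`, `fpr`, `PF_c`, `PF_i`, `V_F`, `V_O`.
#' @export
validate_ethogram <- function(predicted, reference, fs, mask = NULL,
                              behaviours = NULL) {
  dur <- max(duration_s(predicted), duration_s(reference))
  p <- sample_ethogram(predicted, fs, dur)
  r <- sample_ethogram(reference, fs, dur)
  p <- exclude_periods(p, mask, fs)
  r <- exclude_periods(r, mask, fs)
  if (is.null(behaviours))
    behaviours <- intersect(behaviour_levels(), unique(r))
  rows <- lapply(behaviours, function(b) {
    cr <- confusion_rates(p, r, b, fs)
    data.frame(behaviour = b, tpr = cr$tpr, fpr = cr$fpr, PF_c = cr$PF_c,
               PF_i = cr$PF_i, V_F = cr$V_F, V_O = cr$V_O,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}
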