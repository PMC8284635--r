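# shared fixture builders; everything is generated in code at test time

# plain sinusoid series on all axes (z carries the signal)
make_sine_series <- function(freq_hz, fs = 20, duration_s = 30, amp = 0.5,
                             dc = c(0, 0, 1)) {
  t <- seq_len(round(duration_s * fs)) / fs
  accel_series(x = dc[1] + 0 * t, y = dc[2] + 0 * t,
               z = dc[3] + amp * sin(2 * pi * freq_hz * t), fs = fs)
}

# random low-amplitude series for property checks
make_noise_series <- function(n = 500, fs = 20, sd = 0.3) {
  accel_series(x = rnorm(n, 0, sd), y = rnorm(n, 0, sd),
               z = 1 + rnorm(n, 0, sd), fs = fs)
}

# write a small acceleration CSV and return its path
write_accel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# manual decomposed object (bypasses filtering) for detector unit tests
fake_decomposed <- function(zd, fs = 20, xd = NULL, yd = NULL,
                            xs = NULL, tag_kind = "chest_mounted") {
  n <- length(zd)
  if (is.null(xd)) xd <- numeric(n)
  if (is.null(yd)) yd <- numeric(n)
  if (is.null(xs)) xs <- numeric(n)
  structure(list(static = list(x = xs, y = numeric(n), z = rep(1, n)),
                 dynamic = list(x = xd, y = yd, z = zd),
                 fs = fs, tag_kind = tag_kind),
            class = "accel_decomposed")
}

fake_pitch <- function(pitch_deg, fs = 20) {
  structure(list(pitch_deg = pitch_deg, fs = fs), class = "pitch_series")
}

fake_profile <- function(flap_threshold_g = 0.3,
                         large_pitch_change_deg = 10,
                         pfm_pitch_min_med_deg = -4,
                         pfm_pitch_mean_med_deg = 0,
                         pfm_pitch_var_med_deg2 = 4,
                         tag_kind = "chest_mounted") {
  structure(list(pfm_windows = data.frame(start_s = 0, end_s = 60),
                 flap_threshold_g = flap_threshold_g,
                 large_pitch_change_deg = large_pitch_change_deg,
                 pfm_pitch_min_med_deg = pfm_pitch_min_med_deg,
                 pfm_pitch_mean_med_deg = pfm_pitch_mean_med_deg,
                 pfm_pitch_var_med_deg2 = pfm_pitch_var_med_deg2,
                 tag_kind = tag_kind),
            class = "calibration_profile")
}
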