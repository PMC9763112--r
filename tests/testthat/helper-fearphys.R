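# Shared fixtures, all generated in code.

# Kernel taus calibrated once so simulated events have the measured
# kinetics used across the ephys tests (10-90% rise 2.16 ms,
# peak-to-1/e decay 10.93 ms).
CAL_KIN <- calibrate_biexp_taus(2.16, 10.93)

# A small photometry recording with an exactly affine trend in both
# channels (no bleach curvature, no noise) for trend-null checks.
affine_recording <- function(fs = 200, duration = 160,
                             slope465 = -0.02, slope405 = -0.015,
                             onsets = c(50, 100)) {
  t <- (seq_len(fs * duration) - 1) / fs
  photometry_recording(100 + slope465 * t, 80 + slope405 * t, fs,
                       tone_onsets = onsets, tone_offsets = onsets + 30)
}

# One noise-free sweep holding `n_ev` identical events, spaced well
# apart, built straight from the kernel (independent of the simulator).
manual_event_sweep <- function(n_ev = 10, amp = 20, fs = 10000,
                               spacing = 1, tau_r = CAL_KIN$tau_rise,
                               tau_d = CAL_KIN$tau_decay) {
  dur <- n_ev * spacing
  t <- (seq_len(dur * fs) - 1) / fs
  x <- numeric(length(t))
  onsets <- (seq_len(n_ev) - 1) * spacing + 0.05
  for (on in onsets) {
    x <- x - amp * biexp_kernel(t - on, tau_r / 1000, tau_d / 1000)
  }
  sweep_vc(t, x, fs)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
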