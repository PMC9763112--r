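#' Dual-channel photometry recording
#'
#' Container for a demodulated two-wavelength fiber photometry session:
#' the calcium-dependent 465 nm channel, the calcium-independent 405 nm
#' isosbestic channel, and the tone (CS+) onset/offset timestamps used
#' for peri-event alignment.
#'
#' @param ch465,ch405 numeric fluorescence traces (arbitrary units),
#'   uniformly sampled at `fs`, equal length.
#' @param fs sampling rate in Hz (> 0).
#' @param tone_onsets,tone_offsets tone event times in seconds;
#'   onsets strictly increasing, each offset after its onset, all
#'   within the recording.
#' @param meta named list of free-form provenance values.
#' @return object of class `photometry_recording`.
#' @export
photometry_recording <- function(ch465, ch405, fs,
                                 tone_onsets = numeric(0),
                                 tone_offsets = numeric(0),
                                 meta = list()) {
  rec <- structure(
    list(ch465 = as.double(ch465), ch405 = as.double(ch405),
         fs = as.double(fs),
         tone_onsets = as.double(tone_onsets),
         tone_offsets = as.double(tone_offsets),
         meta = meta),
    class = "photometry_recording")
  validate_photometry_recording(rec)
  rec
}

#' Validate a photometry recording's invariants
#'
#' Checks channel lengths, sampling rate, event monotonicity and event
#' bounds; stops with the violated invariant named. Never repairs.
#' @param rec a `photometry_recording`.
#' @return `rec`, invisibly.
#' @export
validate_photometry_recording <- function(rec) {
  if (length(rec$ch465) != length(rec$ch405)) {
    stop("photometry_recording: len(ch465) == len(ch405) violated")
  }
  if (!is.finite(rec$fs) || rec$fs <= 0) {
    stop("photometry_recording: fs > 0 violated")
  }
  if (length(rec$tone_onsets) != length(rec$tone_offsets)) {
    stop("photometry_recording: onsets and offsets differ in length")
  }
  if (is.unsorted(rec$tone_onsets, strictly = TRUE)) {
    stop("photometry_recording: tone_onsets strictly increasing violated")
  }
  if (any(rec$tone_offsets <= rec$tone_onsets)) {
    stop("photometry_recording: every offset > its onset violated")
  }
  dur <- duration.photometry_recording(rec)
  ev <- c(rec$tone_onsets, rec$tone_offsets)
  if (length(ev) && (any(ev < 0) || any(ev > dur))) {
    stop("photometry_recording: event times within [0, duration] violated")
  }
  invisible(rec)
}

duration.photometry_recording <- function(rec) length(rec$ch465) / rec$fs

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf(
    "<photometry_recording> %d samples @ %.4g Hz (%.1f s), %d tones\n",
    length(x$ch465), x$fs, duration.photometry_recording(x),
    length(x$tone_onsets)))
  invisible(x)
}

#' Peri-event photometry trial
#'
#' One tone-aligned window through the pipeline stages: raw (already
#' downsampled + smoothed) channels, per-channel linear-fit
#' predictions, per-channel percent delta-F/F, and the isosbestic-
#' corrected signal. Arrays are filled in as the stages run; `corrected`
#' must always equal `dff465 - dff405` when both are present.
#'
#' @param t time axis in seconds, 0 = tone onset.
#' @param raw465,raw405 windowed traces.
#' @param trial_index 1-based tone number.
#' @param pred465,pred405,dff465,dff405,corrected later-stage arrays
#'   (optional at construction).
#' @param valid logical; trials whose window leaves the recording or
#'   whose predicted signal is non-positive are flagged invalid.
#' @return object of class `peri_event_trial`.
#' @export
peri_event_trial <- function(t, raw465, raw405, trial_index,
                             pred465 = NULL, pred405 = NULL,
                             dff465 = NULL, dff405 = NULL,
                             corrected = NULL, valid = TRUE) {
  tr <- structure(
    list(t = as.double(t), raw465 = as.double(raw465),
         raw405 = as.double(raw405),
         pred465 = pred465, pred405 = pred405,
         dff465 = dff465, dff405 = dff405, corrected = corrected,
         trial_index = as.integer(trial_index), valid = isTRUE(valid),
         fit465 = NULL, fit405 = NULL),
    class = "peri_event_trial")
  validate_peri_event_trial(tr)
  tr
}

#' Validate a peri-event trial's invariants
#' @param tr a `peri_event_trial`.
#' @return `tr`, invisibly.
#' @export
validate_peri_event_trial <- function(tr) {
  n <- length(tr$t)
  for (f in c("raw465", "raw405", "pred465", "pred405",
              "dff465", "dff405", "corrected")) {
    v <- tr[[f]]
    if (!is.null(v) && length(v) != n) {
      stop(sprintf("peri_event_trial: length(%s) != length(t)", f))
    }
  }
  if (n && !(min(tr$t) <= 0 && max(tr$t) >= 0)) {
    stop("peri_event_trial: time axis must span tone onset (t = 0)")
  }
  if (!is.null(tr$corrected) && !is.null(tr$dff465) && !is.null(tr$dff405)) {
    if (max(abs(tr$corrected - (tr$dff465 - tr$dff405))) > 1e-9) {
      stop("peri_event_trial: corrected == dff465 - dff405 violated")
    }
  }
  invisible(tr)
}

#' Voltage-clamp sweep
#'
#' A single current sweep with its time axis (seconds), sampling rate,
#' holding potential and any electrical stimulation times.
#'
#' @param t time axis in seconds.
#' @param i membrane current in pA (inward currents negative).
#' @param fs sampling rate in Hz.
#' @param holding_mv holding potential in mV (default -70, the standard
#'   AMPA-dominated configuration).
#' @param stim_times stimulation times in seconds, possibly empty.
#' @param meta named list of provenance values.
#' @return object of class `sweep_vc`.
#' @export
sweep_vc <- function(t, i, fs, holding_mv = -70, stim_times = numeric(0),
                     meta = list()) {
  sw <- structure(
    list(t = as.double(t), i = as.double(i), fs = as.double(fs),
         holding_mv = as.double(holding_mv),
         stim_times = as.double(stim_times), meta = meta),
    class = "sweep_vc")
  validate_sweep(sw)
  sw
}

#' Validate a sweep's invariants
#' @param sw a `sweep_vc`.
#' @return `sw`, invisibly.
#' @export
validate_sweep <- function(sw) {
  if (length(sw$t) != length(sw$i)) {
    stop("sweep_vc: len(t) == len(i) violated")
  }
  if (!is.finite(sw$fs) || sw$fs <= 0) stop("sweep_vc: fs > 0 violated")
  if (length(sw$stim_times) &&
      (any(sw$stim_times < min(sw$t)) || any(sw$stim_times > max(sw$t)))) {
    stop("sweep_vc: stim_times within sweep duration violated")
  }
  invisible(sw)
}

#' @export
print.sweep_vc <- function(x, ...) {
  cat(sprintf(
    "<sweep_vc> %d samples @ %.4g Hz, holding %g mV, %d stimulations\n",
    length(x$i), x$fs, x$holding_mv, length(x$stim_times)))
  invisible(x)
}

#' Detected synaptic event list
#'
#' Output of the spontaneous EPSC detector (or the simulator's ground
#' truth): event times, positive amplitude magnitudes, and kinetics
#' under the package's definitions (10-90% rise, peak-to-1/e decay).
#' Times are seconds; kinetics are reported in milliseconds.
#'
#' @param event_times event (peak) times in seconds, strictly increasing.
#' @param amplitudes positive amplitudes in pA.
#' @param rise_times 10-90% rise times in ms.
#' @param decay_times peak-to-1/e decay times in ms.
#' @param source_duration duration of the source trace in s.
#' @return object of class `event_list`; `frequency(ev)` gives
#'   count / source_duration in Hz.
#' @export
event_list <- function(event_times, amplitudes, rise_times = NULL,
                       decay_times = NULL, source_duration) {
  n <- length(event_times)
  if (is.null(rise_times)) rise_times <- rep(NA_real_, n)
  if (is.null(decay_times)) decay_times <- rep(NA_real_, n)
  ev <- structure(
    list(event_times = as.double(event_times),
         amplitudes = as.double(amplitudes),
         rise_times = as.double(rise_times),
         decay_times = as.double(decay_times),
         source_duration = as.double(source_duration)),
    class = "event_list")
  validate_event_list(ev)
  ev
}

#' Validate an event list's invariants
#' @param ev an `event_list`.
#' @return `ev`, invisibly.
#' @export
validate_event_list <- function(ev) {
  if (is.unsorted(ev$event_times, strictly = TRUE)) {
    stop("event_list: event_times strictly increasing violated")
  }
  if (length(ev$amplitudes) != length(ev$event_times)) {
    stop("event_list: amplitudes and event_times differ in length")
  }
  if (any(ev$amplitudes <= 0)) stop("event_list: amplitudes > 0 violated")
  if (!is.finite(ev$source_duration) || ev$source_duration <= 0) {
    stop("event_list: source_duration > 0 violated")
  }
  invisible(ev)
}

#' Event frequency of an event list (Hz)
#' @param ev an `event_list`.
#' @return events per second.
#' @export
event_frequency <- function(ev) {
  length(ev$event_times) / ev$source_duration
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events in %.1f s (%.3g Hz)\n",
              length(x$event_times), x$source_duration, event_frequency(x)))
  invisible(x)
}

#' Per-cell release/receptor statistics
#'
#' @param ppr paired-pulse ratio (eEPSC2 / eEPSC1), dimensionless.
#' @param inv_cv2 inverse squared coefficient of variation, mu^2/sigma^2.
#' @param vmr variance-to-mean ratio, sigma^2/mu, in pA.
#' @param ampa_nmda AMPA/NMDA ratio, dimensionless.
#' @param n_sweeps number of evoked sweeps entering inv_cv2/vmr.
#' @return object of class `release_stats`.
#' @export
release_stats <- function(ppr = NA_real_, inv_cv2 = NA_real_,
                          vmr = NA_real_, ampa_nmda = NA_real_,
                          n_sweeps = NA_integer_) {
  rs <- structure(
    list(ppr = ppr, inv_cv2 = inv_cv2, vmr = vmr,
         ampa_nmda = ampa_nmda, n_sweeps = as.integer(n_sweeps)),
    class = "release_stats")
  vals <- c(rs$ppr, rs$inv_cv2, rs$vmr, rs$ampa_nmda)
  if (any(!is.na(vals) & (!is.finite(vals) | vals < 0))) {
    stop("release_stats: defined statistics must be finite and >= 0")
  }
  if (!is.na(rs$n_sweeps) && rs$n_sweeps < 2 &&
      (!is.na(rs$inv_cv2) || !is.na(rs$vmr))) {
    stop("release_stats: n_sweeps >= 2 required for inv_cv2/vmr")
  }
  rs
}

#' Result of an assumption-gated group comparison
#'
#' @param test_name label of the test actually applied.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2).
#' @param p_value two-sided p-value.
#' @param transform `"none"` or `"log"`.
#' @param normality_p smallest per-group Shapiro-Wilk p (after any
#'   transform).
#' @param levene_p Levene homogeneity-of-variance p.
#' @return object of class `group_comparison`.
#' @export
group_comparison <- function(test_name, statistic, df, p_value,
                             transform = "none",
                             normality_p = NA_real_, levene_p = NA_real_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("group_comparison: 0 <= p_value <= 1 violated")
  }
  if (!transform %in% c("none", "log")) {
    stop("group_comparison: transform must be 'none' or 'log'")
  }
  structure(
    list(test_name = test_name, statistic = as.double(statistic),
         df = df, p_value = as.double(p_value), transform = transform,
         normality_p = as.double(normality_p),
         levene_p = as.double(levene_p)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  dfs <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf("<group_comparison> %s: statistic = %.4g, df = (%s), p = %.4g",
              x$test_name, x$statistic, dfs, x$p_value))
  if (x$transform != "none") cat(sprintf(" [%s-transformed]", x$transform))
  cat("\n")
  invisible(x)
}
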