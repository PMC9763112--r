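# Offline fiber-photometry pipeline: downsample -> zero-phase smooth ->
# peri-event windowing -> per-trial per-channel linear detrend to %dF/F
# -> isosbestic subtraction -> peak / AUC metrics. Stage order is fixed
# and recorded; each stage is also exported on its own.

#' Parameters of the photometry pipeline
#'
#' Defaults follow the standard offline treatment of demodulated
#' GCaMP/isosbestic traces: 50x block-mean downsampling, zero-phase
#' 10-sample moving-average smoothing, peri-event windows of -30..+40 s
#' around tone onset, per-trial linear (degree-1) detrending, peak
#' search over the first 5 s of the tone, AUC epochs over the 5 s
#' before and the first 5 s of the tone, and a session summary over the
#' first two tones.
#'
#' @param downsample_factor block size for mean downsampling (>= 1).
#' @param smooth_window moving-average window, samples (post-downsample).
#' @param window peri-event window `(start, end)` s, start < 0 < end.
#' @param detrend_degree polynomial degree of the per-channel fit.
#' @param peak_window half-open interval `(start, end]` s for the peak
#'   search.
#' @param auc_epochs list of `(start, end)` epochs (s) for trapezoidal
#'   AUC, all within `window`.
#' @param trials_for_summary trial indices averaged into the session
#'   summary.
#' @return list of class `photometry_params`.
#' @export
photometry_params <- function(downsample_factor = 50, smooth_window = 10,
                              window = c(-30, 40), detrend_degree = 1,
                              peak_window = c(0, 5),
                              auc_epochs = list(c(-5, 0), c(0, 5)),
                              trials_for_summary = 1:2) {
  p <- structure(as.list(environment()), class = "photometry_params")
  stopifnot(p$downsample_factor >= 1, p$smooth_window >= 1,
            p$detrend_degree >= 1, length(p$window) == 2)
  if (!(p$window[1] < 0 && p$window[2] > 0)) {
    stop("photometry_params: window start < 0 < end required")
  }
  if (p$peak_window[2] <= p$peak_window[1]) {
    stop("photometry_params: empty peak window")
  }
  for (e in p$auc_epochs) {
    if (e[1] < p$window[1] || e[2] > p$window[2] || e[2] <= e[1]) {
      stop("photometry_params: AUC epoch outside peri-event window")
    }
  }
  p
}

#' Block-mean downsampling
#'
#' Non-overlapping block means: `output[k] = mean(trace[(k-1)*factor +
#' 1 .. k*factor])`; a trailing partial block is dropped, and the
#' effective sampling rate is divided by `factor`. Averaging (rather
#' than naive decimation) acts as the anti-alias step.
#'
#' @param trace numeric vector.
#' @param factor integer block size (>= 1, <= `length(trace)`).
#' @return downsampled vector of length `floor(length(trace)/factor)`.
#' @export
downsample <- function(trace, factor = 50) {
  factor <- as.integer(factor)
  if (factor < 1) stop("downsample: factor >= 1 required")
  if (factor > length(trace)) {
    stop("downsample: factor exceeds trace length")
  }
  if (factor == 1L) return(trace)
  n_blocks <- length(trace) %/% factor
  colMeans(matrix(trace[seq_len(n_blocks * factor)], nrow = factor))
}

#' Zero-phase moving-average smoothing
#'
#' A length-`window` boxcar applied forward and then backward
#' (zero-phase; the effective impulse response is triangular with unit
#' DC gain). The trace is reflection-padded by `window` samples at each
#' end so output length equals input length and edge transients stay
#' outside any interior peri-event window.
#'
#' @param trace numeric vector, longer than `window`.
#' @param window boxcar length in samples (>= 1).
#' @return smoothed vector, same length as `trace`.
#' @export
smooth_trace <- function(trace, window = 10) {
  window <- as.integer(window)
  if (window < 1) stop("smooth_trace: window >= 1 required")
  if (window == 1L) return(trace)
  n <- length(trace)
  if (n <= window) stop("smooth_trace: trace must be longer than window")
  pad_l <- trace[(window + 1):2]
  pad_r <- trace[(n - 1):(n - window)]
  x <- c(pad_l, trace, pad_r)
  kern <- rep(1 / window, window)
  y <- stats::filter(x, kern, method = "convolution", sides = 1)
  y <- rev(stats::filter(rev(y), kern, method = "convolution", sides = 1))
  out <- as.double(y[(window + 1):(window + n)])
  if (anyNA(out)) stop("smooth_trace: internal padding error")
  out
}

#' Extract tone-aligned peri-event trials
#'
#' Cuts one window per tone onset out of an (already downsampled and
#' smoothed) recording, with `t = 0` at the sample nearest the onset
#' and inclusive window endpoints. Trials whose window leaves the
#' recording are excluded (returned with `valid = FALSE` and empty
#' arrays) with a warning, never zero-padded or truncated.
#'
#' @param rec a [photometry_recording()] at the processed sampling rate.
#' @param window `(start, end)` seconds around each onset.
#' @return object of class `peri_event_set`: list of
#'   [peri_event_trial()]s plus `fs` and `window`.
#' @export
extract_peri_events <- function(rec, window = c(-30, 40)) {
  validate_photometry_recording(rec)
  if (!length(rec$tone_onsets)) {
    stop("extract_peri_events: recording has no tone onsets")
  }
  n <- length(rec$ch465)
  fs <- rec$fs
  trials <- lapply(seq_along(rec$tone_onsets), function(j) {
    k_on <- round(rec$tone_onsets[j] * fs) + 1L
    i0 <- k_on + round(window[1] * fs)
    i1 <- k_on + round(window[2] * fs)
    if (i0 < 1L || i1 > n) {
      warning(sprintf(
        "trial %d: window [%g, %g] s leaves the recording; excluded",
        j, window[1], window[2]))
      return(structure(
        list(t = numeric(0), raw465 = numeric(0), raw405 = numeric(0),
             pred465 = NULL, pred405 = NULL, dff465 = NULL, dff405 = NULL,
             corrected = NULL, trial_index = j, valid = FALSE,
             fit465 = NULL, fit405 = NULL),
        class = "peri_event_trial"))
    }
    idx <- i0:i1
    peri_event_trial(t = (idx - k_on) / fs,
                     raw465 = rec$ch465[idx], raw405 = rec$ch405[idx],
                     trial_index = j)
  })
  structure(list(trials = trials, fs = fs, window = window),
            class = "peri_event_set")
}

#' @export
print.peri_event_set <- function(x, ...) {
  nv <- sum(vapply(x$trials, function(tr) tr$valid, logical(1)))
  cat(sprintf("<peri_event_set> %d trials (%d valid), window [%g, %g] s @ %.4g Hz\n",
              length(x$trials), nv, x$window[1], x$window[2], x$fs))
  invisible(x)
}

fit_channel_trend <- function(t, y, degree) {
  if (stats::sd(t) == 0) stop("detrend_dff: degenerate (constant) time axis")
  X <- stats::poly(t, degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y)
  list(pred = as.double(cbind(1, X) %*% fit$coefficients),
       coef = fit$coefficients)
}

#' Per-channel polynomial detrend to percent delta-F/F
#'
#' Fits each channel independently against time over the full
#' peri-event window with least-squares polynomial regression (degree 1
#' by default), takes the fit as the predicted signal, and converts to
#' \deqn{\Delta F/F = 100 (raw - pred)/pred \ [\%].}
#' This removes photobleaching and slow drift locally per trial. If the
#' predicted signal is non-positive anywhere the trial is marked
#' invalid (division guard) rather than repaired.
#'
#' @param trial a [peri_event_trial()] with raw channels.
#' @param degree polynomial degree.
#' @return the trial with `pred*`, `dff*` and fit coefficients filled in.
#' @export
detrend_dff <- function(trial, degree = 1) {
  if (!trial$valid) return(trial)
  f465 <- fit_channel_trend(trial$t, trial$raw465, degree)
  f405 <- fit_channel_trend(trial$t, trial$raw405, degree)
  trial$pred465 <- f465$pred
  trial$pred405 <- f405$pred
  trial$fit465 <- f465$coef
  trial$fit405 <- f405$coef
  if (any(f465$pred <= 0) || any(f405$pred <= 0)) {
    warning(sprintf(
      "trial %d: predicted signal non-positive; trial marked invalid",
      trial$trial_index))
    trial$valid <- FALSE
    return(trial)
  }
  trial$dff465 <- 100 * (trial$raw465 - f465$pred) / f465$pred
  trial$dff405 <- 100 * (trial$raw405 - f405$pred) / f405$pred
  trial
}

#' Isosbestic subtraction
#'
#' The corrected calcium signal is the difference of the detrended
#' channels, `corrected = dff465 - dff405` (%dF/F). Shared fractional
#' artifacts (motion, fiber bending) appear equally in both detrended
#' channels and cancel; calcium transients exist only in the 465 nm
#' channel and survive.
#'
#' @param trial a [peri_event_trial()] after [detrend_dff()].
#' @return the trial with `corrected` filled in.
#' @export
subtract_isosbestic <- function(trial) {
  if (!trial$valid) return(trial)
  if (is.null(trial$dff465) || is.null(trial$dff405)) {
    stop("subtract_isosbestic: run detrend_dff first")
  }
  trial$corrected <- trial$dff465 - trial$dff405
  validate_peri_event_trial(trial)
  trial
}

#' Per-trial peak response and session summary
#'
#' Peak = maximum of the corrected signal over the half-open peak
#' window `(start, end]` (default the first 5 s of the tone); summary =
#' mean peak over `trials_for_summary` (default the first two tones).
#' The result carries `log_gate = TRUE`: downstream group comparisons
#' of peak calcium responses should offer the log transform to the
#' normality gate.
#'
#' @param set a `peri_event_set` with corrected trials.
#' @param params a [photometry_params()].
#' @return list with `per_trial` (data.frame `trial`, `peak`),
#'   `summary` (mean over summary trials) and `log_gate`.
#' @export
peak_response <- function(set, params = photometry_params()) {
  pw <- params$peak_window
  rows <- lapply(set$trials, function(tr) {
    if (!tr$valid || is.null(tr$corrected)) {
      return(data.frame(trial = tr$trial_index, peak = NA_real_))
    }
    sel <- tr$t > pw[1] & tr$t <= pw[2]
    if (!any(sel)) stop("peak_response: empty peak window")
    data.frame(trial = tr$trial_index, peak = max(tr$corrected[sel]))
  })
  per_trial <- do.call(rbind, rows)
  sel <- per_trial$trial %in% params$trials_for_summary
  summary <- mean(per_trial$peak[sel], na.rm = TRUE)
  list(per_trial = per_trial, summary = summary, log_gate = TRUE)
}

#' Per-trial, per-epoch area under the corrected signal
#'
#' Trapezoidal integral of the corrected %dF/F over each epoch on the
#' time axis in seconds (units %*s). Epochs must lie within the
#' peri-event window.
#'
#' @param set a `peri_event_set` with corrected trials.
#' @param params a [photometry_params()]; `params$auc_epochs` defines
#'   the epochs.
#' @return numeric matrix, trials x epochs, with `NA` rows for invalid
#'   trials; column names `"[start,end]"`.
#' @export
auc_epochs <- function(set, params = photometry_params()) {
  epochs <- params$auc_epochs
  for (e in epochs) {
    if (e[1] < set$window[1] || e[2] > set$window[2]) {
      stop("auc_epochs: epoch outside peri-event window")
    }
  }
  out <- matrix(NA_real_, nrow = length(set$trials), ncol = length(epochs),
                dimnames = list(NULL, vapply(epochs, function(e)
                  sprintf("[%g,%g]", e[1], e[2]), character(1))))
  for (i in seq_along(set$trials)) {
    tr <- set$trials[[i]]
    if (!tr$valid || is.null(tr$corrected)) next
    for (j in seq_along(epochs)) {
      e <- epochs[[j]]
      sel <- tr$t >= e[1] & tr$t <= e[2]
      out[i, j] <- pracma::trapz(tr$t[sel], tr$corrected[sel])
    }
  }
  out
}

#' Run the full photometry pipeline on a session
#'
#' Executes, in this order: block-mean downsampling of both channels,
#' zero-phase smoothing, peri-event extraction around each tone onset,
#' per-trial per-channel polynomial detrend to %dF/F, isosbestic
#' subtraction, then peak and AUC metrics. The order is recorded in the
#' result's `stage_order` attribute.
#'
#' @param rec a raw [photometry_recording()].
#' @param params a [photometry_params()].
#' @return list with `metrics` (per-trial data.frame: `trial`, `peak`,
#'   one `auc_*` column per epoch, `valid`), `summary` (list:
#'   `peak_mean` over summary trials, per-epoch `auc_mean`, `log_gate`),
#'   and `set` (the processed `peri_event_set`).
#' @export
process_session <- function(rec, params = photometry_params()) {
  validate_photometry_recording(rec)
  f <- params$downsample_factor
  ds465 <- downsample(rec$ch465, f)
  ds405 <- downsample(rec$ch405, f)
  fs_ds <- rec$fs / f
  sm465 <- smooth_trace(ds465, params$smooth_window)
  sm405 <- smooth_trace(ds405, params$smooth_window)
  rec_ds <- photometry_recording(sm465, sm405, fs_ds,
                                 tone_onsets = rec$tone_onsets,
                                 tone_offsets = rec$tone_offsets,
                                 meta = rec$meta)
  set <- extract_peri_events(rec_ds, params$window)
  set$trials <- lapply(set$trials, function(tr) {
    subtract_isosbestic(detrend_dff(tr, params$detrend_degree))
  })
  valid <- vapply(set$trials, function(tr) tr$valid, logical(1))
  if (!any(valid)) stop("process_session: no valid trials in session")

  pk <- peak_response(set, params)
  auc <- auc_epochs(set, params)
  n_ep <- ncol(auc)
  auc_names <- if (n_ep == 2) c("auc_pre", "auc_post")
               else sprintf("auc_%d", seq_len(n_ep))
  metrics <- data.frame(trial = pk$per_trial$trial, peak = pk$per_trial$peak)
  for (j in seq_len(n_ep)) metrics[[auc_names[j]]] <- auc[, j]
  metrics$valid <- valid

  sel <- metrics$trial %in% params$trials_for_summary & valid
  summary <- list(
    peak_mean = pk$summary,
    auc_mean = colMeans(auc[sel, , drop = FALSE]),
    log_gate = pk$log_gate,
    n_trials_valid = sum(valid))
  out <- list(metrics = metrics, summary = summary, set = set)
  attr(out, "stage_order") <-
    c("downsample", "smooth", "peri_event", "detrend_dff",
      "subtract_isosbestic", "metrics")
  out
}
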