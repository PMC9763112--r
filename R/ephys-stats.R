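# Release-probability and receptor-composition statistics of evoked
# EPSCs: paired-pulse ratio, inverse squared coefficient of variation
# (mu^2/sigma^2), variance-to-mean ratio (sigma^2/mu) and AMPA/NMDA
# ratio, plus the per-cell aggregation row.

#' Paired-pulse ratio
#'
#' Ratio of the second to the first evoked amplitude, eEPSC2/eEPSC1.
#' For vectors of per-sweep amplitudes the cell value is computed as
#' the ratio of the mean amplitudes (`"ratio_of_means"`, default) —
#' what one obtains measuring the averaged sweep; with sweep-to-sweep
#' quantal variability this is the estimator whose expectation matches
#' the generating facilitation, whereas the mean of per-sweep ratios
#' carries an upward Jensen bias of about CV(A1)^2. The per-sweep
#' variant remains available as `"mean_of_ratios"`. Sweeps with
#' `a1 <= 0` are excluded with a warning (ratio undefined).
#'
#' @param a1,a2 first/second evoked amplitudes, pA (scalars or
#'   equal-length vectors).
#' @param method aggregation across sweeps.
#' @return dimensionless PPR.
#' @export
ppr <- function(a1, a2, method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  stopifnot(length(a1) == length(a2))
  bad <- a1 <= 0
  if (any(bad)) {
    warning(sprintf("ppr: %d sweep(s) with eEPSC1 <= 0 excluded", sum(bad)))
    a1 <- a1[!bad]; a2 <- a2[!bad]
  }
  if (!length(a1)) stop("ppr: no sweeps with positive eEPSC1")
  if (method == "ratio_of_means") mean(a2) / mean(a1) else mean(a2 / a1)
}

#' Inverse squared coefficient of variation of evoked amplitudes
#'
#' `1/CV^2 = mu^2 / sigma^2` with the unbiased (n-1) sample variance,
#' conventionally computed over 20 consecutive eEPSCs; under a binomial
#' quantal model its population value is `N p / (1 - p)`. The plug-in
#' estimator is biased upward for small n (about +12% at n = 20 under
#' normality); `bias_correct = TRUE` applies the normal-theory
#' correction `(n-3)/(n-1) * mu^2/sigma^2 - 1/n`, which is exactly
#' unbiased for Gaussian amplitudes and appropriate when averaging
#' many small-n cells against a population value.
#'
#' @param amps per-sweep amplitudes, pA (n >= 2).
#' @param bias_correct apply the small-sample correction.
#' @param expected_n warn when `length(amps)` differs from this
#'   conventional sweep count (set `NA` to disable).
#' @return dimensionless 1/CV^2.
#' @export
inverse_cv_squared <- function(amps, bias_correct = FALSE,
                               expected_n = 20) {
  n <- length(amps)
  if (n < 2) stop("inverse_cv_squared: n >= 2 required")
  if (!is.na(expected_n) && n != expected_n) {
    warning(sprintf("inverse_cv_squared: n = %d (convention is %d)",
                    n, expected_n))
  }
  v <- stats::var(amps)
  if (v == 0) stop("inverse_cv_squared: zero variance (1/CV^2 infinite)")
  plug <- mean(amps)^2 / v
  if (!bias_correct) return(plug)
  if (n < 4) stop("inverse_cv_squared: bias correction requires n >= 4")
  (n - 3) / (n - 1) * plug - 1 / n
}

#' Variance-to-mean ratio of evoked amplitudes
#'
#' `VMR = sigma^2 / mu` (pA) with the unbiased (n-1) sample variance,
#' conventionally over 20 consecutive eEPSCs; under a binomial quantal
#' model its population value is `q (1 - p)`.
#'
#' @param amps per-sweep amplitudes, pA (n >= 2, positive mean).
#' @param expected_n warn when `length(amps)` differs from this count
#'   (set `NA` to disable).
#' @return VMR in pA.
#' @export
vmr <- function(amps, expected_n = 20) {
  n <- length(amps)
  if (n < 2) stop("vmr: n >= 2 required")
  if (!is.na(expected_n) && n != expected_n) {
    warning(sprintf("vmr: n = %d (convention is %d)", n, expected_n))
  }
  m <- mean(amps)
  if (m <= 0) stop("vmr: mean amplitude must be positive")
  stats::var(amps) / m
}

#' AMPA/NMDA ratio from a two-holding-potential sweep pair
#'
#' Peak magnitude of the fast (AMPA-receptor) response at -70 mV
#' divided by the magnitude of the mixed current at +40 mV measured
#' exactly 50 ms after response onset (when the AMPA component has
#' largely decayed and the remaining current is NMDA-receptor
#' mediated). Both measurements are baseline-subtracted over the
#' pre-onset baseline window; magnitudes are used since the sign of
#' the current differs between holding potentials.
#'
#' @param sweep_neg70 [sweep_vc()] at -70 mV.
#' @param sweep_pos40 [sweep_vc()] at +40 mV.
#' @param onset response onset time, s; defaults to the sweeps' first
#'   stimulus time.
#' @param params a [detection_params()] (baseline window and peak
#'   search length).
#' @return dimensionless AMPA/NMDA ratio.
#' @export
ampa_nmda_ratio <- function(sweep_neg70, sweep_pos40, onset = NULL,
                            params = detection_params()) {
  validate_sweep(sweep_neg70); validate_sweep(sweep_pos40)
  if (is.null(onset)) {
    if (!length(sweep_neg70$stim_times)) {
      stop("ampa_nmda_ratio: no onset given")
    }
    onset <- sweep_neg70$stim_times[1]
  }
  bl <- params$baseline_window_ms / 1000

  baseline_of <- function(sw) {
    sel <- sw$t >= onset + bl[1] & sw$t <= onset + bl[2]
    if (!any(sel)) stop("ampa_nmda_ratio: baseline window outside sweep")
    c(mean(sw$i[sel]), stats::sd(sw$i[sel]))
  }

  b_neg <- baseline_of(sweep_neg70)
  sel <- sweep_neg70$t > onset &
    sweep_neg70$t <= onset + params$evoked_search_ms / 1000
  if (!any(sel)) stop("ampa_nmda_ratio: peak search window outside sweep")
  ampa <- abs(min(sweep_neg70$i[sel]) - b_neg[1])

  t50 <- onset + 0.050
  if (t50 > max(sweep_pos40$t)) {
    stop("ampa_nmda_ratio: onset + 50 ms outside the +40 mV sweep")
  }
  b_pos <- baseline_of(sweep_pos40)
  i50 <- stats::approx(sweep_pos40$t, sweep_pos40$i, xout = t50)$y
  nmda <- abs(i50 - b_pos[1])
  if (nmda <= b_pos[2]) {
    stop("ampa_nmda_ratio: NMDA component at/below noise floor; ",
         "ratio undefined")
  }
  ampa / nmda
}

#' Summarize one recorded cell
#'
#' Aggregates whatever sweep roles a cell has into one row: spontaneous
#' event frequency/amplitude/kinetics from the detector, PPR / 1/CV^2 /
#' VMR from the paired-pulse set (statistics taken over the first-pulse
#' amplitudes; PPR as ratio of means), and the AMPA/NMDA ratio from a
#' two-holding-potential pair. Missing roles leave their fields `NA`
#' with a message.
#'
#' @param cell list with optional entries: `spont` (a [sweep_vc()]),
#'   `evoked` (list of paired-pulse [sweep_vc()]s, two `stim_times`
#'   each), `ampa_nmda` (list with `sweep_neg70`, `sweep_pos40`,
#'   optional `onset`), plus optional `id` and `group` labels.
#' @param params a [detection_params()].
#' @return one-row data.frame: `id`, `group`, `freq_hz`, `amp_pa`,
#'   `rise_ms`, `decay_ms`, `ppr`, `inv_cv2`, `vmr`, `ampa_nmda`,
#'   `n_sweeps`.
#' @export
summarize_cell <- function(cell, params = detection_params()) {
  row <- data.frame(
    id = if (is.null(cell$id)) NA_character_ else as.character(cell$id),
    group = if (is.null(cell$group)) NA_character_
            else as.character(cell$group),
    freq_hz = NA_real_, amp_pa = NA_real_,
    rise_ms = NA_real_, decay_ms = NA_real_,
    ppr = NA_real_, inv_cv2 = NA_real_, vmr = NA_real_,
    ampa_nmda = NA_real_, n_sweeps = NA_integer_)

  if (!is.null(cell$spont)) {
    ev <- detect_sepscs(cell$spont, params)
    row$freq_hz <- event_frequency(ev)
    if (length(ev$event_times)) {
      row$amp_pa <- mean(ev$amplitudes)
      row$rise_ms <- mean(ev$rise_times, na.rm = TRUE)
      row$decay_ms <- mean(ev$decay_times, na.rm = TRUE)
    }
  } else message("summarize_cell: no spontaneous sweep; fields left NA")

  if (!is.null(cell$evoked)) {
    amps <- t(vapply(cell$evoked, function(sw) {
      if (length(sw$stim_times) < 2) {
        stop("summarize_cell: evoked sweep needs two stimulation times")
      }
      c(measure_eepsc(sw, sw$stim_times[1], params),
        measure_eepsc(sw, sw$stim_times[2], params))
    }, numeric(2)))
    row$ppr <- ppr(amps[, 1], amps[, 2])
    row$inv_cv2 <- inverse_cv_squared(amps[, 1])
    row$vmr <- vmr(amps[, 1])
    row$n_sweeps <- nrow(amps)
  } else message("summarize_cell: no evoked sweeps; fields left NA")

  if (!is.null(cell$ampa_nmda)) {
    row$ampa_nmda <- ampa_nmda_ratio(cell$ampa_nmda$sweep_neg70,
                                     cell$ampa_nmda$sweep_pos40,
                                     cell$ampa_nmda$onset, params)
  }
  row
}
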