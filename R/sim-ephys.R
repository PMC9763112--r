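# Synthetic voltage-clamp data with known ground truth: Poisson-timed
# spontaneous EPSCs, binomial quantal paired-pulse evoked responses, and
# constructed AMPA/NMDA sweep pairs. Currents are in pA with EPSCs
# negative-going at -70 mV; kinetics parameters are in ms.

#' Configuration for the electrophysiology simulators
#'
#' One configuration object shared by [simulate_sepsc_trace()],
#' [simulate_evoked_sweeps()] and [simulate_ampa_nmda_pair()]; each
#' generator reads the fields relevant to it. Kernel time constants are
#' raw biexponential taus; use [calibrate_biexp_taus()] to derive taus
#' from target *measured* kinetics (10-90% rise, peak-to-1/e decay).
#' Defaults give sEPSC-like events (~2 ms measured rise, ~11 ms decay,
#' ~10 pA) and a facilitating paired-pulse protocol (50 ms interpulse
#' interval, 20 sweeps, as in standard 0.05 Hz PPR recordings).
#'
#' @param fs sampling rate, Hz.
#' @param duration trace duration, s (spontaneous).
#' @param event_rate Poisson sEPSC rate, Hz.
#' @param amp_mean,amp_sd sEPSC amplitude distribution, pA (normal,
#'   truncated positive).
#' @param tau_rise_ms,tau_decay_ms biexponential kernel taus, ms.
#' @param noise_sd Gaussian recording noise SD, pA.
#' @param event_times optional explicit event onset times (s),
#'   overriding the Poisson process (used for isolated-event studies).
#' @param n_sites,release_p,quantal_q binomial quantal model: N release
#'   sites, probability p, quantal size q (pA).
#' @param facilitation multiplier on p for the second pulse;
#'   `p * facilitation` must not exceed 1.
#' @param ipi_ms interpulse interval, ms.
#' @param n_sweeps number of paired-pulse sweeps.
#' @param sweep_dur evoked sweep duration, s.
#' @param stim_onset time of the first stimulus within a sweep, s.
#' @param ampa_peak AMPA current peak magnitude at -70 mV, pA.
#' @param nmda_at_50ms NMDA component 50 ms after onset at +40 mV, pA.
#' @param nmda_tau_ms,nmda_rise_ms NMDA kernel taus, ms.
#' @param ampa_rectification fraction of `ampa_peak` appearing as the
#'   fast outward component at +40 mV.
#' @param seed integer RNG seed.
#' @return list of class `ephys_sim_config`.
#' @export
ephys_sim_config <- function(fs = 10000, duration = 60,
                             event_rate = 2, amp_mean = 10, amp_sd = 1.5,
                             tau_rise_ms = 0.9, tau_decay_ms = 11,
                             noise_sd = 1.5, event_times = NULL,
                             n_sites = 10, release_p = 0.5, quantal_q = 10,
                             facilitation = 1, ipi_ms = 50, n_sweeps = 20,
                             sweep_dur = 0.4, stim_onset = 0.1,
                             ampa_peak = 150, nmda_at_50ms = 50,
                             nmda_tau_ms = 100, nmda_rise_ms = 3,
                             ampa_rectification = 0.4, seed = 1) {
  cfg <- structure(as.list(environment()), class = "ephys_sim_config")
  stopifnot(cfg$fs > 0, cfg$duration > 0, cfg$event_rate >= 0,
            cfg$amp_mean > 0, cfg$amp_sd >= 0, cfg$noise_sd >= 0,
            cfg$tau_rise_ms > 0, cfg$tau_rise_ms < cfg$tau_decay_ms,
            cfg$n_sites >= 1, cfg$quantal_q > 0, cfg$ipi_ms > 0,
            cfg$n_sweeps >= 2, cfg$nmda_tau_ms > cfg$nmda_rise_ms)
  if (cfg$release_p <= 0 || cfg$release_p >= 1) {
    stop("ephys_sim_config: 0 < release_p < 1 required")
  }
  cfg
}

# Truth kinetics of the configured kernel, in ms, under the analyzer's
# definitions (10-90% rise, peak-to-1/e decay).
kernel_truth_kinetics <- function(cfg) {
  list(rise_ms = biexp_rise_time(cfg$tau_rise_ms, cfg$tau_decay_ms),
       decay_ms = biexp_decay_time(cfg$tau_rise_ms, cfg$tau_decay_ms),
       peak_ms = biexp_peak_time(cfg$tau_rise_ms, cfg$tau_decay_ms))
}

#' Simulate a spontaneous EPSC trace
#'
#' Event onsets follow a homogeneous Poisson process at `event_rate`
#' (or the explicit `event_times` in the config); each event adds a
#' negative-going biexponential current with unit-peak kernel scaled by
#' an amplitude drawn Normal(`amp_mean`, `amp_sd`) truncated positive;
#' Gaussian noise is added. The ground-truth event list records peak
#' times, amplitudes, and the kernel's analytic 10-90% rise and
#' peak-to-1/e decay times.
#'
#' @param cfg an [ephys_sim_config()].
#' @return list with `sweep` (a [sweep_vc()] at -70 mV) and `truth`
#'   (an [event_list()]; empty-trace case returns `truth = NULL`).
#' @export
simulate_sepsc_trace <- function(cfg = ephys_sim_config()) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  if (cfg$event_rate * cfg$duration > 1e6) {
    stop("simulate_sepsc_trace: > 1e6 expected events; reduce rate or ",
         "duration")
  }
  with_seed(cfg$seed, {
    n <- floor(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    if (!is.null(cfg$event_times)) {
      onsets <- sort(as.double(cfg$event_times))
    } else {
      n_ev <- stats::rpois(1, cfg$event_rate * cfg$duration)
      onsets <- sort(stats::runif(n_ev, 0, cfg$duration))
    }
    amps <- numeric(length(onsets))
    if (length(onsets)) {
      amps <- stats::rnorm(length(onsets), cfg$amp_mean, cfg$amp_sd)
      while (any(amps <= 0)) {
        bad <- amps <= 0
        amps[bad] <- stats::rnorm(sum(bad), cfg$amp_mean, cfg$amp_sd)
      }
    }
    x <- numeric(n)
    if (length(onsets)) {
      x <- -add_kernels(numeric(n), cfg$fs, onsets, amps,
                        cfg$tau_rise_ms / 1000, cfg$tau_decay_ms / 1000)
    }
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    sw <- sweep_vc(t, x, cfg$fs, holding_mv = -70,
                   meta = list(generator = "simulate_sepsc_trace",
                               seed = cfg$seed))
    truth <- NULL
    if (length(onsets)) {
      kin <- kernel_truth_kinetics(cfg)
      truth <- event_list(event_times = onsets + kin$peak_ms / 1000,
                          amplitudes = amps,
                          rise_times = rep(kin$rise_ms, length(onsets)),
                          decay_times = rep(kin$decay_ms, length(onsets)),
                          source_duration = cfg$duration)
    }
    list(sweep = sw, truth = truth)
  })
}

#' Simulate paired-pulse evoked EPSC sweeps (binomial quantal release)
#'
#' Per sweep, the first-pulse amplitude is `q * Binomial(N, p)` and the
#' second-pulse amplitude `q * Binomial(N, p * facilitation)`; unit-peak
#' biexponential responses are placed at the two stimulation times
#' (interval `ipi_ms`) with linear superposition, plus Gaussian noise.
#' Closed forms hold for the first pulse: `E[A1] = N p q`,
#' `Var[A1] = N p (1-p) q^2`, and for `p * facilitation <= 1` the
#' expected paired-pulse ratio of the generating means equals
#' `facilitation`.
#'
#' @param cfg an [ephys_sim_config()].
#' @return list with `sweeps` (list of [sweep_vc()], each with two
#'   `stim_times`) and `truth` (data.frame: `sweep`, `a1`, `a2` in pA).
#' @export
simulate_evoked_sweeps <- function(cfg = ephys_sim_config()) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  p2 <- cfg$release_p * cfg$facilitation
  if (p2 > 1) {
    stop("simulate_evoked_sweeps: release_p * facilitation > 1")
  }
  with_seed(cfg$seed, {
    n <- floor(cfg$sweep_dur * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    stim <- cfg$stim_onset + c(0, cfg$ipi_ms / 1000)
    if (max(stim) >= cfg$sweep_dur) {
      stop("simulate_evoked_sweeps: stimulation times exceed the sweep")
    }
    a1 <- cfg$quantal_q * stats::rbinom(cfg$n_sweeps, cfg$n_sites,
                                        cfg$release_p)
    a2 <- cfg$quantal_q * stats::rbinom(cfg$n_sweeps, cfg$n_sites, p2)
    sweeps <- lapply(seq_len(cfg$n_sweeps), function(k) {
      x <- -add_kernels(numeric(n), cfg$fs, stim, c(a1[k], a2[k]),
                        cfg$tau_rise_ms / 1000, cfg$tau_decay_ms / 1000)
      if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
      sweep_vc(t, x, cfg$fs, holding_mv = -70, stim_times = stim,
               meta = list(generator = "simulate_evoked_sweeps",
                           seed = cfg$seed, sweep = k))
    })
    list(sweeps = sweeps,
         truth = data.frame(sweep = seq_len(cfg$n_sweeps), a1 = a1, a2 = a2))
  })
}

#' Simulate an AMPA/NMDA sweep pair
#'
#' Constructs the two-holding-potential pair used for AMPA/NMDA ratio
#' measurements: at -70 mV, a fast inward biexponential with peak
#' magnitude `ampa_peak`; at +40 mV, an outward mixed current (fast
#' AMPA component of magnitude `ampa_rectification * ampa_peak` plus a
#' slow NMDA kernel) scaled so that its baseline-subtracted value
#' exactly 50 ms after onset equals `nmda_at_50ms`. The true ratio is
#' `ampa_peak / nmda_at_50ms` by construction.
#'
#' @param cfg an [ephys_sim_config()].
#' @return list with `sweep_neg70`, `sweep_pos40` (both [sweep_vc()]
#'   with `stim_times = stim_onset`), `onset` (s) and `truth_ratio`.
#' @export
simulate_ampa_nmda_pair <- function(cfg = ephys_sim_config()) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  if (cfg$ampa_peak <= 0) stop("simulate_ampa_nmda_pair: ampa_peak > 0")
  if (cfg$nmda_at_50ms <= 0) {
    stop("simulate_ampa_nmda_pair: nmda_at_50ms > 0 required")
  }
  with_seed(cfg$seed, {
    dur <- max(cfg$sweep_dur, cfg$stim_onset + 0.3)
    n <- floor(dur * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    onset <- cfg$stim_onset

    neg <- -add_kernels(numeric(n), cfg$fs, onset, cfg$ampa_peak,
                        cfg$tau_rise_ms / 1000, cfg$tau_decay_ms / 1000)

    ampa_out <- cfg$ampa_rectification * cfg$ampa_peak
    k_fast_50 <- biexp_kernel(0.050, cfg$tau_rise_ms / 1000,
                              cfg$tau_decay_ms / 1000)
    k_slow_50 <- biexp_kernel(0.050, cfg$nmda_rise_ms / 1000,
                              cfg$nmda_tau_ms / 1000)
    b <- (cfg$nmda_at_50ms - ampa_out * k_fast_50) / k_slow_50
    if (b <= 0) {
      stop("simulate_ampa_nmda_pair: fast component already exceeds the ",
           "requested 50-ms value; reduce ampa_rectification")
    }
    pos <- add_kernels(numeric(n), cfg$fs, onset, ampa_out,
                       cfg$tau_rise_ms / 1000, cfg$tau_decay_ms / 1000) +
           add_kernels(numeric(n), cfg$fs, onset, b,
                       cfg$nmda_rise_ms / 1000, cfg$nmda_tau_ms / 1000)
    if (cfg$noise_sd > 0) {
      neg <- neg + stats::rnorm(n, 0, cfg$noise_sd)
      pos <- pos + stats::rnorm(n, 0, cfg$noise_sd)
    }
    list(sweep_neg70 = sweep_vc(t, neg, cfg$fs, holding_mv = -70,
                                stim_times = onset),
         sweep_pos40 = sweep_vc(t, pos, cfg$fs, holding_mv = +40,
                                stim_times = onset),
         onset = onset,
         truth_ratio = cfg$ampa_peak / cfg$nmda_at_50ms)
  })
}
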