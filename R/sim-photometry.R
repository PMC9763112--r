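# Synthetic dual-channel photometry sessions with known ground truth.
# The generative model mirrors what the analysis pipeline assumes it can
# remove: slow exponential photobleaching per channel, brief motion
# artifacts that modulate both channels by the same *fraction*, and
# calcium transients (GCaMP6s-like biexponential kernel) present only in
# the 465 nm channel, time-locked to tone onsets.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Tone schedule for a cued fear session
#'
#' Regular tone schedule: `n_tones` tones of `tone_dur` seconds
#' separated by an inter-trial interval `iti`. The study design this
#' emulates uses 6 x 30 s tones with a 3 min ITI.
#'
#' @param n_tones number of tones (>= 1).
#' @param tone_dur tone duration (s).
#' @param iti inter-trial interval between tone offset and next onset (s).
#' @param first_onset time of the first tone onset (s).
#' @return list with `onsets` and `offsets` (seconds).
#' @export
#' @examples
#' make_tone_schedule(6, 30, 180, 60)$onsets  # 60 270 480 690 900 1110
make_tone_schedule <- function(n_tones = 6, tone_dur = 30, iti = 180,
                               first_onset = 60) {
  if (n_tones < 1) stop("make_tone_schedule: n_tones >= 1 required")
  stopifnot(tone_dur > 0, iti >= 0, first_onset >= 0)
  onsets <- first_onset + (seq_len(n_tones) - 1) * (tone_dur + iti)
  list(onsets = onsets, offsets = onsets + tone_dur)
}

#' Configuration for the photometry simulator
#'
#' Defaults emulate a 6-tone fear-expression session: ~1 kHz effective
#' sampling of the demodulated channels, slow photobleaching (time
#' constant 600 s), occasional motion artifacts shared fractionally by
#' both channels, and tone-locked GCaMP6s transients (rise 0.2 s, decay
#' 1.0 s) whose true peak is `100 * transient_amp_frac` %dF/F. Artifact
#' and bleaching magnitudes are free parameters of the simulator, not
#' claims about any particular dataset.
#'
#' @param fs sampling rate, Hz.
#' @param duration session length, s; `NULL` = 40 s past the last tone
#'   plus 20 s margin.
#' @param baseline465,baseline405 static fluorescence baselines, a.u.
#' @param bleach_amp465,bleach_amp405 initial bleaching amplitudes, a.u.
#' @param bleach_tau bleaching time constant, s.
#' @param motion_frac_sd SD of the shared fractional motion artifacts.
#' @param motion_rate artifact rate, events/s.
#' @param motion_dur artifact width (Gaussian SD), s.
#' @param transient_amp_frac peak fractional dF/F of tone transients.
#' @param tau_rise,tau_decay transient kernel time constants, s.
#' @param noise_sd additive Gaussian noise SD per channel, a.u.
#' @param n_tones,tone_dur,iti,first_onset tone schedule, see
#'   [make_tone_schedule()].
#' @param seed integer RNG seed.
#' @return list of class `photometry_sim_config`.
#' @export
photometry_sim_config <- function(fs = 1017, duration = NULL,
                                  baseline465 = 100, baseline405 = 80,
                                  bleach_amp465 = 20, bleach_amp405 = 15,
                                  bleach_tau = 600,
                                  motion_frac_sd = 0.02, motion_rate = 0.2,
                                  motion_dur = 0.3,
                                  transient_amp_frac = 0.04,
                                  tau_rise = 0.2, tau_decay = 1.0,
                                  noise_sd = 0.3,
                                  n_tones = 6, tone_dur = 30, iti = 180,
                                  first_onset = 60, seed = 1) {
  sched <- make_tone_schedule(n_tones, tone_dur, iti, first_onset)
  if (is.null(duration)) duration <- max(sched$offsets) + 60
  cfg <- structure(as.list(environment()), class = "photometry_sim_config")
  stopifnot(cfg$fs > 0, cfg$duration > 0, cfg$bleach_tau > 0,
            cfg$motion_rate >= 0, cfg$motion_dur > 0, cfg$noise_sd >= 0,
            cfg$tau_rise > 0)
  if (cfg$tau_rise >= cfg$tau_decay) {
    stop("photometry_sim_config: tau_rise < tau_decay required")
  }
  if (max(sched$offsets) > cfg$duration) {
    stop("photometry_sim_config: tone schedule exceeds duration")
  }
  cfg
}

# Adds scaled kernels at given onset times into `x` (in place semantics
# via returned vector); support truncated where the kernel is < 1e-8.
add_kernels <- function(x, fs, onsets, amps, tau_rise, tau_decay) {
  support <- biexp_peak_time(tau_rise, tau_decay) +
    tau_decay * log(1e8 / biexp_peak_value(tau_rise, tau_decay))
  n_sup <- ceiling(support * fs)
  n <- length(x)
  for (j in seq_along(onsets)) {
    k0 <- floor(onsets[j] * fs) + 1L
    idx <- k0:min(n, k0 + n_sup)
    tt <- (idx - 1L) / fs - onsets[j]
    x[idx] <- x[idx] + amps[j] * biexp_kernel(tt, tau_rise, tau_decay)
  }
  x
}

#' Simulate a dual-channel photometry session
#'
#' Generative model (sampled on `t = 0, 1/fs, ...`):
#' \deqn{F_{465}(t) = (B_{465} + A_{465} e^{-t/\tau_b})(1 + m(t)) +
#'   a \cdot F^{trend}_{465}(t_{on}) \cdot k(t - t_{on}) + \epsilon(t)}
#' \deqn{F_{405}(t) = (B_{405} + A_{405} e^{-t/\tau_b})(1 + m(t)) +
#'   \epsilon'(t)}
#' where `m(t)` is a sum of brief Gaussian-shaped fractional motion
#' artifacts common to both channels, `k` is the unit-peak GCaMP kernel
#' and `a = transient_amp_frac`. Because the transient is scaled by the
#' local 465 trend, its true peak is exactly `100 * a` %dF/F per tone.
#'
#' @param cfg a [photometry_sim_config()].
#' @return list with `recording` (a [photometry_recording()]) and
#'   `truth` (data.frame: `trial`, `onset`, `peak_dff` in %dF/F).
#' @export
simulate_photometry <- function(cfg = photometry_sim_config()) {
  stopifnot(inherits(cfg, "photometry_sim_config"))
  with_seed(cfg$seed, {
    n <- floor(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    trend465 <- cfg$baseline465 + cfg$bleach_amp465 * exp(-t / cfg$bleach_tau)
    trend405 <- cfg$baseline405 + cfg$bleach_amp405 * exp(-t / cfg$bleach_tau)

    motion <- numeric(n)
    if (cfg$motion_rate > 0 && cfg$motion_frac_sd > 0) {
      n_art <- stats::rpois(1, cfg$motion_rate * cfg$duration)
      if (n_art > 0) {
        centers <- stats::runif(n_art, 0, cfg$duration)
        amps <- stats::rnorm(n_art, 0, cfg$motion_frac_sd)
        half <- ceiling(4 * cfg$motion_dur * cfg$fs)
        for (j in seq_len(n_art)) {
          c0 <- round(centers[j] * cfg$fs) + 1L
          idx <- max(1L, c0 - half):min(n, c0 + half)
          motion[idx] <- motion[idx] +
            amps[j] * exp(-((idx - c0) / cfg$fs)^2 / (2 * cfg$motion_dur^2))
        }
      }
    }

    ch465 <- trend465 * (1 + motion)
    ch405 <- trend405 * (1 + motion)

    onsets <- cfg$sched$onsets
    if (cfg$transient_amp_frac != 0) {
      trend_at_onset <- cfg$baseline465 +
        cfg$bleach_amp465 * exp(-onsets / cfg$bleach_tau)
      ch465 <- add_kernels(ch465, cfg$fs, onsets,
                           cfg$transient_amp_frac * trend_at_onset,
                           cfg$tau_rise, cfg$tau_decay)
    }
    if (cfg$noise_sd > 0) {
      ch465 <- ch465 + stats::rnorm(n, 0, cfg$noise_sd)
      ch405 <- ch405 + stats::rnorm(n, 0, cfg$noise_sd)
    }
    if (any(ch465 < 0) || any(ch405 < 0)) {
      stop("simulate_photometry: composed fluorescence went negative; ",
           "reduce motion_frac_sd / noise_sd or raise the baselines")
    }
    rec <- photometry_recording(
      ch465, ch405, cfg$fs,
      tone_onsets = onsets, tone_offsets = cfg$sched$offsets,
      meta = list(generator = "simulate_photometry", seed = cfg$seed))
    truth <- data.frame(trial = seq_along(onsets), onset = onsets,
                        peak_dff = 100 * cfg$transient_amp_frac)
    list(recording = rec, truth = truth)
  })
}
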