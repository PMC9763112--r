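#' Biexponential synaptic/indicator kernel
#'
#' Difference-of-exponentials waveform
#' \deqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}, \quad t \ge 0,}
#' optionally normalized to unit peak. Used both for GCaMP calcium
#' transients (time constants in seconds) and for EPSC currents
#' (time constants in milliseconds); the function is unit-agnostic as
#' long as `t`, `tau_rise` and `tau_decay` share a unit.
#'
#' @param t numeric vector of times (same unit as the taus); values < 0
#'   evaluate to 0.
#' @param tau_rise,tau_decay rise and decay time constants,
#'   `0 < tau_rise < tau_decay`.
#' @param normalize if `TRUE` (default) scale so the peak equals 1.
#' @return numeric vector, same length as `t`.
#' @export
biexp_kernel <- function(t, tau_rise, tau_decay, normalize = TRUE) {
  stopifnot(tau_rise > 0, tau_decay > 0)
  if (tau_rise >= tau_decay) {
    stop("biexp_kernel: tau_rise must be smaller than tau_decay")
  }
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  if (normalize) k <- k / biexp_peak_value(tau_rise, tau_decay)
  k
}

#' Peak time of the biexponential kernel (closed form)
#' @inheritParams biexp_kernel
#' @return time of the maximum of `biexp_kernel`.
#' @export
biexp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

biexp_peak_value <- function(tau_rise, tau_decay) {
  tp <- biexp_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Analytic 10-90% rise time of the normalized biexponential kernel
#'
#' Time between the 10% and 90% crossings on the rising phase, located
#' by root bracketing on the noise-free kernel.
#' @inheritParams biexp_kernel
#' @return rise time in the unit of the taus.
#' @export
biexp_rise_time <- function(tau_rise, tau_decay) {
  tp <- biexp_peak_time(tau_rise, tau_decay)
  f <- function(t, level) biexp_kernel(t, tau_rise, tau_decay) - level
  t10 <- stats::uniroot(f, c(0, tp), level = 0.1, tol = 1e-12)$root
  t90 <- stats::uniroot(f, c(0, tp), level = 0.9, tol = 1e-12)$root
  t90 - t10
}

#' Analytic peak-to-1/e decay time of the normalized biexponential kernel
#'
#' Time from the peak until the kernel has fallen to 1/e of the peak,
#' located by root bracketing on the noise-free kernel.
#' @inheritParams biexp_kernel
#' @return decay time in the unit of the taus.
#' @export
biexp_decay_time <- function(tau_rise, tau_decay) {
  tp <- biexp_peak_time(tau_rise, tau_decay)
  f <- function(t) biexp_kernel(t, tau_rise, tau_decay) - exp(-1)
  upper <- tp + 20 * tau_decay
  stats::uniroot(f, c(tp, upper), tol = 1e-12)$root - tp
}

#' Calibrate biexponential time constants to target measured kinetics
#'
#' Finds `(tau_rise, tau_decay)` such that the noise-free kernel has a
#' given 10-90% rise time and peak-to-1/e decay time. This inverts the
#' analyzer's kinetic definitions so simulated events can be generated
#' with a prescribed *measured* rise/decay rather than raw taus.
#'
#' @param rise target 10-90% rise time.
#' @param decay target peak-to-1/e decay time (same unit).
#' @param tol relative tolerance on the recovered kinetics.
#' @return list with `tau_rise`, `tau_decay`, and the achieved
#'   `rise`/`decay`.
#' @export
calibrate_biexp_taus <- function(rise, decay, tol = 1e-8) {
  stopifnot(rise > 0, decay > rise)
  obj <- function(lp) {
    tr <- exp(lp[1]); td <- exp(lp[2])
    if (tr >= td) return(1e6)
    r <- biexp_rise_time(tr, td)
    d <- biexp_decay_time(tr, td)
    (log(r / rise))^2 + (log(d / decay))^2
  }
  init <- c(log(rise / 2.2), log(decay * 0.95))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  tr <- exp(fit$par[1]); td <- exp(fit$par[2])
  out <- list(tau_rise = tr, tau_decay = td,
              rise = biexp_rise_time(tr, td),
              decay = biexp_decay_time(tr, td))
  if (abs(out$rise - rise) > tol * rise || abs(out$decay - decay) > tol * decay) {
    # fall back to a polished refinement if Nelder-Mead stalled
    fit <- stats::optim(c(log(tr), log(td)), obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    tr <- exp(fit$par[1]); td <- exp(fit$par[2])
    out <- list(tau_rise = tr, tau_decay = td,
                rise = biexp_rise_time(tr, td),
                decay = biexp_decay_time(tr, td))
  }
  out
}

# Centered moving-average (single pass, zero-phase by symmetry of the
# window). Edges use shrinking windows so the output length matches the
# input. Used for light pre-detection smoothing of current traces.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
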