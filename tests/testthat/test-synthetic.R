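test_that("tone schedule arithmetic matches the session design", {
  s <- make_tone_schedule(6, 30, 180, 60)
  expect_equal(s$onsets, c(60, 270, 480, 690, 900, 1110))
  expect_equal(s$offsets - s$onsets, rep(30, 6))
  expect_equal(diff(s$onsets), rep(210, 5))

  s1 <- make_tone_schedule(1, 30, 180, 0)
  expect_equal(s1$onsets, 0)
  expect_equal(s1$offsets, 30)

  expect_error(make_tone_schedule(0, 30, 180, 60), "n_tones >= 1")
  expect_error(photometry_sim_config(n_tones = 6, duration = 100),
               "exceeds duration")
})

test_that("photometry generator is seed-deterministic and honors nulls", {
  cfg <- photometry_sim_config(fs = 100, n_tones = 2, tone_dur = 5,
                               iti = 20, first_onset = 10, duration = 80,
                               seed = 7)
  a <- simulate_photometry(cfg)
  b <- simulate_photometry(cfg)
  expect_identical(a$recording$ch465, b$recording$ch465)
  expect_identical(a$recording$ch405, b$recording$ch405)

  # transients, noise and motion all off -> pure scaled exponentials
  cfg0 <- photometry_sim_config(fs = 100, n_tones = 1, tone_dur = 5,
                                iti = 20, first_onset = 10, duration = 40,
                                transient_amp_frac = 0, noise_sd = 0,
                                motion_frac_sd = 0, seed = 7)
  sim0 <- simulate_photometry(cfg0)
  t <- (seq_along(sim0$recording$ch465) - 1) / 100
  expect_equal(sim0$recording$ch465,
               cfg0$baseline465 + cfg0$bleach_amp465 * exp(-t / 600),
               tolerance = 1e-12)
  expect_equal(sim0$recording$ch405,
               cfg0$baseline405 + cfg0$bleach_amp405 * exp(-t / 600),
               tolerance = 1e-12)
})

test_that("transient truth equals the closed-form kernel maximum", {
  cfg <- photometry_sim_config(fs = 250, n_tones = 2, tone_dur = 5,
                               iti = 30, first_onset = 20, duration = 100,
                               transient_amp_frac = 0.05, noise_sd = 0,
                               motion_frac_sd = 0, bleach_amp465 = 0,
                               bleach_amp405 = 0, seed = 1)
  sim <- simulate_photometry(cfg)
  expect_equal(sim$truth$peak_dff, rep(5, 2))
  # direct kernel evaluation: max fractional deviation of ch465 from its
  # flat trend is amp_frac * max(normalized kernel) = amp_frac
  dev <- (sim$recording$ch465 - cfg$baseline465) / cfg$baseline465
  expect_equal(max(dev), 0.05, tolerance = 1e-3)
})

test_that("motion artifacts are identical fractional modulations", {
  cfg <- photometry_sim_config(fs = 200, n_tones = 1, tone_dur = 5,
                               iti = 30, first_onset = 20, duration = 60,
                               transient_amp_frac = 0, noise_sd = 0,
                               motion_frac_sd = 0.05, motion_rate = 1,
                               seed = 42)
  sim <- simulate_photometry(cfg)
  t <- (seq_along(sim$recording$ch465) - 1) / cfg$fs
  tr465 <- cfg$baseline465 + cfg$bleach_amp465 * exp(-t / cfg$bleach_tau)
  tr405 <- cfg$baseline405 + cfg$bleach_amp405 * exp(-t / cfg$bleach_tau)
  frac465 <- sim$recording$ch465 / tr465 - 1
  frac405 <- sim$recording$ch405 / tr405 - 1
  expect_gt(stats::sd(frac465), 0)          # artifacts present
  expect_equal(frac465, frac405, tolerance = 1e-12)
})

test_that("sEPSC generator obeys Poisson counts and noise-free amplitudes", {
  cfg <- ephys_sim_config(fs = 5000, duration = 100, event_rate = 1,
                          noise_sd = 1, seed = 3)
  sim <- simulate_sepsc_trace(cfg)
  # Poisson 99% interval for mean 100 (CDF oracle)
  expect_gte(length(sim$truth$event_times), qpois(0.005, 100))
  expect_lte(length(sim$truth$event_times), qpois(0.995, 100))

  one <- simulate_sepsc_trace(ephys_sim_config(
    fs = 10000, duration = 2, event_rate = 0, event_times = 0.5,
    amp_mean = 12.5, amp_sd = 1e-12, noise_sd = 0, seed = 1))
  # max sample sits within the grid spacing of the continuous peak
  expect_equal(max(abs(one$sweep$i)), 12.5, tolerance = 1e-3)

  none <- simulate_sepsc_trace(ephys_sim_config(
    fs = 5000, duration = 2, event_rate = 0, noise_sd = 1, seed = 1))
  expect_null(none$truth)
  expect_gt(stats::sd(none$sweep$i), 0)

  expect_error(
    simulate_sepsc_trace(ephys_sim_config(duration = 1e5, event_rate = 100)),
    "1e6")
})

test_that("binomial evoked release matches its closed-form moments", {
  cfg <- ephys_sim_config(n_sites = 10, release_p = 0.5, quantal_q = 10,
                          n_sweeps = 5000, sweep_dur = 0.01, fs = 1000,
                          stim_onset = 0.001, ipi_ms = 5, noise_sd = 0,
                          seed = 9)
  sim <- simulate_evoked_sweeps(cfg)
  a1 <- sim$truth$a1
  # E[A1] = Npq = 50, Var[A1] = Np(1-p)q^2 = 250; 3-SE bands
  se_mean <- sqrt(250 / 5000)
  expect_lt(abs(mean(a1) - 50), 3 * se_mean)
  se_var <- 250 * sqrt(2 / (5000 - 1))  # approx SE of sample variance
  expect_lt(abs(var(a1) - 250), 3 * se_var)

  expect_error(
    simulate_evoked_sweeps(ephys_sim_config(release_p = 0.8,
                                            facilitation = 1.3)),
    "> 1")

  # facilitation = 1 -> both pulses share the generating mean
  sym <- simulate_evoked_sweeps(ephys_sim_config(
    n_sweeps = 4000, sweep_dur = 0.01, fs = 1000, stim_onset = 0.001,
    ipi_ms = 5, facilitation = 1, noise_sd = 0, seed = 2))
  expect_lt(abs(mean(sym$truth$a2) - mean(sym$truth$a1)),
            3 * sqrt(2 * 25 / 4000) * 10)
})

test_that("evoked and AMPA/NMDA generators are seed-deterministic", {
  cfg <- ephys_sim_config(n_sweeps = 3, noise_sd = 2, seed = 11)
  s1 <- simulate_evoked_sweeps(cfg)
  s2 <- simulate_evoked_sweeps(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sweeps[[3]]$i, s2$sweeps[[3]]$i)

  p1 <- simulate_ampa_nmda_pair(ephys_sim_config(noise_sd = 1, seed = 4))
  p2 <- simulate_ampa_nmda_pair(ephys_sim_config(noise_sd = 1, seed = 4))
  expect_identical(p1$sweep_pos40$i, p2$sweep_pos40$i)
})

test_that("AMPA/NMDA pair construction fixes the true ratio", {
  sim <- simulate_ampa_nmda_pair(ephys_sim_config(
    ampa_peak = 150, nmda_at_50ms = 50, noise_sd = 0))
  expect_equal(sim$truth_ratio, 3.0)
  # -70 mV sweep peak magnitude is ampa_peak (up to the sampling grid
  # missing the continuous kernel maximum); +40 mV value at
  # onset + 50 ms is nmda_at_50ms, by construction
  expect_equal(max(abs(sim$sweep_neg70$i)), 150, tolerance = 1e-3)
  i50 <- stats::approx(sim$sweep_pos40$t, sim$sweep_pos40$i,
                       xout = sim$onset + 0.05)$y
  expect_equal(i50, 50, tolerance = 1e-9)

  expect_error(
    simulate_ampa_nmda_pair(ephys_sim_config(ampa_peak = -5)),
    "ampa_peak")
  expect_error(
    simulate_ampa_nmda_pair(ephys_sim_config(nmda_at_50ms = 0)),
    "nmda_at_50ms")
})
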