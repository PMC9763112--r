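---
title: "Methods: photometry and release-probability analysis in fearphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry and release-probability analysis in fearphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearphys)
```

fearphys analyzes two kinds of recordings from cued fear-conditioning
experiments — in vivo fiber photometry of BLA calcium activity and ex
vivo voltage-clamp recordings of excitatory synaptic currents — plus
the behavioral summary statistics and the gated statistical tests that
go with them. Because such raw recordings are rarely shareable, the
package ships simulators that generate each input type with known
ground truth, and every analysis stage is validated against those
truths in the test suite.

## The photometry model

The recorded 465 nm (calcium-dependent) and 405 nm (isosbestic)
channels are modeled as a slowly bleaching baseline, multiplied by
shared fractional motion artifacts, plus — in the 465 nm channel only —
tone-locked calcium transients:

$$F_{465}(t) = \big(B_{465} + A_{465}e^{-t/\tau_b}\big)\,(1 + m(t)) +
  a\,F^{\mathrm{trend}}_{465}(t_{on})\,k(t - t_{on}) + \varepsilon(t)$$

with the same structure minus the transient term for $F_{405}$. The
transient kernel $k$ is a unit-peak difference of exponentials with
GCaMP6s-like time constants (rise 0.2 s, decay 1.0 s by default).
Motion and fiber-bending artifacts enter both channels as the *same
fractional* modulation $m(t)$ — the physical assumption that justifies
isosbestic subtraction.

The analysis pipeline (`process_session()`) runs, in order:

1. **Block-mean downsampling** (default 50×): non-overlapping block
   means; averaging doubles as the anti-alias step and makes the
   sample count deterministic.
2. **Zero-phase smoothing**: a 10-sample boxcar applied forward and
   backward (net triangular response, unit DC gain), with reflection
   padding so edges stay outside interior peri-event windows.
3. **Peri-event extraction**: one window per tone onset, −30 s to
   +40 s inclusive, t = 0 at the sample nearest the onset. Trials
   whose window leaves the recording are excluded, never padded —
   padding would corrupt the trend fit.
4. **Per-trial, per-channel linear detrend**: a degree-1 least-squares
   fit of each channel against time over the *full* window is the
   predicted signal; $\Delta F/F = 100\,( \mathrm{raw} -
   \mathrm{pred})/\mathrm{pred}$ (%). The fit window includes the
   transient epoch; the resulting bias is small (the transient's
   integral is a tiny fraction of the 70-s window) and quantified in
   the tests.
5. **Isosbestic subtraction**: corrected = dff465 − dff405. Shared
   fractional artifacts cancel to first order; transients survive.
6. **Metrics**: per-trial peak of the corrected signal over the
   half-open window (0, 5] s after tone onset, and trapezoidal AUC
   over (−5, 0) and (0, 5) s. Session summaries average the first two
   tones, where conditioned responding is strongest before
   within-session extinction. Peak-response results carry a flag
   recommending the log transform to the downstream normality gate,
   since peak amplitudes are right-skewed.

Two analysis choices were genuinely open and are exposed as
parameters: the peak-search window (no printed convention exists; the
default mirrors the first AUC epoch) and the peak's baseline reference
(the peak is read directly off the corrected trace, which is already
locally baselined by the detrend).

**A deliberate caveat.** The prescribed smoothing is not harmless for
fast kernels: at the default rates (1017 Hz → 20.3 Hz after
downsampling) the forward-backward 10-sample boxcar is a triangular
smoother of roughly one second total width, which attenuates the peak
of a 0.2 s/1.0 s transient by about 10%. The pipeline's recovery tests
therefore compare measured peaks against an independently computed
smoothed-kernel oracle (agreement within 5%) and document the ~10–15%
deterministic gap to the raw simulated amplitude. Comparisons *between*
groups processed identically are unaffected.

## Spontaneous EPSC detection

No standard detection criterion exists for these recordings, so the
detector's rules are the package's own and are fully parameterized
(`detection_params()`):

- the trace is smoothed with a light zero-phase moving average (2 ms);
- the threshold is `median − 3.5 · 1.4826 · MAD`, i.e. 3.5 robust
  standard deviations, so it adapts to the noise floor without being
  dragged by the events themselves;
- events are local minima below threshold; minima closer than 5 ms
  are merged (largest kept);
- each event's amplitude is measured against its own pre-onset
  baseline (−10 to −5 ms before the peak), and events below 5 pA are
  discarded — this amplitude floor, not the MAD threshold, is what
  rejects noise excursions.

Kinetics follow common conventions: 10–90% rise time and peak-to-1/e
decay time. Level crossings on noisy traces are biased: a scan from
one side stops early on noise excursions. Per event, the shallow 10%
crossing is scanned backward from the peak (where it is unbiased); the
deep 90% and 1/e crossings, which sit next to the flat peak, use the
midpoint of forward and backward scans, cancelling the bias to first
order. For cell-level kinetics, `event_kinetics()` goes further: it
aligns all events at their 50% rise crossing — the steepest, lowest
jitter anchor, refined by a short local linear fit — and measures
kinetics on the raw-trace average waveform, where noise shrinks by
$\sqrt{n}$ and no smoothing broadens the rise. The peak time and value
are pinned by a local parabola fit (the raw argmin jitters across the
flat peak) and each level crossing is refined by a short local
quadratic fit. In simulation with 200 events at SNR 10 this recovers
generating kinetics to within a few percent, versus ~5–15% for means
of per-event crossings.

## Evoked EPSCs and release-probability statistics

`measure_eepsc()` measures evoked amplitudes against a common baseline
taken before the *first* stimulus (−10 to −1 ms). For the second pulse
of a 50 ms interpulse pair, the first response's remaining tail
(roughly 1–2% of its peak with ~11 ms decay) is removed by
mono-exponential extrapolation fitted over the last 20 ms before the
second stimulus — applied only when the tail is resolvable above the
baseline noise, and toggleable.

The four statistics:

- **PPR** = eEPSC2/eEPSC1. Across sweeps, the default cell value is
  the *ratio of means* (equivalently, measuring the averaged sweep).
  With quantal sweep-to-sweep variability the mean of per-sweep ratios
  is biased upward by Jensen's inequality — approximately $CV(A_1)^2$,
  about +7% under a binomial model with 20 sites at p = 0.4 — so it
  cannot recover the generating facilitation; it remains available via
  `method = "mean_of_ratios"`.
- **1/CV²** = $\hat\mu^2/\hat\sigma^2$ (sample variance, n−1), the
  classical release-probability index; under a binomial quantal model
  its population value is $Np/(1-p)$. The plug-in estimator is ~+12%
  biased at the conventional n = 20 (because $E[1/\hat\sigma^2] >
  1/\sigma^2$); when averaging many small-n cells against a population
  value, `bias_correct = TRUE` applies
  $\frac{n-3}{n-1}\hat\mu^2/\hat\sigma^2 - \frac{1}{n}$, exactly
  unbiased under normality. The default stays plug-in, matching the
  printed definition.
- **VMR** = $\hat\sigma^2/\hat\mu$ (pA); binomial population value
  $q(1-p)$. Its small-sample bias is below 1% at n = 20 and is left
  uncorrected.
- **AMPA/NMDA ratio**: peak magnitude of the fast response at −70 mV
  divided by the baseline-subtracted magnitude of the +40 mV current
  exactly 50 ms after onset (interpolated on the time grid), when the
  fast AMPA component has decayed and the slow NMDA component
  dominates. Magnitudes are used because the current reverses sign
  between holding potentials.

The evoked simulator implements binomial quantal release —
$A_1 = q\,\mathrm{Bin}(N, p)$, $A_2 = q\,\mathrm{Bin}(N,
p\cdot\mathrm{facilitation})$ — so the closed forms
$E[A_1] = Npq$, $\mathrm{Var}[A_1] = Np(1-p)q^2$ anchor the
consistency tests. Junction potentials are not corrected anywhere, in
keeping with the recording convention the analyses assume.

## Statistics and behavior

`gated_two_group_test()` reproduces a common decision procedure:
Shapiro–Wilk normality per group at α = 0.05 (delegated to
`stats::shapiro.test`); on rejection, an optional natural-log
transform (intended for positively skewed peak-calcium data) and
retest; Levene's test (`car::leveneTest`) for homogeneity; then a
two-sided unpaired Student t-test if assumptions hold, otherwise
Mann–Whitney. The Mann–Whitney path is exact when $n_1+n_2 \le 12$
without ties and otherwise uses the normal approximation with tie and
continuity corrections. The full decision trail (normality p, Levene
p, transform) is retained. No multiple-testing correction is applied
anywhere; α = 0.05 two-sided throughout.

`two_way_rm_anova()` implements the mixed (between-group ×
within-time) design with an explicit sums-of-squares partition:
between-subject SS splits into group and subjects-within-group (the
group error term); within-subject SS into time, time × group, and the
within error, with df $(g-1, N-g)$, $(t-1, (N-g)(t-1))$ and
$((g-1)(t-1), (N-g)(t-1))$. By default no sphericity correction is
applied — uncorrected df are reported, matching the convention of the
analyses this layer reproduces — with Greenhouse–Geisser available as
an option. The partition is cross-checked against
`stats::aov(Error(subject/time))` in the tests. Missing cells are an
error, never imputed.

Behavioral formulas are direct: block-1 freezing (mean of tones 1–2,
because extinction may begin within a session), recognition index
$t_{novel}/(t_{novel}+t_{familiar})$, and percent open-arm time.

## What the simulators do and do not emulate

The generators reproduce the statistical structure the analyses rely
on: exponential photobleaching, shared fractional motion artifacts,
tone-locked kernel transients, Poisson event timing, truncated-normal
amplitudes, binomial quantal release, Gaussian recording noise, and a
6 × 30 s tone schedule with 3-minute intervals. They do **not**
emulate hemodynamic contamination, indicator nonlinearity or
saturation, correlated (1/f) noise, series-resistance artifacts,
electrical stimulus artifacts, or bursty/non-Poisson event timing.
Passing recovery tests therefore demonstrates that the estimators are
correct under the stated model, not that real recordings satisfy the
model; artifact and bleaching magnitudes are free simulator parameters,
not claims about any dataset.

## Numerical and interface choices

- Time is seconds everywhere in memory; milliseconds appear only at
  reporting boundaries (event kinetics), preventing ms/s unit bugs
  between the photometry and ephys layers.
- Arrays are float64; CSV interchange serializes doubles with `%.17g`,
  which round-trips IEEE doubles exactly, so save/load is
  bit-identical. (HDF5 vendor formats are out of scope; the CSV
  dialect is the interchange format.)
- Event windows are half-open in sample space; peri-event time axes
  include both printed endpoints on the sample grid.
- Degenerate inputs fail loudly with the violated invariant named:
  non-monotone tone onsets, non-positive predicted signals (division
  guard), zero-variance amplitude sets (infinite 1/CV²), NMDA
  components at the noise floor, incomplete repeated-measures designs.
- Validation never repairs data silently; out-of-bounds photometry
  trials are excluded with a warning, not truncated.
- Seeds: every generator takes an explicit seed and restores the
  caller's RNG state, so identical configurations are bit-identical
  and independent of evaluation order.

## Problem sizes in the test suite

The suite favors sizes that make estimator properties measurable at
desk scale: ten 120-s spontaneous sweeps for frequency recovery, 200
isolated events for kinetics, 200 simulated cells × 20 sweeps for PPR,
500 cells for 1/CV²/VMR population checks, 250 noise-free quantal
cells for closed-form consistency (3-standard-error bands), and 10,000
replicates for the type-I-error check of the gated test (0.05 ± 0.01).
Photometry property tests run shortened sessions (2–3 tones at
100–250 Hz) except where the cancellation and recovery checks need the
design sampling rate of 1017 Hz.

## Known limitations

- Per-event kinetic estimates remain noise-limited at low SNR; use
  `event_kinetics()` for cell-level kinetics.
- The linear detrend assumes bleaching is locally linear over 70 s;
  strongly curved bleaching early in a session leaves a residual
  (mitigated by the isosbestic subtraction, which removes the shared
  component).
- The evoked analyzer assumes stimulus timing is known exactly and
  does not model or remove electrical stimulus artifacts.
- `two_way_rm_anova()` supports one between and one within factor
  only, the design it was built for.
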