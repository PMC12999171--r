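---
title: "Methods: models, parameters and design choices in sensorscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sensorscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorscreen)
```

# Scope

`sensorscreen` implements the quantitative pipeline used when engineering
intensiometric fluorescent neurotransmitter sensors: analysis of
field-stimulation screening movies, the equilibrium and kinetic curve fits
that characterize purified and membrane-displayed sensor protein, and the
direction-selectivity statistics applied to imaging of inhibitory release
in the retina. A synthetic-data module generates every input with known
ground truth, so each stage is verifiable in a closed loop.

# The screening model

## Signal model of a well movie

A well movie is a stack of `height x width` frames at frame rate `r`
(default 256 x 256 px at 50 Hz for 14 s). An expressing pixel carries

    F(t) = B * exp(-t / tau_b) * (1 + s * a(t)) + noise,

where `B` is the baseline brightness (counts; default 1000), `tau_b` the
photobleaching time constant (default 60 s — mild over a 14 s recording,
but enough to leave a clearly detectable trend for the correction step to
remove), `s` the sensor polarity (+1, or −1 for negative-going variants),
and `a(t)` the evoked-transient kernel summed over stimulation epochs.
Non-expressing pixels carry background autofluorescence at 10% of the
control baseline; background bleaches with the same time constant, since
autofluorescence fades under illumination just as the sensor does (and a
"correction" applied to an unbleached background would itself create a
spurious trend — see *Degenerate inputs* below). Noise is additive
Gaussian with SD `sigma_read + sigma_shot * sqrt(F)` (defaults 2 and 1
counts), a simple signal-dependent model that is sufficient for the
rank-test machinery being exercised; expressing pixels additionally get a
log-normal brightness gain (SD 0.2) to mimic expression heterogeneity.

Stimulation epochs default to 1, 10 and 40 pulses delivered at ~83 Hz
within a train (the rate implied by a 12 ms inter-pulse interval), with
onsets at 2, 6 and 10 s. The 4 s inter-epoch spacing is a package choice:
it leaves the full 1.5 s pre-stimulus window and the decaying tail of the
previous response without overlap, and it is configurable.

## The transient kernel

The kernel is piecewise exponential: a rise `1 − exp(−t/tau_on)` from the
epoch onset until `3·tau_on` (95% saturation), then a decay
`exp(−(t − t_peak)/tau_off)`, normalized so its maximum equals the
ground-truth peak |ΔF/F₀| for that pulse count. Pulse-train summation is
absorbed into the per-pulse-count amplitude map rather than modeled per
vesicle-release event.

This shape was chosen deliberately over the classic
difference-of-exponentials `(1 − exp(−t/tau_on))·exp(−t/tau_off)` (still
available as `shape = "dexp"` in `transient_kernel()`). The analysis
fits the rising phase with `A(1 − exp(−(t−t₀)/tau_on))` from onset to
peak and the decay with `A·exp(−(t−t_peak)/tau_off)` after it — the
standard practice for these screens. Under a difference-of-exponentials
kernel the decay acts throughout the rise, and the rise-only fit is then
severely biased (fitting the rise of a 43 ms/73 ms difference kernel
recovers ~15 ms). With the piecewise kernel the generator and the
analyzer agree exactly in the noiseless limit, which is what a
ground-truth generator is for; the difference kernel remains available
for robustness studies.

## Responsive-pixel detection

For every pixel and epoch, the 1.5 s of frames preceding the onset
(`floor(1.5 r)` frames) are compared with the 0.4 s from the onset
(`floor(0.4 r)` frames; the onset frame belongs to the post window) by a
Mann–Whitney U test. A pixel is responsive when p < 0.01 for any epoch
(a raw threshold, deliberately without multiple-testing correction, and a
union over epochs). Design choices:

* **Two-sided test.** The screen that motivated this pipeline discovered
  negative-going sensors with the same machinery, so the detector must
  fire for decreases as well as increases.
* **Ties** are handled with midranks and the tie-corrected variance; the
  degenerate all-tied pixel returns p = 1 (no evidence) rather than an
  error.
* **Exact vs approximate p.** When both samples have ≤ 10 observations
  the null distribution is enumerated exactly (this also serves as the
  oracle in the test suite); the per-pixel path (75 vs 20 frames) uses
  the continuity-corrected normal approximation. At those window sizes
  the exact attainable level of the approximate test at α = 0.01 is
  0.0092 (computed from the exact Wilcoxon distribution), i.e. the
  detector is slightly conservative; the type-I acceptance check compares
  the simulated false-positive rate against this exact value rather than
  against the nominal α.

## Photobleach correction

`F_b(t) = A·exp(−t/τ) + C` is fitted to the frames before the first
epoch onset and after the last response window (onset + 0.4 s post
window + 2 s decay pad), and the series is divided by `F_b(t)/F_b(0)` so
the initial level is preserved. For a movie the fit uses the spatial mean
trace and the same multiplicative correction applies to every pixel —
bleaching is a property of fluorophore and illumination, shared across
the well.

Numerically, data confined to the two ends of a recording make the
three-parameter model weakly conditioned (with τ ≈ 4× the record length
the curvature information is tiny). The fit therefore initializes from
the two segment means (a two-point τ estimate) and minimizes with
Levenberg–Marquardt (`minpack.lm::nls.lm`), which tolerates the
near-degenerate Jacobian; non-convergence falls back to a linear detrend
of the same segments, flagged in the output. A corollary, documented in
the tests: per-well τ_b estimates under full screening noise scatter by
~±20% (the curve itself, which is all the correction needs, is far
better determined than τ_b); the closed-loop τ_b recovery check
therefore runs at low photon noise.

## Pooling and scalar metrics

The well's ΔF/F₀ trace is the mean over responsive pixels of the
corrected intensities, converted per epoch with F₀ = mean of the 1.5 s
pre-window. The peak is the extremum of the 3-frame median-smoothed trace
within the 0.4 s post window (resistant to single-frame noise; the raw
extremum is also reported). Kinetics are fitted per phase, with
log-linear initialization and τ bounded to [1 ms, 10 s]; a phase with
fewer than 4 samples or a failed fit is flagged and reports no τ. The
first frame after the peak — not the peak frame itself, which straddles
rise and decay at finite frame rate — anchors the decay window, capped
1 s past the peak to stay clear of the next epoch. d′ is the pooled-SD
standardized window-mean difference
`(mean_post − mean_pre)/sqrt((var_pre + var_post)/2)`, sign-rectified by
polarity — the standard sensitivity index, adopted because the screen's
"signal-to-noise" measure is otherwise unspecified. Group comparisons are
one-way ANOVA with Tukey HSD (base `aov`/`TukeyHSD`), and fold changes
are reported at one decimal, matching how such screens present them.

At 50 Hz a 43 ms rise spans barely three frames, so closed-loop kinetics
checks acquire at 250–500 Hz (the generator's frame rate is a free
parameter); peaks and expression metrics are validated at the screen's
native 50 Hz.

## QC, normalization and winner selection

Wells with fewer than 4 responsive pixels (or no pooled response) are
discarded; variants with fewer than 3 surviving replicates are flagged
for retesting; a discarded control well rejects the entire plate.
Metrics are normalized per plate as variant replicate mean over control
replicate mean — signed for peaks, so an inverted sensor shows e.g.
−2.2× — and variants whose summed responsive pixels fall below 1800
(strict `<`) are eliminated. The 1800-pixel default corresponds to ~0.6%
of four replicate wells' pixels at full frame size; because that
percentage and the absolute count do not reconcile exactly (0.6% of
4·256² is ≈1573), both the threshold and, for scaled-down plates, the
0.6%-of-variant-pixels rule are configuration options, and the package's
scaled simulations use the percentage form.

Winner selection is two-staged: variants whose |ΔF/F₀| at the ranking
epoch (40 pulses) exceeds the in-plate control with a one-sided
Mann–Whitney p < 0.05 across replicate wells (4 vs 8 — chosen to match
the pipeline's nonparametric machinery at these tiny n; the smallest
attainable p is 1/495), then, of those, variants with normalized
responsive pixels > 1. Ranking is by normalized |ΔF/F₀| at 40 pulses, so
negative-going sensors compete on magnitude. Pooling for screening
metrics happens after per-well QC.

# Curve fits

* **Hill**: `F = Fmin + (Fmax−Fmin)·cⁿ/(EC50ⁿ + cⁿ)`, n free in
  [0.5, 4] and initialized at 1 (whether screens fix n is usually
  unstated; a bounded free n reports cooperativity without letting the
  fit run away). EC50 gets a residual-resampling bootstrap CI (default
  200 replicates). Fits are flagged when a parameter lands on a bound,
  the EC50 leaves the sampled range, or the response range is within
  noise. Maximal response is `(Fmax−Fmin)/Fmin`. Both raw-F and ΔF/F₀
  titrations are supported; on-cell data go through
  `extract_step_amplitudes()` (mean of the last 2 s of each 5 s
  application minus the 2 s preceding onset, half-open windows so the
  onset sample belongs to the application).
* **pH**: the stated sigmoid `F = Fmin + (Fmax−Fmin)/(1+10^(pKa−pH))`.
* **Stopped flow**: monoexponential for t ≥ dead time (default 2 ms);
  the lag-1 residual autocorrelation is reported because a biphasic
  relaxation forced through a monoexponential leaves strongly positive
  residual structure, which is how mono- vs biphasic kinetics are
  distinguished. A pseudo-first-order analysis (k_obs vs concentration →
  k_on, k_off) is provided as an extension.

The synthetic titration studies use 5 replicate series with per-point
noise at 2% of the response range — titration experiments are replicated
and fitted to means, and at realistic plate-reader noise this puts
single-study EC50 recovery comfortably within 10%. (A single series at
5%-of-range noise leaves EC50 with ~20% sampling error; that is a
property of the design, not of the fitter.)

# Direction-selectivity statistics

Implemented exactly as defined for retinal imaging: RAI
`(r_s − r_b)/(r_s + r_b)` with r_s the peak ΔF/F₀ of the trial-averaged
trace in the stimulus window and r_b the mean over the baseline window;
reliability `Var[⟨C⟩_r]_t / ⟨Var[C]_t⟩_r` (1 for identical trials,
→1/R for R trials of pure noise, computed over the stimulus window);
SNR `(R_p − SD_b)/(R_p + SD_b)`; and circular variance
`|Σ R_d e^{i2θ_d} / Σ R_d|`. Notes:

* The **doubled angle** makes CV an axis-tuning statistic: sharper
  tuning gives values nearer 1, and responses at opposite directions
  reinforce rather than cancel. The definition is implemented verbatim;
  a single-angle variant (`double_angle = FALSE`) is provided for true
  direction (not axis) tuning, clearly labeled as the non-default.
  Whether "lower CV" should read as better or worse selectivity is left
  to the user, since the statistic itself is what it is.
* R_d is baseline-subtracted (r_s − r_b) by default and negative values
  are clamped to zero before the circular statistics so CV ∈ [0, 1];
  raw values are preserved in the output.
* Ties for the preferred direction are flagged ambiguous and resolved by
  the response-weighted vector-sum angle.

The trial generator produces a baseline period plus a half-sine response
envelope scaled by a per-direction tuning value (von Mises by default)
with i.i.d. Gaussian noise — sufficient for the statistics' identities
and monotonicity properties, with no pretense of modeling retinal
dynamics.

# Degenerate inputs and numerical conventions

* Frames are 0-based in time (`t = (i−1)/r` for R's 1-based index `i`);
  a window of `w` seconds spans `floor(w·r)` frames; the onset frame
  belongs to the post window.
* A rank test at exactly zero noise is ill-posed: after any
  floating-point-scale residual trend (e.g. dividing by a fitted bleach
  curve), ranks separate perfectly and every pixel looks "responsive",
  because rank statistics are scale-free. Noiseless closure tests
  therefore pool over the ground-truth expressing mask; detector
  behavior is validated at realistic noise, where this pathology cannot
  occur.
* All-tied samples give p = 1; zero pooled variance gives an infinite d′
  with a flag; RAI/SNR/CV with zero denominators return NA with a
  warning; a constant stopped-flow trace is flagged unidentifiable.
* Well movies round-trip through 16-bit multi-page TIFF (counts scaled
  by 1/65535), exact to within one count.
* Identical seeds give bit-identical generator output; per-well seeds
  are derived deterministically from the plate seed.

# Problem sizes used by the simulation studies

The test and acceptance suites scale the screen down to run quickly
while keeping every rule intact: type-I calibration uses 100 null wells
of 16 × 16 px; the selection study uses 20 plates of 6 variants × 4
replicates + 8 controls at 24 × 24 px (two planted winners at 2× and 4×
the control response and higher expressing fraction, four control-like
decoys), with the pixel-elimination threshold at 0.6% of the variant
wells' pixels; kinetics closed loops acquire at 250–500 Hz; bootstrap
coverage uses 100 simulated titrations × 100 resamples. Full-frame
256 × 256 movies are supported (one 14 s well is ~370 MB in memory, so
plate-scale work streams well by well through `simulate_screen()` /
`analyze_screen()`).

# Known limitations

* No optics/PSF simulation, cell morphology, or motion artifacts in the
  generator — synthetic wells are statistically, not visually,
  realistic. Passing closed-loop tests shows the analysis recovers the
  generator's truth under its noise model; real movies add structured
  noise (focus drift, stimulation artifacts) the generator does not
  emulate.
* The responsive-pixel count conflates expression level with response
  amplitude (bright but unresponsive expression is invisible to it), a
  known property of this expression proxy.
* τ_b from a single well is weakly identified (by design of the
  start/end-segment fit); treat per-well bleach constants as nuisance
  estimates, not measurements.
* The screen's statistics are nonparametric but the kinetics fits assume
  single-exponential phases; multi-component decays are not modeled
  (the stopped-flow module's autocorrelation diagnostic is the tool for
  spotting them).
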