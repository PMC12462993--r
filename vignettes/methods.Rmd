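---
title: "Methods: tactile information flow between S1 and M1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tactile information flow between S1 and M1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graspflow)
```

This vignette is the package's own account of the science it implements:
the models and procedures, their assumptions, the parameters that matter,
and the choices made where the design was genuinely open. Code chunks are
illustrative and not evaluated when the package is built.

# The problem

During grasping, tactile properties of the object — surface texture felt
at contact, load felt as the grip is maintained — are encoded in both the
primary somatosensory cortex (S1) and the primary motor cortex (M1).
`graspflow` quantifies three things: (1) *where and when* texture and load
are represented in single-unit and population activity; (2) *which way*
tactile information travels between S1 and M1, via directed functional
connectivity; and (3) whether intracortical microstimulation (ICMS)
delivered to S1 engages the same S1→M1 pathway strongly enough to steer
M1 representations, force decoding, and the actual grip force, without
any training of the subject.

All analyses operate on a `SessionBundle`: spike trains (sorted units or
threshold-crossing multi-unit channels), a trial table with cue / touch /
hold-end timestamps, a continuous grip-force trace, and ICMS train
records. Times are stored in seconds on the session clock; every analysis
interface speaks milliseconds relative to an alignment event. Analysis
windows are half-open `[start, start + width)` so a spike on a boundary
belongs to exactly one window.

# Windowed effect decomposition

Per unit, firing rates in 200 ms windows stepping 50 ms are submitted to
a two-way ANOVA (texture × load), and each factor's effect size is the
fraction of summed squares

$$\eta_i^2 = \frac{SS_i}{SS_{tex} + SS_{load} + SS_{tex\times load} + SS_{err}}.$$

Sums of squares are Type II (`car::Anova`); the default design is
balanced, where Type II equals Type I, so the choice only matters for the
mildly unbalanced 25–30-trials-per-cell case. A window with zero response
variance is returned as a degenerate all-zero row rather than an error,
because silent windows are common in real recordings. When the model fit
is perfect (zero residual), the Type-I table is used directly and factor
p-values degenerate to 0 — the decomposition is exact in that case.

The tuning grid holds 23 window starts from −200 to +900 ms around touch.
The corrected significance threshold is
`alpha / (nFactors * nWindows / nInclusion)` — 0.05/(3·23/5), reported to
four decimals as 0.0036 — and a unit is retained when at least five
windows are significant for texture *or* at least five for load; the
interaction factor does not count toward inclusion. The stated analysis
range (−200 to 1000 ms) and the 23-point window count are mutually
inconsistent for a 200/50 ms grid; the package fixes 23 starts (−200..900,
spikes up to +1100 ms) and leaves the grid fully configurable through
`windowGrid()`.

Stage comparisons (touching T, −50..150 ms vs grasping-and-holding GH,
350..550 ms) use Wilcoxon signed-rank tests on per-unit stage-mean η²
(exact distribution below 25 units, normal approximation with continuity
correction above). A window belongs to a stage when its center falls
inside the stage span.

# Population decoding

Tactile classification uses a Gaussian-kernel SVM as a fixed contract:
cost 1, kernel scale 1/d on features standardized with training-fold
statistics only (no leakage), stratified k-fold cross-validation with the
fold split reused across windows so accuracy time courses are comparable.
These hyperparameters are deliberately not tuned — the classifier is a
measurement device here, not a contribution — and fixing them makes runs
reproducible. Features are 50 ms binned rates (4 bins per 200 ms window).
Unit-dropping curves remove units in ascending order of a sensitivity
score (so the most texture- or load-sensitive units are retained longest)
or in random order averaged over 10 seeded repeats, and report the
smallest retained fraction reaching 95% of the ordering's top accuracy.

# Non-parametric conditional Granger causality

Spike trains of the ten highest-rate units per region (ties broken by
unit id) are binned at 1 ms, mean-subtracted per trial, tapered with 3
Slepian tapers (time-bandwidth 2) and Fourier-transformed; trials are
treated as independent realizations of the cross-spectral density. The
frequency grid runs to the 500 Hz Nyquist; the FFT length defaults to at
least twice the window length so that the sample CSD's full lag support
is represented on the factorization circle.

Wilson's iterative spectral matrix factorization computes
`S(f) = H(f) Σ H*(f)` with a causal, minimum-phase `H`. The iteration is
initialized from the Cholesky factor of the lag-0 covariance and
converges when the relative update of the spectral factor drops below
`tol` (default 1e−9, typically 5–10 iterations). Two numerical details
matter. First, the causal-part operator must split *both* self-conjugate
lags: the lag-0 term (upper-triangular convention, halved diagonal) and
the Nyquist lag (halved), because the Nyquist lag coincides with its own
mirror on the circle; keeping it whole double-counts it and the iteration
stalls, while dropping it leaves a small systematic reconstruction error.
With the even split, reconstruction residuals reach machine precision on
both analytic VAR spectra and spike CSDs. Second, a rank-deficient lag-0
covariance (reciprocal condition number below 1e−10) is rejected
outright; a relative diagonal loading (`ridge`, default 1e−6 of mean
power inside `conditionalGC()`) stabilizes near-singular spike spectra.

The conditional measure from source *j* to target *i* given conditioning
set *k* factorizes the reduced `(i, k)` and full `(i, j, k)` systems,
embeds the reduced transfer function into the full variable space
(identity row/column for *j*), applies the partition transform that
removes instantaneous correlation between the target innovation and the
remaining channels, and evaluates

$$I_{j\to i|k}(f) = \ln\frac{\Sigma^{(i,k)}_{ii}}
{|\tilde Q_{ii}(f)|^2\,\Sigma^{(i,j,k)}_{ii}}.$$

The time-domain scalar is the arithmetic mean of the spectral measure
over the one-sided grid — the discrete Geweke integral — with negative
spectral values floored at zero (non-parametric estimates can dip
microscopically below zero; the floor records the convention). On
bivariate VAR fixtures the scalar agrees with the parametric Geweke value
to well within the estimation noise of the spectral route.

The conditioning set of a pair holds the remaining selected units of the
*target's* region (S1→M1|M1 and M1→S1|S1), capped (default 8) for
tractability; the paper-faithful 11-variate setting is obtained by
raising the cap.

## Jitter null and condition effects

Significance of a stage CGC (T: −100..200 ms; GH: 300..600 ms — 300 ms
windows matching the estimator) is assessed against surrogates in which
every spike of the involved units is displaced independently and
uniformly within ±10 ms, within trial, then re-windowed (jittered spikes
may cross the window border; they are re-binned from the extended
raster). Thirty surrogates are drawn and the observed value must strictly
exceed their 95th percentile. The empirical percentile is the ceiling
order statistic (type-1 quantile): interpolated percentiles are
anticonservative at this surrogate count (true null exceedance ≈7.9%
versus ≈6.4% for the order statistic, against the nominal 5%). Surrogate
RNG streams derive from (pair, stage, surrogate index), so parallel or
repeated runs reproduce.

Condition dependence of a pair's CGC draws 20% of each condition cell's
trials with replacement (`round(frac * n)`, so 6 of 30) twenty times,
computes stage CGC per draw, and runs the two-way texture × load ANOVA
across draws. Treating resamples as replicates is pseudo-replication;
the procedure is reproduced as designed, and its p-values should be read
as descriptive. PCA of condition-concatenated CGC time courses is
centered and unscaled, with each component's sign fixed so its
largest-magnitude loading is positive.

# ICMS response characterization

Only the first 10 ms after each pulse are analyzed (the highest train
frequency is 100 Hz), with the first 3 ms and the final 1 ms of each
cycle excluded as stimulation artifacts, leaving the 3–9 ms window; the
counted time per pulse epoch is therefore exactly 6 ms. Per-pulse rates
against the matched sham baseline are compared with a two-sided rank-sum
test (the test statistic is a package choice; only the threshold is
prescribed): elicitation requires p < 0.01, a positive difference, and a
mean post rate of at least 2 Hz — the "normalized firing rate" guard is
read as the blanking-corrected mean rate in the 3–9 ms window — while a
significant decrease marks inhibition.

Pulse-triggered averages use 0.5 ms bins over 3–9 ms. The phase-locking
index is the mean of the highest-probability bin and its adjacent bins
(available neighbors only at the edges, no wraparound) minus the median
bin probability; it is invariant under pulse relabeling and uniform
probability offsets. The shuffle null samples 20% of pulse epochs
(reading "20% of PTAs" as pulse epochs), redistributes their spikes
uniformly over the non-blanked bins with the spike count preserved, and
repeats 1000 times; significance requires strictly exceeding the 99th
percentile (again the order statistic).

# Stimulation-pair design

The original site selection was partly manual; the package replaces it
with an explicit score faithful to its two stated principles. Channels
are ranked by single-channel tactile classification accuracy (50 ms bins,
0–500 ms, stratified 10-fold CV), with sensitivity decided by a
label-permutation test on the accuracy (200 permutations, p < 0.05) — the
quantitative counterpart of visual PSTH inspection. A site's gap
contribution on a sensitive channel is the channel's preferred sign times
the site's response-map magnitude; sites whose significant contributions
carry mixed signs are excluded, and the admissible assignment maximizing
the summed signed score becomes pair D, its swap pair C (the swap negates
the score exactly). The weak pair W takes the two sites with the fewest
significantly modulated channels (then smallest summed magnitude, then
site index). Scores weigh response magnitudes only, not channel
accuracies: magnitude is what superposes on the firing-rate gap.

# Day-2 modulation indices

All day-2 features are aligned to stimulation onset and blanked
identically for stimulated and control trials and for training and
testing data: within the 1 s train, the first 3 ms and last 1 ms of every
10 ms cycle are removed and rates are corrected by the counted time
(60% of a fully covered bin). Blanking keys on the stimulation schedule
(scheduled onset exists for control trials too), never on the amplitude,
so a sham train yields bit-identical features.

I_ACC compares tactile classification of day-2 stimulated versus control
trials under a decoder trained only on day-1 (no-ICMS) trials of channels
with significant tactile main effects (p < 0.05), on 40 ms bins, 5-bin
windows, 1-bin step. The force-decoding bias trains a linear-kernel
support-vector regression on day-1 windows against window-mean force;
`Bias(t) = (F_dec − F_real)/F_real` on trial-averaged forces, and the
index of decoding bias is implemented as the plain difference
`Bias_ICMS − Bias_NONE` (the bias is already normalized by the real
force). Denominators below a configurable floor (default 5% of the peak
condition-mean force) yield missing windows rather than blow-ups. I_F is
the relative trial-averaged force difference per window with a block
summary over the 300–700 ms comparison window; I_N is the stratified
5-fold cross-validated accuracy of classifying stimulated versus control
trials (the CV scheme for this index is a package default). The headline
neural-behavioral correlation uses block-level mean I_N over 140–500 ms
and mean I_F over 200–700 ms, with the full window × window correlation
matrix available for inspection.

# The synthetic-session generator

Spike trains are discretized conditionally-Poisson processes: per 1 ms
bin, a spike occurs with probability `1 − exp(−λΔ)`, with

```
log λ(t) = log(baseline) + αtex·stex·gtex(t) + αload·sload·gload(t)
           + αint·stex·sload·gint(t) + Σ_edges gain·(kernel ∗ source spikes)
```

where `stex`, `sload` are centered ordinal condition scores and the
temporal kernels are Gaussians peaking at +50 ms (texture, inside the
touching stage) and +450 ms (load, inside grasping-and-holding). The
log link makes tuning and coupling superpose multiplicatively, and the
log-rate is clipped (default at log 200 Hz) to avoid pathological bins.
Directed coupling uses alpha-function kernels with 3–6 ms latencies,
mirroring phase-locked cortico-cortical lags. Sessions follow the
mirrored-block design: nine condition cells in a seeded order, then the
same cells reversed, about 30 trials per cell (minimum 25), 270 trials in
total. The force trace rises after touch to a load-ordered plateau in
arbitrary units (no attempt to model newtons). One RNG stream per session
is derived from the master seed by hashing a purpose key, so the same
(config, seed) reproduces bit-identically and different sessions of one
experiment are independent.

Rest-state ICMS sessions deliver 1 s trains at 4 s onset spacing, 14
repetitions per site × parameter set plus matched sham trains, with the
monkey-A parameter ladders (20/50/80 µA at 100 Hz; 10/25/50/100 Hz at
80 µA) as defaults. Responses follow a per-(site, channel) taxonomy:
phase-locked excitation adds a Bernoulli extra spike 3–6 ms after each
pulse with probability scaling with amplitude and, above 25 Hz, frequency
(`freqBoost`, default 1.5); non-phase-locked excitation multiplies the
rate throughout the train; inhibition thins it. Spikes falling into the
artifact blanks of non-sham trains are removed, as threshold crossing
cannot recover them.

The two-day stimulation experiment shares one population across the
day-1 grasping session, the rest-state mapping session, and day-2.
Three regime choices deserve comment:

* **Task-gain scale** (default 0.1): rest-state response gains are scaled
  down when superposed on task activity. Stimulation effects during
  active behavior are perturbative — the study's accuracy indices are a
  few percent — and unscaled gains push stimulated trials far outside the
  day-1 decoder's training distribution, where a Gaussian-kernel SVM's
  decision saturates and accuracy collapses for *any* stimulation,
  contrary to the directional effects the design produces.
* **Structured response truth**: stimulation sites preferentially excite
  M1 channels sharing one tactile preference (and may inhibit the
  opposite group), with a subset of quiet sites. Under a fully random
  taxonomy essentially no site passes the mixed-sign exclusion rule, so
  the design stage would have nothing to select — real projection
  patterns are spatially structured, and the study's selection succeeded.
* **Tactile gate** (SD 0.4): per-(site, channel) gains scale with the
  trial's tactile score, producing the stimulation × tactile interactions
  observed in a quarter of channels; a per-block log-normal gain shared
  by neural and force effects, plus a force deviation proportional to the
  net signed M1 rate modulation starting 300 ms after train onset, ties
  the neural index to the force index by construction. The
  neural-to-force proportionality constant is a free parameter
  (`forceCoupling`, default 0.6); the study gives no quantitative value.

What the generator does *not* emulate: biophysical membrane dynamics,
refractoriness and oscillatory structure; electrode geometry and the
spatial layout of arrays; raw artifact waveforms (artifacts enter as
blanked intervals); behavioral variability in reach kinematics; and
session-to-session nonstationarity. Passing tests therefore demonstrate
that the estimators recover the *statistical structure they assume* at
realistic rates and trial counts — not that they are robust to every
failure mode of real recordings.

# Verification strategy and problem sizes

Every estimator is checked against an independent oracle: the ANOVA
decomposition against explicit group-mean sums of squares; the Wilson
factorization against analytic VAR transfer functions; conditional GC
against the parametric Geweke value computed from VAR coefficients via
the Kolmogorov formula; coupling kernels against cross-correlogram peaks;
phase-locked response gains against their closed-form per-pulse
probabilities. Surrogate tests are calibrated on null fixtures
(independent Poisson units: 100 pairs for the jitter null, 200 channels
for the phase-locking null) and powered on planted-effect fixtures (20
unidirectional pairs; 20 generator seeds for the end-to-end direction
checks at 60-trial day-2 blocks). These sizes were chosen to give stable
fractions at useful statistical resolution while keeping the default
suite in the minutes range; all of them scale through function arguments.

One deliberate deviation from a natural reading of the design: the
force-decode bias direction check runs on the grasping stage (0–280 ms
after onset) rather than holding. In the generator the actual force of
stimulated trials deviates from 300 ms after train onset — that is the
designed neural-to-force coupling — and during holding this deviation
enters the Bias denominator and masks the decode-side sign; before the
300 ms lag the decode-side effect is isolated and the directional pattern
(D amplifies the decoded gap, C opposes it, per the condition's force
demand) is clean.

# Known limitations

* The resampling-with-replacement condition ANOVA inherits the original
  design's pseudo-replication; its p-values are descriptive.
* The non-parametric CGC needs enough spectral realizations
  (trials × tapers) relative to the conditioning-set size; with few
  trials the 11-variate conditioning of the full design is not
  estimable, which is why the cap exists.
* SVM/SVR hyperparameters are fixed contracts, not tuned optima; absolute
  accuracies should not be compared across feature dimensionalities.
* The generator's Bernoulli discretization slightly underweights
  multiple spikes per 1 ms bin at very high rates; the log-rate ceiling
  bounds the error.
* Real percentages and correlations from the original recordings are not
  reproducible from synthetic data; directions and calibrations are the
  testable surface.
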