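---
title: "Local use-dependent sleep in wakefulness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local use-dependent sleep in wakefulness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`localwake` implements an analysis chain linking *local use-dependent sleep*
— brief, spatially circumscribed sleep-like episodes in the waking EEG,
indexed by individual delta (1–4 Hz) half-waves — to performance errors in a
prolonged, repetitive wayfinding task. Because no raw data from such studies
are deposited, the package ships synthetic behavioral and EEG generators
with full ground truth; every analysis stage is exercised, and its
operating characteristics measured, against data whose true structure is
known. This vignette explains each stage's model and assumptions, the
tunable parameters, what the generators do and do not emulate, and the
numerical choices that an auditor or maintainer would want spelled out.

## The behavioral model

A session is a contiguous sequence of *retrievals*: navigation trials from a
start landmark to a target landmark, repeated over a small set of routes.
Two series summarize performance: completion time (s) and path length
("units", maze units). Each route's *optimal path* is the Euclidean distance
between its endpoint coordinates, and the percentage deviation of a set of
retrievals is

$$\mathrm{Deviation} = \frac{1}{N}\sum_{i=1}^{N}
  \frac{\mathrm{Optimal}_i - \mathrm{Units}_i}{\mathrm{Optimal}_i}\times 100,$$

which is nonpositive (travelled paths cannot beat the straight line) and
moves toward 0 as performance improves.

**Breakpoint.** Learning stabilizes at a change-point. `find_breakpoint()`
standardizes the time and unit series *within route type* (routes differ in
length, which would otherwise dominate the variance), fits each series by
exact least-squares mean-shift segmentation (dynamic programming over
cumulative sums, so the segmentation is provably optimal), selects the
number of breaks 0–3 by BIC with the penalty $(2k+2)\log n$ (segment means,
break positions, one variance), and takes the *first* break of each series.
The subject's breakpoint is the farther of the two from the series start.
Minimal segment length defaults to 15 % of the series, the conventional
trimming of least-squares break estimation; without trimming, late clusters
of error outliers occasionally produce a spurious short end segment that the
farthest-of-two rule then latches onto. Zero breaks in both series raises a
no-stabilization error and the subject is skipped.

**Error classification.** Errors exist only after the breakpoint. A
post-breakpoint retrieval is an error when its duration *or* its units
exceed the Tukey upper fence $Q_3 + 1.5\,\mathrm{IQR}$ (`outlier_rule =
"and"` is available). By default the fences are computed on the pooled
route-standardized values: durations and units are z-scored within route
over the post-breakpoint retrievals and a single fence is applied to each
pooled series. The per-route alternative (`fence_scope = "per_route"`) is
statistically fragile here: with roughly 30 post-breakpoint retrievals per
route and realistic error rates, a single route regularly accumulates more
than 25 % errors, which places $Q_3$ among the error trials and destroys the
fence. The pooled-standardized variant keeps the motivation for per-route
standardization (route-specific scale) while computing quantiles from the
full post-breakpoint sample. Fences are always $Q_3 + 1.5\,\mathrm{IQR}$
with *strict* exceedance, so an all-identical series yields no outliers
while a single deviant value above $Q_3$ is still flagged when the IQR is
degenerate.

**Best hits** are the route minima among post-breakpoint hits. A retrieval
counts as a best hit when it attains the route minimum in units *or* in
time (default); the strict both-minima rule is available
(`best_hit_rule = "both"`) but is empty for most routes under independent
trial noise, which is inconsistent with the double-digit best-hit counts
such tasks produce.

**Temporal intervals.** The post-breakpoint session time is divided into k
equal, contiguous, half-open intervals (k = 2 for the error/hit analysis,
k = 4 for the task-versus-control time course), anchored at the breakpoint
retrieval's start time; retrievals are assigned by their start time. A
control session can be partitioned on the clock of the wayfinding cohort by
passing explicit anchor times.

## The spectral chain

Preprocessing follows the standard waking-EEG pipeline: second-order
Butterworth 0.5–45 Hz band-pass applied forward and backward (zero net
phase, which matters for wave morphology), exclusion — not interpolation —
of bad channels, decimation to 125 Hz (the 45 Hz edge is below the decimated
Nyquist frequency, so plain decimation cannot alias), and common-average
re-referencing over the remaining scalp channels. The quality gate of at
least 100 good channels reflects dense-array recordings; synthetic montages
pass an explicit lower bound instead.

Welch power spectral densities use 4 s Hamming-tapered non-overlapping
windows cut from each retrieval's span (trailing remainders and windows
overlapping artifact spans are discarded), giving 0.25 Hz bins at
0–62.5 Hz. The density normalization is one-sided with taper power
correction, so the density summed over bins times the bin width equals the
signal variance; the test suite asserts this Parseval identity and checks
the estimator bin-by-bin against a direct DFT oracle. Band power is the
*mean* density over the band's bins (inclusive endpoints: 13 delta bins at
1–4 Hz, 14 theta bins at 4.25–7.5 Hz), log10-transformed after averaging.
The theta band is also reported as 4.5–7.5 Hz in parts of the source
literature; `spectral_bands(theta_lo = 4.5)` selects that variant.
Windows are pooled per condition (errors/hits × temporal interval, plain
intervals, or the 16-retrieval baseline) *before* Welch averaging, so each
condition's estimate is a single average over all its windows.

## Delta half-waves

The off-period proxy is the individual negative delta half-wave. The signal
is re-referenced to the mastoid average, low-pass filtered at 4 Hz with a
sixth-order Chebyshev type-II filter (stopband 8 Hz at 40 dB, passband
ripple below 4 Hz under 0.02 dB at 125 Hz — verified at design time via the
frequency response; the filter is applied forward-backward, so attenuation
doubles in dB and net phase cancels). Half-waves are negative deflections
between two consecutive zero crossings, located by linear interpolation
between samples, with a sample exactly at zero opening the following
segment. The crossing-to-crossing duration must lie in 0.125–0.5 s — the
half-period range of 1–4 Hz full waves. Events are assigned to the
retrieval containing their negative peak.

Because the detector has no amplitude floor, every recording produces a
tail of small noise deflections. Following standard practice, all
detections of a subject are pooled per channel across the task, each
event weighted by the reciprocal of its retrieval's duration
(standardizing for retrieval length), and only events whose negative peak
magnitude strictly exceeds the weighted 80th percentile (linear
interpolation; plotting positions reduce to the type-7 quantile under
equal weights) are retained as *delta waves*. The unweighted percentile is
available via `weighting = "none"`. Summaries per scalp region × condition
report events per minute of condition time, averaged over the region's
electrodes, and the mean negative peak.

## Cluster-based permutation statistics

Topographic condition differences are tested with the cluster-based
permutation test for paired designs: per-channel dependent-sample t values,
channels exceeding the two-tailed critical value at p = 0.05 clustered into
connected sets (positive and negative channels separately) on a sensor
adjacency graph, cluster mass = the sum of t within the cluster, and the
Monte-Carlo reference distribution of the *maximum* cluster mass obtained by
randomly swapping the two conditions within subject. Each observed cluster's
p is `(1 + #{max-null >= mass}) / (1 + n_perm)`, which is never zero and has
the granularity the permutation count allows. Adjacency derives from sensor
positions with a distance threshold chosen so the median neighbor count is
about six, the usual density for scalp montages; the threshold is
configurable. Sign flips are vectorized (the per-channel mean square is
invariant under sign flips, so only permuted means are recomputed), which is
what makes the 500-run × 1000-permutation calibration experiment in the
acceptance suite affordable.

## Univariate statistics and effect sizes

The remaining statistics wrap base R where base R is correct: one-tailed
paired t tests with Bonferroni correction, Spearman correlations (average
ranks, t-approximation p), and a ranked analysis of covariance that ranks
pre- and post-test scores ignoring group, regresses post-ranks on pre-ranks,
and runs a one-way ANOVA on the residual rank scores. The Wilcoxon
signed-rank test implements Pratt zero handling (zeros ranked, then
dropped) with an exact null distribution obtained by convolving the
retained ranks on a doubled integer grid (exact up to n = 25; ties produce
half-integer ranks, hence the doubling), falling back to the
continuity-corrected normal approximation. Effect sizes use the
two-group-equivalent conversions $d = |t|\sqrt{2/n}$ and
$d = 2|r|/\sqrt{1-r^2}$, which reproduce the published worked examples the
acceptance suite pins. PVT summaries use the conventional 500 ms lapse
cutoff (configurable) and mean reciprocal reaction times, with the slowest
decile delimited by the linearly interpolated 90th percentile. A published
r-type effect size for signed-rank tests is *not* reproduced here: no single
z-based convention recovers those printed values, so the conversion is left
unimplemented rather than guessed.

## The path model

Four per-subject variables form a recursive chain: *repetition-dependent
improvement* (deviation from optimal before the first error, per route,
combined by a weighted average with per-route best-hit counts as weights,
then divided by the number of pre-first-error repetitions — the
multiplicative composition is available via `composition = "product"`;
the weighting prose in the source literature is ambiguous and both
readings are provided), *use-dependent saturation* (clock time of the first
error), *local sleep in wake* (mean regional log delta power during
second-interval errors; scalp regions stand in for source-space activity,
which is out of scope), and the *second-interval error count*.

`fit_path_model()` standardizes the variables and fits the chain
improvement → saturation → local sleep → errors by maximum likelihood on
the implied versus observed covariance matrix. For a recursive
observed-variable chain the ML point estimates coincide with per-equation
least squares (the suite asserts this to 1e−6), and the free parameters are
3 paths + 4 residual variances, leaving df = 10 − 7 = 3. Fit indices follow
the mainstream conventions: $\chi^2 = (n-1) F_{ML}$; SRMR as the root mean
squared standardized covariance residual over the 10 unique elements;
$\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$; CFI against the
independence model; and AIC as $-2\log L + 2k$ with k = 7 (model) and
k = 10 (saturated). Under the true chain the suite verifies a zero
discrepancy on the population covariance, parameter recovery to ±0.03 at
n = 2000, and an empirical $\chi^2$ mean of ≈ 3 at n = 500.

## What the generators emulate — and what they do not

`gen_behavior()` produces a contiguous session (each retrieval starts when
the previous ends) whose duration and path-excess series decline gently
before the configured breakpoint (20 % of the baseline-to-stable gap) and
drop to a stationary level at it. Defaults mirror a ~2 h, 295-retrieval
session over 8 routes with 16 baseline retrievals and a breakpoint near
retrieval 62. Baseline durations default to 45 s against a stable 20 s, and
path excess to 1.0 (paths twice the optimum during early exploration)
against a stable 0.10. These contrasts are deliberately strong: errors
multiply duration and units by 3 (outliers "in time and units"), and the
resulting spikes inflate the post-breakpoint mean and spread; a weak
learning contrast would leave the stabilization statistically invisible
behind them, contradicting the premise that the task has a detectable
breakpoint. Error probabilities rise from 0.10 to 0.24 across the two
post-breakpoint halves (defined on the pre-inflation timeline). Not
emulated: continuing slow improvement after the breakpoint (the generator
is stationary there, so the second-half *best-hit* increase seen in real
learning curves does not arise — our synthetic cohorts can even show the
reverse, since best hits fall uniformly over a half with fewer eligible
hits), within-session fatigue drifts in durations, and any trace-level
detour geometry (traces are summarized by units only; an optional
trace-divergence flag is out of scope).

`gen_eeg()` synthesizes each channel as pink noise (power slope 1.5, 3 µV
RMS) plus a 10 Hz alpha rhythm (15 µV) and a 6 Hz theta rhythm (12 µV)
whose amplitude doubles in the last quartile of the session (end-of-task
sleepiness marker), with negative half-sine half-waves (duration uniform on
0.125–0.5 s) injected at condition-dependent Poisson rates: 3/min during
non-error retrievals, 9/min during errors, drifting upward by 0.04/min per
minute of time-on-task, with mean peaks −40 µV (hits) and −55 µV (errors).
Injection is thinned so no two events on a channel overlap by more than
half the shorter duration, keeping ground truth unambiguous; the discarded
fraction is monitored and warned about above 20 %. SNR is defined as the
injected peak amplitude over the broadband background RMS
(≈ 13.9 µV at the defaults), which puts SNR-3 waves at ≈ 42 µV —
the amplitude range waking delta waves actually occupy. Not emulated:
ocular/muscle artifacts (annotation-based exclusion hooks exist but
synthetic data carries no artifacts), waxing-waning rhythm envelopes
(alpha/theta are constant-amplitude sinusoids with random phase), volume
conduction and realistic covariance between channels (channels are
independent), and the control task's own late delta rise — the control
generator is deliberately flat so the *differential* (wayfinding-only)
time-on-task trend is the tested property. Consequently, passing tests
demonstrate correctness of the analysis chain against known structure, not
the detector's performance on real, artifact-laden EEG.

The background composition matters for detector validity and was fixed on
physiological grounds: waking EEG has low delta-band power and prominent
alpha/theta. The theta rhythm keeps the filtered background's negative
segments mostly shorter than the 0.125 s duration gate, so the gated
noise-event floor is low; the weak pink delta component limits dwell-time
extension of injected waves past the 0.5 s gate. With a pink-only
background of equal RMS, both properties fail (sensitivity drops toward
0.7 and false detections flood the gate) — a structural property of
zero-crossing detectors under continuous noise, not a tuning artifact. One
bound remains unattainable under continuous background at SNR 3: the
detected negative extremum is displaced by background slope over template
curvature, ≈ 1.5–2 samples at 125 Hz, so median peak-time error reaches one
sample only in the near-noiseless single-wave check.

`gen_path_data()` draws the four chain variables in standardized form
(each successor $\beta x + \sqrt{1-\beta^2}\,\varepsilon$), so population
variances are 1 and implied correlations multiply along the chain.

The cohort pipeline (`run_pipeline()`) adds between-subject heterogeneity:
a latent learning factor (log-normal, sd 0.35) scales the pre-breakpoint
path excess and delays the first error, and a correlated latent delta
susceptibility scales injection rates and second-half error probability.
This is what gives the four path variables non-trivial cross-subject
correlations of the right signs.

## Problem sizes and runtimes

The suite and the acceptance script run at deliberately reduced but
statistically meaningful sizes, chosen so each Monte-Carlo answer is stable
at its stated tolerance: cohorts of 12–14 wayfinding plus 5 control
subjects with 100-retrieval (~30 min) sessions at 8 scalp channels; 500
null simulations × 1000 permutations for the family-wise error calibration
(binomial ±0.01 at rate 0.05); 100–200 replicates for breakpoint, path and
χ² recovery. Full-scale settings (295 retrievals, ~2 h sessions, 5000
permutations) are plain configuration changes.

## Known limitations

* Channels are simulated independently; topographic clusters in the
  synthetic data reflect injected condition structure, not volume-conducted
  spatial correlation, so cluster *sizes* are not representative of real
  recordings.
* The scalp-region "local sleep" variable replaces source-space activity;
  regional averages over an 8-channel montage are coarse.
* The exact-Pratt path of the signed-rank test enumerates up to n = 25;
  beyond that the normal approximation with continuity correction is used.
* `fit_path_model()` fits the single recursive chain this analysis needs —
  it is not a general SEM engine (no latent variables, no robust errors,
  no model search).
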