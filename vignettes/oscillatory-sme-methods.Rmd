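---
title: "Oscillatory subsequent-memory effects: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory subsequent-memory effects: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oscsme` implements a complete analysis chain for oscillatory subsequent-memory
effects (SME) in an item-context association task, together with a synthetic-data
generator that makes every stage testable against known ground truth. This
vignette explains the science implemented by each stage, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data do and do
not establish about real recordings.

## The experimental design and its generator

During encoding, participants study scenes, each presented with a sequence of 5
everyday objects (encoding positions 1-5), while imagining using the object in
the depicted place. At test, old objects reappear on their original scene
(*match*), on an old scene that had been studied with other objects (*mismatch*)
or on a new scene (*old-new*), intermixed with new objects on old (*new-old*) or
new (*new-new*) scenes. With `n` scenes the condition sizes are
`2n / 2n / n / 2n / n`; the study-scale design (`n = 50`) has 250 encoding
trials, 400 test trials and 150 new objects. Because the mismatch condition
makes familiarity with the constituent parts useless for the pair judgment, the
design separates three memory outcomes: *miss* (old item called new), *item-only*
(item hit, wrong pair response) and *pair* (item hit, correct pair response).

`generate_design()` enforces three ordering constraints: 2/2/1 assignment of each
scene's objects to match/mismatch/old-new with encoding positions
counterbalanced across conditions (exact whenever `n` is divisible by 5, via
rotated assignment patterns balanced in blocks of five scenes); at most 3
consecutive test trials from one condition; and no scene displayed on
consecutive test trials. Ordering is found by randomized greedy construction
with restarts (cap 1000); an infeasible request errors rather than silently
violating a constraint. For the degenerate one-scene design the scene-repeat
rule is mathematically infeasible (the single old scene fills 6 of 8 test
slots) and is dropped with a warning.

## The generative model of behavior and EEG

Every encoding trial carries a latent Gaussian encoding strength `m ~ N(0, 1)`.
Outcomes follow hard ordered thresholds: miss below `t_lo`, pair above `t_up`,
item-only in between. Both thresholds are shifted per subject by
`N(0, subject_sd)` (default 0.3), which creates between-person variation in
memory ability and is the source of the random-intercept variance the
mixed-model stage estimates. Defaults reproduce the observed group mean rates:
`t_lo = qnorm(0.21)` (miss rate 0.21 in both age groups) and
`t_up = qnorm(1 - 0.49)` for younger versus `qnorm(1 - 0.41)` for older adults
(pair rates 0.49 / 0.41), so the age difference in memory lives entirely in the
pair outcome, as observed.

The two oscillatory signatures load on the latent axis differently:

* **Theta (4 Hz, fronto-central)** reflects *associative binding success*: a
  peristimulus burst (Gaussian envelope centered at 0.75 s, sd 0.35 s) with
  amplitude `theta_base + theta_gain * b`, where `b = 1(m > t_up)` is
  all-or-none. Theta therefore carries information about the pair versus
  item-only contrast and none about the miss versus item-only contrast. (A
  smoothed binding signal is available via `binding_scale > 0`; the all-or-none
  default is what produces the qualitative pattern that theta predicts pair but
  not item memory. A graded binding signal leaks pair information into the item
  contrast and is empirically distinguishable — we verified that with a smooth
  binding signal the item-only model picks theta up reliably.)
* **Alpha (10 Hz, posterior)** reflects *depth of information processing*: an
  ongoing oscillation whose peristimulus amplitude drops by the fraction
  `desync_depth + alpha_gain * attenuation * m'` (clipped to [0, 0.95]), active
  from 0.3 to 3.0 s with 0.25 s ramps. Here `m' = m + N(0, coupling_noise)` is
  the latent seen through trial-level neural variability (default sd 1):
  measured alpha power is a graded *correlate* of encoding strength, not a
  deterministic function of the outcome. Without this noise the extracted
  predictors nearly separate the outcome classes, which no real single-trial
  EEG measure does. `attenuation = age_attenuation` (default 0.2) for older
  adults and 1 for younger; the default is taken from the reported effect
  structure in which the alpha-pair coupling in older adults is roughly one
  fifth of the younger adults' coupling.

A note on coupling magnitudes. The theta coupling default (`theta_gain = 1`
microvolt on a 4 microvolt base) is the weakest coupling that keeps the
pair-model theta effect clearly detectable at the package's desk-scale study
size (Wald z around 5-6). Deliberately strong couplings are not harmless
here: because the standardization pool contains the pair trials, a subject's
mean standardized theta over the *item-frame subset* equals minus their pair
rate times the pair-trial theta elevation, which covaries with memory ability
— so a very strong theta-binding coupling induces a spurious between-subject
association between theta and the miss/item-only contrast that a random
intercept cannot absorb. This confound is inherent to z-scoring over all
trials and then modeling a subset (the same structure the real analysis has);
it is negligible at realistic coupling strengths. At the default, the
item-model theta test is calibrated: over 100 generator replicates its
false-positive rate was statistically indistinguishable from the nominal 5%
(8/100), with mean Wald z of -0.04.

Epochs span -2 to +5 s around stimulus onset at 100 Hz (well above Nyquist for
the 4 and 10 Hz components; the reduced rate keeps desk-scale runs fast) over a
16-channel reduced montage with named fronto-central and posterior groups and a
distance-based neighborhood graph. Each epoch sums 1/f background noise
(spectral exponent 1, sd 10 uV, independent across channels), the alpha
oscillation and the theta burst, both with random phase per trial (shared
across channels, scaled by fixed topographic weights). No phase-locked (evoked)
component, no eye/cardiac artifacts, no volume-conduction head model, and no
spatially correlated noise are simulated.

What passing tests on these data show — and what they do not: the pipeline's
statistics (baseline t-normalization, cluster inference, mixed models) are
exercised under a known effect structure with realistic 1/f spectra and
trial-to-trial variability, so recovery failures would indicate implementation
errors. They do not show robustness to artifacts, inter-subject topographic
variability, or violations of the single-latent-axis assumption, all of which
real data contain.

## Time-frequency decomposition

`morlet_power()` convolves each channel with L2-normalized complex Morlet
wavelets of width 7 cycles at 2-30 Hz in 2 Hz steps, sampling output every
50 ms (the "sliding window" of the decomposition). Power is the squared
magnitude, on a two-sided spectral-density-like scale: broadband input of
variance `v` gives band power `v / sfreq`, and scaling a signal by `a` scales
power by `a^2`. Unit-energy normalization makes power comparable across
frequencies; since every downstream statistic is baseline-contrasted, the
normalization choice cancels there anyway.

Wavelets are truncated at 3 temporal standard deviations
(`sigma_t = cycles / (2 pi f)`). Output points whose 3-sigma support crosses an
epoch edge are flagged in a validity mask rather than silently dropped or
zero-filled; at 2 Hz (`sigma_t = 0.557` s) this affects the early baseline
samples of a -2 s epoch, so the baseline fit averages only valid points per
frequency and errors if a frequency has none. Requesting output outside the
epoch is an error.

## Baseline normalization

Raw power is heavy-tailed and scales arbitrarily across subjects; all analyses
therefore run on baseline-contrast t-values. `fit_baseline()` estimates, per
channel x frequency, the mean prestimulus power `M` over *all* trials
(baseline window -0.7 to -0.2 s, averaged over time — a single prestimulus
reference per channel and frequency), and per channel x frequency x
peristimulus time point the across-trial variance `S2` (activation window 0-3
s). Averaging `M` over all trials regardless of condition washes out condition
differences in the baseline.

Two statistics share this model:

* `condition_tmap()`: the one-sample t of a condition's activation power
  against `M`, `t = (mean_cond - M) / (sd_cond / sqrt(n_cond))`, using the
  *within-condition* sd — the map entering the group analysis.
* `single_trial_t()`: the modified statistic in which the sample mean is
  replaced by single-trial power, `t = (pow - M) / sqrt(S2 / n)`, with the
  across-*all*-trials `S2` and `n` shared by every trial of a subject. It is
  monotone in power and invariant to common rescaling of all trials.

The two denominators follow each statistic's own definition; whether the
condition-level maps should instead reuse the all-trials `S2` is genuinely
underdetermined, so both are implemented and the within-condition sd is the
default for the condition maps. Degenerate cases are handled explicitly: zero
within-condition variance gives t = 0 with a warning (it means the synthetic
input was constant), zero `S2` at a valid point is an error for the single-trial
statistic (the statistic is undefined there).

## Group-level cluster inference

For each channel x frequency x time point, each subject's three condition
t-values are regressed on the condition codes (miss = 1, item-only = 2,
pair = 3) by ordinary least squares, and the one-sample t of the per-subject
slopes across subjects is the dependent-samples regression statistic: positive
means power increases linearly with the amount of information later retrieved.

Multiple comparisons over the ~15,000-point grid are handled by cluster-based
Monte Carlo permutation: points with two-sided p < 0.01 (Student quantile, df =
N - 1) enter clusters; connectivity is adjacency in frequency or time within a
channel (4-neighborhood, no diagonals) plus the sensor graph within a
frequency-time bin; a point additionally needs at least 2 suprathreshold
neighbor channels at its frequency-time bin (single-pass filter). The cluster
statistic is the summed t (mass). The null distribution permutes the three
condition labels independently within each subject — the full `3!` arrangement
set per subject, not sign-flips, because the design is a within-subject
three-level factor — and records the maximum positive and minimum negative
cluster mass of each of 5000 permutations (family-wise control by the
maximum-statistic principle, per tail). Cluster p-values use the
`(exceedances + 1) / (n_perm + 1)` estimator, so p > 0 always and the observed
partition counts as one arrangement; clusters with p < 0.025 per tail are
significant (two-sided 0.05). When `6^N` does not exceed the requested
permutation count the test enumerates all relabelings exactly instead (with a
message), which both removes Monte Carlo error for tiny N and provides the
oracle against which the Monte Carlo path is validated.

Two calibration facts about this test are worth knowing. First, the
permutation machinery itself is calibrated: on pure-noise data with the
spatial constraint disabled, the fraction of datasets with any significant
cluster sits at the nominal two-tailed 0.05 (the test suite checks this over
400 null datasets). Second, the minimum-neighbor spatial constraint makes the
procedure strictly more conservative — on the same null data the family-wise
rate drops far below nominal (below 0.01 in our runs), because isolated null
exceedances rarely have two suprathreshold neighbor channels, so null clusters
rarely form at all. That is a design property of the spatial filter, not a
defect; the calibration study therefore disables it to isolate the Monte Carlo
machinery, and separately verifies that enabling it only lowers the
false-positive rate.

## FROI summarization and the single-trial models

Significant clusters define frequency-and-region-of-interest (FROI) masks:
member points of the largest significant cluster per sign, the positive one
restricted by default to the sustained 2-4 Hz theta range (a restriction only
removes points; emptying the mask is an error). Single-trial t-values are
averaged (unweighted) over the mask per trial, excluding edge-masked points
with a logged count, and z-scored within subject (n-1 sd; the z-scoring pool is
all included match/mismatch trials of the subject, the same population the
models see). Standardization within subject makes slopes comparable across
subjects with different power scales.

Two random-intercept logistic models then predict retrieval outcome from the
standardized predictors with an age moderator:

```
outcome ~ theta * age + alpha * age + (1 | subject)
```

contrasting miss (0) vs item-only (1), and item-only (0) vs pair (1), with
younger adults as the age reference. `agq_logit()` maximizes the marginal
likelihood in which each subject's intercept is integrated out by adaptive
Gauss-Hermite quadrature: the integrand is re-centered at the subject's
posterior mode (found by Newton steps) and scaled by the local curvature before
applying the 10-node rule, so 1 node is exactly the Laplace approximation.
Nodes and weights come from the Golub-Welsch eigendecomposition. Optimization
is BFGS on `(beta, log sigma)` from fixed starting values (zeros, sigma = 1)
with relative tolerance 1e-10 on the deviance, making fits deterministic;
sigma is clamped to `[1e-8, 1e8]` so the mode search stays defined when the
optimizer probes the boundary. Wald standard errors come from the numerically
differentiated observed information (falling back to the fixed-effects block
when the sigma direction is flat at the boundary); p-values are Wald, matching
the z columns such models conventionally report. Model comparisons use
likelihood-ratio tests against the same model without the EEG terms (df 4) and
against the intercept-plus-random-intercept model (df 5). Conditional R^2 uses
the latent-scale formulation for logit models,
`(var(X beta) + sigma^2) / (var(X beta) + sigma^2 + pi^2/3)`.

A cross-check engine (`engine = "lme4"`) delegates the identical interface to
`lme4::glmer(nAGQ = 10)`; the test suite requires agreement of coefficients,
standard errors and log-likelihood, and additionally validates the AGQ
likelihood against dense 1-D trapezoid integration of each subject's marginal
likelihood.

## Behavioral analyses

Responses are categorized deterministically (miss / item-only / pair /
excluded); only match and mismatch trials enter the analysis. Subjects are
excluded when their item accuracy across the three old-item conditions is not
strictly above the chance level `response_probability * n_old / n_total` (0.5 x
250/400 = 0.31 at study scale; ties excluded, the conservative reading of
"below chance"), or when any outcome has fewer than 10 trials. Missing
responses are excluded rather than scored incorrect, which avoids biasing miss
rates. Response rates are compared in a classical two-way mixed ANOVA (between:
age; within: memory level; subject nested in age as error stratum) without
sphericity correction, matching the conventional df = (2, 2(N-2)) reporting;
Welch t-tests provide the per-level follow-ups.

## Problem sizes and reproducibility

The package's own study conditions are 20 subjects per age group with 24 scenes
(120 encoding trials) per subject. Test-suite and verification runs scale the
*sizes* down, never the effect or noise parameters: the end-to-end recovery run
uses 10 subjects per group, 16 scenes and 500 permutations; the mixed-model
replicate checks use 20 replicates of the generator's fast path (which produces
the trial table directly from the identical latent/amplitude model plus
FROI-scale measurement noise, bypassing EEG synthesis); parameter recovery uses
50 subjects x 60 trials; the null false-positive study uses 400 datasets of 20
subjects on a 16 x 8 x 20 grid with 500 permutations. A single global seed fans
out deterministically to per-stage child seeds, and `run_pipeline()` writes a
manifest of MD5 hashes: reruns under the same seed reproduce artifacts
byte-for-byte, and resumed runs equal full runs.

## Known limitations

The generator's single latent axis cannot produce dissociations in which theta
and alpha carry independent trial-level information; its all-or-none binding
signal is one defensible idealization among several; topographies are fixed
across subjects; and the epoch container is package-specific (RDS plus TSV
events plus JSON neighborhood) rather than a community interchange format.
The cluster test implements summed-t masses only (no TFCE), the spatial
constraint as a single filtering pass, and no between-group cluster test — age
effects are assessed in the mixed models, which is where the design places
them.
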