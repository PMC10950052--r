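---
title: "From choices and reaction times to the cortical timing of evidence accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From choices and reaction times to the cortical timing of evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbacascade)
```

# The scientific problem

Perceptual decisions under uncertainty are well described by race models in
which evidence for each available action accumulates to a bound. In
magneto/electroencephalography, the accumulation process leaves a signature in
band-limited power: beta-band (13–30 Hz) envelopes desynchronize in a graded,
ramp-like fashion between stimulus onset and the motor response. `lbacascade`
implements the full analysis cascade that links the two levels:

1. **Behaviour** — fit linear ballistic accumulator (LBA) models to choice/RT
   data from a 2×2 design crossing *perceptual uncertainty* (PU: motion
   coherence set per subject at the 90th vs 75th percentile of a psychometric
   function) with *action uncertainty* (AU: 1 vs 3 valid response options).
2. **Model selection** — compare the 15 variants that free any non-empty
   subset of {v, b, z, t0} across the four condition cells, via BIC and
   random-effects Bayesian model selection, including a between-group test of
   whether both groups share one generating model.
3. **Neural timing** — correlate model-predicted single-trial accumulation
   trajectories against per-ROI power envelopes with a lagged Spearman
   correlation, thereby splitting each subject's non-decision time t0 into a
   pre-accumulation (sensory, τ1) and post-accumulation (motor, τ2)
   component per region, and test for a caudo-rostral gradient of τ1 along
   the dorsal visuomotor pathway.

# The behavioural model

Each available response option has an independent accumulator. On a trial,
accumulator activation starts at a level drawn from Uniform[0, z], rises
linearly at a rate drawn from Normal(v, s), and triggers the response when it
first reaches the bound b; RT adds a constant non-decision time t0. The drift
SD s is not identifiable jointly with the other parameters and is fixed at 1
as the scaling constant, the standard convention for this model family.

The race likelihood of an observed (choice, RT) pair is the first-passage
density of the winning accumulator at `rt − t0` times the survival function
of every other *engaged* accumulator (only available options engage
accumulators: one under low AU, three under high AU), renormalized by the
probability that at least one engaged drift draw is positive. Two numerical
choices matter:

* Trials with `rt ≤ t0` would have likelihood zero; during optimization they
  contribute a floor of −20 log units so that multi-start search can move
  through such regions rather than dying on them. The same floor caps any
  individual trial's penalty.
* `z` is parameterized as a fraction of `b` during fitting, so the constraint
  `b > z` holds by construction; bounds are v ∈ (0.1, 10), b ∈ (0.1, 5),
  z/b ∈ (0.01, 0.95), t0 ∈ (0.05, min(rt) − 0.01) seconds.

RTs outside [0.1, 2.1] s are excluded before fitting, mirroring standard
trial-inclusion practice for this task family.

## Optimization

Each fit runs `n_starts` independent searches; each search draws
`n_presearch` random parameter vectors inside the bounds, starts a bounded
Nelder–Mead simplex (on a logistic-transformed scale) from the best draw, and
finishes with a short BFGS polish. The polish is not cosmetic: at desk-scale
iteration budgets a raw simplex stalls on plateaus of the transformed
surface, and the spread of final log-likelihoods across seeds was ~1.5 log
units; with the polish the spread drops below 1e-8, which is what makes BIC
comparisons across 15 variants trustworthy. The study-scale budget is 25
starts × 100 presearches; tests and the acceptance script use 5 × 20, which
the recovery studies show is sufficient at these trial counts.

The likelihood objective is compiled (Rcpp), as is usual for choice-RT
packages; the exported `lba_race_loglik()` is a plain-R reference
implementation and the two are tested against each other and against
simulation oracles.

## Model space and selection

`enumerate_variants()` lists all 15 non-empty subsets of {v, b, z, t0}; a
freed parameter takes one value per condition cell (4 values), a shared one a
single value. Log model evidence per subject and variant is approximated as
−BIC/2. `rfx_bms()` implements the variational random-effects scheme over a
Dirichlet prior on population model frequencies: expected frequencies are the
posterior Dirichlet mean, and exceedance probabilities (the probability that
a model is more frequent than all competitors) are estimated from 10^6
Dirichlet draws, which bounds their Monte-Carlo error below 0.005. The
between-group question — do controls and patients share one generating model?
— compares the variational free energy of a pooled analysis against the sum
of group-wise free energies through a logistic link. We use the free-energy
bound (rather than the sum of per-subject evidences) because it is the
quantity the variational scheme actually maximizes; this choice is
configurable in principle but fixed here.

# The psychometric front end

Coherence thresholds come from the Log-Quick function
`P(x) = γ + (1 − γ − λ)(1 − 2^(−10^(β(x − α))))` fitted to per-level correct
counts by maximum likelihood. The stimulus axis `x` is log10 coherence: the
exponent makes the function the standard log-axis Quick form, and data-level
coherences are converted at the interface. The guess rate is bounded by the
task chance level + 0.1 and the lapse rate by 0.1 — conventional bounds that
prevent the asymptotes from trading off against the slope. Inversion is
analytic and round-trips to 1e-10. The two uncertainty levels default to the
75% and 90% points; which maps to "low" uncertainty is a user decision
(behaviourally, the 90% point is the easier stimulus, hence low perceptual
uncertainty).

# Envelope processing

`preprocess_envelopes()` reproduces the standard pipeline: 4th-order
Butterworth band-pass (beta 13–30 Hz or gamma 31–90 Hz) applied forward and
backward (zero phase), analytic-signal amplitude, anti-aliased resampling to
100 Hz, and per-trial baseline normalization to percent change against the
mean over −400..−100 ms before coherence onset. "Power" here means Hilbert
amplitude, not amplitude squared; the ramp-correlation analysis is rank-based
and insensitive to that monotone choice. Filtering and envelope extraction
run at the native rate and precede resampling, so band edges are defined
where the data were recorded. ROI reduction (`roi_first_pc()`) takes the
first principal component over vertices, sign-aligned to the vertex mean.
Baseline statistics are per trial (a per-session option would pool them);
per-trial normalization is the stricter choice for single-trial correlation
analyses.

# Latency mapping

`predict_activity()` builds the deterministic trajectory the fitted model
implies for one observed trial under a candidate split t0 = τ1 + τ2: each
engaged accumulator is flat at its expected start level z/2 until τ1, rises
linearly, and freezes at the decision time `rt − τ2`. Per-trial realized
drifts are unobservable, so losers rise at the cell-mean rate (capped at b)
while the winner's slope is set by the geometry — it must reach b exactly at
decision time. The ROI signal prediction is the sum over engaged
accumulators, which is why high-AU trials predict more total accumulated
evidence (and, empirically, deeper beta desynchronization).

`max_lagged_spearman()` slides τ1 over {0, 0.01, …, t0} s (one envelope
sample per step; ties resolve toward smaller τ1), rebuilds all trial
predictions at each lag, concatenates the segments from coherence onset to
each trial's RT, and computes a Spearman correlation between the
concatenated envelope and prediction. The maximization is over |ρ| and the
signed ρ is reported; with desynchronizing envelopes the recovered sign is
negative. Concatenation-level ranking means no artificial pairs arise at
trial boundaries.

Group inference per ROI uses a one-sample sign test on the
Fisher-transformed per-subject correlations: the Z score comes from the
normal approximation with continuity correction, the p-value from the exact
binomial. Significance against chance uses phase-randomized surrogates:
each iteration randomizes the phases of the concatenated per-ROI envelope
series (amplitude spectrum preserved exactly), recomputes the full lag
search and the group sign-test Z, and the two-tailed permutation p is the
smoothed proportion of null |Z| exceeding the observed. We randomize the
concatenation rather than each trial separately: per-trial surrogates
preserve trial-mean levels, which covary with the predictions' cross-trial
structure (longer trials accumulate more), leaving a spurious correlation of
|ρ| ≈ 0.45 in the null under a strong embedded signal and destroying the
test's power. The concatenated surrogate destroys within- and across-trial
alignment while preserving the spectrum. p-values are then
Benjamini–Hochberg corrected across ROIs (and bands, if several maps are
pooled). The study-scale iteration count is 10^4; calibration tests run at
500.

# Group statistics

* `cluster_permutation_test()`: paired t per sample in 0.1–1.0 s,
  cluster-forming at two-tailed α = 0.05, cluster mass = summed t, null from
  subject-wise sign flips of the condition difference. The cluster-forming
  threshold is a design choice with no canonical value; mass and threshold
  are reported with the result.
* `fit_power_lmm()`: ML linear mixed model
  `power ~ PU + AU + Group + PU:Group + AU:Group` with random intercepts for
  subjects nested in ROI, treatment-coded against low/control reference;
  Wald CIs, conditional R², and estimated-marginal-means interaction
  contrasts via `lmm_interaction_contrast()`.
* `latency_gradient()`: OLS of per-ROI mean normalized latency (τ1/t0) on
  caudo-rostral position, slope CI by bootstrap over subjects (2000
  resamples).
* `compare_group_latencies()`: Wilcoxon rank-sum with per-call tail choice.
* `contingency_odds_ratio()`: cross-product odds ratio (second group's odds
  of the first column category over the first group's) with a two-tailed
  Fisher exact p.

# The synthetic cohort

No deposited raw data exist for this design, so `cohort_spec()` +
generators define the study conditions the pipeline is validated under:

* 2×2 design, 160 trials per cell (640 per subject), 21 control-like and 17
  patient-like subjects by default; drift-only (v) variant generates
  behaviour with cell drifts 3.5/2.5/3.0/2.0 (controls) and b = 1.2,
  z = 0.6, t0 = 0.35 s, s = 1, with 10% lognormal between-subject jitter.
* Patient-like drifts 2.6/2.3/2.2/1.8: overall slowing concentrated in
  low-AU cells (blunted reactivity to action uncertainty) while keeping mean
  RTs inside the 2.1 s inclusion window — group RT distributions remain
  broadly overlapping, as in the population this emulates. Markedly slower
  drifts would push one cell's RTs past the window and violate the fitting
  assumptions, which is a property of the design, not of the fitter.
* Envelopes at 100 Hz over −0.5..1.5 s: the negative of each trial's
  predicted trajectory, embedded at the ROI's true τ1 with one shared gain
  per ROI (per-trial rescaling would break the monotone envelope–prediction
  relation the rank correlation assumes), plus 1/f noise and broadband
  Gaussian noise. SNR is defined at envelope level as ramp amplitude over
  baseline noise SD; default 2. The control-like τ1 profile spans 0.05–0.20 s
  across 8 dorsal ROIs (150 ms caudo-rostral span); the patient-like profile
  is flat at 0.08 s.
* Ground truth (parameters, τ1 maps) travels with the data as metadata and
  is never read by analysis functions.

What the generator does *not* emulate: volume conduction and source-leakage
correlations between ROIs, non-stationary noise, artifacts, between-trial
dependence, or deviations of real behaviour from the LBA itself. Passing
recovery tests therefore demonstrates internal consistency of the cascade —
estimator correctness under the model's own assumptions — not robustness to
model misspecification in real recordings.

# Problem sizes and determinism

The test suite and the acceptance script run the complete cascade at sizes a
single desktop core handles comfortably: model recovery with 20 subjects ×
640 trials × 15 variants (5 starts × 20 presearches per fit), τ1 recovery
with 4 subjects × 8 ROIs at SNR 2, and null calibration with 500 surrogate
iterations, 500 BH simulations and 500 cluster-test simulations. Every
stochastic step takes an explicit integer seed, and derived streams are
decoupled so that, e.g., behaviour generation is byte-reproducible
independently of how many envelope ROIs are later requested.

# Known limitations

* The BIC→evidence conversion (−BIC/2) ignores the prior-dependent constant;
  only evidence *differences* across variants matter here, so the constant
  cancels, but absolute free energies are not interpretable.
* The sign-test Z is discrete for small cohorts; permutation p-values
  inherit that discreteness (they are conservative, never anticonservative —
  the calibration test checks exactly this one-sidedly).
* τ1 is estimated on the lag grid (10 ms), so sub-sample latencies are not
  resolved; with very few trials the lag search is biased toward the grid
  interior.
* The LBA variants share one t0 per cell structure; per-accumulator bias
  offsets (an alternative reading of "bias" z) are not modelled.
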