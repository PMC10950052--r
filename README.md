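# lbacascade

Decision-making under uncertainty can be read out at two levels: behaviourally,
from choices and reaction times, and neurally, from the desynchronization of
band-limited cortical power while evidence accumulates. `lbacascade` is an R
package for analyses that join the two. It is aimed at cognitive and clinical
neuroscientists working with choice/RT experiments under a 2×2 uncertainty
design — perceptual uncertainty (stimulus coherence) crossed with action
uncertainty (number of valid response options) — together with per-trial,
per-region power envelopes from source-reconstructed M/EEG.

## What it computes

**Behavioural model.** The linear ballistic accumulator (LBA): each available
response has an accumulator starting at Uniform[0, z], rising at rate
~ Normal(v, s) to a bound b; the first to arrive determines the choice, and
RT = decision time + t0. The race likelihood for a trial with m engaged
accumulators is

    f(rt − t0) · [1 − F(rt − t0)]^(m−1) / (1 − Φ(−v/s)^m),

with f and F the defective first-passage density and distribution. Fitting is
multi-start maximum likelihood (bounded simplex with a quasi-Newton polish,
compiled objective); 15 model variants free any non-empty subset of
{v, b, z, t0} across the four design cells.

**Model selection.** Per-subject log evidence ≈ −BIC/2 enters a
random-effects Bayesian model selection (variational Dirichlet scheme):
expected model frequencies, exceedance probabilities by Monte-Carlo sampling,
and a between-group posterior P(same model | data) =
1 / (1 + exp(log p(Data|H≠) − log p(Data|H=))).

**Latency mapping.** From the winning model, per-trial accumulation
trajectories are predicted under a candidate split of non-decision time,
t0 = τ1 + τ2 (pre-accumulation sensory lag, post-accumulation motor lag). The
lag τ1 maximizing the absolute Spearman correlation between concatenated
trial envelopes and predictions gives each region's accumulation onset;
group-level significance uses sign tests on Fisher-transformed correlations,
phase-randomized surrogate nulls, and Benjamini–Hochberg FDR. A linear
regression of normalized latency (τ1/t0) on caudo-rostral position tests for
a gradient along the dorsal pathway.

**Group statistics.** Cluster-corrected sign-flip permutation tests on
envelope time-courses, a mixed model
`power ~ PU + AU + Group + PU:Group + AU:Group` with subjects nested in ROIs,
Wilcoxon rank-sum group contrasts, and Fisher/odds-ratio demographics tables.

**Synthetic cohorts.** `cohort_spec()` and its generators produce behaviour,
psychophysics counts and envelope arrays with known ground truth (embedded
accumulation ramps, 1/f + broadband noise at controlled SNR, a 150 ms
caudo-rostral latency span), so the entire cascade is testable end to end
without any data download.

## Worked example

Simulate a small control-like cohort, fit the drift-only LBA variant to one
subject, and map accumulation-onset latencies across 8 dorsal-path ROIs:

```r
library(lbacascade)

spec <- cohort_spec(n_controls = 6, n_patients = 0, trials_per_cell = 40,
                    n_roi = 8, n_dorsal = 8, seed = 42)
beh <- generate_cohort_behaviour(spec)

fit_lba(dplyr::filter(beh$trials, subject == "ctrl01"),
        variant = "v", n_starts = 5, n_presearch = 20, seed = 1)
#> LBA fit, variant 'v' (7 free scalars, 159 trials)
#>   loglik 45.01, BIC -54.54
#> LBA parameters (cells: pu_au)
#>    low_low low_high high_low high_high
#> v   4.1503   2.9344   2.7245    2.0728
#> b   1.3593   1.3593   1.3593    1.3593
#> z   1.0039   1.0039   1.0039    1.0039
#> t0  0.4617   0.4617   0.4617    0.4617
```

Drift rates fall from the easiest cell (low perceptual / low action
uncertainty) to the hardest, as the generator prescribed (true cell drifts
3.5/2.5/3.0/2.0 before subject jitter); bound, start-point range and
non-decision time are shared across cells under this variant.

```r
envs <- generate_envelopes(spec, beh)
lat  <- subject_roi_latencies(envs, beh$trials, beh$truth)
latency_map(lat)
#> # A tibble: 8 × 7
#>   roi   n_subjects mean_rho sign_test_z p_sign mean_tau1 mean_norm_latency
#> 1 roi01          6   -0.710       -2.04 0.0313    0.0467             0.130
#> 2 roi02          6   -0.702       -2.04 0.0313    0.075              0.207
#> ...
#> 8 roi08          6   -0.653       -2.04 0.0313    0.2                0.552

latency_gradient(lat, roi_table(spec), n_boot = 500, seed = 2)
#> Caudo-rostral latency gradient (OLS on ROI mean latencies)
#>   slope 0.0600 [boot 95% CI 0.0535, 0.0659], R2 0.984, p 1.347e-06
```

Correlations are negative (power desynchronizes as evidence accumulates) and
consistent across all six subjects per region (sign-test p = 2⁻⁵ · 2). The
recovered onsets rise from ~0.05 s in the most caudal region to ~0.20 s in
the most rostral — the generator's 150 ms gradient — and the regression
recovers it with R² = 0.98.

Result objects have `tidy()` / `glance()` methods and `autoplot()` figures
(`psychometric_fit`, `bms_result`, `envelope_array`, `gradient_fit`).

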