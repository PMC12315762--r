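---
title: "Subject-level brain-behavior decoding: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-level brain-behavior decoding: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decodr)
library(dplyr)
```

## The problem

Group-level fMRI analyses aggregate across subjects and typically localize a
behavioral signature — how fast a decision is made, how confident the
observer feels — to a handful of cortical regions. But when a region's
activation predicts behavior *positively* in some subjects and *negatively*
in others, group averaging cancels real signal. decodr implements the
subject-level alternative: for every subject and every cortical parcel
separately, decode trial-level reaction time (RT) and confidence from
single-trial activation estimates, test each subject-parcel cell against a
permutation null, and only then aggregate — counting, rather than averaging
away, individual differences.

The pipeline consumes per-subject trial tables (one activation column per
parcel of a 200-parcel cortical atlas grouped into 7 large-scale networks),
not raw images: single-trial beta estimation and preprocessing are upstream
of this package.

## The decoding model

For one subject, one parcel, and one behavioral target, trials are split at
random into a training bin of `n_train` trials and a testing bin of `n_test`
trials (350/350 for a 700-trial session). A simple linear regression of
behavior on activation is fit on the training bin, predicts the testing bin,
and performance is the Pearson correlation \(r\) between empirical and
predicted behavior. The split is redrawn 25 times; the 25 correlations are
Fisher-transformed (\(z = \operatorname{atanh} r\)), averaged, and mapped
back (\(\bar r = \tanh \bar z\)). Correlations are clipped to
\(|r| \le 1 - 10^{-12}\) before `atanh` so noiseless data stay finite.

Two decoders satisfy the same fit/predict contract: ordinary least squares
(default, closed form) and an epsilon-insensitive support vector regressor
(`e1071::svm`, linear kernel, cost 1, epsilon 0.1). On strongly linear data
the two agree closely, which is the point of shipping both; results are
reported for the linear model because its slope is interpretable.

A useful identity, exploited by the test suite and the fast permutation
path: for a univariate linear decoder,
\(r(y, \hat y) = \operatorname{sign}(b)\, r(y, x)\) on the testing bin,
where \(b\) is the training slope. Each cell's *direction* is the sign of
the mean training slope across the 25 repeats — the quantity the
opposite-sign analysis consumes.

## Inference

**Permutation null (default subject-level criterion).** The target vector is
shuffled across trials (one global shuffle per permutation, 1000
permutations by default), the repeated-split decode is rerun, and the
one-tailed add-one p-value \(p = (1 + \#\{r_{null} \ge r_{obs}\}) /
(1 + n_{perm})\) is recorded, ties counting against significance. By
default each permutation uses 5 fresh splits rather than the full 25 — a 5x
cost reduction at desk scale. Because a 5-split null aggregate has higher
variance than the 25-split observed aggregate, the default is mildly
*conservative* (measured rejection rate ~1.5-4% at a nominal 5% on null
cohorts); setting `n_null_repeats = 25` makes observed and null statistics
exchangeable and the test calibrated, at 5x the cost. Both configurations
are exercised by the test suite; neither is anticonservative.

**Parametric alternative.** `decode_all()` also reports `p_parametric`, the
one-tailed p from converting \(\bar r\) to a t statistic on
\(n_{test} - 2\) degrees of freedom. A permutation p cannot fall below
\(1/(n_{perm}+1) \approx 10^{-3}\), so the strictest Bonferroni level below
(\(\alpha/10{,}000 = 5\times10^{-6}\)) is unreachable by permutation alone;
the parametric route is provided for exactly that regime, without asserting
it is preferable.

**The Bonferroni ledger.** Subject-level p-values are thresholded at four
nested levels: \(\alpha\), \(\alpha/n_{subjects}\), \(\alpha/n_{rois}\),
\(\alpha/(n_{subjects} \cdot n_{rois})\) (0.05, 0.001, 0.00025,
5e-6 for 50 subjects x 200 parcels). No single level is "right"; the ledger
reports all four, and every downstream summary (coverage, divergence) is
computed per level. Nestedness and the monotonicity of all coverage
percentages across levels are enforced by property tests.

**Group level.** Per parcel, subjects' Fisher-z performance is averaged
(reported back as r) and tested against zero with a one-tailed one-sample
t-test, Bonferroni-corrected for the 200 parcels. Testing on the z scale is
the standard variance-stabilized choice; the package reports degenerate
(zero-variance) and untestable (<3 subjects) parcels explicitly rather than
dropping them.

**Motion QC.** Per target, subjects' mean decoding performance (z scale,
averaged over parcels) is regressed on their mean frame displacement;
R-squared and the two-tailed p are reported. The synthetic generator draws
motion independently of all couplings, so this check is null by
construction on simulated data.

## The trial-number sufficiency test

How many trials are enough? For each subject, a whole-brain multilinear
model (all 200 parcels jointly) is trained on a fraction \(f \in [0.05,
0.95]\) of trials (5% grid, matching the granularity at which its optima
are meaningful) and tested on the remainder, 25 times per fraction; the
curve reports the across-subject mean of (i) mean performance and (ii) the
across-repeat standard deviation. Two optima are located: the fraction
minimizing the SD, and the fraction maximizing mean minus SD, ties broken
toward the smaller fraction. A fixed-test-count policy (e.g. always 35
held-out trials) is available to compare training sizes on equal footing;
under it the SD decreases monotonically with training size, while under the
complement policy it is U-shaped (few training trials: unstable model; few
testing trials: unstable correlation).

At small fractions the design is rank-deficient (35 trials, 201 columns);
the fit is the minimum-norm least-squares solution via the SVD
pseudoinverse — the canonical deterministic choice, equal to OLS whenever
the design has full column rank. Predictors are not standardized by default
(slopes stay in activation units); a z-scoring switch exists.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated. Per subject \(s\), trial \(t\),
parcel \(j\):

\[
\beta_{tj} = a^{rt}_{sj} z^{rt}_t + a^{conf}_{sj} z^{conf}_t
  + \sigma_{shared} f_t + \sigma_{idio}\, \epsilon_{tj},
\]

with independent standard-normal latents and noise. Observed behavior is a
monotone transform of its latent: \(RT = \exp(\mu + \sigma z^{rt})\)
(log-normal, positive, right-skewed) and confidence the equal-probability
ordinal binning of \(z^{conf}\). Couplings are planted per subject x parcel
cell: a cohort-level gate (`coupled_roi_fraction`) decides which parcels
carry any coupling, each eligible cell is coupled with probability
`coupling_sparsity`, and a coupled cell's sign is positive with probability
`sign_mixture` — sign heterogeneity is sampled per subject so the
prevalence of opposite-sign parcels is directly controllable. Loadings are
scaled so the planted coupling \(\rho\) *is* the population correlation
between activation and the target latent.

On the observed scale the correlation is \(\rho\) times a closed-form
attenuation: \(\sigma/\sqrt{e^{\sigma^2}-1}\) for RT (0.985 at the default
\(\sigma = 0.25\)) and a normal-density expression for K-bin confidence
(0.956 at the default K = 4). `expected_correlation()` exposes these so
recovery tests assert against an analytic value, never a fitted one.

Generator defaults mirror the targeted study design: 50 subjects, 700
trials in 6 runs, 200 parcels; a second preset emulates the replication
design (36 subjects, 804 trials, confidence on only the later half of
trials, 402/402 RT and 301/101 confidence splits). Where the design gives
no value the defaults are conventional for perceptual decision tasks:
median RT 1 s with log-scale SD 0.25, a 4-point confidence scale, shared
noise SD 0.5 against idiosyncratic SD 1, per-subject mean frame
displacement log-normal around 0.15 mm. What the generator does *not*
emulate: hemodynamics, within-run autocorrelation, beta-estimation error
structure, or spatially structured noise beyond the single shared factor —
so passing tests demonstrate the statistics are implemented correctly under
the assumed linear-coupling model, not that real cortex behaves this way.

## Opposite-sign (divergent) parcels

At each ledger level, a parcel is *divergent* when at least one subject
decodes significantly with a positive direction and at least one with a
negative direction; percentages are reported overall and per network
(network sizes as denominators). A caution the package's own simulations
quantify: at the uncorrected level with \(S\) subjects, even a fully
uncoupled parcel is falsely flagged with probability
\(1 - 2(1-\alpha/2)^S + (1-\alpha)^S\) — about 15% at \(S = 20\),
\(\alpha = 0.05\) for a calibrated test — because significant null cells
split evenly between directions. Uncorrected divergence percentages
therefore carry a substantial floor, which is precisely why the corrected
ledger levels exist and why divergence is reported at all four.

## Numerical and design choices

- **Seeding.** Every cell, permutation, and split draws from a stream
  derived by hashing (master seed, subject, parcel, target, stage), so
  results are independent of scheduling and bitwise reproducible; the tiny
  preset's `summary.json` is byte-identical across reruns.
- **Degenerate inputs.** Zero-variance activation makes a cell missing (it
  is reported, never silently dropped, and is not significant at any
  level); zero-variance predictions yield a missing repeat; subjects with
  fewer usable trials than the split demands are flagged per cell.
- **Missing targets.** Trials without a confidence rating are dropped
  before splitting; split sizes are absolute counts per target.
- **RT scale.** RT is decoded in raw seconds by default (`log_rt = TRUE`
  recovers the latent scale exactly and removes the log-normal
  attenuation).
- **Problem sizes in tests.** The validation suite runs cohorts of up to 20
  subjects x 20 parcels x 700 trials for inference checks and 10 subjects
  x 200 parcels for sufficiency-shape checks, with 20 fixed seeds per
  ordering claim — sizes chosen so the full suite completes on a laptop
  core while leaving Monte-Carlo error well inside the asserted margins.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config("tiny", seed = 1)
run <- run_pipeline(cfg, out_dir = "run1")
glance(run$ledger)
run$divergence$summary
autoplot(run$sufficiency$rt)
```

## Known limitations

- The permutation floor makes the strictest ledger level unreachable
  without the parametric route; both p-values are always reported.
- The default null policy is conservative (documented above).
- Group inference is a one-sample t-test on z values; no hierarchical
  model, FDR, or permutation-based family-wise alternative is provided.
- Multivariate decoding appears only in the sufficiency test; there is no
  searchlight or cross-subject decoding.
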