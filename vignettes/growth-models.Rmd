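---
title: "Growth models for radiocarbon time-frequency data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth models for radiocarbon time-frequency data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(c14growth)
```

This vignette records how `c14growth` models the data, which knobs matter,
and why the numerical and design choices were made. The README shows a
worked example; here the emphasis is on assumptions and internals.

## The probability model

The analysis window is a fixed interval of calendar years `[b, a]` in
cal BP (0 BP = 1950 CE; we convert a year x BP with x >= 1950 to
x - 1950 + 1 BCE, so 2664 BP is 715 BCE). Time is discrete at one-year
resolution. A *bounded growth model* assigns a probability mass `p_t` to
each year, proportional to the modelled population size at `t`; sampling a
dated event is a draw from this generalised Bernoulli distribution. The
window boundaries are user-set constants, not inferred parameters — the
model describes the shape of the date density inside the window, not where
the phenomenon starts or ends.

Three parametric families are built in.

* **Exponential** (`pmf_exponential`): `p_{t=a-i}` proportional to
  `(1+r)^i`, with `i = 0` at the *older* boundary, so positive `r` is
  growth toward the present. `r` is a dimensionless annual rate; values of
  archaeological interest are within a few tenths of a percent.
* **Double exponential** (`pmf_double_exponential`): rate `r1` before the
  changepoint year `c`, rate `r2` from `c` onwards. The discrete trajectory
  is built step by step, and the step *into* year `t` uses the rate of the
  year being left. This convention was chosen over the alternative (switch
  on the year being entered) because it keeps the trajectory continuous,
  collapses exactly to the single exponential when `r1 = r2`, and places
  the peak of a rise-then-fall history exactly at `t = c`, which is how a
  changepoint is naturally read. `c` may be non-integer: the comparison
  `t > c` is applied to integer years directly, so MCMC can propose `c` on
  the continuous scale (the likelihood is then piecewise constant in `c`
  between integers).
* **Exponential-logistic** (`pmf_exp_logistic`): exponential at rate `r1`
  down to `c`, then a logistic segment with intrinsic rate `r2` whose
  ceiling is fixed by `k`, the population at the older boundary expressed
  as a proportion of carrying capacity (`0 < k < 1`, and
  `k (1+r1)^(a-c) < 1` must hold for the logistic fraction to be defined).
  The canonical printed form of this model measures the logistic exponent
  by the global year index, which leaves a jump at the changepoint; we
  implement that form as the default for comparability, and provide
  `logistic_exponent = "changepoint"` for the continuous variant that
  measures the exponent from `c`. Analyses that hinge on the m3 shape
  should state which variant they used.

Any other growth history enters through `pmf_from_trajectory`, which
normalises a positive vector of population sizes.

The measurement layer links the latent calendar year `theta_j` of sample
`j` to its observed 14C age `X_j` through the calibration curve
`mu(t) ± tau(t)`:

    theta_j ~ BoundedGrowth(a, b, params)
    X_j     ~ Normal(mu(theta_j), sigma_j),
    sigma_j^2 = error_j^2 + tau(theta_j)^2

Lab error and curve error combine in quadrature; back-calibration
(`uncalibrate`) samples from the same single Normal, which equals the
two-stage scheme (draw the curve value, add measurement noise) because both
components are Gaussian and independent.

## Sample selection

Fixing `a` and `b` is only defensible if every analysed sample plausibly
belongs to the window. `window_filter` calibrates each date over the FULL
span of the calibration curve and keeps it when the cumulative calibrated
probability inside the window is at least 0.5 (inclusive — a date with
exactly half its mass inside stays). In-likelihood calibration, by
contrast, normalises within the window: conditional on membership, only the
in-window shape matters. `preprocess_dates` adds the remaining hygiene
rules (drop rows with no age, no lab code, or lab error above 100 14C
years) in an order-independent way.

## Priors

`fit_mcmc` takes one prior per model parameter; the constructors cover the
families needed in practice. Defaults used by `case_study_pipeline`:

* `r ~ Exponential(rate 2500)` for the single-exponential model — mean
  0.0004, the cross-cultural average annual growth rate reported for
  prehistoric populations. Exponential priors are parameterised by RATE
  throughout; a printed "lambda = 1/0.0004" is read as rate 2500.
* `r1 ~ Normal(0, 0.0004)` — the pre-changepoint phase may decline.
* `r2 ~ Exponential(rate 2500)` — the post-changepoint phase is a boom by
  hypothesis; support is positive.
* `c ~ TruncatedNormal(2625, 200, b, a)` — centres the changepoint
  mid-window and discourages edge solutions; renormalised over its bounds.
* `k ~ TruncatedNormal(0.1, 0.1, 0.0001, 0.5)` — initial population around
  10% of carrying capacity, loosely matching settlement-count ratios.

The recovery experiments (`experiment_designs()`) use the wider priors of
their published designs: `Exponential(rate 500)` for single-exponential
rates and `Normal(0, 0.1)` for double-exponential rates. The experiment-4
changepoint prior is `Uniform(1851, 3399)` — bounded by that experiment's
own window; the printed table carries the 6000-4000 bounds of the 3b row,
which cannot contain a changepoint at 2800 cal BP, so we treat it as a
copy-paste slip and bound the prior by the window.

## MCMC scheme

Growth parameters are updated one at a time by Gaussian random-walk
Metropolis-Hastings. Proposal scales adapt toward an acceptance rate of
0.44 (the standard univariate target): every 200 iterations the log scale
moves by `2 / sqrt(batch) * (rate - 0.44)`. The factor 2 lets the scale
traverse several orders of magnitude within a typical burn-in — the
posterior scale of a growth rate is hundreds of times smaller than its
prior scale — while the `1/sqrt(batch)` decay keeps adaptation vanishing,
so the chain is asymptotically valid. Initial proposal scales are the
prior's spread divided by `sqrt(n + 1)`, anticipating posterior
contraction. Reported acceptance rates are measured after burn-in.

Latent calendar dates are updated by *exact discrete Gibbs*: the full
conditional `p(theta_j = t | ...) ∝ p_t N(X_j; mu(t), sigma_j(t))` is a
categorical distribution on the yearly grid and can be sampled directly.
This replaces the generic random-walk update a general-purpose sampler
would use for `theta_j`; the target distribution is identical and mixing is
strictly better (each latent date is regenerated from its exact
conditional every sweep).

Initialisation: growth parameters are drawn from their priors (re-drawn up
to 200 times until the PMF is defined and the prior density finite);
`theta_j` starts at the mode of its calibrated likelihood (first mode on
ties), which avoids log-zero starts.

Configuration defaults mirror the two protocols used throughout: a single
chain of 10,000 iterations with 3,000 burn-in for simulation experiments
(`mcmc_config()`), and three chains of 100,000 with 10,000 burn-in thinned
by 18 — 15,000 retained draws — for empirical analyses
(`mcmc_config_case_study()`). All randomness flows through R's RNG, so a
seed makes runs bitwise reproducible; `run_experiment` derives each
replicate's stream from (master seed, condition, replicate), making results
independent of execution order.

## Diagnostics

* **HPD** (`hpd_interval`): shortest contiguous window of the sorted draws
  containing `ceiling(mass * n)` draws. This assumes a unimodal marginal;
  multimodal draws are summarised by the same rule (an optional crude
  bimodality warning can be enabled). The interval always contains at
  least the nominal fraction of draws.
* **Gelman-Rubin** (`gelman_rubin`): `sqrt((W + B/n) / W)` with `W` the
  mean within-chain variance and `B/n` the variance of chain means — the
  factor by which between-chain spread inflates the within-chain estimate.
  We use this form rather than the `(n-1)/n`-shrunk textbook estimator so
  that coincident chains give exactly 1; the two differ by O(1/n). The
  working convergence threshold is 1.001. `split = TRUE` halves each chain
  first to expose within-chain drift.
* **ESS** (`effective_sample_size`): `n / (1 + 2 sum rho_k)` with
  autocorrelations (FFT-based) summed until the first nonpositive
  consecutive pair — initial-positive-sequence truncation, which is stable
  on thinned chains. A constant sequence has no defined ESS and errors.

## Model comparison

`waic` computes `lppd = sum_j log mean_s exp(ll_sj)` (stable
log-mean-exp), `p_waic = sum_j var_s(ll_sj)`, and
`WAIC = -2 (lppd - p_waic)` from an S x J pointwise log-likelihood matrix.
For fitted growth models that matrix comes from `loglik_matrix`, which
evaluates the MARGINAL per-date likelihood — the latent calendar date
summed out over the grid at each retained parameter draw — rather than the
likelihood conditional on imputed `theta_j`. The marginal version is a
well-defined observation-level predictive density that does not depend on
which latent imputation happened to be stored; it is the package's only
WAIC. Absolute WAIC values are therefore comparable only to other marginal
WAICs; differences and `exp(-delta/2)` weights (`waic_compare`) are the
meaningful outputs.

## Posterior predictive checks

`posterior_predictive_spd` follows the five-step generative recipe: draw a
posterior parameter combination, sample `n_dates` calendar years from its
PMF, back-calibrate each, attach a lab error resampled with replacement
from the observed errors, calibrate, and aggregate into a normalised SPD;
500 simulated SPDs by default. The envelope is the *pointwise* 2.5%/97.5%
quantile band — not a simultaneous band, so with ~95% pointwise coverage
one expects a few percent of years outside even under a correct model, and
isolated excursions should not be over-read. `envelope_coverage` reports
the inside fraction and the years deviating above and below. The
`"calsample"` method is a best-effort variant in which back-calibration
noise uses only the curve error (lab error enters at the calibration
stage); it is provided for comparison and excluded from validation.

## The synthetic-data layer

`synth_curve` generates deterministic calibration curves: `identity`
(`mu(t) = t`, making calibration a discretised Normal — the analytic oracle
used in tests), `linear`, `plateau` and `steep` (emulating the
curve-geometry regimes that degrade or sharpen calendar resolution), and
`wiggle` (identity plus a smooth oscillation — the bundled
`synthetic_wiggle.14c` fixture uses amplitude 25 and period 300 years with
a constant 15-year curve error, spanning 7100-1800 cal BP). These curves
emulate the *geometry* of real calibration curves — slope, plateaus,
wiggles, and a realistic error scale — but not their empirical detail:
real curves have non-stationary wiggle structure, heteroscedastic errors,
and reversals at several scales. Passing recovery tests on synthetic
curves therefore demonstrates that the inferential machinery is calibrated
(intervals cover, no directional bias) under realistic geometry, not that
any particular empirical dataset will yield a particular parameter value.

The simulation chain (`sample_calendar_dates` → `uncalibrate` →
`calibrate` → `fit_mcmc`) is exercised at the published design points by
`experiment_designs()`: rates 0.001-0.005, sample sizes 50-500, windows
6000-4000 / 7000-6400 / 2800-2200 / 3400-1850, a fixed lab error of 20 14C
years, and 20 replicates per condition.

## Numerical choices

* All PMFs are computed in log space and normalised by log-sum-exp
  (`src/growth.cpp`); rates up to 0.01 over 10,000-year windows do not
  overflow.
* Calibration-curve `mu` and `tau` are linearly interpolated between
  published knots onto the 1-year grid — the standard practice of
  calibration software; knot values are preserved exactly.
* Single-date calibration works in plain density space and reports a
  degenerate-support error if every density underflows (date far outside
  the window); the batch/likelihood paths work in log space with per-row
  max subtraction.
* Inside the sampler, each date's likelihood row is truncated where it
  falls below 1e-14 of its row maximum and stored as a contiguous band —
  an evaluation cut far below any mass that could influence an update, not
  a model choice. The Gibbs scan is O(band width) per date.
* The WAIC matrix multiplies the (dates x grid) scaled-likelihood matrix
  by a (grid x draws) PMF matrix in one BLAS call; `waic_draws` in
  `case_study_pipeline` thins the draw dimension (default 1,000) since
  WAIC stabilises long before the full 15,000 draws.
* Tie-breaks: `theta` initialisation takes the first likelihood mode;
  `hpd_interval` takes the first of equally short windows.

## Problem sizes in the shipped tests

The test-suite runs everything at desk scale, chosen to finish in minutes
on one core while leaving the assertions sharp: recovery experiments use
10-20 replicates of 50-500 dates with the single-chain 10,000-iteration
protocol; the end-to-end case-study check fits two models to 288 synthetic
dates with two chains of 8,000 iterations; posterior-predictive envelopes
use 100-500 simulations. The acceptance script
(`scripts/acceptance.R`) re-runs the same designs from scratch under a
user-supplied seed.

## Known limitations

* Window boundaries `a`, `b` are never inferred; edge effects are handled
  only through the membership filter.
* One calibration curve per analysis; no marine or mixed-reservoir
  support, no reservoir offsets, no post-bomb curves.
* No binning of same-site dates and no pooling of same-event dates; the
  hierarchical sampling-intensity structure of real archives is the
  user's responsibility.
* The latent-date Gibbs update relies on the yearly grid; sub-annual
  resolution is out of scope.
* Envelope checks are pointwise; formal simultaneous bands and posterior
  predictive p-values are not provided.
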