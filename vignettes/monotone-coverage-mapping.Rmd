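---
title: "Monotone geostatistical mapping of multi-dose vaccination coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone geostatistical mapping of multi-dose vaccination coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxmono)
```

## The problem

Childhood vaccines such as DTP (diphtheria-tetanus-pertussis) are given in
a series of doses, and subnational maps of the per-dose coverages
$p_1(s), p_2(s), p_3(s)$ guide immunization programs in low- and
middle-income countries. Because a child cannot receive a later dose
without the earlier ones, any sensible set of maps must satisfy the
monotonicity constraint $p_1(s) \ge p_2(s) \ge p_3(s)$ at every location
$s$. Fitting three independent geostatistical models does not guarantee
this; **vaxmono** enforces it by construction, through two equivalent
reparameterizations of the dose series:

* **CP (conditional probability):** model $p_1$, $p_{2|1}$ (second dose
  given first) and $p_{3|2}$. The data for the conditionals are
  $(y_1, y_2)$ and $(y_2, y_3)$: the trial size of each conditional is
  the success count of the previous dose.
* **RB (ratio-based):** model $p_1$ and the ratios $p_{21} = p_2/p_1$,
  $p_{32} = p_3/p_2$, with *pseudo* binomial counts
  $y_{21} = n\, y_2/y_1$ and $y_{32} = n\, y_3/y_2$, so that every
  indicator keeps the full cluster sample size $n$.

In both cases the targets are recovered multiplicatively,
$p_2 = p_1 \times \text{mid}$ and $p_3 = p_2 \times \text{last}$, per
posterior draw. Since every factor lies in $[0,1]$, monotonicity holds
for every draw, every location, with no post-hoc adjustment. The two
parameterizations model the *same* probabilities ($p_{2|1} = p_{21}$);
they differ only in the trial sizes attached to the intermediate
indicators, which is exactly what the simulation study probes.

Either end of the series can serve as the reference: with
`reference = "last"` the third dose is modelled directly and the series
is composed upward (division by a ratio preserves the ordering; values
are clipped at 1).

## The geostatistical model

Each modelled indicator gets an independent binomial geostatistical
model. For cluster $s_i$ with trial size $n(s_i)$ and success count
$y(s_i)$,

$$
y(s_i) \mid p(s_i) \sim \mathrm{Binomial}(n(s_i), p(s_i)), \qquad
\operatorname{logit} p(s_i) = x(s_i)'\beta + \omega(s_i) + \epsilon(s_i),
$$

where $\omega$ is a zero-mean Gaussian field with Matérn covariance
(smoothness $\nu = 1$) and $\epsilon$ is an iid Gaussian nugget. The
Matérn scale is parameterized by the *effective range* $r$, the distance
at which correlation falls to about 0.1, via $\kappa = \sqrt{8\nu}/r$.
The binomial coefficient is omitted from the likelihood (it is constant
in the parameters), which also makes fractional success counts — the RB
pseudo counts and the simulation's exact expected counts — well defined.

Priors: $\beta \sim N(0, 10^3 I)$; penalized-complexity priors
$P(\sigma_\epsilon > 3) = 0.01$ and $P(\sigma > 3) = 0.01$ on the nugget
and field standard deviations (exponential tails), and
$P(r < r_0) = 0.01$ on the range (inverse-range tail,
$\pi(r) = (\lambda_r/r^2)e^{-\lambda_r/r}$). By default $r_0$ is 5% of
the north-south extent of the data. These tail statements are the
tunable prior knobs; their units are those of the logit scale (for the
standard deviations) and of the coordinates (for $r_0$).

Coordinates are treated as planar with Euclidean distances in the user's
units; the range $r$ inherits that unit. No coordinate system is
assumed or reprojected — callers working in degrees should keep study
areas small enough that Euclidean distance is acceptable, or project
first.

### Posterior sampling

Inference is fully Bayesian via MCMC, returning joint draws of
$(\beta, \sigma^2, r, \sigma_\epsilon^2)$ and the latent field:

* The combined latent vector $u = \omega + \epsilon$ (marginally
  Gaussian with covariance $\Sigma_\omega + \sigma^2_\epsilon I$) is
  updated by **elliptical slice sampling** (three sweeps per iteration),
  initialized at its conditional mode found by a few Newton steps from
  the empirical-logit residuals.
* $\beta$ is drawn **exactly by Gibbs**: the likelihood depends on
  $(\beta, u)$ only through $w = X\beta + u$, and given $w$ the prior
  conditional $\beta \mid w \sim N(V X' K^{-1} w,\; V)$ with
  $V = (X'K^{-1}X + \tau^{-1} I)^{-1}$ is Gaussian. This sidesteps the
  strong posterior coupling between $\beta$ and the latent field.
* The covariance parameters move on the log scale by adaptive
  random-walk Metropolis in two interweaved flavours: a *centered*
  update against the Gaussian marginal of $u$, and a *non-centered*
  (whitened) update that transports $u$ through the proposed covariance
  and accepts against the data likelihood. The interweaving breaks the
  mutual shrinkage between the field and its variance parameters that
  traps single-flavour samplers (in early development the nugget
  variance collapsed toward zero without it).

Covariates are standardized internally and the coefficients
back-transformed, so the $N(0, 10^3)$ prior acts on the standardized
scale. Defaults retain 1000 draws after 1000 burn-in iterations with
thinning 2; every fit requires an explicit seed and records acceptance
rates and crude effective sample sizes, warning (not failing) when
mixing looks poor.

### Numerical choices

* The exported `matern_cov()` evaluates the exact Matérn form with
  `besselK`. Inside the sampler, the $\nu=1$ correlation $x K_1(x)$ is
  looked up in a 200,001-knot table uniform in $\log x$ built once from
  `besselK` (linear interpolation, absolute error below $10^{-8}$);
  covariance builds dominate the iteration cost and this lookup makes
  them about four times faster.
* A jitter of $10^{-8}\sigma^2$ is added to covariance diagonals, so
  duplicate coordinates are tolerated (the nugget disambiguates them).
* Probabilities at $\pm\infty$ on the logit scale yield $-\infty$
  log likelihood rather than errors.
* The dense-covariance formulation is exact and appropriate up to a few
  thousand locations; no sparse-matrix or basis approximation is used.

### Prediction

`predict_surface()` draws, for each posterior draw, the latent field at
new locations from its Gaussian conditional given the fitted latent
values (kriging with that draw's covariance parameters, conditioning on
$u$ with the nugget folded into the data covariance), adds a fresh
nugget draw (a held-out or grid location is a *new* cluster; set
`predict_nugget = FALSE` for the smooth-field alternative), and inverts
the logit. Draws with identical covariance parameters share one
Cholesky factorization.

## The synthetic-data generator

`sim_config()` / `generate_study()` emulate a cluster-survey simulation
design and are first-class, tested code:

* Covariates: $N(0,1)$, $\mathrm{Gamma}(1,1)$ and $t_2$ draws, iid per
  location — a symmetric, a skewed and a heavy-tailed regressor.
* Truth: one shared realization of $\omega$ (Matérn, $\sigma^2 = 1$,
  $r = 2.62$) and $\epsilon$ ($\sigma^2_\epsilon = 1$) over observation
  and grid locations jointly; $\eta_1 = x'\beta + \omega + \epsilon$
  with $\beta = (0.5, 0.8, 0.8, 0.2)$; $\eta_2 = \eta_1 - 1.3$ and
  $\eta_3 = \eta_1 - 2.5$. Applying the shifts to the *shared*
  realization keeps the three surfaces ordered at every location (a
  `redraw_residuals` flag provides the independent-realization reading,
  with ordering enforced by sorting). The observation window is
  $10 \times 10$ units with uniformly random cluster locations, which
  makes the first quartile of inter-point distances land near the
  default range 2.62 (`range_from_quartile` recomputes it exactly).
* Sample sizes: $n \sim U\{2, K\}$ per cluster with
  $K \in \{10, 20, \ldots, 80\}$ by default (a `small_sizes` preset uses
  $K \in \{8, 10, 12, 15, 20, 25, 30, 35\}$).
* Counts: $y_k = n \, p_k$ **exactly** — deterministic expected counts,
  fractional, preserving monotonicity by construction. The default
  design yields $8 \times 3 = 24$ datasets sharing one truth.
* Geography fixture: a rectangular prediction grid, two nested levels of
  rectangular admin units, and log-normal cell populations.

What this emulates — and what it does not: the generator reproduces the
sampling structure (few children per cluster, varying trial sizes,
spatially structured risk) but not real-survey features such as urban
clustering of locations, displaced coordinates, survey weights, recall
error, or covariates measured with error. Passing tests on these data
show the machinery is correct under the stated model; they do not
certify performance on any particular national survey.

A consequence of the deterministic counts worth knowing: because the
observed proportions carry *no* binomial noise while the likelihood
expects some, fitted latent variances sit below their generating values
(the model re-attributes the missing sampling noise), and regression
coefficients for covariates that push probabilities near the boundary
are mildly attenuated. An independent maximum-likelihood fit of the same
data (binomial GLMM with an iid random effect) shows the same behaviour,
so it is a property of the design, not of the sampler. With
binomially-sampled counts the same fits recover the coefficients without
bias. In consequence, under the deterministic-count design the credible
intervals for the slope coefficients are narrower than the
replicate-to-replicate spread of their estimates, and their frequentist
coverage of the generating values falls below nominal — a feature of the
design any correctly implemented binomial fit will show, and one to keep
in mind when interpreting simulation results built from exact expected
counts.

Two further calibration facts about the composed targets. The model for
the *reference* indicator is exactly the generating form, and its
out-of-sample 95% intervals achieve close-to-nominal coverage at the
larger sample-size families. The conditional/ratio indicators, by
contrast, have true surfaces that are deterministic transforms of the
dose-1 linear predictor — not themselves logit-linear Gaussian fields —
so their models are only approximately specified; moreover, the three
indicators are fitted independently, so composing $p_2 = p_1 \cdot
p_{21}$ multiplies *independent* posterior draws while the truth's
factors are perfectly dependent. Both effects concentrate the composed
posteriors, and the intervals for $p_2$ and especially $p_3$ sit below
nominal coverage in the simulation. Interval calibration should
therefore be judged on the reference indicator; uncertainty statements
for later doses are conservative in ordering but not nominally
calibrated under this design.

## Validation and post-processing

* `point_metrics()`: average bias, RMSE, MAE and Pearson correlation
  (Pearson chosen; the alternative rank correlation is a one-line
  change but was not needed).
* `interval_coverage()`: percent of truths inside the closed equal-tailed
  95% interval.
* `apv()`: mean posterior variance over prediction cells.
* `crossvalidate()`: k-fold (default 10) splits of *clusters*; training
  indicator datasets are rebuilt per fold so held-out clusters can never
  leak into training; held-out predictions use a fresh nugget and are
  scored against the indicator's own empirical proportions (e.g.
  $y_2/y_1$ for the CP conditional).
* `aggregate_admin()`: population-weighted mean of cell draws per unit,
  per draw — aggregating per draw preserves full uncertainty and
  monotonicity of the aggregates.
* `dropout_rates()`: $100 (p_i - p_j)/p_i$ per draw, in $[0, 100]$ under
  monotonicity; computed per draw and summarized (posterior mean maps by
  default).
* `zero_dose()`: unit population $\times (1 - p_1)$ per draw, with the
  admin-level pathway as default (the grid-level variant, available via
  a flag, can inflate uncertainty intervals).

Direct admin estimates are unweighted ratio estimates $\sum y / \sum n$;
survey weights are out of scope, so comparisons with design-based
estimates from weighted surveys are approximate.

## Design choices on open points

* Zero-denominator clusters ($y_1 = 0$ for the middle indicator,
  $y_2 = 0$ for the last) are excluded from that indicator's dataset
  rather than scored as zero: a 0/0 conditional proportion carries no
  likelihood information, and exclusion keeps the CP and RB empirical
  indicators identical wherever both are defined.
* Held-out prediction includes a fresh nugget draw by default
  (`predict_nugget`), since the nugget is part of the model for a new
  cluster; interval-calibration checks support this reading.
* Missing covariate values are an error, never imputed.
* Counts are stored as reals; `integer_counts = TRUE` opts into
  integer validation.

## Problem sizes used by the test suite

The packaged checks run the simulation design at 300 observation
locations with a 15 x 15 prediction grid, three sample-size families
($K = 10, 40, 80$), three study replicates with 250 retained draws per
fit, and twenty single-fit replicates (550 draws) for coefficient
recovery. These sizes were chosen to exercise the full design while
keeping a complete test run on one desktop core comfortably under half
an hour; all of them are plain arguments, so larger studies are a
configuration change, not a code change.
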