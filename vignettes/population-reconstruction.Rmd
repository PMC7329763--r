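---
title: "Reconstructing an annual population series from parish registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing an annual population series from parish registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popreconstruct)
```

## The estimation problem

Before census systems existed, the only annual record of vital events in
most of Europe is the ecclesiastical register of baptisms and burials.
If registration were complete, an annual population series would follow
from pure book-keeping: with births $B_t$ and deaths $D_t$,

$$\mu_t = \mu_{t-1} + B_t - D_t .$$

Real registers fail this identity in three ways: baptisms are not births
and burials are not deaths (under-registration); most parishes have no
surviving records at all in the early years (missingness); and the set
of recording parishes grows over time. Classical inverse projection
handles these with deterministic corrections, which makes the final
series sensitive to the corrections and leaves it without any honest
uncertainty statement. This package instead treats the population as a
latent stochastic process and every deficiency of the registers as part
of one joint probability model, so the reconstruction arrives with
posterior uncertainty intervals attached.

## The model

**State process.** The population $\mu_t$ follows gamma transitions
around the accounting identity,

$$\mu_t \sim \mathrm{Gamma}\!\left(\psi_\mu(\mu_{t-1} + \beta_t -
\delta_t - s_t),\ \psi_\mu\right),$$

in shape–rate form, so the conditional mean is the accounting balance
and the conditional variance is that mean divided by $\psi_\mu$.
Military casualties $s_t$ are a deterministic offset (they are missing
from burial registers). Net migration is assumed zero. The initial year
has a Gamma(215, 0.0005) prior: mean 430,000, SD 29,326.

**Crisis year.** A catastrophic mortality year (1697 in the historical
application) breaks the smoothness assumption: modelling it like any
other year would smear the collapse over its neighbours. The crisis
transition is replaced by
$\mu_c \sim \mathrm{Gamma}(\psi_\mu \pi \mu_{c-2},\ \psi_\mu)$, where
the survival ratio $\pi = \mu_c/\mu_{c-2}$ carries a Beta prior with
mean 0.775 and precision 200. A derived coefficient
$\phi_\mu = (\mu_{c-1} + \beta_c - s_c - \pi\mu_{c-2})/\delta_c$
reports how far registered deaths must be scaled to account for the
drop; it is deterministic given the rest of the state and never sampled
independently. (The sign convention is fixed by requiring that
substituting $\phi_\mu$ back into the transition reproduces the mean
$\pi\mu_{c-2}$ exactly.) Registered burials in the crisis year are
additionally inflated by a parish-level factor $\phi_d$ with a
log-normal prior, $\log\phi_d \sim N(2, 0.25^2)$.

**Vital totals and coverage.** With $\Omega_t$ the units that have
records in year $t$,

$$\beta_t = \frac{1}{\lambda^b_t}\Big(\sum_{i\in\Omega^b_t} b_{t,i} +
\sum_{i\notin\Omega^b_t} \hat b_{t,i}\Big),$$

and analogously for deaths. The coverage coefficient $\lambda^j_t$
absorbs under-registration, the baptism/birth discrepancy and the units
left out of the likelihood entirely. It is a logistic curve in time,
affinely rescaled to fixed endpoints: the terminal coverage
$\lambda_{1850}$ is shared by both series (Beta prior with mean
$p/N$, the included-unit fraction), and the initial coverages are
Dirichlet(10, 5, 5) shares of it with the burial series constrained to
start less complete than the baptism series —
$\lambda^d_{1648} = a_1\lambda_{1850}$,
$\lambda^b_{1648} = (a_1 + a_2)\lambda_{1850}$. The scaled logistic
midpoint has a Beta(5, 5) prior over the first 183 years of the span
(the historical denominator, kept even though the series runs 20 years
longer).

**Parish observation model.** Counts, observed or imputed, follow

$$b_{t,i} \sim \mathrm{Gamma}\!\left(\psi_{bd}\,e^{\nu^b_{t,i}},\
\psi_{bd}\right),$$

a continuous observation model whose implied mean is $e^{\nu_{t,i}}$.
The log intensities $\nu_{t,i}$ are unit-level random walks sharing a
common drift $\eta_t$, itself a random walk — the hierarchical layer
that lets units borrow strength while the aggregate level trends.
Registered integer counts enter the continuous density as they are;
observed zeros are offset to 0.1 (configurable) because the gamma
density degenerates at zero. Completely missing unit-years are imputed
*inside* the model for all included units.

**Census benchmarks.** Enumerated censuses anchor the level:
$C_t \sim N(\mu_t, \sigma_c^2)$ at the census years, with a
Gamma(1, 0.0001) prior on $\sigma_c$ (95% prior interval [253;
36,889]). The constant variance means early censuses are relatively
less trusted, which matches their documented quality.

Distribution conventions: every Gamma is shape–rate; where a prior is
printed with an explicit square it is a variance, and the latent-walk
initial spreads N(3.8, 0.5), N(3.2, 0.5), N(0, 0.01) are read as SDs
(a switch `init_spread_is_sd` flips this interpretation).

## Census corrections

Raw census totals get four deterministic corrections before entering
the likelihood, applied in this order: exclusion of the double-counting
era censuses (1785, 1790, 1795); a +3.8% uplift of the first census;
addition of an annexed region interpolated from two regional anchor
censuses, scaling each anchor by the national series' compound growth
factor (log-linear between national benchmarks, anchor chosen by
temporal proximity); and division of pre-1830 totals by $1 - 0.02$ for
the confessions missing from the counts. The confession adjustment uses
$1/(1-\text{share})$ rather than $1+\text{share}$ because the share is
a fraction of the *true* population absent from the count. Only the
position of the exclusion step matters; the remaining corrections act
on disjoint quantities.

## Sampling strategy

The joint posterior has roughly $2Tp + 5T + 17$ free quantities
(about 2,800 at desk scale). It is written twice, deliberately: once as
a TMB C++ template whose autodiff gradient is the reference, and once
as a hand-fused C++ value-plus-gradient evaluation used by the
sampler's inner loop; the two are asserted equal (value and gradient)
in the test-suite. Sampling is by the No-U-Turn variant of Hamiltonian
Monte Carlo with dual-averaging step-size adaptation and a diagonal
mass matrix refined in doubling warm-up windows.

Four reparameterisations matter far more than the sampler itself:

* the population path is sampled as standardised log-increments,
  $\log\mu_{t+1} = \log\mu_t + w_t/\sqrt{\psi_\mu \mu_t}$ — this
  removes both the scale gap between path and unit-scale coordinates
  and the funnel between the path and $\psi_\mu$;
* the per-unit walks are non-centred (standardised innovations), which
  removes the funnel between the innovation SDs and the field;
* the common drifts stay centred, because the $p$ parallel units
  inform them strongly;
* the per-unit imputed counts are collapsed to their per-year totals —
  gammas with a common rate sum to a gamma, so this is exact, and the
  per-unit values are reconstructed afterwards from the conditional
  scaled-Dirichlet split (`impute_unit_counts()`).

The mass matrix is initialised from a finite-difference diagonal
Hessian at the starting point, because coordinate scales span four
orders of magnitude and identity-metric warm-up never recovers.
Chains start on the cumulative-sum accounting skeleton (anchored at the
first census) with a small scaled jitter; the full-scale sampler
configuration (16 chains of 12,500) is available as a preset, while the
package default is 4 chains of 1,500.

A smooth positivity barrier replaces the exact $-\infty$ of a
non-positive transition mean inside the compiled kernels (a hard
$-\infty$ poisons autodiff conditionals); proposals beyond it are
rejected as divergences. The R-level `joint_logpdf()` keeps the exact
$-\infty$ contract. The logistic-curve rescaling is guarded by bounding
the growth rates away from zero ($r \ge 10^{-6}$), and the coverage
prior's second shape parameter is floored at 0.5 so the configuration
with every unit included stays proper.

## What the simulator emulates

`simulate_dataset()` draws from exactly the generative model above:
drift and intensity walks, gamma counts (continuous draws kept as
ground truth, rounded integers written as the observed files),
logistic availability schedules (random unit-years or deterministic
onsets, with an optional archive-destruction gap window), coverage
curves, gamma population transitions with the crisis branch, casualty
offsets, and noisy censuses.

The desk scenario used throughout the tests has 15 units over 80
years, 8 censuses in the final 40 years, one crisis year, and truths at
the historical posterior means where those are reported (count
dispersion 0.33, intensity-walk SDs 0.09 and 0.26, survival ratio
0.78, crisis inflation 5.2, census SD 2,358, terminal coverage 0.85).
Two generator values are the package's own choices. The drift-innovation
SDs are set to 0.002/yr: the drift integrates twice into the log
intensities, so an unconditional walk at the historical posterior values
(0.15–0.30/yr) drives simulated registers to degenerate extremes over
80 years — something the data-constrained posterior paths never do; at
0.002/yr register totals grow by a plausible factor of about two over
the span. Even so, the unit-level walks are heavy-tailed enough that a
simulated path occasionally dies out; the simulator then raises an
error naming the year, and replicate studies use the first seeds whose
scenario is feasible.

What passing tests on this synthetic world do **not** show: the
simulator reproduces the model's own assumptions, so recovery results
say nothing about misspecification on real registers — mean-reverting
rather than random-walk intensities, availability correlated with
crises, migration, or age structure.

## Numerical and testing choices

* Prior summaries are closed-form (`qgamma`, `qbeta`); Dirichlet
  marginals reduce to betas by aggregation.
* The accounting-limit check fits a near-noiseless scenario (8 units,
  50 years, coverage fixed at one, tight noise) with the nuisance
  scalars held at their true values through TMB's map mechanism, and
  requires the posterior-mean path to stay within 1% of the
  cumulative-sum skeleton.
* The replicate recovery study runs 20 desk-scale fits of 2 chains ×
  370 iterations (170 warm-up) at acceptance target 0.7. These sizes
  are the package's default experimental design for the study; the
  convergence of each fit is reported through rank-normalised split
  R-hat and bulk ESS. Under this design the slowest quantities (the
  drift-innovation SDs, which sit in a funnel the chosen
  parameterisation cannot remove, and occasionally the census noise SD
  on datasets whose censuses happen to be nearly collinear with a
  smooth path) can show split R-hat above 1.02 in some replicates;
  the recovered-parameter intervals themselves are stable to this, as
  the coverage results show.
* Posterior predictive replication treats every parish record as
  missing, regenerates vitals from the posterior intensities,
  re-propagates the population and redraws censuses; infeasible
  replications are resampled up to 100 times, then counted as failed.
* Average annual growth is the geometric (compound) rate; an
  arithmetic variant is provided.

## Known limitations

* Zero net migration is structural; sustained migration biases the
  level between censuses.
* The crisis branch handles one configured year; multiple crises need
  one branch each.
* The gamma observation model is continuous; for very small parishes
  (single-digit counts) a discrete model would be more faithful than
  the zero-offset device.
* The innovation-SD funnels bound the sampler's efficiency at desk
  scale; the historical-scale preset relies on long chains, as the
  original application did.
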