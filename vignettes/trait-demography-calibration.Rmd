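---
title: "Calibrating a trait-driven community model from static abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a trait-driven community model from static abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Process-based community models are hard to calibrate in species-rich
systems because their demographic parameters multiply with the number of
species: a Lotka-Volterra model of a hundred-species grassland needs
hundreds of per-species rates that nobody can measure directly. `lvtraits`
implements an inverse-modeling route around this wall: demographic
parameters are not estimated freely but expressed as a low-dimensional
function of functional-trait axes (a *transfer function*), and the handful
of transfer parameters is calibrated against static community abundance
data by MCMC. The number of unknowns then scales with the number of trait
axes, not with the number of species.

## The community model

Species $i$ at plot $j$ with standardized temperature $\theta_j$ follows

$$\frac{1}{B_{ij}}\frac{dB_{ij}}{dt} =
  g_i(\theta_j - \theta^{min}_i) - c_i B_{ij} - l_i \sum_k B_{kj},$$

with four per-species parameters: the minimum tolerated temperature
$\theta^{min}_i$ (standardized-temperature units; growth is positive only
above it), the growth slope $g_i$, the intraspecific competition rate
$c_i$, and the sensitivity $l_i$ to the *total* community biomass (the sum
includes the focal species, so conspecifics act at the combined rate
$c_i + l_i$). Because each species is equally sensitive to all
competitors' biomass, the interaction matrix has a one-dimensional
structure that makes the equilibrium unique and globally stable; the test
suite verifies this empirically on prior-plausible parameter draws rather
than re-deriving the proof.

Observed communities are treated as equilibria of this system. Setting the
rates to zero gives the fixed point in closed form: with
$r_i = g_i(\theta_j - \theta^{min}_i)$, a coexisting set $A$ satisfies
$B_i = (r_i - l_i T)/c_i$ and
$T = \sum_A (r_i/c_i) \big/ (1 + \sum_A l_i/c_i)$, and a species persists
exactly when its invasion ratio $r_i / l_i$ exceeds the total biomass $T$.
Sorting species by that ratio makes the surviving set a prefix, so
`analytic_equilibrium()` finds the exact equilibrium in one scan. The ODE
route (`integrate_to_equilibrium()`, `deSolve::lsoda`) is kept as an
independent path; the two agree to better than $10^{-4}$ relative biomass
on random communities, and the likelihood uses the analytic fixed point by
default because MCMC needs on the order of $10^5$ equilibrium evaluations
(`equilibrium = "ode"` switches back).

### Numerical choices

* The ODE is integrated in log-biomass: near-extinct species then drift
  linearly instead of decaying over hundreds of orders of magnitude, which
  removes step-size underflow, and finite-time biomasses stay strictly
  positive by construction.
* Default tolerances are `rtol = 1e-8`, `atol = 1e-12`; the horizon
  (`1e7` time units, arbitrary since only the equilibrium is used) was
  chosen so that prior-plausible communities with growth slopes near the
  fixed $g = 10^{-3.43}$ reach the `1e-6` convergence threshold, which is
  always reported rather than assumed. The residual is the residual
  relative growth rate divided by the local contraction rate
  $c_i B_i + l_i T$ — an estimate of the *relative biomass error*, which
  matters because a low-total-biomass community relaxes at a rate
  proportional to its biomass, so a raw growth-rate residual would flag
  convergence long before the state has settled. Species below the
  reporting extinction threshold (`1e-10` relative abundance) are
  excluded: an effectively extinct species retains a fixed negative
  relative growth rate while its absolute flux is negligible.
* Random initial biomasses are i.i.d. uniform on $(0.1, 1)$,
  seed-controlled; global stability makes this choice immaterial, and the
  suite confirms equilibria from five random starts coincide within
  $10^{-6}$ relative.

## The transfer function

Let $t_{i,n}$ be the species scores on $N$ orthogonal, zero-mean,
unit-variance trait axes (default $N = 3$). For each demographic parameter
$m \in \{\theta^{min}, l, c\}$ a unit-norm coefficient vector is written in
hyperspherical coordinates through $N-1$ angles $\varphi_{m,n}$ (the first
$N-2$ in $[0, \pi]$, the last in $[0, 2\pi]$), giving the link scale

$$E_{i,m} = \cos\varphi_{m,1} t_{i,1} + \sin\varphi_{m,1}\cos\varphi_{m,2}
  t_{i,2} + \dots + \textstyle\prod_k \sin\varphi_{m,k}\, t_{i,N}.$$

On orthonormal standard-normal axes $E$ is itself standard normal for
*any* angles, so the across-species mean and spread of each demographic
parameter are controlled solely by a scale $a_m \ge 0$ and offset $b_m$:
$\theta^{min}$ uses the linear map $a E + b$ (it can take either sign),
while $l$ and $c$ use the log-linear map $e^{aE+b}$ (they must stay
positive). The parameterization is equivalent to an ordinary unit-norm
regression coefficient vector — `unit_vector_to_angles()` inverts it — but
it lets uninformative priors on directions coexist with regularizing
priors on magnitudes.

Two constants are fixed rather than calibrated, because a multinomial
(relative-abundance) likelihood cannot identify them: the growth slope is
shared, $g_i = 10^{-3.43}$, and the offset of the competition map is
pinned at $b_c = 10^{-3.8}$. The suite verifies both flat directions: the
likelihood is exactly invariant in $g$, and exactly invariant under a
joint shift of $b_c$ and $b_l$ (which rescales $\{c, l\}$ and total
biomass together while leaving every relative abundance unchanged — so
with $b_l$ free, $b_c$ is redundant). With $N = 3$ the free parameter
count is $3(N-1) + 5 = 11$.

The exponent of the log-linear map is clipped at $|aE + b| \le 50$ (with a
warning): regularizing priors make that region negligible, but a sampler
visits it during early exploration and must not overflow.

## Trait preprocessing

`average_by_species()` collapses individual measurements to species means
(gaps are fatal and named). `log_transform_traits()` applies natural logs
to every trait except named exemptions — isotopic ratios such as
$\delta^{13}C$ and $\delta^{15}N$ can be negative and stay on their
original scale. `pca_axes()` runs a correlation-matrix PCA (traits mix
units — mm, %, per-mil — so unit-scaling is the only defensible default),
keeps the first $k$ axes (default 3), fixes each axis sign
deterministically (largest-magnitude loading positive) so runs are
reproducible, and rescales the retained axes to unit variance. Unit
variance, rather than eigenvalue scale, is what the link-scale normality
property requires; the per-axis variance explained is reported separately.

## Inference

The likelihood assumes each sampled individual is an independent draw of a
species with probability equal to its equilibrium relative biomass: counts
per plot at fixed effort (101 individuals per plot in the motivating
design) are multinomial. The log-pmf includes the multinomial coefficient,
so absolute deviances, DIC and pseudo-$R^2$ are well defined; inside the
logarithm probabilities are floored at $10^{-300}$, so a proposal that
drives an observed species extinct is penalized enormously but remains
finite and comparable.

Priors: uniform on every angle over its natural range; half-normal
(default scale 1) on each $a_m$; normal on the free offsets, default
$b_{\theta^{min}} \sim N(0, 1)$ (standardized-temperature units) and
$b_l \sim N(-2, 2)$ (log-rate units, centered so that the biomass
sensitivities are comparable with $r_i / T$ at plausible community sizes).
All hyperparameters are surfaced in `prior_spec()` and recorded in run
manifests; none are hard-coded.

Sampling uses DEzs MCMC, implemented in-package: differential-evolution
proposals with difference vectors drawn from a past-state archive Z,
$\gamma = 2.38/\sqrt{2d}$ with occasional $\gamma = 1$ jumps, and snooker
updates with probability 0.1. The archive is appended every generation —
measured effective sample sizes on Gaussian targets were best at this
setting. Out-of-bounds differential-evolution proposals are reflected at
the box boundary (a symmetric fold, preserving detailed balance); snooker
proposals outside the box are rejected, since reflection would break the
snooker acceptance ratio's norm factor. The default burn-in fraction is
0.7, mirroring the 35000-of-50000 convention of the motivating study; the
default chain layout there is eight independent sampler instances whose
post-burn-in draws are pooled after Gelman-Rubin diagnostics
(`gelman_rubin()`, cross-checked against `coda`). "Chains" counts sampler
instances, as in the field's usage — each instance internally runs three
interacting walkers. Before pooling, `screen_chains()` discards instances
whose retained median log-posterior sits far below the best instance's
(default slack: half the 99.9% chi-square quantile on $d$ degrees of
freedom): an instance trapped in a dominated mode for a whole run would
otherwise corrupt pooled medians and intervals. The number of dropped
instances is reported, never hidden.

## Validation and interpretation

`fit_metrics()` evaluates the calibrated model at the posterior median,
materialized as the retained draw nearest the per-parameter marginal
medians (circular medians for the full-circle angles, distances scaled by
each marginal's spread). For a well-mixed unimodal posterior this is the
marginal median up to Monte-Carlo jitter; when chains straddle several
modes the raw component-wise median can land between modes where the
likelihood is meaningless, while a retained draw cannot. At that point it
reports Nagelkerke pseudo-$R^2$ against the
hypothesis that all modeled species are equally abundant in every plot
(the uniform null uses the full modeled pool $1/S$, globally and per plot,
so plots are comparable; per-plot values can be negative when the model
does worse than the uniform null), and DIC with $p_D$ from the retained
deviance trace. `null_trait_randomization()` builds null models by jointly
permuting the species rows of the trait axes — the per-axis multisets and
inter-axis correlations are preserved while the trait-abundance link is
broken; independent per-axis shuffling is available behind a flag.
`auc_presence()` scores presence/absence predictions by equilibrium
relative abundance with a rank-statistic AUC (ties averaged).
`posterior_demography_summary()` rebuilds the demographic vectors for each
retained draw and reports posterior medians and 95% intervals of the
Pearson correlations among $\{\theta^{min}, l, c\}$ and against observed
traits.

## What the synthetic generator does and does not emulate

`synthetic_scenario()` reproduces the statistical structure the method
assumes: orthogonal standard-normal trait axes, an evenly spaced
standardized temperature gradient, demography generated by a known
transfer function, exact equilibrium communities, and multinomial sampling
at fixed effort. Defaults are desk-scale — 40 species, 12 plots, 3 axes,
101 individuals per plot — against the field design's 118 species and 18
plots at the same effort; the default ground truth (`default_true_transfer()`)
couples $\theta^{min}$ and $l$ with opposite signs on the first axis, so
cold-tolerant species are competition-sensitive and the gradient produces
species turnover. What it deliberately does not emulate: measurement error
in traits, intraspecific trait variability, non-equilibrium communities,
transect sampling bias toward dominant species, or any mismatch between
the fitted and generating model. Passing recovery tests therefore
demonstrates the estimator's internal consistency, not the adequacy of the
model for any particular field system.

Desk-scale validation (the sizes the tests and `scripts/acceptance.R`
use): equilibrium oracle equivalence on 100 random communities of up to 30
species; stability from 5 random starts on 50 draws; sampler calibration
on a 5-d Gaussian at 3 chains x 20000 iterations; recovery at 40 species,
12 plots, 3 chains x 20000 iterations; null-model discrimination on
replicate scenarios at 12000 iterations per calibration, including a
zero-signal control (all $a_m = 0$) where real and shuffled axes must be
statistically indistinguishable.

## Known limitations

* Only the equilibrium is used; the package makes no temporal or spatial
  predictions, and the equilibrium assumption itself is untestable from
  static data.
* The transfer function ships only the linear/log-linear maps; the
  architecture keeps the map pluggable, but nonlinear variants are out of
  scope.
* Angle posteriors close to the polar degeneracies ($\varphi_1 \in
  \{0, \pi\}$) or wrapping around $2\pi$ can make naive credible
  intervals (and Gelman-Rubin on those marginals) misleading; circular
  medians are used for point estimates, but interval coverage of
  wrap-around angles should be read with care on real-data fits.
* The posterior can have dominated secondary modes in the $(a_l, b_l)$
  trade-off; single sampler instances occasionally spend a whole
  desk-scale run there. Multiple independent instances plus screening
  handle this, and `recovery_experiment()` flags `mpsrf > 1.1` rather
  than silently accepting a run.

## A worked example

```{r, eval = FALSE}
library(lvtraits)

sc  <- synthetic_scenario(S = 40, J = 12, effort = 101, seed = 1)
dat <- simulate_dataset(sc)
fit <- calibrate(dat$axes, dat$sites, dat$sample,
                 n_iter = 20000, seed = 100)
fit$metrics
fit$convergence$mpsrf
posterior_demography_summary(fit$posterior, dat$axes)
```
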