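# lvtraits

Trait-based inverse calibration of Lotka-Volterra community models for
species-rich ecosystems.

## The problem

Process-based community models promise mechanistic predictions of
community structure, but their per-species demographic parameters multiply
with species richness: a hundred-species grassland needs hundreds of
rates that cannot be measured directly. `lvtraits` is for community
ecologists who have (i) a species x trait table, (ii) static community
abundance counts at fixed sampling effort along an environmental gradient,
and (iii) a per-plot covariate (temperature) — and who want a calibrated,
process-based model of those communities anyway.

## The method

Communities follow a temperature-dependent Lotka-Volterra variant: species
`i` at plot `j` with standardized temperature `theta_j` grows as

    (1/B_ij) dB_ij/dt = g_i (theta_j - thetamin_i) - c_i B_ij - l_i sum_k B_kj

with per-species minimum tolerated temperature `thetamin_i`, growth slope
`g_i`, intraspecific competition `c_i`, and sensitivity `l_i` to total
community biomass. Observed communities are treated as the globally stable
equilibrium of this system.

Instead of estimating the per-species parameters freely, a **transfer
function** maps `N` orthogonal trait axes `t_i` to them: unit-norm
coefficient vectors in hyperspherical coordinates (angles `phi`) give a
link scale `E_i,m = sum_n coef_n t_i,n`, and then
`thetamin = a*E + b` (linear) while `l, c = exp(a*E + b)` (log-linear).
With `N = 3` axes this costs 11 free parameters for the entire community;
`g` and the offset `b_c` are fixed (`10^-3.43`, `10^-3.8`), being
unidentifiable from relative abundances. The 11 parameters are estimated
by DEzs MCMC (differential evolution with a past-state archive and snooker
updates, implemented in-package) under a multinomial likelihood in which
each sampled individual belongs to a species with probability equal to its
equilibrium relative biomass.

Validation follows the same logic as the motivating study design:
Nagelkerke pseudo-R2 against an equal-abundance null, DIC, null models
built by shuffling the trait axes among species, presence/absence AUC, and
posterior summaries of the trait-demography correlations.

## A worked example

Simulate a synthetic study (40 species, 12 plots on a temperature
gradient, 101 individuals sampled per plot, known transfer function),
calibrate, and validate:

```r
library(lvtraits)

sc  <- synthetic_scenario(S = 40, J = 12, effort = 101, seed = 1)
dat <- simulate_dataset(sc)
fit <- calibrate(dat$axes, dat$sites, dat$sample,
                 n_iter = 20000, n_instances = 3, seed = 100)
fit$metrics
#> <fit_metrics> pseudo-R2 0.991, DIC 532.8 (pD 11.0)
round(fit$convergence$mpsrf, 2)
#> [1] 2.29
truth <- build_demography(sc$true_transfer, dat$axes)
est   <- build_demography(unpack_transfer(posterior_median(fit$posterior), 3),
                          dat$axes)
round(cor(truth$theta_min, est$theta_min), 3)
#> [1] 1
round(cor(truth$l, est$l), 3)
#> [1] 0.998
```

The pseudo-R2 compares the model's multinomial likelihood at the posterior
median with the hypothesis that all 40 species are equally abundant in
every plot (0 = no better than uniform, 1 = perfect); the DIC penalizes
the posterior mean deviance by the effective parameter count `pD`; the
correlations show that the calibrated per-species minimum temperatures and
biomass sensitivities recover the generating truth almost exactly. The
multivariate potential scale reduction factor of 2.29 exceeds the usual
1.1 threshold; at this desk scale it is driven by the full-circle angle of
the weakly identified competition direction (per-parameter psrf 1.98 for
`phi_c_2`, whose wrap-around marginal inflates the diagnostic, against
1.02-1.35 elsewhere). The package reports it rather than hiding it, and
`recovery_experiment()` flags such runs; longer chains tighten it.

A shuffled-axes null calibration on the same data
(`null_trait_randomization()` + `calibrate()`) yields a DIC several
thousand units worse, which is the evidence that the trait signal — not
model flexibility — drives the fit.

## Command line

A thin CLI wraps the same functions:

```sh
lvtraits simulate   --species 40 --plots 12 --seed 1 --out sim/
lvtraits calibrate  --axes sim/axes.csv --sites sim/sites.csv \
                    --counts sim/counts.csv --out fit/
lvtraits validate   --posterior fit/posterior.csv --axes sim/axes.csv \
                    --sites sim/sites.csv --counts sim/counts.csv \
                    --occurrence sim/occurrence.csv --out val/
lvtraits nullmodels --axes sim/axes.csv --sites sim/sites.csv \
                    --counts sim/counts.csv -n 5 --out nulls/
lvtraits recover    --species 40 --plots 12 --seed 1 --out rec/
```

(after installation the script lives at `<library>/lvtraits/exec/lvtraits`;
run it with `Rscript`). Every run writes a JSON manifest with the full
configuration and seeds, so results are reconstructible.

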