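---
title: "Models and methods: frequency-dependent ecology of preexisting resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: frequency-dependent ecology of preexisting resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoresist)
```

## The scientific problem

Resistance-conferring mutations usually carry a fitness cost in the absence
of treatment, so purifying selection should purge them quickly — yet
preexisting resistance is observed routinely, from drug-resistant malaria to
targeted-therapy failure in non-small-cell lung cancer. `ecoresist`
implements a quantitative framework for one resolution of this paradox:
*negative frequency-dependent selection* between a resistant mutant and the
ancestor it emerged from. A mutant that grows slowly in monoculture can grow
almost as fast as the ancestor while it is rare and surrounded by ancestor
cells — precisely the situation every newly arisen mutant finds itself in.

## The fitness model

Every mutant is characterised by two dimensionless growth rates, both
relative to the ancestor's rate (normalised to 1):

* **intrinsic fitness** `fi` — growth in monoculture (ancestor fraction 0);
  the **fitness cost** is `1 - fi`;
* **ecological fitness** `fe` — growth in an almost-all-ancestor population
  (ancestor fraction 1).

Between the endpoints the growth rate is linear in the ancestor fraction
`x`: `f(x) = fi + (fe - fi) x`. Linearity is the model's central
simplification: it is the two-type evolutionary-game form (payoffs
`1 - fc` against fellow mutants, `fe` against ancestors) and is also what
the coculture game assay measures. Nothing beyond linear frequency
dependence is modelled.

New mutants draw `fi` and `fe` independently at birth from configurable
distributions:

* the **DFE** (distribution of fitness effects) over `fi` — uniform on
  `[0, 1 - fc]` by default, so `fc` is the *minimum* cost of resistance;
* the **DEE** (distribution of ecological effects) over `fe` — uniform,
  truncated Gaussian, or a tabulated density.

Independence is a modelling choice, not a claim about biology: no data yet
constrain the joint distribution, and every closed form below only requires
the marginals. The DEE has never been measured in any system, which is why
all analytical results are written against an arbitrary density `rho0(fe)`.

## The generalized Moran process

For a single mutant clone versus the ancestor (no mutation),
`moran_spec()` defines a birth–death chain on `s = 0, ..., N` mutants with
absorbing boundaries. One event chooses a reproducing individual with
probability proportional to its expected payoff (self excluded:
`P_R(s) = ((s-1)/(N-1))(1-fc) + ((N-s)/(N-1)) fe`, `P_A = 1`) and kills a
uniformly chosen individual. The fitness-proportional birth with uniform
death used here is the standard generalized Moran formulation in the
frequency-dependent evolutionary-game literature. Times are reported both in
events and in generations (`events / N`).

* `moran_absorption()` evaluates the classical ratio-of-products absorption
  formula in log space (the products underflow badly otherwise). States
  with zero birth probability (`fe = 0`) are treated as limits, not
  division errors.
* `moran_extinction()` computes the full first-passage distribution to
  extinction by iterating the transient tridiagonal structure (a
  phase-type recursion), and independently computes the conditional mean
  extinction time from the exact linear system `(I - Q) u = h`. The two
  routes must agree — the test suite enforces `1e-8` agreement against a
  dense-matrix oracle for `N <= 200`. Distributions are conditioned on
  extinction by default, since fixation of a costly mutant is vanishingly
  rare; the unconditioned mass is kept alongside. When the horizon
  truncates more than 0.1% of the conditional mass the result carries a
  warning flag rather than being silently cut.

## The lineage-tracking Wright-Fisher simulator

`wf_run()` simulates a constant-size population. Each generation is a
mutation step — every ancestor mutates with probability `mu`, each new
mutant founding a lineage of size 1 with fresh `(fi, fe)` draws — followed
by one multinomial resampling of all `N` individuals with weights
proportional to fitness. The ancestor fraction used for fitness evaluation
is `ancestor_count / N` after mutation: all mutant lineages jointly dilute
the ancestor, but do not otherwise interact (the model ignores
mutant–mutant ecology, so only ancestors mutate and a lineage's fitness
never changes after birth). A mutant with no offspring in its first
selection step has extinction time `tau = 0`; lineages alive at the end of
the run are censored and excluded from mean-`tau` summaries (including them
would bias means downward), with their number reported.

The inner loop is compiled (Rcpp) and costs O(active lineages) per
generation independent of `N`, which is what makes the long stationary runs
below routine. It uses R's RNG, so `set.seed()` (or the `seed` arguments)
makes every run exactly reproducible; replicate runs derive child seeds
through the documented scheme in `child_seeds()`, so adding replicates
never perturbs existing ones.

## Closed-form layer and its assumptions

* `tau_approx(fe) = 3 ln(1 - fe) / (fe^2 - 3)` — mean extinction time in
  generations of a newly emerged lineage, a function of `fe` *only*. The
  simulator confirms the independence from `N`, `mu` and `fc`: binned
  mean extinction times collapse onto one curve across parameter
  variations, with a typical (median over fe bins) relative error of ~2–5%.
  Invalid at `fe >= 1`, where extinction is no longer certain.
* `n_mut_noeco(N, mu, fc) = N mu (-ln(fc)/(1-fc) - 1)` — expected mutant
  count when ecology is switched off (growth is `fi` alone, averaged over
  the uniform DFE). This is the reading under which `fc` must be the
  *minimum* cost: the average of `fi/(1-fi)` over `fi ~ U(0, 1-fc)` gives
  exactly this expression.
* `n_mut_eco_small_mu(N, mu, fmax) = N mu (-ln(1-fmax)/fmax - 1)` — the
  ecological counterpart for `mu << 1` and a uniform DEE on `[0, fmax]`.
  `fmax` may approach but never equal 1, or the normalisation fails.
* `n_mut_eco(N, mu, fc, fmax)` — the mutation–selection balance valid
  across several decades of `mu`, solved with the principal Lambert W
  branch. The balance equates the influx `mu` against a per-lineage
  lifetime `1/(1 - fe + m g)`, where the mean mutant fraction `m` feeds
  back through the ancestor fraction and `g = fc^{fc/(fc-1)}/e` is the
  geometric mean of `1 - fi` under the uniform DFE. Writing
  `b = fmax/(mu g)`, the solution is
  `m = (W(b e^{b(1-fmax)-fmax})/b - (1-fmax))/g`. Below `mu = 1e-6` the
  small-mu form is used automatically (the two agree to well under 1%
  there). For very small `mu` the W argument overflows double precision,
  so the package solves `w + ln w = ln(argument)` by Newton iteration —
  the same principal branch, evaluated in log space.
* `stationary_density(fe, mu, dee) = fe mu/(1-fe) rho0(fe)` — the
  stationary density of mutant *individuals* over ecological fitness: the
  probability a mutant with fitness `fe` arises and survives its first
  step (proportional to `fe mu rho0`) balances the rate `1 - fe` at which
  established ones decay. Its integral over a uniform DEE equals the
  small-mu mutant fraction exactly, which pins the per-individual (rather
  than per-lineage) interpretation; the simulator's histogram is
  correspondingly weighted by mutant individuals (a by-lineage variant of
  the underlying lineage table is available via `tidy()`).
* `classify_regime()` compares the two expected counts with 1:
  `small-Nmu` (both below 1 — resistance unlikely either way),
  `rare-mutant` (only the ecological count exceeds 1 — preexistence is
  driven by rare strongly-interacting mutants), `many-mutant` (both above
  1 — mutants common, but ecology still reshapes their distribution). When
  `fmax >= 1 - fc` the ecological count can never be the smaller one; for
  the unusual configuration `fmax < 1 - fc` ecology *suppresses* mutant
  numbers and the function warns and labels the case `small-Nmu`.
* `coexistence_fixed_point()` — for `fe > 1 > fi` the mutant outgrows the
  ancestor when rare and is outgrown when common, giving a stable interior
  equilibrium at ancestor fraction `x* = (1-fi)/(fe-fi)`. None of the
  closed forms above apply for supports extending past `fe = 1`; that
  regime is explored by simulation only.

## Deviation between the Lambert-W count and finite simulations

At the reference simulation size `N = 1000` the simulated stationary counts
sit ~10–15% below *every* branching-based closed form (including the
small-mu form in its own domain of validity) for small `mu`, converging to
~1% at `mu = 0.01`. This is a finite-`N` effect, not an error in either
side: the mean count is dominated by near-critical lineages
(`fe` near `fmax`) conditioned on long survival, whose excursions reach
sizes of order `1/(1-fe)` — 10% of `N` at these settings — where the
frequency-dependent crowding feedback truncates exactly the excursions that
carry the mean. The effect shrinks as `1/((1-fmax) N)`. The package reports
the discrepancy honestly rather than absorbing it into the formula, and an
exact numerically-solved mean-field (kept in the test oracles' spirit)
confirms the Lambert-W expression solves the stated balance accurately.

## The synthetic game assay

`generate_synthetic_assay()` emulates the two-channel coculture design used
to measure `(fi, fe)` experimentally: wells seeded at 1500 cells across
several initial ancestor fractions (default 0.1–0.9, three replicate wells
each), imaged every 4 h over 96 h. The ancestor grows exponentially at a
reference rate of 0.03/h (a ~23 h doubling time, typical of the NSCLC cell
lines that motivated the model); the mutant grows at
`0.03 x mutant_fitness(truth, p)` with `p` the well's *initial* ancestor
fraction. Counts carry multiplicative lognormal noise (default 5% on the
log scale) and are left continuous, standing for image-derived cell
numbers. What the generator deliberately does *not* emulate: frequency
drift within a well (real cocultures move away from their seeding fraction
as they grow), lag phases, saturation, segmentation errors that scale with
confluency, and well-to-well media effects. Passing the recovery tests
therefore shows the estimator is correct and calibrated *under the stated
noise model*, not that real assays are this clean; the fitting window
argument exists precisely so lag/saturation phases of real data can be
excluded.

`estimate_growth_rates()` fits `log(count) ~ time` per well and channel
(wells containing nonpositive counts are flagged and excluded, never
imputed). `fit_frequency_dependence()` divides the mutant rates by the mean
ancestor rate (the model fixes ancestor fitness at 1), regresses the
relative rate on the initial ancestor fraction, and reads `fi` at `p = 0`
and `fe` at `p = 1`. Regressing on the *initial* fraction matches the
experimental design; drift during growth is treated as part of the noise. A
positive ecological interaction is declared by the one-sided slope test at
`alpha = 0.05`, whose type-I rate calibrates to ~3.5–5% on the synthetic
model.

Confidence intervals are bootstrap-t: wells are resampled with replacement
(ancestor normalisation recomputed each time) and the interval is the
estimate ± `t(0.975, n-2)` times the bootstrap SE inflated by
`sqrt(n/(n-2))`. The inflation is the small-sample degrees-of-freedom
correction for the two regression parameters; without it, case-resampling
intervals cover only ~89–91% at this design size (15 wells) instead of the
nominal 95%. With it, simulated coverage is ~94–97%.

## Numerical choices and degenerate inputs

* Truncated Gaussians are sampled by exact rejection and their densities
  renormalised analytically; tabulated densities are linearly interpolated,
  renormalised by the trapezoid rule, and sampled through a 4096-cell
  piecewise-constant discretisation (uniform within a cell).
* The multinomial selection step is drawn as a chain of conditional
  binomials with the final category taking the remainder, so population
  size is conserved exactly by construction.
* `fe = 0` mutants can never reproduce; the Moran absorption formula
  handles the resulting zero birth rates as limits. `fc = 1` is handled as
  the (zero-count) L'Hopital limit in `n_mut_noeco()`; `fc = 0` is a
  domain error there because the expression genuinely diverges.
* Bin edges throughout are half-open `[lo, hi)`; empty histogram bins are
  reported as missing, not zero.

## Problem sizes used by the tests and acceptance script

The extinction-time comparison runs `N = 1e4`, `mu = 1e-4` for 3x10^6
generations (~3x10^6 lineages), chosen so that even the most deleterious
fe bin (`fe <= 0.002`, where the mean extinction time is of order 0.001
generations because only ~1 lineage in a thousand survives a single step)
holds thousands of lineages. The stationary-count comparison runs 20
replicates of 2x10^5 post-burn-in generations at each of four mutation
rates spanning `1e-5`–`1e-2`. Calibration loops for the game assay use
400–500 seeded trials. These sizes make every stochastic check
comfortably tighter than the tolerances asserted on it.

## Known limitations

* Constant population size, one ancestor genotype, no treatment phase, no
  spatial structure, no epistasis or mutant–mutant interactions, and
  strictly linear frequency dependence.
* The closed forms assume `fmax < 1`; the `fe > 1` coexistence regime is
  simulation-only.
* The DEE is unmeasured in any real system; all quantitative outputs are
  conditional on the assumed DEE, which is why it is a first-class,
  swappable object throughout the package.
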