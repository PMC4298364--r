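---
title: "Modeling somatic evolution in aging HSC pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling somatic evolution in aging HSC pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscsoma)
```

## The question the model addresses

Hematopoietic stem cells (HSC) accumulate mutations and epigenetic changes
across life, yet leukemia incidence and stem-cell functional decline are
concentrated in the post-reproductive decades. hscsoma is an agent-based
Monte Carlo model built to ask whether cell-intrinsic mutation accumulation
alone can simultaneously reproduce three observations:

1. the measured slope of neutral (Tier-3) passenger-mutation accumulation
   with age (reference value 0.09162 mutations/year, 95% CI
   0.03759–0.1457, from AML whole-genome data);
2. age-dependent exponential growth in the magnitude of clonal expansions,
   whose shape should track the leukemia-incidence curve; and
3. the roughly 2–3-fold decline in per-HSC fitness observed in old age;

and whether adding an aging-microenvironment model (a *composite* model)
resolves the tension when mutations alone cannot.

## Model structure

The simulation tracks every cell in the HSC pool on a weekly clock over an
85-year lifespan (4420 weeks), starting from 300 cells at fitness 1. Each
week, in a fixed order:

1. **Division.** Each cell divides with the age-dependent probability
   `d(t)`. A dividing mother is replaced by two daughters (symmetric
   division; an asymmetric one-daughter mode is available as a
   configuration toggle). Each daughter inherits her mother's fitness,
   Tier-3 count and clone label, then receives one independent net fitness
   effect drawn from the mutation DFE and a Poisson Tier-3 increment.
2. **Clone bookkeeping.** A daughter whose fitness has diverged more than a
   threshold θ (default 0.05) from her clone founder's recorded fitness
   founds a new clone. Divergence is measured on microenvironment-detrended
   fitness (see *Numerical choices*).
3. **Microenvironment** (composite model only). Every cell loses the
   uniform weekly amount ΔF(t) and receives an independent distributed
   perturbation with spread ΔF(t)/2.
4. **Viability.** Cells whose fitness reaches zero or below are removed
   (loss of competitive viability).
5. **Niche competition.** If the pool exceeds the carrying capacity N(t),
   survivors are drawn without replacement with weight proportional to
   fitness (floored at 1e-6), via exponential keys; exactly the overflow is
   removed.

Four named RNG streams (division, DFE, environment, competition) are
derived from the single run seed, so disabling one mechanism does not
perturb the draws of the others.

### Mutation DFE

Net per-division fitness effects are drawn from a zero-centred sign-mixture
of half-normals: magnitude `|N(0, σ_eff)|`, sign positive with probability
equal to the positive-tail fraction. With tail 0.5 this is exactly a
zero-mean normal; with tail 0 all effects are deleterious, but cells still
diversify by being "less negatively" affected. The studied σ range is
5e-6–5e-1 (fitness units per division).

The mutation rate may rise over life by a fold factor f ∈ [1, 8]; the
default ramp is linear in age, m(t) = 1 + (f − 1)·t/T (an exponential ramp
is available — the original ramp shape is not published, and linear is the
simplest monotone choice consistent with a stated lifetime fold increase).
Because a division's net effect behaves as the sum of m(t) independent
unit-rate contributions, variances add and the effective DFE width is
σ·sqrt(m(t)).

Tier-3 passenger mutations are selectively neutral markers of division
history: per-division increments are Poisson with mean μ0·m(t). The default
μ0 is calibrated so the ordinary least-squares slope (per year, whole
lifespan) of the *analytic* expected accrual curve at stable mutation rate
equals the reference 0.09162 mutations/year. Under symmetric division, the
population-mean weekly increment is μ0·m(t)·2d(t)/(1+d(t)), not
μ0·m(t)·d(t): a divider is replaced by two daughters, each carrying a fresh
increment, before neutral culling, so dividing lineages are transiently
over-represented. The calibration and the neutral-accrual oracle test both
use this exact factor. On the default schedules the calibrated μ0 is about
0.030 mutations per division.

### Demography

The published pool-size and division-rate curves are qualitative; the
package uses a parametric reconstruction with every breakpoint exposed in
the configuration:

* capacity: logistic-type growth anchored exactly at 300 cells at birth,
  midpoint 9 years, reaching the adult size (11,000 cells; desk scale
  2,000) at maturity (18 years); adult phase constant, constant-large
  (25,000) or growing linearly 11,000→25,000 by the end of life;
* division probability: exponential decay from 0.4/week at birth to the
  adult plateau 1/40 per week (≈1.3/year) — within 1% of the plateau by age
  20; the slow-cycling variant plateaus at 0.6/52 ≈ 0.0115/week, the lowest
  published adult estimate.

These defaults front-load divisions: more than 40% of expected lifetime
divisions occur before age 20, consistent with the observation that roughly
half of somatic mutations accumulate early in life.

### Microenvironment

Aging tissue imposes a bicomponent fitness modification. The uniform
component follows the logistic mean-fitness curve

F(A) = F_max − (F_max − F_min) / (1 + 5200·e^(−0.0031·A)),

with F_max = 1, F_min = 0.3 and A in weeks — a smooth ~3-fold decline
concentrated after mid-life (the logistic midpoint falls near age 53). The
analytic |dF/dA| gives the weekly drop ΔF(t) subtracted from every cell.
The distributed component redraws each cell's context: a weekly sign-mixture
perturbation with spread parameter ΔF(t)/2, added persistently to the
cell's fitness (a per-lineage random walk).

Two readings of "spread ΔF(t)/2" are possible — standard deviation or
variance. The package defaults to the standard-deviation reading, which is
the consistent usage for the mutation DFE ("variance in standard
deviations, denoted σ") and which keeps the symmetric-environment pool mean
tracking F(A); the variance reading is available via
`env_spec(spread = "variance")`. Likewise the distributed component
defaults to a zero-centred draw (tail fraction 0.5, matching the model's
base description); the 0% environment tail studied in the panel
comparisons is applied explicitly in those sweeps rather than baked into
the preset.

## Outputs and metrics

`run_simulation()` records weekly series of pool size, mean fitness, mean
Tier-3 count, largest-clone share and clone count.

* **Tier-3 slope**: OLS slope of mean Tier-3 count vs age in years with a
  95% CI, by default over the whole lifespan.
* **Clonal expansion**: the share of the pool held by the most successful
  clone; end-of-life expansion is that share at the final week, in percent.
* **Shape similarity (MRSE)**: both curves are 0–1 normalized, the
  simulated expansion curve is resampled to the reference yearly age grid
  (0–85) by linear interpolation, and similarity is 1 − RMSE, clamped to
  [0, 1]. This is the only reading of a 0-to-1 "mean root square error"
  similarity consistent with 1 as a perfect match. The statistic is
  invariant to affine rescaling of either curve.
* **Reference incidence curve**: the registry curve behind the published
  shape match is not printed anywhere, so the package ships a documented
  synthetic stand-in, incidence(a) = exp(0.087·(a − 85)): negligible and
  flat through reproductive ages, doubling every ~8 years in late life
  (the canonical myeloid-leukemia age profile). Any two-column CSV
  (age_years, incidence) can be substituted.

## Parameter sweeps and the plausible range

`run_grid()` sweeps the (σ, fold) plane — by default 6 log-spaced σ in
[5e-6, 5e-1] × folds 1–8 with 3 seeded replicates per cell — and records
replicate means. The *plausible range* is the set of cells whose Tier-3
slope falls inside the reference CI (closed interval). `overlap_percent()`
reports the percentage of plausible cells whose expansion curve reaches a
similarity stringency (0.7, 0.8 or 0.9). Replicates are aggregated by the
mean; per-cell seeds are derived from one top-level seed so surfaces are
reproducible and order-independent.

## Numerical and design choices

* **Desk scale.** The package's standard reduced scale for stochastic
  checks is a 2,000-cell adult pool with the 6×8 grid and R = 3; the
  11,000-cell presets are provided for faithful replication. Competition
  intensity depends on pool size, so scaled runs are used to check
  directions and bounds, not exact surface values. In particular, genetic
  drift is much stronger at 2,000 cells: the largest-clone share acquires a
  substantial drift component during the small-pool childhood phase, which
  raises mutations-only expansion magnitudes well above what selection
  alone would produce. Shape matching is less affected, because drift
  accumulates gradually while the reference incidence curve rises late.
* **Clone divergence is measured on detrended fitness.** The uniform
  microenvironmental drop affects every cell identically and carries no
  clonal information; left in, it would push every late-life daughter past
  θ and dissolve clone tracking. The comparison therefore excludes the
  cumulative uniform drop accrued since the clone's founding (with the
  environment off this is the plain founder-referenced rule). Divergence is
  founder-referenced rather than parent-referenced to avoid clone churn
  from tiny per-division drift.
* **Non-viable cells.** Fitness ≤ 0 is treated as loss of competitive
  viability and the cell is removed at once; this also keeps competition
  weights positive. Under extreme parameter corners (σ = 0.5 with a
  non-positive tail, or a 0% environment tail late in life) whole pools can
  die out before week 4420; metrics then reflect the pool up to its last
  surviving week and end-of-life quantities are NA. Such cells are treated
  as non-matching in overlap statistics.
* **Competition lottery.** Survivors are drawn without replacement with
  probability proportional to fitness using exponential keys
  (Exp(1)/weight, keep the N smallest), which is distributionally identical
  to successive weighted draws and O(n) per week. The weight floor 1e-6
  prevents zero-weight degeneracy.
* **Order of operations** within a week (division → environment →
  viability → competition) is fixed and documented because results are
  order-sensitive.
* **Equation typography.** The printed form of the mean-fitness curve is
  typographically ambiguous; the package uses the logistic reading
  1 + 5200·e^(−0.0031·A), the only one satisfying the stated boundary
  values F(0) ≈ 1 and end-life 0.3.
* **Eq.-style driver probability.** The multistage driver integral
  P(t) = D(t)·∫ Π p_i dτ is a rate-like heuristic and is deliberately not
  clamped at 1; it is not coupled into the simulator's dynamics.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions: pool demography, division
schedules, DFE construction with asymmetric tails, mutation-rate ramping,
the microenvironment curve, and clone designation. It does not model
per-site genomes, explicit driver identities, progenitor compartments,
spatial niche structure, or a leukemia-onset event — clonal-expansion
magnitude is the proxy for incidence shape. Passing tests therefore show
that the *mechanisms* behave as specified under the stated conditions, not
that any particular parameter combination describes real human
hematopoiesis.

## Worked example

```{r example, eval = FALSE}
cfg <- preset_config("composite",
                     schedules = hsc_schedules(adult_size = 2000),
                     seed = 7)
sim <- run_simulation(cfg)
glance(sim)
autoplot(sim)
plot_shape_match(sim)
```

A desk-scale sweep and its overlap summary:

```{r sweep, eval = FALSE}
base <- preset_config("mutations_only",
                      schedules = hsc_schedules(adult_size = 2000), seed = 11)
surf <- run_grid(base, exp(seq(log(5e-6), log(5e-1), length.out = 6)), 1:8,
                 replicates = 3)
glance(surf)
autoplot(surf)
```

## Known limitations

* The demography curves and the reference incidence curve are documented
  parametric stand-ins, not published numbers.
* The original competition formula, clone threshold and Tier-3 rate are not
  published; the package's choices are recorded above and every one is
  configurable.
* At desk scale the childhood drift component inflates largest-clone shares
  relative to full scale; conclusions should rest on cross-condition
  contrasts at matched scale, which is how the test suite and the
  acceptance analyses are constructed.
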