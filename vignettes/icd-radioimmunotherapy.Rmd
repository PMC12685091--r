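---
title: "Modeling immunogenic cell death in combined radio- and macrophage immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling immunogenic cell death in combined radio- and macrophage immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdrt)
```

## The scientific problem

Radiotherapy (RT) kills tumor cells directly, but most of that death is
immunologically silent. When dying cells release damage-associated
molecular patterns (DAMPs), antigen-presenting cells can convert local
killing into a systemic response — *immunogenic cell death* (ICD). Whether
that conversion happens depends strongly on the innate checkpoint that
silences macrophages: CD47 on tumor cells binds SIRPα on macrophages and
delivers a "don't eat me" signal. `icdrt` implements a compact
ordinary-differential-equation framework that couples tumor–immune
population dynamics, linear-quadratic (LQ) radiation survival, and an ICD
amplification term that switches on when the SIRPα–CD47 axis is disrupted
(knockout, antibody blockade, or adoptive transfer of SIRPα-deficient
macrophages). The package provides the staged calibration, uncertainty and
identifiability machinery needed to fit such models to murine tumor growth
curves, and the prediction tools (abscopal response, treatment-efficacy
phase maps) the calibrated model supports.

## The model

Compartments are tumor burden `C`, effector cells `E` and macrophages —
wild-type `M` or checkpoint-disrupted `M*` — in volume-equivalent units
(mm³ for `C`; engrafted cell counts convert at `kappa = 1e6` cells/mm³).
The cancer–effector (CE) model is

$$\frac{dC}{dt} = c_1 C \left(1 - \frac{C}{c_{max}}\right) - \phi_e C E,
\qquad
\frac{dE}{dt} = \gamma_e - \eta_e C E - \delta_e E,$$

logistic growth with effector killing, constant effector infiltration,
exhaustion proportional to tumor–effector encounters, and constant
clearance. The cancer–effector–macrophage (CEM) model adds phagocytosis
$-\phi_{m^*} C M^*$ (and/or $-\phi_m C M$) to the cancer equation and a
macrophage balance of the same infiltration/exhaustion/clearance form. With
both macrophage compartments disabled the CEM right-hand side reduces to CE
exactly; this identity is asserted in the test suite. All kill terms carry
a factor of `C`, so nonnegativity is structural; the integrator
additionally clamps any compartment below the extinction threshold
(`1e-6` mm³) to exactly zero to prevent numerical resurrection.

### Radiation and ICD

A single RT fraction of dose $d$ leaves the surviving fraction

$$S = e^{-\alpha d - \beta d^2 g(\lambda\tau)}, \qquad
g(x) = \frac{2(x + e^{-x} - 1)}{x^2},$$

where $g$ corrects for sublethal-damage repair (rate $\lambda$) during the
delivery time $\tau$; $g(0) = 1$ and $g \sim 2/x$ for long deliveries. Only
the product $\beta\, g(\lambda\tau)$ enters $S$, so $\lambda$ and $\tau$
are not separately identifiable from growth data; `radiation_params()`
accepts the composite `beta_g` directly and the stage-3 calibration fits
it. ICD enters as

$$I = A\,(1 - S),$$

activation $A$ times the damage fraction. With wild-type macrophages
$A = 0$: RT alone fails to induce ICD. From the event time onward the
cancer derivative is scaled by the growth factor

$$F_{\text{primary}} = S - I, \qquad F_{\text{abscopal}} = 1 - I ,$$

the abscopal (out-of-field) tumor sharing the primary's ICD but receiving
no direct dose. $F < 0$ — possible because calibrated activations give
$I > 1$ — produces sustained regression.

### Why derivative scaling is the default

The post-RT relation $dC/dt^+ = S\,dC/dt^- - I\,dC/dt^-$ can be read
either as a persistent factor on the derivative or as an instantaneous
survival jump followed by ICD scaling. We default to `rt_mode =
"derivative"` (persistent factor, updated at each subsequent event) because
calibrated ICD values above 1 only drive the sustained regressions seen in
checkpoint-disrupted hosts under that reading; a pure state jump with
$I > 1$ and an unchanged derivative would let the tumor regrow
immediately. The alternative `rt_mode = "jump"` ($C^+ = S\,C^-$, then
derivative scaled by $1 - I$) is implemented for comparison. Similarly,
$F$ multiplies the *entire* cancer right-hand side (the literal reading);
`scale_growth_only = TRUE` restricts it to the logistic term.

## Staged calibration

`run_four_step()` mirrors how such models are calibrated in practice, in
four stages of increasing complexity with hard freezing between stages:

1. **Wild-type growth** — fit `c1`, `cmax` on untreated wild-type arms
   (CE model). Effector rates default to fixed, literature-plausible
   values: with `E(0) = 0` and a constant infiltration source they are
   only weakly identified by volume curves, and freeing them mostly
   degrades the growth-parameter estimates. The free set is configurable.
2. **Checkpoint-disrupted growth, no RT** — fit `phi_mstar` on
   knockout/treated arms with stage-1 values frozen. Infiltration,
   exhaustion and clearance of `M*` stay at configured values; the small
   engraftment arm (5×10³ cells) carries most of the information because
   phagocytosis is overwhelmed once the tumor outgrows the macrophage
   pool.
3. **Wild-type + RT** — fit `alpha` and the composite `beta_g` on the
   dose × treatment-day grid, stage-1 frozen (A = 0, so `F = S`).
4. **Checkpoint-disrupted + RT** — fit one activation `A` per
   (dose, size-window) arm with everything else frozen. Arms are fitted
   independently (each activation enters only its own arm), which keeps
   every stage-4 problem one-dimensional.

Fitting minimizes unweighted least squares on the per-arm mean volume
curve (`tumor_cost()`), the convention for cohort growth data;
inverse-variance weighting by replicate standard deviations is available
via `weighting = "inverse_variance"`. The optimizer is bounded `L-BFGS-B`
on log10-transformed parameters (they span nine decades), restarted from
20 seeded log-uniform multistarts by default; staged problems have at most
two free parameters each, so multimodality is mild and a handful of starts
usually suffices — the heavy simulation studies in the test suite use 2–4.
Bounds default to positive literature-plausible ranges
(`default_bounds()`), e.g. `c1` ∈ [0.01, 2]/day and activations in
[0, 100]; a zero lower bound is floored at 10⁻⁹ of the upper bound on the
log scale, so "A ≈ 0" is representable.

## Uncertainty, sensitivity, identifiability

**Parametric bootstrap** (`bootstrap_params()`): replicate observations are
drawn from Poisson laws centered on the best-fit predicted volume (rounded
to the nearest count; `volume_scale` sets counts per mm³, default 1, so
dispersion follows the unit choice), the stage's free parameters are
refitted per replicate, and percentile intervals are read off the
replicate matrix. Refits warm-start from the best fit using a bounded
Levenberg–Marquardt step on the residual vector — the natural refitter for
a least-squares stage — with one multistart fallback when it fails to
converge; failed replicates are excluded with a warning, and more than 20%
failures abort. A nonparametric mode resamples time points with
replacement; `mode = "exact"` is a degenerate test mode. The reference
analysis uses 2,000 replicates; the packaged coverage study scales to 200
replicates × 50 outer replications, which resolves coverage to about ±4
percentage points in a few minutes on one CPU.

**Local sensitivity** (`sensitivity_rank()`): each parameter is perturbed
by ±25% of its value and the mean relative change in the cost is recorded;
parameters with no pathway into the observed volume (disabled
compartments) score exactly zero. This is a local, one-at-a-time measure —
it ranks influence near the optimum and says nothing about interactions.

**Practical identifiability** (`profile_likelihood()`): the profiled
parameter is fixed on a grid while the remaining free parameters are
re-optimized (warm-started along the grid). The profile is summarized as a
pseudo-likelihood rise $(n/2)\,\Delta\log SSR$ and classified *flat* below
a threshold of $3.84/2$ (the 95% χ² quantile with one degree of freedom,
halved) — a documented heuristic, configurable. The package reproduces the
hallmark degeneracy of this model class: on a single-dose, single-schedule
dataset the phagocytosis rate `phi_mstar` trades off against macrophage
infiltration `gamma_mstar` (only their product reaches the dynamics
through `phi * M*`), so its profile is flat while the growth rate's
profile on the same machinery is decisively curved.

## Predictions

`treatment_efficacy()` is the percent reduction of the cancer compartment
relative to untreated control at a fixed evaluation day (default day 22,
after all reference treatment days; an observed-volume variant is a flag).
`efficacy_grid()` sweeps (A, φₘ*, dose) full-factorially — the reference
phase space — and `efficacy_levels()` extracts the 25/50/75/95% contour
polylines per phagocytosis cross-section. `abscopal_predict()` replays a
primary schedule on an out-of-field tumor with `F = 1 − I`. Radio-resistance
is a single multiplier ρ ∈ (0, 1] on both α and β
(`resistance_scale`), which provably raises S and lowers I, hence never
increases efficacy; independent per-parameter scaling can be had by
editing α and β directly.

`activation_interpolator()` builds A(dose, size) from the bundled anchors
by shape-preserving piecewise-cubic (PCHIP) interpolation through the
origin in dose and linear blending across size-window midpoints. PCHIP
cannot overshoot below the data, keeping A ≥ 0 where a natural cubic
through three anchors per size can dip negative. On the anchor doses
{4, 8, 15} Gy the small- and medium-tumor ICD peaks at 8 Gy; on the
interpolated continuum the peak sits near 6 Gy — the biphasic consequence
of damage (1 − S) rising while activation A falls with dose. The
large-tumor window instead rises monotonically to the highest tabulated
dose; the package reports per-window peaks alongside the modal consensus
(`icd_peak_dose()`) rather than forcing a single answer.

## The synthetic-cohort generator

The reference growth curves behind the bundled calibration anchors are not
redistributable, so `four_condition_suite()` generates cohorts with the
statistical structure the calibration assumes: the four conditions
(wild-type, checkpoint-disrupted, each ± RT), engraftments of 5×10³–5×10⁵
cells, single RT fractions of 4/8/15 Gy on days 8/12/14, observations
every 2 days from day 6 to 20, 8 mice per arm, and per-mouse volumes drawn
from Poisson laws centered on the model predictions (`volume_scale = 1`
count per mm³, matching the bootstrap's noise model). The generating truth
(`default_truth()`) uses the anchor activations per (day, dose), LQ
parameters α = 0.01/Gy, β = 10⁻⁴/Gy² with λτ = 1 (damage fractions ≈
0.040/0.081/0.153 at 4/8/15 Gy, matching those implied by the anchors),
and phagocytosis φₘ* = 4.43×10⁻⁸ per cell per day.

Two generator choices deserve explanation:

- **Growth constants.** `c1 = 0.7`/day and `cmax = 2500` mm³ reproduce the
  engraftment pacing of the reference cohorts (≈100 mm³ on day 8 from
  5×10⁵ cells) while keeping growth unsaturated through day 20. A
  carrying capacity low enough to hold the day-14 volume inside the
  400–600 mm³ window would saturate the tumor by the later treatment
  days; the RT factor then multiplies a near-zero derivative and the
  radiosensitivity parameters (and through them the activations) lose
  practical identifiability. Identifiable study conditions were
  prioritized over matching the later size windows, which the generated
  curves overshoot.
- **Macrophage scale.** The tabulated phagocytosis rates (10⁻⁹–10⁻⁶) are
  per cell per day, so `M*` is carried in cell-equivalent abundance
  (infiltration 10⁶/day, steady state ≈ 6.7×10⁶ cells), giving kill rates
  of order 0.3/day that reproduce the knockout's suppressed growth at
  small engraftments. Because cell-equivalent immune abundances are not
  volume-additive, generated cohorts use the cancer-compartment
  observation map; the compartment-sum map remains the simulator default
  and both are flags.

What the generator does **not** emulate: caliper measurement bias, mouse
dropout or ulceration censoring, inter-mouse growth-rate heterogeneity
(noise is purely observational Poisson), treatment-dependent CD47
expression, and any adaptive-immunity memory — the constant-ICD assumption
means post-treatment relapse dynamics are outside the model. Passing the
recovery and coverage tests therefore demonstrates that the pipeline is
correct and well-calibrated *under its own assumptions*, not that those
assumptions hold for any particular in vivo dataset.

## Numerical choices

- Integration: `deSolve::ode` (lsoda), `rtol = 1e-8` / `atol = 1e-10` for
  simulation, relaxed to `1e-6`/`1e-8` inside fitting loops; hard
  breakpoints at every event day; RT applied instantaneously at the start
  of its day (τ enters only through g).
- The right-hand side is compiled C (`src/rhs.c`); a cost evaluation over
  a nine-arm dataset takes ~10 ms, which is what makes the 20-seed
  recovery study and the 50×200 bootstrap coverage study run in minutes.
- Extinction threshold 10⁻⁶ mm³, applied at event boundaries and output.
- Tie-breaks: `icd_peak_dose()` reports the modal per-window argmax as the
  consensus; `which.max` resolves exact ties toward the lower dose.
- Degenerate inputs: zero dose gives S = 1, I = 0, F = 1 and provably
  leaves trajectories unchanged; an all-zero initial state stays zero; a
  zero lower fitting bound is floored on the log scale as described above.

## Problem sizes in the shipped studies

Parameter recovery: 20 Poisson seeds plus one noise-free suite, 22 arms
each, 3 multistarts per stage. Bootstrap coverage: 50 outer replications ×
200 replicates, single-arm single-mouse cohorts so the bootstrap's Poisson
noise model matches the data-generating one exactly. Profile likelihood:
7-point grids spanning one decade either side of the truth. These sizes
were chosen to give statistically meaningful checks (coverage standard
error ≈ 4 points; median recovery errors well separated from the 10%
criterion) at desk-scale runtimes.

## Known limitations

Single-fraction LQ biology only (no fractionation schedules beyond event
lists, no TCP/NTCP); no spatial structure, oxygenation or cell-cycle
effects; constant ICD per event (no immune priming dynamics — the
second-injection activation must be supplied, not predicted); local
sensitivity only; bootstrap assumes the Poisson observation model it
simulates. Structural identifiability is out of scope; practical
identifiability via profiles is the supported tool.
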