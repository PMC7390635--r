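---
title: "Estimating cell-cycle length and mode of division from population counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-cycle length and mode of division from population counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(cyclekin)
```

## The problem

A differentiating stem/progenitor culture — radial glia plated from
embryonic cortex are the motivating system — changes along three axes at
once: how fast cycling progenitors divide (cycle length $T$), what the
daughters become (the mode of division), and how many progenitors are
cycling at all (growth fraction $\gamma$, with $1-\gamma$ quiescent).
Classical thymidine-analog assays (EdU/BrdU cumulative curves, pulse-chase)
estimate $T$ under an assumption of *constant* kinetics.  When kinetics
drift over a culture's lifetime, those assays can fail badly and
inconsistently.  `cyclekin` provides:

1. an agent-based simulator of such a population with an in-silico
   labeling layer, so any estimation protocol can be rehearsed against a
   known ground truth;
2. the four standard estimators — single cumulative (C1), dual cumulative
   (C2), pulse-chase (PC), and a branching-process inversion (BP) of the
   population balance equations — with the error propagation each needs;
3. a benchmarking harness that compares them under constant and
   time-varying conditions.

## The population model

Each simulated cell carries its birth time, a relative cycle length
$r_i$, a progress fraction $f \in [0,1)$ through its cycle, a state
(cycling or quiescent; differentiated and apoptotic cells are terminal and
retire into counters), and a set of heritable binary labels.  Three
equal-length phases partition the cycle: G1 for $f < 1/3$, S for
$1/3 \le f < 2/3$, G2+M above (a `phase_fractions` hook allows unequal
phases).

Four user schedules drive the dynamics, each a constant, a
piecewise-linear breakpoint list, or an arbitrary function of time:

* `T_mean(t)` — mean cycle length (hours);
* `ppdd(t)` $= pp - dd \in [-1, 1]$ — net mode of division;
* `gamma(t)` $\in [0, 1]$ — growth fraction;
* `apoptosis_rate(t)` — per-progenitor hazard (per hour).

**Cycle-length heterogeneity.** Per-cell cycle lengths are gamma
distributed with mean `T_mean` and a standard deviation of 30% of the mean
(`cv = 0.3`; shape $1/\mathrm{cv}^2$, scale $\mathrm{cv}^2 \cdot$ mean),
mimicking clonal cell-to-cell variability.  A cell's instantaneous cycle
length is $r_i \cdot T_{\text{mean}}(t)$: progress advances as
$df = dt / (r_i T_{\text{mean}}(t))$, so when the schedule changes, every
cell rescales proportionally and keeps its phase fraction.  The
alternative — freezing each cell's length at birth — would make the
population's realised kinetics lag a varying $T(t)$ by about one cycle and
distort every estimator's target.

**Division.** When $f$ crosses 1 the mother is replaced by two daughters
(fresh $r_i$, age equal to the small overshoot, full label set inherited).
Under the default independent-fates model each daughter becomes a
progenitor with probability $p = (1 + ppdd)/2$ independently of its
sister, which reproduces the requested $pp - dd$ and, via
`decompose_modes()`, the division-type rates $pp = p^2$,
$pd = 2p(1-p)$, $dd = (1-p)^2$.  A `fate_mode = "triplet"` switch accepts
explicit $(pp, pd, dd)$ probabilities for oracle tests.

**Quiescence.** The quiescent pool is kept at its target share
$(1-\gamma(t)) \cdot (\text{progenitors})$ by a tracking exchange: when the
pool is below target, just-born daughters are moved into quiescence; when
above, random quiescent cells re-enter the cycle (resuming their frozen
progress).  We deliberately did *not* draw quiescence per daughter with
probability $1-\gamma$: in homeostasis that rule feeds the quiescent pool
a continuous stream of label-carrying daughters (turnover
$\gamma(1-\gamma)P/T$ per hour), which drags the cumulative-labeling
plateau far above $\gamma$ within two cycles — contradicting both the
Ki67-style reading of $\gamma$ and the plateau law the estimators rely
on.  The tracking form exchanges essentially nothing while $\gamma$ is
constant and responds in both directions when it changes.

**Apoptosis** is a continuous hazard on all progenitors (cycling and
quiescent): each dies in $(t, t+dt]$ with probability
$1 - e^{-\phi_P(t) dt}$, accumulating in the cumulative counter $A$.  It
is not an at-division fate, because the estimators consume it as a rate.

**Initialisation.** By default the population starts in the stationary age
structure of a freely cycling culture: among cells alive at a random
instant, lifetimes are length-biased relative to the birth draw — for a
gamma$(k, \theta)$ birth distribution that is exactly gamma$(k+1,
\theta)$ — and age is uniform within each cell's own cycle.  This makes
the initial division flux exactly $P/T_{\text{mean}}$ with no transient.
(Sampling plain birth-draw lifetimes instead, `init_lifetimes =
"birth_draw"`, models a freshly plated cohort; it carries a ~10% excess
division flux over the first part of a cycle at cv = 0.3, which measurably
inflates early differentiation output.)  Initial states are quiescent
with probability $1 - \gamma(0)$.

**Time stepping** is a fixed `dt` (default 0.1 h, $\ll T$); divisions are
processed when the progress crosses 1 within a step, and daughters start at
the overshoot so cycle lengths are unbiased.  All randomness flows through
R's seeded Mersenne–Twister stream: identical configs give bit-identical
`counts_ts` tables.

## The labeling layer

`label_protocol()` windows mark any cycling cell whose S phase overlaps an
active exposure interval; the label is binary, permanent, and inherited by
both daughters (no strand segregation or dilution threshold — the analog
is read as positive/negative).  Quiescent cells never incorporate label.
Labeled fractions are reported over *all* progenitors (cycling +
quiescent), matching how a progenitor marker gates the experimental
denominators; this is what makes the cumulative plateau read out
$\gamma$.

Three experiment drivers mirror the standard designs, each fixing
independent replicate simulations (fresh seeds derived from the master
seed) per time point:

* `cumulative_experiment()` — one analog from `label_start`, fixation at
  staggered times (C1 input);
* `dual_cumulative_experiment()` — first analog shared, second analog
  staggered, common fixation; reports double-positive fractions against
  second-label exposure (C2 input);
* `pulse_chase_experiment()` — a short pulse (default 0.5 h, the 30-min
  convention) and per-chase-time fixation with a detector gate: a second
  0.5 h analog pulse just before fixation (default) or direct S-phase
  occupancy (PC input).

For a homeostatic population with deterministic $T$ and uniform ages the
cumulative labeled fraction follows the classical index
$\min(\gamma (T_S + t)/T,\ \gamma)$: initial value $\gamma T_S/T$, slope
$\gamma/T$, plateau $\gamma$ at $t = T - T_S$.  The test suite holds the
simulator to this closed form.

## The four estimators

**C1** (`c1_fit`): OLS slope over the first `n_early` points (default the
classic first four; `"auto"` selects everything below 90% of the plateau),
plateau $\hat\gamma$ as the mean of the last four fractions, and
$\hat T = \hat\gamma / \text{slope}$.  The slope uncertainty is *defined*
as half the difference between refits of the data shifted up and down by
their standard errors (`linear_fit_with_band()`), the plateau uncertainty
as the SE of the late points, and the $T$ uncertainty combines both in
quadrature.

**C2** (`c2_fit`): a line through the pre-plateau double-positive points
gives slope $\gamma/T$ and intercept $\gamma T_S / T$, hence $\hat T$ and
$\hat T_S$.  The dual design cannot measure $\gamma$; it is read off the
plateau when one is reached, otherwise it must be supplied.  Because its
rise spans the full pre-plateau regime, the benchmark arm uses
`n_early = "auto"`.

**PC** (`pc_fit`): the double-positive fraction peaks when pulse-labeled
cells re-enter S one full cycle later, so $\hat T$ is the chase time of
the maximum, refined by a quadratic through the peak and its two
neighbours (sub-grid resolution without shape assumptions).  Short chases
still show the *first* S phase, so the search runs beyond the trough of
that initial decay; a maximum at the last grid point raises a
peak-not-bracketed error rather than returning a floor estimate.  $T_S$
comes from the rising flank (peak height over rise slope).

**BP** (`bp_estimate`): over a window $[t_0, t_1]$ with progenitor change
$\Delta P$, differentiated change $\Delta D$, progenitor exposure
$I = \int P\,dt$, apoptotic mass $\Phi = \int \phi_P P\,dt$ and
window-average growth fraction $\bar\gamma$:

$$\widehat{pp - dd} = \frac{\Delta P + \Phi}{\Delta P + \Delta D + \Phi},
\qquad
\widehat{T} = \frac{\bar\gamma\, I}{\Delta P + \Delta D + \Phi}.$$

The denominator counts divisions: each division contributes $ppdd$ to
$\Delta P$ and $1 - ppdd$ to $\Delta D$ in expectation, so the mode
estimate is exact regardless of timing, while $\widehat T$ is
$\bar\gamma$ over the realised per-cell division flux.  Windows where
$\Delta P + \Delta D + \Phi \le 0$ (no net divisions resolvable) are
masked, never extrapolated; mode estimates outside $[-1, 1]$ are clipped
with a warning.

Two input routes are supported.  `fit = "sigmoid"` first smooths $P(t)$
and $D(t)$ with three-parameter logistics — the route for noisy
experimental counts, and the one `propagate_ci50()` perturbs for its
bands.  `fit = "direct"` interpolates the recorded counts themselves — the
route for simulation output, where no measurement-noise model is wanted.
For a single average over an experiment, apply the equations to one window
spanning the whole run (`grid = c(0, t_end)`); the method needs only two
time points.  We do *not* average hourly-window $\widehat T$ values for
that purpose: when $D(t)$ is nearly linear (homeostasis) a logistic's
flattened tails underestimate the edge derivatives and the edge windows'
$\widehat T$ explodes, roughly doubling the naive average.

**Confidence bands** (`propagate_ci50`): shift the $P$ and $D$ series by
$\pm$ half their maximum standard error, refit the sigmoids, re-run the
inversion for all four shift combinations, and take the envelope — the
50% band convention.  Zero SEs collapse the band onto the point estimate;
inflating SEs widens it monotonically.  The band answers for measurement
error under the logistic model of the trajectories; it does not absorb
structural misfit, so on trajectories a single logistic cannot represent
(e.g. agent-model output with a strong mode ramp) the band under-covers —
use `fit = "direct"` there and treat the windows as the resolution.

**A word on growth corrections.** Under exponential expansion the per-cell
division flux is $\ln(1 + ppdd\,\gamma)/T$ rather than $ppdd\,\gamma/T$
(the age-structure correction), so $\widehat T$ is biased high by the
factor $ppdd/\ln(1+ppdd)$ — about +10% at $ppdd = 0.2$, +14% at 0.3, and
nothing at homeostasis.  The mode estimate is unaffected.  We leave the
estimator in its balance-equation form, document the bias, and keep the
round-trip guarantee (10% on $T$, $\pm 0.10$ on $pp - dd$ at $m \ge 500$,
10 runs) inside it for modest net expansion.

## Sigmoid fitting

`sigmoid_fit()` fits $f(t) = A / (1 + e^{-(t - t_0)/\tau})$ by
Levenberg–Marquardt least squares (weighted $1/\mathrm{se}^2$ when SEs are
given).  The logistic family was chosen over Gompertz for symmetry and
because its derivative is available in closed form.  Logistic fits are
initialisation-sensitive, so the fitter starts from $A_0 = \max$, $t_0$ at
the half-maximum crossing, $\tau_0 = \text{span}/10$, plus a fixed set of
five spread-out restarts (including a near-linear regime start), and keeps
the converged fit with the lowest residual sum of squares.  Negative
$\tau$ represents decreasing series, so shrinking progenitor pools fit.
Exactly constant data return a degenerate flat fit; if no start converges
the fitter falls back to a straight line, recorded in `method` and
warned about — downstream code treats all three identically through
`predict()` and `sigmoid_deriv()`.

## The benchmark

`make_scenario()` freezes the study conditions: $m = 500$ initial cells,
48 h, 10 independent runs, cv 0.3, and the sampling cadences (cumulative
fixations every 2 h to 30 h of exposure; second-label exposures 2–16 h
before a common 30 h fixation; pulse at 2 h with chases every 2 h to
30 h; counts recorded every 2 h).  Named scenarios: `constant`
($T = 20$ h, $pp-dd = 0$, $\gamma = 1$, no apoptosis — the regime in which
cumulative labeling was originally derived), `growing` ($pp-dd = 0.3$),
`variable_T`, `variable_mode` ($pp-dd$ ramping $+0.5 \to -0.5$),
`variable_both`, and `custom`.

The variable cycle-length profile is
$T(t) = 20 + 6\cos(2\pi t/t_{\text{end}})$: smooth, range 14–26 h, and
with time average *exactly* 20 h, which is the convention for the "true"
average under variable kinetics.  With it, C1 reads the slow early phase
(overestimating), C2's staggered second labels read the fast late phase
(underestimating), while PC and BP track the correct average within 10% —
the magnitudes of the cumulative failures depend on the profile, so only
their direction is asserted.

`run_comparison()` simulates every protocol arm per run from derived
seeds, applies all four estimators, and tabulates per-run estimates, the
dispersion across runs, the relative error of the mean, and the mean
absolute relative error; estimator failures are recorded per run, never
fatal.  `forward_consistency()` closes the loop: re-simulating from an
estimate's schedules must place the observed counts inside the 5–95%
envelope of 30 forward runs.  `factor_decomposition()` swaps schedule
components between two condition sets (individually or combined) and
reports the percent change in cycling progenitors after 22 h — the
counterfactual that attributes an expansion phenotype to $T$, $\gamma$ or
the mode of division.

```{r benchmark-example, eval = FALSE}
res <- run_comparison(make_scenario("variable_T", seed = 1))
print(res)
```

## What the generator does and does not emulate

The generator reproduces the population-level count and labeling
trajectories that these assays consume, including sigmoidal expansion,
quiescence plateaus, apoptotic thinning, and the dispersion caused by
per-cell cycle-length variability.  It does not model space (clustered
vs. isolated cells), interkinetic nuclear migration, label toxicity or
cycle-lengthening by the analog, detection noise in immunostaining, or
intermediate progenitor compartments.  Passing benchmarks here therefore
show that an estimator is sound *given its own assay's idealised readout*;
they cannot certify robustness to, say, analog toxicity, which affects
real cumulative curves and is one documented reason cumulative estimates
drift in practice.

## Numerical choices and degenerate inputs

* `dt = 0.1` h: labeling and division placement are resolved to one step;
  all time-stepping biases are $O(dt/T) \approx 0.5\%$.
* Integrals ($I$, $\Phi$, $\bar\gamma$) use the trapezoid rule on 25
  sub-points per window (200 in exactness tests).
* Problem sizes in the shipped tests were chosen to keep the full suite
  around two minutes while leaving every assertion's noise floor well
  below its tolerance: benchmarks at $m = 500 \times 10$ runs, moment
  checks at $10^5$ draws, closed-form curve checks at $m$ = 1000–4000.
* Degenerate inputs fail loudly and typed: empty curves, plateau-only
  curves (no slope), unbracketed PC peaks, all-quiescent populations,
  non-monotone time columns.  `cv = 0` is the exact deterministic limit,
  `m = 0` a valid empty simulation.
* Ties in the PC peak search resolve to the larger fraction; the
  quadratic refinement falls back to the grid argmax if its curvature is
  non-negative.

## Known limitations

* The growth-correction bias above (~$ppdd/\ln(1+ppdd)$) is documented,
  not corrected; at $pp-dd \gtrsim 0.35$ sustained over many cycles BP's
  $\widehat T$ will exceed the 10% envelope.
* BP requires absolute counts of progenitors and terminally differentiated
  cells; fractions (e.g. flow cytometry) or reversible differentiation
  break the balance equations.
* The 50% bands inherit the logistic's shape assumptions (above).
* C2's $T_S$ assumes equal detectability of both analogs; differential
  incorporation corrections are out of scope.
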