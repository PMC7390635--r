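# cyclekin

Cell-cycle length and mode-of-division kinetics from population counts.

## The problem

A differentiating stem/progenitor culture (e.g. radial glia from the
embryonic cortex) changes along three axes at once: the cycle length *T*
of cycling progenitors, the mode of division of their daughters, and the
growth fraction *γ* (share of progenitors actively cycling).  The standard
thymidine-analog assays — single (C1) and dual (C2) cumulative EdU/BrdU
curves and the pulse-chase (PC) design — estimate *T* under an assumption
of constant kinetics and can fail badly, and inconsistently, when kinetics
vary over time.

`cyclekin` is for quantitative developmental biologists who want to

* **estimate** *T*(t) and the net mode of division *pp − dd*(t) directly
  from progenitor/differentiated/quiescent/apoptotic counts via a
  branching-process (BP) inversion, with 50% confidence bands;
* **rehearse** any labeling protocol against a known ground truth, using
  an agent-based simulator with an in-silico EdU/BrdU layer;
* **compare** the four estimators under constant and time-varying
  dynamics.

For a window [t₀, t₁] with progenitor change ΔP, differentiated-cell
change ΔD, progenitor exposure I = ∫P dt, apoptotic mass Φ = ∫∅_P·P dt and
window-average growth fraction γ̄, the BP estimator inverts the population
balance:

    pp − dd = (ΔP + Φ) / (ΔP + ΔD + Φ)
    T       = γ̄ · I  / (ΔP + ΔD + Φ)

with *pp − dd* ∈ [−1, 1] (1: all divisions symmetric proliferative, −1:
all symmetric differentiative, 0: progenitor maintenance).  Under
independent daughter fates, `decompose_modes()` splits *pp − dd* into the
three division-type rates (pp, pd, dd).

The simulator tracks individual cells (gamma-dispersed cycle lengths, CV
30% by default; three equal cycle phases; quiescence tracking γ(t);
apoptosis as a continuous hazard) and marks cells in S phase during
exposure windows with permanent heritable labels, from which the
cumulative, dual-cumulative and pulse-chase readouts are assembled.

## Worked example

Simulate an expanding-then-saturating culture (mode of division ramping
from +0.7 to 0 over 48 h, *T* = 20 h), then invert the counts:

```r
library(cyclekin)

sch <- schedule_set(T_mean = 20,
                    ppdd  = list(t = c(0, 48), value = c(0.7, 0)),
                    gamma = 1)
cfg <- sim_config(initial_count = 300, t_end = 48, schedules = sch, seed = 11)
counts <- run_simulation(cfg)
tail(counts, 2)
#>    time_h   P P_cycling   D Q A
#> 24     46 627       627 668 0 0
#> 25     48 611       611 749 0 0

est <- bp_estimate(counts, gamma = 1, grid = seq(0, 48, 8), fit = "direct")
est
#>   t0 t1 t_mid   ppdd    T masked
#> 1  0  8     4 0.6328 21.5  FALSE
#> 2  8 16    12 0.5462 25.6  FALSE
#> 3 16 24    20 0.3742 25.2  FALSE
#> 4 24 32    28 0.2708 22.6  FALSE
#> 5 32 40    36 0.2000 20.9  FALSE
#> 6 40 48    44 0.0174 21.6  FALSE

summary(est)$ppdd_mean
#> [1] 0.3402308
decompose_modes(summary(est)$ppdd_mean)
#>        ppdd        pp        pd        dd
#> 1 0.3402308 0.4490546 0.4421215 0.1088239
```

The windowed `ppdd` column recovers the programmed ramp (0.63 at 4 h down
to 0.02 at 44 h).  The *T* column is exact at homeostasis and biased high
by ~*ppdd*/ln(1+*ppdd*) while the pool expands (about +10% at
*pp − dd* = 0.2; see the methods vignette), which is visible in the early
windows here.  The mode decomposition says divisions in this culture were,
on average, 45% pp / 44% pd / 11% dd.

The four-method comparison on a named scenario:

```r
run_comparison(make_scenario("variable_T", seed = 1))
#> Benchmark scenario 'variable_T' (true mean T = 20.00 h, 10 runs)
#>  method mean_estimate sd_estimate rel_err_of_mean mean_abs_rel_err n_failed
#>      BP         18.98      0.2096         0.05076          0.05076        0
#>      C1         27.11      3.4156         0.35550          0.35550        0
#>      C2         14.67      1.2818         0.26663          0.26663        0
#>      PC         20.36      0.7584         0.01793          0.03262        0
```

With a cycle length varying smoothly between 14 and 26 h (time average
exactly 20 h), the cumulative methods miss by 27–36% in opposite
directions, while pulse-chase and the branching process stay within 10%
of the correct average — the motivating result for the BP approach.

A thin command-line wrapper covers the common paths
(`exec/cyclekin simulate|estimate|benchmark|decompose|fixture`), reading
YAML/JSON configs and writing CSV/JSON plus a reproducibility manifest.

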