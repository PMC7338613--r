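---
title: "A tumor-immune-drug model for metronomic chemotherapy: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tumor-immune-drug model for metronomic chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metroimmune)
```

## The model

`metroimmune` simulates and calibrates a five-state ordinary
differential equation model of a growing tumor under repeated
("metronomic") bolus dosing of an immunogenic-cell-death drug such as
cyclophosphamide (CPA). The states are the drug concentration in the
tumor microenvironment $C(t)$, the tumor volume $T(t)$ in mm^3^, an
aggregate immune indicator $I(t)$, an immunostimulatory intermediate
$X(t)$ and an immunosuppressive intermediate $Y(t)$. All states except
$T$ are nondimensional — they lump cell populations and signaling
molecules into functional classes rather than tracking particular cell
types:

$$
\begin{aligned}
\dot C &= u(t) - \frac{k_1 C}{k_2 + C} &
\dot T &= k_a T - \frac{k_b\, C\, T}{k_c + T} - k_d\, T I \\
\dot I &= X - k_e T I - k_f C I - k_g Y I - k_h I &
\dot X &= \frac{C}{1 + C/k_i} - k_j X - k_k X Y \\
\dot Y &= \frac{I}{1 + C/k_l} - k_m Y C
\end{aligned}
$$

The structure is an incoherent feed-forward loop: the drug kills tumor
cells directly (via $k_b$) and damages the immune compartment in the
short term (via $k_f$), yet recruits immunity in the longer term
through the intermediate $X$. The suppressor $Y$, produced by the
immune response itself and cleared only by drug exposure ($k_m Y C$),
accumulates over long drug-free breaks; this is the model's mechanism
for *systemic* drug resistance — loss of treatment efficacy arising
from network dynamics rather than tumor-cell genetics.

Tumor growth is exponential with no carrying capacity: the underlying
mouse experiments never approach a maximum volume (animals are removed
long before), so a saturation term would be unidentifiable. A
configurable overflow cap (default $10^8$ mm^3^) terminates runaway
simulations explicitly, flagged on the trajectory, rather than letting
the integrator fail.

### Dosing

Injection and hepatic activation of CPA are fast compared to
tumor-immune dynamics, so each administration is an impulsive bolus:
the input rate $u(t)$ is zero everywhere and a dose instantly
increments $C$. The solver integrates segment by segment between dose
events; values stored *at* an event time are post-dose (the pre-dose
limits are kept alongside for quadrature and inspection). Doses are
nondimensional: the reference 140 mg/kg experimental dose maps to an
amount of 1 and other doses scale proportionally (210 mg/kg gives 1.5),
because the nondimensionalization absorbs absolute units and only the
dose ratio is constrained.

The regimen registry reproduces the experimental arms — untreated,
1/2/3 doses six days apart, repeating schedules every 6/9/12 days, the
alternating 6-9-day schedule, and 210 mg/kg every 9 days (same total
dose per 18-day cycle as 140 mg/kg every 6 days) — plus the two
prediction-only schedules (alternating 9-6 days and every 7.5 days).

## Numerical choices

Integration uses `deSolve`'s stiff-capable `lsodar` with a compiled C
right-hand side, `rtol = 1e-8` / `atol = 1e-10` by default (relaxed to
`1e-5`/`1e-7` inside calibration loops, where speed matters and the
residuals are dominated by measurement noise). The ODE is
positivity-preserving analytically: each state's derivative is
nonnegative wherever that state is zero, so only integrator noise can
undershoot. Components below zero by less than `neg_tol` (default
1e-9) are clipped to zero; larger undershoots raise an error rather
than being silently repaired.

Two independent oracles guard the solver: a plain-R transcription of
the right-hand side (`model_rhs()`, checked against hand-derived
values) and a compiled fixed-step classical RK4 integrator
(`rk4_simulate()`) whose derivative code is a deliberate second
transcription sharing no code with the production path. The test suite
requires agreement to 1e-4 relative across dosed 20-day trajectories.

Kill attribution (`attribute_kill()`) integrates the two tumor-kill
terms with trapezoidal quadrature on the trajectory grid, using the
pre-dose drug concentration for the right endpoint of any interval
ending at a dose so the quadrature never straddles the concentration
jump; with the default output resolution this closes the tumor mass
balance to better than 1e-4 relative.

Immune peak times are refined by parabolic interpolation through the
discrete argmax and its grid neighbors, since reported peak times are
day-resolution and a raw argmax would inherit grid artifacts. Ties
break toward the earliest time; a peak on the window boundary is
flagged and left unrefined.

## The synthetic cohort generator

The raw experimental growth curves behind the original study are not
publicly deposited, so the generator produces cohorts with the
*statistical structure* of that experiment: 4-12 tumors per arm,
initial volumes drawn uniformly from 300-1,000 mm^3^ at first
injection, measurements every 3 days from day 0 to day 45 (the true
sampling days are not published; this grid emulates the reported curve
density), dynamics simulated from a single population parameter set,
and i.i.d. multiplicative lognormal measurement noise
(`noise_sd_log = 0.15` by default — tumor-volume measurement error
scales with size, and no noise model is published). Observed volumes
are censored from below at 1 mm^3^, a caliper detection floor; without
it, fully suppressed arms decay to physically meaningless volumes
(~1e-17 mm^3^) where log residuals measure integrator noise rather
than fit quality. The only inter-subject heterogeneity is the initial
volume: the experiment was fitted with one population parameter set,
and the generator follows that design.

The shipped reference parameter set (`default_truth_params()`) is a
synthetic fixture chosen by preflight simulation to reproduce the
experiment's qualitative regimen ordering — untreated growth,
sustained regression under 6-day dosing, escape under 12-day dosing
that appears first in the largest tumors, and an immune peak that
arrives roughly one inter-dose interval later for each added dose. It
is not a fitted estimate. Consequences of passing tests on this
fixture transfer to real data only insofar as real GL261 dynamics
resemble the model class: the generator cannot exhibit model
misspecification, inter-subject parameter variability, or non-lognormal
measurement error.

```{r peaks}
peaks <- sapply(c("1-CPA", "2-CPA", "3-CPA"), function(r) {
  tr <- simulate_tumor(default_truth_params(), build_schedule(r, 45),
                       T0 = 1000, t_end = 45, dt = 0.1)
  peak_immune_time(tr)$peak_day
})
round(peaks, 1)
```

## Calibration

`multistart_fit()` fits one parameter set jointly to all arms by
minimizing the pooled sum of squared log-volume residuals over every
subject and time point. The log scale weighs regressing arms (volumes
near the detection floor) and escaping arms (volumes in the 10^5^
range) comparably; the alternative `relative_sse` loss is available as
a configuration switch. Each subject is simulated from its own first
measured volume with all other states zero — the immune compartment is
assumed quiescent at treatment start.

Initial guesses are drawn log-uniformly within per-parameter bounds
(default 1e-4 to 1e4, sampling several orders of magnitude), optionally
screened by a single objective evaluation with only the `refine_top`
best refined, and refined by bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`) on the log10-parameter scale. Fits within 1% of
the best objective are flagged as the near-optimal family. Subjects
whose simulation fails or overflows contribute a large finite penalty
to the scalar objective; inside the least-squares refinement they
instead contribute a graded residual that shrinks the later the
failure occurs, so the optimizer retains a descent direction out of
overflow regions instead of stalling on a flat penalty plateau.
Everything is deterministic given the configuration seed, and all
starts are drawn up front so results do not depend on evaluation
order.

### What is, and is not, recoverable at desk scale

The 15-parameter landscape is heavily multimodal and sloppy: many
parameter combinations produce nearly indistinguishable volume curves,
and local optimization funnels to the generating parameters only from
within roughly ±0.3 decade per parameter. A multistart with hundreds
of draws therefore finds good *local* optima but essentially never the
generating basin — the original study required over 10^5^ starts on a
compute cluster and still reported a family of eight near-optimal
fits rather than a unique optimum. The tumor growth rate `ka` is the
best-determined parameter — it is anchored by the untreated arm's
log-linear growth — but even `ka` recovery at desk-scale start counts
depends on which local minimum the multistart reaches: a fit that
trades untreated-arm error against treated-arm error can miss it by
~10%. The test suite asserts both `ka` recovery and full curve
reproduction at the published tolerances deliberately; at desk-scale
budgets these assertions document the identifiability and
multimodality limitations rather than being expected to pass.

### Outlier flagging

The robust policy summarizes each subject by the median of its
absolute log residuals and flags subjects more than 3 MAD-based robust
standard deviations above the cohort median, **and** above 0.1 log
units (~10%). The absolute guard prevents spurious flags in well-fit
cohorts whose residual dispersion is negligible (where 3 MAD can be
~1e-7), and a degenerate zero-MAD cohort flags nothing below the
guard. Flags are annotations; rows are excluded only on explicit
refit.

## Escape classification and predictions

A curve has *escaped* when it attains an interior minimum and later
exceeds `rebound_factor` (default 2.0) times that minimum; the first
crossing is the rebound day. Without a rebound it is *suppressed* when
the final volume is at most `suppression_factor` (default 0.5) times
baseline, otherwise *regressing* or *progressing* by the sign of net
change. The factors are configurable and recorded in every
classification; the published experiments state no numeric rule, so
these conservative defaults are package choices. Both the rule and
normalized mean curves (each curve scaled to 100 at baseline, averaged
arithmetically per day over available subjects) are invariant to
uniform volume rescaling.

`predict_regimens()` sweeps regimens over a grid of initial volumes
and reports escape status, drug-versus-immune kill attribution and
immune peak timing per run. On the shipped fixture, escape counts are
non-decreasing in the inter-dose interval (6, 9, 12 days), the 6-day
schedule ends far below the 12-day schedule for the largest tumors,
and the alternating 6-9-day schedule outperforms its 9-6-day mirror —
the qualitative headline that shorter breaks early in treatment
improve outcomes.

## Problem sizes used by the tests and acceptance script

Simulation-level checks run at full fidelity (they cost seconds). The
calibration study uses the full nine-arm panel with 8 subjects per arm
and 200 multistart draws with the top 8 refined; the noisy replicate
study uses 20 seeded replicates at a reduced per-replicate budget (10
draws, 1 refinement). These sizes were chosen so the whole suite runs
on a single desktop CPU; scaling `n_starts` and `refine_top` up is a
configuration change, not a code change.

## Known limitations

- The fixture is a stand-in, not the published fitted parameters; all
  fixture-level results are qualitative twins of the published
  figures, not reproductions.
- One-compartment PK with impulsive dosing abstracts away hepatic
  activation kinetics; infusion-duration effects are out of scope.
- No inter-subject parameter variability, Bayesian uncertainty, or
  profile likelihoods — point fits and near-optimal families only.
- Exponential growth without saturation overflows on long horizons by
  design; long predictions must respect the overflow flag.
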