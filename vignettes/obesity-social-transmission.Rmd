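---
title: "Modeling social transmission of obesity-related behaviors in adults and children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social transmission of obesity-related behaviors in adults and children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesitydyn)
```

## The model

`obesitydyn` implements a deterministic stock-and-flow model of how
obesity-related behaviors (unhealthy eating, low physical activity) spread
socially through a population of adults and children. Each age group is split
into three stocks — normal weight ($N$), overweight ($S$), obese ($O$) —
expressed as proportions of the group, so $N + S + O = 1$ within each group
at all times.

Four kinds of flow connect the stocks (all rates per week):

* **Social transmission.** Normal-weight individuals become overweight in
  proportion to their contact with overweight and obese individuals. Adults
  are influenced only by adults ($\beta_{AA} N_A (S_A + O_A)$); children are
  influenced by both peers and adults
  ($[\beta_{CC}(S_C+O_C) + \beta_{AC}(S_A+O_A)]\,N_C$). Children do not
  transmit behaviors to adults: child stocks never appear in the adult
  equations.
* **Progression.** Overweight individuals become obese at constant rates
  $\gamma_A S_A$ and $\gamma_C S_C$.
* **Recovery.** Of each overweight/obese stock, a fixed proportion
  ($\rho$, $\varepsilon$) is engaged in weight-loss behaviors, and an engaged
  individual needs on average $p$ weeks to drop one weight category, giving
  flows such as $\rho_{AWL} S_A / p_{SA}$ (overweight adults back to normal)
  and $\varepsilon_{CWL} O_C / p_{OC}$ (obese children back to overweight).

Assumptions worth keeping in mind: mixing is homogeneous (no network
structure), the population is fixed (no births, deaths, or ageing between the
child and adult groups), and stocks are proportions, so the
$\beta \cdot N \cdot (S+O)$ contact terms are already frequency-normalized.
Because each flow leaves one stock and enters another within the same age
group, each group's derivatives sum to zero identically — conservation is
structural, and the test suite verifies it holds to $10^{-8}$ over full runs
across random parameter draws.

## Interventions

Two intervention types act on the behavioral parameters:

* **Prevention** reduces social transmission: adult prevention scales
  $\beta_{AA}$ down, child prevention scales $\beta_{CC}$ down and
  $\beta_{AC}$ down at a *discounted* rate (children have limited influence
  over parental behavior; the discount defaults to 0.5 and is configurable).
* **Treatment** increases the engaged proportions: adult treatment scales
  $\rho_{AWL}$ and $\varepsilon_{AWL}$ up, child treatment $\rho_{CWL}$ and
  $\varepsilon_{CWL}$ up (capped at 1, since they are proportions).

Interventions aimed at one age group partially carry over to the other
through impact factors: the *total* impact on a subgroup is its direct impact
plus the factor-weighted impact aimed at the parallel subgroup of the other
age group, e.g. $h_{NC} = \eta_{NC} + \psi_A \eta_{NA}$ and
$h_{NA} = \eta_{NA} + \psi_C \eta_{NC}$. This additive proportional coupling
is the simplest form consistent with the verbal statement that each total is
"a function of both" the direct impact "and a proportion of" the parallel
one; we adopted it as the package's design choice.

Totals are applied as a linear ramp over the intervention horizon: at time
$t$ with ramp horizon $T$ (default 520 weeks), each targeted parameter is
scaled by $(1 \mp h \cdot \min(t/T, 1))$. Exactly seven parameters can
respond ($\beta_{AA}$, $\beta_{CC}$, $\beta_{AC}$, and the four engagement
proportions); progression rates and transition times never change. A total
prevention impact above 1 would drive a transmission rate negative and is
rejected rather than clamped.

`alternative_catalog()` enumerates the 15 named combinations of the four
intervention components (adult/child × prevention/treatment, `"AP"` through
`"ALL"`), each applying a default direct magnitude of 0.5 — a 50% parameter
change at full ramp. `scenario_catalog()` enumerates the six
$(\psi_A, \psi_C)$ settings: $\psi_A \in \{0.25, 0.5, 0.75\}$ crossed with
$\psi_C \in \{0.10, 0.25\}$.

## Parameters: defaults and provenance

All defaults live in `inst/extdata/default_config.json` and in the
constructor signatures; `load_config()` validates user overrides against
them. They are placeholders in the sense that the original study's full
baseline table is not reproduced here; each value is either derived by the
package's own estimation formulas or calibrated as described below.

| parameter | default | units | how chosen |
|---|---|---|---|
| `beta_aa`, `beta_cc` | 0.0015 | week⁻¹ | midpoint of the sensitivity range 0.0011–0.0019 |
| `beta_ac` | 0.00225 | week⁻¹ | 50% above `beta_cc` (parental influence on child intake exceeds peer influence) |
| `gamma_a` | 0.000769 | week⁻¹ | `progression_rate(0.16, 4*52)`: 16% four-year obesity incidence in overweight adults |
| `gamma_c` | 0.000354 | week⁻¹ | `progression_rate(0.043, 28*4.333)`: 4.3% incidence over 28 months in children |
| `p_sa`, `p_oa` | 66.2, 113.5 | weeks | `adult_transition_time()` on 7 kg / 12 kg mean excess weight at 5.5 kg/year expected loss |
| `p_sc`, `p_oc` | 45.9, 104 | weeks | `child_transition_time()` on 1.5 / 3.4 BMI-unit decreases at 1.7 BMI units/year |
| `rho_awl`, `eps_awl` | 0.05 | — | calibrated (see below) |
| `rho_cwl`, `eps_cwl` | 0.12 | — | calibrated (see below) |
| initial stocks | adults 0.312/0.331/0.357, children 0.682/0.149/0.169 | — | US adult and child weight-status prevalences circa 2009–2010 |
| `discount` | 0.5 | — | midpoint placeholder, configurable |
| `magnitude` | 0.5 | — | 50% parameter change at full ramp |

**Calibration.** The engagement proportions are the least constrained inputs,
so they were set by pattern-matching the model's one behavioral anchor: with
no interventions, the childhood overweight and obesity prevalence should grow
by a factor between 1.45 and 1.97 over ten years, the range consistent with
observed US surveillance trends. With the defaults above the no-intervention
run grows from 31.8% to 53.0%, a factor of 1.67, and the adult prevalence
drifts from 68.8% to 72.2%. This behavioral-pattern gate is asserted in the
test suite; absolute end-of-horizon prevalences under specific interventions
should be read as qualitative orderings, not predictions.

## Numerical choices

Integration is fixed-step through `deSolve`: forward Euler at `dt = 0.25`
weeks by default (the convention of the system-dynamics tooling this class of
model is usually built in), with classical RK4 available via
`sim_config(integrator = "rk4")`. The linear recovery-only subsystem
($\beta = \gamma = 0$) has a closed-form matrix-exponential solution, and the
tests require RK4 to match it to $10^{-6}$; Euler converges at first order
(halving `dt` halves the error) and agrees with RK4 on the final stocks to
better than $10^{-4}$ at the default step. Stocks are clipped to $[0, 1]$
only after a tolerance check: float-level noise (within $10^{-6}$) is
silently repaired, anything larger aborts with an error suggesting a smaller
`dt`, so model misuse is not papered over. Time-varying parameters enter
through a `schedule` function evaluated at every step, which is how the
intervention ramps are wired in.

Ranking ties in `rank_alternatives()` break alphabetically by alternative
name, making sweep outputs deterministic; with the default continuous
dynamics exact ties do not arise in practice.

## The two experiments

`run_sensitivity()` sweeps $\beta_{AC}$ and $\beta_{CC}$ over
$\{0.0011, 0.0013, 0.0015, 0.0017, 0.0019\}$ (25 no-intervention runs over
520 weeks), spanning adult-to-child rates between 0.58 and 1.73 times the
child-to-child rate, and records the final childhood prevalence per cell. The
surface is monotone along both axes with its minimum at the low-low corner.

`run_sweep()` crosses the 6 scenarios with the 15 alternatives (90
intervention runs plus a shared no-intervention baseline) at the 520-week
horizon. Structural consequences of the impact algebra, all verified by the
acceptance tests: child-only alternatives (CP, CT, CPCT) are bit-identical
across $\psi_A$; adult-only alternatives' child outcomes are invariant to
$\psi_C$; every alternative weakly dominates baseline; adding a component
never increases final childhood prevalence, so the full combination `ALL`
ranks first in every scenario, while adult prevention alone ranks last.

## The synthetic record generator

`synthesize_records()` emulates the individual-level survey inputs the
engagement estimator consumes: one row per person with a weight-status group,
a weight-loss-diet flag, and typical days-per-week × minutes-per-day of
moderate and vigorous recreational activity. Engagement requires *both* the
diet flag *and* at least 250 weekly activity minutes. The generator plants
exactly `round(target * n)` qualifying records per group and scatters the
rest across the three failure modes (no diet, insufficient activity, or
both), so `weight_loss_engagement()` recovers the target exactly whenever
`target * n` is an integer — a round-trip the tests exploit.

What it deliberately does not emulate: survey design weights, item
non-response, measurement error in self-reported activity, or correlation
between diet and activity behaviors. Passing estimation tests therefore show
the counting and thresholding rules are implemented correctly, not that the
estimator is robust to real survey artifacts.

## Problem sizes used in the checks

The test suite runs the full experiment designs at their native sizes — the
25-cell grid, the 96-row sweep, and a 100-draw random-parameter conservation
lattice, all over 520 weeks at `dt = 0.25` — which completes in well under a
minute; unit tests of the harness logic use shortened horizons (52–260
weeks) since the properties they check are horizon-independent.

## Limitations

* Homogeneous mixing: no social-network clustering, so intervention effects
  that depend on network position are out of reach.
* Deterministic and not predictive: no stochasticity, no parameter
  uncertainty, hence no significance statements about differences between
  alternatives — outputs support ordering and pattern analysis only.
* Fixed population: no demography, so horizons much beyond ten years stretch
  the model's validity.
* Single linear ramp: staged or adaptive intervention schedules are not
  modeled.
* Child growth-chart machinery is not implemented; `child_transition_time()`
  expects a BMI decrease already adjusted for expected growth.
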