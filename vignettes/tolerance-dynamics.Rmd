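---
title: "Modelling migrant influx and resident tolerance breach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling migrant influx and resident tolerance breach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migtol)
```

## The model

`migtol` simulates the arrival of migrants into a city of `M`
neighbourhoods ("cells") initially populated only by residents, and
tracks how quickly, and for how many residents, the migrant influx
pushes neighbourhood compositions past the residents' tolerance. The
model is a Schelling-type threshold model: every agent carries a single
tolerance level, defined as the *maximum* fraction of opposite-type
agents in its neighbourhood it is willing to accept. A resident with
tolerance $\tau_{res}$ is satisfied in cell $i$ when the migrant
fraction there is at most $\tau_{res}$; a migrant with tolerance
$\tau_{mig}$ is satisfied when the resident fraction is at most
$\tau_{mig}$. Because the tolerance is a maximum, boundary equality
counts as satisfied and a *breach* is a strict exceedance.

Each iteration $t$ has two phases, both sequentially updated (every
agent action is visible to the next):

1. **Entry.** $Mig(t) = g\,P(t-1)$ migrants attempt entry, where
   $P(t-1)$ is the city population at the end of the previous iteration
   and $g$ is the entry rate. Each attempting migrant independently
   draws one target cell uniformly at random and is admitted with
   probability
   $$p_{entry}(i) = \exp\!\left(-\beta_{in}\,\frac{P_i^{res}}{P_i^{tot}}\right),$$
   so entry is easiest where few residents live (ethnic-enclave entry);
   a failed attempt is discarded — there is no retry or queueing. Once
   $P(t-1)$ reaches `max_pop_factor` times the initial population, no
   further migrants attempt entry; the study design caps growth at 150%
   so that the transient — not the saturated city — is observed.
2. **Movement.** $P(t)$ agents are drawn uniformly at random *with
   replacement* and processed one at a time: a drawn agent whose
   tolerance is breached picks one uniformly random candidate cell
   (other than its own) and moves there if and only if it would be
   satisfied in the candidate cell evaluated with itself included;
   otherwise it stays.

### Observables

* $B_c(t)$ — fraction of residents whose current cell breaches their
  tolerance, from an end-of-iteration census of cell compositions.
* $B_f(t)$ — fraction of residents *ever* breached up to $t$;
  monotonically nondecreasing by construction.
* $T_\tau$ — mean first-breach iteration over all residents ever
  breached by the end of a run; undefined (an error, not zero) when no
  resident was breached.
* CSI — cell segregation indicator: the mean over non-empty cells of
  $|f_r(i)-f_m(i)|/(f_r(i)+f_m(i))$, where $f_r(i)$ and $f_m(i)$ are
  the cell's shares of the city-wide resident and migrant totals. 1 =
  fully segregated, 0 = proportionally mixed.

## Parameters and defaults

| name | default | meaning |
|---|---|---|
| `M` | 20 | neighbourhoods |
| `n_residents` | 1000 | residents (50 per cell; must divide by `M`) |
| `tau_res` | 0.25 | resident tolerance (max migrant fraction) |
| `tau_mig` | 0.75 | migrant tolerance (max resident fraction) |
| `g` | — | entry rate per iteration (study grid: 0.005–0.05) |
| `beta_in` | 1 | entry friction |
| `max_pop_factor` | 1.5 | population cap, multiple of $P(0)$ |
| `n_iterations` | 200 | run length |

The defaults are the reference study conditions; `default_scenarios()`
returns the eight-scenario grid over `g`, and ensembles of 30 seeded
runs (`run_ensemble()`) are the standard design over which every curve
and scalar is averaged.

## Design decisions

Several micro-choices are not pinned down by the verbal description of
such models; the package fixes them as follows.

* **Breach recording instant.** A resident's ever-breached flag and
  first-breach time are recorded when the agent is *activated* during
  the movement phase and finds its tolerance breached — breach is an
  agent-level assessment event, not a property stamped onto a cell's
  whole population. With replacement sampling at rate $P(t)$ draws per
  iteration, nearly every resident of a persistently breached cell is
  activated within one or two iterations, so little is missed; what the
  activation convention avoids is the alternative census convention
  (`census_breach_marking = TRUE`) marking all ~50 residents of a
  tipping cell in the same instant, which quantises the ensemble
  $B_f$ curve into 5%-of-residents jumps and distorts the timing of
  whole-percent crossings. Both conventions are available; the census
  convention additionally guarantees $B_c(t) \le B_f(t)$ at every
  census.
* **Movement sampling.** With replacement, size $P(t)$ ("on average,
  every agent moves once per iteration"). A permutation variant is
  available (`move_with_replacement = FALSE`); it suppresses the
  repeated-activation bursts and visibly flattens $B_c$, so it is not
  the default.
* **Own-cell composition includes the evaluating agent**, and a
  candidate cell is evaluated *with the agent added*; candidate cells
  exclude the current cell and are uniform over the other $M-1$.
* **Empty cells** have both fractions defined as 0, hence satisfy any
  tolerance and are always acceptable destinations.
* **Rounding.** $Mig(t)$ is rounded half-up, which keeps $g\,P(0)$
  exact on the study grid (e.g. $0.005 \times 1000 = 5$).
* **Cap check** uses $P(t-1)$ only, so the final growth iteration may
  overshoot the cap by its own admissions.
* **Seeding.** One generator per run, seeded `base_seed + run_index`;
  the global RNG state is restored after each run. A scenario plus a
  base seed determines every output byte.
* **Ensemble first-breach time** is the lift-off of the ensemble-mean
  $B_f$ curve — the first iteration at which any run in the ensemble
  has recorded a breach. This is the statistic one reads off a plotted
  mean curve; the per-run average first-breach time is reported
  alongside (`mean_run_first_breach`) and is systematically later.
* **CSI before any migrant enters** uses $f_m(i) = 0$, so the
  indicator is defined from $t=0$ (where it equals 1) rather than only
  after the first admission.

## The deterministic breach cascade

The analytical counterpart strips the stochasticity: `M` sequenced
neighbourhoods share `N` residents equally, every resident has
tolerance $\tau_r$, and $x$ migrants per neighbourhood arrive each
iteration, all admitted. A neighbourhood tips when its
migrant-to-resident ratio *reaches* $\tau_r$ (the threshold condition
is written as an equality, unlike the stochastic model's strict
exceedance — a deliberate asymmetry kept from the derivation), and its
residents are redistributed equally over the neighbourhoods after it in
sequence. With $j = \tau_r N / M$ the closed forms are

$$I_1 = j, \qquad
  I_u = \frac{M j}{(M-u+1)(M-u+2)} \;(u \ge 2), \qquad
  \sum_{q=1}^{u} I_q = \frac{jM}{M-u+1},$$

with breach times $T_u = \sum_{q\le u} I_q / x$, breached fraction
$B_u = u/M$ and mean breach time $\langle T\rangle$ the average of
$T_1..T_S$. Two structural notes:

* The general expression for $I_u$ evaluated at $u=1$ does **not**
  reduce to $j$; the definition is genuinely piecewise, and the
  telescoping identity above (which the tests verify exactly) holds
  under the piecewise reading.
* The last neighbourhood $C_M$ has no destination cells, so the
  cascade stops at $u = M-1$ and $B$ is capped at $(M-1)/M$.

`analytical_oracle()` simulates these rules literally on real-valued
migrant mass with integer iterations. Its breach iterations equal
$\lceil T_u \rceil$, i.e. they bracket the continuous-time values
within one iteration, and the migrant-load *threshold* at each breach
equals the closed-form cumulative load exactly, even when a large $x$
tips several neighbourhoods in one iteration. All quantities are kept
real-valued — the reference configuration ($\tau_r = 0.33$, $N = 5000$,
$M = 20$) makes $j = 82.5$ non-integer by construction.

Because all arrivals enter unconditionally, the cascade reproduces the
inverse relation between $\langle T\rangle$ and $B$ but *linearly*: it
lacks the entry-probability feedback (migrants finding it ever easier
to enter as breaches concentrate them) that makes the stochastic
relationship nonlinear, and its population-increase-versus-$B$ curve is
identical for every $x$.

## What the generator does and does not emulate

All data in this package are self-generated; the simulator *is* the
study system. The scenarios emulate a stylised city: homogeneous
tolerances, well-mixed neighbourhoods without geometry, migrants who
never become residents, and an entry stream proportional to current
population. Passing tests therefore show internal consistency of the
model and agreement with its published summary statistics — they say
nothing about real cities, where tolerances are heterogeneous,
neighbourhoods are spatial, and migration responds to far more than
neighbourhood composition.

## Numerical choices and degenerate inputs

* Strict/non-strict comparisons on fractions are done in integer
  arithmetic (`migrants > tau * total`), so there is no floating-point
  ambiguity at boundary compositions such as 1 migrant among 4 agents
  with $\tau_{res}=0.25$.
* The oracle uses an absolute slack of $10^{-9}$ on its equality
  threshold to absorb accumulated redistribution error.
* `n_iterations = 0` yields a trajectory holding only the initial
  census; `g = 0` is a valid scenario in which nothing ever happens;
  `M = 1` is a valid degenerate city for the stochastic model (movement
  is impossible), while the cascade model requires $M \ge 2$.
* A run with no breached residents makes $T_\tau$ an explicit error;
  ensemble summaries average over the runs that did breach and report
  how many did.

## Problem sizes

One run of the reference scenario (200 iterations, up to 1500 agents)
takes roughly 0.2 s in pure R; the full eight-scenario, 30-run study
finishes in about a minute. The package's acceptance checks use 60-run
ensembles (double the study design) to halve the standard errors of
the stochastic comparisons; unit tests use miniature cities (e.g.
4 cells x 40 residents) where invariants can be checked against brute
force.

## Known limitations

* $B_f$ moves in steps of one resident (0.1% at the reference size),
  and whole-cell tipping makes ensemble-mean crossing times of high
  percent levels sensitive to a few runs; statistics such as the peak
  of the mean $B_c$ curve retain a relative standard deviation of
  ~15% across 30-run ensembles.
* The movement phase is sequential by definition, so runs cannot be
  parallelised internally (ensembles parallelise trivially, though the
  package keeps everything single-threaded).
* The cascade model is a continuum approximation with a fixed
  neighbourhood ordering; it is a validation target and a qualitative
  guide, not a quantitative stand-in for the stochastic model.
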