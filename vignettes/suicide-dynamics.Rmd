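---
title: "A Markov illness-death model of suicide dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov illness-death model of suicide dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosemarkov)
```

## The model and its assumptions

`rosemarkov` models a closed population of size $Q_0$ moving yearly
between four compartments: healthy ($w$), mentally ill ($x$), death from
causes other than suicide ($y$) and death by suicide ($z$). Six annual
transition probabilities drive the dynamics, indexed *to–from* with
states 1–4 in the order above: $p_{21}$ (psychiatric incidence),
$p_{12}$ (recovery), $p_{31}, p_{32}$ (other-cause mortality of the
healthy and the ill) and $p_{41}, p_{42}$ (suicide mortality of the
healthy and the ill). The model is Markovian and homogeneous: everyone in
a compartment carries the same one-year risks, with no age, sex or
duration structure and no secular trend.

Two variants of the yearly map are provided.

* **Without replacement** the death compartments are absorbing stocks.
  Whenever any death probability is positive the living population
  $w + x$ decays geometrically to zero, so the long-run behaviour is
  trivial; the variant exists as a baseline and a test fixture.
* **With replacement** (the default and the object of study) every death
  of year $n$ re-enters the population as a healthy newborn in year
  $n+1$. Here $y_n$ and $z_n$ are *annual flows* — the deaths occurring
  in year $n$ — not cumulative totals. This is the only reading under
  which the total $w + x + y + z$ is conserved at $Q_0$ and the
  stationary formula below holds, so the package adopts it throughout.
  One-for-one replacement into the healthy compartment is a mathematical
  device that keeps the system alive and comparable across years, not a
  demographic claim.

With replacement the flows are

$$\begin{aligned}
w_{n+1} &= (1 - p_{21} - p_{31} - p_{41})\,w_n + p_{12}\,x_n + y_n + z_n\\
x_{n+1} &= p_{21}\,w_n + (1 - p_{12} - p_{32} - p_{42})\,x_n\\
y_{n+1} &= p_{31}\,w_n + p_{32}\,x_n\\
z_{n+1} &= p_{41}\,w_n + p_{42}\,x_n.
\end{aligned}$$

The package implements these flow equations directly (`step_population()`)
rather than a transition matrix: written as a matrix acting on a column
state the system is easy to mis-transpose, while the flows are
unambiguous and conserve the total algebraically, not merely numerically.

## The stationary state

Let $S = p_{12} + p_{32} + p_{42}$ be the ill compartment's total annual
exit probability. The yearly map has a unique fixed point, proportional to

$$(w, x, y, z) \;\propto\; \bigl(S,\; p_{21},\; p_{31}S + p_{32}p_{21},\;
p_{41}S + p_{42}p_{21}\bigr),$$

normalized by $R = (1 + p_{31} + p_{41})\,S + p_{21}(1 + p_{32} + p_{42})$,
which is exactly the sum of the four unnormalized entries — so the
fractions sum to one by construction. `equilibrium()` evaluates this
closed form; `iterate_to_equilibrium()` power-iterates the map until the
largest per-compartment change falls below `tol * Q0` and serves as the
independent cross-check (the two agree to $10^{-9}$ on a thousand random
parameter sets in the test suite).

When $S = 0$ the living ill state is absorbing, the unnormalized vector
degenerates and no limit is well defined, so `equilibrium()` raises a
`"degenerate chain"` error rather than guessing a continuation.

```{r}
m <- suicide_model()   # Hong Kong 2012 scenario
equilibrium(m)
```

## Parameters, defaults and units

All six probabilities are per person-year. The default scenario is the
Hong Kong 2012 configuration: about 150,000 psychiatric-service users in
a population of 7 million (an initial ill share of 2.14%) and roughly
20,000 new cases a year among the 6.85 million healthy, giving
$p_{21} = 0.00286$; a recovery rate of 6.67 per 100 ($p_{12} = 0.0667$);
other-cause death rates of 6 and 12 per 1,000 ($p_{31}, p_{32}$); and
suicide rates of 8.34 and 250 per 100,000 ($p_{41} = 0.0000834$,
$p_{42} = 0.0025$) — a thirty-fold excess risk among the mentally ill.
The 150,000 prevalent cases are taken as the ill *stock* at year 0,
exclusive of the incident flow; the distinction only shifts the starting
point of the transient, not the equilibrium.

Validation is strict: every probability must lie in $[0, 1]$ and each
living compartment's exits must sum to at most 1; violations are errors
naming the offending row. Compartment values are kept as doubles, not
integers, in the deterministic model — the map is an expectation, and
rounding yearly would bias long trajectories.

## Sensitivity and the Rose comparison

The equilibrium suicide count is $z = Q_0 N / R$ with
$N = p_{41}S + p_{42}p_{21}$. `dz_dparam()` differentiates this quotient
analytically, propagating the dependence of $N$, $S$ and $R$ on the
perturbed parameter, for all six parameters. A first-order projection
$\Delta z \approx \Delta p \cdot \partial z / \partial p$
(`project_delta_z()`) then prices an intervention in suicides per year.

Two alternative methods exist deliberately. Central finite differences
are the independent numerical oracle (the suite checks relative agreement
below $10^{-4}$ at step $10^{-7}$ on 200 random parameter sets). The
back-of-envelope shortcut that takes the derivative with respect to
$p_{41}$ as just the stationary healthy count $w$ is also exposed
(`method = "approximate"`): it matches the full derivative to one decimal
at the reference scenario (both give 67.2 suicides per $10^{-5}$), but it
is *inconsistent* with the equivalent-perturbation column of the scenario
sweep — only the full quotient-rule derivative reproduces the published
29 (the shortcut would give 28) — so the analytic method is canonical.

`equivalent_delta_p42()` answers the Rose question directly: how large a
change in the high-risk group's $p_{42}$ matches a population-wide change
of $p_{41}$ by $10^{-5}$? The linearized answer divides the projected
$\Delta z$ by $\partial z/\partial p_{42}$; the exact answer bisects (to
$10^{-12}$ in the probability) for the perturbation of $p_{42}$ whose
recomputed equilibrium shifts $z$ by the same amount. The exact search
perturbs $p_{42}$ *upward* within its remaining row headroom
$[0,\, 1 - S]$: for scenarios where $p_{42}$ is small (e.g. $10^{-4}$)
the equivalent magnitude ($\approx 2.8\times10^{-4}$) exceeds $p_{42}$
itself, so a downward search could never bracket the target, while the
magnitude of the matched change is direction-symmetric at first order.
Both modes agree within $0.5\times10^{-5}$ across all tabulated
scenarios. Interventions *reduce* probabilities; derivatives are stored
positive and reported as reductions.

```{r}
sensitivity_table(m)
```

`sensitivity_table()` reproduces the published 11-scenario sweep; the
reference row uses the model's own $(p_{41}, p_{42})$ so that custom
configurations appear as their own reference. Rounding for the table is
half-away-from-zero — $z$ and $\Delta z$ to integers, $\Delta z/z$ to 0.1
percentage point, the equivalent $\Delta p_{42}$ to an integer in
$10^{-5}$ units — because R's default banker's rounding would drop
half-cases the published table rounds up. Unrounded values are kept in
`raw_*` columns.

## The stochastic generator and parameter recovery

`simulate()` realizes the same dynamics stochastically: one four-outcome
multinomial draw per compartment-year — (stay, become ill, die other, die
by suicide) for the healthy, (stay, recover, die other, die by suicide)
for the ill — which is exactly the aggregate of independent per-person
categorical draws. Deaths re-enter as healthy the following year, so
living plus current-year deaths is $Q_0$ every simulated year. A single
integer seed fixes the whole run (draws are consumed in a fixed year
order, so identical seeds give identical tallies).

The generator emulates annual *transition tallies* of a closed
population: start-of-year compartment counts, six event counts and the
replacement flow. It does **not** emulate individual event histories,
overdispersion, contagion or clustering of suicides, reporting error,
migration, or any age/sex structure — so passing recovery tests show that
the estimator inverts *this* generating process, not that real registry
data would identify the parameters equally cleanly.

`estimate_transitions()` recovers each probability as pooled events over
pooled start-of-year exposure with exact binomial standard errors, and
refuses (rather than returning 0) when a compartment has no exposure.
The test suite demonstrates recovery within 4 standard errors at
$Q_0 = 10^6$ over 500 years, roughly nominal coverage of 2-SE intervals
across 20 replicate runs at $Q_0 = 10^5$ over 100 years, and agreement of
the long-run simulated ill share with the closed-form fraction at the
Hong Kong scale ($Q_0 = 7\times10^6$, 200 years, discarding a 50-year
burn-in while the transient decays). These sizes keep the whole suite in
the tens of seconds while leaving Monte-Carlo error well below the
tolerances tested.

## Numerical choices

* Convergence of the power iteration: maximum absolute per-compartment
  change below `tol * Q0`, with `tol = 1e-10` and a 100,000-year cap;
  exceeding the cap is an error reporting the final residual.
* All computation in double precision; conservation holds to $10^{-9}$
  relative per step by construction of the flow equations.
* Bisection tolerance for the exact equivalent perturbation:
  $10^{-12}$ in probability.
* Degenerate chains ($S = 0$) and zero-exposure estimates raise errors;
  no silent limits.
* Report files are written deterministically (fixed column order, fixed
  rounding rules, seeded simulation), so re-running a configuration
  reproduces byte-identical data files; only the log timestamp changes.

## Interface notes

The package follows the classic R modelling idiom: `suicide_model()`
constructs the central classed object, and `coef()`, `summary()`,
`predict()` (deterministic trajectory), `plot()` (approach to
equilibrium), `simulate()` (stochastic tallies) and
`residuals()`/`confint()` on the derived fits do what their names
promise. Pipelines are scripted through `scenario_config()` /
`read_scenario_config()` (YAML or JSON, with programmatic overrides
standing in for command-line flags) and `run_report()`, which writes the
full bundle; these functions, together with `scripts/acceptance.R`, are
the package's command-line surface.

## Known limitations

The model is a two-living-compartment caricature: no severity gradient
within mental illness, no treatment dynamics, no age structure, and a
replacement rule chosen for mathematical convenience. The parameters are
place- and period-specific (Hong Kong, 2012); conclusions about the
population-versus-high-risk differential transfer only insofar as the
~30-fold risk ratio and the compartment sizes do. The package estimates
parameters from its own simulated tallies; fitting to observed mortality
registers is out of scope.
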