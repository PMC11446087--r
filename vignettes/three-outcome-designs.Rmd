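---
title: "Designing three-outcome progression criteria for external pilot trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing three-outcome progression criteria for external pilot trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopgo)
```

## The decision problem

An external pilot trial estimates a feasibility parameter $\rho$ — an
adherence, recruitment or retention probability, or a continuous outcome mean
— and a pre-specified progression criterion maps the estimate to one of three
outcomes: *stop* (red), *pause* (amber) or *go* (green). `stopgo` treats this
rule as a three-outcome hypothesis test. The user states a poor value
$\rho_0$ and a promising value $\rho_1 > \rho_0$, and the package chooses the
sample size $n$ and thresholds $x_0 \le x_1$ so that the probabilities of the
decisions that matter are controlled.

Two sampling models are supported:

* **binary**: the count of successes $X \sim \mathrm{Bin}(n, \rho)$, with
  integer thresholds on the count scale and every probability an exact
  binomial tail — no normal approximation anywhere;
* **continuous**: the estimate $\hat\rho \sim N(\rho, \sigma^2/n)$ with
  $\sigma$ **known** and real-valued thresholds on the estimate scale.
  Estimating $\sigma$ from the pilot itself, and small-sample $t$
  refinements, are out of scope: the framework conditions on a known
  sampling distribution.

The decision convention is: stop iff the statistic is $\le x_0$, pause iff it
lies in $(x_0, x_1]$, go iff it exceeds $x_1$. On the count scale
$x_0 = -1$ encodes an empty stop region and $x_1 = n$ an empty direct-go
region, so the search space is complete even under extreme constraints;
$x_0 = x_1$ is an ordinary two-outcome stop/go rule. One could equally define
the regions with the complementary strict/non-strict pattern; we fix this one
convention everywhere, and the threshold constructor accepts proportion-scale
fractions (`"9/15"`) with an exactness check so that published rules can be
entered unambiguously. Criteria where *smaller* is better (e.g. dropout) are
reflected at the interface — $\rho \mapsto 1-\rho$ for binary endpoints,
$\rho \mapsto -\rho$ for continuous ones, via `reflect_problem()` and
`reflect_estimate()` — rather than handled inside the engines, which keeps
every formula in a single orientation.

## Operating characteristics

Classic phase-II characterisations of three-outcome rules
(`oc_classic()`) evaluate, at $\rho_0$, $\rho_1$ and a borderline value
$\rho_m$:

| symbol | definition | meaning |
|---|---|---|
| $\alpha_a$ | $\Pr[X > x_1 \mid \rho_0]$ | immediate go under the null |
| $\beta_a$ | $\Pr[X \le x_0 \mid \rho_1]$ | immediate stop under the alternative |
| $\lambda,\ \delta$ | $\Pr[x_0 < X \le x_1 \mid \rho_0],\ \cdot \mid \rho_1$ | pause probabilities |
| $\alpha_b,\ \beta_b$ | $\alpha_a + \lambda,\ \beta_a + \delta$ | non-stop / non-go errors |
| $\gamma_L,\ \gamma_U$ | $\Pr[X \le x_0 \mid \rho_m],\ \Pr[X > x_1 \mid \rho_m]$ | conclusive decisions at the borderline |

$\gamma = \gamma_L + \gamma_U$ is the probability of *any* conclusive
decision when the truth is borderline; constraining it forces a usefully wide
amber zone. $\rho_m$ defaults to the midpoint $(\rho_0+\rho_1)/2$.

A pause is not a terminal state: the trial team eventually decides to go or
stop using whatever else they know. Let $\eta_0$ be the probability that this
post-pause decision is a wrong go when $\rho = \rho_0$, and $\eta_1$ a wrong
stop when $\rho = \rho_1$. The error rates that actually matter are then

$$\alpha = \alpha_a + \eta_0\lambda, \qquad \beta = \beta_a + \eta_1\delta.$$

`oc_reformulated()` computes these. Because the pilot estimate is typically a
sufficient statistic for $\rho$, nothing else observed in the pilot can
improve the post-pause call on $\rho$ itself, and the defensible default is
$\eta_0 = \eta_1 = 0.5$ — a coin flip. Smaller values are only credible when
a genuinely informative correlated outcome (say, retention informing an
adherence pause) will be consulted; `misspecified_eta_curve()` quantifies the
cost of assuming so wrongly, re-evaluating each optimistically-optimal design
at the true $\eta$. Note the pause-route contribution can never exceed the
overall rate it feeds into ($\eta_0\lambda \le \alpha$), which is why the
reformulated search needs no separate constraints on $\lambda$ and $\delta$.

### Adjustments after a pause

When a pause triggers a modification of the intervention or trial design
(e.g. switching postal to telephone follow-up), the main-trial parameter
becomes $\rho' = \rho + \tau$ with the adjustment effect known up to an
interval $\tau \in [\tau_{min}, \tau_{max}]$, $0 \le \tau_{min} \le
\tau_{max}$. Redefining $\alpha$ ($\beta$) as the probability of proceeding
(not proceeding) when $\rho' \le \rho_0$ ($\rho' \ge \rho_1$) and maximising
over the parameter values consistent with an error gives

$$\alpha = \max\big[\Pr(X > x_1 \mid \rho_0),\;
  \eta\Pr(x_0 < X \le x_1 \mid \rho_0 - \tau_{min}) +
  \Pr(X > x_1 \mid \rho_0 - \tau_{min})\big],$$
$$\beta = \Pr(X \le x_0 \mid \rho_1 - \tau_{max}) +
  \eta\Pr(x_0 < X \le x_1 \mid \rho_1 - \tau_{max}).$$

The interior maximisations are resolved analytically at the interval
endpoints (the pause-route term of $\alpha$ is decreasing in $\rho$ once
written as $1 + (\eta-1)F(x_1) - \eta F(x_0)$, and the $\beta$ expression
$(1-\eta)F(x_0) + \eta F(x_1)$ likewise), so the engines evaluate exactly two
shifted parameter values and never re-maximise numerically. These formulas
are derived for a common $\eta$; the package therefore refuses
$\eta_0 \ne \eta_1$ whenever $\tau_{max} > 0$, while at
$\tau_{min}=\tau_{max}=0$ they reduce to the decomposition above with
separate $\eta_0, \eta_1$ allowed. $\gamma$ is always evaluated at $\rho_m$,
unshifted and unweighted: it describes the pilot's own decisiveness at the
borderline, not a downstream error.

## The search

`find_three_outcome()` minimises $n$ subject to $\alpha \le \alpha^*$,
$\beta \le \beta^*$, $\gamma \le \gamma^*$ by the nested procedure:

1. for fixed $n$ and a candidate $x_1$ with direct-go error
   $\Pr(X > x_1 \mid \rho_0) \le \alpha^*$, set the pause-route term of
   $\alpha$ equal to $\alpha^*$ and invert:
   $F(x_0) = \tfrac1\eta + \tfrac{\eta-1}{\eta}F(x_1) -
   \tfrac{\alpha^*}{\eta}$ at $\rho_0 - \tau_{min}$. On the count scale
   `x0_from_alpha()` returns the smallest integer $x_0$ keeping
   $\alpha \le \alpha^*$ (which maximises $\alpha$, and — since $\beta$ is
   increasing in $x_0$ — minimises $\beta$); on the continuous scale the
   normal quantile attains $\alpha = \alpha^*$ exactly;
2. keep the largest $x_1$ with $x_0 \le x_1$ and $\beta \le \beta^*$;
3. accept the smallest $n$ whose resulting design also has
   $\gamma \le \gamma^*$.

Sample size ascends from `n_min` with no approximate warm start: searches to
$n$ in the many hundreds complete in well under a second, and starting from
the bottom makes minimality self-evident. `brute_force_min_n()` is an
independent oracle that enumerates every $(x_0, x_1)$ pair at every $n$; the
test suite checks the two agree on randomized problems (50 problems capped at
$n \le 150$), and the returned designs are always re-validated against their
constraints by the exact engine. The classic searches
(`find_sargent_original()`, `find_storer_original()`) are exhaustive over
$(x_0, x_1)$ with ties broken by the largest $x_1$, then the largest $x_0$;
tie-breaks are a documented convention, not a claim about published
precedent, and only $n$ is oracle-checked.

For continuous endpoints (`find_three_outcome_normal()`) step 2 is a
root-finding problem; thresholds are resolved to $10^{-8}$ on the estimate
scale (a 512-point bracketing grid plus `uniroot`), $n$ stays integer, and in
the two-outcome limit ($\gamma^* = 1$, $\eta = 0.5$, $\tau = 0$) the result
agrees with the classical closed form
$\lceil \sigma^2 (z_{\alpha^*}+z_{\beta^*})^2/(\rho_1-\rho_0)^2 \rceil$
within one subject — the discrepancy of at most one arises because a
one-point-wide pause region can substitute for a slightly larger $n$.

Constraint comparisons carry an absolute guard of $10^{-12}$, protecting
against floating-point representation only — it is far below the $10^{-6}$
scale at which binomial feasibility can genuinely turn. Infeasible problems
(cap `n_max`, default 2000) raise a classed condition carrying the best
near-feasible candidate so that the CLI can exit distinctly and the sweeps
can record the gap.

### Knife edges

Because the feasible set changes discretely in $n$ and continuously in the
problem parameters, the optimal $n$ is a step function with occasional knife
edges, and third-decimal differences in a constraint or parameter can move a
step boundary. Two examples in the running problem
($\rho_0=0.5, \rho_1=0.7, \alpha^*=0.05, \beta^*=0.1$), both computed by this
package: at $\eta = 0.2$ the best $n = 41$ design, $(x_0, x_1) = (23, 27)$,
has $\beta = 0.1000021$ — infeasible by $2\times10^{-6}$ — so the optimum is
42 at $\eta = 0.2$ and 41 for $\eta$ just below it; and with a known
adjustment effect the optimum jumps $268 \to 277 \to 279 \to 281$ as $\tau$
moves from 0.124 to 0.125. Reported sample sizes at such boundaries should
always be read alongside the realised operating characteristics, which the
result objects attach. We deliberately do not soften constraint comparisons
to absorb these margins: a tolerance large enough to matter (say $10^{-5}$)
would silently admit designs whose error rates exceed their nominal levels.

## Sweeps and the fixed-n view

`sweep_eta()`, `sweep_gamma()` and `sweep_tau()` re-solve the design problem
over grids of $\eta \in [0, 0.5]$ (0.05 steps by default; $\eta > 0.5$ means
worse-than-guessing and the two-outcome design prevails),
$\gamma^* \in [0.3, 1]$, and a Cartesian grid of $\tau_{min} \in [0, 0.1]$
by interval width $[0, 0.05]$. The defaults cover the ranges a pilot
designer plausibly faces; grid points with no feasible design below the cap
are recorded as infeasible rows rather than errors, and outputs are plain
data frames writable as RFC 4180 CSV (`write_sweep_csv()`) so figures can be
drawn with any tool. Expected monotonicities — $n$ non-decreasing in $\eta$
and in $\tau_{max}$, non-increasing in $\gamma^*$ — are asserted in the test
suite. `fixed_n_tradeoff()` inverts the exercise: hold $n$ fixed and tabulate
what widening the amber zone does to $(\alpha, \beta, \gamma)$.

## Monte Carlo validation

`simulate_oc()` simulates the whole decision process: draw the pilot
statistic, classify it, and resolve pauses with a single Bernoulli
"final decision" event — the same $\eta$ abstraction the analytic formulas
use, not a mechanistic model of a correlated secondary endpoint. When an
adjustment interval is set, each pause draws
$\tau \sim U[\tau_{min}, \tau_{max}]$ (a simulation choice; the analytic
framework only ever uses the interval endpoints) and judges correctness
against $\rho + \tau$: below $\rho_0$ a go is wrong with probability
$\eta_0$, above $\rho_1$ a stop is wrong with probability $\eta_1$, and
strictly between the hypotheses neither decision is an error of either kind,
so the simulator flips a fair coin. Runs are seeded explicitly and scoped
with `withr::with_seed()`, leaving the caller's RNG state untouched. The
test suite requires empirical rates within three standard errors of the
exact engine at $10^5$ replicates.

What passing simulations do and do not show: they confirm the analytic tail
arithmetic and the post-pause bookkeeping under the stated model. They say
nothing about real pilot data — non-binomial clustering, drift in $\rho$
between pilot and main trial, post-pause decisions that are not a simple
Bernoulli event, or adjustment effects outside the assumed interval.

## Known limitations

* One progression criterion at a time; simultaneous multivariate criteria
  and decision rules combining several parameters are not modelled.
* Single-stage external pilots only: no two-stage or group-sequential
  extensions, no expected-sample-size optimality, and no modelling of the
  correlation between an internal pilot and the final analysis.
* The $\eta$ abstraction is deliberately crude; if you can model the joint
  distribution of the pilot estimate and the information consulted after a
  pause, a bespoke decision analysis will beat a constant $\eta$.
* Frequentist throughout; prior information on $\rho$ or $\tau$ enters only
  through the choice of hypotheses and the adjustment interval.
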