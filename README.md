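# stopgo

Exact design and evaluation of **three-outcome (stop / pause / go) progression
criteria** for external pilot trials.

External pilot trials commonly pre-specify "traffic light" progression rules
for feasibility parameters such as adherence, recruitment or retention: stop
(red) if the estimate is poor, go straight to the definitive trial (green) if
it is clearly adequate, and pause (amber) in between, with the final decision
then made using other information, other stakeholders, or after adjusting the
intervention. `stopgo` treats such rules as three-outcome hypothesis tests and
chooses the thresholds and the pilot sample size to control frequentist error
rates, for trial statisticians writing progression criteria into protocols.

## The model

For a binary feasibility outcome, the number of successes in the pilot's
intervention arm is `X ~ Binomial(n, ρ)`; for a continuous outcome the
estimate is `N(ρ, σ²/n)` with known `σ`. A design is `(n, x0, x1)` with

- **stop** if the statistic is ≤ `x0`,
- **pause** if it lies in `(x0, x1]`,
- **go** if it exceeds `x1`.

Hypotheses `ρ0 < ρ1` mark a poor and a promising value of the parameter. The
classic phase-II characterisations of such rules are the Sargent operating
characteristics (immediate-go error `α_a`, immediate-stop error `β_a`, pause
probabilities `λ`, `δ`) and the Storer ones (`α_b`, `β_b`, and the
conclusive-decision errors `γ_L`, `γ_U` at a borderline value `ρ_m`). A pause,
however, still ends in a final go-or-stop decision. Writing `η` for the
probability that this post-pause decision is wrong, the overall error rates
are

    α = α_a + η₀ λ,        β = β_a + η₁ δ,

and when a pause triggers an adjustment with effect `τ ∈ [τ_min, τ_max]`
(so the main-trial parameter becomes `ρ' = ρ + τ`), their worst cases over the
parameter values consistent with an error:

    α = max[ P(X > x₁ | ρ₀),  η·P(x₀ < X ≤ x₁ | ρ₀ − τ_min) + P(X > x₁ | ρ₀ − τ_min) ]
    β = P(X ≤ x₀ | ρ₁ − τ_max) + η·P(x₀ < X ≤ x₁ | ρ₁ − τ_max)

The design search minimises `n` subject to `α ≤ α*`, `β ≤ β*` and
`γ = γ_L + γ_U ≤ γ*`, all computed exactly (binomial tails; no normal
approximation for binary endpoints). See the methods vignette
(`vignettes/three-outcome-designs.Rmd`) for derivations, conventions and
numerical choices.

## Worked example

Adherence is poor at 50% and promising at 70%. We want overall error rates
`α ≤ 0.05`, `β ≤ 0.1`, assume post-pause decisions are no better than guessing
(`η = 0.5`), and want at most a 40% chance of a conclusive decision when the
true rate sits at the borderline value 0.6:

```r
library(stopgo)
p <- pilot_problem(rho0 = 0.5, rho1 = 0.7, gamma_star = 0.4)
find_three_outcome(p)
#> Three-outcome binary design: n = 98
#>   stop  (red)  : estimate <= 55
#>   pause (amber): 55 < estimate <= 64
#>   go    (green): estimate > 64
#>   alpha = 0.0476 (<= 0.05), beta = 0.0924 (<= 0.1), gamma = 0.3663 (<= 0.4)
```

So 98 participants are needed: stop if 55 or fewer adhere, go if more than 64
do, pause otherwise. The realised error rates (0.048, 0.092) and the 0.37
conclusive-decision probability at `ρ = 0.6` all sit inside their bounds.
Dropping the `γ` constraint (`gamma_star = 1`, the default) gives `n = 52` —
the price of a meaningful amber zone is roughly a doubling of the pilot.

At a fixed small pilot size the same trade-off appears in the error rates
instead:

```r
fixed_n_tradeoff(30, pilot_problem(0.5, 0.7), designs = list(c(17, 17), c(15, 20)))
#>    n x0 x1     alpha       beta     gamma ...
#> 1 30 17 17 0.1807973 0.08447006 1.0000000
#> 2 30 15 20 0.2245774 0.21406431 0.3516555
```

The two-outcome rule `x = 17` has `α = 0.18`, `β = 0.08` but always reaches a
conclusive decision at the borderline; widening to `(15, 20]` cuts that to
0.35 at the cost of `α = 0.22`, `β = 0.21`.

Other entry points: `find_two_outcome()` (exact single-stage stop/go design),
`find_sargent_original()` / `find_storer_original()` (the classic searches),
`find_three_outcome_normal()` (continuous endpoints), `sweep_eta()` /
`sweep_gamma()` / `sweep_tau()` / `misspecified_eta_curve()` (sensitivity
tables), `simulate_oc()` (Monte Carlo validation), and a command-line front
end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "stopgo.R", package = "stopgo"))')" \
  design --rho0 0.5 --rho1 0.7 --gamma 0.4
```

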