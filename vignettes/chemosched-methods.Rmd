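---
title: "Models and methods behind chemosched"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemosched}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemosched` studies how chemotherapy should be dosed when a tumor contains a
drug-resistant subclone and its growth is limited by its own vasculature.
This vignette documents the model, its parameters, the numerical machinery,
and the design decisions taken where the problem was genuinely open. It
states no empirical result beyond what the package's tests and acceptance
script themselves compute.

## The model and its assumptions

The state is `(N1, N2, K)`: sensitive tumor volume, resistant tumor volume,
and vascular carrying capacity, all in mm³. Both clones follow Gompertz
growth toward the *shared* capacity `K` — this is the one coupling through
which the clones compete. The vasculature is stimulated by tumor mass (`b`),
inhibited by tumor-derived factors (`d (N1+N2)^{2/3} K`, the surface-law term
responsible for saturation), dies naturally (`μ`), and is damaged by both
drugs (`β K u`, `γ K v`). Chemotherapy kills only sensitive cells, by
log-kill (`β₁ N1 u`); mutation exchanges cells at constant per-cell rates
`τ₁` (to resistance) and `τ₂` (back). The model deliberately ignores
pharmacokinetics (dose = plasma concentration), vessel normalization, and
immune response.

Key structural consequences, each covered by a test:

* **Positivity.** The logarithm requires `N1, N2, K > 0`; with doses in
  `[0,1]` the positive orthant is forward-invariant.
* **Untreated saturation.** With no mutation the single-clone branch settles
  at `N = K = ((b-μ)/d)^{3/2}` (≈ 17,346 mm³ at nominal rates; about
  17,000 rounded to the nearest thousand). With mutation on, the untreated
  equilibrium has `N2/N1 = τ₁/τ₂` at the same total volume.
* **Treated equilibria are resistant.** Under sustained dosing the attracting
  steady state is dominated by `N2` — the model's statement that constant
  therapy cannot eradicate, only delay.
* **Time rescaling.** Scaling all first-order rates rescales time; doubling
  every rate constant halves all event times. Conclusions therefore transfer
  across proliferation rates.

Nominal parameter values (all rates per day) are the package defaults:
`λ₁ = 0.192`, `λ₂ = 0.096`, `τ₁ = 2·10⁻⁵`, `τ₂ = 10⁻⁵`, `μ = 0`, `b = 5.85`,
`d = 8.73·10⁻³`, `β₁ = 0.3`, `β = 0.1`, `γ = 2`; doses are dimensionless
fractions of the maximum tolerated dose (MTD); the reference initial state is
`(280, 20, 650)` and the critical (fatal) volume is 8000 mm³. The
chemo-sensitivity pair `(β₁, β)` and the mutation rates are the quantities
with the greatest biological uncertainty; the sensitivity module varies them
systematically, and the short-horizon scheduling analyses use the
high-sensitivity pair `(β₁, β) = (0.6, 0.2)` — one of the two pairs the
robustness study covers — because that is the regime in which the
bang–singular–bang schedule structure (and the resistance takeover it guards
against) actually develops within a 14-day window from a 300 mm³ tumor. With
the low pair `(0.3, 0.1)` the takeover cannot occur that fast from that
state, the resistance penalty stays inert, and full dosing is trivially
optimal over 14 days.

## Survival analysis under constant dosing

The survival time `T_s(u, v)` is the first passage of `N1+N2` through
`N_crit`. Events are located by an adaptive RK45 scan that brackets the
crossing, then bisection on re-integrations from the stored bracket-left
state refines it to 1e-6 day (a tolerance we fixed; the underlying
integration uses relative tolerance 1e-8 here and 1e-6 for plain
simulation). `t_max = 1000` days defines the "never reached" sentinel; it is
configurable, and at nominal rates no `(u, v)` in the unit box holds the
tumor below 8000 mm³ at equilibrium (the fully suppressed steady total is
≈ 8900 mm³), so the sentinel is a statement about the cap, not about true
indefinite control.

`optimal_constant_dose()` does a coarse grid scan followed by golden-section
refinement of `T_s(u)`; near-ties (within 1e-3 day) break to the lower dose,
so a drug with no effect is dosed at zero. Heatmap grids default to 101×101
uniform on `[0,1]²` and mutation-rate grids are logarithmically spaced —
resolutions we chose; the landscape is smooth enough that halving the grid
spacing moves the located optimum by less than one coarse cell (tested).

## The scheduling objective

The 14-day objective charges terminal volumes (`ω₁ = 5`, `ω₂ = 25`), running
volumes (`η₁ = 1`, `η₂ = 5`; the resistant clone is five times as expensive
because it is the clone treatment cannot touch), a dose penalty
(`θ = 0`, implemented but inert at nominal weights), and a smoothed step
`(ξ/2)(1 + tanh((N2-N1)/ε))` with `ξ = 1000`, `ε = 10 mm³` that charges ξ
per day whenever the tumor is majority-resistant. One weight table we
inherited prints the label `η₁` twice (values 1.00 and 5.00); we read the
second row as `η₂ = 5`, matching the displayed integrand in which `N1`
appears unweighted and `N2` carries `η₂`.

Continuous-time evaluation uses composite trapezoid on the RK45 output grid;
the transcription uses the left-rectangle rule, the quadrature conjugate to
forward Euler, so the optimizer's reported objective is exactly the NLP's.
Both are exposed (`evaluate_objective(quadrature =)`), and objective gaps
are always computed with a single quadrature on both sides.

## Solving the optimal-control problem

We discretize first and optimize second: forward Euler on a regular grid of
400 intervals over 14 days (grids of 200–800 change the reported average
dose by < 0.1 percentage point, tested at first-order convergence), controls
bounded in `[0,1]`, states floored at 1e-9 mm³ inside the kernel to keep
logarithms defined. Rather than carrying the state variables as decision
variables, the implementation eliminates them through the Euler recursion —
the reduced problem in the 400 control values has the same minimizers as the
full transcription — and solves it with projected quasi-Newton (L-BFGS-B)
at projected-gradient tolerance 1e-12, using the exact discrete adjoint of
the hand-coded analytic Jacobian (verified against finite differences).
Interior-point local minima are the main reproducibility risk, so the solver
multistarts from the constant controls `{0, 0.5, 1}` and returns the best
objective, ties broken toward the lower average dose. A brute-force check on
a 20-interval grid confirms the solver beats every 3-segment bang-bang
control.

Singular (interior) arcs are extracted as maximal runs of at least 3 nodes
with `0.02 < u < 0.98`; the thresholds are ours, and because the singular
dose itself varies smoothly in time, the reported "mean singular dose"
depends mildly on where the run is cut. Protocols are classified full-dose
when the time-averaged dose strictly exceeds 90% of MTD.

Multi-window problems are solved sequentially (receding horizon): the
terminal state of the continuous-time simulation of one window's schedule
initializes the next. The four-way protocol comparison (optimal, MTD,
constant mean-optimal dose, optimal-then-MTD) reports end-of-window volumes
and resistant fractions. In this implementation the resistance-penalizing
schedule can undercut MTD's volume even at the end of the first window —
MTD's early kill of the sensitive clone releases the resistant clone from
competition — so MTD's short-term advantage is not guaranteed; what is
robust (and asserted) is that MTD drives the resistant fraction above 99%
by mid-therapy and ends with a substantially larger tumor.

## Piecewise-constant suboptimal protocols

The deployable approximation of a bang–singular–bang schedule is
MTD / c₁ / c₂ / MTD with switch times `t₁ < t₂ < t₃`. Initialization takes
`t₁, t₃` from the detected singular-arc boundaries, `t₂` as their midpoint
and `c₁, c₂` as segment means of the optimal control; refinement is
Nelder–Mead (restarted once) on the continuous-time objective — the deployed
protocol runs in continuous time — with infeasible simplices rejected by a
large penalty. `levels = "mean"` freezes the interior levels at the segment
means and moves only the switch times, since it is not obvious a priori
whether reported interior levels should be means or re-optimized constants;
both modes are provided. The refined protocol never scores worse than its
initialization (enforced), and its objective gap against the reference
solution is computed on the solver's own Euler grid.

## The mutation-rate robustness study

Mutation rates are the least identifiable parameters, so the study draws
`n = 400` random `(τ₁, τ₂)` pairs (default) over `[10⁻⁵, 0.05]` and
re-solves the scheduling problem per pair under four
`(β₁, β, v)` scenarios. The sampling law is log-uniform per axis — the
classification is read on the `(log₁₀τ₁, log₁₀τ₂)` plane, and an order-of-
magnitude-uncertain rate is naturally sampled on the log scale; uniform
sampling is retained as an option. Per-sample multistart is trimmed to
`{0.5, 1}` to bound runtime (the `u ≡ 0` start never wins in this regime).
Solver failures are kept in the outputs with a status label rather than
resampled, so `n` stays interpretable. The packaged tests run the study at
`n = 50` per scenario — enough to exhibit the qualitative contrasts
(intermediate-dose dominance at high chemo-sensitivity; a τ₁-driven
full/intermediate split at low sensitivity) at desk scale — with the full
`n = 400` available through the same interface.

## Numerical choices, degenerate inputs, limitations

* Integration is RK45 (deSolve `ode45`) at relative tolerance 1e-6 by
  default, with the integrator restarted at every control breakpoint so
  discontinuities never cross an adaptive step; zero-length spans return the
  initial point.
* Steady states are found as roots of the *per-capita* rates in
  log-coordinates (Levenberg–Marquardt plus a capped Newton polish): the
  extensive rates all vanish at the origin, which attracts naive least
  squares, and the per-capita form removes that trivial root. Stability is
  reported from the eigenvalues of a central-finite-difference Jacobian.
* Parameter validation permits degenerate zero rates (frozen vasculature,
  zero growth) so that closed-form limits — the Gompertz solution, mutation
  conservation — remain expressible; the biological regime has
  `λ₁ > 0`, `d > 0`, `b > μ`.
* The doubling-time operation reports the first passage through twice the
  initial volume; started at the saturating volume it reports "not reached".
  The closed-form Gompertz doubling time `ln 2 / (λ (ln N_sat − ln N_init))`
  is provided separately; the two deliberately answer different questions
  (full coupled dynamics vs. frozen-capacity growth law) and need not agree.
* Test problem sizes are deliberately modest (transcription grids of 20–400,
  survival caps of 40–300 days, `n = 50` robustness samples); they were
  chosen as the smallest sizes at which the assessed properties are stable.

Synthetic inputs throughout: every analysis in the package is a self-
contained simulation from printed parameter values; no experimental data are
fitted, so passing tests demonstrate internal consistency and faithful
numerics, not biological validation. The model omits pharmacokinetics, drug
toxicity constraints beyond the MTD box, vessel normalization, immune
response, and stochastic extinction of small clones — with volumes as low as
1e-9 mm³ representable, deterministic dynamics can regrow a clone a real
tumor would have lost.
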