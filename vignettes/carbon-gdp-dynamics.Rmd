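---
title: "Coupled CO2, GDP, forest and population dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled CO2, GDP, forest and population dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbodyn)
```

## The model

`carbodyn` implements a four-compartment nonlinear ODE system for the
interaction of atmospheric CO2 concentration $C$ (ppm), gross domestic
product $G$ (billion USD), forest area $F$ (million hectares) and human
population $N$ (million persons):

$$
\begin{aligned}
\dot C &= \alpha + \phi N + (\beta - \varepsilon) G - \eta C F - p C,\\
\dot G &= \mu - \varepsilon G,\\
\dot F &= \omega F\Big(1 - \frac{F}{K}\Big) - \theta N F + \eta\sigma C F,\\
\dot N &= s N\Big(1 - \frac{N}{M}\Big) + \theta\nu N F - \pi C N.
\end{aligned}
$$

CO2 is fed by a natural source $\alpha$, a population-proportional
anthropogenic source $\phi N$ and a net GDP term $(\beta-\varepsilon)G$
(emissions from economic activity minus GDP-funded abatement), and is
depleted by forest photosynthesis $\eta C F$ and natural decay $p C$.
GDP follows a linear inflow/decay balance and is fully decoupled from
the other states — a structural fact the package exploits repeatedly:
$G(t) = \mu/\varepsilon + (G_0 - \mu/\varepsilon)e^{-\varepsilon t}$
exactly, and $-\varepsilon$ is an eigenvalue of the Jacobian at *every*
state. Forest and population follow logistic growth with carrying
capacities $K$ and $M$, coupled through deforestation ($\theta N F$),
CO2 fertilisation ($\eta\sigma C F$), forest-supported population growth
($\theta\nu N F$) and CO2-induced mortality ($\pi C N$).

### Parameters

Baselines are a China-2000–2022-style calibration; all fifteen constants
live in `carbo_params()` with units documented there. The forest
absorption coefficient $\eta$ circulates with two values differing by a
factor of ten ($10^{-7}$ and $10^{-6}$). The package defaults to
$\eta = 10^{-7}$ because only that value makes the reported interior
equilibrium satisfy the CO2 nullcline to rounding accuracy (residual
$\approx 2.5\times10^{-6}$ versus $\approx -0.43$ for $10^{-6}$); the
alternative is one `eta_variant = "table1"` away, and the sensitivity
intervals bracket the larger value. Parameters are validated as
non-negative, with strict positivity required only where a quantity
appears in a denominator ($\varepsilon, p, \omega, K, s, M$); this
admits the degenerate limits ($\phi = 0$, $\sigma = 0$, $\theta \to 0$)
used throughout the analysis, while $\pi = 0$ raises an explicit
diagnostic where the Lyapunov weights $\phi/\pi$ would be undefined.

## Analysis chain

### Invariant region

Comparison arguments give the attracting box
$G_{\max} = \mu/\varepsilon$,
$C_{\max} = (\alpha + \phi N_{\max} + (\beta-\varepsilon)G_{\max})/p$,
$F_{\max} = K(\omega + \eta\sigma C_{\max})/\omega$,
$N_{\max} = M + (\theta\nu M/s)F_{\max}$. The three non-GDP bounds are
mutually circular; substituting the chains reduces them to a single
linear equation in $C_{\max}$, which `invariant_region()` solves exactly
rather than iterating (the fixed-point iteration is kept as a test
oracle). A non-positive denominator — possible only for degenerate
parameter combinations — is reported as an infeasibility.

### Equilibria

All equilibria share $G = \mu/\varepsilon$ (26.8125 at baselines).
`boundary_equilibria()` evaluates the three boundary points in closed
form. Two typographical defects in the circulating closed forms were
resolved in favour of direct substitution, which is what the derivations
themselves describe: the forest/population-free CO2 level is implemented
as $C_1 = (\alpha + (\beta-\varepsilon)\mu/\varepsilon)/p$ (the printed
variant is dimensionally inconsistent and is retained as a labelled
note), and the population-free point's quadratic constant term is
$\alpha + (\beta-\varepsilon)\mu/\varepsilon$. That quadratic's leading
coefficient is $\eta^2\sigma K/\omega \sim 10^{-17}$, so the textbook
root formula $(-b+\sqrt{b^2+4ac})/2a$ cancels catastrophically; the
package uses the equivalent $2c/(b+\sqrt{b^2+4ac})$, which is exact in
the $\sigma \to 0$ limit as well.

`interior_equilibrium()` eliminates $G$ analytically and solves the
remaining three nullclines in $(C, F, N)$ by damped Newton iteration
with the analytic $3\times3$ Jacobian, started at the midpoint of the
invariant region, with a steady-state-integration fallback
($t = 10^5$) if Newton stalls. The result is accepted only when all
components are strictly positive and the full vector-field residual is
below $10^{-8}$; by default it is also cross-validated against the
long-time integration endpoint. Tests validate the root against an
independent one-dimensional reduction (given $F$, the CO2 and forest
nullclines are linear in $(C, N)$; the population nullcline residual is
then a scalar function of $F$ solved by bisection).

A deliberate asymmetry: the reported interior equilibrium components for
forest and population do not satisfy the forest nullcline (per-capita
residual $\approx 0.017$, three orders of magnitude beyond rounding), so
the package treats only the CO2 and GDP components of the reported point
as checkable, via `solve_cn_at_forest()` — the exact $2\times2$ solve of
the CO2 and population balances with forest held at the reported value.
That reproduces the reported $C \approx 130.9959$ to four significant
figures, while the self-consistent equilibrium solved from all four
balances sits at $(141.14, 26.8125, 5054.6, 82.87)$.

### Local and global stability

`stability_report()` classifies an equilibrium by the eigenvalues of the
full Jacobian; real parts within $10^{-12}$ of zero are called marginal,
never stable. Closed-form directional eigenvalues are used for the
boundary points; note that the population-direction eigenvalue at the
forest/population-free point is $s - \pi C_1$ (the Jacobian's diagonal
entry), which at baselines is $+8.2\times10^{-5}$ — the point is
unstable regardless, through the forest direction
$\omega + \eta\sigma C_1 > 0$.

For the interior point, `cubic_coefficients()` factors the
characteristic polynomial as
$(\psi+\varepsilon)(\psi^3 + A_1\psi^2 + A_2\psi + A_3)$ and computes
$A_1, A_2, A_3$ from the nullcline-reduced $3\times3$ Jacobian (whose
forest and population diagonal entries collapse to $-\omega F_4/K$ and
$-s N_4/M$). A previously published closed-form coefficient set is
retained verbatim under the `paper` label for comparison, but it
disagrees with the characteristic polynomial (its trace term carries
extra $2\omega F_4/K$ and $2\nu\theta F_4$ contributions) and never
drives the verdict. The Routh–Hurwitz condition
($A_i > 0$, $A_1A_2 - A_3 > 0$) is checked against the eigenvalue sign
pattern on 500 jittered parameter sets in the test suite.

`global_stability_check()` evaluates the Lyapunov condition for
$V = \tfrac12(C-C_4)^2 + \tfrac12(G-G_4)^2 + m_1 V_F + m_2 V_N$ (with
Volterra terms $V_X = X - X_4 - X_4\log(X/X_4)$ and weights
$m_2 = \phi/\pi$, $m_1 = \nu m_2$ chosen to cancel two cross terms).
The sufficient condition circulates in two forms differing in the power
of $\eta$ in the forest brace term; the squared form is what the
completion-of-squares derivation produces, so it drives the `satisfied`
flag, and both are reported. At baselines the squared form holds with
little margin ($0.0316 < 0.0330$) and the first-power form fails by
seven orders of magnitude — numerically the Lyapunov function is
monotone along baseline trajectories to below $10^{-10}$ per step.

Two timescale facts shape the convergence tests. First, GDP relaxes at
rate $\varepsilon$ (time constant 1250 yr), so from a near-zero initial
GDP its residual at $t = 4000$ is about 4% of the offset — convergence
is therefore asserted per component at its natural scale (CO2 within
1 ppm; forest and population within 1%; GDP against its exact
exponential). Second, starts near the invariant region's corners (very
high CO2 with a tiny population) push the population through
near-extinction, and its logistic recovery alone exceeds any practical
horizon; the Monte-Carlo basin corroboration (60 seeded starts) samples
away from the absorbing faces for that reason.

## Sensitivity analysis

`lhs_sample()` wraps a Latin hypercube (one draw per equal-probability
stratum per parameter) over the documented $\pm10\%$-style intervals,
and `prcc()` implements the standard partial rank correlation: ranks
with tie-averaging, each of rank($X_i$) and rank($Y$) regressed on the
other fourteen rank columns, and the product-moment correlation of the
residual pairs. (A circulating rendition of the formula repeats the same
residual sum in both denominator factors; the standard definition is
implemented and is verified in tests against precision-matrix partial
correlation.) Optional p-values use $n - 2 - 13$ degrees of freedom,
unadjusted. `prcc_over_time()` integrates the model once per sample row
from a common initial state — $(130, 0.121, 1003, 80)$, the optimal
control experiment's start, since no initial state is documented for the
sensitivity runs — and computes PRCC per output and time point, failing
hard if more than 1% of integrations fail.

At $n = 300$, seed 1, the signs reproduce the expected structure:
$\alpha$ and $\phi$ positive on CO2, $p$ strongly negative, $\mu$ and
$\varepsilon$ dominating GDP with everything else negligible, and the
curves settle between $t = 2000$ and $t = 4000$ (max change 0.053).
One ranking deliberately *fails* in the acceptance suite: the expected
"natural decay rate most negative on CO2" does not hold, because the
mortality coefficient $\pi$ out-ranks it ($-0.96$ vs $-0.89$).
This is not a sampling artefact: deterministic elasticities of the
computed equilibrium give
$|\partial \ln C_4 / \partial \ln \pi| = 0.58$ versus
$0.34$ for $p$ — the CO2–mortality–population feedback ($\pi$ lowers
$N$, which lowers $\phi N$) is simply the stronger lever at these
baselines, and since $t = 4000$ is effectively at equilibrium the
ranking is independent of the initial state and sample size. The test
records the discrepancy rather than masking it.

## Optimal mitigation control

Replacing the constant abatement rate with a bounded effort $u(t)$
(entering as $(\beta - u)G$ in the CO2 balance and $-uG$ in the GDP
balance) and minimising
$J = \int_0^{t_f} \big[A\,C(t) + \tfrac{B}{2}u^2(t)\big]\,dt$
over $0 \le u \le u_{\max}$ yields, via the Pontryagin conditions, four
adjoint ODEs with zero terminal values and the projected minimiser
$u_* = \max\{0, \min\{u_{\max}, (\lambda_1+\lambda_2)G/B\}\}$.
`forward_backward_sweep()` solves the two-point problem with fixed-step
RK4 passes (default $10^4$ steps), zero initial control, relaxed updates
$u \leftarrow (1-\rho)u + \rho u_*$ with $\rho = 0.5$, and joint
relative sup-norm tolerance $10^{-3}$ (cap 200 iterations) — the
horizon, weights and box follow the reference experiment
($A = 10^{-4}$, $B = 10$, $u_{\max} = 0.008$, $t_f = 100$); the
relaxation, tolerance and grid are package choices, exposed in the
configuration. At that setting the sweep converges in about ten
iterations; the converged control is interior (max $\approx 4\times
10^{-4}$), satisfies the projection fixed point and interior
stationarity $|Bu - (\lambda_1+\lambda_2)G| < 10\,\delta$, and the
controlled CO2 path dominates the uncontrolled one pointwise with
$J \le J(u\equiv0) \le J(u\equiv u_{\max})$. The "uncontrolled"
comparator is $u \equiv 0$ (no intervention); since $u$ only ever
removes CO2 and GDP, any admissible control lowers $C$ pointwise
relative to it. No published number for $J$ or the terminal CO2 level
exists, so the checks are property-based by design.

## Synthetic observations and parameter recovery

`generate_observations()` integrates the model at annual points over a
23-year window and applies independent multiplicative lognormal noise
(defaults 2% on CO2 and forest, 1% on GDP and population — positive
magnitudes spanning orders of magnitude argue for relative noise). What
it emulates is the *statistical shape* of national annual series: rising
CO2, near-linear GDP inflow, slowly growing forest, logistic population.
What it does not emulate: reporting revisions, autocorrelated
measurement error, structural breaks (policy shifts, economic shocks),
or any unit conversion between emission mass and concentration. Tests
passing on these series therefore demonstrate correctness of the
machinery, not fidelity of the model to real national statistics.

`estimate_rates()` provides the averaging-style closed-form estimators:
the GDP inflow from the exact one-step solution of the linear subsystem
(recovering the generating 0.02145 essentially exactly on noiseless
series), and logistic-corrected mean log-increments for the forest and
population growth rates (both to well under 1% on pure-logistic series).

`recover_parameters()` is a least-squares trajectory-matching harness:
scaled residuals (each variable over its series mean), bounded L-BFGS-B
from the bound-box midpoint plus three seeded random restarts, keeping
the best objective. Two numerical choices matter. The optimiser is given
`parscale` equal to the start (the parameters span five orders of
magnitude, and `optim`'s default *absolute* finite-difference step of
$10^{-3}$ would otherwise perturb small rates by more than 100%). And
the simulation starts from the generator's stored initial state rather
than the first noisy observation, so first-row noise does not bias every
residual.

A genuine identifiability finding: the pair $(\phi, p)$ is sloppy.
They enter the CO2 balance only through $\phi N - pC$, and over a
23-year window $N$ and $C$ change shape too little to separate them:
profiling the objective along the ridge shows variation of order
$10^{-5}$ across the entire $\pm50\%$ bound box at 1% noise, so the
individual estimates slide to wherever the noise tilts the ridge (often
a bound), while the combination $\phi\bar N - p\bar C$ is recovered to
a few percent. A local optimiser left near a truth-equal start will
*appear* to recover both to a few percent; a converged one will not.
The acceptance suite states the stricter individual-recovery claim and
is allowed to fail it; the unit suite asserts the identified
combination. Identifiable subsets ($\{\mu, \varepsilon\}$ through the
closed-form GDP subsystem, $\{\alpha\}$) are recovered to optimizer
tolerance at zero noise, and recovery error shrinks with the noise
level (checked over eight seeds).

## Problem sizes used by the checks

Suite sizes are package choices balancing statistical resolution against
a test run of well under a minute: Jacobian finite-difference checks on
100 draws, Hurwitz-versus-eigenvalue agreement on 500 jittered parameter
sets, PRCC designs of $n = 300$ (signs and rankings stabilise well below
the published $n = 1000$), 60 Monte-Carlo basin starts, recovery
monotonicity over 8 seeds, and a single full sweep at the reference
$10^4$-step grid.

## Known limitations

* The model treats CO2 in ppm with emission parameters taken as given;
  no mass-to-concentration conversion is attempted or validated.
* No bifurcation continuation, center-manifold or Hopf analysis; the
  stability toolkit covers hyperbolic equilibria only.
* The control problem handles a single bounded control with a quadratic
  running cost; no bang-bang or singular-arc analysis.
* Calibration is local least squares on one series; no posterior
  uncertainty, and sloppy directions (above) are reported, not resolved.
* The sensitivity initial state is a package default; coefficient
  *magnitudes* therefore carry no reproduction claim — signs and
  rankings at equilibrium do.
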