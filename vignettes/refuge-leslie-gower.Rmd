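---
title: "Methods: equilibria, stability, and iterative attractivity certificates for a Leslie-Gower model with a prey refuge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: refuge-modified Leslie-Gower dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgrefuge)
```

## The model and its assumptions

The package analyses the planar system

$$
\dot x = \Big(r_1 - b_1 x - \frac{a_1(1-m)\,y}{(1-m)x + k_1}\Big)x,
\qquad
\dot y = \Big(r_2 - \frac{a_2\,y}{(1-m)x + k_2}\Big)y,
$$

a Leslie–Gower predator–prey model with a Holling type II functional
response in which a constant fraction $m \in [0,1)$ of the prey
population is protected by a refuge. Only the exposed prey $(1-m)x$
enters the functional response and the predator's carrying capacity
$r_2\big((1-m)x + k_2\big)/a_2$. The modelling assumptions are the
usual ones for this family: homogeneous mixing outside the refuge, a
refuge proportion that is constant in time and density, instantaneous
(undelayed) responses, and deterministic dynamics on the non-negative
quadrant.

Parameters, with units (`time` and `density` are arbitrary but must be
used consistently):

| parameter | meaning | units | constraint |
|---|---|---|---|
| `r1`, `r2` | intrinsic growth rates of prey / predator | 1/time | $> 0$ |
| `b1` | prey intraspecific competition | 1/(time·density) | $> 0$ |
| `a1` | maximum per-capita predation rate | 1/time | $> 0$ |
| `k1` | prey protection (half-saturation) constant | density | $> 0$ |
| `a2` | food-quantity conversion measure | density/(time·density) | $> 0$ |
| `k2` | predator protection constant (alternate food) | density | $\ge 0$ |
| `m` | refuge fraction | — | $[0, 1)$ |

With $m = 0$ the refuge disappears and the model reduces to the
refuge-free modified Leslie–Gower system; the package treats that as an
ordinary parameter choice, not a separate code path. The boundary case
$k_2 = 0$ (no alternate food, the Holling–Tanner model) makes the
predator equation singular at $x = 0$, so `lg_params()` rejects
$k_2 = 0$ unless `holling_tanner = TRUE` is passed explicitly; this
prevents a silent division by zero in code that did not mean to opt in.
State validation otherwise permits $x = 0$ or $y = 0$, because the
boundary dynamics (extinction, prey-only, predator-only) are
scientifically meaningful.

## Equilibrium structure

Interior equilibria lie on the predator nullcline
$y = r_2\big((1-m)x + k_2\big)/a_2$; substituting it into the prey
nullcline gives the quadratic

$$
a_2 b_1 (1-m)\,x^2 + B\,x + \big[(1-m)a_1 r_2 k_2 - a_2 r_1 k_1\big] = 0,
\qquad
B = a_1 r_2 (1-m)^2 - a_2 r_1 (1-m) + a_2 b_1 k_1,
$$

with discriminant
$\Delta = B^2 - 4(1-m)a_2 b_1\big[(1-m)a_1 r_2 k_2 - a_2 r_1 k_1\big]$.
Existence is governed by $B$, $\Delta$ and the refuge threshold
$1 - a_2 r_1 k_1/(a_1 r_2 k_2)$: above the threshold (or at it with
$B < 0$, or below it with $B < 0$ and $\Delta = 0$) there is exactly
one interior equilibrium `E3_1`; below the threshold with $B < 0$ and
$\Delta > 0$ there are two, `E3_minus < E3_plus`; otherwise none
(`lg_classify_case()`).

Numerical choices:

* **Knife-edge equalities.** "$m$ at the threshold" and "$\Delta = 0$"
  are exact algebraic events; they are detected with an absolute
  tolerance of $10^{-12}$ scaled by the magnitude of the compared
  quantities. Generic parameter sets never sit on these measure-zero
  boundaries, and the classification is verified (by test) to be stable
  under $\pm 10^{-9}$ relative perturbations away from them.
* **Stable quadratic roots.** Roots are computed as
  $q = -(B + \operatorname{sign}(B)\sqrt\Delta)/2$, first root $q/a$,
  companion root $c/q$ from the product of roots, which avoids the
  catastrophic cancellation of the textbook formula when $B$ and
  $\sqrt\Delta$ nearly cancel.
* **Boundary collisions.** A root with $x$ below $10^{-12}$ times the
  prey carrying capacity is treated as a boundary collision and
  excluded from the interior list (this happens exactly at the
  threshold, where one root passes through zero).
* **Uncovered corner.** The case list is silent about $B \ge 0$ with
  $m$ below the threshold and $\Delta > 0$ (the quadratic then has no
  positive root, since the product of roots is positive and their sum
  is negative). The package classifies it as the no-equilibrium case by
  the literal rule and flags the configuration in the returned object
  so the report shows the rule was applied rather than derived.
* **$k_2 = 0$.** The threshold formula diverges to $-\infty$; any
  admissible $m$ is then "above threshold", which the code represents
  literally with `m_threshold = -Inf`.

## Linearized stability

`lg_stability()` computes the eigenvalues of the analytic Jacobian; a
real part within $10^{-9}(1 + |\lambda|)$ of zero makes the verdict
`nonhyperbolic` (the theory's strict inequalities give no guidance at
the boundary, so the package refuses to guess there). For interior
equilibria the sufficient polynomial criterion

$$
2 b_1 (1-m) x^2 - \big(r_1(1-m) - r_2(1-m) - b_1 k_1\big)x + k_1 r_2 > 0
$$

is evaluated and recorded as a diagnostic. It is one-sided: a positive
value guarantees stability of `E3_1`/`E3_plus`, a non-positive value
says nothing. The eigenvalue computation is therefore the
authoritative verdict; `prop1_agrees` records agreement where the
criterion speaks, and `lg_stability_scan()` hunts for contradictions
over random parameter sets (none exist if the implementation is
correct; the scan is a standing cross-check between the two routes, and
biases half its draws toward the two-equilibrium regime so the
instability of the smaller equilibrium is actually exercised).

## The iterative attractivity certificate

When the margin of

$$
C_3:\quad a_2 b_1 r_1 k_1 - a_1(1-m)^2 r_1 r_2 - a_1(1-m) b_1 r_2 k_2 > 0
$$

is positive, the unique interior equilibrium attracts every positive
solution. The certificate is constructive. A logistic comparison
argument bounds any positive solution ultimately by
$x \le r_1/b_1 + \varepsilon$; feeding that bound through the predator
equation, then back through the prey equation, yields first-round
bounds $M_1^{(1)}, M_2^{(1)}, m_1^{(1)}, m_2^{(1)}$, and repeating the
procedure with the current bracket in place of the crude bound gives
the recurrences (implemented verbatim in `lg_iterate_bounds()`, with
the $\varepsilon/n$ slack terms kept exactly)

$$
M_1^{(n)} = \frac{r_1 - \frac{a_1(1-m)\,m_2^{(n-1)}}{(1-m)M_1^{(n-1)} + k_1}}{b_1}
  + \frac{\varepsilon}{n},
\qquad
M_2^{(n)} = \frac{r_2\big((1-m)M_1^{(n)} + k_2\big)}{a_2} + \frac{\varepsilon}{n},
$$
$$
m_1^{(n)} = \frac{r_1 - \frac{a_1(1-m)\,M_2^{(n)}}{(1-m)m_1^{(n-1)} + k_1}}{b_1}
  - \frac{\varepsilon}{n},
\qquad
m_2^{(n)} = \frac{r_2\big((1-m)m_1^{(n)} + k_2\big)}{a_2} - \frac{\varepsilon}{n}.
$$

The upper sequences are non-increasing, the lower ones non-decreasing
and positive, every positive solution is eventually squeezed inside
$[m_1^{(n)}, M_1^{(n)}] \times [m_2^{(n)}, M_2^{(n)}]$, and under $C_3$
the common limit of the brackets is the equilibrium — uniqueness of the
limit follows because the two limit points would otherwise be distinct
positive roots of an auxiliary quadratic whose constant term `D`
(reported by `lg_discriminants()`) is negative under $C_3$.

### Choosing the slack $\varepsilon$

The theory asks only for $\varepsilon$ "small enough". Two families of
inequalities must survive it:

1. the strict slack inequality
   $\frac{\text{C3 margin}}{a_2 b_1 k_1} -
   \big(\frac{a_1(1-m)^2 r_2}{a_2 k_1} + \frac{a_1(1-m)}{k_1}\big)
   \varepsilon > 0$, and
2. positivity of the first-round lower bounds $m_1^{(1)}(\varepsilon)$
   and $m_2^{(1)}(\varepsilon)$, which are affine decreasing functions
   of $\varepsilon$.

Point 2 matters in practice: on the worked example the critical
$\varepsilon$ of inequality 1 alone is $\approx 4.86$, yet
$m_1^{(1)}$ already turns negative at $\varepsilon \approx 0.97$.
Using only inequality 1 to pick the slack would hand the iteration a
negative "lower bound" and invalidate the certificate on the very
system it is meant to certify. `lg_epsilon()` therefore returns half
the minimum of the three critical values (all closed-form), which is
deterministic, reproducible, and keeps every required inequality strict
with a factor-two margin. An `epsilon` override that still drives a
lower bound non-positive is an error, never silently repaired —
a negative bound means the certificate as constructed is wrong, and
masking it would defeat the point of a certificate.

### Sequences versus limits

With any fixed $\varepsilon$ the raw iterates carry an
$O(\varepsilon/n)$ offset, so they approach their limits harmonically,
not geometrically: the iterates themselves are honest ultimate bounds
but slow pointers to the limit. The limits — the objects the
attractivity statement is actually about — satisfy the same
recurrences with the vanishing offset removed, so
`lg_iterate_bounds()` computes them by iterating the offset-free map,
which contracts geometrically (13 rounds to $10^{-10}$ bracket-width
stability on the worked example). Both views are returned: `sequences`
(the certificate, monotone by construction) and `limits` (their common
limit, compared against the quadratic's root in `lg_certify()` as the
`agreement_gap`). Convergence is declared when the change in the two
bracket widths falls below `tol` (default $10^{-10}$), with a cap of
`n_max = 10000` rounds.

### Permanence and special cases

The first-round bounds at $\varepsilon \to 0$ give the explicit
permanence box of `lg_permanence_bounds()`:
$\bar x = r_1/b_1$, $\bar y = r_2((1-m)\bar x + k_2)/a_2$,
$\underline x = (r_1 - a_1(1-m)\bar y/k_1)/b_1$,
$\underline y = r_2((1-m)\underline x + k_2)/a_2$, all positive under
$C_3$. Two reductions are handled by the same code path rather than by
special cases:

* At $m = 0$ the margin of $C_3$ equals, term by term, the margin of
  the refuge-free condition $C_1$; the historical second condition
  $C_2$ (built from the auxiliary constants $L$ and $M$) is computed
  and reported for comparison but never gates anything — randomized
  search readily finds parameter sets where $C_1$ holds, $C_2$ fails,
  and the certificate still converges, demonstrating numerically that
  $C_2$ is redundant.
* At $k_2 = 0$ the $C_3$ margin coincides with the Holling–Tanner
  condition $C_4$ margin and the predator recurrences lose their $k_2$
  terms automatically.

`lg_certify()` refuses parameter sets in the two-equilibrium regime:
the iterative argument covers only the unique-equilibrium case, and
with a stable node and a saddle coexisting no global certificate can
exist, so extrapolating would be wrong rather than merely unproven.

## Simulation

`lg_integrate()` wraps `deSolve::ode` (default `lsoda`) with the
analytic Jacobian supplied. Defaults: `rtol = 1e-9`, `atol = 1e-12`,
so that integrator error is orders of magnitude below the $10^{-3}$
tolerance used when checking convergence onto the equilibrium;
`t_end = 50`, ample for systems with rates of order ten (the worked
example's transient is over by $t \approx 2$), and overridable for
slower parameter regimes. The output grid (default 1001 points) only
samples the dense solution; tests verify the final state is invariant
to grid halving at $10^{-6}$.

Interior trajectories of this model stay positive analytically, so the
integrator is not projected onto the quadrant: a value below
$-10^{-9}$ aborts with an error (it would mean integrator failure, and
clipping would hide it), while round-off undershoot in $(-10^{-9}, 0)$
is clipped to zero and flagged on the returned object.

`lg_sweep_refuge()` re-runs the classification, the $C_3$ margin and
the stability verdicts over a grid of refuge fractions. The margin is
non-decreasing in $m$ — predation pressure enters $C_3$ only through
$(1-m)$ factors — so sweeps show directly how a larger refuge makes
certified coexistence easier.

## What the tests do and do not show

The test suite exercises the package on the canonical worked example
(`r1=11, b1=5, a1=4, k1=6.5, r2=8, a2=2, k2=2, m=0.4`), on hand-built
fixtures for the two-equilibrium and no-equilibrium regimes, and on
log-uniform random parameter draws over $[0.05, 20]^7$ with
$m \sim U[0, 0.95]$ (30–200 draws per property; independent oracles:
nullcline bisection for roots, central finite differences for the
Jacobian, eigenvalues for stability). These are synthetic parameter
regimes, not fits to data: passing tests show the algebra, the
certificate construction and the integrator are mutually consistent
and reproduce the reference analysis, not that any particular
ecological population obeys this model. Real systems with strongly
seasonal rates, density-dependent refuge use, or delays are outside
the model class by assumption.

## Known limitations

* No bifurcation-curve continuation: classification is pointwise (plus
  grid sweeps); the package does not track fold points in parameter
  space.
* No center-manifold analysis at nonhyperbolic equilibria and no Hopf
  detection; `nonhyperbolic` is a terminal verdict.
* The attractivity certificate is sufficient, not necessary: a failing
  $C_3$ margin proves nothing about divergence, and the certificate
  does not cover the two-equilibrium regime by design.
* Stochastic, delayed, impulsive and harvested variants of the model
  are out of scope, as are spatial (PDE) refuges.
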