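---
title: "Event-space generating functions for linear population dynamics"
author: "eventpgf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-space generating functions for linear population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventpgf)
```

## The model

`eventpgf` works with Markov jump processes for populations divided into
`N` compartments, driven by `E` event types occurring at rates that are
*linear* in the current population numbers ("first-order reactions").
A model is the triple

* `X(0)`: nonnegative integer initial populations,
* `delta` (`N x E`): the incidence matrix, `delta[j, a]` being the change
  of population `j` when event `a` fires,
* `r` (`E x N`): nonnegative rate coefficients, with event rate
  `R_a = sum_k r[a, k] X_k` (units 1/time).

The state carried through time is not the population vector but the
lattice of cumulative event counts `n = (n_1, ..., n_E)`; populations are
recovered by the bookkeeping identity `X(t) = X(0) + delta %*% n`.
Working in event space keeps biological information (how many
maturations, how many deaths) that projection onto populations destroys,
and regularises the mathematics: every event increases its count by one.

Two structural rules make population space positively invariant and are
enforced by `validate_model()`:

* `delta[j, a] >= -1` — a linear-rate event removes at most one
  individual;
* if `delta[i, a] == -1`, then `r[a, k] == 0` for `k != i` — an event
  that removes an individual from compartment `i` fires at a rate
  proportional to `X_i` alone, so it cannot fire on an empty compartment.

We additionally assume *linearly independent increments* (LII): no fixed
linear combination of population increments vanishes identically, which
is equivalent to `delta` having full row rank.  Rank and kernel
statements are structural claims, so they are computed in exact integer
(fraction-free) elimination rather than floating point.

When `E > N` the incidence matrix has a nontrivial kernel.  Each integer
kernel vector `v` ("structural zero") is a combination of events with no
net population effect — e.g. one birth plus one death — and yields a
conserved monomial `prod_a x_a^{v_a}` along the characteristic ODEs
below.  Under LII there are exactly `E - N` of them.

## Exact solution by characteristics

The probability generating function
`Psi(z, t) = sum_n P(n, t) prod_a z_a^{n_a}` satisfies a first-order
linear PDE whose characteristics form a small autonomous ODE system.
The package's primary route uses *population coordinates*: per-individual
factors `w_k(z, t)` with

```
dw_k/dt = w_k * sum_b r[b, k] * (z_b * prod_j w_j^delta[j, b] - 1),   w_k(0) = 1,
Psi(z, t) = prod_k w_k(z, t)^{X_k(0)}.
```

This formulation has two advantages: structural zeroes are satisfied
automatically (no auxiliary integer vector `m` with `F m = R0` needs to
be chosen — `find_m_vector()` exists purely as a diagnostic, and we store
a real-valued minimal-norm solution because the solution is only defined
up to kernel shifts anyway), and the cohort factorises into independent
individuals, which is also what makes the simulation schemes below
consistent.  A second, independent route (`solve_f_via_phi1()`)
integrates the characteristic flow started at the transform point
together with an exponent integral; the two routes agree to `1e-7` on
random models, and both are pinned against the closed forms below.
The sign/orientation convention (integrate forward over `[0, t]` from
unit initial data) is fixed by the pure-death closed form in the unit
tests.

The ODE integrator is `deSolve::zvode` (complex-valued state) in
Adams/functional-iteration mode — the systems are smooth and non-stiff on
the unit polydisk, and this keeps memory linear in the number of stacked
transform points.  Default tolerances are `rtol = 1e-10`,
`atol = 1e-12`, chosen so that transform-inversion error is dominated by
lattice truncation, not integration.  Transform arguments with
`|z| > 1.5` are rejected (`Psi` generally has a finite-radius pole
outside the closed unit disk; grid evaluation only ever uses `|z| = 1`).
The projection wrapper `population_psi()` disables the guard because
projection points `z_a = prod_k y_k^delta[k, a]` legitimately leave the
disk.

`event_count_distribution()` inverts the transform on a tensor grid of
roots of unity, one stacked ODE solve for the whole grid followed by a
multidimensional FFT.  Counts beyond the per-event truncation alias
back onto the lattice; the captured-mass attribute reports the
truncation quality, and automatic truncation doubles the bounds until
the tail mass falls below `1e-6`.  Tiny negative probabilities (below
`1e-8` in magnitude) are clipped to zero with a warning.

`moments()` differentiates `Psi` at `z = 1`: complex-step derivatives
(step `1e-4`) for means and central differences (step `1e-3`) for second
derivatives, with tighter ODE tolerances (`1e-12`/`1e-14`) for these
solves.  `Psi` is analytic, so steps this large carry negligible
truncation error while keeping the integrator noise amplified by `1/h`
or `1/h^2` at the `1e-5`–`1e-4` level; meaningfully smaller steps would
amplify integrator noise beyond the truncation gain.

## Closed forms

The classic linear processes and the developmental cascades admit closed
forms, all implemented and all cross-checked against the ODE route:

* **Pure death** — `Psi = (e^{-rt} + z(1 - e^{-rt}))^M`: deaths are
  binomial.
* **Linear birth–death** — the familiar rational form in population
  space with `W = e^{(r2 - r1) t}`; the equal-rate case is evaluated by
  its analytic limit `((y + rt(1-y)) / (1 + rt(1-y)))^X0` once the
  relative rate gap falls below `1e-9`, where the generic expression
  loses digits to cancellation.
* **Developmental cascade** (`E` maturation stages, per-stage
  exponential waiting): the per-individual factor `W0` in a
  partial-fraction form for pairwise-distinct rates and a compact
  Erlang/Poisson form for equal rates.  The coefficient of
  `prod z` is the exit-time CDF: regularized incomplete gamma
  `P(E, rt)` (Erlang) for equal rates, the hypoexponential CDF for
  distinct rates.
* **Cascade with per-stage mortality**: maturation competes with death
  at every stage; the exit-time law is defective with mass
  `prod r/(q+r)`.  The partial-fraction form, as this result is usually
  written, abbreviates its stage factors with indexed brackets whose
  index ranges are easy to misread; the implementation fixes the
  interpretation (stage-`E-k` factors `r_{E-k} y_{E-k}` and
  `q_{E-k} z_{E-k}`) *by requiring agreement with the integral
  recursion for the stage factors to `1e-8`* — this verification is a
  permanent unit test, not an assumption.  The same
  recursion, integrated directly (`cascade_W0_ode()`), also serves as
  the evaluation route for near-degenerate rates.
* **Stage occupancy / drug delivery**: for a four-stage cascade
  (stomach, duodenum, jejunum, ilium, with dissolution as the death
  analogue) the probability of being undissolved in stage `i` at time
  `t` has an explicit partial-fraction expression, verified against
  coefficient extraction from the mortality-cascade `W0`.

Degeneracy policy: the partial-fraction forms divide by rate gaps, so
exact ties route to the equal-rate forms, and relative gaps below `1e-6`
raise an error pointing at the ODE recursion (`cascade_W0()` automates
this routing).  The threshold is deliberately conservative: at a `1e-6`
relative gap the cancellation error in the distinct form is still only
of order `1e-10` over the tested horizons, and the monotone convergence
of distinct to equal forms as gaps shrink through `1e-2 .. 1e-4` is
itself a test.

## Short-time approximation schemes

When the characteristic ODEs are not worth solving (inside a simulation
step, say), the package provides the systematic short-time hierarchy:

* **Poisson** (`poisson_psi()`): freeze every event at its initial rate;
  `Psi ~ exp(t sum R0 (z - 1))`, independent Poisson counts.  One-step
  total-variation error decays as `h^2` (global error `o(t)`).
  Structural zeroes are respected; positive invariance is not.
* **Multinomial order n** (`picard_iterate()`): truncated Picard
  iterates of the `w` ODE, with Maclaurin truncation in `t` of order
  `n - 1` inside the integral.  The iterate `w^(n)` is a polynomial of
  degree `n` in `z` whose total-degree-`p` coefficient has leading time
  order `t^p`, evaluates to exactly 1 at `z = 1`, and has nonnegative
  coefficients for small steps — i.e. it is a genuine per-individual
  generating function, which is what guarantees populations can never go
  negative in the derived simulation scheme.  Successive differences
  shrink like `h^n`.

Polynomial arithmetic is exact term algebra on multi-indexed
coefficient vectors: products truncate in `t` only, and the `z`-degree
cap equal to the `t`-cap is lossless because any term of higher
`z`-degree carries a higher power of `t` (the reciprocals needed for
`delta = -1` factors are geometric series that terminate at the
`t`-cap).  With double-precision rate coefficients the algebraic
identities (normalisation at `z = 1`, probabilities summing to one) hold
to roundoff, about `1e-15`; tests assert them at `1e-12`.

The order-2 step probabilities (`second_order_step()`) are filled
exactly from the second-order expansion: no event, single event,
ordered two-event, plus the decomposition used by the simulator —
marginal first-event probabilities and conditional second-event
probabilities.  One coefficient that is easy to get wrong (the
`-h^2 sum_a r_a^k` term of the single-event probability, which lacks
the 1/2 carried by the neighbouring terms) is re-derived from the
expansion in a dedicated unit test.  The admissible step bound
`h_max` is found by bisection on the minimum probability entry.  The
residual `o(h^2)` mass of the conditional row is assigned to "no second
event"; if a near-bound step makes the row sum exceed one, the row is
renormalised and the correction logged when it exceeds `1e-6`.

`order_of_accuracy()` measures one-step total-variation error against
the exact distribution over a geometric ladder of step sizes and reports
the log-log slope.  The default ladder spans `2^-6 .. 2^-11`: larger
steps visibly mix in the next-order term and bias the slope low, and the
reference is solved at `1e-12`/`1e-14` tolerances so that the smallest
order-2 errors (~`1e-10`) stay above the reference noise floor.
Expected slopes are 2 (Poisson and order-1) and 3 (order-2).

## Simulators and oracles

* `ssa_simulate()`: the exact algorithm — exponential waiting times at
  the total rate, event choice proportional to rates.  Used as a
  distribution-level oracle (ensembles of terminal counts) and for
  waiting-time law checks.
* `master_equation_integrate()`: brute-force integration of the forward
  equation on a truncated count lattice (at most `1e5` states), with
  boundary out-flux discarded and reported.  This is the independent
  oracle for the transform-inversion route.
* `multinomial_step_simulate()`: the fixed-step scheme.  Per step and
  population, one multinomial with `X_k` trials over (no event, first
  event `b`); at order 2, each first event draws a conditional second
  event.  Populations update at step end; the step probabilities already
  account for intra-step sequencing.  A single multinomial with `X_k`
  trials replaces `X_k` independent categorical draws — distributionally
  identical and much faster.

Random-number policy: every simulator takes an explicit integer seed and
is bit-reproducible under it (`withr::with_seed`, so the caller's RNG
state is untouched).

`compare_to_exact()` reports total-variation distance and per-cell
deviations: z-scores with binomial standard errors where the expected
cell count is at least 5, and an equivalent two-sided Poisson tail test
for rarer cells, where the normal approximation would flag spuriously.

## The synthetic model families

`generate_fixture()` builds the study systems: pure death, birth–death,
maturation cascades with and without mortality (bidiagonal incidence,
diagonal rates; the post-cascade absorbing stage carries no events and
is deliberately not modelled as a population, since including it would
create a conserved total and violate LII), and random valid linear
models for property-style tests.  Random models are built from removal,
transfer, and single-birth production events, so validity holds by
construction; production is capped at one individual per event, keeping
the drawn models in the regime where the characteristic flow is
well-conditioned over the tested horizons — multi-offspring events are
legal in the framework and enter the validation tests, but make poor
random test beds because their generating functions develop poles close
to the unit circle.

What these families do *not* emulate: time-varying environments
(rate coefficients are constant per model; piecewise-constant schedules
can be composed by restarting from projected populations), density
dependence (rates are strictly linear), and observation noise.  Passing
tests therefore demonstrate correctness of the linear-rate machinery,
not fit to any particular insect data set.

## Problem sizes used in the checks

The shipped checks run on one CPU in a few minutes total: transform
inversions on lattices up to ~`1e5` points, master-equation oracles on
lattices up to `1e5` states, simulation ensembles of `1e4` runs on the
birth–death fixture (horizon `0.3`, order-2 step `0.01 / total rate`),
and ten random fixtures with at most 3 populations, 4 events, initial
counts at most 5 and horizons with `t * total rate <= 2`.  These sizes
were chosen so that every oracle comparison resolves at the tolerance it
asserts (truncation tails below `1e-8`, Monte-Carlo cells tested at the
4-sigma level).

## Known limitations

* Rates must be constant in time within a model; the paper-level
  generality of time-varying coefficients is supported only as
  piecewise-constant composition by the caller.
* Nonlinear (density-dependent) rates are out of scope.
* The `o(t^{3/2})`-corrected Poisson scheme and Picard orders above 6
  are not implemented.
* The master-equation oracle is dense; it is an oracle for small
  models, not a production solver.
* Start times other than 0 are handled by shifting the time origin,
  which is lossless for constant rates.
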