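---
title: "Fractional-order couple dynamics: model, solver, stability, and a priori bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order couple dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplefde)
```

## The model

`couplefde` studies a two-person interpersonal-dynamics model in which the
feelings $x_1(t)$, $x_2(t)$ of two individuals evolve under a Caputo
fractional derivative:

$$
D^{\nu} x_1 = -\alpha_1 x_1 + \beta_1 x_2 (1 - \varepsilon x_2^2) + A_1,
\qquad
D^{\nu} x_2 = -\alpha_2 x_2 + \beta_2 x_1 (1 - \varepsilon x_1^2) + A_2,
$$

with $x_1(0) = x_2(0) = 0$ (a relationship starting from indifference).
The $\alpha_i > 0$ are *oblivion* constants (feelings decay in the partner's
absence), $\beta_i$ are *reaction* constants (response to the partner,
either sign), $\varepsilon \ge 0$ saturates strong feelings through the
cubic term, and $A_i$ are constant *attraction* (appeal) terms.  The signs
of the $\beta_i$ encode "romantic styles": a *secure or cautious lover* is
encouraged by the partner ($\beta_1 > 0$), a *hermit* retreats from the
partner ($\beta_2 < 0$).  We store the oblivion constants positive and let
the decay enter the right-hand side as $-\alpha_i x_i$; the style presets in
[`sample_scenarios()`] pin only the reaction signs, which is the convention
consistent with the reference parameter set (all $\alpha_i > 0$,
$\beta_2 < 0$).

Two derivative-order regimes matter:

* $1 < \nu \le 2$ — the *accelerated* model.  Raising the order beyond one
  adds inertia ("acceleration in feelings") while retaining fractional
  memory.
* $0 < \nu < 1$ — the setting of the a priori bound machinery
  (`theorem9_bounds()`).

## Order reduction

For $1 < \nu \le 2$ the model is never integrated directly.  Under zero
initial conditions the Caputo composition identity
$D^{\alpha}(D^{\alpha} x) = D^{2\alpha} x$ holds with $\alpha = \nu/2$, so
the substitution $y_1 = x_1$, $y_2 = D^{\alpha} x_1$, $y_3 = x_2$,
$y_4 = D^{\alpha} x_2$ yields a four-dimensional system of order
$\alpha \in (0.5, 1]$ (`transform_to_first_order()`).  The zero initial
state is hard-wired on this path because the identity requires it; the 2-D
order-$\nu$ path (`as_fde_system_2d()`, $\nu \le 1$) accepts arbitrary
initial states.  Orders in $(0, 1]$ also mean only $y(0)$ is needed as
initial data, so multi-term initial conditions never arise anywhere in the
package.

## The predictor–corrector solver

`caputo_pece_solve()` implements the fractional Adams–Bashforth–Moulton
(PECE) scheme on the Volterra integral form of the Caputo problem: a
fractional rectangle-rule predictor followed by a fractional trapezoid
corrector (weights given in the function documentation).  Design choices:

* **Uniform grid only.** The reference simulations use a fixed step; no
  adaptivity is attempted.
* **Corrector iterations default to 1** (classic PECE).  More iterations
  drive the step toward the implicit fractional trapezoid solution; this is
  configurable but does not reliably reduce the error against exact
  solutions, so 1 is the default.
* **Full-memory sums.** The Caputo kernel is nonlocal: step $n$ costs
  $O(n)$, the whole solve $O(N^2)$.  Each history sum is a single
  `crossprod`, which keeps a $6{,}000$-step, 4-dimensional solve at about
  two seconds.  No short-memory truncation is applied — truncation would
  perturb exactly the slow algebraic tails this model exhibits.
* **Failure over clipping.** A non-finite state raises a classed error
  carrying the step index.  The cubic right-hand side genuinely blows up
  for bad parameter draws, and silent clipping would corrupt sweeps.
* **Defaults for the reference run**: $h = 0.05$, $T = 300$.  No step size
  or horizon is prescribed by the source material; these were fixed once so
  that the trajectory's approach to its equilibrium is clearly visible at
  desk scale.

At $\alpha = 1$ the weights collapse to the classical one-step ABM pair,
and the empirical convergence slope on $y' = -y$ is $2$ (checked by
`estimate_convergence_order()`, which fits $\log$ error at $T$ against
$\log h$).  For $\alpha < 1$ the theoretical order for smooth solutions is
$\min(2, 1 + \alpha)$; the tests assert a slope of at least 1 plus pointwise
agreement with the Mittag-Leffler solution of the linear problem.

## Mittag-Leffler evaluation

$E_\alpha(z)$ is the analytic oracle for linear problems:
$D^\alpha y = \lambda y$, $y(0) = y_0$ has $y(t) = y_0
E_\alpha(\lambda t^\alpha)$.  The power series is numerically poisonous on
the far negative axis — its largest term grows like
$\exp(|z|^{1/\alpha})$ before cancellation — so `mittag_leffler()` switches
representation:

* series for $z \ge 0$ and for moderate negative $z$
  ($|z| \le 5$ and $|z|^{1/\alpha} \le 10$, capping cancellation at about
  four digits);
* for far-negative $z$ with $\alpha < 1$, the complete-monotonicity
  spectral integral, after the substitution $w = r^\alpha$ that removes the
  endpoint singularity (validated against $E_{1/2}(-1) = e\,\mathrm{erfc}(1)$
  and against the series where both are accurate);
* $\exp(z)$ at $\alpha = 1$; the half-order duplication identity with a
  complex series for $\alpha \in (1, 2]$.

Exhausting the iteration budget raises an explicit error rather than
returning a poor value.

## Equilibria and stability

Equilibria of the transformed system force $y_2^* = y_4^* = 0$, leaving two
algebraic equations.  `find_equilibria()` eliminates $y_1$ (a cubic in
$y_3$), assembles the resulting degree-$\le 9$ polynomial in $y_3$
*symbolically in its coefficients* — no floating subtraction of like terms —
and calls the companion-matrix root finder.  This reproduces the reference
positive equilibrium $(4.38469, 0, 4.92833, 0)$ to five decimals.  Real
roots are residual-filtered ($10^{-8}$ by default) and de-duplicated.  When
several equilibria exist the reported one is the smallest-norm equilibrium
with both feeling coordinates positive, falling back to the
smallest-residual one — the "positive equilibrium" convention.

The Jacobian is biquadratic: $P(\lambda) = \lambda^4 + a_1 \lambda^2 + a_2$
with $a_1 = \alpha_1 + \alpha_2$ and $a_2 = \alpha_1\alpha_2 - ab$, where
$a = \beta_1(1 - 3\varepsilon y_3^{*2})$, $b = \beta_2(1 - 3\varepsilon
y_1^{*2})$.  Two *independent* verdicts are computed:

* **fractional Routh–Hurwitz** on the reduced quadratic
  $k^2 + a_1 k + a_2$: stable if $a_1 > 0$ and $a_2 > 0$; unstable if
  $a_2 < 0$ (a positive real root then exists); otherwise *indeterminate* —
  the sufficient conditions are silent on the boundary, and we do not force
  a verdict there.  Sign strictness uses tolerance $10^{-12}$.
* **eigenvalue-argument test**: asymptotic stability iff every eigenvalue
  satisfies $|\arg \lambda_i| > \alpha\pi/2$.  The four $\lambda$ are both
  principal square roots of each $k$ root (so each $\lambda^2$ reproduces a
  $k$); the test is applied to the $\lambda$, the actual system eigenvalues.
  A zero eigenvalue counts as violating the condition; angles within
  tolerance of the sector boundary report *marginal*.

The two verdicts can genuinely disagree when the $k$ roots are complex with
arguments near $\pi/2$ — the sufficient sign conditions promise stability
for *all* $\alpha \in (0,1)$, while the sector condition can fail for
$\alpha$ near 1.  `full_stability_report()` therefore records both verdicts
and a `verdicts_agree` flag instead of resolving the tension; the test
suite checks that disagreement never occurs when the $k$ roots are real and
negative.

## A priori bounds

For the order-$\alpha \in (0,1)$ 2-D system with zero initial data, if the
right-hand sides satisfy the linear envelope
$|f_1| \le a_1(t)|x_1| + b_1(t)|x_2|$ (and symmetrically), the solutions
admit explicit upper bounds built from three ingredients:

1. the closed-form power-kernel integral
   $\int_0^t (t-s)^{p(\beta-1)} s^{p(\gamma-1)} ds =
   t^{\theta} B[p(\gamma-1)+1, p(\beta-1)+1]$ (`beta_integral()`);
2. the Hölder conjugate pair $p = (1+4\alpha)/(1+3\alpha)$,
   $q = (1+4\alpha)/\alpha$, chosen so that both kernel exponents stay
   integrable: $p(\alpha-1)+1 = 4\alpha^2/(1+3\alpha) > 0$ and
   $q\alpha - 1 = 4\alpha > 0$ (`holder_exponents()`);
3. the nondecreasing kernel factor
   $k^*(t) = t^{q\alpha-1} B^{q/p}[\cdot,\cdot] / \Gamma^q(\alpha)$
   (`kstar()`), computed in log space because $q$ blows up as
   $\alpha \to 0$.

The envelope curves of `theorem9_bounds()` carry the singular prefactor
$t^{\alpha-1}$, so evaluation grids must be strictly positive even though
the integrals start at 0.  The two-function Gronwall lemma behind the
derivation is exposed directly as `coupled_gronwall_bound()`, with
monotonicity and nonnegativity of all inputs verified on the grid and
violations rejected with the offending index.

**Quadrature.** Every running integral — including the nested inner ones,
whose kernels $\varphi(t,s)$ depend on the outer variable — is a cumulative
composite trapezoid sum on a once-refined (midpoint-inserted) copy of the
evaluation grid.  Cumulative Simpson rules are awkward when every grid
point must serve as an upper limit and the kernel changes with that limit;
midpoint refinement recovers comparable accuracy (the tests pin constant
and decoupled kernels to their closed forms at $10^{-4}$, and envelope
values move by less than $10^{-4}$ under a $10\times$ finer grid).

**Two incompatibilities worth knowing.**  First, the linear envelope forces
$f(t, 0, 0) = 0$, which the couple model violates whenever $A_i \ne 0$;
`couple_bound_coefficients()` therefore refuses nonzero attraction
constants rather than silently absorbing them, and its constant
coefficients ($|\beta_i|(1 + \varepsilon M^2)$ on a box $|x_i| \le M$) are
documented as a local, not global, linearization.  Second, with Lipschitz
right-hand sides inside the envelope and zero initial data the unique
solution is identically zero, making the bounds trivially true.  The
empirical probe in the test suite therefore uses the non-Lipschitz
right-hand side $f_i = c\sqrt{|x_1 x_2|}$ — inside the envelope with
coefficients $c/2$ by AM–GM, yet with nonunique solutions from rest — and
starts the solver at a tiny positive state ($10^{-8}$) to select a
nontrivial branch.  That run grows away from zero and stays below its
envelope at every grid point.

## Scenario generation

`sample_scenarios()` draws parameter magnitudes uniformly from
per-parameter ranges defaulting to one order of magnitude around the
reference regime ($[v/10,\ 10v]$ for each reference value $v$) and applies
the style's sign pattern; unpinned reaction signs are drawn at random, and
oblivion/attraction constants stay positive.  The range default keeps the
cubic term perturbative, as in the regime the model was designed around.
Draws are reproducible from the seed (the global RNG state is restored
afterwards).  The pseudo-style `"paper_section5"` returns the reference
parameter set exactly.

What the generator emulates is the *parameter regimes*, not data: there is
no observation noise, no time-varying parameters, no fitted individuals.
Passing sweep tests therefore says the analysis pipeline is internally
consistent across romantic-style regimes, and nothing about how real
couples behave.

## Numerical choices and limitations

* **Problem sizes.** The test suite solves up to $6{,}000$ steps
  (reference run), uses grids of 61–481 points for the Gronwall
  comparisons, 100–1000 random draws for identity sweeps, and Picard
  oracles on $8\times$ refined grids; the whole suite runs in well under a
  minute.
* **Slow saturation.** In the reference regime the equilibrium's
  eigenvalues are *purely imaginary* ($\pm 0.0710i$, $\pm 0.0772i$), so
  stability is entirely a fractional-order effect and the approach is an
  algebraically damped oscillation with envelope $\sim t^{-\alpha}$.
  Proximity thresholds must be read against that tail: halving the distance
  takes roughly a $2.4\times$ longer horizon, and tight thresholds are
  reached only on horizons several times the default $T = 300$.
* **Degenerate inputs.** $\alpha_1 = 0$ breaks the equilibrium elimination
  and is rejected; grids containing $0$ are rejected by the envelope
  evaluator; non-monotone Gronwall inputs are rejected with the offending
  index; solver blow-ups carry the step index.
* **Out of scope.** Global stability, basins of attraction, bifurcation
  analysis, parameter estimation from observed relationship data, and
  direct discretizations of Riemann–Liouville or Grünwald–Letnikov
  derivatives (the model is solved in Caputo form only, and orders above 1
  only via the transformation).
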