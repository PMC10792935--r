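---
title: "Shape-constrained temporal classification of short time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained temporal classification of short time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempclass)
```

## The model and its assumptions

`tempclass` treats a short replicate time series as noisy observations
of a smooth latent kinetic, `y_i = f(t_i) + ε_i`.  Two assumptions carry
all the statistical weight:

* **Smoothness.**  Molecular abundances cannot oscillate arbitrarily
  fast; synthesis and degradation are costly.  The fit is therefore a
  natural cubic spline with knots at the measured time points,
  penalized by the integrated squared curvature `∫ f''(t)² dt`.
* **Heteroscedastic measurement quality.**  Time points measured with
  high replicate scatter should influence the curve less.  The data
  fidelity term is `(λ/n)‖W(a − y)‖²` with diagonal weights
  `w_i ∝ 1/σ_i`, normalized to mean one so that rescaling all SDs
  leaves the fit unchanged.

The estimation problem is a convex quadratic program in the knot values
`a`; second derivatives follow as `c = D⁻¹ H a` from the classical band
matrices.  `D` is factorized, never inverted.

A third, structural assumption restricts *shape*: a biological response
has few extrema.  Candidate shapes ("parent shapes") fix the number of
extrema `k = 0..4` and the type of the first one; a placement assigns
each extremum to one inter-timepoint interval.  Every other interval is
constrained monotone through five linear conditions (the secant sign,
both endpoint slopes, and the two Fritsch–Carlson-type bounds
`3(a_{i+1}−a_i)/h_i − f'` at either endpoint — sufficient conditions for
a monotone cubic).  The printed source family of these conditions is
symmetric in the two endpoint slopes, so the fifth row uses the
right-endpoint slope.  All rows form `C a ≥ 0`; a constant vector is
always feasible, so the constrained QP always has a solution.

## Selection machinery

Within one shape, λ is chosen by grid search over a modified GCV score
with inflation factor ρ: constraint rows active at the optimum
(`C_A a = 0`) reduce the effective flexibility of the fit, which the
influence matrix accounts for through an orthonormal null-space basis
`Z` of `C_A`.  Because the solution satisfies all active rows exactly,
`a = A_λ y` holds exactly with
`A_λ = 2(λ/n) Z (Zᵀ G_λ Z)⁻¹ Zᵀ WᵀW`; the score is
`n‖W(a−y)‖²/Tr(I − ρA_λ)²` and a fit whose trace term is non-positive
is excluded.  With ρ = 1.3 and n = 8 this caps the usable effective
degrees of freedom near `n/ρ ≈ 6.2` — a deliberately conservative
choice for small samples: fits that would need more flexibility lose to
smoother ones unless active constraints absorb the difference.

Across parent shapes, the final model minimizes the extrema-penalized
small-sample AIC with `k` = the enforced number of extrema.  For the
unconstrained candidate no extrema count is enforced; this package
charges it the number of extrema its fit actually contains (a switch
`unconstrained_k = "zero"` restores the literal reading), so that
unconstrained flexibility is still penalized.  Exact AICc ties resolve
toward fewer extrema, then toward the increasing parent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_grid(min, max, count)` | 1e-4 … 1e7, 61 log-spaced | smoothing factor search grid; the lower end behaves like the weighted least-squares line, the upper end interpolates |
| `rho` | 1.3 | mGCV inflation for small samples |
| `max_extrema` | 4 | parent-shape ceiling; 11 candidate fits |
| `weight_mode` | `"inverse-sd"` | `"sd"` preserves the literal initial-weight reading; `"uniform"` disables weighting |
| `tol` | 1e-7 | active-set membership, relative to `1 + max(a)` |
| `quasi_constant_threshold` | 1.0 | range-to-pooled-SD ratio below which a signal is labelled `"C"` |

The weight direction deserves a note: low weights must encode high
variances for the outlier-damping mechanism to work, hence the
reciprocal initial weight with a floor of `1e-3` times the median
positive SD; single-replicate time points (SD undefined) receive the
mean initial weight rather than a silent zero.

## Numerical choices

* The QP is solved by a textbook primal active-set iteration started at
  the (always feasible) constant vector; equality subproblems are
  solved in the null space of the working rows via Cholesky, falling
  back to an eigenvalue-clamped solve for the near-singular systems
  that arise at very small λ (the penalty kernel has rank n−2).
  Stationarity is declared when the step or its predicted objective
  decrease falls below rounding noise — a pure step-norm test is
  unattainable for badly conditioned `G_λ`.  Sweeps over the λ grid
  warm-start each solve from the previous λ's solution.
* Extrema are roots of the per-interval quadratic `s'(u)` in `[0, 1)`
  (final interval `[0, 1]`, avoiding double counting at shared knots),
  computed with the numerically stable quadratic formula.  A root where
  `s''` vanishes relative to the model's curvature scale is either a
  constraint-pinned extremum sitting exactly on a knot (the common case
  under active monotonicity constraints) or a tangency artefact; the
  two are told apart by probing the slope sign change across the point.
* Prominence pruning: the QP resolves knot values to a tolerance
  relative to their magnitude, so alternating extrema separated by less
  than `1e-6 (1 + max|a|)` in value — solver noise on numerically flat
  stretches — cancel in pairs (an isolated extremum indistinguishable
  from both neighbours is dropped too).
* Tie-breaks: mGCV ties keep the smaller (smoother) λ; nearest-knot
  ties assign an extremum to the earlier knot; two extrema mapping to
  one knot are merged to the more prominent one, and Max/Min
  alternation is restored by dropping the weaker of any same-type pair.

## What the synthetic generator emulates

`generator_config()` defaults to the perturbation-response design the
method targets: 8 time points on the interval-doubling schedule 0, 0.5,
1, 2, 4, 8, 16, 24 h, 3 replicates, Gaussian replicate noise with SD 5%
of the dynamic range, optional outliers and a heavy-tailed (t, 3 df)
noise switch.

Latent ground-truth curves deserve care, because a recovery study is
only meaningful if the truth lies in the family the method believes in:

* Anchor values (extrema at the named time points; maxima at the
  amplitude, minima at zero) are connected by strictly monotone cubic
  steps in a log-warped time coordinate `τ = log(t − t_1 + h_1)`.  A
  response-rate sampling design places time points where comparable
  change is expected per sample, so a realistic kinetic changes by
  comparable amounts between consecutive samples rather than per unit
  time.
* After the last extremum the curve relaxes exponentially toward the
  opposite level (first-order kinetics, reaching it at the final time
  point) — the canonical transient-response tail, which also keeps the
  tail informatively sloped rather than flat.
* The anchor profile is then presmoothed by the constrained smoothing
  spline itself (uniform weights, the label's own monotonicity pattern
  with one free interval per extremum, alternating left/right of the
  extremum knot so a monotone run separates consecutive extrema).  A
  fixed smoothing ladder (λ = 300, 1000, 3000, 10000, 100) is scanned
  and the smoothest member kept whose natural interpolant realizes the
  requested class exactly with every extremum separated from its
  neighbouring levels by at least 25% of the dynamic range; otherwise
  construction fails loudly.  Presmoothing encodes the same smoothness
  premise the classifier relies on — ground truth is drawn from the
  smooth shape family, as is customary in parameter-recovery studies.

What the generator does **not** emulate: intensity-dependent
missingness, normalization artefacts, correlated replicate errors, or
batch effects.  Recovery rates measured on these simulations therefore
quantify the method's behaviour under its own assumptions, not its
robustness to violations of them; on rougher real kinetics the
conservative mGCV (see above) shades toward smoother, lower-`k` fits.

## Study sizes used by the test suite

The packaged checks run at deliberate desk scale: oracle equivalence on
20 random 8-point signals; constraint satisfaction on 100 signals × 11
parent shapes against a 1000-point dense grid; extrema extraction on
500 fitted splines against a 10⁴-points-per-interval oracle; class
recovery on 200 signals per class from {I, D, Max4, Min3,Max4} at 5%
noise (≥ 90% per class, exact at zero noise); outlier robustness on 100
paired fits.  The clustering and validation baselines run on small
simulated mixes.

## Known limitations

* Classification quality at interior knots adjacent to long sampling
  gaps is intrinsically asymmetric: curvature is cheap in long
  intervals, so overly smooth candidates can drag an extremum toward
  the longer side.  The conservative ρ amplifies this on clean data,
  where monotone-compatible fits have no active rows and hence no
  flexibility credit.
* With very low (but nonzero) noise, AICc's `2k` penalty can lose
  against near-interpolating fits of residual structure, occasionally
  adding a spurious low-amplitude extremum; at the design noise levels
  this is rare.
* The method is intended for 4–12 time points; beyond that the
  placement enumeration grows combinatorially and the class space
  becomes unwieldy.
* Boundary extrema can be *labelled* (the class space includes them)
  but a constrained fit can only produce them through the unconstrained
  parent.
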