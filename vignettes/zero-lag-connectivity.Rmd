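---
title: "Estimating directed connectivity from zero-lag covariances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating directed connectivity from zero-lag covariances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and why directions are recoverable

zlconn estimates a *directed, signed* coupling matrix between the nodes of
a network (brain regions, neuronal populations) from nothing but the
zero-lag covariance of their recorded activity.  The generative model is
the linear consistency equation

$$x = G x + v,$$

where $x$ is the vector of node activities, $G$ the coupling matrix
(entry $(i,j)$: influence of node $j$ on node $i$; the diagonal is not
modelled), and $v$ independent unit-variance external inputs.  Under this
model the precision matrix of the activity factorizes:

$$C^{-1} = (I - G)^\top (I - G) = I - G - G^\top + G^\top G .$$

Covariances are symmetric, so a symmetric measure cannot by itself orient
an edge.  The product term $G^\top G$ is what breaks the symmetry: its
entry $(i,j)$ is nonzero exactly when nodes $i$ and $j$ send connections
to a *common target* (a collider $i \to k \leftarrow j$).  Flipping the
direction of an edge changes which source pairs share targets, hence
changes $C^{-1}$ — the direction is encoded in the data whenever enough
collider structure is present.  Where none is (an isolated source hub,
say), the two orientations produce identical covariances and no method
can distinguish them; see *Limitations*.

Any factor $B$ with $B^\top B = C^{-1}$ equals $W (I-G)$ for some
orthogonal $W$, so the estimation problem is reduced to choosing a
rotation.  Assuming the true network is sparse, zlconn selects the
rotation whose factor has minimal L1 norm,

$$\Gamma(U) = \| U B_0 \|_1, \qquad B_0 = \text{the symmetric positive
definite square root of } C^{-1},$$

minimized over the orthogonal group (unitary group for complex input).
The minimizer is fixed only up to a signed permutation, which
`canonicalize_factor()` resolves by a linear assignment placing each
row's dominant entry on the diagonal and flipping row signs to make the
diagonal nonnegative — appropriate because the target factor $I - G$ has
unit diagonal.  The estimate is then $\hat G = I - B$ with the diagonal
zeroed.

The norm in $\Gamma$ is the full matrix L1 norm, including the diagonal.
This matters: if the diagonal is excluded, the cost can be lowered by
rotations that push off-diagonal mass onto the diagonal, and the global
minimizer is no longer the sparse truth (we verified this numerically —
with the diagonal-free cost, deeper optimization *degrades* recovery,
while with the full norm a 100-node, 10%-density network is recovered
exactly from its noise-free covariance).  The *output* diagonal is
meaningless either way and is always zeroed.

## The optimizer

`unitary_minimize()` performs gradient descent along geodesics of the
orthogonal group.  One iteration:

1. subgradient $d = S B_0^\top$ with $S$ the entrywise sign (phase) of
   $U B_0$, zero at exact zeros — the minimal-norm subgradient;
2. tangent direction $a = \tfrac12 (d U^\top - U d^\top)$, which is
   skew-symmetric, so $\exp(-\delta a)\,U$ stays orthogonal.  The
   quantity $\|d - U d^\top U\|_F = 2\|a\|_F$ is the Riemannian gradient
   norm used for convergence;
3. step $\delta = 2\pi / (|\lambda_{\max}(a)|\,\kappa)$: the cost along a
   geodesic is close to periodic with period $2\pi/|\lambda_{\max}|$, and
   the step is a fixed fraction $1/\kappa$ of that period
   ($\kappa = 500$);
4. safeguard: a step that would increase the cost is halved up to 20
   times, so the accepted cost sequence never increases.

The stopping rules are a gradient-norm test
($\|d - U d^\top U\|_F < \text{gtol}$) and a stall test
($\|U - U_{old}\|_F / N < \text{xtol}$ together with a relative cost
change below ftol).  With $\kappa = 500$ the progress of a single step is
of the same order as ftol, so the stall test is best understood as an
*oscillation detector*: near a kink of the piecewise-linear cost the
iterates bounce and per-step progress collapses long before the minimum
is reached.  zlconn therefore treats a stall as a signal, not a
terminus: it runs a one-dimensional search along the last descent
direction over a full geodesic period (coarse 50-point grid plus local
refinement) and resumes descent from the polished point, stopping only
when a whole descent-plus-line-search cycle improves the cost by less
than `restart_tol` ($10^{-7}$ relative, far below ftol) or after
`max_cycles` cycles per phase.

Plain subgradient descent on an L1 objective also jams at kinks far from
the optimum.  The engine therefore embeds the descent in a smoothing
continuation: phases minimize
$\sum \sqrt{(UB_0)^2 + \varepsilon^2} - \varepsilon$ with $\varepsilon$
shrunk geometrically from `smooth_eps0` $\times \max|B_0|$ (default 0.3,
shrink 0.25) down to $10^{-6}$, followed by exact phases at
$\varepsilon = 0$ — which are precisely the algorithm described above.
During smoothed phases the landscape is differentiable and a larger step
fraction is safe (`smooth_kappa`, default 50); the tabulated
$\kappa = 500$ governs the exact phases.  For large problems the line
searches are reserved for the exact phases (a smoothed phase's stall
point is a genuine local optimum of its differentiable surrogate, and
the searches dominate runtime); small problems ($n \le 40$) keep the
polish everywhere, and very small ones ($n \le 10$) receive a final
deterministic sweep of exact line searches along the coordinate
(Givens) tangent directions, which escapes the kink points where
full-gradient descent stalls in low dimension.  The accepted cost sequence is
non-increasing *within* each phase; across a phase boundary the exact
cost can tick up slightly because the phases optimize different
surrogates.  The compiled (RcppArmadillo) path handles real input; a
plain-R reference implementation, used as a cross-check in the tests,
also accepts complex Hermitian input and then works in $U(n)$.

Tunable parameters (defaults): xtol $0.7\cdot10^{-2}$, ftol
$0.7\cdot10^{-4}$, gtol $0.7\cdot10^{-2}$, $\kappa$ 500 — the reference
tolerances; `max_iter` 10000, re-orthonormalization (polar projection)
every 100 accepted steps, `restart_tol` $10^{-7}$, `max_cycles` 60,
smoothing schedule as above — the package's own engineering constants,
chosen once on noise-free problems and left alone.

## The surrogate-data generator

`simulate_ou()` produces BOLD-like surrogate recordings with known
ground truth.  Node activity follows a multivariate Ornstein–Uhlenbeck
process $dx = A x\,dt + dW$ with drift $A = (G - I)/\tau$; stability
requires the spectrum of $G$ left of 1.  The stationary covariance
$\Sigma$ solves the Lyapunov equation $A\Sigma + \Sigma A^\top = -I$
(unit-intensity driving noise; the package solves it by a Van Loan block
exponential plus doubling, which also handles the defective drifts that
sparse couplings routinely produce).  Sampling uses the exact
discretization

$$x(t + \Delta t) = e^{A\Delta t} x(t) + n(t), \qquad
n(t) \sim N\!\left(0,\; \Sigma - e^{A\Delta t}\Sigma e^{A^\top\Delta t}\right),$$

whose marginals coincide with the continuous process at every step; the
initial state is drawn from the stationary law, so no burn-in is needed.
Drawing $n(t)$ from the stationary $\Sigma$ itself (a convention that
appears in the literature) inflates the marginal variance; it is kept
behind `noise = "stationary"` for comparison.

The neural series is passed through the canonical double-gamma
hemodynamic response (response gamma: shape 6, unit scale, mode at 5 s;
undershoot gamma: shape 16, weight 1/6; 32 s support; unit peak),
applied as a causal FIR convolution.  Gaussian observation noise with
standard deviation $\sigma_{obs}$ can be added afterwards; the recorded
signal-to-noise ratio is the node-averaged signal variance over
$\sigma_{obs}^2$, computed on the filtered signal before
standardization.  Heavy low-pass filtering is not a nuisance here but an
asset: the zero-lag covariance of the filtered signal approaches the
zero-frequency cross-spectrum, which is exactly the quantity the
factorization models.

Defaults mirror the reference simulation protocol: $N = 100$ nodes,
connection probability $p = 0.1$, $\Delta t = 0.1$ s, $\tau = 0.1$ s,
$T = 350000$ s, spectral radius $\rho = 0.3$, 20 repetitions.  The
literature around this protocol quotes both $\rho = 0.3$ and
$\rho = 0.74$ as defaults; both are exposed (`ou_preset("table")`,
`ou_preset("results")`).  Our reproductions of the published worked
example — estimator metrics near 0.98/0.97/0.95 and raw-correlation
metrics near 0.93/0.54/0.29 — come out at $\rho = 0.3$, so that is what
`scripts/acceptance.R` runs.  A `"ci"` preset shortens $T$ tenfold for
quick runs.  For recordings of millions of samples,
`surrogate_covariance()` streams the simulation, HRF filter, optional
noise and running moments in one compiled pass, returning the sample
correlation without materializing the series; with `sigma_obs = 0` it is
bit-identical to composing `simulate_ou()`, `apply_hrf()`,
`standardize_ts()` and `sample_covariance()` under the same seed (with
noise, the interleaving of random draws differs, the distribution does
not).

What the generator deliberately does not emulate: nonlinear neural-mass
or balloon-model hemodynamics, per-node time constants, scanner-specific
physiological noise, motion, or spatial structure.  Passing the
benchmarks here shows the estimator inverts the linear OU + HRF forward
model at realistic sizes and noise levels — not that real fMRI obeys
that model.

## Numerical and design choices

* **Network sampling.** Edges are independent Bernoulli($p$) per ordered
  pair (the $G(n,p)$ reading of "random network"); signs are i.i.d.
  Bernoulli(`inhibitory_fraction`), with an `exact_half` option.  All
  connections share one magnitude $|J| = \rho / \sqrt{p(1-p)N}$, the
  asymptotic relation between magnitude and bulk spectral radius; an
  `exact_radius` option rescales a realization to hit $\rho$ exactly.
* **Covariance.** Population convention throughout (denominator $M$,
  variances computed around the sample mean); standardization brings
  every node to mean 0, variance 1, so the estimator consumes a
  correlation matrix.  A near-singular covariance (condition number
  above $10^{10}$) is a hard error; an optional ridge exists but is off
  by default because the method is defined for plain inversion.
* **Thresholding.** `threshold_network()` keeps the
  $\lfloor \text{keep\_fraction} \times N^2 \rfloor$ entries of largest
  magnitude over the full $N^2$ grid (the convention that makes a
  90-node estimate at 10% keep exactly 810 connections), signs
  preserved, ties broken by first column-major index.
* **Confusion reports.** Edge called when $|\hat G_{ij}|$ exceeds a
  threshold; default threshold is half the smallest true edge magnitude
  (equal-magnitude ground truths make any value in $(0, |J|)$
  equivalent for a perfect estimate).  Rates follow ROC conventions:
  miss $= FN/(TP+FN)$, false-positive rate $= FP/(FP+TN)$, both over
  off-diagonal cells.  `pearson()` correlates off-diagonal entries;
  note that correlating full matrices (diagonal included) gives a much
  lower value for a correlation matrix scored against a zero-diagonal
  truth — both conventions appear in the literature, and the acceptance
  script reports the full-matrix value where the reference number was
  computed that way.
* **Seeds.** Every stochastic routine takes a seed; benchmark sweeps
  derive per-run seeds deterministically from a master seed, so
  repetitions are reproducible and order-independent.

## Limitations

* **Small networks.** Direction identifiability rests on collider
  coverage, which grows with network size; at $N = 100$, $p = 0.1$
  noise-free recovery is exact, but at $N \approx 20$–30 many edges sit
  in motifs whose orientation the covariance does not constrain, and
  element-wise recovery fails no matter how well the cost is minimized
  (we verified that the truth is then not the unique L1 minimizer).
  Performance rises steeply with $N$ — the benchmark suite asserts the
  trend.
* **Dense networks.** The L1 preference for sparsity shrinks and
  deletes entries of dense ground truths; at $p \approx 0.2$ roughly one
  седьмой of the matrix entries are misclassified at the default
  threshold.  The strongest connections remain reliable (the
  skeleton-plus-background benchmark), which is the regime the method is
  meant for.
* **Model scope.** Interactions are linear and instantaneous with
  independent unit-variance inputs ($Z = I$); violations (shared input,
  strong nonlinearity) masquerade as connectivity.  Frequency-resolved
  estimation (complex cross-spectra) is supported by the optimizer but
  no spectral estimator is provided.

## Problem sizes in the test suite

The unit tests run on 3–50-node problems; the acceptance suite runs the
reference conditions — 20 noise-free realizations at $N = 100$ for the
sparse and dense regimes, one full-length ($T = 350000$ s) surrogate
recording, and reduced-repetition parameter sweeps (2 per value) for the
qualitative trends — sizes chosen to keep a complete run in minutes on
one core while leaving the estimator's operating regime untouched.
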