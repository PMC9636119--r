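---
title: "Stochastic proximal estimation of latent variable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic proximal estimation of latent variable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxlvm)
```

## The estimation problem

Marginal maximum likelihood (MML) estimation of a latent variable model
minimizes
$$-l(\beta) + R(\beta), \qquad
  l(\beta) = \log \int f(y, \xi \mid \beta)\, d\xi,$$
over a feasible set $\mathcal B$, where $\xi$ collects person-level latent
variables, $R$ is an optional penalty, and the integral is intractable
whenever the latent space has more than a few dimensions.  `proxlvm`
implements a quasi-Newton stochastic proximal algorithm for this problem:
writing $R = R_1 + R_2$ with $R_1$ smooth, $h(\beta) = -l(\beta) +
R_1(\beta)$ and $g = R_2 + I_{\mathcal B}$ (the indicator of the feasible
set), each iteration performs

1. **a stochastic step** — draw $\xi^{(t)}$ from the posterior of the
   latent variables at $\beta^{(t-1)}$, exactly when possible (discrete
   latent classes) and by Gibbs sampling with adaptive rejection sampling
   (ARS) otherwise;
2. **a scaled proximal step** —
   $\beta^{(t)} = \mathrm{Prox}^{D^{(t)}}_{\gamma_t, g}\!\big(
     \beta^{(t-1)} - \gamma_t (D^{(t)})^{-1} G^{(t)}\big)$,
   where $G^{(t)} = \partial H(\xi^{(t)}, \beta)/\partial\beta$ is the
   complete-data gradient ($H(\xi,\beta) = -\log f(y,\xi\mid\beta) +
   R_1(\beta)$), $\gamma_t = \mu\, t^{-1/2-\epsilon}$, and $D^{(t)}$ is a
   running, truncated estimate of the diagonal of $\nabla^2 h$.

The estimate is the Polyak–Ruppert average
$\bar\beta_n = \sum_{t=\varpi+1}^{n}\beta^{(t)}/(n-\varpi)$ of the
post-burn-in iterates.  Because the stochastic gradient is conditionally
unbiased (exact sampling) or asymptotically so (MCMC), the averaged iterate
converges at a nearly optimal rate under the slowly decaying step size.

The diagonal curvature estimate combines two exponentially smoothed
statistics,
$$\tilde\delta_{i,1}^{(t)} = (1-\gamma_t)\tilde\delta_{i,1}^{(t-1)} +
  \gamma_t\Big(\tfrac{\partial^2 H}{\partial\beta_i^2} -
  \big(\tfrac{\partial H}{\partial\beta_i}\big)^2\Big), \qquad
  \tilde\delta_{i,2}^{(t)} = (1-\gamma_t)\tilde\delta_{i,2}^{(t-1)} +
  \gamma_t \tfrac{\partial H}{\partial\beta_i},$$
whose combination $\tilde\delta_{i,1} + \tilde\delta_{i,2}^2$ estimates the
marginal curvature $\partial^2 h/\partial\beta_i^2$ through the Louis
missing-information identity
($\nabla^2 l = E[\nabla^2\log f + ss^\top \mid y] - E[s\mid y]E[s\mid
y]^\top$ with $s$ the complete-data score).  The estimate is truncated into
$[c_1, c_2]$ and averaged over iterations before use, which keeps the
scaling matrix positive definite with bounded eigenvalues.

## Model back-ends

**Item factor analysis (IFA).**  Binary responses follow
$P(Y_{ij}=1\mid\xi_i) = \mathrm{logistic}(d_j + a_j^\top\xi_i)$ with
$\xi_i \sim N(0, \Sigma)$, $\Sigma = BB^\top$ reparameterized by its lower
Cholesky factor with unit-norm rows.  Confirmatory fits fix the zero
pattern of the loadings from a design matrix $Q$; exploratory fits leave
all loadings free and add a lasso (or elastic-net) penalty, which breaks
rotational indeterminacy up to column permutation.  The proximal map is
blockwise: identity on intercepts, soft-thresholding on penalized loadings
($\kappa = \lambda\gamma_t/\delta_i$), and a weighted projection of each
Cholesky row onto the unit sphere, solved by the method of Lagrange
multipliers with bisection on the multiplier (tolerance $10^{-12}$ on the
unit-norm residual; the "hard case" of a zero target on every
minimum-weight coordinate places the residual mass deterministically on the
first such coordinate; an all-zero target falls back deterministically to
the first free coordinate with a warning).  The stochastic step performs
one full Gibbs scan per iteration (configurable); each univariate
conditional — log-concave as the product of a Gaussian prior conditional
and logistic likelihood terms — is drawn exactly by Gilks–Wild ARS with a
tangent upper hull and chord squeeze, initialized at the conditional mode
located by safeguarded Newton from a per-coordinate cache; numerical hull
failures fall back to stepping-out slice sampling, which preserves the
target distribution.

**Restricted latent class analysis (RLCA).**  Each person carries a binary
attribute profile $\alpha \in \{0,1\}^K$ with class probabilities
$\propto e^{\nu_\alpha}$ ($\nu_0 = 0$ pinned, so only $2^K - 1$ structural
parameters are free) and item response logits $\theta_{j\alpha}$.  The
design matrix induces the monotonicity constraints: all capable profiles
($\alpha \succeq q_j$) share one value, which dominates every other
profile's value, each of which dominates the all-zero profile's value.
The stochastic step samples profiles exactly from their categorical
posterior; the proximal step solves one quadratic program per item —
projection of the $2^K$ item logits onto the constraint polyhedron under
the diagonal metric — with the equalities encoded as explicit rows and a
primal active-set solver written for the purpose (no QP package is
available in the package's dependency set), warm-started across
iterations.  Because the feasible set is convex, the trajectory average is
feasible whenever the iterates are.

## Algorithm variants

`usp_control(variant = ...)` selects: `USP` (the full algorithm),
`USP-PPG` (forces $c_1 = c_2 = 1$, removing the second-order information —
a perturbed proximal gradient method), `USP-RM1` (no averaging, last
iterate returned), `USP-RM2` (additionally $\gamma_t = 1/t$, the classical
Robbins–Monro step), and `StEM` (replaces the proximal step by full
maximization of the complete-data objective, implemented as iterated
proximal Newton updates with unit step, truncated complete-data curvature,
inner tolerance $10^{-6}$, at most 500 inner iterations, and step halving
on divergence).

## Tuning parameters and the package's defaults

* **Step size** $\gamma_t = \mu t^{-1/2-\epsilon}$ with $\mu = 1$,
  $\epsilon = 0.01$, i.e. $t^{-0.51}$.  The theory requires
  $\sum\gamma_t = \infty$, $\sum\gamma_t^2 < \infty$.
* **Truncation bounds.**  $c_2 = 10^4$.  For $c_1$ the package's default is
  *scale-aware*: one quarter of the median positive complete-data diagonal
  curvature at the first iteration.  A fixed small $c_1$ (say $10^{-2}$)
  is dangerous in practice: early in a run the drift of the parameters
  inflates the subtracted variance term of the Louis estimate, the
  candidate $\tilde\delta$ goes negative, truncates to $c_1$, and the
  averaged diagonal collapses — after which $\gamma_t G/\delta$ steps
  explode (in the restricted-LCA model this manifests as a latent class
  emptying irreversibly while its structural log-odds diverge).  Bounding
  the diagonal below at the problem's own curvature scale removes the
  failure mode without affecting the estimator's limit; an explicitly
  supplied numeric `c1` is always honored.  `usp_control(curv_clamp =
  kappa)` optionally clamps the candidate into $[\kappa h_i, h_i]$ (where
  $h_i$ is the current complete-data curvature, applied only where $h_i >
  0$), exploiting that the marginal curvature always lies in $[0, h_i]$;
  it is off by default since the scale-aware $c_1$ suffices.
* **Burn-in** $\varpi$: 500 of 1000 iterations in the fixed-length
  confirmatory study; 50 for the adaptive-stop studies.
* **Stopping.**  The engines monitor a window (default 3) of successive
  max-norm differences against a threshold (default $10^{-3}$).  For the
  averaging variants the monitored sequence is the *running
  Polyak–Ruppert average* — the quantity actually reported — rather than
  the raw iterates: raw successive differences are of order
  $\gamma_t|G|/\delta$ and would need on the order of $10^6$ iterations to
  fall below $10^{-3}$, while the averaged sequence contracts like $1/t$
  and stops at a few hundred to a few thousand iterations.  This matters
  beyond run time: the unpenalized restricted-LCA likelihood has
  boundary-degenerate maximizers in small samples (a class–item cell with
  no observed successes drives its logit to $-\infty$), so running the
  optimizer to full convergence *degrades* the parameter estimate; the
  windowed stop on the averaged sequence acts as the implicit
  regularization under which the published error levels are reproduced.
  Stopping is only evaluated after the burn-in, so the average is never
  empty; `stop_threshold = 0` disables it (fixed-length runs).
* **Gibbs scans per iteration**: 1.  More scans reduce the MCMC bias of
  the stochastic gradient at proportional cost; with the slowly decaying
  step size a single scan is the standard choice.

## Starting points

Confirmatory fits start at $d = 0$, loadings 1 on the design support,
$B = I$ (the benchmark study starts at the generating truth, as its
purpose is comparing convergence speed toward the quadrature-EM optimum).
Restricted-LCA fits start at $\nu = 0$ and $\theta = +1$ on capable
profiles, $-1$ elsewhere — a feasible interior point.

Exploratory penalized fits are different: the objective is non-convex with
rotated local optima, and a symmetric start (identical loading columns) is
an exact saddle from which the iteration reliably falls into an
orthogonal-factor local optimum (factor correlations near 0 instead of the
generating 0.4, loading error an order of magnitude too large).  The
default is therefore a *spectral start* (`ifa_spectral_start()`): top-$K$
SVD of the centered response matrix scaled to the logit metric, promax
rotation toward a sparse pattern, and the rotation's implied factor
correlation matrix — the field's standard remedy, in line with the usual
advice to start stochastic fits from spectral or joint-likelihood
estimates.

## The synthetic-data generators

`study_design()` encodes the three benchmark designs:

* **I** — confirmatory IFA, $N = 1000$, $J = 20$, $K = 2$, items 1–5 on
  factor 1, 6–10 on factor 2, 11–20 on both; intercepts $N(0,1)$, nonzero
  loadings $U(0.5, 1.5)$, factor correlation 0.4.  The truth is drawn once
  per study; datasets are replicated.
* **II** — exploratory IFA, $J = 80$, $K = 5$, the sparse pattern with 24
  items per factor (50 simple-structure items, 20 two-factor items, 10
  three-factor items; 120 nonzero loadings in total), compound-symmetric
  correlations 0.4, penalty $\lambda_N = \sqrt{\log J / N}$; truth redrawn
  each replication (a fixed-truth mode is exposed).
* **III** — restricted LCA, $J = 20$, $K = 4$, the benchmark design
  matrix, conjunctive (DINA) truth with slipping and guessing
  $U(0.05, 0.2)$, uniform profiles ($\nu \equiv 0$); truth redrawn each
  replication.

The generators emulate clean, correctly specified data: no missingness, no
model misspecification, independent persons.  Passing tests therefore
validate the estimation machinery, not robustness to the complications of
real assessment data.

## Numerical choices

* Logistic quantities use shifted-exponential/`log1p` forms throughout and
  are stable to linear predictors of magnitude several hundred.
* The quadrature reference (`ifa_marginal_loglik()`, `ifa_em()`) adapts a
  tensor Gauss–Hermite grid to the current covariance via $x = \sqrt2 Bz$;
  31 points per dimension reproduce adaptive 1-D integration to $10^{-8}$.
  The EM M-step solves per-item Newton logistic regressions and a
  unit-diagonal covariance update (1-D optimization of the expected
  Gaussian log-likelihood over the correlation for $K = 2$).
* The active-set QP solves its equality-constrained subproblems through
  the diagonal-metric closed form; linearly dependent active sets fall
  back to a pseudoinverse multiplier; a 500-iteration guard is never hit
  in practice.
* `louis_hessian()` estimates posterior expectations by the by-product
  smoothing recursion; at a fixed parameter value its default schedule is
  harmonic ($\gamma_t = 1/t$), making the recursion an exact running mean
  with the plain Monte Carlo rate.  Elements where the complete
  information and the score variance nearly cancel carry absolute (not
  relative) Monte Carlo error.  The complete-data Hessian is analytic for
  the RLCA back-end and obtained by central differences of the analytic
  score for the IFA back-end.
* Reproducibility: all compiled samplers consume R's global RNG stream, so
  a single `set.seed()` (or the `seed` argument of the fit functions)
  makes runs bitwise reproducible; study replication $r$ uses seed
  `seed + 1000 r`.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the restricted-LCA study at
the full 50 replications per sample size; the exploratory-IFA study at 10
replications per sample size (3 at the intermediate size used only for the
monotonicity check); and the five-variant confirmatory comparison at 8
replications.  These sizes were chosen so a complete run fits comfortably
on one CPU; the drivers accept any replication count.

## Known limitations

* The restricted-LCA error levels at $N = 1000$ depend on the early-stop
  behavior discussed above; running far past the stopping point lets
  boundary-degenerate cells drift and inflates the parameter error even
  as the likelihood improves.  This is a property of the unpenalized
  maximum likelihood estimator in small samples, not of the optimizer.
* For the exploratory study, the published loading-error levels are not
  matched by either natural reading of the penalty scale: with the
  printed $\lambda_N = \sqrt{\log J/N}$ applied to the summed
  log-likelihood the converged estimates are *more* accurate than the
  published values (and carry no exact zeros); at the consistency-theory
  scale $\sqrt{N \log J}$ they are sparse (support recovery is nearly
  exact at $N = 4000$) but more shrunken and less accurate.  The package
  defaults to the printed value; the discrepancy is documented rather
  than tuned away.
* Factor sign indeterminacy is not resolved by the L1 penalty; the
  positive-orientation convention of the spectral start and the positive
  generating loadings keep fits in the positive orientation, but data
  with predominantly negative loadings would require flipping signs.
* The scaling matrix is diagonal by construction; no BFGS-style updates.
* No automatic penalty-weight selection: $\lambda$ is treated as fixed.
* The probit-link variant and polytomous responses are out of scope.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
des <- study_design("III", N = 1000, seed = 1)
dat <- generate_rlca_data(des)
fit <- fit_rlca(dat$Y, des$Q, seed = 2)
fit
mse_block(fit$theta, dat$theta)   # item-parameter error vs truth
mse_block(fit$nu[-1], dat$nu[-1]) # structural-parameter error
```
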