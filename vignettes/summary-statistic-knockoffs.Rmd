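---
title: "Controlled variable selection from summary statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled variable selection from summary statistics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large association studies — genome-wide association studies above all —
often release only aggregates of their data: per-variant score statistics
$z_s = X^\top Y$ (or marginal Z-scores), the squared response norm
$\|Y\|_2^2$, the sample size $n$, and sometimes the empirical Gram matrix
$X^\top X$. An analyst who wants to decide *which* variables influence the
response, with a guarantee on the fraction of false selections, cannot run
the usual model-X knockoffs machinery because that requires the
individual-level matrix $X$.

`knocksum` implements a family of procedures that run the knockoff filter
entirely from such summary statistics, controlling the false discovery
rate (FDR) at a user-chosen level $q$ under the model-X assumption
$x_i \sim \mathcal N(0, \Sigma)$ with $\Sigma$ known (in genetics: an LD
matrix from a reference panel) or estimable.

## Gaussian knockoffs from a covariance matrix

The Gaussian knockoff sampler is parameterized by a slack vector $s$ with
$D = \mathrm{diag}(s)$, and
$$P = I - \Sigma^{-1} D, \qquad V = 2D - D\Sigma^{-1}D,$$
so that $\tilde X = XP + EV^{1/2}$ (with i.i.d. standard normal $E$) is a
valid knockoff copy: $[X\ \tilde X]$ has joint covariance
$\begin{pmatrix}\Sigma & \Sigma-D\\ \Sigma-D & \Sigma\end{pmatrix}$.
`solve_s()` offers the two standard constructions:

* **equi** — $s = \min\!\big(\tfrac{M+1}{M}\lambda_{\min}(\Sigma),
  \min_j \Sigma_{jj}\big)\cdot \mathbf 1$, closed form, any dimension;
* **sdp** — maximize $\sum_j s_j$ subject to $0 \le s_j \le \Sigma_{jj}$
  and $\mathrm{diag}(s) \preceq \tfrac{M+1}{M}\Sigma$. The package solves
  this by exact cyclic coordinate ascent: with
  $B = \tfrac{M+1}{M}\Sigma - D_{-j}$, the coordinate-wise maximum is
  $s_j \le 1/(B^{-1})_{jj}$, maintained with Sherman–Morrison updates.
  Because the objective is linear, a fully greedy ascent can park at a
  corner of the feasible set (early coordinates absorbing all joint
  slack); the first sweeps therefore take damped (half) steps, and the
  result is kept only if it dominates the equicorrelated point, which is
  always feasible. The default uses `sdp` for $p \le 500$ and `equi`
  beyond.

The factor $\tfrac{M+1}{M}$ makes the construction valid for $M$
simultaneous knockoff copies; `multi_knockoff_filter()` implements the
generalized filter (winner index $\kappa_j$, gap $\tau_j$ = top score
minus the median of the others, numerator offset and factor $1/M$), which
reduces exactly to the standard filter at $M = 1$. Multi-knockoffs matter
in practice because the single-knockoff filter can only ever reject
$\ge \lceil 1/q\rceil$ hypotheses or none.

## Knockoff scores without knockoff data

The key distributional fact is that, conditional on the data,
$$\tilde X^\top Y \;\overset{d}{=}\; P^\top X^\top Y + \|Y\|_2\, Z,
\qquad Z \sim \mathcal N(0, V)\ \text{independent of the data},$$
so the vector of knockoff scores can be *sampled directly from the
summary statistics* (`sample_ghost_scores()`). With the marginal
difference statistic $W_j = |z_{s,j}| - |\tilde z_{s,j}|$ this gives the
baseline procedure `gk_marginal()`.

## Penalized statistics when the Gram matrix is available

When $X^\top X$ is also released, any statistic that depends on the data
only through the Gram matrix of $[X, \tilde X, Y]$ can be computed from a
*reconstruction*: `reconstruct_pseudo_data()` builds $\check X, \check Y$
with exactly the released Gram matrix (eigen-decomposition rows
$\Lambda^{1/2}Q^\top$, padded with zero rows; any completion with the
right Gram matrix induces the same conditional law of the statistics, so
the padding choice is immaterial). Knockoffs of $\check X$ are sampled
with the same machinery, and three statistics are available:

* `lasso_cd_statistic()` — lasso coefficient difference
  $W_j = |\hat\beta_j| - |\hat\beta_{j+p}|$ at a *fixed* penalty, for the
  objective $\tfrac12\|\check Y - A\beta\|_2^2 + \lambda\|\beta\|_1$
  (no $1/n$ factor; every $\lambda$ in the package is defined against
  this scaling).
* `sqrt_lasso_statistic()` — the square-root lasso
  $\min_\beta \|\check Y - A\beta\|_2 + \lambda\|\beta\|_1$ with the
  pivotal penalty $\lambda = \kappa\,E[\|A^\top\epsilon\|_\infty /
  \|\epsilon\|_2 \mid A]$, $\kappa = 0.3$ by default, the expectation
  estimated from 200 Monte Carlo draws. The penalty depends on the design
  only through its Gram matrix (rotational invariance), which is what
  licenses the summary-statistic version. The solver is the scaled-lasso
  fixed point (alternate a lasso at $\lambda\hat\sigma$ with
  $\hat\sigma = \|\check Y - A\hat\beta\|_2$), with Aitken $\Delta^2$
  extrapolation of the linearly convergent $\hat\sigma$ sequence.
* `lasso_max_statistic()` — per-column entry values
  $\sup\{\lambda: \hat\beta_j(\lambda) \ne 0\}$, contrasted between each
  variable and its knockoff. Entry points are located on a 100-point
  log-spaced grid from $\lambda_{\max} = \|A^\top\check Y\|_\infty$ down
  to $\lambda_{\max}/1000$ and refined by shared-interval bisection to a
  relative tolerance of $10^{-3}$. Refinement is spent where it can
  change the result: pairs whose two entry points fall in the same grid
  cell (where the sign of $W_j$ is still undecided) are refined; all
  other entries are reported at grid resolution (geometric cell
  midpoints), which leaves the selection essentially unchanged at a
  fraction of the cost. Coarser and finer grids are available through
  `n_grid`.

Cross-validation is deliberately absent: without individual rows there is
no way to split the data, which is exactly why the square-root lasso and
entry-value statistics are attractive here.

## Penalized statistics without the Gram matrix: the pseudo-lasso

When only $X^\top Y$, $\|Y\|_2^2$ and $n$ are available, the package
replaces the empirical Gram blocks with their population counterparts:
$$\hat\beta(\lambda) = \arg\min_\beta\ \tfrac12\beta^\top C\beta -
d^\top\beta + \lambda\|\beta\|_1, \qquad
C = \begin{pmatrix}\Sigma & \Sigma-D\\ \Sigma-D & \Sigma\end{pmatrix}
+ c\,I, \quad d = \tfrac1n \begin{pmatrix} z_s\\ \tilde z_s
\end{pmatrix},$$
with a small ridge $c$ (default $10^{-4}\cdot\overline{\Sigma_{jj}}$) for
numerical stability. $C$ is *swap-invariant*: permuting original/knockoff
entries of $d$ permutes $\hat\beta$ identically, which yields the
flip-sign property of $W_j = |\hat\beta_j| - |\hat\beta_{j+p}|$ and hence
FDR control for any fixed or symmetric data-driven $\lambda$, for any
ridge $c$. At $\Sigma = D = I$, $c = 0$ the program separates and
$\hat\beta$ is the coordinatewise soft-threshold of $d$ — the procedure
then soft-thresholds the marginal correlations, a useful exact test case.

Two penalty rules are provided:

* **lasso-min** (`lambda_lasso_min()`):
  $\lambda = \kappa \cdot \tfrac{\hat\sigma_0}{n} \cdot
  E\|R^\top\epsilon\|_\infty$ with $\kappa = 0.6$, where $R$ has i.i.d.
  $\mathcal N(0, C_0)$ rows and the expectation — a numerical constant of
  $(C_0, n)$ — is estimated from 200 Monte Carlo draws using
  $R^\top\epsilon \overset{d}{=} \|\epsilon\|_2 \cdot \mathcal N(0,C_0)$.
  The noise scale $\hat\sigma_0$ is the moment-based summary-statistic
  estimator
  $\hat\sigma_0^2 = \max\big(\tfrac{k+n+1}{n(n+1)}\|Y\|^2 -
  \tfrac{1}{n(n+1)} w^\top C^{-1} w,\ 0\big)$, $w = [z_s;\tilde z_s]$,
  $k = 2p$: it targets $\sigma^2$, so the square root of the clipped
  value is returned. The ridge-stabilized $C$ is inverted, which
  guarantees existence; the difference from the un-ridged matrix is
  $O(c)$.
* **pseudo-sum** (`lambda_pseudo_sum()`): split the statistics into
  independent pseudo-training and pseudo-validation parts with
  $n_t = 0.8n$, $n_v = 0.2n$:
  $r_t = r + \sqrt{n_v/(n\,n_t)}\;\sqrt{\|Y\|^2/n}\; R$,
  $R \sim \mathcal N(0, C_0)$, and
  $r_v = (n r - n_t r_t)/n_v$. The factor $\sqrt{\|Y\|^2/n}$ carries the
  response scale (unity for a standardized response): it is exactly what
  makes $\mathrm{Var}(r_t) = \mathrm{Var}(r)\cdot n/n_t$, i.e. the
  training statistics look like statistics computed from $n_t$ samples.
  Without it the training and validation parts nearly coincide whenever
  $\mathrm{Var}(Y) \ne 1$ and the grid search degenerates to the
  smallest penalty. The penalty maximizes
  $f(\lambda) = \hat\beta_{t,\lambda}^\top r_v \big/
  \sqrt{\hat\beta_{t,\lambda}^\top C_0 \hat\beta_{t,\lambda}}$ over a
  100-point grid, log-linear from $\lambda_{\max} = \|d\|_\infty$ to
  $\lambda_{\max}/1000$; $f = -\infty$ for a null fit, so the empty model
  is never chosen when any candidate fits something.

`gk_pseudolasso()` composes the whole pipeline; with `M > 1` the block
matrix grows to $(M+1)p$ and the multi-knockoff filter is applied.

## The selection filter

`knockoff_threshold()` implements
$$T = \min\Big\{t \in \mathcal W:
\frac{\text{offset} + \#\{j: W_j \le -t\}}{\#\{j: W_j \ge t\} \vee 1}
\le q\Big\},$$
with $\mathcal W$ the distinct nonzero $|W_j|$ (zeros never enter the
candidate set), offset 1 by default (knockoff+, exact FDR control),
$T = +\infty$ and an empty selection when no candidate qualifies.

## The synthetic-data generator

`sim_scenario()` / `run_replications()` emulate three designs:

* **independent** — $x_i \sim \mathcal N(0, I_p)$;
* **ar1** — $x_i \sim \mathcal N(0, \Sigma_\rho)$,
  $\Sigma_\rho[s,t] = \rho^{|s-t|}$, with $\rho$ swept over
  $\{0, 0.1, \ldots, 0.8\}$ in the canonical experiments;
* **genotype** — standardized Binomial(2, maf) allele counts with maf
  uniform on `maf_range`, a discrete, non-Gaussian stress test of the
  Gaussian-knockoff assumption. With `sigma_source = "reference"` the
  methods receive a shrinkage correlation estimate from an independent
  panel of the same size rather than the truth, emulating the
  reference-panel workflow.

Responses are $Y = X\beta + \sqrt{n}\,\epsilon$ with `k_nonzero = 30`
coefficients of size `amplitude` and equiprobable signs; the
$\sqrt n$ noise scale makes `amplitude` read as an expected marginal
Z-score, so the canonical amplitudes (4, 4 and 7 for
$(n,p) \in \{(600,200), (400,400), (200,600)\}$) sit in the informative
power range. For the independent-feature experiments, where the
amplitude is a free choice, the package uses $A = 4$ — the same value the
AR(1) design pins at $\rho = 0$, which is the identical design. A
mixed-effect logit response is also available
($\mathrm{logit}(\mu_i) = \beta_0 + x_i^\top\beta + \epsilon^B_i$,
intercept $\beta_0 = \mathrm{logit}(\text{prevalence})$, default
prevalence 10%). The latent noise standard deviation defaults to 1 and is
exposed as `logit_latent_sd`; note that with nonzero latent noise the
realized prevalence sits somewhat above the intercept target (about
13.6% at unit noise), since averaging the logistic function over noise
inflates small probabilities. Genotype-scale effect sizes
$\beta_j = 1/(20\sqrt{m_j(1-m_j)})$ on allele counts (a constant
$\sqrt 2/20$ on standardized columns) are available behind
`logit_maf_effects`.

`run_replications()` measures, per replication,
$\mathrm{FDP} = |S \cap H_0| / \max(|S|, 1)$ (the $0/0 = 0$ convention)
and power $|S \cap H_0^c| / k$, aggregates with Monte Carlo standard
errors, derives per-replication seeds from one master seed, and logs and
excludes per-replication failures with a reported count.
`kf_lassocv_reference()` is the individual-level benchmark (knockoffs
with cross-validated lasso via `glmnet`), the upper reference curve the
summary-statistic methods are compared against.

What the generator does *not* emulate: linkage-disequilibrium blocks of
real genomes, case-control ascertainment, population structure, or
meta-analytic heterogeneity across studies. Passing tests demonstrate
correctness of the procedures under their stated assumptions and
robustness to the discreteness and estimated-covariance perturbations the
generator does model — not performance on any particular real cohort.

## Numerical choices

* **Coordinate descent** (compiled): cyclic over coordinates with
  active-set inner cycling; convergence only when a *full* sweep moves
  every coordinate by less than the tolerance. The pseudo-lasso solves to
  an absolute coefficient tolerance of $10^{-8}$ (at most $10^4$ sweeps;
  non-convergence is an error, not a silent result).
* **Scale-aware tolerances**: for the data-Gram statistics the
  characteristic coefficient magnitude is
  $\|A^\top Y\|_\infty / \overline{\mathrm{diag}(G)}$; the square-root
  lasso inner solves use $10^{-5}$ of it, the entry-value path $10^{-4}$
  (entry *detection* needs supports, not digits — the filter only sees
  entry values at $10^{-3}$ relative precision anyway). Oracle-agreement
  tests run the same solver at $10^{-12}$.
* **PSD repair**: covariance-derived matrices are repaired by the
  smallest jitter $c\,I$ from an escalating ladder making the minimum
  eigenvalue $\ge -10^{-10}$; the jitter used is recorded on the
  `knockoff_params` object. Matrix square roots clip small negative
  eigenvalues at zero.
* **Ties in the filter**: candidate thresholds are the distinct nonzero
  $|W_j|$; $W_j = 0$ is never selectable.
* **Degenerate inputs**: $\|Y\|^2 = 0$ propagates to zero statistics
  everywhere; $\lambda \ge \|d\|_\infty$ returns the zero solution by
  KKT; a Gram matrix of rank larger than $n$ is rejected with an
  explicit error.
* **Statistic convention**: $W_j = |\hat\beta_j| - |\hat\beta_{j+p}|$ by
  default; the barless variant $\hat\beta_j - \hat\beta_{j+p}$ (equally
  flip-sign valid) is available via `barless = TRUE`.

## Problem sizes used by the shipped experiments

The package's replication experiments (test suite and
`scripts/acceptance.R`) run the canonical designs at 100 replications,
with the AR(1) sweep evaluated at the three-point subset
$(\rho, n, p, A) \in \{(0, 600, 200, 4), (0.4, 400, 400, 4),
(0.8, 200, 600, 7)\}$ — one point per $(n, p)$ setting at its canonical
amplitude, spanning the full $\rho$ range. These sizes give Monte Carlo
standard errors of roughly 0.01–0.02 on FDR and power, small enough to
resolve FDR control at $q = 0.2$ and the power orderings among methods.

## Known limitations

* The Gaussian model-X assumption is load-bearing: FDR control for
  discrete or misspecified covariates is an empirical robustness
  property (exercised by the genotype design), not a theorem.
* The SDP slack solver is a coordinate scheme, not an interior-point SDP
  solver; it is exact per coordinate but can terminate at a good feasible
  point rather than the global optimum on hard instances (it never
  returns less than the equicorrelated construction).
* Group knockoffs and Bayesian (posterior-inclusion-probability)
  statistics are out of scope; externally computed flip-sign statistics
  can be fed to `knockoff_threshold()` directly.
* Meta-analytic aggregation of multiple studies' Z-scores must happen
  upstream; `zscores_to_summary()` documents the standardized-variable
  approximation it applies.
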