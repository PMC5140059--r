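---
title: "Structure learning of stochastic reaction networks from snapshot time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure learning of stochastic reaction networks from snapshot time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactionet)
```

## The model

A stochastic mass-action reaction network over $N$ species with copy
numbers $X_1,\dots,X_N$ and $L$ reactions evolves according to the Chemical
Master Equation. Each reaction $l$ has a stoichiometry vector $s_l$ and
propensity $a_l(x) = k_l\,g_l(x)$, where $g_l$ is the mass-action
combinatorial factor: $x_a$ for a unary reactant, $x_a x_b$ for two distinct
reactants, and $x_a(x_a-1)$ for a homodimerisation (this package absorbs the
conventional $1/2$ symmetry factor into $k_l$, which fixes one of the two
equivalent conventions so that rate recovery is well defined).

Taking expectations of the CME yields a closed-form ODE system for the
central moments $M_r$ of the copy-number distribution,

$$ \dot M_r \;=\; \sum_l k_l\, F_{rl}(M), $$

where each *stoichiometric moment function* $F_{rl}$ is a polynomial in
means, variances, covariances and (for bimolecular propensities) third
central moments:

* means: $F_{\mu_i,l} = s_{li}\,\mathrm{E}[g_l]$;
* second central moments:
  $F_{C_{ij},l} = s_{li}\,\mathrm{Cov}(X_j, g_l) + s_{lj}\,\mathrm{Cov}(X_i, g_l)
  + s_{li}s_{lj}\,\mathrm{E}[g_l]$,

with all expectations expanded about the mean (e.g.
$\mathrm{E}[X_aX_b] = \mu_a\mu_b + C_{ab}$). The package derives these
polynomials symbolically for any network or candidate library
(`derive_moment_equations()`) and compiles them into a sparse evaluator so
that a full design block is one sparse matrix–vector product.

Because single-cell snapshots destroy cell identity, the data are samples
from the time-marginal distributions — not trajectories. *Gradient matching*
estimates $\dot M_r(t_j)$ directly from interpolated empirical moments, so
rate inference becomes a linear regression: response $b$ stacks the gradient
estimates (moment block–major, then time), and the design matrix $A$ holds
the $F_{rl}$ evaluated at the empirical moments. Third moments appear only
as design inputs, never as regression targets, which is why no moment
closure is needed.

## The two-step sparse regression

The candidate library enumerates every conversion $A \to B$ (one per
unordered pair, canonical direction low index $\to$ high index), split
$A \to B + C$ and association $A + B \to C$ over distinct species — 2275
candidates for 14 species, i.e. more than $10^{600}$ possible topologies.
Two features make naive least squares unusable: both $b$ and $A$ are noisy
(the residual depends on $k$ itself), and rate constants span orders of
magnitude.

**Step 1 — feasible generalized least squares (FGLS).** Bootstrap
resampling of cells within each snapshot (B replicates through the entire
estimator pipeline) yields standard deviations for every entry of $b$ and
$A$. A preliminary nonnegative least squares (NNLS) fit on the mean rows
gives order-of-magnitude estimates $k^{LS}$; the row-wise residual variance
is modeled as $\sigma^2_j = \sigma^2_{b,j} + \sum_l (k^{LS}_l)^2
\sigma^2_{A,jl}$ (independent residual components); rows are whitened by
$\sigma_j^{-1}$ and NNLS on the whitened system gives $k^{FG}$. The support
$\Phi$ keeps coefficients above $10^{-6}$ relative to the largest. Adaptive
penalty weights $\tilde k$ are the magnitudes of the Moore–Penrose
pseudoinverse solution restricted to $\Phi$, floored at $10^{-12}$ (the NNLS
magnitudes are available as an alternative via `weight_source = "fg"`; the
`kls_rows = "all"` switch likewise exposes fitting $k^{LS}$ on all rows).

**Step 2 — adaptive relaxed lasso.** For each $\lambda$ on a decreasing
grid (50 log-spaced values from the analytic all-zero bound
$\lambda_{\max} = 2\max_i \tilde k_i (A^\top b)_i^+$ down to
$\lambda_{\max}10^{-6}$), the nonnegative weighted-$\ell_1$ problem

$$ \hat k = \arg\min_{k \ge 0} \lVert b_S - A_{S,\Phi}k \rVert_2^2
   + \lambda \sum_i k_i/\tilde k_i $$

is solved by ADMM (under $k \ge 0$ the penalty is linear). Shrinkage bias is
removed by a relaxed NNLS refit on each active set. Five-fold
cross-validation — rows split uniformly at random, stratified by moment
block — records held-out error and per-fold selections. Model choice uses
BIC $= n\ln(\mathrm{RSS}/n) + s\ln n$ on the full-data relaxed refit, with
$s$ the number of nonzero coefficients; for libraries above 1000 candidates
the sparsest model within 1% of the total BIC drop is used instead of the
argmin (the "large initial improvement" elbow). The stability filter then
keeps reactions whose *peak* selection frequency across folds along the path
reaches $\pi = 0.8$: the peak (the Meinshausen–Bühlmann stability-selection
statistic) rather than the frequency at exactly $\lambda^*$, because at the
grid point where a reaction first enters the full-data path the fold fits
lag by one grid step and the pointwise frequency is spuriously zero.
Backward stepwise refinement finally drops, one at a time, the reaction
whose removal least increases RSS, as long as BIC does not increase.

Prior knowledge is a membership constraint: known reactions are never
penalized, never dropped, and held strictly positive ($k \ge 10^{-12}$) in
every regression step. Replicate experiments are handled by row-wise
concatenation of their systems (`concat_replicates()`).

## Measurement noise

Single-cell instruments detect each molecule with capture efficiency $p$,
modeled as binomial thinning $X^{obs} \sim \mathrm{Bi}(X, p)$ with $p$
assumed known. The package inverts the thinning on moment estimates of
orders 1–3 through the falling-factorial identity
$\mathrm{E}[(X^{obs})_{(r)}] = p^{|r|}\,\mathrm{E}[(X)_{(r)}]$, applied
coordinate-wise; at orders 1–2 this reduces to the familiar
$\mathrm{E}[X] = \mathrm{E}[X^{obs}]/p$,
$\mathrm{Var}[X] = (\mathrm{Var}[X^{obs}] - p(1-p)\mathrm{E}[X])/p^2$ and
$\mathrm{cov} = \mathrm{cov}^{obs}/p^2$. The inversion is exact for the
thinning model (unit-tested against exact enumeration of the binomial
mixture); corrected variances that come out negative under sampling noise
are clipped to zero with a warning.

## Gradient estimators

* `spline` — derivative of the natural cubic interpolating spline through
  the per-time moment estimates (the recommended estimator);
* `fds` — nonuniform-grid finite differences, three-point central formulas
  at interior points and one-sided at the ends;
* `smooth` — sliding-window (default 5-point moving average) finite
  differences of densely sampled ensemble moments. This needs the dense
  per-cell trajectories and is therefore an oracle available in simulation
  only; the window is configurable because no canonical width exists.

On smooth curves the spline derivative is accurate to well under 2% at
interior points of a 13-point grid, while finite differences carry an
$O(h^2)$ bias that is consistently larger on the same fixture.

## The synthetic-data generator

`ssa_simulate()` draws independent exact Gillespie (direct method)
realizations per cell and samples them on the requested grid; snapshots at
different times come from the same ensemble but the estimators never use
cell identity, honoring the snapshot data model. Each cell owns an RNG
stream keyed by (seed, cell index), so enlarging the ensemble leaves
earlier cells unchanged and runs are bit-reproducible. Initial conditions
are deterministic by default; a Poisson-dispersed sampler is available for
robustness studies. The generator emulates intrinsic stochastic-kinetics
variability and binomial capture noise; it does not emulate extrinsic
cell-to-cell parameter variability, cell division, or instrument
background, so passing benchmarks here speaks to the estimator under the
assumed noise model, not to every artifact of real cytometry or sequencing
data.

### The enzymatic benchmark fixture

The built-in fixture is the classical enzyme–substrate system
$E + S \to ES$, $ES \to E + S$, $ES \to E + P$ with defaults
$k = (0.002, 0.1, 0.3)$ and $x_0 = (E, S, ES, P) = (100, 200, 0, 0)$.
Benchmarks measure 13 uniform time points on $[5, 30]$: by $t = 30$ about
95% of substrate is converted, and the window starts roughly five
complex-equilibration times after induction. The window choice matters:
with a deterministic $x_0$, a snapshot at $t = 0$ has zero variance, and
the fast initial $ES$ equilibration (relaxation time $\approx 1$) cannot be
resolved by a uniform 13-point grid — the resulting early gradient rows are
strongly biased yet heavily weighted after whitening. Worse, along the
quasi-steady state the association and dissociation design columns are
nearly collinear in the mean rows ($\mathrm{E}[X_EX_S]/\mathrm{E}[X_{ES}]
\approx K_m$ is constant), so the dissociation rate is identified mostly by
the second-moment rows, which need accurate gradients. Starting the
measurement window after the transient restores identifiability; this is an
experimental-design observation a practitioner would apply to real
measurements as well (measure after fast binding equilibria have settled,
or resolve them with extra early time points).

## Numerical choices

* ADMM: the quadratic is preconditioned by scaling $A$, $b$ (and $\lambda$
  alike) so the penalty parameter $\rho = 1$ matches the problem scale —
  the argmin is unchanged; $\rho$ adapts by factors of 2 when the
  primal/dual residual ratio exceeds 10; absolute tolerance $10^{-8}$,
  relative $10^{-6}$, at most $10^4$ iterations. Non-converged fits are
  flagged and retained.
* NNLS uses Lawson–Hanson (`pracma::lsqnonneg`) with a projected
  coordinate-descent fallback for near-degenerate systems that exceed its
  internal iteration cap.
* Rows with a zero residual-variance estimate are floored at the smallest
  positive estimate (with a warning) before whitening.
* RSS below the relative machine precision of the response
  ($(10^{-12}\lVert b\rVert)^2$) is treated as an exact fit when computing
  information criteria, so models that both fit to rounding error are
  compared by their parameter counts.
* Unbiased moment estimators throughout: divisor $C-1$ at order 2 and the
  $h$-statistic factor $C^2/((C-1)(C-2))$ at order 3, so small ensembles do
  not bias the design matrix.
* One master seed expands into deterministic per-stage streams
  (simulation, noise, bootstrap, cross-validation), making any run exactly
  reproducible from its metadata file.

## Problem sizes used by the test suite

The packaged benchmarks run the full pipeline on the enzymatic fixture with
its 30-candidate library at $10^2$–$10^4$ cells per snapshot, 13 time
points, bootstrap $B = 60$ for the recovery benchmarks ($B = 200$ is the
package default and is used for the noise-correction checks), 50-value
$\lambda$ grids and 5 seeds. Moment-equation oracles are validated against
finite differences of SSA ensemble moments at $10^4$ cells, and the
selection procedure against exhaustive best-BIC enumeration on 6-candidate
systems. These sizes are scaled-down analogues of snapshot experiments with
$10^5$ cells and libraries of thousands of candidates; the procedure is the
same, only the ensemble and library sizes differ.

## Limitations

* Mass-action kinetics only; Hill/Michaelis–Menten propensities and moment
  closure are out of scope (gradient matching avoids the need for closure).
* Candidates cover unary/binary conversions, splits and associations;
  synthesis and degradation reactions can be part of explicit network
  specifications but are not enumerated as candidates.
* All relevant species are assumed measured; latent species are not
  modeled.
* The capture efficiency $p$ must be known; it is not estimated.
* The recovered model is a single point estimate; alternative
  near-equivalent topologies are only visible through the reported
  stability frequencies and regularization path, not through posterior
  samples.
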