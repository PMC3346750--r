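---
title: "Sparse two-layer Gaussian models of transcriptional regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse two-layer Gaussian models of transcriptional regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsegrn)
```

## The model

sparsegrn infers a bipartite transcriptional regulatory network from
expression data alone. The observed variables are split into two disjoint
layers: a set of d known or putative transcription factors (TFs) with
expression vector $r$, and the remaining p genes with expression vector
$x$. Because unknown regulators and confounders (expression heterogeneity,
batch structure) also shape expression, the upper layer additionally
contains q hidden factors $z$ with a standard-normal prior. Each gene is a
linear function of the whole upper layer:

$$x = W r + \Lambda z + \mu + \varepsilon,
  \qquad z \sim N(0, I_q),
  \qquad \varepsilon \sim N(0, \sigma^2 I_p).$$

$W$ (p × d) carries the TF regulatory weights — positive entries read as
activation, negative as repression — and $\Lambda$ (p × q) the
hidden-factor loadings. The construction is linear regression fused with
probabilistic PCA: setting q = 0 leaves a pure regression model, d = 0 a
pure PPCA model, and both limits are exercised by the test suite. Genes
are conditionally independent given the upper layer, and the TF/gene sets
are disjoint, so the graph is acyclic by construction.

Integrating $z$ out, $x \mid r \sim N(W r + \mu,\; C)$ with
$C = \Lambda \Lambda^\top + \sigma^2 I_p$. The negative log-likelihood over
N samples is minimized with an L1 penalty on the weight blocks:

$$\mathcal{L}(\theta) = \sum_{n=1}^{N} -\log N(x_n \mid W r_n + \mu, C)
  \; + \; \lambda \Big( \textstyle\sum_{ij} |W_{ij}| +
  \sum_{ik} |\Lambda_{ik}| \Big).$$

Most genes are regulated by few TFs, so the true weight matrices are
sparse; the L1 penalty drives irrelevant weights to exactly zero, and the
surviving nonzeros *are* the inferred network edges. The intercept $\mu$
and noise variance $\sigma^2$ are not penalized — sparsity has no
biological reading for them.

### Likelihood computation

$C$ is p × p, but only q-rank structured. All likelihood and gradient code
goes through the Woodbury factorization: with
$M = \sigma^2 I_q + \Lambda^\top \Lambda$,

$$C^{-1} = \sigma^{-2}\left(I_p - \Lambda M^{-1} \Lambda^\top\right),
  \qquad
  \log |C| = (p - q) \log \sigma^2 + \log |M|,$$

so each objective/gradient evaluation costs O(N p (d + q)) and no p × p
matrix is ever formed. `woodbury_terms()` exposes the factorization, and a
dense-covariance oracle in the tests confirms agreement to 1e-8 up to
p = 50. Gradients of all four parameter blocks are analytic (derived from
the Gaussian marginal) and checked against central finite differences to a
relative error of 1e-5.

The noise is optimized as $\nu = \log \sigma^2$, which keeps the domain
unconstrained — a requirement of the optimizer below — and guarantees
positivity without projection.

## Optimization: OWL-QN

The objective is smooth plus an L1 term, the setting of the orthant-wise
limited-memory quasi-Newton (OWL-QN) family. `owlqn_minimize()` is a
from-scratch implementation:

* a **pseudo-gradient** collapses the L1 subdifferential to the steepest
  descent direction (`pseudo_gradient()`);
* an L-BFGS two-loop recursion (memory 10 by default) builds the search
  direction from the pseudo-gradient, then the direction is sign-aligned
  with it coordinate-wise;
* a backtracking line search (Armijo constant 1e-4, halving steps)
  measures sufficient decrease against the pseudo-gradient directional
  derivative and **projects each trial point onto the current orthant**:
  any penalized coordinate that would cross zero is clamped to exactly
  zero. Zeros in the solution are therefore exact, and gene-set membership
  downstream is a `!= 0` test, never a threshold.

Convergence is declared when the pseudo-gradient infinity norm falls below
`tol` (default 1e-7) or the relative objective decrease stays below `tol`
for 5 consecutive iterations. Non-finite trial values (overflowing
$e^\nu$ during long steps) are treated as rejected steps.

### Restarts and the penalty path

The penalized likelihood is not convex. `grn_fit()` restarts the optimizer
`n_restarts = 10` times from independent random initializations (W = 0,
$\Lambda_{ik} \sim N(0, 0.01)$, intercept at the gene means, noise at the
pooled variance) and keeps the best objective, reporting the spread across
restarts as a stability diagnostic. Each restart is solved **pathwise** by
default: the penalty is increased over the sequence λ/27, λ/9, λ/3, λ with
warm starts. At small penalties the optimum is essentially unique, so
continuation steers every restart into the same basin; without it,
one-shot fits at a large penalty occasionally collapse a hidden factor to
zero. With a single hidden factor the restart spread is at numerical
precision; with several factors, near-tied sparse optima (differing in a
few support entries, objectives within ~1%) can persist — the reported
spread makes this visible, and it is the reason the multi-restart design
exists.

Fitting is done on column-centered data (the intercept is translated back
afterwards); an optional flag also scales columns to unit variance, in
which case the model describes the standardized data and the training
transform is stored with the fit.

## Choosing the penalty and the number of hidden factors

Two different questions call for two different criteria.

**Prediction / model comparison.** `cross_validate()` implements the
evaluation protocol: 10 outer folds, and within the first outer fold's
training data a 2-fold cross-validation over the (λ, q) grids that
maximizes mean held-out log-likelihood; the selected values are reused for
the remaining folds (a `retune_per_fold` flag repeats the search
everywhere). The default penalty grid has 8 logarithmic points between
λ_max/100 and λ_max, where λ_max is the smallest penalty at which the
zero-weight solution satisfies the subgradient condition on the training
data. Three models are compared on each held-out fold by total
out-of-sample log-likelihood: the full model, the no-hidden-factor model
(q = 0), and an independent-genes reference model (per-gene Gaussian MLEs,
variances floored at 1e-8 of the pooled variance to survive constant
genes). Paired differences over folds are tested with an exact Wilcoxon
signed-rank test (`wilcoxon_signed_rank()` enumerates all sign assignments
for up to 15 pairs; beyond that a tie-corrected normal approximation is
used).

**Support recovery.** The predictively optimal penalty is the wrong tool
for recovering the network: when samples outnumber TFs, held-out
likelihood barely notices tiny spurious coefficients, so the
likelihood-optimal penalty retains many near-zero false edges. This is the
classic overselection of prediction-tuned lasso. `select_penalty_ebic()`
therefore scores each grid penalty by the extended BIC (γ = 0.5) of the
model *refitted without shrinkage* on the recovered support
(`refit_support()`), the standard sparsity-consistent criterion for
graphical-model selection; the extended term accounts for the size of the
p(d + q) candidate-edge space. On planted-network simulations (p = 100,
d = 10, q = 3, N = 500, 5% W density, noise σ = 0.5) this recovers the W
support with F1 ≥ 0.9 and the Λ columns up to sign/permutation with
correlation ≥ 0.9 — both asserted in the test suite. The q grid is still
selected by held-out likelihood, which does not overselect the factor
count in the same way.

## Gene sets and enrichment

Each hidden factor defines a gene set (the nonzero entries of its Λ
column), as does each TF (nonzero W column): `extract_gene_sets()`. For a
category collection (GMT format, e.g. GO Biological Process from a GSEA
distribution), `min_category_p()` finds the category minimizing the
one-sided Fisher exact (hypergeometric tail) p-value; ties break
lexicographically. Scanning many categories biases that minimum, so
`calibrate_p()` repeats the identical scan on B = 1000 uniformly random
gene sets of the same size and reports the fraction of null minima at or
below the observed one. The default estimator is r/B, which can be exactly
0 when the observed set beats every null draw — matching the convention of
reporting hard zeros for overwhelming enrichment — and a conservative
(r+1)/(B+1) variant is a flag. Benjamini–Hochberg q-values are computed
over the calibrated p-values.

Design choices here: the universe defaults to the genes present in both
the model and the collection; categories with fewer than 5 or more than
5000 members in the universe are skipped (gene-set-analysis convention);
and each gene set's randomization runs on an independent substream derived
from the seed and the set's index, so results are reproducible regardless
of evaluation order. Under a null simulation (random gene sets, random
categories) the calibrated p-values are uniform to within sampling error;
planted categories receive calibrated p = 0 and survive FDR control —
both asserted in the acceptance tests.

## The NCA baseline

Network component analysis decomposes a genes × samples matrix as
E = A·P with a *fixed* connectivity zero pattern in A — it infers
regulator activities for a known topology, whereas the sparse model infers
the topology itself. The baseline (`nca_decompose()`) uses alternating
least squares on the fixed support: full least squares for P, per-row
masked least squares for A, until the relative reconstruction-error change
drops below tolerance; masked entries are never touched, and columns of A
are unit-normalized afterwards (scaling is the decomposition's intrinsic
ambiguity). ALS is a simplification of the original two-stage NCA
optimization, but solves the same fixed-support objective.

`make_random_connectivity()` builds the random input topology with exactly
L−1 zeros per column, the minimum demanded by the identifiability
criteria, which `check_nca_criteria()` diagnoses (full column rank,
full rank after removing any regulator with its targets, N ≥ L). A
practical observation from the test suite: with only the minimal L−1 zeros
the decomposition is weakly pinned and ALS converges very slowly; the
planted-recovery tests therefore use sparser (still criteria-satisfying)
masks, where ALS reaches the global optimum (per-column cosine ≥ 0.999) in
a few hundred sweeps. `prune_edges()` trims the learned A to a target edge
budget by absolute weight (row-then-column tie-break) so NCA networks can
be compared with the sparse model's at equal edge counts.

## Synthetic data

`simulate_grn_data()` draws from the model's own generative process: R and
Z i.i.d. standard normal (the upper layer is mutually independent), W and
Λ with uniformly placed nonzero positions of fixed magnitude
± `effect_scale` (so "support recovery" is unambiguous), Gaussian
isotropic noise, and a N(0,1) intercept. Defaults — 5% W density, 20% Λ
density, effect 1, σ = 0.5 — reflect a sparse TF layer and moderately
dense confounders at a signal-to-noise ratio typical of log-scale
expression data. The model-comparison simulations use a denser W (20%)
so the TF layer contributes to most genes' expression, as in a
liver-cohort-scale dataset; the recovery simulations use the sparse
defaults.

What the generator deliberately does not emulate: probe-level microarray
noise, batch effects, heavy-tailed expression, gene-gene regulation, or a
realistic GO DAG (planted categories are 80% subsamples of true supports
plus uniform noise sets). Passing tests therefore certify the inference
machinery under the model's own assumptions — identifiability, optimizer
correctness, calibration — not robustness to real-data violations of
those assumptions.

## Problem sizes and numerical choices

The test and acceptance experiments run at desk scale, chosen so each
stage finishes in seconds to a few minutes on one core: gradient checks at
p ≤ 12, Woodbury checks at p ≤ 50, model comparison at p = 50, d = 5,
N = 400 with 10 folds, recovery at p = 100, d = 10, q = 3, N = 500,
enrichment calibration with 100 null sets at B = 1000, NCA at p = 50,
L = 5. Other numerical choices: optimizer tolerance 1e-7 (1e-9 to 1e-12
where closed-form agreement is asserted), L-BFGS memory 10, Armijo
constant 1e-4, curvature pairs kept only when sᵀy > 1e-10‖y‖², ridge
jitter 1e-10 on singular NCA subsystems, reference-model variance floor
1e-8 × pooled variance, missing-value tokens `NA`/empty cell, and one
global seed expanded into named substreams (restarts, folds, enrichment
draws) so every component is independently reproducible.

## Limitations

The noise is isotropic — a single σ² for all genes (factor analysis with
per-gene variances is out of scope), which also explains why the
independent-genes reference model, which *does* have per-gene variances,
can be competitive when the upper layer explains little. The likelihood
is Gaussian on (log-)expression; counts should be transformed first. The
graph is bipartite and acyclic by construction: TF–TF regulation and
feedback loops are not representable. L1 breaks rotational invariance of
Λ but not sign/permutation, so loadings are comparable across runs only
up to column sign and order. And with several hidden factors the penalized
likelihood has near-tied local optima; the restart spread should be
checked before interpreting an individual fit.
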