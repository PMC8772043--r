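---
title: "Network rewiring and module biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network rewiring and module biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrn)
```

# The problem

Disease mutations do not only shift the expression of individual genes; they
rewire the regulatory relationships *between* genes. Two samples groups —
say tumors and matched normals — can therefore be compared at the level of
network structure: which regulations hold in one condition but not the other.
`dgrn` implements a complete workflow for this comparison when a prior,
condition-agnostic *background* regulatory network is available (e.g. a
literature-curated regulon collection). The workflow has four statistical
stages, each exposed as ordinary functions and chained by `run_pipeline()`:

1. **Condition-specific network reconstruction** (`pc_prune()`): carve a
   normal-condition and a disease-condition network out of the background by
   deleting edges whose endpoints are (conditionally) independent in that
   condition's expression data.
2. **Differential network extraction** (`build_dgrn()`): collect the genes
   whose connections changed, plus their neighbors, with every edge tagged
   `common`, `normal_only` or `disease_only`.
3. **Module detection** (`greedy_communities()`): partition the differential
   network into densely connected communities by greedy modularity
   maximization.
4. **Biomarker selection** (`rfe_select()`): within each module, select a
   minimal gene panel whose joint expression separates the two phenotypes,
   by L2-regularized logistic regression with recursive feature elimination
   under cross-validation, evaluated on held-out samples (`evaluate_panel()`)
   and against size-matched random panels (`random_panel_test()`).

# Conditional independence testing by binned mutual information

Dependence between expression profiles is measured by the plug-in mutual
information on discretized data,

$$ I(X;Y) = \sum_{i,j} p(i,j)\,\log\frac{p(i,j)}{p_x(i)\,p_y(j)}, $$

and, for a conditioning set $Z$,

$$ I(X;Y\mid Z) = \sum_{i,j,k} p(i,j,k)\,
   \log\frac{p_z(k)\,p(i,j,k)}{p_{xz}(i,k)\,p_{yz}(j,k)}, $$

both in nats. The probabilities are empirical frequencies over bins; several
conditioning genes are handled by forming the composite (joint) discretization
of the set. These estimators are symmetric, non-negative after clamping, and
satisfy the chain rule $I(X;Y\mid Z) = I(X;(Y,Z)) - I(X;Z)$ exactly on the
binned data — properties the test suite verifies against brute-force
summation.

## Binning: why so coarse?

`binning_scheme()` defaults to **3 equal-frequency bins** (low / medium /
high expression). The choice is driven by the bias of the plug-in estimator:
under (conditional) independence its expectation is approximately
$(k-1)^2 k^{\ell} / (2n)$ nats for $k$ bins and conditioning order $\ell$.
Bin counts that grow with $n$ (e.g. the cube-root rule common in density
estimation) make the order-1 statistic sit near 0.25 nats at $n = 500$ —
far above any sensible deletion threshold, so no conditionally independent
edge could ever be removed. With $k = 3$ the order-1 bias stays near 0.01
nats at the sample sizes this package targets ($n \gtrsim 100$ per
condition), leaving a usable gap between independent and dependent pairs.
Equal-frequency bins are the default because expression distributions are
routinely skewed; equal-width binning is available.

## Path-consistency pruning

`pc_prune()` escalates the conditioning order. At order 0, every background
edge with $I(X;Y)$ below the threshold is deleted. At order
$\ell \ge 1$, each surviving edge $(X,Y)$ is tested against all
$\ell$-subsets of the *current* common neighbors of $X$ and $Y$ (capped at
`max_sets = 50`, lowest-degree neighbors first, to bound cost); the edge is
deleted when the **minimum** statistic over the enumerated subsets falls
below the threshold — one separating set suffices, the usual
conditional-independence semantics. Deletions are applied synchronously
after each full pass so the result does not depend on edge iteration order.
Escalation stops at `max_order` (default 1) or as soon as a pass deletes
nothing.

The default threshold is **0.03 nats**, used identically in both conditions.
At 3 bins this sits roughly three standard deviations above the
independence bias at $n = 200$, while direct linear links of moderate
strength (correlation $\ge 0.5$) score around 0.1 nats. Both threshold and
order are configurable; raising the threshold can only remove edges
(monotonicity), never add them, and the output is always a subset of the
background — the method cannot invent regulations.

# The differential network

A gene is a *rewiring seed* when it is present in both condition networks
but its undirected neighbor sets differ. The differential network contains
the seeds, their neighbors in either condition network, and **all** edges of
either network induced on that node set (not only seed-incident ones): the
induced reading gives downstream community detection the complete local
topology. Genes absent from one condition network entirely have no defined
connections there and are deliberately not treated as seeds. Edge direction
from the prior is retained as metadata but plays no role from this point on
— the information-theoretic statistics are symmetric, so the analysis view
is undirected throughout.

# Module detection

Communities are found by greedy agglomerative modularity maximization.
With $e_{ii}$ the fraction of edges inside module $i$ (a cross-module edge
contributing half to each side) and $a_i = \sum_j e_{ij}$,

$$ Q = \sum_i \left( e_{ii} - a_i^2 \right). $$

Starting from singletons, the connected module pair with the largest
$\Delta Q = 2(e_{ij} - a_i a_j)$ is merged until no connected pair remains;
the partition along the merge path with maximum $Q$ is returned together
with the full merge history. Two determinism conventions are fixed because
the greedy procedure is otherwise order-sensitive: ties in $\Delta Q$ are
broken toward the lexicographically smallest module pair (modules named by
their smallest contained node id), and disconnected modules are never merge
candidates (their gain $-2a_ia_j$ is always negative). On small graphs the
greedy optimum is verified against exhaustive enumeration over all set
partitions; no minimum module size is imposed by the detection itself
(`run_pipeline()` offers `min_module_size`, default 1, to filter what enters
biomarker selection — even 2–3-gene modules can carry a usable panel).

# Biomarker panels by LR-RFE

Within a module with gene matrix $X$ and labels $y$, the classifier is
logistic regression with an L2 penalty,

$$ \pi_i = \frac{e^{x_i^\top\theta}}{1 + e^{x_i^\top\theta}},
   \qquad
   \min_\theta\; -\!\sum_i \big[ y_i\log\pi_i + (1-y_i)\log(1-\pi_i) \big]
   + \lambda\sum_{j\ge1}\theta_j^2, $$

with the intercept unpenalized and $\lambda = 1$ by default (configurable;
no nested search over $\lambda$ is attempted). The solver is a damped Newton
iteration on the exact gradient and Hessian, converged to a gradient
sup-norm of $10^{-8}$, so fits are deterministic.

Recursive feature elimination removes **one gene per step** — the one with
the smallest absolute coefficient after z-scoring the features — down to a
single gene. Every candidate panel size is scored by stratified tenfold
cross-validation (features re-standardized inside each training fold; mean
F1 across folds), and the selected size is the smallest whose mean CV score
is within `tie_tol` of the maximum: genes are removed as long as removal
costs no performance.

`tie_tol` defaults to **0.005**. This is the resolution of tenfold-CV mean
F1 at typical fold sizes: flipping a single test sample in one fold moves
the mean by about 0.005, so differences below it are sub-resolution and are
treated as ties rather than as signal. A strict (near-zero) tolerance makes
the choice track pure CV noise and inflates panels with uninformative
genes. Even so, panel-*size* selection is the noisiest part of the whole
workflow: at moderate effect sizes the cost of dropping the weakest
informative gene (~0.01 mean F1 at $n = 200$) is the same order as the CV
noise floor, so the chosen size wobbles by a gene or two around the planted
optimum. The elimination *order* is far more stable than the size choice —
in the package's synthetic benchmarks the informative genes always outlast
the noise genes along the path. Panels are evaluated on held-out samples by
F1 at probability cutoff 0.5 and by the rank-statistic AUC (ties count
one-half; verified against brute-force pairwise concordance).

The random-panel comparison draws size-matched gene sets from the analysis
universe, fits and evaluates them identically (without RFE, since the size
is fixed), and compares per-module AUC pairs with a one-sided Wilcoxon
signed-rank test; the test is exact by sign-flip enumeration up to $n = 15$
modules (valid under ties) and a tie-corrected normal approximation beyond.
The paired signed-rank choice is a convention of this package — it is the
natural test for few paired, non-Gaussian AUCs — not a claim about how any
particular published comparison was computed.

# The synthetic benchmark generator

`make_instance()` produces fully specified instances for recovery testing:

* a random DAG backbone (default **50 genes, 75 edges**) as the normal-
  condition truth;
* a disease-condition truth obtained by rewiring a controlled fraction
  (default **20%**) of backbone edges — removed edges and their random
  acyclic replacements form the planted rewired set, their endpoints the
  *driver genes*;
* a background network equal to the union of both truths plus **50%**
  spurious edges never used by either generative model — emulating a prior
  with many redundant regulations;
* expression from a linear-Gaussian structural-equation model: each gene is
  the weighted sum of its parents plus unit-variance Gaussian noise, weights
  uniform in magnitude 0.6–1.2 with random sign, **200 samples per
  condition**. Weights are drawn once over the union of true edges and
  shared between conditions, so the between-class signal is carried by the
  rewired edges rather than smeared over every gene.

One deliberate extension beyond the bare structural-equation model: driver
genes receive a disease-condition baseline (mean) shift of magnitude 1.0
noise-SD (random sign) that propagates to their descendants. A pure
zero-mean model would make the two classes differ only in covariance and be
symmetric about the origin, so *no linear classifier could beat chance* and
the biomarker stage would be untestable; the shift mirrors the differential
expression that rewired modules show in real case–control data. Defaults
were chosen once, on these grounds, as the package's study conditions.

What the generator does **not** emulate: nonlinear regulation, count noise
(negative-binomial), batch effects, or missing genes between prior and
data. Passing recovery tests therefore demonstrates correctness of the
algorithms under the model where conditional independence matches graph
separation — not performance on any particular real dataset.

The closed-form covariance $(I-A)^{-1}\sigma^2(I-A)^{-\top}$ of the model is
exported (`sem_covariance()`) and the simulator is validated against it.

# Numerical conventions and degenerate inputs

* Statistics are clamped at zero; symmetry holds to $10^{-12}$.
* Constant expression vectors discretize to a single bin; conditioning on a
  constant reduces CMI to MI exactly. Zero-variance genes are flagged on
  loading.
* An empty inferred network scores precision 1 and recall 0 in recovery
  reports (no false assertions were made); this convention is documented in
  `edge_recovery()`.
* A run in which the two condition networks show no rewiring exits
  gracefully with status `"no rewiring detected"`.
* One global seed fans out to the stages as `seed + stage offset`; identical
  configuration and seed give byte-identical metrics files.

# Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on generated data:
default 50-gene instances (25 replicate seeds for recovery rates), the
three-gene chain fixture at $n = 500$ (50 seeds) for path-consistency
behavior, and small enumeration fixtures for the exact oracles. These sizes
were chosen so the whole suite documents the method's behavior at
desk-scale while each Monte-Carlo rate still has a usable standard error;
all of them are ordinary function arguments and scale up unchanged.

# Known limitations

* The binned plug-in estimator is biased upward at higher conditioning
  orders; `max_order` beyond 1 is rarely informative at $n \le 500$ and the
  conditioning-set cap makes high orders heuristic on dense priors.
* Gene identifiers are matched by exact string equality (after whitespace
  stripping); no alias resolution is attempted.
* Edge direction is never inferred from data; the prior's directions are
  carried as metadata only.
* Panel-size selection by CV is intrinsically noisy at moderate effect
  sizes (see above); panel *membership* of strong markers is much more
  reproducible than panel size.
* No statistical test is attached to individual rewired edges; the
  differential network is a deterministic set comparison of two pruned
  networks.
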