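---
title: "Inferring spatial cell-cell communication by collective optimal transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spatial cell-cell communication by collective optimal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialcot)
```

## The model

Spatial transcriptomics measures, at every spot (or cell) of a tissue
section, the expression of thousands of genes together with the spot's
position. Cell–cell communication (CCC) happens when a ligand secreted by
one cell binds a receptor on another, and expression of ligand and receptor
genes is the observable proxy for the amounts available. Two physical
constraints make naive co-expression scoring misleading: a ligand can only
act within a limited distance of its source, and the same ligand molecules
cannot be counted twice — if WNT5B at a spot signals to one neighbour, that
amount is no longer available to others, and different receptors for the
same ligand compete for it.

spatialcot treats expression as *mass* and infers communication as a
coupled, inequality-constrained optimal transport plan over all ligand and
receptor species simultaneously. Writing $X^L_{i,k}$ for the amount of
ligand species $i$ at spot $k$ and $X^R_{j,l}$ for receptor species $j$ at
spot $l$, the method seeks a four-index coupling $P_{i,j,k,l} \ge 0$
(signal from sender $k$ to receiver $l$ through the pair $(i,j)$)
minimizing

$$\sum_{(i,j) \in I} \langle P_{i,j,\cdot,\cdot},\, C_{(i,j)} \rangle
  + \rho \left( \|\mu\|_1 + \|\nu\|_1 \right),$$

subject to $P_{i,j,\cdot,\cdot} = 0$ for species pairs that cannot bind
($\,(i,j) \notin I$), and to the capacity inequalities

$$\sum_{j,l} P_{i,j,k,l} \le X^L_{i,k}, \qquad
  \sum_{i,k} P_{i,j,k,l} \le X^R_{j,l},$$

where $\mu, \nu$ are the untransported remainders. The cost
$C_{(i,j)}[k,l] = \varphi(D_{k,l})$ if the Euclidean spot distance
$D_{k,l}$ is within the pair's spatial limit $T_{(i,j)}$ and $+\infty$
otherwise, which makes signaling beyond the limit *structurally*
impossible rather than merely expensive. Because all species share the
per-spot capacities, the couplings are not independent: raising one
ligand's supply can only divert, never create, a competitor's signal (a
property the test suite checks exactly).

Heteromeric complexes (e.g. a receptor written `FZD1_LRP6`) are quantified
by the minimum expression over their subunits: a complex is limited by its
scarcest part.

## The solver

After adding entropic regularization
$\varepsilon H(\cdot)$ (with a single common coefficient for the plan and
both slacks), the problem is flattened: all ligand species' spot vectors
are stacked into one source vector $a$, all receptor species into a target
vector $b$, and the per-pair costs become one big sparse cost matrix whose
stored entries are exactly the finite ones. The solution has the Gibbs form
$P^* = e^{(f \oplus g - C)/\varepsilon}$ and the duals $f, g$ satisfy a
pair of closed-form alternating updates, which we evaluate in the log
domain with log-sum-exp stabilization over the sparse row/column supports:

$$f_k = \varepsilon \log a_k - \varepsilon\,\mathrm{LSE}\!\left(
  \{(g_l - C_{kl})/\varepsilon\}_{l},\, -\rho/\varepsilon \right),$$

and symmetrically for $g$. The extra $-\rho/\varepsilon$ atom is the
untransported-mass option: mass stays home when every route costs more than
the penalty. Spots with zero amount are masked ($f = -\infty$) and yield
exactly zero rows/columns. Memory is $O(\text{nnz}(C))$: only finite costs
and nonzero couplings are ever stored.

Numerical choices:

* **Initialization** $f^{(0)} = g^{(0)} = 0$, fixed for determinism.
* **Convergence** when the max-norm dual change drops below `tol`
  (default `1e-8`); non-convergence returns the best iterate flagged
  `converged = FALSE`, never silently.
* **$\varepsilon$-annealing** (default on): iterations start at
  $\varepsilon_0 = \max C$ and halve down to the target, warm-starting the
  duals at each level. The regularized problem is strictly convex, so the
  fixed point is unchanged; annealing only removes the slow cold-start
  transient, which otherwise dominates at small $\varepsilon$ on
  near-balanced instances (total ligand mass close to total receptor
  capacity).
* **Defaults** $\varepsilon = 0.01 \times \mathrm{median}(C)$ and
  $\rho = 10 \times \max(C)$. With $\rho$ far above any transport cost,
  signal couples wherever the spatial limit allows — the right regime for
  screening a database of pairs. Both are configurable; for data with a
  known diffusion length $\lambda$ and linear costs, setting
  $\varepsilon = \lambda$ makes the entropic kernel
  $e^{-D/\varepsilon}$ coincide with the screened-diffusion kernel
  $e^{-d/\lambda}$, which is what the end-to-end validation uses.
* **Post-solve sparsification** drops entries below
  $10^{-8} \times$ (transported mass / support size): entropic plans are
  dense on their support and the tail is numerical fog.
* The general case of *unequal* entropic coefficients for plan and slacks
  is intentionally not implemented; the common-coefficient iteration is the
  production path.

There is no silent default for the spatial limit: pairs without a `limit`
in the database require an explicit `dis_thr`. The correct magnitude is
data-dependent (units follow the coordinates; no unit conversion is ever
attempted), and a wrong default would be invisible and consequential. The
default cost scaling is `linear` ($\varphi(d) = d$), the least aggressive
choice and the one that keeps costs in distance units; `square` and
`exponential` ($e^{d/T} - 1$, pinned so $\varphi(0) = 0$ and the scale is
limit-relative) are available.

Expression is assumed normalized on a *linear* scale. The optional
`normalize_total_counts()` step scales each spot's total to the median
total and applies no log transform: transport marginals are amounts, and
log units would destroy the mass semantics. Pairs whose ligand or receptor
is expressed in fewer than 0.5% of spots are dropped before solving
(configurable), mirroring common screening practice.

## Downstream summaries

* **Per-spot totals.** For a coupling $S$, the signal sent by spot $i$ is
  the row sum, the signal received the column sum.
* **Direction fields.** The sending vector of spot $i$ is the
  signal-weighted sum of unit offsets towards its top-$k$ receivers
  (default $k = 5$, ties broken to the lower index), re-normalized and
  scaled by the total sent, so the norm of each vector *is* the total
  signal. When the weighted offsets cancel exactly the direction is
  genuinely ambiguous and the zero vector is returned. A Gaussian-kernel
  interpolation onto a regular grid supports streamline-style displays.
* **Cluster networks.** Mean coupling over all ordered spot pairs between
  clusters, diagonal pairs included (the aggregation averages every
  $(k,l)$ with $L_k = i$, $L_l = j$). Significance comes from label
  permutations with the add-one estimator
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$,
  which is never exactly zero and is exactly valid under exchangeability.
  Because label permutation after solving cannot detect structure tied to
  space itself, two location-permutation modes re-solve the transport with
  shuffled locations (all spots, or within clusters) via a caller-supplied
  resolver.
* **Communication profiles.** Each spot gets a $2 n_{lr}$-vector of
  per-pair sent and received totals; k-means on row-normalized profiles or
  Louvain communities on a kNN graph cluster cells by communication
  behavior. The clustering backend for this kind of display is not
  standardized in the field; both backends are deterministic given the
  seed.
* **Signaling-associated genes.** Expression is regressed on the *rank* of
  received signal through a cubic B-spline basis (4 interior knots) and
  tested against the intercept-only model by an F-test with BH correction.
  This is a self-contained association test in the spirit of GAM-based
  trajectory DE tools; ranks make it invariant to monotone rescaling of
  the received signal. Pathway-level signal sums per-pair couplings after
  sparsification.
* **Unique impact.** A random-forest regression of a target gene on the
  received signal plus its 20 most-correlated genes (all features
  considered at every split, 500 trees); the normalized impurity-decrease
  importance of the signal feature measures what communication explains
  that co-expression cannot.

## Evaluation metrics

Vector fields are compared by a magnitude-weighted cosine distance in
$[0, 2]$ (rows with zero reference vector carry zero weight; a zero
compared vector takes the maximal penalty); binarized cluster networks
($p < 0.05$) by the Jaccard distance on edge sets; inferred signaling
against known target-gene activity by Spearman correlation across
clusters.

## The synthetic tissue generator

Validating CCC inference on real tissue is hard because ligand-receptor
binding is not directly observed, so the package ships a
reaction-diffusion simulator with known ground truth. Designated sender
spots secrete ligands at rates $q_{i,k}$; the steady state of diffusion
with linear degradation gives the screened-diffusion kernel
$K_i(d) = e^{-d/\lambda_i}$ for the free-ligand field ($\lambda_i$ the
diffusion length). Receptor binding saturates Michaelis–Menten style,
allocating each receptor's amount $R_{j,l}$ among all incoming flux:

$$G_{i,j,k,l} = \frac{R_{j,l}\, \kappa_{ij}\, q_{i,k}\, K_i(d_{kl})}
  {\kappa_0 + \sum_{(i',j') \in I} \sum_{k'} \kappa_{i'j'}\, q_{i',k'}\,
  K_{i'}(d_{k'l})},$$

so total flux into a receptor never exceeds its amount, and identical
ligands split a shared receptor exactly evenly. Defaults: a 20×20 unit
grid, $\lambda_i \sim U[2, 8]$ grid units, 5% of spots secreting each
ligand with rates $U[0.5, 1.5]$, receptor amounts $U[0.5, 1.5]$ on all
spots, $\kappa_0 = 1$.

The expression readout is
$X = (\text{value} + \text{floor}) \cdot e^{\sigma Z - \sigma^2/2}$ with
$Z \sim N(0,1)$, $\sigma = 0.2$ by default and a background floor of
$0.1 \times$ the mean secretion rate. The floor is what makes recovery
non-trivial — every spot shows some ligand expression, so the solver must
rank true senders above background — and the multiplicative lognormal term
is mean-one, so the readout is unbiased and degrades gracefully as
$\sigma$ grows (recovery AUROC decreases monotonically in $\sigma$, a
property the suite tests). What the simulator does *not* emulate: gene
count noise models (it draws continuous amounts, not counts), intracellular
regulation downstream of binding, anisotropic or obstructed diffusion, and
segmentation artefacts. Passing the recovery tests therefore shows the
inference is sound when expression faithfully proxies amounts, not that
real-tissue couplings are guaranteed correct.

Ground truth labels an edge positive when its steady-state flux is
positive, i.e. when the sender truly secretes; recovery is scored by AUROC
over the spatial-support candidate set, plus Spearman correlation of
strengths on true edges.

## Problem sizes and verification

The shipped checks run at desk scale, chosen to finish in minutes while
exercising every contract: exact-LP agreement on 50 instances with up to 4
spots and 2×2 species (relative objective gap below 1% at
$\varepsilon = 10^{-3} \times$ median cost); feasibility and support on
100 random solves up to 200 spots and 5×5 species; permutation-test
uniformity over 50 null replicates of 200 spots with 999 permutations;
association-test calibration on 2,000 null genes and power on planted
monotone effects explaining half the variance at 300 spots; and end-to-end
recovery on the 20×20 simulated tissue with two ligands competing for a
shared receptor ($\lambda = 5$, $\sigma = 0.2$), where the solver is run
with $\varepsilon = \lambda$ as motivated above. `scripts/acceptance.R`
recomputes all of these from scratch with a caller-supplied seed.

## Known limitations

* Euclidean distances only; tissue geometry (barriers, curvature) is not
  modelled.
* Expression is a proxy for protein amounts; post-translational state is
  invisible.
* The entropic plan is dense on its spatial support before
  sparsification; extremely small $\varepsilon$ on large tissues is
  expensive even with annealing.
* Location-permutation significance re-solves the transport per
  permutation and costs accordingly.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_tissue(n_spots = 400, n_ligands = 2, n_receptors = 1,
                       lambda = 5, seed = 1)
ccc <- infer_communication(sim$expr, sim$db, dis_thr = 10, eps = 5)
glance(ccc)
evaluate_recovery(ccc, sim)

field <- signaling_direction(total_matrix(ccc), sim$expr$coords, k = 5)
autoplot(field)

tot <- received_sent_totals(total_matrix(ccc))
deg <- signaling_deg_test(sim$expr, tot$received)
head(deg)
```
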