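---
title: "Methods: morphological networks, infinite feature selection, and reproducible discriminative connections"
author: "cmnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological networks, infinite feature selection, and reproducible discriminative connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cmnet` implements an end-to-end analysis for discovering group-discriminative
connections in *cortical morphological networks* (CMNs). A CMN represents each
cortical hemisphere as a fully connected graph over $n_r$ regions of interest
(by default the 35 Desikan-Killiany regions, `dk_regions()`): for a
morphological measurement $m$ (maximum principal curvature, mean cortical
thickness, mean sulcal depth, or mean average curvature), the ROI value is the
vertex average

$$\tilde m_i = \frac{1}{\#\{v \in R_i\}} \sum_{v \in R_i} m(v),$$

and the connection weight between regions $i$ and $j$ is the absolute
difference $C_m(i,j) = |\tilde m_i - \tilde m_j|$. Morphologically similar
regions therefore have weights near zero. Each subject's symmetric,
zero-diagonal matrix is vectorized over the strict upper triangle in a fixed
row-major order (`edge_index_map()`), giving $n_f = n_r(n_r-1)/2$ features
(595 for $n_r = 35$). The ordering is arbitrary but must be — and is — the
same bijection everywhere: across subjects, cross-validation schemes and
reports.

Two elementary invariances follow from the definition and are asserted in the
test suite: translation invariance ($C(\tilde m + c) = C(\tilde m)$) and
absolute-scale equivariance ($C(a \tilde m) = |a| C(\tilde m)$).

# Infinite feature selection

Connectional features are ranked by graph-based *infinite feature selection*:
features are nodes of a weighted graph with adjacency

$$A(k,l) = \alpha\,\sigma_{kl} + (1-\alpha)\,c_{kl}, \qquad
\sigma_{kl} = \max(\sigma^{(k)}, \sigma^{(l)}), \qquad
c_{kl} = 1 - |\mathrm{Spearman}(f^{(k)}, f^{(l)})|,$$

where $\sigma^{(k)}$ is the standard deviation of feature $k$ over subjects
and $\alpha \in [0,1]$ mixes dispersion against decorrelation. A feature's
relevance sums weighted walks of *every* length through this graph, which has
the closed form

$$\tilde S = (I - rA)^{-1} - I, \qquad \tilde s_i = [\tilde S\, e]_i,$$

equal to the Neumann series $\sum_{p\ge1} r^p (A^p e)_i$ whenever the
spectral radius $\rho(rA) < 1$. The implementation checks this condition
(cheap row-sum bound first, exact symmetric eigenvalue only when the bound is
inconclusive) and raises an error telling the user to lower $r$ or
standardize — it never regularizes silently, because a divergent series has
no meaningful score.

## Tunable parameters

* `alpha` (default 0.5, unitless): the method's definition only constrains
  $\alpha$ to $[0,1]$; 0.5 weights both terms equally and is kept
  configurable.
* `r` (default 0.01, unitless): damping of long walks. Note that the
  convergence condition couples $r$ to $n_f$ and to the scale of $A$: with
  raw attribute scales and $n_f = 595$ the product $r\rho(A)$ can exceed 1,
  in which case the loud error fires and either `standardize = TRUE` or a
  smaller `r` is required. All pipeline-scale analyses in the test suite run
  at $n_r = 15$ ($n_f = 105$), where $r = 0.01$ converges comfortably.
* `standardize` (default `FALSE`): z-score features before building $A$.

## Why `standardize` defaults to off

The printed scoring formulas contain no label term. Supervision enters the
pipeline *only* through fold restriction (the ranking is recomputed on the
training subjects of every cross-validation fold). The single channel through
which a group difference can influence the ranking is the dispersion term: a
group mean shift on a connection inflates its pooled variance (mixture
variance $\sigma^2 + p q \delta^2$), raising $\sigma^{(k)}$ and hence the
feature's row of $A$. Z-scoring sets every $\sigma^{(k)} = 1$ and removes
that channel entirely, leaving a ranking driven purely by decorrelation that
is provably blind to group structure. We therefore default to the raw-scale
path and keep standardization as an explicit option for convergence at large
$n_f$, with the documented cost that it cannot prefer discriminative edges.

A further consequence, measured in development and worth knowing: effect
edges are mutually correlated (they share the shifted ROIs' noise and the
group shift), so the decorrelation term actively *penalizes* them. For
measurements whose raw scale is small (curvatures, $\sigma \approx 0.02$) the
dispersion boost is numerically tiny against the decorrelation term at
$\alpha = 0.5$, and a strongly affected edge can rank near the *bottom*.
Recovery of injected effects through the cross-measurement aggregation relies
on the higher-dispersion measurements (thickness, sulcal depth) carrying the
edge. Dispersion-dominant settings ($\alpha \to 1$) make recovery uniform
across measurements; the package leaves $\alpha = 0.5$ as the neutral default
and documents the trade-off here rather than hiding it.

# Classification and cross-validation

A linear max-margin classifier (SVM) is trained on the top $K = 100$ ranked
connections. No maintained linear-SVM package is available in the target
environment, so the package ships a small dual coordinate-descent solver for
the L1-loss linear SVM (the LIBLINEAR algorithm) as compiled code; its
optimality is certified in the tests by the primal-dual duality gap rather
than by comparison with another library. Features are z-scored with
training-fold statistics before fitting.

Three cross-validation schemes are run: leave-one-out, 5-fold and 10-fold.
Folds are stratified by group and deterministic given the scheme seed;
subjects are shuffled within class and assigned to folds cyclically by global
position, which makes `n_folds = n` reproduce the leave-one-out partition
exactly (a property the tests assert). Within every outer fold the margin
cost is tuned by an inner stratified 5-fold cross-validation over the
log-spaced grid $10^{-3}, \dots, 10^3$ (the grid is a conventional choice;
ties go to the smaller cost). Accuracy is the pooled fraction of correct
held-out predictions — well-defined for leave-one-out, and at these sample
sizes indistinguishable from fold-averaged accuracy.

Held-out purity is structural: ranking, scaling, tuning and fitting all
receive only training rows. The test suite additionally runs a canary check —
a feature column equal to the labels drives accuracy to ~1 when visible, and
excluding it from the usable columns returns accuracy to chance on pure
noise.

# Reproducibility aggregation

For each measurement, each scheme's per-feature weight is the mean inFS score
over that scheme's outer folds (the least surprising, seed-stable reduction;
the source method does not prescribe one). Weights are min-max normalized to
$[0,1]$ per scheme before averaging because raw score magnitudes vary with
training-fold size; raw-scale averaging remains available behind
`normalize = FALSE`. On the union of the three top-$k_f$ sets, each scheme
contributes its normalized weight where the edge made its top set and 0 where
it did not — absence is evidence against reproducibility and is counted as
such. The per-measurement union weights are then averaged across
measurements (again 0 for absent edges) and the final top $k_f = 5$ edges are
reported with ties broken by edge index.

# Effect sizes

For any connection, Cohen's d is computed exactly as
$d = |\mu_a - \mu_b| / \mathrm{stdm}$ with
$\mathrm{stdm} = (\sigma_a + \sigma_b)/2$, using sample ($n-1$) standard
deviations. This statistic is nonnegative and *unbounded above* (the
occasional informal claim that it lies in $[0,1]$ does not follow from the
formula); values are reported as computed. Banding uses Cohen's conventional
boundaries exactly: $d \ge 0.8$ large, $\ge 0.5$ medium, $\ge 0.2$ small,
else not substantial. Both sds zero with equal means defines $d = 0$; with
unequal means the statistic is undefined and reported as an error per edge.

# The synthetic world

The generator (`synthetic_config()` / `simulate_cohort()`) emulates a
two-group cohort (default 308 vs 390 subjects, mirroring a typical large
single-site study) with independent Gaussian noise per ROI. It makes three
deliberate, documented simplifications:

* **Equal baseline means across ROIs** (per measurement, at realistic
  scales: thickness 2.5 mm, sulcal depth 1.5, maximum principal curvature
  0.12, average curvature 0.08; sds 0.15 / 0.6 / 0.02 / 0.015). Under the
  null every connection then has the same folded-normal distribution
  $|N(0, \sigma_i^2 + \sigma_j^2)|$, so no edge is structurally favoured and
  false-positive behaviour is interpretable. Real cortices have strong
  regional mean structure; a green test here does **not** establish
  robustness to that structure (with unequal baselines, partially folded
  edges have systematically different dispersion and correlation profiles
  and the label-free ranking acquires deterministic favourites).
* **No spatial correlation, no covariates, no hemispheric asymmetry**: both
  hemispheres are generated by the same independent procedure.
* **Effects are injected on ROI means**, because connectivity is a
  deterministic function of ROI values. `expected_connection_effect()`
  translates any set of injected shifts into the implied population Cohen's
  d via closed-form folded-normal moments
  ($E|X|$ and $\mathrm{sd}|X|$ for $X \sim N(\mu, s^2)$), verified in the
  tests against brute-force Monte-Carlo. A single-ROI shift elevates all
  $n_r - 1$ incident connections identically, which leaves "the affected
  edge" ill-defined; recovery tests therefore shift the two incident ROIs in
  *opposite* directions ($\pm\delta/2$) in one group, making the target
  connection the unique argmax of the oracle effect size.

Vertex-level generation (`vertices_per_roi = V`) draws per-vertex values at
the stated sd and ROI-averages them, distributionally identical to ROI-level
generation at $\mathrm{sd}/\sqrt V$.

# Numerical and design choices

* Edge order: row-major strict upper triangle; ROI order: the shipped
  35-name Desikan-Killiany list (FreeSurfer aparc labels including
  `corpuscallosum`, alphabetical) — the atlas definition does not prescribe
  either, but every reported region pair depends on them being fixed.
* Constant features get $c_{kl} = 1$ (treated as uncorrelated),
  $\sigma^{(k)} = 0$, and a warning.
* Ranking ties break by ascending feature index, everywhere.
* Inner-fold and solver seeds derive from the scheme seed plus the smallest
  held-out index, so identical partitions give identical results regardless
  of fold enumeration order.
* Min-max normalization of a constant weight vector is defined as all zeros.
* The pipeline summary JSON contains parameters and results only (no
  timestamps), so identical configurations produce byte-identical summaries.

# Known limitations

* The supervision mechanism is fold restriction only; no label-aware
  relevance term is invented beyond the printed formulas, with the
  selection-power consequences described above.
* Statistical significance of effect sizes is out of scope: no test is
  specified for the banding, and none is invented.
* The convergence domain of the closed-form score shrinks with $n_f$ at raw
  scales; full 595-feature rankings may require standardization (losing the
  dispersion channel) or a smaller `r`.
* The circular plot is a convenience rendering, not a publication graphic.
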