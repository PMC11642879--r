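---
title: "Manifold-constrained velocity refinement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold-constrained velocity refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphvelo)
```

## The problem

RNA velocity estimators assign each cell a vector $v_i$ — the expected
instantaneous change of its expression state $x_i$. These vectors are noisy,
cover only a subset of genes (those with usable splicing dynamics), and are
generally *not* tangent to the low-dimensional manifold that the sampled
cell states trace out. Yet if the velocities describe the motion of cells
*on* that manifold, they must lie in its tangent space. This package
enforces that constraint, and exploits it to move velocity vectors between
representations and modalities.

## The projection model

For cell $i$ with neighbourhood $\mathcal N_i$ (a kNN graph on the cell
state manifold), the displacements $\delta_{ij} = x_j - x_i$ form a
complete, redundant, non-orthogonal basis of the local tangent space. The
projected velocity is the linear combination

$$v^{\parallel}_i = \sum_{j \in \mathcal N_i} \phi_{ij}\, \delta_{ij}.$$

Solving for $\phi_i$ by plain least squares is numerically unstable
(the basis is redundant), so the weights minimise the tangent-space
projection loss

$$\mathcal L(\phi_i) = a \lVert v_i - v^{\parallel}_i \rVert^2
  - b \cos(\phi_i, \phi_i^{\mathrm{corr}})
  + \lambda \lVert \phi_i \rVert^2,$$

where $\phi_i^{\mathrm{corr}}$ are the cosine-kernel weights
$\cos(v_i, \delta_{ij})$ — the classical heuristic that is asymptotically
direction-correct but magnitude-free. The first term preserves magnitude,
the second anchors the direction, the ridge bounds the redundant weights.

**Defaults**: $a = 1$, $b = 10$, $\lambda = 1$ (dimensionless; `tsp_config()`).
Graph size `k = 30` for single-modality data, `k = 8` for spatial graphs
(combined with the expression graph by `union_graph()`). These are the
standard settings of this model family and are deliberately not adaptive.

Each cell is an independent optimisation over at most `k` weights. We use
BFGS with the analytic gradient, initialised at the closed-form ridge
solution of the quadratic part ($b = 0$). The quadratic part dominates and
the cosine term is bounded, so the landscape is benign; with $b = 0$ the
closed form is returned directly (and equals ordinary least-squares
projection when $\lambda = 0$, a property the test suite checks against an
independent normal-equations oracle). Convergence tolerance `1e-6` on the
loss, at most 200 iterations; non-convergence returns the best iterate with
a warning, and the final loss can never exceed the loss at initialisation.
Results are independent of cell order.

**Missing velocities.** Upstream estimators emit velocities only for
"velocity genes"; missing entries are `NA` in the velocity layer. When
fitting, missing dimensions are dropped from both $v_i$ and the
displacement rows; the learned weights are then applied to the *full*
displacement basis. This is exactly the subspace-to-full-space inference
route, and it is why no special case is needed for inferring unmeasured
features.

## Changing basis: representations and modalities

Because the weights $\phi_{ij}$ are attached to pairs of *cells*, not to
features, the same weights transport velocity to any other coordinate
system of the same cells: $v^{\parallel}(y_i) = \sum_j \phi_{ij}(y_j - y_i)$
(`transform_velocity()` / `predict()`). For any linear map $A$ the
transform commutes exactly: $\sum_j \phi_{ij} (Ax_j - Ax_i) =
A v^{\parallel}_i$. The interesting uses are the *non*-trivial ones: target
coordinates given by chromatin accessibility, viral transcript counts, or
genes without velocity estimates. The mathematical justification is that a
smooth manifold embeds in modest dimension (Whitney), so a well-chosen
feature subset carries a one-to-one image of the manifold and the local
linear patches correspond.

`velocity_to_embedding()` uses finite propagation with the adaptive step
$dt_i = \mathrm{median}_j \lVert\delta_{ij}\rVert / \lVert v_i \rVert$,
which keeps the extrapolated state within the neighbourhood scale. We
resolved the step-size definition as this median-over-neighbours form; any
linear embedding makes the step cancel algebraically (the tests assert
equality with $v_i Q$), but the propagation form is the construction that
generalises to nonlinear maps. Cells with zero speed have an undefined step
and are flagged, not guessed.

## Scores

* **MacK** (manifold-consistent kinetics): per cell and gene, the fraction
  of neighbours whose pseudotime finite difference
  $\Delta x_{ij}/\Delta t_{ij}$ agrees in sign with the velocity.
  `sign(0)` is its own symbol — a zero velocity only matches a zero finite
  difference — so silent genes do not inflate scores. Neighbours with
  $\Delta t = 0$ are excluded (a zero divisor admits no sensible sign).
  Per-gene aggregation is the
  unweighted mean over scoreable cells; with the per-cell neighbour
  normalisation this makes the two readings of the leading $1/n$ coincide.
* **CBC** (cross-boundary correctness): mean cosine between boundary-cell
  velocities and displacements towards their neighbours in the annotated
  target population, computed in the full expression space (2-D embeddings
  distort geometry). Antisymmetric under $v \mapsto -v$ by construction.
* **Velocity consistency**: mean cosine between a cell's velocity and its
  neighbours'. Zero vectors contribute 0.
* **Cell speed**: $\lVert v_i \rVert_2$ over a feature subset (all genes:
  transition speed; viral genes: infection speed).
* **Cell-specific rates**: with $\beta \equiv 1$,
  $\alpha = u + du/dt$ and $\gamma = (u - ds/dt)/s$, masked where
  $s < 10^{-6}$. $du/dt$ comes from an unspliced-velocity layer when
  present, else by basis-swapping the spliced fit onto the unspliced
  coordinates.

All cosine-based scores are invariant under positive rescaling of the
velocities and equivariant under cell permutations; the suite asserts both.

## Synthetic data and what it does (not) show

The generators provide ground-truth velocities, which real data never has.

* **Toggle switch on a sphere.** Two mutually inhibiting, self-activating
  genes with Hill kinetics, integrated by Euler–Maruyama on the drift with
  reflection at zero; each cell is an independent trajectory of duration
  uniform in $[0, t_{\max}]$, so the population covers progenitor,
  decision region, and both branches. We chose stochastic simulation on
  the drift rather than an exact Gillespie decomposition: downstream tests
  only need states concentrated near the deterministic manifold. Rate
  constants ($a_{1,2} = 40$, $b_{1,2} = 20$, $S = K = 25$, $n = 4$,
  $\gamma = 1$, $\sigma = 2$, $t_{\max} = 15$) are repository choices made
  once so that states span tens of units and stay inside the benchmark
  sphere of radius $r = 70$; the committed attractors sit near $(58, 1)$.
  The lift $z = \sqrt{\max(r^2 - x^2 - y^2, 0)}$ with finite-difference
  vertical velocity (step $dt = 1$) yields a curved 2-D manifold in 3-D
  with tangent ground truth.
* **Noise injection** is either isotropic Gaussian on the velocity vector
  or purely along the manifold normal (radial direction) — the component a
  tangent projection should remove entirely.
* **Variable degradation.** A miRNA $m$ rises as $dm/dt = \alpha_m -
  \gamma_m m$ and both represses transcription ($\alpha = \alpha_0 -
  k_\alpha m$; we read the coupling as acting through $m$, which is the
  stated mechanism) and accelerates degradation ($\gamma = \gamma_0 +
  k_\gamma m$). Started at the unperturbed steady state, the trajectory
  spends most of its time with $\beta u - \gamma_0 s > 0$ while the true
  $ds/dt < 0$ — the failure mode of constant-rate estimators. Default
  fixture: $\alpha_0 = 10$, $\beta = 1$, $\gamma_0 = 1$, $k_\alpha = 2$,
  $k_\gamma = 3$, $\alpha_m = 1$, $\gamma_m = 0.5$, $t_{\max} = 10$
  (repository defaults, integrated by `lsoda` at `rtol 1e-8`).
* **Transcription burst.** Constant-rate kinetics from zero with
  $\alpha \to 3\alpha$ at $t_{\mathrm{burst}}$, integrated piecewise so the
  discontinuity is exact; from the pre-burst steady state the instantaneous
  jump in $du/dt$ is $2\alpha$.

Passing on these fixtures demonstrates correctness of the projection
machinery under a known manifold with known dynamics. It does **not**
demonstrate robustness to features of real data the generators omit: count
noise and sparsity, upstream estimator bias, batch structure, manifolds
with boundaries or varying dimension, or neighbourhood graphs corrupted by
doublets.

## Vector fields and dose-response curves

The continuous field is the RKHS expansion $v(x) = \sum_\alpha
\Gamma(x, \tilde x_\alpha) c_\alpha$ with Gaussian kernel. We fix the
kernel convention as $\Gamma = \exp(-w \lVert x - \tilde x \rVert^2)$ and
expose $w$ directly (any constant in the exponent folds into $w$; the
printed form of the kernel in this literature is typographically
ambiguous). Coefficients come from the normal equations of the
Tikhonov-regularised objective; the system is solved directly, with a tiny
escalating jitter if round-off makes it numerically singular, and a
pseudo-inverse (with a warning) only for genuinely unregularised fits.
Defaults: `n_centers = min(500, n/2)` seeded uniform subsample;
$w = 1/(2 q_{0.05})$ with $q_{0.05}$ the 5% quantile of squared pairwise
distances (localized bases keep the system well-conditioned);
$\lambda = 10^{-3}\, n\, \overline{K^2}$, which makes the two objective
terms commensurate.

The Jacobian is analytic:
$J_{ij}(x) = \sum_\alpha \Gamma(x,\tilde x_\alpha) c_{\alpha i}
(-2w)(x_j - \tilde x_{\alpha j})$, verified against central finite
differences. The effective dose-response curve bins $J_{ij}$ by the
regulator value (20 equal-width bins), averages within bins, and integrates
the bin means; the integration constant is 0 by convention, so curves are
meaningful up to an additive constant. Empty bins carry the previous mean
forward. A heterogeneity warning fires when the pooled within-bin spread is
comparable to the signal itself, which indicates context-dependent
regulation best handled by stratifying cells first.

## Trends, clustering, decoupling

Per-gene velocity trends along a 1-D axis (pseudotime, viral fraction) are
penalized cubic B-splines: a full B-spline basis on 10 equally spaced
interior knots with a second-difference coefficient penalty, the penalty
weight chosen by GCV over a fixed grid $10^{-6} \ldots 10^{6}$ (25
log-spaced points) unless supplied. We implement the penalized solve
directly — the fit is a single ridge-type linear system, which keeps it
exactly reproducible by an independent normal-equations oracle (asserted to
`1e-8`). Trends are evaluated at 100 equally spaced points covering the
axis range.

Trend clustering builds a kNN graph (`k = 15`) on Euclidean distances
between trend vectors and partitions it with Leiden at resolution 0.3. We
use the modularity objective, matching the semantics that "resolution"
carries in the single-cell ecosystem's default Leiden configuration.

Decoupling detection min-max normalises each modality's trend to $[0,1]$
(removing scale differences between RNA and chromatin velocities), computes
the classic DTW distance (symmetric step, no window, absolute local cost,
$O(n^2)$ dynamic program), ranks genes by descending distance, and cuts at
the elbow of the ranked curve — the point of maximum perpendicular distance
to the chord between its endpoints. Two numerical choices matter here.
First, larger DTW distance means *less* similar trends, hence "decoupled";
the opposite reading is inconsistent with cutting the ranked curve from
above. Second, on step-like ranked curves the perpendicular distance is
nearly flat along the lower plateau and its argmax wobbles between adjacent
ranks; we therefore take the first index within 1% of the maximum, which
anchors the cutoff at the top of the plateau, and flag genes *strictly*
above the cutoff. Constant trends normalise to zeros and are never flagged.

## Degenerate inputs and tie-breaking

* kNN ties are broken by ascending cell index; the graph build is exact
  (no approximate backend), so graphs are bit-reproducible.
* Cells with no neighbours keep their input velocity and are flagged;
  cells with all-missing velocities are flagged and excluded.
* An all-zero velocity short-circuits to zero weights.
* Cosines involving a zero vector are defined as 0 throughout.
* Union graphs are ragged; no code path assumes a fixed `k`.
* All stochastic steps (simulators, center subsampling, Leiden) take
  explicit seeds; rerunning a seeded pipeline is bit-reproducible.

## Problem sizes

The shipped tests and the acceptance script use the generators at their
study sizes: 2,000 cells for the sphere benchmark (graph `k = 30`), 1,500
for hidden-coordinate recovery, 500-cell score nulls, 400-point kinetics
trajectories, 400-sample vector-field fits with 100-200 centers, and
100-gene trend cohorts. These sizes were chosen as the smallest at which
the benchmarked properties are stable across seeds.

## Known limitations

* The projection assumes the kNN graph approximates the tangent space;
  in undersampled regions or across manifold boundaries the displacement
  basis is biased and the projected velocity inherits that bias.
* Velocity transfer to a target modality is only as good as the
  homeomorphism assumption between source and target manifolds; features
  uncorrelated with the manifold get near-zero inferred velocities.
* The cosine anchor term uses raw cosine-kernel weights without further
  normalisation; no constraint (e.g. simplex) is placed on $\phi$.
* Moment smoothing uses the arithmetic neighbourhood mean (optionally
  including self); no distance weighting.
* On-disk support covers dense and CSR/CSC h5ad and a delimited CSV
  bundle; out-of-core access is out of scope.
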