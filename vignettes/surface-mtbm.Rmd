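---
title: "Surface multivariate tensor-based morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface multivariate tensor-based morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`surfmorph` implements a complete surface-based morphometry pipeline for
subcortical structures: a closed structure surface (for example a segmented
putamen) is opened into a topological cylinder, mapped conformally onto a
rectangle, registered to a template by an inverse-consistent fluid flow of
surface feature images in the parameter domain, and compared between groups
with four per-vertex statistics — the areal Jacobian determinant, the log
deformation tensor, the medial-axis radial distance, and the combination of
the last two — under vertex-wise and map-wise permutation tests with a
CDF-based FDR summary. A synthetic-cohort generator produces two groups of
putamen-like surfaces with a known implanted deficit so that every stage can
be validated against ground truth.

This vignette explains the models, the tunable parameters, and the design
choices that were genuinely open; it states no empirical result beyond what
the test suite and `scripts/acceptance.R` compute themselves.

# Topology optimization

A closed genus-zero surface admits no rectangle parameterization, so two
small vertex patches are removed at the geometric extremities: the k-ring
neighborhoods (default `k = 2`) of the two extreme vertices along the first
principal axis of the vertex cloud. The result is a genus-zero surface with
two open boundaries — a topological cylinder — whose boundary loops serve as
landmarks shared by all subjects. The loop on the larger-projection side is
labeled *anterior* and becomes the `u = 0` end of the rectangle.

The cut size and placement rule are a package convention: the elongated
putamen has well-separated principal-axis extremes, and a 2-ring patch on a
subdivision-3 mesh removes roughly 2–3% of the surface. Degenerate clouds
(near-spherical) fall back to coordinate axes ranked by vertex range, so the
cut is deterministic on any input.

# Conformal parameterization by holomorphic 1-forms

On the cylinder mesh the harmonic function $f$ solves the discrete
(cotangent) Laplace equation with Dirichlet data $f = 0$ on the anterior
loop and $f = 1$ on the posterior loop. Its exterior derivative
$\omega = df$ is the harmonic 1-form; the conjugate form $\omega^*$ is
obtained by rotating the face-wise gradient of $f$ by 90 degrees about each
face normal and re-integrating in the least-squares (finite-element Poisson)
sense on the mesh cut open along a seam path between the loops. Integrating
the pair $(\omega, \omega^*)$ from the seam root yields the conformal
coordinates: $u \in [0, 1]$ axial and $v \in [0, h)$ circular, where $h$ is
the conformal modulus (for a right tube of radius $r$ and length $\ell$,
$h = 2\pi r/\ell$). The per-vertex conformal factor $\lambda$ is the ratio
of 3-D to parameter-domain area, and the mean curvature $H$ comes from the
cotangent mean-curvature-normal formula with mixed Voronoi areas.

Two numerical choices matter here:

* **Seam jump constraint.** The conjugate potential is solved with the jump
  across the seam constrained to a single unknown — the period $h$ — rather
  than taken as the mean of per-vertex jumps of an unconstrained solve. With
  the constraint, the parameter domain tiles the strip $[0,1] \times
  \mathbb{R}$ exactly under $v \mapsto v \pm h$, so point location near the
  seam has no coverage gaps. (Without it, per-vertex jump variation leaves
  slivers in which corresponded points collapse onto face corners.)
* **Seam anchor.** The circular coordinate is only defined up to rotation,
  and nothing intrinsic fixes it consistently across subjects. The seam
  starts at the anterior-loop vertex with the largest projection onto the
  second principal axis — a geometric landmark that is stable under the
  smooth per-subject shape variability the generator produces — and
  boundary-incident edges are heavily penalized in the shortest-path search
  so the seam leaves the loops immediately. An unanchored shortest path
  lands at noise-dependent positions around the cylinder, which randomizes
  the initial circular alignment between subjects and measurably degrades
  correspondence quality.

Local injectivity is enforced, not assumed: all parameter triangles must
have positive signed area, and any flip aborts with a count.

# Surface feature images and fluid registration

The registration operates on 2-channel feature images sampled on a regular
$n_u \times n_v$ grid over the rectangle: the conformal factor $\lambda$
(surface metric) and the mean curvature $H$ (extrinsic shape), each
z-scored over the grid so both contribute comparably to the intensity
difference. The circular direction is periodic; `u` includes both boundary
rows. The grid resolution trades sharpness of the force field against cost;
the pipeline default is 32 × 32 and the validation studies use 16 × 16,
which resolves the smooth synthetic deformations.

The flow model is the classic viscous-fluid registration restricted to the
parameter rectangle: at each iteration the multi-channel SSD body force
$-\sum_c (M_c(x + u(x)) - F_c(x))\,\nabla M_c(x + u(x))$ drives a velocity
field $v$ through $\mu \nabla^2 v + (\mu + \lambda_v)\nabla(\nabla\!\cdot\!v)
= -f$, discretized with finite differences (periodic circumferentially,
displacement pinned to zero on the two boundary rows — the loops are hard
landmarks) and solved by a cached sparse LU factorization. Displacements
advance with the material-transport term $u \mathrel{+}= \delta t\,(v -
(\nabla u)v)$, steps are accepted only if the symmetric SSD decreases
(otherwise the step is halved), and regridding keeps the incremental maps
above the Jacobian threshold (default 0.5) so the total maps remain
diffeomorphic. The force can be weighted by the template's conformal factor
(default on), which expresses the flat-domain PDE in surface area units.

Inverse consistency is enforced, as in the classic symmetric formulations,
by estimating the forward map $g$ (subject grid onto template grid) and the
backward map $h$ simultaneously and applying, each iteration, a correction
step of size `ic_weight` (default 0.2) along the residuals
$g(x) + h(x + g(x))$ and $h(x) + g(x + h(x))$. The returned object records
the final inverse-consistency RMS in grid nodes.

Because the boundary rows are pinned, a rigid rotation of the whole
cylinder about its axis is outside the span of the flow. That degree of
freedom is restored up front: the registration first searches all integer
circular shifts of the moving image (with a parabolic refinement to a
fractional shift, kept only when it lowers the SSD) and folds the winning
shift back into the returned fields. Identity inputs short-circuit to zero
displacement exactly.

Default physics follows common fluid-registration practice: $\mu = 1$,
$\lambda_v = 0$ (the $\mu\nabla(\nabla\cdot v)$ coupling remains), step
bound 0.4 nodes per iteration
(a CFL-style limit), regrid threshold 0.5. None of these is stated by the
morphometry literature this pipeline follows; all are `registration_params`
fields.

The *constrained harmonic map* baseline maps rectangle to rectangle with
the loops corresponded proportionally from the common seam anchor; its
displacement components are harmonic with zero boundary data, i.e. the
modulus-matching linear map, computed by the generic grid Laplace solver so
the solver contract (interior residual) is still checked. It is the
feature-blind baseline the fluid method is compared against.

# Morphometry

The registration induces, for every template vertex, a corresponded 3-D
point on the subject surface (template rectangle coordinates pushed through
the forward map and located barycentrically on the subject's
parameterization — so corresponded points lie on the subject surface by
construction). From the correspondence:

* **Jacobian.** Per template face, $J$ is the 2 × 2 linear map taking the
  template face edges to the corresponded edges, both expressed in
  orthonormal tangent frames aligned with the parameter-$u$ direction. This
  frame field is smooth across faces and gauge-consistent between template
  and subject, so the identity correspondence gives $J = I$ exactly and any
  rigid motion of either surface leaves the derived tensors unchanged.
  Vertex Jacobians are area-weighted averages of incident face Jacobians
  (the face-to-vertex rule is unspecified in the literature; averaging is
  the documented choice).
* **Deformation features.** $\det J$ is the areal ratio;
  $S = (J^\top J)^{1/2}$ is the deformation tensor and the statistic is its
  matrix logarithm, vectorized as $(\ell_{11}, \sqrt{2}\,\ell_{12},
  \ell_{22})$ so the Euclidean norm equals the Frobenius norm of
  $\log S$. Vertices with $\det J \le 0$ (excluded by the diffeomorphism
  guard in practice) are flagged, counted and dropped from inference.
* **Medial axis and radial distance.** The medial axis is the centroid
  curve of the iso-parametric circles $u = \mathrm{const}$ on the conformal
  grid; the radial distance $R$ of a vertex is the Euclidean distance from
  its corresponded point to the axis point at the same $u$ level. By
  default the axis is recomputed from the corresponded points
  (subject-side), so $R$ measures the subject's own local thickness at
  corresponding locations; `axis_side = "template"` switches to the
  template axis. The combined statistic appends $R$ to the
  $\log S$ 3-vector.

# Statistics

Age at scan is a confound between preterm and term groups, so each measure
is adjusted per vertex and channel by fitting value $= \beta_0 + \beta_1\,
\mathrm{age} + \beta_2\,\mathrm{group}$ by least squares — keeping the
diagnosis in the design so group signal is not absorbed into the age slope —
and subtracting $\beta_1(\mathrm{age} - \overline{\mathrm{age}})$. Scalar
measures use the pooled-variance two-sample $t$ statistic, squared so the
permutation test is two-sided; vector measures use Hotelling's
$T^2 = \frac{n_1 n_2}{n_1 + n_2}\,\bar{d}^\top \Sigma_{\mathrm{pooled}}^{-1}
\bar{d}$, with a trace-scaled ridge at numerically singular vertices. In
dimension 1 the two coincide to rounding, which the tests assert.

Inference is permutation-based throughout, with one seeded stream reused by
both levels. Without covariate adjustment, group labels are reassigned
without replacement preserving group sizes; when the cohort is small
enough, all distinct splits are enumerated instead (making the p-values
exact). When the age adjustment is active the permutation follows the
Freedman–Lane scheme: the reduced (intercept + age) model is fitted once,
its residual rows are permuted, the full-model adjustment is re-estimated
on each permuted data set, and the statistic is computed with the observed
labels. This matters because age is correlated with group (cases are
scanned younger): naively permuting labels of once-adjusted data leaves the
observed labeling aligned with the adjustment design while the permuted
ones are not, biasing the null distribution; the calibration study
(`calibration_study()`) checks the resulting type-I error directly.
Vertex-wise
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + B)$; map-wise, the
summary per relabeling is the count of vertices with permutation $p$ below
the threshold (default 0.05), and the corrected $p$ compares the observed
count against that null distribution. The CDF-based FDR summary reports the
largest $p_{(i)} \le q\,i/m$ — the highest non-origin crossing of the
empirical CDF of p-values with the line $y = x/q$ — which the tests verify
against the reference step-up rule.

# The synthetic cohort and what it does (not) show

The generator emulates the study conditions: 19 controls aged
$\mathcal{N}(45.1, 5.1)$ weeks versus 17 cases aged $\mathcal{N}(41.1,
5.0)$ weeks. The base shape is a bent superellipsoid with semi-axes
(12.5, 6, 4) mm, exponent 2.5 and a 0.4 rad bend — putamen-like in scale,
elongation and curvature. Each subject adds a smooth random shape field
(white noise on the vertices low-passed by 12 rounds of neighborhood
averaging, amplitude 0.02 of the local centroid distance) along the vertex
normals; group 1 additionally carries the implanted deficit: vertices
within 8 mm geodesic radius of the surface point nearest the
anterior/inferior direction $(1, 0, -1)/\sqrt 2$ are displaced inward along
the normal by $\delta$ times the local scale with a cosine taper
($\delta = 0.1$ by default; $\delta = 0$ gives exchangeable null cohorts).
All parameters live in `cohort_spec()` and every cohort is reproducible
from its seed.

What the synthetic cohorts do *not* emulate: segmentation error and its
spatial correlation structure, inter-subject topology-of-noise differences,
left/right asymmetry, or any real age effect on shape (the age slope
defaults to 0, so the age adjustment is exercised as a no-op plus noise).
Passing the validation studies therefore demonstrates that the machinery is
correct and calibrated on smooth, well-behaved surfaces — not that effect
sizes or p-values transfer to clinical segmentations.

# Validation studies and problem sizes

Two standardized studies are exported and used by both the acceptance tests
and `scripts/acceptance.R`:

* `calibration_study()` — 150 independent null cohorts at the study's group
  sizes, 250 permutations per test, 16 × 16 grids and a 20-iteration fluid
  cap; the map-level rejection rate at $\alpha = 0.05$ is reported per
  statistic. With 150 repeats the binomial standard error of a true 5%
  rate is about 1.8 percentage points. These sizes are the package's
  chosen validation design; larger designs (more repeats, 10,000
  permutations as in full studies) are a matter of passing different
  arguments.
* `effect_study()` — the default deficit cohort (δ = 0.1, 17 vs 19) with
  1000 permutations; reported are corrected p-values, suprathreshold
  counts, and the Dice overlap between each detection map (vertex $p <
  0.05$) and the implanted patch.

# Known limitations

* The rectangle registration inherits the conformal parameterization's
  area distortion; the optional $\lambda$ weighting compensates the force
  magnitude but not the anisotropy of the grid metric.
* The medial axis is the iso-parametric centroid curve, not a true
  medial-surface (m-rep) axis; for strongly bent or branching structures
  the two differ.
* The template is one subject, as in the study design the pipeline
  follows; its own morphometry row is the identity, and template choice
  contributes variance that a group-wise template would remove (out of
  scope here).
* Boundary rows are hard landmarks: correspondence on the cut loops is
  fixed up to the global circular shift, so signal within one ring of the
  cuts is partially constrained.
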