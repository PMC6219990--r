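---
title: "Model-based paraspinal muscle segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based paraspinal muscle segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chemical shift encoding (Dixon) MRI separates the MR signal into water and
fat images; the proton-density fat fraction, `PDFF = 100·F/(F+W)` percent,
measures the fat content of muscle tissue and is a biomarker for muscle
quality. Extracting compartment-wise PDFF of the lumbar paraspinal muscles
(bilateral erector spinae, quadratus lumborum, psoas, typically from the
upper endplate of L2 to the lower endplate of L5) requires a segmentation
of all six compartments, which is prohibitively slow to draw by hand.
`paraseg` implements an automatic model-based segmentation of these
compartments from a water/fat image pair, plus the evaluation and
synthetic-data machinery needed to validate it without patient data.

## Pipeline and model

### Shape model by fuzzy averaging

Training label volumes are rigidly aligned to the first subject by least
squares on the six compartment centroids (`align_training_set()`; rotation
and translation only — the later rigid adaptation stage works in the same
family, and scale differences across subjects are left to the free-form
stage). Each aligned binary compartment mask is converted to a signed
Euclidean distance field (exact separable transform, anisotropic spacing),
truncated at ±10 voxels so distant geometry cannot dominate (a saturating
"fuzzy membership"), averaged voxel-wise across subjects on a common grid
(the padded bounding box of all masks at the finest input spacing), and the
zero level set of the mean field is the average surface.

Surfaces are represented as closed triangle meshes. The default extractor
(`wrap_mesh_to_sdf()`) shrink-wraps a tapered-tube mesh — initialized from
the principal axes and extents of the interior voxels — onto the zero level
set by iterated gradient projection with Laplacian regularization. This
yields well-shaped triangles and a fixed budget of ~1000 triangles per
compartment, inside the 1000–3000 target adopted for the model. A marching
tetrahedra extractor (watertight by construction, exact combinatorial
winding) is available as `method = "marching"` for general label volumes;
it produces grid-resolution meshes and is used where fidelity to an
arbitrary voxel shape matters more than triangle budget.

### Correspondence and the dual-channel feature model

The mean mesh is adapted back to every training subject's labels (rigid
stage then free-form, with a simple gradient feature on the binary mask)
to obtain meshes in per-vertex correspondence. Boundary features are then
trained per triangle and per channel (water, fat) on the native images.
A feature candidate is a polarity-gated (`rising`/`falling`/`either`),
damping-capped central-difference derivative along the outward normal,
zeroed outside an intensity window. The catalogue holds 2 polarities × 5
quantile-based windows × 3 damping levels per channel, damping levels in
decreasing order (0.5/0.15/0.05 of the robust intensity span, minimum to
the 99th percentile).

Candidate selection uses simulated search: profiles are sampled at the true
boundary, and each candidate is scored by its mean absolute detected
boundary position when the search starts from displaced positions (±30 % of
the profile half-length). Scoring is penalty-free (γ = 0): the residual
must reflect the image information a candidate carries, not the
detection-time proximity prior. Residuals are cross-validated across
training subjects — with 30 candidates and a small cohort the in-sample
minimum is optimistically biased on uninformative channels — and the two
channels are combined per triangle with inverse-variance weights
`w_water = r_w^{-2} / (r_w^{-2} + r_f^{-2})`, 0.5 on ties.

### Boundary detection at segmentation time

At each triangle centroid the combined response
`w·resp_water + (1−w)·resp_fat` is evaluated along the outward normal
(profile half-length 10 mm, step 1 mm at the finest level, both doubled
per coarser level). The winning offset maximizes the damping-capped
response minus a distance penalty `γ·offset²`
(`γ = 0.1·cap/L²`); the cap equalizes strong edges so the *nearest
sufficient* edge wins — the robustness role of damping. Because a capped
response is a plateau with no localization information, the boundary is
then localized *inside* the winning saturated run by the uncapped
derivative, with parabolic sub-step refinement. The detection weight is
the capped response normalized by the triangle's combined damping cap, so
weights live in [0, 1] and the shape-deviation weight α has a stable
meaning.

Two numerical choices here deserve emphasis, both found the hard way:

* With capped responses, an "earliest maximum wins" tie rule turns the
  plateau into a position hysteresis — the mesh believes it is on the
  boundary anywhere inside the clipped ramp — which interacts with any
  systematic target correction to produce a steady drift. The two-stage
  capped-select / uncapped-localize rule removes the hysteresis while
  keeping the nearest-edge robustness.
* Raw (unnormalized) response weights make the external energy overwhelm
  the shape prior wherever edges are strong, and the free-form stage
  oscillates; normalization by the damping cap restores the intended
  balance.

### Localization and adaptation

A translation-only generalized Hough transform initializes the model: the
r-table maps quantized directions (12 azimuth × 6 elevation bins) of the
mean-mesh triangle normals to offsets from boundary to model centroid;
voxels whose (fat-image, by default) gradient magnitude exceeds 30 % of the
maximum vote; the accumulator (4 mm cells, padded image bounding box) is
smoothed with a one-cell Gaussian and its peak, refined by the 3³ weighted
centroid, is the position estimate. Rotation and scale are not voted:
supine axial acquisitions are approximately pose-normalized and the rigid
stage absorbs the residual — at the cost of failing on grossly rotated
data, a known limitation.

Adaptation is coarse-to-fine over an image pyramid (×4/×2/×1 with Gaussian
pre-smoothing). The coarsest level serves global pose only: a joint rigid
stage over all six compartments (weighted point-to-plane estimation,
small-angle linearization iterated to convergence). Per-compartment rigid
and free-form stages start at the middle level; the 40 mm coarse-level
search range is unreliable for the small quadratus lumborum compartments.
The free-form energy

`E = Σ_i w_i (n_i·(c_i − t_i))² + α Σ_(j,k) ‖(v_j − v_k) − (m_j − m_k)‖²`

(αs 1.0 / 1.0 / 0.5 from coarse to fine; `m` the mean mesh under the
compartment's current rigid transform) is a sparse positive-definite
quadratic solved exactly (Cholesky) each iteration, so the energy for the
current targets cannot increase within an iteration; the trace records
before/after values per iteration. Stages stop when the mean vertex
displacement drops below 0.05 mm (caps: 20 rigid, 30 free-form iterations
per level).

One tessellation-scale correction matters at the accuracy level this
pipeline reaches: the external term drives triangle *centroids* onto the
detected boundary, but the centroid of a triangle inscribed in a curved
surface sits below it by the sagitta `≈ ρ²κ/2` (ρ the RMS vertex-centroid
distance, κ the local curvature) — 0.2–0.4 mm at the default resolution,
which inflates every convex compartment by a thin shell and, with a
high-PDFF epimuscular rim just outside the boundary, biases compartment
PDFF upward. Targets are therefore pulled inward by a per-triangle sagitta
estimate (face-neighbor secant curvature, calibrated ×1.3 against the
analytic centroid-to-sphere gap, clamped to ±1 mm).

### Evaluation

`dice_coefficient()` (two empty masks define Dice 1, with a warning),
`compartment_stats()` (volumes as voxel count × voxel volume; mean PDFF
over each mask; absolute PDFF difference; missing ground-truth compartments
are flagged `NA`, never silently zeroed) and `wilcoxon_signed_rank()`.
The Wilcoxon test drops zero differences (reporting their count), uses
midranks for ties, and computes the exact two-sided p-value from the full
distribution of the signed-rank sum over all 2^n sign assignments (a
dynamic program over doubled midranks, identical to complete enumeration)
for n ≤ 25, with a tie-corrected normal approximation beyond.
In the cohort summary (`evaluate_cohort()`), the compartment Δ fat
fraction is the difference of the cohort means (mean automatic PDFF minus
mean ground-truth PDFF across the test observations, in magnitude), the
statistic conventionally reported per compartment in cohort tables; the
per-observation absolute differences remain available in the
per-observation output.

## The phantom: what it emulates, what it does not

`phantom_spec()` defaults define the study conditions: the acquisition
grid (72 × 110 × 73 voxels, 3.1 × 2.0 × 3.0 mm), per-compartment PDFF
mean/SD taken from the training-cohort statistics (erector spinae
6.66/6.29 ± ~2, quadratus lumborum 6.44/7.46 ± ~5.5, psoas 4.19/4.04 ±
~3 %), a fat-dominant background (85 %), a 3 mm epimuscular rim at 70 %
PDFF, smooth random anatomy deformation (5 mm RMS on a 40 mm control
grid), small per-time-point rigid pose changes (≤3°, ≤5 mm — the
longitudinal repositioning of a supine subject), and 3 % Gaussian channel
noise. The template holds six closed tapered elliptical tubes in a
bilaterally symmetric arrangement with volumes in the cohort's proportions
(≈ 241 : 45 : 120 cm³ per side-pair class). Each subject is one anatomy
(deformation + PDFF draw); time points share the anatomy and differ in
pose and noise. All randomness derives from one seed; identical seeds give
bit-identical volumes.

Deliberate simplifications: no vertebrae or intervertebral discs, no
intramuscular fat texture (compartments are homogeneous up to noise), no
B0/B1 artifacts, no Rician noise floor, sharp (non-partial-volume) tissue
boundaries, and channel noise clamped at zero because magnitude images are
nonnegative. The clamping rectifies the noise where the fat signal is
within ~2 SD of zero, so recomputed compartment PDFF carries a small
positive bias (up to ~0.5 % at the lowest compartment PDFFs) relative to
the drawn value — as real magnitude data would. Passing tests on this
phantom demonstrate the pipeline's geometric and numerical correctness and
its behavior under the study's nominal contrast; they do not demonstrate
robustness to pathology, atrophic muscles, field inhomogeneity or
inter-protocol variation.

Ground truth equals the voxelization of the generating mesh — the exact
muscle boundary. A human operator drawing conservatively *inside* the
visible boundary produces systematically smaller reference masks; an
accurate algorithm therefore *overestimates* volume relative to human
ground truth while matching the phantom's exact ground truth closely. The
mesh-shrinking remedy for epimuscular fat inclusion is provided
(`shrink_mesh()`, inward vertex-normal offset in ≤1 mm steps with
smoothing), and its effect is testable on the phantom, but the
human-operator volume gap itself has no phantom counterpart.

## Problem sizes and numerical defaults

The test suite and the acceptance script run the full study at its native
scale: 10 subjects × 2 time points at 72 × 110 × 73, training on 7
subjects, segmenting 6 held-out observations (a few minutes on one CPU);
unit tests use the same fields of view at half resolution. Signed
distances are exact (no truncation except the fuzzy ±10 voxel saturation);
the sparse free-form systems (~2000 unknowns per compartment) are solved
direct; voxelization uses x-ray parity with inclusive fills (boundary
voxel centers count as inside) and ray origins carry a fixed sub-voxel
offset so rays essentially never graze mesh vertices; marching tetrahedra
snaps field values equal to the iso level by 1e-9 to avoid degenerate
triangles.
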