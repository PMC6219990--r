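# paraseg

Automatic segmentation of the six lumbar paraspinal muscle compartments —
right/left erector spinae, quadratus lumborum and psoas — in chemical shift
encoding-based water/fat-separated MRI, with quantification of the
proton-density fat fraction (PDFF) inside each compartment.

Muscle PDFF, the fat signal as a fraction of the total signal
`PDFF = 100 · F / (F + W)`, is a quantitative imaging biomarker of muscle
quality in disc disease, osteoporosis, sarcopenia and neuromuscular
disorders. Its clinical use is limited by the cost of manual segmentation;
this package implements a fully automatic, model-based pipeline and the
tooling to validate it.

## Method

The segmentation engine is a multi-compartment deformable surface model:

* **Shape model.** Training label volumes are rigidly pose-normalized
  (least squares on the six compartment centroids) and fuzzy-averaged:
  each binary compartment mask becomes a truncated signed-distance field,
  the fields are averaged on a common grid, and the zero level set of the
  mean field is extracted as the average compartment surface (a closed
  triangle mesh, ~1000 triangles per compartment).
* **Dual-channel feature model.** Every surface triangle is associated with
  an edge detector on the water *and* the fat image: a polarity-gated,
  damping-capped directional derivative restricted to an intensity window.
  Candidates are selected per triangle by simulated search — sampling
  profiles at the true boundary of the training subjects and scoring each
  candidate by its boundary localization error from displaced starting
  positions — and the two channels are combined with inverse-variance
  weights.
* **Localization.** A translation-only 3-D generalized Hough transform:
  strong image-gradient voxels vote with the r-table offsets of their
  quantized gradient direction; the smoothed accumulator peak initializes
  the model position.
* **Adaptation.** Coarse-to-fine (image pyramid ×4/×2/×1): a joint rigid
  stage, then per compartment a rigid stage followed by free-form
  deformation minimizing
  `E = Σ_i w_i (n_i · (c_i − t_i))² + α Σ_(j,k) ‖(v_j − v_k) − (m_j − m_k)‖²`,
  the weighted point-to-plane match of triangle centroids `c_i` to detected
  boundary targets `t_i` plus an edge-vector deviation penalty against the
  rigidly transformed mean shape `m`. The sparse normal equations are
  solved exactly per iteration.
* **Evaluation.** Dice overlap, compartment volumes (cm³), mean PDFF and
  paired exact Wilcoxon signed-rank tests, reported per compartment as in
  a standard cohort table.

Because no patient data ship with the package, a synthetic water/fat
phantom generator (`phantom_spec()`, `generate_cohort()`) emulates the
acquisition geometry (72×110×73 voxels at 3.1×2.0×3.0 mm), realistic
per-compartment PDFF statistics, a fat-dominant background, an epimuscular
fat rim, smooth anatomy deformation, per-time-point pose and channel noise
— making the entire pipeline testable end to end.

## Worked example

```r
library(paraseg)

spec   <- phantom_spec()                       # study-protocol defaults
cohort <- generate_cohort(spec, n_subjects = 10, time_points = 2, seed = 42)

train <- unlist(lapply(cohort$split$train,
                       function(s) cohort$subjects[[s]]), recursive = FALSE)
model <- train_model(train)

obs <- cohort$subjects[[8]][[1]]               # a held-out observation
res <- adapt(model, obs$water, obs$fat)
lab <- voxelize(res$mesh, vol_geometry(obs$labels))
pdff <- compute_pdff_map(obs$water, obs$fat)
compartment_stats(obs$labels, lab, pdff)[, c("name", "dice", "gt_pdff", "as_pdff")]
#>                       name      dice   gt_pdff   as_pdff
#> 1     right_erector_spinae 0.9914722  4.578185  4.786709
#> 2      left_erector_spinae 0.9895422  5.306327  5.612799
#> 3 right_quadratus_lumborum 0.9918602  3.981148  4.274761
#> 4  left_quadratus_lumborum 0.9849575 11.303117 11.767237
#> 5              right_psoas 0.9889640  4.009252  4.407728
#> 6               left_psoas 0.9903351 10.668038 11.119277
```

`dice` is the overlap of the automatic mask with ground truth (1 = exact);
`gt_pdff`/`as_pdff` are mean compartment PDFF in percent over the
ground-truth and the automatic mask — their difference is the error a
clinician would incur by trusting the automatic contours.

A disk-based workflow (`cmd_simulate`, `cmd_train`, `cmd_segment`,
`cmd_evaluate` with a YAML configuration) and a command-line wrapper
(`inst/cli/paraseg.R`) are also provided.

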