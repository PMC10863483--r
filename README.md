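# glenoidbl

Semiautomated quantification of anterior glenoid bone loss and bony shoulder
stability from CT segmentations, in R.

Anterior shoulder instability erodes the anterior glenoid rim, and the size
of the bony defect decides between soft-tissue repair and bony
reconstruction. Starting from a scapula/humerus label map (NIfTI or NRRD) or
a bone surface mesh (PLY/STL), `glenoidbl` computes the three standard
CT measurement families deterministically:

* **Linear (1D)** — a best-fit circle (BFC) on the inferior glenoid rim,
  which anterior defects spare; bone loss is the defect diameter over the
  BFC diameter: `100 · defect / (2R)`.
* **Area (2D)** — the defect area over the BFC area (surface/PICO method),
  computed by projecting the glenoid contour onto the BFC plane and clipping
  it against the circle.
* **Concavity (3D)** — the bony shoulder stability ratio (BSSR) from the
  glenoid concavity's depth `d` and chord `c` over 10 parallel cross-section
  cuts, using a circular-arc model: radius of curvature
  `r = (d² + (c/2)²) / (2d)`, rim angle `α = asin(c / (2r))`,
  `BSSR = 100 · tan(α)` — the tangential force the bony socket can resist
  relative to the compressive load (concavity compression).

The pipeline is the programmatic counterpart of an interactive clinical
workflow: surface extraction from the label map (anti-aliased marching
tetrahedra), articular-region isolation by distance to the humeral head (or
seeded, crease-bounded growth; or an explicit vertex mask), a
principal-component anatomical frame, a posteroinferior-rim circle fit
(algebraic start, damped Gauss–Newton refinement), contour projection, and
parallel-cut concavity analysis. Manual refinement is modelled as override
hooks (circle, region mask) recorded in the report's provenance.

The package also ships the reliability statistics used to validate such
pipelines — ICC(A,1) (two-way random, absolute agreement, single measures)
with F-based 95% confidence intervals, Landis–Koch interpretation, rater
averaging, and Kolmogorov–Smirnov-gated paired t / Wilcoxon comparisons —
and a synthetic glenoid **phantom generator** with closed-form ground truth
(spherical-cap concavity, pear-shaped outline, chord-like anterior defect,
seeded surface jitter, CT-like voxelization at 0.625 mm), so every stage is
validated without patient data.

## Worked example

Generate a phantom with a known anterior defect (BFC radius 12.5 mm,
concavity depth 2 mm, chord defect 8.5 mm from the centre — true linear loss
16.0%, true area loss 10.3%) and measure it:

```r
library(glenoidbl)

ph <- generate_phantom(phantom_spec(defect_offset_mm = 8.5))
m <- measure_glenoid(
  ph$scapula, ph$humerus, side = "left",
  orientation_hint = list(superior = c(1, 0, 0), anterior = c(0, 1, 0)),
  config = run_config(max_distance = 0.3)  # congruent phantom joint space
)
m
#> glenoid measurement
#>   BFC: diameter 25.00 mm, area 490.87 mm^2 (fitted)
#>   1D: defect 4.00 mm, bone loss 16.0%
#>   2D: defect 50.73 mm^2, bone loss 10.3%
#>   3D: depth 1.64 mm, chord 25.00 mm, BSSR 26.7%
```

The BFC radius, the 1D ratio and the 2D ratio (closed form 10.33%) are
recovered essentially exactly. The 3D depth illustrates a genuine property
of the method: an anterior defect tilts the PCA frame's normal axis by a few
degrees, which shifts the supporting-line depth (on the intact phantom the
same pipeline recovers the mean depth within 0.5% and BSSR 32.7% vs the
analytic 32.8%). See the methods vignette
(`vignettes/glenoid-bone-loss-methods.Rmd`) for the model, parameter
defaults, and known limitations.

Reports, reliability tables and comparisons:

```r
write_report(m, "report.json")      # full metrics + provenance, stable keys

tab <- reliability_table(read_ratings_csv("ratings.csv"))  # per-parameter ICC
res <- compare_paired(manual_values, automated_values)     # gated t/Wilcoxon
```

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/glenoid_tool.R", package="glenoidbl"))') \
  measure --volume labels.nii.gz --side left --out report.json
```

(commands: `measure`, `phantom`, `reliability`, `compare`).

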