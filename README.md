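# facepatches

A hierarchical computational model of primate face processing, after
the organisation of the macaque face-patch system, together with the
representational-similarity statistics and behavioural-effect analyses
used to probe it. The package is for computational and cognitive
neuroscientists who want a compact, fully reproducible implementation
of the view-to-identity transformation story: generic features
(posterior patch) feed view-tuned units (middle patches) which are
bound across views into identity-tuned units (anterior-medial patch)
by temporal continuity.

## The model

* **S1/C1** — Gabor simple cells (4 orientations, 8 sizes in 4 scale
  bands) with local max pooling: edge energy, tolerant to small shifts.
* **S2/C2** — radial-basis templates over C1 patches,
  `R = exp(-γ‖x̂ − P‖²)`, with global max pooling: part-based face
  features (1000 prototypes at full scale, 200 in the desk-scale
  configuration).
* **VSL** — view-selective units, Gaussian in C2 space
  (`g_i = exp(-‖x − P_i‖²/2σ²)`, σ = 0.5) with an additive trace
  (α = 0.3), grown under an adaptive-resonance vigilance rule (ρ = 0.9):
  an input matched below ρ by every unit becomes a new template.
* **ISL** — identity-selective units that max-pool disjoint sets of VSL
  units through binary weights wired by a trace rule: a newborn VSL unit
  joins the ISL unit still active from the previous view, so an
  identity's views converge onto one unit; blank images between
  identities silence the traces and start a fresh unit.

Training presents identities sequentially (random start view, then the
5°-step sweep with wrap-around, then a blank), and each identity's new
units are kept only if the view-invariant identity selectivity index
(VISI) on a held-out evaluation set improves.

A bundled parametric generator replaces the photographic multi-view
face sets: 11-parameter synthetic identities from two populations
("races"), rendered across the 37-view yaw grid with smooth
view-to-view appearance change, plus inverted, in-plane-rotated,
aperture-masked and composite (aligned/misaligned) variants.

## A worked example

```r
library(facepatches)

train <- lapply(1:20, function(i) sample_identity(1000 + i, "A"))
eval  <- lapply(1:10, function(i) sample_identity(2000 + i, "A"))
model <- train_model(train, eval, model_config(), seed = 1)
model
#> <face_model> 518 VSL units, 14 ISL units, 200 prototypes

test <- lapply(1:10, function(i) sample_identity(3000 + i, "A"))
ev <- evaluate_model(model, test, seed = 1)
ev$visi; ev$accuracy
#> [1] 5.27   # same-identity cross-view similarity ~5x the background
#> [1] 0.547  # cross-view SVM identification accuracy, chance 0.10
```

A VISI well above 1 says that different views of one face evoke much
more similar ISL patterns than different faces do — the signature of a
view-invariant identity code; the same features identify novel faces
across views far above chance.

The behavioural experiment battery (representational geometry,
canonical views, inversion, in-plane rotation, composite faces,
other-race effect) is driven by `run_experiment()` /
`run_study()`, or from a shell:

```sh
Rscript inst/cli/facepatches.R generate-data --n 20 --seed 1 --out data/
Rscript inst/cli/facepatches.R train --n-train 20 --seed 1 --out model.json
Rscript inst/cli/facepatches.R run --experiment composite --out results/
Rscript inst/cli/facepatches.R report --dir results/
```

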