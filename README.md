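# moodmap

Unsupervised classification and visualization of mood states from
psychometric and behavioral signals.

`moodmap` is aimed at affective-computing and mental-health-informatics
work where repeated, low-burden measurements — a mood questionnaire, an eye
tracker, a camera — are collected over weeks and the goal is to *see*
structure in a cohort's mood states without ground-truth labels. It
implements a complete pipeline:

1. **Psychometrics.** POMS2 component scores (AH, CB, DD, FI, TA, VA, F)
   are reduced to two indicators: total mood disturbance
   `TMD = AH + CB + DD + FI + TA − VA` (vigor enters inverted) and
   friendliness `F`, both standardized to T-scores
   (`50 + 10·(x − x̄)/s`, sample sd with the n−1 denominator).
2. **Self-organizing map (SOM).** A from-scratch online SOM on a J×K
   rectangular lattice (defaults 50×50). The winner unit for input `x` is
   `c = argmin_{j,k} Σ_i (x_i − w_ijk)²`; all units in a square
   neighborhood of radius `ψ(t) = ⌊ψ(0)(1 − t/O) + 0.5⌋` around the winner
   move by `w ← w + α_t (x − w)` with `α_t = α₀(1 − t/O)`; defaults
   `α₀ = 0.1`, `ψ(0) = 40`, `O = 200` epochs. The hot loop is compiled
   (Rcpp); all RNG stays on the R side, so runs are bit-reproducible.
3. **U-Matrix.** Per-unit boundary depth from squared distances to lateral
   neighbors and averaged diagonal cross-pairs; thresholding at a quantile
   plus 4-connected components yields a category segmentation, and each
   category is tagged positive / neutral / negative from its members' mean
   TMD and F against configurable decision boundaries (defaults 51 and 52
   T-points).
4. **Recurrent SOM (RSOM).** A 15-unit chain with leaky two-step
   activations `y(t) = β₁y(t−1) + β₂y(t−2) + β₃(x_t − w)` (defaults
   0.5, 0.2, 0.3) extracts smile-expression frames from facial time
   series; the per-session smile count is the fusion feature `R`.
5. **Growing hierarchical SOM (GHSOM).** Organizes the 15 RSOM prototypes
   into a tree of small maps: a map grows laterally while its mean
   quantization error `v_m` exceeds `T_m` (default 0.08) times the parent
   deviation, and units still above threshold spawn fresh 2×2 child maps.
   The leaf count is the fusion feature `G`.
6. **Gaze features.** Velocity-threshold saccade detection (`S`) and
   Gaussian-kernel gaze heatmaps with a quantile-based extent count (`E`).
7. **Fusion.** Input patterns TMD+F, I (+E,S), II (+R,G), III (all six),
   z-scored per column, feed the SOM/U-Matrix visualization.

Because the study data this emulates is not public, the package ships
seeded generators for every signal (20-subject weekly cohort with five
planted mood clusters, fixation/saccade gaze traces, trapezoidal
smile-tempo cycles with ground truth), so the whole pipeline is testable
end to end.

## Worked example

```r
library(moodmap)

co   <- generate_cohort(cohort_spec(seed = 1))   # 120 session records
pts  <- mood_points(co$scores)                   # TMD, F in T-scores
head(pts, 3)
#>   subject_id session      TMD        F
#> 1          A       1 34.51145 63.73524
#> 2          A       2 37.51393 64.57729
#> 3          A       3 38.36445 63.24441

X    <- assemble_features(pts, "TMD_F")
grid <- som_train(X, train_config(seed = 2))     # 50x50, 200 epochs
seg  <- segment_categories(compute_umatrix(grid), grid, 0.80)
seg  <- assign_semantic_labels(seg, pts, bmu_assign(grid, X))
seg$summary
#>   category   n mean_TMD   mean_F      tag
#> 1        1 113 50.43708 49.67102  neutral
#> 2        2   6 42.20561 55.67462 positive
#> 3        3   0       NA       NA  neutral
#> 4        4   1 47.37592 53.12727 positive
```

Low-TMD/high-F categories read as positive mood, high-TMD/low-F as
negative. (At the default 0.80 boundary quantile the deepest walls
dominate and most sessions stay in one component; see the vignette's
discussion of boundary-quantile behavior.)

```r
sq  <- generate_smile_sequence(smile_spec(seed = 3))   # 8 tempo cycles
map <- rsom_train(sq$features, rsom_config(seed = 4))  # 15 units
sm  <- extract_smiles(sq$features, map)
sm$R                                  # 283 smile frames out of 720
mean((seq_along(sq$gt) %in% sm$smile_frames) == sq$gt) # 0.929 vs GT

tree <- build_tree(map$W, seed = 5)   # GHSOM over the 15 prototypes
tree$G                                # leaf clusters
```

A full run (`run_pipeline(run_config(pattern = "III", out_dir = "out"))`)
writes the fusion matrix (CSV), U-Matrix (CSV + PNG), segmentation and
per-category report (JSON) and a reproducibility manifest.

A command-line interface with `simulate`, `score`, `features`, `smiles`,
`ghsom`, `map` and `run` verbs is installed at
`system.file("cli", "moodmap.R", package = "moodmap")`.

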