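---
title: "Mood-state maps: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mood-state maps: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `moodmap`, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the method left room.

## The problem

Chronic stress shifts mood slowly. A practical monitoring setup collects,
weekly, (a) a POMS2 mood questionnaire, (b) eye-tracking during a
communication task, and (c) facial video of repeated intentional smiles.
None of these carry ground-truth labels, so the analysis is unsupervised
throughout: sessions are embedded, clustered into categories on a
self-organizing map, and the categories are read semantically
(positive / neutral / negative) from their mood scores.

## Psychometrics

POMS2 yields seven component scores per session. Total mood disturbance is
the fixed linear combination

$$\mathrm{TMD} = AH + CB + DD + FI + TA - VA,$$

with vigor--activity inverted; friendliness $F$ is kept as an independent
second indicator. Both are expressed as T-scores,
$50 + 10\,(x - \bar x)/s$ with the $n-1$ sample standard deviation.

Decisions taken here:

* **Self-normalization by default.** Published norm tables for POMS2 are
  proprietary, so T-scores are computed against the loaded dataset's own
  mean and sd; external $(\mu, \sigma)$ pairs are accepted for
  norm-referenced use (`t_score(raw, norm = c(mean, sd))`).
* **Raw-then-standardize order.** TMD is computed from raw component
  scores and then T-scored. The alternative (T-score each component, then
  sum) is available via `mood_points(order = "t_then_sum")`; on realistic
  data the two orders agree to rank correlation > 0.95.
* The semantic decision boundaries default to 51 T-points (TMD) and 52
  (F); the normative means they were observed against (55 and 49) are not
  hard-coded anywhere.

## The SOM core

Online training on a $J \times K$ lattice (defaults $50 \times 50$) of
$I$-dimensional weights:

* winner: $c = \arg\min_{j,k} \sum_i (x_i - w_{ijk})^2$, ties broken to
  the smallest $(j, k)$;
* square (Chebyshev) neighborhood of radius
  $\psi(t) = \lfloor \psi(0)(1 - t/O) + 0.5 \rfloor$, clipped at the
  edges — there is deliberately **no** kernel weighting, matching the
  plain update $w \leftarrow w + \alpha_t (x - w)$;
* $\alpha_t = \alpha_0 (1 - t/O)$, defaults $\alpha_0 = 0.1$,
  $\psi(0) = 40$, $O = 200$ epochs; every epoch presents all samples once
  in a seeded shuffled order; weights initialize uniformly in the
  per-dimension data range.

As printed in its source, the neighborhood schedule carried an extra
factor of $J$, which with $\psi(0) = 40$ and $J = 50$ would give radii
of ~2000 units on a 50-unit-wide lattice; the only reading consistent
with the published defaults is plain linear decay from $\psi(0)$, which is
what `neighborhood_extent()` implements.

The training loop is compiled (Rcpp). All randomness — weight
initialization and per-epoch presentation orders — is drawn on the R side
and passed in, so a seed fully determines the result, and squared
distances accumulate in extended precision so winner decisions agree
bit-for-bit with the R-side reference operations (`find_bmu`,
`update_weights`), which the tests replay against the compiled loop.

## U-Matrix and category segmentation

For each unit the squared Euclidean distances to its available neighbors
are aggregated: four lateral components, and for each diagonal the average
of the two distinct cross-pair squared distances
$\tfrac12\|w_{j,k}-w_{j\pm1,k\pm1}\|^2 +
\tfrac12\|w_{j\pm1,k}-w_{j,k\pm1}\|^2$ (the printed form of the diagonal
term repeats one cross-pair twice; we read that as a typo and use the
standard treatment). The per-unit value is the mean of available
components — interior units have eight, edges fewer. High values are deep
category boundaries; the display convention renders deep boundaries dark
(`render_umatrix(invert = TRUE)`).

The source study drew category boundaries *by hand*. For reproducibility
`segment_categories()` replaces that with an algorithmic rule: units above
the `threshold_quantile` (default 0.80) of U values are boundary walls,
the rest form 4-connected components, and wall units are absorbed into the
adjacent component with the nearest weight.

**Known behavior of the default quantile.** On a 2500-unit map carrying
~120 sessions, inter-cluster gaps occupy wide bands of units, and squared
distances make the U distribution heavy-tailed. The deepest one or two gap
bands therefore consume most of the top-20% boundary budget, shallower
walls between adjacent categories do not always close, and small noise
pockets inside clusters (a side effect of the kernel-free square-
neighborhood updates) can add spurious components. In our five-cluster
synthetic world the default quantile recovers the five categories only on
a minority of seeds (five components appear reliably near quantile
0.60–0.65). We keep 0.80 as the documented default and state this
limitation rather than calibrating the value to the synthetic world; the
package's own acceptance suite leaves the corresponding criterion red with
this analysis.

## Recurrent SOM and smile extraction

Facial frames arrive as feature vectors (Gabor features of 160×160
grayscale images, or synthetic vectors). The RSOM is a 15-unit chain — 15
prototypes is the fixed granularity of the expression-chart representation
the study built on — with leaky two-step activations

$$y(t) = \beta_1 y(t-1) + \beta_2 y(t-2) + \beta_3 (x_t - w),$$

defaults $(\beta_1,\beta_2,\beta_3) = (0.5, 0.2, 0.3)$; the winner
minimizes $\|y(t)\|^2$. As printed, the recursion had $y(t)$ on both
sides; we read it as the second-order recursion above. The printed weight
update multiplies $(x - w)$ elementwise by the activation vector, which is
dimensionally unstable; we implement the intent — an activation-gated
step — as $w \leftarrow w + \gamma_t (x - w)\,\|y\|/(1 + \|y\|)$, which
preserves "stronger activation, larger step" while bounding the gain
below 1. A plain SOM-rule update (`update = "som"`) exists, and with
$\beta = (0, 0, 1)$ the model then reproduces the static SOM trajectory
exactly (the suite checks unit-for-unit agreement). The chain
neighborhood radius (default 1) shrinks on the same linear schedule as
the static SOM.

Smile-frame extraction assigns every frame to its winner, splits the 15
prototypes by 2-means (initialized at the most distant prototype pair, so
deterministic), and calls the group farther from the sequence's
per-dimension **median frame** the smile group. This anchor assumes the
expressionless state dominates the recording, which holds for repeated
intentional-smile protocols and for the generator's defaults. Residual
errors concentrate at ramp frames, where the leaky memory lags the
intensity crossing; accuracy on default synthetic tempo cycles is ~93%.

## GHSOM

The hierarchy starts from a single virtual unit at the input mean with
deviation $v_0$ (mean Euclidean distance of inputs to their prototype —
the printed formula sums unsquared coordinate differences over all units,
which we read as intending the quantization error actually needed by the
growth test). One 2×2 map trains on all inputs and grows while
$v_m / v_\text{parent} > T_m$ (default 0.08): the error unit $u_e$ is the
one with maximal assignment deviation; the dissimilar unit $u_d$ is, per
the method's literal wording, the *lateral neighbor with minimal
deviation* (the standard-GHSOM alternative — most dissimilar weight — is
available via `ud_rule = "max_weight_distance"`); a full row or column of
units is inserted between them with weights interpolated from the flanking
units, keeping the lattice rectangular; the map retrains and reassigns.
Units whose own assignment deviation still exceeds the threshold spawn
fresh 2×2 child maps on their inputs. "At most four categories per layer"
is implemented as at most four growth insertions per layer map (a 2×2 map
can reach 4×4 = 16 units), which keeps five- or six-cluster first layers
representable, as observed structures require. The ratio's denominator is
the parent *unit's* assignment deviation (the global $v_0$ for the first
layer) — the printed text is ambiguous between parent unit and parent map.

On near-continuum inputs (e.g. RSOM prototypes of a smooth
intensity cycle) the fixed ratio threshold resolves structure at every
scale and can split down to singleton leaves; this is the model behaving
as specified, not an error, but it makes the per-session leaf count `G`
a coarse feature.

## Gaze features

Saccades are detected by a velocity threshold (default 1000 px/s) on
point-to-point speeds of valid samples; maximal above-threshold runs
bounded by fixation samples count once, and runs separated by fixations
shorter than 100 ms merge. The extent feature `E` counts heatmap cells
above the 0.90 quantile of nonzero density, where the heatmap is a
mass-preserving separable Gaussian blur (σ = 20 px) of binned valid
samples on a 192×108 cell grid. All gaze processing stays in screen
pixels; no degree conversion is attempted. `E` is defined operationally
and used only comparatively.

## What the generators emulate — and what they do not

* `generate_cohort()`: 20 subjects, half measured 4 and half 8 weeks (120
  sessions), each subject anchored to one of five mood clusters placed so
  two read positive, one neutral, two negative, with the mixture centered
  near (50, 50) and spread near 10 so self-normalized T-scoring
  approximately preserves the layout. Within-cluster sd defaults to 2
  T-points, putting adjacent centers ≥ 4 sd apart — the "well-separated
  categories" regime the recovery properties assume. Components are
  decomposed so the TMD identity holds exactly (VA solved last,
  non-negative by resampling).
* `generate_gaze()`: alternating fixations (white Gaussian jitter, default
  2 px — small enough that implied speeds stay far below the saccade
  threshold) and instantaneous jumps of at least 60 px; a 3-sample
  ballistic profile is available for threshold-sensitivity checks.
* `generate_smile_sequence()`: trapezoidal intensity cycles
  (rest–rise–plateau–fall; defaults 45% rest, 25% plateau), features =
  base + intensity·direction + noise, or parametric 160×160 face renders
  for the image path; ground truth is intensity > 0.5.

They are *structural* stand-ins: cluster coordinates, behavioral
tendencies per cluster (concentrated gaze / fewer saccades / steadier
smiles for positive moods) and noise levels are package constants, not
measured values. A green test therefore establishes that the pipeline
recovers planted structure of the stated shape — not that real cohorts
have that shape. Real facial data, head pose, blinks, tracker dropout
patterns and photorealistic appearance are out of scope; face detection is
expected to happen upstream (inputs are pre-cropped or synthetic).

## Numerical and degenerate-input choices

* Ties in winner search and in GHSOM unit selection break to the smallest
  lattice index; 2-means initialization is the most distant prototype
  pair — no hidden randomness anywhere.
* `t_score()` refuses constant input (sd = 0) and fewer than 2 values.
* A constant face sequence makes smile extraction degenerate; it is
  flagged (`degenerate = TRUE`) rather than guessed.
* `should_grow()` returns `FALSE` for a perfectly quantized parent
  (`v_parent = 0`), terminating growth.
* Derived child seeds stay below $2^{31}$; every generator restores the
  caller's RNG state.

## Limitations

* The boundary-quantile limitation described above is the main known gap
  between the implementation and the headline five-category behavior.
* Eq-level ambiguities of the source (neighborhood factor, recursion
  order, activation-gated update, deviation formula, diagonal term) are
  resolved as documented here; each has a test pinning the chosen reading.
* The RSOM smile/neutral split assumes a rest-dominated recording; for
  smile-dominated footage supply a labeled calibration frame instead of
  relying on the median anchor.
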