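---
title: "plumfw: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plumfw: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumfw)
```

## The problem and the model

A plum's fresh weight FW (g) is tightly determined by its two top-view
dimensions — maximum length $L$ and maximum equatorial diameter $D$ (mm) —
because fruit density and the third axis vary little within a genotype.
`plumfw` implements the full chain from a single-fruit photograph to a
weight estimate, and an evaluation harness to compare estimators.

The allometric family at the core is

$$\mathrm{FW} = a + b\,f(L, D), \qquad
  f \in \{LD,\; L^3,\; D^3,\; LD^2,\; L^2D\},$$

fitted by exact least squares (for a single basis function the
RMSE-minimizing fit is the closed-form simple regression, which is what
`fit_form()` computes; an oracle test checks it against a brute-force grid
minimizer). Alongside it: multiple linear regression
$\mathrm{FW}=\beta_0+\beta_1 L+\beta_2 D$, $\varepsilon$-SVR with three
kernels, a one-hidden-layer perceptron, and an M5-style model tree. All
learners consume the same record format (`length_mm`, `diameter_mm`,
`weight_g`) and share `predict(model, newdata)`.

## The synthetic world

No fruit-level dataset is publicly deposited for this problem, so the
package's generator *is* the data source for all tests. A cohort spec
(`cohort_spec()`) states, per genotype: truncated bivariate-normal moments
and bounds for $(L, D)$, their correlation `rho_LD`, and a generating law
$\mathrm{FW} = a + b f(L,D) + \mathcal N(0, \sigma)$ clipped below at a
small positive floor.

Choices worth knowing:

* **Published moments as population values.** The five built-in specs
  (`plum_cohort_specs()`) use the published per-genotype means, dispersions
  and min/max as the truncated-normal parameters. The published dispersion
  column is labelled "SE" but is treated as a standard deviation: a true
  standard error of the mean at $n \approx 500{-}1000$ would be an order of
  magnitude smaller than the printed 1.2–2.6 mm.
* **`rho_LD = 0.8` by default.** The source reports strong significant
  $L$–$D$–FW correlations as heat maps without printed coefficients; 0.8 is
  a realistic within-genotype dimensional correlation and is configurable.
* **Generating laws from the published best fits.** The 2019 development
  cohort uses $\mathrm{FW} = 0.0225\,(L\times D) - 4.4940$ with
  $\sigma = 0.5$ g; the 2021 cohorts use their published $L D^2$ laws with
  $\sigma$ equal to the published training RMSE of those fits. Note a
  consequence: the five cohorts do *not* share one physical allometry, so
  transferring the 2019 model to, e.g., the small-fruited Jangali cohort
  shows honest bias; same-law transfer behaviour is what the transfer tests
  assert.
* **Truncation by rejection** with a budget of 1000 draws per record;
  exhausting it signals infeasible bounds rather than looping forever.
* **Rendering.** Fruits are rasterized as (super)ellipses with
  hue-class-dependent colour (green/yellow/red), radial shading, optional
  smooth illumination gradient and additive Gaussian sensor noise, on a
  near-white matte background (`background_gray = 0.92`), default
  0.2 mm/px on a 256×256 px frame. The manifest carries the exact
  rasterized mask, so segmentation accuracy (IoU) and dimension round-trips
  are measured against ground truth, not against another estimate.

What a green test does **not** establish: real orchard images have shadows,
specular highlights, stems, calyx remnants, non-elliptical outlines and
textured backgrounds. The renderer deliberately models none of these (the
superellipse exponent is the only shape-robustness dial), so passing
round-trips validate the algorithmic chain, not field robustness.

## Segmentation and morphometry

* RGB → CIELAB uses `grDevices::convertColor` under the sRGB/D65
  convention (the capture device is a consumer smartphone; no other
  convention is stated anywhere).
* K-means runs on $(a^*, b^*)$ only; excluding $L^*$ is what makes the mask
  insensitive to smooth lighting changes (a property test multiplies the
  image by a 30% gradient and allows ≤ 2% mask-area change).
  Initialization is farthest-point completion from a seeded random pixel,
  with `nstart = 5` deterministic restarts keeping the lowest
  within-cluster sum of squares — a single start can land in a local
  optimum on small instances, which would violate the exhaustive-search
  equivalence the tests demand on tiny images. Assignment ties break
  toward the lower cluster index; the iteration cap is 300.
* The cleanup operator is standard morphological **opening**
  (erosion→dilation) with a disk of radius 5 px. The source text glosses
  opening as "dilation followed by erosion", which literally describes
  closing; both are exposed via `refine_mask(operation=)` and opening is
  the default, matching the named operator and the cited `imopen`
  behaviour.
* Hole filling marks background components not connected to the border;
  afterwards the largest 8-connected component is retained (single-fruit
  scenes are assumed; the rule is made explicit here).
* "Equatorial diameter" is formalized as the foreground extent
  perpendicular to the moments-derived major axis, measured on pixel
  centers with a +1 px end-correction (an $n$-pixel run has extent $n$).
  For near-circular masks the orientation is degenerate and falls back to
  the image axes; `length_mm >= diameter_mm` is enforced by axis swap. For
  convex, near-elliptical fruit this coincides with the maximum Feret
  diameter, which is why the cheaper moments-based definition is used.
* The calibration square's side is estimated as the mean of its
  bounding-box row and column extents after midpoint thresholding;
  `mm_per_px = 10 / side_px`. Anti-aliased edges bias this by < 2%.

## The learners: tunable parameters and numerics

**ε-SVR** (`fit_svr()`): the dual is solved by a compiled SMO solver
(LIBSVM-style 2n formulation, maximal-violating-pair working set, KKT gap
tolerance `tol = 1e-6`, iteration cap 2e6, hard error on non-convergence).
Features are min-max normalized to $[0,1]$ internally — the convention of
the widely used reference implementation whose PUK defaults
($\omega = \sigma = 1$) this package adopts; those defaults are calibrated
to that scale, and on z-standardized features they make the kernel ~6×
too narrow and the model overfits. The target stays in grams, so
`epsilon = 0.001` is a 1 mg insensitive tube. The PUK kernel is

$$k(u,v) = \Big[1 + \big(2\sqrt{2^{1/\omega}-1}\,\lVert u-v\rVert /
\sigma\big)^2\Big]^{-\omega},$$

RBF uses `gamma = 1/(2d)` with $d = 2$ features, and "2D polynomial" is
read as the degree-2 kernel $(u\cdot v + 1)^2$. The grid
(`grid_search_svr()`) crosses the three kernels with $c \in \{0.1, 1,
10\}$ and selects by 10-fold cross-validated RMSE; per-cell solver
failures are recorded in the report, not fatal. Correctness is checked
against a dense QP oracle (multi-start SLSQP with tight tolerances) on
tiny instances and by PSD checks of the kernel matrices.

**MLP** (`fit_mlp()`): a 2–h–1 network, tangent-sigmoid hidden layer,
linear output, on z-standardized features and target. Training is
full-batch iRprop⁻ (sign-based resilient back-propagation: step factors
1.2/0.5, steps clipped to $[10^{-8}, 1]$), epoch cap 2000, early stopping
with patience 50 on a held-out 15% of the training records; the best
validation weights are kept. Everything is a pure function of (records,
h, seed). `tune_mlp()` sweeps $h = 1..20$ and reports the chosen topology
as "2-h-1".

**M5-style model tree** (`fit_m5p()`): standard-deviation-reduction
splitting on $L$ or $D$ over midpoints of consecutive unique values;
growth stops when a node's target SD drops below 5% of the root SD or the
node has fewer than `2 * min_instances` (default 8) records. Every node
carries a full linear model over $(L, D)$ (mean fallback when singular).
Pruning is bottom-up, comparing the node model's compensated error
$\mathrm{MAE}\times(n+p)/(n-p)$ against the size-weighted subtree error; a
$10^{-9}$ relative tolerance in the comparison absorbs floating-point
residue on exactly-fitted subtrees, which otherwise blocks the single-leaf
collapse on noise-free linear data. Smoothing blends each child
prediction with its parent's model, weight $n_\text{child} : 15$.

## Evaluation machinery

The train count of a 70/30 split uses half-up rounding,
`floor(0.7 n + 0.5)` — the unique rule reproducing all five published
partition sizes (1028 → 720/308; 518 → 363; 508 → 356; 530 → 371;
486 → 340). 10-fold CV is used for hyperparameter selection inside
training only; reported metrics come from the held-out 30% (the source is
ambiguous on this point, so resubstitution and CV numbers are labelled
distinctly wherever both appear). The 1:1-line diagnostic regresses
measured on estimated weights and t-tests slope = 1 and intercept = 0 at
$\alpha = 0.05$. `select_best()` ranks by training RMSE, breaking ties by
training R² and then declaration order.

One structural caveat the tests reflect: on LD-law synthetic data the LD
form, the PUK-SVR and the model tree all sit at the noise floor and their
training-RMSE ranking is a coin flip; the pipeline test therefore asserts
that the winner is statistically tied with the LD form and the SVR (within
5%) rather than naming a single winner, while the single-dimension forms
$L^3$ and $D^3$ must be strictly worse.

## Reproducibility

All randomness descends from one root seed through
`derive_seed(seed, label)` (a rolling hash modulo $2^{31}-1$), so each
pipeline stage has an independent, stable substream; every fit is a pure
function of its inputs and seed, and `run_simulate()` is byte-identical
across reruns. Output files carry an 8-hex-digit hash of the generating
configuration.

## Known limitations

* Single-fruit scenes on a near-uniform light stage only; no shadow or
  background-clutter handling.
* PNG is the only supported image codec.
* The renderer's fruit are superellipses; strongly asymmetric or lobed
  fruit are outside the synthetic world.
* Transfer validation across cohorts with different generating laws shows
  the bias such transfer deserves; it does not certify cross-season
  generality of any single fitted model.
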