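---
title: "Methods: height/crown-radius biomass allometry from laser scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: height/crown-radius biomass allometry from laser scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Classical tree allometry predicts individual aboveground biomass (AGB,
kg dry mass) from stem diameter at breast height (DBH, cm, at 1.3 m):
remote platforms cannot see the stem, but they measure tree height
*H* (m) and — through crown delineation — an "equivalent-circle" crown
radius *R* (m), the radius of the circle whose area equals the
delineated crown footprint. The package evaluates whether the pair
(H, R) can replace DBH.

Reference biomass is taken from species group allometry,

$$W_\mathrm{ref} = \alpha\,(D^2 H)^{\beta},$$

with (α, β) = (0.1179, 0.815) for larch and (0.093, 0.869) for the
broadleaf group (ash, sophora). These coefficients are used as printed
in the forestry protocol they come from, not re-estimated locally —
a known source of bias that the package inherits deliberately.

Nine candidate (H, R) forms (power laws in H, R, H+R², H·R and H+R; an
exponential, a linear, a logarithmic and a quadratic form in H+R) are
fitted by *untransformed* least squares on W: nothing in the source
protocol suggests log-space fitting, and untransformed fitting keeps
RMSE in kg interpretable. Log–log (or log-linear) ordinary least
squares supplies starting values only. Eq3's predictor H + R² is
dimensionally mixed (m + m²); it is implemented literally, as printed.

Fitting uses closed-form least squares for the three
linear-in-parameter forms (Eq6 linear, Eq7 logarithmic, Eq9 quadratic)
and a damped Gauss–Newton (Levenberg–Marquardt) iteration for the
power and exponential families, with a relative-cost tolerance of
1e-10, at most 200 iterations, and an honest convergence flag.
Negative predictions — possible for Eq6/7/9 — are retained in the
metrics by default; clipping at zero is an opt-in flag
(`run_config(clip_negative = TRUE)`), because silent clipping would
flatter exactly the model forms under scrutiny.

Accuracy is scored with
$R^2 = 1 - \sum(y_i-\hat y_i)^2/\sum(y_i-\bar y)^2$,
$\mathrm{RMSE} = \sqrt{\tfrac1n\sum(y_i-\hat y_i)^2}$ and
$\mathrm{rRMSE} = 100\,\mathrm{RMSE}/\bar y$, on a 70/30 random split
(training size = `round(0.7 n)`, banker's rounding, platform-stable).
Whether published figures of this kind report training-set or held-out
values is usually ambiguous; the package therefore reports **both**
(`r2_train`/`r2_test`, etc.) and the acceptance checks use the
full-data fit, the less seed-sensitive of the two. Degenerate metric
cases are pinned down explicitly: zero variance in y with zero
residuals gives R² = 0 (a constant carries no explanatory power), zero
variance with nonzero residuals gives NA, and rRMSE is NA when
$\bar y = 0$.

## The synthetic world

The generator replaces the study's field data, so its defaults *are*
the stated world:

* Four plots — two conifer (larch, cone crowns) and two broadleaf
  (ash, sophora; ellipsoid crowns) — with 126, 127, 290 and 82 trees
  and the published per-plot ranges of H, DBH and R.
* DBH is uniform within its plot range: with only minima and maxima
  published, the uniform is the minimal assumption.
* H and R follow power laws of DBH (`H = s·DBH^e + ε`), with exponent
  and scale calibrated so the law passes through the plot's range
  endpoints — the defaults reproduce the published ranges by
  construction. The power-law form itself is a modelling choice
  justified by the strong mutual correlation of DBH, H and R in
  closed-canopy stands.
* Coupling noise is Gaussian with SD = 25 % of the mid-range value of
  H and of R, then clipped into the range. This figure was calibrated
  against the published *accuracy levels*, not against any ordering
  criterion: it reproduces a combined-model R² near 0.81 in the first
  conifer plot (the published headline for that plot) and implies a
  within-plot H–DBH correlation near 0.6, typical of even-aged
  plantations. One published level (the short-broadleaf plot, ~0.75)
  is not reachable simultaneously: that plot's H range is so narrow
  that clipping saturates any noise level. The first-plot figure was
  prioritised; the residual mismatch is a documented limitation.
* Stems are placed by rejection sampling with a 2 m minimum spacing on
  45/50/60/40 m squares (stem densities of 0.05–0.08 m⁻², plantation
  regime). A bounded number of attempts guards against infeasible
  configurations, which raise an error naming the plot.
* Rendering: ALS samples the upper crown surface (cone mantle /
  upper half-ellipsoid, crown base at 0.35·H for conifers and 0.45·H
  for broadleaves) plus ground returns, with one exact apex point per
  tree; TLS adds stem-cylinder returns of diameter DBH up to the crown
  base, guaranteeing a usable 1.3 m slice. The total point budget is
  `density × area`, so the realised density tracks the request within
  10 %. Published densities bound the defaults (ALS 600 pts/m² within
  581.9–1866.7; TLS 2281.92 pts/m²).

What the generator does **not** emulate: occlusion, multiple returns,
intensity, crown asymmetry and inter-tree crown interlocking, registration
error between the two scanners, and understorey. A green round-trip
test therefore establishes that the extraction chain is internally
consistent on idealised geometry — not that it would segment a closed
natural canopy correctly.

## Point-cloud processing choices

* **Ground filtering** is progressive TIN densification: seeds are
  block minima on a coarse grid (default 5 m), and a point joins the
  ground set when its vertical offset to the current TIN surface is at
  most 0.6 m *and* the angle it subtends to the nearest TIN vertex is
  at most 6°, iterated to convergence (published parameters; the 60°
  terrain-inclination setting acts as a slope sanity bound between
  neighbouring seeds). Two numerical details: the TIN vertex set is
  decimated to per-metre-cell minima (the physical facet scale — and
  it keeps the triangulation small), and the angle's horizontal
  distance is floored at 1 m to avoid the vertex-adjacent degeneracy
  where the angle tends to 90°.
* **DEM/CHM**: per-cell minimum of ground points (TIN-interpolated
  into empty cells) and per-cell maximum height above the DEM, floored
  at zero; cells without returns get height 0. Default cell sizes
  0.25 m (ALS) and 0.10 m (TLS) give ≳4 points per cell at the
  working densities. Vegetation height windows are closed intervals
  (both bounds inclusive; the parameter tables give no open/closed
  convention).
* **Crown segmentation** substitutes CHM marker-controlled watershed
  for the commercial point-cloud tool used in the original workflow:
  the CHM is pit-filled (3×3 median) and Gaussian-smoothed (σ = 1
  cell), treetop markers are local maxima separated by at least the
  trunk/canopy step (2 m ALS), connected plateau maxima are merged
  into a single marker, and vegetation cells are flooded level by
  level with the flood-level bin set by the growth step (1 m ALS).
  Segments supported by fewer than the minimum object size (20 points
  ALS / 40 TLS) are discarded. Crown radius is the equivalent-circle
  radius √(area/π).
* **DBH** comes from a least-squares circle on the 1.3 ± 0.05 m
  normalized-height slice near the detected stem: a robust median
  pre-screen (gross outliers have quadratic leverage on the algebraic
  fit), a Kåsa algebraic fit, Gauss–Newton geometric refinement, one
  3-MAD trim, one refit. Slices with too few points flag the tree
  rather than fail the run.
* **Fusion** solves the optimal one-to-one assignment (Hungarian
  algorithm on connected components of the thresholded distance graph)
  rather than greedy nearest-neighbour matching: the result is
  deterministic, order-independent, and maximizes match cardinality
  before total distance. The 1 m default threshold is a declared
  assumption (no threshold is published); cost ties break to the lower
  tree id.

## Degenerate inputs and numerical conventions

Raster indexing is row-major from the north-west origin with
closed-open cell intervals; the vegetation height window is the one
deliberate exception (closed at both ends). Empty point clouds pass
through the ground filter unchanged; all-collinear clouds raise an
error (no TIN exists). The assignment uses a large-M construction so
that "unmatched" is always feasible. Circle fits refuse collinear
inputs; the three-point circumcircle has a closed form against which
both fitters are tested.

## What the tests establish

The suite cross-checks every numerically substantive path against an
independent route: closed-form OLS against the iterative optimizer,
the circumcircle against both circle fitters, brute-force enumeration
against the Hungarian assignment, dense grid search against the
Levenberg–Marquardt optimum, hand-computed metric values against
`evaluate_predictions()`, and generator truth against the full
extraction chain. The acceptance suite adds parameter recovery for all
nine forms at 5 % noise and the qualitative finding that combined
(H, R) models outperform single-predictor models in all seven
scenarios of the calibrated synthetic world — the package-level
restatement of the headline scientific claim.

## Known limitations

* The watershed stand-in is not the original point-cloud segmentation
  algorithm; parameters were mapped by role (marker spacing, flood
  step), not by equivalence proof.
* Reference coefficients are fixed constants; no uncertainty is
  propagated from them, and no bootstrap intervals are provided.
* Single-station TLS occlusion is modelled only through an optional
  visible-arc fraction in the renderer.
* The short-broadleaf plot's published accuracy level is not exactly
  reproducible under range clipping (see above).
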