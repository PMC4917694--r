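---
title: "Methods: a synthetic corneal-map cohort and cluster-aware diagnostic accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic corneal-map cohort and cluster-aware diagnostic accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcmaps)
```

## The scientific setting

Keratoconus is a progressive corneal ectasia: the stroma thins and steepens
into a cone, usually decentred inferotemporally. Before the front surface
shows any topographic sign, the epithelium already remodels — a localized
patch of thinner epithelium over the cone surrounded by an annulus of
thickened epithelium. OCT corneal mapping therefore extracts, over the
central 5 mm, seven pachymetry variables (SN−IT, Min, Min−Med, S−I,
Y location, Min−Max, CCT) and seven epithelial variables (Sup, Inf_ep,
Min_ep, Max, Min−Max_ep, SD, CET), and asks how well each discriminates
three groups of eyes: frank keratoconic eyes, healthy-subject normal eyes,
and the topographically normal *fellow* eyes of patients with very
asymmetric keratoconus. Fellow eyes are the clinically interesting group:
they look normal on topography but most will eventually develop the
disease.

The raw patient maps behind the published three-group table are not
available. This package therefore rebuilds the study as a simulation
replica: a generative model of per-eye thickness maps calibrated so that
the *extracted* features reproduce the published group means, plus the full
statistical pipeline (group tests, cluster-aware ROC/AUC, spline
probability transforms, logistic combination) run end-to-end on the
synthetic cohort.

## The map model

Each eye carries three scalar fields on a polar grid over the central 6 mm
(64 rings x 128 spokes by default; features use the central 5 mm, the
outermost 0.5 mm ring band only feeds the topographic indices sampled at
3 mm):

* **Pachymetry** (um): `T0 + k r^p + g y + h x + noise − depth · G(cone)`,
  with `G` a Gaussian in map-plane distance from the cone apex.
  `T0` is the apical base thickness; `k r^p` the peripheral thickening
  (quadratic for keratoconic eyes, cubic for the two non-keratoconic
  groups — the steeper profile concentrates the thickening at the rim,
  which is what reconciles the small Min−Med of healthy corneas with
  their large Min−Max); `g y` a vertical gradient (superior cornea
  thicker, `g > 0`); `h x` a nasal-temporal gradient (`h < 0`, nasal
  thicker) which is what makes the superonasal octant thicker than the
  inferotemporal one over and above the vertical gradient; `depth` the
  stromal depression of the cone.
* **Epithelium** (um): `E0 + s y + ek r^2 + noise − thin · G_e + A · ring`,
  with the same cone centre: a depression of `thin` um at the apex
  (`G_e` shares the centre but is 0.6x as wide as the stromal depression —
  epithelial remodelling is more localized), a Gaussian-profile annulus of
  thickening of amplitude `A` at radius `R` from the apex — the classic
  doughnut pattern — and a mild radial curvature `ek`.
* **Axial power** (D): `K0 + (astig/2) cos 2(θ − axis) + 0.08 · depth ·
  G_p`, where `G_p` shares the cone centre but is 1.6x broader than the
  stromal depression: curvature change extends beyond the depression
  itself, which is what lets a paracentral cone raise the
  inferior-superior power difference sampled at 3 mm.

The model form is not taken from any device; it is the minimal smooth
parametric family we found able to reproduce all fourteen published group
means simultaneously. Smoothness matters: the "noise" is not white but a
sum of six broad random Gaussian bumps (0.9 mm radius, centres uniform in
the analysis disc, zero pointwise expectation), so map extremes — and with
them Min, Max, Y location — are stable under grid refinement (the test
suite checks < 1 um feature movement on doubling the grid).

### Latent severity and the two-eye structure

Each eye has a latent severity `z ~ N(0, 1)` that loads negatively on
`T0`, positively on log depth and log epithelial thinning, and negatively
on the apex height `cy` (worse disease: thinner, deeper, more inferior
cone). The two eyes of a patient draw `(z_OD, z_OS)` from a bivariate
normal with correlation `rho` (default 0.5), which propagates into
within-patient correlation of the extracted features — the reason the AUC
machinery treats the patient as a cluster. The published study gives no
estimate of this correlation, so `rho` is an exposed free parameter; tests
only rely on its qualitative effect (higher `rho`, higher within-pair
feature correlation).

Severity and noise draws are winsorized at ±3 SD, and the cohort samplers
redraw the rare parameter combinations whose maps would leave the
physical bounds (pachymetry 300–700 um, epithelium 20–90 um). The
published per-group ranges are themselves bounded, so this mild truncation
of the severity tail is part of the generative model rather than a
distortion of it; a user-supplied calibration that *systematically*
produces out-of-bounds maps still fails loudly, naming the offending
parameters.

### Calibration

`default_calibration()` fixes, per group, the distribution (mean,
across-eye SD, severity loading) of every generative parameter. The means
were fitted numerically against the fourteen published group means: weakly
coupled parameters by damped scalar iteration, one lever per mean — `T0`
against CCT, the vertical gradient `g` against S−I (a unit of `g` moves
S−I by 2.364 um, the area-weighted mean of `2y` over a half-annulus), `h`
against SN−IT, `k` against Min−Max — and the strongly coupled blocks by
damped Newton steps on finite-difference Jacobians: the seven epithelial
means against their six-to-seven levers with tolerance-weighted least
squares, and (depth, noise amplitude, apex height) jointly against
(Min, Min−Med, Y location), whose one-lever-at-a-time updates otherwise
chase each other. The fit was accepted when, with 500 generated eyes per
group, every thickness-valued feature mean sat within 2% of its published
value and every difference/dispersion feature within 15%; the shipped
defaults pass that check with at least 40% margin on every feature.

The fitted groups read sensibly. Keratoconic eyes are cone-dominated:
median stromal depression ≈ 48 um on top of a thinned base, apex ≈ 0.9 mm
inferior, 12 um of epithelial thinning inside a pronounced annulus.
Fellow eyes carry an attenuated focal thinning (≈ 11 um) and a mildly
inferior thin point, reproducing their reduced Min/CCT and inferiorly
displaced thin point without tripping any topographic flag. Normal eyes
are noise-dominated — their thin point location is set by the smooth
random surface against the gradients, not by a disease cone; the mean
location of their small residual focal spot is a calibration degree of
freedom (it lands slightly superior, offsetting the inferior pull of the
vertical gradient on the arg-min) rather than an anatomical claim.

Across-eye SDs are set to plausible values near the published per-group
SDs but are deliberately slightly tighter for features whose spread is
dominated by rare extremes (notably Y location): only the group *means*
are calibration targets, and a tighter spread keeps the Monte-Carlo error
of a 500-eye check well inside the acceptance band. The published ranges
are not used as truncation limits.

### What the generator does not emulate

No biomechanics, no optics, no A-scan simulation, no segmentation error,
no tear film (the published thicknesses include it; ours are "as
measured" by construction), and feature correlations beyond those induced
by the shared surface parameters and latent severity. A passing
calibration therefore shows that the pipeline recovers the published
group structure *given* maps with these moments — not that real OCT maps
look like our parametric family.

## Feature extraction choices

"Central 2 mm" and "2–5 mm" zone labels are read as diameters (radii 1.0
and 1.0–2.5 mm), the convention of the device family the variables come
from. Octants are 45° sectors centred on the eight principal
semi-meridians; only SN and IT are named in the variable list, the rest
follow the same convention. Zone means, the map median and the epithelial
SD are area-weighted over the polar grid (cell area proportional to
radius) because the device's exact point set is unknown; the vertex
participates in the extremes with zero area weight. Min−Med is
Min − median (the published values are negative, which forces this sign).
Y location is the signed vertical offset of the arg-min in um of map-plane
displacement (the published magnitudes, hundreds of um, rule out a mm or
degree convention); arg-min ties break deterministically toward the
smaller radius, then the smaller angle. Left-eye maps are mirrored about
the vertical axis before extraction so nasal/temporal sectors align across
eyes; the spoke count is kept even so the mirror is grid-exact.

## Topographic screening

The four screening criteria are implemented on the synthetic axial power
map: I-S (five inferior minus five superior points at 3 mm, 30°
intervals), central power (area-weighted mean over the central 3 mm — the
averaging zone is not specified in the source and is exposed as an
argument), KISA% = K · (I-S) · AST · SRAX / 300 expressed in percent with
each component pluggable (AST is steep-minus-flat from a cos 2θ fit at the
1.5 mm ring; SRAX the skew angle between the steepest superior and
inferior radial axes), and an optional KPI linear discriminant that ships
disabled because its coefficients are not published — only its 0.23
threshold is retained for user-supplied coefficient sets. All thresholds
are inclusive (`>=`). Negative I-S (superior steeper) is floored at zero
inside KISA so the index stays non-negative.

Two properties tie the screen to the cohort construction: keratoconic
eyes exceed the normals' flag rates, and — mirroring how the study's
groups were defined — *every* generated fellow eye must screen
non-keratoconic at the default calibration. The calibration guarantees
the latter structurally: with winsorized draws, the worst-case fellow
central power and I-S stay below their thresholds by construction, not
just in expectation.

## Statistics layer

Summaries are mean, sample SD (n−1), median and range per group; a
single-eye group reports SD 0 with a degenerate flag rather than failing.
Normality is checked with the one-sample KS statistic against a normal
with estimated mean/SD; because the parameters are estimated, the
asymptotic p-value is conservative (the Lilliefors bias) and is documented
as an upper bound — the test suite derives honest critical values by
simulation where it needs power statements. Group differences use the
tie-corrected Kruskal–Wallis H (chi-square reference) with pairwise
Mann–Whitney post hoc tests, unadjusted by default since the source
reports raw pairwise p-values against 0.05; Holm adjustment is a flag.
The all-identical-values corner returns H = 0, p = 1 rather than erroring.

## Diagnostic accuracy

The AUC point estimate is the Mann–Whitney pair-counting estimator
(computed via midranks, algebraically the same thing), auto-oriented so
reported AUCs are ≥ 0.5 with the direction retained. The cluster-adjusted
standard error is a leave-one-patient-out jackknife: delete each patient
(both eyes), recompute the unoriented AUC, and use the jackknife variance
over patients. We chose the jackknife over a structural-components
estimator for transparency — it is exactly reproducible by a five-line
oracle — and validate it by coverage: over 500 replicates of 60 two-eye
patients with within-pair marker correlation 0.5, the nominal 95% Wald
interval `auc ± 1.96 SE` must cover the true binormal AUC between 90% and
99% of the time. The Wald interval is reported both truncated to [0, 1]
and raw; the source's own printed upper bound above 1 shows it used the
untruncated form, and Wald (not bootstrap) is adopted for the same reason.
A leave-one-out replicate that loses an entire class is dropped from the
jackknife rather than poisoning the variance.

Markers whose relationship with disease is non-monotone (Y location is
the motivating case: both strongly inferior *and* superior thin points are
atypical) are replaced by their estimated disease probability before ROC
analysis: a P-spline logistic fit (B-spline basis, second-order difference
penalty, penalized IRLS) with the smoothing parameter chosen by GCV, via
`mgcv`. Monotonicity itself is decided from the fitted smooth: slopes on a
201-point grid, a 5% relative tolerance band to ignore numerical wiggle,
monotone iff all non-negligible slopes share a sign. In the heavy-penalty
limit the second-order penalty leaves exactly a linear logistic fit, which
the tests exploit as an oracle (predictions must match `glm` within 1%);
a monotone transform leaves the ROC curve unchanged pointwise, which is
the other invariance the tests pin down. Whether the original analysis
transformed every variable or only the non-monotone ones is not stated;
this pipeline applies the transform exactly when the monotonicity check
fails.

Multi-marker combination is plain in-sample logistic regression (the
linear predictor is the combined marker), matching the source's in-sample
reporting — no cross-validation by default. Complete separation falls back
to a lightly ridge-penalized IRLS with a warning; rank deficiency is an
error naming the collinear columns.

## Problem sizes and numerical choices

The calibration checks use 500 generated eyes per group (Monte-Carlo SE of
each feature mean is then a small fraction of its acceptance band), the
ROC floor checks 2 000 feature-level eyes per group for single markers and
500 per group for fitted combinations, coverage 500 replicates, and the
transform-gain check 100 replicates at n = 400 — sizes chosen so each
property is measured with comfortable margin while a full test run stays
in the minutes range. Map generation is vectorized per eye; 1 500 eyes
generate and extract in well under a minute. All randomness flows through
R's RNG from a single seed per experiment; cohorts are pure functions of
their spec, and the report bundle of `run_study()` is byte-reproducible.

## Known limitations

* Feature-level sampling (`feature_sample()`) draws the 14 variables as
  independent normals at the published moments unless a correlation
  matrix is supplied; the all-variable combined model trained on such
  draws sees a friendlier covariance than real, correlated features
  would provide.
* The KS check inherits the Lilliefors bias by design fidelity.
* KPI is a configurable stub (coefficients unpublished).
* The generator's parametric family is a modelling convenience; only the
  extracted feature means are calibrated, not map shapes, and the
  published group SDs/ranges are matched only approximately. Because an
  AUC depends on spreads as well as separations, the ranking of
  single-variable AUCs computed on map-level cohorts can differ from the
  published ranking even though every group mean matches.
* In-sample combined models at the study's group sizes can separate the
  synthetic classes completely (AUC 1.0 with the ridge fallback); the
  published in-sample AUCs just below 1 reflect real-data noise the
  feature-level replica reproduces only partially.
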