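---
title: "Posterior eyeball topography and the LC/BMO offset: methods and design choices"
author: "eyetopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior eyeball topography and the LC/BMO offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adult human eyeballs are not ellipsoids. During axial elongation the globe
can expand asymmetrically, leaving a focal outward protrusion of the
posterior wall with a reciprocal flattening next to it. At the optic nerve
head (ONH), the scleral-side canal opening (proxied by the lamina cribrosa,
LC) can be displaced relative to the retinal-side opening (the Bruch's
membrane opening, BMO); this misalignment — the *LC/BMO offset* — is
measured by the deviation of the central retinal vascular trunk (CRVT) from
the BMO center. `eyetopo` quantifies both phenomena and their association:

1. **Globe topography** — extract the globe contour from a T2-weighted
   volumetric scan, fit an optimal ellipsoid to the posterior 2/3 of the
   contour, and analyze the signed residual field: classify eyes into group
   1 (no asymmetry) or group 2 (a single dominant outward protrusion with
   an immediately adjacent reciprocal inward depression), locate the
   outermost protruded point (OPP), and compute the protrusion depth.
2. **ONH offset** — fit an ellipse to human-marked BMO margin points on an
   infrared fundus image, and express the CRVT deviation from the BMO
   center as an angle (from the nasal fovea–BMO axis, positive superior)
   and an offset index \(a/b\), the ratio of the CRVT–center distance to
   the center–margin distance along the same ray.
3. **Cohort statistics** — exclusion-flow accounting, group comparisons,
   correlations, random-intercept logistic regression and linear GEE that
   account for the correlation between paired eyes of one subject.

No patient data ship with the package: a synthetic generator produces voxel
phantoms, ONH scenes and cohort manifests with known ground truth, so every
stage is testable end to end.

# The optimal ellipsoid fit

An ellipsoid is represented implicitly as
\(ax^2+by^2+cz^2+dx+ey+fz+gxy+hyz+izx+j=0\). The quadric has a one-parameter
scale freedom; we fix the gauge by scaling the quadratic-form matrix to
trace 3 and orienting the polynomial negative at the center, which makes
the 10-tuple unique and the sign convention (negative inside, positive
outside) unambiguous.

The cost function is the sum of squared **exact Euclidean point-to-surface
distances**. The foot point of a point \(y\) (principal frame, semi-axes
\(s_j\)) solves \(x_j = s_j^2 y_j/(s_j^2+t)\) with \(t\) the unique root of
\(\sum_j (s_j y_j)^2/(s_j^2+t)^2 = 1\) on \((-\min_j s_j^2, \infty)\); the
root is found by a bisection-safeguarded Newton iteration, vectorized
across points. Exact distance (rather than the algebraic residual) was
chosen because the downstream quantities — fit RMSE and protrusion depth —
are defined as ratios of geometric lengths.

Minimisation uses the Nelder–Mead simplex over 9 free coefficients (the
trace gauge eliminates one), seeded by an algebraic least-squares quadric
(smallest singular vector of the design matrix; a least-squares sphere if
that quadric is not an ellipsoid). Excursions out of ellipsoid space are
penalized by \(10^6\) times the summed magnitude of offending eigenvalues,
which keeps the simplex inside the positive-definite cone. Up to five
restarts with ±5% jitter on the seed are used when a run fails to converge
or terminates on a non-ellipsoid; the best valid run wins.

**Tolerances.** The simplex stops when the relative cost spread falls below
`reltol` (default `1e-8`) and the simplex diameter below `1e-6` of the
parameter scale, or immediately when the cost is at the exact-interpolation
floor. The `1e-8` default is deliberate: the exact-distance cost has a
numerical noise floor near `1e-8` relative (per-point Newton tolerance
propagated through ~2000 squared distances), and tighter settings make the
simplex chase round-off without changing any reported digit. Noise-free
phantom recovery is accurate to ~1e-14 mm in the semi-axes; at 1% radius
noise the semi-axes are recovered to ~0.1%.

**RMSE.** The reported RMSE is the root mean square of radius-normalized
signed residuals — each residual is the Euclidean distance divided by the
center-to-surface radius along the center-to-point direction, signed
positive outside. This makes RMSE dimensionless and scale-invariant, on the
same scale as the protrusion depth (a 1% radius deviation contributes
0.01).

# Contour extraction

Volumes are linearly rescaled to 0–256. Edges are traced per axial slice by
a Canny detector (Gaussian blur σ = 1 voxel; Sobel gradients; non-maximum
suppression; hysteresis at 0.1/0.3 of the volume-wide maximum gradient
magnitude), keeping the largest connected edge component per slice as the
globe boundary. Edge positions are refined to sub-pixel accuracy by
parabolic interpolation of the gradient magnitude along the quantized
gradient direction; without this, the half-voxel quantization at 1 mm
resolution (±0.5 mm ≈ 0.04 of the radius) would dominate the residual
field and mask group-2-scale bulges. Even with refinement, reliable
asymmetry classification of a 0.06-amplitude bulge needs ≤ 0.5 mm voxels;
at 1 mm the fit itself is accurate (axes within half a voxel) but the
residual field is noise-limited — a genuine resolution limitation worth
knowing when applying the method.

The standardized eye frame puts the lens→ONH axis on +z (posterior pole at
large z) via the minimal rotation, which preserves the scanner's vertical
as "superior"; left eyes are mirrored in x so nasal = +x for every eye.
Fovea and BMO landmarks are consumed as marked (they are human inputs, not
detected) and kept un-snapped: the nasal fovea–BMO reference axis is short
(~3–4 mm projected), and snapping landmarks onto a ~0.6 mm-spaced contour
would jitter the angular reference by several degrees — more than the 5°
accuracy the OPP angle aims for. A diagnostic warns when a landmark is far
from the contour.

The "posterior 2/3" is measured along the standardized visual axis between
the contour's extreme z values, matching a planar cut.

# The residual field and the asymmetry rule

Every posterior contour point gets its signed radius-normalized residual.
Points at or above `magnitudeFloor` × RMSE (default 1.0 — tying the floor
to the fit quality makes the rule scale-free) are grouped by polarity into
connected components of a k = 8 nearest-neighbor graph; components smaller
than 5 points are sampling specks and are not treated as regions.
Area is estimated per point by Voronoi-like weights (squared distance to
the 8th neighbor), compensating the non-uniform slice-wise sampling.

An eye is **group 2** when

* the largest outward component holds ≥ 70% of the total suprathreshold
  outward area ("dominant … existing singularly"),
* an inward component lies within 3 hops of it on the surface graph
  ("immediately adjacent"), and
* the pair's joint area exceeds half the posterior-pole area.

The clinical definition quantifies none of the three clauses; the 70%
dominance share, the 3-hop adjacency and the pair-reading of the half-area
rule are this package's operationalization, all exposed in
`pipelineConfig()` (`areaRule = "depression"` switches to the alternative
reading in which the depression alone must exceed the threshold). The
*posterior pole* is likewise not a defined anatomical surface; we take the
polar cap within 35 degrees of the posterior pole as seen from the fitted
center (`poleCapDeg`), the central posterior region that clinical usage of
"posterior pole" (the area between the temporal arcades) corresponds to on
a globe. Area fractions are
restricted to this cap; a broad, shallow compensation band far from the
pole (an artifact of the fit re-centering) therefore does not dilute the
dominance rule.

The **OPP** is the point of maximal signed residual inside the dominant
outward region (near-exact ties go to the larger area-weighted neighborhood
mean); its angle is measured in the posterior polar plane (the xy-plane)
from the nasal fovea–BMO axis, positive toward superior. The **protrusion
depth** is the mean absolute residual over the dominant outward region plus
the same over its paired depression. Note that an ellipsoid fitted through
a bulged surface absorbs part of a smooth perturbation into its center and
axes: an injected amplitude of 0.06 yields a visible residual maximum of
roughly half that, and a measured depth of ~0.035. Depth is strictly
monotone in the injected amplitude, and the OPP azimuth is unbiased, but
absolute depths are attenuated relative to the generative amplitude — a
property of the method, not a defect of the implementation.

# ONH offset metrics

The BMO margin ellipse is fitted by the direct least-squares conic method
with the ellipse constraint (Fitzgibbon; Halir–Flusser block formulation),
which cannot return a non-ellipse. The offset index divides the CRVT
distance by the **ray–ellipse intersection** distance in the same direction
(not the radius at the CRVT's parametric angle). A visible CRVT outside the
fitted margin is clipped to index 1.0 with a warning; an invisible CRVT
gets index 1.0 and the angle opposite the longest externally-oblique-border
meridian. A CRVT exactly at the center has index 0 and no defined angle.

Two angle conventions are in clinical use (nasal fovea–BMO axis
vs nasal horizontal midline as 0°): the fovea–BMO axis is used, making the
ONH angles commensurable with the OPP angle. "Clockwise" is replaced by the
intrinsic rule *positive toward superior* in right-eye orientation, which
is independent of image handedness; for the PPA angle (temporal reference)
this means the opposite rotational sense than for the offset angle (nasal
reference) in a mathematical frame.

# Cohort statistics

Group comparisons use the classic equal-variance two-sample t-test (the
common default of commercial statistics packages; Welch available via
`welch = TRUE`) and the chi-square test. Correlations are Pearson on
signed degrees — angles are treated as linear quantities, which is how the
association between OPP location and offset direction is conventionally
expressed; a circular treatment would be defensible and is a known
alternative, but it changes the meaning of the correlation, so it is
intentionally not the default. No
multiple-testing correction is applied (the analysis is explicitly
screening-plus-multivariable at P < 0.10, then P < 0.05).

Paired-eye correlation is handled twice: a random-intercept-per-subject
logistic model (adaptive Gauss–Hermite quadrature, 7 points, via `lme4`)
for the binary asymmetry outcome, and a linear GEE with exchangeable
working correlation for the offset direction. The GEE is implemented in
the package (moment estimation of the exchangeable parameter, cluster-robust
sandwich covariance with the finite-cluster correction \(g/(g-p)\) and
t-quantiles on \(g-p\) degrees of freedom); with one eye per subject it
reduces exactly to ordinary least squares. Simulated 95% CI coverage is
~0.95 for both models at the cohort's size (85 subjects).

# The synthetic generator

`phantomSpec()` defaults describe the reference conditions the generator emulates: semi-axes
12.5/12.0/11.5 mm; a von-Mises–Fisher-shaped bulge of amplitude A = 0.06
(the group-2 mean depth scale) at −70° (the inferonasal mean OPP location),
inclination 40° from the posterior pole, concentration κ = 6; a reciprocal
depression of equal amplitude 40° up-meridian, i.e. centered on the
posterior pole — genuinely *immediately adjacent* to the bulge, as the
asymmetry rule requires. Placing the depression on the bulge meridian makes
the depression's pull on the residual maximum purely inclinational, so the
recovered OPP azimuth is unbiased. Scan noise is modeled as isotropic
Gaussian point noise (σ = 0.12 mm ≈ 1% of the radius) or voxel-intensity
noise for rasterized volumes (1 mm spacing by default, like the source
scans).

`makeScene()` places 24 margin points on the BMO ellipse (one per radial
scan), the fovea on the nasal axis, and the CRVT by inverting the offset
definition, so (angle, index) round-trip exactly. `makeCohort()` draws
demographics from the reference cohort moments (age 55.0 ± 16.2 y, axial
length 25.6 ± 1.9 mm, 49% female), marks exclusion flags reproducing the
reference exclusion flow (96 enrolled → 3 withdrew, 1 metallic foreign
body, 4 poor MRI, 2 poor OCT, 1 CRVT bifurcation → 85 subjects, 170 eyes),
and couples the group-2 offset direction to the OPP angle linearly,
`offset = wrap(-0.716·opp + 12.6 + noise)`, the slope and intercept chosen
so the group-2 offset mean is ≈61° when the OPP mean is ≈−68°. With 30°
coupling noise this yields r ≈ −0.74 on synthetic cohorts; a "+180°
wrapped" coupling was considered and rejected because wrapping destroys
the very linear correlation the opposed-direction relation shows.

What the generator does **not** emulate: MRI bias fields and motion
artifacts, partial-volume intensity profiles, peripapillary anatomy
(conus, tilted disc), digitization error in human landmark marking, and
any biomechanical growth process. Passing phantom tests therefore
demonstrates the correctness of the geometry and statistics, not clinical
validity on real scans.

# Problem sizes and numerical notes

Unit and acceptance tests run on phantoms of 1000–2500 surface points and
voxel grids of 1 mm (0.5 mm where the test is about resolution), cohorts of
96 subjects, 500-replicate coverage simulations and a 2000-replicate type-I
simulation; these sizes give stable estimates while keeping a full test run
in minutes. Degenerate inputs are refused early: fewer than 9 or coplanar
points for the fit, fewer than 5 or collinear points for the BMO ellipse,
constant-intensity volumes, coincident lens/ONH landmarks, empty groups in
comparisons. Points numerically at the ellipsoid center or on a principal
plane of the smallest axis are nudged by ~1e-12 before the distance solve
(error far below the 1e-10 mm tolerance).

# Known limitations

* At 1 mm voxel spacing the residual field is quantization-limited;
  asymmetry classification from volumes is only reliable at ≤ 0.5 mm.
* The measured protrusion depth is attenuated relative to the generative
  amplitude by fit absorption (see above); depths are comparable across
  eyes but are not direct estimates of the physical bulge height.
* The dominance (70%), adjacency (3 hops) and pole-cap (35°) constants are
  operational choices; sensitivity to them should be reported alongside
  any scientific claim.
* Angles are analyzed linearly; cohorts with offset distributions
  straddling ±180° would need the circular alternative.
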