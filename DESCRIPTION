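Package: eyetopo
Title: Posterior Eyeball Topography and Optic Nerve Head Canal Offset Morphometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies focal posterior bulging of the human eyeball from
    volumetric T2-weighted scans and relates it to the misalignment between the
    lamina cribrosa and the Bruch's membrane opening (the LC/BMO offset) at the
    optic nerve head. The package extracts the globe contour slice-wise with a
    Canny edge detector, fits an optimal ellipsoid to the posterior two thirds
    of the contour by Nelder-Mead minimisation of exact point-to-surface
    distances, builds the signed radial residual field, classifies eyeball
    asymmetry (a dominant outward protrusion with an immediately adjacent
    reciprocal inward depression), and measures the outermost protruded point
    and the protrusion depth. A companion two-dimensional stage fits the BMO
    margin ellipse and computes the central retinal vascular trunk offset
    (angular deviation and offset index). A cohort stage provides exclusion-flow
    accounting, group comparisons, correlations, random-intercept logistic
    regression and linear generalized estimating equations for paired eyes.
    Synthetic phantom, scene and cohort generators with known ground truth make
    the whole chain testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    RNifti,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
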