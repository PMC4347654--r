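---
title: "Quantifying infarct size and area at risk on cardiac MR: methods and design"
author: "cmrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infarct size and area at risk on cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrquant)
```

## The measurement problem

After an acute ST-elevation myocardial infarction, two imaging measures
carry most of the prognostic information obtainable from cardiac MR: the
**infarct size (IS)** — the mass of hyperenhanced myocardium on late
gadolinium enhancement (LGE) imaging — and the **ischaemic area at risk
(AAR)** — the mass of hyperintense (oedematous) myocardium on T2-weighted
STIR imaging. Both are conventionally expressed as a percentage of left
ventricular mass (%LVM), and their difference defines the **myocardial
salvage index**, `MSI = 100 * (AAR - IS) / AAR`, the fraction of the
jeopardised myocardium that did not infarct.

There is no histological gold standard for either measure in living
patients, and several semi-automated thresholding conventions coexist.
This package implements the three families in routine use, the manual
corrections applied to all of them, and the agreement statistics used to
compare them, together with a synthetic short-axis phantom whose ground
truth is known exactly — so that every operator in the chain can be tested
quantitatively rather than by visual inspection.

## The quantification methods

All methods operate on a signal-intensity (SI) stack plus a myocardial
mask rasterised from manually drawn endocardial/epicardial contours
(contouring itself is an input, not something the package attempts to
automate). A voxel is *enhanced* iff `SI > T` — strictly greater, one
consistent convention for every method.

**kSD remote-ROI thresholding** (`thresholdKSD()`). A region of interest
of 2 cm² is placed in *remote* myocardium (no enhancement, no oedema).
One global threshold `T = mu + k * sd` is applied to all slices, with `mu`
and `sd` the ROI mean and **sample** standard deviation (n − 1). Which SD
convention commercial workstations use is unknowable; the sample form is
pinned here because the exactness tests need a single definition, and at
the conventional ROI size (~89 voxels at 1.5 mm pixels) the difference is
negligible. `k` = 5–8 is used for IS on LGE and `k` = 2 for AAR on
T2w-STIR.

**FWHM thresholding** (`thresholdFWHM()`). The threshold is half the
maximum SI of the infarct core, `T = 0.5 * SImax`, shared by all slices.
Because only the single brightest pixel matters, the method is insensitive
to ROI size; in automatic mode the core search is therefore reduced to the
global myocardial maximum over quantifiable slices, which is exactly what
the manual "try candidate ROIs, keep the brightest" procedure converges
to. FWHM is not offered for AAR: with the low contrast-to-noise of
T2w-STIR most of the myocardium exceeds half the maximum, which makes the
method degenerate there (the uniform-myocardium degenerate — the whole
wall "enhances" — is kept, documented, for LGE too).

**Otsu automated thresholding, per slice** (`thresholdOtsu()`). Each
quantifiable slice gets its own threshold: over the 255 interior edges of
a 256-bin histogram spanning that slice's myocardial SI range, the
threshold minimising the within-class variance sum (equivalently
maximising the between-class variance) is chosen. Ties break toward the
lowest threshold. Numerically, the within-class sum of squared errors is
evaluated once per *distinct induced partition*, directly from the raw
voxel values rather than from binned approximations, and the lowest
candidate edge of the optimal partition is returned — this makes the
result exactly reproducible by an exhaustive brute-force search, which the
test suite performs on every small slice. A constant-SI slice has no
Otsu threshold; it is assigned "no enhancement" with a warning. Crucially,
a threshold is computed on *every* slice whether or not infarct is
present — this is deliberate, as it is the method's documented
overestimation mechanism: on an infarct-free slice the brighter half of
the noise distribution is declared enhanced.

**Manual reference** (`manualReference()`). In the absence of a gold
standard the reference is the arithmetic mean of repeated manual
quantifications (conventionally six: two each by three readers).

### Corrections

Two manual corrections are standard and are implemented as deterministic
operators:

* **[a] enclosed-core inclusion** (`fillEnclosedCores()`) — hypointense
  regions enclosed within enhancement correspond to microvascular
  obstruction (LGE) or intramyocardial haemorrhage (T2w) and belong to the
  total IS/AAR. Slice by slice, any non-enhanced myocardial 2-D component
  (8-connectivity) whose entire surrounding pixel set is enhanced is
  filled. Components touching remote myocardium, the blood pool or the
  epicardial edge are untouched. 2-D-per-slice operation is intentional:
  observers include these cores image by image.
* **[b] interslice-continuity noise removal** (`removeNoiseIslands()`) —
  isolated enhancement without interslice continuity in non-infarct
  territory is noise artefact. 3-D connected components (26-connectivity)
  spanning fewer than `minSliceSpan = 2` slices are removed. Knowledge of
  the infarct-related artery territory is observer-supplied in practice;
  it enters here as an optional `protectMask` whose components are always
  retained, and is never inferred.

Both operators are idempotent, and they commute on solid lesions.

### Mass normalisation

`lvMass()` computes `voxels x pixel area x (thickness + gap) x density`
with density 1.05 g/mL (configurable; it cancels in every %LVM ratio,
which the tests verify indirectly by computing %LVM as a voxel-count
ratio). The most apical contoured slice is excluded
(`excludeApicalSlice()`) to minimise partial-volume effects. Whether the
excluded slice's mass belongs in the %LVM denominator is not settled
usage; the default convention here removes it from **both** numerator and
denominator, keeping IS a ratio over the same tissue, and
`percentLVM(..., apicalInDenominator = TRUE)` provides the alternative.

## The phantom

`generatePhantom()` builds paired LGE and T2w-STIR stacks from an
idealised geometry: per slice, an annular myocardium between concentric
circles, containing a circular-sector infarct of given angular extent and
transmurality (growing from the endocardium), inside a transmural oedema
wedge wider by a configurable angular margin, with an optional enclosed
hypointense core occupying a set fraction of the infarct area. Isolated
single-slice false-enhancement speckles are placed in remote territory at
mutually distinct angles (so they are 26-connectivity-disconnected from
the infarct and from each other), partial volume is modelled as in-plane
Gaussian blur of the noiseless SI map, and noise is additive Gaussian.

Default parameters (a 128 × 128 matrix at 1.5 mm, nine 8 mm slices with
2 mm gaps, annulus radii 22/32 mm, a 90° infarct of 0.75 transmurality on
the five central slices, oedema margin 15° per side, core fraction 0.15,
SI means 100/400/200/50 for remote/infarct/oedema/core, noise SD 10, blur
1 mm, three speckles) describe a plausible acute anterior infarct study;
none of them is calibrated to any particular scanner, and the partial
volume width and noise texture are configurable rather than claimed
realistic. Two modelling choices deserve mention:

* Noise is Gaussian, not Rician: the methods' behaviour under test depends
  only on SI contrast, and Gaussian noise keeps all analytic oracles
  simple.
* On LGE the oedematous border zone is given an intermediate SI
  (`siLgeBorder`, default 170, between remote 100 and infarct 400). This
  reproduces the mechanism by which low-k SD thresholds and per-slice Otsu
  overestimate IS: intermediate intensities at infarct borders fall above
  low thresholds. Setting `siLgeBorder = siRemote` together with zero
  noise and blur yields a fully *separable* phantom on which every
  threshold strictly between remote and infarct SI segments the true
  infarct exactly after correction [a] — the configuration used by the
  noise-free recovery tests.

Rasterisation details are pinned for testability: wedge membership is
half-open in signed angle, `(-extent/2, extent/2]`, so lattice-aligned
wedge edges (e.g. a 90° wedge centred on an axis) are counted once rather
than twice; the enclosed core is a radially and angularly shrunken
sub-wedge whose linear scale is `sqrt(fraction)`, which gives the
requested area fraction exactly in the continuum limit. Ground-truth
percentages follow the default mass convention (apical slice excluded
from numerator and denominator), so they are directly comparable with
pipeline output. The contours the phantom emits are 180-vertex polygons of
the true circles, and the ground-truth myocardial mask is *defined* as
their rasterisation, which makes mask/contour consistency exact by
construction while annulus areas still match the closed form to better
than 1%.

What the phantom does **not** emulate: papillary muscles and trabeculae
(excluded by contouring in practice — the contour input already encodes
that), cine motion, blood-pool artefact, coil-profile shading, Rician
noise floors, and infarct heterogeneity (grey zone). Tests passing on the
phantom therefore demonstrate correctness of the operators under the
stated model, not clinical accuracy on real images.

## Observer simulation and the cohort pipeline

`runCohort()` reproduces a method-comparison study design over a list of
phantom subjects: per subject, measure (IS/AAR), method, observer and
replicate it produces one corrected %LVM value, then assembles the
accuracy table (mean ± SD per method, ICC and Bland–Altman bias versus
the manual reference) and the interobserver/intraobserver blocks.
Observer variability is injected at its true sources — radial jitter of
contour vertices and in-plane jitter of the remote-ROI seed — because in
this workflow the contours and ROI placement are the only user inputs.
Manual quantification is simulated as ground truth plus measurement
jitter, and the reference is the mean of 3 × 2 manual analyses. The
simulated reader also refuses to place a remote ROI over visible
enhancement: among quantifiable slices the candidate ROI with the
smallest maximum SI is used, mirroring how remote regions are chosen in
practice.

`reproduceSupplementary()` performs the reverse direction: given any
long-format raw ratings table (subject, field strength, measure, method,
rater, replicate, value) it recomputes the full summary-table layout.
Externally named tables are ingested via an explicit column mapping
(`readRatings(path, mapping = ...)`) rather than by guessing headers.

## Agreement statistics

`iccAgreement()` is the single-measure two-way intraclass correlation
from the ANOVA decomposition of the complete subjects × raters matrix:

`ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`

The label "ICC(3,1) for absolute agreement" mixes two naming systems
(Shrout–Fleiss model 3 is the consistency form; the absolute-agreement
single-measure coefficient is McGraw–Wong ICC(A,1)). Since absolute
agreement is what is stated and wanted when comparing methods with
systematic offsets, the absolute-agreement formula above is the default
and the consistency variant sits behind `type = "consistency"`. Zero total
variance and missing cells are errors — no imputation. Qualitative
categories use the conventional bins (≥ 0.75 excellent, 0.60–0.74 good,
0.40–0.59 fair, < 0.40 poor).

`blandAltman()` returns the mean difference and `bias ± 1.96 SD` limits
(sample SD; the multiplier is configurable but defaults to the tabled
convention). `pairedT()` wraps the standard paired t-test with two pinned
degenerates: all-zero differences are an error (0/0 statistic), constant
non-zero differences return p = 0 with a warning (the t → ∞ limit).
`wilcoxonSquaredDiffs()` compares the reproducibility of two methods by a
signed-rank test on per-subject differences of squared differences; zeros
follow the Pratt convention and the null distribution is exact (computed
by convolution over doubled ranks) up to 25 non-zero subjects, with a
tie-corrected normal approximation beyond. `pearsonCor()` supports the
injury-versus-ejection-fraction correlation analysis; ejection fraction
is accepted as subject metadata, never computed from cine imaging.
Normality diagnostics are deliberately left to standard tools
(`shapiro.test()`, Q–Q plots) and are not re-derived here. Reports emit
raw p-values; whether to apply multiplicity control is left to the
analyst (`p.adjust()` composes directly with the report columns).

## Problem sizes and numerical tolerances

The shipped test-suite and acceptance-script problem sizes are chosen to
exercise every operator while keeping a full run in the order of a minute
or two: coarse 64 × 64 / 6-slice phantoms for bulk property checks
(100-phantom monotonicity sweeps), the full 128 × 128 / 9-slice default
geometry wherever the enclosed core must survive rasterisation with a
safe enclosure margin (about two pixels at default parameters), 1000
random small slices for the Otsu-versus-brute-force equivalence, 200
random tables for the ICC-versus-ANOVA oracle (agreement to 1e-10), and
exhaustive sign-flip enumeration for all Wilcoxon cases up to n = 10.
Threshold identities (kSD, FWHM) are checked to machine precision;
phantom-recovery checks use a one-percentage-point band, which absorbs
rasterisation granularity at the default grid.

## Known limitations

* The phantom's idealised annulus cannot produce contour-quality failure
  modes (open contours, crossing endo/epi) except synthetically.
* The enclosed-core fill is resolution-dependent by nature: a core whose
  rasterised rim touches non-enhanced myocardium diagonally is correctly
  — but perhaps surprisingly — not filled. At coarse grids (pixel size
  approaching the core's enclosure margin) corrected values can
  under-represent the core; the default grid keeps a ≥ 2 pixel margin.
* DICOM support is a minimal explicit-VR little-endian reader/writer
  sufficient for geometry-faithful slice I/O, not a general DICOM
  implementation; NIfTI (with a JSON sidecar for the thickness/gap split)
  is the primary interchange format.
* The statistics assume complete, balanced designs; hierarchical or
  mixed-model extensions are out of scope.
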