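---
title: "Methods: calibrated muscle-section analysis on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated muscle-section analysis on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myosectr)
```

`myosectr` implements a complete measurement chain for quantitative muscle
histochemistry — myoglobin (Mb) microdensitometry, fiber morphometry,
myonuclear stereology, qPCR expression and group statistics — together with
a synthetic section generator that renders every input the chain consumes
with known ground truth. This vignette is the package's own account of the
models, the tunable parameters, the numerical choices, and the limits of
what the synthetic tests demonstrate.

## The densitometry model

The peroxidase assay produces light attenuation proportional to Mb
concentration. We model a transmission image under Beer–Lambert:

$$I = I_0 \cdot 10^{-\varepsilon\,[\mathrm{Mb}]}, \qquad
  \mathrm{OD} = -\log_{10}(I/I_0),$$

with a single effective extinction scale $\varepsilon$ (OD per mM) folding
molar absorptivity and optical path length together. The assumptions are
(i) attenuation is linear in concentration over the calibrated range,
(ii) the background intensity $I_0$ is spatially uniform, and (iii) noise
is additive, Gaussian and small relative to $I_0$. Calibration is ordinary
least squares of OD on the known standard concentrations, *with* an
intercept: a true assay can carry a section-thickness or fixation offset,
and on clean data the intercept estimates ~0 anyway. The functional form of
the calibration (linear) is a declared convention of this package; the
assay literature the method descends from asserts calibration without
reproducing its form.

Fibers whose pixels are saturated by capillary peroxidase ("black spots",
hemoglobin) would bias the mean OD upward, so pixels above the OD of the
highest calibration standard plus a margin (default 0.2 OD) are excluded
before averaging. The threshold is a package convention: the source method
states only that spots *were excluded*, not how. A fiber whose pixels are
all above threshold is reported as unusable (NA) rather than silently
averaged.

**Parameters** (defaults in `optics_params()`): `background_intensity`
$I_0 = 200$ on an 8-bit range, `extinction_scale` 1.0 OD/mM, `noise_sd` 2
gray levels, `pixel_size` 2 µm/px, calibration standards
$\{0, 0.2, 0.4, 0.8, 1.2, 1.6\}$ mM, capillary spot OD 2.0 (near-black).
The standard concentrations are not stated by the assay description we
emulate; the set here is a declared convention chosen so that the standards
**span the simulated concentration range**. That span matters: control
subjects' type I fibers are drawn with a large between-subject spread and
can reach ~1.3 mM, and a calibration ceiling of 0.8 mM would make the spot
exclusion rule swallow legitimately dark, high-Mb fibers. The spot OD (2.0)
stays above the top standard's OD (1.6), preserving the separation the
exclusion rule relies on.

## The synthetic cohort

`cohort_params()` holds the group moments the generator targets; its
defaults are the published cohort of 29 elite cyclists and 20
physically-active controls (weighted Mb 0.38 ± 0.04 vs 0.48 ± 0.19 mM, MHC
type I 66.0 ± 13.7 vs 45.2 ± 10.6 %, FCSA by type, myonuclei 4.34 ± 0.76 vs
4.30 ± 0.83 per cross-section, satellite cells 0.13/0.15 per fiber,
nuclear length 11 ± 2 µm, relative mRNA 0.067 ± 0.019 vs 0.088 ± 0.027,
RNA yield 53.4 ± 29.9 vs 45.1 ± 26.0 ng/mg).

Per-type Mb is parameterised as the type II concentration plus the percent
excess of type I over type II, because cohort reports print the weighted
mean and the excess (25 ± 9 % in cyclists, 84 ± 54 % in controls) rather
than per-type moments. The type II SDs (0.030 / 0.123 mM) were chosen once,
by the delta method, so that the implied weighted-mean SDs reproduce the
printed 0.04 / 0.19 mM; the implied type I means are ~0.41 mM (cyclists)
and ~0.64 mM (controls). All quantities are drawn from truncated normals:
positive quantities truncated just above zero, percentages clipped to
[1, 99] — without truncation the controls' large Mb SD would occasionally
produce impossible values. The excess draw is additionally bounded at ±3 SD
of its mean, which keeps the implied type I concentrations inside the range
the calibration standards span; the effect on the first two moments is
negligible. Subject-level mRNA is coupled to the latent normal behind the
Mb draw through a Gaussian copula (`mb_mrna_rho`, default 0.4) so that
pooled Mb–mRNA correlations are recoverable downstream.

## The synthetic section

Fibers are packed by a Lloyd-relaxed, area-weighted Voronoi tessellation of
the pixel grid — convex, roughly isodiametric cells that resemble
transverse fiber profiles and deliberately pass the circularity filter.
Boundaries are eroded into a ~4 px wide WGA-positive basal-lamina network;
the width is chosen so an interstitial nucleus fits *between* the laminas
of adjacent fibers without overlapping either. Each fiber receives a type
(Bernoulli at the subject's type I percentage), a target area drawn around
the subject's per-type FCSA (20 % CV), and an Mb concentration drawn around
the subject's per-type mean with a 5 % fiber-to-fiber CV — realistic
biological within-subject variation which also decorrelates 8-bit rounding
errors across fibers, so subject-level means are not biased by
quantization.

Nuclear fragments are placed by class: myonuclei and Pax7⁺ satellite cells
centred on fiber-edge pixels (touching the lamina), occasional central
nuclei in the eroded fiber interior (1 % of the myonuclear rate),
interstitial nuclei on the lamina core between fibers (10 % of the
myonuclear rate per fiber). Central and interstitial rates are package
conventions — every class must occur for the classifier to be testable —
as no rates are printed in the cohort reports. A minimum centre separation
keeps rendered DAPI blobs from merging, so connected-component detection
is exact at zero noise. Capillary spots are stamped at fiber boundaries
(Poisson, one per fiber on average) at OD 2.0.

Longitudinal sections render nuclei as filled ellipses (11 ± 2 µm major
axis by default) on a non-touching grid; the measured major axis comes from
the second moments of each component's pixel coordinates
($\mathrm{length} = 4\sqrt{\lambda_{\max}}$, exact for a filled ellipse).

**What the generator does not emulate**: vapor-fixation chemistry, antibody
binding kinetics, optical blur/PSF, uneven illumination, out-of-focus
fragments, touching nuclei, non-convex or split fibers, and hybrid
(double-positive) MHC staining. Tests passing on this ground truth
therefore validate the *computational* chain — calibration algebra,
exclusion rules, geometry, classification logic, stereology and statistics
— not the robustness of segmentation to real histological artefacts.

## Morphometry choices

Outlines are traced with marching-squares contouring at level 0.5 on each
fiber's indicator image, which cuts pixel corners diagonally; naive
pixel-edge tracing inflates perimeters by up to ~27 % for smooth shapes and
would depress every circularity. Area and perimeter use the shoelace
formula and Euclidean vertex distances, after scaling x by the pixel size
and y by pixel size × aspect ratio. The circularity filter excludes fibers
at *or below* 0.60 (the boundary value is excluded), and border-touching
fibers are excluded from area and nuclear statistics since truncated
outlines bias both. Double-positive (hybrid) fibers are pooled into type II
for the two-class distribution — the convention is configurable
(`hybrid_as`) and documented because the underlying antibody pair pools
type II subtypes; how a specific study classified double-positives is
generally not stated.

## Stereology choices

The correction factor is computed from the average nuclear length as
$F = \lfloor (L_{nuc} - d_{min})/D_s \rfloor + 1$ — the number of
consecutive sections in which an average nucleus leaves a detectable
(≥ 1 µm) fragment — and defaults to the global $F = 2$ that 11 µm nuclei in
10 µm sections imply. For nuclei longer than ~21 µm this formula
extrapolates the same counting logic; that regime is outside the data the
rule was derived from. Counting is restricted to circularity-passing
fibers (avoiding myonuclear-domain overestimation in obliquely cut cells),
and MDS pairs the *same* fiber set's mean FCSA with its nuclear counts.
Per-subject results aggregate fibers first, then subjects (mean of ratios),
matching subject-wise reporting; this is why pushing group means through
the MDS formulas reproduces a printed group MDS only to ~1 %
(ratio-of-means vs mean-of-ratios).

## Statistics choices

All tests are two-sided at α = 0.05. Shapiro–Wilk failure in either group
routes to Mann–Whitney; otherwise Levene's test (car's median-centred
default) decides pooled vs Welch t — the Welch fallback is standard
practice where the source analysis names only "independent samples
T-test". Bonferroni with m = 2 covers exactly the type I/type II Mb pair;
all other variables are single pre-planned contrasts (m = 1). Percent
differences are reported relative to the control group mean. A design note
on power: with groups of 29 and 20 at weighted-Mb moments of 0.38 ± 0.04 vs
0.48 ± 0.19 mM, the two-sided Welch noncentrality is ≈ 2.3, so a single
simulated cohort at these moments detects the group difference in roughly
six of ten replicates, not nearly always; a single observed significant
comparison is compatible with this, but simulation studies at these moments
should expect moderate power. The test suite computes this detection rate
explicitly.

## Numerical details and degenerate inputs

* Truncated-normal draws use the inverse-CDF transform; `sd = 0` returns
  the mean exactly (degenerate distribution), which the tests use to pin
  down arithmetic.
* Intensities above background clamp to OD 0; fitted concentrations below
  zero clamp to 0 mM with a warning (noise can push low-Mb fibers below
  the calibration intercept).
* Background is estimated as the modal gray value of the calibration-free
  margin — robust to dark outliers, exact at zero noise.
* The calibration fit refuses non-positive slopes (assay failure) and
  fewer than two distinct standards; r² is computed from residuals
  directly so a perfect fit is reported as exactly 1.
* Fully spot-covered fibers, empty fiber regions, zero typed fibers, zero
  total nuclei, and constant correlation inputs all raise informative
  errors; `run_study()` records skipped comparisons rather than failing
  the whole cohort.
* Seeds: every stochastic step is seeded; per-subject section seeds derive
  deterministically from the study seed and stay within 32-bit integer
  range. Fixed seed ⇒ bit-identical cohorts, images and tables.

## Problem sizes

The shipped tests exercise sections of ~25–30 fibers (~230 × 260 px at
2 µm/px) and cohorts of 3–6 subjects per group for image round-trips, 200
seeded cohorts for correlation/power properties and 500 replicates for
null calibration — sizes chosen to keep the default suite fast while
leaving every statistical check adequately powered. All generator defaults
(29/20 subjects, printed moments) remain the study conditions; tests that
need the full design generate cohort tables, which are cheap, rather than
rendered images.

## Known limitations

* The per-type Mb construction matches printed means, weighted SDs and
  excess moments, but the true joint distribution (e.g. skew in control
  type I Mb) is unknown; only a figure shows it.
* Fragment-to-fiber assignment uses the detected centroid's label; a
  fragment straddling the lamina midline between two fibers is assigned to
  at most one.
* MDS is a 2-D stereological estimate with a global correction factor; no
  3-D (disector/confocal) counting is attempted.
* The qPCR module implements plain $2^{-\Delta CT}$ without
  amplification-efficiency correction, matching the analysis it mirrors.
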