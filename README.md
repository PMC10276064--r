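# myosectr

Quantitative histochemistry of skeletal-muscle biopsy cross-sections in R:
calibrated peroxidase microdensitometry of myoglobin (Mb) concentration,
fiber morphometry with a circularity filter, myosin-heavy-chain fiber
typing, myonuclear/satellite-cell classification and myonuclear-domain
stereology, qPCR relative expression, and the two-group comparison
statistics that tie them together. A synthetic muscle-section generator
with known ground truth makes the whole chain testable without any raw
biopsy images.

## Who this is for

Muscle physiologists and image-analysis developers who quantify Mb content,
fiber-type composition and myonuclear content from stained biopsy sections
— for example when comparing endurance athletes against active controls —
and who want every stage of that measurement chain (calibration, exclusion
rules, stereological corrections, test selection) reproducible and
verifiable against simulated ground truth.

## The measurement chain

**Densitometry.** Transmission gray values are converted to optical density
by Beer–Lambert, `OD = −log₁₀(I / I₀)`, and mapped to concentration through
an ordinary-least-squares calibration line fitted to gelatin standards of
known Mb concentration rendered beside the tissue:
`OD = slope·[Mb] + intercept`. Near-black capillary peroxidase spots
(hemoglobin) are excluded pixel-wise before averaging. Subject-level Mb is
the fiber-type-weighted mean

```
[Mb]_avg = [Mb]_I · p_I + [Mb]_II · (1 − p_I)
```

with `p_I` the type I fiber fraction, each type mean taken over up to 20
randomly sampled fibers.

**Morphometry.** Fiber outlines are traced sub-pixel (marching squares);
area and perimeter give `circularity = 4π·FCSA / perimeter²`, and fibers
with circularity ≤ 0.60 (or touching the image border) are excluded from
area and nuclear statistics.

**Stereology.** DAPI⁺ fragments are classified by position and Pax7 status:
against the basal lamina → myonucleus (Pax7⁻) or satellite cell (Pax7⁺);
inside the fiber but off the lamina → central nucleus; between laminas →
interstitial cell. Only myonuclei enter the counts. With fragments per
cross-section `N_m,f`, segment length `L_f = 1000 µm`, section thickness
`D_s = 10 µm` and multiple-counting correction
`F = ⌊(L_nuc − d_min)/D_s⌋ + 1` (= 2 for 11 µm nuclei and a 1 µm detection
limit):

```
N_m,l = N_m,f · L_f / (D_s · F)        # myonuclei per mm fiber
MDS   = FCSA / N_m,l                   # myonuclear domain size, pL
```

**Expression.** Mb mRNA relative to 18S as `2^−ΔCT`, `ΔCT = CT_Mb − CT_18S`,
plus total RNA per mg muscle.

**Statistics.** Shapiro–Wilk (per group) and Levene gates select pooled-t,
Welch-t or Mann–Whitney; Bonferroni (m = 2) covers the type I/type II Mb
pair; Spearman correlation of Mb with mRNA expression is computed on the
pooled cohort.

## Worked example

```r
library(myosectr)

subj <- generate_cohort(cohort_params(seed = 42))[1, ]   # one cyclist
sec  <- generate_section(subj, optics_params(), n_fibers = 30, seed = 42)
sec
#> <muscle_section> 228x255 px (456x510 um), 30 fibers, 130 nuclear
#>   fragments, 31 capillary spots

m <- measure_subject(sec, seed = 42)
glance(m$curve)
#>   slope intercept r.squared n_standards max_concentration
#> 1 0.999  0.000831     1.000           6               1.6

dplyr::select(m$subject, mb_weighted_mM, pct_type1, mds_pL)
#>   mb_weighted_mM pct_type1 mds_pL
#> 1          0.375      63.3   31.5
```

The calibration slope recovers the rendering extinction (1 OD/mM) from the
standards alone; the measured weighted Mb (0.375 mM) agrees with this
subject's ground truth (0.371 mM) to ~1%, the residual being fiber
sampling plus 8-bit quantization. A full cohort runs the same way:

```r
study <- run_study(cohort_params(n_per_group = c(cyclists = 6, controls = 6),
                                 seed = 7), n_fibers = 24)
study
#> <mb_study> 12 subjects (cyclists vs controls), seed 7
#>   significant (adj. P < 0.05): none
#>   pooled Spearman rho = 0.45 (P = 0.140, 21% of variance)
```

(At n = 6 + 6 nothing reaches significance — the group contrast needs the
full 29 + 20 design; `tidy(study)` and `glance(study)` expose the
comparison table and headline summary, `autoplot(study)` the group panels.)

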