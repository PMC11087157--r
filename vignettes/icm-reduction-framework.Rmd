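---
title: "Planning iodinated contrast dose reduction at matched CNR: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning iodinated contrast dose reduction at matched CNR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Iodinated contrast media (ICM) is injected before most body CT exams to make
vessels and perfused tissue attenuate more than their surroundings. Supply
shortages and renal-safety concerns both push in the same direction: use less
iodine without making the exam non-diagnostic. Two scanner-side levers raise
the *contrast efficiency* of a protocol — how much contrast-to-noise ratio
(CNR) each mg/mL of iodine buys:

* lowering the tube potential (kV) in single-energy CT (SECT), which moves
  the beam spectrum closer to iodine's K-edge at 33.2 keV; and
* reconstructing lower-energy virtual monochromatic images (VMI, keV) from a
  dual-energy CT (DECT) acquisition.

`icmreduce` implements the quantitative bookkeeping that turns phantom
measurements of these levers into concrete dose-reduction percentages, plus a
synthetic phantom-image generator so the whole chain is testable without
scanner time.

## The model

For each acquisition *stratum* — a combination of scanner, mode (SECT kV or
DECT-VMI keV), phantom size and reconstruction — the CNR of an iodine insert
is modelled as proportional to its concentration:

$$\mathrm{CNR}_{E,\,\mathrm{size}} = \alpha_{E,\,\mathrm{size}} \cdot
  \mathrm{Conc}_{E,\,\mathrm{size}}$$

The line is forced through the origin: zero iodine gives zero contrast, so a
free intercept would only absorb measurement artefacts. The slope
$\alpha$ (CNR per mg/mL) is the stratum's contrast efficiency. Matching CNR
between a baseline technique $b$ and a target technique $t$ *within the same
phantom size* gives the equivalent concentration and the achievable ICM
reduction:

$$\mathrm{Conc}_t = \frac{\alpha_b}{\alpha_t}\,\mathrm{Conc}_b,
  \qquad
  \mathrm{reduction\ \%} = 100\left(1 - \frac{\alpha_b}{\alpha_t}\right).$$

Both orientations of the slope ratio circulate in protocol-optimisation
write-ups, and the two are easy to confuse because they differ only by which
slope sits in the numerator. `icmreduce` fixes the orientation above, under
which a target with the *larger* slope (more CNR per mg/mL, e.g. a low-keV
VMI) yields a *positive* reduction, and a target with a smaller slope (e.g.
raising 120 kV to 140 kV) yields a negative value that is reported as a
required ICM *increase* of $100(\alpha_b/\alpha_t - 1)$ percent. The
inversion identity $(1 - r_{b\to t}/100)(1 - r_{t\to b}/100) = 1$ holds
exactly and is enforced by tests.

Cross-size comparisons are refused by default (`allow_cross_size = TRUE`
overrides with a warning): a slope measured in a newborn-sized phantom says
nothing about the dose needed at adult attenuation, so equivalence is only
meaningful within a size stratum.

### CNR definition

CNR is computed as

$$\mathrm{CNR} = \frac{\bar{H}_\mathrm{insert} -
  \bar{H}_\mathrm{background}}{\mathrm{SD}_\mathrm{background}}$$

with the noise taken from the background, not the insert, so insert texture
does not conflate contrast with noise. The sign is preserved: a
negative-contrast insert shows up as negative CNR in QA output instead of
being silently rectified. The background SD uses the sample ($n-1$)
estimator.

## Measurement pipeline

`locate_rois()` places one circular ROI per insert, with diameter a fraction
`roi_fraction` (default 0.7) of the insert's inner diameter — eroding the rim
where partial-volume pixels mix insert and background material — and four
background ROIs of the same area at the peripheral-insert radius, rotated
midway between inserts and checked against the body outline and all insert
footprints (collisions are configuration errors, not silent shifts). Two
placement modes exist: `"geometry"` trusts the phantom specification, and
`"auto"` detects high-HU disks by thresholding the slice-averaged image at
median + 5 MAD, labelling connected components (via `EBImage`), and matching
centroids to the specified inserts; on clean images both agree within one
pixel, and a missing component is reported by insert name. Voxels are pooled
across the central 60% of slices before computing mean and SD
(`central_fraction = 0.6`), because the end slices of physical contrast rods
are vulnerable to cone-beam and edge effects.

## Slope fitting and standard errors

`fit_slope()` estimates $\alpha$ by unweighted least squares through the
origin, $\hat\alpha = \sum c_i \mathrm{CNR}_i / \sum c_i^2$ (computed via
`lm(cnr ~ concentration - 1)`), with replicate measurements entering
individually. $R^2$ is reported about the zero-intercept model
($1 - \sum r_i^2 / \sum \mathrm{CNR}_i^2$, uncentred), which is the honest
goodness-of-fit for a no-intercept regression; it is not comparable to the
centred $R^2$ of an intercept model, and the output headers say so. A
diagnostic fit with a free intercept is always run and flagged when the
intercept differs from zero by more than two standard errors; it is never
used by the planner.

The standard error of $\hat\alpha$ needs care, because CNR measurement
errors violate the classical assumptions twice over:

1. all inserts of one image share the same measured background mean and SD,
   so their CNR errors are correlated within an image; and
2. the background-SD estimation error enters multiplicatively, so the error
   of $\mathrm{CNR}_i$ grows with $\mathrm{CNR}_i$ itself.

Three estimators are provided. `"ols"` is the classical formula (kept for
reference; it can understate slope uncertainty several-fold in replicated
designs). `"cluster"` is a cluster-robust estimator grouping by the
`replicate` column. `"model"` propagates the ROI sampling model analytically
— insert-mean noise $1/n_\mathrm{ins}$, shared background-mean noise
$1/n_\mathrm{bg}$, and the shared background-SD factor via inverse-chi
moments on $n_\mathrm{bg}-1$ degrees of freedom — and, unlike the empirical
estimators, carries no sampling noise of its own, so $\pm 3\,\mathrm{SE}$
intervals stay near nominal coverage even with ten replicate images (where
any empirical SE is a ~9-df estimate and $\pm 3\,\mathrm{SE}$ coverage is
capped near 98.5%). The default (`"auto"`) uses `"model"` whenever the ROI
voxel counts are available, falling back to `"cluster"` then `"ols"`. The
model SE assumes the generator's error structure (i.i.d. Gaussian noise,
known voxel counts); for real scanner data with correlated noise texture the
cluster estimator is the safer choice.

Uncertainty on a reduction percentage is first-order propagation treating
the two slopes as independent:
$\mathrm{Var}(r) \approx (\alpha_b/\alpha_t)^2
[(\mathrm{SE}_b/\alpha_b)^2 + (\mathrm{SE}_t/\alpha_t)^2] \times 100^2$.

Reports round percentages to one decimal; per-energy averages across phantom
sizes are always computed on unrounded values.

## The synthetic phantom generator

No public image data accompany the measurement campaign this framework
automates, so `simulate_phantom_image()` generates volumes with exactly the
statistical structure the analysis assumes, and *only* that structure:

* air at −1000 HU outside an elliptical water-equivalent body, a constant
  background HU inside it (0 HU solid water for the adult multi-energy
  phantoms, 30 HU tissue-equivalent for the pediatric/adult SECT set);
* insert HU = background + $\kappa(E)\cdot c$, with $\kappa(E)$ the iodine
  contrast coefficient (HU per mg/mL) derived from a bundled table of
  approximate iodine/water mass-attenuation values (35–160 keV, log-log
  interpolated). The values have published magnitudes — e.g.
  $\kappa(70\,\mathrm{keV}) \approx 25$ HU/(mg/mL) — but are simulation
  stand-ins, not dosimetry references;
* SECT tube potentials are mapped to configurable effective monochromatic
  energies (default 70→45, 80→52, 100→58, 120→65, 135→70, 140→72 keV);
  no polychromatic spectrum is modelled because the framework only needs a
  monotone contrast–energy response;
* i.i.d. Gaussian noise inside the body with SD
  $\sigma = \sigma_\mathrm{ref}\,
  e^{k_d (d - d_\mathrm{ref})}\sqrt{\mathrm{CTDI}_\mathrm{ref}/\mathrm{CTDI}}
  \cdot f_\mathrm{recon}$: exponential growth with effective diameter
  (attenuation is exponential in path length), inverse-square-root dose
  dependence (quantum noise), and a multiplicative factor per reconstruction
  label. Defaults: $\sigma_\mathrm{ref} = 10$ HU at $d_\mathrm{ref} = 20$ cm
  and 10 mGy, $k_d = 0.05$/cm, SBIR factor 1.0, DLR factor 0.7 — values in
  the range a body-CT physicist would call typical, chosen once as the
  package's simulation conditions;
* voxels are classified by centre point (no partial-volume area weighting);
  the downstream ROIs erode insert edges anyway;
* one top-level seed; per-volume child seeds derive from a stable hash of
  the stratum labels, so adding a volume to a suite never changes existing
  ones.

The standard fixture suites reproduce the study geometries: four circular
pediatric/adult SECT phantoms (effective diameters 9.7, 15.9, 21.1,
28.5 cm) with 13.1 mm rods at 2–20 mg/mL, and four adult multi-energy
phantoms (20, 29.5, 34.6, 39.7 cm, elliptical above the smallest) with
28.5 mm inserts at 2–15 mg/mL. One deliberate simplification: the physical
SECT rods stack their five concentration sections along z, while the
simulator places five single-concentration rods in the phantom's five holes
so that every concentration is measurable on every slice.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: noise texture and spatial correlation
from reconstruction kernels, beam hardening and other artefacts, automatic
exposure control, detector-specific spectral behaviour, partial-volume
blur, or any difference between reconstruction algorithms beyond a scalar
noise factor. Slope *ratios* measured on real scanners embed all of those;
the synthetic suite validates the estimator and planner machinery, not any
particular scanner's achievable reduction.

## Numerical choices and degenerate inputs

* Background SD of exactly zero makes CNR undefined → explicit
  degenerate-input error, not `Inf`.
* A stratum with fewer than two distinct positive concentrations cannot
  identify a slope → collected under `failures` with a reason by
  `cnr_calibration()`, never silently dropped.
* A target slope $\le 0$ cannot be matched → degenerate-slope error.
* Sizes without a baseline fit appear in the reduction matrix's
  `unavailable` attribute rather than being extrapolated.
* All-zero CNR yields $\alpha = 0$ with undefined (NA) $R^2$.
* Auto ROI detection uses `median + max(5 MAD, 5 HU)` as threshold so a
  noise-free image (MAD = 0) still thresholds sensibly; components smaller
  than a quarter of the smallest insert's area are discarded as noise
  specks.

## Problem sizes used by the test-suite simulations

The packaged tests and the acceptance script run the simulations at reduced
scale — 2–3 mm pixels, 2–5 slices, 4–10 replicate images, 200–500 seed
replications for the estimator-calibration studies — sizes chosen so the
Monte-Carlo error of each checked quantity is well below its assertion
tolerance. Slope-recovery coverage is evaluated over 500 seeds because a
1%-miss criterion measured on 200 runs carries ±0.4% binomial noise, which
is larger than the quantity's distance from its threshold.

## Known limitations

* The simulator's constants are stand-ins; no claim is made that the
  synthetic reduction percentages match any physical scanner.
* Material-decomposition iodine maps, noise-power spectra, resolution
  changes and injection-protocol effects (flow rate, bolus timing, scan
  delay) are out of scope.
* The patient worked-example module operates on printed ROI summary
  statistics only; it performs arithmetic, not image analysis, and makes no
  clinical claim.
* Reported patient CNR values whose background statistics were never
  recorded are displayed as context and cannot be recomputed; the packaged
  example marks them as such.
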