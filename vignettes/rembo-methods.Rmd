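---
title: "Methods: partition-model dosimetry and target-volume concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partition-model dosimetry and target-volume concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rembo)
```

## The problem

In yttrium-90 radioembolization (RE), microspheres are delivered through a
hepatic artery and deposit their dose in the perfused liver territory — the
*target volume* (TgV), comprising tumor and non-tumoral parenchyma. The TgV
enters every dosimetric calculation, but at planning time it can only be
estimated from imaging: contrast-enhanced CT (CECT, the anatomical
standard), C-arm cone-beam CT acquired during angiography (CBCT), or the
distribution of 99mTc-labelled macroaggregated albumin (MAA) on SPECT/CT,
injected as a microsphere surrogate. Only after treatment does 90Y PET/CT
show where the microspheres actually went. This package implements the full
audit chain: the dosimetry that consumes a TgV, the volumetry that produces
one from an activity map, the agreement statistics that compare modalities
against the PET/CT reference, and seeded simulators for validating each
stage against known ground truth.

## Partition-model dosimetry

The partition model splits an administered activity $A$ (GBq) over three
compartments. The lung receives the hepatopulmonary shunt fraction $h$
(measured on planar MAA scintigraphy); the hepatic remainder
$A_h = A(1-h)$ is divided between tumor and normal parenchyma in proportion
to mass times activity concentration, with the tumor concentrating
$TNR$-fold:

$$A_t = A_h \frac{TNR \cdot M_t}{TNR \cdot M_t + M_n}, \qquad A_n = A_h - A_t,$$

with masses $M = V \rho / 1000$ kg. Each compartment's absorbed dose for
complete local 90Y decay is

$$D = 49.67 \, \frac{A}{M} \ \mathrm{Gy},$$

with the lung mass fixed at 1 kg. The constants — 49.67 Gy·kg/GBq, tissue
density $\rho = 1.03$ g/ml, 1 kg lung — are the standard MIRD/partition
conventions and are exposed in `dose_constants()` rather than hard-coded,
since centres differ in the density they carry through. The
single-compartment model (`uniform_dose()`) is the $TNR = 1$ limit and is
verified to agree with the partition model to $10^{-9}$ in the tests.

Activity prescription (`prescribe_activity()`) encodes two clinical rules:
in cirrhotic patients with a predicted spared volume under 40% of the
liver, the activity is the largest keeping the normal-compartment dose at
or below 40 Gy (the REILD-safety cap); in non-cirrhotic patients with a
target under 60% of the liver, it is the smallest activity driving the
tumor dose strictly above 100 Gy (tumoricidal). The source protocol does
not specify how the two rules interact in the remaining intermediate cases,
so the package takes the conservative choice — the minimum of the two
candidate activities, so the safety cap can never be exceeded — and records
which rule fired in the returned rationale. The strict inequality of the
tumoricidal floor is realised as $D_t = 100 + \varepsilon$ Gy with
$\varepsilon = 10^{-6}$ Gy (configurable). Both binding constraints are
exact to $10^{-6}$ Gy because the model is linear in $A$.

`split_activity()` divides a prescribed activity across feeding arteries in
proportion to the tumor volume each perfuses, the planning manoeuvre that
CBCT volumetry enables when a lesion has several feeders.

## Isocontour volumetry and planar shunt

`isocontour_volume()` reproduces the "VOI + isocontour" workstation tool:
within a drawn search VOI, all voxels at or above a percentage of the
maximum voxel value form the molecular tumor volume (MTV). Three choices
the clinical description leaves open are fixed here and tested as such:

* the threshold references the **VOI-local** maximum, not the global image
  maximum — the per-target semantics of the tool (a surrogate; workstations
  differ);
* comparison is `>=`, so uniform regions segment deterministically
  (a 100% threshold still includes every voxel tied with the maximum);
* no connectivity filtering — every supra-threshold voxel counts.

Volumes are `voxel_count * dx*dy*dz / 1000` ml. The implementation is
checked voxel-for-voxel against an exhaustive triple-loop enumeration on
randomized maps, and MTV is verified non-increasing over 1–100% threshold
sweeps. `fit_isocontour_to_reference()` automates the radiologist's visual
threshold adjustment by picking, from a candidate grid (default 1–10%, the
clinically reported range with mode 3%), the threshold whose MTV is closest
to a reference volume, ties resolved toward the lower threshold (larger,
more inclusive volume).

The hepatopulmonary shunt (`lung_shunt_fraction()`) uses conjugate-view
quantification: per-ROI geometric means of anterior and posterior total
counts, $HPS = GM_{lung} / (GM_{lung} + GM_{liver})$, with the
conventional 20% contraindication flag. The planar source says only
"calculated on planar images"; the geometric-mean form is the standard
attenuation-robust estimator and is the documented choice here.

## Agreement statistics

`lin_ccc()` implements Lin's concordance correlation coefficient

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

with 1/n moment estimators by default — Lin's original definition. The
1/(n−1) variant is available (`estimator = "unbiased"`); at n = 19–24 the
two differ in the second decimal, and the default is the form under which
the packaged cohort reproduces its published coefficients. The 95% CI uses
Lin's asymptotic standard error on the Fisher z scale, back-transformed.
This CI choice was validated empirically: it reproduces the published
intervals to their printed precision on essentially every subgroup (e.g.
0.489–0.854 computed vs "0.49–0.85" printed for CECT over all patients),
which is as close to a method fingerprint as a reanalysis can get.

`r_squared()` is ordinary least squares via `lm()`;
`approach_comparison()` is the pooled-variance two-sample t test via
`t.test(var.equal = TRUE)`, with an explicit degenerate branch (identical
groups give $t = 0$, $p = 1$ rather than 0/0).

## The packaged cohort and its discrepancies

The builtin table (`load_cohort()`) carries 24 patients: per-modality TgVs,
MAA injection sites and split fractions, prescribed per-artery activities,
and two flags — pure lobar/total administration (7 patients) and changed
administration between MAA and treatment (4 patients; one patient carries
both flags, and the two flags filter independently). CBCT volumetry is
missing for 5 patients. Validation enforces positive volumes, unique sorted
ids, and MAA fractions summing to 1 within 0.01 (two patients' printed
thirds sum to 0.99).

Recomputing the published summary statistics from this per-patient table
reproduces the volume medians exactly and the concordance coefficients at
2-decimal rounding for CECT (all), CBCT (available), MAA (all), MAA
excluding changed administrations, CBCT on the selective subgroup, and both
selective-excluding-changed coefficients. Two published values do **not**
follow from the published per-patient data: the CECT-selective CCC (0.66
computed vs 0.5 published) and the MAA-selective CCC (0.85 computed vs 0.71
published — the published MAA-selective line is character-identical to the
published CBCT-all line, suggesting a transcription slip), along with the
published R² values. The per-patient table is the ground truth for this
package, so `reproduce_analysis()` reports the computed values and marks these
checks `discrepant_in_source` rather than silently passing or failing; no
estimator was tuned toward either side of the discrepancy.

The published per-patient tumor volumes, TNR and shunt fractions are not
available (only cohort means: TNR 2.6 ± 1.5, HPS 6.9% ± 3.4%), so the
published absorbed-dose medians (152/125/116/102 Gy at a fictitious 1 GBq)
cannot be recomputed. `reproduce_analysis()` runs that comparison with
seeded draws from the cohort-level distributions and flags the dose medians
`not_reproducible` with the reason; the property that *is* asserted (in the
acceptance suite) is structural: when modality volumes understate the
reference volume in a configured order, the magnitude of the median percent
dose change ranks in the same order, aggregated over 200 seeded replicates.

## What the simulators emulate — and what they do not

`generate_phantom()` builds a piecewise-constant ellipsoidal liver with
spherical tumors (uptake = TNR multiplier), an ellipsoidal lung
compartment receiving the shunt fraction, separable Gaussian PSF blur, and
Poisson counting noise; planar views are attenuation-free axis sums with
independent Poisson realisations per view. Defaults: 2 mm isotropic voxels
on a 64×64×88 grid, PSF σ = 4 mm (SPECT-like resolution), 5×10⁶ total
counts, TNR 2.6 and shunt 6.9% (the cohort means). The blur kernel is
truncated at 4σ and normalized, so counts are conserved away from grid
edges and — because the default geometry keeps liver and lung farther apart
than the kernel support — noise-free shunt recovery is exact to the $10^{-6}$
asserted in tests, not merely approximate. What is *not* modelled:
attenuation, scatter, reconstruction artefacts, breathing motion, irregular
organ shapes. Passing phantom tests therefore validates the measurement
*operators* (segmentation, ratio, shunt estimators), not their robustness
to real acquisition physics.

`generate_cohort()` draws cohorts with the statistical structure of the
packaged table: log-normal true TgVs (meanlog 6.73, sdlog 0.66 — the
fitted reference-volume distribution), per-modality multiplicative bias and
log-normal noise frozen to the fixture's observed geometric-mean ratios and
log-residual spreads (bias 0.59/0.60/0.88, noise SD 0.55/0.60/0.14 for
CECT/CBCT/MAA, the MAA figures taken after setting aside changed
administrations, which instead receive an extra 0.6 log-SD discordance),
4/24 changed, 7/24 lobar/total, 5/24 missing CBCT, truncated-normal TNR and
shunt at the cohort means. The simulated tumor volume is drawn as a
0.15–0.45 fraction of the patient's smallest observed TgV so every
modality's normal compartment stays positive. These defaults were set once
from the fixture, before any acceptance measurement, and are not tuning
knobs. The simulator reproduces rank structure (MAA most concordant,
excluding changed patients raises MAA concordance) but makes no claim to
reproduce exact published CCCs, which depend on one 24-patient draw.

## Numerical choices and edge cases

* Volumes ml, activities GBq, fractions 0–1 everywhere; mass conversion
  happens only inside the dose engine.
* Geometric means of planar ROI counts are computed in double precision
  (integer count sums overflow the 32-bit product at ~2×10⁶ counts).
* `lin_ccc()` refuses $n < 3$ and two equal constant sequences (0/0); a
  perfect $|\rho_c| = 1$ returns a degenerate CI at the point estimate.
* Dose at zero tumor mass is defined as 0 Gy (no 0/0).
* All simulator randomness sits behind a single mandatory integer seed;
  identical specs give bit-identical outputs.

## Problem sizes

The shipped analyses are desk-scale by design: the cohort is 24 rows, the
default phantom is a 64×64×88 grid (seconds to generate and blur), the
brute-force volumetry oracle runs on ~10³-voxel maps, and the replicate
studies (ranking property, power checks) use 200–400 seeded replicates of
24-patient cohorts. The full test suite runs in well under a minute.

## Known limitations

* The prescription logic for intermediate cases (neither rule's guard
  condition met) is a documented surrogate; the clinical protocol it
  abstracts is not fully specified in the public record.
* The isocontour threshold reference (VOI-local maximum) and the TNR ROI
  protocol are likewise surrogates for under-specified clinical procedures.
* No voxel-level dosimetry, BSA-family formulas, decay-timing or
  microsphere-count modelling; no DICOM ingestion (NIfTI only); no
  attenuation or scatter in the planar model.
* Whether the fictitious 1 GBq comparison deducts the lung shunt before or
  after assigning activity per modality is unstated in the source; the
  package applies $(1-h)$ uniformly across modalities, which cancels in
  percent changes.
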