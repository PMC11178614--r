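---
title: "Methods: automated bone-marrow PET quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated bone-marrow PET quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowquant)
```

## The problem

In multiple myeloma, [18F]FDG PET/CT carries prognostic information through
both focal hypermetabolic lesions and diffuse bone-marrow (BM) infiltration,
but visual reading is poorly standardized. `marrowquant` implements an
automated, whole-body, threshold-based quantification of BM glucose
metabolism: the skeleton is partitioned on CT, an SUV cutoff defines
pathological marrow uptake, and the segmented volume yields the metabolic
tumor volume (MTV, mL) and total lesion glycolysis (TLG = SUVmean x MTV, g).
Ten alternative cutoff rules are implemented side by side, referenced either
to the patient's own liver or muscle uptake or to absolute SUV constants.
Downstream, the package provides the full prognostic toolchain (Spearman
correlation with marrow infiltration, Kaplan-Meier, log-rank, Cox models,
ROC with Youden cut points, ISS/R-ISS staging) and an automated,
IMPeTUs-style structured reading.

Because no patient cohort ships with the package, every stage is validated
on seeded digital phantoms and simulated survival cohorts with known ground
truth. This vignette records the modelling choices, defaults and their
rationale, and what the synthetic validation does and does not establish.

## Quantification model

**Skeletal partition.** The axial skeleton (vertebrae, scapulae, clavicles,
sternum, ribs, sacrum, pelvis) and the extremities (humeri, femora) are
treated as separate compartments with separate thresholds; the skull is
segmented but excluded from all analysis, because physiological brain uptake
spills into calvarial marrow at PET resolution. For real CT, bone extraction
is an HU threshold (default 150 HU) followed by morphological closing; for
phantoms, masks come from the ground-truth label map. The learned organ
segmentation used clinically is out of scope here — the quantification
rules, not the segmenter, are what this package tests.

**The ten threshold approaches.** For reference statistics we use the median
and mean SUV over the full liver mask and the median over the full muscle
mask (no sub-VOI sphere: a fixed VOI protocol is not part of the method
definition, and full-mask statistics are exactly reproducible). The rules
are, per compartment (axial / extremities):

| id | axial | extremities |
|----|----------------------------|----------------------------|
| 1  | liver SUVmedian x 1.1 | muscle SUVmedian x 4 |
| 2  | liver SUVmedian x 1.5 | muscle SUVmedian x 4 |
| 3  | 2.5 | 2.5 |
| 4  | 2.5 | 2.0 |
| 5  | liver SUVmedian | liver SUVmedian |
| 6  | liver SUVmedian | muscle SUVmedian x 4 |
| 7  | liver SUVmedian x 1.2 | liver SUVmedian x 1.2 |
| 8  | liver SUVmedian x 1.2 | muscle SUVmedian x 4 |
| 9  | liver SUVmean | liver SUVmean |
| 10 | 3.0 | 3.0 |

Segmentation is inclusive: a voxel with SUV **at or equal to** the threshold
is positive. MTV is voxel count times voxel volume; SUVmean is averaged over
segmented voxels only; TLG is their product, so the identity
`tlg = suv_mean * mtv` holds to machine precision by construction and is
regression-tested at 1e-9 relative tolerance.

**Spillover refinement.** Uptake from adjacent hot organs can bleed into the
bone mask. `refine_bone_mask()` is deliberately contractive: erosion of the
bone compartments (default 1 voxel, 26-connectivity box element) plus an
optional exclusion margin around liver and mediastinum (default 0 mm). The
exact clinical postprocessing is not specified at this level of detail, so
both knobs are exposed rather than guessed; the invariant that refinement
never adds voxels is property-tested. Refinement is applied *before*
thresholding. For phantom batches `run_quantification()` defaults to erosion
0: phantom masks are ground-truth labels with no point-spread blur, so there
is no spillover to mitigate and lesion recovery stays exact.

## IMPeTUs-style reading

The structured reading covers: the diffuse marrow Deauville score (DS) read
in the lower lumbar spine after excluding focal-lesion voxels; the focal
medullary lesion count with the 4-level F bins (0 / 1–3 / 4–10 / >10) and
locations (skull / spine / other); the DS of the hottest lesion; the CT
lytic lesion count with the same L bins; and fracture, paramedullary (PMD)
and extramedullary (EMD) disease flags.

Decisions where the printed 5-point rules leave gaps:

* DS 3 covers "above blood pool, up to liver"; DS 4 starts "above liver
  + 10%". Targets in the gap `(liver, 1.1 x liver]` score 3 — conservative
  and continuous with the DS-3 rule.
* DS 5 ("far above liver") is read as a factor-2 rule: target >= 2 x liver.
* "No uptake at all" (DS 1) is target <= 0.1 SUV by default (`epsilon`).

A focal lesion has no published numeric definition, so detection is
parameterized: connected components (26-connectivity throughout) of bone
voxels with SUV >= `detection_factor` (default 2.0) times the diffuse marrow
background (the median SUV over the bone compartments — robust to the
lesions themselves), minimum 3 voxels. PMD is a hypermetabolic component
spanning bone and adjacent soft tissue (such a lesion also counts as a focal
bone lesion); EMD is a component entirely outside bone. Reference organs
(liver, muscle, mediastinum) and the skull are excluded from candidacy, a
stand-in for the physiological-uptake masking a human reader performs.
Lytic lesions on CT are components of HU <= 40 inside bone (min 3 voxels) —
a phantom-oriented proxy, explicitly not a clinical criterion. Fractures are
carried as an annotation, not detected from the image. If the mediastinum
mask is missing, DS items are reported `NA`, never guessed.

## The synthetic data: what it emulates

**Phantoms** are axis-aligned primitives (boxes for spine with a lumbar VOI,
pelvis, a rib/sternum plate, skull, humeri, femora, liver, thigh muscle,
mediastinal blood pool) on a 48 x 48 x 72 grid at 4 mm isotropic spacing —
about a 19 x 19 x 29 cm field of view, coarse but sufficient to exercise
every rule while keeping brute-force test oracles exact. Defaults follow
typical clinical values: liver SUV 2.0, mediastinal blood pool 1.6, muscle
0.6, soft tissue 0.4, non-infiltrated marrow 1.0. Diffuse disease raises
marrow SUV linearly: `1.0 + 2.0 x infiltration_fraction`, so full
infiltration reaches SUV 3.0 — the range over which the ten thresholds
genuinely disagree, which is the regime the method is about. Focal lesions
are spheres (center voxel, radius in mm, SUV); ground truth records their
exact voxel volumes. Noise is i.i.d. Gaussian on SUV, default sd 0.05 —
small relative to every threshold gap, keeping reference medians stable
while still exercising the noise path. CT is two-valued (bone 700 HU, soft
40 HU) with lytic lesions carved to soft HU.

Deliberately **not** modelled: scanner physics (point-spread blur, scatter,
partial-volume effects, reconstruction artifacts), anatomical mesh realism,
SUV normalization variants, and DICOM. Consequently, passing tests show the
*rules* are implemented exactly and behave as designed — they do not show
robustness to PET resolution effects, which is precisely what the spillover
refinement's configurability is for on real data.

**Cohorts** draw event times from a constant-baseline proportional-hazards
model, `h(t|x) = h0 exp(b_mtv MTV + b_cyto HR + b_inf INF)`, with
administrative censoring at 120 months plus uniform dropout (15% of
subjects). Defaults mirror a newly diagnosed myeloma population: MTV
log-normal with median 200 mL; infiltration Beta-distributed with mean
about 40%; high-risk cytogenetics and elevated LDH each 20% prevalent;
beta2-microglobulin log-normal with median 3.0 mg/L; albumin near
4.0 g/dL. Effect sizes default to the magnitude reported for this kind of
cohort: hazard ratio about 1.0012 per mL of MTV and about 1.9 for high-risk
cytogenetics; baseline hazard 0.01/month. TLG is MTV scaled by a noisy
lesion-level SUVmean so the two markers are strongly but not perfectly
correlated, as in practice.

## Statistical stage

Standard estimators are delegated to the field's packages — `survival` for
Kaplan-Meier, log-rank and Cox (Efron ties by default, Breslow available),
`stats` for Spearman with midrank ties, `pROC` for AUC with DeLong CI — while
the method-specific logic (median dichotomization with ties going low,
per the "higher than the median" convention; the Youden cut scan with ties
broken toward the lower cut; horizon classification) is implemented here
and checked against brute-force oracles in the tests. Follow-up time uses
the reverse Kaplan-Meier estimator. No multiple-testing correction is
applied anywhere: the analyses are exploratory by design, and the package
does not adjust p-values silently.

For the 2-year outcome, the default ROC design is the simple binary one:
subjects censored before the horizon are non-evaluable and excluded. A
time-dependent alternative — inverse-probability-of-censoring weighting with
weights from the reverse-KM censoring curve — is available via
`roc_at_horizon(..., mode = "ipcw")`, because with heavy early censoring the
binary design can bias the AUC; neither mode is claimed to be canonical, and
with little early censoring they agree (tested).

ISS uses the standard rule grid (I: beta2-microglobulin < 3.5 mg/L and
albumin >= 3.5 g/dL; III: beta2-microglobulin > 5.5 mg/L; II otherwise);
R-ISS I additionally requires no high-risk abnormality and normal LDH, and
R-ISS III requires ISS III plus high-risk cytogenetics or elevated LDH. The
full truth table is enumerated in the tests.

## Numerical choices and degenerate inputs

* Even-count medians are midpoints of the central pair (`stats::median`).
* Empty segmentations are valid results: MTV = TLG = 0.
* Empty liver or muscle masks are hard errors (the thresholds would be
  undefined), naming the offending mask.
* A lumbar VOI fully covered by focal lesions raises an error asking for
  manual review rather than scoring diffuse uptake from lesion voxels.
* Morphology uses separable box structuring elements (Chebyshev balls),
  consistent with 26-connectivity; mm radii convert to voxel radii by
  `floor(r/spacing)` per axis.
* All generators are pure functions of their config including the seed; the
  caller's RNG state is saved and restored.
* Component labelling is renumbered by first linear index, so lesion ids are
  invariant to internal traversal order.

## Validation scale

The test suite runs the heavy checks at sizes chosen to keep the whole suite
around half a minute on one core while leaving the statistical checks
well-powered: 1000 random 8^3 grids for the MTV/TLG oracle equivalence, 200
replicates of n = 500 for CI coverage, 400 replicates of n = 200 for the
null type-I error, 1000 log-rank replicates for the null-uniformity KS
check, and n = 2000 for the closed-form KM and null-AUC checks. The analysis
drivers under `analysis/` use 12-phantom series and an n = 200 cohort for
the same reason.

## Known limitations

* The HU-threshold skeleton is a stand-in: on real CT it will include
  non-marrow cortical bone and miss osteopenic bone; the clinical method's
  learned segmentation is explicitly out of scope.
* Whole-body MTV only; per-lesion MTV reporting is not implemented.
* The IMPeTUs reader is a single deterministic reader; inter-observer
  variability is not modelled.
* Phantom geometry is coarse; absolute MTV magnitudes on phantoms should not
  be compared with clinical values, only their ordering and coupling
  behaviour.
* SUV is taken as given; dose/weight/decay normalization is upstream of this
  package.
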