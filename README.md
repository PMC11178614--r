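# marrowquant

Automated, whole-body quantification of bone-marrow (BM) glucose metabolism
on [18F]FDG PET/CT for multiple myeloma, with the downstream prognostic
statistics — validated end to end on seeded digital phantoms and simulated
survival cohorts, so no patient data is required to exercise any stage.

## What it computes

PET reading in myeloma is hard to standardize. The approach implemented here
replaces visual scoring with a threshold pipeline:

1. **Anatomy** — the skeleton is extracted from CT (HU threshold + closing,
   or ground-truth labels for phantoms), partitioned into the *axial*
   skeleton and the *extremities*, with the skull excluded (physiological
   brain uptake contaminates calvarial marrow). Contractive spillover
   refinement (erosion, reference-organ exclusion margin) is available.
2. **Quantification** — ten SUV cutoff rules are applied per compartment,
   referenced to the patient's own liver SUV median/mean, 4x the muscle SUV
   median, or absolute constants (2.5, 3.0). Voxels with SUV ≥ threshold
   are pathological; MTV (mL) is their volume and TLG (g) = SUVmean x MTV.
3. **IMPeTUs-style reading** — diffuse marrow Deauville score from the
   lumbar spine, focal lesion count with F bins (0 / 1–3 / 4–10 / >10) and
   locations, hottest-lesion score, CT lytic lesion count with L bins,
   fracture, paramedullary (PMD) and extramedullary (EMD) disease flags.
4. **Prognostics** — Spearman correlation with marrow plasma-cell
   infiltration, Kaplan–Meier with median survival and inverse-KM follow-up,
   log-rank on median-dichotomized markers, uni-/multivariable Cox
   (HR, 95% CI, p per covariate), ROC with Youden-optimal cut points for the
   2-year outcome (binary or IPCW design), and ISS/R-ISS staging.

The `synthetic` layer generates PET/CT phantoms with known planted lesion
volumes and diffuse uptake monotone in the infiltration fraction, and
survival cohorts from a proportional-hazards model with MTV as covariate —
the ground truth every test and calibration check compares against.

## Worked example

```r
library(marrowquant)

cfg <- phantom_config(
  infiltration_fraction = 0.5,            # diffuse marrow SUV = 1 + 2*0.5
  lesion_specs = list(
    list(center = c(24, 24, 30), radius_mm = 8, suv = 6, compartment = "axial"),
    list(center = c(24, 24, 46), radius_mm = 6, suv = 7, compartment = "axial")),
  noise_sd = 0.05, seed = 7)
ph    <- generate_phantom(cfg)
bone  <- array(ph$label_map %in% bone_label_codes(), dim = dim(ph$label_map))
masks <- partition_regions(bone, ph$label_map, cfg$spacing_mm)

quant <- quantify_all_approaches(ph$suv, masks)
quant[, c("approach", "axial_threshold", "mtv_ml", "tlg_g")]
#>    approach axial_threshold mtv_ml tlg_g
#> 1         1             2.2   3.33  21.2
#> 4         4             2.5  20.54  56.3
#> 5         5             2.0 167.23 355.7
#> 9         9             2.0 171.39 364.0
#> 10       10             3.0   3.33  21.2    (6 rows omitted)

assemble_impetus_report(ph$suv, ph$ct, masks, ph$label_map)
#> <impetus_report>
#>   diffuse marrow DS: 3 (lumbar SUVmean 1.99)
#>   focal lesions: 2 (F2), hottest DS 5, locations: spine
#>   lytic lesions: 0 (L1)
#>   fracture: FALSE, PMD: FALSE, EMD: FALSE
```

With diffuse marrow uptake sitting exactly at the liver median, the
liver-referenced approaches (5, 9) segment ~170 mL of diffuse disease while
the stricter cutoffs (2.2–3.0) see only the two planted focal lesions
(3.3 mL) — the threshold choice *is* the result, which is why all ten are
reported side by side. The reading scores the diffuse uptake DS 3 (above
blood pool, at liver level) and bins the two focal spine lesions as F2.

For the survival stage on a simulated cohort:

```r
co  <- generate_cohort(cohort_config(n_subjects = 200, seed = 20260903))
st  <- run_survival_study(co)   # KM, log-rank, Cox, ROC at 24 months
st$cox_univariable[, c("marker", "hr", "hr_lower", "hr_upper", "p")]
#>  marker      hr hr_lower hr_upper           p
#>  mtv_ml 1.00126  1.00075  1.00178 1.55507e-06
#>   tlg_g 1.00031  1.00017  1.00046 1.68801e-05
```

i.e. a hazard ratio of ~1.0013 per mL of MTV, recovering the simulated
effect (1.0012/mL) with its 95% CI.

The `analysis/` directory contains the numbered study drivers
(`01_phantom_quantification.R` … `04_calibration.R`) that produce the
tables under `results/`; each prints a short narrative of what it found.

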