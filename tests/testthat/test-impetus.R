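test_that("Deauville scoring matches the printed 5-point rules exactly", {
  med <- 1.6; liv <- 2.0
  expect_identical(deauville_score(0, med, liv), 1L)
  expect_identical(deauville_score(med, med, liv), 2L)       # = blood pool
  expect_identical(deauville_score(1.8, med, liv), 3L)       # <= liver
  expect_identical(deauville_score(1.1 * liv, med, liv), 3L) # gap rule
  expect_identical(deauville_score(2.3, med, liv), 4L)       # > liver + 10%
  expect_identical(deauville_score(3.9, med, liv), 4L)       # < 2x liver
  expect_identical(deauville_score(4.0, med, liv), 5L)       # 2x liver
  expect_identical(deauville_score(4.5, med, liv), 5L)
  # exhaustive ratio grid: target = r x liver for a fine grid of r
  r <- seq(0, 3, by = 0.01)
  sc <- deauville_score(r * liv, med, liv)
  expect_true(all(sc[r * liv <= 0.1] == 1L))
  expect_true(all(sc[r * liv > 0.1 & r * liv <= med] == 2L))
  expect_true(all(sc[r * liv > med & r <= 1.1] == 3L))
  expect_true(all(sc[r > 1.1 & r < 2] == 4L))
  expect_true(all(sc[r >= 2] == 5L))
  expect_error(deauville_score(-1, med, liv), "nonnegative")
})

test_that("Deauville score is monotone nondecreasing in the target", {
  set.seed(14)
  for (rep in 1:50) {
    med <- stats::runif(1, 0.5, 3)
    liv <- stats::runif(1, 0.5, 3)
    targets <- sort(stats::runif(40, 0, 8))
    sc <- deauville_score(targets, med, liv)
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("F/L bins match the printed scheme for all counts 0..20", {
  expected <- c(1L, rep(2L, 3), rep(3L, 7), rep(4L, 10))
  expect_identical(bin_count_score(0:20), expected)
  expect_true(all(diff(bin_count_score(0:20)) >= 0))
  expect_error(bin_count_score(-1), "nonnegative")
})

test_that("diffuse marrow score uses the lumbar mean with lesions excluded", {
  masks <- make_small_masks()
  suv <- paint_suv(masks, bone = 1.5, liver = 2.0, mediastinum = 1.6)
  # uniform lumbar at blood-pool level -> DS 2
  suv$values[masks$lumbar_spine] <- 1.6
  r <- diffuse_bm_score(suv, masks$lumbar_spine, NULL, 1.6, 2.0)
  expect_identical(r$score, 2L)
  # one hot focal voxel must not drag the mean: score from 1.5, not 10
  suv$values[masks$lumbar_spine] <- 1.5
  hot <- which(masks$lumbar_spine)[1]
  suv$values[hot] <- 10
  focal <- array(FALSE, dim = dim(suv$values)); focal[hot] <- TRUE
  r2 <- diffuse_bm_score(suv, masks$lumbar_spine, focal, 1.6, 2.0)
  expect_equal(r2$lumbar_suv_mean, 1.5)
  expect_identical(r2$score, 2L)
  # lumbar at twice liver -> DS 5
  suv$values[masks$lumbar_spine] <- 4.0
  r3 <- diffuse_bm_score(suv, masks$lumbar_spine, NULL, 1.6, 2.0)
  expect_identical(r3$score, 5L)
  # fully covered lumbar -> explicit error
  allfoc <- masks$lumbar_spine
  expect_error(diffuse_bm_score(suv, masks$lumbar_spine, allfoc, 1.6, 2.0),
               "manual review")
})

test_that("focal lesion detection counts connected components correctly", {
  cfg0 <- phantom_config(infiltration_fraction = 0.3, noise_sd = 0)
  ph0 <- generate_phantom(cfg0)
  bone0 <- array(ph0$label_map %in% bone_label_codes(), dim = dim(ph0$label_map))
  masks0 <- partition_regions(bone0, ph0$label_map, cfg0$spacing_mm)
  les0 <- detect_focal_lesions(ph0$suv, masks0, ph0$label_map)
  expect_identical(nrow(les0), 0L)   # homogeneous marrow -> no lesions

  # two disjoint hot spheres in the spine -> 2 components
  cfg2 <- phantom_config(
    infiltration_fraction = 0.3,
    lesion_specs = list(
      list(center = c(24, 24, 28), radius_mm = 6, suv = 6, compartment = "axial"),
      list(center = c(24, 24, 50), radius_mm = 6, suv = 6, compartment = "axial")),
    noise_sd = 0)
  ph2 <- generate_phantom(cfg2)
  masks2 <- partition_regions(array(ph2$label_map %in% bone_label_codes(),
                                    dim = dim(ph2$label_map)),
                              ph2$label_map, cfg2$spacing_mm)
  les2 <- detect_focal_lesions(ph2$suv, masks2, ph2$label_map)
  expect_identical(nrow(les2), 2L)
  expect_true(all(les2$location == "spine"))

  # two hot spheres sharing a face merge into one 26-connected component
  cfg1 <- phantom_config(
    infiltration_fraction = 0.3,
    lesion_specs = list(
      list(center = c(24, 24, 30), radius_mm = 4.1, suv = 6, compartment = "axial"),
      list(center = c(24, 24, 33), radius_mm = 4.1, suv = 6, compartment = "axial")),
    noise_sd = 0)
  ph1 <- generate_phantom(cfg1)
  masks1 <- partition_regions(array(ph1$label_map %in% bone_label_codes(),
                                    dim = dim(ph1$label_map)),
                              ph1$label_map, cfg1$spacing_mm)
  les1 <- detect_focal_lesions(ph1$suv, masks1, ph1$label_map)
  expect_identical(nrow(les1), 1L)
  expect_error(detect_focal_lesions(ph1$suv, masks1, ph1$label_map,
                                    detection_factor = 1), "> 1")
})

test_that("constructed phantoms yield the designed report", {
  # 2 medullary lesions + 1 extra-osseous lesion:
  # focal_count 2, F2, EMD flagged, no PMD
  cfg <- phantom_config(
    infiltration_fraction = 0.3,
    lesion_specs = list(
      list(center = c(24, 24, 28), radius_mm = 6, suv = 6, compartment = "axial"),
      list(center = c(24, 24, 50), radius_mm = 6, suv = 7, compartment = "axial"),
      list(center = c(14, 24, 30), radius_mm = 5, suv = 5,
           compartment = "extramedullary")),
    lytic_specs = list(list(center = c(24, 24, 20), radius_mm = 5)),
    fracture = TRUE,
    noise_sd = 0)
  ph <- generate_phantom(cfg)
  masks <- partition_regions(array(ph$label_map %in% bone_label_codes(),
                                   dim = dim(ph$label_map)),
                             ph$label_map, cfg$spacing_mm)
  rep <- assemble_impetus_report(ph$suv, ph$ct, masks, ph$label_map,
                                 fracture = ph$truth$fracture)
  expect_identical(rep$focal_count, 2L)
  expect_identical(rep$f_score, 2L)
  expect_true(rep$emd_flag)
  expect_false(rep$pmd_flag)
  expect_true(rep$fracture_flag)
  expect_identical(rep$lytic_count, 1L)
  expect_identical(rep$l_score, 2L)
  # hottest lesion SUV 7 >= 2x liver (2.0) -> DS 5
  expect_identical(rep$hottest_ds, 5L)

  # lesion spanning the bone boundary: PMD true, EMD false
  cfg_pmd <- phantom_config(
    infiltration_fraction = 0.3,
    lesion_specs = list(
      list(center = c(22, 24, 30), radius_mm = 6, suv = 6,
           compartment = "paramedullary")),
    noise_sd = 0)
  ph2 <- generate_phantom(cfg_pmd)
  masks2 <- partition_regions(array(ph2$label_map %in% bone_label_codes(),
                                    dim = dim(ph2$label_map)),
                              ph2$label_map, cfg_pmd$spacing_mm)
  rep2 <- assemble_impetus_report(ph2$suv, ph2$ct, masks2, ph2$label_map)
  expect_true(rep2$pmd_flag)
  expect_false(rep2$emd_flag)

  # no lesions anywhere: F1, hottest DS absent, flags false
  cfg0 <- phantom_config(infiltration_fraction = 0.2, noise_sd = 0)
  ph0 <- generate_phantom(cfg0)
  masks0 <- partition_regions(array(ph0$label_map %in% bone_label_codes(),
                                    dim = dim(ph0$label_map)),
                              ph0$label_map, cfg0$spacing_mm)
  rep0 <- assemble_impetus_report(ph0$suv, ph0$ct, masks0, ph0$label_map)
  expect_identical(rep0$focal_count, 0L)
  expect_identical(rep0$f_score, 1L)
  expect_true(is.na(rep0$hottest_ds))
  expect_false(rep0$pmd_flag)
  expect_false(rep0$emd_flag)
  expect_identical(rep0$lytic_count, 0L)

  # missing mediastinum: Deauville items reported NA, counts still computed
  masks_nomed <- masks
  masks_nomed$mediastinum[] <- FALSE
  rep3 <- assemble_impetus_report(ph$suv, ph$ct, masks_nomed, ph$label_map)
  expect_true(is.na(rep3$diffuse_ds))
  expect_true(is.na(rep3$hottest_ds))
  expect_identical(rep3$focal_count, 2L)
})
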