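#' Digital PET/CT phantom configuration
#'
#' Describes a whole-body phantom built from axis-aligned primitives: a
#' vertebral column with a lumbar VOI, pelvis, a rib/sternum plate, skull,
#' humeri and femora (extremities), liver, thigh muscle and the mediastinal
#' blood pool. Bone voxels carry a diffuse bone-marrow SUV that increases
#' linearly with the plasma-cell infiltration fraction; focal lesions are
#' spheres that overwrite the local SUV.
#'
#' Default reference uptake follows typical clinical values: liver SUV about
#' 2.0, mediastinal blood pool slightly below the liver, muscle well below
#' both, and non-infiltrated marrow near 1.0.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param spacing_mm positive triple, voxel spacing in mm.
#' @param geometry list of region primitives; each element is a list with
#'   `label` (name from [label_vocabulary()]), `type` ("box" or "ellipsoid"),
#'   and inclusive voxel bounds `min`/`max` (box) or `center`/`semi_axes_vox`
#'   (ellipsoid). `NULL` uses the built-in whole-body layout.
#' @param liver_suv,muscle_suv,mediastinum_suv,soft_suv mean SUV of the
#'   reference organs and of unlabeled soft tissue.
#' @param bm_baseline_suv diffuse marrow SUV at zero infiltration.
#' @param infiltration_fraction plasma-cell infiltration fraction in `[0, 1]`.
#' @param diffuse_gain SUV increment of diffuse marrow uptake per unit
#'   infiltration fraction (marrow SUV = baseline + gain x fraction).
#' @param lesion_specs list of lesions; each a list with `center` (voxel
#'   triple), `radius_mm`, `suv`, and `compartment` (one of "axial",
#'   "extremity", "paramedullary", "extramedullary").
#' @param lytic_specs list of CT lytic lesions (same `center`/`radius_mm`
#'   fields); carved into bone on CT at soft-tissue HU.
#' @param fracture logical annotation carried into the ground truth (fracture
#'   reading on CT is an annotation, not an image-derived quantity here).
#' @param ct_bone_hu,ct_soft_hu CT attenuation of bone and soft tissue (HU).
#' @param noise_sd standard deviation of i.i.d. Gaussian SUV noise (0 = none).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 72L),
                           spacing_mm = c(4, 4, 4),
                           geometry = NULL,
                           liver_suv = 2.0,
                           muscle_suv = 0.6,
                           mediastinum_suv = 1.6,
                           soft_suv = 0.4,
                           bm_baseline_suv = 1.0,
                           infiltration_fraction = 0,
                           diffuse_gain = 2.0,
                           lesion_specs = list(),
                           lytic_specs = list(),
                           fracture = FALSE,
                           ct_bone_hu = 700,
                           ct_soft_hu = 40,
                           noise_sd = 0.05,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be strictly positive")
  for (s in c(liver_suv, muscle_suv, mediastinum_suv, soft_suv, bm_baseline_suv))
    if (!is.finite(s) || s <= 0) stop("all SUV parameters must be positive")
  if (infiltration_fraction < 0 || infiltration_fraction > 1)
    stop("`infiltration_fraction` must lie in [0, 1]")
  if (diffuse_gain <= 0) stop("`diffuse_gain` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (is.null(geometry)) geometry <- default_phantom_geometry()
  cfg <- list(grid_shape = grid_shape, spacing_mm = spacing_mm,
              geometry = geometry, liver_suv = liver_suv,
              muscle_suv = muscle_suv, mediastinum_suv = mediastinum_suv,
              soft_suv = soft_suv, bm_baseline_suv = bm_baseline_suv,
              infiltration_fraction = infiltration_fraction,
              diffuse_gain = diffuse_gain, lesion_specs = lesion_specs,
              lytic_specs = lytic_specs, fracture = isTRUE(fracture),
              ct_bone_hu = ct_bone_hu, ct_soft_hu = ct_soft_hu,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# built-in whole-body layout (voxel bounds on the default 48x48x72 grid):
# disjoint boxes for spine (with lumbar VOI), pelvis, rib/sternum plate,
# skull, femora, humeri, liver, thigh muscle and mediastinum
default_phantom_geometry <- function() {
  box <- function(label, min, max) list(label = label, type = "box",
                                        min = as.integer(min), max = as.integer(max))
  list(
    box("lumbar_spine",   c(22, 22, 10), c(27, 27, 17)),
    box("spine",          c(22, 22, 18), c(27, 27, 58)),
    box("axial_bone",     c(14, 18,  4), c(35, 31,  9)),   # pelvis
    box("axial_bone",     c(16, 10, 36), c(33, 12, 54)),   # sternum/rib plate
    box("skull",          c(19, 19, 62), c(30, 30, 70)),
    box("extremity_bone", c(16, 22,  1), c(19, 25,  3)),   # left femur
    box("extremity_bone", c(30, 22,  1), c(33, 25,  3)),   # right femur
    box("extremity_bone", c( 4, 22, 40), c( 7, 25, 54)),   # left humerus
    box("extremity_bone", c(40, 22, 40), c(43, 25, 54)),   # right humerus
    box("liver",          c(30, 26, 38), c(41, 37, 50)),
    box("muscle",         c( 8, 16,  1), c(13, 31,  9)),   # left thigh
    box("muscle",         c(36, 16,  1), c(43, 31,  9)),   # right thigh
    box("mediastinum",    c(22, 14, 40), c(27, 19, 50))
  )
}

region_voxel_mask <- function(region, grid_shape) {
  m <- array(FALSE, dim = grid_shape)
  if (region$type == "box") {
    lo <- pmax(region$min, 1L); hi <- pmin(region$max, grid_shape)
    if (any(lo > hi)) return(m)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else if (region$type == "ellipsoid") {
    co <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
    u <- sweep(co, 2, region$center, "-")
    u <- sweep(u, 2, region$semi_axes_vox, "/")
    m[rowSums(u^2) <= 1] <- TRUE
  } else stop("unknown region type: ", region$type)
  m
}

# voxels whose centres lie within radius_mm of the given centre voxel
sphere_voxels <- function(center, radius_mm, spacing_mm, grid_shape) {
  r_vox <- ceiling(radius_mm / spacing_mm)
  lo <- pmax(center - r_vox, 1); hi <- pmin(center + r_vox, grid_shape)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  co <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dmm <- sweep(co, 2, center, "-")
  dmm <- sweep(dmm, 2, spacing_mm, "*")
  co[rowSums(dmm^2) <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Generate a digital PET/CT phantom
#'
#' Builds the label map from the configured geometry, the CT grid (bone at
#' `ct_bone_hu`, everything else at `ct_soft_hu`, lytic lesions carved to
#' soft-tissue HU), and the SUV grid (organ means, diffuse marrow uptake
#' `bm_baseline_suv + diffuse_gain * infiltration_fraction`, focal lesions
#' overwriting the local SUV, then optional Gaussian noise). The ground truth
#' records exact planted lesion volumes (voxel count x voxel volume).
#'
#' @param config a [phantom_config()].
#' @return list with elements `ct` and `suv` ([voxel_grid()]s), `label_map`
#'   (integer array), and `truth` (list: `lesions` data.frame with per-lesion
#'   voxel counts/volumes, `lesion_volume_by_compartment_ml`,
#'   `infiltration_fraction`, `bm_suv_true`, `liver_suv_true`,
#'   `muscle_suv_true`, `fracture`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  voc <- label_vocabulary()
  labels <- array(voc[["background"]], dim = d)
  for (region in config$geometry) {
    code <- voc[[region$label]]
    if (is.null(code)) stop("unknown region label: ", region$label)
    labels[region_voxel_mask(region, d)] <- code
  }

  ct <- array(config$ct_soft_hu, dim = d)
  bone <- array(labels %in% bone_label_codes(), dim = d)
  ct[bone] <- config$ct_bone_hu

  bm_suv <- config$bm_baseline_suv +
    config$diffuse_gain * config$infiltration_fraction
  suv <- array(config$soft_suv, dim = d)
  suv[bone] <- bm_suv
  suv[labels == voc[["liver"]]] <- config$liver_suv
  suv[labels == voc[["muscle"]]] <- config$muscle_suv
  suv[labels == voc[["mediastinum"]]] <- config$mediastinum_suv

  vv <- voxel_volume_ml(config$spacing_mm)
  n_les <- length(config$lesion_specs)
  lesions <- data.frame(
    lesion = seq_len(n_les),
    compartment = character(n_les),
    suv = numeric(n_les),
    radius_mm = numeric(n_les),
    voxels = integer(n_les),
    volume_ml = numeric(n_les),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_les)) {
    les <- config$lesion_specs[[i]]
    ctr <- as.integer(les$center)
    if (any(ctr < 1L) || any(ctr > d))
      stop(sprintf("lesion %d center (%s) lies outside the grid", i,
                   paste(ctr, collapse = ",")))
    r_vox <- ceiling(les$radius_mm / config$spacing_mm)
    if (any(ctr - r_vox < 1L) || any(ctr + r_vox > d))
      stop(sprintf("lesion %d (radius %.1f mm) extends outside the grid", i,
                   les$radius_mm))
    vox <- sphere_voxels(ctr, les$radius_mm, config$spacing_mm, d)
    lin <- (vox[, 3] - 1L) * (d[1] * d[2]) + (vox[, 2] - 1L) * d[1] + vox[, 1]
    suv[lin] <- les$suv
    lesions$compartment[i] <- les$compartment
    lesions$suv[i] <- les$suv
    lesions$radius_mm[i] <- les$radius_mm
    lesions$voxels[i] <- nrow(vox)
    lesions$volume_ml[i] <- nrow(vox) * vv
  }

  for (lyt in config$lytic_specs) {
    vox <- sphere_voxels(as.integer(lyt$center), lyt$radius_mm,
                         config$spacing_mm, d)
    lin <- (vox[, 3] - 1L) * (d[1] * d[2]) + (vox[, 2] - 1L) * d[1] + vox[, 1]
    keep <- bone[lin]
    ct[lin[keep]] <- config$ct_soft_hu
  }

  if (config$noise_sd > 0) {
    suv <- with_rng_seed(config$seed, {
      suv + array(stats::rnorm(prod(d), 0, config$noise_sd), dim = d)
    })
  }

  comp_vol <- tapply(lesions$volume_ml, lesions$compartment, sum)
  truth <- list(
    lesions = lesions,
    lesion_volume_by_compartment_ml = comp_vol,
    total_lesion_volume_ml = sum(lesions$volume_ml),
    infiltration_fraction = config$infiltration_fraction,
    bm_suv_true = bm_suv,
    liver_suv_true = config$liver_suv,
    muscle_suv_true = config$muscle_suv,
    fracture = config$fracture
  )

  list(ct = voxel_grid(ct, config$spacing_mm),
       suv = voxel_grid(suv, config$spacing_mm),
       label_map = labels,
       truth = truth)
}

# --- survival cohort simulator ---------------------------------------------

#' Simulated survival cohort configuration
#'
#' Event times follow a proportional-hazards model with constant baseline
#' hazard: `h(t | x) = baseline_hazard * exp(beta_mtv*MTV + beta_cyto*cyto +
#' beta_infiltration*infiltration)`. Observation is cut by administrative
#' censoring at `horizon_months` and, independently, by uniform dropout on
#' `(0, horizon)` affecting a `dropout_rate` fraction of subjects.
#'
#' Covariate marginals mirror a newly diagnosed myeloma population: MTV is
#' log-normal (median about 200 mL), infiltration is Beta-distributed with
#' mean about 40%, high-risk cytogenetics about 20% prevalent,
#' beta2-microglobulin log-normal with median 3.0 mg/L, albumin Gaussian
#' around 4.0 g/dL, and elevated LDH about 20% prevalent.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param baseline_hazard events per month at covariates 0.
#' @param beta_mtv log-hazard per mL of MTV.
#' @param beta_cyto log-hazard for the high-risk cytogenetics flag.
#' @param beta_infiltration log-hazard per percentage point of infiltration.
#' @param mtv_meanlog,mtv_sdlog log-normal parameters of the MTV marginal.
#' @param horizon_months administrative censoring horizon (> 0).
#' @param dropout_rate fraction of subjects with a uniform dropout time.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 200L,
                          baseline_hazard = 0.01,
                          beta_mtv = 0.0012,
                          beta_cyto = log(1.9),
                          beta_infiltration = log(1.0028),
                          mtv_meanlog = log(200),
                          mtv_sdlog = 0.9,
                          horizon_months = 120,
                          dropout_rate = 0.15,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2")
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be positive")
  for (b in c(beta_mtv, beta_cyto, beta_infiltration))
    if (!is.finite(b)) stop("hazard coefficients must be finite")
  if (horizon_months <= 0) stop("`horizon_months` must be positive")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must lie in [0, 1]")
  structure(list(n_subjects = n_subjects, baseline_hazard = baseline_hazard,
                 beta_mtv = beta_mtv, beta_cyto = beta_cyto,
                 beta_infiltration = beta_infiltration,
                 mtv_meanlog = mtv_meanlog, mtv_sdlog = mtv_sdlog,
                 horizon_months = horizon_months, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `subject`, `mtv_ml`, `tlg_g`,
#'   `infiltration_pct`, `cyto_highrisk`, `b2m_mg_l`, `albumin_g_dl`,
#'   `ldh_high`, `time_months`, `event`. `tlg_g` is MTV scaled by a noisy
#'   lesion SUVmean so that MTV and TLG are strongly but not perfectly
#'   correlated, as in real cohorts.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  with_rng_seed(config$seed, {
    mtv <- stats::rlnorm(n, config$mtv_meanlog, config$mtv_sdlog)
    suv_mean <- stats::rlnorm(n, log(3), 0.2)
    infiltration <- 100 * stats::rbeta(n, 1.6, 2.4)
    cyto <- stats::rbinom(n, 1, 0.2)
    b2m <- stats::rlnorm(n, log(3.0), 0.5)
    albumin <- pmax(stats::rnorm(n, 4.0, 0.6), 1.5)
    ldh <- stats::rbinom(n, 1, 0.2)
    lp <- config$beta_mtv * mtv + config$beta_cyto * cyto +
      config$beta_infiltration * infiltration
    t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
    dropout <- ifelse(stats::runif(n) < config$dropout_rate,
                      stats::runif(n, 0, config$horizon_months), Inf)
    t_cens <- pmin(config$horizon_months, dropout)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    data.frame(subject = seq_len(n),
               mtv_ml = mtv,
               tlg_g = mtv * suv_mean,
               infiltration_pct = infiltration,
               cyto_highrisk = cyto,
               b2m_mg_l = b2m,
               albumin_g_dl = albumin,
               ldh_high = ldh,
               time_months = time,
               event = event)
  })
}
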