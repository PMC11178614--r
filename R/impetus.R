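#' Five-point Deauville score of a target uptake
#'
#' Scores a target SUV against the mediastinal blood pool and liver
#' references: 1 = no uptake at all (target at or below `epsilon`); 2 = at or
#' below the mediastinal blood pool; 3 = above the blood pool but at or below
#' 110% of liver uptake; 4 = above that but below twice liver uptake; 5 = at
#' or above twice liver uptake. The score is monotone nondecreasing in the
#' target for fixed references.
#'
#' @param target_suv nonnegative scalar (vectorised).
#' @param mediastinum_suv,liver_suv positive reference uptakes.
#' @param epsilon "no uptake" tolerance; default 0.1 SUV.
#' @return integer score(s) in 1..5.
#' @export
deauville_score <- function(target_suv, mediastinum_suv, liver_suv,
                            epsilon = 0.1) {
  if (any(target_suv < 0) || mediastinum_suv <= 0 || liver_suv <= 0)
    stop("target must be nonnegative and references positive")
  score <- rep(5L, length(target_suv))
  score[target_suv < 2 * liver_suv] <- 4L
  score[target_suv <= 1.1 * liver_suv] <- 3L
  score[target_suv <= mediastinum_suv] <- 2L
  score[target_suv <= epsilon] <- 1L
  score
}

#' Diffuse bone-marrow Deauville score from the lower lumbar spine
#'
#' The diffuse marrow metabolic state is read in the lower lumbar spine in
#' the absence of focal enhancement: mean lumbar SUV over voxels not covered
#' by any detected focal lesion, scored on the Deauville scale.
#'
#' @param suv a [voxel_grid()].
#' @param lumbar_mask logical array, nonempty.
#' @param focal_mask logical array of focal-lesion voxels (may be all-FALSE).
#' @param mediastinum_suv,liver_suv reference uptakes.
#' @param epsilon see [deauville_score()].
#' @return list `score` (1..5) and `lumbar_suv_mean`.
#' @export
diffuse_bm_score <- function(suv, lumbar_mask, focal_mask = NULL,
                             mediastinum_suv, liver_suv, epsilon = 0.1) {
  stopifnot(inherits(suv, "voxel_grid"))
  if (!any(lumbar_mask)) stop("lumbar spine mask is empty")
  eval_mask <- lumbar_mask
  if (!is.null(focal_mask)) eval_mask <- lumbar_mask & !focal_mask
  if (!any(eval_mask))
    stop("lumbar spine is fully covered by focal lesions; manual review required")
  m <- mean(suv$values[eval_mask])
  list(score = deauville_score(m, mediastinum_suv, liver_suv, epsilon),
       lumbar_suv_mean = m)
}

#' Score a lesion count on the 4-level F/L bins
#'
#' Identical bins for focal hypermetabolic (F) and CT lytic (L) lesions:
#' 1 = none, 2 = 1-3, 3 = 4-10, 4 = more than 10.
#'
#' @param n nonnegative integer count (vectorised).
#' @return integer score(s) in 1..4.
#' @export
bin_count_score <- function(n) {
  if (any(n < 0)) stop("lesion count must be nonnegative")
  ifelse(n == 0, 1L, ifelse(n <= 3, 2L, ifelse(n <= 10, 3L, 4L)))
}

# hypermetabolic candidate voxels: SUV >= factor x diffuse marrow background,
# with physiologically hot / reference organs excluded from candidacy
hypermetabolic_candidates <- function(suv, masks, label_map, detection_factor,
                                      background) {
  voc <- label_vocabulary()
  excl <- masks$liver | masks$muscle | masks$mediastinum | masks$skull
  cand <- suv$values >= detection_factor * background & !excl
  dim(cand) <- dim(suv$values)
  cand
}

#' Detect focal hypermetabolic lesions in the skeleton
#'
#' Connected components (26-connectivity) of bone voxels with SUV at or above
#' `detection_factor` times the diffuse marrow background (the median SUV
#' over the analyzed bone compartments), filtered by a minimum volume. Each
#' component is tagged skull / spine / other from the label map (majority
#' label among its voxels).
#'
#' @param suv a [voxel_grid()].
#' @param masks a [region_mask_set()].
#' @param label_map integer label array.
#' @param detection_factor multiplier above background (> 1); default 2.
#' @param min_volume_voxels minimum component size; default 3.
#' @return data.frame, one row per lesion: `lesion`, `voxels`, `volume_ml`,
#'   `suv_max`, `location`; attribute `lesion_mask` holds the combined
#'   logical mask and attribute `background_suv` the background estimate.
#' @export
detect_focal_lesions <- function(suv, masks, label_map, detection_factor = 2,
                                 min_volume_voxels = 3L) {
  stopifnot(inherits(suv, "voxel_grid"), inherits(masks, "region_mask_set"))
  if (detection_factor <= 1) stop("`detection_factor` must be > 1")
  bone <- masks$axial_bone | masks$extremity_bone
  empty <- data.frame(lesion = integer(0), voxels = integer(0),
                      volume_ml = numeric(0), suv_max = numeric(0),
                      location = character(0), stringsAsFactors = FALSE)
  if (!any(bone)) {
    attr(empty, "lesion_mask") <- array(FALSE, dim = dim(suv$values))
    attr(empty, "background_suv") <- NA_real_
    return(empty)
  }
  background <- stats::median(suv$values[bone])
  hot <- bone & (suv$values >= detection_factor * background)
  comp <- label_components(hot)
  vv <- voxel_volume_ml(suv$spacing_mm)
  voc <- label_vocabulary()
  spine_codes <- c(voc[["spine"]], voc[["lumbar_spine"]])
  k <- max(comp)
  rows <- list()
  keep_mask <- array(FALSE, dim = dim(suv$values))
  li <- 0L
  for (ci in seq_len(k)) {
    vox <- comp == ci
    nv <- sum(vox)
    if (nv < min_volume_voxels) next
    li <- li + 1L
    labs <- label_map[vox]
    loc <- if (mean(labs == voc[["skull"]]) > 0.5) "skull"
    else if (mean(labs %in% spine_codes) > 0.5) "spine"
    else "other"
    rows[[li]] <- data.frame(lesion = li, voxels = nv, volume_ml = nv * vv,
                             suv_max = max(suv$values[vox]), location = loc,
                             stringsAsFactors = FALSE)
    keep_mask <- keep_mask | vox
  }
  out <- if (li > 0L) do.call(rbind, rows) else empty
  attr(out, "lesion_mask") <- keep_mask
  attr(out, "background_suv") <- background
  out
}

#' Assemble an automated IMPeTUs-style report
#'
#' Covers the structured reading items: diffuse marrow Deauville score from
#' the lumbar spine, focal medullary lesion count with F score and locations,
#' Deauville score of the hottest lesion, CT lytic lesion count with L score,
#' fracture flag (carried from annotation), paramedullary disease (a
#' hypermetabolic component spanning bone and adjacent soft tissue) and
#' extramedullary disease (a hypermetabolic soft-tissue component with no
#' bone involvement). Detection of hypermetabolic components excludes the
#' reference organs and skull. If the mediastinum mask is empty, the
#' Deauville items are reported as `NA` rather than guessed.
#'
#' @param suv,ct [voxel_grid()]s.
#' @param masks a [region_mask_set()].
#' @param label_map integer label array.
#' @param detection_factor,min_volume_voxels see [detect_focal_lesions()].
#' @param lytic_hu HU at or below which intra-osseous voxels count as lytic;
#'   default 40 (a phantom-oriented proxy, not a clinical criterion).
#' @param fracture annotation flag (default `FALSE`).
#' @param epsilon see [deauville_score()].
#' @return list of class `impetus_report`: `diffuse_ds`, `focal_count`,
#'   `f_score`, `focal_locations`, `hottest_ds`, `lytic_count`, `l_score`,
#'   `fracture_flag`, `pmd_flag`, `emd_flag`, `emd_count`, plus the
#'   `lesions` table and reference values used.
#' @export
assemble_impetus_report <- function(suv, ct, masks, label_map,
                                    detection_factor = 2,
                                    min_volume_voxels = 3L,
                                    lytic_hu = 40,
                                    fracture = FALSE,
                                    epsilon = 0.1) {
  stopifnot(inherits(suv, "voxel_grid"), inherits(ct, "voxel_grid"))
  has_refs <- any(masks$mediastinum) && any(masks$liver)
  med_suv <- if (any(masks$mediastinum)) mean(suv$values[masks$mediastinum]) else NA_real_
  liv_suv <- if (any(masks$liver)) mean(suv$values[masks$liver]) else NA_real_

  lesions <- detect_focal_lesions(suv, masks, label_map,
                                  detection_factor, min_volume_voxels)
  focal_mask <- attr(lesions, "lesion_mask")
  background <- attr(lesions, "background_suv")
  # focal medullary count excludes the skull (consistent with its exclusion
  # from the quantitative analysis)
  medullary <- lesions[lesions$location != "skull", , drop = FALSE]
  focal_count <- nrow(medullary)

  diffuse <- if (has_refs && any(masks$lumbar_spine))
    diffuse_bm_score(suv, masks$lumbar_spine, focal_mask, med_suv, liv_suv,
                     epsilon)
  else list(score = NA_integer_, lumbar_suv_mean = NA_real_)

  hottest_ds <- if (focal_count == 0L || !has_refs) NA_integer_
  else deauville_score(max(medullary$suv_max), med_suv, liv_suv, epsilon)

  # PMD / EMD: components of hypermetabolic voxels anywhere outside the
  # excluded organs; classified by their overlap with the bone compartments
  bone <- masks$axial_bone | masks$extremity_bone
  pmd_flag <- FALSE
  emd_count <- 0L
  if (is.finite(background)) {
    cand <- hypermetabolic_candidates(suv, masks, label_map,
                                      detection_factor, background)
    comp <- label_components(cand)
    for (ci in seq_len(max(comp))) {
      vox <- comp == ci
      if (sum(vox) < min_volume_voxels) next
      in_bone <- vox & bone
      if (any(in_bone) && any(vox & !in_bone)) pmd_flag <- TRUE
      if (!any(in_bone)) emd_count <- emd_count + 1L
    }
  }

  lytic_in_bone <- bone & (ct$values <= lytic_hu)
  lcomp <- label_components(lytic_in_bone)
  lytic_count <- if (max(lcomp) == 0L) 0L else
    sum(tabulate(lcomp[lcomp > 0]) >= min_volume_voxels)

  structure(list(
    diffuse_ds = diffuse$score,
    lumbar_suv_mean = diffuse$lumbar_suv_mean,
    focal_count = focal_count,
    f_score = bin_count_score(focal_count),
    focal_locations = unique(medullary$location),
    hottest_ds = hottest_ds,
    lytic_count = as.integer(lytic_count),
    l_score = bin_count_score(lytic_count),
    fracture_flag = isTRUE(fracture),
    pmd_flag = pmd_flag,
    emd_flag = emd_count > 0L,
    emd_count = emd_count,
    lesions = medullary,
    mediastinum_suv = med_suv,
    liver_suv = liv_suv,
    background_suv = background
  ), class = "impetus_report")
}

#' @export
print.impetus_report <- function(x, ...) {
  cat("<impetus_report>\n")
  cat(sprintf("  diffuse marrow DS: %s (lumbar SUVmean %.2f)\n",
              x$diffuse_ds, x$lumbar_suv_mean))
  cat(sprintf("  focal lesions: %d (F%d)%s\n", x$focal_count, x$f_score,
              if (x$focal_count > 0)
                paste0(", hottest DS ", x$hottest_ds, ", locations: ",
                       paste(x$focal_locations, collapse = ", "))
              else ""))
  cat(sprintf("  lytic lesions: %d (L%d)\n", x$lytic_count, x$l_score))
  cat(sprintf("  fracture: %s, PMD: %s, EMD: %s\n",
              x$fracture_flag, x$pmd_flag, x$emd_flag))
  invisible(x)
}
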