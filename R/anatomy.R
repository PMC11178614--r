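#' Region mask set
#'
#' Named binary masks over one grid: the two skeletal compartments used for
#' thresholding (axial skeleton without skull, extremities), the excluded
#' skull, and the reference/VOI organs (liver, muscle, lumbar spine,
#' mediastinal blood pool).
#'
#' @param axial_bone,extremity_bone,skull,liver,muscle,lumbar_spine,mediastinum
#'   logical 3D arrays of identical shape (any may be all-FALSE).
#' @param spacing_mm voxel spacing of the source grid.
#' @return object of class `region_mask_set`.
#' @export
region_mask_set <- function(axial_bone, extremity_bone, skull, liver, muscle,
                            lumbar_spine, mediastinum,
                            spacing_mm = c(1, 1, 1)) {
  masks <- list(axial_bone = axial_bone, extremity_bone = extremity_bone,
                skull = skull, liver = liver, muscle = muscle,
                lumbar_spine = lumbar_spine, mediastinum = mediastinum)
  d <- dim(axial_bone)
  for (nm in names(masks)) {
    if (!is.logical(masks[[nm]]) || !identical(dim(masks[[nm]]), d))
      stop("mask `", nm, "` must be a logical array of the common shape")
  }
  masks$spacing_mm <- as.numeric(spacing_mm)
  class(masks) <- "region_mask_set"
  masks
}

#' @export
print.region_mask_set <- function(x, ...) {
  nm <- setdiff(names(x), "spacing_mm")
  counts <- vapply(nm, function(n) sum(x[[n]]), integer(1))
  cat("<region_mask_set>\n")
  for (n in nm) cat(sprintf("  %-15s %d voxels\n", n, counts[[n]]))
  invisible(x)
}

#' Segment the skeleton from CT by HU thresholding
#'
#' Stand-in for a learned organ segmentation: voxels at or above
#' `hu_threshold` are bone candidates, then a morphological closing with the
#' given radius fills marrow cavities and trabecular holes. The mask is
#' monotone (shrinking) in the threshold when the closing radius is 0.
#'
#' @param ct a [voxel_grid()] in Hounsfield units.
#' @param hu_threshold bone attenuation cutoff (HU); default 150.
#' @param closing_radius_mm radius of the closing structuring element (mm).
#' @return logical 3D array. An all-empty result is allowed (with a warning).
#' @export
segment_skeleton_from_ct <- function(ct, hu_threshold = 150,
                                     closing_radius_mm = 0) {
  stopifnot(inherits(ct, "voxel_grid"))
  mask <- ct$values >= hu_threshold
  dim(mask) <- dim(ct$values)
  if (closing_radius_mm > 0) {
    r <- mm_to_voxel_radius(closing_radius_mm, ct$spacing_mm)
    if (any(r > 0)) mask <- binary_close(mask, pmax(r, 0L))
  }
  if (!any(mask))
    warning("skeleton segmentation is empty at HU threshold ", hu_threshold)
  mask
}

#' Partition a bone mask into axial, extremity and skull compartments
#'
#' Each bone voxel is assigned by its anatomical label; the skull is kept as
#' its own mask so it can be excluded from all downstream analysis (intense
#' physiological brain uptake would otherwise contaminate the skull marrow
#' signal). Bone voxels carrying no bone label (e.g. closing spilled past the
#' labeled extent) are assigned by the nearest labeled bone voxel, found by
#' iterative 26-neighbourhood dilation of the three compartments; their count
#' is returned as a diagnostic.
#'
#' @param bone_mask logical 3D array.
#' @param label_map integer array (codes from [label_vocabulary()]).
#' @param spacing_mm voxel spacing, stored in the result.
#' @return a [region_mask_set()]; attribute `unlabeled_bone_voxels` holds the
#'   diagnostic count.
#' @export
partition_regions <- function(bone_mask, label_map, spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(bone_mask), dim(label_map)))
    stop("bone mask and label map shapes differ")
  voc <- label_vocabulary()
  d <- dim(bone_mask)
  axial <- bone_mask & array(label_map %in% axial_label_codes(), dim = d)
  extremity <- bone_mask & (label_map == voc[["extremity_bone"]])
  skull <- bone_mask & (label_map == voc[["skull"]])

  unassigned <- bone_mask & !(axial | extremity | skull)
  n_unlabeled <- sum(unassigned)
  guard <- 0L
  while (any(unassigned) && guard < max(d)) {
    grew <- FALSE
    for (nm in c("axial", "extremity", "skull")) {
      cur <- switch(nm, axial = axial, extremity = extremity, skull = skull)
      grow <- binary_dilate(cur, 1L) & unassigned
      if (any(grow)) {
        grew <- TRUE
        if (nm == "axial") axial <- axial | grow
        else if (nm == "extremity") extremity <- extremity | grow
        else skull <- skull | grow
        unassigned <- unassigned & !grow
      }
    }
    if (!grew) break
    guard <- guard + 1L
  }
  # isolated bone voxels with no labeled bone anywhere near: count as axial
  if (any(unassigned)) axial <- axial | unassigned

  res <- region_mask_set(
    axial_bone = axial,
    extremity_bone = extremity,
    skull = skull,
    liver = array(label_map == voc[["liver"]], dim = d),
    muscle = array(label_map == voc[["muscle"]], dim = d),
    lumbar_spine = array(label_map == voc[["lumbar_spine"]], dim = d),
    mediastinum = array(label_map == voc[["mediastinum"]], dim = d),
    spacing_mm = spacing_mm
  )
  attr(res, "unlabeled_bone_voxels") <- n_unlabeled
  res
}

#' Refine skeletal masks against tracer spillover
#'
#' PET's limited spatial resolution lets uptake from adjacent hot organs
#' spill into the bone mask. Mitigation here is deliberately contractive:
#' the axial and extremity masks are eroded by `erosion_radius_voxels`
#' (26-connectivity box element), and bone voxels within
#' `exclusion_margin_mm` of the liver or mediastinal blood pool are removed.
#' The refined masks are always subsets of the inputs.
#'
#' @param masks a [region_mask_set()].
#' @param erosion_radius_voxels nonnegative integer; default 1.
#' @param exclusion_margin_mm nonnegative scalar; default 0 (off).
#' @return a [region_mask_set()] with refined `axial_bone`/`extremity_bone`.
#' @export
refine_bone_mask <- function(masks, erosion_radius_voxels = 1L,
                             exclusion_margin_mm = 0) {
  stopifnot(inherits(masks, "region_mask_set"))
  r <- as.integer(erosion_radius_voxels)
  if (r < 0L) stop("`erosion_radius_voxels` must be >= 0")
  axial <- masks$axial_bone
  extremity <- masks$extremity_bone
  if (r > 0L) {
    axial <- binary_erode(axial, r)
    extremity <- binary_erode(extremity, r)
  }
  if (exclusion_margin_mm > 0) {
    rv <- mm_to_voxel_radius(exclusion_margin_mm, masks$spacing_mm)
    halo <- binary_dilate(masks$liver | masks$mediastinum, pmax(rv, 0L))
    axial <- axial & !halo
    extremity <- extremity & !halo
  }
  if (!any(axial) && any(masks$axial_bone))
    warning("refinement emptied the axial bone mask")
  if (!any(extremity) && any(masks$extremity_bone))
    warning("refinement emptied the extremity bone mask")
  out <- masks
  out$axial_bone <- axial
  out$extremity_bone <- extremity
  out
}
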