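#' Reference-organ SUV statistics
#'
#' Median and mean liver SUV and median muscle SUV over the full organ masks.
#' Medians over an even voxel count are the midpoint of the two central
#' values (the stats::median convention).
#'
#' @param suv a [voxel_grid()] in SUV units.
#' @param masks a [region_mask_set()] with nonempty liver and muscle masks.
#' @return list with `liver_suv_median`, `liver_suv_mean`,
#'   `muscle_suv_median`.
#' @export
compute_reference_stats <- function(suv, masks) {
  stopifnot(inherits(suv, "voxel_grid"), inherits(masks, "region_mask_set"))
  if (!any(masks$liver)) stop("liver mask is empty; reference SUV undefined")
  if (!any(masks$muscle)) stop("muscle mask is empty; reference SUV undefined")
  lv <- suv$values[masks$liver]
  mu <- suv$values[masks$muscle]
  list(liver_suv_median = stats::median(lv),
       liver_suv_mean = mean(lv),
       muscle_suv_median = stats::median(mu))
}

# the ten published threshold rules: per compartment either a
# (reference, multiplier) pair or an absolute SUV constant
approach_rule_table <- function() {
  ref <- function(reference, multiplier) list(kind = "reference",
                                              reference = reference,
                                              multiplier = multiplier)
  abs_ <- function(value) list(kind = "absolute", value = value)
  list(
    `1`  = list(axial = ref("liver_median", 1.1), extremity = ref("muscle_median", 4)),
    `2`  = list(axial = ref("liver_median", 1.5), extremity = ref("muscle_median", 4)),
    `3`  = list(axial = abs_(2.5),                extremity = abs_(2.5)),
    `4`  = list(axial = abs_(2.5),                extremity = abs_(2.0)),
    `5`  = list(axial = ref("liver_median", 1),   extremity = ref("liver_median", 1)),
    `6`  = list(axial = ref("liver_median", 1),   extremity = ref("muscle_median", 4)),
    `7`  = list(axial = ref("liver_median", 1.2), extremity = ref("liver_median", 1.2)),
    `8`  = list(axial = ref("liver_median", 1.2), extremity = ref("muscle_median", 4)),
    `9`  = list(axial = ref("liver_mean", 1),     extremity = ref("liver_mean", 1)),
    `10` = list(axial = abs_(3.0),                extremity = abs_(3.0))
  )
}

#' Threshold approach specification
#'
#' The ten published SUV threshold rules for pathological marrow uptake.
#' Approaches 1, 2, 6 and 8 reference the axial skeleton to the liver SUV
#' median (factors 1.0-1.5) and the extremities to 4x the muscle SUV median;
#' 5, 7 and 9 apply a liver-derived cutoff to both compartments; 3, 4 and 10
#' use absolute SUV constants (2.5 / 2.5, 2.5 / 2.0, 3.0 / 3.0).
#'
#' @param id integer 1..10.
#' @return object of class `approach_spec` with `id`, `axial_rule`,
#'   `extremity_rule`, and a human-readable `description`.
#' @export
approach_spec <- function(id) {
  id <- as.integer(id)
  tab <- approach_rule_table()
  if (is.na(id) || is.null(tab[[as.character(id)]]))
    stop("unknown approach id: ", id, " (valid ids are 1..10)")
  rules <- tab[[as.character(id)]]
  fmt <- function(rule) {
    if (rule$kind == "absolute") return(sprintf("SUV >= %.1f", rule$value))
    nm <- c(liver_median = "liver SUVmedian", liver_mean = "liver SUVmean",
            muscle_median = "muscle SUVmedian")[[rule$reference]]
    if (rule$multiplier == 1) sprintf("SUV >= %s", nm)
    else sprintf("SUV >= %s x %.1f", nm, rule$multiplier)
  }
  structure(list(id = id, axial_rule = rules$axial,
                 extremity_rule = rules$extremity,
                 description = sprintf("axial: %s; extremities: %s",
                                       fmt(rules$axial), fmt(rules$extremity))),
            class = "approach_spec")
}

eval_rule <- function(rule, refs) {
  th <- if (rule$kind == "absolute") rule$value
  else rule$multiplier * switch(rule$reference,
                                liver_median = refs$liver_suv_median,
                                liver_mean = refs$liver_suv_mean,
                                muscle_median = refs$muscle_suv_median,
                                stop("unknown reference: ", rule$reference))
  if (!is.finite(th) || th <= 0)
    stop("threshold evaluated to a non-positive value")
  th
}

#' Evaluate an approach's axial and extremity SUV thresholds
#'
#' @param spec an [approach_spec()] (or an id 1..10).
#' @param refs reference statistics from [compute_reference_stats()].
#' @return named numeric: `axial`, `extremity` (both strictly positive).
#' @export
approach_thresholds <- function(spec, refs) {
  if (!inherits(spec, "approach_spec")) spec <- approach_spec(spec)
  c(axial = eval_rule(spec$axial_rule, refs),
    extremity = eval_rule(spec$extremity_rule, refs))
}

#' Segment pathological bone-marrow uptake
#'
#' A voxel is segmented iff it lies in the (refined) axial mask with SUV at
#' or above the axial threshold, or in the extremity mask with SUV at or
#' above the extremity threshold. The comparison is inclusive (>=).
#'
#' @param suv a [voxel_grid()].
#' @param masks a [region_mask_set()] (already refined if desired).
#' @param thresholds named numeric with `axial` and `extremity`.
#' @return logical 3D array; an empty segmentation is a valid result.
#' @export
segment_bm_uptake <- function(suv, masks, thresholds) {
  stopifnot(inherits(suv, "voxel_grid"), inherits(masks, "region_mask_set"))
  (masks$axial_bone & suv$values >= thresholds[["axial"]]) |
    (masks$extremity_bone & suv$values >= thresholds[["extremity"]])
}

#' Metabolic tumor volume and total lesion glycolysis of a segmentation
#'
#' MTV (mL) is the segmented voxel count times the voxel volume; SUVmean is
#' averaged over the segmented voxels only; TLG (g) = SUVmean x MTV. An
#' empty segmentation yields MTV = TLG = 0 (and SUVmean 0 by convention).
#'
#' @param segmented logical 3D array.
#' @param suv a [voxel_grid()] of matching shape.
#' @param spacing_mm voxel spacing (defaults to the SUV grid's).
#' @return list `voxel_count`, `mtv_ml`, `suv_mean`, `tlg_g`.
#' @export
compute_mtv_tlg <- function(segmented, suv, spacing_mm = suv$spacing_mm) {
  stopifnot(inherits(suv, "voxel_grid"))
  if (!identical(dim(segmented), dim(suv$values)))
    stop("segmentation and SUV grid shapes differ")
  n <- sum(segmented)
  mtv <- n * voxel_volume_ml(spacing_mm)
  sm <- if (n == 0L) 0 else mean(suv$values[segmented])
  list(voxel_count = as.integer(n), mtv_ml = mtv, suv_mean = sm,
       tlg_g = sm * mtv)
}

#' Quantify all ten threshold approaches on one study
#'
#' Computes the reference statistics once, then per approach evaluates the
#' thresholds, segments the axial and extremity compartments separately
#' (they are disjoint by construction) and reports whole-body MTV/TLG as
#' their sum.
#'
#' @param suv a [voxel_grid()].
#' @param masks a [region_mask_set()] (refined).
#' @param approaches integer vector of approach ids; default 1:10.
#' @return data.frame, one row per approach: `approach`, `description`,
#'   `axial_threshold`, `extremity_threshold`, `voxel_count`, `mtv_ml`,
#'   `suv_mean`, `tlg_g`, `mtv_axial_ml`, `mtv_extremity_ml`.
#' @export
quantify_all_approaches <- function(suv, masks, approaches = 1:10) {
  refs <- compute_reference_stats(suv, masks)
  rows <- lapply(approaches, function(id) {
    spec <- approach_spec(id)
    th <- approach_thresholds(spec, refs)
    seg_ax <- masks$axial_bone & suv$values >= th[["axial"]]
    seg_ex <- masks$extremity_bone & suv$values >= th[["extremity"]]
    qa <- compute_mtv_tlg(seg_ax, suv)
    qe <- compute_mtv_tlg(seg_ex, suv)
    n <- qa$voxel_count + qe$voxel_count
    mtv <- qa$mtv_ml + qe$mtv_ml
    sm <- if (n == 0L) 0 else
      (qa$suv_mean * qa$voxel_count + qe$suv_mean * qe$voxel_count) / n
    data.frame(approach = spec$id, description = spec$description,
               axial_threshold = th[["axial"]],
               extremity_threshold = th[["extremity"]],
               voxel_count = n, mtv_ml = mtv, suv_mean = sm,
               tlg_g = sm * mtv,
               mtv_axial_ml = qa$mtv_ml, mtv_extremity_ml = qe$mtv_ml,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
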