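#' 3D voxel grid
#'
#' Lightweight container for a scalar field sampled on a regular 3D grid:
#' either PET standardized uptake values (SUV, dimensionless g/mL convention)
#' or CT attenuation in Hounsfield units (HU). PET and CT grids are assumed
#' co-registered (same shape, spacing and origin); no resampling is performed.
#'
#' @param values 3D numeric array.
#' @param spacing_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param origin length-3 numeric, position of the first voxel centre in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a strictly positive length-3 vector")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Volume of one voxel in mL
#' @param spacing_mm length-3 voxel spacing in mm.
#' @return scalar, voxel volume in millilitres (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(spacing_mm) prod(spacing_mm) / 1000

# --- anatomical label vocabulary -------------------------------------------

#' Anatomical label vocabulary
#'
#' Integer codes used in label maps. Spine codes (generic spine and lumbar
#' spine) are part of the axial skeleton; the lumbar code additionally defines
#' the VOI used for the diffuse bone-marrow Deauville score.
#'
#' @return named integer vector of label codes.
#' @export
label_vocabulary <- function() {
  c(background     = 0L,
    axial_bone     = 1L,   # pelvis, ribs, sternum, scapulae, clavicles, sacrum
    extremity_bone = 2L,   # humeri, femora
    skull          = 3L,
    liver          = 4L,
    muscle         = 5L,
    spine          = 6L,   # vertebral column above the lumbar VOI (axial)
    mediastinum    = 7L,
    lumbar_spine   = 8L)   # lower lumbar VOI (axial)
}

#' Label codes counted as bone
#' @return integer vector.
#' @export
bone_label_codes <- function() {
  v <- label_vocabulary()
  unname(v[c("axial_bone", "extremity_bone", "skull", "spine", "lumbar_spine")])
}

axial_label_codes <- function() {
  v <- label_vocabulary()
  unname(v[c("axial_bone", "spine", "lumbar_spine")])
}

# --- separable binary morphology (box structuring elements) -----------------

# shift a logical 3D array by `k` voxels along `axis`, padding with `fill`
shift_array <- function(x, k, axis, fill = FALSE) {
  if (k == 0L) return(x)
  d <- dim(x)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- idx_dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(x), idx_src)))))
  out
}

dilate_axis <- function(mask, r, axis) {
  if (r <= 0L) return(mask)
  out <- mask
  for (k in seq_len(r)) {
    out <- out | shift_array(mask, k, axis) | shift_array(mask, -k, axis)
  }
  out
}

#' Binary dilation with a box structuring element
#'
#' Separable dilation: the structuring element is the Chebyshev ball of the
#' given per-axis voxel radii (a (2rx+1) x (2ry+1) x (2rz+1) box), matching
#' the 26-connectivity convention used throughout.
#'
#' @param mask logical 3D array.
#' @param radius_vox integer radius per axis (scalar recycled to 3).
#' @return logical 3D array.
#' @export
binary_dilate <- function(mask, radius_vox) {
  r <- rep_len(as.integer(radius_vox), 3L)
  out <- mask
  for (ax in 1:3) out <- dilate_axis(out, r[ax], ax)
  out
}

#' Binary erosion with a box structuring element
#' @inheritParams binary_dilate
#' @return logical 3D array.
#' @export
binary_erode <- function(mask, radius_vox) {
  !binary_dilate(!mask, radius_vox)
}

#' Binary closing (dilation then erosion) with a box structuring element
#' @inheritParams binary_dilate
#' @return logical 3D array.
#' @export
binary_close <- function(mask, radius_vox) {
  binary_erode(binary_dilate(mask, radius_vox), radius_vox)
}

mm_to_voxel_radius <- function(radius_mm, spacing_mm) {
  as.integer(floor(radius_mm / spacing_mm + 1e-9))
}

# --- 26-connectivity connected components ----------------------------------

# the 13 "forward" neighbour offsets of the 26-neighbourhood (the other 13
# are their negatives; one direction suffices to enumerate each edge once)
half_neighbourhood_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  keep <- off[, 3] > 0 |
    (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

#' Label connected components under 26-connectivity
#'
#' Foreground voxels sharing a face, edge or corner belong to one component.
#' Labels are renumbered 1..k in order of each component's smallest linear
#' index, so the labelling is invariant to any internal ordering.
#'
#' @param mask logical 3D array.
#' @return integer 3D array; 0 = background, 1..k component ids.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  m <- length(idx)
  if (m == 0L) return(lab)
  pos <- integer(prod(d))
  pos[idx] <- seq_len(m)
  co <- arrayInd(idx, d)
  offs <- half_neighbourhood_26()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], nrow = m, ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    p <- pos[lin]
    hit <- p > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, p[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(m)]
  # renumber deterministically by first occurrence along the linear index order
  relab <- match(comp, unique(comp))
  lab[idx] <- relab
  lab
}

# run a deterministic expression under a seed without disturbing the caller's
# RNG state
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
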