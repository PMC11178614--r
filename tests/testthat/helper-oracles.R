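# Independent brute-force oracles. These deliberately avoid the package's
# vectorised/igraph code paths: plain loops over voxels, flood fill with an
# explicit stack, exhaustive threshold enumeration.

# MTV/TLG by an explicit voxel loop
oracle_mtv_tlg <- function(segmented, suv_values, spacing_mm) {
  d <- dim(segmented)
  n <- 0L
  s <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (segmented[i, j, k]) {
      n <- n + 1L
      s <- s + suv_values[i, j, k]
    }
  }
  vv <- prod(spacing_mm) / 1000   # volume of one voxel in mL
  mtv <- n * vv
  sm <- if (n == 0L) 0 else s / n
  list(voxel_count = n, mtv_ml = mtv, suv_mean = sm, tlg_g = sm * mtv)
}

# connected components by flood fill with an explicit stack (26-connectivity)
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nextlab <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] && lab[i, j, k] == 0L) {
      nextlab <- nextlab + 1L
      stack <- list(c(i, j, k))
      lab[i, j, k] <- nextlab
      while (length(stack) > 0L) {
        v <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          x <- v[1] + dx; y <- v[2] + dy; z <- v[3] + dz
          if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) next
          if (mask[x, y, z] && lab[x, y, z] == 0L) {
            lab[x, y, z] <- nextlab
            stack[[length(stack) + 1L]] <- c(x, y, z)
          }
        }
      }
    }
  }
  lab
}

# box erosion by checking every voxel's full (2r+1)^3 neighbourhood
oracle_erode <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    keep <- TRUE
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      x <- i + dx; y <- j + dy; z <- k + dz
      if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3] ||
          !mask[x, y, z]) { keep <- FALSE; break }
    }
    out[i, j, k] <- keep
  }
  out
}

# count of lattice voxels (centres) inside a sphere of radius_mm
oracle_sphere_count <- function(radius_mm, spacing_mm) {
  r <- ceiling(radius_mm / spacing_mm)
  n <- 0L
  for (x in -r[1]:r[1]) for (y in -r[2]:r[2]) for (z in -r[3]:r[3]) {
    if ((x * spacing_mm[1])^2 + (y * spacing_mm[2])^2 +
        (z * spacing_mm[3])^2 <= radius_mm^2 + 1e-9) n <- n + 1L
  }
  n
}

# exhaustive-threshold ROC: every midpoint cut, trapezoid-free AUC via
# pairwise comparisons (Mann-Whitney), best Youden cut toward the lower value
oracle_roc <- function(marker, label) {
  label <- as.logical(label)
  pos <- marker[label]; neg <- marker[!label]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  auc <- conc / (length(pos) * length(neg))
  u <- sort(unique(marker))
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (ct in cuts) {
    sens <- mean(pos >= ct); spec <- mean(neg < ct)
    if (is.null(best) || sens + spec > best$j + 1e-12)
      best <- list(cut = ct, sens = sens, spec = spec, j = sens + spec)
  }
  list(auc = auc, cut = best$cut, sensitivity = best$sens,
       specificity = best$spec)
}

# region masks over a small grid for unit tests: two bone slabs, liver,
# muscle, lumbar and mediastinum blocks
make_small_masks <- function(d = c(10L, 10L, 10L), spacing = c(2, 2, 2)) {
  z <- array(FALSE, dim = d)
  axial <- z; axial[2:5, 2:5, 2:9] <- TRUE
  extremity <- z; extremity[7:9, 2:4, 2:6] <- TRUE
  skull <- z
  liver <- z; liver[7:9, 6:9, 2:5] <- TRUE
  muscle <- z; muscle[2:4, 7:9, 2:5] <- TRUE
  lumbar <- z; lumbar[2:5, 2:5, 2:3] <- TRUE
  mediastinum <- z; mediastinum[7:9, 6:8, 7:9] <- TRUE
  region_mask_set(axial, extremity, skull, liver, muscle, lumbar,
                  mediastinum, spacing_mm = spacing)
}

# a uniform SUV grid with organ values painted into the masks
paint_suv <- function(masks, d = c(10L, 10L, 10L), spacing = c(2, 2, 2),
                      background = 0.4, bone = 1.0, liver = 2.0,
                      muscle = 0.6, mediastinum = 1.6) {
  v <- array(background, dim = d)
  v[masks$axial_bone | masks$extremity_bone] <- bone
  v[masks$liver] <- liver
  v[masks$muscle] <- muscle
  v[masks$mediastinum] <- mediastinum
  voxel_grid(v, spacing_mm = spacing)
}
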