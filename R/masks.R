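#' Binary structure mask on a regular voxel grid
#'
#' A `voxel_mask` stores a binary structure volume (CTV, spinal cord, skin,
#' ITV) together with its placement in the patient coordinate frame
#' (x = left-right, y = dorsal-ventral, z = cranial-caudal).  The voxel
#' center of index `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 0.5) * spacing` mm; the working grid is
#' 1 x 1 x 1 mm unless stated otherwise.
#'
#' @param data logical (or coercible) 3-D array of voxel occupancy.
#' @param origin numeric length-3, mm; corner of the grid.
#' @param spacing numeric length-3 (or scalar), mm per voxel.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(data) <- "logical"
  structure(list(data = data, origin = as.numeric(origin)[1:3],
                 spacing = spacing),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("voxel_mask: ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm, ", sum(x$data), " foreground (",
      signif(mask_volume_ml(x), 4), " ml)\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$data)

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$origin - b$origin)) < 1e-6 &&
    max(abs(a$spacing - b$spacing)) < 1e-9
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("masks are defined on different grids")
}

#' Foreground volume of a mask in millilitres
#'
#' One millilitre equals 1000 voxels on the 1 mm^3 working grid.
#' @param mask a [voxel_mask].
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' World coordinates (mm) of foreground voxel centers
#' @param mask a [voxel_mask].
#' @return n x 3 matrix of positions, mm.
#' @export
mask_points <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(idx - 0.5, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# voxel indices (1-based integer matrix) of world points; points off the
# grid get indices outside 1..dim and must be filtered by the caller
world_to_index <- function(pos, mask) {
  idx <- sweep(pos, 2, mask$origin, "-")
  idx <- sweep(idx, 2, mask$spacing, "/")
  matrix(as.integer(floor(idx)) + 1L, ncol = 3)
}

# squared EDT (mm^2) to the foreground
mask_edt_sq <- function(mask) {
  d <- .edt_sq(as.logical(mask$data), dim(mask$data), mask$spacing)
  array(d, dim = dim(mask$data))
}

#' Morphological dilation / erosion by a Euclidean ball
#'
#' Dilation marks every voxel whose center lies within `radius_mm` of a
#' foreground voxel center (a discretized spherical structuring element);
#' erosion is the dual operation.  Implemented through an exact Euclidean
#' distance transform, so the structuring element is the true digital ball.
#'
#' @param mask a [voxel_mask].
#' @param radius_mm ball radius, mm (>= 0).
#' @return dilated / eroded [voxel_mask] on the same grid.
#' @export
mask_dilate <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  out <- mask
  out$data <- mask_edt_sq(mask) <= radius_mm^2 + 1e-9
  out$data[is.na(out$data)] <- FALSE
  out
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  inv <- mask
  inv$data <- !mask$data
  out <- mask
  out$data <- mask$data & !(mask_edt_sq(inv) <= radius_mm^2 + 1e-9)
  out
}

# one-pass morphological closing
mask_close <- function(mask, radius_mm = 1) {
  mask_erode(mask_dilate(mask, radius_mm), radius_mm)
}

# Seal rasterization cracks: a background voxel becomes foreground when
# it has foreground on both sides along some axis (opposite face
# neighbors).  Fills the one-voxel planes that nearest-voxel deposition
# leaves under expansive warps, while leaving concave surface staircases
# (hence any un-warped mask) untouched.  Iterated to a fixpoint (at most
# three passes) because where two crack planes intersect, the line of
# voxels only gains opposite foreground neighbors after the planes fill.
fill_cracks <- function(mask) {
  out <- mask
  for (pass in 1:3) {
    d <- dim(out$data)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- out$data
    xpair <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
      pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)]
    ypair <- pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)]
    zpair <- pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    new <- out$data | xpair | ypair | zpair
    if (identical(new, out$data)) break
    out$data <- new
  }
  out
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face neighbors (or the volume boundary) is background.
#'
#' @param mask a [voxel_mask].
#' @return integer n x 3 matrix of 1-based voxel indices.
#' @export
mask_surface_voxels <- function(mask) {
  d <- dim(mask$data)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

# Forward-warp foreground voxel centers by per-point displacements (n x 3,
# mm) and rasterize by nearest-voxel deposition onto the same grid, then
# seal rasterization cracks.
rasterize_warped <- function(mask, displacements, seal = TRUE) {
  pos <- mask_points(mask)
  if (nrow(pos) == 0) return(mask)
  new_pos <- pos + displacements
  idx <- world_to_index(new_pos, mask)
  d <- dim(mask$data)
  keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- mask
  out$data <- array(FALSE, d)
  out$data[idx[keep, , drop = FALSE]] <- TRUE
  if (seal) out <- fill_cracks(out)
  out
}

#' Warp a mask by an arbitrary displacement function
#'
#' Used by the synthetic cohort generator, whose ground-truth deformations
#' are analytic fields independent of the finite-element solver.
#'
#' @param mask a [voxel_mask].
#' @param fn function taking an n x 3 matrix of positions (mm) and
#'   returning n x 3 displacements (mm).
#' @param seal fill rasterization cracks after deposition.
#' @return warped [voxel_mask].
#' @export
mask_warp_fn <- function(mask, fn, seal = TRUE) {
  pos <- mask_points(mask)
  if (nrow(pos) == 0) return(mask)
  rasterize_warped(mask, fn(pos), seal)
}
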