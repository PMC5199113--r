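#' Approach 1: constant margin
#'
#' Morphological dilation of the CTV by a discretized sphere of the given
#' radius on the working grid; 3 mm is the clinically common choice under
#' daily image guidance.
#'
#' @param ctv CTV [voxel_mask].
#' @param radius margin radius, mm (>= 0).
#' @return ITV [voxel_mask] (always a superset of the CTV).
#' @export
margin_constant <- function(ctv, radius = 3) {
  stopifnot(radius >= 0)
  mask_dilate(ctv, radius)
}

#' Per-landmark residual-error statistics over a training cohort
#'
#' Splits each landmark coordinate's residual displacement (after the
#' simulated couch correction) into the systematic component `Sigma`
#' (SD over patients of the per-patient mean) and the random component
#' `sigma` (root-mean-square over patients of the per-patient SD),
#' per axis (left-right, dorsal-ventral, cranial-caudal).
#'
#' @param residuals_by_patient named list; per patient an F x 3M matrix
#'   of residual displacements in landmark-major order (`NA` = missing).
#' @param exclude patient ids to leave out (leave-one-out protocol).
#' @return list with `Sigma` and `sigma`, each an M x 3 matrix (mm), and
#'   `n_patients`.
#' @export
residual_statistics <- function(residuals_by_patient, exclude = NULL) {
  keep <- setdiff(names(residuals_by_patient), exclude)
  if (!length(keep)) stop("no training patients left")
  R <- residuals_by_patient[keep]
  means <- t(vapply(R, function(m) colMeans(m, na.rm = TRUE),
                    numeric(ncol(R[[1]]))))
  sds <- t(vapply(R, function(m) apply(m, 2, stats::sd, na.rm = TRUE),
                  numeric(ncol(R[[1]]))))
  Sigma <- apply(means, 2, stats::sd)
  sigma <- sqrt(colMeans(sds^2, na.rm = TRUE))
  Sigma[!is.finite(Sigma)] <- 0
  sigma[!is.finite(sigma)] <- 0
  list(Sigma = matrix(Sigma, ncol = 3, byrow = TRUE),
       sigma = matrix(sigma, ncol = 3, byrow = TRUE),
       n_patients = length(keep))
}

#' Approach 2, step 1: local margin field on the CTV surface
#'
#' At each CTV surface point the local (per-axis) margin is the weighted
#' average `r(x) = sum_i w_i m_i` of per-landmark margins with
#' normalized inverse-distance weights `w_i = d_i^-p / sum_j d_j^-p`.
#' Two per-landmark margin recipes are available: the 95% confidence
#' interval form `m_i = 1.96 sigma_i` per axis, and the classical
#' systematic-plus-random recipe `m_i = 2.5 Sigma_i + 0.7 sigma_i`.
#'
#' @param ctv CTV [voxel_mask].
#' @param landmark_positions M x 3 landmark positions, mm (planning
#'   pose of the target patient).
#' @param stats a [residual_statistics()] result (computed leave-one-out
#'   with the target patient excluded).
#' @param mode `"ci"` (default) or `"yang"`.
#' @param ci_quantile two-sided normal quantile for `"ci"` mode (1.96
#'   for the conventional 95% interval).
#' @param weight_exponent inverse-distance exponent p.
#' @return object of class `local_margin_field`: `surface` (n x 3 voxel
#'   indices), `radii` (n x 3 per-axis margins, mm), grid geometry.
#' @export
margin_distance_field <- function(ctv, landmark_positions, stats,
                                  mode = c("ci", "yang"),
                                  ci_quantile = 1.96,
                                  weight_exponent = 1) {
  mode <- match.arg(mode)
  landmark_positions <- matrix(as.numeric(landmark_positions), ncol = 3)
  m_i <- switch(mode,
                ci = ci_quantile * stats$sigma,
                yang = 2.5 * stats$Sigma + 0.7 * stats$sigma)
  ok <- stats::complete.cases(landmark_positions) &
    stats::complete.cases(m_i)
  if (!any(ok)) stop("no landmark with usable statistics")
  landmark_positions <- landmark_positions[ok, , drop = FALSE]
  m_i <- m_i[ok, , drop = FALSE]

  surf <- mask_surface_voxels(ctv)
  pos <- sweep(sweep(surf - 0.5, 2, ctv$spacing, "*"), 2, ctv$origin, "+")
  radii <- matrix(0, nrow(surf), 3)
  for (s in seq_len(nrow(surf))) {
    d <- sqrt(colSums((t(landmark_positions) - pos[s, ])^2))
    if (any(d < 1e-9)) {
      w <- as.numeric(d == min(d))
      w <- w / sum(w)
    } else {
      w <- d^(-weight_exponent)
      w <- w / sum(w)
    }
    radii[s, ] <- as.numeric(w %*% m_i)
  }
  structure(list(surface = surf, radii = radii, origin = ctv$origin,
                 spacing = ctv$spacing, dim = dim(ctv$data),
                 mode = mode),
            class = "local_margin_field")
}

#' Approach 2, step 2: spatially varying dilation
#'
#' Expands each CTV surface point by its local per-axis (ellipsoidal)
#' margin; with a constant isotropic field the result equals
#' [margin_constant()] of that radius.
#'
#' @param ctv CTV [voxel_mask].
#' @param field a [margin_distance_field()] result.
#' @return ITV [voxel_mask] (superset of the CTV).
#' @export
margin_distance <- function(ctv, field) {
  stopifnot(identical(dim(ctv$data), field$dim))
  stamped <- .stamp_ellipsoids(dim(ctv$data), ctv$spacing,
                               field$surface - 1L, field$radii)
  out <- ctv
  out$data <- ctv$data | array(stamped, dim(ctv$data))
  out
}

#' Approach 3: statistical biomechanical margin
#'
#' Deforms the CTV with every sampled pose scenario's displacement field,
#' accumulates a per-voxel hit count, and keeps the voxels hit in
#' strictly more than `hit_threshold` of the scenarios (5% by default).
#' With `hit_threshold = 0` this is the union of all deformed CTVs.
#'
#' @param ctv CTV [voxel_mask].
#' @param scenario_fields list of [displacement_field]s, one per sampled
#'   pose scenario.
#' @param hit_threshold fraction in `[0, 1)`.
#' @param attachments optional precomputed [locate_in_mesh] result for
#'   the CTV's foreground voxel centers (shared across scenarios).
#' @param include_identity also count the undeformed CTV as a scenario
#'   baseline (default FALSE; the sampled scenarios normally bracket the
#'   identity).
#' @param return_counts attach the accumulation array as attribute
#'   `counts`.
#' @return ITV [voxel_mask].
#' @export
margin_fem <- function(ctv, scenario_fields, hit_threshold = 0.05,
                       attachments = NULL, include_identity = FALSE,
                       return_counts = FALSE) {
  stopifnot(length(scenario_fields) >= 1, hit_threshold >= 0,
            hit_threshold < 1)
  if (is.null(attachments) && length(scenario_fields))
    attachments <- locate_in_mesh(mask_points(ctv),
                                  scenario_fields[[1]]$mesh)
  counts <- array(0L, dim(ctv$data))
  for (fld in scenario_fields) {
    def <- propagate_mask(ctv, fld, attachments = attachments)
    counts <- counts + def$data
  }
  n <- length(scenario_fields)
  if (include_identity) {
    counts <- counts + ctv$data
    n <- n + 1
  }
  out <- ctv
  out$data <- counts > hit_threshold * n
  if (return_counts) attr(out, "counts") <- counts
  out
}
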