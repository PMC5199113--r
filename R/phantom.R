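#' Geometry specification of the synthetic head-and-neck phantom
#'
#' The phantom body is a head sphere on a neck cylinder on a shoulder
#' slab, with 24 bony landmarks (8 skull, 8 spine, 8 shoulder), a
#' horseshoe CTV in the neck (a cylinder with a posterior wedge removed,
#' which keeps it disjoint from the spinal cord by construction) and a
#' posterior spinal-cord cylinder.  All dimensions in mm, patient frame
#' (x = left-right, y = dorsal-ventral, z = cranial-caudal; the shoulders
#' sit at caudal z).
#'
#' The `deform_z0` / `deform_scale` parameters define the logistic
#' cranio-caudal ramp `w(z) = 1 / (1 + exp((z - z0) / scale))` that
#' weights all deformation modes: close to 1 at the shoulders, close to 0
#' at the skull.
#'
#' @param preset `"default"` (fine mesh, larger CTV) or `"tiny"` (coarse
#'   mesh, small CTV; intended for fast test runs).
#' @param ... named overrides of individual fields.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("default", "tiny"), ...) {
  preset <- match.arg(preset)
  spec <- list(
    head_radius = 70, head_center_z = 145,
    neck_radius = 45, neck_z = c(0, 90),
    slab_x = c(-150, 150), slab_y = c(-80, 80), slab_z = c(-80, 0),
    ctv_target_ml = 500, ctv_z = c(-50, 70), ctv_wedge_deg = 80,
    cord_xy = c(0, -30), cord_radius = 5, cord_z = c(-70, 100),
    mesh_edge_mm = 15, grid_pad_mm = 15, spacing = c(1, 1, 1),
    deform_z0 = -25, deform_scale = 10,
    deform_lat_x0 = 40, deform_lat_scale = 12, deform_lat_floor = 0.45)
  if (preset == "tiny") {
    spec$ctv_target_ml <- 120
    spec$ctv_z <- c(-35, 45)
    spec$mesh_edge_mm <- 30
    spec$grid_pad_mm <- 12
  }
  spec$preset <- preset
  over <- list(...)
  stopifnot(all(names(over) %in% names(spec)))
  spec[names(over)] <- over
  structure(spec, class = "phantom_spec")
}

# logistic cranio-caudal deformability ramp
deform_ramp <- function(spec, z) {
  1 / (1 + exp((z - spec$deform_z0) / spec$deform_scale))
}

phantom_inside_body <- function(spec) {
  function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    slab <- p[, 1] >= spec$slab_x[1] & p[, 1] <= spec$slab_x[2] &
      p[, 2] >= spec$slab_y[1] & p[, 2] <= spec$slab_y[2] &
      p[, 3] >= spec$slab_z[1] & p[, 3] <= spec$slab_z[2]
    neck <- p[, 1]^2 + p[, 2]^2 <= spec$neck_radius^2 &
      p[, 3] >= spec$neck_z[1] & p[, 3] <= spec$neck_z[2]
    head <- p[, 1]^2 + p[, 2]^2 + (p[, 3] - spec$head_center_z)^2 <=
      spec$head_radius^2
    slab | neck | head
  }
}

# CTV radius that hits the target volume of the blunted-wedge cylinder:
# V = (1 - wf) pi r^2 L + wf pi r_in^2 L, with wedge fraction wf and
# blunting radius r_in = 8 mm
ctv_radius_for_target <- function(spec) {
  wf <- spec$ctv_wedge_deg / 360
  len <- diff(spec$ctv_z)
  sqrt((spec$ctv_target_ml * 1000 / len - wf * pi * 64) /
         ((1 - wf) * pi))
}

# horseshoe CTV: cylinder minus a posterior wedge; the wedge is blunted
# near the axis (inner radius) so the notch never narrows below voxel
# scale
phantom_inside_ctv <- function(spec) {
  r <- ctv_radius_for_target(spec)
  half <- spec$ctv_wedge_deg / 2 * pi / 180
  r_in <- 8
  function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    ang <- atan2(p[, 1], -p[, 2])   # 0 = posterior (toward the cord)
    rad2 <- p[, 1]^2 + p[, 2]^2
    in_wedge <- abs(ang) <= half & rad2 > r_in^2
    rad2 <= r^2 &
      p[, 3] >= spec$ctv_z[1] & p[, 3] <= spec$ctv_z[2] &
      !in_wedge
  }
}

phantom_inside_cord <- function(spec) {
  function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    (p[, 1] - spec$cord_xy[1])^2 + (p[, 2] - spec$cord_xy[2])^2 <=
      spec$cord_radius^2 &
      p[, 3] >= spec$cord_z[1] & p[, 3] <= spec$cord_z[2]
  }
}

phantom_landmark_layout <- function(spec) {
  dirs <- rbind(c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(-1, -1, 1),
                c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, -1))
  dirs <- dirs / sqrt(3)
  skull <- sweep(dirs * (spec$head_radius - 15), 2,
                 c(0, 0, spec$head_center_z), "+")
  spine_z <- seq(-30, 75, length.out = 8)
  spine <- cbind(0, -28, spine_z)
  shoulder <- rbind(
    c(95, 0, -40), c(-95, 0, -40), c(60, 25, -40), c(-60, 25, -40),
    c(115, 0, -50), c(-115, 0, -50), c(60, -25, -50), c(-60, -25, -50))
  pos <- rbind(skull, spine, shoulder)
  list(names = c(paste0("skull_", 1:8), paste0("spine_", 1:8),
                 paste0("shoulder_", 1:8)),
       positions = pos,
       region = rep(c("skull", "spine", "shoulder"), each = 8))
}

#' Default same-bone grouping of the phantom landmarks
#'
#' Skull landmarks share one bone; spine landmarks are grouped in
#' adjacent pairs (vertebra proxies); shoulder landmarks split into a
#' left and a right bone.  Used to build the geometric rigid-body model.
#'
#' @param phantom a [generate_phantom()] result.
#' @return named character vector mapping landmark name to bone label.
#' @export
default_bone_assignment <- function(phantom) {
  lm <- phantom$landmarks
  bones <- character(length(lm$names))
  names(bones) <- lm$names
  bones[lm$region == "skull"] <- "skull"
  spine <- which(lm$region == "spine")
  bones[spine] <- paste0("vertebra_", ceiling(seq_along(spine) / 2))
  sh <- lm$names[lm$region == "shoulder"]
  bones[sh] <- ifelse(lm$positions[sh, 1] > 0, "shoulder_right",
                      "shoulder_left")
  bones
}

#' Generate the synthetic phantom
#'
#' Builds the tetrahedral body mesh, the planning-pose landmark set, the
#' CTV and spinal-cord masks on a common 1 mm working grid covering both
#' structures plus a margin headroom, and keeps the implicit geometry
#' functions for rendering and validity checks.  The construction is
#' deterministic; `seed` is accepted for interface symmetry with the
#' pose simulator.
#'
#' @param spec a [phantom_spec].
#' @param seed unused (generation is deterministic).
#' @return object of class `phantom`: `mesh`, `landmarks`, `ctv`, `cord`,
#'   `spec`, `inside_body`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  inside <- phantom_inside_body(spec)
  bbox <- rbind(c(spec$slab_x[1], spec$slab_y[1], spec$slab_z[1]),
                c(spec$slab_x[2], spec$slab_y[2],
                  spec$head_center_z + spec$head_radius))
  mesh <- mesh_implicit_solid(inside, bbox, spec$mesh_edge_mm)

  r_ctv <- ctv_radius_for_target(spec)
  if (r_ctv + 2 > spec$neck_radius)
    stop("infeasible geometry: CTV radius ", round(r_ctv, 1),
         " mm exceeds the neck")
  pad <- spec$grid_pad_mm
  lo <- floor(c(min(-r_ctv, spec$cord_xy[1] - spec$cord_radius) - pad,
                min(-r_ctv, spec$cord_xy[2] - spec$cord_radius) - pad,
                spec$ctv_z[1] - pad))
  hi <- ceiling(c(max(r_ctv, spec$cord_xy[1] + spec$cord_radius) + pad,
                  max(r_ctv, spec$cord_xy[2] + spec$cord_radius) + pad,
                  spec$ctv_z[2] + pad))
  dims <- as.integer(round((hi - lo) / spec$spacing))
  grid_centers <- function() {
    as.matrix(expand.grid(
      x = lo[1] + (seq_len(dims[1]) - 0.5) * spec$spacing[1],
      y = lo[2] + (seq_len(dims[2]) - 0.5) * spec$spacing[2],
      z = lo[3] + (seq_len(dims[3]) - 0.5) * spec$spacing[3]))
  }
  pts <- grid_centers()
  ctv <- voxel_mask(array(phantom_inside_ctv(spec)(pts), dims), lo,
                    spec$spacing)
  cord <- voxel_mask(array(phantom_inside_cord(spec)(pts), dims), lo,
                     spec$spacing)
  if (any(ctv$data & cord$data)) stop("CTV and cord overlap")

  lay <- phantom_landmark_layout(spec)
  landmarks <- landmark_set(lay$names, lay$positions, lay$region,
                            fraction_id = 0L)
  structure(list(mesh = mesh, landmarks = landmarks, ctv = ctv,
                 cord = cord, spec = spec, inside_body = inside),
            class = "phantom")
}

#' Pose-variation simulation parameters
#'
#' Defaults emulate the inter-fraction variability reported for a
#' head-and-neck cohort: per-axis rigid setup translation scales of
#' (0.73, 1.08, 1.76) mm and rotation scales of (1.06, 0.70, 0.92)
#' degrees, residual deformation largest at the shoulders (mean magnitude
#' about 9.2 mm) and negligible at the skull, roughly 1 in 6 landmark
#' observations lost, and a cohort of 19 patients with 25 fractions each.
#'
#' Four analytic deformation modes (lateral, dorsal-ventral, cranial-
#' caudal, and left-right-asymmetric cranial-caudal) are scaled by the
#' phantom's cranio-caudal ramp; per-fraction mode coefficients are
#' standard normal with a per-patient systematic component.
#'
#' @param n_patients,n_fractions cohort size.
#' @param trans_sd per-axis rigid translation SD, mm.
#' @param rot_sd_deg per-axis rigid rotation SD, degrees.
#' @param mode_amplitudes SDs (mm) of the four deformation modes at
#'   ramp weight 1.
#' @param systematic_frac fraction of each mode coefficient's SD that is
#'   a per-patient systematic offset.
#' @param tracking_noise_sd isotropic landmark observation noise, mm.
#' @param missingness probability that a landmark observation is lost.
#' @param outlier_rate probability of a gross (25 mm) tracking blunder;
#'   0 by default (blunder injection is used to exercise the outlier
#'   filter in dedicated tests).
#' @param seed RNG seed for the cohort draw.
#' @return object of class `pose_sim_spec`.
#' @export
pose_sim_spec <- function(n_patients = 19, n_fractions = 25,
                          trans_sd = c(0.73, 1.08, 1.76),
                          rot_sd_deg = c(1.06, 0.70, 0.92),
                          mode_amplitudes = c(lateral = 2.5, ap = 2.5,
                                              si = 8.5, si_asym = 8.5),
                          systematic_frac = 0.5,
                          tracking_noise_sd = 0.5,
                          missingness = 0.166, outlier_rate = 0,
                          seed = 1L) {
  stopifnot(all(trans_sd >= 0), all(rot_sd_deg >= 0),
            all(mode_amplitudes >= 0), missingness >= 0, missingness < 1,
            n_patients >= 1, n_fractions >= 2)
  structure(list(n_patients = n_patients, n_fractions = n_fractions,
                 trans_sd = trans_sd, rot_sd_deg = rot_sd_deg,
                 mode_amplitudes = mode_amplitudes,
                 systematic_frac = systematic_frac,
                 tracking_noise_sd = tracking_noise_sd,
                 missingness = missingness, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "pose_sim_spec")
}

# lateral weight of the shoulder-elevation modes: the arm girdle
# (|x| beyond ~40 mm) rises almost rigidly while midline tissue follows
# only partially
lat_ramp <- function(spec, x) {
  spec$deform_lat_floor + (1 - spec$deform_lat_floor) /
    (1 + exp(-(abs(x) - spec$deform_lat_x0) / spec$deform_lat_scale))
}

# the four analytic mode fields evaluated at points (n x 3) -> list of
# n x 3 unit-direction fields scaled by the cranio-caudal (and, for the
# shoulder-elevation modes, lateral) ramps
mode_fields <- function(spec, points) {
  w <- deform_ramp(spec, points[, 3])
  wl <- w * lat_ramp(spec, points[, 1])
  zero <- numeric(nrow(points))
  list(lateral = cbind(w, zero, zero),
       ap = cbind(zero, w, zero),
       si = cbind(zero, zero, wl),
       si_asym = cbind(zero, zero, wl * tanh(points[, 1] / 50)))
}

#' Ground-truth deformation field of one fraction
#'
#' Returns the analytic smooth displacement function
#' `u(x) = sum_j amplitude_j coef_j mode_j(x)`.  These fields are
#' deliberately independent of the finite-element solver, so solver
#' accuracy is measured against an external truth.
#'
#' @param phantom_or_spec a [phantom] or [phantom_spec].
#' @param coefs length-4 mode coefficients.
#' @param amplitudes length-4 mode SDs, mm.
#' @return function mapping an n x 3 position matrix to n x 3
#'   displacements (mm).
#' @export
deformation_fn <- function(phantom_or_spec, coefs, amplitudes) {
  spec <- if (inherits(phantom_or_spec, "phantom")) phantom_or_spec$spec
          else phantom_or_spec
  force(coefs); force(amplitudes)
  function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    modes <- mode_fields(spec, points)
    u <- matrix(0, nrow(points), 3)
    for (j in seq_along(modes)) u <- u + amplitudes[j] * coefs[j] * modes[[j]]
    u
  }
}

rotation_from_angles_deg <- function(ang) {
  a <- ang * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  rx %*% ry %*% rz
}

#' Simulate fraction poses for a phantom cohort
#'
#' Each fraction applies a random rigid setup transform (about the skull
#' centroid) on top of a smooth residual deformation built from the mode
#' fields; the reported landmark sets additionally carry isotropic
#' tracking noise, missing observations and occasional gross blunders,
#' while the ground truth (mode coefficients, noise-free landmark
#' positions) is retained separately.  At least three skull landmarks are
#' always kept valid so the couch-correction step remains solvable.
#'
#' @param phantom a [generate_phantom()] result.
#' @param sim a [pose_sim_spec].
#' @return object of class `phantom_cohort`: `phantom`, `sim`, `patients`
#'   (per patient: `planning` landmark set, `fractions` with `observed`
#'   landmark set, `coefs`, `rigid`, `truth_positions`).
#' @export
simulate_fraction_poses <- function(phantom, sim) {
  set.seed(sim$seed)
  lm <- phantom$landmarks
  n_lm <- length(lm$names)
  skull_idx <- which(lm$region == "skull")
  center <- colMeans(lm$positions[skull_idx, ])
  amps <- sim$mode_amplitudes
  n_modes <- length(amps)
  sys_sd <- sim$systematic_frac
  rnd_sd <- sqrt(max(0, 1 - sys_sd^2))

  patients <- lapply(seq_len(sim$n_patients), function(p) {
    sys_coef <- stats::rnorm(n_modes, sd = sys_sd)
    fractions <- lapply(seq_len(sim$n_fractions), function(f) {
      coefs <- sys_coef + stats::rnorm(n_modes, sd = rnd_sd)
      def <- deformation_fn(phantom, coefs, amps)
      truth <- lm$positions + def(lm$positions)
      R <- rotation_from_angles_deg(stats::rnorm(3, sd = sim$rot_sd_deg))
      t <- stats::rnorm(3, sd = sim$trans_sd)
      moved <- sweep(sweep(truth, 2, center) %*% t(R), 2, center + t, "+")
      obs <- moved + matrix(stats::rnorm(3 * n_lm,
                                         sd = sim$tracking_noise_sd),
                            n_lm, 3)
      blunder <- stats::runif(n_lm) < sim$outlier_rate
      if (any(blunder)) {
        dir <- matrix(stats::rnorm(3 * sum(blunder)), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        obs[blunder, ] <- obs[blunder, ] + 25 * dir
      }
      valid <- stats::runif(n_lm) >= sim$missingness
      if (sum(valid[skull_idx]) < 3)
        valid[skull_idx[1:3]] <- TRUE
      observed <- landmark_set(lm$names, obs, lm$region, valid = valid,
                               fraction_id = f)
      list(observed = observed, coefs = coefs,
           rigid = list(rotation = R, translation = t, center = center),
           truth_positions = truth)
    })
    list(patient_id = sprintf("P%02d", p),
         planning = lm, fractions = fractions)
  })
  names(patients) <- vapply(patients, `[[`, character(1), "patient_id")
  structure(list(phantom = phantom, sim = sim, patients = patients),
            class = "phantom_cohort")
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: phantom geometry plus simulated fraction poses.
#'
#' @param spec a [phantom_spec].
#' @param sim a [pose_sim_spec].
#' @return a `phantom_cohort`.
#' @export
generate_cohort <- function(spec = phantom_spec(), sim = pose_sim_spec()) {
  simulate_fraction_poses(generate_phantom(spec), sim)
}

#' Render a synthetic intensity volume
#'
#' Piecewise-constant body / air intensities with bright spherical blobs
#' at the landmark sites (bone proxies), optionally at deformed landmark
#' positions, plus Gaussian noise.  Exercises the template-matching
#' tracker on data with known truth.
#'
#' @param phantom a [generate_phantom()] result.
#' @param landmark_positions n x 3 landmark positions to render blobs at
#'   (default: planning positions).
#' @param bbox 2 x 3 matrix restricting the rendered region (default:
#'   a box around the landmarks).
#' @param spacing voxel spacing, mm.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param blob_radius radius of the landmark blobs, mm.
#' @return an [intensity_volume].
#' @export
render_intensity_volume <- function(phantom,
                                    landmark_positions = NULL,
                                    bbox = NULL, spacing = c(2, 2, 2),
                                    noise_sd = 0, blob_radius = 5) {
  if (is.null(landmark_positions))
    landmark_positions <- phantom$landmarks$positions
  landmark_positions <- matrix(as.numeric(landmark_positions), ncol = 3)
  if (is.null(bbox))
    bbox <- rbind(apply(landmark_positions, 2, min) - 20,
                  apply(landmark_positions, 2, max) + 20)
  spacing <- rep_len(as.numeric(spacing), 3)
  dims <- pmax(1L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / spacing)))
  pts <- as.matrix(expand.grid(
    x = bbox[1, 1] + (seq_len(dims[1]) - 0.5) * spacing[1],
    y = bbox[1, 2] + (seq_len(dims[2]) - 0.5) * spacing[2],
    z = bbox[1, 3] + (seq_len(dims[3]) - 0.5) * spacing[3]))
  val <- ifelse(phantom$inside_body(pts), 100, 0)
  for (i in seq_len(nrow(landmark_positions))) {
    d2 <- rowSums(sweep(pts, 2, landmark_positions[i, ])^2)
    val[d2 <= blob_radius^2] <- 300
  }
  if (noise_sd > 0) val <- val + stats::rnorm(length(val), sd = noise_sd)
  intensity_volume(array(val, dims), bbox[1, ], spacing)
}
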