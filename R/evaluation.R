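#' Margin-quality metrics
#'
#' Four voxel-counting metrics compare an ITV against the planning CTV
#' and against the CTV / spinal cord propagated to each fraction
#' (fCTV / fraction cord):
#' * `internal_margin_volume`: |ITV \ CTV| in ml - healthy tissue
#'   expected to be irradiated from the planning perspective.
#' * `healthy_tissue_hit`: |ITV \ fCTV| in ml - healthy tissue actually
#'   inside the ITV for a fraction (can exceed the margin volume when
#'   the CTV moves out of the ITV).
#' * `missed_ctv`: |fCTV \ ITV| in ml - target volume missed in a
#'   fraction.
#' * `distance_to_oar_slicewise`: per transversal slice of the ITV, the
#'   minimum 3-D distance to the propagated OAR (spinal cord).
#'
#' All masks must share one grid; volumes use the voxel volume (1 ml =
#' 1000 voxels at 1 mm^3); distances are voxel-center to voxel-center.
#'
#' @param itv,ctv,fctv [voxel_mask]s on a common grid.
#' @return volume in ml.
#' @export
internal_margin_volume <- function(itv, ctv) {
  stop_if_grid_mismatch(itv, ctv)
  sum(itv$data & !ctv$data) * prod(itv$spacing) / 1000
}

#' @rdname internal_margin_volume
#' @export
healthy_tissue_hit <- function(itv, fctv) {
  stop_if_grid_mismatch(itv, fctv)
  sum(itv$data & !fctv$data) * prod(itv$spacing) / 1000
}

#' @rdname internal_margin_volume
#' @export
missed_ctv <- function(itv, fctv) {
  stop_if_grid_mismatch(itv, fctv)
  sum(fctv$data & !itv$data) * prod(itv$spacing) / 1000
}

#' @rdname internal_margin_volume
#' @param oar_fraction_mask OAR (spinal cord) [voxel_mask], propagated to
#'   the fraction anatomy.
#' @return for `distance_to_oar_slicewise`, a named numeric vector: per
#'   z-slice containing ITV voxels, the minimum 3-D Euclidean distance
#'   (mm) from that slice's ITV voxels to any OAR voxel; names are slice
#'   z-centers in mm.
#' @export
distance_to_oar_slicewise <- function(itv, oar_fraction_mask) {
  stop_if_grid_mismatch(itv, oar_fraction_mask)
  if (!any(oar_fraction_mask$data)) stop("empty OAR mask")
  dist <- sqrt(pmax(mask_edt_sq(oar_fraction_mask), 0))
  nz <- dim(itv$data)[3]
  out <- numeric(0)
  for (k in seq_len(nz)) {
    sl <- itv$data[, , k]
    if (!any(sl)) next
    z_mm <- itv$origin[3] + (k - 0.5) * itv$spacing[3]
    out[as.character(z_mm)] <- min(dist[, , k][sl])
  }
  out
}

# default pipeline configuration used by the cohort comparison
default_eval_config <- function() {
  list(margin_radius = 3,
       ncc_threshold = 0.7,
       head_threshold = 15, shoulder_threshold = 60,
       shoulder_rule = "higher",
       young_modulus = 10, poisson_ratio = 0.45, spring_k = 1000,
       fem_tol = 1e-3, fem_max_iter = 60,
       n_components = 5, n_scenarios = 400, hit_threshold = 0.05,
       denoise_min_patients = 11,
       margin2_mode = "ci", weight_exponent = 1,
       use_outlier_filter = TRUE)
}

# align one observed fraction set onto the planning pose; returns the
# aligned landmark_set or NULL when alignment is impossible
align_fraction <- function(planning, observed, model, config) {
  if (config$use_outlier_filter && !is.null(model))
    observed <- flag_outliers(observed, model,
                              head_threshold = config$head_threshold,
                              shoulder_threshold = config$shoulder_threshold,
                              shoulder_rule = config$shoulder_rule)
  tr <- tryCatch(procrustes_align(planning, observed),
                 error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  apply_rigid(tr, observed)
}

#' Leave-one-out cohort comparison of the three margin approaches
#'
#' Runs the full internal-margin pipeline on a synthetic cohort: outlier
#' rejection and Procrustes couch-correction on the observed landmark
#' sets, per-patient ITV construction with each requested approach
#' (1 = constant dilation, 2 = distance-weighted local margins,
#' 3 = statistical biomechanical scenario accumulation), and the four
#' quality metrics per patient and fraction.  Every statistic or model a
#' patient's margin depends on is built from the other patients only;
#' fraction-level ground-truth fCTVs come from the generator's true
#' deformations, so model error is measured rather than hidden.
#'
#' @param cohort a [simulate_fraction_poses()] cohort.
#' @param approaches subset of `c(1, 2, 3)`.
#' @param config named list overriding entries of the default
#'   configuration (margin radius, FEM material and spring parameters,
#'   scenario count, thresholds, ...).
#' @param seed RNG seed governing scenario sampling.
#' @return object of class `margin_report`: `per_patient` and `cohort`
#'   data frames, the configuration, and (optionally) the ITVs.
#' @param keep_itvs retain the per-patient ITV masks in the result.
#' @export
run_loocv_comparison <- function(cohort, approaches = c(1, 2, 3),
                                 config = list(), seed = 1,
                                 keep_itvs = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"),
            all(approaches %in% 1:3))
  if (length(cohort$patients) < 3) stop("need at least 3 patients")
  cfg <- utils::modifyList(default_eval_config(), config)
  set.seed(seed)
  phantom <- cohort$phantom
  ctv <- phantom$ctv
  cord <- phantom$cord
  pids <- names(cohort$patients)

  # --- landmark pipeline: outlier filter + couch correction -------------
  geo_model <- NULL
  if (cfg$use_outlier_filter) {
    training <- unlist(lapply(cohort$patients, function(p)
      lapply(p$fractions, `[[`, "observed")), recursive = FALSE)
    geo_model <- fit_geometric_model(training,
                                     default_bone_assignment(phantom))
  }
  aligned <- lapply(cohort$patients, function(p) {
    sets <- lapply(p$fractions, function(fr)
      align_fraction(p$planning, fr$observed, geo_model, cfg))
    sets[!vapply(sets, is.null, logical(1))]
  })
  pose <- build_pose_vectors(aligned)
  planning_vec <- as.vector(t(phantom$landmarks$positions))
  residuals_by_patient <- lapply(pose$patients, function(pp) {
    R <- sweep(pp$U, 2, pp$mean_pose - planning_vec, "+")
    R[!pp$observed] <- NA
    R
  })

  # --- shared precomputation for approach 3 ----------------------------
  mesh <- phantom$mesh
  material <- material_params(cfg$young_modulus, cfg$poisson_ratio)
  ctv_attach <- NULL
  lm_attach <- NULL
  if (3 %in% approaches) {
    ctv_attach <- locate_in_mesh(mask_points(ctv), mesh)
    lm_attach <- locate_in_mesh(phantom$landmarks$positions, mesh)
  }

  itvs <- list()
  rows <- list()
  v_ctv <- mask_volume_ml(ctv)
  for (pid in pids) {
    others <- setdiff(pids, pid)
    itv_p <- list()
    if (1 %in% approaches)
      itv_p[["1"]] <- margin_constant(ctv, cfg$margin_radius)
    if (2 %in% approaches) {
      st <- residual_statistics(residuals_by_patient, exclude = pid)
      fld <- margin_distance_field(ctv, phantom$landmarks$positions, st,
                                   mode = cfg$margin2_mode,
                                   weight_exponent = cfg$weight_exponent)
      itv_p[["2"]] <- margin_distance(ctv, fld)
    }
    if (3 %in% approaches) {
      model <- fit_ppca(pooled_u(pose, exclude = pid),
                        n_components = cfg$n_components,
                        observed = pooled_observed(pose, exclude = pid))
      means <- mean_pose_matrix(pose)
      if (length(others) >= cfg$denoise_min_patients) {
        # mean-pose noise reduction: reconstruct the target's mean pose
        # from the inter-patient subspace (needs enough patients to
        # estimate that subspace; with few patients the raw
        # within-patient mean is the better estimator)
        mm <- fit_ppca(mean_pose_matrix(pose, exclude = pid),
                       n_components = cfg$n_components)
        target_mean <- ppca_reconstruct(mm, means[pid, , drop = FALSE])
      } else {
        target_mean <- means[pid, , drop = FALSE]
      }
      scen <- sample_pose_scenarios(model, n = cfg$n_scenarios)
      fields <- vector("list", nrow(scen))
      for (s in seq_len(nrow(scen))) {
        targets <- pose_to_positions(target_mean + scen[s, ])
        bc <- spring_bc(mesh, phantom$landmarks$positions, targets,
                        stiffness = cfg$spring_k,
                        attachments = lm_attach)
        fields[[s]] <- suppressWarnings(
          solve_pose_deformation(mesh, material, bc, tol = cfg$fem_tol,
                                 max_iter = cfg$fem_max_iter))
      }
      itv_p[["3"]] <- margin_fem(ctv, fields,
                                 hit_threshold = cfg$hit_threshold,
                                 attachments = ctv_attach)
    }
    if (keep_itvs) itvs[[pid]] <- itv_p

    # --- metrics against generator ground truth ------------------------
    frs <- cohort$patients[[pid]]$fractions
    fr_masks <- lapply(frs, function(fr) {
      def <- deformation_fn(phantom, fr$coefs, cohort$sim$mode_amplitudes)
      list(fctv = mask_warp_fn(ctv, def), fcord = mask_warp_fn(cord, def))
    })
    for (a in names(itv_p)) {
      itv <- itv_p[[a]]
      hit <- vapply(fr_masks, function(m) healthy_tissue_hit(itv, m$fctv),
                    numeric(1))
      mis <- vapply(fr_masks, function(m) missed_ctv(itv, m$fctv),
                    numeric(1))
      dsc <- vapply(fr_masks, function(m)
        mean(distance_to_oar_slicewise(itv, m$fcord)), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        patient = pid, approach = as.integer(a),
        v_ctv_ml = v_ctv,
        v_itv_ctv_ml = internal_margin_volume(itv, ctv),
        healthy_hit_ml = mean(hit), healthy_hit_sd = stats::sd(hit),
        missed_ctv_ml = mean(mis), missed_ctv_sd = stats::sd(mis),
        d_sc_mm = mean(dsc))
    }
  }
  per_patient <- do.call(rbind, rows)

  cohort_tab <- do.call(rbind, lapply(sort(unique(per_patient$approach)),
                                      function(a) {
    sub <- per_patient[per_patient$approach == a, ]
    data.frame(approach = a,
               v_itv_ctv_ml = mean(sub$v_itv_ctv_ml),
               healthy_hit_ml = mean(sub$healthy_hit_ml),
               missed_ctv_ml = mean(sub$missed_ctv_ml),
               d_sc_mm = mean(sub$d_sc_mm))
  }))
  if (1 %in% cohort_tab$approach) {
    base <- cohort_tab[cohort_tab$approach == 1, ]
    pct <- function(x, b) {
      if (b == 0) return(rep(NA_real_, length(x)))
      100 * (x - b) / b
    }
    cohort_tab$v_itv_ctv_pct <- pct(cohort_tab$v_itv_ctv_ml,
                                    base$v_itv_ctv_ml)
    cohort_tab$healthy_hit_pct <- pct(cohort_tab$healthy_hit_ml,
                                      base$healthy_hit_ml)
    cohort_tab$missed_ctv_pct <- pct(cohort_tab$missed_ctv_ml,
                                     base$missed_ctv_ml)
    cohort_tab$d_sc_pct <- pct(cohort_tab$d_sc_mm, base$d_sc_mm)
  }
  structure(list(per_patient = per_patient, cohort = cohort_tab,
                 config = cfg, seed = seed,
                 itvs = if (keep_itvs) itvs),
            class = "margin_report")
}

#' @export
print.margin_report <- function(x, ...) {
  cat("margin_report:", length(unique(x$per_patient$patient)),
      "patients,", nrow(x$cohort), "approaches\n")
  print(x$cohort, row.names = FALSE)
  invisible(x)
}
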