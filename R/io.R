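#' Read / write landmark tables
#'
#' Landmark tables are CSV files with columns `patient_id, fraction_id,
#' name, region, x_mm, y_mm, z_mm, valid, ncc_score`; rows with
#' `valid = FALSE` are preserved on round trips.  Invalid rows (missing
#' columns, non-numeric coordinates for valid landmarks) are rejected
#' with their row numbers.
#'
#' @param path CSV file path.
#' @return `read_landmarks`: a data.frame in the schema above.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "fraction_id", "name", "region", "x_mm",
                "y_mm", "z_mm", "valid")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("landmark table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!"ncc_score" %in% names(df)) df$ncc_score <- NA_real_
  df$valid <- as.logical(df$valid)
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & df$valid)
    if (length(bad))
      stop("non-numeric ", col, " in row(s) ",
           paste(bad, collapse = ", "), " of ", path)
    df[[col]] <- v
  }
  df
}

#' @rdname read_landmarks
#' @param df landmark data.frame.
#' @export
write_landmarks <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert between landmark sets and table rows
#'
#' @param ls a [landmark_set].
#' @param patient_id patient identifier for the table rows.
#' @return `landmark_table`: data.frame rows; `landmark_set_from_table`:
#'   a [landmark_set].
#' @export
landmark_table <- function(ls, patient_id) {
  data.frame(patient_id = patient_id, fraction_id = ls$fraction_id,
             name = ls$names, region = ls$region,
             x_mm = ls$positions[, 1], y_mm = ls$positions[, 2],
             z_mm = ls$positions[, 3], valid = ls$valid,
             ncc_score = if (is.null(ls$ncc_score)) NA_real_
                         else ls$ncc_score,
             row.names = NULL)
}

#' @rdname landmark_table
#' @param df landmark table rows for a single patient and fraction.
#' @export
landmark_set_from_table <- function(df) {
  stopifnot(length(unique(df$fraction_id)) == 1)
  landmark_set(df$name, cbind(df$x_mm, df$y_mm, df$z_mm), df$region,
               valid = df$valid, fraction_id = df$fraction_id[1],
               ncc_score = df$ncc_score)
}

#' Read / write binary masks as NIfTI
#'
#' Masks are stored as uint8 NIfTI volumes with the grid origin in the
#' qform offset.  Inputs whose spacing differs from the requested working
#' grid are resampled by nearest neighbor with a notice.
#'
#' @param path `.nii` / `.nii.gz` path (the suffix is added by
#'   `oro.nifti` on write when absent).
#' @param target_spacing working grid spacing, mm; `NULL` keeps the
#'   file's spacing.
#' @return a [voxel_mask].
#' @export
read_mask_nifti <- function(path, target_spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(oro.nifti::readNIfTI(path, reorient = FALSE),
                  error = function(e)
                    stop("malformed NIfTI file ", path, ": ",
                         conditionMessage(e)))
  spacing <- oro.nifti::pixdim(img)[2:4]
  origin <- c(img@qoffset_x, img@qoffset_y, img@qoffset_z)
  mask <- voxel_mask(img@.Data > 0, origin, spacing)
  if (!is.null(target_spacing) &&
      max(abs(spacing - target_spacing)) > 1e-6) {
    message("resampling ", path, " from ",
            paste(signif(spacing, 3), collapse = "x"), " to ",
            paste(target_spacing, collapse = "x"),
            " mm (nearest neighbor)")
    mask <- resample_mask(mask, target_spacing)
  }
  mask
}

#' @rdname read_mask_nifti
#' @export
read_intensity_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(oro.nifti::readNIfTI(path, reorient = FALSE),
                  error = function(e)
                    stop("malformed NIfTI file ", path, ": ",
                         conditionMessage(e)))
  intensity_volume(img@.Data, c(img@qoffset_x, img@qoffset_y,
                                img@qoffset_z),
                   oro.nifti::pixdim(img)[2:4])
}

#' @rdname read_mask_nifti
#' @param volume an [intensity_volume].
#' @export
write_intensity_nifti <- function(volume, path) {
  img <- oro.nifti::nifti(volume$data, datatype = 16)  # float32
  img@pixdim[1] <- 1
  img@pixdim[2:4] <- volume$spacing
  img@qform_code <- 1L
  img@qoffset_x <- volume$origin[1]
  img@qoffset_y <- volume$origin[2]
  img@qoffset_z <- volume$origin[3]
  img@quatern_d <- 1
  oro.nifti::writeNIfTI(img, sub("\\.nii(\\.gz)?$", "", path))
  invisible(path)
}

resample_mask <- function(mask, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3)
  extent <- dim(mask$data) * mask$spacing
  dims <- pmax(1L, as.integer(round(extent / spacing)))
  src <- lapply(1:3, function(a) {
    ctr <- (seq_len(dims[a]) - 0.5) * spacing[a]
    pmin(pmax(as.integer(floor(ctr / mask$spacing[a])) + 1L, 1L),
         dim(mask$data)[a])
  })
  voxel_mask(mask$data[src[[1]], src[[2]], src[[3]], drop = FALSE],
             mask$origin, spacing)
}

#' @rdname read_mask_nifti
#' @param mask a [voxel_mask].
#' @export
write_mask_nifti <- function(mask, path) {
  img <- oro.nifti::nifti(array(as.integer(mask$data), dim(mask$data)),
                          datatype = 2)  # uint8
  img@pixdim[1] <- 1
  img@pixdim[2:4] <- mask$spacing
  img@qform_code <- 1L
  img@qoffset_x <- mask$origin[1]
  img@qoffset_y <- mask$origin[2]
  img@qoffset_z <- mask$origin[3]
  img@quatern_d <- 1
  path <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(img, path)
  invisible(path)
}

#' Read / write tetrahedral meshes in legacy VTK ASCII format
#'
#' Supports `UNSTRUCTURED_GRID` datasets with tetrahedral cells (VTK cell
#' type 10); node units mm.
#'
#' @param path `.vtk` file path.
#' @return a [tet_mesh].
#' @export
read_mesh_vtk <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  pi_ <- grep("^POINTS", lines)
  ci_ <- grep("^CELLS", lines)
  ti_ <- grep("^CELL_TYPES", lines)
  if (!length(pi_) || !length(ci_) || !length(ti_))
    stop("malformed VTK file ", path,
         ": POINTS/CELLS/CELL_TYPES section missing")
  np <- as.integer(strsplit(lines[pi_], "\\s+")[[1]][2])
  coords <- scan(text = paste(lines[(pi_ + 1):(ci_ - 1)],
                              collapse = " "),
                 quiet = TRUE)
  nodes <- matrix(coords[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  nc <- as.integer(strsplit(lines[ci_], "\\s+")[[1]][2])
  cells <- scan(text = paste(lines[(ci_ + 1):(ti_ - 1)],
                             collapse = " "),
                quiet = TRUE)
  types <- scan(text = paste(lines[(ti_ + 1):length(lines)],
                             collapse = " "),
                quiet = TRUE, n = nc)
  tets <- matrix(0L, 0, 4)
  pos <- 1
  rows <- list()
  for (i in seq_len(nc)) {
    cnt <- cells[pos]
    if (types[i] == 10) {
      if (cnt != 4) stop("tetrahedral cell with ", cnt, " nodes in ", path)
      rows[[length(rows) + 1]] <- cells[(pos + 1):(pos + 4)] + 1L
    }
    pos <- pos + cnt + 1
  }
  if (!length(rows)) stop("no tetrahedra in ", path)
  tet_mesh(nodes, do.call(rbind, rows))
}

#' @rdname read_mesh_vtk
#' @param mesh a [tet_mesh].
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral patient mesh, units mm", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE,
                     col.names = FALSE)
  m <- nrow(mesh$tets)
  writeLines(paste("CELLS", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(10L, m)), con)
  invisible(path)
}

#' Persist / restore a fitted pose model
#'
#' Flat YAML container holding the mean, components, variances and
#' provenance fields.
#'
#' @param model a [fit_ppca()] result.
#' @param path output file.
#' @param extra named list of provenance entries (seed, cohort manifest).
#' @export
write_pose_model <- function(model, path, extra = list()) {
  obj <- c(list(mean = as.numeric(model$mean),
                components = lapply(seq_len(ncol(model$components)),
                                    function(j)
                                      as.numeric(model$components[, j])),
                component_variances =
                  as.numeric(model$component_variances),
                noise_variance = model$noise_variance), extra)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_pose_model
#' @export
read_pose_model <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(list(mean = as.numeric(obj$mean),
                 components = do.call(cbind,
                                      lapply(obj$components, as.numeric)),
                 component_variances =
                   as.numeric(obj$component_variances),
                 noise_variance = as.numeric(obj$noise_variance)),
            class = "ppca_model")
}

#' Read and validate a pipeline configuration file
#'
#' Single declarative YAML file; unknown keys are rejected and values
#' are range-checked before any compute.  `overrides` entries
#' (`key=value` strings, as from a `--set` command-line flag) take
#' precedence.
#'
#' @param path YAML file (optional; `NULL` gives the defaults).
#' @param overrides character vector of `key=value` strings.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL, overrides = character()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad --set override: ", ov)
    if (!kv[1] %in% names(cfg))
      stop("unknown configuration key: ", kv[1])
    old <- cfg[[kv[1]]]
    cfg[[kv[1]]] <- if (is.numeric(old)) as.numeric(kv[2])
                    else if (is.logical(old)) as.logical(kv[2])
                    else kv[2]
  }
  validate_pipeline_config(cfg)
  cfg
}

default_pipeline_config <- function() {
  c(list(preset = "tiny", n_patients = 6, n_fractions = 10, seed = 1,
         approaches = c(1, 2, 3), output_dir = "itvmargin_out",
         write_masks = FALSE),
    default_eval_config())
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$preset %in% c("default", "tiny"),
            cfg$n_patients >= 3, cfg$n_fractions >= 2,
            cfg$margin_radius >= 0,
            cfg$ncc_threshold >= -1, cfg$ncc_threshold <= 1,
            cfg$head_threshold > 0, cfg$shoulder_threshold > 0,
            cfg$shoulder_rule %in% c("higher", "lower"),
            cfg$young_modulus > 0,
            cfg$poisson_ratio >= 0, cfg$poisson_ratio < 0.5,
            cfg$spring_k > 0, cfg$fem_tol > 0, cfg$fem_max_iter >= 1,
            cfg$n_components >= 1, cfg$n_scenarios >= 1,
            cfg$hit_threshold >= 0, cfg$hit_threshold < 1,
            cfg$margin2_mode %in% c("ci", "yang"),
            cfg$weight_exponent > 0,
            all(cfg$approaches %in% 1:3))
  invisible(cfg)
}

#' Run the end-to-end pipeline
#'
#' Generates (or re-uses) a synthetic cohort, runs the leave-one-out
#' margin comparison and writes the per-patient and cohort report CSVs
#' plus a run manifest (configuration, seed, package version) to the
#' output directory.  Deterministic given the seeds; inputs are never
#' mutated on disk.
#'
#' @param config configuration list from [read_config()].
#' @param cohort optional pre-built cohort (otherwise generated from the
#'   config's preset / size / seed).
#' @return the [run_loocv_comparison()] report, invisibly; files are the
#'   primary output.
#' @export
run_pipeline <- function(config = read_config(), cohort = NULL) {
  validate_pipeline_config(config)
  if (is.null(cohort))
    cohort <- generate_cohort(
      phantom_spec(config$preset),
      pose_sim_spec(n_patients = config$n_patients,
                    n_fractions = config$n_fractions,
                    seed = config$seed))
  report <- run_loocv_comparison(cohort, approaches = config$approaches,
                                 config = config, seed = config$seed,
                                 keep_itvs = isTRUE(config$write_masks))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_patient,
                   file.path(config$output_dir, "per_patient.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cohort,
                   file.path(config$output_dir, "cohort.csv"),
                   row.names = FALSE)
  if (isTRUE(config$write_masks)) {
    for (pid in names(report$itvs))
      for (a in names(report$itvs[[pid]]))
        write_mask_nifti(report$itvs[[pid]][[a]],
                         file.path(config$output_dir,
                                   sprintf("itv_%s_approach%s", pid, a)))
  }
  manifest <- list(
    package = "itvmargin",
    version = as.character(utils::packageVersion("itvmargin")),
    seed = config$seed,
    config = config[order(names(config))],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(manifest,
                   file.path(config$output_dir, "manifest.yaml"))
  invisible(report)
}
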