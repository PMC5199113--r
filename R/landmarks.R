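#' Named 3-D landmark set for one image / fraction
#'
#' Landmark positions are in mm in the patient frame (x = left-right,
#' y = dorsal-ventral, z = cranial-caudal).  Landmarks lost to tracking
#' failure or a limited field of view are carried with `valid = FALSE`,
#' never imputed; downstream stages must tolerate substantial missingness.
#'
#' @param names unique landmark identifiers.
#' @param positions n x 3 matrix, mm.
#' @param region per-landmark tag in `c("skull", "spine", "shoulder")`.
#' @param valid per-landmark logical validity flag.
#' @param fraction_id integer; 0 denotes the planning image.
#' @param ncc_score optional per-landmark tracking score.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(names, positions, region, valid = NULL,
                         fraction_id = 0L, ncc_score = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(names)
  stopifnot(nrow(positions) == n, length(region) == n,
            !anyDuplicated(names),
            all(region %in% c("skull", "spine", "shoulder")))
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (any(valid & !stats::complete.cases(positions)))
    stop("valid landmarks must have finite positions")
  rownames(positions) <- names
  structure(list(names = as.character(names), positions = positions,
                 region = as.character(region), valid = as.logical(valid),
                 fraction_id = as.integer(fraction_id),
                 ncc_score = ncc_score),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set: fraction ", x$fraction_id, ", ", length(x$names),
      " landmarks (", sum(x$valid), " valid); regions: ",
      paste(names(table(x$region)), table(x$region), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rigid transform (rotation + translation, no scaling)
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation is not orthogonal")
  if (det(rotation) < 0) stop("rotation is a reflection")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)[1:3]),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a landmark set
#'
#' @param transform a [rigid_transform].
#' @param x n x 3 matrix of points (mm) or a [landmark_set].
#' @return object of the same type as `x`, transformed.
#' @export
apply_rigid <- function(transform, x) {
  if (inherits(x, "landmark_set")) {
    out <- x
    ok <- stats::complete.cases(x$positions)
    out$positions[ok, ] <- apply_rigid(transform,
                                       x$positions[ok, , drop = FALSE])
    return(out)
  }
  p <- matrix(as.numeric(x), ncol = 3)
  sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Least-squares rigid alignment of a fraction onto the planning pose
#'
#' Simulates the daily image-guided couch correction: the rigid transform
#' (rotation + translation, no scaling, reflections excluded by SVD sign
#' correction) minimizing the sum of squared distances between shared
#' valid landmarks of a reference region (skull by default) is computed
#' and is meant to be applied to all landmarks downstream.
#'
#' @param planning planning-image [landmark_set].
#' @param fraction fraction-image [landmark_set].
#' @param reference_region region tag used for the fit.
#' @return a [rigid_transform] `T` such that `apply_rigid(T, fraction)`
#'   best matches `planning` on the reference region.
#' @export
procrustes_align <- function(planning, fraction,
                             reference_region = "skull") {
  shared <- intersect(planning$names[planning$valid &
                                       planning$region == reference_region],
                      fraction$names[fraction$valid])
  if (length(shared) < 3)
    stop("alignment failure: fewer than 3 shared valid '",
         reference_region, "' landmarks")
  X <- planning$positions[shared, , drop = FALSE]
  Y <- fraction$positions[shared, , drop = FALSE]
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  sv <- svd(crossprod(Yc, Xc))   # H = Y' X
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("alignment failure: reference landmarks are collinear")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, xc - as.numeric(R %*% yc))
}

#' Residual landmark displacements after rigid alignment
#'
#' The residual displacements at individual landmarks, fraction minus
#' planning position, represent the individual (non-rigid) deformations
#' that remain after the simulated couch correction.
#'
#' @param planning planning [landmark_set].
#' @param aligned_fraction fraction [landmark_set], already rigidly
#'   aligned onto the planning pose.
#' @return n x 3 matrix of displacements (mm) with landmark row names;
#'   rows for landmarks invalid in either set are `NA`.
#' @export
residual_displacements <- function(planning, aligned_fraction) {
  shared <- intersect(planning$names, aligned_fraction$names)
  out <- matrix(NA_real_, length(shared), 3,
                dimnames = list(shared, c("x", "y", "z")))
  ok <- planning$valid[match(shared, planning$names)] &
    aligned_fraction$valid[match(shared, aligned_fraction$names)]
  if (!any(ok)) {
    warning("no shared valid landmarks; empty residual set")
    return(out)
  }
  out[ok, ] <- aligned_fraction$positions[shared[ok], , drop = FALSE] -
    planning$positions[shared[ok], , drop = FALSE]
  out
}

#' 3-D intensity volume
#'
#' Same geometry conventions as [voxel_mask] but with numeric voxel data;
#' used by the template-matching landmark tracker.
#'
#' @param data numeric 3-D array.
#' @inheritParams voxel_mask
#' @return object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, origin = c(0, 0, 0),
                             spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0))
  structure(list(data = data, origin = as.numeric(origin)[1:3],
                 spacing = spacing),
            class = "intensity_volume")
}

# extract a patch (template) centered on a world position; half_size in
# voxels per axis
extract_patch <- function(volume, center_mm, half_size) {
  ci <- as.integer(floor((center_mm - volume$origin) / volume$spacing)) + 1L
  lo <- ci - half_size
  hi <- ci + half_size
  d <- dim(volume$data)
  if (any(lo < 1) || any(hi > d))
    stop("tracking failure: template window leaves the volume")
  volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

#' Track a landmark by normalized cross-correlation template matching
#'
#' Slides an intensity template over every integer-voxel offset of a
#' search window and reports the position maximizing the normalized
#' cross-correlation together with that maximum.  NCC acts as an absolute
#' measure of conformity; the caller marks the landmark invalid when the
#' score falls below the acceptance threshold (0.7 by default in the
#' pipeline), which catches landmarks outside the field of view and
#' doubtful correspondences.  No subvoxel refinement is performed; ties
#' are broken by the first offset in lexicographic voxel order.
#'
#' @param template numeric 3-D array (odd dimensions), cut around the
#'   planning-image landmark; must have non-zero intensity variance.
#' @param search_volume an [intensity_volume].
#' @param center_mm search-window center in mm (typically the planning
#'   landmark position).
#' @param search_half_size integer half-extent of the search window in
#'   voxels per axis (template must fit strictly inside).
#' @return list with `position` (mm, template-center position at the best
#'   offset) and `score` (in `[-1, 1]`).
#' @export
ncc_track <- function(template, search_volume, center_mm,
                      search_half_size) {
  td <- dim(template)
  if (any(td %% 2 == 0)) stop("template dimensions must be odd")
  tvec <- as.numeric(template)
  if (stats::sd(tvec) == 0)
    stop("tracking failure: template has zero intensity variance")
  th <- (td - 1L) %/% 2L
  search_half_size <- rep_len(as.integer(search_half_size), 3L)
  if (any(search_half_size <= th))
    stop("template must be strictly smaller than the search window")
  win <- tryCatch(extract_patch(search_volume, center_mm,
                                search_half_size),
                  error = function(e) stop("tracking failure: ",
                                           conditionMessage(e)))
  wd <- dim(win)
  offs <- expand.grid(i = 0:(wd[1] - td[1]), j = 0:(wd[2] - td[2]),
                      k = 0:(wd[3] - td[3]))
  tcent <- tvec - mean(tvec)
  tnorm <- sqrt(sum(tcent^2))
  best <- -Inf
  best_off <- c(0L, 0L, 0L)
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    sub <- win[(o[1] + 1):(o[1] + td[1]), (o[2] + 1):(o[2] + td[2]),
               (o[3] + 1):(o[3] + td[3])]
    svec <- as.numeric(sub)
    scent <- svec - mean(svec)
    den <- tnorm * sqrt(sum(scent^2))
    score <- if (den == 0) -Inf else sum(tcent * scent) / den
    if (score > best) {  # strict: first lexicographic offset wins ties
      best <- score
      best_off <- o
    }
  }
  if (!is.finite(best))
    stop("tracking failure: search window has zero intensity variance")
  ci <- as.integer(floor((center_mm - search_volume$origin) /
                           search_volume$spacing)) + 1L
  win_lo <- ci - search_half_size
  center_idx <- win_lo + best_off + th   # template-center voxel index
  position <- search_volume$origin +
    (center_idx - 0.5) * search_volume$spacing
  list(position = as.numeric(position), score = min(best, 1.0))
}

#' Fit the geometric rigid-body landmark model
#'
#' Landmarks on the same bone cannot change their relative distance;
#' for every such pair (edge) the distribution (mean and covariance) of
#' the inter-landmark difference vector is estimated over a training set
#' of landmark sets.  Covariances are regularized with `reg * I` so they
#' stay invertible for small training sets.
#'
#' @param training_landmark_sets list of [landmark_set]s (>= 3).
#' @param bone_assignment named character vector mapping landmark name to
#'   bone; edges connect all pairs sharing a bone.
#' @param reg ridge added to each covariance, mm^2.
#' @return object of class `geometric_landmark_model`: per-edge `a`, `b`
#'   (landmark names), `mean` (3-vector), `cov` (3 x 3).
#' @export
fit_geometric_model <- function(training_landmark_sets, bone_assignment,
                                reg = 1e-6) {
  stopifnot(length(training_landmark_sets) >= 3)
  bones <- split(names(bone_assignment), unname(bone_assignment))
  edges <- list()
  for (grp in bones) {
    if (length(grp) < 2) next
    for (i in seq_len(length(grp) - 1))
      for (j in (i + 1):length(grp))
        edges[[length(edges) + 1]] <- c(grp[i], grp[j])
  }
  fitted <- list()
  for (e in edges) {
    diffs <- lapply(training_landmark_sets, function(ls) {
      ia <- match(e[1], ls$names)
      ib <- match(e[2], ls$names)
      if (is.na(ia) || is.na(ib) || !ls$valid[ia] || !ls$valid[ib])
        return(NULL)
      ls$positions[ia, ] - ls$positions[ib, ]
    })
    diffs <- do.call(rbind, diffs)
    if (is.null(diffs) || nrow(diffs) < 3) {
      warning("edge ", e[1], "-", e[2],
              " observed in fewer than 3 training sets; dropped")
      next
    }
    fitted[[length(fitted) + 1]] <- list(
      a = e[1], b = e[2], n = nrow(diffs),
      mean = colMeans(diffs),
      cov = stats::cov(diffs) + diag(reg, 3))
  }
  if (!length(fitted)) stop("no edge observed in >= 3 training sets")
  structure(list(edges = fitted, reg = reg),
            class = "geometric_landmark_model")
}

#' Flag implausible landmark correspondences with the geometric model
#'
#' For every landmark, the Mahalanobis distance of each incident
#' inter-landmark difference vector under the model's edge distribution
#' is evaluated and the minimum over the landmark's valid neighbors is
#' taken (a landmark consistent with at least one same-bone neighbor is
#' plausible).  Head-region (skull and spine) landmarks whose distance is
#' strictly above `head_threshold` are invalidated; shoulder landmarks
#' follow `shoulder_rule` (`"higher"`: invalidate strictly above
#' `shoulder_threshold`; `"lower"`: invalidate strictly below it).
#' Thresholds are exclusive: a landmark exactly at the threshold is kept.
#'
#' @param landmarks a [landmark_set].
#' @param model a [fit_geometric_model()] result.
#' @param head_threshold Mahalanobis threshold for skull/spine landmarks.
#' @param shoulder_threshold threshold for shoulder landmarks.
#' @param shoulder_rule direction of the shoulder rule.
#' @return the [landmark_set] with updated `valid` flags and a
#'   `mahalanobis` attribute holding the per-landmark distances.
#' @export
flag_outliers <- function(landmarks, model, head_threshold = 15,
                          shoulder_threshold = 60,
                          shoulder_rule = c("higher", "lower")) {
  shoulder_rule <- match.arg(shoulder_rule)
  n <- length(landmarks$names)
  dist <- rep(NA_real_, n)
  names(dist) <- landmarks$names
  for (i in seq_len(n)) {
    if (!landmarks$valid[i]) next
    nm <- landmarks$names[i]
    ds <- c()
    for (e in model$edges) {
      other <- if (e$a == nm) e$b else if (e$b == nm) e$a else next
      io <- match(other, landmarks$names)
      if (is.na(io) || !landmarks$valid[io]) next
      d <- landmarks$positions[i, ] - landmarks$positions[io, ]
      if (e$b == nm) d <- -d   # edge stores a - b
      ds <- c(ds, sqrt(stats::mahalanobis(matrix(d, 1), e$mean, e$cov)))
    }
    if (!length(ds)) {
      warning("landmark ", nm, " has no valid same-bone neighbor; kept")
      next
    }
    dist[i] <- min(ds)
  }
  out <- landmarks
  head <- landmarks$region %in% c("skull", "spine")
  bad_head <- head & !is.na(dist) & dist > head_threshold
  bad_sh <- if (shoulder_rule == "higher") {
    landmarks$region == "shoulder" & !is.na(dist) & dist > shoulder_threshold
  } else {
    landmarks$region == "shoulder" & !is.na(dist) & dist < shoulder_threshold
  }
  out$valid <- landmarks$valid & !(bad_head | bad_sh)
  attr(out, "mahalanobis") <- dist
  out
}
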