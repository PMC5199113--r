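#' Build per-patient pose vectors from aligned fraction landmark sets
#'
#' A pose vector stacks the aligned landmark coordinates of one fraction
#' in landmark-major order (x1, y1, z1, x2, ...).  Per patient, the mean
#' pose over that patient's fractions (observed coordinates only) is
#' subtracted, giving the centered pose vectors `u = p - p_mean` that feed
#' the cohort pose model.  Missing coordinates (invalid landmarks) are
#' mean-imputed within patient, i.e. enter as `u = 0`, and the observed
#' mask is retained.
#'
#' @param aligned_sets_by_patient named list (per patient) of lists of
#'   [landmark_set]s, rigidly aligned onto the planning pose; at least two
#'   fractions per patient.  All sets must share the same landmark names
#'   in the same order.
#' @return object of class `pose_vectors`: list with `patients` (per
#'   patient: `mean_pose` length-3M, `U` fractions x 3M, `observed`
#'   logical matrix, `fraction_ids`), `landmark_names`, `coord_names`.
#' @export
build_pose_vectors <- function(aligned_sets_by_patient) {
  stopifnot(length(aligned_sets_by_patient) >= 1)
  ref <- aligned_sets_by_patient[[1]][[1]]
  lm_names <- ref$names
  d <- 3L * length(lm_names)
  coord_names <- paste(rep(lm_names, each = 3), c("x", "y", "z"),
                       sep = ".")
  patients <- lapply(names(aligned_sets_by_patient), function(pid) {
    sets <- aligned_sets_by_patient[[pid]]
    if (length(sets) < 2)
      stop("patient ", pid, " has fewer than 2 fractions")
    P <- t(vapply(sets, function(ls) {
      stopifnot(identical(ls$names, lm_names))
      pos <- ls$positions
      pos[!ls$valid, ] <- NA_real_
      as.vector(t(pos))
    }, numeric(d)))
    obs <- !is.na(P)
    never <- colSums(obs) == 0
    if (any(never))
      warning("patient ", pid, ": ", sum(never) / 3,
              " landmark(s) never observed; centered at 0 displacement")
    mean_pose <- colMeans(P, na.rm = TRUE)
    mean_pose[never] <- NA_real_
    U <- sweep(P, 2, ifelse(is.na(mean_pose), 0, mean_pose))
    U[!obs] <- 0   # within-patient mean imputation
    list(patient_id = pid, mean_pose = mean_pose, U = U, observed = obs,
         fraction_ids = vapply(sets, `[[`, integer(1), "fraction_id"))
  })
  names(patients) <- names(aligned_sets_by_patient)
  structure(list(patients = patients, landmark_names = lm_names,
                 coord_names = coord_names),
            class = "pose_vectors")
}

# stack all patients' centered pose vectors, optionally excluding one
pooled_u <- function(pose_vectors, exclude = NULL) {
  keep <- setdiff(names(pose_vectors$patients), exclude)
  do.call(rbind, lapply(pose_vectors$patients[keep], `[[`, "U"))
}

# matching availability mask for pooled_u
pooled_observed <- function(pose_vectors, exclude = NULL) {
  keep <- setdiff(names(pose_vectors$patients), exclude)
  do.call(rbind, lapply(pose_vectors$patients[keep], `[[`, "observed"))
}

# matrix of per-patient mean poses (patients x 3M); NA (never-observed)
# coordinates filled with the column mean over the other patients
mean_pose_matrix <- function(pose_vectors, exclude = NULL) {
  keep <- setdiff(names(pose_vectors$patients), exclude)
  M <- t(vapply(pose_vectors$patients[keep], `[[`,
                numeric(length(pose_vectors$coord_names)), "mean_pose"))
  if (anyNA(M)) {
    cm <- colMeans(M, na.rm = TRUE)
    for (j in which(colSums(is.na(M)) > 0)) M[is.na(M[, j]), j] <- cm[j]
  }
  rownames(M) <- keep
  M
}

#' Maximum-likelihood probabilistic PCA
#'
#' Closed-form Tipping-Bishop estimator via eigendecomposition of the
#' sample covariance: the retained components span the top eigenspace,
#' the isotropic noise variance is the mean of the discarded eigenvalues,
#' and each component variance is its eigenvalue minus the noise
#' variance.  Chosen over EM for determinism (the pose dimension,
#' 3M = 72 for 24 landmarks, is small).
#'
#' @param X n x d data matrix (rows = pose vectors).
#' @param n_components number of retained components (5 by default, the
#'   model order used throughout the margin pipeline).
#' @param observed optional n x d logical availability mask.  When given,
#'   the sample covariance is computed over pairwise jointly observed
#'   entries: mean imputation alone would attenuate every variance by
#'   about the missingness rate, and a scenario model fitted on such a
#'   covariance systematically under-disperses.
#' @return object of class `ppca_model`: `mean` (length d), `components`
#'   (d x q, orthonormal columns), `component_variances` (length q,
#'   descending), `noise_variance`, `eigenvalues`.
#' @export
fit_ppca <- function(X, n_components = 5, observed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n <= n_components) {
    n_components <- max(1L, n - 1L)
    warning("too few vectors; component count reduced to ", n_components)
  }
  if (is.null(observed)) {
    mu <- colMeans(X)
    S <- stats::cov(X)
  } else {
    stopifnot(identical(dim(observed), dim(X)))
    O <- observed * 1
    n_col <- pmax(colSums(O), 1)
    mu <- colSums(X * O) / n_col
    Xc <- sweep(X, 2, mu) * O
    n_pair <- crossprod(O)
    S <- crossprod(Xc) / pmax(n_pair - 1, 1)
    S[n_pair < 2] <- 0
  }
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  q <- min(n_components, d)
  rank <- sum(ev > max(ev[1], 1) * 1e-12)
  if (rank < q) {
    warning("data rank ", rank, " below requested components; reduced")
    q <- max(1L, rank)
  }
  sigma2 <- if (q < d) mean(ev[(q + 1):d]) else 0
  structure(list(mean = mu,
                 components = eg$vectors[, seq_len(q), drop = FALSE],
                 component_variances = pmax(ev[seq_len(q)] - sigma2, 0),
                 noise_variance = sigma2,
                 eigenvalues = ev,
                 n = n),
            class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat("ppca_model: ", length(x$mean), " dims, ",
      ncol(x$components), " components; variances ",
      paste(signif(x$component_variances, 3), collapse = ", "),
      "; noise ", signif(x$noise_variance, 3), "\n", sep = "")
  invisible(x)
}

#' Posterior-mean PPCA reconstruction
#'
#' Shrinks each observation toward the model subspace:
#' `x_hat = mu + C diag(v / (v + sigma2)) C' (x - mu)`.  With zero noise
#' variance this is the orthogonal projection onto the subspace.
#'
#' @param model a [fit_ppca()] result.
#' @param X n x d matrix of observations.
#' @return n x d matrix of reconstructions.
#' @export
ppca_reconstruct <- function(model, X) {
  X <- matrix(as.numeric(X), ncol = length(model$mean))
  v <- model$component_variances
  shrink <- ifelse(v + model$noise_variance > 0,
                   v / (v + model$noise_variance), 0)
  Xc <- sweep(X, 2, model$mean)
  Z <- Xc %*% model$components
  sweep(Z %*% (t(model$components) * shrink), 2, model$mean, "+")
}

#' Noise-reduce per-patient mean poses
#'
#' Fits a PPCA model of the per-patient mean landmark positions across
#' the cohort and replaces each mean pose by its reconstruction from the
#' retained components, suppressing patient-specific tracking noise
#' before scenario sampling.  With `loo = TRUE` each patient's
#' reconstruction uses a model fitted without that patient.
#'
#' @param means patients x 3M matrix of mean poses (rows named by
#'   patient).
#' @param n_components retained components (reduced with a warning when
#'   fewer patients are available).
#' @param loo leave the reconstructed patient out of the fit.
#' @return matrix of the same shape with denoised mean poses.
#' @export
denoise_mean_poses <- function(means, n_components = 5, loo = FALSE) {
  means <- as.matrix(means)
  if (nrow(means) < 2) stop("need at least 2 patients")
  if (!loo) {
    model <- fit_ppca(means, n_components)
    out <- ppca_reconstruct(model, means)
  } else {
    out <- means
    for (i in seq_len(nrow(means))) {
      model <- fit_ppca(means[-i, , drop = FALSE], n_components)
      out[i, ] <- ppca_reconstruct(model, means[i, , drop = FALSE])
    }
  }
  dimnames(out) <- dimnames(means)
  out
}

#' Sample synthetic pose scenarios from a pose model
#'
#' Coefficients are drawn independently from zero-mean Gaussians with the
#' model's component variances and mapped through the components:
#' `sample = mean + C q`.  No isotropic noise term is added by default
#' (the retained components alone define a consistent pose); set
#' `include_noise = TRUE` to add `N(0, noise_variance I)`.
#'
#' @param model a [fit_ppca()] result.
#' @param n number of scenarios (400 by default).
#' @param seed optional RNG seed for reproducibility.
#' @param include_noise add the isotropic residual term.
#' @return n x d matrix of sampled pose vectors.
#' @export
sample_pose_scenarios <- function(model, n = 400, seed = NULL,
                                  include_noise = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- ncol(model$components)
  Q <- matrix(stats::rnorm(n * q), n, q) %*%
    diag(sqrt(model$component_variances), q)
  X <- sweep(Q %*% t(model$components), 2, model$mean, "+")
  if (include_noise && model$noise_variance > 0)
    X <- X + matrix(stats::rnorm(n * length(model$mean),
                                 sd = sqrt(model$noise_variance)),
                    n, length(model$mean))
  X
}

# convert a pose vector (length 3M, landmark-major) to an M x 3 matrix
pose_to_positions <- function(pose, landmark_names = NULL) {
  m <- matrix(pose, ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  if (!is.null(landmark_names)) rownames(m) <- landmark_names
  m
}
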