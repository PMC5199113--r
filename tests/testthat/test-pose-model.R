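toy_aligned_sets <- function(positions_list, fraction_ids = NULL) {
  n <- nrow(positions_list[[1]])
  nm <- paste0("lm", seq_len(n))
  reg <- rep(c("skull", "spine", "shoulder"), length.out = n)
  lapply(seq_along(positions_list), function(i)
    landmark_set(nm, positions_list[[i]], reg,
                 fraction_id = if (is.null(fraction_ids)) i
                               else fraction_ids[i]))
}

test_that("build_pose_vectors centers fractions on the patient mean", {
  base <- matrix(stats::runif(18, 0, 100), 6, 3)
  # identical fractions: all u = 0
  pv <- build_pose_vectors(list(A = toy_aligned_sets(list(base, base))))
  expect_equal(max(abs(pv$patients$A$U)), 0)
  # fractions at +a and -a around the mean: u exactly +/- a
  a <- matrix(stats::rnorm(18), 6, 3)
  pv2 <- build_pose_vectors(list(A = toy_aligned_sets(
    list(base + a, base - a))))
  expect_equal(pv2$patients$A$U[1, ], as.vector(t(a)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pv2$patients$A$U[2, ], -as.vector(t(a)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("missing coordinates are imputed at the patient mean (u = 0)", {
  base <- matrix(stats::runif(18, 0, 100), 6, 3)
  sets <- toy_aligned_sets(list(base + 1, base - 1, base))
  sets[[2]]$valid[4] <- FALSE
  pv <- build_pose_vectors(list(A = sets))
  ix <- (4 - 1) * 3 + 1:3
  expect_equal(pv$patients$A$U[2, ix], c(0, 0, 0), ignore_attr = TRUE)
  expect_false(any(pv$patients$A$observed[2, ix]))
  # never-observed landmark: warning and zero displacement
  sets2 <- toy_aligned_sets(list(base, base + 1))
  sets2[[1]]$valid[2] <- FALSE
  sets2[[2]]$valid[2] <- FALSE
  expect_warning(pv2 <- build_pose_vectors(list(A = sets2)),
                 "never observed")
  expect_equal(pv2$patients$A$U[, 4:6], matrix(0, 2, 3),
               ignore_attr = TRUE)
})

test_that("empirical variance of pose vectors matches the generator", {
  set.seed(20)
  base <- matrix(stats::runif(18, 0, 100), 6, 3)
  sdmat <- matrix(rep(c(0.5, 1.5, 3), each = 6), 6, 3)  # per-axis truth
  n <- 400
  sets <- toy_aligned_sets(lapply(seq_len(n), function(i)
    base + matrix(stats::rnorm(18, sd = as.vector(sdmat)), 6, 3)))
  pv <- build_pose_vectors(list(A = sets))
  emp <- apply(pv$patients$A$U, 2, stats::sd)
  truth <- as.vector(t(sdmat))
  se <- truth * sqrt(1 / (2 * (n - 1)))
  expect_true(all(abs(emp - truth) < 4 * se))
})

test_that("fit_ppca recovers a noiseless low-rank subspace", {
  set.seed(21)
  d <- 30
  q <- 5
  basis <- qr.Q(qr(matrix(stats::rnorm(d * q), d, q)))
  scores <- matrix(stats::rnorm(200 * q, sd = rep(c(5, 4, 3, 2, 1),
                                                  each = 200)), 200, q)
  X <- scores %*% t(basis)
  m <- fit_ppca(X, n_components = 5)
  expect_lt(m$noise_variance, 1e-10)
  # principal angles between fitted and true subspace
  sv <- svd(t(m$components) %*% basis)$d
  angles <- acos(pmin(sv, 1))
  expect_lt(max(angles), 1e-6)
  # orthonormal components, variances sorted descending
  expect_lt(max(abs(crossprod(m$components) - diag(5))), 1e-8)
  expect_true(all(diff(m$component_variances) <= 1e-9))
})

test_that("fit_ppca on isotropic noise attributes variance to noise", {
  set.seed(22)
  X <- matrix(stats::rnorm(4000 * 20), 4000, 20)
  m <- fit_ppca(X, n_components = 5)
  expect_lt(max(m$component_variances) / m$noise_variance, 0.25)
  expect_equal(m$noise_variance, 1, tolerance = 0.1)
})

test_that("PPCA reconstruction error is non-increasing in component count", {
  set.seed(23)
  X <- matrix(stats::rnorm(50 * 12), 50, 12) %*%
    diag(seq(3, 0.5, length.out = 12))
  errs <- vapply(1:6, function(q) {
    m <- fit_ppca(X, n_components = q)
    sum((ppca_reconstruct(m, X) - X)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("sample_pose_scenarios reproduces the model covariance", {
  set.seed(24)
  d <- 12
  basis <- qr.Q(qr(matrix(stats::rnorm(d * 3), d, 3)))
  model <- structure(list(mean = stats::rnorm(d), components = basis,
                          component_variances = c(9, 4, 1),
                          noise_variance = 0),
                     class = "ppca_model")
  S <- sample_pose_scenarios(model, n = 1e4, seed = 99)
  # scenarios lie exactly in the affine span of the components
  resid <- sweep(S, 2, model$mean) %*%
    (diag(d) - basis %*% t(basis))
  expect_lt(max(abs(resid)), 1e-9)
  # coefficient covariance within 5 % of the model variances
  Q <- sweep(S, 2, model$mean) %*% basis
  expect_true(all(abs(apply(Q, 2, stats::var) /
                        model$component_variances - 1) < 0.05))
  # zero variances: every sample equals the mean
  model0 <- model
  model0$component_variances <- c(0, 0, 0)
  S0 <- sample_pose_scenarios(model0, n = 10, seed = 1)
  expect_equal(max(abs(sweep(S0, 2, model$mean))), 0)
  # reproducible under a fixed seed
  expect_identical(sample_pose_scenarios(model, 50, seed = 5),
                   sample_pose_scenarios(model, 50, seed = 5))
})

test_that("parameter recovery on a synthetic 5-mode cohort within 10 %", {
  set.seed(25)
  d <- 72
  n <- 600
  basis <- qr.Q(qr(matrix(stats::rnorm(d * 5), d, 5)))
  truth_var <- c(25, 16, 9, 4, 2)
  X <- matrix(stats::rnorm(n * 5), n, 5) %*% diag(sqrt(truth_var)) %*%
    t(basis) + matrix(stats::rnorm(n * d, sd = 0.1), n, d)
  m <- fit_ppca(X, n_components = 5)
  expect_true(all(abs(m$component_variances / truth_var - 1) < 0.10))
})

test_that("denoise_mean_poses reconstructs subspace means and reduces noise", {
  set.seed(26)
  d <- 24
  # identical means: reconstruction returns them unchanged
  mu <- matrix(rep(stats::rnorm(d), 6), 6, d, byrow = TRUE)
  expect_lt(max(abs(quiet(denoise_mean_poses(mu, 5)) - mu)), 1e-8)
  # means exactly in a 5-dim affine subspace: error < 1e-8
  basis <- qr.Q(qr(matrix(stats::rnorm(d * 5), d, 5)))
  centers <- matrix(stats::rnorm(30 * 5, sd = 3), 30, 5) %*% t(basis)
  M <- sweep(centers, 2, stats::rnorm(d), "+")
  expect_lt(max(abs(denoise_mean_poses(M, 5) - M)), 1e-8)
  # subspace signal + noise: denoising reduces the error below sigma
  sigma <- 0.5
  noisy <- M + matrix(stats::rnorm(length(M), sd = sigma), nrow(M))
  den <- denoise_mean_poses(noisy, 5)
  err_den <- sqrt(mean((den - M)^2))
  expect_lt(err_den, sigma)
  # leave-one-out never uses the reconstructed patient
  den_loo <- denoise_mean_poses(noisy, 5, loo = TRUE)
  expect_false(isTRUE(all.equal(den_loo, den)))
})

test_that("component count is reduced with a warning when data are scarce", {
  X <- matrix(stats::rnorm(4 * 10), 4, 10)
  expect_warning(m <- fit_ppca(X, n_components = 5), "reduced")
  expect_lte(ncol(m$components), 3)
})
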