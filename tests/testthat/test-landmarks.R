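test_that("procrustes_align recovers constructed rigid transforms", {
  set.seed(42)
  planning <- toy_landmarks()
  for (i in 1:20) {
    R <- random_rotation(10)
    t <- stats::runif(3, -10, 10)
    moved <- planning
    moved$positions <- sweep(planning$positions %*% t(R), 2, t, "+")
    moved$fraction_id <- 1L
    tr <- procrustes_align(planning, moved)
    # recovered transform must undo (R, t)
    back <- apply_rigid(tr, moved)
    expect_lt(max(abs(back$positions - planning$positions)), 1e-8)
    expect_lt(max(abs(tr$rotation %*% R - diag(3))), 1e-8)
  }
})

test_that("procrustes_align is rigid: identity, idempotence, no reflection", {
  planning <- toy_landmarks()
  tr <- procrustes_align(planning, planning)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tr$translation)), 1e-10)

  # aligning an already-aligned set gives the identity again
  set.seed(7)
  moved <- planning
  moved$positions <- sweep(planning$positions %*% t(random_rotation(8)),
                           2, c(3, -2, 5), "+")
  aligned <- apply_rigid(procrustes_align(planning, moved), moved)
  tr2 <- procrustes_align(planning, aligned)
  expect_lt(max(abs(tr2$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(tr2$translation)), 1e-8)

  # mirror-image fraction: returned rotation still proper
  mirror <- planning
  mirror$positions[, 1] <- -mirror$positions[, 1]
  tr3 <- procrustes_align(planning, mirror)
  expect_gt(det(tr3$rotation), 0)
})

test_that("procrustes_align fails on degenerate reference sets", {
  planning <- toy_landmarks()
  few <- planning
  few$valid[planning$region == "skull"][1:2] <- FALSE
  few$valid <- few$valid & !(planning$region == "skull" &
                               cumsum(planning$region == "skull") > 2)
  expect_error(procrustes_align(planning, few), "fewer than 3")

  collin <- landmark_set(paste0("s", 1:4),
                         cbind(1:4, 1:4, 1:4) * 10,
                         rep("skull", 4))
  expect_error(procrustes_align(collin, collin), "collinear")
})

test_that("residual_displacements subtracts planning from aligned positions", {
  planning <- toy_landmarks()
  frac <- planning
  frac$fraction_id <- 1L
  expect_equal(unname(residual_displacements(planning, frac)),
               matrix(0, 8, 3))
  frac$positions["lm5", 3] <- frac$positions["lm5", 3] + 5
  r <- residual_displacements(planning, frac)
  expect_equal(unname(r["lm5", ]), c(0, 0, 5))
  frac$valid[1] <- FALSE
  r2 <- residual_displacements(planning, frac)
  expect_true(all(is.na(r2["lm1", ])))
  none <- frac
  none$valid[] <- FALSE
  expect_warning(r3 <- residual_displacements(planning, none),
                 "no shared valid")
  expect_true(all(is.na(r3)))
})

test_that("fit_geometric_model estimates edge distributions", {
  planning <- toy_landmarks()
  bones <- c(lm1 = "skull", lm2 = "skull", lm3 = "skull", lm4 = "skull",
             lm5 = "spineA", lm6 = "spineA",
             lm7 = "shL", lm8 = "shR")
  # identical training sets: covariance at the regularization floor
  m0 <- fit_geometric_model(rep(list(planning), 5), bones)
  for (e in m0$edges) {
    expect_lt(max(abs(e$cov - diag(1e-6, 3))), 1e-12)
  }
  # known Gaussian difference vectors: mean/cov recovered within 3 SE
  set.seed(1)
  n <- 1000
  true_mean <- c(2, -1, 0.5)
  true_sd <- c(1, 2, 0.5)
  sets <- lapply(seq_len(n), function(i) {
    ls <- planning
    ls$positions["lm5", ] <- ls$positions["lm6", ] + true_mean +
      stats::rnorm(3, sd = true_sd)
    ls
  })
  m <- fit_geometric_model(sets, c(lm5 = "b", lm6 = "b"))
  e <- m$edges[[1]]
  expect_true(all(abs(e$mean - true_mean) < 3 * true_sd / sqrt(n)))
  expect_true(all(abs(diag(e$cov) - true_sd^2) <
                    3 * true_sd^2 * sqrt(2 / (n - 1))))
  # never jointly observed edge dropped with warning
  miss <- lapply(1:5, function(i) {
    ls <- planning
    ls$valid[5] <- FALSE
    ls
  })
  expect_warning(expect_error(fit_geometric_model(miss,
                                                  c(lm5 = "b", lm6 = "b")),
                              "no edge"),
                 "dropped")
})

test_that("flag_outliers computes Mahalanobis distances and applies thresholds", {
  planning <- toy_landmarks()
  bones <- c(lm1 = "sk", lm2 = "sk", lm5 = "sp", lm6 = "sp",
             lm7 = "shb", lm8 = "shb")
  set.seed(2)
  sets <- lapply(1:50, function(i) {
    ls <- planning
    ls$positions <- ls$positions + matrix(stats::rnorm(24), 8, 3)
    ls
  })
  model <- fit_geometric_model(sets, bones)

  # landmark exactly at the model-mean relative position: distance ~ 0
  at_mean <- planning
  e1 <- model$edges[[which(vapply(model$edges, function(e)
    e$a == "lm1" || e$b == "lm1", logical(1)))[1]]]
  ref <- if (e1$a == "lm1") "lm2" else "lm2"
  at_mean$positions["lm1", ] <- at_mean$positions["lm2", ] +
    (if (e1$a == "lm1") e1$mean else -e1$mean)
  out <- quiet(flag_outliers(at_mean, model))
  expect_lt(attr(out, "mahalanobis")["lm1"], 1e-6)
  expect_true(out$valid[1])

  # injected displacement along a unit-variance axis equals the distance
  unit_model <- model
  unit_model$edges <- lapply(model$edges, function(e) {
    e$cov <- diag(3)
    e
  })
  shifted <- at_mean
  shifted$positions["lm1", ] <- shifted$positions["lm1", ] + c(7, 0, 0)
  d <- attr(quiet(flag_outliers(shifted, unit_model)), "mahalanobis")["lm1"]
  expect_equal(unname(d), 7, tolerance = 1e-8)

  # head landmark above 15 invalidated; threshold is exclusive
  shifted20 <- at_mean
  shifted20$positions["lm1", ] <- shifted20$positions["lm1", ] + c(20, 0, 0)
  expect_false(quiet(flag_outliers(shifted20, unit_model))$valid[1])
  at15 <- at_mean
  at15$positions["lm1", ] <- at15$positions["lm1", ] + c(15, 0, 0)
  expect_true(quiet(flag_outliers(at15, unit_model))$valid[1])

  # shoulder rule: default invalidates above 60; "lower" flips direction
  sh61 <- at_mean
  sh61$positions["lm7", ] <- sh61$positions["lm8", ] +
    (if (model$edges[[length(model$edges)]]$a == "lm7") 1 else -1) *
      model$edges[[length(model$edges)]]$mean + c(61, 0, 0)
  um <- unit_model
  expect_false(quiet(flag_outliers(sh61, um))$valid[7])
  expect_true(quiet(flag_outliers(sh61, um, shoulder_rule = "lower"))$valid[7])
  sh10 <- at_mean
  expect_false(quiet(flag_outliers(sh10, um, shoulder_rule = "lower"))$valid[7])

  # no valid neighbor: left unchanged with warning
  alone <- at_mean
  alone$valid[c(2, 5, 6, 8)] <- FALSE
  w <- testthat::capture_warnings(out2 <- flag_outliers(alone, unit_model))
  expect_true(any(grepl("no valid", w)))
  expect_true(out2$valid[1])
})

test_that("Mahalanobis distance is invariant under linear reparameterization", {
  set.seed(3)
  A <- matrix(stats::rnorm(9), 3, 3) + diag(3) * 2
  mu <- c(1, 2, 3)
  S <- crossprod(matrix(stats::rnorm(9), 3, 3)) + diag(3)
  x <- c(4, 1, -2)
  d1 <- stats::mahalanobis(matrix(x, 1), mu, S)
  d2 <- stats::mahalanobis(matrix(as.numeric(A %*% x), 1),
                           as.numeric(A %*% mu), A %*% S %*% t(A))
  expect_equal(d1, d2, tolerance = 1e-8)
})
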