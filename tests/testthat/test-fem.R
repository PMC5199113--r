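# closed-form constant-strain energy of a linear elastic tet under an
# affine displacement u(x) = A x
affine_energy <- function(mesh, material, A) {
  lp <- itvmargin:::lame_params(material)
  eps <- (A + t(A)) / 2
  vol <- sum(tet_volumes(mesh$nodes, mesh$tets))
  vol * (0.5 * lp$lambda * sum(diag(eps))^2 + lp$mu * sum(eps^2))
}

test_that("patch test: affine displacement reproduces constant-strain energy", {
  mesh <- regular_tet(10)
  mat <- material_params(young_modulus = 10, poisson_ratio = 0.45)
  A <- rbind(c(0.01, 0.004, 0), c(0.002, -0.008, 0.003),
             c(0, 0.005, 0.006))
  u <- mesh$nodes %*% t(A)
  e_num <- elastic_energy(mesh, mat, u, method = "linear")
  e_ref <- affine_energy(mesh, mat, A)
  expect_equal(e_num, e_ref, tolerance = 1e-8)

  # also on a multi-element mesh (energy is additive over elements)
  mesh2 <- box_mesh(hi = c(20, 20, 20), h = 10)
  u2 <- mesh2$nodes %*% t(A)
  expect_equal(elastic_energy(mesh2, mat, u2, method = "linear"),
               affine_energy(mesh2, mat, A), tolerance = 1e-8)
})

test_that("springs at rest positions give zero displacement", {
  mesh <- box_mesh(hi = c(30, 30, 30), h = 10)
  mat <- material_params()
  pts <- rbind(c(5, 5, 5), c(25, 5, 5), c(5, 25, 5), c(15, 15, 25))
  bc <- spring_bc(mesh, pts, pts, stiffness = 1000)
  fld <- solve_pose_deformation(mesh, mat, bc)
  expect_true(fld$convergence$converged)
  expect_lt(max(abs(fld$node_displacements)), 1e-9)
})

test_that("stiff-spring limit drives landmarks onto their targets", {
  mesh <- box_mesh(hi = c(30, 30, 30), h = 10)
  mat <- material_params(young_modulus = 10)
  pts <- rbind(c(5, 5, 5), c(25, 5, 5), c(5, 25, 5), c(15, 15, 25))
  tgt <- pts + rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 1, 0))
  bc <- spring_bc(mesh, pts, tgt, stiffness = 1e6)
  fld <- solve_pose_deformation(mesh, mat, bc, tol = 1e-2, max_iter = 400)
  res <- landmark_residuals(fld, bc)
  expect_lt(max(res$per_landmark), 0.01)
})

test_that("co-rotational solve is rigid-motion insensitive (linear oracle)", {
  mesh <- box_mesh(hi = c(30, 30, 30), h = 10)
  mat <- material_params()
  pts <- rbind(c(5, 5, 5), c(25, 5, 5), c(5, 25, 5), c(15, 15, 25))
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tgt <- sweep(pts %*% t(R), 2, c(4, -2, 1), "+")
  bc <- spring_bc(mesh, pts, tgt, stiffness = 1e4)
  fld_cr <- solve_pose_deformation(mesh, mat, bc, max_iter = 400)
  e_cr <- elastic_energy(mesh, mat, fld_cr$node_displacements)
  fld_lin <- solve_pose_deformation(mesh, mat, bc, method = "linear")
  e_lin <- elastic_energy(mesh, mat, fld_lin$node_displacements,
                          method = "linear")
  expect_lt(e_cr, 1e-6 * e_lin)
  # and the landmarks actually reach the rigid targets
  expect_lt(landmark_residuals(fld_cr, bc)$mean, 0.05)
})

test_that("degenerate spring configurations are rejected", {
  mesh <- box_mesh(hi = c(30, 30, 30), h = 10)
  mat <- material_params()
  two <- rbind(c(5, 5, 5), c(25, 5, 5))
  expect_error(solve_pose_deformation(mesh, mat,
                                      spring_bc(mesh, two, two + 1)),
               "degenerate")
  collin <- rbind(c(5, 5, 5), c(15, 5, 5), c(25, 5, 5))
  expect_error(solve_pose_deformation(mesh, mat,
                                      spring_bc(mesh, collin, collin)),
               "degenerate")
})

test_that("landmark_residuals measures attachment-to-target distances", {
  mesh <- regular_tet(10)
  pts <- matrix(colMeans(mesh$nodes), 1)
  bc <- spring_bc(mesh, pts, pts + c(0, 0, 2), stiffness = 1)
  zero <- displacement_field(mesh, matrix(0, 4, 3))
  r <- landmark_residuals(zero, bc)
  expect_equal(r$mean, 2)
  bc0 <- spring_bc(mesh, pts, pts, stiffness = 1)
  expect_equal(landmark_residuals(zero, bc0)$mean, 0)
})

test_that("doubling E and k together leaves the field unchanged", {
  ph <- tiny_phantom()
  lm <- ph$landmarks$positions
  def <- deformation_fn(ph, c(0.8, -0.5, 1.2, 0.4),
                        c(2.5, 2.5, 8.5, 8.5))
  tgt <- lm + def(lm)
  f1 <- solve_pose_deformation(ph$mesh, material_params(10),
                               spring_bc(ph$mesh, lm, tgt, 1000),
                               tol = 1e-4, max_iter = 100)
  f2 <- solve_pose_deformation(ph$mesh, material_params(20),
                               spring_bc(ph$mesh, lm, tgt, 2000),
                               tol = 2e-4, max_iter = 100)
  expect_lt(max(abs(f1$node_displacements - f2$node_displacements)),
            1e-3)
})

test_that("mesh refinement changes landmark residuals by < 10 %", {
  ph <- tiny_phantom()
  spec2 <- phantom_spec("tiny", mesh_edge_mm = 20)
  mesh2 <- generate_phantom(spec2)$mesh
  lm <- ph$landmarks$positions
  def <- deformation_fn(ph, c(0.5, 0.5, 1, -0.8), c(2.5, 2.5, 8.5, 8.5))
  tgt <- lm + def(lm)
  mat <- material_params()
  r1 <- landmark_residuals(
    f <- solve_pose_deformation(ph$mesh, mat,
                                bc1 <- spring_bc(ph$mesh, lm, tgt, 1000),
                                max_iter = 100), bc1)$mean
  r2 <- landmark_residuals(
    f2 <- solve_pose_deformation(mesh2, mat,
                                 bc2 <- spring_bc(mesh2, lm, tgt, 1000),
                                 max_iter = 100), bc2)$mean
  expect_lt(abs(r1 - r2) / r1, 0.10)
})

test_that("spring stiffness calibration selects the smallest adequate k", {
  ph <- tiny_phantom()
  lm <- ph$landmarks$positions
  mat <- material_params()
  # targets at rest: every k satisfies the criterion, smallest returned
  cal0 <- calibrate_spring_stiffness(ph$mesh, mat, lm, list(lm, lm),
                                     candidate_ks = c(10, 100, 1000))
  expect_true(cal0$achieved)
  expect_equal(cal0$k, 10)
  # deformed targets: residual curve non-increasing, 0.5 mm reachable
  set.seed(9)
  tgts <- lapply(1:2, function(i)
    lm + deformation_fn(ph, stats::rnorm(4), c(2.5, 2.5, 8.5, 8.5))(lm))
  cal <- calibrate_spring_stiffness(ph$mesh, mat, lm, tgts,
                                    candidate_ks = c(30, 300, 3000),
                                    max_iter = 60)
  expect_true(all(diff(cal$report$mean_residual) <= 1e-6))
  expect_true(cal$achieved)
  # unreachable target flag
  cal_bad <- quiet(calibrate_spring_stiffness(ph$mesh, mat, lm, tgts,
                                              candidate_ks = c(0.01, 0.1),
                                              fit_target = 0.001,
                                              max_iter = 30))
  expect_false(cal_bad$achieved)
  expect_equal(cal_bad$k, 0.1)
})
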