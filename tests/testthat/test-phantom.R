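test_that("generate_phantom builds a consistent geometry", {
  ph <- tiny_phantom()
  spec <- ph$spec
  # CTV hits its target volume within 10 %
  expect_lt(abs(mask_volume_ml(ph$ctv) / spec$ctv_target_ml - 1), 0.10)
  # CTV and cord disjoint
  expect_equal(sum(ph$ctv$data & ph$cord$data), 0)
  # mesh valid: positive volumes, one component (constructor enforces);
  # all landmarks inside the mesh
  expect_true(all(tet_volumes(ph$mesh$nodes, ph$mesh$tets) > 0))
  loc <- locate_in_mesh(ph$landmarks$positions, ph$mesh)
  expect_false(any(loc$exterior))
  # 24 landmarks, 8 per region
  expect_equal(unname(table(ph$landmarks$region)[c("shoulder", "skull",
                                                   "spine")]),
               c(8L, 8L, 8L), ignore_attr = TRUE)
  # infeasible CTV rejected
  expect_error(generate_phantom(phantom_spec("tiny",
                                             ctv_target_ml = 5000)),
               "infeasible")
})

test_that("cohort generation is deterministic under the seed", {
  sim <- pose_sim_spec(n_patients = 2, n_fractions = 3, seed = 42)
  c1 <- generate_cohort(phantom_spec("tiny"), sim)
  c2 <- generate_cohort(phantom_spec("tiny"), sim)
  expect_identical(c1$patients, c2$patients)
  c3 <- generate_cohort(phantom_spec("tiny"),
                        pose_sim_spec(n_patients = 2, n_fractions = 3,
                                      seed = 43))
  expect_false(identical(c1$patients, c3$patients))
})

test_that("zero amplitudes reproduce the planning pose exactly", {
  ph <- tiny_phantom()
  sim <- pose_sim_spec(n_patients = 1, n_fractions = 3,
                       trans_sd = c(0, 0, 0), rot_sd_deg = c(0, 0, 0),
                       mode_amplitudes = c(0, 0, 0, 0),
                       tracking_noise_sd = 0, missingness = 0, seed = 1)
  co <- simulate_fraction_poses(ph, sim)
  for (fr in co$patients[[1]]$fractions) {
    expect_equal(fr$truth_positions, ph$landmarks$positions,
                 tolerance = 1e-12)
    expect_equal(fr$observed$positions, ph$landmarks$positions,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # and the true fCTV equals the CTV
  def <- deformation_fn(ph, c(0, 0, 0, 0), sim$mode_amplitudes)
  expect_identical(mask_warp_fn(ph$ctv, def)$data, ph$ctv$data)
})

test_that("rigid-only simulation leaves only tracking noise after alignment", {
  ph <- tiny_phantom()
  noise <- 0.4
  sim <- pose_sim_spec(n_patients = 1, n_fractions = 40,
                       mode_amplitudes = c(0, 0, 0, 0),
                       tracking_noise_sd = noise, missingness = 0,
                       seed = 2)
  co <- simulate_fraction_poses(ph, sim)
  res <- lapply(co$patients[[1]]$fractions, function(fr) {
    aligned <- apply_rigid(procrustes_align(ph$landmarks, fr$observed),
                           fr$observed)
    residual_displacements(ph$landmarks, aligned)
  })
  skull <- ph$landmarks$region == "skull"
  skull_mags <- unlist(lapply(res, function(r)
    sqrt(rowSums(r[skull, ]^2))))
  all_mags <- unlist(lapply(res, function(r) sqrt(rowSums(r^2))))
  # on the skull the residual is tracking noise (slightly shrunk by the
  # fit); away from the skull the fitted rotation's error is amplified by
  # the lever arm, so only the order of magnitude is noise-like
  expected <- noise * sqrt(8 / pi)
  expect_gt(mean(skull_mags), 0.5 * expected)
  expect_lt(mean(skull_mags), 1.5 * expected)
  expect_lt(mean(all_mags), 4 * expected)
})

test_that("shoulder residuals match the configured motion scale", {
  ph <- tiny_phantom()
  sim <- pose_sim_spec(n_patients = 4, n_fractions = 25,
                       tracking_noise_sd = 0, missingness = 0, seed = 3)
  co <- simulate_fraction_poses(ph, sim)
  sh <- ph$landmarks$region == "shoulder"
  mags <- unlist(lapply(co$patients, function(p)
    lapply(p$fractions, function(fr) {
      d <- fr$truth_positions - ph$landmarks$positions
      mean(sqrt(rowSums(d[sh, ]^2)))
    })))
  expect_lt(abs(mean(mags) - 9.2) / 9.2, 0.10)
})

test_that("deformation is spatially heterogeneous (shoulder >> skull)", {
  ph <- tiny_phantom()
  sim <- pose_sim_spec(n_patients = 2, n_fractions = 50,
                       tracking_noise_sd = 0, missingness = 0, seed = 4)
  co <- simulate_fraction_poses(ph, sim)
  sk <- which(ph$landmarks$region == "skull")[1]
  sh <- which(ph$landmarks$region == "shoulder")[1]
  z_disp <- sapply(co$patients[[1]]$fractions, function(fr)
    (fr$truth_positions - ph$landmarks$positions)[c(sk, sh), 3])
  sk_sd <- stats::sd(z_disp[1, ])
  sh_sd <- stats::sd(z_disp[2, ])
  expect_gt(sh_sd / max(sk_sd, 1e-12), 5)
})

test_that("missingness keeps the skull subset alignable", {
  ph <- tiny_phantom()
  sim <- pose_sim_spec(n_patients = 3, n_fractions = 20,
                       missingness = 0.4, seed = 5)
  co <- simulate_fraction_poses(ph, sim)
  for (p in co$patients)
    for (fr in p$fractions) {
      skull_valid <- sum(fr$observed$valid[fr$observed$region == "skull"])
      expect_gte(skull_valid, 3)
    }
  # observed missingness near the configured rate
  rate <- mean(!unlist(lapply(co$patients, function(p)
    lapply(p$fractions, function(fr) fr$observed$valid))))
  expect_lt(abs(rate - 0.4), 0.06)
})

test_that("gross blunders are injected when requested and filtered out", {
  ph <- tiny_phantom()
  sim <- pose_sim_spec(n_patients = 3, n_fractions = 10,
                       missingness = 0, outlier_rate = 0.05, seed = 6)
  co <- simulate_fraction_poses(ph, sim)
  errs <- unlist(lapply(co$patients, function(p)
    lapply(p$fractions, function(fr)
      sqrt(rowSums((fr$observed$positions - fr$truth_positions)^2)))))
  expect_gt(sum(errs > 10), 0)

  # geometric model trained on a clean cohort flags most head-region
  # blunders in the contaminated one
  clean <- simulate_fraction_poses(
    ph, pose_sim_spec(n_patients = 3, n_fractions = 10,
                      missingness = 0, outlier_rate = 0, seed = 6))
  model <- fit_geometric_model(
    unlist(lapply(clean$patients, function(p)
      lapply(p$fractions, `[[`, "observed")), recursive = FALSE),
    default_bone_assignment(ph))
  caught <- 0
  total <- 0
  for (p in co$patients)
    for (fr in p$fractions) {
      flagged <- quiet(flag_outliers(fr$observed, model))
      err <- sqrt(rowSums((fr$observed$positions -
                             fr$truth_positions)^2))
      head <- fr$observed$region %in% c("skull", "spine")
      bad <- head & err > 10
      total <- total + sum(bad)
      caught <- caught + sum(bad & !flagged$valid[seq_along(err)])
    }
  skip_if(total == 0)
  expect_gt(caught / total, 0.7)
})
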