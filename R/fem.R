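#' Elastic material parameters
#'
#' Homogeneous isotropic linear material for the whole head-and-neck
#' region.  Units are consistent with mm / N: Young's modulus in MPa
#' (N/mm^2), so forces come out in N and energies in N mm.
#'
#' @param young_modulus MPa; default 10 (mid-range of reported soft-tissue
#'   stiffness).
#' @param poisson_ratio unitless in `[0, 0.5)`; default 0.45 (near the
#'   upper end of values reported for head structures, 0.29-0.49).
#' @return object of class `material_params`.
#' @export
material_params <- function(young_modulus = 10, poisson_ratio = 0.45) {
  stopifnot(young_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_params")
}

lame_params <- function(material) {
  E <- material$young_modulus
  nu <- material$poisson_ratio
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Spring boundary conditions at landmark attachment points
#'
#' Each landmark is attached to its containing tetrahedron by barycentric
#' coordinates; during the solve a force `f = k (target - x)` acts at the
#' deformed attachment point and is lumped onto the tetrahedron's nodes by
#' the barycentric weights.  The spring stiffness `k` (N/mm) is the single
#' calibrated model parameter (see [calibrate_spring_stiffness()]).
#'
#' @param mesh a [tet_mesh].
#' @param points landmark positions in the rest configuration, n x 3 mm.
#' @param targets landmark positions in the fraction image, n x 3 mm.
#' @param stiffness spring stiffness k, N/mm (default 1000).
#' @param attachments optional precomputed [locate_in_mesh] result.
#' @return object of class `spring_bc`.
#' @export
spring_bc <- function(mesh, points, targets, stiffness = 1000,
                      attachments = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  targets <- matrix(as.numeric(targets), ncol = 3)
  stopifnot(nrow(points) == nrow(targets), nrow(points) >= 1,
            stiffness > 0, all(is.finite(targets)))
  if (is.null(attachments)) attachments <- locate_in_mesh(points, mesh)
  structure(list(attachments = attachments, points = points,
                 targets = targets, stiffness = stiffness),
            class = "spring_bc")
}

# constant sparse stiffness contribution of all springs (3n x 3n)
spring_stiffness_matrix <- function(bc, mesh) {
  n <- nrow(mesh$nodes)
  tv <- mesh$tets[bc$attachments$tet, , drop = FALSE]
  b <- bc$attachments$bary
  ii <- jj <- xx <- vector("list", nrow(tv))
  for (s in seq_len(nrow(tv))) {
    nodes4 <- tv[s, ]
    w <- b[s, ]
    blk <- bc$stiffness * outer(w, w)
    rows <- rep(nodes4, each = 4)
    cols <- rep(nodes4, times = 4)
    vals <- as.vector(t(blk))
    ii[[s]] <- rep(3 * (rows - 1), each = 1)
    jj[[s]] <- rep(3 * (cols - 1), each = 1)
    xx[[s]] <- vals
  }
  base_i <- unlist(ii); base_j <- unlist(jj); vals <- unlist(xx)
  # expand to the three diagonal (x,y,z) entries of each 3x3 block k*w_a*w_b*I
  i <- c(base_i + 1, base_i + 2, base_i + 3)
  j <- c(base_j + 1, base_j + 2, base_j + 3)
  x <- rep(vals, 3)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(3 * n, 3 * n))
}

# deformed attachment-point positions (n x 3)
attachment_positions <- function(bc, mesh, u) {
  tv <- mesh$tets[bc$attachments$tet, , drop = FALSE]
  b <- bc$attachments$bary
  pos <- mesh$nodes + u
  b[, 1] * pos[tv[, 1], , drop = FALSE] +
    b[, 2] * pos[tv[, 2], , drop = FALSE] +
    b[, 3] * pos[tv[, 3], , drop = FALSE] +
    b[, 4] * pos[tv[, 4], , drop = FALSE]
}

# nodal force vector (length 3n) from the springs at displacement u
spring_forces <- function(bc, mesh, u) {
  n <- nrow(mesh$nodes)
  f <- numeric(3 * n)
  cur <- attachment_positions(bc, mesh, u)
  frc <- bc$stiffness * (bc$targets - cur)
  tv <- mesh$tets[bc$attachments$tet, , drop = FALSE]
  b <- bc$attachments$bary
  for (s in seq_len(nrow(tv)))
    for (a in 1:4) {
      id <- 3 * (tv[s, a] - 1)
      f[(id + 1):(id + 3)] <- f[(id + 1):(id + 3)] + b[s, a] * frc[s, ]
    }
  f
}

# non-collinearity of spring attachment points (needed to pin the
# rigid-body modes of the free-floating elastic body)
springs_well_posed <- function(points) {
  if (nrow(points) < 3) return(FALSE)
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)$d
  sv[2] > 1e-8 * max(sv[1], 1)
}

#' Solve the static pose deformation under landmark springs
#'
#' Deforms the body from the planning pose toward fraction landmark
#' positions: static equilibrium of the co-rotational linear-elastic model
#' under spring forces re-evaluated at the deformed landmark positions.
#' Newton-type iteration with stiffness warping and backtracking line
#' search; converged when the largest nodal residual force norm drops
#' below `tol`.
#'
#' @param mesh a [tet_mesh].
#' @param material a [material_params].
#' @param bc a [spring_bc]; at least three non-collinear attachments are
#'   required so the springs pin the rigid-body modes.
#' @param tol convergence tolerance on the max nodal residual force, N.
#' @param max_iter maximum Newton iterations.
#' @param method `"corotational"` (default) or `"linear"` (small-strain
#'   solve without rotation extraction; used as an oracle in tests).
#' @return a [displacement_field] with attributes-like extra fields:
#'   `convergence` list (`converged`, `iterations`, `max_residual` N,
#'   `n_inverted`).
#' @export
solve_pose_deformation <- function(mesh, material, bc, tol = 1e-3,
                                   max_iter = 200,
                                   method = c("corotational", "linear")) {
  method <- match.arg(method)
  if (!springs_well_posed(bc$points))
    stop("degenerate spring configuration: need >= 3 non-collinear attachments")
  lp <- lame_params(material)
  n <- nrow(mesh$nodes)
  corot <- method == "corotational"
  Ks <- spring_stiffness_matrix(bc, mesh)
  u <- matrix(0, n, 3)

  residual <- function(u) {
    sys <- .fem_system(mesh$nodes, mesh$tets, lp$lambda, lp$mu, u,
                       corot, FALSE)
    spring_forces(bc, mesh, u) - sys$fint
  }
  node_resid_max <- function(r)
    max(sqrt(rowSums(matrix(r, ncol = 3, byrow = TRUE)^2)))

  converged <- FALSE
  it <- 0L
  n_inverted <- 0L
  r <- residual(u)
  maxres <- node_resid_max(r)
  while (it < max_iter) {
    if (maxres < tol) { converged <- TRUE; break }
    it <- it + 1L
    sys <- .fem_system(mesh$nodes, mesh$tets, lp$lambda, lp$mu, u,
                       corot, TRUE)
    n_inverted <- sys$n_inverted
    K <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x,
                              dims = c(3 * n, 3 * n)) + Ks
    du <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(K), r)),
      error = function(e) stop("singular system: ", conditionMessage(e)))
    du <- matrix(du, ncol = 3, byrow = TRUE)
    # backtracking on the residual norm
    alpha <- 1
    best <- NULL
    for (ls in 1:6) {
      r_try <- residual(u + alpha * du)
      m_try <- node_resid_max(r_try)
      if (is.null(best) || m_try < best$m)
        best <- list(a = alpha, r = r_try, m = m_try)
      if (m_try < maxres) break
      alpha <- alpha / 2
    }
    u <- u + best$a * du
    r <- best$r
    maxres <- best$m
  }
  if (maxres < tol) converged <- TRUE
  if (!converged)
    warning(sprintf("solver did not converge (max residual %.3g N after %d iterations)",
                    maxres, it))
  field <- displacement_field(mesh, u)
  field$convergence <- list(converged = converged, iterations = it,
                            max_residual = maxres,
                            n_inverted = n_inverted, method = method)
  field
}

#' Elastic strain energy of a displacement state
#'
#' @param mesh a [tet_mesh].
#' @param material a [material_params].
#' @param u n x 3 nodal displacements, mm.
#' @param method `"corotational"` (rotation-compensated strain) or
#'   `"linear"` (small-strain energy `u' K u / 2`).
#' @return energy in N mm.
#' @export
elastic_energy <- function(mesh, material, u,
                           method = c("corotational", "linear")) {
  method <- match.arg(method)
  lp <- lame_params(material)
  sys <- .fem_system(mesh$nodes, mesh$tets, lp$lambda, lp$mu,
                     as.matrix(u), method == "corotational", FALSE)
  sys$energy
}

#' Landmark-to-target residual distances of a solved field
#'
#' The fit criterion of the spring-stiffness calibration: the Euclidean
#' distance between each deformed landmark attachment point and its target
#' position, and their mean.
#'
#' @param field a [displacement_field] from [solve_pose_deformation()].
#' @param bc the [spring_bc] used in the solve.
#' @return list with `per_landmark` (mm) and `mean` (mm).
#' @export
landmark_residuals <- function(field, bc) {
  cur <- attachment_positions(bc, field$mesh, field$node_displacements)
  d <- sqrt(rowSums((cur - bc$targets)^2))
  list(per_landmark = d, mean = mean(d))
}

#' Calibrate the landmark spring stiffness k
#'
#' Single parameter sweep over candidate stiffness values: for each k the
#' pose deformation is solved for every fraction target set and the mean
#' landmark residual recorded; the smallest k whose mean residual over all
#' fractions is at most `fit_target` (0.5 mm by default) is returned.
#'
#' @param mesh a [tet_mesh].
#' @param material a [material_params].
#' @param points rest-configuration landmark positions, n x 3 mm.
#' @param fraction_target_sets list of n x 3 target matrices (one per
#'   fraction image).
#' @param candidate_ks strictly positive sweep grid, N/mm (sorted
#'   internally).
#' @param fit_target mean-residual acceptance level, mm.
#' @param ... passed to [solve_pose_deformation()].
#' @return list: `k` (calibrated value; grid maximum when the target is
#'   not achieved), `achieved` (logical), `report` (data.frame with the
#'   residual-vs-k curve).
#' @export
calibrate_spring_stiffness <- function(mesh, material, points,
                                       fraction_target_sets, candidate_ks,
                                       fit_target = 0.5, ...) {
  stopifnot(all(candidate_ks > 0), length(fraction_target_sets) >= 1)
  candidate_ks <- sort(candidate_ks)
  attachments <- locate_in_mesh(points, mesh)
  mean_res <- vapply(candidate_ks, function(k) {
    res <- vapply(fraction_target_sets, function(tgt) {
      bc <- spring_bc(mesh, points, tgt, stiffness = k,
                      attachments = attachments)
      fld <- solve_pose_deformation(mesh, material, bc, ...)
      landmark_residuals(fld, bc)$mean
    }, numeric(1))
    mean(res)
  }, numeric(1))
  report <- data.frame(k = candidate_ks, mean_residual = mean_res)
  viol <- which(diff(mean_res) > 1e-6)
  if (length(viol))
    message("residual-vs-k curve not monotone at k = ",
            paste(signif(candidate_ks[viol + 1], 3), collapse = ", "))
  ok <- which(mean_res <= fit_target)
  if (length(ok)) {
    list(k = candidate_ks[min(ok)], achieved = TRUE, report = report)
  } else {
    list(k = max(candidate_ks), achieved = FALSE, report = report)
  }
}
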