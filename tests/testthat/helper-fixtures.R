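# shared fixtures, all built in code

# regular tetrahedron with edge length `a`, one vertex at the origin
regular_tet <- function(a = 10) {
  nodes <- a * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                     c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  tet_mesh(nodes, matrix(1:4, 1))
}

# structured tet mesh of an axis-aligned box
box_mesh <- function(lo = c(0, 0, 0), hi = c(40, 40, 40), h = 10) {
  mesh_implicit_solid(function(p) rep(TRUE, nrow(p)),
                      rbind(lo, hi), h)
}

# digital ball mask of radius r voxels in a cube of side n (1 mm grid)
ball_mask <- function(r = 20, n = 2 * r + 20, center = rep(n / 2, 3)) {
  g <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n),
                             k = seq_len(n)))
  d2 <- rowSums(sweep(g - 0.5, 2, center)^2)
  voxel_mask(array(d2 <= r^2, c(n, n, n)))
}

# random small proper rotation (angles up to max_deg per axis)
random_rotation <- function(max_deg = 10) {
  ang <- stats::runif(3, -max_deg, max_deg) * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

# small landmark set: 4 skull + 2 spine + 2 shoulder
toy_landmarks <- function(jitter = 0) {
  pos <- rbind(c(0, 0, 100), c(30, 0, 110), c(0, 30, 115), c(15, 15, 130),
               c(0, -20, 60), c(0, -20, 30),
               c(60, 0, -20), c(-60, 0, -20))
  if (jitter > 0) pos <- pos + matrix(stats::rnorm(24, sd = jitter), 8, 3)
  landmark_set(paste0("lm", 1:8), pos,
               rep(c("skull", "spine", "shoulder"), c(4, 2, 2)))
}

# tiny phantom shared across expensive tests (built once per test run)
tiny_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(phantom_spec("tiny"))
    ph
  }
})

# uniform-displacement field on a mesh (pure translation)
translation_field <- function(mesh, t) {
  displacement_field(mesh, matrix(rep(t, each = nrow(mesh$nodes)),
                                  ncol = 3))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
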