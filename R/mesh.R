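#' Tetrahedral mesh of the patient body
#'
#' @param nodes n x 3 numeric matrix of node positions, mm.
#' @param tets m x 4 integer matrix of 1-based node indices; every
#'   tetrahedron must have strictly positive signed volume.
#' @param check validate positivity / connectivity (default TRUE).
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, check = TRUE) {
  nodes <- as.matrix(nodes)
  tets <- matrix(as.integer(tets), ncol = 4)
  if (check) {
    if (min(tets) < 1 || max(tets) > nrow(nodes))
      stop("tetrahedron node index out of range")
    v <- tet_volumes(nodes, tets)
    if (any(v <= 0))
      stop(sum(v <= 0), " tetrahedra have non-positive volume")
    if (n_components(nrow(nodes), tets) != 1L)
      stop("mesh is not a single connected component")
  }
  structure(list(nodes = nodes, tets = tets), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh: ", nrow(x$nodes), " nodes, ", nrow(x$tets),
      " tetrahedra, total volume ",
      signif(sum(tet_volumes(x$nodes, x$tets)) / 1000, 4), " ml\n", sep = "")
  invisible(x)
}

#' Signed volumes (mm^3) of all tetrahedra
#' @param nodes,tets mesh arrays as in [tet_mesh].
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# number of connected components of the node graph induced by tets
n_components <- function(n_nodes, tets) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(tets))) {
    a <- find(tets[r, 1])
    for (c in 2:4) {
      b <- find(tets[r, c])
      if (a != b) parent[b] <- a
    }
  }
  used <- unique(as.vector(tets))
  length(unique(vapply(used, find, integer(1))))
}

#' Locate points in a tetrahedral mesh
#'
#' Returns, per query point, the containing tetrahedron and its barycentric
#' coordinates.  Points outside the mesh are assigned the nearest
#' tetrahedron (closest clamped-barycentric reconstruction) with an
#' `exterior` flag and the remaining distance.
#'
#' @param points n x 3 matrix of positions, mm.
#' @param mesh a [tet_mesh].
#' @return list with `tet` (1-based index), `bary` (n x 4, non-negative,
#'   rows sum to 1), `exterior` (logical), `dist` (mm).
#' @export
locate_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(mesh$tets) == 0) stop("empty mesh")
  .locate_points(points, mesh$nodes, mesh$tets)
}

#' Dense displacement field on a tetrahedral mesh
#'
#' Couples a rest-configuration mesh with per-node displacements; together
#' they define a displacement vector field (DVF) everywhere inside the
#' mesh via barycentric interpolation.
#'
#' @param mesh a [tet_mesh] (rest configuration).
#' @param node_displacements n x 3 matrix, mm.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(mesh, node_displacements) {
  node_displacements <- as.matrix(node_displacements)
  stopifnot(nrow(node_displacements) == nrow(mesh$nodes),
            all(is.finite(node_displacements)))
  def <- mesh$nodes + node_displacements
  v <- tet_volumes(def, mesh$tets)
  if (any(v <= 0))
    warning(sum(v <= 0), " element(s) inverted in the deformed configuration")
  structure(list(mesh = mesh, node_displacements = node_displacements),
            class = "displacement_field")
}

#' Interpolate a displacement field at arbitrary points
#'
#' Barycentric mapping: each point is displaced by the barycentric
#' interpolation of its containing tetrahedron's nodal displacements
#' (clamped-nearest for exterior points).
#'
#' @param points n x 3 matrix of positions, mm.
#' @param field a [displacement_field].
#' @param attachments optional precomputed [locate_in_mesh] result for
#'   `points` (reused across scenarios for speed).
#' @return n x 3 matrix of displacements, mm.
#' @export
interpolate_field <- function(points, field, attachments = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(attachments)) attachments <- locate_in_mesh(points, field$mesh)
  u <- field$node_displacements
  tv <- field$mesh$tets[attachments$tet, , drop = FALSE]
  b <- attachments$bary
  b[, 1] * u[tv[, 1], , drop = FALSE] +
    b[, 2] * u[tv[, 2], , drop = FALSE] +
    b[, 3] * u[tv[, 3], , drop = FALSE] +
    b[, 4] * u[tv[, 4], , drop = FALSE]
}

#' Displace points through a displacement field
#'
#' @inheritParams interpolate_field
#' @return n x 3 matrix of displaced positions, mm.
#' @export
barycentric_map <- function(points, field, attachments = NULL) {
  matrix(as.numeric(points), ncol = 3) +
    interpolate_field(points, field, attachments)
}

#' Propagate a binary mask through a displacement field
#'
#' Forward-warps the mask's foreground voxel centers by the barycentrically
#' interpolated field and rasterizes by nearest-voxel deposition with a
#' one-pass crack-sealing step.
#'
#' @param mask a [voxel_mask] sharing the patient frame with the mesh.
#' @param field a [displacement_field].
#' @param attachments optional precomputed [locate_in_mesh] result for the
#'   mask's foreground voxel centers.
#' @param seal fill rasterization cracks after deposition.
#' @return propagated [voxel_mask].
#' @export
propagate_mask <- function(mask, field, attachments = NULL, seal = TRUE) {
  pos <- mask_points(mask)
  if (nrow(pos) == 0) return(mask)
  if (is.null(attachments)) {
    attachments <- locate_in_mesh(pos, field$mesh)
    if (all(attachments$exterior)) {
      warning("mask lies entirely outside the mesh; returned unchanged")
      return(mask)
    }
  }
  rasterize_warped(mask, interpolate_field(pos, field, attachments), seal)
}

#' Structured tetrahedral mesher for implicit solids
#'
#' Fills the bounding box with cubic cells of edge `h`, keeps cells whose
#' center lies inside the solid, and splits each cell into six tetrahedra
#' (Kuhn subdivision, conforming across cells).  Used to mesh the synthetic
#' phantom body; imported meshes are read with [read_mesh_vtk()].
#'
#' @param inside function: n x 3 matrix of points (mm) -> logical vector.
#' @param bbox 2 x 3 matrix, rows = lower / upper corner, mm.
#' @param h target edge length, mm.
#' @return a [tet_mesh].
#' @export
mesh_implicit_solid <- function(inside, bbox, h) {
  stopifnot(h > 0)
  nx <- max(1L, ceiling((bbox[2, 1] - bbox[1, 1]) / h))
  ny <- max(1L, ceiling((bbox[2, 2] - bbox[1, 2]) / h))
  nz <- max(1L, ceiling((bbox[2, 3] - bbox[1, 3]) / h))
  hx <- (bbox[2, 1] - bbox[1, 1]) / nx
  hy <- (bbox[2, 2] - bbox[1, 2]) / ny
  hz <- (bbox[2, 3] - bbox[1, 3]) / nz
  cells <- as.matrix(expand.grid(i = 0:(nx - 1), j = 0:(ny - 1),
                                 k = 0:(nz - 1)))
  centers <- cbind(bbox[1, 1] + (cells[, 1] + 0.5) * hx,
                   bbox[1, 2] + (cells[, 2] + 0.5) * hy,
                   bbox[1, 3] + (cells[, 3] + 0.5) * hz)
  keep <- inside(centers)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) stop("no cells inside the solid; enlarge it or shrink h")

  node_id <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  # Kuhn split: six tets per cube, one per axis permutation
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  unit <- diag(3)
  tet_list <- vector("list", 6)
  for (p in 1:6) {
    o <- matrix(0, 4, 3)
    o[2, ] <- unit[perms[p, 1], ]
    o[3, ] <- unit[perms[p, 1], ] + unit[perms[p, 2], ]
    o[4, ] <- c(1, 1, 1)
    ids <- sapply(1:4, function(v)
      node_id(cells[, 1] + o[v, 1], cells[, 2] + o[v, 2],
              cells[, 3] + o[v, 3]))
    tet_list[[p]] <- matrix(ids, ncol = 4)
  }
  tets <- do.call(rbind, tet_list)

  used <- sort(unique(as.vector(tets)))
  remap <- integer(node_id(nx, ny, nz))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  u0 <- used - 1L
  ui <- u0 %% (nx + 1L)
  uj <- (u0 %/% (nx + 1L)) %% (ny + 1L)
  uk <- u0 %/% ((nx + 1L) * (ny + 1L))
  nodes <- cbind(bbox[1, 1] + ui * hx, bbox[1, 2] + uj * hy,
                 bbox[1, 3] + uk * hz)

  # enforce positive orientation
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  # drop cells in secondary components (cell-center sampling can detach
  # a few cubes from thin features)
  if (n_components(nrow(nodes), tets) != 1L) {
    comp <- node_component_labels(nrow(nodes), tets)
    main <- as.integer(names(which.max(table(comp[tets[, 1]]))))
    tets <- tets[comp[tets[, 1]] == main, , drop = FALSE]
    used2 <- sort(unique(as.vector(tets)))
    remap2 <- integer(nrow(nodes))
    remap2[used2] <- seq_along(used2)
    tets <- matrix(remap2[tets], ncol = 4)
    nodes <- nodes[used2, , drop = FALSE]
  }
  tet_mesh(nodes, tets)
}

node_component_labels <- function(n_nodes, tets) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(tets))) {
    a <- find(tets[r, 1])
    for (c in 2:4) {
      b <- find(tets[r, c])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n_nodes), find, integer(1))
}
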