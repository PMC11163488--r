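# Regular tetrahedral meshes.
#
# Each cell of a dx x dy x dz lattice of cubes is split into 6 tetrahedra
# around the same main diagonal (Freudenthal/Kuhn subdivision). Using one
# diagonal orientation for every cube makes the mesh conforming: the two
# triangles on any shared cube face are split identically on both sides.
# The Kuhn simplices are the sets {f[s1] >= f[s2] >= f[s3]} over the 6
# permutations s of the local cube coordinates f in [0,1]^3, which makes
# point location and barycentric interpolation pure lattice arithmetic.

# permutation table; row = perm index used for tet ordering within a cube
KUHN_PERMS <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
KUHN_ODD <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
# comparison code (f1>=f2)*4 + (f2>=f3)*2 + (f1>=f3) -> perm index
KUHN_CODE2PERM <- c(6L, 6L, 4L, 3L, 5L, 2L, 1L, 1L)

# natural vertex offsets of Kuhn simplex for perm s: v0 = 0, v1 = v0+e_s1,
# v2 = v1+e_s2, v3 = (1,1,1); stored with v3, v2 swapped for odd perms so
# every tetrahedron has positive signed volume.
kuhn_offsets <- function(p) {
  s <- KUHN_PERMS[p, ]
  e <- diag(3)
  v <- rbind(0, e[s[1], ], e[s[1], ] + e[s[2], ], c(1, 1, 1))
  if (KUHN_ODD[p]) v[c(1, 2, 4, 3), ] else v
}

#' Regular tetrahedral mesh over a box
#'
#' Builds a `(dx+1)(dy+1)(dz+1)`-node lattice over `[box_min, box_max]`,
#' splitting each of the `dx*dy*dz` cubes into 6 tetrahedra by a uniform
#' main-diagonal scheme, which tiles the box exactly and is conforming
#' (shared faces share nodes). Every tetrahedron is stored with positive
#' signed volume.
#'
#' @param divisions integer vector of length 3 (cubes per axis, each >= 1);
#'   a scalar is recycled.
#' @param box_min,box_max numeric length-3 corners in mm, `box_max > box_min`
#'   on every axis.
#' @return A `tet_mesh` with fields `nodes` (n x 3 mm), `tets`
#'   (m x 4 node indices), `divisions`, `box_min`, `box_max`, `h`
#'   (cube edge lengths mm).
#' @examples
#' m <- build_cubic_tet_mesh(c(2, 2, 2), c(0, 0, 0), c(20, 20, 20))
#' nrow(m$nodes)  # 27
#' nrow(m$tets)   # 48
#' @export
build_cubic_tet_mesh <- function(divisions, box_min, box_max) {
  dv <- rep_len(as.integer(divisions), 3L)
  box_min <- rep_len(as.numeric(box_min), 3L)
  box_max <- rep_len(as.numeric(box_max), 3L)
  if (any(dv < 1L)) stop("divisions must be >= 1", call. = FALSE)
  if (any(box_max <= box_min))
    stop("degenerate box: box_max must exceed box_min on every axis",
         call. = FALSE)
  h <- (box_max - box_min) / dv
  nd <- dv + 1L
  lat <- as.matrix(expand.grid(i = 0:dv[1], j = 0:dv[2], k = 0:dv[3]))
  nodes <- sweep(sweep(lat, 2, h, "*"), 2, box_min, "+")
  dimnames(nodes) <- NULL
  node_id <- function(ijk) 1L + ijk[, 1] + nd[1] * (ijk[, 2] + nd[2] * ijk[, 3])
  cubes <- as.matrix(expand.grid(i = 0:(dv[1] - 1L), j = 0:(dv[2] - 1L),
                                 k = 0:(dv[3] - 1L)))
  ntet <- 6L * nrow(cubes)
  tets <- matrix(0L, ntet, 4L)
  for (p in 1:6) {
    off <- kuhn_offsets(p)
    for (v in 1:4) {
      ijk <- sweep(cubes, 2, off[v, ], "+")
      tets[seq(p, ntet, by = 6L), v] <- node_id(ijk)
    }
  }
  structure(list(nodes = nodes, tets = tets, divisions = dv,
                 box_min = box_min, box_max = box_max, h = h),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "tet_mesh: %d nodes, %d tetrahedra (%s divisions), box [%s] - [%s] mm\n",
    nrow(x$nodes), nrow(x$tets), paste(x$divisions, collapse = "x"),
    paste(signif(x$box_min, 4), collapse = ", "),
    paste(signif(x$box_max, 4), collapse = ", ")))
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param mesh a `tet_mesh`.
#' @return Numeric vector of signed volumes (mm^3), positive under the
#'   stored vertex ordering.
#' @export
tet_volumes <- function(mesh) {
  p1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - p1
  c3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Scale a mesh to cover a set of voxels
#'
#' The mesh box is the axis-aligned bounding box of the given voxel centres
#' expanded by `margin_mm` on every side, so each listed voxel centre lies
#' strictly inside the mesh. This is how a correction mesh is fitted around
#' the boundary voxels of the structures being modelled.
#'
#' @param divisions cubes per axis, as in [build_cubic_tet_mesh()].
#' @param voxels integer matrix (n x 3) of 1-based voxel indices.
#' @param grid the [grid3d()] those indices refer to.
#' @param margin_mm non-negative expansion of the bounding box (mm).
#' @return A `tet_mesh` covering all the voxel centres.
#' @export
scale_mesh_to_cover <- function(divisions, voxels, grid, margin_mm = 5) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (nrow(voxels) == 0L)
    stop("scale_mesh_to_cover: empty voxel list", call. = FALSE)
  ctr <- sweep(sweep(voxels - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  lo <- apply(ctr, 2, min) - margin_mm
  hi <- apply(ctr, 2, max) + margin_mm
  if (any(hi <= lo))
    stop("degenerate box: voxel set is flat on some axis and margin_mm = 0",
         call. = FALSE)
  build_cubic_tet_mesh(divisions, lo, hi)
}

#' Nearest mesh node to each query point
#'
#' Exploits the regular lattice: the nearest node is found by rounding the
#' lattice coordinates, with exact midpoints resolved toward the lower
#' per-axis index, i.e. the lowest linear node index among the tied set.
#'
#' @param mesh a `tet_mesh`.
#' @param points numeric matrix (n x 3) of mm coordinates (a single point
#'   may be given as a vector).
#' @return Integer vector of node indices.
#' @export
nearest_node <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  nd <- mesh$divisions + 1L
  idx <- matrix(0L, nrow(points), 3L)
  for (ax in 1:3) {
    t <- (points[, ax] - mesh$box_min[ax]) / mesh$h[ax]
    idx[, ax] <- pmax(0L, pmin(mesh$divisions[ax], as.integer(ceiling(t - 0.5))))
  }
  1L + idx[, 1] + nd[1] * (idx[, 2] + nd[2] * idx[, 3])
}

# Lattice location of points: cube index (0-based), local coords f, perm.
# Returns NULL columns for points; inside = within box up to `tol` lattice
# units.
kuhn_locate <- function(mesh, points, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  t <- matrix(0, n, 3)
  for (ax in 1:3)
    t[, ax] <- (points[, ax] - mesh$box_min[ax]) / mesh$h[ax]
  inside <- rowSums(t >= -tol & t <= rep(mesh$divisions, each = n) + tol) == 3L
  cube <- matrix(pmax(0L, pmin(rep(mesh$divisions, each = n) - 1L,
                               as.integer(floor(t)))), n, 3)
  f <- t - cube
  code <- (f[, 1] >= f[, 2]) * 4L + (f[, 2] >= f[, 3]) * 2L +
          (f[, 1] >= f[, 3]) * 1L
  perm <- KUHN_CODE2PERM[code + 1L]
  list(inside = inside, cube = cube, f = f, perm = perm)
}

#' Locate the tetrahedron containing a point
#'
#' Regular-lattice arithmetic restricts the search to a single cube and a
#' single coordinate ordering, so location is O(1) per point. Barycentric
#' coordinates are returned in the stored vertex order of the tetrahedron;
#' they are all >= -1e-9 and sum to 1 for interior points.
#'
#' @param mesh a `tet_mesh`.
#' @param point numeric length-3 point (mm).
#' @return `list(tet = index, bary = length-4 numeric)` or `NULL` when the
#'   point lies outside the mesh box (the outside sentinel).
#' @export
locate_tet <- function(mesh, point) {
  loc <- kuhn_locate(mesh, point)
  if (!loc$inside[1]) return(NULL)
  p <- loc$perm[1]
  s <- KUHN_PERMS[p, ]
  f <- loc$f[1, ]
  lam <- c(1 - f[s[1]], f[s[1]] - f[s[2]], f[s[2]] - f[s[3]], f[s[3]])
  if (KUHN_ODD[p]) lam <- lam[c(1, 2, 4, 3)]
  cube_lin <- loc$cube[1, 1] +
    mesh$divisions[1] * (loc$cube[1, 2] + mesh$divisions[2] * loc$cube[1, 3])
  list(tet = cube_lin * 6L + p, bary = lam)
}

# Interpolate per-node values (n_nodes x q matrix) at query points by
# barycentric interpolation; rows are NA outside the mesh box. Fully
# vectorized; the backbone of interpolate_solution_to_field().
lattice_interp <- function(mesh, nodal, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  nodal <- as.matrix(nodal)
  loc <- kuhn_locate(mesh, points)
  n <- nrow(points)
  out <- matrix(NA_real_, n, ncol(nodal))
  ok <- which(loc$inside)
  if (!length(ok)) return(out)
  f <- loc$f[ok, , drop = FALSE]
  cube <- loc$cube[ok, , drop = FALSE]
  perm <- loc$perm[ok]
  s1 <- KUHN_PERMS[perm, 1]; s2 <- KUHN_PERMS[perm, 2]; s3 <- KUHN_PERMS[perm, 3]
  fs1 <- f[cbind(seq_along(ok), s1)]
  fs2 <- f[cbind(seq_along(ok), s2)]
  fs3 <- f[cbind(seq_along(ok), s3)]
  lam <- cbind(1 - fs1, fs1 - fs2, fs2 - fs3, fs3)
  nd <- mesh$divisions + 1L
  nid <- function(ijk) 1L + ijk[, 1] + nd[1] * (ijk[, 2] + nd[2] * ijk[, 3])
  # natural vertices: v0 = cube, v1 = v0 + e_s1, v2 = v1 + e_s2, v3 = cube+1
  v0 <- cube
  v1 <- cube; v1[cbind(seq_along(ok), s1)] <- v1[cbind(seq_along(ok), s1)] + 1L
  v2 <- v1;   v2[cbind(seq_along(ok), s2)] <- v2[cbind(seq_along(ok), s2)] + 1L
  v3 <- cube + 1L
  acc <- lam[, 1] * nodal[nid(v0), , drop = FALSE] +
         lam[, 2] * nodal[nid(v1), , drop = FALSE] +
         lam[, 3] * nodal[nid(v2), , drop = FALSE] +
         lam[, 4] * nodal[nid(v3), , drop = FALSE]
  out[ok, ] <- acc
  out
}

#' Node-to-voxel lookup table
#'
#' For every voxel of `grid` whose centre lies inside the mesh box, the
#' index of its nearest mesh node; `NA` for voxels outside the mesh.
#'
#' @param mesh a `tet_mesh`.
#' @param grid a [grid3d()].
#' @return Integer array of `grid$shape`.
#' @export
node_voxel_lookup <- function(mesh, grid) {
  ctr <- voxel_centers(grid)
  inside <- rep(TRUE, nrow(ctr))
  for (ax in 1:3)
    inside <- inside & ctr[, ax] >= mesh$box_min[ax] &
                       ctr[, ax] <= mesh$box_max[ax]
  ids <- rep(NA_integer_, nrow(ctr))
  ids[inside] <- nearest_node(mesh, ctr[inside, , drop = FALSE])
  array(ids, grid$shape)
}

#' Export a mesh as a legacy VTK unstructured grid
#'
#' Plain-text legacy VTK, for inspection in ParaView and friends.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path (conventionally `.vtk`).
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  invisible(path)
}
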