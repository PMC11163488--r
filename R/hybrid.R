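# Hybrid FEM correction of an existing displacement field: keep the DVF's
# own organ-boundary displacements, re-derive everything inside the
# modelled region from linear elasticity, and leave voxels outside the
# mesh untouched.

# voxels of `lab` that are on a label boundary: some 6-face-neighbour
# carries a different label, or the voxel lies on the grid edge
label_boundary_array <- function(lab) {
  n <- dim(lab)
  b <- array(FALSE, n)
  b[c(1L, n[1]), , ] <- TRUE
  b[, c(1L, n[2]), ] <- TRUE
  b[, , c(1L, n[3])] <- TRUE
  d <- lab[-n[1], , ] != lab[-1L, , ]
  b[-n[1], , ] <- b[-n[1], , ] | d
  b[-1L, , ] <- b[-1L, , ] | d
  d <- lab[, -n[2], ] != lab[, -1L, ]
  b[, -n[2], ] <- b[, -n[2], ] | d
  b[, -1L, ] <- b[, -1L, ] | d
  d <- lab[, , -n[3]] != lab[, , -1L]
  b[, , -n[3]] <- b[, , -n[3]] | d
  b[, , -1L] <- b[, , -1L] | d
  b
}

# surface voxels (n x 3 indices) of a logical occupancy array
boundary_voxels_of <- function(occ) {
  lab <- array(as.integer(occ), dim(occ))
  vox <- which(occ & label_boundary_array(lab), arr.ind = TRUE)
  dimnames(vox) <- NULL
  vox
}

#' Boundary voxels of selected structures
#'
#' Voxels carrying one of the selected labels that have at least one
#' 6-connected face neighbour with a different label (voxels on the grid
#' edge count as boundary). These are the surface voxels whose
#' displacements are trusted and kept as constraints.
#'
#' @param labels a [label_map()].
#' @param structure_labels integer vector of labels to extract surfaces
#'   for.
#' @return Integer matrix (n x 3) of 1-based voxel indices.
#' @export
extract_boundary_voxels <- function(labels, structure_labels) {
  stopifnot(inherits(labels, "label_map"))
  structure_labels <- as.integer(structure_labels)
  present <- structure_labels %in% labels$labels
  if (!all(present))
    stop("extract_boundary_voxels: label(s) ",
         paste(structure_labels[!present], collapse = ", "),
         " not present in the label map", call. = FALSE)
  sel <- array(labels$labels %in% structure_labels, dim(labels$labels))
  vox <- which(sel & label_boundary_array(labels$labels), arr.ind = TRUE)
  dimnames(vox) <- NULL
  vox
}

#' Driving-node constraints from a field's boundary displacements
#'
#' Reads the preliminary field at the given boundary voxels, assigns each
#' voxel to its nearest mesh node, and averages the displacements of all
#' voxels assigned to one node -- that average becomes the node's
#' prescribed displacement.
#'
#' @param boundary_voxels n x 3 integer voxel indices (see
#'   [extract_boundary_voxels()]).
#' @param field the preliminary [displacement_field()].
#' @param mesh a `tet_mesh` covering the boundary voxels.
#' @return A `boundary_constraints` object: list with `voxels`,
#'   `displacements` (per voxel), `nodes` (driving node indices),
#'   `node_displacements` (k x 3 mm) and `assignment` (node per voxel).
#' @export
build_constraints <- function(boundary_voxels, field, mesh) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(mesh, "tet_mesh"))
  if (is.null(dim(boundary_voxels)))
    boundary_voxels <- matrix(boundary_voxels, ncol = 3)
  g <- field$grid
  n <- nrow(boundary_voxels)
  U <- cbind(field$u[cbind(boundary_voxels, rep(1L, n))],
             field$u[cbind(boundary_voxels, rep(2L, n))],
             field$u[cbind(boundary_voxels, rep(3L, n))])
  ctr <- sweep(sweep(boundary_voxels - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  if (any(ctr < rep(mesh$box_min, each = n)) ||
      any(ctr > rep(mesh$box_max, each = n)))
    stop("build_constraints: mesh does not cover all boundary voxels",
         call. = FALSE)
  nid <- nearest_node(mesh, ctr)
  agg <- rowsum(U, nid)
  cnt <- as.vector(rowsum(rep(1, n), nid))
  structure(list(voxels = boundary_voxels, displacements = U,
                 nodes = as.integer(rownames(agg)),
                 node_displacements = agg / cnt,
                 assignment = nid),
            class = "boundary_constraints")
}

#' @export
print.boundary_constraints <- function(x, ...) {
  cat(sprintf(
    "boundary_constraints: %d boundary voxel(s) -> %d driving node(s)\n",
    nrow(x$voxels), length(x$nodes)))
  invisible(x)
}

#' Hybrid FEM correction of a displacement field
#'
#' Replaces the interior of `preliminary` with the linear-elasticity
#' solution driven by the field's own displacements at the selected
#' structures' boundary voxels: surfaces are kept (up to mesh
#' discretization), interiors are re-derived mechanically, and voxels
#' outside the mesh are returned bit-identical to the preliminary field.
#' With `per_organ = TRUE` each structure gets its own mesh and solve,
#' applied sequentially (later corrections see the earlier ones outside
#' their mesh). By default the mesh-surface nodes are also driven, with
#' displacements sampled (trilinearly) from the preliminary field, so the
#' merged field stays continuous across the mesh boundary instead of
#' relaxing freely toward it.
#'
#' @param preliminary a [displacement_field()] on the reference grid.
#' @param labels reference [label_map()].
#' @param structure_labels labels whose surfaces supply the constraints.
#' @param materials a [material_table()].
#' @param mesh_divisions cubes per axis of the correction mesh.
#' @param margin_mm mesh margin around the boundary voxels (mm).
#' @param per_organ correct each structure with its own mesh.
#' @param anchor_surface drive the mesh-surface nodes with the preliminary
#'   field for boundary continuity (default `TRUE`).
#' @param method FEM solver, see [assemble_and_solve()].
#' @param details attach mesh/constraints/solution as attribute `details`.
#' @return The corrected `displacement_field`.
#' @export
correct_field <- function(preliminary, labels, structure_labels, materials,
                          mesh_divisions = 12, margin_mm = 10,
                          per_organ = FALSE, anchor_surface = TRUE,
                          method = "direct", details = FALSE) {
  stopifnot(inherits(preliminary, "displacement_field"),
            inherits(labels, "label_map"),
            same_grid(preliminary$grid, labels$grid))
  if (per_organ) {
    out <- preliminary
    for (sl in structure_labels)
      out <- correct_field(out, labels, sl, materials, mesh_divisions,
                           margin_mm, per_organ = FALSE,
                           anchor_surface = anchor_surface, method = method)
    return(out)
  }
  vox <- extract_boundary_voxels(labels, structure_labels)
  mesh <- scale_mesh_to_cover(mesh_divisions, vox, labels$grid, margin_mm)
  cons <- build_constraints(vox, preliminary, mesh)
  driving <- cons$nodes
  dd <- cons$node_displacements
  if (anchor_surface) {
    surf <- setdiff(mesh_surface_nodes(mesh), driving)
    if (length(surf)) {
      su <- vapply(1:3, function(comp)
        sample_image(preliminary$u[, , , comp], preliminary$grid,
                     mesh$nodes[surf, , drop = FALSE], "linear", 0),
        numeric(length(surf)))
      driving <- c(driving, surf)
      dd <- rbind(dd, matrix(su, ncol = 3))
    }
  }
  mats <- assign_materials(mesh, labels, materials)
  sol <- assemble_and_solve(fem_problem(mesh, mats, driving, dd),
                            method = method)
  out <- interpolate_solution_to_field(mesh, sol, preliminary$grid,
                                       outside = preliminary)
  if (details)
    attr(out, "details") <- list(mesh = mesh, constraints = cons,
                                 solution = sol)
  out
}
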