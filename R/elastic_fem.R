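# Linear-elastic finite elements on tetrahedral meshes.
#
# 4-node constant-strain tetrahedra; the global system K d = f is driven
# purely by prescribed displacements at "driving" nodes (Dirichlet
# constraints), handled by exact partitioned elimination: rows/columns of
# the constrained degrees of freedom are removed and the known
# displacements moved to the right-hand side, then the reduced
# symmetric-positive-definite system is solved for the free nodes.

#' Tissue material table
#'
#' Maps label-map labels to isotropic linear-elastic constants. The bundled
#' presets follow the values commonly used for biomechanical DIR modelling:
#' Young's modulus 1 kPa for lung, 10 kPa for soft tissue and 1 MPa for
#' bone, with Poisson ratios 0.38, 0.45 and 0.49 respectively. Only the
#' ratios of E matter in a purely displacement-driven problem; absolute
#' stiffness cancels out.
#'
#' @param label integer label values as found in the label map.
#' @param name tissue name per label (informational).
#' @param E Young's modulus per label, Pa (> 0).
#' @param nu Poisson ratio per label, in `[0, 0.5)`.
#' @return A `material_table` data.frame with columns
#'   `label`, `name`, `E`, `nu`.
#' @examples
#' material_table(label = c(1, 2), name = c("soft_tissue", "bone"),
#'                E = c(1e4, 1e6), nu = c(0.45, 0.49))
#' @export
material_table <- function(label, name = as.character(label), E, nu) {
  if (!(length(label) == length(E) && length(E) == length(nu)))
    stop("material_table: label, E, nu must have equal length", call. = FALSE)
  if (anyDuplicated(label))
    stop("material_table: duplicate labels", call. = FALSE)
  if (any(E <= 0)) stop("material_table: E must be > 0", call. = FALSE)
  if (any(nu < 0 | nu >= 0.5))
    stop("material_table: nu must lie in [0, 0.5)", call. = FALSE)
  structure(data.frame(label = as.integer(label), name = name,
                       E = as.numeric(E), nu = as.numeric(nu)),
            class = c("material_table", "data.frame"))
}

#' @rdname material_table
#' @export
tissue_presets <- function() {
  material_table(label = 1:3,
                 name = c("lung", "soft_tissue", "bone"),
                 E = c(1e3, 1e4, 1e6),
                 nu = c(0.38, 0.45, 0.49))
}

# soft-tissue entry of a table (fallback material), by name when present,
# else the 10 kPa / 0.45 preset
soft_tissue_entry <- function(table) {
  i <- match("soft_tissue", table$name)
  if (!is.na(i)) return(list(E = table$E[i], nu = table$nu[i]))
  list(E = 1e4, nu = 0.45)
}

#' Assign a material to every mesh element
#'
#' Each tetrahedron takes the material of the label found at its centroid's
#' voxel. Centroids that fall outside the label grid, or on background
#' (label 0) or on a label missing from the table, take the soft-tissue
#' entry; the count of such fallbacks is reported via `message()` and kept
#' as attribute `n_fallback`.
#'
#' @param mesh a `tet_mesh`.
#' @param labels a [label_map()] overlapping the mesh.
#' @param table a [material_table()].
#' @return A data.frame with one row per element: columns `E`, `nu`, and
#'   attribute `n_fallback`.
#' @export
assign_materials <- function(mesh, labels, table) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(labels, "label_map"),
            inherits(table, "material_table"))
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  g <- labels$grid
  idx <- voxel_of(cen, g)
  inside <- idx[, 1] >= 1L & idx[, 1] <= g$shape[1] &
            idx[, 2] >= 1L & idx[, 2] <= g$shape[2] &
            idx[, 3] >= 1L & idx[, 3] <= g$shape[3]
  lab <- rep(0L, nrow(cen))
  lab[inside] <- labels$labels[idx[inside, , drop = FALSE]]
  row <- match(lab, table$label)
  fallback <- is.na(row)
  st <- soft_tissue_entry(table)
  E <- ifelse(fallback, st$E, table$E[row])
  nu <- ifelse(fallback, st$nu, table$nu[row])
  if (any(fallback))
    message(sum(fallback), " element(s) outside labelled tissue; ",
            "assigned soft-tissue material")
  structure(data.frame(E = E, nu = nu), n_fallback = sum(fallback))
}

# isotropic elasticity matrix in engineering (Voigt) strain order
# (exx, eyy, ezz, gxy, gyz, gzx)
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  D
}

#' Element stiffness of a linear tetrahedron
#'
#' Standard constant-strain tetrahedron: `K_e = V B' D B` with the 6 x 12
#' strain-displacement matrix built from the (constant) shape-function
#' gradients and the isotropic elasticity matrix `D(E, nu)`. The result is
#' symmetric with the six rigid-body motions in its null space.
#'
#' @param nodes 4 x 3 matrix of vertex coordinates (mm), positively
#'   oriented.
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @return 12 x 12 symmetric stiffness matrix (DOFs ordered x,y,z per
#'   vertex).
#' @export
element_stiffness <- function(nodes, E, nu) {
  M <- nodes[2:4, , drop = FALSE] - rep(nodes[1, ], each = 3)
  V <- det(M) / 6
  scale <- max(abs(M))^3
  if (!(V > 1e-12 * max(scale, 1e-300)))
    stop("element_stiffness: degenerate (non-positive volume) tetrahedron",
         call. = FALSE)
  G <- solve(M)                       # columns: grad N2, N3, N4
  grads <- cbind(-rowSums(G), G)      # grad N1 = -(N2+N3+N4)
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    bx <- grads[1, a]; by <- grads[2, a]; bz <- grads[3, a]
    col <- 3 * (a - 1)
    B[1, col + 1] <- bx
    B[2, col + 2] <- by
    B[3, col + 3] <- bz
    B[4, col + 1] <- by; B[4, col + 2] <- bx
    B[5, col + 2] <- bz; B[5, col + 3] <- by
    B[6, col + 1] <- bz; B[6, col + 3] <- bx
  }
  V * crossprod(B, elasticity_matrix(E, nu) %*% B)
}

#' Displacement-driven elasticity problem
#'
#' Bundles a mesh, per-element materials, and the driving-node constraints
#' `d_1..d_k`. External forces on driving nodes are carried for
#' completeness; since every forced node is also displacement-constrained
#' they only affect reactions, not the solution.
#'
#' @param mesh a `tet_mesh`.
#' @param materials per-element materials from [assign_materials()], or a
#'   list `list(E=, nu=)` applied uniformly.
#' @param driving_nodes distinct node indices carrying prescribed
#'   displacements (>= 3 non-collinear nodes required to pin rigid-body
#'   motion).
#' @param driving_displacements k x 3 matrix, mm.
#' @param external_forces optional k x 3 matrix of forces at driving nodes
#'   (default zero).
#' @return A `fem_problem` object.
#' @export
fem_problem <- function(mesh, materials, driving_nodes, driving_displacements,
                        external_forces = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.list(materials) && !is.data.frame(materials))
    materials <- data.frame(E = rep(materials$E, nrow(mesh$tets)),
                            nu = rep(materials$nu, nrow(mesh$tets)))
  if (nrow(materials) != nrow(mesh$tets))
    stop("fem_problem: one material per element required", call. = FALSE)
  driving_nodes <- as.integer(driving_nodes)
  if (anyDuplicated(driving_nodes))
    stop("fem_problem: driving nodes must be distinct", call. = FALSE)
  dd <- as.matrix(driving_displacements)
  if (nrow(dd) != length(driving_nodes) || ncol(dd) != 3L)
    stop("fem_problem: driving_displacements must be k x 3", call. = FALSE)
  if (length(driving_nodes) < 3L)
    stop("fem_problem: need >= 3 constrained nodes to remove rigid-body ",
         "motion", call. = FALSE)
  P <- mesh$nodes[driving_nodes, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
    stop("fem_problem: constrained nodes are collinear; rigid-body rotation ",
         "about their axis remains unconstrained", call. = FALSE)
  if (is.null(external_forces))
    external_forces <- matrix(0, length(driving_nodes), 3)
  structure(list(mesh = mesh, materials = materials,
                 driving_nodes = driving_nodes, driving_displacements = dd,
                 external_forces = as.matrix(external_forces)),
            class = "fem_problem")
}

#' @export
print.fem_problem <- function(x, ...) {
  cat(sprintf(
    "fem_problem: %d nodes / %d tets, %d driving node(s), E in [%.3g, %.3g] Pa\n",
    nrow(x$mesh$nodes), nrow(x$mesh$tets), length(x$driving_nodes),
    min(x$materials$E), max(x$materials$E)))
  invisible(x)
}

# Assemble the global sparse stiffness matrix. On the regular Kuhn lattice
# there are only 6 tet shapes up to translation, so element matrices are
# memoized by (shape class, E, nu); the generic element_stiffness() path
# covers everything else.
assemble_stiffness <- function(mesh, materials) {
  ntet <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  cls <- ((seq_len(ntet) - 1L) %% 6L) + 1L   # Kuhn shape class
  key <- paste(cls, materials$E, materials$nu)
  ukey <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (t in which(ukey)) {
    Ke <- element_stiffness(mesh$nodes[mesh$tets[t, ], , drop = FALSE],
                            materials$E[t], materials$nu[t])
    assign(key[t], Ke, envir = cache)
  }
  iv <- integer(144L * ntet); jv <- integer(144L * ntet)
  xv <- numeric(144L * ntet)
  rpat <- rep(1:12, times = 12); cpat <- rep(1:12, each = 12)
  for (t in seq_len(ntet)) {
    dofs <- rep(3L * (mesh$tets[t, ] - 1L), each = 3L) + c(1L, 2L, 3L)
    r <- (144L * (t - 1L) + 1L):(144L * t)
    iv[r] <- dofs[rpat]
    jv[r] <- dofs[cpat]
    xv[r] <- get(key[t], envir = cache)
  }
  Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(3L * nn, 3L * nn))
}

# unpreconditioned conjugate gradients on a sparse SPD system
cg_solve <- function(A, b, tol = 1e-10, maxit = 10000L) {
  x <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) <= tol * b2) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  warning("cg_solve: not converged to ", tol, " in ", maxit, " iterations")
  x
}

#' Assemble and solve the constrained elasticity system
#'
#' Assembles the global stiffness matrix, eliminates the driving degrees of
#' freedom by moving their known displacements to the right-hand side, and
#' solves the reduced symmetric-positive-definite system (sparse Cholesky
#' by default; `method = "cg"` switches to conjugate gradients with
#' relative tolerance 1e-10 for very large meshes). Driving nodes carry
#' their prescribed displacements exactly in the returned solution.
#'
#' @param problem a [fem_problem()].
#' @param method `"direct"` (sparse factorization) or `"cg"`.
#' @return A `fem_solution`: list with `displacements` (n x 3 mm) and the
#'   problem's driving nodes.
#' @export
assemble_and_solve <- function(problem, method = c("direct", "cg")) {
  method <- match.arg(method)
  mesh <- problem$mesh
  K <- assemble_stiffness(mesh, problem$materials)
  nn <- nrow(mesh$nodes)
  fixed <- sort(rep(3L * (problem$driving_nodes - 1L), each = 3L) + 1:3)
  dfix <- numeric(3L * nn)
  dfix[rep(3L * (problem$driving_nodes - 1L), each = 3L) + 1:3] <-
    as.vector(t(problem$driving_displacements))
  free <- setdiff(seq_len(3L * nn), fixed)
  d <- dfix
  if (length(free)) {
    rhs <- -as.numeric(K[free, fixed, drop = FALSE] %*% dfix[fixed])
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    if (method == "direct") {
      sol <- tryCatch(as.numeric(Matrix::solve(Kff, rhs)),
                      error = function(e)
                        stop("singular reduced stiffness system: the driving ",
                             "nodes do not pin all rigid-body motion (",
                             conditionMessage(e), ")", call. = FALSE))
    } else {
      sol <- cg_solve(Kff, rhs)
    }
    res <- as.numeric(Kff %*% sol) - rhs
    nr <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), 1e-300)
    if (!all(is.finite(sol)) || nr > 1e-6)
      stop("singular reduced stiffness system: solve failed (relative ",
           "residual ", signif(nr, 3), "); add non-collinear constraints",
           call. = FALSE)
    d[free] <- sol
  }
  structure(list(displacements = matrix(d, nn, 3, byrow = TRUE),
                 driving_nodes = problem$driving_nodes),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("fem_solution: %d nodes, |d| mean %.3g mm, max %.3g mm\n",
              nrow(x$displacements), mean(mag), max(mag)))
  invisible(x)
}

#' Interpolate a nodal solution to a voxel displacement field
#'
#' Voxels whose centres lie inside the mesh receive the barycentric
#' interpolation of the nodal displacements (exact for affine nodal data);
#' voxels outside the mesh copy the `outside` field (zero when omitted) --
#' this is the merge step that combines the model-generated interior with
#' pre-assigned exterior displacements.
#'
#' @param mesh a `tet_mesh`.
#' @param solution a `fem_solution` (or an n x 3 nodal matrix).
#' @param grid the reference [grid3d()] for the output field.
#' @param outside optional [displacement_field()] on `grid` supplying
#'   values outside the mesh.
#' @return A `displacement_field` on `grid`.
#' @export
interpolate_solution_to_field <- function(mesh, solution, grid,
                                          outside = NULL) {
  nodal <- if (inherits(solution, "fem_solution")) solution$displacements
           else as.matrix(solution)
  u <- lattice_interp(mesh, nodal, voxel_centers(grid))
  base <- if (is.null(outside)) matrix(0, nrow(u), 3)
          else {
            stopifnot(inherits(outside, "displacement_field"),
                      same_grid(outside$grid, grid))
            cbind(as.vector(outside$u[, , , 1]),
                  as.vector(outside$u[, , , 2]),
                  as.vector(outside$u[, , , 3]))
          }
  miss <- is.na(u[, 1])
  u[miss, ] <- base[miss, , drop = FALSE]
  displacement_field(grid, array(u, c(grid$shape, 3L)))
}

#' Nodes on the surface of a mesh box
#'
#' Convenience for patch tests and fully-clamped problems: indices of all
#' lattice nodes lying on a face of the mesh bounding box.
#'
#' @param mesh a `tet_mesh`.
#' @return Integer vector of node indices.
#' @export
mesh_surface_nodes <- function(mesh) {
  tol <- 1e-9 * max(mesh$h)
  on_face <- rep(FALSE, nrow(mesh$nodes))
  for (ax in 1:3)
    on_face <- on_face |
      abs(mesh$nodes[, ax] - mesh$box_min[ax]) < tol |
      abs(mesh$nodes[, ax] - mesh$box_max[ax]) < tol
  which(on_face)
}
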