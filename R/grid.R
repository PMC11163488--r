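#' Axis-aligned 3-D sampling grid
#'
#' A `grid3d` describes the lattice on which every image, label map and
#' displacement field in this package lives: an axis-aligned box of
#' `shape` voxels with voxel spacing in millimetres and the physical
#' position of the centre of the first voxel as `origin`. Voxel `(i,j,k)`
#' (1-based, as everywhere in R) sits at `origin + (c(i,j,k) - 1) * spacing`.
#' Direction cosines are always the identity; oblique grids are rejected at
#' the I/O layer.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 2).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0). A
#'   scalar is recycled.
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   centre. Default `c(0, 0, 0)`.
#' @return An object of class `grid3d` with fields `shape`, `spacing`,
#'   `origin`.
#' @examples
#' g <- grid3d(c(32, 32, 24), spacing = c(1.6, 1.6, 2.38))
#' g
#' @export
grid3d <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 2L))
    stop("grid3d: `shape` must be 3 integers, each >= 2", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid3d: `spacing` must be positive and finite", call. = FALSE)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin)))
    stop("grid3d: `origin` must be finite", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
format.grid3d <- function(x, ...) {
  sprintf("%dx%dx%d @ %s mm", x$shape[1], x$shape[2], x$shape[3],
          paste(signif(x$spacing, 3), collapse = "x"))
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Physical coordinates of every voxel centre
#'
#' @param grid a [grid3d()].
#' @return An n-voxel-by-3 matrix of mm coordinates, voxels ordered with the
#'   first index fastest (R array order).
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid3d"))
  idx <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                               j = seq_len(grid$shape[2]),
                               k = seq_len(grid$shape[3])))
  dimnames(idx) <- NULL
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' 3-D scalar image (intensity or dose)
#'
#' @param grid a [grid3d()].
#' @param values numeric array with `dim == grid$shape`; all values finite.
#' @return A `scalar_image` object.
#' @export
scalar_image <- function(grid, values) {
  stopifnot(inherits(grid, "grid3d"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("scalar_image: `values` dim must equal grid shape", call. = FALSE)
  if (!all(is.finite(values)))
    stop("scalar_image: all values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("scalar_image on %s; range [%.4g, %.4g]\n",
              format(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' 3-D label map (integer segmentation)
#'
#' Label 0 is background/air; positive labels identify structures or
#' material regions.
#'
#' @param grid a [grid3d()].
#' @param labels integer array with `dim == grid$shape`, all labels >= 0.
#' @return A `label_map` object.
#' @export
label_map <- function(grid, labels) {
  stopifnot(inherits(grid, "grid3d"))
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label_map: `labels` dim must equal grid shape", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("label_map: labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("label_map on %s; %d structure label(s): %s\n",
              format(x$grid), length(tab),
              paste(sprintf("%s (%d vox)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Displacement vector field (DVF)
#'
#' Pull-back convention: a point `x` on the reference grid corresponds to
#' `x + u(x)` in the moving/source image, with `u` in millimetres. The zero
#' field is the identity correspondence.
#'
#' @param grid a [grid3d()]; the reference lattice.
#' @param u numeric array of dim `c(grid$shape, 3)`, displacement per voxel
#'   in mm; must be finite everywhere.
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(grid, u) {
  stopifnot(inherits(grid, "grid3d"))
  u <- as.array(u)
  if (length(dim(u)) != 4L || !identical(as.integer(dim(u)[1:3]), grid$shape) ||
      dim(u)[4] != 3L)
    stop("displacement_field: `u` must have dim c(grid$shape, 3)", call. = FALSE)
  if (!all(is.finite(u)))
    stop("displacement_field: non-finite displacement values", call. = FALSE)
  storage.mode(u) <- "double"
  structure(list(grid = grid, u = u), class = "displacement_field")
}

#' Zero (identity) displacement field on a grid
#' @param grid a [grid3d()].
#' @return A `displacement_field` with u = 0 everywhere.
#' @export
zero_field <- function(grid) {
  displacement_field(grid, array(0, c(grid$shape, 3L)))
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("displacement_field on %s; |u| mean %.3g mm, max %.3g mm\n",
              format(x$grid), mean(mag), max(mag)))
  invisible(x)
}

#' Jacobian-determinant map
#'
#' Holds `J(x) = det(I + grad u(x))`, the local volume-change ratio of a
#' deformation (1 = volume preserving). Constructed by
#' [jacobian_determinant_map()]; represented as a scalar image subclass.
#'
#' @name jacobian_map
NULL

#' @export
print.jacobian_map <- function(x, ...) {
  cat(sprintf("jacobian_map on %s; J in [%.4g, %.4g], mean %.4g\n",
              format(x$grid), min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}
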