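# Displacement-field calculus: Jacobian maps, backward warping, grid images.

# Finite-difference gradient of a 3-D array along one axis in physical units:
# central differences in the interior, one-sided at the two faces.
axis_gradient <- function(a, axis, h) {
  n <- dim(a)[axis]
  g <- array(0, dim(a))
  ix <- function(r) switch(axis,
                           a[r, , , drop = FALSE],
                           a[, r, , drop = FALSE],
                           a[, , r, drop = FALSE])
  set <- function(r, v) {
    if (axis == 1L) g[r, , ] <<- v
    else if (axis == 2L) g[, r, ] <<- v
    else g[, , r] <<- v
  }
  set(2:(n - 1), (ix(3:n) - ix(1:(n - 2))) / (2 * h))
  set(1L, (ix(2L) - ix(1L)) / h)
  set(n, (ix(n) - ix(n - 1L)) / h)
  g
}

#' Jacobian-determinant map of a displacement field
#'
#' Computes `J(x) = det(I + grad u(x))` per voxel, the local volume-change
#' ratio of the deformation `x -> x + u(x)`. The displacement gradient is
#' estimated by central differences in physical units (mm), falling back to
#' one-sided differences on the grid faces. Central differences are exact
#' for affine fields, so affine `u = A x + b` yields `det(I + A)` at every
#' interior voxel.
#'
#' @param field a [displacement_field()] on a grid with >= 3 voxels per axis.
#' @return A `jacobian_map` (scalar image subclass) on the same grid.
#' @examples
#' g <- grid3d(c(8, 8, 8), 2)
#' jmap <- jacobian_determinant_map(zero_field(g))
#' range(jmap$values)  # 1 1
#' @export
jacobian_determinant_map <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  if (any(field$grid$shape < 3L))
    stop("jacobian_determinant_map: grid must have >= 3 voxels per axis",
         call. = FALSE)
  if (!all(is.finite(field$u)))
    stop("jacobian_determinant_map: non-finite field values", call. = FALSE)
  sp <- field$grid$spacing
  # D[[c]][[a]] = d u_c / d x_a (+ identity on the diagonal)
  D <- vector("list", 3L)
  for (comp in 1:3) {
    D[[comp]] <- lapply(1:3, function(ax)
      axis_gradient(field$u[, , , comp], ax, sp[ax]))
    D[[comp]][[comp]] <- D[[comp]][[comp]] + 1
  }
  J <- D[[1]][[1]] * (D[[2]][[2]] * D[[3]][[3]] - D[[2]][[3]] * D[[3]][[2]]) -
       D[[1]][[2]] * (D[[2]][[1]] * D[[3]][[3]] - D[[2]][[3]] * D[[3]][[1]]) +
       D[[1]][[3]] * (D[[2]][[1]] * D[[3]][[2]] - D[[2]][[2]] * D[[3]][[1]])
  out <- scalar_image(field$grid, J)
  class(out) <- c("jacobian_map", class(out))
  out
}

# Sample a 3-D array at physical points (n x 3 matrix, mm).
# mode "linear": trilinear, valid while the point lies within the voxel-centre
# hull; "nearest": nearest voxel, valid within half a voxel beyond it.
# Out-of-extent samples take `fill`.
sample_image <- function(values, grid, pts, mode = c("linear", "nearest"),
                         fill = 0) {
  mode <- match.arg(mode)
  n <- nrow(pts)
  t1 <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  t2 <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  t3 <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  sh <- grid$shape
  out <- rep(as.numeric(fill), n)
  if (mode == "nearest") {
    i1 <- floor(t1 + 0.5); i2 <- floor(t2 + 0.5); i3 <- floor(t3 + 0.5)
    ok <- i1 >= 1 & i1 <= sh[1] & i2 >= 1 & i2 <= sh[2] & i3 >= 1 & i3 <= sh[3]
    if (any(ok))
      out[ok] <- values[cbind(i1[ok], i2[ok], i3[ok])]
    return(out)
  }
  ok <- t1 >= 1 & t1 <= sh[1] & t2 >= 1 & t2 <= sh[2] & t3 >= 1 & t3 <= sh[3]
  if (!any(ok)) return(out)
  t1 <- t1[ok]; t2 <- t2[ok]; t3 <- t3[ok]
  i1 <- pmin(floor(t1), sh[1] - 1); f1 <- t1 - i1
  i2 <- pmin(floor(t2), sh[2] - 1); f2 <- t2 - i2
  i3 <- pmin(floor(t3), sh[3] - 1); f3 <- t3 - i3
  v <- 0
  for (d1 in 0:1) for (d2 in 0:1) for (d3 in 0:1) {
    w <- (if (d1 == 1) f1 else 1 - f1) *
         (if (d2 == 1) f2 else 1 - f2) *
         (if (d3 == 1) f3 else 1 - f3)
    v <- v + w * values[cbind(i1 + d1, i2 + d2, i3 + d3)]
  }
  out[ok] <- v
  out
}

#' Backward warping of a scalar image
#'
#' Builds the warped image on the field's grid by backward mapping: the
#' output at reference position `x` is the source image sampled at
#' `x + u(x)` (trilinear or nearest-neighbour). The source may live on a
#' different grid; samples falling outside its extent take `fill`.
#'
#' @param source a [scalar_image()] to be pulled back.
#' @param field a [displacement_field()]; its grid is the output lattice.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @param fill value assigned where `x + u(x)` leaves the source extent.
#' @return A `scalar_image` on `field$grid`.
#' @export
warp_scalar_backward <- function(source, field, mode = c("linear", "nearest"),
                                 fill = 0) {
  stopifnot(inherits(source, "scalar_image"),
            inherits(field, "displacement_field"))
  mode <- match.arg(mode)
  pts <- voxel_centers(field$grid)
  pts <- pts + cbind(as.vector(field$u[, , , 1]),
                     as.vector(field$u[, , , 2]),
                     as.vector(field$u[, , , 3]))
  vals <- sample_image(source$values, source$grid, pts, mode, fill)
  scalar_image(field$grid, array(vals, field$grid$shape))
}

#' Backward warping of a label map
#'
#' Nearest-neighbour pull-back of structure occupancy: the warped label at
#' `x` is the source label at the voxel nearest to `x + u(x)`; out-of-extent
#' samples become background (0).
#'
#' @param mask a [label_map()].
#' @param field a [displacement_field()] defining the output lattice.
#' @return A `label_map` on `field$grid`.
#' @export
warp_mask_backward <- function(mask, field) {
  stopifnot(inherits(mask, "label_map"))
  img <- scalar_image(mask$grid, array(as.numeric(mask$labels), mask$grid$shape))
  w <- warp_scalar_backward(img, field, mode = "nearest", fill = 0)
  label_map(field$grid, array(as.integer(round(w$values)), field$grid$shape))
}

#' Rectilinear grid-line image
#'
#' Marks planes at regular physical intervals, the classic visual check for
#' deformation fields: warping this image makes local expansions and
#' contractions visible as stretched or compressed cells. A voxel takes
#' `line_value` when its physical coordinate on any axis lies within half a
#' voxel of a multiple of `interval_mm`.
#'
#' @param grid a [grid3d()].
#' @param interval_mm spacing between line planes (>= 2 * max voxel spacing);
#'   default 10 mm (1 cm grid).
#' @param line_value,bg_value intensities for line and background voxels.
#' @return A `scalar_image`.
#' @export
make_grid_image <- function(grid, interval_mm = 10, line_value = 1,
                            bg_value = 0) {
  stopifnot(inherits(grid, "grid3d"))
  if (interval_mm < 2 * max(grid$spacing))
    stop("make_grid_image: `interval_mm` must be >= 2 * max(spacing)",
         call. = FALSE)
  on_line <- function(ax) {
    x <- grid$origin[ax] + (seq_len(grid$shape[ax]) - 1) * grid$spacing[ax]
    d <- abs(x - round(x / interval_mm) * interval_mm)
    d <= grid$spacing[ax] / 2 + 1e-12
  }
  l1 <- on_line(1); l2 <- on_line(2); l3 <- on_line(3)
  line <- outer(outer(l1, l2, "|"), l3, "|")
  scalar_image(grid, array(ifelse(line, line_value, bg_value), grid$shape))
}
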