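# DVF-based dose transfer and DVH summaries.

#' Transfer a dose grid through a displacement field
#'
#' Trilinear backward mapping: the transferred dose at reference position
#' `x` is the source dose sampled at `x + u(x)`. Samples leaving the dose
#' extent become 0 and their count is reported via `warning()`.
#'
#' @param dose a [scalar_image()] in Gy.
#' @param field a [displacement_field()] defining the output lattice.
#' @return A `scalar_image` on `field$grid`.
#' @export
transfer_dose <- function(dose, field) {
  stopifnot(inherits(dose, "scalar_image"),
            inherits(field, "displacement_field"))
  pts <- voxel_centers(field$grid) +
    cbind(as.vector(field$u[, , , 1]), as.vector(field$u[, , , 2]),
          as.vector(field$u[, , , 3]))
  g <- dose$grid
  out_of_extent <- sum(
    pts[, 1] < g$origin[1] | pts[, 1] > g$origin[1] + (g$shape[1] - 1) * g$spacing[1] |
    pts[, 2] < g$origin[2] | pts[, 2] > g$origin[2] + (g$shape[2] - 1) * g$spacing[2] |
    pts[, 3] < g$origin[3] | pts[, 3] > g$origin[3] + (g$shape[3] - 1) * g$spacing[3])
  if (out_of_extent > 0L)
    warning("transfer_dose: ", out_of_extent,
            " voxel(s) sampled outside the dose extent; set to 0")
  vals <- sample_image(dose$values, g, pts, "linear", 0)
  scalar_image(field$grid, array(vals, field$grid$shape))
}

#' Cumulative dose-volume histogram
#'
#' Fraction of structure voxels receiving at least each bin-edge dose
#' (voxel counting, `>=` at edges). The curve starts at 1 for dose 0 and is
#' monotone non-increasing.
#'
#' @param dose a [scalar_image()] in Gy.
#' @param mask a [label_map()] or logical array selecting the structure.
#' @param bin_gy bin width in Gy.
#' @return A `dvh_curve`: data.frame with `dose` (bin edges, Gy) and
#'   `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_gy = 1) {
  stopifnot(inherits(dose, "scalar_image"), bin_gy > 0)
  sel <- as_mask_array(mask)
  if (!identical(dim(sel), dim(dose$values)))
    stop("dvh: mask shape does not match the dose grid", call. = FALSE)
  v <- dose$values[sel]
  if (!length(v)) stop("dvh: empty structure mask", call. = FALSE)
  edges <- seq(0, max(v) + bin_gy, by = bin_gy)
  frac <- vapply(edges, function(e) mean(v >= e), numeric(1))
  structure(data.frame(dose = edges, volume_fraction = frac),
            class = c("dvh_curve", "data.frame"))
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: %d bins, D0 fraction %.3f, max dose %.4g Gy\n",
              nrow(x), x$volume_fraction[1], max(x$dose)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = "Dose (Gy)",
                           ylab = "Volume fraction", type = "s") {
  graphics::plot(x$dose, x$volume_fraction, type = type, xlab = xlab,
                 ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' V_x dose metric
#'
#' Percent of structure voxels receiving at least `threshold_gy`.
#'
#' @inheritParams dvh
#' @param threshold_gy dose threshold in Gy.
#' @return Percentage in `[0, 100]`.
#' @export
v_metric <- function(dose, mask, threshold_gy) {
  stopifnot(inherits(dose, "scalar_image"))
  sel <- as_mask_array(mask)
  v <- dose$values[sel]
  if (!length(v)) stop("v_metric: empty structure mask", call. = FALSE)
  100 * mean(v >= threshold_gy)
}
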