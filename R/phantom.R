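# Synthetic abdominal phantoms: nested ellipsoid "organs" in a soft-tissue
# body box, analytic ground-truth deformations, interior field corruption,
# and simple dose distributions. Every generator is a pure function of its
# spec and seed so fixtures are reproducible bit-for-bit.

#' Phantom specification
#'
#' @param grid a [grid3d()]; default 64^3 voxels at 2 mm spacing (a 128 mm
#'   abdomen-scale box).
#' @param organs data.frame with one ellipsoid organ per row: columns
#'   `label` (integer >= 2; label 1 is the body), `name`,
#'   `cx, cy, cz` (centre mm), `ax, ay, az` (semi-axes mm), `material`
#'   (a [tissue_presets()] name). Defaults to three soft-tissue organs with
#'   abdominal-organ dimensions.
#' @param seed integer; fixes the jitter applied to organ centres and
#'   semi-axes so each seed yields a distinct but reproducible anatomy.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid = grid3d(c(64, 64, 64), 2), organs = NULL,
                         seed = 1L) {
  if (is.null(organs)) {
    base <- data.frame(
      label = 2:4,
      name = c("organ_a", "organ_b", "organ_c"),
      cx = c(38, 88, 62), cy = c(44, 46, 90), cz = c(60, 68, 64),
      ax = c(20, 18, 17), ay = c(17, 20, 18), az = c(21, 17, 20),
      material = "soft_tissue")
    rng <- rng_stream(seed, 101L)
    jit <- matrix(rng(18), 3, 6)
    base[, c("cx", "cy", "cz")] <- base[, c("cx", "cy", "cz")] +
      round(2 * (2 * jit[, 1:3] - 1), 1)
    base[, c("ax", "ay", "az")] <- base[, c("ax", "ay", "az")] +
      round(1 * (2 * jit[, 4:6] - 1), 1)
    organs <- base
  }
  stopifnot(all(organs$label >= 2L), !anyDuplicated(organs$label))
  structure(list(grid = grid, organs = organs, seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic uniform stream decoupled from the global RNG
rng_stream <- function(seed, salt) {
  state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    if (is.null(state)) set.seed((seed * 7919L + salt) %% 2147483647L)
    else assign(".Random.seed", state, globalenv())
    out <- stats::runif(n)
    state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
}

ellipsoid_mask <- function(grid, center, semi) {
  x <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  qx <- ((x - center[1]) / semi[1])^2
  qy <- ((y - center[2]) / semi[2])^2
  qz <- ((z - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

#' Build a phantom anatomy
#'
#' Voxelizes the spec's ellipsoid organs inside a body box of soft tissue
#' (label 1), extracts a surface point cloud per organ, and assembles the
#' matching material table. Overlapping organs after voxelization are an
#' error.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom`: list with `labels` ([label_map()]), `structures`
#'   (list of [structure_surface()]), `materials` ([material_table()]) and
#'   the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  lab <- array(1L, g$shape)
  occupied <- array(FALSE, g$shape)
  for (i in seq_len(nrow(spec$organs))) {
    o <- spec$organs[i, ]
    m <- ellipsoid_mask(g, c(o$cx, o$cy, o$cz), c(o$ax, o$ay, o$az))
    if (any(m & occupied))
      stop("make_phantom: organs '", o$name, "' overlaps an earlier organ ",
           "after voxelization", call. = FALSE)
    occupied <- occupied | m
    lab[m] <- as.integer(o$label)
  }
  labels <- label_map(g, lab)
  structures <- lapply(seq_len(nrow(spec$organs)), function(i) {
    o <- spec$organs[i, ]
    surface_from_mask(labels, o$label, o$name)
  })
  names(structures) <- spec$organs$name
  pres <- tissue_presets()
  mat_rows <- match(c("soft_tissue", spec$organs$material), pres$name)
  if (any(is.na(mat_rows)))
    stop("make_phantom: unknown material name", call. = FALSE)
  materials <- material_table(label = c(1L, spec$organs$label),
                              name = c("soft_tissue", spec$organs$material),
                              E = pres$E[mat_rows], nu = pres$nu[mat_rows])
  structure(list(labels = labels, structures = structures,
                 materials = materials, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom (seed %d): %s; organs %s\n", x$spec$seed,
              format(x$labels$grid),
              paste(x$spec$organs$name, collapse = ", ")))
  invisible(x)
}

#' Analytic ground-truth displacement fields
#'
#' Evaluates a known deformation at the voxel centres of `grid`, in the
#' pull-back convention. Kinds:
#' \describe{
#'   \item{translation}{`u = t`; params `list(t)`. JD = 1.}
#'   \item{affine}{`u = A (x - c) + b`; params `list(A, b, center)`.
#'     JD = `det(I + A)`.}
#'   \item{radial}{`u = alpha (x - c)`; params `list(alpha, center)`.
#'     JD = `(1 + alpha)^3`.}
#'   \item{swirl}{divergence-free Gaussian vortex
#'     `u = a exp(-r^2 / (2 s^2)) (omega x (x - c))`;
#'     params `list(a, sigma, center, axis)`.}
#' }
#' For the first three kinds the analytic Jacobian determinant is attached
#' as attribute `jd`.
#'
#' @param kind one of `"translation"`, `"affine"`, `"radial"`, `"swirl"`.
#' @param params named list of parameters, see above.
#' @param grid a [grid3d()].
#' @return A [displacement_field()].
#' @export
make_ground_truth_field <- function(kind = c("translation", "affine",
                                             "radial", "swirl"),
                                    params, grid) {
  kind <- match.arg(kind)
  ctr <- voxel_centers(grid)
  u <- switch(kind,
    translation = {
      t0 <- rep_len(as.numeric(params$t), 3L)
      matrix(t0, nrow(ctr), 3, byrow = TRUE)
    },
    affine = {
      A <- params$A
      b <- if (is.null(params$b)) c(0, 0, 0) else params$b
      c0 <- if (is.null(params$center)) c(0, 0, 0) else params$center
      sweep(sweep(ctr, 2, c0) %*% t(A), 2, b, "+")
    },
    radial = {
      c0 <- params$center
      params$alpha * sweep(ctr, 2, c0)
    },
    swirl = {
      c0 <- params$center
      ax <- params$axis / sqrt(sum(params$axis^2))
      d <- sweep(ctr, 2, c0)
      r2 <- rowSums(d^2)
      w <- params$a * exp(-r2 / (2 * params$sigma^2))
      w * cbind(ax[2] * d[, 3] - ax[3] * d[, 2],
                ax[3] * d[, 1] - ax[1] * d[, 3],
                ax[1] * d[, 2] - ax[2] * d[, 1])
    })
  field <- displacement_field(grid, array(u, c(grid$shape, 3L)))
  attr(field, "jd") <- switch(kind,
    translation = 1,
    affine = det(diag(3) + params$A),
    radial = (1 + params$alpha)^3,
    NULL)
  field
}

# inverse of the analytic maps x -> x + u(x), needed to voxelize the moving
# anatomy exactly
analytic_inverse_map <- function(kind, params, pts) {
  switch(kind,
    translation = sweep(pts, 2, rep_len(as.numeric(params$t), 3L)),
    affine = {
      A <- params$A
      b <- if (is.null(params$b)) c(0, 0, 0) else params$b
      c0 <- if (is.null(params$center)) c(0, 0, 0) else params$center
      sweep(sweep(pts, 2, c0 + b) %*% t(solve(diag(3) + A)), 2, c0, "+")
    },
    radial = {
      c0 <- params$center
      sweep(sweep(pts, 2, c0) / (1 + params$alpha), 2, c0, "+")
    },
    stop("analytic_inverse_map: no closed-form inverse for kind '", kind,
         "'", call. = FALSE))
}

#' Deform a phantom analytically
#'
#' Produces the moving-image anatomy for a known deformation: each moving
#' voxel takes the reference label of its analytically inverse-mapped
#' position, so warping the moving masks back with the ground-truth field
#' reproduces the reference masks exactly (up to voxelization). Supports
#' the kinds with closed-form inverses (`translation`, `affine`,
#' `radial`).
#'
#' @param phantom a [make_phantom()] result.
#' @param kind,params as in [make_ground_truth_field()].
#' @return List with `labels` (moving [label_map()]), `structures` (moving
#'   [structure_surface()] list) and `field` (the ground-truth
#'   [displacement_field()] on the reference grid).
#' @export
deform_phantom <- function(phantom, kind, params) {
  g <- phantom$labels$grid
  ctr <- voxel_centers(g)
  src <- analytic_inverse_map(kind, params, ctr)
  lab <- array(1L, g$shape)
  for (i in seq_len(nrow(phantom$spec$organs))) {
    o <- phantom$spec$organs[i, ]
    q <- ((src[, 1] - o$cx) / o$ax)^2 + ((src[, 2] - o$cy) / o$ay)^2 +
         ((src[, 3] - o$cz) / o$az)^2
    lab[array(q <= 1, g$shape)] <- as.integer(o$label)
  }
  labels <- label_map(g, lab)
  structures <- lapply(seq_len(nrow(phantom$spec$organs)), function(i) {
    o <- phantom$spec$organs[i, ]
    surface_from_mask(labels, o$label, o$name)
  })
  names(structures) <- phantom$spec$organs$name
  list(labels = labels, structures = structures,
       field = make_ground_truth_field(kind, params, g))
}

#' Corruption specification
#'
#' Compactly supported radial "hot/cold spot" bumps added strictly inside
#' organs, emulating the interior errors of intensity-driven DIR while
#' leaving every boundary displacement bit-exact. Each bump displaces
#' `u += amplitude * (x - c) * (1 - (r/R)^2)^2` for `r < R` (C^1, zero
#' value and slope at `R`), so its Jacobian perturbation at the centre is
#' `(1 + amplitude)^3`.
#'
#' The defaults emulate severe interior hot/cold spots: per-organ STD-JD of
#' a corrupted smooth field lands around 0.2-0.5, the scale reported for
#' intensity-driven DIR in abdominal organs. Amplitudes are kept at <= 1 so
#' a single bump never folds the deformation (`J > 0` everywhere).
#'
#' @param n_bumps bumps per organ.
#' @param amplitude dimensionless divergence scale of each bump, in
#'   `(0, 1]`.
#' @param radius_mm bump support radius `R` (mm).
#' @param min_depth_vox minimum distance (voxels) between the bump support
#'   and the organ surface.
#' @param seed integer; fixes bump centres and signs.
#' @return A `corruption_spec` object.
#' @export
corruption_spec <- function(n_bumps = 8L, amplitude = 1.0, radius_mm = 6,
                            min_depth_vox = 2L, seed = 1L) {
  if (amplitude > 1)
    stop("corruption_spec: amplitude > 1 can fold the deformation",
         call. = FALSE)
  stopifnot(n_bumps >= 0, amplitude > 0, radius_mm > 0, min_depth_vox >= 0)
  structure(list(n_bumps = as.integer(n_bumps), amplitude = amplitude,
                 radius_mm = radius_mm, min_depth_vox = as.integer(min_depth_vox),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a displacement field inside organs
#'
#' Adds `spec$n_bumps` alternating-sign bumps per selected organ, centred
#' at interior voxels whose Euclidean distance to the organ surface is at
#' least `radius_mm + min_depth_vox * max(spacing)`, so the clean field is
#' returned bit-exact at and outside every organ boundary. The achieved
#' per-organ STD-JD of the corrupted field is attached as attribute
#' `achieved_std_jd` so corruption severity can be calibrated against the
#' uncertainty scale under study.
#'
#' @param clean a [displacement_field()].
#' @param labels the reference [label_map()].
#' @param spec a [corruption_spec()].
#' @param organ_labels labels to corrupt (default: all labels >= 2).
#' @return The corrupted `displacement_field`.
#' @export
corrupt_field <- function(clean, labels, spec, organ_labels = NULL) {
  stopifnot(inherits(clean, "displacement_field"),
            inherits(labels, "label_map"),
            same_grid(clean$grid, labels$grid),
            inherits(spec, "corruption_spec"))
  if (spec$n_bumps == 0L) return(clean)
  g <- clean$grid
  if (is.null(organ_labels))
    organ_labels <- setdiff(sort(unique(as.vector(labels$labels))), 0:1)
  rng <- rng_stream(spec$seed, 367L)
  ctr <- voxel_centers(g)
  u <- array(clean$u, dim(clean$u))
  sgn <- 1
  for (ol in organ_labels) {
    inside <- which(labels$labels == ol)
    if (!length(inside)) next
    surf <- mask_to_surface_points(labels, ol)
    clearance <- spec$radius_mm + spec$min_depth_vox * max(g$spacing)
    depth <- nearest_dists(ctr[inside, , drop = FALSE], surf)
    ok <- inside[depth >= clearance]
    if (!length(ok)) {
      warning("corrupt_field: organ label ", ol, " too small for bumps of ",
              "radius ", spec$radius_mm, " mm at depth ", spec$min_depth_vox,
              " voxels; skipped")
      next
    }
    # greedy draw keeping bump centres >= radius_mm apart, so no two bump
    # cores overlap and the single-bump fold-free guarantee carries over
    perm <- ok[order(rng(length(ok)))]
    picks <- integer(0)
    for (p in perm) {
      if (length(picks) == spec$n_bumps) break
      if (!length(picks) ||
          min(sqrt(rowSums(sweep(ctr[picks, , drop = FALSE], 2,
                                 ctr[p, ])^2))) >= spec$radius_mm)
        picks <- c(picks, p)
    }
    if (length(picks) < spec$n_bumps)
      warning("corrupt_field: organ label ", ol, ": placed ", length(picks),
              " of ", spec$n_bumps, " bumps")
    for (p in picks) {
      c0 <- ctr[p, ]
      d <- sweep(ctr, 2, c0)
      r2 <- rowSums(d^2)
      s <- r2 < spec$radius_mm^2
      w <- numeric(length(r2))
      w[s] <- sgn * spec$amplitude * (1 - r2[s] / spec$radius_mm^2)^2
      u <- u + array(w * d, dim(u))
      sgn <- -sgn
    }
  }
  out <- displacement_field(g, u)
  jmap <- jacobian_determinant_map(out)
  achieved <- vapply(organ_labels, function(ol)
    jd_stats(jmap, labels$labels == ol)$std_jd, numeric(1))
  names(achieved) <- organ_labels
  attr(out, "achieved_std_jd") <- achieved
  out
}

#' Synthetic dose distributions
#'
#' @param kind `"uniform"` (params `list(dose)`), `"gradient"`
#'   (`list(g, d0, center)`: dose `d0 + g . (x - center)`), or
#'   `"spherical"` (`list(center, radius_mm, d_max, falloff_mm)`: `d_max`
#'   inside the target sphere, linear falloff to zero over `falloff_mm`).
#' @param params named parameter list.
#' @param grid a [grid3d()].
#' @return A [scalar_image()] in Gy.
#' @export
make_dose <- function(kind = c("uniform", "gradient", "spherical"), params,
                      grid) {
  kind <- match.arg(kind)
  ctr <- voxel_centers(grid)
  v <- switch(kind,
    uniform = rep(params$dose, nrow(ctr)),
    gradient = params$d0 + as.numeric(sweep(ctr, 2, params$center) %*%
                                        params$g),
    spherical = {
      r <- sqrt(rowSums(sweep(ctr, 2, params$center)^2))
      pmax(0, params$d_max *
                pmin(1, (params$radius_mm + params$falloff_mm - r) /
                          params$falloff_mm))
    })
  scalar_image(grid, array(v, grid$shape))
}
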