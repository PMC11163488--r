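# Contour matching: per-point displacements between a reference structure
# surface R and its moving counterpart M.
#
# After translating M's centroid onto R's, every reference point r_i is
# matched to the candidate translated moving point m_t,j (within a search
# radius) minimizing
#
#     G(r_i, m_t,j) + lambda * N(r_i, m_t,j)
#
# where G is the Euclidean distance in mm and N compares binary
# contour-occupancy rasters in Gaussian-weighted windows around the two
# points. The winning displacements (with the centroid shift restored)
# drive the elastic model of the CM-FEM registration.

#' Structure surface
#'
#' A named anatomical structure represented both as an ordered contour
#' point cloud (mm) and as its voxelized occupancy mask. When only a mask
#' is available, [mask_to_surface_points()] derives the point cloud.
#'
#' @param name structure name; pairs reference and moving structures.
#' @param points n x 3 matrix of contour points (mm), n >= 4, non-coplanar,
#'   all within the grid extent.
#' @param mask a [label_map()] with nonzero voxels marking the structure.
#' @return A `structure_surface` object.
#' @export
structure_surface <- function(name, points, mask) {
  stopifnot(inherits(mask, "label_map"))
  points <- as.matrix(points)
  if (nrow(points) < 4L)
    stop("structure_surface: need >= 4 contour points", call. = FALSE)
  if (qr(sweep(points, 2, colMeans(points)))$rank < 3L)
    stop("structure_surface: contour points are coplanar", call. = FALSE)
  if (!any(mask$labels > 0L))
    stop("structure_surface: empty mask", call. = FALSE)
  g <- mask$grid
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$shape - 0.5) * g$spacing
  if (any(sweep(points, 2, lo) < 0) || any(sweep(points, 2, hi) > 0))
    stop("structure_surface: points outside the grid extent", call. = FALSE)
  structure(list(name = name, points = points, mask = mask, grid = g),
            class = "structure_surface")
}

#' @export
print.structure_surface <- function(x, ...) {
  cat(sprintf("structure_surface '%s': %d points, %d mask voxels on %s\n",
              x$name, nrow(x$points), sum(x$mask$labels > 0L),
              format(x$grid)))
  invisible(x)
}

#' Surface point cloud of a labelled structure
#'
#' Centres of structure voxels that touch a different label through one of
#' their 6 faces (grid-edge voxels count as surface).
#'
#' @param mask a [label_map()].
#' @param label the structure label (default: any nonzero voxel).
#' @return n x 3 matrix of mm coordinates.
#' @export
mask_to_surface_points <- function(mask, label = NULL) {
  occ <- if (is.null(label)) mask$labels > 0L else mask$labels == label
  vox <- boundary_voxels_of(occ)
  sweep(sweep(vox - 1, 2, mask$grid$spacing, "*"), 2, mask$grid$origin, "+")
}

#' Surface structure from a mask
#' @inheritParams mask_to_surface_points
#' @param name structure name.
#' @return A [structure_surface()].
#' @export
surface_from_mask <- function(mask, label = NULL, name = "structure") {
  occ <- if (is.null(label)) mask$labels > 0L else mask$labels == label
  structure_surface(name, mask_to_surface_points(mask, label),
                    label_map(mask$grid, array(as.integer(occ), mask$grid$shape)))
}

#' Matching configuration
#'
#' @param lambda weight of the occupancy-similarity term; default 1.0.
#' @param search_radius_mm candidate radius defining `L_i` (mm).
#' @param gaussian_sigma_mm scale of the window Gaussian (mm).
#' @param neighborhood_radius_vox half-width of the cubic comparison window
#'   (voxels).
#' @param window_mode `"offset"` compares occupancy at corresponding
#'   offsets about the two points; `"absolute"` evaluates both rasters in
#'   the window of the reference point only (comparison mode).
#' @return A `match_config` object.
#' @export
match_config <- function(lambda = 1.0, search_radius_mm = 15,
                         gaussian_sigma_mm = 3, neighborhood_radius_vox = 3,
                         window_mode = c("offset", "absolute")) {
  window_mode <- match.arg(window_mode)
  vals <- c(lambda = lambda, search_radius_mm = search_radius_mm,
            gaussian_sigma_mm = gaussian_sigma_mm,
            neighborhood_radius_vox = neighborhood_radius_vox)
  if (any(vals <= 0))
    stop("match_config: all numeric parameters must be positive",
         call. = FALSE)
  structure(list(lambda = lambda, search_radius_mm = search_radius_mm,
                 gaussian_sigma_mm = gaussian_sigma_mm,
                 neighborhood_radius_vox = as.integer(neighborhood_radius_vox),
                 window_mode = window_mode),
            class = "match_config")
}

#' Centroid alignment of a moving structure
#'
#' Rigidly translates the moving structure so its point centroid coincides
#' with the reference centroid; the shift is returned and later removed
#' from the matched displacements.
#'
#' @param moving,reference [structure_surface()] objects.
#' @return `list(translated = shifted n x 3 points, shift = length-3 mm)`.
#' @export
center_translate <- function(moving, reference) {
  stopifnot(inherits(moving, "structure_surface"),
            inherits(reference, "structure_surface"))
  shift <- colMeans(reference$points) - colMeans(moving$points)
  list(translated = sweep(moving$points, 2, shift, "+"), shift = shift)
}

# binary occupancy raster of a point cloud: 1 where a voxel contains >= 1
# contour point
contour_occupancy <- function(points, grid) {
  occ <- array(0L, grid$shape)
  idx <- voxel_of(points, grid)
  keep <- idx[, 1] >= 1L & idx[, 1] <= grid$shape[1] &
          idx[, 2] >= 1L & idx[, 2] <= grid$shape[2] &
          idx[, 3] >= 1L & idx[, 3] <= grid$shape[3]
  occ[idx[keep, , drop = FALSE]] <- 1L
  occ
}

# cubic window offsets and separable Gaussian weights
match_window <- function(grid, cfg) {
  w <- cfg$neighborhood_radius_vox
  off <- as.matrix(expand.grid(dx = -w:w, dy = -w:w, dz = -w:w))
  d2 <- sweep(off, 2, grid$spacing, "*")^2
  g <- exp(-rowSums(d2) / (2 * cfg$gaussian_sigma_mm^2))
  list(offsets = off, weights = g)
}

voxel_of <- function(points, grid) {
  # half-up rounding: round() would send exact half-voxel offsets to the
  # even sublattice and collapse rasters of half-voxel-shifted clouds
  idx <- matrix(0L, nrow(points), 3)
  for (ax in 1:3)
    idx[, ax] <- as.integer(floor((points[, ax] - grid$origin[ax]) /
                                    grid$spacing[ax] + 0.5)) + 1L
  idx
}

# occupancy lookup with zero outside the grid
occ_at <- function(occ, idx) {
  sh <- dim(occ)
  ok <- idx[, 1] >= 1L & idx[, 1] <= sh[1] &
        idx[, 2] >= 1L & idx[, 2] <= sh[2] &
        idx[, 3] >= 1L & idx[, 3] <= sh[3]
  v <- numeric(nrow(idx))
  v[ok] <- occ[idx[ok, , drop = FALSE]]
  v
}

#' Local occupancy similarity of two contour points
#'
#' Direct evaluation of the Gaussian-weighted occupancy mismatch
#' `N(r, m) = sum_k g_k | I_R(k_r) - I_M(k_m) |` over a cubic voxel window,
#' with `k_r`, `k_m` the corresponding offsets about `r` and `m`
#' (`window_mode = "offset"`), or the absolute window of `r` applied to
#' both rasters (`"absolute"`). Occupancy outside the grid counts as 0.
#' `N = 0` when the two local rasters agree; it equals the full Gaussian
#' window mass when they disagree everywhere.
#'
#' @param r,m length-3 points (mm) on the reference grid.
#' @param ref_occ,mov_occ binary occupancy arrays (see internals of
#'   [match_contour()]), reference and translated-moving contours.
#' @param grid the reference [grid3d()].
#' @param cfg a [match_config()].
#' @return The non-negative similarity value (0 = identical neighbourhoods).
#' @export
local_similarity <- function(r, m, ref_occ, mov_occ, grid, cfg) {
  win <- match_window(grid, cfg)
  vr <- voxel_of(matrix(r, 1), grid)
  vm <- voxel_of(matrix(m, 1), grid)
  ir <- occ_at(ref_occ, sweep(win$offsets, 2, vr, "+"))
  im <- if (cfg$window_mode == "offset")
    occ_at(mov_occ, sweep(win$offsets, 2, vm, "+"))
  else
    occ_at(mov_occ, sweep(win$offsets, 2, vr, "+"))
  sum(win$weights * abs(ir - im))
}

# separable truncated-Gaussian window sum of a binary raster:
# out[v] = sum_k g_k occ[v + k] (zero outside), same window as match_window
window_sum <- function(occ, grid, cfg) {
  w <- cfg$neighborhood_radius_vox
  a <- array(as.numeric(occ), dim(occ))
  for (ax in 1:3) {
    g1 <- exp(-(((-w:w) * grid$spacing[ax])^2) / (2 * cfg$gaussian_sigma_mm^2))
    n <- dim(a)[ax]
    out <- array(0, dim(a))
    for (s in -w:w) {
      src <- max(1, 1 + s):min(n, n + s)
      dst <- src - s
      wgt <- g1[s + w + 1]
      if (ax == 1L) out[dst, , ] <- out[dst, , ] + wgt * a[src, , ]
      else if (ax == 2L) out[, dst, ] <- out[, dst, ] + wgt * a[, src, ]
      else out[, , dst] <- out[, , dst] + wgt * a[, , src]
    }
    a <- out
  }
  a
}

#' Match a moving contour to a reference contour
#'
#' Centroid-aligns the moving structure, rasterizes both contours on the
#' reference grid, and selects for each reference point the candidate
#' translated moving point within `search_radius_mm` minimizing
#' `G + lambda * N` (ties broken by smaller `G`, then lower candidate
#' index). The recorded displacement of a matched point is
#' `original moving point - reference point`, i.e. the centroid shift is
#' restored, so displacements map reference anatomy onto moving anatomy.
#' Reference points with no candidate in range are flagged unmatched and
#' excluded (a `message()` reports the count).
#'
#' @param reference,moving [structure_surface()] objects on the same grid.
#' @param cfg a [match_config()].
#' @return A `point_correspondences` object: data.frame with one row per
#'   matched reference point (`ref` index, `cand` moving-point index,
#'   displacement `ux,uy,uz` mm, `G`, `N`, `score`), plus attributes
#'   `shift`, `unmatched` (indices), `objective` (the summed minimum).
#' @export
match_contour <- function(reference, moving, cfg = match_config()) {
  stopifnot(inherits(reference, "structure_surface"),
            inherits(moving, "structure_surface"))
  grid <- reference$grid
  ct <- center_translate(moving, reference)
  mt <- ct$translated
  R <- reference$points
  ref_occ <- contour_occupancy(R, grid)
  mov_occ <- contour_occupancy(mt, grid)
  GR <- window_sum(ref_occ, grid, cfg)   # Gaussian occupancy mass around r
  GM <- window_sum(mov_occ, grid, cfg)
  # product decomposition of the mismatch for binary rasters:
  # N(r,m) = GR(vr) + GM(vm) - 2 * sum_k g_k IR(vr+k) IM(vm+k)
  win <- match_window(grid, cfg)
  vr_all <- voxel_of(R, grid)
  vm_all <- voxel_of(mt, grid)
  nR <- nrow(R)
  rows <- vector("list", nR)
  unmatched <- integer(0)
  r2 <- cfg$search_radius_mm^2
  chunk <- 256L
  mt2 <- rowSums(mt^2)
  # per unique reference voxel: window offsets hitting the reference raster
  vr_key <- paste(vr_all[, 1], vr_all[, 2], vr_all[, 3])
  kr_cache <- new.env(parent = emptyenv())
  for (i0 in seq(1L, nR, by = chunk)) {
    ii <- i0:min(nR, i0 + chunk - 1L)
    d2 <- outer(rowSums(R[ii, , drop = FALSE]^2), mt2, "+") -
      2 * R[ii, , drop = FALSE] %*% t(mt)
    for (q in seq_along(ii)) {
      i <- ii[q]
      cand <- which(d2[q, ] <= r2 + 1e-9)
      if (!length(cand)) { unmatched <- c(unmatched, i); next }
      G <- sqrt(pmax(d2[q, cand], 0))
      if (cfg$window_mode == "offset") {
        key <- vr_key[i]
        kr <- get0(key, envir = kr_cache)
        if (is.null(kr)) {
          hit <- occ_at(ref_occ, sweep(win$offsets, 2, vr_all[i, ], "+")) > 0
          kr <- list(off = win$offsets[hit, , drop = FALSE],
                     w = win$weights[hit])
          assign(key, kr, envir = kr_cache)
        }
        vm <- vm_all[cand, , drop = FALSE]
        C <- numeric(length(cand))
        if (nrow(kr$off))
          for (k in seq_len(nrow(kr$off)))
            C <- C + kr$w[k] * occ_at(mov_occ, sweep(vm, 2, kr$off[k, ], "+"))
        N <- GR[vr_all[i, , drop = FALSE]] + GM[vm] - 2 * C
      } else {
        # absolute window of r applied to both rasters: independent of m up
        # to the raster values, evaluated directly
        N <- vapply(cand, function(j)
          local_similarity(R[i, ], mt[j, ], ref_occ, mov_occ, grid, cfg),
          numeric(1))
      }
      score <- G + cfg$lambda * N
      best <- which(score == min(score))
      if (length(best) > 1L) best <- best[order(G[best], best)][1] else best <- best[1]
      j <- cand[best]
      disp <- (mt[j, ] - ct$shift) - R[i, ]
      rows[[i]] <- c(i, j, disp, G[best], N[best], score[best])
    }
  }
  if (length(unmatched) == nR)
    stop("match_contour: no reference point found any candidate within ",
         cfg$search_radius_mm, " mm; increase search_radius_mm", call. = FALSE)
  if (length(unmatched))
    message("match_contour ('", reference$name, "'): ", length(unmatched),
            " of ", nR, " reference points unmatched")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- as.data.frame(out)
  names(out) <- c("ref", "cand", "ux", "uy", "uz", "G", "N", "score")
  structure(out, shift = ct$shift, unmatched = unmatched,
            objective = sum(out$score),
            class = c("point_correspondences", "data.frame"))
}

#' @export
print.point_correspondences <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf(paste0(
    "point_correspondences: %d matched (%d unmatched), |u| mean %.2f mm, ",
    "objective %.4g\n"),
    nrow(x), length(attr(x, "unmatched")), mean(mag), attr(x, "objective")))
  invisible(x)
}

#' Contour-matching FEM registration (CM-FEM)
#'
#' Matches each reference structure to its moving counterpart, pools the
#' per-point displacements, prescribes them at the nearest mesh nodes
#' (averaging when several points share a node), solves the linear-elastic
#' model, and interpolates the nodal solution to a displacement field on
#' the reference grid (zero outside the mesh).
#'
#' @param ref_structures,mov_structures lists of [structure_surface()]
#'   objects, paired by `name`.
#' @param labels reference [label_map()] used for material assignment.
#' @param materials a [material_table()].
#' @param cfg a [match_config()].
#' @param mesh_divisions cubes per axis for the correction mesh.
#' @param margin_mm mesh margin around the pooled contour points.
#' @param details if `TRUE`, attach the correspondences, mesh and solution
#'   as attribute `details`.
#' @return A [displacement_field()] on `labels$grid`.
#' @export
register_cmfem <- function(ref_structures, mov_structures, labels, materials,
                           cfg = match_config(), mesh_divisions = 12,
                           margin_mm = 10, details = FALSE) {
  if (inherits(ref_structures, "structure_surface"))
    ref_structures <- list(ref_structures)
  if (inherits(mov_structures, "structure_surface"))
    mov_structures <- list(mov_structures)
  mov_names <- vapply(mov_structures, `[[`, character(1), "name")
  pts <- list(); disp <- list(); corr <- list()
  for (rs in ref_structures) {
    j <- match(rs$name, mov_names)
    if (is.na(j))
      stop("register_cmfem: no moving structure named '", rs$name, "'",
           call. = FALSE)
    cm <- match_contour(rs, mov_structures[[j]], cfg)
    corr[[rs$name]] <- cm
    pts[[rs$name]] <- rs$points[cm$ref, , drop = FALSE]
    disp[[rs$name]] <- as.matrix(cm[, c("ux", "uy", "uz")])
  }
  P <- do.call(rbind, pts)
  U <- do.call(rbind, disp)
  grid <- labels$grid
  vox <- voxel_of(P, grid)
  mesh <- scale_mesh_to_cover(mesh_divisions, vox, grid, margin_mm)
  nid <- nearest_node(mesh, P)
  agg <- rowsum(U, nid)
  cnt <- rowsum(rep(1, length(nid)), nid)
  driving <- as.integer(rownames(agg))
  dd <- agg / as.vector(cnt)
  mats <- assign_materials(mesh, labels, materials)
  sol <- assemble_and_solve(fem_problem(mesh, mats, driving, dd))
  field <- interpolate_solution_to_field(mesh, sol, grid)
  if (details)
    attr(field, "details") <- list(correspondences = corr, mesh = mesh,
                                   driving_nodes = driving,
                                   driving_displacements = dd, solution = sol)
  field
}
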