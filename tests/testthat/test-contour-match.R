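# Contour matching: centroid alignment, occupancy similarity, matching
# objective, CM-FEM recovery of known transforms.

# toy structure: voxelized sphere plus its surface cloud
toy_structure <- function(grid, center, radius, name = "s") {
  surface_from_mask(sphere_label_map(grid, center, radius), 1L, name)
}

test_that("center_translate aligns centroids exactly", {
  g <- grid3d(c(24, 24, 24), 2)
  a <- toy_structure(g, c(20, 20, 20), 10)
  expect_equal(center_translate(a, a)$shift, c(0, 0, 0))
  b <- toy_structure(g, c(25, 20, 20), 10)
  ct <- center_translate(b, a)
  # moving = reference + 5 mm in x (up to voxelization) -> shift ~ -5
  expect_equal(ct$shift, c(-5, 0, 0), tolerance = 0.15)
  expect_equal(colMeans(ct$translated), colMeans(a$points), tolerance = 1e-12)
})

test_that("local similarity is zero for identical rasters and maximal for
           disjoint ones, and matches a double-loop oracle", {
  g <- grid3d(c(16, 16, 16), 2)
  cfg <- match_config(gaussian_sigma_mm = 3, neighborhood_radius_vox = 2)
  set.seed(15)
  occ_r <- array(as.integer(runif(prod(g$shape)) < 0.15), g$shape)
  occ_m <- array(as.integer(runif(prod(g$shape)) < 0.15), g$shape)
  r <- c(14, 14, 14); m <- c(16, 12, 14)
  # identical rasters at the same point
  expect_equal(local_similarity(r, r, occ_r, occ_r, g, cfg), 0)
  # all-1 reference window vs all-0 moving window = full Gaussian mass
  ones <- array(1L, g$shape); zeros <- array(0L, g$shape)
  w <- 2
  off <- as.matrix(expand.grid(-w:w, -w:w, -w:w))
  gmass <- sum(exp(-rowSums(sweep(off, 2, g$spacing, "*")^2) / (2 * 3^2)))
  expect_equal(local_similarity(r, m, ones, zeros, g, cfg), gmass)
  # random rasters vs an explicit double loop over the window
  oracle <- 0
  vr <- round((r - g$origin) / g$spacing) + 1
  vm <- round((m - g$origin) / g$spacing) + 1
  for (q in seq_len(nrow(off))) {
    d <- off[q, ]
    gk <- exp(-sum((d * g$spacing)^2) / (2 * 3^2))
    at <- function(occ, v) {
      v <- v + d
      if (any(v < 1) || any(v > g$shape)) 0 else occ[v[1], v[2], v[3]]
    }
    oracle <- oracle + gk * abs(at(occ_r, vr) - at(occ_m, vm))
  }
  expect_equal(local_similarity(r, m, occ_r, occ_m, g, cfg), oracle,
               tolerance = 1e-12)
})

test_that("matching identical structures is the exact zero minimum", {
  g <- grid3d(c(24, 24, 24), 2)
  s <- toy_structure(g, c(22, 22, 22), 11)
  cm <- match_contour(s, s, match_config(lambda = 1.0))
  expect_equal(nrow(cm), nrow(s$points))
  expect_equal(max(abs(as.matrix(cm[, c("ux", "uy", "uz")]))), 0)
  expect_equal(attr(cm, "objective"), 0)
})

test_that("the matching objective agrees with a brute-force scorer", {
  g <- grid3d(c(20, 20, 20), 2)
  ref <- toy_structure(g, c(19, 19, 19), 9, "toy")
  mov <- toy_structure(g, c(22, 17, 20), 9, "toy")
  cfg <- match_config(search_radius_mm = 8, neighborhood_radius_vox = 2)
  cm <- match_contour(ref, mov, cfg)
  ct <- center_translate(mov, ref)
  occ_r <- dvfmend:::contour_occupancy(ref$points, g)
  occ_m <- dvfmend:::contour_occupancy(ct$translated, g)
  # check a subsample of reference points against exhaustive scoring
  idx <- seq(1, nrow(cm), by = 17)
  for (q in idx) {
    i <- cm$ref[q]
    r <- ref$points[i, ]
    sc <- vapply(seq_len(nrow(ct$translated)), function(j) {
      m <- ct$translated[j, ]
      G <- sqrt(sum((m - r)^2))
      if (G > cfg$search_radius_mm) return(Inf)
      G + cfg$lambda * local_similarity(r, m, occ_r, occ_m, g, cfg)
    }, numeric(1))
    expect_equal(min(sc), cm$score[q], tolerance = 1e-9)
    # displacement restores the centroid shift
    jbest <- cm$cand[q]
    expect_equal(as.numeric(cm[q, c("ux", "uy", "uz")]),
                 mov$points[jbest, ] - r, tolerance = 1e-12)
  }
})

test_that("lambda = 0 reduces to nearest-neighbour matching in range", {
  g <- grid3d(c(20, 20, 20), 2)
  ref <- toy_structure(g, c(19, 19, 19), 9)
  mov <- toy_structure(g, c(21, 18, 19), 9)
  cm <- match_contour(ref, mov, match_config(lambda = 1e-12,
                                             search_radius_mm = 8))
  ct <- center_translate(mov, ref)
  for (q in seq(1, nrow(cm), by = 23)) {
    i <- cm$ref[q]
    d <- sqrt(rowSums(sweep(ct$translated, 2, ref$points[i, ])^2))
    expect_equal(cm$G[q], min(d), tolerance = 1e-9)
  }
})

test_that("matching is invariant to a common rigid translation", {
  g <- grid3d(c(26, 26, 26), 2)
  ref <- toy_structure(g, c(20, 20, 20), 9)
  mov <- toy_structure(g, c(23, 19, 21), 9)
  cm1 <- match_contour(ref, mov, match_config(search_radius_mm = 8))
  shift <- c(4, 4, -2)
  ref2 <- structure_surface("s", sweep(ref$points, 2, shift, "+"),
                            sphere_label_map(g, c(20, 20, 20) + shift, 9))
  mov2 <- structure_surface("s", sweep(mov$points, 2, shift, "+"),
                            sphere_label_map(g, c(23, 19, 21) + shift, 9))
  cm2 <- match_contour(ref2, mov2, match_config(search_radius_mm = 8))
  # voxelization ties on the symmetric sphere may resolve differently in
  # floating point, so compare the optimum rather than per-point winners
  expect_equal(nrow(cm1), nrow(cm2))
  expect_equal(cm1$score, cm2$score, tolerance = 1e-9)
  expect_equal(attr(cm1, "objective"), attr(cm2, "objective"),
               tolerance = 1e-9)
  expect_equal(colMeans(as.matrix(cm1[, c("ux", "uy", "uz")])),
               colMeans(as.matrix(cm2[, c("ux", "uy", "uz")])),
               tolerance = 1e-6)
})

test_that("unmatched points are flagged; empty candidate sets are an error", {
  g <- grid3d(c(30, 30, 30), 2)
  ref <- toy_structure(g, c(20, 20, 20), 8)
  # off-lattice centre: after centroid alignment the two voxelized clouds
  # do not coincide, so a vanishing radius leaves every point unmatched
  mov <- toy_structure(g, c(44.7, 44.3, 43.9), 8)
  expect_error(suppressMessages(
    match_contour(ref, mov, match_config(search_radius_mm = 1e-6))),
    "search_radius")
})

test_that("CM-FEM recovers a known translation on the phantom", {
  ph <- small_phantom(seed = 21)
  t0 <- c(5.5, -3.8, 2.6)
  def <- deform_phantom(ph, "translation", list(t = t0))
  fld <- suppressMessages(
    register_cmfem(ph$structures, def$structures, ph$labels, ph$materials,
                   match_config(), mesh_divisions = 10, margin_mm = 8))
  g <- ph$labels$grid
  for (l in ph$spec$organs$label) {
    sel <- ph$labels$labels == l
    for (comp in 1:3) {
      err <- fld$u[, , , comp][sel] - t0[comp]
      expect_lt(mean(abs(err)), 1)   # interior recovery well below a voxel
    }
  }
  rep <- evaluate_registration(fld, ph$structures, def$structures)
  expect_true(all(rep$dsc >= 0.9))
  # identical structures give a near-zero field inside the mesh
  fld0 <- suppressMessages(
    register_cmfem(ph$structures, ph$structures, ph$labels, ph$materials,
                   match_config(), mesh_divisions = 8, margin_mm = 8))
  expect_lt(max(abs(fld0$u)), 1e-8)
})
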