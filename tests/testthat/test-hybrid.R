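# Hybrid FEM correction: boundary extraction, constraint building, interior
# replacement with boundary fidelity.

test_that("boundary voxels follow the 6-neighbour definition", {
  g <- grid3d(c(9, 9, 9), 2)
  lab <- array(0L, g$shape)
  lab[4:6, 4:6, 4:6] <- 1L            # 3x3x3 solid cube
  lm <- label_map(g, lab)
  vox <- extract_boundary_voxels(lm, 1L)
  expect_equal(nrow(vox), 26)          # all but the centre
  expect_false(any(vox[, 1] == 5 & vox[, 2] == 5 & vox[, 3] == 5))
  # single-voxel structure is its own boundary
  lab2 <- array(0L, g$shape); lab2[5, 5, 5] <- 2L
  expect_equal(extract_boundary_voxels(label_map(g, lab2), 2L),
               matrix(c(5L, 5L, 5L), 1))
  expect_error(extract_boundary_voxels(lm, 7L), "not present")
  # solid sphere vs brute-force 6-neighbour scan
  gs <- grid3d(c(20, 20, 20), 1)
  sph <- sphere_label_map(gs, c(9.5, 9.5, 9.5), 8)
  vox <- extract_boundary_voxels(sph, 1L)
  brute <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (sph$labels[i, j, k] != 1L) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    edge <- any(nb < 1 | nb > 20)
    diff <- edge || any(apply(nb, 1, function(v)
      sph$labels[v[1], v[2], v[3]] != 1L))
    if (diff) brute <- brute + 1L
  }
  expect_equal(nrow(vox), brute)
})

test_that("constraints average the displacements assigned to a node", {
  g <- grid3d(c(10, 10, 10), 2)
  mesh <- build_cubic_tet_mesh(c(2, 2, 2), c(-1, -1, -1), c(19, 19, 19))
  # constant field: every driving node receives that constant
  cf <- affine_test_field(g, matrix(0, 3, 3), b = c(1.5, -2.5, 0.5))
  vox <- rbind(c(3L, 3L, 3L), c(7L, 7L, 7L), c(3L, 7L, 5L))
  cons <- build_constraints(vox, cf, mesh)
  expect_true(all(abs(sweep(cons$node_displacements, 2,
                            c(1.5, -2.5, 0.5))) < 1e-12))
  # two voxels mapping to one node get the mean displacement
  f2 <- zero_field(g)
  f2$u[5, 5, 5, ] <- c(2, 0, 0)        # centre 8,8,8 mm
  f2$u[5, 5, 6, ] <- c(0, 4, 0)        # centre 8,8,10 mm -> same node (9,9,9)
  c2 <- build_constraints(rbind(c(5L, 5L, 5L), c(5L, 5L, 6L)), f2, mesh)
  expect_equal(nrow(c2$node_displacements), 1)
  expect_equal(as.numeric(c2$node_displacements), c(1, 2, 0))
  # random field: node values match a group-by oracle
  set.seed(16)
  fr <- smooth_random_field(g, amplitude = 2, seed = 16)
  voxr <- unique(cbind(sample(10, 40, TRUE), sample(10, 40, TRUE),
                       sample(10, 40, TRUE)))
  cr <- build_constraints(voxr, fr, mesh)
  ctrr <- sweep(sweep(voxr - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  nid <- nearest_node(mesh, ctrr)
  for (q in seq_along(cr$nodes)) {
    sel <- nid == cr$nodes[q]
    oracle <- colMeans(cr$displacements[sel, , drop = FALSE])
    expect_lt(max(abs(cr$node_displacements[q, ] - oracle)), 1e-12)
  }
  # mesh must cover the voxels
  tiny <- build_cubic_tet_mesh(c(1, 1, 1), c(0, 0, 0), c(2, 2, 2))
  expect_error(build_constraints(vox, cf, tiny), "cover")
})

test_that("an affine preliminary field is reproduced by its own correction", {
  ph <- small_phantom(seed = 22)
  A <- matrix(c(0.04, 0.01, 0, -0.01, 0.03, 0.02, 0.01, 0, -0.02), 3, 3)
  pre <- affine_test_field(ph$labels$grid, A, b = c(2, -1, 1))
  post <- suppressMessages(
    correct_field(pre, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 10, margin_mm = 8))
  # node averaging samples the affine field at voxel-mean positions, so
  # recovery is exact up to that quadrature offset
  expect_lt(max(abs(post$u - pre$u)), 0.3)
  # voxels outside the mesh are bit-identical to the preliminary field
  d <- suppressMessages(
    correct_field(pre, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 10, margin_mm = 8, details = TRUE))
  mesh <- attr(d, "details")$mesh
  ctr <- voxel_centers(ph$labels$grid)
  outside <- rowSums(sweep(ctr, 2, mesh$box_min) >= 0 &
                     sweep(ctr, 2, mesh$box_max) <= 0) != 3
  for (comp in 1:3)
    expect_identical(d$u[, , , comp][array(outside, ph$labels$grid$shape)],
                     pre$u[, , , comp][array(outside, ph$labels$grid$shape)])
})

test_that("correction smooths interior noise while preserving boundaries", {
  ph <- small_phantom(seed = 23)
  t0 <- c(4, -3, 2)
  def <- deform_phantom(ph, "translation", list(t = t0))
  cspec <- corruption_spec(n_bumps = 4, amplitude = 0.8, radius_mm = 4,
                           min_depth_vox = 2, seed = 23)
  corrupted <- suppressWarnings(corrupt_field(def$field, ph$labels, cspec))
  corrected <- suppressMessages(
    correct_field(corrupted, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 10, margin_mm = 8))
  jm_pre <- jacobian_determinant_map(corrupted)
  jm_post <- jacobian_determinant_map(corrected)
  for (l in ph$spec$organs$label) {
    roi <- ph$labels$labels == l
    s_pre <- jd_stats(jm_pre, roi)$std_jd
    s_post <- jd_stats(jm_post, roi)$std_jd
    expect_lt(s_post, 0.5 * s_pre)
    # boundary-voxel displacements move by well under half a voxel
    bv <- extract_boundary_voxels(ph$labels, l)
    for (comp in 1:3) {
      idx <- cbind(bv, comp)
      expect_lt(max(abs(corrected$u[idx] - corrupted$u[idx])),
                0.5 * max(ph$labels$grid$spacing))
    }
  }
  # boundary metric fidelity: DSC/MDA nearly unchanged by the correction
  r_pre <- evaluate_registration(corrupted, ph$structures, def$structures)
  r_post <- evaluate_registration(corrected, ph$structures, def$structures)
  expect_true(all(abs(r_pre$dsc - r_post$dsc) < 0.02))
  expect_true(all(abs(r_pre$mda - r_post$mda) < 0.3))
})

test_that("correction is idempotent at the driving nodes", {
  ph <- small_phantom(seed = 24)
  def <- deform_phantom(ph, "translation", list(t = c(3, 2, -2)))
  cspec <- corruption_spec(n_bumps = 3, amplitude = 0.7, radius_mm = 4,
                           min_depth_vox = 2, seed = 24)
  corrupted <- suppressWarnings(corrupt_field(def$field, ph$labels, cspec))
  once <- suppressMessages(
    correct_field(corrupted, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 10, margin_mm = 8))
  twice <- suppressMessages(
    correct_field(once, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 10, margin_mm = 8))
  expect_lt(max(abs(twice$u - once$u)), 1e-6)
})

test_that("per-organ meshes concatenate to the same boundary fidelity", {
  ph <- small_phantom(seed = 25)
  def <- deform_phantom(ph, "translation", list(t = c(4, -2, 3)))
  cspec <- corruption_spec(n_bumps = 3, amplitude = 0.7, radius_mm = 4,
                           min_depth_vox = 2, seed = 25)
  corrupted <- suppressWarnings(corrupt_field(def$field, ph$labels, cspec))
  po <- suppressMessages(
    correct_field(corrupted, ph$labels, ph$spec$organs$label, ph$materials,
                  mesh_divisions = 8, margin_mm = 6, per_organ = TRUE))
  jm <- jacobian_determinant_map(po)
  for (l in ph$spec$organs$label)
    expect_lt(jd_stats(jm, ph$labels$labels == l)$std_jd,
              jd_stats(jacobian_determinant_map(corrupted),
                       ph$labels$labels == l)$std_jd)
})
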