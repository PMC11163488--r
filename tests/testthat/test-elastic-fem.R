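# Linear-elastic FEM: element stiffness, constrained solves, interpolation.

test_that("element stiffness is symmetric with the rigid-body null space", {
  set.seed(8)
  for (rep in 1:20) {
    nodes <- random_tet()
    Ke <- element_stiffness(nodes, E = 1e4, nu = 0.3)
    expect_lt(max(abs(Ke - t(Ke))) / max(abs(Ke)), 1e-12)
    # three rigid translations
    for (ax in 1:3) {
      tmode <- rep(diag(3)[ax, ], 4)
      expect_lt(max(abs(Ke %*% tmode)), 1e-9 * max(abs(Ke)))
    }
    # three linearized rotations about the centroid
    cen <- colMeans(nodes)
    for (ax in 1:3) {
      w <- diag(3)[ax, ]
      rmode <- as.vector(apply(nodes, 1, function(p) {
        d <- p - cen
        c(w[2] * d[3] - w[3] * d[2], w[3] * d[1] - w[1] * d[3],
          w[1] * d[2] - w[2] * d[1])
      }))
      expect_lt(max(abs(Ke %*% rmode)), 1e-9 * max(abs(Ke)))
    }
  }
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(element_stiffness(flat, 1, 0.3), "degenerate")
})

test_that("element stiffness matches the independent Lame-form oracle", {
  # unit reference tetrahedron, E = 1, nu = 0.25
  unit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Ke <- element_stiffness(unit, E = 1, nu = 0.25)
  expect_lt(max(abs(Ke - stiffness_oracle(unit, 1, 0.25))), 1e-12)
  set.seed(9)
  for (rep in 1:10) {
    nodes <- random_tet()
    E <- stats::runif(1, 1e3, 1e6); nu <- stats::runif(1, 0.05, 0.45)
    Ke <- element_stiffness(nodes, E, nu)
    Ko <- stiffness_oracle(nodes, E, nu)
    expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-10)
  }
})

test_that("material assignment follows the element centroid", {
  g <- grid3d(c(20, 20, 20), 2)
  # two-region phantom split by the plane x = 19 mm
  lab <- array(1L, g$shape)
  lab[11:20, , ] <- 2L
  labels <- label_map(g, lab)
  table <- material_table(label = 1:2, name = c("soft_tissue", "bone"),
                          E = c(1e4, 1e6), nu = c(0.45, 0.49))
  mesh <- build_cubic_tet_mesh(c(4, 4, 4), c(2, 2, 2), c(36, 36, 36))
  mats <- assign_materials(mesh, labels, table)
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  # centroid-side oracle: voxel of the centroid decides the label
  side <- round(cen[, 1] / 2) + 1 >= 11
  expect_equal(mats$E, ifelse(side, 1e6, 1e4))
  # uniform map gives uniform materials; lung preset carries (1 kPa, 0.38)
  lung <- label_map(g, array(1L, g$shape))
  ml <- assign_materials(mesh, lung, tissue_presets())
  expect_true(all(ml$E == 1e3) && all(ml$nu == 0.38))
  # centroids outside the labelled grid fall back to soft tissue, reported
  far <- build_cubic_tet_mesh(c(2, 2, 2), c(30, 30, 30), c(70, 70, 70))
  expect_message(mf <- assign_materials(far, labels, table), "soft-tissue")
  expect_gt(attr(mf, "n_fallback"), 0)
})

test_that("constant and affine Dirichlet data pass the patch test", {
  mesh <- build_cubic_tet_mesh(c(4, 4, 4), c(0, 0, 0), c(40, 40, 40))
  surf <- mesh_surface_nodes(mesh)
  # constant translation
  t0 <- c(3, -2, 1)
  pr <- fem_problem(mesh, list(E = 1e4, nu = 0.45), surf,
                    matrix(t0, length(surf), 3, byrow = TRUE))
  sol <- assemble_and_solve(pr)
  expect_lt(max(abs(sweep(sol$displacements, 2, t0))), 1e-8)
  # driving nodes carry their prescription exactly
  expect_identical(sol$displacements[surf, ],
                   matrix(t0, length(surf), 3, byrow = TRUE))
  # affine data reproduced at interior nodes (constant-strain exactness)
  A <- matrix(c(0.06, 0.02, -0.01, 0.01, -0.04, 0.03, 0.02, 0, 0.05), 3, 3)
  pra <- fem_problem(mesh, list(E = 1e4, nu = 0.45), surf,
                     mesh$nodes[surf, ] %*% t(A))
  sola <- assemble_and_solve(pra)
  expect_lt(max(abs(sola$displacements - mesh$nodes %*% t(A))), 1e-8)
  # conjugate-gradient path agrees with the direct solve
  solc <- assemble_and_solve(pra, method = "cg")
  expect_lt(max(abs(solc$displacements - sola$displacements)), 1e-6)
})

test_that("Dirichlet-only solutions depend on E only through its ratios", {
  mesh <- build_cubic_tet_mesh(c(3, 3, 3), c(0, 0, 0), c(30, 30, 30))
  lab <- array(1L, c(15, 15, 15))
  lab[8:15, , ] <- 2L
  labels <- label_map(grid3d(c(15, 15, 15), 2), lab)
  t1 <- material_table(1:2, c("soft_tissue", "bone"), c(1e4, 1e6),
                       c(0.45, 0.49))
  t2 <- material_table(1:2, c("soft_tissue", "bone"), c(1e4, 1e6) * 137,
                       c(0.45, 0.49))
  surf <- mesh_surface_nodes(mesh)
  set.seed(10)
  dd <- matrix(rnorm(length(surf) * 3), ncol = 3)
  s1 <- assemble_and_solve(fem_problem(mesh, assign_materials(mesh, labels, t1),
                                       surf, dd))
  s2 <- assemble_and_solve(fem_problem(mesh, assign_materials(mesh, labels, t2),
                                       surf, dd))
  expect_lt(max(abs(s1$displacements - s2$displacements)), 1e-10)
})

test_that("a two-material bar stretches like springs in series", {
  # nu = 0 keeps the problem exactly one-dimensional; E ratio 10:1
  L <- 40
  mesh <- build_cubic_tet_mesh(c(4, 2, 2), c(0, 0, 0), c(L, 20, 20))
  cen_x <- (mesh$nodes[mesh$tets[, 1], 1] + mesh$nodes[mesh$tets[, 2], 1] +
            mesh$nodes[mesh$tets[, 3], 1] + mesh$nodes[mesh$tets[, 4], 1]) / 4
  mats <- data.frame(E = ifelse(cen_x < L / 2, 1e5, 1e4), nu = 0)
  tol <- 1e-9
  left <- which(abs(mesh$nodes[, 1]) < tol)
  right <- which(abs(mesh$nodes[, 1] - L) < tol)
  delta <- 2
  pr <- fem_problem(mesh, mats, c(left, right),
                    rbind(matrix(0, length(left), 3),
                          cbind(delta, 0, 0)[rep(1, length(right)), ]))
  sol <- assemble_and_solve(pr)
  # series springs: u(L/2) = delta * E2 / (E1 + E2)
  mid <- which(abs(mesh$nodes[, 1] - L / 2) < tol)
  expected <- delta * 1e4 / (1e5 + 1e4)
  expect_lt(max(abs(sol$displacements[mid, 1] - expected)) / expected, 1e-6)
})

test_that("constraint validation and singular systems raise named errors", {
  mesh <- build_cubic_tet_mesh(c(2, 2, 2), c(0, 0, 0), c(20, 20, 20))
  mats <- list(E = 1e4, nu = 0.45)
  expect_error(fem_problem(mesh, mats, c(1, 1, 2), matrix(0, 3, 3)),
               "distinct")
  expect_error(fem_problem(mesh, mats, c(1, 2), matrix(0, 2, 3)), ">= 3")
  # collinear constraints leave a rotation free
  expect_error(fem_problem(mesh, mats, c(1, 2, 3), matrix(0, 3, 3)),
               "collinear")
})

test_that("nodal solutions interpolate exactly and merge with the outside
           field", {
  mesh <- build_cubic_tet_mesh(c(3, 3, 3), c(6, 6, 6), c(30, 30, 30))
  g <- grid3d(c(20, 20, 20), 2)
  A <- matrix(c(0.05, 0.01, 0, -0.02, 0.04, 0.01, 0, 0.02, -0.03), 3, 3)
  b <- c(1, -2, 0.5)
  nodal <- sweep(mesh$nodes %*% t(A), 2, b, "+")
  out_field <- smooth_random_field(g, amplitude = 3, seed = 13)
  fld <- interpolate_solution_to_field(mesh, nodal, g, outside = out_field)
  ctr <- voxel_centers(g)
  inside <- rowSums(sweep(ctr, 2, mesh$box_min) >= 0 &
                    sweep(ctr, 2, mesh$box_max) <= 0) == 3
  expected <- sweep(ctr %*% t(A), 2, b, "+")
  got <- cbind(as.vector(fld$u[, , , 1]), as.vector(fld$u[, , , 2]),
               as.vector(fld$u[, , , 3]))
  expect_lt(max(abs(got[inside, ] - expected[inside, ])), 1e-12)
  # outside voxels are bit-identical to the outside field
  outside_u <- cbind(as.vector(out_field$u[, , , 1]),
                     as.vector(out_field$u[, , , 2]),
                     as.vector(out_field$u[, , , 3]))
  expect_identical(got[!inside, ], outside_u[!inside, ])
  # probe points against an independent locate-then-interpolate oracle
  set.seed(14)
  nodal_r <- matrix(rnorm(nrow(mesh$nodes) * 3), ncol = 3)
  pts <- matrix(runif(60, 7, 29), 20, 3)
  via_lattice <- dvfmend:::lattice_interp(mesh, nodal_r, pts)
  for (i in 1:20) {
    lt <- locate_tet(mesh, pts[i, ])
    oracle <- colSums(lt$bary * nodal_r[mesh$tets[lt$tet, ], ])
    expect_lt(max(abs(via_lattice[i, ] - oracle)), 1e-12)
  }
})

test_that("volume-preserving boundary data keeps the interior JD near 1", {
  # homogeneous near-incompressible sphere, det(I + A) = 1 boundary data
  g <- grid3d(c(24, 24, 24), 2)
  mesh <- build_cubic_tet_mesh(c(8, 8, 8), c(3, 3, 3), c(43, 43, 43))
  A <- diag(c(0.05, -0.03, 1 / (1.05 * 0.97) - 1))
  expect_equal(det(diag(3) + A), 1, tolerance = 1e-12)
  c0 <- c(23, 23, 23); R <- 16
  rad <- sqrt(rowSums(sweep(mesh$nodes, 2, c0)^2))
  shell <- which(abs(rad - R) <= 5)
  pr <- fem_problem(mesh, list(E = 1e4, nu = 0.49), shell,
                    sweep(mesh$nodes[shell, ], 2, c0) %*% t(A))
  fld <- interpolate_solution_to_field(mesh, assemble_and_solve(pr), g)
  jm <- jacobian_determinant_map(fld)
  inside <- array(rowSums(sweep(voxel_centers(g), 2, c0)^2) < (R - 6)^2,
                  g$shape)
  expect_lt(max(abs(jm$values[inside] - 1)), 0.02)
})
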