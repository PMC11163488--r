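# Shared fixtures: everything is generated in code, no files on disk.

# field u(x) = A x + b evaluated at voxel centres
affine_test_field <- function(grid, A, b = c(0, 0, 0)) {
  u <- sweep(voxel_centers(grid) %*% t(A), 2, b, "+")
  displacement_field(grid, array(u, c(grid$shape, 3L)))
}

# smooth pseudo-random field from a few low-frequency sine modes
smooth_random_field <- function(grid, amplitude = 1, seed = 1) {
  set.seed(seed)
  ctr <- voxel_centers(grid)
  L <- (grid$shape - 1) * grid$spacing
  u <- matrix(0, nrow(ctr), 3)
  for (comp in 1:3) for (m in 1:3) {
    k <- stats::runif(3, 0.5, 1.5) * pi / L
    ph <- stats::runif(3, 0, 2 * pi)
    u[, comp] <- u[, comp] + amplitude / 3 *
      sin(ctr[, 1] * k[1] + ph[1]) * sin(ctr[, 2] * k[2] + ph[2]) *
      sin(ctr[, 3] * k[3] + ph[3])
  }
  displacement_field(grid, array(u, c(grid$shape, 3L)))
}

# solid-sphere label map
sphere_label_map <- function(grid, center, radius, label = 1L) {
  ctr <- voxel_centers(grid)
  inside <- rowSums(sweep(ctr, 2, center)^2) <= radius^2
  label_map(grid, array(as.integer(inside) * label, grid$shape))
}

# small two-organ phantom used by several suites (cheaper than the default)
small_phantom <- function(seed = 1) {
  g <- grid3d(c(40, 40, 40), 2)
  organs <- data.frame(label = 2:3, name = c("organ_a", "organ_b"),
                       cx = c(26, 54), cy = c(28, 52), cz = c(40, 40),
                       ax = c(12, 11), ay = c(11, 12), az = c(13, 11),
                       material = "soft_tissue")
  make_phantom(phantom_spec(grid = g, organs = organs, seed = seed))
}
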