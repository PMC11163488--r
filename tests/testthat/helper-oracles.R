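# Independent oracles: deliberately naive per-element implementations used
# to validate the vectorized package code.

# per-voxel finite-difference Jacobian determinant, explicit loops and
# base det()
jacobian_oracle <- function(field) {
  sh <- field$grid$shape
  sp <- field$grid$spacing
  J <- array(NA_real_, sh)
  diff1 <- function(comp, ax, i, j, k) {
    idx <- c(i, j, k)
    n <- sh[ax]
    if (idx[ax] > 1 && idx[ax] < n) {
      lo <- idx; lo[ax] <- lo[ax] - 1
      hi <- idx; hi[ax] <- hi[ax] + 1
      (field$u[hi[1], hi[2], hi[3], comp] -
         field$u[lo[1], lo[2], lo[3], comp]) / (2 * sp[ax])
    } else if (idx[ax] == 1) {
      hi <- idx; hi[ax] <- 2
      (field$u[hi[1], hi[2], hi[3], comp] -
         field$u[idx[1], idx[2], idx[3], comp]) / sp[ax]
    } else {
      lo <- idx; lo[ax] <- n - 1
      (field$u[idx[1], idx[2], idx[3], comp] -
         field$u[lo[1], lo[2], lo[3], comp]) / sp[ax]
    }
  }
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (k in seq_len(sh[3])) {
    F <- diag(3)
    for (comp in 1:3) for (ax in 1:3)
      F[comp, ax] <- F[comp, ax] + diff1(comp, ax, i, j, k)
    J[i, j, k] <- det(F)
  }
  J
}

# constant-strain tetrahedron stiffness from the Lame-form tensor identity
#   K[3(a-1)+i, 3(b-1)+j] =
#     V * (lambda dNa/dxi dNb/dxj + mu dNa/dxj dNb/dxi
#          + delta_ij mu sum_k dNa/dxk dNb/dxk)
# with shape-function gradients obtained by inverting [1 | x y z].
stiffness_oracle <- function(nodes, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- solve(cbind(1, nodes))       # rows 2:4 are the gradients
  grads <- t(C[2:4, ])              # 4 x 3: grad N_a in row a
  V <- abs(det(cbind(1, nodes))) / 6
  K <- matrix(0, 12, 12)
  for (a in 1:4) for (b in 1:4) for (i in 1:3) for (j in 1:3) {
    v <- lam * grads[a, i] * grads[b, j] + mu * grads[a, j] * grads[b, i]
    if (i == j) v <- v + mu * sum(grads[a, ] * grads[b, ])
    K[3 * (a - 1) + i, 3 * (b - 1) + j] <- V * v
  }
  K
}

# random positively oriented tetrahedron
random_tet <- function() {
  repeat {
    nodes <- matrix(stats::runif(12, -10, 10), 4, 3)
    v <- det(nodes[2:4, ] - rep(nodes[1, ], each = 3)) / 6
    if (abs(v) > 5) {
      if (v < 0) nodes <- nodes[c(1, 2, 4, 3), ]
      return(nodes)
    }
  }
}

# exhaustive one-tailed WMW p-value by enumerating group assignments
wmw_enum_oracle <- function(x, y, alternative) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  U <- u_of(seq_len(n1))
  combos <- utils::combn(N, n1)
  Us <- apply(combos, 2, u_of)
  if (alternative == "less") mean(Us <= U) else mean(Us >= U)
}

# counts of triangular faces shared by 1 vs 2 tets
face_share_counts <- function(mesh) {
  faces <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
                 mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  table(table(key))
}
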