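# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Horn's quaternion method for optimal superposition (independent of the
# SVD-based Kabsch route).  Returns the rmsd after the optimal fit.
quaternion_rmsd <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  M <- crossprod(P0, Q0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Dihedral via an independent projection formulation: project the outer
# bonds onto the plane normal to the central bond and take the signed
# angle between the projections.
dihedral_projection <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / sqrt(sum(b2^2))
  v1 <- -b1 + sum(b1 * u) * u   # component of p1->p2 reversed, in-plane
  v2 <- b3 - sum(b3 * u) * u
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cr * u) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# Naive double-loop minimum pairwise distance.
brute_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Naive kernel-sum bias evaluation.
brute_bias <- function(kernels, s) {
  tot <- 0
  for (i in seq_len(nrow(kernels))) {
    e <- (s[1] - kernels$cv1[i])^2 / (2 * kernels$sigma1[i]^2) +
      (s[2] - kernels$cv2[i])^2 / (2 * kernels$sigma2[i]^2)
    tot <- tot + kernels$height[i] * exp(-e)
  }
  tot
}

# Coarse 3-D brute-force pore radius at one z: dense in-plane grid, no
# refinement.
brute_pore_radius <- function(xyz, rv, center0, e1, e2, extent = 3,
                              spacing = 0.05) {
  g <- seq(-extent, extent, by = spacing)
  best <- -Inf
  for (a in g) {
    for (b in g) {
      c_ <- center0 + a * e1 + b * e2
      r <- min(sqrt(rowSums(sweep(xyz, 2, c_)^2)) - rv)
      if (r > best) best <- r
    }
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
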