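test_that("Kabsch superposition recovers exact rigid motions", {
  g <- small_pentamer()
  m <- g$model
  self_fit <- superpose_kabsch(m, m)
  expect_equal(self_fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(self_fit$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(self_fit$rmsd, 0, tolerance = 1e-9)

  R <- random_rotation(3)
  t_ <- c(12, -4, 7)
  moved <- transform_model(m, R, t_)
  fit <- superpose_kabsch(moved, m)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch rmsd matches the quaternion-method oracle on random pairs", {
  set.seed(21)
  mk <- function(xyz) structure_model(tibble::tibble(
    atom_name = "CA", residue_name = "ALA", chain = "A",
    residue_number = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "C"
  ))
  for (rep in 1:5) {
    P <- matrix(rnorm(150, sd = 8), ncol = 3)
    Q <- P %*% t(random_rotation(rep)) + matrix(rnorm(150, sd = 1), ncol = 3)
    fit <- superpose_kabsch(mk(P), mk(Q))
    expect_equal(fit$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-9)
  }
  expect_error(superpose_kabsch(mk(matrix(rnorm(6), 2, 3)),
                                mk(matrix(rnorm(6), 2, 3))), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose_kabsch(mk(line), mk(line + 1)), "collinear")
})

test_that("dihedral matches the planar references and an independent formula", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  set.seed(31)
  for (i in 1:100) {
    p <- lapply(1:4, function(j) rnorm(3, sd = 3))
    ours <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    oracle <- dihedral_projection(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(ours, oracle, tolerance = 1e-9)
    # reversing the point order leaves the signed torsion unchanged
    expect_equal(dihedral_angle(p[[4]], p[[3]], p[[2]], p[[1]]), ours,
                 tolerance = 1e-9)
    # mirror reflection flips the sign
    refl <- function(v) v * c(1, 1, -1)
    if (abs(abs(ours) - 180) > 1e-6) {
      expect_equal(dihedral_angle(refl(p[[1]]), refl(p[[2]]),
                                  refl(p[[3]]), refl(p[[4]])), -ours,
                   tolerance = 1e-9)
    }
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "collinear|coincide")
  expect_error(dihedral_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 1, 0)),
               "collinear")
})

test_that("twist recovers imposed rotations and is rigid-invariant", {
  g <- small_pentamer()
  m0 <- g$model; ann <- g$annotation
  tw0 <- twist_result(m0, ann)
  expect_equal(tw0$twist[1:5], rep(0, 5), tolerance = 1e-6)
  expect_equal(attr(tw0, "beta_mean"), 0, tolerance = 1e-6)

  for (theta in c(-30, -13, 0, 13, 15, 30)) {
    mt <- apply_ecd_twist(m0, ann, theta)
    tw <- vapply(ann$chain, function(ch) twist_angle(mt, ann, ch), numeric(1))
    expect_equal(unname(tw), rep(theta, 5), tolerance = 1e-6)
  }

  m15 <- apply_ecd_twist(m0, ann, 15)
  moved <- transform_model(m15, random_rotation(8), c(30, -12, 4))
  expect_equal(twist_angle(moved, ann, "A"), twist_angle(m15, ann, "A"),
               tolerance = 1e-9)
  expect_error(twist_angle(m0, ann, "Z"), "not annotated")
})

test_that("twist recovery under coordinate noise is unbiased within 3 SE", {
  g <- small_pentamer(n = 24)
  ann <- g$annotation
  for (theta in c(13, 15)) {
    twisted <- apply_ecd_twist(g$model, ann, theta)
    recovered <- vapply(1:20, function(seed) {
      noisy <- perturb_coordinates(twisted, sigma = 0.5, seed = seed)
      mean(vapply(ann$chain, function(ch) twist_angle(noisy, ann, ch),
                  numeric(1)))
    }, numeric(1))
    se <- sd(recovered) / sqrt(length(recovered))
    expect_lt(abs(mean(recovered) - theta), 3 * se + 1e-12)
  }
})

test_that("ECD spread normalization behaves as a ratio metric", {
  g <- small_pentamer()
  m0 <- g$model; ann <- g$annotation
  sp_self <- ecd_spread(m0, ann)
  expect_equal(sp_self$normalized, rep(1, 5))
  for (f in c(0.9, 1.0, 1.1)) {
    sp <- ecd_spread(apply_ecd_bloom(m0, ann, f), ann, reference = m0)
    expect_equal(sp$normalized, rep(f, 5), tolerance = 1e-6)
  }
  moved <- transform_model(m0, random_rotation(4), c(5, 5, 5))
  sp_m <- ecd_spread(moved, ann, reference = m0)
  expect_equal(sp_m$normalized, rep(1, 5), tolerance = 1e-9)

  # all subunit COMs on the axis -> degenerate reference
  collapsed <- m0
  expect_error(ecd_spread(m0, ann, reference = apply_ecd_bloom(m0, ann, 1e-13)),
               "factor|degenerate")
})

test_that("per-frame rmsd matches expectation under isotropic noise", {
  g <- make_ideal_pentamer(residues_per_domain = 104, noise_sigma = 0)
  m <- g$model  # 1040 CA atoms
  expect_equal(rmsd_series(list(m), m)$rmsd, 0, tolerance = 1e-12)
  moved <- transform_model(m, random_rotation(2), c(8, 8, -3))
  expect_lt(rmsd_series(list(moved), m)$rmsd, 1e-9)
  sigma <- 0.5
  noisy <- perturb_coordinates(m, sigma, seed = 6)
  r <- rmsd_series(list(noisy), m)$rmsd
  expect_equal(r, sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
})

test_that("Cartesian PCA separates constructed clusters and flags degeneracy", {
  g <- small_pentamer()
  ann <- g$annotation
  # constructed mode: rigid radial expansion of the ECD
  models <- lapply(1:10, function(i) {
    f <- if (i <= 5) 1.0 else 1.08
    m <- apply_ecd_bloom(g$model, ann, f)
    m <- perturb_coordinates(m, sigma = 0.05, seed = 100 + i)
    attr(m, "identifier") <- paste0("model_", i)
    m
  })
  pca <- cartesian_pca(models, ann, region = "ecd", reference = models[[1]])
  expect_gte(pca$variance_fraction[1], 0.95)
  pc1 <- pca$projections$PC1
  expect_true(max(pc1[1:5]) < min(pc1[6:10]) || min(pc1[1:5]) > max(pc1[6:10]))
  # orthonormal components, variance fractions sum to 1
  G <- unname(pca$components %*% t(pca$components))
  expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-8)

  # identical models -> zero-variance flag
  same <- cartesian_pca(list(g$model, g$model, g$model), ann)
  expect_true(same$zero_variance)
  expect_length(same$variance_fraction, 0)
})

test_that("PCA eigenvalues match a brute-force eigendecomposition", {
  ann <- subunit_annotation("A", "other", ecd_start = 1, ecd_end = 3,
                            tmd_start = 10, tmd_end = 12)
  mk <- function(xyz, id) structure_model(tibble::tibble(
    atom_name = "CA", residue_name = "ALA", chain = "A", residue_number = 1:3,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "C"
  ), identifier = id)
  set.seed(77)
  models <- lapply(1:3, function(i) mk(matrix(rnorm(9, sd = 2), 3, 3),
                                       paste0("m", i)))
  pca <- cartesian_pca(models, ann, region = "ecd")
  X <- t(vapply(models, function(m) as.numeric(t(coords(m))), numeric(9)))
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(pca$sdev^2, ev[seq_along(pca$sdev)], tolerance = 1e-9)

  # order invariance of the spectrum and projections (up to sign)
  pca_rev <- cartesian_pca(rev(models), ann, region = "ecd")
  expect_equal(pca_rev$variance_fraction, pca$variance_fraction,
               tolerance = 1e-9)
  p1 <- pca$projections$PC1[match(pca_rev$projections$model,
                                  pca$projections$model)]
  expect_equal(abs(p1), abs(pca_rev$projections$PC1), tolerance = 1e-8)
})

test_that("tidy/glance summarise a PCA fit", {
  g <- small_pentamer()
  ann <- g$annotation
  models <- lapply(1:4, function(i) {
    m <- perturb_coordinates(g$model, 0.2, seed = i)
    attr(m, "identifier") <- paste0("m", i)
    m
  })
  pca <- cartesian_pca(models, ann)
  td <- tidy(pca)
  expect_named(td, c("component", "sdev", "variance_fraction", "cumulative"))
  expect_equal(nrow(td), 3)  # n_models - 1
  gl <- glance(pca)
  expect_equal(gl$n_models, 4)
  expect_false(gl$zero_variance)
})
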