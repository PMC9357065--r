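test_that("funnel geometry is built from residue COMs with stated defaults", {
  # synthetic binding site: site residues centered at origin, loop C above
  mk_res <- function(chain, resno, center, n = 4) {
    phi <- 2 * pi * (seq_len(n) - 1) / n
    tibble::tibble(
      atom_name = paste0("C", seq_len(n)), residue_name = "ALA",
      chain = chain, residue_number = resno,
      x = center[1] + cos(phi), y = center[2] + sin(phi),
      z = center[3] + 0.3 * cos(2 * phi), element = "C"
    )
  }
  site <- lapply(1:7, function(i) {
    ang <- 2 * pi * i / 7
    mk_res("A", 100 + i, c(3 * cos(ang), 3 * sin(ang), 0))
  })
  loopc <- lapply(1:2, function(i) mk_res("A", 206 + i, c(0, 0, 10)))
  model <- structure_model(dplyr::bind_rows(c(site, loopc)))
  site_keys <- tibble::tibble(chain = "A", residue_number = 101:107)
  loopc_keys <- tibble::tibble(chain = "A", residue_number = 207:208)

  geom <- build_funnel_geometry(model, site_keys, loopc_keys)
  expect_equal(geom$cone_angle, 20)
  expect_equal(geom$r_cyl, 0.1)
  expect_equal(geom$z_cc, 2.5)
  expect_equal(geom$wall_k, 1000)
  # apex at the site COM (nm), axis along +z toward loop C
  expect_equal(geom$apex, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(geom$axis, c(0, 0, 1), tolerance = 1e-9)

  expect_error(build_funnel_geometry(model, tibble::tibble(
    chain = "A", residue_number = 999), loopc_keys), "missing")
})

test_that("funnel axis is unit length for random geometries", {
  set.seed(9)
  for (i in 1:20) {
    g <- funnel_geometry(apex = rnorm(3), axis = rnorm(3))
    expect_equal(sqrt(sum(g$axis^2)), 1, tolerance = 1e-9)
  }
  expect_error(funnel_geometry(c(0, 0, 0), c(0, 0, 0)), "zero-length")
  expect_error(funnel_geometry(c(0, 0, 0), c(0, 0, 1), cone_angle = 95),
               "cone_angle")
})

test_that("allowed radius follows the cone formula and its cylinder limit", {
  g <- funnel_geometry(c(0, 0, 0), c(0, 0, 1))
  expect_equal(funnel_allowed_radius(g, 2.5), 0.1)
  expect_equal(funnel_allowed_radius(g, 1.5), 0.1 + tan(20 * pi / 180),
               tolerance = 1e-12)
  z <- seq(-0.5, 4, by = 0.01)
  R <- funnel_allowed_radius(g, z)
  expect_true(all(diff(R) <= 1e-12))                 # non-increasing
  expect_true(all(R[z >= 2.5] == 0.1))               # constant past z_cc
  # continuity at the transition
  eps <- 1e-9
  expect_equal(funnel_allowed_radius(g, 2.5 - eps),
               funnel_allowed_radius(g, 2.5 + eps), tolerance = 1e-7)
})

test_that("wall energy is half-harmonic, C1 at the boundary, zero inside", {
  g <- funnel_geometry(c(0, 0, 0), c(0, 0, 1), wall_k = 1000)
  on_axis <- funnel_wall_energy(g, c(0, 0, 1))
  expect_equal(on_axis$energy, 0)
  expect_equal(on_axis$gradient, c(0, 0, 0))

  z <- 1.0
  Rz <- funnel_allowed_radius(g, z)
  out <- funnel_wall_energy(g, c(Rz + 0.1, 0, z))
  expect_equal(out$energy, 5.0, tolerance = 1e-9)   # 1000/2 * 0.01

  # gradient matches central differences (1e-6 relative) along a transect
  h <- 1e-7
  for (r in c(Rz + 0.02, Rz + 0.2, Rz - 0.05)) {
    p <- c(r, 0, z)
    ana <- funnel_wall_energy(g, p)$gradient
    num <- vapply(1:3, function(d) {
      dp <- rep(0, 3); dp[d] <- h
      (funnel_wall_energy(g, p + dp)$energy -
         funnel_wall_energy(g, p - dp)$energy) / (2 * h)
    }, numeric(1))
    expect_equal(ana, num, tolerance = 1e-5)
  }
  # C1 across the boundary: energy and gradient -> 0 as r -> R(z)+
  close_out <- funnel_wall_energy(g, c(Rz + 1e-7, 0, z))
  expect_lt(close_out$energy, 1e-10)
  expect_lt(sqrt(sum(close_out$gradient^2)), 1e-3)
})

test_that("restraint spec export is bit-exact and carries the protocol values", {
  g <- funnel_geometry(c(0.1, 0.2, 0.3), c(0, 0, 1))
  b <- bias_state()
  s1 <- export_restraint_spec(g, b)
  s2 <- export_restraint_spec(g, b)
  expect_identical(s1, s2)
  expect_true("cone_angle_deg 20.000000" %in% s1)
  expect_true("z_cc_nm 2.500000" %in% s1)
  expect_true("r_cyl_nm 0.100000" %in% s1)
  expect_true("bias_w0_kj_mol 2.000000" %in% s1)
  expect_true("bias_factor 15.000000" %in% s1)
  path <- tempfile(fileext = ".txt")
  export_restraint_spec(g, b, path = path)
  expect_identical(readLines(path), s1)
})

test_that("bias evaluation matches a naive kernel loop", {
  b <- bias_state(widths = c(0.07, 0.12))
  expect_equal(evaluate_bias(b, c(0.3, -0.2)), 0)
  b <- wt_deposit(b, c(0.5, 0.1))
  expect_equal(evaluate_bias(b, c(0.5, 0.1)), b$kernels$height[1])
  set.seed(13)
  for (i in 1:49) b <- wt_deposit(b, rnorm(2, sd = 0.3))
  for (i in 1:10) {
    s <- rnorm(2, sd = 0.3)
    expect_equal(evaluate_bias(b, s), brute_bias(b$kernels, s),
                 tolerance = 1e-12)
  }
})

test_that("well-tempered deposition follows the damping rule", {
  kT <- 2 / (log(2) * 14)  # makes (gamma-1) kT = 2/ln 2 for gamma = 15
  b <- bias_state(w0 = 2, gamma = 15, kT = kT)
  b <- wt_deposit(b, c(0, 0))
  expect_equal(b$kernels$height[1], 2)  # first deposition anywhere is w0
  # V_bias at the center now equals w0 = (gamma-1) kT ln 2 -> next height w0/2
  b <- wt_deposit(b, c(0, 0))
  expect_equal(b$kernels$height[2], 1, tolerance = 1e-12)

  # standard-metadynamics limit: gamma -> huge keeps heights at w0
  b2 <- bias_state(w0 = 2, gamma = 1e9)
  for (i in 1:100) b2 <- wt_deposit(b2, c(0, 0))
  expect_equal(b2$kernels$height, rep(2, 100), tolerance = 1e-6)

  # heights at a revisited point decay monotonically and never exceed w0
  b3 <- bias_state()
  for (i in 1:30) b3 <- wt_deposit(b3, c(0.2, 0.2))
  expect_true(all(diff(b3$kernels$height) < 0))
  expect_true(all(b3$kernels$height <= 2))
})

test_that("recrossing counter matches hand-built label sequences", {
  traj <- tibble::tibble(cv1 = c(-0.5, -0.5, 0, 0.5, 0, -0.5, 0.5),
                         cv2 = 0)
  ba <- list(cv1 = c(-0.75, -0.25))
  bb <- list(cv1 = c(0.25, 0.75))
  expect_equal(count_recrossings(traj, ba, bb), 3)  # A,B,A,B
  stay <- tibble::tibble(cv1 = rep(-0.5, 10), cv2 = 0)
  expect_equal(count_recrossings(stay, ba, bb), 0)
  expect_error(count_recrossings(traj, ba, list(cv1 = c(-0.5, 0.5))), "overlap")

  # randomized series vs a brute-force label scan
  set.seed(17)
  x <- cumsum(rnorm(500, sd = 0.3))
  traj2 <- tibble::tibble(cv1 = x, cv2 = 0)
  lab <- ifelse(x >= ba$cv1[1] & x <= ba$cv1[2], 1L,
                ifelse(x >= bb$cv1[1] & x <= bb$cv1[2], 2L, 0L))
  cur <- 0L; n <- 0L
  for (l in lab) {
    if (l != 0L) {
      if (cur != 0L && l != cur) n <- n + 1L
      cur <- l
    }
  }
  expect_equal(count_recrossings(traj2, ba, bb), n)
})
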