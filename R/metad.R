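#' Well-tempered metadynamics with overdamped Langevin CV sampling
#'
#' A desk-scale surrogate of funnel metadynamics: the two collective
#' variables are sampled directly by Euler-Maruyama overdamped Langevin
#' dynamics on `U(s) = potential(s) + V_bias(s, t) + wall(s)`, with a
#' well-tempered Gaussian deposited every `pace` steps.  Runs are
#' deterministic for a fixed seed.
#'
#' @param potential A `toy_potential` (see [make_double_well()]).
#' @param bias A `bias_state` carrying `w0`, `gamma`, `widths`, `kT` and
#'   `pace`; returned updated with the deposited kernels.
#' @param n_steps Number of integration steps.
#' @param timestep Integration timestep (time units in which the
#'   effective diffusion constant is `kT / friction`).
#' @param friction Friction coefficient (default 1, i.e. unit mobility).
#' @param s0 Starting CV point (defaults to the first potential minimum).
#' @param grid Internal bias-accumulation grid, a [fes_grid_spec()];
#'   defaults to `[-2, 2]^2` at 0.01 spacing.
#' @param stride Record every `stride`-th step in the trajectory.
#' @param wall Optional 1-D funnel-style wall on CV1:
#'   `list(lower =, upper =, k =)` half-harmonic bounds (kJ/mol/CV^2).
#' @param seed Integer seed.
#' @param deposit If `FALSE`, run plain (unbiased) Langevin dynamics.
#' @param sanity_bound Trajectories beyond `|s| > sanity_bound` raise an
#'   integration error.
#' @return A list with `trajectory` (a `metad_trajectory` tibble: `time`,
#'   `cv1`, `cv2`, `v_bias`) and `bias` (the updated `bias_state`, with
#'   the deposition log in `$kernels`).
#' @export
langevin_metad_sample <- function(potential, bias = bias_state(),
                                  n_steps = 2e6, timestep = 2e-5,
                                  friction = 1, s0 = NULL, grid = NULL,
                                  stride = 10, wall = NULL, seed = 1,
                                  deposit = TRUE, sanity_bound = 25) {
  stopifnot(inherits(potential, "toy_potential"), inherits(bias, "bias_state"))
  if (timestep <= 0 || friction <= 0) abort("timestep and friction must be > 0")
  if (is.null(s0)) {
    s0 <- if (!is.null(potential$minima)) potential$minima[[1]] else c(0, 0)
  }
  if (is.null(grid)) grid <- fes_grid_spec(c(-2, 2), c(-2, 2), n = c(401, 401))
  form <- switch(potential$form, double_well = 0L, harmonic = 1L, free = 2L,
                 abort(paste0("unsupported potential form: ", potential$form)))
  pot_params <- switch(
    potential$form,
    double_well = c(potential$params$barrier, potential$params$separation / 2,
                    potential$params$k2),
    harmonic = c(potential$params$k1, potential$params$k2),
    free = numeric(0)
  )
  use_wall <- !is.null(wall)
  wall_vec <- if (use_wall) c(wall$lower, wall$upper, wall$k) else c(0, 0, 0)
  res <- with_preserved_rng(seed, {
    metad_run_cpp(form, pot_params, bias$w0, bias$gamma, as.integer(bias$pace),
                  bias$widths, bias$kT, friction, timestep,
                  as.integer(n_steps), s0,
                  c(grid$cv1_range, grid$n[1]), c(grid$cv2_range, grid$n[2]),
                  as.integer(stride), use_wall, wall_vec, sanity_bound,
                  deposit)
  })
  traj <- tibble::tibble(time = res$time, cv1 = res$cv1, cv2 = res$cv2,
                         v_bias = res$v_bias)
  class(traj) <- c("metad_trajectory", class(traj))
  bias$kernels <- tibble::tibble(
    time = res$dep_time, cv1 = res$dep_cv1, cv2 = res$dep_cv2,
    height = res$dep_height,
    sigma1 = bias$widths[1], sigma2 = bias$widths[2]
  )
  attr(traj, "timestep") <- timestep
  attr(traj, "seed") <- seed
  out <- list(trajectory = traj, bias = bias)
  class(out) <- "metad_run"
  out
}

#' Summary of a metadynamics run
#'
#' @param x A list as returned by [langevin_metad_sample()].
#' @param basin_a,basin_b Basin definitions for [count_recrossings()].
#' @param ... Unused.
#' @return A one-row tibble: steps recorded, kernels deposited, final and
#'   minimum kernel height, recrossing count (if basins given).
#' @exportS3Method generics::glance
glance.metad_run <- function(x, basin_a = NULL, basin_b = NULL, ...) {
  k <- x$bias$kernels
  out <- tibble::tibble(
    n_samples = nrow(x$trajectory),
    n_kernels = nrow(k),
    final_height = if (nrow(k) > 0) k$height[nrow(k)] else NA_real_,
    min_height = if (nrow(k) > 0) min(k$height) else NA_real_
  )
  if (!is.null(basin_a) && !is.null(basin_b)) {
    out$recrossings <- count_recrossings(x$trajectory, basin_a, basin_b)
  }
  out
}
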