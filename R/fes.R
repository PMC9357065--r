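#' Uniform 2-D CV grid specification
#'
#' @param cv1_range,cv2_range Length-2 ranges in CV units.
#' @param n Number of grid points per axis (length 1 or 2).
#' @return A `fes_grid_spec` list with `cv1_range`, `cv2_range`, `n`.
#' @export
fes_grid_spec <- function(cv1_range, cv2_range, n = c(101, 101)) {
  n <- rep(as.integer(n), length.out = 2)
  if (any(n < 2)) abort("fes_grid_spec: need >= 2 points per axis")
  if (cv1_range[2] <= cv1_range[1] || cv2_range[2] <= cv2_range[1]) {
    abort("fes_grid_spec: ranges must be increasing")
  }
  out <- list(cv1_range = as.numeric(cv1_range),
              cv2_range = as.numeric(cv2_range), n = n)
  class(out) <- "fes_grid_spec"
  out
}

grid_axes <- function(grid) {
  if (inherits(grid, "fes_grid_spec")) {
    list(cv1 = seq(grid$cv1_range[1], grid$cv1_range[2], length.out = grid$n[1]),
         cv2 = seq(grid$cv2_range[1], grid$cv2_range[2], length.out = grid$n[2]))
  } else {
    list(cv1 = grid$cv1, cv2 = grid$cv2)
  }
}

new_fes_grid <- function(df, axes, estimator) {
  class(df) <- c("fes_grid", class(df))
  attr(df, "cv1_axis") <- axes$cv1
  attr(df, "cv2_axis") <- axes$cv2
  attr(df, "estimator") <- estimator
  df
}

#' Free-energy surface from the final well-tempered bias
#'
#' Under well-tempering the converged bias is proportional to the free
#' energy: `F(s) = -gamma/(gamma - 1) V_bias(s)`, shifted so the grid
#' minimum is zero.
#'
#' @param bias A `bias_state` with at least one kernel.
#' @param grid A [fes_grid_spec()].
#' @return A `fes_grid` tibble with columns `cv1`, `cv2`, `free_energy`
#'   (kJ/mol, min 0).
#' @export
fes_from_final_bias <- function(bias, grid) {
  k <- bias$kernels
  if (nrow(k) == 0) abort("fes_from_final_bias: no kernels deposited")
  axes <- grid_axes(grid)
  pts <- tidyr::expand_grid(cv2 = axes$cv2, cv1 = axes$cv1)[, c("cv1", "cv2")]
  v <- bias_sum_cpp(pts$cv1, pts$cv2, k$cv1, k$cv2, k$height, k$sigma1,
                    k$sigma2)
  f <- -bias$gamma / (bias$gamma - 1) * v
  df <- tibble::tibble(cv1 = pts$cv1, cv2 = pts$cv2,
                       free_energy = f - min(f))
  new_fes_grid(df, axes, "final_bias")
}

#' Free-energy surface by time-dependent reweighting
#'
#' Recovers the unbiased free-energy surface from the biased trajectory:
#' each sample carries weight `exp((V_bias(s_t, t) - c(t)) / kT)`, where
#' `c(t)` is the running bias offset computed from the accumulating bias
#' via the well-tempered relation between bias and free energy.  The
#' weighted 2-D histogram gives `F = -kT log(density)`, shifted to
#' minimum zero.
#'
#' @param traj A `metad_trajectory` (must carry per-sample `v_bias`).
#' @param bias The `bias_state` holding the deposition log of the same
#'   run.
#' @param grid Output [fes_grid_spec()].
#' @param kT Thermal energy (defaults to the bias state's).
#' @param offset_every Recompute `c(t)` every this many kernel
#'   depositions (linear interpolation in between).
#' @return A `fes_grid` tibble (`cv1`, `cv2` are cell centers,
#'   `free_energy` in kJ/mol with min 0; empty cells are `Inf`).
#' @export
reweight_fes <- function(traj, bias, grid, kT = bias$kT, offset_every = 20) {
  if (nrow(traj) == 0) abort("reweight_fes: empty trajectory")
  k <- bias$kernels
  gamma <- bias$gamma
  axes <- grid_axes(grid)
  if (nrow(k) == 0) {
    c_t <- rep(0, nrow(traj))
  } else {
    # c(t) checkpoints on the accumulating bias, evaluated on a coarse grid
    off_ax <- list(cv1 = seq(min(axes$cv1), max(axes$cv1), length.out = 61),
                   cv2 = seq(min(axes$cv2), max(axes$cv2), length.out = 61))
    pts1 <- rep(off_ax$cv1, times = 61)
    pts2 <- rep(off_ax$cv2, each = 61)
    ck_idx <- unique(c(seq(offset_every, nrow(k), by = offset_every), nrow(k)))
    v_grid <- matrix(0, length(pts1), length(ck_idx))
    prev <- 0
    for (m in seq_along(ck_idx)) {
      rows <- (prev + 1):ck_idx[m]
      v_new <- bias_sum_cpp(pts1, pts2, k$cv1[rows], k$cv2[rows],
                            k$height[rows], k$sigma1[rows], k$sigma2[rows])
      v_grid[, m] <- (if (m == 1) 0 else v_grid[, m - 1]) + v_new
      prev <- ck_idx[m]
    }
    lse <- function(x) {
      mx <- max(x)
      mx + log(sum(exp(x - mx)))
    }
    beta <- 1 / kT
    c_ck <- vapply(seq_along(ck_idx), function(m) {
      v <- v_grid[, m]
      kT * (lse(beta * gamma / (gamma - 1) * v) -
              lse(beta / (gamma - 1) * v))
    }, numeric(1))
    ck_time <- k$time[ck_idx]
    c_t <- stats::approx(x = c(0, ck_time), y = c(0, c_ck), xout = traj$time,
                         rule = 2)$y
  }
  log_w <- (traj$v_bias - c_t) / kT
  log_w <- log_w - max(log_w)
  w <- exp(log_w)

  # weighted 2-D histogram over the output grid cells
  br1 <- cell_breaks(axes$cv1)
  br2 <- cell_breaks(axes$cv2)
  i1 <- findInterval(traj$cv1, br1, rightmost.closed = TRUE)
  i2 <- findInterval(traj$cv2, br2, rightmost.closed = TRUE)
  ok <- i1 >= 1 & i1 <= length(axes$cv1) & i2 >= 1 & i2 <= length(axes$cv2)
  h <- matrix(0, length(axes$cv1), length(axes$cv2))
  acc <- tapply(w[ok], list(factor(i1[ok], levels = seq_along(axes$cv1)),
                            factor(i2[ok], levels = seq_along(axes$cv2))),
                sum)
  acc[is.na(acc)] <- 0
  h[] <- acc
  f <- -kT * log(h)
  f <- f - min(f[is.finite(f)])
  df <- tibble::tibble(
    cv1 = rep(axes$cv1, times = length(axes$cv2)),
    cv2 = rep(axes$cv2, each = length(axes$cv1)),
    free_energy = as.numeric(f)
  )
  new_fes_grid(df, axes, "reweight")
}

cell_breaks <- function(axis) {
  d <- diff(axis[1:2])
  c(axis - d / 2, axis[length(axis)] + d / 2)
}

#' Free energy of a CV region
#'
#' `-kT log` of the summed Boltzmann weight of the finite FES cells in a
#' rectangular CV region — the basin free energy used for basin
#' comparisons.
#'
#' @param fes A `fes_grid`.
#' @param cv1,cv2 Length-2 ranges (default: whole axis).
#' @param kT Thermal energy in kJ/mol.
#' @return Scalar free energy in kJ/mol.
#' @export
fes_region_energy <- function(fes, cv1 = NULL, cv2 = NULL, kT = 2.494) {
  keep <- rep(TRUE, nrow(fes))
  if (!is.null(cv1)) keep <- keep & fes$cv1 >= cv1[1] & fes$cv1 <= cv1[2]
  if (!is.null(cv2)) keep <- keep & fes$cv2 >= cv2[1] & fes$cv2 <= cv2[2]
  f <- fes$free_energy[keep]
  f <- f[is.finite(f)]
  if (length(f) == 0) return(Inf)
  fmin <- min(f)
  fmin - kT * log(sum(exp(-(f - fmin) / kT)))
}

#' Minimum free energy along CV1 (profile over CV2)
#'
#' @param fes A `fes_grid`.
#' @return Tibble `cv1`, `free_energy` with the minimum over CV2 per CV1
#'   column (the 1-D profile used for barrier measurements).
#' @export
fes_profile_cv1 <- function(fes) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fes), .data$cv1),
    free_energy = min(.data$free_energy[is.finite(.data$free_energy)],
                      Inf),
    .groups = "drop"
  )
  df
}

#' @rdname fes_from_final_bias
#' @param object A `fes_grid`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fes_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$free_energy[!is.finite(df$free_energy)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$cv1, .data$cv2,
                                   fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)", na.value = "grey90") +
    ggplot2::labs(x = "CV1", y = "CV2",
                  title = paste0("Free-energy surface (",
                                 attr(object, "estimator"), ")")) +
    ggplot2::theme_minimal()
}

#' Export a FES grid or trajectory
#'
#' CSV has one row per grid cell (`cv1`, `cv2`, `free_energy`) or sample
#' (`time`, `cv1`, `cv2`, `v_bias`); JSON additionally carries the axis
#' metadata.
#'
#' @param fes A `fes_grid`.
#' @param path Output path (`.csv` or `.json` decides the format).
#' @return `path`, invisibly.
#' @export
export_fes <- function(fes, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      estimator = attr(fes, "estimator"),
      cv1_axis = attr(fes, "cv1_axis"),
      cv2_axis = attr(fes, "cv2_axis"),
      free_energy = fes$free_energy
    ), path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(tibble::as_tibble(fes), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_fes
#' @param traj A `metad_trajectory`.
#' @export
export_trajectory <- function(traj, path) {
  utils::write.csv(tibble::as_tibble(traj), path, row.names = FALSE)
  invisible(path)
}
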