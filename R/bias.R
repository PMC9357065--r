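#' Well-tempered bias state
#'
#' Holds the deposited Gaussian kernels of a two-dimensional
#' well-tempered metadynamics run together with the bias parameters: the
#' initial Gaussian height `w0`, the bias factor `gamma`, the kernel
#' widths, the thermal energy `kT` and the deposition `pace`.
#'
#' @param w0 Initial Gaussian height in kJ/mol (default 2).
#' @param gamma Bias factor, > 1 (default 15).
#' @param widths Per-CV Gaussian sigma, length 2 (CV units; default
#'   0.05).
#' @param kT Thermal energy in kJ/mol (default 2.494, i.e. 300 K).
#' @param pace Integration steps between depositions.
#' @return A `bias_state` object with an empty kernel table (tibble with
#'   columns `time`, `cv1`, `cv2`, `height`, `sigma1`, `sigma2`).
#' @export
bias_state <- function(w0 = 2, gamma = 15, widths = c(0.05, 0.05),
                       kT = 2.494, pace = 500) {
  if (gamma <= 1) abort("bias_state: gamma must be > 1")
  if (w0 <= 0 || any(widths <= 0) || kT <= 0) {
    abort("bias_state: w0, widths and kT must be > 0")
  }
  widths <- rep(widths, length.out = 2)
  out <- list(
    kernels = tibble::tibble(time = numeric(0), cv1 = numeric(0),
                             cv2 = numeric(0), height = numeric(0),
                             sigma1 = numeric(0), sigma2 = numeric(0)),
    w0 = w0, gamma = gamma, widths = widths, kT = kT, pace = pace
  )
  class(out) <- "bias_state"
  out
}

#' @export
print.bias_state <- function(x, ...) {
  cat("<bias_state> ", nrow(x$kernels), " kernels, w0 = ", x$w0,
      " kJ/mol, gamma = ", x$gamma, ", sigma = (",
      paste(x$widths, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate the metadynamics bias at CV points
#'
#' Sum over deposited kernels of
#' `height * exp(-sum_d (s_d - center_d)^2 / (2 sigma_d^2))`.
#'
#' @param bias A `bias_state`.
#' @param s A length-2 CV vector, or an n x 2 matrix of CV points.
#' @param kernels Optional row subset of kernels to include (used for
#'   time-resolved evaluation).
#' @return Bias in kJ/mol (scalar or length-n vector).
#' @export
evaluate_bias <- function(bias, s, kernels = NULL) {
  kt <- bias$kernels
  if (!is.null(kernels)) kt <- kt[kernels, , drop = FALSE]
  if (is.null(dim(s))) s <- matrix(s, ncol = 2)
  if (nrow(kt) == 0) return(rep(0, nrow(s)))
  # n_points x n_kernels exponent matrix, built per CV dimension
  e1 <- outer(s[, 1], kt$cv1, "-")^2 / matrix(2 * kt$sigma1^2, nrow(s),
                                              nrow(kt), byrow = TRUE)
  e2 <- outer(s[, 2], kt$cv2, "-")^2 / matrix(2 * kt$sigma2^2, nrow(s),
                                              nrow(kt), byrow = TRUE)
  as.numeric(exp(-(e1 + e2)) %*% kt$height)
}

#' Deposit a well-tempered Gaussian
#'
#' Appends a kernel at `s` with height
#' `w = w0 exp(-V_bias(s, t) / ((gamma - 1) kT))` — the well-tempered
#' damping rule, under which the first kernel anywhere has height exactly
#' `w0` and heights at a revisited point decay monotonically.
#'
#' @param bias A `bias_state`.
#' @param s Length-2 CV vector.
#' @param time Deposition time (recorded in the kernel log).
#' @return The updated `bias_state`.
#' @export
wt_deposit <- function(bias, s, time = NA_real_) {
  v <- evaluate_bias(bias, s)
  h <- bias$w0 * exp(-v / ((bias$gamma - 1) * bias$kT))
  bias$kernels <- dplyr::bind_rows(bias$kernels, tibble::tibble(
    time = time, cv1 = s[1], cv2 = s[2], height = h,
    sigma1 = bias$widths[1], sigma2 = bias$widths[2]
  ))
  bias
}

#' Count recrossings between two CV basins
#'
#' Labels each trajectory sample by basin (frames outside both basins
#' keep the previous label) and counts label changes.
#'
#' @param traj A `metad_trajectory` (or any data frame with `cv1`,
#'   `cv2`).
#' @param basin_a,basin_b Lists with `cv1` (length-2 range) and optional
#'   `cv2` range defining disjoint basin regions.
#' @return Integer number of transitions.
#' @export
count_recrossings <- function(traj, basin_a, basin_b) {
  in_basin <- function(b) {
    ok <- traj$cv1 >= b$cv1[1] & traj$cv1 <= b$cv1[2]
    if (!is.null(b$cv2)) ok <- ok & traj$cv2 >= b$cv2[1] & traj$cv2 <= b$cv2[2]
    ok
  }
  a <- in_basin(basin_a)
  b <- in_basin(basin_b)
  if (any(a & b)) abort("count_recrossings: basin regions overlap")
  lab <- ifelse(a, 1L, ifelse(b, 2L, 0L))
  lab <- vctrs_fill_locf(lab)
  lab <- lab[lab != 0L]
  if (length(lab) < 2) return(0L)
  sum(diff(lab) != 0L)
}

# last-observation-carried-forward for integer labels (0 = unset)
vctrs_fill_locf <- function(x) {
  set <- x != 0L
  idx <- cummax(ifelse(set, seq_along(x), 0L))
  out <- ifelse(idx > 0L, x[pmax(idx, 1L)], 0L)
  out
}
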