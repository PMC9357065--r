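#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' atoms of `mobile` and `reference` matched by key (chain, residue
#' number, insertion code, atom name) within the given selection.
#'
#' @param mobile,reference `structure_model` tibbles.
#' @param chains,residues,atom_names,heavy_only Selection criteria applied
#'   to both models before matching (see [select_atoms()]); defaults to
#'   all Calpha atoms.
#' @return A `superposition` list: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (post-fit, Angstrom), `n_atoms`,
#'   and `apply(model)` transforming any model into the reference frame.
#' @export
superpose_kabsch <- function(mobile, reference, chains = NULL,
                             residues = NULL, atom_names = "CA",
                             heavy_only = FALSE) {
  m_sel <- select_atoms(mobile, chains, residues, atom_names, heavy_only = heavy_only)
  r_sel <- select_atoms(reference, chains, residues, atom_names, heavy_only = heavy_only)
  mk <- match_key(m_sel)
  rk <- match_key(r_sel)
  common <- intersect(mk, rk)
  if (length(common) < 3) {
    abort(paste0("superpose_kabsch: need >= 3 matched atom pairs, got ",
                 length(common)))
  }
  P <- coords(m_sel)[match(common, mk), , drop = FALSE]  # mobile
  Q <- coords(r_sel)[match(common, rk), , drop = FALSE]  # reference
  pc <- unname(colMeans(P))
  qc <- unname(colMeans(Q))
  P0 <- sweep(P, 2, pc)
  Q0 <- sweep(Q, 2, qc)
  if (collinear(P0)) {
    abort("superpose_kabsch: matched atoms are collinear")
  }
  H <- crossprod(P0, Q0)  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- qc - as.numeric(R %*% pc)
  P0 <- unname(P0); Q0 <- unname(Q0)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  out <- list(
    rotation = R, translation = translation, rmsd = rmsd,
    n_atoms = length(common),
    apply = function(model) transform_model(model, R, translation)
  )
  class(out) <- "superposition"
  out
}

collinear <- function(centered, tol = 1e-8) {
  s <- svd(centered, nu = 0, nv = 0)$d
  sum(s > tol * max(s, tol)) < 2
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> ", x$n_atoms, " atom pairs, rmsd = ",
      format(x$rmsd, digits = 6), " A\n", sep = "")
  invisible(x)
}

#' Per-frame best-fit RMSD against a reference
#'
#' Each frame is superposed on the reference over the stated selection and
#' the post-fit RMSD over that same selection is reported, mirroring the
#' usual trajectory-RMSD convention.
#'
#' @param frames List of `structure_model` frames.
#' @param reference A `structure_model`.
#' @inheritParams superpose_kabsch
#' @return A tibble with `frame` (index), `model` (identifier) and
#'   `rmsd` (Angstrom).
#' @export
rmsd_series <- function(frames, reference, chains = NULL, residues = NULL,
                        atom_names = "CA", heavy_only = FALSE) {
  vals <- vapply(frames, function(fr) {
    superpose_kabsch(fr, reference, chains, residues, atom_names,
                     heavy_only = heavy_only)$rmsd
  }, numeric(1))
  tibble::tibble(
    frame = seq_along(frames),
    model = vapply(frames, model_id, character(1)),
    rmsd = vals
  )
}
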