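#' Two-dimensional double-well model potential
#'
#' A symmetric quartic double well along CV1 with a harmonic channel along
#' CV2, standing in for the bound/unbound basins of a ligand-binding
#' collective-variable space:
#' \deqn{U(x, y) = B\,\big[(x/a)^2 - 1\big]^2 + \tfrac{k_y}{2} y^2}
#' with \eqn{a = \mathrm{separation}/2}.  The minima sit at
#' \eqn{(\pm a, 0)} with \eqn{U = 0}; the saddle at the origin has
#' \eqn{U = B}, so the barrier equals `barrier` exactly.  For a single
#' overdamped particle the analytic free-energy surface equals the
#' potential (up to an additive constant).
#'
#' @param barrier Barrier height B in kJ/mol (> 0).
#' @param separation Distance between the two minima along CV1 (CV units).
#' @param k2 Harmonic stiffness along CV2 in kJ/mol per CV unit squared.
#' @return A `toy_potential` object: a list with the functional `form`,
#'   `params`, scalar evaluators `fn(s)` / `grad(s)` taking a length-2 CV
#'   vector, and `minima` / `saddle` locations.
#' @export
make_double_well <- function(barrier, separation = 1, k2 = 100) {
  if (barrier <= 0) abort("barrier must be > 0")
  if (separation <= 0) abort("separation must be > 0")
  a <- separation / 2
  pot <- list(
    form = "double_well",
    params = list(barrier = barrier, separation = separation, k2 = k2),
    fn = function(s) {
      barrier * ((s[1] / a)^2 - 1)^2 + 0.5 * k2 * s[2]^2
    },
    grad = function(s) {
      c(4 * barrier * s[1] * ((s[1] / a)^2 - 1) / a^2, k2 * s[2])
    },
    minima = list(c(-a, 0), c(a, 0)),
    saddle = c(0, 0)
  )
  class(pot) <- "toy_potential"
  pot
}

#' Evaluate a toy potential on a CV grid
#'
#' @param potential A `toy_potential`.
#' @param grid A [fes_grid_spec()] (or a list with `cv1`, `cv2` axis vectors).
#' @return A tibble with columns `cv1`, `cv2`, `energy` (kJ/mol), minimum
#'   shifted to zero — the analytic free-energy surface of a single
#'   particle on the potential.
#' @export
potential_fes <- function(potential, grid) {
  axes <- grid_axes(grid)
  df <- tidyr::expand_grid(cv1 = axes$cv1, cv2 = axes$cv2)
  df$energy <- vapply(seq_len(nrow(df)),
                      function(i) potential$fn(c(df$cv1[i], df$cv2[i])),
                      numeric(1))
  df$energy <- df$energy - min(df$energy)
  df
}

#' Build a toy pore lining with a known radius profile
#'
#' Stacks rings of pseudo-atoms around the +z axis; the ring radius at
#' height z follows `radius_profile(z)`, so the accessible pore radius is
#' analytically `radius_profile(z) - vdw(element)`.
#'
#' @param radius_profile Function mapping z (Angstrom) to the lining
#'   radius (Angstrom, > 0).
#' @param z_range Length-2 vector, z extent in Angstrom.
#' @param spacing Ring spacing along z (Angstrom).
#' @param atoms_per_ring Atoms per ring (>= 6).
#' @param element Element symbol of the lining atoms (sets their van der
#'   Waals radius; default carbon, 1.70 Angstrom).
#' @return A `structure_model` of HETATM lining atoms (chain "P").
#' @export
make_toy_pore <- function(radius_profile, z_range = c(0, 30), spacing = 1,
                          atoms_per_ring = 16, element = "C") {
  if (z_range[2] <= z_range[1]) abort("z_range must be increasing")
  if (atoms_per_ring < 6) abort("atoms_per_ring must be >= 6")
  zs <- seq(z_range[1], z_range[2], by = spacing)
  phi <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
  parts <- lapply(seq_along(zs), function(i) {
    r <- radius_profile(zs[i])
    if (!is.finite(r) || r <= 0) abort("radius_profile must be positive and finite")
    # stagger alternate rings so gaps between rings do not line up
    off <- if (i %% 2 == 0) pi / atoms_per_ring else 0
    tibble::tibble(
      atom_name = "C1",
      residue_name = "POR",
      chain = "P",
      residue_number = i,
      x = r * cos(phi + off), y = r * sin(phi + off), z = zs[i],
      element = element,
      record_type = "HETATM"
    )
  })
  atoms <- dplyr::bind_rows(parts)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$atom_name <- paste0("C", sequence(rle(atoms$residue_number)$lengths))
  structure_model(atoms, identifier = "toy_pore")
}

#' Build a frame ensemble with prescribed ligand contact fractions
#'
#' Generates `n_frames` single-ligand frames in which each listed residue
#' sits within the contact cutoff of the ligand in exactly
#' `round(fraction * n_frames)` frames (chosen at random per residue,
#' deterministic per seed) and far outside it otherwise.
#'
#' @param n_frames Number of frames.
#' @param contact_plan Named numeric vector or two-column data frame
#'   (`residue_number`, `fraction`) of target contact fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @param contact_distance Ligand-residue distance used for in-contact
#'   frames (Angstrom; default 3, inside the standard 4 Angstrom cutoff).
#' @return A list of `structure_model` frames; each has a one-atom ligand
#'   (chain "L", residue LIG) and one CA atom per planned residue
#'   (chain "A").
#' @export
make_contact_ensemble <- function(n_frames, contact_plan, seed = 1,
                                  contact_distance = 3) {
  if (is.data.frame(contact_plan)) {
    resno <- contact_plan$residue_number
    frac <- contact_plan$fraction
  } else {
    resno <- as.integer(names(contact_plan))
    frac <- as.numeric(contact_plan)
  }
  if (any(frac < 0 | frac > 1)) abort("contact fractions must be in [0, 1]")
  n_res <- length(resno)
  contact_frames <- with_preserved_rng(seed, {
    lapply(seq_len(n_res), function(j) {
      k <- round(frac[j] * n_frames)
      if (k == 0) integer(0) else sort(sample.int(n_frames, k))
    })
  })
  lapply(seq_len(n_frames), function(f) {
    # residues fan out in distinct directions from the ligand at the origin
    ang <- 2 * pi * (seq_len(n_res) - 1) / max(n_res, 1)
    in_contact <- vapply(contact_frames, function(v) f %in% v, logical(1))
    d <- ifelse(in_contact, contact_distance, 60 + 10 * seq_len(n_res))
    atoms <- tibble::tibble(
      atom_name = c("C1", rep("CA", n_res)),
      residue_name = c("LIG", rep("ALA", n_res)),
      chain = c("L", rep("A", n_res)),
      residue_number = c(1L, resno),
      x = c(0, d * cos(ang)), y = c(0, d * sin(ang)), z = 0,
      element = "C",
      record_type = c("HETATM", rep("ATOM", n_res))
    )
    structure_model(atoms, identifier = sprintf("frame_%04d", f))
  })
}
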