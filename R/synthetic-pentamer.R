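#' Generate an ideal pseudo-pentamer
#'
#' Builds a five-chain Calpha model emulating the two-ring (ECD over TMD)
#' architecture of a pentameric ligand-gated ion channel.  Chains A-E are
#' placed counterclockwise (viewed from the extracellular side, +z) at 72
#' degree spacing; each chain carries one blob of Calpha atoms centered on
#' the ECD ring and one on the TMD ring.  Blob atoms are arranged
#' symmetrically so that, noise-free, each subunit domain COM lies exactly
#' at its ring position.  Chains A and C are annotated beta2, B and D
#' alpha1, E gamma2.
#'
#' @param residues_per_domain Calpha atoms per domain blob (>= 3).
#' @param ecd_ring_radius,tmd_ring_radius Ring radii in Angstrom (> 0).
#' @param ecd_z_center,tmd_z_center Ring heights in Angstrom (must differ);
#'   the extracellular side is +z, so `ecd_z_center > tmd_z_center`
#'   in the usual orientation.
#' @param blob_radius Radius of each domain blob in Angstrom.
#' @param noise_sigma Isotropic Gaussian coordinate noise in Angstrom.
#' @param seed Integer seed controlling the noise; generation is a pure
#'   function of the arguments.
#' @return A list with elements `model` (a [structure_model()]) and
#'   `annotation` (a [subunit_annotation()]).
#' @export
make_ideal_pentamer <- function(residues_per_domain = 24,
                                ecd_ring_radius = 25,
                                tmd_ring_radius = 18,
                                ecd_z_center = 50,
                                tmd_z_center = 10,
                                blob_radius = 3,
                                noise_sigma = 0,
                                seed = 1) {
  if (residues_per_domain < 3) abort("residues_per_domain must be >= 3")
  if (ecd_ring_radius <= 0 || tmd_ring_radius <= 0) abort("ring radii must be > 0")
  if (ecd_z_center == tmd_z_center) abort("ECD and TMD ring heights must differ")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")

  annotation <- default_pentamer_annotation()
  n <- residues_per_domain
  if (n > 208) abort("residues_per_domain must fit the ECD range (<= 208)")

  # Blob: atoms on a ring of radius blob_radius with a cos(2*phi) height
  # modulation; both patterns sum to zero so the blob COM is its center.
  phi <- 2 * pi * (seq_len(n) - 1) / n
  local_xyz <- cbind(blob_radius * cos(phi),
                     blob_radius * sin(phi),
                     0.5 * blob_radius * cos(2 * phi))

  chains <- annotation$chain
  theta <- 2 * pi * (seq_along(chains) - 1) / 5  # counterclockwise from +x
  parts <- list()
  for (i in seq_along(chains)) {
    rot <- rotation_about_z(theta[i])
    for (dom in c("ecd", "tmd")) {
      ring_r <- if (dom == "ecd") ecd_ring_radius else tmd_ring_radius
      zc <- if (dom == "ecd") ecd_z_center else tmd_z_center
      start <- if (dom == "ecd") annotation$ecd_start[i] else annotation$tmd_start[i]
      center <- c(ring_r * cos(theta[i]), ring_r * sin(theta[i]), zc)
      xyz <- sweep(local_xyz %*% t(rot), 2, center, "+")
      parts[[length(parts) + 1]] <- tibble::tibble(
        atom_name = "CA",
        residue_name = "ALA",
        chain = chains[i],
        residue_number = seq(start, length.out = n),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = "C"
      )
    }
  }
  atoms <- dplyr::bind_rows(parts)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, identifier = paste0("pentamer_seed", seed))
  if (noise_sigma > 0) {
    model <- perturb_coordinates(model, sigma = noise_sigma, seed = seed)
  }
  list(model = model, annotation = annotation)
}

rotation_about_z <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, -s_, 0,
           s_,  c_, 0,
           0,   0,  1), 3, 3, byrow = TRUE)
}

# Rodrigues rotation about a unit axis.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Pore axis of an annotated model: unit vector from global TMD Calpha COM
# toward global ECD Calpha COM (i.e. pointing extracellular), plus anchors.
pore_axis <- function(model, annotation) {
  ecd_com <- center_of_mass(domain_ca(model, annotation, "ecd"))
  tmd_com <- center_of_mass(domain_ca(model, annotation, "tmd"))
  d <- ecd_com - tmd_com
  len <- sqrt(sum(d^2))
  if (len < 1e-9) abort("degenerate pore axis: ECD and TMD COMs coincide")
  list(ecd_com = ecd_com, tmd_com = tmd_com, axis = d / len)
}

#' Impose a rigid ECD twist on an annotated model
#'
#' Rotates every ECD atom of every annotated chain rigidly by `angle`
#' about the axis through the global ECD and TMD Calpha COMs.  The
#' rotation follows the right-hand rule about the axis pointing from the
#' TMD COM toward the ECD COM (counterclockwise viewed from the
#' extracellular side), so the measured four-point twist dihedral of every
#' chain changes by exactly `+angle` in the noise-free case.  TMD atoms
#' are untouched.
#'
#' @param model A `structure_model` of a pentamer.
#' @param annotation Its [subunit_annotation()].
#' @param angle Rotation in degrees.
#' @return The twisted `structure_model`.
#' @export
apply_ecd_twist <- function(model, annotation, angle) {
  annotation <- check_annotation(annotation, model)
  ax <- pore_axis(model, annotation)
  R <- rotation_about_axis(ax$axis, angle)
  xyz <- coords(model)
  idx <- ecd_atom_index(model, annotation)
  centered <- sweep(xyz[idx, , drop = FALSE], 2, ax$ecd_com, "-")
  xyz[idx, ] <- sweep(centered %*% t(R), 2, ax$ecd_com, "+")
  new_structure_model(set_coords(model, xyz), model_id(model))
}

ecd_atom_index <- function(model, annotation) {
  idx <- rep(FALSE, nrow(model))
  for (i in seq_len(nrow(annotation))) {
    idx <- idx | (model$chain == annotation$chain[i] &
                    model$residue_number >= annotation$ecd_start[i] &
                    model$residue_number <= annotation$ecd_end[i])
  }
  which(idx)
}

#' Impose a radial ECD expansion ("bloom") on an annotated model
#'
#' Translates each chain's ECD atoms radially (perpendicular to the pore
#' axis) so that the chain's ECD COM offset from the global ECD COM is
#' scaled by `factor`.  For ring-symmetric models whose subunit COM
#' offsets are perpendicular to the axis this scales the ECD spread
#' exactly by `factor`.
#'
#' @inheritParams apply_ecd_twist
#' @param factor Radial scale factor (> 0); 1 leaves the model unchanged.
#' @return The bloomed `structure_model`.
#' @export
apply_ecd_bloom <- function(model, annotation, factor) {
  if (factor <= 0) abort("bloom factor must be > 0")
  annotation <- check_annotation(annotation, model)
  ax <- pore_axis(model, annotation)
  xyz <- coords(model)
  for (i in seq_len(nrow(annotation))) {
    ch <- annotation$chain[i]
    sub_com <- center_of_mass(domain_ca(model, annotation, "ecd", chain = ch))
    v <- sub_com - ax$ecd_com
    v_perp <- v - sum(v * ax$axis) * ax$axis
    if (sqrt(sum(v_perp^2)) < 1e-12) {
      abort(paste0("degenerate geometry: chain ", ch,
                   " ECD COM lies on the pore axis"))
    }
    shift <- (factor - 1) * v_perp
    idx <- model$chain == ch &
      model$residue_number >= annotation$ecd_start[i] &
      model$residue_number <= annotation$ecd_end[i]
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, "+")
  }
  new_structure_model(set_coords(model, xyz), model_id(model))
}

#' Add isotropic Gaussian coordinate noise
#'
#' Displaces every coordinate by i.i.d. Gaussian noise of standard
#' deviation `sigma`; deterministic for a fixed seed and side-effect free
#' (the global RNG state is restored).
#'
#' @param model A `structure_model`.
#' @param sigma Noise standard deviation per Cartesian coordinate (Angstrom).
#' @param seed Integer seed.
#' @return The perturbed `structure_model`.
#' @export
perturb_coordinates <- function(model, sigma, seed = 1) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(model)
  noise <- with_preserved_rng(seed, {
    matrix(rnorm(3 * nrow(model), sd = sigma), ncol = 3)
  })
  new_structure_model(set_coords(model, coords(model) + noise), model_id(model))
}

# Evaluate expr under set.seed(seed) and restore the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
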