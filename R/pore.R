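#' Pore-radius profile by in-plane sphere fitting
#'
#' A simplified sphere-fitting profiler in the spirit of HOLE: at each
#' height z along a user-supplied axis, the accessible pore radius is the
#' largest sphere radius centered in the plane at z that touches no atom,
#' i.e. `max over in-plane centers c of min over atoms i of
#' (|c - x_i| - vdw_i)`.  The center search starts on the axis with a
#' coarse in-plane grid and is refined by Nelder-Mead.  Heights where the
#' optimum exceeds `search_cap` (or where no atoms are near the plane)
#' are reported at the cap and flagged.
#'
#' @param model A `structure_model` (heavy atoms are used).
#' @param anchor Point on the pore axis (Angstrom).
#' @param direction Axis direction (need not be unit length).
#' @param z_range Length-2 vector: profile extent along the axis,
#'   relative to `anchor` (Angstrom).
#' @param step Grid step along the axis (Angstrom).
#' @param search_extent Half-width of the in-plane coarse search
#'   (Angstrom).
#' @param coarse_step In-plane coarse-grid spacing (Angstrom).
#' @param search_cap Radius cap (Angstrom); larger optima are truncated
#'   and flagged.
#' @param vdw Named vector of van der Waals radii per element; defaults
#'   to the built-in table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
#'   P 1.80 Angstrom).
#' @return A `pore_profile` tibble with columns `z` (Angstrom, along the
#'   axis relative to `anchor`), `radius` (Angstrom), `capped` (logical);
#'   the constriction (minimum over non-capped rows) is stored in the
#'   `"constriction"` attribute as `c(z, radius)`.
#' @export
pore_radius_profile <- function(model, anchor, direction = c(0, 0, 1),
                                z_range, step = 0.5,
                                search_extent = 3, coarse_step = 0.25,
                                search_cap = 10, vdw = NULL) {
  atoms <- select_atoms(model, heavy_only = TRUE)
  if (nrow(atoms) == 0) abort("pore_radius_profile: no heavy atoms")
  if (is.null(vdw)) vdw <- .vdw_radii
  rv <- vdw[toupper(atoms$element)]
  if (any(is.na(rv))) {
    abort(paste0("pore_radius_profile: no vdW radius for element(s): ",
                 paste(unique(atoms$element[is.na(rv)]), collapse = ", ")))
  }
  u <- direction / sqrt(sum(direction^2))
  # in-plane orthonormal basis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(u, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  xyz <- coords(atoms)
  vdw_max <- max(rv)
  zs <- seq(z_range[1], z_range[2], by = step)
  radius_at <- function(center, sub_xyz, sub_rv) {
    d <- sqrt(rowSums(sweep(sub_xyz, 2, center)^2)) - sub_rv
    min(d)
  }
  res <- lapply(zs, function(z) {
    c0 <- anchor + z * u
    near <- sqrt(rowSums(sweep(xyz, 2, c0)^2)) <= 2 * search_cap + vdw_max
    if (!any(near)) {
      return(c(radius = search_cap, capped = 1))
    }
    sub_xyz <- xyz[near, , drop = FALSE]
    sub_rv <- rv[near]
    # coarse in-plane grid
    g <- seq(-search_extent, search_extent, by = coarse_step)
    best <- c(0, 0)
    best_r <- radius_at(c0, sub_xyz, sub_rv)
    for (a in g) {
      for (b in g) {
        r <- radius_at(c0 + a * e1 + b * e2, sub_xyz, sub_rv)
        if (r > best_r) {
          best_r <- r
          best <- c(a, b)
        }
      }
    }
    opt <- stats::optim(
      best,
      function(p) -radius_at(c0 + p[1] * e1 + p[2] * e2, sub_xyz, sub_rv),
      method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 400)
    )
    r <- -opt$value
    if (r >= search_cap) c(radius = search_cap, capped = 1)
    else c(radius = max(r, 0), capped = 0)
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(z = zs, radius = res[, "radius"],
                        capped = res[, "capped"] > 0)
  ok <- !out$capped
  constriction <- if (any(ok)) {
    i <- which(ok)[which.min(out$radius[ok])]
    c(z = out$z[i], radius = out$radius[i])
  } else {
    c(z = NA_real_, radius = NA_real_)
  }
  attr(out, "constriction") <- constriction
  class(out) <- c("pore_profile", class(out))
  out
}

#' Constriction of a pore profile
#' @param profile A `pore_profile` tibble.
#' @return Named vector `c(z, radius)` of the profile minimum.
#' @export
constriction <- function(profile) {
  attr(profile, "constriction", exact = TRUE)
}

#' @rdname pore_radius_profile
#' @param object A `pore_profile`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pore_profile <- function(object, ...) {
  cz <- constriction(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$radius, .data$z)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = data.frame(radius = cz["radius"], z = cz["z"]),
                        color = "red") +
    ggplot2::labs(x = "pore radius (Å)", y = "z (Å)",
                  title = "Pore radius profile") +
    ggplot2::theme_minimal()
}

#' Ligand-residue contact frequencies over a frame ensemble
#'
#' For each residue, the fraction of frames in which its minimum
#' heavy-atom distance to the ligand selection is at or below `cutoff`.
#'
#' @param frames List of `structure_model` frames.
#' @param ligand List of selection criteria identifying the ligand in
#'   every frame, e.g. `list(residue_names = "LIG")` (passed to
#'   [select_atoms()]).
#' @param residues Data frame with columns `chain` and `residue_number`
#'   listing the residues to score.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4).
#' @return A `contact_table` tibble with columns `chain`,
#'   `residue_number`, `n_contact`, `n_frames`, `fraction`; the cutoff is
#'   stored in the `"cutoff"` attribute.
#' @export
contact_frequency <- function(frames, ligand, residues, cutoff = 4) {
  if (length(frames) == 0) abort("contact_frequency: no frames")
  residues <- tibble::as_tibble(residues)
  counts <- matrix(0L, nrow(residues), 1)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    lig <- do.call(select_atoms, c(list(fr), ligand, list(heavy_only = TRUE)))
    if (nrow(lig) == 0) {
      abort(paste0("contact_frequency: ligand selection empty in frame ", f))
    }
    for (j in seq_len(nrow(residues))) {
      res <- select_atoms(fr, chains = residues$chain[j],
                          residues = residues$residue_number[j],
                          heavy_only = TRUE)
      if (nrow(res) == 0) {
        abort(paste0("contact_frequency: residue ", residues$chain[j], ":",
                     residues$residue_number[j], " absent from frame ", f))
      }
      if (min_distance(res, lig) <= cutoff) counts[j] <- counts[j] + 1L
    }
  }
  out <- tibble::tibble(
    chain = residues$chain,
    residue_number = residues$residue_number,
    n_contact = as.integer(counts[, 1]),
    n_frames = length(frames),
    fraction = as.numeric(counts[, 1]) / length(frames)
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", class(out))
  out
}
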