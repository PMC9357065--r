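#' Funnel restraint geometry
#'
#' A cone-plus-cylinder wall confining a ligand's unbound exploration:
#' the conical section (half-angle `cone_angle`) allows sampling of bound
#' poses near the apex, and transitions to a narrow cylinder of radius
#' `r_cyl` at axial distance `z_cc`, which restricts unbound phase-space
#' exploration.  Units at this module's boundary are nm and kJ/mol.
#'
#' @param apex Length-3 vector, funnel apex in nm.
#' @param axis Length-3 vector; normalized internally.
#' @param cone_angle Cone half-angle in degrees (default 20).
#' @param r_cyl Cylinder radius in nm (default 0.1, i.e. 1 Angstrom).
#' @param z_cc Cone-to-cylinder transition distance in nm (default 2.5).
#' @param wall_k Wall stiffness in kJ/mol/nm^2 (default 1000).
#' @return A `funnel_geometry` object.
#' @export
funnel_geometry <- function(apex, axis, cone_angle = 20, r_cyl = 0.1,
                            z_cc = 2.5, wall_k = 1000) {
  len <- sqrt(sum(axis^2))
  if (len < 1e-12) abort("funnel_geometry: zero-length axis")
  if (cone_angle <= 0 || cone_angle >= 90) abort("cone_angle must be in (0, 90)")
  if (r_cyl <= 0 || z_cc <= 0 || wall_k <= 0) {
    abort("r_cyl, z_cc and wall_k must be > 0")
  }
  out <- list(apex = as.numeric(apex), axis = as.numeric(axis) / len,
              cone_angle = cone_angle, r_cyl = r_cyl, z_cc = z_cc,
              wall_k = wall_k)
  class(out) <- "funnel_geometry"
  out
}

#' @export
print.funnel_geometry <- function(x, ...) {
  cat("<funnel_geometry> cone ", x$cone_angle, " deg -> cylinder r = ",
      x$r_cyl, " nm at z = ", x$z_cc, " nm\n", sep = "")
  invisible(x)
}

#' Build a funnel geometry from binding-site and loop C residues
#'
#' The funnel axis is the vector from the mass-weighted heavy-atom COM of
#' the residues surrounding the ligand (the apex) toward the COM of the
#' residues forming the loop C turn.  Structure coordinates are in
#' Angstrom; the returned geometry is in nm.
#'
#' @param model A `structure_model`.
#' @param site_residues Data frame (`chain`, `residue_number`) of the
#'   binding-site residues (the published protocol uses seven).
#' @param loopc_residues Data frame (`chain`, `residue_number`) of the
#'   loop C turn residues (two in the published protocol).
#' @inheritParams funnel_geometry
#' @return A `funnel_geometry` (nm units).
#' @export
build_funnel_geometry <- function(model, site_residues, loopc_residues,
                                  cone_angle = 20, r_cyl = 0.1, z_cc = 2.5,
                                  wall_k = 1000) {
  res_com <- function(res) {
    parts <- lapply(seq_len(nrow(res)), function(i) {
      sel <- select_atoms(model, chains = res$chain[i],
                          residues = res$residue_number[i], heavy_only = TRUE)
      if (nrow(sel) == 0) {
        abort(paste0("build_funnel_geometry: residue ", res$chain[i], ":",
                     res$residue_number[i], " missing or has no heavy atoms"))
      }
      sel
    })
    center_of_mass(dplyr::bind_rows(parts), weighting = "mass")
  }
  apex_ang <- res_com(tibble::as_tibble(site_residues))
  loopc_ang <- res_com(tibble::as_tibble(loopc_residues))
  d <- loopc_ang - apex_ang
  if (sqrt(sum(d^2)) < 1e-9) {
    abort("build_funnel_geometry: site and loop C COMs coincide (degenerate axis)")
  }
  funnel_geometry(apex = apex_ang / 10, axis = d,
                  cone_angle = cone_angle, r_cyl = r_cyl, z_cc = z_cc,
                  wall_k = wall_k)
}

#' Allowed radius of the funnel at axial distance z
#'
#' `R(z) = r_cyl + (z_cc - z) tan(cone_angle)` inside the cone
#' (`z < z_cc`), constant `r_cyl` beyond; behind the apex (`z < 0`) the
#' cone continues linearly.
#'
#' @param geom A `funnel_geometry`.
#' @param z Axial distance(s) from the apex in nm.
#' @return Allowed radius (nm), vectorized over `z`.
#' @export
funnel_allowed_radius <- function(geom, z) {
  tan_a <- tan(geom$cone_angle * pi / 180)
  ifelse(z < geom$z_cc, geom$r_cyl + (geom$z_cc - z) * tan_a, geom$r_cyl)
}

#' Funnel wall energy and gradient at a point
#'
#' Half-harmonic wall: zero inside the allowed radius,
#' `wall_k/2 (r - R(z))^2` outside; C1-continuous across the boundary.
#' A back wall at `z = -0.2` nm (half-harmonic along the axis) prevents
#' escape behind the binding site.
#'
#' @param geom A `funnel_geometry`.
#' @param point Length-3 vector in nm.
#' @return List with `energy` (kJ/mol) and `gradient` (length-3, kJ/mol/nm).
#' @export
funnel_wall_energy <- function(geom, point) {
  v <- as.numeric(point) - geom$apex
  z <- sum(v * geom$axis)
  radial <- v - z * geom$axis
  r <- sqrt(sum(radial^2))
  Rz <- funnel_allowed_radius(geom, z)
  energy <- 0
  grad <- c(0, 0, 0)
  if (r > Rz) {
    excess <- r - Rz
    energy <- 0.5 * geom$wall_k * excess^2
    r_hat <- radial / r
    # dR/dz = -tan(a) inside the cone, 0 in the cylinder
    dRdz <- if (z < geom$z_cc) -tan(geom$cone_angle * pi / 180) else 0
    grad <- geom$wall_k * excess * (r_hat - dRdz * geom$axis)
  }
  z_back <- -0.2
  if (z < z_back) {
    energy <- energy + 0.5 * geom$wall_k * (z - z_back)^2
    grad <- grad + geom$wall_k * (z - z_back) * geom$axis
  }
  list(energy = energy, gradient = grad)
}

#' Export a funnel/CV restraint specification
#'
#' A plain-text block (stable ordering, fixed formatting, bit-exact for
#' fixed inputs) listing the funnel geometry, the two collective
#' variables and the bias parameters, suitable for feeding an external
#' simulation engine.
#'
#' @param geom A `funnel_geometry`.
#' @param bias Optional `bias_state` whose parameters are recorded.
#' @param path Optional file to write; when `NULL` the lines are
#'   returned.
#' @return Character vector of spec lines (invisibly when written).
#' @export
export_restraint_spec <- function(geom, bias = NULL, path = NULL) {
  num <- function(x) sprintf("%.6f", x)
  lines <- c(
    "FUNNEL_RESTRAINT v1",
    paste0("apex_nm ", paste(num(geom$apex), collapse = " ")),
    paste0("axis ", paste(num(geom$axis), collapse = " ")),
    paste0("cone_angle_deg ", num(geom$cone_angle)),
    paste0("z_cc_nm ", num(geom$z_cc)),
    paste0("r_cyl_nm ", num(geom$r_cyl)),
    paste0("wall_k_kj_mol_nm2 ", num(geom$wall_k)),
    "cv1 distance ligand_com site_com nm",
    "cv2 projection loopc_com funnel_axis nm"
  )
  if (!is.null(bias)) {
    lines <- c(
      lines,
      paste0("bias_w0_kj_mol ", num(bias$w0)),
      paste0("bias_factor ", num(bias$gamma)),
      paste0("bias_sigma_nm ", paste(num(bias$widths), collapse = " ")),
      paste0("bias_pace_steps ", format(bias$pace)),
      paste0("kT_kj_mol ", num(bias$kT))
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
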