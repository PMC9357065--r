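#' Signed dihedral of four points
#'
#' IUPAC right-handed torsion of p1-p2-p3-p4: zero for the cis (eclipsed)
#' arrangement, returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors.
#' @return Signed angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12) abort("dihedral_angle: central points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
    abort("dihedral_angle: collinear end triplet")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' ECD-TMD twist dihedral of one subunit
#'
#' The relative rotation of a subunit's extracellular domain against its
#' transmembrane domain, quantified as the signed dihedral of four
#' center-of-mass points: subunit ECD Calpha COM, entire ECD Calpha COM,
#' entire TMD Calpha COM, subunit TMD Calpha COM.
#'
#' @param model A `structure_model`.
#' @param annotation A [subunit_annotation()] covering the chain.
#' @param chain Chain identifier.
#' @return Signed twist in degrees, in (-180, 180].
#' @export
twist_angle <- function(model, annotation, chain) {
  annotation <- check_annotation(annotation, model)
  p1 <- center_of_mass(domain_ca(model, annotation, "ecd", chain = chain))
  p2 <- center_of_mass(domain_ca(model, annotation, "ecd"))
  p3 <- center_of_mass(domain_ca(model, annotation, "tmd"))
  p4 <- center_of_mass(domain_ca(model, annotation, "tmd", chain = chain))
  dihedral_angle(p1, p2, p3, p4)
}

#' Twist dihedrals of all annotated chains plus the beta-subunit mean
#'
#' Computes [twist_angle()] for every annotated chain and the mean over
#' the beta2 chains (the convention used for reporting ECD-TMD twist).
#' The beta mean is a plain arithmetic mean; if the two beta angles
#' differ by more than 180 degrees a circular mean is used instead so the
#' wraparound at +/-180 cannot corrupt the average.
#'
#' @inheritParams twist_angle
#' @return A `twist_result` tibble with columns `chain`, `role` and
#'   `twist` (degrees); the beta mean is in attribute `"beta_mean"` and as
#'   the row with `chain == "beta_mean"`.
#' @export
twist_result <- function(model, annotation) {
  annotation <- check_annotation(annotation, model)
  tw <- vapply(annotation$chain,
               function(ch) twist_angle(model, annotation, ch), numeric(1))
  out <- tibble::tibble(chain = annotation$chain, role = annotation$role,
                        twist = unname(tw))
  beta <- out$twist[out$role == "beta2"]
  if (length(beta) != 2) {
    warn(paste0("twist_result: expected 2 beta2 chains, found ", length(beta)))
  }
  beta_mean <- if (length(beta) > 0 && diff(range(beta)) <= 180) {
    mean(beta)
  } else if (length(beta) > 0) {
    circular_mean_deg(beta)
  } else NA_real_
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(chain = "beta_mean", role = "beta2", twist = beta_mean)
  )
  attr(out, "beta_mean") <- beta_mean
  class(out) <- c("twist_result", class(out))
  out
}

circular_mean_deg <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' ECD spread of a subunit, normalized to a reference structure
#'
#' The raw spread is the distance between the subunit's ECD Calpha COM
#' and the entire structure's ECD Calpha COM; radial expansion of the
#' ECD ("blooming") increases it.  The normalized value divides by the
#' same chain's raw spread in the reference structure, so the reference
#' against itself is exactly 1.  Set `region = "subunit"` to use all of
#' the chain's Calpha atoms (ECD + TMD ranges) for the subunit COM
#' instead of the ECD range only.
#'
#' @param model A `structure_model`.
#' @param annotation A [subunit_annotation()] valid for both models.
#' @param reference Reference `structure_model` (e.g. the agonist-only
#'   structure); defaults to `model` itself.
#' @param chains Chains to report (default: all annotated).
#' @param region `"ecd"` (default) or `"subunit"` for the subunit COM.
#' @return A `spread_result` tibble with columns `chain`, `role`,
#'   `raw` (Angstrom), `raw_reference` (Angstrom) and `normalized`.
#' @export
ecd_spread <- function(model, annotation, reference = model,
                       chains = NULL, region = c("ecd", "subunit")) {
  region <- match.arg(region)
  annotation <- check_annotation(annotation, model)
  check_annotation(annotation, reference)
  if (is.null(chains)) chains <- annotation$chain
  raw_one <- function(m, ch) {
    global <- center_of_mass(domain_ca(m, annotation, "ecd"))
    sub <- if (region == "ecd") {
      domain_ca(m, annotation, "ecd", chain = ch)
    } else {
      dplyr::bind_rows(domain_ca(m, annotation, "ecd", chain = ch),
                       domain_ca(m, annotation, "tmd", chain = ch))
    }
    sqrt(sum((center_of_mass(sub) - global)^2))
  }
  raw <- vapply(chains, raw_one, numeric(1), m = model)
  raw_ref <- vapply(chains, raw_one, numeric(1), m = reference)
  if (any(raw_ref < 1e-9)) {
    abort("ecd_spread: degenerate reference (subunit COM coincides with global ECD COM)")
  }
  out <- tibble::tibble(
    chain = chains,
    role = annotation$role[match(chains, annotation$chain)],
    raw = unname(raw),
    raw_reference = unname(raw_ref),
    normalized = unname(raw / raw_ref)
  )
  class(out) <- c("spread_result", class(out))
  out
}
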