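#' Structure models as atom tibbles
#'
#' A `structure_model` is a tibble with one row per atom and columns
#' `serial`, `atom_name`, `alt_loc`, `residue_name`, `chain`,
#' `residue_number`, `insertion_code`, `x`, `y`, `z` (Angstrom),
#' `occupancy`, `b_factor`, `element` and `record_type`
#' (`"ATOM"`/`"HETATM"`).  The model identifier is carried in the
#' `"identifier"` attribute.  All structure-level operations take and
#' return these tibbles, so they compose with the pipe.
#'
#' @param atoms A data frame with the columns above (missing optional
#'   columns are filled with defaults).
#' @param identifier Character scalar naming the model.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms, identifier = "model") {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(
    serial = seq_len(nrow(atoms)), alt_loc = "", insertion_code = "",
    occupancy = 1, b_factor = 0, record_type = "ATOM"
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$atom_name)
  }
  required <- c("atom_name", "residue_name", "chain", "residue_number",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("structure_model: missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      abort("structure_model: non-finite coordinates")
    }
    if (any(!nzchar(atoms$chain))) {
      abort("structure_model: empty chain identifier")
    }
    key <- atom_key(atoms)
    if (anyDuplicated(key) > 0) {
      abort("structure_model: duplicated atom key (chain, residue, insertion, atom name, alt loc)")
    }
  }
  ord <- c("serial", "atom_name", "alt_loc", "residue_name", "chain",
           "residue_number", "insertion_code", "x", "y", "z",
           "occupancy", "b_factor", "element", "record_type")
  atoms <- atoms[, c(ord, setdiff(names(atoms), ord))]
  new_structure_model(atoms, identifier)
}

new_structure_model <- function(atoms, identifier = "model") {
  atoms <- tibble::as_tibble(atoms)
  class(atoms) <- c("structure_model", class(atoms))
  attr(atoms, "identifier") <- identifier
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", model_id(x), ": ", nrow(x), " atoms, chains ",
      paste(unique(x$chain), collapse = " "), "\n", sep = "")
  NextMethod()
}

#' Model identifier
#' @param model A `structure_model`.
#' @return Character scalar.
#' @export
model_id <- function(model) {
  id <- attr(model, "identifier", exact = TRUE)
  if (is.null(id)) "model" else id
}

# Unique per-atom key; insertion codes sort after the bare residue number.
atom_key <- function(atoms) {
  paste(atoms$chain, atoms$residue_number, atoms$insertion_code,
        atoms$atom_name, atoms$alt_loc, sep = "|")
}

# Key without alt_loc, used for cross-model atom matching.
match_key <- function(atoms) {
  paste(atoms$chain, atoms$residue_number, atoms$insertion_code,
        atoms$atom_name, sep = "|")
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  el <- sub("^([A-Z]).*", "\\1", nm)
  two <- substr(nm, 1, 2)
  el[two %in% c("CL", "BR", "SE")] <- two[two %in% c("CL", "BR", "SE")]
  el[substr(nm, 1, 1) %in% as.character(0:9)] <- "H"  # e.g. 1HB2
  el
}

#' Select atoms from a structure model
#'
#' Every stated criterion must hold; unset criteria match everything.
#' Residue intervals are inclusive on both ends in author numbering.
#'
#' @param model A `structure_model`.
#' @param chains Optional character vector of chain identifiers.
#' @param residues Optional residue intervals: a numeric vector of residue
#'   numbers, or a list of `c(start, end)` inclusive intervals.
#' @param atom_names Optional character vector of atom names (e.g. `"CA"`).
#' @param residue_names Optional character vector of residue names
#'   (e.g. a ligand code).
#' @param heavy_only If `TRUE`, drop hydrogens.
#' @return A `structure_model` tibble with the matching atoms, input order
#'   preserved (may be empty).
#' @export
select_atoms <- function(model, chains = NULL, residues = NULL,
                         atom_names = NULL, residue_names = NULL,
                         heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chains)) keep <- keep & model$chain %in% chains
  if (!is.null(residues)) {
    if (is.list(residues)) {
      in_any <- rep(FALSE, nrow(model))
      for (iv in residues) {
        in_any <- in_any |
          (model$residue_number >= iv[1] & model$residue_number <= iv[2])
      }
      keep <- keep & in_any
    } else {
      keep <- keep & model$residue_number %in% residues
    }
  }
  if (!is.null(atom_names)) keep <- keep & model$atom_name %in% atom_names
  if (!is.null(residue_names)) keep <- keep & model$residue_name %in% residue_names
  if (heavy_only) keep <- keep & model$element != "H"
  new_structure_model(model[keep, , drop = FALSE], model_id(model))
}

#' Coordinate matrix of a structure model
#' @param model A `structure_model` (or any atom tibble).
#' @return An n x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

set_coords <- function(model, xyz) {
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

#' Center of mass of an atom selection
#'
#' @param atoms An atom tibble (e.g. from [select_atoms()]).
#' @param weighting `"uniform"` (plain mean, appropriate for all-Calpha
#'   selections) or `"mass"` (element masses).
#' @return A length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(atoms, weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  if (nrow(atoms) == 0) abort("center_of_mass: empty atom selection")
  xyz <- coords(atoms)
  if (weighting == "uniform") {
    w <- rep(1, nrow(atoms))
  } else {
    w <- .element_masses[toupper(atoms$element)]
    if (any(is.na(w))) {
      abort(paste0("center_of_mass: unknown element(s): ",
                   paste(unique(atoms$element[is.na(w)]), collapse = ", ")))
    }
  }
  colSums(xyz * w) / sum(w)
}

#' Minimum pairwise distance between two atom selections
#'
#' @param set_a,set_b Atom tibbles.
#' @return Minimum Euclidean distance in Angstrom.
#' @export
min_distance <- function(set_a, set_b) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    abort("min_distance: empty atom selection")
  }
  a <- coords(set_a)
  b <- coords(set_b)
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Apply a rigid transform to a structure model
#' @param model A `structure_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector (Angstrom).
#' @return The transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(model) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  new_structure_model(set_coords(model, xyz), model_id(model))
}
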