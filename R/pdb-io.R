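#' Read a structure model from a PDB file
#'
#' Parsing is delegated to bio3d; this wrapper applies the package's atom
#' policies: only the first MODEL block is kept (unless `model` selects
#' another), alternate locations are collapsed to the highest-occupancy
#' conformer (ties resolved in favour of the first encountered), waters
#' (HOH/WAT/DOD) are dropped by default, and HETATM ligand records are
#' retained and addressable by `residue_name`.
#'
#' @param path Path to a PDB file.
#' @param identifier Model identifier; defaults to the file base name.
#' @param keep_water Keep water records (default `FALSE`).
#' @param model Which MODEL block to read (1-based, default first).
#' @return A [structure_model()] tibble.
#' @export
read_structure <- function(path, identifier = NULL, keep_water = FALSE,
                           model = 1) {
  if (!file.exists(path)) {
    abort(paste0("read_structure: file not found: ", path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model > 1, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("read_structure: unreadable PDB: ", path,
                                     " (", conditionMessage(e), ")"))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("read_structure: no atoms in ", path))
  }
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      abort(paste0("read_structure: MODEL ", model, " not present in ", path))
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  blank <- function(v) ifelse(is.na(v), "", v)
  atoms <- tibble::tibble(
    serial = at$eleno,
    atom_name = at$elety,
    alt_loc = blank(at$alt),
    residue_name = at$resid,
    chain = blank(at$chain),
    residue_number = at$resno,
    insertion_code = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     guess_element(at$elety), toupper(trimws(at$elesy))),
    record_type = at$type
  )
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  if (!keep_water) {
    atoms <- atoms[!atoms$residue_name %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  }
  atoms <- collapse_alt_loc(atoms)
  if (nrow(atoms) == 0) {
    abort(paste0("read_structure: no atoms retained from ", path))
  }
  if (is.null(identifier)) {
    identifier <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  structure_model(atoms, identifier)
}

# Keep, per (chain, residue, insertion, atom name), the conformer with the
# highest occupancy; ties go to the first encountered.  alt_loc is cleared on
# the survivors so downstream keys are single-conformer.
collapse_alt_loc <- function(atoms) {
  key <- match_key(atoms)
  if (!anyDuplicated(key)) {
    atoms$alt_loc <- ""
    return(atoms)
  }
  ord <- order(match(key, unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  atoms <- atoms[keep, , drop = FALSE]
  atoms$alt_loc <- ""
  atoms
}

#' Write a structure model to a PDB file
#'
#' Fixed-column PDB via bio3d, coordinates to three decimals.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (nrow(model) == 0) abort("write_structure: empty model")
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("write_structure: directory does not exist: ", dir))
  }
  bio3d::write.pdb(
    file = path,
    type = model$record_type,
    eleno = model$serial,
    elety = model$atom_name,
    resid = model$residue_name,
    chain = model$chain,
    resno = model$residue_number,
    insert = ifelse(nzchar(model$insertion_code), model$insertion_code, ""),
    xyz = as.numeric(t(coords(model))),
    o = model$occupancy,
    b = model$b_factor,
    elesy = model$element
  )
  invisible(path)
}
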