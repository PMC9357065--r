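#' Subunit annotation: chain roles and ECD/TMD residue ranges
#'
#' Maps each chain of a pentamer to a subunit role and to inclusive
#' extracellular-domain (ECD) and transmembrane-domain (TMD) residue
#' ranges in author numbering.  The default ranges follow the beta2-subunit
#' equivalent partition used throughout the package: ECD residues 10-217,
#' TMD residues 218-338.
#'
#' @param chains Character vector of chain identifiers.
#' @param roles Character vector, one of `"alpha1"`, `"beta2"`, `"gamma2"`,
#'   `"other"` per chain.
#' @param ecd_start,ecd_end,tmd_start,tmd_end Residue range bounds
#'   (recycled across chains).
#' @return A `subunit_annotation` tibble with columns `chain`, `role`,
#'   `ecd_start`, `ecd_end`, `tmd_start`, `tmd_end`.
#' @export
subunit_annotation <- function(chains, roles,
                               ecd_start = 10, ecd_end = 217,
                               tmd_start = 218, tmd_end = 338) {
  ann <- tibble::tibble(
    chain = as.character(chains),
    role = as.character(roles),
    ecd_start = as.integer(ecd_start), ecd_end = as.integer(ecd_end),
    tmd_start = as.integer(tmd_start), tmd_end = as.integer(tmd_end)
  )
  bad_role <- setdiff(ann$role, c("alpha1", "beta2", "gamma2", "other"))
  if (length(bad_role) > 0) {
    abort(paste0("subunit_annotation: unknown role(s): ",
                 paste(bad_role, collapse = ", ")))
  }
  if (any(ann$ecd_start > ann$ecd_end) || any(ann$tmd_start > ann$tmd_end)) {
    abort("subunit_annotation: range start must be <= end")
  }
  overlap <- pmax(ann$ecd_start, ann$tmd_start) <= pmin(ann$ecd_end, ann$tmd_end)
  if (any(overlap)) {
    abort("subunit_annotation: ECD and TMD ranges overlap within a chain")
  }
  if (anyDuplicated(ann$chain) > 0) {
    abort("subunit_annotation: duplicated chain")
  }
  class(ann) <- c("subunit_annotation", class(ann))
  ann
}

#' Default pentamer annotation (chains A-E)
#'
#' Chains A and C are beta2, B and D alpha1, E gamma2, with the beta2
#' ECD/TMD partition 10-217 / 218-338.
#'
#' @inheritParams subunit_annotation
#' @return A `subunit_annotation` tibble.
#' @export
default_pentamer_annotation <- function(ecd_start = 10, ecd_end = 217,
                                        tmd_start = 218, tmd_end = 338) {
  subunit_annotation(
    chains = c("A", "B", "C", "D", "E"),
    roles = c("beta2", "alpha1", "beta2", "alpha1", "gamma2"),
    ecd_start = ecd_start, ecd_end = ecd_end,
    tmd_start = tmd_start, tmd_end = tmd_end
  )
}

check_annotation <- function(annotation, model = NULL, pentamer = FALSE) {
  if (!inherits(annotation, "subunit_annotation")) {
    annotation <- subunit_annotation(
      annotation$chain, annotation$role,
      annotation$ecd_start, annotation$ecd_end,
      annotation$tmd_start, annotation$tmd_end
    )
  }
  if (pentamer && nrow(annotation) != 5) {
    abort("annotation must cover exactly five chains for pentamer operations")
  }
  if (!is.null(model)) {
    missing <- setdiff(annotation$chain, unique(model$chain))
    if (length(missing) > 0) {
      abort(paste0("annotation chains absent from model: ",
                   paste(missing, collapse = ", ")))
    }
  }
  annotation
}

#' Read / write a subunit annotation as YAML
#'
#' The file maps chain identifiers to `{role, ecd: [start, end],
#' tmd: [start, end]}`.
#'
#' @param path Path to a YAML file.
#' @return [read_annotation()] returns a `subunit_annotation` tibble;
#'   [write_annotation()] returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("read_annotation: file not found: ", path))
  raw <- yaml::read_yaml(path)
  subunit_annotation(
    chains = names(raw),
    roles = vapply(raw, function(x) x$role, character(1)),
    ecd_start = vapply(raw, function(x) x$ecd[1], numeric(1)),
    ecd_end = vapply(raw, function(x) x$ecd[2], numeric(1)),
    tmd_start = vapply(raw, function(x) x$tmd[1], numeric(1)),
    tmd_end = vapply(raw, function(x) x$tmd[2], numeric(1))
  )
}

#' @rdname read_annotation
#' @param annotation A `subunit_annotation` tibble.
#' @export
write_annotation <- function(annotation, path) {
  lst <- setNames(
    lapply(seq_len(nrow(annotation)), function(i) {
      list(role = annotation$role[i],
           ecd = c(annotation$ecd_start[i], annotation$ecd_end[i]),
           tmd = c(annotation$tmd_start[i], annotation$tmd_end[i]))
    }),
    annotation$chain
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

# Calpha atoms of one chain's ECD or TMD range (or all annotated chains).
domain_ca <- function(model, annotation, domain = c("ecd", "tmd"),
                      chain = NULL) {
  domain <- match.arg(domain)
  rows <- if (is.null(chain)) seq_len(nrow(annotation)) else {
    which(annotation$chain %in% chain)
  }
  if (length(rows) == 0) {
    abort(paste0("chain ", paste(chain, collapse = ","), " not annotated"))
  }
  parts <- lapply(rows, function(i) {
    iv <- if (domain == "ecd") {
      c(annotation$ecd_start[i], annotation$ecd_end[i])
    } else {
      c(annotation$tmd_start[i], annotation$tmd_end[i])
    }
    sel <- select_atoms(model, chains = annotation$chain[i],
                        residues = list(iv), atom_names = "CA")
    if (nrow(sel) == 0) {
      abort(paste0("no Calpha atoms in chain ", annotation$chain[i], " ",
                   toupper(domain), " range [", iv[1], ", ", iv[2], "]"))
    }
    sel
  })
  new_structure_model(dplyr::bind_rows(parts), model_id(model))
}
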