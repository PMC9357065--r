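#' Load and validate a run configuration
#'
#' A single YAML file drives reproducible runs; `overrides` (a named
#' list, e.g. from command-line flags) take precedence over file keys.
#' Recognized top-level keys: `models` (paths), `annotation` (path),
#' `reference` (model identifier), `metrics` (subset of twist, spread,
#' pca, pore, contacts), `funnel`, `bias`, `sampler`, `grid`, `synth`,
#' `seed`, `output_dir`.
#'
#' @param path Path to a YAML config (optional if `overrides` carries
#'   everything).
#' @param overrides Named list of values overriding file keys.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("run_config: file not found: ", path))
    yaml::read_yaml(path)
  } else list()
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  for (p in cfg$models) {
    if (!file.exists(p)) abort(paste0("run_config: model file not found: ", p))
  }
  if (!is.null(cfg$annotation) && is.character(cfg$annotation) &&
      !file.exists(cfg$annotation)) {
    abort(paste0("run_config: annotation file not found: ", cfg$annotation))
  }
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "run_config"
  cfg
}

provenance <- function(config) {
  list(
    config_hash = config$hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("plgictools")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
}

write_report <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(config$output_dir, "run_report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  report
}

load_config_annotation <- function(config) {
  if (is.null(config$annotation)) {
    default_pentamer_annotation()
  } else if (is.character(config$annotation)) {
    read_annotation(config$annotation)
  } else {
    config$annotation
  }
}

#' Run the structural metrics of a configuration
#'
#' Reads the configured models, computes the selected metrics (twist,
#' spread, pca, pore, contacts) and writes one CSV per metric plus a
#' `run_report.json` provenance block (config hash, seed, package
#' version, timestamp) to the output directory.  CSV bodies are
#' deterministic for a fixed config and seed.
#'
#' @param config A [run_config()] (or a path to one).
#' @return The report list, invisibly; tables are also returned in
#'   `$tables`.
#' @export
run_metrics <- function(config) {
  if (is.character(config)) config <- run_config(config)
  models <- lapply(config$models, read_structure)
  if (length(models) == 0) abort("run_metrics: no models configured")
  annotation <- load_config_annotation(config)
  metrics <- config$metrics %||% c("twist", "spread")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  write_tab <- function(tab, name) {
    utils::write.csv(tibble::as_tibble(tab),
                     file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    tab
  }
  ref_idx <- 1L
  if (!is.null(config$reference)) {
    ids <- vapply(models, model_id, character(1))
    ref_idx <- match(config$reference, ids)
    if (is.na(ref_idx)) {
      abort(paste0("run_metrics: reference model not loaded: ", config$reference))
    }
  }
  if ("twist" %in% metrics) {
    tw <- dplyr::bind_rows(lapply(models, function(m) {
      dplyr::mutate(twist_result(m, annotation), model = model_id(m),
                    .before = 1)
    }))
    tables$twist <- write_tab(tw, "twist")
  }
  if ("spread" %in% metrics) {
    sp <- dplyr::bind_rows(lapply(models, function(m) {
      dplyr::mutate(ecd_spread(m, annotation, reference = models[[ref_idx]]),
                    model = model_id(m), .before = 1)
    }))
    tables$spread <- write_tab(sp, "spread")
  }
  if ("pca" %in% metrics) {
    pca <- cartesian_pca(models, annotation,
                         region = config$pca_region %||% "ecd",
                         reference = models[[ref_idx]])
    tables$pca_projections <- write_tab(pca$projections, "pca_projections")
    tables$pca_variance <- write_tab(tidy(pca), "pca_variance")
  }
  if ("pore" %in% metrics) {
    pr <- config$pore %||% list()
    prof <- pore_radius_profile(
      models[[1]],
      anchor = as.numeric(pr$anchor %||% c(0, 0, 0)),
      direction = as.numeric(pr$direction %||% c(0, 0, 1)),
      z_range = as.numeric(pr$z_range %||% c(0, 30)),
      step = pr$step %||% 0.5
    )
    tables$pore <- write_tab(prof, "pore_profile")
  }
  if ("contacts" %in% metrics) {
    ct <- config$contacts
    if (is.null(ct)) abort("run_metrics: contacts metric needs a contacts block")
    res <- tibble::tibble(chain = vapply(ct$residues, function(r) r$chain,
                                         character(1)),
                          residue_number = vapply(ct$residues,
                                                  function(r) r$residue_number,
                                                  numeric(1)))
    tab <- contact_frequency(models, ligand = list(residue_names = ct$ligand),
                             residues = res, cutoff = ct$cutoff %||% 4)
    tables$contacts <- write_tab(tab, "contacts")
  }
  report <- list(provenance = provenance(config),
                 metrics = metrics,
                 n_models = length(models))
  write_report(report, config)
  invisible(c(report, list(tables = tables)))
}

#' Run the funnel-metadynamics workflow of a configuration
#'
#' Depending on the configured blocks: builds the funnel geometry from a
#' structure and writes the restraint spec (`funnel` block), runs the
#' well-tempered sampler on the configured model potential and writes
#' the trajectory plus both FES estimates and the recrossing count
#' (`sampler` block).  A run with fewer recrossings than the convergence
#' threshold (default 10) completes with a prominent `converged: false`
#' flag in the report.
#'
#' @param config A [run_config()] (or a path to one).
#' @return The report list, invisibly.
#' @export
run_funnel <- function(config) {
  if (is.character(config)) config <- run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(provenance = provenance(config))
  bias_cfg <- config$bias %||% list()
  bias <- bias_state(
    w0 = bias_cfg$w0 %||% 2, gamma = bias_cfg$gamma %||% 15,
    widths = as.numeric(bias_cfg$widths %||% c(0.05, 0.05)),
    kT = bias_cfg$kT %||% 2.494, pace = bias_cfg$pace %||% 500
  )
  geom <- NULL
  if (!is.null(config$funnel)) {
    fc <- config$funnel
    model <- read_structure(fc$model)
    keys <- function(x) {
      tibble::tibble(chain = vapply(x, function(r) r$chain, character(1)),
                     residue_number = vapply(x, function(r) r$residue_number,
                                             numeric(1)))
    }
    geom <- build_funnel_geometry(
      model, keys(fc$site_residues), keys(fc$loopc_residues),
      cone_angle = fc$cone_angle %||% 20, r_cyl = fc$r_cyl %||% 0.1,
      z_cc = fc$z_cc %||% 2.5, wall_k = fc$wall_k %||% 1000
    )
    export_restraint_spec(geom, bias,
                          path = file.path(out_dir, "restraint_spec.txt"))
    report$funnel <- list(cone_angle = geom$cone_angle, r_cyl = geom$r_cyl,
                          z_cc = geom$z_cc, wall_k = geom$wall_k)
  }
  if (!is.null(config$sampler)) {
    sc <- config$sampler
    pot <- make_double_well(
      barrier = sc$barrier %||% (5 * bias$kT),
      separation = sc$separation %||% 1,
      k2 = sc$k2 %||% 100
    )
    run <- langevin_metad_sample(
      pot, bias,
      n_steps = sc$n_steps %||% 2e6,
      timestep = sc$timestep %||% 2e-5,
      friction = sc$friction %||% 1,
      stride = sc$stride %||% 10,
      seed = config$seed
    )
    a <- pot$params$separation / 2
    basin_a <- list(cv1 = c(-a - 0.25, -a + 0.25))
    basin_b <- list(cv1 = c(a - 0.25, a + 0.25))
    n_re <- count_recrossings(run$trajectory, basin_a, basin_b)
    grid <- fes_grid_spec(c(-1.5 * a - 0.5, 1.5 * a + 0.5) * 1,
                          c(-0.8, 0.8), n = c(121, 81))
    fes_b <- fes_from_final_bias(run$bias, grid)
    fes_r <- reweight_fes(run$trajectory, run$bias, grid)
    export_trajectory(run$trajectory, file.path(out_dir, "trajectory.csv"))
    export_fes(fes_b, file.path(out_dir, "fes_final_bias.csv"))
    export_fes(fes_r, file.path(out_dir, "fes_reweighted.csv"))
    threshold <- config$recrossing_threshold %||% 10
    converged <- n_re >= threshold
    if (!converged) {
      warn(paste0("run_funnel: NOT CONVERGED - only ", n_re,
                  " recrossings (threshold ", threshold, ")"))
    }
    report$sampler <- list(
      n_kernels = nrow(run$bias$kernels),
      recrossings = n_re,
      converged = converged,
      bias = list(w0 = bias$w0, gamma = bias$gamma, kT = bias$kT,
                  widths = bias$widths, pace = bias$pace)
    )
  }
  write_report(report, config)
  invisible(report)
}

#' Generate synthetic fixtures from a configuration
#'
#' Writes pseudo-pentamer PDBs (with their annotation YAML) and a
#' manifest recording the seeds, so downstream metric runs are fully
#' reproducible.
#'
#' @param config A [run_config()] (or a path to one); the `synth` block
#'   supports `pentamer: {residues_per_domain, noise_sigma, twist,
#'   bloom}`.
#' @return The manifest list, invisibly.
#' @export
run_synth <- function(config) {
  if (is.character(config)) config <- run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- config$synth %||% list(pentamer = list())
  manifest <- list(provenance = provenance(config), files = list())
  if (!is.null(sy$pentamer)) {
    pc <- sy$pentamer
    gen <- make_ideal_pentamer(
      residues_per_domain = pc$residues_per_domain %||% 24,
      noise_sigma = pc$noise_sigma %||% 0,
      seed = config$seed
    )
    model <- gen$model
    if (!is.null(pc$twist)) {
      model <- apply_ecd_twist(model, gen$annotation, pc$twist)
    }
    if (!is.null(pc$bloom)) {
      model <- apply_ecd_bloom(model, gen$annotation, pc$bloom)
    }
    pdb_path <- file.path(out_dir, "pentamer.pdb")
    ann_path <- file.path(out_dir, "annotation.yaml")
    write_structure(model, pdb_path)
    write_annotation(gen$annotation, ann_path)
    manifest$files$pentamer <- pdb_path
    manifest$files$annotation <- ann_path
    manifest$pentamer <- list(seed = config$seed,
                              twist = pc$twist %||% 0,
                              bloom = pc$bloom %||% 1,
                              noise_sigma = pc$noise_sigma %||% 0)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
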