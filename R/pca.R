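#' Cartesian principal component analysis of a structure ensemble
#'
#' Stacks the Calpha coordinates of each model (restricted to the ECD,
#' TMD, or whole annotated region) into 3N-dimensional vectors and
#' performs an unscaled, mean-centered PCA.  Models must be pre-aligned
#' to a common reference (see [superpose_kabsch()]); when `reference` is
#' supplied every model is aligned to it on all Calpha atoms first.
#' Only atoms whose key is present in every model enter the analysis.
#'
#' @param models List of `structure_model` tibbles.
#' @param annotation A [subunit_annotation()] valid for every model.
#' @param region `"ecd"`, `"tmd"` or `"all"`.
#' @param reference Optional `structure_model` to align all models onto
#'   (all-Calpha Kabsch fit) before the PCA.
#' @return A `plgic_pca` object with elements `mean` (3N vector),
#'   `components` (orthonormal rows, one per component),
#'   `variance_fraction`, `sdev`, `projections` (tibble: `model`, `PC1`,
#'   `PC2`, ...), `n_atoms`, `region` and `zero_variance` flag.
#' @export
cartesian_pca <- function(models, annotation, region = c("ecd", "tmd", "all"),
                          reference = NULL) {
  region <- match.arg(region)
  if (length(models) < 2) abort("cartesian_pca: need >= 2 models")
  annotation <- check_annotation(annotation)
  if (!is.null(reference)) {
    models <- lapply(models, function(m) {
      superpose_kabsch(m, reference, atom_names = "CA")$apply(m)
    })
  }
  region_ca <- function(m) {
    if (region == "all") {
      dplyr::bind_rows(domain_ca(m, annotation, "ecd"),
                       domain_ca(m, annotation, "tmd"))
    } else {
      domain_ca(m, annotation, region)
    }
  }
  sels <- lapply(models, region_ca)
  keys <- lapply(sels, match_key)
  common <- Reduce(intersect, keys)
  if (length(common) == 0) abort("cartesian_pca: no common Calpha atoms across models")
  X <- t(vapply(seq_along(sels), function(i) {
    xyz <- coords(sels[[i]])[match(common, keys[[i]]), , drop = FALSE]
    as.numeric(t(xyz))  # x1 y1 z1 x2 y2 z2 ...
  }, numeric(3 * length(common))))
  n <- nrow(X)
  total_var <- sum(apply(X, 2, stats::var))
  zero_variance <- !is.finite(total_var) || total_var < 1e-12
  k <- min(n - 1, ncol(X))
  if (zero_variance) {
    comp <- matrix(0, 0, ncol(X))
    vf <- numeric(0)
    sdev <- numeric(0)
    proj <- matrix(0, n, 0)
  } else {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(k, ncol(pc$rotation)))
    comp <- t(pc$rotation[, keep, drop = FALSE])
    sdev <- pc$sdev[keep]
    vf <- pc$sdev[keep]^2 / sum(pc$sdev^2)
    proj <- pc$x[, keep, drop = FALSE]
  }
  ids <- vapply(models, model_id, character(1))
  projections <- tibble::as_tibble(as.data.frame(proj))
  if (ncol(projections) > 0) {
    names(projections) <- paste0("PC", seq_len(ncol(projections)))
  }
  projections <- dplyr::bind_cols(tibble::tibble(model = ids), projections)
  out <- list(
    mean = if (zero_variance) colMeans(X) else colMeans(X),
    components = comp,
    variance_fraction = vf,
    sdev = sdev,
    projections = projections,
    atom_keys = common,
    n_atoms = length(common),
    n_models = n,
    region = region,
    zero_variance = zero_variance
  )
  class(out) <- "plgic_pca"
  out
}

#' @export
print.plgic_pca <- function(x, ...) {
  cat("<plgic_pca> ", x$n_models, " models, ", x$n_atoms, " Calpha atoms (",
      x$region, ")\n", sep = "")
  if (x$zero_variance) {
    cat("  total variance is zero (identical models)\n")
  } else {
    cat("  PC1..PC", length(x$variance_fraction), " variance fractions: ",
        paste(format(round(x$variance_fraction, 3), nsmall = 3),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname cartesian_pca
#' @param x A `plgic_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plgic_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_fraction),
    sdev = x$sdev,
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}

#' @rdname cartesian_pca
#' @exportS3Method generics::glance
glance.plgic_pca <- function(x, ...) {
  tibble::tibble(
    n_models = x$n_models,
    n_atoms = x$n_atoms,
    region = x$region,
    zero_variance = x$zero_variance,
    pc1_variance_fraction = if (length(x$variance_fraction) > 0) {
      x$variance_fraction[1]
    } else NA_real_
  )
}

#' @rdname cartesian_pca
#' @param object A `plgic_pca` object.
#' @exportS3Method ggplot2::autoplot
autoplot.plgic_pca <- function(object, ...) {
  df <- object$projections
  if (ncol(df) < 3) abort("autoplot.plgic_pca: fewer than two components")
  labs <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$variance_fraction[1:2])
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, label = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = paste0("Cartesian PCA (", object$region, ")")) +
    ggplot2::theme_minimal()
}
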