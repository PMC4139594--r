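#' Pipeline configuration
#'
#' Collects the thresholds every stage of the discovery pipeline consumes:
#'
#' * `r_threshold` — Pearson correlation cutoff for spatial network edges
#'   (strict `r > r_threshold`); default 0.7.
#' * `fold_min` — minimum linear fold change for the differential screens and
#'   the zone-enrichment prefilter; default 6.
#' * `alpha` — family-wise significance level applied to Holm-adjusted
#'   p-values; default 1e-9.
#' * `k_extend` — number of associated genes added when a query list is
#'   extended over the association compendium; default 50.
#' * `propagation_alpha` — restart/diffusion parameter of the label
#'   propagation used for extension, in (0, 1); default 0.85.
#' * `seed` — base seed for the stochastic stages.
#'
#' @param r_threshold correlation threshold in (0, 1].
#' @param fold_min minimum fold change, >= 1.
#' @param alpha significance level in (0, 1).
#' @param k_extend positive integer.
#' @param propagation_alpha diffusion parameter in (0, 1).
#' @param seed integer seed.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(r_threshold = 0.7, fold_min = 6, alpha = 1e-9,
                            k_extend = 50, propagation_alpha = 0.85,
                            seed = 1L) {
  cfg <- list(
    r_threshold = as.numeric(r_threshold),
    fold_min = as.numeric(fold_min),
    alpha = as.numeric(alpha),
    k_extend = as.integer(k_extend),
    propagation_alpha = as.numeric(propagation_alpha),
    seed = as.integer(seed)
  )
  if (!(cfg$r_threshold > 0 && cfg$r_threshold <= 1)) {
    stop("r_threshold must be in (0, 1]", call. = FALSE)
  }
  if (cfg$fold_min < 1) stop("fold_min must be >= 1", call. = FALSE)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$k_extend < 0) stop("k_extend must be non-negative", call. = FALSE)
  if (!(cfg$propagation_alpha > 0 && cfg$propagation_alpha < 1)) {
    stop("propagation_alpha must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @param config a [pipeline_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
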