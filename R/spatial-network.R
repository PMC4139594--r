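#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' Thin wrapper over the textbook estimator that turns the constant-vector
#' degeneracy into a catchable error (the network builder drops such genes
#' and logs the count).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  as.numeric(cor(x, y))
}

#' Define a zone mask over an expression set
#'
#' A mask names the samples entering a spatial analysis (`included`, e.g.
#' all structures at the target age) and the target subset (`target`, e.g.
#' the VZ samples at that age).
#'
#' @param expr an [expr_set()].
#' @param age age/stage label selecting the included samples (NULL = all).
#' @param target_structures structures forming the target zone.
#' @param included_sample_ids,target_sample_ids explicit overrides.
#' @return an object of class `zone_mask` with `included` and `target`
#'   sample-id vectors.
#' @export
zone_mask <- function(expr, age = NULL, target_structures = "VZ",
                      included_sample_ids = NULL, target_sample_ids = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  s <- expr$samples
  included <- included_sample_ids %||%
    s$sample_id[if (is.null(age)) rep(TRUE, nrow(s)) else s$age == age]
  target <- target_sample_ids %||%
    intersect(included, s$sample_id[s$structure %in% target_structures])
  if (!length(included) || !length(target)) {
    stop("zone mask must have non-empty included and target sample sets",
         call. = FALSE)
  }
  if (!all(target %in% included)) {
    stop("target samples must be a subset of included samples", call. = FALSE)
  }
  structure(list(included = included, target = target), class = "zone_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert a zone mask
#'
#' Swaps the target for its complement within the included samples, turning
#' a VZ mask into its non-VZ counterpart.
#'
#' @param mask a [zone_mask()].
#' @return a `zone_mask` with `target = included \ target`.
#' @export
invert_mask <- function(mask) {
  stopifnot(inherits(mask, "zone_mask"))
  inv <- setdiff(mask$included, mask$target)
  if (!length(inv)) stop("cannot invert: target covers all included samples",
                         call. = FALSE)
  structure(list(included = mask$included, target = inv), class = "zone_mask")
}

#' Zone enrichment of a gene
#'
#' Ratio of the gene's mean expression over the target samples to its mean
#' over the remaining included samples, with a pseudocount on both means.
#'
#' @param expr an [expr_set()].
#' @param mask a [zone_mask()].
#' @param gene gene symbol (must be present), or NULL for all genes.
#' @param eps pseudocount added to both means.
#' @return named numeric vector of enrichment ratios.
#' @export
zone_enrichment <- function(expr, mask, gene = NULL, eps = 1e-9) {
  stopifnot(inherits(expr, "expr_set"), inherits(mask, "zone_mask"))
  comp <- setdiff(mask$included, mask$target)
  if (!length(comp)) {
    stop("zone enrichment needs a non-empty complement within the mask",
         call. = FALSE)
  }
  v <- expr$values
  if (!is.null(gene)) {
    if (!all(gene %in% rownames(v))) {
      stop("gene(s) not in matrix: ",
           paste(setdiff(gene, rownames(v)), collapse = ", "), call. = FALSE)
    }
    v <- v[gene, , drop = FALSE]
  }
  t_mean <- rowMeans(v[, mask$target, drop = FALSE])
  c_mean <- rowMeans(v[, comp, drop = FALSE])
  (t_mean + eps) / (c_mean + eps)
}

#' Build a spatial co-expression (VZ) network
#'
#' The zone-network construction: (i) prefilter to genes expressed within
#' the mask (mean over included samples at or above an expression floor) and
#' zone-enriched at least `fold_min`-fold; (ii) compute all pairwise Pearson
#' correlations over the included-sample profiles; (iii) keep edges with
#' `r > r_threshold` (strict); (iv) report the connected component containing
#' the most zone-enriched gene (default seed rule), all components, or the
#' component of a named seed gene. Genes with constant profiles are dropped
#' with a recorded count.
#'
#' @param expr an [expr_set()].
#' @param mask a [zone_mask()] (see [invert_mask()] for the non-VZ analogue).
#' @param config a [pipeline_config()]; `r_threshold` and `fold_min` are used.
#' @param floor_quantile expression floor: quantile of all gene means over
#'   the included samples ("expressed in the region" operationalization).
#' @param seed_rule `"top-enriched-component"`, `"all-components"` or
#'   `"seed-gene"`.
#' @param seed_gene required when `seed_rule = "seed-gene"`.
#' @return an object of class `correlation_network`: a list with `graph`
#'   (igraph, edge attribute `weight` = r), `nodes`, `enrichment` (per-node),
#'   `r_threshold`, `seed_rule`, and diagnostic counts (`n_prefilter`,
#'   `n_constant_dropped`).
#' @export
build_vz_network <- function(expr, mask, config = pipeline_config(),
                             floor_quantile = 0.2,
                             seed_rule = c("top-enriched-component",
                                           "all-components", "seed-gene"),
                             seed_gene = NULL) {
  stopifnot(inherits(expr, "expr_set"), inherits(mask, "zone_mask"))
  seed_rule <- match.arg(seed_rule)
  v <- expr$values[, mask$included, drop = FALSE]
  gmeans <- rowMeans(v)
  floor_value <- quantile(gmeans, floor_quantile, names = FALSE)
  enr <- zone_enrichment(expr, mask)
  pass <- names(gmeans)[gmeans >= floor_value & enr >= config$fold_min]
  if (length(pass) < 2) {
    stop("fewer than 2 genes pass the prefilters (floor ",
         signif(floor_value, 4), ", fold >= ", config$fold_min, "); ",
         length(pass), " passed", call. = FALSE)
  }
  sub <- v[pass, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  n_constant <- sum(sds == 0)
  keep <- sds > 0
  if (sum(keep) < 2) {
    stop("fewer than 2 non-constant genes pass the prefilters", call. = FALSE)
  }
  sub <- sub[keep, , drop = FALSE]
  cm <- cor(t(sub))
  adj <- cm > config$r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$weight <- cm[igraph::as_edgelist(g, names = FALSE)]
  comp <- igraph::components(g)
  members <- switch(
    seed_rule,
    "all-components" = rownames(sub),
    "top-enriched-component" = {
      top <- names(which.max(enr[rownames(sub)]))
      rownames(sub)[comp$membership == comp$membership[top]]
    },
    "seed-gene" = {
      if (is.null(seed_gene) || !seed_gene %in% rownames(sub)) {
        stop("seed_gene must name a gene passing the prefilters", call. = FALSE)
      }
      rownames(sub)[comp$membership == comp$membership[seed_gene]]
    }
  )
  graph <- igraph::induced_subgraph(g, members)
  structure(
    list(
      graph = graph,
      nodes = sort(members),
      enrichment = enr[members],
      r_threshold = config$r_threshold,
      seed_rule = seed_rule,
      floor_value = floor_value,
      n_prefilter = length(pass),
      n_constant_dropped = n_constant
    ),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network: ", length(x$nodes), " genes, ",
      igraph::ecount(x$graph), " edges (r > ", x$r_threshold, ", rule '",
      x$seed_rule, "')\n", sep = "")
  cat("  prefiltered genes: ", x$n_prefilter,
      "; constant profiles dropped: ", x$n_constant_dropped, "\n", sep = "")
  cat("  nodes: ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
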