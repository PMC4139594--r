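#' Combine evidence networks into one weighted graph
#'
#' Composite edge weight is the weighted sum of the per-evidence edge
#' weights, with the combination weights normalized to sum to 1 (uniform by
#' default). Vertices are the union of all input vertex sets.
#'
#' @param networks list of `igraph` objects (edge attribute `weight`;
#'   unweighted edges count as weight 1).
#' @param weights optional non-negative combination weights, one per
#'   network, summing to a positive value.
#' @return an undirected weighted `igraph`.
#' @export
combine_networks <- function(networks, weights = NULL) {
  stopifnot(length(networks) >= 1)
  if (is.null(weights)) weights <- rep(1, length(networks))
  if (length(weights) != length(networks) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be non-negative, one per network, with positive sum",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  all_vertices <- sort(unique(unlist(lapply(networks, function(g) {
    igraph::V(g)$name
  }))))
  edges <- do.call(rbind, lapply(seq_along(networks), function(i) {
    g <- networks[[i]]
    if (igraph::ecount(g) == 0) return(NULL)
    el <- igraph::as_edgelist(g)
    w <- if ("weight" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$weight
    } else {
      rep(1, nrow(el))
    }
    # canonical unordered pair key
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    data.frame(from = a, to = b, w = weights[i] * w, stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || !nrow(edges)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(igraph::add_vertices(g, length(all_vertices), name = all_vertices))
  }
  agg <- stats::aggregate(w ~ from + to, data = edges, FUN = sum)
  names(agg)[names(agg) == "w"] <- "weight"
  igraph::graph_from_data_frame(
    agg[agg$weight > 0, , drop = FALSE], directed = FALSE,
    vertices = data.frame(name = all_vertices, stringsAsFactors = FALSE)
  )
}

#' Gaussian-field label propagation over a composite network
#'
#' Solves `s = (I - alpha * S)^{-1} y` where `S` is the symmetric
#' degree-normalized adjacency (`D^{-1/2} A D^{-1/2}`) of the composite
#' graph and `y` places mass `1/|query|` on each query gene present in the
#' graph. Scores are non-negative; genes unreachable from the query score
#' exactly 0.
#'
#' @param composite a weighted undirected `igraph` (from
#'   [combine_networks()]).
#' @param query character vector (or [gene_list()]) of query genes.
#' @param alpha diffusion parameter in (0, 1).
#' @return named numeric vector of scores over all graph vertices.
#' @export
propagate <- function(composite, query, alpha = 0.85) {
  query <- as.character(query)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  vnames <- igraph::V(composite)$name
  q_in <- intersect(query, vnames)
  if (!length(q_in)) {
    stop("no query gene is present in the composite graph", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(composite, attr =
    if ("weight" %in% igraph::edge_attr_names(composite)) "weight" else NULL,
    sparse = FALSE)
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- A * (inv_sqrt %o% inv_sqrt)
  y <- setNames(rep(0, length(vnames)), vnames)
  y[q_in] <- 1 / length(q_in)
  s <- solve(diag(length(vnames)) - alpha * S, y)
  s[s < 0 & s > -1e-12] <- 0  # clamp numerical dust
  setNames(as.numeric(s), vnames)
}

#' Extend a query gene list over an association-network compendium
#'
#' Combines the evidence networks (uniform weights by default), propagates
#' query labels, ranks non-query genes by score (descending, ties broken
#' lexicographically by symbol) and keeps the top `k_extend`. The result is
#' the induced subgraph of query plus associated genes over all evidence
#' networks, with per-node roles and scores.
#'
#' @param networks named list of evidence `igraph`s (see
#'   [simulate_association_compendium()]).
#' @param query a [gene_list()] or character vector.
#' @param config a [pipeline_config()]; `k_extend` and `propagation_alpha`
#'   are used.
#' @param exclude_evidence evidence-type names to drop before combining
#'   (e.g. `"predicted"`).
#' @param network_weights optional combination weights.
#' @return an object of class `extended_network`: list with `graph` (igraph
#'   over query + associated, edges typed by evidence), `query`,
#'   `associated`, `scores`.
#' @export
extend_list <- function(networks, query, config = pipeline_config(),
                        exclude_evidence = NULL, network_weights = NULL) {
  query <- as.character(query)
  if (!is.null(exclude_evidence)) {
    keep <- !(names(networks) %in% exclude_evidence)
    if (!any(keep)) stop("all evidence networks excluded", call. = FALSE)
    networks <- networks[keep]
    if (!is.null(network_weights)) network_weights <- network_weights[keep]
  }
  composite <- combine_networks(networks, network_weights)
  scores <- propagate(composite, query, config$propagation_alpha)
  cand <- scores[setdiff(names(scores), query)]
  cand <- cand[cand > 0]
  ord <- order(-cand, names(cand))
  k <- config$k_extend
  if (length(cand) < k) {
    warning("only ", length(cand), " scorable genes available (k_extend = ",
            k, ")", call. = FALSE)
    k <- length(cand)
  }
  associated <- names(cand)[ord][seq_len(k)]
  nodes <- c(intersect(query, names(scores)), associated)
  # induced typed multigraph over all evidence channels
  typed_edges <- do.call(rbind, lapply(names(networks), function(nm) {
    g <- networks[[nm]]
    sub <- igraph::induced_subgraph(g, intersect(nodes, igraph::V(g)$name))
    if (igraph::ecount(sub) == 0) return(NULL)
    el <- igraph::as_edgelist(sub)
    data.frame(
      from = el[, 1], to = el[, 2],
      type = nm,
      weight = if ("weight" %in% igraph::edge_attr_names(sub)) {
        igraph::E(sub)$weight
      } else {
        rep(1, nrow(el))
      },
      stringsAsFactors = FALSE
    )
  }))
  vert <- data.frame(
    name = nodes,
    role = ifelse(nodes %in% query, "query", "associated"),
    score = as.numeric(scores[nodes]),
    stringsAsFactors = FALSE
  )
  graph <- igraph::graph_from_data_frame(
    typed_edges %||% data.frame(from = character(), to = character(),
                                type = character(), weight = numeric()),
    directed = FALSE, vertices = vert
  )
  structure(
    list(graph = graph,
         query = intersect(query, names(scores)),
         associated = associated,
         scores = scores[nodes]),
    class = "extended_network"
  )
}

#' @export
print.extended_network <- function(x, ...) {
  cat("extended_network: ", length(x$query), " query + ", length(x$associated),
      " associated = ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " typed edges\n", sep = "")
  invisible(x)
}
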