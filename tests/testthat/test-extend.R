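ring_graph <- function(names, weight = 1) {
  n <- length(names)
  igraph::graph_from_data_frame(
    data.frame(from = names, to = names[c(2:n, 1)], weight = weight),
    directed = FALSE
  )
}

test_that("network combination is a normalized weighted sum of edge weights", {
  g <- ring_graph(LETTERS[1:4], weight = 0.5)
  single <- combine_networks(list(g))
  expect_equal(sort(igraph::E(single)$weight), rep(0.5, 4))

  two_same <- combine_networks(list(g, g))
  expect_equal(sort(igraph::E(two_same)$weight), rep(0.5, 4))  # convexity

  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", weight = 1), directed = FALSE,
    vertices = data.frame(name = c("A", "B", "C")))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "B", to = "C", weight = 1), directed = FALSE,
    vertices = data.frame(name = c("A", "B", "C")))
  u <- combine_networks(list(g1, g2), weights = c(0.5, 0.5))
  expect_equal(igraph::ecount(u), 2)
  expect_equal(unique(igraph::E(u)$weight), 0.5)

  expect_error(combine_networks(list(g1, g2), weights = c(0, 0)), "weights")
})

test_that("propagation solves the Gaussian field: closed form, zeros, equivariance", {
  # single edge query-g: closed-form 2x2 solution s = (I - aS)^{-1} y
  g <- igraph::graph_from_data_frame(
    data.frame(from = "Q", to = "G", weight = 2), directed = FALSE,
    vertices = data.frame(name = c("Q", "G", "ISO")))
  a <- 0.85
  s <- propagate(g, "Q", alpha = a)
  expect_equal(unname(s["Q"]), 1 / (1 - a^2), tolerance = 1e-12)
  expect_equal(unname(s["G"]), a / (1 - a^2), tolerance = 1e-12)
  expect_equal(unname(s["ISO"]), 0)

  # permuting labels permutes scores
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "G", to = "Q", weight = 2), directed = FALSE,
    vertices = data.frame(name = c("ISO", "G", "Q")))
  s2 <- propagate(g2, "Q", alpha = a)
  expect_equal(s2[names(s)], s, tolerance = 1e-12)

  expect_error(propagate(g, "ABSENT", 0.5), "query")
  expect_error(propagate(g, "Q", 1), "alpha")
})

test_that("propagation matches an independent series solution on random graphs", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    A <- matrix(0, n, n)
    edges <- which(upper.tri(A), arr.ind = TRUE)
    on <- runif(nrow(edges)) < 0.15
    w <- runif(sum(on), 0.1, 1)
    A[edges[on, , drop = FALSE]] <- w
    A <- A + t(A)
    names_ <- sprintf("N%02d", 1:n)
    dimnames(A) <- list(names_, names_)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    q <- sample(names_, 3)
    alpha <- 0.85
    got <- propagate(g, q, alpha)
    want <- propagate_series_oracle(A[igraph::V(g)$name, igraph::V(g)$name],
                                    match(q, igraph::V(g)$name), alpha)
    expect_equal(unname(got), want, tolerance = 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("alpha -> 0 limit concentrates scores on the query", {
  nets <- exact_compendium(sprintf("Q%02d", 1:5), sprintf("A%02d", 1:10),
                           sprintf("D%02d", 1:10))
  comp <- combine_networks(nets)
  s <- propagate(comp, sprintf("Q%02d", 1:5), alpha = 1e-8)
  y <- ifelse(grepl("^Q", names(s)), 1 / 5, 0)
  expect_equal(unname(s), unname(y), tolerance = 1e-6)
})

test_that("duplicating an evidence network leaves propagation scores unchanged", {
  nets <- simulate_association_compendium(sprintf("G%03d", 1:60),
                                          sprintf("G%03d", 1:8),
                                          k_assoc = 15, seed = 3)
  s1 <- propagate(combine_networks(nets), sprintf("G%03d", 1:8), 0.85)
  s2 <- propagate(combine_networks(c(nets, nets[1]),
                                   weights = c(0.5, rep(1, 4), 0.5)),
                  sprintf("G%03d", 1:8), 0.85)
  expect_equal(s2[names(s1)], s1, tolerance = 1e-10)
})

test_that("list extension returns query + k ranked genes with exact tier recovery", {
  q <- sprintf("Q%02d", 1:13)
  assoc <- sprintf("A%02d", 1:50)
  decoys <- sprintf("D%03d", 1:120)
  nets <- exact_compendium(q, assoc, decoys)
  cfg <- pipeline_config(k_extend = 50)
  ext <- extend_list(nets, q, cfg)
  expect_equal(igraph::vcount(ext$graph), 63)
  expect_setequal(ext$associated, assoc)  # exact wiring: tier recovered
  expect_true(all(igraph::V(ext$graph)$role[match(q, igraph::V(ext$graph)$name)]
                  == "query"))
  # every associated score >= any excluded score
  comp <- combine_networks(nets)
  all_scores <- propagate(comp, q, cfg$propagation_alpha)
  excluded <- setdiff(names(all_scores), c(q, ext$associated))
  expect_gte(min(all_scores[ext$associated]), max(all_scores[excluded]))

  # k = 0: induced subgraph on query only
  ext0 <- extend_list(nets, q, pipeline_config(k_extend = 0))
  expect_setequal(igraph::V(ext0$graph)$name, q)

  # fewer scorable genes than k: warning, all returned
  small <- exact_compendium(q[1:3], assoc[1:5], decoys[1:4])
  expect_warning(
    ext_small <- extend_list(small, q[1:3], pipeline_config(k_extend = 50)),
    "scorable")
  expect_lt(length(ext_small$associated), 50)
})

test_that("score ties break lexicographically by symbol", {
  # star: query center with identical-weight leaves -> equal leaf scores
  leaves <- c("ZZZ", "AAA", "MMM", "BBB")
  g <- igraph::graph_from_data_frame(
    data.frame(from = "Q", to = leaves, weight = 1), directed = FALSE)
  ext <- extend_list(list(star = g), "Q", pipeline_config(k_extend = 2))
  expect_identical(sort(ext$associated), c("AAA", "BBB"))
})

test_that("evidence channels can be excluded before combination", {
  q <- sprintf("Q%02d", 1:4)
  nets <- exact_compendium(q, sprintf("A%02d", 1:6), sprintf("D%02d", 1:6),
                           evidence = c("coexpression", "predicted"))
  ext <- extend_list(nets, q, pipeline_config(k_extend = 3),
                     exclude_evidence = "predicted")
  expect_false("predicted" %in% igraph::E(ext$graph)$type)
  expect_error(extend_list(nets, q, exclude_evidence = names(nets)),
               "excluded")
})
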