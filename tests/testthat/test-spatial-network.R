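test_that("pearson_r matches the definition and flags degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  # brute force from the product-moment definition
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    byhand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b), byhand, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("zone enrichment is a pseudocounted target/complement mean ratio", {
  vals <- matrix(c(rep(12, 2), rep(2, 4),
                   rep(5, 6)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), paste0("s", 1:6)))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        structure = c("VZ", "VZ", "CP", "CP", "GE", "GE"),
                        age = "E15.5", species = "mouse")
  ex <- expr_set(vals, samples)
  mask <- zone_mask(ex, target_structures = "VZ")
  expect_equal(unname(zone_enrichment(ex, mask, "B")), 1)
  expect_equal(unname(zone_enrichment(ex, mask, "A")), 6, tolerance = 1e-9)

  sim <- small_mouse_atlas(sigma = 0, seed = 5)
  m <- zone_mask(sim$expr, age = "E15.5")
  enr <- zone_enrichment(sim$expr, m, sim$truth$planted$members)
  expect_equal(unname(enr), rep(sim$truth$planted_fold, 13), tolerance = 1e-9)

  expect_error(zone_enrichment(ex, zone_mask(ex, included_sample_ids = c("s1", "s2"),
                                             target_sample_ids = c("s1", "s2"))),
               "complement")
})

test_that("network construction recovers the planted module and respects the strict threshold", {
  sim <- small_mouse_atlas(sigma = 0, seed = 6)
  mask <- zone_mask(sim$expr, age = "E15.5")
  net <- build_vz_network(sim$expr, mask)
  expect_setequal(net$nodes, sim$truth$planted$members)

  # strict threshold at r = 1: no edge survives, component is a singleton
  noisy <- small_mouse_atlas(sigma = 0.3, seed = 6)
  net1 <- build_vz_network(noisy$expr, zone_mask(noisy$expr, age = "E15.5"),
                           pipeline_config(r_threshold = 1))
  expect_lte(length(net1$nodes), 1)
})

test_that("raising the correlation threshold never adds nodes or edges", {
  sim <- small_mouse_atlas(sigma = 0.5, seed = 7)
  mask <- zone_mask(sim$expr, age = "E15.5")
  lo <- build_vz_network(sim$expr, mask, pipeline_config(r_threshold = 0.5),
                         seed_rule = "all-components")
  hi <- build_vz_network(sim$expr, mask, pipeline_config(r_threshold = 0.8),
                         seed_rule = "all-components")
  edge_key <- function(net) {
    el <- igraph::as_edgelist(net$graph)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  expect_true(all(edge_key(hi) %in% edge_key(lo)))
  expect_true(all(hi$nodes %in% lo$nodes))
})

test_that("mask inversion yields a disjoint non-VZ network on noise-free data", {
  # two planted modules: one VZ-high, one CP-high
  structures <- c("VZ", "CP", "GE", "MZ")
  samples <- data.frame(sample_id = paste0("s", 1:4), structure = structures,
                        age = "E15.5", species = "mouse")
  vals <- rbind(
    VzA = c(60, 5, 5, 5), VzB = c(66, 5.5, 5.5, 5.5),
    CpA = c(5, 60, 5, 5), CpB = c(5.5, 66, 5.5, 5.5),
    Flat1 = c(5, 5, 5, 5) * 1.0, Flat2 = c(6, 6, 6, 6)
  )
  colnames(vals) <- samples$sample_id
  ex <- expr_set(vals, samples)
  # pearson needs >= 3 samples; 4 structures is enough
  vz_mask <- zone_mask(ex, target_structures = "VZ")
  cp_mask <- zone_mask(ex, target_structures = "CP")
  vz_net <- build_vz_network(ex, vz_mask, floor_quantile = 0)
  cp_net <- build_vz_network(ex, cp_mask, floor_quantile = 0)
  expect_setequal(vz_net$nodes, c("VzA", "VzB"))
  expect_setequal(cp_net$nodes, c("CpA", "CpB"))
  expect_length(intersect(vz_net$nodes, cp_net$nodes), 0)
  inv <- invert_mask(vz_mask)
  expect_setequal(inv$target, setdiff(vz_mask$included, vz_mask$target))
})

test_that("permuting gene order permutes network nodes and nothing else", {
  sim <- small_mouse_atlas(sigma = 0.3, seed = 8)
  mask <- zone_mask(sim$expr, age = "E15.5")
  net <- build_vz_network(sim$expr, mask)
  set.seed(1)
  perm <- sample(nrow(sim$expr$values))
  permuted <- expr_set(sim$expr$values[perm, ], sim$expr$samples)
  net_p <- build_vz_network(permuted, mask)
  expect_setequal(net_p$nodes, net$nodes)
  expect_equal(igraph::ecount(net_p$graph), igraph::ecount(net$graph))
})

test_that("edges match brute-force all-pairs correlation on small inputs", {
  sim <- small_mouse_atlas(n_genes = 40, sigma = 0.4, seed = 9)
  mask <- zone_mask(sim$expr, age = "E15.5")
  cfg <- pipeline_config(r_threshold = 0.7)
  net <- build_vz_network(sim$expr, mask, cfg, seed_rule = "all-components")

  # recompute the prefilter and all-pairs correlations from definitions
  v <- sim$expr$values[, mask$included]
  gmeans <- rowMeans(v)
  floor_value <- quantile(gmeans, 0.2, names = FALSE)
  enr <- zone_enrichment(sim$expr, mask)
  pass <- names(gmeans)[gmeans >= floor_value & enr >= cfg$fold_min]
  expected_edges <- character()
  for (i in seq_along(pass)) {
    for (j in seq_along(pass)) {
      if (i < j) {
        r <- pearson_r(v[pass[i], ], v[pass[j], ])
        if (r > cfg$r_threshold) {
          expected_edges <- c(expected_edges,
                              paste(sort(c(pass[i], pass[j])), collapse = "|"))
        }
      }
    }
  }
  el <- igraph::as_edgelist(net$graph)
  got <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                             sep = "|") else character()
  expect_setequal(got, expected_edges)
})
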