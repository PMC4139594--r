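test_that("generators are deterministic given a seed", {
  a <- small_mouse_atlas(seed = 11)
  b <- small_mouse_atlas(seed = 11)
  expect_identical(a$expr$values, b$expr$values)
  expect_false(identical(a$expr$values, small_mouse_atlas(seed = 12)$expr$values))

  hs1 <- simulate_human_spatial(n_genes = 200, planted_size = 20, seed = 3)
  hs2 <- simulate_human_spatial(n_genes = 200, planted_size = 20, seed = 3)
  expect_identical(hs1$expr$values, hs2$expr$values)

  ht1 <- simulate_human_temporal(n_genes = 150, planted_size = 15, seed = 3)
  ht2 <- simulate_human_temporal(n_genes = 150, planted_size = 15, seed = 3)
  expect_identical(ht1$expr$values, ht2$expr$values)

  n1 <- simulate_association_compendium(sprintf("G%03d", 1:80),
                                        sprintf("G%03d", 1:10),
                                        k_assoc = 20, seed = 5)
  n2 <- simulate_association_compendium(sprintf("G%03d", 1:80),
                                        sprintf("G%03d", 1:10),
                                        k_assoc = 20, seed = 5)
  expect_identical(lapply(n1, igraph::as_edgelist),
                   lapply(n2, igraph::as_edgelist))
})

test_that("noise-free planted genes are exact scalar multiples of the template", {
  sim <- small_mouse_atlas(sigma = 0, planted_gene_sd = 0.2, seed = 2)
  planted <- sim$truth$planted$members
  v <- sim$expr$values[planted, ]
  base <- v[1, ] / v[1, 1]
  for (g in seq_len(nrow(v))) {
    expect_equal(v[g, ] / v[g, 1], base, tolerance = 1e-12)
  }
  cors <- cor(t(v))
  expect_true(all(abs(cors - 1) < 1e-12))
})

test_that("noise-free limit: planted genes pass the six-fold filter, decoys cannot", {
  hs <- simulate_human_spatial(n_genes = 400, planted_size = 30, sigma = 0,
                               seed = 4)
  fold <- fold_change(hs$expr, zone_contrast(hs$expr))
  planted <- hs$truth$planted$members
  expect_true(all(fold[planted] >= 6))
  expect_true(all(fold[setdiff(names(fold), planted)] < 6))

  ht <- simulate_human_temporal(n_genes = 300, planted_size = 20, sigma = 0,
                                seed = 4)
  foldt <- fold_change(ht$expr, stage_contrast(ht$expr, "8-9pcw"))
  plantedt <- ht$truth$planted$members
  expect_true(all(foldt[plantedt] >= 6))
  expect_true(all(foldt[setdiff(names(foldt), plantedt)] < 6))
})

test_that("human spatial generator carries exactly `overlap` mouse-module genes", {
  hs <- simulate_human_spatial(n_genes = 200, planted_size = 20, overlap = 7,
                               seed = 1)
  mouse13 <- gene_list(mouse_vz_genes(), species = "mouse")
  mapped <- suppressMessages(map_orthologs(mouse13, direction = "mouse_to_human"))
  shared <- intersect(mapped$members, hs$truth$planted$members)
  expect_length(shared, 7)
})

test_that("planted zone fold is delivered at the stated rate across replicates", {
  ratios <- vapply(1:50, function(seed) {
    sim <- small_mouse_atlas(n_genes = 120, seed = seed)
    v <- sim$expr$values[sim$truth$planted$members, ]
    s <- sim$expr$samples
    tgt <- s$structure == "VZ" & s$age == "E15.5"
    mean(rowMeans(v[, tgt, drop = FALSE]) / rowMeans(v[, !tgt]) >= 6)
  }, numeric(1))
  expect_gte(mean(ratios == 1), 0.95)
})

test_that("raising the planted fold never loses six-fold passers (matched seeds)", {
  for (seed in 1:5) {
    lo <- simulate_human_spatial(n_genes = 200, planted_size = 20,
                                 planted_fold = 8, seed = seed)
    hi <- simulate_human_spatial(n_genes = 200, planted_size = 20,
                                 planted_fold = 16, seed = seed)
    n_lo <- sum(fold_change(lo$expr, zone_contrast(lo$expr))[
      lo$truth$planted$members] >= 6)
    n_hi <- sum(fold_change(hi$expr, zone_contrast(hi$expr))[
      hi$truth$planted$members] >= 6)
    expect_gte(n_hi, n_lo)
  }
})

test_that("compendium wiring: exact clique at p_within = 1, elevated module degree otherwise", {
  q <- sprintf("Q%02d", 1:6)
  uni <- c(q, sprintf("D%03d", 1:60))
  nets <- simulate_association_compendium(uni, q, k_assoc = 10,
                                          p_within = 1, p_assoc = 0,
                                          p_background = 0, seed = 2)
  for (g in nets) {
    sub <- igraph::induced_subgraph(g, q)
    expect_equal(igraph::ecount(sub), choose(length(q), 2))
    expect_equal(igraph::ecount(g), choose(length(q), 2))  # nothing else
  }

  deg_gap <- vapply(1:10, function(seed) {
    nets <- simulate_association_compendium(uni, q, k_assoc = 10, seed = seed)
    comp <- combine_networks(nets)
    deg <- igraph::strength(comp)
    mean(deg[q]) - mean(deg[setdiff(uni, q)])
  }, numeric(1))
  expect_gt(mean(deg_gap), 0)
})

test_that("annotation generator: planted saturation, printed-size C column, universe guard", {
  uni <- sprintf("G%04d", 1:600)
  planted <- uni[1:25]
  sets <- simulate_annotations(uni, planted, set_sizes = 25,
                               enriched_fraction = 1, n_background = 1,
                               seed = 3)
  expect_setequal(sets$enriched_set_01, planted)  # O = C for that set

  default_sets <- simulate_annotations(sprintf("H%04d", 1:2000),
                                       sprintf("H%04d", 1:60), seed = 1)
  expect_identical(unname(lengths(default_sets[attr(default_sets, "enriched")])),
                   c(318L, 261L, 242L, 158L, 99L, 141L, 307L, 118L, 109L, 121L))

  expect_error(simulate_annotations(uni[1:50], planted[1:5], set_sizes = 100),
               "universe")
})
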