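make_two_group_expr <- function(values_a, values_b, n_genes = 1) {
  n_a <- length(values_a); n_b <- length(values_b)
  vals <- matrix(rep(c(values_a, values_b), each = n_genes),
                 nrow = n_genes, byrow = FALSE)
  rownames(vals) <- sprintf("G%02d", seq_len(n_genes))
  colnames(vals) <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  samples <- data.frame(
    sample_id = colnames(vals),
    structure = c(rep("VZ", n_a), rep("CP", n_b)),
    age = "E15.5", species = "mouse"
  )
  ex <- expr_set(vals, samples)
  list(expr = ex,
       contrast = make_contrast(ex, "a vs b", paste0("a", seq_len(n_a))))
}

test_that("fold change is a pseudocounted mean ratio, scale invariant", {
  f <- make_two_group_expr(c(5, 5), c(5, 5))
  expect_equal(unname(fold_change(f$expr, f$contrast)), 1)
  f <- make_two_group_expr(c(12, 12), c(2, 2))
  expect_equal(unname(fold_change(f$expr, f$contrast)), 6, tolerance = 1e-8)
  scaled <- expr_set(f$expr$values * 10, f$expr$samples)
  expect_equal(fold_change(scaled, f$contrast), fold_change(f$expr, f$contrast),
               tolerance = 1e-8)
})

test_that("welch_p matches stats::t.test on log2 scale and is symmetric", {
  f <- make_two_group_expr(c(10, 11, 12), c(1, 1.2, 0.9))
  ref <- stats::t.test(log2(c(10, 11, 12) + 1), log2(c(1, 1.2, 0.9) + 1),
                       var.equal = FALSE)$p.value
  expect_equal(welch_p(f$expr, f$contrast, "G01"), ref, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    a <- rlnorm(4 + i %% 3); b <- rlnorm(5)
    f <- make_two_group_expr(a, b)
    ref <- stats::t.test(log2(a + 1), log2(b + 1), var.equal = FALSE)$p.value
    expect_equal(welch_p(f$expr, f$contrast, "G01"), ref, tolerance = 1e-12)
    swapped <- make_contrast(f$expr, "b vs a",
                             grep("^b", colnames(f$expr$values), value = TRUE))
    expect_equal(welch_p(f$expr, swapped, "G01"),
                 welch_p(f$expr, f$contrast, "G01"), tolerance = 1e-12)
  }

  # degenerate conventions
  f <- make_two_group_expr(c(3, 3), c(3, 3))
  expect_equal(welch_p(f$expr, f$contrast, "G01"), 1)
  f <- make_two_group_expr(c(3, 3), c(9, 9))
  expect_equal(welch_p(f$expr, f$contrast, "G01"), .Machine$double.xmin)
})

test_that("Holm adjustment matches hand computation and the step-down oracle", {
  one <- holm_bonferroni(0.03, alpha = 0.05)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$reject)

  h <- holm_bonferroni(c(1e-12, 1e-10, 0.5), alpha = 1e-9)
  expect_equal(h$adjusted, c(3e-12, 2e-10, 0.5), tolerance = 1e-12)
  expect_identical(h$reject, c(TRUE, TRUE, FALSE))

  expect_false(any(holm_bonferroni(rep(1, 5), alpha = 0.05)$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (m in c(1, 2, 10, 1000, 10000)) {
    p <- runif(m)^2
    expect_equal(holm_bonferroni(p)$adjusted, holm_oracle(p), tolerance = 1e-12)
  }
})

test_that("rejection nesting: Bonferroni within Holm within BH at equal alpha", {
  set.seed(32)
  for (i in 1:20) {
    p <- runif(50)^3
    alpha <- 0.05
    bonf <- p * length(p) < alpha
    holm <- holm_bonferroni(p, alpha)$reject
    bh <- bh_fdr(p) < alpha
    expect_true(all(!bonf | holm))  # bonferroni => holm
    expect_true(all(!holm | bh))   # holm => bh
  }
})

test_that("screen recovers the planted set: exact in the noise-free limit, near-complete by default", {
  hs0 <- simulate_human_spatial(n_genes = 300, planted_size = 25, sigma = 0,
                                seed = 41)
  scr0 <- run_screen(hs0$expr, zone_contrast(hs0$expr))
  expect_setequal(scr0$gene[scr0$pass], hs0$truth$planted$members)

  hs <- simulate_human_spatial(seed = 1)
  scr <- run_screen(hs$expr, zone_contrast(hs$expr))
  hits <- scr$gene[scr$pass]
  planted <- hs$truth$planted$members
  expect_gte(length(intersect(hits, planted)) / length(planted), 0.95)
  expect_true(all(hits %in% planted))  # no decoy passes at alpha = 1e-9

  # vanishingly small alpha empties the pass set
  scr_tiny <- run_screen(hs0$expr, zone_contrast(hs0$expr),
                         pipeline_config(alpha = .Machine$double.xmin))
  expect_equal(sum(scr_tiny$pass), 0)
})

test_that("screen pass-set is invariant under global matrix scaling", {
  hs <- simulate_human_spatial(n_genes = 250, planted_size = 20, seed = 42)
  scr <- run_screen(hs$expr, zone_contrast(hs$expr))
  scaled <- expr_set(hs$expr$values * 1000, hs$expr$samples)
  scr_s <- run_screen(scaled, zone_contrast(scaled))
  expect_setequal(scr$gene[scr$pass], scr_s$gene[scr_s$pass])
})

test_that("pure-null screens produce essentially no passes at alpha = 1e-9", {
  passes <- vapply(1:100, function(seed) {
    null_sim <- simulate_human_spatial(n_genes = 200, planted_size = 1,
                                       planted_fold = 1.0001, n_reps = 1,
                                       overlap = 0, seed = seed)
    scr <- run_screen(null_sim$expr, zone_contrast(null_sim$expr))
    sum(scr$pass)
  }, numeric(1))
  expect_lte(sum(passes), 1)
})
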