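test_that("the row t-test matches hand-worked and stats::t.test results", {
  m <- matrix(c(5, 6, 7, 1, 2, 3), nrow = 1,
              dimnames = list("g1", paste0("S", 1:6)))
  tab <- deg_ttest(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(tab$Log2FC, 4)
  expect_equal(tab$T, 4 / sqrt(2 / 3), tolerance = 1e-12)   # pooled SD 1, df 4
  expect_equal(tab$P, 2 * pt(-4 / sqrt(2 / 3), df = 4), tolerance = 1e-12)

  # cross-check pooled and Welch modes against stats::t.test per gene
  mm <- random_expr(20, 9, seed = 31)
  a <- colnames(mm)[1:4]; b <- colnames(mm)[5:9]
  pooled <- deg_ttest(mm, a, b)
  welch <- deg_ttest(mm, a, b, variance = "welch")
  for (i in c(1, 7, 20)) {
    tp <- t.test(mm[i, a], mm[i, b], var.equal = TRUE)
    tw <- t.test(mm[i, a], mm[i, b])
    expect_equal(pooled$T[i], unname(tp$statistic), tolerance = 1e-12)
    expect_equal(pooled$P[i], tp$p.value, tolerance = 1e-12)
    expect_equal(welch$T[i], unname(tw$statistic), tolerance = 1e-12)
    expect_equal(welch$P[i], tw$p.value, tolerance = 1e-12)
  }
})

test_that("t-test symmetry and degenerate-variance conventions hold", {
  m <- rbind(random_expr(5, 8, seed = 12),
             flat = 4, shifted = rep(c(2, 3), each = 4))
  a <- colnames(m)[1:4]; b <- colnames(m)[5:8]
  ab <- deg_ttest(m, a, b)
  ba <- deg_ttest(m, b, a)
  expect_equal(ba$T, -ab$T)
  expect_equal(ba$P, ab$P)

  expect_equal(ab[ab$Gene == "flat", "T"], 0)      # identical groups
  expect_equal(ab[ab$Gene == "flat", "P"], 1)
  expect_equal(ab[ab$Gene == "shifted", "P"], 0)   # zero variance, shifted
  expect_true(ab[ab$Gene == "shifted", "ZeroVariance"])

  expect_error(deg_ttest(m, a, a), "overlap")
  expect_error(deg_ttest(m, a[1], b), ">= 2 samples")
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)            # n = 1 identity
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))  # cap at 1
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_adjust(p) - oracle_bh(p))), 1e-12)
  }
})

test_that("DEG calling applies both thresholds and is monotone", {
  m <- random_expr(200, 12, seed = 41)
  m[1:20, 7:12] <- m[1:20, 7:12] + 3
  tab <- deg_ttest(m, colnames(m)[7:12], colnames(m)[1:6])
  vac <- call_degs(tab, min_abs_log2fc = 0, max_adj_p = 1)
  expect_identical(deg_count(vac), nrow(m))      # vacuous thresholds

  d1 <- deg_count(call_degs(tab, 1, 0.05))
  d2 <- deg_count(call_degs(tab, 1, 0.01))
  d3 <- deg_count(call_degs(tab, 2, 0.05))
  expect_lte(d2, d1)
  expect_lte(d3, d1)
  one <- call_degs(tab, 1, 0.05)
  expect_true(all(one$Significant ==
                    (abs(one$Log2FC) >= 1 & one$AdjP <= 0.05)))
})

test_that("an empty outlier report leaves the before/after comparison unchanged", {
  sim <- simulate_bulk(n_outlier_controls = 0, seed = 17)
  fit <- suppressMessages(mdp(sim$expr, sim$pheno))
  rep <- flag_outliers(fit, k = 1e6)             # nothing flagged
  cmp <- compare_outlier_removal(sim$expr, sim$pheno, rep, "disease", "healthy")
  expect_identical(cmp$count_before, cmp$count_after)
  expect_equal(cmp$fold_change, 1)
})

test_that("type-I error of the t-test wiring is calibrated on null data", {
  sim <- simulate_bulk(n_genes = 2000, n_controls = 10,
                       n_cases = c(disease = 10), n_signal_genes = 0,
                       n_outlier_controls = 0, seed = 50)
  tab <- deg_ttest(sim$expr, sim$pheno$Sample[11:20], sim$pheno$Sample[1:10])
  frac <- mean(tab$P < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("the random-removal null is seeded, stratified, and degenerate-safe", {
  sim <- simulate_preset("outlier-cohort", seed = 4)
  base <- deg_count(call_degs(deg_ttest(
    sim$expr, sim$pheno$Sample[sim$pheno$Class == "disease"],
    sim$pheno$Sample[sim$pheno$Class == "healthy"])))

  # zero removals: every rep equals the baseline
  n0 <- random_removal_null(sim$expr, sim$pheno, c(disease = 0L),
                            "disease", "healthy", reps = 5, seed = 1)
  expect_true(all(n0$counts == base))
  expect_equal(n0$sd, 0)

  n1 <- random_removal_null(sim$expr, sim$pheno, c(healthy = 1L, disease = 2L),
                            "disease", "healthy", reps = 20, seed = 7)
  n2 <- random_removal_null(sim$expr, sim$pheno, c(healthy = 1L, disease = 2L),
                            "disease", "healthy", reps = 20, seed = 7)
  expect_identical(n1$counts, n2$counts)         # same seed, same vector
  expect_length(n1$counts, 20L)
  n3 <- random_removal_null(sim$expr, sim$pheno, c(healthy = 1L, disease = 2L),
                            "disease", "healthy", reps = 20, seed = 8)
  expect_false(identical(n1$counts, n3$counts))  # different seed differs

  expect_error(random_removal_null(sim$expr, sim$pheno, c(healthy = 11L),
                                   "disease", "healthy", reps = 2, seed = 1),
               "leaves < 2")
})

test_that("outlier removal beats the random-removal null on planted data", {
  sim <- simulate_preset("outlier-cohort", seed = 11)
  fit <- suppressMessages(mdp(sim$expr, sim$pheno))
  rep <- flag_outliers(fit)
  cmp <- compare_outlier_removal(sim$expr, sim$pheno, rep, "disease", "healthy")
  expect_gt(cmp$count_after, cmp$count_before)
  rc <- table(rep$Class[rep$Flagged])
  null <- random_removal_null(sim$expr, sim$pheno, rc, "disease", "healthy",
                              reps = 30, seed = 11)
  expect_gt(cmp$count_after, null$mean)
})
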