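test_that("gene stats match hand-worked values in both estimator modes", {
  m <- matrix(c(1, 2, 3, 4, 5,
                7, 7, 7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("C", 1:5)))
  st <- estimate_gene_stats(m, colnames(m))
  # median 3, raw MAD 1, rescaled 1.4826
  expect_equal(st$Center, c(3, 7))
  expect_equal(st$Scale, c(1.4826, 0))
  expect_identical(st$Degenerate, c(FALSE, TRUE))

  m2 <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g1", paste0("C", 1:3)))
  st2 <- estimate_gene_stats(m2, colnames(m2),
                             mdp_control(center = "mean", scale = "sd"))
  expect_equal(st2$Center, 2)
  expect_equal(st2$Scale, 1)

  expect_error(estimate_gene_stats(m, "C1"), "at least 2 control")
})

test_that("z-scores follow |x - m|/s with strict-below-cutoff zeroing", {
  ctrl <- mdp_control()
  st <- data.frame(Gene = c("g1", "g2", "g3"),
                   Center = c(3, 0, 5), Scale = c(1.4826, 1, 0),
                   Degenerate = c(FALSE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  m <- matrix(c(6,    3,
                1.9,  2.0,
                9,    1), nrow = 3, byrow = TRUE,
              dimnames = list(st$Gene, c("S1", "S2")))
  z <- suppressMessages(compute_z(m, st, ctrl))
  expect_equal(z["g1", "S1"], 3 / 1.4826)       # ~2.0235, survives cutoff 2
  expect_equal(z["g1", "S2"], 0)                # x equals the center
  expect_equal(z["g2", "S1"], 0)                # 1.9 < 2 is zeroed
  expect_equal(z["g2", "S2"], 2.0)              # exactly 2 survives
  expect_equal(unname(z["g3", ]), c(0, 0))      # degenerate row
  expect_true(all(z == 0 | z >= 2))
})

test_that("perturbed-gene ranking keeps the top fraction, stably", {
  z <- matrix(c(0, 0.5, 3.0, 1.2), nrow = 4, ncol = 3,
              dimnames = list(paste0("g", 1:4), paste0("P", 1:3)))
  pg <- rank_perturbed_genes(z, colnames(z), mdp_control(perturbed_fraction = 0.5))
  expect_identical(pg$Gene, c("g3", "g4"))
  expect_equal(pg$RankStat, c(3.0, 1.2))

  z8 <- matrix(runif(8 * 2), nrow = 8,
               dimnames = list(paste0("g", 1:8), c("P1", "P2")))
  expect_identical(nrow(rank_perturbed_genes(z8, colnames(z8))), 2L)  # floor(0.25*8)

  z3 <- z8[1:3, ]
  expect_identical(nrow(rank_perturbed_genes(z3, colnames(z3))), 1L)  # max(1, floor)

  # ties broken by input gene order
  zt <- matrix(1, nrow = 4, ncol = 2,
               dimnames = list(paste0("g", 1:4), c("P1", "P2")))
  expect_identical(rank_perturbed_genes(zt, colnames(zt),
                                        mdp_control(perturbed_fraction = 0.5))$Gene,
                   c("g1", "g2"))
  expect_error(rank_perturbed_genes(z, character()), "empty")
})

test_that("sample scores are universe means with intersection semantics", {
  z <- matrix(c(0, 0, 2.5, 3.5), nrow = 4,
              dimnames = list(paste0("g", 1:4), "S1"))
  expect_equal(score_samples(z)$Score, 1.5)
  expect_equal(score_samples(z, c("g3", "g4"), "pair")$Score, 3.0)
  # explicit full list == ALL
  expect_equal(score_samples(z, paste0("g", 1:4), "x")$Score,
               score_samples(z)$Score)
  # absent genes are dropped, size reported
  s <- score_samples(z, c("g3", "g4", "missing"), "pair")
  expect_identical(attr(s, "n_genes"), 2L)
  expect_error(score_samples(z, c("nope"), "empty_set"), "empty_set")
})

test_that("gene-set scoring skips undersized sets with a warning", {
  z <- matrix(c(0, 0, 2.5, 3.5), nrow = 4,
              dimnames = list(paste0("g", 1:4), "S1"))
  sets <- list(small = c("g1", "g2"), all = paste0("g", 1:4))
  expect_warning(out <- score_gene_sets(z, sets, min_size = 3),
                 "small")
  expect_identical(names(out), "all")
  expect_identical(attr(out, "skipped"), "small")
  expect_equal(out$all$Score, score_samples(z)$Score)
})

test_that("the fit agrees with the brute-force oracle on random matrices", {
  for (seed in 1:5) {
    m <- random_expr(50, 20, seed = seed)
    ph <- two_class_pheno(m, n_controls = 8)
    fit <- suppressMessages(mdp(m, ph))
    ctrl_ids <- ph$Sample[ph$Class == "healthy"]
    case_ids <- ph$Sample[ph$Class == "disease"]

    o <- oracle_gene_stats(m, ctrl_ids)
    expect_lt(max(abs(fit$gene_stats$Center - o$center)), 1e-10)
    expect_lt(max(abs(fit$gene_stats$Scale - o$scale)), 1e-10)

    oz <- oracle_z(m, o$center, o$scale)
    expect_lt(max(abs(fit$z - oz)), 1e-10)

    expect_identical(fit$perturbed_genes$Gene, oracle_perturbed(oz, case_ids))
    expect_lt(max(abs(mdp_scores(fit, "allgenes")$Score - oracle_scores(oz))),
              1e-10)
    expect_lt(max(abs(mdp_scores(fit, "perturbedgenes")$Score -
                        oracle_scores(oz, fit$perturbed_genes$Gene))), 1e-10)
  }
})

test_that("a sample equal to the control centers scores zero in every universe", {
  m <- random_expr(40, 10, seed = 3)
  st <- estimate_gene_stats(m, colnames(m)[1:6])
  m <- cbind(m, probe = st$Center)           # plant a center-identical sample
  ph <- data.frame(Sample = colnames(m),
                   Class = c(rep("healthy", 6), rep("disease", 5)),
                   stringsAsFactors = FALSE)
  fit <- suppressMessages(mdp(m, ph))
  sc <- fit$scores[fit$scores$Sample == "probe", ]
  expect_true(all(sc$Score == 0))
})

test_that("the z matrix is invariant under per-gene positive affine maps", {
  m <- random_expr(30, 12, seed = 9)
  ph <- two_class_pheno(m, n_controls = 6)
  a <- runif(nrow(m), 0.5, 3)
  b <- rnorm(nrow(m), sd = 10)
  m2 <- m * a + b
  for (ctrl in list(mdp_control(),
                    mdp_control(center = "mean", scale = "sd"))) {
    f1 <- suppressMessages(mdp(m, ph, control = ctrl))
    f2 <- suppressMessages(mdp(m2, ph, control = ctrl))
    expect_lt(max(abs(f1$z - f2$z)), 1e-9)
  }
})

test_that("mean perturbedgenes score dominates mean allgenes score on the ranking group", {
  for (seed in 1:5) {
    sim <- simulate_bulk(n_signal_genes = 40, effect_size = 1.5, seed = seed)
    fit <- suppressMessages(mdp(sim$expr, sim$pheno))
    cases <- fit$pheno$Sample[fit$pheno$Class != "healthy"]
    sa <- mdp_scores(fit, "allgenes")
    sp <- mdp_scores(fit, "perturbedgenes")
    expect_gte(mean(sp$Score[sp$Sample %in% cases]),
               mean(sa$Score[sa$Sample %in% cases]))
  }
})

test_that("permuting the sample order permutes all outputs identically", {
  m <- random_expr(30, 12, seed = 21)
  ph <- two_class_pheno(m, n_controls = 6)
  set.seed(1)
  perm <- sample(ncol(m))
  f1 <- suppressMessages(mdp(m, ph))
  f2 <- suppressMessages(mdp(m[, perm], ph[perm, , drop = FALSE]))
  expect_equal(f1$z[, colnames(m)[perm]], f2$z, ignore_attr = TRUE)
  s1 <- mdp_scores(f1, "allgenes"); s2 <- mdp_scores(f2, "allgenes")
  expect_equal(s2$Score[match(s1$Sample, s2$Sample)], s1$Score)
  expect_identical(f1$perturbed_genes, f2$perturbed_genes)
})

test_that("the same inputs give bit-identical fits", {
  m <- random_expr(25, 10, seed = 4)
  ph <- two_class_pheno(m, n_controls = 5)
  f1 <- suppressMessages(mdp(m, ph))
  f2 <- suppressMessages(mdp(m, ph))
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("per-class ranking produces one perturbed universe per case class", {
  m <- random_expr(40, 12, seed = 5)
  ph <- data.frame(Sample = colnames(m),
                   Class = rep(c("healthy", "flu", "sepsis"), each = 4),
                   stringsAsFactors = FALSE)
  fit <- suppressMessages(mdp(m, ph, control = mdp_control(ranking = "per_class")))
  expect_setequal(names(fit$perturbed_genes), c("flu", "sepsis"))
  expect_true(all(c("perturbedgenes_flu", "perturbedgenes_sepsis") %in%
                    unique(fit$scores$Universe)))
})

test_that("gmt universes are scored through the fit", {
  m <- random_expr(40, 10, seed = 6)
  ph <- two_class_pheno(m, n_controls = 5)
  sets <- structure(list(mod1 = rownames(m)[1:10],
                         everything = rownames(m)), class = "gmt")
  fit <- suppressMessages(mdp(m, ph, gene_sets = sets))
  expect_equal(mdp_scores(fit, "everything")$Score,
               mdp_scores(fit, "allgenes")$Score)
  expect_identical(unname(fit$universe_sizes["mod1"]), 10L)
})
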