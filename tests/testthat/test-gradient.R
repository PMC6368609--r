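bulk_frame <- function() {
  meta <- expand.grid(replicate = c("r1", "r2"),
                      cell_type = names(default_cell_type_ranks()),
                      donor = paste0("D", 1:6), stringsAsFactors = FALSE)
  meta$rank <- rank_cell_types(meta$cell_type)
  meta
}

test_that("cell-type ranks follow the canonical gradient order", {
  expect_equal(rank_cell_types("NK"), 7L)
  expect_equal(rank_cell_types("CD4 T"), 1L)
  expect_equal(rank_cell_types(c("MAIT", "Vd2")), c(3L, 6L))
  expect_error(rank_cell_types("B cell"), "B cell")
})

test_that("noiseless gradient gene recovers beta = 1 with vanishing p", {
  meta <- bulk_frame()
  y <- meta$rank + 1e-9 * seq_len(nrow(meta))  # epsilon breaks exact fit
  fit <- fit_lmm_association(y, meta$rank, meta$donor)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_lt(fit$p, 1e-12)
})

test_that("mixed-model beta equals OLS beta when donor variance is zero", {
  meta <- bulk_frame()
  set.seed(8)
  y <- 2 + 0.3 * meta$rank + rnorm(nrow(meta), sd = 0.5)
  fit <- fit_lmm_association(y, meta$rank, meta$donor)
  ols <- unname(coef(lm(y ~ meta$rank))[2L])
  expect_equal(fit$beta, ols, tolerance = 1e-6)
})

test_that("beta is invariant to rank shifts and scales inversely", {
  meta <- bulk_frame()
  set.seed(21)
  donor_eff <- rnorm(6, sd = 0.5)[match(meta$donor, unique(meta$donor))]
  y <- 1 + 0.4 * meta$rank + donor_eff + rnorm(nrow(meta), sd = 0.3)
  base <- fit_lmm_association(y, meta$rank, meta$donor)
  shift <- fit_lmm_association(y, meta$rank + 10, meta$donor)
  scaled <- fit_lmm_association(y, meta$rank * 3, meta$donor)
  expect_equal(shift$beta, base$beta, tolerance = 1e-6)
  expect_equal(scaled$beta, base$beta / 3, tolerance = 1e-6)
  expect_equal(shift$lrt, base$lrt, tolerance = 1e-4)
})

test_that("LRT statistic is nonnegative over random genes", {
  meta <- bulk_frame()
  set.seed(31)
  for (i in 1:20) {
    donor_eff <- rnorm(6, sd = runif(1, 0, 1))
    y <- rnorm(nrow(meta)) + donor_eff[match(meta$donor,
                                             unique(meta$donor))]
    fit <- fit_lmm_association(y, meta$rank, meta$donor)
    expect_gte(fit$lrt, 0)
    expect_true(fit$p >= 0 && fit$p <= 1)
  }
})

test_that("input validation: constant predictor, single donor", {
  meta <- bulk_frame()
  y <- rnorm(nrow(meta))
  expect_error(fit_lmm_association(y, rep(1, nrow(meta)), meta$donor),
               "constant")
  expect_error(fit_lmm_association(y[1:14], meta$rank[1:14],
                                   rep("D1", 14)), "2 donors")
})

test_that("single-cell fit enforces the nonzero-cell filter boundary", {
  set.seed(41)
  n <- 300
  pred <- sample(1:7, n, replace = TRUE)
  y99 <- c(rexp(99), rep(0, n - 99))
  fit <- fit_lm_association_sc(y99, pred, min_nonzero_cells = 100L)
  expect_true(fit$skipped)
  y100 <- c(rexp(100), rep(0, n - 100))
  expect_false(fit_lm_association_sc(y100, pred,
                                     min_nonzero_cells = 100L)$skipped)
})

test_that("single-cell fit recovers a deterministic slope and flags collinearity", {
  set.seed(42)
  n <- 200
  pred <- sample(1:7, n, replace = TRUE)
  y <- pred + rnorm(n, sd = 1e-6)
  fit <- fit_lm_association_sc(y, pred, min_nonzero_cells = 10L)
  expect_equal(fit$beta, 1, tolerance = 1e-4)
  covs <- data.frame(c1 = rnorm(n))
  covs$c2 <- 2 * covs$c1
  expect_error(fit_lm_association_sc(y, pred, covs,
                                     min_nonzero_cells = 10L),
               "collinear")
})

test_that("single-cell recovery: planted betas within 2 s.e. for >= 90% of genes", {
  set.seed(43)
  n_cells <- 400; n_genes <- 60
  pred <- sample(1:7, n_cells, replace = TRUE)
  depth <- exp(rnorm(n_cells, 8, 0.3))
  mito <- runif(n_cells, 0, 10)
  covs <- data.frame(log_umi = log(depth), pct_mito = mito)
  beta <- runif(n_genes, -0.3, 0.3)
  hits <- 0
  for (g in seq_len(n_genes)) {
    y <- 1 + beta[g] * pred + 0.2 * covs$log_umi + rnorm(n_cells, sd = 0.8)
    fit <- fit_lm_association_sc(y, pred, covs, min_nonzero_cells = 10L)
    if (abs(fit$beta - beta[g]) <= 2 * fit$se) hits <- hits + 1
  }
  expect_gte(hits / n_genes, 0.90)
})

test_that("one-vs-rest finds a subset-restricted gene and rejects constants", {
  set.seed(44)
  n <- 500
  subset <- rep(c(TRUE, FALSE), length.out = n)
  vals <- rbind(marker = ifelse(subset, rexp(n) + 1, 0),
                flat = rexp(n))
  colnames(vals) <- sprintf("c%03d", 1:n)
  m <- expression_matrix(vals, data.frame(sample = colnames(vals)),
                         "counts")
  ln <- sc_normalize(m)
  de <- de_one_vs_rest(ln, subset, min_nonzero_cells = 60L)
  expect_gt(de$beta[de$gene == "marker"], 0)
  expect_true(de$significant[de$gene == "marker"])
  expect_error(de_one_vs_rest(ln, rep(TRUE, n)), "constant")
})

test_that("Bonferroni threshold is alpha over tests", {
  expect_equal(signif(bonferroni_threshold(0.05, 19931), 2), 2.5e-06)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("one-way ANOVA F matches the anova() oracle and handles degeneracy", {
  expect_equal(anova_f(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2)), 16)
  near_zero <- anova_f(c(1, 2, 1, 2, 1, 2), rep(1:3, each = 2))
  expect_lt(near_zero, 1e-10)
  f_inf <- anova_f(c(1, 1, 2, 2), rep(1:2, each = 2))
  expect_true(isTRUE(attr(f_inf, "unbounded")))
  expect_true(is.finite(f_inf))
  expect_error(anova_f(1:3, c(1, 1, 2)), ">= 2 samples")
})

test_that("concordance summarizes agreement of effect directions", {
  a <- c(g1 = 1, g2 = -2, g3 = 3, g4 = 0.5)
  expect_equal(concordance(a, a), list(rho = 1, sign_concordance = 1))
  expect_equal(concordance(a, -a), list(rho = -1, sign_concordance = 0))
  b <- c(g1 = 2, g2 = -1, g3 = 0, g4 = 1)  # zero excluded from signs
  expect_equal(concordance(a, b)$sign_concordance, 1)
  expect_error(concordance(a, c(x = 1)), ">= 3")
})
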