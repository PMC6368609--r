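test_that("mHG handles the degenerate and hand-checked cases", {
  expect_equal(mhg_test(rep(FALSE, 5))$p, 1)
  r <- mhg_test(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$stat, 1 / 6)
  expect_equal(r$p, 1 / 6)  # only 1 of the C(4,2)=6 orderings as extreme
  expect_equal(r$n_opt, 2L)
  all_in <- mhg_test(rep(TRUE, 4))
  expect_equal(all_in$p, 1)
})

test_that("mHG exact p equals exhaustive enumeration on random orderings", {
  set.seed(55)
  for (i in 1:60) {
    N <- sample(3:12, 1)
    K <- sample(1:N, 1)
    mem <- rep(FALSE, N)
    mem[sample(N, K)] <- TRUE
    res <- mhg_test(mem)
    expect_equal(res$p, oracle_mhg_p(mem), tolerance = 1e-12)
    expect_equal(res$stat, oracle_mhg_stat(mem), tolerance = 1e-12)
    expect_gte(res$p, res$stat - 1e-12)
  }
})

test_that("promoting a member gene never worsens the mHG statistic", {
  set.seed(56)
  for (i in 1:50) {
    N <- sample(5:40, 1)
    mem <- runif(N) < 0.3
    if (!any(mem) || all(mem)) next
    movable <- which(mem)[vapply(which(mem), function(p)
      any(!mem[seq_len(p)]), logical(1))]
    if (!length(movable)) next
    pos <- movable[sample(length(movable), 1)]
    dest <- max(which(!mem[seq_len(pos)]))
    mem2 <- mem
    mem2[c(dest, pos)] <- c(TRUE, FALSE)
    expect_lte(mhg_test(mem2)$stat, mhg_test(mem)$stat + 1e-15)
  }
})

test_that("gradient gene-set enrichment detects a planted innate set", {
  sim <- simulate_bulk(bulk_sim_design(seed = 61L))
  mlog <- log_transform_bulk(sim$matrix)
  fit <- data.frame(gene = sim$truth$gene, beta = NA_real_)
  ranks <- rank_cell_types(mlog$meta$cell_type)
  X <- cbind(1, ranks)
  fit$beta <- solve(crossprod(X), crossprod(X, t(mlog$values)))[2, ]
  up <- sim$truth$gene[sim$truth$beta_true > 0.2]
  planted <- list(innate_like = sample(up, min(25, length(up))))
  res_in <- go_enrichment(fit, planted, "innate")
  expect_lt(res_in$p, 0.01)
  res_ad <- go_enrichment(fit, planted, "adaptive")
  expect_gt(res_ad$p, 0.5)
  expect_warning(
    out <- go_enrichment(fit, c(planted, list(alien = c("nope1", "nope2"))),
                         "innate"),
    "disjoint")
  expect_false("alien" %in% out$set)
})

test_that("pathway F test matches the exact rank-sum tail", {
  f <- c(setNames(101:105, paste0("p", 1:5)),
         setNames(seq(1, 20), paste0("q", 1:20)))
  p <- pathway_f_test(f, paste0("p", 1:5))
  expect_equal(p, 1 / choose(25, 5), tolerance = 1e-12)
  same <- c(setNames(c(1, 2), c("a", "b")), setNames(c(1, 2), c("c", "d")))
  expect_gte(suppressWarnings(pathway_f_test(same, c("a", "b"))), 0.5)
  expect_error(pathway_f_test(f, names(f)), "universe")
  expect_error(pathway_f_test(f, "absent"), "no pathway gene")
})

test_that("matched-null candidates respect the expression tolerance and seed", {
  set.seed(65)
  n <- 400
  f <- setNames(rf(n, 6, 70), sprintf("g%03d", 1:n))
  mu <- setNames(runif(n, 0, 10), names(f))
  path <- sample(names(f), 15)
  a <- matched_null_f_test(f, path, mu, seed = 7L)
  b <- matched_null_f_test(f, path, mu, seed = 7L)
  expect_identical(a$null_genes, b$null_genes)
  window <- 0.10 * sd(mu)
  nulls_per_gene <- split(a$null_genes,
                          rep(path, each = length(a$null_genes) / length(path)))
  for (g in path)
    expect_true(all(abs(mu[nulls_per_gene[[g]]] - mu[g]) <= window))
  expect_false(any(a$null_genes %in% path))
})

test_that("matched-null relaxes an empty pool to the nearest gene and flags it", {
  f <- setNames(rep(1, 5), c("far", "n1", "n2", "n3", "n4"))
  mu <- setNames(c(100, 1, 1.1, 1.2, 1.3), names(f))
  res <- matched_null_f_test(f, "far", mu, n_matched = 2L, seed = 1L)
  expect_identical(res$relaxed_pools, "far")
  expect_true(all(res$null_genes == "n4"))  # nearest by mean expression
})

test_that("matched-null test flags planted signal but not matched noise", {
  set.seed(66)
  n <- 600
  mu <- setNames(runif(n, 0, 10), sprintf("g%03d", 1:n))
  f0 <- setNames(rf(n, 6, 70), names(mu))
  path <- sample(names(mu), 20)
  f1 <- f0
  f1[path] <- f1[path] * 2 + 2 * median(f0)
  expect_lt(matched_null_f_test(f1, path, mu, seed = 1L)$p, 0.05)
  # infinite tolerance reduces to a random-subsample comparison
  pv <- vapply(1:60, function(i) {
    pth <- sample(names(mu), 20)
    matched_null_f_test(f0, pth, mu, tolerance = Inf, seed = i)$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("peak-to-gene windows match the spec geometry", {
  gene_p <- data.frame(gene = "gP", chrom = "chr1", start = 3000,
                       end = 5000, strand = "+")
  near <- data.frame(chrom = "chr1", start = 1000, end = 1100, name = "a")
  far <- data.frame(chrom = "chr1", start = 100, end = 200, name = "b")
  expect_true(assign_peak_targets(near, gene_p, "body2kb")$is_target)
  expect_false(assign_peak_targets(far, gene_p, "body2kb")$is_target)
  gene_m <- data.frame(gene = "gM", chrom = "chr1", start = 3000,
                       end = 5000, strand = "-")
  up <- data.frame(chrom = "chr1", start = 5500, end = 5600, name = "c")
  expect_true(assign_peak_targets(up, gene_m, "promoter")$is_target)
  other_chrom <- data.frame(chrom = "chrX", start = 3000, end = 3100,
                            name = "d")
  res <- assign_peak_targets(other_chrom, gene_p, "body2kb")
  expect_false(res$is_target)
  expect_equal(attr(res, "n_skipped_peaks"), 1L)
})

test_that("peak targeting agrees with a per-base oracle on random genomes", {
  set.seed(71)
  for (i in 1:40) {
    gene <- data.frame(gene = "g", chrom = sample(c("c1", "c2"), 1),
                       start = sample(2000:4000, 1), strand = sample(c("+", "-"), 1))
    gene$end <- gene$start + sample(50:2000, 1)
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 3, replace = TRUE),
                        start = sample(0:8000, 3), name = paste0("p", 1:3))
    peaks$end <- peaks$start + sample(10:300, 3)
    for (rule in c("body2kb", "promoter")) {
      got <- assign_peak_targets(peaks, gene, rule)$is_target
      expect_identical(got, oracle_peak_target(peaks, gene, rule),
                       info = paste(rule, i))
    }
  }
})

test_that("ortholog filter keeps exactly the 1-to-1 pairs", {
  tab <- data.frame(mouse = c("a1", "a2"), human = c("b1", "b2"))
  expect_equal(nrow(ortholog_filter(tab)), 2L)
  dup_a <- data.frame(mouse = c("a1", "a1"), human = c("b1", "b2"))
  expect_equal(nrow(ortholog_filter(dup_a)), 0L)
  dup_b <- data.frame(mouse = c("a1", "a2"), human = c("b1", "b1"))
  expect_equal(nrow(ortholog_filter(dup_b)), 0L)
  mixed <- data.frame(mouse = c("a1", "a1", "a2", "a3"),
                      human = c("b1", "b2", "b3", "b4"))
  expect_equal(ortholog_filter(mixed)$mouse, c("a2", "a3"))
})

test_that("target-enrichment logistic regression detects planted association", {
  set.seed(73)
  n <- 1000
  beta <- setNames(rnorm(n), sprintf("g%04d", 1:n))
  prob <- plogis(2 * beta - 1)
  targets <- setNames(runif(n) < prob, names(beta))
  res <- target_enrichment_logistic(targets, beta)
  expect_gt(res$coefficient, 0)
  expect_lt(res$p, 1e-6)
  expect_false(res$separated)
  # null targets: slope p should be well calibrated
  pv <- vapply(1:100, function(i) {
    t0 <- setNames(runif(n) < 0.2, names(beta))
    target_enrichment_logistic(t0, beta)$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  # deterministic thresholding separates perfectly: flagged, positive slope
  sep <- setNames(beta > median(beta), names(beta))
  expect_warning(rs <- target_enrichment_logistic(sep, beta), "separation")
  expect_true(rs$separated)
  expect_gt(rs$coefficient, 0)
  expect_error(target_enrichment_logistic(setNames(rep(TRUE, n),
                                                   names(beta)), beta),
               "both target classes")
})
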