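make_em <- function(vals, scale = "log2tpm1") {
  if (is.null(dimnames(vals)))
    dimnames(vals) <- list(sprintf("g%02d", seq_len(nrow(vals))),
                           sprintf("s%02d", seq_len(ncol(vals))))
  expression_matrix(vals, data.frame(sample = colnames(vals)), scale)
}

test_that("log2(tpm+1) transform hits its anchor points and guards scale", {
  m <- make_em(matrix(c(3, 0, 1023, 7), 2, 2), "tpm")
  lg <- log_transform_bulk(m)
  expect_equal(unname(lg$values[1, 1]), 2)
  expect_equal(unname(lg$values[2, 1]), 0)
  expect_equal(unname(lg$values[1, 2]), 10)
  expect_identical(lg$scale, "log2tpm1")
  expect_error(log_transform_bulk(lg), "expected scale")
  # exact inverse
  expect_equal(2^lg$values - 1, m$values, tolerance = 1e-10)
})

test_that("expressed filter uses strict > cutoff and >= sample count", {
  n <- 84
  vals <- rbind(boundary = rep(2.0, n),
                just_in = c(rep(2.1, 10), rep(0, n - 10)),
                too_few = c(rep(5.0, 9), rep(0, n - 9)))
  colnames(vals) <- sprintf("s%02d", 1:n)
  m <- make_em(vals)
  expect_identical(filter_expressed(m), "just_in")
  expect_warning(filter_expressed(make_em(vals[, 1:5]), min_samples = 10),
                 "exceeds")
})

test_that("quantile normalization matches the rank-mean oracle and tie policy", {
  m <- make_em(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values),
               matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3, 2))
  # identical columns unchanged
  m2 <- make_em(matrix(c(1, 5, 9, 1, 5, 9), 3, 2))
  expect_equal(quantile_normalize(m2)$values, m2$values)
  # ties: tied entries get the mean of the reference values at tied ranks
  m3 <- make_em(matrix(c(1, 1, 4, 2, 3, 10), 3, 2))
  qn3 <- quantile_normalize(m3)
  ref <- rowMeans(apply(m3$values, 2, sort))
  expect_equal(unname(qn3$values[1:2, 1]), rep(mean(ref[1:2]), 2))
})

test_that("quantile normalization equalizes sorted columns and is idempotent", {
  set.seed(11)
  for (i in 1:5) {
    m <- make_em(matrix(rnorm(40 * 6), 40, 6))
    qn <- quantile_normalize(m)
    srt <- apply(qn$values, 2, sort)
    expect_equal(srt, srt[, c(1, 1:5)], ignore_attr = TRUE)
    expect_equal(quantile_normalize(qn)$values, qn$values,
                 tolerance = 1e-12)
    # within-column order preserved
    expect_equal(apply(qn$values, 2, rank), apply(m$values, 2, rank))
  }
})

test_that("s.d. variable-gene selection excludes constants, honors cutoff", {
  vals <- rbind(flat = rep(3, 20), wobble = rep(c(0, 4), 10))
  colnames(vals) <- sprintf("s%02d", 1:20)
  m <- make_em(vals)
  expect_identical(select_variable_genes_sd(m, 1.4), "wobble")
  expect_length(select_variable_genes_sd(m, Inf), 0L)
})

test_that("single-cell normalization applies ln(counts per 1e4 + 1)", {
  vals <- matrix(c(1, 9999, 5, 2495), 2, 2)
  dimnames(vals) <- list(c("gA", "gB"), c("c1", "c2"))
  m <- expression_matrix(vals, data.frame(sample = c("c1", "c2")), "counts")
  ln <- sc_normalize(m)
  expect_equal(unname(ln$values["gA", "c1"]), log(2))
  expect_equal(unname(ln$values["gA", "c2"]), log(21))
  expect_identical(ln$scale, "lognorm-sc")
  vals0 <- vals; vals0[, 1] <- 0
  m0 <- expression_matrix(vals0, data.frame(sample = c("c1", "c2")),
                          "counts")
  expect_error(sc_normalize(m0), "zero-depth")
})

test_that("CV variable-gene selection drops zero means and breaks ties by id", {
  vals <- rbind(zero = rep(0, 10), flat = rep(2, 10),
                b_tie = c(rep(0, 5), rep(2, 5)),
                a_tie = c(rep(2, 5), rep(0, 5)),
                big = c(rep(0, 9), 10))
  colnames(vals) <- sprintf("s%02d", 1:10)
  m <- make_em(vals)
  out <- select_variable_genes_cv(m, 3L)
  expect_identical(out, c("big", "a_tie", "b_tie"))
  expect_warning(all_out <- select_variable_genes_cv(m, 10L), "top_n")
  expect_length(all_out, 4L)  # zero-mean gene excluded
})

test_that("gene scaling centers, scales by sample s.d., and drops constants", {
  vals <- rbind(two = c(1, 3), flat = c(5, 5))
  colnames(vals) <- c("s1", "s2")
  m <- make_em(vals)
  expect_warning(sc <- scale_genes(m), "zero-variance")
  expect_equal(unname(sc$values["two", ]), c(-1, 1) / sqrt(2))
  expect_equal(unname(sc$scale["two"]), sd(c(1, 3)))
  expect_false("flat" %in% rownames(sc$values))
  # an already standardized gene is unchanged
  z <- rnorm(8); z <- (z - mean(z)) / sd(z)
  m2 <- make_em(matrix(z, 1, 8))
  expect_equal(unname(scale_genes(m2)$values[1, ]), z, tolerance = 1e-12)
})

test_that("row L2 normalization yields unit rows and flags zero rows", {
  x <- rbind(c(3, 4), c(1, 0), c(0, 0))
  out <- l2_normalize_rows(x)
  expect_equal(out[1, ], c(0.6, 0.8))
  expect_equal(out[2, ], c(1, 0))
  expect_equal(out[3, ], c(0, 0))
  expect_identical(attr(out, "zero_rows"), c(FALSE, FALSE, TRUE))
})
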