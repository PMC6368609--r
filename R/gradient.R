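#' Map cell-type labels to innateness ranks
#'
#' @param labels character vector of cell-type labels.
#' @param mapping named integer vector label -> rank
#'   (default [default_cell_type_ranks()]).
#' @return integer rank vector aligned to \code{labels}.
#' @export
rank_cell_types <- function(labels, mapping = default_cell_type_ranks()) {
  if (anyDuplicated(mapping)) stop("ranks must be unique")
  unknown <- setdiff(unique(labels), names(mapping))
  if (length(unknown))
    stop("cell type(s) without a rank: ", paste(unknown, collapse = ", "))
  unname(mapping[labels])
}

#' Per-gene linear mixed model association (bulk)
#'
#' Fits, by maximum likelihood, the full model
#' \code{expression ~ predictor + (1 | donor)} and the null model without
#' the predictor, and tests the predictor with a likelihood-ratio test on
#' 1 df (chi-square). ML rather than REML, because REML likelihoods are
#' not comparable across fixed-effect structures. A singular or failed
#' mixed fit (donor variance on the boundary) falls back to ordinary
#' least squares for both nested models, flagged in \code{singular}.
#'
#' The predictor is the innateness rank for gradient association, or a
#' 0/1 indicator for two-group differential expression.
#'
#' @param y numeric expression values (one gene, all samples).
#' @param predictor numeric per-sample predictor (non-constant).
#' @param donor per-sample donor grouping (>= 2 levels).
#' @return one-row data.frame: beta, se, lrt, p, singular.
#' @export
fit_lmm_association <- function(y, predictor, donor) {
  stopifnot(length(y) == length(predictor), length(y) == length(donor))
  if (length(unique(predictor)) < 2L) stop("predictor is constant")
  donor <- factor(donor)
  if (nlevels(donor) < 2L) stop("need >= 2 donors")
  dat <- data.frame(y = y, x = predictor, donor = donor)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | donor), data = dat, REML = FALSE,
                 control = ctrl))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    full <- stats::lm(y ~ x, data = dat)
    null <- stats::lm(y ~ 1, data = dat)
    beta <- stats::coef(full)[["x"]]
    se <- sqrt(diag(stats::vcov(full)))[["x"]]
  } else {
    null <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | donor), data = dat, REML = FALSE,
                   control = ctrl))),
      error = function(e) NULL)
    if (is.null(null)) {  # degenerate null: drop to OLS for both
      return(fit_lmm_association_ols(dat))
    }
    full <- fit
    beta <- lme4::fixef(full)[["x"]]
    se <- sqrt(diag(as.matrix(stats::vcov(full))))[[2L]]
  }
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  data.frame(beta = beta, se = se, lrt = lrt, p = p, singular = singular)
}

fit_lmm_association_ols <- function(dat) {
  full <- stats::lm(y ~ x, data = dat)
  null <- stats::lm(y ~ 1, data = dat)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  data.frame(beta = stats::coef(full)[["x"]],
             se = sqrt(diag(stats::vcov(full)))[["x"]],
             lrt = lrt, p = stats::pchisq(lrt, 1L, lower.tail = FALSE),
             singular = TRUE)
}

#' Fit the innateness gradient model to every gene of a bulk matrix
#'
#' Applies [fit_lmm_association()] per gene with the cell-type rank as
#' predictor, and flags significance at the Bonferroni threshold
#' \code{alpha / n_genes_tested}.
#'
#' @param m \code{ExpressionMatrix} on the log2tpm1 scale (typically
#'   quantile-normalized), with \code{cell_type} and \code{donor} metadata.
#' @param mapping cell-type rank mapping.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.frame: gene, beta, se, lrt, p, singular, significant.
#' @export
fit_gradient_bulk <- function(m, mapping = default_cell_type_ranks(),
                              alpha = 0.05) {
  assert_scale(m, "log2tpm1")
  ranks <- rank_cell_types(m$meta$cell_type, mapping)
  fits <- lapply(seq_len(nrow(m$values)), function(i)
    fit_lmm_association(m$values[i, ], ranks, m$meta$donor))
  out <- do.call(rbind, fits)
  out <- cbind(gene = genes(m), out)
  rownames(out) <- NULL
  thr <- bonferroni_threshold(alpha, nrow(out))
  out$significant <- out$p < thr
  out
}

#' Per-gene linear model association with covariates (single cell)
#'
#' Ordinary linear model of log-normalized expression on a predictor
#' (innateness rank or group indicator) with technical covariates
#' (log total UMIs, percent mitochondrial UMIs on the 0-100 scale, donor
#' indicator), tested by a 1-df likelihood-ratio test between the nested
#' fits. Genes nonzero in fewer than \code{min_nonzero_cells} cells are
#' skipped (NA fit with \code{skipped = TRUE}).
#'
#' @param y per-cell log-normalized expression for one gene.
#' @param predictor per-cell numeric predictor.
#' @param covariates data.frame of per-cell covariates (may have zero
#'   columns).
#' @param min_nonzero_cells minimum cells with nonzero expression.
#' @return one-row data.frame: beta, se, lrt, p, skipped.
#' @export
fit_lm_association_sc <- function(y, predictor, covariates = NULL,
                                  min_nonzero_cells = 100L) {
  stopifnot(length(y) == length(predictor))
  if (sum(y != 0) < min_nonzero_cells)
    return(data.frame(beta = NA_real_, se = NA_real_, lrt = NA_real_,
                      p = NA_real_, skipped = TRUE))
  if (length(unique(predictor)) < 2L) stop("predictor is constant")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    dat <- data.frame(y = y, x = predictor)
    full <- stats::lm(y ~ x, data = dat)
    null <- stats::lm(y ~ 1, data = dat)
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- data.frame(y = y, x = predictor, covariates)
    cov_terms <- paste(names(covariates), collapse = " + ")
    full <- stats::lm(stats::reformulate(c("x", names(covariates)), "y"),
                      data = dat)
    null <- stats::lm(stats::reformulate(names(covariates), "y"),
                      data = dat)
  }
  cf <- stats::coef(full)
  if (anyNA(cf)) stop("collinear covariates (rank-deficient fit)")
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  data.frame(beta = cf[["x"]],
             se = sqrt(diag(stats::vcov(full)))[["x"]],
             lrt = lrt, p = stats::pchisq(lrt, 1L, lower.tail = FALSE),
             skipped = FALSE)
}

#' Gradient association for every gene of a single-cell matrix
#'
#' @param m \code{ExpressionMatrix} on the lognorm-sc scale with
#'   \code{cell_type} metadata.
#' @param covariates per-cell covariate data.frame (log UMIs, percent
#'   mito, donor indicator), as used in the published single-cell model.
#' @param mapping cell-type rank mapping.
#' @param min_nonzero_cells minimum nonzero cells per gene (100 for the
#'   gradient analysis).
#' @param alpha family-wise error rate for the Bonferroni flag (computed
#'   over genes actually tested).
#' @return data.frame: gene, beta, se, lrt, p, skipped, significant.
#' @export
fit_gradient_sc <- function(m, covariates,
                            mapping = default_cell_type_ranks(),
                            min_nonzero_cells = 100L, alpha = 0.05) {
  assert_scale(m, "lognorm-sc")
  ranks <- rank_cell_types(m$meta$cell_type, mapping)
  fits <- lapply(seq_len(nrow(m$values)), function(i)
    fit_lm_association_sc(m$values[i, ], ranks, covariates,
                          min_nonzero_cells))
  out <- cbind(gene = genes(m), do.call(rbind, fits))
  rownames(out) <- NULL
  n_tested <- sum(!out$skipped)
  out$significant <- !out$skipped &
    out$p < bonferroni_threshold(alpha, max(1L, n_tested))
  out
}

#' One-vs-rest differential expression (single cell)
#'
#' [fit_lm_association_sc()] per gene with a 0/1 subset indicator as the
#' predictor and a 60-cell nonzero filter, as used for within-cell-type
#' subset comparisons.
#'
#' @param m \code{ExpressionMatrix} on the lognorm-sc scale.
#' @param subset logical or 0/1 vector marking the subset of interest.
#' @param covariates per-cell covariate data.frame.
#' @param min_nonzero_cells minimum nonzero cells per gene.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.frame: gene, beta, se, lrt, p, skipped, significant.
#' @export
de_one_vs_rest <- function(m, subset, covariates = NULL,
                           min_nonzero_cells = 60L, alpha = 0.05) {
  assert_scale(m, "lognorm-sc")
  ind <- as.numeric(subset)
  if (length(unique(ind)) < 2L) stop("subset indicator is constant")
  fits <- lapply(seq_len(nrow(m$values)), function(i)
    fit_lm_association_sc(m$values[i, ], ind, covariates,
                          min_nonzero_cells))
  out <- cbind(gene = genes(m), do.call(rbind, fits))
  rownames(out) <- NULL
  n_tested <- sum(!out$skipped)
  out$significant <- !out$skipped &
    out$p < bonferroni_threshold(alpha, max(1L, n_tested))
  out
}

#' Bonferroni significance threshold
#'
#' \code{alpha / n_tests}; with alpha 0.05 over the 19,931 expressed
#' genes this gives the published 2.5e-06 threshold.
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' One-way ANOVA F statistic across cell types
#'
#' Between/within mean-square ratio, the per-gene variability metric used
#' upstream of the pathway tests. A zero within-group mean square yields
#' an unbounded statistic, returned as a large finite value with the
#' \code{"unbounded"} attribute set.
#'
#' @param y numeric expression values.
#' @param groups per-sample group labels (>= 2 groups, each >= 2 samples).
#' @return the F statistic (numeric scalar).
#' @export
anova_f <- function(y, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ groups)))
  f <- tab[["F value"]][1L]
  msb <- tab[["Mean Sq"]][1L]
  msw <- tab[["Mean Sq"]][2L]
  if (!is.finite(f) || msw < 1e-10 * max(msb, .Machine$double.xmin)) {
    f <- 1e300
    attr(f, "unbounded") <- TRUE
  }
  f
}

#' Concordance between two effect-size vectors
#'
#' @param beta_a,beta_b named numeric vectors of per-gene effect sizes;
#'   compared on their common gene ids (>= 3 required).
#' @return list with \code{rho} (Spearman) and \code{sign_concordance}
#'   (fraction with the same sign, pairs containing an exact zero
#'   excluded).
#' @export
concordance <- function(beta_a, beta_b) {
  common <- intersect(names(beta_a), names(beta_b))
  if (length(common) < 3L) stop("need >= 3 shared genes")
  a <- beta_a[common]; b <- beta_b[common]
  nz <- a != 0 & b != 0
  list(rho = stats::cor(a, b, method = "spearman"),
       sign_concordance = mean(sign(a[nz]) == sign(b[nz])))
}
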