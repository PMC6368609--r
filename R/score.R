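#' Fit an innateness score model (PC1 loadings)
#'
#' Runs PCA on the centered and scaled variable-gene submatrix of a
#' reference dataset and stores the PC1 loading, center, and scale per
#' gene. The arbitrary PCA sign is fixed so that the mean score of the
#' highest-rank cell type exceeds that of the lowest-rank type -- higher
#' score = more innate.
#'
#' @param reference \code{ExpressionMatrix} on a log scale with
#'   \code{cell_type} metadata.
#' @param variable_genes character vector of genes to use (e.g. from
#'   [select_variable_genes_sd()]); default selects s.d. > 1.4.
#' @param mapping cell-type rank mapping used for orientation.
#' @return list of class \code{ScoreModel}: gene, loading, center, scale,
#'   orientation (+1/-1), provenance.
#' @export
fit_score_model <- function(reference,
                            variable_genes = select_variable_genes_sd(reference),
                            mapping = default_cell_type_ranks()) {
  assert_scale(reference, c("log2tpm1", "lognorm-sc"))
  if (ncol(reference$values) < 3L) stop("need >= 3 reference samples")
  if (length(variable_genes) < 2L) stop("need >= 2 variable genes")
  sc <- scale_genes(reference, variable_genes)
  pca <- stats::prcomp(t(sc$values), center = FALSE, scale. = FALSE)
  if (pca$sdev[1L] < 1e-12) stop("degenerate reference matrix (rank 0)")
  loading <- pca$rotation[, 1L]
  pc1 <- pca$x[, 1L]

  ranks <- rank_cell_types(reference$meta$cell_type, mapping)
  hi <- mean(pc1[ranks == max(ranks)])
  lo <- mean(pc1[ranks == min(ranks)])
  orientation <- if (hi >= lo) 1 else -1

  structure(list(gene = names(loading), loading = unname(loading),
                 center = unname(sc$center), scale = unname(sc$scale),
                 orientation = orientation,
                 provenance = list(n_genes = length(loading),
                                   n_samples = ncol(reference$values))),
            class = "ScoreModel")
}

#' @export
print.ScoreModel <- function(x, ...) {
  cat(sprintf("ScoreModel: %d gene loadings (orientation %+d)\n",
              length(x$gene), x$orientation))
  invisible(x)
}

#' Project samples or cells onto the innateness axis
#'
#' Per query sample: \code{score = orientation * sum_g loading_g * z_g},
#' where \code{z_g} is the scaled expression of model gene \code{g} in
#' the query. By default genes are z-scored within the query dataset
#' (its own per-gene mean and s.d.), so scores are comparable across
#' platforms; \code{scaling = "reference"} applies the stored reference
#' center/scale instead. Model genes absent from the query contribute 0
#' (the mean); gene coverage is reported and a warning fires below 50\%.
#'
#' @param model a \code{ScoreModel}.
#' @param query \code{ExpressionMatrix} on a log-like scale.
#' @param scaling \code{"query"} (default) or \code{"reference"}.
#' @return data.frame: sample, score, coverage.
#' @export
project_score <- function(model, query, scaling = c("query", "reference")) {
  stopifnot(inherits(model, "ScoreModel"))
  scaling <- match.arg(scaling)
  assert_scale(query, c("log2tpm1", "lognorm-sc"))
  present <- model$gene %in% genes(query)
  if (!any(present)) stop("no model gene present in query")
  coverage <- mean(present)
  if (coverage < 0.5)
    warning(sprintf("only %.0f%% of model genes present in query",
                    100 * coverage))
  x <- query$values[model$gene[present], , drop = FALSE]
  if (scaling == "query") {
    ctr <- rowMeans(x)
    scl <- apply(x, 1L, stats::sd)
  } else {
    ctr <- model$center[present]
    scl <- model$scale[present]
  }
  ok <- scl > 0 & is.finite(scl)
  z <- (x[ok, , drop = FALSE] - ctr[ok]) / scl[ok]
  score <- model$orientation *
    as.numeric(crossprod(model$loading[present][ok], z))
  data.frame(sample = samples(query), score = score, coverage = coverage,
             stringsAsFactors = FALSE)
}

#' Summarize scores by group with pairwise rank-sum tests
#'
#' @param scores numeric score vector.
#' @param groups per-score group labels (>= 2 groups, all non-empty).
#' @return list with \code{summary} (group, n, q1, median, q3) and
#'   \code{pairwise} (group_a, group_b, p from a two-sided Wilcoxon
#'   rank-sum test).
#' @export
score_groups <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  qs <- t(vapply(levels(groups), function(g)
    stats::quantile(scores[groups == g], c(0.25, 0.5, 0.75)),
    numeric(3L)))
  summary <- data.frame(group = levels(groups),
                        n = as.integer(table(groups)),
                        q1 = qs[, 1L], median = qs[, 2L], q3 = qs[, 3L],
                        stringsAsFactors = FALSE, row.names = NULL)
  pairs <- utils::combn(levels(groups), 2L)
  pw <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                   p = apply(pairs, 2L, function(pr)
                     stats::wilcox.test(scores[groups == pr[1L]],
                                        scores[groups == pr[2L]],
                                        exact = NULL)$p.value),
                   stringsAsFactors = FALSE)
  list(summary = summary, pairwise = pw)
}

#' Individual innateness metric
#'
#' Per individual, the sum over measured ITC types of the proportion of
#' T cells contributed by that type multiplied by the type's innateness
#' rank. Cohort tables carry percentages; they are divided by 100 first.
#' The adaptive remainder of the T-cell pool is excluded by default;
#' supply \code{remainder_rank} to include it at a chosen rank.
#'
#' @param cohort data.frame with one column per measured cell type
#'   (percent of T cells).
#' @param ranks named numeric vector: measured cell type -> rank. Default
#'   covers the four ITC populations.
#' @param remainder_rank optional rank at which to weight the unmeasured
#'   remainder \code{1 - sum(proportions)}.
#' @return numeric vector, one metric per cohort row.
#' @export
individual_innateness_metric <- function(cohort,
                                         ranks = default_cell_type_ranks()[c("MAIT", "iNKT", "Vd1", "Vd2")],
                                         remainder_rank = NULL) {
  missing <- setdiff(names(ranks), names(cohort))
  if (length(missing))
    stop("cohort missing column(s): ", paste(missing, collapse = ", "))
  prop <- as.matrix(cohort[, names(ranks), drop = FALSE]) / 100
  if (any(prop < 0)) stop("negative proportions")
  tot <- rowSums(prop)
  if (any(tot > 1 + 1e-8))
    stop("ITC proportions sum above 1 for some individual(s)")
  metric <- as.numeric(prop %*% ranks)
  if (!is.null(remainder_rank))
    metric <- metric + (1 - unname(tot)) * remainder_rank
  metric
}
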