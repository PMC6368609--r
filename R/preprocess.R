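#' Log-transform a tpm matrix
#'
#' \code{log2(tpm + 1)}, the main bulk expression measure.
#'
#' @param m \code{ExpressionMatrix} on the tpm scale.
#' @return \code{ExpressionMatrix} on the log2tpm1 scale.
#' @export
log_transform_bulk <- function(m) {
  assert_scale(m, "tpm")
  m$values <- log2(m$values + 1)
  m$scale <- "log2tpm1"
  m
}

#' Filter to expressed genes
#'
#' A gene is expressed when its log2(tpm+1) value exceeds \code{cutoff}
#' (strictly) in at least \code{min_samples} samples. With the defaults
#' this is equivalent to tpm > 3 in >= 10 samples.
#'
#' @param m \code{ExpressionMatrix} on the log2tpm1 scale.
#' @param cutoff strict lower cutoff in log2 units.
#' @param min_samples minimum number of samples above cutoff.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(m, cutoff = 2, min_samples = 10L) {
  assert_scale(m, "log2tpm1")
  if (min_samples > ncol(m$values))
    warning("min_samples exceeds number of samples; no gene can pass")
  n_above <- rowSums(m$values > cutoff)
  genes(m)[n_above >= min_samples]
}

#' Quantile-normalize columns of an expression matrix
#'
#' Every column's values are replaced by the reference distribution (the
#' row-wise mean of the sorted columns), preserving within-column rank
#' order. Ties receive the mean of the reference values at the tied
#' ranks.
#'
#' @param m \code{ExpressionMatrix} (log scale expected).
#' @return \code{ExpressionMatrix} with the same scale tag.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- m$values
  if (ncol(x) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(m)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # tied input values receive the mean of the reference values
    # occupying their tied ranks
    stats::ave(res, match(col, col))
  })
  dimnames(out) <- dimnames(x)
  m$values <- out
  m
}

#' Select variable genes by standard deviation
#'
#' Genes whose across-sample sample s.d. exceeds \code{sd_cutoff},
#' descending by s.d. The published bulk analysis used a cutoff of 1.4
#' (1022 genes).
#'
#' @param m \code{ExpressionMatrix} on a log scale.
#' @param sd_cutoff strict s.d. cutoff.
#' @return character vector of gene ids, descending by s.d.
#' @export
select_variable_genes_sd <- function(m, sd_cutoff = 1.4) {
  assert_scale(m, c("log2tpm1", "lognorm-sc"))
  sds <- apply(m$values, 1L, stats::sd)
  keep <- which(sds > sd_cutoff)
  genes(m)[keep[order(sds[keep], decreasing = TRUE)]]
}

#' Library-size normalize and log-transform single-cell counts
#'
#' \code{ln(count * 1e4 / depth + 1)} per cell (natural log), where depth
#' is the cell's total UMI count.
#'
#' @param m \code{ExpressionMatrix} with UMI counts.
#' @return \code{ExpressionMatrix} on the lognorm-sc scale.
#' @export
sc_normalize <- function(m) {
  assert_scale(m, "counts")
  depth <- colSums(m$values)
  if (any(depth == 0)) stop("zero-depth cell(s): ",
                            paste(samples(m)[depth == 0], collapse = ", "))
  m$values <- log(sweep(m$values, 2L, depth, "/") * 1e4 + 1)
  m$scale <- "lognorm-sc"
  m
}

#' Select variable genes by coefficient of variation
#'
#' Top \code{top_n} genes by s.d./mean (descending). Genes with mean 0 are
#' excluded; CV ties break lexicographically by gene id. The published
#' single-cell analysis used the top 1545.
#'
#' @param m \code{ExpressionMatrix} with nonnegative values.
#' @param top_n number of genes to keep.
#' @return character vector of gene ids.
#' @export
select_variable_genes_cv <- function(m, top_n = 1545L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mu <- rowMeans(m$values)
  sds <- apply(m$values, 1L, stats::sd)
  ok <- mu > 0
  cv <- sds[ok] / mu[ok]
  ids <- genes(m)[ok]
  ord <- order(-cv, ids)
  if (top_n > length(ids)) {
    warning("top_n exceeds available genes; returning all")
    top_n <- length(ids)
  }
  ids[ord][seq_len(top_n)]
}

#' Center and scale selected genes
#'
#' Each selected gene is mean-centered and divided by its sample s.d.
#' across columns. Zero-variance genes are dropped with a warning. The
#' per-gene (center, scale) pair is retained for score-model projection.
#'
#' @param m \code{ExpressionMatrix} on a log scale.
#' @param gene_ids genes to scale (default: all).
#' @return list with \code{values} (scaled genes x samples matrix),
#'   \code{center}, \code{scale} (named numeric vectors).
#' @export
scale_genes <- function(m, gene_ids = genes(m)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(gene_ids, genes(m))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(utils::head(missing), collapse = ", "))
  x <- m$values[gene_ids, , drop = FALSE]
  ctr <- rowMeans(x)
  scl <- apply(x, 1L, stats::sd)
  drop <- scl == 0 | !is.finite(scl)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped")
    x <- x[!drop, , drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
  }
  list(values = (x - ctr) / scl, center = ctr, scale = scl)
}

#' L2-normalize the rows of an embedding
#'
#' Every row is divided by its Euclidean norm, inducing cosine distance
#' between rows. Zero rows are left as zero and flagged.
#'
#' @param x numeric matrix (rows = cells/samples).
#' @return matrix of the same shape with a logical \code{"zero_rows"}
#'   attribute.
#' @export
l2_normalize_rows <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- x / nrm
  attr(out, "zero_rows") <- zero
  out
}
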