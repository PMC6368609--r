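#' CFSE division index
#'
#' Average number of divisions per starting cell, from counts of cells
#' by division number:
#' \deqn{\frac{d_1 + d_2/2 + d_{3+}/2.67}
#'   {u + d_1/2 + d_2/4 + d_{3+}/8}}
#' where u = undivided cells and d_k = cells having divided k times (3+
#' pooled). The coefficients, including 2.67 for the pooled >= 3 class,
#' are used verbatim as published.
#'
#' @param undivided,divided_once,divided_twice,divided_three_plus
#'   nonnegative cell counts (not all zero).
#' @return the division index (numeric scalar).
#' @export
division_index <- function(undivided, divided_once, divided_twice,
                           divided_three_plus) {
  counts <- c(undivided, divided_once, divided_twice, divided_three_plus)
  if (any(counts < 0)) stop("counts must be >= 0")
  denom <- undivided + divided_once / 2 + divided_twice / 4 +
    divided_three_plus / 8
  if (denom == 0) stop("denominator is zero (no cells)")
  (divided_once + divided_twice / 2 + divided_three_plus / 2.67) / denom
}

#' Aggregate expression mass of a gene set
#'
#' Per-sample sum of tpm over the genes of a set (linear scale, as used
#' for the cytokine/chemokine transcriptome mass). Set genes absent from
#' the matrix contribute 0; their count is reported in the
#' \code{"n_missing"} attribute.
#'
#' @param m \code{ExpressionMatrix} on the tpm scale.
#' @param gene_set character vector of gene ids (non-empty).
#' @return named numeric vector of per-sample sums.
#' @export
gene_set_mass <- function(m, gene_set) {
  assert_scale(m, "tpm")
  if (length(gene_set) == 0L) stop("empty gene set")
  present <- intersect(gene_set, genes(m))
  mass <- if (length(present))
    colSums(m$values[present, , drop = FALSE])
  else stats::setNames(rep(0, ncol(m$values)), samples(m))
  attr(mass, "n_missing") <- length(setdiff(gene_set, genes(m)))
  mass
}
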