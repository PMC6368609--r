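#' Expression matrix with sample metadata
#'
#' Lightweight container coupling a genes x samples numeric matrix with
#' per-sample metadata and a scale tag. The scale tag documents what the
#' values mean and is checked by every transform that assumes a particular
#' scale:
#' \describe{
#'   \item{\code{"tpm"}}{transcripts per million, linear scale.}
#'   \item{\code{"log2tpm1"}}{\code{log2(tpm + 1)}.}
#'   \item{\code{"counts"}}{raw UMI counts (single cell).}
#'   \item{\code{"lognorm-sc"}}{\code{ln(counts per 1e4 + 1)}, library-size
#'     normalized single-cell expression.}
#' }
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with one row per sample and at least a
#'   \code{sample} column matching \code{colnames(values)}; typically also
#'   \code{donor}, \code{cell_type}, \code{replicate}.
#' @param scale one of \code{"tpm"}, \code{"log2tpm1"}, \code{"counts"},
#'   \code{"lognorm-sc"}.
#' @return an object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{meta}, \code{scale}.
#' @export
expression_matrix <- function(values, meta, scale) {
  scale <- match.arg(scale, c("tpm", "log2tpm1", "counts", "lognorm-sc"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene id: ", dup)
  }
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.data.frame(meta) || !"sample" %in% names(meta))
    stop("'meta' must be a data.frame with a 'sample' column")
  missing <- setdiff(colnames(values), meta$sample)
  if (length(missing))
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (scale %in% c("tpm", "counts") && any(values < 0))
    stop("negative values are invalid on the '", scale, "' scale")
  structure(list(values = values, meta = meta, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("meta columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

genes <- function(m) rownames(m$values)
samples <- function(m) colnames(m$values)

assert_scale <- function(m, expected) {
  if (!inherits(m, "ExpressionMatrix"))
    stop("expected an ExpressionMatrix")
  if (!m$scale %in% expected)
    stop("expected scale ", paste(expected, collapse = " or "),
         " but got '", m$scale, "'")
  invisible(m)
}

#' Read an expression matrix from TSV with a metadata table
#'
#' The expression file is a TSV with gene ids in the first column and one
#' column per sample; the metadata file is a TSV with a \code{sample}
#' column. Every expression column must have a metadata row.
#'
#' @param path path to the expression TSV.
#' @param meta_path path to the sample metadata TSV.
#' @param scale scale tag to attach (see [expression_matrix()]).
#' @return an \code{ExpressionMatrix}.
#' @export
read_expression <- function(path, meta_path, scale) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs gene ids + >=1 sample")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values")
  rownames(values) <- ids
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale)
}

#' Write an expression matrix (and its metadata) to TSV
#'
#' @param m an \code{ExpressionMatrix}.
#' @param path output path for the expression TSV.
#' @param meta_path optional output path for the metadata TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(m, path, meta_path = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tab <- data.frame(gene = genes(m), m$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(m$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
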