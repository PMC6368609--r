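#' Rank genes by effect size for enrichment
#'
#' @param fits data.frame with \code{gene} and \code{beta} columns (e.g.
#'   from [fit_gradient_bulk()]).
#' @param direction \code{"innate"} sorts beta descending (innateness at
#'   the top), \code{"adaptive"} ascending.
#' @return character vector of gene ids in ranked order.
#' @export
ranked_gene_list <- function(fits, direction = c("innate", "adaptive")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene", "beta") %in% names(fits)))
  if (anyDuplicated(fits$gene)) stop("duplicate genes in fits")
  ord <- order(fits$beta, decreasing = direction == "innate")
  fits$gene[ord]
}

#' GO-style gene-set enrichment along the gradient (mHG)
#'
#' Sorts genes by the gradient effect size and applies [mhg_test()] to
#' each gene set. Set members absent from the fitted universe are dropped
#' and counted.
#'
#' @param fits data.frame with \code{gene} and \code{beta}.
#' @param gene_sets named list of character vectors.
#' @param direction \code{"innate"} or \code{"adaptive"} (see
#'   [ranked_gene_list()]).
#' @return data.frame sorted by p: set, n_members, n_matched, stat, p,
#'   n_opt.
#' @export
go_enrichment <- function(fits, gene_sets,
                          direction = c("innate", "adaptive")) {
  direction <- match.arg(direction)
  if (length(gene_sets) == 0L) stop("empty gene-set collection")
  ranked <- ranked_gene_list(fits, direction)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- gene_sets[[nm]]
    matched <- intersect(members, ranked)
    if (length(matched) == 0L) {
      warning("set '", nm, "' is disjoint from the universe; dropped")
      return(NULL)
    }
    res <- mhg_test(ranked %in% matched)
    data.frame(set = nm, n_members = length(members),
               n_matched = length(matched), stat = res$stat, p = res$p,
               n_opt = res$n_opt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}

#' Pathway enrichment on per-gene F statistics
#'
#' One-sided Wilcoxon rank-sum test of whether the F statistics of the
#' pathway genes are higher than those of all other expressed genes.
#'
#' @param f_stats named numeric vector of per-gene F statistics.
#' @param pathway_genes character vector (subset of
#'   \code{names(f_stats)}).
#' @return one-sided p-value.
#' @export
pathway_f_test <- function(f_stats, pathway_genes) {
  in_path <- names(f_stats) %in% pathway_genes
  if (!any(in_path)) stop("no pathway gene in the universe")
  if (all(in_path)) stop("pathway equals the universe")
  stats::wilcox.test(f_stats[in_path], f_stats[!in_path],
                     alternative = "greater", exact = NULL)$p.value
}

#' Expression-matched null test on per-gene F statistics
#'
#' Controls for the expression dependence of the F statistic: for each
#' pathway gene, \code{n_matched} (default 30) non-pathway genes are
#' sampled whose mean expression lies within \code{tolerance} (default
#' 10\%) of the standard deviation of per-gene mean expression from the
#' pathway gene's mean. The pathway F statistics are then compared with
#' the pooled matched-null F statistics by a one-sided Wilcoxon test.
#' Sampling is without replacement within a gene's candidate pool; pools
#' smaller than \code{n_matched} are sampled with replacement and
#' flagged. A pathway gene with an empty pool (no candidate within the
#' window, as happens at the expression extremes) is relaxed to its
#' single nearest-expression candidate and flagged.
#'
#' @param f_stats named numeric vector of per-gene F statistics.
#' @param pathway_genes character vector of pathway gene ids.
#' @param mean_expr named numeric vector of per-gene mean expression
#'   (across all cell types), same universe as \code{f_stats}.
#' @param n_matched matched genes sampled per pathway gene.
#' @param tolerance matching window as a multiple of the s.d. of
#'   \code{mean_expr}.
#' @param seed integer seed for the matched sampling.
#' @return list: \code{p} (one-sided Wilcoxon p), \code{null_genes}
#'   (sampled ids), \code{undersized_pools} (pathway genes whose pool had
#'   fewer than \code{n_matched} candidates), \code{relaxed_pools}
#'   (pathway genes whose window held no candidate at all).
#' @export
matched_null_f_test <- function(f_stats, pathway_genes, mean_expr,
                                n_matched = 30L, tolerance = 0.10,
                                seed = 1L) {
  stopifnot(setequal(names(f_stats), names(mean_expr)))
  pathway_genes <- intersect(pathway_genes, names(f_stats))
  if (length(pathway_genes) == 0L) stop("no pathway gene in the universe")
  candidates <- setdiff(names(f_stats), pathway_genes)
  if (length(candidates) == 0L) stop("no candidate genes outside pathway")
  window <- tolerance * stats::sd(mean_expr)
  with_seed(seed, {
    undersized <- character(0)
    relaxed <- character(0)
    null_genes <- lapply(pathway_genes, function(g) {
      pool <- candidates[abs(mean_expr[candidates] - mean_expr[[g]]) <=
                           window]
      if (length(pool) == 0L) {
        # no candidate inside the window: relax to the nearest gene
        relaxed <<- c(relaxed, g)
        pool <- candidates[which.min(abs(mean_expr[candidates] -
                                           mean_expr[[g]]))]
      }
      if (length(pool) < n_matched) {
        undersized <<- c(undersized, g)
        sample(pool, n_matched, replace = TRUE)
      } else sample(pool, n_matched)
    })
    null_genes <- unlist(null_genes)
    p <- stats::wilcox.test(f_stats[pathway_genes],
                            f_stats[null_genes],
                            alternative = "greater", exact = FALSE)$p.value
    list(p = p, null_genes = null_genes,
         undersized_pools = undersized, relaxed_pools = relaxed)
  })
}

#' Assign peaks to target genes
#'
#' Coordinates are 0-based, half-open on both inputs. Two rules:
#' \describe{
#'   \item{\code{"body2kb"}}{a gene is a target when a peak overlaps the
#'     gene span padded by 2 kb on both sides (the union of the gene
#'     body and the +-2 kb TSS window, given the TSS sits at one end of
#'     the span).}
#'   \item{\code{"promoter"}}{strand-aware promoter window from 2 kb
#'     upstream to 1 kb downstream of the TSS.}
#' }
#'
#' @param peaks data.frame from [read_peaks()] (chrom, start, end, name).
#' @param annotation data.frame from [read_gene_annotation()] (gene,
#'   chrom, start, end, strand).
#' @param rule \code{"body2kb"} (default) or \code{"promoter"}.
#' @param flank_bp body-rule padding (default 2000).
#' @param promoter_upstream,promoter_downstream promoter-rule window
#'   sizes (defaults 2000 and 1000).
#' @return data.frame: gene, is_target, supporting_peaks
#'   (semicolon-joined peak names), rule. Peaks on chromosomes absent
#'   from the annotation are skipped; their count is in the
#'   \code{"n_skipped_peaks"} attribute.
#' @export
assign_peak_targets <- function(peaks, annotation,
                                rule = c("body2kb", "promoter"),
                                flank_bp = 2000L,
                                promoter_upstream = 2000L,
                                promoter_downstream = 1000L) {
  rule <- match.arg(rule)
  if (!"tss" %in% names(annotation))
    annotation$tss <- ifelse(annotation$strand == "+", annotation$start,
                             annotation$end - 1)
  known <- peaks$chrom %in% annotation$chrom
  n_skipped <- sum(!known)
  peaks <- peaks[known, , drop = FALSE]

  gr_gene <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  windows <- if (rule == "body2kb") {
    suppressWarnings(gr_gene + flank_bp)
  } else {
    suppressWarnings(GenomicRanges::promoters(
      gr_gene, upstream = promoter_upstream,
      downstream = promoter_downstream))
  }
  out <- data.frame(gene = annotation$gene, is_target = FALSE,
                    supporting_peaks = "", rule = rule,
                    stringsAsFactors = FALSE)
  if (nrow(peaks) > 0L) {
    gr_peak <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    hits <- GenomicRanges::findOverlaps(gr_peak, windows,
                                        ignore.strand = TRUE)
    by_gene <- split(peaks$name[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits))
    idx <- as.integer(names(by_gene))
    out$is_target[idx] <- TRUE
    out$supporting_peaks[idx] <- vapply(by_gene, paste,
                                        character(1L), collapse = ";")
  }
  attr(out, "n_skipped_peaks") <- n_skipped
  out
}

#' Filter a homolog table to 1-to-1 orthologs
#'
#' @param homologs data.frame with two columns (species A gene, species B
#'   gene).
#' @return the rows whose members each appear exactly once in the table.
#' @export
ortholog_filter <- function(homologs) {
  stopifnot(ncol(homologs) >= 2L)
  a <- homologs[[1L]]; b <- homologs[[2L]]
  keep <- !(a %in% a[duplicated(a)]) & !(b %in% b[duplicated(b)])
  homologs[keep, , drop = FALSE]
}

#' Logistic regression for target enrichment in differential expression
#'
#' Fits \code{target ~ beta} by maximum-likelihood logistic regression
#' and reports the Wald p-value of the slope. A positive slope means
#' peak targets are enriched among genes upregulated in the comparison.
#' Perfect separation falls back to a small ridge penalty on the slope
#' and is flagged.
#'
#' @param is_target named logical vector (gene -> target status).
#' @param de_betas named numeric vector of differential-expression
#'   effect sizes; compared on the shared genes (>= 10 required).
#' @return list: \code{coefficient} (slope), \code{p} (Wald),
#'   \code{separated} (logical), \code{n}.
#' @export
target_enrichment_logistic <- function(is_target, de_betas) {
  common <- intersect(names(is_target), names(de_betas))
  if (length(common) < 10L) stop("need >= 10 shared genes")
  y <- as.numeric(is_target[common])
  x <- de_betas[common]
  if (length(unique(y)) < 2L) stop("both target classes must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    rf <- ridge_logistic(x, y, lambda = 1e-3)
    warning("perfect separation: ridge-penalized slope reported")
    return(list(coefficient = rf$coefficient, p = rf$p,
                separated = TRUE, n = length(y)))
  }
  sm <- summary(fit)$coefficients
  list(coefficient = sm["x", "Estimate"], p = sm["x", "Pr(>|z|)"],
       separated = FALSE, n = length(y))
}

# logistic fit with an L2 penalty on the slope; Wald p from the
# penalized observed information
ridge_logistic <- function(x, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- b[1L] + b[2L] * x
    sum(log1p(exp(eta))) - sum(y * eta) + lambda * b[2L]^2 / 2
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))[2L]
  z <- opt$par[2L] / se
  list(coefficient = opt$par[2L],
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
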