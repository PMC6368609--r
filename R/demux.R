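#' Antibody exclusion criteria
#'
#' The three hashing-antibody exclusion criteria, applied per barcode
#' set. A cell FAILS a set when any of:
#' \enumerate{
#'   \item total antibody UMIs < \code{min_total_umis} (default 10);
#'   \item second-most-abundant antibody > \code{max_second_fraction}
#'     (default 10\%) of the most abundant;
#'   \item most abundant antibody < \code{min_top_fraction} (default
#'     75\%) of the total.
#' }
#' Boundary semantics follow the wording literally: equality passes in
#' each case (total = 10 keeps; second = exactly 10\% of top keeps;
#' top = exactly 75\% of total keeps).
#'
#' @param min_total_umis minimum total antibody UMIs.
#' @param max_second_fraction maximum second/top ratio.
#' @param min_top_fraction minimum top/total ratio.
#' @return list of class \code{AbCriteria}.
#' @export
ab_criteria <- function(min_total_umis = 10,
                        max_second_fraction = 0.10,
                        min_top_fraction = 0.75) {
  if (min_total_umis < 1) stop("min_total_umis must be >= 1")
  if (max_second_fraction <= 0 || max_second_fraction >= 1 ||
      min_top_fraction <= 0 || min_top_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  structure(list(min_total_umis = min_total_umis,
                 max_second_fraction = max_second_fraction,
                 min_top_fraction = min_top_fraction),
            class = "AbCriteria")
}

#' Collapse a UMI read-count table to antibody UMI counts
#'
#' UMIs supported by fewer than \code{min_reads} reads are discarded
#' before counting (a UMI with exactly \code{min_reads} reads is kept).
#' Counts are UMI cardinalities per (cell barcode, antibody).
#'
#' @param umi_records data.frame with columns \code{barcode},
#'   \code{antibody}, \code{umi}, \code{reads}.
#' @param min_reads minimum reads per UMI (default 5).
#' @return data.frame: barcode, antibody, count.
#' @export
filter_umis_by_reads <- function(umi_records, min_reads = 5L) {
  required <- c("barcode", "antibody", "umi", "reads")
  missing <- setdiff(required, names(umi_records))
  if (length(missing))
    stop("umi_records missing column(s): ", paste(missing, collapse = ", "))
  keep <- umi_records[umi_records$reads >= min_reads, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(barcode = character(0), antibody = character(0),
                      count = integer(0)))
  agg <- stats::aggregate(umi ~ barcode + antibody, data = keep,
                          FUN = function(u) length(unique(u)))
  names(agg)[3L] <- "count"
  agg
}

#' mRNA quality control for a droplet
#'
#' Fails when the droplet expresses \code{min_genes_exclusive} or fewer
#' unique genes (strictly more required), or when at least
#' \code{max_mito} of its UMIs map to mitochondrial genes.
#'
#' @param n_genes unique genes detected.
#' @param mito_fraction fraction of UMIs on mitochondrial genes, in
#'   [0, 1].
#' @param min_genes_exclusive exclusive lower bound on genes (default
#'   500).
#' @param max_mito inclusive failure bound on mito fraction (default
#'   0.20).
#' @return logical: TRUE when the droplet passes.
#' @export
mrna_qc <- function(n_genes, mito_fraction, min_genes_exclusive = 500L,
                    max_mito = 0.20) {
  n_genes > min_genes_exclusive & mito_fraction < max_mito
}

#' Antibody QC for one barcode set
#'
#' Applies the three exclusion criteria of [ab_criteria()] to one
#' droplet's antibody UMI counts for one barcode set.
#'
#' @param counts named numeric vector of antibody UMI counts (one barcode
#'   set).
#' @param criteria an \code{AbCriteria}.
#' @return list: \code{pass} (logical), \code{reasons} (character vector
#'   naming each failed criterion), \code{top} (most abundant barcode, or
#'   NA when the set is empty).
#' @export
antibody_qc <- function(counts, criteria = ab_criteria()) {
  if (length(counts) < 1L) stop("need >= 1 antibody in the set")
  ord <- order(counts, decreasing = TRUE)
  total <- sum(counts)
  top <- counts[ord[1L]]
  second <- if (length(counts) >= 2L) counts[ord[2L]] else 0
  reasons <- character(0)
  if (total < criteria$min_total_umis)
    reasons <- c(reasons, "criterion_1_low_total")
  if (second > criteria$max_second_fraction * top)
    reasons <- c(reasons, "criterion_2_second_too_high")
  if (top < criteria$min_top_fraction * total)
    reasons <- c(reasons, "criterion_3_top_too_low")
  list(pass = length(reasons) == 0L, reasons = reasons,
       top = if (total > 0) names(counts)[ord[1L]] else NA_character_)
}

#' Demultiplex hashed droplets
#'
#' Applies mRNA QC and the antibody criteria independently to the
#' cell-type and donor barcode sets; retained droplets (all three
#' verdicts pass) are assigned the most abundant barcode of each set.
#' Droplets failing criterion 2 on the cell-type set are annotated
#' multiplet-suspect in the summary.
#'
#' @param counts genes x droplets UMI count matrix (mitochondrial genes
#'   identified by \code{mito_prefix}), or a precomputed per-droplet QC
#'   data.frame with columns \code{droplet}, \code{n_genes},
#'   \code{mito_fraction}.
#' @param ab_type cell-type-antibody x droplets UMI count matrix.
#' @param ab_donor donor-antibody x droplets UMI count matrix.
#' @param criteria an \code{AbCriteria}.
#' @param min_genes_exclusive,max_mito mRNA QC thresholds (see
#'   [mrna_qc()]).
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return list with \code{cells} (data.frame: droplet, n_genes,
#'   mito_fraction, mrna_pass, celltype_ab_pass, donor_ab_pass, retained,
#'   cell_type, donor, failure_reasons, multiplet_suspect) and
#'   \code{summary} (data.frame of counts per failure reason and per
#'   assignment).
#' @export
demux <- function(counts, ab_type, ab_donor, criteria = ab_criteria(),
                  min_genes_exclusive = 500L, max_mito = 0.20,
                  mito_prefix = "MT-") {
  if (is.data.frame(counts)) {
    stopifnot(all(c("droplet", "n_genes", "mito_fraction") %in%
                    names(counts)))
    droplets <- counts$droplet
    n <- length(droplets)
    n_genes <- counts$n_genes
    mito_fraction <- counts$mito_fraction
    precomputed <- TRUE
  } else {
    droplets <- colnames(counts)
    n <- ncol(counts)
    precomputed <- FALSE
  }
  stopifnot(ncol(ab_type) == n, ncol(ab_donor) == n)
  if (n == 0L) {
    cells <- data.frame(droplet = character(0), n_genes = integer(0),
                        mito_fraction = numeric(0), mrna_pass = logical(0),
                        celltype_ab_pass = logical(0),
                        donor_ab_pass = logical(0), retained = logical(0),
                        cell_type = character(0), donor = character(0),
                        failure_reasons = character(0),
                        multiplet_suspect = logical(0))
    return(list(cells = cells, summary = demux_summary(cells)))
  }
  if (!precomputed) {
    is_mito <- startsWith(rownames(counts), mito_prefix)
    depth <- colSums(counts)
    n_genes <- colSums(counts > 0)
    mito_fraction <- ifelse(depth > 0,
                            colSums(counts[is_mito, , drop = FALSE]) / depth,
                            0)
  }
  mrna_pass <- mrna_qc(n_genes, mito_fraction, min_genes_exclusive,
                       max_mito)

  cells <- vector("list", n)
  for (j in seq_len(n)) {
    qt <- antibody_qc(ab_type[, j], criteria)
    qd <- antibody_qc(ab_donor[, j], criteria)
    retained <- mrna_pass[j] && qt$pass && qd$pass
    reasons <- c(if (!mrna_pass[j]) {
      c(if (n_genes[j] <= min_genes_exclusive) "mrna_low_genes",
        if (mito_fraction[j] >= max_mito) "mrna_high_mito")
    },
    if (length(qt$reasons)) paste0("celltype_", qt$reasons),
    if (length(qd$reasons)) paste0("donor_", qd$reasons))
    if (retained && sum(ab_type[, j] == max(ab_type[, j])) > 1L)
      stop("tie for top barcode in a passing droplet; criterion 2 should preclude this")
    cells[[j]] <- data.frame(
      droplet = droplets[j], n_genes = n_genes[j],
      mito_fraction = mito_fraction[j], mrna_pass = mrna_pass[j],
      celltype_ab_pass = qt$pass, donor_ab_pass = qd$pass,
      retained = retained,
      cell_type = if (retained) qt$top else NA_character_,
      donor = if (retained) qd$top else NA_character_,
      failure_reasons = paste(reasons, collapse = ";"),
      multiplet_suspect = "criterion_2_second_too_high" %in% qt$reasons,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  list(cells = cells, summary = demux_summary(cells))
}

demux_summary <- function(cells) {
  reasons <- unlist(strsplit(cells$failure_reasons[cells$failure_reasons != ""],
                             ";", fixed = TRUE))
  reason_tab <- as.data.frame(table(reason = reasons),
                              stringsAsFactors = FALSE)
  assigned <- cells[cells$retained, , drop = FALSE]
  assign_tab <- as.data.frame(table(cell_type = assigned$cell_type,
                                    donor = assigned$donor),
                              stringsAsFactors = FALSE)
  assign_tab <- assign_tab[assign_tab$Freq > 0, , drop = FALSE]
  data.frame(
    metric = c("input", "retained", "multiplet_suspect",
               if (nrow(reason_tab)) paste0("fail_", reason_tab$reason),
               if (nrow(assign_tab)) paste0("assigned_",
                                            gsub(" ", "", assign_tab$cell_type),
                                            "_", assign_tab$donor)),
    count = c(nrow(cells), sum(cells$retained),
              sum(cells$multiplet_suspect),
              if (nrow(reason_tab)) reason_tab$Freq,
              if (nrow(assign_tab)) assign_tab$Freq),
    stringsAsFactors = FALSE)
}
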