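#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (set name -> members), with a
#'   \code{"description"} attribute per element.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop("malformed GMT line ", i, ": fewer than 2 fields")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- fields[2L]
    sets[[fields[1L]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED3+ with 0-based, half-open coordinates. Only the first three columns
#' are interpreted; a fourth column, if present, names the peak.
#'
#' @param path path to the BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name} (0-based half-open).
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": need >=3 fields")
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (start >= end)
      stop("malformed BED line ", i, ": start >= end (", f[2L], " >= ",
           f[3L], ")")
    data.frame(chrom = f[1L], start = start, end = end,
               name = if (length(f) >= 4L) f[4L] else paste0("peak_", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a gene annotation table
#'
#' TSV with columns \code{gene}, \code{chrom}, \code{start}, \code{end},
#' \code{strand} in 0-based, half-open coordinates. The TSS is derived from
#' strand: \code{start} on \code{+}, \code{end - 1} on \code{-}.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with the input columns plus \code{tss}.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(ann$start >= ann$end)
  if (length(bad))
    stop("annotation row ", bad[1L], ": start >= end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1)
  ann
}

#' Write a result table to TSV
#'
#' @param tab a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All thresholds default to the published analysis values: expressed-gene
#' cutoff log2(tpm+1) > 2 in >= 10 samples; single-cell mRNA QC > 500
#' unique genes and < 20\% mitochondrial UMIs; antibody criteria 10 total
#' UMIs / second <= 10\% of top / top >= 75\% of total; UMI read filter
#' >= 5 reads; minimum nonzero cells 100 (gradient) and 60 (subset DE);
#' expression-matched null of 30 genes within 10\% of the s.d.; Bonferroni
#' alpha 0.05.
#'
#' @param seed integer seed recorded with the run.
#' @return named list of parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    expressed_cutoff_log2 = 2,
    expressed_min_samples = 10L,
    variable_gene_sd_cutoff = 1.4,
    variable_gene_cv_top_n = 1545L,
    sc_min_genes_exclusive = 500L,
    sc_max_mito = 0.20,
    ab_min_total_umis = 10L,
    ab_max_second_fraction = 0.10,
    ab_min_top_fraction = 0.75,
    umi_min_reads = 5L,
    min_nonzero_cells_gradient = 100L,
    min_nonzero_cells_subset = 60L,
    matched_null_n = 30L,
    matched_null_tolerance = 0.10,
    bonferroni_alpha = 0.05,
    seed = as.integer(seed)
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path path to the YAML config file.
#' @return [read_config()]: named list merged over [default_config()];
#'   unknown keys are an error.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, user)
}

#' @rdname read_config
#' @param config named list as from [default_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
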