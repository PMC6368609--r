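#' Canonical innateness rank order
#'
#' The seven sorted lymphocyte populations ordered along the innateness
#' gradient: CD4 T = 1, CD8 T = 2, MAIT = 3, iNKT = 4, Vd1 = 5, Vd2 = 6,
#' NK = 7.
#'
#' @return named integer vector (cell-type label -> rank).
#' @export
default_cell_type_ranks <- function() {
  c("CD4 T" = 1L, "CD8 T" = 2L, "MAIT" = 3L, "iNKT" = 4L,
    "Vd1" = 5L, "Vd2" = 6L, "NK" = 7L)
}

#' Hashing antibody barcode sequences
#'
#' DNA barcodes of the hashing antibodies used to label the seven sorted
#' cell populations and the two donors before pooling.
#'
#' @return list with named character vectors \code{cell_type} (7 barcodes;
#'   CD4 and CD8 T cells carry the two CD8-class barcodes used in the
#'   pooled run) and \code{donor} (2 barcodes).
#' @export
hashing_barcodes <- function() {
  list(
    cell_type = c("CD4 T" = "GTCAACTCTTTAGCG", "CD8 T" = "TGATGGCCTATTGGG",
                  "MAIT" = "TTCCGCCTCTCTTTG", "iNKT" = "AGTAAGTTCAGCGTA",
                  "Vd1" = "AAGTATCGTTTCGCA", "Vd2" = "GGTTGCCAGATGTCA",
                  "NK" = "TGTCTTTCCTGCCAG"),
    donor = c("Donor1" = "CTCCTCTGCAATTAC", "Donor2" = "CAGTAGTCACGGTCA")
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Bulk simulation design
#'
#' Defaults mirror the profiled study design: 6 donors x 7 cell types x 2
#' replicates, with 10\% of genes linearly associated with the innateness
#' rank. The generative model on the log2(tpm+1) scale is
#' \deqn{y_{gs} = baseline_g + \beta_g \cdot rank_s + donor_{gd(s)} +
#'   \epsilon_{gs}}
#' with donor effects \eqn{N(0, donor\_sd^2)} and residuals
#' \eqn{N(0, noise\_sd^2)} -- the same model class the gradient fit
#' assumes, so parameter recovery is a fair test.
#'
#' @param n_donors number of donors.
#' @param cell_types ordered character vector of cell types; ranks are
#'   their positions 1..length(cell_types).
#' @param n_replicates replicates per donor x cell type.
#' @param n_genes total genes simulated.
#' @param frac_gradient_genes fraction of genes with nonzero gradient beta.
#' @param beta_range interval the gradient betas are drawn from (uniform),
#'   log2 units per rank step.
#' @param donor_sd s.d. of the per-gene donor random intercept (log2).
#' @param noise_sd residual s.d. (log2).
#' @param baseline_range interval of per-gene baseline log2 expression.
#' @param seed integer seed.
#' @return list of class \code{BulkSimDesign}.
#' @export
bulk_sim_design <- function(n_donors = 6L,
                            cell_types = names(default_cell_type_ranks()),
                            n_replicates = 2L,
                            n_genes = 2000L,
                            frac_gradient_genes = 0.10,
                            beta_range = c(-0.5, 0.5),
                            donor_sd = 0.3,
                            noise_sd = 0.4,
                            baseline_range = c(3, 8),
                            seed = 1L) {
  if (n_donors < 1L || n_replicates < 1L || n_genes < 1L ||
      length(cell_types) < 1L)
    stop("design dimensions must be positive")
  if (frac_gradient_genes < 0 || frac_gradient_genes > 1)
    stop("frac_gradient_genes must be in [0, 1]")
  if (donor_sd < 0 || noise_sd < 0) stop("s.d. values must be >= 0")
  structure(list(n_donors = as.integer(n_donors), cell_types = cell_types,
                 n_replicates = as.integer(n_replicates),
                 n_genes = as.integer(n_genes),
                 frac_gradient_genes = frac_gradient_genes,
                 beta_range = beta_range, donor_sd = donor_sd,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "BulkSimDesign")
}

#' Simulate a bulk (low-input) expression matrix along the gradient
#'
#' Draws log2(tpm+1) values from the additive gradient model in
#' [bulk_sim_design()] and back-transforms to tpm
#' (\code{tpm = 2^y - 1}, floored at 0).
#'
#' @param design a \code{BulkSimDesign}.
#' @return list with \code{matrix} (an \code{ExpressionMatrix} on the tpm
#'   scale) and \code{truth} (data.frame: gene, beta_true, gradient_gene).
#' @export
simulate_bulk <- function(design = bulk_sim_design()) {
  stopifnot(inherits(design, "BulkSimDesign"))
  with_seed(design$seed, {
    n_types <- length(design$cell_types)
    ranks <- seq_len(n_types)
    meta <- expand.grid(replicate = paste0("rep", seq_len(design$n_replicates)),
                        cell_type = design$cell_types,
                        donor = paste0("D", seq_len(design$n_donors)),
                        stringsAsFactors = FALSE)
    meta$rank <- rep(rep(ranks, each = design$n_replicates),
                     design$n_donors)
    meta$sample <- sprintf("%s_%s_%s", meta$donor,
                           gsub(" ", "", meta$cell_type), meta$replicate)
    n_samp <- nrow(meta)

    gene_ids <- sprintf("gene_%04d", seq_len(design$n_genes))
    n_grad <- round(design$frac_gradient_genes * design$n_genes)
    is_grad <- rep(FALSE, design$n_genes)
    if (n_grad > 0L) is_grad[sample.int(design$n_genes, n_grad)] <- TRUE
    beta <- numeric(design$n_genes)
    beta[is_grad] <- stats::runif(n_grad, design$beta_range[1L],
                                  design$beta_range[2L])
    baseline <- stats::runif(design$n_genes, design$baseline_range[1L],
                             design$baseline_range[2L])

    donor_idx <- match(meta$donor, unique(meta$donor))
    donor_eff <- matrix(stats::rnorm(design$n_genes * design$n_donors,
                                     sd = design$donor_sd),
                        design$n_genes, design$n_donors)
    y <- baseline + outer(beta, meta$rank) + donor_eff[, donor_idx] +
      matrix(stats::rnorm(design$n_genes * n_samp, sd = design$noise_sd),
             design$n_genes, n_samp)
    tpm <- pmax(2^y - 1, 0)
    dimnames(tpm) <- list(gene_ids, meta$sample)
    m <- expression_matrix(tpm, meta[, c("sample", "donor", "cell_type",
                                         "replicate")], "tpm")
    truth <- data.frame(gene = gene_ids, beta_true = beta,
                        gradient_gene = is_grad,
                        stringsAsFactors = FALSE)
    list(matrix = m, truth = truth)
  })
}

#' Single-cell + hashing simulation design
#'
#' Emulates the pooled droplet run: seven sorted populations from two
#' donors, each population labeled with a cell-type hashing antibody and
#' each donor with a donor antibody, mixed in one droplet run. Per-cell
#' UMI depth is log-normal around \code{mean_depth}; the mitochondrial UMI
#' fraction is Beta-distributed; hashing antibody UMIs per set are Poisson
#' with a multinomial split placing \code{1 - ambient_antibody_rate} of
#' the mass on the true barcode. Doublets split cell-type antibody mass
#' 50/50 between two distinct types while the donor barcode stays single
#' (cells were pooled within donor runs before mixing).
#'
#' @param cells_per_type droplets per cell type.
#' @param n_donors number of donors (size of the donor barcode set).
#' @param n_genes genes in the simulated count matrix.
#' @param n_mito_genes how many genes carry the \code{MT-} prefix.
#' @param mean_depth mean UMIs per droplet.
#' @param depth_sdlog log-scale s.d. of per-droplet depth.
#' @param mito_shape1,mito_shape2 Beta parameters of the mitochondrial
#'   fraction.
#' @param doublet_rate fraction of droplets containing two cells.
#' @param ambient_antibody_rate fraction of antibody UMIs landing on wrong
#'   barcodes.
#' @param antibody_umis_per_cell Poisson mean of antibody UMIs per barcode
#'   set.
#' @param seed integer seed.
#' @return list of class \code{ScSimDesign}.
#' @export
sc_sim_design <- function(cells_per_type = 150L,
                          n_donors = 2L,
                          n_genes = 1000L,
                          n_mito_genes = 13L,
                          mean_depth = 2500,
                          depth_sdlog = 0.5,
                          mito_shape1 = 2, mito_shape2 = 38,
                          doublet_rate = 0.05,
                          ambient_antibody_rate = 0.05,
                          antibody_umis_per_cell = 100,
                          seed = 1L) {
  if (doublet_rate < 0 || doublet_rate > 1 ||
      ambient_antibody_rate < 0 || ambient_antibody_rate > 1)
    stop("rates must be in [0, 1]")
  if (cells_per_type < 1L || n_genes < 1L || mean_depth <= 0 ||
      antibody_umis_per_cell <= 0 || n_donors < 1L)
    stop("counts must be positive")
  structure(list(cells_per_type = as.integer(cells_per_type),
                 n_donors = as.integer(n_donors),
                 n_genes = as.integer(n_genes),
                 n_mito_genes = as.integer(n_mito_genes),
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 mito_shape1 = mito_shape1, mito_shape2 = mito_shape2,
                 doublet_rate = doublet_rate,
                 ambient_antibody_rate = ambient_antibody_rate,
                 antibody_umis_per_cell = antibody_umis_per_cell,
                 seed = as.integer(seed)),
            class = "ScSimDesign")
}

# multinomial antibody split: (1 - ambient) on the true barcode(s),
# ambient spread evenly over the remaining barcodes
ab_probs <- function(n_barcodes, true_idx, ambient) {
  p <- rep(0, n_barcodes)
  p[true_idx] <- (1 - ambient) / length(true_idx)
  others <- setdiff(seq_len(n_barcodes), true_idx)
  if (length(others)) p[others] <- ambient / length(others)
  else p[true_idx] <- p[true_idx] + ambient / length(true_idx)
  p
}

#' Simulate hashed droplet single-cell data
#'
#' @param design an \code{ScSimDesign}.
#' @return list with \code{counts} (genes x droplets UMI matrix;
#'   mitochondrial genes prefixed \code{MT-}), \code{ab_type} (7 x
#'   droplets cell-type antibody UMI matrix), \code{ab_donor} (donors x
#'   droplets), and \code{truth} (data.frame: droplet, cell_type, donor,
#'   doublet, second_type).
#' @export
simulate_sc <- function(design = sc_sim_design()) {
  stopifnot(inherits(design, "ScSimDesign"))
  with_seed(design$seed, {
    types <- names(default_cell_type_ranks())
    donors <- paste0("Donor", seq_len(design$n_donors))
    n <- length(types) * design$cells_per_type
    truth <- data.frame(
      droplet = sprintf("cell_%05d", seq_len(n)),
      cell_type = rep(types, each = design$cells_per_type),
      donor = sample(donors, n, replace = TRUE),
      doublet = stats::runif(n) < design$doublet_rate,
      second_type = NA_character_, stringsAsFactors = FALSE)
    for (i in which(truth$doublet))
      truth$second_type[i] <- sample(setdiff(types, truth$cell_type[i]), 1L)

    n_mito <- min(design$n_mito_genes, design$n_genes - 1L)
    gene_ids <- c(sprintf("MT-G%02d", seq_len(n_mito)),
                  sprintf("gene_%04d", seq_len(design$n_genes - n_mito)))
    # per-gene relative rates for the non-mito pool, mildly skewed
    rate <- stats::rgamma(design$n_genes - n_mito, shape = 0.8)
    rate <- rate / sum(rate)
    mito_rate <- rep(1 / n_mito, n_mito)

    depth <- pmax(1L, round(stats::rlnorm(
      n, log(design$mean_depth) - design$depth_sdlog^2 / 2,
      design$depth_sdlog)))
    mito_frac <- stats::rbeta(n, design$mito_shape1, design$mito_shape2)
    counts <- matrix(0L, design$n_genes, n,
                     dimnames = list(gene_ids, truth$droplet))
    for (j in seq_len(n)) {
      m_umis <- stats::rbinom(1L, depth[j], mito_frac[j])
      if (m_umis > 0L)
        counts[seq_len(n_mito), j] <-
          stats::rmultinom(1L, m_umis, mito_rate)
      rest <- depth[j] - m_umis
      if (rest > 0L)
        counts[(n_mito + 1L):design$n_genes, j] <-
          stats::rmultinom(1L, rest, rate)
    }

    ab_type <- matrix(0L, length(types), n,
                      dimnames = list(types, truth$droplet))
    ab_donor <- matrix(0L, length(donors), n,
                       dimnames = list(donors, truth$droplet))
    for (j in seq_len(n)) {
      true_t <- match(truth$cell_type[j], types)
      if (truth$doublet[j])
        true_t <- c(true_t, match(truth$second_type[j], types))
      tot_t <- stats::rpois(1L, design$antibody_umis_per_cell)
      if (tot_t > 0L)
        ab_type[, j] <- stats::rmultinom(
          1L, tot_t, ab_probs(length(types), true_t,
                              design$ambient_antibody_rate))
      tot_d <- stats::rpois(1L, design$antibody_umis_per_cell)
      if (tot_d > 0L)
        ab_donor[, j] <- stats::rmultinom(
          1L, tot_d, ab_probs(length(donors),
                              match(truth$donor[j], donors),
                              design$ambient_antibody_rate))
    }
    list(counts = counts, ab_type = ab_type, ab_donor = ab_donor,
         truth = truth)
  })
}

#' Simulate a cohort of per-individual ITC percentages
#'
#' Per-individual percentages (of T cells) for the four major innate
#' T-cell populations, drawn log-normally with long-run means calibrated
#' to the immunophenotyping cohort (MAIT 2.4\%, iNKT 0.09\%, Vd1 1.25\%,
#' Vd2 4.7\%) and a negative age effect on MAIT and Vd2. Ages are uniform
#' on 20-58 years. Values below 0.01 are floored at 0.01 (the convention
#' used for undetectable iNKT before log transformation).
#'
#' @param n_individuals cohort size (>= 2).
#' @param seed integer seed.
#' @param age_coef per-year effect on the log percentage for MAIT and Vd2
#'   (negative by default).
#' @return data.frame: individual, age, sex, MAIT, iNKT, Vd1, Vd2
#'   (percent of T cells).
#' @export
simulate_cohort <- function(n_individuals, seed = 1L, age_coef = -0.03) {
  if (n_individuals < 2L) stop("n_individuals must be >= 2")
  with_seed(seed, {
    target_mean <- c(MAIT = 2.4, iNKT = 0.09, Vd1 = 1.25, Vd2 = 4.7)
    sdlog <- c(MAIT = 1.0, iNKT = 1.1, Vd1 = 0.8, Vd2 = 1.0)
    age_b <- c(MAIT = age_coef, iNKT = 0, Vd1 = 0, Vd2 = age_coef)
    age <- stats::runif(n_individuals, 20, 58)
    half <- 19  # age half-range; ages centered at 39
    out <- data.frame(individual = sprintf("ind_%05d",
                                           seq_len(n_individuals)),
                      age = age,
                      sex = sample(c("F", "M"), n_individuals,
                                   replace = TRUE),
                      stringsAsFactors = FALSE)
    for (ct in names(target_mean)) {
      b <- age_b[[ct]]
      # E[exp(b (age - 39))] under Uniform(20, 58), so the long-run mean
      # stays at the calibrated target despite the age effect
      age_corr <- if (b == 0) 1 else
        (exp(b * half) - exp(-b * half)) / (2 * b * half)
      meanlog <- log(target_mean[[ct]]) - sdlog[[ct]]^2 / 2 -
        log(age_corr) + b * (age - 39)
      v <- stats::rlnorm(n_individuals, meanlog, sdlog[[ct]])
      out[[ct]] <- pmax(v, 0.01)
    }
    tot <- out$MAIT + out$iNKT + out$Vd1 + out$Vd2
    over <- tot > 100
    if (any(over)) {  # keep the ITC sum a valid percentage
      sc <- 100 / tot[over]
      for (ct in names(target_mean)) out[[ct]][over] <- out[[ct]][over] * sc
    }
    out
  })
}

#' Generate random gene sets over a universe
#'
#' @param n_sets number of sets.
#' @param sizes integer vector of set sizes (recycled to \code{n_sets}).
#' @param universe character vector of gene ids to draw from.
#' @param seed integer seed.
#' @return named list of character vectors (GMT-compatible).
#' @export
make_gene_sets <- function(n_sets, sizes, universe, seed = 1L) {
  if (length(universe) == 0L) stop("empty universe")
  if (n_sets == 0L) return(stats::setNames(list(), character(0)))
  sizes <- rep_len(sizes, n_sets)
  if (any(sizes > length(universe)))
    stop("set size exceeds universe size")
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, sizes[i]))
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    sets
  })
}
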