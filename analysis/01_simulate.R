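#!/usr/bin/env Rscript
# Generate the synthetic study datasets: bulk low-input expression along
# the innateness gradient (6 donors x 7 cell types x 2 replicates),
# hashed droplet single-cell data (7 populations, 2 donors), a
# 101-individual immunophenotyping cohort, and random gene sets over the
# simulated universe. Writes all fixtures and their truth tables under
# results/sim/.

suppressMessages(library(innateness))

seed <- 20260919L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bulk <- simulate_bulk(bulk_sim_design(seed = seed))
write_expression(bulk$matrix, file.path(out, "bulk_tpm.tsv"),
                 file.path(out, "bulk_meta.tsv"))
write_results(bulk$truth, file.path(out, "bulk_truth.tsv"))
cat(sprintf("bulk: %d genes x %d samples, %d gradient genes\n",
            nrow(bulk$matrix$values), ncol(bulk$matrix$values),
            sum(bulk$truth$gradient_gene)))

sc <- simulate_sc(sc_sim_design(seed = seed + 1L))
write_triplets <- function(m, path) {  # plain-text sparse triplet dump
  df <- data.frame(gene = rownames(m)[row(m)[m > 0]],
                   droplet = colnames(m)[col(m)[m > 0]],
                   count = m[m > 0])
  write_results(df, path)
}
write_triplets(sc$counts, file.path(out, "sc_counts_triplets.tsv"))
write_results(as.data.frame(t(sc$ab_type)),
              file.path(out, "sc_ab_celltype.tsv"))
write_results(as.data.frame(t(sc$ab_donor)),
              file.path(out, "sc_ab_donor.tsv"))
write_results(sc$truth, file.path(out, "sc_truth.tsv"))
cat(sprintf("single-cell: %d droplets, %.1f%% doublets\n",
            nrow(sc$truth), 100 * mean(sc$truth$doublet)))

cohort <- simulate_cohort(101L, seed = seed + 2L)
write_results(cohort, file.path(out, "cohort.tsv"))
cat(sprintf("cohort: %d individuals, MAIT mean %.2f%%, Vd2 mean %.2f%%\n",
            nrow(cohort), mean(cohort$MAIT), mean(cohort$Vd2)))

# random sets plus one planted innate set drawn from true gradient genes
sets <- make_gene_sets(10L, 25L, bulk$truth$gene, seed = seed + 3L)
up_genes <- bulk$truth$gene[bulk$truth$beta_true > 0.2]
set.seed(seed + 4L)
sets$planted_innate <- sample(up_genes, min(25L, length(up_genes)))
write_gene_sets(sets, file.path(out, "gene_sets.gmt"))
cat(sprintf("gene sets: %d (incl. planted innate set of %d genes)\n",
            length(sets), length(sets$planted_innate)))

write_config(default_config(seed = seed), file.path(out, "run_config.yaml"))
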