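#!/usr/bin/env Rscript
# Demultiplex the simulated hashed droplets: mRNA QC (>500 genes, <20%
# mito UMIs) and the three antibody exclusion criteria on both barcode
# sets, then assignment by top barcode. Evaluates accuracy against the
# simulation truth and summarizes exclusions.

suppressMessages(library(innateness))

sim_dir <- "results/sim"
out <- "results/demux"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tri <- read.delim(file.path(sim_dir, "sc_counts_triplets.tsv"))
genes <- sort(unique(tri$gene))
drops <- unique(tri$droplet)
counts <- matrix(0L, length(genes), length(drops),
                 dimnames = list(genes, drops))
counts[cbind(match(tri$gene, genes), match(tri$droplet, drops))] <-
  tri$count
ab_type <- t(as.matrix(read.delim(file.path(sim_dir, "sc_ab_celltype.tsv"),
                                  check.names = FALSE)))
ab_donor <- t(as.matrix(read.delim(file.path(sim_dir, "sc_ab_donor.tsv"),
                                   check.names = FALSE)))
colnames(ab_type) <- colnames(ab_donor) <- drops
truth <- read.delim(file.path(sim_dir, "sc_truth.tsv"))

res <- demux(counts, ab_type, ab_donor)
write_results(res$cells, file.path(out, "assignments.tsv"))
write_results(res$summary, file.path(out, "qc_summary.tsv"))

cat(sprintf("droplets: %d, retained: %d (%.1f%%)\n", nrow(res$cells),
            sum(res$cells$retained), 100 * mean(res$cells$retained)))
singlet <- res$cells$retained & !truth$doublet
acc <- mean(res$cells$cell_type[singlet] == truth$cell_type[singlet] &
              res$cells$donor[singlet] == truth$donor[singlet])
cat(sprintf("assignment accuracy among retained singlets: %.4f\n", acc))
cat(sprintf("doublets retained: %d of %d planted\n",
            sum(res$cells$retained & truth$doublet), sum(truth$doublet)))
print(res$summary[1:min(10, nrow(res$summary)), ], row.names = FALSE)
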