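#!/usr/bin/env Rscript
# Generate the reference synthetic Drop-seq fixture: 3 major cell types x 2
# subtypes, 2 batches (capture factor 1.5), 8-fold markers, mitochondrial
# and negative-control genes, 7.5% doublets. Writes the MTX/TSV fixture and
# its ground truth under results/fixture/.

suppressPackageStartupMessages(library(natalung))

sim <- simulate_counts(sim_config(seed = 1L))
dir.create("results", showWarnings = FALSE)
write_fixture(sim$counts, "results/fixture", truth = sim$truth)

m <- sim$counts$counts
cat("Fixture written to results/fixture/\n")
cat(sprintf("  %d genes x %d cells in %d batches\n",
            nrow(m), ncol(m), nlevels(sim$counts$batch)))
cat(sprintf("  %d doublets (%.1f%%), %d marker genes, %d control genes\n",
            sum(sim$truth$cells$doublet),
            100 * mean(sim$truth$cells$doublet),
            length(unlist(sim$truth$marker_map)),
            length(sim$truth$control_gene_ids)))
cat(sprintf("  median transcripts/cell %d, median genes/cell %d\n",
            median(Matrix::colSums(m)), median(Matrix::colSums(m > 0))))
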