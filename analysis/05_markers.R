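#!/usr/bin/env Rscript
# Marker statistics on the clustered fixture: binomial differential
# expression with effective size and FDR per cell type, signature genes,
# sensitivity-based enrichment of the planted panels, candidate
# transcription factors, and pseudo-bulk profiles. Writes results/markers/.

suppressPackageStartupMessages(library(natalung))

clusters <- read.table("results/cluster/clusters.tsv", header = TRUE,
                       sep = "\t", colClasses = "character")
fx <- read_fixture("results/qc/filtered")
truth <- read_fixture("results/fixture")$truth
stopifnot(identical(clusters$barcode, colnames(fx$counts$counts)))

dir.create("results/markers", recursive = TRUE, showWarnings = FALSE)

# per-type stats on singlet clusters
use <- clusters$doublet_flag == "FALSE"
cm <- count_matrix(fx$counts$counts[, use], fx$counts$batch[use])
stats <- marker_stats(cm, clusters$major_type[use])
sigs <- select_signatures(stats)
write.table(stats, "results/markers/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(lapply(sigs, as.list), "results/markers/signatures.json",
                     auto_unbox = TRUE, pretty = TRUE)

recall <- vapply(names(truth$marker_map), function(tp)
  mean(truth$marker_map[[tp]] %in% sigs[[tp]]), numeric(1))
cat("Signature sizes:", paste(names(sigs), lengths(sigs), sep = "=",
                              collapse = ", "), "\n")
cat("Planted-marker recall by type:",
    paste(names(recall), round(recall, 2), sep = "=", collapse = ", "), "\n")

# gene-by-type association of the planted marker panel (one-tailed Fisher)
panel_genes <- unlist(truth$marker_map)
assoc <- gene_celltype_association(
  count_matrix(fx$counts$counts[panel_genes, use], fx$counts$batch[use]),
  clusters$major_type[use])
write.table(assoc, "results/markers/associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Associations passing p < 0.05 and enrichment >= 1.5: %d of %d\n",
            sum(assoc$pass), nrow(assoc)))

# candidate TFs: treat the first five markers of each type as the TF list
tf_list <- unlist(lapply(truth$marker_map, head, 5))
tfs <- select_candidate_tfs(stats, tf_list)
writeLines(sort(unique(tfs$gene)), "results/markers/tf_candidates.txt")
cat(sprintf("Candidate TFs selected: %d of %d offered\n",
            length(unique(tfs$gene)), length(tf_list)))

# pseudo-bulk per type for comparison against bulk profiles
pb <- pseudobulk(cm, clusters$major_type[use], per_million = TRUE)
write.table(data.frame(gene = rownames(pb), round(pb, 3)),
            "results/markers/pseudobulk.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Pseudo-bulk profiles written for", ncol(pb), "groups\n")
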