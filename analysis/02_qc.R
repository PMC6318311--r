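#!/usr/bin/env Rscript
# Cell and gene quality control of the fixture: remove cells with < 500
# detected genes or > 10% mitochondrial transcripts, then genes detected in
# < 2 cells. Writes the per-cell QC table and summary under results/qc/.

suppressPackageStartupMessages(library(natalung))

fx <- read_fixture("results/fixture")
cellf <- filter_cells(fx$counts)
filtered <- filter_genes(cellf$matrix)
summ <- qc_metrics(filtered, stage = "filtered")

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.table(cellf$records, "results/qc/cell_qc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(summ), "results/qc/qc_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write_fixture(filtered, "results/qc/filtered")

removed <- table(cellf$records$reason[!cellf$records$keep])
cat(sprintf("QC kept %d of %d cells and %d of %d genes\n",
            ncol(filtered$counts), nrow(cellf$records),
            nrow(filtered$counts), nrow(fx$counts$counts)))
for (r in names(removed))
  cat(sprintf("  removed %d cells: %s\n", removed[[r]], r))
print(summ)
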