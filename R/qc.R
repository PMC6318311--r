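#' Filter droplet cells on detected genes and mitochondrial fraction
#'
#' Removes cells with fewer than `min_genes` detected genes (transcript
#' count > 0) or with more than `max_mito` of their transcripts mapped to
#' mitochondrial genes. Keeps are inclusive (`>= min_genes`,
#' `<= max_mito`), mirroring strict removals of `< min_genes` and
#' `> max_mito`.
#'
#' @param x a [count_matrix()].
#' @param min_genes minimum detected genes per kept cell (default 500).
#' @param max_mito maximum mitochondrial transcript fraction (default 0.10).
#' @param mito_genes explicit mitochondrial gene identifiers; by default
#'   genes whose id starts with `mt-` (case-insensitive).
#' @return list with `matrix` (the filtered [count_matrix()]) and `records`:
#'   one row per input cell with barcode, batch, `genes_detected`,
#'   `total_transcripts`, `mito_fraction`, `keep` and a comma-separated
#'   `reason` for removals.
#' @export
filter_cells <- function(x, min_genes = 500, max_mito = 0.10,
                         mito_genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  mito <- mito_gene_ids(rownames(m), mito_genes)
  if (length(mito) == 0 && max_mito < 1)
    stop("no mitochondrial genes identifiable; supply mito_genes or set max_mito = 1")
  genes_detected <- colSums(m > 0)
  total <- colSums(m)
  mito_frac <- if (length(mito))
    colSums(m[mito, , drop = FALSE]) / pmax(total, 1) else rep(0, ncol(m))
  keep <- genes_detected >= min_genes & mito_frac <= max_mito
  reason <- character(ncol(m))
  low <- genes_detected < min_genes
  hi_mito <- mito_frac > max_mito
  reason[low] <- "low_genes"
  reason[hi_mito] <- ifelse(low[hi_mito], "low_genes,mito", "mito")
  records <- data.frame(barcode = colnames(m),
                        batch = as.character(x$batch),
                        genes_detected = as.integer(genes_detected),
                        total_transcripts = as.integer(total),
                        mito_fraction = as.numeric(mito_frac),
                        keep = keep, reason = reason,
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!any(keep))
    stop("cell filtering removed every cell (min_genes = ", min_genes,
         ", max_mito = ", max_mito, ")")
  list(matrix = count_matrix(m[, keep, drop = FALSE], x$batch[keep]),
       records = records)
}

#' Filter genes on detection breadth
#'
#' Removes genes detected (count > 0) in fewer than `min_cells` cells;
#' retained gene order is preserved.
#'
#' @param x a [count_matrix()].
#' @param min_cells minimum number of cells a kept gene is detected in
#'   (default 2).
#' @return the filtered [count_matrix()].
#' @export
filter_genes <- function(x, min_cells = 2) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts > 0) >= min_cells
  count_matrix(x$counts[keep, , drop = FALSE], x$batch)
}

#' Summarize a count matrix
#'
#' Per-matrix QC summary: cell and gene tallies, median detected genes and
#' transcripts per cell, the fraction of non-zero entries exceeding 3 (a
#' shallow-coverage diagnostic for droplet data), and kept cells per batch.
#'
#' @param x a [count_matrix()].
#' @param stage free-text tag recording at which point of the workflow the
#'   summary was taken (e.g. `"raw"`, `"filtered"`).
#' @return a list of class `qc_summary`.
#' @export
qc_metrics <- function(x, stage = "filtered") {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  nz <- m@x[m@x != 0]
  structure(list(
    stage = stage,
    n_cells = ncol(m),
    n_genes = nrow(m),
    median_genes_per_cell = median(colSums(m > 0)),
    median_transcripts_per_cell = median(colSums(m)),
    fraction_nonzero_gt3 = if (length(nz)) mean(nz > 3) else NA_real_,
    cells_per_batch = as.list(table(x$batch))
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0("<qc_summary:%s> %d cells, %d genes | median genes/cell",
                     " %.0f | median transcripts/cell %.0f | nonzero>3 %.3f\n"),
              x$stage, x$n_cells, x$n_genes, x$median_genes_per_cell,
              x$median_transcripts_per_cell, x$fraction_nonzero_gt3))
  invisible(x)
}

#' Filter plate-based (Fluidigm-style) cells
#'
#' Applies the plate-platform QC contract: cells with total read count below
#' `min_reads` or fewer than `min_genes` expressed genes are removed, and
#' cells highly expressing the selective marker panels of two or more
#' distinct major cell types are removed as cross-well contaminants. A cell
#' "highly expresses" a panel when it detects (count > 0) more than
#' `contam_threshold` of the panel's genes.
#'
#' @param x a [count_matrix()] (expression counts).
#' @param read_counts per-cell total aligned reads; defaults to the column
#'   sums of `x` when the platform does not report reads separately.
#' @param min_reads minimum reads per kept cell (default 5e5).
#' @param min_genes minimum expressed genes per kept cell (default 500).
#' @param major_panels named list of major-type marker gene vectors
#'   (>= 2 panels required).
#' @param contam_threshold panel detection fraction above which a panel
#'   counts as highly expressed (default 0.5).
#' @return list with `matrix` and `records`, as [filter_cells()].
#' @export
filter_cells_plate <- function(x, read_counts = NULL, min_reads = 5e5,
                               min_genes = 500, major_panels,
                               contam_threshold = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(major_panels) < 2)
    stop("contamination filtering needs at least 2 major-type panels")
  m <- x$counts
  if (is.null(read_counts)) read_counts <- colSums(m)
  if (length(read_counts) != ncol(m))
    stop("read_counts must have one entry per cell")
  genes_detected <- colSums(m > 0)
  panel_frac <- vapply(major_panels, function(genes) {
    genes <- intersect(genes, rownames(m))
    if (!length(genes)) return(rep(NA_real_, ncol(m)))
    colSums(m[genes, , drop = FALSE] > 0) / length(genes)
  }, numeric(ncol(m)))
  if (ncol(m) == 1) panel_frac <- matrix(panel_frac, nrow = 1)
  n_high <- rowSums(panel_frac > contam_threshold, na.rm = TRUE)
  keep <- read_counts >= min_reads & genes_detected >= min_genes & n_high < 2
  reason <- character(ncol(m))
  add_reason <- function(reason, hit, code)
    ifelse(hit, ifelse(nzchar(reason), paste(reason, code, sep = ","), code),
           reason)
  reason <- add_reason(reason, read_counts < min_reads, "low_reads")
  reason <- add_reason(reason, genes_detected < min_genes, "low_genes")
  reason <- add_reason(reason, n_high >= 2, "contaminant")
  records <- data.frame(barcode = colnames(m),
                        batch = as.character(x$batch),
                        genes_detected = as.integer(genes_detected),
                        total_reads = as.numeric(read_counts),
                        n_panels_high = as.integer(n_high),
                        keep = keep, reason = reason,
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!any(keep)) stop("plate cell filtering removed every cell")
  list(matrix = count_matrix(m[, keep, drop = FALSE], x$batch[keep]),
       records = records)
}
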