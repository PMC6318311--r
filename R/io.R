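#' Write a count matrix (and optional ground truth) as a plain-text fixture
#'
#' Emits the conventional droplet exchange format: `matrix.mtx`
#' (MatrixMarket coordinate integers), `genes.tsv`, `barcodes.tsv`, plus
#' `batches.tsv` (barcode TAB batch) and, when ground truth is supplied,
#' `truth.json`. The fixture round-trips losslessly through
#' [read_fixture()].
#'
#' @param x a [count_matrix()].
#' @param dir output directory, created if missing.
#' @param truth optional `sim_truth` from [simulate_counts()].
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(x, dir, truth = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "batches.tsv"))
  writeMM(x$counts, paths[1])
  writeLines(rownames(x$counts), paths[2])
  writeLines(colnames(x$counts), paths[3])
  write.table(data.frame(barcode = colnames(x$counts),
                         batch = as.character(x$batch)),
              paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(cells = truth$cells, marker_map = truth$marker_map,
           submarker_map = truth$submarker_map,
           control_gene_ids = truth$control_gene_ids,
           mito_gene_ids = truth$mito_gene_ids,
           config = unclass(truth$config)),
      tp, auto_unbox = TRUE, digits = NA, na = "null", matrix = "columnmajor")
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read a plain-text count fixture
#'
#' Reads the MTX + TSV layout written by [write_fixture()] (or any
#' CellRanger-style `matrix.mtx`/`genes.tsv`/`barcodes.tsv` triple; the
#' batch file and truth file are optional).
#'
#' @param dir directory containing the fixture.
#' @return a list with `counts` (a [count_matrix()]) and `truth` (parsed
#'   `truth.json`, or `NULL`).
#' @export
read_fixture <- function(dir) {
  need <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("fixture files missing: ",
                            paste(missing, collapse = ", "))
  m <- as(readMM(need[1]), "CsparseMatrix")
  genes <- readLines(need[2])
  barcodes <- readLines(need[3])
  # genes.tsv may carry id + symbol columns; the first column is the id
  genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
  dimnames(m) <- list(genes, barcodes)
  batch <- NULL
  bf <- file.path(dir, "batches.tsv")
  if (file.exists(bf)) {
    bt <- read.table(bf, sep = "\t", header = FALSE,
                     col.names = c("barcode", "batch"),
                     colClasses = "character")
    batch <- bt$batch[match(barcodes, bt$barcode)]
    if (anyNA(batch)) stop("batches.tsv does not cover every barcode")
  }
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$cells <- as.data.frame(truth$cells, stringsAsFactors = FALSE)
    class(truth) <- "sim_truth"
  }
  list(counts = count_matrix(m, batch = batch), truth = truth)
}

#' Read a dense digital-gene-expression table
#'
#' Reads the dense tab-separated DGE format (genes in rows, first column the
#' gene identifier, header row of cell barcodes) produced by droplet
#' pre-processing tools, into a sparse [count_matrix()].
#'
#' @param path path to the (optionally gzipped) DGE text file.
#' @param batch optional per-cell batch labels.
#' @return a [count_matrix()].
#' @export
read_dge <- function(path, batch = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  count_matrix(as.matrix(tab), batch = batch)
}
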