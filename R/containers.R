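#' Construct a counts container
#'
#' Bundles a sparse genes x cells UMI count matrix with per-cell batch
#' labels. This is the raw-data container every downstream stage consumes.
#'
#' @param counts genes x cells matrix of non-negative integer counts, with
#'   gene identifiers as rownames and cell barcodes as colnames. Coerced to
#'   a sparse `dgCMatrix`.
#' @param batch per-cell batch labels (length `ncol(counts)`); defaults to a
#'   single batch `"batch1"`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix) and `batch` (factor).
#' @export
count_matrix <- function(counts, batch = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell barcode colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(batch)) batch <- rep("batch1", ncol(counts))
  if (length(batch) != ncol(counts))
    stop("batch labels must match the number of cells")
  structure(list(counts = counts, batch = factor(batch)),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, %d batch(es)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$batch)))
  invisible(x)
}

#' Construct a normalized-matrix container
#'
#' Carries a genes x cells non-negative real matrix together with a stage
#' tag recording which transforms were applied, and the provenance of any
#' scaling factors. Stages progress libnorm -> scaled -> log2; the log
#' transform refuses to run twice.
#'
#' @param mat genes x cells numeric matrix (sparse or dense).
#' @param batch per-cell batch factor.
#' @param stage one of `"libnorm"`, `"scaled"`, `"log2"`.
#' @param provenance free-form list recording applied factors.
#' @return an object of class `norm_matrix`.
#' @export
norm_matrix <- function(mat, batch, stage = c("libnorm", "scaled", "log2"),
                        provenance = list()) {
  stage <- match.arg(stage)
  if (length(batch) != ncol(mat))
    stop("batch labels must match the number of cells")
  structure(list(mat = mat, batch = factor(batch), stage = stage,
                 provenance = provenance),
            class = "norm_matrix")
}

#' @export
dim.norm_matrix <- function(x) dim(x$mat)

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix:%s> %d genes x %d cells\n",
              x$stage, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Identify mitochondrial genes by the conventional "mt-" symbol prefix
# (case-insensitive), unless an explicit list is supplied.
mito_gene_ids <- function(gene_ids, mito_genes = NULL) {
  if (!is.null(mito_genes)) return(intersect(mito_genes, gene_ids))
  gene_ids[grepl("^mt-", gene_ids, ignore.case = TRUE)]
}
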