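#' Library-size normalization
#'
#' Divides each cell's counts by its total transcript count and multiplies
#' by the median total over cells, so every normalized cell sums to the
#' median library size. Zeros stay exact zeros; within-cell gene rank order
#' is preserved.
#'
#' @param x a [count_matrix()].
#' @return a [norm_matrix()] at stage `"libnorm"`; the median total used is
#'   recorded in `provenance$median_total`.
#' @export
library_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- colSums(x$counts)
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(head(colnames(x$counts)[totals == 0], 5), collapse = ", "))
  med <- median(totals)
  mat <- x$counts %*% Diagonal(x = med / totals)
  dimnames(mat) <- dimnames(x$counts)
  norm_matrix(mat, x$batch, stage = "libnorm",
              provenance = list(median_total = med))
}

#' Negative-control-gene batch scaling
#'
#' Estimates a multiplicative scaling factor per batch from a set of
#' negative-control genes — genes whose biological expression is assumed
#' constant across cell types and conditions, so any batch difference in
#' their mean expression is technical. The factor for batch b is the mean
#' over control genes of (mean expression in the reference batch / mean
#' expression in batch b); all entries of batch b are multiplied by it.
#' After scaling, control-gene batch means agree with the reference up to
#' sampling noise.
#'
#' @param x a [norm_matrix()] at stage `"libnorm"` (scaling is applied on
#'   the linear scale, before the log transform).
#' @param control_genes identifiers of the negative-control genes.
#' @param reference reference batch (factor level); defaults to the first.
#' @return list with `matrix` (stage `"scaled"`) and `factors`: a list of
#'   class `scaling_factors` with the per-batch factor (reference = 1), the
#'   control genes used, and any dropped for a zero batch mean.
#' @export
control_gene_scaling <- function(x, control_genes, reference = NULL) {
  stopifnot(inherits(x, "norm_matrix"))
  if (x$stage != "libnorm")
    stop("control-gene scaling expects a libnorm-stage matrix, got ", x$stage)
  batches <- levels(x$batch)
  if (length(batches) < 2) {
    # single batch: scaling is the identity
    factors <- structure(list(control_gene_ids = control_genes,
                              factors = setNames(1, batches),
                              reference = batches[1],
                              dropped_genes = character(0)),
                         class = "scaling_factors")
    out <- x
    out$stage <- "scaled"
    out$provenance$scaling <- factors
    return(list(matrix = out, factors = factors))
  }
  missing <- setdiff(control_genes, rownames(x$mat))
  if (length(missing))
    stop("control genes absent from matrix: ",
         paste(head(missing, 5), collapse = ", "))
  if (is.null(reference)) reference <- batches[1]
  if (!reference %in% batches) stop("unknown reference batch: ", reference)
  ctrl <- x$mat[control_genes, , drop = FALSE]
  batch_means <- vapply(batches, function(b)
    rowMeans(ctrl[, x$batch == b, drop = FALSE]), numeric(length(control_genes)))
  if (length(control_genes) == 1)
    batch_means <- matrix(batch_means, nrow = 1,
                          dimnames = list(control_genes, batches))
  zero_any <- rowSums(batch_means == 0) > 0
  if (all(zero_any))
    stop("every control gene has a zero mean in some batch; cannot scale")
  if (any(zero_any))
    warning(sum(zero_any), " control gene(s) dropped for zero batch mean: ",
            paste(head(control_genes[zero_any], 5), collapse = ", "))
  bm <- batch_means[!zero_any, , drop = FALSE]
  factors <- setNames(colMeans(bm[, reference] / bm), batches)
  mat <- x$mat %*% Diagonal(x = factors[as.character(x$batch)])
  dimnames(mat) <- dimnames(x$mat)
  sf <- structure(list(control_gene_ids = control_genes[!zero_any],
                       factors = factors, reference = reference,
                       dropped_genes = control_genes[zero_any]),
                  class = "scaling_factors")
  out <- norm_matrix(mat, x$batch, stage = "scaled",
                     provenance = c(x$provenance, list(scaling = sf)))
  list(matrix = out, factors = sf)
}

#' Log2(x + 1) transform
#'
#' Entrywise `log2(value + 1)`; zeros map to zeros and the transform
#' refuses to run twice (stage guard).
#'
#' @param x a [norm_matrix()] at stage `"libnorm"` or `"scaled"`.
#' @return a [norm_matrix()] at stage `"log2"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "norm_matrix"))
  if (!x$stage %in% c("libnorm", "scaled"))
    stop("log_transform expects stage libnorm or scaled, got ", x$stage)
  mat <- x$mat
  if (is(mat, "sparseMatrix")) {
    if (any(mat@x < 0)) stop("negative entries cannot be log-transformed")
    mat@x <- log2(mat@x + 1)
  } else {
    if (any(mat < 0)) stop("negative entries cannot be log-transformed")
    mat <- log2(mat + 1)
  }
  norm_matrix(mat, x$batch, stage = "log2",
              provenance = c(x$provenance, list(log_base = 2)))
}

#' Batch-shift report on probe (housekeeping) genes
#'
#' Tabulates, for a set of probe genes, the per-batch mean expression and
#' expression frequency (fraction of cells with value > 0) before and after
#' batch scaling, the diagnostic used to judge whether scaling removed the
#' batch difference. Commonly probed: Actb, Actg1, B2m, Rps6, Rpl13.
#'
#' @param before a [norm_matrix()] (pre-scaling).
#' @param after optional [norm_matrix()] (post-scaling); when supplied the
#'   report has a row per probe x batch x stage.
#' @param probe_genes probe gene identifiers; defaults to the five standard
#'   housekeeping genes intersected with the matrix.
#' @return data.frame with columns gene, batch, stage, mean_expr, freq_expr.
#' @export
batch_shift_report <- function(before, after = NULL, probe_genes = NULL) {
  stopifnot(inherits(before, "norm_matrix"))
  default_probes <- c("Actb", "Actg1", "B2m", "Rps6", "Rpl13")
  if (is.null(probe_genes)) probe_genes <- default_probes
  found <- intersect(probe_genes, rownames(before$mat))
  missing <- setdiff(probe_genes, found)
  if (length(missing))
    warning("probe genes absent and skipped: ",
            paste(missing, collapse = ", "))
  if (!length(found)) stop("no probe genes present in the matrix")
  one_stage <- function(x, stage) {
    do.call(rbind, lapply(levels(x$batch), function(b) {
      sub <- x$mat[found, x$batch == b, drop = FALSE]
      data.frame(gene = found, batch = b, stage = stage,
                 mean_expr = as.numeric(rowMeans(sub)),
                 freq_expr = as.numeric(rowMeans(sub > 0)),
                 stringsAsFactors = FALSE)
    }))
  }
  rep <- one_stage(before, before$stage)
  if (!is.null(after)) rep <- rbind(rep, one_stage(after, after$stage))
  rownames(rep) <- NULL
  rep
}
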