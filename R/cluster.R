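#' Per-gene mean/dispersion table for variable-gene selection
#'
#' For each gene, computes the mean and dispersion (variance / mean) of the
#' de-logged expression (2^x - 1), the log2 mean, and a dispersion z-score
#' standardized within equal-frequency bins of the log2 mean. Binning
#' removes the mean-dispersion trend so that genes are compared against
#' peers of similar abundance.
#'
#' @param x a [norm_matrix()] at stage `"log2"`.
#' @param n_bins number of equal-frequency mean bins (default 20); bins
#'   with fewer than 2 genes are merged with their lower neighbour.
#' @return data.frame with gene, mean_linear, log_mean, dispersion, bin,
#'   dispersion_z; genes never detected get dispersion NA and z -Inf.
#' @export
hvg_stats <- function(x, n_bins = 20) {
  stopifnot(inherits(x, "norm_matrix"))
  if (x$stage != "log2") stop("hvg_stats expects a log2-stage matrix")
  lin <- x$mat
  if (is(lin, "sparseMatrix")) lin@x <- 2^lin@x - 1 else lin <- 2^lin - 1
  mu <- as.numeric(rowMeans(lin))
  n <- ncol(lin)
  ex2 <- as.numeric(rowMeans(lin^2))
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  log_mean <- log2(mu + 1)
  # equal-frequency bins on the log mean (detected genes only)
  bin <- rep(NA_integer_, length(mu))
  det <- which(mu > 0)
  if (length(det)) {
    br <- unique(quantile(log_mean[det], probs = seq(0, 1, length.out = n_bins + 1)))
    bin[det] <- as.integer(cut(log_mean[det], breaks = br, include.lowest = TRUE))
    # merge undersized bins downward so every bin can be standardized
    tab <- table(bin[det])
    small <- as.integer(names(tab)[tab < 2])
    for (b in small) {
      tgt <- if (b > 1) b - 1L else b + 1L
      bin[!is.na(bin) & bin == b] <- tgt
    }
  }
  z <- rep(-Inf, length(mu))
  for (b in unique(stats::na.omit(bin))) {
    i <- which(!is.na(bin) & bin == b)
    m <- mean(disp[i]); s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  data.frame(gene = rownames(x$mat), mean_linear = mu, log_mean = log_mean,
             dispersion = disp, bin = bin, dispersion_z = z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select highly variable genes
#'
#' Returns genes whose log2 mean lies inside `mean_range` and whose
#' bin-standardized dispersion z-score is at least `z_cutoff`, sorted by
#' decreasing z. See [hvg_stats()] for the dispersion definition.
#'
#' @inheritParams hvg_stats
#' @param mean_range closed interval for the log2 mean (default
#'   `c(0.0125, 8)`).
#' @param z_cutoff minimum dispersion z-score (default 1).
#' @return character vector of gene identifiers (possibly empty).
#' @export
select_hvg <- function(x, n_bins = 20, mean_range = c(0.0125, 8),
                       z_cutoff = 1) {
  st <- hvg_stats(x, n_bins = n_bins)
  hit <- st$log_mean >= mean_range[1] & st$log_mean <= mean_range[2] &
    is.finite(st$dispersion_z) & st$dispersion_z >= z_cutoff
  g <- st$gene[hit]
  g[order(st$dispersion_z[hit], decreasing = TRUE)]
}

#' PCA on z-scored highly variable genes
#'
#' Standardizes each selected gene to zero mean and unit variance across
#' cells (values capped at +/- `cap` to bound outlier leverage), then runs
#' exact PCA over cells. Constant genes are dropped with a warning.
#'
#' @param x a [norm_matrix()] at stage `"log2"`.
#' @param genes genes to use (typically from [select_hvg()]); >= 2 required.
#' @param cap absolute bound applied to z-scores (default 10).
#' @return list of class `pc_model`: `scores` (cells x components),
#'   `loadings` (genes x components), `sdev`, `genes`, and `cap`.
#' @export
pca_reduce <- function(x, genes, cap = 10) {
  stopifnot(inherits(x, "norm_matrix"))
  genes <- intersect(genes, rownames(x$mat))
  if (length(genes) < 2) stop("PCA needs at least 2 genes")
  if (ncol(x$mat) < 3) stop("PCA needs at least 3 cells")
  sub <- as.matrix(x$mat[genes, , drop = FALSE])
  mu <- rowMeans(sub)
  s <- apply(sub, 1, sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped before PCA")
    sub <- sub[!const, , drop = FALSE]
    mu <- mu[!const]; s <- s[!const]
    if (nrow(sub) < 2) stop("fewer than 2 non-constant genes for PCA")
  }
  z <- (sub - mu) / s
  z[z > cap] <- cap
  z[z < -cap] <- -cap
  fit <- prcomp(t(z), center = FALSE, scale. = FALSE)
  structure(list(scores = fit$x, loadings = fit$rotation, sdev = fit$sdev,
                 genes = rownames(sub), cap = cap),
            class = "pc_model")
}

#' Select principal components by standard-deviation threshold
#'
#' Keeps components whose standard deviation strictly exceeds `threshold`
#' (3 for the major-type pass, 2 for subtype passes). When the threshold
#' alone keeps fewer than 2 components, the first 2 are kept with a
#' warning, so that downstream graph construction stays defined.
#'
#' @param model a `pc_model` from [pca_reduce()].
#' @param threshold standard-deviation cutoff.
#' @return integer vector of selected component indices.
#' @export
select_pcs <- function(model, threshold) {
  stopifnot(inherits(model, "pc_model"))
  sel <- which(model$sdev > threshold)
  if (length(sel) < 2) {
    warning("sd threshold ", threshold, " keeps ", length(sel),
            " component(s); forcing the first 2")
    sel <- seq_len(min(2L, length(model$sdev)))
  }
  sel
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Location-scale batch adjustment of a log-scale expression matrix by the
#' parametric empirical-Bayes ComBat method: per-gene batch effects are
#' estimated, shrunk toward batch-level priors, and removed. Genes with
#' zero variance are passed through unchanged.
#'
#' @param x a [norm_matrix()] at stage `"log2"` with >= 2 batches of >= 2
#'   cells each.
#' @return a [norm_matrix()], same shape and stage, batch-corrected.
#' @export
combat_correct <- function(x) {
  stopifnot(inherits(x, "norm_matrix"))
  if (x$stage != "log2") stop("combat_correct expects a log2-stage matrix")
  tab <- table(x$batch)
  if (length(tab) < 2) stop("batch correction needs >= 2 batches")
  if (any(tab < 2)) stop("every batch needs >= 2 cells")
  dense <- as.matrix(x$mat)
  v <- apply(dense, 1, var)
  varying <- v > 0
  corrected <- dense
  if (sum(varying) >= 2) {
    quiet <- utils::capture.output(suppressMessages(
      adj <- sva::ComBat(dat = dense[varying, , drop = FALSE],
                         batch = x$batch)))
    corrected[varying, ] <- adj
  }
  norm_matrix(corrected, x$batch, stage = "log2",
              provenance = c(x$provenance, list(combat = TRUE)))
}

#' Jaccard-weighted kNN Louvain clustering
#'
#' Builds a k-nearest-neighbour graph in Euclidean space over the supplied
#' coordinates (PC scores), re-weights each edge (i, j) by the Jaccard
#' overlap of the two cells' neighbour sets, drops zero-weight edges, and
#' maximizes modularity with the Louvain algorithm. Cluster labels are
#' integers 1..K ordered by decreasing cluster size.
#'
#' @param scores numeric matrix, cells x dimensions (rownames = barcodes).
#' @param k neighbours per cell; default `max(10, round(0.25 * sqrt(n)))`,
#'   kept small so that communities at the percent scale (such as doublet
#'   clusters) stay resolvable (a community survives only when k is below
#'   its size).
#' @param seed integer seed for the Louvain pass.
#' @return integer vector of cluster labels, named by barcode.
#' @export
jaccard_louvain <- function(scores, k = NULL, seed = 0L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(k)) k <- max(10L, as.integer(round(0.25 * sqrt(n))))
  if (k <= 1) stop("k must be > 1")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(scores))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  # sparse neighbour indicator; A %*% t(A) counts shared neighbours
  A <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.integer(t(nn)),
                    x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)
  # candidate edges: directed kNN pairs, symmetrized
  ei <- rep(seq_len(n), each = k)
  ej <- as.integer(t(nn))
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  shared <- inter[cbind(lo, hi)]
  w <- shared / (2 * k - shared)
  pos <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[pos], to = hi[pos], weight = w[pos]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = 1))
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  # relabel by decreasing size; ties by first occurrence
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(scores)
  out
}

#' t-SNE embedding of PC scores
#'
#' Two-dimensional t-distributed stochastic neighbour embedding for
#' visualization only: clustering and statistics never consume it.
#'
#' @param scores cells x dimensions matrix of PC scores.
#' @param seed integer seed (the embedding is deterministic given it).
#' @param perplexity t-SNE perplexity; default `min(30, (n - 2) %/% 3)`.
#' @return cells x 2 coordinate matrix, rownames preserved.
#' @export
tsne_embed <- function(scores, seed = 0L, perplexity = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 5) stop("t-SNE needs at least 5 cells")
  if (is.null(perplexity)) perplexity <- max(1, min(30, (n - 2) %/% 3))
  fit <- with_seed(seed,
    Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                 pca = FALSE, check_duplicates = FALSE))
  out <- fit$Y
  rownames(out) <- rownames(scores)
  colnames(out) <- c("tsne1", "tsne2")
  out
}

#' Flag doublet clusters by multi-panel marker expression
#'
#' A cluster is flagged as a likely doublet cluster when, for two or more
#' distinct major-type marker panels, the mean within-cluster expression
#' frequency of the panel's genes exceeds `expr_threshold` — the signature
#' of droplets that captured two cells of different major types.
#'
#' @param x a [count_matrix()] or [norm_matrix()] (expression is value > 0).
#' @param labels per-cell cluster labels.
#' @param panels named list (>= 2) of major-type marker gene vectors.
#' @param expr_threshold mean panel expression frequency above which a
#'   panel counts as expressed by the cluster (default 0.5).
#' @return vector of flagged cluster labels (possibly empty).
#' @export
flag_doublet_clusters <- function(x, labels, panels, expr_threshold = 0.5) {
  if (length(panels) < 2) stop("doublet flagging needs >= 2 panels")
  mat <- if (inherits(x, "count_matrix")) x$counts else x$mat
  if (length(labels) != ncol(mat)) stop("labels must cover all cells")
  freq <- panel_frequencies(mat, labels, panels)
  flagged <- rownames(freq)[rowSums(freq > expr_threshold, na.rm = TRUE) >= 2]
  flagged
}

# mean expression frequency of each panel's genes within each cluster
# (clusters x panels)
panel_frequencies <- function(mat, labels, panels) {
  labels <- as.character(labels)
  cl <- unique(labels)
  out <- matrix(NA_real_, length(cl), length(panels),
                dimnames = list(cl, names(panels)))
  B <- mat > 0
  for (p in names(panels)) {
    genes <- intersect(panels[[p]], rownames(mat))
    if (!length(genes)) next
    gf <- B[genes, , drop = FALSE]
    for (k in cl)
      out[k, p] <- mean(rowMeans(gf[, labels == k, drop = FALSE]))
  }
  out
}

#' Assign clusters to cell types by marker-panel enrichment
#'
#' Labels each cluster with the marker panel maximizing the mean
#' sensitivity-based enrichment score of the panel's genes in that cluster
#' (see [enrichment_score()]); the margin to the runner-up panel is
#' reported and exact ties yield the label `"ambiguous"`.
#'
#' @param labels per-cell cluster labels.
#' @param x a [count_matrix()] or [norm_matrix()] (expression is value > 0).
#' @param panels named list of marker panels at the matching level.
#' @return data.frame with cluster, label, score, margin, runner_up.
#' @export
assign_cell_types <- function(labels, x, panels) {
  mat <- if (inherits(x, "count_matrix")) x$counts else x$mat
  labels <- as.character(labels)
  if (length(labels) != ncol(mat)) stop("labels must cover all cells")
  B <- mat > 0
  d <- ncol(mat)
  b_tot <- rowSums(B)
  cl <- unique(labels)
  scores <- matrix(NA_real_, length(cl), length(panels),
                   dimnames = list(cl, names(panels)))
  for (p in names(panels)) {
    genes <- intersect(panels[[p]], rownames(mat))
    if (!length(genes))
      stop("panel '", p, "' has no genes present in the matrix")
    for (k in cl) {
      in_k <- labels == k
      a <- rowSums(B[genes, in_k, drop = FALSE])
      b <- b_tot[genes]
      es <- ifelse(b > 0, (a / b) / (sum(in_k) / d), NA_real_)
      scores[k, p] <- mean(es, na.rm = TRUE)
    }
  }
  res <- do.call(rbind, lapply(cl, function(k) {
    s <- sort(scores[k, ], decreasing = TRUE)
    tie <- length(s) > 1 && isTRUE(all.equal(unname(s[1]), unname(s[2])))
    data.frame(cluster = k,
               label = if (tie) "ambiguous" else names(s)[1],
               score = as.numeric(s[1]),
               margin = if (length(s) > 1) as.numeric(s[1] - s[2]) else NA_real_,
               runner_up = if (length(s) > 1) names(s)[2] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Cell-type dendrogram
#'
#' Represents each cell type by the average expression of its cells over a
#' gene set (typically the union of signature genes), computes pairwise
#' distance as 1 - Pearson correlation, and builds a hierarchical merge
#' tree (Ward linkage by default; average linkage reproduces the
#' plate-data clustering contract).
#'
#' @param x a [norm_matrix()] (log scale recommended).
#' @param type_labels per-cell type labels (>= 3 distinct types).
#' @param genes gene set for the profiles; default all genes.
#' @param linkage hclust method (default `"ward.D2"`; use `"average"` for
#'   the plate contract).
#' @return list of class `type_dendrogram`: `hclust`, `profiles`
#'   (genes x types), `linkage`.
#' @export
type_dendrogram <- function(x, type_labels, genes = NULL,
                            linkage = "ward.D2") {
  mat <- if (inherits(x, "norm_matrix")) x$mat else x
  type_labels <- as.character(type_labels)
  if (length(type_labels) != ncol(mat)) stop("labels must cover all cells")
  types <- unique(type_labels)
  if (length(types) < 3) stop("dendrogram needs >= 3 types")
  if (is.null(genes)) genes <- rownames(mat)
  genes <- intersect(genes, rownames(mat))
  prof <- vapply(types, function(t)
    as.numeric(rowMeans(mat[genes, type_labels == t, drop = FALSE])),
    numeric(length(genes)))
  rownames(prof) <- genes
  d <- as.dist(1 - cor(prof))
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, profiles = prof, linkage = linkage),
            class = "type_dendrogram")
}

#' Serialize a type dendrogram to Newick
#'
#' @param dend a `type_dendrogram` from [type_dendrogram()].
#' @return single Newick string (merge heights as branch lengths).
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "type_dendrogram"))
  ape::write.tree(ape::as.phylo(dend$hclust))
}

#' Iterative subtype clustering under each major type
#'
#' For every non-doublet major cluster with at least `min_cells` cells:
#' restrict the log-scale matrix to its cells, apply empirical-Bayes batch
#' correction when more than one batch is present (with >= 2 cells each),
#' re-select highly variable genes, re-run PCA keeping components with sd
#' > `sd_threshold` (default 2 for subtype passes), and re-cluster with
#' Jaccard-Louvain. Major types below `min_cells` are skipped with a
#' warning and keep subtype NA.
#'
#' @param x a [norm_matrix()] at stage `"log2"` (uncorrected; correction is
#'   applied per major type).
#' @param major_labels per-cell major cluster labels.
#' @param doublet_clusters major cluster labels to exclude from recursion.
#' @param min_cells minimum major-type size to subcluster (default 40).
#' @param sd_threshold PC sd cutoff for subtype passes (default 2).
#' @param hvg_args list of arguments for [select_hvg()].
#' @param min_hvg if the cutoff yields fewer genes than this, fall back to
#'   the top `fallback_n` genes by dispersion z (default 10 / 50).
#' @param fallback_n see `min_hvg`.
#' @param k kNN parameter passed to [jaccard_louvain()] (default
#'   size-adaptive).
#' @param seed master seed; each major type uses a fixed offset from it.
#' @return data.frame with barcode, major_cluster, subtype_cluster (e.g.
#'   `"2.1"`, NA for skipped or doublet clusters).
#' @export
iterate_subclusters <- function(x, major_labels, doublet_clusters = character(0),
                                min_cells = 40, sd_threshold = 2,
                                hvg_args = list(), min_hvg = 10,
                                fallback_n = 50, k = NULL, seed = 0L) {
  stopifnot(inherits(x, "norm_matrix"))
  if (x$stage != "log2") stop("subclustering expects a log2-stage matrix")
  major_labels <- as.character(major_labels)
  barcodes <- colnames(x$mat)
  out <- data.frame(barcode = barcodes, major_cluster = major_labels,
                    subtype_cluster = NA_character_,
                    stringsAsFactors = FALSE)
  majors <- sort(setdiff(unique(major_labels), as.character(doublet_clusters)))
  for (idx in seq_along(majors)) {
    mj <- majors[idx]
    in_mj <- major_labels == mj
    if (sum(in_mj) < min_cells) {
      warning("major cluster ", mj, " has ", sum(in_mj),
              " cells (< ", min_cells, "); subtype pass skipped")
      next
    }
    sub <- norm_matrix(x$mat[, in_mj, drop = FALSE],
                       droplevels(x$batch[in_mj]), stage = "log2")
    tab <- table(sub$batch)
    if (length(tab) > 1 && all(tab >= 2)) sub <- combat_correct(sub)
    hvg <- do.call(select_hvg, c(list(sub), hvg_args))
    if (length(hvg) < min_hvg) {
      st <- hvg_stats(sub)
      st <- st[is.finite(st$dispersion_z), , drop = FALSE]
      hvg <- head(st$gene[order(st$dispersion_z, decreasing = TRUE)],
                  fallback_n)
    }
    if (length(hvg) < 2) next
    pm <- pca_reduce(sub, hvg)
    sel <- suppressWarnings(select_pcs(pm, sd_threshold))
    labs <- jaccard_louvain(pm$scores[, sel, drop = FALSE], k = k,
                            seed = seed + 1000L + idx)
    out$subtype_cluster[in_mj] <- paste(mj, labs, sep = ".")
  }
  out
}
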