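#' Expression-frequency counts per gene and cluster
#'
#' For every (gene, cluster) pair, counts cells expressing the gene
#' (transcript count > 0) inside and outside the cluster and derives the
#' in/out/overall expression frequencies — the skeleton on which the
#' binomial marker test, effective size, and sensitivity are built.
#'
#' @param x a [count_matrix()], [norm_matrix()], or bare matrix.
#' @param labels per-cell cluster labels covering all cells.
#' @return data.frame with gene, cluster, m_in, n_in, m_out, n_out,
#'   freq_in, freq_out, freq_all.
#' @export
expression_frequency <- function(x, labels) {
  mat <- if (inherits(x, "count_matrix")) x$counts
         else if (inherits(x, "norm_matrix")) x$mat else x
  labels <- as.character(labels)
  if (length(labels) != ncol(mat)) stop("labels must cover all cells")
  B <- mat > 0
  m_all <- rowSums(B)
  n <- ncol(mat)
  cl <- unique(labels)
  do.call(rbind, lapply(cl, function(k) {
    in_k <- labels == k
    n_in <- sum(in_k)
    m_in <- as.numeric(rowSums(B[, in_k, drop = FALSE]))
    m_out <- m_all - m_in
    n_out <- n - n_in
    data.frame(gene = rownames(mat), cluster = k,
               m_in = m_in, n_in = n_in, m_out = m_out, n_out = n_out,
               freq_in = m_in / n_in,
               freq_out = if (n_out > 0) m_out / n_out else NA_real_,
               freq_all = m_all / n,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' One-tailed binomial expression-frequency test
#'
#' Tests whether a gene is detected more frequently inside a cluster than
#' its frequency in all other cells: the enrichment tail probability
#' P(X >= m_in) for X ~ Binomial(n_in, p0) with p0 the out-of-cluster
#' expression frequency. A zero out-frequency is replaced by the
#' pseudo-frequency 1 / (n_out + 1) so the tail is defined. Computed by
#' exact tail summation (no normal approximation). Note the out-frequency
#' is plugged in as known, so the test is calibrated only when the
#' out-group is much larger than the cluster (its intended
#' cluster-versus-rest use).
#'
#' @param m_in expressing cells in the cluster (vectorized).
#' @param n_in cluster size.
#' @param freq_out expression frequency outside the cluster.
#' @param n_out size of the out-group (needed for the pseudo-frequency
#'   when `freq_out` is 0).
#' @param alternative `"enriched"` (default) for P(X >= m_in),
#'   `"depleted"` for P(X <= m_in).
#' @return vector of p-values.
#' @export
binomial_de <- function(m_in, n_in, freq_out, n_out = NULL,
                        alternative = c("enriched", "depleted")) {
  alternative <- match.arg(alternative)
  if (any(m_in < 0 | m_in > n_in)) stop("need 0 <= m_in <= n_in")
  if (any(freq_out < 0 | freq_out > 1)) stop("freq_out must lie in [0, 1]")
  p0 <- freq_out
  if (any(freq_out == 0)) {
    if (is.null(n_out))
      stop("freq_out of 0 requires n_out for the pseudo-frequency")
    eps <- 1 / (n_out + 1)
    p0 <- pmax(freq_out, eps)
  }
  if (alternative == "enriched")
    pbinom(m_in - 1, n_in, p0, lower.tail = FALSE)
  else
    pbinom(m_in, n_in, p0, lower.tail = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted p-values (same order).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Effective size of a marker gene
#'
#' Ratio of a gene's expression frequency inside a cluster to its frequency
#' in all other cells. A zero out-frequency is replaced by the
#' pseudo-frequency 1 / (n_out + 1); a zero in-frequency gives 0.
#'
#' @param freq_in,freq_out expression frequencies in \[0, 1\] (vectorized).
#' @param n_out out-group size, required when any `freq_out` is 0.
#' @return vector of effective sizes.
#' @export
effective_size <- function(freq_in, freq_out, n_out = NULL) {
  if (any(freq_in < 0 | freq_in > 1 | freq_out < 0 | freq_out > 1))
    stop("frequencies must lie in [0, 1]")
  denom <- freq_out
  zero <- freq_out == 0
  if (any(zero)) {
    if (is.null(n_out))
      stop("freq_out of 0 requires n_out for the pseudo-frequency")
    denom[zero] <- 1 / (rep_len(n_out, length(freq_out))[zero] + 1)
  }
  ifelse(freq_in == 0, 0, freq_in / denom)
}

#' Full marker-statistics table
#'
#' Combines [expression_frequency()], [effective_size()], sensitivity
#' (m_in / (m_in + m_out): the fraction of all expressing cells that lie in
#' the cluster), the one-tailed binomial p-value, and the BH false
#' discovery rate (adjusted across genes within each cluster).
#'
#' @inheritParams expression_frequency
#' @return data.frame: the [expression_frequency()] columns plus
#'   effective_size, sensitivity, p, fdr.
#' @export
marker_stats <- function(x, labels) {
  st <- expression_frequency(x, labels)
  st$effective_size <- effective_size(st$freq_in, st$freq_out, st$n_out)
  st$sensitivity <- ifelse(st$m_in + st$m_out > 0,
                           st$m_in / (st$m_in + st$m_out), 0)
  st$p <- binomial_de(st$m_in, st$n_in, st$freq_out, st$n_out)
  st$fdr <- ave(st$p, st$cluster, FUN = bh_fdr)
  st
}

#' Select cluster signature genes
#'
#' Applies the four signature criteria — binomial FDR below `fdr_max`,
#' effective size at least `es_min`, detection in at least `freq_in_min` of
#' the cluster's cells, detection in less than `freq_all_max` of all cells
#' — then ranks the survivors by sensitivity (descending), FDR (ascending)
#' and gene id, and keeps up to `max_genes` per cluster.
#'
#' @param stats a [marker_stats()] table.
#' @param fdr_max FDR cutoff, strict (default 0.05).
#' @param es_min minimum effective size, inclusive (default 2).
#' @param freq_in_min minimum in-cluster frequency, inclusive (default 0.2).
#' @param freq_all_max overall-frequency cutoff, strict (default 0.4).
#' @param max_genes signature length cap (default 100).
#' @return list of class `signature_set`: per-cluster character vectors of
#'   signature genes (possibly empty), with the qualifying stats rows in
#'   `attr(, "table")` and the criteria in `attr(, "criteria")`.
#' @export
select_signatures <- function(stats, fdr_max = 0.05, es_min = 2,
                              freq_in_min = 0.2, freq_all_max = 0.4,
                              max_genes = 100) {
  need <- c("gene", "cluster", "freq_in", "freq_all", "effective_size",
            "sensitivity", "fdr")
  if (!all(need %in% names(stats))) stop("stats table is missing columns")
  ok <- stats$fdr < fdr_max & stats$effective_size >= es_min &
    stats$freq_in >= freq_in_min & stats$freq_all < freq_all_max
  tab <- stats[ok, , drop = FALSE]
  tab <- tab[order(tab$cluster, -tab$sensitivity, tab$fdr, tab$gene), ,
             drop = FALSE]
  sigs <- lapply(split(tab, tab$cluster), function(d)
    head(d$gene, max_genes))
  # clusters with empty signatures still appear
  all_cl <- unique(as.character(stats$cluster))
  for (k in setdiff(all_cl, names(sigs))) sigs[[k]] <- character(0)
  sigs <- sigs[order(names(sigs))]
  kept <- do.call(rbind, lapply(names(sigs), function(k)
    tab[tab$cluster == k & tab$gene %in% sigs[[k]], , drop = FALSE]))
  structure(sigs, class = "signature_set", table = kept,
            criteria = list(fdr_max = fdr_max, es_min = es_min,
                            freq_in_min = freq_in_min,
                            freq_all_max = freq_all_max,
                            max_genes = max_genes))
}

#' Sensitivity-based enrichment score
#'
#' For a gene A and cell type X: `enrichment = (a/b) / (c/d)` where a is
#' the number of cells positively expressing A in X, b the total number of
#' cells expressing A, c the number of cells in X, and d the total number
#' of cells. `a/b` is the sensitivity of the gene for the type; dividing
#' by the type's share of all cells (`c/d`) gives 1 for a gene expressed
#' independently of type. Undefined scores (b = 0 or c = 0) are reported
#' as missing, never 0.
#'
#' @param a,b,c,d the four counts (vectorized).
#' @return data.frame with a, b, c, d, sensitivity, enrichment.
#' @export
enrichment_score <- function(a, b, c, d) {
  bad <- a > pmin(b, c) | b > d | c > d | a < 0 | b < 0 | c < 0 | d < 0
  if (any(bad))
    stop("inconsistent counts: need a <= min(b, c), b <= d, c <= d")
  sens <- ifelse(b > 0, a / b, NA_real_)
  enr <- ifelse(b > 0 & c > 0, (a / b) / (c / d), NA_real_)
  data.frame(a = a, b = b, c = c, d = d,
             sensitivity = sens, enrichment = enr)
}

#' One-tailed Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom and a one-tailed p-value in the requested direction (the
#' plate-platform differential-expression contract).
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param direction `"greater"` tests mean(x) > mean(y); `"less"` the
#'   reverse.
#' @return list with `t`, `df`, `p`.
#' @export
welch_de <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  if (vx == 0 && vy == 0) {
    warning("zero variance in both groups; p from mean comparison only")
    mdiff <- mean(x) - mean(y)
    p <- if (mdiff == 0) 1
         else if (direction == "greater") as.numeric(mdiff < 0)
         else as.numeric(mdiff > 0)
    return(list(t = if (mdiff == 0) 0 else sign(mdiff) * Inf,
                df = nx + ny - 2, p = p))
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- if (direction == "greater") pt(t, df, lower.tail = FALSE)
       else pt(t, df, lower.tail = TRUE)
  list(t = t, df = df, p = p)
}

#' Gene-by-cell-type association (one-tailed Fisher)
#'
#' For every gene and cell type, builds the 2x2 table of expressing /
#' non-expressing cells inside / outside the type, computes the one-tailed
#' (enrichment) Fisher exact p-value by hypergeometric tail summation (no
#' mid-p), and the sensitivity-based enrichment score from the same
#' counts. Associations with `p < p_max` and `enrichment >= enr_min` are
#' flagged as passing; all records are returned. A BH-adjusted column is
#' included for reference but does not gate the pass flag.
#'
#' @param x a [count_matrix()], [norm_matrix()] or matrix; expression is
#'   value > 0. Restrict the rows to the gene set of interest first.
#' @param labels per-cell type labels.
#' @param p_max Fisher p cutoff, strict (default 0.05).
#' @param enr_min enrichment cutoff, inclusive (default 1.5).
#' @return data.frame with gene, type, a, b, c, d, sensitivity,
#'   enrichment, p, fdr, pass.
#' @export
gene_celltype_association <- function(x, labels, p_max = 0.05,
                                      enr_min = 1.5) {
  mat <- if (inherits(x, "count_matrix")) x$counts
         else if (inherits(x, "norm_matrix")) x$mat else x
  labels <- as.character(labels)
  if (length(labels) != ncol(mat)) stop("labels must cover all cells")
  B <- mat > 0
  d <- ncol(mat)
  b_tot <- as.numeric(rowSums(B))
  types <- unique(labels)
  out <- do.call(rbind, lapply(types, function(tp) {
    in_t <- labels == tp
    c_n <- sum(in_t)
    a <- as.numeric(rowSums(B[, in_t, drop = FALSE]))
    rec <- enrichment_score(a, b_tot, c_n, d)
    # upper tail P(X >= a), X ~ Hypergeom(b expressing of d; draw c cells)
    p <- phyper(a - 1, b_tot, d - b_tot, c_n, lower.tail = FALSE)
    data.frame(gene = rownames(mat), type = tp, rec, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$fdr <- bh_fdr(out$p)
  out$pass <- !is.na(out$enrichment) & out$p < p_max &
    out$enrichment >= enr_min
  out
}

#' Two-tailed chi-square with Yates continuity correction
#'
#' Compares the frequency a1/n1 against a2/n2 by the 2x2 chi-square test
#' with Yates' correction, df = 1. Errors when any table margin is zero
#' (the test is undefined there).
#'
#' @param a1,n1 positives and total in group 1.
#' @param a2,n2 positives and total in group 2.
#' @return list with `chi2`, `df`, `p`.
#' @export
frequency_chisq <- function(a1, n1, a2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (a1 < 0 || a1 > n1 || a2 < 0 || a2 > n2) stop("need 0 <= a <= n")
  a <- a1; b <- n1 - a1; c <- a2; d <- n2 - a2
  N <- n1 + n2
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi-square undefined: zero table margin")
  num <- max(0, abs(a * d - b * c) - N / 2)
  chi2 <- N * num^2 / prod(margins)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Select candidate transcription factors for a cell type
#'
#' A TF is a candidate when it is differentially expressed in the type
#' (binomial FDR < `fdr_max`, effective size >= `es_min`, in-type
#' expression frequency >= `freq_in_min`, overall frequency <
#' `freq_all_max`, sensitivity >= `sens_min`) or is expressed in more than
#' `bulk_freq` of the type's cells.
#'
#' @param stats a [marker_stats()] table (one or more clusters).
#' @param tf_list identifiers of known transcription factors/cofactors.
#' @param fdr_max,es_min,freq_in_min,freq_all_max,sens_min,bulk_freq the
#'   clause thresholds (defaults 0.1, 2, 0.2, 0.4, 0.2, 0.6).
#' @return data.frame subset of `stats` rows for selected (TF, cluster)
#'   pairs, with a `via` column (`"de"`, `"bulk"` or `"both"`).
#' @export
select_candidate_tfs <- function(stats, tf_list, fdr_max = 0.1, es_min = 2,
                                 freq_in_min = 0.2, freq_all_max = 0.4,
                                 sens_min = 0.2, bulk_freq = 0.6) {
  if (!length(tf_list)) stop("tf_list must be non-empty")
  tf <- stats[stats$gene %in% tf_list, , drop = FALSE]
  de <- tf$fdr < fdr_max & tf$effective_size >= es_min &
    tf$freq_in >= freq_in_min & tf$freq_all < freq_all_max &
    tf$sensitivity >= sens_min
  bulk <- tf$freq_in > bulk_freq
  sel <- tf[de | bulk, , drop = FALSE]
  sel$via <- ifelse(de[de | bulk] & bulk[de | bulk], "both",
                    ifelse(de[de | bulk], "de", "bulk"))
  rownames(sel) <- NULL
  sel
}

#' Pseudo-bulk aggregation
#'
#' Sums raw counts gene-wise within each cell group, optionally scaling
#' each group to counts per million — the construction used to compare
#' single-cell data against bulk RNA-seq.
#'
#' @param x a [count_matrix()] or matrix.
#' @param grouping per-cell group labels covering all cells.
#' @param per_million scale each group's sums to counts per million
#'   (default FALSE).
#' @return genes x groups numeric matrix.
#' @export
pseudobulk <- function(x, grouping, per_million = FALSE) {
  mat <- if (inherits(x, "count_matrix")) x$counts else x
  grouping <- as.character(grouping)
  if (length(grouping) != ncol(mat)) stop("grouping must cover all cells")
  groups <- unique(grouping)
  out <- vapply(groups, function(g)
    as.numeric(rowSums(mat[, grouping == g, drop = FALSE])),
    numeric(nrow(mat)))
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(mat), groups)
  if (per_million) out <- sweep(out, 2, colSums(out) / 1e6, "/")
  out
}
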