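log_nm <- function(m, batch = NULL) {
  if (is.null(batch)) batch <- rep("b1", ncol(m))
  norm_matrix(log2(m + 1), batch = batch, stage = "log2")
}

# topology fingerprint invariant to leaf order
cophenetic_order <- function(dd) {
  cm <- as.matrix(cophenetic(dd$hclust))
  nm <- sort(rownames(cm))
  round(cm[nm, nm], 6)
}

test_that("variable-gene selection finds a planted high-dispersion gene", {
  set.seed(51)
  n_genes <- 2000; n_cells <- 150
  m <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              sprintf("c%03d", 1:n_cells)))
  # one gene with ~10x inflated variance at the same mean
  m[77, ] <- rpois(n_cells, 2) * sample(c(0, 4), n_cells, TRUE, c(0.75, 0.25))
  x <- log_nm(m)
  hvg <- select_hvg(x, z_cutoff = 3)
  expect_true("g0077" %in% hvg)
  # sorted by decreasing z
  st <- hvg_stats(x)
  z <- st$dispersion_z[match(hvg, st$gene)]
  expect_true(all(diff(z) <= 0))
  # +Inf cutoff: empty result, no error
  expect_length(select_hvg(x, z_cutoff = Inf), 0)
})

test_that("under an i.i.d. null the HVG rate tracks the z upper tail", {
  set.seed(52)
  m <- matrix(rpois(3000 * 120, 1.5), 3000, 120,
              dimnames = list(sprintf("g%04d", 1:3000), sprintf("c%03d", 1:120)))
  hvg <- select_hvg(log_nm(m), z_cutoff = 1.645)
  # within-bin z-scores are roughly standard, so the selection rate should
  # be in the vicinity of the normal upper tail (wide band: dispersion of
  # count data is right-skewed, not exactly normal)
  rate <- length(hvg) / 3000
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.15)
})

test_that("PCA matches an eigendecomposition oracle and detects rank", {
  set.seed(53)
  # data on an exact 2-D plane in 6-gene space
  scoresT <- matrix(rnorm(40 * 2), 40, 2)
  basis <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  m <- basis %*% t(scoresT) + 5
  dimnames(m) <- list(sprintf("g%d", 1:6), sprintf("c%02d", 1:40))
  x <- norm_matrix(m, batch = rep("b", 40), stage = "log2")
  pm <- pca_reduce(x, rownames(m), cap = 100)
  expect_lt(pm$sdev[3], 1e-10)
  # sum of component variances equals total variance of the z-scored matrix
  z <- t(scale(t(m)))
  expect_equal(sum(pm$sdev^2), sum(z^2) / (40 - 1), tolerance = 1e-8)
  # eigendecomposition oracle on the covariance of the z-scored data
  ev <- eigen(cov(t(z)), symmetric = TRUE)$values
  expect_equal(pm$sdev^2, ev[seq_along(pm$sdev)], tolerance = 1e-8)
  # permuting cells permutes scores but not sds
  perm <- sample(40)
  x2 <- norm_matrix(m[, perm], batch = rep("b", 40), stage = "log2")
  pm2 <- pca_reduce(x2, rownames(m), cap = 100)
  expect_equal(pm2$sdev, pm$sdev, tolerance = 1e-9)
  expect_equal(abs(pm2$scores[colnames(m), 1]), abs(pm$scores[colnames(m), 1]),
               tolerance = 1e-8)
  # constant genes are dropped with a warning
  m3 <- rbind(m, flat = rep(3, 40))
  x3 <- norm_matrix(m3, batch = rep("b", 40), stage = "log2")
  expect_warning(pca_reduce(x3, rownames(m3), cap = 100), "constant")
})

test_that("PC selection is a strict threshold with a 2-component floor", {
  pm <- structure(list(sdev = c(5, 3.1, 2.9, 1)), class = "pc_model")
  expect_equal(select_pcs(pm, 3), c(1, 2))
  expect_equal(select_pcs(pm, 2), c(1, 2, 3))
  expect_warning(sel <- select_pcs(pm, 10), "forcing")
  expect_equal(sel, c(1, 2))
  # monotonicity: lowering the threshold never drops a component
  expect_true(all(select_pcs(pm, 3) %in% select_pcs(pm, 2)))
})

test_that("batch correction removes a constant additive batch offset", {
  set.seed(54)
  n_genes <- 200; n <- 120
  base <- matrix(rnorm(n_genes * n, 5, 0.3), n_genes, n,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("c%03d", 1:n)))
  batch <- rep(c("b1", "b2"), each = n / 2)
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 2
  x <- norm_matrix(shifted, batch = batch, stage = "log2")
  corr <- combat_correct(x)
  gap <- rowMeans(corr$mat[, batch == "b2"]) - rowMeans(corr$mat[, batch == "b1"])
  # the 2.0 offset is removed down to shrunken estimation noise
  expect_lt(mean(abs(gap)), 0.05)
  expect_lt(max(abs(gap)), 0.1)
  # approximate idempotence: re-correction only moves means by the shrunk
  # estimation noise (empirical-Bayes shrinkage has no exact fixed point)
  corr2 <- combat_correct(corr)
  expect_lt(max(abs(rowMeans(corr2$mat) - rowMeans(corr$mat))), 1e-2)
  # contract errors
  expect_error(combat_correct(norm_matrix(base, batch = rep("b1", n),
                                          stage = "log2")), ">= 2 batches")
  expect_error(combat_correct(norm_matrix(base, batch = c("b2", rep("b1", n - 1)),
                                          stage = "log2")), ">= 2 cells")
})

test_that("zero-variance genes pass through batch correction unchanged", {
  set.seed(55)
  m <- matrix(rnorm(50 * 40, 3), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:40)))
  m[7, ] <- 1.5
  x <- norm_matrix(m, batch = rep(c("b1", "b2"), 20), stage = "log2")
  corr <- combat_correct(x)
  expect_equal(unname(corr$mat[7, ]), rep(1.5, 40))
})

test_that("Jaccard-Louvain separates two well-separated blobs without mixing", {
  set.seed(56)
  n <- 100
  scores <- rbind(matrix(rnorm(n * 2, 0, 1), n, 2),
                  matrix(rnorm(n * 2, 10, 1), n, 2))
  rownames(scores) <- sprintf("c%03d", 1:(2 * n))
  labels <- jaccard_louvain(scores, k = 10, seed = 1L)
  truth <- rep(1:2, each = n)
  # modularity optimization may refine a homogeneous blob into several
  # communities, but no community ever spans the two blobs: mapping each
  # cluster to its blob recovers the truth exactly
  purity <- tapply(truth, labels, function(v) max(table(v)) / length(v))
  expect_true(all(purity == 1))
  mapped <- tapply(truth, labels, function(v) v[1])[as.character(labels)]
  expect_equal(mclust::adjustedRandIndex(mapped, truth), 1.0)
  # labels ordered by decreasing cluster size
  expect_true(all(diff(as.integer(table(labels))) <= 0))
  # determinism under the same seed
  labels2 <- jaccard_louvain(scores, k = 10, seed = 1L)
  expect_identical(labels, labels2)
  # contract errors
  expect_error(jaccard_louvain(scores, k = 1), "k must be")
  expect_error(jaccard_louvain(scores[1:5, ], k = 10), "smaller")
})

test_that("t-SNE embedding is shaped, seeded, and isolated from clustering", {
  set.seed(57)
  scores <- matrix(rnorm(60 * 3), 60, 3,
                   dimnames = list(sprintf("c%02d", 1:60), NULL))
  emb <- tsne_embed(scores, seed = 2L)
  expect_equal(dim(emb), c(60, 2))
  expect_identical(emb, tsne_embed(scores, seed = 2L))
  # clustering output does not depend on whether an embedding was computed
  l1 <- jaccard_louvain(scores, k = 8, seed = 3L)
  invisible(tsne_embed(scores, seed = 4L))
  l2 <- jaccard_louvain(scores, k = 8, seed = 3L)
  expect_identical(l1, l2)
})

test_that("doublet clusters are flagged by dual-panel expression", {
  panels <- list(epi = c("e1", "e2"), endo = c("n1", "n2"))
  genes <- c("e1", "e2", "n1", "n2", "x")
  cells <- 60
  m <- matrix(0, 5, cells, dimnames = list(genes, sprintf("c%02d", 1:cells)))
  labels <- rep(c("pure", "dbl", "other"), each = 20)
  m[c("e1", "e2"), labels == "pure"] <- 1          # 100% of epi panel
  m["n1", labels == "pure"][1] <- 1                # 2.5% of endo panel
  m[c("e1", "e2"), labels == "dbl"][, 1:16] <- 1   # 80% of both panels
  m[c("n1", "n2"), labels == "dbl"][, 1:16] <- 1
  m["x", labels == "other"] <- 1
  flagged <- flag_doublet_clusters(count_matrix(m), labels, panels)
  expect_equal(flagged, "dbl")
})

test_that("cluster type assignment maximizes panel enrichment with tie handling", {
  panels <- list(epithelial = c("Epcam", "Cdh1"), endothelial = c("Pecam1"))
  genes <- c("Epcam", "Cdh1", "Pecam1", "f1")
  n <- 200
  m <- matrix(0, 4, n, dimnames = list(genes, sprintf("c%03d", 1:n)))
  labels <- rep(c("k1", "k2"), each = 100)
  set.seed(58)
  # k1: epithelial markers at 0.9 inside, 0.05 outside
  m["Epcam", ] <- rbinom(n, 1, ifelse(labels == "k1", 0.9, 0.05))
  m["Cdh1", ] <- rbinom(n, 1, ifelse(labels == "k1", 0.9, 0.05))
  m["Pecam1", ] <- rbinom(n, 1, ifelse(labels == "k2", 0.9, 0.05))
  res <- assign_cell_types(labels, count_matrix(m), panels)
  expect_equal(res$label[res$cluster == "k1"], "epithelial")
  expect_equal(res$label[res$cluster == "k2"], "endothelial")
  expect_true(all(res$margin > 0))
  # exact tie -> ambiguous
  m2 <- matrix(0, 2, 4, dimnames = list(c("a", "b"), sprintf("c%d", 1:4)))
  m2["a", 1:2] <- 1; m2["b", 1:2] <- 1
  res2 <- assign_cell_types(rep(c("k", "j"), each = 2), count_matrix(m2),
                            list(p1 = "a", p2 = "b"))
  expect_equal(res2$label[res2$cluster == "k"], "ambiguous")
  # a panel with no genes present errors
  expect_error(assign_cell_types(labels, count_matrix(m),
                                 list(a = "Epcam", ghost = "nope")),
               "ghost")
})

test_that("on simulated types the panel assignment is fully correct", {
  sim <- small_sim()
  truth_types <- sim$truth$cells$type
  res <- assign_cell_types(truth_types, sim$counts, sim$truth$marker_map)
  expect_equal(res$label, res$cluster)  # clusters named by their true type
})

test_that("type dendrogram merges near-duplicate profiles first", {
  set.seed(59)
  n_genes <- 150
  base1 <- rnorm(n_genes, 5); base2 <- rnorm(n_genes, 5)
  prof <- cbind(A = base1, B = base1 + rnorm(n_genes, 0, 0.05),
                C = base2, D = base2 + rnorm(n_genes, 0, 0.05))
  cells <- prof[, rep(1:4, each = 3)] + rnorm(n_genes * 12, 0, 0.01)
  colnames(cells) <- sprintf("c%02d", 1:12)
  rownames(cells) <- sprintf("g%03d", 1:n_genes)
  labels <- rep(c("A", "B", "C", "D"), each = 3)
  dd <- type_dendrogram(log_nm(cells), labels)
  merges <- dd$hclust$merge
  first_two <- list(sort(dd$hclust$labels[-merges[1, ]]),
                    sort(dd$hclust$labels[-merges[2, ]]))
  expect_setequal(lapply(first_two, paste, collapse = "+"),
                  c("A+B", "C+D"))
  # identical profiles merge at zero height
  cells2 <- cbind(cells, cells[, 1:3])
  colnames(cells2) <- sprintf("c%02d", 1:15)
  dd2 <- type_dendrogram(log_nm(cells2), c(labels, rep("A2", 3)))
  expect_lt(min(dd2$hclust$height), 1e-3)
  # permuting type order preserves topology
  perm <- c(10:12, 1:9)
  dd3 <- type_dendrogram(log_nm(cells[, perm]), labels[perm])
  expect_identical(cophenetic_order(dd3), cophenetic_order(dd))
  # newick serialization round-trips through ape
  nw <- dendrogram_newick(dd)
  tree <- ape::read.tree(text = nw)
  expect_setequal(tree$tip.label, c("A", "B", "C", "D"))
})

test_that("nested subtype structure is recovered by the iterative pass", {
  cfg <- sim_config(n_genes = 1500, n_types = 2, n_subtypes_per_type = 2,
                    cells_per_type_per_batch = 100, markers_per_type = 15,
                    submarkers_per_subtype = 10, n_control_genes = 100,
                    doublet_rate = 0, seed = 61L)
  sim <- simulate_counts(cfg)
  lg <- log_transform(library_normalize(sim$counts))
  truth <- sim$truth$cells
  sub <- iterate_subclusters(lg, truth$type, seed = 62L)
  expect_equal(sub$major_cluster, truth$type)
  for (tp in c("T1", "T2")) {
    i <- sub$major_cluster == tp
    # reconcile modularity-refined subclusters by submarker panels, as the
    # workflow does, then compare against the planted subtypes
    pp <- sim$truth$submarker_map[startsWith(names(sim$truth$submarker_map),
                                             paste0(tp, "."))]
    sa <- assign_cell_types(sub$subtype_cluster[i],
                            count_matrix(sim$counts$counts[, i],
                                         sim$counts$batch[i]), pp)
    lab <- setNames(sa$label, sa$cluster)[sub$subtype_cluster[i]]
    ari <- mclust::adjustedRandIndex(lab, truth$subtype[i])
    expect_gte(ari, 0.9)
  }
  # an undersized major type is skipped with a warning, keeping subtype NA
  labs <- truth$type
  labs[1:10] <- "tiny"
  expect_warning(sub2 <- iterate_subclusters(lg, labs, seed = 62L), "tiny")
  expect_true(all(is.na(sub2$subtype_cluster[labs == "tiny"])))
})
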