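#' Configuration for the synthetic Drop-seq generator
#'
#' Builds and validates the parameter set for [simulate_counts()]. Defaults
#' describe the package's reference fixture: three major cell types, each
#' split into two subtypes, profiled in two batches with a 1.5x capture
#' efficiency difference, eight-fold over-expressed marker genes, log-normal
#' library sizes around 2,000 transcripts, negative-binomial counts, a small
#' mitochondrial gene set carrying ~5% of each cell's transcripts, 200
#' negative-control genes with no type effect, and a 5% doublet rate
#' (the commonly cited Drop-seq doublet expectation at ~100 cells/ul
#' loading; detected doublet clusters in real data are a subset of this).
#'
#' @param n_genes total number of genes (mitochondrial genes included).
#' @param n_types number of major cell types.
#' @param n_subtypes_per_type subtypes nested within each major type
#'   (1 = no nested structure).
#' @param cells_per_type_per_batch matrix (type x batch) of cell counts; a
#'   scalar is recycled. Number of columns fixes the number of batches.
#' @param markers_per_type marker genes over-expressed in each major type.
#' @param marker_fold fold over baseline for major-type markers.
#' @param submarkers_per_subtype marker genes over-expressed in each subtype.
#' @param submarker_fold fold over baseline for subtype markers.
#' @param baseline_mean relative expression weight of marker and control
#'   genes outside their over-expressing type (the reference abundance the
#'   fold changes multiply).
#' @param gene_weight_log_sd log-normal sd of the per-gene abundance
#'   weights of unstructured (filler) genes, centred on `baseline_mean`.
#'   Skewed abundance reproduces the sparse detection regime of droplet
#'   data (most genes detected in a small fraction of cells).
#' @param dispersion negative-binomial size parameter (inverse
#'   overdispersion; larger = closer to Poisson).
#' @param libsize_log_mean,libsize_log_sd natural-log mean and sd of the
#'   log-normal per-cell library size.
#' @param batch_factor multiplicative capture-efficiency factor per batch
#'   (length = number of batches; first batch is the reference).
#' @param n_mito_genes number of mitochondrial genes (named `mt-*`).
#' @param mito_mean_fraction expected fraction of each cell's transcripts
#'   from mitochondrial genes.
#' @param n_control_genes negative-control genes: identical expected
#'   expression in every type (technical variation only).
#' @param doublet_rate fraction of cells replaced by two-cell droplets that
#'   mix the profiles of two distinct major types.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_types = 3,
                       n_subtypes_per_type = 2,
                       cells_per_type_per_batch = 200,
                       markers_per_type = 20,
                       marker_fold = 8,
                       submarkers_per_subtype = 10,
                       submarker_fold = 8,
                       baseline_mean = 0.8,
                       gene_weight_log_sd = 2.4,
                       dispersion = 5,
                       libsize_log_mean = log(5500),
                       libsize_log_sd = 0.3,
                       batch_factor = c(1, 1.5),
                       n_mito_genes = 13,
                       mito_mean_fraction = 0.05,
                       n_control_genes = 200,
                       doublet_rate = 0.075,
                       seed = 1L) {
  n_batches <- if (is.matrix(cells_per_type_per_batch))
    ncol(cells_per_type_per_batch) else length(batch_factor)
  if (!is.matrix(cells_per_type_per_batch))
    cells_per_type_per_batch <- matrix(cells_per_type_per_batch,
                                       n_types, n_batches)
  if (length(batch_factor) != ncol(cells_per_type_per_batch))
    stop("batch_factor must have one entry per batch")
  cfg <- list(n_genes = as.integer(n_genes), n_types = as.integer(n_types),
              n_subtypes_per_type = as.integer(n_subtypes_per_type),
              cells_per_type_per_batch = cells_per_type_per_batch,
              markers_per_type = as.integer(markers_per_type),
              marker_fold = marker_fold,
              submarkers_per_subtype = as.integer(submarkers_per_subtype),
              submarker_fold = submarker_fold,
              baseline_mean = baseline_mean,
              gene_weight_log_sd = gene_weight_log_sd,
              dispersion = dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              batch_factor = batch_factor,
              n_mito_genes = as.integer(n_mito_genes),
              mito_mean_fraction = mito_mean_fraction,
              n_control_genes = as.integer(n_control_genes),
              doublet_rate = doublet_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_types, cfg$n_subtypes_per_type,
              cfg$markers_per_type, cfg$submarkers_per_subtype,
              cfg$n_mito_genes, cfg$n_control_genes,
              cfg$cells_per_type_per_batch)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$n_types < 1 || cfg$n_subtypes_per_type < 1)
    stop("need at least one type and one subtype per type")
  fracs <- c(cfg$mito_mean_fraction, cfg$doublet_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  pos <- c(cfg$marker_fold, cfg$submarker_fold, cfg$baseline_mean,
           cfg$dispersion, cfg$batch_factor)
  if (cfg$gene_weight_log_sd < 0) stop("gene_weight_log_sd must be >= 0")
  if (any(pos <= 0)) stop("fold, mean, dispersion and batch factors must be > 0")
  reserved <- cfg$markers_per_type * cfg$n_types +
    cfg$submarkers_per_subtype * cfg$n_types * cfg$n_subtypes_per_type +
    cfg$n_mito_genes + cfg$n_control_genes
  if (reserved > cfg$n_genes)
    stop(sprintf(paste0("gene budget exceeded: %d marker + control + mito ",
                        "genes but only %d genes configured"),
                 reserved, cfg$n_genes))
  invisible(cfg)
}

# Deterministic layout of the gene catalogue: major-type markers first, then
# subtype markers, then control genes, then unstructured filler; the
# mitochondrial genes are appended last under the "mt-" prefix the QC stage
# keys on.
sim_gene_plan <- function(cfg) {
  n_plain <- cfg$n_genes - cfg$n_mito_genes
  ids <- sprintf("g%04d", seq_len(n_plain))
  mito <- sprintf("mt-g%02d", seq_len(cfg$n_mito_genes))
  at <- 0L
  take <- function(n) {
    out <- ids[at + seq_len(n)]
    at <<- at + n
    out
  }
  marker_map <- list()
  for (t in seq_len(cfg$n_types))
    marker_map[[sprintf("T%d", t)]] <- take(cfg$markers_per_type)
  submarker_map <- list()
  for (t in seq_len(cfg$n_types))
    for (s in seq_len(cfg$n_subtypes_per_type))
      submarker_map[[sprintf("T%d.%d", t, s)]] <-
        take(cfg$submarkers_per_subtype)
  control <- take(cfg$n_control_genes)
  list(gene_ids = c(ids, mito), mito_ids = mito, control_ids = control,
       marker_map = marker_map, submarker_map = submarker_map)
}

# Expected relative expression profile for one (type, subtype): raw weights
# (marker/control genes at baseline_mean, fold-multiplied in their own
# type; filler genes at the run's log-normal weights) renormalized so
# non-mito genes carry (1 - mito_mean_fraction) of a cell's expected
# transcripts and mito genes the rest, making the expected mitochondrial
# fraction mito_mean_fraction in every type.
sim_profile <- function(cfg, plan, base_weights, type, subtype) {
  w <- base_weights
  w[plan$marker_map[[sprintf("T%d", type)]]] <-
    cfg$baseline_mean * cfg$marker_fold
  w[plan$submarker_map[[sprintf("T%d.%d", type, subtype)]]] <-
    cfg$baseline_mean * cfg$submarker_fold
  m <- cfg$mito_mean_fraction
  prof <- c(w / sum(w) * (1 - m),
            rep(if (cfg$n_mito_genes > 0) m / cfg$n_mito_genes else m,
                cfg$n_mito_genes))
  names(prof) <- plan$gene_ids
  prof
}

# per-run abundance weights of the non-mito genes: structured genes
# (markers, submarkers, controls) at the fixed baseline weight, filler
# genes log-normal around it
sim_base_weights <- function(cfg, plan) {
  n_plain <- cfg$n_genes - cfg$n_mito_genes
  ids <- plan$gene_ids[seq_len(n_plain)]
  w <- setNames(rep(cfg$baseline_mean, n_plain), ids)
  structured <- c(unlist(plan$marker_map), unlist(plan$submarker_map),
                  plan$control_ids)
  filler <- setdiff(ids, structured)
  # filler abundance is log-normal; the total filler mass is pinned to its
  # expectation so the structured genes' share of the transcriptome is a
  # design quantity, not a heavy-tailed random draw
  raw <- exp(stats::rnorm(length(filler), 0, cfg$gene_weight_log_sd))
  w[filler] <- raw / sum(raw) *
    (length(filler) * exp(cfg$gene_weight_log_sd^2 / 2))
  w
}

#' Simulate a Drop-seq-like count matrix with known ground truth
#'
#' Draws genes x cells UMI counts from a gamma-Poisson (negative-binomial)
#' model: the expected count of gene g in cell c is
#' `library_size(c) * batch_factor(b) * profile(g, type(c))`, where the type
#' profile over-expresses that type's (and subtype's) marker genes, holds
#' negative-control genes at a common baseline in every type, and reserves a
#' fixed expected fraction of transcripts for mitochondrial genes. A
#' configurable fraction of cells are doublets whose profile is the mean of
#' two distinct major-type profiles with a 1.5x library size.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `counts` (a [count_matrix()]) and `truth`
#'   (class `sim_truth`): per-cell `cells` data.frame (barcode, batch, type,
#'   subtype, doublet flag, mixed types), `marker_map`, `submarker_map`,
#'   `control_gene_ids`, `mito_gene_ids`, and the generating `config`.
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  cfg <- config
  plan <- sim_gene_plan(cfg)
  n_batches <- ncol(cfg$cells_per_type_per_batch)
  with_seed(cfg$seed, {
    # cell roster: types within batches, fixed order
    type_i <- integer(0); batch_i <- integer(0); sub_i <- integer(0)
    for (b in seq_len(n_batches)) for (t in seq_len(cfg$n_types)) {
      n_tb <- cfg$cells_per_type_per_batch[t, b]
      if (n_tb == 0) next
      type_i <- c(type_i, rep(t, n_tb))
      batch_i <- c(batch_i, rep(b, n_tb))
      # subtypes balanced round-robin within each (type, batch) block
      sub_i <- c(sub_i,
                 rep_len(seq_len(cfg$n_subtypes_per_type), n_tb))
    }
    n_cells <- length(type_i)
    if (n_cells == 0) stop("configuration yields zero cells")
    barcodes <- sprintf("cell%05d", seq_len(n_cells))

    base_weights <- sim_base_weights(cfg, plan)
    libsize <- rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)

    doublet <- runif(n_cells) < cfg$doublet_rate
    partner_t <- rep(NA_integer_, n_cells)
    can_mix <- cfg$n_types >= 2
    for (i in which(doublet)) {
      if (!can_mix) { doublet[i] <- FALSE; next }
      partner_t[i] <- sample(setdiff(seq_len(cfg$n_types), type_i[i]), 1)
    }

    profiles <- list()
    prof_key <- function(t, s) sprintf("T%d.%d", t, s)
    for (t in seq_len(cfg$n_types)) for (s in seq_len(cfg$n_subtypes_per_type))
      profiles[[prof_key(t, s)]] <- sim_profile(cfg, plan, base_weights, t, s)
    # subtype-agnostic type profiles; doublets mix two of these
    type_profile <- lapply(seq_len(cfg$n_types), function(t)
      rowMeans(vapply(seq_len(cfg$n_subtypes_per_type),
                      function(s) profiles[[prof_key(t, s)]],
                      numeric(cfg$n_genes))))

    mu <- matrix(0, cfg$n_genes, n_cells,
                 dimnames = list(plan$gene_ids, barcodes))
    for (i in seq_len(n_cells)) {
      p <- profiles[[prof_key(type_i[i], sub_i[i])]]
      size_mult <- 1
      if (doublet[i]) {
        p <- (type_profile[[type_i[i]]] + type_profile[[partner_t[i]]]) / 2
        size_mult <- 1.5
      }
      mu[, i] <- libsize[i] * size_mult * cfg$batch_factor[batch_i[i]] * p
    }
    counts <- matrix(rnbinom(length(mu), size = cfg$dispersion, mu = mu),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    cm <- count_matrix(counts, batch = sprintf("batch%d", batch_i))
    cells <- data.frame(
      barcode = barcodes,
      batch = sprintf("batch%d", batch_i),
      libsize = libsize,
      type = sprintf("T%d", type_i),
      subtype = sprintf("T%d.%d", type_i, sub_i),
      doublet = doublet,
      doublet_types = ifelse(doublet,
                             paste(sprintf("T%d", type_i),
                                   sprintf("T%d", partner_t), sep = "+"),
                             NA_character_),
      stringsAsFactors = FALSE)
    truth <- structure(list(cells = cells,
                            marker_map = plan$marker_map,
                            submarker_map = plan$submarker_map,
                            control_gene_ids = plan$control_ids,
                            mito_gene_ids = plan$mito_ids,
                            config = cfg),
                       class = "sim_truth")
    list(counts = cm, truth = truth)
  })
}

#' Simulate a structureless (null) count matrix
#'
#' As [simulate_counts()] but with a single cell type and no marker genes:
#' every gene's expected expression is identical across cells up to library
#' size and batch factor. Used to calibrate the type-I error of the binomial
#' and Fisher tests.
#'
#' @inheritParams simulate_counts
#' @return same structure as [simulate_counts()].
#' @export
simulate_null <- function(config) {
  cfg <- config
  cells <- cfg$cells_per_type_per_batch
  cfg$cells_per_type_per_batch <- matrix(colSums(cells), 1, ncol(cells))
  cfg$n_types <- 1L
  cfg$n_subtypes_per_type <- 1L
  cfg$markers_per_type <- 0L
  cfg$submarkers_per_subtype <- 0L
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  simulate_counts(cfg)
}
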