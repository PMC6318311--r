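pipeline_defaults <- function() {
  list(
    input_dir = NULL,            # read a fixture instead of simulating
    simulate = TRUE,             # simulate with sim_config() defaults
    sim = list(),                # overrides for sim_config()
    seed = 1L,                   # master seed; stages use fixed offsets
    min_genes = 500, max_mito = 0.10, min_cells_per_gene = 2,
    hvg = list(n_bins = 20, mean_range = c(0.0125, 8), z_cutoff = 1),
    pc_sd_major = 3, pc_sd_subtype = 2,
    knn_k = NULL,                # NULL = max(10, round(0.5 * sqrt(n)))
    doublet_expr_threshold = 0.5,
    subtype_min_cells = 40,
    signature = list(fdr_max = 0.05, es_min = 2, freq_in_min = 0.2,
                     freq_all_max = 0.4, max_genes = 100),
    panels = NULL,               # path to a JSON marker-panel file
    embed = FALSE,               # t-SNE is visualization-only; off by default
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for absent keys,
#' and rejects unknown keys and out-of-range values. The returned effective
#' configuration fully determines a pipeline run.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (nested in c("hvg", "signature")) {
    bad <- setdiff(names(cfg[[nested]]), names(defaults[[nested]]))
    if (length(bad))
      stop("unknown ", nested, " key(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(cfg$sim), names(formals(sim_config)))
  if (length(bad))
    stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$knn_k) && cfg$knn_k <= 1) stop("knn_k must be > 1")
  if (cfg$min_genes < 0 || cfg$min_cells_per_gene < 0)
    stop("filter thresholds must be non-negative")
  if (cfg$max_mito < 0 || cfg$max_mito > 1)
    stop("max_mito must lie in [0, 1]")
  if (cfg$pc_sd_major < 0 || cfg$pc_sd_subtype < 0)
    stop("PC sd thresholds must be non-negative")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

# load marker panels from a JSON file: {"panel name": ["gene", ...], ...}
read_panels <- function(path) {
  panels <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(panels) || is.null(names(panels)))
    stop("panel file must map panel names to gene lists: ", path)
  lapply(panels, as.character)
}

# atomic write helpers: write to a temp name in the same directory, then
# rename, so partial output never masquerades as complete
atomic_write_table <- function(d, path) {
  tmp <- paste0(path, ".tmp")
  write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
}
atomic_write_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
}

#' Run the full atlas workflow
#'
#' Orchestrates simulate/read -> cell and gene QC -> library-size
#' normalization -> negative-control batch scaling -> log transform ->
#' major-type Jaccard-Louvain clustering -> doublet-cluster flagging ->
#' marker-panel type assignment -> batch-corrected subtype clustering ->
#' marker statistics and signature selection, under a single master seed.
#' When `out_dir` is set, writes `clusters.tsv`, `markers.tsv`,
#' `signatures.json`, `qc_report.json`, `scaling.json` and
#' `run_report.json` (all atomically).
#'
#' @param config a [validate_config()] result, a list of overrides, or a
#'   YAML path.
#' @return list of class `pipeline_result`: `clusters` (per-cell table),
#'   `signatures`, `marker_stats`, `qc`, `scaling`, `type_assignment`,
#'   `doublet_clusters`, `truth` (when simulated), and `report`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  report <- list(parameters = unclass(cfg), stages = list(),
                 seed = cfg$seed)

  # --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input_dir)) {
    fx <- read_fixture(cfg$input_dir)
    raw <- fx$counts; truth <- fx$truth
    report$stages$input <- list(source = cfg$input_dir,
                                n_genes = nrow(raw), n_cells = ncol(raw))
  } else if (isTRUE(cfg$simulate)) {
    sim_args <- cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_counts(do.call(sim_config, sim_args))
    raw <- sim$counts; truth <- sim$truth
    report$stages$input <- list(source = "simulation",
                                sim_seed = sim_args$seed,
                                n_genes = nrow(raw), n_cells = ncol(raw))
  } else stop("config must set input_dir or simulate = TRUE")

  # --- qc ------------------------------------------------------------------
  cellf <- filter_cells(raw, min_genes = cfg$min_genes,
                        max_mito = cfg$max_mito)
  filtered <- filter_genes(cellf$matrix, min_cells = cfg$min_cells_per_gene)
  qc <- qc_metrics(filtered, stage = "filtered")
  report$stages$qc <- list(cells_in = ncol(raw), cells_kept = ncol(filtered),
                           genes_in = nrow(raw), genes_kept = nrow(filtered),
                           summary = unclass(qc))

  # --- normalize -----------------------------------------------------------
  libnorm <- library_normalize(filtered)
  controls <- if (!is.null(truth)) intersect(truth$control_gene_ids,
                                             rownames(libnorm$mat))
              else character(0)
  if (length(controls) && nlevels(libnorm$batch) > 1) {
    sc <- control_gene_scaling(libnorm, controls)
    scaled <- sc$matrix; scaling <- sc$factors
  } else {
    scaled <- libnorm; scaling <- NULL
  }
  logmat <- log_transform(scaled)
  report$stages$normalize <- list(
    median_total = libnorm$provenance$median_total,
    scaling = if (!is.null(scaling))
      list(factors = as.list(scaling$factors),
           reference = scaling$reference,
           n_control_genes = length(scaling$control_gene_ids)) else NULL)

  # --- major clustering ----------------------------------------------------
  hvg <- do.call(select_hvg, c(list(logmat), cfg$hvg))
  if (length(hvg) < 2) stop("fewer than 2 highly variable genes at the major pass")
  pm <- pca_reduce(logmat, hvg)
  sel <- select_pcs(pm, cfg$pc_sd_major)
  major <- jaccard_louvain(pm$scores[, sel, drop = FALSE], k = cfg$knn_k,
                           seed = cfg$seed + 101L)
  report$stages$major_clustering <- list(n_hvg = length(hvg),
                                         n_pcs = length(sel),
                                         n_clusters = length(unique(major)))

  # --- panels, doublets, type assignment -----------------------------------
  panels <- if (!is.null(cfg$panels)) read_panels(cfg$panels)
            else if (!is.null(truth) &&
                     length(truth$marker_map) >= 2) truth$marker_map
            else NULL
  doublet_cl <- character(0)
  assignment <- NULL
  major_type <- setNames(as.character(major), names(major))
  if (!is.null(panels)) {
    doublet_cl <- flag_doublet_clusters(filtered, major, panels,
                                        cfg$doublet_expr_threshold)
    assignment <- assign_cell_types(major, filtered, panels)
    lab <- setNames(assignment$label, assignment$cluster)
    major_type <- unname(lab[as.character(major)])
    major_type[as.character(major) %in% doublet_cl] <- "doublet"
  }
  report$stages$doublets <- list(flagged_clusters = as.list(doublet_cl))

  # --- subtype clustering (within each assigned major type) ----------------
  # recursion is per major TYPE: all clusters assigned the same type are
  # pooled before the subtype pass, as in the iterative workflow
  recursion_labels <- if (!is.null(assignment)) major_type
                      else as.character(major)
  skip_labels <- intersect(c("doublet", "ambiguous"),
                           unique(recursion_labels))
  subtypes <- iterate_subclusters(
    logmat, recursion_labels, doublet_clusters = skip_labels,
    min_cells = cfg$subtype_min_cells, sd_threshold = cfg$pc_sd_subtype,
    hvg_args = cfg$hvg, k = cfg$knn_k, seed = cfg$seed)
  subtype_label <- rep(NA_character_, ncol(logmat$mat))
  sub_panels <- NULL
  if (!is.null(truth)) {
    sp <- truth$submarker_map[lengths(truth$submarker_map) > 0]
    if (length(sp) >= 2) sub_panels <- sp
  }
  if (!is.null(sub_panels)) {
    for (tp in setdiff(unique(recursion_labels), skip_labels)) {
      in_tp <- recursion_labels == tp & !is.na(subtypes$subtype_cluster)
      if (!any(in_tp)) next
      # offer this major type's own subtype panels where identifiable
      pp <- sub_panels[startsWith(names(sub_panels), paste0(tp, "."))]
      if (length(pp) < 2) pp <- sub_panels
      sa <- assign_cell_types(subtypes$subtype_cluster[in_tp],
                              count_matrix(filtered$counts[, in_tp, drop = FALSE],
                                           filtered$batch[in_tp]), pp)
      sl <- setNames(sa$label, sa$cluster)
      subtype_label[in_tp] <- unname(sl[subtypes$subtype_cluster[in_tp]])
    }
  }

  clusters <- data.frame(
    barcode = colnames(logmat$mat),
    batch = as.character(logmat$batch),
    major_cluster = as.integer(major),
    major_type = major_type,
    subtype_cluster = subtypes$subtype_cluster,
    subtype = subtype_label,
    doublet_flag = as.character(major) %in% doublet_cl,
    stringsAsFactors = FALSE)

  # --- markers & signatures (per assigned cell type; cells of
  # doublet-flagged clusters are not included) ------------------------------
  sig_cells <- !(as.character(major) %in% doublet_cl)
  stats <- marker_stats(count_matrix(filtered$counts[, sig_cells, drop = FALSE],
                                     filtered$batch[sig_cells]),
                        major_type[sig_cells])
  sigs <- do.call(select_signatures, c(list(stats), cfg$signature))
  report$stages$signatures <- list(
    sizes = lapply(sigs, length))
  report$stages$subtypes <- list(
    n_subtype_clusters = length(unique(stats::na.omit(subtypes$subtype_cluster))))

  result <- structure(list(clusters = clusters, signatures = sigs,
                           marker_stats = stats, qc = qc,
                           qc_records = cellf$records, scaling = scaling,
                           type_assignment = assignment,
                           doublet_clusters = doublet_cl,
                           pc_model = pm, selected_pcs = sel,
                           logmat = logmat, filtered = filtered,
                           truth = truth, report = report),
                      class = "pipeline_result")

  # --- outputs -------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    atomic_write_table(clusters, file.path(cfg$out_dir, "clusters.tsv"))
    atomic_write_table(stats, file.path(cfg$out_dir, "markers.tsv"))
    atomic_write_json(lapply(sigs, as.list),
                      file.path(cfg$out_dir, "signatures.json"))
    atomic_write_json(unclass(qc), file.path(cfg$out_dir, "qc_report.json"))
    if (!is.null(scaling))
      atomic_write_json(list(factors = as.list(scaling$factors),
                             reference = scaling$reference,
                             control_genes = scaling$control_gene_ids),
                        file.path(cfg$out_dir, "scaling.json"))
    atomic_write_json(report, file.path(cfg$out_dir, "run_report.json"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d cells, %d genes | %d major ",
                     "clusters (%d doublet-flagged) | %d subtype clusters\n"),
              nrow(x$clusters), nrow(x$filtered$counts),
              length(unique(x$clusters$major_cluster)),
              length(x$doublet_clusters),
              length(unique(stats::na.omit(x$clusters$subtype_cluster)))))
  invisible(x)
}
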