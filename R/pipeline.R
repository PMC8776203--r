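#' Default pipeline configuration
#'
#' Thresholds reproduce the motivating study's settings: fold-change
#' thresholds 1.5 at 4/8 h and 2 at 24/48 h, FDR 0.05, summed mean-CPM
#' floor 25, direction/profile fold-change threshold 1.5, k = 4 clusters
#' with 25 restarts, minimum 5 significant genes per enriched term, 1 Mb
#' colocalization window.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(counts = NULL, design = NULL, gmt = NULL,
       genes_bed = NULL, peaks_bed = NULL,
       simulate = TRUE, n_genes = 12000,
       min_cpm = 1, tau4 = 1.5, tau8 = 1.5, tau24 = 2, tau48 = 2,
       alpha = 0.05, cpm_floor = 25, fc_threshold = 1.5,
       k = 4, restarts = 25, min_sig = 5, window_bp = 1e6,
       seed = 1L, out = NULL)
}

load_config <- function(config) {
  defaults <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> filter/normalize -> per-time-point TREAT tests ->
#' target calling -> timing/direction/profile classification -> trajectory
#' clustering with direct/indirect labels -> contingency analysis ->
#' optional gene-set enrichment -> optional peak colocalization ->
#' consolidated summary. All stage outputs are written as TSV under
#' `config$out` when set; the run is deterministic given the config seed.
#'
#' @param config Named list of options (see [default_config()]) or the path
#'   to a flat YAML file of the same keys; unknown keys are an error.
#' @return List of class `pipeline_result` with every stage's output and a
#'   `summary` produced by [summarize_targets()].
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$out
  logcon <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(out, "pipeline.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  pipeline_log(logcon, "pipeline start; seed=", cfg$seed,
               "; R ", getRversion())

  truth <- NULL
  if (!is.null(cfg$counts) && !is.null(cfg$design)) {
    experiment <- read_experiment(cfg$counts, cfg$design)
    pipeline_log(logcon, "read ", nrow(experiment$counts), " genes x ",
                 ncol(experiment$counts), " samples")
  } else if (isTRUE(cfg$simulate)) {
    sim <- generate_counts(sim_config(n_genes = cfg$n_genes,
                                      seed = cfg$seed))
    experiment <- sim$experiment
    truth <- sim$truth
    pipeline_log(logcon, "simulated ", cfg$n_genes, " genes")
    if (!is.null(out)) write_experiment(experiment, truth, out)
  } else stop("stage input: provide counts+design or set simulate: true")

  experiment <- filter_low_expression(experiment, min_cpm = cfg$min_cpm)
  pipeline_log(logcon, "filtering kept ", attr(experiment, "n_kept"),
               " genes, removed ", attr(experiment, "n_removed"))
  factors <- tmm_factors(experiment)
  write_tsv(factors, out, "normfactors.tsv")
  cpm <- cpm_matrix(experiment, factors)
  lcpm <- cpm_matrix(experiment, factors, log2 = TRUE)
  mds <- mds_distances(lcpm)
  if (!is.null(out))
    utils::write.table(mds, file.path(out, "mds.tsv"), sep = "\t",
                       quote = FALSE)

  pipeline_log(logcon, "estimating dispersions")
  disp <- estimate_dispersions(experiment, factors)
  pipeline_log(logcon, sprintf("common dispersion %.4f", disp$common))
  taus <- c("4" = cfg$tau4, "8" = cfg$tau8, "24" = cfg$tau24,
            "48" = cfg$tau48)
  de <- run_de(experiment, factors, disp, taus = taus)
  write_tsv(de, out, "de_results.tsv")
  targets <- call_targets(de, cpm, experiment$design, alpha = cfg$alpha,
                          cpm_floor = cfg$cpm_floor)
  pipeline_log(logcon, length(targets$union), " target genes (",
               paste(sprintf("%sh=%d", names(targets$per_time),
                             lengths(targets$per_time)), collapse = ", "), ")")

  classification <- classify_targets(de, targets,
                                     fc_threshold = cfg$fc_threshold)
  write_tsv(classification, out, "classification.tsv")
  venn <- venn_counts(targets$per_time)
  write_tsv(venn, out, "venn.tsv")

  clusters <- NULL; cluster_labels <- NULL; contingency <- NULL
  if (length(targets$union) >= cfg$k) {
    std <- standardize_trajectories(lcpm[targets$union, , drop = FALSE],
                                    experiment$design)
    clusters <- kmeans_trajectories(std, k = cfg$k,
                                    n_restarts = cfg$restarts,
                                    seed = cfg$seed)
    cluster_labels <- label_clusters(clusters)
    write_tsv(cluster_labels, out, "cluster_labels.tsv")
    mech <- cluster_labels$mechanism[clusters$assignments]
    names(mech) <- names(clusters$assignments)
    gene_tab <- data.frame(gene = names(clusters$assignments),
                           cluster = unname(clusters$assignments),
                           mechanism = unname(mech),
                           stringsAsFactors = FALSE)
    write_tsv(gene_tab, out, "clusters.tsv")
    if (!is.null(out))
      utils::write.table(clusters$centroids, file.path(out, "centroids.tsv"),
                         sep = "\t", quote = FALSE)
    dirv <- stats::setNames(classification$direction, classification$gene)
    timv <- stats::setNames(classification$timing, classification$gene)
    contingency <- axis_contingency(list(
      direction_vs_mechanism = list(a = dirv[names(mech)], b = mech),
      timing_vs_mechanism = list(a = timv[names(mech)], b = mech)))
    write_tsv(contingency, out, "contingency.tsv")
    pipeline_log(logcon, "clustered ", length(clusters$assignments),
                 " targets into ", cfg$k, " clusters")
  } else pipeline_log(logcon, "clustering skipped: fewer targets than k")

  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    collection <- read_gmt(cfg$gmt)
    dirv <- stats::setNames(classification$direction, classification$gene)
    enrichment <- overrepresentation(targets$union,
                                     rownames(experiment$counts),
                                     collection, min_sig = cfg$min_sig,
                                     directions = dirv)
    write_tsv(enrichment, out, "enrichment.tsv")
    pipeline_log(logcon, "enrichment: ", nrow(enrichment),
                 " terms retained")
  } else pipeline_log(logcon, "enrichment skipped: no GMT configured")

  coloc <- NULL
  if (!is.null(cfg$genes_bed) && !is.null(cfg$peaks_bed)) {
    gbed <- read_bed(cfg$genes_bed)
    pbed <- read_bed(cfg$peaks_bed)
    coloc <- colocalize(gbed, pbed, window_bp = cfg$window_bp)
    write_tsv(coloc, out, "colocalization.tsv")
    pipeline_log(logcon, "colocalization: ", sum(coloc$within_window),
                 "/", nrow(coloc), " genes within window")
  } else pipeline_log(logcon, "colocalization skipped: no BED inputs")

  summary <- summarize_targets(targets, classification, cluster_labels)
  write_tsv(summary$per_time, out, "summary_per_time.tsv")
  write_tsv(summary$overview, out, "summary_overview.tsv")
  pipeline_log(logcon, "pipeline done")

  structure(list(config = cfg, experiment = experiment, truth = truth,
                 factors = factors, cpm = cpm, log2cpm = lcpm, mds = mds,
                 dispersions = disp, de = de, targets = targets,
                 classification = classification, venn = venn,
                 clusters = clusters, cluster_labels = cluster_labels,
                 contingency = contingency, enrichment = enrichment,
                 colocalization = coloc, summary = summary),
            class = "pipeline_result")
}

#' Consolidated summary of the target catalogue
#'
#' Per-time-point significant counts with up/down percentages, plus an
#' overview of union size, timing, direction, profile and cluster mechanism
#' counts. Marginals are asserted to be consistent: timing, direction and
#' profile counts each sum to the union size, and cluster sizes sum to the
#' number of clustered genes.
#'
#' @param targets A `target_calls`.
#' @param classification Output of [classify_targets()].
#' @param cluster_labels Optional output of [label_clusters()].
#' @return List of class `target_summary`: `per_time`, `overview`.
#' @export
summarize_targets <- function(targets, classification,
                              cluster_labels = NULL) {
  stopifnot(inherits(targets, "target_calls"))
  n_union <- length(targets$union)
  tps <- names(targets$per_time)
  per_time <- do.call(rbind, lapply(tps, function(tp) {
    genes <- targets$per_time[[tp]]
    lfc <- classification[match(genes, classification$gene),
                          paste0("log2FC_", tp)]
    data.frame(time_h = as.numeric(tp), n_significant = length(genes),
               pct_up = if (length(genes)) 100 * mean(lfc > 0) else NA_real_,
               pct_down = if (length(genes)) 100 * mean(lfc < 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  count_of <- function(v, lv) sum(v == lv)
  overview <- data.frame(
    n_targets = n_union,
    n_primary = count_of(classification$timing, "primary"),
    n_secondary = count_of(classification$timing, "secondary"),
    n_up = count_of(classification$direction, "up"),
    n_down = count_of(classification$direction, "down"),
    n_mixed = count_of(classification$direction, "mixed"),
    n_persistent = count_of(classification$profile, "persistent"),
    n_transient = count_of(classification$profile, "transient"),
    n_discontinuous = count_of(classification$profile, "discontinuous"),
    n_direct = if (is.null(cluster_labels)) NA_integer_ else
      sum(cluster_labels$size[cluster_labels$mechanism == "direct"]),
    n_indirect = if (is.null(cluster_labels)) NA_integer_ else
      sum(cluster_labels$size[cluster_labels$mechanism == "indirect"]))
  stopifnot(overview$n_primary + overview$n_secondary == n_union,
            overview$n_up + overview$n_down + overview$n_mixed == n_union,
            overview$n_persistent + overview$n_transient +
              overview$n_discontinuous == n_union)
  if (!is.null(cluster_labels))
    stopifnot(sum(cluster_labels$size) ==
                overview$n_direct + overview$n_indirect)
  structure(list(per_time = per_time, overview = overview),
            class = "target_summary")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$targets$union), "targets from",
      nrow(x$experiment$counts), "genes\n")
  print(x$summary$overview, row.names = FALSE)
  invisible(x)
}
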