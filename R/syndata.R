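#' Trajectory archetypes available to the simulator
#'
#' The simulator plants one archetype per gene. Direct archetypes move the
#' treated arm while the control arm stays flat; indirect archetypes let the
#' control arm drift (an ex vivo culture response) while treatment stabilizes
#' the gene at baseline. `transient` carries a treated-arm effect at the early
#' time points only, `discontinuous` at 8 h and 48 h with none at 24 h, and
#' `mixed` flips the sign of the treated-arm effect between the early and the
#' late half of the time course.
#'
#' @export
ARCHETYPES <- c("null", "direct_up", "direct_down", "indirect_up",
                "indirect_down", "transient", "discontinuous", "mixed")

#' Simulation configuration for a planted two-arm time course
#'
#' Defaults emulate the geometry of the motivating PBMC study: ~12,000
#' expression-filtered genes measured in 24 libraries (4 time points x
#' 2 arms x 3 replicates) at bulk RNA-seq depth.
#'
#' @param n_genes Number of genes to simulate.
#' @param archetype_fractions Named numeric vector over [ARCHETYPES]
#'   summing to 1; the proportion of genes planted with each archetype.
#' @param baseline_log2cpm_range Interval from which per-gene baseline
#'   log2-CPM values are drawn (log-uniform on the CPM scale).
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2). `0` gives Poisson counts.
#' @param library_sizes 24 positive totals, one per sample; default a fixed
#'   22-28 million-read gradient.
#' @param n_replicates Replicates per (time point, arm) cell.
#' @param time_points_h Ordered time grid in hours.
#' @param effect_log2_range Interval from which planted |log2 fold changes|
#'   are drawn for non-null genes (uniform).
#' @param onset_choices Time points (hours) from which each non-null gene's
#'   onset is drawn uniformly; must be a subset of `time_points_h`.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000,
                       archetype_fractions = c(null = 0.90,
                                               direct_up = 0.02,
                                               direct_down = 0.02,
                                               indirect_up = 0.02,
                                               indirect_down = 0.02,
                                               transient = 0.008,
                                               discontinuous = 0.006,
                                               mixed = 0.006),
                       baseline_log2cpm_range = c(-1, 9),
                       dispersion = 0.1,
                       library_sizes = NULL,
                       n_replicates = 3,
                       time_points_h = c(4, 8, 24, 48),
                       effect_log2_range = c(0.8, 3),
                       onset_choices = c(4, 8, 24, 48),
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(names(archetype_fractions)) ||
      !all(names(archetype_fractions) %in% ARCHETYPES))
    stop("archetype_fractions must be named with known archetypes: ",
         paste(ARCHETYPES, collapse = ", "))
  if (abs(sum(archetype_fractions) - 1) > 1e-9)
    stop("archetype_fractions must sum to 1")
  if (any(archetype_fractions < 0)) stop("archetype_fractions must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  time_points_h <- sort(unique(time_points_h))
  if (!all(onset_choices %in% time_points_h))
    stop("onset_choices must lie on the time grid")
  n_samples <- 2L * n_replicates * length(time_points_h)
  if (is.null(library_sizes))
    library_sizes <- round(seq(2.2e7, 2.8e7, length.out = n_samples))
  if (length(library_sizes) != n_samples)
    stop("library_sizes must have one entry per sample (", n_samples, ")")
  if (any(library_sizes <= 0)) stop("library_sizes must be > 0")
  if (diff(range(baseline_log2cpm_range)) < 0 ||
      length(baseline_log2cpm_range) != 2)
    stop("baseline_log2cpm_range must be an interval")
  structure(list(n_genes = as.integer(n_genes),
                 archetype_fractions = archetype_fractions,
                 baseline_log2cpm_range = sort(baseline_log2cpm_range),
                 dispersion = dispersion,
                 library_sizes = library_sizes,
                 n_replicates = as.integer(n_replicates),
                 time_points_h = time_points_h,
                 effect_log2_range = sort(effect_log2_range),
                 onset_choices = onset_choices,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected mean of a gene under an archetype (linear scale)
#'
#' Effects are step functions: the affected arm jumps to its full
#' multiplicative effect at `onset_h` and stays there, except for the
#' `transient` (early time points only), `discontinuous` (8 h and 48 h only)
#' and `mixed` (sign flip between early and late half) archetypes.
#'
#' @param archetype One of [ARCHETYPES].
#' @param arm `"treated"` or `"control"`.
#' @param time_h Time point in hours, on the configured grid.
#' @param baseline_mu Baseline mean (> 0), linear scale.
#' @param effect_log2 Planted |log2 fold change| of the effect.
#' @param onset_h Hour at which the effect first reaches full size.
#' @param time_points_h The full time grid (used by the transient/mixed
#'   archetypes to split early from late).
#' @return Expected mean on the linear scale.
#' @export
archetype_mean <- function(archetype, arm, time_h, baseline_mu, effect_log2,
                           onset_h = min(time_points_h),
                           time_points_h = c(4, 8, 24, 48)) {
  if (!archetype %in% ARCHETYPES)
    stop("unknown archetype: ", archetype)
  if (!arm %in% c("treated", "control")) stop("arm must be treated/control")
  if (baseline_mu <= 0) stop("baseline_mu must be > 0")
  if (!time_h %in% time_points_h) stop("time_h not on the time grid")
  half <- stats::median(time_points_h)  # early half: strictly below median
  on <- time_h >= onset_h
  mult <- 1
  if (archetype == "direct_up" && arm == "treated" && on)
    mult <- 2^effect_log2
  if (archetype == "direct_down" && arm == "treated" && on)
    mult <- 2^-effect_log2
  if (archetype == "indirect_up" && arm == "control" && on)
    mult <- 2^effect_log2
  if (archetype == "indirect_down" && arm == "control" && on)
    mult <- 2^-effect_log2
  if (archetype == "transient" && arm == "treated" && time_h < half)
    mult <- 2^effect_log2
  if (archetype == "discontinuous" && arm == "treated" &&
      time_h %in% c(8, 48))
    mult <- 2^effect_log2
  if (archetype == "mixed" && arm == "treated")
    mult <- if (time_h < half) 2^effect_log2 else 2^-effect_log2
  baseline_mu * mult
}

# Expected labels are a pure function of (archetype, onset); the DE log2FC of
# an indirect gene has the opposite sign of its control-arm drift.
truth_labels <- function(archetype, onset_h) {
  timing <- ifelse(archetype == "null", NA_character_,
            ifelse(archetype %in% c("transient", "mixed"), "primary",
            ifelse(archetype == "discontinuous", "primary",
            ifelse(onset_h <= 8, "primary", "secondary"))))
  mechanism <- ifelse(archetype == "null", NA_character_,
               ifelse(archetype %in% c("indirect_up", "indirect_down"),
                      "indirect", "direct"))
  direction <- rep(NA_character_, length(archetype))
  direction[archetype %in% c("direct_up", "transient", "discontinuous",
                             "indirect_down")] <- "up"
  direction[archetype %in% c("direct_down", "indirect_up")] <- "down"
  direction[archetype == "mixed"] <- "mixed"
  list(timing = timing, mechanism = mechanism, direction = direction)
}

# Deterministic per-gene substream so that appending genes never perturbs
# the draws of earlier genes (Knuth multiplicative hash, kept below 2^31).
gene_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

sim_design <- function(config) {
  tp <- config$time_points_h
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      arm = c("treated", "control"),
                      time_h = tp, stringsAsFactors = FALSE)
  grid <- grid[order(grid$time_h, grid$arm, grid$replicate), , drop = FALSE]
  data.frame(sample = sprintf("t%02d_%s_r%d", grid$time_h,
                              ifelse(grid$arm == "treated", "vd", "ctl"),
                              grid$replicate),
             time_h = grid$time_h, arm = grid$arm,
             replicate = grid$replicate, stringsAsFactors = FALSE)
}

#' Generate a planted negative-binomial count experiment
#'
#' Counts are drawn NB(mean = archetype mean scaled to library size,
#' dispersion = `config$dispersion`); `dispersion = 0` degenerates to
#' Poisson. Each gene draws its archetype (with probabilities
#' `archetype_fractions`), baseline, effect size, onset and counts from its
#' own deterministically derived substream, so the same `(config, seed)` is
#' bit-reproducible and appending genes does not perturb earlier genes.
#' Planted baselines are nominal CPM against a 1e6-CPM transcriptome: with
#' the default 12,000-gene configuration the planted totals land near 1e6,
#' so realized CPM tracks the planted baseline closely; smaller simulations
#' realize proportionally higher CPM.
#'
#' @param config A [sim_config()].
#' @return List with `experiment` (a `count_experiment`: integer count matrix
#'   plus design), `truth` (one row per gene: archetype, effect, onset and
#'   the expected timing/mechanism/direction labels), and `mu` (the planted
#'   mean matrix, for calibration checks).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- sim_design(config)
  G <- config$n_genes
  n <- nrow(design)
  fr <- config$archetype_fractions[config$archetype_fractions > 0]
  archetype <- character(G)

  gene_id <- sprintf("gene%05d", seq_len(G))
  bl_range <- config$baseline_log2cpm_range
  ef_range <- config$effect_log2_range
  baseline_log2cpm <- numeric(G)
  effect_log2 <- numeric(G)
  onset_h <- numeric(G)
  counts <- matrix(0L, G, n, dimnames = list(gene_id, design$sample))

  # per-gene parameters, each from the gene's own substream
  for (i in seq_len(G)) {
    set.seed(gene_seed(config$seed, i))
    archetype[i] <- names(fr)[1 + findInterval(stats::runif(1),
                                               cumsum(fr) / sum(fr))]
    baseline_log2cpm[i] <- stats::runif(1, bl_range[1], bl_range[2])
    effect_log2[i] <- if (archetype[i] == "null") 0 else
      stats::runif(1, ef_range[1], ef_range[2])
    onset_h[i] <- if (archetype[i] %in% c("direct_up", "direct_down")) {
      sample(config$onset_choices, 1)
    } else if (archetype[i] %in% c("indirect_up", "indirect_down")) {
      # a drift completing before the first sampled time point would be
      # indistinguishable from an opposite-sign treatment effect, so
      # culture drift onsets start at the second time point
      ch <- setdiff(config$onset_choices, min(config$time_points_h))
      if (length(ch) == 0) ch <- config$onset_choices
      if (length(ch) == 1) ch else sample(ch, 1)
    } else switch(archetype[i], discontinuous = 8,
                  min(config$time_points_h))
  }
  base_cpm <- 2^baseline_log2cpm

  arch_u <- unique(archetype)
  mult <- matrix(1, G, n)
  for (a in arch_u) {
    idx <- which(archetype == a)
    if (a == "null") next
    for (j in seq_len(n)) {
      m <- vapply(idx, function(i)
        archetype_mean(a, design$arm[j], design$time_h[j], 1,
                       effect_log2[i], onset_h[i], config$time_points_h),
        numeric(1))
      mult[idx, j] <- m
    }
  }
  lib <- config$library_sizes
  mu <- base_cpm * mult * rep(lib / 1e6, each = G)
  dimnames(mu) <- dimnames(counts)

  phi <- config$dispersion
  for (i in seq_len(G)) {
    set.seed(gene_seed(config$seed, i) + 1L)
    counts[i, ] <- if (phi == 0) stats::rpois(n, mu[i, ]) else
      stats::rnbinom(n, mu = mu[i, ], size = 1 / phi)
  }

  lab <- truth_labels(archetype, onset_h)
  truth <- data.frame(gene = gene_id, archetype = archetype,
                      baseline_log2cpm = baseline_log2cpm,
                      effect_log2 = effect_log2, onset_h = onset_h,
                      expected_timing = lab$timing,
                      expected_mechanism = lab$mechanism,
                      expected_direction = lab$direction,
                      stringsAsFactors = FALSE)
  experiment <- count_experiment(counts, design)
  list(experiment = experiment, truth = truth, mu = mu)
}

#' Write a simulated experiment to disk
#'
#' Writes tab-delimited `counts.tsv` (first column `gene`, one column per
#' sample), `design.tsv` and `truth.tsv` under `dir`. Round-trips losslessly
#' through [read_experiment()].
#'
#' @param experiment A `count_experiment`.
#' @param truth Truth table from [generate_counts()] (or `NULL` to skip).
#' @param dir Existing output directory.
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, truth, dir) {
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  cf <- file.path(dir, "counts.tsv")
  df <- file.path(dir, "design.tsv")
  counts <- data.frame(gene = rownames(experiment$counts),
                       experiment$counts, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(counts, cf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(experiment$design, df, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(counts = cf, design = df)
  if (!is.null(truth)) {
    tf <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = tf)
  }
  invisible(paths)
}
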