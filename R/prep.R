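#' Construct a count experiment
#'
#' The raw input everything downstream consumes: an integer gene x sample
#' count matrix plus a sample design table (`sample`, `time_h`, `arm`,
#' `replicate`).
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns; column names must match `design$sample`.
#' @param design Data frame with columns `sample`, `time_h`, `arm`,
#'   `replicate`; one row per sample.
#' @return An object of class `count_experiment`.
#' @export
count_experiment <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene row names")
  req <- c("sample", "time_h", "arm", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("design lists a sample more than once")
  if (!identical(sort(colnames(counts)), sort(as.character(design$sample))))
    stop("count columns and design samples do not match")
  counts <- counts[, as.character(design$sample), drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!all(design$arm %in% c("treated", "control")))
    stop("arm must be 'treated' or 'control'")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, design = design),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d genes x %d samples (%d time points, %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$time_h)),
              paste(sort(unique(x$design$arm)), collapse = " vs ")))
  invisible(x)
}

#' Read a count experiment from counts.tsv/design.tsv
#'
#' Inverse of [write_experiment()]: tab-delimited counts with a leading
#' `gene` column and a design table.
#'
#' @param counts_file,design_file Paths to the tab-delimited files.
#' @return A `count_experiment`.
#' @export
read_experiment <- function(counts_file, design_file) {
  ct <- utils::read.table(counts_file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(ct)[1] != "gene") stop("counts file must start with a 'gene' column")
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct$gene
  design <- utils::read.table(design_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  count_experiment(m, design)
}

smallest_group_size <- function(design) {
  min(table(design$time_h, design$arm))
}

#' Filter genes with very low expression
#'
#' Keeps genes whose CPM (raw library sizes, no normalization factors, no
#' prior) reaches `min_cpm` in at least `min_samples` samples — a transparent
#' stand-in for `edgeR::filterByExpr` intent. Both boundaries are inclusive.
#'
#' @param experiment A `count_experiment`.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Number of samples required; default the smallest
#'   (time point, arm) group size.
#' @return The filtered `count_experiment`, with attributes `n_kept` and
#'   `n_removed`.
#' @export
filter_low_expression <- function(experiment, min_cpm = 1,
                                  min_samples = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  if (is.null(min_samples))
    min_samples <- smallest_group_size(experiment$design)
  if (min_samples > ncol(experiment$counts))
    stop("min_samples exceeds the number of samples")
  lib <- colSums(experiment$counts)
  cpm <- t(t(experiment$counts) / lib) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep))
    warning("filtering removed every gene")
  out <- count_experiment(experiment$counts[keep, , drop = FALSE],
                          experiment$design)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference is the sample whose 75th count
#' percentile is closest to the mean 75th percentile; per-gene log-ratios to
#' the reference are doubly trimmed (30% on M, 5% on A), precision-weighted,
#' and the resulting factors are rescaled to geometric mean 1. Computed by
#' `edgeR::calcNormFactors`.
#'
#' @param experiment A `count_experiment`.
#' @param trim_M,trim_A Trim fractions for the log-ratio and absolute-level
#'   dimensions.
#' @return Data frame of class `norm_factors`: `sample`, `lib_size`,
#'   `factor`, `effective_lib_size`.
#' @export
tmm_factors <- function(experiment, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(experiment, "count_experiment"))
  lib <- colSums(experiment$counts)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(names(lib)[lib == 0], collapse = ", "))
  f <- if (ncol(experiment$counts) == 1) 1 else
    edgeR::calcNormFactors(experiment$counts, method = "TMM",
                           logratioTrim = trim_M, sumTrim = trim_A)
  out <- data.frame(sample = colnames(experiment$counts),
                    lib_size = unname(lib), factor = unname(f),
                    effective_lib_size = unname(lib * f),
                    stringsAsFactors = FALSE)
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' (log2-)CPM expression matrix
#'
#' CPM uses effective library sizes (library size x TMM factor). The log2
#' transform adds a prior count (default 2, scaled by relative library size,
#' as in `edgeR::cpm`) so zero counts stay finite.
#'
#' @param experiment A `count_experiment`.
#' @param factors A `norm_factors` table, or `NULL` for unit factors.
#' @param log2 Return log2-CPM instead of CPM.
#' @param prior_count Prior count for the log transform.
#' @return Numeric genes x samples matrix.
#' @export
cpm_matrix <- function(experiment, factors = NULL, log2 = FALSE,
                       prior_count = 2) {
  stopifnot(inherits(experiment, "count_experiment"))
  lib <- if (is.null(factors)) colSums(experiment$counts) else {
    stopifnot(identical(factors$sample, colnames(experiment$counts)))
    factors$effective_lib_size
  }
  edgeR::cpm(experiment$counts, lib.size = lib, log = log2,
             prior.count = prior_count)
}

#' Pairwise sample distances from the largest log2 expression differences
#'
#' For each pair of samples the distance is the root mean square of the
#' `top_n` largest absolute per-gene log2-CPM differences — each pair selects
#' its own top genes, so the matrix is symmetric with a zero diagonal but
#' need not obey the triangle inequality.
#'
#' @param log2cpm Genes x samples log2-CPM matrix.
#' @param top_n Number of top genes per pair (default 500); all genes are
#'   used if fewer are available.
#' @return Symmetric samples x samples distance matrix.
#' @export
mds_distances <- function(log2cpm, top_n = 500) {
  if (top_n < 1) stop("top_n must be >= 1")
  n <- ncol(log2cpm)
  d <- matrix(0, n, n, dimnames = list(colnames(log2cpm), colnames(log2cpm)))
  k <- min(top_n, nrow(log2cpm))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    dif <- sort(abs(log2cpm[, a] - log2cpm[, b]), decreasing = TRUE)[seq_len(k)]
    d[a, b] <- d[b, a] <- sqrt(mean(dif^2))
  }
  d
}
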