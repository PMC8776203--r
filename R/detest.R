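# Negative-binomial machinery for the per-time-point fold-change-threshold
# test. The model is a one-way layout over the (time point, arm) cells with
# per-sample offsets given by effective library sizes:
#   y_gi ~ NB(mu_gi, phi_g),  mu_gi = lambda_{g,cell(i)} * N_i,
#   Var = mu + phi mu^2.

# Vectorized Newton solve of the per-cell log-rate MLE for all genes at once.
# Y: genes x samples (one cell), N: effective library sizes, phi: scalar.
# Returns list(beta = log rate, info = Fisher information of beta).
nb_cell_fit <- function(Y, N, phi, iter = 12) {
  beta <- log((rowSums(Y) + 0.5) / sum(N))
  for (it in seq_len(iter)) {
    mu <- exp(beta) %o% N
    w <- mu / (1 + phi * mu)
    score <- rowSums((Y - mu) / (1 + phi * mu))
    info <- rowSums(w)
    step <- score / pmax(info, 1e-8)
    beta <- pmin(pmax(beta + pmin(pmax(step, -5), 5), -50), 50)
  }
  mu <- exp(beta) %o% N
  list(beta = beta, info = rowSums(mu / (1 + phi * mu)), mu = mu)
}

# Cox-Reid adjusted NB profile log-likelihood per gene at a single phi.
nb_apl <- function(counts, offsets, cell, phi) {
  ll <- numeric(nrow(counts))
  cr <- numeric(nrow(counts))
  for (g in unique(cell)) {
    j <- which(cell == g)
    fit <- nb_cell_fit(counts[, j, drop = FALSE], offsets[j], phi)
    ll <- ll + rowSums(stats::dnbinom(counts[, j, drop = FALSE],
                                      size = 1 / max(phi, 1e-8),
                                      mu = pmax(fit$mu, 1e-10), log = TRUE))
    cr <- cr + 0.5 * log(pmax(fit$info, 1e-8))
  }
  ll - cr
}

# Quadratic interpolation of the maximizer on a log-spaced grid.
grid_peak <- function(logphi, y) {
  k <- which.max(y)
  if (k == 1 || k == length(y)) return(exp(logphi[k]))
  x <- logphi[(k - 1):(k + 1)]; v <- y[(k - 1):(k + 1)]
  den <- (v[1] - 2 * v[2] + v[3])
  if (!is.finite(den) || den >= 0) return(exp(logphi[k]))
  exp(x[2] - 0.5 * (x[3] - x[1]) / 2 * (v[3] - v[1]) / den)
}

#' Estimate common and tagwise negative-binomial dispersions
#'
#' The common dispersion maximizes the summed Cox-Reid adjusted profile
#' likelihood over a log-spaced grid (with quadratic interpolation at the
#' peak). Tagwise dispersions shrink each gene's adjusted likelihood toward
#' the common curve by weighted-likelihood empirical Bayes: gene g maximizes
#' `APL_g(phi) + prior_df * mean_APL(phi)`, so the shared likelihood curve
#' enters with the weight of `prior_df` average genes.
#'
#' @param experiment A `count_experiment` (>= 2 replicates per cell).
#' @param factors Optional `norm_factors`; unit factors if `NULL`.
#' @param prior_df Prior degrees of freedom for the shrinkage (default 10).
#' @param grid_length,grid_range Dispersion grid (log-spaced).
#' @return List of class `dispersion_estimate`: `common`, `tagwise`
#'   (named per gene), `prior_df`, `grid`, `apl` (genes x grid).
#' @export
estimate_dispersions <- function(experiment, factors = NULL, prior_df = 10,
                                 grid_length = 19,
                                 grid_range = c(5e-4, 5)) {
  stopifnot(inherits(experiment, "count_experiment"))
  design <- experiment$design
  cell <- interaction(design$time_h, design$arm, drop = TRUE)
  if (min(table(cell)) < 2)
    stop("dispersion estimation needs >= 2 replicates per (time, arm) cell")
  offsets <- if (is.null(factors)) colSums(experiment$counts) else
    factors$effective_lib_size
  counts <- experiment$counts
  phis <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length))
  apl <- vapply(phis, function(p) nb_apl(counts, offsets, cell, p),
                numeric(nrow(counts)))
  apl <- matrix(apl, nrow = nrow(counts),
                dimnames = list(rownames(counts), NULL))
  tot <- colSums(apl)
  common <- grid_peak(log(phis), tot)
  wl <- apl + prior_df * matrix(colMeans(apl), nrow(apl), ncol(apl),
                                byrow = TRUE)
  tag_idx <- max.col(wl, ties.method = "first")
  tagwise <- vapply(seq_len(nrow(wl)), function(g) {
    k <- tag_idx[g]
    if (k == 1 || k == length(phis)) return(phis[k])
    grid_peak(log(phis[(k - 1):(k + 1)]), wl[g, (k - 1):(k + 1)])
  }, numeric(1))
  names(tagwise) <- rownames(counts)
  structure(list(common = common, tagwise = tagwise, prior_df = prior_df,
                 grid = phis, apl = apl),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("dispersion_estimate: common phi = %.4f, tagwise range %.4f-%.4f\n",
              x$common, min(x$tagwise), max(x$tagwise)))
  invisible(x)
}

#' Fold-change-threshold (TREAT-style) Wald test at one time point
#'
#' Tests each gene for differential expression relative to a fold change
#' threshold `tau` between the treated and control arms at one time point.
#' Group rates are 0.5-prior-adjusted totals over effective library sizes;
#' the Wald p-value against the composite null |log2FC| <= log2(tau) is
#' `min(1, P(+boundary tail) + P(-boundary tail))`, which is exactly 1 at
#' log2FC = 0 and at least 0.5 anywhere inside the null region. Standard
#' errors use the tagwise NB dispersions. Setting `tau = 1` recovers the
#' ordinary two-sided Wald test.
#'
#' @param experiment A `count_experiment`.
#' @param factors Optional `norm_factors`.
#' @param dispersions A `dispersion_estimate`.
#' @param time_h Time point to test.
#' @param tau Fold-change threshold (> 1 for a TREAT test; >= 1 accepted).
#' @return Data frame: `gene`, `time_h`, `log2FC`, `se` (standard error of
#'   the log2FC), `log2CPM`, `p`, `tau`.
#' @export
treat_test <- function(experiment, factors = NULL, dispersions, time_h,
                       tau = 1.5) {
  stopifnot(inherits(experiment, "count_experiment"),
            inherits(dispersions, "dispersion_estimate"))
  if (tau < 1) stop("tau must be >= 1")
  design <- experiment$design
  sel <- design$time_h == time_h
  if (!any(sel)) stop("no samples at time ", time_h)
  arms <- design$arm[sel]
  if (!all(c("treated", "control") %in% arms))
    stop("time point ", time_h, " is missing an arm")
  offsets <- if (is.null(factors)) colSums(experiment$counts) else
    factors$effective_lib_size
  Y <- experiment$counts[, sel, drop = FALSE]
  N <- offsets[sel]
  phi <- dispersions$tagwise[rownames(Y)]

  rate <- function(arm) {
    j <- arms == arm
    lam <- (rowSums(Y[, j, drop = FALSE]) + 0.5) / sum(N[j])
    mu <- lam %o% N[j]
    list(lambda = lam, info = rowSums(mu / (1 + phi * mu)))
  }
  trt <- rate("treated"); ctl <- rate("control")
  b <- log2(trt$lambda / ctl$lambda)
  se <- sqrt(1 / trt$info + 1 / ctl$info) / log(2)
  taul <- log2(tau)
  p <- pmin(1, stats::pnorm((abs(b) - taul) / se, lower.tail = FALSE) +
               stats::pnorm((abs(b) + taul) / se, lower.tail = FALSE))
  lcpm <- log2((trt$lambda + ctl$lambda) / 2 * 1e6)
  data.frame(gene = rownames(Y), time_h = time_h, log2FC = unname(b),
             se = unname(se), log2CPM = unname(lcpm), p = unname(p),
             tau = tau, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control via `stats::p.adjust`; `NA`/`NaN`
#' p-values are propagated and excluded from the ranking.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return FDR values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the per-time-point TREAT tests with BH correction
#'
#' Applies [treat_test()] at every time point with its own threshold and
#' adjusts p-values within each time point separately.
#'
#' @param experiment A `count_experiment`.
#' @param factors Optional `norm_factors`.
#' @param dispersions A `dispersion_estimate`.
#' @param taus Named fold-change thresholds, names = time points in hours.
#'   Default the motivating study's settings: 1.5 at 4/8 h, 2 at 24/48 h.
#' @return Long data frame (gene x time point) with `FDR` added.
#' @export
run_de <- function(experiment, factors = NULL, dispersions,
                   taus = c("4" = 1.5, "8" = 1.5, "24" = 2, "48" = 2)) {
  tps <- sort(unique(experiment$design$time_h))
  if (!all(as.character(tps) %in% names(taus)))
    stop("taus must name every time point: ", paste(tps, collapse = ", "))
  res <- lapply(tps, function(tp) {
    r <- treat_test(experiment, factors, dispersions, tp,
                    taus[[as.character(tp)]])
    r$FDR <- bh_adjust(r$p)
    r
  })
  do.call(rbind, res)
}

#' Call target genes from DE results
#'
#' A gene is significant at a time point iff its FDR there is below `alpha`
#' AND it passes the expression floor: the sum over time points of its mean
#' CPM across all samples at that time point must exceed `cpm_floor`. The
#' union over time points is the target-gene catalogue.
#'
#' @param de Output of [run_de()].
#' @param cpm CPM matrix (linear scale) from [cpm_matrix()].
#' @param design The experiment design (for the time point of each sample).
#' @param alpha FDR cutoff (default 0.05).
#' @param cpm_floor Summed mean-CPM floor (default 25).
#' @return List of class `target_calls`: `per_time` (named list of gene
#'   sets), `union`, `table` (gene x time point logical), `floor_pass`.
#' @export
call_targets <- function(de, cpm, design, alpha = 0.05, cpm_floor = 25) {
  tps <- sort(unique(de$time_h))
  genes <- unique(de$gene)
  mean_cpm_t <- vapply(tps, function(tp)
    rowMeans(cpm[genes, design$time_h == tp, drop = FALSE]),
    numeric(length(genes)))
  mean_cpm_t <- matrix(mean_cpm_t, nrow = length(genes))
  floor_pass <- rowSums(mean_cpm_t) > cpm_floor
  names(floor_pass) <- genes
  sig <- matrix(FALSE, length(genes), length(tps),
                dimnames = list(genes, tps))
  for (tp in tps) {
    r <- de[de$time_h == tp, ]
    sig[r$gene, as.character(tp)] <- !is.na(r$FDR) & r$FDR < alpha &
      floor_pass[r$gene]
  }
  per_time <- lapply(as.character(tps), function(tp)
    rownames(sig)[sig[, tp]])
  names(per_time) <- as.character(tps)
  structure(list(per_time = per_time,
                 union = rownames(sig)[rowSums(sig) > 0],
                 table = sig, floor_pass = floor_pass,
                 alpha = alpha, cpm_floor = cpm_floor),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat("target_calls:", length(x$union), "target genes; per time point:",
      paste(sprintf("%sh=%d", names(x$per_time),
                    lengths(x$per_time)), collapse = ", "), "\n")
  invisible(x)
}
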