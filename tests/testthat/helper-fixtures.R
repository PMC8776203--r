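# Small in-code fixtures shared across test files.

# A toy two-arm experiment with hand-set counts (no randomness).
toy_experiment <- function(counts, time_h = NULL, arm = NULL) {
  n <- ncol(counts)
  if (is.null(time_h)) time_h <- rep(4, n)
  if (is.null(arm)) arm <- rep(c("treated", "control"), length.out = n)
  design <- data.frame(sample = colnames(counts), time_h = time_h,
                       arm = arm,
                       replicate = stats::ave(seq_len(n),
                                              interaction(time_h, arm),
                                              FUN = seq_along),
                       stringsAsFactors = FALSE)
  count_experiment(counts, design)
}

# Full 4-time-point x 2-arm x n_rep design matrix of constant counts.
flat_experiment <- function(n_genes = 10, value = 100, n_rep = 3) {
  design <- expand.grid(replicate = seq_len(n_rep),
                        arm = c("treated", "control"),
                        time_h = c(4, 8, 24, 48), stringsAsFactors = FALSE)
  design$sample <- sprintf("s%02d", seq_len(nrow(design)))
  counts <- matrix(value, n_genes, nrow(design),
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   design$sample))
  count_experiment(counts, design[, c("sample", "time_h", "arm", "replicate")])
}

small_sim <- function(n_genes = 400, seed = 42, phi = 0.1, effect = 2,
                      fractions = c(null = 0.6, direct_up = 0.1,
                                    direct_down = 0.1, indirect_up = 0.1,
                                    indirect_down = 0.1),
                      baseline = c(4, 9), ...) {
  generate_counts(sim_config(n_genes = n_genes, seed = seed,
                             dispersion = phi,
                             archetype_fractions = fractions,
                             effect_log2_range = c(effect, effect),
                             baseline_log2cpm_range = baseline, ...))
}

# --- independent oracles ------------------------------------------------

# Two-sided Fisher p by full enumeration of the 2x2 family at fixed margins.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  pobs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Hypergeometric upper tail by direct summation of binomial coefficients.
hyper_tail_oracle <- function(x, set_size, universe, n_sig) {
  ks <- x:min(set_size, n_sig)
  sum(vapply(ks, function(k)
    choose(set_size, k) * choose(universe - set_size, n_sig - k),
    numeric(1))) / choose(universe, n_sig)
}

# Hand step-up BH.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# Brute-force nearest-peak scan used as the oracle for colocalize().
coloc_oracle <- function(genes, peaks, window_bp) {
  anchor <- ifelse(!is.null(genes$strand) & genes$strand == "-",
                   genes$end - 1, genes$start)
  t(vapply(seq_len(nrow(genes)), function(i) {
    j <- which(peaks$chrom == genes$chrom[i])
    if (length(j) == 0) return(c(NA_real_, NA_real_))
    d <- ifelse(anchor[i] < peaks$start[j], peaks$start[j] - anchor[i],
                ifelse(anchor[i] > peaks$end[j] - 1,
                       peaks$end[j] - 1 - anchor[i], 0))
    k <- which.min(abs(d))
    c(d[k], as.numeric(abs(d[k]) <= window_bp))
  }, numeric(2)))
}

# Minimum WCSS over all bipartitions of the rows of x.
min_wcss_bipartition <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    w <- 0
    for (s in list(x[g, , drop = FALSE], x[!g, , drop = FALSE]))
      w <- w + sum(scale(s, scale = FALSE)^2)
    if (w < best) best <- w
  }
  best
}
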