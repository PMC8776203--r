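test_that("low-expression filtering keeps the right genes", {
  counts <- matrix(0L, 100, 4,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   paste0("s", 1:4)))
  counts[11:100, ] <- 1000L  # survivors
  ex <- toy_experiment(counts)
  filt <- suppressWarnings(filter_low_expression(ex, min_cpm = 1,
                                                 min_samples = 2))
  expect_equal(attr(filt, "n_kept"), 90)
  expect_equal(attr(filt, "n_removed"), 10)
  expect_false(any(rownames(filt$counts) %in% sprintf("g%03d", 1:10)))

  # boundary: CPM exactly min_cpm in exactly min_samples samples is kept
  counts2 <- matrix(1000L, 5, 4,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  counts2[1, ] <- c(1L, 1L, 0L, 0L)  # CPM in s1/s2 depends on lib size
  lib <- colSums(counts2)
  cpm1 <- counts2[1, 1] / lib[1] * 1e6
  filt2 <- filter_low_expression(toy_experiment(counts2),
                                 min_cpm = cpm1, min_samples = 2)
  expect_true("g1" %in% rownames(filt2$counts))

  # idempotence
  refilt <- filter_low_expression(filt, min_cpm = 1, min_samples = 2)
  expect_equal(attr(refilt, "n_removed"), 0)
  expect_error(filter_low_expression(ex, min_samples = 99), "exceeds")
})

test_that("TMM factors have geometric mean one and absorb proportional scaling", {
  set.seed(1)
  base <- matrix(rnbinom(200 * 4, mu = 200, size = 5), 200, 4,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  ex <- toy_experiment(base)
  f <- tmm_factors(ex)
  expect_equal(exp(mean(log(f$factor))), 1, tolerance = 1e-6)
  expect_true(all(f$factor > 0))

  # multiplying one sample's counts by a constant leaves factors unchanged
  # up to the precision weights (which see the changed library size)
  scaled <- base
  scaled[, 2] <- base[, 2] * 3L
  f2 <- tmm_factors(toy_experiment(scaled))
  expect_equal(f2$factor, f$factor, tolerance = 0.01)

  # gene-wise proportional samples: both factors 1
  prop <- cbind(s1 = base[, 1], s2 = base[, 1] * 3L)
  fp <- tmm_factors(toy_experiment(prop))
  expect_equal(fp$factor, c(1, 1), tolerance = 1e-10)

  expect_error(tmm_factors(toy_experiment(
    cbind(s1 = c(g1 = 0L, g2 = 0L), s2 = c(5L, 5L)))), "all-zero")
})

test_that("TMM matches a hand trim-and-average oracle on a planted toy", {
  # 18 genes share one proportion ratio; 2 outliers must be trimmed away
  counts <- cbind(s1 = rep(100L, 20), s2 = c(rep(100L, 18), 2000L, 2000L))
  rownames(counts) <- paste0("g", 1:20)
  f <- tmm_factors(toy_experiment(counts))
  # all surviving M values equal log2((100/5800)/(100/2000)); after
  # geometric-mean normalization each factor is the square root of the ratio
  ratio <- (100 / 5800) / (100 / 2000)
  expect_equal(f$factor, c(1 / sqrt(ratio), sqrt(ratio)), tolerance = 1e-6)
})

test_that("CPM columns are calibrated and scale-invariant", {
  counts <- cbind(s1 = c(g1 = 10L, g2 = 90L), s2 = c(50L, 50L))
  ex <- toy_experiment(counts)
  cpm <- cpm_matrix(ex)
  expect_equal(unname(cpm[, 1]), c(1e5, 9e5))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  # zero counts stay finite in log space
  counts0 <- cbind(s1 = c(g1 = 0L, g2 = 100L), s2 = c(100L, 100L))
  lcpm <- cpm_matrix(toy_experiment(counts0), log2 = TRUE)
  expect_true(all(is.finite(lcpm)))
  # doubling a sample's counts leaves its CPM unchanged
  doubled <- counts
  doubled[, 1] <- counts[, 1] * 2L
  expect_equal(cpm_matrix(toy_experiment(doubled))[, 1], cpm[, 1])
})

test_that("pairwise top-n distances match a brute-force oracle", {
  m <- matrix(0, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  m[, 2] <- 1  # all |differences| are 1
  expect_equal(mds_distances(m, top_n = 500)["a", "b"], 1)
  expect_equal(mds_distances(m, top_n = 500)["a", "a"], 0)

  set.seed(7)
  x <- matrix(rnorm(600 * 3), 600, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  d <- mds_distances(x, top_n = 500)
  oracle <- function(u, v) {
    dif <- sort(abs(u - v), decreasing = TRUE)[1:500]
    sqrt(mean(dif^2))
  }
  expect_equal(d["a", "b"], oracle(x[, 1], x[, 2]))
  expect_equal(d["b", "c"], oracle(x[, 2], x[, 3]))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # fewer genes than top_n: all genes used
  expect_equal(mds_distances(x[1:10, ], top_n = 500)["a", "b"],
               sqrt(mean((x[1:10, 1] - x[1:10, 2])^2)))
})
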