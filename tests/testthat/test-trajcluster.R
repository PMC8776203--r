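make_design <- function() {
  d <- expand.grid(replicate = 1:3, arm = c("treated", "control"),
                   time_h = c(4, 8, 24, 48), stringsAsFactors = FALSE)
  d$sample <- sprintf("s%02d", seq_len(nrow(d)))
  d[, c("sample", "time_h", "arm", "replicate")]
}

test_that("standardization yields zero-mean unit-sd trajectories", {
  design <- make_design()
  m <- matrix(rnorm(5 * 24, mean = 8), 5, 24,
              dimnames = list(paste0("g", 1:5), design$sample))
  std <- standardize_trajectories(m, design)
  expect_equal(ncol(std$z), 8)
  expect_equal(unname(rowMeans(std$z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(std$z, 1, sd)), rep(1, 5), tolerance = 1e-6)
  # location and scale invariance
  std2 <- standardize_trajectories(m + 3, design)
  expect_equal(std2$z, std$z)
  std3 <- standardize_trajectories(m * 5, design)
  expect_equal(std3$z, std$z, tolerance = 1e-9)
  # constant rows are excluded with a warning
  m2 <- rbind(m, flat = rep(1, 24))
  expect_warning(std4 <- standardize_trajectories(m2, design), "constant")
  expect_equal(std4$excluded, "flat")
})

test_that("k-means finds exact optima on small instances", {
  set.seed(1)
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("p", 1:8), NULL))
  res <- kmeans_trajectories(x, k = 2, n_restarts = 25, seed = 7)
  expect_equal(res$wcss, min_wcss_bipartition(x), tolerance = 1e-9)

  res1 <- kmeans_trajectories(x, k = 1, n_restarts = 5, seed = 7)
  expect_equal(unname(res1$centroids[1, ]), unname(colMeans(x)))
  expect_error(kmeans_trajectories(x, k = 50), "exceeds")

  # well-separated planted blobs are recovered exactly
  blob <- rbind(matrix(rnorm(40 * 4), 40, 4),
                matrix(rnorm(40 * 4, mean = 20), 40, 4))
  rownames(blob) <- paste0("g", 1:80)
  resb <- kmeans_trajectories(blob, k = 2, seed = 3)
  lab <- resb$assignments
  expect_true(length(unique(lab[1:40])) == 1 &&
                length(unique(lab[41:80])) == 1 &&
                lab[1] != lab[80])
})

test_that("best-of-restarts WCSS is monotone in the number of restarts", {
  set.seed(10)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(paste0("g", 1:60), NULL))
  w <- vapply(c(1, 5, 25), function(r)
    kmeans_trajectories(x, k = 4, n_restarts = r, seed = 11)$wcss,
    numeric(1))
  expect_true(all(diff(w) <= 1e-9))
  # deterministic given the seed
  expect_identical(kmeans_trajectories(x, k = 4, seed = 11)$assignments,
                   kmeans_trajectories(x, k = 4, seed = 11)$assignments)
})

test_that("cluster labelling separates treatment-driven from culture-driven", {
  cents <- rbind(c(0, 1, 2, 2, 0, 0, 0, 0),    # treated rises -> direct up
                 c(0, -1, -2, -2, 0, 0, 0, 0), # treated falls -> direct down
                 c(0, 0, 0, 0, 0, 1, 2, 2),    # control rises -> indirect up
                 c(0, 0, 0, 0, 0, -1, -2, -2)) # control falls -> indirect down
  colnames(cents) <- c(paste0("treated_", c(4, 8, 24, 48), "h"),
                       paste0("control_", c(4, 8, 24, 48), "h"))
  fake <- structure(list(assignments = setNames(rep(1:4, 2), paste0("g", 1:8)),
                         centroids = cents, wcss = 0, k = 4,
                         n_restarts = 1, seed = 1),
                    class = "cluster_result")
  lab <- label_clusters(fake)
  expect_equal(lab$mechanism, c("direct", "direct", "indirect", "indirect"))
  expect_equal(lab$direction, c("up", "down", "up", "down"))
  # label rule is invariant to permuting cluster indices
  perm <- c(3, 1, 4, 2)
  fake2 <- fake
  fake2$centroids <- cents[perm, ]
  fake2$assignments <- setNames(match(fake$assignments, perm),
                                names(fake$assignments))
  lab2 <- label_clusters(fake2)
  expect_equal(lab2$mechanism, lab$mechanism[perm])
  expect_equal(lab2$direction, lab$direction[perm])
  # tie in ranges goes to indirect with a warning
  fake3 <- fake
  fake3$centroids[1, ] <- rep(c(0, 1, 0, 1), 2)
  expect_warning(lab3 <- label_clusters(fake3), "tie")
  expect_equal(lab3$mechanism[1], "indirect")
})

test_that("planted direct/indirect mechanisms are recovered by clustering", {
  sim <- small_sim(n_genes = 900, seed = 19, phi = 0.1, effect = 2,
                   fractions = c(null = 0.5, direct_up = 0.1,
                                 direct_down = 0.1, indirect_up = 0.15,
                                 indirect_down = 0.15),
                   baseline = c(4, 9))
  ex <- sim$experiment
  f <- tmm_factors(ex)
  d <- estimate_dispersions(ex, f)
  de <- run_de(ex, f, d)
  tg <- call_targets(de, cpm_matrix(ex, f), ex$design)
  lcpm <- cpm_matrix(ex, f, log2 = TRUE)
  std <- standardize_trajectories(lcpm[tg$union, ], ex$design)
  cl <- kmeans_trajectories(std, k = 4, seed = 99)
  lab <- label_clusters(cl)
  mech <- setNames(lab$mechanism[cl$assignments], names(cl$assignments))
  truth <- sim$truth[match(names(mech), sim$truth$gene), ]
  ok <- !is.na(truth$expected_mechanism)
  agree <- mean(mech[ok] == truth$expected_mechanism[ok])
  expect_gte(agree, 0.8)
})

test_that("Fisher contingency p-values match exhaustive enumeration", {
  r <- axis_contingency(list(t = list(
    a = setNames(rep(c("down", "up"), c(4, 4)), paste0("g", 1:8)),
    b = setNames(c(rep("indirect", 3), "direct", "indirect",
                   rep("direct", 3)), paste0("g", 1:8)))))
  expect_equal(r$p, 0.4857, tolerance = 1e-4)
  expect_equal(unname(unlist(r[1, c("n11", "n12", "n21", "n22")])),
               c(1, 3, 3, 1))

  # independence-structured table
  a <- setNames(rep(c("down", "up"), each = 20), paste0("g", 1:40))
  b <- setNames(rep(c("direct", "indirect"), 20), paste0("g", 1:40))
  r2 <- axis_contingency(list(t = list(a = a, b = b)))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)

  # perfectly separated table: p = 2 * C(5,5)C(5,0)/C(10,5)
  a3 <- setNames(rep(c("down", "up"), each = 5), paste0("g", 1:10))
  b3 <- setNames(rep(c("direct", "indirect"), each = 5), paste0("g", 1:10))
  r3 <- axis_contingency(list(t = list(a = a3, b = b3)))
  expect_equal(r3$p, 0.0079, tolerance = 1e-2)
  expect_equal(r3$p, fisher_enum_oracle(matrix(c(5, 0, 0, 5), 2)))

  # random tables up to n = 40 against the enumeration oracle
  set.seed(12)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    av <- setNames(sample(c("x", "y"), n, replace = TRUE), paste0("g", 1:n))
    bv <- setNames(sample(c("u", "v"), n, replace = TRUE), paste0("g", 1:n))
    if (length(unique(av)) < 2 || length(unique(bv)) < 2) next
    r <- axis_contingency(list(t = list(a = av, b = bv)))
    tab <- table(factor(av), factor(bv))
    expect_equal(r$p, fisher_enum_oracle(tab), tolerance = 1e-10)
  }

  # mixed-direction genes are excluded; degenerate margins are skipped
  am <- setNames(c("down", "mixed", "down", "up", "up"), paste0("g", 1:5))
  bm <- setNames(rep(c("direct", "indirect"), c(2, 3)), paste0("g", 1:5))
  rm_ <- axis_contingency(list(t = list(a = am, b = bm)))
  expect_equal(rm_$n11 + rm_$n12 + rm_$n21 + rm_$n22, 4)
  expect_warning(axis_contingency(list(t = list(
    a = setNames(rep("down", 4), paste0("g", 1:4)),
    b = setNames(rep(c("direct", "indirect"), 2), paste0("g", 1:4))))),
    "degenerate")
})
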