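test_that("dispersion estimation recovers the truth", {
  sim0 <- small_sim(n_genes = 1500, phi = 0, seed = 21,
                    fractions = c(null = 1), baseline = c(3, 9))
  d0 <- estimate_dispersions(sim0$experiment)
  expect_lt(d0$common, 0.05)

  sim2 <- small_sim(n_genes = 1500, phi = 0.2, seed = 22,
                    fractions = c(null = 1), baseline = c(3, 9))
  d2 <- estimate_dispersions(sim2$experiment)
  expect_gt(d2$common, 0.15)
  expect_lt(d2$common, 0.25)

  # a gene carrying no information shrinks to the common value
  flatrow <- which.max(rowMeans(sim2$experiment$counts))
  ex <- sim2$experiment
  ex$counts[flatrow, ] <- 500L
  d3 <- estimate_dispersions(ex)
  expect_lt(abs(log(d3$tagwise[flatrow] / d3$common)), 0.7)

  solo <- toy_experiment(cbind(s1 = c(g1 = 5L), s2 = c(7L)),
                         time_h = c(4, 4), arm = c("treated", "control"))
  expect_error(estimate_dispersions(solo), "replicates")
})

test_that("TREAT p-values behave correctly inside and at the null boundary", {
  ex <- flat_experiment(n_genes = 5, value = 200)
  disp <- estimate_dispersions(ex)
  tt <- treat_test(ex, NULL, disp, time_h = 4, tau = 1.5)
  expect_equal(tt$log2FC, rep(0, 5))
  expect_equal(tt$p, rep(1, 5))

  # inside the null region p >= 0.5 by construction
  sim <- small_sim(n_genes = 400, phi = 0.1, seed = 5)
  f <- tmm_factors(sim$experiment)
  d <- estimate_dispersions(sim$experiment, f)
  tt4 <- treat_test(sim$experiment, f, d, 4, tau = 1.5)
  inside <- abs(tt4$log2FC) <= log2(1.5)
  expect_true(all(tt4$p[inside] >= 0.5))

  # monotone non-increasing in |log2FC| at fixed standard error
  pfun <- function(b, se, tau) pmin(1,
    pnorm((abs(b) - log2(tau)) / se, lower.tail = FALSE) +
    pnorm((abs(b) + log2(tau)) / se, lower.tail = FALSE))
  expect_equal(tt4$p, pfun(tt4$log2FC, tt4$se, 1.5))
  bs <- seq(0, 4, by = 0.1)
  expect_true(all(diff(pfun(bs, 0.4, 1.5)) <= 1e-12))

  # tau -> 1 recovers the ordinary two-sided Wald test
  tt1 <- treat_test(sim$experiment, f, d, 4, tau = 1)
  expect_equal(tt1$p,
               pmin(1, 2 * pnorm(abs(tt1$log2FC) / tt1$se,
                                 lower.tail = FALSE)))
  expect_error(treat_test(sim$experiment, f, d, 99, 1.5), "no samples")
})

test_that("swapping arm labels negates log2FC and keeps p", {
  sim <- small_sim(n_genes = 300, seed = 8)
  ex <- sim$experiment
  f <- tmm_factors(ex)
  d <- estimate_dispersions(ex, f)
  tt <- treat_test(ex, f, d, 8, 1.5)
  swapped <- ex
  swapped$design$arm <- ifelse(ex$design$arm == "treated",
                               "control", "treated")
  ts <- treat_test(swapped, f, d, 8, 1.5)
  expect_equal(ts$log2FC, -tt$log2FC)
  expect_equal(ts$p, tt$p)
})

test_that("type-I error of the TREAT test is controlled on all-null data", {
  sim <- small_sim(n_genes = 2000, phi = 0.2, seed = 31,
                   fractions = c(null = 1), baseline = c(2, 9))
  f <- tmm_factors(sim$experiment)
  d <- estimate_dispersions(sim$experiment, f)
  tt <- treat_test(sim$experiment, f, d, 24, 1.5)
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(tt$p < 0.05), 0.05 + 3 * mc_se)
})

test_that("strong planted effects are detected (power)", {
  sim <- small_sim(n_genes = 1000, phi = 0.1, seed = 32, effect = 3,
                   fractions = c(null = 0.6, direct_up = 0.2,
                                 direct_down = 0.2),
                   baseline = c(log2(100), 9), onset_choices = 4)
  f <- tmm_factors(sim$experiment)
  d <- estimate_dispersions(sim$experiment, f)
  tt <- treat_test(sim$experiment, f, d, 24, 2)
  planted <- sim$truth$archetype != "null"
  expect_gte(mean(tt$p[planted] < 0.01), 0.95)
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(2)
  for (m in c(10, 137, 1000)) {
    p <- runif(m)^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  p_na <- c(0.01, NA, 0.5)
  out <- bh_adjust(p_na)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(p_na[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("target calling applies the FDR and expression-floor rules", {
  # hand-built DE table + CPM: enumerate survivors directly
  genes <- sprintf("g%02d", 1:50)
  set.seed(9)
  design <- data.frame(sample = paste0("s", 1:8),
                       time_h = rep(c(4, 8, 24, 48), each = 2),
                       arm = rep(c("treated", "control"), 4),
                       replicate = 1)
  de <- do.call(rbind, lapply(c(4, 8, 24, 48), function(tp)
    data.frame(gene = genes, time_h = tp, log2FC = 0,
               FDR = round(runif(50), 2))))
  cpm <- matrix(round(runif(50 * 8, 0, 20)), 50, 8,
                dimnames = list(genes, design$sample))
  tg <- call_targets(de, cpm, design, alpha = 0.3, cpm_floor = 25)
  for (tp in c(4, 8, 24, 48)) {
    expected <- genes[sapply(genes, function(g) {
      fdr <- de$FDR[de$gene == g & de$time_h == tp]
      floor_val <- sum(sapply(c(4, 8, 24, 48), function(t)
        mean(cpm[g, design$time_h == t])))
      fdr < 0.3 && floor_val > 25
    })]
    expect_setequal(tg$per_time[[as.character(tp)]], expected)
  }
  expect_setequal(tg$union, unique(unlist(tg$per_time)))

  # floor rule alone can veto a significant gene
  de1 <- data.frame(gene = "g", time_h = c(4, 8, 24, 48), log2FC = 2,
                    FDR = c(1, 1, 0.01, 1))
  cpm1 <- matrix(1, 1, 8, dimnames = list("g", design$sample))
  expect_length(call_targets(de1, cpm1, design)$union, 0)
  cpm2 <- matrix(10, 1, 8, dimnames = list("g", design$sample))
  tg2 <- call_targets(de1, cpm2, design)
  expect_equal(tg2$union, "g")
  expect_equal(tg2$per_time[["24"]], "g")
  expect_length(tg2$per_time[["4"]], 0)
})

test_that("the Wald TREAT agrees with edgeR glmTreat as a cross-check", {
  sim <- small_sim(n_genes = 500, phi = 0.1, seed = 77, effect = 2,
                   fractions = c(null = 0.7, direct_up = 0.15,
                                 direct_down = 0.15),
                   baseline = c(log2(50), 9))
  ex <- sim$experiment
  f <- tmm_factors(ex)
  d <- estimate_dispersions(ex, f)
  mine <- treat_test(ex, f, d, 24, 2)
  y <- edgeR::DGEList(ex$counts)
  y <- edgeR::calcNormFactors(y)
  grp <- interaction(ex$design$time_h, ex$design$arm)
  mm <- stats::model.matrix(~0 + grp)
  colnames(mm) <- levels(grp)
  y <- edgeR::estimateDisp(y, mm, robust = TRUE)
  fit <- edgeR::glmQLFit(y, mm, robust = TRUE)
  con <- as.numeric(colnames(mm) == "24.treated") -
    as.numeric(colnames(mm) == "24.control")
  tt <- edgeR::glmTreat(fit, contrast = con, lfc = 1)
  ord <- match(mine$gene, rownames(tt$table))
  expect_gt(cor(mine$log2FC, tt$table$logFC[ord]), 0.999)
  # both tests rank genes almost identically
  expect_gt(cor(rank(mine$p), rank(tt$table$PValue[ord]),
                method = "spearman"), 0.97)
})
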