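test_that("MLM with identity kinship equals per-marker OLS F-tests", {
  g <- subset_geno(fix_small, markers = 1:40)
  y <- sim_polygenic(fix_small, 20, 0.5, seed = 61)
  res <- mlm_scan(y, g, grm = NULL, n_pcs = 0)
  p_ols <- vapply(seq_len(ncol(g$X)), function(j) {
    f <- summary(lm(y ~ g$X[, j]))
    if (nrow(f$coefficients) < 2) return(1)
    f$coefficients[2, 4]
  }, 0)
  expect_equal(res$p, p_ols, tolerance = 1e-8)
})

test_that("P3D p-values track exact per-marker REML p-values", {
  g <- fix_small
  K <- compute_grm(g)
  set.seed(62)
  y <- sim_polygenic(g, 30, 0.6, seed = 62)
  sub <- subset_geno(g, markers = sample(ncol(g$X), 250))
  p3d <- mlm_scan(y, sub, K, n_pcs = 3)
  exact <- mlm_scan(y, sub, K, n_pcs = 3, method = "exact")
  expect_gt(cor(rank(p3d$p), rank(exact$p)), 0.99)
})

test_that("null traits give calibrated inflation for the MLM", {
  g <- fix_small
  K <- compute_grm(g)
  lam <- vapply(1:5, function(s) {
    y <- sim_polygenic(g, 60, 0.4, seed = 400 + s)  # polygenic only, no QTL
    genomic_inflation(mlm_scan(y, g, K)$p)
  }, 0)
  expect_gt(mean(lam), 0.85)
  expect_lt(mean(lam), 1.15)
})

test_that("BH and Bonferroni thresholds match brute-force enumeration", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  th <- significance_threshold(p, "BH", 0.05)
  expect_equal(th$flags, c(TRUE, TRUE, TRUE, FALSE))
  # brute-force step-up enumeration on random vectors
  set.seed(63)
  for (i in 1:20) {
    pv <- runif(25)^2
    th <- significance_threshold(pv, "BH", 0.05)
    m <- length(pv)
    ps <- sort(pv)
    kmax <- suppressWarnings(max(which(ps <= 0.05 * seq_len(m) / m)))
    brute <- if (is.finite(kmax)) pv <= ps[kmax] else rep(FALSE, m)
    expect_identical(th$flags, brute)
  }
  expect_false(any(significance_threshold(rep(1, 5), "BH", 0.05)$flags))
  # Bonferroni cutoff at the study marker count
  bb <- significance_threshold(runif(10), "bonferroni", 0.05)
  expect_equal(bb$cutoff, 0.05 / 10)
  expect_equal(0.05 / 40368, 1.2387e-06, tolerance = 1e-4)
  expect_error(significance_threshold(numeric(0)), "empty")
})

test_that("BH flags are monotone in alpha", {
  set.seed(64)
  pv <- runif(50)^3
  f1 <- significance_threshold(pv, "BH", 0.01)$flags
  f2 <- significance_threshold(pv, "BH", 0.05)$flags
  expect_true(all(f2[f1]))
})

test_that("stepwise marker effect and delta-R2 match regression oracles", {
  g <- fix_small
  set.seed(65)
  x <- g$X[, 10]
  y <- 30 * x + rnorm(nrow(g$X), 0, 1)
  names(y) <- rownames(g$X)
  er <- marker_effect_r2(y, g, colnames(g$X)[c(10, 25)])
  expect_equal(er$effect[1], 30, tolerance = 0.05)
  expect_equal(er$favorable_allele[1], "minor")
  expect_lt(er$r2[2], 0.1)
  # delta-R2 equals the squared partial correlation (no covariates case)
  y2 <- sim_polygenic(g, 20, 0.5, seed = 66)
  er2 <- marker_effect_r2(y2, g, colnames(g$X)[3])
  expect_equal(er2$r2, cor(y2, g$X[, 3])^2, tolerance = 1e-10)
})

test_that("engines agree on marker table and are deterministic", {
  g <- fix_small
  K <- compute_grm(g)
  y <- sim_polygenic(g, 30, 0.6, seed = 67)
  r1 <- mlm_scan(y, g, K)
  r2 <- farmcpu_scan(y, g)
  r3 <- blink_scan(y, g)
  expect_identical(r1$marker, r2$marker)
  expect_identical(r2$marker, r3$marker)
  expect_equal(r1$maf, r2$maf)
  expect_equal(r2$maf, r3$maf)
  r2b <- farmcpu_scan(y, g)
  expect_identical(r2$p, r2b$p)
  r3b <- blink_scan(y, g)
  expect_identical(r3$p, r3b$p)
})

test_that("multi-locus engines find a planted QTL and respect redundancy", {
  g <- fix_structured
  set.seed(68)
  mk <- colnames(g$X)[200]
  xq <- scale(g$X[, mk])[, 1] * sqrt(0.15)
  poly <- drop(scale(g$X[, sample(ncol(g$X), 80)], TRUE, FALSE) %*% rnorm(80))
  poly <- residuals(lm(poly ~ xq))  # keep the planted share at 15%
  poly <- poly / sd(poly) * sqrt(0.35)
  y <- drop(xq + poly + rnorm(nrow(g$X), 0, sqrt(0.5)))
  names(y) <- rownames(g$X)
  rf <- farmcpu_scan(y, g)
  rb <- blink_scan(y, g)
  ld_with_qtl <- function(ids) {
    if (!length(ids)) return(0)
    max(cor(g$X[, ids, drop = FALSE], g$X[, mk])^2)
  }
  # planted marker (or a bin-mate in strong LD) is selected and significant
  expect_gt(ld_with_qtl(attr(rf, "qtn")), 0.9)
  expect_gt(ld_with_qtl(attr(rb, "qtn")), 0.9)
  sig_f <- rf$marker[rf$significant]
  expect_gt(ld_with_qtl(sig_f), 0.9)
  # two markers in perfect LD: only one may enter the BLINK QTN set
  dup <- g
  dup$X <- cbind(g$X, S7D_999 = g$X[, mk])
  dup$map <- rbind(g$map, data.frame(marker = "S7D_999", chrom = "7D",
                                     pos = 999))
  rbd <- blink_scan(y, dup)
  qtn <- attr(rbd, "qtn")
  expect_lte(sum(qtn %in% c(mk, "S7D_999")), 1)
})

test_that("high-LD block around a causal marker: MLM flags more block members than multi-locus engines", {
  g <- simulate_genotypes(genome_sim_config(
    n_lines = 250, n_chrom = 3, markers_per_chrom = 100, ld_block_len = 10,
    within_block_r2 = 0.95, n_subpops = 2, divergence = 0.1, het_rate = 0,
    seed = 71))
  K <- compute_grm(g)
  set.seed(72)
  blockstart <- 41
  block <- colnames(g$X)[blockstart:(blockstart + 9)]
  mk <- block[5]
  xq <- scale(g$X[, mk])[, 1] * sqrt(0.25)
  y <- drop(xq + rnorm(nrow(g$X), 0, sqrt(0.75)))
  names(y) <- rownames(g$X)
  rm_ <- mlm_scan(y, g, K)
  rf <- farmcpu_scan(y, g)
  in_block <- function(r) sum(r$significant & r$marker %in% block)
  expect_gt(in_block(rm_), 1)
  expect_lt(in_block(rf), in_block(rm_))
})

test_that("scan errors are informative", {
  g <- fix_small
  y <- sim_polygenic(g, 10, 0.5, seed = 75)
  bad <- cbind(a = rep(1, nrow(g$X)))  # collinear with intercept
  rownames(bad) <- rownames(g$X)
  expect_error(mlm_scan(y, g, NULL, covariates = bad), "collinear")
  expect_error(mlm_scan(y[1:5], g, NULL), "too few lines")
})
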