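test_that("LD r2 matches the haplotype-frequency oracle on phased inbred lines", {
  # 8 inbred lines: dosage/2 is the haplotype allele
  X <- rbind(c(0, 0), c(0, 0), c(2, 2), c(2, 2), c(2, 2), c(0, 2),
             c(2, 0), c(0, 0)) |> `colnames<-`(c("S1A_10", "S1A_20"))
  rownames(X) <- paste0("l", 1:8)
  g <- geno_matrix(X)
  ld <- ld_matrix(g)
  a <- X[, 1] / 2; b <- X[, 2] / 2
  pA <- mean(a); pB <- mean(b)
  D <- mean(a * b) - pA * pB
  r2_hap <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(ld$r2["S1A_10", "S1A_20"], r2_hap, tolerance = 1e-12)
  # duplicated column gives r2 = 1
  X2 <- cbind(X, S1A_30 = X[, 1])
  ld2 <- ld_matrix(geno_matrix(X2))
  expect_equal(ld2$r2["S1A_10", "S1A_30"], 1)
  # zero-variance marker reported missing
  X3 <- cbind(X, S1A_40 = rep(2, 8))
  ld3 <- ld_matrix(geno_matrix(X3))
  expect_true(all(is.na(ld3$r2["S1A_40", ])))
})

test_that("independent markers reach nominal 5% LD significance", {
  set.seed(111)
  n <- 473
  X <- matrix(rbinom(n * 40, 2, 0.3), n,
              dimnames = list(paste0("l", 1:n), paste0("S1A_", 1:40)))
  ld <- ld_matrix(geno_matrix(X))
  pv <- ld$p[upper.tri(ld$p)]
  rate <- mean(pv < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("cross-chromosome pairs can be masked", {
  X <- matrix(rbinom(60, 2, 0.4), 20,
              dimnames = list(paste0("l", 1:20),
                              c("S1A_1", "S1A_2", "S2B_5")))
  ld <- ld_matrix(geno_matrix(X), same_chrom_only = TRUE)
  expect_true(is.na(ld$r2["S1A_1", "S2B_5"]))
  expect_false(is.na(ld$r2["S1A_1", "S1A_2"]))
})

fake_result <- function(markers, sig, population, trial) {
  data.frame(marker = markers, significant = markers %in% sig,
             population = population, trial = trial,
             stringsAsFactors = FALSE)
}

test_that("consistency rule: >= 2 trials in one population or both populations", {
  mk <- paste0("S1A_", 1:6)
  r1 <- fake_result(mk, c("S1A_1", "S1A_2"), "DP", "2015")
  r2 <- fake_result(mk, c("S1A_1", "S1A_3"), "DP", "2015-2017")
  r3 <- fake_result(mk, c("S1A_3", "S1A_4"), "BL", "2015")
  cons <- consistent_markers(list(r1, r2, r3))
  got <- cons$consistent[match(mk, cons$marker)]
  # S1A_1: two DP trials; S1A_3: DP + BL; S1A_2/4: single hits; 5/6: none
  expect_identical(got, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # brute-force enumeration oracle over the same fixture
  sets <- list(c("S1A_1", "S1A_2"), c("S1A_1", "S1A_3"), c("S1A_3", "S1A_4"))
  pops <- c("DP", "DP", "BL")
  brute <- vapply(mk, function(m) {
    hit <- vapply(sets, function(s) m %in% s, TRUE)
    length(unique(pops[hit])) >= 2 ||
      any(tapply(hit, pops, sum) >= 2)
  }, TRUE)
  expect_identical(unname(brute), got)
  expect_error(consistent_markers(list(r1)), "two result sets")
})

test_that("LD binning collapses linked trios and picks largest-effect representatives", {
  mk <- c("A", "B", "C")
  ld <- matrix(1, 3, 3, dimnames = list(mk, mk))
  eff <- c(A = 10, B = 31, C = 17)
  bins <- bin_consistent_markers(mk, ld, eff)
  expect_length(bins, 1)
  expect_equal(bins[[1]]$representative, "B")
  expect_setequal(bins[[1]]$members, mk)
  # single-linkage chain: A-B .9, B-C .9, A-C .5 -> one bin
  ld2 <- rbind(c(1, .9, .5), c(.9, 1, .9), c(.5, .9, 1))
  dimnames(ld2) <- list(mk, mk)
  bins2 <- bin_consistent_markers(mk, ld2, eff, threshold = 0.8)
  expect_length(bins2, 1)
  # complete-linkage enumeration would separate {A} from {B,C} or keep pairs;
  # single linkage must not
  ld3 <- rbind(c(1, .9, .1), c(.9, 1, .1), c(.1, .1, 1))
  dimnames(ld3) <- list(mk, mk)
  bins3 <- bin_consistent_markers(mk, ld3, eff, threshold = 0.8)
  expect_length(bins3, 2)
  # idempotence: re-binning representatives yields singletons
  reps <- vapply(bins3, `[[`, "", "representative")
  bins4 <- bin_consistent_markers(reps, ld3[reps, reps, drop = FALSE], eff)
  expect_true(all(vapply(bins4, function(b) length(b$members), 0L) == 1))
})

test_that("pyramiding shows additive group means and recovers allele frequencies", {
  set.seed(121)
  n <- 500
  freq <- 0.9
  X <- sapply(1:6, function(j) 2L * rbinom(n, 1, freq))
  colnames(X) <- paste0("S", 1:6, "A_100")
  rownames(X) <- paste0("l", 1:n)
  g <- geno_matrix(X)
  y <- drop(X %*% rep(5, 6)) / 2 + rnorm(n, 0, 1)
  names(y) <- rownames(X)
  ld <- diag(6); dimnames(ld) <- list(colnames(X), colnames(X))
  bins <- bin_consistent_markers(colnames(X), ld,
                                 setNames(rep(5, 6), colnames(X)))
  pyr <- pyramiding_analysis(g, bins, y)
  # favorable frequency recovered near the simulated 0.9
  expect_equal(unname(mean(pyr$favorable_freq)), freq, tolerance = 0.05)
  # group means increase with favorable-allele count (additive signal)
  gr <- pyr$groups[pyr$groups$n >= 5, ]
  expect_true(all(diff(gr$mean) > 0))
  slope <- coef(lm(mean ~ count, data = gr))[2]
  expect_equal(unname(slope), 5, tolerance = 1)
  # zero-effect bins: flat means
  y0 <- rnorm(n); names(y0) <- rownames(X)
  pyr0 <- pyramiding_analysis(g, bins, y0)
  gr0 <- pyr0$groups[pyr0$groups$n >= 5, ]
  expect_lt(max(abs(diff(gr0$mean))), 1)
  # counts invariant to marker order
  pyr_r <- pyramiding_analysis(g, rev(bins), y)
  expect_equal(sort(pyr_r$per_line$count), sort(pyr$per_line$count))
  # joint R2 at least the best single-bin delta-R2
  best_single <- max(vapply(seq_len(6), function(j)
    summary(lm(y ~ X[, j]))$r.squared, 0))
  expect_gte(pyr$total_r2, best_single - 1e-10)
})
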