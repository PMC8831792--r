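test_that("simulated genotypes are valid biallelic dosages with an ordered map", {
  g <- fix_small
  expect_true(all(g$X %in% 0:2))
  expect_true(all(maf(g) >= 0.05))
  for (ch in unique(g$map$chrom)) {
    expect_true(all(diff(g$map$pos[g$map$chrom == ch]) > 0))
  }
  # seed reproducibility
  g2 <- simulate_genotypes(genome_sim_config(
    n_lines = 150, n_chrom = 5, markers_per_chrom = 60, within_block_r2 = 0.7,
    n_subpops = 2, divergence = 0.1, het_rate = 0, seed = 103))
  expect_identical(g$X, g2$X)
})

test_that("degenerate genome configurations are rejected", {
  expect_error(genome_sim_config(n_lines = 0), "degenerate")
  expect_error(genome_sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(genome_sim_config(within_block_r2 = 1.2), "within_block_r2")
})

test_that("within_block_r2 = 1 duplicates block columns exactly", {
  g <- simulate_genotypes(genome_sim_config(
    n_lines = 120, n_chrom = 1, markers_per_chrom = 5, ld_block_len = 5,
    within_block_r2 = 1, n_subpops = 1, divergence = 0, het_rate = 0,
    seed = 7))
  r2 <- cor(g$X)^2
  expect_true(all(abs(r2[upper.tri(r2)] - 1) < 1e-12))
})

test_that("k-means on PCs recovers planted subpopulations (ARI > 0.8)", {
  st <- compute_pcs_and_clusters(fix_structured, n_pcs = 3, k_max = 8,
                                 seed = 5)
  expect_equal(st$elbow_k, 4)
  expect_gt(ari(st$clusters, fix_structured$subpop), 0.8)
})

test_that("unstructured population has no dominant PC axis", {
  st <- compute_pcs_and_clusters(fix_flat, n_pcs = 3, k_max = 6, seed = 5)
  expect_equal(sum(st$var_share), 1, tolerance = 1e-10)
  # PC1 share comparable to PC2 share (no structure axis)
  expect_lt(st$var_share[1] / st$var_share[2], 1.5)
})

test_that("trait pair hits the target genetic correlation", {
  g <- fix_small
  set.seed(4)
  qtl <- sample(colnames(g$X), 25)
  eff <- rnorm(25, 0, 2)
  # identical architecture at rg = 1 gives correlation 1
  a1 <- trait_architecture(qtl, eff, rg_secondary = 1, h2_target = 0.6)
  t1 <- simulate_trait_pair(g, a1, seed = 9)
  expect_equal(cor(t1$bv$trait_a, t1$bv$trait_b), 1, tolerance = 1e-8)
  # rg = 0.5: mean realized correlation within 0.1 over replicates
  a2 <- trait_architecture(qtl, eff, rg_secondary = 0.5, h2_target = 0.6)
  rs <- vapply(1:10, function(s) {
    tr <- simulate_trait_pair(g, a2, seed = s)
    cor(tr$bv$trait_a, tr$bv$trait_b)
  }, 0)
  expect_lt(abs(mean(rs) - 0.5), 0.1)
  # h2 = 0 switches the genetic signal off entirely
  a0 <- trait_architecture(qtl, eff, h2_target = 0)
  t0 <- simulate_trait_pair(g, a0, seed = 9)
  expect_true(all(t0$bv$trait_a == 0) && all(t0$bv$trait_b == 0))
  expect_equal(unname(t0$var_g), c(0, 0))
})

test_that("infeasible correlation targets are rejected with a named constraint", {
  g <- fix_small
  qtl <- colnames(g$X)[1:5]
  expect_error(trait_architecture(qtl, rep(1, 5), rg_secondary = 1.2), "rg_secondary")
  a <- trait_architecture(qtl, rep(1, 5), rg_secondary = 1,
                          shared_qtl_ids = character(0))
  expect_error(simulate_trait_pair(g, a), "shared QTL")
})

test_that("augmented layout places checks per block and entries once per env", {
  entries <- paste0("e", 1:10)
  checks <- paste0("c", 1:3)
  d <- layout_augmented_design(entries, 2, checks, n_env = 1, seed = 1)
  expect_equal(nrow(d), 2 * 3 + 10)
  tab <- table(d$line[d$is_check], d$block[d$is_check])
  expect_true(all(tab == 1))
  expect_true(all(table(d$line[!d$is_check]) == 1))
  # multi-env: every entry exactly once per environment
  d3 <- layout_augmented_design(entries, 2, checks, n_env = 3, seed = 1)
  expect_true(all(table(d3$line[!d3$is_check], d3$env[!d3$is_check]) == 1))
  # permuting entry order changes assignment, not per-line plot counts
  d2 <- layout_augmented_design(rev(entries), 2, checks, n_env = 1, seed = 2)
  expect_equal(table(d2$line), table(d$line))
  expect_error(layout_augmented_design(entries, 2, c("e1", "x"), 1, 1),
               "disjoint")
  expect_error(layout_augmented_design(entries, 1, checks), "blocks")
})

test_that("plot phenotypes honor the component variances", {
  g <- fix_small
  qtl <- colnames(g$X)[1:10]
  arch0 <- trait_architecture(qtl, rep(0, 10), h2_target = 0, gei_var = 0)
  tr <- simulate_trait_pair(g, arch0, seed = 2)
  skel <- layout_augmented_design(rownames(g$X)[6:50], 2, rownames(g$X)[1:5],
                                  n_env = 2, seed = 3)
  # all variance components zero -> every plot equals the grand mean
  ph <- simulate_plot_phenotypes(skel, tr, arch0, mu = 60, block_var = 0,
                                 env_var = 0, block_env_var = 0,
                                 resid_var = 0, seed = 4)
  expect_true(all(abs(ph$value - 60) < 1e-12))
  # gei_var = 0: per-line env-centered means constant across environments
  arch1 <- trait_architecture(qtl, rnorm(10, 0, 3), h2_target = 0.9,
                              gei_var = 0)
  tr1 <- simulate_trait_pair(g, arch1, seed = 5)
  ph1 <- simulate_plot_phenotypes(skel, tr1, arch1, block_var = 0,
                                  env_var = 50, block_env_var = 0,
                                  resid_var = 1e-8, seed = 6)
  cen <- do.call(rbind, lapply(split(ph1, ph1$env), function(dd) {
    data.frame(line = dd$line, dev = dd$value - mean(dd$value))
  }))
  spread <- tapply(cen$dev, cen$line, function(v) diff(range(v)))
  expect_lt(max(spread), 0.1)
})
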