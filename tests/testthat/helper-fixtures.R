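# shared fixtures, built once per test run

# adjusted Rand index by pair counting (independent of any clustering pkg)
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# structured panel reused across structure/GWAS tests
fix_structured <- simulate_genotypes(genome_sim_config(
  n_lines = 400, n_chrom = 5, markers_per_chrom = 80, within_block_r2 = 0.6,
  n_subpops = 4, divergence = 0.15, het_rate = 0, seed = 101
))

# unstructured panel
fix_flat <- simulate_genotypes(genome_sim_config(
  n_lines = 150, n_chrom = 4, markers_per_chrom = 50, n_subpops = 1,
  divergence = 0, het_rate = 0, seed = 102
))

# small panel for scan tests
fix_small <- simulate_genotypes(genome_sim_config(
  n_lines = 150, n_chrom = 5, markers_per_chrom = 60, within_block_r2 = 0.7,
  n_subpops = 2, divergence = 0.1, het_rate = 0, seed = 103
))

# polygenic trait on a genotype panel: n_qtl random markers, h2 on line basis
sim_polygenic <- function(geno, n_qtl = 50, h2 = 0.5, seed = 1) {
  set.seed(seed)
  qtl <- sample(ncol(geno$X), n_qtl)
  g <- drop(scale(geno$X[, qtl], TRUE, FALSE) %*% rnorm(n_qtl))
  g <- g / sd(g)
  y <- g + rnorm(nrow(geno$X), 0, sqrt((1 - h2) / h2))
  names(y) <- rownames(geno$X)
  y
}
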