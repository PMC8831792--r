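#' Genome simulation configuration
#'
#' Parameters for simulating biallelic genotypes of inbred lines with LD
#' blocks and discrete population structure. Structure follows a
#' Balding-Nichols model: each subpopulation draws its allele frequency
#' around a common ancestral frequency with drift parameter `divergence`.
#' LD blocks are built by copying a latent block haplotype with a per-marker
#' flip probability tuned so pairwise within-block r^2 lands near
#' `within_block_r2`.
#'
#' @param n_lines number of inbred lines.
#' @param n_chrom number of chromosomes (21 gives wheat-style 1A..7D labels).
#' @param markers_per_chrom markers simulated per chromosome (before the
#'   simulation-side MAF filter, which may drop a few).
#' @param ld_block_len markers per LD block.
#' @param within_block_r2 target pairwise r^2 inside a block, in `[0, 1]`.
#' @param maf_range ancestral allele frequency range, within `(0, 0.5]`.
#'   Markers whose realized MAF falls below the lower bound are dropped.
#' @param n_subpops number of subpopulations (>= 1).
#' @param divergence Balding-Nichols drift parameter in `[0, 1)`; 0 means no
#'   structure.
#' @param het_rate probability a call is heterozygous (inbred lines, so low).
#' @param seed RNG seed.
#' @return a `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_lines = 473, n_chrom = 21,
                              markers_per_chrom = 100, ld_block_len = 5,
                              within_block_r2 = 0.6,
                              maf_range = c(0.05, 0.5), n_subpops = 4,
                              divergence = 0.15, het_rate = 0.02,
                              seed = 1L) {
  if (n_lines < 1 || n_chrom < 1 || markers_per_chrom < 1) {
    stop("degenerate configuration: need at least one line, chromosome and marker")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    stop("within_block_r2 must be in [0, 1]")
  }
  if (n_subpops < 1) stop("n_subpops must be >= 1")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  structure(list(
    n_lines = as.integer(n_lines), n_chrom = as.integer(n_chrom),
    markers_per_chrom = as.integer(markers_per_chrom),
    ld_block_len = as.integer(ld_block_len),
    within_block_r2 = within_block_r2, maf_range = maf_range,
    n_subpops = as.integer(n_subpops), divergence = divergence,
    het_rate = het_rate, seed = as.integer(seed)
  ), class = "genome_sim_config")
}

wheat_chrom_labels <- function(n) {
  lab <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  if (n <= 21) lab[seq_len(n)] else paste0("chr", seq_len(n))
}

#' Simulate structured inbred genotypes
#'
#' Draws minor-allele dosages for `cfg$n_lines` inbred lines. Lines are
#' split near-equally into subpopulations; per-block ancestral frequencies
#' are perturbed per subpopulation by a Balding-Nichols Beta draw. Within a
#' block every marker copies a latent block haplotype and is flipped to an
#' independent draw with probability `1 - r2^(1/4)`, which makes the expected
#' pairwise within-block correlation `sqrt(r2)` and hence r^2 near target.
#' Markers whose realized MAF falls below `cfg$maf_range[1]` are dropped.
#'
#' @param cfg a [genome_sim_config()].
#' @return a [geno_matrix()] with simulation-truth `subpop` labels.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  subpop <- sort(rep_len(seq_len(cfg$n_subpops), n))
  flip <- 1 - cfg$within_block_r2^(1 / 4)
  F <- cfg$divergence

  cols <- list(); chroms <- character(0); poss <- integer(0)
  for (ch in seq_len(cfg$n_chrom)) {
    pos <- cumsum(sample(5e3:2e6, cfg$markers_per_chrom, replace = TRUE))
    nblocks <- ceiling(cfg$markers_per_chrom / cfg$ld_block_len)
    blk <- rep(seq_len(nblocks), each = cfg$ld_block_len)[seq_len(cfg$markers_per_chrom)]
    for (b in seq_len(nblocks)) {
      idx <- which(blk == b)
      p0 <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      ps <- if (F > 0 && cfg$n_subpops > 1) {
        stats::rbeta(cfg$n_subpops, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      } else rep(p0, cfg$n_subpops)
      ps <- pmin(pmax(ps, 0.01), 0.99)
      pline <- ps[subpop]
      seed_hap <- stats::rbinom(n, 1, pline)
      for (j in idx) {
        a <- seed_hap
        fl <- stats::runif(n) < flip
        a[fl] <- stats::rbinom(sum(fl), 1, pline[fl])
        d <- 2L * a
        het <- stats::runif(n) < cfg$het_rate
        d[het] <- 1L
        cols[[length(cols) + 1L]] <- d
        chroms <- c(chroms, wheat_chrom_labels(cfg$n_chrom)[ch])
        poss <- c(poss, pos[j])
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- sprintf("line%03d", seq_len(n))
  colnames(X) <- paste0("S", chroms, "_", poss)
  keep <- maf(X) >= cfg$maf_range[1] & maf(X) > 0
  X <- X[, keep, drop = FALSE]
  # polarize to minor-allele dosage (drift can push a frequency past 0.5)
  flip <- colMeans(X) > 1
  X[, flip] <- 2L - X[, flip]
  geno_matrix(X, subpop = subpop)
}

#' Trait architecture for a correlated trait pair
#'
#' Describes the genetic architecture of a focal trait (e.g. deep-sowing
#' seedling emergence, percent scale) and a genetically correlated secondary
#' trait (e.g. coleoptile length): QTL positions and additive effects, one
#' high-LD large-effect marker cluster, narrow-sense heritability target,
#' genotype-by-environment interaction variance, and the target genetic
#' correlation between the traits.
#'
#' @param qtl_ids marker ids (or column indices) carrying effects on the
#'   focal trait; must include `major_locus_block`.
#' @param qtl_effects additive effect (trait units per favorable allele copy)
#'   per member of `qtl_ids`.
#' @param major_locus_block marker ids of the large-effect high-LD cluster.
#' @param h2_target plot-basis narrow-sense heritability in `[0, 1]` used to
#'   scale residual noise.
#' @param n_env number of environments (years).
#' @param gei_var variance of genotype-by-environment deviations (trait
#'   units squared).
#' @param rg_secondary target genetic correlation with the secondary trait,
#'   in `[-1, 1]`.
#' @param shared_qtl_ids pleiotropic subset of `qtl_ids` also affecting the
#'   secondary trait.
#' @param rht_effect optional named numeric vector of per-class shifts (trait
#'   units) for the 7-code categorical major-gene (Rht-style) covariate;
#'   `NULL` disables the covariate.
#' @return a `trait_architecture` list.
#' @export
trait_architecture <- function(qtl_ids, qtl_effects,
                               major_locus_block = character(0),
                               h2_target = 0.7, n_env = 1, gei_var = 0,
                               rg_secondary = 0.4,
                               shared_qtl_ids = qtl_ids,
                               rht_effect = NULL) {
  stopifnot(length(qtl_ids) == length(qtl_effects))
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  if (abs(rg_secondary) > 1) stop("|rg_secondary| must be <= 1")
  if (!all(major_locus_block %in% qtl_ids)) {
    stop("major_locus_block must be a subset of qtl_ids")
  }
  if (!all(shared_qtl_ids %in% qtl_ids)) {
    stop("shared_qtl_ids must be a subset of the focal trait's qtl_ids")
  }
  structure(list(
    qtl_ids = qtl_ids, qtl_effects = qtl_effects,
    major_locus_block = major_locus_block, h2_target = h2_target,
    n_env = as.integer(n_env), gei_var = gei_var,
    rg_secondary = rg_secondary, shared_qtl_ids = shared_qtl_ids,
    rht_effect = rht_effect
  ), class = "trait_architecture")
}

rht_class_codes <- function(b1, d1) {
  # b1, d1: dosage of the mutant allele at each locus (0/1/2), inbred lines
  code <- integer(length(b1))
  code[b1 == 2 & d1 == 0] <- 1L  # Rht-B1b
  code[b1 == 0 & d1 == 2] <- 2L  # Rht-D1b
  code[b1 == 1 & d1 == 0] <- 3L  # B1b heterozygous
  code[b1 == 0 & d1 == 1] <- 4L  # D1b heterozygous
  code[b1 == 1 & d1 == 2] <- 5L  # D1b with het B1b
  code[b1 == 2 & d1 == 1] <- 6L  # B1b with het D1b
  code[b1 == 1 & d1 == 1] <- 7L  # both het
  code[b1 == 2 & d1 == 2] <- 2L  # double dwarf folded into D1b class
  code
}

#' Simulate breeding values for a correlated trait pair
#'
#' The focal trait's genetic value is the additive score of its QTL on
#' centered dosages (plus Rht-class shifts if configured). The secondary
#' trait mixes the focal trait's standardized shared-QTL score with an
#' orthogonalized independent polygenic score, with weights `rg` and
#' `sqrt(1 - rg^2)`, so the realized in-sample genetic correlation equals
#' `rg_secondary` (exactly, up to degenerate inputs).
#'
#' @param geno a [geno_matrix()].
#' @param arch a [trait_architecture()].
#' @param seed RNG seed.
#' @param n_bg number of random background markers used for the secondary
#'   trait's independent polygenic component.
#' @return list with `bv` (data frame: `line`, `trait_a`, `trait_b`),
#'   `qtl` (data frame of ids and effects), `var_g` (named genetic variances),
#'   and `rht` (data frame of codes and shifts, or `NULL`).
#' @export
simulate_trait_pair <- function(geno, arch, seed = 1L, n_bg = 100L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(arch, "trait_architecture"))
  set.seed(seed)
  ids <- resolve_markers(geno, arch$qtl_ids)
  W <- scale(geno$X[, ids, drop = FALSE], center = TRUE, scale = FALSE) / 2
  # per favorable-allele-copy effects on dosage scale
  ga <- drop(W %*% (2 * arch$qtl_effects))
  rht <- NULL
  if (!is.null(arch$rht_effect)) {
    b1 <- 2L * stats::rbinom(nrow(geno$X), 1, 0.56)
    d1 <- ifelse(b1 == 0, 2L * stats::rbinom(nrow(geno$X), 1, 0.85), 0L)
    het <- stats::runif(nrow(geno$X)) < 0.03
    b1[het & b1 == 2] <- 1L
    code <- rht_class_codes(b1, d1)
    shift <- arch$rht_effect[as.character(code)]
    shift[is.na(shift)] <- 0
    ga <- ga + shift
    rht <- data.frame(line = rownames(geno$X), rht_code = code,
                      stringsAsFactors = FALSE)
  }
  if (arch$h2_target == 0) ga <- ga * 0

  rg <- arch$rg_secondary
  if (abs(rg) > 0.99 && length(arch$shared_qtl_ids) == 0) {
    stop("rg_secondary near +/-1 requires a non-empty shared QTL set")
  }
  bg <- sample(setdiff(seq_len(ncol(geno$X)), ids), min(n_bg, ncol(geno$X) - length(ids)))
  s_bg <- drop(scale(geno$X[, bg, drop = FALSE], TRUE, FALSE) %*%
                 stats::rnorm(length(bg)))
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
  sA <- std(ga)
  e <- s_bg - sA * sum(s_bg * sA) / max(sum(sA^2), .Machine$double.eps)
  gb_unit <- rg * sA + sqrt(max(0, 1 - rg^2)) * std(e)
  sdb <- if (stats::sd(ga) > 0) stats::sd(ga) else 1
  gb <- gb_unit * sdb
  if (arch$h2_target == 0) gb <- gb * 0

  list(
    bv = data.frame(line = rownames(geno$X), trait_a = ga, trait_b = gb,
                    stringsAsFactors = FALSE),
    qtl = data.frame(marker = ids, effect = arch$qtl_effects,
                     major = ids %in% resolve_markers(geno, arch$major_locus_block),
                     stringsAsFactors = FALSE),
    var_g = c(trait_a = stats::var(ga), trait_b = stats::var(gb)),
    rht = rht
  )
}

resolve_markers <- function(geno, ids) {
  if (is.numeric(ids)) colnames(geno$X)[ids] else as.character(ids)
}

#' Lay out an unreplicated augmented complete block design
#'
#' Each environment is divided into `n_blocks` blocks; every check line is
#' planted once in every block of every environment, and every entry
#' (unreplicated test line) appears exactly once per environment, assigned
#' to a random block.
#'
#' @param lines character vector of entry (test) line ids.
#' @param n_blocks number of blocks per environment (>= 2).
#' @param check_lines character vector of replicated check line ids, disjoint
#'   from `lines`.
#' @param n_env number of environments.
#' @param seed RNG seed for entry randomization.
#' @return data frame (one row per plot): `line`, `env`, `block`, `is_check`,
#'   `rep` (NA for augmented layouts).
#' @export
layout_augmented_design <- function(lines, n_blocks, check_lines, n_env = 1,
                                    seed = 1L) {
  if (length(intersect(lines, check_lines)) > 0) {
    stop("check_lines must be disjoint from entries")
  }
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (length(lines) < 1) stop("design error: no entry lines")
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_env)) {
    ord <- sample(lines)
    blk_entry <- rep_len(seq_len(n_blocks), length(ord))
    out[[k]] <- rbind(
      data.frame(line = rep(check_lines, each = n_blocks),
                 env = paste0("env", k),
                 block = rep(seq_len(n_blocks), length(check_lines)),
                 is_check = TRUE, rep = NA_integer_,
                 stringsAsFactors = FALSE),
      data.frame(line = ord, env = paste0("env", k), block = blk_entry,
                 is_check = FALSE, rep = NA_integer_,
                 stringsAsFactors = FALSE)
    )
  }
  do.call(rbind, out)
}

#' Lay out a replicated multi-environment design
#'
#' Simple replicated layout for the secondary trait (every line in every
#' replicate of every environment), mirroring a greenhouse coleoptile trial.
#'
#' @param lines line ids.
#' @param n_env number of environments.
#' @param n_rep replicates per environment.
#' @return data frame with `line`, `env`, `block` (NA), `is_check`, `rep`.
#' @export
layout_replicated_design <- function(lines, n_env = 1, n_rep = 2) {
  g <- expand.grid(line = lines, env = paste0("env", seq_len(n_env)),
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  data.frame(line = g$line, env = g$env, block = NA_integer_,
             is_check = FALSE, rep = g$rep, stringsAsFactors = FALSE)
}

#' Simulate plot-level phenotypes on a trial skeleton
#'
#' Adds to each plot: grand mean, block main effect, environment effect,
#' block-by-environment interaction, replicate-within-environment effect
#' (replicated layouts), the line's breeding value, a genotype-by-environment
#' deviation at variance `arch$gei_var`, and residual noise. The residual
#' variance defaults to `var_g * (1 - h2) / h2` so the plot-basis
#' heritability matches `arch$h2_target`.
#'
#' @param skeleton design data frame from [layout_augmented_design()] or
#'   [layout_replicated_design()].
#' @param truth output of [simulate_trait_pair()].
#' @param arch the [trait_architecture()] used for `truth`.
#' @param trait `"trait_a"` or `"trait_b"`.
#' @param mu grand mean (trait units).
#' @param block_var,env_var,block_env_var,rep_var variance of the respective
#'   design effects.
#' @param resid_var residual plot variance; `NULL` derives it from
#'   `h2_target`.
#' @param seed RNG seed.
#' @return the skeleton with a `value` column appended (a trial table).
#' @export
simulate_plot_phenotypes <- function(skeleton, truth, arch, trait = "trait_a",
                                     mu = 60, block_var = 25, env_var = 100,
                                     block_env_var = 10, rep_var = 5,
                                     resid_var = NULL, seed = 1L) {
  set.seed(seed)
  bv <- truth$bv[[trait]]
  names(bv) <- truth$bv$line
  if (anyNA(bv[skeleton$line])) stop("skeleton contains lines without breeding values")
  vg <- stats::var(bv)
  if (is.null(resid_var)) {
    h2 <- arch$h2_target
    resid_var <- if (h2 <= 0 || vg == 0) 1 else if (h2 >= 1) 0 else vg * (1 - h2) / h2
  }
  envs <- unique(skeleton$env)
  blocks <- unique(skeleton$block[!is.na(skeleton$block)])
  env_eff <- stats::setNames(stats::rnorm(length(envs), 0, sqrt(env_var)), envs)
  blk_eff <- stats::setNames(stats::rnorm(length(blocks), 0, sqrt(block_var)),
                             as.character(blocks))
  be_key <- unique(paste(skeleton$env, skeleton$block, sep = ":"))
  be_eff <- stats::setNames(stats::rnorm(length(be_key), 0, sqrt(block_env_var)), be_key)
  rep_key <- unique(stats::na.omit(paste(skeleton$env, skeleton$rep, sep = ":")[!is.na(skeleton$rep)]))
  rep_eff <- stats::setNames(stats::rnorm(length(rep_key), 0, sqrt(rep_var)), rep_key)
  ge_key <- unique(paste(skeleton$line, skeleton$env, sep = ":"))
  ge_eff <- stats::setNames(stats::rnorm(length(ge_key), 0, sqrt(arch$gei_var)), ge_key)

  v <- mu + bv[skeleton$line] + env_eff[skeleton$env] +
    ge_eff[paste(skeleton$line, skeleton$env, sep = ":")] +
    stats::rnorm(nrow(skeleton), 0, sqrt(resid_var))
  hasb <- !is.na(skeleton$block)
  v[hasb] <- v[hasb] + blk_eff[as.character(skeleton$block[hasb])] +
    be_eff[paste(skeleton$env, skeleton$block, sep = ":")[hasb]]
  hasr <- !is.na(skeleton$rep)
  v[hasr] <- v[hasr] + rep_eff[paste(skeleton$env, skeleton$rep, sep = ":")[hasr]]
  # single-environment layouts: environment effect is absorbed by the mean
  if (length(envs) == 1) v <- v - env_eff[[1]]
  out <- skeleton
  out$value <- unname(v)
  out
}
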