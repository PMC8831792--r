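#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]. Can be
#' loaded from a YAML file via `pipeline_config(yaml = "config.yml")`.
#' Defaults emulate a diversity-panel study: a structured panel scored in
#' unreplicated augmented trials over several years for the focal trait,
#' plus a replicated secondary trait, and a related validation population
#' scored in one year.
#'
#' @param out_dir output directory for result tables and the manifest.
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param n_lines,n_lines_val panel / validation population sizes.
#' @param n_checks,n_blocks augmented-design checks and blocks.
#' @param n_env number of environments (years) for the focal trait.
#' @param n_chrom,markers_per_chrom,n_subpops,divergence,within_block_r2
#'   genotype simulation parameters (see [genome_sim_config()]).
#' @param n_qtl number of small-effect QTL; a high-LD large-effect cluster
#'   is added on top.
#' @param h2,rg,gei_var focal-trait heritability, genetic correlation with
#'   the secondary trait, and GEI variance.
#' @param engines,covariate_sets GWAS engines and covariate sets crossed
#'   with every trial combination.
#' @param alpha,threshold significance level and method for ST-GWAS.
#' @param yaml optional YAML file; fields there override the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("augwas_run_"), seed = 1L,
                            n_lines = 200, n_lines_val = 100, n_checks = 5,
                            n_blocks = 4, n_env = 4, n_chrom = 7,
                            markers_per_chrom = 100, n_subpops = 4,
                            divergence = 0.15, within_block_r2 = 0.7,
                            n_qtl = 20, h2 = 0.7, rg = 0.4, gei_var = 20,
                            engines = c("MLM", "FarmCPU", "BLINK"),
                            covariate_sets = c("none", "rht", "coleoptile",
                                               "both"),
                            alpha = 0.05, threshold = "BH", yaml = NULL) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg[names(over)] <- over
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated study data
#'
#' Executes, in order: genotype simulation and QC; trait-pair simulation;
#' augmented-trial layout and plot phenotypes per environment (plus a
#' replicated secondary-trait trial); ACBD adjusted means per trial
#' combination; REML heritability and CV per trial; genomic relationship,
#' genetic and phenotypic correlations; single-trait GWAS over every
#' engine x covariate-set x trial combination; multi-trait joint tests;
#' and marker consistency / LD binning / pyramiding, with a validation
#' population scanned without covariates. All result tables are written to
#' `config$out_dir` together with a `manifest.json` recording seeds,
#' package version, configuration and per-stage completion.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return the manifest, invisibly; results are in `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "augwas",
                   version = as.character(utils::packageVersion("augwas")),
                   seed = config$seed, config = unclass(config),
                   stages = character(0), files = character(0))
  emit <- function(df, name) {
    f <- file.path(config$out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files <<- c(manifest$files, name)
  }
  done <- function(stage) manifest$stages <<- c(manifest$stages, stage)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }

  res <- tryCatch({
    ## --- simulate + QC ---------------------------------------------------
    gcfg <- genome_sim_config(
      n_lines = config$n_lines + config$n_lines_val + config$n_checks,
      n_chrom = config$n_chrom, markers_per_chrom = config$markers_per_chrom,
      within_block_r2 = config$within_block_r2, n_subpops = config$n_subpops,
      divergence = config$divergence, seed = config$seed
    )
    geno_all <- simulate_genotypes(gcfg)
    qc <- qc_filter(geno_all)
    geno_all <- qc$geno
    emit(qc$report, "qc_report.tsv")
    all_lines <- rownames(geno_all$X)
    checks <- all_lines[seq_len(config$n_checks)]
    dp_lines <- all_lines[config$n_checks + seq_len(config$n_lines)]
    bl_lines <- setdiff(all_lines, c(checks, dp_lines))
    done("simulate_qc")

    ## --- trait architecture ----------------------------------------------
    set.seed(config$seed + 1L)
    blocks <- split(seq_len(ncol(geno_all$X)),
                    paste(geno_all$map$chrom,
                          cumsum(!duplicated(geno_all$map$chrom))))
    big <- sample(which(maf(geno_all) > 0.15), 1)
    major <- colnames(geno_all$X)[
      which(geno_all$map$chrom == geno_all$map$chrom[big] &
              abs(geno_all$map$pos - geno_all$map$pos[big]) < 5e6)]
    small <- sample(setdiff(colnames(geno_all$X), major), config$n_qtl)
    qtl <- c(major, small)
    eff <- c(rep(8, length(major)), stats::rnorm(length(small), 0, 2))
    arch <- trait_architecture(
      qtl_ids = qtl, qtl_effects = eff, major_locus_block = major,
      h2_target = config$h2, n_env = config$n_env, gei_var = config$gei_var,
      rg_secondary = config$rg, shared_qtl_ids = small,
      rht_effect = c(`1` = 4, `2` = -4, `3` = 2, `4` = -2, `5` = -3,
                     `6` = 3, `7` = 0)
    )
    truth <- simulate_trait_pair(geno_all, arch, seed = config$seed + 2L)
    done("architecture")

    ## --- trials and adjusted means ---------------------------------------
    skel <- layout_augmented_design(dp_lines, config$n_blocks, checks,
                                    n_env = config$n_env,
                                    seed = config$seed + 3L)
    trial <- simulate_plot_phenotypes(skel, truth, arch, trait = "trait_a",
                                      seed = config$seed + 4L)
    skel_bl <- layout_augmented_design(bl_lines, config$n_blocks, checks,
                                       n_env = 1, seed = config$seed + 5L)
    trial_bl <- simulate_plot_phenotypes(skel_bl, truth, arch,
                                         trait = "trait_a",
                                         seed = config$seed + 6L)
    repskel <- layout_replicated_design(dp_lines, n_env = 2, n_rep = 2)
    trial_cl <- simulate_plot_phenotypes(repskel, truth, arch,
                                         trait = "trait_b", mu = 80,
                                         seed = config$seed + 7L)
    envs <- unique(trial$env)
    trials <- c(as.list(envs),
                lapply(2:length(envs), function(k) envs[seq_len(k)]))
    names(trials) <- vapply(trials, function(e)
      paste(e, collapse = "-"), "")
    adjusted <- lapply(trials, function(e) {
      tt <- trial[trial$env %in% e, , drop = FALSE]
      acbd_adjust(tt, scope = if (length(e) > 1) "all" else "env")
    })
    adj_bl <- acbd_adjust(trial_bl, scope = "env")
    adj_cl <- adjust_replicated(trial_cl)
    for (nm in names(adjusted)) emit(adjusted[[nm]],
                                     paste0("adjusted_", nm, ".tsv"))
    emit(adj_cl, "adjusted_secondary.tsv")
    done("adjust")

    ## --- heritability per trial ------------------------------------------
    h2tab <- do.call(rbind, lapply(names(trials), function(nm) {
      tt <- trial[trial$env %in% trials[[nm]], , drop = FALSE]
      sp <- acbd_blup_spec(tt)
      ft <- reml_fit(sp)
      h <- cullis_h2(ft)
      data.frame(trial = nm, heritability = h$H2,
                 cv = 100 * sqrt(ft$vc[["residual"]]) / mean(tt$value),
                 max = max(tt$value), mean = mean(tt$value),
                 min = min(tt$value), sd = stats::sd(tt$value))
    }))
    emit(h2tab, "heritability.tsv")
    done("heritability")

    ## --- correlations -----------------------------------------------------
    # markers can be monomorphic within a population subset: re-filter per pop
    geno_dp <- qc_filter(subset_geno(geno_all, lines = dp_lines))$geno
    grm <- compute_grm(geno_dp)
    pcs <- compute_pcs_and_clusters(geno_dp, n_pcs = 3)$pcs
    yB <- stats::setNames(adj_cl$value, adj_cl$line)[dp_lines]
    cortab <- do.call(rbind, lapply(names(adjusted), function(nm) {
      yA <- with(adjusted[[nm]], stats::setNames(value, line))[dp_lines]
      bf <- fit_bivariate(yA, yB, grm, pcs = pcs)
      pc <- phenotypic_corr(yA, yB)
      data.frame(trial = nm, genetic_r = genetic_corr(bf),
                 phenotypic_r = pc$r, phenotypic_p = pc$p)
    }))
    emit(cortab, "correlations.tsv")
    done("correlations")

    ## --- single-trait GWAS grid ------------------------------------------
    rht_codes <- stats::setNames(truth$rht$rht_code, truth$rht$line)
    n_files <- 0L
    st_results <- list()
    for (nm in names(adjusted)) {
      yA <- with(adjusted[[nm]], stats::setNames(value, line))[dp_lines]
      for (cs in config$covariate_sets) {
        cov <- build_covariates(cs, rht = rht_codes, coleoptile = yB,
                                lines = dp_lines)
        if (ncol(cov) == 0) cov <- NULL
        for (eng in config$engines) {
          r <- switch(eng,
            MLM = mlm_scan(yA, geno_dp, grm, covariates = cov,
                           threshold = config$threshold,
                           alpha = config$alpha, trial = nm),
            FarmCPU = farmcpu_scan(yA, geno_dp, covariates = cov,
                                   threshold = config$threshold,
                                   alpha = config$alpha, trial = nm),
            BLINK = blink_scan(yA, geno_dp, covariates = cov,
                               threshold = config$threshold,
                               alpha = config$alpha, trial = nm))
          r$population <- "DP"
          r$covset <- cs
          fn <- sprintf("gwas_DP_%s_%s_%s.tsv", nm, cs, eng)
          emit(r, fn)
          n_files <- n_files + 1L
          st_results[[fn]] <- r
        }
      }
    }
    geno_bl <- qc_filter(subset_geno(geno_all, lines = bl_lines))$geno
    grm_bl <- compute_grm(geno_bl)
    yBL <- with(adj_bl, stats::setNames(value, line))[bl_lines]
    for (eng in config$engines) {
      r <- switch(eng,
        MLM = mlm_scan(yBL, geno_bl, grm_bl, threshold = config$threshold,
                       alpha = config$alpha, trial = "val"),
        FarmCPU = farmcpu_scan(yBL, geno_bl, threshold = config$threshold,
                               alpha = config$alpha, trial = "val"),
        BLINK = blink_scan(yBL, geno_bl, threshold = config$threshold,
                           alpha = config$alpha, trial = "val"))
      r$population <- "BL"
      r$covset <- "none"
      fn <- sprintf("gwas_BL_val_none_%s.tsv", eng)
      emit(r, fn)
      st_results[[fn]] <- r
    }
    manifest$n_st_gwas_datasets <- length(trials) * length(config$covariate_sets)
    manifest$n_st_gwas_files <- n_files
    done("st_gwas")

    ## --- multi-trait GWAS -------------------------------------------------
    nm_all <- names(trials)[length(trials)]
    yA <- with(adjusted[[nm_all]], stats::setNames(value, line))[dp_lines]
    bf <- fit_bivariate(yA, yB, grm, pcs = pcs)
    V <- mtmm_v_matrix(bf, grm, dp_lines)
    mt <- mtmm_tests(yA, yB, V, geno_dp, pcs = pcs, alpha = config$alpha)
    emit(mt, "mtgwas.tsv")
    done("mt_gwas")

    ## --- post-GWAS --------------------------------------------------------
    cons <- consistent_markers(st_results)
    emit(cons, "consistent_markers.tsv")
    sig <- cons$marker[cons$consistent]
    if (length(sig) >= 1) {
      ld <- ld_matrix(geno_dp, sig)
      effs <- marker_effect_r2(yA, geno_dp, sig)
      bins <- bin_consistent_markers(
        sig, ld$r2, stats::setNames(effs$effect, effs$marker),
        positions = stats::setNames(
          geno_dp$map$pos[match(sig, geno_dp$map$marker)], sig))
      fav <- stats::setNames(effs$favorable_allele, effs$marker)
      pyr <- pyramiding_analysis(geno_dp, bins, yA,
                                 favorable = fav[vapply(bins, `[[`, "",
                                                        "representative")])
      emit(pyr$groups, "pyramiding_groups.tsv")
      emit(data.frame(bin = seq_along(bins),
                      representative = vapply(bins, `[[`, "", "representative"),
                      members = vapply(bins, function(b)
                        paste(b$members, collapse = ","), "")),
           "marker_bins.tsv")
      manifest$pyramiding_total_r2 <- pyr$total_r2
    }
    done("post_gwas")
    finish()
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    finish()
  })
  res
}
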