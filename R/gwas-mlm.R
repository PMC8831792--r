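#' Single-locus mixed-model GWAS scan
#'
#' Per-marker test of `y = covariates + marker + u + e` with polygenic
#' effect `u ~ N(0, K s2_g)`. By default uses P3D: the variance ratio is
#' estimated once under the marker-free null via the spectral decomposition
#' of K, then every marker is tested by generalized least squares on the
#' whitened data (Wald/F test, 1 df). `method = "exact"` re-estimates the
#' variance components for every marker (slow; used as an oracle).
#'
#' @param y named phenotype vector (adjusted means).
#' @param geno a [geno_matrix()] (no missing dosages).
#' @param grm a [compute_grm()] result (or `NULL` for K = identity, which
#'   reduces the scan to ordinary least squares).
#' @param n_pcs number of genotype principal components fitted as fixed
#'   covariates (default 3).
#' @param covariates optional extra covariate matrix (rows named by line),
#'   e.g. from [build_covariates()].
#' @param method `"p3d"` or `"exact"`.
#' @param threshold `"BH"` or `"bonferroni"`; `alpha` its level.
#' @param trial label stored in the result table.
#' @param alpha significance level.
#' @return a `gwas_result` data frame (one row per marker: `marker`,
#'   `chrom`, `pos`, `p`, `effect` per minor-allele copy, `maf`, `r2`,
#'   `significant`), with the threshold stored in attributes.
#' @export
mlm_scan <- function(y, geno, grm = NULL, n_pcs = 3, covariates = NULL,
                     method = c("p3d", "exact"), threshold = "BH",
                     alpha = 0.05, trial = "trial") {
  method <- match.arg(method)
  ids <- intersect(names(y), rownames(geno$X))
  if (length(ids) < 10) stop("too few lines shared between phenotype and genotypes")
  yy <- y[ids]
  G <- geno$X[ids, , drop = FALSE]
  W <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  if (n_pcs > 0) {
    pcs <- compute_pcs_and_clusters(geno_matrix(G, geno$map), n_pcs = n_pcs)$pcs
    W <- cbind(W, pcs)
  }
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates)[ids, , drop = FALSE])
  if (qr(W)$rank < ncol(W)) {
    stop("singular covariate matrix; collinear columns: ",
         paste(colnames(W), collapse = ", "))
  }
  K <- if (is.null(grm)) diag(length(ids)) else grm$K[ids, ids]
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, yy))
  Ws <- crossprod(U, W)
  Gs <- crossprod(U, G)

  if (method == "p3d") {
    nul <- univariate_eigen_reml(ys, d, Ws)
    w <- nul$s2g * d + nul$s2e
    stat <- whitened_scan(ys, Ws, Gs, w)
  } else {
    n <- length(ys)
    stat <- list(p = numeric(ncol(Gs)), beta = numeric(ncol(Gs)),
                 r2 = numeric(ncol(Gs)))
    for (j in seq_len(ncol(Gs))) {
      fitj <- univariate_eigen_reml(ys, d, cbind(Ws, Gs[, j]))
      w <- fitj$s2g * d + fitj$s2e
      sj <- whitened_scan(ys, Ws, Gs[, j, drop = FALSE], w)
      stat$p[j] <- sj$p; stat$beta[j] <- sj$beta; stat$r2[j] <- sj$r2
    }
  }
  gwas_result_table(subset_geno(geno, lines = ids), ids, stat$p, stat$beta,
                    stat$r2, "MLM", trial = trial,
                    threshold = threshold, alpha = alpha)
}

# GLS 1-df marker tests on spectrally whitened data: divide by sqrt(w),
# project out W, then per-marker simple regression (vectorized)
whitened_scan <- function(ys, Ws, Gs, w) {
  sw <- 1 / sqrt(w)
  yw <- ys * sw
  Ww <- Ws * sw
  Gw <- Gs * sw
  qrW <- qr(Ww)
  ry <- qr.resid(qrW, yw)
  rG <- qr.resid(qrW, Gw)
  sxx <- colSums(rG^2)
  sxy <- colSums(rG * ry)
  syy <- sum(ry^2)
  df <- length(yw) - qrW$rank - 1
  beta <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  rss <- syy - beta * sxy
  fstat <- ifelse(sxx > 1e-12, (syy - rss) / (rss / df), 0)
  p <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  p[sxx <= 1e-12] <- 1
  r2 <- ifelse(sxx > 1e-12, (syy - rss) / syy, 0)
  list(p = as.numeric(p), beta = as.numeric(beta), r2 = as.numeric(r2))
}

#' Genomic inflation factor
#'
#' Median chi-squared (1 df) statistic implied by the p-values divided by
#' the null median, `qchisq(0.5, 1)`.
#'
#' @param pvals vector of GWAS p-values.
#' @return lambda-GC.
#' @export
genomic_inflation <- function(pvals) {
  stats::median(stats::qchisq(pvals, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
}
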