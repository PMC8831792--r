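#' Phenotypic variance-covariance matrix for the two-trait model
#'
#' Assembles the stacked 2n x 2n covariance of `(yA, yB)` from a bivariate
#' fit: `V = [K sgA + I seA, K sgAB + I seAB; ..., K sgB + I seB]`.
#'
#' @param fit a `bivariate_fit` from [fit_bivariate()].
#' @param grm the [compute_grm()] result used in the fit.
#' @param lines line ids (order defines the stacking; both traits observed).
#' @return dense 2n x 2n matrix.
#' @export
mtmm_v_matrix <- function(fit, grm, lines) {
  K <- grm$K[lines, lines]
  n <- length(lines)
  I <- diag(n)
  rbind(
    cbind(fit$Sg[1, 1] * K + fit$Se[1, 1] * I,
          fit$Sg[1, 2] * K + fit$Se[1, 2] * I),
    cbind(fit$Sg[1, 2] * K + fit$Se[1, 2] * I,
          fit$Sg[2, 2] * K + fit$Se[2, 2] * I)
  )
}

#' Per-marker GLS effect estimates for two traits
#'
#' Solves the generalized least-squares normal equations
#' `b = (X' V^- X)^- X' V^- y` for each marker, where the marker's design
#' holds its dosage column once per trait (plus per-trait intercepts and
#' optional covariates). `V` is the marker-free phenotypic covariance,
#' estimated once and reused for all markers.
#'
#' @param yA,yB named phenotype vectors (same line set).
#' @param V 2n x 2n phenotypic covariance (see [mtmm_v_matrix()]); a
#'   singular `V` is handled with a generalized inverse via its
#'   eigendecomposition (flagged with a warning).
#' @param geno a [geno_matrix()].
#' @param pcs optional per-trait fixed covariates (rows named by line).
#' @return data frame: `marker`, `effect_a`, `effect_b` (per minor-allele
#'   copy). Zero-variance markers are excluded with a warning.
#' @export
gls_marker_effects <- function(yA, yB, V, geno, pcs = NULL) {
  mt <- mtmm_whiten(yA, yB, V, geno, pcs)
  keep <- mt$sd > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance marker(s) excluded")
  }
  sxx <- cbind(colSums(mt$rA^2), colSums(mt$rA * mt$rB), colSums(mt$rB^2))
  sxy <- cbind(colSums(mt$rA * mt$ry), colSums(mt$rB * mt$ry))
  det2 <- sxx[, 1] * sxx[, 3] - sxx[, 2]^2
  bA <- (sxx[, 3] * sxy[, 1] - sxx[, 2] * sxy[, 2]) / det2
  bB <- (sxx[, 1] * sxy[, 2] - sxx[, 2] * sxy[, 1]) / det2
  data.frame(marker = colnames(mt$G)[keep], effect_a = bA[keep],
             effect_b = bB[keep], stringsAsFactors = FALSE)
}

#' Multi-trait joint F-tests (FULL / IE / COM)
#'
#' On V-whitened stacked data, tests each marker with three nested GLS
#' F-tests: FULL compares the model with trait-specific marker effects
#' (2 numerator df) against the no-marker null; COM compares a single
#' common marker effect (1 df) against the null; IE compares FULL against
#' COM (1 df), picking up trait-antagonistic (interaction) effects.
#' Per-trait marginal tests are included. Significance uses the Bonferroni
#' cutoff `alpha / m`.
#'
#' @inheritParams gls_marker_effects
#' @param alpha family-wise error level for the Bonferroni flags.
#' @return `mtmm_result` data frame: per marker, `effect_a`, `effect_b`,
#'   F statistics and p-values for `full`, `ie`, `com`, marginal `p_a`,
#'   `p_b`, and `sig_*` Bonferroni flags.
#' @export
mtmm_tests <- function(yA, yB, V, geno, pcs = NULL, alpha = 0.05) {
  mt <- mtmm_whiten(yA, yB, V, geno, pcs)
  N <- 2 * length(mt$ids)
  r0 <- mt$rank0
  ryy <- sum(mt$ry^2)
  sAA <- colSums(mt$rA^2); sBB <- colSums(mt$rB^2); sAB <- colSums(mt$rA * mt$rB)
  sAy <- colSums(mt$rA * mt$ry); sBy <- colSums(mt$rB * mt$ry)
  det2 <- pmax(sAA * sBB - sAB^2, 0)
  ok2 <- det2 > 1e-10
  bA <- ifelse(ok2, (sBB * sAy - sAB * sBy) / det2, NA)
  bB <- ifelse(ok2, (sAA * sBy - sAB * sAy) / det2, NA)
  ss_full <- ifelse(ok2, bA * sAy + bB * sBy, 0)
  # common-effect column is rA + rB
  sCC <- sAA + 2 * sAB + sBB
  sCy <- sAy + sBy
  okc <- sCC > 1e-10
  ss_com <- ifelse(okc, sCy^2 / sCC, 0)
  rss_full <- ryy - ss_full
  rss_com <- ryy - ss_com
  df_full <- N - r0 - 2
  df_com <- N - r0 - 1
  F_full <- (ss_full / 2) / (rss_full / df_full)
  F_com <- ss_com / (rss_com / df_com)
  F_ie <- pmax(ss_full - ss_com, 0) / (rss_full / df_full)
  p_full <- stats::pf(F_full, 2, df_full, lower.tail = FALSE)
  p_com <- stats::pf(F_com, 1, df_com, lower.tail = FALSE)
  p_ie <- stats::pf(F_ie, 1, df_full, lower.tail = FALSE)
  # marginal single-trait tests (1 df each)
  okA <- sAA > 1e-10; okB <- sBB > 1e-10
  fA <- ifelse(okA, (sAy^2 / sAA) / ((ryy - sAy^2 / sAA) / df_com), 0)
  fB <- ifelse(okB, (sBy^2 / sBB) / ((ryy - sBy^2 / sBB) / df_com), 0)
  p_a <- stats::pf(fA, 1, df_com, lower.tail = FALSE)
  p_b <- stats::pf(fB, 1, df_com, lower.tail = FALSE)
  m <- sum(mt$sd > 0)
  cut <- alpha / m
  res <- data.frame(
    marker = colnames(mt$G), chrom = geno$map$chrom, pos = geno$map$pos,
    effect_a = bA, effect_b = bB,
    F_full = F_full, p_full = p_full, F_ie = F_ie, p_ie = p_ie,
    F_com = F_com, p_com = p_com, p_a = p_a, p_b = p_b,
    sig_full = !is.na(p_full) & p_full <= cut,
    sig_ie = !is.na(p_ie) & p_ie <= cut,
    sig_com = !is.na(p_com) & p_com <= cut,
    stringsAsFactors = FALSE
  )
  res[mt$sd == 0, c("p_full", "p_ie", "p_com", "p_a", "p_b")] <- NA
  attr(res, "bonferroni_cutoff") <- cut
  attr(res, "alpha") <- alpha
  class(res) <- c("mtmm_result", "data.frame")
  res
}

# whiten the stacked two-trait system by the Cholesky factor of V and
# residualize marker columns on the base (per-trait intercept + covariates)
mtmm_whiten <- function(yA, yB, V, geno, pcs) {
  ids <- intersect(names(yA), names(yB))
  ids <- intersect(ids, rownames(geno$X))
  n <- length(ids)
  stopifnot(nrow(V) == 2 * n)
  y <- c(yA[ids], yB[ids])
  G <- geno$X[ids, , drop = FALSE]
  Xt <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (!is.null(pcs)) Xt <- cbind(Xt, as.matrix(pcs)[ids, , drop = FALSE])
  base <- rbind(cbind(Xt, matrix(0, n, ncol(Xt))),
                cbind(matrix(0, n, ncol(Xt)), Xt))
  Lt <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(Lt)) {
    warning("phenotypic covariance V is singular; using a generalized inverse")
    eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
    d <- pmax(eg$values, max(eg$values) * 1e-10)
    Lt <- eg$vectors %*% diag(sqrt(d))
  }
  wy <- forwardsolve(Lt, y)
  wbase <- forwardsolve(Lt, base)
  zero <- matrix(0, n, ncol(G))
  wGA <- forwardsolve(Lt, rbind(G, zero))
  wGB <- forwardsolve(Lt, rbind(zero, G))
  qb <- qr(wbase)
  list(ids = ids, G = G, sd = apply(G, 2, stats::sd),
       ry = qr.resid(qb, wy), rA = qr.resid(qb, wGA),
       rB = qr.resid(qb, wGB), rank0 = qb$rank)
}
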