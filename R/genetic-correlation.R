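#' Genomic relationship matrix
#'
#' VanRaden-style GRM: `K = W W' / (2 * sum_k p_k q_k)` with `W` the
#' column-centered dosage matrix (`X - 2p`) and `p_k`, `q_k` the two allele
#' frequencies of marker `k`, computed from the analyzed line set itself.
#'
#' @param geno a [geno_matrix()] or dosage matrix (post-QC: no monomorphic
#'   markers, no missing calls).
#' @return a `grm` object: list with `K` (lines x lines), `p` (allele
#'   frequencies), `denom`.
#' @export
compute_grm <- function(geno) {
  X <- if (inherits(geno, "geno_matrix")) geno$X else as.matrix(geno)
  if (anyNA(X)) stop("missing dosages: impute before computing the GRM")
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic markers present (run qc_filter first): ",
         paste(utils::head(colnames(X)[mono], 3), collapse = ", "))
  }
  W <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  structure(list(K = (K + t(K)) / 2, p = p, denom = denom), class = "grm")
}

#' Bivariate genomic mixed model for two traits
#'
#' REML fit of the two-trait model with genetic effects structured by a GRM
#' and trait-specific residuals:
#' `[yA; yB] = X beta + [uA; uB] + e`, `cov(u) = Sg (x) K`,
#' `cov(e) = Se (x) I`, fixed effects per trait = intercept plus the
#' supplied covariates (typically 3 genotype PCs). Lines present in both
#' traits use the fast path (rotation by the eigenvectors of K reduces the
#' likelihood to independent 2x2 blocks, maximized directly over a
#' log/atanh parameterization that keeps both covariance matrices positive
#' definite); lines missing in one trait fall back to a dense
#' average-information fit over the stacked observations.
#'
#' @param yA,yB named numeric vectors of adjusted means (names = line ids;
#'   a line may be missing from one trait).
#' @param grm a [compute_grm()] result covering all lines.
#' @param pcs optional matrix of fixed covariates (rows named by line),
#'   e.g. the first three genotype principal components.
#' @return a `bivariate_fit`: `Sg` and `Se` (2x2 genetic and residual
#'   covariance matrices), `r_G`, `r_E`, `loglik`, `converged`, `lines`.
#' @export
fit_bivariate <- function(yA, yB, grm, pcs = NULL) {
  stopifnot(inherits(grm, "grm"))
  lines <- rownames(grm$K)
  if (is.null(lines)) lines <- names(yA)
  common <- intersect(names(yA), names(yB))
  allobs <- union(names(yA), names(yB))
  if (!all(allobs %in% lines)) stop("trait lines missing from the GRM")
  Xof <- function(ids) {
    X <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
    if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs)[ids, , drop = FALSE])
    X
  }
  if (setequal(names(yA), names(yB))) {
    fit <- bivariate_eigen_fit(yA[common], yB[common],
                               grm$K[common, common], Xof(common))
  } else {
    fit <- bivariate_dense_fit(yA, yB, grm$K, Xof, allobs)
  }
  fit$lines <- allobs
  class(fit) <- "bivariate_fit"
  fit
}

bivariate_eigen_fit <- function(yA, yB, K, X) {
  n <- length(yA)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  ya <- drop(crossprod(U, yA)); yb <- drop(crossprod(U, yB))
  Xs <- crossprod(U, X)
  p <- ncol(X)
  negll <- function(par) {
    Sg <- par_to_cov(par[1:3]); Se <- par_to_cov(par[4:6])
    # per-eigenvalue 2x2 blocks C_i = d_i Sg + Se, all handled vectorized
    c11 <- d * Sg[1, 1] + Se[1, 1]
    c22 <- d * Sg[2, 2] + Se[2, 2]
    c12 <- d * Sg[1, 2] + Se[1, 2]
    det_i <- c11 * c22 - c12^2
    if (any(!is.finite(det_i)) || any(det_i <= 1e-300)) return(1e10)
    a <- c22 / det_i; cc <- c11 / det_i; b2 <- -c12 / det_i
    M <- rbind(cbind(crossprod(Xs, Xs * a), crossprod(Xs, Xs * b2)),
               cbind(crossprod(Xs, Xs * b2), crossprod(Xs, Xs * cc)))
    b <- c(crossprod(Xs, a * ya + b2 * yb), crossprod(Xs, b2 * ya + cc * yb))
    quad <- sum(a * ya^2 + 2 * b2 * ya * yb + cc * yb^2)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(1e10)
    beta <- backsolve(cM, forwardsolve(t(cM), b))
    0.5 * (sum(log(det_i)) + 2 * sum(log(diag(cM))) + quad - sum(b * beta))
  }
  va <- stats::var(yA); vb <- stats::var(yB)
  r0 <- min(max(stats::cor(yA, yB), -0.9), 0.9)
  start <- c(log(va / 2), log(vb / 2), atanh(r0),
             log(va / 2), log(vb / 2), atanh(r0 / 2))
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-10))
  Sg <- par_to_cov(opt$par[1:3]); Se <- par_to_cov(opt$par[4:6])
  rg <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
  re <- Se[1, 2] / sqrt(Se[1, 1] * Se[2, 2])
  if (abs(rg) > 0.995 && abs(re) > 0.995) {
    # traits are (near-)collinear: the bivariate likelihood is unbounded at
    # |rho| = 1 and unidentifiable; return its limit, the univariate fits
    ua <- univariate_eigen_reml(ya, d, Xs)
    ub <- univariate_eigen_reml(yb, d, Xs)
    s <- sign(rg)
    Sg <- matrix(c(ua$s2g, s * sqrt(ua$s2g * ub$s2g),
                   s * sqrt(ua$s2g * ub$s2g), ub$s2g), 2)
    Se <- matrix(c(ua$s2e, s * sqrt(ua$s2e * ub$s2e),
                   s * sqrt(ua$s2e * ub$s2e), ub$s2e), 2)
    rg <- s; re <- s
  }
  dimnames(Sg) <- dimnames(Se) <- list(c("A", "B"), c("A", "B"))
  list(Sg = Sg, Se = Se, r_G = rg, r_E = re,
       loglik = -opt$value, converged = opt$convergence == 0)
}

# single-trait REML on eigen-rotated data (1x1 blocks), used for the
# collinear-trait limit and by the single-locus scan's null fit
univariate_eigen_reml <- function(ys, d, Xs) {
  negll <- function(par) {
    w <- exp(par[1]) * d + exp(par[2])
    if (any(!is.finite(w)) || any(w <= 0)) return(1e10)
    M <- crossprod(Xs, Xs / w)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(1e10)
    b <- crossprod(Xs, ys / w)
    beta <- backsolve(cM, forwardsolve(t(cM), b))
    0.5 * (sum(log(w)) + 2 * sum(log(diag(cM))) +
             sum(ys^2 / w) - sum(b * beta))
  }
  v <- stats::var(ys)
  opt <- stats::optim(log(c(v / 2, v / 2)), negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(s2g = exp(opt$par[1]), s2e = exp(opt$par[2]), loglik = -opt$value,
       converged = opt$convergence == 0)
}

par_to_cov <- function(p3) {
  s1 <- exp(p3[1]); s2 <- exp(p3[2]); r <- tanh(min(max(p3[3], -18), 18))
  matrix(c(s1, r * sqrt(s1 * s2), r * sqrt(s1 * s2), s2), 2)
}

bivariate_dense_fit <- function(yA, yB, K, Xof, allobs) {
  idsA <- names(yA); idsB <- names(yB)
  y <- c(yA, yB)
  nA <- length(yA); nB <- length(yB); n <- nA + nB
  XA <- Xof(idsA); XB <- Xof(idsB)
  X <- rbind(cbind(XA, matrix(0, nA, ncol(XB))),
             cbind(matrix(0, nB, ncol(XA)), XB))
  ZA <- rbind(incidence(idsA, levels = allobs), matrix(0, nB, length(allobs)))
  ZB <- rbind(matrix(0, nA, length(allobs)), incidence(idsB, levels = allobs))
  Ksub <- K[allobs, allobs]
  VgA <- ZA %*% Ksub %*% t(ZA)
  VgB <- ZB %*% Ksub %*% t(ZB)
  VgAB <- ZA %*% Ksub %*% t(ZB); VgAB <- VgAB + t(VgAB)
  DA <- diag(c(rep(1, nA), rep(0, nB)))
  DB <- diag(c(rep(0, nA), rep(1, nB)))
  mAB <- matrix(0, n, n)
  ia <- match(intersect(idsA, idsB), idsA)
  ib <- nA + match(intersect(idsA, idsB), idsB)
  mAB[cbind(ia, ib)] <- 1; mAB <- mAB + t(mAB)
  vy <- stats::var(y)
  spec <- mixed_model_spec(y, X, list(
    gA = list(V = VgA), gB = list(V = VgB),
    gAB = list(V = VgAB, lower = -vy, init = 0),
    eA = list(V = DA), eB = list(V = DB),
    eAB = list(V = mAB, lower = -vy, init = 0)
  ))
  fit <- reml_varstruct(spec)
  th <- fit$vc
  Sg <- matrix(c(th["gA"], th["gAB"], th["gAB"], th["gB"]), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  Se <- matrix(c(th["eA"], th["eAB"], th["eAB"], th["eB"]), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  list(Sg = Sg, Se = Se,
       r_G = Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2]),
       r_E = Se[1, 2] / sqrt(Se[1, 1] * Se[2, 2]),
       loglik = fit$loglik, converged = fit$converged)
}

#' Genetic correlation from a bivariate fit
#'
#' `r_G = sigma_gAB / sqrt(sigma2_gA * sigma2_gB)`.
#'
#' @param fit a `bivariate_fit`.
#' @return the genetic correlation, or `NA` (with a warning) when either
#'   genetic variance is zero.
#' @export
genetic_corr <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  vA <- fit$Sg[1, 1]; vB <- fit$Sg[2, 2]
  tot <- vA + fit$Se[1, 1]
  if (vA <= 1e-6 * tot || vB <= 1e-6 * (vB + fit$Se[2, 2])) {
    warning("a genetic variance is (near) zero; genetic correlation undefined")
    return(NA_real_)
  }
  fit$Sg[1, 2] / sqrt(vA * vB)
}

#' Phenotypic Pearson correlation between two trait vectors
#'
#' @param yA,yB named numeric vectors; correlation uses lines with both
#'   traits observed.
#' @return list `r`, `p`, `n` from `stats::cor.test` on complete pairs.
#' @export
phenotypic_corr <- function(yA, yB) {
  common <- intersect(names(yA), names(yB))
  a <- yA[common]; b <- yB[common]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
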