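#' FarmCPU-style multi-locus GWAS scan
#'
#' Iterates two steps until the pseudo-QTN set is stable (or `max_iter`):
#' (1) a fixed-effect scan of every marker with the current pseudo-QTNs,
#' PCs and covariates as cofactors, excluding a pseudo-QTN from the
#' cofactors when the tested marker falls in its bin; (2) positional
#' binning of the genome at each candidate bin size, taking the best marker
#' per bin as candidate QTNs and choosing the bin size / QTN count that
#' maximizes the REML likelihood of a random-effect model whose kernel is
#' built from the candidate QTN dosages. Candidates must pass the entry
#' gate `p < p_gate` (default `0.01 / m`) so cofactors are not seeded from
#' noise.
#'
#' @inheritParams mlm_scan
#' @param bin_sizes candidate bin widths in bp.
#' @param qtn_counts candidate pseudo-QTN set sizes.
#' @param p_gate scan p-value a marker must beat to become a candidate
#'   pseudo-QTN (`NULL` for `0.01 / m`).
#' @param max_iter iteration cap; an oscillating QTN set stops here and is
#'   flagged in the `converged` attribute.
#' @return a `gwas_result` with attributes `qtn` (ordered pseudo-QTN marker
#'   ids) and `converged`.
#' @export
farmcpu_scan <- function(y, geno, n_pcs = 3, covariates = NULL,
                         bin_sizes = c(5e5, 5e6, 5e7), qtn_counts = 1:20,
                         p_gate = NULL, max_iter = 10, threshold = "BH",
                         alpha = 0.05, trial = "trial") {
  st <- multilocus_setup(y, geno, n_pcs, covariates)
  m <- ncol(st$G)
  if (is.null(p_gate)) p_gate <- 0.01 / m
  map <- geno$map
  qtn <- character(0)
  qtn_p <- numeric(0)  # pseudo-QTN p-values substituted from selection time
  bsel <- bin_sizes[2]
  converged <- FALSE
  scan <- NULL
  for (it in seq_len(max_iter)) {
    excl <- farmcpu_exclusions(map, qtn, bsel)
    scan <- cofactor_scan(st, qtn, excl)
    # a pseudo-QTN keeps the p-value of the scan that selected it: testing
    # it against collinear co-selected QTNs would otherwise null the whole
    # set and oscillate
    sub <- match(names(qtn_p), map$marker)
    scan$p[sub] <- pmin(scan$p[sub], qtn_p)
    newset <- qtn
    best_ll <- -Inf
    cand_ok <- which(scan$p < p_gate)
    if (length(cand_ok)) {
      for (b in bin_sizes) {
        key <- paste(map$chrom, map$pos %/% b)
        ord <- cand_ok[order(scan$p[cand_ok])]
        cand <- ord[!duplicated(key[ord])]
        for (t in unique(pmin(qtn_counts, length(cand)))) {
          ids_t <- map$marker[cand[seq_len(t)]]
          ll <- qtn_kernel_loglik(st$y, st$W, st$G[, ids_t, drop = FALSE])
          if (ll > best_ll) {
            best_ll <- ll; newset <- ids_t; bsel <- b
          }
        }
      }
    } else newset <- character(0)
    qtn_p <- stats::setNames(
      scan$p[match(newset, map$marker)], newset)
    if (setequal(newset, qtn)) { converged <- TRUE; qtn <- newset; break }
    qtn <- newset
  }
  excl <- farmcpu_exclusions(map, qtn, bsel)
  scan <- cofactor_scan(st, qtn, excl)
  sub <- match(names(qtn_p), map$marker)
  scan$p[sub] <- pmin(scan$p[sub], qtn_p)
  res <- gwas_result_table(subset_geno(geno, lines = st$ids), st$ids, scan$p,
                           scan$beta, scan$r2, "FarmCPU", trial = trial,
                           threshold = threshold, alpha = alpha)
  attr(res, "qtn") <- qtn
  attr(res, "converged") <- converged
  res
}

#' BLINK-style multi-locus GWAS scan
#'
#' Like [farmcpu_scan()] but replaces positional binning with an LD rule
#' and the random-model likelihood with BIC in a fixed-effect model:
#' candidate pseudo-QTNs are accepted in p-value order only if their r^2
#' with every already-accepted candidate stays below `ld_threshold`, and
#' the retained set is the p-value-ordered prefix minimizing the BIC of the
#' fixed-effect model. When testing a marker, pseudo-QTNs in LD with it
#' (r^2 >= `ld_threshold`) are dropped from the cofactors.
#'
#' @inheritParams farmcpu_scan
#' @param ld_threshold r^2 above which two markers are considered redundant.
#' @param max_qtn cap on the pseudo-QTN set size.
#' @return a `gwas_result` with attributes `qtn` and `converged`.
#' @export
blink_scan <- function(y, geno, n_pcs = 3, covariates = NULL,
                       ld_threshold = 0.7, p_gate = NULL, max_iter = 10,
                       max_qtn = 20, threshold = "BH", alpha = 0.05,
                       trial = "trial") {
  st <- multilocus_setup(y, geno, n_pcs, covariates)
  m <- ncol(st$G)
  if (is.null(p_gate)) p_gate <- 0.01 / m
  qtn <- character(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    excl <- blink_exclusions(st$G, qtn, ld_threshold)
    scan <- cofactor_scan(st, qtn, excl)
    ord <- order(scan$p)
    ord <- ord[scan$p[ord] < p_gate]
    accepted <- integer(0)
    for (j in ord) {
      if (length(accepted) >= max_qtn) break
      if (length(accepted) == 0) { accepted <- j; next }
      r2 <- stats::cor(st$G[, j], st$G[, accepted, drop = FALSE])^2
      if (all(r2 < ld_threshold, na.rm = TRUE)) accepted <- c(accepted, j)
    }
    # BIC over p-ordered prefixes of the accepted list (k = 0 allowed)
    n <- length(st$y)
    rss0 <- sum(qr.resid(qr(st$W), st$y)^2)
    bic <- n * log(rss0 / n) + ncol(st$W) * log(n)
    kbest <- 0
    for (k in seq_along(accepted)) {
      Xk <- cbind(st$W, st$G[, accepted[seq_len(k)], drop = FALSE])
      fk <- stats::lm.fit(Xk, st$y)
      bk <- n * log(sum(fk$residuals^2) / n) + fk$rank * log(n)
      if (bk < bic) { bic <- bk; kbest <- k }
    }
    newset <- colnames(st$G)[accepted[seq_len(kbest)]]
    if (setequal(newset, qtn)) { converged <- TRUE; qtn <- newset; break }
    qtn <- newset
  }
  excl <- blink_exclusions(st$G, qtn, ld_threshold)
  scan <- cofactor_scan(st, qtn, excl)
  res <- gwas_result_table(subset_geno(geno, lines = st$ids), st$ids, scan$p,
                           scan$beta, scan$r2, "BLINK", trial = trial,
                           threshold = threshold, alpha = alpha)
  attr(res, "qtn") <- qtn
  attr(res, "converged") <- converged
  res
}

# shared alignment/covariate assembly for the multi-locus engines
multilocus_setup <- function(y, geno, n_pcs, covariates) {
  ids <- intersect(names(y), rownames(geno$X))
  if (length(ids) < 10) stop("too few lines shared between phenotype and genotypes")
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
  list(ids = ids, y = unname(y[ids]), W = W, G = G)
}

# exclusion list: for each marker index, which pseudo-QTNs to drop
farmcpu_exclusions <- function(map, qtn, bin_size) {
  if (!length(qtn)) return(NULL)
  qi <- match(qtn, map$marker)
  key <- paste(map$chrom, map$pos %/% bin_size)
  lapply(seq_len(nrow(map)), function(j) qtn[key[qi] == key[j]])
}

# only the pseudo-QTN itself is dropped from its own test; markers merely
# in LD with a pseudo-QTN stay corrected by it (the LD rule governs QTN
# selection, not testing)
blink_exclusions <- function(G, qtn, ld_threshold) {
  if (!length(qtn)) return(NULL)
  lapply(colnames(G), function(mk) intersect(mk, qtn))
}

# fixed-effect scan with cofactors; markers listed in `excl` are re-tested
# against a design with the conflicting pseudo-QTNs removed
cofactor_scan <- function(st, qtn, excl = NULL) {
  W <- if (length(qtn)) cbind(st$W, st$G[, qtn, drop = FALSE]) else st$W
  W <- W[, !duplicated(colnames(W)) | colnames(W) == "", drop = FALSE]
  base <- whitened_scan(st$y, W, st$G, rep(1, length(st$y)))
  if (!is.null(excl)) {
    redo <- which(vapply(excl, length, 0L) > 0)
    for (j in redo) {
      keep <- setdiff(qtn, excl[[j]])
      Wj <- if (length(keep)) cbind(st$W, st$G[, keep, drop = FALSE]) else st$W
      sj <- whitened_scan(st$y, Wj, st$G[, j, drop = FALSE],
                          rep(1, length(st$y)))
      base$p[j] <- sj$p; base$beta[j] <- sj$beta; base$r2[j] <- sj$r2
    }
  }
  base
}

# REML log-likelihood of y = W b + u + e with kernel built from candidate
# pseudo-QTN dosages (low-rank spectral computation)
qtn_kernel_loglik <- function(y, W, Xc) {
  Xc <- scale(Xc, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0)
  pos <- sv$d^2 > 1e-10
  U <- sv$u[, pos, drop = FALSE]
  dg <- sv$d[pos]^2 / mean(sv$d[pos]^2)
  n <- length(y); t <- ncol(U)
  yU <- drop(crossprod(U, y)); WU <- crossprod(U, W)
  yy <- sum(y^2) - sum(yU^2)
  WtW <- crossprod(W) - crossprod(WU)
  Wty <- drop(crossprod(W, y)) - drop(crossprod(WU, yU))
  negll <- function(par) {
    s2g <- exp(par[1]); s2e <- exp(par[2])
    w <- s2g * dg + s2e
    M <- crossprod(WU, WU / w) + WtW / s2e
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(1e10)
    b <- drop(crossprod(WU, yU / w)) + Wty / s2e
    beta <- backsolve(cM, forwardsolve(t(cM), b))
    quad <- sum(yU^2 / w) + yy / s2e - sum(b * beta)
    0.5 * (sum(log(w)) + (n - t) * log(s2e) + 2 * sum(log(diag(cM))) + quad)
  }
  v <- stats::var(y)
  opt <- stats::optim(log(c(v / 2, v / 2)), negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  -opt$value
}
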