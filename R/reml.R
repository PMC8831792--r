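#' Specify a linear mixed model with multiple variance components
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param random named list of random terms; each term is a list with either
#'   `Z` (n x q incidence matrix) plus optional `K` (q x q symmetric PSD
#'   covariance among levels; identity when `NULL`), or a dense n x n
#'   structure matrix `V` (its coefficient is then a free covariance-type
#'   parameter; BLUPs are not produced for such terms). Optional per-term
#'   `lower` (parameter lower bound; covariance terms may set a negative
#'   one) and `init` (starting value).
#' @return a `mixed_model_spec`.
#' @export
mixed_model_spec <- function(y, X, random) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(random) >= 1)
  if (is.null(names(random)) || any(names(random) == "")) {
    names(random) <- paste0("u", seq_along(random))
  }
  for (nm in names(random)) {
    tm <- random[[nm]]
    stopifnot(is.list(tm))
    if (!is.null(tm$V)) {
      stopifnot(nrow(tm$V) == length(y), ncol(tm$V) == length(y))
    } else {
      stopifnot(nrow(tm$Z) == length(y))
      if (!is.null(tm$K)) stopifnot(nrow(tm$K) == ncol(tm$Z))
    }
  }
  if (length(y) <= qr(X)$rank) stop("need more observations than fixed effects")
  structure(list(y = y, X = X, random = random), class = "mixed_model_spec")
}

#' Incidence matrix of a factor
#'
#' @param f factor (or vector coerced to one).
#' @param levels optional explicit level set (columns).
#' @return 0/1 matrix, one column per level.
#' @export
incidence <- function(f, levels = NULL) {
  f <- if (is.null(levels)) factor(f) else factor(f, levels = levels)
  Z <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  idx <- which(!is.na(f))
  Z[cbind(idx, as.integer(f)[idx])] <- 1
  Z
}

#' REML fit by average information with safeguarded steps
#'
#' Estimates variance components of `y = X b + sum_i Z_i u_i + e`,
#' `u_i ~ N(0, K_i s2_i)`, `e ~ N(0, s2_e I)` by average-information REML.
#' Proposed AI updates that would decrease the restricted log-likelihood or
#' leave the parameter space are step-halved toward the current estimate
#' (an EM-flavored safeguard), so the accepted log-likelihood never
#' decreases. Variance components are bounded below at `1e-8` times the
#' phenotypic variance. BLUPs and their prediction-error (co)variances come
#' from the mixed-model equations at the converged components.
#'
#' @param spec a [mixed_model_spec()].
#' @param tol convergence tolerance on the restricted log-likelihood change.
#' @param max_iter maximum iterations; non-convergence is flagged, not an
#'   error.
#' @return a `mixed_model_fit`: `vc` (named variance components incl.
#'   `residual`), `beta` (fixed effects), `blup` (list of BLUP vectors),
#'   `pev` (list of PEV matrices), `loglik`, `converged`, `n`, plus the
#'   internals (`P`, `Vinv`) needed by downstream scans.
#' @export
reml_fit <- function(spec, tol = 1e-8, max_iter = 60L) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  y <- spec$y; X <- spec$X; terms <- spec$random
  n <- length(y); nt <- length(terms)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  lb <- 1e-8 * vy
  lower <- c(vapply(terms, function(tm) {
    if (is.null(tm$lower)) lb else tm$lower
  }, 0), lb)
  theta <- c(vapply(terms, function(tm) {
    if (is.null(tm$init)) vy / (nt + 1) else tm$init
  }, 0), vy / (nt + 1))  # last = residual

  dense <- vapply(terms, function(tm) !is.null(tm$V), TRUE)
  ZK <- lapply(terms, function(tm) {
    if (!is.null(tm$V)) NULL else if (is.null(tm$K)) tm$Z else tm$Z %*% tm$K
  })
  Vof <- function(th) {
    V <- diag(th[nt + 1], n)
    for (i in seq_len(nt)) {
      V <- V + th[i] * (if (dense[i]) terms[[i]]$V else
        tcrossprod(ZK[[i]], terms[[i]]$Z))
    }
    (V + t(V)) / 2
  }
  pieces <- function(th) {
    V <- Vof(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVi <- crossprod(X, Vinv)
    XtViX <- XtVi %*% X
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    XtViXinv <- chol2inv(cX)
    P <- Vinv - t(XtVi) %*% XtViXinv %*% XtVi
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cX))) +
                    sum(y * Py))
    list(Vinv = Vinv, P = P, Py = Py, ll = ll, XtViXinv = XtViXinv,
         XtVi = XtVi)
  }

  cur <- pieces(theta)
  if (is.null(cur)) stop("initial covariance matrix not positive definite")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Py <- cur$Py
    # score and AI matrix over (terms..., residual)
    ViPy <- vector("list", nt + 1)
    trPVi <- numeric(nt + 1)
    for (i in seq_len(nt)) {
      if (dense[i]) {
        trPVi[i] <- sum(cur$P * terms[[i]]$V)
        ViPy[[i]] <- terms[[i]]$V %*% Py
      } else {
        Zi <- terms[[i]]$Z
        PZ <- cur$P %*% Zi
        trPVi[i] <- sum(PZ * ZK[[i]])
        ViPy[[i]] <- ZK[[i]] %*% crossprod(Zi, Py)
      }
    }
    trPVi[nt + 1] <- sum(diag(cur$P))
    ViPy[[nt + 1]] <- Py
    score <- vapply(seq_len(nt + 1), function(i) {
      -0.5 * (trPVi[i] - sum(Py * ViPy[[i]]))
    }, 0)
    AI <- matrix(0, nt + 1, nt + 1)
    PViPy <- lapply(ViPy, function(v) cur$P %*% v)
    for (i in seq_len(nt + 1)) for (j in i:(nt + 1)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(ViPy[[i]] * PViPy[[j]])
    }
    step <- tryCatch(solve(AI + diag(1e-10, nt + 1), score),
                     error = function(e) score * theta^2 / (abs(score) * theta + 1))
    accepted <- FALSE
    fac <- 1
    for (h in seq_len(25)) {
      cand <- pmax(theta + fac * step, lower)
      np <- pieces(cand)
      if (!is.null(np) && is.finite(np$ll) && np$ll >= cur$ll - 1e-12) {
        dll <- np$ll - cur$ll
        theta <- cand; cur <- np; accepted <- TRUE
        if (dll < tol && it > 1) converged <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!accepted) { converged <- TRUE }  # no uphill step left
    if (converged) break
  }

  beta <- drop(cur$XtViXinv %*% (cur$XtVi %*% y))
  names(beta) <- colnames(X)
  blup <- pev <- vector("list", nt)
  names(blup) <- names(pev) <- names(terms)
  for (i in seq_len(nt)) {
    if (dense[i]) next
    Zi <- terms[[i]]$Z
    Ki <- terms[[i]]$K
    ZtPy <- crossprod(Zi, cur$Py)
    u <- theta[i] * (if (is.null(Ki)) ZtPy else Ki %*% ZtPy)
    ZtPZ <- crossprod(Zi, cur$P %*% Zi)
    C <- if (is.null(Ki)) {
      diag(theta[i], ncol(Zi)) - theta[i]^2 * ZtPZ
    } else {
      theta[i] * Ki - theta[i]^2 * Ki %*% ZtPZ %*% Ki
    }
    blup[[i]] <- stats::setNames(drop(u), colnames(Zi))
    pev[[i]] <- (C + t(C)) / 2
  }
  structure(list(
    vc = stats::setNames(theta, c(names(terms), "residual")),
    beta = beta, blup = blup, pev = pev, loglik = cur$ll,
    converged = converged, n = n, spec = spec
  ), class = "mixed_model_fit")
}

# internal alias used where the spec mixes Z-form and dense-V terms
reml_varstruct <- reml_fit

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("mixed_model_fit (AI-REML)\n")
  print(round(x$vc, 4))
  cat(sprintf("logLik(REML) = %.3f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Cullis heritability from a fitted genotype term
#'
#' H2 = 1 - vbar / (2 s2_g), where vbar is the mean variance of a difference
#' between two genotype BLUPs, computed over all genotype pairs from the
#' prediction-error covariance matrix. Suited to unbalanced and augmented
#' designs where the classical entry-mean formula does not apply.
#'
#' @param fit a `mixed_model_fit` containing the genotype random term.
#' @param term name of the genotype term (default `"gen"`).
#' @return a `heritability_result` list: `H2` (clipped to `[0, 1]`),
#'   `vbar_blup_diff`, `sigma2_g`.
#' @export
cullis_h2 <- function(fit, term = "gen") {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (!term %in% names(fit$pev)) stop("no PEV for term '", term, "'")
  C <- fit$pev[[term]]
  s2g <- fit$vc[[term]]
  d <- diag(C)
  q <- length(d)
  # mean over i != j of C_ii + C_jj - 2 C_ij
  vbar <- if (q > 1) {
    (2 * (q - 1) * sum(d) / (q * (q - 1))) - 2 * (sum(C) - sum(d)) / (q * (q - 1))
  } else 2 * d
  if (s2g <= 1e-7 * (s2g + fit$vc[["residual"]])) {
    warning("genotype variance is (near) zero; H2 set to 0")
    h2 <- 0
  } else {
    h2 <- min(max(1 - vbar / (2 * s2g), 0), 1)
  }
  structure(list(H2 = h2, vbar_blup_diff = vbar, sigma2_g = s2g),
            class = "heritability_result")
}

#' Likelihood-ratio tests for variance components, plus trial CV
#'
#' Each random term is dropped in turn and refit; the REML likelihood-ratio
#' statistic is referred to the boundary mixture 0.5 chi2_0 + 0.5 chi2_1.
#' A boundary estimate (statistic <= 0) gives p = 1. The trial coefficient
#' of variation is `100 * sqrt(s2_residual) / mean(y)`.
#'
#' @param spec the [mixed_model_spec()] used for `fit`.
#' @param fit the full-model `mixed_model_fit`.
#' @return data frame with `term`, `sigma2`, `lrt`, `p`; attribute `cv`.
#' @export
varcomp_tests <- function(spec, fit) {
  out <- lapply(names(spec$random), function(nm) {
    red <- spec$random[names(spec$random) != nm]
    ll0 <- if (length(red) == 0) {
      # pure fixed-effect model REML log-likelihood
      ols <- stats::lm.fit(spec$X, spec$y)
      s2 <- sum(ols$residuals^2) / (length(spec$y) - ols$rank)
      sp1 <- mixed_model_spec(spec$y, spec$X,
                              list(dummy = list(Z = matrix(0, length(spec$y), 1))))
      reml_fit(sp1)$loglik
    } else {
      reml_fit(mixed_model_spec(spec$y, spec$X, red))$loglik
    }
    stat <- max(0, 2 * (fit$loglik - ll0))
    p <- if (stat <= 1e-10) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
    data.frame(term = nm, sigma2 = fit$vc[[nm]], lrt = stat, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "cv") <- 100 * sqrt(fit$vc[["residual"]]) / mean(spec$y)
  res
}

#' Build the augmented-design BLUP model for a trial table
#'
#' Classical augmented-design BLUP model: checks fixed, entries (genotypes)
#' random; block
#' random; for multi-environment tables also environment, block-by-
#' environment, check-by-environment and genotype-by-environment random.
#'
#' @param table trial table (`line`, `env`, `block`, `is_check`, `value`).
#' @return a [mixed_model_spec()] whose genotype term is named `"gen"`.
#' @export
acbd_blup_spec <- function(table) {
  multi <- length(unique(table$env)) > 1
  y <- table$value
  checks <- sort(unique(table$line[table$is_check]))
  X <- cbind(`(Intercept)` = 1,
             incidence(ifelse(table$is_check, table$line, NA), levels = checks))
  entries <- sort(unique(table$line[!table$is_check]))
  Zg <- incidence(ifelse(table$is_check, NA, table$line), levels = entries)
  random <- list(
    block = list(Z = incidence(table$block)),
    gen = list(Z = Zg)
  )
  if (multi) {
    random$env <- list(Z = incidence(table$env))
    random$block_env <- list(Z = incidence(paste(table$block, table$env, sep = ":")))
    ce <- ifelse(table$is_check, paste(table$line, table$env, sep = ":"), NA)
    random$check_env <- list(Z = incidence(ce))
    ge <- ifelse(table$is_check, NA, paste(table$line, table$env, sep = ":"))
    random$gen_env <- list(Z = incidence(ge))
  }
  mixed_model_spec(y, X, random)
}

#' Build the replicated-trait BLUP model (genotype random)
#'
#' BLUP model for a replicated multi-environment trait: genotype,
#' environment, replicate-within-environment and genotype-by-environment
#' random (the printed source formula omits the `+` before the interaction;
#' it is treated as part of the sum).
#'
#' @param table replicated trial table.
#' @return a [mixed_model_spec()] with genotype term `"gen"`.
#' @export
replicated_blup_spec <- function(table) {
  y <- table$value
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  random <- list(gen = list(Z = incidence(table$line)))
  if (length(unique(table$env)) > 1) {
    random$env <- list(Z = incidence(table$env))
    random$gen_env <- list(Z = incidence(paste(table$line, table$env, sep = ":")))
  }
  if (length(unique(stats::na.omit(table$rep))) > 1) {
    random$rep_env <- list(Z = incidence(paste(table$env, table$rep, sep = ":")))
  }
  mixed_model_spec(y, X, random)
}
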