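#' Principal components and k-means population structure
#'
#' PCA of the centered dosage matrix plus k-means over a range of k, with
#' the elbow point of the within-cluster sum-of-squares curve chosen as the
#' number of clusters (largest perpendicular distance to the chord joining
#' the first and last WSS points).
#'
#' @param geno a [geno_matrix()] (QC'd, no missing calls).
#' @param n_pcs number of PCs to return / cluster on.
#' @param k_max largest k tried.
#' @param seed seed for k-means restarts.
#' @return list: `pcs` (lines x n_pcs, rownames = line ids), `var_share`
#'   (per-PC share of total variance), `wss` (per-k within-cluster SS),
#'   `elbow_k`, `clusters` (labels at the elbow k).
#' @export
compute_pcs_and_clusters <- function(geno, n_pcs = 3, k_max = 8, seed = 1L) {
  X <- if (inherits(geno, "geno_matrix")) geno$X else as.matrix(geno)
  if (n_pcs > nrow(X)) stop("n_pcs exceeds the number of lines")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  share <- pr$sdev^2 / sum(pr$sdev^2)
  pcs <- pr$x[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- rownames(X)
  set.seed(seed)
  space <- pr$x[, seq_len(min(10, ncol(pr$x))), drop = FALSE]
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) sum(scale(space, scale = FALSE)^2) else
      stats::kmeans(space, k, nstart = 10, iter.max = 50)$tot.withinss
  }, 0)
  # elbow: farthest point from the chord between (1, wss[1]) and (k_max, wss[k_max])
  xs <- seq_len(k_max)
  v <- c(k_max - 1, wss[k_max] - wss[1])
  v <- v / sqrt(sum(v^2))
  dist <- abs((xs - 1) * v[2] - (wss - wss[1]) * v[1])
  elbow <- xs[which.max(dist)]
  set.seed(seed)
  cl <- if (elbow == 1) rep(1L, nrow(X)) else
    stats::kmeans(space, elbow, nstart = 10, iter.max = 50)$cluster
  list(pcs = pcs, var_share = share, wss = wss, elbow_k = elbow,
       clusters = cl)
}

#' Multiple-testing threshold and significance flags
#'
#' Benjamini-Hochberg step-up FDR control or the Bonferroni family-wise
#' cutoff `alpha / m`.
#'
#' @param pvals p-values in `(0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @param alpha target FDR or family-wise error level.
#' @return list: `cutoff` (largest p-value declared significant; for BH the
#'   step-up crossing point, 0 when nothing passes), `flags` (logical),
#'   `method`, `alpha`.
#' @export
significance_threshold <- function(pvals, method = c("BH", "bonferroni"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0) stop("empty p-value vector")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  m <- length(pvals)
  if (method == "bonferroni") {
    cutoff <- alpha / m
    flags <- pvals <= cutoff
  } else {
    o <- order(pvals)
    ps <- pvals[o]
    pass <- which(ps <= alpha * seq_len(m) / m)
    if (length(pass) == 0) {
      cutoff <- 0
      flags <- rep(FALSE, m)
    } else {
      kmax <- max(pass)
      cutoff <- ps[kmax]
      flags <- pvals <= cutoff
    }
  }
  list(cutoff = cutoff, flags = flags, method = method, alpha = alpha)
}

#' Single-marker effect and variance explained by stepwise regression
#'
#' For each marker, adds it alone to the null model (intercept + optional
#' covariates) and reports the gain in R-squared and the allele-substitution
#' effect, expressed for the favorable (trait-increasing) allele.
#'
#' @param y named phenotype vector.
#' @param geno a [geno_matrix()].
#' @param markers marker ids to evaluate.
#' @param covariates optional covariate matrix (rows named by line).
#' @return data frame: `marker`, `effect` (trait units per favorable allele
#'   copy, >= 0), `favorable_allele` (`"minor"`/`"major"`), `r2` (delta
#'   R-squared over the null model), `maf`.
#' @export
marker_effect_r2 <- function(y, geno, markers, covariates = NULL) {
  ids <- intersect(names(y), rownames(geno$X))
  yy <- y[ids]
  W <- cbind(`(Intercept)` = rep(1, length(ids)))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates)[ids, , drop = FALSE])
  f0 <- stats::lm.fit(W, yy)
  rss0 <- sum(f0$residuals^2)
  tss <- sum((yy - mean(yy))^2)
  out <- lapply(markers, function(mk) {
    x <- geno$X[ids, mk]
    f1 <- stats::lm.fit(cbind(W, x), yy)
    beta <- unname(f1$coefficients[ncol(W) + 1])
    if (is.na(beta)) beta <- 0
    dr2 <- (rss0 - sum(f1$residuals^2)) / tss
    data.frame(marker = mk, effect = abs(beta),
               favorable_allele = if (beta >= 0) "minor" else "major",
               r2 = max(dr2, 0), maf = unname(maf(geno$X[ids, mk, drop = FALSE])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the GWAS covariate matrix from Rht codes and a secondary trait
#'
#' Rht-style 7-code categorical calls enter as dummy variables with code 1
#' (Rht-B1b) as the reference class; the secondary-trait values (e.g.
#' coleoptile length BLUPs) enter as a single numeric column.
#'
#' @param set one of `"none"`, `"rht"`, `"coleoptile"`, `"both"`.
#' @param rht named integer vector of codes 1-7 (names = line ids).
#' @param coleoptile named numeric vector (names = line ids).
#' @param lines line ids the matrix must cover (rows, in order).
#' @return covariate matrix (possibly zero columns), rows named by line.
#' @export
build_covariates <- function(set = c("none", "rht", "coleoptile", "both"),
                             rht = NULL, coleoptile = NULL, lines) {
  set <- match.arg(set)
  out <- matrix(numeric(0), nrow = length(lines), ncol = 0,
                dimnames = list(lines, NULL))
  if (set %in% c("rht", "both")) {
    if (is.null(rht)) stop("rht codes required for covariate set '", set, "'")
    f <- factor(rht[lines])  # levels present in this line set only
    D <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(D) <- paste0("rht", levels(f)[-1])
    rownames(D) <- lines
    out <- cbind(out, D)
  }
  if (set %in% c("coleoptile", "both")) {
    if (is.null(coleoptile)) stop("coleoptile values required for covariate set '", set, "'")
    out <- cbind(out, coleoptile = coleoptile[lines])
  }
  out
}

#' Manhattan-plot data from a scan result
#'
#' @param res a `gwas_result`.
#' @return data frame: `chrom`, `pos`, `neglog10p`, `significant`.
#' @export
manhattan_data <- function(res) {
  data.frame(chrom = res$chrom, pos = res$pos,
             neglog10p = -log10(res$p), significant = res$significant,
             stringsAsFactors = FALSE)
}

#' QQ-plot data from a scan result
#'
#' @param res a `gwas_result` (or numeric p-values).
#' @return data frame: `expected`, `observed` (-log10 scale, sorted).
#' @export
qq_data <- function(res) {
  p <- sort(if (is.data.frame(res)) res$p else res)
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p))
}

# assemble a standardized per-marker result table shared by all engines
gwas_result_table <- function(geno, ids, p, beta, r2, engine, covset = "none",
                              trial = "trial", threshold = "BH", alpha = 0.05) {
  mp <- geno$map
  mafv <- maf(subset_geno(geno, lines = ids))
  thr <- significance_threshold(p, ifelse(threshold == "bonferroni",
                                          "bonferroni", "BH"), alpha)
  res <- data.frame(
    marker = mp$marker, chrom = mp$chrom, pos = mp$pos,
    p = p, effect = beta, maf = as.numeric(mafv), r2 = r2,
    engine = engine, covset = covset, trial = trial,
    significant = thr$flags, stringsAsFactors = FALSE
  )
  attr(res, "cutoff") <- thr$cutoff
  attr(res, "threshold") <- thr$method
  attr(res, "alpha") <- alpha
  class(res) <- c("gwas_result", "data.frame")
  res
}
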