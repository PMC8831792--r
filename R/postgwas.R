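#' Pairwise LD (r^2) matrix with significance
#'
#' Squared Pearson correlation of dosage columns, with the correlation-test
#' p-value per pair. Optionally restricted to same-chromosome pairs
#' (cross-chromosome entries set to NA), matching the convention of calling
#' marker pairs "in LD" when on the same chromosome with p < 0.05.
#'
#' @param geno a [geno_matrix()].
#' @param markers marker ids (default: all).
#' @param same_chrom_only if `TRUE`, cross-chromosome pairs are NA.
#' @return list: `r2` and `p` matrices (markers x markers). Zero-variance
#'   markers give NA rows/columns.
#' @export
ld_matrix <- function(geno, markers = NULL, same_chrom_only = FALSE) {
  if (is.null(markers)) markers <- colnames(geno$X)
  miss <- setdiff(markers, colnames(geno$X))
  if (length(miss)) stop("markers not present: ", paste(miss, collapse = ", "))
  X <- geno$X[, markers, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  n <- nrow(X)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(tstat, n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  if (same_chrom_only) {
    ch <- geno$map$chrom[match(markers, geno$map$marker)]
    off <- outer(ch, ch, "!=")
    r[off] <- NA; p[off] <- NA
  }
  list(r2 = r^2, p = p)
}

#' Flag markers consistently significant across trials or populations
#'
#' A marker is consistent when it is significant in at least two trials
#' (e.g. years) of the same population, or significant in at least two
#' populations — under any model.
#'
#' @param results list of `gwas_result` tables (or data frames with
#'   `marker`, `significant` columns); each element must carry `population`
#'   and `trial` labels either as columns or via the names given in
#'   `populations`/`trials`.
#' @param populations,trials optional character vectors (one per element of
#'   `results`) labelling each result set; defaults to columns `population`
#'   (or "pop1") and the table's `trial` column.
#' @return data frame: `marker`, `n_trials` (distinct significant
#'   population:trial pairs), `n_populations`, `consistent`.
#' @export
consistent_markers <- function(results, populations = NULL, trials = NULL) {
  if (length(results) < 2) stop("need at least two result sets")
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    pop <- if (!is.null(populations)) populations[i] else
      if ("population" %in% names(r)) r$population[1] else "pop1"
    tri <- if (!is.null(trials)) trials[i] else
      if ("trial" %in% names(r)) r$trial[1] else paste0("trial", i)
    sig <- r$marker[r$significant]
    if (!length(sig)) return(NULL)
    data.frame(marker = sig, population = pop, trial = tri,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  all_m <- unique(unlist(lapply(results, function(r) r$marker)))
  if (is.null(hits)) {
    return(data.frame(marker = all_m, n_trials = 0L, n_populations = 0L,
                      consistent = FALSE, stringsAsFactors = FALSE))
  }
  per <- split(hits, hits$marker)
  out <- do.call(rbind, lapply(per, function(h) {
    npop <- length(unique(h$population))
    # max distinct trials within any one population
    ntr <- max(vapply(split(h$trial, h$population),
                      function(tt) length(unique(tt)), 0L))
    data.frame(marker = h$marker[1], n_trials = ntr, n_populations = npop,
               consistent = ntr >= 2 || npop >= 2, stringsAsFactors = FALSE)
  }))
  miss <- setdiff(all_m, out$marker)
  if (length(miss)) {
    out <- rbind(out, data.frame(marker = miss, n_trials = 0L,
                                 n_populations = 0L, consistent = FALSE,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Bin consistent markers by LD
#'
#' Single-linkage grouping: markers joined whenever pairwise r^2 is at or
#' above the threshold, taking connected components as bins. The bin
#' representative is the member with the largest absolute effect, ties
#' broken by smaller p-value and then lower position.
#'
#' @param markers marker ids to bin.
#' @param ld r^2 matrix covering `markers` (see [ld_matrix()]).
#' @param effects named effect sizes per marker.
#' @param pvals optional named p-values (tie-break).
#' @param positions optional named positions (tie-break).
#' @param threshold r^2 binning threshold (default 0.8).
#' @return list of `marker_bin` lists: `members`, `representative`.
#' @export
bin_consistent_markers <- function(markers, ld, effects, pvals = NULL,
                                   positions = NULL, threshold = 0.8) {
  if (!all(markers %in% names(effects))) stop("effects required for all markers")
  k <- length(markers)
  A <- matrix(FALSE, k, k)
  r2 <- ld[markers, markers, drop = FALSE]
  A[!is.na(r2) & r2 >= threshold] <- TRUE
  diag(A) <- TRUE
  # connected components by label propagation
  comp <- seq_len(k)
  repeat {
    new <- comp
    for (i in seq_len(k)) new[i] <- min(comp[A[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  lapply(split(seq_len(k), comp), function(idx) {
    mem <- markers[idx]
    o <- order(-abs(effects[mem]),
               if (is.null(pvals)) rep(0, length(mem)) else pvals[mem],
               if (is.null(positions)) rep(0, length(mem)) else positions[mem])
    structure(list(members = mem, representative = mem[o[1]]),
              class = "marker_bin")
  })
}

#' Favorable-allele pyramiding analysis
#'
#' Counts, per line, how many bins' representative favorable alleles it
#' carries (dosage >= 1 of the favorable allele), then summarizes the
#' phenotype by favorable-allele count and reports the total variance
#' explained by regressing the phenotype on all bin representatives
#' jointly.
#'
#' @param geno a [geno_matrix()].
#' @param bins list of `marker_bin` from [bin_consistent_markers()].
#' @param y named phenotype vector (adjusted means).
#' @param favorable named character vector (`"minor"`/`"major"`) per bin
#'   representative; default `"minor"` for all.
#' @return a `pyramid_summary` list: `per_line` (line, count), `groups`
#'   (count, n, mean), `total_r2`, `favorable_freq` (per representative).
#' @export
pyramiding_analysis <- function(geno, bins, y, favorable = NULL) {
  reps <- vapply(bins, function(b) b$representative, "")
  ids <- intersect(names(y), rownames(geno$X))
  X <- geno$X[ids, reps, drop = FALSE]
  if (is.null(favorable)) favorable <- stats::setNames(rep("minor", length(reps)), reps)
  carry <- sapply(seq_along(reps), function(j) {
    x <- X[, j]
    if (favorable[[reps[j]]] == "minor") x >= 1 else (2 - x) >= 1
  })
  carry <- matrix(carry, nrow = length(ids))
  count <- rowSums(carry)
  yy <- y[ids]
  groups <- do.call(rbind, lapply(sort(unique(count)), function(k) {
    data.frame(count = k, n = sum(count == k), mean = mean(yy[count == k]))
  }))
  fit <- stats::lm(yy ~ X)
  structure(list(
    per_line = data.frame(line = ids, count = count, stringsAsFactors = FALSE),
    groups = groups,
    total_r2 = summary(fit)$r.squared,
    favorable_freq = stats::setNames(colMeans(carry), reps)
  ), class = "pyramid_summary")
}
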