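#' Genotype matrix with marker map
#'
#' Container for biallelic SNP genotypes coded as minor-allele dosages
#' (0, 1, 2) for a set of inbred lines, together with a marker map.
#' Marker names follow the `S<chrom>_<position>` convention (1-based
#' physical positions), so the map can be reconstructed from names alone.
#'
#' @param X numeric matrix, lines x markers, values in \{0, 1, 2\} (NA allowed
#'   before imputation). Row names are line ids, column names marker ids.
#' @param map data frame with columns `marker`, `chrom`, `pos`. If `NULL`,
#'   parsed from `colnames(X)` expected as `S<chrom>_<pos>`.
#' @param subpop optional character/integer vector of subpopulation labels per
#'   line (simulation truth; used by structure-recovery checks).
#'
#' @return An object of class `geno_matrix`: a list with elements `X`, `map`
#'   and optionally `subpop`.
#' @export
geno_matrix <- function(X, map = NULL, subpop = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    stop("genotype matrix must have marker column names")
  }
  if (is.null(rownames(X))) {
    rownames(X) <- paste0("line", seq_len(nrow(X)))
  }
  if (is.null(map)) {
    map <- parse_marker_names(colnames(X))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (!identical(as.character(map$marker), colnames(X))) {
    map <- map[match(colnames(X), map$marker), , drop = FALSE]
    if (anyNA(map$marker)) stop("map does not cover all markers in X")
  }
  rownames(map) <- NULL
  bad <- X[!is.na(X) & !(X %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  out <- list(X = X, map = map)
  if (!is.null(subpop)) out$subpop <- subpop
  structure(out, class = "geno_matrix")
}

#' Parse `S<chrom>_<pos>` marker names into a map
#' @param ids character vector of marker names.
#' @return data frame with `marker`, `chrom`, `pos`.
#' @export
parse_marker_names <- function(ids) {
  m <- regmatches(ids, regexec("^S([^_]+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    stop("marker names not in S<chrom>_<pos> form: ",
         paste(utils::head(ids[!ok], 3), collapse = ", "))
  }
  data.frame(
    marker = ids,
    chrom = vapply(m, `[`, "", 2L),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers, %d chromosome(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$chrom))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$X))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param lines line ids or indices to keep (default all).
#' @param markers marker ids or indices to keep (default all).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, lines = NULL, markers = NULL) {
  X <- x$X
  if (!is.null(lines)) X <- X[lines, , drop = FALSE]
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  sp <- x$subpop
  if (!is.null(sp) && !is.null(lines)) {
    sp <- if (is.character(lines)) sp[match(lines, rownames(x$X))] else sp[lines]
  }
  geno_matrix(X, x$map[match(colnames(X), x$map$marker), , drop = FALSE],
              subpop = sp)
}

#' Minor allele frequency per marker
#'
#' @param geno a `geno_matrix` or dosage matrix.
#' @return named numeric vector of per-marker minor allele frequencies in
#'   `[0, 0.5]`, computed from non-missing calls.
#' @export
maf <- function(geno) {
  X <- if (inherits(geno, "geno_matrix")) geno$X else as.matrix(geno)
  p <- colMeans(X, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
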