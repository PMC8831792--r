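#' Read genotypes from numeric TSV, HapMap or VCF
#'
#' Numeric TSV: first column `line`, remaining columns one marker each
#' (dosages 0/1/2, empty/NA for missing). HapMap: standard 11 metadata
#' columns then diploid letter calls (`NN` missing); calls are mapped to
#' dosages of the minor allele (computed from the file itself). VCF (v4.x):
#' biallelic SNP records only — multi-allelic or indel records are skipped
#' with a message; ALT dosages are polarized to the minor allele.
#'
#' @param path file path.
#' @param format `"numeric"`, `"hapmap"` or `"vcf"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("numeric", "hapmap", "vcf")) {
  format <- match.arg(format)
  switch(format,
    numeric = {
      d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
      X <- as.matrix(d[, -1, drop = FALSE])
      rownames(X) <- d[[1]]
      storage.mode(X) <- "integer"
      geno_matrix(X)
    },
    hapmap = {
      d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
      meta <- d[, 1:11]
      calls <- as.matrix(d[, -(1:11), drop = FALSE])
      al <- strsplit(meta$alleles, "/", fixed = TRUE)
      X <- matrix(NA_integer_, ncol(calls), nrow(d),
                  dimnames = list(colnames(calls), meta[[1]]))
      for (i in seq_len(nrow(d))) {
        a1 <- al[[i]][1]; a2 <- al[[i]][2]
        cc <- calls[i, ]
        n2 <- (substr(cc, 1, 1) == a2) + (substr(cc, 2, 2) == a2)
        n2[cc %in% c("NN", "N", "", "--")] <- NA
        # polarize to the minor allele as observed in this file
        if (mean(n2, na.rm = TRUE) > 1) n2 <- 2 - n2
        X[, i] <- as.integer(n2)
      }
      geno_matrix(X, map = data.frame(marker = meta[[1]], chrom = meta$chrom,
                                      pos = meta$pos, stringsAsFactors = FALSE))
    },
    vcf = {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- vcfR::getFIX(v)
      snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
        !grepl(",", fix[, "ALT"], fixed = TRUE)
      if (any(!snp)) {
        message(sum(!snp), " non-biallelic-SNP record(s) skipped")
      }
      gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
      cnt <- function(g) {
        out <- rep(NA_integer_, length(g))
        g <- gsub("|", "/", g, fixed = TRUE)
        out[g == "0/0"] <- 0L; out[g %in% c("0/1", "1/0")] <- 1L
        out[g == "1/1"] <- 2L
        out
      }
      X <- apply(gt, 1, cnt)
      if (is.null(dim(X))) X <- matrix(X, nrow = ncol(gt))
      rownames(X) <- colnames(gt)
      id <- fix[snp, "ID"]
      noid <- is.na(id) | id == "."
      id[noid] <- paste0("S", fix[snp, "CHROM"][noid], "_", fix[snp, "POS"][noid])
      colnames(X) <- id
      flip <- colMeans(X, na.rm = TRUE) > 1
      X[, flip] <- 2L - X[, flip]
      geno_matrix(X, map = data.frame(marker = id, chrom = fix[snp, "CHROM"],
                                      pos = as.integer(fix[snp, "POS"]),
                                      stringsAsFactors = FALSE))
    }
  )
}

#' Write genotypes to numeric TSV, HapMap or minimal VCF
#'
#' Inverse of [read_genotypes()]; dosage 0 maps to the major-allele
#' homozygote. Synthetic allele letters (major `A`, minor `T`) are used,
#' since dosage matrices carry no nucleotide information.
#'
#' @param geno a [geno_matrix()].
#' @param path output file.
#' @param format `"numeric"`, `"hapmap"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("numeric", "hapmap", "vcf")) {
  format <- match.arg(format)
  X <- geno$X; mp <- geno$map
  switch(format,
    numeric = {
      d <- data.frame(line = rownames(X), X, check.names = FALSE,
                      stringsAsFactors = FALSE)
      utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    hapmap = {
      code <- c("AA", "AT", "TT")
      calls <- apply(X, 2, function(x) ifelse(is.na(x), "NN", code[x + 1]))
      d <- data.frame(
        `rs#` = mp$marker, alleles = "A/T", chrom = mp$chrom, pos = mp$pos,
        strand = "+", `assembly#` = NA, center = NA, protLSID = NA,
        assayLSID = NA, panelLSID = NA, QCcode = NA,
        t(calls), check.names = FALSE, stringsAsFactors = FALSE
      )
      utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    vcf = {
      gt <- apply(X, 2, function(x) {
        ifelse(is.na(x), "./.", c("0/0", "0/1", "1/1")[x + 1])
      })
      lines <- c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", rownames(X)), collapse = "\t"),
        vapply(seq_len(ncol(X)), function(j) {
          paste(c(mp$chrom[j], mp$pos[j], mp$marker[j], "A", "T", ".",
                  "PASS", ".", "GT", gt[, j]), collapse = "\t")
        }, "")
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}

#' Marker quality control with naive imputation
#'
#' Applies, in order: (1) remove markers with heterozygote-call rate above
#' `het_max` (inbred material); (2) remove markers with missing rate above
#' `miss_max`, monomorphic markers, and markers with MAF below `maf_min`;
#' (3) impute remaining missing calls with the marker-mean dosage rounded
#' to the nearest integer; (4) re-filter MAF below `maf_min` after
#' imputation. Counts are reported per rule relative to that stage's input.
#'
#' @param geno a [geno_matrix()].
#' @param het_max maximum heterozygous-call rate (default 0.10).
#' @param miss_max maximum missing rate (default 0.20).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list: `geno` (filtered, imputed) and `report` (a `qc_report`
#'   data frame of per-rule removals plus imputation count).
#' @export
qc_filter <- function(geno, het_max = 0.10, miss_max = 0.20, maf_min = 0.05) {
  X <- geno$X
  before <- ncol(X)
  het <- colMeans(X == 1, na.rm = TRUE)
  rm_het <- het > het_max
  X <- X[, !rm_het, drop = FALSE]
  miss <- colMeans(is.na(X))
  rm_miss <- miss > miss_max
  X <- X[, !rm_miss, drop = FALSE]
  mono <- maf(X) == 0
  X <- X[, !mono, drop = FALSE]
  rm_maf <- maf(X) < maf_min
  X <- X[, !rm_maf, drop = FALSE]
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    mm <- round(colMeans(X, na.rm = TRUE))
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mm[idx[, 2]]
  }
  rm_maf2 <- maf(X) < maf_min
  X <- X[, !rm_maf2, drop = FALSE]
  if (ncol(X) == 0) stop("all markers removed by QC")
  report <- data.frame(
    rule = c("heterozygosity", "missingness", "monomorphic", "maf",
             "maf_post_imputation"),
    removed = c(sum(rm_het), sum(rm_miss), sum(mono), sum(rm_maf),
                sum(rm_maf2)),
    stringsAsFactors = FALSE
  )
  attr(report, "before") <- before
  attr(report, "after") <- ncol(X)
  attr(report, "imputed_calls") <- n_imp
  attr(report, "imputation") <- "marker-mean dosage rounded to nearest integer"
  class(report) <- c("qc_report", "data.frame")
  sp <- geno$subpop
  list(geno = geno_matrix(X, geno$map[match(colnames(X), geno$map$marker), ],
                          subpop = sp),
       report = report)
}
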