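# SNP quality control, numeric recoding against a reference founder,
# mean imputation and map interpolation support.

# Allele counts per SNP in the RIL population (heterozygous calls contribute
# one copy of each allele; missing calls are excluded).
snp_allele_counts <- function(geno) {
  a1 <- substr(geno, 1, 1); a2 <- substr(geno, 2, 2)
  a1[a1 == "N"] <- NA; a2[a2 == "N"] <- NA
  list(a1 = matrix(a1, nrow(geno)), a2 = matrix(a2, nrow(geno)))
}

#' SNP quality control statistics and filter
#'
#' Retains SNPs with (i) missing-call rate below `max_missing`, (ii) minor
#' allele frequency in the RIL population above `min_maf`, (iii) a known map
#' position when `require_position` and (iv) complete calls in all eight
#' founders.
#'
#' @param pop a `ril_population`.
#' @param panel the founder panel (checked for complete founder calls).
#' @param max_missing maximum tolerated missing-call proportion (exclusive).
#' @param min_maf minimum minor allele frequency (exclusive).
#' @param require_position drop SNPs with unknown (`NA`) cM position.
#' @return list with `retained` (SNP names) and `stats` (per-SNP data.frame:
#'   `snp`, `chrom`, `bp`, `cM`, `missing_rate`, `maf`, `has_position`,
#'   `retained`).
#' @export
filter_snps <- function(pop, panel, max_missing = 0.05, min_maf = 0.05,
                        require_position = TRUE) {
  stopifnot(inherits(pop, "ril_population"))
  geno <- pop$geno
  if (nrow(geno) == 0L || ncol(geno) == 0L) stop("empty population")
  miss <- colMeans(geno == "NN")
  ac <- snp_allele_counts(geno)
  maf <- vapply(seq_len(ncol(geno)), function(j) {
    al <- c(ac$a1[, j], ac$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al)) return(0)
    tab <- table(al)
    if (length(tab) < 2L) return(0)
    min(tab) / sum(tab)
  }, 0)
  has_pos <- !is.na(pop$map$cM)
  founder_ok <- if (is.null(panel)) rep(TRUE, ncol(geno)) else {
    fa <- panel$alleles[, colnames(geno), drop = FALSE]
    colSums(fa == "N" | is.na(fa)) == 0L
  }
  keep <- miss < max_missing & maf > min_maf & founder_ok &
    (if (require_position) has_pos else TRUE)
  stats <- data.frame(snp = pop$map$snp, chrom = pop$map$chrom,
                      bp = pop$map$bp, cM = pop$map$cM,
                      missing_rate = miss, maf = maf,
                      has_position = has_pos, retained = keep,
                      stringsAsFactors = FALSE)
  if (!any(keep)) stop("all SNPs removed by quality control")
  list(retained = pop$map$snp[keep], stats = stats)
}

#' Subset a population (and its map) to a set of SNPs
#' @param pop a `ril_population`.
#' @param snps SNP names to keep, in map order.
#' @return the subset population.
#' @export
subset_snps <- function(pop, snps) {
  j <- match(snps, pop$map$snp)
  stopifnot(!anyNA(j))
  pop$geno <- pop$geno[, j, drop = FALSE]
  pop$map <- pop$map[j, , drop = FALSE]
  class(pop$map) <- c("genetic_map", "data.frame")
  if (!is.null(pop$mosaic)) {
    pop$mosaic$h1 <- pop$mosaic$h1[, j, drop = FALSE]
    pop$mosaic$h2 <- pop$mosaic$h2[, j, drop = FALSE]
  }
  pop
}

#' Subset a founder panel to a set of SNPs
#' @param panel a `founder_panel`.
#' @param snps SNP names to keep.
#' @return the subset panel.
#' @export
subset_panel <- function(panel, snps) {
  j <- match(snps, panel$map$snp)
  stopifnot(!anyNA(j))
  panel$alleles <- panel$alleles[, j, drop = FALSE]
  panel$map <- panel$map[j, , drop = FALSE]
  class(panel$map) <- c("genetic_map", "data.frame")
  panel
}

#' Recode genotypes as reference-founder allele dosages
#'
#' A line scores 2 at a SNP if it is homozygous for the reference founder's
#' allele, 0 if homozygous for any other allele, 1 if heterozygous (one
#' reference allele); missing calls stay `NA`.
#'
#' @param pop a `ril_population`.
#' @param panel the founder panel supplying the reference alleles.
#' @param reference name of the reference founder.
#' @return numeric N x M matrix with attribute `"reference"`.
#' @export
recode_reference <- function(pop, panel, reference = panel$founders[1L]) {
  stopifnot(reference %in% panel$founders)
  ra <- panel$alleles[reference, colnames(pop$geno), drop = TRUE]
  if (any(ra == "N" | is.na(ra)))
    stop("reference founder ", reference, " has missing calls at retained SNPs")
  a1 <- substr(pop$geno, 1, 1); a2 <- substr(pop$geno, 2, 2)
  rr <- rep(ra, each = nrow(pop$geno))
  d <- (a1 == rr) + (a2 == rr)
  d[a1 == "N" | a2 == "N"] <- NA
  out <- matrix(as.numeric(d), nrow(pop$geno), ncol(pop$geno),
                dimnames = dimnames(pop$geno))
  attr(out, "reference") <- reference
  out
}

#' Mean imputation of missing dosages
#'
#' Each missing value is replaced by its SNP's mean over non-missing lines
#' (the MNI approach); observed values are untouched, so SNP means are
#' preserved exactly.
#'
#' @param mat numeric dosage matrix from [recode_reference()].
#' @return matrix without missing values, entries in `[0, 2]`.
#' @export
impute_mni <- function(mat) {
  nmiss <- colSums(!is.na(mat))
  if (any(nmiss == 0L))
    stop("fully missing SNP column(s): ",
         paste(utils::head(colnames(mat)[nmiss == 0L], 5), collapse = ", "))
  mns <- colMeans(mat, na.rm = TRUE)
  idx <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(idx)) mat[idx] <- mns[idx[, 2L]]
  mat
}
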