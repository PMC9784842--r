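# Plain-text interchange: genotype matrices, maps and phenotype tables as
# TSV, plus a minimal GT-only VCF writer (reading VCF goes through vcfR).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a genetic map as TSV
#' @param map a [genetic_map()].
#' @param path file path.
#' @export
write_map_tsv <- function(map, path) write_tsv(as.data.frame(map), path)

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  d <- read_tsv(path)
  genetic_map(d$snp, d$chrom, d$bp, d$cM)
}

#' Write / read a genotype matrix as TSV
#'
#' Lines x SNPs, calls as two-letter allele pairs (`"AG"`), missing `"NN"`;
#' first column `line`.
#'
#' @param geno character genotype matrix (e.g. `pop$geno` or
#'   [panel_genotypes()]).
#' @param path file path.
#' @export
write_genotypes_tsv <- function(geno, path) {
  write_tsv(data.frame(line = rownames(geno), geno, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_genotypes_tsv
#' @param map the matching [genetic_map()] (column order is taken from it).
#' @return `read_genotypes_tsv` returns a `ril_population` without mosaic.
#' @export
read_genotypes_tsv <- function(path, map) {
  d <- read_tsv(path)
  geno <- as.matrix(d[, map$snp, drop = FALSE])
  rownames(geno) <- d$line
  structure(list(lines = d$line, geno = geno, map = map,
                 founders = NULL, mosaic = NULL, g = NA),
            class = "ril_population")
}

#' Write / read a long-format phenotype table as TSV
#' @param pheno a phenotype table.
#' @param path file path.
#' @export
write_pheno_tsv <- function(pheno, path) write_tsv(as.data.frame(pheno), path)

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  d <- read_tsv(path)
  class(d) <- c("phenotype_table", "data.frame")
  d
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Biallelic sites with REF/ALT taken from the founder panel (the first
#' founder's allele is REF); genotypes are unphased (`0/0`, `0/1`, `1/1`,
#' `./.`).
#'
#' @param pop a `ril_population`.
#' @param panel the founder panel defining REF/ALT.
#' @param path output path (uncompressed `.vcf`).
#' @export
write_vcf <- function(pop, panel, path) {
  map <- pop$map
  fa <- panel$alleles[, map$snp, drop = FALSE]
  ref <- fa[1L, ]
  alt <- vapply(seq_len(ncol(fa)), function(j) {
    o <- setdiff(unique(fa[, j]), ref[j])
    if (length(o)) o[1L] else "."
  }, "")
  M <- nrow(map); N <- length(pop$lines)
  gt <- matrix("", M, N)
  for (j in seq_len(M)) {
    x1 <- substr(pop$geno[, j], 1, 1); x2 <- substr(pop$geno[, j], 2, 2)
    c1 <- ifelse(x1 == "N", ".", ifelse(x1 == ref[j], "0", "1"))
    c2 <- ifelse(x2 == "N", ".", ifelse(x2 == ref[j], "0", "1"))
    gt[j, ] <- paste0(c1, "/", c2)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", pop$lines), collapse = "\t")), con)
  body <- cbind(map$chrom, map$bp, map$snp, ref, alt, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
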