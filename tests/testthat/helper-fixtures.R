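# Shared fixtures, built in code.

# A founder panel with hand-set alleles: 8 founders x given allele columns.
# `cols` is a list of length-8 character vectors; map positions are supplied
# or default to one chromosome with 100-kb spacing and 1 cM per 100 kb.
toy_panel <- function(cols, chrom = NULL, bp = NULL, cM = NULL,
                      founders = paste0("F0", 1:8)) {
  M <- length(cols)
  alleles <- do.call(cbind, cols)
  snp <- sprintf("S%05d", seq_len(M))
  dimnames(alleles) <- list(founders, snp)
  chrom <- chrom %||% rep("1A", M)
  bp <- bp %||% (seq_len(M) * 100000L)
  cM <- cM %||% (bp / 1e5)
  structure(list(founders = founders, alleles = alleles,
                 map = maghap::genetic_map(snp, chrom, bp, cM)),
            class = "founder_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A population built directly from explicit genotype call strings.
toy_pop <- function(geno, map, mosaic = NULL, founders = paste0("F0", 1:8)) {
  lines <- rownames(geno) %||% sprintf("L%04d", seq_len(nrow(geno)))
  rownames(geno) <- lines
  colnames(geno) <- map$snp
  structure(list(lines = lines, geno = geno, map = map, founders = founders,
                 mosaic = mosaic, g = NA), class = "ril_population")
}

# Small simulated population reused by several test files (cached per run).
.sim_cache <- new.env()
small_sim <- function() {
  if (is.null(.sim_cache$res)) {
    panel <- maghap::simulate_founders(600, diversity = 0.59, seed = 101)
    pop <- maghap::funnel_cross(panel, 200, selfing_gens = 4, seed = 102)
    hb <- maghap::build_haploblocks(panel)
    calls <- maghap::call_haplotypes(hb, pop, panel)
    ret <- maghap::filter_haplotypes(calls)
    mm <- maghap::build_marker_matrix(ret, hb, calls, pop, panel)
    .sim_cache$res <- list(panel = panel, pop = pop, hb = hb, calls = calls,
                           retained = ret, mm = mm)
  }
  .sim_cache$res
}

# Balanced phenotype fixture with known effects.
balanced_pheno <- function(n_lines = 6, e = 2, t = 2, g = NULL, seed = 1) {
  set.seed(seed)
  g <- g %||% rnorm(n_lines)
  grid <- expand.grid(line = sprintf("L%02d", seq_len(n_lines)),
                      env = paste0("E", seq_len(e)),
                      treatment = c("N0", "N1")[seq_len(t)],
                      stringsAsFactors = FALSE)
  grid$replicate <- 1L
  grid$trait <- "Y"
  grid$value <- g[match(grid$line, unique(grid$line))] +
    as.integer(factor(grid$env)) * 0.5 +
    as.integer(factor(grid$treatment)) * 2
  grid
}
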