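# Synthetic 8-way MAGIC population generator: inbred founders, funnel cross
# with map-driven recombination (Haldane, no interference), planted
# multi-allelic QTL and multi-environment / multi-treatment phenotypes.

DEFAULT_FOUNDERS <- c("F01", "F02", "F03", "F04", "F05", "F06", "F07", "F08")

#' Simulate a panel of inbred founders
#'
#' Generates eight fully inbred founders genotyped at `n_snps` biallelic SNPs
#' laid out on a synthetic genetic map.  The per-SNP minor-allele count among
#' founders is drawn so that the expected mean pairwise simple-matching
#' similarity equals `diversity` (for an elite winter wheat panel a realistic
#' value is about 0.59).
#'
#' With 8 founders the per-SNP similarity is (choose(k,2) + choose(8-k,2))/28
#' where k is the minor-allele founder count, so achievable mean similarity
#' lies in (12/28, 21/28) = (0.4286, 0.75); targets outside that open interval
#' are rejected.
#'
#' @param n_snps number of SNPs (>= 2).
#' @param map_spec data.frame with columns `chrom`, `len_bp`, `len_cM` giving
#'   chromosome sizes; SNPs are distributed proportionally to `len_cM` with
#'   uniform bp positions and cM linear in bp.  Default: four 150-cM, 750-Mb
#'   chromosomes.
#' @param diversity target mean pairwise simple-matching similarity, in
#'   (12/28, 21/28).
#' @param founders founder names (length 8).
#' @param seed integer seed; identical seeds give identical panels.
#' @return An object of class `"founder_panel"`: list with `founders`,
#'   `alleles` (8 x M single-character gamete matrix; founders are inbred so
#'   one allele per founder per SNP), and `map` (a [genetic_map()]).
#' @export
simulate_founders <- function(n_snps, map_spec = NULL, diversity = 0.59,
                              founders = DEFAULT_FOUNDERS, seed = NULL) {
  stopifnot(n_snps >= 2, length(founders) == 8L)
  if (is.null(map_spec))
    map_spec <- data.frame(chrom = c("1A", "2A", "3A", "4A"),
                           len_bp = rep(7.5e8, 4), len_cM = rep(150, 4))
  stopifnot(all(c("chrom", "len_bp", "len_cM") %in% names(map_spec)))
  if (any(map_spec$len_cM <= 0) || any(map_spec$len_bp <= 0))
    stop("degenerate map: zero-length chromosome in map_spec")
  lo <- 12 / 28; hi <- 21 / 28
  if (diversity <= lo || diversity >= hi)
    stop(sprintf(paste0("target similarity %.3f is not achievable with 8 ",
                        "founders and all SNPs polymorphic (open interval ",
                        "%.4f..%.4f)"), diversity, lo, hi))
  local_seed(seed, {
    # SNP counts per chromosome, proportional to genetic length
    nch <- nrow(map_spec)
    alloc <- diff(round(cumsum(c(0, map_spec$len_cM)) / sum(map_spec$len_cM) * n_snps))
    while (any(alloc < 1)) { # ensure every chromosome gets a marker
      i <- which.min(alloc); j <- which.max(alloc)
      alloc[i] <- alloc[i] + 1L; alloc[j] <- alloc[j] - 1L
    }
    chrom <- rep(map_spec$chrom, alloc)
    bp <- unlist(lapply(seq_len(nch), function(i)
      sort(sample.int(map_spec$len_bp[i], alloc[i]))), use.names = FALSE)
    cM <- unlist(lapply(seq_len(nch), function(i) {
      b <- bp[rep(seq_len(nch), alloc) == i]
      b / map_spec$len_bp[i] * map_spec$len_cM[i]
    }), use.names = FALSE)
    map <- genetic_map(sprintf("S%05d", seq_len(n_snps)), chrom, bp, cM)

    # mixture of minor-count k = 4 (similarity 12/28) and k = 1 (21/28)
    w <- (diversity - lo) / (hi - lo)
    k <- ifelse(stats::runif(n_snps) < w, 1L, 4L)
    nt <- c("A", "C", "G", "T")
    alleles <- matrix("", nrow = 8L, ncol = n_snps,
                      dimnames = list(founders, map$snp))
    for (j in seq_len(n_snps)) {
      ab <- sample(nt, 2L)
      carriers <- sample.int(8L, k[j])
      col <- rep(ab[1L], 8L)
      col[carriers] <- ab[2L]
      alleles[, j] <- col
    }
    structure(list(founders = founders, alleles = alleles, map = map),
              class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", length(x$founders), "inbred founders,",
      ncol(x$alleles), "SNPs on",
      length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

# One meiosis for one chromosome, at SNP resolution.
# h1, h2: integer founder labels per SNP; pos: SNP cM; len: chromosome cM span.
# Crossover count ~ Poisson(len/100) (Haldane, no interference), positions
# uniform on the cM scale.
meiosis_chrom <- function(h1, h2, pos, lo, len) {
  nco <- stats::rpois(1L, len / 100)
  start <- sample.int(2L, 1L)
  if (nco == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort.int(stats::runif(nco, min = lo, max = lo + len))
  strand <- (start - 1L + findInterval(pos, xo)) %% 2L
  out <- h1
  sw <- strand == 1L
  out[sw] <- h2[sw]
  out
}

#' Simulate an 8-way funnel cross to recombinant inbred lines
#'
#' Each line descends from one funnel ((1x2)x(3x4)) x ((5x6)x(7x8)) over the
#' founders in input order, followed by `selfing_gens` generations of selfing
#' by single-seed descent.  All meioses are independent per line (unique
#' funnels).  Crossovers follow the Haldane model: per chromosome the count is
#' Poisson with mean equal to map length in Morgans and positions are uniform
#' on the cM scale.  The true founder-of-origin mosaic of both haploid strands
#' is recorded.
#'
#' @param panel a [simulate_founders()] panel (8 founders).
#' @param n_lines number of RILs.
#' @param selfing_gens number of selfing generations g (>= 0); expected
#'   heterozygosity is (1/2)^g of the post-funnel value.
#' @param seed integer seed.
#' @return Object of class `"ril_population"`: list with `lines`, `geno`
#'   (N x M genotype calls as two-letter strings, e.g. `"AG"`, missing `"NN"`),
#'   `map`, `founders`, `mosaic` (list of two N x M integer matrices, founder
#'   index per haploid strand) and `g`.
#' @export
funnel_cross <- function(panel, n_lines, selfing_gens = 4, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (length(panel$founders) != 8L)
    stop("the funnel crossing scheme requires exactly 8 founders")
  stopifnot(n_lines >= 1, selfing_gens >= 0)
  map <- panel$map
  M <- nrow(map)
  chroms <- unique(map$chrom)
  idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  pos <- lapply(idx, function(i) map$cM[i])
  lo <- vapply(pos, min, 0); len <- vapply(pos, function(p) max(p) - min(p), 0)
  lines <- sprintf("L%04d", seq_len(n_lines))
  h1 <- matrix(0L, n_lines, M, dimnames = list(lines, map$snp))
  h2 <- h1
  local_seed(seed, {
    for (li in seq_len(n_lines)) {
      for (ci in seq_along(chroms)) {
        p <- pos[[ci]]; l0 <- lo[ci]; ln <- len[ci]; n <- length(p)
        gam <- function(a, b) meiosis_chrom(a, b, p, l0, ln)
        # four F1s, two 4-ways, one 8-way individual
        g12 <- gam(rep(1L, n), rep(2L, n)); g34 <- gam(rep(3L, n), rep(4L, n))
        g56 <- gam(rep(5L, n), rep(6L, n)); g78 <- gam(rep(7L, n), rep(8L, n))
        a1 <- gam(g12, g34); a2 <- gam(g56, g78)
        s1 <- a1; s2 <- a2
        if (selfing_gens > 0) for (gg in seq_len(selfing_gens)) {
          n1 <- gam(s1, s2); n2 <- gam(s1, s2)
          s1 <- n1; s2 <- n2
        }
        h1[li, idx[[ci]]] <- s1
        h2[li, idx[[ci]]] <- s2
      }
    }
  })
  a1 <- matrix(panel$alleles[cbind(as.vector(h1), rep(seq_len(M), each = n_lines))],
               n_lines, M)
  a2 <- matrix(panel$alleles[cbind(as.vector(h2), rep(seq_len(M), each = n_lines))],
               n_lines, M)
  geno <- matrix(paste0(pmin(a1, a2), pmax(a1, a2)), n_lines, M,
                 dimnames = list(lines, map$snp))
  structure(list(lines = lines, geno = geno, map = map,
                 founders = panel$founders,
                 mosaic = list(h1 = h1, h2 = h2), g = selfing_gens),
            class = "ril_population")
}

#' @export
print.ril_population <- function(x, ...) {
  cat("RIL population:", length(x$lines), "lines x", ncol(x$geno), "SNPs",
      sprintf("(selfing generations g = %s,%s founder mosaic)\n", x$g,
              if (is.null(x$mosaic)) " no" else ""))
  invisible(x)
}

#' Define a trait architecture for phenotype simulation
#'
#' Planted QTL carry one additive effect per founder allele; a line's QTL
#' contribution is the average of the effects of its two founder strands, so a
#' homozygous carrier of founder f's allele receives the full effect.  On top
#' of the QTL a polygenic line value with variance `V_G` is drawn, and the
#' observation model adds independent genotype-by-environment (`V_GE`),
#' genotype-by-treatment (`V_GT`), genotype-by-environment-by-treatment
#' (`V_GET`) and residual (`V_R`) deviations plus fixed environment and
#' treatment main effects.
#'
#' @param trait trait name (e.g. `"YLD"`).
#' @param qtl `NULL` or a list of `list(snp = , effects = )` entries, with
#'   `effects` a numeric vector of length 8 (per-founder allele effects, trait
#'   units).
#' @param V_G,V_GE,V_GT,V_GET,V_R non-negative variance components
#'   (trait units squared).
#' @param e,t,r numbers of environments, treatments and replicates.
#' @param mu grand mean.
#' @param env_effects fixed environment effects (length `e`; default centered
#'   draws with SD 1 scaled by `mu`'s magnitude is avoided -- default zeros).
#' @param treat_effects fixed treatment effects (length `t`); default
#'   `c(0, treat_shift)` so the second (standard-N) treatment is higher for
#'   yield-like traits.
#' @param treat_shift default shift of treatment 2 vs treatment 1.
#' @param treatments treatment labels, default `c("N0", "N1")` (`t` must match).
#' @return Object of class `"trait_architecture"`.
#' @export
trait_architecture <- function(trait = "YLD", qtl = NULL,
                               V_G = 0, V_GE = 0, V_GT = 0, V_GET = 0, V_R = 1,
                               e = 7, t = 2, r = 1, mu = 0,
                               env_effects = NULL, treat_effects = NULL,
                               treat_shift = 0,
                               treatments = if (t == 2) c("N0", "N1")
                                            else paste0("T", seq_len(t))) {
  comps <- c(V_G = V_G, V_GE = V_GE, V_GT = V_GT, V_GET = V_GET, V_R = V_R)
  if (any(comps < 0)) stop("variance components must be >= 0")
  stopifnot(e >= 1, t >= 1, r >= 1, length(treatments) == t)
  if (!is.null(qtl)) {
    stopifnot(is.list(qtl))
    for (q in qtl) {
      stopifnot(!is.null(q$snp), length(q$effects) == 8L)
    }
  }
  env_effects <- env_effects %||% rep(0, e)
  treat_effects <- treat_effects %||% c(0, rep(treat_shift, t - 1L))
  stopifnot(length(env_effects) == e, length(treat_effects) == t)
  structure(list(trait = trait, qtl = qtl, V_G = V_G, V_GE = V_GE,
                 V_GT = V_GT, V_GET = V_GET, V_R = V_R, e = e, t = t, r = r,
                 mu = mu, env_effects = env_effects,
                 treat_effects = treat_effects, treatments = treatments),
            class = "trait_architecture")
}

# True genotypic QTL contribution per line (mosaic-based when available;
# allele-based with mean imputation for missing calls otherwise).
qtl_genotypic_values <- function(pop, qtl, panel = NULL) {
  gv <- numeric(length(pop$lines))
  for (q in qtl) {
    j <- match(q$snp, pop$map$snp)
    if (is.na(j)) stop("QTL position ", q$snp, " not in the population map")
    eff <- q$effects
    if (!is.null(pop$mosaic)) {
      gv <- gv + (eff[pop$mosaic$h1[, j]] + eff[pop$mosaic$h2[, j]]) / 2
    } else {
      if (is.null(panel))
        stop("population has no founder mosaic; a founder panel is required ",
             "to evaluate QTL ", q$snp)
      g <- pop$geno[, j]
      a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
      per_allele <- function(a) {
        carr <- which(panel$alleles[, j] == a)
        if (!length(carr)) 0 else mean(eff[carr])
      }
      contrib <- (vapply(a1, per_allele, 0) + vapply(a2, per_allele, 0)) / 2
      miss <- g == "NN"
      if (any(miss)) {
        warning("missing genotype at QTL ", q$snp,
                ": using mean-imputed dosage for ", sum(miss), " lines")
        contrib[miss] <- mean(contrib[!miss])
      }
      gv <- gv + contrib
    }
  }
  gv
}

#' Simulate multi-environment, multi-treatment phenotypes
#'
#' @param pop a [funnel_cross()] population (the founder mosaic, if present,
#'   is used to evaluate planted QTL exactly).
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @param founder_panel optionally, a founder panel: founders are then
#'   phenotyped alongside the lines with `r` replicates each (lines get one
#'   replicate, as in an unreplicated multi-environment trial).
#' @return data.frame of class `"phenotype_table"` with columns
#'   `line`, `env`, `treatment`, `replicate`, `trait`, `value`.
#' @export
plant_phenotypes <- function(pop, arch, seed = NULL, founder_panel = NULL) {
  stopifnot(inherits(pop, "ril_population"),
            inherits(arch, "trait_architecture"))
  N <- length(pop$lines); e <- arch$e; t <- arch$t
  local_seed(seed, {
    gq <- if (is.null(arch$qtl)) numeric(N)
          else qtl_genotypic_values(pop, arch$qtl, founder_panel)
    gpoly <- if (arch$V_G > 0) stats::rnorm(N, 0, sqrt(arch$V_G)) else numeric(N)
    g <- gq + gpoly
    ge <- matrix(stats::rnorm(N * e, 0, sqrt(arch$V_GE)), N, e)
    gt <- matrix(stats::rnorm(N * t, 0, sqrt(arch$V_GT)), N, t)
    get <- array(stats::rnorm(N * e * t, 0, sqrt(arch$V_GET)), c(N, e, t))
    envs <- sprintf("E%02d", seq_len(e))
    grid <- expand.grid(line = seq_len(N), env = seq_len(e), tr = seq_len(t),
                        KEEP.OUT.ATTRS = FALSE)
    val <- arch$mu + arch$env_effects[grid$env] + arch$treat_effects[grid$tr] +
      g[grid$line] + ge[cbind(grid$line, grid$env)] +
      gt[cbind(grid$line, grid$tr)] + get[cbind(grid$line, grid$env, grid$tr)] +
      stats::rnorm(nrow(grid), 0, sqrt(arch$V_R))
    out <- data.frame(line = pop$lines[grid$line], env = envs[grid$env],
                      treatment = arch$treatments[grid$tr], replicate = 1L,
                      trait = arch$trait, value = val,
                      stringsAsFactors = FALSE)
    if (!is.null(founder_panel)) {
      fo <- founder_panel$founders; nf <- length(fo); r <- arch$r
      fg <- if (is.null(arch$qtl)) numeric(nf) else {
        vapply(seq_len(nf), function(i) {
          s <- 0
          for (q in arch$qtl) s <- s + q$effects[i]
          s
        }, 0)
      }
      fg <- fg + if (arch$V_G > 0) stats::rnorm(nf, 0, sqrt(arch$V_G)) else 0
      fge <- matrix(stats::rnorm(nf * e, 0, sqrt(arch$V_GE)), nf, e)
      fgt <- matrix(stats::rnorm(nf * t, 0, sqrt(arch$V_GT)), nf, t)
      fget <- array(stats::rnorm(nf * e * t, 0, sqrt(arch$V_GET)), c(nf, e, t))
      fgrid <- expand.grid(line = seq_len(nf), env = seq_len(e),
                           tr = seq_len(t), rep = seq_len(r),
                           KEEP.OUT.ATTRS = FALSE)
      fval <- arch$mu + arch$env_effects[fgrid$env] +
        arch$treat_effects[fgrid$tr] + fg[fgrid$line] +
        fge[cbind(fgrid$line, fgrid$env)] + fgt[cbind(fgrid$line, fgrid$tr)] +
        fget[cbind(fgrid$line, fgrid$env, fgrid$tr)] +
        stats::rnorm(nrow(fgrid), 0, sqrt(arch$V_R))
      out <- rbind(out, data.frame(line = fo[fgrid$line], env = envs[fgrid$env],
                                   treatment = arch$treatments[fgrid$tr],
                                   replicate = fgrid$rep, trait = arch$trait,
                                   value = fval, stringsAsFactors = FALSE))
    }
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

#' Mask genotype calls at random
#'
#' Each call is independently set to missing (`"NN"`) with probability `rate`,
#' to exercise downstream missing-call quality control.
#'
#' @param pop a `ril_population`.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the population with masked `geno` (mosaic left intact -- it is the
#'   simulation truth, not an observable).
#' @export
inject_missingness <- function(pop, rate, seed = NULL) {
  stopifnot(inherits(pop, "ril_population"), rate >= 0, rate < 1)
  if (rate == 0) return(pop)
  local_seed(seed, {
    mask <- stats::runif(length(pop$geno)) < rate
    pop$geno[mask] <- "NN"
    pop
  })
}
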