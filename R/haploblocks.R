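# LD from founder gametes, four-gamete-rule haploblock construction,
# haplotype calling in the population and 0/1 marker-matrix assembly.
#
# Because the eight founders are fully inbred, each founder contributes
# exactly one gamete, so two-locus gamete frequencies are counted directly
# over the eight founder haplotypes.

#' Pairwise linkage disequilibrium from founder gametes
#'
#' Counts the four two-locus gamete classes over the inbred founders and
#' returns `D = f(AB) - f(A) f(B)`, the normalized `D' = |D| / Dmax`, and
#' `r^2 = D^2 / (f(A) f(a) f(B) f(b))`.
#'
#' @param panel a `founder_panel`.
#' @param snp_a,snp_b SNP names or indices; both must be polymorphic in the
#'   panel.
#' @return list of class `"ld_stats"`: `D`, `Dprime`, `r2`, `gamete_freqs`
#'   (named, sums to 1).
#' @export
ld_pair <- function(panel, snp_a, snp_b) {
  ga <- panel$alleles[, snp_a]; gb <- panel$alleles[, snp_b]
  ld_from_gametes(ga, gb)
}

# Core LD computation from two aligned gamete vectors.
ld_from_gametes <- function(ga, gb) {
  ua <- sort(unique(ga)); ub <- sort(unique(gb))
  if (length(ua) < 2L || length(ub) < 2L)
    stop("monomorphic SNP in LD computation")
  if (length(ua) > 2L || length(ub) > 2L)
    stop("more than two alleles in LD computation")
  A <- ga == ua[1L]; B <- gb == ub[1L]
  n <- length(ga)
  fAB <- sum(A & B) / n
  fA <- mean(A); fB <- mean(B)
  D <- fAB - fA * fB
  Dmax <- if (D >= 0) min(fA * (1 - fB), (1 - fA) * fB)
          else min(fA * fB, (1 - fA) * (1 - fB))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (fA * (1 - fA) * fB * (1 - fB))
  gf <- c(sum(A & B), sum(A & !B), sum(!A & B), sum(!A & !B)) / n
  names(gf) <- paste0(rep(c(ua[1L], ua[2L]), each = 2L), c(ub[1L], ub[2L]))
  structure(list(D = D, Dprime = Dprime, r2 = r2, gamete_freqs = gf),
            class = "ld_stats")
}

# Does a consecutive SNP pair qualify for (extension of) a haploblock?
pair_qualifies <- function(panel, i, j, max_pair_bp, fourth_gamete_max,
                           dprime_required) {
  if (panel$map$chrom[i] != panel$map$chrom[j]) return(FALSE)
  if (abs(panel$map$bp[j] - panel$map$bp[i]) >= max_pair_bp) return(FALSE)
  ga <- panel$alleles[, i]; gb <- panel$alleles[, j]
  if (length(unique(ga)) != 2L || length(unique(gb)) != 2L) return(FALSE)
  ld <- ld_from_gametes(ga, gb)
  # four-gamete rule: at least one of the four gametes rarer than the cutoff
  if (sum(ld$gamete_freqs < fourth_gamete_max) < 1L) return(FALSE)
  ld$Dprime >= dprime_required - 1e-12
}

#' Build haploblocks by the four-gamete rule
#'
#' Greedy left-to-right scan per chromosome over map-ordered SNPs: a block is
#' started at the first qualifying adjacent pair and extended while the next
#' consecutive SNP (i) lies within `max_pair_bp` of the previous block member,
#' (ii) shows at most three of the four possible gametes at frequency
#' `>= fourth_gamete_max` against the previous member, and (iii) is in
#' complete LD (`D' >= dprime_required`) with it.  SNPs in no block are
#' returned as "singular".  The partition depends on the founder panel only.
#'
#' @param panel a `founder_panel` (SNPs should already have passed MAF QC).
#' @param max_pair_bp maximum physical distance between consecutive members
#'   (exclusive), default 500 kb.
#' @param fourth_gamete_max frequency below which a gamete class counts as
#'   unobserved, default 0.01.
#' @param dprime_required minimum D' between consecutive members, default 1.
#' @param maf_min minimum founder minor-allele frequency for a SNP to enter
#'   block construction, default 0.05 (non-qualifying SNPs become singular).
#' @return list of class `"haploblock_set"` with `blocks` (data.frame:
#'   `block`, `chrom`, `start_bp`, `end_bp`, `start_cM`, `end_cM`, `n_snps`),
#'   `members` (list of SNP-name vectors, one per block) and `singular`
#'   (SNP names in no block).
#' @export
build_haploblocks <- function(panel, max_pair_bp = 5e5,
                              fourth_gamete_max = 0.01, dprime_required = 1,
                              maf_min = 0.05) {
  map <- panel$map
  M <- nrow(map)
  maf <- vapply(seq_len(M), function(j) {
    tab <- table(panel$alleles[, j])
    if (length(tab) < 2L) 0 else min(tab) / sum(tab)
  }, 0)
  eligible <- maf > maf_min
  members <- list(); in_block <- rep(FALSE, M)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch & eligible)
    if (length(idx) < 2L) next
    cur <- idx[1L]
    for (k in seq_along(idx)[-1L]) {
      j <- idx[k]
      prev <- cur[length(cur)]
      if (pair_qualifies(panel, prev, j, max_pair_bp, fourth_gamete_max,
                         dprime_required)) {
        cur <- c(cur, j)
      } else {
        if (length(cur) >= 2L) { members[[length(members) + 1L]] <- cur
                                 in_block[cur] <- TRUE }
        cur <- j
      }
    }
    if (length(cur) >= 2L) { members[[length(members) + 1L]] <- cur
                             in_block[cur] <- TRUE }
  }
  blk_chrom <- vapply(members, function(m) map$chrom[m[1L]], "")
  ids <- make_block_ids(blk_chrom)
  blocks <- data.frame(
    block = ids,
    chrom = blk_chrom,
    start_bp = vapply(members, function(m) min(map$bp[m]), 0L),
    end_bp = vapply(members, function(m) max(map$bp[m]), 0L),
    start_cM = vapply(members, function(m) min(map$cM[m]), 0),
    end_cM = vapply(members, function(m) max(map$cM[m]), 0),
    n_snps = lengths(members), stringsAsFactors = FALSE)
  members <- lapply(members, function(m) map$snp[m])
  names(members) <- ids
  structure(list(blocks = blocks, members = members,
                 singular = map$snp[!in_block]),
            class = "haploblock_set")
}

make_block_ids <- function(chrom) {
  if (!length(chrom)) return(character(0))
  unsplit(lapply(split(seq_along(chrom), chrom), function(i)
    sprintf("Chr%s_HB%03d", chrom[i][1L], seq_along(i))), chrom)
}

#' @export
print.haploblock_set <- function(x, ...) {
  cat("Haploblock set:", nrow(x$blocks), "blocks (",
      if (nrow(x$blocks)) paste(range(x$blocks$n_snps), collapse = "-") else "0",
      "SNPs each ),", length(x$singular), "singular SNPs\n")
  invisible(x)
}

# Resolve a possibly heterozygous line genotype within a block into an
# unordered pair of haplotype strings using the founder haplotypes as the
# phasing context.  Returns c(h1, h2) or NULL if unresolvable.
resolve_block_call <- function(a1, a2, founder_hts) {
  if (any(a1 == "N") || any(a2 == "N")) return(NULL)
  het <- a1 != a2
  if (!any(het)) {
    h <- paste(a1, collapse = "")
    return(c(h, h))  # homozygous: phase trivial, recombinant strings allowed
  }
  sols <- list()
  for (p in seq_along(founder_hts)) for (q in seq_len(p)) {
    f1 <- founder_hts[[p]]; f2 <- founder_hts[[q]]
    ok <- all((f1 == a1 & f2 == a2) | (f1 == a2 & f2 == a1))
    if (ok) sols[[length(sols) + 1L]] <-
        sort(c(paste(f1, collapse = ""), paste(f2, collapse = "")))
  }
  sols <- unique(sols)
  if (length(sols) == 1L) sols[[1L]] else NULL
}

#' Call haplotypes of a population within haploblocks
#'
#' Reads each line's allele string per block from its genotype.  Homozygous
#' complete calls yield the string directly (recombinant strings absent from
#' the founders are legal and counted).  Heterozygous calls are resolved
#' against the founder haplotypes: if exactly one unordered founder-haplotype
#' pair explains the genotype the line carries both, otherwise its block call
#' is missing.  Haplotype frequency is the allele-dose frequency among
#' resolved lines, so frequencies within a block sum to 1.
#'
#' @param hb a [build_haploblocks()] result.
#' @param pop a `ril_population`.
#' @param panel the founder panel (for founder membership and phasing).
#' @return list of class `"haplotype_calls"` with `haplotypes` (data.frame:
#'   `block`, `ht_id`, `allele_string`, `freq`, `n_carriers`, `founders`
#'   (8-character 0/1 flag string)) and `assignments` (list of two
#'   N x n_blocks character matrices `h1`, `h2`; `NA` = unresolved).
#' @export
call_haplotypes <- function(hb, pop, panel) {
  nb <- nrow(hb$blocks)
  N <- length(pop$lines)
  h1 <- matrix(NA_character_, N, nb, dimnames = list(pop$lines, hb$blocks$block))
  h2 <- h1
  tabs <- vector("list", nb)
  for (b in seq_len(nb)) {
    snps <- hb$members[[b]]
    j <- match(snps, pop$map$snp)
    fj <- match(snps, panel$map$snp)
    fmat <- panel$alleles[, fj, drop = FALSE]
    founder_strings <- apply(fmat, 1L, paste, collapse = "")
    founder_hts <- lapply(seq_len(nrow(fmat)), function(i) fmat[i, ])
    uniq_f <- !duplicated(founder_strings)
    g <- pop$geno[, j, drop = FALSE]
    a1 <- matrix(substr(g, 1, 1), N); a2 <- matrix(substr(g, 2, 2), N)
    for (i in seq_len(N)) {
      r <- resolve_block_call(a1[i, ], a2[i, ], founder_hts[uniq_f])
      if (!is.null(r)) { h1[i, b] <- r[1L]; h2[i, b] <- r[2L] }
    }
    resolved <- !is.na(h1[, b])
    strings <- c(h1[resolved, b], h2[resolved, b])
    tab <- table(strings)
    alleles <- names(tab)
    carriers <- vapply(alleles, function(s)
      sum(h1[resolved, b] == s | h2[resolved, b] == s), 0L)
    fl <- vapply(alleles, function(s)
      paste(as.integer(founder_strings == s), collapse = ""), "")
    tabs[[b]] <- data.frame(
      block = hb$blocks$block[b],
      ht_id = sprintf("%s_%02d", hb$blocks$block[b], seq_along(alleles)),
      allele_string = alleles,
      freq = as.numeric(tab) / (2 * sum(resolved)),
      n_carriers = as.integer(carriers),
      founders = fl, stringsAsFactors = FALSE)
  }
  haplotypes <- if (nb) do.call(rbind, c(tabs, list(make.row.names = FALSE)))
                else data.frame(block = character(0), ht_id = character(0),
                                allele_string = character(0), freq = numeric(0),
                                n_carriers = integer(0), founders = character(0))
  structure(list(haplotypes = haplotypes,
                 assignments = list(h1 = h1, h2 = h2)),
            class = "haplotype_calls")
}

#' Filter haplotypes on frequency and completeness
#'
#' Retains haplotypes with population frequency strictly above `min_freq`
#' whose allele string contains no missing symbol.
#'
#' @param calls a [call_haplotypes()] result (or its `haplotypes` data.frame).
#' @param min_freq frequency threshold (exclusive), default 0.05.
#' @return the retained haplotype data.frame.
#' @export
filter_haplotypes <- function(calls, min_freq = 0.05) {
  ht <- if (inherits(calls, "haplotype_calls")) calls$haplotypes else calls
  ht[ht$freq > min_freq & !grepl("N", ht$allele_string, fixed = TRUE), ,
     drop = FALSE]
}

#' Assemble the 0/1 GWAS marker matrix
#'
#' One presence column per retained haplotype (1 iff the line carries it on
#' either strand) plus two columns per singular SNP, one per allele (1 iff the
#' line carries that allele; missing calls score 0 in both).  Founder
#' membership is attached to every column.  Columns are ordered by
#' chromosome, bp, then allele label.
#'
#' @param retained retained haplotype data.frame from [filter_haplotypes()].
#' @param hb the [build_haploblocks()] result (for block positions and the
#'   singular SNP set).
#' @param calls the [call_haplotypes()] result (for line assignments).
#' @param pop a `ril_population`.
#' @param panel the founder panel.
#' @return Object of class `"marker_matrix"`: list with `X` (N x K 0/1
#'   matrix) and `info` (per-column data.frame: `marker`, `type`
#'   (`"haplotype"`/`"snp_allele"`), `chrom`, `bp`, `cM`, `block`, `allele`,
#'   `founders`).
#' @export
build_marker_matrix <- function(retained, hb, calls, pop, panel) {
  N <- length(pop$lines)
  cols <- list(); info <- list()
  if (nrow(retained)) {
    bidx <- match(retained$block, hb$blocks$block)
    for (k in seq_len(nrow(retained))) {
      b <- retained$block[k]
      pres <- as.integer(!is.na(calls$assignments$h1[, b]) &
        (calls$assignments$h1[, b] == retained$allele_string[k] |
         calls$assignments$h2[, b] == retained$allele_string[k]))
      cols[[length(cols) + 1L]] <- pres
      i <- bidx[k]
      info[[length(info) + 1L]] <- data.frame(
        marker = retained$ht_id[k], type = "haplotype",
        chrom = hb$blocks$chrom[i],
        bp = as.integer(round((hb$blocks$start_bp[i] + hb$blocks$end_bp[i]) / 2)),
        cM = (hb$blocks$start_cM[i] + hb$blocks$end_cM[i]) / 2,
        block = b, allele = retained$allele_string[k],
        founders = retained$founders[k], stringsAsFactors = FALSE)
    }
  }
  for (s in hb$singular) {
    j <- match(s, pop$map$snp); fj <- match(s, panel$map$snp)
    alleles <- sort(unique(panel$alleles[, fj]))
    g <- pop$geno[, j]
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    for (a in alleles) {
      pres <- as.integer((a1 == a | a2 == a) & a1 != "N" & a2 != "N")
      cols[[length(cols) + 1L]] <- pres
      info[[length(info) + 1L]] <- data.frame(
        marker = paste0(s, "_", a), type = "snp_allele",
        chrom = pop$map$chrom[j], bp = pop$map$bp[j], cM = pop$map$cM[j],
        block = NA_character_, allele = a,
        founders = paste(as.integer(panel$alleles[, fj] == a), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cols))
    return(structure(list(X = matrix(0L, N, 0L, dimnames = list(pop$lines, NULL)),
                          info = data.frame()), class = "marker_matrix"))
  info <- do.call(rbind, c(info, list(make.row.names = FALSE)))
  X <- do.call(cbind, cols)
  ord <- order(info$chrom, info$bp, info$allele, info$marker)
  info <- info[ord, , drop = FALSE]; rownames(info) <- NULL
  X <- X[, ord, drop = FALSE]
  dimnames(X) <- list(pop$lines, info$marker)
  structure(list(X = X, info = info), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Marker matrix:", nrow(x$X), "lines x", ncol(x$X), "markers (",
      sum(x$info$type == "haplotype"), "haplotypes,",
      sum(x$info$type == "snp_allele"), "singular-SNP alleles )\n")
  invisible(x)
}
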