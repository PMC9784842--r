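# Independent oracles shared by the unit and acceptance tests.  These are
# deliberately written from first principles, not via the package's own
# code paths.

# Build an 8-founder panel realizing given gamete counts (nAB, nAb, naB, nab).
panel_from_gametes <- function(n) {
  stopifnot(sum(n) == 8L)
  a <- c(rep("A", n[1] + n[2]), rep("G", n[3] + n[4]))
  b <- c(rep("C", n[1]), rep("T", n[2]), rep("C", n[3]), rep("T", n[4]))
  toy_panel(list(a, b))
}

# LD oracle: direct contingency-table identities from gamete counts.
ld_oracle <- function(n) {
  f <- n / sum(n)
  fA <- f[1] + f[2]; fB <- f[1] + f[3]
  D <- f[1] - fA * fB
  Dmax <- if (D >= 0) min(fA * (1 - fB), (1 - fA) * fB)
          else min(fA * fB, (1 - fA) * (1 - fB))
  list(D = D, Dprime = if (D == 0) 0 else abs(D) / Dmax,
       r2 = D^2 / (fA * (1 - fA) * fB * (1 - fB)))
}

# Holm oracle: textbook step-down definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m); out[o] <- adj
  out
}

# Four-gamete block-partition oracle: qualification of every adjacent
# eligible pair from first principles; blocks = maximal runs.
oracle_partition <- function(panel, max_pair_bp = 5e5, fg_max = 0.01) {
  m <- ncol(panel$alleles)
  poly <- vapply(seq_len(m), function(j)
    length(unique(panel$alleles[, j])) == 2L, TRUE)
  idx <- which(poly)
  q <- logical(max(length(idx) - 1L, 0L))
  for (k in seq_along(q)) {
    i <- idx[k]; j <- idx[k + 1L]
    ga <- panel$alleles[, i]; gb <- panel$alleles[, j]
    fA <- mean(ga == ga[1]); fB <- mean(gb == gb[1])
    fAB <- mean(ga == ga[1] & gb == gb[1])
    freqs <- c(fAB, fA - fAB, fB - fAB, 1 - fA - fB + fAB)
    D <- fAB - fA * fB
    Dmax <- if (D >= 0) min(fA * (1 - fB), (1 - fA) * fB)
            else min(fA * fB, (1 - fA) * (1 - fB))
    dp <- if (D == 0) 0 else abs(D) / Dmax
    q[k] <- (panel$map$bp[j] - panel$map$bp[i]) < max_pair_bp &&
      sum(freqs < fg_max) >= 1L && dp >= 1 - 1e-12
  }
  blocks <- list(); run <- integer(0)
  for (k in seq_along(q)) {
    if (q[k]) run <- union(run, c(idx[k], idx[k + 1L]))
    else { if (length(run) >= 2L) blocks[[length(blocks) + 1L]] <- run
           run <- integer(0) }
  }
  if (length(run) >= 2L) blocks[[length(blocks) + 1L]] <- run
  lapply(blocks, function(b) panel$map$snp[b])
}

# Random small panel used by partition-oracle checks.
random_panel <- function(m, seed, bp_max_gap = 8e5) {
  set.seed(seed)
  cols <- replicate(m, {
    k <- sample(0:4, 1)  # k = 0 gives a monomorphic SNP now and then
    a <- rep("A", 8)
    if (k > 0) a[sample(8, k)] <- "G"
    a
  }, simplify = FALSE)
  bp <- cumsum(sample.int(bp_max_gap, m))
  toy_panel(cols, bp = as.integer(bp), cM = bp / 1e6)
}
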