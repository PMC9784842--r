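# Three-step GWAS: screening, SBC cofactors, conditional scan, Holm
# correction, founder effects, explained variance.

sim_markers <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 1, runif(m, 0.1, 0.5)[rep(1:m, each = n)]), n, m)
  colnames(X) <- sprintf("M%04d", 1:m)
  rownames(X) <- sprintf("L%04d", 1:n)
  X
}

test_that("step 1 recovers a planted marker and stays quiet under the null", {
  X <- sim_markers(400, 1000, 61)
  set.seed(62)
  y <- 3 * X[, 7] + rnorm(400)  # R2 ~ 0.9 regime
  tr <- step1_cv_screen(X, y, n_reps = 100, seed = 63)
  expect_gte(tr$inclusion[["M0007"]], 95L)
  expect_true("M0007" %in% tr$robust)
  # pure-noise phenotype: robust set near-empty
  y0 <- rnorm(400)
  tr0 <- step1_cv_screen(X, y0, n_reps = 100, seed = 64)
  expect_lt(length(tr0$robust), 15L)
  # n_reps = 1 cannot produce a robust marker (threshold "more than one")
  tr1 <- step1_cv_screen(X, y, n_reps = 1, seed = 65)
  expect_length(tr1$robust, 0L)
  # degenerate split rejected
  expect_error(step1_cv_screen(X[1:3, ], y[1:3], train_frac = 0.9, seed = 1),
               "validation set")
})

test_that("step 1 is deterministic in the seed", {
  X <- sim_markers(100, 50, 71)
  set.seed(72); y <- X[, 3] + rnorm(100)
  t1 <- step1_cv_screen(X, y, n_reps = 10, seed = 7)
  t2 <- step1_cv_screen(X, y, n_reps = 10, seed = 7)
  expect_identical(t1, t2)
})

test_that("SBC closed form and selection properties", {
  expect_equal(sbc(100, 50, 3), 100 * log(0.5) + 3 * log(100))
  expect_equal(round(sbc(100, 50, 3), 1), -55.5)
  X <- sim_markers(200, 30, 81)
  set.seed(82)
  y <- 2 * X[, 1] - 1.5 * X[, 2] + rnorm(200, 0, 0.5)
  cs <- step2_sbc_cofactors(X, y, colnames(X))
  expect_true(all(c("M0001", "M0002") %in% cs$markers))
  expect_true(all(diff(cs$sbc_path) < 0))  # strictly decreasing along entries
  # no candidate improving on the intercept -> empty set
  y0 <- rnorm(200)
  cs0 <- step2_sbc_cofactors(X[, 5, drop = FALSE] * 0, y0, "M0005")
  expect_length(cs0$markers, 0L)
  # adding pure noise to a saturated true model raises SBC (penalty property)
  for (s in 1:5) {
    set.seed(s)
    noise <- rbinom(200, 1, 0.3)
    sse_full <- sum(lm.fit(cbind(1, X[, 1:2]), y)$residuals^2)
    sse_plus <- sum(lm.fit(cbind(1, X[, 1:2], noise), y)$residuals^2)
    expect_gt(sbc(200, sse_plus, 4), sbc(200, sse_full, 3) - 0.5)
  }
  # perfectly collinear candidates are skipped deterministically
  Xd <- cbind(X[, 1:2], M0001b = X[, 1])
  csd <- step2_sbc_cofactors(Xd, y, colnames(Xd))
  expect_false(all(c("M0001", "M0001b") %in% csd$markers))
})

test_that("step 3 reduces to univariate OLS with no cofactors", {
  X <- sim_markers(150, 40, 91)
  set.seed(92)
  y <- X[, 10] + rnorm(150)
  mta <- step3_scan(X, y, character(0))
  for (j in c(1, 10, 25)) {
    f <- summary(lm(y ~ X[, j]))
    expect_equal(mta$effect[j], unname(coef(f)[2, 1]), tolerance = 1e-10)
    expect_equal(mta$p[j], unname(coef(f)[2, 4]), tolerance = 1e-10)
    expect_equal(mta$partial_r2[j], f$r.squared, tolerance = 1e-10)
  }
  expect_equal(mta$bon_p, holm_adjust(mta$p))
  expect_true(all(mta$bon_p >= mta$p))
  expect_identical(mta$significant, mta$bon_p < 0.05)
})

test_that("orthogonal markers keep their marginal effect under cofactors", {
  set.seed(101)
  n <- 128
  # orthogonal +-1 contrasts guarantee zero sample correlation
  z1 <- rep(c(0, 1), each = n / 2)
  z2 <- rep(rep(c(0, 1), each = n / 4), 2)
  z3 <- rep(rep(c(0, 1), each = n / 8), 4)
  X <- cbind(C1 = z1, C2 = z2, Mtest = z3)
  rownames(X) <- paste0("L", 1:n)
  y <- z1 + 0.5 * z2 + 2 * z3 + rnorm(n)
  marg <- step3_scan(X, y, character(0))
  cond <- step3_scan(X, y, c("C1", "C2"))
  expect_equal(cond$effect[cond$marker == "Mtest"],
               marg$effect[marg$marker == "Mtest"], tolerance = 1e-10)
  # cofactors themselves are tested with self removed from the background
  expect_true(all(is.finite(cond$effect)))
  expect_true(all(cond$is_cofactor[cond$marker %in% c("C1", "C2")]))
  # collinear marker flagged with p = 1
  Xc <- cbind(X, Dup = z1)
  res <- step3_scan(Xc, y, c("C1"))
  expect_false(res$estimable[res$marker == "Dup"])
  expect_equal(res$p[res$marker == "Dup"], 1)
})

test_that("planted QTL rank top by partial R2 in the conditional scan", {
  X <- sim_markers(400, 500, 111)
  set.seed(112)
  y <- 2 * X[, 42] + 1.5 * X[, 333] + rnorm(400)
  fit <- hb_gwas(X, setNames(y, rownames(X)), n_reps = 30, seed = 113)
  top2 <- fit$mta$marker[order(-fit$mta$partial_r2)][1:2]
  expect_setequal(top2, c("M0042", "M0333"))
  expect_true(all(c("M0042", "M0333") %in%
                  fit$mta$marker[fit$mta$significant]))
  expect_gt(fit$explained_r2, 0.3)
})

test_that("Holm adjustment matches its step-by-step definition", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(holm_adjust(p), holm_oracle(p))
  }
})

test_that("founder effects map marker effects onto carriers", {
  fe <- founder_effects(2.0, c("F02", "F05"))
  expect_equal(unname(fe), c(0, 2, 0, 0, 2, 0, 0, 0))
  fe2 <- founder_effects(-1.3, "01100000")
  expect_equal(unname(fe2), c(0, -1.3, -1.3, 0, 0, 0, 0, 0))
  expect_error(founder_effects(1, rep(TRUE, 8)), "all founders")
  expect_warning(founder_effects(1, rep(FALSE, 8)), "no founder")
})

test_that("founder effect ranking is recovered from an 8-haplotype block", {
  # staircase panel: founder i carries "G" at SNP j iff i <= j, giving one
  # 7-SNP four-gamete block whose 8 founder haplotypes are all distinct
  cols <- lapply(1:7, function(j) ifelse(1:8 <= j, "G", "A"))
  set.seed(121)
  rhos <- vapply(1:5, function(s) {
    p <- toy_panel(cols)
    hb <- build_haploblocks(p)
    stopifnot(nrow(hb$blocks) == 1L, hb$blocks$n_snps == 7L)
    pop <- funnel_cross(p, 400, 6, seed = 300 + s)
    eff <- seq(-2, 2, length.out = 8)[sample.int(8)]
    arch <- trait_architecture(qtl = list(list(snp = p$map$snp[4],
                                               effects = eff)),
                               V_G = 0, V_R = 0.5, e = 2, t = 1,
                               treatments = "N0")
    ph <- plant_phenotypes(pop, arch, seed = 400 + s)
    y <- lsmeans(ph, "YLD")
    calls <- call_haplotypes(hb, pop, p)
    mm <- build_marker_matrix(filter_haplotypes(calls), hb, calls, pop, p)
    mta <- step3_scan(mm, y[pop$lines], character(0))
    # each founder carries exactly one haplotype: its estimated effect is
    # that haplotype column's marker effect
    est <- rep(NA_real_, 8)
    for (k in seq_len(nrow(mta))) {
      fl <- as.integer(strsplit(mta$founders[k], "")[[1]]) == 1
      if (any(fl) && !all(fl)) est[fl] <- founder_effects(
        mta$effect[k], mta$founders[k])[fl]
    }
    cor(est, eff, method = "spearman", use = "complete.obs")
  }, 0)
  expect_gte(mean(rhos), 0.8)
})

test_that("explained variance identities hold", {
  set.seed(131)
  y <- rnorm(60)
  x <- rbinom(60, 1, 0.4)
  expect_equal(explained_variance(y, cbind(x)), cor(y, x)^2, tolerance = 1e-10)
  expect_equal(explained_variance(y, cbind(x, x)),
               explained_variance(y, cbind(x)), tolerance = 1e-10)
  expect_equal(explained_variance(y, NULL), 0)
})
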