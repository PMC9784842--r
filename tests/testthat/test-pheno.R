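# LSMEANS, ANOVA, variance components, heritability, descriptives,
# correlations, similarity and PCA.

test_that("balanced LSMEANS equal plain means; constants pass through", {
  ph <- balanced_pheno(n_lines = 5, e = 2, t = 2)
  lsm <- lsmeans(ph, "Y")
  plain <- tapply(ph$value, ph$line, mean)
  expect_equal(unname(lsm), as.numeric(plain[names(lsm)]))
  ph$value <- 7
  expect_true(all(lsmeans(ph, "Y") == 7))
  # per-treatment scope restricts correctly
  lsm0 <- lsmeans(balanced_pheno(4, 2, 2), "Y", scope = "N0")
  ph2 <- balanced_pheno(4, 2, 2)
  expect_equal(unname(lsm0),
               as.numeric(tapply(ph2$value[ph2$treatment == "N0"],
                                 ph2$line[ph2$treatment == "N0"],
                                 mean)[names(lsm0)]))
})

test_that("unbalanced LSMEANS match a direct normal-equations oracle", {
  ph <- balanced_pheno(n_lines = 4, e = 2, t = 2, seed = 3)
  set.seed(4); ph$value <- ph$value + rnorm(nrow(ph), 0, .3)
  ph_un <- ph[-1, ]  # delete one cell -> unbalanced
  lsm <- lsmeans(ph_un, "Y")
  # oracle: explicit OLS on treatment-coded design, equal-weight marginal means
  d <- ph_un
  d$line <- factor(d$line); d$env <- factor(d$env)
  d$treatment <- factor(d$treatment)
  fit <- lm(value ~ line + env + treatment + env:treatment + line:env +
              line:treatment, data = d)
  grid <- expand.grid(line = levels(d$line), env = levels(d$env),
                      treatment = levels(d$treatment))
  pred <- predict(fit, newdata = grid)
  oracle <- tapply(pred, grid$line, mean)
  expect_equal(lsm, setNames(as.numeric(oracle[names(lsm)]), names(lsm)),
               tolerance = 1e-8)
})

test_that("ANOVA flags a strong treatment shift and behaves under the null", {
  s <- small_sim()
  arch <- trait_architecture(V_G = 1, V_R = 1, e = 3, t = 2, treat_shift = 3)
  ph <- plant_phenotypes(s$pop, arch, seed = 12)
  a <- anova_fixed(ph, "YLD")
  expect_lt(a$p[a$term == "treatment"], 0.001)
  expect_identical(a$stars[a$term == "treatment"], "***")
  # null calibration: environment p-values roughly uniform over repetitions
  set.seed(77)
  ps <- replicate(40, {
    ph0 <- data.frame(line = rep(paste0("L", 1:12), 4),
                      env = rep(c("E1", "E2"), each = 24),
                      treatment = rep(rep(c("N0", "N1"), each = 12), 2),
                      replicate = 1L, trait = "Y", value = rnorm(48))
    anova_fixed(ph0, "Y")$p[2]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # single-level factor skipped with a warning
  ph1 <- balanced_pheno(4, 2, 1)
  expect_warning(anova_fixed(ph1, "Y"), "single-level")
})

test_that("variance components recover simulated truth (EMS and REML)", {
  p <- simulate_founders(50, seed = 31)
  tru <- c(V_G = 1, V_GE = 0.5, V_GT = 0.25, V_R = 1)
  est <- replicate(5, {
    pop <- funnel_cross(p, 800, 4, seed = sample.int(1e6, 1))
    arch <- trait_architecture(V_G = 1, V_GE = 0.5, V_GT = 0.25, V_R = 1,
                               e = 7, t = 2)
    ph <- plant_phenotypes(pop, arch, seed = sample.int(1e6, 1))
    vc <- variance_components(ph, "YLD", method = "ems")
    c(vc$V_G, vc$V_GE, vc$V_GT, vc$V_R)
  })
  m <- rowMeans(est)
  expect_true(all(abs(m - tru) / tru < 0.20))
  # REML agrees with EMS on balanced data
  set.seed(5)
  pop <- funnel_cross(p, 200, 4, seed = 2)
  ph <- plant_phenotypes(pop, trait_architecture(V_G = 1, V_GE = 0.5,
                                                 V_GT = 0.25, V_R = 1,
                                                 e = 3, t = 2), seed = 3)
  ems <- variance_components(ph, "YLD", method = "ems")
  reml <- variance_components(ph, "YLD", method = "reml")
  expect_equal(reml$V_G, ems$V_G, tolerance = 0.1)
  expect_equal(reml$V_R, ems$V_R, tolerance = 0.1)
})

test_that("destroying genotype labels destroys V_G", {
  p <- simulate_founders(50, seed = 41)
  pop <- funnel_cross(p, 300, 4, seed = 42)
  ph <- plant_phenotypes(pop, trait_architecture(V_G = 2, V_R = 1, e = 3,
                                                 t = 2), seed = 43)
  set.seed(44)
  perm <- ph
  for (ev in unique(ph$env)) for (tr in unique(ph$treatment)) {
    i <- perm$env == ev & perm$treatment == tr
    perm$line[i] <- sample(perm$line[i])
  }
  vc <- variance_components(perm, "YLD", method = "ems")
  expect_lt(vc$V_G, 0.15)
  # zero-noise genotype-only data: V_G = variance of genotype means
  g <- rnorm(10)
  ph0 <- balanced_pheno(10, 2, 2, g = g * 0)
  ph0$value <- g[as.integer(factor(ph0$line))] +
    0.5 * as.integer(factor(ph0$env)) + 2 * as.integer(factor(ph0$treatment))
  vc0 <- variance_components(ph0, "Y", method = "ems")
  expect_equal(vc0$V_G, var(g), tolerance = 1e-8)
  expect_equal(vc0$V_GE + vc0$V_GT + vc0$V_R, 0, tolerance = 1e-8)
})

test_that("heritability follows the closed form and is monotone", {
  vc <- list(V_G = 1, V_GE = 1, V_GT = 1, V_R = 1, e = 7, t = 2)
  expect_equal(heritability(vc, model = "line"),
               1 / (1 + 1 / 7 + 1 / 2 + 1 / 14), tolerance = 1e-12)
  expect_equal(round(heritability(vc, model = "line"), 4), 0.5833)
  # founder model includes V_GET and replicates
  vcf <- list(V_G = 1, V_GE = 1, V_GT = 1, V_GET = 1, V_R = 1,
              e = 7, t = 2, r = 4)
  expect_equal(heritability(vcf, model = "founder"),
               1 / (1 + 1 / 7 + 1 / 2 + 1 / 14 + 1 / 56), tolerance = 1e-12)
  # noise-free limit
  expect_equal(heritability(list(V_G = 3, V_GE = 0, V_GT = 0, V_R = 0,
                                 e = 2, t = 2), model = "line"), 1)
  # monotone: increasing in V_G, decreasing in noise; -> 1 as e, t grow
  h <- vapply(c(1, 2, 4, 8), function(vg)
    heritability(list(V_G = vg, V_GE = 1, V_GT = 1, V_R = 1, e = 3, t = 2),
                 model = "line"), 0)
  expect_true(all(diff(h) > 0))
  h2 <- vapply(c(2, 5, 20, 100), function(k)
    heritability(list(V_G = 1, V_GE = 1, V_GT = 1, V_R = 1, e = k, t = k),
                 model = "line"), 0)
  expect_true(all(diff(h2) > 0) && h2[4] > 0.97)
  expect_true(all(h >= 0 & h <= 1))
  expect_error(heritability(list(V_G = 0, V_GE = 0, V_GT = 0, V_R = 0,
                                 e = 2, t = 2), model = "line"), "undefined")
})

test_that("descriptive statistics and CV match the reporting convention", {
  expect_equal(cv_percent(5.3, 75.5), 7.0)   # yield-like
  expect_equal(cv_percent(3.7, 42.1), 8.8)   # thousand-grain-weight-like
  expect_equal(descriptives(rep(5, 10))$cv_percent, 0)
  x <- c(2, 4, 6, 8)
  d <- descriptives(x)
  expect_equal(d$lsmean, 5)
  expect_equal(d$sd, sd(x))
  expect_equal(d$n, 4L)
  expect_true(d$min <= d$lsmean && d$lsmean <= d$max)
  expect_warning(cv_percent(1, 0), "undefined")
})

test_that("pearson correlations match oracles and flag degenerate traits", {
  set.seed(9)
  x <- rnorm(100)
  lsm <- cbind(a = x, b = -x, c = rnorm(100))
  pc <- pearson_correlations(lsm)
  expect_equal(diag(pc$r), c(a = 1, b = 1, c = 1))
  expect_equal(pc$r["a", "b"], -1)
  expect_true(all(abs(pc$r) <= 1 + 1e-12))
  expect_equal(pc$r["a", "c"], cor(x, lsm[, "c"]))
  expect_equal(pc$p["a", "c"], cor.test(x, lsm[, "c"])$p.value,
               tolerance = 1e-10)
  # sampling check at known rho = 0.6
  set.seed(10)
  z <- rnorm(800); w <- 0.6 * z + sqrt(1 - 0.36) * rnorm(800)
  expect_lt(abs(pearson_correlations(cbind(z, w))$r[1, 2] - 0.6), 0.07)
  expect_warning(pearson_correlations(cbind(k = rep(1, 10), j = rnorm(10))),
                 "zero-variance")
})

test_that("simple-matching similarity and PCA match hand oracles", {
  g <- rbind(a = c("AA", "AG", "GG", "CC", "TT"),
             b = c("AA", "AG", "GG", "CC", "TT"),
             c = c("AA", "GG", "GG", "CC", "NN"),
             d = c("GG", "AA", "AA", "TT", "CC"),
             e = c("AA", "NN", "GG", "NN", "TT"))
  sp <- similarity_pca(g, n_axes = 2)
  S <- sp$similarity
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "d"], 0)        # differ at every SNP
  expect_equal(S["a", "c"], 3 / 4)    # hand count over 4 shared calls
  expect_equal(S["a", "e"], 3 / 3)    # over shared non-missing only
  expect_equal(S["c", "e"], 2 / 2)
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, 5))
  # PCA oracle: eigen decomposition of the covariance of S columns
  ev <- eigen(cov(S), symmetric = TRUE)$values
  ve_oracle <- 100 * ev / sum(ev)
  expect_equal(sp$var_explained, ve_oracle[1:2], tolerance = 1e-8)
  expect_lte(sum(sp$var_explained), 100 + 1e-8)
})
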