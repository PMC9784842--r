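# MTA merging, scope accounting, pleiotropy, prediction, transgression.

mta_fixture <- function(marker, trait, scope, chrom, cM,
                        effect = 1, bon_p = 0.01) {
  data.frame(marker = marker, trait = trait, scope = scope, chrom = chrom,
             cM = cM, bp = as.integer(cM * 1e6), effect = effect,
             partial_r2 = 0.1, p = bon_p / 2, bon_p = bon_p,
             significant = TRUE, estimable = TRUE, is_cofactor = FALSE,
             founders = "10000000", stringsAsFactors = FALSE)
}

ind_markers <- function(n, m, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 1, 0.4), n, m,
              dimnames = list(NULL, paste0("M", seq_len(m))))
  X
}

test_that("MTA merging follows the r2 / cM link rule", {
  X <- ind_markers(200, 4)
  X[, 2] <- X[, 1]  # perfect LD pair
  # two same-trait MTAs 3 cM apart with r2 = 1 -> one QTL
  m1 <- rbind(mta_fixture("M1", "YLD", "N0", "3A", 10),
              mta_fixture("M2", "YLD", "N1", "3A", 13))
  q1 <- merge_mtas(m1, X)
  expect_equal(nrow(q1), 1L)
  expect_equal(q1$qtl, "QYLD_3A")
  expect_equal(q1$scopes, "N0,N1")
  # 10 cM apart, r2 ~ 0 -> two QTL
  m2 <- rbind(mta_fixture("M1", "YLD", "N0", "3A", 10),
              mta_fixture("M3", "YLD", "N0", "3A", 20))
  q2 <- merge_mtas(m2, X)
  expect_equal(nrow(q2), 2L)
  expect_setequal(q2$qtl, c("QYLD_3Aa", "QYLD_3Ab"))
  # different traits never merge
  m3 <- rbind(mta_fixture("M1", "YLD", "N0", "3A", 10),
              mta_fixture("M2", "HEI", "N0", "3A", 10))
  expect_equal(nrow(merge_mtas(m3, X)), 2L)
})

test_that("merging is single-linkage, idempotent and order-independent", {
  X <- ind_markers(300, 3)
  # chain: A-B close, B-C close, A-C far -> one QTL by single linkage
  m <- rbind(mta_fixture("M1", "GNE", "N0", "2B", 10),
             mta_fixture("M2", "GNE", "N0", "2B", 14),
             mta_fixture("M3", "GNE", "N0", "2B", 18))
  q <- merge_mtas(m, X)
  expect_equal(nrow(q), 1L)
  expect_equal(q$n_mta, 3L)
  expect_equal(q$start_cM, 10); expect_equal(q$end_cM, 18)
  # brute-force oracle: transitive closure of the pairwise link relation
  link <- function(a, b) abs(m$cM[a] - m$cM[b]) < 5
  adj <- outer(1:3, 1:3, Vectorize(link))
  reach <- adj | diag(3)
  for (k in 1:3) reach <- reach | (reach %*% reach > 0)
  expect_equal(length(unique(apply(reach, 1, paste, collapse = ""))), 1L)
  # permuting the input rows yields the same QTL set
  for (s in 1:5) {
    set.seed(s)
    qp <- merge_mtas(m[sample(3), ], X)
    expect_equal(as.data.frame(qp), as.data.frame(q))
  }
})

test_that("scope accounting reproduces the treatment-unique percentages", {
  # 71 QTL: 14 N0-only, 25 N1-only, 7 across-only, rest multi-scope
  scopes <- c(rep("N0", 14), rep("N1", 25), rep("across", 7),
              rep("N0,N1", 10), rep("N0,N1,across", 15))
  q <- data.frame(qtl = paste0("Q", seq_along(scopes)), trait = "YLD",
                  chrom = "1A", start_cM = seq_along(scopes) * 10,
                  end_cM = seq_along(scopes) * 10, n_mta = 1L,
                  scopes = scopes, best_marker = "M", min_bon_p = 0.01,
                  unmapped = FALSE, stringsAsFactors = FALSE)
  class(q) <- c("qtl_set", "data.frame")
  acc <- classify_scopes(q)
  expect_equal(acc$pct_single_treatment_unique, 54.9)
  expect_equal(acc$totals[["N0_unique"]], 14)
  expect_equal(acc$totals[["N1_unique"]], 25)
  expect_equal(acc$totals[["across_unique"]], 7)
  expect_equal(acc$pct_across_unique, 9.9)
  # a QTL significant in all scopes counts in all scope columns, unique in none
  expect_equal(acc$totals[["across"]], 7 + 15)
  expect_equal(acc$totals[["N0"]], 14 + 10 + 15)
  expect_equal(acc$totals[["n_qtl"]], 71)
})

test_that("pleiotropy windows group nearby QTL of different traits", {
  mk <- function(qtl, trait, cM) data.frame(
    qtl = qtl, trait = trait, chrom = "2B", start_cM = cM, end_cM = cM,
    n_mta = 1L, scopes = "N0", best_marker = "M", min_bon_p = 0.01,
    unmapped = FALSE, stringsAsFactors = FALSE)
  # HEI and TGW 2 cM apart -> one locus; third QTL 6 cM away -> excluded
  q <- rbind(mk("QHEI_2B", "HEI", 10), mk("QTGW_2B", "TGW", 12),
             mk("QYLD_2B", "YLD", 30))
  pl <- pleiotropy_scan(q)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$traits, "HEI,TGW")
  expect_equal(pl$n_traits, 2L)
  # 6 cM apart -> not grouped
  q2 <- rbind(mk("QHEI_2B", "HEI", 10), mk("QTGW_2B", "TGW", 16))
  expect_equal(nrow(pleiotropy_scan(q2)), 0L)
  # four traits at one position -> one locus listing all four
  q4 <- rbind(mk("QHEI_2B", "HEI", 50), mk("QEAR_2B", "EAR", 50),
              mk("QGNE_2B", "GNE", 50.5), mk("QTGW_2B", "TGW", 51))
  pl4 <- pleiotropy_scan(q4)
  expect_equal(pl4$n_traits, 4L)
  expect_equal(pl4$traits, "EAR,GNE,HEI,TGW")
  # brute-force all-pairs oracle on a random fixture
  set.seed(3)
  cms <- sort(runif(8, 0, 40))
  qr <- do.call(rbind, lapply(seq_along(cms), function(i)
    mk(paste0("Q", i), paste0("T", i), cms[i])))
  plr <- pleiotropy_scan(qr)
  adj <- abs(outer(cms, cms, "-")) < 5
  comp <- rep(0L, 8); cur <- 0L
  for (i in 1:8) if (comp[i] == 0L) {
    cur <- cur + 1L; frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0 &
                                comp == 0L), frontier)
    }
  }
  oracle_groups <- table(comp)
  expect_equal(nrow(plr), sum(oracle_groups >= 2L))
})

test_that("stepwise yield prediction recovers component traits", {
  set.seed(7)
  n <- 400
  comp <- cbind(TGW = rnorm(n), GNE = rnorm(n), EAR = rnorm(n),
                HEI = rnorm(n))
  Xq <- ind_markers(n, 6, seed = 8)
  y <- 1.0 * comp[, "TGW"] + 0.8 * comp[, "GNE"] + 0.6 * comp[, "EAR"] +
    0.5 * Xq[, 1] + rnorm(n, 0, 0.8)
  names(y) <- paste0("L", 1:n)
  pm <- predict_yield(y, Xq, comp)
  expect_true(all(c("TGW", "GNE", "EAR") %in% pm$selected))
  r2_true <- 1 - 0.8^2 / var(y)
  expect_lt(abs(pm$r2 - r2_true), 0.1)
  # markers-only model never beats the full model
  expect_lte(pm$r2_markers_only, pm$r2 + 1e-12)
  # pure-noise predictors -> intercept-only model
  y0 <- rnorm(n)
  p0 <- predict_yield(y0, Xq, NULL)
  expect_length(p0$selected, 0L)
  expect_equal(p0$r2, 0)
})

test_that("transgression report compares best line to best founder", {
  lines <- setNames(c(89.33, 80.1, 85.2, 70.0), paste0("WM_", 1:4))
  founders <- setNames(c(84.93, 80.0, 75.7), c("Tobak", "Safari", "Bernstein"))
  tg <- transgression_report(lines, founders)
  expect_equal(tg$gain, 4.40, tolerance = 1e-12)
  expect_equal(tg$gain_percent, 5.2)
  expect_identical(tg$best_founder, "Tobak")
  expect_equal(tg$n_lines_exceeding, 2L)
  # equal best line and founder -> zero gain
  tg0 <- transgression_report(c(L1 = 10), c(F1 = 10))
  expect_equal(tg0$gain, 0); expect_equal(tg0$gain_percent, 0)
  expect_error(transgression_report(numeric(0), founders), "empty")
  # brute-force count on a random fixture
  set.seed(11)
  lm10 <- setNames(runif(10, 60, 90), paste0("L", 1:10))
  fm8 <- setNames(runif(8, 60, 90), paste0("F", 1:8))
  expect_equal(transgression_report(lm10, fm8)$n_lines_exceeding,
               sum(lm10 > max(fm8)))
})
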