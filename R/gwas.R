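# Three-step cofactor-conditioned GWAS on 0/1 haplotype and singular-SNP
# allele markers:
#   step 1 -- cross-validated stepwise screening: repeated 80/20 splits,
#             forward+backward moves accepted only while the validation-set
#             mean squared prediction error (ASE) decreases;
#   step 2 -- non-repeated forward selection among the robust markers
#             minimizing the Schwarz Bayesian Criterion (SBC);
#   step 3 -- every marker tested by OLS with the selected cofactors in the
#             background (sequential tests), Bonferroni-Holm corrected.
#
# All numerics are plain least squares on small designs; forward steps are
# vectorized over candidates via residual projections (Frisch-Waugh).

# Fit OLS of y on design C (with intercept already included); returns
# coefficients, residuals and SSE.  Uses QR for rank safety.
ols_fit <- function(C, y) {
  f <- stats::lm.fit(C, y)
  list(coef = f$coefficients, resid = f$residuals,
       sse = sum(f$residuals^2), rank = f$rank)
}

# Residual-projection quantities of candidate columns Z on current design C:
# B (proj coefficients), Ztil (residualized candidates), d (their SSQs).
project_candidates <- function(C, Z) {
  B <- tryCatch(solve(crossprod(C), crossprod(C, Z)),
                error = function(e) {
    # rank-deficient background: fall back to pseudo-inverse via QR
    qr.coef(qr(C), Z)
  })
  B[is.na(B)] <- 0
  Ztil <- Z - C %*% B
  list(B = B, Ztil = Ztil, d = colSums(Ztil^2))
}

#' Schwarz Bayesian Criterion
#'
#' `SBC = n * ln(SSE / n) + k * ln(n)` where `k` counts all fitted
#' parameters including the intercept.
#'
#' @param n number of observations.
#' @param sse residual sum of squares.
#' @param k number of fitted parameters (including the intercept).
#' @return the criterion value (smaller is better).
#' @examples
#' sbc(100, 50, 3)  # ~ -55.50
#' @export
sbc <- function(n, sse, k) n * log(sse / n) + k * log(n)

#' Step 1: cross-validated stepwise marker screening
#'
#' In each of `n_reps` repetitions the lines are split at random into a
#' training (`train_frac`) and a validation set.  Starting from the
#' intercept-only model, the forward candidate is the marker with the
#' largest training sum-of-squares reduction (ties to the smaller marker
#' index); it is accepted only if it strictly decreases the validation-set
#' mean squared prediction error (ASE) of the training-fit model.  After
#' each forward step a backward sweep removes members whose removal
#' decreases the validation ASE.  The procedure stops when no move decreases
#' the ASE.  Markers included in the terminal model of more than one
#' repetition form the robust set.
#'
#' @param X 0/1 marker matrix (lines x markers) or a `marker_matrix`.
#' @param y per-line trait LSMEANS aligned with `X` rows.
#' @param n_reps number of cross-validation repetitions (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed fixing all splits.
#' @param max_steps safety cap on forward inclusions per repetition.
#' @return object of class `"selection_trace"`: `inclusion` (named counts),
#'   `robust` (marker names with count >= 2), `models` (per-repetition
#'   terminal sets), `ase_paths`, `n_reps`.
#' @export
step1_cv_screen <- function(X, y, n_reps = 100, train_frac = 0.8, seed = NULL,
                            max_steps = 50L) {
  if (inherits(X, "marker_matrix")) X <- X$X
  X <- as.matrix(X)
  y <- as.vector(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  n_val <- round(n * (1 - train_frac))
  if (n_val < 1L)
    stop("fewer lines than 1/(1 - train_frac): validation set would be empty")
  if (n < 50L) warning("fewer than 50 lines: screening may be unstable")
  M <- ncol(X)
  inclusion <- stats::setNames(integer(M), colnames(X))
  models <- vector("list", n_reps)
  ase_paths <- vector("list", n_reps)
  storage.mode(X) <- "double"
  local_seed(seed, {
    for (rep_i in seq_len(n_reps)) {
      val <- sample.int(n, n_val)
      tr <- setdiff(seq_len(n), val)
      Xtr <- X[tr, , drop = FALSE]; Xval <- X[val, , drop = FALSE]
      ytr <- y[tr]; yval <- y[val]
      # residualize everything against the intercept (training-fit based);
      # after each inclusion, project the remaining candidates out of the
      # new member (modified Gram-Schmidt), so forward steps stay O(n * M)
      bm <- colMeans(Xtr)
      Zt <- sweep(Xtr, 2L, bm)
      r_tr <- ytr - mean(ytr); r_val <- yval - mean(ytr)
      d <- colSums(Zt^2)
      ase <- mean(r_val^2)
      model <- integer(0); in_model <- logical(M)
      path <- ase
      # validation-side residualized candidates are materialized lazily:
      # zv(j) = Xval[, j] - bm[j] - sum_k bs[[k]][j] * uvs[[k]]
      uvs <- list(); bs <- list()
      zv <- function(j) {
        v <- Xval[, j] - bm[j]
        for (k in seq_along(uvs)) v <- v - bs[[k]][j] * uvs[[k]]
        v
      }
      rebuild <- function(model) {
        C <- cbind(1, Xtr[, model, drop = FALSE])
        Cv <- cbind(1, Xval[, model, drop = FALSE])
        B <- qr.coef(qr(C), Xtr)
        B[is.na(B)] <- 0
        f <- stats::lm.fit(C, ytr)
        cf <- f$coefficients; cf[is.na(cf)] <- 0
        # re-express the lazy validation form: single basis "column" Cv B
        list(Zt = Xtr - C %*% B, r_tr = f$residuals,
             r_val = as.vector(yval - Cv %*% cf), Cv = Cv, B = B)
      }
      repeat {
        moved <- FALSE
        # forward: best training SSE reduction, accepted on validation ASE
        if (length(model) < max_steps) {
          num <- as.vector(crossprod(Zt, r_tr))
          red <- num^2 / d
          red[d < 1e-8 | in_model] <- -Inf
          j <- which.max(red)
          if (is.finite(red[j])) {
            gam <- num[j] / d[j]
            uv <- zv(j)
            cand_rval <- r_val - gam * uv
            ase_new <- mean(cand_rval^2)
            if (ase_new < ase - 1e-12) {
              u <- Zt[, j]; duu <- d[j]
              b <- as.vector(crossprod(Zt, u)) / duu
              r_tr <- r_tr - gam * u
              r_val <- cand_rval
              Zt <- Zt - tcrossprod(u, b)
              d <- pmax(d - b^2 * duu, 0)
              uvs[[length(uvs) + 1L]] <- uv; bs[[length(bs) + 1L]] <- b
              in_model[j] <- TRUE; model <- c(model, j)
              ase <- ase_new; path <- c(path, ase)
              moved <- TRUE
            }
          }
        }
        # backward sweep: drop members while removal decreases validation ASE
        while (length(model) > 1L) {
          ases_rm <- vapply(seq_along(model), function(m) {
            Cm <- cbind(1, Xtr[, model[-m], drop = FALSE])
            Cvm <- cbind(1, Xval[, model[-m], drop = FALSE])
            fm <- stats::lm.fit(Cm, ytr)
            cf <- fm$coefficients; cf[is.na(cf)] <- 0
            mean((yval - Cvm %*% cf)^2)
          }, 0)
          m <- which.min(ases_rm)
          if (ases_rm[m] < ase - 1e-12) {
            in_model[model[m]] <- FALSE
            model <- model[-m]
            st <- rebuild(model)
            Zt <- st$Zt; r_tr <- st$r_tr; r_val <- st$r_val
            d <- colSums(Zt^2); d[in_model] <- 0
            # fold the rebuilt projection into the lazy validation form:
            # Cv B expressed as basis columns (uvs) x coefficient rows (bs)
            bm <- rep(0, M)
            uvs <- lapply(seq_len(ncol(st$Cv)), function(k) st$Cv[, k])
            bs <- lapply(seq_len(nrow(st$B)), function(k) st$B[k, ])
            ase <- ases_rm[m]; path <- c(path, ase)
            moved <- TRUE
          } else break
        }
        if (!moved) break
      }
      models[[rep_i]] <- colnames(X)[sort(model)]
      ase_paths[[rep_i]] <- path
      inclusion[model] <- inclusion[model] + 1L
    }
  })
  structure(list(inclusion = inclusion,
                 robust = names(inclusion)[inclusion >= 2L],
                 models = models, ase_paths = ase_paths, n_reps = n_reps),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Selection trace:", x$n_reps, "repetitions;",
      sum(x$inclusion > 0L), "markers ever included;",
      length(x$robust), "robust (included in > 1 model)\n")
  invisible(x)
}

#' Step 2: SBC-minimizing forward cofactor selection
#'
#' Non-repeated forward stepwise regression on the full data, restricted to
#' the robust markers from step 1.  A marker enters if it yields the largest
#' strict decrease of the Schwarz criterion; selection stops when no entry
#' lowers the SBC.  Perfectly collinear candidates are skipped
#' deterministically.
#'
#' @param X marker matrix (or `marker_matrix`).
#' @param y trait LSMEANS.
#' @param robust candidate marker names (possibly empty), e.g.
#'   `step1_cv_screen(...)$robust`.
#' @return object of class `"cofactor_set"`: `markers` (entry order) and
#'   `sbc_path` (intercept-only value first; non-increasing).
#' @export
step2_sbc_cofactors <- function(X, y, robust) {
  if (inherits(X, "marker_matrix")) X <- X$X
  y <- as.vector(y)
  n <- length(y)
  cand_names <- intersect(colnames(X), robust)
  sel <- character(0)
  C <- matrix(1, n, 1L)
  fit <- ols_fit(C, y)
  cur_sbc <- sbc(n, fit$sse, 1L)
  path <- cur_sbc
  while (length(cand_names)) {
    Z <- X[, cand_names, drop = FALSE]
    pr <- project_candidates(C, Z)
    ok <- pr$d > 1e-8
    if (!any(ok)) break
    num <- colSums(pr$Ztil * fit$resid)
    sses <- pmax(fit$sse - num^2 / pr$d, .Machine$double.xmin)
    sbcs <- sbc(n, sses, 1L + length(sel) + 1L)
    sbcs[!ok] <- Inf
    j <- which.min(sbcs)
    if (!(sbcs[j] < cur_sbc - 1e-12)) break
    sel <- c(sel, cand_names[j])
    C <- cbind(C, X[, cand_names[j]])
    fit <- ols_fit(C, y)
    cur_sbc <- sbc(n, fit$sse, 1L + length(sel))
    path <- c(path, cur_sbc)
    cand_names <- cand_names[-j]
  }
  structure(list(markers = sel, sbc_path = path), class = "cofactor_set")
}

#' @export
print.cofactor_set <- function(x, ...) {
  cat("Cofactor set:", length(x$markers), "markers; SBC",
      sprintf("%.2f -> %.2f\n", x$sbc_path[1L], x$sbc_path[length(x$sbc_path)]))
  invisible(x)
}

#' Step 3: cofactor-conditioned per-marker scan
#'
#' Every marker is tested by OLS of the trait on the cofactors (in their
#' step-2 entry order) plus the marker; the marker's effect is its
#' coefficient, its partial R-squared is the sequential (type-I) R-squared
#' after the cofactors, and its p-value is the sequential t-test.  A marker
#' that is itself a cofactor is tested with itself removed from the
#' background.  Markers collinear with the background are reported with
#' `p = 1` and flagged non-estimable.  Bonferroni-Holm correction over all
#' tested markers yields `bon_p`; significance is `bon_p < alpha`.
#'
#' @param X marker matrix or `marker_matrix` (its metadata is then joined
#'   onto the result).
#' @param y trait LSMEANS.
#' @param cofactors a [step2_sbc_cofactors()] result (or character vector of
#'   marker names in entry order).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame of class `"mta_table"`: `marker`, `effect`,
#'   `partial_r2`, `p`, `bon_p`, `significant`, `estimable`, `is_cofactor`
#'   (+ marker metadata columns when available).
#' @export
step3_scan <- function(X, y, cofactors, alpha = 0.05) {
  info <- NULL
  if (inherits(X, "marker_matrix")) { info <- X$info; X <- X$X }
  cof <- if (inherits(cofactors, "cofactor_set")) cofactors$markers
         else as.character(cofactors)
  y <- as.vector(y)
  n <- length(y); M <- ncol(X)
  stopifnot(nrow(X) == n)
  sst <- sum((y - mean(y))^2)
  Cfull <- cbind(1, X[, cof, drop = FALSE])
  eff <- p <- pr2 <- rep(NA_real_, M)
  estimable <- rep(TRUE, M)
  scan_against <- function(C, js) {
    pr <- project_candidates(C, X[, js, drop = FALSE])
    fitC <- ols_fit(C, y)
    num <- colSums(pr$Ztil * fitC$resid)
    d <- pr$d
    ok <- d > 1e-8
    effj <- ifelse(ok, num / d, NA_real_)
    ssef <- fitC$sse - ifelse(ok, num^2 / d, 0)
    df <- n - ncol(C) - 1L
    tstat <- effj * sqrt(d) / sqrt(pmax(ssef, .Machine$double.xmin) / df)
    pj <- 2 * stats::pt(-abs(tstat), df)
    # exact-fit guard: zero residual with nonzero effect
    pj[ok & ssef <= .Machine$double.xmin & abs(num) > 0] <- .Machine$double.xmin
    list(eff = effj, p = ifelse(ok, pj, 1), pr2 = ifelse(ok, num^2 / d / sst, 0),
         ok = ok)
  }
  plain <- setdiff(seq_len(M), match(cof, colnames(X)))
  if (length(plain)) {
    r <- scan_against(Cfull, plain)
    eff[plain] <- r$eff; p[plain] <- r$p; pr2[plain] <- r$pr2
    estimable[plain] <- r$ok
  }
  for (cf in cof) {
    j <- match(cf, colnames(X))
    Cm <- cbind(1, X[, setdiff(cof, cf), drop = FALSE])
    r <- scan_against(Cm, j)
    eff[j] <- r$eff; p[j] <- r$p; pr2[j] <- r$pr2; estimable[j] <- r$ok
  }
  bon_p <- holm_adjust(p)
  out <- data.frame(marker = colnames(X), effect = eff, partial_r2 = pr2,
                    p = p, bon_p = bon_p, significant = bon_p < alpha,
                    estimable = estimable,
                    is_cofactor = colnames(X) %in% cof,
                    stringsAsFactors = FALSE)
  if (!is.null(info))
    out <- cbind(out, info[match(out$marker, info$marker),
                           setdiff(names(info), "marker"), drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("mta_table", "data.frame")
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Monotone step-down family-wise error correction; adjusted values are
#' always at least the raw p-values and controlling at `alpha` guarantees
#' FWER `<= alpha`.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Map a marker effect onto the eight founders
#'
#' Presence/absence marker effects translate directly to founders: each
#' founder carrying the marker allele is assigned the estimated effect, the
#' non-carriers the 0 baseline.
#'
#' @param effect estimated marker effect (trait units per presence).
#' @param membership founder carrier set: logical vector of length 8, an
#'   8-character 0/1 flag string, or founder names.
#' @param founders the founder names (default the simulator's).
#' @return named numeric vector of length 8.
#' @export
founder_effects <- function(effect, membership, founders = DEFAULT_FOUNDERS) {
  carriers <- if (is.character(membership) && length(membership) == 1L &&
                  grepl("^[01]+$", membership)) {
    as.logical(as.integer(strsplit(membership, "")[[1L]]))
  } else if (is.logical(membership)) membership
  else founders %in% membership
  stopifnot(length(carriers) == length(founders))
  if (all(carriers))
    stop("marker carried by all founders: founder contrast undefined")
  if (!any(carriers))
    warning("marker carried by no founder (recombinant haplotype): ",
            "all founders at baseline")
  stats::setNames(ifelse(carriers, effect, 0), founders)
}

#' Explained variance of a trait by its significant markers
#'
#' R-squared of the joint OLS of the trait LSMEANS on all significant
#' markers of a trait/scope (rank-deficiency safe; duplicated columns do not
#' change the value).
#'
#' @param y trait LSMEANS.
#' @param X_sig matrix of significant marker columns (0 columns allowed).
#' @return R-squared in `[0, 1]` (0 when no marker is significant).
#' @export
explained_variance <- function(y, X_sig) {
  y <- as.vector(y)
  if (is.null(X_sig) || NCOL(X_sig) == 0L) return(0)
  f <- stats::lm.fit(cbind(1, as.matrix(X_sig)), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' Haplotype-based three-step GWAS
#'
#' Runs the full association scan for one trait and scope: cross-validated
#' stepwise screening ([step1_cv_screen()]), SBC cofactor selection
#' ([step2_sbc_cofactors()]) and the cofactor-conditioned marker scan with
#' Bonferroni-Holm correction ([step3_scan()]).
#'
#' @param markers a `marker_matrix` (or plain 0/1 matrix).
#' @param y named vector of per-line trait LSMEANS; names must match the
#'   marker-matrix rows (reordered if needed).
#' @param trait,scope labels stored with the results (scope is `"N0"`,
#'   `"N1"` or `"across"`).
#' @param n_reps,train_frac,seed,alpha see the step functions.
#' @return object of class `"hb_gwas"` with components `trace`, `cofactors`,
#'   `mta` (the [step3_scan()] table with `trait`/`scope` columns),
#'   `explained_r2` (joint R-squared of significant markers), `trait`,
#'   `scope`, `n`, `alpha`.
#' @seealso [merge_mtas()] for QTL merging, [plot.hb_gwas()] for a Manhattan
#'   plot.
#' @export
hb_gwas <- function(markers, y, trait = "trait", scope = "across",
                    n_reps = 100, train_frac = 0.8, seed = NULL,
                    alpha = 0.05) {
  y <- stats::setNames(as.numeric(y), names(y))
  X <- if (inherits(markers, "marker_matrix")) markers$X else as.matrix(markers)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(y))
    if (!length(common)) stop("no lines shared between markers and phenotype")
    X2 <- X[common, , drop = FALSE]
    y <- y[common]
    markers2 <- if (inherits(markers, "marker_matrix"))
      structure(list(X = X2, info = markers$info), class = "marker_matrix")
      else X2
  } else markers2 <- markers
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]
    if (inherits(markers2, "marker_matrix"))
      markers2$X <- markers2$X[keep, , drop = FALSE]
    else markers2 <- markers2[keep, , drop = FALSE]
  }
  Xw <- if (inherits(markers2, "marker_matrix")) markers2$X else markers2
  trace <- step1_cv_screen(Xw, y, n_reps = n_reps, train_frac = train_frac,
                           seed = seed)
  cof <- step2_sbc_cofactors(Xw, y, trace$robust)
  mta <- step3_scan(markers2, y, cof, alpha = alpha)
  mta$trait <- trait; mta$scope <- scope
  r2 <- explained_variance(y, Xw[, mta$marker[mta$significant], drop = FALSE])
  structure(list(trace = trace, cofactors = cof, mta = mta,
                 explained_r2 = r2, trait = trait, scope = scope,
                 n = length(y), alpha = alpha, y = y),
            class = "hb_gwas")
}

#' @export
print.hb_gwas <- function(x, ...) {
  cat(sprintf("Haplotype GWAS: trait %s, scope %s, %d lines, %d markers\n",
              x$trait, x$scope, x$n, nrow(x$mta)))
  cat(sprintf("  robust markers: %d; cofactors: %d; significant MTAs (BON_p < %g): %d\n",
              length(x$trace$robust), length(x$cofactors$markers),
              x$alpha, sum(x$mta$significant)))
  cat(sprintf("  explained variance of significant markers: R2 = %.3f\n",
              x$explained_r2))
  invisible(x)
}

#' @export
summary.hb_gwas <- function(object, ...) {
  sig <- object$mta[object$mta$significant, , drop = FALSE]
  sig <- sig[order(sig$bon_p), , drop = FALSE]
  out <- list(trait = object$trait, scope = object$scope, n = object$n,
              n_sig = nrow(sig), explained_r2 = object$explained_r2,
              cofactors = object$cofactors$markers, significant = sig)
  class(out) <- "summary.hb_gwas"
  out
}

#' @export
print.summary.hb_gwas <- function(x, ...) {
  cat(sprintf("GWAS summary -- trait %s (%s), %d lines\n", x$trait, x$scope, x$n))
  cat("Cofactors:", if (length(x$cofactors)) paste(x$cofactors, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("%d significant MTAs; joint R2 = %.3f\n", x$n_sig, x$explained_r2))
  if (x$n_sig) print(utils::head(
    x$significant[, c("marker", "effect", "partial_r2", "p", "bon_p")], 20L))
  invisible(x)
}

#' @export
coef.hb_gwas <- function(object, significant_only = FALSE, ...) {
  m <- object$mta
  if (significant_only) m <- m[m$significant, , drop = FALSE]
  stats::setNames(m$effect, m$marker)
}

#' Manhattan plot of a haplotype GWAS
#'
#' Plots `-log10(BON_p)` against genetic position with chromosomes laid side
#' by side and the `alpha` threshold as a horizontal line.  Requires marker
#' metadata (run the GWAS on a `marker_matrix`).
#'
#' @param x an `hb_gwas` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hb_gwas <- function(x, ...) {
  m <- manhattan_export(x)
  chs <- unique(m$chrom)
  off <- 0; xs <- numeric(nrow(m)); mids <- numeric(length(chs))
  for (i in seq_along(chs)) {
    j <- m$chrom == chs[i]
    xs[j] <- m$cM[j] + off
    mids[i] <- off + mean(range(m$cM[j]))
    off <- off + max(m$cM[j]) + 10
  }
  graphics::plot(xs, m$neg_log10_bon_p,
                 col = ifelse(match(m$chrom, chs) %% 2 == 0, "grey40", "grey70"),
                 pch = 20, xaxt = "n", xlab = "chromosome",
                 ylab = expression(-log[10](BON[p])), ...)
  graphics::axis(1, at = mids, labels = chs)
  graphics::abline(h = m$threshold[1L], lty = 2)
  invisible(x)
}

#' Manhattan export table
#'
#' @param fit an `hb_gwas` object whose MTA table carries map metadata.
#' @return data.frame: `marker`, `chrom`, `bp`, `cM`, `neg_log10_bon_p`,
#'   `significant`, `threshold` (the `-log10(alpha)` line), `trait`, `scope`.
#' @export
manhattan_export <- function(fit) {
  m <- fit$mta
  if (is.null(m$chrom)) stop("no marker metadata: run hb_gwas on a marker_matrix")
  data.frame(marker = m$marker, chrom = m$chrom, bp = m$bp, cM = m$cM,
             neg_log10_bon_p = -log10(pmax(m$bon_p, .Machine$double.xmin)),
             significant = m$significant,
             threshold = -log10(fit$alpha),
             trait = m$trait, scope = m$scope, stringsAsFactors = FALSE)
}
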