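# Trait summaries: least-squares means, fixed-effects ANOVA, variance
# components, broad-sense heritability, correlations, genetic similarity
# and PCA.

check_pheno <- function(pheno, trait) {
  stopifnot(is.data.frame(pheno),
            all(c("line", "env", "treatment", "value") %in% names(pheno)))
  if ("trait" %in% names(pheno) && !is.null(trait))
    pheno <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(pheno)) stop("no observations", if (!is.null(trait))
    paste0(" for trait ", trait))
  pheno
}

scope_filter <- function(pheno, scope) {
  if (identical(scope, "across")) return(pheno)
  out <- pheno[pheno$treatment == scope, , drop = FALSE]
  if (!nrow(out)) stop("no observations in scope ", scope)
  out
}

is_balanced <- function(pheno) {
  tab <- table(pheno$line, pheno$env, pheno$treatment)
  length(unique(as.vector(tab))) == 1L && all(tab > 0L)
}

#' Least-squares means per line
#'
#' Model-based marginal means from a fixed-effects model with genotype,
#' environment and treatment main effects and all two-way interactions,
#' marginalizing over environment/treatment levels with equal weights.  For
#' balanced data these equal the arithmetic cell means, which are then used
#' directly.
#'
#' @param pheno a phenotype table (`line`, `env`, `treatment`, `replicate`,
#'   `trait`, `value`).
#' @param trait trait to summarize (ignored if the table has no `trait`
#'   column).
#' @param scope `"across"` or a treatment label (e.g. `"N0"`, `"N1"`).
#' @return named numeric vector of LSMEANS, one element per line.
#' @export
lsmeans <- function(pheno, trait = NULL, scope = "across") {
  ph <- scope_filter(check_pheno(pheno, trait), scope)
  ph$line <- factor(ph$line); ph$env <- factor(ph$env)
  ph$treatment <- factor(ph$treatment)
  if (is_balanced(ph)) {
    out <- tapply(ph$value, ph$line, mean)
    return(stats::setNames(as.numeric(out), names(out))[levels(ph$line)])
  }
  terms <- c("line",
             if (nlevels(ph$env) > 1L) "env",
             if (nlevels(ph$treatment) > 1L) "treatment")
  if (all(c("env", "treatment") %in% terms)) terms <- c(terms, "env:treatment")
  if ("env" %in% terms) terms <- c(terms, "line:env")
  if ("treatment" %in% terms) terms <- c(terms, "line:treatment")
  fit <- stats::lm(stats::reformulate(terms, "value"), data = ph)
  em <- emmeans::emmeans(fit, "line", weights = "equal")
  s <- summary(em)
  out <- stats::setNames(s$emmean, as.character(s$line))
  if (anyNA(out))
    warning("LSMEANS not estimable for ", sum(is.na(out)), " line(s)")
  out[levels(ph$line)]
}

#' Fixed-effects ANOVA for genotype, environment and treatment
#'
#' Sequential (type-I) analysis of variance with genotype, environment and
#' treatment as fixed main effects plus all two-way interactions.
#' Significance stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @inheritParams lsmeans
#' @return data.frame with `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`,
#'   `stars`.
#' @export
anova_fixed <- function(pheno, trait = NULL) {
  ph <- check_pheno(pheno, trait)
  ph$line <- factor(ph$line); ph$env <- factor(ph$env)
  ph$treatment <- factor(ph$treatment)
  main <- c(line = "line", env = "env", treatment = "treatment")
  keep <- vapply(main, function(v) nlevels(ph[[v]]) > 1L, TRUE)
  if (!all(keep))
    warning("single-level factor(s) skipped: ",
            paste(main[!keep], collapse = ", "))
  terms <- main[keep]
  if (length(terms) >= 2L)
    terms <- c(terms, utils::combn(terms, 2L, paste, collapse = ":"))
  if (!length(terms)) stop("no factor with >= 2 levels")
  fit <- stats::lm(stats::reformulate(terms, "value"), data = ph)
  a <- stats::anova(fit)
  p <- a$`Pr(>F)`
  Fv <- a$`F value`
  # zero residual variance (incl. saturated fits): tests degenerate,
  # report p below the machine floor rather than NaN
  res_ms <- a$`Mean Sq`[nrow(a)]
  if (nrow(a) && (!is.finite(res_ms) || res_ms < .Machine$double.eps)) {
    Fv[-nrow(a)] <- Inf
    p[-nrow(a)] <- .Machine$double.xmin
  }
  data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
             mean_sq = a$`Mean Sq`, F = Fv, p = p,
             stars = p_stars(p), stringsAsFactors = FALSE)
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Variance components for genotype, environment and treatment
#'
#' Estimates the random-model variance components V_G, V_GE, V_GT (and V_GET
#' when replicates allow) and V_R.  Balanced data may use the closed-form
#' expected-mean-squares (EMS) method; the default is REML via
#' \code{lme4::lmer} with genotype, environment, treatment and their two-way
#' interactions as random factors.  Negative EMS estimates are truncated to 0
#' and flagged.
#'
#' @inheritParams lsmeans
#' @param model `"line"` (unreplicated trial: V_GET is confounded with the
#'   residual) or `"founder"` (replicated: V_GET estimated separately).
#' @param method `"reml"` or `"ems"` (EMS requires balanced data).
#' @return object of class `"variance_components"`: list with `V_G`, `V_GE`,
#'   `V_GT`, `V_GET` (`NA` for the line model), `V_R`, `e`, `t`, `r`,
#'   `method`, `truncated`.
#' @export
variance_components <- function(pheno, trait = NULL,
                                model = c("line", "founder"),
                                method = c("reml", "ems")) {
  model <- match.arg(model); method <- match.arg(method)
  ph <- check_pheno(pheno, trait)
  ph$line <- factor(ph$line); ph$env <- factor(ph$env)
  ph$treatment <- factor(ph$treatment)
  e <- nlevels(ph$env); t <- nlevels(ph$treatment)
  r <- if (model == "founder") max(table(ph$line, ph$env, ph$treatment)) else 1L
  truncated <- character(0)
  if (method == "ems") {
    if (!is_balanced(ph)) stop("EMS method requires balanced data; use REML")
    ms <- balanced_mean_squares(ph)
    ms_res <- ms[["Residuals"]]
    if (r > 1L) {
      ms_get <- ms[["line:env:treatment"]]
      raw <- c(V_G = (ms[["line"]] - ms[["line:env"]] - ms[["line:treatment"]] +
                        ms_get) / (r * e * t),
               V_GE = (ms[["line:env"]] - ms_get) / (r * t),
               V_GT = (ms[["line:treatment"]] - ms_get) / (r * e),
               V_GET = (ms_get - ms_res) / r,
               V_R = ms_res)
    } else {
      raw <- c(V_G = (ms[["line"]] - ms[["line:env"]] - ms[["line:treatment"]] +
                        ms_res) / (e * t),
               V_GE = (ms[["line:env"]] - ms_res) / t,
               V_GT = (ms[["line:treatment"]] - ms_res) / e,
               V_GET = NA_real_,
               V_R = ms_res)
    }
    truncated <- names(raw)[!is.na(raw) & raw < 0]
    raw[!is.na(raw) & raw < 0] <- 0
    vc <- as.list(raw)
  } else {
    re <- c("(1 | line)", "(1 | env)", "(1 | treatment)",
            "(1 | line:env)", "(1 | line:treatment)", "(1 | env:treatment)",
            if (r > 1L) "(1 | line:env:treatment)")
    f <- stats::as.formula(paste("value ~", paste(re, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = ph,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore"))))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    get_vc <- function(grp) {
      i <- match(grp, vcdf$grp)
      if (is.na(i)) NA_real_ else vcdf$vcov[i]
    }
    vc <- list(V_G = get_vc("line"), V_GE = get_vc("line:env"),
               V_GT = get_vc("line:treatment"),
               V_GET = if (r > 1L) get_vc("line:env:treatment") else NA_real_,
               V_R = get_vc("Residual"))
  }
  structure(c(vc, list(e = e, t = t, r = r, model = model, method = method,
                       truncated = truncated)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s model, %s): V_G=%.4g V_GE=%.4g V_GT=%.4g V_GET=%s V_R=%.4g  [e=%d t=%d r=%d]\n",
              x$model, x$method, x$V_G, x$V_GE, x$V_GT,
              if (is.na(x$V_GET)) "NA" else sprintf("%.4g", x$V_GET),
              x$V_R, x$e, x$t, x$r))
  if (length(x$truncated))
    cat("  negative estimates truncated to 0:",
        paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

# Mean squares of the balanced three-way crossed design (genotype x
# environment x treatment with n replicates), computed from cell means --
# avoids forming the huge fixed-effects model matrix for large populations.
balanced_mean_squares <- function(ph) {
  a <- nlevels(ph$line); b <- nlevels(ph$env); cc <- nlevels(ph$treatment)
  cells <- tapply(ph$value, list(ph$line, ph$env, ph$treatment), mean)
  n <- nrow(ph) / (a * b * cc)
  g <- mean(cells)
  mA <- apply(cells, 1L, mean); mB <- apply(cells, 2L, mean)
  mC <- apply(cells, 3L, mean)
  mAB <- apply(cells, c(1L, 2L), mean); mAC <- apply(cells, c(1L, 3L), mean)
  mBC <- apply(cells, c(2L, 3L), mean)
  ssA <- b * cc * n * sum((mA - g)^2)
  ssAB <- cc * n * sum((sweep(sweep(mAB, 1L, mA), 2L, mB) + g)^2)
  ssAC <- b * n * sum((sweep(sweep(mAC, 1L, mA), 2L, mC) + g)^2)
  res3 <- cells -
    outer(mAB, rep(1, cc)) -
    aperm(outer(mAC, rep(1, b)), c(1L, 3L, 2L)) -
    aperm(outer(mBC, rep(1, a)), c(3L, 1L, 2L)) +
    outer(mA, matrix(1, b, cc)) +
    aperm(outer(mB, matrix(1, a, cc)), c(2L, 1L, 3L)) +
    aperm(outer(mC, matrix(1, a, b)), c(2L, 3L, 1L)) - g
  ssABC <- n * sum(res3^2)
  out <- c("line" = ssA / (a - 1),
           "line:env" = ssAB / ((a - 1) * (b - 1)),
           "line:treatment" = ssAC / ((a - 1) * (cc - 1)))
  if (n > 1) {
    cell_of <- cells[cbind(as.integer(ph$line), as.integer(ph$env),
                           as.integer(ph$treatment))]
    ssE <- sum((ph$value - cell_of)^2)
    out <- c(out, "line:env:treatment" = ssABC / ((a - 1) * (b - 1) * (cc - 1)),
             "Residuals" = ssE / (a * b * cc * (n - 1)))
  } else {
    out <- c(out, "Residuals" = ssABC / ((a - 1) * (b - 1) * (cc - 1)))
  }
  out
}

#' Broad-sense heritability from variance components
#'
#' Line (unreplicated) model:
#' \deqn{h^2 = V_G / (V_G + V_{GE}/e + V_{GT}/t + V_R/(e t))}
#' Founder (replicated) model:
#' \deqn{h^2 = V_G / (V_G + V_{GE}/e + V_{GT}/t + V_{GET}/(e t) + V_R/(e t r))}
#'
#' @param vc a [variance_components()] object, or a named list with fields
#'   `V_G`, `V_GE`, `V_GT`, (`V_GET`,) `V_R`, `e`, `t` (, `r`).
#' @param model `"line"` or `"founder"`; defaults to the model recorded in
#'   `vc`.
#' @return h-squared in `[0, 1]`.
#' @export
heritability <- function(vc, model = NULL) {
  model <- model %||% vc$model %||% "line"
  e <- vc$e; t <- vc$t
  stopifnot(e >= 1, t >= 1)
  denom <- if (model == "founder") {
    r <- vc$r
    stopifnot(r >= 1)
    vc$V_G + vc$V_GE / e + vc$V_GT / t + vc$V_GET / (e * t) + vc$V_R / (e * t * r)
  } else {
    vc$V_G + vc$V_GE / e + vc$V_GT / t + vc$V_R / (e * t)
  }
  if (is.na(denom) || denom <= 0)
    stop("heritability undefined: phenotypic variance of genotype means is 0")
  vc$V_G / denom
}

#' Descriptive statistics of per-line trait means
#'
#' @param x numeric vector of per-line means (one scope).
#' @return one-row data.frame: `lsmean`, `sd`, `min`, `max`, `n`,
#'   `cv_percent` (reported at one decimal, half-up; `NA` with a warning for
#'   zero-mean traits).
#' @export
descriptives <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2L)
  m <- mean(x); s <- stats::sd(x)
  data.frame(lsmean = m, sd = s, min = min(x), max = max(x), n = length(x),
             cv_percent = cv_percent(s, m))
}

#' Coefficient of variation in percent
#' @param sd,mean standard deviation and mean of a positive-mean trait.
#' @param digits decimals for half-up rounding (default 1, as reported).
#' @return CV = sd/mean x 100, rounded.
#' @export
cv_percent <- function(sd, mean, digits = 1) {
  if (any(mean == 0)) { warning("CV undefined for zero mean"); }
  ifelse(mean == 0, NA_real_, round_half_up(sd / mean * 100, digits))
}

#' Pearson correlations among traits with significance stars
#'
#' @param lsm numeric matrix, lines x traits, of per-line means in one scope.
#' @return list with `r` (correlation matrix), `p` (two-sided t-test
#'   p-values), `stars`, `n` (pairwise complete sample sizes).
#' @export
pearson_correlations <- function(lsm) {
  lsm <- as.matrix(lsm)
  stopifnot(ncol(lsm) >= 1L)
  zerovar <- apply(lsm, 2L, function(v) stats::var(v, na.rm = TRUE)) == 0
  if (any(zerovar)) warning("zero-variance trait(s): ",
                            paste(colnames(lsm)[zerovar], collapse = ", "))
  r <- suppressWarnings(stats::cor(lsm, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(lsm))
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  diag(p) <- NA
  list(r = r, p = p, stars = matrix(p_stars(p), nrow(p),
                                    dimnames = dimnames(p)), n = n)
}

#' Simple-matching genetic similarity and PCA
#'
#' Pairwise similarity is the fraction of identical genotype calls over SNPs
#' where both individuals have calls.  Population structure is summarized by
#' a principal component analysis of the similarity matrix (centered columns),
#' with percent variance explained per axis.
#'
#' @param geno character genotype matrix, individuals x SNPs (calls such as
#'   `"AA"`, `"AG"`; `"NN"` = missing).  Use [panel_genotypes()] to append
#'   founders.
#' @param n_axes number of principal axes to return.
#' @return list of class `"similarity_pca"`: `similarity` (symmetric matrix,
#'   unit diagonal), `scores` (individuals x `n_axes`), `var_explained`
#'   (percent per axis, sums to <= 100).
#' @export
similarity_pca <- function(geno, n_axes = 5L) {
  geno <- as.matrix(geno)
  N <- nrow(geno)
  stopifnot(N >= 2L)
  obs <- geno != "NN" & !is.na(geno)
  vals <- unique(as.vector(geno[obs]))
  match_counts <- matrix(0, N, N)
  for (v in vals) {
    iv <- (geno == v) & obs
    match_counts <- match_counts + tcrossprod(iv * 1)
  }
  shared <- tcrossprod(obs * 1)
  S <- match_counts / shared
  S[shared == 0] <- NA
  diag(S) <- 1
  dimnames(S) <- list(rownames(geno), rownames(geno))
  n_axes <- min(n_axes, N - 1L)
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(similarity = S, scores = pc$x[, seq_len(n_axes), drop = FALSE],
                 var_explained = ve[seq_len(n_axes)]),
            class = "similarity_pca")
}

#' Founder genotypes as diploid call strings
#'
#' @param panel a `founder_panel`.
#' @return 8 x M character matrix of homozygous calls (e.g. `"AA"`).
#' @export
panel_genotypes <- function(panel) {
  g <- matrix(paste0(panel$alleles, panel$alleles), nrow(panel$alleles),
              ncol(panel$alleles), dimnames = dimnames(panel$alleles))
  g
}
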