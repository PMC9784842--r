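# Downstream of the association scan: merging marker-trait associations into
# QTL, treatment-scope accounting, pleiotropy windows, stepwise yield
# prediction and the transgression report.

#' Merge marker-trait associations into QTL
#'
#' Significant MTAs of the same trait are joined by single-linkage
#' clustering, where two MTAs are linked iff the squared correlation of their
#' marker columns in the population is at least `r2_min`, or they lie on the
#' same chromosome less than `cm_window` cM apart.  Each cluster becomes one
#' QTL named `Q<TRAIT>_<chrom>` (letter suffixes disambiguate several QTL of
#' one trait on one chromosome).  MTAs from different scopes (N0, N1,
#' across) enter jointly; the QTL records every scope in which a member is
#' significant.
#'
#' @param mtas one or more `mta_table`s (rows with `significant == TRUE` are
#'   used), e.g. `rbind`-ed across scopes, or a list of `hb_gwas` fits.
#' @param X population marker matrix (or `marker_matrix`) for the pairwise
#'   LD among MTA markers.
#' @param r2_min LD link threshold (default 0.8).
#' @param cm_window map-distance link threshold in cM (default 5, exclusive).
#' @return data.frame of class `"qtl_set"`: `qtl`, `trait`, `chrom`,
#'   `start_cM`, `end_cM`, `n_mta`, `scopes` (comma-separated),
#'   `best_marker`, `min_bon_p`, `best_founder_effects` (the best marker's
#'   effect spread over its carrier founders), `unmapped` (flag: a member
#'   lacked a map position), plus a `members` attribute (list of member MTA
#'   marker/scope data.frames).
#' @export
merge_mtas <- function(mtas, X, r2_min = 0.8, cm_window = 5) {
  if (inherits(mtas, "hb_gwas")) mtas <- list(mtas)
  if (is.list(mtas) && !is.data.frame(mtas))
    mtas <- do.call(rbind, lapply(mtas, function(f)
      if (inherits(f, "hb_gwas")) f$mta else f))
  if (inherits(X, "marker_matrix")) X <- X$X
  m <- mtas[mtas$significant, , drop = FALSE]
  if (!nrow(m)) return(empty_qtl_set())
  if (is.null(m$chrom)) stop("MTA table lacks map metadata")
  res <- list(); members <- list()
  for (tr in unique(m$trait)) {
    mt <- m[m$trait == tr, , drop = FALSE]
    u <- !duplicated(mt$marker)
    um <- mt[u, , drop = FALSE]
    k <- nrow(um)
    links <- NULL
    if (k > 1L) {
      cols <- X[, um$marker, drop = FALSE]
      r2m <- suppressWarnings(stats::cor(cols))^2
      r2m[is.na(r2m)] <- 0
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        ld_link <- r2m[a, b] >= r2_min
        cm_link <- !is.na(um$cM[a]) && !is.na(um$cM[b]) &&
          um$chrom[a] == um$chrom[b] && abs(um$cM[a] - um$cM[b]) < cm_window
        if (ld_link || cm_link) links <- rbind(links, c(a, b))
      }
    }
    comp <- uf_components(k, links)
    for (cc in unique(comp)) {
      sel <- um$marker[comp == cc]
      mem <- mt[mt$marker %in% sel, , drop = FALSE]
      best <- mem[order(mem$bon_p, mem$marker), , drop = FALSE][1L, ]
      fe_str <- NA_character_
      if (!is.null(best$founders) && !is.na(best$founders)) {
        fe <- tryCatch(suppressWarnings(
          founder_effects(best$effect, best$founders)), error = function(e) NULL)
        if (!is.null(fe))
          fe_str <- paste(sprintf("%s:%.4g", names(fe), fe), collapse = ",")
      }
      res[[length(res) + 1L]] <- data.frame(
        trait = tr, chrom = best$chrom,
        start_cM = suppressWarnings(min(mem$cM, na.rm = TRUE)),
        end_cM = suppressWarnings(max(mem$cM, na.rm = TRUE)),
        n_mta = nrow(mem),
        scopes = paste(sort(unique(mem$scope)), collapse = ","),
        best_marker = best$marker, min_bon_p = best$bon_p,
        best_founder_effects = fe_str,
        unmapped = anyNA(mem$cM), stringsAsFactors = FALSE)
      mem_out <- mem[, c("marker", "trait", "scope", "effect", "bon_p")]
      mem_out <- mem_out[order(mem_out$marker, mem_out$scope), , drop = FALSE]
      rownames(mem_out) <- NULL
      members[[length(members) + 1L]] <- mem_out
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$start_cM[!is.finite(out$start_cM)] <- NA_real_
  out$end_cM[!is.finite(out$end_cM)] <- NA_real_
  # deterministic order and naming: trait, chromosome, position
  ord <- order(out$trait, out$chrom, out$start_cM, out$best_marker)
  out <- out[ord, , drop = FALSE]; members <- members[ord]
  ids <- character(nrow(out))
  key <- paste(out$trait, out$chrom)
  for (kk in unique(key)) {
    i <- which(key == kk)
    base <- paste0("Q", out$trait[i[1L]], "_", out$chrom[i[1L]])
    ids[i] <- if (length(i) == 1L) base else paste0(base, letters[seq_along(i)])
  }
  out <- cbind(qtl = ids, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(members) <- ids
  attr(out, "members") <- members
  if (any(out$unmapped))
    warning(sum(out$unmapped), " QTL contain MTAs without map positions")
  class(out) <- c("qtl_set", "data.frame")
  out
}

empty_qtl_set <- function() {
  out <- data.frame(qtl = character(0), trait = character(0),
                    chrom = character(0), start_cM = numeric(0),
                    end_cM = numeric(0), n_mta = integer(0),
                    scopes = character(0), best_marker = character(0),
                    min_bon_p = numeric(0),
                    best_founder_effects = character(0),
                    unmapped = logical(0))
  attr(out, "members") <- list()
  class(out) <- c("qtl_set", "data.frame")
  out
}

qtl_scope_list <- function(qtls) strsplit(qtls$scopes, ",", fixed = TRUE)

#' Treatment-scope accounting of QTL
#'
#' Counts QTL per trait and scope (N0, N1, across), QTL unique to a single
#' scope, and the percentage of QTL detected under exactly one of the two N
#' treatments -- reported at one decimal, half-up.
#'
#' @param qtls a [merge_mtas()] result.
#' @return list of class `"qtl_accounting"`: `by_trait` (data.frame with
#'   per-scope and unique counts and MTA counts), `totals` (named vector),
#'   `pct_single_treatment_unique`, `pct_across_unique`.
#' @export
classify_scopes <- function(qtls) {
  sc <- qtl_scope_list(qtls)
  scopes <- c("N0", "N1", "across")
  traits <- sort(unique(qtls$trait))
  rows <- lapply(traits, function(tr) {
    i <- qtls$trait == tr
    cnt <- vapply(scopes, function(s) sum(vapply(sc[i], function(x)
      s %in% x, TRUE)), 0L)
    uni <- vapply(scopes, function(s) sum(vapply(sc[i], function(x)
      identical(x, s), TRUE)), 0L)
    data.frame(trait = tr, n_qtl = sum(i), n_mta = sum(qtls$n_mta[i]),
               t(cnt), t(stats::setNames(uni, paste0(scopes, "_unique"))),
               stringsAsFactors = FALSE)
  })
  by_trait <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  totals <- colSums(by_trait[, -1L, drop = FALSE])
  n <- nrow(qtls)
  pct1 <- if (n) round_half_up((totals[["N0_unique"]] + totals[["N1_unique"]])
                               / n * 100, 1) else NA_real_
  pcta <- if (n) round_half_up(totals[["across_unique"]] / n * 100, 1)
          else NA_real_
  structure(list(by_trait = by_trait, totals = totals,
                 pct_single_treatment_unique = pct1,
                 pct_across_unique = pcta),
            class = "qtl_accounting")
}

#' @export
print.qtl_accounting <- function(x, ...) {
  print(x$by_trait)
  cat(sprintf("Single-treatment-unique QTL: %.1f%%; across-unique: %.1f%%\n",
              x$pct_single_treatment_unique, x$pct_across_unique))
  invisible(x)
}

#' Scan for pleiotropic loci
#'
#' Groups QTL on the same chromosome whose cM spans lie within a `cm_window`
#' window (single linkage on the span gap) and reports groups affecting at
#' least two distinct traits.
#'
#' @param qtls a [merge_mtas()] result.
#' @param cm_window window size in cM (default 5, exclusive on the gap).
#' @return data.frame: `locus`, `chrom`, `anchor_cM` (span midpoint),
#'   `start_cM`, `end_cM`, `n_traits`, `traits` (canonical order), `qtls`.
#' @export
pleiotropy_scan <- function(qtls, cm_window = 5) {
  q <- qtls[!is.na(qtls$start_cM), , drop = FALSE]
  out <- list()
  for (ch in sort(unique(q$chrom))) {
    qi <- q[q$chrom == ch, , drop = FALSE]
    k <- nrow(qi)
    links <- NULL
    if (k > 1L) for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      gap <- max(0, max(qi$start_cM[a], qi$start_cM[b]) -
                    min(qi$end_cM[a], qi$end_cM[b]))
      if (gap < cm_window) links <- rbind(links, c(a, b))
    }
    comp <- uf_components(k, links)
    for (cc in unique(comp)) {
      g <- qi[comp == cc, , drop = FALSE]
      traits <- sort(unique(g$trait))
      if (length(traits) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, anchor_cM = mean(c(min(g$start_cM), max(g$end_cM))),
        start_cM = min(g$start_cM), end_cM = max(g$end_cM),
        n_traits = length(traits),
        traits = paste(traits, collapse = ","),
        qtls = paste(g$qtl, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(locus = character(0), chrom = character(0),
                      anchor_cM = numeric(0), start_cM = numeric(0),
                      end_cM = numeric(0), n_traits = integer(0),
                      traits = character(0), qtls = character(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(res$chrom, res$anchor_cM), , drop = FALSE]
  cbind(locus = sprintf("PL%02d", seq_len(nrow(res))), res,
        stringsAsFactors = FALSE)
}

# Forward stepwise OLS minimizing SBC over an arbitrary predictor matrix.
sbc_forward <- function(Xp, y) {
  cs <- step2_sbc_cofactors(Xp, y, colnames(Xp))
  sel <- cs$markers
  C <- cbind(`(Intercept)` = 1, Xp[, sel, drop = FALSE])
  f <- ols_fit(C, y)
  r2 <- 1 - f$sse / sum((y - mean(y))^2)
  list(selected = sel, coefficients = stats::setNames(f$coef, colnames(C)),
       r2 = r2, sbc_path = cs$sbc_path, fitted = as.vector(C %*% f$coef))
}

#' Stepwise yield prediction from QTL markers and component traits
#'
#' Forward-stepwise OLS minimizing the Schwarz criterion over the pooled set
#' of significant yield-QTL marker columns and agronomic/developmental
#' component traits; a markers-only model is fitted alongside for comparison.
#'
#' @param y per-line yield LSMEANS for the scope.
#' @param qtl_markers matrix of 0/1 significant yield-QTL marker columns.
#' @param components matrix of per-line component-trait LSMEANS (e.g. TGW,
#'   GNE, EAR, HEA, MAT, HEI); may be `NULL`.
#' @param scope label stored with the model.
#' @return object of class `"yield_prediction"`: `selected`, `coefficients`,
#'   `r2`, `selected_markers_only`, `r2_markers_only`, `scope`, `prediction`
#'   (data.frame of observed and fitted values).
#' @export
predict_yield <- function(y, qtl_markers, components = NULL,
                          scope = "across") {
  qm <- if (is.null(qtl_markers)) NULL else as.matrix(qtl_markers)
  comp <- if (is.null(components)) NULL else as.matrix(components)
  pool <- cbind(qm, comp)
  if (is.null(pool) || ncol(pool) == 0L)
    stop("no predictors supplied")
  full <- sbc_forward(pool, y)
  mo <- if (!is.null(qm) && ncol(qm)) sbc_forward(qm, y)
        else list(selected = character(0), r2 = 0)
  structure(list(selected = full$selected, coefficients = full$coefficients,
                 r2 = full$r2, selected_markers_only = mo$selected,
                 r2_markers_only = mo$r2, scope = scope,
                 prediction = data.frame(line = names(y) %||% seq_along(y),
                                         observed = as.vector(y),
                                         fitted = full$fitted)),
            class = "yield_prediction")
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat(sprintf("Yield prediction (%s): %d predictors selected by SBC, R2 = %.3f\n",
              x$scope, length(x$selected), x$r2))
  cat(sprintf("  markers-only model: %d predictors, R2 = %.3f\n",
              length(x$selected_markers_only), x$r2_markers_only))
  invisible(x)
}

#' Transgressive segregation report
#'
#' Compares the best line against the best founder on a common scope.
#'
#' @param line_means named per-line trait means.
#' @param founder_means named per-founder trait means.
#' @return list: `best_line`, `best_line_value`, `best_founder`,
#'   `best_founder_value`, `gain` (best line minus best founder),
#'   `gain_percent` (one decimal, half-up), `n_lines_exceeding`.
#' @export
transgression_report <- function(line_means, founder_means) {
  line_means <- line_means[!is.na(line_means)]
  founder_means <- founder_means[!is.na(founder_means)]
  if (!length(line_means) || !length(founder_means)) stop("empty input")
  bl <- which.max(line_means); bf <- which.max(founder_means)
  gain <- line_means[[bl]] - founder_means[[bf]]
  list(best_line = names(line_means)[bl] %||% bl,
       best_line_value = line_means[[bl]],
       best_founder = names(founder_means)[bf] %||% bf,
       best_founder_value = founder_means[[bf]],
       gain = gain,
       gain_percent = round_half_up(gain / founder_means[[bf]] * 100, 1),
       n_lines_exceeding = sum(line_means > founder_means[[bf]]))
}
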