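# End-to-end pipeline: simulate -> QC -> haploblocks -> phenotype statistics
# -> GWAS per trait and scope -> QTL merging, accounting, pleiotropy,
# prediction and transgression -- with a TSV/JSON output bundle.

#' Default pipeline configuration
#'
#' Thresholds default to the haplotype-GWAS conventions: QC at <5% missing
#' calls and MAF >5%, four-gamete blocks within 500 kb at D' = 1, haplotype
#' frequency >5%, 100 cross-validation repetitions, Bonferroni-Holm at 0.05,
#' QTL merging at r-squared >= 0.8 or <5 cM, 5 cM pleiotropy windows.
#'
#' @param n_lines,n_snps simulated population size.
#' @param selfing_gens selfing generations after the 8-way cross.
#' @param diversity target founder similarity.
#' @param qtl planted QTL list for the yield trait (`list(snp =, effects =)`
#'   entries; `snp` may be an index into the retained map).
#' @param scopes GWAS scopes to run.
#' @return nested configuration list.
#' @export
pipeline_config <- function(n_lines = 400, n_snps = 2000, selfing_gens = 4,
                            diversity = 0.59, qtl = NULL,
                            scopes = c("N0", "N1", "across")) {
  list(
    sim = list(n_lines = n_lines, n_snps = n_snps, selfing_gens = selfing_gens,
               diversity = diversity, missing_rate = 0.02,
               trait = list(name = "YLD", qtl = qtl, V_G = 4, V_GE = 4,
                            V_GT = 1, V_R = 4, e = 7, t = 2, mu = 75,
                            treat_shift = 11)),
    qc = list(max_missing = 0.05, min_maf = 0.05, require_position = TRUE,
              reference = NULL),
    blocks = list(max_pair_bp = 5e5, fourth_gamete_max = 0.01,
                  dprime_required = 1, maf_min = 0.05, ht_min_freq = 0.05),
    gwas = list(n_reps = 100, train_frac = 0.8, alpha = 0.05, scopes = scopes),
    qtl = list(r2_min = 0.8, cm_window = 5, pleiotropy_window = 5))
}

#' Run the full haplotype-GWAS pipeline on a simulated population
#'
#' Simulates founders, the funnel cross and phenotypes, applies SNP QC,
#' builds four-gamete haploblocks and the 0/1 marker matrix, computes
#' LSMEANS, variance components and heritability, runs the three-step GWAS
#' for each requested scope, merges significant MTAs to QTL and writes a TSV
#' output bundle plus a JSON manifest.  Identical seeds and configurations
#' give byte-identical bundles.
#'
#' @param config a [pipeline_config()] list (or a YAML file path with the
#'   same structure).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @return invisible list with all intermediate objects (`panel`, `pop`,
#'   `qc`, `blocks`, `markers`, `lsm`, `vc`, `h2`, `gwas` (per scope),
#'   `qtl`, `accounting`, `pleiotropy`, `transgression`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_stage("config", "yaml package required to read a YAML config")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_config(), config)
  seed <- as.integer(seed)
  sseed <- function(k) as.integer((as.numeric(seed) * 113 + k) %% 2e9)

  # --- simulate ---------------------------------------------------------
  sim <- cfg$sim
  panel <- tryCatch(
    simulate_founders(sim$n_snps, diversity = sim$diversity,
                      seed = sseed(1L)),
    error = function(e) stop_stage("simulate", conditionMessage(e)))
  pop <- funnel_cross(panel, sim$n_lines, sim$selfing_gens, seed = sseed(2L))
  tr <- sim$trait
  if (!is.null(tr$qtl)) tr$qtl <- lapply(tr$qtl, function(q) {
    if (is.numeric(q$snp)) q$snp <- pop$map$snp[q$snp]
    q
  })
  arch <- trait_architecture(trait = tr$name, qtl = tr$qtl, V_G = tr$V_G,
                             V_GE = tr$V_GE, V_GT = tr$V_GT,
                             V_R = tr$V_R, e = tr$e, t = tr$t, mu = tr$mu,
                             treat_shift = tr$treat_shift, r = 4)
  pheno <- plant_phenotypes(pop, arch, seed = sseed(3L),
                            founder_panel = panel)
  pop_obs <- inject_missingness(pop, sim$missing_rate, seed = sseed(4L))

  # --- QC ---------------------------------------------------------------
  qc <- tryCatch(
    filter_snps(pop_obs, panel, cfg$qc$max_missing, cfg$qc$min_maf,
                cfg$qc$require_position),
    error = function(e) stop_stage("qc", conditionMessage(e)))
  pop_qc <- subset_snps(pop_obs, qc$retained)
  panel_qc <- subset_panel(panel, qc$retained)
  reference <- cfg$qc$reference %||% panel$founders[8L]
  dosage <- impute_mni(recode_reference(pop_qc, panel_qc, reference))

  # --- haploblocks and markers -----------------------------------------
  hb <- tryCatch(
    build_haploblocks(panel_qc, cfg$blocks$max_pair_bp,
                      cfg$blocks$fourth_gamete_max,
                      cfg$blocks$dprime_required, cfg$blocks$maf_min),
    error = function(e) stop_stage("blocks", conditionMessage(e)))
  calls <- call_haplotypes(hb, pop_qc, panel_qc)
  retained <- filter_haplotypes(calls, cfg$blocks$ht_min_freq)
  markers <- build_marker_matrix(retained, hb, calls, pop_qc, panel_qc)

  # --- phenotype statistics --------------------------------------------
  wm <- pheno[pheno$line %in% pop$lines, , drop = FALSE]
  lsm <- lapply(stats::setNames(nm = cfg$gwas$scopes), function(s)
    lsmeans(wm, tr$name, scope = s))
  vc <- variance_components(wm, tr$name, model = "line", method = "ems")
  h2 <- heritability(vc)
  fo <- pheno[pheno$line %in% panel$founders, , drop = FALSE]
  founder_lsm <- lsmeans(fo, tr$name, scope = "across")
  transgression <- transgression_report(lsm$across %||% lsm[[1L]], founder_lsm)

  # --- GWAS per scope ---------------------------------------------------
  fits <- lapply(stats::setNames(nm = cfg$gwas$scopes), function(s)
    tryCatch(hb_gwas(markers, lsm[[s]], trait = tr$name, scope = s,
                     n_reps = cfg$gwas$n_reps,
                     train_frac = cfg$gwas$train_frac,
                     seed = sseed(10L + match(s, cfg$gwas$scopes)),
                     alpha = cfg$gwas$alpha),
             error = function(e) stop_stage("gwas", conditionMessage(e))))

  # --- QTL --------------------------------------------------------------
  qtl <- merge_mtas(fits, markers, cfg$qtl$r2_min, cfg$qtl$cm_window)
  accounting <- classify_scopes(qtl)
  pleio <- pleiotropy_scan(qtl, cfg$qtl$pleiotropy_window)

  desc <- do.call(rbind, lapply(names(lsm), function(s)
    cbind(trait = tr$name, scope = s, descriptives(lsm[[s]]))))
  simpca <- similarity_pca(rbind(pop_qc$geno, panel_genotypes(panel_qc)),
                           n_axes = 2L)

  res <- list(panel = panel, pop = pop, pheno = pheno, qc = qc,
              blocks = hb, calls = calls, markers = markers,
              dosage = dosage, lsm = lsm, vc = vc, h2 = h2,
              descriptives = desc, simpca = simpca, gwas = fits, qtl = qtl,
              accounting = accounting, pleiotropy = pleio,
              transgression = transgression, config = cfg, seed = seed)

  if (!is.null(out_dir)) write_bundle(res, out_dir)
  invisible(res)
}

# Write the TSV/JSON output bundle of a pipeline run.
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_genotypes_tsv(res$pop$geno, fp("genotypes.tsv"))
  write_map_tsv(res$pop$map, fp("map.tsv"))
  write_pheno_tsv(res$pheno, fp("phenotypes.tsv"))
  write_tsv(res$qc$stats, fp("snp_qc.tsv"))
  write_tsv(res$blocks$blocks, fp("haploblocks.tsv"))
  write_tsv(res$calls$haplotypes, fp("haplotypes.tsv"))
  write_tsv(res$markers$info, fp("marker_info.tsv"))
  write_tsv(data.frame(line = rownames(res$markers$X), res$markers$X,
                       check.names = FALSE), fp("marker_matrix.tsv"))
  write_tsv(data.frame(line = rownames(res$dosage),
                       round(res$dosage, 6), check.names = FALSE),
            fp("dosages.tsv"))
  write_tsv(res$descriptives, fp("descriptives.tsv"))
  vc <- res$vc
  write_tsv(data.frame(V_G = vc$V_G, V_GE = vc$V_GE, V_GT = vc$V_GT,
                       V_GET = vc$V_GET, V_R = vc$V_R, e = vc$e, t = vc$t,
                       r = vc$r, h2 = res$h2), fp("heritability.tsv"))
  write_tsv(data.frame(id = rownames(res$simpca$scores),
                       res$simpca$scores,
                       check.names = FALSE), fp("pca_scores.tsv"))
  trace <- do.call(rbind, lapply(names(res$gwas), function(s)
    data.frame(scope = s, marker = names(res$gwas[[s]]$trace$inclusion),
               inclusion_count = unname(res$gwas[[s]]$trace$inclusion),
               robust = names(res$gwas[[s]]$trace$inclusion) %in%
                 res$gwas[[s]]$trace$robust)))
  write_tsv(trace[trace$inclusion_count > 0L, ], fp("selection_trace.tsv"))
  mta <- do.call(rbind, lapply(res$gwas, function(f) f$mta))
  write_tsv(mta, fp("mta.tsv"))
  man <- do.call(rbind, lapply(res$gwas, manhattan_export))
  write_tsv(man, fp("manhattan.tsv"))
  write_tsv(as.data.frame(res$qtl), fp("qtl.tsv"))
  write_tsv(res$accounting$by_trait, fp("qtl_accounting.tsv"))
  write_tsv(res$pleiotropy, fp("pleiotropy.tsv"))
  tg <- res$transgression
  write_tsv(data.frame(best_line = tg$best_line,
                       best_line_value = tg$best_line_value,
                       best_founder = tg$best_founder,
                       best_founder_value = tg$best_founder_value,
                       gain = tg$gain, gain_percent = tg$gain_percent,
                       n_lines_exceeding = tg$n_lines_exceeding),
            fp("transgression.tsv"))
  files <- sort(list.files(out_dir, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- basename(files)
  manifest <- list(
    seed = res$seed,
    thresholds = res$config[c("qc", "blocks", "gwas", "qtl")],
    h2 = res$h2,
    n_lines = length(res$pop$lines),
    n_snps_retained = length(res$qc$retained),
    n_markers = ncol(res$markers$X),
    n_significant_mta = sum(mta$significant),
    n_qtl = nrow(res$qtl),
    file_md5 = as.list(md5))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
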