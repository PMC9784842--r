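Package: maghap
Title: Haplotype-Based GWAS for Multi-Parent (MAGIC) Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for haplotype-based genome-wide
    association studies in eight-way MAGIC (multi-parent advanced generation
    intercross) populations of inbred lines.  Provides a map-driven funnel-cross
    simulator with planted multi-allelic QTL and multi-environment phenotypes;
    SNP quality control with reference-founder dosage recoding, mean imputation
    and genetic-map interpolation; four-gamete-rule haploblock construction from
    founder gametes with haplotype calling and 0/1 presence marker coding;
    phenotype statistics (least-squares means, fixed-effects ANOVA, variance
    components, broad-sense heritability, trait correlations, simple-matching
    similarity and PCA); a three-step cofactor-conditioned GWAS
    (cross-validated stepwise screening, Schwarz-criterion cofactor selection,
    per-marker conditional tests with Bonferroni-Holm correction and
    founder-specific effects); and downstream QTL merging, treatment
    classification, pleiotropy scanning and stepwise yield prediction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, lme4, emmeans, jsonlite
Suggests: testthat (>= 3.0.0), vcfR, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
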