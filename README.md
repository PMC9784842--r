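# maghap — haplotype-based GWAS for eight-way MAGIC populations

Multi-parent advanced generation intercross (MAGIC) populations cross eight
inbred founders through a funnel and self the offspring to recombinant
inbred lines (RILs).  Because every chromosome is a mosaic of eight founder
haplotypes, association mapping gains power by testing *haplotypes* —
multi-allelic runs of SNPs in complete founder LD — instead of single
biallelic SNPs, and every marker effect translates directly into an effect
of a named founder allele, which is what a breeder needs.

`maghap` is a simulation and analysis toolkit for this design, aimed at
quantitative geneticists working with multi-parent cereal populations
(the defaults emulate an 800-line winter wheat MAGIC trial under two
nitrogen treatments in seven environments):

* **Simulator** — inbred founders at a target genetic similarity, map-driven
  funnel cross (Haldane recombination, Poisson crossovers), planted
  multi-allelic QTL with per-founder effects, and phenotypes with variance
  components V<sub>G</sub>, V<sub>GE</sub>, V<sub>GT</sub>, V<sub>GET</sub>,
  V<sub>R</sub> over *e* environments × *t* treatments.
* **QC** — SNP filters (<5% missing, MAF >5%, mapped, complete founder
  calls), reference-founder 0/1/2 dosage coding, mean imputation, and linear
  genetic-map interpolation.
* **Haploblocks** — Haploview-style four-gamete-rule blocks built from the
  eight founder gametes (<500 kb, one gamete class below frequency 0.01,
  D′ = 1), haplotype calling in the population (recombinant haplotypes
  included), frequency filtering, and a 0/1 presence marker matrix
  (one column per haplotype, two per singular SNP).
* **Phenotype statistics** — LSMEANS, fixed-effects ANOVA, variance
  components (REML or balanced EMS), broad-sense heritability
  h² = V<sub>G</sub> / (V<sub>G</sub> + V<sub>GE</sub>/e + V<sub>GT</sub>/t +
  V<sub>R</sub>/(e·t)), descriptive tables with CV, Pearson correlations,
  simple-matching similarity and PCA.
* **Three-step GWAS** (`hb_gwas()`) — 100× cross-validated stepwise
  screening (moves accepted only while the validation-set ASE decreases),
  Schwarz-criterion (SBC) cofactor selection,
  and a cofactor-conditioned scan of every marker with sequential tests,
  Bonferroni–Holm correction (BON_p < 0.05) and founder-specific effects.
* **QTL layer** — merging significant associations into QTL (r² ≥ 0.8 or
  <5 cM, single linkage), N0/N1/across treatment classification, 5-cM
  pleiotropy windows, SBC-stepwise yield prediction from QTL markers plus
  component traits, and transgression reports.

## Worked example

Simulate a 400-line population with one planted yield QTL carried by
founders F01 and F02 (+4 dt/ha each), run the full chain, and inspect it:

```r
library(maghap)

panel <- simulate_founders(1500, diversity = 0.59, seed = 1)
pop   <- funnel_cross(panel, 400, selfing_gens = 4, seed = 2)
arch  <- trait_architecture(
  trait = "YLD", mu = 75, treat_shift = 11,
  qtl = list(list(snp = pop$map$snp[700],
                  effects = c(4, 4, 0, 0, 0, 0, 0, 0))),
  V_G = 4, V_GE = 4, V_GT = 1, V_R = 4, e = 7, t = 2)
pheno <- plant_phenotypes(pop, arch, seed = 3)

hb      <- build_haploblocks(panel)
calls   <- call_haplotypes(hb, pop, panel)
markers <- build_marker_matrix(filter_haplotypes(calls), hb, calls, pop, panel)

vc  <- variance_components(pheno, "YLD", method = "ems")
y   <- lsmeans(pheno, "YLD", scope = "across")
fit <- hb_gwas(markers, y, trait = "YLD", scope = "across", seed = 4)
qtl <- merge_mtas(fit, markers)
```

This prints (abridged):

```
Haploblock set: 210 blocks ( 2-4 SNPs each ), 1044 singular SNPs
Marker matrix: 400 lines x 2743 markers ( 655 haplotypes, 2088 singular-SNP alleles )
Variance components (line model, ems): V_G=6.26 V_GE=3.972 V_GT=1.127 V_GET=NA V_R=4.021  [e=7 t=2 r=1]
h2 = 0.815
Haplotype GWAS: trait YLD, scope across, 400 lines, 2743 markers
  robust markers: 14; cofactors: 8; significant MTAs (BON_p < 0.05): 2
  explained variance of significant markers: R2 = 0.275
      qtl chrom start_cM   end_cM n_mta    best_marker   min_bon_p
1 QYLD_2A    2A 130.8237 134.8314     2 Chr2A_HB048_02 0.000161654
```

The planted QTL sits at 130.6 cM on chromosome 2A; the scan recovers it as
`QYLD_2A` from two significant haplotype markers whose founder memberships
(`01000000`, `10000000`) point back at the two planted carrier founders.
`founder_effects(2.13, "01000000")` spreads the marker effect onto founder
F02, the others staying at the zero baseline.  The heritability 0.815 is
what the planted architecture implies for genotype means over 7 environments
and 2 treatments.

`plot(fit)` draws the Manhattan plot with the BON_p = 0.05 line;
`run_pipeline(pipeline_config(...), seed, out_dir)` executes the whole chain
and writes a TSV/JSON bundle (byte-identical under identical seeds), and
`inst/cli/maghap.R` wraps it for shell use.

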