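---
title: "Haplotype-based GWAS in eight-way MAGIC populations: models and methods"
author: "maghap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based GWAS in eight-way MAGIC populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maghap)
```

# Scope

`maghap` implements an analysis chain for multi-parent advanced generation
intercross (MAGIC) populations of inbred lines: a funnel-cross simulator, SNP
quality control, four-gamete-rule haploblock construction, haplotype presence
markers, multi-environment phenotype statistics, a three-step
cofactor-conditioned genome-wide association scan with Bonferroni–Holm
family-wise correction and founder-specific effects, and downstream merging of
associations into QTL with treatment classification, pleiotropy windows and
stepwise yield prediction.

The package is organized around one central fit: `hb_gwas()` runs the
three-step scan for one trait and scope and returns a classed object with
`print`, `summary`, `coef` and `plot` (Manhattan) methods.  The surrounding
steps — simulation, QC, block building, phenotype statistics, QTL merging —
are plain functions because they are transformations between well-defined
data structures rather than model fits.

# The synthetic MAGIC design

The simulator emulates an eight-parent winter wheat MAGIC design: 8 fully
inbred elite founders, an eight-way funnel cross
((1×2)×(3×4)) × ((5×6)×(7×8)), and several generations of selfing to
near-fixation (default four, approximating an F~4:6~ bulk with residual
heterozygosity retained rather than forced to zero).

* **Founders.** `simulate_founders()` draws biallelic SNPs on a synthetic map
  (default four 150-cM, 750-Mb chromosomes; cM linear in bp).  The per-SNP
  minor-allele founder count is a two-point mixture chosen so the expected
  mean pairwise simple-matching similarity equals the `diversity` target.
  The default target 0.59 reflects the similarity typical of modern elite
  wheat panels.  With 8 founders and all SNPs polymorphic the achievable mean
  similarity is the open interval (12/28, 21/28); targets outside it error.
* **Meiosis.** Crossover counts per chromosome are Poisson with mean equal to
  the map length in Morgans, positions uniform on the cM scale and no
  interference (Haldane).  This is the simplest defensible recombination
  model; nothing downstream depends on interference.
* **Funnels.** Founders are paired in input order, one funnel per line with
  independent meioses ("unique funnels").  Whether real designs replicate
  funnels across lines varies; a shared-funnel variant would only add
  between-line covariance that none of the implemented statistics use.
* **Truth tracking.** The founder-of-origin mosaic of both haploid strands is
  recorded per line; planted QTL are evaluated on the mosaic, so the
  simulation truth is exact even after masking genotype calls.

Phenotypes follow a components-of-variance observation model: for line $i$,
environment $l$, treatment $t$ (and replicate $r$ for founders),

$$y_{ilt(r)} = \mu + E_l + T_t + g_i + (gE)_{il} + (gT)_{it} + (gET)_{ilt}
  + \varepsilon_{iltr},$$

with $g_i$ the genotypic value (planted QTL contributions from the mosaic
plus a polygenic draw with variance $V_G$) and independent normal draws with
variances $V_{GE}$, $V_{GT}$, $V_{GET}$, $V_R$.  Defaults in the pipeline
configuration (seven environments, two nitrogen treatments, a positive
treatment shift for the standard-nitrogen level) mirror a two-season,
multi-location trial with contrasting nitrogen fertilization.  What the
generator deliberately does not emulate: genotyping error, segregation
distortion, selection during line development, spatial field trends, and
non-normal trait distributions — conclusions from passing tests therefore
concern the statistical machinery, not robustness to those artifacts.

# SNP quality control and numeric coding

`filter_snps()` retains SNPs with missing-call rate `< 0.05`, population
minor-allele frequency `> 0.05` (computed in the lines, not the founders,
because the mapping resolution depends on segregation in the population),
complete founder calls, and a known map position.  `recode_reference()`
translates ACGT calls to reference-founder allele dosages (2 homozygous
reference, 1 heterozygous, 0 homozygous other), `impute_mni()` fills missing
dosages with the SNP mean, and `interpolate_map()` places unmapped SNPs
between their two closest mapped neighbours linearly in bp, clamping beyond
the terminal anchors (the behaviour at chromosome extremes is not dictated
by any published rule; clamping keeps the completed map monotone).

# Haploblocks and haplotype markers

Blocks are built from the **founder gametes only** — the eight inbred
founders each contribute one gamete, so two-locus gamete frequencies are
simple counts over eight haplotypes.  `build_haploblocks()` scans each
chromosome left to right and extends a block while the next consecutive SNP
is (i) within 500 kb of the previous member, (ii) shows at most three of the
four possible gametes at frequency ≥ 0.01 against it, and (iii) is in
complete LD (D′ = 1) with it.  This is the pairwise-consecutive four-gamete
rule; extension is greedy with no backtracking.  SNPs in no block are kept
as *singular SNPs*.

`call_haplotypes()` reads each line's allele string per block.  Homozygous
complete calls give the string directly — strings absent from all founders
are legal (recombinants formed inside a block) and are counted.
Heterozygous calls are resolved against the founder haplotypes: if exactly
one unordered pair of founder strings explains the genotype, the line
carries both haplotypes; otherwise the block call is missing.  Residual
heterozygosity near F~6~ is a few percent, so ambiguous calls are rare.
Haplotype frequency is the allele-dose frequency among resolved lines
(homozygous carriers count twice), which makes frequencies within a block
sum to exactly 1.

`filter_haplotypes()` keeps haplotypes with frequency > 0.05 and no missing
nucleotide.  `build_marker_matrix()` then codes one 0/1 presence column per
retained haplotype plus **two** columns per singular SNP (one per allele), so
the marker count obeys K = #haplotypes + 2 × #singular SNPs.  Lines whose
rare haplotype was filtered keep all-zero rows in that block; a line missing
its call at a singular SNP scores 0 in both allele columns (absence coding).
Founder membership (an 8-bit flag string) is attached to every column, which
is what later turns marker effects into founder effects.

# Phenotype statistics

* `lsmeans()` — least-squares means per line from a fixed-effects model with
  genotype, environment, treatment and all two-way interactions, equal-weight
  marginalization (for balanced data these are the arithmetic means and are
  computed as such; unbalanced data go through `lm` + `emmeans`).
* `anova_fixed()` — sequential fixed-effects ANOVA with significance stars
  at 0.05/0.01/0.001.  Saturated or zero-residual designs report F = ∞ and a
  p-value at the machine floor rather than NaN.
* `variance_components()` — REML (`lme4`) by default; for balanced designs a
  closed-form expected-mean-squares estimator computed from cell means (used
  as the oracle cross-check in the tests, and much faster at 800 lines).
  Negative estimates are truncated to zero and flagged.  In the unreplicated
  line model the genotype×environment×treatment term is confounded with the
  residual; with replicates (the founder model) it is estimated separately.
* `heritability()` — broad-sense heritability on a genotype-mean basis:
  line model $h^2 = V_G / (V_G + V_{GE}/e + V_{GT}/t + V_R/(et))$, founder
  model with the additional $V_{GET}/(et)$ and $V_R/(etr)$ terms.  The
  divisors follow the plot-mean reading of the variance components — the only
  reading consistent with e, t and r being the numbers of environments,
  treatments and replicates.
* `descriptives()`, `pearson_correlations()`, `similarity_pca()` — trait
  summaries with CV reported at one decimal (half-up), pairwise Pearson
  correlations with two-sided t-tests, and simple-matching similarity over
  shared non-missing calls with a PCA of the similarity matrix.

# The three-step GWAS

Step 1 (`step1_cv_screen()`) repeats 100 times: split the lines 80/20 into
training and validation, then run stepwise selection where the forward
candidate is the marker with the largest training sum-of-squares reduction
and a move (forward or backward) is accepted only if it strictly decreases
the validation-set mean squared prediction error (ASE) of the training-fit
model.  Selecting the candidate *by* validation ASE instead would optimize
over thousands of markers against 20% of the data and floods the robust set
with noise markers (we measured several hundred under a pure null); the
implemented schedule matches the classic cross-validated stepwise procedure
in which the training criterion proposes and the validation error disposes.
Ties go to the smaller marker index; markers included in more than one of
the 100 terminal models form the robust set.

Step 2 (`step2_sbc_cofactors()`) runs a single forward selection over the
robust markers on the full data, minimizing the Schwarz Bayesian criterion
$SBC = n\ln(SSE/n) + k\ln n$ with $k$ counting the intercept.  Entry
requires a strict decrease; perfectly collinear candidates are skipped
deterministically.

Step 3 (`step3_scan()`) tests **every** marker by OLS with the step-2
cofactors (in entry order) in the background.  The marker's effect is its
coefficient given the cofactors, its partial R² is the sequential (type-I)
R² after the cofactors, and its p-value the sequential t-test — a marker
that is itself a cofactor is tested with itself removed from the background.
Markers collinear with the background report p = 1 and are flagged.
Bonferroni–Holm correction over all tested markers declares significance at
BON~p~ < 0.05.  Because step 3 tests all markers and Holm corrects over the
full family, the family-wise error guarantee does not depend on the
screening steps; the acceptance suite verifies this on a 200-run global-null
Monte Carlo.  Founder effects are read directly off the marker effect and
the column's founder membership: carriers receive the effect, non-carriers
the zero baseline (a marker carried by all eight founders has no contrast
and errors).

Numerical notes: all stepwise machinery works on residualized candidate
columns (Frisch–Waugh), with forward steps vectorized over candidates and
the validation side materialized lazily; degenerate candidates are screened
by a squared-norm tolerance of 1e-8; rank-deficient backgrounds fall back to
a QR pseudo-inverse.  With no cofactors the scan reduces to closed-form
univariate OLS to 1e-10 relative accuracy (tested).

# QTL merging and downstream summaries

`merge_mtas()` joins significant same-trait associations (across all scopes
jointly) by single linkage, linking two markers when their population r² is
at least 0.8 **or** they lie within 5 cM on the same chromosome.  The two
thresholds are reported as interchangeable operational rules in the
literature this design follows; the union is the conservative closure, and
single linkage is the simplest transitive completion of a pairwise rule.
QTL are named `Q<TRAIT>_<chrom>` with letter suffixes on collisions.
`classify_scopes()` tabulates QTL per scope (N0, N1, across), scope-unique
QTL, and the percentage detected under exactly one nitrogen treatment at one
decimal (half-up).  `pleiotropy_scan()` groups QTL of different traits whose
spans fall within a 5-cM window.  `predict_yield()` pools significant
yield-QTL marker columns with component-trait means and selects predictors
by the same forward-SBC routine, also reporting a markers-only model, whose
R² is never higher.  `transgression_report()` compares the best line with
the best founder (absolute and percent gain, count of transgressive lines).

# Problem sizes, tolerances and defaults

The test and acceptance suites use desk-scale designs chosen to keep every
Monte Carlo informative: a 400-line × ~2,000-marker null with 200 full
three-step runs for the family-wise error check (bound 0.05 plus two
Monte-Carlo standard deviations); 800 lines and a planted haplotype QTL at
roughly 10% of the variance of the analyzed line means for the power check
(≥ 80% detection); five 800-line replicates for variance-component (±20%)
and heritability (±0.08) recovery; 2,000 SNPs for the founder-similarity
target (±0.05).  Tunable thresholds and their defaults: QC missingness 0.05
and MAF 0.05; block distance 500 kb, fourth-gamete frequency 0.01, D′ = 1,
haplotype frequency 0.05; 100 cross-validation repetitions at an 80%
training fraction; BON~p~ 0.05; merge r² 0.8 and 5-cM window; 5-cM
pleiotropy window.  All randomness flows through explicit seeds; identical
seeds reproduce output bundles byte for byte.

# Known limitations

Only the funnel design with exactly eight founders is implemented for the
crossing scheme; the GWAS itself is agnostic to how the 0/1 markers arose.
There is no kinship or population-structure correction — in a balanced
MAGIC design relatedness is homogeneous by construction, but applying the
scan to structured material would inflate associations.  The stepwise
screening schedule is one deterministic member of a family of equivalent
procedures; on real data the robust set (though rarely the final QTL list)
can differ between implementations.  Variance components assume normal,
homoscedastic deviations, and the pleiotropy window is a positional
heuristic, not a test of a shared causal variant.
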