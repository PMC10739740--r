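---
title: "Methods: co-expression modules and master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`comodmr` infers phenotype-associated co-expression modules from a
case-control bulk RNA-seq count matrix and asks whether any module gene has
genetic and protein-interaction support for being a *driver* ("master
regulator") of the module's expression shift. This vignette explains each
model, the tunable parameters and their defaults, the design decisions
taken where the procedure was genuinely open, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## Count model and QC

Raw input is a gene × sample matrix of non-negative integer counts in a
`SummarizedExperiment` with the sample table as `colData`. QC follows a
fixed recipe:

* **Gene filter.** Keep a gene iff it has ≥ `min_count` (5) counts in
  ≥ `min_samples` (10) samples. The rule is idempotent and boundary
  conditions are exact (5 counts in exactly 10 samples is kept).
* **Normalisation and transform.** Size factors are median-of-ratios over
  genes with all-positive counts (fallback: library size over its
  geometric mean when no gene qualifies). The working scale is
  `log2(count/size_factor + 1)`. A parametric variance-stabilising
  transform would differ in the tails, but every downstream network
  quantity is a Pearson correlation, which is insensitive to monotone
  rescaling of this kind; the divergence matters only if one tries to
  reproduce numbers computed on a different transform.
* **Outlier flagging.** Samples are clustered by average linkage on
  Euclidean distance over the `top_expressed` (100) most expressed genes.
  A sample is *flagged* when its singleton merge height exceeds
  `mean + k·sd` (k = 3) of all singleton merge heights. Visual tree
  inspection is not automatable, so a height rule replaces it; flagged
  samples are reported, never dropped silently. Under homogeneous
  Gaussian data the rule flags nothing in ≥ 95% of runs.
* **Variable genes.** The top `ceil(q·G)` genes by variance (q = 0.75),
  ties broken by gene id so the selection is deterministic. At
  G = 12,810 this keeps 9,608 genes (the ceiling of 9,607.5; a floor rule
  would give 9,607).
* **Residualisation.** Per gene, OLS on an intercept plus sex, batch,
  PCR cycles and the selected cell-proportion covariates (categorical
  covariates one-hot encoded, first level dropped). Residuals plus the
  fitted intercept are returned; orthogonality to the design holds at
  machine precision, and rank-deficient designs are rejected with the
  collinear columns named.

## Deconvolution covariates

Cell-type proportions are estimated by non-negative least squares of each
bulk sample's CPM on a CPM-scale signature (per-type mean of the labelled
single-cell reference), with coefficients renormalised to sum to one. A
reference-moment-matching estimator would need fitted moments from the
single-cell data; plain NNLS is fully specifiable, scale-invariant in the
bulk sample, and accurate to well under 0.05 mean absolute error at 5%
multiplicative noise — ample for covariate use. Cell types with mean
proportion strictly greater than 5% become covariates. When *every* type
passes, the kept proportions sum to one and are collinear with the
intercept, so the least abundant kept type is dropped. The NNLS system is
jointly rescaled by the mean signature value before solving; this leaves
the coefficients unchanged but keeps the active-set iteration
well-conditioned at CPM magnitudes.

## Signed-hybrid network, TOM, modules

* **Correlation.** Pearson, for reproducibility; the estimator is the one
  point where a robust alternative (biweight midcorrelation) could be
  substituted without changing any other step.
* **Adjacency.** `a_ij = cor_ij^β` when `cor_ij > 0`, else 0 ("signed
  hybrid": anti-correlated genes share no edge). β defaults to 6. The
  diagonal is zeroed so connectivities `k_i = Σ_j a_ij` exclude
  self-adjacency.
* **Soft-threshold report.** For each candidate β, connectivities are
  binned into 10 logarithmic bins (empty bins dropped) and
  `log10 p(k)` is regressed on `log10 k`; R² counts only when the slope
  is negative. The chosen power is the smallest candidate with
  R² ≥ 0.80, else the argmax with a warning. The default β = 6 is used
  when selection is not requested.
* **TOM.** `TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
  `ℓ = A²`, diagonal 1. The implementation is checked element-for-element
  against a brute-force evaluation of the formula (agreement < 1e-12).
* **Module detection.** Average linkage on `1 − TOM`; static cut at
  0.995 of the maximum merge height (configurable); clusters smaller than
  `min_module_size` (30) go to label 0; labels are renumbered by
  decreasing size; unassigned genes are rescued into their best-kME
  module when that kME exceeds 0.3. This replaces the adaptive
  tree-cutting heuristic with an automatable, testable rule; on planted
  two-module fixtures it recovers labels at ARI ≥ 0.9 in ≥ 18/20 seeds,
  and on pure noise it leaves ≥ 90% of genes unassigned. The adaptive
  heuristic can split nested branches that a static cut merges, so module
  *counts* on real data are not directly comparable.
* **Eigengenes.** Per module, genes are standardised across samples and
  the eigengene is the first right singular vector: unit norm, sign
  chosen so its correlation with the module's mean profile is positive.
  It equals the first principal-component score vector of an independent
  eigendecomposition up to sign (|cor| > 1 − 1e-10).
* **Merging.** Pairs of modules with eigengene correlation above
  `merge_cor` (0.75) merge iteratively; the operation is idempotent.
* **MM and GS.** Module membership is `cor(x_g, ME_m)`; gene
  significance is `cor(x_g, phenotype)` with the phenotype as 0/1.

## Eigengene association

One logistic regression per module of case status on the eigengene
(covariates optional; by default the expression is already residualised,
so none are added). The Wald p-values are BH-adjusted across modules and
`q < 0.20` is called significant — a deliberately liberal threshold for a
screening step whose hits are triaged by enrichment, colocalisation and
PPI evidence downstream. BH is used because "FDR" without a named
procedure means BH in this field. (Quasi-)separation is detected from
degenerate fitted probabilities together with a divergent estimate and
reported as non-estimable rather than returning a meaningless
coefficient; no penalised fallback is attempted in this version. Under
the null at 32/11 cases/controls, the test's type-I error at nominal 0.05
sits in [0.03, 0.07].

For subject-characteristics tables, `compareGroups()` tests categorical
2×2 counts by Fisher's exact test when any expected cell count is below 5
and by Pearson's chi-squared *without* continuity correction otherwise,
and numeric variables by the Wilcoxon rank-sum test (normal approximation
with tie correction). The expected-count rule is adopted because it is
the only single rule that reproduces, from the printed counts, all four
categorical p-values of the reference cohort table this pipeline targets
(33 asthmatics, 12 controls); a blanket exact test does not.

## Over-representation

For each gene set, `p = P(X ≥ n)` with
`X ~ Hypergeometric(|U|, N, |module|)`, BH across the collection,
`gene_ratio = n/|module ∩ U|`. The default universe is the post-filter
network gene set; a genome-wide universe inflates enrichment of anything
expression-restricted, so the universe is configurable and recorded. The
gene-ratio convention (overlap over module size) follows the common ORA
tooling; the alternative reading (module over set) is recoverable as
`n/N`.

## Colocalisation

Per SNP and trait, the Wakefield approximate Bayes factor uses
`r = W/(se² + W)`, `log ABF = ½·log(1−r) + z²r/2`, with prior effect SD
`√W` = 0.15 for quantitative traits and 0.20 (log-odds) for case-control.
Regional hypothesis sums are accumulated in log space (log-sum-exp; the
distinct-causal term as `S1·S2 − S12` via a log-difference), so outputs
stay finite for |z| ≤ 50. Priors `p1 = p2 = 1e-4`, `p12 = 1e-5` are the
conventional single-variant defaults; the cis window is 1 Mb around the
gene body and regions with fewer than 50 harmonised SNPs are skipped with
a warning. The source study states none of these choices, so all are
configurable and none is asserted as that study's. Harmonisation
intersects on SNP id, flips the second beta where alleles are swapped,
and drops strand-ambiguous palindromic SNPs with a logged count. PP4 >
0.5 is the evidence call. The implementation agrees with brute-force
enumeration of causal-configuration pairs to 1e-10, and on synthetic
regions with a shared (distinct) causal SNP, PP4 (PP3) exceeds 0.9 in ≥
95% of runs.

## SNP-to-gene annotation

Lead SNPs (|z| above a configurable threshold) are expanded with all
proxies at r² ≥ 0.7, then annotated by three independent rules: gene-body
overlap; nearest gene ending before and nearest gene starting after the
position (both flanks kept — the boundary convention is gene-body ends,
not TSS, and strand is ignored); and containment in a promoter-capture
interaction other-end, tagging the bait gene. Coordinates are BED-native
0-based half-open internally, converted at the readers (1-based inputs
via a flag). The output is the tagged union, and permuting the gene-model
input order never changes it.

## Master-regulator call

The top-gene set is
`{PP4 ≥ 0.5} ∪ {MM ≥ Q90 within own module AND |GS| ≥ Q90 over the
combined associated-module genes}`. Union semantics are used because
colocalisation lists are typically an order of magnitude shorter than the
MM/GS top decile, so an intersection would leave almost no network to
build; the operator, the per-module-vs-global MM quantile and
signed-vs-absolute GS are all configurable since reasonable conventions
differ.
Channel scores are recombined by the prior-corrected noisy-OR with prior
0.041 and a 0.4 combined-score floor (the standard interaction-database
conventions), with the co-expression, neighbourhood and gene-fusion
channels excluded — those channels would recycle the very co-expression
information the modules were built from. On a single active channel the
recombination round-trip is the identity to 1e-12.

The hub is the maximum-degree node of the subnetwork induced on the top
set (ties lexicographic, all reported). Its significance is an add-one
empirical p over B = 10,000 random same-size sets drawn without
replacement from the combined associated-module genes:
`p = (1 + #{stat_b ≥ observed})/(1 + B)` — strictly positive and
monotone in the observed degree.

**Discreteness of the permutation p.** The max-degree statistic is
integer-valued, so this p-value is discrete and, with ties counted in the
numerator, *super-uniform* under the null: `P(p ≤ α) ≤ α` holds (the test
is valid and conservative), but the p-distribution cannot pass an exact
continuous-uniformity test — its CDF touches the diagonal only at the
atoms of the null max-degree distribution and dips below it in between,
by roughly the largest atom mass. The suite therefore asserts the
conservative-validity direction, and a planted-hub fixture whose excess
edges lie inside the candidate set (the alternative the test is designed
to detect) reaches p ≤ 1e-4 at B = 10,000. A hub whose extra edges spread
uniformly over the module universe is *not* detectable by this statistic,
by design: the observed set is then no more interconnected than a random
one.

## Synthetic-data generator

The generator emulates the study conditions end to end: 32 cases and 11
controls; Poisson-lognormal counts (`count ~ Pois(L_s · exp(latent))`)
with per-gene lognormal baselines, a biological log-scale SD of 0.5, and
library sizes lognormal around 600 counts/gene — the depth of an ~8M-read
library over ~13k expressed genes; block co-expression built from latent
unit-variance module factors with gene-factor loading
`within_module_cor` (so two same-module genes correlate at the loading
squared); case-control shifts of `factor_effect` SD on the factors of the
associated modules; covariate effects (sex, batch, PCR cycles, cell
proportions) as per-gene random coefficients; Dirichlet cell proportions;
AR(1) LD (`R_ij = decay^|i−j|`) with marginal z-scores `R z_causal +
MVN(0, R)` and the standard `se = 1/√(2·N·maf·(1−maf))`; an Erdős–Rényi
PPI graph with per-channel scores and an optionally planted hub. A
negative-binomial count model was not used: overdispersion enters through
the lognormal latent, and every downstream statistic is
correlation-based, not likelihood-based. Each generator seeds the global
RNG once from the configuration seed plus a fixed per-generator offset,
so all outputs are byte-reproducible and sub-streams independent.

What it does **not** emulate: read-level structure (FASTQ, UMIs),
single-cell dropout, genuinely scale-free co-expression topology,
population LD beyond AR(1), or evidence-channel correlation structure in
the PPI scores. Passing tests therefore demonstrate correctness of the
algorithms under the assumed generating model, not performance on real
data.

Two generator-design details matter for internal consistency. Marker
blocks of the single-cell reference occupy the *trailing* genes, away
from the planted modules at the head of the gene list: otherwise
estimated proportions track the module factors and residualisation
erases the planted structure — a real phenomenon (signature genes
overlapping disease modules) that the fixtures deliberately avoid. And
the planted hub sits ~10 genes into the associated block so that its cis
window contains the full summary-statistic region.

## Numerical choices and degenerate inputs

Log-space accumulation everywhere in colocalisation; exact-tie handling
by lexicographic gene id (variable-gene selection, hub ties) or
first-index (kME rescue); eigengene sign fixed by the mean-profile
orientation; modules of size zero skipped with a warning; empty module
sets propagate as empty results through association, enrichment and the
hub stage rather than erroring; all-zero NNLS coefficient vectors yield
uniform proportions with a warning; collinear signatures and rank-
deficient covariate designs are hard errors naming the offending columns.

## Problem sizes in the test-suite and acceptance runs

The suite exercises networks of 100–400 genes × 43 samples, regions of
60–150 SNPs, PPI graphs of 200–500 nodes, and B up to 10,000
permutations; the full pipeline fixture uses 400 genes with planted
modules of 90 and 70 genes. These sizes were chosen so the planted
structure is comfortably above the detection floor (module sizes well
above `min_module_size` after variable-gene attrition) while the whole
suite completes in about a minute; the algorithms themselves are dense
matrix computations with O(G²)–O(G³) cost, practical to a few thousand
genes on one core (a 500-gene network run completes in seconds).

## Limitations

* The static tree cut plus kME rescue is coarser than adaptive
  tree-cutting on real, nested dendrograms; module counts will differ.
* The log2 transform is not a parametric VST; correlation-based results
  are robust to this, absolute expression summaries are not.
* Single-causal-variant colocalisation only; allelic heterogeneity
  violates the five-hypothesis partition.
* NNLS deconvolution assumes the signature spans the bulk mixture;
  missing cell types are absorbed into the nearest available profile.
* The hub permutation detects enrichment of interconnection *within the
  candidate set*, not hubness per se (see above).
* Real-data reproduction of any specific cohort's module tables,
  enrichment lists and colocalisation hits requires that cohort's
  expression data and the external GWAS/eQTL/PPI resources, all outside
  this package's scope.
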