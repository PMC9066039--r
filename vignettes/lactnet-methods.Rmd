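---
title: "lactnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lactnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lactnet` re-implements, as a tested and reusable pipeline, an inference
chain that goes from assembled transcript models, expression values and GWAS
summary statistics to candidate functional long non-coding RNAs (lncRNAs) in
a longitudinal mammary-gland design: 15 RNA-seq samples from 3 individuals
at 5 stages around parturition (days −14, −10, −6, −2 before and +1 after).
This vignette documents the statistical models, the tunable parameters, the
synthetic-data generator the test suite runs on, and the design decisions
taken where the methodology was genuinely open.

## 1. lncRNA discovery cascade

Assembled transcripts are filtered in a fixed order; the first failing step
is recorded per transcript so the report partitions the input exactly:

0. **Assembly support.** Keep a model seen in ≥ 2 samples *or* supported by
   ≥ 2 assemblers. Everything else is treated as a likely assembly artifact.
1. **Class code.** gffcompare-style class codes: `=` transcripts are known
   genes and exit the cascade as *known*; only `u` (novel intergenic) and
   `i` (novel intronic) continue; all other codes are removed.
2. **Structure.** Length ≥ 200 nt and ≥ 2 exons (the conventional lncRNA
   length floor; single-exon models are too often incomplete assemblies).
3. **Expression.** Aggregated FPKM ≥ 0.3. The aggregation across the 15
   samples is configurable (`max`, the default, or `mean`); the source
   methodology states the threshold but not the aggregation rule, and `max`
   ("expressed somewhere") is the permissive reading that still removes
   never-expressed artifacts.
4. **Open reading frame.** Longest ATG-initiated, stop-terminated ORF in the
   three forward frames must be < 360 nt. The length *includes* the stop
   codon, so 360 nt corresponds to 119 aa + stop — the convention that makes
   "120 amino acids" and "360 nt" consistent with each other. Codons
   containing `N` never match a start or stop.
5. **Coding potential.** Three score columns (CPC/PLEK/CNCI-style, computed
   upstream, consumed as inputs). `coding_mode = "any"` (default) removes a
   transcript when *any* score is positive — the strictest lncRNA set;
   `"all"` implements the laxer conjunction reading. Both are tested.

Unknown strand `.` is scanned as sense strand with a warning: transcript
FASTA is transcript-oriented, so the choice only matters for malformed
inputs.

## 2. Differential expression

Counts are modeled per feature with a negative-binomial log-link GLM under
the two-factor design `~ individual + stage`, baseline stage −14. The NB
parameterization is `Var(y) = μ + φμ²` everywhere.

* **Normalization.** TMM factors against the column whose total is closest
  to the median total; log-ratios trimmed 30% each side, abundances 5%,
  inverse-variance weights, factors rescaled to geometric mean 1. Offsets
  are `log(library size × factor)`.
* **Dispersion.** A single common dispersion maximizes the Cox–Reid
  adjusted profile likelihood on a coarse log grid (`10⁻⁴…10`, 25 points),
  sharpened by quadratic interpolation through the best grid point and its
  neighbours. The interpolation matters: the raw grid quantizes φ by steps
  of ~60%, which alone shifted the empirical type-I error from ≈0.05 to
  ≈0.03 in null calibration runs. A common dispersion (rather than tagwise
  shrinkage) keeps the module self-contained; it is an approximation to the
  reference tooling, not a numerical reproduction of it.
* **Testing.** Each non-baseline stage is tested by a likelihood-ratio test
  against the design with that stage column removed (χ², 1 df). IRLS runs at
  most 50 iterations to a deviance tolerance of 1e−8; non-converged or
  all-zero features get `p = NA`. Benjamini–Hochberg adjustment is applied
  within each contrast ("adjusted p-value" with no stated method defaults to
  BH, the reference tool's default); DE means `p_adj < 0.05`.
* **Fold changes.** Reported from a fit with 0.5 added to all counts —
  stabilization for reporting only, never used in the test statistic.

Calibration is part of the acceptance suite: on 2,000 null NB features
(φ = 0.1, the 3 × 5 design) the empirical type-I error at α = 0.05 must lie
in [0.035, 0.065], and planted log2 fold changes of 2 at stage +1 with
μ = 100 must be recalled at ≥ 80% under BH 0.05.

## 3. Expression-pattern clustering

DE features are summarized as 5-point stage profiles (mean FPKM per stage),
z-scored per feature — shape, not level, defines a pattern, and without
standardization the highest-expressed features dominate every distance.
k-means uses Lloyd's algorithm with 25 random restarts, and labels are
renumbered by descending cluster size for determinism. The cluster number is
chosen by the Tibshirani gap statistic with uniform reference datasets drawn
per dimension over the data range (B = 50 by default) and the 1-SE rule:
the smallest k with `gap(k) ≥ gap(k+1) − s(k+1)`. Identical profiles yield
k = 1 with a warning rather than an error.

## 4. GWAS-signal enrichment

The enrichment statistic for a feature set is the sum of squared marker
effects, `T_sum = Σ β²`, over the `m_g` SNPs lying in the feature bodies
± 10 kb (each SNP counted once however many intervals cover it; strand
ignored). The null is built by drawing `m_g` SNPs uniformly without
replacement from the whole QC-passed universe, 10,000 times by default. No
LD or MAF matching is attempted — a documented limitation of the plain
count-matched permutation.

* The empirical p is one-tailed with the `(r + 1)/(N + 1)` correction and
  `≥` comparison (standard permutation-test practice; the plain strict
  proportion is available via `p_mode = "plain"`).
* Enrichment fold is `T_obs / mean(T_null)` — the natural reading of a
  sum-based enrichment factor; no formula is given in the source
  methodology.
* SNP QC before testing: minor allele frequency ≥ 0.01 and Hardy–Weinberg
  1-df χ² goodness-of-fit p ≥ 0.001, both computed from genotype counts.
* The milk-ability phenotype helper implements the litter-weight balance
  (weaning − born − fostered-in + died + fostered-out, kg); breeding-value
  estimation and GWAS fitting themselves are out of scope — per-SNP β are
  inputs.

Under an exchangeable null the fold converges to 1 and p is uniform; both
are asserted in the acceptance suite (rejection rate at 0.05 within
[0.03, 0.08] over 500 null universes), alongside exact agreement with full
enumeration on a C(4,2) toy universe.

## 5. Cis-target prediction

Candidate pairs are a lncRNA and a coding gene on the same chromosome whose
interval boundaries are ≤ 100 kb apart (overlap ⇒ distance 0). Distance is
measured body-to-body, not TSS-to-TSS — the 100 kb window is stated
"upstream/downstream" without an anchor, and body distance is symmetric and
strand-free. Expression correlation is Spearman (mid-ranks for ties) with
the two-sided t-approximation `t = ρ√((n−2)/(1−ρ²))`; `|ρ| = 1` maps to the
smallest positive double. Pairs with p < 0.05 are flagged, unadjusted by
default to match the stated rule; BH is available via `adjust = TRUE`. At
n = 15 the t-approximation's significance calls agree with exact permutation
enumeration in the cases where they can be compared exhaustively (n = 5,
|ρ| = 1), which the tests verify.

## 6. Co-expression modules

An unsigned weighted network: adjacency `a_ij = |cor(x_i, x_j)|^β`, with the
soft power β chosen as the smallest value whose connectivity distribution is
approximately scale-free (R² ≥ 0.8 of `log10 p(k)` against `log10 k` over a
10-bin histogram, counted only when the log–log slope is negative). Two
guards proved necessary in simulation and are part of the design:

* **Mean-connectivity floor** (`k_min = 1`): at extreme powers the adjacency
  of pure noise collapses toward zero and its degree histogram mimics a
  power law; requiring mean connectivity ≥ 1 removes exactly those spurious
  fits, so white noise falls back to the conventional default power 6 with a
  warning.
* **Negative-slope requirement**: a decaying degree distribution is what
  scale-free means; an increasing log–log trend must not count.

The topological overlap matrix is
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with unit
diagonal. Modules come from average-linkage clustering of `1 − TOM` with a
**static cut at a fixed height (0.95)**; branches of ≥ 5 features become
modules, the rest stay unassigned (label 0). A data-adaptive cut that
maximizes the number of large branches was implemented first and measured:
it systematically over-splits coherent blocks (median adjusted Rand index
0.69 on a two-block benchmark that the fixed cut recovers perfectly), so the
field's fixed-height static cut was adopted instead. Noise features sit near
TOM dissimilarity 1, above any sensible cut, which is what keeps the
procedure specific.

Each module is summarized by its eigengene — the first principal component
across samples of the members' standardized expression, sign-oriented so the
mean member correlation is positive — and associated with each stage's 0/1
sample indicator by Pearson correlation with Student-t p-values (n − 2 df).
Stage can alternatively be coded as a single quantitative day covariate.

## 7. The synthetic study

`simulate_dataset()` writes a complete self-consistent study with known
ground truth; every downstream stage is tested against it without any
external download. The stated world:

* 15 samples = 3 individuals × 5 stages; NB counts with common dispersion
  0.1 and log-normal baseline means around 100 counts; individual effects
  N(0, 0.1) on the log scale.
* Transcript classes `=`/`u`/`i` in proportions 0.5/0.3/0.2; 15% of novel
  transcripts are decoys violating *exactly one* discovery filter each
  (support, class code, length, exon count, expression, ORF, coding
  potential — cycled), which is what makes per-filter unit tests possible.
  Novel non-decoy sequences are rejection-sampled to carry no ORF ≥ 360 nt;
  ORF decoys carry one planted 399-nt ORF.
* Planted DE lncRNAs get a log2 fold change of 2 at stages −2 and +1
  (the stages where expression changes in the emulated biology); planted
  cis pairs share a latent log-expression profile at correlation 0.9 with a
  coding gene relocated within 100 kb; planted co-expression blocks share
  latent stage-tracking profiles (amplitude 1.5 on the log scale).
* SNPs are uniform on a 3-chromosome 150 Mb genome with effects
  N(0, 0.1); an enriched subset lands inside the planted DE lncRNA loci
  with effects at 5× the variance. Genotype counts for QC are drawn from
  Hardy–Weinberg proportions for 985 animals at allele frequencies
  U(0.05, 0.45). Effect scales are free parameters — the source reports no
  β scale for the trait — so only *relative* enrichment is meaningful.
* `simulate_null_gwas()` keeps the placement but draws every effect from
  the background distribution: the exchangeable null used for calibration.

What a green test does **not** establish: the generator has no LD structure,
no MAF–effect coupling, no length biases in FPKM, no tagwise dispersion, no
trans-regulation, and decoys violate exactly one filter (real artifacts
violate several). Results on real study data can therefore differ in ways
the suite cannot detect; the suite establishes that the implemented
procedures do what they claim on data whose truth is known.

## 8. Determinism and numerical choices

Every stochastic function takes a seed and restores the caller's RNG state.
The pipeline splits one global seed into fixed per-stage seeds, so toggling
one stage never perturbs another's randomness; two runs of `run_pipeline()`
with the same config are byte-identical, which the acceptance suite checks
file by file. Other numerical conventions: internal coordinates are 1-based
inclusive (GTF-native) and converted only at the BED boundary (0-based
half-open); IRLS linear predictors are clamped to ±30 to avoid overflow;
empirical p-values are floored at `1/(N+1)`; k-means labels and module
labels are size-ordered; BH propagates `NA` p-values untouched.

## 9. Known limitations

* The DE module approximates the reference tool (common dispersion, LRT);
  numerical identity with any particular edgeR version is a non-goal.
* The permutation null matches SNP count only; enrichment p-values on
  structured real genotypes will be anti-conservative in high-LD regions.
* The static module cut uses one fixed height; very heterogeneous module
  tightness would need the dynamic tree cut this package deliberately does
  not implement.
* Single-exon lncRNAs are excluded by design (step 2), as in the emulated
  discovery protocol.
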