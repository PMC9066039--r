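# lactnet

Candidate functional lncRNA discovery and lactation-stage expression
analysis for longitudinal RNA-seq designs.

## The problem

Mammary-gland RNA-seq sampled around parturition (here: 3 individuals × 5
stages, days −14, −10, −6, −2 and +1 relative to farrowing) yields thousands
of assembled transcript models. Which of them are credible long non-coding
RNAs, which change across lactation stages, and which of those changes
plausibly matter for a production trait such as milk ability? `lactnet`
implements the full inference chain as a reusable, tested R package:

1. **Discovery** — a multi-step filter cascade over assembled transcripts:
   assembly support, gffcompare class code (`u`/`i` novel vs `=` known),
   length ≥ 200 nt and ≥ 2 exons, FPKM ≥ 0.3, longest ORF < 360 nt, and
   coding-potential scores ≤ 0.
2. **Differential expression** — a self-contained negative-binomial GLM
   (`Var = μ + φμ²`, log link) under `~ individual + stage` with TMM
   offsets, common dispersion by Cox–Reid adjusted profile likelihood, and
   likelihood-ratio tests of each stage against the −14 baseline with BH
   adjustment.
3. **Pattern clustering** — k-means over z-scored 5-stage profiles with the
   Tibshirani gap statistic (uniform reference, 1-SE rule) choosing k.
4. **GWAS-signal enrichment** — the sum-based statistic
   `T_sum = Σ_{i=1..m_g} β_i²` over SNPs within a feature set ± 10 kb,
   against a null of `m_g` SNPs drawn uniformly without replacement from the
   QC-passed universe (MAF ≥ 0.01, Hardy–Weinberg χ² p ≥ 0.001); empirical
   one-tailed p and enrichment fold `T_obs / mean(T_null)`.
5. **Cis-target prediction** — coding genes within 100 kb of a lncRNA,
   Spearman correlation across the 15 samples, p < 0.05.
6. **Co-expression modules** — unsigned weighted network
   `a_ij = |cor|^β`, topological overlap matrix, static tree cut, module
   eigengenes and module–stage associations.

A first-class synthetic-data generator (`simulate_dataset()`) emits a
complete study — GTF, FASTA, coding scores, counts/FPKM/design, SNP table —
with known planted truth (decoy transcripts violating exactly one filter
each, planted fold changes, correlated cis pairs, enriched SNP sets,
co-expression blocks), so the whole chain is testable offline.

## Worked example

```r
library(lactnet)

cfg <- default_pipeline_config(seed = 1L,
                               sim_n_transcripts = 200L, sim_n_snps = 800L,
                               sim_n_enriched_snps = 40L, sim_n_de_lnc = 20L,
                               gap_B = 15L, enrich_n_perm = 1000L,
                               module_max_features = 100L)
res <- run_pipeline(cfg, "lactnet_run")
str(res$summary)
```

Output of this exact call (seed 1):

```
List of 11
 $ seed               : int 1
 $ n_lncrna           : int 85
 $ n_known            : int 100
 $ n_de_lncrna        : int 44
 $ dispersion         : num 0.267
 $ k_clusters         : int 8
 $ enrichment         :List of 2
  ..$ lncrna   : m_g 52, fold 3.33, p 0.000999
  ..$ de_lncrna: m_g 48, fold 3.59, p 0.000999
 $ n_candidate_pairs  : int 27
 $ n_significant_pairs: int 21
 $ n_modules          : int 1
 $ soft_power         : int 12
```

Reading it: of 200 simulated transcripts, 85 survive the discovery cascade
as lncRNA candidates and 100 are classified known (`=`); 44 lncRNAs are DE
against the −14 baseline in at least one contrast at BH 0.05; the gap
statistic picks 8 expression-pattern clusters; SNP effects are strongly
enriched in the DE lncRNA loci (48 SNPs assigned, observed `T_sum` 3.59×
the permutation-null mean, empirical p ≈ 0.001 at 1,000 permutations — the
generator planted 40 high-variance SNPs inside those loci); 21 of 27
cis candidate pairs correlate significantly; and the co-expression step
finds 1 module at soft power 12. The estimated common dispersion (0.267)
exceeds the generating value (0.1) because planted cis/module latent
variation is extra-Poisson noise the common-dispersion model absorbs.

Each stage directory under `lactnet_run/` holds its outputs (TSV/BED) plus
a `manifest.json` (parameters, derived seed, input md5 hashes);
`summary.json` aggregates the headline numbers. Running the same config
twice gives byte-identical outputs.

There is also a CLI wrapper:

```sh
Rscript -e 'lactnet::lactnet_main()' run-all --seed 1 --out lactnet_run
```

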