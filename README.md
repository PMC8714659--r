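# cernet

Competing endogenous RNA (ceRNA) network inference from paired case/control
expression profiles of mRNAs, lncRNAs, circRNAs and miRNAs — the analysis
used to nominate lncRNA/circRNA–miRNA–mRNA regulatory axes in diseases such
as Graves' ophthalmopathy, where a handful of miRNAs (miR-21, miR-27a/b,
miR-146a, miR-155) have experimentally established directions of
dysregulation in orbital fibroblasts.

## The method

Under the ceRNA hypothesis, a lncRNA or circRNA that shares a miRNA
response element with an mRNA competes for that miRNA: abundant ceRNA
sequesters the miRNA into RISC and de-represses the mRNA. `cernet` screens
for this signature with a filter chain:

1. quantile normalization of the log2 intensity matrix;
2. differential expression per feature: log2FC = mean(case) − mean(control),
   two-tailed pooled-variance Student's *t*; flagged when |log2FC| > 1 and
   p < 0.05;
3. canonical miRNA seed matching (6mer, 7mer-A1, 7mer-m8, 8mer; perfect
   Watson–Crick pairing to miRNA positions 2–7/8, target A opposite
   position 1) against the differentially expressed lncRNAs/circRNAs and
   mRNAs, with circular transcripts scanned across the back-splice
   junction;
4. intersection of (ceRNA, miRNA) and (mRNA, miRNA) pairs through shared
   miRNAs, cross-validated against a curated miRNA list with direction
   labels;
5. Pearson correlation of ceRNA vs mRNA expression across all samples,
   r > 0.95, with a direction-consistency rule
   (sign(ceRNA) = sign(mRNA) = −sign(miRNA));
6. network assembly (SIF/GraphML export), degree-based hub ranking on a
   STRING-style PPI edge list (combined score ≥ 0.4, top 30), and
   Fisher's-exact (hypergeometric tail) gene-set enrichment with BH
   q ≤ 0.05.

A synthetic-data generator (`generate_dataset()`) emulates the 3-vs-3
paired study design and plants known DE effects and ceRNA triples with
seed sites, so every stage — and the pipeline end-to-end — is validated
against a recoverable ground truth. See the vignette
(`vignettes/cerna-network-inference.Rmd`) for the model, parameter
semantics and generator design.

## Worked example

```r
library(cernet)

cfg <- pipeline_config(
  simulation = simulation_config(noise_sd = 0.05, rng_seed = 7),
  out_dir = "go_run")
manifest <- run_pipeline(cfg)
#> [simulate] generating synthetic dataset
#> [normalize] quantile normalization of 100 x 6 matrix
#> [de] 8 zero-variance feature(s) with differing means: p recorded as the 0 limit
#> [de] flagged: mRNA=5, lncRNA=3, circRNA=2, miRNA=5
#> [targets] 5 ceRNA-miRNA pairs, 5 mRNA-miRNA pairs
#> [cerna] 5 candidates -> 5 cross-validated -> 5 triples

manifest
#> cernet run manifest
#>   triples: 5  nodes: 15  edges: 10
#>   candidates: 5  cross-validated: 5

manifest$results$triples[, c("cerna_id", "mirna_id", "mrna_id", "r")]
#>      cerna_id        mirna_id  mrna_id         r
#> 1 circRNA_004  hsa-miR-27a-5p mRNA_026 0.9942481
#> 2 circRNA_006  hsa-miR-27b-5p mRNA_022 0.9893029
#> 3  lncRNA_003 hsa-miR-146a-5p mRNA_008 0.9968489
#> 4  lncRNA_008  hsa-miR-27a-3p mRNA_047 0.9975158
#> 5  lncRNA_015  hsa-miR-155-3p mRNA_040 0.9966119
```

The run simulated 100 features (50 mRNA, 20 lncRNA, 20 circRNA, 10 miRNA)
across 3 case and 3 control samples with 5 planted ceRNA triples at noise
0.05 log2 units. The DE screen flags 15 features (the planted effects);
seed scanning of the flagged transcripts yields exactly the planted
ceRNA–miRNA and mRNA–miRNA pairs; intersection, the curated-miRNA gate and
the r > 0.95 correlation filter pass all 5 planted triples and nothing
else — precision and recall 1.0 against the generator's truth table. The
`r` column is the pooled 6-sample Pearson correlation of each ceRNA–mRNA
pair. All stage artifacts (DE table, site/pair/triple tables, SIF and
GraphML network, node/edge attributes) are written under `out_dir`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/run-cerna-pipeline.R`:

```sh
Rscript inst/scripts/run-cerna-pipeline.R --simulate --seed 7 --out-dir run/
```

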