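# humiSig

Derivation and scoring of an aged-human-microglia gene signature from
purified-cell vs bulk-tissue RNA-seq.

## The problem

Microglia — the brain's resident innate immune cells — constitute only
about 12% of cells in the aged human cortex, yet carry much of the
genetic risk for Alzheimer's disease and other late-onset
neurodegeneration. Bulk cortical RNA-seq dilutes their program roughly
eight-fold; purified aged microglia are available only in small numbers.
This package implements, as reusable tested components, the analysis
that contrasts the two data types to define the genes preferentially
expressed by microglia in the aged brain, and everything downstream of
that signature:

* **Signature derivation** — per-dataset low-expression filtering
  (abundance < 0.1 in more than two samples), log2 transform, restriction
  to protein-coding (UniProt-flagged) genes, joint robust (Huber,
  k = 1.345) removal of per-sample GC-content and gene-length artifacts
  from the log-ratio against the grand mean, then the contrast
  Δ_g = mean(purified) − mean(bulk). The **FC set** is
  {g : Δ_g ≥ log2 4} (one-sided, boundary inclusive); the **PVAL set**
  additionally requires an empirical-Bayes moderated-t with
  Benjamini–Hochberg adjusted p < 0.05, where the moderated statistic
  shrinks per-gene variances via
  s̃² = (d₀s₀² + d s²)/(d₀ + d), with (d₀, s₀²) estimated from the spread
  of log s² by digamma/trigamma moment matching.
* **Gene-set statistics** — exact upper-tail hypergeometric
  over-representation P(X ≥ k) of the signature in disease gene sets
  over a configurable universe, and pre-ranked GSEA (weighted
  Kolmogorov–Smirnov running sum, gene-label permutation null, NES and
  permutation p).
* **Meta-feature trait association** — each signature gene scaled to
  unit variance and averaged per sample; univariate linear models of the
  score on age at death, sex, clinical AD, pathology burdens and APOE
  ε2/ε4 dosages.
* **Aging differential expression** — harmonization of an aged (n = 10)
  vs middle-aged (n = 3) microglia pair to reliably detected genes with
  optional quantile alignment, moderated-t classification at
  |log2 FC| > 2 and adjusted p < 0.05.
* **Proteome concordance** — overlap of a shotgun-proteomics table with
  the signature and Spearman correlation of protein vs transcript
  abundance.
* **Synthetic study generator** — seeded bulk mixtures (Dirichlet
  proportions around a 12% microglia fraction), planted markers, planted
  GC/length artifacts, trait effects, disease-set overlaps and a
  proteomics table, with full ground truth for recovery testing.

Data containers follow Bioconductor conventions: expression matrices are
`ExprMatrix` objects (a `SummarizedExperiment` with a raw/log2/normalized
scale tag), results are S4 classes with accessors
(`fcSet()`, `pvalSet()`, `signatureTable()`, `scoreValues()`, ...).

## Worked example

A complete synthetic study at the default conditions (3 cell types, 12%
microglia, 540 bulk samples, 10 purified replicates, 50 planted markers
per type):

```r
library(humiSig)
design <- MixtureDesign(seed = 1)
study  <- synthStudy(design)

res <- deriveMicrogliaSignature(study$purified, study$bulk, study$annotation)
res$signature
#> SignatureResult: 1752 genes tested
#>   FC set (fold change >= 4, purified > bulk): 50 genes
#>   PVAL set (+ BH adj p < 0.05): 50 genes

ora <- hypergeometricORA(fcSet(res$signature), study$diseaseSets,
                         signatureTable(res$signature)$gene)
head(ora, 3)
#>   set_name universe_size set_size signature_size overlap      p_value
#> 1  AD_like          1752       56             50      15 5.129539e-12
#> 2  MS_like          1752       57             50       8 1.410048e-04
#> 3  PD_like          1752       56             50       0 1.000000e+00

score <- metafeatureScore(res$bulk, fcSet(res$signature))
assoc <- associateTraits(score, study$traits)
assoc[assoc$trait %in% c("age_at_death", "apoe_e2_count"), 1:5]
#>          trait    estimate   std_error   t_value      p_value
#>   age_at_death  0.04187713 0.002887104 14.504891 1.776559e-40
#>  apoe_e2_count -0.19951373 0.049966426 -3.992956 7.432408e-05
```

Reading the output: the derivation tested 1752 genes present in both
datasets after filtering; all 50 planted microglia markers — and nothing
else — pass the 4-fold criterion, so recovery is perfect at these
conditions. The planted AD-like disease set shares 15 of its 56 genes
with the signature, far more than the hypergeometric null expects
(p ≈ 5×10⁻¹²), while the null PD-like set shows no enrichment. The
meta-feature rises with age at death and falls with APOE ε2 dosage — the
directions planted in the generator, mirroring the biology the signature
is used to probe.

`runPipeline(synthConfig(seed = 1), outDir = "out")` runs all stages in
one call and writes TSV/GMT/JSON outputs plus a parameter manifest; with
file-based configurations (see `readRunConfig()`) the same pipeline runs
on user-supplied matrices.

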