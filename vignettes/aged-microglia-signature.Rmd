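---
title: "Deriving and scoring an aged-microglia gene signature: models and methods"
author: "humiSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring an aged-microglia gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humiSig)
```

## The problem

Microglia make up roughly 12% of the cells of the human prefrontal cortex
and carry a disproportionate share of the genetic risk for late-onset
neurodegenerative disease. Bulk cortical RNA-seq therefore dilutes their
transcriptional program roughly eight-fold, while purified-microglia
RNA-seq from aged autopsy donors is rare and small (tens of samples at
most). **humiSig** implements the analysis that joins the two: genes whose
abundance in purified microglia exceeds their abundance in bulk cortex by
a large factor are, to first order, genes expressed primarily by
microglia. The derived signature is then used three ways — as a gene set
tested for over-representation of disease susceptibility genes, as a
per-sample meta-feature associated with clinicopathological traits in the
large bulk cohort, and as context for an aged-vs-middle-aged differential
expression comparison and a proteomic concordance check.

Because the cohort data underlying the original analysis are
access-controlled, the package ships a synthetic bulk-mixture generator
with complete ground truth. Every stage of the pipeline is tested against
that truth or against an independent oracle; nothing in the test suite
requires a download.

## The signature model

Let $x_{gs}$ be log2 abundance (FPKM-like, after a pseudocount) of gene
$g$ in sample $s$, where samples comprise $n_p$ purified-microglia
replicates and $n_b$ bulk samples.

**Preprocessing.** Genes with raw abundance below 0.1 in more than two
samples of a dataset are removed (an absolute-count rule, applied per
dataset); values are transformed as $\log_2(x + 1)$; genes without a
protein (UniProt) identifier are removed, with unannotated genes treated
conservatively as lacking one.

**Residual artifact normalization.** Library chemistry leaves sample-
specific biases in GC content and transcript length. For each sample the
log-ratio against the grand mean, $r_{gs} = x_{gs} - \bar x_{g\cdot}$, is
regressed on GC fraction and $\log_{10}$ length with a Huber M-estimator
(tuning constant 1.345, IRLS, at most 50 iterations, tolerance $10^{-8}$),
and the fitted component is subtracted. The robust loss matters: true
marker genes *are* outliers of this regression and must not leverage the
slopes. The two datasets are normalized **jointly** (`residualNormalizePair()`),
so a bias affecting all samples of one dataset is still visible against
the common grand mean; the purified-vs-bulk contrast is then invariant to
adding any $a\,\mathrm{gc} + b\log_{10}(\mathrm{len}) + c$ to one dataset,
a property the test suite checks to $10^{-6}$ in the noiseless case.

**Contrast and inference.** The per-gene contrast is
$\Delta_g = \bar x^{\text{pur}}_g - \bar x^{\text{bulk}}_g$. The *FC set*
is $\{g : \Delta_g \ge \log_2 4\}$ — one-sided (microglia-enriched only)
and boundary-inclusive. Significance uses an empirical-Bayes moderated t:
with pooled variance $s_g^2$ on $d$ degrees of freedom, variances are
squeezed toward a prior,
$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_p + 1/n_b}},$$
with $t_g$ referred to a t distribution on $d + d_0$ degrees of freedom.
$(d_0, s_0^2)$ are estimated from the spread of $\log s_g^2$ by moment
matching: $\operatorname{Var}(\log s^2) = \psi'(d/2) + \psi'(d_0/2)$ is
solved for $d_0$ by Newton inversion of the trigamma function, and $s_0^2$
follows from the mean. When the observed spread is no larger than the
chi-square sampling noise, $d_0 = \infty$ (complete shrinkage). Setting
`priorDf = 0` recovers the ordinary pooled t exactly, which the tests
assert to $10^{-9}$. Genes with zero variance in both groups get $p = 1$
when the difference is also zero; otherwise the shrunk variance keeps the
statistic finite. The *PVAL set* adds Benjamini–Hochberg adjusted
$p < 0.05$ to the FC criterion and is always a subset of the FC set.

Optional precision weights from `meanVarianceWeights()` — a lowess trend
(span 0.5) of $\sqrt{\mathrm{sd}_g}$ on $\bar x_g$, with weight equal to
the inverse fourth power of the predicted value, i.e. the reciprocal
predicted variance — can be passed to `moderatedT()`. This is a
deliberately simplified mean-variance weighting: with an intercept-only
gene model the fitted mean is the row mean, so weights are constant within
a gene, and exact reproduction of more elaborate observation-level
weighting schemes is a non-goal.

## Gene-set statistics

**Over-representation.** For universe size $N$, disease set size $K$
(after intersecting with the universe), signature size $n$ and overlap
$k$, the p-value is the exact hypergeometric upper tail
$P(X \ge k)$. Tests are one-sided (enrichment), reported unadjusted
across the handful of disease sets. The universe is the set of genes that
survived filtering in *both* datasets with a protein identifier — exactly
the genes the signature could have contained. The test suite verifies the
tail against exhaustive subset enumeration for every instance with
$N \le 12$ and against the worked value $155/4845$ at
$(N, K, n, k) = (20, 5, 4, 3)$.

**Pre-ranked GSEA.** Given a score-ranked list, the running sum gains
$|s_i|^w / \sum_{\text{hits}} |s|^w$ at set genes and loses $1/(N - |S|)$
elsewhere; the enrichment score is the extremum of larger magnitude
(signed). Numerical choices: ties in the ranking keep input order (stable
sort); if the positive and negative extrema tie in magnitude to within
$10^{-10}$, the negative one is reported; if all hit scores are zero at
$w > 0$, hit increments fall back to $1/|S|$. The null permutes gene
labels: NES is ES over the mean magnitude of same-sign null scores, and
the permutation p is $(1 + b)/(m + 1)$ with $b$ the number of same-sign
nulls at least as extreme and $m$ the number of same-sign nulls, so
$p \ge 1/(m+1)$ always. The implementation computes ES in closed form
from hit positions (the running sum is piecewise linear, so extrema occur
immediately after or before hits); tests compare it gene-by-gene against
a literal step-through scan, and its type-I error at $\alpha = 0.05$
against the binomial 99% band over 500 null sets.

## The meta-feature and trait association

Each signature gene is divided by its across-sample standard deviation
(no centering, following the construction of the trait analysis this
package reproduces; a `center` flag exists, and regression slopes are
identical either way since centering only shifts the score by a constant)
and averaged within a sample. The score is tested one trait at a time
with `lm(score ~ trait)` — slope, SE, t, two-sided p — mirroring a
clinicopathological association table with age at death, sex (male
reference), clinical AD status, pathology burdens, and APOE ε2/ε4 allele
dosages coded 0/1/2. With five primary hypotheses the conventional
threshold is $p < 0.01$; the package reports raw p-values and leaves
thresholding to the caller. Constant traits are flagged not-estimable; an
exact linear fit reports its slope with `std_error = 0` and a
`degenerate_exact_fit` note rather than fabricating infinite t values.

## Aging differential expression

Two microglia datasets (aged, $n = 10$; middle-aged reference, $n = 3$)
are restricted to genes detected — abundance $\ge 0.1$ in at least half
the samples — in *both* datasets, log-transformed, and by default
quantile-aligned on the combined matrix so the two protocols share one
value distribution. Moderated-t inference and BH adjustment classify
genes as `up` (log2 FC $> 2$ and adjusted $p < 0.05$, both strict),
`down` (symmetric), or `ns`. Swapping the datasets negates every fold
change and exchanges the classes exactly, which is asserted in the tests.
The detection rule's parameters are exposed because the comparable
published analysis defers its exact criterion to supplementary material.

## Proteome concordance

A protein table (iBAQ-like relative abundances) is mapped into the gene
namespace via its own `gene_id` column or a user-supplied two-column
mapping — never an online identifier service, for reproducibility — and
two quantities are reported: the exact overlap with the signature
(unmapped identifiers are listed, not silently counted) and the Spearman
correlation between protein abundance and mean log2 transcript abundance
across purified samples (median available as an option; which summary the
comparable published value used is not stated).

## The synthetic study generator

`synthStudy()` draws everything the pipeline consumes, under explicit
seeds with no hidden RNG state (the caller's `.Random.seed` is restored).
Defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| cell types | 3 | minimal mixture with a minority type |
| mean microglia fraction | 0.12 | microglia share of cortical cells |
| Dirichlet concentration | 200 | proportion SD ≈ 0.023 across donors |
| genes | 2000 | desk-scale transcriptome |
| markers per type | 50 | comfortably identifiable program |
| marker log2 effect | 6 | canonical microglia markers are 50–100× enriched |
| noise SD (log2) | 0.5 | typical biological + technical spread |
| GC / length artifact coefficient | 1 / 0.5 | visible but sub-biological bias |
| bulk samples / purified replicates | 540 / 10 | cohort scale |

Bulk samples are proportion-weighted mixtures of cell-type profiles times
a per-sample GC/length artifact ($2^{u_s(\beta_{gc}\,\mathrm{gc}_c +
\beta_{len}\log_{10}\mathrm{len}_c)}$ with $u_s$ uniform on $[-1, 1]$, so
the artifact averages out across samples but is recoverable per sample)
times lognormal noise. Baseline log2 abundance is N(3, 2.5), so a
realistic few percent of genes fall below the 0.1 detection threshold and
the filter does real work. Marker genes are always flagged with a protein
identifier (curated cell-type markers are protein-coding); other genes
carry the flag with probability 0.9.

Traits follow the generative form *trait = intercept + effect × program +
noise*, with the program the standardized microglia proportion; binary
traits threshold a unit-variance latent and APOE allele counts are
Binomial(2, p) with logit-linear p. Planted directions follow the
qualitative biology (program increases with age, is reduced by ε2 dosage,
ε4 null). One consequence of this direction of generation: the slope of
the *score-on-trait* regression is an attenuated function of the planted
latent effect, not the effect itself, so the slope-coverage check
simulates (score, trait) pairs directly from the linear model the
estimator fits — that is where a "planted slope" is well defined — while
type-I calibration and direction checks run through `generateTraits()`
itself.

For the aging comparison, `generateAgingPair()` plants up- and
down-effects of 3 log2 units on 50 + 50 genes whose baseline is at least
log2 8. The restriction is deliberate: a multiplicative down-effect on a
gene already at the detection floor is invisible after the detection
filter and the log-pseudocount, so planting it would make the "truth"
unobservable by construction rather than difficult statistically.

What the generator does **not** emulate: read-level sampling (no FASTQ,
no negative-binomial count noise), correlated gene-gene expression
modules, batch structure beyond the GC/length artifact, cross-type
expression of markers (markers are clean by construction), or linkage
between disease sets and real GWAS catalogs. Passing recovery tests
therefore demonstrates that the statistics do what they claim on data
matching their assumptions — not that the thresholds are optimal for any
particular real cohort.

## Problem sizes and numerical choices in the tests

The suite runs the full derivation at the default 2000 genes × 540 bulk
samples (a few seconds), GSEA calibration over 500 null sets of 200 genes
at 199 permutations, moderated-t null uniformity at 2000 genes, trait
null calibration over 1000 simulations at 100 samples, and slope coverage
over 200 replicates at 540 samples — sizes chosen so the whole suite
completes in well under a minute per file while keeping Monte-Carlo bands
meaningful. Key tolerances: exact-oracle comparisons at $10^{-12}$,
noiseless linear-algebra identities at $10^{-6}$–$10^{-9}$, calibration
rates judged against binomial 99% intervals.

## Known limitations

* The moderated-t prior estimation uses plain moment matching on all
  genes; no robustification against variance outliers and no
  mean-variance trend in the prior.
* Quantile alignment forces identical marginal distributions; with
  grossly asymmetric planted effects this slightly compresses true fold
  changes.
* The FC threshold of 4 is inherited as a convention; nothing in the
  package selects it from data.
* Protein–gene mapping is table-based only; ambiguous many-to-one
  mappings are collapsed by exact identifier match.
* The pipeline order (filter → log → identifier filter → joint robust
  normalization → contrast) is one defensible resolution of an ordering
  the underlying methods description leaves open; the stages are exposed
  individually so any other order can be composed.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 1)
report <- runPipeline(cfg, outDir = "humi_out")
report$signature
head(report$ora)
head(report$associations)
report$deCounts
```
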