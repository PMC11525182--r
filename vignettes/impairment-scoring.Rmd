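---
title: "Gene impairment scoring with set networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene impairment scoring with set networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rvatnet implements a trait-agnostic *gene impairment score* for rare-variant
association testing (RVAT), learned end-to-end from variant annotations, plus
the statistical machinery around it: burden/SKAT seed-gene discovery,
cross-validated ensembling without information leakage, gene-based association
testing with expected-allele-frequency (EAF) gating and conditional analysis,
pseudodosage export for single-marker frameworks, and rare-variant-augmented
phenotype prediction. Because real biobank genotypes are access-controlled,
the package ships a first-class synthetic-cohort generator with a known
ground-truth impairment function; every downstream claim in the test suite is
checked against that truth.

## The model

For individual $i$ and gene $j$, the input is the unordered set
$V_{ij} = \{a_k : \text{variant } k \text{ carried by } i,\ k \text{ assigned to } j\}$
of annotation vectors of the qualifying rare variants carried. The impairment
score is a deep set network

$$\psi(V_{ij}) = \sigma\!\left(\rho\!\left(\max_{a_k \in V_{ij}} \varphi(a_k)\right)\right),$$

with $\varphi$ a two-layer MLP of width 20, an element-wise maximum over the
set dimension, $\rho$ an MLP with two hidden layers of width 10 and a linear
output, and $\sigma$ the logistic function. Activations are leaky rectifiers
with negative slope 0.01. Because the pooling is a maximum, $\psi$ is
invariant to permutation and duplication of set members — the property-based
tests draw random parameters and verify this to full precision.

Training is multitask: for each training trait $p$ with seed-gene set
$S^{(p)}$,

$$\hat y_i^{(p)} = \mathbf{x}_i^\top \boldsymbol\alpha^{(p)}
  + \sum_{j \in S^{(p)}} w_j^{(p)}\, \psi(V_{ij}),$$

and the loss is the per-trait mean squared error averaged over traits. The
network parameters are shared across variants, genes and traits; only
$\boldsymbol\alpha^{(p)}$ and $w_j^{(p)}$ are trait-specific. Seed genes come
from the conventional burden/SKAT combined test, so the network learns *which
annotation patterns make a variant damaging* from genes whose trait relevance
was established by annotation-agnostic means.

### Key tunable parameters

| parameter | default | rationale |
|---|---|---|
| qualifying MAF, training | < 1% | wider rarity range gives the network more carriers to learn from |
| qualifying MAF, association | < 0.1% | the conventional rare-variant testing regime |
| CADD (PHRED) cutoff | > 5 | drops the bulk of near-neutral variants |
| variant-to-gene window | 300 bp around exons | captures proximal splice-region variants |
| EAF testability gate | ≥ 50 expected alleles | score tests are unstable below it |
| optimizer | AdamW, lr 0.001, weight decay 0.01 | decoupled decay; 0.01 is the optimizer's conventional default (the choice is not critical and is not tuned) |
| batch size | 1,024 individual–phenotype pairs | |
| epochs | min 50, max 1,000 | checkpoint = lowest validation loss reached *after* the minimum epoch count |
| early-stopping patience | 10 epochs | the epoch bounds alone leave stopping under-determined |
| validation holdout | 20% of individuals, drawn per trait | traits may have different missingness |
| CV scheme | K = 5 folds × R = 6 restarts | restart seeds derived deterministically from one base seed |
| Beta weights | Beta(MAF; 1, 25) | standard rare-variant up-weighting |
| SKAT MAC collapsing | MAC ≤ 10 → one pseudo-marker (per-individual max) | ultra-rare columns individually carry no kernel information |
| SKAT marker cap | 5,000 | wide outlier genes are skipped, flagged, and excluded from the Bonferroni multiplier |

## Numerical choices

**Score tests.** The burden score test is computed exactly as
$T = (\tilde g^\top r)^2 / (\hat\sigma^2\, \tilde g^\top \tilde g)$ with
$\tilde g$ the burden residualized on the covariates, compared against
$\chi^2_1$; for binary traits the logistic analogue uses working residuals
and expected information. The SKAT statistic
$Q = r^\top G W^2 G^\top r$ is compared against its null mixture
$\sum_i \lambda_i \chi^2_1$ via four-moment (Liu-type) matching, refined by
an Imhof-type numerical inversion integral whenever the matched p-value falls
below $10^{-4}$. Both tails are validated against permutation oracles and a
Monte-Carlo mixture simulation in the test suite. With one marker, SKAT and
the weighted burden test coincide; this identity is tested to $10^{-6}$.

**Empty variant sets.** $\psi := 0$ exactly, rather than feeding a zero
embedding through $\rho$: non-carriers sit at a clean baseline and exports
stay interpretable. Association tests are invariant to this constant (any
affine shift of a burden is absorbed by the intercept; also tested).

**Variable-size sets.** Rather than padding each gene's variant list to a
common length with a sentinel excluded from the max, the implementation pools
with a grouped max/argmax over a long (pair, variant) table. Padding can then
never contaminate a score by construction; the equivalent contracts —
order, duplication and batch-composition invariance, and insensitivity to
adding a variant whose embedding is element-wise dominated — are tested
directly.

**Quantile transform.** Ranks with average ties, mapped through
$\Phi^{-1}((r - 0.5)/n)$; the offset avoids infinite extremes, and missing
values are preserved. Constant inputs are refused.

**Zygosity.** $V_{ij}$ has set semantics: a homozygous carrier contributes
the variant once (max pooling would ignore the duplicate anyway). Allele
counts are kept in the sparse genotype container and used as dosages by the
burden/SKAT tests.

**Bonferroni bookkeeping.** Per gene, the combined burden/SKAT p-value is
$\min(1, m \cdot \min p)$ with $m$ the number of tests *attempted* — a
skipped test produced no p-value to protect. Across genes, the multiplier is
the number of genes passing the EAF gate for that trait.

**Conditional tests.** The caller supplies the conditioning dosages
(clumping and window selection are upstream concerns); columns collinear
with the covariates are dropped with a warning, and an empty conditioning
set reproduces the unconditional p-value exactly.

**Binary traits.** The native logistic score test is provided but flagged:
for imbalanced case–control traits it is known to be poorly calibrated, and
the recommended route is pseudodosage export (probabilities
$(\psi, 0, 1-\psi)$, dosage $2\psi$) to an external Firth-penalized
single-marker tester.

## What the synthetic cohorts emulate — and what they do not

The generator reproduces the statistical structure the method assumes:

* **Genotypes**: allele counts drawn independently as Binomial(2, MAF), MAFs
  log-uniform on $[10^{-4}, 10^{-2}]$ — a heavy rare tail spanning both the
  training and association rarity regimes — stored sparsely. No linkage
  disequilibrium: rare variants are nearly independent in real cohorts, and
  all tests here treat genes marginally.
* **Annotations**: $d = 8$ columns, the first 4 causal, decoys correlated
  with causal columns at 0.3 by default; damaging variant classes (pLOF,
  disruptive missense) shift the first causal annotation so that class masks
  are informative, and a CADD-like score is correlated with it. The
  transformed MAF $[p(1-p)]^{-1/2}$ is appended as a model annotation.
* **Ground truth**: per-variant impact $u_k \in [0,1]$ through a linear
  (logistic of a weighted annotation sum), threshold (step), or interaction
  form; the interaction form is $\sigma(b\, a_1 a_2 - 2)$, damaging only
  when both causal annotations align, so that no single annotation is
  marginally sufficient — the regime where a learned nonlinear score should
  beat fixed-weight tests. Gene-level truth $u_{ij}$ is the max over carried
  impacts (matching the model's inductive bias; threshold/interaction forms
  exist precisely to break that match in robustness experiments). Variants
  are placed inside exons, just inside the 300 bp window, and just outside
  it, so the assignment rule is exercised on both sides.
* **Traits**: $y_i = \mathbf{x}_i^\top\boldsymbol\alpha + \sum_j w_j u_{ij} +
  \varepsilon$; binary traits by liability threshold at a configured
  prevalence; null traits ($w \equiv 0$) for calibration. The default
  seed-gene effect $w = 0.4$ makes one strong gene explain roughly 0.5% of
  trait variance — large by biobank standards, but appropriate for
  desk-scale cohorts of $10^3$–$10^4$ individuals where the paper-scale
  $n > 10^5$ regime is out of reach. Covariates are binary sex, Normal age,
  derived age², age×sex and 10 PC-like Normal columns, with small fixed
  effects.

Passing tests on these cohorts show that the machinery is correct and
calibrated under its own assumptions. They do **not** show robustness to LD,
population structure, relatedness, genotyping error, annotation error or
confounded covariates — none of which the generator models.

## Desk-scale experiment sizes

The validation experiments are sized for a single CPU:

* **Null calibration**: one cohort of n = 5,000 with 400 genes; five null
  traits tested (2,000 gene–trait tests) with out-of-fold scores from an
  ensemble trained on two separate seeded traits in the same cohort (K = 2
  folds × 2 restarts).
* **Leakage demonstration**: a pure-null cohort (n = 2,000, 80 genes) with
  40 deliberately nonassociated "decoy" seed genes, trained for a fixed 120
  epochs with early stopping disabled; the same ensemble is scored both
  out-of-fold and in-fold, and the inflation factor λ is compared between
  the two scorings of the same data. A caveat worth knowing: with
  overfitting forced this way, even the *out-of-fold* λ can sit above 1 on
  the trained trait, because a variant shared across folds lets one fold's
  model memorize the other fold's carrier noise while both folds are
  tested. In-fold scoring is still clearly worse. The clean calibration
  guarantee is the null-calibration experiment, where the tested traits
  never enter training; in the honest pipeline early stopping keeps the
  memorization channel small.
* **Parameter recovery**: n = 10,000, 20 seed genes, linear truth; held-out
  Spearman correlation between ψ and the true impairment, against every
  single-annotation alternative burden.
* **Power ordering**: n = 6,000, 100 genes, interaction-only truth; true
  seed genes recovered at FWER 0.05 by the learned score versus the best of
  the four burden/SKAT arms, plus the linear-ablation comparison.

At these sample sizes the EAF ≥ 50 gate cannot be met at the 0.1% qualifying
cutoff (cumulative allele frequencies of a few × 10⁻³ would require
n ≳ 10⁴–10⁵, as in real biobanks), so the synthetic association analyses
qualify variants at the 1% training cutoff while keeping the gate at 50.
The gate semantics themselves (CAF·n, case count for binary traits,
inclusive threshold) are tested at their stated values.

## Open choices made here

* The 20% validation individuals are drawn independently per trait.
* $\rho$'s output layer is linear before the logistic squashing.
* Seed-gene discovery runs once on the full training cohort before CV — a
  deliberate mirror of the standard workflow despite the mild circularity.
* For an individual of the training cohort, out-of-fold scoring averages
  exactly the R models of its held-out fold; models from other folds are not
  excluded for having seen the individual in their *validation* split, only
  fold-level exclusion is applied.
* The seed-selection FWER defaults to 0.05, the same level used for the
  prediction gene sets.
* A variant assigned to several genes contributes to each of them.
* The linear ablation (`activation = "linear"`) removes the nonlinearity
  from both $\varphi$ and $\rho$: with identity activations the score is a
  monotone function of a linear functional of max-pooled linear features,
  which cannot represent annotation products; this is what the interaction
  experiments compare against.
* Deviation-based enrichment aggregates across traits with an unweighted
  mean when several traits are reported together.

## Known limitations

* The logistic score test path is secondary (see above); seed-gene discovery
  on binary traits is supported but flagged.
* The BGEN export/import pair implements exactly the subset the package
  writes (layout 2, zlib, 16-bit, biallelic unphased diploid pseudovariants);
  it is not a general-purpose BGEN reader.
* Training is CPU-bound and sized for desk-scale cohorts; there is no GPU
  path, hyperparameter search, or alternative pooling (sum/attention).
* The sparse genotype container is the package's own binary CSC format, not
  an HDF5 interchange file.
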