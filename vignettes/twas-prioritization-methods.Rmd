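---
title: "Methods: multi-stage TWAS gene prioritization"
author: "twasprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage TWAS gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasprio)
```

# The problem

A genome-wide association study (GWAS) of a disease such as testicular germ
cell tumors yields per-SNP Z-scores, but linkage disequilibrium (LD) and the
density of genes at associated loci make it hard to say *which gene* carries
the signal. A transcriptome-wide association study (TWAS) attacks this by
testing whether *genetically predicted gene expression* — a sparse weighted
combination of cis-SNP genotypes learned in an eQTL reference panel — is
associated with the trait, using only GWAS summary statistics and an LD
reference panel. `twasprio` implements the full prioritization cascade
around that test: marginal association, a permutation guard against
GWAS-inflated statistics, locus-wise joint-conditional fine-mapping,
Bayes-factor colocalization, SNP-level conditioning of the GWAS on the
selected genes, and an expression-enrichment check in independent tissue
data — plus a synthetic-data generator that makes every stage testable with
no external downloads.

# The model, stage by stage

## Marginal TWAS statistic

For a gene with cis-SNP weights $w$, GWAS Z-scores $z$, and LD correlation
matrix $V$ estimated from a reference panel over the same (allele-aligned)
SNPs,

$$Z_{TWAS} = \frac{w'z}{\sqrt{w' V_\lambda w}},
\qquad V_\lambda = (1-\lambda)V + \lambda I .$$

This is the summary-statistic form of the correlation test between
predicted expression and the polygenic signal; under the null it is
standard normal, and the test suite verifies it against a brute-force
individual-level simulation. The ridge $\lambda = 0.1$ (configurable;
exact-arithmetic tests set it to 0) guards against rank-deficient LD
estimates from a few hundred reference samples over wide cis-windows — the
same shrinkage convention the established summary-TWAS tools use.

Model quality gates mirror standard practice: a model enters only with
significant cis-heritability ($p < 0.05$) and cross-validated predictive
performance ($p < 0.05$ and $R^2 > 0.01$). When a gene has models from
several source panels, they are mutually exclusive in the priority order
normal testis, then tumor tissue, then the cross-tissue panel; within the
cross-tissue panel the best-performing feature wins. FDR is controlled by
Benjamini–Hochberg at $q < 0.01$ pooled over *all* tests from all panels —
one family, matching "over the total number of tests".

## Harmonization

SNPs are matched by identifier across GWAS, weights, and panel. An allele
pair that is the swap of the model's flips the Z sign (and complements the
panel dosage); irreconcilable pairs are dropped. Strand-ambiguous (A/T,
C/G) SNPs are kept by default — the intended upstream is an
rsID-harmonized, imputed GWAS — with `dropAmbiguous = TRUE` as the
conservative alternative. The composition harmonize → statistic is
invariant to flipping the allele coding of the whole GWAS, which the suite
asserts.

## Permutation test conditional on GWAS effects

Strong SNP-trait signals in extensive LD can make *any* weight vector light
up. The guard resamples the weight entries across SNP positions and
recomputes the statistic against the fixed $z$ and $V$; the empirical
p-value is add-one corrected, so it is never exactly zero. Resampling is
*with replacement* by default, following the method description's
parenthetical; a without-replacement shuffle is available
(`mode = "shuffle"`) because permutation is what the reference
implementation of the post-processing does — both are exposed rather than
asserting which the original analysis used. Draws stop early once 100
exceedances are seen (at which point the relative error of the estimate is
about 10%), with a 100,000-draw ceiling; this interprets "an effective
number of 100,000 permutations" without wasting time on $p \approx 1$
genes, where the early-stopped estimator is unbiased anyway. Single-SNP
models get $p = 1$ by convention: resampling a length-one weight vector has
no variability.

## Locus assembly and joint-conditional selection

Genes passing both gates are grouped into loci: boundary intervals merging
whenever their gap is at most 100 kb (inclusive at exactly 100 kb — the
openness of the window is unspecified upstream, and inclusive is
deterministic), with transitive closure, implemented on
`GenomicRanges::reduce`.

Within a locus, the marginal TWAS Z-scores of the member genes are jointly
multivariate normal with correlation
$\Sigma_{ij} = w_i' V w_j / \sqrt{(w_i'Vw_i)(w_j'Vw_j)}$ — the correlation
of the genes' predicted expression under shared LD. Forward-stepwise
selection seeds with the smallest-p gene and repeatedly admits the gene
with the smallest conditional statistic

$$z_{cond} = \frac{z_r - \Sigma_{rS}\Sigma_{SS}^{-1} z_S}
{\sqrt{1 - \Sigma_{rS}\Sigma_{SS}^{-1}\Sigma_{Sr}}}$$

while its p-value stays below $0.05/k$, where $k$ is the number of
TWAS-significant genes on the chromosome. We count *FDR-significant* genes
for $k$ (not the smaller permutation-passing set): the larger divisor is
the more conservative reading of the Bonferroni rule. Ties break by
smallest p, then largest $|z|$, then gene id — determinism over elegance.
Joint statistics for the selected set are $b = \Sigma_{SS}^{-1} z_S$,
$z_j = b_j / \sqrt{(\Sigma_{SS}^{-1})_{jj}}$.

Collinearity plays two distinct roles: a selection-time guard excludes
genes with $|\Sigma| \ge 0.99$ against a selected gene (numerical
stability), and a reporting flag labels unselected genes with
$\Sigma^2 > 0.9$ against a leading gene as "correlated" (biological
annotation); the remaining unselected members are "conditional".

## Colocalization

For each leading gene, per-SNP approximate Bayes factors are computed for
both traits with the standard error reconstructed from sample size and
allele frequency, $se^2 = 1/(2nf(1-f))$ for the quantitative eQTL trait and
$se^2 = 1/(2nf(1-f)s(1-s))$ for the case-control GWAS with case fraction
$s = 10{,}156/189{,}839$. With shrinkage $r = W/(W+se^2)$,
$\log ABF = \frac12\log(1-r) + \frac12 z^2 r$. The five hypothesis sums use
the canonical priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior
effect SDs 0.15 (quantitative) and 0.2 (case-control) — the method was
cited without overriding its defaults, so the defaults are adopted and
surfaced in the interface. All accumulation is in log space via
log-sum-exp: $e^{z^2/2}$ overflows doubles near $|z| \approx 40$, and
colocalization inputs routinely exceed that. A gene colocalizes at
$PP4 > 0.5$. The test suite checks the posteriors against exhaustive
enumeration of all causal configurations on small SNP sets.

What the expression side of the input should be is genuinely ambiguous
upstream ("eQTL weights" as summary statistics): the package accepts real
per-SNP eQTL summary tables, and for synthetic runs derives LD-consistent
marginals from the weight model, $z_i \propto \sqrt{n}\,\sqrt{h^2}\,
(Vw)_i/\sqrt{w'Vw}$ plus sampling noise (`syntheticEqtlZ`). Neither path is
asserted to reproduce any published posterior.

## GWAS conditional on TWAS effects

With $C$ the SNP-by-gene correlation matrix
$c_{ig} = (Vw_g)_i/\sqrt{w_g'Vw_g}$, each SNP's Z is imputed from the
selected genes' TWAS Z-scores and the standardized residual reported:
$z^{res}_i = (z_i - C_i\Sigma_{SS}^{-1}z_S)/\sqrt{1 - C_i\Sigma_{SS}^{-1}C_i'}$.
Fully mediated SNPs are 0/0 by construction; the denominator is floored at
$10^{-6}$ and the residual set to exactly 0 when the numerator is also
below tolerance. The per-locus "proportion of GWAS signal explained" has no
published closed form; we define it as $1 - \chi^2_{res}/\chi^2_{marg}$ at
the locus lead SNP (the convention of the conditional-imputation framework
this stage follows), clipped to $[0,1]$, with a mean-over-significant-SNPs
alternative behind `method = "mean_sig"`. This is a documented choice, not
a claim of equivalence to the published per-locus percentages.

## Expression enrichment

Independent expression matrices are reduced to per-gene, per-group
summaries by the convention of each data kind: single-cell matrices are
variance-scaled per group (zero-SD genes stay 0) and averaged; log-scale
microarray intensities are log10-averaged; RNA-seq counts are scaled to
TPM, normalized per column, and log10(x+1)-averaged. The upstream
description of the RNA-seq normalization is internally contradictory
("quantile normalized … normalizing each sample to its mean expression"):
per-column mean scaling is the default and a true quantile normalization is
available via `normalization = "quantile"`; neither is asserted to be the
original. The enrichment test compares the median summary of the leading
genes with 10,000 random same-size sets drawn from the genes present in
both the association analysis and the dataset, one-sided for enrichment
(the question is whether prioritized genes are *more* expressed), add-one
corrected. For single-cell data the median proportion of cells with
strictly nonzero expression is a second statistic.

# The synthetic-data generator

The generator emulates the statistical structure of the study inputs, not
their biology:

* **LD panel** — a Gaussian copula per block with Markov (AR-like) latent
  correlation, thresholded to dosages by Hardy–Weinberg quantiles at MAFs
  drawn from `mafRange`. Thresholding attenuates correlation, so the latent
  correlation is *calibrated* by numerical inversion of the bivariate
  normal so that the realized adjacent-SNP dosage correlation approximates
  `ldRho`; for strongly mismatched MAFs the target may be unattainable (a
  property real dosage data share) and the latent value is capped. Blocks
  are independent; monomorphic draws are rejected.
* **Weight models** — contiguous cis-windows of `snpsPerGene` SNPs with
  `ceiling(sparsity × snpsPerGene)` standard-normal weights, and metadata
  drawn to pass the quality filters (with an option for deliberately
  failing models to exercise the filters).
* **GWAS Z-scores** — the mediated causal-gene model: each causal gene with
  effect $\alpha$ adds $\alpha\,Vw/\sqrt{w'Vw}$ to the mean of its window,
  so its expected TWAS Z is exactly $\alpha$; overlapping windows add
  linearly; noise is $MVN(0, V)$ per block. By default $V$ here is the LD
  *estimated from the panel genotypes* — the same matrix the pipeline will
  estimate — which makes the finite-sample LD estimate the correct one and
  isolates the statistical logic from LD-estimation error;
  `usePopulationLd = TRUE` flips this for robustness checks.
* **Expression matrices** — bulk mode is log10-normal around per-gene
  baselines (positive, no zeros); single-cell mode is negative-binomial
  with Bernoulli dropout, the simplest generator with the zero-expression
  structure the nonzero-proportion statistic needs. Genes in the planted
  set are shifted by `expressionShift` log10 units.
* **Passenger loci** (`simulatePassengerLoci`) — one causal gene plus
  passengers whose predicted-expression correlation with it is *exactly*
  `rhoGene` (Gram–Schmidt in the $V$ inner product), for validating that
  joint-conditional selection suppresses passengers.

Default study conditions used by the validation suite and the acceptance
script: 2,000 genes × 8 cis-SNPs with 300 reference samples for null
calibration; 800 genes with 5% causal at $\alpha = 7$ (10 seeds) for
recovery; 10 × 10 three-gene loci at passenger correlation 0.8; 20 mediated
colocalization loci at $\alpha = 8$ with eQTL $n = 500$; a planted 46-gene
set against a 5,000-gene background with a 2-log10 shift for enrichment.
These sizes make the whole suite run in a couple of minutes while keeping
binomial tolerances comfortably inside the asserted bounds.

What the generator does *not* emulate: real haplotype structure,
imputation error, population stratification, sex chromosomes,
allele-frequency–dependent architecture, or cell-type mixtures. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery under its own model assumptions — not performance on
real cohort data.

# Numerical choices

* LD ridge 0.1 everywhere LD is inverted or used in a quadratic form;
  tests that need exact arithmetic set it to 0.
* Conditional-z denominators floored at $10^{-6}$; 0/0 resolved to 0.
* All Bayes-factor sums in log space; `log1p`-based differences for the
  two-distinct-SNPs hypothesis, which is exactly $-\infty$ for one SNP.
* Empirical p-values add-one corrected, hence never 0.
* Genes are processed in (chromosome, start, gene id) order and one global
  seed expands into fixed per-stage, per-gene child seeds, so results are
  bit-identical under input shuffling and reruns.
* Coordinates are 1-based inclusive throughout; the genome build is opaque
  to the pipeline (positions are never lifted over).
* The GWAS-locus overlap window and the locus merge gap are closed
  intervals (boundary cases are vanishingly rare; closed is deterministic).

# A worked run

```{r run, eval = TRUE}
cfg <- simulationConfig(nGenes = 60, nRefSamples = 200, snpsPerGene = 8,
                        ldBlockSize = 8, causalGeneFraction = 0.1,
                        causalEffect = 7, seed = 11)
sim <- simulateTwasStudy(cfg, expressionShift = 1.5)
res <- runPipeline(sim, options = pipelineOptions(permMax = 2000, seed = 11))
res
head(subset(resultsTable(res), leading,
            select = c(gene_id, z_twas, q, perm_p, joint_z, pp4)))
```

The tallies shrink monotonically through the stages (tested ≥ FDR ≥
permutation ≥ leading ≥ colocalized), and the leading set recovers the
planted causal genes:

```{r truth}
intersect(resultsTable(res)$gene_id[resultsTable(res)$leading],
          sim@truth$causalGenes)
```

# Known limitations

* The weight models are consumed, never trained; nothing here validates
  model-training choices.
* LD is estimated from the same panel used by the generator's default,
  which is the point (isolating pipeline logic), but it means LD-mismatch
  robustness must be probed explicitly with `usePopulationLd = TRUE`.
* Single-signal colocalization only; multiple causal variants per trait in
  one region violate the single-causal-variant assumption behind the five
  hypotheses.
* The proportion-of-signal-explained definition is one of several
  reasonable ones; compare like with like.
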