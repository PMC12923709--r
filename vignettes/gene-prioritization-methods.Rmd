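---
title: "Models and methods behind the priogwas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the priogwas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priogwas)
```

`priogwas` turns quality-controlled GWAS summary statistics and an LD
reference panel into a ranked, rule-based list of candidate causal genes.
This vignette describes the statistical models each stage assumes, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The summary-statistic model

Everything downstream of QC operates on the standardized-genotype scale.
For a block of variants with LD correlation matrix $R$ and standardized
causal effects $b$ (zero off the causal set), the marginal z-statistics of
a GWAS with effective sample size $n$ follow

$$ z \sim \mathcal{N}\!\left(R\,\sqrt{n}\,b,\; R\right), $$

so that $\beta = z/\sqrt{n}$ and $\mathrm{se} = 1/\sqrt{n}$. This is the
standard large-sample likelihood for summary statistics, and the package's
conditional, joint, and fine-mapping algebra is exactly self-consistent
with it. Allele frequencies are carried as metadata and enter only through
the QC filters (minor allele count, absolute and fold frequency
differences against the panel) and the MAF > 1% filter of the gene-based
test. A consequence worth stating: effect sizes here are per standard
deviation of genotype, not per allele, and the conditional/joint algebra
approximates the frequency-weighted algebra of classic
conditional-analysis implementations. On simulated data the two coincide by
construction; on real data the standardized scale is a documented
deviation.

## Signal isolation

Clumping is the classic greedy algorithm (index = smallest p below
$5\times10^{-8}$, assignment within 3 Mb at $r^2 \ge 0.1$); ties on p
break to the smaller genomic position. Clumps are padded by 500 kb and
merged on touch; merging exactly-abutting expansions is the simpler
convention and the more conservative choice (fewer, larger regions). Within a region, forward
stepwise selection adds the variant with the smallest conditional p given
the selected set,

$$ z_{t|S} = \frac{z_t - r_{tS} R_{SS}^{-1} z_S}
                  {\sqrt{1 - r_{tS} R_{SS}^{-1} r_{St}}}, $$

skipping candidates with $r^2 > 0.9$ to any selected hit; joint effects
are $b_J = B^{-1} z / \sqrt{n}$ with $B$ the selected-set LD matrix, and
hits with joint $p > 5\times10^{-8}$ are dropped. Targets whose multiple
correlation with the conditioning set exceeds $r^2 = 0.9$ are masked
(reported missing) rather than returned as numerically unstable values.
With $k$ selected hits in a region, each signal's fine-mapping input is
the leave-one-hit-out conditional statistics; with $k = 1$ the marginal
statistics are used directly.

## Fine-mapping and loci

Under a single causal variant per signal, the log approximate Bayes
factor of variant $j$ is

$$ \log \mathrm{ABF}_j = \tfrac12 \log\frac{V_j}{V_j + W}
   + \frac{W z_j^2}{2 (V_j + W)}, \qquad V_j = \mathrm{se}_j^2 , $$

with prior effect variance $W = 0.04$ (prior sd 0.2 on the standardized
scale, the customary single-causal default; exposed as a parameter). PIPs are ABFs normalized by log-sum-exp; the 95% credible set
is the minimal PIP-descending prefix reaching coverage, with positional
tie-breaking; the signal's location summary is the PIP-weighted mean
position over set members with renormalized PIPs. Loci are credible sets
padded by ±300 kb, and a locus's candidate genes are all gene models with
any base overlap.

## Gene-based test

The gene statistic is the SNP-wise mean $T = \bar{z^2}$ over the $\ge 3$
variants mapped to the gene body (no window padding; panel MAF > 1%).
Under the null, $mT = \sum_j z_j^2 \sim \sum_i \lambda_i \chi^2_1$ with
$\lambda_i$ the eigenvalues of the variants' LD matrix. The upper tail is
evaluated by Ruben's series — the mixture rewritten as
$\sum_k a_k\, P(\chi^2_{m+2k} > q/\beta)$ with positive weights summing to
one, so the truncation error is bounded by the unconsumed weight
($10^{-12}$ here). When the eigenvalue spread makes that series slow
(ratio below $10^{-3}$), Imhof's characteristic-function inversion is
used, and a moment-matched gamma tail is the last resort. The gene z is
the one-sided probit of p, clipped at ±38 (the double-precision floor).
Per-gene LD is shrunk by $10^{-3}$ on the diagonal (renormalized) for
numerical stability. Ancestry-specific gene z-scores are meta-analyzed by
$(\sqrt{n_a} z_a + \sqrt{n_b} z_b)/\sqrt{n_a+n_b}$ — note this is the
Stouffer form, under which two concordant studies reinforce each other;
it is not an averaging operator.

## Feature-based priority scores

The priority score is the fitted value of a ridge regression of gene
z-scores on a standardized gene × feature matrix, with the intercept
unpenalized and prediction strictly leave-one-chromosome-out: feature
standardization, intercept, penalty choice, and coefficients for
chromosome $c$ use only genes not on $c$. The penalty is chosen by 5-fold
cross-validation within each training fold over the grid
$10^{-2}, \dots, 10^{6}$; the penalty protocol for feature-based gene
scores is under-documented in the literature, so both the grid and a
fixed-λ override are exposed, and univariate feature screening is
available but off by default. Fold
assignment is deterministic (round-robin), so fits are reproducible
without consuming RNG state. Genes with missing feature rows are imputed
at the training column mean and flagged; non-autosomal genes are
excluded. Percentiles are average ranks divided by the number of scored
genes, so a unique genome-wide maximum has percentile 1. Cross-ancestry
meta-analysis operates on raw scores and re-ranks afterwards.

## Prioritization rules

Three routes can fire per locus. The distance route requires all of:
locus size ≤ 20 genes; the gene holds the strictly largest raw score in
the locus (a tie never fires — tied scores arise in synthetic data even
though they are vanishingly rare in practice); the gene is nearest to the
credible-set centroid by gene-body distance (0 inside the body, else
distance to the nearer end; ties to the smaller gene id); and its
genome-wide percentile is ≥ 0.9. The non-synonymous route fires when the
summed PIP of a gene's non-synonymous credible-set variants exceeds 50%,
counting only variants that pass the per-variant heritability eligibility
flag supplied with the annotation (the heritability model itself is an
input, not something this package fits). The summed-per-gene rule is the default — it is the rule that aggregates
evidence across several moderate-PIP coding variants in the same gene —
and a per-variant mode (a single variant with PIP > 50%) is available as
a switch. The burden route is a pass-through of a
rare-variant burden FDR flag, with unknown never counting as true.

The locus-gene classifier is a three-predictor logistic regression
(loss-of-function intolerance, brain-specific expression,
neurodevelopmental-gene membership) trained leave-one-chromosome-out with
nearest genes as positives and, as this package's design choice, the
*other locus genes* as negatives, which keeps folds balanced at
simulation scale rather than diluting them with the whole genome.
Separated folds are capped at |8| on the logit scale, preserving ordering
while keeping probabilities finite. Enrichment against label sets uses
the cross-product odds ratio with a Haldane correction only when a cell
is zero (flagged), and the exact two-sided Fisher p either way.

## Colocalization

For two traits restricted to the variants present in both tables over a
shared locus, per-variant ABFs feed the five-hypothesis enumeration; the
H3 term uses the identity
$\sum_{j \ne k} A_j B_k = (\sum_j A_j)(\sum_k B_k) - \sum_j A_j B_j$
rather than the quadratic enumeration, with both implementations kept and
asserted equal in tests. All sums are accumulated in log space, so
posteriors are normalized to $10^{-9}$ even with z-scores in the tens.
Priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ are the conventional
defaults of enumeration-based colocalization. Variants present in only one trait are dropped; fewer than two
shared variants is an error because H3 is undefined.

## The synthetic-data generator

The generator is the package's study environment, not a fixture: it
produces block-diagonal LD panels (exchangeable or AR(1) within block),
summary statistics from the exact likelihood above, tiled gene models,
standardized feature matrices with a designated enriched subset,
annotation tables enriched in causal genes, and paired traits sharing a
configurable causal subset — all deterministically seeded, with a truth
table for recovery scoring. Panel genotypes are standardized Gaussian
variables with exact block correlation; frequencies are drawn separately
from the configured MAF range. This gives closed-form expectations for
every test, at the price of realism: no discrete genotypes, no
haplotype-scale LD decay, no imputation error, no case/control
liability-scale effects, no X chromosome, and no confounding or
stratification. Passing tests therefore demonstrate the *algorithms* are
correct under the stated model, not that the pipeline is robust to the
failure modes of real cohort data. Default simulation conditions mirror a large two-ancestry psychiatric
GWAS meta-analysis: two ancestries with effective sample sizes 126,282 and
30,515 and panels of 2,191 and 538 samples mixed 80/20 for the combined
analysis, 20 blocks of 100 variants at 10 kb spacing over 10 chromosomes,
2,000 overlapping 30 kb gene models, 12 causal variants with standardized
effects 0.02–0.035 (marginal z around 8–14 after meta-analysis), 50
features with one enriched by 2 SD in causal genes, and a paired trait
sharing half the causal variants.

Calibration and recovery checks run at sizes chosen to keep the full
suite in minutes: 500 replicates for credible-set coverage (effects set
for a median lead z of 7), 100 replicates each for two-causal recovery
and the two colocalization regimes, 2,000 independent genes for the
gene-test null, 200,000 Monte-Carlo draws per LD matrix for the mixture
tail, and 100 simulated loci for the precision comparison between
nearest-gene-alone and score-filtered nearest-gene calls.

## Numerical notes and limitations

* Everything LD-related uses the panel's sample correlations; with the
  default panel sizes, sampling noise in $R$ is part of the simulated
  conditions, as it is in real analyses.
* `stepwise_joint` refuses (with the offending pair named) to invert a
  singular selected-set LD matrix — reachable only if the collinearity
  screen is relaxed.
* Credible sets built from conditional statistics ignore masked variants
  (those in tight LD with the conditioning hits); their PIP mass is
  redistributed over the remaining variants by normalization.
* Single-causal fine-mapping is assumed throughout; multi-causal
  fine-mapping and functional priors are out of scope, as are live
  drug-database queries (drug annotation is a deterministic join against
  a supplied table) and any claims about specific real genes.
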