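---
title: "Gene-based rare-variant association for longevity case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-variant association for longevity case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centiskat)
```

## The problem this package addresses

Case-control studies of exceptional longevity compare rare genetic variation
between long-lived individuals (here called centenarians: people living
independently at 95 or older) and younger controls. Individually, rare
variants (minor allele frequency, MAF, below 0.05) carry too few carriers for
single-variant tests to resolve, so the workhorse is the gene-based kernel
association test: per-variant score statistics are aggregated over a gene
region with frequency-dependent weights, and significance comes from the
quadratic form's mixture-of-chi-squares null. Around that core sit the
supporting stages of a staged candidate-gene design: single-variant Fisher
exact scans, prioritization of predicted-functional variants, sub-pathway
over-representation, and extraction of a protein-protein interaction (PPI)
subnetwork around the top genes. `centiskat` implements the full pipeline
together with a synthetic-cohort generator, so every stage is testable
without access to any cohort's genotypes.

## The kernel tests

For a binary phenotype $y_i \in \{0,1\}$ with no covariates, the null model
is the intercept-only logistic fit: $\hat\mu$ is the case fraction for every
individual, residuals are $y_i - \hat\mu$, and the variance weight is
$v = \hat\mu(1-\hat\mu)$ (`fit_null()`). With genotype dosages $g_{ij}$ and
per-variant weights $w_j$, the statistic is

$$Q \;=\; \sum_j w_j^2 \Big(\sum_i (y_i - \hat\mu)\, g_{ij}\Big)^2 .$$

Under the null, $Q$ is distributed as $\sum_k \lambda_k \chi^2_1$, where the
$\lambda_k$ are the eigenvalues of the weighted, null-variance-projected
genotype cross-product $v\,W G_c' G_c W$ ($G_c$ column-centred, $W =
\mathrm{diag}(w)$). Weights are the Beta$(1, 25)$ density evaluated at the
folded whole-sample MAF — the standard choice that up-weights the rarest
variants sharply — and Beta$(0.5, 0.5)$ for the common-variant block of the
combined test. Both shape pairs, the 0.05 rare/common threshold, and the
$\rho$ grid live in `skat_config()`.

Three variants of the test are provided:

* `skat()` — the pure variance-component (kernel) test above.
* `skat_o()` — the optimal convex combination
  $Q_\rho = (1-\rho)\,Q_{\text{SKAT}} + \rho\,Q_{\text{burden}}$ over a grid
  of $\rho$, where the burden statistic is the squared weighted sum of
  scores. The minimum per-$\rho$ p-value is the statistic; its null
  distribution is evaluated by the one-dimensional integral over the shared
  $\chi^2_1$ factor obtained by decomposing the weighted genotype matrix
  along the average variant vector. Single-point grids short-circuit to the
  exact per-$\rho$ test, so `rho_grid = 0` is identical to `skat()` and
  `rho_grid = 1` to the weighted burden score test.
* `skat_c()` — variants are partitioned at the rare/common threshold by
  folded sample MAF; rare variants get the rare weights, common variants the
  common weights, and the two kernel statistics add, which is one kernel
  test with class-specific weights and a combined eigenvalue spectrum.

### Numerical choices

The mixture tail $P(\sum_k \lambda_k \chi^2_1 \ge q)$ (`davies_pvalue()`) is
computed by characteristic-function inversion with adaptive quadrature on
the Imhof integrand. A single eigenvalue is handled by the exact scaled
$\chi^2_1$ closed form. If the integrator fails or returns a value outside
$(0, 1]$, the fallback matches mean, variance and skewness to a scaled
noncentral chi-square; the method actually used is recorded on the result.
Eigenvalues below $10^{-10}\lambda_{\max}$ are truncated. Inside the
SKAT-O mixing integral the conditional survivor uses the moment-matched
tail — the fast published variant of that integral; inversion there costs
two orders of magnitude more runtime for well under 1% difference in the
combined p-value. The combined p is clamped to
$[\min_\rho p_\rho,\; |\text{grid}| \cdot \min_\rho p_\rho]$, the
Bonferroni sandwich that the min-p construction guarantees analytically.

### Small-sample behaviour (a known limitation)

The mixture null is the Gaussian-score approximation. Binary-trait residuals
have negative excess kurtosis, so for a few hundred individuals and a
rare-heavy spectrum the test is conservative: in our own calibration
(2000 null cohorts of 100 cases / 100 controls, 20 variants, ~81% of MAFs
below 0.05) the empirical type-I error at $\alpha = 0.05$ is ~0.03-0.04,
and it reaches the nominal 0.05 at cohort sizes in the low thousands. The
package deliberately ships no small-sample moment correction or resampling
calibration; p-values at small $n$ should be read as conservative.

## The pooled-sequencing adaptation

In a pooled design only per-pool allele frequencies are observed.
`pooled_skat()` treats each phenotype-homogeneous pool as one observational
unit with dosage $2 \times$ (pool alternate AF) per variant, the pool
phenotype as the response, and weights computed from the size-weighted
across-pool MAF; the kernel machinery then runs on the pool-level matrix.
With pools of size one and exact (infinite-depth) frequencies this is
bit-identical to the individual-level test — the correctness anchor for the
adaptation. Results carry a `pooled_anti_conservative` flag propagating the
original description's caveat that pooling loses individual genotype
information; in our own experiments the pool-as-unit construction is in
fact *less* powerful than the individual-level test (pooling averages
within-pool signal), and we found no regime in which it underestimates
p-values. The flag documents the provenance of the caveat, not a measured
property of this implementation; the alternative construction that does
underestimate p-values (assigning every individual its pool's dosage while
keeping $n$ at the number of individuals) has a catastrophically inflated
null (type-I error near 1) and is not offered.

## Single-variant tests

`allelic_fisher()` is the two-sided Fisher exact test by the
point-probability rule: at fixed margins, the p-value sums hypergeometric
probabilities of all tables no more probable than the observed one (with a
$10^{-7}$ relative tie tolerance). `genotypic_fisher()` extends this to 2x3
genotype tables by full enumeration, guarded by an enumeration cap.
`reconstruct_counts()` bridges printed 3-decimal MAFs back to integer allele
counts by round-half-up of $\text{MAF} \times 2n$ — the minimal-assumption
inverse of table formatting, and the route by which the package reproduces
published worked examples to their printed precision. Pairwise LD is the
squared Pearson correlation of dosages over pairwise-complete individuals
(`ld_r2()`). Alternate-allele frequencies are carried unfolded throughout;
folding to MAF happens only where a weight function demands it.

## Prioritization rules

Deterministic filters over the annotation table (`build_strata()`):

* **coding** — non-synonymous, stop-gain, stop-loss, frameshift or splicing;
* **regulatory** — RegulomeDB-style integer class at most 5 *and* overlap
  with at least one transcription-factor binding site or DNase I
  hypersensitive site. Score ordering uses the leading integer only ("3a"
  ranks as 3), and the rule carries no region gate: a synonymous exonic
  variant with strong regulatory evidence is classified regulatory;
* **3'UTR-functional** — a 3'UTR variant with at least one CLIP-seq
  experiment reporting Argonaute binding (folded into the regulatory
  stratum);
* **combined** — coding ∪ regulatory.

Missing annotations classify as non-functional (conservative), with a
reported tally. `select_genotyping_candidates()` unions three criteria:
nominal significance, rarity with any group enrichment, and
coding-functionality with any group MAF difference; both "any difference"
criteria expose a configurable floor defaulting to zero because the source
design stated none.

## Enrichment and subnetwork

`subpathway_enrichment()` is the one-sided hypergeometric
over-representation test of significant genes within each sub-pathway, with
the enrichment ratio $(k/m)/(K/N)$. Nominal p-values are primary —
mirroring the staged candidate-gene convention of treating $p < 0.05$ as
significant without multiplicity correction — and a Benjamini-Hochberg
column is appended as supplementary output. One-sidedness is a design
choice: the scientific question is over-representation.

`extract_subnetwork()` builds the seed subnetwork: the union of *all*
shortest paths between every pair of seed genes whose distance does not
exceed the adaptive cutoff $L^\*$. The cutoff sentence in the source design
is ambiguous; we adopt the smallest $L$ at which every seed joins the
subnetwork — for each seed its nearest-partner distance, maximized over
seeds — because that is literally the minimal inclusive length. The
alternative (the maximum over all pairwise seed distances) is available via
`mode = "max-pairwise"`. Seeds missing from the graph or unreachable from
every other seed are excluded with a warning rather than failing the run.
Edges are unweighted; interaction databases carry no lengths.

## The synthetic-cohort generator

`simulate_cohort()` emulates the data structure of a staged targeted-capture
study: 450 cases / 500 controls by default; a rare-heavy MAF law (81% of
variants drawn log-uniformly below 0.05, the rest uniform on [0.05, 0.5]);
a genomic-region mix dominated by intronic (51%), upstream (13%) and 3'UTR
(17%) classes as targeted capture of gene loci produces; and designated
causal variants parameterized directly as (case MAF, control MAF) pairs,
because that is how effect sizes are reported in the field's tables.
Genotypes are sampled per group under Hardy-Weinberg equilibrium
(dosage ~ Binomial(2, group MAF)) — a modelling choice, since the source
design never states a genotype model, and the one consistent with allelic
Fisher testing. One master seed drives three named substreams (genotypes,
pooling, annotations) so stages can be regenerated independently.
`pool_cohort()` models pooled sequencing at the allele-frequency level:
observed pool AF ~ Binomial(depth, true pool AF)/depth, with an
infinite-depth exact mode; no read-level simulation is attempted. Pool size
defaults to 50 where a run does not specify one — the source design never
states pool sizes, so this is an arbitrary, exposed default.

What the generator does *not* emulate: linkage disequilibrium between
variants (genotypes are independent across sites), population structure and
relatedness, genotyping error, and covariate effects such as sex. Passing
tests on these cohorts therefore demonstrates the statistical machinery —
calibration under independence, recovery of designed effects, exactness of
the deterministic rules — not robustness to the confounders of real data.

## Study-condition experiments shipped with the package

The test suite and the acceptance script run scaled experiments chosen to
finish in minutes on one CPU: null calibration uses 2000 cohorts of 200
individuals with 20 variants; the recovery experiment plants 5 causal genes
among 50 (three rare causal variants each, case/control MAF pairs at the
magnitudes of the published candidate table, e.g. 0.012/0.001 and
0.050/0.023) in cohorts of 450/500 and asks that all 5 rank in the SKAT
top 10 in at least 90% of 100 runs; pooled-vs-individual comparisons use
200 replicates with 10-person pools at exact depth. Causal variants are
deliberately *rare*: the common-variant rows of the same table are
down-weighted by Beta(1, 25) essentially to zero, so planting them would
not constitute a configured effect for the rare-variant test.

## Known limitations

* No covariate adjustment, kinship correction, or phased-haplotype handling.
* The exact conditional 2x3 test is enumeration-bound; large margins are
  rejected with a pointer to the allelic test.
* Conservative p-values for binary traits at small cohort sizes (above).
* The pooled adaptation is validated against its unit-pool anchor, not
  against any unpublished pooled-analysis script.
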