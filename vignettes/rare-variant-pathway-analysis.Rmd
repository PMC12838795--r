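---
title: "Rare-variant pathway analysis of differential treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant pathway analysis of differential treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvpathrx)
```

## The analysis this package implements

`rvpathrx` contrasts two clinical response groups — labelled SR
(suboptimal responders) and OR (optimal responders) throughout — by the
rare damaging variants their exomes carry. The pipeline starts from a
called cohort VCF plus an externally produced annotation table and runs
five stages:

1. **Genotype QC** (`run_qc()`): individual genotypes are set to missing
   when read depth < 20, genotype quality < 20, or a heterozygote's
   allelic balance (alt reads / (ref + alt reads)) is < 0.2; multiallelic
   records are split into biallelic ones with shared allele sequence
   trimmed; variants missing in more than 5% of samples are removed. All
   genotype cutoffs are strict `<` and the missingness bound is a strict
   `>`, so boundary calls survive.
2. **Variant classification** (`classify_variants()`): one annotation row
   is picked per variant–gene pair (canonical transcript first, then
   consequence severity, then transcript id), missense deleteriousness is
   the mean of whichever of REVEL and MetaRNN is present, and a variant is
   *damaging* when it is either a missense with consensus score strictly
   above 0.5 or a LOFTEE high-confidence loss-of-function call
   (frameshift, start/stop lost, stop gained, essential splice). Rarity
   requires gnomAD frequency strictly below 0.05; with two gnomAD columns
   the default takes their maximum (common in either resource means not
   rare), with `rule = "min"` available because the underlying wording
   ("either") admits both readings.
3. **Gene-set construction** (`map_variants_to_group_genes()`): a gene
   enters a group's set when at least one member of that group carries
   (dominance coding, at least one alt allele) at least one carried rare
   damaging variant in it. Binary gene-by-individual matrices
   (`carrier_matrix()`) expose the same information for display.
4. **Pathway statistics**: over-representation per group
   (`run_ora()` — one-sided hypergeometric tail, BH adjustment, a
   Monte-Carlo rank-deviation z-score, combined score
   `-ln(p) * |z|`, and the between-group `delta_combined =
   combined_OR - combined_SR` volcano table); per-pathway carrier burden
   (`run_burden()` — two-sided Fisher on the 2x2 carrier table with the
   sample odds ratio `(a*d)/(b*c)`); and a from-scratch SKAT-O
   (`run_skato()`).
5. **Baseline clinical comparisons** (`compare_clinical()`): exact
   r x 2 contingency tests (Freeman–Halton enumeration) and
   Mann-Whitney / Wilcoxon signed-rank tests for the cohort description
   table.

## The SKAT-O model

For a pathway with dosage matrix $G$ ($n$ samples by $m$ qualifying
variants), weights $w_j$ and a logistic null model with fitted means
$\mu_i$ (age and 0/1-coded sex as covariates), the per-variant scores are
$S_j = \sum_i G_{ij}(y_i - \mu_i)$ and

$$Q_\rho = (1-\rho)\sum_j (w_j S_j)^2 + \rho\Big(\sum_j w_j S_j\Big)^2,$$

which interpolates between the variance-component kernel statistic
($\rho = 0$, powerful for mixed-direction effects) and the squared
weighted burden score ($\rho = 1$, powerful for unidirectional effects).
Under the null each $Q_\rho$ is asymptotically a weighted sum of 1-df
chi-squares whose weights are the eigenvalues of the projected,
variance-weighted kernel $R_\rho^{1/2} Z^\top Z R_\rho^{1/2}$ with
$Z = P^{1/2} G W$ and $P$ the usual logistic-model projection. The final
p-value is that of $\min_\rho p_\rho$ over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the conventional
grid; the source method names none), computed by decomposing each
$Q_\rho$ into its shared burden-direction chi-square plus a remainder
mixture and integrating the joint exceedance probability over the shared
component. $\rho = 1$ is capped at 0.999 inside that machinery, grid
thresholds use moment-matched quantiles, and a Bonferroni envelope
$|{\rm grid}| \cdot \min_\rho p_\rho$ is both the fallback when the
integration fails (flagged in the `method` column) and a hard bound on
the reported value.

Tail probabilities of the chi-square mixtures come from numerical
inversion of the characteristic function on an oscillation-resolving
Simpson grid (absolute error target $10^{-6}$; validated against
closed-form chi-squares and million-draw Monte Carlo in the test suite).
A single eigenvalue is handled in closed form, and tails below
$10^{-12}$ switch to a skewness-matched noncentral chi-square moment
approximation.

Weights default to the Beta(1, 25) density of the cohort minor allele
frequency, computed on non-missing post-QC calls — weights must describe
the tested sample, not the reference population. Missing dosages are
mean-imputed per variant (`2 * MAF`; `impute = "zero"` available), which
never changes the number of qualifying variants $m$. Uncarried variants
(cohort MAF 0) are dropped with a log entry, since their weight and score
are both degenerate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_dp`, `min_gq` | 20, 20 | genotype-level depth/quality cutoffs (reads, phred) |
| `min_het_ab` | 0.2 | heterozygote allelic-balance cutoff |
| `max_missing_fraction` | 0.05 | per-variant missing-genotype bound |
| `rarity_threshold` | 0.05 | gnomAD frequency cutoff for "rare" |
| `rarity_rule` | `"max"` | aggregation over gnomAD exomes/genomes |
| `B` | 2000 | Monte-Carlo draws behind the ORA z-score |
| `combined_p` | `"adjusted"` | p entering the combined score |
| `rho_grid` | 8-point grid | SKAT-O burden/kernel mixing weights |
| `weights_beta` | (1, 25) | Beta density parameters for variant weights |
| `fdr` | 0.05 | BH threshold across pathways |

The combined score is stated in its source as integrating the *adjusted*
p-value with the rank z-score, while the tool it cites uses the raw p;
both are supported and `combined_p = "adjusted"` follows the text. Note
that under the adjusted convention BH plateaus can give several pathways
identical p terms, so their combined scores differ only through `z`.

## What the synthetic cohort emulates

`synthetic_config()` defaults encode the target study conditions: 31 SR
vs 32 OR samples; overlapping gene-sets (30 pathways of 15 genes drawn
from a 350-gene pool); per-gene variant counts 1 + Poisson(3); true MAFs
log-uniform on [5e-4, 0.2] (about three quarters below the 0.05 rarity
cutoff); REVEL/MetaRNN scores Beta(8, 3) for damaging and Beta(2, 6) for
benign missense variants with 10% of single-tool scores missing; gnomAD
exomes/genomes columns as independent lognormal perturbations (sd 0.3 on
the log scale) of the true MAF, so the two resources disagree near the
rarity cutoff and exercise the max/min rule; and one planted pathway
whose per-individual carrier probability is exactly 0.58 in SR vs 0.28
in OR — the regime in which the carrier-burden odds ratio is near 3.5.
Mixed-direction effects (extra alt alleles for half the chosen variants
in each group) generate the opposing-effect configuration that SKAT-O
detects but carrier counting cannot. QC corruption lowers DP, GQ or
heterozygote AB on disjoint recorded call subsets (0.4%/0.3%/0.2% of
calls, plus 0.3% baseline missingness) — roughly one percent of calls
fail QC, keeping variant attrition through the 5% missingness filter at
realistic levels.

Genotypes are Hardy-Weinberg draws without linkage disequilibrium,
population structure or relatedness; the analysis operates on carrier
indicators and score statistics, for which LD realism is unnecessary at
the unit-test level, but passing tests on this generator says nothing
about confounding from structure in real cohorts. The generator emits a
first-class truth bundle (per-variant class and qualifying status,
planted carrier targets, corrupted-call set) so tests compare against
recorded truth rather than reverse-engineering pipeline output.

## Numerical and design choices

- Variant identity is `(chrom, pos, ref, alt)` after biallelic
  normalization; trimming is suffix-first then prefix, reference-free
  (full left-alignment against a FASTA is out of scope).
- Genotypes lacking DP/GQ/AD skip the corresponding sub-filter — the
  least destructive reading of the filter description. A heterozygote
  whose AD sums to zero reads is treated as AB = 0 and masked.
- Filter order is fixed and reported: mask, then split/trim, then
  missingness. The alternative order (missingness before splitting) is
  not inferable from the method description; the chosen order is declared
  in the QC report rather than guessed.
- "Either gnomAD exomes or genomes" is implemented as max-of-available
  (conservative) with the permissive min behind a flag; absent in both
  resources counts as novel (frequency 0, rare).
- pLoF takes precedence over damaging-missense when one record satisfies
  both, so no variant is double-counted.
- The rank-deviation z is estimated by seeded Monte Carlo (uniform query
  draws from the universe) because the cited enrichment tool's
  precomputed lookup tables are not redistributable; B and the seed are
  recorded in output headers and results are bit-reproducible.
- Exact rank tests switch to tie-corrected normal approximations with
  continuity correction beyond 20 (unpaired) or 15 (paired) observations,
  the standard convention; zero paired differences are dropped.
- X/Y contigs are treated autosomally and flagged in logs; hemizygote
  handling is not modeled.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes chosen to keep
the checks sharp but bounded: exhaustive 2x2 enumeration for all row
margins up to 12 plus one random table per even margin pair up to 40;
million-draw Monte Carlo for the quadratic-form tail; a 100,000-
permutation oracle for SKAT-O on a 60 x 4 pathway; 2000 null cohorts at
n = 63 for type-I calibration; and 200 end-to-end generator replicates
for effect recovery.

## Known limitations

- At n around 63 with a binary phenotype, the score-test chi-square
  mixture null is conservative relative to the exact permutation null
  (measured type-I error in the test suite's calibration: about 0.037
  for SKAT-O and 0.040 for the exact carrier-burden test at nominal
  0.05 over 2000 null cohorts). Error
  control holds, but p-values near a threshold should be read with this
  in mind; small-sample variance corrections for binary traits are not
  implemented.
- With roughly thirty candidate pathways, a planted carrier effect of
  the 0.58-vs-0.28 magnitude yields a burden p around 0.02 and therefore
  cannot reliably out-rank every null pathway; detection should be judged
  at a significance level, not by top rank.
- The Freeman-Halton test enumerates exhaustively and is bounded at a
  table total of 10,000; no Monte-Carlo fallback is provided.
- Pathway-hierarchy redundancy (parent/child gene sets sharing genes) is
  not collapsed; interpretation across nested pathways is the analyst's
  responsibility.
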