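---
title: "Detecting two-locus hybrid incompatibilities from haploid genotypes"
author: "hapBDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting two-locus hybrid incompatibilities from haploid genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapBDM)
```

## The biological setting

Hybrid breakdown is the loss of fitness that appears in second-generation
(F2) hybrids once recombination has broken up co-adapted gene complexes.
Under the Bateson–Dobzhansky–Muller (BDM) model the loss is caused by
epistatic interactions between alleles of different parental origin.
hapBDM targets a particularly favourable setting for detecting such
interactions: haplodiploid species in which males are haploid (no
dominance masking) and in which breakdown is incomplete, so that both
viable F2 males and inviable F2 male eggs can be collected and genotyped.

The data are genotypes of haploid hybrid individuals at a small panel of
*diagnostic* biallelic markers — loci fixed for different alleles in the
two parental lineages — so each allele can be recoded to its lineage of
origin, I or II. Individuals are labelled by phenotype (viable/inviable)
and by cytotype (the maternally inherited cytoplasmic background, I or
II, determined by the direction of the original cross). This yields four
hybrid groups: viable I, viable II, inviable I and inviable II.

Three comparisons carry all the information:

1. **viable I vs viable II** (cytonuclear): the groups differ only in
   cytotype, so a per-locus allele-frequency difference indicates a
   nuclear–cytoplasmic interaction affecting viability.
2. **viable I vs inviable I** and 3. **viable II vs inviable II**
   (nuclear): within one cytotype, genotype differences between viable
   and inviable individuals reflect nuclear effects on viability.

Because every comparison is *between* hybrid groups produced by the same
crosses, neither linkage between markers nor deviations from Mendelian
segregation can generate spurious differences: both affect all groups
identically.

## The two-locus statistic

Single-locus allele frequencies cannot reveal interactions, so the core
object is the two-locus haplotype count: for each pair of markers (28
pairs for an 8-marker panel) and each group, the number of individuals
carrying each of the four allele combinations I.I, I.II, II.I and II.II
(first symbol = allele at the alphabetically first marker of the pair).
I.I and II.II are parental haplotypes; I.II and II.I are recombinant.
Only individuals with calls at both loci of a pair enter its table
(pairwise-complete deletion), so each pair uses as much data as possible.

The overall viable–inviable difference in haplotype composition is tested
with a generalized Cochran–Mantel–Haenszel (CMH) test of general
association, treating the 28 pair tables as strata: with row-1 counts
$x_k$, column totals $m_k$ and total $N_k$ in stratum $k$,

$$M^2 = U^\top V^{-1} U, \qquad
  U = \sum_k \left(x'_k - n_{1k} m'_k / N_k\right),$$

where the primes drop the last column and $V$ sums the multivariate
hypergeometric covariances; $M^2 \sim \chi^2_{C-1}$ under the null, so
2 × 4 strata give df = 3.

To localize the signal, each 2 × 4 table is converted to adjusted
(standardized) residuals,

$$d_{ij} = \frac{n_{ij} - E_{ij}}
  {\sqrt{E_{ij}\,(1 - n_{i+}/N)\,(1 - n_{+j}/N)}},
  \qquad E_{ij} = \frac{n_{i+} n_{+j}}{N},$$

which behave as approximate z-scores and are therefore comparable across
pairs with different sample sizes and margins. Only the viable row is
used (the inviable row is its exact negative in a two-row table). A cell
with zero expected count has no defined residual and is omitted; the
28 × 4 = 112 cells per comparison (224 over both nuclear comparisons)
therefore occasionally lose a member.

Haplotype counts are correlated with single-locus allele frequencies by
construction. That marginal component is captured by the **allele
indicator** of haplotype x.y at pair (A, B): the sum of the viable-row
adjusted residuals of allele x at A and allele y at B, taken from the
2 × 2 group × allele tables of the same comparison. In the absence of
interactions, haplotype residuals should track the indicator linearly;
systematic deviation that differs between parental and recombinant
haplotypes is the signature of two-locus epistasis. This is tested with
the ordinary least squares model

```
residual ~ indicator + pair * hapClass
```

(57 coefficients for a complete 28-pair design, leaving 112 − 57 = 55
residual df, or 54 when one cell is inestimable). The pair × class
interaction is assessed both as a partial F-test and as a Gaussian
likelihood-ratio chi-square. For each pair, the post-hoc contrast is the
fitted parental mean minus the fitted recombinant mean, evaluated at a
common indicator value of 0 — the indicator enters additively, so the
evaluation point cancels from the difference. A significantly positive
contrast (viable individuals enriched for parental haplotypes) is
labelled **BDM**; a significantly negative one (viable enriched for
recombinant) is labelled **heterosis**; anything else, including an
inestimable contrast, is **none**, so labels always partition the pairs.

The cytonuclear comparison needs no two-locus machinery: per locus, a
two-sided Fisher exact test on the 2 × 2 group × allele table, with
Holm's sequential Bonferroni across loci.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `noiseCutoff` | 400 fluorescence units | background-noise floor for peak calling |
| `dominanceRatio` | 2 | called peak must be at least double every other peak |
| `minCallRate` | 0.8 | "consistent amplification" for diagnostic markers; the underlying criterion is qualitative, so this is a package choice |
| `maxMissing` | 2 (of 8 markers) | exclusion threshold for hybrid individuals |
| `alpha` | 0.05 | significance level throughout |
| `adjust` | `"holm"` | post-hoc contrast adjustment; set `"none"` to skip |

Sign conventions are fixed once: haplotype columns are ordered I.I, I.II,
II.I, II.II keyed to alphabetical marker order; responses and indicators
both use the viable row, which makes the marginal allele-frequency
relation a positive-slope one and makes "positive contrast = BDM"
deterministic. Two design consequences are worth noting. First, the
adjusted residual is the standard cell-wise standardized residual
(Pearson residual divided by its estimated standard error) — the
construction that actually delivers unit-variance z-scores; descriptions
that divide by "the s.d. of all residuals" are read as informal wording
for the same quantity. Second, classification is exactly antisymmetric:
swapping the viable and inviable groups negates residuals and indicators
and swaps the BDM and heterosis labels, which the test suite verifies.

## The simulator

`simulateHybridData()` generates the gametes of F1 hybrid females — each
F2 male is one recombinant haploid genome. The first marker of the map
follows its transmission bias (probability of transmitting the lineage-I
allele; 0.5 = Mendelian), and each subsequent marker either switches
lineage with its recombination fraction (linked) or, at the unlinked
default of 0.5, is drawn independently so that per-marker bias can act
anywhere on the map. Survival is Bernoulli with probability

$$v = v_0 \prod_{\text{epistasis}} (1 - s)^{[\text{penalized class carried}]}
        \prod_{\text{cytonuclear}} (1 - c)^{[\text{allele on matching cytoplasm}]},$$

i.e. penalties combine multiplicatively; survivors form the viable group
and the rest the inviable group, after which missing calls are injected
completely at random at rate 0.09. Defaults emulate the study design the
package is built around: 8 unlinked markers, 226 and 228 F2 males per
reciprocal cross (so the four groups land near the 80–130 range after
survival and filtering), and a baseline viability of 0.41, the viable
fraction implied by those group sizes. A single seed drives every draw,
so datasets reproduce bit-for-bit.

What the simulator does *not* emulate: genotyping error and allelic
stutter (calls are correct or missing), phenotype-dependent missingness
(inviable eggs may amplify worse in reality; the rate here is uniform),
diploid F2 females, fertility phenotypes, and any interaction involving
three or more loci. Passing simulation-based tests therefore shows that
the statistical machinery behaves as designed under its own assumptions,
not that those assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

- Two peaks tied for the largest area can never satisfy the dominance
  rule, so a tie is a no-call.
- Non-parental alleles in hybrids are recoded to missing with a warning
  rather than raising an error.
- An all-zero count table is rejected; a column with zero total yields
  undefined residuals; a singular CMH covariance (after dropping columns
  empty in all strata) falls back to a Moore–Penrose inverse with df
  reduced to the covariance rank, with a warning.
- Fisher's two-sided p uses the probability-mass definition with the
  conventional 1e−7 relative tolerance, clamped at 1.
- A rank-deficient residual model (a pair missing an entire haplotype
  class) drops the inestimable coefficients with a warning; contrasts
  touching them are reported as `NA`.
- A numerically exact model fit (residual sum of squares at rounding
  error) has no error variance to test against: zero contrasts get
  p = 1, non-zero ones p = 0, and an interaction block that explains
  nothing yields F = 0 rather than 0/0.

## Validation problem sizes

The package's validation suites (mirrored by `scripts/acceptance.R`) use:
exhaustive Fisher-vs-enumeration agreement over all 2 × 2 tables with
N ≤ 40 (up to table symmetries); 25-table random checks of the
single-stratum CMH identity $M^2 = (N-1)/N \times \chi^2_{\rm Pearson}$
and of the residual formula; 500 null simulations at the default design
for calibration; 200 replicates each for BDM and heterosis injection
recovery (selection coefficient 0.9 at one pair); and 100 replicates each
for the cytonuclear power and null scans (penalty 0.9 at one locus).

## Known limitations

- **The omnibus and contrast tests are anticonservative under the null.**
  The 28 marker-pair strata are built from the same individuals, so the
  CMH variance (which assumes independent strata) understates the true
  variance of the summed deviations. More severely, within a pair the
  haplotype residuals' deviations around their class means are almost
  exactly proportional to the allele indicator (both are functions of the
  same counts), so the regression's residual variance collapses while the
  per-pair class-mean contrasts retain sampling variance of order one.
  The F statistic and the contrast t statistics are therefore inflated
  even for data with no interactions at all: in the package's 500-run
  null suite the omnibus p-values are far from uniform and nearly every
  run labels at least one pair at α = 0.05. Strong signals (the injected
  s = 0.9 pair is recovered essentially always, and carries the most
  extreme contrast) remain unambiguous, but nominal p-values near the
  threshold overstate the evidence, and *ranking* pairs by contrast size
  is more trustworthy than the labels of marginal pairs. The
  Fisher-based cytonuclear scan does not share this problem and is
  calibrated (slightly conservative, as exact tests are).
- Label counts at nominal α are therefore best read as descriptive
  summaries, not family-wise-controlled discoveries.
- With eight markers, marker density is far too low to say anything
  about the number or genomic location of incompatibility loci; the
  method detects interactions between (regions linked to) marker pairs.
- Interactions among three or more loci are outside the model.

## Session info

```{r}
sessionInfo()
```
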