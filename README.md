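# clonodyn

Pharmacodynamic analysis of peripheral-blood TCR-β CDR3 repertoires from
paired baseline / end-of-first-cycle immunosequencing samples, for
translational scientists comparing how immunotherapy regimens reshape the
circulating T-cell pool across the arms of a multi-arm trial and whether
that reshaping tracks clinical response.

## What it computes

**Per-sample diversity.** For the productive (in-frame, translatable)
rearrangements of a sample with counts *n₁ … n_R* and total *N = Σ nᵢ*:

- Simpson clonality `C = Σᵢ pᵢ²` with `pᵢ = nᵢ/N` — 0 for perfectly even
  repertoires, 1 for monoclonal ones;
- downsampled richness — the number of unique productive rearrangements
  after sampling *D* templates without replacement, averaged over *K* = 5
  resamples at a common depth *D*, so richness is comparable across
  sequencing depths;
- fraction of productive T cells — productive / total templates;
- T-cell fraction — total templates / nucleated cells (reference-gene
  denominator from the assay, carried in the manifest).

**Per-clone expansion test.** For each unique productive rearrangement
present in either sample of a participant's pair, the combined count
*n = c₁ + c₂* is a fixed number of trials in an exact two-sided binomial
test of the on-treatment count *c₂* under the null that templates split
between the samples in proportion to repertoire size, *q₀ = N₂/(N₁+N₂)*.
P-values are Benjamini–Hochberg adjusted within the pair (FDR 0.01);
significant clones with a higher on-treatment frequency are *expanded*
(further *new* if undetected at baseline, else *existing*), lower are
*contracted*.

**Cohort statistics.** One-way ANOVA of baseline metrics across arms,
pairwise arm Wilcoxon rank-sum tests with BH adjustment, within-arm paired
Wilcoxon signed-rank change tests, responder-vs-nonresponder Wilcoxon
comparisons of expanded-clone counts (nonevaluable participants counted as
zero-expansion nonresponders), and per-arm proportions of participants
above an expansion threshold (default: the durvalumab-arm median).

**Expression signatures.** ssGSEA scoring of a genes × samples log₂ TPM
matrix against GMT gene sets (running sum with |rank|^τ weights, τ = 0.25),
and a per-arm two-timepoint random-participant-intercept slope model —
computed via its exact balanced-design reduction, the mean per-participant
score delta with a paired t-test — with p ≤ 0.05 signature selection.

**Synthetic cohort generator.** Because patient-level trial data are not
public, a seeded generator produces paired repertoires for five arms
(D+B, D, T75+D, STRIDE, T) with a power-law baseline frequency law,
multinomial sequencing noise, arm-dependent numbers of fold-expanded and
novel clones, responder boosts and response labels — the substrate for all
calibration, power and truth-recovery tests.

## Worked example

```r
library(clonodyn)

cfg  <- simConfig(seed = 42L)            # five-arm default cohort
coh  <- simulateCohort(cfg)
calls <- lapply(coh$pairs, testPair, fdr = 0.01)

first <- !duplicated(coh$manifest$participant_id)
arms  <- setNames(coh$manifest$arm[first], coh$manifest$participant_id[first])
resp  <- setNames(coh$manifest$response[first], coh$manifest$participant_id[first])
dyn   <- summarizeDynamics(calls, arms = arms, responses = resp)

subset(dynamicsArmSummary(dyn), metric == "n_expanded_total")
#>     arm           metric  n median q25 q75
#>     D+B n_expanded_total 37      5   5  11
#>       D n_expanded_total 31      7   6  19
#>   T75+D n_expanded_total 26     14  13  15
#>  STRIDE n_expanded_total 28     22  20  24
#>       T n_expanded_total 17     40  38  40
```

The recovered per-arm medians of expanded clones reproduce the injected
tremelimumab-dose ordering D+B ≈ D < T75+D < STRIDE < T. Response
association in the pooled tremelimumab-containing arms:

```r
tab <- cohortTable(coh$manifest, dynamics = dyn)
responseTest(tab, "pooled_tremelimumab")$p_value
#> [1] 3.234623e-05
proportionAboveThreshold(tab)   # threshold = durvalumab-arm median (7 here)
```

Responders carry significantly more expanded clones than nonresponders
(the generator boosts responder expansion 3-fold by default), and the
proportion of participants above the durvalumab median rises with
tremelimumab dose.

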