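---
title: "Methods: paired TCR-β repertoire pharmacodynamics"
author: "clonodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired TCR-β repertoire pharmacodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonodyn)
```

## The measurement and its unit of analysis

Bulk immunosequencing of the TCR-β CDR3 region reports, per blood draw,
the absolute template count of each unique nucleotide rearrangement. A
rearrangement is *productive* when it is in-frame with no stop codon.
The analyses here treat one participant's **pair** of draws — baseline and
end of the first treatment cycle — as the unit of pharmacodynamic
inference, and a cohort of such pairs, labelled by treatment arm and
radiographic response, as the unit of group inference.

Clone identity across the two timepoints is exact string match on the
nucleotide rearrangement key. No V/D/J annotation, CDR3 clustering or
similarity grouping is done: two clones are the same clone only if their
rearrangements are identical.

## Diversity statistics

With productive counts $n_1,\dots,n_R$, $N = \sum_i n_i$ and
$p_i = n_i/N$:

* **Simpson clonality** $C = \sum_{i=1}^{R} p_i^2 \in [1/R,\, 1]$.
  Computed on productive clones only. It is invariant to scaling all
  counts, so it does not need depth normalisation. A sample with no
  productive templates has no clonality; `simpsonClonality()` raises an
  error rather than returning 0, because 0 is a meaningful value (a
  perfectly even, infinitely rich repertoire).
* **Downsampled richness**: $D$ templates are drawn *without replacement*
  from the expanded multiset of productive templates; the number of
  distinct rearrangements is averaged over $K$ resamples. $K = 5$ by
  default; the expectation under this scheme is the multivariate
  hypergeometric form $\sum_i \bigl(1 - \binom{N-n_i}{D}\big/
  \binom{N}{D}\bigr)$, which the test suite uses as a closed-form oracle
  at $K = 10^4$.
  The common depth $D$ defaults to the minimum productive total across
  the analysis set, so no sample is extrapolated; with an explicit $D$,
  shallower samples are excluded from richness (reported as `NA` with a
  message), never inflated.
* **Productive fraction**: productive / total templates.
* **T-cell fraction**: total templates / nucleated cells. The
  nucleated-cell denominator comes from the assay's reference-gene panel
  and is supplied through the manifest; the package does not recompute
  it, and reports the metric as `NA` (not 0) when the denominator is
  absent. Downsampling applies to templates only; we do not subsample
  nucleated-cell equivalents.

## The expansion test

For each unique productive rearrangement present in either sample,
$(c_1, c_2)$ are its template counts (0 when absent), $n = c_1 + c_2$ the
binomial trials, and the null is that the $n$ templates split between the
samples in proportion to repertoire size:
$q_0 = N_2 / (N_1 + N_2)$ over total *productive* templates.
The two-sided p-value is the minimum-likelihood exact binomial:
$p = \sum_j \{\Pr(j \mid n, q_0) : \Pr(j) \le \Pr(c_2)\}$.

Choices that the procedure's verbal description leaves open, fixed here:

* **Test universe.** The union of productive clones observed in either
  sample. Absent clones enter with count 0 — necessary for *new* clones
  (zero baseline templates) to be testable at all. Nonproductive
  rearrangements are excluded from both the universe and $N_1, N_2$.
* **Multiplicity family.** BH is applied *within* each participant pair,
  not pooled across participants: expansion counts are reported per
  participant, and pooling would let one participant's p-value
  distribution move another's calls. A pooled variant would be a
  one-line change; per-pair is the default and the only mode used here.
* **Threshold convention.** Clones with adjusted $q \le$ FDR (inclusive)
  are significant; direction comes from the frequency comparison
  $c_2/N_2$ vs $c_1/N_1$.
* **No minimum-count filter.** Presence implies $n \ge 1$, and the
  discreteness of the exact test already makes singletons untestable in
  practice (their p-values cannot fall below typical cutoffs); a
  `minTemplates` argument exists but defaults to 0.
* **Novelty is detection-based.** "New" means zero *observed* baseline
  templates. Sampling can miss a pre-existing low-frequency clone, so
  some "new" clones are recruits into the detectable range rather than
  genuinely primed clones; this is a limitation of any finite-depth
  design, not of the test.

Numerically, the p-value sums `dbinom` over a sorted cumulative table per
distinct $n$, with a $1 + 10^{-7}$ relative tolerance when comparing point
probabilities, so floating-point noise cannot drop an outcome that is
analytically tied with the observed one. Deduplication over distinct
$(c_2, n)$ pairs makes a 20,000-clone pair test run in milliseconds.

## Cohort statistics

* Baseline metrics across the five arms: one-way fixed-effects ANOVA.
  With a degenerate perfect separation (zero residual variance) the F
  statistic is capped at the largest finite double and the p-value
  floored at the smallest positive double, so downstream code never sees
  `Inf`/0.
* Pairwise arm comparisons: two-sided Wilcoxon rank-sum on every arm
  pair, BH-adjusted across the pairs. The test is exact (full
  enumeration) when both groups have $\le 25$ observations and no ties,
  otherwise the tie-corrected normal approximation with continuity
  correction; the variant used is recorded in the result's `method`
  field. Identical groups give $p = 1$ under this convention.
* Within-arm paired changes: two-sided Wilcoxon signed-rank on the
  per-participant deltas, zeros dropped before ranking (the classical
  Wilcoxon convention, the default of the era's standard software);
  all-zero deltas return $p = 1$ with a warning. A paired t-test variant
  was considered and rejected as the default because repertoire deltas
  are heavy-tailed.
* Responder comparisons: Wilcoxon rank-sum of total expanded clones,
  responders vs nonresponders, within an arm, the pooled
  tremelimumab-containing group `{T, T75+D, STRIDE}`, or the whole
  cohort. Participants whose response is nonevaluable join the
  nonresponder side with an imputed count of zero, and participants with
  no evaluable repertoire pair likewise enter at zero — a participant
  without a confirmed response or without measurable expansion
  contributes no expansion signal. When a response group is empty the
  comparison is reported as not-available rather than an error, since
  small arms can legitimately lack evaluable responders.
* Threshold proportions: strictly greater than the threshold ("exceeds"
  is read as strict); the automatic threshold is the median
  expanded-clone count of the durvalumab-monotherapy reference arm.
  Descriptive summaries report medians with 25th/75th percentiles using
  linear-interpolation quantiles (`type = 7`), configurable because
  vendor quartile conventions differ.

## Signature pharmacodynamics

Scores are ssGSEA: within each sample, genes are ranked by expression
(average ranks at ties) and walked from highest to lowest; in-set genes
add $|r|^\tau / \sum_{S}|r|^\tau$, out-of-set genes subtract
$1/(G - |S|)$, and the score is the sum of the running-sum values over
all positions. $\tau = 0.25$, the method's conventional exponent. Scores
are min–max normalised across the whole score matrix by default (divide
by the global range); both modes are exposed because published analyses
are split on this, and the downstream slope test is unaffected by the
choice (it is a per-signature linear rescaling).

The pharmacodynamic model per signature and arm is a mixed model — score
on timepoint with a random participant intercept. With exactly two
timepoints and complete pairs, the ML/REML estimator of the timepoint
effect *equals* the mean of per-participant deltas and its test reduces
to the paired t-test; the package computes that reduction directly, and
the test suite cross-checks it against a general REML fit. Participants
missing a timepoint are excluded (with a message) instead of entering an
unbalanced fit: with $n \ge 2$ complete pairs the reduction is exact, and
rescuing single-timepoint participants buys almost nothing at these
sample sizes. Fits are per-arm, matching a design where each arm's
pharmacodynamics is displayed separately; a pooled arm-by-time
interaction model would answer a different question (differences *between*
arms' slopes) and is out of scope. Selection keeps signatures with
unadjusted $p \le 0.05$ — the display convention this reproduces — and a
BH-adjusted column is always attached so readers can apply a stricter
rule. Degenerate all-equal deltas get a flagged guard p-value
(`.Machine$double.xmin`, or 1 when the common delta is zero) rather than
an error from the t-test.

## The synthetic cohort generator

No patient-level repertoire data are deposited for the trial this design
emulates, so every calibration and power claim in the package is made
against a generator whose defaults *are* the study conditions:

* per-arm participant counts 37/31/26/28/17 (D+B, D, T75+D, STRIDE, T),
  the evaluable-pair sample sizes of the emulated cohort;
* baseline frequencies: power law $p_i \propto i^{-\alpha}$, $\alpha = 2$
  over $U = 2\times10^4$ clones (a strongly clonal blood repertoire; a
  symmetric Dirichlet alternative covers the flat extreme);
* sequencing noise: multinomial draws of $5\times10^4$ templates per
  sample — template counts are sums of independent molecule captures, and
  at these depths multinomial sampling is the dominant noise source;
* treatment effect: in each arm, `nExpandedExisting` clones have their
  frequency multiplied by `fold` (default 6) and `nNewClones` novel
  clones are inserted, then frequencies renormalise; effects are ordered
  D+B ≈ D < T75+D < STRIDE < T (4+3, 5+4, 10+8, 16+14, 28+24 clones),
  chosen to reproduce the qualitative tremelimumab-dose ordering of
  expanded-clone medians, not any arm's exact published median;
* responders (drawn per arm at the evaluable-population response rates,
  with 10% response-nonevaluable) have both effect counts multiplied by
  `responderBoost = 3`;
* 3% of unique clones are nonproductive, independently, so
  productive-fraction statistics are exercised;
* nucleated-cell denominators correspond to T-cell fractions drawn
  uniformly from 0.05–0.25, the typical blood range.

Two design points deserve emphasis. First, **novel clones are injected
into the frequency model, not the count tables**, at `fold` times the
median frequency of the *detectable support* (clones with expected
baseline count ≥ 1 at the configured depth). Under a heavy-tailed law the
median over all $U$ clones is orders of magnitude below one expected
template, which would make every injected novel clone invisible and the
new-clone machinery untestable; anchoring the insertion to the detectable
support keeps novel clones subject to real sampling noise (they can still
be missed) while making the generator's new-clone dial meaningful.
Second, truly expanded clones are drawn among clones with baseline
frequency between $1/\text{depth}$ and `maxCloneFreq` = 0.01: below the
window an expansion cannot be observed, and multiplying a dominant clone
(under $\alpha = 2$ the top clone holds ~60% of the repertoire) would
renormalise every other clone downward and turn a "clone-level" effect
into a repertoire-wide artefact.

Randomness is split per participant into named substreams (frequencies
and truth selection; baseline draw; on-treatment draw), each seeded as a
deterministic function of the master seed, arm and participant index.
Identical configurations therefore reproduce cohorts byte-for-byte, and
changing only `fold` leaves all sampling streams aligned, which is what
makes the fold-monotonicity property testable.

What the generator does **not** emulate: real CDR3 sequences (clone ids
are opaque keys), V/D/J usage, PCR amplification bias or the vendor's
template-collapsing chemistry, batch effects between draws, longitudinal
drift unrelated to treatment, or competition between expanding clones
beyond frequency renormalisation. Passing calibration on this generator
shows the *procedures* are correctly implemented and controlled under
their stated nulls — it does not certify performance on real repertoires,
where overdispersion relative to the multinomial would make the binomial
test anti-conservative.

The expression generator is Gaussian on the log₂ TPM scale with
per-(participant, gene) random intercepts shared across timepoints and
arm-by-timepoint mean shifts on designated signature genes. It emulates
the correlation structure the slope model assumes, not RNA-seq count
noise.

## Problem sizes used by the test suite

Calibration tests run at the scale the package targets where that is
cheap (200 null pairs at depth $5\times10^4$ over $2\times10^4$ clones
for FDR calibration; one full 139-participant cohort for truth-recovery
ordering) and at reduced but statistically adequate scale elsewhere
(40 single-arm replicate cohorts for responder-test power; $10^4$
resamples for the richness oracle; 300 replicate null cohorts for
signature-selection calibration). Monte-Carlo assertions use three
Monte-Carlo standard errors as their band.

## Known limitations

* The binomial null assumes multinomial sampling of a fixed frequency
  vector; biological replicate overdispersion is not modelled, so on
  real data the FDR guarantee is approximate.
* "New" clones are detection-defined (see above).
* The per-pair BH family and the inclusive $q \le$ FDR convention are
  choices; both are exposed, neither is certain to match the original
  software's internals.
* The signature slope model excludes incomplete pairs rather than
  fitting unbalanced mixed models.
* Quartile conventions differ across vendors; summaries default to
  `type = 7`.
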