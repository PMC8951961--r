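---
title: "Scoring disorders for newborn screening panels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disorders for newborn screening panels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbspanel)
```

## The problem and the model

Newborn screening panels differ enormously between countries, even where
the same dried-blood-spot (DBS) specimen could support the same assays. To
compare candidate disorders on a common footing, `nbspanel` scores each
inherited metabolic disorder (IMD) on a weighted ordinal rubric organised
around the Wilson–Jungner screening principles: is the **condition**
serious and frequent enough, is a **screening** test workable, and does
early **treatment** change outcomes?

The rubric is purely additive. Seven criteria take discrete levels in
half-point steps; pillar sums are capped at 6 (Condition), 3 (Screening)
and 4 (Treatment) by construction, because each cap equals the sum of its
criteria's maxima; and the total lies in [0, 13]. A disorder whose total
meets the recommendation threshold — a rubric field, default 8.5 — is
flagged as a candidate for panel inclusion. Additivity is what makes the
sensitivity tools exact: removing a pillar or criterion subtracts exactly
its points from every total.

Non-additive aggregation (multiplicative weighting, outranking methods) is
deliberately out of scope: the rubric's purpose is auditability, and an
additive half-point ledger can be checked by hand.

## Criteria, levels and their rationale

**Severity** and **treatment outcomes** are curator-assigned ordinal
levels with documented anchors (e.g. "rapidly progressing form; can be
fatal by adolescence"; "pre-symptomatic initiation changes prognosis for
all forms"). They are pass-throughs, not quantities the engine derives from
raw natural-history data: the sub-criterion decomposition that produces
them belongs to evidence curation, and representing the curator's
conclusion as a level keeps the scored quantity explicit and disputable.
The default level sets are the distinct values observed across the bundled
reference cohort, with one interior severity level (1 point) included for
schema regularity.

**Onset** maps a three-way classification: all forms of the disorder
asymptomatic in the first weeks of life (2 points — the window in which
screening can beat symptoms), some forms asymptomatic (1), symptomatic at
birth or unknown (0).

**Frequency** bands birth prevalence *p* (cases per birth):

| band | points |
|---|---|
| p ≥ 1/50,000 | 2 |
| 1/100,000 ≤ p < 1/50,000 | 1.5 |
| 1/150,000 ≤ p < 1/100,000 | 1 |
| 1/250,000 ≤ p < 1/150,000 | 0.5 |
| p < 1/250,000, or no estimate | 0 |

The top band is closed at 1/50,000 and the interior bands are half-open
(closed at their lower-prevalence bound), so every prevalence maps to
exactly one band; prose descriptions of bands as "between X and Y" do not
fix the boundary convention, and this one makes the banding a
non-decreasing step function of prevalence with the inclusive endpoint at
the stated top-band bound. A disorder with no defensible estimate scores
0 rather than being imputed: the rubric scores available evidence only.

**Screening availability** gives 2 points to a DBS assay in use in a
public programme *or* CE-marked/FDA-approved, 1 to an assay in
development, 0 otherwise; **performance** gives 1 point to an assay with a
low false-positive rate on its own and 0.5 where a second-tier
confirmatory strategy (e.g. enzyme activity on the same spot) is required
and available. **Treatment availability** reflects the highest-scoring
strategy only — EMA-approved (1.5), phase III or an established
intervention such as diet/HSCT/BMT (1), limited intervention (0.5), none
(0) — and a disorder with no strategy cannot carry outcomes points; that
cross-field rule is enforced at validation and again at scoring.

## Numerical conventions

Scores are stored as numerics but every comparison (equality, threshold,
cap checks) goes through integer half-units (`round(2x)`), so the
half-point grid is exact and no tolerance ever enters a decision. The
threshold test is `total ≥ τ` on half-units, making 8.5 itself
recommended.

Ranking must be deterministic for reproducible reports, but totals tie
heavily on a 27-point grid. The order is: descending total, then
descending Treatment, Screening and Condition pillar sums (in that order,
privileging actionability among equals), then ascending display name under
the C collation. Re-ranking a ranked table is the identity, and ranking is
always a permutation of its input.

Summary bins over totals are configuration, not code
(`default_score_bins()`): the defaults mirror how panel reports group
scores — {12–13, 11–11.5, 10–10.5, 9–9.5, 8.5, <8.5} — and sum to the
cohort size by construction.

## The bundled reference cohort

`imd_cohort()` ships a 48-disorder evaluation of candidates for expanded
European screening: 20 lysosomal storage disorders, 8 organic acid, 7
amino acid and 9 fatty acid metabolism disorders, and 4 others (SCID,
classic galactosaemia, biotinidase deficiency, X-ALD). Each record stores
*both* the curated evidence levels and the reference sub-scores
(`printed_*` columns), so the test suite can separate two claims: the
engine maps evidence to points correctly, and the fixture was transcribed
correctly. All 48 reference totals equal the sum of their seven
sub-scores, and scoring the evidence reproduces every sub-score and total.

Two caveats are part of the cohort's documentation rather than its data.
First, the per-disorder birth-prevalence estimates behind the frequency
sub-scores are not distributed; the `prevalence` column carries synthetic
band representatives (1/40,000, 1/75,000, 1/120,000, 1/200,000, or absent)
that reproduce the reference frequency points but are not the curated
estimates. Second, a handful of summary counts quoted around the original
evaluation depend on curation detail below the sub-score level (e.g. how
many disorders reached full screening availability via the "in use" route
versus the "registered assay" route, or onset sub-criterion counts) and
cannot be derived from the bundled columns; this package reports only
fixture-derived counts and makes no claim about those. Related published
tallies also disagree internally in small ways (eight vs nine disorders in
the 9–9.5 bin, four vs three at exactly 8.5 — both versions give 35 at or
above threshold — and 20 vs 21 lysosomal storage disorders); the bundled
labels follow the enumeration that yields 20 LSDs and the bin counts are
whatever the scored cohort produces (8 and 4).

## The synthetic generator

`generate_cohort()` emulates evidence records, not disorders: each field
is drawn from a per-criterion categorical distribution whose default
weights are the empirical level frequencies of the bundled cohort, so
synthetic score distributions resemble the reference one. Prevalence is
drawn by sampling a frequency band and then a value uniformly within the
band intersected with `prevalence_range` (default 1/2,000,000 to
1/10,000); the zero band yields an absent estimate. Cross-field invariants
are enforced during sampling, so generated cohorts always validate, and a
seed makes output byte-identical across runs.

What the generator does *not* emulate: correlations between criteria that
exist in real cohorts (treatable disorders attract assay development, so
screening and treatment levels correlate), class-dependent level profiles,
and any real-world prevalence distribution within a band. Passing
property tests on synthetic cohorts therefore demonstrates the pipeline's
algebraic invariants — additivity, caps, monotonicity, determinism —
under arbitrary valid evidence, not calibration against real
epidemiology.

## Sensitivity analytics

`threshold_sweep()` recounts the recommended set over an ascending
threshold grid (default 0 to 13 in half-points, matching score
granularity); counts are non-increasing and the recommended sets are
nested. `criterion_ablation()` removes one pillar or criterion and
recomputes totals by subtraction, reporting rank stability as Kendall
τ-b between the original and ablated score orderings. τ-b is the
tie-corrected variant; with at most 27 distinct totals over a cohort,
ties dominate and the uncorrected statistic would be systematically
deflated. Two fully tied vectors are reported as concordance 1 (trivial
agreement); one-sided degeneracy is undefined and returned as `NA`. The
implementation delegates to R's tie-corrected Kendall correlation and is
tested against an independent brute-force concordant/discordant pair
count.

## Problem sizes and test design

The package's own checks run the full 48-disorder reference cohort
end-to-end (scoring, ranking, classification, summaries, sweeps,
ablations) and synthetic cohorts of up to 60 records across a handful of
seeds; the τ-b oracle comparison uses cohorts of at most 8 records, where
exhaustive pair enumeration is transparent. These sizes exercise every
code path — the pipeline is O(n) in the cohort apart from the O(n log n)
sort and O(n²) pair counts in the oracle — and the same functions scale
unchanged to cohorts orders of magnitude larger.

## Known limitations

- The rubric is additive by design; interactions between pillars (a
  superb treatment with no assay) influence the total only through their
  separate points.
- Severity and outcomes levels encode curator judgement; the package
  validates and scores them but cannot audit the judgement itself.
- Evidence is scored as point values; uncertainty in prevalence or
  treatment-effect estimates is not propagated. A prevalence near a band
  boundary can move a total by half a point, which `threshold_sweep()`
  can surface but not resolve.
- The recommendation threshold is a policy choice. 8.5 is the default
  because it was validated against an established national programme's
  panel, but the package treats it as a parameter, and the classification
  near the threshold (where four disorders sit at exactly 8.5) is
  correspondingly sensitive.
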