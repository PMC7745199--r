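---
title: "Tracking evidence instability across preprint and journal sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking evidence instability across preprint and journal sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlink)
```

## The problem

During a fast-moving health crisis a single study often exists as several
evidence sources at once: one or more dated preprint versions and, later, a
journal article. Effect estimates, p-values, sample sizes and abstract
conclusions can differ between those sources, and a systematic reviewer who
reads only one of them may work from outdated evidence. evlink implements
the computational core of a meta-research analysis of this instability:

1. **Record linkage** — decide from bibliographic metadata alone which
   journal article reports the same study as a given preprint.
2. **Change detection** — compare the evidence components of two source
   versions and classify the change.
3. **Descriptive synthesis** — corpus summaries, a time-to-publication
   survival curve, conclusion-transition matrices, and usage metrics
   normalized by exposure time.
4. **A synthetic corpus generator** — because the real corpus behind such an
   analysis is assembled from living-review databases and cannot be
   redistributed, every stage here is exercised on generated corpora with
   planted ground truth.

The `analysis/` directory runs these stages as a numbered workflow
(`01_simulate.R` … `04_summarize.R`) writing its tables under `results/`.

## Record linkage

For a candidate preprint–article pair the package computes the features a
bibliographic matcher can obtain from registry metadata:

* `orcid_overlap` — shared ORCIDs over the ORCIDs present on the shorter
  byline (0 when either side has none);
* `first_author_match` — equality of normalized first-author keys
  (lowercased, diacritics transliterated, given name reduced to an initial,
  so "T." and "Theodora" collide);
* `author_overlap` — Jaccard index of normalized author keys;
* `byline_order_similarity` — longest common subsequence of the key
  sequences over the shorter byline length, which rewards preserved
  coauthor order;
* `title_similarity` — Jaccard index of title token sets after removing 25
  function words plus corpus-wide boilerplate tokens (`covid`, `19`,
  `sars`, `cov`, `2`) that carry no discriminating signal;
* `registration_match` — equality of non-null trial-registration IDs;
* `timeline_ok` — the article is not online more than 30 days *before* the
  preprint. Real pairs occasionally publish the article first, so an
  implausible timeline halves the score rather than excluding the pair.

The score is a weighted sum (weights 0.25 / 0.15 / 0.25 / 0.10 / 0.25,
summing to 1); a registration-ID match short-circuits to a match
regardless of score. Matching is a greedy one-to-one assignment in
descending score with deterministic tie-breaking (smaller date gap, then
lexicographic IDs). Only pairs sharing at least one author key or a
registration ID are scored, which keeps the candidate set near-linear.

**Threshold calibration.** The decision threshold defaults to 0.65,
calibrated on the package's own validation harness
(`simulate_linkage_validation()`: 740 true pairs plus 300 decoys under
metadata perturbation). Under that noise model the lowest score a true pair
attains is 2/3 — an article byline with no ORCID information and one
dropped middle author out of three — while unrelated records never exceed
about 0.4. Any threshold inside that margin separates the populations; 0.65
leaves headroom on both sides. A stricter 0.70 would cut into the true-pair
range and cost three to five matches per 740.

## Change detection

Two source versions are compared component-wise:

* **Results** are paired on (normalized outcome label, metric), where the
  metric is one of hazard ratio, odds ratio, relative risk, event rate
  (percent scale), correlation, or regression coefficient. Any numeric
  change in a matched estimate or p-value beyond the tolerance (default
  `1e-9`, so re-extraction rounding noise does not register) is a **result
  change**.
* A result change is **important** when the largest relative change
  $|x_{\text{new}} - x_{\text{init}}| / |x_{\text{init}}|$ over matched
  pairs reaches the threshold (default 0.10 — at least 10% of the initial
  value, boundary inclusive) and/or a p-value crosses alpha (default 0.05).
* **Conclusions** are states in direction (positive / neutral / negative
  toward the intervention) × uncertainty (hedged or not); any state change
  counts.
* **Sample size** and the five risk-of-bias-relevant **methods fields**
  (blinding, missing data, randomization/allocation, participant inclusion,
  confounder adjustment) are compared for inequality after whitespace
  normalization; information appearing or disappearing counts as a change.

Pair types per study: first preprint version vs article, latest preprint
version vs article (only when more than one preprint version exists), and
first vs latest preprint version. Study-level flags are the OR over pairs.

Numerical and convention choices, fixed so that results are reproducible:

* A p-value exactly equal to alpha is *not significant* (strict `<`); the
  crossing rule compares the predicate on both sides, so 0.05 → 0.04 is a
  crossing and 0.05 → 0.06 is not. The boundary has measure zero in
  practice but needs one convention.
* Event rates are compared on the ratio scale by default (a change from
  24% to 35% of patients is a 45.8% relative change, not 11 percentage
  points); `change_criteria(event_rate_scale = "percentage_point")` exposes
  the alternative reading, since reasonable analysts differ here.
* An initial estimate of zero leaves the relative change undefined: such
  pairs can trigger a result change but never magnitude-based importance.
* Outcomes reported in only one version are counted as added/removed but do
  not by themselves constitute a result change — the change rules speak of
  changes in metrics and significance, not of outcome-set churn.
* The ≥ 10% boundary is evaluated with the numeric tolerance folded in, so
  a change of exactly 10% classifies as important in floating point too.

**Conclusion coding.** Human coding of abstract conclusions is replaced by
a transparent cue lexicon (`default_cue_lexicon()`): direction by majority
of matched positive/negative cues with ties and no-matches coding neutral
(a deliberately conservative reading of mixed conclusions), uncertainty
"reported" when any hedge cue matches ("might", "further studies", "should
be confirmed", …). Pre-coded assessments, when present on a version, take
precedence over the lexicon. The generator writes conclusion texts from the
same lexicon's templates, which makes the text path testable end to end;
the lexicon is *not* a validated NLP instrument for real abstracts.

## The synthetic corpus generator

`generate_corpus()` emulates the corpus such an analysis observes. The
defaults are the study conditions and are not tuned per run:

| Parameter | Default | Meaning |
|---|---|---|
| `n_studies` | 556 | studies in the corpus |
| `p_preprint` | 0.61 | share reported as preprints |
| `p_article_given_preprint` | 0.195 | preprints acquiring an article |
| `p_multiversion_given_preprint` | 0.27 | preprints with > 1 version |
| `delay_median_days`, `delay_sigma` | 76, 0.49 | log-normal publication delay |
| `p_any_change` … `p_conclusion_change` | 0.45 / 0.30 / 0.21 / 0.24 | change rates among multi-source studies |
| `perturbation_level` | 0.2 | metadata noise on derived article records |

The delay is log-normal because publication delays are right-skewed;
sigma 0.49 places the quartiles near 55 and 106 days around the 76-day
median. Version counts for multi-version preprints follow a decreasing
distribution over 2–6, keeping the median preprint at one version
(IQR 1–2). The perturbation level 0.2 reflects realistic registry noise:
journals abbreviate given names, drop diacritics, occasionally reorder
title words or omit a middle author, and online dates shift by days.

**Planting changes.** Change flags must satisfy the classifier's own
implication chain (important ⇒ result change; crossing ⇒ important), and
the three probabilities are marginal rates among multi-source studies. The
generator draws "any change" at its rate and then allocates components by
the minimal-dependence joint honoring all marginals: given any change, both
components occur with probability $a + b - 1$, result-only with $1 - b$,
conclusion-only with $1 - a$, where $a$ and $b$ are the conditional result
and conclusion rates. Fully independent planting would not leave the
any-change rate as a free parameter, so this small coupling is required for
all four rates to be recoverable; it requires
$p_\text{result} + p_\text{conclusion} \ge p_\text{any}$, which the
parameter validator enforces. Planted changes are constructed to sit on the
right side of every rule: sub-important changes scale an estimate by
2–8% of its initial value, important magnitude changes by 10–45%, and
p-crossings move one p-value across 0.05 while leaving estimates untouched.
Conclusion transitions are drawn from a fixed categorical distribution
whose mode is positive-without-uncertainty → positive-with-uncertainty,
with neutral → positive the most common direction change.

**What the generator does not emulate.** Scientific prose (conclusion texts
are lexicon templates), correlated change types beyond the minimal coupling
above, retractions and corrections, multi-arm outcome keying, and the
heavy-tailed sociology of real bylines. Passing tests therefore demonstrate
that the pipeline's logic is correct under its stated rules — not that the
lexicon or the linkage features would attain the same accuracy on real
bibliographic data.

## Descriptive synthesis

* Percentages are integers rounded half away from zero, each with its
  stated denominator (preprint share over all studies; published and
  multi-version shares over preprint-reported studies; change shares over
  multi-source studies). `summarize_corpus()` re-derives every percentage
  from its own counts, and the test suite asserts that consistency.
* `km_unpublished()` is the product-limit estimator of the probability that
  a preprint remains unpublished, computed via the survival package;
  unpublished preprints are censored at a configurable cutoff date (default
  2020-09-02). With no censoring the curve equals the empirical survivor
  function, and the tests check it against a hand-written product-limit
  oracle.
* Quantiles use linear interpolation between order statistics (type 7) —
  a convention that had to be fixed once for reproducibility.
* Usage metrics are divided by days since first online publication, with
  the denominator clamped at one day so same-day retrieval is defined.
  The preprint's citation share is undefined (and excluded from medians)
  when a pair has zero total citations.

## Problem sizes and determinism

Every random process flows from explicit integer seeds; identical
configuration gives bit-identical outputs (corpus serialization keeps
doubles at full precision for that reason). The test suite exercises the
generator at 150–5,000 studies, the recovery properties at five seeds × 800
studies, and the linkage harness at its full 740 + 300 scale; these sizes
give the binomial checks (3 standard errors) comfortable power while
keeping a full run in minutes on one core. The generator uses a single
seeded stream per corpus, so determinism holds for a fixed call sequence;
per-record sub-streams (insertion-order invariance) were considered and not
implemented, as no consumer mutates corpus order between generation and
analysis.

## Known limitations

* The linkage scoring is a reconstruction of the named metadata features
  with calibrated weights, not a replica of any production matcher; its
  accuracy figures are properties of the synthetic noise model.
* The cue lexicon is a reproducible surrogate for human conclusion coding
  and will misread negated or subtle phrasing in real abstracts.
* Results are keyed by outcome label and metric only; per-arm results that
  share both are flagged as ambiguous rather than resolved.
* Author-outreach counts and subgroup membership are not part of the study
  data model and enter `summarize_corpus()` as arguments.
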