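# evlink

Linkage and change tracking across preprint and journal evidence sources.

A single study assessing, say, a COVID-19 intervention often exists as
several evidence sources at once: one or more dated preprint versions and,
later, a journal article. Effect estimates, p-values, sample sizes and
abstract conclusions can differ between those sources, which matters to
anyone maintaining a living systematic review. evlink is an R package plus
a scripted analysis workflow for studying this instability:

* **Record linkage** — decide from bibliographic metadata (ORCIDs, author
  names, byline order, title words, timelines, trial-registration IDs)
  which journal article reports the same study as a given preprint. A
  candidate pair is scored as a weighted feature sum

  `score = 0.25·orcid + 0.15·first_author + 0.25·authors + 0.10·byline + 0.25·title`,

  matched one-to-one greedily above a calibrated threshold (0.65), with a
  registration-ID match short-circuiting to a match.
* **Change detection** — a change in results is any numeric change in a
  matched effect estimate or p-value; it is *important* when
  `|new − initial| / |initial| ≥ 0.10` for any estimate and/or a p-value
  crosses 0.05. Abstract conclusions are states in direction
  (positive/neutral/negative) × uncertainty (hedged or not); any state
  change counts. Sample-size and risk-of-bias-relevant methods fields are
  compared field-wise.
* **Descriptive synthesis** — corpus summary tables with their stated
  denominators, a Kaplan–Meier curve of preprints remaining unpublished,
  conclusion-transition matrices, and usage metrics normalized per day
  online.
* **Synthetic corpus generator** — corpora with known ground truth (true
  preprint–article links, planted changes that satisfy the classification
  rules exactly), so every stage is testable without any external data.

See `vignettes/evidence-instability.Rmd` for the full methods account.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a
thin script over the package's functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # corpus + ground truth
Rscript analysis/02_link.R       # record linkage + validation harness
Rscript analysis/03_detect.R     # change classification
Rscript analysis/04_summarize.R  # summaries, survival, transitions, usage
```

Output of a run at the default seed:

```
generated 556 studies (seed 20200815)
  337 reported as preprints; 73 preprint-article pairs; 152 multi-source
corpus linkage: 73/73 true pairs recovered (100.00%), 0 false positives
validation harness: 740/740 recovered (100.00%), 0 false positives
202 pair comparisons across 152 multi-source studies (404 studies had nothing to compare)
planted vs detected study-level flags: exact agreement
<corpus summary> 556 studies
  preprint-reported: 337 (61%); article-only: 219
  preprints published: 73 (22%); >1 version: 104 (31%)
  multi-source studies: 152 (27%)
  median delay to publication: 77 days (IQR 57-104)
  changes among multi-source: any 62 (41%), results 37 (24%), important 27 (18%), conclusion 38 (25%)
survival: 337 preprints, 73 published by cutoff; P(unpublished at 90 d) = 0.82
conclusion transitions: 152 studies, 38 changed
citation share attributed to the preprint: median 33% (IQR 14-55)
```

Reading this: 61% of the generated studies were first reported as
preprints; about a fifth of those acquired a journal article, a median of
77 days later; a quarter of the corpus has multiple sources or versions,
and among those studies roughly two in five show a change in at least one
evidence component. The detector's study-level flags agree exactly with
the generator's planted ground truth — the core correctness property of the
pipeline. The 740-pair validation harness puts the linkage algorithm under
metadata noise (abbreviated given names, stripped diacritics, reordered
title words, dropped middle authors, shifted dates) among 300 decoys and
reports recall and false positives.

As a library, the same steps are three calls:

```r
library(evlink)
gen <- generate_corpus(generator_params(seed = 1))
changes <- detect_changes(gen$studies)
summarize_corpus(gen$studies, changes)
```

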