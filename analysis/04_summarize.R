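#!/usr/bin/env Rscript
# Stage 4: descriptive synthesis.
#
# Corpus summary (counts and percentages with their stated denominators),
# Kaplan-Meier curve of preprints remaining unpublished, the conclusion
# transition matrix, and exposure-normalized usage metrics for
# preprint-article pairs.

suppressPackageStartupMessages(library(evlink))

studies <- read_corpus("results/corpus.jsonl")
changes <- utils::read.csv("results/changes.csv", stringsAsFactors = FALSE)

s <- summarize_corpus(studies, changes)
print(s)
jsonlite::write_json(unclass(s), "results/summary.json", auto_unbox = TRUE,
                     digits = NA, null = "null", pretty = TRUE)

delays <- publication_delays(studies, cutoff = as.Date("2020-09-02"))
curve <- km_unpublished(delays)
utils::write.csv(data.frame(time = curve$time, surv = curve$surv,
                            n_risk = curve$n_risk, n_event = curve$n_event,
                            n_censor = curve$n_censor),
                 "results/survival.csv", row.names = FALSE)
cat(sprintf("survival: %d preprints, %d published by cutoff; P(unpublished at 90 d) = %.2f\n",
            nrow(delays), sum(delays$event), surv_at(curve, 90)))

ends <- conclusion_endpoints(studies)
tm <- transition_counts(ends$first, ends$last)
tm_df <- as.data.frame(as.table(unclass(tm)), stringsAsFactors = FALSE)
names(tm_df) <- c("from", "to", "count")
utils::write.csv(tm_df, "results/transitions.csv", row.names = FALSE)
off_diag <- sum(tm) - sum(diag(unclass(tm)))
cat(sprintf("conclusion transitions: %d studies, %d changed\n",
            sum(tm), off_diag))

# per-day usage rates and the preprint share of citations, for pairs
rates <- list()
for (st in studies) {
  if (is.null(st$usage) || is.null(st$usage$preprint) ||
      is.null(st$usage$article)) next
  pr <- normalize_usage(st$usage$preprint, st$preprint$record$online_date)
  ar <- normalize_usage(st$usage$article, st$article$record$online_date)
  rates[[length(rates) + 1L]] <- data.frame(
    study_id = st$study_id,
    preprint_citations_per_day = pr[["citations_per_day"]],
    article_citations_per_day = ar[["citations_per_day"]],
    citation_share_preprint = citation_share(st$usage$preprint$citations,
                                             st$usage$article$citations))
}
usage <- do.call(rbind, rates)
utils::write.csv(usage, "results/usage_rates.csv", row.names = FALSE)
share <- usage$citation_share_preprint[!is.na(usage$citation_share_preprint)]
mi <- median_iqr(100 * share)
cat(sprintf("citation share attributed to the preprint: median %.0f%% (IQR %.0f-%.0f)\n",
            mi["median"], mi["q1"], mi["q3"]))
cat("wrote results/summary.json, survival.csv, transitions.csv, usage_rates.csv\n")
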