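# Descriptive outputs: corpus summary tables (counts and integer
# percentages with their stated denominators), time-to-publication survival,
# conclusion-transition matrices, and exposure-normalized usage metrics.

CONCLUSION_STATES <- c(
  "positive.not_reported", "positive.reported",
  "neutral.not_reported", "neutral.reported",
  "negative.not_reported", "negative.reported"
)

#' Median and interquartile range
#'
#' Quantiles by linear interpolation between order statistics (type 7, the
#' default convention), fixed here so every summary is reproducible.
#'
#' @param values Non-empty numeric vector.
#' @return Named vector `c(median =, q1 =, q3 =)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # 2.5, 1.75, 3.25
median_iqr <- function(values) {
  if (length(values) == 0 || !is.numeric(values))
    stop_validation("median_iqr needs a non-empty numeric vector")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Kaplan-Meier curve of preprints remaining unpublished
#'
#' Product-limit estimate of the probability that a preprint is still
#' unpublished as a journal article after a given number of days online.
#' With no censoring it equals the empirical survivor function.
#'
#' @param delays Data frame with columns `days` (>= 0 follow-up in days) and
#'   `event` (`TRUE` = journal publication observed at that delay, `FALSE` =
#'   censored at the data cutoff).
#' @return A `survival_curve` list: `time`, `surv` (probability still
#'   unpublished after each time), `n_risk`, `n_event`, `n_censor`.
#' @export
km_unpublished <- function(delays) {
  if (!is.data.frame(delays) || !all(c("days", "event") %in% names(delays)))
    stop_validation("delays must be a data frame with columns days, event")
  if (nrow(delays) == 0)
    stop_validation("km_unpublished needs at least one observation")
  if (any(delays$days < 0))
    stop_validation("follow-up days must be >= 0")
  fit <- survival::survfit(
    survival::Surv(delays$days, as.integer(delays$event)) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = sum(fit$n)),
            class = "survival_curve")
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [km_unpublished()] curve (right-continuous:
#' the probability of still being unpublished just after `t` days).
#'
#' @param curve A `survival_curve`.
#' @param times Numeric vector of days.
#' @return Numeric vector of survival probabilities.
#' @export
surv_at <- function(curve, times) {
  vapply(times, function(t) {
    idx <- which(curve$time <= t)
    if (length(idx) == 0) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Per-day usage rates
#'
#' Divides each usage metric by the number of days the source has been
#' online at retrieval, clamped at a minimum of one day so same-day
#' retrieval does not divide by zero.
#'
#' @param metrics A [usage_metrics()] snapshot.
#' @param online_date Date the source first appeared online.
#' @return Named vector of per-day rates (`citations_per_day`,
#'   `attention_per_day`, `pubpeer_per_day`) plus `exposure_days`.
#' @export
normalize_usage <- function(metrics, online_date) {
  online_date <- as_iso_date(online_date, "online_date")
  days <- as.numeric(metrics$retrieval_date - online_date)
  if (days < 0)
    stop_validation("retrieval_date precedes online_date")
  days <- max(1, days)
  c(citations_per_day = metrics$citations / days,
    attention_per_day = metrics$attention_score / days,
    pubpeer_per_day = metrics$pubpeer_comments / days,
    exposure_days = days)
}

#' Preprint share of a study's total citations
#'
#' @param preprint_citations,article_citations Non-negative counts.
#' @return `preprint / (preprint + article)`, or `NA` when both are zero
#'   (such studies are excluded from citation-share medians).
#' @export
citation_share <- function(preprint_citations, article_citations) {
  if (preprint_citations < 0 || article_citations < 0)
    stop_validation("citation counts must be >= 0")
  total <- preprint_citations + article_citations
  if (total == 0) return(NA_real_)
  preprint_citations / total
}

#' Conclusion-transition counts
#'
#' 6x6 matrix of counts over conclusion states (direction x uncertainty)
#' from the first preprint version to the latest available source. The
#' diagonal holds unchanged conclusions; the off-diagonal total equals the
#' number of conclusion changes.
#'
#' @param first,last Lists of [conclusion_assessment()] of equal length
#'   (paired by study).
#' @return A `transition_matrix`: integer matrix with state dimnames and an
#'   attribute `direction_matrix` giving the 3x3 direction-only aggregation.
#' @export
transition_counts <- function(first, last) {
  if (length(first) != length(last))
    stop_validation("first and last must have equal length")
  state <- function(c) paste(c$direction, c$uncertainty, sep = ".")
  m <- matrix(0L, 6, 6, dimnames = list(from = CONCLUSION_STATES,
                                        to = CONCLUSION_STATES))
  for (i in seq_along(first)) {
    m[state(first[[i]]), state(last[[i]])] <-
      m[state(first[[i]]), state(last[[i]])] + 1L
  }
  dirs <- c("positive", "neutral", "negative")
  d <- matrix(0L, 3, 3, dimnames = list(from = dirs, to = dirs))
  for (a in dirs) for (b in dirs) {
    d[a, b] <- sum(m[grep(paste0("^", a), CONCLUSION_STATES),
                     grep(paste0("^", b), CONCLUSION_STATES)])
  }
  structure(m, class = c("transition_matrix", "matrix"),
            direction_matrix = d)
}

#' First-to-latest conclusion pairs of a corpus
#'
#' For every study with more than one source or version, the coded
#' conclusion of the first preprint version and of the latest available
#' source (journal article if present, otherwise the latest preprint
#' version).
#'
#' @param studies List of [study()] objects.
#' @param lexicon Cue lexicon for versions without a pre-coded conclusion.
#' @return `list(first =, last =, study_id =)`.
#' @export
conclusion_endpoints <- function(studies, lexicon = default_cue_lexicon()) {
  first <- list(); last <- list(); ids <- character(0)
  for (s in studies) {
    nv <- if (is.null(s$preprint)) 0L else length(s$preprint$versions)
    multi <- (nv >= 1L && !is.null(s$article)) || nv > 1L
    if (!multi) next
    v_first <- s$preprint$versions[[1]]
    v_last <- if (!is.null(s$article)) s$article$version
              else s$preprint$versions[[nv]]
    first[[length(first) + 1L]] <- version_conclusion(v_first, lexicon)
    last[[length(last) + 1L]] <- version_conclusion(v_last, lexicon)
    ids <- c(ids, s$study_id)
  }
  list(first = first, last = last, study_id = ids)
}

study_has_preprint <- function(s) !is.null(s$preprint)
study_has_article <- function(s) !is.null(s$article)
study_multiversion <- function(s) {
  !is.null(s$preprint) && length(s$preprint$versions) > 1L
}
study_multisource <- function(s) {
  (study_has_preprint(s) && study_has_article(s)) || study_multiversion(s)
}

#' Summarize a corpus with its change records
#'
#' Computes the corpus-level counts, integer percentages (rounded half away
#' from zero, each with its stated denominator), publication-delay and
#' version-count medians, and per-pair-type change rates.
#'
#' Denominators: the preprint share is over all studies; the published and
#' multiversion shares over preprint-reported studies; change shares over
#' multi-source studies (more than one source or version); the author
#' response rate over contacted authors; the subgroup change share over
#' subgroup studies with multiple sources.
#'
#' @param studies List of [study()] objects.
#' @param change_records Data frame from [detect_changes()]; must reference
#'   known study IDs.
#' @param subgroup_ids Optional study IDs forming an analysis subgroup (e.g.
#'   studies usable for quantitative evidence synthesis); change shares are
#'   reported for it separately.
#' @param author_contact Optional `c(contacted =, responded =)` counts from
#'   an author-outreach step; reported as a response percentage.
#' @return A `corpus_summary` list of counts, percentages (`NA` where a
#'   denominator is zero) and medians.
#' @export
summarize_corpus <- function(studies, change_records = NULL,
                             subgroup_ids = NULL, author_contact = NULL) {
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (!is.null(change_records) && nrow(change_records) > 0 &&
      !all(change_records$study_id %in% ids))
    stop_validation("change records reference unknown study ids: %s",
                    paste(setdiff(change_records$study_id, ids), collapse = ", "))
  n <- length(studies)
  has_pp <- vapply(studies, study_has_preprint, logical(1))
  has_art <- vapply(studies, study_has_article, logical(1))
  multi_v <- vapply(studies, study_multiversion, logical(1))
  multi_s <- vapply(studies, study_multisource, logical(1))

  n_preprint <- sum(has_pp)
  n_article_only <- sum(!has_pp & has_art)
  n_published <- sum(has_pp & has_art)
  n_multiversion <- sum(multi_v)
  n_multisource <- sum(multi_s)

  delays <- numeric(0)
  versions <- integer(0)
  for (s in studies) {
    if (study_has_preprint(s)) {
      versions <- c(versions, s$preprint$record$version_count)
      if (study_has_article(s))
        delays <- c(delays, as.numeric(s$article$record$online_date -
                                         s$preprint$record$online_date))
    }
  }

  changes <- NULL
  by_pair <- NULL
  if (!is.null(change_records) && nrow(change_records) > 0) {
    sl <- study_level_changes(change_records)
    count <- function(flag) sum(sl[[flag]])
    changes <- list(
      n_any = count("any_change"),
      n_results = count("result_changed"),
      n_important = count("important_change"),
      n_conclusion = count("conclusion_changed"),
      n_methods = count("methods_changed"),
      pct_any = pct_round(count("any_change"), n_multisource),
      pct_results = pct_round(count("result_changed"), n_multisource),
      pct_important = pct_round(count("important_change"), n_multisource),
      pct_conclusion = pct_round(count("conclusion_changed"), n_multisource),
      pct_methods = pct_round(count("methods_changed"), n_multisource)
    )
    by_pair <- lapply(PAIR_TYPES, function(pt) {
      r <- change_records[change_records$pair_type == pt, , drop = FALSE]
      list(pair_type = pt, n_pairs = nrow(r),
           n_any = sum(r$result_changed | r$conclusion_changed |
                         nzchar(methods_field_col(r$methods_fields_changed))),
           n_results = sum(r$result_changed),
           n_important = sum(r$important_change),
           n_conclusion = sum(r$conclusion_changed))
    })
    names(by_pair) <- PAIR_TYPES
  }

  subgroup <- NULL
  if (!is.null(subgroup_ids)) {
    sub_multi <- intersect(subgroup_ids, ids[multi_s])
    n_sub <- length(sub_multi)
    n_sub_any <- 0L
    if (!is.null(change_records) && nrow(change_records) > 0) {
      sl <- study_level_changes(change_records)
      n_sub_any <- sum(sl$any_change & sl$study_id %in% sub_multi)
    }
    subgroup <- list(n_multisource = n_sub, n_any = n_sub_any,
                     pct_any = pct_round(n_sub_any, n_sub))
  }

  response <- NULL
  if (!is.null(author_contact)) {
    response <- list(contacted = author_contact[["contacted"]],
                     responded = author_contact[["responded"]],
                     pct_responded = pct_round(author_contact[["responded"]],
                                               author_contact[["contacted"]]))
  }

  structure(list(
    n_studies = n,
    n_preprint_reported = n_preprint,
    n_article_only = n_article_only,
    n_preprints_published = n_published,
    n_multiversion = n_multiversion,
    n_multisource = n_multisource,
    pct_preprint_reported = pct_round(n_preprint, n),
    pct_article_only = pct_round(n_article_only, n),
    pct_preprints_published = pct_round(n_published, n_preprint),
    pct_multiversion = pct_round(n_multiversion, n_preprint),
    pct_multisource = pct_round(n_multisource, n),
    median_delay_days = if (length(delays)) median_iqr(delays) else NULL,
    median_versions = if (length(versions)) c(median_iqr(versions),
                                              min = min(versions),
                                              max = max(versions)) else NULL,
    changes = changes,
    by_pair_type = by_pair,
    subgroup = subgroup,
    author_response = response
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus summary> %d studies\n", x$n_studies))
  cat(sprintf("  preprint-reported: %d (%s%%); article-only: %d\n",
              x$n_preprint_reported, x$pct_preprint_reported, x$n_article_only))
  cat(sprintf("  preprints published: %d (%s%%); >1 version: %d (%s%%)\n",
              x$n_preprints_published, x$pct_preprints_published,
              x$n_multiversion, x$pct_multiversion))
  cat(sprintf("  multi-source studies: %d (%s%%)\n",
              x$n_multisource, x$pct_multisource))
  if (!is.null(x$median_delay_days))
    cat(sprintf("  median delay to publication: %.0f days (IQR %.0f-%.0f)\n",
                x$median_delay_days["median"], x$median_delay_days["q1"],
                x$median_delay_days["q3"]))
  if (!is.null(x$changes))
    cat(sprintf("  changes among multi-source: any %d (%s%%), results %d (%s%%), important %d (%s%%), conclusion %d (%s%%)\n",
                x$changes$n_any, x$changes$pct_any,
                x$changes$n_results, x$changes$pct_results,
                x$changes$n_important, x$changes$pct_important,
                x$changes$n_conclusion, x$changes$pct_conclusion))
  invisible(x)
}

#' Publication-delay observations for survival analysis
#'
#' One row per preprint-reported study: observed delay and event indicator
#' for published preprints, censoring at the cutoff date for unpublished
#' ones. Studies whose preprint appeared after the cutoff are excluded.
#'
#' @param studies List of [study()] objects.
#' @param cutoff Censoring date for unpublished preprints.
#' @return Data frame with `study_id`, `days`, `event`.
#' @export
publication_delays <- function(studies, cutoff = as.Date("2020-09-02")) {
  cutoff <- as_iso_date(cutoff, "cutoff")
  rows <- list()
  for (s in studies) {
    if (!study_has_preprint(s)) next
    pp_date <- s$preprint$record$online_date
    if (pp_date > cutoff) next
    if (study_has_article(s)) {
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = s$study_id,
        days = as.numeric(s$article$record$online_date - pp_date),
        event = TRUE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = s$study_id, days = as.numeric(cutoff - pp_date),
        event = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(study_id = character(), days = numeric(),
                      event = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
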