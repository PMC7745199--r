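# Classification of changes between evidence sources or versions of one
# study: numeric result changes and their importance (>= 10% relative change
# in any effect estimate and/or a p-value crossing 0.05), abstract-conclusion
# changes (direction x uncertainty), sample-size changes, and field-wise
# changes in risk-of-bias-relevant methods descriptions.

PAIR_TYPES <- c("first_preprint_vs_article", "latest_preprint_vs_article",
                "first_vs_latest_preprint")

#' Change-classification criteria
#'
#' @param relative_change_threshold Minimum relative change in an effect
#'   estimate (|new - initial| / |initial|) for a result change to count as
#'   important. Default 0.10: a change of at least 10\% of the initial value.
#' @param alpha Significance threshold whose crossing by a p-value makes a
#'   change important. Default 0.05.
#' @param numeric_tolerance Absolute difference below which two reported
#'   values are considered equal, so rounding artifacts in extracted decimals
#'   do not register as changes.
#' @param event_rate_scale `"relative"` (default) treats percent event rates
#'   like any other estimate, so 24 -> 35 is a 45.8\% relative change;
#'   `"percentage_point"` divides the absolute percentage-point difference
#'   by 100 instead.
#' @return A `change_criteria` list.
#' @export
change_criteria <- function(relative_change_threshold = 0.10, alpha = 0.05,
                            numeric_tolerance = 1e-9,
                            event_rate_scale = c("relative", "percentage_point")) {
  if (!is_scalar_number(relative_change_threshold) ||
      relative_change_threshold <= 0)
    stop_validation("relative_change_threshold must be > 0")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must lie in (0, 1)")
  if (!is_scalar_number(numeric_tolerance) || numeric_tolerance < 0)
    stop_validation("numeric_tolerance must be >= 0")
  structure(list(relative_change_threshold = relative_change_threshold,
                 alpha = alpha, numeric_tolerance = numeric_tolerance,
                 event_rate_scale = match.arg(event_rate_scale)),
            class = "change_criteria")
}

#' Relative change of an estimate
#'
#' `|new - initial| / |initial|`; the denominator is always the initial
#' value, so the measure is deliberately asymmetric in its arguments.
#'
#' @param initial,new Numeric estimates; `initial` must be non-zero.
#' @return Non-negative relative change.
#' @export
#' @examples
#' relative_change(24, 35) # 0.4583...
relative_change <- function(initial, new) {
  if (!is_scalar_number(initial) || !is_scalar_number(new))
    stop_validation("relative_change needs two numbers")
  if (initial == 0)
    stop_validation("relative change is undefined for initial = 0")
  abs(new - initial) / abs(initial)
}

#' Does a p-value cross the significance threshold?
#'
#' `TRUE` iff both p-values are present and exactly one of them is strictly
#' below `alpha`. A p-value exactly equal to `alpha` is treated as not
#' significant (strict `<`). Missing values never cross.
#'
#' @param p_old,p_new P-values in `[0, 1]` or `NULL`.
#' @param alpha Significance threshold.
#' @return Logical.
#' @export
p_crossing <- function(p_old, p_new, alpha = 0.05) {
  if (is.null(p_old) || is.null(p_new)) return(FALSE)
  if (is.na(p_old) || is.na(p_new)) return(FALSE)
  (p_old < alpha) != (p_new < alpha)
}

result_key <- function(r) paste(normalize_ws(r$outcome_label), r$metric, sep = "\r")

#' Pair reported results of two versions by outcome and metric
#'
#' Results are matched on (normalized outcome label, metric); labels are
#' lowercased and whitespace-collapsed. Results present only in `b` are
#' "added", only in `a` "removed".
#'
#' @param a,b Lists of [reported_result()].
#' @return `list(matched = list of list(a=, b=), added =, removed =)` where
#'   `added`/`removed` are lists of unmatched results. Duplicate keys within
#'   one version are ambiguous and raise an error.
#' @export
pair_results <- function(a, b) {
  ka <- vapply(a, result_key, character(1))
  kb <- vapply(b, result_key, character(1))
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop_validation("duplicate (outcome_label, metric) within one version")
  common <- intersect(ka, kb)
  matched <- lapply(common, function(k) {
    list(a = a[[match(k, ka)]], b = b[[match(k, kb)]])
  })
  list(matched = matched,
       added = b[!kb %in% ka],
       removed = a[!ka %in% kb])
}

#' Classify the result change between two versions
#'
#' A result change is any numeric change (beyond tolerance) in a matched
#' effect estimate or p-value. It is important when the largest relative
#' estimate change reaches the threshold and/or a p-value crosses alpha.
#' Pairs whose initial estimate is zero can trigger a result change but are
#' excluded from the magnitude criterion (relative change undefined).
#' Outcomes present in only one version are counted as added/removed but do
#' not by themselves constitute a result change.
#'
#' @param a,b Lists of [reported_result()] (initial and later version).
#' @param n_a,n_b Sample sizes of the two versions.
#' @param criteria A [change_criteria()].
#' @return List with `result_changed`, `important_change`,
#'   `max_relative_change` (`NA` when no matched pair has a usable
#'   denominator), `p_crossed`, `sample_size_changed`, `outcomes_added`,
#'   `outcomes_removed`.
#' @export
classify_result_change <- function(a, b, n_a = NA, n_b = NA,
                                   criteria = change_criteria()) {
  pairs <- pair_results(a, b)
  tol <- criteria$numeric_tolerance
  result_changed <- FALSE
  p_crossed <- FALSE
  rel_changes <- numeric(0)
  for (m in pairs$matched) {
    ea <- m$a$estimate; eb <- m$b$estimate
    if (!is.null(ea) && !is.null(eb)) {
      if (abs(eb - ea) > tol) result_changed <- TRUE
      if (abs(ea) > 0) {
        rc <- if (m$a$metric == "event_rate" &&
                  criteria$event_rate_scale == "percentage_point")
          abs(eb - ea) / 100
        else relative_change(ea, eb)
        rel_changes <- c(rel_changes, rc)
      }
    }
    pa <- m$a$p_value; pb <- m$b$p_value
    if (!is.null(pa) && !is.null(pb) && abs(pb - pa) > tol)
      result_changed <- TRUE
    if (p_crossing(pa, pb, criteria$alpha)) p_crossed <- TRUE
  }
  max_rel <- if (length(rel_changes)) max(rel_changes) else NA_real_
  # inclusive >= boundary, robust to floating-point representation (a change
  # of exactly 10% of the initial value counts as important)
  important <- (!is.na(max_rel) &&
                  max_rel >= criteria$relative_change_threshold -
                    criteria$numeric_tolerance) || p_crossed
  list(
    result_changed = result_changed,
    important_change = important,
    max_relative_change = max_rel,
    p_crossed = p_crossed,
    sample_size_changed = !is.na(n_a) && !is.na(n_b) && n_a != n_b,
    outcomes_added = length(pairs$added),
    outcomes_removed = length(pairs$removed)
  )
}

# Conclusion coding -------------------------------------------------------

#' Default cue lexicon for conclusion coding
#'
#' Regular-expression cues (matched on lowercased text) for positive and
#' negative stances toward the intervention and for hedged phrasing. The
#' lexicon is a reproducible surrogate for human coding of abstract
#' conclusions; pre-coded assessments, when present, take precedence.
#'
#' @return List with `positive`, `negative` and `hedge` character vectors.
#' @export
default_cue_lexicon <- function() {
  list(
    positive = c("\\beffectiv", "\\befficac", "\\bimprov", "\\bbenefi",
                 "\\bprotectiv", "reduced mortality", "reduction in harms",
                 "\\bfavorab", "shorter .*(recovery|hospital)"),
    negative = c("\\bharm", "\\badverse (outcomes|effects) increas",
                 "\\bworsen", "\\bdeteriorat", "increased mortality",
                 "\\bunsafe\\b", "\\bdetriment"),
    hedge = c("\\bmight\\b", "\\bmay\\b", "\\bcould\\b", "further stud",
              "should be confirmed", "needs? to be confirmed", "\\bpreliminar",
              "larger trials", "\\buncertain", "additional (studies|trials|evidence)",
              "needed to confirm")
  )
}

count_cues <- function(text, patterns) {
  sum(vapply(patterns, function(p) grepl(p, text), logical(1)))
}

#' Code an abstract conclusion from its text
#'
#' The direction is decided by majority over matched positive and negative
#' cues (ties and no matches code as neutral); uncertainty is `"reported"`
#' iff any hedge cue matches.
#'
#' @param text Non-empty conclusion text.
#' @param lexicon Cue lexicon, see [default_cue_lexicon()].
#' @return A [conclusion_assessment()].
#' @export
#' @examples
#' classify_conclusion("The drug might be effective.") # positive, reported
classify_conclusion <- function(text, lexicon = default_cue_lexicon()) {
  if (!is_scalar_string(text) || !nzchar(trimws(text)))
    stop_validation("conclusion text must be non-empty")
  low <- tolower(text)
  pos <- count_cues(low, lexicon$positive)
  neg <- count_cues(low, lexicon$negative)
  direction <- if (pos > neg) "positive" else if (neg > pos) "negative" else "neutral"
  uncertainty <- if (count_cues(low, lexicon$hedge) > 0) "reported" else "not_reported"
  conclusion_assessment(direction, uncertainty)
}

#' Did the conclusion change?
#'
#' Any change in direction (positive/neutral/negative) or in whether
#' uncertainty is reported counts as a conclusion change.
#'
#' @param a,b [conclusion_assessment()] objects.
#' @return Logical.
#' @export
conclusion_changed <- function(a, b) {
  a$direction != b$direction || a$uncertainty != b$uncertainty
}

# Coded assessment of a version: pre-coded when present (human coding takes
# precedence), otherwise lexicon-coded from the text.
version_conclusion <- function(v, lexicon = default_cue_lexicon()) {
  if (!is.null(v$conclusion)) return(v$conclusion)
  classify_conclusion(v$conclusion_text, lexicon)
}

#' Field-wise methods-profile comparison
#'
#' Names of risk-of-bias-relevant fields whose whitespace-normalized values
#' differ between two profiles; a field going from absent to present (or
#' vice versa) counts as a change, since adding or removing such information
#' can alter a risk-of-bias appraisal. Field order is stable.
#'
#' @param a,b [methods_profile()] objects (either may be `NULL`, treated as
#'   all-absent).
#' @return Character vector of changed field names.
#' @export
detect_methods_changes <- function(a, b) {
  if (is.null(a)) a <- methods_profile()
  if (is.null(b)) b <- methods_profile()
  changed <- vapply(METHODS_FIELDS, function(f) {
    va <- a[[f]]; vb <- b[[f]]
    if (is.null(va) && is.null(vb)) return(FALSE)
    if (is.null(va) != is.null(vb)) return(TRUE)
    !identical(normalize_ws(va), normalize_ws(vb))
  }, logical(1))
  METHODS_FIELDS[changed]
}

# Pair enumeration --------------------------------------------------------

compare_versions <- function(study_id, pair_type, va, vb, criteria, lexicon) {
  res <- classify_result_change(va$results, vb$results,
                                va$sample_size, vb$sample_size, criteria)
  ca <- version_conclusion(va, lexicon)
  cb <- version_conclusion(vb, lexicon)
  cc <- conclusion_changed(ca, cb)
  data.frame(
    study_id = study_id, pair_type = pair_type,
    result_changed = res$result_changed,
    important_change = res$important_change,
    max_relative_change = res$max_relative_change,
    p_crossed = res$p_crossed,
    sample_size_changed = res$sample_size_changed,
    conclusion_changed = cc,
    conclusion_from = paste(ca$direction, ca$uncertainty, sep = "."),
    conclusion_to = paste(cb$direction, cb$uncertainty, sep = "."),
    methods_fields_changed = paste(
      detect_methods_changes(va$methods_profile, vb$methods_profile),
      collapse = ";"),
    outcomes_added = res$outcomes_added,
    outcomes_removed = res$outcomes_removed,
    stringsAsFactors = FALSE
  )
}

#' Compare all applicable source pairs of one study
#'
#' Emits one change record per applicable pair type: first preprint version
#' vs journal article, latest preprint version vs journal article (only when
#' more than one preprint version exists), and first vs latest preprint
#' version. Study-level flags are the OR over these records.
#'
#' @param study An [study()] object with at least two sources or versions.
#' @param criteria A [change_criteria()].
#' @param lexicon Cue lexicon for versions without a pre-coded conclusion.
#' @return Data frame with one row per pair (1 to 3 rows). A study with a
#'   single source and a single version raises a `not_comparable` condition;
#'   corpus-level callers catch and count it (see [detect_changes()]).
#' @export
compare_sources <- function(study, criteria = change_criteria(),
                            lexicon = default_cue_lexicon()) {
  nv <- if (is.null(study$preprint)) 0L else length(study$preprint$versions)
  has_article <- !is.null(study$article)
  if (nv <= 1L && !(nv >= 1L && has_article))
    stop_not_comparable(study$study_id)
  rows <- list()
  if (nv >= 1L && has_article) {
    rows[[length(rows) + 1L]] <- compare_versions(
      study$study_id, "first_preprint_vs_article",
      study$preprint$versions[[1]], study$article$version, criteria, lexicon)
  }
  if (nv > 1L && has_article) {
    rows[[length(rows) + 1L]] <- compare_versions(
      study$study_id, "latest_preprint_vs_article",
      study$preprint$versions[[nv]], study$article$version, criteria, lexicon)
  }
  if (nv > 1L) {
    rows[[length(rows) + 1L]] <- compare_versions(
      study$study_id, "first_vs_latest_preprint",
      study$preprint$versions[[1]], study$preprint$versions[[nv]],
      criteria, lexicon)
  }
  do.call(rbind, rows)
}

#' Detect changes across a whole corpus
#'
#' Applies [compare_sources()] to every study with more than one source or
#' version; single-source single-version studies are skipped and counted.
#'
#' @param studies List of [study()] objects.
#' @param criteria A [change_criteria()].
#' @param lexicon Cue lexicon.
#' @return Data frame of change records (zero rows if nothing is comparable)
#'   with an attribute `n_skipped`: the number of studies with nothing to
#'   compare.
#' @export
detect_changes <- function(studies, criteria = change_criteria(),
                           lexicon = default_cue_lexicon()) {
  rows <- list(); skipped <- 0L
  for (s in studies) {
    rec <- tryCatch(compare_sources(s, criteria, lexicon),
                    evlink_not_comparable = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L
    else rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    compare_versions("x", "first_vs_latest_preprint",
                     source_version(1, "2020-01-01",
                                    conclusion = conclusion_assessment("neutral", "not_reported")),
                     source_version(2, "2020-01-02",
                                    conclusion = conclusion_assessment("neutral", "not_reported")),
                     criteria, lexicon)[0, ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

# CSV round trips turn an all-empty character column into logical NA;
# normalize before testing for non-empty field lists.
methods_field_col <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Collapse change records to one row per study
#'
#' Study-level flags are the OR over a study's pair records; the maximum
#' relative change is the max over pairs.
#'
#' @param records Data frame from [detect_changes()].
#' @return Data frame with one row per study: `study_id`, `result_changed`,
#'   `important_change`, `p_crossed`, `conclusion_changed`,
#'   `sample_size_changed`, `methods_changed`, `any_change`,
#'   `max_relative_change`.
#' @export
study_level_changes <- function(records) {
  ids <- unique(records$study_id)
  out <- lapply(ids, function(id) {
    r <- records[records$study_id == id, , drop = FALSE]
    methods_changed <- any(nzchar(methods_field_col(r$methods_fields_changed)))
    data.frame(
      study_id = id,
      result_changed = any(r$result_changed),
      important_change = any(r$important_change),
      p_crossed = any(r$p_crossed),
      conclusion_changed = any(r$conclusion_changed),
      sample_size_changed = any(r$sample_size_changed),
      methods_changed = methods_changed,
      any_change = any(r$result_changed) || any(r$conclusion_changed) ||
        methods_changed,
      max_relative_change = if (all(is.na(r$max_relative_change))) NA_real_
                            else max(r$max_relative_change, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- records[0, c("study_id"), drop = FALSE]
  rownames(res) <- NULL
  res
}
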