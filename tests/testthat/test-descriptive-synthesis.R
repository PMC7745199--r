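test_that("median and quartiles follow linear interpolation", {
  expect_equal(median_iqr(76), c(median = 76, q1 = 76, q3 = 76))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  set.seed(4)
  x <- rlnorm(37, 4, 0.5)
  got <- median_iqr(x)
  expect_equal(unname(got),
               c(oracle_quantile(x, 0.5), oracle_quantile(x, 0.25),
                 oracle_quantile(x, 0.75)))
  expect_equal(median_iqr(sample(x)), got) # permutation invariance
  expect_error(median_iqr(numeric(0)), class = "evlink_validation_error")
})

test_that("product-limit estimate matches hand-computed cases", {
  all_censored <- data.frame(days = c(10, 40, 90), event = FALSE)
  expect_true(all(km_unpublished(all_censored)$surv == 1))

  two_events <- km_unpublished(data.frame(days = c(10, 20), event = TRUE))
  expect_equal(surv_at(two_events, c(5, 10, 20)), c(1, 0.5, 0))

  mixed <- km_unpublished(data.frame(days = c(5, 7, 9),
                                     event = c(TRUE, FALSE, TRUE)))
  # at day 5: 3 at risk, 1 event -> 2/3; at day 9 the risk set is the single
  # remaining subject, so survival drops to 0
  expect_equal(surv_at(mixed, c(5, 8, 9)), c(2 / 3, 2 / 3, 0))

  expect_error(km_unpublished(data.frame(days = -1, event = TRUE)),
               class = "evlink_validation_error")
})

test_that("without censoring the curve is the empirical survivor function", {
  set.seed(8)
  for (i in 1:25) {
    days <- sample(1:60, sample(3:30, 1), replace = TRUE)
    curve <- km_unpublished(data.frame(days = days, event = TRUE))
    probe <- c(0, sort(unique(days)), max(days) + 1)
    expect_equal(surv_at(curve, probe),
                 vapply(probe, function(t) oracle_empirical_surv(days, t),
                        numeric(1)))
  }
})

test_that("with censoring the curve matches the literal product-limit oracle", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    days <- sample(1:80, n, replace = TRUE)
    event <- runif(n) < 0.6
    if (!any(event)) event[1] <- TRUE
    curve <- km_unpublished(data.frame(days = days, event = event))
    o <- oracle_km(days, event)
    expect_equal(surv_at(curve, o$time), o$surv)
  }
})

test_that("usage normalization divides by clamped exposure days", {
  u <- usage_metrics(30, 15, 2, "2020-04-30")
  r <- normalize_usage(u, "2020-03-31")
  expect_equal(r[["citations_per_day"]], 1)
  expect_equal(r[["attention_per_day"]], 0.5)
  expect_equal(r[["exposure_days"]], 30)
  # same-day retrieval clamps the denominator at one day
  r0 <- normalize_usage(usage_metrics(7, 0, 0, "2020-03-31"), "2020-03-31")
  expect_equal(r0[["citations_per_day"]], 7)
  expect_equal(normalize_usage(usage_metrics(0, 0, 0, "2020-06-01"),
                               "2020-03-31")[["citations_per_day"]], 0)
  # scale equivariance: doubling a metric doubles its rate
  expect_equal(normalize_usage(usage_metrics(60, 30, 4, "2020-04-30"),
                               "2020-03-31")[["citations_per_day"]], 2)
  expect_error(normalize_usage(u, "2020-06-01"),
               class = "evlink_validation_error")
})

test_that("citation share handles the zero-citation case", {
  expect_equal(citation_share(29, 71), 0.29)
  expect_equal(citation_share(0, 5), 0)
  expect_true(is.na(citation_share(0, 0)))
})

test_that("transition counts tally state pairs and aggregate directions", {
  pn <- conclusion_assessment("positive", "not_reported")
  pr <- conclusion_assessment("positive", "reported")
  nn <- conclusion_assessment("neutral", "not_reported")
  pp <- conclusion_assessment("positive", "not_reported")

  same <- replicate(5, pn, simplify = FALSE)
  tm0 <- transition_counts(same, same)
  expect_equal(sum(tm0), 5)
  expect_equal(sum(tm0) - sum(diag(unclass(tm0))), 0)

  first <- c(replicate(12, pn, simplify = FALSE),
             replicate(6, nn, simplify = FALSE))
  last <- c(replicate(12, pr, simplify = FALSE),
            replicate(6, pp, simplify = FALSE))
  tm <- transition_counts(first, last)
  expect_equal(tm["positive.not_reported", "positive.reported"], 12L)
  d <- attr(tm, "direction_matrix")
  expect_equal(d["neutral", "positive"], 6L)
  expect_error(transition_counts(first, last[-1]),
               class = "evlink_validation_error")
})

test_that("off-diagonal transitions equal the conclusion-change count", {
  set.seed(10)
  first <- replicate(40, random_assessment(), simplify = FALSE)
  last <- replicate(40, random_assessment(), simplify = FALSE)
  tm <- transition_counts(first, last)
  n_changed <- sum(mapply(conclusion_changed, first, last))
  expect_equal(sum(tm), 40)
  expect_equal(sum(tm) - sum(diag(unclass(tm))), n_changed)
})

test_that("summary percentages are consistent with their own counts", {
  gen <- generate_corpus(generator_params(n_studies = 200, seed = 17))
  ch <- detect_changes(gen$studies)
  s <- summarize_corpus(gen$studies, ch)
  expect_equal(s$n_preprint_reported + s$n_article_only, s$n_studies)
  expect_equal(s$pct_preprint_reported,
               pct_round(s$n_preprint_reported, s$n_studies))
  expect_equal(s$pct_preprints_published,
               pct_round(s$n_preprints_published, s$n_preprint_reported))
  expect_equal(s$pct_multiversion,
               pct_round(s$n_multiversion, s$n_preprint_reported))
  expect_equal(s$changes$pct_any,
               pct_round(s$changes$n_any, s$n_multisource))
  expect_equal(s$changes$pct_results,
               pct_round(s$changes$n_results, s$n_multisource))
})

test_that("degenerate corpora summarize to zero counts and NA percentages", {
  s <- summarize_corpus(list())
  expect_equal(s$n_studies, 0)
  expect_true(is.na(s$pct_preprint_reported))
  expect_null(s$changes)

  # all single-source: no multi-source stratum, no change section
  conc <- conclusion_assessment("neutral", "not_reported")
  one <- study("s1", "rct", preprint = list(
    record = bib_record("p1", "preprint", "t", list(author("A")), "2020-03-01"),
    versions = list(source_version(1, "2020-03-01", conclusion = conc))))
  ch <- detect_changes(list(one))
  s1 <- summarize_corpus(list(one), ch)
  expect_equal(s1$n_multisource, 0)
  expect_null(s1$changes)
})

test_that("unknown study references are rejected", {
  gen <- generate_corpus(generator_params(n_studies = 10, seed = 2))
  ch <- detect_changes(gen$studies)
  if (nrow(ch) == 0) skip("no comparable studies in this tiny corpus")
  ch$study_id[1] <- "study-9999"
  expect_error(summarize_corpus(gen$studies, ch), "unknown",
               class = "evlink_validation_error")
})

test_that("publication delays censor unpublished preprints at the cutoff", {
  gen <- generate_corpus(generator_params(n_studies = 120, seed = 23))
  cutoff <- as.Date("2020-09-02")
  d <- publication_delays(gen$studies, cutoff)
  expect_true(all(d$days >= 0))
  published <- vapply(gen$studies, function(s)
    !is.null(s$preprint) && !is.null(s$article), logical(1))
  expect_equal(sum(d$event), sum(published))
  cens <- d[!d$event, ]
  for (s in gen$studies) {
    if (!is.null(s$preprint) && is.null(s$article) &&
        s$preprint$record$online_date <= cutoff) {
      expect_true(s$study_id %in% cens$study_id)
    }
  }
})
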