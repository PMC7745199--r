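test_that("relative change is |new - initial| / |initial|", {
  expect_equal(relative_change(24, 35), 11 / 24)
  expect_equal(relative_change(3.2, 3.2), 0)
  expect_equal(relative_change(2.0, 1.8), 0.10)
  expect_equal(relative_change(-2, -1), 0.5)
  expect_error(relative_change(0, 1), class = "evlink_validation_error")
})

test_that("relative change is asymmetric; detection is symmetric", {
  expect_false(relative_change(24, 35) == relative_change(35, 24))
  set.seed(7)
  for (i in 1:20) {
    a <- random_result_list()
    b <- random_result_list()
    ab <- classify_result_change(a, b)
    ba <- classify_result_change(b, a)
    expect_identical(ab$result_changed, ba$result_changed)
    expect_identical(ab$p_crossed, ba$p_crossed)
  }
})

test_that("p-value crossings use strict < at the threshold", {
  expect_true(p_crossing(0.06, 0.04))
  expect_false(p_crossing(0.2, 0.08))
  expect_true(p_crossing(0.05, 0.04))  # 0.05 itself is not significant
  expect_false(p_crossing(0.05, 0.06))
  expect_false(p_crossing(NULL, 0.01))
  expect_false(p_crossing(0.2, NULL))
})

test_that("results pair on normalized label and metric", {
  a <- list(reported_result("Mortality ", "odds_ratio", 1.2),
            reported_result("mortality", "event_rate", 10))
  b <- list(reported_result("mortality", "odds_ratio", 1.2),
            reported_result("recovery", "odds_ratio", 0.8))
  p <- pair_results(a, b)
  expect_length(p$matched, 1)        # same label, different metric: unmatched
  expect_length(p$added, 1)
  expect_length(p$removed, 1)
  p2 <- pair_results(a, a)
  expect_length(p2$matched, 2)
  expect_length(p2$added, 0)
  expect_length(p2$removed, 0)
  expect_error(pair_results(c(a, a[1]), b), "duplicate",
               class = "evlink_validation_error")
})

test_that("result-change classification follows the worked criteria", {
  a <- list(reported_result("adverse events", "event_rate", 24))
  b <- list(reported_result("adverse events", "event_rate", 35))
  r <- classify_result_change(a, b)
  expect_true(r$result_changed)
  expect_true(r$important_change)
  expect_equal(r$max_relative_change, 11 / 24)

  # identical versions: nothing changes
  r0 <- classify_result_change(a, a)
  expect_false(r0$result_changed)
  expect_false(r0$important_change)
  expect_equal(r0$max_relative_change, 0)

  # a 10% change is important under the >= rule (boundary inclusive)
  r10 <- classify_result_change(
    list(reported_result("m", "hazard_ratio", 2.0)),
    list(reported_result("m", "hazard_ratio", 1.8)))
  expect_true(r10$important_change)
  expect_equal(r10$max_relative_change, 0.10)

  # p-value moves without crossing: a change, but not important
  rp <- classify_result_change(
    list(reported_result("m", "odds_ratio", 1.5, p_value = 0.3)),
    list(reported_result("m", "odds_ratio", 1.5, p_value = 0.2)))
  expect_true(rp$result_changed)
  expect_false(rp$important_change)
  expect_false(rp$p_crossed)

  # initial = 0: numeric change detected, magnitude criterion skipped
  rz <- classify_result_change(
    list(reported_result("m", "regression_coefficient", 0)),
    list(reported_result("m", "regression_coefficient", 0.04)))
  expect_true(rz$result_changed)
  expect_false(rz$important_change)
  expect_true(is.na(rz$max_relative_change))

  # sample size
  rs <- classify_result_change(a, a, n_a = 44, n_b = 86)
  expect_true(rs$sample_size_changed)
})

test_that("every classification satisfies the implication chain", {
  set.seed(13)
  for (i in 1:50) {
    r <- classify_result_change(random_result_list(), random_result_list())
    if (r$important_change) expect_true(r$result_changed)
    if (r$p_crossed) expect_true(r$important_change)
  }
})

test_that("raising the importance threshold never adds important changes", {
  gen <- generate_corpus(generator_params(n_studies = 150, seed = 31))
  counts <- vapply(c(0.05, 0.10, 0.25, 0.5), function(thr) {
    ch <- detect_changes(gen$studies,
                         change_criteria(relative_change_threshold = thr))
    sum(study_level_changes(ch)$important_change)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("conclusion coding follows the cue lexicon", {
  c1 <- classify_conclusion("The drug might be effective in severe cases.")
  expect_identical(c1$direction, "positive")
  expect_identical(c1$uncertainty, "reported")

  c2 <- classify_conclusion("These results prove the efficacy of the intervention")
  expect_identical(c2$direction, "positive")
  expect_identical(c2$uncertainty, "not_reported")

  c3 <- classify_conclusion("No difference was observed between arms")
  expect_identical(c3$direction, "neutral")
  expect_identical(c3$uncertainty, "not_reported")

  c4 <- classify_conclusion("Treatment was associated with harm to patients.")
  expect_identical(c4$direction, "negative")

  expect_error(classify_conclusion("  "), class = "evlink_validation_error")
})

test_that("generated conclusion templates code back to their state", {
  for (state in names(evlink:::CONCLUSION_TEMPLATES)) {
    for (intervention in c("remdesivir", "mask mandates")) {
      txt <- sprintf(evlink:::CONCLUSION_TEMPLATES[[state]], intervention)
      coded <- classify_conclusion(txt)
      expect_identical(paste(coded$direction, coded$uncertainty, sep = "."),
                       state, info = txt)
    }
  }
})

test_that("any direction or uncertainty change is a conclusion change", {
  pn <- conclusion_assessment("positive", "not_reported")
  pr <- conclusion_assessment("positive", "reported")
  nn <- conclusion_assessment("neutral", "not_reported")
  expect_true(conclusion_changed(pn, pr))
  expect_true(conclusion_changed(nn, pn))
  expect_false(conclusion_changed(pr, pr))
})

test_that("methods-profile comparison is field-wise with stable order", {
  a <- methods_profile(blinding = "open label")
  expect_identical(detect_methods_changes(a, a), character(0))
  b <- methods_profile(blinding = "open  label",
                       confounder_adjustment = "time-dependent propensity score")
  # whitespace differences are normalized away; added information counts
  expect_identical(detect_methods_changes(a, b), "confounder_adjustment")
  c2 <- methods_profile(blinding = "double blind",
                        missing_data = "complete case")
  expect_identical(detect_methods_changes(a, c2),
                   c("blinding", "missing_data"))
})

test_that("pair enumeration emits one record per applicable pair type", {
  conc <- conclusion_assessment("neutral", "not_reported")
  mkv <- function(k, d) source_version(k, d, conclusion = conc)
  pp <- bib_record("p", "preprint", "t", list(author("A")), "2020-03-01",
                   version_count = 2)
  pp3 <- bib_record("p", "preprint", "t", list(author("A")), "2020-03-01",
                    version_count = 3)
  art <- list(record = bib_record("a", "journal_article", "t",
                                  list(author("A")), "2020-06-01"),
              version = mkv(1, "2020-06-01"))

  two_versions <- study("s1", "rct",
                        preprint = list(record = pp,
                                        versions = list(mkv(1, "2020-03-01"),
                                                        mkv(2, "2020-04-01"))))
  expect_identical(compare_sources(two_versions)$pair_type,
                   "first_vs_latest_preprint")

  full <- study("s2", "rct",
                preprint = list(record = pp3,
                                versions = list(mkv(1, "2020-03-01"),
                                                mkv(2, "2020-04-01"),
                                                mkv(3, "2020-05-01"))),
                article = art)
  expect_setequal(compare_sources(full)$pair_type,
                  c("first_preprint_vs_article", "latest_preprint_vs_article",
                    "first_vs_latest_preprint"))

  single <- study("s3", "rct",
                  preprint = list(
                    record = bib_record("p1", "preprint", "t",
                                        list(author("A")), "2020-03-01"),
                    versions = list(mkv(1, "2020-03-01"))))
  expect_error(compare_sources(single), class = "evlink_not_comparable")
  ch <- detect_changes(list(single, two_versions))
  expect_identical(attr(ch, "n_skipped"), 1L)
  expect_identical(nrow(ch), 1L)
})
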