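test_that("the generator is deterministic given the seed", {
  p <- generator_params(n_studies = 40, seed = 77)
  g1 <- generate_corpus(p)
  g2 <- generate_corpus(p)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(g1$studies, f1); write_corpus(g2$studies, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$ground_truth, g2$ground_truth)
})

test_that("p_preprint = 0 yields an article-only corpus with no links", {
  g <- generate_corpus(generator_params(n_studies = 30, p_preprint = 0,
                                        seed = 5))
  expect_true(all(vapply(g$studies, function(s) is.null(s$preprint),
                         logical(1))))
  expect_equal(nrow(g$ground_truth$true_links), 0L)
})

test_that("inconsistent change probabilities are rejected", {
  expect_error(generator_params(p_important_change = 0.4,
                                p_result_change = 0.3),
               class = "evlink_validation_error")
  expect_error(generator_params(p_result_change = 0.5, p_any_change = 0.4),
               class = "evlink_validation_error")
  expect_error(generator_params(p_any_change = 0.9, p_result_change = 0.4,
                                p_conclusion_change = 0.4),
               class = "evlink_validation_error")
  expect_error(generator_params(p_preprint = 1.2),
               class = "evlink_validation_error")
})

test_that("realized shares converge on the parameters (binomial check)", {
  n <- 1500
  g <- generate_corpus(generator_params(n_studies = n, seed = 19))
  has_pp <- vapply(g$studies, function(s) !is.null(s$preprint), logical(1))
  se <- sqrt(0.61 * 0.39 / n)
  expect_lt(abs(mean(has_pp) - 0.61), 3 * se)

  n_pp <- sum(has_pp)
  published <- vapply(g$studies, function(s)
    !is.null(s$preprint) && !is.null(s$article), logical(1))
  se_pub <- sqrt(0.195 * 0.805 / n_pp)
  expect_lt(abs(sum(published) / n_pp - 0.195), 3 * se_pub)
})

test_that("perturbation at level 0 is the identity", {
  g <- generate_corpus(generator_params(n_studies = 5, seed = 3))
  rec <- g$studies[[1]]$preprint$record %||%
    g$studies[[1]]$article$record
  expect_identical(perturb_record(rec, 0), rec)
})

test_that("perturbation at level 1 changes the record deterministically", {
  rec <- bib_record("p", "preprint", "alpha beta gamma delta",
                    list(author("Müller", "Émile"), author("Okafor", "Ngozi"),
                         author("Silva", "João")),
                    "2020-04-01")
  p1 <- perturb_record(rec, 1, seed = 101)
  p2 <- perturb_record(rec, 1, seed = 101)
  expect_identical(p1, p2)
  expect_false(identical(p1, rec))
  # given names become initials at level 1
  expect_true(all(grepl("^[A-Z]\\.$", vapply(p1$authors, `[[`, "", "given"))))
})

test_that("perturbation never reorders beyond the stated token budget", {
  set.seed(55)
  for (i in 1:20) {
    g <- generate_corpus(generator_params(n_studies = 1, seed = i))
    rec <- g$studies[[1]]$preprint$record %||% g$studies[[1]]$article$record
    level <- runif(1)
    pert <- perturb_record(rec, level)
    toks0 <- sort(strsplit(tolower(rec$title), " +")[[1]])
    toks1 <- sort(strsplit(tolower(pert$title), " +")[[1]])
    n_diff <- length(toks0) - sum(toks1 %in% toks0)
    expect_lte(n_diff, ceiling(level * length(toks0)))
    # first author's family name untouched at moderate noise
    if (level <= 0.5)
      expect_identical(pert$authors[[1]]$family, rec$authors[[1]]$family)
  }
})

test_that("planted changes are recovered exactly by the detector", {
  for (seed in c(101, 202)) {
    g <- generate_corpus(generator_params(n_studies = 150, seed = seed))
    detected <- study_level_changes(detect_changes(g$studies))
    planted <- g$ground_truth$planted
    planted <- planted[planted$multi_source, ]
    m <- merge(planted, detected, by = "study_id")
    expect_equal(nrow(m), nrow(planted))
    expect_identical(m$result_changed.y, m$result_changed.x)
    expect_identical(m$important_change, m$important)
    expect_identical(m$p_crossed.y, m$p_crossed.x)
    expect_identical(m$conclusion_changed.y, m$conclusion_changed.x)
    expect_identical(m$sample_size_changed.y, m$sample_size_changed.x)
    expect_identical(m$any_change,
                     m$result_changed.x | m$conclusion_changed.x)
  }
})

test_that("plant_changes enforces its flag preconditions and boundaries", {
  conc <- conclusion_assessment("neutral", "not_reported")
  mkv <- function(k, d) source_version(
    k, d, results = list(reported_result("m", "odds_ratio", 2.0,
                                         p_value = 0.06)),
    sample_size = 50L, conclusion = conc)
  st <- study("s1", "rct", preprint = list(
    record = bib_record("p1", "preprint", "t", list(author("A")),
                        "2020-03-01", version_count = 2),
    versions = list(mkv(1, "2020-03-01"), mkv(2, "2020-04-01"))))

  expect_error(plant_changes(st, list(important = TRUE), seed = 1),
               class = "evlink_validation_error")

  # all-false spec: the detector sees nothing
  st0 <- plant_changes(st, list(), seed = 1)
  rec0 <- compare_sources(st0)
  expect_false(any(rec0$result_changed | rec0$conclusion_changed |
                     rec0$sample_size_changed))

  # p-crossing: the p-value moves across 0.05 and nothing else changes
  stp <- plant_changes(st, list(result_changed = TRUE, important = TRUE,
                                p_crossed = TRUE), seed = 2)
  p_old <- stp$preprint$versions[[1]]$results[[1]]$p_value
  p_new <- stp$preprint$versions[[2]]$results[[1]]$p_value
  expect_true((p_old < 0.05) != (p_new < 0.05))
  recp <- compare_sources(stp)
  expect_true(all(recp$p_crossed))
  expect_equal(recp$max_relative_change, 0)

  # magnitude route: relative change lands at or above the 10% boundary
  stm <- plant_changes(st, list(result_changed = TRUE, important = TRUE),
                       seed = 3)
  recm <- compare_sources(stm)
  expect_true(all(recm$important_change))
  expect_gte(recm$max_relative_change[1], 0.10)

  # sub-threshold route stays below importance
  sts <- plant_changes(st, list(result_changed = TRUE), seed = 4)
  recs <- compare_sources(sts)
  expect_true(all(recs$result_changed))
  expect_false(any(recs$important_change))
})

test_that("the linkage harness produces disjoint truth and decoys", {
  v <- simulate_linkage_validation(n_true = 15, n_decoys = 5, level = 0.3,
                                   seed = 2)
  expect_length(v$preprints, 15)
  expect_length(v$articles, 20)
  aids <- vapply(v$articles, `[[`, "", "record_id")
  expect_setequal(intersect(aids, v$true_links$article_id),
                  v$true_links$article_id)
})
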