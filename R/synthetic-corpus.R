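# Synthetic corpus generator with planted ground truth. Default parameters
# emulate a pandemic-era intervention-study corpus: 556 studies, 61% with a
# preprint, 19.5% of preprints later published (log-normal delay, median 76
# days), 27% of preprints with >1 version, and conditional change rates of
# 45/30/21/24% (any / results / important / conclusion) among multi-source
# studies. Every planted change is constructed to satisfy exactly the
# classification rule it is labeled with, so detector output can be compared
# against ground truth for exact recovery.

# Name and vocabulary pools (fixed; the generator samples from them).
FAMILY_POOL <- local({
  onsets <- c("al", "ber", "car", "dan", "er", "fis", "gar", "hen", "iz",
              "jan", "kov", "lor", "mar", "nor", "ol", "pet", "qui", "ros",
              "san", "tor", "ul", "vas", "wes", "yil", "zab")
  ends <- c("sen", "ton", "ez", "ini", "ova", "sky", "man", "berg", "dal", "ico")
  pool <- as.vector(outer(onsets, ends, paste0))
  pool <- paste0(toupper(substr(pool, 1, 1)), substr(pool, 2, nchar(pool)))
  c(pool, "Müller", "Gómez", "Nuñez", "Sørensen",
    "Çelik", "Dvořák", "Fernández", "Björk")
})

GIVEN_POOL <- c(
  "Anna", "Bruno", "Carla", "David", "Elena", "Fatima", "Georg", "Hana",
  "Igor", "Julia", "Kenji", "Lucia", "Miguel", "Nadia", "Omar", "Priya",
  "Qing", "Rosa", "Stefan", "Theodora", "Umar", "Vera", "Wei", "Xin",
  "Yusuf", "Zoe", "Émile", "Bjørn", "Inès", "Jürgen"
)

INTERVENTION_POOL <- c(
  "hydroxychloroquine", "remdesivir", "lopinavir-ritonavir", "tocilizumab",
  "corticosteroids", "convalescent plasma", "anticoagulation", "favipiravir",
  "interferon beta", "azithromycin", "ivermectin", "colchicine",
  "lockdown measures", "school closures", "mask mandates",
  "travel restrictions", "contact tracing", "physical distancing"
)

OUTCOME_POOL <- c("all-cause mortality", "viral clearance", "hospitalization",
                  "icu admission", "time to recovery", "adverse events",
                  "case growth rate", "symptom resolution")

VENUE_POOL_PP <- c("medRxiv", "Research Square", "SSRN", "bioRxiv")
VENUE_POOL_J <- c("Journal of Clinical Epidemiology", "Lancet Regional",
                  "Clinical Trials Quarterly", "Epidemiology Letters",
                  "Annals of Evidence", "Respiratory Medicine Reports")

# Conclusion templates keyed "direction.uncertainty"; each template is built
# from the default cue lexicon so that lexicon coding reproduces the state.
CONCLUSION_TEMPLATES <- c(
  "positive.not_reported" = "Treatment with %s was effective and improved clinical outcomes.",
  "positive.reported" = "Treatment with %s might be effective, but further studies are needed to confirm the findings.",
  "neutral.not_reported" = "No difference was observed between the %s and control arms.",
  "neutral.reported" = "Findings for %s were inconclusive and additional studies are required.",
  "negative.not_reported" = "Treatment with %s was associated with harm and worse outcomes.",
  "negative.reported" = "Treatment with %s may be associated with harm; these results should be confirmed in larger trials."
)

conclusion_for_state <- function(state, intervention) {
  parts <- strsplit(state, ".", fixed = TRUE)[[1]]
  list(
    text = sprintf(CONCLUSION_TEMPLATES[[state]], intervention),
    coded = conclusion_assessment(parts[1], parts[2])
  )
}

# Marginal distribution of conclusion states and the transition distribution
# used when a conclusion change is planted. The dominant planted transition
# is positive-without-uncertainty to positive-with-uncertainty, and among
# direction changes neutral-to-positive is the most common.
CONCLUSION_STATE_PROBS <- c(
  "positive.not_reported" = 0.26, "positive.reported" = 0.24,
  "neutral.not_reported" = 0.20, "neutral.reported" = 0.15,
  "negative.not_reported" = 0.08, "negative.reported" = 0.07
)

CONCLUSION_TRANSITIONS <- data.frame(
  from = c("positive.not_reported", "neutral.not_reported", "neutral.reported",
           "positive.not_reported", "neutral.not_reported",
           "positive.reported", "negative.not_reported", "neutral.not_reported"),
  to = c("positive.reported", "positive.not_reported", "positive.reported",
         "neutral.not_reported", "negative.not_reported",
         "positive.not_reported", "neutral.not_reported", "neutral.reported"),
  prob = c(0.30, 0.15, 0.10, 0.12, 0.08, 0.10, 0.08, 0.07),
  stringsAsFactors = FALSE
)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Parameters for the synthetic corpus generator
#'
#' Defaults emulate the corpus the pipeline was designed for: 556
#' intervention studies, of which 61\% appear as preprints; 19.5\% of
#' preprints acquire a journal article after a log-normal delay with median
#' 76 days and log-scale sigma 0.49 (quartiles near 55 and 106 days); 27\%
#' of preprints have more than one version; among multi-source studies, 45\%
#' have any change, 30\% a result change, 21\% an important change and 24\%
#' a conclusion change.
#'
#' @param n_studies Number of studies to generate.
#' @param p_preprint Probability a study is reported as a preprint.
#' @param p_article_given_preprint Probability a preprint has an associated
#'   journal article.
#' @param p_multiversion_given_preprint Probability a preprint has more than
#'   one version.
#' @param delay_median_days,delay_sigma Median (days) and log-scale sigma of
#'   the log-normal preprint-to-article delay.
#' @param p_any_change,p_result_change,p_important_change,p_conclusion_change
#'   Change probabilities conditional on a study being multi-source. Must
#'   satisfy `p_important <= p_result <= p_any`, `p_conclusion <= p_any` and
#'   `p_result + p_conclusion >= p_any` (a study with "any" change has at
#'   least one component change).
#' @param p_sample_size_change_given_result Probability that a planted result
#'   change is accompanied by a sample-size change.
#' @param perturbation_level Metadata noise level in `[0, 1]` applied when an
#'   article record is derived from its preprint record.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   parameters.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_studies = 556,
                             p_preprint = 0.61,
                             p_article_given_preprint = 0.195,
                             p_multiversion_given_preprint = 0.27,
                             delay_median_days = 76,
                             delay_sigma = 0.49,
                             p_any_change = 0.45,
                             p_result_change = 0.30,
                             p_important_change = 0.21,
                             p_conclusion_change = 0.24,
                             p_sample_size_change_given_result = 1 / 3,
                             perturbation_level = 0.2,
                             seed = 20200815) {
  n_studies <- as.integer(n_studies)
  if (is.na(n_studies) || n_studies < 0)
    stop_validation("n_studies must be a non-negative integer")
  probs <- c(p_preprint = p_preprint,
             p_article_given_preprint = p_article_given_preprint,
             p_multiversion_given_preprint = p_multiversion_given_preprint,
             p_any_change = p_any_change, p_result_change = p_result_change,
             p_important_change = p_important_change,
             p_conclusion_change = p_conclusion_change,
             p_sample_size_change_given_result = p_sample_size_change_given_result)
  for (nm in names(probs)) {
    if (!is_probability(probs[[nm]]))
      stop_validation("%s must lie in [0, 1]", nm)
  }
  if (p_important_change > p_result_change)
    stop_validation("p_important_change must be <= p_result_change")
  if (p_result_change > p_any_change)
    stop_validation("p_result_change must be <= p_any_change")
  if (p_conclusion_change > p_any_change)
    stop_validation("p_conclusion_change must be <= p_any_change")
  if (p_any_change > 0 && p_result_change + p_conclusion_change < p_any_change)
    stop_validation(
      "p_result_change + p_conclusion_change must be >= p_any_change (a study with any change has at least one component change)")
  if (!is_scalar_number(delay_median_days) || delay_median_days <= 0)
    stop_validation("delay_median_days must be > 0")
  if (!is_scalar_number(delay_sigma) || delay_sigma <= 0)
    stop_validation("delay_sigma must be > 0")
  if (!is_probability(perturbation_level))
    stop_validation("perturbation_level must lie in [0, 1]")
  structure(list(
    n_studies = n_studies, p_preprint = p_preprint,
    p_article_given_preprint = p_article_given_preprint,
    p_multiversion_given_preprint = p_multiversion_given_preprint,
    delay_median_days = delay_median_days, delay_sigma = delay_sigma,
    p_any_change = p_any_change, p_result_change = p_result_change,
    p_important_change = p_important_change,
    p_conclusion_change = p_conclusion_change,
    p_sample_size_change_given_result = p_sample_size_change_given_result,
    perturbation_level = perturbation_level, seed = as.integer(seed)
  ), class = "generator_params")
}

random_orcid <- function() {
  sprintf("0000-%04d-%04d-%04d", sample.int(9999, 1), sample.int(9999, 1),
          sample.int(9999, 1))
}

random_authors <- function(n = NULL, p_orcid = 0.6) {
  if (is.null(n)) n <- sample(3:10, 1)
  lapply(seq_len(n), function(i) {
    author(family = sample(FAMILY_POOL, 1), given = sample(GIVEN_POOL, 1),
           orcid = if (runif(1) < p_orcid) random_orcid() else NULL)
  })
}

random_title <- function(intervention, design) {
  sprintf("%s of %s %s %s in patients with COVID-19: a %s %s",
          sample(c("Effect", "Impact", "Association", "Efficacy"), 1),
          intervention,
          sample(c("on", "with"), 1),
          sample(OUTCOME_POOL, 1),
          sample(c("multicenter", "retrospective", "nationwide",
                   "single-center", "pragmatic"), 1),
          if (design == "rct") "randomized trial" else "cohort analysis")
}

base_results <- function(design) {
  list(
    reported_result("all-cause mortality",
                    if (design == "rct") "hazard_ratio" else "odds_ratio",
                    estimate = round(exp(rnorm(1, 0, 0.35)), 3),
                    p_value = round(runif(1, 0.001, 0.6), 3)),
    reported_result("adverse events", "event_rate",
                    estimate = round(runif(1, 5, 60), 1)),
    reported_result("time to recovery", "regression_coefficient",
                    estimate = round(rnorm(1, -1, 2), 3),
                    p_value = round(runif(1, 0.001, 0.6), 3))
  )
}

#' Perturb a bibliographic record (metadata noise)
#'
#' Applies, each with probability scaled by `level`: given names reduced to
#' initials, diacritics stripped from names, a swap of two adjacent title
#' tokens, dropping one middle author (never the first or last), and a shift
#' of the online date by up to 14 days either way. The first author's family
#' name is never altered at `level <= 0.5`. `level = 0` returns the record
#' unchanged.
#'
#' @param record A [bib_record()].
#' @param level Noise level in `[0, 1]`.
#' @param seed Optional integer seed for a self-contained draw; `NULL` uses
#'   the current RNG stream.
#' @return A perturbed [bib_record()] with the same `record_id`.
#' @export
perturb_record <- function(record, level, seed = NULL) {
  if (!is_probability(level))
    stop_validation("perturbation level must lie in [0, 1]")
  if (level == 0) return(record)
  with_seed(seed, {
    authors <- record$authors
    # drop one middle author
    if (length(authors) >= 3 && runif(1) < level) {
      # middle positions only; sample(2:2, 1) would draw from 1:2
      middle <- seq(2L, length(authors) - 1L)
      drop <- if (length(middle) == 1L) middle else sample(middle, 1)
      authors <- authors[-drop]
    }
    authors <- lapply(seq_along(authors), function(i) {
      a <- authors[[i]]
      giv <- a$given
      if (nzchar(giv) && runif(1) < level)
        giv <- paste0(substr(giv, 1, 1), ".")
      fam <- a$family
      strip_ok <- i > 1 || level > 0.5
      if (runif(1) < level) {
        giv <- stringi::stri_trans_general(giv, "Latin-ASCII")
        if (strip_ok) fam <- stringi::stri_trans_general(fam, "Latin-ASCII")
      }
      author(family = fam, given = giv, orcid = a$orcid)
    })
    title <- record$title
    toks <- strsplit(title, " +")[[1]]
    if (length(toks) >= 2 && runif(1) < level) {
      i <- sample(seq_len(length(toks) - 1), 1)
      toks[c(i, i + 1)] <- toks[c(i + 1, i)]
      title <- paste(toks, collapse = " ")
    }
    date <- record$online_date
    if (runif(1) < level)
      date <- date + sample(-14:14, 1)
    bib_record(record_id = record$record_id, source_type = record$source_type,
               title = title, authors = authors, online_date = date,
               venue = record$venue, doi = record$doi,
               registration_id = record$registration_id,
               version_count = record$version_count)
  })
}

#' Plant a prescribed set of changes into a study
#'
#' Modifies every source after the first preprint version (later preprint
#' versions and the article version) so that change classification at
#' default criteria recovers exactly the requested flags: a non-important
#' result change perturbs one estimate by under 10\% of its initial value; an
#' important magnitude change scales an estimate by at least 1.10; a p-value
#' crossing moves one p across 0.05 leaving estimates untouched; a
#' conclusion transition rewrites the first version to the from-state and
#' later versions to the to-state. With `result_changed = FALSE` all later
#' results are numerically identical to the first version's.
#'
#' @param study A [study()] with at least two versions or a preprint-article
#'   pair.
#' @param spec List of flags: `result_changed`, `important`, `p_crossed`,
#'   `sample_size_changed` (logicals) and `conclusion_transition` (`NULL` or
#'   `list(from =, to =)` of `"direction.uncertainty"` states).
#' @param seed Optional seed for a self-contained draw.
#' @return The modified study.
#' @export
plant_changes <- function(study, spec, seed = NULL) {
  spec <- utils::modifyList(
    list(result_changed = FALSE, important = FALSE, p_crossed = FALSE,
         sample_size_changed = FALSE, conclusion_transition = NULL),
    spec)
  if (spec$important && !spec$result_changed)
    stop_validation("cannot plant important = TRUE without result_changed")
  if (spec$p_crossed && !spec$important)
    stop_validation("cannot plant p_crossed = TRUE without important")
  nv <- if (is.null(study$preprint)) 0L else length(study$preprint$versions)
  if (nv + as.integer(!is.null(study$article)) < 2L && nv < 2L)
    stop_validation("study '%s': planting needs >= 2 versions or a preprint-article pair",
                    study$study_id)
  tr <- spec$conclusion_transition
  if (!is.null(tr) && identical(tr$from, tr$to))
    stop_validation("conclusion_transition must change the state")
  with_seed(seed, {
    first <- study$preprint$versions[[1]]
    modified <- first
    if (spec$result_changed) {
      if (spec$p_crossed) {
        idx <- which(vapply(modified$results,
                            function(r) !is.null(r$p_value), logical(1)))[1]
        r <- modified$results[[idx]]
        r$p_value <- if (r$p_value < 0.05) round(runif(1, 0.055, 0.4), 3)
                     else round(runif(1, 0.005, 0.045), 3)
        modified$results[[idx]] <- r
      } else {
        idx <- which(vapply(modified$results, function(r) {
          !is.null(r$estimate) && r$estimate != 0
        }, logical(1)))[1]
        r <- modified$results[[idx]]
        factor <- if (spec$important) 1 + runif(1, 0.10, 0.45)
                  else 1 + runif(1, 0.02, 0.08)
        r$estimate <- r$estimate * factor
        if (r$metric == "event_rate") r$estimate <- min(r$estimate, 100)
        modified$results[[idx]] <- r
      }
    }
    if (spec$sample_size_changed)
      modified$sample_size <- modified$sample_size +
        max(1L, as.integer(round(modified$sample_size * 0.5)))
    intervention <- study$intervention_category
    if (!is.null(tr)) {
      from <- conclusion_for_state(tr$from, intervention)
      to <- conclusion_for_state(tr$to, intervention)
      first$conclusion_text <- from$text
      first$conclusion <- from$coded
      modified$conclusion_text <- to$text
      modified$conclusion <- to$coded
    }
    versions <- study$preprint$versions
    versions[[1]] <- first
    if (nv > 1) {
      for (k in 2:nv) {
        v <- modified
        v$version_number <- versions[[k]]$version_number
        v$date <- versions[[k]]$date
        versions[[k]] <- v
      }
    }
    study$preprint$versions <- versions
    if (!is.null(study$article)) {
      av <- modified
      av$version_number <- 1L
      av$date <- study$article$version$date
      study$article$version <- av
    }
    study
  })
}

draw_planted_flags <- function(params) {
  any_change <- runif(1) < params$p_any_change
  flags <- list(result_changed = FALSE, important = FALSE, p_crossed = FALSE,
                sample_size_changed = FALSE, conclusion_transition = NULL)
  if (!any_change) return(flags)
  # Joint of (result, conclusion) given any-change: marginals
  # p_result/p_any and p_conclusion/p_any, constrained to at least one TRUE.
  a <- params$p_result_change / params$p_any_change
  b <- params$p_conclusion_change / params$p_any_change
  u <- runif(1)
  if (u < a + b - 1) {
    result <- TRUE; conclusion <- TRUE
  } else if (u < a) {
    result <- TRUE; conclusion <- FALSE
  } else {
    result <- FALSE; conclusion <- TRUE
  }
  if (result) {
    flags$result_changed <- TRUE
    flags$important <- runif(1) < params$p_important_change / params$p_result_change
    if (flags$important) flags$p_crossed <- runif(1) < 0.5
    flags$sample_size_changed <-
      runif(1) < params$p_sample_size_change_given_result
  }
  if (conclusion) {
    k <- sample.int(nrow(CONCLUSION_TRANSITIONS), 1,
                    prob = CONCLUSION_TRANSITIONS$prob)
    flags$conclusion_transition <- list(from = CONCLUSION_TRANSITIONS$from[k],
                                        to = CONCLUSION_TRANSITIONS$to[k])
  }
  flags
}

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic given `params$seed`. Realized corpus-level proportions
#' converge to the parameters as `n_studies` grows; publication delays are
#' log-normal with the stated median and sigma; every planted change
#' satisfies the classification rule it is labeled with, so change detection
#' at default criteria recovers the planted flags exactly.
#'
#' @param params A [generator_params()].
#' @return `list(studies =, ground_truth =)` where `ground_truth` holds
#'   `true_links` (data frame of preprint/article record-ID pairs) and
#'   `planted` (one row per study: multi-source status and planted flags).
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n_studies
  studies <- vector("list", n)
  links <- list()
  planted_rows <- vector("list", n)
  origin <- as.Date("2020-01-15")
  for (i in seq_len(n)) {
    sid <- sprintf("study-%04d", i)
    design <- if (runif(1) < 0.3) "rct" else "observational"
    intervention <- sample(INTERVENTION_POOL, 1)
    title <- random_title(intervention, design)
    authors <- random_authors()
    reg_id <- if (design == "rct" && runif(1) < 0.5)
      sprintf("NCT%08d", sample.int(1e7, 1)) else NULL
    has_preprint <- runif(1) < params$p_preprint
    base_date <- origin + sample(0:210, 1)

    state0 <- sample(names(CONCLUSION_STATE_PROBS), 1,
                     prob = CONCLUSION_STATE_PROBS)
    conc0 <- conclusion_for_state(state0, intervention)
    n0 <- if (design == "rct") sample(40:800, 1) else sample(100:5000, 1)
    make_version <- function(k, date) {
      source_version(version_number = k, date = date,
                     results = results0, sample_size = n0,
                     conclusion_text = conc0$text, conclusion = conc0$coded)
    }
    results0 <- base_results(design)

    if (!has_preprint) {
      rec <- bib_record(sprintf("art-%04d", i), "journal_article", title,
                        authors, base_date, venue = sample(VENUE_POOL_J, 1),
                        doi = sprintf("10.9999/a%04d", i),
                        registration_id = reg_id)
      studies[[i]] <- study(sid, design, intervention,
                            article = list(record = rec,
                                           version = make_version(1L, base_date)))
      planted_rows[[i]] <- data.frame(
        study_id = sid, multi_source = FALSE, result_changed = FALSE,
        important = FALSE, p_crossed = FALSE, sample_size_changed = FALSE,
        conclusion_changed = FALSE, conclusion_from = NA_character_,
        conclusion_to = NA_character_, stringsAsFactors = FALSE)
      next
    }

    published <- runif(1) < params$p_article_given_preprint
    multiversion <- runif(1) < params$p_multiversion_given_preprint
    n_versions <- if (multiversion)
      sample(2:6, 1, prob = c(0.55, 0.25, 0.10, 0.06, 0.04)) else 1L
    vdates <- base_date + c(0, cumsum(sample(5:40, n_versions - 1, replace = TRUE)))
    versions <- lapply(seq_len(n_versions), function(k) make_version(k, vdates[k]))
    pp_rec <- bib_record(sprintf("pp-%04d", i), "preprint", title, authors,
                         base_date, venue = sample(VENUE_POOL_PP, 1),
                         doi = sprintf("10.1101/p%04d", i),
                         registration_id = reg_id,
                         version_count = n_versions)

    article <- NULL
    usage <- NULL
    if (published) {
      delay <- stats::rlnorm(1, meanlog = log(params$delay_median_days),
                             sdlog = params$delay_sigma)
      art_date <- base_date + max(1L, as.integer(round(delay)))
      art_rec <- perturb_record(pp_rec, params$perturbation_level)
      art_rec <- bib_record(sprintf("art-%04d", i), "journal_article",
                            art_rec$title, art_rec$authors, art_date,
                            venue = sample(VENUE_POOL_J, 1),
                            doi = sprintf("10.9999/a%04d", i),
                            registration_id = reg_id)
      art_version <- versions[[n_versions]]
      art_version$version_number <- 1L
      art_version$date <- art_date
      article <- list(record = art_rec, version = art_version)
      links[[length(links) + 1L]] <- data.frame(
        preprint_id = pp_rec$record_id, article_id = art_rec$record_id,
        study_id = sid, stringsAsFactors = FALSE)
      retrieval <- art_date + sample(30:120, 1)
      usage <- list(
        preprint = usage_metrics(stats::rnbinom(1, mu = 8, size = 1),
                                 round(stats::rexp(1, 1 / 15), 1),
                                 stats::rpois(1, 0.08), retrieval),
        article = usage_metrics(stats::rnbinom(1, mu = 15, size = 1),
                                round(stats::rexp(1, 1 / 25), 1),
                                stats::rpois(1, 0.05), retrieval))
    }

    st <- study(sid, design, intervention,
                preprint = list(record = pp_rec, versions = versions),
                article = article, usage = usage)

    multi_source <- published || n_versions > 1L
    flags <- list(result_changed = FALSE, important = FALSE, p_crossed = FALSE,
                  sample_size_changed = FALSE, conclusion_transition = NULL)
    if (multi_source) {
      flags <- draw_planted_flags(params)
      st <- plant_changes(st, flags)
    }
    studies[[i]] <- st
    tr <- flags$conclusion_transition
    planted_rows[[i]] <- data.frame(
      study_id = sid, multi_source = multi_source,
      result_changed = flags$result_changed, important = flags$important,
      p_crossed = flags$p_crossed,
      sample_size_changed = flags$sample_size_changed,
      conclusion_changed = !is.null(tr),
      conclusion_from = if (is.null(tr)) NA_character_ else tr$from,
      conclusion_to = if (is.null(tr)) NA_character_ else tr$to,
      stringsAsFactors = FALSE)
  }
  true_links <- if (length(links)) do.call(rbind, links) else
    data.frame(preprint_id = character(), article_id = character(),
               study_id = character(), stringsAsFactors = FALSE)
  list(studies = studies,
       ground_truth = list(true_links = true_links,
                           planted = do.call(rbind, planted_rows)))
}

#' Build a linkage validation harness
#'
#' Generates `n_true` preprint records, derives their journal-article records
#' by metadata perturbation at the given level plus a log-normal publication
#' delay, and adds `n_decoys` unrelated article records. The article list is
#' shuffled so input order carries no signal.
#'
#' @param n_true Number of true preprint-article pairs.
#' @param n_decoys Number of decoy articles with no preprint counterpart.
#' @param level Perturbation level applied to the derived article records.
#' @param seed Integer seed.
#' @param p_registration Fraction of true pairs carrying a shared trial
#'   registration ID. Default 0: the harness measures the metadata features
#'   alone.
#' @return `list(preprints =, articles =, true_links =)` with `true_links` a
#'   data frame of (preprint_id, article_id).
#' @export
simulate_linkage_validation <- function(n_true = 740, n_decoys = 300,
                                        level = 0.2, seed = 1,
                                        p_registration = 0) {
  set.seed(seed)
  origin <- as.Date("2020-01-15")
  preprints <- vector("list", n_true)
  articles <- vector("list", n_true + n_decoys)
  for (i in seq_len(n_true)) {
    intervention <- sample(INTERVENTION_POOL, 1)
    reg <- if (runif(1) < p_registration)
      sprintf("NCT%08d", sample.int(1e7, 1)) else NULL
    pp <- bib_record(sprintf("vpp-%04d", i), "preprint",
                     random_title(intervention, "observational"),
                     random_authors(), origin + sample(0:180, 1),
                     venue = sample(VENUE_POOL_PP, 1), registration_id = reg)
    preprints[[i]] <- pp
    art <- perturb_record(pp, level)
    delay <- stats::rlnorm(1, log(76), 0.49)
    articles[[i]] <- bib_record(sprintf("vart-%04d", i), "journal_article",
                                art$title, art$authors,
                                pp$online_date + max(1L, as.integer(round(delay))),
                                venue = sample(VENUE_POOL_J, 1),
                                registration_id = reg)
  }
  for (j in seq_len(n_decoys)) {
    intervention <- sample(INTERVENTION_POOL, 1)
    articles[[n_true + j]] <- bib_record(
      sprintf("vdec-%04d", j), "journal_article",
      random_title(intervention, "rct"), random_authors(),
      origin + sample(0:240, 1), venue = sample(VENUE_POOL_J, 1))
  }
  articles <- articles[sample.int(length(articles))]
  list(preprints = preprints, articles = articles,
       true_links = data.frame(
         preprint_id = sprintf("vpp-%04d", seq_len(n_true)),
         article_id = sprintf("vart-%04d", seq_len(n_true)),
         stringsAsFactors = FALSE))
}

#' Evaluate a matching against known true links
#'
#' @param links Data frame from [match_corpus()].
#' @param true_links Data frame with `preprint_id`, `article_id`.
#' @return List with `n_true`, `true_positives`, `false_positives`,
#'   `false_negatives`, `recall`, `precision` and `pct_linked`
#'   (recall as a percentage).
#' @export
evaluate_links <- function(links, true_links) {
  matched <- links[links$decision == "match", c("preprint_id", "article_id")]
  key <- function(d) paste(d$preprint_id, d$article_id, sep = "\r")
  tp <- sum(key(matched) %in% key(true_links))
  fp <- nrow(matched) - tp
  fn <- nrow(true_links) - tp
  recall <- if (nrow(true_links)) tp / nrow(true_links) else NA_real_
  precision <- if (nrow(matched)) tp / nrow(matched) else NA_real_
  list(n_true = nrow(true_links), true_positives = tp, false_positives = fp,
       false_negatives = fn, recall = recall, precision = precision,
       pct_linked = 100 * recall)
}
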