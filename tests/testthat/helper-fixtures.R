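# A deterministic fixture corpus whose marginal counts equal the published
# corpus: 556 studies; 338 preprint-reported (66 with a journal article, 91
# with >1 preprint version, overlapping in 18); 218 article-only; among the
# 139 multi-source studies 63 have any change (42 results, 29 important, 33
# conclusion; 12 studies have both a result and a conclusion change). The
# 25-study subgroup contains 15 changed studies; 123 of 272 contacted
# authors responded.
build_marginal_fixture <- function() {
  make_one <- function(i) {
    sid <- sprintf("study-%03d", i)
    authors <- list(author(sprintf("Fam%03d", i), "A"))
    base_date <- as.Date("2020-02-01") + (i %% 120)
    results <- list(reported_result("all-cause mortality", "odds_ratio",
                                    estimate = 1.5, p_value = 0.2))
    conc <- conclusion_assessment("positive", "not_reported")
    make_v <- function(k, d) source_version(k, d, results = results,
                                            sample_size = 100L,
                                            conclusion = conc)
    if (i > 338) {
      rec <- bib_record(sprintf("art-%03d", i), "journal_article",
                        sprintf("Investigation %03d of outcomes", i),
                        authors, base_date)
      return(study(sid, "observational",
                   article = list(record = rec,
                                  version = make_v(1L, base_date))))
    }
    published <- i <= 66
    nv <- if (i >= 49 && i <= 139) 2L else 1L
    vdates <- base_date + (seq_len(nv) - 1L) * 21
    pp <- bib_record(sprintf("pp-%03d", i), "preprint",
                     sprintf("Investigation %03d of outcomes", i),
                     authors, base_date, version_count = nv)
    art <- NULL
    if (published) {
      art_date <- base_date + 50 + (i %% 55)
      art <- list(record = bib_record(sprintf("art-%03d", i),
                                      "journal_article",
                                      sprintf("Investigation %03d of outcomes", i),
                                      authors, art_date),
                  version = make_v(1L, art_date))
    }
    st <- study(sid, "observational",
                preprint = list(record = pp,
                                versions = lapply(seq_len(nv), function(k)
                                  make_v(k, vdates[k]))),
                article = art)
    if (i <= 139) {
      flags <- list(
        result_changed = i <= 42,
        important = i <= 29,
        p_crossed = FALSE,
        sample_size_changed = FALSE,
        conclusion_transition =
          if (i <= 12 || (i >= 43 && i <= 63))
            list(from = "positive.not_reported", to = "positive.reported")
          else NULL
      )
      st <- plant_changes(st, flags, seed = 1000L + i)
    }
    st
  }
  list(
    studies = lapply(1:556, make_one),
    subgroup_ids = sprintf("study-%03d", c(1:15, 64:73)),
    author_contact = c(contacted = 272, responded = 123)
  )
}
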