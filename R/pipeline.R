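# End-to-end orchestration: simulate (or read) a corpus, link preprints to
# articles, detect changes, summarize. Every output file carries a
# provenance header (package version, seed, configuration hash) and a rerun
# with the same configuration is bit-identical.

#' Pipeline configuration
#'
#' @param report_dir Directory for all outputs (created if needed).
#' @param corpus_path Optional existing JSON Lines corpus; when `NULL` a
#'   synthetic corpus is generated from `params`.
#' @param params A [generator_params()] (ignored when `corpus_path` given,
#'   except for its seed, which seeds downstream randomness).
#' @param link_cfg A [link_config()].
#' @param criteria A [change_criteria()].
#' @param cutoff Censoring date for the publication-delay survival analysis.
#' @param verbose Log stage progress to standard error.
#' @return A `run_config` list.
#' @export
run_config <- function(report_dir, corpus_path = NULL,
                       params = generator_params(),
                       link_cfg = link_config(),
                       criteria = change_criteria(),
                       cutoff = as.Date("2020-09-02"),
                       verbose = FALSE) {
  structure(list(report_dir = report_dir, corpus_path = corpus_path,
                 params = params, link_cfg = link_cfg, criteria = criteria,
                 cutoff = as_iso_date(cutoff, "cutoff"), verbose = verbose),
            class = "run_config")
}

pipeline_log <- function(config, stage, msg, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

config_hash <- function(config) {
  # Stable digest of the configuration: serialize deterministic fields to
  # canonical JSON and fold the md5 of the text.
  fields <- list(params = unclass(config$params),
                 link_cfg = unclass(config$link_cfg),
                 criteria = unclass(config$criteria),
                 cutoff = format(config$cutoff, "%Y-%m-%d"),
                 corpus_path = config$corpus_path)
  txt <- as.character(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

provenance_header <- function(config) {
  sprintf("# evlink %s seed=%d config=%s",
          as.character(utils::packageVersion("evlink")),
          config$params$seed, config_hash(config))
}

write_csv_prov <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance comment lines
#'
#' @param path CSV written by [run_pipeline()].
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

summary_to_list <- function(s) {
  out <- unclass(s)
  for (nm in c("median_delay_days", "median_versions"))
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  out
}

#' Run the full pipeline
#'
#' Stages: simulate (or read) the corpus; link the preprint records against
#' the article records and score the matching against ground truth when
#' available; detect changes; summarize (corpus summary JSON, change-record
#' CSV, survival-curve CSV, conclusion-transition CSV, run manifest).
#' Deterministic: identical configuration implies bit-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage outputs (`studies`,
#'   `links`, `changes`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$report_dir, recursive = TRUE, showWarnings = FALSE)
  header <- provenance_header(config)
  paths <- list()

  # Stage 1: corpus
  if (is.null(config$corpus_path)) {
    pipeline_log(config, "simulate", "generating %d studies (seed %d)",
                 config$params$n_studies, config$params$seed)
    gen <- generate_corpus(config$params)
    studies <- gen$studies
    ground_truth <- gen$ground_truth
    paths$corpus <- file.path(config$report_dir, "corpus.jsonl")
    write_corpus(studies, paths$corpus)
    paths$ground_truth <- file.path(config$report_dir, "ground_truth.json")
    jsonlite::write_json(
      list(provenance = header, true_links = ground_truth$true_links,
           planted = ground_truth$planted),
      paths$ground_truth, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    pipeline_log(config, "read", "reading corpus from %s", config$corpus_path)
    studies <- read_corpus(config$corpus_path)
    ground_truth <- NULL
  }

  # Stage 2: linkage over the corpus's own records
  preprints <- list(); articles <- list()
  for (s in studies) {
    if (!is.null(s$preprint)) preprints[[length(preprints) + 1L]] <- s$preprint$record
    if (!is.null(s$article)) articles[[length(articles) + 1L]] <- s$article$record
  }
  pipeline_log(config, "link", "%d preprints vs %d articles",
               length(preprints), length(articles))
  links <- match_corpus(preprints, articles, config$link_cfg)
  paths$links <- file.path(config$report_dir, "links.csv")
  write_csv_prov(links, paths$links, header)
  link_eval <- if (!is.null(ground_truth))
    evaluate_links(links, ground_truth$true_links) else NULL

  # Stage 3: change detection
  changes <- detect_changes(studies, config$criteria)
  pipeline_log(config, "detect", "%d change records (%d studies skipped)",
               nrow(changes), attr(changes, "n_skipped"))
  paths$changes <- file.path(config$report_dir, "changes.csv")
  write_csv_prov(changes, paths$changes, header)

  # Stage 4: summaries
  summary <- summarize_corpus(studies, changes)
  delays <- publication_delays(studies, config$cutoff)
  curve <- if (nrow(delays)) km_unpublished(delays) else NULL
  if (!is.null(curve)) {
    paths$survival <- file.path(config$report_dir, "survival.csv")
    write_csv_prov(data.frame(time = curve$time, surv = curve$surv,
                              n_risk = curve$n_risk, n_event = curve$n_event,
                              n_censor = curve$n_censor),
                   paths$survival, header)
  }
  ends <- conclusion_endpoints(studies)
  if (length(ends$first)) {
    tm <- transition_counts(ends$first, ends$last)
    paths$transitions <- file.path(config$report_dir, "transitions.csv")
    tm_df <- as.data.frame(as.table(unclass(tm)), stringsAsFactors = FALSE)
    names(tm_df) <- c("from", "to", "count")
    write_csv_prov(tm_df, paths$transitions, header)
  }
  paths$summary <- file.path(config$report_dir, "summary.json")
  jsonlite::write_json(
    list(provenance = header, summary = summary_to_list(summary),
         linkage = link_eval),
    paths$summary, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  paths$manifest <- file.path(config$report_dir, "manifest.json")
  jsonlite::write_json(
    list(provenance = header,
         seed = config$params$seed,
         outputs = lapply(paths[names(paths) != "manifest"], basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  pipeline_log(config, "summarize", "report written to %s", config$report_dir)
  invisible(list(studies = studies, links = links, changes = changes,
                 summary = summary, link_eval = link_eval, paths = paths))
}
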