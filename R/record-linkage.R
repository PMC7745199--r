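# Preprint-to-journal-article record linkage. Candidate pairs sharing an
# author key or a trial-registration ID are scored on ORCID overlap, author
# overlap, byline order, title words and publication timeline; a greedy
# one-to-one assignment above a threshold yields the matching. Registration
# ID equality short-circuits to a match.

# Function words plus tokens shared corpus-wide by pandemic-era titles; these
# carry no discriminating signal between candidate pairs.
TITLE_STOP_TOKENS <- c(
  "a", "an", "the", "of", "in", "on", "for", "and", "or", "to", "with",
  "from", "by", "at", "as", "is", "are", "was", "were", "be", "among",
  "between", "during", "after", "study",
  "covid", "19", "sars", "cov", "2"
)

#' Default linkage feature weights
#'
#' Relative weights of the five linkage features (registration-ID equality is
#' handled separately and short-circuits to a match). They sum to 1, so a
#' perfect candidate scores 1.
#'
#' @return Named numeric vector of weights.
#' @export
default_link_weights <- function() {
  c(orcid_overlap = 0.25, first_author_match = 0.15, author_overlap = 0.25,
    byline_order_similarity = 0.10, title_similarity = 0.25)
}

#' Linkage configuration
#'
#' @param weights Named non-negative weights over the five scored features;
#'   must sum to 1.
#' @param threshold Minimum score for a non-registration match. The default
#'   0.65 is calibrated on the synthetic validation harness: under realistic
#'   metadata noise the lowest score a true pair attains is 2/3 (no ORCID
#'   information and one dropped middle author on a three-author byline),
#'   while unrelated records stay below about 0.4, so 0.65 sits in the wide
#'   margin between the two populations.
#' @param grace_days Days an article may precede its preprint before the
#'   timeline is considered implausible (journal records occasionally carry
#'   an earlier online date than the preprint).
#' @param timeline_penalty Multiplier applied to the score when the timeline
#'   check fails; a soft penalty rather than a hard exclusion.
#' @return A `link_config` list.
#' @export
link_config <- function(weights = default_link_weights(), threshold = 0.65,
                        grace_days = 30, timeline_penalty = 0.5) {
  required <- names(default_link_weights())
  if (!all(required %in% names(weights)))
    stop_validation("weights must name: %s", paste(required, collapse = ", "))
  weights <- weights[required]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_validation("weights must be non-negative and sum to 1")
  if (!is_probability(threshold))
    stop_validation("threshold must lie in [0, 1]")
  if (!is_scalar_number(grace_days) || grace_days < 0)
    stop_validation("grace_days must be >= 0")
  if (!is_probability(timeline_penalty))
    stop_validation("timeline_penalty must lie in [0, 1]")
  structure(list(weights = weights, threshold = threshold,
                 grace_days = grace_days, timeline_penalty = timeline_penalty),
            class = "link_config")
}

#' Normalize an author to a comparison key
#'
#' Lowercases, strips diacritics by Unicode transliteration, and reduces the
#' given name to its first initial, so that "Theodora" and "T." collide:
#' `family|initial`, or just `family` when no given name is available.
#'
#' @param a An [author()] object.
#' @return A single string key.
#' @export
#' @examples
#' normalize_author(author("Müller", "Émile")) # "muller|e"
normalize_author <- function(a) {
  fam <- tolower(stringi::stri_trans_general(trimws(a$family), "Latin-ASCII"))
  giv <- tolower(stringi::stri_trans_general(trimws(a$given %||% ""), "Latin-ASCII"))
  giv <- gsub("[^a-z]", "", substr(giv, 1, 1))
  if (nzchar(giv)) paste0(fam, "|", giv) else fam
}

author_keys <- function(record) {
  vapply(record$authors, normalize_author, character(1))
}

title_tokens <- function(x, drop_stop = TRUE) {
  x <- tolower(stringi::stri_trans_general(x %||% "", "Latin-ASCII"))
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks <- toks[nzchar(toks)]
  if (drop_stop) toks <- toks[!toks %in% TITLE_STOP_TOKENS]
  toks
}

#' Title similarity as token-set Jaccard
#'
#' Jaccard index of the lowercased, punctuation-stripped token sets of two
#' titles after stop-token removal. Two titles that both normalize to the
#' empty set count as identical (1).
#'
#' @param a,b Title strings.
#' @return Fraction in `[0, 1]`.
#' @export
title_similarity <- function(a, b) {
  ta <- unique(title_tokens(a))
  tb <- unique(title_tokens(b))
  if (length(ta) == 0 && length(tb) == 0) return(1)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

# Longest-common-subsequence length of two character vectors.
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Compute linkage features for a candidate preprint-article pair
#'
#' @param p Preprint [bib_record()].
#' @param a Journal-article [bib_record()].
#' @param grace_days Timeline grace window in days (see [link_config()]).
#' @return A `link_features` list: `orcid_overlap` (shared ORCIDs over the
#'   ORCIDs on the shorter byline; 0 when either byline has none),
#'   `first_author_match`, `author_overlap` (Jaccard of normalized author
#'   keys), `byline_order_similarity` (LCS of key sequences over the shorter
#'   byline length), `title_similarity`, `registration_match` (equal
#'   non-null registry IDs) and `timeline_ok` (article not earlier than the
#'   preprint minus the grace window).
#' @export
link_features <- function(p, a, grace_days = 30) {
  if (p$source_type != "preprint" || a$source_type != "journal_article")
    stop_contract("link_features expects (preprint, journal_article), got (%s, %s)",
                  p$source_type, a$source_type)
  kp <- author_keys(p); ka <- author_keys(a)
  op <- unlist(lapply(p$authors, `[[`, "orcid"))
  oa <- unlist(lapply(a$authors, `[[`, "orcid"))
  shorter_orcids <- if (length(kp) <= length(ka)) op else oa
  orcid_overlap <- if (length(op) == 0 || length(oa) == 0) 0
                   else length(intersect(op, oa)) / length(unique(shorter_orcids))
  author_overlap <- length(intersect(unique(kp), unique(ka))) /
                    length(union(kp, ka))
  byline <- lcs_length(kp, ka) / min(length(kp), length(ka))
  features <- list(
    orcid_overlap = orcid_overlap,
    first_author_match = kp[1] == ka[1],
    author_overlap = author_overlap,
    byline_order_similarity = byline,
    title_similarity = title_similarity(p$title, a$title),
    registration_match = !is.null(p$registration_id) &&
      !is.null(a$registration_id) &&
      p$registration_id == a$registration_id,
    timeline_ok = as.numeric(a$online_date - p$online_date) >= -grace_days
  )
  structure(features, class = "link_features")
}

#' Score a feature vector
#'
#' Weighted sum of the five scored features (booleans as 0/1); a failed
#' timeline check multiplies the score by the timeline penalty.
#'
#' @param f A `link_features` object from [link_features()].
#' @param weights Named weights (non-negative, sum 1).
#' @param timeline_penalty Multiplier when `timeline_ok` is `FALSE`.
#' @return Score in `[0, 1]`.
#' @export
link_score <- function(f, weights = default_link_weights(),
                       timeline_penalty = 0.5) {
  required <- names(default_link_weights())
  if (!all(required %in% names(weights)))
    stop_validation("weights must name: %s", paste(required, collapse = ", "))
  weights <- weights[required]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_validation("weights must be non-negative and sum to 1")
  vals <- c(f$orcid_overlap, as.numeric(f$first_author_match),
            f$author_overlap, f$byline_order_similarity, f$title_similarity)
  s <- sum(weights * vals)
  if (!f$timeline_ok) s <- s * timeline_penalty
  s
}

#' Match a preprint corpus against an article corpus
#'
#' Candidate pairs are those sharing at least one normalized author key or a
#' trial-registration ID (quadratic blow-up control mirroring first-author
#' anchoring in manual searches). Registration-ID matches are accepted
#' unconditionally; remaining candidates are scored and assigned greedily in
#' descending score (ties broken by smaller absolute date gap, then
#' lexicographic IDs) subject to the threshold, so each preprint and each
#' article appears in at most one match.
#'
#' @param preprints,articles Lists of [bib_record()] with unique IDs.
#' @param config A [link_config()].
#' @return A data frame with one row per scored candidate pair: `preprint_id`,
#'   `article_id`, the seven features, `score` and `decision`
#'   (`"match"`/`"no_match"`). Use `subset(., decision == "match")` for the
#'   matching itself.
#' @export
match_corpus <- function(preprints, articles, config = link_config()) {
  empty <- data.frame(
    preprint_id = character(), article_id = character(),
    orcid_overlap = numeric(), first_author_match = logical(),
    author_overlap = numeric(), byline_order_similarity = numeric(),
    title_similarity = numeric(), registration_match = logical(),
    timeline_ok = logical(), score = numeric(), decision = character(),
    stringsAsFactors = FALSE
  )
  if (length(preprints) == 0 || length(articles) == 0) return(empty)
  pids <- vapply(preprints, `[[`, character(1), "record_id")
  aids <- vapply(articles, `[[`, character(1), "record_id")
  if (anyDuplicated(pids) || anyDuplicated(aids))
    stop_validation("record ids must be unique within each input")

  # Blocking: index articles by author key and registration ID.
  akeys <- lapply(articles, author_keys)
  key_index <- new.env(parent = emptyenv())
  for (j in seq_along(articles)) {
    for (k in unique(akeys[[j]]))
      assign(k, c(key_index[[k]], j), envir = key_index)
  }
  reg_index <- new.env(parent = emptyenv())
  for (j in seq_along(articles)) {
    rid <- articles[[j]]$registration_id
    if (!is.null(rid)) assign(rid, c(reg_index[[rid]], j), envir = reg_index)
  }

  rows <- list()
  for (i in seq_along(preprints)) {
    p <- preprints[[i]]
    cand <- integer(0)
    for (k in unique(author_keys(p))) cand <- c(cand, key_index[[k]])
    if (!is.null(p$registration_id)) cand <- c(cand, reg_index[[p$registration_id]])
    for (j in unique(cand)) {
      f <- link_features(p, articles[[j]], grace_days = config$grace_days)
      s <- link_score(f, config$weights, config$timeline_penalty)
      rows[[length(rows) + 1L]] <- data.frame(
        preprint_id = p$record_id, article_id = articles[[j]]$record_id,
        orcid_overlap = f$orcid_overlap,
        first_author_match = f$first_author_match,
        author_overlap = f$author_overlap,
        byline_order_similarity = f$byline_order_similarity,
        title_similarity = f$title_similarity,
        registration_match = f$registration_match,
        timeline_ok = f$timeline_ok,
        score = s,
        date_gap = abs(as.numeric(articles[[j]]$online_date - p$online_date)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  cand_df <- do.call(rbind, rows)

  # Greedy one-to-one assignment: registration matches first (unconditional),
  # then by descending score / smaller date gap / lexicographic ids.
  ord <- order(-cand_df$registration_match, -cand_df$score, cand_df$date_gap,
               cand_df$preprint_id, cand_df$article_id)
  taken_p <- character(0); taken_a <- character(0)
  decision <- rep("no_match", nrow(cand_df))
  for (idx in ord) {
    row <- cand_df[idx, ]
    if (row$preprint_id %in% taken_p || row$article_id %in% taken_a) next
    if (row$registration_match || row$score >= config$threshold) {
      decision[idx] <- "match"
      taken_p <- c(taken_p, row$preprint_id)
      taken_a <- c(taken_a, row$article_id)
    }
  }
  cand_df$decision <- decision
  cand_df$date_gap <- NULL
  rownames(cand_df) <- NULL
  cand_df
}
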