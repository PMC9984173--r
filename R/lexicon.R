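#' Build a seed set
#'
#' The three initial seed key phrases describing acute food insecurity are
#' "food insecurity", "hunger crisis" and "famine"; expanded seeds are added
#' by [expand_seeds()].
#'
#' @param phrases character vector of seed n-grams (n <= 3)
#' @param origin "initial" or "expanded", recycled
#' @return tibble `phrase`, `origin` of class `cc_seeds`
#' @export
seed_set <- function(phrases = c("food insecurity", "hunger crisis", "famine"),
                     origin = "initial") {
  stopifnot(!anyDuplicated(phrases))
  n_tok <- lengths(tokenize(phrases))
  stopifnot(all(n_tok >= 1 & n_tok <= 3))
  out <- tibble::tibble(phrase = phrases,
                        origin = rep(origin, length.out = length(phrases)))
  class(out) <- c("cc_seeds", class(out))
  out
}

#' Expand seed key phrases by word mover's distance
#'
#' Ranks candidate n-grams by their smallest word mover's distance to any
#' existing seed and keeps the `keep_k` closest, with the constraint that a
#' bigram or trigram is only eligible if it contains the word "food" or the
#' word "hunger". Ties are broken lexicographically.
#'
#' @param initial a [seed_set()]
#' @param candidates character vector of candidate n-grams
#' @param emb embedding matrix
#' @param keep_k number of candidates to keep
#' @return the enlarged seed set (initial seeds first, then the selected
#'   candidates with `origin = "expanded"`), with a `distance` column for the
#'   selected candidates
#' @export
expand_seeds <- function(initial, candidates, emb, keep_k = 100) {
  stopifnot(inherits(initial, "cc_seeds"), keep_k >= 1)
  candidates <- setdiff(unique(candidates), initial$phrase)
  if (length(candidates) == 0) return(initial)
  toks <- tokenize(candidates)
  eligible <- lengths(toks) == 1 |
    vapply(toks, function(tk) any(c("food", "hunger") %in% tk), logical(1))
  candidates <- candidates[eligible]
  toks <- toks[eligible]
  if (length(candidates) == 0) return(initial)
  seed_toks <- tokenize(initial$phrase)
  dmin <- vapply(toks, function(tk) {
    min(vapply(seed_toks, function(st) wmd(tk, st, emb, on_empty = "inf"),
               numeric(1)))
  }, numeric(1))
  ord <- order(dmin, candidates)
  keep <- ord[seq_len(min(keep_k, sum(is.finite(dmin))))]
  keep <- keep[is.finite(dmin[keep])]
  expanded <- tibble::tibble(phrase = candidates[keep], origin = "expanded",
                             distance = dmin[keep])
  out <- dplyr::bind_rows(
    dplyr::mutate(initial, distance = NA_real_), expanded)
  class(out) <- c("cc_seeds", setdiff(class(out), "cc_seeds"))
  out
}

# case-insensitive contiguous token-sequence match of `phrase` inside `tokens`
contains_phrase <- function(tokens, phrase_tokens) {
  np <- length(phrase_tokens); nt <- length(tokens)
  if (np == 0 || nt < np) return(FALSE)
  for (i in seq_len(nt - np + 1)) {
    if (all(tokens[i:(i + np - 1)] == phrase_tokens)) return(TRUE)
  }
  FALSE
}

#' Select text features from semantic frames (the four-step filter)
#'
#' Applies, in order: (1) keep frames having at least one "cause" and one
#' "effect" constituent role; (2) keep frames in which some effect
#' constituent contains a seed phrase (case-insensitive contiguous token
#' match); (3) keep frames whose trigger is one of the causal links; (4) emit
#' every unigram, bigram and trigram occurring in a cause or effect
#' constituent of the surviving frames. The output is deduplicated and is
#' invariant to frame order.
#'
#' @param frames tibble with columns `trigger` and `constituents` (list of
#'   data frames with `text`, `role`), as produced by [gen_articles()] or
#'   [read_frames_jsonl()]
#' @param seeds a [seed_set()] (or character vector of seed phrases)
#' @param causal_links character vector of causal trigger names
#' @param origin origin tag for the emitted features ("frame_news" by
#'   default; use "frame_scholarly" for a scholarly frame stream)
#' @return tibble `ngram`, `origin`, `status` ("candidate") of class
#'   `cc_features`
#' @export
select_frame_features <- function(frames, seeds,
                                  causal_links = default_causal_links(),
                                  origin = "frame_news") {
  stopifnot(length(causal_links) > 0)
  if (inherits(seeds, "cc_seeds")) seeds <- seeds$phrase
  seed_toks <- tokenize(seeds)
  if (nrow(frames) == 0) {
    return(text_features(character(), origin))
  }
  k <- nrow(frames)
  n_con <- vapply(frames$constituents, function(cons) length(cons$role),
                  integer(1))
  idx <- rep(seq_len(k), n_con)
  role <- tolower(unlist(lapply(frames$constituents, `[[`, "role")))
  text <- unlist(lapply(frames$constituents, `[[`, "text"))
  norm <- vapply(tokenize(text), paste, character(1), collapse = " ")
  has_cause <- tabulate(idx[role == "cause"], k) > 0
  has_effect <- tabulate(idx[role == "effect"], k) > 0        # step 1
  eff <- role == "effect"
  pats <- vapply(seed_toks, function(st)
    paste0("(^| )", paste(st, collapse = " "), "( |$)"), character(1))
  seed_hit <- Reduce(`|`, lapply(pats, grepl, x = norm[eff]))
  seeded <- tabulate(idx[eff][seed_hit], k) > 0               # step 2
  causal <- frames$trigger %in% causal_links                  # step 3
  ok <- has_cause & has_effect & seeded & causal
  ce <- unique(norm[idx %in% which(ok) & role %in% c("cause", "effect")])
  kept <- unlist(lapply(tokenize(ce), ngrams, n_max = 3))     # step 4
  text_features(sort(unique(kept)), origin)
}

#' Construct a text-feature table
#'
#' @param ngram character vector of 1..3-token n-grams
#' @param origin "frame_news", "frame_scholarly" or "expansion"
#' @param status feature status, "candidate" by default
#' @return tibble of class `cc_features`
#' @export
text_features <- function(ngram, origin = "frame_news",
                          status = "candidate") {
  n_tok <- lengths(tokenize(ngram))
  stopifnot(all(n_tok >= 1 & n_tok <= 3))
  out <- tibble::tibble(ngram = ngram,
                        origin = rep(origin, length.out = length(ngram)),
                        status = rep(status, length.out = length(ngram)))
  class(out) <- c("cc_features", class(out))
  out
}

#' Expand text features to semantically close corpus n-grams
#'
#' Candidate features are all corpus unigrams plus the bigrams and trigrams
#' occurring strictly more than `min_count` times. A candidate is added (with
#' origin "expansion") iff its word mover's distance to some original
#' feature is strictly smaller than `dist_max`. Original features are never
#' removed.
#'
#' @param features a `cc_features` table (the originals)
#' @param corpus_ngrams tibble with columns `ngram`, `count` describing the
#'   corpus n-gram inventory
#' @param emb embedding matrix
#' @param dist_max strict distance cutoff (the reference analysis uses 6 on
#'   300-dimensional news embeddings; synthetic embeddings need a value
#'   matched to their scale)
#' @param min_count strict occurrence cutoff for bigrams/trigrams
#' @return the features table with expansion rows appended (deduplicated)
#' @export
expand_keywords <- function(features, corpus_ngrams, emb, dist_max = 6,
                            min_count = 1000) {
  stopifnot(dist_max > 0)
  corpus_ngrams <- tibble::as_tibble(corpus_ngrams)
  toks <- tokenize(corpus_ngrams$ngram)
  is_uni <- lengths(toks) == 1
  cand <- corpus_ngrams$ngram[is_uni | corpus_ngrams$count > min_count]
  cand <- setdiff(unique(cand), features$ngram)
  if (length(cand) == 0) return(features)
  feat_toks <- tokenize(features$ngram)
  dmin <- vapply(tokenize(cand), function(tk) {
    min(vapply(feat_toks, function(ft) wmd(tk, ft, emb, on_empty = "inf"),
               numeric(1)))
  }, numeric(1))
  added <- cand[dmin < dist_max]
  dplyr::bind_rows(features, text_features(added, origin = "expansion"))
}

#' Corpus n-gram inventory of an article stream
#'
#' Counts, over all articles, in how many articles each mention n-gram
#' occurs (the synthetic mention table already stores bags of n-grams).
#'
#' @param articles a `cc_articles` object
#' @return tibble `ngram`, `count`
#' @export
corpus_ngram_counts <- function(articles) {
  dplyr::count(articles$mentions, .data$ngram, name = "count")
}
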