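#' Word-level vocabulary of a planted lexicon
#'
#' Splits every lexicon n-gram into tokens and assigns each word the cluster
#' label of the first feature it occurs in (a word shared across clusters gets
#' a single embedding, as in a real embedding table).
#'
#' @param lexicon tibble with `ngram` and `cluster` columns
#' @param extra_words optional character vector of additional words, assigned
#'   to cluster "other"
#' @return tibble `word`, `cluster`
#' @export
lexicon_vocab <- function(lexicon, extra_words = character()) {
  words <- tibble::tibble(
    word = unlist(strsplit(lexicon$ngram, " ", fixed = TRUE)),
    cluster = rep(lexicon$cluster,
                  lengths(strsplit(lexicon$ngram, " ", fixed = TRUE)))
  )
  if (length(extra_words)) {
    words <- dplyr::bind_rows(
      words, tibble::tibble(word = extra_words, cluster = "other"))
  }
  dplyr::distinct(words, .data$word, .keep_all = TRUE)
}

#' Generate a cluster-structured embedding table
#'
#' Draws one centroid per cluster (isotropic normal, sd `between_sd`) and each
#' word around its cluster centroid (sd `within_sd`), so that words sharing a
#' cluster are nearer to each other than to words of other clusters whenever
#' `within_sd < between_sd`.
#'
#' @param vocab tibble with columns `word` and `cluster`
#' @param dim embedding dimension
#' @param within_sd,between_sd within-cluster and centroid standard deviations
#' @param seed integer seed
#' @return `cc_embeddings`: numeric matrix with one row per word
#' @export
gen_embeddings <- function(vocab, dim = 25, within_sd = 0.1, between_sd = 2,
                           seed = 1L) {
  vocab <- tibble::as_tibble(vocab)
  stopifnot(all(c("word", "cluster") %in% names(vocab)))
  if (anyNA(vocab$cluster) | any(vocab$cluster == "")) {
    stop("configuration error: every word needs a cluster label")
  }
  if (!(within_sd < between_sd)) {
    stop("configuration error: within_sd must be smaller than between_sd")
  }
  vocab <- dplyr::distinct(vocab, .data$word, .keep_all = TRUE)
  set.seed(seed)
  clusters <- unique(vocab$cluster)
  centroids <- matrix(stats::rnorm(length(clusters) * dim, 0, between_sd),
                      nrow = length(clusters),
                      dimnames = list(clusters, NULL))
  emb <- centroids[vocab$cluster, , drop = FALSE] +
    matrix(stats::rnorm(nrow(vocab) * dim, 0, within_sd), nrow = nrow(vocab))
  rownames(emb) <- vocab$word
  structure(emb, class = c("cc_embeddings", "matrix", "array"))
}

#' Look up embedding vectors
#'
#' @param emb a `cc_embeddings` matrix (or any matrix with word rownames)
#' @param words character vector
#' @param error_on_missing if TRUE (default) an absent word raises an error;
#'   otherwise missing words are silently dropped
#' @return matrix of vectors for the (found) words
#' @export
emb_lookup <- function(emb, words, error_on_missing = TRUE) {
  idx <- match(words, rownames(emb))
  if (anyNA(idx)) {
    if (error_on_missing) {
      stop("words absent from embedding table: ",
           paste(words[is.na(idx)], collapse = ", "))
    }
    idx <- idx[!is.na(idx)]
  }
  emb[idx, , drop = FALSE]
}

#' Default causal-link trigger list
#'
#' Frame names signalling an explicit cause-effect link, in the spirit of the
#' causal frames of the FrameNet lexical database; used as the step-3 filter
#' of [select_frame_features()] and as the triggers emitted by the synthetic
#' article generator.
#'
#' @return character vector of trigger names
#' @export
default_causal_links <- function() {
  path <- system.file("extdata", "causal_links.txt", package = "crisiscast")
  if (nzchar(path)) return(readLines(path))
  c("Causation", "Cause_to_start", "Cause_to_end", "Cause_change",
    "Reason", "Response", "Trigger", "Means", "Consequence")
}

frame_cause_templates <- function() {
  c("%s have ravaged crops in the area",
    "%s have devastated local harvests",
    "intensifying %s across the region")
}

frame_effect_templates <- function() {
  c("%s may return to parts of the country",
    "%s is looming in several districts",
    "a worsening %s threatens thousands")
}

#' Generate the synthetic article stream and semantic frames
#'
#' Article counts per district-month are Poisson with a per-district
#' log-normal coverage-bias multiplier (drawn independently of risk). Each
#' article mentions its district; the probability that it mentions a planted
#' cause feature of component k rises (in log-odds) with the component's
#' current latent risk, so mentions lead the phase impact by `lead_tau`
#' months. Noise features and seed phrases are mentioned at constant base
#' rates. A configured fraction of cause-feature mentions also emits a
#' semantic frame whose "cause" constituent contains the feature, whose
#' "effect" constituent contains a seed phrase, and whose trigger is a causal
#' link; decoy frames (no seed in the effect, or a non-causal trigger) are
#' emitted at a small rate to exercise the frame filters.
#'
#' @param world a [gen_world()] object
#' @param risk a [gen_latent_risk()] object
#' @param config a [scenario_config()]; defaults to the world's
#' @param seed integer seed
#' @return `cc_articles` object: list with
#'   * `articles`: tibble `article_id`, `ym`, `source`, `district_id`
#'     (one row per article-district mention),
#'   * `mentions`: tibble `article_id`, `ngram`,
#'   * `frames`: tibble `article_id`, `sentence_id`, `trigger`,
#'     `constituents` (list column of tibbles with `text`, `role`).
#' @export
gen_articles <- function(world, risk, config = world$config,
                         seed = config$seed + 3L) {
  stopifnot(inherits(world, "cc_world"), inherits(risk, "cc_risk"))
  lex <- config$lexicon
  if (nrow(lex) == 0) stop("configuration error: planted lexicon is empty")
  set.seed(seed)
  geo <- world$geo
  D <- nrow(geo); Tn <- length(world$months)

  bias <- exp(stats::rnorm(D, 0, config$coverage_sdlog) -
                config$coverage_sdlog^2 / 2)  # mean-one multiplier
  grid <- tidyr::expand_grid(d = seq_len(D), t = seq_len(Tn))
  n_art <- stats::rpois(nrow(grid), config$article_rate * bias[grid$d])
  art <- tibble::tibble(
    d = rep(grid$d, n_art),
    ym = rep(world$months[grid$t], n_art)
  )
  n <- nrow(art)
  art$article_id <- sprintf("A%08d", seq_len(n))
  srcs <- c("All Africa Global Media", "Reuters", "BBC", "AFP", "IRIN",
            "Local Press")
  art$source <- sample(srcs, n, replace = TRUE,
                       prob = c(0.184, 0.20, 0.15, 0.14, 0.12, 0.206))
  art$district_id <- geo$district_id[art$d]

  # mentions: planted cause features follow the component risk, others constant
  cause_lex <- lex[lex$component %in% risk$components, ]
  flat_lex <- lex[!lex$component %in% risk$components, ]
  base_logit <- stats::qlogis(config$base_mention_prob)
  mention_list <- vector("list", nrow(lex))
  i <- 1L
  for (r in seq_len(nrow(cause_lex))) {
    z <- risk_z(risk, cause_lex$component[r], art$district_id, art$ym)
    p <- stats::plogis(base_logit + config$mention_slope * z)
    hit <- stats::runif(n) < p
    mention_list[[i]] <- tibble::tibble(article_id = art$article_id[hit],
                                        ngram = cause_lex$ngram[r])
    i <- i + 1L
  }
  for (r in seq_len(nrow(flat_lex))) {
    p0 <- if (flat_lex$component[r] == "seed") 0.05 else
      config$noise_mention_prob
    hit <- stats::runif(n) < p0
    mention_list[[i]] <- tibble::tibble(article_id = art$article_id[hit],
                                        ngram = flat_lex$ngram[r])
    i <- i + 1L
  }
  mentions <- dplyr::arrange(dplyr::bind_rows(mention_list),
                             .data$article_id, .data$ngram)

  frames <- gen_frames(art, mentions, cause_lex, lex, config)

  structure(list(
    articles = dplyr::select(art, "article_id", "ym", "source", "district_id"),
    mentions = mentions, frames = frames, coverage_bias = bias
  ), class = "cc_articles")
}

# emit causal frames for a fraction of cause-feature mentions, plus decoys
gen_frames <- function(art, mentions, cause_lex, lex, config) {
  seeds <- lex$ngram[lex$component == "seed"]
  links <- default_causal_links()
  cause_mentions <- mentions[mentions$ngram %in% cause_lex$ngram, ]
  emit <- stats::runif(nrow(cause_mentions)) < config$frame_emission_prob
  fm <- cause_mentions[emit, ]
  k <- nrow(fm)
  frames <- tibble::tibble(
    article_id = fm$article_id,
    trigger = sample(links, k, replace = TRUE),
    cause_text = sprintf(sample(frame_cause_templates(), k, replace = TRUE),
                         fm$ngram),
    effect_text = sprintf(sample(frame_effect_templates(), k, replace = TRUE),
                          sample(seeds, k, replace = TRUE))
  )
  # decoys: (a) effect without any seed phrase; (b) seedful effect but a
  # non-causal trigger -- both must be dropped by the frame filter
  n_dec <- stats::rbinom(1, nrow(art), config$decoy_frame_prob)
  if (n_dec > 0) {
    dec_id <- sample(art$article_id, n_dec)
    half <- seq_len(n_dec) <= n_dec / 2
    decoys <- tibble::tibble(
      article_id = dec_id,
      trigger = ifelse(half, sample(links, n_dec, replace = TRUE),
                       "Temporal_collocation"),
      cause_text = sprintf("a surge in %s this season",
                           sample(c("tourism", "festivals", "exports"),
                                  n_dec, replace = TRUE)),
      effect_text = ifelse(
        half, "bumper harvests are expected this year",
        sprintf(sample(frame_effect_templates(), n_dec, replace = TRUE),
                sample(seeds, n_dec, replace = TRUE)))
    )
    frames <- dplyr::bind_rows(frames, decoys)
  }
  frames <- dplyr::arrange(frames, .data$article_id)
  frames$sentence_id <- stats::ave(seq_len(nrow(frames)), frames$article_id,
                                   FUN = seq_along)
  # constituents as light (text, role) lists; tibble-compatible accessors
  frames$constituents <- mapply(
    function(ca, ef) list(text = c(ca, ef), role = c("cause", "effect")),
    frames$cause_text, frames$effect_text,
    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  dplyr::select(frames, "article_id", "sentence_id", "trigger", "constituents")
}

#' Generate a full synthetic scenario
#'
#' Convenience wrapper running the whole generator: world, latent risk, IPC
#' panel, traditional factors, embeddings, articles and frames, all from one
#' configuration (and hence one seed).
#'
#' @param config a [scenario_config()]
#' @return list with elements `world`, `risk`, `ipc`, `trad`, `embeddings`,
#'   `articles`, `config`
#' @export
gen_scenario <- function(config = scenario_config()) {
  world <- gen_world(config)
  risk <- gen_latent_risk(world)
  ipc <- gen_ipc_panel(world, risk)
  trad <- gen_traditional_factors(world, risk)
  vocab <- lexicon_vocab(config$lexicon,
                         extra_words = c("have", "ravaged", "crops",
                                         "may", "return"))
  emb <- gen_embeddings(vocab, dim = config$embedding_dim,
                        within_sd = config$embedding_within_sd,
                        between_sd = config$embedding_between_sd,
                        seed = config$seed + 4L)
  articles <- gen_articles(world, risk, config)
  list(world = world, risk = risk, ipc = ipc, trad = trad,
       embeddings = emb, articles = articles, config = config)
}
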