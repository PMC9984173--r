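#' Read and write the package's interchange formats
#'
#' Plain-text formats shared with external tools: JSONL article and frame
#' streams, a word2vec-style text embedding table, and CSV panels for IPC
#' phases, traditional factors and news factors. Year-months travel as
#' "YYYY-MM" strings and are converted to the internal integer index (see
#' [ym()]) on read.
#'
#' @name crisiscast-io
NULL

#' @describeIn crisiscast-io Write an article stream (one JSON object per
#'   line: `id`, `ym`, `source`, `district_ids`, `province_ids`,
#'   `country_ids`, `ngrams`).
#' @param articles a `cc_articles` object
#' @param world a [gen_world()] object (for the district-to-province map)
#' @param path output file
#' @export
write_articles_jsonl <- function(articles, world, path) {
  art <- dplyr::left_join(articles$articles,
                          dplyr::select(world$geo, "district_id",
                                        "province_id", "country_id"),
                          by = "district_id")
  men <- split(articles$mentions$ngram, articles$mentions$article_id)
  grp <- dplyr::group_by(art, .data$article_id, .data$ym, .data$source)
  recs <- dplyr::summarise(grp,
                           district_ids = list(unique(.data$district_id)),
                           province_ids = list(unique(.data$province_id)),
                           country_ids = list(unique(.data$country_id)),
                           .groups = "drop")
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(recs))) {
    rec <- list(id = recs$article_id[i], ym = ym_format(recs$ym[i]),
                source = recs$source[i],
                district_ids = recs$district_ids[[i]],
                province_ids = recs$province_ids[[i]],
                country_ids = recs$country_ids[[i]],
                ngrams = men[[recs$article_id[i]]] %||% character())
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @describeIn crisiscast-io Read an article stream back into a
#'   `cc_articles` object (one row per article-district pair; the n-gram bag
#'   becomes the mention table).
#' @export
read_articles_jsonl <- function(path) {
  recs <- jsonlite::stream_in(file(path), verbose = FALSE,
                              simplifyDataFrame = TRUE)
  n_d <- vapply(recs$district_ids, length, integer(1))
  articles <- tibble::tibble(
    article_id = rep(recs$id, n_d),
    ym = rep(ym_parse(recs$ym), n_d),
    source = rep(recs$source, n_d),
    district_id = unlist(recs$district_ids)
  )
  n_g <- vapply(recs$ngrams, length, integer(1))
  mentions <- tibble::tibble(article_id = rep(recs$id, n_g),
                             ngram = unlist(recs$ngrams))
  structure(list(articles = articles, mentions = mentions,
                 frames = tibble::tibble()),
            class = "cc_articles")
}

#' @describeIn crisiscast-io Write semantic frames (one JSON object per
#'   line: `article_id`, `sentence_id`, `constituents` as `{text, role}`
#'   pairs, `trigger`).
#' @param frames a frames tibble (e.g. `articles$frames`)
#' @export
write_frames_jsonl <- function(frames, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(frames))) {
    rec <- list(article_id = frames$article_id[i],
                sentence_id = frames$sentence_id[i],
                constituents = as.data.frame(frames$constituents[[i]],
                                             stringsAsFactors = FALSE),
                trigger = frames$trigger[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows"),
               con)
  }
  invisible(path)
}

#' @describeIn crisiscast-io Read semantic frames.
#' @export
read_frames_jsonl <- function(path) {
  recs <- jsonlite::stream_in(file(path), verbose = FALSE,
                              simplifyDataFrame = TRUE)
  tibble::tibble(
    article_id = recs$article_id,
    sentence_id = recs$sentence_id,
    trigger = recs$trigger,
    constituents = lapply(recs$constituents, tibble::as_tibble)
  )
}

#' @describeIn crisiscast-io Write an embedding table in word2vec text
#'   format (header "V D", then one word and D floats per line).
#' @param emb embedding matrix with word rownames
#' @export
write_embeddings_txt <- function(emb, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  for (i in seq_len(nrow(emb))) {
    writeLines(paste(rownames(emb)[i],
                     paste(formatC(emb[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @describeIn crisiscast-io Read a word2vec text embedding table.
#' @export
read_embeddings_txt <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ")
  words <- vapply(parts, `[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  stopifnot(length(words) == hdr[1])
  rownames(vecs) <- words
  structure(vecs, class = c("cc_embeddings", "matrix", "array"))
}

#' @describeIn crisiscast-io Write the IPC panel
#'   (`district_id,period_end_month,phase`).
#' @param ipc tibble `district_id`, `period_ym`, `phase`
#' @export
write_ipc_csv <- function(ipc, path) {
  out <- data.frame(district_id = ipc$district_id,
                    period_end_month = ym_format(ipc$period_ym),
                    phase = ipc$phase)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn crisiscast-io Read an IPC panel.
#' @export
read_ipc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(district_id = df$district_id,
                        period_ym = ym_parse(df$period_end_month),
                        phase = as.integer(df$phase))
  class(out) <- c("cc_ipc", class(out))
  out
}

#' @describeIn crisiscast-io Write traditional factors: the time-varying
#'   panel to `factors.csv` (`unit_id,level,month,factor_name,value`) and the
#'   static attributes to `static.csv` (`district_id,attr_name,value`).
#' @param trad a `cc_factors` object
#' @param dir output directory
#' @export
write_factors_csv <- function(trad, dir) {
  tv <- data.frame(unit_id = trad$time_varying$district_id,
                   level = "district",
                   month = ym_format(trad$time_varying$ym),
                   factor_name = trad$time_varying$factor,
                   value = trad$time_varying$value)
  utils::write.csv(tv, file.path(dir, "factors.csv"), row.names = FALSE)
  st <- data.frame(district_id = trad$static$district_id,
                   attr_name = trad$static$attr,
                   value = trad$static$value)
  utils::write.csv(st, file.path(dir, "static.csv"), row.names = FALSE)
  invisible(dir)
}

#' @describeIn crisiscast-io Read traditional factors from a directory
#'   holding `factors.csv` and `static.csv`.
#' @export
read_factors_csv <- function(dir) {
  tv <- utils::read.csv(file.path(dir, "factors.csv"),
                        stringsAsFactors = FALSE)
  st <- utils::read.csv(file.path(dir, "static.csv"),
                        stringsAsFactors = FALSE)
  structure(list(
    time_varying = tibble::tibble(factor = tv$factor_name,
                                  district_id = tv$unit_id,
                                  ym = ym_parse(tv$month),
                                  value = tv$value),
    static = tibble::tibble(district_id = st$district_id,
                            attr = st$attr_name, value = st$value)),
    class = "cc_factors")
}

#' @describeIn crisiscast-io Write a news-factor panel
#'   (`feature,unit_id,level,month,value,coverage`).
#' @param news a `cc_news_panel`
#' @export
write_news_factors_csv <- function(news, path) {
  out <- data.frame(feature = news$feature, unit_id = news$unit_id,
                    level = news$level, month = ym_format(news$ym),
                    value = news$value, coverage = news$coverage)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn crisiscast-io Read a news-factor panel.
#' @export
read_news_factors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(feature = df$feature, unit_id = df$unit_id,
                        level = df$level, ym = ym_parse(df$month),
                        value = df$value, coverage = df$coverage)
  class(out) <- c("cc_news_panel", class(out))
  out
}

#' @describeIn crisiscast-io Write a text-feature table
#'   (`ngram,origin,status`).
#' @param features a `cc_features` table
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features)[, c("ngram", "origin", "status")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @describeIn crisiscast-io Read a text-feature table.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  text_features(df$ngram, origin = df$origin, status = df$status)
}

#' @describeIn crisiscast-io Write a factor-feature pairing
#'   (`factor,feature,spearman_rho`).
#' @param pairing a [match_traditional()] result
#' @export
write_pairing_csv <- function(pairing, path) {
  utils::write.csv(as.data.frame(pairing), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn crisiscast-io Write a screening result
#'   (`feature,d,p,q,F,pvalue,decision,reason`).
#' @param screen a [granger_screen()] result
#' @export
write_screen_csv <- function(screen, path) {
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn crisiscast-io Write forecast predictions
#'   (`model,district_id,period,y,yhat,fold`).
#' @param forecast a `cc_forecast` object
#' @param model model name recorded in the file
#' @export
write_predictions_csv <- function(forecast, model, path) {
  p <- forecast$predictions
  out <- data.frame(model = model, district_id = p$district_id,
                    period = ym_format(p$period_ym), y = p$y, yhat = p$yhat,
                    fold = p$fold)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
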