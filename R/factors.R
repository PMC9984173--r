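#' Build news-factor panels at district, province and country level
#'
#' For each text feature w, geographic unit i and calendar month t, the news
#' factor is the proportion of articles mentioning unit i during month t that
#' also mention w. An article mentions a province or country when it mentions
#' any of its districts. Months in which no article mentions the unit get
#' value 0 with coverage 0 (a flag, not a missing value, so downstream lag
#' matrices stay complete).
#'
#' @param articles a `cc_articles` object (see [gen_articles()]); its
#'   `articles` element may contain several rows per article when an article
#'   mentions several districts
#' @param features character vector of feature n-grams (or a `cc_features`
#'   table)
#' @param world a [gen_world()] object
#' @param months months to cover; defaults to the world's calendar
#' @param levels which aggregation levels to compute (all three by default;
#'   screening only consumes the district level, so restricting saves time on
#'   large candidate sets)
#' @return tibble `feature`, `unit_id`, `level` ("district", "province",
#'   "country"), `ym`, `value`, `coverage` of class `cc_news_panel`, complete
#'   over features x units x months
#' @export
build_news_factors <- function(articles, features, world,
                               months = world$months,
                               levels = c("district", "province",
                                          "country")) {
  levels <- match.arg(levels, several.ok = TRUE)
  if (inherits(features, "cc_features")) features <- features$ngram
  features <- unique(features)
  geo <- world$geo
  art <- dplyr::inner_join(articles$articles,
                           dplyr::select(geo, "district_id", "province_id",
                                         "country_id"),
                           by = "district_id")
  art <- art[art$ym %in% months, ]
  men <- articles$mentions[articles$mentions$ngram %in% features, ]

  level_tab <- function(unit_col, level) {
    units <- unique(geo[[unit_col]])
    u <- dplyr::distinct(art, .data$article_id, .data$ym,
                         unit_id = .data[[unit_col]])
    cov <- dplyr::count(u, .data$unit_id, .data$ym, name = "coverage")
    num <- dplyr::inner_join(u, men, by = "article_id",
                             relationship = "many-to-many")
    num <- dplyr::count(num, feature = .data$ngram, .data$unit_id, .data$ym,
                        name = "n_mention")
    grid <- tidyr::expand_grid(feature = features, unit_id = units,
                               ym = months)
    grid <- dplyr::left_join(grid, cov, by = c("unit_id", "ym"))
    grid <- dplyr::left_join(grid, num, by = c("feature", "unit_id", "ym"))
    grid$coverage <- dplyr::coalesce(grid$coverage, 0L)
    grid$n_mention <- dplyr::coalesce(grid$n_mention, 0L)
    grid$value <- ifelse(grid$coverage > 0, grid$n_mention / grid$coverage, 0)
    grid$level <- level
    dplyr::select(grid, "feature", "unit_id", "level", "ym", "value",
                  "coverage")
  }
  cols <- c(district = "district_id", province = "province_id",
            country = "country_id")
  out <- dplyr::bind_rows(lapply(levels, function(lev)
    level_tab(cols[[lev]], lev)))
  class(out) <- c("cc_news_panel", class(out))
  out
}

#' Hazen percentile ranks
#'
#' Ranks a series onto the 0-100 scale with the Hazen plotting position
#' (r - 0.5) / n * 100, using average ranks for ties; invariant under strictly
#' increasing transforms of the input.
#'
#' @param series numeric vector (non-empty)
#' @return numeric vector of percentile ranks in (0, 100)
#' @examples
#' percentile_rank(c(1, 2, 3, 4))  # 12.5 37.5 62.5 87.5
#' @export
percentile_rank <- function(series) {
  stopifnot(length(series) > 0)
  (rank(series, ties.method = "average") - 0.5) / length(series) * 100
}

#' Check the coherence of a feature cluster partition
#'
#' Converts every feature into a per-article binary mention indicator,
#' computes pairwise Pearson correlations between features, and reports, for
#' each feature, the mean correlation with the other members of its own
#' cluster and with each other cluster. A feature is coherent when its
#' within-cluster mean exceeds every other-cluster mean; the partition is
#' coherent when all (usable) features are.
#'
#' @param features character vector of feature n-grams
#' @param articles a `cc_articles` object
#' @param partition data frame `feature`, `cluster` assigning each feature to
#'   exactly one cluster (at least 2 clusters with at least 2 features each)
#' @return list with `per_feature` (tibble: feature, cluster, within_mean,
#'   max_other_mean, coherent), `excluded` (zero-variance features) and
#'   `coherent` (partition-level flag)
#' @export
cluster_coherence <- function(features, articles, partition) {
  partition <- tibble::as_tibble(partition)
  stopifnot(all(c("feature", "cluster") %in% names(partition)))
  if (anyDuplicated(partition$feature)) {
    stop("partition invariant violated: a feature appears in several clusters")
  }
  partition <- partition[partition$feature %in% features, ]
  sizes <- table(partition$cluster)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 clusters with at least 2 features each")
  }
  ids <- unique(articles$articles$article_id)
  men <- articles$mentions[articles$mentions$ngram %in% partition$feature, ]
  ind <- matrix(0L, length(ids), nrow(partition),
                dimnames = list(NULL, partition$feature))
  ind[cbind(match(men$article_id, ids), match(men$ngram, partition$feature))] <- 1L
  v <- apply(ind, 2, stats::var)
  excluded <- colnames(ind)[v == 0]
  usable <- colnames(ind)[v > 0]
  part <- partition[partition$feature %in% usable, ]
  cc <- stats::cor(ind[, usable, drop = FALSE])
  per_feature <- purrr::map_dfr(seq_len(nrow(part)), function(i) {
    f <- part$feature[i]; cl <- part$cluster[i]
    own <- setdiff(part$feature[part$cluster == cl], f)
    others <- split(part$feature[part$cluster != cl],
                    part$cluster[part$cluster != cl])
    within_mean <- if (length(own)) mean(cc[f, own]) else NA_real_
    other_means <- vapply(others, function(g) mean(cc[f, g]), numeric(1))
    tibble::tibble(feature = f, cluster = cl, within_mean = within_mean,
                   max_other_mean = if (length(other_means))
                     max(other_means) else NA_real_,
                   coherent = !is.na(within_mean) &
                     within_mean > max(other_means))
  })
  list(per_feature = per_feature, excluded = excluded,
       coherent = all(per_feature$coherent, na.rm = TRUE))
}

#' Pair traditional risk factors with their best-matching news factors
#'
#' Associates with each time-varying traditional factor the news factor with
#' which it has the highest Spearman correlation across pooled
#' district-months (pairwise-complete observations; ties broken
#' lexicographically by feature name). Pairs with fewer than 3 complete
#' observations are skipped.
#'
#' @param news a `cc_news_panel` (district-level rows are used)
#' @param trad a `cc_factors` object (or its `time_varying` tibble)
#' @return tibble `factor`, `feature`, `spearman_rho`
#' @export
match_traditional <- function(news, trad) {
  tv <- if (inherits(trad, "cc_factors")) trad$time_varying else trad
  nd <- news[news$level == "district", ]
  key <- paste(nd$unit_id, nd$ym)
  feats <- unique(nd$feature)
  purrr::map_dfr(unique(tv$factor), function(k) {
    fk <- tv[tv$factor == k, ]
    fkey <- paste(fk$district_id, fk$ym)
    rho <- vapply(feats, function(w) {
      nw <- nd[nd$feature == w, ]
      idx <- match(paste(nw$unit_id, nw$ym), fkey)
      ok <- !is.na(idx) & !is.na(nw$value) & !is.na(fk$value[idx])
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(nw$value[ok], fk$value[idx][ok],
                                  method = "spearman"))
    }, numeric(1))
    if (all(is.na(rho))) {
      return(tibble::tibble(factor = k, feature = NA_character_,
                            spearman_rho = NA_real_))
    }
    best <- order(-rho, feats)[1]
    tibble::tibble(factor = k, feature = feats[best],
                   spearman_rho = unname(rho[best]))
  })
}
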