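mk_world <- function() {
  gen_world(scenario_config(n_countries = 1, provinces_per_country = 2,
                            districts_per_province = 2, n_months = 3,
                            start_year = 2012, seed = 1))
}

# a hand-built six-article fixture over one month
mk_articles <- function(w) {
  m <- w$months[1]
  articles <- tibble::tibble(
    article_id = paste0("a", 1:6),
    ym = m,
    source = "src",
    district_id = c("C01-P01-D01", "C01-P01-D01", "C01-P01-D02",
                    "C01-P01-D02", "C01-P02-D01", "C01-P02-D01"))
  mentions <- tibble::tibble(
    article_id = c("a1", "a3", "a5", "a6"),
    ngram = "drought")
  structure(list(articles = articles, mentions = mentions,
                 frames = tibble::tibble()), class = "cc_articles")
}

test_that("news factors are mention proportions with hierarchy roll-up", {
  w <- mk_world()
  art <- mk_articles(w)
  nf <- build_news_factors(art, "drought", w, months = w$months[1])
  dv <- nf[nf$level == "district", ]
  expect_equal(dv$value[dv$unit_id == "C01-P01-D01"], 0.5)  # 1 of 2
  expect_equal(dv$value[dv$unit_id == "C01-P01-D02"], 0.5)
  expect_equal(dv$value[dv$unit_id == "C01-P02-D01"], 1.0)  # 2 of 2
  expect_equal(dv$value[dv$unit_id == "C01-P02-D02"], 0)    # no coverage
  expect_equal(dv$coverage[dv$unit_id == "C01-P02-D02"], 0L)
  # province: mentions of any descendant district count
  pv <- nf[nf$level == "province", ]
  expect_equal(pv$value[pv$unit_id == "C01-P01"], 2 / 4)
  expect_equal(pv$value[pv$unit_id == "C01-P02"], 2 / 2)
  cv <- nf[nf$level == "country", ]
  expect_equal(cv$value[cv$unit_id == "C01"], 4 / 6)
})

test_that("panel values are invariant to article order and duplication", {
  w <- mk_world()
  art <- mk_articles(w)
  base <- build_news_factors(art, "drought", w, months = w$months[1])
  # shuffle article order
  perm <- c(4, 2, 6, 1, 3, 5)
  art2 <- art
  art2$articles <- art$articles[perm, ]
  shuffled <- build_news_factors(art2, "drought", w, months = w$months[1])
  expect_equal(base$value, shuffled$value)
  # duplicate every article: proportions unchanged
  art3 <- art
  art3$articles <- dplyr::bind_rows(
    art$articles,
    dplyr::mutate(art$articles, article_id = paste0(article_id, "x")))
  art3$mentions <- dplyr::bind_rows(
    art$mentions, dplyr::mutate(art$mentions,
                                article_id = paste0(article_id, "x")))
  doubled <- build_news_factors(art3, "drought", w, months = w$months[1])
  expect_equal(base$value, doubled$value)
  # absent feature: all-zero series, not an error
  zero <- build_news_factors(art, "unseen", w, months = w$months[1])
  expect_true(all(zero$value == 0))
})

test_that("percentile ranks follow the Hazen formula with tie averaging", {
  expect_equal(percentile_rank(c(1, 2, 3, 4)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(percentile_rank(rep(7, 5)), rep(50, 5))
  expect_equal(percentile_rank(c(1, 1, 2)),
               c((1.5 - 0.5) / 3, (1.5 - 0.5) / 3, (3 - 0.5) / 3) * 100)
  # invariance under strictly monotone transforms
  set.seed(8)
  x <- rnorm(50)
  expect_equal(percentile_rank(x), percentile_rank(exp(x)))
  expect_error(percentile_rank(numeric()))
})

test_that("cluster coherence separates co-mention structure from shuffles", {
  set.seed(5)
  n <- 400
  # two blocks of perfectly co-mentioned features, no cross co-mention
  block <- rep(c(TRUE, FALSE), each = n / 2)
  articles <- tibble::tibble(article_id = paste0("a", 1:n), ym = 1,
                             source = "s", district_id = "d")
  mentions <- dplyr::bind_rows(
    tibble::tibble(article_id = articles$article_id[block], ngram = "f1"),
    tibble::tibble(article_id = articles$article_id[block], ngram = "f2"),
    tibble::tibble(article_id = articles$article_id[!block], ngram = "g1"),
    tibble::tibble(article_id = articles$article_id[!block], ngram = "g2"))
  art <- structure(list(articles = articles, mentions = mentions,
                        frames = tibble::tibble()), class = "cc_articles")
  part <- tibble::tibble(feature = c("f1", "f2", "g1", "g2"),
                         cluster = c("A", "A", "B", "B"))
  res <- cluster_coherence(part$feature, art, part)
  expect_true(res$coherent)
  expect_equal(res$per_feature$within_mean, rep(1, 4))

  # swapping labels across blocks must break coherence
  bad <- tibble::tibble(feature = c("f1", "g2", "g1", "f2"),
                        cluster = c("A", "A", "B", "B"))
  res_bad <- cluster_coherence(part$feature, art, bad)
  expect_false(res_bad$coherent)

  # duplicated feature across clusters violates the partition invariant
  dup <- dplyr::bind_rows(part, tibble::tibble(feature = "f1", cluster = "B"))
  expect_error(cluster_coherence(part$feature, art, dup), "several clusters")
})

test_that("random label shuffles of a coherent partition fail for some features", {
  sc <- tiny_scenario(seed = 23, n_months = 48, n_countries = 1)
  lex <- sc$config$lexicon
  feats <- lex$ngram[lex$component %in% sc$config$components]
  part <- tibble::tibble(feature = feats,
                         cluster = lex$cluster[match(feats, lex$ngram)])
  base <- cluster_coherence(feats, sc$articles, part)
  expect_true(mean(base$per_feature$coherent) > 0.9)
  set.seed(99)
  fails <- vapply(1:20, function(i) {
    shuf <- part
    shuf$cluster <- sample(shuf$cluster)
    res <- cluster_coherence(feats, sc$articles, shuf)
    any(!res$per_feature$coherent)
  }, logical(1))
  expect_true(mean(fails) > 0.9)
})

test_that("traditional-news pairing maximizes Spearman correlation", {
  set.seed(3)
  months <- 1:20
  base <- tibble::tibble(district_id = "d1", ym = months)
  trad <- structure(list(
    time_varying = dplyr::bind_rows(
      dplyr::mutate(base, factor = "k1", value = sin(months)),
      dplyr::mutate(base, factor = "k2", value = cos(months)),
      dplyr::mutate(base, factor = "k3", value = months * 1.0)),
    static = tibble::tibble()), class = "cc_factors")
  mk_news <- function(f, v)
    tibble::tibble(feature = f, unit_id = "d1", level = "district",
                   ym = months, value = v, coverage = 10L)
  news <- dplyr::bind_rows(
    mk_news("w1", sin(months)),            # identical to k1
    mk_news("w2", exp(cos(months))),       # monotone transform of k2
    mk_news("w3", rnorm(20)),
    mk_news("w4", -months * 2.0))          # anti-monotone to k3
  pair <- match_traditional(news, trad)
  expect_equal(pair$feature[pair$factor == "k1"], "w1")
  expect_equal(pair$spearman_rho[pair$factor == "k1"], 1)
  # rank invariance: monotone transform still achieves rho = 1
  expect_equal(pair$feature[pair$factor == "k2"], "w2")
  expect_equal(pair$spearman_rho[pair$factor == "k2"], 1)

  # brute-force correlation table oracle
  for (k in unique(trad$time_varying$factor)) {
    tv <- trad$time_varying[trad$time_varying$factor == k, ]
    rhos <- sapply(unique(news$feature), function(w)
      cor(news$value[news$feature == w], tv$value, method = "spearman"))
    expect_equal(pair$feature[pair$factor == k],
                 names(rhos)[order(-rhos, names(rhos))[1]])
  }
})
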