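test_that("world generation produces the requested geography and calendar", {
  cfg <- scenario_config(n_countries = 2, provinces_per_country = 2,
                         districts_per_province = 3, n_months = 24,
                         start_year = 2012)
  w <- gen_world(cfg)
  expect_equal(nrow(w$geo), 12)
  expect_equal(length(unique(w$geo$province_id)), 4)
  expect_false(anyDuplicated(w$geo$district_name) > 0)
  # 2 pre-switch years -> 4 reporting periods per year
  expect_length(w$period_ends, 8)
  expect_equal(ym_month(w$period_ends), rep(c(1, 4, 7, 10), 2))

  # 12 months entirely post-switch -> 3 periods (Feb, Jun, Oct)
  cfg2 <- scenario_config(n_countries = 1, provinces_per_country = 1,
                          districts_per_province = 2, n_months = 12,
                          start_year = 2018)
  w2 <- gen_world(cfg2)
  expect_equal(ym_month(w2$period_ends), c(2, 6, 10))

  expect_error(scenario_config(n_countries = 0), "positive")
  expect_error(scenario_config(ipc_cutpoints = c(1, 1, 2, 3)), "increasing")
})

test_that("reporting periods are strictly increasing across the regime switch", {
  cfg <- scenario_config(n_countries = 1, provinces_per_country = 1,
                         districts_per_province = 1, n_months = 48,
                         start_year = 2014)
  w <- gen_world(cfg)
  expect_true(all(diff(w$period_ends) > 0))
  pre <- w$period_ends[w$period_ends < ym(2016, 1)]
  post <- w$period_ends[w$period_ends >= ym(2016, 1)]
  expect_true(all(diff(pre) == 3))
  expect_true(all(ym_month(post) %in% c(2, 6, 10)))
})

test_that("IPC phases are the cutpoint count of aggregated risk", {
  cfg <- scenario_config(n_countries = 1, provinces_per_country = 2,
                         districts_per_province = 2, n_months = 36,
                         start_year = 2010, seed = 4)
  w <- gen_world(cfg)
  r <- gen_latent_risk(w)
  # cutpoints far above any risk value -> all phase 1
  ipc_lo <- gen_ipc_panel(w, r, cutpoints = c(1e6, 2e6, 3e6, 4e6))
  expect_true(all(ipc_lo$phase == 1))
  # cutpoints far below -> all phase 5
  ipc_hi <- gen_ipc_panel(w, r, cutpoints = c(-4e6, -3e6, -2e6, -1e6))
  expect_true(all(ipc_hi$phase == 5))
  ipc <- gen_ipc_panel(w, r)
  expect_true(all(ipc$phase %in% 1:5))
  # complete panel
  expect_equal(nrow(ipc), nrow(w$geo) * length(w$period_ends))
  expect_error(gen_ipc_panel(w, r, cutpoints = c(2, 1, 3, 4)), "increasing")
})

test_that("phase frequencies are stable across independent seed streams", {
  freqs <- lapply(c(7, 7007), function(s) {
    cfg <- scenario_config(n_countries = 8, provinces_per_country = 5,
                           districts_per_province = 5, n_months = 120,
                           start_year = 2010, ar_coef = 0.9, shock_sd = 1,
                           seed = s)
    w <- gen_world(cfg)
    r <- gen_latent_risk(w, ar_coef = 0.9, shock_sd = 1)
    ipc <- gen_ipc_panel(w, r)
    tabulate(ipc$phase, 5) / nrow(ipc)
  })
  # empirical phase distribution within 3 percentage points between two
  # Monte-Carlo replicates (200 districts x 40 periods each); the shared
  # country/province shocks keep the effective sample well below 8000
  expect_true(all(abs(freqs[[1]] - freqs[[2]]) < 0.03))
})

test_that("traditional factors are lagged monotone transforms of the risk", {
  cfg <- scenario_config(n_countries = 1, provinces_per_country = 1,
                         districts_per_province = 1, n_months = 300,
                         start_year = 1995, seed = 5)
  w <- gen_world(cfg)
  r <- gen_latent_risk(w, seed = 6)
  # zero noise, zero lag: exact monotone transform of the component
  tf0 <- gen_traditional_factors(w, r, noise_sd = 0, report_lag_months = 0)
  rd <- tf0$time_varying[tf0$time_varying$factor == "rainfall_deficit", ]
  z <- sapply(rd$ym, function(m)
    crisiscast:::risk_z(r, "weather", rd$district_id[1], m))
  expect_equal(rd$value, z, tolerance = 1e-12)

  # lag 2: cross-correlation peaks at displacement 2 (n = 300 months)
  tf2 <- gen_traditional_factors(w, r, noise_sd = 0.2, report_lag_months = 2,
                                 seed = 8)
  f2 <- tf2$time_varying[tf2$time_varying$factor == "rainfall_deficit", ]
  f2 <- f2[order(f2$ym), ]
  zs <- sapply(sort(f2$ym), function(m)
    crisiscast:::risk_z(r, "weather", f2$district_id[1], m))
  cc <- stats::ccf(f2$value, zs, lag.max = 6, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 2)

  # time-invariant attributes do not vary over months (single table)
  expect_equal(nrow(tf0$static), nrow(w$geo) * 5)
})

test_that("synthetic embeddings respect the cluster geometry", {
  vocab <- data.frame(word = sprintf("w%02d", 1:50),
                      cluster = rep(c("a", "b", "c", "d", "e"), each = 10))
  emb <- gen_embeddings(vocab, dim = 16, within_sd = 0.1, between_sd = 2,
                        seed = 3)
  expect_equal(nrow(emb), 50)
  dmat <- as.matrix(dist(emb))
  same <- outer(vocab$cluster, vocab$cluster, "==") & upper.tri(dmat)
  diffc <- !outer(vocab$cluster, vocab$cluster, "==") & upper.tri(dmat)
  expect_lt(mean(dmat[same]), mean(dmat[diffc]))

  # within_sd 0 is rejected only when >= between_sd; near-zero collapses
  # same-cluster words onto the centroid
  emb0 <- gen_embeddings(vocab, dim = 4, within_sd = 1e-12, between_sd = 2,
                         seed = 3)
  expect_lt(max(dist(emb0[1:10, ])), 1e-9)

  # determinism: same seed, same table
  emb2 <- gen_embeddings(vocab, dim = 16, within_sd = 0.1, between_sd = 2,
                         seed = 3)
  expect_identical(emb, emb2)
  expect_error(gen_embeddings(data.frame(word = "x", cluster = NA)),
               "cluster")
  expect_error(gen_embeddings(vocab, within_sd = 3, between_sd = 2),
               "within_sd")
})

test_that("article stream has the configured mention structure", {
  sc <- tiny_scenario(seed = 13, n_months = 60, n_countries = 1,
                      article_rate = 30)
  art <- sc$articles
  expect_true(all(art$articles$ym %in% sc$world$months))
  expect_true(all(art$mentions$article_id %in% art$articles$article_id))

  # noise features: observed mention proportion within 3 SE of the base rate
  cfg <- sc$config
  noise <- cfg$lexicon$ngram[cfg$lexicon$component == "noise"][1]
  n_art <- length(unique(art$articles$article_id))
  p_hat <- sum(art$mentions$ngram == noise) / n_art
  se <- sqrt(cfg$noise_mention_prob * (1 - cfg$noise_mention_prob) / n_art)
  expect_lt(abs(p_hat - cfg$noise_mention_prob), 3 * se)

  # frame emission probability 0 -> no causal frames beyond decoys
  cfg0 <- scenario_config(n_countries = 1, provinces_per_country = 2,
                          districts_per_province = 2, n_months = 24,
                          frame_emission_prob = 0, decoy_frame_prob = 0,
                          seed = 2)
  w0 <- gen_world(cfg0)
  r0 <- gen_latent_risk(w0)
  a0 <- gen_articles(w0, r0, cfg0)
  expect_equal(nrow(a0$frames), 0)

  # empty lexicon rejected
  cfg_bad <- cfg0
  cfg_bad$lexicon <- cfg0$lexicon[0, ]
  expect_error(gen_articles(w0, r0, cfg_bad), "lexicon")
})

test_that("planted cause-feature mentions lead the IPC phase by lead_tau", {
  cfg <- scenario_config(n_countries = 6, provinces_per_country = 5,
                         districts_per_province = 5, n_months = 120,
                         start_year = 2010, article_rate = 30,
                         lead_tau = 4, seed = 11)
  w <- gen_world(cfg)
  r <- gen_latent_risk(w)
  ipc <- gen_ipc_panel(w, r)
  art <- gen_articles(w, r, cfg)
  news <- build_news_factors(art, "drought", w)
  nd <- news[news$level == "district", ]
  # monthly phase step function per district
  months <- w$months
  cors <- sapply(0:8, function(lag) {
    x <- nd$value
    pm <- vapply(seq_len(nrow(nd)), function(i) {
      pe <- w$period_ends[w$period_ends >= nd$ym[i] + lag]
      if (!length(pe)) return(NA_real_)
      ipc$phase[ipc$district_id == nd$unit_id[i] &
                  ipc$period_ym == pe[1]][1]
    }, numeric(1))
    suppressWarnings(cor(x, pm, use = "complete.obs"))
  })
  # mention proportion correlates most with the phase 4-6 months later
  # (lead_tau = 4 plus the within-period aggregation window)
  expect_true(which.max(cors) - 1 >= 3 && which.max(cors) - 1 <= 6)
})

test_that("fixing the seed fixes every generated byte", {
  a <- tiny_scenario(seed = 42, n_months = 36, n_countries = 1)
  b <- tiny_scenario(seed = 42, n_months = 36, n_countries = 1)
  expect_identical(a$ipc, b$ipc)
  expect_identical(a$trad, b$trad)
  expect_identical(a$articles$articles, b$articles$articles)
  expect_identical(a$articles$mentions, b$articles$mentions)
  expect_identical(a$articles$frames, b$articles$frames)
  expect_identical(a$embeddings, b$embeddings)
})
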