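# shared fixtures and independent oracles, built in code at test time

# a small but fully featured scenario
tiny_scenario <- function(seed = 11, n_months = 96, n_countries = 2,
                          article_rate = 25) {
  cfg <- scenario_config(n_countries = n_countries,
                         provinces_per_country = 3,
                         districts_per_province = 3,
                         n_months = n_months, start_year = 2010,
                         article_rate = article_rate, seed = seed)
  gen_scenario(cfg)
}

# hand-set embedding table from named vectors
manual_emb <- function(...) {
  vecs <- list(...)
  m <- do.call(rbind, vecs)
  rownames(m) <- names(vecs)
  m
}

# --- independent WMD oracle -------------------------------------------------
# uniform-weight optimal transport reduces, after expanding both bags to
# lcm(m, n) equal-mass units, to an assignment problem, solved here by full
# permutation enumeration (exact by Birkhoff's theorem; sizes <= 6)

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

lcm2 <- function(a, b) a * b / gcd2(a, b)
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

oracle_wmd <- function(doc_a, doc_b, emb) {
  doc_a <- doc_a[doc_a %in% rownames(emb)]
  doc_b <- doc_b[doc_b %in% rownames(emb)]
  m <- length(doc_a); n <- length(doc_b)
  stopifnot(m > 0, n > 0)
  L <- lcm2(m, n)
  ea <- emb[rep(doc_a, each = L / m), , drop = FALSE]
  eb <- emb[rep(doc_b, each = L / n), , drop = FALSE]
  cost <- as.matrix(stats::dist(rbind(ea, eb)))[seq_len(L), L + seq_len(L),
                                                drop = FALSE]
  best <- Inf
  for (p in perms(seq_len(L))) {
    v <- sum(cost[cbind(seq_len(L), p)]) / L
    if (v < best) best <- v
  }
  best
}

# --- nested-F oracle: direct two-regression transcription -------------------
oracle_panel_f <- function(ipc, x, p, q, period_max = NULL) {
  periods <- sort(unique(ipc$period_ym))
  rows <- list()
  for (d in unique(ipc$district_id)) {
    yd <- ipc[ipc$district_id == d, ]
    yd <- yd[order(yd$period_ym), ]
    xd <- x[x$district_id == d, ]
    for (i in seq_along(periods)) {
      if (i <= p) next
      if (!is.null(period_max) && periods[i] > period_max) next
      ylags <- sapply(seq_len(p), function(j)
        yd$phase[match(periods[i - j], yd$period_ym)])
      xlags <- sapply(3:(q + 2), function(l)
        xd$value[match(periods[i] - l, xd$ym)])
      rows[[length(rows) + 1]] <-
        c(y = yd$phase[match(periods[i], yd$period_ym)], ylags, xlags)
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("y", paste0("yl", seq_len(p)), paste0("xl", seq_len(q)))
  df <- df[stats::complete.cases(df), ]
  full <- stats::lm(y ~ ., data = df)
  restr <- stats::lm(stats::reformulate(paste0("yl", seq_len(p)), "y"),
                     data = df)
  rss_f <- sum(stats::resid(full)^2)
  rss_r <- sum(stats::resid(restr)^2)
  n <- nrow(df)
  f <- ((rss_r - rss_f) / q) / (rss_f / (n - p - q - 1))
  list(F = f, p_value = stats::pf(f, q, n - p - q - 1, lower.tail = FALSE),
       n = n)
}

# --- outbreak sweep oracle: per-threshold exhaustive evaluation -------------
oracle_sweep <- function(pred, labels, thr) {
  pred <- dplyr::arrange(pred, district_id, period_ym)
  g <- dplyr::group_by(pred, district_id)
  g <- dplyr::mutate(g, prev = dplyr::lag(yhat), nxt = dplyr::lead(yhat))
  g <- dplyr::ungroup(g)
  g <- g[!is.na(g$prev) & !is.na(g$nxt), ]
  g <- dplyr::inner_join(g, labels[, c("district_id", "period_ym", "onset")],
                         by = c("district_id", "period_ym"))
  out <- list()
  for (u in thr) for (l in thr[thr <= u]) {
    pos <- g$yhat >= u & g$nxt >= u & g$prev <= l
    if (!any(pos)) next
    tp <- sum(pos & g$onset)
    out[[length(out) + 1]] <- data.frame(
      l = l, u = u, tp = tp, fp = sum(pos) - tp, fn = sum(g$onset) - tp)
  }
  do.call(rbind, out)
}

# --- DM / CI oracle: literal formula transcription --------------------------
oracle_dm <- function(ea, eb) {
  d <- ea^2 - eb^2
  n <- length(d)
  dbar <- mean(d)
  M <- floor(n^(1/3)) + 1
  gam <- sapply(0:M, function(k) {
    s <- 0
    for (i in (k + 1):n) s <- s + (d[i] - dbar) * (d[i - k] - dbar)
    s / n
  })
  v <- (gam[1] + 2 * sum(gam[-1])) / n
  stat <- dbar / sqrt(v)
  list(statistic = stat, p_value = 2 * stats::pnorm(-abs(stat)))
}

oracle_rmse_ci <- function(e) {
  e2 <- e^2
  n <- length(e2)
  m <- mean(e2)
  M <- floor(n^(1/3)) + 1
  gam <- sapply(0:M, function(k) {
    s <- 0
    for (i in (k + 1):n) s <- s + (e2[i] - m) * (e2[i - k] - m)
    s / n
  })
  sig <- sqrt((gam[1] + 2 * sum(gam[-1])) / n)
  list(gamma = gam, sigma = sig, ci = c(m - 1.96 * sig, m + 1.96 * sig))
}
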