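# internal: pivot the IPC panel to a district x period matrix
ipc_matrix <- function(ipc) {
  periods <- sort(unique(ipc$period_ym))
  districts <- sort(unique(ipc$district_id))
  y <- matrix(NA_real_, length(districts), length(periods),
              dimnames = list(districts, as.character(periods)))
  y[cbind(match(ipc$district_id, districts),
          match(ipc$period_ym, periods))] <- ipc$phase
  y
}

# internal: pivot a (district_id, ym, value) series to district x month matrix
series_matrix <- function(x, districts) {
  months <- sort(unique(x$ym))
  m <- matrix(NA_real_, length(districts), length(months),
              dimnames = list(districts, as.character(months)))
  idx <- cbind(match(x$district_id, districts), match(x$ym, months))
  keep <- !is.na(idx[, 1])
  m[idx[keep, , drop = FALSE]] <- x$value[keep]
  m
}

#' Fit a panel autoregressive distributed lag (ADL) model
#'
#' Pooled least squares over stacked district-period observations of
#' \deqn{y_{d,t} = a_0 + a_1 y_{d,t-1 period} + ... + a_p y_{d,t-p periods}
#'   + b_1 x_{d,t-3} + ... + b_q x_{d,t-q-2} + e_{d,t}}
#' where the phase lags step over reporting periods and the factor lags over
#' calendar months starting three months back. The orders (p, q) are chosen
#' by AIC over `p_range` x `q_range` on a common estimation sample (the rows
#' available at the largest orders), then the chosen model and its
#' y-lags-only restriction are refit on the maximal sample for those orders.
#'
#' @param ipc tibble `district_id`, `period_ym`, `phase`
#' @param x tibble `district_id`, `ym`, `value`: one feature's district-level
#'   monthly series (already differenced if needed)
#' @param p_range candidate phase-lag orders (periods)
#' @param q_range candidate factor-lag orders (months)
#' @param period_max only use target periods `<= period_max` (train split)
#' @return `cc_adl_fit`: list with `coefficients` (a0, a1..ap, b1..bq), `p`,
#'   `q`, `aic`, `rss`, `rss_restricted`, `n_obs`, plus the model frame used
#' @export
fit_panel_adl <- function(ipc, x, p_range = 1:4, q_range = 1:6,
                          period_max = NULL) {
  y <- ipc_matrix(ipc)
  districts <- rownames(y)
  periods <- as.integer(colnames(y))
  xm <- series_matrix(x, districts)
  xmonths <- as.integer(colnames(xm))
  pmax <- max(p_range); qmax <- max(q_range)

  design_for <- function(p, q) {
    ti <- seq_along(periods)[-seq_len(p)]
    if (!is.null(period_max)) ti <- ti[periods[ti] <= period_max]
    # x lag months 3..q+2 must exist in the x matrix
    ti <- ti[periods[ti] - (q + 2) >= min(xmonths) &
               periods[ti] - 3 <= max(xmonths)]
    if (length(ti) == 0) stop("cc_fit_failure: no estimable observations")
    rows_d <- rep(seq_along(districts), times = length(ti))
    rows_t <- rep(ti, each = length(districts))
    resp <- y[cbind(rows_d, rows_t)]
    ylags <- sapply(seq_len(p), function(j) y[cbind(rows_d, rows_t - j)])
    xlags <- sapply(3:(q + 2), function(l)
      xm[cbind(rows_d, match(periods[rows_t] - l, xmonths))])
    X <- cbind(1, ylags, xlags)
    colnames(X) <- c("a0", paste0("a", seq_len(p)), paste0("b", seq_len(q)))
    ok <- stats::complete.cases(cbind(resp, X))
    list(y = resp[ok], X = X[ok, , drop = FALSE],
         district = districts[rows_d[ok]], period = periods[rows_t[ok]])
  }

  # order selection on the common sample of the largest orders
  common <- design_for(pmax, qmax)
  best <- NULL
  for (p in sort(p_range)) for (q in sort(q_range)) {
    cols <- c("a0", paste0("a", seq_len(p)), paste0("b", seq_len(q)))
    X <- common$X[, cols, drop = FALSE]
    fit <- stats::lm.fit(X, common$y)
    if (fit$rank < ncol(X)) next
    n <- length(common$y)
    rss <- sum(fit$residuals^2)
    aic <- n * log(rss / n) + 2 * (ncol(X) + 1)
    if (is.null(best) || aic < best$aic) best <- list(p = p, q = q, aic = aic)
  }
  if (is.null(best)) stop("cc_fit_failure: rank-deficient design at all orders")

  # refit chosen orders (and the y-lags-only restriction) on their own sample
  d <- design_for(best$p, best$q)
  full <- stats::lm.fit(d$X, d$y)
  if (full$rank < ncol(d$X)) stop("cc_fit_failure: rank-deficient design")
  Xr <- d$X[, seq_len(best$p + 1), drop = FALSE]
  restr <- stats::lm.fit(Xr, d$y)
  n <- length(d$y)
  rss <- sum(full$residuals^2)
  if (n <= best$p + best$q + 1) stop("cc_fit_failure: too few observations")
  structure(list(
    coefficients = full$coefficients, p = best$p, q = best$q,
    aic = n * log(rss / n) + 2 * (best$p + best$q + 2),
    rss = rss, rss_restricted = sum(restr$residuals^2), n_obs = n,
    data = d), class = "cc_adl_fit")
}

#' Nested F test of an ADL fit's factor block
#'
#' Tests the joint null b_1 = ... = b_q = 0 against the full fit:
#' F = ((RSS_r - RSS_f)/q) / (RSS_f/(n - p - q - 1)).
#'
#' @param fit a [fit_panel_adl()] result
#' @return list with `F`, `p_value`, `df1`, `df2`
#' @export
adl_f_test <- function(fit) {
  stopifnot(inherits(fit, "cc_adl_fit"))
  df1 <- fit$q
  df2 <- fit$n_obs - fit$p - fit$q - 1
  f <- ((fit$rss_restricted - fit$rss) / df1) / (fit$rss / df2)
  list(F = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Screen news factors by panel Granger causality
#'
#' For each feature: (1) difference its district series until stationary by
#' the ADF rule (the feature-level difference order is the smallest order
#' sufficient for at least half of the testable district series); (2) fit the
#' panel ADL model on training observations with AIC order selection; (3)
#' retain the feature iff the nested F test of the factor lags rejects at
#' `level`. When evaluation periods are supplied, the full and restricted
#' models are also scored out-of-split (reported, not used for the decision).
#'
#' @param news a `cc_news_panel` (district rows are used) or a tibble
#'   `feature`, `unit_id`, `ym`, `value`
#' @param ipc tibble `district_id`, `period_ym`, `phase`
#' @param train_end last period (year-month index) used for estimation; must
#'   precede all forecast-evaluation data
#' @param eval_end optional last period of the held-out screening check
#' @param level F-test level (default 0.01)
#' @param p_range,q_range ADL order search ranges
#' @param adf_level,max_diff differencing rule parameters
#' @param max_adf_districts cap on the number of district series entering the
#'   differencing vote (an evenly spaced, deterministic subset; the vote is a
#'   feature-level decision and stabilizes well before all districts are
#'   tested)
#' @return `cc_screen` tibble: `feature`, `d`, `p`, `q`, `F`, `pvalue`,
#'   `decision`, `reason`, `eval_rmse_full`, `eval_rmse_restricted`
#' @export
granger_screen <- function(news, ipc, train_end, eval_end = NULL,
                           level = 0.01, p_range = 1:4, q_range = 1:6,
                           adf_level = 0.05, max_diff = 2,
                           max_adf_districts = 40) {
  if ("level" %in% names(news)) news <- news[news$level == "district", ]
  stopifnot(train_end < max(ipc$period_ym) || is.null(eval_end))
  if (!is.null(eval_end) && eval_end <= train_end) {
    stop("eval_end must follow train_end")
  }
  feats <- unique(news$feature)
  out <- purrr::map_dfr(feats, function(w) {
    xw <- news[news$feature == w, c("unit_id", "ym", "value")]
    names(xw)[1] <- "district_id"
    row <- tibble::tibble(feature = w, d = NA_integer_, p = NA_integer_,
                          q = NA_integer_, F = NA_real_, pvalue = NA_real_,
                          decision = "discarded", reason = "",
                          eval_rmse_full = NA_real_,
                          eval_rmse_restricted = NA_real_)
    if (stats::sd(xw$value) == 0) {
      row$reason <- "degenerate: zero variance"
      return(row)
    }
    # feature-level difference order: smallest d covering >= half the
    # testable district series (evenly spaced district subset)
    all_d <- sort(unique(xw$district_id))
    if (length(all_d) > max_adf_districts) {
      all_d <- all_d[unique(round(seq(1, length(all_d),
                                      length.out = max_adf_districts)))]
    }
    ds <- vapply(split(xw[xw$district_id %in% all_d, ],
                       xw$district_id[xw$district_id %in% all_d]),
                 function(s) {
      s <- s[order(s$ym), ]
      if (stats::sd(s$value) == 0) return(NA_integer_)
      r <- tryCatch(adf_difference(s$value, level = adf_level,
                                   max_diff = max_diff),
                    error = function(e) NULL)
      if (is.null(r)) NA_integer_ else r$d
    }, integer(1))
    ds <- ds[!is.na(ds)]
    if (length(ds) == 0) {
      row$reason <- "screening-skip: no testable district series"
      return(row)
    }
    d_feat <- as.integer(sort(ds)[ceiling(length(ds) / 2)])
    if (d_feat > 0) {
      xw <- dplyr::group_by(xw, .data$district_id)
      xw <- dplyr::arrange(xw, .data$ym, .by_group = TRUE)
      xw <- dplyr::mutate(xw, value = .data$value -
                            dplyr::lag(.data$value, d_feat))
      xw <- dplyr::ungroup(xw)
      xw <- xw[!is.na(xw$value), ]
    }
    fit <- tryCatch(
      fit_panel_adl(ipc, xw, p_range = p_range, q_range = q_range,
                    period_max = train_end),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row$d <- d_feat
      row$reason <- paste("fit failure:", conditionMessage(fit))
      return(row)
    }
    ft <- adl_f_test(fit)
    row$d <- d_feat; row$p <- fit$p; row$q <- fit$q
    row$F <- ft$F; row$pvalue <- ft$p_value
    row$decision <- if (ft$p_value < level) "retained" else "discarded"
    row$reason <- if (row$decision == "retained") "granger" else "f-test"
    if (!is.null(eval_end)) {
      ev <- tryCatch(
        adl_eval_rmse(fit, ipc, xw, train_end, eval_end),
        error = function(e) NULL)
      if (!is.null(ev)) {
        row$eval_rmse_full <- ev$full
        row$eval_rmse_restricted <- ev$restricted
      }
    }
    row
  })
  class(out) <- c("cc_screen", class(out))
  out
}

# out-of-split RMSE of the fitted full model and its restriction over the
# evaluation periods (train_end, eval_end]
adl_eval_rmse <- function(fit, ipc, xw, train_end, eval_end) {
  all_fit <- fit_panel_adl(ipc, xw, p_range = fit$p, q_range = fit$q,
                           period_max = eval_end)
  d <- all_fit$data
  sel <- d$period > train_end & d$period <= eval_end
  if (!any(sel)) return(NULL)
  X <- d$X[sel, , drop = FALSE]
  yv <- d$y[sel]
  pred_full <- drop(X %*% fit$coefficients)
  b_restr <- stats::lm.fit(fit$data$X[, seq_len(fit$p + 1), drop = FALSE],
                           fit$data$y)$coefficients
  pred_restr <- drop(X[, seq_len(fit$p + 1), drop = FALSE] %*% b_restr)
  list(full = sqrt(mean((yv - pred_full)^2)),
       restricted = sqrt(mean((yv - pred_restr)^2)))
}
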