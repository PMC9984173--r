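# Dickey-Fuller tau_mu critical values (regression with constant, no trend),
# Fuller (1976) table; rows are sample sizes, columns lower/upper tail
# probabilities used for p-value interpolation.
adf_tau_mu_table <- function() {
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  tab <- rbind(
    `25`  = c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    `50`  = c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    `100` = c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    `250` = c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    `500` = c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    `1e5` = c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
  list(n = c(25, 50, 100, 250, 500, 1e5), probs = probs, tab = tab)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the ADF regression with a constant and no trend,
#' \eqn{\Delta y_t = \alpha + \rho y_{t-1} + \sum_{i=1}^k \phi_i \Delta y_{t-i}
#' + \epsilon_t}, choosing the augmentation order k by AIC on a common sample
#' up to `k_max`, and evaluates the t statistic of \eqn{\rho} against the
#' Dickey-Fuller tau_mu distribution (table interpolation over sample size and
#' tail probability; p-values are clamped to [0.01, 0.99]).
#'
#' @param series numeric series
#' @param k_max maximum augmentation lag (default min(12, trunc((n-1)^(1/3))
#'   + 4), capped by the sample)
#' @return list with `statistic`, `p_value`, `lag` (chosen k), `n_used`
#' @export
adf_test <- function(series, k_max = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (stats::sd(series) == 0 || !all(is.finite(series))) {
    stop("adf_test: degenerate series (zero variance or non-finite values)")
  }
  if (is.null(k_max)) k_max <- min(12L, max(0L, trunc((n - 1)^(1/3)) + 4L))
  k_max <- min(k_max, max(0L, n - 10L))
  if (n - k_max - 1 < 8) stop("adf_test: series too short")
  dy <- diff(series)
  # common estimation sample across candidate k for AIC comparability
  t0 <- k_max + 1L
  idx <- t0:length(dy)
  y_lag <- series[idx]           # y_{t-1} for Delta y_t at positions idx
  resp <- dy[idx]
  lagmat <- if (k_max > 0)
    sapply(seq_len(k_max), function(i) dy[idx - i]) else NULL
  best <- NULL
  for (k in 0:k_max) {
    X <- cbind(1, y_lag, if (k > 0) lagmat[, seq_len(k), drop = FALSE])
    fit <- stats::lm.fit(X, resp)
    rss <- sum(fit$residuals^2)
    nn <- length(resp)
    aic <- nn * log(rss / nn) + 2 * (k + 2)
    if (is.null(best) || aic < best$aic) best <- list(k = k, aic = aic, X = X,
                                                     fit = fit, rss = rss)
  }
  # refit at chosen k on the longest sample for the reported statistic
  k <- best$k
  t0 <- k + 1L
  idx <- t0:length(dy)
  X <- cbind(1, series[idx],
             if (k > 0) sapply(seq_len(k), function(i) dy[idx - i]))
  resp <- dy[idx]
  fit <- stats::lm.fit(X, resp)
  rss <- sum(fit$residuals^2)
  df <- length(resp) - ncol(X)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se_rho <- sqrt(rss / df * XtX_inv[2, 2])
  stat <- fit$coefficients[2] / se_rho
  tbl <- adf_tau_mu_table()
  cv <- apply(tbl$tab, 2, function(col)
    stats::approx(tbl$n, col, xout = length(resp), rule = 2)$y)
  p <- stats::approx(cv, tbl$probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = unname(p), lag = k,
       n_used = length(resp))
}

#' Difference a series until it passes the ADF test
#'
#' Returns the d-th difference with the smallest d <= `max_diff` for which
#' the ADF unit-root null is rejected at `level`. If no difference order up
#' to `max_diff` passes, the `max_diff`-th difference is returned with
#' `stationary = FALSE`.
#'
#' @param series numeric series (length >= 20 after differencing)
#' @param level rejection level of the ADF test (default 0.05)
#' @param max_diff maximum difference order (default 2)
#' @return list with `series` (the differenced series), `d`, `stationary`,
#'   `degenerate` (zero-variance input flag)
#' @export
adf_difference <- function(series, level = 0.05, max_diff = 2) {
  series <- as.numeric(series)
  if (length(series) - max_diff < 20) {
    stop("screening-skip: series too short for adf_difference")
  }
  if (stats::sd(series) == 0) {
    return(list(series = diff(series, differences = 1), d = 1L,
                stationary = FALSE, degenerate = TRUE))
  }
  for (d in 0:max_diff) {
    s <- if (d == 0) series else diff(series, differences = d)
    if (stats::sd(s) == 0) {       # differencing produced a constant
      return(list(series = s, d = as.integer(d), stationary = TRUE,
                  degenerate = TRUE))
    }
    res <- tryCatch(adf_test(s), error = function(e) NULL)
    if (!is.null(res) && res$p_value < level) {
      return(list(series = s, d = as.integer(d), stationary = TRUE,
                  degenerate = FALSE))
    }
  }
  list(series = diff(series, differences = max_diff), d = as.integer(max_diff),
       stationary = FALSE, degenerate = FALSE)
}
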