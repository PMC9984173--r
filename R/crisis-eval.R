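#' Label food-crisis outbreaks in an IPC panel
#'
#' An outbreak starts at the period where the phase reaches 3 or more and
#' stays at 3 or more for the following period, while the previous period's
#' phase was at most 2. The first period of a series can never be an onset
#' (no previous period), nor can the last (no following period). The episode
#' runs from the onset until the phase first drops back to 2 or below; it is
#' severe when any episode period reaches phase 4 or 5.
#'
#' @param ipc tibble `district_id`, `period_ym`, `phase`
#' @return tibble `district_id`, `period_ym`, `onset` (logical), `severe`,
#'   `duration` (episode length in periods; NA off-onsets)
#' @export
label_outbreaks <- function(ipc) {
  ipc <- dplyr::arrange(ipc, .data$district_id, .data$period_ym)
  purrr::map_dfr(split(ipc, ipc$district_id), function(s) {
    ph <- s$phase
    n <- length(ph)
    onset <- rep(FALSE, n)
    severe <- rep(NA, n)
    duration <- rep(NA_integer_, n)
    if (n >= 3) {
      for (t in 2:(n - 1)) {
        if (ph[t] >= 3 && ph[t + 1] >= 3 && ph[t - 1] <= 2) {
          onset[t] <- TRUE
          ep_end <- t
          while (ep_end < n && ph[ep_end + 1] >= 3) ep_end <- ep_end + 1
          severe[t] <- any(ph[t:ep_end] >= 4)
          duration[t] <- ep_end - t + 1L
        }
      }
    }
    tibble::tibble(district_id = s$district_id, period_ym = s$period_ym,
                   onset = onset, severe = severe, duration = duration)
  })
}

# internal: per (district, period) triples (yhat_prev, yhat, yhat_next) and,
# if truth is supplied, the outbreak label; only periods with both
# neighbours present are evaluable
onset_triples <- function(pred, labels = NULL) {
  pred <- dplyr::arrange(pred, .data$district_id, .data$period_ym)
  g <- dplyr::group_by(pred, .data$district_id)
  g <- dplyr::mutate(g,
                     prev = dplyr::lag(.data$yhat),
                     nxt = dplyr::lead(.data$yhat))
  g <- dplyr::ungroup(g)
  g <- g[!is.na(g$prev) & !is.na(g$nxt), ]
  if (!is.null(labels)) {
    g <- dplyr::inner_join(g,
                           labels[, c("district_id", "period_ym", "onset")],
                           by = c("district_id", "period_ym"))
  }
  g
}

#' Convert phase predictions into predicted outbreak onsets
#'
#' A model predicts an onset in period t iff its predicted phase is at least
#' `u` in t and in the following period, and at most `l` in the previous
#' period (the adjacent-reporting-period reading of the +/- one quarter
#' rule). Periods missing a neighbouring prediction are unevaluable and are
#' excluded (their count is reported as an attribute).
#'
#' @param pred tibble `district_id`, `period_ym`, `yhat`
#' @param l,u lower and upper thresholds, `l <= u`
#' @param observed optional IPC tibble (`district_id`, `period_ym`,
#'   `phase`); when supplied, the prior-period condition tests the observed
#'   phase instead of the prediction (the formula as printed uses the
#'   prediction; this variant is provided behind this argument)
#' @return tibble `district_id`, `period_ym`, `pred_onset`; attribute
#'   `n_unevaluable`
#' @export
classify_outbreaks <- function(pred, l, u, observed = NULL) {
  stopifnot(l <= u)
  g <- onset_triples(pred)
  prev <- g$prev
  if (!is.null(observed)) {
    obs <- dplyr::arrange(observed, .data$district_id, .data$period_ym)
    obs <- dplyr::mutate(dplyr::group_by(obs, .data$district_id),
                         prev_phase = dplyr::lag(.data$phase))
    obs <- dplyr::ungroup(obs)
    prev <- obs$prev_phase[match(paste(g$district_id, g$period_ym),
                                 paste(obs$district_id, obs$period_ym))]
  }
  keep <- !is.na(prev)
  g <- g[keep, ]; prev <- prev[keep]
  out <- tibble::tibble(district_id = g$district_id,
                        period_ym = g$period_ym,
                        pred_onset = g$yhat >= u & g$nxt >= u & prev <= l)
  attr(out, "n_unevaluable") <-
    nrow(pred) - nrow(out)
  out
}

#' Precision-recall sweep over the dual-threshold grid
#'
#' Evaluates the outbreak classifier over a grid of thresholds l <= u (each
#' running from 1 to 5 in steps of `step`), computing precision and recall
#' against the labelled onsets on the evaluable (district, period) points.
#' Grid points with no predicted positives are skipped. The Pareto front is
#' the set of non-dominated (precision, recall) points; the AUC is the
#' trapezoidal area under the front, extended left of the smallest-recall
#' front point at constant precision and contributing nothing beyond the
#' largest achieved recall.
#'
#' @param pred tibble `district_id`, `period_ym`, `yhat`
#' @param labels a [label_outbreaks()] table (truth)
#' @param step threshold grid step (default 0.01; 0.001 reproduces the
#'   reference grid at ~8M threshold pairs)
#' @return `cc_prcurve`: list with `points` (tibble `l`, `u`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `on_front`), `front`, `auc`, `n_outbreaks`
#' @export
pr_sweep <- function(pred, labels, step = 0.01) {
  stopifnot(step > 0)
  g <- onset_triples(pred, labels)
  n_pos <- sum(g$onset)
  if (n_pos == 0) stop("no labelled outbreaks among evaluable observations")
  thr <- seq(1, 5, by = step)
  nt <- length(thr)
  # s = min(yhat_t, yhat_{t+1}): predicted positive iff s >= u and prev <= l.
  # Bin s and prev onto the grid: s >= thr[ui]  <=>  sbin >= ui where sbin is
  # the number of grid values <= s; prev <= thr[li] <=> rbin <= li where rbin
  # is the index of the smallest grid value >= prev (nt+1 when none).
  s <- pmin(g$yhat, g$nxt)
  sbin <- findInterval(s, thr)                      # 0..nt
  rbin <- nt + 1L - findInterval(-g$prev, rev(-thr))  # 1..nt+1
  count_grid <- function(sel) {
    m <- matrix(0, nt + 1L, nt + 2L)  # rows sbin 0..nt, cols rbin 1..nt+2
    tab <- table(sbin[sel] + 1L, rbin[sel])
    m[cbind(as.integer(rownames(tab))[row(tab)],
            as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
    # cum[s, r] = # obs with sbin >= s and rbin <= r
    cum <- apply(m, 2, function(col) rev(cumsum(rev(col))))
    t(apply(cum, 1, cumsum))
  }
  cum_pos <- count_grid(g$onset)
  cum_all <- count_grid(rep(TRUE, nrow(g)))
  ui <- rep(seq_len(nt), times = nt)
  li <- rep(seq_len(nt), each = nt)
  keep <- li <= ui
  ui <- ui[keep]; li <- li[keep]
  tp <- cum_pos[cbind(ui + 1L, li)]
  pp <- cum_all[cbind(ui + 1L, li)]
  nz <- pp > 0
  tpz <- tp[nz]; ppz <- pp[nz]
  pts <- tibble::tibble(l = thr[li[nz]], u = thr[ui[nz]],
                        tp = tpz, fp = ppz - tpz,
                        fn = n_pos - tpz,
                        precision = tpz / ppz,
                        recall = tpz / n_pos)
  if (nrow(pts) == 0) stop("no threshold pair yields a predicted positive")
  pts$on_front <- pareto_front_flag(pts$precision, pts$recall)
  front <- dplyr::distinct(pts[pts$on_front, ], .data$precision,
                           .data$recall, .keep_all = TRUE)
  front <- dplyr::arrange(front, .data$recall, .data$precision)
  structure(list(points = pts, front = front,
                 auc = pr_front_auc(front$recall, front$precision),
                 n_outbreaks = n_pos),
            class = "cc_prcurve")
}

# TRUE for points not dominated by any other (precision, recall) point
# (dominated: another point is >= in both coordinates and > in one)
pareto_front_flag <- function(precision, recall) {
  up <- tapply(precision, recall, max)        # best precision per recall
  ur <- as.numeric(names(up))
  ord <- order(-ur)                           # recall descending
  upo <- as.numeric(up)[ord]
  prevmax <- cummax(upo)
  keep <- c(TRUE, upo[-1] > prevmax[-length(upo)])
  fr <- ur[ord][keep]; fp <- upo[keep]
  paste(recall, precision) %in% paste(fr, fp)
}

# trapezoidal area under the front: constant extension from recall 0 to the
# first point; zero contribution beyond the largest achieved recall
pr_front_auc <- function(recall, precision) {
  ord <- order(recall)
  r <- recall[ord]; p <- precision[ord]
  r <- c(0, r); p <- c(p[1], p)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Best recall on the Pareto front at a precision floor
#'
#' @param curve a [pr_sweep()] result
#' @param target precision floor (e.g. 0.8)
#' @return list with `recall`, `l`, `u`, `precision`, `attainable`
#' @export
recall_at_precision <- function(curve, target) {
  stopifnot(inherits(curve, "cc_prcurve"))
  f <- curve$front[curve$front$precision >= target, ]
  if (nrow(f) == 0) {
    return(list(recall = NA_real_, l = NA_real_, u = NA_real_,
                precision = NA_real_, attainable = FALSE))
  }
  i <- which.max(f$recall)
  list(recall = f$recall[i], l = f$l[i], u = f$u[i],
       precision = f$precision[i], attainable = TRUE)
}

# truncated autocovariances of a series around its mean, lags 0..m
autocov_truncated <- function(x, m) {
  n <- length(x)
  mu <- mean(x)
  vapply(0:m, function(k)
    sum((x[(k + 1):n] - mu) * (x[1:(n - k)] - mu)) / n, numeric(1))
}

dm_truncation_lag <- function(n) floor(n^(1/3)) + 1L

#' Diebold-Mariano test of equal forecast accuracy
#'
#' Tests the squared-error loss differential d_i = e_{a,i}^2 - e_{b,i}^2
#' pooled across test periods, with the serial-correlation-robust variance
#' using truncated autocovariances up to lag floor(n^(1/3)) + 1, against a
#' two-sided normal reference. Identical error vectors give statistic 0 and
#' p-value 1.
#'
#' @param errors_a,errors_b equal-length paired forecast-error vectors
#' @return `cc_dm`: list with `statistic`, `p_value`, `mean_diff`, `n`,
#'   `small_sample` (flag when n < 10)
#' @export
dm_test <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) == length(errors_b))
  n <- length(errors_a)
  d <- errors_a^2 - errors_b^2
  m <- dm_truncation_lag(n)
  gam <- autocov_truncated(d, min(m, n - 1))
  v <- (gam[1] + 2 * sum(gam[-1])) / n
  stat <- if (v <= 0) {
    if (abs(mean(d)) < 1e-15) 0 else sign(mean(d)) * Inf
  } else mean(d) / sqrt(v)
  structure(list(statistic = stat,
                 p_value = 2 * stats::pnorm(-abs(stat)),
                 mean_diff = mean(d), n = n, small_sample = n < 10),
            class = "cc_dm")
}

#' Serial-correlation-corrected RMSE confidence interval
#'
#' From pooled forecast errors: the mean squared error m, its truncated
#' autocovariances gamma_k (k up to floor(n^(1/3)) + 1), the variance term
#' sigma^2 = (gamma_0 + 2 sum_k gamma_k) / n, and the 95% interval
#' m +/- 1.96 sigma, reported on both the squared and the root scale. A
#' negative truncated variance estimate is clamped at 0 and flagged.
#'
#' @param errors forecast-error vector (n >= 2)
#' @return list with `mse`, `rmse`, `gamma` (lags 0..m), `sigma`,
#'   `ci_mse`, `ci_rmse`, `clamped`
#' @export
rmse_ci <- function(errors) {
  n <- length(errors)
  stopifnot(n >= 2)
  e2 <- errors^2
  m <- dm_truncation_lag(n)
  gam <- autocov_truncated(e2, min(m, n - 1))
  v <- (gam[1] + 2 * sum(gam[-1])) / n
  clamped <- v < 0
  if (clamped) v <- 0
  sigma <- sqrt(v)
  mse <- mean(e2)
  ci_mse <- c(mse - 1.96 * sigma, mse + 1.96 * sigma)
  list(mse = mse, rmse = sqrt(mse), gamma = gam, sigma = sigma,
       ci_mse = ci_mse, ci_rmse = sqrt(pmax(ci_mse, 0)), clamped = clamped)
}

#' Percent change between a baseline and a new value
#'
#' 100 (base - new) / base: positive when the new value improves (reduces)
#' the baseline, negative when it deteriorates it. Rounding to whole percent
#' is left to the reporting layer.
#'
#' @param base baseline value (> 0)
#' @param new new value
#' @return percent change
#' @examples
#' percent_change(0.1486, 0.0819)  # ~ 44.9
#' @export
percent_change <- function(base, new) {
  if (any(base <= 0)) stop("percent change undefined for base <= 0")
  100 * (base - new) / base
}
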