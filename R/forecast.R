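# internal: (unit, ym, value) long table -> unit x month matrix
panel_matrix <- function(tbl, units, months, value_col = "value",
                         unit_col = "unit_id") {
  m <- matrix(NA_real_, length(units), length(months),
              dimnames = list(units, as.character(months)))
  idx <- cbind(match(tbl[[unit_col]], units), match(tbl$ym, months))
  keep <- stats::complete.cases(idx)
  m[idx[keep, , drop = FALSE]] <- tbl[[value_col]][keep]
  m
}

#' Assemble the lagged forecasting design
#'
#' One row per (district, reporting period) holding: six period-lags of the
#' IPC phase; the five time-invariant district attributes; six monthly lags
#' of each time-varying traditional factor at district, province and country
#' level (province/country values are the means over member districts); and,
#' for the news/combined variants, six monthly lags of each retained news
#' factor at the three levels. All time-varying lags end `horizon_months`
#' before the target period's end month (months t - horizon - 0..5), so no
#' regressor is more recent than t - horizon; rows lacking full lag history
#' are dropped and counted. With nine factors the traditional block has
#' 9 x 3 x 6 + 5 = 167 columns; the news block adds |w| x 3 x 6.
#'
#' @param ipc tibble `district_id`, `period_ym`, `phase`
#' @param trad a `cc_factors` object (ignored under `variant = "news"`)
#' @param news a `cc_news_panel` of the retained features (ignored under
#'   `variant = "traditional"`)
#' @param world a [gen_world()] object
#' @param variant "traditional", "news" or "combined"
#' @param horizon_months forecast horizon (minimum regressor age), default 3
#' @param n_y_lags period-lags of the phase (default 6)
#' @param n_m_lags monthly lags of each factor (default 6)
#' @param expert optional tibble `district_id`, `period_ym`, `forecast`: an
#'   expert forecast of the target period's phase, entering as one extra
#'   regressor column
#' @return tibble `district_id`, `period_ym`, `y`, then predictor columns; of
#'   class `cc_design`, with attributes `predictors`, `lag_month_offsets`,
#'   `horizon`, `variant`, `n_dropped`
#' @export
build_design <- function(ipc, trad, news, world,
                         variant = c("combined", "traditional", "news"),
                         horizon_months = 3, n_y_lags = 6, n_m_lags = 6,
                         expert = NULL) {
  variant <- match.arg(variant)
  geo <- world$geo
  districts <- sort(intersect(geo$district_id, ipc$district_id))
  y <- ipc_matrix(ipc)
  y <- y[districts, , drop = FALSE]
  periods <- as.integer(colnames(y))
  P <- length(periods)
  rows_d <- rep(seq_along(districts), times = P)
  rows_t <- rep(seq_len(P), each = length(districts))
  base <- tibble::tibble(district_id = districts[rows_d],
                         period_ym = periods[rows_t],
                         y = y[cbind(rows_d, rows_t)])
  cols <- list()
  offsets <- integer()

  for (j in seq_len(n_y_lags)) {
    lag_t <- rows_t - j
    v <- rep(NA_real_, nrow(base))
    ok <- lag_t >= 1
    v[ok] <- y[cbind(rows_d[ok], lag_t[ok])]
    cols[[paste0("ylag", j)]] <- v
  }

  unit_of <- list(district = geo$district_id[match(districts,
                                                  geo$district_id)],
                  province = geo$province_id[match(districts,
                                                  geo$district_id)],
                  country = geo$country_id[match(districts, geo$district_id)])

  add_block <- function(mat_by_level, prefix) {
    for (lev in names(mat_by_level)) {
      m <- mat_by_level[[lev]]
      months <- as.integer(colnames(m))
      ui <- match(unit_of[[lev]], rownames(m))
      for (n in seq_len(n_m_lags)) {
        off <- horizon_months + n - 1L
        mi <- match(base$period_ym - off, months)
        nm <- sprintf("%s_%s_lag%d", prefix, substr(lev, 1, 1), n)
        cols[[nm]] <<- m[cbind(ui[rows_d], mi)]
        offsets[[nm]] <<- off
      }
    }
  }

  if (variant %in% c("combined", "traditional")) {
    tv <- trad$time_varying
    names(tv)[names(tv) == "district_id"] <- "unit_id"
    tv <- dplyr::left_join(tv,
                           dplyr::select(geo, unit_id = "district_id",
                                         "province_id", "country_id"),
                           by = "unit_id")
    months <- sort(unique(tv$ym))
    for (k in sort(unique(tv$factor))) {
      tk <- tv[tv$factor == k, ]
      dmat <- panel_matrix(tk, districts, months)
      pk <- dplyr::summarise(dplyr::group_by(tk, unit_id = .data$province_id,
                                             .data$ym),
                             value = mean(.data$value), .groups = "drop")
      ck <- dplyr::summarise(dplyr::group_by(tk, unit_id = .data$country_id,
                                             .data$ym),
                             value = mean(.data$value), .groups = "drop")
      add_block(list(district = dmat,
                     province = panel_matrix(pk, unique(geo$province_id),
                                             months),
                     country = panel_matrix(ck, unique(geo$country_id),
                                            months)),
                prefix = paste0("v_", k))
    }
    st <- trad$static
    for (a in sort(unique(st$attr))) {
      sa <- st[st$attr == a, ]
      cols[[paste0("s_", a)]] <- sa$value[match(base$district_id,
                                                sa$district_id)]
    }
  }

  if (variant %in% c("combined", "news")) {
    feats <- sort(unique(news$feature))
    if (length(feats) == 0) {
      stop("configuration error: empty retained-feature list under variant '",
           variant, "'")
    }
    months <- sort(unique(news$ym))
    for (w in feats) {
      nw <- news[news$feature == w, ]
      mats <- lapply(c(district = "district", province = "province",
                       country = "country"), function(lev) {
        sub <- nw[nw$level == lev, ]
        units <- switch(lev, district = districts,
                        province = unique(geo$province_id),
                        country = unique(geo$country_id))
        panel_matrix(sub, units, months)
      })
      add_block(mats, prefix = paste0("x_", gsub("[^a-z0-9]+", "_", w)))
    }
  }

  if (!is.null(expert)) {
    cols[["expert_forecast"]] <- expert$forecast[
      match(paste(base$district_id, base$period_ym),
            paste(expert$district_id, expert$period_ym))]
  }

  design <- dplyr::bind_cols(base, tibble::as_tibble(cols))
  ok <- stats::complete.cases(design)
  n_dropped <- sum(!ok)
  design <- design[ok, ]
  structure(design,
            class = c("cc_design", class(tibble::tibble())),
            predictors = names(cols), lag_month_offsets = offsets,
            horizon = horizon_months, variant = variant,
            n_dropped = n_dropped)
}

#' Build a temporal cross-validation fold plan
#'
#' Splits the reporting periods after a burn-in into `n_folds` contiguous,
#' disjoint, ordered test windows; each fold's validation window is the
#' `val_periods` periods immediately before its test window, and its training
#' range is every period before the validation window.
#'
#' @param periods sorted reporting-period end months (or a `cc_world`)
#' @param n_folds number of folds (default 10)
#' @param val_periods validation window length in periods (default 2)
#' @param test_periods test window length in periods; default: as large as
#'   fits after a minimum burn-in of `min_burn` periods
#' @param min_burn minimum number of burn-in periods (default 10: six phase
#'   lags plus validation room)
#' @return `cc_folds` tibble: `fold`, `train_end`, `val_start`, `val_end`,
#'   `test_start`, `test_end` (period end months)
#' @export
make_folds <- function(periods, n_folds = 10, val_periods = 2,
                       test_periods = NULL, min_burn = 10) {
  if (inherits(periods, "cc_world")) periods <- periods$period_ends
  periods <- sort(unique(periods))
  P <- length(periods)
  if (is.null(test_periods)) {
    test_periods <- (P - min_burn) %/% n_folds
  }
  if (test_periods < 1) {
    stop("configuration error: ", P, " periods cannot hold ", n_folds,
         " folds after a burn-in of ", min_burn,
         " (need at least ", min_burn + n_folds, ")")
  }
  burn <- P - n_folds * test_periods
  if (burn < val_periods + 1) {
    stop("configuration error: burn-in of ", burn,
         " periods leaves no training data before the first validation window")
  }
  out <- purrr::map_dfr(seq_len(n_folds), function(f) {
    ts <- burn + (f - 1) * test_periods + 1
    te <- ts + test_periods - 1
    vs <- ts - val_periods
    tibble::tibble(fold = f,
                   train_end = periods[vs - 1],
                   val_start = periods[vs], val_end = periods[ts - 1],
                   test_start = periods[ts], test_end = periods[te])
  })
  class(out) <- c("cc_folds", class(out))
  out
}

#' Default random-forest hyperparameter grid
#'
#' The full tuning grid: number of trees 10..100 by 10; minimum node size to
#' split 0.1 and 0.5 (fractions of the training set), 1, 2, 3, 4, 5; and
#' mtry rule "auto" (all predictors, the historical regression default),
#' "sqrt" or "log2". (An impurity-decrease threshold is not part of the grid:
#' ranger, the forest implementation used here, has no such stopping rule.)
#'
#' @return tibble with columns `n_estimators`, `min_samples_split`,
#'   `max_features`
#' @export
default_rf_grid <- function() {
  tidyr::expand_grid(n_estimators = seq(10L, 100L, 10L),
                     min_samples_split = c(0.1, 0.5, 1, 2, 3, 4, 5),
                     max_features = c("auto", "sqrt", "log2"))
}

# a small grid for quick runs
small_rf_grid <- function() {
  tidyr::expand_grid(n_estimators = c(50L, 100L),
                     min_samples_split = c(2, 5),
                     max_features = c("auto", "sqrt"))
}

rf_params <- function(row, n_train, n_pred) {
  mss <- row$min_samples_split
  min_node <- if (mss < 1) max(2L, ceiling(mss * n_train)) else
    max(1L, as.integer(mss))
  mtry <- switch(as.character(row$max_features),
                 auto = n_pred,
                 sqrt = max(1L, floor(sqrt(n_pred))),
                 log2 = max(1L, floor(log2(n_pred))))
  list(num.trees = row$n_estimators, min.node.size = min_node, mtry = mtry)
}

#' Fit and predict under temporal cross-validation
#'
#' For each fold: every hyperparameter combination is fit on the training
#' range and scored on the validation window (RMSE); the winner is refit on
#' training + validation and predicts the test window. The overall RMSE is
#' the unweighted mean of the per-fold test RMSEs. Fixed `seed` gives
#' bit-identical predictions (single-threaded forests).
#'
#' @param design a [build_design()] table
#' @param folds a [make_folds()] plan
#' @param grid hyperparameter grid (see [default_rf_grid()]); the full grid
#'   is expensive, [small_rf_grid()] style subsets are adequate for small
#'   scenarios
#' @param seed integer seed
#' @return `cc_forecast`: list with `predictions` (tibble `district_id`,
#'   `period_ym`, `y`, `yhat`, `fold`), `cv_report` (per-fold winners and
#'   RMSEs), `rmse` (unweighted mean of fold test RMSEs), `variant`
#' @export
fit_predict <- function(design, folds, grid = small_rf_grid(), seed = 1L) {
  stopifnot(inherits(design, "cc_design"), inherits(folds, "cc_folds"))
  preds_cols <- attr(design, "predictors")
  X <- as.matrix(design[, preds_cols, drop = FALSE])
  yv <- design$y
  per_fold <- vector("list", nrow(folds))
  cv_report <- vector("list", nrow(folds))
  for (f in seq_len(nrow(folds))) {
    fd <- folds[f, ]
    tr <- design$period_ym <= fd$train_end
    va <- design$period_ym >= fd$val_start & design$period_ym <= fd$val_end
    te <- design$period_ym >= fd$test_start & design$period_ym <= fd$test_end
    if (!any(te)) {
      cv_report[[f]] <- tibble::tibble(fold = fd$fold, skipped = TRUE)
      next
    }
    val_rmse <- rep(NA_real_, nrow(grid))
    for (g in seq_len(nrow(grid))) {
      par <- rf_params(grid[g, ], sum(tr), ncol(X))
      fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = yv[tr],
                            num.trees = par$num.trees, mtry = par$mtry,
                            min.node.size = par$min.node.size,
                            seed = seed * 1000L + f * 37L + g,
                            num.threads = 1)
      pv <- stats::predict(fit, X[va, , drop = FALSE],
                           num.threads = 1)$predictions
      val_rmse[g] <- rmse(pv - yv[va])
    }
    best <- which.min(val_rmse)
    par <- rf_params(grid[best, ], sum(tr | va), ncol(X))
    refit <- ranger::ranger(x = X[tr | va, , drop = FALSE], y = yv[tr | va],
                            num.trees = par$num.trees, mtry = par$mtry,
                            min.node.size = par$min.node.size,
                            seed = seed * 1000L + f * 37L, num.threads = 1)
    yhat <- stats::predict(refit, X[te, , drop = FALSE],
                           num.threads = 1)$predictions
    per_fold[[f]] <- tibble::tibble(district_id = design$district_id[te],
                                    period_ym = design$period_ym[te],
                                    y = yv[te], yhat = yhat, fold = fd$fold)
    cv_report[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = fd$fold, skipped = FALSE,
                     n_train = sum(tr), n_val = sum(va), n_test = sum(te),
                     val_rmse = val_rmse[best],
                     test_rmse = rmse(yhat - yv[te])),
      grid[best, ])
  }
  predictions <- dplyr::bind_rows(per_fold)
  cv_report <- dplyr::bind_rows(cv_report)
  structure(list(predictions = predictions, cv_report = cv_report,
                 rmse = mean(cv_report$test_rmse[!cv_report$skipped]),
                 variant = attr(design, "variant")),
            class = "cc_forecast")
}

#' Root mean square error
#'
#' @param errors numeric vector of forecast errors (non-empty)
#' @return sqrt of the mean squared error
#' @export
rmse <- function(errors) {
  if (length(errors) == 0) stop("rmse undefined for an empty error vector")
  sqrt(mean(errors^2))
}

#' Assert the anti-leakage properties of a design and fold plan
#'
#' Checks that every time-varying regressor column of the design is lagged by
#' at least the forecast horizon, that phase lags refer to strictly earlier
#' periods, and that every fold satisfies train < validation < test with
#' disjoint, ordered test windows.
#'
#' @param design a [build_design()] table
#' @param folds an optional [make_folds()] plan
#' @return TRUE invisibly; errors describing the first violation otherwise
#' @export
assert_no_leakage <- function(design, folds = NULL) {
  offs <- attr(design, "lag_month_offsets")
  h <- attr(design, "horizon")
  if (length(offs) && any(offs < h)) {
    stop("leakage: column(s) ", paste(names(offs)[offs < h], collapse = ", "),
         " lagged less than the horizon")
  }
  if (!is.null(folds)) {
    if (!all(folds$train_end < folds$val_start &
               folds$val_start <= folds$val_end &
               folds$val_end < folds$test_start &
               folds$test_start <= folds$test_end)) {
      stop("leakage: a fold violates train < validation < test ordering")
    }
    if (nrow(folds) > 1 &&
        !all(utils::head(folds$test_end, -1) < folds$test_start[-1])) {
      stop("leakage: test windows overlap or are out of order")
    }
  }
  invisible(TRUE)
}

#' Compare two forecasts on their common observations
#'
#' Intersects the two prediction sets on (district, period), recomputes both
#' pooled RMSEs on the shared rows, runs the Diebold-Mariano test on the
#' paired squared-error loss differential (observations ordered by period),
#' and reports the percent RMSE change.
#'
#' @param a,b `cc_forecast` objects (or their `predictions` tibbles)
#' @return list with `n`, `rmse_a`, `rmse_b`, `pct_change` (positive when `b`
#'   improves on `a`), and `dm` (a [dm_test()] result)
#' @export
compare_forecasts <- function(a, b) {
  pa <- if (inherits(a, "cc_forecast")) a$predictions else a
  pb <- if (inherits(b, "cc_forecast")) b$predictions else b
  j <- dplyr::inner_join(pa, pb, by = c("district_id", "period_ym"),
                         suffix = c("_a", "_b"))
  j <- dplyr::arrange(j, .data$period_ym, .data$district_id)
  stopifnot(nrow(j) <= nrow(pa), nrow(j) <= nrow(pb))
  ea <- j$y_a - j$yhat_a
  eb <- j$y_a - j$yhat_b
  list(n = nrow(j), rmse_a = rmse(ea), rmse_b = rmse(eb),
       pct_change = percent_change(rmse(ea), rmse(eb)),
       dm = dm_test(ea, eb))
}
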