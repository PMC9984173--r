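mk_ipc <- function(...) {
  series <- list(...)
  dplyr::bind_rows(lapply(seq_along(series), function(i)
    tibble::tibble(district_id = paste0("d", i),
                   period_ym = seq_along(series[[i]]),
                   phase = series[[i]])))
}

test_that("outbreak labelling follows the two-consecutive-period definition", {
  lab <- label_outbreaks(mk_ipc(c(2, 2, 3, 3, 2)))
  expect_equal(which(lab$onset), 3)
  expect_false(lab$severe[3])
  expect_equal(lab$duration[3], 2)

  # never two consecutive phases >= 3: no onset
  expect_false(any(label_outbreaks(mk_ipc(c(2, 3, 2, 3, 2)))$onset))

  # escalation to phase 4 marks the episode severe
  lab3 <- label_outbreaks(mk_ipc(c(2, 3, 4, 3, 1)))
  expect_equal(which(lab3$onset), 2)
  expect_true(lab3$severe[2])
  expect_equal(lab3$duration[2], 3)

  # series-initial and series-final periods can never be onsets
  lab4 <- label_outbreaks(mk_ipc(c(3, 3, 2, 2, 3)))
  expect_false(any(lab4$onset))
})

test_that("threshold classification reproduces labelling on integer truth", {
  set.seed(61)
  ipc <- tidyr::expand_grid(district_id = paste0("d", 1:6), period_ym = 1:12)
  ipc$phase <- sample(1:5, nrow(ipc), replace = TRUE,
                      prob = c(.4, .3, .15, .1, .05))
  lab <- label_outbreaks(ipc)
  pred <- tibble::tibble(district_id = ipc$district_id,
                         period_ym = ipc$period_ym, yhat = ipc$phase)
  cls <- classify_outbreaks(pred, l = 2, u = 3)
  merged <- dplyr::inner_join(cls, lab, by = c("district_id", "period_ym"))
  expect_equal(merged$pred_onset, merged$onset)
  # u above the phase range -> nothing predicted
  none <- classify_outbreaks(pred, l = 2, u = 5.01)
  expect_false(any(none$pred_onset))
  expect_error(classify_outbreaks(pred, l = 3, u = 2))
  # observed-prior variant: with yhat == phase both readings coincide
  obs_var <- classify_outbreaks(pred, l = 2, u = 3, observed = ipc)
  expect_equal(obs_var$pred_onset, cls$pred_onset)
  # and diverges when the prediction overshoots the prior period
  pred2 <- pred
  pred2$yhat[pred2$period_ym == 1] <- 5
  base2 <- classify_outbreaks(pred2, l = 2, u = 3)
  obs2 <- classify_outbreaks(pred2, l = 2, u = 3, observed = ipc)
  t2 <- base2$period_ym == 2
  expect_false(any(base2$pred_onset[t2]))  # predicted prior 5 blocks onsets
  expect_equal(obs2$pred_onset[t2], cls$pred_onset[cls$period_ym == 2])
})

test_that("the sweep matches exhaustive per-threshold evaluation", {
  set.seed(67)
  ipc <- tidyr::expand_grid(district_id = paste0("d", 1:5), period_ym = 1:10)
  ipc$phase <- sample(1:5, nrow(ipc), replace = TRUE,
                      prob = c(.3, .3, .2, .15, .05))
  lab <- label_outbreaks(ipc)
  expect_gt(sum(lab$onset), 0)
  pred <- tibble::tibble(district_id = ipc$district_id,
                         period_ym = ipc$period_ym,
                         yhat = ipc$phase + rnorm(nrow(ipc), 0, 0.4))
  pr <- pr_sweep(pred, lab, step = 0.25)
  oracle <- oracle_sweep(pred, lab, seq(1, 5, by = 0.25))
  expect_equal(nrow(pr$points), nrow(oracle))
  merged <- merge(as.data.frame(pr$points), oracle, by = c("l", "u"))
  expect_equal(merged$tp.x, merged$tp.y)
  expect_equal(merged$fp.x, merged$fp.y)
  expect_equal(merged$fn.x, merged$fn.y)
  # front is non-dominated
  f <- pr$front
  for (i in seq_len(nrow(f))) {
    dominated <- any(pr$points$precision >= f$precision[i] &
                       pr$points$recall >= f$recall[i] &
                       (pr$points$precision > f$precision[i] |
                          pr$points$recall > f$recall[i]))
    expect_false(dominated)
  }
  # halving the step cannot change the front once all confusion matrices
  # are resolved (predictions here sit on a 0.05 lattice after rounding)
  pred2 <- pred
  pred2$yhat <- round(pred2$yhat * 4) / 4
  a <- pr_sweep(pred2, lab, step = 0.25)
  b <- pr_sweep(pred2, lab, step = 0.125)
  expect_equal(a$auc, b$auc)
  expect_equal(dplyr::distinct(a$front[, c("precision", "recall")]),
               dplyr::distinct(b$front[, c("precision", "recall")]))
})

test_that("sweep edge cases are signalled", {
  ipc <- mk_ipc(c(2, 2, 3, 3, 2))
  lab <- label_outbreaks(ipc)
  perfect <- tibble::tibble(district_id = ipc$district_id,
                            period_ym = ipc$period_ym, yhat = ipc$phase)
  pr <- pr_sweep(perfect, lab, step = 0.5)
  expect_true(any(pr$front$precision == 1 & pr$front$recall == 1))
  expect_equal(pr$auc, 1)
  # constant predictor at 1: no predicted positives anywhere
  flat <- perfect; flat$yhat <- 0.9
  expect_error(pr_sweep(flat, lab, step = 0.5), "no threshold pair")
  # no labelled outbreaks
  calm <- mk_ipc(c(1, 1, 1, 1, 1))
  expect_error(pr_sweep(perfect, label_outbreaks(calm), step = 0.5),
               "no labelled outbreaks")
})

test_that("recall at a precision floor selects from the front", {
  curve <- structure(list(front = tibble::tibble(
    l = c(2, 2.2, 2.4), u = c(3.4, 3.2, 3.0),
    precision = c(0.9, 0.8, 0.7), recall = c(0.4, 0.6, 0.8))),
    class = "cc_prcurve")
  at80 <- recall_at_precision(curve, 0.8)
  expect_equal(at80$recall, 0.6)
  expect_equal(c(at80$l, at80$u), c(2.2, 3.2))
  expect_equal(recall_at_precision(curve, 0)$recall, 0.8)
  expect_false(recall_at_precision(curve, 0.95)$attainable)
})

test_that("the DM statistic matches a direct formula transcription", {
  set.seed(13)
  ea <- rnorm(50); eb <- rnorm(50, 0, 1.3)
  got <- dm_test(ea, eb)
  want <- oracle_dm(ea, eb)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  # identical errors: statistic 0, p-value 1
  same <- dm_test(ea, ea)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry
  expect_equal(dm_test(eb, ea)$statistic, -got$statistic, tolerance = 1e-12)
  expect_true(dm_test(rnorm(5), rnorm(5))$small_sample)
})

test_that("DM test holds its size on equal-accuracy forecasts", {
  set.seed(71)
  rej <- vapply(1:1000, function(i) {
    ea <- rnorm(200); eb <- rnorm(200)
    dm_test(ea, eb)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("the RMSE confidence interval matches direct summation", {
  set.seed(2)
  e <- rnorm(40)
  got <- rmse_ci(e)
  want <- oracle_rmse_ci(e)
  expect_equal(got$gamma[2], want$gamma[2], tolerance = 1e-12)
  expect_equal(got$sigma, want$sigma, tolerance = 1e-12)
  expect_equal(got$ci_mse, want$ci, tolerance = 1e-12)
  expect_true(got$ci_mse[1] <= got$mse && got$mse <= got$ci_mse[2])
  # constant |errors|: all autocovariances vanish, zero-width interval
  flat <- rmse_ci(c(1, -1, 1, -1))
  expect_equal(flat$gamma, rep(0, length(flat$gamma)))
  expect_equal(flat$ci_mse, c(1, 1))
})

test_that("percent change reproduces the published arithmetic", {
  expect_equal(percent_change(0.1486, 0.0819), 44.9, tolerance = 0.05)
  expect_equal(round(percent_change(0.1486, 0.0819)), 45)
  expect_equal(percent_change(0.0819, 0.1137), -38.8, tolerance = 0.05)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "undefined")
})
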