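test_that("direction-selective neurons are recognized and non-DS rejected", {
  pas <- fix_passive()
  cl <- classify_ds(pas)
  is_min_truth <- cl$label %in% c("Min_left", "Min_right")
  expect_gte(mean(cl$is_min[is_min_truth]), 0.8)     # sensitivity
  expect_lte(mean(cl$is_min[cl$label == "other"]), 0.1) # false positives
  # preferences match the planted direction
  got <- cl[cl$is_min & is_min_truth, ]
  expect_true(all(got$preferred_dir ==
                    ifelse(got$label == "Min_left", "left", "right")))
  # Tin-labeled neurons are excluded regardless of their response
  expect_true(all(!cl$is_min[cl$label %in% c("Tin_con", "Tin_ips")]))
  expect_error(classify_ds(fix_session()), "passive")
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  set.seed(51)
  x <- rpois(80, 4); y <- rpois(60, 3)
  expect_equal(dvtrace:::auc_rank(x, y),
               auc_left_right(c(x, y), c(rep(TRUE, 80), rep(FALSE, 60))),
               tolerance = 1e-12)
})

test_that("CUSUM latency recovers planted onsets within one bin", {
  for (lat in c(0.08, 0.1, 0.15)) {
    ses <- make_planted_ds_session(n_trials = 400, latency = lat,
                                   seed = round(lat * 1000),
                                   kind = "decision")
    est <- cusum_latency(ses, neuron_id = 1)
    expect_lt(abs(est$latency_s - lat), 0.025)
    expect_false(est$degenerate)
    expect_gt(est$slope, 0) # left-preferring: positive CUSUM slope
  }
})

test_that("CUSUM is difference-based and flags degenerate input", {
  ses <- make_planted_ds_session(n_trials = 300, latency = 0.1, seed = 5,
                                 kind = "decision", baseline = 10)
  ses2 <- make_planted_ds_session(n_trials = 300, latency = 0.1, seed = 5,
                                  kind = "decision", baseline = 20)
  e1 <- cusum_latency(ses, 1); e2 <- cusum_latency(ses2, 1)
  expect_lt(abs(e1$latency_s - e2$latency_s), 0.05)
  # a non-selective neuron gives a (noise-dominated) flat CUSUM
  e3 <- cusum_latency(ses, 3)
  expect_gt(abs(e3$latency_s - 0.1), 0) # no planted structure to recover
  expect_error(cusum_latency(ses[c("trials", "spikes", "neurons")], 1))
})

test_that("Min->Tin coupling is detected only when planted", {
  xc <- min_tin_xcorr(acc_session(), n_shuffle = 100, seed = 1)
  expect_gt(xc$z, 3)
  uncoupled <- fixture("uncoupled_xc", function() {
    generate_decision_session(population_config(n_neurons = 60,
                                                min_coupled = FALSE),
                              params_m(), n_trials = 1200, seed = 62)
  })
  xu <- min_tin_xcorr(uncoupled, n_shuffle = 100, seed = 1)
  expect_lt(abs(xu$z), 2.5)
  # under integration, correlation is roughly flat across long lags
  lag <- outer(xc$tx, xc$ty, function(a, b) b - a)
  sel <- lag > 0.1 & lag <= 0.25 &
    matrix(xc$tx > 0.1, length(xc$tx), length(xc$ty)) &
    matrix(xc$ty > 0.2, length(xc$tx), length(xc$ty), byrow = TRUE)
  by_lag <- tapply(xc$r[sel], round(lag[sel] / 0.025), mean)
  expect_lt(diff(range(by_lag)), 0.06)
})

test_that("the Min direction signal correlates negatively with RT when coupled", {
  ps <- psi_rt_correlation(acc_session())
  expect_lt(ps$rho, 0)
  expect_lt(ps$p_value, 0.05)
})

test_that("Min leverage on choice stays flat while Tin leverage grows", {
  ses <- fix_session()
  lev_min <- min_leverage(ses, "Min_left")
  lev_tin <- leverage_behavior(project_signal(fix_rt25_std(), fix_tin()))
  tt <- leverage_times()
  use <- tt <= 0.5
  slope_min <- coef(lm(lev_min$beta1_norm[use] ~ tt[use]))[2]
  slope_tin <- coef(lm(lev_tin$beta1_norm[use] ~ tt[use]))[2]
  expect_lt(abs(slope_min), abs(slope_tin))
  expect_gt(slope_tin, 0)
})
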