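test_that("label assignment follows the configured fractions", {
  cfg <- population_config(n_neurons = 135)
  lab <- table(factor(generate_passive_session(cfg, n_trials = 60,
                                               seed = 1)$neurons$label,
                      levels = c("Tin_con", "Tin_ips", "Min_left",
                                 "Min_right", "other")))
  expected <- round(135 * c(0.145, 0.072, 0.042, 0.025))
  expect_true(all(abs(lab[1:4] - expected) <= 2))
  expect_error(population_config(n_neurons = 5), "n_neurons")
  expect_error(population_config(frac_tin_con = 0.9, frac_tin_ips = 0.5),
               "fractions")
})

test_that("correlated noise hits its target pairwise correlation", {
  set.seed(2)
  X <- correlated_noise(2e4, 12, r = 0.09)
  cm <- cor(X)
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.09), 0.015)
})

test_that("residual spike-count correlations match the shared-noise target", {
  ses <- fix_session()
  rt <- bin_and_smooth(ses, t_lim = c(0.3, 0.3), step = 0.2,
                       kernel = kernel_spec("boxcar", 200), censor = FALSE)
  cnt <- rt$rates[, , 1] * 0.2 # counts in the 200 ms window
  g <- ses$trials$signed_coh
  res <- t(apply(cnt, 1, function(x) demean_by(x, g)))
  cm <- suppressWarnings(cor(t(res)))
  r_bar <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  expect_lt(abs(r_bar - 0.09), 0.02)
})

test_that("without DV coupling, choice decoding collapses to chance", {
  cfg <- population_config(n_neurons = 40, dv_gain = 0, peri_gain = 0,
                           min_gain = 0)
  ses <- generate_decision_session(cfg, params_m(), n_trials = 1000,
                                   seed = 9)
  wd <- what_decoder(ses, bin_centers = c(0.275, 0.425))
  expect_true(all(abs(wd$accuracy - 0.5) < 0.05))
})

test_that("passive sessions plant direction selectivity at the set latency", {
  pas <- fix_passive()
  rt <- bin_and_smooth(pas, t_lim = c(-0.1875, 0.4875), step = 0.025,
                       kernel = kernel_spec("boxcar", 25), censor = FALSE)
  left <- pas$trials$signed_coh > 0
  lab <- pas$neurons$label
  tt <- rt$time
  win <- tt >= 0.15 & tt <= 0.5
  for (n in which(lab == "Min_left")) {
    m <- rt$rates[n, , ]
    expect_gt(mean(m[left, win]), mean(m[!left, win]))
  }
  # before 100 ms the directions are statistically indistinguishable
  pre <- tt >= 0 & tt < 0.0875
  for (n in which(lab %in% c("Min_left", "Min_right"))) {
    cl <- rowMeans(rt$rates[n, left, pre])
    cr <- rowMeans(rt$rates[n, !left, pre])
    expect_gt(stats::t.test(cl, cr)$p.value, 0.01)
  }
  # untuned neurons carry no direction information
  for (n in which(lab == "other")[1:10]) {
    cnt <- rowMeans(rt$rates[n, , win])
    expect_true(abs(auc_left_right(cnt, left) - 0.5) < 0.06)
  }
})

test_that("delayed-saccade sessions give Tin neurons spatial selectivity", {
  cfg <- population_config(n_neurons = 40)
  ds1 <- generate_delayed_saccade_session(cfg, n_per_loc = 40, seed = 11)
  lab <- ds1$neurons$label
  rt <- bin_and_smooth(ds1, t_lim = c(0.1, 0.5), step = 0.05, censor = FALSE)
  cnt <- apply(rt$rates, c(1, 2), mean)
  loc <- ds1$trials$target_loc
  for (n in which(lab == "Tin_con")) {
    a <- auc_left_right(cnt[n, ], loc == 1)
    expect_gt(a, 0.8)
  }
  for (n in which(lab == "other")[1:8]) {
    best <- max(vapply(1:8, function(l) auc_left_right(cnt[n, ], loc == l), 0))
    expect_lt(best, 0.72) # no systematic spatial tuning
  }
  # seeded determinism
  ds2 <- generate_delayed_saccade_session(cfg, n_per_loc = 40, seed = 11)
  expect_identical(ds1$spikes, ds2$spikes)
})

test_that("spiking is Poisson-like in fixed-rate segments", {
  ses <- fix_session()
  # pre-motion window: baseline + weak shared noise only
  rt <- bin_and_smooth(ses, t_lim = c(-0.15, -0.15), step = 0.2,
                       kernel = kernel_spec("boxcar", 200), censor = FALSE)
  cnt <- rt$rates[, , 1] * 0.2
  fano <- apply(cnt, 1, var) / rowMeans(cnt)
  other <- ses$neurons$label == "other"
  expect_true(mean(fano[other] > 0.8 & fano[other] < 1.25) > 0.9)
})

test_that("projected condition means are ordered by signed coherence", {
  cm <- condition_means(fix_sig_ramp())
  at45 <- cm[abs(cm$t - 0.45) < 0.013, ]
  expect_gt(cor(at45$signed_coh, at45$mean, method = "spearman"), 0.9)
})

test_that("coding directions recover the ground-truth coupling weights", {
  tw <- fix_session()$neurons$truth_weight
  expect_gt(cosine_similarity(fix_ramp()$weights, tw), 0.5)
  expect_gt(cosine_similarity(fix_pc1()$weights, tw), 0.5)
})
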