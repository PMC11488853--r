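test_that("ramp regression finds a planted sawtooth neuron", {
  # one neuron whose rate is an exact ramp over the decision epoch, among
  # pure-noise neurons: it should dominate the weights and fit the target
  set.seed(31)
  n_tr <- 120
  rt_s <- runif(n_tr, 0.6, 1.1)
  dt <- 0.001
  ids <- list(); times <- list(); trs <- list()
  n_neu <- 6
  for (i in seq_len(n_tr)) {
    tg <- seq(dt / 2, rt_s[i] + 0.1, by = dt)
    ramp <- pmin(pmax((tg - 0.2) / (rt_s[i] - 0.05 - 0.2), 0), 1)
    # planted neuron: regular spiking at an exact high-rate sawtooth, so its
    # binned rate is the target up to quantization
    cum <- cumsum((100 + 500 * ramp) * dt)
    t_plant <- tg[diff(c(0, floor(cum))) > 0]
    cnt <- matrix(rpois(length(tg) * (n_neu - 1), 30 * dt),
                  length(tg), n_neu - 1)
    nz <- which(cnt > 0, arr.ind = TRUE)
    reps <- cnt[nz]
    ids[[i]] <- c(rep(1L, length(t_plant)), rep(nz[, 2] + 1L, reps))
    times[[i]] <- c(t_plant, tg[rep(nz[, 1], reps)])
    trs[[i]] <- rep(i, length(t_plant) + sum(reps))
  }
  ses <- structure(list(
    trials = tibble::tibble(trial_id = seq_len(n_tr), signed_coh = 0,
                            choice = "left", rt_s = rt_s, motion_on_s = 0,
                            saccade_s = rt_s, correct = TRUE),
    spikes = tibble::tibble(neuron_id = unlist(ids), trial_id = unlist(trs),
                            t_s = unlist(times)),
    neurons = tibble::tibble(neuron_id = seq_len(n_neu),
                             label = c("Tin_con", rep("other", n_neu - 1)),
                             truth_weight = c(1, rep(0, n_neu - 1))),
    kind = "decision"), class = "dv_session")
  cd <- ramp_cd(ses)
  expect_equal(which.max(abs(cd$weights)), 1L)
  expect_gt(abs(cd$weights[1]) / max(abs(cd$weights[-1]) + 1e-12), 3)
  expect_gt(cd$training_meta$r2, 0.5)
  # regularized and unregularized solutions render near-identical signals
  cd0 <- ramp_cd(ses, lambda = 0)
  rt25 <- bin_and_smooth(ses, t_lim = c(0.2, 0.5), step = 0.025,
                         kernel = kernel_spec("boxcar", 25), censor = FALSE)
  s1 <- as.vector(project_signal(rt25, cd)$values)
  s0 <- as.vector(project_signal(rt25, cd0)$values)
  expect_gt(cor(s1, s0), 0.95)
  expect_error(ramp_cd(ses, min_samples = 1e6), "eligible")
})

test_that("PC1 behaves on rank-1 input and the PR closed form holds", {
  expect_equal(participation_ratio(rep(2.5, 7)), 7, tolerance = 1e-12)
  expect_equal(participation_ratio(c(1, 0, 0)), 1, tolerance = 1e-12)
  pc <- fix_pc1()
  ve <- pc$training_meta$var_explained
  expect_gt(ve[1], ve[2])
  expect_gt(pc$training_meta$participation_ratio, 1)
  # sign convention: projected means increase with leftward coherence
  sig <- project_signal(fix_rt25_std(), pc)
  cm <- condition_means(sig)
  at45 <- cm[abs(cm$t - 0.45) < 0.013, ]
  expect_gt(cor(at45$signed_coh, at45$mean), 0)
})

test_that("tin-average weights are 1/N on Tin_con and zero elsewhere", {
  ses <- fix_session()
  cd <- tin_mean_cd(ses)
  is_t <- ses$neurons$label == "Tin_con"
  expect_true(all(cd$weights[is_t] == 1 / sum(is_t)))
  expect_true(all(cd$weights[!is_t] == 0))
  expect_error(tin_mean_cd(ses, label = "nope"), "no neurons")
})

test_that("choice decoders generalize across training times", {
  ses <- fix_session()
  wd <- what_decoder(ses)
  k <- wd$train_times >= 0.3 & wd$train_times <= 0.5
  block <- wd$accuracy[k, k]
  # variation along columns (fixed test time, varying training time) is
  # smaller than along rows (fixed training time, varying test time)
  col_var <- mean(apply(block, 2, sd))
  row_var <- mean(apply(block, 1, sd))
  expect_lt(col_var, row_var)
  # strict train/test split: decoder at 0.45 was never shown odd trials
  expect_true(all(wd$accuracy >= 0.3 & wd$accuracy <= 1))
})

test_that("the simulated-DV ceiling decoder improves with test time", {
  sim <- fix_race_paths()
  cc <- dv_ceiling_decoder(sim$trials, t(sim$dv_left), sim$path_time + 0.2,
                           test_times = seq(0.25, 0.65, by = 0.1))
  expect_true(all(diff(cc$accuracy) > 0))
  expect_gt(max(cc$accuracy), 0.7)
})

test_that("when-decoder labels and validation follow the 150 ms rule", {
  starts <- seq(0, 0.375, by = 0.025)
  lab <- when_labels(starts, saccade_t = 0.4)
  expect_identical(lab, as.integer(starts >= 0.25))
  wh <- fixture("when", function() when_decoder(fix_session()))
  expect_gt(wh$auc$mean, 0.7)
  acc <- wh$choice_accuracy$accuracy
  expect_gt(max(acc, na.rm = TRUE), 0.6)
})

test_that("cosine similarity behaves and permutation nulls center at zero", {
  x <- c(1, 2, -1, 0.5)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  set.seed(33)
  nl <- similarity_nulls(new_cd_for_test(100), new_cd_for_test(100),
                         n_perm = 1000)
  expect_lt(abs(mean(nl$cosine[nl$kind == "permuted"])), 0.02)
  expect_lt(abs(mean(nl$cosine[nl$kind == "unit"])), 0.02)
})

test_that("within-trial correlations detect the shared decision variable", {
  rts <- fix_rt25_std()
  sig_r <- detrend_signal(project_signal(rts, fix_ramp()))
  sig_t <- detrend_signal(project_signal(rts, fix_tin()))
  self <- within_trial_correlation(sig_r, sig_r)
  expect_equal(self$mean_r, 1, tolerance = 1e-9)
  obs <- within_trial_correlation(sig_r, sig_t)
  expect_gt(obs$mean_r, 0)
  set.seed(34)
  nulls <- within_trial_nulls(rts, fix_ramp(), fix_tin(), n_perm = 100)
  expect_gt(obs$mean_r, quantile(nulls, 0.99))
  # independent white-noise signals correlate near zero
  s_a <- sig_r; s_a$values <- matrix(rnorm(length(sig_r$values)),
                                     nrow(sig_r$values))
  s_b <- sig_r; s_b$values <- matrix(rnorm(length(sig_r$values)),
                                     nrow(sig_r$values))
  expect_lt(abs(within_trial_correlation(s_a, s_b)$mean_r), 0.02)
})

test_that("ablating task-related neurons lowers decoding accuracy", {
  ses <- fix_session()
  base <- fixture("what_base", function() {
    what_decoder(ses, bin_centers = c(0.325, 0.425))
  })
  none <- ablate_and_decode(ses, drop = character(0),
                            bin_centers = c(0.325, 0.425))
  expect_equal(none$accuracy, base$accuracy, tolerance = 0.02)
  dropped <- ablate_and_decode(ses, drop = c("Tin_con", "Tin_ips",
                                             "Min_left", "Min_right"),
                               bin_centers = c(0.325, 0.425))
  expect_lt(mean(dropped$accuracy), mean(base$accuracy))
  only_tin <- ablate_and_decode(ses, drop = "all_but_tin",
                                bin_centers = c(0.325, 0.425))
  # dropping Tin+Min hurts more than restricting to Tin alone
  expect_lt(mean(dropped$accuracy), mean(only_tin$accuracy))
  expect_error(ablate_and_decode(ses, drop = c("Tin_con", "Tin_ips",
                                               "Min_left", "Min_right",
                                               "other")), "every neuron")
})
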