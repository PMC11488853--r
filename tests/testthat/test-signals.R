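test_that("kernel bookkeeping matches the stated windows", {
  k50 <- kernel_spec("boxcar", 50)
  expect_equal(c(k50$back_ms, k50$fwd_ms), c(24, 25))
  k51 <- kernel_spec("boxcar", 51)
  expect_equal(c(k51$back_ms, k51$fwd_ms), c(25, 25))
  kg <- kernel_spec("gaussian", 80, gauss_alpha = 1.5)
  expect_equal(round(kg$sigma_ms), 26)
  expect_equal(sum(kg$w), 1, tolerance = 1e-12)
})

test_that("boxcar smoothing has the stated impulse response and constants", {
  # one spike at t = 0 in a single-trial, single-neuron session
  ses <- list(trials = tibble::tibble(trial_id = 1L, signed_coh = 0,
                                      choice = "left", rt_s = 1,
                                      motion_on_s = 0, saccade_s = 1,
                                      correct = TRUE),
              spikes = tibble::tibble(neuron_id = 1L, trial_id = 1L,
                                      t_s = 0.0004),
              neurons = tibble::tibble(neuron_id = 1L, label = "other",
                                       truth_weight = 0),
              kind = "decision")
  class(ses) <- "dv_session"
  rt <- bin_and_smooth(ses, t_lim = c(-0.06, 0.06), step = 0.001,
                       censor = FALSE)
  v <- rt$rates[1, 1, ]
  nz <- rt$time[v > 0]
  expect_equal(range(nz) * 1000, c(-25, 24), tolerance = 0.5)
  # regular spiking at 20 sp/s recovers a 20 sp/s rate away from edges
  ses$spikes <- tibble::tibble(neuron_id = 1L, trial_id = 1L,
                               t_s = seq(0.025, 0.975, by = 0.05))
  rt2 <- bin_and_smooth(ses, t_lim = c(0.2, 0.8), step = 0.025,
                        censor = FALSE)
  expect_true(all(abs(rt2$rates[1, 1, ] - 20) <= 20 / 50 + 1e-9))
})

test_that("projection is linear and censoring propagates", {
  rts <- fix_rt25_std()
  n <- dim(rts$rates)[1]
  w1 <- rnorm(n); w2 <- rnorm(n)
  s1 <- project_signal(rts, w1)
  s2 <- project_signal(rts, w2)
  s12 <- project_signal(rts, w1 + w2)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-9)
  one_hot <- replace(numeric(n), 3, 1)
  expect_equal(project_signal(rts, one_hot)$values, rts$rates[3, , ],
               ignore_attr = TRUE)
  expect_true(all(project_signal(rts, numeric(n))$values %in% c(0, NA)))
  expect_error(project_signal(rts, numeric(n - 1)), "length")
  # censored samples are NA beyond rt - 0.1
  tr <- rts$trials
  i <- which.min(tr$rt_s)
  expect_true(all(is.na(s1$values[i, rts$time > tr$rt_s[i] - 0.1])))
})

test_that("standardization centers the reference epoch and flags silence", {
  rts <- fix_rt25_std()
  sel <- rts$time >= 0.2 & rts$time <= 0.6
  kept <- which(!rts$norm$excluded)[1:5]
  for (n in kept) {
    v <- rts$rates[n, , sel]
    expect_lt(abs(mean(v, na.rm = TRUE)), 1e-8)
    expect_equal(sd(v, na.rm = TRUE), 1, tolerance = 1e-6)
  }
  # standardizing an already-standardized tensor changes nothing
  rts2 <- standardize_neurons(rts)
  expect_equal(rts2$rates, rts$rates, tolerance = 1e-8)
  # a silent neuron is excluded
  ses <- fix_session()
  ses2 <- ses
  ses2$spikes <- ses$spikes[ses$spikes$neuron_id != 1L, ]
  rt_sil <- standardize_neurons(bin_and_smooth(ses2, t_lim = c(0.2, 0.6),
                                               step = 0.05))
  expect_true(1L %in% attr(rt_sil, "excluded"))
})

test_that("condition means follow the censoring and error-exclusion rules", {
  sig <- fix_sig_ramp()
  cm <- condition_means(sig)
  expect_true(all(sort(unique(cm$signed_coh)) == sort(unique(sig$trials$signed_coh))))
  # a trial with rt = 0.4 contributes nothing at t > 0.3
  tr <- sig$trials
  i <- which(tr$rt_s < 0.45)[1]
  expect_true(all(is.na(sig$values[i, sig$time >= tr$rt_s[i] - 0.075])))
  # all-identical trials: mean equals the single trial
  sub <- sig
  sub$values <- sig$values[rep(5, 4), ]
  sub$trials <- sig$trials[rep(5, 4), ]
  cm1 <- condition_means(sub, correct_only = FALSE)
  expect_equal(cm1$mean, unname(sig$values[5, ]))
})

test_that("detrending removes group means, is idempotent, shrinks variance", {
  sig <- fix_sig_ramp()
  d1 <- detrend_signal(sig)
  for (cc in unique(sig$trials$signed_coh)) {
    idx <- sig$trials$signed_coh == cc
    mu <- colMeans(d1$values[idx, , drop = FALSE], na.rm = TRUE)
    expect_true(all(abs(mu[!is.na(mu)]) < 1e-10))
  }
  d2 <- detrend_signal(d1)
  expect_equal(d2$values, d1$values, tolerance = 1e-9)
  v_raw <- apply(sig$values, 2, var, na.rm = TRUE)
  v_det <- apply(d1$values, 2, var, na.rm = TRUE)
  expect_true(all(v_det <= v_raw + 1e-9))
  # baseline subtraction zeroes the anchor column
  d3 <- detrend_signal(sig, baseline_t = 0.2)
  j <- which.min(abs(sig$time - 0.2))
  expect_true(all(abs(d3$values[, j]) < 1e-12, na.rm = TRUE))
})

test_that("session normalization maps the four-trace range onto [0, 1]", {
  ses <- fix_session()
  rts <- fix_rt25_std()
  sig_m <- project_signal(rts, fix_ramp())
  rt_s <- bin_and_smooth(ses, t_lim = c(-0.6, 0.05), step = 0.025,
                         alignment = "saccade")
  sig_s <- project_signal(standardize_neurons(rt_s, window = c(-0.6, 0)),
                          fix_ramp())
  nn <- normalize_session(sig_m, sig_s)
  cm_m <- condition_means(nn$motion, by = "choice", correct_only = FALSE)
  cm_s <- condition_means(nn$saccade, by = "choice")
  vals <- c(cm_m$mean[cm_m$t >= 0 & cm_m$t <= 0.6],
            cm_s$mean[cm_s$t >= -0.6 & cm_s$t <= 0])
  expect_equal(min(vals, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(max(vals, na.rm = TRUE), 1, tolerance = 1e-9)
  # affine invariance of the normalized output
  sig_m2 <- sig_m; sig_m2$values <- 3 * sig_m$values + 7
  sig_s2 <- sig_s; sig_s2$values <- 3 * sig_s$values + 7
  nn2 <- normalize_session(sig_m2, sig_s2)
  expect_equal(nn2$motion$values, nn$motion$values, tolerance = 1e-9)
})

test_that("urgency is the 0% coherence mean and its removal symmetrizes", {
  sig <- fix_sig_ramp()
  u <- estimate_urgency(sig)
  idx0 <- sig$trials$signed_coh == 0
  expect_equal(u$u, unname(colMeans(sig$values[idx0, ], na.rm = TRUE)))
  cm <- condition_means(sig)
  cmc <- remove_urgency(cm, u)
  # corrected +c and -c means should be near-mirror images mid-trial
  for (cc in c(0.128, 0.256)) {
    jp <- cmc$signed_coh == cc & cmc$t > 0.3 & cmc$t < 0.5
    jm <- cmc$signed_coh == -cc & cmc$t > 0.3 & cmc$t < 0.5
    asym <- abs(cmc$mean[jp] + cmc$mean[jm])
    bound <- 2 * sqrt(cmc$se[jp]^2 + cmc$se[jm]^2)
    expect_true(mean(asym < bound + 1e-9) > 0.6)
  }
})

test_that("fisher_mean matches the closed form", {
  expect_equal(fisher_mean(c(0.4, 0.4, 0.4)), 0.4, tolerance = 1e-12)
  expect_equal(fisher_mean(c(0, 0)), 0)
  expect_equal(fisher_mean(c(0.2, 0.6)),
               tanh(mean(atanh(c(0.2, 0.6)))), tolerance = 1e-12)
  expect_true(is.na(fisher_mean(numeric(0))))
})

test_that("smoothing and projection commute for linear kernels", {
  ses <- fix_session()
  n <- nrow(ses$neurons)
  w <- rnorm(n)
  rt_a <- bin_and_smooth(ses, t_lim = c(0.2, 0.5), step = 0.025,
                         kernel = kernel_spec("boxcar", 75), censor = FALSE)
  rt_b <- bin_and_smooth(ses, t_lim = c(0.175, 0.525), step = 0.025,
                         kernel = kernel_spec("boxcar", 25), censor = FALSE)
  s_a <- project_signal(rt_a, w)$values
  # project 25 ms rates, then 75 ms boxcar = mean of three 25 ms samples
  s_b_raw <- project_signal(rt_b, w)$values
  jj <- match(round(rt_a$time, 6), round(rt_b$time, 6))
  s_b <- (s_b_raw[, jj - 1] + s_b_raw[, jj] + s_b_raw[, jj + 1]) / 3
  expect_equal(s_a, s_b, tolerance = 1e-8)
})
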