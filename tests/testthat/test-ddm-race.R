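test_that("truncated-exponential delays respect their support and mean bound", {
  # degenerate range collapses to a point mass
  expect_equal(sample_truncated_exp(delay_spec(0.3, 0.3, 0.15), 50),
               rep(0.3, 50))
  set.seed(1)
  spec <- delay_spec(0.25, 0.7, 0.15)
  x <- sample_truncated_exp(spec, 2e4)
  expect_true(all(x >= 0.25 & x <= 0.7))
  # truncation pulls the expectation below t_min + lambda
  expect_lt(mean(x), 0.25 + 0.15)
  # empirical CDF against the closed-form CDF
  q <- seq(0.25, 0.7, by = 0.001)
  ks <- max(abs(stats::ecdf(x)(q) - ptrunc_exp(q, spec)))
  expect_lt(ks, 0.012)
  expect_error(delay_spec(0.5, 0.3, 0.1), "t_min")
  expect_error(delay_spec(0.1, 0.3, -1), "lam")
})

test_that("collapsing bound is linear, floored, and monotone", {
  p0 <- ddm_params(10, 1.03, 0, 0.3, 0.05, 0)
  expect_equal(bound_at(c(0, 0.5, 2), p0), rep(1.03, 3))
  p <- ddm_params_monkey("M")
  expect_equal(bound_at(1, p), 1.03 - 0.4199, tolerance = 1e-12)
  tt <- seq(0, 5, by = 0.1)
  expect_true(all(diff(bound_at(tt, p)) <= 0))
  expect_true(all(bound_at(tt, p) >= 0.01 * p$B0))
})

test_that("symmetric race yields ~50% left choices at every coherence", {
  p <- ddm_params(kappa = 0, B0 = 1, alpha_collapse = 0.4, mu_nd = 0.3,
                  sigma_nd = 0.04, C0 = 0)
  sim <- simulate_race(p, coherences = c(-0.256, 0, 0.256),
                       n_per_coh = 4000, seed = 2)
  pl <- tapply(sim$trials$choice == "left", sim$trials$signed_coh, mean)
  expect_true(all(abs(pl - 0.5) < 0.025))
})

test_that("momentary-evidence increments carry the stated anticorrelation", {
  p <- ddm_params_monkey("M")
  set.seed(4)
  inc <- race_increments(2e5, p)
  expect_equal(cor(inc)[1, 2], -sqrt(0.5), tolerance = 0.01)
  expect_equal(sd(inc[, 1]), sqrt(0.001), tolerance = 0.01)
})

test_that("accuracy rises and mean RT falls with motion strength", {
  p <- ddm_params_monkey("M")
  sim <- simulate_race(p, n_per_coh = 3000, seed = 5)
  tr <- sim$trials
  ac <- abs(tr$signed_coh)
  acc <- tapply(tr$correct, ac, mean)[-1] # drop 0% (undefined accuracy)
  rt <- tapply(tr$rt_s, ac, mean)
  expect_true(all(diff(acc) > 0))
  expect_true(all(diff(rt) < 0))
})

test_that("DV paths freeze at termination until the response", {
  p <- ddm_params_monkey("M")
  sim <- simulate_race(p, coherences = c(0, 0.128), n_per_coh = 40,
                       seed = 6, keep_paths = TRUE, path_t_max = 1.5,
                       path_dt = 0.005)
  tr <- sim$trials
  for (i in which(tr$decision_time_s < 1.4)[1:30]) {
    frozen <- sim$path_time >= tr$decision_time_s[i]
    expect_lt(diff(range(sim$dv_left[frozen, i])), 1e-12)
    expect_lt(diff(range(sim$dv_right[frozen, i])), 1e-12)
  }
  # rt decomposition
  expect_equal(tr$rt_s, tr$nd_pre_s + tr$decision_time_s + tr$nd_post_s)
  expect_true(all(tr$nd_post_s >= 0))
})

test_that("collapsing bounds shorten 0% coherence decisions", {
  p <- ddm_params_monkey("M")
  p_flat <- ddm_params(p$kappa, p$B0, 0, p$mu_nd, p$sigma_nd, p$C0)
  s1 <- simulate_race(p, coherences = 0, n_per_coh = 10000, seed = 7)
  s2 <- simulate_race(p_flat, coherences = 0, n_per_coh = 10000, seed = 7)
  expect_lt(mean(s1$trials$rt_s), mean(s2$trials$rt_s))
})

test_that("simulator rejects invalid inputs", {
  p <- ddm_params_monkey("M")
  expect_error(simulate_race(p, dt = 0), "dt")
  expect_error(simulate_race(p, coherences = numeric(0)), "empty")
  expect_error(ddm_params(10, -1, 0.4, 0.3, 0.05, 0), "B0")
  expect_error(ddm_params(10, 1, 0.4, 0.3, 0.05, 0, rho = 0.5), "rho")
})
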