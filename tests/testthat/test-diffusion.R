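test_that("smoothed-Wiener closed forms match quadrature and first moments", {
  # variance of the window mean starting at the origin is w/3
  w <- 0.051
  th0 <- wiener_theory(sample_centers = 0.2 + w / 2, w = w)
  expect_equal(th0$cov[1, 1], w / 3, tolerance = 1e-6)
  # default six-window layout: closed forms for var and non-overlap cov
  th <- wiener_theory()
  expect_equal(diag(th$cov), th$tau - w / 6, tolerance = 1e-12)
  expect_equal(th$cov[1, 4], th$tau[1], tolerance = 1e-12)
  # non-overlapping pair correlation formula
  expect_equal(th$corr[2, 5],
               th$tau[2] / sqrt((th$tau[2] - w / 6) * (th$tau[5] - w / 6)),
               tolerance = 1e-12)
  # closed form against quadrature for an overlapping pair
  thq <- wiener_theory(sample_centers = c(0.24, 0.26), w = 0.051)
  s <- seq(0.24 - w / 2, 0.24 + w / 2, length.out = 901)
  u <- seq(0.26 - w / 2, 0.26 + w / 2, length.out = 901)
  ref <- mean(outer(pmax(s - 0.2, 0), pmax(u - 0.2, 0), pmin))
  expect_equal(thq$cov[1, 2], ref, tolerance = 1e-3)
  # correlation matrix structure
  expect_equal(diag(th$corr), rep(1, 6))
  expect_equal(th$corr, t(th$corr))
  expect_true(all(eigen(th$corr, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("theory matches a Monte-Carlo oracle of smoothed Wiener paths", {
  th <- wiener_theory()
  set.seed(21)
  mc <- wiener_window_mc(3e4)
  expect_lt(max(abs(th$corr - mc$corr)), 0.015)
})

test_that("the w->0 limit recovers the unsmoothed Wiener autocorrelation", {
  lim <- function(th) {
    m <- sqrt(outer(th$tau, th$tau, "/"))
    pmin(m, t(m))
  }
  th_small <- wiener_theory(w = 0.00025)
  expect_lt(max(abs(th_small$corr - lim(th_small))), 1e-3)
  # the deviation shrinks with the window
  th_1ms <- wiener_theory(w = 0.001)
  expect_lt(max(abs(th_small$corr - lim(th_small))),
            max(abs(th_1ms$corr - lim(th_1ms))))
})

test_that("empirical variance and autocorrelation recover the theory", {
  set.seed(22)
  M <- simulate_smoothed_wiener(4000)
  emp <- empirical_var_autocorr(M, n_boot = 100)
  th <- wiener_theory()
  v_th <- diag(th$cov) / th$cov[1, 1]
  expect_true(all(abs(emp$var_curve - v_th) <= 2.5 * emp$var_se + 1e-9))
  expect_true(all(diff(emp$var_curve) > 0))
  expect_equal(diag(emp$corr), rep(1, 6))
  expect_error(empirical_var_autocorr(M[1:50, ]), "eligible")
})

test_that("phi recovery: pure diffusion gives ~1, planted nuisance gives f", {
  th <- wiener_theory()
  set.seed(23)
  M1 <- simulate_smoothed_wiener(5000, diffusion_frac = 1)
  f1 <- fit_phi(empirical_var_autocorr(M1, n_boot = 10), th)
  expect_equal(f1$phi, 1, tolerance = 0.05)
  M6 <- simulate_smoothed_wiener(5000, diffusion_frac = 0.6)
  f6 <- fit_phi(empirical_var_autocorr(M6, n_boot = 10), th)
  expect_equal(f6$phi, 0.6, tolerance = 0.05)
  expect_lte(f1$phi, 1) # hard constraint
})

test_that("bounded accumulation renders the variance sublinear", {
  p <- ddm_params_monkey("M")
  sim <- simulate_race(p, coherences = c(-0.032, 0, 0.032),
                       n_per_coh = 2000, seed = 24, keep_paths = TRUE,
                       path_t_max = 0.6, path_dt = 0.001)
  centers <- 0.026 + 0.051 * (0:5) # integration time of the Fig-3 layout
  C <- dvtrace:::wiener_window_coefs(centers + 0.2, 0.051, 0.2, 0.001)
  inc <- rbind(sim$dv_left[1, , drop = FALSE], diff(sim$dv_left))
  M <- t(C %*% inc[seq_len(ncol(C)), , drop = FALSE])
  # keep trials surviving the pre-saccade censoring of the last window
  keep <- sim$trials$rt_s >= 0.2 + max(centers) + 0.0255 + 0.1
  M <- M[keep, , drop = FALSE]
  for (gi in split(seq_len(nrow(M)), sim$trials$signed_coh[keep])) {
    M[gi, ] <- sweep(M[gi, , drop = FALSE], 2, colMeans(M[gi, , drop = FALSE]))
  }
  v <- apply(M, 2, var)
  v_th <- wiener_theory()$tau - 0.051 / 6
  # normalized to the first sample, later samples fall below the linear theory
  expect_lt(v[6] / v[1], (v_th[6] / v_th[1]))
})
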