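# crafted sample matrices make the mediation algebra checkable exactly-ish
make_lev_data <- function(n = 600, seed = 41, rho_med = 0.9) {
  set.seed(seed)
  times <- leverage_times()
  coh <- sample(rep(c(-0.064, -0.032, 0, 0.032, 0.064), length.out = n))
  latent <- rnorm(n) # shared decision variable sample
  S <- sapply(seq_along(times), function(k) {
    rho_med * latent + sqrt(1 - rho_med^2) * rnorm(n)
  })
  pr <- plogis(1.5 * latent + 20 * coh)
  choice <- ifelse(runif(n) < pr, "left", "right")
  rt <- 1.2 - 0.2 * latent + rnorm(n, 0, 0.15)
  rt <- pmin(pmax(rt, 0.7), 1.95)
  trials <- tibble::tibble(trial_id = seq_len(n), signed_coh = coh,
                           choice = choice, rt_s = rt)
  list(S = S, trials = trials, times = times, latent = latent)
}

test_that("mediation statistics follow their defining algebra", {
  d <- make_lev_data()
  k4 <- which.min(abs(d$times - 0.4))
  k55 <- which.min(abs(d$times - 0.55))
  # mediator = the latent that generated both signal and behavior:
  # conditioning on it removes (nearly) all leverage
  r2 <- leverage_behavior(d$S, d$trials, d$times, mediator = d$latent)
  expect_gt(r2$xi_rt, 0.85)
  expect_gt(r2$xi_ch, 0.85)
  # constant mediator: partial equals simple correlation, no mediation
  S3 <- d$S
  S3[, k55] <- 0
  r3 <- suppressWarnings(leverage_behavior(S3, d$trials, d$times))
  expect_equal(r3$partial_r_rt[k4], r3$r_rt[k4], tolerance = 1e-6)
  expect_equal(r3$xi_rt, 0, tolerance = 1e-6)
  # anti-predictive signal: choice mediation undefined, explicitly marked
  S4 <- -d$S
  r4 <- leverage_behavior(S4, d$trials, d$times)
  expect_false(r4$xi_ch_defined)
  expect_true(is.na(r4$xi_ch))
})

test_that("leverage uses one shared filtered trial set", {
  d <- make_lev_data()
  r1 <- leverage_behavior(d$S, d$trials, d$times)
  r2 <- leverage_behavior(2 * d$S + 1, d$trials, d$times)
  expect_identical(r1$trial_mask, r2$trial_mask)
  expect_error(leverage_behavior(d$S[1:20, ], d$trials[1:20, ], d$times),
               "eligible")
})

test_that("cross-mediation reduces to self-mediation for the same signal", {
  d <- make_lev_data()
  k55 <- which.min(abs(d$times - 0.55))
  self <- leverage_behavior(d$S, d$trials, d$times)
  crossed <- leverage_behavior(d$S, d$trials, d$times,
                               mediator = d$S[, k55])
  expect_equal(crossed$xi_rt, self$xi_rt, tolerance = 1e-9)
  expect_equal(crossed$beta1_star_norm, self$beta1_star_norm,
               tolerance = 1e-9)
  # an unrelated mediator leaves leverage unmediated
  set.seed(42)
  indep <- leverage_behavior(d$S, d$trials, d$times,
                             mediator = rnorm(nrow(d$S)))
  expect_lt(indep$xi_rt, 0.2)
})

test_that("noiseless DV leverage is fully mediated; noise weakens mediation", {
  sim <- fix_race_paths()
  r0 <- dv_leverage_ceiling(sim, noise_sd = 0)
  expect_gt(r0$xi_rt, 0.75)
  expect_gt(r0$xi_ch, 0.75)
  # RT leverage is negative for contraversive choices (sign convention)
  expect_lt(r0$r_rt[which.min(abs(r0$times - 0.4))], 0)
  xis <- vapply(c(0.25, 1, 3), function(sd) {
    dv_leverage_ceiling(sim, noise_sd = sd, seed = 2)$xi_rt
  }, 0)
  expect_true(all(diff(xis) < 0)) # monotone in noise level
  # beta1 grows during accumulation
  expect_gt(r0$beta1_norm[which.min(abs(r0$times - 0.5))],
            r0$beta1_norm[1])
})

test_that("bootstrap and permutation inference are well-formed", {
  d <- make_lev_data(n = 500)
  mb <- mediation_bootstrap(d$S, d$trials, d$times, n_boot = 60, n_null = 60,
                            seed = 5)
  expect_true(all(mb$se$beta1_norm_se > 0))
  expect_gt(mb$xi_rt_se, 0)
  # real mediation beats the broken-correspondence null
  expect_lt(mb$p_rt, 0.05)
  expect_true(is.finite(mb$p_ch))
})

test_that("null leverage bands are centred and seeded deterministically", {
  d <- make_lev_data()
  set.seed(6)
  n1 <- trial_shuffle_null(d$S, d$trials, n = 60, seed = 7, times = d$times)
  n2 <- trial_shuffle_null(d$S, d$trials, n = 60, seed = 7, times = d$times)
  expect_identical(n1$beta1_norm, n2$beta1_norm)
  k <- which.min(abs(d$times - 0.5))
  expect_lt(abs(mean(n1$r_rt[, k], na.rm = TRUE)), 0.05)
  # observed leverage exceeds the null band
  obs <- leverage_behavior(d$S, d$trials, d$times)
  expect_lt(obs$r_rt[k], quantile(n1$r_rt[, k], 0.01, na.rm = TRUE))
  expect_gt(obs$beta1_norm[k], quantile(n1$beta1_norm[, k], 0.99,
                                        na.rm = TRUE))
})

test_that("random coding directions carry no leverage on a real session", {
  rts <- fix_rt25_std()
  set.seed(8)
  nl <- random_cd_null(rts, fix_pc1(), n = 40)
  obs <- leverage_behavior(fix_sig_ramp())
  k <- which.min(abs(leverage_times() - 0.5))
  expect_gt(obs$beta1_norm[k], quantile(nl$beta1_norm[, k], 0.975,
                                        na.rm = TRUE))
  expect_lt(abs(mean(nl$r_rt[, k], na.rm = TRUE)), 0.1)
})
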