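#' Trial filter for leverage analyses
#'
#' Leverage analyses use the early epoch of evidence accumulation and
#' restrict to trials whose outcome occurs well after the analyzed samples:
#' reaction times in (0.67, 2) s and motion strength at or below 6.4%
#' coherence. RT leverage additionally uses contraversive (left) choices
#' only; choice leverage uses both choices (the logistic model needs both
#' outcomes), with the same RT window.
#'
#' @param rt_min,rt_max RT window (s), exclusive.
#' @param coh_max Maximum |signed coherence|.
#' @return List of class \code{trial_filter}.
#' @export
trial_filter <- function(rt_min = 0.67, rt_max = 2, coh_max = 0.064) {
  structure(list(rt_min = rt_min, rt_max = rt_max, coh_max = coh_max),
            class = "trial_filter")
}

#' Default leverage sample times
#'
#' 50 ms boxcar samples every 25 ms over 0.2-0.5 s plus the later mediator
#' sample at 0.55 s.
#' @return Numeric vector of times (s).
#' @export
leverage_times <- function() c(seq(0.2, 0.5, by = 0.025), 0.55)

# Fast logistic fit returning coefficients, standard errors, convergence.
fast_logit <- function(X, y, maxit = 25) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = list(maxit = maxit)))
  p <- ncol(X)
  R <- qr.R(structure(fit$qr, class = "qr"))[seq_len(p), seq_len(p), drop = FALSE]
  se <- rep(NA_real_, p)
  cv <- try(chol2inv(R), silent = TRUE)
  if (!inherits(cv, "try-error")) se <- sqrt(diag(cv))
  sep <- !fit$converged || any(abs(fit$coefficients) > 50, na.rm = TRUE)
  list(coef = fit$coefficients, se = se, separation = sep)
}

# Assemble the filtered, detrended sample matrix used by both leverage
# branches. Returns NULL-safe list or errors when too few trials remain.
leverage_data <- function(S, times, trials, filter, min_trials = 30) {
  stopifnot(length(times) == ncol(S), nrow(trials) == nrow(S))
  keep <- trials$rt_s > filter$rt_min & trials$rt_s < filter$rt_max &
    abs(trials$signed_coh) <= filter$coh_max + 1e-9
  keep[is.na(keep)] <- FALSE
  keep <- keep & stats::complete.cases(S)
  if (sum(keep) < min_trials) {
    stop(sprintf("only %d eligible trials after filtering (need >= %d)",
                 sum(keep), min_trials), call. = FALSE)
  }
  tr <- trials[keep, ]
  Sf <- S[keep, , drop = FALSE]
  g <- factor(tr$signed_coh)
  # detrend signals per signed coherence; residualize RT per coherence x choice
  for (gi in split(seq_len(nrow(Sf)), g)) {
    Sf[gi, ] <- sweep(Sf[gi, , drop = FALSE], 2,
                      colMeans(Sf[gi, , drop = FALSE]))
  }
  rt_res <- demean_by(tr$rt_s, interaction(g, tr$choice))
  list(S = Sf, trials = tr, g = g, rt_res = rt_res, keep = keep)
}

#' Leverage of single-trial signals on choice and reaction time
#'
#' Quantifies how strongly early samples of a single-trial signal predict
#' the eventual choice and RT, and how much of that leverage a later sample
#' (at \code{mediator_time}) mediates.
#'
#' Choice leverage at time t is the coefficient \eqn{\beta_1(t)} of S(t) in
#' a logistic regression of the (left) choice with one intercept per signed
#' coherence; the mediated coefficient \eqn{\beta_1^*(t)} adds the mediator
#' sample to the model. Both are divided by the standard error of
#' \eqn{\beta_1(t)} (the same normalization for both) before any averaging
#' across sessions. The choice-mediation summary at t = 0.4 s is
#' \eqn{\xi_{Ch} = 1 - \beta_1^*/\beta_1} (1 if \eqn{\beta_1^* \le 0};
#' undefined, and explicitly marked, if \eqn{\beta_1 \le 0}).
#'
#' RT leverage (left-choice trials only) is the Pearson correlation between
#' the detrended S(t) and the residual RT; the mediated version is the
#' partial correlation given the mediator sample, and
#' \eqn{\xi_{RT} = 1 - r_{partial}(0.4)^2 / r(0.4)^2} (undefined when the
#' simple correlation at 0.4 s is not negative).
#'
#' @param S Matrix (trials x times) of signal samples (50 ms boxcar), or a
#'   \code{dv_signal} (then samples are extracted at \code{times}).
#' @param trials Trials tibble (needed when \code{S} is a matrix).
#' @param times Sample times; default [leverage_times()].
#' @param filter A [trial_filter()].
#' @param mediator_time Time of the later sample (default 0.55 s).
#' @param xi_time Time at which the mediation summaries are computed (0.4).
#' @param mediator Optional per-trial mediator values replacing the
#'   signal's own later sample (cross-mediation, e.g. the Tin signal at
#'   0.55 s); a vector over all trials in \code{trials}.
#' @return Object of class \code{mediation_result} with per-time leverage
#'   traces (raw and normalized), mediated traces, \code{xi_ch},
#'   \code{xi_rt}, flags, and the filtered trial mask.
#' @export
leverage_behavior <- function(S, trials = NULL, times = leverage_times(),
                              filter = trial_filter(),
                              mediator_time = 0.55, xi_time = 0.4,
                              mediator = NULL) {
  if (inherits(S, "dv_signal")) {
    trials <- S$trials
    S <- sample_signal(S, times)
  }
  med_all <- mediator
  ld <- leverage_data(S, times, trials, filter)
  tr <- ld$trials
  k_med <- which.min(abs(times - mediator_time))
  med <- if (is.null(med_all)) ld$S[, k_med] else {
    m <- med_all[ld$keep]
    demean_by(m, ld$g) # detrended like the signal samples
  }
  y <- tr$choice == "left"
  Xint <- stats::model.matrix(~ 0 + ld$g)

  n_t <- length(times)
  beta1 <- beta1_se <- beta1_star <- rep(NA_real_, n_t)
  sep_flags <- logical(n_t)
  for (k in seq_len(n_t)) {
    f1 <- fast_logit(cbind(Xint, ld$S[, k]), y)
    beta1[k] <- f1$coef[ncol(Xint) + 1]
    beta1_se[k] <- f1$se[ncol(Xint) + 1]
    f2 <- fast_logit(cbind(Xint, ld$S[, k], med), y)
    beta1_star[k] <- f2$coef[ncol(Xint) + 1]
    sep_flags[k] <- f1$separation || f2$separation
  }
  b1n <- beta1 / beta1_se
  b1sn <- beta1_star / beta1_se

  kx <- which.min(abs(times - xi_time))
  xi_ch <- if (is.na(beta1[kx]) || beta1[kx] <= 0) {
    NA_real_ # mediation undefined
  } else if (beta1_star[kx] <= 0) 1 else 1 - beta1_star[kx] / beta1[kx]
  xi_ch_defined <- !is.na(beta1[kx]) && beta1[kx] > 0

  # RT branch: left-choice trials only
  lft <- y
  r_rt <- partial_r_rt <- rep(NA_real_, n_t)
  for (k in seq_len(n_t)) {
    r_rt[k] <- stats::cor(ld$S[lft, k], ld$rt_res[lft])
    partial_r_rt[k] <- partial_cor(ld$S[lft, k], ld$rt_res[lft], med[lft])
  }
  xi_rt <- if (is.na(r_rt[kx]) || r_rt[kx] >= 0) NA_real_ else
    1 - partial_r_rt[kx]^2 / r_rt[kx]^2
  xi_rt_defined <- !is.na(r_rt[kx]) && r_rt[kx] < 0

  structure(list(times = times, beta1 = beta1, beta1_se = beta1_se,
                 beta1_star = beta1_star,
                 beta1_norm = b1n, beta1_star_norm = b1sn,
                 r_rt = r_rt, partial_r_rt = partial_r_rt,
                 xi_ch = xi_ch, xi_ch_defined = xi_ch_defined,
                 xi_rt = xi_rt, xi_rt_defined = xi_rt_defined,
                 xi_time = times[kx], mediator_time = times[k_med],
                 separation = sep_flags,
                 n_trials = nrow(tr), n_left = sum(lft),
                 trial_mask = ld$keep),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (%d trials, %d left)\n", x$n_trials, x$n_left))
  cat(sprintf("  xi_ch = %s, xi_rt = %s (at t = %.2f s, mediator %.2f s)\n",
              if (x$xi_ch_defined) sprintf("%.3f", x$xi_ch) else "undefined",
              if (x$xi_rt_defined) sprintf("%.3f", x$xi_rt) else "undefined",
              x$xi_time, x$mediator_time))
  invisible(x)
}

#' Combine mediation results across sessions
#'
#' RT leverage is Fisher-z averaged; normalized choice leverage is averaged
#' arithmetically; positive mediated RT partial correlations are rectified
#' to zero before combination; sessions with undefined mediation statistics
#' are excluded from the corresponding summary.
#'
#' @param results List of \code{mediation_result}s.
#' @return A list with combined traces and mean \code{xi_ch}, \code{xi_rt}.
#' @export
combine_mediation <- function(results) {
  stopifnot(length(results) > 0)
  times <- results[[1]]$times
  r_mat <- vapply(results, `[[`, numeric(length(times)), "r_rt")
  pr_mat <- vapply(results, `[[`, numeric(length(times)), "partial_r_rt")
  pr_mat <- pmin(pr_mat, 0) # rectify positive partials when combining
  list(times = times,
       beta1_norm = rowMeans(vapply(results, `[[`, numeric(length(times)),
                                    "beta1_norm")),
       beta1_star_norm = rowMeans(vapply(results, `[[`,
                                         numeric(length(times)),
                                         "beta1_star_norm")),
       r_rt = apply(r_mat, 1, fisher_mean),
       partial_r_rt = apply(pr_mat, 1, fisher_mean),
       xi_ch = mean(vapply(results, function(r)
         if (r$xi_ch_defined) r$xi_ch else NA_real_, 0), na.rm = TRUE),
       xi_rt = mean(vapply(results, function(r)
         if (r$xi_rt_defined) r$xi_rt else NA_real_, 0), na.rm = TRUE))
}

#' Cross-mediation by another signal's later sample
#'
#' Re-runs the mediation analysis with the mediator replaced by another
#' signal (typically the Tin-average signal) sampled at the mediator time.
#'
#' @param S_x Signal being evaluated (\code{dv_signal} or matrix).
#' @param S_med Mediating signal (\code{dv_signal} on the same trials).
#' @inheritParams leverage_behavior
#' @return A \code{mediation_result}.
#' @export
cross_mediation <- function(S_x, S_med, trials = NULL,
                            times = leverage_times(),
                            filter = trial_filter(), mediator_time = 0.55,
                            xi_time = 0.4) {
  med_vals <- if (inherits(S_med, "dv_signal")) {
    as.numeric(sample_signal(S_med, mediator_time))
  } else as.numeric(S_med)
  leverage_behavior(S_x, trials = trials, times = times, filter = filter,
                    mediator_time = mediator_time, xi_time = xi_time,
                    mediator = med_vals)
}

#' Bootstrap and permutation inference for mediation
#'
#' Bootstrap: resamples trials with replacement (1000 surrogate data sets
#' by default), giving standard errors of the leverage traces and of the
#' mediation statistics. Null: the correspondence between a trial and its
#' later (mediator) sample is broken by permuting the mediator within
#' signed-coherence groups (trial counts per coherence preserved exactly);
#' the bootstrap and null distributions of each mediation statistic are
#' compared with a Wilcoxon rank-sum test.
#'
#' @inheritParams leverage_behavior
#' @param n_boot Bootstrap resamples.
#' @param n_null Null permutations.
#' @param seed Integer seed.
#' @return List: \code{se} (tibble of per-time SEs), \code{xi_ch_se},
#'   \code{xi_rt_se}, the observed statistics, bootstrap and null
#'   distributions, permutation p-values \code{p_ch}, \code{p_rt}
#'   (one-sided: observed mediation exceeds the null), and the rank-sum
#'   p-values \code{p_ranksum_ch}, \code{p_ranksum_rt}.
#' @export
mediation_bootstrap <- function(S, trials = NULL, times = leverage_times(),
                                filter = trial_filter(), n_boot = 1000,
                                n_null = 1000, seed = 1,
                                mediator_time = 0.55, xi_time = 0.4) {
  if (inherits(S, "dv_signal")) {
    trials <- S$trials
    S <- sample_signal(S, times)
  }
  set.seed(seed)
  ld <- leverage_data(S, times, trials, filter)
  n <- nrow(ld$S)
  run <- function(idx, med_override = NULL) {
    leverage_behavior(ld$S[idx, , drop = FALSE], trials = ld$trials[idx, ],
                      times = times, filter = trial_filter(0, Inf, Inf),
                      mediator_time = mediator_time, xi_time = xi_time,
                      mediator = med_override)
  }
  boots <- lapply(seq_len(n_boot), function(b) run(sample.int(n, replace = TRUE)))
  getv <- function(lst, f) vapply(lst, `[[`, numeric(length(times)), f)
  xi_of <- function(lst, f, def) vapply(seq_along(lst), function(i) {
    if (lst[[i]][[def]]) lst[[i]][[f]] else NA_real_
  }, 0)
  # null: break the trial-mediator correspondence by permuting the mediator
  # within signed-coherence groups (per-coherence trial counts preserved)
  k_med <- which.min(abs(times - mediator_time))
  nulls <- lapply(seq_len(n_null), function(b) {
    med <- ld$S[, k_med]
    for (gi in split(seq_len(n), ld$g)) med[gi] <- med[gi][sample.int(length(gi))]
    run(seq_len(n), med_override = med)
  })
  obs <- run(seq_len(n))
  boot_xi_ch <- xi_of(boots, "xi_ch", "xi_ch_defined")
  boot_xi_rt <- xi_of(boots, "xi_rt", "xi_rt_defined")
  null_xi_ch <- xi_of(nulls, "xi_ch", "xi_ch_defined")
  null_xi_rt <- xi_of(nulls, "xi_rt", "xi_rt_defined")
  # calibrated inference: permutation p-value of the observed statistic
  # against the broken-correspondence null (undefined nulls count as no
  # mediation, i.e. below any defined observed value)
  perm_p <- function(o, nl) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(nl >= o, na.rm = TRUE)) / (1 + length(nl))
  }
  # the rank-sum comparison of the bootstrap and null distributions is also
  # reported; note it is anti-conservative for near-zero effects (both
  # distributions are tight around dataset-specific values)
  rs <- function(b, nl) {
    b <- b[!is.na(b)]; nl <- nl[!is.na(nl)]
    if (length(b) < 2 || length(nl) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(b, nl, alternative = "greater")$p.value)
  }
  obs_xi_ch <- if (obs$xi_ch_defined) obs$xi_ch else NA_real_
  obs_xi_rt <- if (obs$xi_rt_defined) obs$xi_rt else NA_real_
  list(se = tibble::tibble(t = times,
                           beta1_norm_se = apply(getv(boots, "beta1_norm"), 1, sd),
                           r_rt_se = apply(getv(boots, "r_rt"), 1, sd)),
       xi_ch_se = stats::sd(boot_xi_ch, na.rm = TRUE),
       xi_rt_se = stats::sd(boot_xi_rt, na.rm = TRUE),
       xi_ch = obs_xi_ch, xi_rt = obs_xi_rt,
       boot_xi_ch = boot_xi_ch, boot_xi_rt = boot_xi_rt,
       null_xi_ch = null_xi_ch, null_xi_rt = null_xi_rt,
       p_ch = perm_p(obs_xi_ch, null_xi_ch),
       p_rt = perm_p(obs_xi_rt, null_xi_rt),
       p_ranksum_ch = rs(boot_xi_ch, null_xi_ch),
       p_ranksum_rt = rs(boot_xi_rt, null_xi_rt))
}

#' Random-coding-direction null for leverage
#'
#' Projects the population onto random coding directions obtained by
#' permuting the weights of a base direction (the first PC by default) and
#' recomputes the leverage traces, yielding a null band at each time.
#'
#' @param rt_tensor A standardized rate tensor on the leverage grid.
#' @param base_cd Coding direction whose weights are permuted.
#' @param trials Trials tibble.
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @inheritParams leverage_behavior
#' @return List of matrices \code{beta1_norm} and \code{r_rt}
#'   (\code{n} x times) of null leverage values.
#' @export
random_cd_null <- function(rt_tensor, base_cd, trials = rt_tensor$trials,
                           n = 1000, seed = 1, times = leverage_times(),
                           filter = trial_filter()) {
  set.seed(seed)
  nw <- length(base_cd$weights)
  b1 <- rr <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    w <- base_cd$weights[sample.int(nw)]
    sig <- project_signal(rt_tensor, w)
    res <- leverage_behavior(sig, times = times, filter = filter)
    b1[i, ] <- res$beta1_norm
    rr[i, ] <- res$r_rt
  }
  list(beta1_norm = b1, r_rt = rr)
}

#' Trial-shuffle null for leverage
#'
#' Breaks the correspondence between neural activity and behavior by
#' permuting the trial indices of the neural samples relative to the
#' behavioral measures, and recomputes the leverage traces.
#'
#' @param S Signal samples (\code{dv_signal} or matrix).
#' @inheritParams random_cd_null
#' @return List of matrices \code{beta1_norm} and \code{r_rt}.
#' @export
trial_shuffle_null <- function(S, trials = NULL, n = 1000, seed = 1,
                               times = leverage_times(),
                               filter = trial_filter()) {
  if (inherits(S, "dv_signal")) {
    trials <- S$trials
    S <- sample_signal(S, times)
  }
  set.seed(seed)
  b1 <- rr <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    idx <- sample.int(nrow(S))
    res <- try(leverage_behavior(S[idx, , drop = FALSE], trials = trials,
                                 times = times, filter = filter),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    b1[i, ] <- res$beta1_norm
    rr[i, ] <- res$r_rt
  }
  list(beta1_norm = b1, r_rt = rr)
}

#' Leverage ceiling from simulated decision variables
#'
#' Emulates having access to the true drift-diffusion decision variable,
#' observed through a small population of noisy neurons: each trial's
#' latent DV (left accumulator) is sampled at the leverage times, \code{n_inst}
#' noisy instantiations are generated (noise independent across time
#' points, weakly correlated across instantiations at level \code{r}), and
#' their mean is analyzed with [leverage_behavior()]. With
#' \code{noise_sd = 0} the signal is the noiseless Markovian DV, for which
#' mediation is complete.
#'
#' @param sim A [simulate_race()] result with paths.
#' @param n_inst Number of noisy instantiations (neurons).
#' @param noise_sd Marginal noise s.d. (evidence units).
#' @param r Pairwise noise correlation (default 0.09).
#' @inheritParams leverage_behavior
#' @param seed Integer seed.
#' @return A \code{mediation_result}.
#' @export
dv_leverage_ceiling <- function(sim, n_inst = 17, noise_sd = 1, r = 0.09,
                                times = leverage_times(),
                                filter = trial_filter(), seed = 1) {
  stopifnot(inherits(sim, "race_trials"), !is.null(sim$dv_left))
  set.seed(seed)
  # DV in trial time: path time + pre-integration latency
  t_trial <- sim$path_time + sim$params$pre_latency
  j <- vapply(times, function(tt) which.min(abs(t_trial - tt)), 1L)
  S_true <- t(sim$dv_left[j, , drop = FALSE])
  if (noise_sd > 0) {
    n_tr <- nrow(S_true)
    S <- matrix(0, n_tr, length(times))
    for (k in seq_along(times)) {
      S[, k] <- S_true[, k] +
        rowMeans(correlated_noise(n_tr, n_inst, r = r, sd = noise_sd))
    }
  } else S <- S_true
  leverage_behavior(S, trials = sim$trials, times = times, filter = filter)
}
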