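#' Classify direction-selective (Min) neurons from passive viewing
#'
#' A neuron is direction selective if it shows (i) a short-latency visual
#' response to motion onset — a fivefold increase in firing rate relative
#' to the pre-onset baseline within the first 80 ms, and a greater increase
#' in the rate of rise in those 80 ms than any rise in the 200 ms preceding
#' onset — and (ii) direction selectivity: the leftward-vs-rightward AUC of
#' spike counts exceeds 0.6 in either the 0.15-0.3 s or the 0.3-0.5 s
#' epoch. Neurons already labeled Tin are excluded, as are neurons whose
#' preference switches between the two epochs.
#'
#' @param session A passive-viewing \code{dv_session}.
#' @param tin_labels Labels treated as Tin for exclusion.
#' @param min_trials Refuse below this many passive trials.
#' @return Tibble of class \code{ds_classification}: per neuron
#'   \code{is_min}, \code{preferred_dir}, \code{auc_early}, \code{auc_late},
#'   onset-criteria flags and \code{excluded_reason}.
#' @export
classify_ds <- function(session, tin_labels = c("Tin_con", "Tin_ips"),
                        min_trials = 50) {
  stopifnot(inherits(session, "dv_session"), session$kind == "passive")
  trials <- session$trials
  if (nrow(trials) < min_trials) {
    stop(sprintf("only %d passive trials (need >= %d)", nrow(trials),
                 min_trials), call. = FALSE)
  }
  # 25 ms binned rates from -200 ms to 500 ms
  rtc <- bin_and_smooth(session, t_lim = c(-0.1875, 0.4875), step = 0.025,
                        kernel = kernel_spec("boxcar", 25), censor = FALSE)
  tt <- rtc$time
  left <- trials$signed_coh > 0
  n_neu <- dim(rtc$rates)[1]
  res <- purrr::map_dfr(seq_len(n_neu), function(n) {
    m <- rtc$rates[n, , ] # trials x bins
    psth <- colMeans(m, na.rm = TRUE)
    base <- mean(psth[tt < 0])
    early_bins <- tt >= 0 & tt < 0.08
    onset_5x <- max(psth[early_bins]) >= 5 * base
    rise_post <- max(diff(psth[tt < 0.08]), na.rm = TRUE)
    rise_pre <- max(diff(psth[tt < 0]), na.rm = TRUE)
    onset_rise <- rise_post > rise_pre
    cnt <- function(lo, hi) rowMeans(m[, tt >= lo & tt < hi, drop = FALSE]) *
      (hi - lo)
    auc_e <- auc_rank(cnt(0.15, 0.3)[left], cnt(0.15, 0.3)[!left])
    auc_l <- auc_rank(cnt(0.3, 0.5)[left], cnt(0.3, 0.5)[!left])
    tibble::tibble(neuron_id = session$neurons$neuron_id[n],
                   label = session$neurons$label[n],
                   baseline = base, onset_5x = onset_5x,
                   onset_rise = onset_rise,
                   auc_early = auc_e, auc_late = auc_l)
  })
  ds_auc <- pmax(res$auc_early, res$auc_late) > 0.6 |
    pmin(res$auc_early, res$auc_late) < 0.4
  switched <- (res$auc_early > 0.6 & res$auc_late < 0.4) |
    (res$auc_early < 0.4 & res$auc_late > 0.6)
  tin <- res$label %in% tin_labels
  res$excluded_reason <- dplyr::case_when(
    tin ~ "tin_overlap",
    switched ~ "switched_preference",
    .default = "none")
  res$is_min <- res$onset_5x & res$onset_rise & ds_auc &
    res$excluded_reason == "none"
  res$preferred_dir <- ifelse(!res$is_min, NA_character_,
                              ifelse(res$auc_early + res$auc_late >= 1,
                                     "left", "right"))
  class(res) <- c("ds_classification", class(res))
  res
}

#' CUSUM latency of direction-selective responses
#'
#' Accumulates the per-bin (25 ms) difference in spike counts between
#' correct leftward- and rightward-motion trials (RT > 450 ms, |coh| >
#' 10%), then fits a dog-leg function — flat at zero up to the latency
#' \code{t1}, linear afterwards — to the cumulative sum by grid search over
#' \code{t1} at 1 ms resolution with the closed-form least-squares slope.
#'
#' @param session A decision \code{dv_session} (spikes and trials).
#' @param neuron_id Neuron to analyze.
#' @param t_max Upper end of the analysis window (s); latency is searched
#'   on [0, 0.5].
#' @param rt_min,coh_min Trial filters (paper values 0.45 s, 0.10).
#' @return List of class \code{latency_estimate}: \code{latency_s},
#'   \code{slope}, \code{sse}, \code{cusum} (tibble), \code{degenerate}
#'   flag (no direction difference).
#' @export
cusum_latency <- function(session, neuron_id, t_max = 0.5, rt_min = 0.45,
                          coh_min = 0.10) {
  stopifnot(inherits(session, "dv_session"))
  trials <- session$trials
  keep <- trials$correct %in% TRUE & trials$rt_s > rt_min &
    abs(trials$signed_coh) > coh_min
  tl <- trials$trial_id[keep & trials$signed_coh > 0]
  tr <- trials$trial_id[keep & trials$signed_coh < 0]
  if (length(tl) < 5 || length(tr) < 5) {
    stop("too few eligible trials for CUSUM", call. = FALSE)
  }
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  bins <- seq(0, t_max, by = 0.025)
  cnt <- function(ids) {
    s <- sp$t_s[sp$trial_id %in% ids]
    s <- s[s >= 0 & s < t_max]
    tabulate(findInterval(s, bins), nbins = length(bins) - 1) / length(ids)
  }
  d <- cnt(tl) - cnt(tr)
  cusum <- cumsum(d)
  t_bin <- bins[-1] # CUSUM evaluated at bin ends
  # dog leg: 0 on [0, t1], then slope * (t - t1); grid search t1 at 1 ms
  t1_grid <- seq(0, 0.5, by = 0.001)
  sse <- vapply(t1_grid, function(t1) {
    x <- pmax(t_bin - t1, 0)
    if (all(x == 0)) return(sum(cusum^2))
    b <- sum(cusum * x) / sum(x^2)
    sum((cusum - b * x)^2)
  }, 0)
  best <- which.min(sse)
  t1 <- t1_grid[best]
  x <- pmax(t_bin - t1, 0)
  slope <- if (all(x == 0)) 0 else sum(cusum * x) / sum(x^2)
  degenerate <- stats::sd(cusum) < 1e-12 ||
    (max(sse) - min(sse)) < 1e-9 * max(sum(cusum^2), 1e-12)
  structure(list(latency_s = t1, slope = slope, sse = sse[best],
                 cusum = tibble::tibble(t = t_bin, cusum = cusum),
                 degenerate = degenerate, neuron_id = neuron_id),
            class = "latency_estimate")
}

# 25-ms standardized residual count matrices used by the Min/Tin coupling
# analyses: residuals per signed coherence and bin, z-scored per bin, with
# the mean over the last 100 ms before motion onset subtracted per trial.
min_tin_signals <- function(session, t_lim = c(0, 0.5), rt_min = 0.55) {
  trials <- session$trials
  keep <- which(trials$rt_s >= rt_min)
  rtc <- bin_and_smooth(session, t_lim = c(-0.0875, t_lim[2] - 0.0125),
                        step = 0.025, kernel = kernel_spec("boxcar", 25),
                        censor = FALSE)
  lab <- session$neurons$label
  pool <- function(lset) {
    idx <- which(lab %in% lset)
    if (length(idx) == 0) return(NULL)
    m <- apply(rtc$rates[idx, keep, , drop = FALSE], c(2, 3), mean) * 0.025
    m
  }
  std <- function(m) {
    if (is.null(m)) return(NULL)
    g <- trials$signed_coh[keep]
    for (gi in split(seq_along(g), g)) {
      m[gi, ] <- sweep(m[gi, , drop = FALSE], 2,
                       colMeans(m[gi, , drop = FALSE]))
    }
    m <- scale(m) # z-score per bin
    base_cols <- rtc$time < 0
    m - rowMeans(m[, base_cols, drop = FALSE])
  }
  list(time = rtc$time, keep = keep,
       min_l = std(pool("Min_left")), min_r = std(pool("Min_right")),
       tin = std(pool("Tin_con")))
}

#' Min-to-Tin temporal correlation map and ROI test
#'
#' Correlates, across trials, the Min direction signal (difference of
#' standardized residual Min_left and Min_right counts) at time tx with the
#' standardized residual Tin_con signal at time ty, for all 25 ms bins in
#' [0, 0.5] s (trials with RT < 0.55 s discarded). The test statistic is
#' the mean correlation in ROI1 (tx > 100 ms, ty > 200 ms, ty > tx; where
#' an integrator of the Min signal should correlate) minus that in ROI2
#' (same but ty < tx); its null distribution comes from shuffling the trial
#' order of one dimension.
#'
#' @param session A decision \code{dv_session} with Min and Tin neurons.
#' @param n_shuffle Number of trial-order shuffles (default 200).
#' @param seed Integer seed.
#' @return Object of class \code{min_tin_xcorr}: correlation matrix
#'   \code{r} (tx x ty), \code{stat}, null mean/sd, \code{z},
#'   \code{p_value}, and the alternative-ROI2 statistic (tx < 100 ms and
#'   ty < 200 ms).
#' @export
min_tin_xcorr <- function(session, n_shuffle = 200, seed = 1) {
  sg <- min_tin_signals(session)
  if (is.null(sg$min_l) || is.null(sg$min_r) || is.null(sg$tin)) {
    stop("session lacks Min or Tin neurons", call. = FALSE)
  }
  set.seed(seed)
  X <- sg$min_l - sg$min_r
  Y <- sg$tin
  use <- sg$time >= 0
  tx <- ty <- sg$time[use]
  X <- X[, use, drop = FALSE]; Y <- Y[, use, drop = FALSE]
  r <- suppressWarnings(stats::cor(X, Y)) # tx x ty
  TX <- matrix(tx, length(tx), length(ty))
  TY <- matrix(ty, length(tx), length(ty), byrow = TRUE)
  roi1 <- TX > 0.1 & TY > 0.2 & TY > TX
  roi2 <- TX > 0.1 & TY > 0.2 & TY < TX
  roi2_alt <- TX < 0.1 & TY < 0.2
  stat_of <- function(rm) mean(rm[roi1]) - mean(rm[roi2])
  stat <- stat_of(r)
  stat_alt <- mean(r[roi1]) - mean(r[roi2_alt])
  nulls <- vapply(seq_len(n_shuffle), function(s) {
    perm <- sample.int(nrow(X))
    stat_of(suppressWarnings(stats::cor(X[perm, ], Y)))
  }, 0)
  z <- (stat - mean(nulls)) / stats::sd(nulls)
  structure(list(r = r, tx = tx, ty = ty, stat = stat, stat_alt = stat_alt,
                 null_mean = mean(nulls), null_sd = stats::sd(nulls),
                 z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
                 n_shuffle = n_shuffle),
            class = "min_tin_xcorr")
}

#' @export
print.min_tin_xcorr <- function(x, ...) {
  cat(sprintf("min_tin_xcorr: ROI statistic %.4f (null %.4f +/- %.4f), z = %.2f\n",
              x$stat, x$null_mean, x$null_sd, x$z))
  invisible(x)
}

#' Correlation between the Min direction signal and reaction time
#'
#' Per trial, psi is the mean of the standardized Min_left - Min_right
#' difference over 0.1-0.4 s from motion onset; trials with contraversive
#' (left) choices and RT >= 0.5 s are included. The Pearson correlation
#' between psi and the per-coherence z-scored RT is tested one-tailed
#' against the null that it is non-negative.
#'
#' @param session A decision \code{dv_session}.
#' @return List: \code{rho}, \code{p_value} (one-tailed), \code{n}.
#' @export
psi_rt_correlation <- function(session) {
  sg <- min_tin_signals(session, rt_min = 0)
  if (is.null(sg$min_l) || is.null(sg$min_r)) {
    stop("session lacks Min neurons", call. = FALSE)
  }
  trials <- session$trials[sg$keep, ]
  use_t <- sg$time >= 0.1 & sg$time <= 0.4
  psi <- rowMeans((sg$min_l - sg$min_r)[, use_t, drop = FALSE])
  keep <- trials$choice == "left" & trials$rt_s >= 0.5
  rt_z <- demean_by(trials$rt_s, trials$signed_coh) /
    stats::ave(trials$rt_s, trials$signed_coh, FUN = stats::sd)
  rho <- stats::cor(psi[keep], rt_z[keep])
  n <- sum(keep)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = stats::pt(tstat, n - 2), n = n)
}

#' Leverage of Min signals on behavior
#'
#' Applies the leverage machinery to the pooled Min_left and Min_right
#' signals (mean standardized rates of each group), as used for the
#' momentary-evidence comparison: a signal representing momentary evidence
#' (rather than its integral) should show weak leverage that does not grow
#' over time.
#'
#' @param session A decision \code{dv_session}.
#' @param label "Min_left" or "Min_right".
#' @inheritParams leverage_behavior
#' @return A \code{mediation_result}.
#' @export
min_leverage <- function(session, label = "Min_left",
                         times = leverage_times(), filter = trial_filter()) {
  rt50 <- bin_and_smooth(session, t_lim = c(0.15, 0.6), step = 0.025)
  rts <- standardize_neurons(rt50)
  cd <- tin_mean_cd(session, label = label)
  sig <- project_signal(rts, cd)
  leverage_behavior(sig, times = times, filter = filter)
}
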