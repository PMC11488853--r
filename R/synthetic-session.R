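#' Configuration of the synthetic population generator
#'
#' Defines a population whose spiking statistics embody the structure the
#' downstream analyses assume: a minority of neurons with response fields on
#' the contralateral (Tin_con) or ipsilateral (Tin_ips) choice target whose
#' rates follow the latent decision variable with ~200 ms integration onset
#' plus an evidence-independent urgency ramp; direction-selective neurons
#' (Min_left / Min_right) that follow the boxcar-smoothed momentary evidence
#' with ~100 ms latency and no terminal convergence; and untuned "other"
#' neurons. All neurons share a weak common-noise latent calibrated so that
#' residual spike counts in 200 ms windows are correlated at about
#' \code{noise_r} across pairs. Spiking is inhomogeneous Poisson.
#'
#' @param n_neurons Population size (>= 10).
#' @param frac_tin_con,frac_tin_ips,frac_min_left,frac_min_right Category
#'   fractions; defaults are the session-mean fractions of the recordings
#'   the generator emulates (14.5, 7.2, 4.2, 2.5 %).
#' @param baseline_rate Baseline rate of Tin/other neurons (sp/s).
#' @param min_baseline Baseline rate of Min neurons (sp/s).
#' @param dv_gain Tin coupling, sp/s per evidence unit of the DV.
#' @param min_gain Min coupling, sp/s per unit of smoothed momentary
#'   evidence (evidence/s after the 50 ms boxcar).
#' @param urgency_slope Evidence-independent rate ramp (sp/s per s) added to
#'   Tin neurons from integration onset. Default \code{NULL}: set at
#'   generation time to \code{dv_gain * alpha_collapse} of the behavioral
#'   parameters, the rate-level equivalent of the collapsing bound (so
#'   rates on contraversive trials terminate at a common level and the 0%
#'   coherence average rises).
#' @param noise_r Target pairwise count correlation in 200 ms windows.
#' @param noise_block Width (s) of the piecewise-constant shared-noise
#'   latent.
#' @param tin_latency Integration onset of Tin coupling (s after motion on).
#' @param min_latency Latency of Min direction selectivity (s).
#' @param transient_rate Peak of the non-selective visual onset transient of
#'   Min neurons (sp/s above baseline).
#' @param peri_gain Peak of the perisaccadic buildup of Tin neurons whose
#'   response field matches the chosen target (sp/s, ramping over the last
#'   180 ms before the saccade), as seen in target-selective parietal
#'   neurons.
#' @param dt Rate-resolution of the generator (s); spike times are drawn
#'   uniformly within bins, so timestamps are continuous.
#' @param min_coupled If \code{TRUE} (default) Min rates follow the same
#'   momentary-evidence stream the decision variable integrates; if
#'   \code{FALSE} they follow a coherence-matched but trial-shuffled stream
#'   (no within-trial coupling), the control condition for coupling tests.
#' @param other_dv_gain Optional DV coupling of "other" neurons (default 0,
#'   the generator's null for decision-related covariability outside the
#'   labeled classes).
#' @return Object of class \code{population_config}.
#' @export
population_config <- function(n_neurons = 135,
                              frac_tin_con = 0.145, frac_tin_ips = 0.072,
                              frac_min_left = 0.042, frac_min_right = 0.025,
                              baseline_rate = 12, min_baseline = 15,
                              dv_gain = 15, min_gain = 1,
                              urgency_slope = NULL,
                              noise_r = 0.09, noise_block = 0.05,
                              tin_latency = 0.2, min_latency = 0.1,
                              transient_rate = 150, peri_gain = 12,
                              dt = 0.005,
                              min_coupled = TRUE, other_dv_gain = 0) {
  if (n_neurons < 10) stop("n_neurons must be >= 10", call. = FALSE)
  fr <- c(frac_tin_con, frac_tin_ips, frac_min_left, frac_min_right)
  if (any(fr < 0) || sum(fr) > 1) stop("invalid category fractions", call. = FALSE)
  structure(as.list(environment()), class = "population_config")
}

# Deterministic label assignment: round(frac * n) per category, rest "other".
assign_labels <- function(config) {
  n <- config$n_neurons
  counts <- round(n * c(Tin_con = config$frac_tin_con,
                        Tin_ips = config$frac_tin_ips,
                        Min_left = config$frac_min_left,
                        Min_right = config$frac_min_right))
  lab <- rep("other", n)
  i <- 1
  for (k in names(counts)) {
    if (counts[[k]] > 0) {
      lab[i:(i + counts[[k]] - 1)] <- k
      i <- i + counts[[k]]
    }
  }
  lab
}

# Shared-noise amplitude (sp/s) so that two baseline-rate Poisson neurons
# have count correlation ~ r in 200 ms windows:
#   r = a^2 block T / (rate T + a^2 block T)
noise_amplitude <- function(config) {
  with(config, sqrt(noise_r / (1 - noise_r) * baseline_rate / noise_block))
}

#' Correlated noise instantiations
#'
#' Gaussian noise that is independent across time samples and weakly
#' correlated (exchangeably, at level \code{r}) across neurons:
#' \eqn{x_n(t) = \sqrt{r}\, z(t) + \sqrt{1-r}\,\epsilon_n(t)}. This is the
#' nuisance noise used when turning a simulated decision variable into a
#' small population of noisy instantiations.
#'
#' @param n_samples Number of time samples (rows).
#' @param n_neurons Number of neurons (columns).
#' @param r Target pairwise correlation; default 0.09.
#' @param sd Marginal standard deviation.
#' @return Matrix \code{n_samples x n_neurons}.
#' @export
correlated_noise <- function(n_samples, n_neurons, r = 0.09, sd = 1) {
  z <- stats::rnorm(n_samples)
  eps <- matrix(stats::rnorm(n_samples * n_neurons), n_samples, n_neurons)
  sd * (sqrt(r) * z + sqrt(1 - r) * eps)
}

#' Generate a synthetic decision session
#'
#' Simulates the race model for each trial, couples neuron firing rates to
#' the latent decision variable (Tin), to the smoothed momentary evidence
#' (Min), or to neither (other), adds the shared noise and an urgency ramp,
#' rectifies at zero, and draws inhomogeneous Poisson spikes from 300 ms
#' before motion onset until 150 ms after the saccade. Ground truth (labels,
#' coupling weights, DV paths) is retained.
#'
#' @param config A [population_config()].
#' @param ddm_params A [ddm_params()] object (behavioral ground truth).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param coherences Signed coherence set; default [default_coherences()].
#' @return Object of class \code{dv_session} with elements \code{trials},
#'   \code{spikes}, \code{neurons} (with ground-truth \code{label} and
#'   \code{truth_weight}), \code{dv} (latent paths: \code{time},
#'   \code{left}, \code{right} matrices trials x time), \code{config},
#'   \code{params}, \code{kind = "decision"}.
#' @export
generate_decision_session <- function(config, ddm_params, n_trials = 2000,
                                      seed = 1,
                                      coherences = default_coherences()) {
  stopifnot(inherits(config, "population_config"),
            inherits(ddm_params, "ddm_params"))
  set.seed(seed)
  if (is.null(config$urgency_slope)) {
    config$urgency_slope <- config$dv_gain * ddm_params$alpha_collapse
  }
  coh <- sample(rep(coherences, length.out = n_trials))
  path_t_max <- 1.8
  sim <- simulate_race(ddm_params, coherences = coh, n_per_coh = 1,
                       dt = 0.001, keep_paths = TRUE,
                       path_t_max = path_t_max, path_dt = config$dt)
  trials <- sim$trials
  trials$motion_on_s <- 0
  trials$saccade_s <- trials$rt_s

  labels <- assign_labels(config)
  n_neurons <- config$n_neurons
  gain_jit <- stats::runif(n_neurons, 0.6, 1.4)
  truth <- numeric(n_neurons)
  truth[labels == "Tin_con"] <- config$dv_gain * gain_jit[labels == "Tin_con"]
  truth[labels == "Tin_ips"] <- -config$dv_gain * gain_jit[labels == "Tin_ips"]
  neurons <- tibble::tibble(neuron_id = seq_len(n_neurons), label = labels,
                            truth_weight = truth)

  # per-trial evidence stream for Min neurons (possibly trial-shuffled)
  ev_src <- seq_len(nrow(trials))
  if (!config$min_coupled) {
    for (cc in unique(trials$signed_coh)) {
      idx <- which(trials$signed_coh == cc)
      ev_src[idx] <- idx[sample.int(length(idx))]
    }
  }

  sp <- generate_spikes(config, trials, labels, gain_jit,
                        dv_left = sim$dv_left, dv_right = sim$dv_right,
                        ev_left = sim$ev_left[, ev_src, drop = FALSE],
                        path_time = sim$path_time, kind = "decision")

  structure(list(trials = trials, spikes = sp$spikes, neurons = neurons,
                 dv = list(time = sim$path_time, left = t(sim$dv_left),
                           right = t(sim$dv_right)),
                 zero_rate_frac = sp$zero_rate_frac,
                 config = config, params = ddm_params, kind = "decision"),
            class = "dv_session")
}

# Rate construction + Poisson spike draw shared by the session generators.
# dv_* and ev_left are path-time x trial matrices in integration time
# (trial time minus tin_latency for the DV; the evidence stream is shifted
# by min_latency).
generate_spikes <- function(config, trials, labels, gain_jit,
                            dv_left = NULL, dv_right = NULL, ev_left = NULL,
                            path_time = NULL, kind = "decision",
                            t_start = -0.3) {
  n_tr <- nrow(trials)
  n_neurons <- config$n_neurons
  dt <- config$dt
  a_noise <- noise_amplitude(config)
  base <- ifelse(labels %in% c("Min_left", "Min_right"),
                 config$min_baseline, config$baseline_rate)
  is_tin_con <- labels == "Tin_con"; is_tin_ips <- labels == "Tin_ips"
  is_min_l <- labels == "Min_left"; is_min_r <- labels == "Min_right"
  is_other <- labels == "other"
  w_box <- 0.05 # boxcar for the momentary-evidence rate (s)

  ids <- list(); times <- list(); tr_ids <- list()
  zero_frac <- numeric(0)
  t_end_all <- if (kind == "passive") rep(0.5, n_tr) else trials$saccade_s + 0.15

  for (i in seq_len(n_tr)) {
    t_end <- t_end_all[i]
    tg <- seq(t_start + dt / 2, t_end, by = dt) # bin centers
    nb <- length(tg)
    R <- matrix(rep(base, each = nb), nb, n_neurons)

    if (!is.null(dv_left)) {
      # DV value at trial time t: path index of (t - tin_latency)
      pi_ <- findInterval(tg - config$tin_latency, path_time)
      dvl <- c(0, dv_left[, i])[pi_ + 1L]
      dvr <- c(0, dv_right[, i])[pi_ + 1L]
      # hold the frozen value beyond the retained path
      dvl[pi_ >= length(path_time)] <- dv_left[nrow(dv_left), i]
      dvr[pi_ >= length(path_time)] <- dv_right[nrow(dv_right), i]
      urg <- config$urgency_slope * pmax(tg - config$tin_latency, 0)
      R[, is_tin_con] <- R[, is_tin_con] +
        outer(dvl, config$dv_gain * gain_jit[is_tin_con]) + urg
      R[, is_tin_ips] <- R[, is_tin_ips] +
        outer(dvr, config$dv_gain * gain_jit[is_tin_ips]) + urg
      if (config$other_dv_gain != 0) {
        R[, is_other] <- R[, is_other] +
          outer(dvl, config$other_dv_gain * gain_jit[is_other])
      }
      if (kind == "decision" && config$peri_gain > 0 &&
          !is.na(trials$saccade_s[i])) {
        peri <- config$peri_gain *
          pmax(1 - (trials$saccade_s[i] - tg) / 0.18, 0)
        tuned <- if (trials$choice[i] == "left") is_tin_con else is_tin_ips
        R[, tuned] <- R[, tuned] + peri
      }
    }
    if (!is.null(ev_left) && any(is_min_l | is_min_r)) {
      # smoothed momentary evidence at trial time t: causal boxcar over the
      # physical-evidence times [t - min_latency - w, t - min_latency]
      s <- tg - config$min_latency
      evf <- function(q) {
        j <- findInterval(q, path_time)
        v <- c(0, ev_left[, i])[pmax(j, 0) + 1L]
        v[j >= length(path_time)] <- ev_left[nrow(ev_left), i]
        v
      }
      ev_sm <- (evf(s) - evf(s - w_box)) / w_box
      R[, is_min_l] <- R[, is_min_l] + outer(ev_sm, config$min_gain * gain_jit[is_min_l])
      R[, is_min_r] <- R[, is_min_r] - outer(ev_sm, config$min_gain * gain_jit[is_min_r])
    }
    if (any(is_min_l | is_min_r) && config$transient_rate > 0) {
      # non-selective visual onset transient, latency 40 ms, 50 ms decay
      tr_shape <- config$transient_rate *
        exp(-pmax(tg - 0.04, 0) / 0.05) * (tg >= 0.04)
      R[, is_min_l | is_min_r] <- R[, is_min_l | is_min_r] + tr_shape
    }
    # shared noise: piecewise-constant latent common to all neurons
    nblk <- ceiling((t_end - t_start) / config$noise_block)
    z <- rep(stats::rnorm(nblk), each = ceiling(config$noise_block / dt))[seq_len(nb)]
    R <- R + a_noise * z

    zero_frac <- c(zero_frac, mean(R <= 0))
    R[R < 0] <- 0
    counts <- matrix(stats::rpois(nb * n_neurons, R * dt), nb, n_neurons)
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      reps <- counts[nz]
      rows <- rep(nz[, 1], reps); cols <- rep(nz[, 2], reps)
      ids[[i]] <- cols
      times[[i]] <- tg[rows] - dt / 2 + stats::runif(length(rows)) * dt
      tr_ids[[i]] <- rep(trials$trial_id[i], length(rows))
    }
  }
  zf <- mean(zero_frac)
  if (zf > 0.5) {
    warning(sprintf("rates rectified to zero for %.0f%% of time bins; check config",
                    100 * zf), call. = FALSE)
  }
  spikes <- tibble::tibble(neuron_id = unlist(ids),
                           trial_id = unlist(tr_ids),
                           t_s = unlist(times))
  spikes <- spikes[order(spikes$neuron_id, spikes$trial_id, spikes$t_s), ]
  list(spikes = spikes, zero_rate_frac = zf)
}

#' Generate a synthetic passive-viewing session
#'
#' Only the strongest motion strength (+/- 51.2% coherence) is shown, for
#' 500 ms, with no choice. Min neurons show a non-selective onset transient
#' and direction selectivity from \code{min_latency}; Tin and other neurons
#' are untuned.
#'
#' @inheritParams generate_decision_session
#' @param n_trials Number of passive trials.
#' @return A \code{dv_session} with \code{kind = "passive"}; trials carry
#'   \code{signed_coh} (+/- 0.512) and a 500 ms motion epoch.
#' @export
generate_passive_session <- function(config, ddm_params = ddm_params_monkey("M"),
                                     n_trials = 400, seed = 1) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(config$urgency_slope)) config$urgency_slope <- 0
  set.seed(seed)
  coh <- sample(rep(c(-0.512, 0.512), length.out = n_trials))
  # momentary-evidence streams only (no bounds, no choice)
  n_steps <- round(0.6 / config$dt)
  mu <- ddm_params$kappa * (coh + ddm_params$C0)
  ev <- matrix(stats::rnorm(n_steps * n_trials, sd = sqrt(config$dt)),
               n_steps, n_trials)
  ev <- apply(ev + rep(mu * config$dt, each = n_steps), 2, cumsum)
  path_time <- seq_len(n_steps) * config$dt

  trials <- tibble::tibble(trial_id = seq_len(n_trials), signed_coh = coh,
                           choice = NA_character_, rt_s = NA_real_,
                           motion_on_s = 0, saccade_s = NA_real_,
                           correct = NA)
  labels <- assign_labels(config)
  gain_jit <- stats::runif(config$n_neurons, 0.6, 1.4)
  sp <- generate_spikes(config, trials, labels, gain_jit,
                        ev_left = ev, path_time = path_time, kind = "passive")
  neurons <- tibble::tibble(neuron_id = seq_len(config$n_neurons),
                            label = labels, truth_weight = 0)
  structure(list(trials = trials, spikes = sp$spikes, neurons = neurons,
                 config = config, params = ddm_params, kind = "passive"),
            class = "dv_session")
}

#' Generate a synthetic delayed-saccade session
#'
#' One target at one of eight locations; after a truncated-exponential
#' delay the fixation point is extinguished and a saccade follows. Tin_con
#' neurons respond selectively (visual, delay, and perisaccadic epochs)
#' when the target is at the contralateral choice location (location 1),
#' Tin_ips at the ipsilateral location (location 5); other neurons are
#' untuned.
#'
#' @inheritParams generate_decision_session
#' @param n_per_loc Trials per target location.
#' @param tuned_gain Added rate (sp/s) at the preferred location.
#' @return A \code{dv_session} with \code{kind = "delayed_saccade"}; trials
#'   carry \code{target_loc} (1..8), \code{go_s} and \code{saccade_s}.
#' @export
generate_delayed_saccade_session <- function(config, n_per_loc = 40, seed = 1,
                                             tuned_gain = 15) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed)
  n_trials <- 8 * n_per_loc
  loc <- sample(rep(1:8, n_per_loc))
  delay <- sample_truncated_exp(delay_spec(0.4, 1.1, 0.3), n_trials)
  sac_lat <- pmax(stats::rnorm(n_trials, 0.2, 0.04), 0.08)
  trials <- tibble::tibble(trial_id = seq_len(n_trials), target_loc = loc,
                           go_s = delay, saccade_s = delay + sac_lat,
                           motion_on_s = NA_real_)
  labels <- assign_labels(config)
  n_neurons <- config$n_neurons
  dt <- config$dt
  a_noise <- noise_amplitude(config)
  pref <- rep(NA_integer_, n_neurons)
  pref[labels == "Tin_con"] <- 1L
  pref[labels == "Tin_ips"] <- 5L

  ids <- list(); times <- list(); tr_ids <- list()
  for (i in seq_len(n_trials)) {
    t_end <- trials$saccade_s[i] + 0.15
    tg <- seq(-0.2 + dt / 2, t_end, by = dt)
    nb <- length(tg)
    R <- matrix(config$baseline_rate, nb, n_neurons)
    tuned <- !is.na(pref) & pref == loc[i]
    if (any(tuned)) {
      # visual transient + sustained delay activity + perisaccadic ramp
      vis <- 1.5 * exp(-pmax(tg - 0.05, 0) / 0.08) * (tg >= 0.05)
      sus <- 1.0 * (tg >= 0.05)
      peri <- 1.2 * pmax(1 - abs(tg - trials$saccade_s[i]) / 0.1, 0)
      R[, tuned] <- R[, tuned] + tuned_gain * (vis + sus + peri)
    }
    nblk <- ceiling((t_end + 0.2) / config$noise_block)
    z <- rep(stats::rnorm(nblk), each = ceiling(config$noise_block / dt))[seq_len(nb)]
    R <- pmax(R + a_noise * z, 0)
    counts <- matrix(stats::rpois(nb * n_neurons, R * dt), nb, n_neurons)
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      reps <- counts[nz]
      ids[[i]] <- rep(nz[, 2], reps)
      times[[i]] <- tg[rep(nz[, 1], reps)] - dt / 2 +
        stats::runif(sum(reps)) * dt
      tr_ids[[i]] <- rep(i, sum(reps))
    }
  }
  spikes <- tibble::tibble(neuron_id = unlist(ids), trial_id = unlist(tr_ids),
                           t_s = unlist(times))
  neurons <- tibble::tibble(neuron_id = seq_len(n_neurons), label = labels,
                            truth_weight = 0)
  structure(list(trials = trials, spikes = spikes, neurons = neurons,
                 config = config, kind = "delayed_saccade"),
            class = "dv_session")
}

#' @export
print.dv_session <- function(x, ...) {
  cat(sprintf("dv_session (%s): %d trials, %d neurons, %d spikes\n",
              x$kind, nrow(x$trials), nrow(x$neurons), nrow(x$spikes)))
  print(table(x$neurons$label))
  invisible(x)
}
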