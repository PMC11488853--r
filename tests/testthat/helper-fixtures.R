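# Shared fixtures, built once per test run and cached. Sizes are chosen to
# keep the default suite fast while leaving enough statistical power for
# the property checks; the acceptance tests use larger, criterion-stated
# sizes.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

params_m <- function() ddm_params_monkey("M")

# mid-sized decision session used by most signal/CD/mediation tests
fix_session <- function() fixture("session", function() {
  generate_decision_session(population_config(n_neurons = 60),
                            params_m(), n_trials = 1200, seed = 42)
})

fix_rt25_std <- function() fixture("rt25_std", function() {
  standardize_neurons(bin_and_smooth(fix_session(),
                                     t_lim = c(0.15, 0.62), step = 0.025))
})

fix_ramp <- function() fixture("ramp", function() ramp_cd(fix_session()))
fix_pc1 <- function() fixture("pc1", function() pc1_cd(fix_session(), fix_rt25_std()))
fix_tin <- function() fixture("tin", function() tin_mean_cd(fix_session()))

fix_sig_ramp <- function() fixture("sig_ramp", function() {
  project_signal(fix_rt25_std(), fix_ramp())
})

fix_passive <- function() fixture("passive", function() {
  generate_passive_session(population_config(n_neurons = 60), params_m(),
                           n_trials = 400, seed = 7)
})

# small race simulation with retained paths for DV-level tests
fix_race_paths <- function() fixture("race_paths", function() {
  simulate_race(params_m(), n_per_coh = 300, seed = 3, keep_paths = TRUE,
                path_t_max = 1.2, path_dt = 0.005)
})

# synthetic session with a planted direction-selective neuron set and known
# latency, built directly from rates (used by classifier/CUSUM tests)
make_planted_ds_session <- function(n_trials = 400, latency = 0.1,
                                    seed = 1, rate_gain = 20,
                                    onset_peak = 80, baseline = 12,
                                    kind = "passive") {
  set.seed(seed)
  coh <- sample(rep(c(-0.512, 0.512), length.out = n_trials))
  dt <- 0.005
  tg <- seq(-0.3 + dt / 2, 0.5, by = dt)
  labels <- c("Min_left", "Min_right", "other", "other", "Tin_con",
              rep("other", 7))
  n_neu <- length(labels)
  ids <- list(); times <- list(); trs <- list()
  rt_s <- if (kind == "decision") stats::runif(n_trials, 0.5, 1.2) else NA
  for (i in seq_len(n_trials)) {
    R <- matrix(baseline, length(tg), n_neu)
    trans <- onset_peak * exp(-pmax(tg - 0.045, 0) / 0.035) * (tg >= 0.045)
    ds <- rate_gain * sign(coh[i]) * (tg >= latency)
    R[, 1] <- R[, 1] + trans + ds
    R[, 2] <- R[, 2] + trans - ds
    R <- pmax(R, 0)
    cnt <- matrix(stats::rpois(length(tg) * n_neu, R * dt), length(tg), n_neu)
    nz <- which(cnt > 0, arr.ind = TRUE)
    reps <- cnt[nz]
    ids[[i]] <- rep(nz[, 2], reps)
    times[[i]] <- tg[rep(nz[, 1], reps)] - dt / 2 + stats::runif(sum(reps)) * dt
    trs[[i]] <- rep(i, sum(reps))
  }
  trials <- tibble::tibble(trial_id = seq_len(n_trials), signed_coh = coh,
                           choice = ifelse(coh > 0, "left", "right"),
                           rt_s = rt_s, motion_on_s = 0, saccade_s = rt_s,
                           correct = TRUE)
  structure(list(trials = trials,
                 spikes = tibble::tibble(neuron_id = unlist(ids),
                                         trial_id = unlist(trs),
                                         t_s = unlist(times)),
                 neurons = tibble::tibble(neuron_id = seq_len(n_neu),
                                          label = labels, truth_weight = 0),
                 config = population_config(n_neurons = 12),
                 kind = kind),
            class = "dv_session")
}

# brute-force AUC (pairwise comparisons) — independent of the package's
# rank-based implementation
auc_left_right <- function(x, pos) {
  a <- x[pos]; b <- x[!pos]
  (sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))) /
    (length(a) * length(b))
}

demean_by <- function(x, g) x - stats::ave(x, g, FUN = mean)

new_cd_for_test <- function(n) {
  structure(list(weights = rnorm(n), method = "custom", offset = 0,
                 training_meta = list()), class = "coding_direction")
}

# large default-configuration decision session shared by acceptance and
# Min-coupling tests
acc_session <- function() fixture("acc_session", function() {
  generate_decision_session(population_config(), params_m(),
                            n_trials = 2000, seed = 101)
})
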