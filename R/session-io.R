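#' Write a session to plain-text tables
#'
#' Writes \code{trials.csv}, \code{spikes.csv}, \code{neurons.csv} and a
#' \code{manifest.json} (kind, seed/config provenance when available) into
#' a directory.
#'
#' @param session A \code{dv_session}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "dv_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(session$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  manifest <- list(kind = session$kind,
                   n_trials = nrow(session$trials),
                   n_neurons = nrow(session$neurons),
                   config = session$config[setdiff(names(session$config),
                                                   c())])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from plain-text tables
#'
#' Counterpart of [write_session()]; validates the schema and basic
#' invariants (required columns, positive RTs, spike times within the
#' recorded trial window, labels from the closed vocabulary) and names the
#' offending rows on failure.
#'
#' @param dir Directory containing \code{trials.csv}, \code{spikes.csv},
#'   \code{neurons.csv}.
#' @return A \code{dv_session} (without generator ground truth beyond what
#'   the tables carry).
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("trials.csv", "spikes.csv", "neurons.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing session files: ",
                         paste(basename(miss), collapse = ", "), call. = FALSE)
  trials <- tibble::as_tibble(utils::read.csv(need[1]))
  spikes <- tibble::as_tibble(utils::read.csv(need[2]))
  neurons <- tibble::as_tibble(utils::read.csv(need[3]))
  kind <- "decision"
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) kind <- jsonlite::read_json(mf)$kind %||% "decision"
  validate_session_tables(trials, spikes, neurons, kind)
  structure(list(trials = trials, spikes = spikes, neurons = neurons,
                 kind = kind),
            class = "dv_session")
}

validate_session_tables <- function(trials, spikes, neurons, kind) {
  req_tr <- c("trial_id", "signed_coh")
  if (kind == "decision") req_tr <- c(req_tr, "choice", "rt_s")
  for (cn in req_tr) {
    if (!cn %in% names(trials)) {
      stop("trials table lacks column '", cn, "'", call. = FALSE)
    }
  }
  if (nrow(trials) == 0) stop("empty session: no trials", call. = FALSE)
  for (cn in c("neuron_id", "trial_id", "t_s")) {
    if (!cn %in% names(spikes)) {
      stop("spikes table lacks column '", cn, "'", call. = FALSE)
    }
  }
  for (cn in c("neuron_id", "label")) {
    if (!cn %in% names(neurons)) {
      stop("neurons table lacks column '", cn, "'", call. = FALSE)
    }
  }
  if (kind == "decision") {
    bad <- which(!is.na(trials$rt_s) & trials$rt_s <= 0)
    if (length(bad)) stop("non-positive RT in trials row(s) ",
                          paste(utils::head(bad, 5), collapse = ", "),
                          call. = FALSE)
  }
  vocab <- c("Tin_con", "Tin_ips", "Min_left", "Min_right", "other")
  badlab <- which(!neurons$label %in% vocab)
  if (length(badlab)) stop("unknown neuron label in neurons row(s) ",
                           paste(utils::head(badlab, 5), collapse = ", "),
                           call. = FALSE)
  orphan <- which(!spikes$trial_id %in% trials$trial_id)
  if (length(orphan)) stop("spikes reference unknown trial in row(s) ",
                           paste(utils::head(orphan, 5), collapse = ", "),
                           call. = FALSE)
  if (kind == "decision") {
    rt <- trials$rt_s[match(spikes$trial_id, trials$trial_id)]
    bad_t <- which(spikes$t_s < -0.35 | spikes$t_s > rt + 0.2)
    if (length(bad_t)) stop("spike time outside trial window in row(s) ",
                            paste(utils::head(bad_t, 5), collapse = ", "),
                            call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the standard stage order — simulate/generate, derive coding
#' directions, project signals, diffusion diagnostics, leverage/mediation,
#' Min analyses — and returns one report per stage. Stages can be
#' restricted; dependencies are created on demand.
#'
#' @param config A [population_config()].
#' @param ddm_params A [ddm_params()].
#' @param n_trials Trials in the generated decision session.
#' @param seed Master seed; stage-level substreams are derived from it.
#' @param stages Character subset of
#'   \code{c("session", "coding_directions", "signals", "diffusion",
#'   "mediation", "min")}.
#' @return Named list of stage reports (class \code{dv_pipeline}), with
#'   timing per stage.
#' @export
run_pipeline <- function(config = population_config(),
                         ddm_params = ddm_params_monkey("M"),
                         n_trials = 1000, seed = 1,
                         stages = c("session", "coding_directions",
                                    "signals", "diffusion", "mediation",
                                    "min")) {
  all_stages <- c("session", "coding_directions", "signals", "diffusion",
                  "mediation", "min")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- list()
  timing <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  session <- generate_decision_session(config, ddm_params,
                                       n_trials = n_trials,
                                       seed = substream_seed(seed, "population"))
  timing["session"] <- lap(t0)
  if ("session" %in% stages) {
    out$session <- list(n_trials = nrow(session$trials),
                        n_neurons = nrow(session$neurons),
                        label_counts = as.list(table(session$neurons$label)))
  }
  needs_cd <- any(c("coding_directions", "signals", "diffusion",
                    "mediation") %in% stages)
  if (needs_cd) {
    t0 <- tic()
    rt25 <- bin_and_smooth(session, t_lim = c(0.15, 0.62), step = 0.025)
    rts <- standardize_neurons(rt25)
    cds <- list(ramp = ramp_cd(session), pc1 = pc1_cd(session, rts),
                tin = tin_mean_cd(session))
    timing["coding_directions"] <- lap(t0)
    if ("coding_directions" %in% stages) {
      out$coding_directions <- list(
        cosine_ramp_pc1 = cosine_similarity(cds$ramp, cds$pc1),
        cosine_ramp_tin = cosine_similarity(cds$ramp, cds$tin),
        cosine_ramp_truth = cosine_similarity(cds$ramp$weights,
                                              session$neurons$truth_weight),
        participation_ratio = cds$pc1$training_meta$participation_ratio)
    }
  }
  if (any(c("signals", "diffusion", "mediation") %in% stages)) {
    t0 <- tic()
    sig <- project_signal(rts, cds$ramp)
    timing["signals"] <- lap(t0)
    if ("signals" %in% stages) {
      cm <- condition_means(sig)
      at_t <- cm[abs(cm$t - 0.45) < 0.013, ]
      out$signals <- list(
        coh_ordering_spearman = stats::cor(at_t$signed_coh, at_t$mean,
                                           method = "spearman"),
        urgency_at_0.5 = estimate_urgency(sig)$u[which.min(abs(sig$time - 0.5))])
    }
  }
  if ("diffusion" %in% stages) {
    t0 <- tic()
    rt1 <- bin_and_smooth(session, t_lim = c(0.175, 0.54), step = 0.001,
                          kernel = kernel_spec("boxcar", 51))
    sig1 <- detrend_signal(project_signal(rt1, cds$ramp), baseline_t = 0.2)
    low <- abs(session$trials$signed_coh) <= 0.032 + 1e-9
    samp <- sample_signal(sig1, 0.226 + 0.051 * (0:5))[low, ]
    emp <- empirical_var_autocorr(samp,
                                  session$trials$signed_coh[low],
                                  n_boot = 200)
    ph <- fit_phi(emp, wiener_theory())
    timing["diffusion"] <- lap(t0)
    out$diffusion <- list(var_curve = emp$var_curve, phi = ph$phi,
                          n_trials = emp$n)
  }
  if ("mediation" %in% stages) {
    t0 <- tic()
    med <- leverage_behavior(sig)
    timing["mediation"] <- lap(t0)
    out$mediation <- list(xi_ch = med$xi_ch, xi_rt = med$xi_rt,
                          n_trials = med$n_trials)
  }
  if ("min" %in% stages) {
    t0 <- tic()
    xc <- try(min_tin_xcorr(session), silent = TRUE)
    psi <- try(psi_rt_correlation(session), silent = TRUE)
    timing["min"] <- lap(t0)
    out$min <- list(
      xcorr_z = if (inherits(xc, "try-error")) NA_real_ else xc$z,
      psi_rho = if (inherits(psi, "try-error")) NA_real_ else psi$rho,
      psi_p = if (inherits(psi, "try-error")) NA_real_ else psi$p_value)
  }
  structure(list(reports = out, timing = timing, seed = seed),
            class = "dv_pipeline")
}

#' @export
print.dv_pipeline <- function(x, ...) {
  cat("dv_pipeline:", paste(names(x$reports), collapse = ", "), "\n")
  cat("timing (s):", paste(sprintf("%s %.1f", names(x$timing), x$timing),
                           collapse = ", "), "\n")
  invisible(x)
}
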