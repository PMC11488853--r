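#' Simulate the anticorrelated race model
#'
#' Euler simulation of the bounded race between two negatively correlated
#' accumulators at time step \code{dt}. The accumulator that first reaches
#' its collapsing bound determines the choice and the decision time; the
#' decision-variable paths are frozen at the values attained at termination
#' and remain constant until the response. Reaction time is assembled as
#' \code{pre_latency + decision_time + post}, where \code{post} is a Gaussian
#' post-termination latency clipped at zero. Trials still undecided at
#' \code{t_max} are resolved by the accumulator closest to its bound.
#'
#' @param params A [ddm_params] object.
#' @param coherences Signed coherences to simulate; default
#'   [default_coherences()]. Positive = leftward (contraversive).
#' @param n_per_coh Trials per coherence.
#' @param dt Simulation time step (s); default 0.001.
#' @param t_max Maximum integration time (s); default 5.
#' @param seed Optional integer seed.
#' @param keep_paths If \code{TRUE}, retain decision-variable paths (both
#'   accumulators, frozen at termination) and the unfrozen cumulative
#'   evidence stream for the left accumulator, thinned to \code{path_dt}
#'   resolution up to \code{path_t_max} seconds of integration time.
#' @param path_t_max,path_dt Path retention horizon and resolution (s).
#'
#' @return An object of class \code{race_trials}: a list with
#'   \item{trials}{tibble with \code{trial_id}, \code{signed_coh},
#'     \code{choice} ("left"/"right"), \code{rt_s}, \code{decision_time_s},
#'     \code{nd_pre_s}, \code{nd_post_s}, \code{correct}, \code{undecided}.
#'     Trial order is randomized so that even/odd splits are balanced across
#'     coherences.}
#'   \item{dv_left, dv_right}{(if \code{keep_paths}) matrices, time x trial,
#'     of the frozen accumulator paths, in integration time.}
#'   \item{ev_left}{(if \code{keep_paths}) unfrozen cumulative evidence of
#'     the left accumulator (pure diffusion continues past termination).}
#'   \item{path_time}{time base of the paths (s from integration onset).}
#' @examples
#' p <- ddm_params_monkey("M")
#' sim <- simulate_race(p, n_per_coh = 50, seed = 1)
#' head(sim$trials)
#' @export
simulate_race <- function(params, coherences = default_coherences(),
                          n_per_coh = 1000, dt = 0.001, t_max = 5,
                          seed = NULL, keep_paths = FALSE,
                          path_t_max = 1.5, path_dt = 0.005) {
  stopifnot(inherits(params, "ddm_params"))
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (length(coherences) == 0) stop("empty coherence list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  coh <- rep(coherences, each = n_per_coh)
  n <- length(coh)
  mu <- params$kappa * (coh + params$C0)
  thin <- max(1L, as.integer(round(path_dt / dt)))
  path_steps <- if (keep_paths) as.integer(floor(path_t_max / dt / thin)) else 0L

  res <- cpp_simulate_race(mu, dt, params$rho, params$B0,
                           params$alpha_collapse,
                           params$bound_floor_frac * params$B0,
                           t_max, path_steps, thin)

  post <- pmax(stats::rnorm(n, params$post_latency_mu, params$post_latency_sd), 0)
  trials <- tibble::tibble(
    trial_id = seq_len(n),
    signed_coh = coh,
    choice = ifelse(res$choice == 0L, "left", "right"),
    decision_time_s = res$decision_time,
    nd_pre_s = params$pre_latency,
    nd_post_s = post,
    rt_s = params$pre_latency + res$decision_time + post,
    undecided = as.logical(res$undecided)
  )
  trials$correct <- ifelse(trials$signed_coh == 0, TRUE,
                           (trials$signed_coh > 0) == (trials$choice == "left"))

  ord <- sample.int(n)
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(n)

  out <- list(trials = trials, params = params, dt = dt)
  if (keep_paths) {
    out$dv_left <- res$dv_left[, ord, drop = FALSE]
    out$dv_right <- res$dv_right[, ord, drop = FALSE]
    out$ev_left <- res$ev_left[, ord, drop = FALSE]
    out$path_time <- seq_len(path_steps) * thin * dt
  }
  structure(out, class = "race_trials")
}

#' @export
print.race_trials <- function(x, ...) {
  cat(sprintf("race_trials: %d trials, %d coherences%s\n",
              nrow(x$trials), length(unique(x$trials$signed_coh)),
              if (!is.null(x$dv_left)) ", with DV paths" else ""))
  print(utils::head(x$trials, 3))
  invisible(x)
}

#' Draw momentary-evidence increment pairs
#'
#' Samples the per-step momentary evidence of the two accumulators: a
#' bivariate Normal with means \code{+/- kappa * (coh + C0) * dt}, variance
#' \code{dt} each, and correlation \code{rho}. Used to verify the evidence
#' anticorrelation of the race.
#'
#' @param n Number of increment pairs.
#' @param params A [ddm_params] object.
#' @param coh Signed coherence (default 0).
#' @param dt Time step (s).
#' @return A matrix with columns \code{left}, \code{right}.
#' @examples
#' p <- ddm_params_monkey("M")
#' set.seed(1)
#' cor(race_increments(1e4, p))[1, 2] # ~ -0.71
#' @export
race_increments <- function(n, params, coh = 0, dt = 0.001) {
  stopifnot(inherits(params, "ddm_params"))
  m <- params$kappa * (coh + params$C0) * dt
  z1 <- stats::rnorm(n)
  z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * stats::rnorm(n)
  cbind(left = m + sqrt(dt) * z1, right = -m + sqrt(dt) * z2)
}
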