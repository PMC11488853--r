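#' Fit the race model to choice and reaction-time data
#'
#' Maximum-likelihood fit of the six behavioral parameters (\code{kappa},
#' \code{B0}, \code{alpha_collapse}, \code{mu_nd}, \code{sigma_nd},
#' \code{C0}); the evidence anticorrelation \code{rho} is fixed. The
#' likelihood of each trial is the predicted RT density for its choice at
#' its RT, computed with [fpt_solve()] and the Gaussian non-decision-time
#' convolution. The search is multi-start Nelder-Mead over
#' (\code{kappa}, \code{B0}, \code{alpha_collapse}, \code{C0}) with
#' positivity enforced by log transforms; \code{mu_nd} and \code{sigma_nd}
#' are profiled out in an inner optimization (they enter only through a
#' cheap convolution). Starts are run on a coarse solver grid and the best
#' is polished on a finer one.
#'
#' @param trials Data frame with columns \code{signed_coh}, \code{choice}
#'   ("left"/"right"), \code{rt_s}. At least two coherences, positive RTs.
#' @param rho Fixed accumulator correlation.
#' @param n_starts Number of Nelder-Mead starts (first start is a
#'   data-driven initialization, the rest are jittered).
#' @param seed Integer seed for the start jitter.
#' @param rt_cap Trials with RT above this value (s) are dropped from the
#'   likelihood (they are a sub-percent tail under the collapsing bound)
#'   and the solver horizon is set to it.
#' @param stages List of solver/optimizer settings (\code{dt}, \code{h},
#'   \code{maxit}) for successive refinement stages; the multi-start runs
#'   on the first, later stages polish the best solution on finer grids.
#' @param verbose Print stage progress.
#'
#' @return Object of class \code{ddm_fit}: fitted [ddm_params], \code{logLik},
#'   \code{convergence} flag (\code{TRUE} if the polish stage converged;
#'   non-convergence is flagged, never silent), number of likelihood
#'   evaluations, and the per-start results.
#' @examples
#' \donttest{
#' p <- ddm_params_monkey("M")
#' sim <- simulate_race(p, n_per_coh = 500, seed = 1)
#' fit <- fit_ddm(sim$trials, n_starts = 2,
#'                stages = list(list(dt = 0.0125, h = 0.09, maxit = 30),
#'                              list(dt = 0.0075, h = 0.065, maxit = 40)))
#' tidy(fit)
#' }
#' @export
fit_ddm <- function(trials, rho = -sqrt(0.5), n_starts = 5, seed = 1,
                    rt_cap = 2.3,
                    stages = list(list(dt = 0.0125, h = 0.09, maxit = 50),
                                  list(dt = 0.0075, h = 0.065, maxit = 110),
                                  list(dt = 0.005, h = 0.05, maxit = 50)),
                    verbose = FALSE) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("signed_coh", "choice", "rt_s") %in% names(trials)))
  if (any(trials$rt_s <= 0)) stop("RTs must be positive", call. = FALSE)
  # trials beyond rt_cap enter as right-censored observations (their choice
  # is marginalized): without the censoring term the truncated likelihood
  # would reward parameters that push probability mass past the cap
  slow <- trials$rt_s > rt_cap
  cohs <- sort(unique(trials$signed_coh))
  if (length(cohs) < 2) stop("need >= 2 coherences", call. = FALSE)
  n_slow_by_coh <- vapply(cohs, function(cc)
    sum(slow & trials$signed_coh == cc), 0L)
  trials <- trials[!slow, ]
  t_max <- rt_cap

  coh_idx <- match(trials$signed_coh, cohs)
  is_left <- trials$choice == "left"
  rt <- trials$rt_s
  n_eval <- 0L

  make_nll <- function(dt, h) {
    n_steps <- as.integer(round(t_max / dt))
    # per-trial linear interpolation weights on the solver time grid
    pos <- rt / dt
    i0 <- pmin(pmax(floor(pos), 1), n_steps - 1L)
    fr <- pmin(pmax(pos - i0, 0), 1)
    groups <- split(seq_len(nrow(trials)),
                    interaction(coh_idx, is_left, drop = FALSE))
    nd_state <- c(0.3, log(0.05))
    function(p) {
      n_eval <<- n_eval + 1L
      kappa <- exp(p[1]); B0 <- exp(p[2]); alpha <- exp(p[3]); C0 <- p[4]
      if (!is.finite(kappa) || kappa > 80 || B0 > 8 || alpha > 15) return(1e10)
      pars <- ddm_params(kappa, B0, alpha, mu_nd = 0.3, sigma_nd = 0.05,
                         C0 = C0, rho = rho)
      sols <- lapply(cohs, function(cc) {
        fpt_solve(pars, cc, dt = dt, t_max = t_max, h = h, state_floor = -2)
      })
      nll_nd <- function(q) {
        mu_nd <- q[1]; s_nd <- exp(q[2])
        if (mu_nd < 0.05 || mu_nd > 0.8 || s_nd > 0.4) return(1e10)
        k <- nd_kernel(mu_nd, s_nd, dt)
        total <- 0
        for (ci in seq_along(cohs)) {
          dl <- shift_convolve(sols[[ci]]$f_left, k) / dt
          dr <- shift_convolve(sols[[ci]]$f_right, k) / dt
          for (left in c(TRUE, FALSE)) {
            g <- groups[[paste(ci, left, sep = ".")]]
            if (is.null(g) || length(g) == 0) next
            d <- if (left) dl else dr
            dens <- d[i0[g]] * (1 - fr[g]) + d[i0[g] + 1L] * fr[g]
            total <- total - sum(log(pmax(dens, 1e-10)))
          }
          if (n_slow_by_coh[ci] > 0) {
            p_tail <- 1 - sum(dl + dr) * dt
            total <- total - n_slow_by_coh[ci] * log(pmax(p_tail, 1e-8))
          }
        }
        total
      }
      inner <- stats::optim(nd_state, nll_nd, method = "Nelder-Mead",
                            control = list(maxit = 30, reltol = 1e-6))
      nd_state <<- inner$par
      attr(inner$value, "nd") <- inner$par
      inner$value
    }
  }

  # data-driven initialization
  gl <- stats::glm(is_left ~ trials$signed_coh, family = stats::binomial())
  slope <- max(unname(stats::coef(gl)[2]), 1)
  B0_0 <- 1
  kappa0 <- max(min(slope / (2 * B0_0), 40), 2)
  C0_0 <- -unname(stats::coef(gl)[1]) / slope
  init <- c(log(kappa0), log(B0_0), log(0.4), C0_0)

  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    if (i == 1) init
    else init + c(stats::runif(3, -0.35, 0.35), stats::rnorm(1, 0, 0.02))
  })

  nll_coarse <- make_nll(stages[[1]]$dt, stages[[1]]$h)
  stage1 <- lapply(seq_along(starts), function(i) {
    o <- stats::optim(starts[[i]], nll_coarse, method = "Nelder-Mead",
                      control = list(maxit = stages[[1]]$maxit,
                                     reltol = 1e-6))
    if (verbose) message(sprintf("start %d: nll %.2f", i, o$value))
    o
  })
  polish <- stage1[[which.min(vapply(stage1, `[[`, 0, "value"))]]
  nll_fine <- nll_coarse
  for (stg in stages[-1]) {
    nll_fine <- make_nll(stg$dt, stg$h)
    polish <- stats::optim(polish$par, nll_fine, method = "Nelder-Mead",
                           control = list(maxit = stg$maxit, reltol = 1e-6))
    if (verbose) message(sprintf("stage dt=%g: nll %.2f (conv %d)",
                                 stg$dt, polish$value, polish$convergence))
  }
  final_value <- nll_fine(polish$par) # refresh to recover profiled nd
  nd <- attr(final_value, "nd")

  pars <- ddm_params(kappa = exp(polish$par[1]), B0 = exp(polish$par[2]),
                     alpha_collapse = exp(polish$par[3]),
                     mu_nd = nd[1], sigma_nd = exp(nd[2]),
                     C0 = polish$par[4], rho = rho,
                     post_latency_mu = nd[1] - 0.2)
  converged <- polish$convergence == 0
  if (!converged) {
    warning("fit_ddm: polish stage hit its iteration budget; ",
            "estimates flagged as not fully converged", call. = FALSE)
  }
  structure(list(
    params = pars,
    logLik = -as.numeric(final_value),
    convergence = converged,
    n_eval = n_eval,
    n_trials = nrow(trials),
    start_values = vapply(stage1, `[[`, 0, "value")
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("ddm_fit (%d trials): logLik %.1f, %sconverged\n",
              x$n_trials, x$logLik, if (x$convergence) "" else "NOT "))
  print(x$params)
  invisible(x)
}

#' Log-likelihood of a parameter set under choice-RT data
#'
#' Used for likelihood-dominance checks: the generating parameters should
#' beat random perturbations on data simulated from them.
#'
#' @param params A [ddm_params] object.
#' @param trials Data frame as in [fit_ddm()].
#' @param dt,h,t_max Solver settings.
#' @return Scalar log-likelihood.
#' @export
ddm_loglik <- function(params, trials, dt = 0.005, h = 0.05, t_max = 2.5) {
  trials <- tibble::as_tibble(trials)
  t_max <- max(t_max, max(trials$rt_s) - 0.15)
  cohs <- sort(unique(trials$signed_coh))
  total <- 0
  k <- nd_kernel(params$mu_nd, params$sigma_nd, dt)
  n_steps <- as.integer(round(t_max / dt))
  for (cc in cohs) {
    sol <- fpt_solve(params, cc, dt = dt, t_max = t_max, h = h)
    dl <- shift_convolve(sol$f_left, k) / dt
    dr <- shift_convolve(sol$f_right, k) / dt
    sub <- trials[trials$signed_coh == cc, ]
    pos <- sub$rt_s / dt
    i0 <- pmin(pmax(floor(pos), 1), n_steps - 1L)
    fr <- pmin(pmax(pos - i0, 0), 1)
    d <- ifelse(sub$choice == "left",
                dl[i0] * (1 - fr) + dl[i0 + 1L] * fr,
                dr[i0] * (1 - fr) + dr[i0 + 1L] * fr)
    total <- total + sum(log(pmax(d, 1e-10)))
  }
  total
}
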