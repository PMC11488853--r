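#' First-passage-time solution of the race model
#'
#' Propagates the joint density of the two accumulators forward in discrete
#' time with absorbing collapsing bounds. The propagation works in rotated
#' coordinates \code{u = x + y}, \code{v = x - y}, in which the correlated
#' momentary-evidence increments become independent, so each step is a pair
#' of one-dimensional Gaussian convolutions. Discrete kernels are built from
#' cell-integrated Gaussians with a moment-matching correction (the
#' discretization variance \code{h^2/12} is subtracted), and mass is
#' conserved exactly at every step.
#'
#' A Broadie-Glasserman continuity correction (\code{0.5826 * (sqrt(dt) -
#' sqrt(dt_ref))} subtracted from the bound) makes a coarse-step solve
#' approximate the finer reference discretization \code{dt_ref} used by
#' [simulate_race()]; with \code{dt == dt_ref} no correction is applied.
#'
#' @param params A [ddm_params] object.
#' @param coh Signed coherence of the trial type to solve.
#' @param dt Solver time step (s).
#' @param t_max Time horizon (s of integration time).
#' @param h Spatial grid step (evidence units).
#' @param dt_ref Reference step the correction targets (default 0.001).
#' @param state_floor Lower edge (evidence units) at which the accumulator
#'   state space is truncated (mass is clamped, not lost); paths this deep
#'   essentially never return to the bound.
#' @return Object of class \code{fpt_solution}: time grid \code{t}, per-step
#'   first-passage probabilities \code{f_left}, \code{f_right} (mass per
#'   step), cumulative choice probabilities \code{p_left}, \code{p_right},
#'   \code{p_undecided}, and the solver settings.
#' @examples
#' p <- ddm_params_monkey("M")
#' sol <- fpt_solve(p, coh = 0.256, dt = 0.005, t_max = 1.5)
#' sol$p_left + sol$p_right + sol$p_undecided # 1 to within 1e-6
#' @export
fpt_solve <- function(params, coh, dt = 0.005, t_max = 2.5, h = 0.05,
                      dt_ref = 0.001, state_floor = -2.5) {
  stopifnot(inherits(params, "ddm_params"))
  if (!(dt > 0 && h > 0 && t_max > dt)) stop("invalid grid", call. = FALSE)
  mu <- params$kappa * (coh + params$C0)
  shift <- 0.5826 * (sqrt(dt) - sqrt(dt_ref))
  u_lo <- 2 * state_floor
  v_abs <- params$B0 + 0.3 - state_floor
  res <- cpp_fpt_propagate(mu, dt, params$rho, params$B0,
                           params$alpha_collapse,
                           params$bound_floor_frac * params$B0,
                           t_max, h, shift, u_lo, v_abs)
  mass <- sum(res$f_left) + sum(res$f_right) + res$p_undecided
  if (abs(mass - 1) > 1e-6) {
    stop(sprintf("mass conservation violated (total %.8f); grid too coarse",
                 mass), call. = FALSE)
  }
  structure(list(
    t = seq_len(res$n_steps) * dt,
    f_left = res$f_left, f_right = res$f_right,
    p_left = sum(res$f_left), p_right = sum(res$f_right),
    p_undecided = res$p_undecided,
    coh = coh, dt = dt, h = h, params = params
  ), class = "fpt_solution")
}

#' @export
print.fpt_solution <- function(x, ...) {
  cat(sprintf("fpt_solution: coh %+.3f, P(left) = %.4f, P(right) = %.4f, P(undec) = %.2g\n",
              x$coh, x$p_left, x$p_right, x$p_undecided))
  invisible(x)
}

#' Reaction-time densities from a first-passage solution
#'
#' Convolves the first-passage (decision-time) densities with the Gaussian
#' non-decision time \code{N(mu_nd, sigma_nd)} to give predicted RT
#' densities on the same time grid.
#'
#' @param sol An [fpt_solve()] result.
#' @param mu_nd,sigma_nd Non-decision time parameters (s); default from the
#'   solution's parameters.
#' @return List with \code{t}, \code{rt_left}, \code{rt_right} (densities
#'   per second, summing over the grid to the choice probabilities).
#' @export
rt_densities <- function(sol, mu_nd = sol$params$mu_nd,
                         sigma_nd = sol$params$sigma_nd) {
  stopifnot(inherits(sol, "fpt_solution"))
  k <- nd_kernel(mu_nd, sigma_nd, sol$dt)
  list(t = sol$t,
       rt_left = shift_convolve(sol$f_left, k) / sol$dt,
       rt_right = shift_convolve(sol$f_right, k) / sol$dt)
}

# Discrete non-decision-time kernel on the solver grid: offset (in steps)
# plus cell-integrated Gaussian weights. Supports mu_nd spanning many steps.
nd_kernel <- function(mu_nd, sigma_nd, dt) {
  lo <- floor((mu_nd - 6 * sigma_nd) / dt)
  hi <- ceiling((mu_nd + 6 * sigma_nd) / dt)
  j <- lo:hi
  w <- stats::pnorm((j + 0.5) * dt, mu_nd, sigma_nd) -
    stats::pnorm((j - 0.5) * dt, mu_nd, sigma_nd)
  list(offset = lo, w = w / sum(w))
}

# out[t] = sum_j w[j] x[t - offset - j + 1] (FFT convolution), trimmed to
# length(x); indices outside the support contribute zero.
shift_convolve <- function(x, kernel) {
  n <- length(x)
  cv <- stats::convolve(x, rev(kernel$w), type = "open") # cv[k] = sum x[j] w[k-j+1]
  idx <- seq_len(n) - kernel$offset
  out <- numeric(n)
  ok <- idx >= 1L & idx <= length(cv)
  out[ok] <- cv[idx[ok]]
  out
}
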