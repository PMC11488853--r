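#' Parameters of the anticorrelated race drift-diffusion model
#'
#' The behavioral model is a race between two accumulators, one integrating
#' momentary evidence for a leftward (contraversive) choice and one for a
#' rightward choice. Momentary evidence samples are bivariate Normal with
#' means \eqn{\pm\kappa (C + C_0) dt}, per-step variance \eqn{dt} (unit
#' variance per second), and correlation \eqn{\rho}. The decision terminates
#' when one accumulator reaches its positive, linearly collapsing bound
#' \eqn{B(t) = B_0 - \alpha t} (clipped at a small positive floor).
#' Reaction time adds a non-decision time, modeled either as a single
#' Gaussian \eqn{N(\mu_{nd}, \sigma_{nd})} (fitting) or split into a fixed
#' pre-integration latency plus a Gaussian post-termination latency
#' (simulation; the split means sum to \code{mu_nd}).
#'
#' @param kappa Drift scaling (evidence s^-1 per unit signed coherence).
#' @param B0 Initial bound height (evidence units), > 0.
#' @param alpha_collapse Linear bound collapse rate (evidence s^-1), >= 0.
#' @param mu_nd Mean non-decision time (s).
#' @param sigma_nd Standard deviation of the non-decision time (s), > 0.
#' @param C0 Bias, in units of signed coherence. Positive signed coherence
#'   means leftward (contraversive) motion; the left accumulator's drift is
#'   \code{kappa * (C + C0)}, so the choice function is balanced at
#'   \code{C = -C0}.
#' @param rho Correlation of the momentary evidence between the accumulators;
#'   default \code{-sqrt(0.5)} (the accumulators share half their variance).
#' @param pre_latency Visual latency from motion onset to integration onset
#'   (s); default 0.2.
#' @param post_latency_mu,post_latency_sd Mean and s.d. (s) of the Gaussian
#'   post-termination (motor) latency used in simulation; defaults 0.117 and
#'   0.039. Samples are truncated at zero (negligible mass).
#' @param bound_floor_frac Bounds are clipped at this fraction of \code{B0}
#'   so they stay positive at long times; default 0.01.
#'
#' @return An object of class \code{ddm_params}.
#' @examples
#' p <- ddm_params(kappa = 13.37, B0 = 1.03, alpha_collapse = 0.4199,
#'                 mu_nd = 0.317, sigma_nd = 0.039, C0 = -0.0144)
#' bound_at(c(0, 0.5, 1), p)
#' @export
ddm_params <- function(kappa, B0, alpha_collapse, mu_nd, sigma_nd, C0,
                       rho = -sqrt(0.5),
                       pre_latency = 0.200,
                       post_latency_mu = 0.117,
                       post_latency_sd = 0.039,
                       bound_floor_frac = 0.01) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (!(B0 > 0)) stop("B0 must be > 0", call. = FALSE)
  if (!(alpha_collapse >= 0)) stop("alpha_collapse must be >= 0", call. = FALSE)
  if (!(sigma_nd > 0)) stop("sigma_nd must be > 0", call. = FALSE)
  if (!(rho > -1 && rho < 0)) stop("rho must lie in (-1, 0)", call. = FALSE)
  if (!(pre_latency >= 0 && post_latency_sd > 0)) {
    stop("latency parameters invalid", call. = FALSE)
  }
  structure(
    list(kappa = kappa, B0 = B0, alpha_collapse = alpha_collapse,
         mu_nd = mu_nd, sigma_nd = sigma_nd, C0 = C0, rho = rho,
         pre_latency = pre_latency, post_latency_mu = post_latency_mu,
         post_latency_sd = post_latency_sd,
         bound_floor_frac = bound_floor_frac),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Anticorrelated race DDM parameters\n")
  cat(sprintf("  kappa = %.4g, B0 = %.4g, alpha = %.4g\n",
              x$kappa, x$B0, x$alpha_collapse))
  cat(sprintf("  mu_nd = %.4g s (pre %.3g + post %.3g), sigma_nd = %.4g s\n",
              x$mu_nd, x$pre_latency, x$post_latency_mu, x$sigma_nd))
  cat(sprintf("  C0 = %.4g, rho = %.4g\n", x$C0, x$rho))
  invisible(x)
}

#' Reference parameter sets for the race model
#'
#' Fitted parameter values for the two animals in the motion-discrimination
#' study (drift scaling, bound, collapse rate, non-decision time, bias).
#'
#' @param monkey \code{"M"} or \code{"J"}.
#' @return A [ddm_params] object.
#' @export
ddm_params_monkey <- function(monkey = c("M", "J")) {
  monkey <- match.arg(monkey)
  if (monkey == "M") {
    ddm_params(kappa = 13.37, B0 = 1.03, alpha_collapse = 0.4199,
               mu_nd = 0.317, sigma_nd = 0.039, C0 = -0.0144)
  } else {
    ddm_params(kappa = 13.72, B0 = 1.76, alpha_collapse = 1.3591,
               mu_nd = 0.291, sigma_nd = 0.055, C0 = 0.0008)
  }
}

#' Default signed-coherence set
#'
#' Signed motion strengths used in the task; positive is leftward
#' (contraversive).
#' @return Numeric vector of 11 signed coherences (proportions).
#' @export
default_coherences <- function() {
  c <- c(0, 0.032, 0.064, 0.128, 0.256, 0.512)
  sort(unique(c(-c, c)))
}

#' Bound height at time t
#'
#' Linearly collapsing decision bound \eqn{B(t) = \max(B_0 - \alpha t,
#' \mathrm{floor})}, with the floor a small positive constant
#' (\code{bound_floor_frac * B0}).
#'
#' @param t Time(s) from integration onset (s), >= 0.
#' @param params A [ddm_params] object.
#' @return Bound height(s), same length as \code{t}.
#' @export
bound_at <- function(t, params) {
  stopifnot(inherits(params, "ddm_params"), all(t >= 0))
  pmax(params$B0 - params$alpha_collapse * t,
       params$bound_floor_frac * params$B0)
}

#' Truncated-exponential delay specification
#'
#' Task delays are distributed as truncated exponentials on
#' \eqn{[t_{min}, t_{max}]} with time constant \eqn{\lambda}:
#' \eqn{f(t) = (\alpha/\lambda) e^{-(t - t_{min})/\lambda}} on the support,
#' with \eqn{\alpha} the normalization. Because of the truncation the
#' expectation is below \eqn{t_{min} + \lambda}.
#'
#' @param t_min,t_max Support bounds (s), \code{0 <= t_min <= t_max}.
#' @param lam Exponential time constant (s), > 0.
#' @return An object of class \code{delay_spec} with the derived
#'   normalization constant \code{norm_const}.
#' @export
delay_spec <- function(t_min, t_max, lam) {
  if (!(t_min >= 0 && t_max >= t_min)) stop("need 0 <= t_min <= t_max", call. = FALSE)
  if (!(lam > 0)) stop("lam must be > 0", call. = FALSE)
  # integral of (1/lam) exp(-(t - t_min)/lam) over [t_min, t_max]
  z <- 1 - exp(-(t_max - t_min) / lam)
  norm_const <- if (z > 0) 1 / z else NA_real_ # degenerate range: point mass
  structure(list(t_min = t_min, t_max = t_max, lam = lam,
                 norm_const = norm_const),
            class = "delay_spec")
}

#' Sample truncated-exponential delays
#'
#' @param spec A [delay_spec].
#' @param n Number of samples.
#' @return Numeric vector of delays in \code{[t_min, t_max]} (s).
#' @export
sample_truncated_exp <- function(spec, n) {
  stopifnot(inherits(spec, "delay_spec"), n >= 0)
  if (spec$t_max == spec$t_min) return(rep(spec$t_min, n))
  u <- stats::runif(n)
  z <- 1 - exp(-(spec$t_max - spec$t_min) / spec$lam)
  spec$t_min - spec$lam * log(1 - u * z)
}

#' Truncated-exponential CDF
#'
#' @param q Quantiles (s).
#' @param spec A [delay_spec].
#' @return CDF values.
#' @export
ptrunc_exp <- function(q, spec) {
  stopifnot(inherits(spec, "delay_spec"))
  z <- 1 - exp(-(spec$t_max - spec$t_min) / spec$lam)
  p <- (1 - exp(-(q - spec$t_min) / spec$lam)) / z
  p[q < spec$t_min] <- 0
  p[q >= spec$t_max] <- 1
  p
}
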