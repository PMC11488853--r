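#' Tidy a fitted race model
#'
#' @param x A [fit_ddm()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter (\code{term},
#'   \code{estimate}).
#' @export
tidy.ddm_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("kappa", "B0", "alpha_collapse", "mu_nd", "sigma_nd", "C0", "rho"),
    estimate = c(p$kappa, p$B0, p$alpha_collapse, p$mu_nd, p$sigma_nd,
                 p$C0, p$rho),
    fixed = c(rep(FALSE, 6), TRUE))
}

#' @rdname tidy.ddm_fit
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, converged = x$convergence,
                 n_trials = x$n_trials, n_eval = x$n_eval)
}

#' Tidy a mediation result
#'
#' @param x A [leverage_behavior()] result.
#' @param ... Unused.
#' @return Tibble: per-time leverage and mediated leverage for choice
#'   (normalized) and RT.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(t = x$times,
                 beta1 = x$beta1, beta1_se = x$beta1_se,
                 beta1_norm = x$beta1_norm,
                 beta1_star_norm = x$beta1_star_norm,
                 r_rt = x$r_rt, partial_r_rt = x$partial_r_rt)
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(xi_ch = x$xi_ch, xi_ch_defined = x$xi_ch_defined,
                 xi_rt = x$xi_rt, xi_rt_defined = x$xi_rt_defined,
                 n_trials = x$n_trials, n_left = x$n_left)
}

#' Tidy a decoder surface
#'
#' @param x A [what_decoder()] result.
#' @param ... Unused.
#' @return Long tibble: \code{train_t}, \code{test_t}, \code{accuracy}.
#' @export
tidy.decoder_surface <- function(x, ...) {
  expand.grid(train_t = x$train_times, test_t = x$test_times) |>
    tibble::as_tibble() |>
    dplyr::mutate(accuracy = as.vector(x$accuracy))
}

#' Tidy an empirical diffusion fit
#'
#' @param x An [empirical_var_autocorr()] result.
#' @param ... Unused.
#' @return Tibble: sample index, normalized variance and its bootstrap SE.
#' @export
tidy.diffusion_emp <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$var_curve),
                 var_norm = x$var_curve, var_se = x$var_se)
}

#' Tidy a DS classification
#'
#' @param x A [classify_ds()] result.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.ds_classification <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
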