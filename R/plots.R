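#' Plot condition-averaged single-trial signals
#'
#' Mean projected signal per signed coherence, the standard display for a
#' coding direction.
#'
#' @param object A \code{dv_signal}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dv_signal <- function(object, ...) {
  cm <- condition_means(object)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$t, y = .data$mean,
                                   color = factor(.data$signed_coh))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("time from %s (s)",
                              ifelse(object$alignment == "motion_on",
                                     "motion onset", "saccade")),
                  y = sprintf("S (%s)", object$cd_name),
                  color = "signed coh") +
    ggplot2::theme_minimal()
}

#' Plot a cross-temporal decoding surface
#'
#' @param object A \code{decoder_surface}.
#' @param ... Unused.
#' @return A ggplot heatmap (train time x test time accuracy).
#' @export
autoplot.decoder_surface <- function(object, ...) {
  df <- tidy.decoder_surface(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$train_t, y = .data$test_t,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0.4, 1)) +
    ggplot2::labs(x = "training time (s)", y = "testing time (s)",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot leverage and mediated leverage traces
#'
#' Normalized choice leverage and RT correlation as a function of time,
#' with their mediated counterparts.
#'
#' @param object A \code{mediation_result}.
#' @param ... Unused.
#' @return A ggplot with two facets (choice, RT).
#' @export
autoplot.mediation_result <- function(object, ...) {
  df <- tidy.mediation_result(object)
  long <- dplyr::bind_rows(
    tibble::tibble(t = df$t, value = df$beta1_norm, trace = "leverage",
                   outcome = "choice"),
    tibble::tibble(t = df$t, value = df$beta1_star_norm, trace = "mediated",
                   outcome = "choice"),
    tibble::tibble(t = df$t, value = df$r_rt, trace = "leverage",
                   outcome = "RT"),
    tibble::tibble(t = df$t, value = df$partial_r_rt, trace = "mediated",
                   outcome = "RT"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     linetype = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "time from motion onset (s)", y = "leverage") +
    ggplot2::theme_minimal()
}

#' Plot empirical vs. theoretical diffusion variance
#'
#' @param object A \code{diffusion_emp}.
#' @param theory Optional [wiener_theory()] for the overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_emp <- function(object, theory = NULL, ...) {
  df <- tidy.diffusion_emp(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$var_norm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$var_norm - .data$var_se,
                                          ymax = .data$var_norm + .data$var_se)) +
    ggplot2::labs(x = "sample", y = "normalized variance") +
    ggplot2::theme_minimal()
  if (!is.null(theory)) {
    v <- diag(theory$cov) / theory$cov[1, 1]
    p <- p + ggplot2::geom_line(data = tibble::tibble(sample = seq_along(v),
                                                      var_norm = v),
                                color = "red")
  }
  p
}

#' Plot a Min-to-Tin correlation map
#'
#' @param object A [min_tin_xcorr()] result.
#' @param ... Unused.
#' @return A ggplot heatmap of r(tx, ty).
#' @export
autoplot.min_tin_xcorr <- function(object, ...) {
  df <- expand.grid(tx = object$tx, ty = object$ty)
  df$r <- as.vector(object$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tx, y = .data$ty, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Min time (s)", y = "Tin time (s)", fill = "r") +
    ggplot2::theme_minimal()
}
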