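#' Smoothing kernel specification
#'
#' Two kernels are used throughout: a 50 ms boxcar for analysis (the window
#' plotted at time t covers t-24 to t+25 ms; for odd widths the window is
#' symmetric) and a truncated Gaussian for visualization (width \code{N}
#' samples at 1 kHz with shape factor \code{alpha}, so
#' \eqn{\sigma = (N-1)/(2\alpha)} samples; the default 80 ms / 1.5 gives
#' \eqn{\sigma \approx 26} ms), truncated at the window edges and
#' renormalized to unit sum.
#'
#' @param kind "boxcar" or "gaussian".
#' @param width_ms Kernel width in ms.
#' @param gauss_alpha Width factor (gaussian only); default 1.5.
#' @return Object of class \code{kernel_spec} with elements \code{kind},
#'   \code{width_ms}, \code{back_ms}, \code{fwd_ms}, and for the gaussian
#'   \code{sigma_ms} and the weight vector \code{w}.
#' @examples
#' kernel_spec("gaussian", 80)$sigma_ms # ~26
#' @export
kernel_spec <- function(kind = c("boxcar", "gaussian"), width_ms = 50,
                        gauss_alpha = 1.5) {
  kind <- match.arg(kind)
  stopifnot(width_ms >= 1)
  back <- floor((width_ms - 1) / 2)
  fwd <- width_ms - 1 - back
  out <- list(kind = kind, width_ms = width_ms, back_ms = back, fwd_ms = fwd)
  if (kind == "gaussian") {
    out$sigma_ms <- (width_ms - 1) / (2 * gauss_alpha)
    x <- seq(-(width_ms - 1) / 2, (width_ms - 1) / 2)
    w <- exp(-0.5 * (x / out$sigma_ms)^2)
    out$w <- w / sum(w)
    out$back_ms <- floor((width_ms - 1) / 2)
    out$fwd_ms <- ceiling((width_ms - 1) / 2)
  }
  structure(out, class = "kernel_spec")
}

#' Bin and smooth spikes into per-neuron rate tensors
#'
#' Counts spikes on a 1 ms grid per neuron and trial, applies the smoothing
#' kernel, and samples the result at the requested output times. Rates are
#' in spikes/s. Censored samples (within 100 ms of the saccade and beyond,
#' for motion-aligned decision data; before motion onset or beyond the
#' recorded window, for saccade-aligned data) are marked \code{NA}; for the
#' boxcar kernel any window touching a censored sample is \code{NA}
#' (analyses never read censored data), while the Gaussian visualization
#' kernel is truncated and renormalized over the available samples.
#'
#' @param session A \code{dv_session}.
#' @param t_lim Output time range (s, relative to the alignment event).
#' @param step Output sampling step (s); default 0.025.
#' @param kernel A [kernel_spec()]; default 50 ms boxcar.
#' @param alignment "motion_on" or "saccade".
#' @param censor Apply the saccade/window censoring rules (default TRUE for
#'   decision sessions).
#' @return Object of class \code{rate_tensor}: array
#'   \code{[neuron, trial, time]} with attributes \code{time},
#'   \code{alignment}, plus \code{$trials} metadata.
#' @export
bin_and_smooth <- function(session, t_lim = c(0, 0.6), step = 0.025,
                           kernel = kernel_spec("boxcar", 50),
                           alignment = c("motion_on", "saccade"),
                           censor = session$kind == "decision") {
  alignment <- match.arg(alignment)
  stopifnot(inherits(kernel, "kernel_spec"))
  trials <- session$trials
  n_tr <- nrow(trials)
  n_neu <- nrow(session$neurons)
  t_out <- seq(t_lim[1], t_lim[2], by = step)
  pad <- max(kernel$back_ms, kernel$fwd_ms) / 1000 + 0.001
  f_lo <- t_lim[1] - pad; f_hi <- t_lim[2] + pad
  nf <- round((f_hi - f_lo) * 1000)
  # spike times relative to the alignment event
  sp <- session$spikes
  t_rel <- if (alignment == "motion_on") sp$t_s else
    sp$t_s - trials$saccade_s[match(sp$trial_id, trials$trial_id)]
  fine_bin <- floor((t_rel - f_lo) * 1000) + 1L
  keep <- fine_bin >= 1L & fine_bin <= nf
  sp_neu <- sp$neuron_id[keep]
  sp_idx <- (match(sp$trial_id[keep], trials$trial_id) - 1L) * nf + fine_bin[keep]

  # per-trial NA regions on the fine grid (times at bin centers)
  t_fine <- f_lo + (seq_len(nf) - 0.5) / 1000
  na_mask <- matrix(FALSE, n_tr, nf)
  if (censor && session$kind == "decision") {
    rt <- trials$rt_s
    if (alignment == "motion_on") {
      for (i in seq_len(n_tr)) {
        na_mask[i, t_fine >= rt[i] - 0.1 | t_fine < -0.3] <- TRUE
      }
    } else {
      for (i in seq_len(n_tr)) {
        na_mask[i, t_fine < -rt[i] - 0.3 | t_fine > 0.15] <- TRUE
      }
    }
  }
  # output at time t reads the fine bin whose left edge is t, so the
  # boxcar window [idx-back, idx+fwd] spans [t-back, t+fwd+1) ms
  out_idx <- as.integer(round((t_out - f_lo) * 1000)) + 1L

  arr <- array(NA_real_, c(n_neu, n_tr, length(t_out)))
  by_neuron <- split(sp_idx, factor(sp_neu, levels = session$neurons$neuron_id))
  valid <- !na_mask
  if (kernel$kind == "boxcar") {
    csm <- cbind(0, t(apply(valid, 1, cumsum)))
    lo <- pmax(out_idx - kernel$back_ms, 1L)
    hi <- pmin(out_idx + kernel$fwd_ms, nf)
    wlen <- kernel$back_ms + kernel$fwd_ms + 1L
    n_valid <- csm[, hi + 1L, drop = FALSE] - csm[, lo, drop = FALSE]
    full <- n_valid == wlen # strict: all samples in window uncensored
  }
  for (n in seq_len(n_neu)) {
    cnt <- matrix(tabulate(by_neuron[[n]], nbins = n_tr * nf), n_tr, nf,
                  byrow = TRUE)
    if (kernel$kind == "boxcar") {
      cs <- cbind(0, t(apply(cnt * valid, 1, cumsum)))
      sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) / wlen * 1000
      sm[!full] <- NA_real_
    } else {
      cnt[na_mask] <- NA_real_
      sm <- matrix(NA_real_, n_tr, length(t_out))
      offs <- seq(-kernel$back_ms, kernel$fwd_ms)
      wts <- kernel$w
      num <- matrix(0, n_tr, length(t_out))
      den <- matrix(0, n_tr, length(t_out))
      for (j in seq_along(offs)) {
        src <- out_idx + offs[j]
        ok <- src >= 1L & src <= nf
        v <- cnt[, src[ok], drop = FALSE]
        m <- !is.na(v)
        v[!m] <- 0
        num[, ok] <- num[, ok] + wts[j] * v
        den[, ok] <- den[, ok] + wts[j] * m
      }
      sm <- ifelse(den > 0.2, num / den * 1000, NA_real_)
    }
    arr[n, , ] <- sm
  }
  structure(list(rates = arr, time = t_out, alignment = alignment,
                 kernel = kernel, trials = trials,
                 neurons = session$neurons),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("rate_tensor: %d neurons x %d trials x %d times (%s-aligned, %s %d ms)\n",
              d[1], d[2], d[3], x$alignment, x$kernel$kind, x$kernel$width_ms))
  invisible(x)
}

#' Standardize per-neuron firing rates
#'
#' z-scores each neuron's rates using the mean and s.d. of its firing rate
#' in a reference epoch (default 200-600 ms after motion onset, across all
#' trials and uncensored times). Neurons with no spikes (or zero variance)
#' in the window are excluded and must receive zero weight downstream.
#'
#' @param rt A motion-aligned [bin_and_smooth()] rate tensor.
#' @param window Reference epoch (s).
#' @return A \code{rate_tensor} with standardized rates; attribute
#'   \code{excluded} lists excluded neuron ids, and \code{$norm} carries the
#'   per-neuron means/sds.
#' @export
standardize_neurons <- function(rt, window = c(0.2, 0.6)) {
  stopifnot(inherits(rt, "rate_tensor"))
  sel <- rt$time >= window[1] & rt$time <= window[2]
  if (!any(sel)) stop("reference window outside tensor times", call. = FALSE)
  n_neu <- dim(rt$rates)[1]
  m <- s <- numeric(n_neu)
  for (n in seq_len(n_neu)) {
    v <- rt$rates[n, , sel]
    m[n] <- mean(v, na.rm = TRUE)
    s[n] <- stats::sd(v, na.rm = TRUE)
  }
  excluded <- which(!is.finite(m) | m == 0 | !is.finite(s) | s == 0)
  s_safe <- ifelse(s > 0 & is.finite(s), s, 1)
  m_safe <- ifelse(is.finite(m), m, 0)
  out <- rt
  out$rates <- (rt$rates - rep(m_safe, prod(dim(rt$rates)[2:3]))) /
    rep(s_safe, prod(dim(rt$rates)[2:3]))
  out$norm <- tibble::tibble(neuron_id = rt$neurons$neuron_id,
                             mean = m, sd = s,
                             excluded = seq_len(n_neu) %in% excluded)
  attr(out, "excluded") <- rt$neurons$neuron_id[excluded]
  out
}

#' Project population rates onto a coding direction
#'
#' The single-trial population signal is the weighted sum of the per-neuron
#' rates, \eqn{S_i(t) = \sum_n w_n s_{i,n}(t)}. Censoring (\code{NA})
#' propagates.
#'
#' @param rt A [bin_and_smooth()] rate tensor (standardized if the coding
#'   direction was derived from standardized rates).
#' @param cd A \code{coding_direction} or a numeric weight vector of length
#'   equal to the neuron count.
#' @return Object of class \code{dv_signal}: \code{values} (trials x time),
#'   \code{time}, \code{alignment}, \code{trials}, \code{cd_name}.
#' @export
project_signal <- function(rt, cd) {
  stopifnot(inherits(rt, "rate_tensor"))
  w <- if (inherits(cd, "coding_direction")) cd$weights else as.numeric(cd)
  d <- dim(rt$rates)
  if (length(w) != d[1]) stop("weight length != neuron count", call. = FALSE)
  flat <- matrix(rt$rates, d[1], d[2] * d[3])
  vals <- matrix(crossprod(flat, w), d[2], d[3])
  structure(list(values = vals, time = rt$time, alignment = rt$alignment,
                 trials = rt$trials,
                 cd_name = if (inherits(cd, "coding_direction")) cd$method else "custom"),
            class = "dv_signal")
}

#' @export
print.dv_signal <- function(x, ...) {
  cat(sprintf("dv_signal [%s]: %d trials x %d times (%s-aligned)\n",
              x$cd_name, nrow(x$values), ncol(x$values), x$alignment))
  invisible(x)
}

#' Condition-averaged signal traces
#'
#' Mean traces per signed coherence (or per choice). Motion-aligned means
#' use all trials with the per-trial pre-saccade censoring already encoded
#' as \code{NA}; saccade-aligned means use correct trials only.
#'
#' @param sig A [project_signal()] result.
#' @param by Grouping column of the trials table: "signed_coh" or "choice".
#' @param correct_only Default: saccade-aligned only.
#' @return Tibble: group value, \code{t}, \code{mean}, \code{se}, \code{n}.
#' @export
condition_means <- function(sig, by = "signed_coh",
                            correct_only = sig$alignment == "saccade") {
  stopifnot(inherits(sig, "dv_signal"))
  trials <- sig$trials
  keep <- if (correct_only && "correct" %in% names(trials))
    which(trials$correct %in% TRUE) else seq_len(nrow(trials))
  g <- trials[[by]][keep]
  v <- sig$values[keep, , drop = FALSE]
  purrr::map_dfr(split(seq_along(g), g), function(idx) {
    m <- v[idx, , drop = FALSE]
    n_ok <- colSums(!is.na(m))
    tibble::tibble(group = g[idx[1]], t = sig$time,
                   mean = colMeans(m, na.rm = TRUE),
                   se = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1)),
                   n = n_ok)
  }) |> dplyr::rename(!!by := "group")
}

#' Detrend single-trial signals
#'
#' Subtracts, at every time, the mean signal of trials sharing the same
#' signed coherence, leaving the diffusion (residual) component. Optionally
#' also subtracts each trial's own value at a baseline time (used before
#' variance/autocorrelation diagnostics).
#'
#' @param sig A [project_signal()] result.
#' @param baseline_t Optional time (s) whose per-trial value is subtracted.
#' @return A \code{dv_signal} of residuals.
#' @export
detrend_signal <- function(sig, baseline_t = NULL) {
  stopifnot(inherits(sig, "dv_signal"))
  g <- sig$trials$signed_coh
  v <- sig$values
  for (grp in split(seq_along(g), g)) {
    mu <- colMeans(v[grp, , drop = FALSE], na.rm = TRUE)
    v[grp, ] <- sweep(v[grp, , drop = FALSE], 2, mu)
  }
  if (!is.null(baseline_t)) {
    j <- which.min(abs(sig$time - baseline_t))
    v <- v - v[, j]
  }
  out <- sig
  out$values <- v
  out
}

#' Session-range normalization of signals
#'
#' Rescales signals to an approximate [0, 1] range per session: the range
#' is set by the minimum and maximum over four condition-average traces
#' (two choices, motion-aligned 0-0.6 s and saccade-aligned -0.6-0 s), and
#' the same affine map is applied to the single-trial values (which may
#' therefore exceed [0, 1]).
#'
#' @param sig_motion,sig_saccade Motion- and saccade-aligned signals from
#'   the same coding direction.
#' @return List: normalized signals \code{motion} and \code{saccade},
#'   \code{a_min}, \code{a_max}.
#' @export
normalize_session <- function(sig_motion, sig_saccade) {
  stopifnot(inherits(sig_motion, "dv_signal"), inherits(sig_saccade, "dv_signal"))
  cm_m <- condition_means(sig_motion, by = "choice", correct_only = FALSE)
  cm_s <- condition_means(sig_saccade, by = "choice")
  use_m <- cm_m$t >= 0 & cm_m$t <= 0.6
  use_s <- cm_s$t >= -0.6 & cm_s$t <= 0
  rng <- range(c(cm_m$mean[use_m], cm_s$mean[use_s]), na.rm = TRUE)
  a_min <- rng[1]; a_max <- rng[2]
  scale <- function(s) { s$values <- (s$values - a_min) / (a_max - a_min); s }
  list(motion = scale(sig_motion), saccade = scale(sig_saccade),
       a_min = a_min, a_max = a_max)
}

#' Estimate and remove the urgency component
#'
#' The urgency signal u(t) is the across-trial mean of the signal on 0%
#' coherence trials (both choices). Removing it from the non-zero coherence
#' condition means renders positive and negative coherence averages
#' approximately symmetric around zero.
#'
#' @param sig A motion-aligned [project_signal()] result.
#' @return Tibble with \code{t} and \code{u}.
#' @export
estimate_urgency <- function(sig) {
  stopifnot(inherits(sig, "dv_signal"))
  idx <- which(sig$trials$signed_coh == 0)
  if (length(idx) == 0) stop("no 0% coherence trials", call. = FALSE)
  tibble::tibble(t = sig$time,
                 u = colMeans(sig$values[idx, , drop = FALSE], na.rm = TRUE))
}

#' @rdname estimate_urgency
#' @param cond_means A [condition_means()] tibble (motion-aligned).
#' @param u An [estimate_urgency()] tibble.
#' @return \code{remove_urgency}: the condition means with \code{mean}
#'   replaced by the urgency-corrected values.
#' @export
remove_urgency <- function(cond_means, u) {
  j <- match(cond_means$t, u$t)
  cond_means$mean <- cond_means$mean - u$u[j]
  cond_means
}

#' Sample a signal at given times
#'
#' Extracts per-trial values at the output times nearest to \code{times}
#' (censored samples stay \code{NA}).
#'
#' @param sig A [project_signal()] result.
#' @param times Times to sample (s).
#' @return Matrix trials x length(times).
#' @export
sample_signal <- function(sig, times) {
  stopifnot(inherits(sig, "dv_signal"))
  j <- vapply(times, function(tt) which.min(abs(sig$time - tt)), 1L)
  if (any(abs(sig$time[j] - times) > 0.013)) {
    warning("some requested times are > 13 ms from the signal grid")
  }
  sig$values[, j, drop = FALSE]
}
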