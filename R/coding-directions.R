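new_coding_direction <- function(weights, method, offset = 0, meta = list()) {
  structure(list(weights = as.numeric(weights), method = method,
                 offset = offset, training_meta = meta),
            class = "coding_direction")
}

#' @export
print.coding_direction <- function(x, ...) {
  cat(sprintf("coding_direction [%s]: %d weights (%d nonzero)\n",
              x$method, length(x$weights), sum(x$weights != 0)))
  invisible(x)
}

#' Cosine similarity between coding directions
#'
#' @param cd_x,cd_y \code{coding_direction} objects or numeric vectors.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(cd_x, cd_y) {
  x <- if (inherits(cd_x, "coding_direction")) cd_x$weights else cd_x
  y <- if (inherits(cd_y, "coding_direction")) cd_y$weights else cd_y
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Ramp coding direction
#'
#' Regression of standardized population activity onto idealized single-
#' trial ramps: on every contralateral (left) choice trial the target ramps
#' linearly from -1 at t = 0.2 s after motion onset to +1 at 50 ms before
#' the saccade, sampled every 25 ms and concatenated into a sawtooth.
#' Regressors are 25 ms boxcar rates at the same samples, z-scored by the
#' statistics of the sampled values. Weights come from lasso regression at
#' \code{lambda} (0.005 by default, as a fraction of the glmnet objective).
#'
#' @param session A decision \code{dv_session}.
#' @param lambda Lasso penalty; 0 gives ordinary least squares.
#' @param t_hi Cap on sample times (s); trials contribute samples up to
#'   \code{min(rt - 0.05, t_hi)}.
#' @param min_samples Refuse below this many eligible samples.
#' @return A \code{coding_direction} (method "ramp"); training metadata
#'   records the fitted-signal R^2 on the training sawtooth.
#' @export
ramp_cd <- function(session, lambda = 0.005, t_hi = 2, min_samples = 50) {
  stopifnot(inherits(session, "dv_session"), session$kind == "decision")
  trials <- session$trials
  elig <- which(trials$choice == "left" & trials$rt_s - 0.05 > 0.2)
  if (length(elig) == 0) stop("no eligible contralateral trials", call. = FALSE)
  t_top <- min(max(trials$rt_s[elig]) - 0.05, t_hi)
  rt25 <- bin_and_smooth(session, t_lim = c(0.2, t_top), step = 0.025,
                         kernel = kernel_spec("boxcar", 25), censor = FALSE)
  n_neu <- dim(rt25$rates)[1]
  X <- NULL; y <- NULL
  rows <- list(); targs <- list()
  for (i in elig) {
    t1 <- min(trials$rt_s[i] - 0.05, t_top)
    jj <- which(rt25$time <= t1 + 1e-9)
    if (length(jj) < 2) next
    rows[[length(rows) + 1L]] <- t(rt25$rates[, i, jj])
    targs[[length(targs) + 1L]] <-
      -1 + 2 * (rt25$time[jj] - 0.2) / (t1 - 0.2)
  }
  X <- do.call(rbind, rows)
  y <- unlist(targs)
  if (length(y) < min_samples) {
    stop(sprintf("only %d eligible ramp samples (need >= %d)",
                 length(y), min_samples), call. = FALSE)
  }
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  excluded <- which(!is.finite(sdv) | sdv == 0)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (lambda > 0) {
    fit <- glmnet::glmnet(Z, y, alpha = 1, lambda = lambda,
                          standardize = FALSE, intercept = TRUE)
    w <- as.numeric(fit$beta)
    b0 <- as.numeric(fit$a0)
  } else {
    fit <- stats::lm.fit(cbind(1, Z), y)
    w <- fit$coefficients[-1]
    w[is.na(w)] <- 0
    b0 <- fit$coefficients[1]
  }
  w[excluded] <- 0
  # weights act on z-scored rates; fold the scaling so they apply to rates
  pred <- Z %*% w + b0
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  new_coding_direction(w / sdv, "ramp", offset = b0,
                       meta = list(lambda = lambda, r2 = r2,
                                   n_samples = length(y),
                                   z_mu = mu, z_sd = sdv,
                                   excluded = excluded))
}

#' First principal component coding direction
#'
#' PCA of the per-signed-coherence trial-averaged standardized rates in the
#' epoch from 200 ms after motion onset to 600 ms or 100 ms before the
#' median RT of the coherence, whichever is shorter. PC1 defines the coding
#' direction; its sign is chosen so the projected signal increases with
#' leftward coherence.
#'
#' @param session A decision \code{dv_session}.
#' @param rt_std Optional precomputed standardized [bin_and_smooth()]
#'   tensor (motion-aligned, 25 ms step covering 0.2-0.6 s).
#' @return A \code{coding_direction} (method "pc1") with eigenvalues and
#'   the participation ratio in \code{training_meta}.
#' @export
pc1_cd <- function(session, rt_std = NULL) {
  stopifnot(inherits(session, "dv_session"))
  if (is.null(rt_std)) {
    rt_std <- standardize_neurons(
      bin_and_smooth(session, t_lim = c(0.1, 0.62), step = 0.025))
  }
  trials <- rt_std$trials
  cohs <- sort(unique(trials$signed_coh))
  rows <- list()
  for (cc in cohs) {
    idx <- which(trials$signed_coh == cc)
    t_end <- min(0.6, median(trials$rt_s[idx]) - 0.1)
    jj <- which(rt_std$time >= 0.2 & rt_std$time <= t_end + 1e-9)
    if (length(jj) == 0) next
    m <- apply(rt_std$rates[, idx, jj, drop = FALSE], c(1, 3),
               mean, na.rm = TRUE)
    rows[[as.character(cc)]] <- t(m)
  }
  M <- do.call(rbind, rows)
  M[!is.finite(M)] <- 0
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  w <- pc$rotation[, 1]
  excl <- rt_std$norm$excluded %||% rep(FALSE, length(w))
  w[excl] <- 0
  # sign: projected condition means should increase with leftward coherence
  last_rows <- vapply(rows, function(r) as.numeric(r[nrow(r), ] %*% w), 0)
  if (stats::cor(cohs[seq_along(last_rows)], last_rows) < 0) w <- -w
  new_coding_direction(w, "pc1",
                       meta = list(eigenvalues = ev,
                                   var_explained = ev / sum(ev),
                                   participation_ratio = sum(ev)^2 / sum(ev^2)))
}

#' Participation ratio of a session
#'
#' Effective dimensionality \eqn{(\sum\lambda)^2 / \sum\lambda^2} of the
#' eigenvalue spectrum used for the PC1 coding direction.
#'
#' @inheritParams pc1_cd
#' @param session A decision session, or a numeric vector of eigenvalues.
#' @return Scalar.
#' @export
participation_ratio <- function(session, rt_std = NULL) {
  if (is.numeric(session)) return(sum(session)^2 / sum(session^2))
  pc1_cd(session, rt_std)$training_meta$participation_ratio
}

#' Tin-average coding direction
#'
#' Weight 1/N for each of the N Tin_con neurons and 0 elsewhere (the
#' unweighted mean of the contralateral-target neurons).
#'
#' @param session A \code{dv_session}.
#' @param label Which label to average (default "Tin_con").
#' @return A \code{coding_direction} (method "tin_mean").
#' @export
tin_mean_cd <- function(session, label = "Tin_con") {
  is_t <- session$neurons$label == label
  if (!any(is_t)) stop("no neurons with label ", label, call. = FALSE)
  w <- ifelse(is_t, 1 / sum(is_t), 0)
  new_coding_direction(w, "tin_mean", meta = list(label = label, n = sum(is_t)))
}

#' Logistic choice decoder (What)
#'
#' Trains an L1-regularized logistic choice decoder on standardized spike
#' counts in 50 ms bins spanning the first 500 ms after motion onset, on
#' even-numbered trials, and evaluates accuracy on held-out odd trials for
#' every (train time, test time) pair. The decoder trained at the bin
#' centered on \code{what_time} (450 ms) defines the What coding direction.
#'
#' @param session A decision \code{dv_session}.
#' @param lambda Lasso penalty (default 0.01).
#' @param bin_centers Training/testing bin centers (s).
#' @param what_time Training time defining the What coding direction.
#' @param rt_std Optional precomputed standardized rate tensor at the bin
#'   centers (boxcar 50).
#' @return Object of class \code{decoder_surface}: \code{train_times},
#'   \code{test_times}, \code{accuracy} (train x test), per-time coding
#'   directions \code{cds}, \code{what_cd}, imbalance \code{flags}.
#' @export
what_decoder <- function(session, lambda = 0.01,
                         bin_centers = seq(0.025, 0.475, by = 0.05),
                         what_time = 0.45, rt_std = NULL) {
  stopifnot(inherits(session, "dv_session"), session$kind == "decision")
  if (is.null(rt_std)) {
    rt50 <- bin_and_smooth(session, t_lim = range(bin_centers), step = 0.05,
                           kernel = kernel_spec("boxcar", 50))
    rt_std <- standardize_neurons(rt50)
  }
  trials <- rt_std$trials
  even <- trials$trial_id %% 2 == 0
  y <- trials$choice == "left"
  n_t <- length(bin_centers)
  jmap <- vapply(bin_centers, function(tt) which.min(abs(rt_std$time - tt)), 1L)
  excl <- rt_std$norm$excluded %||% rep(FALSE, dim(rt_std$rates)[1])

  cds <- list(); flags <- character(0)
  for (k in seq_len(n_t)) {
    Xk <- t(rt_std$rates[, , jmap[k]])
    ok <- even & stats::complete.cases(Xk)
    frac <- mean(y[ok])
    if (frac > 0.95 || frac < 0.05) {
      flags <- c(flags, sprintf("imbalance at %.3f s (p_left=%.2f)",
                                bin_centers[k], frac))
    }
    fit <- glmnet::glmnet(Xk[ok, !excl, drop = FALSE], y[ok],
                          family = "binomial", alpha = 1, lambda = lambda,
                          standardize = FALSE)
    w <- numeric(ncol(Xk)); w[!excl] <- as.numeric(fit$beta)
    cds[[k]] <- new_coding_direction(w, "what", offset = as.numeric(fit$a0),
                                     meta = list(train_time = bin_centers[k],
                                                 lambda = lambda))
  }
  acc <- matrix(NA_real_, n_t, n_t,
                dimnames = list(train = NULL, test = NULL))
  odd <- !even
  for (k in seq_len(n_t)) {
    w <- cds[[k]]$weights; b <- cds[[k]]$offset
    for (m in seq_len(n_t)) {
      Xm <- t(rt_std$rates[, , jmap[m]])
      ok <- odd & stats::complete.cases(Xm)
      pred <- as.numeric(Xm[ok, , drop = FALSE] %*% w + b) > 0
      acc[k, m] <- mean(pred == y[ok])
    }
  }
  what_k <- which.min(abs(bin_centers - what_time))
  structure(list(train_times = bin_centers, test_times = bin_centers,
                 accuracy = acc, cds = cds, what_cd = cds[[what_k]],
                 flags = flags),
            class = "decoder_surface")
}

#' @export
print.decoder_surface <- function(x, ...) {
  cat(sprintf("decoder_surface: %d train x %d test times, accuracy %.2f-%.2f\n",
              length(x$train_times), length(x$test_times),
              min(x$accuracy, na.rm = TRUE), max(x$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Choice-decoding ceiling from the simulated decision variable
#'
#' Applies the held-out choice-decoding procedure to the one-dimensional
#' latent DV of the session (or of a race simulation): logistic decoder of
#' choice from DV(t), trained on even trials, accuracy on odd trials. This
#' estimates the decoding accuracy attainable were the true drift-diffusion
#' signal observable.
#'
#' @param trials Trials tibble with \code{trial_id}, \code{choice}.
#' @param dv_values Matrix trials x times of the latent DV.
#' @param times Time base of \code{dv_values} (trial time, s).
#' @param test_times Times at which to decode.
#' @return Tibble: \code{t}, \code{accuracy}.
#' @export
dv_ceiling_decoder <- function(trials, dv_values, times,
                               test_times = seq(0.025, 0.475, by = 0.05)) {
  even <- trials$trial_id %% 2 == 0
  y <- trials$choice == "left"
  purrr::map_dfr(test_times, function(tt) {
    j <- which.min(abs(times - tt))
    df <- data.frame(x = dv_values[, j], y = y)
    fit <- stats::glm(y ~ x, data = df[even, ], family = stats::binomial())
    pred <- stats::predict(fit, newdata = df[!even, ]) > 0
    tibble::tibble(t = tt, accuracy = mean(pred == df$y[!even]))
  })
}

#' Saccade-time decoder (When)
#'
#' Trains an L1-regularized logistic decoder to predict whether a saccade
#' to the left (contralateral) target occurs within the next 150 ms, from
#' raw spike counts in 25 ms bins spanning 200 ms before motion onset to
#' 50 ms before the saccade, using even-numbered left-choice trials
#' (correct and error). Validation: AUC on held-out odd left-choice trials.
#' The weights define the When coding direction; its ability to predict
#' choice on all trials is evaluated with the sign rule on the detrended
#' signal (subtracting the across-trial mean at each time).
#'
#' @param session A decision \code{dv_session}.
#' @param lambda Lasso penalty (default 0.01).
#' @param horizon Look-ahead horizon (s; default 0.15).
#' @return Object of class \code{when_decoder}: the \code{coding_direction}
#'   (with offset beta0), \code{auc} (per-time AUC tibble and its mean),
#'   and \code{choice_accuracy} (tibble of accuracy vs time from the sign
#'   rule).
#' @export
when_decoder <- function(session, lambda = 0.01, horizon = 0.15) {
  stopifnot(inherits(session, "dv_session"), session$kind == "decision")
  trials <- session$trials
  left <- which(trials$choice == "left")
  if (length(left) == 0) stop("no left-choice trials", call. = FALSE)
  bin_w <- 0.025
  t_cap <- min(max(trials$rt_s[left]), 2) # very long trials are excluded
  left <- left[trials$rt_s[left] <= t_cap]
  # 25 ms counts, bins indexed by start; counts = rate * bin width.
  # Only left-choice trials are needed here, so restrict the tensor.
  sub <- session
  sub$trials <- trials[left, ]
  sub$spikes <- session$spikes[session$spikes$trial_id %in%
                                 trials$trial_id[left], ]
  rtc <- bin_and_smooth(sub, t_lim = c(-0.2 + bin_w / 2, t_cap - 0.0375),
                        step = bin_w, kernel = kernel_spec("boxcar", 25),
                        censor = FALSE)
  row_of <- match(trials$trial_id, sub$trials$trial_id)
  starts <- rtc$time - bin_w / 2
  n_neu <- dim(rtc$rates)[1]

  build <- function(idx) {
    Xs <- list(); ys <- list(); tt <- list(); tr <- list()
    for (i in idx) {
      jj <- which(starts + bin_w <= trials$rt_s[i] - 0.05 + 1e-9)
      if (length(jj) == 0) next
      Xs[[length(Xs) + 1]] <-
        t(rtc$rates[, row_of[i], jj, drop = FALSE][, 1, ]) * bin_w
      ys[[length(ys) + 1]] <- when_labels(starts[jj], trials$rt_s[i], horizon)
      tt[[length(tt) + 1]] <- starts[jj]
      tr[[length(tr) + 1]] <- rep(i, length(jj))
    }
    list(X = do.call(rbind, Xs), y = unlist(ys), t = unlist(tt),
         trial = unlist(tr))
  }
  even_left <- left[trials$trial_id[left] %% 2 == 0]
  odd_left <- left[trials$trial_id[left] %% 2 == 1]
  tr_set <- build(even_left)
  fit <- glmnet::glmnet(tr_set$X, tr_set$y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  w <- as.numeric(fit$beta); b0 <- as.numeric(fit$a0)
  cd <- new_coding_direction(w, "when", offset = b0,
                             meta = list(lambda = lambda, horizon = horizon,
                                         frac_zero = mean(w == 0)))
  # held-out AUC per time point (odd left-choice trials)
  te <- build(odd_left)
  sc <- as.numeric(te$X %*% w) + b0
  auc_t <- purrr::map_dfr(split(seq_along(sc), te$t), function(ii) {
    y <- te$y[ii]
    if (length(unique(y)) < 2) return(NULL)
    tibble::tibble(t = te$t[ii[1]], auc = auc_rank(sc[ii][y == 1], sc[ii][y == 0]))
  })
  # choice accuracy on ALL trials via the sign of the detrended signal,
  # rendered with the standard 50 ms analysis boxcar
  rt50 <- bin_and_smooth(session, t_lim = c(0.0125, 0.4875), step = bin_w,
                         kernel = kernel_spec("boxcar", 50), censor = TRUE)
  sig <- project_signal(rt50, cd)
  sig$values <- sig$values * bin_w # signal in count units, as trained
  s_star <- sweep(sig$values, 2, colMeans(sig$values, na.rm = TRUE))
  is_left <- trials$choice == "left"
  correct_call <- (s_star > 0 & is_left) | (s_star <= 0 & !is_left)
  acc <- colMeans(ifelse(is.na(s_star), NA, correct_call), na.rm = TRUE)
  structure(list(cd = cd,
                 auc = list(by_time = auc_t, mean = mean(auc_t$auc)),
                 choice_accuracy = tibble::tibble(t = sig$time, accuracy = acc)),
            class = "when_decoder")
}

#' @export
print.when_decoder <- function(x, ...) {
  cat(sprintf("when_decoder: mean held-out AUC %.3f; choice accuracy %.2f at %.2f s\n",
              x$auc$mean, max(x$choice_accuracy$accuracy, na.rm = TRUE),
              x$choice_accuracy$t[which.max(x$choice_accuracy$accuracy)]))
  invisible(x)
}

#' Step labels for the When decoder
#'
#' A 25 ms bin is labeled 1 when the saccade occurs within \code{horizon}
#' of its start (e.g. a saccade at 400 ms labels exactly the bins whose
#' start is at or after 250 ms).
#'
#' @param bin_starts Bin start times (s).
#' @param saccade_t Saccade time (s).
#' @param horizon Look-ahead (s), default 0.15.
#' @return Integer 0/1 labels.
#' @export
when_labels <- function(bin_starts, saccade_t, horizon = 0.15) {
  as.integer(bin_starts >= saccade_t - horizon - 1e-9)
}

#' Null distributions for coding-direction similarity
#'
#' Cosine similarities between random coding directions: (i) random
#' permutations of each direction's weights, (ii) random unit vectors.
#'
#' @param cd_x,cd_y Coding directions.
#' @param n_perm Number of draws (default 1000).
#' @return Tibble with \code{kind} ("permuted"/"unit") and \code{cosine}.
#' @export
similarity_nulls <- function(cd_x, cd_y, n_perm = 1000) {
  x <- cd_x$weights; y <- cd_y$weights
  n <- length(x)
  perm <- vapply(seq_len(n_perm), function(i) {
    cosine_similarity(x[sample.int(n)], y[sample.int(n)])
  }, 0)
  unitv <- vapply(seq_len(n_perm), function(i) {
    cosine_similarity(stats::rnorm(n), stats::rnorm(n))
  }, 0)
  tibble::tibble(kind = rep(c("permuted", "unit"), each = n_perm),
                 cosine = c(perm, unitv))
}

#' Within-trial correlation of two single-trial signals
#'
#' Pearson correlation, per trial, between two detrended signals over
#' successive 50 ms bins from 200 ms after motion onset to 100 ms before
#' the saccade; trials with fewer than \code{min_bins} bins are excluded.
#' The mean correlation is the Fisher-z average across trials.
#'
#' @param sig_x,sig_y Detrended [project_signal()] results on a common
#'   50-ms-step grid.
#' @param min_bins Minimum usable bins per trial (default 4).
#' @return List: \code{mean_r}, per-trial \code{r}, \code{n_trials}.
#' @export
within_trial_correlation <- function(sig_x, sig_y, min_bins = 4) {
  stopifnot(identical(sig_x$time, sig_y$time))
  use_t <- sig_x$time >= 0.2
  r <- rep(NA_real_, nrow(sig_x$values))
  for (i in seq_len(nrow(sig_x$values))) {
    a <- sig_x$values[i, use_t]; b <- sig_y$values[i, use_t]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_bins) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    r[i] <- stats::cor(a[ok], b[ok])
  }
  list(mean_r = fisher_mean(r), r = r, n_trials = sum(!is.na(r)))
}

#' Permuted-weight nulls for within-trial correlations
#'
#' Re-projects the population onto weight-permuted (or random unit) coding
#' directions and recomputes the within-trial correlation, yielding a null
#' distribution for the similarity of single-trial signals.
#'
#' @param rt_det A rate tensor (50 ms boxcar grid) from which signals are
#'   projected; detrending is applied to each null projection.
#' @param cd_x,cd_y Coding directions whose weights are permuted.
#' @param n_perm Number of permutations.
#' @param kind "permuted" or "unit".
#' @return Numeric vector of null mean correlations.
#' @export
within_trial_nulls <- function(rt_det, cd_x, cd_y, n_perm = 200,
                               kind = c("permuted", "unit")) {
  kind <- match.arg(kind)
  n <- length(cd_x$weights)
  vapply(seq_len(n_perm), function(i) {
    wx <- if (kind == "permuted") cd_x$weights[sample.int(n)] else stats::rnorm(n)
    wy <- if (kind == "permuted") cd_y$weights[sample.int(n)] else stats::rnorm(n)
    sx <- detrend_signal(project_signal(rt_det, wx))
    sy <- detrend_signal(project_signal(rt_det, wy))
    within_trial_correlation(sx, sy)$mean_r
  }, 0)
}

#' Retrain the choice decoder after ablating neuron groups
#'
#' Drops the listed ground-truth label groups (their weights are forced to
#' zero by excluding them from training) and re-runs [what_decoder()].
#'
#' @param session A decision \code{dv_session}.
#' @param drop Character vector of labels to remove (e.g.
#'   \code{c("Tin_con", "Tin_ips", "Min_left", "Min_right")}), or
#'   \code{"all_but_tin"} to keep only Tin neurons.
#' @param ... Passed to [what_decoder()].
#' @return A \code{decoder_surface}.
#' @export
ablate_and_decode <- function(session, drop = character(0), ...) {
  stopifnot(inherits(session, "dv_session"))
  keep <- if (identical(drop, "all_but_tin")) {
    session$neurons$label %in% c("Tin_con", "Tin_ips")
  } else {
    !(session$neurons$label %in% drop)
  }
  if (!any(keep)) stop("ablation removes every neuron", call. = FALSE)
  sub <- session
  sub$neurons <- session$neurons[keep, ]
  sub$spikes <- session$spikes[session$spikes$neuron_id %in%
                                 session$neurons$neuron_id[keep], ]
  what_decoder(sub, ...)
}
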