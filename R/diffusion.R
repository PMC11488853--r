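#' Closed-form covariance of boxcar-smoothed Wiener samples
#'
#' For a standard Wiener process started at \code{t_origin} (unit variance
#' per second; zero before the origin), consider window means
#' \eqn{M_i = w^{-1}\int_{window_i} W(s)\,ds} for boxcar windows of width
#' \code{w} centered at \code{sample_centers}. Their covariance is
#' \deqn{Cov(M_i, M_j) = w^{-2}\iint \min((s-t_0)_+, (u-t_0)_+)\, ds\, du.}
#' For windows fully past the origin, non-overlapping or identical, closed
#' forms apply: \eqn{Cov = \tau_i} (diffusion-time center of the earlier
#' window) and \eqn{Var(M_i) = \tau_i - w/6}; the general/overlapping case
#' is evaluated by midpoint quadrature of the double integral. As
#' \eqn{w \to 0} the correlation reduces to the unsmoothed Wiener form
#' \eqn{\sqrt{\tau_i/\tau_j}}.
#'
#' @param sample_centers Window centers (s from the alignment event).
#'   Default: six windows separated by the filter width, starting 26 ms
#'   into diffusion time.
#' @param w Boxcar width (s); default 0.051.
#' @param t_origin Diffusion (integration) origin (s); default 0.2.
#' @param n_quad Midpoint nodes per axis for the quadrature fallback.
#' @return Object of class \code{wiener_theory}: \code{centers}, \code{tau}
#'   (centers minus origin), \code{w}, \code{cov}, \code{corr}.
#' @examples
#' th <- wiener_theory()
#' round(th$corr[1, ], 3)
#' @export
wiener_theory <- function(sample_centers = 0.226 + 0.051 * (0:5),
                          w = 0.051, t_origin = 0.2, n_quad = 400) {
  k <- length(sample_centers)
  if (k < 1) stop("need at least one window", call. = FALSE)
  a <- sample_centers - w / 2
  b <- sample_centers + w / 2
  tau <- sample_centers - t_origin
  cv <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      past <- a[i] >= t_origin && a[j] >= t_origin
      disjoint <- b[i] <= a[j] + 1e-12
      if (past && i == j) {
        cv[i, i] <- tau[i] - w / 6
      } else if (past && disjoint) {
        cv[i, j] <- cv[j, i] <- tau[i]
      } else {
        # midpoint quadrature of the clipped double integral
        s <- a[i] + (seq_len(n_quad) - 0.5) * (b[i] - a[i]) / n_quad
        u <- a[j] + (seq_len(n_quad) - 0.5) * (b[j] - a[j]) / n_quad
        g <- outer(pmax(s - t_origin, 0), pmax(u - t_origin, 0), pmin)
        cv[i, j] <- cv[j, i] <- mean(g)
      }
    }
  }
  cr <- stats::cov2cor(cv)
  structure(list(centers = sample_centers, tau = tau, w = w,
                 t_origin = t_origin, cov = cv, corr = cr),
            class = "wiener_theory")
}

#' Monte-Carlo oracle for boxcar-smoothed Wiener covariance
#'
#' Simulates discrete Wiener paths at \code{1/dt} Hz (increments
#' \eqn{N(0, dt)}, integration starting at \code{t_origin}), averages each
#' path over the boxcar windows, and returns the sample covariance and
#' correlation. Window means are formed exactly as weighted sums of
#' increments, so memory stays flat in the number of paths.
#'
#' @inheritParams wiener_theory
#' @param n_paths Number of simulated paths.
#' @param dt Sampling step (s); default 0.001.
#' @param chunk Paths per block.
#' @return List with \code{cov}, \code{corr}, \code{n_paths}.
#' @export
wiener_window_mc <- function(n_paths, sample_centers = 0.226 + 0.051 * (0:5),
                             w = 0.051, t_origin = 0.2, dt = 0.001,
                             chunk = 10000) {
  k <- length(sample_centers)
  C <- wiener_window_coefs(sample_centers, w, t_origin, dt)
  n_steps <- ncol(C)
  cp <- matrix(0, k, k); sm <- numeric(k); n_done <- 0
  while (n_done < n_paths) {
    m <- min(chunk, n_paths - n_done)
    E <- matrix(stats::rnorm(m * n_steps, sd = sqrt(dt)), m, n_steps)
    M <- E %*% t(C)
    cp <- cp + crossprod(M)
    sm <- sm + colSums(M)
    n_done <- n_done + m
  }
  cv <- (cp - tcrossprod(sm) / n_paths) / (n_paths - 1)
  list(cov = cv, corr = stats::cov2cor(cv), n_paths = n_paths)
}

#' Simulate smoothed-Wiener window samples with planted nuisance variance
#'
#' Draws per-trial window means of a boxcar-smoothed Wiener process (as in
#' [wiener_window_mc()]) and optionally adds independent Gaussian noise to
#' each sample so that diffusion contributes a fraction
#' \code{diffusion_frac} of each sample's total variance. Used to verify
#' that the nuisance-variance factor \eqn{\phi} is recovered.
#'
#' @inheritParams wiener_window_mc
#' @param n_trials Number of trials (rows).
#' @param diffusion_frac Fraction of each sample's variance contributed by
#'   diffusion; 1 means pure smoothed Wiener.
#' @return Matrix \code{n_trials x length(sample_centers)}.
#' @export
simulate_smoothed_wiener <- function(n_trials,
                                     sample_centers = 0.226 + 0.051 * (0:5),
                                     w = 0.051, t_origin = 0.2, dt = 0.001,
                                     diffusion_frac = 1) {
  stopifnot(diffusion_frac > 0, diffusion_frac <= 1)
  th <- wiener_theory(sample_centers, w, t_origin)
  k <- length(sample_centers)
  C <- wiener_window_coefs(sample_centers, w, t_origin, dt)
  E <- matrix(stats::rnorm(n_trials * ncol(C), sd = sqrt(dt)), n_trials, ncol(C))
  M <- E %*% t(C)
  if (diffusion_frac < 1) {
    extra_sd <- sqrt(diag(th$cov) * (1 / diffusion_frac - 1))
    M <- M + matrix(stats::rnorm(n_trials * k), n_trials, k) %*% diag(extra_sd)
  }
  M
}

#' Empirical variance and autocorrelation of single-trial window samples
#'
#' Computes the across-trial variance of each window sample (normalized so
#' the first sample is 1), the covariance and correlation matrices, and
#' bootstrap standard errors from resamples that respect the composition of
#' signed motion strength.
#'
#' @param samples Matrix, trials x windows, of detrended (and, for neural
#'   signals, t-origin baseline-corrected) window means. Rows with any
#'   \code{NA} (censored windows) are dropped.
#' @param signed_coh Optional per-trial signed coherence used to stratify
#'   the bootstrap; default one stratum.
#' @param n_boot Bootstrap resamples (default 500).
#' @param min_trials Refuse below this many complete trials.
#' @return Object of class \code{diffusion_emp}: \code{var_curve},
#'   \code{var_se}, \code{cov}, \code{corr}, \code{corr_se}, \code{n}.
#' @export
empirical_var_autocorr <- function(samples, signed_coh = NULL, n_boot = 500,
                                   min_trials = 100) {
  samples <- as.matrix(samples)
  ok <- stats::complete.cases(samples)
  samples <- samples[ok, , drop = FALSE]
  n <- nrow(samples)
  if (n < min_trials) {
    stop(sprintf("only %d eligible trials (need >= %d)", n, min_trials),
         call. = FALSE)
  }
  g <- if (is.null(signed_coh)) rep(1, n) else signed_coh[ok]
  stat <- function(m) {
    cv <- stats::cov(m)
    list(var_curve = diag(cv) / cv[1, 1], cov = cv, corr = stats::cov2cor(cv))
  }
  obs <- stat(samples)
  idx_by_g <- split(seq_len(n), g)
  k <- ncol(samples)
  bv <- matrix(NA_real_, n_boot, k)
  bc <- array(NA_real_, c(n_boot, k, k))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_g, function(ii) ii[sample.int(length(ii),
                                                              replace = TRUE)]),
                  use.names = FALSE)
    s <- stat(samples[idx, , drop = FALSE])
    bv[b, ] <- s$var_curve
    bc[b, , ] <- s$corr
  }
  structure(list(var_curve = obs$var_curve,
                 var_se = apply(bv, 2, stats::sd),
                 cov = obs$cov, corr = obs$corr,
                 corr_se = apply(bc, c(2, 3), stats::sd),
                 n = n),
            class = "diffusion_emp")
}

#' Fit the nuisance-variance factor phi
#'
#' Unexplained (non-diffusion) variance inflates the diagonal of the
#' empirical covariance and hence deflates the autocorrelations. A scalar
#' \eqn{\phi \le 1} multiplies the diagonal before normalization:
#' \eqn{r_{ij}(\phi) = C_{ij} / (\phi\sqrt{C_{ii} C_{jj}})}. \eqn{\phi} is
#' found by bounded scalar minimization of the sum of squared differences
#' between Fisher-z transformed model and theory correlations.
#'
#' @param emp_cov Empirical covariance matrix (or a \code{diffusion_emp}).
#' @param theory A [wiener_theory()] object (or a correlation matrix).
#' @param tol Optimizer tolerance; default 1e-4.
#' @return List: \code{phi}, \code{boundary} (\code{TRUE} if the solution
#'   lies at 0 or 1), \code{objective}.
#' @export
fit_phi <- function(emp_cov, theory, tol = 1e-4) {
  if (inherits(emp_cov, "diffusion_emp")) emp_cov <- emp_cov$cov
  rth <- if (inherits(theory, "wiener_theory")) theory$corr else theory
  k <- nrow(emp_cov)
  ut <- upper.tri(emp_cov)
  r_raw <- stats::cov2cor(emp_cov)[ut]
  z_th <- atanh(pmin(pmax(rth[ut], -0.999999), 0.999999))
  obj <- function(phi) {
    r <- pmin(pmax(r_raw / phi, -0.999999), 0.999999)
    sum((atanh(r) - z_th)^2)
  }
  o <- stats::optimize(obj, c(1e-3, 1), tol = tol)
  phi <- o$minimum
  boundary <- phi <= 1e-3 + 2 * tol || phi >= 1 - 2 * tol
  list(phi = phi, boundary = boundary, objective = o$objective)
}

# Increment-weight matrix for boxcar window means of a discrete Wiener path:
# M_i = sum_j C[i, j] e_j, where e_j ~ N(0, dt) is the increment ending at
# sample time t_origin + j*dt. Each window covers the samples within w/2 of
# its center; an increment is weighted by the fraction of window samples at
# or after it (1 for increments before the window).
wiener_window_coefs <- function(sample_centers, w, t_origin, dt) {
  k <- length(sample_centers)
  n_steps <- ceiling((max(sample_centers) + w / 2 - t_origin) / dt) + 1L
  t_s <- t_origin + seq_len(n_steps) * dt
  C <- matrix(0, k, n_steps)
  for (i in seq_len(k)) {
    win <- which(t_s >= sample_centers[i] - w / 2 - 1e-9 &
                   t_s <= sample_centers[i] + w / 2 + 1e-9)
    C[i, win] <- rev(seq_along(win)) / length(win)
    if (min(win) > 1) C[i, seq_len(min(win) - 1)] <- 1
  }
  C
}
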