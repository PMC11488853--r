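# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fisher-z mean of correlation coefficients: atanh-average, back-transformed.
#' Fisher-z mean of correlations
#'
#' Averages correlation coefficients on the variance-stabilized atanh scale
#' and back-transforms: \eqn{\bar r = \tanh(\mathrm{mean}(\mathrm{atanh}(r_k)))}.
#' @param r Vector of correlations; \code{NA}s dropped.
#' @return Scalar mean correlation.
#' @export
fisher_mean <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0) return(NA_real_)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

# Rank-based AUC (equivalent to the Wilcoxon/Mann-Whitney statistic):
# P(X > Y) + 0.5 P(X = Y) for x ~ positive class, y ~ negative class.
auc_rank <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) return(NA_real_)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

# Running boxcar mean over the columns of a matrix (rows = series), window
# [i - back, i + fwd] in samples, edge windows truncated and renormalized.
boxcar_rows <- function(m, back, fwd) {
  n <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
}

# Residualize y on columns of X (adds intercept); returns residuals.
residualize <- function(y, X) {
  X <- cbind(1, X)
  stats::lm.fit(X, y)$residuals
}

# Partial correlation of x and y given z, via regression residuals.
partial_cor <- function(x, y, z) {
  stats::cor(residualize(x, z), residualize(y, z))
}

# group-wise demeaning: returns x - mean(x | g)
demean_by <- function(x, g) {
  x - stats::ave(x, g, FUN = function(v) mean(v, na.rm = TRUE))
}

# Simple deterministic seed-stream derivation: stable sub-seeds below 2^31.
substream_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + match(stream, letters28())[1] * 7919L) %% 2147483647L
}

letters28 <- function() {
  c("simulate", "population", "passive", "saccade", "signals", "cd", "what",
    "when", "diffusion", "mediate", "boot", "null", "perm", "min", "latency",
    "xcorr", "psi", "pipeline", "noise", "split", "misc", "a", "b", "c", "d",
    "e", "f", "g")
}
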