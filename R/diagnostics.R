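# MCMC convergence diagnostics: rank-normalised split R-hat and bulk
# effective sample size, following the standard split/rank formulations.

#' Convergence diagnostics for posterior draws
#'
#' Computes, per parameter, the rank-normalised split potential scale
#' reduction factor (split R-hat) and the bulk effective sample size (ESS,
#' from the combined-chain autocorrelation with Geyer's initial monotone
#' truncation).  The overall `pass` flag requires every parameter to have
#' split R-hat below 1.01 and ESS above 400 and no divergent transitions;
#' the Gibbs/slice backend used here does not produce divergences, so the
#' divergence count is reported as zero.  Parameters with zero variance
#' yield `NA` diagnostics and fail the check.
#'
#' @param x An `nst_draws` object, or an iterations x chains x parameters
#'   array.
#' @param rhat_max,ess_min Pass thresholds.
#' @return List of class `nst_diagnostics`: `summary` (data frame with
#'   `parameter`, `rhat`, `ess`), `pass`, `max_rhat`, `min_ess`,
#'   `divergences`.
#' @export
compute_diagnostics <- function(x, rhat_max = 1.01, ess_min = 400) {
  arr <- if (inherits(x, "nst_draws")) x$draws else x
  if (length(dim(arr)) != 3L) {
    stop_("x must be an iterations x chains x parameters array")
  }
  if (dim(arr)[2] < 2L) stop_("split-R-hat undefined with a single chain")
  if (dim(arr)[1] < 4L) stop_("need at least 4 iterations per chain")
  pn <- dimnames(arr)[[3]] %||% paste0("par", seq_len(dim(arr)[3]))
  rhat <- vapply(seq_len(dim(arr)[3]), function(j) {
    split_rhat(arr[, , j, drop = TRUE])
  }, numeric(1))
  ess <- vapply(seq_len(dim(arr)[3]), function(j) {
    ess_bulk(arr[, , j, drop = TRUE])
  }, numeric(1))
  summary <- data.frame(parameter = pn, rhat = rhat, ess = ess,
                        stringsAsFactors = FALSE)
  pass <- !anyNA(rhat) && !anyNA(ess) &&
    all(rhat < rhat_max) && all(ess > ess_min)
  structure(
    list(summary = summary, pass = pass,
         max_rhat = if (anyNA(rhat)) NA_real_ else max(rhat),
         min_ess = if (anyNA(ess)) NA_real_ else min(ess),
         divergences = 0L,
         rhat_max = rhat_max, ess_min = ess_min),
    class = "nst_diagnostics"
  )
}

#' @export
print.nst_diagnostics <- function(x, ...) {
  cat(sprintf(
    "MCMC diagnostics over %d parameters: max split-R-hat %s, min ESS %s -> %s\n",
    nrow(x$summary),
    formatC(x$max_rhat, digits = 4, format = "f"),
    formatC(x$min_ess, digits = 0, format = "f"),
    if (isTRUE(x$pass)) "PASS" else "NOT PASSED"
  ))
  invisible(x)
}

# split each chain in half, dropping one leading iteration if odd length
split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  m <- m[(n - 2L * half + 1L):n, , drop = FALSE]
  cbind(m[seq_len(half), , drop = FALSE],
        m[half + seq_len(half), , drop = FALSE])
}

# rank-normalise the pooled draws, preserving the matrix layout
rank_normalize <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- stats::qnorm((r - 0.375) / (length(m) + 0.25))
  matrix(z, nrow(m), ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2L, stats::var))
  B <- n * stats::var(colMeans(m))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_rhat <- function(m) {
  if (all(m == m[1])) return(NA_real_)
  rhat_basic(rank_normalize(split_chains(m)))
}

# FFT autocovariance at lags 0..n-1 (biased 1/n normalisation)
autocovariance <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2L^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, nfft - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (nfft * n)
}

ess_bulk <- function(m) {
  if (all(m == m[1])) return(NA_real_)
  m <- rank_normalize(split_chains(m))
  n <- nrow(m)
  nch <- ncol(m)
  acov <- sapply(seq_len(nch), function(j) autocovariance(m[, j]))
  W <- mean(acov[1, ]) * n / (n - 1) # within-chain sample variance
  var_plus <- W * (n - 1) / n + stats::var(colMeans(m))
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus # rho[1] = lag 0
  # Geyer initial positive monotone sequence over paired lag sums
  tau_pairs <- numeric(0)
  prev <- Inf
  k <- 1L
  while (k + 1L <= n - 1L) {
    pair <- rho[k] + rho[k + 1L] # lags k-1 and k
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau_pairs <- c(tau_pairs, pair)
    prev <- pair
    k <- k + 2L
  }
  tau <- max(-1 + 2 * sum(tau_pairs), 1 / log10(n * nch))
  min(n * nch / tau, n * nch * log10(n * nch))
}
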