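# Model comparison: WAIC with standard errors of differences, posterior
# predictive acceptance curves, and the confound-check correlations.

#' Widely-Applicable Information Criterion
#'
#' From a draws x trials matrix of pointwise log-likelihoods:
#' `lppd_i = log mean_d exp(loglik_di)` (computed with an overflow-safe
#' log-sum-exp), `p_waic_i = var_d loglik_di`, and on the deviance scale
#' `waic = -2 (lppd - p_waic)` with
#' `se_waic = sqrt(n var(waic_i))` over the pointwise contributions
#' `waic_i = -2 (lppd_i - p_waic_i)`.  The pointwise unit is the trial,
#' the convention for Bernoulli observations.
#'
#' @param loglik Matrix of log-likelihood draws, draws in rows, trials in
#'   columns (from [loglik_matrix()] or any backend).
#' @return List of class `nst_waic`: `lppd`, `p_waic`, `waic`, `se_waic`,
#'   `elpd` (the elpd-scale accessor, `lppd - p_waic`) and `pointwise`
#'   (data frame of per-trial `lppd_i`, `p_waic_i`, `waic_i`).
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2L) stop_("variance undefined with a single draw")
  if (ncol(loglik) < 1L || any(!is.finite(loglik))) {
    stop_("loglik must be a finite draws x trials matrix")
  }
  D <- nrow(loglik)
  mx <- apply(loglik, 2L, max)
  lppd_i <- log(colMeans(exp(sweep(loglik, 2L, mx)))) + mx
  mu <- colMeans(loglik)
  p_waic_i <- colSums(sweep(loglik, 2L, mu)^2) / (D - 1)
  waic_i <- -2 * (lppd_i - p_waic_i)
  n <- length(lppd_i)
  structure(
    list(
      lppd = sum(lppd_i), p_waic = sum(p_waic_i), waic = sum(waic_i),
      elpd = sum(lppd_i) - sum(p_waic_i),
      se_waic = sqrt(n * stats::var(waic_i)),
      pointwise = data.frame(lppd_i = lppd_i, p_waic_i = p_waic_i,
                             waic_i = waic_i)
    ),
    class = "nst_waic"
  )
}

#' @export
print.nst_waic <- function(x, ...) {
  cat(sprintf("WAIC %.1f (SE %.1f); lppd %.1f, p_waic %.1f, n = %d\n",
              x$waic, x$se_waic, x$lppd, x$p_waic, nrow(x$pointwise)))
  invisible(x)
}

#' Rank models by WAIC
#'
#' Computes WAIC per model and the difference of each model to the best
#' (lowest-WAIC) model, with the standard error of that difference from
#' the paired pointwise contributions:
#' `se_delta = sqrt(n var(waic_i^model - waic_i^best))`.  Ties in WAIC are
#' broken by the lower model id.
#'
#' @param models Named list (names = model ids) of either loglik matrices
#'   (draws x trials) or [waic()] results; all must share the same trials.
#' @return Data frame of class `nst_comparison`, sorted by WAIC:
#'   `model_id`, `waic`, `se_waic`, `delta_waic`, `se_delta`, `rank`.
#' @export
compare_models <- function(models) {
  if (length(models) < 1L) stop_("no models to compare")
  ids <- names(models) %||% as.character(seq_along(models))
  ws <- lapply(models, function(m) {
    if (inherits(m, "nst_waic")) m else waic(m)
  })
  n <- nrow(ws[[1]]$pointwise)
  if (!all(vapply(ws, function(w) nrow(w$pointwise), integer(1)) == n)) {
    stop_("mismatched trial counts: all models must score the same dataset")
  }
  wv <- vapply(ws, `[[`, numeric(1), "waic")
  best <- order(wv, as.numeric(ids))[1]
  pw_best <- ws[[best]]$pointwise$waic_i
  delta <- wv - wv[best]
  se_delta <- vapply(ws, function(w) {
    d <- w$pointwise$waic_i - pw_best
    if (all(abs(d) < 1e-12)) 0 else sqrt(n * stats::var(d))
  }, numeric(1))
  out <- data.frame(
    model_id = as.integer(ids),
    waic = wv,
    se_waic = vapply(ws, `[[`, numeric(1), "se_waic"),
    delta_waic = delta,
    se_delta = se_delta
  )
  out <- out[order(out$waic, out$model_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("nst_comparison", "data.frame")
  out
}

#' Write a model-comparison table to CSV
#'
#' Header: `model_id,waic,se_waic,delta_waic,se_delta,rank`.
#'
#' @param comparison Result of [compare_models()].
#' @param file Path.
#' @export
write_comparison <- function(comparison, file) {
  utils::write.csv(
    comparison[, c("model_id", "waic", "se_waic", "delta_waic",
                   "se_delta", "rank")],
    file, row.names = FALSE, quote = FALSE
  )
  invisible(comparison)
}

#' Posterior predictive acceptance curves
#'
#' For each of the 16 reward-by-effort cells, summarises the posterior of
#' the population-level acceptance probability (the linear predictor at
#' the population means, through the logistic) and of a new subject's
#' acceptance probability (integrating over the population SDs by
#' simulation).  Under effort discounting these curves decrease in effort
#' and flatten at higher reward.
#'
#' @param fit An `nst_draws` object.
#' @param prob Central interval probability (0.89 by convention here).
#' @param draw_subsample Posterior draws used (deterministic thinning).
#' @param newsubj_draws Simulated new subjects per posterior draw.
#' @param seed Seed for the new-subject simulation.
#' @return Data frame with `reward_points`, `effort_label`, `kind`
#'   (`"population"` or `"new_subject"`), `mean`, `lower`, `upper`.
#' @export
posterior_predictive_acceptance <- function(fit, prob = 0.89,
                                            draw_subsample = 500L,
                                            newsubj_draws = 1000L,
                                            seed = 1L) {
  stopifnot(inherits(fit, "nst_draws"))
  m <- as.matrix(fit)
  if (nrow(m) > draw_subsample) {
    m <- m[round(seq(1, nrow(m), length.out = draw_subsample)), ,
           drop = FALSE]
  }
  D <- nrow(m)
  spec <- fit$spec
  cells <- expand.grid(reward_points = REWARD_POINTS,
                       effort_label = EFFORT_LABELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z <- standardize_predictors(cells$reward_points, cells$effort_label)
  z$intercept <- 1
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  pop_rows <- vector("list", nrow(cells))
  new_rows <- vector("list", nrow(cells))
  zmat <- with_seed(seed, {
    vt <- names(spec$terms)[spec$terms == "varying"]
    stats::setNames(lapply(vt, function(t) {
      matrix(stats::rnorm(D * newsubj_draws), D, newsubj_draws)
    }), vt)
  })
  for (i in seq_len(nrow(cells))) {
    eta_pop <- rep(0, D)
    eta_new <- matrix(0, D, newsubj_draws)
    for (term in names(spec$terms)) {
      x <- if (term == "intercept") 1 else z[[term_predictor[[term]]]][i]
      if (spec$terms[[term]] == "varying") {
        mu <- m[, paste0("mu_", term)]
        sg <- m[, paste0("sigma_", term)]
        eta_pop <- eta_pop + mu * x
        eta_new <- eta_new + (mu + sg * zmat[[term]]) * x
      } else {
        b <- m[, term_par(term)]
        eta_pop <- eta_pop + b * x
        eta_new <- eta_new + b * x
      }
    }
    p_pop <- stats::plogis(eta_pop)
    p_new <- stats::plogis(as.vector(eta_new))
    pop_rows[[i]] <- c(mean(p_pop), stats::quantile(p_pop, qs))
    new_rows[[i]] <- c(mean(p_new), stats::quantile(p_new, qs))
  }
  bind <- function(rows, kind) {
    v <- do.call(rbind, rows)
    data.frame(cells, kind = kind, mean = v[, 1], lower = v[, 2],
               upper = v[, 3], row.names = NULL)
  }
  out <- rbind(bind(pop_rows, "population"), bind(new_rows, "new_subject"))
  attr(out, "prob") <- prob
  out
}

#' Write posterior predictive cell summaries to CSV
#'
#' Header: `reward_points,effort_label,mean,lower89,upper89` (one `kind`
#' at a time; intervals are the 89% quantile interval by default).
#'
#' @param ppc Result of [posterior_predictive_acceptance()].
#' @param file Path.
#' @param kind `"population"` or `"new_subject"`.
#' @export
write_ppc <- function(ppc, file, kind = "population") {
  x <- ppc[ppc$kind == kind, c("reward_points", "effort_label",
                               "mean", "lower", "upper")]
  names(x) <- c("reward_points", "effort_label", "mean", "lower89",
                "upper89")
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Prior predictive acceptance curves
#'
#' The prior-predictive-check counterpart of
#' [posterior_predictive_acceptance()]: population-level acceptance curves
#' implied by the prior alone, for tuning prior scales before seeing data.
#'
#' @param spec [model_spec()].
#' @param priors [nst_priors()].
#' @param n_draws Prior draws.
#' @param prob Central interval probability.
#' @param seed Optional seed.
#' @return Data frame with `reward_points`, `effort_label`, `mean`,
#'   `lower`, `upper` of the prior population-level acceptance probability.
#' @export
prior_predictive_acceptance <- function(spec, priors = nst_priors(),
                                        n_draws = 1000L, prob = 0.89,
                                        seed = NULL) {
  pr <- sample_prior(spec, priors, n_draws, seed)
  cells <- expand.grid(reward_points = REWARD_POINTS,
                       effort_label = EFFORT_LABELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z <- standardize_predictors(cells$reward_points, cells$effort_label)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    eta <- rep(0, n_draws)
    for (term in names(spec$terms)) {
      x <- if (term == "intercept") 1 else z[[term_predictor[[term]]]][i]
      b <- if (spec$terms[[term]] == "varying") pr[[paste0("mu_", term)]]
           else pr[[term_par(term)]]
      eta <- eta + b * x
    }
    p <- stats::plogis(eta)
    c(mean(p), stats::quantile(p, qs))
  })
  v <- do.call(rbind, out)
  data.frame(cells, mean = v[, 1], lower = v[, 2], upper = v[, 3],
             row.names = NULL)
}

#' Observed acceptance frequency per design cell
#'
#' @param data Choice dataset.
#' @return Data frame `reward_points`, `effort_label`, `n`, `acceptance`.
#' @export
cell_acceptance <- function(data) {
  agg <- stats::aggregate(
    accepted ~ reward_points + effort_label, data = data,
    FUN = function(x) c(n = length(x), acc = mean(x))
  )
  data.frame(
    reward_points = agg$reward_points,
    effort_label = agg$effort_label,
    n = agg$accepted[, "n"],
    acceptance = agg$accepted[, "acc"]
  )
}

#' Pearson correlation test
#'
#' Pearson r with `t = r sqrt(df / (1 - r^2))`, `df = n - 2`, and a
#' two-sided p-value from the t distribution -- the form used for the
#' effort-sensitivity vs success and acceptance vs completion-time
#' confound checks.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return List of class `nst_cortest` with `r`, `df`, `t`, `p`, `n`.
#' @export
#' @examples
#' correlation_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_("degenerate input")
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(r = r, df = df, t = t, p = p, n = n),
            class = "nst_cortest")
}

#' @export
print.nst_cortest <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, t = %.2f, p = %.3g\n", x$df, x$r, x$t, x$p))
  invisible(x)
}
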