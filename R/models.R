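# Model suite: predictor standardisation, the 12 fixed/varying logistic
# model variants, priors, likelihood/posterior densities and MCMC sampling
# through JAGS.

MODEL_TERMS <- c("intercept", "reward", "reward2", "effort", "effort2")

#' Standardise reward and effort predictors
#'
#' Predictors are standardised against the four design-level values (the
#' population SD of the level grid, not the realised trial mix), so
#' z-values are dataset-independent: z = (x - mean of levels) / population
#' SD of levels.  Both grids are affine images of 1..4, so the four reward
#' z-values equal the four effort z-values.  Quadratic terms are the
#' squares of the standardised linear terms.
#'
#' @param reward_points Reward offers, each in 3/6/9/12.
#' @param effort_label Effort levels as `"20%"`-style labels or numeric
#'   percentages.
#' @return Data frame with `reward_z`, `reward_z2`, `effort_z`, `effort_z2`.
#' @export
#' @examples
#' standardize_predictors(3, "20%") # both z = -1.3416
standardize_predictors <- function(reward_points, effort_label) {
  if (!all(reward_points %in% REWARD_POINTS)) {
    stop_("out-of-grid reward level; expected one of 3, 6, 9, 12")
  }
  eff <- normalize_effort(effort_label)
  rz <- (reward_points - mean(REWARD_POINTS)) / pop_sd(REWARD_POINTS)
  ez <- (eff - mean(c(20, 40, 60, 80))) / pop_sd(c(20, 40, 60, 80))
  data.frame(reward_z = rz, reward_z2 = rz^2, effort_z = ez, effort_z2 = ez^2)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' The twelve model variants
#'
#' Every model is a logistic regression of the accept/reject choice with a
#' subset of the terms intercept (I), reward (R), reward squared (R2),
#' effort (E) and effort squared (E2); each included term is either fixed
#' (one shared value) or varying (a value per subject constrained by a
#' hierarchical Normal prior).  `model_catalogue()` returns all twelve;
#' `model_spec(id)` returns one.
#'
#' @param id Model id, 1..12.
#' @return A list of `nst_model_spec` objects, or a single one.  Each spec
#'   has `id` and `terms`, a named character vector mapping term ->
#'   `"fixed"`/`"varying"`.
#' @export
#' @examples
#' model_spec(9)  # varying I, R, R2, E
#' length(model_catalogue())
model_catalogue <- function() {
  defs <- list(
    `1` = c(intercept = "fixed"),
    `2` = c(intercept = "fixed", reward = "fixed", effort = "fixed"),
    `3` = c(intercept = "varying", reward = "fixed", effort = "fixed"),
    `4` = c(intercept = "varying", reward = "varying", effort = "varying"),
    `5` = c(intercept = "fixed", reward = "fixed", effort = "fixed",
            effort2 = "fixed"),
    `6` = c(intercept = "varying", reward = "fixed", effort = "fixed",
            effort2 = "fixed"),
    `7` = c(intercept = "varying", reward = "varying", effort = "varying",
            effort2 = "varying"),
    `8` = c(intercept = "varying", reward = "varying", effort2 = "varying"),
    `9` = c(intercept = "varying", reward = "varying", reward2 = "varying",
            effort = "varying"),
    `10` = c(intercept = "varying", reward2 = "varying", effort = "varying"),
    `11` = c(intercept = "varying", reward = "varying", reward2 = "varying",
             effort = "varying", effort2 = "varying"),
    `12` = c(intercept = "varying", reward2 = "varying", effort2 = "varying")
  )
  lapply(seq_along(defs), function(i) {
    structure(list(id = i, terms = defs[[i]]), class = "nst_model_spec")
  })
}

#' @rdname model_catalogue
#' @export
model_spec <- function(id) {
  if (!is_count(id) || id < 1 || id > 12) {
    stop_("model id must be an integer in 1..12")
  }
  model_catalogue()[[id]]
}

#' @export
format.nst_model_spec <- function(x, ...) {
  abbr <- c(intercept = "I", reward = "R", reward2 = "R2",
            effort = "E", effort2 = "E2")
  paste0("Model ", x$id, ": ",
         paste0(ifelse(x$terms == "varying", "v", "f"),
                abbr[names(x$terms)], collapse = " + "))
}

#' @export
print.nst_model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# predictor column (in a standardised dataset) and parameter base name
term_predictor <- c(intercept = "", reward = "reward_z",
                    reward2 = "reward_z2", effort = "effort_z",
                    effort2 = "effort_z2")
term_par <- function(term) {
  ifelse(term == "intercept", "alpha", paste0("beta_", term))
}

#' Prior configuration for the model suite
#'
#' Hierarchical priors: the population mean of each varying term gets a
#' Normal prior (scale 1.5 for the intercept, 1 for slopes, on the
#' standardised log-odds scale), population SDs get Half-Normal(1), and
#' fixed terms get the same Normal priors as the corresponding means.
#' All scales are overridable; [prior_predictive_acceptance()] supports
#' the prior-predictive-check workflow used to tune them.
#'
#' @param intercept_loc,intercept_scale Normal prior on the intercept mean
#'   (and on a fixed intercept).
#' @param slope_loc,slope_scale Normal prior on slope means (and fixed
#'   slopes).
#' @param sigma_scale Half-Normal scale of the population SDs.
#' @return List of class `nst_priors`.
#' @export
nst_priors <- function(intercept_loc = 0, intercept_scale = 1.5,
                       slope_loc = 0, slope_scale = 1, sigma_scale = 1) {
  if (intercept_scale <= 0 || slope_scale <= 0 || sigma_scale <= 0) {
    stop_("prior scales must be positive")
  }
  structure(
    list(intercept_loc = intercept_loc, intercept_scale = intercept_scale,
         slope_loc = slope_loc, slope_scale = slope_scale,
         sigma_scale = sigma_scale),
    class = "nst_priors"
  )
}

prior_loc_scale <- function(term, priors) {
  if (term == "intercept") {
    c(priors$intercept_loc, priors$intercept_scale)
  } else {
    c(priors$slope_loc, priors$slope_scale)
  }
}

#' Per-trial log-likelihood of a parameter assignment
#'
#' Entry t is `y_t log p_t + (1 - y_t) log(1 - p_t)` where p_t passes the
#' model's linear predictor through the logistic.  Fixed terms use one
#' shared value; varying terms index the subject's value.
#'
#' @param params Named list: scalar `alpha`/`beta_<term>` for fixed terms,
#'   a vector over subjects for varying terms.
#' @param data Standardised choice dataset (columns `subject`, `accepted`
#'   and the predictor z columns used by the model).
#' @param spec [model_spec()] of the model.
#' @return Numeric vector, one log-likelihood per trial.
#' @export
pointwise_log_likelihood <- function(params, data, spec) {
  stopifnot(inherits(spec, "nst_model_spec"))
  subj <- subject_index(data$subject)
  S <- max(subj)
  eta <- linear_predictor(params, data, spec, subj, S)
  y <- data$accepted
  # stable Bernoulli-logit log density
  -log1p(exp(-(2 * y - 1) * eta))
}

subject_index <- function(subject) {
  as.integer(factor(subject, levels = unique(subject)))
}

linear_predictor <- function(params, data, spec, subj, S) {
  eta <- numeric(nrow(data))
  for (term in names(spec$terms)) {
    par <- term_par(term)
    v <- params[[par]]
    if (is.null(v)) stop_("missing parameter: ", par)
    kind <- spec$terms[[term]]
    if (kind == "varying" && length(v) != S) {
      stop_("parameter ", par, " must have one value per subject (", S, ")")
    }
    coef <- if (kind == "varying") v[subj] else v
    x <- if (term == "intercept") 1 else data[[term_predictor[[term]]]]
    eta <- eta + coef * x
  }
  eta
}

#' Log posterior density of a parameter assignment
#'
#' Sum of the pointwise log-likelihood and the log hierarchical prior:
#' each varying term contributes Normal(subject value | population mean,
#' population SD) per subject plus the hyperpriors on mean and SD; fixed
#' terms contribute their prior directly.  A non-positive population SD
#' yields `-Inf` (a rejected state), not an error.
#'
#' @inheritParams pointwise_log_likelihood
#' @param priors [nst_priors()] configuration.
#' @return Scalar log density (up to the normalising constant of the
#'   truncated half-normal, which is itself included analytically).
#' @export
log_posterior_density <- function(params, data, spec, priors = nst_priors()) {
  lp <- 0
  for (term in names(spec$terms)) {
    par <- term_par(term)
    v <- params[[par]]
    if (is.null(v)) stop_("missing parameter: ", par)
    ls <- prior_loc_scale(term, priors)
    if (spec$terms[[term]] == "varying") {
      mu <- params[[paste0("mu_", term)]]
      sg <- params[[paste0("sigma_", term)]]
      if (is.null(mu)) stop_("missing parameter: mu_", term)
      if (is.null(sg)) stop_("missing parameter: sigma_", term)
      if (sg <= 0) return(-Inf)
      lp <- lp + sum(stats::dnorm(v, mu, sg, log = TRUE)) +
        stats::dnorm(mu, ls[1], ls[2], log = TRUE) +
        stats::dnorm(sg, 0, priors$sigma_scale, log = TRUE) + log(2)
    } else {
      lp <- lp + stats::dnorm(v, ls[1], ls[2], log = TRUE)
    }
  }
  ll <- if (nrow(data) > 0) sum(pointwise_log_likelihood(params, data, spec))
        else 0
  lp + ll
}

#' Sampler configuration
#'
#' @param chains Number of MCMC chains.
#' @param adapt Adaptation iterations (JAGS tuning phase).
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param iter Retained iterations per chain.
#' @param thin Thinning interval.
#' @param noncentred Varying terms given the non-centred parameterisation
#'   (subject effect = mu + sigma * z, z ~ N(0,1)).  Weakly-identified
#'   population SDs -- in practice the quadratic terms -- mix far better
#'   non-centred, while strongly-identified terms mix better centred.
#' @param quiet Suppress JAGS progress output.
#' @return List of class `nst_sampler_control`.
#' @export
sampler_control <- function(chains = 4L, adapt = 500L, warmup = 500L,
                            iter = 1000L, thin = 1L,
                            noncentred = c("reward2", "effort2"),
                            quiet = TRUE) {
  stopifnot(chains >= 1, adapt >= 0, warmup >= 0, iter >= 1, thin >= 1)
  structure(
    list(chains = as.integer(chains), adapt = as.integer(adapt),
         warmup = as.integer(warmup), iter = as.integer(iter),
         thin = as.integer(thin), noncentred = noncentred, quiet = quiet),
    class = "nst_sampler_control"
  )
}

# JAGS model code for a spec.  Non-centred varying terms are inlined in the
# linear predictor and also exposed as deterministic nodes for monitoring.
jags_model_code <- function(spec, priors, noncentred = character(0)) {
  lik_terms <- character(0)
  subj_lines <- character(0)
  hyper_lines <- character(0)
  uses_subject <- FALSE
  for (term in names(spec$terms)) {
    par <- term_par(term)
    x <- if (term == "intercept") "" else sprintf(" * x_%s[t]", term)
    ls <- prior_loc_scale(term, priors)
    if (spec$terms[[term]] == "varying") {
      uses_subject <- TRUE
      if (term %in% noncentred) {
        lik_terms <- c(lik_terms, sprintf(
          "(mu_%s + sigma_%s * z_%s[subj[t]])%s", term, term, term, x))
        subj_lines <- c(subj_lines,
                        sprintf("    z_%s[s] ~ dnorm(0, 1)", term),
                        sprintf("    %s[s] <- mu_%s + sigma_%s * z_%s[s]",
                                par, term, term, term))
      } else {
        lik_terms <- c(lik_terms, sprintf("%s[subj[t]]%s", par, x))
        subj_lines <- c(subj_lines, sprintf(
          "    %s[s] ~ dnorm(mu_%s, tau_%s)", par, term, term))
        hyper_lines <- c(hyper_lines, sprintf(
          "  tau_%s <- pow(sigma_%s, -2)", term, term))
      }
      hyper_lines <- c(hyper_lines,
        sprintf("  mu_%s ~ dnorm(%g, %g)", term, ls[1], ls[2]^-2),
        sprintf("  sigma_%s ~ dnorm(0, %g) T(0,)", term,
                priors$sigma_scale^-2))
    } else {
      lik_terms <- c(lik_terms, sprintf("%s%s", par, x))
      hyper_lines <- c(hyper_lines,
        sprintf("  %s ~ dnorm(%g, %g)", par, ls[1], ls[2]^-2))
    }
  }
  subj_block <- if (uses_subject) {
    paste0("  for (s in 1:S) {\n", paste(subj_lines, collapse = "\n"),
           "\n  }\n")
  } else {
    ""
  }
  paste0(
    "model {\n",
    "  for (t in 1:N) {\n",
    "    y[t] ~ dbern(p[t])\n",
    "    logit(p[t]) <- ", paste(lik_terms, collapse = " +\n      "), "\n",
    "  }\n",
    subj_block,
    paste(hyper_lines, collapse = "\n"), "\n",
    "}\n"
  )
}

#' Draw from the posterior of a model by MCMC
#'
#' Fits the model with JAGS (glm module loaded for efficient logistic
#' block updates).  The returned object contains the retained draws as an
#' iterations x chains x parameters array; a fixed seed fully determines
#' the output.  Convergence is not asserted here -- run
#' [compute_diagnostics()] on the result and decide.
#'
#' Parameter names follow the convention `mu_<term>` / `sigma_<term>` for
#' population mean and SD of a varying term, `alpha[s]` / `beta_<term>[s]`
#' for subject values, and plain `alpha` / `beta_<term>` for fixed terms.
#'
#' @param data Standardised choice dataset (needs `subject`, `accepted`,
#'   `reward_z`, `reward_z2`, `effort_z`; `effort_z2` is derived).
#' @param spec [model_spec()] to fit.
#' @param priors [nst_priors()] configuration.
#' @param control [sampler_control()] settings.
#' @param seed Integer seed driving initial values and all chain RNGs.
#' @return Object of class `nst_draws`.
#' @export
sample_posterior <- function(data, spec, priors = nst_priors(),
                             control = sampler_control(), seed = 1L) {
  stopifnot(inherits(spec, "nst_model_spec"))
  if (is.null(data) || nrow(data) == 0L) stop_("dataset is empty")
  data <- add_effort_z2(data)
  subj <- subject_index(data$subject)
  S <- max(subj)
  jd <- list(y = as.integer(data$accepted), N = nrow(data))
  varying <- names(spec$terms)[spec$terms == "varying"]
  if (length(varying) > 0) {
    jd$subj <- subj
    jd$S <- S
  }
  for (term in setdiff(names(spec$terms), "intercept")) {
    jd[[paste0("x_", term)]] <- data[[term_predictor[[term]]]]
  }
  noncentred <- intersect(control$noncentred, varying)
  code <- jags_model_code(spec, priors, noncentred)
  monitors <- monitor_names(spec)
  inits <- lapply(seq_len(control$chains), function(ch) {
    make_inits(spec, priors, S, noncentred,
               seed = sub_seed(seed, ch, 3L),
               rng_seed = sub_seed(seed, ch, 4L))
  })
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(
    textConnection(code), data = jd, inits = inits,
    n.chains = control$chains, n.adapt = control$adapt, quiet = control$quiet
  )
  if (control$warmup > 0) {
    stats::update(jm, control$warmup, progress.bar = "none")
  }
  sm <- rjags::coda.samples(jm, variable.names = monitors,
                            n.iter = control$iter * control$thin,
                            thin = control$thin, progress.bar = "none")
  arr <- mcmc_list_to_array(sm)
  structure(
    list(draws = arr, params = dimnames(arr)[[3]], spec = spec,
         priors = priors, control = control, seed = seed,
         n_subjects = S, subjects = unique(data$subject),
         warmup = control$warmup + control$adapt),
    class = "nst_draws"
  )
}

add_effort_z2 <- function(data) {
  if (!"effort_z2" %in% names(data)) data$effort_z2 <- data$effort_z^2
  data
}

monitor_names <- function(spec) {
  out <- character(0)
  for (term in names(spec$terms)) {
    par <- term_par(term)
    if (spec$terms[[term]] == "varying") {
      out <- c(out, paste0("mu_", term), paste0("sigma_", term), par)
    } else {
      out <- c(out, par)
    }
  }
  out
}

make_inits <- function(spec, priors, S, noncentred, seed, rng_seed) {
  with_seed(seed, {
    ini <- list(".RNG.name" = "base::Mersenne-Twister",
                ".RNG.seed" = rng_seed)
    for (term in names(spec$terms)) {
      par <- term_par(term)
      if (spec$terms[[term]] == "varying") {
        mu0 <- stats::rnorm(1, 0, 0.3)
        sg0 <- stats::runif(1, 0.3, 0.8)
        ini[[paste0("mu_", term)]] <- mu0
        ini[[paste0("sigma_", term)]] <- sg0
        if (term %in% noncentred) {
          ini[[paste0("z_", term)]] <- stats::rnorm(S, 0, 0.1)
        } else {
          ini[[par]] <- stats::rnorm(S, mu0, 0.1)
        }
      } else {
        ini[[par]] <- stats::rnorm(1, 0, 0.3)
      }
    }
    ini
  })
}

mcmc_list_to_array <- function(sm) {
  pn <- colnames(sm[[1]])
  it <- nrow(sm[[1]])
  arr <- array(NA_real_, dim = c(it, length(sm), length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(sm)) arr[, ch, ] <- as.matrix(sm[[ch]])
  arr
}

#' @export
print.nst_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("%s\n%d chains x %d retained iterations, %d parameters\n",
              format(x$spec), d[2], d[1], d[3]))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param x An `nst_draws` object.
#' @param ... Unused.
#' @return Matrix with one column per parameter, chains stacked.
#' @export
as.matrix.nst_draws <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(x$draws, nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- x$params
  out
}

#' Extract subject-level posterior means of a term
#'
#' @param fit An `nst_draws` object.
#' @param term One of `"intercept"`, `"reward"`, `"reward2"`, `"effort"`,
#'   `"effort2"` (must be varying in the fitted model).
#' @return Named numeric vector (one posterior mean per subject, names are
#'   the dataset's subject ids).
#' @export
subject_posterior_means <- function(fit, term = "effort") {
  stopifnot(inherits(fit, "nst_draws"))
  if (!identical(fit$spec$terms[[term]], "varying")) {
    stop_("term '", term, "' is not a varying effect of ", format(fit$spec))
  }
  m <- as.matrix(fit)
  cols <- paste0(term_par(term), "[", seq_len(fit$n_subjects), "]")
  est <- colMeans(m[, cols, drop = FALSE])
  names(est) <- fit$subjects
  est
}

#' Matrix of pointwise log-likelihood draws
#'
#' Evaluates the model's per-trial Bernoulli log-likelihood at every
#' retained posterior draw (optionally thinned deterministically to at
#' most `max_draws` evenly-spaced draws), producing the draws x trials
#' matrix consumed by [waic()].
#'
#' @param fit An `nst_draws` object.
#' @param data The dataset the model was fitted to.
#' @param max_draws Cap on the number of draws used.
#' @param chunk Trials per block (memory control).
#' @return Matrix, draws in rows and trials in columns.
#' @export
loglik_matrix <- function(fit, data, max_draws = 2000L, chunk = 2000L) {
  stopifnot(inherits(fit, "nst_draws"))
  data <- add_effort_z2(data)
  m <- as.matrix(fit)
  if (nrow(m) > max_draws) {
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]
  }
  subj <- subject_index(data$subject)
  S <- fit$n_subjects
  spec <- fit$spec
  D <- nrow(m)
  N <- nrow(data)
  y <- data$accepted
  out <- matrix(NA_real_, D, N)
  coefs <- lapply(names(spec$terms), function(term) {
    par <- term_par(term)
    if (spec$terms[[term]] == "varying") {
      m[, paste0(par, "[", seq_len(S), "]"), drop = FALSE]
    } else {
      m[, par, drop = FALSE]
    }
  })
  names(coefs) <- names(spec$terms)
  for (lo in seq(1, N, by = chunk)) {
    hi <- min(lo + chunk - 1L, N)
    idx <- lo:hi
    eta <- matrix(0, D, length(idx))
    for (term in names(spec$terms)) {
      cf <- coefs[[term]]
      cf <- if (ncol(cf) > 1L) cf[, subj[idx], drop = FALSE]
            else cf[, rep(1L, length(idx)), drop = FALSE]
      if (term == "intercept") {
        eta <- eta + cf
      } else {
        eta <- eta + cf * rep(data[[term_predictor[[term]]]][idx],
                              each = D)
      }
    }
    sgn <- rep(2 * y[idx] - 1, each = D)
    out[, idx] <- -log1p(exp(-sgn * eta))
  }
  out
}

#' Draw parameters from the prior
#'
#' Samples population-level (and, optionally, new-subject) parameters from
#' the prior alone -- the ingredient of a prior predictive check.
#'
#' @param spec [model_spec()].
#' @param priors [nst_priors()].
#' @param n_draws Number of prior draws.
#' @param seed Optional seed.
#' @return Data frame of prior draws, one column per population parameter.
#' @export
sample_prior <- function(spec, priors = nst_priors(), n_draws = 1000L,
                         seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (term in names(spec$terms)) {
      ls <- prior_loc_scale(term, priors)
      if (spec$terms[[term]] == "varying") {
        out[[paste0("mu_", term)]] <- stats::rnorm(n_draws, ls[1], ls[2])
        out[[paste0("sigma_", term)]] <-
          abs(stats::rnorm(n_draws, 0, priors$sigma_scale))
      } else {
        out[[term_par(term)]] <- stats::rnorm(n_draws, ls[1], ls[2])
      }
    }
    as.data.frame(out)
  })
}

#' Serialise posterior draws to CSV
#'
#' Long format with header `chain,iteration,parameter,value`.
#'
#' @param fit An `nst_draws` object (for reading, any such file).
#' @param file Path.
#' @return `read_draws()` returns a long data frame.
#' @export
write_draws <- function(fit, file) {
  stopifnot(inherits(fit, "nst_draws"))
  d <- dim(fit$draws)
  long <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1], times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(fit$params, each = d[1] * d[2]),
    value = as.vector(fit$draws)
  )
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(fit)
}

#' @rdname write_draws
#' @export
read_draws <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!identical(names(x), c("chain", "iteration", "parameter", "value"))) {
    stop_("malformed draws header; expected chain,iteration,parameter,value")
  }
  x
}
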