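# End-to-end orchestration: simulate -> fit -> compare -> recover ->
# report, with configuration and file output.

#' Configuration of a recovery run
#'
#' @param seed Master seed (mandatory); every source of randomness in the
#'   run derives from it.
#' @param n_subjects Cohort size.
#' @param hyper Generating [nst_hyperparameters()].
#' @param models Integer vector of model ids to fit (subset of 1..12).
#' @param priors [nst_priors()] used for fitting.
#' @param control [sampler_control()] used for fitting.
#' @param out_dir Optional output directory; when given, all artifacts
#'   (dataset, ground truth, comparison table, posterior predictive cells,
#'   report JSON, plain-text summary, log) are written there.
#' @param save_draws Also write each model's draws CSV (large)?
#' @param max_loglik_draws Draws used for WAIC log-likelihood matrices.
#' @param ppc Compute posterior predictive cells for the best model?
#' @param verbose Log progress with `message()`?
#' @return List of class `nst_config`.
#' @export
nst_config <- function(seed, n_subjects = 100L,
                       hyper = nst_hyperparameters(),
                       models = c(1L, 4L, 9L),
                       priors = nst_priors(),
                       control = sampler_control(),
                       out_dir = NULL, save_draws = FALSE,
                       max_loglik_draws = 2000L, ppc = TRUE,
                       verbose = TRUE) {
  if (missing(seed) || !is_count(seed)) stop_("an integer seed is mandatory")
  if (!all(models %in% 1:12)) stop_("model ids must lie in 1..12")
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         hyper = hyper, models = as.integer(models), priors = priors,
         control = control, out_dir = out_dir, save_draws = save_draws,
         max_loglik_draws = as.integer(max_loglik_draws), ppc = ppc,
         verbose = verbose),
    class = "nst_config"
  )
}

#' Read a recovery-run configuration from YAML
#'
#' Recognised keys: `seed`, `n_subjects`, `models`, `out_dir`,
#' `save_draws`, `ppc`, plus nested blocks `hyper` (arguments of
#' [nst_hyperparameters()]), `priors` ([nst_priors()]) and `sampler`
#' ([sampler_control()]).
#'
#' @param file YAML file path.
#' @return [nst_config()] object.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$seed)) stop_("config must set a seed")
  args <- list(
    seed = y$seed,
    n_subjects = y$n_subjects %||% 100L,
    hyper = do.call(nst_hyperparameters, y$hyper %||% list()),
    models = unlist(y$models %||% c(1L, 4L, 9L)),
    priors = do.call(nst_priors, y$priors %||% list()),
    control = do.call(sampler_control, y$sampler %||% list()),
    out_dir = y$out_dir,
    save_draws = isTRUE(y$save_draws),
    ppc = !isFALSE(y$ppc)
  )
  do.call(nst_config, args)
}

#' Run a full parameter-recovery study
#'
#' Simulates a cohort from the generating hyperparameters, fits the
#' requested models, ranks them by WAIC, extracts subject-level estimates
#' from the best model, measures recovery of the population means and of
#' the subject-level effects, and computes the confound-check
#' correlations (effort sensitivity vs success rate; acceptance
#' probability vs mean completion time per effort level; overall tendency
#' to accept vs allowed time).
#'
#' @param config [nst_config()] object.
#' @return List of class `nst_recovery`; see the report fields
#'   (`comparison`, `population`, `subject_cor`, `confounds`,
#'   `diagnostics`, `best_model_id`, `study_summary`).
#' @export
run_recovery <- function(config) {
  stopifnot(inherits(config, "nst_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (config$verbose) message(msg)
  }
  say("recovery run: seed %d, %d subjects, models %s",
      config$seed, config$n_subjects,
      paste(config$models, collapse = ","))

  stage <- "simulate"
  report <- tryCatch({
    study <- simulate_study(config$hyper, config$n_subjects,
                            seed = config$seed)
    data <- study$choices
    say("simulated %d trials; mean acceptance %.3f, mean success %.3f",
        nrow(data), mean(data$accepted),
        mean(data$success, na.rm = TRUE))

    fits <- list()
    diags <- list()
    lls <- list()
    for (id in config$models) {
      stage <- paste0("fit model ", id)
      spec <- model_spec(id)
      t0 <- Sys.time()
      fit <- sample_posterior(data, spec, config$priors, config$control,
                              seed = sub_seed(config$seed, id, 10L))
      fits[[as.character(id)]] <- fit
      diags[[as.character(id)]] <- compute_diagnostics(fit)
      lls[[as.character(id)]] <- loglik_matrix(
        fit, data, max_draws = config$max_loglik_draws
      )
      say("fitted model %d in %.1f s; diagnostics %s", id,
          as.numeric(Sys.time() - t0, units = "secs"),
          if (diags[[as.character(id)]]$pass) "pass" else "NOT passed")
    }

    stage <- "compare"
    comparison <- compare_models(lls)
    best_id <- comparison$model_id[1]
    best <- fits[[as.character(best_id)]]
    say("best model by WAIC: %d", best_id)

    stage <- "recover"
    truth_map <- c(intercept = "alpha_mean", reward = "reward_mean",
                   reward2 = "reward2_mean", effort = "effort_mean")
    pop <- population_recovery(best, config$hyper, truth_map)
    subj_cor <- subject_recovery(best, study$agents)

    stage <- "confound checks"
    confounds <- confound_checks(best, data, study$agents)

    ppc_cells <- if (config$ppc) {
      posterior_predictive_acceptance(
        best, seed = sub_seed(config$seed, 1L, 11L)
      )
    } else {
      NULL
    }

    structure(
      list(
        config = config,
        study_summary = summarize_study(study),
        comparison = comparison,
        diagnostics = diags,
        best_model_id = best_id,
        population = pop,
        subject_cor = subj_cor,
        confounds = confounds,
        ppc = ppc_cells,
        study = study,
        fits = fits,
        log = log
      ),
      class = "nst_recovery"
    )
  }, error = function(e) {
    stop_("recovery aborted at stage '", stage, "' (seed ", config$seed,
          "): ", conditionMessage(e))
  })

  if (!is.null(config$out_dir)) write_recovery(report, config$out_dir)
  report
}

summarize_study <- function(study) {
  data <- study$choices
  subj_success <- tapply(data$success, data$subject,
                         function(x) mean(x, na.rm = TRUE))
  list(
    n_subjects = nrow(study$agents),
    n_trials = nrow(data),
    n_excluded = length(study$excluded),
    mean_acceptance = mean(data$accepted),
    mean_success_rate = mean(subj_success, na.rm = TRUE),
    sd_success_rate = stats::sd(subj_success[is.finite(subj_success)]),
    mean_allowed_time_ms = mean(study$agents$allowed_time_ms),
    sd_allowed_time_ms = stats::sd(study$agents$allowed_time_ms),
    mean_prop_completion_time =
      mean(data$elapsed_ms / data$allowed_time_ms, na.rm = TRUE)
  )
}

population_recovery <- function(fit, hyper, truth_map) {
  m <- as.matrix(fit)
  rows <- lapply(names(fit$spec$terms), function(term) {
    if (fit$spec$terms[[term]] != "varying" || !term %in% names(truth_map)) {
      return(NULL)
    }
    draws <- m[, paste0("mu_", term)]
    truth <- hyper[[truth_map[[term]]]]
    data.frame(
      term = term, truth = truth,
      posterior_mean = mean(draws), posterior_sd = stats::sd(draws),
      lower89 = unname(stats::quantile(draws, 0.055)),
      upper89 = unname(stats::quantile(draws, 0.945)),
      abs_bias = abs(mean(draws) - truth),
      z = (mean(draws) - truth) / stats::sd(draws)
    )
  })
  do.call(rbind, rows)
}

subject_recovery <- function(fit, agents) {
  rows <- lapply(names(fit$spec$terms), function(term) {
    if (fit$spec$terms[[term]] != "varying") return(NULL)
    truth_col <- term_par(term)
    if (!truth_col %in% names(agents)) return(NULL)
    est <- subject_posterior_means(fit, term)
    truth <- agents[[truth_col]][match(names(est), agents$subject)]
    data.frame(term = term,
               correlation = stats::cor(truth, est),
               n = length(est))
  })
  do.call(rbind, rows)
}

confound_checks <- function(fit, data, agents,
                            successful_only_times = FALSE) {
  out <- list()
  # effort sensitivity vs probability of success
  if (identical(fit$spec$terms[["effort"]], "varying")) {
    be <- subject_posterior_means(fit, "effort")
    succ <- tapply(data$success, data$subject,
                   function(x) mean(x, na.rm = TRUE))
    succ <- succ[match(names(be), names(succ))]
    keep <- is.finite(succ)
    out$effort_vs_success <- correlation_test(be[keep], succ[keep])
  }
  # acceptance vs mean completion time, per subject x effort level
  tdat <- data
  if (successful_only_times) {
    tdat$elapsed_ms[which(tdat$success == 0L)] <- NA
  }
  key <- interaction(tdat$subject, tdat$effort_label, drop = TRUE)
  acc <- tapply(tdat$accepted, key, mean)
  mt <- tapply(tdat$elapsed_ms, key, function(x) mean(x, na.rm = TRUE))
  keep <- is.finite(acc) & is.finite(mt)
  out$acceptance_vs_time <- correlation_test(acc[keep], mt[keep])
  # overall tendency to accept vs allowed time
  if (identical(fit$spec$terms[["intercept"]], "varying")) {
    ai <- subject_posterior_means(fit, "intercept")
    at <- agents$allowed_time_ms[match(names(ai), agents$subject)]
    out$intercept_vs_allowed_time <- correlation_test(ai, at)
  }
  out
}

write_recovery <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_dataset(report$study$choices, p("dataset.csv"))
  write_ground_truth(report$study$agents, p("ground_truth.csv"))
  write_comparison(report$comparison, p("comparison.csv"))
  if (!is.null(report$ppc)) write_ppc(report$ppc, p("ppc_cells.csv"))
  if (report$config$save_draws) {
    for (id in names(report$fits)) {
      write_draws(report$fits[[id]], p(paste0("draws_model", id, ".csv")))
    }
  }
  jsonlite::write_json(recovery_json(report), p("recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(utils::capture.output(print(report)), "", report$log),
             p("summary.txt"))
  invisible(report)
}

recovery_json <- function(report) {
  diag_tab <- lapply(report$diagnostics, function(d) {
    list(pass = d$pass, max_rhat = d$max_rhat, min_ess = d$min_ess)
  })
  list(
    seed = report$config$seed,
    study = report$study_summary,
    best_model_id = report$best_model_id,
    comparison = report$comparison[, c("model_id", "waic", "se_waic",
                                       "delta_waic", "se_delta", "rank")],
    population = report$population,
    subject_cor = report$subject_cor,
    confounds = lapply(report$confounds, function(ct) {
      list(r = ct$r, df = ct$df, t = ct$t, p = ct$p)
    }),
    diagnostics = diag_tab
  )
}

#' @export
print.nst_recovery <- function(x, ...) {
  cat("NST parameter-recovery report\n")
  cat(sprintf("  seed %d, %d subjects, %d trials\n",
              x$config$seed, x$study_summary$n_subjects,
              x$study_summary$n_trials))
  cat(sprintf("  mean acceptance %.3f, mean success rate %.3f (SD %.3f)\n",
              x$study_summary$mean_acceptance,
              x$study_summary$mean_success_rate,
              x$study_summary$sd_success_rate))
  cat(sprintf("  best model by WAIC: %d\n", x$best_model_id))
  cat("  model comparison:\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  cat("  population-mean recovery (best model):\n")
  print(x$population, row.names = FALSE)
  if (!is.null(x$subject_cor)) {
    cat("  subject-level truth-estimate correlations:\n")
    print(x$subject_cor, row.names = FALSE)
  }
  for (nm in names(x$confounds)) {
    ct <- x$confounds[[nm]]
    cat(sprintf("  %s: r(%d) = %.3f, p = %.3g\n", nm, ct$df, ct$r, ct$p))
  }
  invisible(x)
}
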