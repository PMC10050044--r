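# WAIC, model ranking, posterior predictive curves and correlation tests.

test_that("waic matches an independent direct implementation", {
  set.seed(51)
  for (rep in 1:5) {
    ll <- matrix(rnorm(50 * 30, mean = -0.7, sd = 0.4), 50, 30)
    w <- waic(ll)
    o <- oracle_waic(ll)
    expect_equal(w$lppd, o$lppd, tolerance = 1e-10)
    expect_equal(w$p_waic, o$p_waic, tolerance = 1e-10)
    expect_equal(w$waic, o$waic, tolerance = 1e-10)
    expect_equal(w$se_waic, o$se_waic, tolerance = 1e-10)
    # internal identities
    expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-10)
    expect_equal(w$elpd, w$lppd - w$p_waic, tolerance = 1e-10)
  }
})

test_that("waic handles degenerate and structured inputs exactly", {
  ll <- matrix(rep(c(-0.2, -1.1, -0.6), each = 10), 10, 3)
  w <- waic(ll) # zero variance across draws
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))
  # duplicating every trial column doubles all totals
  set.seed(52)
  ll <- matrix(rnorm(40 * 8), 40, 8)
  w1 <- waic(ll)
  w2 <- waic(cbind(ll, ll))
  expect_equal(w2$lppd, 2 * w1$lppd, tolerance = 1e-10)
  expect_equal(w2$p_waic, 2 * w1$p_waic, tolerance = 1e-10)
  expect_equal(w2$waic, 2 * w1$waic, tolerance = 1e-10)
  # invariant to trial reordering
  perm <- sample(8)
  expect_equal(waic(ll[, perm])$waic, w1$waic, tolerance = 1e-10)
  expect_equal(waic(ll[, perm])$se_waic, w1$se_waic, tolerance = 1e-10)
  # overflow safety
  big <- matrix(c(700, 710, 705, 702), 2, 2)
  expect_true(is.finite(waic(big)$lppd))
  expect_error(waic(matrix(-1, 1, 4)), "single draw")
})

test_that("model comparison deltas and their SEs follow the paired definitions", {
  set.seed(53)
  ll <- matrix(rnorm(30 * 20), 30, 20)
  # a model against itself
  cmp <- compare_models(list(`3` = ll, `7` = ll))
  expect_equal(cmp$delta_waic, c(0, 0))
  expect_equal(cmp$se_delta, c(0, 0))
  expect_identical(cmp$model_id[1], 3L) # tie broken by lower id
  # constant per-trial shift: delta exact, se_delta 0
  shift <- 0.05
  cmp2 <- compare_models(list(`1` = ll, `2` = ll + shift))
  expect_identical(cmp2$model_id[1], 2L) # higher loglik wins
  d21 <- cmp2$delta_waic[cmp2$model_id == 1]
  expect_equal(d21, 2 * 20 * shift, tolerance = 1e-8)
  expect_equal(cmp2$se_delta[cmp2$model_id == 1], 0, tolerance = 1e-8)
  # symmetry of the paired SE
  llb <- matrix(rnorm(30 * 20), 30, 20)
  se_ab <- compare_models(list(`4` = ll, `5` = llb))
  se_ba <- compare_models(list(`5` = llb, `4` = ll))
  expect_equal(sort(se_ab$se_delta), sort(se_ba$se_delta), tolerance = 1e-10)
  expect_error(compare_models(list(`4` = ll, `5` = llb[, 1:5])),
               "mismatched trial counts")
})

test_that("comparison accepts precomputed waic objects and writes its CSV", {
  set.seed(54)
  lls <- list(`2` = matrix(rnorm(20 * 10), 20, 10),
              `9` = matrix(rnorm(20 * 10, 0.2), 20, 10))
  cmp <- compare_models(lapply(lls, waic))
  expect_identical(cmp, compare_models(lls))
  f <- withr::local_tempfile(fileext = ".csv")
  write_comparison(cmp, f)
  expect_identical(readLines(f, n = 1),
                   "model_id,waic,se_waic,delta_waic,se_delta,rank")
})

test_that("posterior predictive curves collapse correctly in edge cases", {
  # constructed draws object: all slopes zero -> flat curves at logistic(a)
  params <- c("mu_intercept", "sigma_intercept", "mu_reward", "sigma_reward",
              "mu_reward2", "sigma_reward2", "mu_effort", "sigma_effort",
              paste0("alpha[", 1:2, "]"), paste0("beta_reward[", 1:2, "]"),
              paste0("beta_reward2[", 1:2, "]"), paste0("beta_effort[", 1:2, "]"))
  arr <- array(0, dim = c(50, 2, length(params)),
               dimnames = list(NULL, NULL, params))
  arr[, , "mu_intercept"] <- 1.2
  fit <- structure(
    list(draws = arr, params = params, spec = model_spec(9),
         n_subjects = 2L, subjects = 1:2),
    class = "nst_draws"
  )
  ppc <- posterior_predictive_acceptance(fit, seed = 1)
  pop <- ppc[ppc$kind == "population", ]
  expect_equal(pop$mean, rep(plogis(1.2), 16), tolerance = 1e-12)
  expect_equal(pop$lower, pop$upper, tolerance = 1e-12)
  # negative effort slope with zero SDs -> strictly decreasing in effort
  arr[, , "mu_effort"] <- -0.8
  fit$draws <- arr
  ppc2 <- posterior_predictive_acceptance(fit, seed = 1)
  for (kind in c("population", "new_subject")) {
    for (r in reward_levels()) {
      rows <- ppc2[ppc2$kind == kind & ppc2$reward_points == r, ]
      rows <- rows[order(nstask:::normalize_effort(rows$effort_label)), ]
      expect_true(all(diff(rows$mean) < 0), label = paste(kind, r))
    }
  }
})

test_that("predictive bands widen when population SDs are inflated", {
  params <- c("mu_intercept", "sigma_intercept", "alpha[1]",
              "beta_reward", "beta_effort") # model 3: fixed slopes at 0
  make_fit <- function(sd_val) {
    arr <- array(0, dim = c(100, 2, length(params)),
                 dimnames = list(NULL, NULL, params))
    arr[, , "mu_intercept"] <- 0.5
    arr[, , "sigma_intercept"] <- sd_val
    structure(list(draws = arr, params = params, spec = model_spec(3),
                   n_subjects = 1L, subjects = 1L),
              class = "nst_draws")
  }
  narrow <- posterior_predictive_acceptance(make_fit(0.2), seed = 2)
  wide <- posterior_predictive_acceptance(make_fit(1.5), seed = 2)
  nw <- narrow[narrow$kind == "new_subject", ]
  ww <- wide[wide$kind == "new_subject", ]
  expect_true(all(ww$upper - ww$lower > nw$upper - nw$lower))
})

test_that("observed cell frequencies are covered by the predictive bands", {
  st <- simulate_study(nst_hyperparameters(), 60, seed = 61)
  d <- st$choices
  fit <- sample_posterior(d, model_spec(9), control = tiny_control(),
                          seed = 62)
  ppc <- posterior_predictive_acceptance(fit, prob = 0.95, seed = 63)
  obs <- cell_acceptance(d)
  new <- ppc[ppc$kind == "new_subject", ]
  key <- paste(new$reward_points, new$effort_label)
  obs_acc <- obs$acceptance[match(key, paste(obs$reward_points, obs$effort_label))]
  inside <- obs_acc >= new$lower & obs_acc <= new$upper
  expect_gte(sum(inside), 14)
})

test_that("correlation test agrees with the closed form and with cor.test", {
  expect_equal(correlation_test(1:10, (1:10) * 2 + 3)$r, 1)
  expect_equal(correlation_test(1:10, -(1:10))$r, -1)
  ct <- correlation_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  # independent direct Pearson computation
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_direct, tolerance = 1e-12)
  expect_identical(ct$df, 2L)
  set.seed(55)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  ct <- correlation_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-10)
  expect_error(correlation_test(rep(1, 5), rnorm(5)), "degenerate input")
  expect_error(correlation_test(1:2, 1:2), "at least 3")
})
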