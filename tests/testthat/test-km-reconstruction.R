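test_that("a flat curve reconstructs to zero events, all censored at the end", {
  curve <- digitized_curve(time = c(0, 6, 12), surv = c(1, 1, 1),
                           risk_time = c(0, 12), n_risk = c(10, 10))
  ipd <- reconstruct_ipd(curve)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$status), 0)
  expect_true(all(ipd$time == 12))
})

test_that("a single vertical drop with full risk information inverts exactly", {
  # both corners of the step recorded, as a digitizer would click them
  curve <- digitized_curve(time = c(0, 5, 5), surv = c(1, 1, 0.5),
                           risk_time = c(0, 5), n_risk = c(10, 10), n_total = 10)
  ipd <- reconstruct_ipd(curve)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$status), 5)
  expect_true(all(ipd$time[ipd$status == 1] == 5))
})

test_that("synthetic KM curves round-trip through reconstruction within 0.02", {
  for (seed in c(21, 22, 23)) {
    recipe <- simulation_recipe(loglogistic_pfs(), n_subjects = 200,
                                accrual_months = 12, cutoff_months = 30,
                                seed = seed)
    ipd <- simulate_ipd(recipe)
    dig <- digitize_curve(km_estimate(ipd), n_points = 40)
    rec <- reconstruct_ipd(dig)
    expect_equal(nrow(rec), dig$n_total)
    km2 <- km_textbook(rec$time, rec$status)
    dev <- km_step_at(km2$time, km2$surv, dig$time) - dig$surv
    expect_lte(max(abs(dev)), 0.02)
  }
})

test_that("an inconsistent risk table is rejected", {
  expect_error(digitized_curve(time = c(0, 5), surv = c(1, 0.6),
                               risk_time = c(0, 5), n_risk = c(10, 12)),
               "non-increasing")
  curve <- digitized_curve(time = c(0, 5), surv = c(1, 0.5),
                           risk_time = c(0, 5), n_risk = c(10, 5), n_total = 10)
  expect_error(reconstruct_ipd(digitized_curve(c(0, 5), c(1, 0.5),
                                               risk_time = 0, n_risk = 10)),
               "at least 2")
})

test_that("exponential maximum likelihood matches the closed-form estimator", {
  recipe <- simulation_recipe(surv_spec("exponential", c(rate = 0.1)),
                              n_subjects = 200, accrual_months = 6,
                              cutoff_months = 24, seed = 11)
  ipd <- simulate_ipd(recipe)
  fit <- fit_parametric(ipd, "exponential")
  closed_form <- sum(ipd$status) / sum(ipd$time)
  expect_equal(unname(fit$spec$params["rate"]), closed_form, tolerance = 1e-8)
  # the reported loglik is the censored log-likelihood at the optimum
  rate <- closed_form
  ll <- sum(ipd$status * log(rate)) - rate * sum(ipd$time)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("log-logistic parameters are recovered from large simulated samples", {
  recipe <- simulation_recipe(surv_spec("loglogistic", c(theta = 0.0392, kappa = 1.525)),
                              n_subjects = 1000, seed = 9)
  fit <- fit_parametric(simulate_ipd(recipe), "loglogistic")
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$spec$params["theta"] / 0.0392 - 1), 0.15)
  expect_lt(abs(fit$spec$params["kappa"] / 1.525 - 1), 0.15)
})

test_that("nesting: a Weibull fit to exponential data has shape near 1", {
  recipe <- simulation_recipe(surv_spec("exponential", c(rate = 0.1)),
                              n_subjects = 1000, seed = 5)
  fit <- fit_parametric(simulate_ipd(recipe), "weibull")
  expect_lt(abs(fit$spec$params["shape"] - 1), 0.1)
})

test_that("degenerate fitting inputs raise errors", {
  expect_error(fit_parametric(pseudo_ipd(1:5, rep(1, 5)), "weibull"),
               "at least 10")
  expect_error(fit_parametric(pseudo_ipd(1:20, rep(0, 20)), "exponential"),
               "no events")
})

test_that("select_best picks minimal AIC with deterministic tie-breaking", {
  fake <- function(family, aic, k) {
    structure(list(family = family, spec = NULL, loglik = (2 * k - aic) / 2,
                   aic = aic, n_params = k, status = "ok"),
              class = "parametric_fit")
  }
  fits <- list(fake("weibull", 100.0, 2), fake("lognormal", 98.5, 2),
               fake("generalized_gamma", 101.2, 3))
  expect_equal(select_best(fits)$family, "lognormal")
  expect_equal(select_best(fits[1])$family, "weibull")
  # tie on AIC: fewer parameters wins; then family order
  ties <- list(fake("generalized_gamma", 90, 3), fake("weibull", 90, 2),
               fake("exponential", 90, 1))
  expect_equal(select_best(ties)$family, "exponential")
  ties2 <- list(fake("lognormal", 90, 2), fake("weibull", 90, 2))
  expect_equal(select_best(ties2)$family, "weibull")
  expect_error(select_best(list()), "empty")
})

test_that("AIC selection on exponential data lands on or near the truth", {
  recipe <- simulation_recipe(surv_spec("exponential", c(rate = 0.09)),
                              n_subjects = 2000, seed = 17)
  ipd <- simulate_ipd(recipe)
  fits <- lapply(c("exponential", "weibull", "lognormal", "loglogistic"),
                 function(f) fit_parametric(ipd, f))
  best <- select_best(fits)
  aic_exp <- fits[[1]]$aic
  expect_lte(best$aic, aic_exp)
  expect_lte(aic_exp - best$aic, 2)
})

test_that("AIC ordering is invariant to likelihood-scale constants", {
  recipe <- simulation_recipe(surv_spec("loglogistic", c(theta = 0.1, kappa = 1.8)),
                              n_subjects = 300, seed = 31)
  ipd <- simulate_ipd(recipe)
  fits <- lapply(surv_families()[1:4], function(f) fit_parametric(ipd, f))
  shift <- lapply(fits, function(f) {
    f$loglik <- f$loglik + 7
    f$aic <- f$aic - 14
    f
  })
  expect_equal(select_best(shift)$family, select_best(fits)$family)
})
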