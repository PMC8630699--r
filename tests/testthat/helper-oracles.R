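# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and survival::survfit) so that agreement is a
# genuine cross-check.

# textbook product-limit estimator: S(t) = prod over event times <= t of
# (1 - d_i / n_i)
km_textbook <- function(time, status) {
  ord <- order(time)
  time <- time[ord]
  status <- status[ord]
  ev_times <- sort(unique(time[status == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    ti <- ev_times[i]
    n_i <- sum(time >= ti)
    d_i <- sum(time == ti & status == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ev_times, surv = surv)
}

# evaluate a step function (right-continuous) at arbitrary times
km_step_at <- function(time, surv, at) {
  stats::approx(c(0, time), c(1, surv), xout = at, method = "constant",
                f = 0, rule = 2)$y
}

# trapezoid integral of f over [0, upper]
trapz_integral <- function(f, upper, n = 20000) {
  x <- seq(0, upper, length.out = n + 1)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2) * (upper / n)
}

# base-case printed results used as reference values in the acceptance tests
table2 <- list(
  ly_ipi = 1.31, ly_combo = 3.80, qaly_ipi = 0.79, qaly_combo = 2.17,
  cost_ipi = 142083, cost_combo = 243480,
  d_ly = 2.48, d_qaly = 1.39,
  icer_qaly = 73163, icer_ly = 40820)

loglogistic_os <- function() surv_spec("loglogistic", c(theta = 0.03916796, kappa = 1.52458))
loglogistic_pfs <- function() surv_spec("loglogistic", c(theta = 0.1380415, kappa = 1.922389))

# one representative, well-behaved spec per family
family_specs <- function() {
  list(
    exponential = surv_spec("exponential", c(rate = 0.08)),
    weibull = surv_spec("weibull", c(shape = 1.3, scale = 12)),
    lognormal = surv_spec("lognormal", c(meanlog = 2, sdlog = 0.8)),
    loglogistic = loglogistic_os(),
    gompertz = surv_spec("gompertz", c(shape = 0.05, rate = 0.05)),
    generalized_gamma = surv_spec("generalized_gamma", c(mu = 2, sigma = 0.7, Q = 0.5)))
}
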