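#' Parametric survival specification
#'
#' A `surv_spec` bundles a parametric survival family with its parameters and
#' time unit. Six candidate families are supported: exponential, Weibull,
#' lognormal, log-logistic, Gompertz and generalized gamma. Times are in
#' months throughout the package.
#'
#' Parameterizations:
#' \describe{
#'   \item{exponential}{`rate` (> 0): \eqn{S(t) = e^{-\lambda t}}.}
#'   \item{weibull}{`shape`, `scale` (> 0), as in [stats::pweibull()].}
#'   \item{lognormal}{`meanlog`, `sdlog` (> 0), as in [stats::plnorm()].}
#'   \item{loglogistic}{`theta`, `kappa` (> 0):
#'     \eqn{S(t) = 1 / (1 + \theta t^{\kappa})}. This is the parameterization
#'     in which the bundled overall-survival and progression-free-survival
#'     curves of the ipilimumab arm are expressed
#'     (\eqn{\theta} = `scale^(-shape)`, \eqn{\kappa} = `shape` of
#'     [flexsurv::pllogis()]).}
#'   \item{gompertz}{`shape` (real), `rate` (> 0), as in
#'     [flexsurv::pgompertz()]. Negative shape gives an improper survival
#'     function (a cured fraction); allowed but flagged by [surv_median()].}
#'   \item{generalized_gamma}{`mu`, `sigma` (> 0), `Q`, the log-time
#'     parameterization of [flexsurv::pgengamma()]; `Q = 0` reduces to the
#'     lognormal and `Q = 1` to the Weibull.}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"generalized_gamma"`.
#' @param params Named numeric vector of family parameters (names above).
#' @param time_unit Unit of `t`; only `"months"` is supported.
#' @return An object of class `surv_spec`.
#' @examples
#' os <- surv_spec("loglogistic", c(theta = 0.03916796, kappa = 1.52458))
#' surv_prob(os, c(0, 6, 12))
#' surv_median(os)
#' @export
surv_spec <- function(family = c("exponential", "weibull", "lognormal",
                                 "loglogistic", "gompertz", "generalized_gamma"),
                      params, time_unit = "months") {
  family <- match.arg(family)
  time_unit <- match.arg(time_unit, "months")
  params <- unlist(params)
  need <- surv_family_params(family)
  if (!all(need %in% names(params)))
    stop("family '", family, "' needs parameters: ", paste(need, collapse = ", "))
  params <- params[need]
  if (anyNA(params) || any(!is.finite(params)))
    stop("non-finite survival parameters")
  pos <- switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    lognormal = "sdlog",
    loglogistic = c("theta", "kappa"),
    gompertz = "rate",
    generalized_gamma = "sigma")
  if (any(params[pos] <= 0))
    stop("parameters ", paste(pos, collapse = ", "), " must be positive for '", family, "'")
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "surv_spec")
}

surv_family_params <- function(family) {
  switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    loglogistic = c("theta", "kappa"),
    gompertz = c("shape", "rate"),
    generalized_gamma = c("mu", "sigma", "Q"))
}

#' Ordered list of supported survival families
#'
#' Order is used for deterministic tie-breaking in [select_best()].
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz",
    "generalized_gamma")
}

#' @export
print.surv_spec <- function(x, ...) {
  cat("<surv_spec>", x$family, "(",
      paste(names(x$params), signif(x$params, 6), sep = "=", collapse = ", "),
      "), time in", x$time_unit, "\n")
  invisible(x)
}

#' Survival probability S(t)
#'
#' @param spec A [surv_spec()].
#' @param t Time(s) in months, `>= 0`.
#' @return Survival probabilities in `[0, 1]`, with `S(0) = 1`.
#' @export
surv_prob <- function(spec, t) {
  stopifnot(inherits(spec, "surv_spec"))
  if (any(t < 0)) stop("t must be non-negative")
  p <- spec$params
  s <- switch(spec$family,
    exponential = exp(-p["rate"] * t),
    weibull = stats::pweibull(t, p["shape"], p["scale"], lower.tail = FALSE),
    lognormal = stats::plnorm(t, p["meanlog"], p["sdlog"], lower.tail = FALSE),
    loglogistic = 1 / (1 + p["theta"] * t^p["kappa"]),
    gompertz = flexsurv::pgompertz(t, p["shape"], p["rate"], lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, p["mu"], p["sigma"], p["Q"],
                                            lower.tail = FALSE))
  unname(s)
}

#' Hazard function h(t)
#'
#' Instantaneous event rate per month. Requires `t > 0` because several
#' families (e.g. Weibull with shape < 1, log-logistic) have a singular or
#' undefined hazard at the origin.
#'
#' @inheritParams surv_prob
#' @param t Time(s) in months, strictly positive.
#' @return Non-negative hazard rates (per month).
#' @export
surv_hazard <- function(spec, t) {
  stopifnot(inherits(spec, "surv_spec"))
  if (any(t <= 0)) stop("t must be strictly positive for the hazard")
  p <- spec$params
  h <- switch(spec$family,
    exponential = rep_len(p["rate"], length(t)),
    weibull = (p["shape"] / p["scale"]) * (t / p["scale"])^(p["shape"] - 1),
    lognormal = stats::dlnorm(t, p["meanlog"], p["sdlog"]) /
      stats::plnorm(t, p["meanlog"], p["sdlog"], lower.tail = FALSE),
    loglogistic = p["theta"] * p["kappa"] * t^(p["kappa"] - 1) /
      (1 + p["theta"] * t^p["kappa"]),
    gompertz = flexsurv::hgompertz(t, p["shape"], p["rate"]),
    generalized_gamma = flexsurv::hgengamma(t, p["mu"], p["sigma"], p["Q"]))
  unname(h)
}

#' Quantile of the event-time distribution
#'
#' Time `t` at which the cumulative incidence reaches `p`, i.e.
#' `S(t) = 1 - p`. Used for inverse-CDF simulation.
#'
#' @inheritParams surv_prob
#' @param p Probability (or vector) in `[0, 1)`.
#' @return Times in months (possibly `Inf` for improper distributions).
#' @export
surv_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "surv_spec"))
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  pr <- spec$params
  q <- switch(spec$family,
    exponential = stats::qexp(p, pr["rate"]),
    weibull = stats::qweibull(p, pr["shape"], pr["scale"]),
    lognormal = stats::qlnorm(p, pr["meanlog"], pr["sdlog"]),
    loglogistic = (p / ((1 - p) * pr["theta"]))^(1 / pr["kappa"]),
    gompertz = flexsurv::qgompertz(p, pr["shape"], pr["rate"]),
    generalized_gamma = flexsurv::qgengamma(p, pr["mu"], pr["sigma"], pr["Q"]))
  unname(q)
}

#' Median survival time
#'
#' @inheritParams surv_prob
#' @return Median in months; `Inf` with a warning when the survival function
#'   never reaches 0.5 (improper Gompertz).
#' @export
surv_median <- function(spec) {
  s_inf <- surv_prob(spec, 1e9)
  if (s_inf >= 0.5) {
    warning("survival never falls below 0.5; median is infinite")
    return(Inf)
  }
  surv_quantile(spec, 0.5)
}

#' Apply a hazard ratio to a baseline survival curve
#'
#' Under proportional hazards (`method = "ph"`, the default) the adjusted
#' curve is \eqn{S_1(t) = S_0(t)^{HR}}, equivalent to scaling the cumulative
#' hazard by `hr`. With `method = "aft"` the ratio is instead interpreted as a
#' time-acceleration factor, \eqn{S_1(t) = S_0(hr \cdot t)}, so `hr < 1` again
#' improves survival; this alternative is provided because trial reports
#' rarely state which scale a published ratio lives on.
#'
#' @param spec Baseline [surv_spec()].
#' @param hr Positive hazard ratio.
#' @param method `"ph"` (proportional hazards) or `"aft"` (accelerated time).
#' @return A vectorized function `S1(t)` with `S1(0) = 1`, non-increasing.
#' @export
apply_hazard_ratio <- function(spec, hr, method = c("ph", "aft")) {
  stopifnot(inherits(spec, "surv_spec"))
  method <- match.arg(method)
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop("hr must be a single positive number")
  if (method == "ph") {
    function(t) surv_prob(spec, t)^hr
  } else {
    function(t) surv_prob(spec, t * hr)
  }
}

#' Survival function of a specification
#'
#' Convenience closure, `function(t) surv_prob(spec, t)`.
#' @inheritParams surv_prob
#' @return A vectorized survival function.
#' @export
surv_fn <- function(spec) {
  force(spec)
  function(t) surv_prob(spec, t)
}
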