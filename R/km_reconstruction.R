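#' Digitized Kaplan-Meier curve
#'
#' Container for survival coordinates read off a published Kaplan-Meier plot
#' together with its numbers-at-risk table, the inputs to pseudo
#' individual-patient-data reconstruction.
#'
#' @param time Non-decreasing times (months) of the digitized coordinates;
#'   the first coordinate must be `(0, 1)`.
#' @param surv Survival probabilities at `time`, non-increasing, in `[0, 1]`.
#' @param risk_time Times of the number-at-risk table (first entry must be 0
#'   or the first coordinate time).
#' @param n_risk Numbers at risk at `risk_time`, non-increasing positive
#'   integers.
#' @param n_total Total number of patients; defaults to `n_risk[1]`.
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(time, surv, risk_time, n_risk, n_total = n_risk[1]) {
  stopifnot(length(time) == length(surv), length(risk_time) == length(n_risk))
  if (length(time) < 1L || time[1] != 0 || surv[1] != 1)
    stop("digitized curve must start at (0, 1)")
  if (is.unsorted(time)) stop("times must be non-decreasing")
  if (any(diff(surv) > 1e-9)) stop("survival coordinates must be non-increasing")
  if (any(surv < 0 | surv > 1)) stop("survival coordinates must lie in [0, 1]")
  if (any(diff(n_risk) > 0)) stop("numbers at risk must be non-increasing")
  if (any(n_risk < 0)) stop("numbers at risk must be non-negative")
  if (n_risk[1] > n_total) stop("more patients at risk than n_total")
  structure(list(time = as.numeric(time), surv = pmin(surv, cummin(surv)),
                 risk_time = as.numeric(risk_time),
                 n_risk = as.integer(round(n_risk)),
                 n_total = as.integer(n_total)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve> ", length(x$time), " coordinates over [0, ",
      signif(max(x$time), 4), "] months, n = ", x$n_total, ", ",
      length(x$risk_time), " risk-table entries\n", sep = "")
  invisible(x)
}

#' Pseudo individual-patient data
#'
#' @param time Follow-up times in months.
#' @param status Event indicator: 1 = event, 0 = censored.
#' @return A `data.frame` of class `pseudo_ipd` with columns `time`, `status`.
#' @export
pseudo_ipd <- function(time, status) {
  stopifnot(length(time) == length(status))
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(status %in% c(0, 1))) stop("status must be 0 (censored) or 1 (event)")
  structure(data.frame(time = as.numeric(time), status = as.integer(status)),
            class = c("pseudo_ipd", "data.frame"))
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Inverts the product-limit estimator interval by interval between
#' consecutive number-at-risk times, iteratively allocating censoring
#' (spread uniformly within each interval) so that the implied number at
#' risk matches the published risk table, and rounding event counts so the
#' recomputed KM curve tracks the digitized coordinates. After the last
#' risk-table time censoring is assumed absent until the final coordinate;
#' patients still at risk there are administratively censored.
#'
#' @param curve A [digitized_curve()].
#' @return A [pseudo_ipd()] with exactly `n_total` records.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  t_s <- curve$time
  s <- curve$surv
  t_risk <- curve$risk_time
  n_risk <- as.numeric(curve$n_risk)
  K <- length(t_risk)
  if (K < 2L) stop("need at least 2 risk-table entries")
  n_t <- length(t_s)
  # first digitized index in each risk interval
  lower <- vapply(t_risk, function(tk) which(t_s >= tk - 1e-9)[1], 1L)
  if (anyNA(lower)) stop("risk-table times outside the digitized range")
  upper <- c(lower[-1] - 1L, n_t)

  n_hat <- rep(NA_real_, n_t + 1L)
  n_hat[1] <- n_risk[1]
  cen <- d <- rep(0, n_t)
  km_hat <- rep(1, n_t)
  last_i <- rep(1L, K)
  n_censor <- rep(0, K)

  if (any(diff(n_risk) > 0) || n_risk[1] > curve$n_total)
    stop("inconsistent risk table: more at risk than remaining patients")
  for (i in seq_len(K - 1L)) {
    # initial guess of censorings in interval i from the KM drop
    ratio <- if (s[lower[i]] > 0) s[lower[i + 1L]] / s[lower[i]] else 1
    n_censor[i] <- round(n_risk[i] * ratio - n_risk[i + 1L])
    guard <- 0L
    repeat {
      guard <- guard + 1L
      n_censor[i] <- max(0, min(n_censor[i], n_risk[i]))
      end_t <- t_s[lower[i + 1L]]
      cen_t <- if (n_censor[i] > 0)
        t_s[lower[i]] + seq_len(n_censor[i]) * (end_t - t_s[lower[i]]) / (n_censor[i] + 1)
      else numeric(0)
      n_hat[lower[i]] <- n_risk[i]
      last <- last_i[i]
      for (j in lower[i]:upper[i]) {
        cen[j] <- sum(cen_t >= t_s[j] &
                        cen_t < if (j < n_t) t_s[j + 1L] else Inf)
        if (j == 1L) {
          d[j] <- 0
          km_hat[j] <- 1
        } else {
          d[j] <- if (km_hat[last] > 0 && n_hat[j] > 0)
            round(n_hat[j] * (1 - s[j] / km_hat[last])) else 0
          d[j] <- max(0, min(d[j], n_hat[j]))
          km_hat[j] <- km_hat[last] * (1 - d[j] / max(n_hat[j], 1))
        }
        n_hat[j + 1L] <- n_hat[j] - d[j] - cen[j]
        if (d[j] != 0) last <- j
      }
      gap <- n_hat[lower[i + 1L]] - n_risk[i + 1L]
      if (abs(gap) < 0.5 || (gap < 0 && n_censor[i] <= 0) || guard > 200L) break
      n_censor[i] <- n_censor[i] + gap
    }
    if (n_hat[lower[i + 1L]] < n_risk[i + 1L])
      n_risk[i + 1L] <- n_hat[lower[i + 1L]]
    last_i[i + 1L] <- last
    if (n_censor[i] > 0) attr(cen, paste0("times_", i)) <- cen_t
  }
  # last interval: no interior censoring assumed
  i <- K
  n_hat[lower[i]] <- n_risk[i]
  last <- last_i[i]
  for (j in lower[i]:upper[i]) {
    cen[j] <- 0
    if (j == 1L) {
      d[j] <- 0
      km_hat[j] <- 1
    } else {
      d[j] <- if (km_hat[last] > 0 && n_hat[j] > 0)
        round(n_hat[j] * (1 - s[j] / km_hat[last])) else 0
      d[j] <- max(0, min(d[j], n_hat[j]))
      km_hat[j] <- km_hat[last] * (1 - d[j] / max(n_hat[j], 1))
    }
    n_hat[j + 1L] <- n_hat[j] - d[j]
    if (d[j] != 0) last <- j
  }

  # events detected at coordinate j occurred somewhere in (t[j-1], t[j]];
  # place them mid-interval (unbiased for grid-sampled curves, exact when the
  # digitization records both corners of a step)
  ev_time <- (c(0, t_s[-n_t]) + t_s) / 2
  ev_time[1] <- t_s[1]
  times <- rep(ev_time, times = round(d))
  status <- rep(1L, length(times))
  for (i in seq_len(K - 1L)) {
    ct <- attr(cen, paste0("times_", i))
    if (!is.null(ct)) {
      times <- c(times, ct)
      status <- c(status, rep(0L, length(ct)))
    }
  }
  # remaining patients administratively censored at the last coordinate
  n_left <- curve$n_total - length(times)
  if (n_left > 0) {
    times <- c(times, rep(max(t_s), n_left))
    status <- c(status, rep(0L, n_left))
  } else if (n_left < 0) {
    # rounding overshoot: drop the latest censored records
    idx <- order(status == 0L, times, decreasing = TRUE)[seq_len(-n_left)]
    times <- times[-idx]
    status <- status[-idx]
  }
  pseudo_ipd(times, status)
}

#' Fit a parametric survival family to (pseudo) IPD by maximum likelihood
#'
#' Right-censored maximum likelihood via [flexsurv::flexsurvreg()], reported
#' in this package's parameterizations. The log-likelihood is the censored
#' likelihood \eqn{\sum_{events} \ln f(t_i) + \sum_{censored} \ln S(t_i)} and
#' `aic = 2k - 2 loglik`.
#'
#' @param ipd A [pseudo_ipd()] (or data.frame with `time`, `status`),
#'   at least 10 records and at least one event.
#' @param family A family name from [surv_families()].
#' @return Object of class `parametric_fit`: `spec`, `loglik`, `aic`,
#'   `n_params`, `status` (`"ok"` or `"failed"`).
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  if (nrow(ipd) < 10L) stop("need at least 10 records to fit")
  if (sum(ipd$status) < 1L) stop("cannot fit a survival model with no events")
  if (any(ipd$time <= 0)) ipd$time <- pmax(ipd$time, 1e-6)
  dist <- switch(family,
    exponential = "exp", weibull = "weibull", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz",
    generalized_gamma = "gengamma")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, data = ipd,
                          dist = dist,
                          control = list(reltol = 1e-12, maxit = 10000)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(family = family, spec = NULL, loglik = NA_real_,
                          aic = NA_real_, n_params = NA_integer_,
                          status = "failed", message = conditionMessage(fit)),
                     class = "parametric_fit"))
  }
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  params <- switch(family,
    exponential = c(rate = unname(est["rate"])),
    weibull = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    lognormal = c(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"])),
    loglogistic = c(theta = unname(est["scale"])^(-unname(est["shape"])),
                    kappa = unname(est["shape"])),
    gompertz = c(shape = unname(est["shape"]), rate = unname(est["rate"])),
    generalized_gamma = c(mu = unname(est["mu"]), sigma = unname(est["sigma"]),
                          Q = unname(est["Q"])))
  spec <- surv_spec(family, params)
  if (family == "gompertz" && params["shape"] < 0)
    warning("Gompertz fit has negative shape: improper survival, ",
            "extrapolated mean may not exist")
  structure(list(family = family, spec = spec,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 n_params = fit$npars, status = "ok"),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat("<parametric_fit>", x$family, "status:", x$status)
  if (x$status == "ok")
    cat(sprintf("  loglik %.3f  AIC %.3f  (%d params)", x$loglik, x$aic, x$n_params))
  cat("\n")
  invisible(x)
}

#' Select the best parametric fit by AIC
#'
#' Minimum AIC among converged fits; ties broken by fewer parameters, then by
#' the family order of [surv_families()].
#'
#' @param fits A list of [fit_parametric()] results.
#' @return The selected `parametric_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list")
  if (inherits(fits, "parametric_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) identical(f$status, "ok"), TRUE)
  if (!any(ok)) stop("no converged fits to select from")
  fits <- fits[ok]
  aic <- vapply(fits, function(f) as.numeric(f$aic), 0)
  k <- vapply(fits, function(f) as.numeric(f$n_params), 0)
  fam <- match(vapply(fits, `[[`, "", "family"), surv_families())
  fits[[order(aic, k, fam)[1L]]]
}
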