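# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Recipe for simulating censored survival data
#'
#' Describes the ground truth of a synthetic trial arm: the event-time
#' distribution, cohort size, uniform accrual window and administrative
#' cutoff. Stands in for the unpublished source Kaplan-Meier curves so the
#' reconstruction and fitting stages can be tested end to end.
#'
#' @param spec True event-time distribution, a [surv_spec()].
#' @param n_subjects Number of subjects (> 0).
#' @param accrual_months Uniform accrual window width in months (0 = all
#'   enter at time 0).
#' @param cutoff_months Administrative cutoff, measured from the start of
#'   accrual; `Inf` disables censoring.
#' @param seed Mandatory integer seed.
#' @return Object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(spec, n_subjects, accrual_months = 0,
                              cutoff_months = Inf, seed) {
  stopifnot(inherits(spec, "surv_spec"), n_subjects > 0, cutoff_months > 0,
            accrual_months >= 0)
  if (missing(seed)) stop("seed is mandatory")
  structure(list(spec = spec, n_subjects = as.integer(n_subjects),
                 accrual_months = accrual_months,
                 cutoff_months = cutoff_months, seed = as.integer(seed)),
            class = "simulation_recipe")
}

#' Simulate censored individual-patient data
#'
#' Event times are drawn by inverse-CDF sampling from the recipe's
#' distribution; each subject's follow-up is `cutoff - entry` with entry
#' uniform over the accrual window, and events beyond follow-up are
#' administratively censored. Reproducible: the same recipe (same seed)
#' yields identical records.
#'
#' @param recipe A [simulation_recipe()].
#' @return A [pseudo_ipd()].
#' @export
simulate_ipd <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  with_seed(recipe$seed, {
    n <- recipe$n_subjects
    u <- stats::runif(n)
    t_event <- surv_quantile(recipe$spec, u)
    entry <- if (recipe$accrual_months > 0)
      stats::runif(n, 0, recipe$accrual_months) else rep(0, n)
    fu <- recipe$cutoff_months - entry
    pseudo_ipd(pmin(t_event, fu), as.integer(t_event <= fu))
  })
}

#' Kaplan-Meier estimate with a number-at-risk table
#'
#' Product-limit estimator (via [survival::survfit()]) packaged as a
#' [digitized_curve()], with numbers at risk emitted on a regular time grid.
#'
#' @param ipd A [pseudo_ipd()].
#' @param risk_interval_months Spacing of the number-at-risk table.
#' @return A [digitized_curve()] whose coordinates are the step-function
#'   values at time 0 and every event time.
#' @export
km_estimate <- function(ipd, risk_interval_months = 3) {
  stopifnot(nrow(ipd) >= 1)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = ipd)
  time <- c(0, fit$time)
  surv <- c(1, fit$surv)
  risk_time <- seq(0, max(ipd$time), by = risk_interval_months)
  sm <- summary(fit, times = risk_time, extend = TRUE)
  digitized_curve(time, surv, risk_time, sm$n.risk, n_total = nrow(ipd))
}

#' Sample a digitized version of a Kaplan-Meier curve
#'
#' Emulates reading coordinates off a published plot: evaluates the step
#' function on an equally spaced grid (keeping the exact `(0, 1)` origin)
#' while preserving the risk table.
#'
#' @param curve A [digitized_curve()] (e.g. from [km_estimate()]).
#' @param n_points Number of grid points after time 0 (default 40).
#' @return A coarser [digitized_curve()].
#' @export
digitize_curve <- function(curve, n_points = 40) {
  stopifnot(inherits(curve, "digitized_curve"))
  grid <- seq(0, max(curve$time), length.out = n_points + 1)
  s <- stats::approx(curve$time, curve$surv, xout = grid, method = "constant",
                     f = 0, rule = 2)$y
  digitized_curve(grid, s, curve$risk_time, curve$n_risk, curve$n_total)
}

#' Write a digitized curve to CSV files
#'
#' Emits `<stem>_curve.csv` (`time`, `surv`) and `<stem>_risk.csv`
#' (`time`, `n_risk`).
#'
#' @param curve A [digitized_curve()].
#' @param stem Path stem for the two files.
#' @return The two paths, invisibly.
#' @export
write_curve_csv <- function(curve, stem) {
  p1 <- paste0(stem, "_curve.csv")
  p2 <- paste0(stem, "_risk.csv")
  utils::write.csv(data.frame(time = curve$time, surv = curve$surv), p1,
                   row.names = FALSE)
  utils::write.csv(data.frame(time = curve$risk_time, n_risk = curve$n_risk),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a digitized curve from CSV files
#'
#' @param stem Path stem used by [write_curve_csv()].
#' @param n_total Total number of patients (defaults to the first risk count).
#' @return A [digitized_curve()].
#' @export
read_curve_csv <- function(stem, n_total = NULL) {
  cv <- utils::read.csv(paste0(stem, "_curve.csv"))
  rt <- utils::read.csv(paste0(stem, "_risk.csv"))
  digitized_curve(cv$time, cv$surv, rt$time, rt$n_risk,
                  n_total = n_total %||% rt$n_risk[1])
}
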