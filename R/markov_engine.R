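#' Cohort model configuration
#'
#' Settings of the three-week-cycle cohort model. The cycle length is 21 days
#' expressed in average months (21/30.4375). The horizon is rounded up to a
#' whole number of cycles. Discounting is 3% per annum, applied at each
#' cycle's evaluation time. With `half_cycle_correction = TRUE` (default)
#' state membership is evaluated at cycle midpoints, which approximates
#' trapezoid integration of the survival curves; otherwise at cycle ends.
#'
#' @param cycle_length_months Cycle length in months (default three weeks).
#' @param horizon_months Model horizon in months. The default, 480 months,
#'   operationalizes a lifetime horizon for a metastatic-melanoma cohort.
#' @param annual_discount Annual discount rate (default 0.03).
#' @param half_cycle_correction Evaluate membership at cycle midpoints.
#' @param occupancy_mode `"partitioned_survival"` (membership read directly
#'   off the OS/PFS curves) or `"transition_probability"` (per-cycle
#'   probabilities from interval survival ratios).
#' @param hr_method How hazard ratios adjust the baseline curves; passed to
#'   [apply_hazard_ratio()].
#' @param bsc_unit Unit of the best-supportive-care cost:
#'   `"once_at_progression"` (default; one-time on entering the progressed
#'   state), `"per_cycle"` or `"per_week"` while progressed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(cycle_length_months = 21 / 30.4375,
                         horizon_months = 480,
                         annual_discount = 0.03,
                         half_cycle_correction = TRUE,
                         occupancy_mode = c("partitioned_survival",
                                            "transition_probability"),
                         hr_method = c("ph", "aft"),
                         bsc_unit = c("once_at_progression", "per_cycle",
                                      "per_week")) {
  occupancy_mode <- match.arg(occupancy_mode)
  hr_method <- match.arg(hr_method)
  bsc_unit <- match.arg(bsc_unit)
  stopifnot(cycle_length_months > 0, horizon_months > 0, annual_discount >= 0)
  n_cycles <- as.integer(ceiling(horizon_months / cycle_length_months - 1e-9))
  structure(list(cycle_length_months = cycle_length_months,
                 horizon_months = n_cycles * cycle_length_months,
                 n_cycles = n_cycles,
                 annual_discount = annual_discount,
                 half_cycle_correction = half_cycle_correction,
                 occupancy_mode = occupancy_mode,
                 hr_method = hr_method,
                 bsc_unit = bsc_unit),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("<model_config> %d cycles of %.4f months (horizon %.1f mo), ",
                     "discount %.1f%%/yr, half-cycle %s, %s\n"),
              x$n_cycles, x$cycle_length_months, x$horizon_months,
              100 * x$annual_discount, ifelse(x$half_cycle_correction, "on", "off"),
              x$occupancy_mode))
  invisible(x)
}

#' Health-state utilities
#'
#' Utility weights for the response and stable-disease sub-states of the
#' progression-free state and for progressed disease, plus the arm-specific
#' share of progression-free patients in response.
#'
#' @param u_response,u_stable,u_progressed Utilities in `[0, 1]`.
#' @param response_share Proportion of progression-free patients in the
#'   response sub-state (0.31 combination arm, 0.13 ipilimumab arm).
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(u_response = 0.88, u_stable = 0.80,
                        u_progressed = 0.52, response_share = 0.13) {
  vals <- c(u_response, u_stable, u_progressed, response_share)
  if (any(vals < 0 | vals > 1)) stop("utilities and response share must be in [0, 1]")
  structure(list(u_response = u_response, u_stable = u_stable,
                 u_progressed = u_progressed, response_share = response_share),
            class = "utility_set")
}

#' Build the per-cycle cohort trace from OS and PFS curves
#'
#' Partitioned-survival occupancy: progression-free `PF(t) = min(PFS(t),
#' OS(t))` (clamped with a warning if PFS exceeds OS), progressed
#' `PD(t) = OS(t) - PF(t)`, dead `1 - OS(t)`. The progression-free state is
#' split into response and stable-disease sub-states by a constant
#' `response_share`. In `"transition_probability"` mode the same curves
#' supply per-cycle interval transition probabilities
#' (`1 - S(t+c)/S(t)`) that drive a three-state cohort recursion, and
#' membership is the midpoint average of the cycle's boundary values when
#' half-cycle correction is on.
#'
#' @param os_fn,pfs_fn Vectorized survival functions of time in months
#'   (e.g. from [surv_fn()] or [apply_hazard_ratio()]).
#' @param cfg A [model_config()].
#' @param response_share Constant response proportion of PF occupancy.
#' @return A `data.frame` of class `cohort_trace` with one row per cycle:
#'   `cycle`, `time_start`, `time_eval`, `time_end`, `pf_start`, `pd_start`,
#'   `response`, `stable`, `progressed`, `dead`, `incident_deaths`,
#'   `pd_entrants`, `discount`, `discount_start`.
#' @export
build_trace <- function(os_fn, pfs_fn, cfg = model_config(),
                        response_share = 0) {
  stopifnot(inherits(cfg, "model_config"),
            is.function(os_fn), is.function(pfs_fn),
            response_share >= 0, response_share <= 1)
  cl <- cfg$cycle_length_months
  n <- cfg$n_cycles
  bounds <- (0:n) * cl
  t_eval <- if (cfg$half_cycle_correction) bounds[-1] - cl / 2 else bounds[-1]

  os_b <- os_fn(bounds)
  pfs_b <- pfs_fn(bounds)
  if (abs(os_b[1] - 1) > 1e-9 || abs(pfs_b[1] - 1) > 1e-9)
    stop("survival functions must satisfy S(0) = 1")
  if (any(pfs_b > os_b + 1e-9))
    warning("PFS exceeds OS at some times; clamped to OS (min rule)")
  pfs_b <- pmin(pfs_b, os_b)

  if (cfg$occupancy_mode == "partitioned_survival") {
    os_e <- os_fn(t_eval)
    pfs_e <- pmin(pfs_fn(t_eval), os_e)
  } else {
    # three-state recursion on interval transition probabilities
    r_os <- ifelse(os_b[-(n + 1)] > 0, os_b[-1] / os_b[-(n + 1)], 1)
    r_pfs <- ifelse(pfs_b[-(n + 1)] > 0, pfs_b[-1] / pfs_b[-(n + 1)], 1)
    pf <- cumprod(r_pfs)
    alive <- cumprod(r_os)
    pf <- pmin(pf, alive)
    if (cfg$half_cycle_correction) {
      os_e <- (c(1, alive[-n]) + alive) / 2
      pfs_e <- (c(1, pf[-n]) + pf) / 2
    } else {
      os_e <- alive
      pfs_e <- pf
    }
  }
  pd_e <- pmax(os_e - pfs_e, 0)
  dead_e <- 1 - os_e

  r <- cfg$annual_discount
  disc_eval <- (1 + r)^(-t_eval / 12)
  disc_start <- (1 + r)^(-bounds[-(n + 1)] / 12)

  trace <- data.frame(
    cycle = seq_len(n),
    time_start = bounds[-(n + 1)],
    time_eval = t_eval,
    time_end = bounds[-1],
    pf_start = pfs_b[-(n + 1)],
    pd_start = pmax(os_b[-(n + 1)] - pfs_b[-(n + 1)], 0),
    response = response_share * pfs_e,
    stable = (1 - response_share) * pfs_e,
    progressed = pd_e,
    dead = dead_e,
    incident_deaths = diff(c(0, dead_e)),
    pd_entrants = pmax(diff(c(0, pd_e)), 0),
    discount = disc_eval,
    discount_start = disc_start)
  structure(trace, class = c("cohort_trace", "data.frame"),
            config = cfg, response_share = response_share)
}

trace_config <- function(trace, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(trace, "config")
  if (is.null(cfg)) stop("trace carries no model_config; pass cfg explicitly")
  cfg
}

#' Discounted life-years of a cohort trace
#'
#' Per-cycle survival (`1 - dead`) times the cycle's discount factor,
#' integrated over the horizon and expressed in years.
#'
#' @param trace A [build_trace()] result.
#' @param cfg Optional [model_config()]; defaults to the one stored in the
#'   trace.
#' @return Discounted life-years.
#' @export
accrue_life_years <- function(trace, cfg = NULL) {
  cfg <- trace_config(trace, cfg)
  sum((1 - trace$dead) * trace$discount) * cfg$cycle_length_months / 12
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' @inheritParams accrue_life_years
#' @param utilities A [utility_set()]. Its `response_share` is not used here;
#'   the split is fixed in the trace.
#' @return Discounted QALYs (always `<=` the discounted life-years when all
#'   utilities are `<= 1`).
#' @export
accrue_qalys <- function(trace, utilities = utility_set(), cfg = NULL) {
  cfg <- trace_config(trace, cfg)
  q <- trace$response * utilities$u_response +
    trace$stable * utilities$u_stable +
    trace$progressed * utilities$u_progressed
  sum(q * trace$discount) * cfg$cycle_length_months / 12
}

#' Per-cycle incident deaths
#'
#' First difference of the cumulative dead column; attaches the one-time
#' terminal-care cost in the costing module.
#'
#' @inheritParams accrue_life_years
#' @return Numeric vector, one element per cycle, summing to the dead
#'   occupancy at the horizon.
#' @export
death_incidence <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  trace$incident_deaths
}

#' Export a cohort trace as CSV
#'
#' @inheritParams accrue_life_years
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
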