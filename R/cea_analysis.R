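#' Run one treatment arm of the model
#'
#' Builds the arm's OS/PFS curves from the baseline log-logistic fits (the
#' combination arm by hazard-ratio adjustment), runs the cohort trace and
#' accrues discounted life-years, QALYs and costs.
#'
#' @param values Named list of parameter values (see [baseline_values()]).
#' @param arm `"ipilimumab"` or `"combination"`.
#' @param cfg A [model_config()].
#' @param hr_os,hr_pfs Optional hazard-ratio overrides (used by subgroup and
#'   sensitivity analyses); default to `values$hr_os` / `values$hr_pfs`.
#' @return List with `ly`, `qaly`, `cost`, `cost_breakdown`, `trace`.
#' @export
run_arm <- function(values, arm = c("ipilimumab", "combination"),
                    cfg = model_config(), hr_os = NULL, hr_pfs = NULL) {
  arm <- match.arg(arm)
  inp <- values_to_inputs(values, cfg)
  if (arm == "ipilimumab") {
    os_fn <- surv_fn(inp$os0)
    pfs_fn <- surv_fn(inp$pfs0)
    resp <- values$resp_ipi
  } else {
    os_fn <- apply_hazard_ratio(inp$os0, hr_os %||% values$hr_os, cfg$hr_method)
    pfs_fn <- apply_hazard_ratio(inp$pfs0, hr_pfs %||% values$hr_pfs, cfg$hr_method)
    resp <- values$resp_combo
  }
  trace <- build_trace(os_fn, pfs_fn, cfg, response_share = resp)
  u <- utility_set(values$u_response, values$u_stable, values$u_progressed, resp)
  cost <- accrue_total_cost(trace, arm_cost_config(arm), inp$prices, cfg)
  list(arm = arm,
       ly = accrue_life_years(trace, cfg),
       qaly = accrue_qalys(trace, u, cfg),
       cost = cost$total,
       cost_breakdown = cost$breakdown,
       trace = trace)
}

#' Base-case incremental cost-effectiveness analysis
#'
#' Runs both arms at the supplied parameter values and reports per-arm
#' discounted life-years, QALYs and costs plus the incremental results. The
#' ICER is computed from unrounded increments.
#'
#' @param params A `parameter_set` (default [default_parameters()]) or a
#'   named list of values.
#' @param cfg A [model_config()].
#' @param hr_os,hr_pfs Optional hazard-ratio overrides.
#' @return Object of class `cea_result`: `arms` data.frame and an
#'   `incremental` list (`delta_ly`, `delta_qaly`, `delta_cost`,
#'   `icer_qaly`, `icer_ly`, `dominance`). ICERs are `NA` when the QALY (or
#'   LY) increment is zero; `dominance` is `"combination"` when it is
#'   cheaper and more effective, `"ipilimumab"` for the reverse, otherwise
#'   `"none"`.
#' @export
run_base_case <- function(params = default_parameters(), cfg = model_config(),
                          hr_os = NULL, hr_pfs = NULL) {
  values <- if (inherits(params, "parameter_set")) baseline_values(params) else params
  a0 <- run_arm(values, "ipilimumab", cfg)
  a1 <- run_arm(values, "combination", cfg, hr_os = hr_os, hr_pfs = hr_pfs)
  d_ly <- a1$ly - a0$ly
  d_q <- a1$qaly - a0$qaly
  d_c <- a1$cost - a0$cost
  dominance <- if (d_c < 0 && d_q > 0) "combination"
    else if (d_c > 0 && d_q < 0) "ipilimumab" else "none"
  structure(list(
    arms = data.frame(arm = c("ipilimumab", "combination"),
                      ly = c(a0$ly, a1$ly), qaly = c(a0$qaly, a1$qaly),
                      cost = c(a0$cost, a1$cost)),
    breakdown = rbind(ipilimumab = a0$cost_breakdown,
                      combination = a1$cost_breakdown),
    incremental = list(delta_ly = d_ly, delta_qaly = d_q, delta_cost = d_c,
                       icer_qaly = if (d_q != 0) d_c / d_q else NA_real_,
                       icer_ly = if (d_ly != 0) d_c / d_ly else NA_real_,
                       dominance = dominance)),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  a <- x$arms
  cat("<cea_result>\n")
  cat(sprintf("  %-12s LY %5.2f  QALY %5.2f  cost $%s\n", a$arm, a$ly, a$qaly,
              format(round(a$cost), big.mark = ",")), sep = "")
  inc <- x$incremental
  cat(sprintf("  incremental: %+.2f LY, %+.2f QALY, $%s\n",
              inc$delta_ly, inc$delta_qaly,
              format(round(inc$delta_cost), big.mark = ",")))
  if (!is.na(inc$icer_qaly))
    cat(sprintf("  ICER: $%s/QALY, $%s/LY\n",
                format(round(inc$icer_qaly), big.mark = ","),
                format(round(inc$icer_ly), big.mark = ",")))
  else cat("  ICER undefined (zero QALY increment)\n")
  if (inc$dominance != "none") cat("  dominant strategy:", inc$dominance, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; at equal willingness-to-pay the strategy with the
#' higher net monetary benefit is preferred, which for two strategies is
#' equivalent to the ICER-threshold rule.
#'
#' @param cost,qaly Absolute cost (USD) and effect (QALYs).
#' @param wtp Willingness-to-pay per QALY, `>= 0`.
#' @return USD.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * qaly - cost
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER per QALY with each varied parameter set to its range
#' minimum and maximum while all others stay at baseline. Parameters with a
#' `fixed` distribution (the survival-curve coefficients) are not varied.
#'
#' @param params A `parameter_set`.
#' @param cfg A [model_config()].
#' @return `data.frame` of class `owsa_result`, sorted by decreasing ICER
#'   span: `name`, `label`, `min`, `max`, `icer_at_min`, `icer_at_max`,
#'   `icer_low`, `icer_high`, `span`.
#' @export
one_way_sa <- function(params = default_parameters(), cfg = model_config()) {
  base <- baseline_values(params)
  varied <- params[params$distribution != "fixed", ]
  icer_at <- function(name, value) {
    v <- base
    v[[name]] <- value
    run_base_case(v, cfg)$incremental$icer_qaly
  }
  rows <- lapply(seq_len(nrow(varied)), function(i) {
    nm <- varied$name[i]
    lo <- icer_at(nm, varied$min[i])
    hi <- icer_at(nm, varied$max[i])
    data.frame(name = nm, label = varied$label[i],
               min = varied$min[i], max = varied$max[i],
               icer_at_min = lo, icer_at_max = hi,
               icer_low = min(lo, hi), icer_high = max(lo, hi),
               span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, class = c("owsa_result", "data.frame"))
}

# moment-matched PSA distributions; sd = range/3.92 (normal 95% CI divisor),
# on the log scale for hazard ratios
psa_sampler <- function(row) {
  b <- row$baseline
  lo <- row$min
  hi <- row$max
  if (row$distribution == "fixed" || isTRUE(lo == hi))
    return(function(n) rep(b, n))
  switch(row$distribution,
    lognormal = {
      sdlog <- (log(hi) - log(lo)) / 3.92
      function(n) stats::rlnorm(n, log(b), sdlog)
    },
    gamma = {
      s <- (hi - lo) / 3.92
      function(n) stats::rgamma(n, shape = (b / s)^2, scale = s^2 / b)
    },
    beta = {
      s <- (hi - lo) / 3.92
      v <- s^2
      vmax <- b * (1 - b)
      if (v >= vmax) {
        warning("beta moment match infeasible for '", row$name,
                "'; clamping variance")
        v <- 0.99 * vmax
      }
      k <- b * (1 - b) / v - 1
      function(n) stats::rbeta(n, b * k, (1 - b) * k)
    })
}

#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Gamma (costs) and beta (utilities, probabilities) distributions are moment
#' matched to mean = baseline and sd = (max - min)/3.92; hazard ratios are
#' lognormal with meanlog = log(baseline) and sdlog = (log max - log min)/3.92,
#' so the sampled 2.5/97.5 percentiles reproduce the reported 95% CI.
#' Degenerate (`min == max`) and `fixed` parameters stay constant.
#'
#' @param params A `parameter_set`.
#' @param n Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return `data.frame` with `n` rows, one column per parameter.
#' @export
sample_parameters <- function(params = default_parameters(), n, seed = NULL) {
  draw <- function() {
    cols <- lapply(seq_len(nrow(params)), function(i)
      psa_sampler(params[i, ])(n))
    stats::setNames(as.data.frame(cols), params$name)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Probabilistic sensitivity analysis and acceptability curve
#'
#' Monte Carlo propagation of the parameter distributions through the full
#' model. For each draw both arms are re-run; the cost-effectiveness
#' acceptability curve (CEAC) is the fraction of draws in which the
#' combination arm has the higher net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param params A `parameter_set`.
#' @param cfg A [model_config()].
#' @param n_draws Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed; the same seed reproduces the run bit for bit.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param hr_os_override,hr_pfs_override Optional subgroup hazard-ratio
#'   distributions: lists `(point, lo, hi)` replacing the base lognormal.
#' @return Object of class `psa_result`: `draws` (per-draw per-arm costs and
#'   QALYs plus increments), `ceac` (`wtp`, `probability`), `n_draws`, `seed`.
#' @export
run_psa <- function(params = default_parameters(), cfg = model_config(),
                    n_draws = 10000, seed = 1,
                    wtp_grid = seq(0, 200000, by = 5000),
                    hr_os_override = NULL, hr_pfs_override = NULL) {
  stopifnot(n_draws >= 1)
  override <- function(df, nm, o) {
    if (is.null(o)) return(df)
    i <- match(nm, df$name)
    df$baseline[i] <- o$point
    df$min[i] <- o$lo
    df$max[i] <- o$hi
    df
  }
  params <- override(params, "hr_os", hr_os_override)
  params <- override(params, "hr_pfs", hr_pfs_override)
  samples <- sample_parameters(params, n_draws, seed = seed)
  res <- matrix(NA_real_, n_draws, 6,
                dimnames = list(NULL, c("cost_ipi", "qaly_ipi", "cost_combo",
                                        "qaly_combo", "delta_cost", "delta_qaly")))
  for (i in seq_len(n_draws)) {
    v <- as.list(samples[i, ])
    a0 <- run_arm(v, "ipilimumab", cfg)
    a1 <- run_arm(v, "combination", cfg)
    res[i, ] <- c(a0$cost, a0$qaly, a1$cost, a1$qaly,
                  a1$cost - a0$cost, a1$qaly - a0$qaly)
  }
  draws <- as.data.frame(res)
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w)
      mean(net_monetary_benefit(draws$delta_cost, draws$delta_qaly, w) > 0), 0))
  structure(list(draws = draws, ceac = ceac, n_draws = n_draws, seed = seed),
            class = "psa_result")
}

#' Probability of cost-effectiveness at a willingness-to-pay value
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay per QALY (vectorized).
#' @return Fraction of draws in which the combination arm has the higher net
#'   monetary benefit.
#' @export
ce_probability <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  vapply(wtp, function(w)
    mean(net_monetary_benefit(psa$draws$delta_cost, psa$draws$delta_qaly, w) > 0),
    0)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws, seed", x$seed, "\n")
  at <- c(50000, 100000, 150000)
  cat(sprintf("  P(CE) at $%sk/QALY: %s\n", paste(at / 1000, collapse = "/"),
              paste(sprintf("%.1f%%", 100 * ce_probability(x, at)), collapse = " / ")))
  invisible(x)
}

#' Subgroup cost-effectiveness analysis
#'
#' For each subgroup, both hazard ratios (and their CIs) are replaced by the
#' subgroup's values with all other parameters unchanged; reports the
#' deterministic ICER per QALY and, when `n_draws > 0`, the PSA probability
#' of cost-effectiveness at `wtp`.
#'
#' @param params A `parameter_set`.
#' @param subgroups A [subgroup_table()]-style data.frame.
#' @param cfg A [model_config()].
#' @param n_draws PSA draws per subgroup (0 skips the PSA).
#' @param seed Integer seed; each subgroup uses an offset of it.
#' @param wtp Willingness-to-pay threshold for the probability column.
#' @return `data.frame`: `subgroup`, `pfs_hr`, `os_hr`, `icer_qaly`,
#'   `ce_prob` (NA when `n_draws = 0`).
#' @export
run_subgroups <- function(params = default_parameters(),
                          subgroups = subgroup_table(),
                          cfg = model_config(), n_draws = 2000, seed = 1,
                          wtp = 150000) {
  rows <- lapply(seq_len(nrow(subgroups)), function(i) {
    sg <- subgroups[i, ]
    det <- run_base_case(params, cfg, hr_os = sg$os_hr, hr_pfs = sg$pfs_hr)
    prob <- NA_real_
    if (n_draws > 0) {
      psa <- run_psa(params, cfg, n_draws = n_draws, seed = seed + i,
                     hr_os_override = list(point = sg$os_hr, lo = sg$os_lo,
                                           hi = sg$os_hi),
                     hr_pfs_override = list(point = sg$pfs_hr, lo = sg$pfs_lo,
                                            hi = sg$pfs_hi))
      prob <- ce_probability(psa, wtp)
    }
    data.frame(subgroup = sg$subgroup, pfs_hr = sg$pfs_hr, os_hr = sg$os_hr,
               icer_qaly = det$incremental$icer_qaly, ce_prob = prob)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
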