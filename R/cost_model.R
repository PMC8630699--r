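#' Unit prices (2021 USD)
#'
#' Drug prices are per mg at 106% of the average sales price; administration
#' fees follow the CMS physician fee schedule (first infusion hour, each
#' additional started hour); disease-management rates are per week in the
#' progression-free state, on or off treatment; best supportive care and
#' terminal care are lump sums (see `bsc_unit` in [model_config()] for how
#' the BSC sum is attached).
#'
#' @param ipilimumab_per_mg,nivolumab_per_mg,pembrolizumab_per_mg USD per mg.
#' @param bsc Best-supportive-care cost after progression.
#' @param mgmt_pfd_on_tx_per_week,mgmt_pfd_off_tx_per_week Disease-management
#'   cost per progression-free week, on/off treatment.
#' @param terminal_care One-time terminal-care cost at death.
#' @param admin_first_hour,admin_additional_hour Infusion administration fees.
#' @return Object of class `price_table`.
#' @export
price_table <- function(ipilimumab_per_mg = 166, nivolumab_per_mg = 30,
                        pembrolizumab_per_mg = 55, bsc = 4492,
                        mgmt_pfd_on_tx_per_week = 189,
                        mgmt_pfd_off_tx_per_week = 590,
                        terminal_care = 18042,
                        admin_first_hour = 148, admin_additional_hour = 31) {
  prices <- list(ipilimumab_per_mg = ipilimumab_per_mg,
                 nivolumab_per_mg = nivolumab_per_mg,
                 pembrolizumab_per_mg = pembrolizumab_per_mg,
                 bsc = bsc,
                 mgmt_pfd_on_tx_per_week = mgmt_pfd_on_tx_per_week,
                 mgmt_pfd_off_tx_per_week = mgmt_pfd_off_tx_per_week,
                 terminal_care = terminal_care,
                 admin_first_hour = admin_first_hour,
                 admin_additional_hour = admin_additional_hour)
  if (any(unlist(prices) < 0)) stop("prices must be non-negative")
  structure(prices, class = "price_table")
}

#' Cost of one drug administration
#'
#' Per-kg rule: `price_per_mg * dose_mg_per_kg * weight_kg`; flat rule:
#' `price_per_mg * dose_mg`.
#'
#' @param drug `"ipilimumab"`, `"nivolumab"` or `"pembrolizumab"`.
#' @param dose Dose in mg/kg (`rule = "per_kg"`) or mg (`rule = "flat"`).
#' @param prices A [price_table()].
#' @param weight_kg Body weight (default 70 kg).
#' @param rule Dosing rule.
#' @return USD per administration.
#' @export
dose_cost <- function(drug, dose, prices = price_table(), weight_kg = 70,
                      rule = c("per_kg", "flat")) {
  rule <- match.arg(rule)
  key <- paste0(drug, "_per_mg")
  if (is.null(prices[[key]])) stop("unknown drug: ", drug)
  if (dose < 0) stop("dose must be non-negative")
  mg <- if (rule == "per_kg") dose * weight_kg else dose
  prices[[key]] * mg
}

#' Administration fee for one infusion visit
#'
#' First hour at the first-hour fee; each additional started hour at the
#' additional-hour fee (partial hours round up). Drugs infused on the same
#' visit share a single first hour.
#'
#' @param infusion_hours Total infusion duration of the visit, > 0.
#' @param prices A [price_table()].
#' @return USD per visit.
#' @export
administration_cost <- function(infusion_hours, prices = price_table()) {
  if (any(infusion_hours <= 0)) stop("infusion hours must be positive")
  extra <- ceiling(pmax(infusion_hours - 1, 0) - 1e-9)
  prices$admin_first_hour + extra * prices$admin_additional_hour
}

#' Treatment regimen
#'
#' An induction block of up to `induction_doses` visits every
#' `induction_interval_weeks` weeks, with one or more drug components per
#' visit, optionally followed by a maintenance drug given until progression.
#' Infusion durations: ipilimumab 90 min, anti-PD-1 30 min (label-standard);
#' same-day components bill a single first administration hour.
#'
#' @param name Regimen label.
#' @param induction `data.frame` with columns `drug`, `dose`, `rule`
#'   (`"per_kg"`/`"flat"`), `infusion_hours`; one row per same-day component.
#' @param induction_doses Number of induction visits (default 4).
#' @param induction_interval_weeks Weeks between induction visits (default 3).
#' @param maintenance `NULL`, or a list with `drug`, `dose_mg` (flat),
#'   `admins_per_cycle` (expected administrations per 3-week model cycle;
#'   1.5 for an every-2-week drug, 1 for every-3-week), `infusion_hours`,
#'   and optional `max_duration_months` cap.
#' @param weight_kg Body weight used for per-kg dosing.
#' @return Object of class `regimen`.
#' @export
regimen <- function(name, induction, induction_doses = 4,
                    induction_interval_weeks = 3, maintenance = NULL,
                    weight_kg = 70) {
  stopifnot(is.data.frame(induction),
            all(c("drug", "dose", "rule", "infusion_hours") %in% names(induction)),
            all(induction$dose > 0), induction_doses >= 1)
  structure(list(name = name, induction = induction,
                 induction_doses = induction_doses,
                 induction_interval_weeks = induction_interval_weeks,
                 maintenance = maintenance, weight_kg = weight_kg),
            class = "regimen")
}

#' @rdname regimen
#' @export
regimen_ipilimumab <- function(weight_kg = 70) {
  regimen("ipilimumab",
          data.frame(drug = "ipilimumab", dose = 3, rule = "per_kg",
                     infusion_hours = 1.5),
          weight_kg = weight_kg)
}

#' @rdname regimen
#' @export
regimen_ipi_nivolumab <- function(weight_kg = 70) {
  regimen("ipilimumab + nivolumab",
          data.frame(drug = c("ipilimumab", "nivolumab"), dose = c(3, 1),
                     rule = "per_kg", infusion_hours = c(1.5, 0.5)),
          maintenance = list(drug = "nivolumab", dose_mg = 240,
                             admins_per_cycle = 1.5, infusion_hours = 0.5,
                             max_duration_months = Inf),
          weight_kg = weight_kg)
}

#' @rdname regimen
#' @export
regimen_ipi_pembrolizumab <- function(weight_kg = 70) {
  regimen("ipilimumab + pembrolizumab",
          data.frame(drug = c("ipilimumab", "pembrolizumab"), dose = c(1, 2),
                     rule = "per_kg", infusion_hours = c(1.5, 0.5)),
          maintenance = list(drug = "pembrolizumab", dose_mg = 200,
                             admins_per_cycle = 1, infusion_hours = 0.5,
                             max_duration_months = Inf),
          weight_kg = weight_kg)
}

#' Arm-level costing configuration
#'
#' The combination arm mixes the nivolumab- and pembrolizumab-based regimens
#' 99%/1%; the ipilimumab arm is its 4-dose regimen alone. A progression-free
#' patient is "on treatment" (cheaper weekly disease management) while any
#' drug is still scheduled: the first 4 cycles in the ipilimumab arm, until
#' progression in the combination arm.
#'
#' @param arm `"ipilimumab"` or `"combination"`.
#' @param weight_kg Body weight for per-kg dosing.
#' @param pembrolizumab_share Mix weight of the pembrolizumab regimen in the
#'   combination arm.
#' @param maintenance_cap_months Optional cap on maintenance anti-PD-1
#'   duration (default uncapped).
#' @return Object of class `arm_cost_config`: list of `(regimen, weight)`
#'   pairs plus the on-treatment rule.
#' @export
arm_cost_config <- function(arm = c("ipilimumab", "combination"),
                            weight_kg = 70, pembrolizumab_share = 0.01,
                            maintenance_cap_months = Inf) {
  arm <- match.arg(arm)
  if (arm == "ipilimumab") {
    mix <- list(list(regimen = regimen_ipilimumab(weight_kg), weight = 1))
    on_tx <- "induction_only"
  } else {
    rn <- regimen_ipi_nivolumab(weight_kg)
    rp <- regimen_ipi_pembrolizumab(weight_kg)
    rn$maintenance$max_duration_months <- maintenance_cap_months
    rp$maintenance$max_duration_months <- maintenance_cap_months
    mix <- list(list(regimen = rn, weight = 1 - pembrolizumab_share),
                list(regimen = rp, weight = pembrolizumab_share))
    on_tx <- "until_progression"
  }
  structure(list(arm = arm, mix = mix, on_treatment = on_tx,
                 maintenance_cap_months = maintenance_cap_months),
            class = "arm_cost_config")
}

# per-cycle expected drug and administration cost for one regimen (undiscounted
# unless `discounted`); doses are weighted by the probability of still being
# progression-free at each scheduled administration
regimen_cycle_costs <- function(trace, reg, prices, cfg, discounted = FALSE) {
  n <- nrow(trace)
  drug <- admin <- numeric(n)
  cl <- cfg$cycle_length_months
  # induction visits fall at cycle starts 0, interval, 2*interval, ...
  visit_months <- (seq_len(reg$induction_doses) - 1) * reg$induction_interval_weeks * 7 / 30.4375
  visit_cycle <- pmin(floor(visit_months / cl + 1e-9) + 1, n)
  per_visit_drug <- sum(mapply(function(d, ds, ru) dose_cost(d, ds, prices, reg$weight_kg, ru),
                               reg$induction$drug, reg$induction$dose, reg$induction$rule))
  per_visit_admin <- administration_cost(sum(reg$induction$infusion_hours), prices)
  for (i in seq_along(visit_cycle)) {
    k <- visit_cycle[i]
    w <- trace$pf_start[k] * if (discounted) trace$discount_start[k] else 1
    drug[k] <- drug[k] + w * per_visit_drug
    admin[k] <- admin[k] + w * per_visit_admin
  }
  if (!is.null(reg$maintenance)) {
    m <- reg$maintenance
    last_induction <- max(visit_cycle)
    cap <- m$max_duration_months %||% Inf
    elig <- trace$cycle > last_induction & trace$time_start < cap
    w <- trace$response + trace$stable  # PF occupancy during the cycle
    w <- w * elig * m$admins_per_cycle * if (discounted) trace$discount else 1
    drug <- drug + w * dose_cost(m$drug, m$dose_mg, prices, reg$weight_kg, "flat")
    admin <- admin + w * administration_cost(m$infusion_hours, prices)
  }
  data.frame(cycle = trace$cycle, drug = drug, administration = admin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected per-cycle drug and administration cost
#'
#' Undiscounted expected acquisition plus administration cost per model
#' cycle, mixing the arm's regimens. Induction doses accrue with the
#' probability of being progression-free at each scheduled visit; maintenance
#' anti-PD-1 accrues per cycle in proportion to progression-free occupancy
#' until progression (or a configured cap).
#'
#' @param trace A [build_trace()] result.
#' @param arm_cfg An [arm_cost_config()].
#' @param prices A [price_table()].
#' @param cfg Optional [model_config()] (defaults to the trace's).
#' @return `data.frame` with columns `cycle`, `drug`, `administration`.
#' @export
expected_drug_cost_per_cycle <- function(trace, arm_cfg, prices = price_table(),
                                         cfg = NULL) {
  cfg <- trace_config(trace, cfg)
  out <- data.frame(cycle = trace$cycle, drug = 0, administration = 0)
  for (m in arm_cfg$mix) {
    cc <- regimen_cycle_costs(trace, m$regimen, prices, cfg)
    out$drug <- out$drug + m$weight * cc$drug
    out$administration <- out$administration + m$weight * cc$administration
  }
  out
}

#' Total discounted cost of an arm
#'
#' Sums five discounted components over the trace: drug acquisition,
#' administration fees, progression-free disease management (on-treatment
#' weeks at the on-treatment rate, off-treatment weeks otherwise), best
#' supportive care after progression, and one-time terminal care at death.
#' Point costs (doses, BSC entry, terminal care) are discounted at their
#' attachment times; continuous costs at the cycle evaluation time.
#'
#' @inheritParams expected_drug_cost_per_cycle
#' @return Object of class `cost_result`: `total` plus a `breakdown` vector
#'   (`drug`, `administration`, `management`, `bsc`, `terminal`) that sums
#'   exactly to the total.
#' @export
accrue_total_cost <- function(trace, arm_cfg, prices = price_table(),
                              cfg = NULL) {
  cfg <- trace_config(trace, cfg)
  drug <- admin <- 0
  for (m in arm_cfg$mix) {
    cc <- regimen_cycle_costs(trace, m$regimen, prices, cfg, discounted = TRUE)
    drug <- drug + m$weight * sum(cc$drug)
    admin <- admin + m$weight * sum(cc$administration)
  }
  weeks_per_cycle <- cfg$cycle_length_months * 30.4375 / 7
  pf <- trace$response + trace$stable
  on <- switch(arm_cfg$on_treatment,
    induction_only = trace$cycle <= max(vapply(
      arm_cfg$mix, function(m) m$regimen$induction_doses, 1)),
    until_progression = trace$time_start < arm_cfg$maintenance_cap_months)
  rate <- ifelse(on, prices$mgmt_pfd_on_tx_per_week, prices$mgmt_pfd_off_tx_per_week)
  management <- sum(pf * rate * trace$discount) * weeks_per_cycle
  bsc <- switch(cfg$bsc_unit,
    once_at_progression = sum(trace$pd_entrants * trace$discount) * prices$bsc,
    per_cycle = sum(trace$progressed * trace$discount) * prices$bsc,
    per_week = sum(trace$progressed * trace$discount) * weeks_per_cycle * prices$bsc)
  terminal <- sum(trace$incident_deaths * trace$discount) * prices$terminal_care
  breakdown <- c(drug = drug, administration = admin, management = management,
                 bsc = bsc, terminal = terminal)
  structure(list(total = sum(breakdown), breakdown = breakdown),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat("<cost_result> total $", format(round(x$total), big.mark = ","), "\n", sep = "")
  print(round(x$breakdown))
  invisible(x)
}
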