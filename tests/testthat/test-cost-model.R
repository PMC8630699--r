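one <- function(t) rep(1, length(t))

test_that("dose costs follow the per-kg and flat arithmetic", {
  expect_equal(dose_cost("ipilimumab", 3, rule = "per_kg"), 3 * 70 * 166)
  expect_equal(dose_cost("nivolumab", 240, rule = "flat"), 240 * 30)
  expect_equal(dose_cost("pembrolizumab", 2, rule = "per_kg"), 2 * 70 * 55)
  expect_equal(dose_cost("ipilimumab", 0, rule = "flat"), 0)
  expect_error(dose_cost("vemurafenib", 1), "unknown drug")
})

test_that("administration fees bill the first hour once and round partial hours up", {
  expect_equal(administration_cost(1.0), 148)
  expect_equal(administration_cost(1.5), 148 + 31)
  expect_equal(administration_cost(2.0), 148 + 31)
  expect_equal(administration_cost(3.0), 148 + 2 * 31)
  expect_equal(administration_cost(0.5), 148)
  expect_error(administration_cost(0), "positive")
})

test_that("doses accrue only while progression-free", {
  cfg <- model_config(horizon_months = 12, annual_discount = 0,
                      half_cycle_correction = FALSE)
  # progression-free only at time 0: a single induction dose accrues
  pfs0 <- function(t) as.numeric(t <= 0)
  tr <- suppressWarnings(build_trace(one, pfs0, cfg))
  cc <- expected_drug_cost_per_cycle(tr, arm_cost_config("ipilimumab"))
  expect_equal(sum(cc$drug), 3 * 70 * 166)
  expect_equal(sum(cc$administration), 179)
  # fully progression-free: exactly 4 induction doses
  tr1 <- build_trace(one, one, cfg)
  cc1 <- expected_drug_cost_per_cycle(tr1, arm_cost_config("ipilimumab"))
  expect_equal(sum(cc1$drug), 4 * 34860)
  expect_equal(sum(cc1$administration), 4 * 179)
  expect_true(all(cc1$drug[5:nrow(cc1)] == 0))
})

test_that("expected ipilimumab doses equal PFS evaluated at the schedule", {
  cfg <- model_config()
  tr <- build_trace(surv_fn(loglogistic_os()), surv_fn(loglogistic_pfs()), cfg,
                    response_share = 0.13)
  cc <- expected_drug_cost_per_cycle(tr, arm_cost_config("ipilimumab"))
  n_doses <- sum(cc$drug) / 34860
  # direct oracle: S_pfs at 0, 3, 6, 9 weeks from the closed form, capped by OS
  t_k <- (0:3) * 21 / 30.4375
  oracle <- sum(pmin(1 / (1 + 0.1380415 * t_k^1.922389),
                     1 / (1 + 0.03916796 * t_k^1.52458)))
  expect_equal(n_doses, oracle, tolerance = 1e-10)
  expect_equal(oracle, 3.3737, tolerance = 1e-3)
})

test_that("maintenance anti-PD-1 runs until progression and honours a cap", {
  cfg <- model_config(horizon_months = 24, annual_discount = 0,
                      half_cycle_correction = FALSE)
  tr <- build_trace(one, one, cfg, response_share = 0.31)
  cc <- expected_drug_cost_per_cycle(tr, arm_cost_config("combination"))
  n <- nrow(tr)
  # every post-induction cycle carries 1.5 nivolumab administrations (99%)
  # and 1 pembrolizumab administration (1%)
  maint <- 0.99 * 1.5 * 240 * 30 + 0.01 * 1 * 200 * 55
  expect_equal(cc$drug[n], maint)
  capped <- expected_drug_cost_per_cycle(
    tr, arm_cost_config("combination", maintenance_cap_months = 12))
  expect_equal(capped$drug[n], 0)
  expect_lt(sum(capped$drug), sum(cc$drug))
})

test_that("cost breakdown is additive, non-negative and price-monotone", {
  cfg <- model_config()
  tr <- build_trace(surv_fn(loglogistic_os()), surv_fn(loglogistic_pfs()), cfg,
                    response_share = 0.13)
  arm <- arm_cost_config("ipilimumab")
  res <- accrue_total_cost(tr, arm)
  expect_true(all(res$breakdown >= 0))
  expect_identical(res$total, sum(res$breakdown))
  # zero prices give zero cost
  zero <- price_table(0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(accrue_total_cost(tr, arm, zero)$total, 0)
  # raising any single price never lowers the total
  base <- price_table()
  for (field in names(unclass(base))) {
    up <- base
    up[[field]] <- up[[field]] * 1.5 + 1
    expect_gte(accrue_total_cost(tr, arm, up)$total, res$total)
  }
})

test_that("undiscounted terminal care conserves total deaths", {
  cfg <- model_config(horizon_months = 120, annual_discount = 0)
  tr <- build_trace(surv_fn(loglogistic_os()), surv_fn(loglogistic_pfs()), cfg)
  res <- accrue_total_cost(tr, arm_cost_config("ipilimumab"))
  expect_equal(unname(res$breakdown["terminal"]), 18042 * tr$dead[nrow(tr)],
               tolerance = 1e-9)
})

test_that("a never-progressing, untreated cohort accrues management cost only", {
  cfg <- model_config(horizon_months = 12, annual_discount = 0)
  prices <- price_table(ipilimumab_per_mg = 0, nivolumab_per_mg = 0,
                        pembrolizumab_per_mg = 0, admin_first_hour = 0,
                        admin_additional_hour = 0)
  tr <- build_trace(one, one, cfg)
  res <- accrue_total_cost(tr, arm_cost_config("ipilimumab"), prices)
  expect_equal(unname(res$breakdown[c("drug", "administration", "bsc", "terminal")]),
               rep(0, 4))
  weeks <- cfg$cycle_length_months * 30.4375 / 7
  manual <- (4 * 189 + (cfg$n_cycles - 4) * 590) * weeks
  expect_equal(unname(res$breakdown["management"]), manual, tolerance = 1e-9)
})

test_that("BSC unit conventions scale as configured", {
  os <- surv_fn(loglogistic_os())
  pfs <- surv_fn(loglogistic_pfs())
  totals <- sapply(c("once_at_progression", "per_cycle"), function(u) {
    cfg <- model_config(horizon_months = 120, bsc_unit = u)
    tr <- build_trace(os, pfs, cfg)
    unname(accrue_total_cost(tr, arm_cost_config("ipilimumab"),
                             cfg = cfg)$breakdown["bsc"])
  })
  # per-cycle accrual over years of progressed survival dwarfs the one-time cost
  expect_gt(totals["per_cycle"], 10 * totals["once_at_progression"])
})
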