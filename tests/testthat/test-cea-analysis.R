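test_that("identical effectiveness leaves the ICER undefined", {
  v <- baseline_values()
  v$hr_os <- 1
  v$hr_pfs <- 1
  v$resp_combo <- v$resp_ipi
  res <- run_base_case(v, model_config(horizon_months = 60))
  expect_equal(res$incremental$delta_qaly, 0, tolerance = 1e-12)
  expect_true(is.na(res$incremental$icer_qaly))
  expect_equal(res$incremental$dominance, "none")
})

test_that("the ICER is computed from unrounded increments", {
  res <- run_base_case(cfg = model_config(horizon_months = 120))
  inc <- res$incremental
  expect_equal(inc$icer_qaly, inc$delta_cost / inc$delta_qaly)
  a <- res$arms
  expect_equal(inc$delta_cost, a$cost[2] - a$cost[1])
  # rounding per-arm values first would give a visibly different ratio
  rounded <- round(inc$delta_cost) / round(inc$delta_qaly * 100) * 100
  expect_false(isTRUE(all.equal(rounded, inc$icer_qaly, tolerance = 1e-6)))
})

test_that("net monetary benefit is linear and reproduces the threshold rule", {
  expect_equal(net_monetary_benefit(100000, 1, 150000), 50000)
  expect_equal(net_monetary_benefit(2500, 0, 0), -2500)
  expect_error(net_monetary_benefit(1, 1, -5), "non-negative")
  set.seed(404)
  for (i in 1:200) {
    c0 <- runif(1, 0, 3e5); c1 <- runif(1, 0, 3e5)
    q0 <- runif(1, 0, 4); q1 <- runif(1, 0, 4)
    w <- runif(1, 0, 2e5)
    by_nmb <- net_monetary_benefit(c1, q1, w) > net_monetary_benefit(c0, q0, w)
    dq <- q1 - q0; dc <- c1 - c0
    by_icer <- if (dq > 0) dc / dq < w else if (dq < 0) dc / dq > w else dc < 0
    expect_identical(by_nmb, by_icer)
  }
})

test_that("PSA sampling is moment-matched to the stated ranges", {
  params <- default_parameters()
  s <- sample_parameters(params, 10000, seed = 2)
  # gamma cost: mean within 1% of baseline, sd near range/3.92
  expect_lt(abs(mean(s$price_ipilimumab_mg) / 166 - 1), 0.01)
  expect_lt(abs(sd(s$price_ipilimumab_mg) / ((199 - 133) / 3.92) - 1), 0.05)
  # lognormal HR: sampled 2.5/97.5 percentiles near the reported CI
  q <- quantile(s$hr_os, c(0.025, 0.975))
  expect_equal(unname(q[1]), 0.38, tolerance = 0.03)
  expect_equal(unname(q[2]), 0.66, tolerance = 0.03)
  # beta utilities stay in [0, 1] with the right mean
  expect_true(all(s$u_stable >= 0 & s$u_stable <= 1))
  expect_lt(abs(mean(s$u_stable) - 0.80), 0.01)
  # fixed parameters are constant
  expect_equal(unique(s$os_theta), 0.03916796)
  # degenerate range collapses to a constant
  p2 <- params
  p2$min[p2$name == "cost_bsc"] <- p2$max[p2$name == "cost_bsc"] <-
    p2$baseline[p2$name == "cost_bsc"]
  s2 <- sample_parameters(p2, 50, seed = 3)
  expect_equal(unique(s2$cost_bsc), 4492)
})

test_that("tornado spans are well-defined, order-invariant and zero for fixed ranges", {
  cfg <- model_config(horizon_months = 120)
  params <- default_parameters()
  params$min[params$name == "u_stable"] <- 0.80
  params$max[params$name == "u_stable"] <- 0.80
  ow <- one_way_sa(params, cfg)
  expect_equal(ow$span[ow$name == "u_stable"], 0)
  expect_true(all(diff(ow$span) <= 1e-9))
  shuffled <- params[rev(seq_len(nrow(params))), ]
  ow2 <- one_way_sa(shuffled, cfg)
  m <- match(ow$name, ow2$name)
  expect_equal(ow$span, ow2$span[m], tolerance = 1e-9)
})

test_that("PSA is bit-reproducible under a fixed seed and stable across seeds", {
  cfg <- model_config(horizon_months = 240)
  p1 <- run_psa(n_draws = 40, seed = 5, cfg = cfg)
  p2 <- run_psa(n_draws = 40, seed = 5, cfg = cfg)
  expect_identical(p1$draws, p2$draws)
  a <- ce_probability(run_psa(n_draws = 1500, seed = 101, cfg = cfg), 150000)
  b <- ce_probability(run_psa(n_draws = 1500, seed = 202, cfg = cfg), 150000)
  expect_lt(abs(a - b), 0.03)
})

test_that("CEAC limits reduce to sign frequencies of the increments", {
  psa <- run_psa(n_draws = 200, seed = 8, cfg = model_config(horizon_months = 120),
                 wtp_grid = c(0, 150000))
  expect_equal(psa$ceac$probability[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  expect_equal(ce_probability(psa, 1e12), mean(psa$draws$delta_qaly > 0))
})

test_that("a subgroup with base-case hazard ratios reproduces the base case", {
  cfg <- model_config(horizon_months = 240)
  base <- run_base_case(cfg = cfg)
  sg <- data.frame(subgroup = "base", pfs_hr = 0.69, pfs_lo = 0.55,
                   pfs_hi = 0.87, os_hr = 0.50, os_lo = 0.38, os_hi = 0.66)
  res <- run_subgroups(subgroups = sg, cfg = cfg, n_draws = 0)
  expect_equal(res$icer_qaly, base$incremental$icer_qaly, tolerance = 1e-12)
  expect_true(is.na(res$ce_prob))
})

test_that("the ICER falls monotonically as the OS hazard ratio improves", {
  cfg <- model_config(horizon_months = 240)
  icers <- sapply(c(0.35, 0.45, 0.55, 0.65, 0.8),
                  function(h) run_base_case(cfg = cfg, hr_os = h)$incremental$icer_qaly)
  expect_true(all(diff(icers) > 0))
})

test_that("tornado and CEAC plot builders produce valid ggplot objects", {
  cfg <- model_config(horizon_months = 60)
  ow <- one_way_sa(cfg = cfg)
  p1 <- plot_tornado(ow, base_icer = ow$icer_low[1])
  p2 <- plot_ceac(run_psa(n_draws = 20, seed = 2, cfg = cfg))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
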