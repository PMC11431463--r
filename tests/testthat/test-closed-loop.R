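std_program <- function() load_program_fixture("globalfiler_standard")

test_that("termination decisions match a brute-force rule oracle", {
  crit <- termination_criteria(min_detect_cycle = 16,
                               detect_threshold_rfu = 500,
                               min_rate = 5, max_amount_rfu = 5000,
                               max_cycles = 40)
  oracle <- function(cycle, f, rate) {
    if (f > 5000) return("terminated_sufficient")
    if (f < 500 && cycle >= 16) return("terminated_undetectable")
    if (f >= 500 && rate < 5) return("terminated_low_rate")
    "continue"
  }
  grid <- expand.grid(cycle = c(1, 15, 16, 30),
                      fluorescence = c(0, 499, 500, 4999, 5001, 20000),
                      rate = c(0, 4.9, 5, 100))
  for (i in seq_len(nrow(grid))) {
    st <- as.list(grid[i, ])
    expect_identical(check_termination(st, crit),
                     oracle(st$cycle, st$fluorescence, st$rate),
                     info = paste(unlist(st), collapse = "/"))
  }
})

test_that("sufficiency takes precedence over the other rules", {
  crit <- termination_criteria(min_detect_cycle = 1,
                               detect_threshold_rfu = 1e6,
                               min_rate = 1e6, max_amount_rfu = 100)
  # state violates every rule at once; sufficiency must win
  expect_identical(
    check_termination(list(cycle = 50, fluorescence = 200, rate = 0), crit),
    "terminated_sufficient"
  )
})

test_that("the nearest-condition policy picks the best nearby rate", {
  bank <- rule_bank(condition_rfu = c(100, 10000),
                    metric_rate = c(0.2, 0.5),
                    anneal_seconds = c(30, 70))
  # equidistant on log10 scale from 1000: rates 0.2 vs 0.5
  expect_equal(nearest_condition_policy(bank, 1000)$anneal_seconds, 70)
  # exact condition match wins outright
  expect_equal(nearest_condition_policy(bank, 100)$anneal_seconds, 30)
  # one-entry bank returns that entry
  one <- rule_bank(condition_rfu = 500, metric_rate = 0.1,
                   anneal_seconds = 45)
  expect_equal(nearest_condition_policy(one, 123456)$anneal_seconds, 45)
  # ties in rate break by entry order
  tie <- rule_bank(condition_rfu = c(500, 500), metric_rate = c(0.3, 0.3),
                   anneal_seconds = c(10, 90))
  expect_equal(nearest_condition_policy(tie, 500)$anneal_seconds, 10)
  expect_error(nearest_condition_policy(
    rule_bank(condition_rfu = numeric(), metric_rate = numeric(),
              anneal_seconds = numeric()), 100),
    class = "smartpcr_domain_error")
})

test_that("zero template terminates undetectable exactly at min_detect_cycle", {
  dev <- sim_device(sim_params(template_pg = 0), seed = 3)
  rec <- run_closed_loop(dev, std_program(),
                         termination_criteria(min_detect_cycle = 16,
                                              max_cycles = 30))
  expect_identical(rec$status, "terminated_undetectable")
  expect_identical(nrow(rec$record), 16L)
  expect_identical(rec$record$decision[16], "terminated_undetectable")
  expect_true(all(rec$record$decision[1:15] == "continue"))
})

test_that("a saturating run terminates sufficient before the cycle budget", {
  dev <- sim_device(sim_params(template_pg = 5e4), seed = 3)
  rec <- run_closed_loop(dev, std_program(),
                         termination_criteria(max_amount_rfu = 5000,
                                              max_cycles = 30))
  expect_identical(rec$status, "terminated_sufficient")
  expect_lt(nrow(rec$record), 30L)
})

test_that("with criteria disabled a fixed policy runs exactly max_cycles", {
  dev <- sim_device(sim_params(template_pg = 30), seed = 5)
  rec <- run_closed_loop(dev, std_program(), no_termination(max_cycles = 25))
  expect_identical(rec$status, "completed")
  expect_identical(nrow(rec$record), 25L)
  expect_equal(unique(rec$record$anneal_seconds), 90)
})

test_that("the closed loop reproduces the open-loop curve under one seed", {
  p <- sim_params(template_pg = 30, noise_sd = 0.03)
  open <- simulate_qpcr(p, std_program(), seed = 11)
  dev <- sim_device(p, seed = 11)
  rec <- run_closed_loop(dev, std_program(), no_termination(max_cycles = 30))
  expect_equal(rec$record$fluorescence, open$fluorescence[1:30],
               tolerance = 1e-12)
})

test_that("policy outputs are clipped to the declared bounds", {
  bank <- rule_bank(condition_rfu = c(10, 1e4), metric_rate = c(1, 2),
                    anneal_seconds = c(5, 500))
  dev <- sim_device(sim_params(template_pg = 100), seed = 2)
  rec <- run_closed_loop(
    dev, std_program(), no_termination(max_cycles = 24),
    bank = bank,
    param_bounds = tibble::tibble(parameter = "anneal_seconds",
                                  lower = 10, upper = 120)
  )
  after <- rec$record$anneal_seconds[-(1:16)] # post-intervention segments
  expect_true(all(after >= 10 & after <= 120))
  expect_true(any(after != 90)) # the policy actually intervened
})

test_that("a policy-driven loop responds to the rule bank", {
  bank <- rule_bank(condition_rfu = c(50, 5000), metric_rate = c(0.4, 0.9),
                    anneal_seconds = c(30, 70))
  dev <- sim_device(sim_params(template_pg = 1000), seed = 7)
  rec <- run_closed_loop(dev, std_program(), no_termination(max_cycles = 22),
                         bank = bank)
  expect_true(all(rec$record$anneal_seconds[-(1:16)] %in% c(30, 70)))
})

test_that("a device fault aborts with the partial record preserved", {
  dev <- sim_device(sim_params(template_pg = 30), seed = 1,
                    fail_after_cycle = 10)
  rec <- run_closed_loop(dev, std_program(), no_termination(max_cycles = 30))
  expect_identical(rec$status, "device_fault")
  expect_identical(nrow(rec$record), 10L)
})

test_that("the device contract enforces define-before-start and fetch scope", {
  dev <- sim_device(sim_params(template_pg = 30), seed = 1)
  expect_error(device_start(dev), class = "smartpcr_device_error")
  device_define_program(dev, std_program())
  device_start(dev)
  device_run_cycles(dev, 4)
  fetched <- device_fetch(dev)
  expect_identical(nrow(fetched), 4L)
  expect_true(all(fetched$cycle <= 4))
  # loop record bookkeeping: one row per cycle, one terminal status
  rec <- run_closed_loop(sim_device(sim_params(template_pg = 30), seed = 2),
                         std_program(), no_termination(max_cycles = 20))
  expect_identical(nrow(rec$record), 20L)
  expect_identical(sum(rec$record$decision != "continue"), 0L)
  expect_identical(glance(rec)$status, "completed")
})
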