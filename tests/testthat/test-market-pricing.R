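make_pricing <- function(...) {
  pr <- default_config()$pricing
  args <- list(...)
  pr[names(args)] <- args
  pr
}

fixed_prices <- function(p1 = 10, p2 = 10, p3 = 12, p4 = 13, p5 = 14.4) {
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
                 eps = rep(0, 5), period = 1L), class = "period_prices")
}

test_that("price formation follows the cost-anchored markup chain", {
  # weight 1 on the unsafe cost collapses the farmgate price to Cu
  pr <- make_pricing(alpha_price = 1, cost_unsafe = 5, cost_safe = 8,
                     e1 = 0, e2 = 0, price2_premium = 0)
  pp <- draw_period_prices(pr, eps = rep(0, 5))
  expect_equal(pp$p1, 5)
  expect_equal(pp$p2, 5)

  # P3 is a direct markup on P1
  pr <- make_pricing(alpha_price = 0.5, cost_unsafe = 5, cost_safe = 15,
                     e1 = 0, e3 = 0, markup_eta = 0.2)
  pp <- draw_period_prices(pr, eps = rep(0, 5))
  expect_equal(pp$p1, 10)
  expect_equal(pp$p3, 12)

  # identical noise draws give identical prices
  eps <- c(0.3, -0.2, 0.1, 0, -0.5)
  expect_identical(draw_period_prices(pr, eps = eps),
                   draw_period_prices(pr, eps = eps))
})

test_that("price-chain identities hold to machine precision", {
  pr <- default_config()$pricing
  set.seed(9)
  for (i in 1:50) {
    pp <- draw_period_prices(pr, eps = rnorm(5, 0, 1))
    expect_equal(pp$p3, (1 + pr$markup_eta) * pp$p1 + pr$e3, tolerance = 1e-12)
    expect_equal(pp$p4, (1 + pr$markup_beta) * pp$p2 + pr$e4, tolerance = 1e-12)
    expect_equal(pp$p5, (1 + pr$markup_delta) * pp$p3 + pr$e5, tolerance = 1e-12)
    expect_true(all(c(pp$p1, pp$p2, pp$p3, pp$p4, pp$p5) >= 0))
  }
})

test_that("farmer profit matches the three-case profit functions per mode", {
  pr <- make_pricing(cost_unsafe = 5, cost_safe = 8, tech_cost = 1)
  reg <- default_config()$regulation
  reg$fine_farmer <- 6
  pp <- fixed_prices(p1 = 12, p2 = 14)
  # traditional: phi1, phi2, phi3
  expect_equal(farmer_profit("traditional", FALSE, FALSE, 10, pp, pr, reg)$profit, 70)
  expect_equal(farmer_profit("traditional", FALSE, TRUE, 10, pp, pr, reg)$profit, 10)
  expect_equal(farmer_profit("traditional", TRUE, FALSE, 10, pp, pr, reg)$profit, 40)
  # blockchain: pi1, pi2, pi3
  expect_equal(farmer_profit("blockchain", FALSE, FALSE, 10, pp, pr, reg)$profit, 80)
  expect_equal(farmer_profit("blockchain", FALSE, TRUE, 10, pp, pr, reg)$profit, 20)
  expect_equal(farmer_profit("blockchain", TRUE, FALSE, 10, pp, pr, reg)$profit, 50)
  # a safe lot is never fined, even when inspected
  expect_equal(farmer_profit("traditional", TRUE, TRUE, 10, pp, pr, reg)$fine, 0)
  expect_error(farmer_profit("traditional", TRUE, FALSE, -1, pp, pr, reg),
               "negative units")
})

test_that("wholesaler income is a fee for blockchain, a margin for traditional", {
  pr <- make_pricing(logistics_fee = 0.5)
  reg <- default_config()$regulation
  reg$fine_wholesaler <- 6
  pp <- fixed_prices(p1 = 10, p3 = 12)
  bc <- wholesaler_income("blockchain", 10, TRUE, pp, pr, reg)
  expect_equal(bc$profit, 5)
  expect_equal(bc$fine, 0)  # traceback: wholesaler never pays
  expect_equal(wholesaler_income("traditional", 10, FALSE, pp, pr, reg)$profit, 20)
  expect_equal(wholesaler_income("traditional", 10, TRUE, pp, pr, reg)$profit, -40)
})

test_that("retailer income matches the margin functions per mode", {
  pr <- make_pricing(logistics_fee = 0.5, tech_cost = 1)
  reg <- default_config()$regulation
  reg$fine_retailer <- 6
  pp <- fixed_prices(p2 = 14, p3 = 12, p4 = 16, p5 = 14.4)
  bc <- retailer_income("blockchain", 10, TRUE, pp, pr, reg)
  expect_equal(bc$profit, 5)
  expect_equal(bc$fine, 0)
  expect_equal(retailer_income("traditional", 10, FALSE, pp, pr, reg)$profit, 24)
  expect_equal(retailer_income("traditional", 10, TRUE, pp, pr, reg)$profit, -36)
})

test_that("every profit breakdown reconciles with its components", {
  cfg <- default_config()
  pp <- fixed_prices(p1 = 9, p2 = 11, p3 = 10.8, p4 = 14.3, p5 = 12.96)
  cases <- expand.grid(role = c("farmer", "wholesaler", "retailer"),
                       mode = c("traditional", "blockchain"),
                       det = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    b <- switch(cases$role[i],
      farmer = farmer_profit(cases$mode[i], FALSE, cases$det[i], 10, pp,
                             cfg$pricing, cfg$regulation),
      wholesaler = wholesaler_income(cases$mode[i], 10, cases$det[i], pp,
                                     cfg$pricing, cfg$regulation),
      retailer = retailer_income(cases$mode[i], 10, cases$det[i], pp,
                                 cfg$pricing, cfg$regulation))
    expect_equal(b$profit,
                 b$revenue - b$production_cost - b$tech_cost - b$logistics -
                   b$fine, tolerance = 1e-12)
  }
})

test_that("equal production costs and no fines make safe and unsafe equal", {
  pr <- make_pricing(cost_safe = 6, cost_unsafe = 6)
  reg <- default_config()$regulation
  pp <- fixed_prices(p1 = 10)
  expect_equal(farmer_profit("traditional", TRUE, FALSE, 10, pp, pr, reg)$profit,
               farmer_profit("traditional", FALSE, FALSE, 10, pp, pr, reg)$profit)
})

test_that("the standardized benefit gap has the logistic closed form", {
  pr <- make_pricing(cost_safe = 8, cost_unsafe = 5)
  reg <- default_config()$regulation
  reg$sample_prob_farmer <- 0.2
  reg$fine_farmer <- 6
  pp <- fixed_prices(p1 = 12)
  # hand-computed: E_unsafe = 10*(12-5) - 0.2*10*6 = 58, E_safe = 40,
  # k = logistic(18/30)
  k <- expected_benefit_gap("traditional", pp, 10, pr, reg, 30)
  expect_equal(k, plogis(0.6), tolerance = 1e-12)
  expect_equal(k, 0.6456563, tolerance = 1e-6)

  # zero gap (equal costs, no fines) sits exactly at 1/2
  pr0 <- pr; pr0$cost_safe <- 5
  reg0 <- reg; reg0$fine_farmer <- 0
  expect_equal(expected_benefit_gap("traditional", pp, 10, pr0, reg0, 30), 0.5)

  # enormous fines drive the gap toward 0
  regb <- reg; regb$fine_farmer <- 1e9
  expect_lt(expected_benefit_gap("traditional", pp, 10, pr, regb, 30), 1e-6)
})

test_that("the benefit gap decreases in every fine and sampling probability", {
  pr <- default_config()$pricing
  pp <- fixed_prices(p1 = 10, p2 = 12)
  for (mode in c("traditional", "blockchain")) {
    last <- Inf
    for (fine in c(0, 2, 6, 12, 30)) {
      reg <- default_config()$regulation
      reg$fine_farmer <- fine
      k <- expected_benefit_gap(mode, pp, 10, pr, reg, 30)
      expect_lte(k, last)
      last <- k
    }
    last <- Inf
    for (a in c(0, 0.1, 0.3, 0.6, 1)) {
      reg <- default_config()$regulation
      reg$sample_prob_farmer <- a
      if (mode == "blockchain") {
        reg$sample_prob_wholesaler <- a
        reg$sample_prob_retailer <- a
      }
      k <- expected_benefit_gap(mode, pp, 10, pr, reg, 30)
      expect_lte(k, last)
      last <- k
    }
  }
})
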