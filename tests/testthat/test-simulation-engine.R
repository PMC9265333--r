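test_that("initialization assigns modes by deterministic rounding", {
  cfg <- small_config()
  cfg$population$n_farmers <- 100L
  cfg$population$init_blockchain_frac_farmers <- 0.3
  st <- initialize_state(cfg)
  expect_equal(sum(st$farmers$mode == "blockchain"), 30)

  cfg$population$init_blockchain_frac_farmers <- 0
  cfg$population$init_blockchain_frac_wholesalers <- 0
  cfg$population$init_blockchain_frac_retailers <- 0
  st <- initialize_state(cfg)
  expect_true(all(st$farmers$mode == "traditional"))
  expect_true(all(st$wholesalers$mode == "traditional"))
  expect_true(all(st$retailers$mode == "traditional"))

  # honesty drawn inside the configured band, thresholds at their G0
  expect_true(all(st$farmers$honesty >= cfg$population$init_honesty_low &
                    st$farmers$honesty <= cfg$population$init_honesty_high))
  expect_true(all(st$farmers$G == cfg$behavior$G0))
  expect_true(all(st$farmers$wealth == 0))
})

test_that("identical seeds give identical states and identical runs", {
  cfg <- small_config(periods = 15L)
  s1 <- initialize_state(cfg)
  s2 <- initialize_state(cfg)
  expect_identical(s1$farmers, s2$farmers)
  expect_identical(s1$wholesalers, s2$wholesalers)

  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$prices, r2$prices)

  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  r3 <- run_simulation(cfg2)
  expect_false(identical(r1$ledger, r3$ledger))
  expect_identical(names(r1$metrics), names(r3$metrics))
})

test_that("the user's RNG state is not perturbed by a run", {
  set.seed(99)
  before <- .Random.seed
  invisible(run_simulation(small_config(periods = 3L)))
  expect_identical(.Random.seed, before)
})

test_that("zero sampling means no fines and decaying honesty", {
  cfg <- small_config(periods = 25L)
  cfg$regulation$sample_prob_farmer <- 0
  cfg$regulation$sample_prob_wholesaler <- 0
  cfg$regulation$sample_prob_retailer <- 0
  sim <- run_simulation(cfg)
  expect_true(all(sim$metrics$total_fines == 0))
  expect_true(all(is.na(sim$ledger$fine_payer_role)))
  # all honesty follows the decay map: after 25 periods every farmer is
  # below the initial lower bound and heading for minimal/f_plus
  fp <- cfg$behavior$minimal_honesty / cfg$behavior$f_plus
  expect_true(all(sim$final_state$farmers$honesty <
                    cfg$population$init_honesty_low))
  expect_true(all(sim$final_state$farmers$honesty >= fp - 1e-12))
})

test_that("single-mode populations run and emit single-chain metrics", {
  cfg <- small_config(periods = 10L)
  for (frac in c(0, 1)) {
    cfg$population$init_blockchain_frac_farmers <- frac
    cfg$population$init_blockchain_frac_wholesalers <- frac
    cfg$population$init_blockchain_frac_retailers <- frac
    sim <- run_simulation(cfg)
    want <- if (frac == 0) "traditional" else "blockchain"
    expect_setequal(unique(sim$metrics$chain), want)
    expect_equal(nrow(sim$metrics), 10)
    # one absorbed mode is permanent: conversion needs other-mode peers
    expect_true(all(sim$final_state$farmers$mode == want))
    expect_true(all(sim$final_state$wholesalers$mode == want))
    expect_true(all(sim$final_state$retailers$mode == want))
  }
})

test_that("a mode without traders produces no lots and warns once", {
  cfg <- small_config(periods = 5L)
  cfg$population$init_blockchain_frac_wholesalers <- 0
  expect_warning(sim <- run_simulation(cfg), "no blockchain wholesaler")
  expect_setequal(unique(sim$ledger$chain), "traditional")
})

test_that("agent populations are conserved while modes shift", {
  cfg <- small_config(periods = 20L)
  sim <- run_simulation(cfg)
  expect_length(sim$final_state$farmers$id, cfg$population$n_farmers)
  expect_length(sim$final_state$wholesalers$id, cfg$population$n_wholesalers)
  expect_length(sim$final_state$retailers$id, cfg$population$n_retailers)
  m <- sim$metrics
  per_period <- tapply(m$n_farmers, m$period, sum)
  expect_true(all(per_period == cfg$population$n_farmers))
})

test_that("a lattice neighborhood covering the grid reduces to global comparison", {
  cfg <- small_config(periods = 15L)
  cfg$neighborhood_mode <- "grid_radius"
  cfg$grid_radius <- 20L  # covers the whole 7x7-ish lattice of 40 farmers
  wide <- run_simulation(cfg)
  cfg$neighborhood_mode <- "global"
  glob <- run_simulation(cfg)
  expect_identical(wide$ledger, glob$ledger)

  # a tight radius runs cleanly on the same seed
  cfg$neighborhood_mode <- "grid_radius"
  cfg$grid_radius <- 1L
  tight <- run_simulation(cfg)
  expect_equal(nrow(tight$metrics), nrow(glob$metrics))
})

test_that("the ledger-walking oracle reproduces wealth and money balance", {
  cfg <- small_config(periods = 20L)
  sim <- run_simulation(cfg)
  ow <- oracle_wealth(sim)
  expect_equal(sim$final_state$farmers$wealth, ow$farmers, tolerance = 1e-9)
  expect_equal(sim$final_state$wholesalers$wealth, ow$wholesalers,
               tolerance = 1e-9)
  expect_equal(sim$final_state$retailers$wealth, ow$retailers,
               tolerance = 1e-9)
  expect_true(all(abs(oracle_money_balance(sim)) < 1e-9))
})

test_that("blockchain-chain fines are only ever paid by farmers", {
  cfg <- small_config(periods = 30L)
  cfg$regulation$sample_prob_wholesaler <- 0.5
  cfg$regulation$sample_prob_retailer <- 0.5
  sim <- run_simulation(cfg)
  bc <- sim$ledger[sim$ledger$chain == "blockchain", ]
  fined <- bc[!is.na(bc$fine_payer_role), ]
  expect_gt(nrow(fined), 0)
  expect_true(all(fined$fine_payer_role == "farmer"))
  expect_true(all(fined$fine_payer_id == fined$farmer_id))
})

test_that("traditional lots carry the P1/P3/P5 path, blockchain the P2/P4 path", {
  cfg <- small_config(periods = 10L)
  sim <- run_simulation(cfg)
  led <- merge(sim$ledger, sim$prices, by = "period")
  tr <- led[led$chain == "traditional", ]
  bc <- led[led$chain == "blockchain", ]
  expect_equal(tr$price_farmgate, tr$p1)
  expect_equal(tr$price_wholesale, tr$p3)
  expect_equal(tr$price_retail, tr$p5)
  expect_equal(bc$price_farmgate, bc$p2)
  expect_equal(bc$price_retail, bc$p4)
  expect_true(all(is.na(bc$price_wholesale)))
  expect_equal(bc$logistics_fee,
               bc$units * cfg$pricing$logistics_fee)
})
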