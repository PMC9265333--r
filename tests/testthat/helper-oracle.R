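# Test-only oracles, written independently of the engine: they recompute
# agent wealth, per-period money balance and all metrics by walking the lot
# ledger row by row with plain arithmetic.

small_config <- function(periods = 40L, seed = 11L) {
  cfg <- default_config()
  cfg$population$n_farmers <- 40L
  cfg$population$n_wholesalers <- 10L
  cfg$population$n_retailers <- 12L
  cfg$population$periods <- as.integer(periods)
  cfg$seed <- as.integer(seed)
  cfg
}

# per-row profits for each role, from raw ledger columns only
oracle_row_profits <- function(row, cfg) {
  pr <- cfg$pricing
  cost_unit <- if (row$safe) pr$cost_safe else pr$cost_unsafe
  fine_to <- function(role) {
    if (!is.na(row$fine_payer_role) && row$fine_payer_role == role)
      row$fine_total else 0
  }
  if (row$chain == "blockchain") {
    farmer <- row$units * (row$price_farmgate - cost_unit) -
      row$tech_cost_farmer - fine_to("farmer")
    whole <- row$logistics_fee
    retail <- row$units * (row$price_retail - row$price_farmgate) -
      row$tech_cost_retailer - row$logistics_fee - fine_to("retailer")
  } else {
    farmer <- row$units * (row$price_farmgate - cost_unit) - fine_to("farmer")
    whole <- row$units * (row$price_wholesale - row$price_farmgate) -
      fine_to("wholesaler")
    retail <- row$units * (row$price_retail - row$price_wholesale) -
      fine_to("retailer")
  }
  c(farmer = farmer, wholesaler = whole, retailer = retail)
}

oracle_wealth <- function(sim) {
  cfg <- sim$config
  led <- sim$ledger
  fw <- numeric(cfg$population$n_farmers)
  ww <- numeric(cfg$population$n_wholesalers)
  rw <- numeric(cfg$population$n_retailers)
  for (i in seq_len(nrow(led))) {
    row <- led[i, ]
    p <- oracle_row_profits(row, cfg)
    fw[row$farmer_id] <- fw[row$farmer_id] + p[["farmer"]]
    ww[row$wholesaler_id] <- ww[row$wholesaler_id] + p[["wholesaler"]]
    rw[row$retailer_id] <- rw[row$retailer_id] + p[["retailer"]]
  }
  list(farmers = fw, wholesalers = ww, retailers = rw)
}

# per-period money balance: total agent profit must equal consumer payments
# minus production costs, technology costs and fines (logistics fees are a
# transfer from retailers to wholesalers and cancel)
oracle_money_balance <- function(sim) {
  cfg <- sim$config
  led <- sim$ledger
  sapply(sort(unique(led$period)), function(t) {
    sub <- led[led$period == t, ]
    profits <- sum(sapply(seq_len(nrow(sub)),
                          function(i) sum(oracle_row_profits(sub[i, ], cfg))))
    rhs <- sum(sub$revenue_consumer) - sum(sub$production_cost) -
      sum(sub$tech_cost_farmer) - sum(sub$tech_cost_retailer) -
      sum(sub$fine_total)
    profits - rhs
  })
}

oracle_metrics <- function(sim) {
  cfg <- sim$config
  led <- sim$ledger
  w <- cfg$efficiency$weight_qualification
  out <- list()
  for (t in sort(unique(led$period))) {
    for (ch in c("traditional", "blockchain")) {
      sub <- led[led$period == t & led$chain == ch, ]
      if (nrow(sub) == 0) next
      q <- sum(sub$units[sub$safe]) / sum(sub$units)
      input <- sum(sub$production_cost) + sum(sub$tech_cost_farmer) +
        sum(sub$tech_cost_retailer) + sum(sub$logistics_fee)
      io <- sum(sub$revenue_consumer) / input
      out[[length(out) + 1L]] <- data.frame(
        period = t, chain = ch, qualification_rate = q, io_ratio = io,
        circulation_efficiency = w * q + (1 - w) * io / (1 + io))
    }
  }
  do.call(rbind, out)
}
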