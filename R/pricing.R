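#' Realize the five chain prices for one period
#'
#' The two farmgate prices are cost-anchored:
#' `P1 = alpha*Cu + (1-alpha)*Cs + eps1 + e1` and
#' `P2 = alpha*Cu + (1-alpha)*Cs + eps2 + e2 + price2_premium`, where the
#' premium reflects the traceability guarantee blockchain farmers sell with
#' the product. Downstream prices are markups on the upstream ones:
#' `P3 = (1+eta)*P1 + e3` (wholesale), `P4 = (1+beta)*P2 + e4` (blockchain
#' retail) and `P5 = (1+delta)*P3 + e5` (traditional retail). Each `eps` is
#' an independent `N(eps_mu, eps_sigma^2)` draw; realized prices are floored
#' at zero.
#'
#' @param pricing the `pricing` component of an [default_config()] list.
#' @param period period index stored on the result.
#' @param eps optional numeric(5) of noise draws; by default drawn from the
#'   session RNG (the engine supplies draws from its price stream).
#' @return a `period_prices` list with fields `p1..p5`, `eps` (length 5) and
#'   `period`.
#' @examples
#' pr <- default_config()$pricing
#' draw_period_prices(pr, period = 1, eps = rep(0, 5))
#' @export
draw_period_prices <- function(pricing, period = 0L, eps = NULL) {
  if (is.null(eps)) {
    eps <- stats::rnorm(5, pricing$eps_mu, pricing$eps_sigma)
  }
  stopifnot(length(eps) == 5)
  base <- pricing$alpha_price * pricing$cost_unsafe +
    (1 - pricing$alpha_price) * pricing$cost_safe
  p1 <- base + eps[1] + pricing$e1
  p2 <- base + eps[2] + pricing$e2 + pricing$price2_premium
  p1 <- max(0, p1)
  p2 <- max(0, p2)
  p3 <- max(0, (1 + pricing$markup_eta) * p1 + pricing$e3)
  p4 <- max(0, (1 + pricing$markup_beta) * p2 + pricing$e4)
  p5 <- max(0, (1 + pricing$markup_delta) * p3 + pricing$e5)
  structure(
    list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
         eps = eps, period = as.integer(period)),
    class = "period_prices"
  )
}

#' @export
print.period_prices <- function(x, ...) {
  cat(sprintf("<period_prices t=%d>  P1=%.3f P2=%.3f P3=%.3f P4=%.3f P5=%.3f\n",
              x$period, x$p1, x$p2, x$p3, x$p4, x$p5))
  invisible(x)
}

new_breakdown <- function(role, revenue, production_cost = 0, tech_cost = 0,
                          logistics = 0, fine = 0) {
  structure(
    list(role = role, revenue = revenue, production_cost = production_cost,
         tech_cost = tech_cost, logistics = logistics, fine = fine,
         profit = revenue - production_cost - tech_cost - logistics - fine),
    class = "profit_breakdown"
  )
}

#' Per-period profit of one farmer's lot
#'
#' Traditional farmers realize one of three profits for a lot of `s` units:
#' `s*(P1-Cu)` (unsafe, not caught), `s*(P1-Cu-B1)` (unsafe, caught) or
#' `s*(P1-Cs)` (safe). Blockchain farmers sell at `P2` and additionally bear
#' the per-unit technology cost `Ct`: `s*(P2-Cu-Ct)`, `s*(P2-Cu-Ct-B1)`,
#' `s*(P2-Cs-Ct)`. A safe lot is never fined, whether inspected or not.
#'
#' @param mode `"traditional"` or `"blockchain"`.
#' @param safe logical, was the lot produced safely.
#' @param detected logical, was the lot detected unsafe by the regulator
#'   (ignored for safe lots).
#' @param s units in the lot.
#' @param prices a `period_prices` object.
#' @param pricing,regulation components of a configuration list.
#' @return a `profit_breakdown` with fields `revenue`, `production_cost`,
#'   `tech_cost`, `logistics`, `fine`, `profit` satisfying
#'   `profit = revenue - production_cost - tech_cost - logistics - fine`.
#' @export
farmer_profit <- function(mode, safe, detected, s, prices, pricing, regulation) {
  if (s < 0) stop("negative units", call. = FALSE)
  fined <- !safe && detected
  unit_cost <- if (safe) pricing$cost_safe else pricing$cost_unsafe
  if (mode == "blockchain") {
    new_breakdown(
      role = "farmer_blockchain",
      revenue = s * prices$p2,
      production_cost = s * unit_cost,
      tech_cost = s * pricing$tech_cost,
      fine = if (fined) s * regulation$fine_farmer else 0
    )
  } else {
    new_breakdown(
      role = "farmer_traditional",
      revenue = s * prices$p1,
      production_cost = s * unit_cost,
      fine = if (fined) s * regulation$fine_farmer else 0
    )
  }
}

#' Per-lot income of a wholesaler
#'
#' A blockchain wholesaler is a logistics provider: it earns the fixed fee
#' `logistics_fee` per unit and is never fined (unsafe blockchain lots are
#' traced back to the producing farmer). A traditional wholesaler earns the
#' margin `r1 = P3 - P1` per unit on a lot that is untested or passes
#' inspection, and `r2 = P3 - P1 - B2` when the lot is detected unsafe while
#' in its hands.
#'
#' @inheritParams farmer_profit
#' @param lot_units units handled.
#' @param detected_unsafe logical, was the lot detected unsafe at this node.
#' @return a `profit_breakdown`.
#' @export
wholesaler_income <- function(mode, lot_units, detected_unsafe, prices,
                              pricing, regulation) {
  if (lot_units < 0) stop("negative units", call. = FALSE)
  if (mode == "blockchain") {
    new_breakdown("wholesaler_blockchain",
                  revenue = lot_units * pricing$logistics_fee)
  } else {
    new_breakdown(
      "wholesaler_traditional",
      revenue = lot_units * prices$p3,
      production_cost = lot_units * prices$p1,  # acquisition cost
      fine = if (detected_unsafe) lot_units * regulation$fine_wholesaler else 0
    )
  }
}

#' Per-lot income of a retailer
#'
#' A blockchain retailer buys directly from the farmer at `P2`, pays the
#' logistics fee and the per-unit technology cost, and sells at `P4`:
#' margin `y1 = P4 - P2 - theta - Ct` per unit; it is never fined (traceback
#' fines the farmer). A traditional retailer earns `y2 = P5 - P3`, or
#' `y3 = P5 - P3 - B3` when the lot is detected unsafe at the shelf.
#'
#' @inheritParams wholesaler_income
#' @return a `profit_breakdown`.
#' @export
retailer_income <- function(mode, lot_units, detected_unsafe, prices,
                            pricing, regulation) {
  if (lot_units < 0) stop("negative units", call. = FALSE)
  if (mode == "blockchain") {
    new_breakdown(
      "retailer_blockchain",
      revenue = lot_units * prices$p4,
      production_cost = lot_units * prices$p2,  # acquisition cost
      tech_cost = lot_units * pricing$tech_cost,
      logistics = lot_units * pricing$logistics_fee
    )
  } else {
    new_breakdown(
      "retailer_traditional",
      revenue = lot_units * prices$p5,
      production_cost = lot_units * prices$p3,  # acquisition cost
      fine = if (detected_unsafe) lot_units * regulation$fine_retailer else 0
    )
  }
}

#' Standardized expected-benefit gap of unsafe production
#'
#' The raw gap is `Delta = E[profit | unsafe] - E[profit | safe]` for a lot
#' of `s` units at the current prices, where the expected fine on an unsafe
#' lot uses the probability that the lot is detected anywhere it can be
#' fined: `a1*sensitivity` for a traditional farmer (downstream detections
#' fine the trader holding the lot, not the farmer) and
#' `(1 - (1-a1)(1-a2)(1-a3)) * sensitivity` for a blockchain farmer, whose
#' lot is traced back from any sampled node. The gap is standardized into
#' (0,1) with a logistic map, `k = plogis(Delta / ki_scale)`, so `k = 0.5`
#' exactly when safe and unsafe production break even, and larger unsafe
#' advantage gives larger `k`.
#'
#' @inheritParams farmer_profit
#' @param ki_scale currency scale of the logistic standardization.
#' @return the standardized gap `k` in (0,1).
#' @examples
#' cfg <- default_config()
#' pp <- draw_period_prices(cfg$pricing, eps = rep(0, 5))
#' expected_benefit_gap("traditional", pp, 10, cfg$pricing, cfg$regulation, 30)
#' @export
expected_benefit_gap <- function(mode, prices, s, pricing, regulation,
                                 ki_scale) {
  stopifnot(ki_scale > 0)
  sens <- regulation$detection_sensitivity
  if (mode == "blockchain") {
    p_det <- (1 - (1 - regulation$sample_prob_farmer) *
                (1 - regulation$sample_prob_wholesaler) *
                (1 - regulation$sample_prob_retailer)) * sens
    price <- prices$p2
    tech <- pricing$tech_cost
  } else {
    p_det <- regulation$sample_prob_farmer * sens
    price <- prices$p1
    tech <- 0
  }
  e_unsafe <- s * (price - pricing$cost_unsafe - tech) -
    p_det * s * regulation$fine_farmer
  e_safe <- s * (price - pricing$cost_safe - tech)
  delta <- e_unsafe - e_safe
  stats::plogis(delta / ki_scale)
}
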