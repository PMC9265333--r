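#' Default simulation configuration
#'
#' Returns the package's reference calibration as a nested list of class
#' `agrichain_config`. Every constant of the model is held here and can be
#' overridden through [load_config()] or by editing the returned list (the
#' result must still pass [validate_config()]).
#'
#' The calibration is chosen so that (i) every structural constraint of the
#' model holds (`cost_safe > cost_unsafe`, `f_minus > f_plus`, the threshold
#' adjustment ordering `v2_minus > v1_minus > v1_plus > v2_plus`, the
#' blockchain farmgate price exceeding the traditional one), and (ii) the
#' expected per-period payoff of the blockchain mode is comparable to the
#' traditional mode for each role at the default sampling intensity, so that
#' neither chain is drained by conversion. The margin-parity algebra behind
#' the price and fee defaults is worked through in the methods vignette.
#'
#' @section Components:
#' \describe{
#'   \item{population}{agent counts, units per farmer `s`, initial blockchain
#'     adoption fractions, initial honesty range, number of periods.}
#'   \item{pricing}{price-formation constants: cost weights `alpha_price`,
#'     unit costs `cost_safe`/`cost_unsafe`, per-price market effects
#'     `e1..e5`, markups `markup_eta`/`markup_beta`/`markup_delta`, price
#'     noise `eps_mu`/`eps_sigma`, blockchain farmgate premium
#'     `price2_premium`, logistics fee `logistics_fee`, per-unit blockchain
#'     technology cost `tech_cost`.}
#'   \item{behavior}{honesty impact factors `f_plus`/`f_minus` and floor
#'     increment `minimal_honesty`; decision weight `alpha_decision`;
#'     conversion weight `alpha_convert`; benefit-gap scale `ki_scale`;
#'     initial conversion thresholds `G0` (farmers), `G1_0` (wholesalers),
#'     `G2_0` (retailers); threshold adjustment rates `v1_plus`, `v1_minus`,
#'     `v2_plus`, `v2_minus`; `decision_direction` and
#'     `retailer_rule_direction` flags (`"semantic"` or `"literal"`).}
#'   \item{regulation}{per-role sampling probabilities `a1..a3` and per-unit
#'     fines `B1..B3`; `detection_sensitivity`.}
#'   \item{efficiency}{qualification-rate weight `weight_qualification`,
#'     input-output normalization flag, trailing stabilization window.}
#' }
#'
#' @return an `agrichain_config` list.
#' @examples
#' cfg <- default_config()
#' validate_config(cfg)  # character(0)
#' @export
default_config <- function() {
  cfg <- list(
    population = list(
      n_farmers = 100L,
      n_wholesalers = 20L,
      n_retailers = 30L,
      units_per_farmer = 10L,
      init_blockchain_frac_farmers = 0.3,
      init_blockchain_frac_wholesalers = 0.3,
      init_blockchain_frac_retailers = 0.3,
      init_honesty_low = 0.4,
      init_honesty_high = 0.6,
      periods = 120L
    ),
    pricing = list(
      alpha_price = 0.5,
      cost_safe = 8,
      cost_unsafe = 5,
      eps_mu = 0,
      eps_sigma = 1,
      e1 = 2, e2 = 0, e3 = 0, e4 = 0, e5 = 0,
      markup_eta = 0.2,
      markup_beta = 0.3,
      markup_delta = 0.16,
      logistics_fee = 1.2,
      tech_cost = 0.5,
      price2_premium = 3.5
    ),
    behavior = list(
      f_plus = 0.05,
      f_minus = 0.2,
      minimal_honesty = 0.005,
      alpha_decision = 0.5,
      alpha_convert = 0.5,
      ki_scale = 30,
      G0 = 0.99,
      G1_0 = 0.99,
      G2_0 = 0.99,
      v1_plus = 0.0002,
      v1_minus = 0.0003,
      v2_plus = 0.0001,
      v2_minus = 0.0006,
      decision_direction = "semantic",
      retailer_rule_direction = "semantic"
    ),
    regulation = list(
      sample_prob_farmer = 0.2,
      sample_prob_wholesaler = 0.2,
      sample_prob_retailer = 0.2,
      fine_farmer = 6,
      fine_wholesaler = 6,
      fine_retailer = 6,
      detection_sensitivity = 1
    ),
    efficiency = list(
      weight_qualification = 0.5,
      io_normalization = "ratio_over_one_plus_ratio",
      stabilization_window = 30L
    ),
    seed = 42L,
    neighborhood_mode = "global",
    grid_radius = 1L
  )
  class(cfg) <- "agrichain_config"
  cfg
}

# field -> predicate table used by validate_config; each rule is checked with
# fields already coerced to numeric where relevant
.prop01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the model parameterization and
#' returns the violations as data, not errors: an empty character vector
#' means the configuration is valid.
#'
#' @param cfg an `agrichain_config` list (see [default_config()]).
#' @return character vector of violation messages, each naming the field and
#'   the rule it breaks; `character(0)` if valid.
#' @examples
#' cfg <- default_config()
#' cfg$behavior$f_plus <- 0.9
#' validate_config(cfg)  # names the f_minus > f_plus rule
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  p <- cfg$population
  for (f in c("n_farmers", "n_wholesalers", "n_retailers",
              "units_per_farmer", "periods")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0 || p[[f]] != floor(p[[f]]))
      add(sprintf("population$%s: must be a non-negative integer count", f))
  }
  for (f in c("init_blockchain_frac_farmers", "init_blockchain_frac_wholesalers",
              "init_blockchain_frac_retailers", "init_honesty_low",
              "init_honesty_high")) {
    if (!.prop01(p[[f]]))
      add(sprintf("population$%s: must be a proportion in [0,1]", f))
  }
  if (.prop01(p$init_honesty_low) && .prop01(p$init_honesty_high) &&
      p$init_honesty_low > p$init_honesty_high)
    add("population$init_honesty_low: must satisfy init_honesty_low <= init_honesty_high")

  pr <- cfg$pricing
  if (!isTRUE(pr$cost_safe > pr$cost_unsafe))
    add("pricing$cost_safe: must satisfy cost_safe > cost_unsafe")
  if (!isTRUE(pr$cost_unsafe > 0))
    add("pricing$cost_unsafe: must satisfy cost_unsafe > 0")
  if (!(is.numeric(pr$alpha_price) && pr$alpha_price > 0 && pr$alpha_price < 1))
    add("pricing$alpha_price: must lie in (0,1)")
  for (f in c("markup_eta", "markup_beta", "markup_delta")) {
    if (!(is.numeric(pr[[f]]) && pr[[f]] > 0 && pr[[f]] < 1))
      add(sprintf("pricing$%s: markup must lie in (0,1)", f))
  }
  if (!isTRUE(pr$eps_sigma >= 0))
    add("pricing$eps_sigma: must satisfy eps_sigma >= 0")
  if (!isTRUE(pr$logistics_fee >= 0))
    add("pricing$logistics_fee: must satisfy logistics_fee >= 0")
  if (!isTRUE(pr$tech_cost >= 0))
    add("pricing$tech_cost: must satisfy tech_cost >= 0")

  b <- cfg$behavior
  if (!isTRUE(b$f_minus > b$f_plus))
    add("behavior$f_minus: must satisfy f_minus > f_plus")
  for (f in c("f_plus", "f_minus", "v1_plus", "v1_minus", "v2_plus", "v2_minus")) {
    if (!(is.numeric(b[[f]]) && b[[f]] > 0 && b[[f]] < 1))
      add(sprintf("behavior$%s: rate must lie in (0,1)", f))
  }
  if (!isTRUE(b$v2_minus > b$v1_minus && b$v1_minus > b$v1_plus &&
              b$v1_plus > b$v2_plus))
    add("behavior$v2_minus: must satisfy v2_minus > v1_minus > v1_plus > v2_plus")
  if (!isTRUE(b$minimal_honesty <= b$f_plus))
    add("behavior$minimal_honesty: must satisfy minimal_honesty <= f_plus (keeps honesty <= 1)")
  for (f in c("alpha_decision", "alpha_convert")) {
    if (!(is.numeric(b[[f]]) && b[[f]] > 0 && b[[f]] < 1))
      add(sprintf("behavior$%s: weight must lie in (0,1)", f))
  }
  if (!isTRUE(b$ki_scale > 0))
    add("behavior$ki_scale: must satisfy ki_scale > 0")
  for (f in c("G0", "G1_0", "G2_0")) {
    if (!.prop01(b[[f]]))
      add(sprintf("behavior$%s: threshold must lie in [0,1]", f))
  }
  if (!b$decision_direction %in% c("semantic", "literal"))
    add("behavior$decision_direction: must be 'semantic' or 'literal'")
  if (!b$retailer_rule_direction %in% c("semantic", "literal"))
    add("behavior$retailer_rule_direction: must be 'semantic' or 'literal'")

  r <- cfg$regulation
  for (f in c("sample_prob_farmer", "sample_prob_wholesaler",
              "sample_prob_retailer", "detection_sensitivity")) {
    if (!.prop01(r[[f]]))
      add(sprintf("regulation$%s: probability must lie in [0,1]", f))
  }
  for (f in c("fine_farmer", "fine_wholesaler", "fine_retailer")) {
    if (!isTRUE(r[[f]] >= 0))
      add(sprintf("regulation$%s: fine must be >= 0", f))
  }

  e <- cfg$efficiency
  if (!.prop01(e$weight_qualification))
    add("efficiency$weight_qualification: weight must lie in [0,1]")
  if (!e$io_normalization %in% c("ratio_over_one_plus_ratio", "minmax_over_run"))
    add("efficiency$io_normalization: unknown normalization flag")
  if (!isTRUE(e$stabilization_window >= 1))
    add("efficiency$stabilization_window: window must be >= 1")

  if (!(is.numeric(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed)))
    add("seed: must be a single integer")
  if (!cfg$neighborhood_mode %in% c("global", "grid_radius"))
    add("neighborhood_mode: must be 'global' or 'grid_radius'")
  if (!(is.numeric(cfg$grid_radius) && length(cfg$grid_radius) == 1 &&
        !is.na(cfg$grid_radius) && cfg$grid_radius >= 1 &&
        cfg$grid_radius == floor(cfg$grid_radius)))
    add("grid_radius: must be a positive integer")

  v
}

assert_valid_config <- function(cfg) {
  v <- validate_config(cfg)
  if (length(v)) {
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' File values override the defaults of [default_config()]; keys are matched
#' strictly, so an unknown or misspelled key is an error rather than a
#' silently ignored setting. An empty file yields the default configuration.
#'
#' @param path path to a YAML file whose structure mirrors
#'   [default_config()] (top-level sections `population`, `pricing`,
#'   `behavior`, `regulation`, `efficiency`, plus scalars `seed`,
#'   `neighborhood_mode`, `grid_radius`). Any subset of keys may be given.
#' @return validated `agrichain_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("seed: 7", f)
#' load_config(f)$seed
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(raw)) return(cfg)
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  cfg <- merge_config(cfg, raw, prefix = "")
  class(cfg) <- "agrichain_config"
  assert_valid_config(cfg)
  cfg
}

merge_config <- function(base, override, prefix) {
  for (key in names(override)) {
    full <- if (nzchar(prefix)) paste0(prefix, "$", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]])) {
      if (!is.list(override[[key]]))
        stop("configuration key ", full, " must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Write a configuration to a YAML file
#'
#' Serializes the full configuration; [load_config()] on the result
#' reproduces it exactly (round-trip identity).
#'
#' @param cfg an `agrichain_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @export
print.agrichain_config <- function(x, ...) {
  cat("<agrichain_config>\n")
  cat(sprintf("  farmers %d (s=%d units), wholesalers %d, retailers %d, periods %d\n",
              x$population$n_farmers, x$population$units_per_farmer,
              x$population$n_wholesalers, x$population$n_retailers,
              x$population$periods))
  cat(sprintf("  sampling a1/a2/a3 = %.2f/%.2f/%.2f, fines B1/B2/B3 = %g/%g/%g\n",
              x$regulation$sample_prob_farmer, x$regulation$sample_prob_wholesaler,
              x$regulation$sample_prob_retailer, x$regulation$fine_farmer,
              x$regulation$fine_wholesaler, x$regulation$fine_retailer))
  cat(sprintf("  seed %d\n", as.integer(x$seed)))
  invisible(x)
}
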