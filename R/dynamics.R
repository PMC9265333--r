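#' Honesty decay for an uninspected farmer
#'
#' A farmer whose chain was not touched by the regulator this period loses
#' honesty by the affine map `h' = (1 - f_plus) * h + minimal_honesty`,
#' clipped to `[0,1]`. Iterated, the map converges geometrically to the
#' floor `minimal_honesty / f_plus`.
#'
#' @param h honesty value(s) in `[0,1]` (vectorized).
#' @param f_plus decay rate in (0,1).
#' @param minimal per-period floor increment (`minimal_honesty`).
#' @return updated honesty, clipped to `[0,1]`.
#' @export
honesty_unsampled <- function(h, f_plus, minimal) {
  pmin(1, pmax(0, (1 - f_plus) * h + minimal))
}

#' Honesty boost for an inspected farmer
#'
#' Inspection (of the farmer, or of any blockchain node handling the
#' farmer's lot) raises honesty by `h' = (1 - f_minus) * h + f_minus`, an
#' affine contraction toward 1.
#'
#' @param h honesty value(s) in `[0,1]` (vectorized).
#' @param f_minus boost rate in (0,1).
#' @return updated honesty in `[0,1]`.
#' @export
honesty_sampled <- function(h, f_minus) {
  pmin(1, pmax(0, (1 - f_minus) * h + f_minus))
}

#' Safe-versus-unsafe production decision
#'
#' The farmer weighs the standardized unsafe-benefit gap `k`, a uniform
#' random shock `rho` and its own honesty. Under the default `"semantic"`
#' direction the lot is safe iff
#' `alpha * k + (1 - alpha) * rho <= honesty`, so a fully honest farmer
#' (honesty 1) always produces safely, a fully dishonest one (honesty 0)
#' never does, and a larger unsafe advantage lowers the safe probability;
#' the closed form is `P(safe) = clamp((honesty - alpha*k) / (1-alpha))`.
#' The `"literal"` direction runs the reversed inequality (safe iff the
#' score exceeds honesty).
#'
#' @param honesty honesty value(s) in `[0,1]` (vectorized).
#' @param k_i standardized benefit gap(s) in (0,1), see
#'   [expected_benefit_gap()].
#' @param alpha decision weight in (0,1).
#' @param rho uniform(0,1) draw(s); defaults to session RNG draws of the
#'   common length.
#' @param direction `"semantic"` (default) or `"literal"`.
#' @return logical vector, `TRUE` = safe.
#' @export
production_decision <- function(honesty, k_i, alpha,
                                rho = stats::runif(max(length(honesty), length(k_i))),
                                direction = "semantic") {
  score <- alpha * k_i + (1 - alpha) * rho
  if (identical(direction, "literal")) score > honesty else score <= honesty
}

#' Chain-switching decision of a farmer
#'
#' A farmer converts to the other mode when
#' `alpha * (peer - own)/peer + (1 - alpha) * p > G`, where `peer` is the
#' mean current profit of the other-mode farmers and `p ~ Uniform(0,1)`.
#' The relative gain is capped at 1: a shortfall larger than the whole
#' reference profit counts as total. When `peer <= 0` the relative-gain term
#' is ill-defined (or sign-flipped) and is set to 0, so conversion then
#' rides on the random term alone. When no other-mode farmers exist (`peer`
#' is `NA`), no conversion is possible.
#'
#' @param own_profit this farmer's current-period profit (vectorized).
#' @param peer_mean_profit mean current profit of the other mode's farmers
#'   (scalar or vector; `NA` = other mode extinct).
#' @param threshold conversion threshold(s) `G` in `[0,1]`.
#' @param alpha conversion weight in (0,1).
#' @param p uniform(0,1) draw(s).
#' @return logical vector, `TRUE` = convert.
#' @export
farmer_conversion <- function(own_profit, peer_mean_profit, threshold, alpha,
                              p = stats::runif(length(own_profit))) {
  n <- max(length(own_profit), length(peer_mean_profit), length(threshold))
  own <- rep_len(own_profit, n)
  peer <- rep_len(peer_mean_profit, n)
  thr <- rep_len(threshold, n)
  p <- rep_len(p, n)
  gain <- ifelse(!is.na(peer) & peer > 0, pmin(1, (peer - own) / peer), 0)
  out <- alpha * gain + (1 - alpha) * p > thr
  out[is.na(peer)] <- FALSE
  out
}

#' Conversion-threshold dynamics of a farmer
#'
#' The resistance-to-conversion threshold `G` reacts to how the farmer's
#' income compares with the other mode's average and to whether a fine was
#' paid this period:
#' high income, not fined: `G' = (1 - v1_plus) * G + v1_plus` (marked rise);
#' low income, not fined: `G' = (1 - v1_minus) * G` (slight fall);
#' high income, fined: `G' = (1 - v2_plus) * G + v2_plus` (slight rise);
#' low income, fined: `G' = (1 - v2_minus) * G` (marked fall).
#' The rates obey `v2_minus > v1_minus > v1_plus > v2_plus`.
#'
#' @param G threshold(s) in `[0,1]` (vectorized).
#' @param income_high logical, own profit exceeds the other mode's average.
#' @param fined logical, a fine was levied on this farmer this period.
#' @param behavior the `behavior` component of a configuration (supplies the
#'   four rates).
#' @return updated threshold(s) in `[0,1]`.
#' @export
update_threshold_G <- function(G, income_high, fined, behavior) {
  n <- max(length(G), length(income_high), length(fined))
  G <- rep_len(G, n)
  income_high <- rep_len(income_high, n)
  fined <- rep_len(fined, n)
  out <- numeric(n)
  hi_un <- income_high & !fined
  lo_un <- !income_high & !fined
  hi_fi <- income_high & fined
  lo_fi <- !income_high & fined
  out[hi_un] <- (1 - behavior$v1_plus) * G[hi_un] + behavior$v1_plus
  out[lo_un] <- (1 - behavior$v1_minus) * G[lo_un]
  out[hi_fi] <- (1 - behavior$v2_plus) * G[hi_fi] + behavior$v2_plus
  out[lo_fi] <- (1 - behavior$v2_minus) * G[lo_fi]
  pmin(1, pmax(0, out))
}

#' Chain-switching decision of a wholesaler or retailer
#'
#' Traders compare per-unit margins. A wholesaler converts when
#' `alpha * (peer - own)/peer + (1 - alpha) * p > G1`. Retailers use the
#' same form under the default `"semantic"` direction; `"literal"` runs the
#' reversed `<` inequality against `G2` instead. The non-positive-peer guard
#' of [farmer_conversion()] applies.
#'
#' @param own_margin trader's current per-unit margin (vectorized).
#' @param peer_mean_margin mean margin of other-mode traders of the same
#'   role (`NA` = other mode extinct).
#' @param threshold conversion threshold `G1` (wholesalers) or `G2`
#'   (retailers).
#' @param alpha conversion weight in (0,1).
#' @param p uniform(0,1) draw(s).
#' @param role `"wholesaler"` or `"retailer"`.
#' @param retailer_direction `"semantic"` (default) or `"literal"`; only
#'   consulted for retailers.
#' @return logical vector, `TRUE` = convert.
#' @export
trader_conversion <- function(own_margin, peer_mean_margin, threshold, alpha,
                              p = stats::runif(length(own_margin)),
                              role = "wholesaler",
                              retailer_direction = "semantic") {
  n <- max(length(own_margin), length(peer_mean_margin), length(threshold))
  own <- rep_len(own_margin, n)
  peer <- rep_len(peer_mean_margin, n)
  thr <- rep_len(threshold, n)
  p <- rep_len(p, n)
  gain <- ifelse(!is.na(peer) & peer > 0, pmin(1, (peer - own) / peer), 0)
  score <- alpha * gain + (1 - alpha) * p
  out <- if (identical(role, "retailer") &&
             identical(retailer_direction, "literal")) {
    score < thr
  } else {
    score > thr
  }
  out[is.na(peer)] <- FALSE
  out
}
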