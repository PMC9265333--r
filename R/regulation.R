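#' Sample nodes of one role for inspection
#'
#' Each node is independently selected with the role's sampling probability;
#' a selected node has every lot currently in its hands inspected this
#' period.
#'
#' @param ids node identifiers.
#' @param sample_prob per-node Bernoulli probability in `[0,1]`.
#' @param u optional uniform(0,1) draws, one per node (defaults to session
#'   RNG; the engine supplies draws from its sampling stream).
#' @return the sampled node ids (possibly empty).
#' @export
sample_nodes <- function(ids, sample_prob, u = stats::runif(length(ids))) {
  stopifnot(sample_prob >= 0, sample_prob <= 1, length(u) == length(ids))
  ids[u < sample_prob]
}

#' Inspect one lot at a sampled node
#'
#' No false positives are modeled: a safe lot is never flagged. An unsafe
#' lot is flagged with probability `sensitivity` (default 1, i.e. certain
#' detection of sampled unsafe product).
#'
#' @param safe logical, the lot's true safety flag.
#' @param sensitivity detection probability in `[0,1]`.
#' @param u uniform(0,1) draw for the sensitivity test.
#' @return logical `detected_unsafe`.
#' @export
inspect_lot <- function(safe, sensitivity = 1, u = stats::runif(1)) {
  !safe && (u < sensitivity)
}

#' Convert detections into fines
#'
#' Detection of an unsafe blockchain lot at any node is traced back through
#' the ledger to the producing farmer, who pays `B1` per unit. Detection of
#' an unsafe traditional lot fines the node holding it: `B1` per unit at the
#' farmer, `B2` at a wholesaler, `B3` at a retailer. A lot is fined at most
#' once per period; when several nodes detect the same lot, the earliest in
#' chain order (farmer, wholesaler, retailer) pays.
#'
#' @param events data.frame of inspection events with columns `lot_id`,
#'   `node_role` (`"farmer"`, `"wholesaler"`, `"retailer"`), `node_id`,
#'   `chain`, `detected_unsafe`.
#' @param lots data.frame ledger with columns `lot_id`, `farmer_id`,
#'   `units`, `chain`.
#' @param regulation the `regulation` component of a configuration.
#' @return data.frame of fine records: `lot_id`, `payer_role`, `payer_id`,
#'   `per_unit_fine`, `units`, `total`, `traced`.
#' @export
assign_fines <- function(events, lots, regulation) {
  empty <- data.frame(lot_id = integer(0), payer_role = character(0),
                      payer_id = integer(0), per_unit_fine = numeric(0),
                      units = numeric(0), total = numeric(0),
                      traced = logical(0), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0) return(empty)
  det <- events[events$detected_unsafe, , drop = FALSE]
  if (nrow(det) == 0) return(empty)
  if (!all(det$lot_id %in% lots$lot_id)) {
    stop("inspection event references unknown lot", call. = FALSE)
  }
  role_rank <- c(farmer = 1L, wholesaler = 2L, retailer = 3L)
  det <- det[order(det$lot_id, role_rank[det$node_role]), , drop = FALSE]
  first <- det[!duplicated(det$lot_id), , drop = FALSE]
  idx <- match(first$lot_id, lots$lot_id)
  units <- lots$units[idx]
  is_bc <- lots$chain[idx] == "blockchain"
  per_unit <- ifelse(is_bc, regulation$fine_farmer,
                     c(farmer = regulation$fine_farmer,
                       wholesaler = regulation$fine_wholesaler,
                       retailer = regulation$fine_retailer)[first$node_role])
  payer_role <- ifelse(is_bc, "farmer", first$node_role)
  payer_id <- ifelse(is_bc, lots$farmer_id[idx],
                     ifelse(first$node_role == "farmer",
                            lots$farmer_id[idx], first$node_id))
  data.frame(
    lot_id = first$lot_id,
    payer_role = payer_role,
    payer_id = as.integer(payer_id),
    per_unit_fine = as.numeric(per_unit),
    units = as.numeric(units),
    total = as.numeric(per_unit) * as.numeric(units),
    traced = is_bc & first$node_role != "farmer",
    stringsAsFactors = FALSE
  )
}
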