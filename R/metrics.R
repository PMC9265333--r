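#' Qualification rate of a set of lots
#'
#' Fraction of circulated units that are safe.
#'
#' @param lots ledger rows (data.frame with `units` and `safe` columns),
#'   typically one chain in one period.
#' @return proportion of safe units; errors on an empty set.
#' @export
qualification_rate <- function(lots) {
  if (is.null(lots) || nrow(lots) == 0) {
    stop("qualification rate undefined for an empty set of lots",
         call. = FALSE)
  }
  sum(lots$units[lots$safe]) / sum(lots$units)
}

#' Input-output ratio of a set of lots
#'
#' Output is total consumer expenditure (units times retail price); input is
#' the total resource cost of circulation: production cost plus technology
#' costs (farmer and retailer sides) plus logistics fees. Fines are
#' transfers to the regulator, not resource costs, and are excluded by
#' default.
#'
#' @param lots ledger rows with columns `revenue_consumer`,
#'   `production_cost`, `tech_cost_farmer`, `tech_cost_retailer`,
#'   `logistics_fee` (and `fine_total` if `include_fines`).
#' @param include_fines logical; add fines to the input side.
#' @return output/input ratio; errors on zero input.
#' @export
io_ratio <- function(lots, include_fines = FALSE) {
  if (is.null(lots) || nrow(lots) == 0) {
    stop("input-output ratio undefined for an empty set of lots",
         call. = FALSE)
  }
  output <- sum(lots$revenue_consumer)
  input <- sum(lots$production_cost) + sum(lots$tech_cost_farmer) +
    sum(lots$tech_cost_retailer) + sum(lots$logistics_fee)
  if (include_fines) input <- input + sum(lots$fine_total)
  if (input <= 0) stop("zero input in input-output ratio", call. = FALSE)
  output / input
}

normalize_io <- function(io, eff) {
  # run-level min-max (the "minmax_over_run" flag) is applied by
  # run_simulation once the whole trajectory is known
  io / (1 + io)
}

#' Circulation efficiency
#'
#' Weighted blend of the qualification rate and the normalized input-output
#' ratio: `CE = w * q + (1 - w) * io/(1 + io)` under the default
#' normalization, which maps any non-negative ratio into `[0,1)`
#' monotonically. `CE` always lies in `[0,1]` and is non-decreasing in both
#' arguments.
#'
#' @param q qualification rate in `[0,1]`.
#' @param io input-output ratio (>= 0).
#' @param eff the `efficiency` component of a configuration
#'   (`weight_qualification`).
#' @return efficiency in `[0,1]`.
#' @examples
#' circulation_efficiency(0.75, 1.8, default_config()$efficiency)
#' @export
circulation_efficiency <- function(q, io, eff) {
  w <- eff$weight_qualification
  w * q + (1 - w) * normalize_io(io, eff)
}

#' Trailing-window stabilized summary of a metrics table
#'
#' Mean of each metric over the last `window` periods of the run, per
#' chain. This is the "stabilized" value read off the late, flat part of a
#' trajectory.
#'
#' @param metrics a metrics data.frame from [run_simulation()].
#' @param window number of trailing periods to average over.
#' @return data.frame with one row per chain present in the window and mean
#'   columns `qualification_rate`, `io_ratio`, `io_normalized`,
#'   `circulation_efficiency`, `total_fines`, plus `n_periods` averaged.
#' @export
stabilized_summary <- function(metrics, window) {
  if (nrow(metrics) == 0) stop("empty metrics table", call. = FALSE)
  last <- max(metrics$period)
  if (last < window) {
    stop("run shorter than the stabilization window", call. = FALSE)
  }
  tail_rows <- metrics[metrics$period > last - window, , drop = FALSE]
  chains <- unique(tail_rows$chain)
  cols <- c("qualification_rate", "io_ratio", "io_normalized",
            "circulation_efficiency", "total_fines")
  out <- do.call(rbind, lapply(chains, function(ch) {
    sub <- tail_rows[tail_rows$chain == ch, , drop = FALSE]
    row <- as.data.frame(as.list(colMeans(sub[cols])))
    cbind(data.frame(chain = ch, stringsAsFactors = FALSE), row,
          data.frame(n_periods = nrow(sub)))
  }))
  rownames(out) <- NULL
  out
}

#' Regulatory-intensity sweep experiment
#'
#' For each sampling probability, sets the three per-role probabilities to
#' that common value and runs `reps` replications; replication `j` uses the
#' same master seed across all probabilities (common random numbers), so
#' contrasts between probabilities are paired within-seed. Stabilized
#' qualification rate and circulation efficiency are summarized per chain.
#'
#' @param cfg base configuration.
#' @param probs sampling probabilities to sweep over.
#' @param reps replications per probability (>= 1).
#' @return an `agrichain_sweep` list: `summary` (one row per probability per
#'   chain: means, dispersions as standard deviations across replications,
#'   `n_replications`) and `detail` (one row per probability per replication
#'   per chain, with the replication seed).
#' @export
regulatory_sweep <- function(cfg, probs = c(0.1, 0.2, 0.3), reps = 30L) {
  stopifnot(reps >= 1)
  detail <- list()
  for (j in seq_len(reps)) {
    seed_j <- as.integer((as.numeric(cfg$seed) + j * 7919) %% 2147483629)
    for (prob in probs) {
      cfg2 <- cfg
      cfg2$seed <- seed_j
      cfg2$regulation$sample_prob_farmer <- prob
      cfg2$regulation$sample_prob_wholesaler <- prob
      cfg2$regulation$sample_prob_retailer <- prob
      sim <- run_simulation(cfg2)
      stab <- stabilized_summary(sim$metrics,
                                 cfg$efficiency$stabilization_window)
      detail[[length(detail) + 1L]] <- data.frame(
        sample_prob = prob, rep = j, seed = seed_j, chain = stab$chain,
        stabilized_qualification_rate = stab$qualification_rate,
        stabilized_circulation_efficiency = stab$circulation_efficiency,
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  keys <- unique(detail[c("sample_prob", "chain")])
  summary <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- detail[detail$sample_prob == keys$sample_prob[i] &
                    detail$chain == keys$chain[i], , drop = FALSE]
    data.frame(
      sample_prob = keys$sample_prob[i], chain = keys$chain[i],
      stabilized_qualification_rate =
        mean(sub$stabilized_qualification_rate),
      stabilized_circulation_efficiency =
        mean(sub$stabilized_circulation_efficiency),
      n_replications = nrow(sub),
      dispersion_qualification =
        if (nrow(sub) > 1) stats::sd(sub$stabilized_qualification_rate) else 0,
      dispersion_efficiency =
        if (nrow(sub) > 1) stats::sd(sub$stabilized_circulation_efficiency) else 0,
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, detail = detail, probs = probs,
                 reps = reps), class = "agrichain_sweep")
}

#' @export
print.agrichain_sweep <- function(x, ...) {
  cat(sprintf("<agrichain_sweep> probs %s, %d replications\n",
              paste(x$probs, collapse = "/"), x$reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

metrics_columns <- c("period", "chain", "n_units", "n_safe_units",
                     "qualification_rate", "io_ratio", "io_normalized",
                     "circulation_efficiency", "total_fines", "n_farmers",
                     "n_wholesalers", "n_retailers")

#' Write run outputs to files
#'
#' Writes the per-period metrics CSV (fixed column order), a JSON run
#' summary (configuration echo, seed, stabilized per-chain values) and
#' optionally the full lot ledger CSV. Identical runs produce byte-identical
#' files.
#'
#' @param sim an `agrichain_sim` from [run_simulation()].
#' @param dir output directory (created if needed).
#' @param ledger also write `ledger.csv`.
#' @return named character vector of the files written, invisibly.
#' @export
write_outputs <- function(sim, dir, ledger = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(metrics = file.path(dir, "metrics.csv"),
             summary = file.path(dir, "summary.json"))
  write_metrics_csv(sim$metrics, files[["metrics"]])
  win <- sim$config$efficiency$stabilization_window
  stab <- if (nrow(sim$metrics) > 0 && max(sim$metrics$period) >= win) {
    stabilized_summary(sim$metrics, win)
  } else NULL
  summary <- list(seed = sim$config$seed,
                  periods = sim$config$population$periods,
                  config = unclass(sim$config),
                  stabilized = stab)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  if (ledger && !is.null(sim$ledger)) {
    files <- c(files, ledger = file.path(dir, "ledger.csv"))
    utils::write.table(sim$ledger, files[["ledger"]], sep = ",",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(files)
}

#' Write a metrics table as CSV
#'
#' @param metrics a metrics data.frame (possibly empty; the header is still
#'   written) with the standard columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  stopifnot(all(metrics_columns %in% names(metrics)))
  utils::write.table(metrics[metrics_columns], path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a metrics CSV
#'
#' @param path path written by [write_metrics_csv()].
#' @return metrics data.frame.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
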