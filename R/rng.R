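#' Named random-number substreams
#'
#' The simulator draws from five independent substreams (prices, decisions,
#' sampling, routing, conversion) plus an initialization stream, all derived
#' deterministically from one master seed. Keeping subsystems on separate
#' streams means that, e.g., changing the regulator's sampling probability
#' consumes draws only from the sampling stream, so the realized price series
#' is unchanged — the common-random-numbers design used by the sweep
#' experiments.
#'
#' @param seed master integer seed.
#' @param names character vector of stream names.
#' @return an environment mapping each name to a stream object.
#' @keywords internal
#' @noRd
make_rng_streams <- function(seed,
                             names = c("init", "prices", "decisions",
                                       "sampling", "routing", "conversion")) {
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    # distinct sub-seed per stream, kept inside 32-bit integer range
    sub <- as.integer((as.numeric(seed) + i * 1000003) %% 2147483629)
    streams[[names[i]]] <- new_stream(sub)
  }
  streams
}

new_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- save_global_seed()
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  s$state <- .GlobalEnv$.Random.seed
  restore_global_seed(old)
  s
}

save_global_seed <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
}

#' Evaluate a drawing function on a stream
#'
#' Swaps the stream's saved generator state into the session, evaluates
#' `fn()`, stores the advanced state back on the stream, and restores the
#' session generator, so package simulations never perturb the user's RNG.
#'
#' @keywords internal
#' @noRd
stream_do <- function(stream, fn) {
  old <- save_global_seed()
  assign(".Random.seed", stream$state, envir = .GlobalEnv)
  on.exit({
    stream$state <- get(".Random.seed", envir = .GlobalEnv)
    restore_global_seed(old)
  })
  fn()
}
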