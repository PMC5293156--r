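#' Run the event-driven crypt simulation
#'
#' Advances a crypt lattice with continuous-time per-cell exponential
#' division clocks. Each division inserts the progeny into one of the three
#' higher sites (stem cells may instead divide horizontally, displacing the
#' nearest stem-cell neighbour into the TA compartment), pushes the target
#' column up by one, and extrudes the top cell, so the lattice is always
#' fully occupied and divisions and extrusions balance exactly. Fate
#' commitment is applied according to `config$commitment_mode`; dispersive
#' migration, clonal synchronization, and the goblet division-rate factor
#' act as configured. Given the same RNG state and config, the trajectory is
#' reproducible bit for bit.
#'
#' @param config A [sim_config()].
#' @param duration Days of recorded dynamics (after `burn_in`, which is
#'   simulated first and discarded from all statistics).
#' @param init Optional `crypt_state` to resume from; when supplied, no
#'   burn-in is run (set `burn_in = 0` behaviour explicitly).
#' @param snapshot_times Times (days, relative to the start of the recorded
#'   window) at which full lattice snapshots are kept. The final state is
#'   always returned.
#' @param record_events Keep a per-division event log (`time`, `row`, `col`,
#'   `target_row`, `target_col`, `clone_id`, `horizontal`).
#' @param check_invariants Re-verify full occupancy, base-row immobility and
#'   the commitment-zone exclusion after every event (slower; used in tests).
#' @return A `crypt_run`: `state` (final `crypt_state`), `entrants` (data
#'   frame of differentiated-compartment entrants: `time`, `fate`,
#'   `clone_id`), `counters` (named numeric: divisions, extrusions,
#'   ta_entries, diff_entries, ...), `departures` (per-row counts of upward
#'   displacements during the recorded window), `obs_time`, `snapshots`,
#'   `events` (or `NULL`), `violations`, and the `config`.
#' @export
run_crypt <- function(config, duration,
                      init = NULL,
                      snapshot_times = numeric(0),
                      record_events = config$record_events,
                      check_invariants = FALSE) {
  stopifnot(inherits(config, "crypt_config"), duration > 0)
  ecfg <- engine_config(config)
  if (is.null(init)) {
    state <- build_lattice(config)
    if (config$burn_in > 0) {
      burn <- .crypt_engine(unclass(state)[1:7], ecfg, config$burn_in,
                            numeric(0), FALSE, FALSE)
      state <- burned_state(burn$state, config)
    }
    if (config$nicd_fraction > 0)
      state <- apply_nicd_mosaic(state, config$nicd_fraction)
  } else {
    stopifnot(inherits(init, "crypt_state"))
    state <- init
  }
  t0 <- state$time
  res <- .crypt_engine(unclass(state)[1:7], ecfg, duration,
                       sort(snapshot_times) + t0, record_events,
                       check_invariants)
  out <- list(
    state = burned_state(res$state, config),
    entrants = res$entrants,
    cz_exits = res$cz_exits,
    counters = res$counters,
    departures = as.numeric(res$departures),
    obs_time = res$obs_time,
    snapshots = res$snapshots,
    events = res$events,
    violations = res$violations,
    record_events = record_events,
    config = config
  )
  class(out) <- "crypt_run"
  out
}

burned_state <- function(raw, config) {
  raw$config <- config
  class(raw) <- "crypt_state"
  raw
}

#' @export
print.crypt_run <- function(x, ...) {
  cat(sprintf("<crypt_run> %.1f d recorded, %d divisions (= %d extrusions)\n",
              x$obs_time, x$counters[["divisions"]],
              x$counters[["extrusions"]]))
  invisible(x)
}

#' Simulate an ensemble of replicate crypts
#'
#' Runs `n_crypts` independent crypts under one configuration; each replicate
#' builds its own lattice (re-drawing the stem-cell count when
#' `sc_count_sd > 0`), discards `config$burn_in` days, and records `duration`
#' days. All replicate-level statistics in the package
#' ([goblet_patch_proportions()], [neighbor_pair_profile()],
#' [dwell_time_profile()], [flux_amplification()]) accept the returned
#' ensemble.
#'
#' @inheritParams run_crypt
#' @param n_crypts Number of replicate crypts.
#' @param seed Optional integer seed set once before the ensemble.
#' @return A `crypt_ensemble`: list of `crypt_run`s with the shared config.
#' @export
simulate_crypts <- function(config, n_crypts, duration = 50,
                            snapshot_times = numeric(0),
                            record_events = config$record_events,
                            check_invariants = FALSE,
                            seed = NULL) {
  stopifnot(inherits(config, "crypt_config"), n_crypts >= 1)
  if (!is.null(seed)) set.seed(seed)
  runs <- vector("list", n_crypts)
  for (i in seq_len(n_crypts))
    runs[[i]] <- run_crypt(config, duration,
                           snapshot_times = snapshot_times,
                           record_events = record_events,
                           check_invariants = check_invariants)
  structure(list(runs = runs, config = config), class = "crypt_ensemble")
}

#' @export
print.crypt_ensemble <- function(x, ...) {
  cat(sprintf("<crypt_ensemble> %d replicate crypts (%s commitment)\n",
              length(x$runs), x$config$commitment_mode))
  invisible(x)
}

#' Draw a progeny's realized cell-cycle period
#'
#' Implements clonal division synchronization: with probability `s` the
#' progeny inherits its parent's realized period; otherwise a fresh period
#' is drawn from the configured lognormal distribution (mean
#' `division_period`, coefficient of variation `period_cv`; a zero CV makes
#' the fresh draw deterministic). `s = 1` makes clones fully synchronous in
#' their rates, `s = 0` fully independent.
#'
#' @param parent_period Parent's realized period (days).
#' @param s Synchronization probability in `[0, 1]`.
#' @param division_period Mean of the period distribution (days).
#' @param period_cv Coefficient of variation of the period distribution.
#' @param n Number of draws.
#' @return Numeric vector of periods (days).
#' @export
draw_division_period <- function(parent_period, s,
                                 division_period = 2.5, period_cv = 0,
                                 n = 1) {
  stopifnot(s >= 0, s <= 1, parent_period > 0)
  inherit <- runif(n) < s
  fresh <- if (period_cv > 0) {
    sdlog <- sqrt(log(1 + period_cv^2))
    rlnorm(n, log(division_period) - sdlog^2 / 2, sdlog)
  } else rep(division_period, n)
  ifelse(inherit, parent_period, fresh)
}
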