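#' Simulation configuration for a crypt lattice
#'
#' Collects and validates every parameter of the crypt simulator. The default
#' values describe the distal-colon crypt geometry used throughout: a
#' cylindrical hexagonal lattice of 22 rows and 16 columns whose base row
#' holds 8 stem cells (SCs) intermingled with 8 immotile deep secretory
#' (niche) cells, 6 rows of transit-amplifying (TA) progenitors, 15 rows of
#' post-mitotic differentiated cells, and a division period of 2.5 days for
#' every cycling cell.
#'
#' @param n_columns Number of lattice columns (circumference of the cylinder).
#' @param n_sc Number of stem cells in the base row.
#' @param n_niche Number of immotile niche cells in the base row. Together
#'   with `n_sc` this must equal `n_columns`.
#' @param n_ta_rows Number of transit-amplifying rows above the SC row.
#' @param n_diff_rows Number of post-mitotic differentiated rows.
#' @param division_period Mean cell-cycle period in days (`Inf` freezes all
#'   dynamics). The division rate is `1 / division_period`.
#' @param p_secretory Probability of the secretory (goblet) fate at the
#'   stochastic commitment step. Ignored in `"cz"` mode, where the secretory
#'   fraction is an emergent property of lateral inhibition.
#' @param commitment_mode `"early"` (fate drawn when a cell enters the bottom
#'   TA row), `"late"` (fate drawn when a cell enters the differentiated
#'   compartment) or `"cz"` (Delta-Notch lateral inhibition confined to the
#'   commitment zone).
#' @param cz_rows Height of the commitment zone: the rows directly above the
#'   SC row in which lateral inhibition operates (`"cz"` mode only).
#' @param cz_update How lateral inhibition is enforced while a cell resides
#'   in the commitment zone. `"maintained"` (default) restores the stable
#'   Delta pattern after every event: adjacent secretory pairs created by
#'   cell movement are resolved and Delta-capable cells whose inhibitor has
#'   left re-adopt the default Delta fate, so the exclusion holds at all
#'   times and fates freeze at zone exit. `"entry"` assigns the fate once,
#'   when the cell enters the zone; `"entry_exit"` additionally re-checks it
#'   at zone exit (the exit check wins on conflict). `"quota"` is a
#'   diagnostic rule that replaces the exclusion by a deterministic 1-in-4
#'   round-robin assignment at zone entry; it isolates the noise added by
#'   clonal amplification above the zone from the noise of the commitment
#'   rule itself.
#' @param cycle_model Distribution of division waiting times. `"cycle"`
#'   (default) schedules each division one realized cell-cycle period after
#'   the previous one (a deterministic 2.5-day cycle when `period_cv = 0`,
#'   with random initial phases), reading "divide once every `division_period`
#'   days" literally and preserving cohort structure. `"exponential"` uses
#'   memoryless clocks at rate `1 / period` (Gillespie-style dynamics).
#' @param mixing Dispersive-migration rate `m` in `[0, 1]`: the per-push
#'   probability that a differentiated secretory cell lets the absorptive
#'   cell pushing past it slip by (so secretory cells lag and clusters break).
#' @param sync Clonal synchronization `s` in `[0, 1]`: the probability that a
#'   newborn TA cell inherits its parent's realized cell-cycle period rather
#'   than drawing a fresh one. Cells produced by stem-cell divisions always
#'   draw fresh periods, so synchronization acts within TA clones rather
#'   than homogenizing the whole crypt.
#' @param period_cv Coefficient of variation of the lognormal cell-cycle
#'   period distribution used when fresh periods are drawn. The default 0
#'   gives every cell the same period (equal division rates); set it to a
#'   positive value (0.3 is used for the synchronization experiments) to give
#'   clones heritable rate variation.
#' @param goblet_division_factor Multiplier in `(0, 1]` on the division rate
#'   of secretory-fate TA cells. Values below 1 make goblet clones terminate
#'   at smaller sizes than enterocyte clones.
#' @param goblet_migration_factor Multiplier in `(0, 1]` on the dispersive
#'   retention probability; the effective per-push lag probability is
#'   `mixing * goblet_migration_factor`.
#' @param sc_count_sd Standard deviation of the per-crypt SC count. With the
#'   default 0 every crypt has exactly `n_sc` stem cells in alternating
#'   columns; with a positive value each crypt draws its SC count from a
#'   rounded normal (clamped to `[2, n_columns - 2]`) and places the SCs in
#'   random columns.
#' @param nicd_fraction Fraction of SC lineages rendered Delta-incapable
#'   (Notch hyperactive): they always adopt the absorptive fate and never
#'   deliver lateral inhibition. Only meaningful in `"cz"` mode.
#' @param sc_horizontal_prob Probability that an SC division is horizontal
#'   (neutral-drift replacement of the nearest SC neighbour, which is then
#'   displaced into the TA compartment) rather than upward into one of the
#'   three higher sites.
#' @param burn_in Days of dynamics discarded before any statistic is sampled.
#'   The default, three whole-crypt turnover times, is computed from the
#'   geometry and division rate.
#' @param record_events If `TRUE`, simulations keep a division-event log.
#' @param track_ta_clones If `TRUE`, every cell entering the bottom TA row
#'   receives a fresh clone identifier, so clones are the progenies of
#'   single first TA progenitors (the clone definition of the
#'   commitment-stage analysis) rather than whole stem-cell lineages.
#'
#' @return A validated list of class `"crypt_config"`.
#' @export
sim_config <- function(n_columns = 16L,
                       n_sc = 8L,
                       n_niche = 8L,
                       n_ta_rows = 6L,
                       n_diff_rows = 15L,
                       division_period = 2.5,
                       p_secretory = 0.25,
                       commitment_mode = c("early", "late", "cz"),
                       cz_rows = 2L,
                       cz_update = c("maintained", "entry", "entry_exit", "quota"),
                       cycle_model = c("cycle", "exponential"),
                       mixing = 0,
                       sync = 0,
                       period_cv = 0,
                       goblet_division_factor = 1,
                       goblet_migration_factor = 1,
                       sc_count_sd = 0,
                       nicd_fraction = 0,
                       sc_horizontal_prob = 0.4,
                       burn_in = NULL,
                       record_events = FALSE,
                       track_ta_clones = FALSE) {
  commitment_mode <- match.arg(commitment_mode)
  cz_update <- match.arg(cz_update)
  cycle_model <- match.arg(cycle_model)
  cfg <- list(
    n_columns = as.integer(n_columns), n_sc = as.integer(n_sc),
    n_niche = as.integer(n_niche), n_ta_rows = as.integer(n_ta_rows),
    n_diff_rows = as.integer(n_diff_rows),
    division_period = as.numeric(division_period),
    p_secretory = as.numeric(p_secretory),
    commitment_mode = commitment_mode, cz_rows = as.integer(cz_rows),
    cz_update = cz_update, cycle_model = cycle_model,
    mixing = as.numeric(mixing), sync = as.numeric(sync),
    period_cv = as.numeric(period_cv),
    goblet_division_factor = as.numeric(goblet_division_factor),
    goblet_migration_factor = as.numeric(goblet_migration_factor),
    sc_count_sd = as.numeric(sc_count_sd),
    nicd_fraction = as.numeric(nicd_fraction),
    sc_horizontal_prob = as.numeric(sc_horizontal_prob),
    burn_in = if (is.null(burn_in)) NULL else as.numeric(burn_in),
    record_events = isTRUE(record_events),
    track_ta_clones = isTRUE(track_ta_clones)
  )
  if (is.null(cfg$burn_in))
    cfg$burn_in <- if (is.finite(cfg$division_period))
      3 * crypt_turnover_time(cfg) else 0
  validate_config(cfg)
  structure(cfg, class = "crypt_config")
}

# mean time for the cell flux to replace every site once, times rows
crypt_turnover_time <- function(cfg) {
  dividers <- cfg$n_sc + cfg$n_ta_rows * cfg$n_columns
  total_rows <- 1 + cfg$n_ta_rows + cfg$n_diff_rows
  per_column_flux <- dividers / cfg$division_period / cfg$n_columns
  total_rows / per_column_flux
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_columns >= 4, cfg$n_sc >= 1, cfg$n_niche >= 0,
    cfg$n_ta_rows >= 0, cfg$n_diff_rows >= 1,
    cfg$division_period > 0, cfg$cz_rows >= 1,
    cfg$sc_horizontal_prob >= 0, cfg$sc_horizontal_prob <= 1,
    cfg$goblet_division_factor > 0, cfg$goblet_division_factor <= 1,
    cfg$goblet_migration_factor > 0, cfg$goblet_migration_factor <= 1,
    cfg$sc_count_sd >= 0, cfg$burn_in >= 0
  )
  if (cfg$n_sc + cfg$n_niche != cfg$n_columns)
    stop("n_sc + n_niche must equal n_columns", call. = FALSE)
  for (p in c("p_secretory", "mixing", "sync", "nicd_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("%s must lie in [0, 1]", p), call. = FALSE)
  if (cfg$commitment_mode == "cz" && cfg$cz_rows > cfg$n_ta_rows)
    stop("cz_rows cannot exceed n_ta_rows", call. = FALSE)
  invisible(cfg)
}

#' @export
print.crypt_config <- function(x, ...) {
  cat("<crypt_config>\n")
  cat(sprintf("  lattice: %d rows x %d columns (%d SC + %d niche, %d TA rows, %d differentiated rows)\n",
              1 + x$n_ta_rows + x$n_diff_rows, x$n_columns,
              x$n_sc, x$n_niche, x$n_ta_rows, x$n_diff_rows))
  cat(sprintf("  division period: %.3g d; commitment: %s", x$division_period,
              x$commitment_mode))
  if (x$commitment_mode == "cz") cat(sprintf(" (%d rows)", x$cz_rows))
  else cat(sprintf(" (p_secretory = %.3g)", x$p_secretory))
  cat("\n")
  cat(sprintf("  mixing = %.3g, sync = %.3g, period_cv = %.3g, goblet factors: division %.3g, migration %.3g\n",
              x$mixing, x$sync, x$period_cv,
              x$goblet_division_factor, x$goblet_migration_factor))
  cat(sprintf("  sc_horizontal_prob = %.3g, sc_count_sd = %.3g, nicd_fraction = %.3g, burn_in = %.3g d\n",
              x$sc_horizontal_prob, x$sc_count_sd, x$nicd_fraction, x$burn_in))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' The plain-text config file holds exactly the fields of [sim_config()];
#' unknown keys are rejected so that typos cannot silently fall back to
#' defaults. Every simulation result carries its config for provenance, and
#' [write_sim_config()] is the inverse of [read_sim_config()].
#'
#' @param path File path.
#' @return For `read_sim_config`, a `crypt_config`; for `write_sim_config`,
#'   `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @param config A `crypt_config`.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "crypt_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# config list in the form the C++ engine expects
engine_config <- function(cfg) {
  list(
    n_ta_rows = cfg$n_ta_rows, cz_rows = cfg$cz_rows,
    cz_continuous = switch(cfg$cz_update, maintained = 1L, entry_exit = 0L, entry = 2L, quota = 3L),
    sched_exponential = as.integer(identical(cfg$cycle_model, "exponential")),
    track_ta_clones = as.integer(cfg$track_ta_clones),
    mode = unname(.MODE[cfg$commitment_mode]),
    p_secretory = cfg$p_secretory, division_period = cfg$division_period,
    period_cv = cfg$period_cv, sync = cfg$sync, mixing = cfg$mixing,
    goblet_division_factor = cfg$goblet_division_factor,
    goblet_migration_factor = cfg$goblet_migration_factor,
    sc_horizontal_prob = cfg$sc_horizontal_prob
  )
}
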