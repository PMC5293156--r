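#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. Used
#' throughout for the inter-crypt variability of goblet-cell proportions.
#'
#' @param x Numeric vector, or a `proportion_sample` from
#'   [goblet_patch_proportions()] / [gen_crypt_proportions()].
#' @return The CV as a single number.
#' @export
cv <- function(x) {
  if (inherits(x, "proportion_sample")) x <- x$proportions
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  sd(x) / m
}

#' Closed-form binomial commitment statistics
#'
#' Under stochastic commitment of `n` progenitors with secretory probability
#' `p`, followed by deterministic `amplification`-fold clonal expansion, the
#' secretory output per commitment round is `a * Binomial(n, p)`:
#' mean `a n p`, SD `a sqrt(n p (1 - p))`, and a CV of
#' `sqrt((1 - p) / (n p))` that the deterministic amplification leaves
#' unchanged. With `n = 8, p = 0.25` this gives `2 +/- 1.22` committed
#' secretory clones, i.e. `20 +/- 12` secretory cells after 10-fold
#' amplification (CV 0.61), whereas 80 independent late deciders give
#' `20 +/- 3.9` (CV 0.19).
#'
#' @param n Number of cells making the stochastic choice.
#' @param p Secretory probability.
#' @param amplification Deterministic clonal amplification factor (>= 1).
#' @return A list with `mean`, `sd` and `cv`.
#' @export
binomial_commitment_stats <- function(n, p, amplification = 1) {
  stopifnot(n >= 1, p >= 0, p <= 1, amplification >= 1)
  m <- amplification * n * p
  s <- amplification * sqrt(n * p * (1 - p))
  list(mean = m, sd = s, cv = if (m > 0) s / m else NaN)
}

#' Per-crypt goblet proportions in differentiated-compartment patches
#'
#' Computes, for each replicate crypt, the goblet (secretory) fraction in a
#' patch of `patch_size` differentiated cells, and returns the vector of
#' proportions whose CV measures inter-crypt variability.
#'
#' Two patch definitions are supported, mirroring the two natural readings
#' of "sampling epithelial patches": `"window"` (default) takes the
#' `patch_size` cells in the lowest differentiated rows of the final
#' lattice, a spatial patch whose composition integrates production over the
#' time those rows took to fill (this is the estimator that is sensitive to
#' dispersive migration); `"entrants"` takes the `patch_size` most recent
#' cells to cross into the differentiated compartment from the event log, a
#' pure production-flux patch.
#'
#' @param x A `crypt_ensemble` or single `crypt_run`.
#' @param patch_size Cells per patch, between 20 and 100.
#' @param method `"window"` or `"entrants"`.
#' @return A `proportion_sample`: list with `proportions` (one per crypt),
#'   `patch_size`, `source = "simulation"`, `method`.
#' @export
goblet_patch_proportions <- function(x, patch_size = 80,
                                     method = c("window", "entrants")) {
  method <- match.arg(method)
  runs <- ensemble_runs(x)
  if (patch_size < 20 || patch_size > 100)
    stop("patch_size must lie in [20, 100]", call. = FALSE)
  props <- vapply(runs, function(run) {
    if (method == "window") {
      st <- run$state
      diff_start <- 2L + run$config$n_ta_rows # 1-based bottom diff row
      fates <- t(st$fate[diff_start:nrow(st$fate), , drop = FALSE])
      # row-major from the compartment bottom: fill whole rows first
      fates <- as.vector(fates)
      if (patch_size > length(fates))
        stop("patch larger than the differentiated compartment", call. = FALSE)
      mean(fates[seq_len(patch_size)] == .FATE[["secretory"]])
    } else {
      ent <- run$entrants
      if (nrow(ent) < patch_size)
        stop("fewer differentiated-compartment entrants than patch_size; ",
             "increase duration", call. = FALSE)
      mean(tail(ent$fate, patch_size) == .FATE[["secretory"]])
    }
  }, numeric(1))
  structure(list(proportions = props, patch_size = patch_size,
                 source = "simulation", method = method),
            class = "proportion_sample")
}

#' Sample epithelial patches of 20-100 cells, one per crypt
#'
#' The patch-sampling procedure used for the headline inter-crypt
#' variability numbers: for each replicate crypt a patch size is drawn
#' uniformly from `sizes`, and a compact (near-square) block of that many
#' differentiated-compartment cells is read out at a random height and a
#' random position around the crypt circumference. Pooling patch sizes
#' mimics sampling epithelial patches of varying extent; compact patches are
#' contiguous pieces of epithelium rather than full rings or full columns.
#'
#' @param x A `crypt_ensemble` or `crypt_run`.
#' @param sizes Integer patch sizes to draw from (cells per patch).
#' @return A `proportion_sample` with one goblet proportion per crypt
#'   (`patch_size` is the mean size drawn).
#' @export
sample_patch_proportions <- function(x, sizes = 20:100) {
  runs <- ensemble_runs(x)
  cfg <- runs[[1]]$config
  n_cols <- cfg$n_columns
  diff_start <- 2L + cfg$n_ta_rows
  n_diff <- cfg$n_diff_rows
  drawn <- sample(sizes, length(runs), replace = TRUE)
  props <- mapply(function(run, n) {
    if (n > n_diff * n_cols)
      stop("patch larger than the differentiated compartment", call. = FALSE)
    w <- max(2L, min(n_cols, as.integer(round(sqrt(n)))))
    h <- as.integer(ceiling(n / w))
    if (h > n_diff) { h <- n_diff; w <- as.integer(ceiling(n / h)) }
    r0 <- diff_start + sample.int(n_diff - h + 1L, 1L) - 1L
    cols <- ((sample.int(n_cols, 1L) + seq_len(w) - 2L) %% n_cols) + 1L
    f <- run$state$fate[r0:(r0 + h - 1L), cols, drop = FALSE]
    mean(as.vector(t(f))[seq_len(n)] == .FATE[["secretory"]])
  }, runs, drawn)
  structure(list(proportions = props, patch_size = mean(drawn),
                 source = "simulation", method = "patch"),
            class = "proportion_sample")
}

#' @export
print.proportion_sample <- function(x, ...) {
  cat(sprintf("<proportion_sample> %d patches of %.0f cells (%s): mean %.3f, CV %.3f\n",
              length(x$proportions), x$patch_size, x$source,
              mean(x$proportions), cv(x)))
  invisible(x)
}

ensemble_runs <- function(x) {
  if (inherits(x, "crypt_ensemble")) x$runs
  else if (inherits(x, "crypt_run")) list(x)
  else stop("expected a crypt_run or crypt_ensemble", call. = FALSE)
}

#' Goblet neighbour-pair profile along the crypt axis
#'
#' For every row above the crypt base, the fraction of goblet cells that
#' have at least one goblet cell among their hexagonal neighbours, averaged
#' over the ensemble and box-smoothed along the axis. A rising profile in
#' the TA rows followed by a decline in the differentiated compartment is
#' the signature of clonal goblet expansion followed by dispersive
#' migration.
#'
#' @param x A `crypt_ensemble`, `crypt_run` or `crypt_state`.
#' @param window Odd smoothing window in rows (centred moving average,
#'   truncated at the edges).
#' @return A tibble with `row_above_base`, `fraction` (smoothed), `raw` and
#'   `se` (standard error over replicate crypts; `NA` for a single state).
#' @export
neighbor_pair_profile <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1", call. = FALSE)
  states <- if (inherits(x, "crypt_state")) list(x)
            else lapply(ensemble_runs(x), `[[`, "state")
  n_rows <- nrow(states[[1]]$fate); n_cols <- ncol(states[[1]]$fate)
  nb_idx <- neighbor_index(n_rows, n_cols)
  per_state <- vapply(states, function(st) {
    sec <- st$fate == .FATE[["secretory"]]
    has_nb <- vapply(seq_along(sec), function(i) {
      sec[i] && any(sec[nb_idx[[i]]])
    }, logical(1))
    dim(has_nb) <- dim(sec)
    vapply(2:n_rows, function(r) {
      n_gob <- sum(sec[r, ])
      if (n_gob == 0) NA_real_ else sum(has_nb[r, ]) / n_gob
    }, numeric(1))
  }, numeric(n_rows - 1L))
  raw <- rowMeans(per_state, na.rm = TRUE)
  se <- apply(per_state, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  tibble::tibble(
    row_above_base = seq_len(n_rows - 1L),
    fraction = box_smooth(raw, window),
    raw = raw,
    se = se
  )
}

# centred moving average with truncated edges
box_smooth <- function(v, window) {
  half <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(v[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

# list of neighbour linear indices per site, row-major (R matrix) layout
neighbor_index <- function(n_rows, n_cols) {
  lapply(seq_len(n_rows * n_cols), function(i) {
    r <- ((i - 1L) %% n_rows) + 1L
    c <- ((i - 1L) %/% n_rows) + 1L
    nb <- hex_neighbors(r, c, n_rows, n_cols)
    nb[, "row"] + (nb[, "col"] - 1L) * n_rows
  })
}

#' Mean dwell time per crypt row
#'
#' Mean residence time of a cell in each row, estimated from the recorded
#' upward-displacement events: a row's mean dwell is the observation time
#' times the number of sites in the row, divided by the number of departures
#' from that row. Dwell times shrink with height because cells higher up
#' have more dividing cells below them (mitotic-pressure acceleration).
#'
#' @param x A `crypt_ensemble` or `crypt_run` simulated with
#'   `record_events = TRUE`.
#' @return A tibble with `row_above_base` (0 = SC row) and
#'   `mean_dwell_days`.
#' @export
dwell_time_profile <- function(x) {
  runs <- ensemble_runs(x)
  if (!all(vapply(runs, function(r) isTRUE(r$record_events), logical(1))))
    stop("dwell times need runs with record_events = TRUE", call. = FALSE)
  dep <- Reduce(`+`, lapply(runs, `[[`, "departures"))
  if (sum(dep) == 0) stop("no events recorded", call. = FALSE)
  total_time <- sum(vapply(runs, `[[`, numeric(1), "obs_time"))
  n_cols <- runs[[1]]$config$n_columns
  tibble::tibble(
    row_above_base = seq_along(dep) - 1L,
    mean_dwell_days = total_time * n_cols / dep
  )
}

#' Percent noise reduction of a variant relative to a baseline
#'
#' `100 * (1 - cv_variant / cv_baseline)`: the percentage by which a
#' homeostatic mechanism reduces the CV of goblet proportions relative to
#' the plain stochastic early-commitment baseline.
#'
#' @param cv_variant CV with the mechanism enabled.
#' @param cv_baseline Baseline CV (> 0).
#' @return Percent reduction (negative if the variant is noisier).
#' @export
noise_reduction <- function(cv_variant, cv_baseline) {
  if (cv_baseline <= 0) stop("baseline CV must be positive", call. = FALSE)
  100 * (1 - cv_variant / cv_baseline)
}

#' Flux amplification between the TA and differentiated compartments
#'
#' Ratio of the number of cells entering the differentiated compartment to
#' the number entering the bottom TA row per unit time. Because every
#' division below the differentiated boundary pushes exactly one cell across
#' it while only stem-cell divisions feed the bottom TA row, this measures
#' the clonal amplification the TA compartment applies to each commitment
#' decision.
#'
#' @param x A `crypt_ensemble` or `crypt_run`.
#' @return A list with `amplification`, `diff_entries`, `ta_entries` and the
#'   independently counted `divisions_below_boundary / sc_divisions` ratio
#'   (`by_division_count`), which must agree.
#' @export
flux_amplification <- function(x) {
  runs <- ensemble_runs(x)
  period <- runs[[1]]$config$division_period
  if (any(vapply(runs, `[[`, numeric(1), "obs_time") < 5 * period))
    stop("need at least 5 division periods of recorded events", call. = FALSE)
  tot <- Reduce(`+`, lapply(runs, `[[`, "counters"))
  if (tot[["ta_entries"]] == 0) stop("no TA entries recorded", call. = FALSE)
  list(
    amplification = tot[["diff_entries"]] / tot[["ta_entries"]],
    diff_entries = unname(tot[["diff_entries"]]),
    ta_entries = unname(tot[["ta_entries"]]),
    by_division_count = tot[["divisions"]] / tot[["sc_divisions"]]
  )
}
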