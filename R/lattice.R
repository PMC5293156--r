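#' Hexagonal neighbourhood on the crypt cylinder
#'
#' The crypt surface is a hexagonal lattice wrapped into a cylinder: columns
#' wrap around, rows do not. The package uses "odd-row right-shifted" offset
#' coordinates throughout: for a cell in row `r` (1-based, row 1 = crypt
#' base) and column `c`, the neighbours are the two lateral cells
#' `(r, c - 1)` and `(r, c + 1)` (columns modulo `n_cols`) plus two diagonal
#' neighbours in each existing adjacent row, at columns `c - 1, c` when
#' `r` is odd and `c, c + 1` when `r` is even. Interior cells therefore have
#' exactly 6 neighbours; cells in the bottom or top row have 4.
#'
#' @param row,col 1-based position.
#' @param n_rows,n_cols Lattice dimensions (defaults: the 22 x 16 crypt).
#' @return A two-column integer matrix of neighbour positions (`row`, `col`).
#' @export
hex_neighbors <- function(row, col, n_rows = 22L, n_cols = 16L) {
  if (row < 1 || row > n_rows || col < 1 || col > n_cols)
    stop("position outside the lattice", call. = FALSE)
  wrapc <- function(c) ((c - 1L) %% n_cols) + 1L
  off <- if ((row - 1L) %% 2L == 0L) -1L else 0L
  out <- rbind(c(row, wrapc(col - 1L)), c(row, wrapc(col + 1L)))
  for (dr in c(-1L, 1L)) {
    rr <- row + dr
    if (rr < 1L || rr > n_rows) next
    out <- rbind(out, c(rr, wrapc(col + off)), c(rr, wrapc(col + off + 1L)))
  }
  colnames(out) <- c("row", "col")
  out
}

#' Positions pushed when a column shifts upward
#'
#' Mitotic pressure is strictly vertical: when a progeny is inserted at a
#' position, every cell above it in the same column moves up one row and the
#' top cell is extruded. This returns the ordered positions above a site.
#'
#' @inheritParams hex_neighbors
#' @return A two-column integer matrix, ordered from `row + 1` to the top.
#' @export
column_above <- function(row, col, n_rows = 22L, n_cols = 16L) {
  if (row < 1 || row > n_rows || col < 1 || col > n_cols)
    stop("position outside the lattice", call. = FALSE)
  if (row == n_rows)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  cbind(row = (row + 1L):n_rows, col = col)
}

#' Build the initial crypt lattice
#'
#' Creates a fully occupied lattice: the base row holds stem cells and
#' immotile niche cells (alternating columns when `sc_count_sd = 0`, random
#' columns otherwise), the TA rows hold uncommitted or placeholder-fated
#' progenitors, and the differentiated rows hold placeholder post-mitotic
#' cells. Placeholder fates are drawn i.i.d. with `p_secretory` (in `"cz"`
#' mode the commitment-zone rows are instead filled by sequential lateral-
#' inhibition exclusion so the zone invariant holds from time zero); the
#' burn-in period replaces all of them with cells produced by the dynamics.
#' Division clocks are initialized from exponential waiting times at the
#' configured rates.
#'
#' @param config A [sim_config()] object.
#' @return A `crypt_state`: integer matrices `cls`, `fate`, `clone_id`,
#'   `delta`, numeric matrices `period`, `next_t`, plus `time` and the
#'   originating `config`.
#' @export
build_lattice <- function(config) {
  stopifnot(inherits(config, "crypt_config"))
  n_rows <- 1L + config$n_ta_rows + config$n_diff_rows
  n_cols <- config$n_columns

  n_sc <- config$n_sc
  if (config$sc_count_sd > 0) {
    n_sc <- as.integer(round(rnorm(1, config$n_sc, config$sc_count_sd)))
    n_sc <- max(2L, min(n_cols - 2L, n_sc))
    sc_cols <- sort(sample.int(n_cols, n_sc))
  } else {
    sc_cols <- seq(1L, by = 2L, length.out = n_sc) # even offset columns
  }

  cls <- matrix(.CLS[["differentiated"]], n_rows, n_cols)
  cls[1, ] <- .CLS[["niche"]]
  cls[1, sc_cols] <- .CLS[["SC"]]
  if (config$n_ta_rows > 0)
    cls[2:(1 + config$n_ta_rows), ] <- .CLS[["progenitor"]]

  fate <- matrix(.FATE[["uncommitted"]], n_rows, n_cols)
  p <- config$p_secretory
  draw <- function(n) commit_stochastic(n, p)
  diff_rows <- (2L + config$n_ta_rows):n_rows
  ta_rows <- if (config$n_ta_rows > 0) 2:(1 + config$n_ta_rows) else integer(0)
  mode <- config$commitment_mode
  fate[diff_rows, ] <- draw(length(diff_rows) * n_cols)
  if (mode == "early") {
    fate[ta_rows, ] <- draw(length(ta_rows) * n_cols)
  } else if (mode == "cz") {
    cz_rows <- 2:(1 + config$cz_rows)
    above_cz <- setdiff(ta_rows, cz_rows)
    if (length(above_cz) > 0) fate[above_cz, ] <- draw(length(above_cz) * n_cols)
    # sequential exclusion fill of the commitment zone, in random order
    sites <- expand.grid(row = cz_rows, col = seq_len(n_cols))
    for (i in sample(nrow(sites))) {
      r <- sites$row[i]; c <- sites$col[i]
      nb <- hex_neighbors(r, c, n_rows, n_cols)
      in_cz <- nb[, "row"] %in% cz_rows
      blocked <- any(fate[nb[in_cz, , drop = FALSE]] == .FATE[["secretory"]])
      fate[r, c] <- .FATE[[if (blocked) "absorptive" else "secretory"]]
    }
  } # late: TA rows stay uncommitted

  storage.mode(cls) <- "integer"
  storage.mode(fate) <- "integer"
  clone_id <- matrix(0L, n_rows, n_cols)
  delta <- matrix(1L, n_rows, n_cols)

  period <- matrix(config$division_period, n_rows, n_cols)
  if (config$period_cv > 0) {
    sdlog <- sqrt(log(1 + config$period_cv^2))
    meanlog <- log(config$division_period) - sdlog^2 / 2
    period[] <- rlnorm(n_rows * n_cols, meanlog, sdlog)
  }

  next_t <- matrix(Inf, n_rows, n_cols)
  gdf <- config$goblet_division_factor
  for (r in seq_len(1 + config$n_ta_rows)) {
    for (c in seq_len(n_cols)) {
      k <- cls[r, c]
      rate <- if (k == .CLS[["SC"]]) 1 / period[r, c]
              else if (k == .CLS[["progenitor"]])
                (if (fate[r, c] == .FATE[["secretory"]]) gdf else 1) / period[r, c]
              else 0
      if (is.finite(rate) && rate > 0)
        next_t[r, c] <- if (identical(config$cycle_model, "exponential"))
          rexp(1) / rate else runif(1) / rate
    }
  }

  structure(list(cls = cls, fate = fate, clone_id = clone_id, delta = delta,
                 period = period, next_t = next_t, time = 0,
                 config = config),
            class = "crypt_state")
}

#' @export
print.crypt_state <- function(x, ...) {
  cat(sprintf("<crypt_state> %d x %d lattice at t = %.2f d\n",
              nrow(x$cls), ncol(x$cls), x$time))
  tab <- table(factor(x$fate, levels = .FATE, labels = names(.FATE)))
  cat("  fates:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a crypt state as a data frame
#'
#' @param x A `crypt_state`.
#' @param row.names,optional,... Ignored (base-generic signature).
#' @return A data frame with one row per lattice site: `row` (1 = crypt
#'   base), `row_above_base` (rows above the SC row), `col`, `cell_class`,
#'   `fate`, `clone_id`.
#' @export
as.data.frame.crypt_state <- function(x, row.names = NULL, optional = FALSE, ...) {
  n_rows <- nrow(x$cls); n_cols <- ncol(x$cls)
  data.frame(
    row = rep(seq_len(n_rows), n_cols),
    row_above_base = rep(seq_len(n_rows) - 1L, n_cols),
    col = rep(seq_len(n_cols), each = n_rows),
    cell_class = names(.CLS)[as.vector(x$cls) + 1L],
    fate = names(.FATE)[as.vector(x$fate) + 1L],
    clone_id = as.vector(x$clone_id)
  )
}

#' Mark Notch-hyperactive (Delta-incapable) stem-cell lineages
#'
#' Emulates mosaic Notch hyperactivation: each stem cell is independently
#' marked with probability `nicd_fraction`. Marked cells and all their future
#' progeny are Delta-incapable: in `"cz"` mode they always adopt the
#' absorptive fate and never laterally inhibit their neighbours. Wild-type
#' lineages keep committing by the commitment-zone rule among the remaining
#' Delta-capable cells.
#'
#' @param state A `crypt_state` (typically after burn-in).
#' @param nicd_fraction Probability in `[0, 1]` that an SC lineage is marked.
#' @return The updated `crypt_state`.
#' @export
apply_nicd_mosaic <- function(state, nicd_fraction) {
  stopifnot(inherits(state, "crypt_state"))
  if (nicd_fraction < 0 || nicd_fraction > 1)
    stop("nicd_fraction must lie in [0, 1]", call. = FALSE)
  sc <- which(state$cls[1, ] == .CLS[["SC"]])
  marked <- sc[runif(length(sc)) < nicd_fraction]
  state$delta[1, marked] <- 0L
  state
}

#' Give every stem cell a distinct clone label
#'
#' Resets all clone identifiers to zero and assigns labels `1, 2, ...` to the
#' stem cells in the base row, so that subsequent dynamics trace the neutral
#' drift and the progeny of each SC.
#'
#' @param state A `crypt_state`.
#' @return The updated `crypt_state`.
#' @export
label_sc_clones <- function(state) {
  stopifnot(inherits(state, "crypt_state"))
  state$clone_id[] <- 0L
  sc <- which(state$cls[1, ] == .CLS[["SC"]])
  state$clone_id[1, sc] <- seq_along(sc)
  state
}
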