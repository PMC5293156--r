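#' Stochastic fate commitment
#'
#' Draws irreversible secretory/absorptive fates for cells crossing a
#' commitment boundary: secretory with probability `p`, absorptive
#' otherwise. This is the rule applied at TA entry under early commitment
#' and at differentiated-compartment entry under late commitment; all
#' subsequent progeny inherit the fate.
#'
#' @param n Number of cells committing.
#' @param p Secretory probability.
#' @return An integer vector of fate codes with levels named by
#'   `c("secretory", "absorptive")` (see [as.data.frame.crypt_state()] for
#'   the code mapping).
#' @export
commit_stochastic <- function(n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  ifelse(runif(n) < p, .FATE[["secretory"]], .FATE[["absorptive"]])
}

#' Commitment-zone lateral-inhibition rule for a single cell
#'
#' Evaluates the Delta-Notch exclusion rule at one lattice position: a
#' Delta-capable cell entering the commitment zone adopts the secretory
#' (Delta) fate if and only if none of its hexagonal neighbours currently
#' residing in the zone holds the secretory fate; otherwise it is
#' Notch-activated and becomes absorptive. Delta-incapable cells (NICD
#' lineages) are always absorptive.
#'
#' @param state A `crypt_state`.
#' @param row,col Position of the entering cell (1-based; the commitment
#'   zone is rows `2 .. 1 + cz_rows`).
#' @return The fate code the cell adopts.
#' @export
commit_cz <- function(state, row, col) {
  stopifnot(inherits(state, "crypt_state"))
  cfg <- state$config
  cz_rows <- 2:(1 + cfg$cz_rows)
  if (!(row %in% cz_rows))
    stop("position is not inside the commitment zone", call. = FALSE)
  if (!state$delta[row, col]) return(.FATE[["absorptive"]])
  nb <- hex_neighbors(row, col, nrow(state$fate), ncol(state$fate))
  in_cz <- nb[, "row"] %in% cz_rows
  blocked <- any(state$fate[nb[in_cz, , drop = FALSE]] == .FATE[["secretory"]])
  .FATE[[if (blocked) "absorptive" else "secretory"]]
}
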