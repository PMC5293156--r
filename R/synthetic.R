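#' Specification for synthetic lineage-tracing and proportion data
#'
#' Describes the statistical structure of the two table types the analysis
#' pipeline consumes: per-clone cell lists (clone table) and per-crypt
#' goblet proportions. Defaults emulate the distal-colon datasets the
#' pipeline was built for: 119 multi-cell clones with a geometric-like size
#' distribution, a 0.24/0.76 goblet/enterocyte cell frequency, and 100
#' crypts of counted cells.
#'
#' @param n_clones Number of clones in a generated clone table.
#' @param clone_sizes Integer support of the clone-size distribution.
#' @param size_weights Unnormalized weights over `clone_sizes` (default: a
#'   geometric decay with ratio 0.72, mean size about 4.3 cells).
#' @param p_secretory Marginal secretory (goblet) frequency.
#' @param commitment_regime `"early"` (one fate per clone), `"late"` (i.i.d.
#'   fates per cell) or `"mixture"` (a clone is early-style with probability
#'   `theta`).
#' @param theta Mixture weight of the early regime.
#' @param chase_days Chase times cycled over the clones.
#' @param lgr5_fraction Fraction of clones given an Lgr5-positive cell (for
#'   exclusion-rule tests).
#' @param n_crypts Number of crypts in a generated proportion table.
#' @param cells_per_crypt Cells counted per crypt.
#' @param overdispersion Beta-binomial intra-crypt correlation `rho` in
#'   `[0, 1)`; 0 gives pure binomial counting noise.
#' @return A validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_clones = 119L,
                       clone_sizes = 2:12,
                       size_weights = 0.72^(0:10),
                       p_secretory = 0.24,
                       commitment_regime = c("early", "late", "mixture"),
                       theta = 0.5,
                       chase_days = c(5, 7, 10, 14),
                       lgr5_fraction = 0,
                       n_crypts = 100L,
                       cells_per_crypt = 80L,
                       overdispersion = 0) {
  commitment_regime <- match.arg(commitment_regime)
  stopifnot(n_clones >= 1, n_crypts >= 1, cells_per_crypt >= 1,
            length(clone_sizes) == length(size_weights),
            all(size_weights >= 0), all(clone_sizes >= 1),
            p_secretory >= 0, p_secretory <= 1,
            theta >= 0, theta <= 1,
            lgr5_fraction >= 0, lgr5_fraction <= 1,
            overdispersion >= 0, overdispersion < 1)
  structure(list(
    n_clones = as.integer(n_clones), clone_sizes = as.integer(clone_sizes),
    size_weights = size_weights / sum(size_weights),
    p_secretory = p_secretory, commitment_regime = commitment_regime,
    theta = theta, chase_days = chase_days, lgr5_fraction = lgr5_fraction,
    n_crypts = as.integer(n_crypts),
    cells_per_crypt = as.integer(cells_per_crypt),
    overdispersion = overdispersion
  ), class = "synth_spec")
}

#' Generate a synthetic clone table
#'
#' Clone sizes are drawn from the spec's size distribution; fates follow the
#' commitment regime (`"early"`: the whole clone inherits one
#' Bernoulli(`p_secretory`) draw; `"late"`: every cell draws independently;
#' `"mixture"`: early-style with probability `theta`). Cells of a clone
#' occupy consecutive crypt rows starting at a chase-dependent height
#' (clones that have been chased longer have migrated further up), and a
#' `lgr5_fraction` of clones keep an Lgr5-positive cell at their base.
#'
#' @param spec A [synth_spec()].
#' @return A clone-table tibble (see [read_clone_table()] for the schema).
#' @export
gen_clone_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_clones
  sizes <- spec$clone_sizes[sample.int(length(spec$clone_sizes), n,
                                       replace = TRUE,
                                       prob = spec$size_weights)]
  chase <- rep_len(spec$chase_days, n)
  mouse <- rep_len(seq_len(8L), n)
  early_style <- switch(spec$commitment_regime,
    early = rep(TRUE, n),
    late = rep(FALSE, n),
    mixture = runif(n) < spec$theta)
  has_lgr5 <- runif(n) < spec$lgr5_fraction
  rows_per_clone <- lapply(seq_len(n), function(i) {
    base <- 1L + rpois(1, 0.9 * chase[i])
    pmin(base + seq_len(sizes[i]) - 1L, 21L)
  })
  cells <- lapply(seq_len(n), function(i) {
    k <- sizes[i]
    sec <- if (early_style[i]) rep(runif(1) < spec$p_secretory, k)
           else runif(k) < spec$p_secretory
    tibble::tibble(
      clone_id = i, mouse_id = mouse[i], chase_days = chase[i],
      row = rows_per_clone[[i]],
      marker = ifelse(sec, "Gob5pos", "Gob5neg"),
      lgr5 = c(has_lgr5[i], rep(FALSE, k - 1L))
    )
  })
  do.call(rbind, cells)
}

#' Generate per-crypt goblet proportions
#'
#' Draws one goblet proportion per crypt from a beta-binomial with mean
#' `p_secretory`, `cells_per_crypt` counted cells and intra-crypt
#' correlation `overdispersion`; zero overdispersion reduces to pure
#' binomial counting noise, for which the CV is
#' `sqrt((1 - p) / (n p))`.
#'
#' @param spec A [synth_spec()].
#' @return A `proportion_sample` with `source = "table"`.
#' @export
gen_crypt_proportions <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_crypts; size <- spec$cells_per_crypt
  p <- spec$p_secretory; rho <- spec$overdispersion
  pr <- if (rho > 0) {
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    rbinom(n, size, rbeta(n, a, b)) / size
  } else {
    rbinom(n, size, p) / size
  }
  structure(list(proportions = pr, patch_size = size, source = "table",
                 method = "generated"),
            class = "proportion_sample")
}

#' Beta-binomial overdispersion matching a target CV
#'
#' Solves for the intra-crypt correlation `rho` that gives a beta-binomial
#' proportion sample the requested coefficient of variation at mean `p` and
#' `n` counted cells. Errors if the target CV is below the binomial floor
#' `sqrt((1 - p) / (n p))`.
#'
#' @param target_cv Desired CV of the per-crypt proportions.
#' @param p Mean proportion.
#' @param n Counted cells per crypt.
#' @return The overdispersion `rho`.
#' @export
overdispersion_for_cv <- function(target_cv, p = 0.25, n = 80) {
  rho <- (target_cv^2 * n * p / (1 - p) - 1) / (n - 1)
  if (rho < 0)
    stop("target CV below the binomial counting floor", call. = FALSE)
  rho
}

#' Generate neutral-drift clone sizes with a known rate
#'
#' Simulates the labelled-clone dynamics on a ring of `n_sc` stem cells
#' explicitly: every cell divides symmetrically at the given rate and
#' replaces one of its two ring neighbours, so a single labelled cell's
#' clone performs neutral drift until loss or fixation. Each simulated clone
#' is observed at one chase time (cycled over `chase_days`), and only
#' surviving clones (size >= 1) are reported, mirroring what lineage tracing
#' observes.
#'
#' @param rate Symmetric replacement rate per stem cell per day.
#' @param n_clones Clones to simulate (before loss).
#' @param chase_days Chase times.
#' @param n_sc Ring size.
#' @return A tibble with `clone_id`, `chase_days`, `size`, carrying the
#'   generating rate as attribute `"true_rate"`.
#' @export
gen_lineage_truth <- function(rate = 0.27, n_clones = 300,
                              chase_days = c(4, 7, 10, 14), n_sc = 8) {
  stopifnot(rate >= 0, n_clones >= 1, n_sc >= 2, all(chase_days > 0))
  chase <- rep_len(chase_days, n_clones)
  sizes <- vapply(seq_len(n_clones), function(i) {
    labelled <- c(TRUE, rep(FALSE, n_sc - 1L))
    t_end <- chase[i]
    t <- 0
    if (rate > 0) repeat {
      t <- t + rexp(1, n_sc * rate)
      if (t > t_end) break
      k <- sum(labelled)
      if (k == 0L || k == n_sc) break # absorbed
      divider <- sample.int(n_sc, 1)
      side <- if (runif(1) < 0.5) 1L else -1L
      replaced <- ((divider - 1L + side) %% n_sc) + 1L
      labelled[replaced] <- labelled[divider]
    }
    sum(labelled)
  }, integer(1))
  keep <- sizes >= 1L
  out <- tibble::tibble(clone_id = seq_len(n_clones)[keep],
                        chase_days = chase[keep], size = sizes[keep])
  attr(out, "true_rate") <- rate
  out
}
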