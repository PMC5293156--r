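#' Read or write a clone table
#'
#' Clone tables are tab-delimited text with one row per traced cell and
#' columns `clone_id`, `mouse_id`, `chase_days`, `row` (crypt rows above the
#' base), `marker` (`"Gob5pos"` for goblet cells, `"Gob5neg"` for
#' enterocytes) and `lgr5` (logical: Lgr5 expression, marking cells still in
#' the stem-cell compartment).
#'
#' @param path File path.
#' @return For `read_clone_table`, a tibble of cells; for
#'   `write_clone_table`, `path`, invisibly.
#' @export
read_clone_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("clone_id", "mouse_id", "chase_days", "row", "marker", "lgr5")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("clone table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$marker), c("Gob5pos", "Gob5neg"))
  if (length(bad) > 0)
    stop("unknown marker values: ", paste(bad, collapse = ", "), call. = FALSE)
  df$lgr5 <- as.logical(df$lgr5)
  tibble::as_tibble(df)
}

#' @param cells A clone-table data frame.
#' @rdname read_clone_table
#' @export
write_clone_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify traced clones as uniform or mixed
#'
#' For the commitment-stage analysis, clones containing any Lgr5-positive
#' cell are excluded (their cells may descend from more than one stem-cell
#' extrusion event); remaining clones are uniform if all cells carry the
#' same differentiation marker, mixed otherwise. The headline statistic is
#' the uniform fraction among multi-cell clones, since single-cell clones
#' are uniform trivially.
#'
#' @param cells A clone table (see [read_clone_table()]).
#' @return A list of class `"clone_classification"`: `clones` (tibble with
#'   `clone_id`, `n_cells`, `height`, `classification`),
#'   `uniform_fraction` (among included multi-cell clones),
#'   `n_multicell`, `n_excluded`.
#' @export
classify_clones <- function(cells) {
  if (nrow(cells) == 0) stop("empty clone table", call. = FALSE)
  by_clone <- split(cells, cells$clone_id)
  clones <- tibble::tibble(
    clone_id = names(by_clone),
    n_cells = vapply(by_clone, nrow, integer(1)),
    height = vapply(by_clone, function(d) max(d$row), numeric(1)),
    classification = vapply(by_clone, function(d) {
      if (any(d$lgr5)) return("excluded")
      m <- unique(d$marker)
      if (length(m) > 1) "mixed"
      else if (m == "Gob5pos") "uniform_secretory"
      else "uniform_absorptive"
    }, character(1))
  )
  multi <- clones[clones$n_cells >= 2 & clones$classification != "excluded", ]
  structure(list(
    clones = clones,
    uniform_fraction = if (nrow(multi) > 0)
      mean(multi$classification != "mixed") else NA_real_,
    n_multicell = nrow(multi),
    n_excluded = sum(clones$classification == "excluded")
  ), class = "clone_classification")
}

#' @export
print.clone_classification <- function(x, ...) {
  cat(sprintf("<clone_classification> %d clones (%d excluded as Lgr5+)\n",
              nrow(x$clones), x$n_excluded))
  cat(sprintf("  uniform fraction among %d multi-cell clones: %.3f\n",
              x$n_multicell, x$uniform_fraction))
  invisible(x)
}

#' Randomization null model for clone uniformity under late commitment
#'
#' Under late commitment each cell of a clone picks its fate independently,
#' so the expected uniform fraction depends only on the clone sizes and the
#' marginal secretory frequency. This generates `n_rand` randomized datasets
#' with the observed clone sizes, assigning each cell the secretory type
#' independently with probability `freq_secretory`, and returns the mean and
#' SD of the uniform fraction across randomizations, plus a one-sided Z-test
#' of an observed fraction against this null (observed > expected, the
#' direction implied by early commitment).
#'
#' @param clone_sizes Integer sizes of the (multi-cell) observed clones; all
#'   must be >= 2.
#' @param observed_uniform_fraction Optional observed uniform fraction to
#'   test.
#' @param freq_secretory Marginal secretory-cell frequency (0.24 in the
#'   distal colon dataset emulated here).
#' @param n_rand Number of randomized datasets.
#' @return A list with `expected_uniform_fraction`, `sd`, `n_rand`, and,
#'   when an observed fraction is supplied, `z` and `p_value`.
#' @export
late_commitment_null <- function(clone_sizes,
                                 observed_uniform_fraction = NULL,
                                 freq_secretory = 0.24,
                                 n_rand = 1e6) {
  clone_sizes <- as.integer(clone_sizes)
  if (any(clone_sizes < 2))
    stop("late-commitment null is defined for multi-cell clones (sizes >= 2)",
         call. = FALSE)
  stopifnot(freq_secretory >= 0, freq_secretory <= 1, n_rand >= 2)
  n_clones <- length(clone_sizes)
  uniform_count <- integer(n_rand)
  for (k in clone_sizes) {
    x <- rbinom(n_rand, k, freq_secretory)
    uniform_count <- uniform_count + (x == 0L | x == k)
  }
  frac <- uniform_count / n_clones
  out <- list(expected_uniform_fraction = mean(frac), sd = sd(frac),
              n_rand = n_rand)
  if (!is.null(observed_uniform_fraction)) {
    out$z <- (observed_uniform_fraction - out$expected_uniform_fraction) / out$sd
    out$p_value <- pnorm(out$z, lower.tail = FALSE)
  }
  out
}

#' Bootstrap standard deviation of the uniform-clone fraction
#'
#' Resamples the clone-level uniformity labels with replacement and returns
#' the SD of the uniform fraction across resamples (the error bars of the
#' clone-uniformity analysis).
#'
#' @param uniform Logical vector: is each clone uniform?
#' @param n_boot Number of bootstrap resamples.
#' @return The bootstrap SD.
#' @export
bootstrap_fraction_sd <- function(uniform, n_boot = 1e4) {
  uniform <- as.logical(uniform)
  n <- length(uniform)
  stopifnot(n >= 1)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  fracs <- colMeans(matrix(uniform[idx], nrow = n))
  sd(fracs)
}

#' Compare a metric between two clone groups
#'
#' Positional metrics (clone height, vertical position) are compared with a
#' Kruskal-Wallis test; clone sizes with a Welch t-test, which tolerates the
#' unequal variances of goblet and enterocyte clone-size distributions.
#'
#' @param groups A named list of two numeric vectors.
#' @param metric `"height"`, `"position"` (rank test) or `"size"` (Welch t).
#' @return A list with `method`, `statistic`, `p_value` and a descriptive
#'   `summary` tibble (mean and SD per group).
#' @export
compare_clone_groups <- function(groups, metric = c("height", "size", "position")) {
  metric <- match.arg(metric)
  stopifnot(is.list(groups), length(groups) == 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  x <- groups[[1]]; y <- groups[[2]]
  if (metric == "size") {
    ht <- t.test(x, y, var.equal = FALSE)
    method <- "Welch t-test"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- kruskal.test(list(x, y))
    method <- "Kruskal-Wallis test"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- c("group1", "group2")
  list(method = method, statistic = statistic, p_value = p,
       summary = tibble::tibble(group = nm,
                                n = c(length(x), length(y)),
                                mean = c(mean(x), mean(y)),
                                sd = c(sd(x), sd(y))))
}

#' Probability that a traced clone is informative about commitment stage
#'
#' A clone whose cells all lie outside the stem-cell compartment can still
#' descend from a stem cell that self-renewed (divided symmetrically) before
#' extrusion; such clones combine several independent compartment exits and
#' are uninformative about commitment stage. This estimates, by Monte Carlo
#' on the stem-cell ring, the probability that a labelled stem cell is
#' displaced out of the compartment before undergoing any symmetric
#' (SC-retaining) division. Because displacement of the labelled cell and
#' its own symmetric division occur at the same rate
#' (`division_rate * sc_horizontal_prob` each), this is a pure competition
#' of event types: the value is close to 1/2 and independent of the division
#' period.
#'
#' @param config A [sim_config()].
#' @param n_rep Monte Carlo replicates.
#' @return Estimated probability.
#' @export
informative_clone_probability <- function(config, n_rep = 4000) {
  stopifnot(inherits(config, "crypt_config"))
  if (config$sc_horizontal_prob <= 0)
    stop("with sc_horizontal_prob = 0 stem cells are never displaced; ",
         "no clone ever leaves the compartment entirely", call. = FALSE)
  n_sc <- config$n_sc
  shp <- config$sc_horizontal_prob
  informative <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    repeat {
      divider <- sample.int(n_sc, 1) # equal rates: uniform divider
      if (runif(1) >= shp) next      # upward division: ring unchanged
      side <- if (runif(1) < 0.5) 1L else -1L
      displaced <- ((divider - 1L + side) %% n_sc) + 1L
      # founder sits at position 1
      if (divider == 1L) { informative[i] <- FALSE; break }
      if (displaced == 1L) { informative[i] <- TRUE; break }
    }
  }
  mean(informative)
}

#' Infer the stem-cell replacement rate from clone sizes over time
#'
#' Fits a one-dimensional neutral-drift model on a ring of `n_sc` stem
#' cells: a labelled contiguous clone of size `k` gains or loses one cell at
#' rate `alpha` each (boundary replacements), with absorbing states at 0
#' (loss) and `n_sc` (monoclonal fixation). The likelihood of observed
#' surviving clone sizes at each chase time is computed exactly from the
#' matrix exponential of the birth-death generator, conditioned on survival,
#' and maximized over `alpha`. The data enter only through `alpha * t`, so
#' halving the rate and doubling all chase times leaves the likelihood
#' unchanged.
#'
#' @param clone_size_by_time Data frame with columns `chase_days` and `size`
#'   (number of labelled stem cells of each surviving clone).
#' @param n_sc Ring size.
#' @param interval Search interval for the rate (per day).
#' @param n_boot Bootstrap resamples for the confidence interval (0 skips
#'   it).
#' @param conf Confidence level.
#' @return A list with `rate` (symmetric replacements per SC per day), `ci`,
#'   `loglik` and `n_clones`.
#' @export
fit_neutral_drift_rate <- function(clone_size_by_time, n_sc = 8,
                                   interval = c(0.005, 3), n_boot = 200,
                                   conf = 0.95) {
  df <- clone_size_by_time
  stopifnot(all(c("chase_days", "size") %in% names(df)))
  if (length(unique(df$chase_days)) < 2)
    stop("need clone sizes at >= 2 chase times to identify the rate",
         call. = FALSE)
  if (any(df$size < 1 | df$size > n_sc))
    stop("sizes must lie in 1..n_sc (surviving clones)", call. = FALSE)
  times <- sort(unique(df$chase_days))

  nll <- function(log_alpha, dat) {
    alpha <- exp(log_alpha)
    ll <- 0
    for (tt in times) {
      sizes <- dat$size[dat$chase_days == tt]
      if (length(sizes) == 0) next
      p <- drift_size_pmf(alpha * tt, n_sc) # conditional on survival
      ll <- ll + sum(log(pmax(p[sizes], 1e-300)))
    }
    -ll
  }

  fit1 <- function(dat) {
    opt <- optimize(nll, log(interval), dat = dat, tol = 1e-4)
    exp(opt$minimum)
  }
  rate <- fit1(df)
  out <- list(rate = rate, loglik = -nll(log(rate), df), n_clones = nrow(df))
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(i) {
      fit1(df[sample.int(nrow(df), replace = TRUE), , drop = FALSE])
    }, numeric(1))
    a <- (1 - conf) / 2
    out$ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  out
}

# pmf of the surviving-clone size after scaled time tau = alpha * t,
# starting from one labelled cell on a ring of n stem cells
drift_size_pmf <- function(tau, n) {
  Q <- matrix(0, n + 1, n + 1) # states 0..n; 0 and n absorbing
  for (k in 1:(n - 1)) {
    Q[k + 1, k] <- 1
    Q[k + 1, k + 2] <- 1
    Q[k + 1, k + 1] <- -2
  }
  P <- as.matrix(Matrix::expm(Q * tau))
  p <- P[2, ] # start at size 1
  surv <- p[2:(n + 1)]
  surv / sum(surv)
}
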