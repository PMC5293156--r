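test_that("frozen dynamics produce no events and leave the state unchanged", {
  set.seed(11)
  cfg <- sim_config(division_period = Inf, burn_in = 0)
  st0 <- build_lattice(cfg)
  run <- run_crypt(cfg, 5, init = st0)
  expect_equal(run$counters[["divisions"]], 0)
  expect_equal(run$counters[["extrusions"]], 0)
  expect_equal(run$state$fate, st0$fate)
  expect_equal(run$state$clone_id, st0$clone_id)
})

test_that("occupancy is conserved and divisions balance extrusions", {
  set.seed(12)
  run <- run_crypt(sim_config(commitment_mode = "cz"), 40,
                   check_invariants = TRUE)
  expect_equal(run$violations, 0)
  expect_gt(run$counters[["divisions"]], 0)
  expect_equal(run$counters[["divisions"]], run$counters[["extrusions"]])
  # the whole grid remains classified compartment by compartment
  expect_true(all(run$state$cls[1, ] %in% c(0L, 1L)))
  expect_true(all(run$state$cls[2:7, ] == 2L))
  expect_true(all(run$state$cls[8:22, ] == 3L))
})

test_that("trajectories are reproducible bit for bit from the seed", {
  cfg <- sim_config(commitment_mode = "cz", mixing = 0.4,
                    goblet_division_factor = 0.8, record_events = TRUE)
  set.seed(99)
  a <- run_crypt(cfg, 20)
  set.seed(99)
  b <- run_crypt(cfg, 20)
  expect_identical(a$state$fate, b$state$fate)
  expect_identical(a$entrants, b$entrants)
  expect_identical(a$events, b$events)
})

test_that("stem-cell neutral drift matches an independent 1D ring oracle", {
  set.seed(13)
  cfg <- sim_config()
  n_rep <- 120
  mono <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    st <- label_sc_clones(run_crypt(cfg, 1)$state)
    out <- run_crypt(cfg, 40, init = st)
    sc <- which(out$state$cls[1, ] == 0L)
    mono[i] <- length(unique(out$state$clone_id[1, sc])) == 1L
  }
  p_lattice <- mean(mono)
  p_ring <- ring_monoclonal_prob(t_end = 40, reps = 1500)
  expect_lt(abs(p_lattice - p_ring), 0.12)
  # absorbing behaviour: a clone never both fixes and dies
  expect_true(all(mono %in% c(TRUE, FALSE)))
})

test_that("division-period inheritance implements clonal synchronization", {
  set.seed(14)
  expect_equal(draw_division_period(3.7, 1, n = 50), rep(3.7, 50))
  fresh <- draw_division_period(9.9, 0, division_period = 2.5,
                                period_cv = 0.3, n = 2e4)
  expect_lt(abs(mean(fresh) - 2.5), 0.02)
  expect_lt(abs(sd(fresh) / mean(fresh) - 0.3), 0.02)
  expect_false(any(fresh == 9.9))
  # clone sizes disperse more when progeny inherit their parent's period
  v0 <- var(replicate(250, branching_clone_size(0)))
  v1 <- var(replicate(250, branching_clone_size(1)))
  expect_gt(v1, v0)
})

test_that("cells accelerate upward: dwell time falls with crypt row", {
  set.seed(15)
  ens <- simulate_crypts(sim_config(record_events = TRUE), 25, duration = 50)
  d <- dwell_time_profile(ens)$mean_dwell_days
  # strictly decreasing up through the TA compartment and into the boundary
  expect_true(all(diff(d[2:8]) < 0))
  # mitotic pressure is uniform within the post-mitotic compartment
  diff_rows <- d[9:21]
  expect_lt(max(diff_rows) / min(diff_rows), 1.25)
  expect_lt(max(diff_rows), min(d[2:7]))
})

test_that("flux amplification matches the geometry and double counting agrees", {
  set.seed(16)
  ens <- simulate_crypts(sim_config(record_events = TRUE), 25, duration = 50)
  fa <- flux_amplification(ens)
  expect_equal(fa$amplification, fa$by_division_count)
  # about tenfold: below the (n_sc + n_ta_rows * n_columns) / n_sc = 13
  # site-count ratio because cells extruded mid-cycle never divide
  expect_gt(fa$amplification, 9)
  expect_lt(fa$amplification, 14)
  # memoryless clocks restore the site-count ratio exactly
  set.seed(161)
  ens_exp <- simulate_crypts(sim_config(cycle_model = "exponential",
                                        record_events = TRUE),
                             25, duration = 50)
  expect_lt(abs(flux_amplification(ens_exp)$amplification - 13) / 13, 0.05)
})

test_that("rigid pushing keeps a goblet run contiguous; mixing breaks it up", {
  gap_count <- function(mixing, seed) {
    set.seed(seed)
    # a seeded vertical goblet run in an otherwise all-enterocyte crypt
    # (p_secretory = 0 so no new goblet cells are produced)
    cfg <- sim_config(commitment_mode = "early", p_secretory = 0,
                      mixing = mixing, burn_in = 0)
    st <- build_lattice(cfg)
    st$fate[st$cls == 3L | st$cls == 2L] <- F_ABS
    st$fate[9:13, 4] <- F_SEC
    out <- run_crypt(cfg, 3, init = st)$state
    sum(sapply(1:16, function(c) {
      r <- rle(out$fate[8:22, c] == F_SEC)
      sum(r$values) # number of distinct goblet runs in the column
    }))
  }
  expect_lte(gap_count(0, 171), 1) # one run, one column, never fragmented
  # partial mixing lets some enterocytes overtake part of the stack only,
  # breaking the run into fragments
  expect_gt(mean(sapply(1:6, function(i) gap_count(0.5, 171 + i))), 1.3)
})

test_that("dispersive migration makes goblet cells lag behind enterocytes", {
  set.seed(18)
  ens <- simulate_crypts(sim_config(commitment_mode = "early", mixing = 1,
                                    goblet_division_factor = 0.6),
                         20, duration = 30)
  rows <- do.call(rbind, lapply(ens$runs, function(r) {
    f <- r$state$fate[8:22, ]
    pos <- row(f) # height within the differentiated compartment
    c(gob = mean(pos[f == 1]), ent = mean(pos[f == 2]))
  }))
  expect_lt(mean(rows[, "gob"]), mean(rows[, "ent"]))
  # swaps actually occurred
  expect_gt(sum(sapply(ens$runs, function(r) r$counters[["mixing_swaps"]])), 0)
})
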