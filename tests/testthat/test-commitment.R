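test_that("stochastic commitment draws fates at the configured probability", {
  set.seed(21)
  expect_true(all(commit_stochastic(100, 0) == 2L)) # all absorptive
  expect_true(all(commit_stochastic(100, 1) == 1L)) # all secretory
  frac <- mean(commit_stochastic(1e5, 0.25) == 1L)
  expect_lt(abs(frac - 0.25), 0.005)
})

test_that("the commitment-zone rule inhibits neighbours of Delta cells", {
  set.seed(22)
  st <- build_lattice(sim_config(commitment_mode = "cz"))
  st$fate[2:3, ] <- 0L
  expect_equal(commit_cz(st, 2, 5), 1L) # no inhibitor anywhere: Delta
  st$fate[3, 5] <- 1L                   # secretory directly above
  expect_equal(commit_cz(st, 2, 5), 2L)
  st$delta[2, 10] <- 0L                 # NICD lineages cannot take Delta
  expect_equal(commit_cz(st, 2, 10), 2L)
  expect_error(commit_cz(st, 10, 1), "commitment zone")
})

test_that("no two adjacent commitment-zone residents are both secretory, ever", {
  set.seed(23)
  for (i in 1:4) {
    run <- run_crypt(sim_config(commitment_mode = "cz"), 25,
                     check_invariants = TRUE)
    expect_equal(run$violations, 0)
    sec <- run$state$fate == 1L
    for (r in 2:3) for (c in 1:16) {
      if (!sec[r, c]) next
      nb <- hex_neighbors(r, c)
      nb <- nb[nb[, "row"] %in% 2:3, , drop = FALSE]
      expect_false(any(sec[nb]), info = sprintf("rep %d site (%d,%d)", i, r, c))
    }
  }
})

test_that("a 1:3 secretory fraction emerges from the zone without any tuned probability", {
  ens <- acceptance_ensembles()$cz
  outflow <- unlist(lapply(ens$runs, function(r) r$cz_exits$fate == 1))
  frac <- mean(outflow)
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.30)
  # independent oracle: random sequential adsorption with nearest-neighbour
  # exclusion on the same triangular band
  set.seed(24)
  rsa <- rsa_secretory_fraction()
  expect_gt(rsa, 0.20)
  expect_lt(rsa, 0.30)
  expect_lt(abs(frac - rsa), 0.06)
})

test_that("goblet neighbour pairs are depleted in the zone but common just above it", {
  ens <- acceptance_ensembles()$cz
  pair_frac <- function(states, rows) {
    hit <- 0; tot <- 0
    for (st in states) {
      sec <- st$fate == 1L
      for (r in rows + 1L) for (c in 1:16) { # rows above base -> grid rows
        if (!sec[r, c]) next
        tot <- tot + 1
        if (any(sec[hex_neighbors(r, c)])) hit <- hit + 1
      }
    }
    hit / tot
  }
  states <- lapply(ens$runs[1:60], `[[`, "state")
  f12 <- pair_frac(states, 1:2)
  f34 <- pair_frac(states, 3:4)
  expect_gt(f34, f12)
  expect_lt(f12, 0.45)
  expect_gt(f34, 0.35)
})

test_that("Notch-hyperactive mosaics push wild-type progeny toward the goblet fate", {
  set.seed(25)
  wt_frac <- sapply(c(0, 0.4, 0.8), function(nf) {
    ens <- simulate_crypts(sim_config(commitment_mode = "cz",
                                      nicd_fraction = nf),
                           50, duration = 30)
    hits <- unlist(lapply(ens$runs, function(r) {
      f <- r$state$fate[8:22, ]; d <- r$state$delta[8:22, ]
      f[d == 1L]
    }))
    mean(hits == 1L)
  })
  # nicd_fraction = 0 reproduces the plain commitment-zone statistics
  ens0 <- acceptance_ensembles()$cz
  base <- mean(unlist(lapply(ens0$runs, function(r) r$state$fate[8:22, ] == 1L)))
  expect_lt(abs(wt_frac[1] - base), 0.03)
  # monotone increase of the wild-type goblet fraction with the NICD load
  expect_gt(wt_frac[2], wt_frac[1] + 0.02)
  expect_gt(wt_frac[3], wt_frac[2] + 0.02)
})

test_that("early commitment yields uniform clones; late matches the mixing closed form", {
  set.seed(26)
  clone_table <- function(mode) {
    ens <- simulate_crypts(sim_config(commitment_mode = mode,
                                      track_ta_clones = TRUE),
                           30, duration = 30)
    do.call(rbind, lapply(seq_along(ens$runs), function(i) {
      st <- ens$runs[[i]]$state
      f <- as.vector(st$fate[8:22, ]); cid <- as.vector(st$clone_id[8:22, ])
      keep <- cid > 0
      data.frame(crypt = i, clone = cid[keep], sec = f[keep] == 1L)
    }))
  }
  summarize <- function(df) {
    by_clone <- split(df$sec, paste(df$crypt, df$clone))
    multi <- by_clone[lengths(by_clone) >= 2]
    list(uniform = mean(sapply(multi, function(v) length(unique(v)) == 1)),
         sizes = lengths(multi))
  }
  early <- summarize(clone_table("early"))
  expect_gt(early$uniform, 0.999)
  late <- summarize(clone_table("late"))
  expected <- uniform_closed_form(late$sizes, 0.25)
  expect_lt(abs(late$uniform - expected), 0.04)
  expect_lt(late$uniform, 0.9) # late commitment really does mix clones
})
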