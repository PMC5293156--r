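make_cells <- function(markers, lgr5 = rep(FALSE, length(markers)),
                       clone_id = 1, row = seq_along(markers)) {
  tibble::tibble(clone_id = clone_id, mouse_id = 1, chase_days = 10,
                 row = row, marker = markers, lgr5 = lgr5)
}

test_that("clones classify as uniform, mixed or excluded", {
  cells <- rbind(
    make_cells(c("Gob5pos", "Gob5pos"), clone_id = 1),
    make_cells(c("Gob5pos", "Gob5neg"), clone_id = 2),
    make_cells(c("Gob5neg", "Gob5neg", "Gob5neg"), clone_id = 3),
    make_cells(c("Gob5pos", "Gob5pos"), lgr5 = c(TRUE, FALSE), clone_id = 4),
    make_cells("Gob5neg", clone_id = 5)
  )
  cl <- classify_clones(cells)
  got <- setNames(cl$clones$classification, cl$clones$clone_id)
  expect_equal(unname(got[c("1", "2", "3", "4")]),
               c("uniform_secretory", "mixed", "uniform_absorptive", "excluded"))
  expect_equal(cl$n_excluded, 1)
  expect_equal(cl$n_multicell, 3) # the Lgr5+ clone is dropped, singleton too
  expect_equal(cl$uniform_fraction, 2 / 3)
  expect_error(classify_clones(cells[0, ]), "empty")
})

test_that("the late-commitment randomization null matches closed forms", {
  set.seed(41)
  two <- late_commitment_null(c(2, 2), freq_secretory = 0.5, n_rand = 2e4)
  expect_lt(abs(two$expected_uniform_fraction - 0.5), 0.01)
  sizes <- c(2, 2, 3, 3, 3, 4, 4, 5, 6, 7, 8, 9, 2, 3, 4, 2, 5, 3, 2, 6)
  null <- late_commitment_null(sizes, observed_uniform_fraction = 0.7,
                               freq_secretory = 0.24, n_rand = 1e5)
  closed <- uniform_closed_form(sizes, 0.24)
  expect_lt(abs(null$expected_uniform_fraction - closed),
            3 * null$sd / sqrt(null$n_rand) + 1e-3)
  expect_gt(null$z, 0)
  expect_lt(null$p_value, 0.05)
  expect_error(late_commitment_null(c(1, 3)), "sizes >= 2")
})

test_that("bootstrap SD of the uniform fraction behaves from n = 2 to the binomial limit", {
  set.seed(42)
  expect_equal(bootstrap_fraction_sd(rep(TRUE, 10), 1000), 0)
  # two clones, one uniform: the four equiprobable resamples give sd sqrt(1/8)
  expect_lt(abs(bootstrap_fraction_sd(c(TRUE, FALSE), 2e4) - sqrt(0.125)), 0.01)
  labels <- runif(400) < 0.3
  f <- mean(labels)
  expect_lt(abs(bootstrap_fraction_sd(labels, 5e3) - sqrt(f * (1 - f) / 400)) /
              sqrt(f * (1 - f) / 400), 0.10)
})

test_that("clone-group comparisons use the right tests and detect the reported patterns", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- compare_clone_groups(same, "height")
  expect_match(res$method, "Kruskal")
  expect_gt(res$p_value, 0.9)
  set.seed(43)
  heights <- list(goblet = rnorm(7, 11, 4), enterocyte = rnorm(11, 24, 3))
  hres <- compare_clone_groups(heights, "height")
  expect_lt(hres$p_value, 0.05)
  expect_lt(hres$summary$mean[1], hres$summary$mean[2])
  sizes <- list(goblet = pmax(1, rnorm(10, 3, 1)),
                enterocyte = pmax(1, rnorm(22, 5, 2.5)))
  sres <- compare_clone_groups(sizes, "size")
  expect_match(sres$method, "Welch")
  expect_lt(sres$p_value, 0.05)
  expect_error(compare_clone_groups(list(1, 1:5), "size"), "at least 2")
})

test_that("neutral-drift rate inference recovers known rates and scales exactly", {
  set.seed(44)
  truth <- gen_lineage_truth(rate = 0.4, n_clones = 200,
                             chase_days = c(4, 7, 10, 14))
  fit <- fit_neutral_drift_rate(truth, n_boot = 0)
  expect_lt(abs(fit$rate - 0.4) / 0.4, 0.15)
  # frozen clones pin the estimate to zero
  frozen <- gen_lineage_truth(rate = 0, n_clones = 50, chase_days = c(5, 10))
  expect_lt(fit_neutral_drift_rate(frozen, n_boot = 0)$rate, 0.02)
  # likelihood depends on rate * time only
  doubled <- truth
  doubled$chase_days <- truth$chase_days * 2
  fit2 <- fit_neutral_drift_rate(doubled, n_boot = 0)
  expect_lt(abs(fit2$rate - fit$rate / 2) / (fit$rate / 2), 0.03)
  expect_error(fit_neutral_drift_rate(data.frame(chase_days = 5, size = 2)),
               "chase times")
})

test_that("informative-clone probability is one half by rate symmetry", {
  set.seed(45)
  p <- informative_clone_probability(sim_config(), n_rep = 6000)
  expect_lt(abs(p - 0.5), 0.05)
  # pure competition of equal-rate event types: no dependence on the
  # division period or on the horizontal-division probability
  p2 <- informative_clone_probability(sim_config(division_period = 25,
                                                 sc_horizontal_prob = 0.9),
                                      n_rep = 6000)
  expect_lt(abs(p2 - 0.5), 0.05)
  expect_error(informative_clone_probability(
    sim_config(sc_horizontal_prob = 0)), "never displaced")
})

test_that("clone tables round-trip through the tab-delimited format", {
  set.seed(46)
  spec <- synth_spec(n_clones = 25, lgr5_fraction = 0.2)
  tab <- gen_clone_table(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(tab, path)
  back <- read_clone_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(classify_clones(back)$uniform_fraction,
                   classify_clones(tab)$uniform_fraction)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clone_id\tmarker\n1\tGob5pos", bad)
  expect_error(read_clone_table(bad), "lacks columns")
})
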