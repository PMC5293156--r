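# Independent oracles and shared simulation ensembles for the test suite.
# Oracles re-derive expected values through a different route than the code
# they check (explicit enumeration, independent lattice/ring code, closed
# forms), so agreement is informative.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the four study conditions at the scale of the headline analysis
acceptance_ensembles <- function() cached("acc", {
  conds <- list(
    early = sim_config(commitment_mode = "early"),
    late = sim_config(commitment_mode = "late"),
    cz = sim_config(commitment_mode = "cz"),
    dm = sim_config(commitment_mode = "early", mixing = 0.65,
                    goblet_division_factor = 0.6)
  )
  out <- list()
  seeds <- c(early = 5101, late = 5102, cz = 5103, dm = 5104)
  for (nm in names(conds)) {
    set.seed(seeds[[nm]])
    out[[nm]] <- simulate_crypts(conds[[nm]], 200, duration = 50)
  }
  out
})

# closed-form expected uniform-clone fraction under i.i.d. cell fates
uniform_closed_form <- function(sizes, p) mean(p^sizes + (1 - p)^sizes)

# Random sequential adsorption with nearest-neighbour exclusion on the
# 2-row triangular band wrapped on a cylinder (own adjacency code): the
# stated oracle for the emergent secretory fraction of the commitment zone.
rsa_secretory_fraction <- function(n_rows = 2, n_cols = 16, reps = 300) {
  neigh <- function(r, c) {
    wrapc <- function(x) ((x - 1) %% n_cols) + 1
    off <- if (r %% 2 == 1) -1 else 0 # row 1 unshifted, row 2 right-shifted
    nb <- cbind(r, c(wrapc(c - 1), wrapc(c + 1)))
    for (rr in c(r - 1, r + 1)) {
      if (rr < 1 || rr > n_rows) next
      nb <- rbind(nb, cbind(rr, c(wrapc(c + off), wrapc(c + off + 1))))
    }
    nb
  }
  dens <- replicate(reps, {
    acc <- matrix(FALSE, n_rows, n_cols)
    sites <- cbind(rep(seq_len(n_rows), n_cols),
                   rep(seq_len(n_cols), each = n_rows))
    for (i in sample(nrow(sites))) {
      r <- sites[i, 1]; c <- sites[i, 2]
      if (!any(acc[neigh(r, c)])) acc[r, c] <- TRUE
    }
    mean(acc)
  })
  mean(dens)
}

# Independent 1D ring simulation of the stem-cell row dynamics (matched
# cycle clocks, horizontal-replacement probability and phase handling),
# used as the oracle for neutral-drift monoclonality on the lattice.
ring_monoclonal_prob <- function(t_end, n_sc = 8, period = 2.5, shp = 0.4,
                                 reps = 2000) {
  mean(replicate(reps, {
    clone <- seq_len(n_sc)
    nxt <- runif(n_sc) * period
    t <- 0
    repeat {
      i <- which.min(nxt)
      t <- nxt[i]
      if (t > t_end) break
      if (runif(1) < shp) {
        j <- if (runif(1) < 0.5) i %% n_sc + 1L else (i - 2L) %% n_sc + 1L
        clone[j] <- clone[i]
        nxt[j] <- t + period
      }
      nxt[i] <- t + period
    }
    length(unique(clone)) == 1L
  }))
}

# single-lineage branching process driven by draw_division_period(): clone
# size at a fixed time under clonal rate synchronization s
branching_clone_size <- function(s, t_end = 10, period = 2.5, cvp = 0.3) {
  pers <- draw_division_period(period, 0, period, cvp)
  nxts <- runif(1) * pers
  repeat {
    i <- which.min(nxts)
    t <- nxts[i]
    if (t > t_end) break
    child <- draw_division_period(pers[i], s, period, cvp)
    pers <- c(pers, child)
    nxts <- c(nxts, t + child)
    nxts[i] <- t + pers[i]
  }
  length(pers)
}

# hand-built crypt state with a given fate matrix (for profile unit tests)
make_state <- function(fate, config = sim_config()) {
  n_rows <- nrow(fate); n_cols <- ncol(fate)
  cls <- matrix(3L, n_rows, n_cols)
  cls[1, ] <- rep(c(0L, 1L), length.out = n_cols)
  cls[2:(1 + config$n_ta_rows), ] <- 2L
  storage.mode(fate) <- "integer"
  structure(list(cls = cls, fate = fate,
                 clone_id = matrix(0L, n_rows, n_cols),
                 delta = matrix(1L, n_rows, n_cols),
                 period = matrix(config$division_period, n_rows, n_cols),
                 next_t = matrix(Inf, n_rows, n_cols),
                 time = 0, config = config),
            class = "crypt_state")
}

# fate codes (mirrors the internal mapping)
F_UNC <- 0L; F_SEC <- 1L; F_ABS <- 2L
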