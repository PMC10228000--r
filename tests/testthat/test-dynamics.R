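# interaction-free parameter set: every potential term switched off
free_forcefield <- function(system) {
  p <- wt_parameters()
  p$class_eps[, ] <- 0
  p$eps_l <- 0
  forcefield(system, params = p, ne_on = FALSE, k_bond = 0, het_eps = 0,
             eps_rep = 0, nucleolus_k = 0)
}

test_that("free-particle velocities satisfy equipartition", {
  sys <- tiny_system(n_tads = 40, seed = 1)
  ff <- free_forcefield(sys)
  st <- structure(list(positions = matrix(rnorm(3 * nrow(sys$beads)), ncol = 3),
                       velocities = NULL, system = sys, topology = NA,
                       step = 0L), class = "flynuc_state")
  tr <- integrate_dynamics(st, ff, n_steps = 2e4, gamma = 1, stride = 100,
                           seed = 21)
  # stationary kinetic temperature: mean over snapshots -> kT within 3 SE
  kt <- tr$kinetic_temp[-(1:20)]
  n_comp <- 3 * nrow(sys$beads)
  se <- sqrt(2 / (n_comp * length(kt))) # chi-square variance, indep. samples
  expect_lt(abs(mean(kt) - 1), 3 * max(se, 0.01))
  # per-bead variance scales as kT/m: heavy beads move less
  v2 <- rowSums(tr$end_state$velocities^2)
  m <- sys$beads$mass_red
  expect_gt(cor(log(m), log(v2 * m)), -0.5) # m*v^2 independent of m
  expect_lt(cor(m, v2), 0)                  # raw v^2 decreases with mass
})

test_that("gamma = 0 limit conserves energy to 1e-3 relative", {
  sys <- tiny_system(n_tads = 12, seed = 2)
  ff <- forcefield(sys)
  st <- init_nucleus(sys, "CIS-X6S", seed = 3, collapse_steps = 2e3,
                     stages = 4, steps_per_stage = 1e3)
  # short thermalized segment, then a conservative run
  warm <- integrate_dynamics(st, ff, n_steps = 5e3, gamma = 1, stride = 5e3,
                             seed = 4)
  st2 <- warm$end_state
  e_tot <- function(state) {
    ke <- 0.5 * sum(state$system$beads$mass_red * rowSums(state$velocities^2))
    ke + as.numeric(total_energy(ff, state$positions))
  }
  # symplectic-limit oracle: with gamma = 0 and a refined step (the bounded
  # Verlet energy oscillation scales as dt^2) the segment-averaged energy
  # must show no drift over 1e5 steps
  segs <- 20
  e_series <- numeric(segs + 1)
  e_series[1] <- e_tot(st2)
  cur <- st2
  for (k in seq_len(segs)) {
    run <- integrate_dynamics(cur, ff, n_steps = 5e3, gamma = 0, dt = 0.005,
                              stride = 5e3, seed = 5)
    cur <- run$end_state
    e_series[k + 1] <- e_tot(cur)
  }
  e_head <- mean(e_series[1:5])
  e_tail <- mean(e_series[(segs - 3):(segs + 1)])
  expect_lt(abs(e_tail - e_head) / abs(e_head), 1e-3)
})

test_that("kinetic temperature holds within 2% for all friction presets", {
  sys <- small_system()
  ff <- forcefield(sys)
  st <- small_state()
  runs <- list(c(gamma = 1, n = 1e5, seed = 31),
               c(gamma = 0.1, n = 3e5, seed = 32),
               c(gamma = 0.01, n = 1e6, seed = 33))
  for (r in runs) {
    tr <- integrate_dynamics(st, ff, n_steps = r[["n"]], gamma = r[["gamma"]],
                             stride = r[["n"]] / 200, seed = r[["seed"]])
    kt <- tr$kinetic_temp[-(1:50)]  # burn-in
    expect_lt(abs(mean(kt) - 1), 0.02)
  }
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  sys <- tiny_system(n_tads = 15, seed = 6)
  ff <- forcefield(sys)
  st <- init_nucleus(sys, "TRANS-X3S", seed = 8, collapse_steps = 2e3,
                     stages = 4, steps_per_stage = 1e3)
  t1 <- integrate_dynamics(st, ff, n_steps = 5e3, gamma = 0.1, stride = 500,
                           seed = 99)
  t2 <- integrate_dynamics(st, ff, n_steps = 5e3, gamma = 0.1, stride = 500,
                           seed = 99)
  expect_identical(t1$positions, t2$positions)
  t3 <- integrate_dynamics(st, ff, n_steps = 5e3, gamma = 0.1, stride = 500,
                           seed = 100)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("chain bonds stay intact during production", {
  tr <- wt_trajectory()
  sys <- tr$system
  i <- sys$bonds$i + 1L; j <- sys$bonds$j + 1L
  for (s in seq(1, n_snapshots(tr), by = 25)) {
    p <- tr$positions[, , s]
    blen <- sqrt(rowSums((p[i, ] - p[j, ])^2))
    expect_true(all(blen < 3 * sys$bonds$r0))
  }
})

test_that("trajectory bookkeeping is consistent", {
  tr <- wt_trajectory()
  expect_true(all(diff(tr$snap_steps) > 0))
  expect_true(all(is.finite(tr$positions)))
  # all beads inside the nucleus at every snapshot
  r_max <- apply(tr$positions, 3, function(p) max(sqrt(rowSums(p^2))))
  expect_true(all(r_max <= tr$nucleus_radius))
})

test_that("neighbor search agrees with the all-pairs oracle", {
  set.seed(17)
  for (rep in 1:3) {
    pos <- matrix(runif(50 * 3, -1, 1), ncol = 3)
    cutoff <- runif(1, 0.3, 0.9)
    got <- neighbor_pairs(pos, cutoff)
    d <- as.matrix(dist(pos))
    exp_pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    expect_equal(nrow(got), nrow(exp_pairs))
    expect_setequal(paste(got$i, got$j),
                    paste(exp_pairs[, 1], exp_pairs[, 2]))
  }
  # empty system and all-pairs cutoff
  expect_equal(nrow(neighbor_pairs(matrix(0, 0, 3), 1)), 0)
  pos <- matrix(runif(30, 0, 0.5), ncol = 3)
  expect_equal(nrow(neighbor_pairs(pos, 10)), choose(10, 2))
})

test_that("removing the NE lets chromatin decompact", {
  sys <- small_system()
  ff <- remove_ne(forcefield(sys))
  tr <- integrate_dynamics(small_state(), ff, n_steps = 1e5, gamma = 1,
                           stride = 1e4, seed = 55)
  mean_r <- apply(tr$positions, 3, function(p) mean(sqrt(rowSums(p^2))))
  # mean radial extent grows beyond the confined value and keeps growing
  expect_gt(tail(mean_r, 1), mean_r[1])
  expect_gt(tail(mean_r, 1), sys$nucleus_radius * 0.7)
  # no wall energy contribution once removed
  comps <- attr(total_energy(ff, tr$end_state$positions), "components")
  expect_equal(comps[["wall"]], 0)
  expect_equal(comps[["confine"]], 0)
})
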