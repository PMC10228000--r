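# Shared fixtures. Expensive objects (initialized states, trajectories) are
# built once per test run and memoized here; all are generated in code.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A hand-written 20-TAD toy annotation covering all six arms.
toy_tad_table <- function() {
  tibble::tibble(
    arm = c(rep("2L", 4), rep("2R", 4), rep("3L", 3), rep("3R", 4),
            rep("4", 2), rep("X", 3)),
    start = c(0, 100, 220, 300,  0, 80, 200, 320,  0, 150, 260,
              0, 90, 210, 330,  0, 50,  0, 120, 240) * 1e3,
    end   = c(100, 220, 300, 420,  80, 200, 320, 400,  150, 260, 400,
              90, 210, 330, 440,  50, 110,  120, 240, 330) * 1e3,
    class = rep(c("Active", "Null", "PcG", "HP1", "Null"), 4),
    hard_radius_um = seq(0.05, 0.12, length.out = 20)
  )
}

toy_lad_table <- function() {
  # overlaps TADs: 2L #2 (partially), 2R #1 (exactly), X #3 (inside)
  tibble::tibble(
    arm = c("2L", "2R", "X"),
    start = c(150e3, 0, 250e3),
    end = c(180e3, 80e3, 300e3)
  )
}

# Small synthetic genome + system used across dynamics/analysis tests.
small_annotation <- function() {
  memo("small_ann", synth_genome(n_tads = 120, seed = 5))
}

small_system <- function() {
  memo("small_sys",
       build_system(small_annotation(), nucleus_radius = 1.0,
                    het_radius = 0.1))
}

# Initialized state (scaled-down preparation schedule).
small_state <- function() {
  memo("small_state",
       init_nucleus(small_system(), "CIS-X6S", seed = 7,
                    collapse_steps = 2e4, stages = 8, steps_per_stage = 2e3))
}

# Production-style WT trajectory reused by analysis and acceptance tests.
wt_trajectory <- function() {
  memo("wt_traj", {
    ff <- forcefield(small_system(), params = wt_parameters())
    integrate_dynamics(small_state(), ff, n_steps = 1e6, gamma = 1,
                       stride = 2000, seed = 11)
  })
}

mutant_trajectory <- function() {
  memo("mut_traj", {
    ff <- forcefield(small_system(), params = lamin_mutant_parameters())
    integrate_dynamics(small_state(), ff, n_steps = 1e6, gamma = 1,
                       stride = 2000, seed = 11)
  })
}

# Build a bare-bones trajectory object from a positions array, for analysis
# functions that only need positions + system + metadata.
fake_trajectory <- function(positions, system, stride = 1000,
                            nucleus_radius = system$nucleus_radius) {
  ns <- dim(positions)[3]
  structure(
    list(snap_steps = (seq_len(ns) - 1L) * stride,
         positions = positions,
         system = system, end_state = NULL,
         gamma = 1, dt = 0.01, kT = 1, stride = stride,
         topology = "CIS-X6S", nucleus_radius = nucleus_radius,
         forcefield_hash = "fixture", ne_on = TRUE),
    class = "flynuc_trajectory"
  )
}

# A tiny 2-chain system whose geometry is fully hand-controllable: positions
# set directly, used for contact-map and layer oracles.
tiny_system <- function(n_tads = 12, seed = 2, radius = 1.0) {
  ann <- synth_genome(n_tads = n_tads, seed = seed)
  build_system(ann, nucleus_radius = radius, het_radius = 0.06)
}
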