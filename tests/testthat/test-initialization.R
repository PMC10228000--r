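arm_azimuths <- function(system, pos, arm) {
  sel <- which(system$beads$arm == arm & system$beads$kind == "TAD")
  atan2(pos[sel, 2], pos[sel, 1]) %% (2 * pi)
}

test_that("linear chains start inside their wedges, touching, polarized", {
  sys <- small_system()
  pos <- make_linear_chains(sys, "CIS-X6S", seed = 1)
  occ <- wedge_occupancy(sys, pos, "CIS-X6S")
  expect_true(all(occ == 1))

  # consecutive TAD beads are separated by r_i + r_j (up to the tiny jitter)
  b <- sys$beads
  for (arm in c("2L", "X")) {
    sel <- which(b$arm == arm & b$kind == "TAD")
    d <- sqrt(rowSums((pos[sel[-1], ] - pos[sel[-length(sel)], ])^2))
    r0 <- b$radius_um[sel[-1]] + b$radius_um[sel[-length(sel)]]
    expect_equal(d, r0, tolerance = 0.15)
  }

  # Rabl polarization: autosome centromeric ends near the top (z max);
  # X runs South in an XS topology
  sel2L <- which(b$arm == "2L" & b$kind == "TAD")
  expect_gt(pos[sel2L[length(sel2L)], 3], pos[sel2L[1], 3]) # cen end higher
  selX <- which(b$arm == "X" & b$kind == "TAD")
  expect_lt(mean(pos[selX, 3]), 0)

  expect_identical(make_linear_chains(sys, "CIS-X6S", seed = 1),
                   make_linear_chains(sys, "CIS-X6S", seed = 1))
})

test_that("CIS topologies place 2R next to 3R in azimuth", {
  sys <- small_system()
  pos <- make_linear_chains(sys, "CIS-X6S", seed = 1)
  mean_az <- vapply(c("2R", "3R", "2L", "3L"), function(a) {
    az <- arm_azimuths(sys, pos, a)
    atan2(mean(sin(az)), mean(cos(az))) %% (2 * pi)
  }, numeric(1))
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% (2 * pi); min(d, 2 * pi - d)
  }
  w <- 2 * pi / 5
  expect_equal(circ_dist(mean_az[["2R"]], mean_az[["3R"]]), w, tolerance = 0.01)
  expect_equal(circ_dist(mean_az[["2L"]], mean_az[["3L"]]), w, tolerance = 0.01)
  # TRANS separates the like arms
  post <- make_linear_chains(sys, "TRANS-X3S", seed = 1)
  az_t <- vapply(c("2R", "3R"), function(a) {
    az <- arm_azimuths(sys, post, a)
    atan2(mean(sin(az)), mean(cos(az))) %% (2 * pi)
  }, numeric(1))
  expect_gt(circ_dist(az_t[["2R"]], az_t[["3R"]]), w * 1.5)
})

test_that("collapse compacts arms while respecting wedges", {
  sys <- tiny_system(n_tads = 40, seed = 3, radius = 1.0)
  pos0 <- make_linear_chains(sys, "CIS-X7N", seed = 2)
  col <- collapse_chains(sys, pos0, "CIS-X7N", n_steps = 1e4, seed = 5)
  rg <- function(p, sel) {
    c <- colMeans(p[sel, ]); sqrt(mean(rowSums(sweep(p[sel, ], 2, c)^2)))
  }
  sel <- which(sys$beads$arm == "3R" & sys$beads$kind == "TAD")
  expect_lt(rg(col$positions, sel), rg(pos0, sel))
  # connectivity preserved
  i <- sys$bonds$i + 1L; j <- sys$bonds$j + 1L
  blen <- sqrt(rowSums((col$positions[i, ] - col$positions[j, ])^2))
  expect_true(all(blen < 3 * sys$bonds$r0))
})

test_that("collapsed arms stay in their wedges at working scale", {
  sys <- small_system()
  pos0 <- make_linear_chains(sys, "CIS-X6S", seed = 7)
  col <- collapse_chains(sys, pos0, "CIS-X6S", n_steps = 2e4, seed = 7)
  # harmonic wedge penalties allow a thermal-width excursion past the planes
  occ <- wedge_occupancy(sys, col$positions, "CIS-X6S", tolerance = 0.05)
  expect_true(all(occ >= 0.95))
  expect_gte(mean(occ), 0.98)
})

test_that("shrinking confines every bead inside the final sphere", {
  sys <- tiny_system(n_tads = 40, seed = 3, radius = 1.0)
  pos0 <- make_linear_chains(sys, "CIS-X7N", seed = 2)
  col <- collapse_chains(sys, pos0, "CIS-X7N", n_steps = 1e4, seed = 5)
  fin <- assemble_and_shrink(sys, col$positions, stages = 6,
                             steps_per_stage = 1500, seed = 6)
  rr <- sqrt(rowSums(fin$positions^2))
  expect_true(all(rr <= sys$nucleus_radius - sys$beads$radius_um))
  i <- sys$bonds$i + 1L; j <- sys$bonds$j + 1L
  blen <- sqrt(rowSums((fin$positions[i, ] - fin$positions[j, ])^2))
  expect_true(all(blen < 3 * sys$bonds$r0))
})

test_that("initialized nuclei are territorial", {
  sys <- small_system()
  st <- small_state()
  mixing <- territory_mixing(sys, st$positions)
  # baseline: same coordinates with arm labels shuffled
  set.seed(1)
  shuffled <- sys
  tad_rows <- which(sys$beads$kind == "TAD")
  shuffled$beads$arm[tad_rows] <- sample(sys$beads$arm[tad_rows])
  expect_lt(mixing, 0.35)
  expect_lt(mixing, 0.5 * territory_mixing(shuffled, st$positions))
})

test_that("unknown topologies are rejected; roster names are canonical", {
  sys <- tiny_system()
  expect_error(make_linear_chains(sys, "CIS-X9Q"), "unknown topology")
  expect_setequal(topology_names(),
                  c("CIS-X6S", "CIS-X7N", "TRANS-X3S", "TRANS-X4N"))
})
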