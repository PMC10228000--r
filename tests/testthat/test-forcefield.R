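test_that("LJ-cos pair potential has the stated shape", {
  sigma <- 0.2; eps <- 1.5; omega <- 0.25 * sigma
  rmin <- 2^(1 / 6) * sigma
  # well minimum of depth -eps at 2^(1/6) sigma
  expect_equal(pair_energy(rmin, sigma, eps), -eps)
  # exactly zero at and beyond the cutoff
  expect_equal(pair_energy(rmin + omega, sigma, eps), 0)
  expect_equal(pair_energy(rmin + omega + 0.3, sigma, eps), 0)
  # half depth at the taper midpoint (cos^2(pi/4) = 1/2)
  expect_equal(pair_energy(rmin + omega / 2, sigma, eps), -eps / 2)
  expect_error(pair_energy(-0.1, sigma, eps), "positive")
})

test_that("pair potential is C1: derivative matches finite differences", {
  sigma <- 0.15; eps <- 2; h <- 1e-7
  # probe points sit just off the branch boundaries so the FD stencil never
  # straddles a change of analytic form
  rs <- c(0.9 * sigma, 2^(1 / 6) * sigma - 1e-6, 2^(1 / 6) * sigma + 1e-6,
          1.2 * sigma, 2^(1 / 6) * sigma + 0.25 * sigma - 1e-6)
  for (r in rs) {
    fd <- -(pair_energy(r + h, sigma, eps) - pair_energy(r - h, sigma, eps)) / (2 * h)
    # absolute scale: the derivative vanishes at the minimum
    expect_lt(abs(pair_force(r, sigma, eps) - fd), 1e-4 * max(1, abs(fd)))
  }
  # continuity of the value across the minimum and the cutoff
  expect_equal(pair_energy(2^(1 / 6) * sigma - 1e-10, sigma, eps),
               pair_energy(2^(1 / 6) * sigma + 1e-10, sigma, eps),
               tolerance = 1e-6)
})

test_that("soft-core cap keeps overlap energies finite with constant force", {
  sigma <- 0.2; eps <- 1
  u_small <- pair_energy(c(1e-4, 0.01, 0.02), sigma, eps)
  expect_true(all(is.finite(u_small)))
  # inside the cap radius the force is constant (linear continuation)
  f <- pair_force(c(0.01, 0.02, 0.03), sigma, eps)
  expect_equal(f[1], f[2])
  expect_equal(f[2], f[3])
  # and the energy at the cap radius is the cap value
  expect_gt(u_small[1], 50)
})

test_that("purely repulsive branch is zero beyond contact", {
  sigma <- 0.2
  expect_equal(pair_energy(2^(1 / 6) * sigma + 1e-9, sigma, 0), 0)
  expect_gt(pair_energy(0.9 * sigma, sigma, 0), 0)
})

test_that("wall potential has well depth eps_l for L-TADs only", {
  r <- 0.09
  # well minimum at d = bead radius with the configured depth
  expect_equal(wall_energy(r, r, TRUE, 4), -4)
  expect_equal(wall_energy(r, r, TRUE, 0.1), -0.1)
  # non-L-TAD beads: purely repulsive, zero beyond contact
  expect_equal(wall_energy(r + 1e-6, r, FALSE, 4), 0)
  expect_gt(wall_energy(0.5 * r, r, FALSE, 4), 0)
  # outside the nucleus: clamped with a warning, finite
  expect_warning(u <- wall_energy(-0.05, r, TRUE, 4), "clamped")
  expect_true(is.finite(u))
})

test_that("bond energy is harmonic and symmetric about r0", {
  expect_equal(bond_energy(0.3, 0.3, 100), 0)
  expect_equal(bond_energy(0.35, 0.3, 100), bond_energy(0.25, 0.3, 100))
  expect_equal(bond_energy(0.4, 0.3, 100), 0.5 * 100 * 0.01)
})

test_that("specific-pair depths follow the log-enrichment fit", {
  pr <- tibble::tibble(tad_i = 0:3, tad_j = 10:13,
                       enrichment = c(1, exp(1), exp(2), exp(10)))
  d <- specific_pair_depths(pr, a = 0, b = 1, cap = 6)
  expect_equal(d$well_depth, c(0, 1, 2, 6))  # clamped at the cap
  # monotone non-decreasing in enrichment for b > 0
  expect_true(all(diff(d$well_depth[order(d$enrichment)]) >= 0))
  # depth = a at enrichment 1
  expect_equal(specific_pair_depths(pr[1, ], a = 0.7)$well_depth, 0.7)
  expect_error(specific_pair_depths(dplyr::mutate(pr, enrichment = -1)),
               "positive")
  expect_error(specific_pair_depths(tibble::tibble(tad_i = 1, tad_j = 1,
                                                   enrichment = 2)),
               "distinct")
})

test_that("WT and mutant parameter sets match the published values", {
  wt <- wt_parameters()
  expect_equal(diag(wt$class_eps),
               c(Active = 0.1, Null = 1.5, PcG = 1.5, HP1 = 1.5))
  off <- wt$class_eps[upper.tri(wt$class_eps)]
  expect_true(all(off == 0.5))
  expect_equal(wt$eps_l, 4.0)
  mut <- lamin_mutant_parameters()
  expect_equal(mut$eps_l, 0.1)
  # mutant differs from WT only in the LAD-NE affinity
  expect_identical(mut$class_eps, wt$class_eps)
})

test_that("the WT matrix satisfies the Flory-Huggins criterion", {
  fh <- flory_huggins_check(wt_parameters())
  expect_true(all(fh$satisfied))
  an <- fh[fh$class_a == "Active" & fh$class_b == "Null", ]
  expect_equal(an$bound, (0.1 + 1.5) / 2)
  expect_lt(an$eps_ab, an$bound)
})

test_that("energy decomposition is exact: zeroing a term removes it", {
  sys <- tiny_system()
  set.seed(8)
  n <- nrow(sys$beads)
  pos <- matrix(rnorm(3 * n, sd = 0.3), ncol = 3)

  pairs <- specific_pair_depths(
    synth_specific_pairs(synth_genome(n_tads = 12, seed = 2),
                         n_pairs = 3, min_separation = 5, seed = 1))
  ff_full <- forcefield(sys, specific_pairs = pairs)
  ff_nospec <- forcefield(sys)
  e_full <- total_energy(ff_full, pos)
  e_nospec <- total_energy(ff_nospec, pos)
  cf <- attr(e_full, "components"); cn <- attr(e_nospec, "components")
  expect_equal(cn[["specific"]], 0)
  expect_equal(cf[names(cf) != "specific"], cn[names(cn) != "specific"])
  expect_equal(sum(cf), as.numeric(e_full))

  # removing the NE zeroes the wall component and only that
  ff_off <- remove_ne(ff_full)
  co <- attr(total_energy(ff_off, pos), "components")
  expect_equal(co[["wall"]], 0)
  expect_equal(co[["bond"]], cf[["bond"]])
  expect_equal(co[["nonbonded"]], cf[["nonbonded"]])
})

test_that("energy is invariant under global rotation about the center", {
  sys <- tiny_system()
  set.seed(10)
  n <- nrow(sys$beads)
  pos <- matrix(rnorm(3 * n, sd = 0.25), ncol = 3)
  ff <- forcefield(sys)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(as.numeric(total_energy(ff, pos %*% rot)),
               as.numeric(total_energy(ff, pos)), tolerance = 1e-10)
})

test_that("two isolated beads beyond the cutoff do not interact", {
  sys <- tiny_system()
  n <- nrow(sys$beads)
  # string the chain out along x with huge spacing; all pair terms vanish
  pos <- cbind(seq_len(n) * 5, 0, 0)
  ff <- forcefield(sys, ne_on = FALSE, nucleolus_k = 0)
  comps <- attr(total_energy(ff, pos), "components")
  expect_equal(comps[["nonbonded"]], 0)
})

test_that("forces equal minus the energy gradient (finite differences)", {
  sys <- tiny_system()
  ff <- forcefield(sys, specific_pairs = specific_pair_depths(
    synth_specific_pairs(synth_genome(n_tads = 12, seed = 2),
                         n_pairs = 3, min_separation = 5, seed = 1)))
  n <- nrow(sys$beads)
  set.seed(14)
  h <- 1e-6
  for (rep in 1:8) {
    pos <- matrix(rnorm(3 * n, sd = 0.35), ncol = 3)
    F <- total_forces(ff, pos)
    for (probe in 1:6) {
      i <- sample(n, 1); d <- sample(3, 1)
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      fd <- -(as.numeric(total_energy(ff, p1)) -
                as.numeric(total_energy(ff, p2))) / (2 * h)
      expect_equal(F[i, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("forcefield hash tracks the parameter set", {
  sys <- tiny_system()
  ff1 <- forcefield(sys)
  ff2 <- forcefield(sys, params = lamin_mutant_parameters())
  expect_false(identical(ff1$hash, ff2$hash))
  expect_identical(ff1$hash, forcefield(sys)$hash)
})
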