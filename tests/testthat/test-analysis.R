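# Hand-buildable contact map with class metadata
toy_map <- function(m, classes, ltad = rep(FALSE, nrow(m))) {
  structure(m, class = c("flynuc_contact_map", "matrix", "array"),
            tad_id = seq_len(nrow(m)) - 1L, epi_class = classes,
            is_ltad = ltad)
}

test_that("contact map: bonded neighbours in contact, distant beads not", {
  sys <- tiny_system(n_tads = 12, seed = 2)
  b <- sys$beads
  n <- nrow(b)
  # place the chain stretched: consecutive beads at rest length (contact),
  # all non-neighbours far apart
  pos <- cbind(cumsum(c(0, 2 * (b$radius_um[-n] + b$radius_um[-1]))), 0, 0)
  tad <- which(b$kind == "TAD")
  pos[tad, 1] <- cumsum(c(0, (b$radius_um[tad[-length(tad)]] +
                              b$radius_um[tad[-1]])))[seq_along(tad)]
  pos[setdiff(seq_len(n), tad), ] <- 100  # park junction beads far away
  arr <- array(rep(pos, 4), dim = c(n, 3, 4))
  tr <- fake_trajectory(arr, sys)
  cm <- contact_map(tr, window_steps = 1e9)
  expect_s3_class(cm, "flynuc_contact_map")
  expect_equal(dim(cm), c(length(tad), length(tad)))
  expect_true(all(diag(cm) == 1))
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  expect_true(all(cm >= 0 & cm <= 1))
  # consecutive TADs of the same arm are within 1.2*(ri+rj): probability 1
  arm_counts <- table(b$arm[tad])
  arm_big <- names(arm_counts)[arm_counts >= 2][1]
  arm1 <- which(b$arm[tad] == arm_big)
  expect_equal(cm[arm1[1], arm1[2]], 1)
  # far pair: zero
  last <- length(tad)
  expect_equal(cm[1, last], 0)
})

test_that("contact map is invariant under snapshot permutation in a window", {
  tr <- wt_trajectory()
  cm1 <- contact_map(tr, window_steps = 1e9, burn_in_windows = 0)
  perm <- sample(n_snapshots(tr))
  tr2 <- tr
  tr2$positions <- tr$positions[, , perm]
  cm2 <- contact_map(tr2, window_steps = 1e9, burn_in_windows = 0)
  expect_equal(unclass(cm1), unclass(cm2), ignore_attr = TRUE)
})

test_that("pearson correlation of maps matches hand arithmetic", {
  a <- matrix(0, 3, 3); a[upper.tri(a)] <- c(1, 2, 4)
  a <- a + t(a); diag(a) <- 1
  b <- matrix(0, 3, 3); b[upper.tri(b)] <- c(2, 1, 3)
  b <- b + t(b); diag(b) <- 1
  # hand-computed: cov = 1, var_a = 7/3, var_b = 1 -> r = sqrt(3/7)
  expect_equal(pearson_maps(a, b), sqrt(3 / 7))
  expect_equal(pearson_maps(a, a), 1)
  expect_equal(pearson_maps(a, max(a) - a), -1)
  expect_error(pearson_maps(a, matrix(1, 2, 2)), "dimensions")
  expect_error(pearson_maps(a, matrix(1, 3, 3)), "variance")
  # stratification drops low-probability reference entries
  expect_equal(pearson_maps(a, b, exclude_below = 2),
               stats::cor(c(1, 4), c(2, 3)))
})

test_that("difference maps are antisymmetric and exact", {
  a <- toy_map(matrix(c(1, .2, .2, 1), 2), c("Active", "Null"))
  b <- toy_map(matrix(c(1, .5, .5, 1), 2), c("Active", "Null"))
  d <- difference_map(a, b)
  expect_equal(unclass(d), matrix(c(0, -.3, -.3, 0), 2), ignore_attr = TRUE)
  expect_equal(unclass(difference_map(b, a)), -unclass(d), ignore_attr = TRUE)
  expect_true(all(unclass(difference_map(a, a)) == 0))
})

test_that("radial density is flat for uniform points and conserves counts", {
  sys <- tiny_system(n_tads = 12, seed = 2)
  n <- nrow(sys$beads)
  set.seed(23)
  ns <- 400
  # uniform points in the sphere via rejection
  runif_ball <- function(k, R) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < k) {
      cand <- matrix(runif(3 * k, -R, R), ncol = 3)
      out <- rbind(out, cand[rowSums(cand^2) < R^2, , drop = FALSE])
    }
    out[seq_len(k), ]
  }
  arr <- array(0, dim = c(n, 3, ns))
  for (s in seq_len(ns)) arr[, , s] <- runif_ball(n, sys$nucleus_radius)
  tr <- fake_trajectory(arr, sys)
  rd <- radial_density(tr, bins = 8, burn_in_steps = 0)
  # conservation: shell-integrated density equals the bead count exactly
  shell_vol <- 4 / 3 * pi * (rd$r_hi^3 - rd$r_lo^3)
  expect_equal(sum(rd$density * shell_vol), n - 1)  # nucleolus excluded
  # flat within sampling error (inner bins have few counts; compare to mean)
  dens_expected <- (n - 1) / (4 / 3 * pi * sys$nucleus_radius^3)
  expect_equal(mean(rd$density[4:8]), dens_expected, tolerance = 0.1)

  # a delta shell: all beads at r = 0.55 R fall into a single bin
  arr2 <- array(0, dim = c(n, 3, 2))
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * sys$nucleus_radius * 0.55
  arr2[, , 1] <- dirs; arr2[, , 2] <- dirs
  rd2 <- radial_density(fake_trajectory(arr2, sys), bins = 8,
                        burn_in_steps = 0, subset = seq_len(n))
  expect_equal(sum(rd2$density > 0), 1)
  expect_true(rd2$density[rd2$r_lo <= 0.55 & rd2$r_hi > 0.55] > 0)
  expect_error(radial_density(tr, subset = integer(0)), "empty")
})

test_that("NE-layer occupancies are exact on constructed geometry", {
  sys <- tiny_system(n_tads = 12, seed = 2, radius = 1.0)
  n <- nrow(sys$beads)
  # half the snapshots at d = 0.05 (inside all layers), half at d = 0.5
  ns <- 10
  arr <- array(0, dim = c(n, 3, ns))
  for (s in seq_len(ns)) {
    d <- if (s <= 5) 0.05 else 0.5
    arr[, 1, s] <- 1.0 - d
  }
  tr <- fake_trajectory(arr, sys)
  ls <- ne_layer_stats(tr)
  expect_true(all(ls$p_adjacent == 0.5))
  expect_true(all(ls$p_contact == 0.5))
  expect_true(all(ls$p_half_volume == 0.5))  # d = 0.5 is outside 0.4 um
  expect_equal(ls$p_half_volume + ls$p_half_volume_inner, rep(1, nrow(ls)))
  expect_equal(attr(ls, "ltad_fraction_ne"), 0.5)
  expect_error(ne_layer_stats(tr, layers = c(adjacent = 1.5)), "thicker")
})

test_that("mobility report counts attachment events and dwells", {
  sys <- tiny_system(n_tads = 12, seed = 2, radius = 1.0)
  n <- nrow(sys$beads)
  ltads <- which(sys$beads$is_ltad)
  skip_if(length(ltads) < 2)
  ns <- 12
  arr <- array(0, dim = c(n, 3, ns))
  # bead A pinned at the NE; bead B alternates 3-in/3-out
  patternB <- rep(c(0.1, 0.6), each = 3, length.out = ns)
  for (s in seq_len(ns)) {
    arr[, 1, s] <- 0.3
    arr[ltads[1], 1, s] <- 1.0 - 0.05
    arr[ltads[2], 1, s] <- 1.0 - patternB[s]
  }
  rep_ <- ltad_mobility_report(fake_trajectory(arr, sys))
  a <- rep_[rep_$tad_id == sys$beads$tad_id[ltads[1]], ]
  expect_equal(a$p_contact, 1)
  expect_equal(a$n_attach, 1)
  expect_equal(a$n_detach, 0)
  b <- rep_[rep_$tad_id == sys$beads$tad_id[ltads[2]], ]
  expect_equal(b$p_contact, 0.5)
  expect_equal(b$n_attach, 2)
  expect_equal(b$mean_dwell_steps, 3 * 1000)
  # a pinned-only system does not reject the static null; mixed ones do
  expect_true(isTRUE(attr(rep_, "static_null_rejected")) ||
                all(rep_$p_contact %in% c(0, 1)))
  short <- fake_trajectory(arr[, , 1:2, drop = FALSE], sys)
  expect_error(ltad_mobility_report(short), "too short")
})

test_that("class contact sums match hand arithmetic", {
  m <- matrix(c(1,  .1, .2, .3,
                .1, 1,  .4, .5,
                .2, .4, 1,  .6,
                .3, .5, .6, 1), 4, byrow = TRUE)
  map <- toy_map(m, c("Null", "Active", "Null", "Active"))
  s <- class_contact_sums(map, "Null", "Active")
  # Null TADs are rows 1 and 3; their Active partners are columns 2 and 4
  expect_equal(s$sum_contact, c(.1 + .3, .4 + .6))
  expect_equal(class_contact_change(map, map, "Null", "Active"), 0)
  expect_error(class_contact_sums(map, "PcG", "Active"), "empty")
  # a uniform 10% enrichment shows up as a 10% mean relative change
  map2 <- toy_map(m * 1.1, c("Null", "Active", "Null", "Active"))
  expect_equal(class_contact_change(map2, map, "Null", "Active"), 0.1)
})

test_that("per-TAD radial distributions flag bimodality correctly", {
  sys <- tiny_system(n_tads = 12, seed = 2, radius = 2.0)
  n <- nrow(sys$beads)
  tid <- sys$beads$tad_id[which(sys$beads$kind == "TAD")[1]]
  bead <- which(sys$beads$tad_id == tid)
  ns <- 600
  set.seed(31)
  make_traj <- function(rvals) {
    arr <- array(0, dim = c(n, 3, ns))
    dirs <- matrix(rnorm(3 * ns), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    for (s in seq_len(ns)) arr[bead, , s] <- dirs[s, ] * rvals[s]
    fake_trajectory(arr, sys)
  }
  # pinned at the wall: unimodal
  pinned <- make_traj(rep(2.0 - 0.07, ns))
  d1 <- per_tad_radial_distribution(pinned, tid)
  expect_false(attr(d1, "bimodal"))
  # 70% wall / 30% deep interior: bimodal
  rmix <- ifelse(runif(ns) < 0.7, 2.0 - 0.07, runif(ns, 0.2, 1.2))
  d2 <- per_tad_radial_distribution(make_traj(rmix), tid)
  expect_true(attr(d2, "bimodal"))
  expect_error(per_tad_radial_distribution(pinned, tid, min_samples = 1e6),
               "samples")
  expect_error(per_tad_radial_distribution(pinned, 99999), "not in the system")
})

test_that("a uniformly wandering TAD sits at the single-TAD density level", {
  # reference level: one TAD anywhere in a 2-um nucleus -> 1/V = 0.0298 um^-3
  sys <- tiny_system(n_tads = 12, seed = 2, radius = 2.0)
  n <- nrow(sys$beads)
  tid <- sys$beads$tad_id[which(sys$beads$kind == "TAD")[1]]
  bead <- which(sys$beads$tad_id == tid)
  set.seed(37)
  ns <- 4000
  arr <- array(0, dim = c(n, 3, ns))
  got <- 0
  while (got < ns) {
    cand <- matrix(runif(3 * ns, -2, 2), ncol = 3)
    cand <- cand[rowSums(cand^2) < 4, , drop = FALSE]
    take <- min(nrow(cand), ns - got)
    for (k in seq_len(take)) arr[bead, , got + k] <- cand[k, ]
    got <- got + take
  }
  d <- per_tad_radial_distribution(fake_trajectory(arr, sys), tid, bins = 10)
  vol <- 4 / 3 * pi * 2^3
  expect_equal(1 / vol, 0.0298, tolerance = 0.01)
  mid <- d$density[d$r_mid > 0.8 & d$r_mid < 1.8]
  expect_equal(mean(mid), 1 / vol, tolerance = 0.15)
})

test_that("with eps_l near zero, L-TADs are indistinguishable from others", {
  tr <- mutant_trajectory()
  ls <- ne_layer_stats(tr, burn_in_steps = 2e5)
  tads <- ls[!is.na(ls$tad_id), ]
  w <- stats::wilcox.test(tads$p_contact[tads$is_ltad],
                          tads$p_contact[!tads$is_ltad])
  expect_gt(w$p.value, 0.01)
})
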