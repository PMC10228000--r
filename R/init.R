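## Initial configurations: territorial, Rabl-polarized chromosome arms.
## The five large arms (2L, 2R, 3L, 3R, X) occupy five non-overlapping 72
## degree dihedral wedges about the z-axis; Chr 4 sits at the North pole.
## Four experimentally observed topologies are provided: CIS arrangements
## place the two R-arms (and the two L-arms) of the autosomes next to each
## other in azimuth, TRANS is the complementary arrangement; the X6S/X7N/
## X3S/X4N suffix gives the pole of Chr X.

.topologies <- list(
  "CIS-X6S"   = list(order = c("2R", "3R", "X", "3L", "2L"), x_pole = "S"),
  "CIS-X7N"   = list(order = c("2R", "3R", "X", "3L", "2L"), x_pole = "N"),
  "TRANS-X3S" = list(order = c("2L", "3R", "X", "3L", "2R"), x_pole = "S"),
  "TRANS-X4N" = list(order = c("2L", "3R", "X", "3L", "2R"), x_pole = "N")
)

#' Available nucleus topologies
#' @return Character vector of topology names.
#' @export
topology_names <- function() names(.topologies)

topology_spec <- function(name) {
  if (!name %in% names(.topologies)) {
    stop("unknown topology `", name, "`; one of ",
         paste(names(.topologies), collapse = ", "), call. = FALSE)
  }
  .topologies[[name]]
}

# wedge sector [a, b] (radians) for each big arm under a topology
.wedge_angles <- function(topo) {
  w <- 2 * pi / 5
  ang <- lapply(seq_along(topo$order), function(k) c((k - 1) * w, k * w))
  names(ang) <- topo$order
  ang
}

#' Wedge restraints for a topology
#'
#' Builds the per-bead half-plane restraint data keeping each large arm inside
#' its 72 degree dihedral wedge during chain collapse. Junction beads, Chr 4
#' and the nucleolus are unrestrained.
#'
#' @param system A `flynuc_system`.
#' @param topology Topology name (see [topology_names()]).
#' @return List with inward plane normals `n1`, `n2` (n x 2) and logical
#'   `active`.
#' @export
wedge_restraints <- function(system, topology) {
  topo <- topology_spec(topology)
  ang <- .wedge_angles(topo)
  b <- system$beads
  n <- nrow(b)
  n1 <- matrix(0, n, 2); n2 <- matrix(0, n, 2)
  active <- rep(FALSE, n)
  for (arm in names(ang)) {
    sel <- !is.na(b$arm) & b$arm == arm & b$kind == "TAD"
    a <- ang[[arm]][1]; bb <- ang[[arm]][2]
    n1[sel, 1] <- -sin(a); n1[sel, 2] <- cos(a)
    n2[sel, 1] <- sin(bb); n2[sel, 2] <- -cos(bb)
    active[sel] <- TRUE
  }
  list(n1 = n1, n2 = n2, active = active)
}

# cumulative center positions of beads along a chain segment
.chain_offsets <- function(radii) {
  m <- length(radii)
  if (m == 1) return(0)
  cumsum(c(0, radii[-m] + radii[-1]))
}

#' Straight-chain starting positions for a topology
#'
#' Places every large arm as a straight bead string parallel to the z-axis
#' inside its wedge, polarized centromere-to-telomere (Rabl orientation):
#' centromere-proximal ends near the North pole, or the South pole for Chr X
#' in the S-pole topologies. Consecutive beads touch (spacing r_i + r_j).
#'
#' @param system A `flynuc_system`.
#' @param topology Topology name.
#' @param seed Optional seed for the tiny symmetry-breaking jitter.
#' @param axis_rho Axial distance of each arm string from the z-axis, um.
#' @return n x 3 matrix of positions (um).
#' @export
make_linear_chains <- function(system, topology, seed = NULL, axis_rho = 1.1) {
  stopifnot(inherits(system, "flynuc_system"))
  topo <- topology_spec(topology)
  ang <- .wedge_angles(topo)
  if (!is.null(seed)) set.seed(seed)
  b <- system$beads
  pos <- matrix(0, nrow(b), 3)
  z_top <- 0.5

  arm_axis <- function(arm) {
    th <- mean(ang[[arm]])
    axis_rho * c(cos(th), sin(th))
  }
  place_arm <- function(arm, cen_end = c("last", "first"), pole = "N") {
    cen_end <- match.arg(cen_end)
    sel <- which(!is.na(b$arm) & b$arm == arm & b$kind == "TAD")
    r <- b$radius_um[sel]
    cum <- .chain_offsets(r)
    z <- if (pole == "N") {
      if (cen_end == "last") z_top - (cum[length(cum)] - cum) else z_top - cum
    } else {
      # centromere-proximal end at the South extremity
      if (cen_end == "last") -z_top - cum else -z_top - (cum[length(cum)] - cum)
    }
    xy <- arm_axis(arm)
    pos[sel, 1] <<- xy[1]
    pos[sel, 2] <<- xy[2]
    pos[sel, 3] <<- z
    sel
  }

  place_arm("2L", "last"); place_arm("2R", "first")
  place_arm("3L", "last"); place_arm("3R", "first")
  x_pole <- topo$x_pole
  xsel <- place_arm("X", "last", pole = x_pole)

  # junction beads of Chr 2 and 3: between the centromeric arm ends
  for (chr in c("2", "3")) {
    jsel <- which(!is.na(b$chain) & b$chain == chr & b$kind != "TAD")
    pA <- c(arm_axis(paste0(chr, "L")), z_top)
    pB <- c(arm_axis(paste0(chr, "R")), z_top)
    for (k in seq_along(jsel)) {
      f <- k / (length(jsel) + 1)
      pos[jsel[k], ] <- (1 - f) * pA + f * pB + c(0, 0, 0.3)
    }
  }
  # Chr X junction: HET then CEN continuing past the centromere-proximal end
  xj <- which(!is.na(b$chain) & b$chain == "X" & b$kind != "TAD")
  x_end <- xsel[length(xsel)]
  zdir <- if (x_pole == "N") 1 else -1
  prev <- x_end
  for (k in seq_along(xj)) {
    step <- b$radius_um[prev] + b$radius_um[xj[k]]
    pos[xj[k], ] <- pos[prev, ] + c(0, 0, zdir * step)
    prev <- xj[k]
  }
  # Chr 4 at the North pole, near the axis, CEN first
  c4 <- which(!is.na(b$chain) & b$chain == "4")
  r4 <- b$radius_um[c4]
  cum4 <- .chain_offsets(r4)
  pos[c4, 1] <- 0.08
  pos[c4, 2] <- 0.08
  pos[c4, 3] <- 1.2 - cum4

  # nucleolus at half the nuclear radius
  pos[system$nucleolus_index, ] <- c(0, -system$nucleus_radius / 2, 0)

  pos + matrix(rnorm(length(pos), sd = 0.005), ncol = 3)
}

#' Collapse straight chains into compact arm globules
#'
#' Runs Langevin dynamics with a weak harmonic spring between every chain bead
#' and the nucleus center (equilibrium length 0.99 um, spring constant 0.5
#' kT/um^2) plus the wedge restraints, collapsing each straight arm into a
#' compact fractal-like globule while keeping arms territorial. The center
#' spring is used only here and removed from all later stages. Default length
#' 1e5 steps of 1.36 ns.
#'
#' @param system A `flynuc_system`.
#' @param positions Output of [make_linear_chains()].
#' @param topology Topology name (for the wedge restraints).
#' @param n_steps Number of Langevin steps (default 1e5).
#' @param gamma Friction, 1/tau (default 1; the preparation stages use the
#'   high-friction preset).
#' @param kappa,l0 Center spring constant (kT/um^2) and equilibrium length
#'   (um).
#' @param params Interaction parameters used for the excluded-volume and
#'   class terms during collapse.
#' @param seed Seed for the thermal noise.
#' @return List with `positions` and `velocities` matrices.
#' @export
collapse_chains <- function(system, positions, topology,
                            n_steps = 1e5, gamma = 1,
                            kappa = 0.5, l0 = 0.99,
                            params = wt_parameters(), seed = NULL) {
  ff <- forcefield(system, params = params, ne_on = FALSE,
                   center_kappa = kappa, center_l0 = l0,
                   wedges = wedge_restraints(system, topology))
  if (!is.null(seed)) set.seed(seed)
  vel <- mb_velocities(system)
  res <- cpp_run_langevin(ff$data, positions, vel, as.integer(n_steps),
                          .TSTEP_TAU, gamma, 1.0,
                          as.integer(n_steps), 20L, 0.15)
  if (!res$ok) {
    stop("chain collapse diverged at step ", res$bad_step, call. = FALSE)
  }
  list(positions = res$positions, velocities = res$velocities)
}

#' Shrink the assembled nucleus to its final radius
#'
#' Surrounds the collapsed chromosomes with a large repulsive sphere and runs
#' a schedule of short Langevin simulations while the sphere radius decreases
#' geometrically to `final_radius` (default 10 stages of 1e4 steps). Wedge and
#' center restraints are off; the nucleolus is restrained at half the final
#' radius. The returned configuration has every bead strictly inside the
#' final sphere (violating beads, if any, are projected onto the allowed
#' shell at the end).
#'
#' @param system A `flynuc_system`.
#' @param positions Collapsed positions.
#' @param final_radius Target nucleus radius, um (default the system's).
#' @param stages,steps_per_stage Shrink schedule (defaults 10 x 1e4 steps).
#' @param gamma Friction, 1/tau (default 1).
#' @param params Interaction parameters.
#' @param seed Seed for the thermal noise.
#' @return List with `positions` and `velocities`.
#' @export
assemble_and_shrink <- function(system, positions,
                                final_radius = system$nucleus_radius,
                                stages = 10, steps_per_stage = 1e4,
                                gamma = 1, params = wt_parameters(),
                                seed = NULL) {
  stopifnot(inherits(system, "flynuc_system"))
  if (!is.null(seed)) set.seed(seed)
  radii <- system$beads$radius_um
  rr <- sqrt(rowSums(positions^2))
  r0 <- max(rr + radii) + 0.2
  if (r0 < final_radius) r0 <- final_radius
  schedule <- r0 * (final_radius / r0)^(seq_len(stages) / stages)
  vel <- mb_velocities(system)
  pos <- positions
  for (rs in schedule) {
    ff <- forcefield(system, params = params, ne_on = FALSE,
                     confine_radius = rs)
    res <- cpp_run_langevin(ff$data, pos, vel, as.integer(steps_per_stage),
                            .TSTEP_TAU, gamma, 1.0,
                            as.integer(steps_per_stage), 20L, 0.15)
    if (!res$ok) {
      stop("shrink stage diverged at step ", res$bad_step, call. = FALSE)
    }
    pos <- res$positions; vel <- res$velocities
    rr <- sqrt(rowSums(pos^2))
    if (any(rr > rs + 0.5)) {
      stop("bead escaped the restraining sphere during shrink", call. = FALSE)
    }
  }
  # guarantee all beads strictly inside the final sphere
  rr <- sqrt(rowSums(pos^2))
  lim <- final_radius - 1.01 * radii
  bad <- rr > lim
  if (any(bad)) {
    scale <- lim[bad] / rr[bad]
    pos[bad, ] <- pos[bad, , drop = FALSE] * scale
  }
  list(positions = pos, velocities = vel)
}

#' Prepare a starting nucleus state
#'
#' Full initialization pipeline: straight wedge-restrained chains, chain
#' collapse with the center spring, assembly and sphere shrinking to the
#' nuclear radius.
#'
#' @inheritParams collapse_chains
#' @inheritParams assemble_and_shrink
#' @param seed Master seed for the whole pipeline.
#' @param collapse_steps Steps for the collapse stage (default 1e5).
#' @return A `flynuc_state`: list with `positions`, `velocities`, `system`,
#'   `topology`, `step` (0) and provenance.
#' @export
init_nucleus <- function(system, topology = "CIS-X6S", seed = 1,
                         collapse_steps = 1e5, stages = 10,
                         steps_per_stage = 1e4, gamma = 1,
                         params = wt_parameters()) {
  set.seed(seed)
  pos <- make_linear_chains(system, topology)
  col <- collapse_chains(system, pos, topology, n_steps = collapse_steps,
                         gamma = gamma, params = params)
  fin <- assemble_and_shrink(system, col$positions,
                             stages = stages,
                             steps_per_stage = steps_per_stage,
                             gamma = gamma, params = params)
  structure(
    list(positions = fin$positions, velocities = mb_velocities(system),
         system = system, topology = topology, step = 0L,
         provenance = list(seed = seed, collapse_steps = collapse_steps,
                           stages = stages,
                           steps_per_stage = steps_per_stage, gamma = gamma)),
    class = "flynuc_state"
  )
}

#' @export
print.flynuc_state <- function(x, ...) {
  cat(sprintf("<flynuc_state> %d beads, topology %s, R = %g um, step %d\n",
              nrow(x$positions), x$topology, x$system$nucleus_radius, x$step))
  invisible(x)
}

# Maxwell-Boltzmann velocities at kT = 1 from the reduced bead masses
mb_velocities <- function(system, kT = 1) {
  m <- system$beads$mass_red
  matrix(rnorm(3 * length(m), sd = rep(sqrt(kT / m), 3)), ncol = 3)
}

#' Chain-territory mixing score
#'
#' For every TAD bead, the fraction of its `k` nearest TAD beads that belong
#' to a different arm, averaged over beads. Fully territorial configurations
#' score near 0; well-mixed ones approach the arm-frequency-weighted maximum.
#'
#' @param system A `flynuc_system`.
#' @param positions n x 3 position matrix.
#' @param k Neighbours per bead (default 5).
#' @return A single number in `[0, 1]`.
#' @export
territory_mixing <- function(system, positions, k = 5) {
  sel <- which(system$beads$kind == "TAD")
  p <- positions[sel, , drop = FALSE]
  arm <- system$beads$arm[sel]
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  mix <- vapply(seq_along(sel), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(arm[nb] != arm[i])
  }, numeric(1))
  mean(mix)
}

#' Fraction of arm beads inside their topology wedge
#'
#' @param system A `flynuc_system`.
#' @param positions n x 3 position matrix.
#' @param topology Topology name.
#' @param tolerance Allowed penetration distance past a wedge plane, um
#'   (default 0). The wedge restraints are harmonic, so beads fluctuate a
#'   thermal width `sqrt(kT/k_wedge)` past the planes; a small tolerance
#'   counts such beads as inside.
#' @return Named numeric vector, one entry per restrained arm.
#' @export
wedge_occupancy <- function(system, positions, topology, tolerance = 0) {
  w <- wedge_restraints(system, topology)
  b <- system$beads
  arms <- intersect(c("2L", "2R", "3L", "3R", "X"), unique(b$arm))
  out <- vapply(arms, function(a) {
    sel <- which(!is.na(b$arm) & b$arm == a & b$kind == "TAD")
    v1 <- positions[sel, 1] * w$n1[sel, 1] + positions[sel, 2] * w$n1[sel, 2]
    v2 <- positions[sel, 1] * w$n2[sel, 1] + positions[sel, 2] * w$n2[sel, 2]
    mean(v1 >= -tolerance - 1e-9 & v2 >= -tolerance - 1e-9)
  }, numeric(1))
  names(out) <- arms
  out
}
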