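#' Wild-type and Lamin-mutant interaction parameter sets
#'
#' The wild-type set: Active-Active 0.1 kT, Null-Null 1.5 kT, PcG-PcG 1.5 kT,
#' HP1-HP1 1.5 kT, all unlike class pairs 0.5 kT, and L-TAD to nuclear
#' envelope affinity eps_L = 4 kT. The Lamin-mutant set is identical except
#' that eps_L is reduced to essentially zero (0.1 kT), modelling lamin
#' depletion. The wild-type matrix satisfies the Flory-Huggins phase
#' separation criterion for every unlike pair (see [flory_huggins_check()]).
#'
#' @return A `flynuc_params` object: list with `class_eps` (symmetric 4x4
#'   matrix of well depths, kT), `eps_l` (kT) and `label`.
#' @export
wt_parameters <- function() {
  m <- matrix(0.5, 4, 4, dimnames = list(flynuc_classes, flynuc_classes))
  diag(m) <- c(0.1, 1.5, 1.5, 1.5)
  structure(list(class_eps = m, eps_l = 4.0, label = "WT"),
            class = "flynuc_params")
}

#' @rdname wt_parameters
#' @export
lamin_mutant_parameters <- function() {
  p <- wt_parameters()
  p$eps_l <- 0.1
  p$label <- "LaminMutant"
  p
}

#' @export
print.flynuc_params <- function(x, ...) {
  cat(sprintf("<flynuc_params> %s (eps_L = %g kT)\n", x$label, x$eps_l))
  print(x$class_eps)
  invisible(x)
}

#' Flory-Huggins phase-separation check
#'
#' Verifies the microphase-separation condition eps_AB < (eps_AA + eps_BB)/2
#' for every unlike pair of epigenetic classes in a parameter set.
#'
#' @param params A `flynuc_params`.
#' @return Tibble with one row per unlike pair: `class_a`, `class_b`,
#'   `eps_ab`, `bound`, `satisfied`.
#' @export
flory_huggins_check <- function(params) {
  m <- params$class_eps
  cls <- rownames(m)
  combs <- utils::combn(cls, 2)
  tibble::tibble(
    class_a = combs[1, ], class_b = combs[2, ],
    eps_ab = m[cbind(combs[1, ], combs[2, ])],
    bound = (m[cbind(combs[1, ], combs[1, ])] +
             m[cbind(combs[2, ], combs[2, ])]) / 2
  ) |>
    dplyr::mutate(satisfied = .data$eps_ab < .data$bound)
}

#' LJ-cos pair potential
#'
#' Repulsive 12-6 core for r below the minimum position 2^(1/6) sigma (with a
#' linear "soft-bead" continuation once the core energy reaches `cap`), a well
#' of depth `-eps` at the minimum, and a cos^2 taper that reaches exactly zero
#' at the cutoff 2^(1/6) sigma + omega. Value and first derivative are
#' continuous everywhere. With `eps = 0` the potential degenerates to a purely
#' repulsive (Weeks-Chandler-Andersen) wall of amplitude `eps_rep`.
#'
#' @param r Center-center distances, um (positive).
#' @param sigma Contact distance r_i + r_j, um.
#' @param eps Well depth, kT (>= 0).
#' @param omega Taper width, um; default 0.25 sigma (the taper-width calibration selected by the model-development criteria).
#' @param eps_rep Repulsion amplitude used when `eps = 0`, kT (default 3).
#' @param cap Soft-core cap energy, kT (default 50).
#' @return Energies in kT (`pair_energy`) or radial derivatives -dU/dr i.e.
#'   forces along r (`pair_force`).
#' @export
pair_energy <- function(r, sigma, eps, omega = 0.25 * sigma,
                        eps_rep = 3, cap = 50) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  cpp_pair_potential(r, sigma, eps, eps_rep, omega / sigma, cap, FALSE)
}

#' @rdname pair_energy
#' @export
pair_force <- function(r, sigma, eps, omega = 0.25 * sigma,
                       eps_rep = 3, cap = 50) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  -cpp_pair_potential(r, sigma, eps, eps_rep, omega / sigma, cap, TRUE)
}

#' Nuclear-envelope wall energy for a single bead
#'
#' Energy as a function of the distance `d` of the bead center from the inner
#' envelope surface. L-TAD beads feel an LJ-cos well of depth `eps_l` with its
#' minimum at `d = radius` (bead touching the wall); all other beads feel only
#' the repulsive core, which likewise turns on below `d = radius`. Negative
#' `d` (bead center outside the nucleus) is clamped to 0 with a warning.
#'
#' @param d Distance from the inner NE surface, um.
#' @param radius Bead radius, um.
#' @param is_ltad Does the bead contain a LAD?
#' @param eps_l LAD-NE affinity, kT.
#' @inheritParams pair_energy
#' @return Energy in kT.
#' @export
wall_energy <- function(d, radius, is_ltad, eps_l,
                        omega = 0.25 * radius / 2^(1 / 6), eps_rep = 3,
                        cap = 50) {
  if (any(d < 0)) {
    warning(sum(d < 0), " bead distance(s) outside the nucleus clamped to 0")
    d <- pmax(d, 0)
  }
  d <- pmax(d, 1e-9)
  eps <- if (isTRUE(is_ltad)) eps_l else 0
  sw <- radius / 2^(1 / 6)
  cpp_pair_potential(d, sw, eps, eps_rep, omega / sw, cap, FALSE)
}

#' Harmonic backbone bond energy
#'
#' `U = k/2 (r - r0)^2` with rest length `r0 = r_i + r_j`.
#'
#' @param r Distance, um.
#' @param r0 Rest length, um.
#' @param k Stiffness, kT/um^2.
#' @export
bond_energy <- function(r, r0, k) {
  0.5 * k * (r - r0)^2
}

#' Well depths for specific long-range TAD pairs
#'
#' Maps contact-probability enrichments of the specific pairs to attractive
#' well depths via `depth = a + b * log(enrichment)`, clamped to `[0, cap]`.
#'
#' @param pairs Tibble with columns `tad_i`, `tad_j`, `enrichment` (> 0).
#' @param a,b Fit coefficients (kT and kT per log-enrichment unit; defaults 0
#'   and 1).
#' @param cap Maximum depth, kT (default 6).
#' @return The input with a `well_depth` column added.
#' @export
specific_pair_depths <- function(pairs, a = 0, b = 1, cap = 6) {
  stopifnot(all(c("tad_i", "tad_j", "enrichment") %in% names(pairs)))
  if (any(pairs$enrichment <= 0)) {
    stop("enrichments must be positive", call. = FALSE)
  }
  if (any(pairs$tad_i == pairs$tad_j)) {
    stop("specific pairs must join distinct TADs", call. = FALSE)
  }
  dplyr::mutate(pairs,
                well_depth = pmin(pmax(a + b * log(.data$enrichment), 0), cap))
}

#' Assemble the full force field for a bead system
#'
#' Collects every energy term acting on the system: harmonic backbone bonds,
#' class-pair LJ-cos attractions between non-bonded beads, extra wells for the
#' specific long-range pairs, the spherical NE wall (attractive for L-TADs
#' with depth `eps_l`, purely repulsive otherwise), the optional plain
#' confinement sphere and chain-collapse center spring used during
#' initialization, the nucleolus radial restraint, and optional wedge
#' restraints keeping arms territorial.
#'
#' @param system A `flynuc_system`.
#' @param params A `flynuc_params` (default [wt_parameters()]).
#' @param specific_pairs Optional tibble from [specific_pair_depths()] (or
#'   with an `enrichment` column, in which case depths are computed with the
#'   defaults).
#' @param ne_on Include the nuclear envelope (default TRUE).
#' @param confine_radius Radius of a plain repulsive confinement sphere, um
#'   (default `NA` = off; used during assembly/shrink).
#' @param center_kappa,center_l0 Chain-collapse center spring `U = kappa/2
#'   (|r| - l0)^2` per bead; `center_kappa = 0` (default) disables it, the
#'   collapse stage uses kappa = 0.5 kT/um^2 and l0 = 0.99 um.
#' @param wedges Optional wedge restraint list from [wedge_restraints()].
#' @param k_bond Dimensionless bond stiffness; the actual spring constant per
#'   bond is `k_bond / sigma_ij^2` kT/um^2 (default 30).
#' @param het_eps Attraction of HET/CEN beads to every chain bead class, kT
#'   (default 0.5, the cross-type level).
#' @param omega_factor Taper width as a fraction of sigma (default 0.25, selected during model development; see the methods vignette).
#' @param eps_rep Repulsive amplitude for eps = 0 pairs, kT (default 3).
#' @param cap_u Soft-core cap, kT (default 50).
#' @param exclude_bonded Exclude bonded neighbours from non-bonded sums
#'   (default TRUE).
#' @param k_wedge Wedge restraint stiffness, kT/um^2 (default 10).
#' @param nucleolus_k Nucleolus radial restraint stiffness, kT/um^2
#'   (default 100).
#' @return A `flynuc_forcefield` object.
#' @export
forcefield <- function(system, params = wt_parameters(),
                       specific_pairs = NULL,
                       ne_on = TRUE, confine_radius = NA,
                       center_kappa = 0, center_l0 = 0.99,
                       wedges = NULL,
                       k_bond = 30, het_eps = 0.5,
                       omega_factor = 0.25, eps_rep = 3, cap_u = 50,
                       exclude_bonded = TRUE,
                       k_wedge = 10, nucleolus_k = 100) {
  stopifnot(inherits(system, "flynuc_system"))
  b <- system$beads
  n <- nrow(b)
  # canonical form so equal parameter values always hash identically
  params <- structure(list(class_eps = params$class_eps,
                           eps_l = params$eps_l, label = params$label),
                      class = "flynuc_params")

  eps <- matrix(0, 7, 7)
  eps[1:4, 1:4] <- params$class_eps
  eps[5:6, 1:6] <- het_eps
  eps[1:6, 5:6] <- het_eps
  eps[7, ] <- 0; eps[, 7] <- 0  # nucleolus: excluded volume only

  spec_i <- integer(0); spec_j <- integer(0); spec_eps <- numeric(0)
  if (!is.null(specific_pairs) && nrow(specific_pairs) > 0) {
    if (!"well_depth" %in% names(specific_pairs)) {
      specific_pairs <- specific_pair_depths(specific_pairs)
    }
    # map TAD ids to bead indices (0-based)
    tad_to_bead <- setNames(b$bead_id[!is.na(b$tad_id)] - 1L,
                            b$tad_id[!is.na(b$tad_id)])
    spec_i <- unname(tad_to_bead[as.character(specific_pairs$tad_i)])
    spec_j <- unname(tad_to_bead[as.character(specific_pairs$tad_j)])
    if (any(is.na(spec_i)) || any(is.na(spec_j))) {
      stop("specific pairs refer to TAD ids absent from the system", call. = FALSE)
    }
    spec_eps <- specific_pairs$well_depth
  }

  bonds <- system$bonds
  sig_b <- bonds$r0
  bond_k <- k_bond / sig_b^2

  sigma_max <- 2 * max(b$radius_um)
  cutoff <- (2^(1 / 6) + omega_factor) * sigma_max

  wedge_n1 <- NULL; wedge_n2 <- NULL; wedge_active <- NULL
  if (!is.null(wedges)) {
    wedge_n1 <- wedges$n1; wedge_n2 <- wedges$n2; wedge_active <- wedges$active
    stopifnot(nrow(wedge_n1) == n, length(wedge_active) == n)
  }

  ff <- list(
    radius = b$radius_um, mass = b$mass_red,
    type = as.integer(b$type), is_ltad = b$is_ltad,
    eps = eps,
    bonds = as.matrix(bonds[, c("i", "j")]),
    bond_r0 = bonds$r0, bond_k = bond_k,
    exclude_bonded = exclude_bonded,
    spec_i = spec_i, spec_j = spec_j, spec_eps = spec_eps,
    omega_factor = omega_factor, cap_u = cap_u, eps_rep = eps_rep,
    ne_radius = if (ne_on) system$nucleus_radius else 0,
    eps_l = params$eps_l,
    confine_radius = if (is.na(confine_radius)) 0 else confine_radius,
    nuc_index = system$nucleolus_index - 1L,
    nuc_d0 = system$nucleus_radius / 2, nuc_k = nucleolus_k,
    center_kappa = center_kappa, center_l0 = center_l0,
    wedge_n1 = wedge_n1, wedge_n2 = wedge_n2, wedge_active = wedge_active,
    k_wedge = k_wedge,
    cutoff = cutoff
  )
  out <- structure(
    list(data = ff, params = params, system_n = n,
         nucleus_radius = system$nucleus_radius,
         settings = list(k_bond = k_bond, het_eps = het_eps,
                         omega_factor = omega_factor, eps_rep = eps_rep,
                         cap_u = cap_u, exclude_bonded = exclude_bonded,
                         nucleolus_k = nucleolus_k,
                         n_specific = length(spec_eps))),
    class = "flynuc_forcefield"
  )
  out$hash <- forcefield_hash(out)
  out
}

forcefield_hash <- function(ff) {
  rlang::hash(list(ff$data[setdiff(names(ff$data), "cutoff")], ff$params))
}

#' @export
print.flynuc_forcefield <- function(x, ...) {
  cat(sprintf(
    "<flynuc_forcefield> %s, %d beads, NE %s (eps_L = %g kT), %d specific pairs, hash %s\n",
    x$params$label, x$system_n,
    if (x$data$ne_radius > 0) sprintf("R = %g um", x$data$ne_radius) else "off",
    x$data$eps_l, x$settings$n_specific, substr(x$hash, 1, 8)))
  invisible(x)
}

#' Total potential energy and its decomposition
#'
#' @param ff A `flynuc_forcefield`.
#' @param positions n x 3 matrix of bead positions, um.
#' @return `total_energy`: total in kT with the per-term breakdown (`bond`,
#'   `nonbonded`, `specific`, `wall`, `confine`, `nucleolus`, `center`,
#'   `wedge`) in attribute `"components"`. `total_forces`: n x 3 matrix of
#'   forces (kT/um), equal to minus the energy gradient.
#' @export
total_energy <- function(ff, positions) {
  stopifnot(inherits(ff, "flynuc_forcefield"))
  check_positions(positions, ff$system_n)
  comp <- cpp_energy(ff$data, positions)
  structure(sum(comp), components = comp)
}

#' @rdname total_energy
#' @export
total_forces <- function(ff, positions) {
  stopifnot(inherits(ff, "flynuc_forcefield"))
  check_positions(positions, ff$system_n)
  cpp_forces(ff$data, positions)
}

check_positions <- function(positions, n) {
  if (!is.matrix(positions) || ncol(positions) != 3 || nrow(positions) != n) {
    stop("`positions` must be an n x 3 matrix matching the system", call. = FALSE)
  }
  if (any(!is.finite(positions))) {
    stop("`positions` contains non-finite values", call. = FALSE)
  }
  invisible(positions)
}

#' Remove the nuclear envelope from a force field
#'
#' Deletes the wall and confinement terms so subsequent dynamics runs
#' unconfined - the numerical analogue of dissolving the envelope, under which
#' chromatin de-compacts.
#'
#' @param ff A `flynuc_forcefield`.
#' @return The modified force field.
#' @export
remove_ne <- function(ff) {
  stopifnot(inherits(ff, "flynuc_forcefield"))
  ff$data$ne_radius <- 0
  ff$data$confine_radius <- 0
  ff$hash <- forcefield_hash(ff)
  ff
}
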