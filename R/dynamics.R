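#' Integrate the Langevin dynamics of a nucleus
#'
#' Advances `m_i d2r/dt2 = -grad U - gamma m_i dr/dt + L_i(t)` with a BAOAB
#' velocity-Verlet splitting. The friction is mass-proportional, so the same
#' `gamma` (in units of 1/tau, tau = 136 ns) applies to every bead, and the
#' Gaussian noise satisfies fluctuation-dissipation at `kT` per bead mass; in
#' the `gamma = 0` limit the scheme reduces to plain velocity Verlet. The low
#' friction presets (0.1, 0.01 per tau) keep bead inertia relevant and buy the
#' large speed-up that makes hour-scale biological time reachable.
#'
#' @param state A `flynuc_state` (from [init_nucleus()]) or a previous
#'   trajectory's end state.
#' @param ff A `flynuc_forcefield`.
#' @param n_steps Number of steps of `dt`.
#' @param gamma Langevin friction in 1/tau; presets 1, 0.1, 0.01 (default
#'   0.01, the production value).
#' @param dt Time step in tau (default 0.01, i.e. 1.36 ns).
#' @param kT Temperature (default 1).
#' @param stride Steps between stored snapshots (default `n_steps / 100`,
#'   at least 1).
#' @param seed Optional seed; with a fixed seed runs are bit-identical.
#' @return A `flynuc_trajectory`: list with `snap_steps` (absolute step index
#'   of each snapshot, including the initial state at the current step),
#'   `positions` (n x 3 x n_snap array, um), `kinetic_temp` (instantaneous
#'   kinetic temperature per snapshot), `system`, `end_state`, and
#'   metadata (`gamma`, `dt`, `kT`, `stride`, `forcefield_hash`, `topology`).
#' @export
integrate_dynamics <- function(state, ff, n_steps, gamma = 0.01,
                               dt = .TSTEP_TAU, kT = 1, stride = NULL,
                               seed = NULL) {
  stopifnot(inherits(ff, "flynuc_forcefield"))
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, floor(n_steps / 100))
  if (!is.null(seed)) set.seed(seed)
  pos <- state$positions
  vel <- state$velocities
  if (is.null(vel)) vel <- mb_velocities(state$system, kT)
  check_positions(pos, ff$system_n)
  res <- cpp_run_langevin(ff$data, pos, vel, as.integer(n_steps), dt, gamma,
                          kT, as.integer(stride), 20L, 0.15)
  if (!res$ok) {
    stop("integration diverged at step ", res$bad_step,
         " (", res$n_recorded, " snapshots recorded)", call. = FALSE)
  }
  step0 <- if (!is.null(state$step)) state$step else 0L
  n_rec <- res$n_recorded
  traj <- res$traj
  # prepend the initial configuration as snapshot 0
  n <- nrow(pos)
  all_pos <- array(0, dim = c(n, 3, n_rec + 1))
  all_pos[, , 1] <- pos
  if (n_rec > 0) all_pos[, , 1 + seq_len(n_rec)] <- traj[, , seq_len(n_rec)]
  end_state <- structure(
    list(positions = res$positions, velocities = res$velocities,
         system = state$system, topology = state$topology,
         step = step0 + as.integer(n_steps),
         provenance = state$provenance),
    class = "flynuc_state"
  )
  structure(
    list(snap_steps = c(step0, step0 + res$snap_steps[seq_len(n_rec)]),
         positions = all_pos,
         kinetic_temp = c(
           sum(state$system$beads$mass_red * rowSums(vel^2)) / (3 * nrow(vel)),
           res$snap_ktemp[seq_len(n_rec)]),
         system = state$system,
         end_state = end_state,
         gamma = gamma, dt = dt, kT = kT, stride = as.integer(stride),
         topology = state$topology,
         nucleus_radius = state$system$nucleus_radius,
         forcefield_hash = ff$hash,
         ne_on = ff$data$ne_radius > 0),
    class = "flynuc_trajectory"
  )
}

#' @export
print.flynuc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<flynuc_trajectory> %d beads, %d snapshots, steps %d..%d (gamma = %g/tau)\n",
    dim(x$positions)[1], dim(x$positions)[3],
    x$snap_steps[1], x$snap_steps[length(x$snap_steps)], x$gamma))
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param trajectory A `flynuc_trajectory`.
#' @export
n_snapshots <- function(trajectory) dim(trajectory$positions)[3]

#' Candidate non-bonded pairs within a cutoff
#'
#' Cell-list neighbour search returning every bead pair with center distance
#' at most `cutoff` (a superset of the interacting pairs is acceptable; this
#' implementation returns exactly the pairs within the cutoff).
#'
#' @param positions n x 3 matrix, um.
#' @param cutoff Search radius, um.
#' @return Tibble with 1-based columns `i < j`.
#' @export
neighbor_pairs <- function(positions, cutoff) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, cutoff > 0)
  if (nrow(positions) < 2) {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  m <- cpp_candidate_pairs(positions, cutoff)
  tibble::as_tibble(data.frame(i = m[, 1], j = m[, 2])) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Kinetic temperature of a state
#'
#' `T_kin = 2 E_kin / (3 N kT)` in units of the target temperature.
#'
#' @param state A `flynuc_state` (or any list with `velocities` and `system`).
#' @export
kinetic_temperature <- function(state) {
  m <- state$system$beads$mass_red
  v2 <- rowSums(state$velocities^2)
  sum(m * v2) / (3 * length(m))
}
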