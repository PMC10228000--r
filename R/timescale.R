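## Mapping simulation steps onto biological time. The radial MSD of unlinked
## (non-LAD) beads follows the experimentally observed sub-diffusive law
## MSD = 4 D_app (dt / lambda)^0.39 with 4 D_app = 0.061 um^2; fitting lambda
## (steps per second) against that law calibrates the step -> seconds
## conversion for each friction preset.

.lambda_presets <- tibble::tibble(
  gamma = c(1, 0.1, 0.01),
  lambda = c(20e4, 2.8e4, 1e4)
)

#' Calibrated steps-per-second factors
#'
#' The time-mapping factor lambda (simulation steps per second of biological
#' time) for the three friction presets: 20e4 /s at gamma = 1/tau, 2.8e4 /s at
#' gamma = 0.1/tau, 1e4 /s at gamma = 0.01/tau.
#'
#' @return Tibble with columns `gamma` (1/tau) and `lambda` (steps/s).
#' @export
lambda_presets <- function() .lambda_presets

#' Radial mean squared displacement of selected beads
#'
#' MSD of the distance `R_i(t)` between bead i and the nucleus center,
#' `<[R(t + dt) - R(t)]^2>`, averaged over beads and time origins. By default
#' nine randomly selected non-LAD TAD beads are used, matching the
#' calibration protocol.
#'
#' @param trajectory A `flynuc_trajectory`.
#' @param bead_ids 1-based bead indices; default samples 9 non-L-TAD TAD
#'   beads.
#' @param max_lag Maximum lag in snapshots (default half the trajectory).
#' @param seed Seed for the default bead selection.
#' @return Tibble with `lag_snapshots`, `lag_steps`, `msd` (um^2),
#'   `n_origins`.
#' @export
radial_msd <- function(trajectory, bead_ids = NULL, max_lag = NULL,
                       seed = NULL) {
  stopifnot(inherits(trajectory, "flynuc_trajectory"))
  ns <- n_snapshots(trajectory)
  if (ns < 2) stop("need at least 2 snapshots", call. = FALSE)
  if (is.null(bead_ids)) {
    if (!is.null(seed)) set.seed(seed)
    pool <- which(trajectory$system$beads$kind == "TAD" &
                  !trajectory$system$beads$is_ltad)
    bead_ids <- sample(pool, min(9, length(pool)))
  }
  if (any(bead_ids < 1 | bead_ids > dim(trajectory$positions)[1])) {
    stop("bead ids out of range", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- floor((ns - 1) / 2)
  if (max_lag >= ns) stop("`max_lag` exceeds the trajectory length", call. = FALSE)
  # radial coordinate per bead and snapshot
  p <- trajectory$positions[bead_ids, , , drop = FALSE]
  rmat <- sqrt(apply(p^2, c(1, 3), sum))  # beads x snapshots
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(L) {
    d <- rmat[, (1 + L):ns, drop = FALSE] - rmat[, 1:(ns - L), drop = FALSE]
    mean(d^2)
  }, numeric(1))
  step_per_snap <- diff(trajectory$snap_steps)
  stride <- step_per_snap[1]
  tibble::tibble(
    lag_snapshots = lags,
    lag_steps = lags * stride,
    msd = msd,
    n_origins = (ns - lags) * length(bead_ids)
  )
}

#' Fit the time-mapping factor lambda
#'
#' Least-squares fit of `msd = 4 D_app (lag_steps / lambda)^alpha` with the
#' apparent diffusion constant and the sub-diffusion exponent held fixed at
#' their calibrated values (4 D_app = 0.061 um^2, alpha = 0.39); only lambda
#' is free. Fitting is linear in log space, followed by a 1-D refinement of
#' the linear-space residual sum of squares.
#'
#' @param msd Tibble from [radial_msd()] (columns `lag_steps`, `msd`).
#' @param four_d_app 4 D_app in um^2 (default 0.061).
#' @param exponent Sub-diffusion exponent (default 0.39).
#' @param max_lag_steps Use only lags up to this step count (default 3e5,
#'   the calibration's fitted range).
#' @return A `flynuc_lambda_fit`: list with `lambda` (steps per second),
#'   `rmse`, `n_lags`, the constants, and the fitted curve.
#' @export
fit_lambda <- function(msd, four_d_app = 0.061, exponent = 0.39,
                       max_lag_steps = 3e5) {
  stopifnot(all(c("lag_steps", "msd") %in% names(msd)))
  use <- msd$lag_steps <= max_lag_steps & msd$lag_steps > 0
  if (!any(use)) stop("no lags within the fitted range", call. = FALSE)
  x <- msd$lag_steps[use]; y <- msd$msd[use]
  if (any(y <= 0)) stop("MSD values must be positive to fit", call. = FALSE)
  # closed-form log-space estimate: each lag gives lambda_k = x / (y/4D)^(1/a)
  loglam <- mean(log(x) - log(y / four_d_app) / exponent)
  sse <- function(ll) {
    sum((y - four_d_app * (x / exp(ll))^exponent)^2)
  }
  opt <- optimize(sse, interval = loglam + c(-2, 2), tol = 1e-12)
  lambda <- exp(opt$minimum)
  fitted <- four_d_app * (x / lambda)^exponent
  structure(
    list(lambda = lambda,
         rmse = sqrt(mean((y - fitted)^2)),
         n_lags = length(x),
         four_d_app = four_d_app, exponent = exponent,
         data = tibble::tibble(lag_steps = x, msd = y, fitted = fitted)),
    class = "flynuc_lambda_fit"
  )
}

#' @export
print.flynuc_lambda_fit <- function(x, ...) {
  cat(sprintf(
    "<flynuc_lambda_fit> lambda = %.4g steps/s (rmse %.3g um^2, %d lags)\n",
    x$lambda, x$rmse, x$n_lags))
  invisible(x)
}

#' Convert simulation steps to biological time
#'
#' `seconds = n_steps / lambda(gamma)` using the calibrated presets (or an
#' explicit `lambda`).
#'
#' @param n_steps Number of integration steps.
#' @param gamma Friction preset in 1/tau (1, 0.1 or 0.01).
#' @param lambda Optional explicit steps-per-second factor overriding the
#'   preset.
#' @return Seconds of biological time.
#' @export
#' @examples
#' steps_to_biotime(400e6, gamma = 0.01) / 60  # about 667 minutes
steps_to_biotime <- function(n_steps, gamma = 0.01, lambda = NULL) {
  if (any(n_steps < 0)) stop("`n_steps` must be non-negative", call. = FALSE)
  if (is.null(lambda)) {
    hit <- which(abs(.lambda_presets$gamma - gamma) < 1e-9)
    if (length(hit) != 1) {
      stop("no calibrated lambda for gamma = ", gamma,
           "; supply `lambda` explicitly", call. = FALSE)
    }
    lambda <- .lambda_presets$lambda[hit]
  }
  n_steps / lambda
}

#' Human-readable biological time
#'
#' @param seconds Seconds of biological time.
#' @return Character scalar like "667 min (11.1 h)".
#' @export
format_biotime <- function(seconds) {
  if (seconds < 120) return(sprintf("%.3g s", seconds))
  mins <- seconds / 60
  if (mins < 120) return(sprintf("%.3g min", mins))
  sprintf("%.0f min (%.3g h)", mins, mins / 60)
}
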