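## Internal unit system: lengths in micrometres, energies in kT, time in units
## of the LJ time tau. With the LJ energy scale eps = 3 kT, tau corresponds to
## 136 ns of wall-clock time and the integration step dt = 0.01 tau = 1.36 ns.

#' @export
flynuc_arms <- c("2L", "2R", "3L", "3R", "4", "X")

#' @export
flynuc_classes <- c("Active", "Null", "PcG", "HP1")

## bead kind -> row index (0-based) of the type-pair interaction matrix
.bead_types <- c(Active = 0L, Null = 1L, PcG = 2L, HP1 = 3L,
                 HET = 4L, CEN = 5L, NUC = 6L)

.TAU_NS <- 136            # LJ time in ns
.TSTEP_TAU <- 0.01        # integration step in tau
.TSTEP_NS <- 1.36         # = 0.01 * 136 ns
.EPS_LJ <- 3              # LJ energy scale in kT, anchors tau
.RADIUS_SCALE <- 1.254031 # hard radius -> bead radius (doubled volume)
.MASS_PER_BP <- 132500 / 200 + 660  # Da per bp: nucleosome protein + DNA

#' Mass of a bead representing a pair of homologous TADs
#'
#' The bead mass combines the DNA mass (660 Da/bp) with the protein mass of
#' one nucleosome (132500 Da) per 200 bp repeat, doubled because each bead
#' stands for two homologous TADs: `m = 2 L (132500/200 + 660)` Da.
#'
#' @param length_bp TAD length in base pairs (non-negative).
#' @return Mass in daltons.
#' @export
#' @examples
#' bead_mass(1e5)  # 2.645e8 Da
bead_mass <- function(length_bp) {
  if (any(!is.finite(length_bp)) || any(length_bp < 0)) {
    stop("`length_bp` must be non-negative and finite", call. = FALSE)
  }
  2 * length_bp * .MASS_PER_BP
}

#' Bead radius from the single-TAD hard radius
#'
#' Scales the "hard" radius of one TAD by 1.254031 (= 2^(1/3) within rounding)
#' so that the bead volume accounts for both homologous TADs.
#'
#' @param hard_radius Hard radius of the single TAD, micrometres (> 0).
#' @return Bead radius in micrometres.
#' @export
bead_radius <- function(hard_radius) {
  if (any(!is.finite(hard_radius)) || any(hard_radius <= 0)) {
    stop("`hard_radius` must be positive", call. = FALSE)
  }
  hard_radius * .RADIUS_SCALE
}
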