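#' Build the bead-chain system for a genome annotation
#'
#' Converts an annotation into the beads-on-a-string representation of the
#' diploid genome: one bead per pair of homologous TADs, chained per
#' chromosome with pericentromeric heterochromatin (HET) and centromere (CEN)
#' junction beads - Chr 2 and Chr 3 join their arms through a HET-CEN-HET
#' triplet, Chr 4 starts with a CEN-HET head, Chr X ends with a HET-CEN tail -
#' plus a nucleolus bead of 0.333 um radius restrained at half the nuclear
#' radius. For the fly annotation this yields 1169 + 6 HET + 4 CEN = 1179
#' chain beads.
#'
#' @param annotation A `flynuc_annotation` covering all six arms.
#' @param nucleus_radius Nuclear envelope radius in micrometres (default 2).
#' @param het_radius Radius of HET/CEN junction beads, um (default 0.2).
#' @param het_length_bp Sequence length assigned to HET/CEN beads for their
#'   mass (default 5e5 bp).
#' @param nucleolus_radius Nucleolus bead radius, um (default 0.333).
#' @param nucleolus_mass_bp Sequence-equivalent length setting the nucleolus
#'   mass (default 2e6 bp).
#' @return A `flynuc_system`: list with `beads` (tibble), `bonds` (tibble with
#'   0-based `i`, `j` and rest length `r0`), `nucleus_radius`, and reduced-unit
#'   masses (`mass_red` column) in which the LJ time tau = 1.
#' @export
build_system <- function(annotation, nucleus_radius = 2,
                         het_radius = 0.2, het_length_bp = 5e5,
                         nucleolus_radius = 0.333, nucleolus_mass_bp = 2e6) {
  stopifnot(inherits(annotation, "flynuc_annotation"))
  missing_arms <- setdiff(flynuc_arms, unique(annotation$arm))
  if (length(missing_arms) > 0) {
    stop("annotation does not cover arm(s): ",
         paste(missing_arms, collapse = ", "), call. = FALSE)
  }
  if (nucleus_radius <= 0) stop("`nucleus_radius` must be positive", call. = FALSE)

  tad_row <- function(a) {
    sub <- annotation[annotation$arm == a, ]
    tibble::tibble(
      kind = "TAD", arm = a, tad_id = sub$tad_id,
      epi_class = sub$epi_class, is_ltad = sub$is_ltad,
      length_bp = sub$length_bp,
      radius_um = bead_radius(sub$hard_radius_um),
      mass_da = bead_mass(sub$length_bp)
    )
  }
  junction <- function(kind, arm) {
    tibble::tibble(
      kind = kind, arm = arm, tad_id = NA_integer_,
      epi_class = NA_character_, is_ltad = FALSE,
      length_bp = het_length_bp, radius_um = het_radius,
      mass_da = bead_mass(het_length_bp)
    )
  }
  chain_tabs <- list(
    "2" = dplyr::bind_rows(tad_row("2L"), junction("HET", "2"),
                           junction("CEN", "2"), junction("HET", "2"),
                           tad_row("2R")),
    "3" = dplyr::bind_rows(tad_row("3L"), junction("HET", "3"),
                           junction("CEN", "3"), junction("HET", "3"),
                           tad_row("3R")),
    "4" = dplyr::bind_rows(junction("CEN", "4"), junction("HET", "4"),
                           tad_row("4")),
    "X" = dplyr::bind_rows(tad_row("X"), junction("HET", "X"),
                           junction("CEN", "X"))
  )
  beads <- dplyr::bind_rows(chain_tabs, .id = "chain")
  # bonds connect consecutive beads within each chain (0-based indices)
  offs <- c(0, cumsum(vapply(chain_tabs, nrow, integer(1))))
  bonds <- dplyr::bind_rows(lapply(seq_along(chain_tabs), function(k) {
    n <- nrow(chain_tabs[[k]])
    tibble::tibble(i = offs[k] + seq_len(n - 1) - 1L,
                   j = offs[k] + seq_len(n - 1))
  }))

  nuc <- tibble::tibble(
    chain = NA_character_, kind = "NUC", arm = NA_character_,
    tad_id = NA_integer_, epi_class = NA_character_, is_ltad = FALSE,
    length_bp = nucleolus_mass_bp, radius_um = nucleolus_radius,
    mass_da = bead_mass(nucleolus_mass_bp)
  )
  beads <- dplyr::bind_rows(beads, nuc)
  beads$bead_id <- seq_len(nrow(beads))
  beads$type <- ifelse(beads$kind == "TAD",
                       .bead_types[beads$epi_class],
                       .bead_types[beads$kind])
  beads <- beads[, c("bead_id", "chain", "kind", "arm", "tad_id", "epi_class",
                     "is_ltad", "length_bp", "radius_um", "mass_da", "type")]

  # reduced masses: tau = sigma_min sqrt(m_min / eps_LJ) = 1, with sigma_min
  # and m_min taken over the TAD beads
  tadsel <- beads$kind == "TAD"
  sigma_min <- 2 * min(beads$radius_um[tadsel])
  m_min <- min(beads$mass_da[tadsel])
  beads$mass_red <- .EPS_LJ * (beads$mass_da / m_min) / sigma_min^2

  bonds$r0 <- beads$radius_um[bonds$i + 1L] + beads$radius_um[bonds$j + 1L]

  structure(
    list(beads = beads, bonds = bonds,
         nucleus_radius = nucleus_radius,
         nucleolus_index = nrow(beads),  # 1-based
         sigma_min = sigma_min, mass_min_da = m_min),
    class = "flynuc_system"
  )
}

#' @export
print.flynuc_system <- function(x, ...) {
  k <- table(x$beads$kind)
  cat(sprintf(
    "<flynuc_system> %d beads (%d TAD, %d HET, %d CEN, %d nucleolus), R = %.2f um\n",
    nrow(x$beads), k[["TAD"]], k[["HET"]], k[["CEN"]], k[["NUC"]],
    x$nucleus_radius))
  invisible(x)
}

#' Number of chain beads (TAD + HET + CEN, excluding the nucleolus)
#' @param system A `flynuc_system`.
#' @export
n_chain_beads <- function(system) {
  sum(system$beads$kind != "NUC")
}
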