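## Chromatin-architecture readouts computed from trajectories: in-silico Hi-C
## contact maps, radial density profiles, NE-layer occupancies, LAD mobility
## and class-class contact statistics.

as_traj_list <- function(trajectories) {
  if (inherits(trajectories, "flynuc_trajectory")) return(list(trajectories))
  stopifnot(is.list(trajectories), length(trajectories) > 0)
  lapply(trajectories, function(t) {
    stopifnot(inherits(t, "flynuc_trajectory")); t
  })
}

# snapshot indices at or after the burn-in step count (relative to the
# trajectory's own first step)
.post_burnin <- function(traj, burn_in_steps) {
  rel <- traj$snap_steps - traj$snap_steps[1]
  which(rel >= burn_in_steps)
}

#' Model Hi-C contact probability map
#'
#' For each snapshot, two TADs are in contact when their center distance is at
#' most `scale * (r_i + r_j)`. Per-snapshot indicators are averaged within
#' time windows of `window_steps` steps (5 biological minutes at the
#' production calibration), then across windows and nuclei. The first window
#' of each trajectory is discarded as burn-in by default.
#'
#' @param trajectories A `flynuc_trajectory` or a list of them (sharing the
#'   same TAD indexing).
#' @param scale Contact threshold in units of the contact distance
#'   `r_i + r_j` (default 1.2).
#' @param window_steps Averaging window in steps (default 3e6 = 5 min).
#' @param burn_in_windows Windows discarded at the start of each trajectory
#'   (default 1; ignored when a trajectory has a single window).
#' @return A `flynuc_contact_map`: symmetric TAD x TAD matrix of contact
#'   probabilities in `[0, 1]` with unit diagonal; TAD ids, classes and the
#'   contact rule are attached as attributes.
#' @export
contact_map <- function(trajectories, scale = 1.2, window_steps = 3e6,
                        burn_in_windows = 1) {
  trajs <- as_traj_list(trajectories)
  b0 <- trajs[[1]]$system$beads
  tad_sel <- which(b0$kind == "TAD")
  for (t in trajs) {
    if (!identical(which(t$system$beads$kind == "TAD"), tad_sel)) {
      stop("trajectories have mismatched TAD bead sets", call. = FALSE)
    }
  }
  m <- length(tad_sel)
  acc <- matrix(0, m, m)
  n_win_total <- 0
  for (t in trajs) {
    radii <- t$system$beads$radius_um
    rel <- t$snap_steps - t$snap_steps[1]
    win <- floor(rel / window_steps)
    keep_wins <- sort(unique(win))
    if (length(keep_wins) > burn_in_windows) {
      keep_wins <- keep_wins[-seq_len(burn_in_windows)]
    }
    for (w in keep_wins) {
      snaps <- which(win == w)
      counts <- cpp_contact_counts(t$positions, radii,
                                   tad_sel - 1L, scale,
                                   min(snaps) - 1L, max(snaps))
      acc <- acc + counts / length(snaps)
      n_win_total <- n_win_total + 1
    }
  }
  map <- acc / n_win_total
  diag(map) <- 1
  structure(map,
            class = c("flynuc_contact_map", "matrix", "array"),
            tad_id = b0$tad_id[tad_sel],
            epi_class = b0$epi_class[tad_sel],
            is_ltad = b0$is_ltad[tad_sel],
            contact_scale = scale,
            window_steps = window_steps,
            n_windows = n_win_total,
            n_nuclei = length(trajs))
}

#' @export
print.flynuc_contact_map <- function(x, ...) {
  cat(sprintf(
    "<flynuc_contact_map> %d x %d TADs, %s windows over %s nuclei, contact rule %.3g*(ri+rj)\n",
    nrow(x), ncol(x),
    attr(x, "n_windows") %||% "?", attr(x, "n_nuclei") %||% "?",
    attr(x, "contact_scale") %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation between two contact maps
#'
#' Correlates the off-diagonal upper triangles. `exclude_below` drops entries
#' where the reference map `map_b` falls below a threshold (stratifying away
#' low-probability contacts dominated by noise).
#'
#' @param map_a,map_b Square matrices of identical dimension.
#' @param exclude_below Optional threshold applied to `map_b`.
#' @return Pearson correlation coefficient.
#' @export
pearson_maps <- function(map_a, map_b, exclude_below = NULL) {
  if (!all(dim(map_a) == dim(map_b))) {
    stop("maps have different dimensions", call. = FALSE)
  }
  ut <- upper.tri(map_a, diag = FALSE)
  a <- map_a[ut]; b <- map_b[ut]
  if (!is.null(exclude_below)) {
    keep <- b >= exclude_below
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) {
    stop("maps have zero variance on the compared entries", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Entrywise difference of two contact maps
#'
#' @param map_a,map_b Contact maps of identical dimension.
#' @return `map_a - map_b` as a `flynuc_contact_map` flagged as a difference
#'   map (antisymmetric under argument exchange).
#' @export
difference_map <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) {
    stop("maps have different dimensions", call. = FALSE)
  }
  out <- unclass(map_a) - unclass(map_b)
  structure(out,
            class = c("flynuc_contact_map", "matrix", "array"),
            tad_id = attr(map_a, "tad_id"),
            epi_class = attr(map_a, "epi_class"),
            is_ltad = attr(map_a, "is_ltad"),
            map_type = "difference")
}

#' Radial chromatin density profile
#'
#' Number density of bead centers in spherical shells, averaged over
#' snapshots, with the ensemble mean and standard deviation of the mean
#' across nuclei. Shell-integrated counts equal the bead count exactly, per
#' snapshot. With `relative = TRUE` the radial axis is r/R so nuclei of
#' different sizes can be pooled.
#'
#' @param trajectories A `flynuc_trajectory` or list of them.
#' @param bins Number of radial bins (default 40).
#' @param subset Bead indices to include (default: all chain beads).
#' @param relative Use the relative radius r/R (default FALSE).
#' @param burn_in_steps Steps discarded at the start of each trajectory
#'   (default 3e6, one 5-min window).
#' @return A `flynuc_radial_profile` tibble: `r_lo`, `r_mid`, `r_hi`,
#'   `density` (um^-3, or probability per unit relative volume), `sd_mean`,
#'   `n_nuclei`.
#' @export
radial_density <- function(trajectories, bins = 40, subset = NULL,
                           relative = FALSE, burn_in_steps = 3e6) {
  trajs <- as_traj_list(trajectories)
  if (is.null(subset)) {
    subset <- which(trajs[[1]]$system$beads$kind != "NUC")
  }
  if (length(subset) == 0) stop("empty bead subset", call. = FALSE)
  rmax <- if (relative) 1 else max(vapply(trajs, function(t) t$nucleus_radius,
                                          numeric(1)))
  edges <- seq(0, rmax, length.out = bins + 1)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  per_nuc <- vapply(trajs, function(t) {
    keep <- .post_burnin(t, burn_in_steps)
    if (length(keep) == 0) {
      stop("no snapshots after burn-in; lower `burn_in_steps`", call. = FALSE)
    }
    p <- t$positions[subset, , keep, drop = FALSE]
    r <- sqrt(apply(p^2, c(1, 3), sum))
    if (relative) r <- r / t$nucleus_radius
    counts <- vapply(seq_len(bins), function(k) {
      sum(r >= edges[k] & r < edges[k + 1])
    }, numeric(1))
    # clamp stragglers into the last shell so counts are conserved
    counts[bins] <- counts[bins] + sum(r >= edges[bins + 1])
    counts / length(keep) / shell_vol
  }, numeric(bins))
  per_nuc <- matrix(per_nuc, nrow = bins)
  nn <- length(trajs)
  out <- tibble::tibble(
    r_lo = edges[-(bins + 1)], r_hi = edges[-1],
    r_mid = (edges[-(bins + 1)] + edges[-1]) / 2,
    density = rowMeans(per_nuc),
    sd_mean = if (nn > 1) apply(per_nuc, 1, sd) / sqrt(nn) else 0,
    n_nuclei = nn
  )
  class(out) <- c("flynuc_radial_profile", class(out))
  attr(out, "relative") <- relative
  attr(out, "n_beads") <- length(subset)
  out
}

#' Nuclear-envelope layer occupancy statistics
#'
#' Time- and ensemble-averaged probabilities for each bead center to lie
#' within named layers adjacent to the envelope: the 0.09 um layer (average
#' bead radius, the "at the NE" criterion used for the 25% LAD fraction), the
#' 0.2 um contact layer (average bead diameter, the NE-contact criterion for
#' LAD mobility), and the 0.4 um layer containing half the nuclear volume.
#'
#' @param trajectories A `flynuc_trajectory` or list of them.
#' @param layers Named layer thicknesses in um.
#' @param burn_in_steps Steps discarded at the start of each trajectory.
#' @return A `flynuc_layer_stats` tibble with one row per chain bead:
#'   `bead_id`, `tad_id`, `epi_class`, `is_ltad`, `radius_um`, and one
#'   `p_<layer>` column per layer (plus `p_half_volume_inner`). The mean
#'   0.09-um occupancy over L-TADs is attached as attribute
#'   `ltad_fraction_ne`.
#' @export
ne_layer_stats <- function(trajectories,
                           layers = c(adjacent = 0.09, contact = 0.2,
                                      half_volume = 0.4),
                           burn_in_steps = 0) {
  trajs <- as_traj_list(trajectories)
  R <- trajs[[1]]$nucleus_radius
  if (any(layers >= R)) {
    stop("layer thicker than the nuclear radius", call. = FALSE)
  }
  b <- trajs[[1]]$system$beads
  sel <- which(b$kind != "NUC")
  occ <- matrix(0, length(sel), length(layers))
  n_snap_total <- 0
  for (t in trajs) {
    keep <- .post_burnin(t, burn_in_steps)
    p <- t$positions[sel, , keep, drop = FALSE]
    d <- t$nucleus_radius - sqrt(apply(p^2, c(1, 3), sum))
    for (k in seq_along(layers)) {
      occ[, k] <- occ[, k] + rowSums(d <= layers[k])
    }
    n_snap_total <- n_snap_total + length(keep)
  }
  occ <- occ / n_snap_total
  out <- tibble::tibble(
    bead_id = b$bead_id[sel], tad_id = b$tad_id[sel],
    epi_class = b$epi_class[sel], is_ltad = b$is_ltad[sel],
    radius_um = b$radius_um[sel]
  )
  for (k in seq_along(layers)) {
    out[[paste0("p_", names(layers)[k])]] <- occ[, k]
  }
  if ("half_volume" %in% names(layers)) {
    out$p_half_volume_inner <- 1 - out$p_half_volume
  }
  class(out) <- c("flynuc_layer_stats", class(out))
  if ("adjacent" %in% names(layers) && any(out$is_ltad)) {
    attr(out, "ltad_fraction_ne") <- mean(out$p_adjacent[out$is_ltad])
  }
  attr(out, "n_snapshots") <- n_snap_total
  out
}

#' Per-L-TAD NE attachment and mobility report
#'
#' For a single-nucleus trajectory, computes each L-TAD's probability to be in
#' contact with the envelope (center within the 0.2 um contact layer), the
#' number of attachment and detachment events, and dwell-time summaries. If
#' LADs were statically anchored, single-nucleus contact probabilities would
#' be 0 or 1; interior probabilities reject that static-LAD picture.
#'
#' @param trajectory A single `flynuc_trajectory`.
#' @param layer Contact layer thickness, um (default 0.2).
#' @param burn_in_steps Steps discarded at the start.
#' @return Tibble with one row per L-TAD: `tad_id`, `epi_class`,
#'   `p_contact`, `n_attach`, `n_detach`, `mean_dwell_steps`,
#'   `max_dwell_steps`. Attribute `static_null_rejected` is TRUE when any
#'   probability is strictly inside (0, 1).
#' @export
ltad_mobility_report <- function(trajectory, layer = 0.2, burn_in_steps = 0) {
  stopifnot(inherits(trajectory, "flynuc_trajectory"))
  keep <- .post_burnin(trajectory, burn_in_steps)
  if (length(keep) < 4) {
    stop("trajectory too short for a mobility report (",
         length(keep), " snapshots)", call. = FALSE)
  }
  b <- trajectory$system$beads
  sel <- which(b$is_ltad)
  if (length(sel) == 0) stop("no L-TADs in the system", call. = FALSE)
  stride <- diff(trajectory$snap_steps)[1]
  p <- trajectory$positions[sel, , keep, drop = FALSE]
  d <- trajectory$nucleus_radius - sqrt(apply(p^2, c(1, 3), sum))
  inlayer <- d <= layer
  per <- lapply(seq_along(sel), function(k) {
    s <- inlayer[k, ]
    r <- rle(s)
    dw <- r$lengths[r$values]
    tibble::tibble(
      tad_id = b$tad_id[sel[k]],
      epi_class = b$epi_class[sel[k]],
      p_contact = mean(s),
      n_attach = sum(diff(as.integer(s)) == 1) + as.integer(s[1]),
      n_detach = sum(diff(as.integer(s)) == -1),
      mean_dwell_steps = if (length(dw)) mean(dw) * stride else 0,
      max_dwell_steps = if (length(dw)) max(dw) * stride else 0
    )
  })
  out <- dplyr::bind_rows(per)
  class(out) <- c("flynuc_mobility", class(out))
  attr(out, "static_null_rejected") <-
    any(out$p_contact > 0 & out$p_contact < 1)
  attr(out, "layer") <- layer
  out
}

#' Summed contact probabilities between TAD classes
#'
#' For each TAD of `source_class`, the sum of its contact probabilities with
#' all TADs of `target_class` (diagonal excluded). Used, e.g., to quantify
#' how lamin depletion enhances Null-Active mixing.
#'
#' @param map A `flynuc_contact_map`.
#' @param source_class,target_class Epigenetic class names.
#' @return Tibble with `tad_id`, `sum_contact`.
#' @export
class_contact_sums <- function(map, source_class, target_class) {
  cls <- attr(map, "epi_class")
  if (is.null(cls)) stop("map lacks class metadata", call. = FALSE)
  src <- which(cls == source_class)
  tgt <- which(cls == target_class)
  if (length(src) == 0 || length(tgt) == 0) {
    stop("empty class: ", if (length(src) == 0) source_class else target_class,
         call. = FALSE)
  }
  m <- unclass(map)
  diag(m) <- 0
  tibble::tibble(
    tad_id = attr(map, "tad_id")[src],
    sum_contact = rowSums(m[src, tgt, drop = FALSE])
  )
}

#' Mean relative change of class-class contact sums between two maps
#'
#' `mean over source TADs of (sum_a - sum_b) / sum_b`; e.g. the mutant-vs-WT
#' relative increase of Null-Active contacts.
#'
#' @param map_a,map_b Contact maps sharing TAD metadata.
#' @inheritParams class_contact_sums
#' @return A single number (fractional change; multiply by 100 for percent).
#' @export
class_contact_change <- function(map_a, map_b, source_class, target_class) {
  a <- class_contact_sums(map_a, source_class, target_class)
  b <- class_contact_sums(map_b, source_class, target_class)
  mean((a$sum_contact - b$sum_contact) / b$sum_contact)
}

#' Radial position distribution of a single TAD
#'
#' Normalized radial density of one TAD's position over a trajectory
#' ensemble, with a dip-test bimodality heuristic: the distribution is called
#' bi-modal when both the wall peak and the interior maximum exceed three
#' times the density in the dip between them (an NE-bound mode coexisting
#' with a diffusive interior mode).
#'
#' @param trajectories A `flynuc_trajectory` or list of them.
#' @param tad_id 0-based TAD id.
#' @param bins Number of radial bins (default 40).
#' @param wall_layer Thickness of the wall region, um (default 0.15).
#' @param burn_in_steps Steps discarded at the start of each trajectory.
#' @param min_samples Minimum number of position samples (default 50).
#' @return Tibble `r_lo`, `r_mid`, `r_hi`, `density` (um^-3) with attributes
#'   `bimodal`, `wall_density`, `interior_max`, `dip`.
#' @export
per_tad_radial_distribution <- function(trajectories, tad_id, bins = 40,
                                        wall_layer = 0.15,
                                        burn_in_steps = 0,
                                        min_samples = 50) {
  trajs <- as_traj_list(trajectories)
  b <- trajs[[1]]$system$beads
  bead <- which(!is.na(b$tad_id) & b$tad_id == tad_id)
  if (length(bead) != 1) stop("TAD id ", tad_id, " not in the system", call. = FALSE)
  R <- trajs[[1]]$nucleus_radius
  r <- unlist(lapply(trajs, function(t) {
    keep <- .post_burnin(t, burn_in_steps)
    sqrt(colSums(t$positions[bead, , keep, drop = TRUE]^2, dims = 1))
  }))
  if (length(r) < min_samples) {
    stop("only ", length(r), " samples; need >= ", min_samples, call. = FALSE)
  }
  edges <- seq(0, R, length.out = bins + 1)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  counts <- vapply(seq_len(bins), function(k) {
    sum(r >= edges[k] & r < edges[k + 1])
  }, numeric(1))
  counts[bins] <- counts[bins] + sum(r >= edges[bins + 1])
  dens <- counts / length(r) / shell_vol
  mids <- (edges[-(bins + 1)] + edges[-1]) / 2
  wall_sel <- mids > R - wall_layer
  int_sel <- mids < R - 2 * wall_layer
  wall_density <- if (any(wall_sel)) max(dens[wall_sel]) else 0
  interior_max <- if (any(int_sel)) max(dens[int_sel]) else 0
  dip <- 0
  if (interior_max > 0 && any(int_sel)) {
    peak_at <- max(which(int_sel & dens == interior_max))
    between <- which(mids >= mids[peak_at] & mids <= R - wall_layer)
    dip <- if (length(between)) min(dens[between]) else 0
  }
  bimodal <- wall_density > 3 * dip && interior_max > 3 * dip &&
    wall_density > 0 && interior_max > 0
  out <- tibble::tibble(r_lo = edges[-(bins + 1)], r_mid = mids,
                        r_hi = edges[-1], density = dens)
  attr(out, "bimodal") <- bimodal
  attr(out, "wall_density") <- wall_density
  attr(out, "interior_max") <- interior_max
  attr(out, "dip") <- dip
  attr(out, "n_samples") <- length(r)
  out
}
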