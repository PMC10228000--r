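#' Build a genome annotation from TAD and LAD interval tables
#'
#' Joins a TAD table (one row per TAD, with chromosome arm, 0-based half-open
#' coordinates, epigenetic class and hard radius) with a LAD interval table,
#' flagging every TAD that a LAD overlaps as an L-TAD. The default rule flags
#' a TAD on any overlap of at least one base pair; `min_overlap_frac` can
#' require a minimum overlapped fraction of the TAD instead.
#'
#' @param tads Data frame with columns `arm`, `start`, `end`, `class`,
#'   `hard_radius_um` (see [read_tad_table()]).
#' @param lads Data frame with columns `arm`, `start`, `end`, or `NULL` for no
#'   LADs.
#' @param min_overlap_frac Minimum fraction of the TAD length that must be
#'   covered by LADs for the TAD to count as an L-TAD. Default 0 (>= 1 bp).
#' @return A `flynuc_annotation` tibble with columns `tad_id` (0-based index
#'   along the concatenated genome, arms ordered 2L, 2R, 3L, 3R, 4, X),
#'   `arm`, `start_bp`, `end_bp`, `length_bp`, `epi_class`, `is_ltad`,
#'   `hard_radius_um`.
#' @export
load_annotation <- function(tads, lads = NULL, min_overlap_frac = 0) {
  stopifnot(is.data.frame(tads))
  need <- c("arm", "start", "end", "class", "hard_radius_um")
  miss <- setdiff(need, names(tads))
  if (length(miss) > 0) {
    stop("TAD table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_class <- which(!tads$class %in% flynuc_classes)
  if (length(bad_class) > 0) {
    stop("unknown epigenetic class in TAD table row(s) ",
         paste(head(bad_class, 5), collapse = ", "),
         " (expected one of ", paste(flynuc_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_arm <- which(!tads$arm %in% flynuc_arms)
  if (length(bad_arm) > 0) {
    stop("unknown chromosome arm in TAD table row(s) ",
         paste(head(bad_arm, 5), collapse = ", "), call. = FALSE)
  }
  if (any(tads$end <= tads$start)) {
    stop("TAD table has rows with end <= start", call. = FALSE)
  }
  if (any(tads$hard_radius_um <= 0)) {
    stop("TAD hard radii must be positive", call. = FALSE)
  }

  ann <- tads |>
    dplyr::mutate(arm = factor(.data$arm, levels = flynuc_arms)) |>
    dplyr::arrange(.data$arm, .data$start)
  # contiguity/overlap check per arm
  by_arm <- split(ann, ann$arm, drop = TRUE)
  for (tab in by_arm) {
    if (nrow(tab) > 1 && any(tab$start[-1] < tab$end[-nrow(tab)])) {
      stop("overlapping TADs within arm ", as.character(tab$arm[1]), call. = FALSE)
    }
  }

  is_ltad <- rep(FALSE, nrow(ann))
  if (!is.null(lads) && nrow(lads) > 0) {
    miss <- setdiff(c("arm", "start", "end"), names(lads))
    if (length(miss) > 0) {
      stop("LAD table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    for (k in seq_len(nrow(ann))) {
      sel <- lads$arm == as.character(ann$arm[k])
      if (!any(sel)) next
      ov <- pmin(lads$end[sel], ann$end[k]) - pmax(lads$start[sel], ann$start[k])
      ov_total <- sum(pmax(0, ov))
      len <- ann$end[k] - ann$start[k]
      is_ltad[k] <- if (min_overlap_frac > 0) {
        ov_total >= min_overlap_frac * len
      } else {
        ov_total > 0
      }
    }
  }

  out <- tibble::tibble(
    tad_id = seq_len(nrow(ann)) - 1L,
    arm = as.character(ann$arm),
    start_bp = as.numeric(ann$start),
    end_bp = as.numeric(ann$end),
    length_bp = as.numeric(ann$end - ann$start),
    epi_class = ann$class,
    is_ltad = is_ltad,
    hard_radius_um = ann$hard_radius_um
  )
  new_annotation(out)
}

new_annotation <- function(tbl) {
  stopifnot(all(c("tad_id", "arm", "epi_class", "is_ltad",
                  "hard_radius_um", "length_bp") %in% names(tbl)))
  class(tbl) <- c("flynuc_annotation", class(tbl))
  tbl
}

#' @export
print.flynuc_annotation <- function(x, ...) {
  cnt <- table(factor(x$epi_class, levels = flynuc_classes))
  lcnt <- table(factor(x$epi_class[x$is_ltad], levels = flynuc_classes))
  cat(sprintf("<flynuc_annotation> %d TADs (%d L-TADs) on %d arms\n",
              nrow(x), sum(x$is_ltad), length(unique(x$arm))))
  cat("  TADs per class:  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
  cat("  L-TADs per class:", paste(sprintf("%s=%d", names(lcnt), lcnt), collapse = " "), "\n")
  invisible(x)
}

#' Local linear L-TAD density along the chromosome chains
#'
#' For each TAD, the fraction of L-TADs among the TADs in a window of
#' `window_tads` TADs centred on it, truncated at arm boundaries. This is the
#' local linear L-TAD density f_L that drives the radial positioning of
#' chromosome segments: L-TAD-rich stretches are pulled to the envelope as a
#' group, L-TAD-poor stretches stay interior.
#'
#' @param annotation A `flynuc_annotation`.
#' @param window_tads Odd window size in TADs (default 17).
#' @return The annotation tibble with columns `f_l` and `window_n` (the
#'   truncated window size actually used) added. The exact genome-wide ratio
#'   (#L-TADs)/(#TADs) is attached as attribute `genome_mean`; the unweighted
#'   mean of `f_l` equals it up to arm-boundary truncation.
#' @export
linear_lad_density <- function(annotation, window_tads = 17) {
  stopifnot(inherits(annotation, "flynuc_annotation"))
  if (window_tads < 1 || window_tads %% 2 == 0) {
    stop("`window_tads` must be a positive odd integer", call. = FALSE)
  }
  h <- (window_tads - 1L) / 2L
  f_l <- numeric(nrow(annotation))
  win_n <- integer(nrow(annotation))
  idx_by_arm <- split(seq_len(nrow(annotation)), annotation$arm)
  for (idx in idx_by_arm) {
    flags <- annotation$is_ltad[idx]
    n <- length(idx)
    for (k in seq_len(n)) {
      lo <- max(1L, k - h); hi <- min(n, k + h)
      f_l[idx[k]] <- mean(flags[lo:hi])
      win_n[idx[k]] <- hi - lo + 1L
    }
  }
  out <- annotation
  out$f_l <- f_l
  out$window_n <- win_n
  attr(out, "genome_mean") <- mean(annotation$is_ltad)
  attr(out, "window_tads") <- window_tads
  out
}
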