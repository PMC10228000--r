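## Synthetic genome generator. Emulates the statistics of the fly TAD/LAD
## annotation so every downstream stage can be exercised without the real
## tables: 1169 TADs in classes Active/Null/PcG/HP1 = 494/492/131/52, of which
## 54/228/50/18 contain LADs (350 L-TADs), bead diameters 0.08-0.38 um with
## mean 0.18 um, and LADs clustered along the chains so the local linear
## L-TAD density f_L is heterogeneous (~0.05-0.7) around the genome mean 0.30.

# fractions of TADs per arm, proportional to arm sizes of the fly genome
.arm_fracs <- c("2L" = 0.176, "2R" = 0.190, "3L" = 0.211,
                "3R" = 0.241, "4" = 0.009, "X" = 0.173)

# largest-remainder apportionment of `total` into parts proportional to w
.apportion <- function(total, w) {
  q <- total * w / sum(w)
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    add <- order(q - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1
  }
  as.integer(n)
}

# clustered binary sequence: two-state persistence process along each arm,
# then count-preserving boundary flips to hit `target` ones exactly
.clustered_flags <- function(arm_sizes, target, p, persistence) {
  flags <- logical(0)
  for (n in arm_sizes) {
    f <- logical(n)
    f[1] <- runif(1) < p
    p11 <- persistence + (1 - persistence) * p
    p01 <- (1 - persistence) * p
    for (k in seq_len(n)[-1]) {
      f[k] <- runif(1) < (if (f[k - 1]) p11 else p01)
    }
    flags <- c(flags, f)
  }
  # fix the total without destroying clusters: flip at cluster boundaries
  n <- length(flags)
  repeat {
    excess <- sum(flags) - target
    if (excess == 0) break
    if (excess > 0) {
      ones <- which(flags)
      nb0 <- vapply(ones, function(i) {
        (i > 1 && !flags[i - 1]) || (i < n && !flags[i + 1])
      }, logical(1))
      pool <- if (any(nb0)) ones[nb0] else ones
      flags[pool[sample.int(length(pool), 1)]] <- FALSE
    } else {
      zeros <- which(!flags)
      nb1 <- vapply(zeros, function(i) {
        (i > 1 && flags[i - 1]) || (i < n && flags[i + 1])
      }, logical(1))
      pool <- if (any(nb1)) zeros[nb1] else zeros
      flags[pool[sample.int(length(pool), 1)]] <- TRUE
    }
  }
  flags
}

#' Generate a synthetic TAD/LAD genome annotation
#'
#' Produces a reproducible annotation with exactly the requested per-class TAD
#' and L-TAD counts. TAD sizes are log-normal (clamped so bead diameters fall
#' in the observed 0.08-0.38 um range); LAD-containing TADs are placed by a
#' two-state persistence process along each arm so that L-TADs cluster,
#' reproducing the strong heterogeneity of the local linear L-TAD density.
#'
#' @param n_tads Total number of TADs (default 1169, the fly genome).
#' @param class_counts Named integer vector of TAD counts per class. Defaults
#'   to the fly counts (Active 494, Null 492, PcG 131, HP1 52); scaled
#'   proportionally when `n_tads` differs from their sum.
#' @param ltad_counts Named integer vector of L-TAD counts per class
#'   (defaults Active 54, Null 228, PcG 50, HP1 18; scaled with `n_tads`).
#' @param persistence Clustering persistence of the LAD placement process in
#'   `[0, 1)`; 0 gives independent Bernoulli placement, values near 1 give
#'   long L-TAD-rich / poor segments. The default 0.4 reproduces the observed
#'   spread of the 17-TAD-window linear L-TAD density (roughly 0.05-0.7
#'   around the genome mean 0.30).
#' @param size_meanlog,size_sdlog Log-normal parameters of TAD length in bp.
#' @param seed Integer seed; the same seed reproduces the annotation exactly.
#' @return A `flynuc_annotation` tibble (see [load_annotation()]).
#' @export
#' @examples
#' ann <- synth_genome(seed = 1)
#' table(ann$epi_class)
synth_genome <- function(n_tads = 1169,
                         class_counts = NULL,
                         ltad_counts = NULL,
                         persistence = 0.4,
                         size_meanlog = log(9e4),
                         size_sdlog = 0.55,
                         seed = NULL) {
  base_cls <- c(Active = 494L, Null = 492L, PcG = 131L, HP1 = 52L)
  base_l <- c(Active = 54L, Null = 228L, PcG = 50L, HP1 = 18L)
  if (is.null(class_counts)) {
    class_counts <- if (n_tads == sum(base_cls)) base_cls else
      setNames(.apportion(n_tads, base_cls), names(base_cls))
  }
  if (sum(class_counts) != n_tads) {
    stop("`class_counts` must sum to `n_tads`", call. = FALSE)
  }
  if (is.null(ltad_counts)) {
    n_l <- round(n_tads * sum(base_l) / sum(base_cls))
    ltad_counts <- if (n_tads == sum(base_cls)) base_l else
      setNames(.apportion(n_l, base_l), names(base_l))
  }
  if (any(ltad_counts > class_counts[names(ltad_counts)])) {
    stop("infeasible counts: more L-TADs than TADs in a class", call. = FALSE)
  }
  if (persistence < 0 || persistence >= 1) {
    stop("`persistence` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  arm_n <- .apportion(n_tads, .arm_fracs[flynuc_arms])
  names(arm_n) <- flynuc_arms
  arm_n["4"] <- max(arm_n["4"], 3L)  # keep the dot chromosome non-degenerate
  while (sum(arm_n) > n_tads) {
    big <- which.max(arm_n[setdiff(flynuc_arms, "4")])
    arm_n[names(big)] <- arm_n[names(big)] - 1L
  }
  arm <- rep(flynuc_arms, times = arm_n)

  len <- rlnorm(n_tads, size_meanlog, size_sdlog)
  len <- pmin(pmax(round(len), 1.5e4), 5e5)
  # bead volume proportional to sequence length; clamp to the observed range
  hard_r <- 0.0715 * (len / 9e4)^(1 / 3)
  hard_r <- pmin(pmax(hard_r, 0.04 / .RADIUS_SCALE), 0.19 / .RADIUS_SCALE)

  n_l_total <- sum(ltad_counts)
  flags <- .clustered_flags(arm_n, n_l_total, n_l_total / n_tads, persistence)

  # class labels: draw the L and non-L quotas independently so both sets of
  # per-class totals come out exact
  cls <- character(n_tads)
  cls[flags] <- sample(rep(names(ltad_counts), times = ltad_counts))
  rest <- class_counts - ltad_counts[names(class_counts)]
  cls[!flags] <- sample(rep(names(rest), times = rest))

  start <- unlist(lapply(split(len, factor(arm, levels = flynuc_arms)),
                         function(l) cumsum(c(0, l[-length(l)]))),
                  use.names = FALSE)
  out <- tibble::tibble(
    tad_id = seq_len(n_tads) - 1L,
    arm = arm,
    start_bp = start,
    end_bp = start + len,
    length_bp = len,
    epi_class = cls,
    is_ltad = flags,
    hard_radius_um = hard_r
  )
  out <- new_annotation(out)
  attr(out, "synthetic") <- TRUE
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic specific-pair table
#'
#' Samples long-range TAD pairs with log-normal contact enrichments, standing
#' in for the table of 268 specific pairs with enhanced contact probability.
#'
#' @param annotation A `flynuc_annotation`.
#' @param n_pairs Number of pairs (default 268).
#' @param min_separation Minimum index separation along the genome (default 20
#'   TADs) so the pairs are genuinely long-range.
#' @param seed Integer seed.
#' @return Tibble with columns `tad_i`, `tad_j` (0-based TAD ids, i < j) and
#'   `enrichment`.
#' @export
synth_specific_pairs <- function(annotation, n_pairs = 268,
                                 min_separation = 20, seed = NULL) {
  stopifnot(inherits(annotation, "flynuc_annotation"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(annotation)
  if (n <= min_separation + 1) {
    stop("annotation too small for the requested separation", call. = FALSE)
  }
  seen <- character(0)
  ii <- integer(0); jj <- integer(0)
  while (length(ii) < n_pairs) {
    i <- sample.int(n, 1) - 1L
    j <- sample.int(n, 1) - 1L
    if (abs(i - j) < min_separation) next
    a <- min(i, j); b <- max(i, j)
    key <- paste(a, b)
    if (key %in% seen) next
    seen <- c(seen, key)
    ii <- c(ii, a); jj <- c(jj, b)
  }
  tibble::tibble(tad_i = ii, tad_j = jj,
                 enrichment = rlnorm(n_pairs, meanlog = 1, sdlog = 0.6))
}
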