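#' Default 18-nucleus ensemble roster
#'
#' The simulated ensemble: the four experimentally observed topologies with
#' the CIS arrangements weighted twice (CIS-X6S x2, CIS-X7N x2, TRANS-X3S,
#' TRANS-X4N), each at three nucleus radii - 6 weighted arrangements x 3
#' sizes = 18 members, each with its own seed.
#'
#' @param radii Three nucleus radii in um (default 1.8, 2.0, 2.2).
#' @param base_seed Base seed; member seeds are `base_seed * 100 + member`.
#' @return Tibble with `member`, `topology`, `radius`, `seed`.
#' @export
default_roster <- function(radii = c(1.8, 2.0, 2.2), base_seed = 1) {
  if (length(radii) != 3) {
    stop("the default roster uses exactly 3 nucleus radii", call. = FALSE)
  }
  topos <- c("CIS-X6S", "CIS-X6S", "CIS-X7N", "CIS-X7N",
             "TRANS-X3S", "TRANS-X4N")
  grid <- tidyr::expand_grid(radius = radii, topology = topos)
  grid |>
    dplyr::mutate(member = dplyr::row_number(),
                  seed = base_seed * 100 + .data$member) |>
    dplyr::select("member", "topology", "radius", "seed")
}

#' Reduced single-radius roster
#'
#' The 6-member subset used for single-size analyses (4 CIS + 2 TRANS
#' members at one radius).
#'
#' @param radius Nucleus radius, um (default 2).
#' @inheritParams default_roster
#' @export
reduced_roster <- function(radius = 2, base_seed = 1) {
  topos <- c("CIS-X6S", "CIS-X6S", "CIS-X7N", "CIS-X7N",
             "TRANS-X3S", "TRANS-X4N")
  tibble::tibble(member = seq_along(topos), topology = topos,
                 radius = radius, seed = base_seed * 100 + seq_along(topos))
}

#' Run an ensemble of independent nuclei
#'
#' Builds, initializes and integrates one nucleus per roster row. Members are
#' independent; a member that fails is recorded and the remaining members
#' still run.
#'
#' @param roster Tibble with `member`, `topology`, `radius`, `seed` (see
#'   [default_roster()]).
#' @param annotation A `flynuc_annotation` shared by all members.
#' @param params Interaction parameters (default [wt_parameters()]).
#' @param n_steps Production steps per member.
#' @param gamma Production friction, 1/tau (default 0.01).
#' @param specific_pairs Optional specific-pair table applied to every member.
#' @param init_args Extra arguments for [init_nucleus()] (e.g. scaled-down
#'   `collapse_steps`).
#' @param dyn_args Extra arguments for [integrate_dynamics()] (e.g. `stride`).
#' @return A `flynuc_ensemble`: list with `trajectories` (one per successful
#'   member, named by member id), `roster`, and `failures` (tibble).
#' @export
run_ensemble <- function(roster, annotation, params = wt_parameters(),
                         n_steps = 1e5, gamma = 0.01,
                         specific_pairs = NULL,
                         init_args = list(), dyn_args = list()) {
  stopifnot(all(c("member", "topology", "radius", "seed") %in% names(roster)))
  results <- vector("list", nrow(roster))
  fail <- list()
  for (k in seq_len(nrow(roster))) {
    row <- roster[k, ]
    res <- tryCatch({
      system <- build_system(annotation, nucleus_radius = row$radius)
      state <- do.call(init_nucleus, c(
        list(system = system, topology = row$topology, seed = row$seed,
             params = params), init_args))
      ff <- forcefield(system, params = params,
                       specific_pairs = specific_pairs)
      do.call(integrate_dynamics, c(
        list(state = state, ff = ff, n_steps = n_steps, gamma = gamma,
             seed = row$seed + 1L), dyn_args))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[length(fail) + 1]] <- tibble::tibble(
        member = row$member, message = conditionMessage(res))
    } else {
      results[[k]] <- res
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  structure(
    list(trajectories = setNames(results[ok],
                                 paste0("member", roster$member[ok])),
         roster = roster,
         failures = if (length(fail)) dplyr::bind_rows(fail) else
           tibble::tibble(member = integer(0), message = character(0))),
    class = "flynuc_ensemble"
  )
}

#' @export
print.flynuc_ensemble <- function(x, ...) {
  cat(sprintf("<flynuc_ensemble> %d/%d members completed\n",
              length(x$trajectories), nrow(x$roster)))
  if (nrow(x$failures) > 0) print(x$failures)
  invisible(x)
}

#' Ensemble mean and standard deviation of the mean
#'
#' Aggregates a per-nucleus statistic across ensemble members: the mean and
#' its standard deviation `sd / sqrt(n)` (the error bars of ensemble-averaged
#' profiles). Aggregation is permutation-invariant in the member order.
#'
#' @param values Data frame with a `member` column and one or more numeric
#'   statistic columns, or a plain numeric vector (one value per member).
#' @return Tibble with `statistic`, `mean`, `sd_mean`, `n`.
#' @export
ensemble_stats <- function(values) {
  if (is.numeric(values)) {
    values <- tibble::tibble(member = seq_along(values), value = values)
  }
  stopifnot("member" %in% names(values))
  num <- names(values)[vapply(values, is.numeric, logical(1))]
  num <- setdiff(num, "member")
  purrr::map_dfr(num, function(col) {
    x <- values[[col]]
    tibble::tibble(statistic = col, mean = mean(x),
                   sd_mean = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
                   n = length(x))
  })
}
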