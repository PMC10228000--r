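#' Tidy a contact map into long format
#'
#' @param x A `flynuc_contact_map`.
#' @param upper_only Keep only the upper triangle (default TRUE).
#' @param ... Unused.
#' @return Tibble with `tad_i`, `tad_j`, `class_i`, `class_j`, `p`.
#' @export
tidy.flynuc_contact_map <- function(x, upper_only = TRUE, ...) {
  ids <- attr(x, "tad_id") %||% (seq_len(nrow(x)) - 1L)
  cls <- attr(x, "epi_class") %||% rep(NA_character_, nrow(x))
  idx <- if (upper_only) which(upper.tri(x), arr.ind = TRUE) else
    which(row(x) != col(x), arr.ind = TRUE)
  tibble::tibble(
    tad_i = ids[idx[, 1]], tad_j = ids[idx[, 2]],
    class_i = cls[idx[, 1]], class_j = cls[idx[, 2]],
    p = unclass(x)[idx]
  )
}

#' @export
glance.flynuc_contact_map <- function(x, ...) {
  ut <- unclass(x)[upper.tri(x)]
  tibble::tibble(
    n_tads = nrow(x),
    mean_p = mean(ut),
    max_offdiag = max(ut),
    frac_nonzero = mean(ut > 0),
    n_windows = attr(x, "n_windows") %||% NA_integer_,
    n_nuclei = attr(x, "n_nuclei") %||% NA_integer_
  )
}

#' @export
tidy.flynuc_lambda_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "four_d_app", "exponent"),
    estimate = c(x$lambda, x$four_d_app, x$exponent),
    fixed = c(FALSE, TRUE, TRUE)
  )
}

#' @export
glance.flynuc_lambda_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, rmse = x$rmse, n_lags = x$n_lags)
}

#' @export
tidy.flynuc_mobility <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.flynuc_mobility <- function(x, ...) {
  tibble::tibble(
    n_ltads = nrow(x),
    mean_p_contact = mean(x$p_contact),
    max_p_contact = max(x$p_contact),
    frac_low = mean(x$p_contact < 0.2),
    static_null_rejected = isTRUE(attr(x, "static_null_rejected"))
  )
}
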