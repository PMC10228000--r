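## Plain-text readers and writers: BED-like annotation tables, specific-pair
## tables, dense contact-map TSV, a text trajectory container and XYZ export,
## and YAML serialization of the force-field configuration. All readers
## tolerate '#' comment lines.

read_tsv_commented <- function(path, col_names) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_names = col_names)
}

#' Read a TAD annotation table
#'
#' Tab-separated with columns `arm`, `start`, `end`, `class`,
#' `hard_radius_um`; lines starting with `#` are ignored. Coordinates are
#' 0-based half-open.
#'
#' @param path File path.
#' @return Tibble ready for [load_annotation()].
#' @export
read_tad_table <- function(path) {
  tab <- read_tsv_commented(path, TRUE)
  need <- c("arm", "start", "end", "class", "hard_radius_um")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("TAD table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a LAD interval table (BED3: arm, start, end)
#' @param path File path.
#' @export
read_lad_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_names = c("arm", "start", "end"))
  if (is.character(tab$start)) {
    # file had a header line
    tab <- read_tsv_commented(path, TRUE)
  }
  tab
}

#' Read a specific-pair table (tad_i, tad_j, enrichment)
#' @param path File path.
#' @export
read_pairs_table <- function(path) {
  tab <- read_tsv_commented(path, TRUE)
  need <- c("tad_i", "tad_j", "enrichment")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("pair table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write / read a TAD annotation table
#' @param annotation A `flynuc_annotation`.
#' @param path File path.
#' @export
write_tad_table <- function(annotation, path) {
  tab <- tibble::tibble(arm = annotation$arm, start = annotation$start_bp,
                        end = annotation$end_bp, class = annotation$epi_class,
                        hard_radius_um = annotation$hard_radius_um,
                        is_ltad = annotation$is_ltad)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Dense contact-map TSV I/O
#'
#' The first row and column carry 0-based TAD ids; a `#`-prefixed header
#' records the contact rule and TAD classes.
#'
#' @param map A `flynuc_contact_map`.
#' @param path File path.
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flynuc contact map: %d TADs, scale %s",
                     nrow(map), attr(map, "contact_scale") %||% "NA"), con)
  cls <- attr(map, "epi_class")
  if (!is.null(cls)) {
    writeLines(paste0("# classes: ", paste(cls, collapse = ",")), con)
  }
  ids <- attr(map, "tad_id") %||% (seq_len(nrow(map)) - 1L)
  writeLines(paste(c("tad_id", ids), collapse = "\t"), con)
  m <- unclass(map)
  for (k in seq_len(nrow(m))) {
    writeLines(paste(c(ids[k], format(m[k, ], digits = 8)), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_contact_map
#' @param threshold Entries below this value are dropped from the sparse
#'   triplet export (default 0: keep all non-zero entries).
#' @export
write_contact_triplets <- function(map, path, threshold = 0) {
  long <- tidy(map)
  long <- long[long$p > threshold, c("tad_i", "tad_j", "p")]
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  cls <- NULL
  cl_line <- grep("^# classes:", lines, value = TRUE)
  if (length(cl_line)) {
    cls <- strsplit(sub("^# classes: ", "", cl_line[1]), ",")[[1]]
  }
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t")[[1]]
  ids <- as.integer(header[-1])
  rows <- strsplit(body[-1], "\t")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(ids))))
  structure(m, class = c("flynuc_contact_map", "matrix", "array"),
            tad_id = ids, epi_class = cls)
}

#' Write a trajectory as a text container
#'
#' A `#`-prefixed YAML header (system size, gamma, dt, stride, topology,
#' nucleus radius, force-field hash) followed by a long-format table
#' `step`, `bead`, `x`, `y`, `z`.
#'
#' @param trajectory A `flynuc_trajectory`.
#' @param path File path.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  meta <- list(n_beads = dim(trajectory$positions)[1],
               n_snapshots = n_snapshots(trajectory),
               gamma = trajectory$gamma, dt = trajectory$dt,
               stride = trajectory$stride,
               topology = trajectory$topology,
               nucleus_radius = trajectory$nucleus_radius,
               forcefield_hash = trajectory$forcefield_hash)
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  n <- meta$n_beads
  tab <- purrr::map_dfr(seq_len(meta$n_snapshots), function(s) {
    tibble::tibble(step = trajectory$snap_steps[s], bead = seq_len(n),
                   x = trajectory$positions[, 1, s],
                   y = trajectory$positions[, 2, s],
                   z = trajectory$positions[, 3, s])
  })
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @param system Optional `flynuc_system` to attach to the read trajectory.
#' @export
read_trajectory_tsv <- function(path, system = NULL) {
  lines <- readLines(path, n = 50)
  hdr <- sub("^# ?", "", lines[startsWith(lines, "#")])
  meta <- yaml::yaml.load(paste(hdr, collapse = "\n"))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  steps <- sort(unique(tab$step))
  n <- meta$n_beads
  pos <- array(0, dim = c(n, 3, length(steps)))
  for (s in seq_along(steps)) {
    sub <- tab[tab$step == steps[s], ]
    sub <- sub[order(sub$bead), ]
    pos[, , s] <- as.matrix(sub[, c("x", "y", "z")])
  }
  structure(
    list(snap_steps = steps, positions = pos, system = system,
         end_state = NULL, gamma = meta$gamma, dt = meta$dt,
         stride = meta$stride, topology = meta$topology,
         nucleus_radius = meta$nucleus_radius,
         forcefield_hash = meta$forcefield_hash,
         kT = 1, ne_on = NA),
    class = "flynuc_trajectory"
  )
}

#' Export a trajectory to XYZ for molecular viewers
#'
#' One frame per snapshot; atom names encode the bead kind/class.
#'
#' @param trajectory A `flynuc_trajectory`.
#' @param path File path.
#' @export
write_xyz <- function(trajectory, path) {
  b <- trajectory$system$beads
  name <- ifelse(b$kind == "TAD", substr(b$epi_class, 1, 1), substr(b$kind, 1, 1))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(b)
  for (s in seq_len(n_snapshots(trajectory))) {
    writeLines(c(as.character(n),
                 sprintf("step %d", trajectory$snap_steps[s])), con)
    p <- trajectory$positions[, , s]
    writeLines(sprintf("%s %.5f %.5f %.5f", name, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Serialize a force field configuration to YAML
#'
#' Writes the resolved parameter set (class matrix, eps_L, taper, caps, bond
#' stiffness, NE radius, specific-pair count and hash) so a run's interaction
#' model is fully reproducible from its config file.
#'
#' @param ff A `flynuc_forcefield`.
#' @param path File path.
#' @export
write_forcefield_yaml <- function(ff, path) {
  cfg <- list(
    label = ff$params$label,
    class_eps = lapply(seq_len(4), function(i) as.list(setNames(
      as.numeric(ff$params$class_eps[i, ]), colnames(ff$params$class_eps)))),
    eps_l = ff$params$eps_l,
    ne_radius = ff$data$ne_radius,
    settings = ff$settings,
    hash = ff$hash
  )
  names(cfg$class_eps) <- rownames(ff$params$class_eps)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_forcefield_yaml
#' @return `read_forcefield_yaml` returns a `flynuc_params` plus the stored
#'   settings (attribute `settings`).
#' @export
read_forcefield_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- matrix(0, 4, 4, dimnames = list(flynuc_classes, flynuc_classes))
  for (a in flynuc_classes) {
    for (b in flynuc_classes) m[a, b] <- cfg$class_eps[[a]][[b]]
  }
  out <- structure(list(class_eps = m, eps_l = cfg$eps_l, label = cfg$label),
                   class = "flynuc_params")
  attr(out, "settings") <- cfg$settings
  attr(out, "hash") <- cfg$hash
  out
}
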