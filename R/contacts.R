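#' Contact identification criteria
#'
#' Two contact definitions are supported. In `heavy_atom` mode a residue pair
#' is in contact in a frame when the shortest distance between any two of
#' their heavy (non-hydrogen) atoms is below `heavy_atom_cutoff` (default
#' 0.45 nm). In `c_alpha` mode the single Calpha-Calpha distance is compared
#' against `c_alpha_cutoff` (default 0.8 nm). A pair becomes a contact
#' feature when it is in contact for at least `population_threshold` of all
#' frames pooled over the ensemble, and the two residues are separated by
#' more than `neighbor_exclusion` positions in sequence (the rule applies
#' only within a chain; protein-ligand pairs are never sequence-excluded).
#'
#' @param heavy_atom_cutoff contact cutoff in nm for heavy-atom mode.
#' @param population_threshold minimum fraction of frames in contact.
#' @param neighbor_exclusion require `|i - j| > neighbor_exclusion` within a
#'   chain (default 2, i.e. exclude the two nearest neighbors).
#' @param mode `"heavy_atom"` or `"c_alpha"`.
#' @param c_alpha_cutoff cutoff in nm for Calpha mode.
#' @param feature_transform `"distance"` (nm) or `"inverse_distance"`
#'   (nm^-1) applied when time series are extracted.
#' @return A list of class `"cd_contact_criteria"`.
#' @export
contact_criteria <- function(heavy_atom_cutoff = 0.45,
                             population_threshold = 0.10,
                             neighbor_exclusion = 2L,
                             mode = c("heavy_atom", "c_alpha"),
                             c_alpha_cutoff = 0.8,
                             feature_transform = c("distance", "inverse_distance")) {
  mode <- match.arg(mode)
  feature_transform <- match.arg(feature_transform)
  stopifnot(heavy_atom_cutoff > 0, c_alpha_cutoff > 0,
            population_threshold > 0, population_threshold <= 1,
            neighbor_exclusion >= 0)
  structure(list(heavy_atom_cutoff = heavy_atom_cutoff,
                 population_threshold = population_threshold,
                 neighbor_exclusion = as.integer(neighbor_exclusion),
                 mode = mode,
                 c_alpha_cutoff = c_alpha_cutoff,
                 feature_transform = feature_transform),
            class = "cd_contact_criteria")
}

# Atom row indices of one residue relevant for a contact mode.
residue_atom_rows <- function(topology, res, mode) {
  rows <- which(topology$resid == res)
  if (length(rows) == 0) stop("residue ", res, " not found in topology")
  if (mode == "c_alpha") {
    ca <- rows[topology$atom[rows] == "CA"]
    if (length(ca) == 0) stop("residue ", res, " has no CA atom (c_alpha mode)")
    ca[1]
  } else {
    heavy <- rows[is_heavy_atom(topology$atom[rows])]
    if (length(heavy) == 0) stop("residue ", res, " has no heavy atoms")
    heavy
  }
}

#' Minimum inter-residue distance in a single frame
#'
#' In `heavy_atom` mode, the minimum over all heavy-atom pairs of the two
#' residues; in `c_alpha` mode, the Calpha-Calpha distance. Symmetric in the
#' order of the pair.
#'
#' @param frame_coords numeric matrix `[n_atoms, 3]` of coordinates (nm).
#' @param topology a [cd_topology()].
#' @param pair integer vector of two residue indices.
#' @param mode `"heavy_atom"` or `"c_alpha"`.
#' @return distance in nm.
#' @export
min_residue_distance <- function(frame_coords, topology, pair,
                                 mode = c("heavy_atom", "c_alpha")) {
  mode <- match.arg(mode)
  ra <- residue_atom_rows(topology, pair[1], mode)
  rb <- residue_atom_rows(topology, pair[2], mode)
  a <- frame_coords[ra, , drop = FALSE]
  b <- frame_coords[rb, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# Per-frame minimum distance between two atom groups, vectorized over frames.
# coords: [frames, atoms, 3]; returns numeric vector of length n_frames.
pair_min_dist_series <- function(coords, rows_a, rows_b) {
  nfr <- dim(coords)[1]
  best <- rep(Inf, nfr)
  for (p in rows_a) {
    dx <- coords[, rep(p, length(rows_b)), 1, drop = FALSE] - coords[, rows_b, 1, drop = FALSE]
    dy <- coords[, rep(p, length(rows_b)), 2, drop = FALSE] - coords[, rows_b, 2, drop = FALSE]
    dz <- coords[, rep(p, length(rows_b)), 3, drop = FALSE] - coords[, rows_b, 3, drop = FALSE]
    d2 <- dx^2 + dy^2 + dz^2
    dim(d2) <- c(nfr, length(rows_b))
    best <- pmin(best, sqrt(do.call(pmin, c(asplit(d2, 2), list(Inf)))))
  }
  best
}

# Candidate residue pairs after the neighbor-exclusion rule, in lexicographic
# order. Pairs on different chains are never sequence-excluded.
candidate_pairs <- function(topology, neighbor_exclusion) {
  res <- unique(topology[, c("resid", "chain")])
  res <- res[order(res$resid), , drop = FALSE]
  n <- nrow(res)
  if (n < 2) return(data.frame(res_a = integer(0), res_b = integer(0)))
  idx <- utils::combn(n, 2)
  a <- res$resid[idx[1, ]]; b <- res$resid[idx[2, ]]
  ca <- res$chain[idx[1, ]]; cb <- res$chain[idx[2, ]]
  keep <- ca != cb | abs(a - b) > neighbor_exclusion
  out <- data.frame(res_a = a[keep], res_b = b[keep])
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

#' Identify contact features in a coordinate ensemble
#'
#' Evaluates the contact criteria over all frames of all trajectories pooled
#' together ("total simulation time") and returns the residue pairs whose
#' contact population reaches the threshold.
#'
#' @param ensemble a [cd_ensemble()].
#' @param criteria a [contact_criteria()].
#' @return A data.frame of class `"cd_contact_set"` with columns `res_a`,
#'   `res_b`, `population`, ordered lexicographically by residue indices;
#'   the criteria are attached as attribute `"criteria"`.
#' @export
identify_contacts <- function(ensemble, criteria = contact_criteria()) {
  stopifnot(inherits(ensemble, "cd_ensemble"),
            inherits(criteria, "cd_contact_criteria"))
  top <- ensemble$topology
  cutoff <- if (criteria$mode == "heavy_atom") criteria$heavy_atom_cutoff else criteria$c_alpha_cutoff
  pairs <- candidate_pairs(top, criteria$neighbor_exclusion)
  if (nrow(pairs) == 0) stop("no candidate residue pairs in topology")
  rows_by_res <- lapply(stats::setNames(nm = unique(top$resid)), function(r)
    residue_atom_rows(top, as.integer(r), criteria$mode))
  n_below <- numeric(nrow(pairs))
  n_total <- 0L
  for (tr in ensemble$trajectories) {
    nfr <- dim(tr$coords)[1]
    if (nfr == 0) next
    n_total <- n_total + nfr
    for (k in seq_len(nrow(pairs))) {
      d <- pair_min_dist_series(tr$coords,
                                rows_by_res[[as.character(pairs$res_a[k])]],
                                rows_by_res[[as.character(pairs$res_b[k])]])
      n_below[k] <- n_below[k] + sum(d < cutoff)
    }
  }
  if (n_total == 0L) stop("ensemble contains zero frames")
  pop <- n_below / n_total
  keep <- pop >= criteria$population_threshold
  out <- data.frame(res_a = pairs$res_a[keep], res_b = pairs$res_b[keep],
                    population = pop[keep])
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  class(out) <- c("cd_contact_set", "data.frame")
  out
}

#' @export
as.data.frame.cd_contact_set <- function(x, ...) {
  out <- x
  attr(out, "criteria") <- NULL
  class(out) <- "data.frame"
  out
}

#' Contact feature name, "a_b" with a < b
#' @param res_a,res_b residue indices.
#' @return character vector.
#' @export
contact_name <- function(res_a, res_b) {
  a <- pmin(res_a, res_b); b <- pmax(res_a, res_b)
  paste(a, b, sep = "_")
}

#' Parse "a_b" contact names into residue index pairs
#' @param name character vector of contact names.
#' @return data.frame with columns `res_a`, `res_b`.
#' @export
parse_contact_name <- function(name) {
  m <- regmatches(name, regexec("^(-?[0-9]+)_(-?[0-9]+)$", name))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed contact name: ", name[bad][1])
  data.frame(res_a = as.integer(vapply(m, `[`, "", 2)),
             res_b = as.integer(vapply(m, `[`, "", 3)))
}

#' Extract per-contact distance time series from an ensemble
#'
#' One series is produced per (contact, trajectory). The time axis starts at
#' 0 (the perturbation frame) and advances by the trajectory frame interval.
#' The `feature_transform` of the criteria is applied (`inverse_distance`
#' returns 1/r in nm^-1).
#'
#' @param ensemble a [cd_ensemble()].
#' @param contact_set a `"cd_contact_set"` (or data.frame with `res_a`,
#'   `res_b`).
#' @param criteria optional [contact_criteria()]; defaults to the set's own.
#' @return A list of class `"cd_series_list"`; each element has fields
#'   `contact`, `res_a`, `res_b`, `trajectory_id`, `times` (ns), `values`,
#'   `transform`.
#' @export
extract_series <- function(ensemble, contact_set, criteria = NULL) {
  stopifnot(inherits(ensemble, "cd_ensemble"))
  if (is.null(criteria)) criteria <- attr(contact_set, "criteria")
  if (is.null(criteria)) criteria <- contact_criteria()
  top <- ensemble$topology
  mode <- criteria$mode
  rows_by_res <- lapply(stats::setNames(nm = unique(top$resid)), function(r)
    residue_atom_rows(top, as.integer(r), mode))
  out <- list()
  for (tr in ensemble$trajectories) {
    nfr <- dim(tr$coords)[1]
    times <- (seq_len(nfr) - 1) * tr$dt_ns
    for (k in seq_len(nrow(contact_set))) {
      a <- contact_set$res_a[k]; b <- contact_set$res_b[k]
      if (!as.character(a) %in% names(rows_by_res) ||
          !as.character(b) %in% names(rows_by_res)) {
        stop("contact residue not resolvable in topology: ",
             contact_name(a, b))
      }
      d <- pair_min_dist_series(tr$coords, rows_by_res[[as.character(a)]],
                                rows_by_res[[as.character(b)]])
      v <- if (criteria$feature_transform == "inverse_distance") 1 / d else d
      out[[length(out) + 1L]] <- list(
        contact = contact_name(a, b), res_a = a, res_b = b,
        trajectory_id = tr$id, times = times, values = v,
        transform = criteria$feature_transform)
    }
  }
  structure(out, class = "cd_series_list")
}

#' Subsample a distance series by a constant stride
#'
#' Keeps frames 0, stride, 2*stride, ... Intended for the correlation /
#' clustering stage only (the timescale fit always uses the full series).
#'
#' @param series one series element (list with `times`, `values`) or a
#'   `"cd_series_list"`.
#' @param stride integer >= 1.
#' @return object of the same shape with subsampled `times`/`values`.
#' @export
subsample <- function(series, stride = 5L) {
  if (stride < 1) stop("stride must be >= 1")
  stride <- as.integer(stride)
  sub1 <- function(s) {
    keep <- seq(1L, length(s$values), by = stride)
    s$times <- s$times[keep]; s$values <- s$values[keep]
    s
  }
  if (inherits(series, "cd_series_list")) {
    structure(lapply(series, sub1), class = "cd_series_list")
  } else sub1(series)
}

#' Write a contact set as TSV or JSON
#' @param contact_set a `"cd_contact_set"`.
#' @param file output path; format chosen by extension (".json" or TSV
#'   otherwise).
#' @return `file`, invisibly.
#' @export
write_contact_set <- function(contact_set, file) {
  df <- as.data.frame(contact_set)[, c("res_a", "res_b", "population")]
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(df, file, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Read a contact set written by [write_contact_set()]
#' @param file TSV or JSON path.
#' @return A `"cd_contact_set"` data.frame.
#' @export
read_contact_set <- function(file) {
  df <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    utils::read.delim(file)
  }
  class(df) <- c("cd_contact_set", "data.frame")
  df
}

#' Write one trajectory's distance series as CSV
#'
#' Dialect: a `time_ns` column plus one column per contact named `"a_b"`.
#'
#' @param series_list a `"cd_series_list"` restricted to one trajectory.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_distance_csv <- function(series_list, file) {
  ids <- unique(vapply(series_list, `[[`, "", "trajectory_id"))
  if (length(ids) != 1) stop("write_distance_csv expects a single trajectory")
  times <- series_list[[1]]$times
  df <- data.frame(time_ns = times)
  for (s in series_list) {
    if (!isTRUE(all.equal(s$times, times))) stop("series time grids differ")
    df[[s$contact]] <- s$values
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read distance-series CSV files (one file per trajectory)
#'
#' @param files character vector of CSV paths in the
#'   [write_distance_csv()] dialect.
#' @param transform how the stored values were transformed
#'   (`"distance"` or `"inverse_distance"`).
#' @return A `"cd_series_list"` over all files.
#' @export
read_distance_csv <- function(files, transform = "distance") {
  out <- list()
  for (f in files) {
    if (!file.exists(f)) stop("distance CSV does not exist: ", f)
    df <- utils::read.csv(f, check.names = FALSE)
    if (!"time_ns" %in% names(df)) stop("missing time_ns column in ", f)
    contacts <- setdiff(names(df), "time_ns")
    pr <- parse_contact_name(contacts)
    for (k in seq_along(contacts)) {
      out[[length(out) + 1L]] <- list(
        contact = contacts[k], res_a = pr$res_a[k], res_b = pr$res_b[k],
        trajectory_id = sub("\\.[^.]*$", "", basename(f)),
        times = df$time_ns, values = df[[contacts[k]]],
        transform = transform)
    }
  }
  structure(out, class = "cd_series_list")
}
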