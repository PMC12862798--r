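#' Specification of a planted block-correlation ensemble
#'
#' Features inside a cluster share a latent per-frame signal, so the
#' expected pairwise Pearson correlation is exactly `rho_in` within a
#' cluster and `rho_out` between clusters (latent-factor construction:
#' `x = sqrt(rho_out) g + sqrt(rho_in - rho_out) z_c + sqrt(1 - rho_in) eps`
#' with standardized independent components). Additional noise features are
#' uncorrelated with everything.
#'
#' @param sizes integer vector of cluster sizes (>= 1 each).
#' @param rho_in target intra-cluster correlation, in (0, 1].
#' @param rho_out target inter-cluster correlation, in [0, 1), strictly
#'   below `rho_in`.
#' @param n_noise number of unclustered noise features.
#' @param mean_nm,sd_nm affine map from standardized latents to distances
#'   (nm); correlations are unaffected.
#' @return list of class `"cd_cluster_spec"`.
#' @export
planted_cluster_spec <- function(sizes, rho_in = 0.8, rho_out = 0,
                                 n_noise = 0L, mean_nm = 0.5, sd_nm = 0.05) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1),
            rho_in > 0, rho_in <= 1, rho_out >= 0, rho_out < 1)
  if (rho_out >= rho_in) stop("infeasible correlation targets: rho_out >= rho_in")
  structure(list(sizes = as.integer(sizes), rho_in = rho_in,
                 rho_out = rho_out, n_noise = as.integer(n_noise),
                 mean_nm = mean_nm, sd_nm = sd_nm),
            class = "cd_cluster_spec")
}

# Synthetic contact names "i_(i+5)" for n features; valid under the
# neighbor-exclusion rule and unique.
synthetic_feature_names <- function(n) contact_name(seq_len(n), seq_len(n) + 5L)

#' Generate distance series with planted block-correlation structure
#'
#' @param spec a [planted_cluster_spec()].
#' @param n_frames frames per feature.
#' @param seed RNG seed; generation is deterministic given (spec, seed).
#' @return list with `series` (n_frames x n_features matrix of distances in
#'   nm, feature names as columns), `labels` (integer ground-truth cluster
#'   per feature; 0 = noise), `spec`.
#' @export
generate_clustered_series <- function(spec, n_frames = 5000L, seed = 1L) {
  stopifnot(inherits(spec, "cd_cluster_spec"), n_frames >= 2)
  set.seed(as.integer(seed))
  n_feat <- sum(spec$sizes) + spec$n_noise
  labels <- c(rep(seq_along(spec$sizes), spec$sizes), rep(0L, spec$n_noise))
  g <- stats::rnorm(n_frames)
  z <- matrix(stats::rnorm(n_frames * length(spec$sizes)), n_frames)
  x <- matrix(0, n_frames, n_feat)
  a <- sqrt(spec$rho_out)
  b <- sqrt(spec$rho_in - spec$rho_out)
  cnoise <- sqrt(1 - spec$rho_in)
  for (j in seq_len(n_feat)) {
    if (labels[j] > 0) {
      x[, j] <- a * g + b * z[, labels[j]] + cnoise * stats::rnorm(n_frames)
    } else {
      x[, j] <- stats::rnorm(n_frames)
    }
  }
  d <- spec$mean_nm + spec$sd_nm * x
  d[d < 0.01] <- 0.01
  colnames(d) <- synthetic_feature_names(n_feat)
  list(series = d, labels = labels, spec = spec)
}

#' Specification of a planted multiexponential response ensemble
#'
#' The generator is the forward model of the timescale fit: each feature's
#' ensemble mean is `r(t) = offset + sum_k a_k exp(-t / tau_k)` and every
#' trajectory adds iid Gaussian observation noise per frame. A fraction of
#' the trajectories runs to `t_max`, the rest to `t_max / 10`, emulating a
#' mixed short/long nonequilibrium design.
#'
#' @param components list, one element per feature, each a data.frame with
#'   columns `tau` (ns, > 0) and `amplitude` (nm, signed).
#' @param offset baseline distance in nm.
#' @param noise_sd Gaussian observation noise sd per frame (nm).
#' @param n_traj number of trajectories (>= 1).
#' @param t_max longest trajectory length (ns).
#' @param frame_interval frame interval in ns (default 0.02, i.e. 20 ps).
#' @param long_traj_fraction fraction of trajectories reaching `t_max`
#'   (default 0.25; the rest stop at `t_max / 10`).
#' @param feature_names optional contact-style names, default `"i_(i+5)"`.
#' @param ar1 optional AR(1) coefficient in [0, 1) for temporally
#'   correlated noise (0 = iid, the default).
#' @param cluster_labels optional integer label per feature; features
#'   sharing a label get correlated observation noise (latent-factor mix
#'   with weight `noise_rho`), so contact clusters are recoverable from the
#'   generated series.
#' @param noise_rho intra-cluster noise correlation in [0, 1).
#' @return list of class `"cd_response_spec"`.
#' @export
planted_response_spec <- function(components, offset = 1.0, noise_sd = 0.05,
                                  n_traj = 12L, t_max = 1000,
                                  frame_interval = 0.02,
                                  long_traj_fraction = 0.25,
                                  feature_names = NULL, ar1 = 0,
                                  cluster_labels = NULL, noise_rho = 0) {
  if (is.data.frame(components)) components <- list(components)
  stopifnot(length(components) >= 1, n_traj >= 1, frame_interval > 0,
            t_max > frame_interval, long_traj_fraction >= 0,
            long_traj_fraction <= 1, ar1 >= 0, ar1 < 1,
            noise_rho >= 0, noise_rho < 1)
  if (!is.null(cluster_labels)) {
    stopifnot(length(cluster_labels) == length(components))
  }
  for (cmp in components) {
    stopifnot(is.data.frame(cmp), all(c("tau", "amplitude") %in% names(cmp)),
              all(cmp$tau > 0))
  }
  if (is.null(feature_names)) {
    feature_names <- synthetic_feature_names(length(components))
  }
  structure(list(components = components, offset = offset,
                 noise_sd = noise_sd, n_traj = as.integer(n_traj),
                 t_max = t_max, frame_interval = frame_interval,
                 long_traj_fraction = long_traj_fraction,
                 feature_names = feature_names, ar1 = ar1,
                 cluster_labels = cluster_labels, noise_rho = noise_rho),
            class = "cd_response_spec")
}

#' Closed-form planted mean response
#' @param spec a [planted_response_spec()].
#' @param feature feature index.
#' @param t times (ns).
#' @return numeric vector `offset + sum_k a_k exp(-t / tau_k)`.
#' @export
planted_mean_response <- function(spec, feature, t) {
  cmp <- spec$components[[feature]]
  out <- rep(spec$offset, length(t))
  for (i in seq_len(nrow(cmp))) {
    out <- out + cmp$amplitude[i] * exp(-t / cmp$tau[i])
  }
  out
}

#' Generate a nonequilibrium response ensemble with known ground truth
#'
#' @param spec a [planted_response_spec()].
#' @param seed RNG seed; deterministic given (spec, seed).
#' @return list with `series` (a `"cd_series_list"`: one element per
#'   (feature, trajectory)), `truth` (the spec: per-feature components and
#'   offset), `n_long` (number of full-length trajectories).
#' @export
generate_response_ensemble <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cd_response_spec"))
  set.seed(as.integer(seed))
  n_long <- max(1L, round(spec$long_traj_fraction * spec$n_traj))
  n_frames_long <- floor(spec$t_max / spec$frame_interval) + 1L
  n_frames_short <- floor(spec$t_max / 10 / spec$frame_interval) + 1L
  out <- list()
  labels <- spec$cluster_labels
  for (tr in seq_len(spec$n_traj)) {
    nfr <- if (tr <= n_long) n_frames_long else n_frames_short
    times <- (seq_len(nfr) - 1) * spec$frame_interval
    latents <- if (!is.null(labels) && spec$noise_rho > 0) {
      matrix(stats::rnorm(nfr * length(unique(labels))), nfr,
             dimnames = list(NULL, as.character(sort(unique(labels)))))
    } else NULL
    for (f in seq_along(spec$components)) {
      mu <- planted_mean_response(spec, f, times)
      eps <- stats::rnorm(nfr)
      if (!is.null(latents)) {
        eps <- sqrt(spec$noise_rho) * latents[, as.character(labels[f])] +
          sqrt(1 - spec$noise_rho) * eps
      }
      eps <- eps * spec$noise_sd
      if (spec$ar1 > 0) {
        eps <- as.numeric(stats::filter(eps, spec$ar1, method = "recursive")) *
          sqrt(1 - spec$ar1^2)
      }
      nm <- spec$feature_names[f]
      pr <- parse_contact_name(nm)
      out[[length(out) + 1L]] <- list(
        contact = nm, res_a = pr$res_a, res_b = pr$res_b,
        trajectory_id = sprintf("traj%03d", tr),
        times = times, values = mu + eps, transform = "distance")
    }
  }
  list(series = structure(out, class = "cd_series_list"),
       truth = spec, n_long = n_long)
}

#' Specification of a toy multi-residue structure ensemble
#'
#' Residues are placed on a wide 3D grid (3 nm spacing) so that unplanned
#' residue pairs are always far beyond the contact cutoff. For each planned
#' pair, residue `res_b` is moved next to `res_a` along x: at separation
#' `d_in` (default 0.3 nm, in contact) in a prescribed fraction of frames
#' and `d_out` (default 0.48 nm, not in contact) otherwise. Each residue
#' carries up to four atoms: CA at the center, CB and O offset in +/-y, and
#' a hydrogen HA offset +0.05 nm in x — so a planned pair at `d_out` has a
#' hydrogen-involving distance below 0.45 nm while its shortest heavy-atom
#' distance stays above, exercising the heavy-atom rule.
#'
#' @param n_residues protein residues (numbered 1..n).
#' @param n_ligand ligand residues (numbered -(n_ligand-1)..0; 0 = none).
#' @param atoms_per_residue 1 to 4 atoms per residue (order CA, CB, O, HA).
#' @param contact_plan data.frame with columns `res_a`, `res_b`,
#'   `population` (target fraction of in-contact frames). Each residue may
#'   appear in at most one planned pair.
#' @param d_in,d_out in/out-of-contact heavy-atom separations (nm).
#' @param dt_ns frame interval (ns).
#' @return list of class `"cd_structure_spec"`.
#' @export
toy_structure_spec <- function(n_residues, n_ligand = 0L,
                               atoms_per_residue = 4L, contact_plan = NULL,
                               d_in = 0.3, d_out = 0.48, dt_ns = 0.02) {
  stopifnot(n_residues >= 1, n_ligand >= 0, atoms_per_residue >= 1,
            atoms_per_residue <= 4, d_in > 0, d_out > d_in, dt_ns > 0)
  resids <- c(if (n_ligand > 0) seq(-(n_ligand - 1L), 0L), seq_len(n_residues))
  if (!is.null(contact_plan)) {
    stopifnot(all(c("res_a", "res_b", "population") %in% names(contact_plan)),
              all(contact_plan$population >= 0),
              all(contact_plan$population <= 1))
    planned <- c(contact_plan$res_a, contact_plan$res_b)
    if (!all(planned %in% resids)) stop("contact_plan references unknown residues")
    if (anyDuplicated(planned)) {
      stop("each residue may appear in at most one planned pair")
    }
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_ligand = as.integer(n_ligand),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 contact_plan = contact_plan, d_in = d_in, d_out = d_out,
                 dt_ns = dt_ns, resids = as.integer(sort(resids))),
            class = "cd_structure_spec")
}

#' Generate a toy structure ensemble with a known contact table
#'
#' @param spec a [toy_structure_spec()].
#' @param n_frames frames to generate.
#' @param seed RNG seed (selects which frames are in contact).
#' @param criteria [contact_criteria()] used to compute the expected
#'   contact set.
#' @return list with `ensemble` (a single-trajectory [cd_ensemble()]),
#'   `expected` (data.frame `res_a`, `res_b`, `population` — exactly what
#'   [identify_contacts()] must return under `criteria`), `spec`.
#' @export
generate_toy_structure_ensemble <- function(spec, n_frames = 50L, seed = 1L,
                                            criteria = contact_criteria()) {
  stopifnot(inherits(spec, "cd_structure_spec"), n_frames >= 1)
  set.seed(as.integer(seed))
  resids <- spec$resids
  nres <- length(resids)
  atom_templ <- list(
    c("CA", 0, 0, 0), c("CB", 0, 0.1, 0), c("O", 0, -0.1, 0),
    c("HA", 0.05, 0, 0))[seq_len(spec$atoms_per_residue)]
  # home grid: 3 nm spacing, wide enough for everything
  side <- ceiling(nres^(1 / 3)) + 1L
  home <- 3 * cbind(seq_len(nres) %% side,
                    (seq_len(nres) %/% side) %% side,
                    seq_len(nres) %/% side^2)
  rownames(home) <- as.character(resids)

  plan <- spec$contact_plan
  in_contact <- list()
  if (!is.null(plan)) {
    for (k in seq_len(nrow(plan))) {
      n_in <- round(plan$population[k] * n_frames)
      in_contact[[k]] <- sort(sample.int(n_frames, n_in))
    }
  }
  atoms <- do.call(rbind, lapply(seq_len(nres), function(i)
    data.frame(atom = vapply(atom_templ, `[`, "", 1), resid = resids[i])))
  top <- cd_topology(atoms$atom, atoms$resid)
  offs <- t(vapply(atom_templ, function(a) as.numeric(a[2:4]), numeric(3)))
  nat <- nrow(top)
  coords <- array(0, dim = c(n_frames, nat, 3))
  centers <- matrix(0, nres, 3)
  for (fr in seq_len(n_frames)) {
    centers[] <- home
    if (!is.null(plan)) {
      for (k in seq_len(nrow(plan))) {
        d <- if (fr %in% in_contact[[k]]) spec$d_in else spec$d_out
        ia <- match(plan$res_a[k], resids); ib <- match(plan$res_b[k], resids)
        centers[ib, ] <- centers[ia, ] + c(d, 0, 0)
      }
    }
    coords[fr, , ] <- centers[rep(seq_len(nres), each = spec$atoms_per_residue), ] +
      offs[rep(seq_len(spec$atoms_per_residue), nres), ]
  }
  traj <- cd_trajectory(coords, top, spec$dt_ns, id = "toy")
  ens <- cd_ensemble(list(traj))

  # expected contact table under the criteria
  cutoff <- if (criteria$mode == "heavy_atom") criteria$heavy_atom_cutoff else criteria$c_alpha_cutoff
  exp_df <- data.frame(res_a = integer(0), res_b = integer(0),
                       population = numeric(0))
  if (!is.null(plan)) {
    for (k in seq_len(nrow(plan))) {
      a <- min(plan$res_a[k], plan$res_b[k]); b <- max(plan$res_a[k], plan$res_b[k])
      same_chain <- (a >= 1) == (b >= 1)
      if (same_chain && abs(a - b) <= criteria$neighbor_exclusion) next
      pop <- (if (spec$d_in < cutoff) length(in_contact[[k]]) else 0) / n_frames +
        (if (spec$d_out < cutoff) (n_frames - length(in_contact[[k]])) else 0) / n_frames
      if (pop >= criteria$population_threshold) {
        exp_df <- rbind(exp_df, data.frame(res_a = a, res_b = b, population = pop))
      }
    }
    exp_df <- exp_df[order(exp_df$res_a, exp_df$res_b), , drop = FALSE]
    rownames(exp_df) <- NULL
  }
  class(exp_df) <- c("cd_contact_set", "data.frame")
  attr(exp_df, "criteria") <- criteria
  list(ensemble = ens, expected = exp_df, spec = spec)
}
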