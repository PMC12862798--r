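# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package code.

# Brute-force contact identification: full atom-distance matrix per frame
# (stats::dist), then an explicit min over each residue pair's block.
brute_force_contacts <- function(ensemble, criteria = contact_criteria()) {
  top <- ensemble$topology
  cutoff <- if (criteria$mode == "heavy_atom") criteria$heavy_atom_cutoff else criteria$c_alpha_cutoff
  resids <- sort(unique(top$resid))
  rows <- lapply(resids, function(r) {
    ix <- which(top$resid == r)
    if (criteria$mode == "c_alpha") ix[top$atom[ix] == "CA"][1]
    else ix[atom_element(top$atom[ix]) != "H"]
  })
  n <- length(resids)
  below <- matrix(0, n, n)
  total <- 0L
  for (tr in ensemble$trajectories) {
    for (fr in seq_len(dim(tr$coords)[1])) {
      total <- total + 1L
      dm <- as.matrix(stats::dist(tr$coords[fr, , ]))
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (min(dm[rows[[i]], rows[[j]]]) < cutoff) below[i, j] <- below[i, j] + 1
      }
    }
  }
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- resids[i]; b <- resids[j]
    same_chain <- (a >= 1) == (b >= 1)
    if (same_chain && abs(a - b) <= criteria$neighbor_exclusion) next
    pop <- below[i, j] / total
    if (pop >= criteria$population_threshold) {
      out <- rbind(out, data.frame(res_a = a, res_b = b, population = pop))
    }
  }
  if (is.null(out)) out <- data.frame(res_a = integer(0), res_b = integer(0),
                                      population = numeric(0))
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct-summation convolution with a truncated, edge-renormalized Gaussian
# kernel (double loop; the oracle for the vectorized filter).
direct_gauss_conv <- function(x, sigma) {
  n <- length(x)
  r <- ceiling(4 * sigma)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (o in -r:r) {
      j <- i + o
      if (j >= 1 && j <= n) {
        wk <- exp(-o^2 / (2 * sigma^2))
        num <- num + wk * x[j]
        den <- den + wk
      }
    }
    out[i] <- num / den
  }
  out
}

# A response object that is already log-spaced and exactly representable in
# the exponential basis (bypasses preprocessing distortion).
prep_response <- function(times, values, sem = 0, offset_hint = NULL) {
  r <- structure(list(feature = "f", times = times, mean = values,
                      sem = rep(sem, length(times)),
                      n_traj = rep(1L, length(times))),
                 class = "cd_response")
  attr(r, "preprocessed") <- TRUE
  if (!is.null(offset_hint)) attr(r, "extension_value") <- offset_hint
  r
}

# Every planted component has a matching spectral peak: same sign, within
# half a decade in tau.
components_recovered <- function(spectrum, components) {
  pk <- spectrum_peaks(spectrum)
  all(vapply(seq_len(nrow(components)), function(i) {
    any(sign(pk$amplitude) == sign(components$amplitude[i]) &
          abs(log10(pk$tau / components$tau[i])) <= 0.5)
  }, logical(1)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

partition_labels <- function(partition) {
  ifelse(is.na(partition$assignment), 0L, partition$assignment)
}

write_series_csvs <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tids <- unique(vapply(series, `[[`, "", "trajectory_id"))
  files <- file.path(dir, paste0(tids, ".csv"))
  for (i in seq_along(tids)) {
    sub <- series[vapply(series, `[[`, "", "trajectory_id") == tids[i]]
    class(sub) <- "cd_series_list"
    write_distance_csv(sub, files[i])
  }
  files
}
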