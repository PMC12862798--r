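# Strict local maxima of a non-negative series (boundary points count when
# they exceed their single neighbor).
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1) return(1L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which(v > left & v > right)
}

#' Peaks of a relaxation spectrum
#'
#' Local maxima of the absolute amplitude `|a_k|`, with small bumps below
#' `floor_frac` of the global maximum suppressed; the sign of each peak is
#' the sign of the amplitude there.
#'
#' @param spectrum a `"cd_spectrum"`.
#' @param floor_frac suppression floor as a fraction of `max |a|`
#'   (default 0.01).
#' @return data.frame with columns `tau`, `amplitude`, `sign`.
#' @export
spectrum_peaks <- function(spectrum, floor_frac = 0.01) {
  a <- spectrum$amplitudes
  mag <- abs(a)
  if (max(mag) == 0) {
    return(data.frame(tau = numeric(0), amplitude = numeric(0),
                      sign = numeric(0)))
  }
  idx <- local_maxima(mag)
  idx <- idx[mag[idx] >= floor_frac * max(mag)]
  data.frame(tau = spectrum$taus[idx], amplitude = a[idx], sign = sign(a[idx]))
}

#' Dynamical content of a set of spectra
#'
#' The dynamical content `D(tau_k) = sum_j a_kj^2` sums the squared fitted
#' amplitudes of all features at each timescale; its peaks mark the
#' characteristic response times of the system. With a cluster partition the
#' profile is decomposed into per-cluster contributions `D_n` (features not
#' in any cluster contribute to a `"noise"` column); the per-cluster columns
#' sum to the total exactly at every `tau_k`.
#'
#' @param spectra list of `"cd_spectrum"` objects on one common grid.
#' @param partition optional `"cd_partition"` (or list with `clusters`,
#'   `noise`) over the spectra's feature names.
#' @param floor_frac peak suppression floor as a fraction of the global
#'   maximum of D (default 0.01).
#' @return list of class `"cd_content"`: `taus`, `total`, `per_cluster`
#'   (matrix, one column per cluster plus `"noise"` when a partition is
#'   given), `peaks` (data.frame `tau`, `height`).
#' @export
dynamical_content <- function(spectra, partition = NULL, floor_frac = 0.01) {
  if (length(spectra) == 0) stop("no spectra")
  taus <- spectra[[1]]$taus
  amp <- vapply(spectra, function(sp) {
    if (!isTRUE(all.equal(sp$taus, taus))) stop("spectra use mixed tau grids")
    sp$amplitudes
  }, numeric(length(taus)))
  amp <- matrix(amp, nrow = length(taus))
  feats <- vapply(spectra, `[[`, "", "feature")
  colnames(amp) <- feats
  total <- rowSums(amp^2)
  per_cluster <- NULL
  if (!is.null(partition)) {
    cl <- partition$clusters
    assigned <- unlist(cl, use.names = FALSE)
    noise <- setdiff(feats, assigned)
    cols <- c(lapply(cl, function(members) {
      members <- intersect(members, feats)
      if (length(members) == 0) rep(0, length(taus))
      else rowSums(amp[, members, drop = FALSE]^2)
    }), list(noise = if (length(noise)) rowSums(amp[, noise, drop = FALSE]^2)
             else rep(0, length(taus))))
    per_cluster <- do.call(cbind, cols)
    colnames(per_cluster) <- c(names(cl), "noise")
  }
  idx <- local_maxima(total)
  if (max(total) > 0) idx <- idx[total[idx] >= floor_frac * max(total)]
  structure(list(taus = taus, total = total, per_cluster = per_cluster,
                 peaks = data.frame(tau = taus[idx], height = total[idx])),
            class = "cd_content")
}

#' @export
print.cd_content <- function(x, ...) {
  cat(sprintf("cd_content: %d taus, %d peaks", length(x$taus), nrow(x$peaks)))
  if (!is.null(x$per_cluster)) {
    cat(sprintf(", %d clusters", ncol(x$per_cluster) - 1L))
  }
  cat("\n")
  if (nrow(x$peaks)) {
    cat("  peaks at:", paste(sprintf("%.3g ns", x$peaks$tau), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a dynamical content profile as CSV
#'
#' Columns: `tau_ns`, `total`, and one column per cluster (plus `noise`)
#' when a decomposition is present; suitable for log-axis plotting.
#'
#' @param content a `"cd_content"`.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_content_csv <- function(content, file) {
  df <- data.frame(tau_ns = content$taus, total = content$total)
  if (!is.null(content$per_cluster)) {
    df <- cbind(df, as.data.frame(content$per_cluster))
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Power-law fit of a long-time response tail
#'
#' Fits `r(t) = prefactor * t^alpha` by least squares on the log-log scale
#' over the window `[t_lo, t_hi]`. Diffusion-governed protein relaxation
#' typically shows `alpha` between about 0.3 (subdiffusive) and 0.5 (normal
#' diffusion).
#'
#' @param response a `"cd_response"` (or list with `times`, `mean`).
#' @param window numeric `c(t_lo, t_hi)` in ns, spanning at least one
#'   decade.
#' @param baseline `"none"` fits `log r`; `"subtract_start"` fits
#'   `log |r(t) - r(t_lo)|` (the window's first point is dropped).
#' @return list of class `"cd_powerlaw"`: `feature`, `alpha`, `prefactor`,
#'   `window`, `r2`.
#' @export
powerlaw_fit <- function(response, window,
                         baseline = c("none", "subtract_start")) {
  baseline <- match.arg(baseline)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[2] / window[1] < 10) stop("window must span at least one decade")
  sel <- response$times >= window[1] & response$times <= window[2]
  t <- response$times[sel]; v <- response$mean[sel]
  if (length(t) < 3) stop("fewer than 3 points in window")
  if (baseline == "subtract_start") {
    v <- abs(v - v[1]); v <- v[-1]; t <- t[-1]
  }
  if (any(v <= 0)) {
    stop("non-positive values in window under baseline mode '", baseline, "'")
  }
  fit <- stats::lm(log(v) ~ log(t))
  lv <- log(v)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((lv - mean(lv))^2)
  structure(list(feature = if (is.null(response$feature)) "feature" else response$feature,
                 alpha = unname(stats::coef(fit)[2]),
                 prefactor = unname(exp(stats::coef(fit)[1])),
                 window = window,
                 r2 = if (sst > 0) 1 - ssr / sst else 1),
            class = "cd_powerlaw")
}
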