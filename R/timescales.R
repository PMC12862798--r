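#' Configuration of the maximum-entropy timescale fit
#'
#' The fit minimizes `chi2 - lambda * S_ent` over signed amplitudes on a
#' log-spaced timescale grid. `chi2` is the mean squared deviation between
#' the multiexponential model and the ensemble-averaged response, weighted
#' pointwise by `1/sem^2` (so that noisy long-time points, averaged over
#' fewer trajectories, count less); `S_ent` is the Skilling entropy of the
#' two-channel amplitude representation (see [maxent_fit()]).
#'
#' @param lam regularization weight `lambda >= 0`. Controls over- vs
#'   under-fitting; scan with [lambda_scan()] to choose per system.
#' @param interp_factor linear-interpolation upsampling factor applied before
#'   log-resampling (default 4).
#' @param frames_per_decade target density of the log-spaced time grid
#'   (default 750 frames per decade).
#' @param filter_sigma standard deviation, in (log-spaced) frames, of the
#'   low-pass Gaussian filter (default 6).
#' @param extend_decades number of decades of constant extension appended
#'   beyond the data window (default 1); the constant is the mean over the
#'   last half decade of the filtered data.
#' @param entropy_prior default amplitude scale `m` of the entropy; `NULL`
#'   sets it per feature to 10% of the response's peak-to-peak range.
#' @param weighting `"sem"` (default) or `"uniform"` chi-square weights.
#' @param max_iter,tol optimizer budget and relative objective tolerance.
#' @return list of class `"cd_maxent_config"`.
#' @export
maxent_config <- function(lam = 1e-3, interp_factor = 4L, frames_per_decade = 750,
                          filter_sigma = 6, extend_decades = 1,
                          entropy_prior = NULL,
                          weighting = c("sem", "uniform"),
                          max_iter = 500L, tol = 1e-12) {
  weighting <- match.arg(weighting)
  stopifnot(lam >= 0, interp_factor >= 1, frames_per_decade > 0,
            filter_sigma > 0, extend_decades >= 0, max_iter >= 1, tol > 0)
  structure(list(lam = lam, interp_factor = as.integer(interp_factor),
                 frames_per_decade = frames_per_decade,
                 filter_sigma = filter_sigma, extend_decades = extend_decades,
                 entropy_prior = entropy_prior, weighting = weighting,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "cd_maxent_config")
}

#' Ensemble-average a feature's distance series over trajectories
#'
#' Trajectories share the perturbation time origin (t = 0) and frame
#' interval but may differ in length (mixed short/long nonequilibrium runs);
#' at each time point the mean and standard error are taken over the
#' trajectories still running, and the contributing count is recorded.
#'
#' @param series_list a `"cd_series_list"` (or plain list of lists with
#'   `times`, `values`) holding one feature's series across trajectories.
#' @return list of class `"cd_response"` with fields `feature`, `times`
#'   (ns), `mean`, `sem`, `n_traj`.
#' @export
ensemble_average <- function(series_list) {
  if (length(series_list) == 0) stop("need >= 1 trajectory")
  feats <- unique(vapply(series_list, function(s)
    if (is.null(s$contact)) "feature" else s$contact, ""))
  if (length(feats) > 1) {
    stop("ensemble_average expects series of a single feature; got: ",
         paste(feats, collapse = ", "))
  }
  lens <- vapply(series_list, function(s) length(s$values), integer(1))
  grid <- series_list[[which.max(lens)]]$times
  for (s in series_list) {
    if (!isTRUE(all.equal(s$times, grid[seq_along(s$times)]))) {
      stop("trajectory time grids are not nested prefixes of a common grid")
    }
  }
  vals <- matrix(NA_real_, length(grid), length(series_list))
  for (j in seq_along(series_list)) {
    vals[seq_along(series_list[[j]]$values), j] <- series_list[[j]]$values
  }
  n_traj <- rowSums(!is.na(vals))
  keep <- n_traj > 0
  if (!all(keep)) warning("time grid truncated to points covered by >= 1 trajectory")
  vals <- vals[keep, , drop = FALSE]; grid <- grid[keep]; n_traj <- n_traj[keep]
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_traj >= 2, sdv / sqrt(n_traj), 0)
  structure(list(feature = feats, times = grid, mean = mu, sem = sem,
                 n_traj = as.integer(n_traj)),
            class = "cd_response")
}

#' Build a log-spaced timescale grid
#'
#' Time constants `tau_k` equally distributed on a logarithmic scale with
#' `per_decade` terms per order of magnitude, spanning `t_min` to
#' `t_max * 10^extend_decades`.
#'
#' @param t_min,t_max grid bounds in ns, `0 < t_min < t_max`.
#' @param per_decade grid density (default 10 terms per decade).
#' @param extend_decades decades appended beyond `t_max` (default 0).
#' @param includes_constant whether fits on this grid carry an explicit
#'   constant (infinite-timescale) offset component.
#' @return list of class `"cd_tau_grid"` with `taus` (ns), `per_decade`,
#'   `includes_constant`.
#' @export
build_tau_grid <- function(t_min, t_max, per_decade = 10L, extend_decades = 0,
                           includes_constant = TRUE) {
  if (!(t_min > 0 && t_max > t_min)) stop("require 0 < t_min < t_max")
  stopifnot(per_decade >= 1)
  span <- log10(t_max) + extend_decades - log10(t_min)
  k <- floor(span * per_decade + 1e-9)
  taus <- 10^(log10(t_min) + (0:k) / per_decade)
  structure(list(taus = taus, per_decade = as.integer(per_decade),
                 includes_constant = isTRUE(includes_constant)),
            class = "cd_tau_grid")
}

#' Gaussian low-pass filter of a uniformly indexed series
#'
#' Discrete convolution with a normalized Gaussian kernel of standard
#' deviation `sigma` samples, truncated at 4 sigma; near the boundaries the
#' kernel is renormalized over the in-range samples.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples.
#' @return filtered vector, same length.
#' @export
gaussian_filter <- function(x, sigma = 6) {
  n <- length(x)
  r <- ceiling(4 * sigma)
  offs <- -r:r
  wk <- exp(-offs^2 / (2 * sigma^2))
  num <- numeric(n); den <- numeric(n)
  for (s in seq_along(offs)) {
    o <- offs[s]
    src <- seq_len(n) + o
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + wk[s] * x[src[ok]]
    den[ok] <- den[ok] + wk[s]
  }
  num / den
}

#' Preprocess an ensemble-averaged response for timescale fitting
#'
#' Applies, in order: (1) linear interpolation between neighboring frames,
#' increasing the frame count by `interp_factor`; (2) resampling onto a
#' log-spaced time axis so every decade contributes equally (about
#' `frames_per_decade` frames); (3) low-pass Gaussian filtering with
#' `filter_sigma` samples to suppress fast fluctuations; (4) extension of
#' the data by `extend_decades` orders of magnitude with a constant equal to
#' the mean over the last half decade of the filtered data. The SEM is
#' propagated through the interpolation/resampling and extension (it is not
#' filtered).
#'
#' @param response a `"cd_response"`.
#' @param config a [maxent_config()].
#' @return a preprocessed `"cd_response"` (attribute `"preprocessed"` set),
#'   with the extension value in attribute `"extension_value"`.
#' @export
preprocess <- function(response, config = maxent_config()) {
  stopifnot(inherits(response, "cd_response"))
  t <- response$times; y <- response$mean
  if (length(t) < 2) stop("need at least 2 frames to preprocess")
  if (!all(is.finite(y))) stop("non-finite response values")
  sem <- response$sem; ntr <- response$n_traj

  # (1) linear interpolation, interp_factor subdivisions per gap
  t1 <- interp_times(t, config$interp_factor)
  y1 <- stats::approx(t, y, xout = t1, rule = 2)$y
  s1 <- stats::approx(t, sem, xout = t1, rule = 2)$y
  n1 <- stats::approx(t, ntr, xout = t1, method = "constant", f = 0, rule = 2)$y

  # (2) log-spaced resampling, ~frames_per_decade per decade
  tpos <- t1[t1 > 0]
  t_lo <- min(tpos); t_hi <- max(tpos)
  ndec <- log10(t_hi / t_lo)
  npts <- max(2L, as.integer(round(config$frames_per_decade * ndec)) + 1L)
  t2 <- 10^seq(log10(t_lo), log10(t_hi), length.out = npts)
  y2 <- stats::approx(t1, y1, xout = t2, rule = 2)$y
  s2 <- stats::approx(t1, s1, xout = t2, rule = 2)$y
  n2 <- stats::approx(t1, n1, xout = t2, method = "constant", f = 0, rule = 2)$y

  # (3) Gaussian low-pass filtering of the mean
  y3 <- gaussian_filter(y2, config$filter_sigma)

  # (4) constant extension beyond the data window
  win <- t2 >= t_hi * 10^(-0.5)
  ext_val <- mean(y3[win])
  ext_sem <- mean(s2[win])
  if (config$extend_decades > 0) {
    dlog <- (log10(t_hi) - log10(t_lo)) / (npts - 1)
    t_ext <- 10^seq(log10(t_hi) + dlog, log10(t_hi) + config$extend_decades,
                    by = dlog)
    t2 <- c(t2, t_ext)
    y3 <- c(y3, rep(ext_val, length(t_ext)))
    s2 <- c(s2, rep(ext_sem, length(t_ext)))
    n2 <- c(n2, rep(n2[npts], length(t_ext)))
  }
  out <- structure(list(feature = response$feature, times = t2, mean = y3,
                        sem = s2, n_traj = as.integer(round(n2))),
                   class = "cd_response")
  attr(out, "preprocessed") <- TRUE
  attr(out, "extension_value") <- ext_val
  out
}

# Time grid after linear upsampling: each gap subdivided into `factor`
# parts, so n frames become factor * (n - 1) + 1.
interp_times <- function(t, factor) {
  if (factor <= 1L) return(t)
  unique(sort(c(t, unlist(lapply(seq_len(length(t) - 1), function(i)
    t[i] + (seq_len(factor - 1) / factor) * (t[i + 1] - t[i]))))))
}

# chi-square weights: 1/sem^2 where available, normalized to mean 1.
chi2_weights <- function(sem, weighting) {
  n <- length(sem)
  if (weighting == "uniform" || all(sem <= 0)) return(rep(1, n))
  s <- sem
  s[s <= 0] <- min(s[s > 0])
  w <- 1 / s^2
  w / mean(w)
}

#' Maximum-entropy multiexponential fit of a response
#'
#' Fits `r(t) = sum_k a_k exp(-t / tau_k) + c` on the log-spaced `tau` grid
#' by minimizing `chi2(a) - lambda * S_ent(a)`. Signed amplitudes are
#' represented by two non-negative channels, `a_k = a_k^+ - a_k^-`, and
#' `S_ent = sum_k sum_pm [a_k^pm - m - a_k^pm log(a_k^pm / m)]` is the
#' Skilling entropy with default scale `m`; the constant offset `c` is an
#' explicit parameter excluded from the entropy, initialized to the
#' long-time extension value. The optimizer is deterministic gradient-based
#' minimization (L-BFGS in log-amplitude space) from the flat start
#' `a^pm = m`, so results are reproducible bit-for-bit given the
#' configuration.
#'
#' @param response a preprocessed `"cd_response"` (see [preprocess()]); raw
#'   responses are accepted and preprocessed on the fly.
#' @param grid a [build_tau_grid()] covering the data window.
#' @param config a [maxent_config()].
#' @return list of class `"cd_spectrum"`: `feature`, `grid`, `taus`,
#'   `amplitudes` (signed, nm), `a_plus`, `a_minus`, `offset` (nm), `chi2`,
#'   `entropy`, `lam`, `objective`, `trace` (objective after each outer
#'   optimizer iteration), `converged`, plus the fitted curve (`times`,
#'   `fitted`, `data`, `weights`).
#' @export
maxent_fit <- function(response, grid, config = maxent_config()) {
  stopifnot(inherits(response, "cd_response"), inherits(grid, "cd_tau_grid"))
  if (!isTRUE(attr(response, "preprocessed"))) {
    response <- preprocess(response, config)
  }
  t <- response$times; y <- response$mean
  if (!all(is.finite(t)) || !all(is.finite(y))) stop("non-finite data in response")
  w <- chi2_weights(response$sem, config$weighting)
  taus <- grid$taus
  K <- length(taus); N <- length(y)
  A <- exp(-outer(t, 1 / taus))
  m <- config$entropy_prior
  if (is.null(m)) m <- 0.1 * diff(range(y))
  if (!is.finite(m) || m <= 0) m <- 1e-8
  lam <- config$lam
  use_offset <- isTRUE(grid$includes_constant)
  c0 <- attr(response, "extension_value")
  if (is.null(c0) || !use_offset) c0 <- 0

  # The objective chi2(a) - lam * S_ent(a) is convex in (a+, a-, offset):
  # chi2 is a convex quadratic and -S_ent = sum a log(a/m) - a + m is convex
  # on a > 0. Solve by damped Newton iteration with the exact Hessian; the
  # entropy's 1/a curvature acts as a natural interior-point barrier and the
  # step is clipped to keep the amplitudes strictly positive.
  P <- 2 * K + as.integer(use_offset)
  B <- cbind(A, -A, if (use_offset) rep(1, N))
  H0 <- (2 / N) * crossprod(B, w * B)
  ridge <- 1e-12 * max(diag(H0))
  objective <- function(z) {
    a <- z[seq_len(2 * K)]
    res <- drop(B %*% z) - y
    chi2 <- mean(w * res^2)
    sent <- sum(a - m - a * log(a / m))
    list(value = chi2 - lam * sent, chi2 = chi2, sent = sent, res = res)
  }
  z <- c(rep(m, 2 * K), if (use_offset) c0)
  st <- objective(z)
  trace <- st$value
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    a <- z[seq_len(2 * K)]
    g <- drop(crossprod(B, (2 / N) * (w * st$res)))
    g[seq_len(2 * K)] <- g[seq_len(2 * K)] + lam * log(a / m)
    H <- H0
    dH <- c(if (lam > 0) lam / a else rep(0, 2 * K), if (use_offset) 0)
    diag(H) <- diag(H) + dH + ridge
    # Bound-constrained Newton step. Amplitudes pinned at (numerical) zero
    # whose gradient pushes them further down are frozen; each coordinate's
    # shrink is limited to 95% of its current value, and coordinates that
    # hit that limit are fixed there while the reduced system is re-solved,
    # so the final direction remains a descent direction.
    idx <- seq_len(2 * K)
    frozen <- c(a <= 1e-10 * m & g[idx] > 0, if (use_offset) FALSE)
    lo <- c(-0.95 * a, if (use_offset) -Inf)
    p <- numeric(P)
    bound <- frozen  # frozen coords behave as bound at step 0
    for (round in 1:6) {
      free <- which(!bound)
      if (length(free) == 0) break
      rhs <- -g[free]
      bnz <- which(bound & !frozen)
      if (length(bnz)) {
        rhs <- rhs - drop(H[free, bnz, drop = FALSE] %*% p[bnz])
      }
      p[free] <- tryCatch(drop(solve(H[free, free, drop = FALSE], rhs)),
                          error = function(e) -g[free])
      viol <- free[p[free] < lo[free]]
      if (length(viol) == 0) break
      p[viol] <- lo[viol]
      bound[viol] <- TRUE
    }
    p[frozen] <- 0
    p[idx] <- pmax(p[idx], lo[idx])
    slope <- sum(g * p)
    if (!is.finite(slope) || slope >= 0) {
      p <- -g
      p[frozen] <- 0
      p[idx] <- pmax(p[idx], lo[idx])
      slope <- sum(g * p)
    }
    alpha <- 1
    # Armijo backtracking (guarantees a monotone objective trace)
    f0 <- st$value
    repeat {
      z_try <- z + alpha * p
      st_try <- objective(z_try)
      if (is.finite(st_try$value) &&
          st_try$value <= f0 + 1e-4 * alpha * slope) break
      alpha <- alpha / 2
      if (alpha < 1e-14) { st_try <- st; z_try <- z; break }
    }
    z <- z_try; st <- st_try
    trace <- c(trace, st$value)
    if (abs(f0 - st$value) <= config$tol * max(1, abs(st$value))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("maxent_fit: optimizer did not converge within max_iter")
  }
  ap <- z[seq_len(K)]; am <- z[K + seq_len(K)]
  cc <- if (use_offset) z[2 * K + 1] else 0
  og <- st
  fitted <- drop(B %*% z)
  structure(list(feature = response$feature, grid = grid, taus = taus,
                 amplitudes = ap - am, a_plus = ap, a_minus = am,
                 offset = cc, chi2 = og$chi2, entropy = og$sent,
                 lam = lam, objective = og$value, trace = trace,
                 converged = converged, prior = m,
                 times = t, fitted = fitted, data = y, weights = w),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  pk <- spectrum_peaks(x)
  cat(sprintf("cd_spectrum [%s]: %d taus (%g..%g ns), lambda = %g, chi2 = %.4g, offset = %.4g nm\n",
              x$feature, length(x$taus), min(x$taus), max(x$taus),
              x$lam, x$chi2, x$offset))
  if (nrow(pk)) {
    cat("  peaks:", paste(sprintf("%.3g ns (%+.3g nm)", pk$tau, pk$amplitude),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scan the regularization parameter lambda
#'
#' Refits the same response at each lambda and tabulates the fit residual,
#' entropy and peak count; chi2 is non-decreasing in lambda.
#'
#' @param response a `"cd_response"`.
#' @param grid a [build_tau_grid()].
#' @param lambdas positive, sorted vector of regularization weights.
#' @param config base [maxent_config()] (its `lam` is ignored).
#' @return list with `summary` (data.frame: lam, chi2, entropy, n_peaks)
#'   and `fits` (list of `"cd_spectrum"`).
#' @export
lambda_scan <- function(response, grid, lambdas, config = maxent_config()) {
  stopifnot(length(lambdas) >= 1, all(lambdas > 0), !is.unsorted(lambdas))
  if (!isTRUE(attr(response, "preprocessed"))) {
    response <- preprocess(response, config)
  }
  fits <- lapply(lambdas, function(l) {
    cfg <- config; cfg$lam <- l
    maxent_fit(response, grid, cfg)
  })
  summary <- data.frame(
    lam = lambdas,
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    entropy = vapply(fits, `[[`, numeric(1), "entropy"),
    n_peaks = vapply(fits, function(f) nrow(spectrum_peaks(f)), integer(1)))
  list(summary = summary, fits = fits)
}

#' Write spectra as CSV (tau_ns plus one amplitude column per feature)
#' @param spectra list of `"cd_spectrum"` sharing one grid.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_spectra_csv <- function(spectra, file) {
  taus <- spectra[[1]]$taus
  df <- data.frame(tau_ns = taus)
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp$taus, taus))) stop("spectra grids differ")
    df[[sp$feature]] <- sp$amplitudes
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a response as CSV (time_ns, mean, sem, n_traj)
#' @param response a `"cd_response"`.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_response_csv <- function(response, file) {
  utils::write.csv(data.frame(time_ns = response$times, mean = response$mean,
                              sem = response$sem, n_traj = response$n_traj),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a response CSV written by [write_response_csv()]
#' @param file CSV path with columns time_ns, mean, sem, n_traj.
#' @param feature feature name to attach.
#' @return a `"cd_response"`.
#' @export
read_response_csv <- function(file, feature = "feature") {
  df <- utils::read.csv(file)
  need <- c("time_ns", "mean", "sem", "n_traj")
  if (!all(need %in% names(df))) stop("response CSV must have columns: ",
                                      paste(need, collapse = ", "))
  structure(list(feature = feature, times = df$time_ns, mean = df$mean,
                 sem = df$sem, n_traj = as.integer(df$n_traj)),
            class = "cd_response")
}
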