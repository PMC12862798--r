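test_that("ensemble_average pools trajectories of mixed length", {
  mk <- function(v, dt = 0.02) list(contact = "1_6", res_a = 1, res_b = 6,
                                    trajectory_id = paste0("t", length(v)),
                                    times = (seq_along(v) - 1) * dt,
                                    values = v, transform = "distance")
  # identical trajectories -> sem 0
  r <- ensemble_average(list(mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(r$sem, c(0, 0, 0))
  # two values 1 and 3 -> mean 2, sem 1
  r2 <- ensemble_average(list(mk(1), mk(3)))
  expect_equal(r2$mean, 2)
  expect_equal(r2$sem, 1)
  # mixed-length design: contributing count drops past the short length
  short <- lapply(1:9, function(i) mk(rep(1, 10)))
  long <- lapply(1:3, function(i) mk(rep(1, 100)))
  r3 <- ensemble_average(c(short, long))
  expect_equal(r3$n_traj[1], 12L)
  expect_equal(r3$n_traj[11], 3L)
  expect_equal(r3$n_traj[100], 3L)
})

test_that("tau grids are log-spaced with the requested density", {
  g <- build_tau_grid(1, 1e4, per_decade = 10)
  expect_length(g$taus, 41)
  expect_equal(unique(round(diff(log10(g$taus)), 12)), 0.1)
  expect_equal(g$taus[1], 1)
  expect_equal(g$taus[41], 1e4)
  g2 <- build_tau_grid(0.04, 1000, per_decade = 10, extend_decades = 1)
  expect_equal(max(g2$taus), 0.04 * 10^(floor(log10(1000 * 10 / 0.04) * 10) / 10))
  expect_error(build_tau_grid(10, 1), "t_min < t_max")
})

test_that("linear interpolation yields the predicted sample counts", {
  t <- (0:9) * 0.02
  t1 <- contactdyn:::interp_times(t, 4L)
  expect_length(t1, 4 * 9 + 1)
  expect_true(all(t %in% t1))
  expect_length(contactdyn:::interp_times(t, 1L), 10)
})

test_that("constants are fixed points of the whole preprocessing chain", {
  resp <- structure(list(feature = "f", times = (0:499) * 0.02,
                         mean = rep(1.7, 500), sem = rep(0.01, 500),
                         n_traj = rep(10L, 500)), class = "cd_response")
  prep <- preprocess(resp, maxent_config())
  expect_equal(prep$mean, rep(1.7, length(prep$times)))
  expect_equal(attr(prep, "extension_value"), 1.7)
  expect_equal(prep$sem, rep(0.01, length(prep$times)))
  # extension adds one decade beyond the data window
  expect_gt(max(prep$times) / max(resp$times), 9.9)
})

test_that("the Gaussian filter equals direct-summation convolution", {
  set.seed(4)
  x <- exp(-(1:400) / 120) + rnorm(400, sd = 0.05)
  expect_equal(gaussian_filter(x, 6), direct_gauss_conv(x, 6),
               tolerance = 1e-13)
  expect_equal(max(abs(gaussian_filter(x, 6) - direct_gauss_conv(x, 6))), 0,
               tolerance = 1e-12)
})

test_that("the boundary extension equals the mean of the last half decade", {
  set.seed(5)
  resp <- structure(list(feature = "f", times = (0:999) * 0.02,
                         mean = 1 + exp(-(0:999) * 0.02 / 2) +
                           rnorm(1000, sd = 0.01),
                         sem = rep(0.01, 1000), n_traj = rep(10L, 1000)),
                    class = "cd_response")
  cfg <- maxent_config()
  prep0 <- preprocess(resp, maxent_config(extend_decades = 0))
  t_hi <- max(prep0$times)
  ref <- mean(prep0$mean[prep0$times >= t_hi * 10^(-0.5)])
  prep1 <- preprocess(resp, cfg)
  expect_equal(attr(prep1, "extension_value"), ref)
  # the appended points carry exactly that constant
  expect_equal(unique(prep1$mean[prep1$times > t_hi * 1.0001]), ref)
})

test_that("maxent_fit concentrates mass at an on-grid tau for noiseless data", {
  t <- 10^seq(log10(0.01), 4, length.out = 3000)
  resp <- prep_response(t, 1 + exp(-t / 30), offset_hint = 1)
  grid <- build_tau_grid(0.03, 1000, per_decade = 5, extend_decades = 1)
  expect_true(any(abs(log10(grid$taus / 30)) < 1e-9))
  sp <- maxent_fit(resp, grid, maxent_config(lam = 1e-12, weighting = "uniform",
                                             tol = 1e-18, max_iter = 3000))
  mass <- abs(sp$amplitudes)
  near <- abs(log10(sp$taus / 30)) <= 1 / grid$per_decade + 1e-9
  expect_gte(sum(mass[near]) / sum(mass), 0.9)
  expect_lt(sqrt(mean((sp$fitted - sp$data)^2)), 0.01)
})

test_that("flat data yields an offset and a near-empty spectrum", {
  t <- 10^seq(log10(0.01), 3, length.out = 2000)
  resp <- prep_response(t, rep(2, length(t)), offset_hint = 2)
  grid <- build_tau_grid(0.03, 100, per_decade = 10, extend_decades = 1)
  sp <- maxent_fit(resp, grid, maxent_config(lam = 1e-3, entropy_prior = 0.1))
  expect_equal(sp$offset, 2, tolerance = 1e-6)
  expect_lte(max(abs(sp$amplitudes)), 0.1 * 1e-2)
})

test_that("opposite-sign components (rise at 30 ns, decay at 800 ns) are recovered", {
  comps <- data.frame(tau = c(30, 800), amplitude = c(-0.3, 0.5))
  spec <- planted_response_spec(list(comps), offset = 1, noise_sd = 0.025,
                                n_traj = 12, t_max = 10000,
                                frame_interval = 0.02,
                                long_traj_fraction = 0.25)
  gen <- generate_response_ensemble(spec, seed = 2)
  resp <- ensemble_average(gen$series)
  grid <- build_tau_grid(0.04, 10000, per_decade = 10, extend_decades = 1)
  sp <- maxent_fit(resp, grid, maxent_config())
  expect_true(components_recovered(sp, comps))
  expect_true(sp$converged)
  expect_true(all(diff(sp$trace) <= 1e-12))
})

test_that("amplitudes scale linearly with the data when the prior is scaled", {
  t <- 10^seq(log10(0.05), 3, length.out = 1500)
  y <- 0.6 * exp(-t / 20) + 1
  grid <- build_tau_grid(0.1, 1000, per_decade = 5, extend_decades = 0)
  base <- maxent_fit(prep_response(t, y, offset_hint = 1), grid,
                     maxent_config(lam = 1e-6, weighting = "uniform",
                                   entropy_prior = 0.05))
  # chi2 is quadratic in the data scale while S_ent is linear, so matched
  # regularization scales both the prior and lambda with the data
  for (cc in c(0.5, 2)) {
    scaled <- maxent_fit(prep_response(t, cc * y, offset_hint = cc), grid,
                         maxent_config(lam = 1e-6 * cc, weighting = "uniform",
                                       entropy_prior = 0.05 * cc))
    expect_equal(scaled$amplitudes, cc * base$amplitudes, tolerance = 1e-3)
    expect_equal(scaled$offset, cc * base$offset, tolerance = 1e-3)
  }
})

test_that("lambda_scan: chi2 grows with lambda and the zero limit is least squares", {
  set.seed(9)
  t <- 10^seq(log10(0.1), 3, length.out = 1500)
  y <- 1 + 0.8 * exp(-t / 3) - 0.4 * exp(-t / 80) + rnorm(length(t), sd = 0.01)
  resp <- prep_response(t, y, sem = 0.01, offset_hint = 1)
  grid <- build_tau_grid(0.2, 1000, per_decade = 5)
  sc <- lambda_scan(resp, grid, c(1e-12, 1e-3, 0.05, 1, 50),
                    maxent_config(weighting = "uniform", tol = 1e-16,
                                  max_iter = 2000))
  expect_true(!is.unsorted(sc$summary$chi2))
  # independent reference: unregularized least squares on the same basis
  X <- cbind(exp(-outer(t, 1 / grid$taus)), 1)
  chi2_ls <- mean(stats::lm.fit(X, y)$residuals^2)
  expect_equal(sc$summary$chi2[1], chi2_ls, tolerance = 0.01)
  expect_gte(sc$summary$chi2[5], sc$summary$chi2[2])
})

test_that("response CSV and spectra CSV writers round-trip", {
  resp <- structure(list(feature = "1_6", times = c(0, 0.02, 0.04),
                         mean = c(1, 1.1, 1.2), sem = c(0, 0.1, 0.1),
                         n_traj = c(3L, 3L, 2L)), class = "cd_response")
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(resp, f)
  back <- read_response_csv(f, feature = "1_6")
  expect_equal(back$mean, resp$mean)
  expect_equal(back$n_traj, resp$n_traj)
})
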