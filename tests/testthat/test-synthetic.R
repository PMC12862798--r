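test_that("planted correlations hit their targets", {
  spec <- planted_cluster_spec(sizes = c(6, 6), rho_in = 0.8, rho_out = 0.05)
  gen <- generate_clustered_series(spec, n_frames = 8000, seed = 2)
  r <- stats::cor(gen$series)
  intra1 <- r[1:6, 1:6][upper.tri(diag(6))]
  inter <- r[1:6, 7:12]
  expect_lt(abs(mean(intra1) - 0.8), 0.05)
  expect_lt(abs(mean(inter) - 0.05), 0.05)

  # rho_in = 1 means identical standardized series: correlation exactly 1
  spec1 <- planted_cluster_spec(sizes = c(4), rho_in = 1, rho_out = 0)
  gen1 <- generate_clustered_series(spec1, n_frames = 500, seed = 3)
  expect_equal(max(abs(stats::cor(gen1$series) - 1)), 0, tolerance = 1e-12)

  # independent clusters decorrelate at large n
  spec0 <- planted_cluster_spec(sizes = c(5, 5), rho_in = 0.8, rho_out = 0)
  gen0 <- generate_clustered_series(spec0, n_frames = 1e5, seed = 4)
  r0 <- stats::cor(gen0$series)
  expect_lt(mean(abs(r0[1:5, 6:10])), 0.02)

  expect_error(planted_cluster_spec(sizes = 4, rho_in = 0.5, rho_out = 0.6),
               "infeasible")
})

test_that("generators are deterministic and seeds give compatible ensembles", {
  spec <- planted_cluster_spec(sizes = c(5, 5), rho_in = 0.8, rho_out = 0)
  a <- generate_clustered_series(spec, n_frames = 2000, seed = 7)
  b <- generate_clustered_series(spec, n_frames = 2000, seed = 7)
  expect_identical(a$series, b$series)
  ref <- generate_clustered_series(spec, n_frames = 2000, seed = 1)
  for (s in 2:10) {
    other <- generate_clustered_series(spec, n_frames = 2000, seed = s)
    p <- suppressWarnings(stats::ks.test(ref$series[, 1], other$series[, 1]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("response generator matches its closed form and SEM scaling", {
  comps <- data.frame(tau = 50, amplitude = 0.5)
  spec <- planted_response_spec(list(comps), offset = 1, noise_sd = 0,
                                n_traj = 1, t_max = 100,
                                frame_interval = 0.1, long_traj_fraction = 1)
  gen <- generate_response_ensemble(spec, seed = 1)
  s <- gen$series[[1]]
  expect_equal(s$values, 1 + 0.5 * exp(-s$times / 50))

  # SEM ~ sigma / sqrt(n_traj) at full-coverage times
  specn <- planted_response_spec(list(comps), offset = 1, noise_sd = 0.1,
                                 n_traj = 100, t_max = 20,
                                 frame_interval = 0.1, long_traj_fraction = 1)
  genn <- generate_response_ensemble(specn, seed = 2)
  r <- ensemble_average(genn$series)
  expect_lt(abs(mean(r$sem) - 0.1 / 10) / (0.1 / 10), 0.2)

  # ensemble mean converges on the closed form (3 sem pointwise)
  specm <- planted_response_spec(list(comps), offset = 1, noise_sd = 0.05,
                                 n_traj = 10000, t_max = 5,
                                 frame_interval = 0.1, long_traj_fraction = 1)
  genm <- generate_response_ensemble(specm, seed = 3)
  rm_ <- ensemble_average(genm$series)
  truth <- 1 + 0.5 * exp(-rm_$times / 50)
  expect_true(all(abs(rm_$mean - truth) <= 3 * rm_$sem))
})

test_that("trajectory length mixture follows the long fraction", {
  spec <- planted_response_spec(list(data.frame(tau = 10, amplitude = 0.3)),
                                n_traj = 12, t_max = 100,
                                frame_interval = 0.1,
                                long_traj_fraction = 0.25)
  gen <- generate_response_ensemble(spec, seed = 5)
  expect_equal(gen$n_long, 3L)
  lens <- vapply(gen$series, function(s) max(s$times), numeric(1))
  expect_equal(sum(lens == 100), 3L)
  expect_equal(sum(lens == 10), 9L)
})

test_that("a fast-quiet then slow-response scenario leaves early times empty", {
  # nothing before ~200 ns, then a 3 us component
  comps <- data.frame(tau = 3000, amplitude = 0.5)
  spec <- planted_response_spec(list(comps), offset = 1, noise_sd = 0.04,
                                n_traj = 30, t_max = 30000,
                                frame_interval = 0.5,
                                long_traj_fraction = 0.3)
  gen <- generate_response_ensemble(spec, seed = 8)
  grid <- build_tau_grid(1, 30000, per_decade = 10, extend_decades = 1)
  sp <- maxent_fit(ensemble_average(gen$series), grid,
                   maxent_config(lam = 0.01))
  frac_early <- sum(abs(sp$amplitudes[sp$taus < 100])) / sum(abs(sp$amplitudes))
  expect_lt(frac_early, 0.05)
  expect_true(components_recovered(sp, comps))
})

test_that("toy structures honor planted populations and contact modes", {
  spec <- toy_structure_spec(n_residues = 8, contact_plan = data.frame(
    res_a = c(1, 4), res_b = c(6, 8), population = c(1, 0.05)))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 100, seed = 6)
  expect_equal(as.data.frame(gen$expected),
               data.frame(res_a = 1, res_b = 6, population = 1))
  cs <- identify_contacts(gen$ensemble)
  expect_equal(as.data.frame(cs), as.data.frame(gen$expected))

  # CA-CA distance is never below the heavy-atom minimum
  tr <- gen$ensemble$trajectories[[1]]
  for (fr in c(1, 50)) {
    for (pair in list(c(1, 6), c(4, 8), c(2, 7))) {
      ha <- min_residue_distance(tr$coords[fr, , ], tr$topology, pair)
      ca <- min_residue_distance(tr$coords[fr, , ], tr$topology, pair,
                                 mode = "c_alpha")
      expect_gte(ca + 1e-12, ha)
    }
  }
})

test_that("the hydrogen rule matters: H-only proximity is not a contact", {
  # planned pair out of contact sits at 0.48 nm heavy-atom separation but
  # 0.43 nm between a hydrogen and a heavy atom
  spec <- toy_structure_spec(n_residues = 6, contact_plan = data.frame(
    res_a = 1, res_b = 5, population = 0))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 10, seed = 1)
  tr <- gen$ensemble$trajectories[[1]]
  top <- tr$topology
  ia <- which(top$resid == 1); ib <- which(top$resid == 5)
  dall <- Inf
  for (p in ia) for (q in ib) {
    dall <- min(dall, sqrt(sum((tr$coords[1, p, ] - tr$coords[1, q, ])^2)))
  }
  expect_lt(dall, 0.45)  # some atom pair (involving H) is inside the cutoff
  expect_gt(min_residue_distance(tr$coords[1, , ], top, c(1, 5)), 0.45)
  expect_equal(nrow(identify_contacts(gen$ensemble)), 0L)
})
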