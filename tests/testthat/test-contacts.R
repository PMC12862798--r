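test_that("min_residue_distance matches hand-checkable geometries", {
  top <- cd_topology(c("CA", "CA"), c(1L, 5L))
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_equal(min_residue_distance(xyz, top, c(1, 5)), 0.3)
  expect_equal(min_residue_distance(xyz, top, c(5, 1)), 0.3)

  top2 <- cd_topology(c("CA", "CB", "CA"), c(1L, 1L, 5L))
  xyz2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.4, 0, 0))
  expect_equal(min_residue_distance(xyz2, top2, c(1, 5)), 0.4)
})

test_that("min_residue_distance equals the brute-force all-pairs minimum", {
  set.seed(101)
  n_res <- 50
  top <- cd_topology(rep(c("N", "CA", "C"), n_res),
                     rep(seq_len(n_res), each = 3))
  xyz <- matrix(runif(3 * n_res * 3, 0, 5), ncol = 3)
  for (k in 1:25) {
    pair <- sample(n_res, 2)
    got <- min_residue_distance(xyz, top, pair)
    ra <- which(top$resid == pair[1]); rb <- which(top$resid == pair[2])
    ref <- Inf
    for (p in ra) for (q in rb) ref <- min(ref, sqrt(sum((xyz[p, ] - xyz[q, ])^2)))
    expect_equal(got, ref)
  }
})

test_that("c_alpha mode uses the single CA pair and reports missing CA", {
  top <- cd_topology(c("CA", "CB", "CB"), c(1L, 1L, 5L))
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(1, 0, 0))
  expect_error(min_residue_distance(xyz, top, c(1, 5), mode = "c_alpha"),
               "no CA atom")
  top2 <- cd_topology(c("CA", "CB", "CA"), c(1L, 1L, 5L))
  expect_equal(min_residue_distance(xyz, top2, c(1, 5), mode = "c_alpha"), 1)
  # only hydrogens -> no heavy atoms
  top3 <- cd_topology(c("HA", "CA"), c(1L, 5L))
  expect_error(min_residue_distance(xyz[1:2, ], top3, c(1, 5)),
               "no heavy atoms")
})

test_that("identify_contacts applies population threshold and neighbor exclusion", {
  spec <- toy_structure_spec(n_residues = 10, contact_plan = data.frame(
    res_a = c(1, 4, 7), res_b = c(9, 8, 10),
    population = c(0.05, 0.10, 0.50)))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 100, seed = 5)
  cs <- identify_contacts(gen$ensemble)
  # the 5% pair is below threshold; the 10% and 50% pairs are kept
  expect_equal(as.data.frame(cs),
               data.frame(res_a = c(4, 7), res_b = c(8, 10),
                          population = c(0.10, 0.50)))

  # a persistent (i, i+2) pair is sequence-excluded
  spec2 <- toy_structure_spec(n_residues = 6, contact_plan = data.frame(
    res_a = 2, res_b = 4, population = 1))
  gen2 <- generate_toy_structure_ensemble(spec2, n_frames = 20, seed = 1)
  expect_equal(nrow(identify_contacts(gen2$ensemble)), 0L)

  # protein-ligand pairs are never sequence-excluded
  spec3 <- toy_structure_spec(n_residues = 4, n_ligand = 2, contact_plan =
    data.frame(res_a = 0, res_b = 1, population = 1))
  gen3 <- generate_toy_structure_ensemble(spec3, n_frames = 20, seed = 1)
  cs3 <- identify_contacts(gen3$ensemble)
  expect_equal(as.data.frame(cs3),
               data.frame(res_a = 0L, res_b = 1L, population = 1))
})

test_that("identify_contacts is invariant to trajectory order and atom order", {
  spec <- toy_structure_spec(n_residues = 8, contact_plan = data.frame(
    res_a = c(1, 5), res_b = c(6, 8), population = c(0.4, 0.9)))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 30, seed = 2)
  tr <- gen$ensemble$trajectories[[1]]
  half <- dim(tr$coords)[1] %/% 2
  t1 <- cd_trajectory(tr$coords[1:half, , , drop = FALSE], tr$topology,
                      tr$dt_ns, "a")
  t2 <- cd_trajectory(tr$coords[(half + 1):dim(tr$coords)[1], , , drop = FALSE],
                      tr$topology, tr$dt_ns, "b")
  cs12 <- identify_contacts(cd_ensemble(list(t1, t2)))
  cs21 <- identify_contacts(cd_ensemble(list(t2, t1)))
  expect_equal(as.data.frame(cs12), as.data.frame(cs21))

  # shuffle atoms within the topology
  set.seed(3)
  perm <- order(tr$topology$resid, runif(nrow(tr$topology)))
  top_p <- cd_topology(tr$topology$atom[perm], tr$topology$resid[perm])
  tr_p <- cd_trajectory(tr$coords[, perm, , drop = FALSE], top_p, tr$dt_ns)
  cs_p <- identify_contacts(cd_ensemble(list(tr_p)))
  expect_equal(as.data.frame(cs_p), as.data.frame(identify_contacts(gen$ensemble)))
})

test_that("raising the population threshold only shrinks the contact set", {
  spec <- toy_structure_spec(n_residues = 12, contact_plan = data.frame(
    res_a = c(1, 4, 7, 10), res_b = c(12, 8, 11, 5),
    population = c(0.15, 0.3, 0.6, 0.95)))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 40, seed = 7)
  sets <- lapply(c(0.1, 0.25, 0.5, 0.9), function(th)
    identify_contacts(gen$ensemble, contact_criteria(population_threshold = th)))
  for (i in seq_len(length(sets) - 1)) {
    larger <- contact_name(sets[[i]]$res_a, sets[[i]]$res_b)
    smaller <- contact_name(sets[[i + 1]]$res_a, sets[[i + 1]]$res_b)
    expect_true(all(smaller %in% larger))
  }
})

test_that("extract_series applies transform and the frame-interval time axis", {
  spec <- toy_structure_spec(n_residues = 6, contact_plan = data.frame(
    res_a = 1, res_b = 5, population = 1), dt_ns = 0.02)
  gen <- generate_toy_structure_ensemble(spec, n_frames = 10, seed = 1)
  cs <- gen$expected
  ser <- extract_series(gen$ensemble, cs)
  expect_length(ser, 1)
  expect_equal(ser[[1]]$times, seq(0, 0.18, by = 0.02))
  expect_equal(ser[[1]]$values, rep(0.3, 10))

  crit_inv <- contact_criteria(feature_transform = "inverse_distance")
  ser_inv <- extract_series(gen$ensemble, cs, crit_inv)
  expect_equal(ser_inv[[1]]$values, 1 / ser[[1]]$values)
})

test_that("subsample keeps every stride-th frame and validates stride", {
  s <- list(times = (0:9) * 0.02, values = 1:10)
  out <- subsample(s, 5)
  expect_equal(out$values, c(1, 6))
  expect_equal(subsample(s, 1)$values, s$values)
  long <- list(times = (0:999) * 0.02, values = rnorm(1000))
  expect_length(subsample(long, 5)$values, 200)
  expect_error(subsample(s, 0), "stride")
})

test_that("contact set and distance CSV writers round-trip", {
  spec <- toy_structure_spec(n_residues = 8, contact_plan = data.frame(
    res_a = c(1, 4), res_b = c(6, 8), population = c(0.5, 1)))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 20, seed = 4)
  cs <- identify_contacts(gen$ensemble)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contact_set(cs, tsv)
  expect_equal(as.data.frame(read_contact_set(tsv)), as.data.frame(cs))

  ser <- extract_series(gen$ensemble, cs)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(ser, csv)
  back <- read_distance_csv(csv)
  expect_length(back, 2)
  expect_equal(back[[1]]$values, ser[[1]]$values)
  expect_equal(back[[2]]$contact, ser[[2]]$contact)
})

test_that("multi-model PDB round-trips through the reader", {
  spec <- toy_structure_spec(n_residues = 5, n_ligand = 2, contact_plan =
    data.frame(res_a = 1, res_b = 4, population = 0.5))
  gen <- generate_toy_structure_ensemble(spec, n_frames = 8, seed = 9)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(gen$ensemble$trajectories[[1]], pdb)
  ens <- read_structure_ensemble(pdb, dt_ns = 0.02)
  expect_equal(dim(ens$trajectories[[1]]$coords),
               dim(gen$ensemble$trajectories[[1]]$coords))
  # PDB stores 3 decimals in Angstrom -> 1e-4 nm resolution
  expect_equal(ens$trajectories[[1]]$coords,
               gen$ensemble$trajectories[[1]]$coords, tolerance = 1e-3)
  cs <- identify_contacts(ens)
  expect_equal(as.data.frame(cs), as.data.frame(gen$expected))
})
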