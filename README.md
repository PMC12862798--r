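# contactdyn

Contact-cluster and relaxation-timescale analysis of protein MD ensembles.

When an ensemble of nonequilibrium molecular dynamics trajectories records a
protein relaxing after a perturbation (a photoswitch flip, a ligand event),
the mechanistic question is *which parts move, together with whom, and when*.
`contactdyn` answers it in four steps:

1. **Contacts** — identify inter-residue contact features: shortest
   heavy-atom distance below 0.45 nm for at least 10% of all frames,
   excluding nearest sequence neighbors (|i − j| > 2). A Cα variant
   (0.8 nm) and an inverse-distance transform are available.
2. **Contact clusters** — compute the |Pearson| correlation matrix of all
   contact distances (every fifth frame suffices) and partition it with
   Leiden community detection under the constant Potts model,
   maximizing Σ_c [W_c − γ·n_c(n_c−1)/2] over partitions; γ ∈ (0, 1] sets
   the minimum average internal correlation of a cluster.
3. **Timescales** — fit each ensemble-averaged distance r_j(t) with a
   maximum-entropy regularized multiexponential expansion,
   r_j(t) = Σ_k a_kj exp(−t/τ_k) + c_j, on a log-spaced τ grid (10 per
   decade), minimizing χ² − λS_ent with a two-channel Skilling entropy so
   amplitudes can take either sign.
4. **Dynamical content** — D(τ_k) = Σ_j a_kj², decomposed by cluster: its
   peaks are the characteristic response times, attributed to specific
   groups of contacts. Power-law tail fits r(t) ∝ t^α classify
   diffusion-governed long-time relaxation (α ≈ 0.3 subdiffusive,
   α ≈ 0.5 diffusive).

A synthetic-data module generates ensembles with planted correlation blocks,
planted relaxation spectra, and toy atomic structures, so every stage is
testable against exact ground truth without any MD data. See the vignette
(`vignettes/contact-cluster-timescales.Rmd`) for the methods and design
rationale.

## Worked example

Two planted contact clusters relaxing at 30 ns and 800 ns, 12 trajectories
(a quarter running 10× longer), 5% observation noise:

```r
library(contactdyn)

comps <- list(data.frame(tau = 30,  amplitude = 0.5),
              data.frame(tau = 30,  amplitude = 0.4),
              data.frame(tau = 800, amplitude = -0.4),
              data.frame(tau = 800, amplitude = -0.5))
spec <- planted_response_spec(comps, offset = 1, noise_sd = 0.05,
                              n_traj = 12, t_max = 10000, frame_interval = 0.1,
                              long_traj_fraction = 0.25,
                              cluster_labels = c(1, 1, 2, 2), noise_rho = 0.7)
gen <- generate_response_ensemble(spec, seed = 1)

x     <- series_feature_matrix(gen$series, stride = 5)
model <- correlation_matrix(x, method = "pearson_abs")
part  <- leiden_cpm(model, mosaic_config(gamma = 0.4))
part
#> cd_partition: 2 clusters (+0 noise features), gamma = 0.4, CPM objective = 0.89257
#>   C1 (2): 1_6 2_7
#>   C2 (2): 3_8 4_9

resp <- ensemble_average(gen$series[vapply(gen$series, `[[`, "", "contact") == "1_6"])
grid <- build_tau_grid(0.2, 10000, per_decade = 10, extend_decades = 1)
maxent_fit(resp, grid, maxent_config())
#> cd_spectrum [1_6]: 57 taus (0.2..79621.4 ns), lambda = 0.001, chi2 = 4.936e-05, offset = 0.9992 nm
#>   peaks: ..., 31.7 ns (+0.0662 nm), ...
```

The partition recovers the planted clusters exactly, and the dominant
spectral peak of feature `1_6` sits at 31.7 ns with positive sign — the
planted 30 ns rise (neighboring grid point; peak positions are accurate to a
few hundredths of a decade). Decomposing the dynamical content,

```r
spectra <- lapply(colnames(x), function(f) {
  sub <- gen$series[vapply(gen$series, `[[`, "", "contact") == f]
  class(sub) <- "cd_series_list"
  maxent_fit(ensemble_average(sub), grid, maxent_config())
})
dynamical_content(spectra, part)
#> cd_content: 57 taus, 3 peaks, 2 clusters
#>   peaks at: 2.52 ns, 31.7 ns, 796 ns
```

the two main D(τ) peaks land at 31.7 ns (cluster C1) and 796 ns (cluster
C2), each within a grid step of its planted timescale; the small 2.5 ns bump
is residual noise structure an order of magnitude below them.

For file-based runs, `run_pipeline()` orchestrates
contacts → cluster → fit → content from a YAML config, persists every
intermediate with MD5 checksums in a run manifest, supports `--resume`, and
is byte-reproducible given the same config and seed
(`inst/scripts/contactdyn-pipeline.R` is the command-line wrapper).

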