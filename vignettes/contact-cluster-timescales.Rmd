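---
title: "Contact clusters and relaxation timescales: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact clusters and relaxation timescales: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactdyn)
```

## The problem

When a protein is perturbed at one site — for example by the photoisomerization
of a covalently attached azobenzene switch — the perturbation propagates
through the structure on timescales from picoseconds to tens of microseconds.
Ensembles of nonequilibrium molecular dynamics (MD) trajectories, all launched
at the moment of the perturbation, record this relaxation, but distilling the
mechanism from hundreds of gigabytes of coordinates requires (i) a feature set
that captures short-range mechanics, (ii) a way to discard uncorrelated
motion, and (iii) a way to assign timescales to what remains.

`contactdyn` implements this chain:

1. **Contacts.** Inter-residue contact distances are the features: a residue
   pair is a contact feature when its shortest heavy-atom distance is below
   0.45 nm in at least 10% of all frames, excluding the two nearest sequence
   neighbors (`|i - j| > 2`).
2. **Contact clusters.** The (absolute) Pearson correlation matrix of all
   contact distances is partitioned by Leiden community detection under the
   constant Potts model (CPM); a cluster is a group of contacts whose
   distance fluctuations are mutually correlated — the candidate "moving
   parts" of an allosteric mechanism.
3. **Timescales.** Each ensemble-averaged contact distance $r_j(t)$ is fitted
   with a multiexponential expansion
   $r_j(t) = \sum_k a_{kj}\, e^{-t/\tau_k} + c_j$
   on a log-spaced grid of time constants, regularized by a maximum-entropy
   term.
4. **Dynamical content.** $D(\tau_k) = \sum_j a_{kj}^2$ summarizes when the
   system responds; decomposing the sum by cluster attributes each response
   timescale to a specific group of contacts.

## Contact identification

Heavy atoms are identified from PDB-style atom names: leading digits are
stripped and the first letter is the element, so `"1HB2"` is hydrogen and
`"CA"` carbon. This convention covers protein and peptide residues; exotic
two-letter elements (selenium, metals) would need an explicit topology and
are out of scope.

Two choices deserve comment:

* **Population pooling.** The 10% population criterion is evaluated over all
  frames of all trajectories pooled together, reading "fraction of the total
  simulation time" literally. The threshold mainly removes irrelevant pairs
  and is not critical; `identify_contacts()` exposes it as a parameter, and a
  monotonicity property (raising the threshold can only shrink the set) is
  enforced by tests.
* **Chains and the neighbor rule.** Ligand residues are numbered `-4..0` and
  protein residues `1..n`, so sequence exclusion is only applied within a
  chain; a protein-ligand pair such as `r(101, -4)` is never excluded even
  though the indices may be numerically close.

Distances are computed on coordinates as given; inputs are expected to be
whole-molecule (PBC-corrected) trajectories. A Calpha-based variant
(cutoff 0.8 nm) and an inverse-distance feature transform are available for
sensitivity analyses; inverse distances emphasize short-range changes.

## Correlation and Leiden/CPM clustering

For clustering, every fifth frame is sufficient (the correlation estimate is
robust to subsampling), and each feature's per-trajectory mean is removed
before trajectories are concatenated, so that static offsets between
nonequilibrium runs do not masquerade as correlation.

Correlations enter as **absolute** Pearson values: an anticorrelated contact
pair is just as dynamically coupled as a correlated one. The signed matrix is
retained for reporting. A histogram-based normalized mutual information
estimator (`ceiling(sqrt(N))` equal-width bins, normalization by the mean of
the marginal entropies) is available for strongly nonlinear couplings.

The CPM objective
$\sum_c \left[ W_c - \gamma\, n_c (n_c - 1)/2 \right]$
rewards intra-cluster similarity $W_c$ (each unordered pair counted once,
diagonal excluded) against a resolution penalty $\gamma \in (0, 1]$: clusters
form exactly where the average internal correlation exceeds $\gamma$. Leiden
optimization is stochastic, so `leiden_cpm()` runs 10 seeded restarts and
keeps the best objective, breaking ties toward fewer clusters and then
lexicographically — results are reproducible bit-for-bit for a given
configuration. Clusters smaller than `min_cluster_size` (default 2) are
reported as noise. The default $\gamma = 0.5$ is a neutral middle of the
useful range; `gamma_scan()` tabulates cluster counts and mean intra-cluster
correlation so users can pick a resolution per system, which is how the
parameter is meant to be used.

For up to ~13 features `cpm_exhaustive()` enumerates every set partition
(in C++) and is used by the test suite to confirm that Leiden attains the
global CPM optimum on small instances.

## Ensemble averaging and preprocessing

`ensemble_average()` pools trajectories that share the perturbation origin
but may differ in length — a common design runs many short and few long
trajectories (e.g. 90 to 1 us plus 22 to 10 us). The mean and the standard
error of the mean (SEM) are computed from whatever trajectories are alive at
each time point, and the per-point trajectory count is recorded; fluctuations
visibly grow where coverage drops.

The fit operates on a preprocessed response; the four steps, in order:

1. **Linear interpolation** between neighboring frames, increasing the frame
   count fourfold (`n` frames become `4(n-1)+1`).
2. **Log-resampling** of the time axis so that each decade contributes
   equally, about 750 frames per decade. A log axis is the natural scale for
   a process spanning six decades; without it the last decade would dominate
   the fit 10:1.
3. **Gaussian low-pass filtering** with sigma = 6 samples, suppressing
   fluctuations faster than ~0.01 decade. The kernel is truncated at
   4 sigma and renormalized at the boundaries; the implementation is tested
   to agree with direct-summation convolution to 1e-12.
4. **Constant extension** by one decade beyond the data window, at the mean
   of the last half decade of filtered data, which stabilizes the fit near
   the upper boundary.

SEM is propagated through interpolation/resampling and extension but is not
filtered (it weights the fit; smoothing it would understate the noise).
Constants are exact fixed points of the entire chain. Since time zero cannot
sit on a log axis, the log grid starts at the first positive time after
interpolation (a quarter of the frame interval by default).

## The maximum-entropy fit

With amplitudes free to take either sign (distances both rise and fall), the
spectrum is represented by two non-negative channels, $a_k = a_k^+ - a_k^-$,
and the objective is

$$\chi^2(a) \;-\; \lambda\, S_\mathrm{ent}(a), \qquad
S_\mathrm{ent} = \sum_{k,\pm} \left[ a_k^\pm - m - a_k^\pm
\ln\!\left(a_k^\pm/m\right) \right],$$

the Skilling entropy with prior scale $m$, by default 10% of the response's
peak-to-peak range. $\chi^2$ is the mean squared residual, weighted by
$1/\mathrm{sem}^2$ (normalized to mean 1) so long-time points averaged over
fewer trajectories count less; a uniform-weight mode exists. The constant
offset is an explicit parameter outside the entropy, initialized to the
boundary-extension value. Time constants are log-spaced at 10 per decade from
twice the frame interval (faster components are unidentifiable) to one decade
beyond the data window.

The objective is convex in $(a^+, a^-, c)$, and the solver is a damped Newton
iteration with the exact Hessian: the entropy's $\lambda/a$ curvature acts as
an interior-point barrier, coordinates pinned at zero with inward gradients
are frozen, shrink steps are limited to 95% per iteration with an active-set
re-solve when bounds are hit, and an Armijo backtracking line search makes
the objective trace monotone by construction. The start is the flat spectrum
$a^\pm = m$; there is no randomness anywhere in the fit. Typical fits
converge in 10-30 iterations.

### Choosing lambda

$\lambda$ trades fit fidelity against spectral smoothness and must be chosen
before the analysis; $\chi^2$ is non-decreasing in $\lambda$ (a property the
tests assert) and `lambda_scan()` tabulates $\chi^2$, entropy and peak counts
over a ladder of values, supporting a per-system choice. Because $\chi^2$ here
is a weighted *mean* squared residual while published analyses of this type
normalize their misfit differently, regularization weights quoted elsewhere
(tens to hundreds) do not transfer to this implementation's scale. The
package default $\lambda = 10^{-3}$ was calibrated once on synthetic
ensembles with ~5% observation noise and 10-30 trajectories, where it leaves
the reconstruction within the noise floor while suppressing spurious
structure; for smoother or noisier data a scan around $10^{-3}..10^{-1}$ is
recommended.

Two scale relations are worth knowing. Scaling the data by $c$ scales
$\chi^2$ by $c^2$ but $S_\mathrm{ent}$ (with $m \to cm$) by $c$, so exact
amplitude equivariance under data rescaling requires scaling both the prior
and $\lambda$ by $c$. And in the $\lambda \to 0$ limit the fit converges to
ordinary (weighted) least squares on the same exponential basis — verified in
the tests to a relative $\chi^2$ difference of 1e-7.

### Resolution limits

Neighboring basis functions $e^{-t/\tau_k}$ at 10 grid points per decade are
nearly collinear: in double precision, data cannot distinguish mass placed at
one grid point from mass spread over its immediate neighbors, and the entropy
prefers the spread (spreading to the prior height costs nothing). Peak
*positions* are accurate to a few hundredths of a decade, but peak *mass* on
a dense grid smears over roughly +/-0.2 decades even for noiseless input. On
a 5-per-decade grid the same fit concentrates >99.9% of the mass at the true
component. This is an identifiability property of multiexponential inversion,
not of the optimizer; interpret spectra through peaks and the dynamical
content, not through single-amplitude values.

## Dynamical content, peaks, power-law tails

$D(\tau_k) = \sum_j a_{kj}^2$ is computed per cluster by restricting the sum
to member features; unclustered features contribute a `noise` column, and the
per-cluster columns sum to the total exactly at every $\tau_k$ (an identity
the tests assert, not an approximation). Peaks are strict local maxima above
1% of the global maximum — discrete peak lists are the useful summary, and
the floor suppresses numerical ripple.

Long-time tails that decay without a characteristic timescale are
diffusion-governed; `powerlaw_fit()` fits $r(t) \propto t^\alpha$ by least
squares on the log-log scale over a window of at least one decade, with
$\alpha \approx 0.3$ indicating subdiffusive and $\alpha \approx 0.5$ normal
diffusive relaxation. A `subtract_start` baseline mode fits
$|r(t) - r(t_\mathrm{lo})|$ for responses that start from a plateau.

## Synthetic data: what it emulates, what it does not

The generators are first-class, tested code and define the package's
validation conditions:

* `generate_clustered_series()` plants exact block correlation via a latent
  factor construction ($x = \sqrt{\rho_\mathrm{out}}\, g +
  \sqrt{\rho_\mathrm{in} - \rho_\mathrm{out}}\, z_c +
  \sqrt{1 - \rho_\mathrm{in}}\, \epsilon$), so target Pearson correlations
  are exact in expectation.
* `generate_response_ensemble()` is the forward model of the fit:
  deterministic multiexponential mean plus Gaussian observation noise, with
  a short/long trajectory-length mixture (default: a quarter of the
  trajectories run 10x longer) and optionally cluster-correlated noise so
  clusters are recoverable from the same series. An AR(1) noise mode exists;
  slow power-law-like tails are planted as explicit long-tau components so
  ground truth stays representable in the fit basis.
* `generate_toy_structure_ensemble()` builds multi-residue structures on a
  wide grid with designated pairs toggled across the 0.45 nm cutoff at
  prescribed frame fractions, including hydrogens placed to defeat a naive
  all-atom distance rule.

What the generators do **not** emulate: force-field physics, autocorrelated
conformational noise (beyond AR(1)), non-exponential kinetics, and any real
protein geometry. Passing tests therefore demonstrate the correctness of the
machinery — contact detection, clustering, inversion, bookkeeping — under
known ground truth, not the scientific validity of any particular MD study.

## Problem sizes and runtime

The test and validation runs use deliberately scaled-down versions of a
realistic study design: ensembles of 8-30 trajectories at 0.02-0.5 ns
write-out spanning 10-30 us, 6-60 features, 2-5 planted clusters, 5% noise.
A single max-ent fit on ~4000 log-spaced points with ~110 amplitude channels
takes well under a second; the full synthetic end-to-end pipeline (generate,
CSV round-trip, cluster, fit six features, decompose) runs in ~20 seconds.

## Pipeline reproducibility

`run_pipeline()` persists every intermediate (contact table, correlation
matrix, partition, spectra, content profile) under the output directory,
records MD5 checksums in a JSON manifest, and with `resume = TRUE` re-runs
only stages whose outputs are missing or fail their checksum. All
stochastic steps (Leiden restarts) derive from the configured seed, and the
numeric output files are byte-identical across reruns of the same
configuration. The YAML config round-trips losslessly, so a manifest plus a
config file is a complete record of a run.

## Known limitations

* No XTC/TRR trajectory readers (multi-model PDB and DCD are supported);
  precomputed distance tables in CSV are the general interchange format.
* Spectral mass on dense tau grids smears over ~0.2 decades (see above);
  amplitude uncertainty is only explorable via `lambda_scan()`, not
  quantified.
* The NMI estimator uses fixed equal-width binning; for heavy-tailed
  marginals a rank transform before `correlation_matrix()` is advisable.
* Element inference from atom names assumes biomolecular PDB conventions.
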