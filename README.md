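# paintquant

Quantitative analysis of multitarget DNA-PAINT single-molecule localization
data, for cell biologists and microscopists studying membrane-protein
assemblies (the shipped presets describe EGFR and its adaptor Grb2 in HeLa
cells under EGF stimulation).

DNA-PAINT blinking comes from reversible imager-strand binding, so the
kinetics are molecularly informative: the mean dark time τ_d at a binding
site is inversely proportional to the imager influx rate ξ = k_on·c_i and
to the number of docking strands, giving the qPAINT counting relation

    N = 1 / (τ_d · ξ)

The package implements the full chain around that statistic:

- **Post-processing** — NeNA localization precision from consecutive-frame
  nearest-neighbour distances (fit of p(d) = d/(2σ²)·exp(−d²/4σ²) + a·d);
  fiducial drift correction; transitive linking of consecutive-frame
  localizations (radius 4×NeNA, one dark frame allowed); DBSCAN cluster
  isolation (ε = 1×NeNA, ≥ 7 localizations); kinetic mean-frame filter
  (µ ± 2σ, with the fixed 1,500–8,000-frame window as a preset).
- **qPAINT** — per-cluster dark/bright times, τ_d estimation (exponential
  MLE, CDF fit as cross-check), molecule counting, surface-trace influx
  calibration, and a four-Gaussian decomposition of the 1/τ_d distribution
  into monomer–tetramer fractions (component means fixed at k·µ₁, monomer
  peak from the resting condition), compared across conditions by
  error-propagated z-scores.
- **Spatial statistics** — cluster/localization densities per masked cell
  area; self/cross nearest-neighbour distances; cumulative partner-protein
  proximity profiles (0–150 nm, 10-nm bins) with trapezoidal AUC and
  Mann–Whitney comparisons.
- **Per-cell embedding** — a documented 44-feature vector (11 base
  quantities × mean/SD/min/max), UMAP projection, and k-means partitioning
  with k = number of conditions.
- **Simulator** — a kinetically realistic generator (per-docking-strand
  telegraph binding, camera discretization, Gaussian precision, drift,
  background, fiducials) whose presets are the reported study conditions,
  providing ground truth for every stage.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` visualizations.

## Worked example

```r
library(paintquant)

cfg <- sim_preset("resting", "EGFR", mask = square_mask(5), seed = 7)
sim <- simulate_cell(cfg)                     # 226 clusters on 25 um^2

nena   <- nena_precision(sim$locs)
nena
#> <nena_fit: sigma = 10.91 nm from 47204 pairs>

linked <- link_localizations(sim$locs, nena$sigma_nena_nm)
kept   <- kinetic_filter(dbscan_clusters(linked, nena$sigma_nena_nm, 7), "auto")
densities(kept, linked, cfg$mask)[, c("n_clusters", "clusters_per_um2")]
#>   n_clusters clusters_per_um2
#> 1        213             8.52

kin <- extract_kinetics(kept, linked, cfg$exposure_s)
median(molecules_per_cluster(kin$tau_d_s[!kin$flagged], influx_rate()))
#> [1] 1.02

fit_oligomer_mixture(kin$inv_tau_d_per_s[!kin$flagged])
#> <mixture_fit: mu1 = 0.01996 /s (fitted), n = 213>
#> fractions: mono 0.869, di 0.131, tri 0.000, tetra 0.000
```

Reading: the precision estimate recovers the simulated 10.9 nm; 213 of the
226 simulated clusters survive the full isolation chain (the µ±2σ kinetic
filter alone removes ~4.6% by construction); qPAINT counts a median of
~1 molecule per cluster, and the mixture fit reports the 90/10
monomer/dimer resting preset to within sampling error.

Multi-condition batch runs:

```r
man <- simulate_study("study/", conditions = c("resting", "EGF_15min"),
                      n_cells = 3, seed = 1)
rep <- run_pipeline(man, pipeline_params(seed = 42))
write_report(rep, "study/report")
```

or from a shell via the thin CLI wrapper
`inst/cli/paintquant <simulate|postprocess|spatial|qpaint|embed|run> ...`.

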