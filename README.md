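# hypoxiamap

Quantitative analysis of genetically encoded hypoxia-biosensor imaging in the
developing *Drosophila* larval brain — and in any comparable multi-channel 3D
stack where a ratiometric sensor reports cellular state and a tubular
structure (here, tracheoles) supplies oxygen.

The biosensor couples two ubiquitously expressed fluorophores: GFP fused to
the oxygen-dependent degradation (ODD) domain of HIF-1α/Sima, degraded in
proportion to available oxygen, and a nuclear RFP that is oxygen-independent.
Per nucleus, the ratio

```
ratio = mean(GFP-ODD) / mean(RFP)        (hypoxia response)
ratio⁻¹ = RFP / GFP-ODD                  (oxygen-availability proxy)
```

is the readout. The package implements the full analysis chain around it:

* **Segmentation** — 3D nucleus segmentation from the RFP channel
  (background subtraction, Gaussian smoothing, Otsu threshold, 26-connected
  labelling, volume filter, optional distance-transform-seeded watershed),
  and extraction of the voxel-level tracheal map with TEASAR-style
  skeletonization and total branch length.
* **Ratiometrics** — per-nucleus ratio of channel means, whole-hemisphere
  normalisation, compartment assignment (densely tracheolated central brain
  vs sparsely tracheolated optic lobe).
* **Spatial** — exact minimum 3D Euclidean distance from every nucleus to
  the tracheal map, in micrometres, anisotropy-aware.
* **Decay model** — the oxygenation-versus-distance model

  ```
  ratio⁻¹(x) = y₀ + A · exp(−(x − x₀)/λ)
  ```

  fitted by Levenberg–Marquardt least squares (orthogonal-distance refinement
  available), averaged across brains, and inverted into per-cell predicted
  hypoxia heatmaps. λ is the decay constant: the distance over which the
  exponential term falls to 37% (1/e) of its initial value.
* **Cell types** — marker-channel typing (Deadpan → neuroblast, Prospero →
  GMC, Elav → neuron, Repo → glia; neuroepithelium from a region mask) with
  priority resolution of multi-positive nuclei, stratified summaries and
  per-type decay fits.
* **Statistics** — assumption-gated two-group tests (Shapiro–Wilk + Levene
  gate choosing Student's *t* vs Mann–Whitney *U*), normalised frequency
  histograms, and the exact upper-tail hypergeometric enrichment test.
* **Synthetic data** — a 3D brain-phantom generator (branching tracheal
  tree, spherical nuclei of five cell types, sensor channels driven by the
  decay model or by configured per-type means, realistic noise) with full
  ground truth, so every stage is testable without microscopy data.

## Worked example

Simulate a hemisphere-like phantom under normoxia (true λ = 51.8 µm) and run
the whole pipeline:

```r
library(hypoxiamap)

cfg <- phantom_config(volume_shape = c(64, 256, 256), n_nuclei = 500,
                      compartment_split = 0.4,
                      tracheal_density_cb = 0.01,
                      tracheal_density_ol = 0.0002,
                      marker_channels = FALSE, seed = 1)
rep <- run_pipeline(run_config(phantom = cfg, seed = 1))
rep
#> run_report: 494 nuclei ( 0 flagged ), 17448 tracheal voxels, seed 1
#> decay_fit (least_squares): A=0.9275 y0=0.5406 lambda=52.8 um x0=0.1914 um
#>   n=494 rms=0.112 converged=TRUE lambda identifiable=TRUE
#> mann_whitney: statistic=4168 p=5.642e-58 *** (n=192 vs 302)

summarize_groups(rep$table, "compartment")[, c("compartment", "n",
    "mean_ratio", "sem_ratio", "mean_dist_um")]
#>     compartment   n mean_ratio sem_ratio mean_dist_um
#> 1 central_brain 192      0.758   0.00664         8.53
#> 2    optic_lobe 302      1.059   0.01109        43.44
```

Reading the output: the fitted decay constant (52.8 µm) recovers the
generator's truth (51.8 µm) from the rendered images alone; the sparsely
tracheolated optic lobe sits farther from tracheoles (43 µm vs 9 µm on
average) and shows the stronger hypoxia response (mean ratio 1.06 vs 0.76),
significant under the assumption-gated test (Mann–Whitney, p ≈ 6e-58). The
per-nucleus table (`rep$table`) carries `id`, centroid (`z_um`, `y_um`,
`x_um`), `volume_um3`, `mean_gfp`, `mean_rfp`, `ratio`, `ratio_norm`,
`inv_ratio`, `flagged`, `dist_um` and `compartment`; `write_results()` and
`run_config(out_dir=)` export it as CSV with fit JSON and a checksum
manifest.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/hypoxiamap.R simulate --out phantom_dir --seed 7
Rscript inst/cli/hypoxiamap.R run --config run.yaml --out results
Rscript inst/cli/hypoxiamap.R fit --table nuclei.csv --out fit.json
```

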