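# lcnet — connectomics of the osteocyte lacuno-canalicular network

Cortical bone is permeated by the lacuno-canalicular network (LCN):
micrometre-sized pores (lacunae) housing osteocyte cell bodies, connected
by sub-micrometre channels (canaliculi) housing their processes. Confocal
imaging of rhodamine-stained bone shows this network directly, and
calcein labelling separates newly formed bone from pre-existing tissue.
`lcnet` is for researchers who want to treat such image stacks the way
neuroscience treats wiring diagrams: convert the image into a spatial
network (a *connectome*) and quantify its architecture.

The pipeline implements, end to end:

* dual-pass **Difference-of-Gaussians segmentation** with an adaptive,
  shift-invariant threshold — one pass scale-matched to thin canaliculi,
  one to bulky lacunae — plus volume/extent classification of lacunae and
  vascular canals;
* calcein-based **region partitioning** of the cortex (endosteal new
  bone / intercortex / periosteal new bone);
* topology-preserving **3D skeletonization**, chain-graph construction
  and **cubic-spline** edge fitting with arc-length measurement;
* the connectomic statistics:

  * `Can.Dn = Σ Can.Seg_i / V_ROI` — canalicular length per pore-excluded
    bone volume (µm/µm³; 1 µm/µm³ ≡ 10³ km/cm³, so a murine mean of
    0.202 µm/µm³ is 202 km of network per cm³ of bone — about three times
    the human osteonal reference of 0.074 µm/µm³);
  * `Can.Ln` histograms (1 µm bins, % distribution; canaliculi > 5 µm are
    "long");
  * `DoC` distributions over junction nodes (minimum degree 3; degree-3
    junctions are "tree-like");
  * 5 µm (125 µm³) sub-volume density maps with a 1–20 µm convergence
    scan, normalized endosteal→periosteal cortical profiles, and
    OLS regressions of %long and %tree-like against Can.Dn;

* a first-class **synthetic phantom generator**: ground-truth branching
  networks grown from lacunae, rendered into confocal-like stacks
  (anisotropic voxels, PSF, photon/read noise, depth attenuation) with
  calcein label surfaces — so every stage is validated against known
  truth.

## Worked example

Generate a small phantom cortex (24 × 24 × 12 µm at 0.15 µm/µm³), image
it, and push it through segmentation, network extraction and the full
connectomic analysis:

```r
library(lcnet)

cfg <- default_config(seed = 2)
cfg$synthetic$spec <- synthetic_spec(domain_size = c(24, 24, 12),
                                     lacuna_count = 4,
                                     target_density = 0.15, seed = 2)
cfg$synthetic$calcein_surfaces <- list(6, 18)   # label planes at x = 6, 18 um

summary <- run_pipeline(cfg)
print(summary)
#> == LCN connectome summary ==
#> global Can.Dn: 0.1352 um/um^3 (135 km/cm^3)
#>   periosteal_new  mean 0.1463 +/- 0.0924 um/um^3 over 15 sub-volumes
#>   intercortex     mean 0.1437 +/- 0.0805 um/um^3 over 45 sub-volumes
#>   endosteal_new   mean 0.1252 +/- 0.0657 um/um^3 over 15 sub-volumes
#> <canln_histogram> 231 canaliculi, 26.8% longer than 5 um (length-weighted 57.4%)
#> <doc_histogram> 104 junctions, tree-like (DoC = 3) fraction 0.933
#> %long (length-weighted) vs Can.Dn: slope -55.323, intercept 55.21, R^2 0.010 (n = 62)
#> %tree-like vs Can.Dn:          slope -8.351, intercept 94.06, R^2 0.001 (n = 45)
```

Reading the output: the extracted network has a global canalicular
density of 0.135 µm/µm³ (somewhat below the 0.15 µm/µm³ ground truth —
segmentation and skeletonization shorten the network slightly, see the
methods vignette), per-region sub-volume means with their spatial SDs,
a Can.Ln distribution in which 26.8% of canaliculi exceed 5 µm, and a
junction population that is 93% tree-like (DoC = 3), the architecture
typical of the LCN. Setting `cfg$output$dir` additionally writes the
network (GraphML + CSV), the sub-volume grid, histogram/profile CSVs and
a summary JSON.

Individual stages are plain functions — `generate_network()`,
`render_volume()`, `dog_binarize()`, `classify_pores()`,
`build_region_mask()`, `skeletonize()`, `build_chain_graph()`,
`fit_splines()`, `subvolume_map()`, `length_histogram()`,
`doc_histogram()`, `cortical_profile()`,
`density_connectivity_regression()` — and a thin command-line wrapper
lives in `inst/cli/lcn-pipeline.R`:

```sh
Rscript inst/cli/lcn-pipeline.R run --seed 7 --out results/
Rscript inst/cli/lcn-pipeline.R simulate --seed 7 --out phantom/
```

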