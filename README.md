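# radiomaps

Parametric radiomic feature maps for VOI-size-robust CT texture analysis.

## The problem

CT radiomics summarises a segmented volume of interest (VOI) with dozens of
intensity and texture features. Many of these features depend on the VOI's
voxel count rather than on tissue texture — energy is a sum over voxels,
histogram entropy grows as more voxels fill more bins, run/zone statistics
scale with region extent — so comparing differently sized VOIs manufactures
spurious "biological" differences. `radiomaps` implements a phantom
experiment that measures this confounding and a preprocessing strategy that
removes it: compute every feature over fixed-size cubic blocks (edge
b = 4 mm), store the per-block values as a *parametric map* with preserved
spatial reference, and read a VOI as the plain mean of the map voxels
inside it. Because the computation unit never changes size, feature values
become comparable across VOI sizes.

The package is aimed at radiomics methodologists: it simulates seeded
series of CT-like phantom scans, computes 93 first-order and texture-matrix
features (GLCM, GLRLM, GLSZM, GLDM, NGTDM; IBSI-consistent definitions,
fixed bin width 25 HU, voxel-array shift 1000 HU) from arbitrary voxel
masks, builds per-feature block maps, and quantifies cross-size stability
with exact Mann-Whitney U tests (Bonferroni ×3, α = 0.05) and overall
concordance correlation coefficients

    OCCC = 2 Σ_{j<k} σ_jk / [ (J−1) Σ_j σ_j² + Σ_{j<k} (μ_j − μ_k)² ],

with OCCC ≥ 0.85 classified as excellent agreement.

## Worked example

```r
library(radiomaps)

# why fixed blocks help: share of a sphere occupied by its central block
central_voxel_fraction(8, 4)
#> [1] 0.2387324          # an 8 mm VOI draws ~24% of its volume from one block
central_voxel_fraction(16, 4)
#> [1] 0.02984155         # a 16 mm VOI only ~3%

# the full study: 10 repositioned scans, VOIs of 4/8/16 mm, both modes
report <- run_experiment(experiment_config(master_seed = 1))
print(report)
#> <stability_report> 93 features, 10 scans, VOIs 4/8/16 mm, blocks 4 mm
#>   significant (any pair):  conventional 79, map 26
#>   map per pair (4-8, 4-16, 8-16 mm): 0, 17, 16
#>   OCCC increased with maps: all sizes 89, upper pair 59
#>   excellent OCCC (upper pair): map 0, conventional 0
```

Reading: under conventional extraction 79 of 93 features differ
significantly between VOI sizes on a *homogeneous* phantom — pure size
confounding (energy scales exactly with the voxel count; the tests assert
the 16-vs-8 mm energy ratio equals the voxel-count ratio). Read from the
4-mm parametric maps, the 4-vs-8 mm comparison shows no significant feature
at all, the overall significant count drops to 26, and the concordance
across the three sizes improves for 89 of 93 features. With purely white
voxel noise no feature reaches OCCC ≥ 0.85: there is no scan-level
variability for the sizes to agree *on* (see the vignette for why this
differs from scanner data).

Per-feature tables, the long measurement table, a summary JSON and optional
boxplots can be written with `write_report(report, "report_dir")`, and a
thin CLI wrapper lives at `inst/scripts/run_experiment.R`. Individual
stages are exported (`generate_scan_series()`, `extract_features()`,
`compute_feature_maps()`, `map_readout()`, `occc()`, ...) and volumes/maps
round-trip through NIfTI-1 bit-exactly.

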