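# Shared experiment runs, cached so several acceptance checks can reuse the
# same seeded study instead of re-simulating it.

.report_cache <- new.env(parent = emptyenv())

default_report <- function(seed) {
  key <- paste0("seed_", seed)
  if (is.null(.report_cache[[key]]))
    .report_cache[[key]] <- run_experiment(experiment_config(master_seed = seed))
  .report_cache[[key]]
}

# Small, fast geometry used by pipeline unit tests: holds the 16 mm VOI with
# the required margin at 1 mm spacing.
small_geometry <- function() {
  phantom_geometry(vol_dim = c(48, 48, 48), spacing = c(1, 1, 1),
                   body_radius = 12, body_height = 24)
}

# A feature subset spanning all six classes, for cheap pipeline runs.
pipeline_features <- function() {
  c("firstorder_Mean", "firstorder_Energy", "firstorder_TotalEnergy",
    "firstorder_Entropy", "glcm_Contrast", "glcm_Correlation",
    "gldm_DependenceEntropy", "glrlm_RunPercentage",
    "glszm_SmallAreaEmphasis", "ngtdm_Busyness")
}
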