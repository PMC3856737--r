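# Shared setup for the numbered analysis scripts: one study configuration,
# one results tree. Every script can be run on its own from the repository
# root; stages are deterministic under the seed, so re-deriving upstream
# objects is cheap and keeps the scripts independent.

library(volescape)

study_seed <- 2026
cfg <- synthetic_config(seed = study_seed)
thresholds <- c(250, 500, 1000, 1500, 2000, 3000)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

out_path <- function(...) file.path(results_dir, ...)

# rebuild the landscape-scale objects every script needs (about 2 s)
derive_landscape <- function() {
  land <- generate_landscape(cfg)
  patches <- label_patches(land$age, min_age = 60)
  dmat <- patch_distance_matrix(patches, max_distance = max(thresholds))
  list(land = land, patches = patches, dmat = dmat)
}
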