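# Shared configuration for the analysis scripts: the study conditions used
# throughout (series size 41 train / 13 test, 2,000-conformer ensembles,
# 1.0 A grid, <= 9-term models) and the fixed seed of record.

library(qsar4d)

STUDY_SEED <- 20120615L   # fixed seed of record for the whole workflow

study_spec <- function(seed = STUDY_SEED) {
  synthetic_spec(n_compounds = 54L, n_train = 41L, atoms_per_compound = 15L,
                 n_true_descriptors = 3L, noise_sd = 0.1,
                 ensemble_size = 2000L, seed = seed)
}

study_grid <- function() grid_spec(1.0)

study_reduction <- function() reduction_config(min_abs_activity_corr = 0.1,
                                               min_self_variance = 1e-4,
                                               max_empty_cells = 37L)

study_gfa <- function(seed = STUDY_SEED) {
  gfa_config(population_size = 100L, n_crossovers = 6000L,
             mutation_prob = 1.0, smoothing_d = 1.0, seed = seed)
}

# scripts are run from the repository root: Rscript analysis/01_...R
results_dir <- function() {
  d <- "results"
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
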