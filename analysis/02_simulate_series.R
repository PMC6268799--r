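#!/usr/bin/env Rscript
# Step 2 - simulate the synthetic compound series.
#
# The original molecular-dynamics ensembles are not available, so the
# workflow runs on a generated congeneric series at the study scale: 54
# compounds (41 train / 13 test), 2,000 conformations each, with the
# activity planted as a sparse linear function of three grid cell
# occupancies plus N(0, 0.1) noise. The planted model is written out so
# later steps can score recovery. One compound's ensemble is exported as
# multi-frame XYZ to document the interchange format.

source("analysis/common.R")
out <- results_dir()

syn <- generate_synthetic_series(study_spec(), study_grid())

write.csv(syn$activity, file.path(out, "synthetic_activity.csv"),
          row.names = FALSE)
truth <- data.frame(key = syn$true_model$descriptor_keys,
                    coefficient = unname(syn$true_model$coefficients))
write.csv(truth, file.path(out, "synthetic_true_model.csv"),
          row.names = FALSE)

cat(sprintf("Generated %d compounds x %d conformations (%d atoms each)\n",
            nrow(syn$activity), n_conformations(syn$ensembles[[1]]),
            dim(syn$ensembles[[1]]$coords)[1]))
cat(sprintf("Planted: pIC50 = %.2f %s + noise(sd = %.2f)\n",
            syn$true_model$intercept,
            paste(sprintf("%+.1f %s", syn$true_model$coefficients,
                          syn$true_model$descriptor_keys), collapse = " "),
            syn$true_model$noise_sd))
cat(sprintf("Activity range: %.2f - %.2f\n", min(syn$activity$pic50),
            max(syn$activity$pic50)))

# thinned interchange example (the full 2,000-frame file is bulky)
ex <- syn$ensembles[[1]]
thin <- conformer_ensemble(ex$compound_id,
                           ex$coords[, , seq(1, 2000, by = 100)],
                           ex$energies[seq(1, 2000, by = 100)],
                           ex$elements)
write_ensemble(thin, file.path(out, "synthetic_compound1_sample.xyz"), "xyz")
cat("Wrote 20-frame XYZ sample for compound 1\n")
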