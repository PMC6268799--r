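#!/usr/bin/env Rscript
# Step 1 - the published benchmark equations and their residual tables.
#
# Loads the five best models reported for the 1.0 A lattice (1B7/1B9 from
# alignment 1, 2B7/2B8/2B9 from alignment 2), prints them in equation
# form, and recomputes the residual statistics of the two representative
# nine-term models from the packaged potency table: the residual SD of
# training and test sets, the two-sigma outlier calls, the residual
# correlation between the two models, and the inter-cell distances of the
# descriptor pairs singled out in the original discussion.

source("analysis/common.R")
out <- results_dir()

models <- lapply(c("1B7", "1B9", "2B7", "2B8", "2B9"), load_published_model)
eqs <- vapply(models, format_equation, character(1))
writeLines(paste0(vapply(models, `[[`, character(1), "name"), ": ", eqs),
           file.path(out, "published_equations.txt"))
cat("Published equations (intercepts:",
    paste(vapply(models, `[[`, numeric(1), "intercept"), collapse = ", "),
    ")\n")

stats <- do.call(rbind, lapply(c("1B9", "2B9"), function(nm) {
  rt <- load_residual_table(nm)
  do.call(rbind, lapply(c("train", "test"), function(role) {
    r <- rt$residual[rt$role == role]
    ids <- rt$id[rt$role == role]
    sdr <- residual_sd(r)
    data.frame(model = nm, set = role, n = length(r),
               sd_res = round(sdr, 4),
               outliers = paste(find_outliers(r, sdr, ids), collapse = ";"))
  }))
}))
write.csv(stats, file.path(out, "published_residual_stats.csv"),
          row.names = FALSE)
print(stats, row.names = FALSE)

# residual correlation between the two representative models (training set)
r1 <- load_residual_table("1B9")
r2 <- load_residual_table("2B9")
tr <- r1$role == "train"
cc <- cross_correlation(list(model_1B9 = r1$residual[tr],
                             model_2B9 = r2$residual[tr]))
cat(sprintf("Training-set residual correlation 1B9 vs 2B9: R = %.2f\n",
            cc[1, 2]))

# lattice geometry of the correlated descriptor pairs discussed alongside
# the models
geom <- data.frame(
  pair = c("(1,13,1)-( -1,8,2)", "(0,1,-2)-(0,-2,-1)",
           "(0,10,-2)-(0,12,-1)", "(0,2,2)-(1,3,6)"),
  distance_A = c(
    round(cell_center_distance(c(1, 13, 1), c(-1, 8, 2), 1.0), 2),
    round(cell_center_distance(c(0, 1, -2), c(0, -2, -1), 1.0), 2),
    round(cell_center_distance(c(0, 10, -2), c(0, 12, -1), 1.0), 2),
    round(cell_center_distance(c(0, 2, 2), c(1, 3, 6), 1.0), 2)))
write.csv(geom, file.path(out, "gcod_pair_distances.csv"), row.names = FALSE)
print(geom, row.names = FALSE)
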