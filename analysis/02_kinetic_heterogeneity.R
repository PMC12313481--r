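#!/usr/bin/env Rscript
# Step 2 — kinetic subregion segmentation and heterogeneity parameters.
#
# Re-simulates the step-1 cohort from its recorded seeds, segments each
# phantom's enhancing voxels into washout/plateau/persistent subregions
# (>50% rise gate, +/-10% late-change band), and computes the per-tumor
# kinetic parameters: component percentages, KH entropy, peak enhancement,
# enhanced volume, predominant and worst type. Segmentation accuracy
# against the known voxel labels is reported alongside.
#
# Outputs:
#   results/kinetic_profiles.csv   per-phantom parameters + voxel agreement

library(kinhet)

truth <- read.csv("results/cohort_ground_truth.csv")

rows <- vector("list", nrow(truth))
for (i in seq_len(nrow(truth))) {
  tr <- truth[i, ]
  ph <- simulate_phantom(phantom_spec(
    grid_shape = c(36L, 36L, 36L),
    semi_axes = c(13, 12, 11),  # geometry does not affect the comparison
    lobulation = 0.15,
    class_proportions = c(tr$p_washout, tr$p_plateau, tr$p_persistent),
    noise_sd = tr$noise_sd, seed = tr$seed))
  sub <- segment_kinetics(ph$series, ph$mask)
  prof <- kinetic_profile(ph$series, sub)
  prof$phantom <- tr$phantom
  prof$voxel_agreement <- mean(sub[ph$mask == 1L] == ph$truth[ph$mask == 1L])
  rows[[i]] <- prof
}
profiles <- do.call(rbind, rows)
write.csv(profiles, "results/kinetic_profiles.csv", row.names = FALSE)

cat(sprintf("segmented %d phantoms at noise SD %.0f\n",
            nrow(profiles), truth$noise_sd[1]))
cat(sprintf("mean voxel agreement with ground truth: %.3f (min %.3f)\n",
            mean(profiles$voxel_agreement), min(profiles$voxel_agreement)))
cat(sprintf("KH range across phantoms: %.3f - %.3f\n",
            min(profiles$kinetic_heterogeneity),
            max(profiles$kinetic_heterogeneity)))
cat("per-tumor parameters -> results/kinetic_profiles.csv\n")
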