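#!/usr/bin/env Rscript
# Hierarchical grouping of the baseline (FD-T1, WD-T1) component sets:
# level 1 matches each subject's two baseline decompositions, level 2
# clusters the per-subject representatives into 10 group clusters of 8
# members (one per subject). Random-effects t-maps and Bonferroni
# (P = 0.05 corrected) template masks are written for the five clusters
# matched to the generator's networks.
#
# Usage: Rscript analysis/03_group_templates.R [seed]

library(rsnica)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- file.path("results", sprintf("study_seed%d", seed))
dir.create(file.path(out, "templates"), recursive = TRUE,
           showWarnings = FALSE)

study <- simulate_reference_study(seed = seed)
grid <- study$grid
atlas <- study$truth$atlas

t1 <- grep("-T1$", names(study$scans), value = TRUE)
idx <- match(t1, names(study$scans))
sets <- lapply(seq_along(t1), function(j) {
  sim <- study$scans[[t1[j]]]
  decompose_scan(preprocess_scan(sim$scan, sim$confounds), K = 10,
                 seed = seed + 500 + idx[j])
})
grouping <- hierarchical_group(sets)
message(sprintf("Grouping: %d clusters, members per cluster: %s",
                length(grouping$clusters),
                paste(unique(vapply(grouping$clusters,
                                    function(c) nrow(c$members),
                                    integer(1))), collapse = ",")))
write_cluster_membership(grouping$clusters,
                         file.path(out, "cluster_membership.csv"))

matching <- match_clusters_to_reference(grouping$clusters, atlas$maps)
utils::write.csv(matching, file.path(out, "cluster_matching.csv"),
                 row.names = FALSE)
print(matching)

for (net in matching$network) {
  cl <- grouping$clusters[[matching$cluster[matching$network == net]]]
  tm <- cluster_tmap(cl)
  tpl <- make_template_mask(tm, alpha = 0.05, n_tests = grid$n_voxels,
                            label = sprintf("network%d", net))
  write_map_nifti(tm$values, grid,
                  file.path(out, "templates",
                            sprintf("network%d_tmap.nii.gz", net)))
  write_map_nifti(tpl$mask, grid,
                  file.path(out, "templates",
                            sprintf("network%d_mask.nii.gz", net)))
  d <- dice_overlap(which(tpl$mask), which(atlas$supports[net, ]))
  message(sprintf("network %d: template %d voxels, Dice vs truth support %.2f",
                  net, sum(tpl$mask), d))
}
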