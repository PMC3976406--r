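#!/usr/bin/env Rscript
# Generate the reference synthetic study: 8 subjects x five scans
# (FD-T1, FD-T3, WD-T1, WD-T2, WD-T3) on a 24x24x16 grid at 3 mm, five
# networks, with a WD-T3 amplitude enhancement (gain 1.5) planted in
# network 1 and a suppression (gain 0.6) in network 2. Writes the scans,
# masks, truth regions and behavioural table under results/.
#
# Usage: Rscript analysis/01_simulate_study.R [seed]

library(rsnica)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- file.path("results", sprintf("study_seed%d", seed))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_reference_study(seed = seed)
atlas <- study$truth$atlas
grid <- study$grid

message(sprintf("Simulated %d scans (%d subjects x %d conditions), %d brain voxels",
                length(study$scans), length(study$truth$subjects),
                length(rsn_conditions()), grid$n_voxels))

write_map_nifti(grid$brain_mask, grid, file.path(out, "brain_mask.nii.gz"))
for (k in seq_len(nrow(atlas$maps)))
  write_map_nifti(atlas$maps[k, ], grid,
                  file.path(out, sprintf("truth_network%d.nii.gz", k)))
for (i in seq_along(study$truth$effects)) {
  ef <- study$truth$effects[[i]]
  reg <- logical(grid$n_voxels); reg[ef$target_region] <- TRUE
  write_map_nifti(reg, grid,
                  file.path(out, sprintf("truth_region_net%d.nii.gz",
                                         ef$target_network)))
}
utils::write.csv(study$behavior, file.path(out, "behavior.csv"),
                 row.names = FALSE)
utils::write.csv(study$truth$amplitudes, file.path(out, "amplitudes.csv"),
                 row.names = FALSE)

# scans + confounds (NIfTI-1 4D + TSV), plus a plain-text config sidecar
for (nm in names(study$scans)) {
  sim <- study$scans[[nm]]
  write_scan_nifti(sim$scan, file.path(out, paste0(nm, ".nii.gz")))
  conf <- cbind(sim$confounds$motion,
                cardiac_phase = sim$confounds$cardiac_phase,
                resp_phase = sim$confounds$resp_phase)
  utils::write.table(conf, file.path(out, paste0(nm, "_confounds.tsv")),
                     sep = "\t", row.names = FALSE)
}
writeLines(c(sprintf("seed: %d", seed),
             "subjects: 8", "networks: 5", "n_vol: 120", "tr_s: 2",
             "grid: 24x24x16 @ 3 mm",
             "effects: net1 WD-T3 gain 1.5 (enhancement); net2 WD-T3 gain 0.6 (suppression)"),
           file.path(out, "config.txt"))
message("Wrote ", out)
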