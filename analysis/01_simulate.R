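#!/usr/bin/env Rscript
# Step 1 — build the synthetic study inputs.
#
# Generates the toy receptor/ligand complex (with its exhaustively
# enumerated score minimum), a bound-state trajectory with contrasting
# per-residue flexibility, and the preset-driven assay datasets.  Everything
# downstream reads from results/.

suppressMessages(library(nfyscreen))
seed <- 20260925L
dir.create("results", showWarnings = FALSE)

message("building toy pocket complex and enumerating its score minimum ...")
toy <- make_toy_complex(seed = 1)
write_structure(toy$receptor, "results/toy_receptor.pdb")
box_to_json(toy$box, "results/toy_box.json")
km <- toy$known_minimum
message(sprintf("  exhaustive minimum: %.3f kcal/mol over %d poses at (%.2f, %.2f, %.2f)",
                km$best_score, km$n_poses, km$best_pose$translation[1],
                km$best_pose$translation[2], km$best_pose$translation[3]))
write.table(
  data.frame(quantity = c("grid_min_kcal_mol", "n_enumerated_poses"),
             value = c(km$best_score, km$n_poses)),
  "results/toy_minimum.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

message("simulating a flexibility-contrast trajectory ...")
pr <- get_preset("rmsf_contrast")
topo <- make_line_topology(12)
amp <- c(rep(0, 4), rep(pr$amplitude_high, 4), rep(pr$amplitude_low, 4), 0)
traj <- simulate_trajectory(topo, amp, n_frames = 500, seed = seed)
write_trajectory(traj, "results/toy_trajectory.pdb")

message("simulating assay datasets from the packaged presets ...")
for (nm in c("ic50_human", "ic50_rat")) {
  d <- simulate_dose_response(get_preset(nm))
  write.csv(data.frame(dose = d$doses, response = d$responses,
                       replicate = d$replicate_ids),
            sprintf("results/%s.csv", nm), row.names = FALSE)
}
for (nm in c("chase_nfya_control", "chase_nfya_treated",
             "chase_flag_wt", "chase_flag_6ktor")) {
  d <- simulate_chase(get_preset(nm))
  write.csv(data.frame(time_h = d$times, level = d$levels,
                       condition = d$condition, replicate = d$replicate_ids),
            sprintf("results/%s.csv", nm), row.names = FALSE)
}
message("done; inputs written under results/")
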