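#!/usr/bin/env Rscript
# Step 4 — trajectory readouts.
#
# Reads the multi-model PDB trajectory from step 1 and computes the four
# stability readouts: ligand RMSD series, per-residue RMSF, ligand-contact
# occupancy, and the per-frame interaction-enthalpy series.

suppressMessages(library(nfyscreen))

traj <- read_trajectory("results/toy_trajectory.pdb")
topo <- traj$topology
lig <- select_atoms(topo, chain = "L")
rec <- select_atoms(topo, chain = "A")
anchor <- select_atoms(topo, chain = "A", resno = 1:4)  # rigid residues

rmsd <- ligand_rmsd_series(traj, lig, rec, window = 25)
write_series_tsv(rmsd, "results/traj_rmsd.tsv")
message(sprintf("ligand RMSD: mean %.3f nm (first value %.3f)",
                mean(rmsd$values), rmsd$values[1]))

rmsf <- rmsf_profile(traj, rec, fit = anchor)
write_profile_tsv(rmsf, "results/traj_rmsf.tsv")
message("per-residue RMSF (nm):")
print(data.frame(residue = rmsf$keys$residue_number,
                 rmsf_nm = round(rmsf$values, 3)))

occ <- contact_occupancy(traj, lig, cutoff = 6)
write_profile_tsv(occ, "results/traj_occupancy.tsv")
message(sprintf("occupancy > 0 at %d residues", sum(occ$values > 0)))

ent <- enthalpy_series(traj, lig, rec, window = 50)
write_series_tsv(ent, "results/traj_enthalpy.tsv")
message(sprintf("interaction enthalpy: mean %.3f kcal/mol, moving-average range [%.3f, %.3f]",
                mean(ent$values), min(ent$moving_average),
                max(ent$moving_average)))
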