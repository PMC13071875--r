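#!/usr/bin/env Rscript
# Step 3 — hit triage.
#
# Applies the post-screen curation to a demonstration compound table:
# calculated logP window, PAINS-style substructure flags, and Tanimoto
# max-min diversity selection of a chemically diverse test set.

suppressMessages(library(nfyscreen))

candidates <- data.frame(
  compound_id = c("amide1", "ether1", "quinone1", "greasy1", "aniline1",
                  "catechol1"),
  smiles = c("CC(=O)Nc1ccccc1", "CCOc1ccccc1", "O=C1C=CC(=O)C=C1",
             "CCCCCCCCCCCCCCCC", "Nc1ccc(OC)cc1", "Oc1ccccc1O"),
  total = c(-9.1, -8.7, -8.5, -8.2, -7.9, -7.5))

out <- triage_hits(candidates, clogp_range = c(-1, 4), select_k = 3)
write.table(out, "results/triage.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message("triage table:")
print(out[, c("compound_id", "clogp", "pains_flags", "pass_clogp",
              "pass_pains", "selected")], digits = 3)
message(sprintf("%d/%d pass both filters; %d selected for diversity",
                sum(out$pass_clogp & out$pass_pains), nrow(out),
                sum(out$selected)))
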