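#!/usr/bin/env Rscript
# Step 2: descriptive structure of the simulated network — degree/sign
# profiles of drugs and targets (hubs, monochromaticity) and connected
# components of the signed restriction.

suppressPackageStartupMessages(library(sdtnet))

net <- load_edge_list("results/network_edges.tsv")
signed <- restrict_to_signed(net)

prof <- degree_profiles(signed)
write.table(prof, "results/degree_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

drugs <- prof[prof$side == "drug", ]
mono <- drugs$n_positive == 0 | drugs$n_negative == 0
cat(sprintf("drugs: %d; max targets per drug: %d; monochromatic: %.1f%%\n",
            nrow(drugs), max(drugs$n_total), 100 * mean(mono)))

comps <- connected_components(signed)
comps$members <- NULL
write.table(comps, "results/components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("connected components: %d; largest holds %.0f%% of drugs and %.0f%% of targets\n",
            nrow(comps), 100 * comps$drug_fraction[1],
            100 * comps$target_fraction[1]))
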