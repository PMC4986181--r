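#!/usr/bin/env Rscript
# Step 1: simulate a signed drug-target network at the published scale
# (1315 drugs, 820 targets, 4128 signed edges, ~65.7% negative, strongly
# monochromatic drugs) and persist it as the standard edge-list TSV that
# every later step reads.

suppressPackageStartupMessages(library(sdtnet))

seed <- 20260921L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- generator_config()   # published-scale defaults
net <- generate_network(cfg, seed = seed)
write_edge_list(net, file.path(out_dir, "network_edges.tsv"))

s <- summarize_network(net)
writeLines(format_summary_table(s), file.path(out_dir, "network_summary.txt"))
summary_to_json(s, file.path(out_dir, "network_summary.json"))

cat("Simulated network:\n")
print(net)
cat(sprintf("negative fraction among signed edges: %.3f (target %.3f)\n",
            s$n_negative / (s$n_positive + s$n_negative),
            cfg$negative_fraction))
cat("edge list written to", file.path(out_dir, "network_edges.tsv"), "\n")
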