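#!/usr/bin/env Rscript
# Step 4: length-4 cycle motifs. Counts all two-drug/two-target squares of
# the simulated signed network by sign-pattern class and reports the
# coherent / mixed / incoherent / positive fractions.

suppressPackageStartupMessages(library(sdtnet))

net <- restrict_to_signed(load_edge_list("results/network_edges.tsv"))

counts <- enumerate_4cycles(net)
write.table(counts, "results/cycle_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(counts)

if (sum(counts$n) >= 1) {
  fr <- cycle_fractions(counts)
  jsonlite::write_json(fr, "results/cycle_fractions.json",
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("cycles: %d total; %.1f%% coherent, %.1f%% mixed, %.1f%% incoherent, %.1f%% positive\n",
              fr$total, 100 * fr$frac_coherent, 100 * fr$frac_mixed,
              100 * fr$frac_incoherent, 100 * fr$frac_positive))
} else {
  cat("no length-4 cycles in this network\n")
}
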