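#!/usr/bin/env Rscript
# Discover SRS groups: Ward clustering (Euclidean) of the top 10% most
# variable probes, k chosen by the within-group sum-of-squares
# criterion, k-means consolidation, and orientation so SRS1 carries the
# majority-downregulated program. Scores recovery against the planted
# truth.

library(srsomics)

expr <- read_expression_tsv("results/cohort/expression.tsv")
truth <- read_truth("results/cohort/truth")
out <- "results/discovery"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

disc <- discover_srs(expr)
cat(sprintf("top-variable probes clustered: %d\n",
            length(disc$variable_probes)))
cat("WSS by k:", paste(names(disc$wss_by_k),
                       round(disc$wss_by_k), sep = "=", collapse = "  "),
    "\n")
cat(sprintf("chosen k: %d; group sizes: %s\n", disc$chosen_k,
            paste(names(table(disc$labels)), table(disc$labels),
                  sep = "=", collapse = ", ")))

ari <- adjusted_rand_index(disc$labels, truth$group_of_sample)
cat(sprintf("adjusted Rand index vs planted groups: %.3f\n", ari))

write_table_tsv(data.frame(sample_id = names(disc$labels),
                           srs = unname(disc$labels)),
                file.path(out, "srs_labels.tsv"))
write_table_tsv(data.frame(k = names(disc$wss_by_k),
                           wss = unname(disc$wss_by_k)),
                file.path(out, "wss_by_k.tsv"))
pcs <- compute_expression_pcs(expr[disc$variable_probes, ], 3)
write_table_tsv(data.frame(sample_id = rownames(pcs), pcs,
                           srs = unname(disc$labels[rownames(pcs)])),
                file.path(out, "pc_scatter.tsv"))
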