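#!/usr/bin/env Rscript
# Moderated-t differential expression between SRS groups (FC > 1.5,
# FDR < 0.05 calling), unadjusted and adjusted for the cell-proportion
# covariate.

library(srsomics)

expr <- read_expression_tsv("results/cohort/expression.tsv")
labels <- read_table_tsv("results/discovery/srs_labels.tsv")
meta <- read_table_tsv("results/cohort/metadata.tsv")
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

srs <- setNames(labels$srs, labels$sample_id)[colnames(expr)]

dt <- de_table(expr, srs)
pars <- attr(dt, "params")
cat(sprintf("moderation prior: d0 = %.2f, s0sq = %.4f\n",
            pars$d0, pars$s0sq))
cat(sprintf("%d probes called (FC > 1.5, FDR < 0.05); %.1f%% down in SRS1\n",
            sum(dt$called), 100 * mean(dt$direction[dt$called] == "down")))
write_table_tsv(dt, file.path(out, "de_table.tsv"))

# adjusted for the white-cell proportion difference between groups
covs <- meta[match(colnames(expr), meta$sample_id),
             c("neut_prop", "age"), drop = FALSE]
dt_adj <- de_table(expr, srs, covariates = covs)
cat(sprintf("adjusted analysis: %d probes called\n", sum(dt_adj$called)))
write_table_tsv(dt_adj, file.path(out, "de_table_adjusted.tsv"))
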