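#!/usr/bin/env Rscript
# Enrichment of lead cis-eSNPs in epigenetic-mark intervals: overlap
# proportions (Fisher) and distance to the nearest mark (Mann-Whitney),
# against the background of all SNPs within 1 Mb of a probe start.

library(srsomics)

snp_ann <- read_table_tsv("results/cohort/snp_ann.tsv")
probe_ann <- read_table_tsv("results/cohort/probe_ann.tsv")
marks <- read_bed("results/cohort/marks.bed")
lead <- read_table_tsv("results/eqtl/lead_cis.tsv")
out <- "results/epimarks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sig_lead <- lead[lead$fdr < 0.05, ]
fg <- snp_ann[snp_ann$snp_id %in% sig_lead$snp_id, ]
cat(sprintf("foreground: %d lead eSNPs; marks: %s\n", nrow(fg),
            paste(unique(marks$mark), collapse = ", ")))

enr <- mark_enrichment(fg, marks, snp_ann, probe_ann)
print(enr, digits = 3)
write_table_tsv(enr, file.path(out, "mark_enrichment.tsv"))

cat(sprintf("pooled overlap: %.2f%% of eSNPs vs %.2f%% of background\n",
            100 * mean(enr$prop_fg), 100 * mean(enr$prop_bg)))
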