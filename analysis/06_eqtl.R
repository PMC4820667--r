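#!/usr/bin/env Rscript
# eQTL mapping: cis/trans pair universe, covariate adjustment by 30
# expression PCs, per-stream BH FDR, lead SNPs, SRS-group-specific
# mapping with 25 PCs per group, context comparison against an emulated
# reference (population) mapping, and enrichment of eQTL genes among DE
# genes.

library(srsomics)

expr <- read_expression_tsv("results/cohort/expression.tsv")
dos <- read_dosage_tsv("results/cohort/dosages.tsv")
probe_ann <- read_table_tsv("results/cohort/probe_ann.tsv")
snp_ann <- read_table_tsv("results/cohort/snp_ann.tsv")
labels <- read_table_tsv("results/discovery/srs_labels.tsv")
de <- read_table_tsv("results/de/de_table.tsv")
truth <- read_truth("results/cohort/truth")
out <- "results/eqtl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- eqtl_config()
geno <- list(dosages = dos, snp_ann = snp_ann)
pairs <- build_pair_universe(snp_ann, probe_ann, cfg, n_trans = 5000,
                             seed = 23, required_pairs = truth$eqtl_pairs)
cat(sprintf("tested pairs: %d cis, %d trans\n",
            sum(pairs$klass == "cis"), sum(pairs$klass == "trans")))

pcs <- compute_expression_pcs(expr, cfg$n_pcs_main)
rec <- map_eqtl(expr, dos, pcs, pairs)
write_table_tsv(rec, file.path(out, "eqtl_records.tsv"))
cis <- rec[rec$klass == "cis", ]
cat(sprintf("significant at FDR < 0.05: %d cis pairs, %d trans pairs\n",
            sum(cis$fdr < 0.05), sum(rec$fdr < 0.05 & rec$klass == "trans")))

lead <- lead_snp_per_probe(cis)
write_table_tsv(lead, file.path(out, "lead_cis.tsv"))
sig_lead <- lead[lead$fdr < 0.05, ]
cat(sprintf("probes with a cis-eQTL (FDR < 0.05): %d; median r2 of lead = %.3f\n",
            nrow(sig_lead), median(sig_lead$r2)))

# recovery vs planted truth
truth_key <- paste(truth$eqtl_pairs$snp_id, truth$eqtl_pairs$probe_id)
called_key <- paste(rec$snp_id, rec$probe_id)[rec$fdr < 0.05]
cat(sprintf("planted-pair sensitivity at FDR < 0.05: %.3f\n",
            mean(truth_key %in% called_key)))

# SRS-group-specific mapping
srs <- setNames(labels$srs, labels$sample_id)[colnames(expr)]
g1 <- srs == "SRS1"
map_group <- function(keep) {
  v <- expr[, keep]
  map_eqtl(v, dos[, keep], compute_expression_pcs(v, cfg$n_pcs_group),
           pairs[pairs$klass == "cis", ])
}
spec <- srs_specific_eqtl(map_group(g1), map_group(!g1), cfg)
write_table_tsv(spec, file.path(out, "srs_specific.tsv"))
cat(sprintf("SRS-specific cis-eQTL: %d SRS1-only, %d SRS2-only, %d shared\n",
            sum(spec$call == "srs1_only"), sum(spec$call == "srs2_only"),
            sum(spec$call == "shared")))

# context comparison against an emulated reference cohort
sim_cfg <- sim_config(seed = 2026)
ref_expr <- simulate_reference_expression(geno, truth, sim_cfg, probe_ann)
rec_ref <- map_eqtl(ref_expr$values, dos,
                    compute_expression_pcs(ref_expr$values, cfg$n_pcs_main),
                    pairs[pairs$klass == "cis", ])
cc <- compare_contexts(cis, rec_ref,
                       setNames(probe_ann$start, probe_ann$probe_id))
write_table_tsv(cc$gene_calls, file.path(out, "context_calls.tsv"))
cat(sprintf(paste0("context-specific genes: %d, shared: %d; lead-SNP ",
                   "distance Mann-Whitney p = %.2g\n"),
            cc$n_specific, cc$n_shared, cc$mannwhitney_p))

# are eQTL genes enriched among DE genes?
eqtl_genes <- unique(sig_lead$probe_id)
de_genes <- de$probe_id[de$called]
enr <- enrichment_chisq(eqtl_genes, de_genes, probe_ann$probe_id)
cat(sprintf("DE x eQTL enrichment: chi-square = %.1f, p = %.2g, OR = %.2f\n",
            enr$statistic, enr$p, enr$odds_ratio))
write_table_tsv(data.frame(statistic = enr$statistic, p = enr$p,
                           odds_ratio = enr$odds_ratio),
                file.path(out, "de_eqtl_enrichment.tsv"))
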