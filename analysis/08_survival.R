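#!/usr/bin/env Rscript
# Outcome analysis by SRS group: Kaplan-Meier curves, log-rank test, Cox
# proportional hazards, 14-day mortality, and a group comparison table
# of the clinical covariates.

library(srsomics)

meta <- read_table_tsv("results/cohort/metadata.tsv")
labels <- read_table_tsv("results/discovery/srs_labels.tsv")
out <- "results/survival"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

srs <- setNames(labels$srs, labels$sample_id)[meta$sample_id]

km <- km_estimate(meta$time, meta$event, srs)
write_table_tsv(km, file.path(out, "km.tsv"))

lr <- logrank_test(meta$time, meta$event, srs)
cx <- cox_fit(meta$time, meta$event,
              data.frame(srs1 = as.integer(srs == "SRS1")))
cat(sprintf("Cox: HR %.2f (95%% CI %.2f-%.2f), Wald p = %.3g; log-rank p = %.3g\n",
            cx$hr, cx$ci_low, cx$ci_high, cx$wald_p, lr$p))
write_table_tsv(data.frame(hr = cx$hr, ci_low = cx$ci_low,
                           ci_high = cx$ci_high, wald_p = cx$wald_p,
                           score_p = cx$score_p, logrank_p = lr$p),
                file.path(out, "cox.tsv"))

mt <- mortality_at(meta$time, meta$event, srs, 14)
print(mt, digits = 3)
write_table_tsv(mt, file.path(out, "mortality14.tsv"))

cmp <- compare_covariates(meta, srs,
                          columns = c("age", "sex", "neut_prop",
                                      "severity"))
print(cmp, digits = 3)
write_table_tsv(cmp, file.path(out, "covariate_comparison.tsv"))
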