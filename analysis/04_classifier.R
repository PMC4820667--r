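#!/usr/bin/env Rscript
# Sparse (L1-penalized logistic) gene signature for SRS membership with a
# seven-feature cap mirroring the minimal predictive panel, plus a
# comparison of predictor families (expression vs clinical covariates)
# by leave-one-out cross-validation at a feature subset that keeps the
# inner selection tractable.

library(srsomics)

expr <- read_expression_tsv("results/cohort/expression.tsv")
labels <- read_table_tsv("results/discovery/srs_labels.tsv")
meta <- read_table_tsv("results/cohort/metadata.tsv")
de <- read_table_tsv("results/de/de_table.tsv")
out <- "results/classifier"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

srs <- setNames(labels$srs, labels$sample_id)[colnames(expr)]
y <- as.integer(srs == "SRS1")

# full-transcriptome sparse model with a 7-feature cap
x <- t(expr)
m <- select_predictive_model(x, y, max_features = 7, seed = 11)
cat("selected features:", paste(m$features, collapse = ", "), "\n")
write_table_tsv(data.frame(feature = m$features,
                           coefficient = unname(m$coefficients),
                           center = unname(m$center),
                           scale = unname(m$scale),
                           intercept = m$intercept, lambda = m$lambda),
                file.path(out, "model.tsv"))
pred <- assign_srs(x, m)
agree <- mean(pred$label == srs)
cat(sprintf("resubstitution agreement with discovery labels: %.3f\n", agree))
write_table_tsv(pred, file.path(out, "predictions.tsv"))

# family comparison on the 300 most variable probes vs clinical columns
top <- select_variable_probes(expr, 300 / nrow(expr))
families <- list(
  expression = x[, top],
  clinical = as.matrix(meta[match(colnames(expr), meta$sample_id),
                            c("age", "neut_prop", "severity")])
)
tab <- compare_predictor_families(families, y, nfolds = 5, seed = 13)
print(tab)
write_table_tsv(tab, file.path(out, "family_comparison.tsv"))
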