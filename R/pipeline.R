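#' Pipeline configuration
#'
#' One config object driving the full workflow: simulate a cohort,
#' discover SRS groups, differential expression, sparse classifier,
#' signature rotation test, eQTL mapping (full cohort and per group),
#' epigenetic-mark enrichment, and survival analysis.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param sim a [sim_config()]; defaults to `sim_config(seed)`.
#' @param eqtl an [eqtl_config()].
#' @param stages character vector of stages to run, in dependency order.
#' @param discovery list of [discover_srs()] options
#'   (variance_fraction, k_range, wss_threshold).
#' @param n_trans_pairs trans pairs sampled into the tested universe.
#' @param n_rotations rotations for the signature test.
#' @param classifier_max_features optional support cap for the sparse
#'   model.
#' @param signature_size planted signature genes drawn for the rotation
#'   stage.
#' @param write_vcf also write genotypes as VCF v4.2.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            sim = sim_config(seed),
                            eqtl = eqtl_config(),
                            stages = c("simulate", "discover", "de",
                                       "classify", "geneset", "eqtl",
                                       "epimarks", "survive"),
                            discovery = list(),
                            n_trans_pairs = 3000L,
                            n_rotations = 999L,
                            classifier_max_features = NULL,
                            signature_size = 200L,
                            write_vcf = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory")
  structure(list(seed = as.integer(seed), sim = sim, eqtl = eqtl,
                 stages = stages, discovery = discovery,
                 n_trans_pairs = as.integer(n_trans_pairs),
                 n_rotations = as.integer(n_rotations),
                 classifier_max_features = classifier_max_features,
                 signature_size = as.integer(signature_size),
                 write_vcf = write_vcf),
            class = "pipeline_config")
}

write_manifest <- function(stage_dir, config_hash) {
  files <- setdiff(list.files(stage_dir, recursive = TRUE), "manifest.tsv")
  paths <- file.path(stage_dir, files)
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(paths)),
                    config_md5 = config_hash,
                    stringsAsFactors = FALSE)
  write_table_tsv(man, file.path(stage_dir, "manifest.tsv"))
}

#' Run the integrated analysis pipeline
#'
#' Executes the configured stages in dependency order into an artifact
#' directory; each stage writes plain-text outputs plus a manifest of
#' file hashes, so a rerun with an identical config is bit-identical.
#' A stage failure writes a FAILED marker and aborts downstream stages,
#' retaining completed outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- unname(tools::md5sum(
    write_table_tsv(data.frame(dput = deparse(config)),
                    file.path(out_dir, "config.txt"))))
  res <- list(config = config)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s); dir.create(d, showWarnings = FALSE); d
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    d <- stage_dir(name)
    ok <- tryCatch({ fun(d); TRUE },
                   error = function(e) {
                     writeLines(conditionMessage(e),
                                file.path(d, "FAILED"))
                     message("stage '", name, "' FAILED: ",
                             conditionMessage(e))
                     FALSE
                   })
    if (ok) write_manifest(d, cfg_hash)
    if (!ok) stop("pipeline aborted at stage '", name, "'")
  }

  run_stage("simulate", function(d) {
    co <- simulate_cohort(config$sim)
    res$cohort <<- co
    write_expression_tsv(co$expr$values, file.path(d, "expression.tsv"))
    write_dosage_tsv(co$genotypes, file.path(d, "dosages.tsv"))
    if (config$write_vcf) {
      write_genotypes_vcf(co$genotypes, file.path(d, "genotypes.vcf"))
    }
    write_table_tsv(co$expr$probe_ann, file.path(d, "probe_ann.tsv"))
    write_table_tsv(co$genotypes$snp_ann, file.path(d, "snp_ann.tsv"))
    write_table_tsv(co$metadata, file.path(d, "metadata.tsv"))
    write_bed(co$marks, file.path(d, "marks.bed"))
    write_truth(co$truth, file.path(d, "truth"))
  })

  run_stage("discover", function(d) {
    co <- res$cohort
    disc <- do.call(discover_srs,
                    c(list(values = co$expr$values), config$discovery))
    res$srs <<- disc
    write_table_tsv(data.frame(sample_id = names(disc$labels),
                               srs = unname(disc$labels)),
                    file.path(d, "srs_labels.tsv"))
    write_table_tsv(data.frame(k = names(disc$wss_by_k),
                               wss = unname(disc$wss_by_k),
                               chosen = names(disc$wss_by_k) ==
                                 disc$chosen_k),
                    file.path(d, "wss.tsv"))
    pcs <- compute_expression_pcs(co$expr$values[disc$variable_probes, ], 3)
    write_table_tsv(data.frame(sample_id = rownames(pcs), pcs,
                               srs = unname(disc$labels)),
                    file.path(d, "pc_scatter.tsv"))
    if (!is.null(co$truth)) {
      ari <- adjusted_rand_index(disc$labels, co$truth$group_of_sample)
      write_table_tsv(data.frame(metric = "adjusted_rand_index",
                                 value = ari),
                      file.path(d, "recovery.tsv"))
    }
  })

  run_stage("de", function(d) {
    co <- res$cohort
    dt <- de_table(co$expr$values, res$srs$labels)
    res$de <<- dt
    write_table_tsv(dt, file.path(d, "de_table.tsv"))
    pars <- attr(dt, "params")
    write_table_tsv(data.frame(key = c("d0", "s0sq"),
                               value = c(pars$d0, pars$s0sq)),
                    file.path(d, "moderation.tsv"))
  })

  run_stage("classify", function(d) {
    co <- res$cohort
    y <- as.integer(res$srs$labels == "SRS1")
    x <- t(co$expr$values)
    m <- select_predictive_model(x, y,
                                 max_features = config$classifier_max_features,
                                 seed = config$seed)
    res$model <<- m
    write_table_tsv(data.frame(feature = m$features,
                               coefficient = unname(m$coefficients),
                               center = unname(m$center),
                               scale = unname(m$scale),
                               intercept = m$intercept,
                               lambda = m$lambda),
                    file.path(d, "model.tsv"))
    pred <- assign_srs(x, m)
    write_table_tsv(pred, file.path(d, "predictions.tsv"))
    write_table_tsv(data.frame(
      metric = "resubstitution_agreement",
      value = mean((pred$label == "SRS1") == (y == 1))),
      file.path(d, "fit_summary.tsv"))
  })

  run_stage("geneset", function(d) {
    co <- res$cohort
    # reference DE table emulating an external directional contrast over
    # the planted program, then a rotation test of the derived signature
    set.seed(stream_seed(config$seed, "rotation"))
    de_pool <- co$truth$de_probes
    take <- de_pool[sample.int(nrow(de_pool),
                               min(config$signature_size, nrow(de_pool))), ]
    ref <- data.frame(gene = take$probe_id,
                      log2_fc = take$effect + stats::rnorm(nrow(take), 0, 0.05),
                      fdr = stats::runif(nrow(take), 0, 0.01))
    sig <- derive_signature(list(ref), measured_universe =
                              rownames(co$expr$values))
    design <- cbind(intercept = 1,
                    group = as.numeric(res$srs$labels == "SRS1"))
    rt <- rotation_test(co$expr$values, design, sig,
                        n_rotations = config$n_rotations,
                        seed = config$seed)
    res$rotation <<- rt
    write_table_tsv(sig, file.path(d, "signature.tsv"))
    write_table_tsv(data.frame(statistic = rt$statistic,
                               p_rotation = rt$p_rotation,
                               n_rotations = rt$n_rotations),
                    file.path(d, "rotation.tsv"))
  })

  run_stage("eqtl", function(d) {
    co <- res$cohort
    pairs <- build_pair_universe(co$genotypes$snp_ann, co$expr$probe_ann,
                                 config$eqtl,
                                 n_trans = config$n_trans_pairs,
                                 seed = config$seed,
                                 required_pairs = co$truth$eqtl_pairs)
    pcs <- compute_expression_pcs(co$expr$values, config$eqtl$n_pcs_main)
    rec <- map_eqtl(co$expr$values, co$genotypes$dosages, pcs, pairs)
    res$eqtl <<- rec
    write_table_tsv(rec, file.path(d, "eqtl_records.tsv"))
    lead <- lead_snp_per_probe(rec[rec$klass == "cis", ])
    res$eqtl_lead <<- lead
    write_table_tsv(lead, file.path(d, "lead_cis.tsv"))

    # per-SRS-group mapping with group-level PCs
    g1 <- res$srs$labels == "SRS1"
    map_group <- function(keep) {
      v <- co$expr$values[, keep, drop = FALSE]
      npc <- min(config$eqtl$n_pcs_group, sum(keep) - 2L)
      p <- compute_expression_pcs(v, npc)
      map_eqtl(v, co$genotypes$dosages[, keep, drop = FALSE], p,
               pairs[pairs$klass == "cis", ])
    }
    spec <- srs_specific_eqtl(map_group(g1), map_group(!g1), config$eqtl)
    res$srs_specific <<- spec
    write_table_tsv(spec, file.path(d, "srs_specific.tsv"))

    # reference-context comparison
    ref_expr <- simulate_reference_expression(co$genotypes, co$truth,
                                              config$sim, co$expr$probe_ann)
    pcs_ref <- compute_expression_pcs(ref_expr$values,
                                      config$eqtl$n_pcs_main)
    rec_ref <- map_eqtl(ref_expr$values, co$genotypes$dosages, pcs_ref,
                        pairs[pairs$klass == "cis", ])
    cc <- compare_contexts(rec[rec$klass == "cis", ], rec_ref,
                           stats::setNames(co$expr$probe_ann$start,
                                           co$expr$probe_ann$probe_id))
    res$contexts <<- cc
    write_table_tsv(cc$gene_calls, file.path(d, "context_calls.tsv"))
    write_table_tsv(data.frame(n_specific = cc$n_specific,
                               n_shared = cc$n_shared,
                               mannwhitney_p = cc$mannwhitney_p,
                               median_dist_specific = cc$median_dist_specific,
                               median_dist_shared = cc$median_dist_shared),
                    file.path(d, "context_summary.tsv"))
  })

  run_stage("epimarks", function(d) {
    co <- res$cohort
    lead <- res$eqtl_lead
    sig_lead <- lead[lead$fdr < config$eqtl$fdr_cis, ]
    snps <- co$genotypes$snp_ann
    fg <- snps[snps$snp_id %in% sig_lead$snp_id, ]
    enr <- mark_enrichment(fg, co$marks, snps, co$expr$probe_ann)
    res$epimarks <<- enr
    write_table_tsv(enr, file.path(d, "mark_enrichment.tsv"))
  })

  run_stage("survive", function(d) {
    co <- res$cohort
    md <- co$metadata
    srs <- res$srs$labels[md$sample_id]
    km <- km_estimate(md$time, md$event, srs)
    write_table_tsv(km, file.path(d, "km.tsv"))
    cx <- cox_fit(md$time, md$event,
                  data.frame(srs1 = as.integer(srs == "SRS1")))
    lr <- logrank_test(md$time, md$event, srs)
    write_table_tsv(data.frame(hr = cx$hr, ci_low = cx$ci_low,
                               ci_high = cx$ci_high, wald_p = cx$wald_p,
                               score_p = cx$score_p,
                               logrank_chisq = lr$chisq,
                               logrank_p = lr$p),
                    file.path(d, "cox.tsv"))
    write_table_tsv(mortality_at(md$time, md$event, srs, 14),
                    file.path(d, "mortality14.tsv"))
    cmp <- compare_covariates(md, srs,
                              columns = c("age", "sex", "neut_prop",
                                          "severity"))
    write_table_tsv(cmp, file.path(d, "covariate_comparison.tsv"))
    res$survival <<- list(cox = cx, logrank = lr)
  })

  invisible(res)
}

report_section <- function(dir, stage, body_fun) {
  d <- file.path(dir, stage)
  if (!dir.exists(d) || file.exists(file.path(d, "FAILED")) ||
      !file.exists(file.path(d, "manifest.tsv"))) {
    return(c(paste0("## ", stage), "", "_not run_", ""))
  }
  c(paste0("## ", stage), "", body_fun(d), "")
}

#' Write a markdown report over a pipeline artifact directory
#'
#' Summarises each completed stage (cluster sizes and PC scatter file,
#' DE volcano summary, rotation result, eQTL counts by class, mark
#' enrichment, Kaplan-Meier/Cox results) and, when the ground truth is
#' present, a recovery-vs-truth section. Missing stages are marked "not
#' run".
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path report path (default `report.md` inside `out_dir`).
#' @return the report path, invisibly.
#' @export
write_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  lines <- c("# SRS analysis pipeline report", "")
  lines <- c(lines, report_section(out_dir, "discover", function(d) {
    lab <- read_table_tsv(file.path(d, "srs_labels.tsv"))
    wss <- read_table_tsv(file.path(d, "wss.tsv"))
    c(sprintf("- group sizes: %s",
              paste(names(table(lab$srs)), table(lab$srs),
                    sep = "=", collapse = ", ")),
      sprintf("- chosen k: %s", wss$k[wss$chosen][1]),
      "- PC scatter: `pc_scatter.tsv`")
  }))
  lines <- c(lines, report_section(out_dir, "de", function(d) {
    de <- read_table_tsv(file.path(d, "de_table.tsv"))
    c(sprintf("- %d probes called (of %d); %.1f%% downregulated in SRS1",
              sum(de$called), nrow(de),
              100 * mean(de$direction[de$called] == "down")))
  }))
  lines <- c(lines, report_section(out_dir, "geneset", function(d) {
    rt <- read_table_tsv(file.path(d, "rotation.tsv"))
    sprintf("- rotation statistic %.2f, p = %.3g (%d rotations)",
            rt$statistic, rt$p_rotation, rt$n_rotations)
  }))
  lines <- c(lines, report_section(out_dir, "eqtl", function(d) {
    rec <- read_table_tsv(file.path(d, "eqtl_records.tsv"))
    spec <- read_table_tsv(file.path(d, "srs_specific.tsv"))
    c(sprintf("- tested pairs: %d cis, %d trans",
              sum(rec$klass == "cis"), sum(rec$klass == "trans")),
      sprintf("- significant at stream FDR < 0.05: %d cis, %d trans",
              sum(rec$fdr < 0.05 & rec$klass == "cis"),
              sum(rec$fdr < 0.05 & rec$klass == "trans")),
      sprintf("- SRS-specific calls: %d SRS1-only, %d SRS2-only",
              sum(spec$call == "srs1_only"), sum(spec$call == "srs2_only")))
  }))
  lines <- c(lines, report_section(out_dir, "epimarks", function(d) {
    enr <- read_table_tsv(file.path(d, "mark_enrichment.tsv"))
    sprintf("- %s: %.2f%% vs %.2f%% (Fisher p = %.2g)", enr$mark,
            100 * enr$prop_fg, 100 * enr$prop_bg, enr$fisher_p)
  }))
  lines <- c(lines, report_section(out_dir, "survive", function(d) {
    cx <- read_table_tsv(file.path(d, "cox.tsv"))
    mt <- read_table_tsv(file.path(d, "mortality14.tsv"))
    c(sprintf("- Cox HR %.2f (95%% CI %.2f-%.2f), p = %.3g",
              cx$hr, cx$ci_low, cx$ci_high, cx$wald_p),
      sprintf("- 14-day mortality %s: %.0f%%", mt$group,
              100 * mt$proportion))
  }))
  lines <- c(lines, report_section(out_dir, "simulate", function(d) {
    if (!dir.exists(file.path(d, "truth"))) return("- no truth available")
    rec <- file.path(out_dir, "discover", "recovery.tsv")
    if (file.exists(rec)) {
      r <- read_table_tsv(rec)
      sprintf("- recovery vs planted truth: ARI = %.3f", r$value[1])
    } else "- truth present; discovery not run"
  }))
  writeLines(lines, path)
  invisible(path)
}
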