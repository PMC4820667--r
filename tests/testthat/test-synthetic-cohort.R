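test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_samples = 40, n_probes = 300, n_snps = 60,
                    n_de_probes = 50, n_cis_eqtl = 10, n_trans_eqtl = 2,
                    n_group_specific = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$marks, b$marks)
})

test_that("genotypes follow Hardy-Weinberg at the stated MAF", {
  cfg <- sim_config(seed = 3, n_samples = 10000, n_probes = 100,
                    n_snps = 1, n_de_probes = 10, n_cis_eqtl = 0,
                    n_trans_eqtl = 0, n_group_specific = 0,
                    maf_range = c(0.3, 0.3))
  g <- simulate_genotypes(cfg)
  counts <- tabulate(g$dosages[1, ] + 1L, nbins = 3)
  # HWE at maf 0.3: genotype frequencies (0.49, 0.42, 0.09)
  exp_p <- c(0.49, 0.42, 0.09)
  se <- sqrt(exp_p * (1 - exp_p) / 10000)
  expect_true(all(abs(counts / 10000 - exp_p) < 3 * se))

  # symmetry at maf 0.5: mean dosage near 1
  cfg5 <- sim_config(seed = 3, n_samples = 10000, n_probes = 100,
                     n_snps = 1, n_de_probes = 10, n_cis_eqtl = 0,
                     n_trans_eqtl = 0, n_group_specific = 0,
                     maf_range = c(0.5, 0.5))
  g5 <- simulate_genotypes(cfg5)
  expect_lt(abs(mean(g5$dosages[1, ]) - 1), 3 * sqrt(0.5 / 10000))
})

test_that("planted group sizes are exact and DE sign counts deterministic", {
  cfg <- sim_config(seed = 2, n_samples = 265, n_probes = 5000,
                    n_snps = 50, n_de_probes = 3080, n_cis_eqtl = 5,
                    n_trans_eqtl = 1, n_group_specific = 0)
  ann <- simulate_probe_annotation(cfg)
  truth <- make_sim_truth(cfg, ann)
  expect_equal(sum(truth$group_of_sample == 1L), ceiling(265 * 0.41))
  expect_lte(abs(sum(truth$group_of_sample == 1L) - 265 * 0.41), 1)
  # 73.4% of 3080 planted effects negative in group 1: exactly 2260
  expect_equal(sum(truth$de_probes$effect < 0), 2260)
})

test_that("planted eQTL respect cis/trans distance classes", {
  co <- small_cohort(seed = 13)
  pairs <- co$truth$eqtl_pairs
  ann <- co$genotypes$snp_ann
  pann <- co$expr$probe_ann
  si <- match(pairs$snp_id, ann$snp_id)
  pi <- match(pairs$probe_id, pann$probe_id)
  same <- ann$chrom[si] == pann$chrom[pi]
  d <- abs(ann$pos[si] - pann$start[pi])
  cis <- pairs$klass == "cis"
  expect_true(all(same[cis]))
  expect_true(all(d[cis] < 1e6))
  expect_true(all(!same[!cis]))  # trans planted cross-chromosome
  # group-restricted pairs have planted beta zeroed in the excluded group
  # by construction of simulate_expression: checked via recovery tests
  expect_true(all(pairs$group_restriction %in%
                    c("both", "group1", "group2")))
})

test_that("expression responds additively to planted dosage effects", {
  # planted beta = 1, sigma = 0.1, n = 500: OLS slope within [0.97, 1.03]
  cfg <- sim_config(seed = 21, n_samples = 500, n_probes = 200,
                    n_snps = 20, n_de_probes = 0, n_cis_eqtl = 5,
                    n_trans_eqtl = 0, n_group_specific = 0,
                    beta_range = c(1, 1), d0 = 1e8, s0sq = 0.01)
  ann <- simulate_probe_annotation(cfg)
  truth <- make_sim_truth(cfg, ann)
  truth$eqtl_pairs$beta <- abs(truth$eqtl_pairs$beta)
  geno <- simulate_genotypes(cfg, ann, truth$eqtl_pairs)
  ex <- simulate_expression(geno, truth, cfg, ann)
  for (j in seq_len(nrow(truth$eqtl_pairs))) {
    y <- ex$values[truth$eqtl_pairs$probe_id[j], ]
    g <- geno$dosages[truth$eqtl_pairs$snp_id[j], ]
    slope <- unname(coef(lm(y ~ g))[2])
    expect_gt(slope, 0.97)
    expect_lt(slope, 1.03)
  }
})

test_that("null generator has no group mean differences beyond noise", {
  cfg <- sim_config(seed = 5, n_samples = 200, n_probes = 2000,
                    n_snps = 10, n_de_probes = 0, n_cis_eqtl = 0,
                    n_trans_eqtl = 0, n_group_specific = 0,
                    confound_strength = 0, covariate_effect_sd = 0)
  co <- simulate_cohort(cfg, with_marks = FALSE)
  g1 <- co$metadata$group_true == 1
  d <- rowMeans(co$expr$values[, g1]) - rowMeans(co$expr$values[, !g1])
  sd_g <- sqrt(co$expr$sigma2_true * (1 / sum(g1) + 1 / sum(!g1)))
  z <- d / sd_g
  # standardized group differences are N(0,1) under the null program
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.08)
})

test_that("gene-wise variance prior is recoverable at scale", {
  cfg <- sim_config(seed = 17, n_samples = 80, n_probes = 6000,
                    n_snps = 10, n_de_probes = 0, n_cis_eqtl = 0,
                    n_trans_eqtl = 0, n_group_specific = 0,
                    d0 = 4, s0sq = 0.05, confound_strength = 0,
                    covariate_effect_sd = 0)
  co <- simulate_cohort(cfg, with_marks = FALSE)
  s2 <- apply(co$expr$values, 1, var)
  fd <- limma::fitFDist(s2, df1 = ncol(co$expr$values) - 1)
  expect_lt(abs(fd$df2 - 4) / 4, 0.2)
  expect_lt(abs(fd$scale - 0.05) / 0.05, 0.2)
})

test_that("survival generator reproduces the mortality contrast", {
  cfg <- sim_config(seed = 29, n_samples = 265)
  # large pooled sample for a tight check of the planted rates
  truth <- list(sample_ids = sprintf("S%05d", 1:20000),
                group_of_sample = rep(c(1L, 2L), c(8000, 12000)))
  sv <- simulate_survival(truth, cfg)
  expect_true(all(sv$time <= 28))
  expect_true(all(sv$time[sv$event == 1] < 28))
  expect_true(all(sv$time > 0))
  m1 <- mean(sv$time[truth$group_of_sample == 1] <= 14 &
               sv$event[truth$group_of_sample == 1] == 1)
  m2 <- mean(sv$time[truth$group_of_sample == 2] <= 14 &
               sv$event[truth$group_of_sample == 2] == 1)
  # planted 14-day mortality: 1-0.9^2.4 = 22.3% vs 10%
  expect_lt(abs(m1 - (1 - 0.9^2.4)), 3 * sqrt(0.22 * 0.78 / 8000))
  expect_lt(abs(m2 - 0.10), 3 * sqrt(0.1 * 0.9 / 12000))
})

test_that("hazard-ratio-1 generator yields uniform log-rank p-values", {
  cfg <- sim_config(seed = 31, hazard_ratio = 1)
  ps <- vapply(1:40, function(i) {
    cfg$seed <- 1000L + i
    truth <- list(sample_ids = sprintf("S%03d", 1:200),
                  group_of_sample = rep(c(1L, 2L), each = 100))
    sv <- simulate_survival(truth, cfg)
    logrank_test(sv$time, sv$event, truth$group_of_sample)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("mark intervals respect the enrichment placement rule", {
  co <- small_cohort(seed = 41)
  cfg <- co$config
  snp_ann <- co$genotypes$snp_ann
  esnp_ids <- co$truth$eqtl_pairs$snp_id[co$truth$eqtl_pairs$klass == "cis"]
  esnps <- snp_ann[snp_ann$snp_id %in% esnp_ids, ]

  # factor 4, background 0.008: true-eSNP overlap ~3.2% over many draws
  hits <- 0; tot <- 0
  for (i in 1:25) {
    cfg$seed <- 5000L + i
    iv <- simulate_mark_intervals(co$truth, 4, cfg, snp_ann = snp_ann,
                                  marks = "m")
    hits <- hits + sum(overlap_snps(esnps, iv))
    tot <- tot + nrow(esnps)
  }
  rate <- hits / tot
  expect_lt(abs(rate - 0.032), 3 * sqrt(0.032 * 0.968 / tot))

  # factor 1: overlap at background rate
  hits1 <- 0
  for (i in 1:25) {
    cfg$seed <- 7000L + i
    iv <- simulate_mark_intervals(co$truth, 1, cfg, snp_ann = snp_ann,
                                  marks = "m")
    hits1 <- hits1 + sum(overlap_snps(esnps, iv))
  }
  expect_lt(abs(hits1 / tot - 0.008), 3 * sqrt(0.008 * 0.992 / tot))

  # degenerate: no eSNPs still yields background intervals
  no_truth <- co$truth
  no_truth$eqtl_pairs <- no_truth$eqtl_pairs[0, ]
  iv0 <- simulate_mark_intervals(no_truth, 4, cfg, snp_ann = snp_ann,
                                 marks = "m")
  expect_gt(nrow(iv0), 0)
  # inadmissible enrichment fails with the admissible maximum
  cfg_bad <- co$config
  cfg_bad$mark_background_rate <- 0.3
  expect_error(simulate_mark_intervals(co$truth, 4, cfg_bad,
                                       snp_ann = snp_ann),
               "admissible")
})

test_that("eqtl plan referencing unknown probes fails with the pair id", {
  cfg <- sim_config(seed = 4, n_samples = 30, n_probes = 100, n_snps = 20,
                    n_de_probes = 10, n_cis_eqtl = 2, n_trans_eqtl = 0,
                    n_group_specific = 0)
  ann <- simulate_probe_annotation(cfg)
  truth <- make_sim_truth(cfg, ann)
  geno <- simulate_genotypes(cfg, ann, truth$eqtl_pairs)
  truth$eqtl_pairs$probe_id[1] <- "NOPE1"
  expect_error(simulate_expression(geno, truth, cfg, ann), "NOPE1")
})
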