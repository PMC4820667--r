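test_that("expression PCs capture structure with a fixed sign convention", {
  set.seed(21)
  # rank-1 planted structure dominates PC1
  u <- rnorm(40); v <- rnorm(200)
  x <- outer(v, u) * 5 + matrix(rnorm(200 * 40, 0, 0.1), 200, 40)
  rownames(x) <- sprintf("P%03d", 1:200)
  colnames(x) <- sprintf("S%02d", 1:40)
  pcs <- compute_expression_pcs(x, 3)
  vars <- apply(t(x) - colMeans(t(x)), 2, var)
  expect_gt(var(pcs[, 1]) / sum(apply(x, 1, var)), 0.99)
  # orthogonality
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # deterministic under column-sign ambiguity: recompute equals original
  expect_equal(compute_expression_pcs(x, 3), pcs)
  expect_error(compute_expression_pcs(x[1:3, ], 3), "rank")
})

test_that("a planted global confounder is captured by the first PC", {
  set.seed(23)
  n <- 60; p <- 300
  conf <- rnorm(n, 0, 2)
  load <- rnorm(p, 1, 0.2)
  x <- outer(load, conf) + matrix(rnorm(p * n), p, n)
  rownames(x) <- sprintf("P%03d", 1:p)
  pcs <- compute_expression_pcs(x, 2)
  r2 <- summary(lm(conf ~ pcs[, 1]))$r.squared
  expect_gte(r2, 0.9)
})

test_that("pair classification follows the printed distance rules", {
  snp_ann <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4"),
    chrom = c("chr1", "chr1", "chr2", "chrX"),
    pos = c(1500000, 2200000, 5000, 1000)
  )
  probe_ann <- data.frame(
    probe_id = c("p1", "p2"),
    chrom = c("chr1", "chr3"),
    start = c(999999, 50000)
  )
  cl <- classify_pairs(NULL, snp_ann, probe_ann)
  get <- function(s, p) cl$klass[cl$snp_id == s & cl$probe_id == p]
  # |1500000 - 999999| = 500001 < 1 Mb: cis
  expect_equal(get("s1", "p1"), "cis")
  expect_equal(cl$distance[cl$snp_id == "s1" & cl$probe_id == "p1"], 500001)
  # 1200001 bp: the 1-2.5 Mb gap zone is excluded
  expect_equal(get("s2", "p1"), "excluded")
  # different autosomes: trans
  expect_equal(get("s3", "p2"), "trans")
  # X chromosome pairs cannot be trans under the autosome restriction
  expect_equal(get("s4", "p2"), "excluded")
  cfgx <- eqtl_config(trans_autosomes_only = FALSE)
  clx <- classify_pairs(NULL, snp_ann, probe_ann, cfgx)
  expect_equal(clx$klass[clx$snp_id == "s4" & clx$probe_id == "p2"], "trans")
})

test_that("the vectorized engine matches the per-pair OLS oracle", {
  co <- small_cohort(seed = 61, n_samples = 60, n_probes = 100)
  values <- co$expr$values[1:20, ]
  dosages <- co$genotypes$dosages[1:50, ]
  pairs <- expand.grid(snp_id = rownames(dosages)[1:50],
                       probe_id = rownames(values)[1:20],
                       stringsAsFactors = FALSE)
  pairs$klass <- "cis"
  covs <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  rec <- map_eqtl(values, dosages, covs, pairs)
  oracle <- naive_eqtl(values, dosages, as.data.frame(covs), pairs)
  key <- paste(rec$snp_id, rec$probe_id)
  okey <- paste(oracle$snp_id, oracle$probe_id)
  m <- match(key, okey)
  expect_lt(max(abs(rec$beta - oracle$beta[m])), 1e-8)
  expect_lt(max(abs(rec$p - oracle$p[m])), 1e-8)
})

test_that("adding a dosage-orthogonal covariate leaves betas unchanged", {
  co <- small_cohort(seed = 63, n_samples = 50, n_probes = 100)
  values <- co$expr$values[1:10, ]
  dosages <- co$genotypes$dosages[1:10, ]
  pairs <- expand.grid(snp_id = rownames(dosages),
                       probe_id = rownames(values),
                       stringsAsFactors = FALSE)
  pairs$klass <- "cis"
  r0 <- map_eqtl(values, dosages, NULL, pairs)
  # project a random covariate off every dosage row and the intercept
  z <- rnorm(50)
  z <- residuals(lm(z ~ t(dosages)))
  r1 <- map_eqtl(values, dosages, cbind(z = z), pairs)
  expect_lt(max(abs(r0$beta - r1$beta)), 1e-10)
})

test_that("planted cis effects are recovered with calibrated FDR", {
  co <- small_cohort(seed = 65, n_samples = 150, n_probes = 1200,
                     n_snps = 400)
  cfg <- eqtl_config(n_pcs_main = 10)
  pairs <- build_pair_universe(co$genotypes$snp_ann, co$expr$probe_ann,
                               cfg, n_trans = 1500, seed = 1,
                               required_pairs = co$truth$eqtl_pairs)
  pcs <- compute_expression_pcs(co$expr$values, 10)
  rec <- map_eqtl(co$expr$values, co$genotypes$dosages, pcs, pairs)
  truth_key <- with(co$truth$eqtl_pairs[co$truth$eqtl_pairs$klass == "cis" &
                                          co$truth$eqtl_pairs$group_restriction ==
                                          "both", ],
                    paste(snp_id, probe_id))
  cis <- rec[rec$klass == "cis", ]
  hit_key <- paste(cis$snp_id, cis$probe_id)[cis$fdr < 0.05]
  sens <- mean(truth_key %in% hit_key)
  expect_gte(sens, 0.8)
})

test_that("permuted dosages yield no cis calls", {
  co <- small_cohort(seed = 67, n_samples = 100, n_probes = 500)
  set.seed(5)
  dos <- co$genotypes$dosages[, sample(ncol(co$genotypes$dosages))]
  colnames(dos) <- colnames(co$genotypes$dosages)
  pairs <- data.frame(
    snp_id = sample(rownames(dos), 2000, replace = TRUE),
    probe_id = sample(rownames(co$expr$values), 2000, replace = TRUE),
    klass = "cis", stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  rec <- map_eqtl(co$expr$values, dos, NULL, pairs)
  expect_equal(sum(rec$fdr < 0.05), 0)
})

test_that("lead SNP selection applies the documented tie rules", {
  rec <- data.frame(
    snp_id = c("b", "a", "c", "z"),
    probe_id = c("p1", "p1", "p1", "p2"),
    klass = "cis", distance = 0,
    beta = c(1, 1, 2, 3), se = 1,
    t = c(5, 5, 5, 2), p = c(0.01, 0.01, 0.01, 0.2),
    fdr = 0.05, r2 = 0.1, stringsAsFactors = FALSE
  )
  lead <- lead_snp_per_probe(rec)
  # p tie: larger |beta| wins
  expect_equal(lead$snp_id[lead$probe_id == "p1"], "c")
  expect_equal(lead$snp_id[lead$probe_id == "p2"], "z")
  rec$beta <- 1
  lead2 <- lead_snp_per_probe(rec)
  # full tie: lexicographically smaller snp_id
  expect_equal(lead2$snp_id[lead2$probe_id == "p1"], "a")
})

test_that("SRS-specific calling implements the two-FDR rule", {
  mk <- function(fdr) data.frame(snp_id = sprintf("s%d", 1:4),
                                 probe_id = sprintf("p%d", 1:4),
                                 fdr = fdr, stringsAsFactors = FALSE)
  r1 <- mk(c(0.001, 0.5, 0.005, 0.2))
  r2 <- mk(c(0.5, 0.001, 0.04, 0.3))
  out <- srs_specific_eqtl(r1, r2)
  expect_equal(out$call, c("srs1_only", "srs2_only", "shared",
                           "unclassified"))
  # identical tables produce no specific calls
  same <- srs_specific_eqtl(r1, r1)
  expect_false(any(same$call %in% c("srs1_only", "srs2_only")))
  expect_error(srs_specific_eqtl(r1, mk(c(0.1, 0.1, 0.1, 0.1))[0, ]),
               "disjoint")
})

test_that("planted group-restricted eQTL are recovered as group-specific", {
  hits <- 0
  for (s in 1:5) {
    co <- small_cohort(seed = 700 + s, n_samples = 240, n_probes = 800,
                       n_snps = 300, n_cis_eqtl = 30, n_group_specific = 10,
                       beta_range = c(1, 1.5))
    g1 <- co$metadata$group_true == 1
    pairs <- co$truth$eqtl_pairs
    pairs$klass[pairs$klass == "trans"] <- "trans"
    cl <- classify_pairs(pairs[, c("snp_id", "probe_id")],
                         co$genotypes$snp_ann, co$expr$probe_ann)
    cl <- cl[cl$klass == "cis", ]
    map_group <- function(keep) {
      v <- co$expr$values[, keep]
      p <- compute_expression_pcs(v, 5)
      map_eqtl(v, co$genotypes$dosages[, keep], p, cl)
    }
    out <- srs_specific_eqtl(map_group(g1), map_group(!g1))
    key <- paste(out$snp_id, out$probe_id)
    spec1 <- pairs[pairs$group_restriction == "group1" &
                     pairs$klass == "cis", ]
    got <- out$call[match(paste(spec1$snp_id, spec1$probe_id), key)]
    if (mean(got == "srs1_only", na.rm = TRUE) >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("context comparison separates condition-specific eQTL", {
  # reference identical to condition: nothing context-specific
  rec <- data.frame(
    snp_id = sprintf("s%d", 1:6), probe_id = sprintf("p%d", 1:6),
    klass = "cis", distance = c(-1, 2, -3, 4, 5, -6) * 1e4,
    beta = 1, se = 0.1, t = 10, p = rep(1e-6, 6),
    fdr = rep(1e-4, 6), r2 = 0.3, stringsAsFactors = FALSE
  )
  cc_same <- suppressWarnings(compare_contexts(rec, rec, NULL))
  expect_equal(cc_same$n_specific, 0)

  # exact Mann-Whitney oracle: distances {1,2,3} vs {4,5,6} -> p = 0.1
  ref <- rec
  ref$fdr <- c(1, 1, 1, 1e-4, 1e-4, 1e-4)
  rec2 <- rec
  rec2$distance <- c(1, 2, 3, 4, 5, 6)
  cc <- compare_contexts(rec2, ref, NULL)
  expect_equal(cc$n_specific, 3)
  expect_equal(cc$n_shared, 3)
  expect_equal(cc$mannwhitney_p, 0.1, tolerance = 1e-10)
})
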