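make_reference <- function(n_pass, n_fail = 50, seed = 1) {
  set.seed(seed)
  data.frame(
    gene = sprintf("G%04d", seq_len(n_pass + n_fail)),
    log2_fc = c(runif(n_pass, 0.7, 2) * sample(c(-1, 1), n_pass, TRUE),
                runif(n_fail, -0.3, 0.3)),
    fdr = c(runif(n_pass, 0, 0.01), runif(n_fail, 0.2, 1)),
    stringsAsFactors = FALSE
  )
}

test_that("signature derivation counts defined and measured genes", {
  ref <- make_reference(398)
  universe <- ref$gene[c(1:331, 399:430)]   # 331 of the passing genes measured
  sig <- derive_signature(list(ref), measured_universe = universe)
  expect_equal(attr(sig, "n_defined"), 398)
  expect_equal(attr(sig, "n_measured"), 331)
  expect_setequal(unique(sig$direction), c("up", "down"))
  # vacuous thresholds admit every reference gene
  sig_all <- derive_signature(list(ref), fdr = 1.01, fc = 1,
                              measured_universe = ref$gene)
  expect_equal(nrow(sig_all), nrow(ref[abs(ref$log2_fc) > 0, ]))
  # disjoint references intersect to an empty signature, with a warning
  ref2 <- make_reference(30, seed = 2)
  ref2$gene <- paste0("X", ref2$gene)
  expect_warning(
    sig0 <- derive_signature(list(ref, ref2), measured_universe = ref$gene),
    "empty"
  )
  expect_equal(nrow(sig0), 0)
})

test_that("rotation statistic equals the mean signed moderated t exactly", {
  co <- small_cohort(seed = 51, n_samples = 80, n_probes = 800)
  srs <- ifelse(co$metadata$group_true == 1, "SRS1", "SRS2")
  design <- cbind(intercept = 1, group = as.numeric(srs == "SRS1"))
  dt <- de_table(co$expr$values, srs)
  genes <- co$truth$de_probes$probe_id[1:50]
  sig <- data.frame(gene = genes,
                    direction = ifelse(co$truth$de_probes$effect[1:50] > 0,
                                       "up", "down"))
  pars <- attr(dt, "params")
  rt <- rotation_test(co$expr$values, design, sig, n_rotations = 0,
                      d0 = pars$d0, s0sq = pars$s0sq)
  # statistic-only mode: identical to the moderated t from the DE fit
  tm <- dt$t_mod[match(genes, dt$probe_id)]
  sgn <- ifelse(sig$direction == "up", 1, -1)
  expect_equal(rt$statistic, mean(sgn * tm), tolerance = 1e-8)
  expect_true(is.na(rt$p_rotation))
  expect_error(rotation_test(co$expr$values, design, sig, n_rotations = 50),
               "99")
})

test_that("concordant planted signatures are detected with small p", {
  co <- small_cohort(seed = 53, n_samples = 120, n_probes = 1000)
  srs <- ifelse(co$metadata$group_true == 1, "SRS1", "SRS2")
  design <- cbind(intercept = 1, group = as.numeric(srs == "SRS1"))
  de <- co$truth$de_probes
  sig <- data.frame(gene = de$probe_id,
                    direction = ifelse(de$effect > 0, "up", "down"))
  rt <- rotation_test(co$expr$values, design, sig, n_rotations = 9999,
                      seed = 4)
  expect_lte(rt$p_rotation, 1e-4)
  expect_gte(rt$p_rotation, 1 / 10000)
  # inverted directions flip the tail (discrete complement identity)
  sig_inv <- sig
  sig_inv$direction <- ifelse(sig$direction == "up", "down", "up")
  rt_inv <- rotation_test(co$expr$values, design, sig_inv,
                          n_rotations = 9999, seed = 4)
  expect_equal(rt_inv$statistic, -rt$statistic, tolerance = 1e-10)
  expect_equal(rt$p_rotation + rt_inv$p_rotation, 1 + 1 / 10000,
               tolerance = 1e-10)
})

test_that("rotation p is invariant to relabeling non-signature genes", {
  co <- small_cohort(seed = 55, n_samples = 60, n_probes = 500)
  srs <- ifelse(co$metadata$group_true == 1, "SRS1", "SRS2")
  design <- cbind(intercept = 1, group = as.numeric(srs == "SRS1"))
  sig <- data.frame(gene = co$truth$de_probes$probe_id[1:30],
                    direction = "down")
  v <- co$expr$values
  rt1 <- rotation_test(v, design, sig, n_rotations = 999, seed = 9)
  others <- setdiff(rownames(v), sig$gene)
  v2 <- v
  rownames(v2)[match(others, rownames(v2))] <- sample(others)
  rt2 <- rotation_test(v2, design, sig, n_rotations = 999, seed = 9)
  expect_equal(rt1$p_rotation, rt2$p_rotation)
  expect_equal(rt1$statistic, rt2$statistic, tolerance = 1e-12)
})

test_that("rotation agrees directionally with the limma roast oracle", {
  co <- small_cohort(seed = 57, n_samples = 80, n_probes = 600)
  srs <- ifelse(co$metadata$group_true == 1, "SRS1", "SRS2")
  design <- cbind(intercept = 1, group = as.numeric(srs == "SRS1"))
  de <- co$truth$de_probes
  sig <- data.frame(gene = de$probe_id,
                    direction = ifelse(de$effect > 0, "up", "down"))
  rt <- rotation_test(co$expr$values, design, sig, n_rotations = 999,
                      seed = 3)
  idx <- match(sig$gene, rownames(co$expr$values))
  set.seed(77)
  ro <- limma::roast(co$expr$values, index = idx, design = design,
                     contrast = 2, gene.weights = ifelse(sig$direction ==
                                                           "up", 1, -1),
                     nrot = 999)
  expect_lte(rt$p_rotation, 0.01)
  expect_lte(ro$p.value["Up", "P.Value"], 0.01)
})

test_that("chi-square enrichment equals the Pearson closed form", {
  # hand-checked 2x2: (10, 90, 10, 890)
  u <- sprintf("g%04d", 1:1000)
  a <- u[1:100]            # 100 in set A
  b <- u[c(1:10, 101:110)] # 10 overlap, 10 outside
  res <- suppressWarnings(enrichment_chisq(a, b, u))
  expect_equal(res$odds_ratio, (10 * 890) / (90 * 10), tolerance = 1e-10)
  tab <- matrix(c(10, 90, 10, 890), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / 1000
  chi_closed <- sum((tab - e)^2 / e)
  expect_equal(res$statistic, chi_closed, tolerance = 1e-10)
  expect_lt(res$p, 1e-4)
  # random sets: closed-form equality across many tables
  set.seed(12)
  for (i in 1:20) {
    aa <- sample(u, sample(50:300, 1))
    bb <- sample(u, sample(50:300, 1))
    r <- suppressWarnings(enrichment_chisq(aa, bb, u))
    t2 <- table(factor(u %in% aa, c(TRUE, FALSE)),
                factor(u %in% bb, c(TRUE, FALSE)))
    e2 <- outer(rowSums(t2), colSums(t2)) / length(u)
    expect_equal(unname(r$statistic), sum((t2 - e2)^2 / e2),
                 tolerance = 1e-10)
  }
  expect_error(enrichment_chisq(u, u, u), "degenerate")
})
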