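test_that("two-group fit reduces to the difference of group means", {
  pt <- planted_two_groups(seed = 3, n = 40, p = 100, delta = 1.2)
  design <- cbind(intercept = 1, group = as.numeric(pt$group == 1))
  fit <- fit_gene_models(pt$values, design)
  dm <- rowMeans(pt$values[, pt$group == 1]) -
    rowMeans(pt$values[, pt$group == 2])
  expect_equal(unname(fit$log2_fc), unname(dm), tolerance = 1e-10)
  expect_equal(unique(fit$df_residual), 40 - 2)
})

test_that("a covariate orthogonal to the group leaves the contrast intact", {
  pt <- planted_two_groups(seed = 4, n = 40, p = 60)
  g <- as.numeric(pt$group == 1)
  z <- rnorm(40)
  z <- residuals(lm(z ~ g))          # exactly orthogonal to the contrast
  d0 <- fit_gene_models(pt$values, cbind(intercept = 1, group = g))
  d1 <- fit_gene_models(pt$values, cbind(intercept = 1, group = g, z = z))
  expect_equal(d0$log2_fc, d1$log2_fc, tolerance = 1e-10)
  # rank deficiency is reported with the offending column
  expect_error(
    fit_gene_models(pt$values, cbind(intercept = 1, group = g, g2 = g)),
    "g2"
  )
})

test_that("planted effects are estimated within OLS sampling bounds", {
  # planted log2 effect 1.0, sigma 0.2, n = 265
  set.seed(6)
  n <- 265; p <- 400
  g <- rep(c(1, 0), c(109, 156))
  x <- matrix(rnorm(p * n, 0, 0.2), p, n) + outer(rep(1, p), g)
  rownames(x) <- sprintf("P%03d", 1:p)
  fit <- fit_gene_models(x, cbind(intercept = 1, group = g))
  inside <- mean(fit$log2_fc > 0.93 & fit$log2_fc < 1.07)
  expect_gte(inside, 0.95)
})

test_that("variance moderation matches its limiting cases", {
  set.seed(7)
  s2 <- rchisq(200, 10) / 10
  coefv <- rnorm(200)
  su <- rep(0.3, 200)
  # d0 = 0: ordinary t
  m0 <- moderate_variances(s2, 10, coefv, su, d0 = 0, s0sq = 1)
  expect_equal(m0$t_mod, coefv / (sqrt(s2) * su), tolerance = 1e-12)
  # d0 = Inf: pooled prior variance everywhere
  mi <- moderate_variances(s2, 10, coefv, su, d0 = Inf, s0sq = 0.7)
  expect_equal(unique(mi$s2_post), 0.7)
  expect_equal(mi$t_mod, coefv / (sqrt(0.7) * su), tolerance = 1e-12)
  # identical variances push the estimated d0 to infinity
  mfix <- moderate_variances(rep(0.5, 100), 10, coefv[1:100], su[1:100])
  expect_true(is.infinite(mfix$params$d0))
  expect_equal(unique(mfix$s2_post), mfix$params$s0sq, tolerance = 1e-6)
})

test_that("trigamma inversion and prior recovery under the generating model", {
  # oracle: root-finding solution of trigamma(x) = 0.5, checked by
  # substitution and against an independent Newton iteration
  root <- uniroot(function(x) trigamma(x) - 0.5, c(0.5, 10),
                  tol = 1e-12)$root
  expect_equal(trigamma(root), 0.5, tolerance = 1e-9)
  newton <- 1
  for (i in 1:50) newton <- newton - (trigamma(newton) - 0.5) / psigamma(newton, 2)
  expect_equal(root, newton, tolerance = 1e-8)
  expect_equal(root, 2.46003, tolerance = 1e-4)
  # recovery: sigma2 ~ s0sq * d0 / chisq(d0), d0 = 4, s0sq = 0.05
  set.seed(8)
  d0 <- 4; s0sq <- 0.05; df <- 50
  s2_true <- s0sq * d0 / rchisq(10000, d0)
  s2_obs <- s2_true * rchisq(10000, df) / df
  fd <- limma::fitFDist(s2_obs, df1 = df)
  expect_gt(fd$df2, 3.2); expect_lt(fd$df2, 4.8)
  expect_lt(abs(fd$scale - s0sq) / s0sq, 0.15)
})

test_that("BH adjustment matches hand-computed values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  # fdr >= p after monotonicity enforcement
  set.seed(9)
  p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("DE calling applies the fold-change threshold on the anti-log scale", {
  calls <- call_de(c(0.6, 0.5, -0.7), c(0.01, 0.001, 0.04))
  expect_equal(calls$called, c(TRUE, FALSE, TRUE))  # 2^0.5 = 1.41 < 1.5
  expect_equal(calls$direction, c("up", "up", "down"))
})

test_that("de_table reproduces the majority-downregulated program", {
  co <- small_cohort(seed = 23, n_samples = 200, n_probes = 3000)
  srs <- ifelse(co$metadata$group_true == 1, "SRS1", "SRS2")
  dt <- de_table(co$expr$values, srs)
  expect_true(all(dt$fdr >= dt$p))
  frac_down <- mean(dt$direction[dt$called] == "down")
  # planted 73.4% downregulated among DE effects
  expect_lt(abs(frac_down - 0.734), 3 * sqrt(0.734 * 0.266 / sum(dt$called)) + 0.03)
  # covariate-adjusted analysis with a constant covariate is identical
  dt2 <- de_table(co$expr$values, srs,
                  covariates = data.frame(c1 = rep(1.7, 200)))
  expect_equal(dt$log2_fc, dt2$log2_fc, tolerance = 1e-10)
})

test_that("called probes under the global null respect the FDR level", {
  # pooled over replicates: V / max(R, 1) stays near or below 0.05
  rates <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- matrix(rnorm(1000 * 60), 1000, 60,
                dimnames = list(sprintf("P%04d", 1:1000), NULL))
    srs <- rep(c("SRS1", "SRS2"), each = 30)
    dt <- de_table(x, srs)
    sum(dt$called) / max(sum(dt$called), 1)
  }, numeric(1))
  # every call is a false positive under the null; mean V/max(R,1) <= level
  expect_lte(mean(rates), 0.05 + 2 * sd(rates) / sqrt(length(rates)) + 1e-8)
})
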