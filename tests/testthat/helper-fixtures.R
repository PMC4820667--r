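# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; sizes are kept small except where a check is only meaningful at
# cohort scale.

# A small but fully featured cohort for module-level tests.
small_cohort <- function(seed = 11, n_samples = 120L, n_probes = 1500L,
                         n_snps = 300L,
                         n_de_probes = min(200L, round(n_probes / 5)),
                         n_cis_eqtl = 40L, n_trans_eqtl = 5L,
                         n_group_specific = 8L, ...) {
  cfg <- sim_config(seed = seed, n_samples = n_samples,
                    n_probes = n_probes, n_snps = n_snps,
                    n_de_probes = n_de_probes, n_cis_eqtl = n_cis_eqtl,
                    n_trans_eqtl = n_trans_eqtl,
                    n_group_specific = n_group_specific, ...)
  simulate_cohort(cfg)
}

# Two-group expression matrix with a planted mean shift; returns matrix,
# group factor and the probe indices carrying the shift.
planted_two_groups <- function(seed = 1, n = 60, p = 300,
                               n_de = max(2, round(p / 5)),
                               delta = 2, sigma = 1) {
  set.seed(seed)
  g <- rep(c(1, 2), length.out = n)
  x <- matrix(rnorm(p * n, 0, sigma), p, n)
  de <- seq_len(n_de)
  x[de, g == 1] <- x[de, g == 1] + delta
  dimnames(x) <- list(sprintf("P%04d", seq_len(p)),
                      sprintf("S%03d", seq_len(n)))
  list(values = x, group = g, de = de)
}

# Naive per-pair eQTL mapping by lm(): the brute-force oracle the
# vectorized engine is checked against.
naive_eqtl <- function(values, dosages, covariates, pairs) {
  out <- pairs
  out$beta <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    y <- values[pairs$probe_id[i], ]
    g <- dosages[pairs$snp_id[i], ]
    df <- data.frame(y = y, g = g)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    out$beta[i] <- cf["g", "Estimate"]
    out$p[i] <- cf["g", "Pr(>|t|)"]
  }
  out
}

# Within-group sum of squares of samples (columns of values) by label.
wss_of <- function(values, labels) {
  x <- t(values)
  sum(vapply(split(seq_len(nrow(x)), labels), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}
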