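#' Fit per-probe linear models
#'
#' Ordinary least squares per probe against a design matrix containing an
#' intercept, the group indicator, and any adjustment covariates. The
#' group-contrast coefficient is the log2 fold change SRS1 vs SRS2.
#' Model fitting is delegated to limma's `lmFit`.
#'
#' @param values probes x samples matrix.
#' @param design design matrix (samples x covariates) of full rank,
#'   containing a column named `group` coded 1 for SRS1 and 0 for SRS2.
#' @param coef name of the contrast column (default "group").
#' @return list with `log2_fc`, `sigma2` (residual variance),
#'   `df_residual`, `stdev_unscaled` (SE of the contrast per unit sigma),
#'   and the `fit` object.
#' @export
fit_gene_models <- function(values, design, coef = "group") {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(design) <= ncol(design)) {
    stop("need more samples than design columns")
  }
  if (!coef %in% colnames(design)) stop("no '", coef, "' column in design")
  fit <- limma::lmFit(values, design)
  list(
    log2_fc = fit$coefficients[, coef],
    sigma2 = fit$sigma^2,
    df_residual = fit$df.residual,
    stdev_unscaled = fit$stdev.unscaled[, coef],
    fit = fit
  )
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks gene-wise residual variances toward a prior estimated across
#' all genes. The prior (d0, s0sq) is the closed-form moment estimator
#' matching log variances to a scaled-F distribution via trigamma
#' inversion (limma's `fitFDist`); the posterior variance is
#' s2_post = (d0 * s0sq + df * sigma2) / (d0 + df), the moderated t is
#' the coefficient over its posterior standard error, and p-values use
#' d0 + df degrees of freedom. `d0 = 0` recovers the ordinary t;
#' `d0 = Inf` (all variances identical) uses s0sq everywhere.
#'
#' @param sigma2 gene-wise residual variances.
#' @param df_residual residual degrees of freedom (scalar or vector).
#' @param coef contrast coefficients (e.g. log2 fold changes).
#' @param stdev_unscaled per-unit-sigma SE of the contrast.
#' @param d0,s0sq optionally fix the prior instead of estimating it.
#' @return list with `params` (d0, s0sq), `s2_post`, `t_mod`, `p`,
#'   `df_total`.
#' @export
moderate_variances <- function(sigma2, df_residual, coef, stdev_unscaled,
                               d0 = NULL, s0sq = NULL) {
  if (is.null(d0) || is.null(s0sq)) {
    if (length(sigma2) < 50) {
      stop("need at least 50 probes to estimate the variance prior")
    }
    fd <- limma::fitFDist(sigma2, df1 = df_residual)
    d0 <- fd$df2
    s0sq <- fd$scale
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0sq, length(sigma2))
  } else if (d0 == 0) {
    s2_post <- sigma2
  } else {
    s2_post <- (d0 * s0sq + df_residual * sigma2) / (d0 + df_residual)
  }
  t_mod <- coef / (sqrt(s2_post) * stdev_unscaled)
  df_total <- df_residual + d0
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  list(params = list(d0 = d0, s0sq = s0sq), s2_post = s2_post,
       t_mod = t_mod, p = p, df_total = df_total)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement (`p.adjust`).
#'
#' @param p p-values in \[0, 1\].
#' @return FDR-adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed probes
#'
#' A probe is called when |log2 FC| exceeds log2(fc_threshold) and its
#' FDR is below fdr_threshold; direction is the sign of the fold change
#' relative to SRS1.
#'
#' @param log2_fc,fdr per-probe statistics.
#' @param fc_threshold fold-change threshold on the anti-log scale.
#' @param fdr_threshold FDR threshold.
#' @return list with logical `called` and character `direction`
#'   ("up"/"down" in SRS1).
#' @export
call_de <- function(log2_fc, fdr, fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(fc_threshold > 0, fdr_threshold > 0)
  called <- abs(log2_fc) > log2(fc_threshold) & fdr < fdr_threshold
  list(called = called, direction = ifelse(log2_fc > 0, "up", "down"))
}

#' Moderated-t differential expression between SRS groups
#'
#' Fits per-probe linear models, moderates variances by empirical Bayes,
#' applies BH FDR, and calls probes at the fold-change/FDR thresholds.
#' Probes with zero residual degrees of freedom are excluded with a
#' logged count.
#'
#' @param values probes x samples matrix.
#' @param srs character SRS label per sample ("SRS1"/"SRS2"), aligned to
#'   the columns of `values`.
#' @param covariates optional data.frame of adjustment covariates
#'   (numeric columns used as-is, factors expanded).
#' @param fc_threshold,fdr_threshold calling thresholds.
#' @return a data.frame (class `de_table`) with one row per probe:
#'   probe_id, log2_fc, sigma2, df_residual, t_mod, p, fdr, called,
#'   direction; moderation parameters in `attr(, "params")`.
#' @export
de_table <- function(values, srs, covariates = NULL,
                     fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(length(srs) == ncol(values))
  group <- as.numeric(srs == "SRS1")
  design <- cbind(intercept = 1, group = group)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                     drop = FALSE]
    # constant covariates carry no information beyond the intercept
    keep_cov <- apply(mm, 2, function(v) stats::var(v) > 0)
    if (any(!keep_cov)) {
      message("dropping constant covariate(s): ",
              paste(colnames(mm)[!keep_cov], collapse = ", "))
    }
    design <- cbind(design, mm[, keep_cov, drop = FALSE])
  }
  fitres <- fit_gene_models(values, design)
  keep <- fitres$df_residual > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " probe(s) with zero residual df excluded")
  }
  mod <- moderate_variances(fitres$sigma2[keep], fitres$df_residual[keep],
                            fitres$log2_fc[keep],
                            fitres$stdev_unscaled[keep])
  fdr <- bh_fdr(mod$p)
  calls <- call_de(fitres$log2_fc[keep], fdr, fc_threshold, fdr_threshold)
  out <- data.frame(
    probe_id = rownames(values)[keep],
    log2_fc = unname(fitres$log2_fc[keep]),
    sigma2 = unname(fitres$sigma2[keep]),
    df_residual = unname(fitres$df_residual[keep]),
    t_mod = unname(mod$t_mod),
    p = unname(mod$p),
    fdr = fdr,
    called = calls$called,
    direction = calls$direction,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- mod$params
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("de_table", "data.frame")
  out
}
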