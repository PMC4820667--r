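#' Derive a directional gene signature from reference DE results
#'
#' Genes passing both thresholds (FDR below `fdr`, fold change above `fc`
#' on the anti-log scale) in every supplied reference table, with
#' concordant direction across references, intersected with the measured
#' universe. Used to construct e.g. an endotoxin-tolerance signature from
#' reference endotoxin-exposure contrasts.
#'
#' @param references list of data.frames with columns `gene`, `log2_fc`,
#'   `fdr`.
#' @param fdr,fc thresholds.
#' @param measured_universe character vector of measurable gene ids.
#' @return a `signature_set` data.frame (gene, direction in up/down) with
#'   attributes `n_defined` (before universe intersection) and
#'   `n_measured`.
#' @export
derive_signature <- function(references, fdr = 0.05, fc = 1.5,
                             measured_universe) {
  stopifnot(length(references) >= 1)
  passing <- lapply(references, function(ref) {
    check_columns(ref, c("gene", "log2_fc", "fdr"), "reference table")
    ok <- ref$fdr < fdr & abs(ref$log2_fc) > log2(fc)
    data.frame(gene = ref$gene[ok], sign = sign(ref$log2_fc[ok]),
               stringsAsFactors = FALSE)
  })
  sig <- passing[[1]]
  for (p in passing[-1]) {
    m <- merge(sig, p, by = "gene")
    sig <- m[m$sign.x == m$sign.y, c("gene", "sign.x")]
    names(sig) <- c("gene", "sign")
  }
  n_defined <- nrow(sig)
  sig <- sig[sig$gene %in% measured_universe, ]
  out <- data.frame(gene = sig$gene,
                    direction = ifelse(sig$sign > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) warning("derived signature is empty")
  attr(out, "n_defined") <- n_defined
  attr(out, "n_measured") <- nrow(out)
  class(out) <- c("signature_set", "data.frame")
  out
}

#' Directional rotation gene-set test
#'
#' Self-contained test of whether a directional signature is coherently
#' differentially expressed along the group contrast. Each gene's data
#' are reduced to the contrast dimension plus the residual space of the
#' design; the set statistic is the mean moderated t over signature
#' genes with "down" genes sign-flipped, so concordance with the stated
#' directions pushes the statistic up. The null is generated by random
#' rotations (uniform unit vectors in the combined contrast + residual
#' space, shared across genes within a rotation, preserving gene-gene
#' correlation), and the right-tail p is (1 + #\{rotated >= observed\}) /
#' (n_rotations + 1). Variance moderation parameters are estimated from
#' all rows of `values` unless supplied.
#'
#' @param values probes x samples matrix (the full matrix; moderation is
#'   estimated across all probes).
#' @param design samples x covariates design matrix with the contrast
#'   column named in `coef`.
#' @param signature a `signature_set` (gene, direction) with genes among
#'   the rownames of `values`.
#' @param n_rotations number of rotations (>= 99, or 0 for the
#'   statistic-only mode).
#' @param seed integer seed for the rotation stream.
#' @param coef contrast column name.
#' @param d0,s0sq optionally fix the moderation prior.
#' @return a `rotation_result` list: `statistic`, `p_rotation`,
#'   `n_rotations`, `gene_t` (signed moderated t per signature gene).
#' @export
rotation_test <- function(values, design, signature, n_rotations = 9999L,
                          seed = 1L, coef = "group",
                          d0 = NULL, s0sq = NULL) {
  if (n_rotations != 0 && n_rotations < 99) {
    stop("n_rotations must be 0 (statistic only) or >= 99")
  }
  check_columns(signature, c("gene", "direction"), "signature")
  genes <- intersect(signature$gene, rownames(values))
  if (!length(genes)) stop("signature has no genes in the expression matrix")
  n <- nrow(design)
  p <- ncol(design)
  stopifnot(coef %in% colnames(design), n == ncol(values))

  # orthonormal basis: nuisance space, then the contrast direction, then
  # the residual space; genes are projected onto [contrast, residual].
  ord <- c(setdiff(seq_len(p), match(coef, colnames(design))),
           match(coef, colnames(design)))
  qrx <- qr(design[, ord, drop = FALSE])
  if (qrx$rank < p) stop("design is rank deficient")
  Qfull <- qr.Q(qrx, complete = TRUE)
  basis <- Qfull[, p:n, drop = FALSE]          # contrast dim + residual dims
  # pin the contrast direction: positive projection on the design column,
  # so gene-level signs match the regression coefficient convention
  if (sum(basis[, 1] * design[, coef]) < 0) basis[, 1] <- -basis[, 1]
  d <- n - p + 1L
  df_res <- n - p

  Zall <- values %*% basis                      # probes x d
  sigma2_all <- rowSums(Zall[, -1, drop = FALSE]^2) / df_res
  if (is.null(d0) || is.null(s0sq)) {
    fd <- limma::fitFDist(sigma2_all, df1 = df_res)
    d0 <- fd$df2; s0sq <- fd$scale
  }
  posterior <- function(s2) {
    if (is.infinite(d0)) rep(s0sq, length(s2))
    else (d0 * s0sq + df_res * s2) / (d0 + df_res)
  }

  Z <- Zall[genes, , drop = FALSE]
  sgn <- ifelse(signature$direction[match(genes, signature$gene)] == "up",
                1, -1)
  t_obs <- Z[, 1] / sqrt(posterior(rowSums(Z[, -1, drop = FALSE]^2) / df_res))
  stat_obs <- mean(sgn * t_obs)

  p_rot <- NA_real_
  if (n_rotations > 0) {
    set.seed(stream_seed(seed, "rotation"))
    R <- matrix(stats::rnorm(n_rotations * d), d, n_rotations)
    R <- sweep(R, 2, sqrt(colSums(R^2)), "/")    # unit vectors, columns
    Z1 <- Z %*% R                                # genes x rotations
    ssq <- rowSums(Z^2)
    s2 <- (ssq - Z1^2) / df_res
    Tm <- Z1 / sqrt((d0 * s0sq + df_res * s2) / (d0 + df_res))
    if (is.infinite(d0)) Tm <- Z1 / sqrt(s0sq)
    stat_rot <- colMeans(sgn * Tm)
    p_rot <- (1 + sum(stat_rot >= stat_obs)) / (n_rotations + 1)
  }
  structure(list(statistic = stat_obs, p_rotation = p_rot,
                 n_rotations = n_rotations,
                 gene_t = stats::setNames(sgn * t_obs, genes),
                 params = list(d0 = d0, s0sq = s0sq)),
            class = "rotation_result")
}

#' Chi-square enrichment of one gene set in another
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 membership table of two sets within a universe, with a
#' Haldane-corrected odds ratio when a cell is empty.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param correct apply Yates continuity correction.
#' @return list with `table`, `statistic`, `p`, `odds_ratio`.
#' @export
enrichment_chisq <- function(set_a, set_b, universe, correct = FALSE) {
  if (!length(universe)) stop("universe is empty")
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a set is empty or covers the universe")
  }
  ct <- stats::chisq.test(tab, correct = correct)
  m <- as.numeric(tab) # a&b, !a&b, a&!b, !a&!b (column-major)
  if (any(m == 0)) m <- m + 0.5
  or <- (m[1] * m[4]) / (m[2] * m[3])
  list(table = tab, statistic = unname(ct$statistic),
       p = ct$p.value, odds_ratio = or)
}
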