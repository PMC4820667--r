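#' Expression principal components for eQTL covariates
#'
#' PCs of the probe-centered expression matrix with samples as
#' observations, ordered by decreasing explained variance, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). Used as covariates to absorb SRS group and
#' other broad confounders (30 PCs for the full cohort, 25 within an SRS
#' group).
#'
#' @param values probes x samples matrix.
#' @param n_pcs number of components.
#' @return samples x n_pcs score matrix.
#' @export
compute_expression_pcs <- function(values, n_pcs) {
  stopifnot(n_pcs >= 1)
  x <- t(values)                       # samples x probes, probe-centered below
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank_attained <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_pcs >= rank_attained) {
    stop("n_pcs = ", n_pcs, " not below the attained rank (", rank_attained, ")")
  }
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' eQTL mapping configuration
#'
#' @param cis_window maximum SNP-to-probe-start distance for cis (bp).
#' @param trans_min minimum same-chromosome distance for trans (bp);
#'   cross-chromosome pairs are always trans.
#' @param n_pcs_main,n_pcs_group expression PCs for the full-cohort and
#'   per-group analyses.
#' @param fdr_cis,fdr_trans significance thresholds per stream.
#' @param srs_fdr_in,srs_fdr_out FDR bounds defining group-specific eQTL
#'   (significant below `srs_fdr_in` in one group, above `srs_fdr_out`
#'   in the other).
#' @param trans_autosomes_only restrict trans pairs to autosomes.
#' @return an `eqtl_config` list.
#' @export
eqtl_config <- function(cis_window = 1e6, trans_min = 2.5e6,
                        n_pcs_main = 30L, n_pcs_group = 25L,
                        fdr_cis = 0.05, fdr_trans = 0.05,
                        srs_fdr_in = 0.01, srs_fdr_out = 0.05,
                        trans_autosomes_only = TRUE) {
  stopifnot(cis_window < trans_min, srs_fdr_in < srs_fdr_out,
            n_pcs_main >= 0, n_pcs_group >= 0)
  structure(list(cis_window = cis_window, trans_min = trans_min,
                 n_pcs_main = as.integer(n_pcs_main),
                 n_pcs_group = as.integer(n_pcs_group),
                 fdr_cis = fdr_cis, fdr_trans = fdr_trans,
                 srs_fdr_in = srs_fdr_in, srs_fdr_out = srs_fdr_out,
                 trans_autosomes_only = trans_autosomes_only),
            class = "eqtl_config")
}

is_autosome <- function(chrom) !grepl("X|Y", chrom)

#' Classify SNP-probe pairs as cis, trans, or excluded
#'
#' cis: same chromosome with |SNP position - probe start| below the cis
#' window (1 Mb). trans: different chromosome, or same chromosome beyond
#' `trans_min` (2.5 Mb); with `trans_autosomes_only`, both members must
#' be autosomal. Same-chromosome pairs in the 1-2.5 Mb gap zone are
#' excluded. Coordinates are 1-based.
#'
#' @param pairs data.frame with `snp_id`, `probe_id`; if NULL the full
#'   cross of `snp_ann` x `probe_ann` is classified.
#' @param snp_ann data.frame (snp_id, chrom, pos).
#' @param probe_ann data.frame (probe_id, chrom, start).
#' @param config an [eqtl_config()].
#' @return data.frame: snp_id, probe_id, klass, distance (signed
#'   snp_pos - probe_start; NA across chromosomes).
#' @export
classify_pairs <- function(pairs = NULL, snp_ann, probe_ann,
                           config = eqtl_config()) {
  check_columns(snp_ann, c("snp_id", "chrom", "pos"))
  check_columns(probe_ann, c("probe_id", "chrom", "start"))
  if (is.null(pairs)) {
    pairs <- expand.grid(snp_id = snp_ann$snp_id,
                         probe_id = probe_ann$probe_id,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  }
  si <- match(pairs$snp_id, snp_ann$snp_id)
  pi <- match(pairs$probe_id, probe_ann$probe_id)
  if (anyNA(si) || anyNA(pi)) stop("pair references unknown SNP or probe")
  schrom <- snp_ann$chrom[si]; pchrom <- probe_ann$chrom[pi]
  known <- c(unique(snp_ann$chrom), unique(probe_ann$chrom))
  if (any(!nzchar(known)) || anyNA(known)) stop("unknown chromosome label")
  same <- schrom == pchrom
  dist <- ifelse(same, snp_ann$pos[si] - probe_ann$start[pi], NA_real_)
  auto_ok <- !config$trans_autosomes_only |
    (is_autosome(schrom) & is_autosome(pchrom))
  klass <- ifelse(same & abs(dist) < config$cis_window, "cis",
           ifelse((!same | abs(dist) > config$trans_min) & auto_ok, "trans",
                  "excluded"))
  data.frame(snp_id = pairs$snp_id, probe_id = pairs$probe_id,
             klass = klass, distance = dist, stringsAsFactors = FALSE)
}

#' Build a tested pair universe
#'
#' All cis pairs plus a seeded random subsample of trans pairs (the full
#' trans cross is quadratic and statistically redundant for recovery
#' testing).
#'
#' @param snp_ann,probe_ann annotations.
#' @param config an [eqtl_config()].
#' @param n_trans number of trans pairs to sample.
#' @param seed seed for the trans subsample.
#' @param required_pairs data.frame (snp_id, probe_id) always included
#'   (e.g. planted pairs).
#' @return classified pair data.frame as from [classify_pairs()], without
#'   excluded pairs.
#' @export
build_pair_universe <- function(snp_ann, probe_ann, config = eqtl_config(),
                                n_trans = 5000L, seed = 1L,
                                required_pairs = NULL) {
  # cis candidates per chromosome to avoid the full cross
  cis_list <- lapply(intersect(unique(snp_ann$chrom), unique(probe_ann$chrom)),
                     function(ch) {
    s <- snp_ann[snp_ann$chrom == ch, ]
    p <- probe_ann[probe_ann$chrom == ch, ]
    if (!nrow(s) || !nrow(p)) return(NULL)
    g <- expand.grid(i = seq_len(nrow(s)), j = seq_len(nrow(p)),
                     KEEP.OUT.ATTRS = FALSE)
    keep <- abs(s$pos[g$i] - p$start[g$j]) < config$cis_window
    data.frame(snp_id = s$snp_id[g$i[keep]], probe_id = p$probe_id[g$j[keep]],
               stringsAsFactors = FALSE)
  })
  cis <- do.call(rbind, Filter(Negate(is.null), cis_list))
  set.seed(stream_seed(seed, "pipeline"))
  tr <- data.frame(
    snp_id = sample(snp_ann$snp_id, n_trans, replace = TRUE),
    probe_id = sample(probe_ann$probe_id, n_trans, replace = TRUE),
    stringsAsFactors = FALSE
  )
  all_pairs <- rbind(cis, tr, required_pairs[, c("snp_id", "probe_id")])
  all_pairs <- unique(all_pairs)
  cl <- classify_pairs(all_pairs, snp_ann, probe_ann, config)
  cl[cl$klass != "excluded", ]
}

#' Map eQTL by covariate-adjusted additive linear models
#'
#' Per SNP-probe pair, OLS of expression on allele dosage adjusting for
#' covariates, computed by residualizing both matrices against the
#' covariates (with intercept) and correlating residuals — algebraically
#' identical to the per-pair multiple regression by Frisch-Waugh. t has
#' n - n_cov - 2 degrees of freedom (n_cov counting the non-intercept
#' covariates); r2 is the squared partial correlation of dosage given
#' covariates; BH FDR is computed separately within the cis and the
#' trans stream. Monomorphic SNPs in the analysed subset are skipped and
#' counted in `attr(, "n_skipped")`.
#'
#' @param values probes x samples matrix.
#' @param dosages SNPs x samples dosage matrix (0/1/2 or fractional).
#' @param covariates samples x k covariate matrix (no intercept column),
#'   or NULL.
#' @param pairs classified pairs from [classify_pairs()] (klass "cis" or
#'   "trans").
#' @return `eqtl_table` data.frame: snp_id, probe_id, klass, distance,
#'   beta, se, t, p, fdr, r2.
#' @export
map_eqtl <- function(values, dosages, covariates, pairs) {
  stopifnot(ncol(values) == ncol(dosages))
  if (!is.null(covariates)) stopifnot(nrow(covariates) == ncol(values))
  check_columns(pairs, c("snp_id", "probe_id", "klass"))
  pairs <- pairs[pairs$klass %in% c("cis", "trans"), , drop = FALSE]
  n <- ncol(values)
  X <- cbind(intercept = rep(1, n), covariates)
  k <- ncol(X)
  df <- n - k - 1L
  if (df < 1) stop("not enough residual degrees of freedom")

  # residualize against covariates once
  qx <- qr(X)
  resid_rows <- function(m) m - t(qr.fitted(qx, t(m)))
  E <- resid_rows(values)
  G <- resid_rows(dosages)

  gvar <- rowSums(G^2)
  mono <- stats::setNames(apply(dosages, 1, stats::var) == 0,
                          rownames(dosages))
  si <- match(pairs$snp_id, rownames(dosages))
  pi <- match(pairs$probe_id, rownames(values))
  if (anyNA(si) || anyNA(pi)) stop("pair references unknown SNP or probe")
  skip <- mono[si]
  n_skipped <- sum(skip)
  pairs <- pairs[!skip, , drop = FALSE]
  si <- si[!skip]; pi <- pi[!skip]

  num <- rowSums(G[si, , drop = FALSE] * E[pi, , drop = FALSE])
  gss <- gvar[si]
  ess <- rowSums(E[pi, , drop = FALSE]^2)
  beta <- num / gss
  r <- num / sqrt(gss * ess)
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  se <- beta / tstat
  se[!is.finite(se)] <- sqrt(ess / gss / df)[!is.finite(se)]

  out <- data.frame(
    snp_id = pairs$snp_id, probe_id = pairs$probe_id, klass = pairs$klass,
    distance = if ("distance" %in% names(pairs)) pairs$distance else NA_real_,
    beta = beta, se = se, t = tstat, p = p,
    fdr = NA_real_, r2 = r^2, stringsAsFactors = FALSE
  )
  for (kl in c("cis", "trans")) {
    idx <- out$klass == kl
    out$fdr[idx] <- bh_fdr(out$p[idx])
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "df") <- df
  class(out) <- c("eqtl_table", "data.frame")
  out
}

#' Lead SNP per probe
#'
#' The minimum-p record per probe; ties broken by larger |beta|, then by
#' snp_id order.
#'
#' @param records an `eqtl_table`.
#' @return one record per probe.
#' @export
lead_snp_per_probe <- function(records) {
  if (!nrow(records)) stop("no eQTL records")
  ord <- order(records$probe_id, records$p, -abs(records$beta),
               records$snp_id)
  rec <- records[ord, ]
  rec[!duplicated(rec$probe_id), ]
}

#' SRS-group-specific eQTL calling
#'
#' A pair is group-1-specific when its FDR is below `srs_fdr_in` in the
#' SRS1 mapping and above `srs_fdr_out` in the SRS2 mapping (and
#' symmetrically); shared when below `srs_fdr_out` in both. The pair
#' universes are intersected and must overlap.
#'
#' @param records_srs1,records_srs2 `eqtl_table`s from per-group mapping.
#' @param config an [eqtl_config()].
#' @return data.frame with snp_id, probe_id, fdr_srs1, fdr_srs2, call in
#'   \{srs1_only, srs2_only, shared, unclassified\}.
#' @export
srs_specific_eqtl <- function(records_srs1, records_srs2,
                              config = eqtl_config()) {
  key1 <- paste(records_srs1$snp_id, records_srs1$probe_id)
  key2 <- paste(records_srs2$snp_id, records_srs2$probe_id)
  common <- intersect(key1, key2)
  if (!length(common)) stop("pair universes are disjoint")
  r1 <- records_srs1[match(common, key1), ]
  r2 <- records_srs2[match(common, key2), ]
  fin <- config$srs_fdr_in; fout <- config$srs_fdr_out
  call <- ifelse(r1$fdr < fin & r2$fdr > fout, "srs1_only",
          ifelse(r2$fdr < fin & r1$fdr > fout, "srs2_only",
          ifelse(r1$fdr < fout & r2$fdr < fout, "shared", "unclassified")))
  data.frame(snp_id = r1$snp_id, probe_id = r1$probe_id,
             fdr_srs1 = r1$fdr, fdr_srs2 = r2$fdr, call = call,
             stringsAsFactors = FALSE)
}

#' Compare eQTL between a condition and a reference context
#'
#' Genes significant (FDR < 0.05) in the condition but not in the
#' reference are context-specific; the lead-SNP distance to the
#' transcription start site is compared between context-specific and
#' shared genes by a two-sided Mann-Whitney test (context-specific eQTL
#' are expected to sit more distally).
#'
#' @param records_condition,records_reference `eqtl_table`s (cis stream).
#' @param tss_positions named numeric vector of TSS coordinates per
#'   probe (1-based); here the annotated probe start.
#' @param fdr_threshold significance threshold in both contexts.
#' @return list with `gene_calls` (probe_id, call), `n_specific`,
#'   `n_shared`, `mannwhitney_p`, `median_dist_specific`,
#'   `median_dist_shared`.
#' @export
compare_contexts <- function(records_condition, records_reference,
                             tss_positions, fdr_threshold = 0.05) {
  genes <- intersect(unique(records_condition$probe_id),
                     unique(records_reference$probe_id))
  lead_c <- lead_snp_per_probe(
    records_condition[records_condition$probe_id %in% genes, ])
  lead_r <- lead_snp_per_probe(
    records_reference[records_reference$probe_id %in% genes, ])
  sig_c <- lead_c$probe_id[lead_c$fdr < fdr_threshold]
  sig_r <- lead_r$probe_id[lead_r$fdr < fdr_threshold]
  specific <- setdiff(sig_c, sig_r)
  shared <- intersect(sig_c, sig_r)
  calls <- data.frame(
    probe_id = genes,
    call = ifelse(genes %in% specific, "context_specific",
           ifelse(genes %in% shared, "shared", "not_significant")),
    stringsAsFactors = FALSE
  )
  dist_of <- function(ids) {
    idx <- match(ids, lead_c$probe_id)
    abs(lead_c$distance[idx])
  }
  mw_p <- NA_real_; md_s <- NA_real_; md_h <- NA_real_
  if (length(specific) && length(shared)) {
    ds <- dist_of(specific); dh <- dist_of(shared)
    ds <- ds[is.finite(ds)]; dh <- dh[is.finite(dh)]
    if (length(ds) && length(dh)) {
      mw_p <- stats::wilcox.test(ds, dh)$p.value
      md_s <- stats::median(ds); md_h <- stats::median(dh)
    }
  } else {
    warning("a context class is empty; distance test skipped")
  }
  list(gene_calls = calls, n_specific = length(specific),
       n_shared = length(shared), mannwhitney_p = mw_p,
       median_dist_specific = md_s, median_dist_shared = md_h)
}
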