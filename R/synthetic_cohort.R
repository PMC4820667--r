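#' Configuration for the synthetic sepsis cohort generator
#'
#' Bundles every tunable of the generator with defaults mirroring the
#' discovery-cohort conditions the package is calibrated against: 265
#' patients, 26185 expression probes, a 41/59 SRS1/SRS2 split, a
#' differential-expression program of 3080 probes of which 73.4% are
#' downregulated in SRS1, gene-wise variances from a scaled inverse
#' chi-square prior (limma's hierarchical model), additive cis/trans
#' genotype effects on designated probes (some restricted to one SRS
#' group), and exponential survival with hazard ratio 2.4 for SRS1 tuned
#' so SRS2 14-day mortality is 10%.
#'
#' @param seed master integer seed (mandatory); all stage randomness is
#'   derived from it through named streams.
#' @param n_samples,n_probes,n_snps cohort dimensions.
#' @param group1_fraction fraction of samples planted in SRS1.
#' @param n_de_probes number of probes with a group effect.
#' @param frac_down_in_group1 fraction of DE effects negative in SRS1.
#' @param de_effect_sd scale of half-normal DE effect magnitudes (log2).
#' @param d0,s0sq prior degrees of freedom and prior variance of the
#'   scaled inverse chi-square gene variance distribution.
#' @param sigma2_cap upper bound on gene-wise variances (log2 scale).
#'   The raw inverse chi-square tail occasionally draws single probes
#'   with variances orders of magnitude beyond anything seen on
#'   normalized arrays; capping at sd = 2 truncates ~0.03% of draws.
#' @param n_cis_eqtl,n_trans_eqtl planted eQTL pair counts.
#' @param n_group_specific number of cis pairs restricted to one group
#'   (alternating SRS1-only / SRS2-only).
#' @param beta_range absolute per-allele effect range (log2 units).
#' @param maf_range minor allele frequency range, in (0, 0.5].
#' @param confound_strength strength of the cell-proportion confounder's
#'   association with group (0 = none, 1 = the full observed contrast).
#' @param covariate_effect_sd sd of per-probe loadings on the z-scored
#'   cell-proportion covariate.
#' @param baseline_hazard daily hazard of the SRS2 group; the default
#'   solves 1 - exp(-14 * lambda) = 0.10.
#' @param hazard_ratio multiplicative SRS1 hazard.
#' @param censor_horizon_days administrative censoring time.
#' @param mark_background_rate genome fraction covered by each epigenetic
#'   mark under the null.
#' @param mark_width interval width in bp.
#' @param enrichment_factor multiple of the background overlap rate at
#'   which true lead eSNPs fall inside a mark.
#' @param context_specific_fraction fraction of cis pairs active only in
#'   the disease context (absent from a reference/population mapping and
#'   placed distally from the probe start, emulating distal enhancers).
#' @param n_chrom number of autosomes in the synthetic genome (plus one X).
#' @param chrom_length autosome length in bp.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 265L,
                       n_probes = 26185L,
                       n_snps = 1000L,
                       group1_fraction = 0.41,
                       n_de_probes = 3080L,
                       frac_down_in_group1 = 0.734,
                       de_effect_sd = 0.8,
                       d0 = 4,
                       s0sq = 0.05,
                       sigma2_cap = 4,
                       n_cis_eqtl = 200L,
                       n_trans_eqtl = 20L,
                       n_group_specific = 20L,
                       beta_range = c(0.5, 1.5),
                       maf_range = c(0.1, 0.5),
                       confound_strength = 0.5,
                       covariate_effect_sd = 0.1,
                       baseline_hazard = -log(0.9) / 14,
                       hazard_ratio = 2.4,
                       censor_horizon_days = 28,
                       mark_background_rate = 0.008,
                       mark_width = 1000L,
                       enrichment_factor = 4,
                       context_specific_fraction = 0.363,
                       n_chrom = 4L,
                       chrom_length = 120e6) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config()")
  stopifnot(
    group1_fraction > 0, group1_fraction < 1,
    frac_down_in_group1 > 0, frac_down_in_group1 < 1,
    n_de_probes <= n_probes,
    d0 > 0, s0sq > 0,
    all(maf_range > 0), all(maf_range <= 0.5),
    baseline_hazard > 0, hazard_ratio > 0,
    n_group_specific <= n_cis_eqtl
  )
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_probes = as.integer(n_probes), n_snps = as.integer(n_snps),
    group1_fraction = group1_fraction, n_de_probes = as.integer(n_de_probes),
    frac_down_in_group1 = frac_down_in_group1, de_effect_sd = de_effect_sd,
    d0 = d0, s0sq = s0sq, sigma2_cap = sigma2_cap,
    n_cis_eqtl = as.integer(n_cis_eqtl), n_trans_eqtl = as.integer(n_trans_eqtl),
    n_group_specific = as.integer(n_group_specific),
    beta_range = beta_range, maf_range = maf_range,
    confound_strength = confound_strength,
    covariate_effect_sd = covariate_effect_sd,
    baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
    censor_horizon_days = censor_horizon_days,
    mark_background_rate = mark_background_rate,
    mark_width = as.integer(mark_width),
    enrichment_factor = enrichment_factor,
    context_specific_fraction = context_specific_fraction,
    n_chrom = as.integer(n_chrom), chrom_length = chrom_length
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_chromosomes <- function(config, autosomes_only = FALSE) {
  auto <- paste0("chr", seq_len(config$n_chrom))
  if (autosomes_only) auto else c(auto, "chrX")
}

#' Simulate probe genomic annotation
#'
#' Places probes uniformly on a synthetic genome of `n_chrom` autosomes
#' plus chrX (X carries ~5% of probes).
#'
#' @param config a [sim_config()].
#' @return data.frame with `probe_id`, `chrom`, `start` (1-based).
#' @export
simulate_probe_annotation <- function(config) {
  set_stream(config$seed, "probes")
  n <- config$n_probes
  chroms <- sim_chromosomes(config)
  w <- c(rep(0.95 / config$n_chrom, config$n_chrom), 0.05)
  data.frame(
    probe_id = sprintf("P%05d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE, prob = w),
    start = sample.int(as.integer(config$chrom_length), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Plant the cohort ground truth
#'
#' Deterministic group assignment (first `ceiling(n * group1_fraction)`
#' samples after a seeded shuffle), signed DE effects with exactly
#' `floor(frac_down_in_group1 * n_de_probes)` negative in SRS1, and the
#' planted eQTL plan (cis within 1 Mb, trans across chromosomes, a subset
#' restricted to one group with beta = 0 in the other).
#'
#' @param config a [sim_config()].
#' @param probe_ann output of [simulate_probe_annotation()].
#' @return a `sim_truth` list: `group_of_sample`, `sample_ids`,
#'   `de_probes` (probe_id, effect), `eqtl_pairs` (snp_id, probe_id, beta,
#'   klass, group_restriction), `variance_prior`, `hazard_ratio_true`.
#' @export
make_sim_truth <- function(config, probe_ann) {
  set_stream(config$seed, "groups")
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  ord <- sample.int(n)
  n1 <- ceiling(n * config$group1_fraction)
  group <- rep(2L, n)
  group[ord[seq_len(n1)]] <- 1L

  # DE program: the planted probes emulate the called set (FC > 1.5), so
  # magnitudes are shifted half-normal above log2(1.5); signs are
  # fixed-count per direction.
  de_idx <- sample.int(config$n_probes, config$n_de_probes)
  n_down <- floor(config$frac_down_in_group1 * config$n_de_probes)
  signs <- rep(1, config$n_de_probes)
  signs[sample.int(config$n_de_probes, n_down)] <- -1
  mags <- log2(1.5) +
    abs(stats::rnorm(config$n_de_probes, 0, config$de_effect_sd))
  de_probes <- data.frame(
    probe_id = probe_ann$probe_id[de_idx],
    effect = signs * mags,
    stringsAsFactors = FALSE
  )

  # eQTL plan: distinct target probes per pair; autosomal probes only so
  # trans pairs respect the autosome restriction.
  autos <- probe_ann$chrom != "chrX"
  n_pairs <- config$n_cis_eqtl + config$n_trans_eqtl
  targets <- sample(which(autos), n_pairs)
  klass <- rep(c("cis", "trans"), c(config$n_cis_eqtl, config$n_trans_eqtl))
  beta <- stats::runif(n_pairs, config$beta_range[1], config$beta_range[2]) *
    sample(c(-1, 1), n_pairs, replace = TRUE)
  restrict <- rep("both", n_pairs)
  if (config$n_group_specific > 0) {
    restrict[seq_len(config$n_group_specific)] <-
      rep_len(c("group1", "group2"), config$n_group_specific)
  }
  # disease-context-only cis pairs: absent from a reference mapping and
  # placed distally from the probe start by simulate_genotypes
  context <- rep("shared", n_pairs)
  cis_idx <- which(klass == "cis")
  n_spec <- round(config$context_specific_fraction * length(cis_idx))
  if (n_spec > 0) {
    context[sample(cis_idx, n_spec)] <- "condition_only"
  }
  eqtl_pairs <- data.frame(
    snp_id = sprintf("SNP%05d", seq_len(n_pairs)),
    probe_id = probe_ann$probe_id[targets],
    beta = beta, klass = klass, group_restriction = restrict,
    context = context,
    stringsAsFactors = FALSE
  )

  structure(list(
    sample_ids = sample_ids,
    group_of_sample = group,
    de_probes = de_probes,
    eqtl_pairs = eqtl_pairs,
    variance_prior = c(d0_true = config$d0, s0sq_true = config$s0sq),
    hazard_ratio_true = config$hazard_ratio
  ), class = "sim_truth")
}

#' Simulate genotype dosages on the synthetic genome
#'
#' Dosages are Binomial(2, MAF) per sample (Hardy-Weinberg). When an eQTL
#' plan is supplied, planted cis SNPs are placed within 1 Mb of their
#' target probe start and planted trans SNPs on a different (autosomal)
#' chromosome; remaining SNPs are uniform. Monomorphic draws are
#' regenerated up to a bounded retry count.
#'
#' @param config a [sim_config()].
#' @param probe_ann probe annotation (required when `eqtl_plan` given).
#' @param eqtl_plan the `eqtl_pairs` data.frame of a `sim_truth`, or NULL.
#' @param max_retries retries per monomorphic SNP before failing.
#' @return list with `dosages` (SNPs x samples integer matrix) and
#'   `snp_ann` (snp_id, chrom, pos, maf).
#' @export
simulate_genotypes <- function(config, probe_ann = NULL, eqtl_plan = NULL,
                               max_retries = 50L) {
  set_stream(config$seed, "genotypes")
  n_planted <- if (is.null(eqtl_plan)) 0L else nrow(eqtl_plan)
  n_snps <- max(config$n_snps, n_planted)
  n <- config$n_samples
  maf <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])

  dos <- matrix(0L, n_snps, n)
  for (i in seq_len(n_snps)) {
    g <- stats::rbinom(n, 2L, maf[i])
    tries <- 0L
    while (stats::var(g) == 0 && tries < max_retries) {
      g <- stats::rbinom(n, 2L, maf[i])
      tries <- tries + 1L
    }
    if (stats::var(g) == 0) {
      stop("SNP ", i, " monomorphic after ", max_retries,
           " retries (maf = ", signif(maf[i], 3), ")")
    }
    dos[i, ] <- g
  }

  snp_id <- sprintf("SNP%05d", seq_len(n_snps))
  chrom <- sample(sim_chromosomes(config, autosomes_only = TRUE),
                  n_snps, replace = TRUE)
  pos <- sample.int(as.integer(config$chrom_length), n_snps, replace = TRUE)

  if (n_planted > 0) {
    if (is.null(probe_ann)) stop("probe_ann required with an eqtl_plan")
    check_columns(eqtl_plan, c("snp_id", "probe_id", "klass"))
    pidx <- match(eqtl_plan$probe_id, probe_ann$probe_id)
    if (anyNA(pidx)) {
      stop("eqtl plan references unknown probe(s): ",
           paste(eqtl_plan$probe_id[is.na(pidx)], collapse = ", "))
    }
    for (j in seq_len(n_planted)) {
      i <- match(eqtl_plan$snp_id[j], snp_id)
      pc <- probe_ann$chrom[pidx[j]]
      ps <- probe_ann$start[pidx[j]]
      if (eqtl_plan$klass[j] == "cis") {
        chrom[i] <- pc
        # condition-only pairs sit distally (emulating distal enhancers),
        # shared pairs proximally to the probe start
        rng <- if (!is.null(eqtl_plan$context) &&
                   eqtl_plan$context[j] == "condition_only") {
          c(300000L, 999999L)
        } else {
          c(1L, 299999L)
        }
        off <- sample(c(-1, 1), 1) *
          sample(seq.int(rng[1], rng[2]), 1)
        pos[i] <- min(max(ps + off, 1), config$chrom_length)
      } else {
        others <- setdiff(sim_chromosomes(config, autosomes_only = TRUE), pc)
        chrom[i] <- sample(others, 1)
        pos[i] <- sample.int(as.integer(config$chrom_length), 1)
      }
    }
  }

  rownames(dos) <- snp_id
  colnames(dos) <- sprintf("S%04d", seq_len(n))
  list(
    dosages = dos,
    snp_ann = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         maf = maf, stringsAsFactors = FALSE)
  )
}

#' Simulate clinical covariates
#'
#' Age and sex are group-independent; the polymorphonuclear cell
#' proportion and a severity score are group-dependent (the confounding
#' the covariate-adjusted analyses must handle), with the cell-proportion
#' contrast scaled by `confound_strength`.
#'
#' @param truth a `sim_truth`.
#' @param config a [sim_config()].
#' @return data.frame with sample_id, age, sex, neut_prop, severity.
#' @export
simulate_covariates <- function(truth, config) {
  set_stream(config$seed, "covariates")
  g1 <- truth$group_of_sample == 1L
  n <- length(g1)
  neut_mean <- ifelse(g1, 0.82 + config$confound_strength * 0.07, 0.82)
  neut <- pmin(pmax(stats::rnorm(n, neut_mean, 0.08), 0.3), 0.99)
  sev <- pmax(stats::rnorm(n, ifelse(g1, 7.9, 5.4), ifelse(g1, 4.0, 3.2)), 0)
  data.frame(
    sample_id = truth$sample_ids,
    age = round(stats::rnorm(n, 62, 16), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45)),
    neut_prop = neut,
    severity = round(sev, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate the expression matrix
#'
#' Each probe's value is baseline + group effect (DE program) + additive
#' genotype effects over its planted eQTL pairs (zeroed outside the
#' pair's group restriction) + a loading on the z-scored cell-proportion
#' covariate + Gaussian noise with gene-wise variance drawn from the
#' scaled inverse chi-square prior s0sq * d0 / chisq(d0).
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param truth a `sim_truth`.
#' @param config a [sim_config()].
#' @param probe_ann probe annotation defining probe order.
#' @param covariates optional output of [simulate_covariates()]; omit for
#'   a covariate-free matrix.
#' @return list with `values` (probes x samples), `probe_ann`,
#'   `sigma2_true` (planted gene-wise variances).
#' @export
simulate_expression <- function(genotypes, truth, config, probe_ann,
                                covariates = NULL) {
  set_stream(config$seed, "expression")
  n_p <- config$n_probes
  n <- config$n_samples
  stopifnot(nrow(probe_ann) == n_p)

  baseline <- stats::runif(n_p, 6, 12)
  sigma2 <- pmin(config$s0sq * config$d0 / stats::rchisq(n_p, config$d0),
                 config$sigma2_cap)
  vals <- matrix(stats::rnorm(n_p * n, 0, 1), n_p, n) * sqrt(sigma2) + baseline

  g1 <- truth$group_of_sample == 1L
  de_idx <- match(truth$de_probes$probe_id, probe_ann$probe_id)
  if (anyNA(de_idx)) stop("DE program references unknown probes")
  vals[de_idx, g1] <- vals[de_idx, g1] + truth$de_probes$effect

  pairs <- truth$eqtl_pairs
  if (nrow(pairs)) {
    sidx <- match(pairs$snp_id, rownames(genotypes$dosages))
    pidx <- match(pairs$probe_id, probe_ann$probe_id)
    bad <- is.na(sidx) | is.na(pidx)
    if (any(bad)) {
      stop("eqtl pair(s) reference unknown probe/SNP: ",
           paste(pairs$snp_id[bad], pairs$probe_id[bad],
                 sep = "/", collapse = ", "))
    }
    for (j in seq_len(nrow(pairs))) {
      active <- switch(pairs$group_restriction[j],
                       both = rep(TRUE, n), group1 = g1, group2 = !g1)
      dose <- as.numeric(genotypes$dosages[sidx[j], ])
      vals[pidx[j], active] <- vals[pidx[j], active] +
        pairs$beta[j] * dose[active]
    }
  }

  if (!is.null(covariates)) {
    loading <- stats::rnorm(n_p, 0, config$covariate_effect_sd)
    z <- as.numeric(scale(covariates$neut_prop))
    vals <- vals + outer(loading, z)
  }

  rownames(vals) <- probe_ann$probe_id
  colnames(vals) <- truth$sample_ids
  list(values = vals, probe_ann = probe_ann, sigma2_true = sigma2)
}

#' Simulate a reference-context expression matrix
#'
#' Expression for the same genotyped individuals under a reference
#' (population, non-disease) context: no SRS group structure and no DE
#' program, and the condition-only eQTL pairs silenced (beta = 0), so a
#' reference eQTL mapping shares only the "shared" pairs with the
#' disease-context mapping.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param truth the disease-context `sim_truth`.
#' @param config a [sim_config()]; the expression stream is reseeded so
#'   reference noise is independent of the disease-context noise.
#' @param probe_ann probe annotation.
#' @return as [simulate_expression()].
#' @export
simulate_reference_expression <- function(genotypes, truth, config,
                                          probe_ann) {
  truth_ref <- truth
  truth_ref$group_of_sample <- rep(2L, length(truth$group_of_sample))
  truth_ref$de_probes <- truth$de_probes[0, ]
  keep <- truth$eqtl_pairs$context != "condition_only"
  truth_ref$eqtl_pairs <- truth$eqtl_pairs[keep, , drop = FALSE]
  cfg_ref <- config
  cfg_ref$seed <- as.integer((config$seed + 499979) %% 2147483647)
  simulate_expression(genotypes, truth_ref, cfg_ref, probe_ann)
}

#' Simulate survival outcomes
#'
#' Exponential event times with hazard `baseline_hazard` for SRS2 and
#' `baseline_hazard * hazard_ratio` for SRS1, administratively censored
#' at `censor_horizon_days`.
#'
#' @param truth a `sim_truth`.
#' @param config a [sim_config()].
#' @return data.frame with sample_id, time (days), event (0/1).
#' @export
simulate_survival <- function(truth, config) {
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  set_stream(config$seed, "survival")
  g1 <- truth$group_of_sample == 1L
  rate <- config$baseline_hazard * ifelse(g1, config$hazard_ratio, 1)
  raw <- stats::rexp(length(rate), rate)
  horizon <- config$censor_horizon_days
  data.frame(
    sample_id = truth$sample_ids,
    time = pmin(raw, horizon),
    event = as.integer(raw < horizon),
    stringsAsFactors = FALSE
  )
}

#' Simulate epigenetic-mark intervals
#'
#' Fixed-width intervals per mark covering `mark_background_rate` of the
#' genome at random, plus dedicated intervals over true lead eSNPs so
#' their overlap probability is `enrichment_factor` times the background
#' rate. Above factor 1, additional non-covering intervals are clustered
#' close to eSNPs (exponential gaps, mean twice the interval width),
#' emulating the regulatory-neighbourhood proximity of real marks; these
#' shift the distance-to-nearest-mark distribution without touching the
#' calibrated overlap rate. Coordinates are BED convention: 0-based,
#' half-open.
#'
#' @param truth a `sim_truth` (used for its eSNP set; may have none).
#' @param enrichment_factor overlap-rate multiple for true eSNPs (>= 1).
#' @param config a [sim_config()].
#' @param snp_ann SNP annotation locating the planted eSNPs.
#' @param marks mark names to generate.
#' @return data.frame (chrom, start, end, mark), sorted per chromosome.
#' @export
simulate_mark_intervals <- function(truth, enrichment_factor, config,
                                    snp_ann = NULL,
                                    marks = c("H3K27ac", "H3K4me1",
                                              "H3K4me3", "DNaseI")) {
  stopifnot(enrichment_factor >= 1)
  f <- config$mark_background_rate
  if (f * enrichment_factor > 1) {
    stop("background rate x factor exceeds 1; admissible maximum is ",
         signif(1 / f, 4))
  }
  set_stream(config$seed, "marks")
  chroms <- sim_chromosomes(config)
  width <- config$mark_width
  L <- as.integer(config$chrom_length)

  esnp <- character(0)
  if (!is.null(truth) && nrow(truth$eqtl_pairs) > 0 && !is.null(snp_ann)) {
    esnp <- truth$eqtl_pairs$snp_id[truth$eqtl_pairs$klass == "cis"]
  }

  out <- vector("list", length(marks))
  p_add <- (f * enrichment_factor - f) / (1 - f)
  for (m in seq_along(marks)) {
    per_chrom <- lapply(chroms, function(ch) {
      k <- round(f * L / width)
      start <- sort(sample.int(L - width, k)) - 1L
      data.frame(chrom = ch, start = start, end = start + width,
                 mark = marks[m], stringsAsFactors = FALSE)
    })
    iv <- do.call(rbind, per_chrom)
    if (length(esnp)) {
      ann <- snp_ann[match(esnp, snp_ann$snp_id), ]
      add <- stats::runif(nrow(ann)) < p_add
      if (any(add)) {
        off <- sample.int(width, sum(add), replace = TRUE) - 1L
        start <- pmax(ann$pos[add] - 1L - off, 0L)
        iv <- rbind(iv, data.frame(chrom = ann$chrom[add], start = start,
                                   end = start + width, mark = marks[m],
                                   stringsAsFactors = FALSE))
      }
      # regulatory-neighbourhood clustering: nearby, never covering
      p_near <- min(1, (enrichment_factor - 1) * 0.1)
      near <- stats::runif(nrow(ann)) < p_near
      if (any(near)) {
        gap <- 1L + as.integer(stats::rexp(sum(near), 1 / (2 * width)))
        side <- sample(c(-1L, 1L), sum(near), replace = TRUE)
        pos0 <- ann$pos[near] - 1L
        start <- ifelse(side > 0, pos0 + gap + 1L,
                        pmax(pos0 - gap - width, 0L))
        iv <- rbind(iv, data.frame(chrom = ann$chrom[near], start = start,
                                   end = start + width, mark = marks[m],
                                   stringsAsFactors = FALSE))
      }
    }
    out[[m]] <- iv[order(iv$chrom, iv$start), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates annotation, ground truth, genotypes, covariates,
#' expression, survival and epigenetic marks from one seeded config.
#'
#' @param config a [sim_config()].
#' @param with_marks generate epigenetic-mark intervals (skippable for
#'   speed when only expression analyses are needed).
#' @return an `srs_cohort` list: `expr`, `genotypes`, `metadata`
#'   (covariates + time/event + planted group), `marks`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config, with_marks = TRUE) {
  probe_ann <- simulate_probe_annotation(config)
  truth <- make_sim_truth(config, probe_ann)
  genotypes <- simulate_genotypes(config, probe_ann, truth$eqtl_pairs)
  covariates <- simulate_covariates(truth, config)
  expr <- simulate_expression(genotypes, truth, config, probe_ann, covariates)
  surv <- simulate_survival(truth, config)
  metadata <- cbind(covariates,
                    surv[match(covariates$sample_id, surv$sample_id),
                         c("time", "event")],
                    group_true = truth$group_of_sample)
  rownames(metadata) <- NULL
  marks <- if (with_marks) {
    simulate_mark_intervals(truth, config$enrichment_factor, config,
                            snp_ann = genotypes$snp_ann)
  } else NULL
  structure(list(expr = expr, genotypes = genotypes, metadata = metadata,
                 marks = marks, truth = truth, config = config),
            class = "srs_cohort")
}
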