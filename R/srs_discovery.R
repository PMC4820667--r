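#' Select the most variable probes
#'
#' Returns the `ceiling(fraction * n_probes)` probes with the largest
#' sample variance (denominator n - 1) on the normalized log2 scale.
#' Ties are broken by probe id in lexicographic order so the selection is
#' reproducible and independent of sample order.
#'
#' @param values probes x samples expression matrix with probe rownames.
#' @param fraction fraction of probes to keep, in (0, 1].
#' @return character vector of probe ids.
#' @export
select_variable_probes <- function(values, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(values) == 0) stop("no probes in expression matrix")
  v <- row_vars(values)
  ids <- rownames(values)
  ord <- order(-v, ids)
  ids[ord][seq_len(ceiling(fraction * nrow(values)))]
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative minimum-variance (Ward) clustering of sample expression
#' vectors under the Euclidean metric, cut at exactly `k` groups.
#'
#' @param values probes x samples matrix (samples are the objects).
#' @param k number of groups (>= 2).
#' @return integer label per sample (named by sample id).
#' @export
ward_cluster <- function(values, k) {
  n <- ncol(values)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  stopifnot(k >= 1)
  hc <- stats::hclust(stats::dist(t(values)), method = "ward.D2")
  stats::cutree(hc, k = k)
}

cluster_wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

#' Consolidate cluster membership by k-means
#'
#' Lloyd iterations initialized at the centroids of the supplied labels
#' (no random restarts, so consolidation is deterministic). An empty
#' cluster is re-seeded at the point farthest from its nearest centroid.
#'
#' @param values probes x samples matrix.
#' @param labels initial integer labels (e.g. from [ward_cluster()]).
#' @param max_iter maximum Lloyd iterations.
#' @return list with `labels`, `wss` (final within-group sum of squares),
#'   `wss_initial`, `iterations`.
#' @export
consolidate_kmeans <- function(values, labels, max_iter = 100L) {
  x <- t(values)                       # samples x features
  k <- length(unique(labels))
  lab <- as.integer(factor(labels))
  centers <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(x[lab == j, , drop = FALSE])
  }))
  xsq <- rowSums(x * x)
  for (it in seq_len(max_iter)) {
    # squared distances samples x centers via the expansion trick
    d2 <- outer(xsq, rowSums(centers * centers), "+") - 2 * x %*% t(centers)
    new_lab <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_lab == j)) {
        far <- which.max(d2[cbind(seq_along(new_lab), new_lab)])
        new_lab[far] <- j
      }
    }
    if (all(new_lab == lab) && it > 1L) break
    lab <- new_lab
    centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(x[lab == j, , drop = FALSE])
    }))
  }
  out <- stats::setNames(lab, colnames(values))
  list(labels = out,
       wss = cluster_wss(x, lab),
       wss_initial = cluster_wss(x, as.integer(factor(labels))),
       iterations = it)
}

#' Evaluate candidate cluster numbers
#'
#' Runs Ward + k-means consolidation for each k in `k_range` (plus
#' max(k_range) + 1 so the last reduction is measurable) and chooses the
#' smallest k whose relative WSS reduction to k + 1 falls below
#' `threshold`; if none does, the largest k in the range.
#'
#' @param values probes x samples matrix.
#' @param k_range candidate k values (default 2:4).
#' @param threshold relative WSS-reduction cutoff (default 2%; in
#'   high-dimensional noise an extra cluster always buys a small
#'   reduction, empirically 1-1.5% at cohort scale, so the cutoff sits
#'   just above that floor).
#' @param max_iter Lloyd iteration cap.
#' @return list with `wss_by_k` (named numeric over k_range and the
#'   probe k just above it), `chosen_k`.
#' @export
evaluate_k <- function(values, k_range = 2:4, threshold = 0.02,
                       max_iter = 100L) {
  stopifnot(length(k_range) >= 1, min(k_range) >= 2,
            max(k_range) < ncol(values))
  ks <- c(k_range, max(k_range) + 1L)
  hc <- stats::hclust(stats::dist(t(values)), method = "ward.D2")
  wss <- vapply(ks, function(k) {
    consolidate_kmeans(values, stats::cutree(hc, k = k), max_iter)$wss
  }, numeric(1))
  names(wss) <- ks
  chosen <- max(k_range)
  for (k in k_range) {
    red <- (wss[as.character(k)] - wss[as.character(k + 1L)]) /
      wss[as.character(k)]
    if (red < threshold) { chosen <- k; break }
  }
  list(wss_by_k = wss, chosen_k = chosen)
}

#' Name the discovered groups SRS1/SRS2
#'
#' SRS1 is defined as the group in which the majority of differentially
#' expressed probes (quick unmoderated two-sample t pass, p < 0.05 and
#' |difference| > log2(1.5)) are downregulated — the immunosuppressed,
#' majority-downregulated phenotype. On an exact tie, or with no DE
#' probes, the smaller group is named SRS1 with a warning.
#'
#' @param labels two-group integer labels (named by sample).
#' @param values probes x samples matrix (full, not the variable subset).
#' @return list with `srs` (character "SRS1"/"SRS2" per sample),
#'   `orientation_rule` (description), `n_down_votes`, `n_up_votes`.
#' @export
orient_labels <- function(labels, values) {
  gs <- sort(unique(labels))
  if (length(gs) != 2) stop("orient_labels expects exactly 2 groups")
  a <- labels == gs[1]
  na <- sum(a); nb <- sum(!a)
  ma <- rowMeans(values[, a, drop = FALSE])
  mb <- rowMeans(values[, !a, drop = FALSE])
  va <- row_vars(values[, a, drop = FALSE])
  vb <- row_vars(values[, !a, drop = FALSE])
  se <- sqrt(va / na + vb / nb)
  diff <- ma - mb
  tt <- diff / se
  df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  called <- p < 0.05 & abs(diff) > log2(1.5)
  n_down <- sum(called & diff < 0)   # down in group a
  n_up <- sum(called & diff > 0)
  if (n_down == n_up) {
    warning("orientation vote tied (", n_down, " each); ",
            "naming the smaller group SRS1")
    srs1_group <- if (na <= nb) gs[1] else gs[2]
    rule <- "tie fallback: smaller group named SRS1"
  } else {
    srs1_group <- if (n_down > n_up) gs[1] else gs[2]
    rule <- "majority of DE probes downregulated in SRS1"
  }
  srs <- ifelse(labels == srs1_group, "SRS1", "SRS2")
  names(srs) <- names(labels)
  list(srs = srs, orientation_rule = rule,
       n_down_votes = n_down, n_up_votes = n_up)
}

#' Discover sepsis response signature groups
#'
#' The full discovery construction: cluster the most variable probes
#' (default top 10%) by Ward's method with Euclidean distance, choose k
#' by the within-group sum-of-squares criterion, consolidate membership
#' by k-means, and orient the two-group naming so SRS1 carries the
#' majority-downregulated expression program.
#'
#' @param values probes x samples expression matrix.
#' @param variance_fraction fraction of most variable probes clustered.
#' @param k_range candidate group numbers.
#' @param wss_threshold relative WSS-reduction cutoff for choosing k.
#' @param kmeans_max_iter Lloyd iteration cap.
#' @return an `srs_assignment` list: `labels` (SRS names when k = 2,
#'   otherwise "G<k>" names), `cluster` (integer labels), `wss_by_k`,
#'   `chosen_k`, `orientation_rule`, `variable_probes`.
#' @export
discover_srs <- function(values, variance_fraction = 0.10, k_range = 2:4,
                         wss_threshold = 0.02, kmeans_max_iter = 100L) {
  probes <- select_variable_probes(values, variance_fraction)
  sub <- values[probes, , drop = FALSE]
  ev <- evaluate_k(sub, k_range, wss_threshold, kmeans_max_iter)
  cons <- consolidate_kmeans(sub, ward_cluster(sub, ev$chosen_k),
                             kmeans_max_iter)
  if (ev$chosen_k == 2) {
    ori <- orient_labels(cons$labels, values)
    labels <- ori$srs
    rule <- ori$orientation_rule
  } else {
    labels <- paste0("G", cons$labels)
    names(labels) <- names(cons$labels)
    rule <- "more than 2 groups: generic names"
  }
  structure(list(labels = labels, cluster = cons$labels,
                 wss_by_k = ev$wss_by_k, chosen_k = ev$chosen_k,
                 orientation_rule = rule, variable_probes = probes),
            class = "srs_assignment")
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted groups; label-permutation invariant.
#'
#' @param a,b two label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
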