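# Interval logic is delegated to GenomicRanges; mark intervals use BED
# conventions (0-based, half-open) at the interface and are converted to
# 1-based closed ranges internally.

marks_to_granges <- function(interval_set) {
  check_columns(interval_set, c("chrom", "start", "end"), "interval set")
  if (any(interval_set$start < 0) || any(interval_set$start >= interval_set$end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  GenomicRanges::GRanges(
    seqnames = interval_set$chrom,
    ranges = IRanges::IRanges(start = interval_set$start + 1L,
                              end = interval_set$end)
  )
}

snps_to_granges <- function(snps) {
  check_columns(snps, c("chrom", "pos"), "SNP table")
  GenomicRanges::GRanges(seqnames = snps$chrom,
                         ranges = IRanges::IRanges(start = snps$pos,
                                                   width = 1L))
}

#' Overlap SNPs with mark intervals
#'
#' A SNP at 1-based position p overlaps a 0-based half-open interval
#' \[s, e) iff s <= p - 1 < e. Overlapping intervals are merged first so
#' proportions are well defined. SNPs on chromosomes absent from the
#' interval set simply do not overlap.
#'
#' @param snps data.frame with `chrom`, `pos` (1-based).
#' @param interval_set data.frame (chrom, start, end\[, mark\]), BED
#'   coordinates.
#' @return logical vector, one per SNP.
#' @export
overlap_snps <- function(snps, interval_set) {
  gr_m <- GenomicRanges::reduce(marks_to_granges(interval_set))
  # chromosomes absent from the interval set simply never overlap
  suppressWarnings(IRanges::overlapsAny(snps_to_granges(snps), gr_m))
}

#' Distance from each SNP to the nearest mark interval
#'
#' 0 for overlapping SNPs, otherwise the bp gap to the nearest interval
#' edge on the same chromosome; NA (excluded downstream) when the
#' chromosome carries no marks.
#'
#' @inheritParams overlap_snps
#' @return numeric vector of distances (NA where undefined).
#' @export
snp_mark_distance <- function(snps, interval_set) {
  gr_s <- snps_to_granges(snps)
  gr_m <- GenomicRanges::reduce(marks_to_granges(interval_set))
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(gr_s, gr_m))
  out <- rep(NA_real_, length(gr_s))
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}

#' Construct the local-SNP background set
#'
#' All SNPs within 1 Mb of any probe start — the comparator used for
#' mark-enrichment testing of expression-associated SNPs.
#'
#' @param snp_ann data.frame (snp_id, chrom, pos).
#' @param probe_ann data.frame (probe_id, chrom, start).
#' @param window bp window (default 1 Mb).
#' @return subset of `snp_ann`.
#' @export
local_snp_background <- function(snp_ann, probe_ann, window = 1e6) {
  gr_s <- snps_to_granges(snp_ann)
  gr_p <- GenomicRanges::GRanges(
    seqnames = probe_ann$chrom,
    ranges = IRanges::IRanges(start = pmax(probe_ann$start - window, 1),
                              end = probe_ann$start + window)
  )
  snp_ann[IRanges::overlapsAny(gr_s, GenomicRanges::reduce(gr_p)), ,
          drop = FALSE]
}

#' Mark enrichment of foreground SNPs: overlap proportions
#'
#' Fisher's exact test (two-sided) on the 2x2 table of foreground vs
#' background SNPs by overlap with the (merged) mark intervals.
#'
#' @param foreground_snps,background_snps data.frames (chrom, pos).
#' @param interval_set mark intervals (BED coordinates).
#' @return list with `prop_fg`, `prop_bg`, `fisher_p`, `odds_ratio`,
#'   `table`.
#' @export
enrichment_fisher <- function(foreground_snps, background_snps,
                              interval_set) {
  if (!nrow(foreground_snps)) stop("empty foreground SNP set")
  fg <- overlap_snps(foreground_snps, interval_set)
  bg <- overlap_snps(background_snps, interval_set)
  tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), 2,
                dimnames = list(c("overlap", "no_overlap"),
                                c("foreground", "background")))
  ft <- stats::fisher.test(tab)
  list(prop_fg = mean(fg), prop_bg = mean(bg), fisher_p = ft$p.value,
       odds_ratio = unname(ft$estimate), table = tab)
}

#' Mark enrichment of foreground SNPs: distance to nearest mark
#'
#' Two-sided Mann-Whitney test comparing foreground and background
#' distances to the nearest mark interval (0 when overlapping); exact
#' only for small arms (<= 20), otherwise the normal approximation with
#' tie correction. SNPs on mark-free chromosomes are excluded.
#'
#' @inheritParams enrichment_fisher
#' @return list with `median_dist_fg`, `median_dist_bg`,
#'   `mannwhitney_p`, `n_fg`, `n_bg`.
#' @export
distance_test <- function(foreground_snps, background_snps, interval_set) {
  df_ <- snp_mark_distance(foreground_snps, interval_set)
  db <- snp_mark_distance(background_snps, interval_set)
  df_ <- df_[!is.na(df_)]; db <- db[!is.na(db)]
  if (!length(df_) || !length(db)) stop("no usable distances")
  if (length(unique(c(df_, db))) == 1L) {
    p <- 1
  } else {
    exact <- length(df_) <= 20 && length(db) <= 20
    p <- stats::wilcox.test(df_, db, exact = exact)$p.value
  }
  list(median_dist_fg = stats::median(df_),
       median_dist_bg = stats::median(db),
       mannwhitney_p = p, n_fg = length(df_), n_bg = length(db))
}

#' Mark-by-mark enrichment of lead eSNPs
#'
#' Runs the overlap-proportion and distance tests for every mark in the
#' interval set, with the local-SNP background built from the probe
#' annotation.
#'
#' @param lead_snps data.frame (snp_id, chrom, pos) of lead
#'   expression-associated SNPs.
#' @param interval_set data.frame (chrom, start, end, mark).
#' @param snp_ann,probe_ann annotations used to build the background.
#' @return data.frame, one row per mark: mark, prop_fg, prop_bg,
#'   fisher_p, odds_ratio, median_dist_fg, median_dist_bg, mannwhitney_p.
#' @export
mark_enrichment <- function(lead_snps, interval_set, snp_ann, probe_ann) {
  check_columns(interval_set, c("chrom", "start", "end", "mark"))
  bg <- local_snp_background(snp_ann, probe_ann)
  rows <- lapply(unique(interval_set$mark), function(m) {
    iv <- interval_set[interval_set$mark == m, ]
    fe <- enrichment_fisher(lead_snps, bg, iv)
    dt <- distance_test(lead_snps, bg, iv)
    data.frame(mark = m, prop_fg = fe$prop_fg, prop_bg = fe$prop_bg,
               fisher_p = fe$fisher_p, odds_ratio = fe$odds_ratio,
               median_dist_fg = dt$median_dist_fg,
               median_dist_bg = dt$median_dist_bg,
               mannwhitney_p = dt$mannwhitney_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
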