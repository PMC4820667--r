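# Plain-text readers/writers for the cohort artifacts. Coordinates are
# 1-based in TSV/VCF and 0-based half-open in BED. BED IO goes through
# rtracklayer; VCF reading through vcfR.

#' @name cohort_io
#' @title Read and write cohort artifacts
#' @description TSV writers/readers for expression, dosages, annotation
#'   and metadata; BED for mark intervals; VCF v4.2 (GT) for genotypes.
#' @param values,genotypes,df,interval_set,path,snp_ann objects/paths as
#'   per the individual functions.
NULL

#' @rdname cohort_io
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(probe_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname cohort_io
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(snp_id = rownames(genotypes$dosages),
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname cohort_io
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @export
write_bed <- function(interval_set, path) {
  check_columns(interval_set, c("chrom", "start", "end"))
  gr <- GenomicRanges::GRanges(
    seqnames = interval_set$chrom,
    ranges = IRanges::IRanges(start = interval_set$start + 1L,
                              end = interval_set$end),
    name = if ("mark" %in% names(interval_set)) interval_set$mark else "."
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    mark = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' @rdname cohort_io
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  ann <- genotypes$snp_ann
  dos <- genotypes$dosages
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=srsomics synthetic cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(dos)), collapse = "\t")
  )
  body <- paste(ann$chrom, ann$pos, ann$snp_id, "A", "G", ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[] <- vapply(strsplit(gt, "[/|]"),
                  function(a) sum(as.integer(a)), integer(1))
  fix <- vcfR::getFIX(v)
  list(
    dosages = dos,
    snp_ann = data.frame(snp_id = unname(fix[, "ID"]),
                         chrom = unname(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         maf = NA_real_, stringsAsFactors = FALSE)
  )
}

#' Write the generator ground truth as structured text
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(data.frame(sample_id = truth$sample_ids,
                             group = truth$group_of_sample),
                  file.path(dir, "groups.tsv"))
  write_table_tsv(truth$de_probes, file.path(dir, "de_effects.tsv"))
  write_table_tsv(truth$eqtl_pairs, file.path(dir, "eqtl_pairs.tsv"))
  write_table_tsv(
    data.frame(key = c("d0_true", "s0sq_true", "hazard_ratio_true"),
               value = c(truth$variance_prior, truth$hazard_ratio_true)),
    file.path(dir, "params.tsv"))
  invisible(dir)
}

#' Read back a ground truth written by [write_truth()]
#'
#' @param dir directory written by [write_truth()].
#' @return a `sim_truth` list.
#' @export
read_truth <- function(dir) {
  g <- read_table_tsv(file.path(dir, "groups.tsv"))
  par <- read_table_tsv(file.path(dir, "params.tsv"))
  structure(list(
    sample_ids = g$sample_id,
    group_of_sample = g$group,
    de_probes = read_table_tsv(file.path(dir, "de_effects.tsv")),
    eqtl_pairs = read_table_tsv(file.path(dir, "eqtl_pairs.tsv")),
    variance_prior = stats::setNames(par$value[1:2], par$key[1:2]),
    hazard_ratio_true = par$value[3]
  ), class = "sim_truth")
}
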