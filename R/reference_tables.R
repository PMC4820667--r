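#' Reference cohort summary counts
#'
#' Published summary counts of the sepsis discovery and validation
#' cohorts that the synthetic generator is parameterised against
#' (cohort sizes, SRS group sizes, differential-expression counts,
#' 14-day deaths, severity-score summaries, signature sizes, eQTL study
#' dimensions). Shipped as a plain-text fixture.
#'
#' @return named numeric vector of counts and summary statistics.
#' @export
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.tsv",
                      package = "srsomics")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$key)
}

#' Ratios recomputed from the reference cohort counts
#'
#' Recomputes the headline percentages and derived quantities from the
#' raw counts in [reference_cohort_summary()]: the SRS1 fractions of
#' both cohorts, the fraction of differentially expressed probes
#' downregulated in SRS1, 14-day mortality per SRS group, the size of
#' the top-variable-probe set, and the Welch test on the severity-score
#' contrast between groups.
#'
#' @return named list of recomputed values (percentages on the 0-100
#'   scale).
#' @export
reference_ratios <- function() {
  s <- reference_cohort_summary()
  welch <- welch_summary_test(
    s[["sofa_mean_srs1"]], s[["sofa_sd_srs1"]], s[["discovery_srs1_n"]],
    s[["sofa_mean_srs2"]], s[["sofa_sd_srs2"]], s[["discovery_srs2_n"]]
  )
  list(
    srs1_percent_discovery = 100 * s[["discovery_srs1_n"]] / s[["discovery_n"]],
    srs1_percent_validation = 100 * s[["validation_srs1_n"]] / s[["validation_n"]],
    de_down_percent = 100 * s[["de_down_srs1"]] / s[["de_called"]],
    mort14_percent_srs1 = 100 * s[["mort14_srs1_deaths"]] / s[["discovery_srs1_n"]],
    mort14_percent_srs2 = 100 * s[["mort14_srs2_deaths"]] / s[["discovery_srs2_n"]],
    mort14_percent_discovery = 100 * s[["mort14_discovery_deaths"]] / s[["discovery_n"]],
    n_top_variable_probes = ceiling(s[["top_variable_fraction"]] *
                                      s[["probes_measured"]]),
    severity_welch_p = welch$p
  )
}
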