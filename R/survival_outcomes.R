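# Outcome analysis by SRS group, delegated to the survival package
# (product-limit estimator with Greenwood variance and log-log CIs,
# log-rank, Cox partial likelihood with Efron tie handling).

#' Kaplan-Meier curves per group
#'
#' @param time follow-up times (> 0, days).
#' @param event 0/1 death indicator.
#' @param group group label per subject.
#' @return data.frame per group and event time: group, time, n_risk,
#'   n_event, surv, se (Greenwood), lower, upper (95% log-log CI).
#' @export
km_estimate <- function(time, event, group) {
  stopifnot(all(time > 0), all(event %in% 0:1))
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("a group has zero subjects")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(group)[1], length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, se = s$std.err,
             lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard O - E log-rank with hypergeometric variance, 1 df.
#'
#' @inheritParams km_estimate
#' @return list with `chisq`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("log-rank test needs 2 groups")
  if (sum(event) == 0) stop("no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd_$chisq, p = stats::pchisq(sd_$chisq, 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial likelihood maximized by Newton-Raphson with Efron tie
#' handling; Wald CI and p for the first coefficient, plus the score
#' test p. Monotone likelihood (e.g. no events in one group) is flagged.
#'
#' @param time,event as in [km_estimate()].
#' @param covariates data.frame or matrix of covariates (first column is
#'   the coefficient reported, e.g. the SRS1 indicator).
#' @return a `cox_result` list: log_hr, hr, ci_low, ci_high, wald_p,
#'   score_p, n_events, monotone_flag.
#' @export
cox_fit <- function(time, event, covariates) {
  if (sum(event) < 1) stop("need at least one event")
  x <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) stop("covariates rank deficient")
  fit <- survival::coxph(survival::Surv(time, event) ~ mm,
                         ties = "efron")
  sm <- summary(fit)
  b <- sm$coefficients[1, ]
  mono <- any(abs(fit$coefficients) > 15)
  if (mono) warning("monotone likelihood suspected; CI unbounded one side")
  structure(list(
    log_hr = unname(b["coef"]), hr = unname(b["exp(coef)"]),
    ci_low = unname(sm$conf.int[1, "lower .95"]),
    ci_high = unname(sm$conf.int[1, "upper .95"]),
    wald_p = unname(b["Pr(>|z|)"]),
    score_p = unname(sm$sctest["pvalue"]),
    score_chisq = unname(sm$sctest["test"]),
    n_events = sum(event), monotone_flag = mono
  ), class = "cox_result")
}

#' Fixed-horizon mortality per group
#'
#' Deaths at or before the horizon over group size, with exact binomial
#' CIs; raw proportions require administratively complete follow-up to
#' the horizon, otherwise the KM estimate is used with a flag.
#'
#' @param time,event,group as in [km_estimate()].
#' @param horizon_days mortality horizon (> 0).
#' @return data.frame per group: group, n, deaths, proportion, ci_low,
#'   ci_high, km_based.
#' @export
mortality_at <- function(time, event, group, horizon_days) {
  stopifnot(horizon_days > 0)
  incomplete <- any(time < horizon_days & event == 0)
  rows <- lapply(sort(unique(as.character(group))), function(g) {
    idx <- group == g
    n <- sum(idx)
    if (!incomplete) {
      deaths <- sum(event[idx] == 1 & time[idx] <= horizon_days)
      prop <- deaths / n
      ci <- stats::binom.test(deaths, n)$conf.int
    } else {
      fit <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
      s <- summary(fit, times = horizon_days, extend = TRUE)
      prop <- 1 - s$surv
      deaths <- sum(event[idx] == 1 & time[idx] <= horizon_days)
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(group = g, n = n, deaths = deaths, proportion = prop,
               ci_low = ci[1], ci_high = ci[2], km_based = incomplete,
               stringsAsFactors = FALSE)
  })
  if (incomplete) warning("follow-up incomplete to horizon; KM estimate used")
  do.call(rbind, rows)
}

#' Group comparison of clinical covariates
#'
#' Welch t-test for numeric columns; chi-square for categorical columns,
#' switching to Fisher's exact test when any expected count is below 5.
#' Constant columns are skipped with a note.
#'
#' @param metadata data.frame of per-sample covariates.
#' @param group two-level grouping vector.
#' @param columns columns to compare (default all but sample_id).
#' @return data.frame: variable, test, estimate_1, estimate_2, p.
#' @export
compare_covariates <- function(metadata, group,
                               columns = setdiff(names(metadata),
                                                 "sample_id")) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("need exactly 2 groups")
  rows <- lapply(columns, function(cn) {
    x <- metadata[[cn]]
    if (length(unique(x[!is.na(x)])) < 2) {
      message("column '", cn, "' constant; skipped")
      return(NULL)
    }
    if (is.numeric(x)) {
      tt <- stats::t.test(x ~ g)
      data.frame(variable = cn, test = "welch_t",
                 estimate_1 = tt$estimate[1], estimate_2 = tt$estimate[2],
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      tab <- table(x, g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chisq"
      }
      data.frame(variable = cn, test = test,
                 estimate_1 = NA_real_, estimate_2 = NA_real_, p = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Welch t-test from summary statistics
#'
#' Two-sided Welch test computed from group means, SDs and sizes —
#' usable on published summary tables.
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs, sizes.
#' @return list with `t`, `df`, `p`.
#' @export
welch_summary_test <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
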