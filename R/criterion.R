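# Criterion-validity pipeline: outcome contingency summaries, age/sex-adjusted
# logistic odds ratios, rank-based LOS / nursing-minute comparisons, and the
# feasibility summary.

OUTCOME_COLUMNS <- c("los_days", "nursing_minutes", "one_on_one", "mortality",
                     "readmit_30d", "discharge_nh")

#' Contingency summary for one binary outcome
#'
#' Builds the risk-class-by-event 2x2 either from a patient-level cohort or
#' from an aggregate counts fixture, and computes per-group percentages and
#' the uncorrected chi-square p-value. For nursing-home discharge the
#' denominator is a policy choice: `"full_group"` uses whole risk classes
#' (the convention of the published pilot table), `"admitted_from_home"`
#' restricts to patients not already living in a nursing home (the outcome's
#' definition).
#'
#' @param cohort Cohort data frame, or `NULL` when `counts` is given.
#' @param outcome Name of a logical outcome column.
#' @param counts Optional numeric vector
#'   `c(events_low, n_low, events_high, n_high)` of aggregate counts.
#' @param denominator_policy `"full_group"` (default) or `"admitted_from_home"`.
#' @param instrument,threshold Scoring instrument and cut-point (cohort mode).
#' @return List of class `iceberg_contingency`: `outcome`, `counts` (2x2,
#'   rows low/high, cols event/non-event), `pct_overall`, `pct_low`,
#'   `pct_high`, `statistic`, `p_value`, `denominator_policy`, `flag`.
#' @export
outcome_contingency <- function(cohort = NULL, outcome, counts = NULL,
                                denominator_policy = c("full_group", "admitted_from_home"),
                                instrument = load_instrument(), threshold = NULL) {
  denominator_policy <- match.arg(denominator_policy)
  if (is.null(counts)) {
    if (is.null(cohort)) stop_iceberg("either a cohort or aggregate counts must be given")
    if (!outcome %in% names(cohort)) {
      stop_iceberg("cohort lacks outcome column '%s'", outcome)
    }
    threshold <- threshold %||% instrument$threshold_default
    scored <- score_cohort(cohort, instrument, threshold = threshold)
    parts <- split_cohort(scored, threshold)
    lo <- parts$low; hi <- parts$high
    if (denominator_policy == "admitted_from_home") {
      if (!"admitted_from_home" %in% names(cohort)) {
        stop_iceberg("denominator_policy 'admitted_from_home' needs an admitted_from_home column")
      }
      lo <- lo[cohort$admitted_from_home[lo]]
      hi <- hi[cohort$admitted_from_home[hi]]
    }
    y <- as.logical(cohort[[outcome]])
    counts <- c(sum(y[lo], na.rm = TRUE), length(lo),
                sum(y[hi], na.rm = TRUE), length(hi))
  }
  ev_lo <- counts[1]; n_lo <- counts[2]; ev_hi <- counts[3]; n_hi <- counts[4]
  if (n_lo == 0 || n_hi == 0) {
    stop_iceberg("outcome_contingency(%s): zero denominator in a risk class", outcome)
  }
  tab <- rbind(low = c(ev_lo, n_lo - ev_lo), high = c(ev_hi, n_hi - ev_hi))
  colnames(tab) <- c("event", "no_event")
  flag <- NA_character_
  if (ev_lo + ev_hi == 0) {
    flag <- "no events"
    stat <- NA_real_; p <- NA_real_
  } else if (ev_lo + ev_hi == n_lo + n_hi) {
    flag <- "all events"
    stat <- NA_real_; p <- NA_real_
  } else {
    cmp <- proportion_compare(tab, outcome)
    stat <- cmp$statistic; p <- cmp$p_value
  }
  structure(list(outcome = outcome, counts = tab,
                 pct_overall = round_half_up(100 * (ev_lo + ev_hi) / (n_lo + n_hi), 1),
                 pct_low = round_half_up(100 * ev_lo / n_lo, 1),
                 pct_high = round_half_up(100 * ev_hi / n_hi, 1),
                 statistic = stat, p_value = p,
                 denominator_policy = denominator_policy, flag = flag),
            class = "iceberg_contingency")
}

#' @export
print.iceberg_contingency <- function(x, ...) {
  cat(sprintf("%s: overall %s%%, low %s%% vs high %s%%, p %s%s [%s]\n",
              x$outcome, x$pct_overall, x$pct_low, x$pct_high,
              if (is.na(x$p_value)) "NA" else format_p(x$p_value),
              if (is.na(x$flag)) "" else paste0(" (", x$flag, ")"),
              x$denominator_policy))
  invisible(x)
}

#' Logistic odds ratio of an outcome for the high-vs-low risk class
#'
#' Maximum-likelihood logistic regression of a binary outcome on the risk
#' class (high = 1), by default adjusted for age (linear, years) and sex
#' (female = 1). The odds ratio is the exponentiated exposure coefficient
#' with a 95% Wald interval. Degenerate fits (separation: runaway
#' coefficients or standard errors) are reported with `converged = FALSE`
#' and missing CI rather than a spurious finite interval.
#'
#' @param cohort Cohort data frame. If it already carries a `risk_class`
#'   column ("high"/"low", or logical) that column is the exposure;
#'   otherwise the class is computed by scoring the item columns.
#' @param outcome Name of a logical outcome column.
#' @param covariates Adjustment covariates (subset of column names; `"sex"`
#'   is coded female = 1). `NULL` for an unadjusted fit.
#' @param instrument,threshold Scoring instrument and cut-point.
#' @return List of class `iceberg_association`: `outcome`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `covariates`, `n`, `events`, `converged`.
#' @export
fit_outcome_model <- function(cohort, outcome, covariates = c("age", "sex"),
                              instrument = load_instrument(), threshold = NULL) {
  if (!outcome %in% names(cohort)) {
    stop_iceberg("cohort lacks outcome column '%s'", outcome)
  }
  y <- as.logical(cohort[[outcome]])
  if ("risk_class" %in% names(cohort)) {
    rc <- cohort$risk_class
    exposure <- if (is.logical(rc)) as.numeric(rc) else as.numeric(rc == "high")
  } else {
    threshold <- threshold %||% instrument$threshold_default
    scored <- score_cohort(cohort, instrument, threshold = threshold)
    exposure <- as.numeric(scored$risk_class == "high")
  }
  dat <- data.frame(y = y, exposure = exposure)
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop_iceberg("missing covariate column '%s'", cv)
    dat[[cv]] <- if (cv == "sex") as.numeric(cohort$sex == "female") else cohort[[cv]]
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat$y) == 0) stop_iceberg("fit_outcome_model(%s): no events", outcome)
  if (sum(!dat$y) == 0) stop_iceberg("fit_outcome_model(%s): no non-events", outcome)

  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial())
  )
  sm <- summary(fit)$coefficients
  beta <- sm["exposure", "Estimate"]
  se <- sm["exposure", "Std. Error"]
  p <- sm["exposure", "Pr(>|z|)"]
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 10 && abs(beta) < 15
  structure(list(outcome = outcome,
                 odds_ratio = exp(beta),
                 ci_low = if (converged) exp(beta - 1.96 * se) else NA_real_,
                 ci_high = if (converged) exp(beta + 1.96 * se) else NA_real_,
                 p_value = if (converged) p else NA_real_,
                 log_or = beta, se = se,
                 covariates = covariates %||% character(0),
                 n = nrow(dat), events = sum(dat$y),
                 converged = converged),
            class = "iceberg_association")
}

#' @export
print.iceberg_association <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("%s: OR %.2f (95%% CI %.2f-%.2f), %d events / %d patients%s\n",
                x$outcome, x$odds_ratio, x$ci_low, x$ci_high, x$events, x$n,
                if (length(x$covariates)) paste0(", adjusted for ",
                                                 paste(x$covariates, collapse = ", ")) else ""))
  } else {
    cat(sprintf("%s: fit did not converge cleanly (separation suspected); no interval reported\n",
                x$outcome))
  }
  invisible(x)
}

#' Rank-sum comparisons of length of stay and nursing minutes
#'
#' Wilcoxon rank-sum comparison of `los_days` and `nursing_minutes` between
#' risk classes. Missing nursing minutes (the site availability mask) are
#' excluded pairwise and the excluded fraction reported; if every value is
#' missing the nursing row is flagged and LOS is still produced.
#'
#' @inheritParams fit_outcome_model
#' @return Named list of `iceberg_comparison` (`los_days`, `nursing_minutes`),
#'   with `nursing_missing_frac` attached as an attribute.
#' @export
compare_los_and_nursing <- function(cohort, instrument = load_instrument(),
                                    threshold = NULL) {
  if (!"los_days" %in% names(cohort)) stop_iceberg("cohort lacks los_days")
  threshold <- threshold %||% instrument$threshold_default
  scored <- score_cohort(cohort, instrument, threshold = threshold)
  parts <- split_cohort(scored, threshold)
  out <- list(
    los_days = rank_sum_compare(cohort$los_days[parts$low],
                                cohort$los_days[parts$high], "los_days")
  )
  nm <- cohort$nursing_minutes
  miss_frac <- if (is.null(nm)) 1 else mean(is.na(nm))
  if (is.null(nm) || all(is.na(nm))) {
    out$nursing_minutes <- comparison_result("nursing_minutes", "continuous_ranks",
                                             "", "", "", NA_real_, NA_real_,
                                             0, 0, flag = "all nursing minutes missing")
  } else {
    out$nursing_minutes <- rank_sum_compare(nm[parts$low], nm[parts$high],
                                            "nursing_minutes")
  }
  attr(out, "nursing_missing_frac") <- miss_frac
  out
}

#' Feasibility summary of administering the instrument
#'
#' Participation rate (analyzed / consented, rounded to the nearest integer
#' percent), completion-time mean and SD, and per-item distributions of the
#' information source (record / patient / proxy / other) and reported
#' difficulty (easy / difficult / not assessable).
#'
#' @param cohort Cohort with `completion_minutes` and per-item `src_*` /
#'   `diff_*` metadata columns, or `NULL` to summarize enrollment counts only.
#' @param n_consented,n_analyzed Enrollment counts; `n_analyzed` defaults to
#'   the cohort size and must not exceed `n_consented`.
#' @return List of class `iceberg_feasibility`.
#' @export
feasibility_summary <- function(cohort = NULL, n_consented,
                                n_analyzed = if (is.null(cohort)) NULL else nrow(cohort)) {
  if (is.null(n_analyzed)) stop_iceberg("n_analyzed is required when no cohort is given")
  if (n_analyzed > n_consented) {
    stop_iceberg("n_analyzed (%d) exceeds n_consented (%d)", n_analyzed, n_consented)
  }
  cm <- cohort$completion_minutes
  if (!is.null(cm) && any(cm <= 0, na.rm = TRUE)) {
    stop_iceberg("completion minutes must be positive")
  }
  src_cols <- grep("^src_", names(cohort), value = TRUE)
  diff_cols <- grep("^diff_", names(cohort), value = TRUE)
  dist_of <- function(col, levels) {
    tab <- table(factor(cohort[[col]], levels = levels))
    as.numeric(tab) / sum(tab)
  }
  src_levels <- c("record", "patient", "proxy", "other")
  diff_levels <- c("easy", "difficult", "not_assessable")
  source_distribution <- lapply(stats::setNames(src_cols, sub("^src_", "", src_cols)),
                                dist_of, levels = src_levels)
  difficulty_distribution <- lapply(stats::setNames(diff_cols, sub("^diff_", "", diff_cols)),
                                    dist_of, levels = diff_levels)
  source_distribution <- lapply(source_distribution, stats::setNames, src_levels)
  difficulty_distribution <- lapply(difficulty_distribution, stats::setNames, diff_levels)
  structure(list(
    participation_rate = round_half_up(100 * n_analyzed / n_consented, 0),
    n_consented = n_consented, n_analyzed = n_analyzed,
    completion_minutes_mean = if (is.null(cm)) NA_real_ else mean(cm, na.rm = TRUE),
    completion_minutes_sd = if (is.null(cm)) NA_real_ else stats::sd(cm, na.rm = TRUE),
    source_distribution = source_distribution,
    difficulty_distribution = difficulty_distribution),
    class = "iceberg_feasibility")
}

#' @export
print.iceberg_feasibility <- function(x, ...) {
  cat(sprintf("participation %.0f%% (%d of %d); completion %.1f min (SD %.1f)\n",
              x$participation_rate, x$n_analyzed, x$n_consented,
              x$completion_minutes_mean, x$completion_minutes_sd))
  invisible(x)
}

#' Criterion-validity report for a cohort
#'
#' Emits the pilot-2-shaped table — sex, age, completion time, length of
#' stay, one-on-one care, 30-day readmission, in-hospital mortality,
#' nursing-home discharge, nursing minutes — plus the four age/sex-adjusted
#' odds-ratio lines. With `counts_fixture` (an aggregate counts table with
#' columns `variable`, `events_low`, `n_low`, `events_high`, `n_high`) only
#' the contingency rows are produced.
#'
#' @param cohort Patient-level cohort data frame, or `NULL`.
#' @param counts_fixture Aggregate counts data frame, or `NULL`.
#' @param instrument,threshold Scoring instrument and cut-point.
#' @param denominator_policy Denominator policy for nursing-home discharge.
#' @return List of class `iceberg_criterion_report` with elements `table`
#'   (an `iceberg_report`), `associations` (data frame of OR lines) and
#'   `feasibility` (`NULL` unless metadata columns are present).
#' @export
build_criterion_report <- function(cohort = NULL, counts_fixture = NULL,
                                   instrument = load_instrument(), threshold = NULL,
                                   denominator_policy = "full_group") {
  threshold <- threshold %||% instrument$threshold_default
  binary <- c("one_on_one", "readmit_30d", "mortality", "discharge_nh")

  if (is.null(cohort)) {
    if (is.null(counts_fixture)) stop_iceberg("give a cohort or a counts fixture")
    rows <- list()
    for (i in seq_len(nrow(counts_fixture))) {
      v <- counts_fixture$variable[i]
      cs <- outcome_contingency(
        outcome = v,
        counts = as.numeric(counts_fixture[i, c("events_low", "n_low",
                                                "events_high", "n_high")]),
        denominator_policy = denominator_policy)
      rows[[v]] <- contingency_to_comparison(cs)
    }
    out <- list(table = comparisons_to_report(rows), associations = NULL,
                feasibility = NULL)
    class(out) <- "iceberg_criterion_report"
    return(out)
  }

  absent <- setdiff(c("sex", "age", binary, "los_days"), names(cohort))
  if (length(absent) > 0) {
    stop_iceberg("cohort lacks required column(s): %s", paste(absent, collapse = ", "))
  }
  scored <- score_cohort(cohort, instrument, threshold = threshold)
  parts <- split_cohort(scored, threshold)
  lo <- parts$low; hi <- parts$high

  rows <- list()
  sex_tab <- rbind(low = c(sum(cohort$sex[lo] == "female"), sum(cohort$sex[lo] != "female")),
                   high = c(sum(cohort$sex[hi] == "female"), sum(cohort$sex[hi] != "female")))
  rows$women <- proportion_compare(sex_tab, "women")
  rows$age <- mean_compare(cohort$age[lo], cohort$age[hi], "age")
  if ("completion_minutes" %in% names(cohort)) {
    rows$completion_minutes <- mean_compare(cohort$completion_minutes[lo],
                                            cohort$completion_minutes[hi],
                                            "completion_minutes")
  }
  lon <- compare_los_and_nursing(cohort, instrument, threshold)
  rows$los_days <- lon$los_days
  for (oc in binary) {
    pol <- if (oc == "discharge_nh") denominator_policy else "full_group"
    rows[[oc]] <- contingency_to_comparison(
      outcome_contingency(cohort, oc, denominator_policy = pol,
                          instrument = instrument, threshold = threshold))
  }
  rows$nursing_minutes <- lon$nursing_minutes

  associations <- do.call(rbind, lapply(binary, function(oc) {
    a <- tryCatch(fit_outcome_model(cohort, oc, instrument = instrument,
                                    threshold = threshold),
                  error = function(e) NULL)
    if (is.null(a)) {
      return(data.frame(outcome = oc, odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_, n = NA_integer_,
                        events = 0L, converged = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(outcome = oc, odds_ratio = a$odds_ratio, ci_low = a$ci_low,
               ci_high = a$ci_high, p_value = a$p_value, n = a$n,
               events = a$events, converged = a$converged,
               stringsAsFactors = FALSE)
  }))

  feas <- if (length(grep("^src_", names(cohort))) > 0 &&
              "completion_minutes" %in% names(cohort)) {
    feasibility_summary(cohort, n_consented = nrow(cohort))
  } else NULL

  out <- list(table = comparisons_to_report(rows), associations = associations,
              feasibility = feas)
  attr(out, "threshold") <- threshold
  attr(out, "denominator_policy") <- denominator_policy
  attr(out, "nursing_missing_frac") <- attr(lon, "nursing_missing_frac")
  attr(out, "ci_method") <- "Wald, 95%"
  class(out) <- "iceberg_criterion_report"
  out
}

contingency_to_comparison <- function(cs) {
  tab <- cs$counts
  comparison_result(cs$outcome, "binary",
                    sprintf("%d (%s%%)", sum(tab[, 1]), cs$pct_overall),
                    sprintf("%d (%s%%)", tab[1, 1], cs$pct_low),
                    sprintf("%d (%s%%)", tab[2, 1], cs$pct_high),
                    cs$statistic, cs$p_value,
                    sum(tab[1, ]), sum(tab[2, ]), flag = cs$flag)
}

#' @export
print.iceberg_criterion_report <- function(x, ...) {
  print(x$table)
  if (!is.null(x$associations)) {
    cat("\nAdjusted odds ratios (high vs low risk class):\n")
    with(x$associations, for (i in seq_along(outcome)) {
      if (isTRUE(converged[i])) {
        cat(sprintf("  %-14s OR %.2f (95%% CI %.2f-%.2f)\n",
                    outcome[i], odds_ratio[i], ci_low[i], ci_high[i]))
      } else {
        cat(sprintf("  %-14s not estimable\n", outcome[i]))
      }
    })
  }
  if (!is.null(x$feasibility)) print(x$feasibility)
  invisible(x)
}
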