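# Construct-validity pipeline: split a scored cohort at the cut-point and
# compare each CGA component between the high and low risk classes, plus
# Spearman correlations of the total score with every component.

CGA_COMPONENTS <- c("spi", "barthel", "mmse", "mna", "grip_right", "grip_left",
                    "sppb", "clock", "frailty_fried", "frailty_share")

comparison_result <- function(variable, kind, overall, low, high,
                              statistic, p_value, n_low, n_high, flag = NA_character_) {
  structure(list(variable = variable, kind = kind,
                 overall_summary = overall, low_summary = low,
                 high_summary = high, statistic = statistic,
                 p_value = p_value, n_low = n_low, n_high = n_high,
                 flag = flag),
            class = "iceberg_comparison")
}

#' @export
print.iceberg_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: low %s vs high %s, stat %.4g, p %s%s\n",
              x$variable, x$kind, x$low_summary, x$high_summary,
              x$statistic, format_p(x$p_value),
              if (is.na(x$flag)) "" else paste0(" (", x$flag, ")")))
  invisible(x)
}

#' Split a scored cohort into low and high risk classes
#'
#' Partitions at the cut-point: `total >= threshold` is high, below is low.
#' The partition is exhaustive and disjoint over the non-excluded patients.
#'
#' @param scored Data frame as returned by [score_cohort()] (columns `total`,
#'   `excluded`), or a bare numeric vector of totals.
#' @param threshold Integer cut-point.
#' @return List with elements `low` and `high` (row indices into `scored`),
#'   plus `degenerate = TRUE` when either side is empty.
#' @export
split_cohort <- function(scored, threshold) {
  if (is.numeric(scored)) {
    scored <- data.frame(total = scored,
                         excluded = rep(FALSE, length(scored)))
  }
  keep <- which(!scored$excluded & !is.na(scored$total))
  if (length(keep) == 0) stop_iceberg("cannot split an empty (or fully excluded) cohort")
  cls <- classify(scored$total[keep], threshold)
  low <- keep[cls == "low"]
  high <- keep[cls == "high"]
  list(low = low, high = high,
       degenerate = length(low) == 0 || length(high) == 0)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test via the normal approximation with tie correction
#' and no continuity correction (the convention the pilot analyses used;
#' uniquely consistent with their printed p-values). Group summaries are
#' reported as median (IQR).
#'
#' @param values_low,values_high Numeric vectors (NAs dropped).
#' @param variable Label carried into the result.
#' @return An `iceberg_comparison` with `kind = "continuous_ranks"`.
#' @export
rank_sum_compare <- function(values_low, values_high, variable = "variable") {
  values_low <- values_low[!is.na(values_low)]
  values_high <- values_high[!is.na(values_high)]
  if (length(values_low) < 1 || length(values_high) < 1) {
    stop_iceberg("rank_sum_compare(%s): each group needs >= 1 non-missing value",
                 variable)
  }
  pooled <- c(values_low, values_high)
  if (length(unique(pooled)) == 1) {
    return(comparison_result(variable, "continuous_ranks",
                             fmt_median_iqr(pooled), fmt_median_iqr(values_low),
                             fmt_median_iqr(values_high), 0, 1,
                             length(values_low), length(values_high),
                             flag = "no variation"))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_low, values_high,
                                            exact = FALSE, correct = FALSE))
  comparison_result(variable, "continuous_ranks",
                    fmt_median_iqr(pooled), fmt_median_iqr(values_low),
                    fmt_median_iqr(values_high),
                    unname(wt$statistic), wt$p.value,
                    length(values_low), length(values_high))
}

#' Pooled-variance two-sample t comparison
#'
#' @inheritParams rank_sum_compare
#' @return An `iceberg_comparison` with `kind = "continuous_means"` and
#'   mean (SD) group summaries.
#' @export
mean_compare <- function(values_low, values_high, variable = "variable") {
  values_low <- values_low[!is.na(values_low)]
  values_high <- values_high[!is.na(values_high)]
  if (length(values_low) < 2 || length(values_high) < 2) {
    stop_iceberg("mean_compare(%s): each group needs >= 2 non-missing values",
                 variable)
  }
  pooled <- c(values_low, values_high)
  if (stats::var(values_low) == 0 && stats::var(values_high) == 0) {
    # degenerate: pooled SE is zero, so p collapses to 0 or 1
    same <- mean(values_low) == mean(values_high)
    return(comparison_result(variable, "continuous_means",
                             fmt_mean_sd(pooled), fmt_mean_sd(values_low),
                             fmt_mean_sd(values_high),
                             if (same) 0 else Inf, if (same) 1 else 0,
                             length(values_low), length(values_high),
                             flag = "no variation"))
  }
  tt <- stats::t.test(values_low, values_high, var.equal = TRUE)
  comparison_result(variable, "continuous_means",
                    fmt_mean_sd(pooled), fmt_mean_sd(values_low),
                    fmt_mean_sd(values_high),
                    unname(tt$statistic), tt$p.value,
                    length(values_low), length(values_high))
}

#' Pearson chi-square comparison of a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom; rows are the risk classes (low, high), columns are
#' (event, non-event). Per-group percentages are rendered to one decimal.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param variable Label carried into the result.
#' @return An `iceberg_comparison` with `kind = "binary"`.
#' @export
#' @examples
#' proportion_compare(matrix(c(7, 122, 23, 136), 2, byrow = TRUE), "one_on_one")
proportion_compare <- function(table, variable = "variable") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop_iceberg("proportion_compare expects a 2x2 table")
  if (any(table < 0)) stop_iceberg("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_iceberg("proportion_compare(%s): zero margin in the 2x2 table", variable)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  pct <- 100 * table[, 1] / rowSums(table)
  overall <- 100 * sum(table[, 1]) / sum(table)
  comparison_result(variable, "binary",
                    sprintf("%d (%s)", sum(table[, 1]), fmt_pct(overall)),
                    sprintf("%d (%s)", table[1, 1], fmt_pct(pct[1])),
                    sprintf("%d (%s)", table[2, 1], fmt_pct(pct[2])),
                    unname(ct$statistic), ct$p.value,
                    sum(table[1, ]), sum(table[2, ]))
}

#' Spearman correlations of the total score with each CGA component
#'
#' Average-rank handling of ties, pairwise-complete deletion of missing
#' values; components with fewer than 3 complete pairs are flagged rather
#' than dropped.
#'
#' @param cohort Cohort data frame containing item response columns and CGA
#'   component columns.
#' @param instrument Scoring instrument (packaged default).
#' @param components Character vector of component columns; default every
#'   canonical CGA column present in `cohort`.
#' @return Data frame with `variable`, `rho`, `p_value`, `n`, `flag`.
#' @export
spearman_score_vs_components <- function(cohort, instrument = load_instrument(),
                                         components = NULL) {
  components <- components %||% intersect(CGA_COMPONENTS, names(cohort))
  if (length(components) == 0) stop_iceberg("no CGA component columns found")
  total <- score_cohort(cohort, instrument)$total
  rows <- lapply(components, function(comp) {
    y <- cohort[[comp]]
    ok <- !is.na(total) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(variable = comp, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), flag = "fewer than 3 complete pairs",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(total[ok], y[ok],
                                           method = "spearman", exact = FALSE))
    data.frame(variable = comp, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct-validity report for a cohort
#'
#' Scores the cohort, splits it at the cut-point, and emits one row per
#' variable: sex by uncorrected chi-square, age by pooled t-test, and every
#' CGA component by Wilcoxon rank-sum (matching each variable's printed
#' summary format: counts, mean (SD), median (IQR) respectively). No
#' multiple-testing correction is applied (noted in the report footer).
#'
#' @param cohort Cohort data frame (item responses + `sex`, `age`, CGA columns).
#' @param instrument Scoring instrument.
#' @param threshold Cut-point; default the instrument's.
#' @param missing_policy Forwarded to [score_cohort()].
#' @return Data frame of class `iceberg_report`, one row per variable, with
#'   raw statistics and p-values plus display columns.
#' @export
build_construct_report <- function(cohort, instrument = load_instrument(),
                                   threshold = NULL, missing_policy = "zero") {
  threshold <- threshold %||% instrument$threshold_default
  needed <- c("sex", "age", CGA_COMPONENTS)
  absent <- setdiff(needed, names(cohort))
  if (length(absent) > 0) {
    stop_iceberg("cohort lacks required column(s): %s", paste(absent, collapse = ", "))
  }
  scored <- score_cohort(cohort, instrument, missing_policy = missing_policy,
                         threshold = threshold)
  parts <- split_cohort(scored, threshold)
  if (parts$degenerate) {
    warning("degenerate split: one risk class is empty; p-values not computable",
            call. = FALSE)
  }
  lo <- parts$low; hi <- parts$high

  rows <- list()
  if (!parts$degenerate) {
    sex_tab <- rbind(low = c(sum(cohort$sex[lo] == "female"), sum(cohort$sex[lo] != "female")),
                     high = c(sum(cohort$sex[hi] == "female"), sum(cohort$sex[hi] != "female")))
    rows$women <- proportion_compare(sex_tab, "women")
    rows$age <- mean_compare(cohort$age[lo], cohort$age[hi], "age")
    for (comp in CGA_COMPONENTS) {
      rows[[comp]] <- rank_sum_compare(cohort[[comp]][lo], cohort[[comp]][hi], comp)
    }
  } else {
    for (v in c("women", "age", CGA_COMPONENTS)) {
      rows[[v]] <- comparison_result(v, "degenerate", "", "", "", NA_real_,
                                     NA_real_, length(lo), length(hi),
                                     flag = "degenerate split")
    }
  }
  report <- comparisons_to_report(rows)
  attr(report, "threshold") <- threshold
  attr(report, "footer") <- "No multiple-testing correction applied."
  report
}

comparisons_to_report <- function(rows) {
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(variable = r$variable, kind = r$kind,
               overall = r$overall_summary, low = r$low_summary,
               high = r$high_summary, statistic = r$statistic,
               p_value = r$p_value, p_display = format_p(r$p_value),
               n_low = r$n_low, n_high = r$n_high, flag = r$flag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("iceberg_report", "data.frame")
  out
}

#' @export
print.iceberg_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 3)
  print.data.frame(df, row.names = FALSE)
  if (!is.null(attr(x, "footer"))) cat(attr(x, "footer"), "\n")
  invisible(x)
}
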