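# expand an aggregate 2x2 into a patient-level frame with an explicit class
counts_to_cohort <- function(ev_lo, n_lo, ev_hi, n_hi) {
  data.frame(
    risk_class = c(rep("low", n_lo), rep("high", n_hi)),
    y = c(rep(c(TRUE, FALSE), c(ev_lo, n_lo - ev_lo)),
          rep(c(TRUE, FALSE), c(ev_hi, n_hi - ev_hi)))
  )
}

test_that("contingency summaries reproduce the printed pilot-2 percentages", {
  cts <- pilot_counts("pilot2")
  grab <- function(v) {
    r <- cts[cts$variable == v, ]
    outcome_contingency(outcome = v,
                        counts = c(r$events_low, r$n_low, r$events_high, r$n_high))
  }
  nh <- grab("discharge_nh")
  expect_equal(nh$pct_low, 7.8); expect_equal(nh$pct_high, 26.4)
  expect_equal(round(nh$pct_overall), 18)
  rh <- grab("readmit_30d")
  expect_equal(rh$pct_low, 14.7); expect_equal(rh$pct_high, 16.4)
  mt <- grab("mortality")
  expect_equal(mt$pct_low, 3.1); expect_equal(mt$pct_high, 6.3)
  oo <- grab("one_on_one")
  expect_equal(oo$pct_overall, 10.4)
  expect_equal(round(oo$p_value, 3), 0.013)
})

test_that("contingency degenerate cases are flagged or rejected", {
  z <- outcome_contingency(outcome = "x", counts = c(0, 100, 0, 100))
  expect_equal(z$flag, "no events")
  expect_equal(z$pct_low, 0); expect_equal(z$pct_high, 0)
  expect_true(is.na(z$p_value))
  expect_error(outcome_contingency(outcome = "x", counts = c(0, 0, 5, 10)),
               "zero denominator")
})

test_that("exposure-only logistic OR equals the 2x2 cross-product ratio", {
  coh <- counts_to_cohort(7, 129, 23, 159)
  fit <- fit_outcome_model(coh, "y", covariates = NULL)
  expect_equal(fit$odds_ratio, (23 * 122) / (7 * 136), tolerance = 1e-6)
  expect_true(fit$converged)
  # property: ad/bc on random non-degenerate tables
  set.seed(14)
  for (i in 1:20) {
    cells <- rpois(4, 20) + 1
    coh <- counts_to_cohort(cells[1], cells[1] + cells[2],
                            cells[3], cells[3] + cells[4])
    fit <- fit_outcome_model(coh, "y", covariates = NULL)
    expect_equal(fit$odds_ratio, (cells[3] * cells[2]) / (cells[1] * cells[4]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate logistic fits refuse to report a spurious interval", {
  coh <- counts_to_cohort(5, 100, 5, 100)
  coh$y <- coh$risk_class == "high"      # perfect separation
  fit <- fit_outcome_model(coh, "y", covariates = NULL)
  expect_false(fit$converged)
  expect_true(is.na(fit$ci_low))
  coh$y <- FALSE
  expect_error(fit_outcome_model(coh, "y", covariates = NULL), "no events")
  coh$y <- TRUE
  expect_error(fit_outcome_model(coh, "y", covariates = NULL), "no non-events")
})

test_that("an irrelevant covariate leaves the OR essentially unchanged", {
  cfg <- cohort_config(n = 2000, seed = 17)
  coh <- generate_cohort(cfg)
  coh$noise <- rnorm(nrow(coh))
  f0 <- fit_outcome_model(coh, "one_on_one", covariates = NULL)
  f1 <- fit_outcome_model(coh, "one_on_one", covariates = "noise")
  expect_lt(abs(f1$log_or - f0$log_or), 3 * f0$se)
})

test_that("LOS and nursing-minute comparisons respect the availability mask", {
  cfg <- pilot_presets()$pilot2
  coh <- generate_cohort(cfg, seed = 23)
  res <- compare_los_and_nursing(coh)
  expect_s3_class(res$los_days, "iceberg_comparison")
  expect_equal(attr(res, "nursing_missing_frac"), mean(is.na(coh$nursing_minutes)))
  expect_lt(res$nursing_minutes$n_low + res$nursing_minutes$n_high, nrow(coh))
  coh$nursing_minutes <- NA_real_
  res2 <- compare_los_and_nursing(coh)
  expect_equal(res2$nursing_minutes$flag, "all nursing minutes missing")
  expect_false(is.na(res2$los_days$p_value))
})

test_that("feasibility summary reproduces enrollment arithmetic and distributions", {
  enr <- pilot_enrollment()
  f <- feasibility_summary(n_consented = enr$n_consented,
                           n_analyzed = enr$n_analyzed)
  expect_equal(f$participation_rate, 97)
  expect_error(feasibility_summary(n_consented = 100, n_analyzed = 101),
               "exceeds")
  # a constructed metadata table reproduces its difficulty fractions exactly
  n <- 1000
  coh <- data.frame(
    completion_minutes = rep(4.3, n),
    src_Q5 = rep("patient", n),
    diff_Q5 = rep(c("easy", "difficult", "not_assessable"),
                  times = c(902, 63, 35))
  )
  f2 <- feasibility_summary(coh, n_consented = n)
  expect_equal(unname(f2$difficulty_distribution$Q5),
               c(0.902, 0.063, 0.035))
  expect_equal(unname(f2$source_distribution$Q5), c(0, 1, 0, 0))
  for (d in f2$difficulty_distribution) expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_error(feasibility_summary(data.frame(completion_minutes = c(3, -1)),
                                   n_consented = 5), "positive")
})

test_that("the criterion report from the counts fixture shows the printed rows", {
  rep <- build_criterion_report(counts_fixture = pilot_counts("pilot2"))
  mrow <- rep$table[rep$table$variable == "mortality", ]
  expect_equal(mrow$low, "4 (3.1%)")
  expect_equal(mrow$high, "10 (6.3%)")
  nh <- rep$table[rep$table$variable == "discharge_nh", ]
  expect_equal(nh$low, "10 (7.8%)")
  expect_equal(nh$high, "42 (26.4%)")
})

test_that("the cohort-level criterion report is complete, pure and validated", {
  coh <- generate_cohort(pilot_presets()$pilot2)
  rep1 <- build_criterion_report(coh)
  expect_setequal(rep1$table$variable,
                  c("women", "age", "completion_minutes", "los_days",
                    "one_on_one", "readmit_30d", "mortality", "discharge_nh",
                    "nursing_minutes"))
  expect_equal(nrow(rep1$associations), 4)
  expect_identical(rep1$table, build_criterion_report(coh)$table)
  coh2 <- coh
  coh2$mortality <- NULL; coh2$readmit_30d <- NULL
  expect_error(build_criterion_report(coh2), "mortality.*readmit_30d|readmit_30d.*mortality")
})

test_that("the nursing-home denominator policy changes the denominator, not the events", {
  coh <- generate_cohort(pilot_presets()$pilot2, seed = 41)
  full <- outcome_contingency(coh, "discharge_nh", denominator_policy = "full_group")
  home <- outcome_contingency(coh, "discharge_nh",
                              denominator_policy = "admitted_from_home")
  expect_equal(sum(full$counts[, "event"]), sum(home$counts[, "event"]))
  expect_gt(sum(full$counts), sum(home$counts))
  expect_gte(home$pct_high, full$pct_high)
})
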