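test_that("packaged instrument matches the published tool definition", {
  instr <- load_instrument()
  expect_s3_class(instr, "iceberg_instrument")
  expect_equal(length(instr$items), 14)
  expect_equal(length(unique(vapply(instr$items, `[[`, character(1), "domain"))), 9)
  expect_equal(instr$threshold_default, 10L)
  expect_equal(unname(score_bounds(instr)), c(1L, 30L))
  # every option weight agrees with the hand-coded dictionary
  for (it in instr$items) {
    expect_equal(stats::setNames(it$options$weight, it$options$label),
                 ORACLE_WEIGHTS[[it$id]], info = it$id)
  }
  # only the age item is mandatory
  req <- vapply(instr$items, `[[`, logical(1), "required")
  ids <- vapply(instr$items, `[[`, character(1), "id")
  expect_equal(ids[req], "Q2")
})

test_that("malformed instrument configs are rejected with the item named", {
  raw <- raw_instrument_config()
  bad <- raw; bad$items[[3]]$options[[1]]$weight <- -1
  expect_error(as_instrument(bad), "Q3a.*non-negative", ignore.case = TRUE)
  dup <- raw; dup$items[[1]]$options[[2]]$label <- dup$items[[1]]$options[[1]]$label
  expect_error(as_instrument(dup), "Q1.*duplicate|duplicate.*Q1")
  one <- raw; one$items[[5]]$options <- one$items[[5]]$options[1]
  expect_error(as_instrument(one), "Q4a")
  twice <- raw; twice$items[[2]]$id <- "Q1"
  expect_error(as_instrument(twice), "duplicate item id")
})

test_that("removing items reduces the attainable range as the weights dictate", {
  raw <- raw_instrument_config()
  ids <- vapply(raw$items, `[[`, character(1), "id")
  no_q5 <- raw; no_q5$items <- raw$items[ids != "Q5"]
  instr5 <- as_instrument(no_q5)
  expect_equal(length(instr5$items), 13)
  expect_equal(unname(score_bounds(instr5)), c(1L, 27L))
  no_q2 <- raw; no_q2$items <- raw$items[ids != "Q2"]
  expect_equal(unname(score_bounds(as_instrument(no_q2))), c(0L, 28L))
})

test_that("worked response sets reproduce their hand-summed totals", {
  instr <- load_instrument()
  expect_equal(score_responses(min_responses(), instr)$total, 1L)
  expect_equal(score_responses(max_responses(), instr)$total, 30L)
  s <- score_responses(worked_responses(), instr)
  expect_equal(s$total, 16L)
  expect_equal(s$total, oracle_total(worked_responses()))
  expect_equal(s$risk_class, "high")
  expect_equal(s$n_missing, 0L)
})

test_that("risk classification puts the threshold tie in the high class", {
  expect_equal(classify(10, 10), "high")
  expect_equal(classify(9, 10), "low")
  expect_equal(classify(30, 10), "high")
  expect_error(classify(5, 0), "threshold")
  # consistency over the whole attainable range and every cut-point
  for (t in 1:30) {
    expect_equal(classify(1:30, t) == "high", 1:30 >= t, info = paste("t =", t))
  }
})

test_that("totals are additive, order-invariant and monotone in option weight", {
  instr <- load_instrument()
  set.seed(42)
  for (rep in 1:25) {
    r <- random_responses(instr)
    s <- score_responses(r, instr)
    expect_equal(s$total, oracle_total(r))
    shuffled <- r[sample(names(r))]
    expect_equal(score_responses(shuffled, instr)$total, s$total)
    # upgrading any one item to a heavier option never decreases the total
    it <- instr$items[[sample(14, 1)]]
    w_now <- ORACLE_WEIGHTS[[it$id]][[r[[it$id]]]]
    heavier <- it$options$label[it$options$weight >= w_now]
    r2 <- r; r2[[it$id]] <- sample(heavier, 1)
    expect_gte(score_responses(r2, instr)$total, s$total)
  }
})

test_that("exhaustive enumeration of a reduced instrument matches the sum oracle", {
  # Q1 and Q7 (3 options each) plus eight yes/no items: 3*3*2^8 = 2304 combos
  keep <- c("Q1", "Q7", "Q2", "Q3a", "Q4a", "Q5", "Q6a", "Q8a", "Q8b", "Q9a")
  raw <- raw_instrument_config()
  ids <- vapply(raw$items, `[[`, character(1), "id")
  raw$items <- raw$items[ids %in% keep]
  instr <- as_instrument(raw)
  grid <- expand.grid(lapply(instr$items, function(it) it$options$label),
                      stringsAsFactors = FALSE)
  names(grid) <- vapply(instr$items, `[[`, character(1), "id")
  expect_equal(nrow(grid), 2304)
  totals <- vapply(seq_len(nrow(grid)), function(i) {
    score_responses(unlist(grid[i, ]), instr)$total
  }, integer(1))
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    oracle_total(as.list(grid[i, ]))
  }, numeric(1))
  expect_equal(totals, as.integer(oracle))
  b <- score_bounds(instr)
  expect_equal(range(totals), unname(b))
})

test_that("missing responses follow the configured policy", {
  instr <- load_instrument()
  r <- worked_responses()
  r[["Q5"]] <- "not_assessable"
  r[["Q9b"]] <- NA
  s <- score_responses(r, instr, missing_policy = "zero")
  expect_equal(s$n_missing, 2L)
  expect_equal(s$total, 16L - 3L - 1L)  # the two items contribute nothing
  expect_error(score_responses(r, instr, missing_policy = "error"), "Q5, Q9b")
  ex <- score_responses(r, instr, missing_policy = "exclude_patient")
  expect_true(ex$excluded)
  expect_true(is.na(ex$total))
  # the age item is mandatory under every non-excluding policy
  r2 <- worked_responses(); r2[["Q2"]] <- NA
  expect_error(score_responses(r2, instr, missing_policy = "zero"), "required.*Q2")
  expect_true(score_responses(r2, instr, missing_policy = "exclude_patient")$excluded)
})

test_that("unknown labels and unknown item keys are rejected", {
  instr <- load_instrument()
  r <- worked_responses(); r[["Q7"]] <- "11_drugs"
  expect_error(score_responses(r, instr), "Q7.*11_drugs")
  r2 <- c(worked_responses(), QX = "yes")
  expect_error(score_responses(r2, instr), "QX")
})

test_that("cohort scoring equals per-patient scoring and enforces age >= 70", {
  instr <- load_instrument()
  set.seed(7)
  rows <- lapply(1:20, function(i) as.list(random_responses(instr)))
  cohort <- cbind(data.frame(patient_id = sprintf("P%02d", 1:20), age = 70 + 1:20),
                  do.call(rbind, lapply(rows, as.data.frame)))
  sc <- score_cohort(cohort, instr)
  per <- vapply(rows, function(r) score_responses(r, instr)$total, integer(1))
  expect_equal(sc$total, per)
  cohort$age[3] <- 65
  expect_error(score_cohort(cohort, instr), "younger than 70")
})

test_that("the cut-point can be re-derived as the floored cohort median", {
  expect_equal(median_threshold(c(9, 10, 11, 12)), 10L)
  expect_equal(median_threshold(c(7, 10, 16)), 10L)
  expect_error(median_threshold(NA_real_), "no non-missing")
  coh <- generate_cohort(pilot_presets()$pilot1)
  thr <- median_threshold(score_cohort(coh)$total)
  expect_true(thr >= 1 && thr <= 30)
})
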