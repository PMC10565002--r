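#' Load a scoring-instrument definition
#'
#' Reads a declarative questionnaire description (YAML: instrument name, a
#' default high/low cut-point, and an ordered list of items, each with a
#' geriatric domain, a prompt and weighted response options) and validates it.
#' The packaged default is the ICEBERG tool: 14 scoreable sub-items across
#' nine geriatric domains, attainable total 1 to 30, default cut-point 10.
#'
#' @param path Path to a YAML instrument definition. `NULL` (default) loads
#'   the packaged ICEBERG definition.
#' @return An object of class `iceberg_instrument`: a list with `name`,
#'   `threshold_default` and `items` (each item a list with `id`, `domain`,
#'   `prompt`, `required`, and an `options` data frame of `label`/`weight`).
#' @export
#' @examples
#' instr <- load_instrument()
#' instr$name
#' length(instr$items)
#' score_bounds(instr)
load_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "iceberg_instrument.yaml",
                        package = "icebergscreen", mustWork = TRUE)
  }
  if (!file.exists(path)) stop_iceberg("instrument file not found: %s", path)
  raw <- yaml::read_yaml(path)
  as_instrument(raw)
}

#' @rdname load_instrument
#' @param x A list parsed from an instrument config document.
#' @export
as_instrument <- function(x) {
  if (is.null(x$name) || !nzchar(x$name)) {
    stop_iceberg("instrument config must have a non-empty 'name'")
  }
  if (is.null(x$items) || length(x$items) == 0) {
    stop_iceberg("instrument '%s' defines no items", x$name)
  }
  items <- lapply(x$items, validate_item)
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_iceberg("duplicate item id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  thr <- x$threshold_default %||% NA_integer_
  if (!is.na(thr) && (thr != as.integer(thr) || thr < 1)) {
    stop_iceberg("threshold_default must be an integer >= 1, got %s", thr)
  }
  structure(
    list(name = x$name, threshold_default = as.integer(thr), items = items),
    class = "iceberg_instrument"
  )
}

validate_item <- function(item) {
  id <- item$id
  if (is.null(id) || !nzchar(id)) stop_iceberg("item without an id in config")
  opts <- item$options
  if (is.null(opts) || length(opts) < 2) {
    stop_iceberg("item %s: needs >= 2 response options", id)
  }
  labels <- vapply(opts, function(o) as.character(o$label), character(1))
  weights <- vapply(opts, function(o) as.numeric(o$weight), numeric(1))
  if (anyDuplicated(labels)) {
    stop_iceberg("item %s: duplicate option label(s)", id)
  }
  if (any(is.na(weights)) || any(weights < 0) || any(weights != as.integer(weights))) {
    stop_iceberg("item %s: option weights must be non-negative integers", id)
  }
  list(
    id = id,
    domain = item$domain %||% NA_character_,
    prompt = item$prompt %||% NA_character_,
    required = isTRUE(item$required),
    options = data.frame(label = labels, weight = as.integer(weights),
                         stringsAsFactors = FALSE)
  )
}

#' @export
print.iceberg_instrument <- function(x, ...) {
  b <- score_bounds(x)
  cat(sprintf("<instrument '%s': %d items over %d domains, score %d-%d, cut-point %d>\n",
              x$name, length(x$items),
              length(unique(vapply(x$items, `[[`, character(1), "domain"))),
              b[["min"]], b[["max"]], x$threshold_default))
  invisible(x)
}

item_ids <- function(instrument) {
  vapply(instrument$items, `[[`, character(1), "id")
}

#' Attainable score range of an instrument
#'
#' Reduces each item to its minimum and maximum option weight and sums them.
#' For the full ICEBERG tool this is (1, 30): every other item has a
#' zero-weight option, but the age item always contributes at least 1 point
#' for a patient aged 70 or more.
#'
#' @param instrument An `iceberg_instrument`.
#' @return Named integer vector `c(min = , max = )`.
#' @export
score_bounds <- function(instrument) {
  stopifnot(inherits(instrument, "iceberg_instrument"))
  mins <- vapply(instrument$items, function(it) min(it$options$weight), integer(1))
  maxs <- vapply(instrument$items, function(it) max(it$options$weight), integer(1))
  c(min = sum(mins), max = sum(maxs))
}

#' Classify a total score as high or low risk
#'
#' A total at or above the cut-point is `"high"`, below it `"low"`; the tie
#' at the threshold goes to high, mirroring the instrument's ">= 10" rule.
#'
#' @param total Integer vector of total scores.
#' @param threshold Integer cut-point, >= 1.
#' @return Character vector of `"high"` / `"low"` (NA totals stay NA).
#' @export
#' @examples
#' classify(c(9, 10, 30), 10)
classify <- function(total, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1) {
    stop_iceberg("threshold must be a single integer >= 1")
  }
  ifelse(is.na(total), NA_character_, ifelse(total >= threshold, "high", "low"))
}

#' Recompute the high/low cut-point from a scored cohort
#'
#' The instrument's default cut-point is the pooled-cohort median of the pilot
#' scores. For a new cohort the same rule can be re-derived: the interpolated
#' median of the totals, floored to an integer.
#'
#' @param totals Integer vector of total scores.
#' @return Integer threshold.
#' @export
median_threshold <- function(totals) {
  totals <- totals[!is.na(totals)]
  if (length(totals) == 0) stop_iceberg("no non-missing totals to take a median of")
  as.integer(floor(stats::median(totals)))
}

MISSING_LABELS <- c("missing", "unassessable", "not_assessable", "")

#' Score one patient's responses
#'
#' Sums the weights of the selected options. Missing or unassessable answers
#' are handled per `missing_policy`:
#' \describe{
#'   \item{`zero`}{(default) the item contributes 0 points and is counted in
#'     `n_missing` — conservative: missingness never adds risk points.}
#'   \item{`error`}{any missing item aborts with an error naming the items.}
#'   \item{`exclude_patient`}{returns a sentinel result with `excluded = TRUE`
#'     and `NA` total.}
#' }
#' A missing \emph{required} item (the age item Q2 in ICEBERG) is an error
#' under both `zero` and `error`, because the instrument is undefined without
#' it; under `exclude_patient` the patient is excluded.
#'
#' @param responses Named character vector or list mapping item id to the
#'   selected option label (`NA`, `""`, `"missing"`, `"unassessable"` and
#'   `"not_assessable"` mark unanswered items).
#' @param instrument An `iceberg_instrument`.
#' @param missing_policy One of `"zero"`, `"error"`, `"exclude_patient"`.
#' @param threshold Cut-point for risk classification; default the
#'   instrument's `threshold_default`.
#' @param patient_id Optional identifier carried into the result.
#' @return A list of class `iceberg_score`: `patient_id`, `total`,
#'   `risk_class`, `n_missing`, `threshold_used`, `excluded`.
#' @export
#' @examples
#' instr <- load_instrument()
#' r <- c(Q1 = "home_with_support", Q2 = "80_plus", Q3a = "no", Q3b = "no",
#'        Q4a = "yes", Q4b = "no", Q5 = "no", Q6a = "no", Q6b = "yes",
#'        Q7 = "4-7_drugs", Q8a = "yes", Q8b = "yes", Q9a = "no", Q9b = "yes")
#' score_responses(r, instr)$total # 16
score_responses <- function(responses, instrument,
                            missing_policy = c("zero", "error", "exclude_patient"),
                            threshold = NULL, patient_id = NA_character_) {
  stopifnot(inherits(instrument, "iceberg_instrument"))
  missing_policy <- match.arg(missing_policy)
  threshold <- threshold %||% instrument$threshold_default
  responses <- unlist(responses)
  ids <- item_ids(instrument)
  unknown <- setdiff(names(responses), ids)
  if (length(unknown) > 0) {
    stop_iceberg("response keys not in instrument '%s': %s",
                 instrument$name, paste(unknown, collapse = ", "))
  }

  total <- 0L
  missing_items <- character(0)
  required_missing <- character(0)
  for (it in instrument$items) {
    lab <- if (it$id %in% names(responses)) as.character(responses[[it$id]]) else NA_character_
    if (is.na(lab) || lab %in% MISSING_LABELS) {
      missing_items <- c(missing_items, it$id)
      if (it$required) required_missing <- c(required_missing, it$id)
      next
    }
    w <- it$options$weight[match(lab, it$options$label)]
    if (is.na(w)) {
      stop_iceberg("item %s: unknown option label '%s' (expected one of: %s)",
                   it$id, lab, paste(it$options$label, collapse = ", "))
    }
    total <- total + w
  }

  if (missing_policy == "exclude_patient" && length(missing_items) > 0) {
    return(structure(list(patient_id = patient_id, total = NA_integer_,
                          risk_class = NA_character_,
                          n_missing = length(missing_items),
                          threshold_used = as.integer(threshold),
                          excluded = TRUE),
                     class = "iceberg_score"))
  }
  if (missing_policy == "error" && length(missing_items) > 0) {
    stop_iceberg("missing response(s) for item(s): %s",
                 paste(missing_items, collapse = ", "))
  }
  if (length(required_missing) > 0) {
    stop_iceberg("required item(s) unanswered: %s",
                 paste(required_missing, collapse = ", "))
  }
  structure(list(patient_id = patient_id, total = as.integer(total),
                 risk_class = classify(total, threshold),
                 n_missing = length(missing_items),
                 threshold_used = as.integer(threshold),
                 excluded = FALSE),
            class = "iceberg_score")
}

#' @export
print.iceberg_score <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<score %s: excluded (%d missing items)>\n",
                x$patient_id, x$n_missing))
  } else {
    cat(sprintf("<score %s: total %d, %s risk (cut %d), %d missing>\n",
                x$patient_id, x$total, x$risk_class, x$threshold_used, x$n_missing))
  }
  invisible(x)
}

#' Score every patient in a cohort table
#'
#' Vectorized scoring over a cohort data frame whose item columns are named by
#' item id (Q1 ... Q9b for ICEBERG). If an `age` column is present it must be
#' >= 70 for every row — the instrument is undefined below its target
#' population and refuses to extrapolate the age item.
#'
#' @param cohort Data frame with one row per patient; must contain a
#'   `patient_id` column and one column per instrument item.
#' @inheritParams score_responses
#' @return Data frame with columns `patient_id`, `total`, `risk_class`,
#'   `n_missing`, `threshold_used`, `excluded`.
#' @export
score_cohort <- function(cohort, instrument = load_instrument(),
                         missing_policy = c("zero", "error", "exclude_patient"),
                         threshold = NULL) {
  missing_policy <- match.arg(missing_policy)
  threshold <- threshold %||% instrument$threshold_default
  ids <- item_ids(instrument)
  absent <- setdiff(ids, names(cohort))
  if (length(absent) > 0) {
    stop_iceberg("cohort lacks item column(s): %s", paste(absent, collapse = ", "))
  }
  if ("age" %in% names(cohort) && any(cohort$age < 70, na.rm = TRUE)) {
    stop_iceberg("cohort contains %d patient(s) younger than 70; the instrument is defined for age >= 70 only",
                 sum(cohort$age < 70, na.rm = TRUE))
  }
  pid <- if ("patient_id" %in% names(cohort)) as.character(cohort$patient_id)
         else sprintf("P%04d", seq_len(nrow(cohort)))

  n <- nrow(cohort)
  total <- integer(n)
  n_missing <- integer(n)
  required_missing <- logical(n)
  for (it in instrument$items) {
    lab <- as.character(cohort[[it$id]])
    miss <- is.na(lab) | lab %in% MISSING_LABELS
    idx <- match(lab, it$options$label)
    bad <- !miss & is.na(idx)
    if (any(bad)) {
      stop_iceberg("item %s: unknown option label '%s' (patient %s)",
                   it$id, lab[which(bad)[1]], pid[which(bad)[1]])
    }
    w <- it$options$weight[idx]
    w[miss] <- 0L
    total <- total + w
    n_missing <- n_missing + miss
    if (it$required) required_missing <- required_missing | miss
  }

  excluded <- rep(FALSE, n)
  if (missing_policy == "exclude_patient") {
    excluded <- n_missing > 0
  } else if (missing_policy == "error" && any(n_missing > 0)) {
    stop_iceberg("%d patient(s) have missing responses (first: %s)",
                 sum(n_missing > 0), pid[which(n_missing > 0)[1]])
  } else if (any(required_missing)) {
    stop_iceberg("required item unanswered for patient(s): %s",
                 paste(utils::head(pid[required_missing], 5), collapse = ", "))
  }
  total[excluded] <- NA_integer_
  data.frame(patient_id = pid, total = total,
             risk_class = classify(total, threshold),
             n_missing = n_missing, threshold_used = as.integer(threshold),
             excluded = excluded, stringsAsFactors = FALSE)
}
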