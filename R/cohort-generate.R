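#' Generate a synthetic patient cohort
#'
#' Draws a cohort of ER patients aged 70+ from the latent-frailty model
#' described in [cohort_config()]. Per patient: frailty F ~ N(0,1); age
#' jointly normal with F (truncated below at 70 by re-drawing the age-specific
#' noise); questionnaire responses from cumulative-logit models in F (the age
#' item is derived from age); CGA component scores linear in F with Gaussian
#' noise, rounded where integer-valued and clipped to the instrument range;
#' in-hospital mortality, one-on-one care, 30-day readmission and
#' nursing-home discharge Bernoulli with logit linear in F and age; length of
#' stay and nursing minutes lognormal with log-scale mean linear in F.
#'
#' Logical consistency is enforced: decedents can neither be readmitted nor
#' discharged to a nursing home, and nursing-home discharge is generated only
#' for patients admitted from home (i.e. not already living in a nursing
#' home). Output is byte-identical for identical (config, seed).
#'
#' @param config An `iceberg_cohort_config`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A data frame of class `iceberg_cohort`, one row per patient, with
#'   demographics, `latent_frailty` (kept for recovery tests), item response
#'   columns `Q1 ... Q9b`, feasibility metadata `src_*` / `diff_*`, CGA
#'   component columns, and outcome columns (`los_days`, `nursing_minutes`,
#'   `one_on_one`, `mortality`, `readmit_30d`, `discharge_nh`,
#'   `admitted_from_home`, `completion_minutes`).
#' @export
#' @examples
#' cfg <- pilot_presets()$pilot2
#' coh <- generate_cohort(cfg)
#' mean(coh$age)
#' table(score_cohort(coh)$risk_class)
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "iceberg_cohort_config"))
  seed <- seed %||% config$seed
  set.seed(seed)
  n <- config$n
  calib <- config$calib

  frailty <- stats::rnorm(n)
  sex <- ifelse(stats::runif(n) < config$prop_women, "female", "male")

  # age | F, truncated at 70 by re-drawing the independent noise component
  rho <- config$age_frailty_cor
  age <- config$age_mean + config$age_sd *
    (rho * frailty + sqrt(1 - rho^2) * stats::rnorm(n))
  for (i in 1:50) {
    low <- age < 70
    if (!any(low)) break
    age[low] <- config$age_mean + config$age_sd *
      (rho * frailty[low] + sqrt(1 - rho^2) * stats::rnorm(sum(low)))
  }
  age <- round(pmax(age, 70), 1)

  # item responses
  resp <- list(Q2 = ifelse(age >= 80, "80_plus", "70-79"))
  for (id in names(calib$item_cut)) {
    ic <- calib$item_cut[[id]]
    u <- stats::runif(n)
    cat_idx <- rep(1L, n)
    for (k in seq_along(ic$cuts)) {
      cat_idx <- cat_idx + (u < stats::plogis(ic$cuts[k] + ic$loading * frailty))
    }
    resp[[id]] <- ic$labels[cat_idx]
  }

  # feasibility metadata; a not_assessable draw blanks the response
  src <- list(); dif <- list()
  for (id in names(config$source_probs)) {
    sp <- config$source_probs[[id]]
    src[[paste0("src_", id)]] <- sample(names(sp), n, replace = TRUE, prob = sp)
    dp <- config$difficulty_probs[[id]]
    d <- sample(names(dp), n, replace = TRUE, prob = dp)
    dif[[paste0("diff_", id)]] <- d
    if (id %in% names(resp)) resp[[id]][d == "not_assessable"] <- NA_character_
  }

  # CGA components
  cga <- list()
  for (comp in names(config$cga_params)) {
    p <- config$cga_params[[comp]]
    v <- p$intercept + p$slope * frailty + stats::rnorm(n, 0, p$sd)
    if (isTRUE(p$integer)) v <- round_half_up(v, 0)
    rng <- CGA_RANGES[[comp]]
    cga[[comp]] <- pmin(pmax(v, rng[1]), rng[2])
  }

  # exposure indicator (only drawn into outcomes when a config asks for it)
  op <- config$outcome_params
  needs_exposure <- any(vapply(BINARY_OUTCOMES, function(oc) {
    !is.null(op[[oc]]) && op[[oc]]$exposure_log_or != 0
  }, logical(1)))
  high <- if (needs_exposure) {
    instr <- load_instrument()
    item_df <- as.data.frame(resp[item_ids(instr)], optional = TRUE,
                             stringsAsFactors = FALSE)
    names(item_df) <- item_ids(instr)
    totals <- score_cohort(cbind(patient_id = seq_len(n), item_df),
                           instr, missing_policy = "zero",
                           threshold = config$threshold)$total
    as.numeric(totals >= config$threshold)
  } else rep(0, n)

  age_c <- age - 80
  draw_binary <- function(oc, keep = rep(TRUE, n)) {
    p <- op[[oc]]
    eta <- calib$outcome_intercept[[oc]] + p$slope_f * frailty +
      p$slope_age * age_c + p$exposure_log_or * high
    out <- stats::runif(n) < stats::plogis(eta)
    out & keep
  }

  mortality <- draw_binary("mortality")
  one_on_one <- draw_binary("one_on_one")
  readmit_30d <- draw_binary("readmit_30d", keep = !mortality)
  admitted_from_home <- is.na(resp$Q1) | resp$Q1 != "nursing_home"
  discharge_nh <- draw_binary("discharge_nh", keep = !mortality & admitted_from_home)

  pl <- op$los_days
  los_days <- pmax(1, round_half_up(
    exp(stats::rnorm(n, pl$log_median + pl$slope_f * frailty, pl$sdlog)), 0))
  pn <- op$nursing_minutes
  nursing_minutes <- exp(stats::rnorm(n, pn$log_median + pn$slope_f * frailty,
                                      pn$sdlog))
  if (config$nursing_missing_frac > 0) {
    nursing_minutes[stats::runif(n) < config$nursing_missing_frac] <- NA_real_
  }
  completion_minutes <- pmax(0.5, stats::rnorm(n, config$completion_mean,
                                               config$completion_sd))

  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex,
    latent_frailty = round(frailty, 6),
    stringsAsFactors = FALSE
  )
  item_order <- c("Q1", "Q2", "Q3a", "Q3b", "Q4a", "Q4b", "Q5", "Q6a", "Q6b",
                  "Q7", "Q8a", "Q8b", "Q9a", "Q9b")
  for (id in item_order) out[[id]] <- resp[[id]]
  for (nm in names(src)) out[[nm]] <- src[[nm]]
  for (nm in names(dif)) out[[nm]] <- dif[[nm]]
  for (nm in names(cga)) out[[nm]] <- cga[[nm]]
  out$los_days <- as.integer(los_days)
  out$nursing_minutes <- round(nursing_minutes, 1)
  out$one_on_one <- one_on_one
  out$mortality <- mortality
  out$readmit_30d <- readmit_30d
  out$discharge_nh <- discharge_nh
  out$admitted_from_home <- admitted_from_home
  out$completion_minutes <- round(completion_minutes, 2)
  attr(out, "seed") <- seed
  attr(out, "threshold") <- config$threshold
  class(out) <- c("iceberg_cohort", "data.frame")
  out
}
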