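# Cohort generator configuration and marginal calibration.
#
# Generative model: one latent frailty axis F ~ N(0,1) per patient drives
# item responses (cumulative logits over weight-ordered options), CGA
# component scores (linear + Gaussian noise, clipped to the instrument range),
# and acute-care outcomes (logistic in F and age for binary outcomes,
# lognormal in F for length of stay and nursing minutes). Intercepts are
# calibrated so the configured *marginal* rates hold after integrating F out;
# the calibration is deterministic (quadrature + root finding), not simulated.

CGA_RANGES <- list(
  spi           = c(0, 40),
  barthel       = c(0, 100),
  mmse          = c(0, 30),
  mna           = c(0, 30),
  grip_right    = c(0, Inf),
  grip_left     = c(0, Inf),
  sppb          = c(0, 12),
  clock         = c(0, 7),
  frailty_fried = c(0, 5),
  frailty_share = c(0, 5)
)

BINARY_OUTCOMES <- c("mortality", "one_on_one", "readmit_30d", "discharge_nh")

# E[age - 80 | F = z] under the truncated-at-70 conditional age model
age_cond_mean <- function(z, age_mean, age_sd, rho) {
  m <- age_mean + age_sd * rho * z
  s <- age_sd * sqrt(1 - rho^2)
  a <- (70 - m) / s
  m + s * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE) - 80
}

# marginal E[ weight(z) * plogis(a + slope_f z + extra(z)) ] over z ~ N(0,1)
logit_marginal <- function(a, slope_f, extra = NULL, weight = NULL) {
  f <- function(z) {
    eta <- a + slope_f * z + (if (is.null(extra)) 0 else extra(z))
    w <- if (is.null(weight)) 1 else weight(z)
    stats::dnorm(z) * w * stats::plogis(eta)
  }
  stats::integrate(f, -8, 8, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

# intercept a such that logit_marginal(a, ...) == target
calibrate_intercept <- function(target, slope_f, extra = NULL, weight = NULL) {
  wmass <- if (is.null(weight)) 1 else
    stats::integrate(function(z) stats::dnorm(z) * weight(z), -8, 8,
                     rel.tol = 1e-9)$value
  if (target <= 0 || target >= wmass) {
    stop_iceberg("cannot calibrate: target rate %.4f outside attainable (0, %.4f)",
                 target, wmass)
  }
  stats::uniroot(function(a) logit_marginal(a, slope_f, extra, weight) - target,
                 lower = -25, upper = 25, tol = 1e-9)$root
}

default_item_params <- function() {
  list(
    Q1  = list(loading = 1.0, probs = c(independent_at_home = 0.45,
                                        home_with_support = 0.40,
                                        nursing_home = 0.15)),
    Q3a = list(loading = 0.9, probs = c(no = 0.65, yes = 0.35)),
    Q3b = list(loading = 0.5, probs = c(no = 0.75, yes = 0.25)),
    Q4a = list(loading = 1.2, probs = c(no = 0.70, yes = 0.30)),
    Q4b = list(loading = 0.7, probs = c(no = 0.60, yes = 0.40)),
    Q5  = list(loading = 1.2, probs = c(yes = 0.60, no = 0.40)),
    Q6a = list(loading = 0.5, probs = c(no = 0.70, yes = 0.30)),
    Q6b = list(loading = 0.6, probs = c(no = 0.70, yes = 0.30)),
    Q7  = list(loading = 0.6, probs = c(`0-3_drugs` = 0.25,
                                        `4-7_drugs` = 0.45,
                                        `8_plus_drugs` = 0.30)),
    Q8a = list(loading = 1.2, probs = c(no = 0.60, yes = 0.40)),
    Q8b = list(loading = 1.0, probs = c(yes = 0.75, no = 0.25)),
    Q9a = list(loading = 0.8, probs = c(no = 0.70, yes = 0.30)),
    Q9b = list(loading = 0.8, probs = c(no = 0.65, yes = 0.35))
  )
}

default_cga_params <- function() {
  list(
    spi           = list(intercept = 30,   slope = -0.8, sd = 4.5, integer = TRUE),
    barthel       = list(intercept = 52,   slope = -15,  sd = 14,  integer = TRUE),
    mmse          = list(intercept = 25,   slope = -2.5, sd = 2.5, integer = TRUE),
    mna           = list(intercept = 20.5, slope = -1.6, sd = 2.0, integer = FALSE),
    grip_right    = list(intercept = 40,   slope = -6,   sd = 9,   integer = TRUE),
    grip_left     = list(intercept = 38.5, slope = -6,   sd = 9,   integer = TRUE),
    sppb          = list(intercept = 4,    slope = -1.8, sd = 1.8, integer = TRUE),
    clock         = list(intercept = 5,    slope = -1.5, sd = 1.3, integer = TRUE),
    frailty_fried = list(intercept = 2.7,  slope = 1.0,  sd = 0.9, integer = TRUE),
    frailty_share = list(intercept = 2.1,  slope = 1.1,  sd = 1.0, integer = TRUE)
  )
}

default_outcome_params <- function() {
  list(
    mortality    = list(rate = 0.049, slope_f = 0.55, slope_age = 0.04,
                        exposure_log_or = 0),
    one_on_one   = list(rate = 0.104, slope_f = 0.80, slope_age = 0.01,
                        exposure_log_or = 0),
    readmit_30d  = list(rate = 0.156, slope_f = 0.10, slope_age = 0.00,
                        exposure_log_or = 0),
    discharge_nh = list(rate = 0.180, slope_f = 1.80, slope_age = 0.03,
                        exposure_log_or = 0),
    los_days        = list(log_median = log(7),    slope_f = 0.12, sdlog = 0.80),
    nursing_minutes = list(log_median = log(1607), slope_f = 0.30, sdlog = 0.85)
  )
}

default_source_probs <- function() {
  record_based <- c(record = 0.85, patient = 0.10, proxy = 0.04, other = 0.01)
  patient_based <- c(record = 0.05, patient = 0.80, proxy = 0.12, other = 0.03)
  ids <- c("Q1", "Q2", "Q3a", "Q3b", "Q4a", "Q4b", "Q5", "Q6a", "Q6b",
           "Q7", "Q8a", "Q8b", "Q9a", "Q9b")
  out <- stats::setNames(rep(list(patient_based), length(ids)), ids)
  for (id in c("Q1", "Q2", "Q3b", "Q7")) out[[id]] <- record_based
  out
}

default_difficulty_probs <- function() {
  ids <- names(default_source_probs())
  stats::setNames(rep(list(c(easy = 1, difficult = 0, not_assessable = 0)),
                      length(ids)), ids)
}

#' Build a synthetic-cohort configuration
#'
#' Assembles and validates the full set of generator parameters and performs
#' the (deterministic) intercept calibration for items and binary outcomes.
#' Defaults reflect the criterion-validity pilot: n = 288 patients aged 70+
#' (mean 81.5, SD 7.0), 51% women, outcome rates matching the published
#' marginals (one-on-one care 10.4%, in-hospital mortality 4.9%, 30-day
#' readmission 15.6%, nursing-home discharge 18%), median length of stay
#' 7 days and median nursing workload about 1,600 minutes.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; generation is byte-reproducible given (config, seed).
#' @param age_mean,age_sd Mean/SD (years) of the untruncated age distribution;
#'   ages are re-drawn below 70, which shifts the realized mean up slightly.
#' @param age_frailty_cor Correlation between age and the latent frailty axis.
#' @param prop_women Fraction of women (sex is independent of frailty).
#' @param item_params Named list per item id: `loading` (logit slope on
#'   frailty) and `probs` (target marginal option probabilities, named by
#'   option label). The age item Q2 is derived from age and takes no entry.
#' @param cga_params Named list per CGA component: `intercept`, `slope`
#'   (per SD of frailty), `sd` (residual noise), `integer` flag. Admissible
#'   ranges are fixed by the instruments themselves (Barthel 0-100, SPI 0-40,
#'   MMSE 0-30, MNA 0-30, clock 0-7, SPPB 0-12, both frailty indices 0-5,
#'   grip >= 0).
#' @param outcome_params Named list: binary outcomes take `rate` (target
#'   marginal) or a direct `intercept`, plus `slope_f`, `slope_age` (per year
#'   of age minus 80) and `exposure_log_or` (an optional additive log-odds
#'   term for the high-risk class, used in parameter-recovery studies);
#'   `los_days` and `nursing_minutes` take `log_median`, `slope_f`, `sdlog`.
#' @param threshold High/low cut-point used for the exposure term.
#' @param nursing_missing_frac Fraction of patients with nursing minutes
#'   missing at random (site-level availability mask).
#' @param source_probs,difficulty_probs Per-item categorical distributions for
#'   the feasibility metadata (information source; reported difficulty). A
#'   `not_assessable` difficulty draw blanks the item response.
#' @param completion_mean,completion_sd Mean/SD (minutes) of questionnaire
#'   completion time.
#' @return An object of class `iceberg_cohort_config`.
#' @seealso [generate_cohort()], [pilot_presets()], [null_config()]
#' @export
cohort_config <- function(n = 288, seed = 1L,
                          age_mean = 81.5, age_sd = 7.0,
                          age_frailty_cor = 0.25, prop_women = 0.51,
                          item_params = default_item_params(),
                          cga_params = default_cga_params(),
                          outcome_params = default_outcome_params(),
                          threshold = 10L,
                          nursing_missing_frac = 0,
                          source_probs = default_source_probs(),
                          difficulty_probs = default_difficulty_probs(),
                          completion_mean = 4.3, completion_sd = 1.3) {
  if (n < 1) stop_iceberg("cohort size n must be >= 1")
  if (prop_women < 0 || prop_women > 1) stop_iceberg("prop_women must be in [0, 1]")
  if (age_sd <= 0 || completion_sd <= 0) stop_iceberg("scale parameters must be > 0")
  if (abs(age_frailty_cor) >= 1) stop_iceberg("age_frailty_cor must be in (-1, 1)")
  if (nursing_missing_frac < 0 || nursing_missing_frac > 1) {
    stop_iceberg("nursing_missing_frac must be in [0, 1]")
  }
  for (comp in names(cga_params)) {
    p <- cga_params[[comp]]
    if (is.null(CGA_RANGES[[comp]])) {
      stop_iceberg("unknown CGA component '%s'", comp)
    }
    if (p$sd <= 0) stop_iceberg("cga component %s: noise sd must be > 0", comp)
  }
  for (id in names(item_params)) {
    pr <- item_params[[id]]$probs
    if (abs(sum(pr) - 1) > 1e-8) {
      stop_iceberg("item %s: marginal option probabilities must sum to 1", id)
    }
  }

  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed),
         age_mean = age_mean, age_sd = age_sd,
         age_frailty_cor = age_frailty_cor, prop_women = prop_women,
         item_params = item_params, cga_params = cga_params,
         outcome_params = outcome_params, threshold = as.integer(threshold),
         nursing_missing_frac = nursing_missing_frac,
         source_probs = source_probs, difficulty_probs = difficulty_probs,
         completion_mean = completion_mean, completion_sd = completion_sd),
    class = "iceberg_cohort_config"
  )
  cfg$calib <- calibrate_config(cfg)
  cfg
}

# Calibrate all intercepts once, so repeated generation is cheap.
calibrate_config <- function(cfg) {
  instr <- load_instrument()
  item_cut <- list()
  for (id in names(cfg$item_params)) {
    idx <- match(id, item_ids(instr))
    if (is.na(idx)) stop_iceberg("item_params names unknown item '%s'", id)
    it <- instr$items[[idx]]
    p <- cfg$item_params[[id]]
    ord <- order(it$options$weight)              # weight-ascending severity order
    labs <- it$options$label[ord]
    pr <- p$probs[labs]
    if (anyNA(pr)) {
      stop_iceberg("item %s: probs must be named by its option labels (%s)",
                   id, paste(labs, collapse = ", "))
    }
    # cumulative logits: P(category >= k) for k = 2..K, intercepts decreasing
    tail_p <- rev(cumsum(rev(pr)))[-1]
    cuts <- vapply(tail_p, function(tp) calibrate_intercept(tp, p$loading),
                   numeric(1))
    item_cut[[id]] <- list(labels = labs, cuts = cuts, loading = p$loading)
  }

  extra_age <- function(slope_age) {
    force(slope_age)
    function(z) slope_age * age_cond_mean(z, cfg$age_mean, cfg$age_sd,
                                          cfg$age_frailty_cor)
  }
  op <- cfg$outcome_params
  out_int <- list()

  surv_prob <- function(z) 1  # replaced after mortality is calibrated
  p_home <- function(z) {
    q1 <- item_cut[["Q1"]]
    if (is.null(q1)) return(rep(1, length(z)))
    k <- match("nursing_home", q1$labels) - 1L
    1 - stats::plogis(q1$cuts[k] + q1$loading * z)
  }

  for (oc in BINARY_OUTCOMES) {
    p <- op[[oc]]
    if (is.null(p)) next
    if (!is.null(p$intercept)) {
      out_int[[oc]] <- p$intercept
    } else {
      if (p$exposure_log_or != 0) {
        stop_iceberg("outcome %s: rate-based calibration is unsupported with a nonzero exposure_log_or; give 'intercept' directly", oc)
      }
      weight <- switch(oc,
        readmit_30d  = surv_prob,
        discharge_nh = function(z) surv_prob(z) * p_home(z),
        NULL)
      out_int[[oc]] <- calibrate_intercept(p$rate, p$slope_f,
                                           extra = extra_age(p$slope_age),
                                           weight = weight)
    }
    if (oc == "mortality") {
      am <- out_int[["mortality"]]
      pm <- op[["mortality"]]
      ex <- extra_age(pm$slope_age)
      surv_prob <- function(z) 1 - stats::plogis(am + pm$slope_f * z + ex(z))
    }
  }
  list(item_cut = item_cut, outcome_intercept = out_int)
}

#' @export
print.iceberg_cohort_config <- function(x, ...) {
  cat(sprintf("<cohort config: n=%d, seed=%d, age %.1f (%.1f), %.0f%% women, cut-point %d>\n",
              x$n, x$seed, x$age_mean, x$age_sd, 100 * x$prop_women, x$threshold))
  invisible(x)
}

#' Preset configurations emulating the two validation pilots
#'
#' `pilot1` emulates the construct-validity cohort (n = 129, mean age 82.9,
#' SD 6.7, 64.3% women); `pilot2` the criterion-validity cohort (n = 288,
#' mean age 81.5, SD 7.0, 51% women), including the site-level nursing-minute
#' availability mask (one of three hospitals, about 24% of patients, did not
#' export workload minutes) and the delirium item's reported difficulty
#' profile (6.3% difficult, 3.5% not assessable). Item, CGA and outcome
#' parameters are the package defaults, calibrated to the published marginals.
#'
#' @return Named list of two `iceberg_cohort_config` objects.
#' @export
pilot_presets <- function() {
  dp <- default_difficulty_probs()
  dp[["Q5"]] <- c(easy = 0.902, difficult = 0.063, not_assessable = 0.035)
  list(
    pilot1 = cohort_config(n = 129, seed = 101L, age_mean = 82.9, age_sd = 6.7,
                           prop_women = 0.643),
    pilot2 = cohort_config(n = 288, seed = 202L, age_mean = 81.5, age_sd = 7.0,
                           prop_women = 0.51, nursing_missing_frac = 68 / 288,
                           difficulty_probs = dp)
  )
}

#' Null configuration: no frailty structure
#'
#' All item loadings, CGA slopes and outcome slopes set to zero and age made
#' independent of frailty, so the score is independent of every CGA component
#' and outcome (the age item still tracks age by construction). Used for
#' type-I-error calibration of the comparison tests.
#'
#' @inheritParams cohort_config
#' @return An `iceberg_cohort_config`.
#' @export
null_config <- function(n = 100, seed = 1L) {
  ip <- default_item_params()
  for (id in names(ip)) ip[[id]]$loading <- 0
  cp <- default_cga_params()
  for (id in names(cp)) cp[[id]]$slope <- 0
  op <- default_outcome_params()
  for (id in names(op)) op[[id]]$slope_f <- 0
  for (id in BINARY_OUTCOMES) op[[id]]$slope_age <- 0
  cohort_config(n = n, seed = seed, age_frailty_cor = 0,
                item_params = ip, cga_params = cp, outcome_params = op)
}
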