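# Shared fixtures built in code: canonical response sets and an
# independently hand-coded weight dictionary used as the scoring oracle.

# weight of every option, transcribed by hand (independent of the YAML config)
ORACLE_WEIGHTS <- list(
  Q1  = c(independent_at_home = 0, home_with_support = 2, nursing_home = 3),
  Q2  = c(`70-79` = 1, `80_plus` = 2),
  Q3a = c(yes = 3, no = 0),
  Q3b = c(yes = 1, no = 0),
  Q4a = c(yes = 3, no = 0),
  Q4b = c(yes = 2, no = 0),
  Q5  = c(yes = 0, no = 3),
  Q6a = c(yes = 2, no = 0),
  Q6b = c(yes = 2, no = 0),
  Q7  = c(`0-3_drugs` = 0, `4-7_drugs` = 1, `8_plus_drugs` = 2),
  Q8a = c(yes = 2, no = 0),
  Q8b = c(yes = 0, no = 2),
  Q9a = c(yes = 2, no = 0),
  Q9b = c(yes = 1, no = 0)
)

oracle_total <- function(responses) {
  sum(vapply(names(responses), function(id) {
    ORACLE_WEIGHTS[[id]][[responses[[id]]]]
  }, numeric(1)))
}

min_responses <- function() {
  c(Q1 = "independent_at_home", Q2 = "70-79", Q3a = "no", Q3b = "no",
    Q4a = "no", Q4b = "no", Q5 = "yes", Q6a = "no", Q6b = "no",
    Q7 = "0-3_drugs", Q8a = "no", Q8b = "yes", Q9a = "no", Q9b = "no")
}

max_responses <- function() {
  c(Q1 = "nursing_home", Q2 = "80_plus", Q3a = "yes", Q3b = "yes",
    Q4a = "yes", Q4b = "yes", Q5 = "no", Q6a = "yes", Q6b = "yes",
    Q7 = "8_plus_drugs", Q8a = "yes", Q8b = "no", Q9a = "yes", Q9b = "yes")
}

worked_responses <- function() {
  c(Q1 = "home_with_support", Q2 = "80_plus", Q3a = "no", Q3b = "no",
    Q4a = "yes", Q4b = "no", Q5 = "no", Q6a = "no", Q6b = "yes",
    Q7 = "4-7_drugs", Q8a = "yes", Q8b = "yes", Q9a = "no", Q9b = "yes")
}

# raw (list-form) instrument config for programmatic modification
raw_instrument_config <- function() {
  yaml::read_yaml(system.file("extdata", "iceberg_instrument.yaml",
                              package = "icebergscreen"))
}

random_responses <- function(instrument) {
  r <- vapply(instrument$items, function(it) {
    sample(it$options$label, 1)
  }, character(1))
  names(r) <- vapply(instrument$items, `[[`, character(1), "id")
  r
}

temp_csv <- function() tempfile(fileext = ".csv")

temp_dir <- function() {
  d <- tempfile("icebergscreen")
  dir.create(d)
  d
}
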