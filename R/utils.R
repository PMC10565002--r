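#' Round half away from zero
#'
#' Reports in this package render percentages with commercial ("half-up")
#' rounding, matching the printed precision of the pilot summaries, rather
#' than the IEEE round-half-even used by [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # the tiny epsilon guards values such as 2.5 stored as 2.4999...96
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Format a p-value the way the pilot tables print them
#'
#' Values below 0.001 render as `"<0.001"`, below 0.05 as `"<0.05"`, and
#' everything else with two decimals. Machine outputs always retain the raw
#' p-value; this is display only.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  out <- sprintf("%.2f", p)
  out[p < 0.05] <- "<0.05"
  out[p < 0.001] <- "<0.001"
  out[is.na(p)] <- NA_character_
  out
}

fmt_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(x, digits))
}

fmt_median_iqr <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  sprintf("%s (%s-%s)",
          formatC(round_half_up(q[2], digits), format = "fg"),
          formatC(round_half_up(q[1], digits), format = "fg"),
          formatC(round_half_up(q[3], digits), format = "fg"))
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf("%.*f (%.*f)", digits, mean(x, na.rm = TRUE), digits, stats::sd(x, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iceberg <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
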