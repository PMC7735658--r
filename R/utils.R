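#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for every displayed percentage in the reporting layer
#' (base R's `round()` rounds half to even, which would disagree with the
#' printed tables on exact ties).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, display-rounded
#'
#' The single arithmetic rule behind every "k/n (xx.xx%)" pair the reporting
#' layer prints: `100 * k / n`, rounded half-up to 2 decimals.
#'
#' @param k numerator count
#' @param n denominator count
#' @param digits decimal places (default 2)
#' @return numeric percentage on the 0-100 scale
#' @export
pct <- function(k, n, digits = 2) {
  stopifnot(all(n > 0))
  round_half_up(100 * k / n, digits)
}

#' Significance tier label for a p-value
#'
#' Maps a p-value to the tiered annotation used in the mention-frequency and
#' survival reports: `"***"` for p < .001, `"**"` for p < .01, `"*"` for
#' p < .05, `""` otherwise, `NA` for missing.
#'
#' @param p numeric vector of p-values
#' @param tiers strictly decreasing alpha levels
#' @return character vector
#' @export
sig_tier <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  stopifnot(all(diff(tiers) < 0))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ""
  out[ok & p < tiers[1]] <- "*"
  out[ok & p < tiers[2]] <- "**"
  out[ok & p < tiers[3]] <- "***"
  out
}

# internal: stop with a formatted message, no call
abort <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
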