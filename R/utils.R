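#' Round half away from zero
#'
#' Deterministic decimal rounding with ties going away from zero, the
#' convention used for all percentages and summary integers reported by this
#' package (base \code{round()} uses banker's rounding, which would print
#' e.g. 70.45 as 70.4).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded half away from zero
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @param digits Decimal places (default 1, the reporting convention).
#' @return \code{count / total * 100}, rounded.
#' @export
pct_of <- function(count, total, digits = 1) {
  if (total == 0) return(rep(0, length(count)))
  round_half_away(count / total * 100, digits)
}

# internal: stop with a stage-tagged message (used by the pipeline driver)
.stage_stop <- function(stage, msg) {
  stop(sprintf("stage '%s' failed: %s", stage, msg), call. = FALSE)
}

# internal: write a data.frame as a plain TSV with deterministic formatting
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# internal: read a TSV with headers, no factors
.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
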