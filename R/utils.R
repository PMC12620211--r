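#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; spontaneous-report summary tables
#' conventionally round half up (e.g. 35.05 -> 35.1 at one decimal).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Table-style estimate formatting: at most two decimals, trailing zeros
# dropped ("6.40" -> "6.4", "4.30" -> "4.3", "9.53" stays).
fmt_est <- function(x) {
  out <- sprintf("%.2f", x)
  out <- sub("0$", "", out)
  out <- sub("\\.0$", "", out)
  out[is.na(x)] <- NA_character_
  out
}

# Uppercase, trim, collapse internal whitespace; the normal form used for
# drug names, preferred terms and SOC strings throughout the package.
norm_term <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# YYYYMMDD integer -> TRUE if it parses as a real calendar date
valid_yyyymmdd <- function(x) {
  x <- suppressWarnings(as.integer(x))
  ok <- !is.na(x) & x >= 10000101 & x <= 99991231
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(strptime(sprintf("%08d", x[ok]), format = "%Y%m%d"))
  ok & !is.na(d)
}

# "2019Q3" -> c(start, end) as YYYYMMDD integers
quarter_bounds <- function(label) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", label))
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  m0 <- (q - 1) * 3 + 1
  start <- y * 10000 + m0 * 100 + 1
  last_day <- c(331, 630, 930, 1231)[q]
  end <- y * 10000 + last_day
  c(start = start, end = end)
}

# empty character-mode data.frame with the given column names
empty_df <- function(cols) {
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}
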