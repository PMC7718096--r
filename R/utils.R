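`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Reporting convention used for all printed percentages: halves round away
#' from zero (so 0.15 -> 0.2 at one decimal), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Age in completed years at a date
#'
#' Floor of the year difference, adjusted for whether the birthday has
#' occurred by `date` (month/day comparison).
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return integer vector of ages.
#' @export
age_at <- function(birth_date, date) {
  b <- as.POSIXlt(birth_date)
  d <- as.POSIXlt(date)
  age <- d$year - b$year
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - as.integer(before_birthday))
}

# anniversary of a birth date `years` later; Feb 29 birthdays fall on Mar 1
# in non-leap years
anniversary <- function(birth_date, years) {
  b <- as.POSIXlt(birth_date)
  y <- b$year + 1900L + as.integer(years)
  out <- as.Date(sprintf("%04d-%02d-%02d", y, b$mon + 1L, b$mday))
  feb29 <- is.na(out)
  if (any(feb29)) out[feb29] <- as.Date(sprintf("%04d-03-01", y[feb29]))
  out
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

# derived per-stage sub-seeds from one root seed, kept within 32-bit range
stage_seed <- function(seed, stage) {
  offs <- c(population = 11L, claims = 23L, perturb = 37L, misc = 53L)
  (as.integer(seed) * 977L + offs[[stage]]) %% 2147483587L
}

choose2 <- function(n) n * (n - 1) / 2
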