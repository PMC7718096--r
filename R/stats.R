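# Bivariate tests and logistic covariate models for crossover/disposition
# analysis. These wrap the standard R fitting machinery; the package's own
# contribution is upstream (simulation, linkage, screening, projection).

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d cell counts, row-wise: exposed/event, exposed/non-event,
#'   unexposed/event, unexposed/non-event. Alternatively pass a 2x2 matrix
#'   as `a`.
#' @param correct apply Yates continuity correction (off by default, matching
#'   large-sample usage).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' chi_square_test(527, 1861, 39601, 200657)
chi_square_test <- function(a, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  tab <- if (is.matrix(a)) a else matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Two-sample t test
#'
#' Welch (unequal-variance) test by default; set `pooled = TRUE` for the
#' classical equal-variance Student test. When both groups are constant with
#' equal means the test is degenerate and `p = 1` is returned by convention
#' (with a message); constant groups with different means return `p = 0`.
#'
#' @param group_a,group_b numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance Student test.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      message("both groups constant with equal means; returning p = 1")
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    }
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                p_value = 0, df = NA_real_))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit of a binary outcome on dichotomous
#' covariates; odds ratios are exponentiated coefficients with Wald 95%
#' confidence intervals. Convergence uses `glm`'s IRLS criterion
#' (`epsilon = 1e-8`, up to 50 iterations); non-convergence or separation
#' (detected as absolute log-odds above 10) is flagged in the `diagnostic`
#' column rather than failing silently.
#'
#' @param data data frame containing the outcome and covariates.
#' @param outcome name of the binary (0/1 or logical) outcome column.
#' @param covariates character vector of covariate column names.
#' @param conf_level confidence level for the Wald intervals.
#' @return tibble with `term`, `estimate` (log-odds), `std_error`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `diagnostic`.
#' @export
fit_logistic <- function(data, outcome, covariates, conf_level = 0.95) {
  check_cols(data, c(outcome, covariates), "model data")
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  df <- data.frame(.y = y, data[covariates], check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                               collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  diag_flag <- dplyr::case_when(
    !fit$converged ~ "non-convergence",
    abs(est) > 10 ~ "possible separation",
    .default = "ok"
  )
  if (any(diag_flag != "ok")) {
    warning("logistic fit diagnostics: ",
            paste(unique(diag_flag[diag_flag != "ok"]), collapse = ", "))
  }
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(est),
    std_error = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = unname(cf[, "Pr(>|z|)"]),
    diagnostic = unname(diag_flag)
  )
}

#' Format a p value the way epidemiology journals print it
#'
#' Values below the floor are reported as `"<.001"`; otherwise rounded to
#' three decimals with no leading zero.
#'
#' @param p numeric vector of p values.
#' @param floor smallest reportable value.
#' @return character vector.
#' @export
format_p <- function(p, floor = 0.001) {
  ifelse(p < floor,
         paste0("<", sub("^0", "", sprintf("%.3f", floor))),
         sub("^0", "", sprintf("%.3f", round_half_up(p, 3))))
}
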