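#' Build a 2x2 contingency table
#'
#' The unit of all association statistics in the package. Rows are the
#' exposure (suspicious / non-suspicious), columns the outcome (metastatic /
#' non-metastatic):
#' \preformatted{          outcome+   outcome-
#'   exposed      a          b
#'   unexposed    c          d}
#'
#' @param a,b,c,d non-negative integer counts.
#' @return an object of class `contingency_2x2` (a named 2x2 integer matrix).
#' @examples
#' contingency_2x2(156, 85, 256, 582)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort2("nodeconcord_domain_error",
           "contingency_2x2(): counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    abort2("nodeconcord_domain_error",
           "contingency_2x2(): grand total must be positive")
  }
  m <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              outcome = c("positive", "negative")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

as_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) return(table)
  if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    return(contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  }
  if (is.numeric(table) && length(table) == 4) {
    return(contingency_2x2(table[1], table[2], table[3], table[4]))
  }
  abort2("nodeconcord_domain_error",
         "expected a contingency_2x2, a 2x2 matrix or a length-4 vector (a,b,c,d)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson chi-square with 1 degree of freedom: expected cell counts
#' `row_total * col_total / grand_total`, per-cell contributions
#' `(observed - expected)^2 / expected`, statistic equal to the sum of the
#' contributions, and upper-tail p-value from the chi-square distribution.
#' No continuity correction is applied by default; the Yates correction
#' (subtracting 0.5 from each `|observed - expected|`) is available behind
#' `yates = TRUE`.
#'
#' @param table a `contingency_2x2` (or anything [contingency_2x2()] accepts).
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return object of class `chisq_2x2`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `contributions`, `observed`, `yates`.
#' @examples
#' pearson_chi_square(contingency_2x2(156, 85, 256, 582))
#' @export
pearson_chi_square <- function(table, yates = FALSE) {
  obs <- as_2x2(table)
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  if (any(rs == 0) || any(cs == 0)) {
    abort2("nodeconcord_domain_error",
           "pearson_chi_square(): a zero marginal leaves the statistic undefined")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  contributions <- dev^2 / expected
  statistic <- sum(contributions)
  out <- list(
    statistic = statistic,
    df = 1L,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    expected = expected,
    contributions = contributions,
    observed = unclass(obs),
    yates = yates
  )
  class(out) <- "chisq_2x2"
  out
}

#' @export
print.chisq_2x2 <- function(x, digits = 4, ...) {
  cat(sprintf("Pearson chi-square (df = %d%s)\n", x$df,
              if (x$yates) ", Yates-corrected" else ""))
  disp <- matrix(sprintf("%g (%.2f) [%.2f]", x$observed, x$expected,
                         x$contributions), nrow = 2,
                 dimnames = dimnames(x$observed))
  print(disp, quote = FALSE)
  cat("observed (expected) [contribution]\n")
  cat(sprintf("statistic = %.*f, p %s\n", digits, x$statistic,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)`. If any cell is zero and
#' `zero_cell_correction` is enabled (the default), the Haldane-Anscombe
#' correction adds 0.5 to every cell before all computations. The 95%
#' confidence interval is Woolf's log-normal interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells, and the p-value is the two-sided Wald test of
#' `log(OR) = 0`. A Fisher exact p-value can be added via `fisher = TRUE`.
#'
#' @param table a `contingency_2x2` (or anything [contingency_2x2()] accepts).
#' @param zero_cell_correction apply the 0.5 correction on zero cells
#'   (default `TRUE`); with the correction disabled a zero cell is an error.
#' @param conf_level confidence level for the Woolf interval (default 0.95).
#' @param fisher also compute `stats::fisher.test()`'s two-sided p-value.
#' @return object of class `odds_ratio_result`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `correction_applied`, `conf_level`,
#'   and optionally `fisher_p`.
#' @examples
#' odds_ratio(contingency_2x2(156, 85, 256, 582))
#' @export
odds_ratio <- function(table, zero_cell_correction = TRUE,
                       conf_level = 0.95, fisher = FALSE) {
  obs <- as_2x2(table)
  cells <- c(obs[1, 1], obs[1, 2], obs[2, 1], obs[2, 2])
  correction_applied <- FALSE
  if (any(cells == 0)) {
    if (!zero_cell_correction) {
      abort2("nodeconcord_domain_error",
             "odds_ratio(): zero cell with correction disabled; OR undefined")
    }
    cells <- cells + 0.5
    correction_applied <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_z <- log(or) / se
  out <- list(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_value = 2 * stats::pnorm(-abs(wald_z)),
    correction_applied = correction_applied,
    conf_level = conf_level
  )
  if (fisher) {
    out$fisher_p <- stats::fisher.test(unclass(obs))$p.value
  }
  class(out) <- "odds_ratio_result"
  out
}

#' @export
print.odds_ratio_result <- function(x, digits = 3, ...) {
  cat(sprintf("OR %.*f (%.0f%% CI %.*f-%.*f), p %s%s%s\n",
              digits, x$odds_ratio, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high,
              format.pval(x$p_value, digits = 3),
              if (x$correction_applied) " [0.5 added to all cells]" else "",
              if (!is.null(x$fisher_p))
                sprintf(", Fisher p %s", format.pval(x$fisher_p, digits = 3))
              else ""))
  invisible(x)
}

#' Diagnostic metrics of a 2x2 table
#'
#' With rows = suspicious/non-suspicious and columns = metastatic/
#' non-metastatic: sensitivity `a/(a+c)`, specificity `d/(b+d)`,
#' PPV `a/(a+b)`, NPV `d/(c+d)`. A zero denominator yields `NA` for that
#' metric (an explicit undefined marker), never an error.
#'
#' @param table a `contingency_2x2` (or anything [contingency_2x2()] accepts).
#' @return named numeric vector `sensitivity, specificity, ppv, npv`.
#' @examples
#' diagnostic_metrics(contingency_2x2(156, 85, 256, 582))
#' @export
diagnostic_metrics <- function(table) {
  obs <- as_2x2(table)
  a <- obs[1, 1]; b <- obs[1, 2]; c <- obs[2, 1]; d <- obs[2, 2]
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe_div(a, a + c),
    specificity = safe_div(d, b + d),
    ppv = safe_div(a, a + b),
    npv = safe_div(d, c + d))
}
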