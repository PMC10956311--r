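# Exploratory success-vs-failure comparisons: Welch t-tests for continuous
# variables, chi-square / Fisher exact tests for categorical ones.

#' Two-group comparison of a continuous variable (Welch t-test)
#'
#' @param values Numeric vector.
#' @param groups Binary grouping (0/1, logical, or a 2-level factor); group 1
#'   is the "success" group for reporting.
#' @return A `group_comparison` list: per-group n/mean/sd, the Welch t
#'   statistic, Welch-Satterthwaite degrees of freedom and the two-sided
#'   p-value.
#' @export
ttest_groups <- function(values, groups) {
  g <- split_groups(values, groups)
  if (length(g$x0) < 2L || length(g$x1) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  tt <- t.test(g$x1, g$x0, var.equal = FALSE)
  structure(
    list(variable = NULL, type = "continuous",
         n = c(failure = length(g$x0), success = length(g$x1)),
         mean = c(failure = mean(g$x0), success = mean(g$x1)),
         sd = c(failure = sd(g$x0), success = sd(g$x1)),
         test = "Welch two-sample t-test",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "group_comparison"
  )
}

split_groups <- function(values, groups) {
  if (is.factor(groups)) {
    if (nlevels(droplevels(groups)) != 2L) {
      stop("`groups` must have exactly two levels", call. = FALSE)
    }
    groups <- as.integer(droplevels(groups)) - 1L
  }
  groups <- as_outcome01(groups, "groups")
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(values)
  list(x0 = values[ok & groups == 0L], x1 = values[ok & groups == 1L])
}

#' Chi-square or Fisher exact test on a contingency table
#'
#' Pearson's chi-square without continuity correction when every expected
#' cell count is at least 5; otherwise Fisher's exact test (exact for 2x2,
#' network enumeration for small r x c tables). The fallback rule is a
#' convention of this package, chosen to reproduce exact-looking p-values on
#' sparse tables.
#'
#' @param counts Matrix (or table) of non-negative integer counts, groups in
#'   columns.
#' @return A `group_comparison` list with the test name, statistic (NA for
#'   the exact test) and p-value.
#' @export
chisq_or_fisher <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) {
    stop("degenerate margin: row ", which(rs == 0)[1L], " has zero total",
         call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("degenerate margin: column ", which(cs == 0)[1L], " has zero total",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(counts)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    test <- "Pearson chi-square"
    stat <- unname(ct$statistic); p <- ct$p.value
  } else {
    ct <- fisher.test(counts)
    test <- "Fisher exact"
    stat <- NA_real_; p <- ct$p.value
  }
  structure(
    list(variable = NULL, type = "categorical", counts = counts,
         test = test, statistic = stat, p_value = p),
    class = "group_comparison"
  )
}

#' Group summary table for a cohort
#'
#' One comparison per variable, split by a binary outcome: continuous
#' variables get per-group mean +/- SD and a Welch t-test; categorical ones
#' get per-group counts (%) and a chi-square or Fisher exact test (see
#' [chisq_or_fisher()]). Variables that cannot be tested (e.g. constants)
#' are kept in the table with a `not testable` note instead of failing the
#' run. Missing values are dropped per variable.
#'
#' @param cohort A `data.frame`.
#' @param outcome Name of the binary outcome column (1 = success).
#' @param variables Columns to summarise; defaults to every column except
#'   the outcome and `case_id`.
#' @return A `data.frame` with one row per variable: `variable`, `type`,
#'   `failure` and `success` summaries, `test`, `statistic`, `p_value`,
#'   `note`.
#' @examples
#' coh <- generate_cohort(cohort_gen_spec(n = 300, seed = 2))
#' head(summarize_groups(coh, "engrafted", c("age", "ki67", "subtype", "hg")))
#' @export
summarize_groups <- function(cohort, outcome, variables = NULL) {
  stopifnot(is.data.frame(cohort))
  y <- as_outcome01(cohort[[outcome]], outcome)
  variables <- variables %||% setdiff(names(cohort), c(outcome, "case_id"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      fmt <- function(g) sprintf("%.1f ± %.1f", mean(x[ok & y == g]),
                                 sd(x[ok & y == g]))
      cmp <- tryCatch(ttest_groups(x[ok], y[ok]), error = function(e) e)
      if (inherits(cmp, "error")) {
        data.frame(variable = v, type = "continuous",
                   failure = fmt(0L), success = fmt(1L),
                   test = NA_character_, statistic = NA_real_,
                   p_value = NA_real_, note = "not testable")
      } else {
        data.frame(variable = v, type = "continuous",
                   failure = fmt(0L), success = fmt(1L),
                   test = cmp$test, statistic = cmp$statistic,
                   p_value = cmp$p_value, note = "")
      }
    } else {
      tab <- table(as.character(x)[ok], factor(y[ok], c(0L, 1L)))
      fmt <- function(col) paste(sprintf("%s %d (%.1f%%)", rownames(tab),
                                         tab[, col],
                                         100 * tab[, col] / max(sum(tab[, col]), 1L)),
                                 collapse = "; ")
      cmp <- tryCatch(chisq_or_fisher(tab), error = function(e) e)
      if (inherits(cmp, "error")) {
        data.frame(variable = v, type = "categorical",
                   failure = fmt("0"), success = fmt("1"),
                   test = NA_character_, statistic = NA_real_,
                   p_value = NA_real_, note = "not testable")
      } else {
        data.frame(variable = v, type = "categorical",
                   failure = fmt("0"), success = fmt("1"),
                   test = cmp$test, statistic = cmp$statistic,
                   p_value = cmp$p_value, note = "")
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g\n", x$test,
              ifelse(is.na(x$statistic), "exact",
                     format(x$statistic, digits = 4)), x$p_value))
  invisible(x)
}
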