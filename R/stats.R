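# Statistical battery for motor-unit metric tables: normality, group
# comparisons, observer agreement (ICC + Bland-Altman) and correlation.

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, n >= 3.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n`. Constant input
#'   yields `NA`s with a warning.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop_input("normality test needs at least 3 values")
  if (sd(values) == 0) {
    rlang::warn("constant input: normality undefined",
                class = "mumri_undefined_warning")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n = length(values)))
  }
  ht <- shapiro.test(values)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = length(values))
}

#' Compare a motor-unit metric between groups
#'
#' Two designs mirror the validation analyses of motor-unit cohorts:
#' `grouping = "muscle"` runs a one-way ANOVA of the metric across muscles;
#' `grouping = "age_group"` dichotomises subjects at `age_cut` years and runs
#' an unpaired two-tailed Student's t-test (equal variances) between the
#' younger and older groups.
#'
#' @param table A data frame with one row per unit, containing the metric
#'   column and `muscle` (for `"muscle"`) or `age` (for `"age_group"`).
#' @param metric Name of the metric column (string).
#' @param grouping `"muscle"` or `"age_group"`.
#' @param age_cut Age dichotomy in years; default 40.
#' @return A one-row tibble: `method`, `statistic`, `df` (and `df2` for the
#'   ANOVA), `p_value`, `n_groups`.
#' @export
compare_groups <- function(table, metric, grouping = c("muscle", "age_group"),
                           age_cut = 40) {
  grouping <- match.arg(grouping)
  y <- table[[metric]]
  if (is.null(y)) stop_input(sprintf("metric column `%s` not found", metric))
  g <- if (grouping == "muscle") {
    factor(table$muscle)
  } else {
    factor(ifelse(table$age < age_cut, sprintf("<%g", age_cut),
                  sprintf(">=%g", age_cut)))
  }
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2L) stop_input("need at least 2 groups")
  if (any(sizes < 2L)) stop_input("every group needs at least 2 values")
  if (grouping == "age_group") {
    ht <- t.test(y ~ g, var.equal = TRUE)
    tibble(method = "t-test", statistic = unname(ht$statistic),
           df = unname(ht$parameter), df2 = NA_real_,
           p_value = ht$p.value, n_groups = 2L)
  } else {
    fit <- aov(y ~ g)
    s <- summary(fit)[[1]]
    tibble(method = "anova", statistic = s[["F value"]][1],
           df = s[["Df"]][1], df2 = s[["Df"]][2],
           p_value = s[["Pr(>F)"]][1], n_groups = length(sizes))
  }
}

#' Inter-observer agreement: ICC and Bland-Altman
#'
#' Computes the intraclass correlation for absolute agreement under the
#' two-way mixed model (single measures; the conservative choice when the
#' raters are the two fixed observers), together with the Bland-Altman bias
#' (mean paired difference, observer 2 minus observer 1) and coefficient of
#' repeatability (1.96 times the SD of the paired differences).
#'
#' The ICC is computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, with `MSR` the
#' between-subject, `MSC` the between-rater and `MSE` the residual mean
#' square, `n` subjects and `k` raters.
#'
#' @param table A data frame in long format with columns `unit` (or the
#'   first id-like column), `observer`, and the metric column; or a matrix /
#'   data frame with one column per observer via `wide = TRUE`.
#' @param metric Metric column name (long format).
#' @param average_measures If `TRUE`, report the average-measures ICC
#'   `ICC(A,k)` instead of single measures; default `FALSE`.
#' @param wide Set `TRUE` when `table` is already subjects x raters.
#' @return A one-row tibble of class `mumri_agreement`: `icc`, `bias`,
#'   `coefficient_of_repeatability`, `n_pairs`, `form`.
#' @export
agreement <- function(table, metric = NULL, average_measures = FALSE,
                      wide = FALSE) {
  if (wide) {
    m <- as.matrix(table)
  } else {
    if (is.null(metric)) stop_input("long format needs `metric`")
    id_col <- intersect(c("unit", "unit_id", "subject", "id"), names(table))[1]
    if (is.na(id_col)) stop_input("long format needs a unit/subject id column")
    w <- tidyr::pivot_wider(as_tibble(table[, c(id_col, "observer", metric)]),
                            names_from = "observer",
                            values_from = tidyr::all_of(metric))
    m <- as.matrix(w[, -1])
  }
  if (anyNA(m)) stop_input("agreement needs complete paired observations")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop_input("agreement needs at least 3 paired observations")
  if (k < 2L) stop_input("agreement needs at least 2 observers")

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  denom_s <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (average_measures) {
    denom_a <- msr + (msc - mse) / n
    if (denom_a == 0) 1 else (msr - mse) / denom_a
  } else {
    if (denom_s == 0) 1 else (msr - mse) / denom_s
  }

  if (k == 2L) {
    d <- m[, 2] - m[, 1]
    bias <- mean(d)
    cr <- 1.96 * sd(d)
  } else {
    bias <- NA_real_; cr <- NA_real_
  }
  out <- tibble(icc = icc, bias = bias, coefficient_of_repeatability = cr,
                n_pairs = n,
                form = if (average_measures) "ICC(A,k)" else "ICC(A,1)")
  class(out) <- c("mumri_agreement", class(out))
  out
}

#' @export
tidy.mumri_agreement <- function(x, ...) {
  tibble(term = c("icc", "bias", "coefficient_of_repeatability"),
         estimate = c(x$icc, x$bias, x$coefficient_of_repeatability))
}

#' Pearson correlation with significance
#'
#' @param x,y Numeric vectors, n >= 3, finite.
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `n`. Zero-variance
#'   input yields `NA`s with a warning.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_input("correlation needs at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("zero-variance input: correlation undefined",
                class = "mumri_undefined_warning")
    return(tibble(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                  n = length(x)))
  }
  ht <- cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  tibble(r = r, r_squared = r^2, p_value = ht$p.value, n = length(x))
}
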