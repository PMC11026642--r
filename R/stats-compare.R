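#' Two-sample t-test as a tidy row
#'
#' Pooled-variance Student t-test by default (Welch by flag), two-sided,
#' with a significance call at alpha = 0.05. Degenerate inputs with zero
#' pooled variance are handled explicitly: equal means give `p = 1`,
#' unequal means give `p = 0` flagged degenerate.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `significant`, `degenerate`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) abort("each sample needs n >= 2")
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0 && sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
      df = length(x) + length(y) - 2,
      p_value = if (eq) 1 else 0,
      mean_x = mean(x), mean_y = mean(y),
      significant = !eq, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_x = mean(x), mean_y = mean(y),
                 significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Two-way factorial ANOVA with interaction (age x volume)
#'
#' Fits the two-factor linear model with interaction and reports Type II
#' sums of squares, which reduce to the classical orthogonal partition
#' when the design is balanced and remain the conventional choice for
#' unbalanced animal counts absent interaction-driven main-effect
#' hypotheses. The SS type is recorded in the output.
#'
#' @param data Data frame of observations.
#' @param response Response column name.
#' @param factor_a,factor_b Factor column names (each must have exactly 2
#'   observed levels).
#' @return An `anova_table` tibble: one row per term (`factor_a`,
#'   `factor_b`, interaction, `Residuals`) with `sum_sq`, `df`,
#'   `mean_sq`, `statistic`, `p_value`; attribute `ss_type = "II"`.
#' @export
two_way_anova <- function(data, response, factor_a = "age",
                          factor_b = "volume") {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) abort(paste("missing column:", col))
  d <- data.frame(
    y = data[[response]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$a)) != 2L || nlevels(droplevels(d$b)) != 2L)
    abort("both factors must have exactly 2 observed levels")
  cells <- table(d$a, d$b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s = %s, %s = %s",
                  factor_a, rownames(cells)[empty[1]],
                  factor_b, colnames(cells)[empty[2]]))
  }
  if (sum(cells >= 2) < 3L)
    abort("need >= 2 observations in at least 3 of the 4 cells")
  fit <- lm(y ~ a * b, data = d)
  if (fit$rank < 4L) abort("rank-deficient design")
  aov2 <- car::Anova(fit, type = 2)
  term_map <- c(a = factor_a, b = factor_b,
                `a:b` = paste0(factor_a, ":", factor_b),
                Residuals = "Residuals")
  out <- tibble::tibble(
    term = unname(term_map[rownames(aov2)]),
    sum_sq = aov2[["Sum Sq"]],
    df = aov2[["Df"]],
    mean_sq = aov2[["Sum Sq"]] / aov2[["Df"]],
    statistic = aov2[["F value"]],
    p_value = aov2[["Pr(>F)"]]
  )
  attr(out, "ss_type") <- "II"
  class(out) <- c("anova_table", class(out))
  out
}

#' Group summaries as mean and standard error
#'
#' @param data Data frame.
#' @param value Value column name.
#' @param ... Grouping column names (tidy-select).
#' @return Tibble with one row per group: `n`, `mean`, `se` (sample SD
#'   over sqrt(n); `NA` when `n = 1`).
#' @export
summarize_groups <- function(data, value, ...) {
  dplyr::summarise(
    dplyr::group_by(data, ...),
    n = sum(!is.na(.data[[value]])),
    mean = mean(.data[[value]], na.rm = TRUE),
    se = if (sum(!is.na(.data[[value]])) > 1)
      sd(.data[[value]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[value]])))
    else NA_real_,
    .groups = "drop")
}
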