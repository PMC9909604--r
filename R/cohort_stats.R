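# Cohort summarisation and the validation statistics: CV, averaged
# summary tables, Spearman correlation, ordinary least squares and
# two-sample t-tests. The flat significance level is alpha = 0.05 with no
# multiple-testing correction; association tables therefore also report
# how many tests were run.

#' Coefficient of variation
#'
#' `cv = sd / mean`; dimensionless relative dispersion. Undefined (NA with
#' a warning) for non-positive means.
#'
#' @param mean,sd Mean and standard deviation (vectorised).
#' @return `sd / mean`.
#' @export
coefficient_of_variation <- function(mean, sd) {
  out <- ifelse(mean > 0, sd / mean, NA_real_)
  if (anyNA(out)) warn("CV undefined for non-positive mean(s)")
  out
}

#' Across-subject cohort summary
#'
#' Aggregates per-subject summary statistics as the arithmetic mean of
#' each statistic across subjects, per exercise -- the average of the
#' means, of the SDs, of the CVs and of the extremes, not the statistic of
#' the pooled samples.
#'
#' @param per_subject Tibble with columns `subject_id`, `exercise_id` and
#'   one or more statistic columns (e.g. `mean`, `sd`, `cv`, `max`, `min`).
#' @return A tibble with one row per exercise: `avg_of_<stat>` columns and
#'   `n_subjects`.
#' @export
cohort_summary <- function(per_subject) {
  per_subject <- tibble::as_tibble(per_subject)
  if (nrow(per_subject) == 0) stop_value("empty cohort")
  stat_cols <- setdiff(names(per_subject), c("subject_id", "exercise_id"))
  per_subject |>
    dplyr::group_by(.data$exercise_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(stat_cols),
                    \(x) mean(x, na.rm = TRUE), .names = "avg_of_{.col}"),
      n_subjects = dplyr::n(),
      .groups = "drop")
}

association_result <- function(method, estimate, p_value, n,
                               slope = NA_real_, intercept = NA_real_,
                               r_squared = NA_real_) {
  tibble::tibble(method = method, estimate = estimate, p_value = p_value,
                 n = n, slope = slope, intercept = intercept,
                 r_squared = r_squared)
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties and a two-sided
#' p-value; by default the large-sample t approximation, or the exact
#' null distribution for small tie-free samples via `exact = TRUE`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param exact Use the exact p-value (small n, no ties).
#' @return A one-row tibble: `method`, `estimate` (rho), `p_value`, `n`.
#' @export
spearman_corr <- function(x, y, exact = FALSE) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_value("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input; Spearman correlation undefined")
    return(association_result("spearman", NA_real_, NA_real_, length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  association_result("spearman", unname(ct$estimate), ct$p.value, length(x))
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the Pearson correlation, its
#' square, and the two-sided p-value for the slope.
#'
#' @param x,y Equal-length numeric vectors, n >= 3; `x` non-constant.
#' @return A one-row tibble: `method`, `estimate` (Pearson r), `p_value`,
#'   `n`, `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_value("need at least 3 complete pairs")
  if (sd(x) == 0) stop_value("x is constant; regression undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # a perfect fit is legitimate input
  r <- cor(x, y)
  association_result("linear", r, sm$coefficients["x", "Pr(>|t|)"],
                     length(x), slope = unname(coef(fit)["x"]),
                     intercept = unname(coef(fit)["(Intercept)"]),
                     r_squared = r^2)
}

#' Two-sample t-test
#'
#' Two-sided Student's t-test: paired for within-subject exercise
#' comparisons, unpaired (Welch) otherwise, at the study's flat
#' alpha = 0.05.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `n_a`, `n_b`,
#'   `paired`.
#' @export
two_sample_ttest <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop_value("each group needs n >= 2")
  if (paired && length(a) == length(b) && sd(a - b) == 0) {
    # degenerate paired case (identical differences): t.test() refuses it,
    # but zero differences mean no evidence of a shift
    d <- mean(a - b)
    return(tibble::tibble(statistic = if (d == 0) 0 else sign(d) * Inf,
                          p_value = if (d == 0) 1 else 0,
                          df = length(a) - 1, n_a = length(a),
                          n_b = length(b), paired = TRUE))
  }
  tt <- t.test(a, b, paired = paired)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n_a = length(a), n_b = length(b),
                 paired = paired)
}
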