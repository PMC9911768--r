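# Cohort statistics: normality-gated group comparisons, Pearson chi-square
# for categorical tables, confounder-adjusted associations with PVR status,
# and univariate strain-feature regressions.

#' Shapiro-Wilk normality test p-value
#'
#' @param values numeric vector, `3 <= n <= 5000`, non-constant.
#' @return the Shapiro-Wilk p-value.
#' @export
normality_test <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop_bv("normality test needs at least 3 values")
  if (stats::sd(values) == 0) stop_bv("normality test undefined for a constant vector")
  stats::shapiro.test(values)$p.value
}

#' Two-group comparison with a normality gate
#'
#' If both groups pass Shapiro-Wilk normality at alpha, an unpaired
#' two-sample t-test (pooled variance) is used; otherwise a Wilcoxon
#' rank-sum test (normal approximation with midranks, no continuity
#' correction). The choice is reported alongside the p-value.
#'
#' @param values numeric vector.
#' @param labels two-level grouping of the same length.
#' @param alpha normality-gate level (default 0.05).
#' @return list with `test_name` (`"t-test"` or `"rank-sum"`), `p`, and
#'   `statistic`.
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop_bv("labels must have exactly two observed levels")
  sp <- split(as.numeric(values), droplevels(labels))
  if (any(lengths(sp) == 0L)) stop_bv("both groups must be non-empty")
  normal <- all(vapply(sp, function(g) {
    if (length(g) < 3L || stats::sd(g) == 0) return(FALSE)
    normality_test(g) > alpha
  }, logical(1L)))
  if (normal) {
    ht <- stats::t.test(sp[[1L]], sp[[2L]], var.equal = TRUE)
    list(test_name = "t-test", p = ht$p.value,
         statistic = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(sp[[1L]], sp[[2L]],
                                              exact = FALSE, correct = FALSE))
    list(test_name = "rank-sum", p = ht$p.value,
         statistic = unname(ht$statistic))
  }
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Textbook Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the product of the marginals, `df = (R - 1)(C - 1)`, no continuity
#' correction, upper-tail chi-square p-value.
#'
#' @param tab R x C matrix of non-negative counts with positive row and
#'   column sums.
#' @return list with `statistic`, `df` and `p`.
#' @export
chi2_contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop_bv("table must contain non-negative finite counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop_bv("table has a zero marginal row or column")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_bv("table must be at least 2 x 2")
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = statistic, df = df,
       p = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Confounder-adjusted association of a response with PVR status
#'
#' Ordinary least squares of a normalized response on PVR status, sex and
#' repair type (reference-coded categorical predictors: No-PVR, female,
#' transannular patch) plus time after repair and - for shape-mode
#' responses - BSA as z-normalized continuous predictors. All continuous
#' variables (response included) are z-normalized before fitting, so the
#' PVR coefficient is in standardized units. The reported p-value is the
#' two-sided p for the PVR coefficient.
#'
#' @param response numeric vector (an imaging index, a shape-mode Z-score,
#'   or a strain).
#' @param records subject table (data frame) with columns `group`, `sex`,
#'   `repair_type`, `time_after_repair`, `bsa`.
#' @param response_kind `"IMAGING_INDEX"` (BSA omitted: indices are
#'   already BSA-indexed) or `"SHAPE_MODE"` (BSA included).
#' @param response_name label carried into the result.
#' @param include_bsa override the `response_kind`-based BSA rule.
#' @return object of class `pvr_association`: list with `response_name`,
#'   `pvr_coefficient`, `pvr_p_value`, `coefficients` (full table),
#'   `n_used`, `response_kind`.
#' @export
pvr_association <- function(response, records,
                            response_kind = c("IMAGING_INDEX", "SHAPE_MODE"),
                            response_name = deparse(substitute(response)),
                            include_bsa = NULL) {
  response_kind <- match.arg(response_kind)
  response <- as.numeric(response)
  n <- length(response)
  if (n != nrow(records)) stop_bv("response and records length mismatch")
  if (is.null(include_bsa)) include_bsa <- response_kind == "SHAPE_MODE"
  df <- data.frame(
    y = znorm(response, "response"),
    group = droplevels(factor(records$group, levels = c("NO_PVR", "PVR"))),
    sex = droplevels(factor(records$sex, levels = c("F", "M"))),
    repair = droplevels(factor(records$repair_type, levels = REPAIR_TYPES)),
    time = znorm(records$time_after_repair, "time_after_repair")
  )
  form <- y ~ group + sex + repair + time
  if (include_bsa) {
    df$bsa <- znorm(records$bsa, "bsa")
    form <- y ~ group + sex + repair + time + bsa
  }
  n_pred <- 3L + nlevels(df$repair) - 1L + as.integer(include_bsa)
  if (n <= n_pred + 2L)
    stop_bv("too few subjects (", n, ") for ", n_pred, " predictors")
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_bv("rank-deficient design; aliased columns: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  tab <- stats::coef(summary(fit))
  colnames(tab) <- c("estimate", "se", "t", "p")
  structure(list(
    response_name = response_name,
    pvr_coefficient = tab["groupPVR", "estimate"],
    pvr_p_value = tab["groupPVR", "p"],
    coefficients = tab,
    n_used = n,
    response_kind = response_kind,
    df_residual = fit$df.residual
  ), class = "pvr_association")
}

#' @export
print.pvr_association <- function(x, ...) {
  cat(sprintf("PVR association for %s (%s): coef %.3f, p %.4g (n = %d)\n",
              x$response_name, tolower(gsub("_", " ", x$response_kind)),
              x$pvr_coefficient, x$pvr_p_value, x$n_used))
  invisible(x)
}

#' Univariate regression of a strain on a feature
#'
#' Simple linear regression with the Pearson correlation and the two-sided
#' p-value of the slope.
#'
#' @param strain numeric response vector (%).
#' @param feature numeric predictor of the same length (an imaging index
#'   or shape-mode Z-score).
#' @return list with `slope`, `intercept`, `r` and `p`.
#' @export
strain_feature_regression <- function(strain, feature) {
  strain <- as.numeric(strain); feature <- as.numeric(feature)
  if (length(strain) != length(feature)) stop_bv("length mismatch")
  if (length(strain) < 3L) stop_bv("need at least 3 observations")
  if (stats::sd(feature) == 0) stop_bv("feature is constant")
  fit <- stats::lm(strain ~ feature)
  tab <- stats::coef(summary(fit))
  list(slope = tab["feature", "Estimate"],
       intercept = tab["(Intercept)", "Estimate"],
       r = stats::cor(strain, feature),
       p = tab["feature", "Pr(>|t|)"])
}
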