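# Cohort-level statistical machinery: standardization, Pearson correlation,
# standardized age- and sex-adjusted linear regression, and non-obese vs
# obese group comparisons with optional Bonferroni adjustment.

#' Standardize a numeric vector
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (denominator n - 1), the convention used for standardized regression
#' estimates.
#'
#' @param x numeric vector of length >= 2 with positive variance.
#' @return vector with mean 0 and sample sd 1.
#' @export
standardize <- function(x) {
  if (length(x) < 2 || anyNA(x)) {
    mm_abort("`x` must have length >= 2 and no missing values",
             class = "musclemap_degenerate")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    mm_abort("cannot standardize a constant (zero-variance) variable",
             class = "musclemap_degenerate")
  }
  (x - mean(x)) / s
}

#' Pearson correlation with p-value
#'
#' Computes r from the covariance-ratio definition and its p-value from the
#' t-distribution transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return one-row tibble with columns `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) mm_abort("`x` and `y` must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) mm_abort("need at least 3 complete pairs",
                      class = "musclemap_degenerate")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    mm_abort("correlation undefined for constant input",
             class = "musclemap_degenerate")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(1, max(-1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble(r = r, p_value = p, n = n)
}

#' Standardized linear regression adjusted for covariates
#'
#' Ordinary least squares of the standardized outcome on the standardized
#' predictor plus standardized covariates (by default age and sex; the
#' binary sex indicator is standardized like any other covariate). Reports
#' the predictor's standardized slope with a Wald 95% confidence interval
#' (t critical value on the residual degrees of freedom) and p-value. With
#' no covariates the estimate equals the Pearson correlation.
#'
#' @param data data frame containing all columns.
#' @param outcome,predictor column names (strings).
#' @param covariates character vector of adjustment columns; default
#'   `c("age", "sex")`. Use `character(0)` for an unadjusted fit.
#' @param stratum optional stratum label carried into the result.
#' @param conf_level confidence level, default 0.95.
#' @return an object of class `std_ols`; see [tidy.std_ols()].
#' @export
standardized_ols <- function(data, outcome, predictor,
                             covariates = c("age", "sex"),
                             stratum = "all", conf_level = 0.95) {
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  d <- data[, cols, drop = FALSE]
  d <- as.data.frame(lapply(d, function(col) {
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      col <- encode_binary(col)
    }
    col
  }))
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 10) {
    mm_abort("need at least 10 complete cases", class = "musclemap_degenerate")
  }
  dz <- as.data.frame(lapply(d, standardize))
  names(dz) <- c(".y", ".x", covariates)
  fit <- lm(.y ~ ., data = dz)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    mm_abort(paste0("rank-deficient (collinear) design; dropped: ",
                    paste(bad, collapse = ", ")),
             class = "musclemap_collinear")
  }
  sm <- summary(fit)
  est <- coef(fit)[[".x"]]
  se <- sm$coefficients[".x", "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(
      outcome = outcome, predictor = predictor,
      estimate = est, se = se,
      ci_low = est - tcrit * se, ci_high = est + tcrit * se,
      p_value = sm$coefficients[".x", "Pr(>|t|)"],
      n = n, df = df, r_squared = sm$r.squared,
      adjusted_for = covariates, stratum = stratum,
      conf_level = conf_level, fit = fit
    ),
    class = "std_ols"
  )
}

#' @export
print.std_ols <- function(x, ...) {
  adj <- if (length(x$adjusted_for) == 0) "unadjusted" else
    paste("adjusted for", paste(x$adjusted_for, collapse = ", "))
  cat("<std_ols> ", x$outcome, " ~ ", x$predictor, " (", adj,
      "; stratum ", x$stratum, ")\n", sep = "")
  cat(sprintf("  beta = %.3f [%.3f, %.3f], p = %.3g, n = %d\n",
              x$estimate, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Tidy a standardized regression fit
#'
#' @param x a `std_ols` object.
#' @param ... unused.
#' @return one-row tibble: outcome, predictor, estimate, ci_low, ci_high,
#'   p_value, n, adjusted_for, stratum.
#' @export
tidy.std_ols <- function(x, ...) {
  tibble(
    outcome = x$outcome, predictor = x$predictor,
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, n = x$n,
    adjusted_for = paste(x$adjusted_for, collapse = "+"),
    stratum = x$stratum
  )
}

#' @rdname tidy.std_ols
#' @export
glance.std_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared, df_residual = x$df, n = x$n,
         conf_level = x$conf_level)
}

#' Compare a variable between non-obese and obese subjects
#'
#' Quantitative variables use the Welch (unequal-variance) two-sample t-test
#' (`student = TRUE` switches to the pooled-variance test); qualitative
#' variables use the chi-square test without continuity correction. The
#' optional Bonferroni multiplier is applied as adjusted p = min(1, m * p).
#'
#' @param data data frame.
#' @param variable column to compare (string).
#' @param grouping name of the logical/binary grouping column, default
#'   `"obese"`.
#' @param test `"auto"` picks t for numeric and chi-square otherwise.
#' @param bonferroni_m optional number of independent tests to adjust for.
#' @param student use the pooled-variance Student t-test instead of Welch.
#' @return one-row tibble with group summaries, the test statistic, raw and
#'   (if requested) Bonferroni-adjusted p-value.
#' @export
compare_groups <- function(data, variable, grouping = "obese",
                           test = c("auto", "t", "chi2"),
                           bonferroni_m = NULL, student = FALSE) {
  test <- match.arg(test)
  missing_cols <- setdiff(c(variable, grouping), names(data))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  g <- as.logical(encode_binary(data[[grouping]]))
  x <- data[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- g[keep]
  if (length(g) == 0 || !any(g) || all(g)) {
    mm_abort("both groups must be non-empty", class = "musclemap_degenerate")
  }
  quantitative <- if (test == "auto") is.numeric(x) && !is.logical(x) else
    test == "t"
  if (quantitative) {
    if (sum(g) < 2 || sum(!g) < 2) {
      mm_abort("each group needs n >= 2 for the t-test",
               class = "musclemap_degenerate")
    }
    ht <- tryCatch(
      stats::t.test(x[!g], x[g], var.equal = student),
      error = function(e) NULL
    )
    if (is.null(ht)) {
      warning("degenerate t-test (zero variance in both groups) for ",
              variable, call. = FALSE)
      ht <- list(statistic = c(t = 0), p.value = 1)
    }
    out <- tibble(
      variable = variable, test = "t",
      group1 = mean(x[!g]), group2 = mean(x[g]),
      statistic = unname(ht$statistic), p_value = ht$p.value
    )
  } else {
    xb <- encode_binary(x)
    tab <- table(factor(g, levels = c(FALSE, TRUE)),
                 factor(xb, levels = sort(unique(xb))))
    if (ncol(tab) < 2) {
      warning("constant qualitative variable ", variable,
              "; chi-square degenerate", call. = FALSE)
      out <- tibble(variable = variable, test = "chi2",
                    group1 = mean(xb[!g]), group2 = mean(xb[g]),
                    statistic = 0, p_value = 1)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out <- tibble(
        variable = variable, test = "chi2",
        group1 = mean(xb[!g]), group2 = mean(xb[g]),
        statistic = unname(ht$statistic), p_value = ht$p.value
      )
    }
  }
  out$bonferroni_m <- if (is.null(bonferroni_m)) NA_integer_ else
    as.integer(bonferroni_m)
  out$p_adjusted <- if (is.null(bonferroni_m)) out$p_value else
    bonferroni_adjust(out$p_value, bonferroni_m)
  out
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of independent tests.
#' @return adjusted p = min(1, m * p).
#' @export
bonferroni_adjust <- function(p, m) pmin(1, m * p)

# map a two-level vector (logical, character, factor, 0/1) onto 0/1
encode_binary <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      mm_abort("numeric binary variable must be coded 0/1")
    }
    return(x)
  }
  lev <- sort(unique(as.character(x[!is.na(x)])))
  if (length(lev) > 2) {
    mm_abort(paste0("variable has more than two levels: ",
                    paste(lev, collapse = ", ")))
  }
  # stable codings for the package's conventional levels
  ref <- list(c("female", "male"), c("normal", "impaired"))
  for (r in ref) {
    if (setequal(lev, r) || identical(lev, sort(r[1]))) {
      return(as.numeric(as.character(x) == r[2]))
    }
  }
  as.numeric(as.character(x) == lev[length(lev)])
}
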