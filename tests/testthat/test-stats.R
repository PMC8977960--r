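# Statistical machinery: standardization, correlation, standardized OLS
# against a normal-equations oracle, and group comparisons.

test_that("standardize centres and scales with the sample sd", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)  # idempotent
  expect_error(standardize(rep(4, 10)), class = "musclemap_degenerate")
  expect_error(standardize(3), class = "musclemap_degenerate")
})

test_that("pearson_r matches cor.test and the covariance-ratio definition", {
  withr::with_seed(201, {
    for (i in 1:30) {
      n <- sample(5:60, 1)
      x <- rnorm(n)
      y <- 0.4 * x + rnorm(n)
      res <- pearson_r(x, y)
      ct <- stats::cor.test(x, y)
      expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
      r_def <- cov(x, y) / (sd(x) * sd(y))
      expect_equal(res$r, r_def, tolerance = 1e-12)
    }
  })
  lin <- pearson_r(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1, tolerance = 1e-12)
  expect_lt(lin$p_value, 1e-10)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "musclemap_degenerate")
  expect_error(pearson_r(1:2, 1:2), class = "musclemap_degenerate")
})

test_that("uncorrelated variables give near-zero r at large n", {
  withr::with_seed(202, {
    res <- pearson_r(rnorm(10000), rnorm(10000))
    expect_lt(abs(res$r), 0.03)
  })
})

test_that("unadjusted standardized OLS equals the Pearson correlation", {
  withr::with_seed(203, {
    d <- data.frame(x = rnorm(80), e = rnorm(80))
    d$y <- 0.6 * d$x + d$e
    fit <- standardized_ols(d, "y", "x", covariates = character(0))
    expect_equal(fit$estimate, pearson_r(d$x, d$y)$r, tolerance = 1e-12)
  })
})

test_that("standardized OLS matches the normal-equations oracle", {
  withr::with_seed(204, {
    for (i in 1:20) {
      n <- sample(30:200, 1)
      d <- data.frame(
        age = rnorm(n, 55, 9),
        sex = sample(c("male", "female"), n, replace = TRUE),
        x = rnorm(n)
      )
      d$y <- 0.5 * d$x + 0.02 * d$age + 0.3 * (d$sex == "male") + rnorm(n)
      fit <- standardized_ols(d, "y", "x")
      # explicit (X'X)^{-1} X'y on the standardized design
      zy <- standardize(d$y)
      X <- cbind(1, standardize(d$x), standardize(d$age),
                 standardize(as.numeric(d$sex == "male")))
      beta <- solve(crossprod(X), crossprod(X, zy))
      expect_equal(fit$estimate, beta[2], tolerance = 1e-9)
      resid <- zy - X %*% beta
      s2 <- sum(resid^2) / (n - ncol(X))
      se <- sqrt(s2 * solve(crossprod(X))[2, 2])
      expect_equal(fit$se, se, tolerance = 1e-9)
      tcrit <- qt(0.975, n - ncol(X))
      expect_equal(fit$ci_low, beta[2] - tcrit * se, tolerance = 1e-9)
      expect_equal(fit$ci_high, beta[2] + tcrit * se, tolerance = 1e-9)
      expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
    }
  })
})

test_that("collinear designs raise a rank-deficiency error", {
  withr::with_seed(205, {
    d <- data.frame(x = rnorm(50))
    d$y <- d$x + rnorm(50)
    d$x_copy <- d$x
    expect_error(standardized_ols(d, "y", "x", covariates = "x_copy"),
                 class = "musclemap_collinear")
  })
})

test_that("null predictor gives small estimates and uniform-ish p-values", {
  withr::with_seed(206, {
    d <- data.frame(
      x = rnorm(1000),
      age = rnorm(1000, 55, 9),
      sex = sample(c("male", "female"), 1000, replace = TRUE)
    )
    d$y <- rnorm(1000)
    fit <- standardized_ols(d, "y", "x")
    expect_lt(abs(fit$estimate), 0.1)
    td <- tidy(fit)
    expect_s3_class(td, "tbl_df")
    expect_equal(td$estimate, fit$estimate)
    gl <- glance(fit)
    expect_equal(gl$n, 1000)
  })
})

test_that("compare_groups performs Welch t, Student t and chi-square", {
  withr::with_seed(207, {
    d <- data.frame(
      v = c(rnorm(40, 0, 1), rnorm(60, 1, 3)),
      flag = c(sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(.2, .8)),
               sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.6, .4))),
      obese = rep(c(FALSE, TRUE), c(40, 60))
    )
    welch <- compare_groups(d, "v")
    ref <- t.test(d$v[!d$obese], d$v[d$obese])
    expect_equal(welch$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(welch$p_value, ref$p.value, tolerance = 1e-12)
    student <- compare_groups(d, "v", student = TRUE)
    ref_s <- t.test(d$v[!d$obese], d$v[d$obese], var.equal = TRUE)
    expect_equal(student$p_value, ref_s$p.value, tolerance = 1e-12)
    chi <- compare_groups(d, "flag")
    ref_c <- chisq.test(table(d$obese, d$flag), correct = FALSE)
    expect_equal(chi$statistic, unname(ref_c$statistic), tolerance = 1e-12)
    expect_equal(chi$p_value, ref_c$p.value, tolerance = 1e-12)
  })
})

test_that("identical groups are degenerate but handled", {
  d <- data.frame(v = rep(c(1, 2), 10), obese = rep(c(FALSE, TRUE), each = 10))
  res <- compare_groups(d, "v")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  const <- data.frame(v = rep(5, 20), obese = rep(c(FALSE, TRUE), each = 10))
  expect_warning(res2 <- compare_groups(const, "v"), "degenerate")
  expect_equal(res2$p_value, 1)
  one <- data.frame(v = rnorm(10), obese = rep(FALSE, 10))
  expect_error(compare_groups(one, "v"), class = "musclemap_degenerate")
})

test_that("Bonferroni adjustment follows the multiplication rule", {
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  res <- compare_groups(
    data.frame(v = rnorm(40), obese = rep(c(FALSE, TRUE), 20)),
    "v", bonferroni_m = 3
  )
  expect_equal(res$p_adjusted, min(1, 3 * res$p_value))
})

test_that("a true mean shift of 0.5 sd at n = 200 per group is detected", {
  withr::with_seed(208, {
    reject <- logical(300)
    for (i in seq_along(reject)) {
      d <- data.frame(v = c(rnorm(200), rnorm(200, 0.5)),
                      obese = rep(c(FALSE, TRUE), each = 200))
      reject[i] <- compare_groups(d, "v")$p_value < 0.05
    }
    # closed-form power at this design is ~0.999
    expect_gt(mean(reject), 0.95)
  })
})
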