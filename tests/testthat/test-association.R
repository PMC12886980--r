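test_that("OLS reproduces closed-form solutions", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  f <- ols_fit(y, data.frame(x = x))
  # hand normal equations
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(f$coefficients$estimate, c(b0, b1), tolerance = 1e-10)
  # exact fit
  f2 <- ols_fit(2 * x, data.frame(x = x))
  expect_equal(f2$coefficients$estimate[2], 2, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1)
  expect_lt(max(abs(f2$residuals)), 1e-12)
  # CI contains the estimate; lm agreement
  set.seed(1)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  yy <- 1 + 0.5 * X$a - 0.3 * X$b + rnorm(50)
  f3 <- ols_fit(yy, X)
  lm3 <- lm(yy ~ a + b, X)
  expect_equal(f3$coefficients$estimate, unname(coef(lm3)), tolerance = 1e-10)
  expect_equal(f3$coefficients$se, unname(coef(summary(lm3))[, 2]),
               tolerance = 1e-10)
  expect_true(all(f3$coefficients$ci_lower <= f3$coefficients$estimate &
                    f3$coefficients$estimate <= f3$coefficients$ci_upper))
  expect_error(ols_fit(yy, data.frame(a = X$a, a2 = X$a)), "collinear")
})

test_that("the Breusch-Pagan statistic matches the auxiliary-regression oracle", {
  skip_if_not_installed("lmtest")
  set.seed(2)
  x <- rnorm(100)
  y <- 1 + x + rnorm(100, sd = abs(x) + 0.5)   # heteroskedastic
  f <- ols_fit(y, data.frame(x = x))
  ref <- lmtest::bptest(lm(y ~ x))
  expect_equal(f$bp_statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(f$bp_p, unname(ref$p.value), tolerance = 1e-8)
})

test_that("listwise deletion drops incomplete rows and reports n", {
  set.seed(3)
  X <- data.frame(a = rnorm(30))
  y <- X$a + rnorm(30)
  X$a[c(4, 9)] <- NA
  y[15] <- NA
  f <- ols_fit(y, X)
  expect_equal(f$n, 27)
})

test_that("adjusted contrasts recover injected category effects", {
  set.seed(4)
  n <- 2000
  cat_lab <- sample(c("normal", "moderate", "severe"), n, TRUE,
                    prob = c(0.5, 0.3, 0.2))
  z <- rnorm(n)
  y <- 200 + 5 * z - 8 * (cat_lab == "moderate") - 18 * (cat_lab == "severe") +
    rnorm(n, sd = 10)
  cohort <- data.frame(stunting_category = cat_lab, overall_score = y, z = z)
  ct <- adjusted_contrast(cohort, "overall_score", "z")
  sev <- ct[ct$category == "severe", ]
  expect_lt(abs(sev$estimate - (-18)), sev$estimate - sev$ci_lower)
  mod <- ct[ct$category == "moderate", ]
  expect_lt(abs(mod$estimate - (-8)), mod$estimate - mod$ci_lower)
  # no covariates -> raw group-mean differences
  ct0 <- adjusted_contrast(cohort, "overall_score")
  raw <- tapply(y, cat_lab, mean)
  expect_equal(ct0$estimate[ct0$category == "severe"],
               unname(raw["severe"] - raw["normal"]), tolerance = 1e-10)
})

test_that("pair association covers the three type combinations", {
  # monotone continuous pair -> Spearman 1
  expect_equal(pair_association(1:10, (1:10)^3, c("continuous", "continuous")), 1)
  # 2x2 identity table -> Cramer's V 1; independence -> ~0
  x <- rep(c("a", "b"), each = 10)
  expect_equal(pair_association(x, x, c("categorical", "categorical")), 1)
  ind_x <- rep(c("a", "b"), times = 10)
  ind_y <- rep(c("u", "u", "v", "v"), 5)
  v0 <- pair_association(ind_x, ind_y, c("categorical", "categorical"))
  expect_lt(v0, 0.35)
  expect_gte(v0, 0)
  # mixed pair vs brute-force ANOVA sums of squares
  set.seed(5)
  g <- rep(c("a", "b"), each = 50)
  cont <- ifelse(g == "a", -1, 1) + rnorm(100)
  got <- pair_association(cont, g, c("continuous", "categorical"))
  ssb <- sum(tapply(cont, g, function(v) length(v) * (mean(v) - mean(cont))^2))
  sst <- sum((cont - mean(cont))^2)
  expect_equal(got, sqrt(ssb / sst), tolerance = 1e-10)
  # role invariance for mixed, symmetry for like types
  expect_equal(got, pair_association(g, cont, c("categorical", "continuous")))
  expect_equal(pair_association(cont, rev(cont), c("continuous", "continuous")),
               pair_association(rev(cont), cont, c("continuous", "continuous")))
  expect_warning(out <- pair_association(rep(1, 10), 1:10,
                                         c("continuous", "continuous")),
                 "constant")
  expect_true(is.na(out))
})

test_that("Cramer's V vanishes on exact product-of-margins tables", {
  x <- rep(c("a", "a", "b"), times = 8)
  y <- rep(c("u", "v"), each = 12)
  v <- pair_association(x, y, c("categorical", "categorical"))
  expect_equal(v, 0, tolerance = 1e-10)
})

test_that("block eligibility enforces the size-4 and 0.2 rules", {
  set.seed(6)
  n <- 200
  f <- rnorm(n)
  strong <- as.data.frame(sapply(1:5, function(i) f + rnorm(n, sd = 0.5)))
  types5 <- rep("continuous", 5)
  res <- screen_block(strong, types5)
  expect_true(res$eligible)
  expect_gte(res$median_association, 0.5)
  expect_equal(unname(diag(res$matrix)), rep(1, 5))
  expect_equal(res$matrix, t(res$matrix))

  # 3 well-correlated indicators still ineligible (size rule)
  expect_false(screen_block(strong[, 1:3], types5[1:3])$eligible)

  # 4 indicators with near-zero associations ineligible (threshold rule)
  weak <- as.data.frame(matrix(rnorm(n * 4), n))
  res_w <- screen_block(weak, rep("continuous", 4))
  expect_false(res_w$eligible)
  expect_lt(res_w$median_association, 0.2)
})
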