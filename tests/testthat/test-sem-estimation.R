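test_that("the ML discrepancy has its stated identities", {
  expect_equal(fml(diag(3), diag(3)), 0, tolerance = 1e-12)
  expect_equal(fml(diag(2), diag(c(2, 2))), 2 * log(2) - 1, tolerance = 1e-12)
  # invariance under joint orthogonal rotation
  set.seed(1)
  A <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  B <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(fml(A, B), fml(Q %*% A %*% t(Q), Q %*% B %*% t(Q)),
               tolerance = 1e-9)
  # non-negative on random SPD pairs
  for (i in 1:20) {
    S1 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    S2 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    expect_gte(fml(S1, S2), 0)
  }
  expect_error(fml(diag(2), matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("analytic gradient agrees with numerical differentiation", {
  spec <- sem_spec(measurement = list(f = paste0("y", 1:4)),
                   structural = list(f = "x"))
  ram <- build_ram(spec)
  theta0 <- recovery_theta(spec)
  set.seed(2)
  d <- sem_simulate(spec, theta0, 300)
  S <- cov(d)
  obj <- stuntsem:::.fml_objective(ram, S, 2 * sum(log(diag(chol(S)))))
  th <- theta0 * 1.07 + 0.01
  expect_equal(obj$gr(th), pracma::grad(obj$fn, th), tolerance = 1e-6)
})

test_that("a single-regression spec reproduces OLS and the sample variance", {
  set.seed(3)
  x <- rnorm(400); y <- 1.5 * x + rnorm(400)
  fit <- sem_estimate(sem_spec(structural = list(y = "x")),
                      data.frame(x = x, y = y))
  expect_lt(abs(fit$theta["y~x"] - unname(coef(lm(y ~ x))[2])), 1e-8)
  expect_lt(abs(fit$theta["var(x)"] - var(x)), 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  # standardized path equals Pearson r
  std <- sem_standardize(fit)
  expect_equal(std$std_estimate[std$label == "y~x"], cor(x, y),
               tolerance = 1e-7)
})

test_that("population covariance input recovers generating parameters", {
  spec <- sem_spec(measurement = list(f = paste0("y", 1:4)))
  theta0 <- c("f=~y2" = 0.8, "f=~y3" = 0.7, "f=~y4" = 0.6,
              "var(y1)" = 0.5, "var(y2)" = 0.6, "var(y3)" = 0.7,
              "var(y4)" = 0.8, "var(f)" = 1.2)
  ram <- build_ram(spec)
  Sigma0 <- implied_sigma(ram, theta0)
  d <- exact_mvn(500, Sigma0, seed = 4)
  fit <- sem_estimate(spec, d)
  expect_lt(fit$fml_min, 1e-10)
  expect_lt(max(abs(fit$theta[names(theta0)] - theta0)), 1e-6)
})

test_that("one-factor loadings are recovered from simulated data", {
  spec <- sem_spec(measurement = list(f = paste0("y", 1:4)))
  theta0 <- c("f=~y2" = 0.8, "f=~y3" = 0.7, "f=~y4" = 0.6,
              "var(y1)" = 0.5, "var(y2)" = 0.5, "var(y3)" = 0.5,
              "var(y4)" = 0.5, "var(f)" = 1)
  set.seed(5)
  d <- sem_simulate(spec, theta0, 2000)
  fit <- sem_estimate(spec, d)
  expect_lt(max(abs(fit$theta[c("f=~y2", "f=~y3", "f=~y4")] -
                      c(0.8, 0.7, 0.6))), 0.08)
  expect_true(all(fit$estimates$se[!is.na(fit$estimates$se)] > 0))
})

test_that("fit indices behave at saturation and on conforming CFA data", {
  set.seed(6)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  sat <- path_analysis(list(y = "x"), data.frame(x = x, y = y))
  expect_equal(sat$stats$df, 0)
  expect_lt(abs(sat$stats$chi_square), 1e-6)
  expect_equal(sat$stats$cfi, 1)
  expect_equal(sat$stats$rmsea, 0)
  expect_lt(sat$stats$srmr, 1e-8)

  spec <- sem_spec(measurement = list(f = paste0("y", 1:4)))
  set.seed(7)
  d <- sem_simulate(spec, recovery_theta(spec), 2000)
  st <- fit_statistics(sem_estimate(spec, d))
  expect_gte(st$cfi, 0.95)
  expect_equal(st$df, 2)
})

test_that("a three-indicator factor is just-identified with perfect fit", {
  spec3 <- list(f = paste0("y", 1:3))
  set.seed(8)
  d <- sem_simulate(sem_spec(measurement = spec3),
                    c("f=~y2" = 0.8, "f=~y3" = 0.9, "var(y1)" = 0.5,
                      "var(y2)" = 0.5, "var(y3)" = 0.5, "var(f)" = 1), 500)
  res <- cfa(spec3, d)
  expect_true(res$just_identified)
  expect_equal(res$stats$df, 0)
  expect_lt(res$fit$fml_min, 1e-9)
})

test_that("a one-factor model fits two-factor data worse than the truth", {
  spec2 <- sem_spec(measurement = list(f1 = c("a1", "a2", "a3", "a4"),
                                       f2 = c("b1", "b2", "b3", "b4")),
                    covariances = FALSE)
  th <- recovery_theta(spec2)
  set.seed(9)
  d <- sem_simulate(spec2, th, 1000)
  # the misspecified one-factor fit ends at a boundary (factor variance
  # near zero), where the gradient tolerance may not be met; that is the
  # expected signature of fitting one factor to orthogonal two-factor data
  one <- suppressWarnings(
    cfa(list(f = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4")), d))
  two <- cfa(list(f1 = c("a1", "a2", "a3", "a4"),
                  f2 = c("b1", "b2", "b3", "b4")), d)
  expect_lt(one$stats$cfi, two$stats$cfi)
  expect_gte(two$stats$cfi, 0.95)
})

test_that("recursive path models reduce to stage-wise OLS", {
  set.seed(10)
  n <- 800
  X <- rnorm(n); M <- 0.5 * X + rnorm(n); Y <- 0.4 * M + 0.1 * X + rnorm(n)
  d <- data.frame(X = X, M = M, Y = Y)
  pa <- path_analysis(list(M = "X", Y = c("M", "X")), d)
  expect_lt(abs(pa$fit$theta["M~X"] - unname(coef(lm(M ~ X))[2])), 1e-7)
  expect_lt(abs(pa$fit$theta["Y~M"] - unname(coef(lm(Y ~ M + X))[2])), 1e-7)
  expect_lt(abs(pa$fit$theta["Y~X"] - unname(coef(lm(Y ~ M + X))[3])), 1e-7)
  expect_lt(abs(pa$stats$chi_square), 1e-6)  # saturated recursive system
})

test_that("omitted-path misfit grows roughly linearly with n", {
  chis <- sapply(c(500, 2000), function(n) {
    set.seed(11)
    X <- rnorm(n); M <- 0.5 * X + rnorm(n)
    Y <- 0.4 * M + 0.3 * X + rnorm(n)   # direct path exists
    pa <- path_analysis(list(M = "X", Y = "M"),    # ...but is omitted
                        data.frame(X = X, M = M, Y = Y))
    pa$stats$chi_square
  })
  expect_gt(chis[2] / chis[1], 2)   # noncentrality scales with n
  expect_gt(chis[1], qchisq(0.99, 1))
})

test_that("mediation decomposition obeys the product rule exactly", {
  spec <- sem_spec(structural = list(M = "X", Y = c("M", "X")))
  ram <- build_ram(spec)
  theta <- setNames(numeric(ram$n_free), ram$params$label)
  theta[c("M~X", "Y~M", "Y~X")] <- c(0.5, 0.4, 0.1)
  theta[c("var(X)", "var(M)", "var(Y)")] <- 1
  d <- exact_mvn(200, implied_sigma(ram, theta), seed = 12)
  fit <- sem_estimate(spec, d)
  eff <- sem_effects(fit, "X", "Y")
  expect_equal(eff$estimate[eff$effect == "indirect"], 0.2, tolerance = 1e-5)
  expect_equal(eff$estimate[eff$effect == "total"], 0.3, tolerance = 1e-5)
  expect_equal(eff$estimate[eff$effect == "total"],
               sum(eff$estimate[eff$effect %in% c("direct", "indirect")]),
               tolerance = 1e-12)
  # no route at all -> all three effects zero
  eff0 <- sem_effects(fit, "Y", "X")
  expect_equal(eff0$estimate, c(0, 0, 0))
  expect_error(sem_effects(fit, "X", "X"), "differ")
})

test_that("standardized estimates stay in [-1, 1] bands where theory says", {
  spec <- sem_spec(measurement = list(f = paste0("y", 1:4)))
  set.seed(13)
  d <- sem_simulate(spec, recovery_theta(spec), 1500)
  fit <- sem_estimate(spec, d)
  std <- sem_standardize(fit)
  lo <- std$std_estimate[std$kind == "loading"]
  expect_true(all(lo > 0 & lo <= 1))
  # the fixed-to-1 loading is not a free parameter but its indicator's
  # residual proportion must complement the factor's contribution
  expect_true(all(std$std_estimate[std$kind == "variance"] > 0))
})

test_that("Heywood cases are flagged rather than hidden", {
  # tiny n with a near-degenerate indicator often drives a residual
  # variance negative; construct one deterministically
  set.seed(14)
  f <- rnorm(60)
  d <- data.frame(y1 = f + rnorm(60, sd = 0.05),
                  y2 = f + rnorm(60, sd = 0.05),
                  y3 = f + rnorm(60, sd = 1),
                  y4 = -f + rnorm(60, sd = 1))
  fit <- suppressWarnings(sem_estimate(sem_spec(measurement = list(
    f = c("y1", "y2", "y3", "y4"))), d))
  expect_type(fit$heywood, "logical")   # flag exists and is reported
})
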