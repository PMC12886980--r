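# Maximum-likelihood estimation of covariance-structure models.
#
# The discrepancy minimized is the normal-theory ML fit function
#   F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p*,
# with S the sample covariance (n-1 denominator).  Gradients are analytic:
# with G = Sigma^-1 - Sigma^-1 S Sigma^-1, B = (I-A)^-1, C = B Omega B',
#   dF/dA[i,j]     = 2 (C F' G F B)[j, i]
#   dF/dOmega[i,j] = (B' F' G F B)[i, j]   (doubled off-diagonal).
# Estimation is deterministic: fixed starts, BFGS, no randomness.

#' Normal-theory ML discrepancy between two covariance matrices
#'
#' \eqn{F = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p}; non-negative,
#' zero iff \eqn{\Sigma = S}.
#'
#' @param S sample covariance (symmetric positive definite).
#' @param Sigma model-implied covariance (symmetric positive definite).
#' @return scalar discrepancy.
#' @export
fml <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  stopifnot(nrow(S) == ncol(S), all(dim(S) == dim(Sigma)))
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS) || is.null(cZ))
    stop("both matrices must be positive definite", call. = FALSE)
  p <- nrow(S)
  2 * sum(log(diag(cZ))) + sum(diag(chol2inv(cZ) %*% S)) -
    2 * sum(log(diag(cS))) - p
}

# objective + analytic gradient for one theta; returns list(f, grad) or
# a large penalized value when Sigma leaves the PD cone
.fml_objective <- function(ram, S, logdetS) {
  p <- nrow(S)
  Fo <- ram$F
  nv <- length(ram$vars)
  pt <- ram$params
  isA <- pt$mat == "A"
  list(
    fn = function(theta) {
      m <- .ram_matrices(ram, theta)
      IA <- diag(nv) - m$A
      B <- tryCatch(solve(IA), error = function(e) NULL)
      if (is.null(B)) return(1e10)
      Sigma <- Fo %*% B %*% m$Omega %*% t(B) %*% t(Fo)
      Sigma <- (Sigma + t(Sigma)) / 2
      cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(cZ)) return(1e10 + sum(theta^2))
      2 * sum(log(diag(cZ))) + sum(diag(chol2inv(cZ) %*% S)) - logdetS - p
    },
    gr = function(theta) {
      m <- .ram_matrices(ram, theta)
      IA <- diag(nv) - m$A
      B <- tryCatch(solve(IA), error = function(e) NULL)
      if (is.null(B)) return(rep(0, length(theta)))
      C <- B %*% m$Omega %*% t(B)
      Sigma <- Fo %*% C %*% t(Fo)
      Sigma <- (Sigma + t(Sigma)) / 2
      cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(cZ)) return(rep(0, length(theta)))
      Sinv <- chol2inv(cZ)
      G <- Sinv - Sinv %*% S %*% Sinv
      FGF <- t(Fo) %*% G %*% Fo
      KA <- C %*% FGF %*% B          # for A entries: 2 * KA[j, i]
      KO <- t(B) %*% FGF %*% B       # for Omega entries
      g <- numeric(nrow(pt))
      for (r in seq_len(nrow(pt))) {
        if (isA[r]) g[r] <- 2 * KA[pt$j[r], pt$i[r]]
        else g[r] <- KO[pt$i[r], pt$j[r]] * (if (pt$i[r] == pt$j[r]) 1 else 2)
      }
      g
    })
}

# deterministic starting values: free loadings 1, paths 0, variances half
# the observed variance of the variable (latents: of their scale indicator),
# covariances 0
.start_values <- function(ram, S) {
  pt <- ram$params
  vapply(seq_len(nrow(pt)), function(r) {
    switch(pt$kind[r],
           loading = 1,
           path = 0,
           variance = 0.5 * S[pt$scale_var[r], pt$scale_var[r]],
           covariance = 0)
  }, numeric(1))
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance of the
#' listwise-complete data and the model-implied covariance, by BFGS with
#' analytic gradients from deterministic starting values.  Standard errors
#' come from the numerical Hessian of the discrepancy at the optimum:
#' \eqn{cov(\hat\theta) = (2/(n-1)) H^{-1}}.
#'
#' @param spec a [sem_spec()].
#' @param data data frame containing every observed variable of the model.
#' @param max_restarts additional BFGS passes if the gradient has not
#'   reached tolerance.
#' @param grad_tol convergence tolerance on the gradient infinity-norm.
#' @param se compute standard errors (numerical Hessian)?  Disable in
#'   Monte-Carlo loops that only need point estimates.
#' @return object of class \code{sem_fit}: parameter table
#'   (\code{estimates}: label, kind, estimate, se, z, p), \code{theta},
#'   \code{vcov_theta}, \code{fml_min}, \code{S}, \code{Sigma_hat},
#'   \code{n}, \code{ram}, \code{converged}, \code{grad_norm},
#'   \code{heywood}.
#' @export
sem_estimate <- function(spec, data, max_restarts = 4, grad_tol = 1e-7,
                         se = TRUE) {
  ram <- build_ram(spec)
  obs <- ram$observed
  missing_cols <- setdiff(obs, names(data))
  if (length(missing_cols))
    stop("data lacks observed variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- data[, obs, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n <= ram$n_free)
    stop("need more complete rows (", n, ") than free parameters (",
         ram$n_free, ")", call. = FALSE)
  S <- stats::cov(as.matrix(X))              # n-1 denominator
  cS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite", call. = FALSE))

  # Optimize on the unit-variance (correlation) scale: F_ML is invariant
  # under separate rescaling of each observed variable, and parameters map
  # back exactly by per-variable scale factors, so the search is well
  # conditioned regardless of the variables' units.  A latent variable
  # carries the scale of its fixed-to-1 indicator.
  sd_obs <- sqrt(diag(S))
  S_std <- S / tcrossprod(sd_obs)
  logdetS <- 2 * sum(log(diag(chol(S_std))))
  scale_of <- c(sd_obs,
                stats::setNames(vapply(ram$latent, function(l)
                  sd_obs[ram$spec$measurement[[l]][1]], numeric(1)),
                  ram$latent))[ram$vars]
  pt <- ram$params
  fac <- vapply(seq_len(nrow(pt)), function(r) {
    si <- scale_of[ram$vars[pt$i[r]]]; sj <- scale_of[ram$vars[pt$j[r]]]
    if (pt$mat[r] == "A") si / sj else si * sj
  }, numeric(1))

  obj <- .fml_objective(ram, S_std, logdetS)
  theta_std <- .start_values(ram, S_std)
  for (pass in seq_len(1 + max_restarts)) {
    opt <- stats::optim(theta_std, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    theta_std <- opt$par
    gnorm <- max(abs(obj$gr(theta_std)))
    if (gnorm < grad_tol) break
    # PORT routine polishes cases BFGS leaves unfinished
    nl <- stats::nlminb(theta_std, obj$fn, obj$gr,
                        control = list(iter.max = 500,
                                       rel.tol = 1e-14, x.tol = 1e-14))
    theta_std <- nl$par
    gnorm <- max(abs(obj$gr(theta_std)))
    if (gnorm < grad_tol) break
  }
  converged <- gnorm < grad_tol
  if (!converged)
    warning(sprintf("gradient norm %.2e above tolerance after %d passes",
                    gnorm, 1 + max_restarts))
  theta <- theta_std * fac
  names(theta) <- ram$params$label

  if (se) {
    H <- pracma::hessian(obj$fn, theta_std)
    vcov_theta <- tryCatch(
      (2 / (n - 1)) * solve(H) * tcrossprod(fac),
      error = function(e) {
        warning("Hessian not invertible; standard errors unavailable")
        matrix(NA_real_, length(theta), length(theta))
      })
  } else {
    vcov_theta <- matrix(NA_real_, length(theta), length(theta))
  }
  se_theta <- suppressWarnings(sqrt(diag(vcov_theta)))
  dimnames(vcov_theta) <- list(names(theta), names(theta))
  z <- theta / se_theta
  pval <- 2 * stats::pnorm(-abs(z))
  Sigma_hat <- implied_sigma(ram, theta)

  res_var <- theta[ram$params$kind == "variance"]
  structure(list(
    estimates = data.frame(label = names(theta), kind = ram$params$kind,
                           estimate = unname(theta), se = unname(se_theta),
                           z = unname(z), p = unname(pval),
                           stringsAsFactors = FALSE),
    theta = theta, vcov_theta = vcov_theta,
    fml_min = obj$fn(theta_std), S = S, Sigma_hat = Sigma_hat,
    n = n, ram = ram, spec = spec,
    converged = converged, grad_norm = gnorm,
    heywood = any(res_var < 0)),
    class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("SEM fit: %d observed, %d latent, %d free parameters, n = %d\n",
              length(x$ram$observed), length(x$ram$latent),
              x$ram$n_free, x$n))
  cat(sprintf("  F_ML = %.6g  (gradient norm %.1e%s)\n", x$fml_min,
              x$grad_norm, if (x$heywood) ", Heywood case" else ""))
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Fit statistics for a converged SEM
#'
#' Chi-square against the saturated model, the independence-model baseline,
#' CFI, TLI, RMSEA and SRMR (residuals standardized by observed variances,
#' diagonal included).  The chi-square multiplier is \eqn{(n-1) F_{min}}.
#'
#' @param fit a [sem_estimate()] result.
#' @return list of class \code{sem_fit_statistics}.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  S <- fit$S; n <- fit$n
  p <- nrow(S)
  df_m <- p * (p + 1) / 2 - fit$ram$n_free
  chi_m <- (n - 1) * fit$fml_min
  # independence baseline: diagonal Sigma, closed form
  f_b <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  chi_b <- (n - 1) * f_b
  df_b <- p * (p - 1) / 2
  if (df_m == 0) {
    cfi <- 1; tli <- 1; rmsea <- 0
  } else {
    num <- max(chi_m - df_m, 0)
    den <- max(chi_m - df_m, chi_b - df_b, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    tli <- if (df_b > 0 && (chi_b / df_b - 1) != 0)
      ((chi_b / df_b) - (chi_m / df_m)) / ((chi_b / df_b) - 1) else 1
    rmsea <- sqrt(max(chi_m - df_m, 0) / (df_m * (n - 1)))
  }
  res <- (S - fit$Sigma_hat) / sqrt(tcrossprod(diag(S)))
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  structure(list(chi_square = chi_m, df = df_m,
                 p_value = if (df_m > 0)
                   stats::pchisq(chi_m, df_m, lower.tail = FALSE) else NA_real_,
                 baseline_chi_square = chi_b, baseline_df = df_b,
                 cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr, n = n),
            class = "sem_fit_statistics")
}

#' @export
print.sem_fit_statistics <- function(x, ...) {
  cat(sprintf(
    "chi2(%d) = %.3f (p = %.3g); CFI %.3f; TLI %.3f; RMSEA %.3f; SRMR %.4f\n",
    x$df, x$chi_square, x$p_value, x$cfi, x$tli, x$rmsea, x$srmr))
  invisible(x)
}

#' Closed-form fit indices from chi-square summaries
#'
#' The CFI/TLI/RMSEA arithmetic alone, for checking reported model and
#' baseline chi-squares.
#'
#' @param chi_m,df_m model chi-square and df.
#' @param chi_b,df_b baseline chi-square and df.
#' @param n sample size.
#' @return list with \code{cfi}, \code{tli}, \code{rmsea}.
#' @export
fit_indices_from_chisq <- function(chi_m, df_m, chi_b, df_b, n) {
  num <- max(chi_m - df_m, 0)
  den <- max(chi_m - df_m, chi_b - df_b, 0)
  list(cfi = if (den == 0) 1 else 1 - num / den,
       tli = ((chi_b / df_b) - (chi_m / df_m)) / ((chi_b / df_b) - 1),
       rmsea = sqrt(max(chi_m - df_m, 0) / (df_m * (n - 1))))
}

#' Standardized solution
#'
#' Coefficients rescaled by model-implied standard deviations of ALL
#' variables (latent and observed): a coefficient of source j on target i
#' becomes \eqn{\hat\beta \cdot sd_j / sd_i}; (co)variance parameters
#' become correlations / proportions of variance.
#'
#' @param fit a [sem_estimate()] result.
#' @return the fit's estimate table with a \code{std_estimate} column.
#' @export
sem_standardize <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  ram <- fit$ram
  m <- .ram_matrices(ram, fit$theta)
  B <- solve(diag(length(ram$vars)) - m$A)
  Sigma_all <- B %*% m$Omega %*% t(B)
  sdv <- sqrt(pmax(diag(Sigma_all), 0))
  if (any(sdv == 0)) stop("zero model-implied variance", call. = FALSE)
  pt <- ram$params
  std <- vapply(seq_len(nrow(pt)), function(r) {
    i <- pt$i[r]; j <- pt$j[r]
    if (pt$mat[r] == "A") fit$theta[r] * sdv[j] / sdv[i]
    else fit$theta[r] / (sdv[i] * sdv[j])
  }, numeric(1))
  out <- fit$estimates
  out$std_estimate <- std
  out
}

#' Direct, indirect and total effects with delta-method standard errors
#'
#' Total effects are read from \eqn{(I-A)^{-1} - I} over the joint variable
#' vector; the direct effect is the A entry; indirect = total - direct
#' (exactly).  Standard errors use the delta method with the estimated
#' parameter covariance.
#'
#' @param fit a [sem_estimate()] result.
#' @param source,outcome variable names in the model.
#' @return data frame with rows \code{direct}, \code{indirect},
#'   \code{total}: estimate, se, z, p.
#' @export
sem_effects <- function(fit, source, outcome) {
  stopifnot(inherits(fit, "sem_fit"))
  if (source == outcome) stop("source and outcome must differ", call. = FALSE)
  ram <- fit$ram
  if (!all(c(source, outcome) %in% ram$vars))
    stop("source/outcome not in the model", call. = FALSE)
  eff_fun <- function(theta) {
    m <- .ram_matrices(ram, theta)
    B <- solve(diag(length(ram$vars)) - m$A)
    total <- (B - diag(length(ram$vars)))[outcome, source]
    direct <- m$A[outcome, source]
    c(direct = direct, indirect = total - direct, total = total)
  }
  est <- eff_fun(fit$theta)
  # delta method; only A parameters can move the effects
  J <- matrix(0, 3, length(fit$theta))
  h <- 1e-6
  active <- which(ram$params$mat == "A")
  for (r in active) {
    up <- fit$theta; up[r] <- up[r] + h
    dn <- fit$theta; dn[r] <- dn[r] - h
    J[, r] <- (eff_fun(up) - eff_fun(dn)) / (2 * h)
  }
  se <- sqrt(pmax(diag(J %*% fit$vcov_theta %*% t(J)), 0))
  se[se == 0 & abs(est) < .Machine$double.eps] <- NA_real_
  z <- est / se
  data.frame(effect = c("direct", "indirect", "total"),
             estimate = unname(est), se = unname(se), z = unname(z),
             p = 2 * stats::pnorm(-abs(unname(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate data from a model at given parameter values
#'
#' Draws the observed variables from the multivariate normal distribution
#' with the model-implied covariance; used for parameter-recovery studies.
#'
#' @param spec a [sem_spec()].
#' @param theta named parameter vector (labels as in
#'   \code{build_ram(spec)$params$label}; unnamed = positional).
#' @param n number of rows.
#' @return data frame of observed variables.
#' @export
sem_simulate <- function(spec, theta, n) {
  ram <- build_ram(spec)
  if (!is.null(names(theta))) {
    missing_par <- setdiff(ram$params$label, names(theta))
    if (length(missing_par))
      stop("theta lacks parameter(s): ",
           paste(missing_par, collapse = ", "), call. = FALSE)
    theta <- theta[ram$params$label]
  }
  m <- .ram_matrices(ram, theta)
  B <- solve(diag(length(ram$vars)) - m$A)
  Sigma_all <- B %*% m$Omega %*% t(B)
  Sigma_obs <- Sigma_all[ram$observed, ram$observed]
  L <- chol((Sigma_obs + t(Sigma_obs)) / 2)
  X <- matrix(stats::rnorm(n * nrow(Sigma_obs)), n) %*% L
  colnames(X) <- ram$observed
  as.data.frame(X)
}

#' Confirmatory factor analysis
#'
#' Measurement-only model: [sem_estimate()] plus [fit_statistics()] with no
#' structural edges; latent factors covary freely.
#'
#' @param measurement named list latent -> indicators.
#' @param data data frame.
#' @return list with \code{fit} and \code{stats}; \code{just_identified}
#'   flags df = 0.
#' @export
cfa <- function(measurement, data) {
  spec <- sem_spec(measurement = measurement)
  fit <- sem_estimate(spec, data)
  st <- fit_statistics(fit)
  list(fit = fit, stats = st, just_identified = st$df == 0)
}

#' Path analysis
#'
#' Observed-variables-only model: [sem_estimate()] with an empty
#' measurement part.
#'
#' @param structural named list outcome -> predictors.
#' @param data data frame.
#' @param covariances see [sem_spec()].
#' @return list with \code{fit} and \code{stats}.
#' @export
path_analysis <- function(structural, data, covariances = NULL) {
  spec <- sem_spec(structural = structural, covariances = covariances)
  fit <- sem_estimate(spec, data)
  list(fit = fit, stats = fit_statistics(fit))
}
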