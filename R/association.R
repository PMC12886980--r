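# Ordinary-least-squares contrasts with diagnostics and the mixed-type
# pairwise association matrix that gates latent-construct eligibility.

#' Ordinary least squares with classical inference and Breusch-Pagan test
#'
#' Solves the normal equations by QR, reports classical standard errors,
#' t-based 95% confidence intervals, R-squared, numeric influence summaries
#' (max |standardized residual|, max Cook's distance) and the Breusch-Pagan
#' homoskedasticity statistic \eqn{n R^2_{aux}} from regressing squared
#' residuals on the design, referred to chi-square with (p - 1) df.
#' Rows with any missing value are dropped (listwise) and the retained n
#' reported.
#'
#' @param response numeric response vector.
#' @param design numeric matrix or data frame of predictors; an intercept
#'   column is added unless one is already present (constant column).
#' @return object of class \code{ols_fit}: \code{coefficients} data frame
#'   (estimate, se, t, p, ci_lower, ci_upper), \code{residuals},
#'   \code{fitted}, \code{r_squared}, \code{n}, \code{bp_statistic},
#'   \code{bp_df}, \code{bp_p}, \code{max_std_residual}, \code{max_cooks}.
#' @export
ols_fit <- function(response, design) {
  X <- as.matrix(as.data.frame(design))
  if (!any(apply(X, 2, function(c) all(c == c[1], na.rm = TRUE))))
    X <- cbind("(Intercept)" = 1, X)
  ok <- stats::complete.cases(response, X)
  y <- response[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df_res <- n - p
  sigma2 <- sum(resid^2) / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tcrit <- stats::qt(0.975, df_res)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1

  # Breusch-Pagan: n * R^2 of the auxiliary regression of e^2 on X
  e2 <- resid^2
  aux <- qr.coef(qrX, e2)
  aux_fit <- drop(X %*% aux)
  aux_r2 <- if (sum((e2 - mean(e2))^2) > 0)
    1 - sum((e2 - aux_fit)^2) / sum((e2 - mean(e2))^2) else 0
  bp <- n * aux_r2
  bp_df <- p - 1
  bp_p <- if (bp_df > 0) stats::pchisq(bp, bp_df, lower.tail = FALSE) else NA_real_

  h <- rowSums((X %*% XtXinv) * X)           # leverage
  std_res <- resid / sqrt(sigma2 * pmax(1 - h, .Machine$double.eps))
  cooks <- std_res^2 * h / ((1 - h) * p)

  structure(list(
    coefficients = data.frame(
      term = colnames(X), estimate = unname(beta), se = se, t = tval,
      p = pval, ci_lower = unname(beta) - tcrit * se,
      ci_upper = unname(beta) + tcrit * se,
      row.names = NULL, stringsAsFactors = FALSE),
    residuals = resid, fitted = fitted, r_squared = r2, n = n,
    bp_statistic = bp, bp_df = bp_df, bp_p = bp_p,
    max_std_residual = max(abs(std_res)), max_cooks = max(cooks)),
    class = "ols_fit")
}

#' Adjusted mean differences by stunting category
#'
#' Dummy-coded OLS of an outcome on stunting category (reference
#' \code{normal}) plus covariates; returns the moderate and severe
#' coefficients with 95% CIs, the layout of an adjusted-contrast table.
#'
#' @param cohort cohort data frame.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names (possibly
#'   empty, giving raw group-mean differences).
#' @param exposure name of the category column (default
#'   \code{stunting_category}).
#' @return data frame with one row per non-reference category: estimate,
#'   se, ci bounds, p, n.
#' @export
adjusted_contrast <- function(cohort, outcome, covariates = character(),
                              exposure = "stunting_category") {
  cats <- factor(cohort[[exposure]], levels = c("normal", "moderate", "severe"))
  dummies <- sapply(levels(cats)[-1], function(l) as.numeric(cats == l))
  X <- cbind(as.data.frame(dummies),
             cohort[, covariates, drop = FALSE])
  ok <- stats::complete.cases(cohort[[outcome]], X, cats)
  if (any(table(cats[ok]) == 0))
    stop("empty stunting category after listwise deletion", call. = FALSE)
  fit <- ols_fit(cohort[[outcome]][ok], X[ok, , drop = FALSE])
  co <- fit$coefficients
  out <- co[co$term %in% levels(cats)[-1],
            c("term", "estimate", "se", "ci_lower", "ci_upper", "p")]
  names(out)[1] <- "category"
  out$n <- fit$n
  rownames(out) <- NULL
  out
}

#' Mixed-type pairwise association
#'
#' Spearman's r if both variables are continuous; bias-uncorrected Cramer's
#' V \eqn{\sqrt{\chi^2 / (n\,\min(r-1, c-1))}} if both are categorical; the
#' square root of the one-way ANOVA R-squared (continuous variable as
#' response) for a mixed pair.
#'
#' @param x,y the two variables.
#' @param types length-2 character vector in
#'   \{\code{"continuous"}, \code{"categorical"}\}.
#' @return a single association value, or NA (with a warning) if either
#'   variable is constant.
#' @export
pair_association <- function(x, y, types) {
  stopifnot(length(types) == 2,
            all(types %in% c("continuous", "categorical")))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant variable in pair; association undefined")
    return(NA_real_)
  }
  if (all(types == "continuous")) {
    return(stats::cor(x, y, method = "spearman"))
  }
  if (all(types == "categorical")) {
    tab <- table(x, y)
    chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    return(unname(sqrt(chi2 / (sum(tab) * min(nrow(tab) - 1, ncol(tab) - 1)))))
  }
  # mixed: continuous response, categorical grouping
  if (types[1] == "continuous") { resp <- x; grp <- y } else { resp <- y; grp <- x }
  grp <- factor(grp)
  fit <- stats::aov(resp ~ grp)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  sqrt(ss[1] / sum(ss))
}

#' Pairwise association matrix over a variable block
#'
#' @param block data frame of the block's variables.
#' @param types named (or positional) character vector of
#'   \code{"continuous"}/\code{"categorical"} per variable.
#' @return symmetric matrix with unit diagonal; class
#'   \code{association_matrix}.
#' @export
association_matrix <- function(block, types) {
  stopifnot(ncol(block) >= 2, length(types) == ncol(block))
  p <- ncol(block)
  m <- diag(1, p)
  dimnames(m) <- list(names(block), names(block))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    m[i, j] <- m[j, i] <-
      pair_association(block[[i]], block[[j]], types[c(i, j)])
  }
  structure(m, class = c("association_matrix", "matrix"))
}

#' Latent-construct eligibility of a variable block
#'
#' A block is eligible to form a latent construct iff it has at least
#' \code{min_indicators} variables (default 4, required for an identified
#' measurement model) and the median off-diagonal pairwise association is
#' at least \code{threshold} (default 0.2).
#'
#' @param block data frame of candidate indicator variables.
#' @param types per-variable types (see [pair_association()]).
#' @param threshold association cut-off.
#' @param min_indicators minimum block size.
#' @return list: \code{eligible} (logical), \code{n_indicators},
#'   \code{median_association}, \code{matrix}.
#' @export
screen_block <- function(block, types, threshold = 0.2,
                         min_indicators = 4L) {
  m <- association_matrix(block, types)
  off <- abs(m[upper.tri(m)])
  if (all(is.na(off))) stop("all-constant block", call. = FALSE)
  med <- stats::median(off, na.rm = TRUE)
  list(eligible = ncol(block) >= min_indicators && med >= threshold,
       n_indicators = ncol(block), median_association = med, matrix = m)
}
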