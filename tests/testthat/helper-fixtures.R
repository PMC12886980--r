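# shared builders for small in-code fixtures

small_generator <- function(seed = 11, n = 120, ...) {
  generator_config(n_children = n, seed = seed, n_taxa = 60,
                   n_families = 8, depth_mean = 2000, ...)
}

# draw n rows with EXACT sample covariance Sigma (empirical whitening then
# coloring), so a fitted model sees the population covariance
exact_mvn <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- nrow(Sigma)
  Z <- matrix(rnorm(n * p), n)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  as.data.frame(X)
}

# parameter values for each catalog topology, used in recovery studies:
# loadings in a 0.7-1.1 band, paths of moderate size, unit exogenous
# variances with 0.2 covariances, residual variances 0.5
recovery_theta <- function(spec) {
  ram <- build_ram(spec)
  pt <- ram$params
  vals <- numeric(nrow(pt))
  load_seq <- c(0.8, 0.9, 0.7, 1.1, 0.75, 0.85, 0.95, 1.05)
  path_seq <- c(0.3, -0.25, 0.2, 0.35, -0.3, 0.25, 0.15, -0.2, 0.3, 0.2,
                0.25, -0.15, 0.2, 0.3, -0.25)
  il <- 0; ip <- 0
  for (r in seq_len(nrow(pt))) {
    vals[r] <- switch(pt$kind[r],
                      loading = { il <- il + 1
                        load_seq[(il - 1) %% length(load_seq) + 1] },
                      path = { ip <- ip + 1
                        path_seq[(ip - 1) %% length(path_seq) + 1] },
                      variance = if (pt$i[r] <= length(ram$observed) ||
                                     !ram$vars[pt$i[r]] %in%
                                       stuntsem:::.exogenous_vars(spec))
                        0.5 else 1,
                      covariance = 0.2)
  }
  # exogenous variances (latent or observed) at 1
  exo <- stuntsem:::.exogenous_vars(spec)
  for (r in seq_len(nrow(pt)))
    if (pt$kind[r] == "variance" && ram$vars[pt$i[r]] %in% exo) vals[r] <- 1
  names(vals) <- pt$label
  vals
}
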