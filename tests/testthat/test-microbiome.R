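test_that("relative abundance normalizes rows and is scale invariant", {
  m <- rbind(a = c(2, 2, 4), b = c(1, 0, 0))
  ra <- relative_abundance(m)
  expect_equal(ra["a", ], c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  expect_equal(unname(rowSums(ra)), c(1, 1), tolerance = 1e-12)
  expect_equal(relative_abundance(m * 10), ra)
  one <- matrix(5, 3, 1, dimnames = list(letters[1:3], "t"))
  expect_true(all(relative_abundance(one) == 1))
  zero <- rbind(ok = c(1, 1), empty = c(0, 0))
  expect_error(relative_abundance(zero), "empty")
})

test_that("alpha diversity matches direct summation and symmetry limits", {
  uni <- matrix(7, 1, 4)
  d <- alpha_diversity(uni)
  expect_equal(d$shannon, log(4), tolerance = 1e-12)
  expect_equal(d$inverse_simpson, 4, tolerance = 1e-12)
  expect_equal(d$richness, 4L)
  single <- matrix(c(9, 0, 0), 1)
  ds <- alpha_diversity(single)
  expect_equal(ds$shannon, 0)
  expect_equal(ds$inverse_simpson, 1)
  # brute-force oracle on (1,2,3,4)
  x <- c(1, 2, 3, 4); p <- x / sum(x)
  d2 <- alpha_diversity(matrix(x, 1))
  expect_equal(d2$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(d2$inverse_simpson, 1 / sum(p^2), tolerance = 1e-12)
  # inverse Simpson bounded by richness
  set.seed(1)
  cm <- matrix(rpois(60, 5), 6)
  dd <- alpha_diversity(cm)
  expect_true(all(dd$inverse_simpson <= dd$richness + 1e-9))
  expect_true(all(dd$inverse_simpson >= 1))
})

test_that("CLR rows are centered and match hand computation", {
  expect_equal(unname(clr_transform(matrix(c(5, 5, 5), 1), 1)),
               matrix(0, 1, 3))
  # row (1,3), pseudocount 1: logs (log2, log4), centered
  got <- clr_transform(matrix(c(1, 3), 1), 1)
  mid <- (log(2) + log(4)) / 2
  expect_equal(unname(got), cbind(log(2) - mid, log(4) - mid),
               tolerance = 1e-12)
  set.seed(2)
  m <- matrix(rpois(50, 20), 5)
  expect_true(all(abs(rowSums(clr_transform(m, 1))) < 1e-9))
  expect_error(clr_transform(m, 0), "pseudocount")
})

test_that("distance matrices: symmetry, bounds, brute-force Bray-Curtis", {
  x <- rbind(a = c(0.2, 0.3, 0.5), b = c(0.2, 0.3, 0.5), c = c(0.5, 0.5, 0))
  d <- distance_matrix(x, "bray_curtis")
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  disjoint <- rbind(p = c(1, 0), q = c(0, 1))
  expect_equal(distance_matrix(disjoint, "bray_curtis")["p", "q"], 1)
  u <- c(0.1, 0.4, 0.5); v <- c(0.3, 0.3, 0.4)
  bc <- sum(abs(u - v)) / sum(u + v)
  expect_equal(distance_matrix(rbind(u, v), "bray_curtis")[1, 2], bc,
               tolerance = 1e-12)
  set.seed(3)
  comp <- relative_abundance(matrix(rpois(80, 10) + 1, 8))
  dbc <- distance_matrix(comp, "bray_curtis")
  expect_true(all(dbc >= 0 & dbc <= 1))
  expect_error(distance_matrix(x, "unifrac"), "arg")
})

test_that("PCoA on Euclidean distances equals PCA scores up to sign", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), 30)
  ord <- pcoa(distance_matrix(X, "euclidean"))
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:4) {
    delta <- min(max(abs(ord$coordinates[, j] - pca$x[, j])),
                 max(abs(ord$coordinates[, j] + pca$x[, j])))
    expect_lt(delta, 1e-8)
  }
  expect_true(all(diff(ord$variance_explained) <= 1e-12))
  expect_true(all(abs(colMeans(ord$coordinates)) < 1e-10))
})

test_that("PCoA degenerate geometries behave", {
  d2 <- matrix(c(0, 3, 3, 0), 2)
  ord2 <- pcoa(d2)
  expect_equal(sort(ord2$coordinates[, 1]), c(-1.5, 1.5), tolerance = 1e-10)
  # collinear points: a single positive eigenvalue
  pts <- matrix(c(0, 1, 2), ncol = 1)
  ord3 <- pcoa(distance_matrix(pts, "euclidean"))
  expect_equal(length(ord3$eigenvalues), 1L)
  expect_equal(ord3$variance_explained, 1)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("Calinski-Harabasz matches a pairwise-distance oracle", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 4), ncol = 2))
  labels <- rep(1:2, each = 20)
  # oracle from pairwise squared distances: W_g = sum_g d^2 / (2 n_g)
  D2 <- as.matrix(dist(X))^2
  n <- nrow(X); k <- 2
  W <- sum(sapply(unique(labels), function(g) {
    idx <- which(labels == g)
    sum(D2[idx, idx]) / (2 * length(idx))
  }))
  Tot <- sum(D2) / (2 * n)
  ch_oracle <- ((Tot - W) / (k - 1)) / (W / (n - k))
  expect_equal(calinski_harabasz(X, labels), ch_oracle, tolerance = 1e-10)
})

test_that("Ward.D2 with the automated elbow recovers two separated blobs", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 6, 0.3), ncol = 2))
  rownames(X) <- paste0("s", 1:60)
  truth <- rep(1:2, each = 30)
  res <- ward_cluster(distance_matrix(X, "euclidean"), X, k_range = 2:10)
  expect_equal(res$k, 2L)
  tab <- table(res$labels, truth)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 60)   # perfect up to relabel
  expect_true(all(diff(res$tree$height) >= -1e-10)) # monotone merges
  expect_equal(sort(unique(res$labels)), 1:2)
  expect_error(ward_cluster(matrix(0, 4, 4), matrix(1, 4, 2)), "degenerate")
  expect_error(ward_cluster(matrix(0, 2, 2), matrix(1, 2, 2)), "3 samples")
})

test_that("taxon screening computes Pearson r with BH within score", {
  set.seed(7)
  n <- 40
  ab <- matrix(runif(n * 5), n, dimnames = list(paste0("s", 1:n),
                                                paste0("t", 1:5)))
  sc <- data.frame(score1 = ab[, 1], score2 = rnorm(n),
                   row.names = rownames(ab))
  res <- screen_taxa(ab, sc)
  hit <- res[res$taxon == "t1" & res$score == "score1", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_lt(hit$p, 1e-20)
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
  expect_true(all(res$q <= 1 + 1e-12, na.rm = TRUE))
  # zero-variance taxon is NA and excluded from the BH family
  ab2 <- cbind(ab, t6 = 0.5)
  res2 <- screen_taxa(ab2, sc["score2"])
  expect_true(is.na(res2$q[res2$taxon == "t6"]))
  m_used <- sum(!is.na(res2$p))
  expect_equal(sort(res2$q[!is.na(res2$q)]),
               sort(p.adjust(res2$p[!is.na(res2$p)], "BH", n = m_used)))
  expect_error(screen_taxa(ab, data.frame(s = 1, row.names = "zzz")),
               "overlap")
})

test_that("quartile contrast keeps the tails under type-7 quantiles", {
  qc <- quartile_contrast(setNames(1:8, paste0("s", 1:8)))
  expect_setequal(qc$sample_id[qc$group == "low"], c("s1", "s2"))
  expect_setequal(qc$sample_id[qc$group == "high"], c("s7", "s8"))
  sym <- quartile_contrast(c(-4, -3, -2, -1, 1, 2, 3, 4))
  expect_equal(sum(sym$group == "low"), sum(sym$group == "high"))
  expect_error(quartile_contrast(rep(1, 10)), "constant")
  expect_error(quartile_contrast(1:5), "8 samples")
})

test_that("the four constructs are assembled consistently", {
  cfg <- small_generator(seed = 10, n = 40)
  g <- generate_cohort(cfg)
  tc <- generate_taxa_counts(cfg, g$truth)
  cons <- build_constructs(tc$counts, tc$taxonomy)
  expect_named(cons, c("sample_id", "shannon", "streptococcaceae",
                       "cluster", "pcoa1"))
  expect_equal(cons$shannon, alpha_diversity(tc$counts)$shannon)
  ord <- pcoa(distance_matrix(relative_abundance(tc$counts), "euclidean"))
  expect_equal(cons$pcoa1, unname(ord$coordinates[, 1]))
  expect_true(all(cons$cluster %in% 1:2))
  expect_identical(cons, build_constructs(tc$counts, tc$taxonomy))

  # a table whose only family is Streptococcaceae -> relative abundance 1
  tax1 <- data.frame(taxon = colnames(tc$counts),
                     family = "Streptococcaceae", genus = "Streptococcus")
  cons1 <- build_constructs(tc$counts, tax1)
  expect_true(all(cons1$streptococcaceae == 1))

  tax0 <- tc$taxonomy
  tax0$family[tax0$family == "Streptococcaceae"] <- "Lactobacillaceae"
  expect_error(build_constructs(tc$counts, tax0), "available families")
})
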