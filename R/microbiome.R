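# Microbiota data-reduction constructs: alpha diversity, CLR/Aitchison,
# distance matrices, principal coordinates, Ward.D2 clustering with an
# automated Calinski-Harabasz elbow, family/genus-level Pearson screening
# with Benjamini-Hochberg correction, and the quartile-contrast utility
# used to dichotomize continuous scores.

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(rownames(counts)[zero] %||% which(zero), collapse = ", "),
         call. = FALSE)
  counts
}

#' Relative abundances
#'
#' @param counts samples x taxa matrix of non-negative counts.
#' @return matrix of the same shape; each row sums to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- .check_counts(counts)
  sweep(counts, 1, rowSums(counts), "/")
}

#' Alpha diversity (richness, Shannon, inverse Simpson)
#'
#' Computed on unaggregated counts without rarefaction.  Shannon is in
#' nats: \eqn{-\sum p_i \log p_i} over non-zero proportions; inverse
#' Simpson is \eqn{1/\sum p_i^2}; richness is the number of non-zero taxa.
#'
#' @param counts samples x taxa count matrix.
#' @return data frame with \code{sample_id}, \code{richness},
#'   \code{shannon}, \code{inverse_simpson}.
#' @export
alpha_diversity <- function(counts) {
  counts <- .check_counts(counts)
  data.frame(
    sample_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    richness = as.integer(rowSums(counts > 0)),
    shannon = as.numeric(vegan::diversity(counts, index = "shannon")),
    inverse_simpson = as.numeric(vegan::diversity(counts, index = "invsimpson")),
    stringsAsFactors = FALSE)
}

#' Centered log-ratio transform
#'
#' \code{log(count + pseudocount)} minus the row mean of logs; every output
#' row sums to 0, so Euclidean distances on the result are Aitchison
#' distances.
#'
#' @param counts samples x taxa count matrix.
#' @param pseudocount positive offset added before taking logs (default 1).
#' @return real-valued matrix of the same shape.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  lg <- log(as.matrix(counts) + pseudocount)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Sample-by-sample distance matrix
#'
#' @param table samples x features matrix (relative abundances for
#'   \code{bray_curtis}, any real table for \code{euclidean}).
#' @param metric \code{"euclidean"} or \code{"bray_curtis"}.
#' @return symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(table, metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  d <- switch(metric,
              euclidean = stats::dist(table),
              bray_curtis = vegan::vegdist(table, method = "bray"))
  as.matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and keeps the
#' positive-eigenvalue axes.  Axis signs are fixed so the coordinate with
#' the largest magnitude on each axis is positive.
#'
#' @param distances symmetric non-negative matrix with zero diagonal.
#' @return list of class \code{pcoa_result}: \code{coordinates} (n x k),
#'   \code{eigenvalues}, \code{variance_explained}.
#' @export
pcoa <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(distances)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (distances^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10 & e$values > 0)
  vals <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals), length(vals))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(distances)
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 variance_explained = vals / sum(vals)),
            class = "pcoa_result")
}

#' Calinski-Harabasz index
#'
#' Between/within sum-of-squares ratio \eqn{(B/(k-1)) / (W/(n-k))} for a
#' given partition of a feature table.
#'
#' @param table samples x features matrix the clustering was computed on.
#' @param labels integer cluster labels (1..k).
#' @return the index value.
#' @export
calinski_harabasz <- function(table, labels) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- length(unique(labels))
  grand <- colMeans(table)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    rows <- table[labels == g, , drop = FALSE]
    ctr <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, ctr)^2)
    B <- B + nrow(rows) * sum((ctr - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Ward.D2 clustering with automated Calinski-Harabasz elbow
#'
#' Hierarchical clustering with the Ward.D2 criterion (squared-distance
#' Lance-Williams update, square-root merge heights).  The number of
#' clusters is chosen automatically as the k maximizing the second
#' difference of the Calinski-Harabasz curve over \code{k_range} (a
#' reproducible surrogate for choosing the elbow by eye); ties go to the
#' smaller k.
#'
#' @param distances symmetric distance matrix (Euclidean on relative
#'   abundances in the standard workflow).
#' @param table the feature table the distances came from (used for the CH
#'   index).
#' @param k_range candidate cluster numbers, within \code{[2, n-1]}.
#' @return list of class \code{ward_clustering}: \code{tree} (hclust),
#'   \code{k}, \code{labels}, \code{ch_index} (named by k).
#' @export
ward_cluster <- function(distances, table, k_range = 2:10) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 3) stop("at least 3 samples are required", call. = FALSE)
  if (all(distances < .Machine$double.eps))
    stop("degenerate input: all pairwise distances are zero", call. = FALSE)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must lie within [2, n-1]", call. = FALSE)
  tree <- stats::hclust(stats::as.dist(distances), method = "ward.D2")
  ch <- vapply(k_range, function(k)
    calinski_harabasz(table, stats::cutree(tree, k)), numeric(1))
  names(ch) <- k_range
  if (length(ch) >= 2) {
    # discrete curvature with CH(1) := 0 (between-cluster SS vanishes at
    # k = 1): gain achieved up to k minus gain remaining after k;
    # the last candidate cannot be an elbow
    ch_prev <- c(0, ch[-length(ch)])
    curv <- (ch - ch_prev) - (c(ch[-1], NA) - ch)
    curv <- curv[-length(curv)]
    k_best <- k_range[which.max(curv)]
  } else {
    k_best <- k_range[1]
  }
  labels <- stats::cutree(tree, k_best)
  structure(list(tree = tree, k = k_best, labels = labels, ch_index = ch),
            class = "ward_clustering")
}

#' Aggregate taxa counts to a taxonomic level
#'
#' @param counts samples x taxa count matrix.
#' @param taxonomy data frame \code{taxon}/\code{family}/\code{genus}.
#' @param level \code{"family"} or \code{"genus"}.
#' @return samples x groups matrix.
#' @export
aggregate_taxa <- function(counts, taxonomy, level = c("family", "genus")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  grp <- taxonomy[[level]][match(colnames(counts), taxonomy$taxon)]
  if (any(is.na(grp)))
    stop("taxa absent from taxonomy: ",
         paste(utils::head(colnames(counts)[is.na(grp)], 3), collapse = ", "),
         call. = FALSE)
  t(rowsum(t(counts), grp))
}

#' Screen taxa against neurodevelopment scores
#'
#' Pearson correlation of each taxon's relative abundance (aggregated to
#' family or genus) with each score, two-sided p-values, and
#' Benjamini-Hochberg q-values computed within each score across taxa.
#' Zero-variance taxa yield NA and are excluded from the BH family size.
#'
#' @param abundance samples x taxa (aggregated) relative-abundance matrix.
#' @param scores samples x scores data frame / matrix; rownames (or a
#'   \code{sample_id} column) identify samples.
#' @param level label recorded in the output (\code{"family"} or
#'   \code{"genus"}).
#' @return data frame with \code{taxon}, \code{score}, \code{r}, \code{p},
#'   \code{q}, \code{level}.
#' @export
screen_taxa <- function(abundance, scores, level = "family") {
  abundance <- as.matrix(abundance)
  if (is.data.frame(scores) && "sample_id" %in% names(scores)) {
    rownames(scores) <- scores$sample_id
    scores$sample_id <- NULL
  }
  scores <- as.matrix(scores)
  common <- intersect(rownames(abundance), rownames(scores))
  if (!length(common)) stop("no overlapping samples", call. = FALSE)
  abundance <- abundance[common, , drop = FALSE]
  scores <- scores[common, , drop = FALSE]
  out <- list()
  for (sc in colnames(scores)) {
    y <- scores[, sc]
    res <- lapply(colnames(abundance), function(tx) {
      x <- abundance[, tx]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    })
    res <- do.call(rbind, res)
    q <- rep(NA_real_, nrow(res))
    ok <- !is.na(res[, 2])
    q[ok] <- stats::p.adjust(res[ok, 2], method = "BH")
    out[[sc]] <- data.frame(taxon = colnames(abundance), score = sc,
                            r = res[, 1], p = res[, 2], q = q,
                            level = level, stringsAsFactors = FALSE)
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' First/last quartile contrast of a continuous score
#'
#' Samples at or below the first quartile are labelled \code{"low"}, at or
#' above the third quartile \code{"high"}; the middle half is dropped.
#' Quartiles use linear-interpolation (type 7) quantiles.
#'
#' @param score named numeric vector (names = sample ids) or plain vector.
#' @return data frame with \code{sample_id}, \code{score}, \code{group}.
#' @export
quartile_contrast <- function(score) {
  if (length(score) < 8) stop("at least 8 samples are required", call. = FALSE)
  if (stats::sd(score, na.rm = TRUE) == 0)
    stop("score vector is constant", call. = FALSE)
  qs <- stats::quantile(score, c(0.25, 0.75), na.rm = TRUE, type = 7)
  ids <- names(score) %||% as.character(seq_along(score))
  keep <- !is.na(score) & (score <= qs[1] | score >= qs[2])
  data.frame(sample_id = ids[keep], score = unname(score[keep]),
             group = ifelse(score[keep] <= qs[1], "low", "high"),
             stringsAsFactors = FALSE)
}

#' The four microbiota constructs used in the structural models
#'
#' Per-sample Shannon diversity, family-level relative abundance of
#' Streptococcaceae, the two-group Ward.D2 cluster label, and the first
#' principal coordinate of the Euclidean-distance PCoA on relative
#' abundances.
#'
#' @param counts samples x taxa count matrix.
#' @param taxonomy taxonomy data frame.
#' @return data frame with \code{sample_id}, \code{shannon},
#'   \code{streptococcaceae}, \code{cluster}, \code{pcoa1};
#'   \code{attr(, "variance_explained")} holds the PCoA axis-1 share.
#' @export
build_constructs <- function(counts, taxonomy) {
  fam <- aggregate_taxa(counts, taxonomy, "family")
  if (!"Streptococcaceae" %in% colnames(fam))
    stop("family 'Streptococcaceae' absent; available families: ",
         paste(colnames(fam), collapse = ", "), call. = FALSE)
  relab <- relative_abundance(counts)
  fam_rel <- relative_abundance(fam)
  div <- alpha_diversity(counts)
  d_eu <- distance_matrix(relab, "euclidean")
  ord <- pcoa(d_eu)
  cl <- ward_cluster(d_eu, relab, k_range = 2:min(10, nrow(relab) - 1))
  out <- data.frame(sample_id = div$sample_id,
                    shannon = div$shannon,
                    streptococcaceae = fam_rel[, "Streptococcaceae"],
                    cluster = as.integer(stats::cutree(cl$tree, 2)),
                    pcoa1 = ord$coordinates[, 1],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "variance_explained") <- ord$variance_explained[1]
  attr(out, "chosen_k") <- cl$k
  out
}
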