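# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to squared distance from the nearest
# chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) for (i in 2:k) {
    if (all(d2 == 0)) {
      centers[i, ] <- x[sample.int(n, 1), ]
    } else {
      centers[i, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  centers
}

#' K-means clustering of gene expression profiles
#'
#' Clusters genes on row-z-scored log2 expression (so clusters reflect
#' expression pattern across samples, not absolute level) with k-means++
#' initialization, a configurable number of restarts, and the best inertia
#' kept. Deterministic given the seed. Constant rows z-score to zero and
#' cluster together.
#'
#' @param em `expression_matrix` in state `log2`.
#' @param k number of clusters (default 10).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts (default 50).
#' @return list of class `cluster_assignment`: `cluster` (named integer,
#'   1..k), `centers` (cluster x sample z-score means), `inertia`
#'   (total within-cluster sum of squares), `sizes`.
#' @export
kmeans_clusters <- function(em, k = 10, seed = 17L, nstart = 50) {
  check_state(em, "log2")
  v <- em$values
  if (k > nrow(v))
    stop("k (", k, ") exceeds the number of genes (", nrow(v), ")",
         call. = FALSE)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_centers(z, k)
    fit <- suppressWarnings(
      kmeans(z, centers = init, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(cluster = stats::setNames(best$cluster, rownames(z)),
                 centers = best$centers, inertia = best$tot.withinss,
                 sizes = best$size, k = k, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means clustering: k =", x$k, "| inertia =",
      format(x$inertia, digits = 6), "\n")
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of samples over a gene panel
#'
#' SVD-based principal components of the samples after centering each
#' gene across samples (optionally unit-scaling). Components are ordered
#' by decreasing variance; each component's sign is fixed so its
#' largest-magnitude gene loading is positive.
#'
#' @param em an `expression_matrix` (typically the log2 or median-scaled
#'   signature panel).
#' @param scale. unit-scale genes as well as centering (default FALSE).
#' @return list of class `pca_scores`: `scores` (samples x components),
#'   `loadings`, `variance_explained` (percent).
#' @export
pca_scores <- function(em, scale. = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (ncol(v) < 2) stop("PCA needs >= 2 samples", call. = FALSE)
  sdv <- apply(v, 1, sd)
  if (all(sdv == 0)) stop("constant expression matrix", call. = FALSE)
  if (scale.) v <- v[sdv > 0, , drop = FALSE]
  fit <- prcomp(t(v), center = TRUE, scale. = scale.)
  scores <- fit$x
  loadings <- fit$rotation
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("PCA:", ncol(x$scores), "components;",
      "variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$variance_explained, 4)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @export
plot.pca_scores <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "grey30"
         else c("forestgreen", "firebrick")[as.integer(factor(groups))]
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$variance_explained[2]),
                 ...)
  invisible(x)
}
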