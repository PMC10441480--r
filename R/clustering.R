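# PCA embedding and k-means clustering.
#
# Pipeline: standardize features, take the smallest number of principal
# components whose cumulative explained variance exceeds a threshold
# (default 0.8), then k-means in component space with k chosen by the
# elbow rule on the within-cluster sum of squares, formalized as the
# maximum perpendicular distance from the line joining the WCSS curve's
# endpoints.

#' Standardize columns to mean 0, sd 1
#'
#' Constant columns become all-zero (with a message) rather than NaN.
#'
#' @param X Numeric matrix, `nrow >= 2`.
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  mu <- colMeans(X)
  # population sd (ddof = 0), the StandardScaler convention; keeps the
  # transform idempotent and {1, 3} -> {-1, 1}
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- s == 0
  if (any(constant)) {
    message(sprintf("%d constant column(s) standardized to zero", sum(constant)))
    s[constant] <- 1
  }
  out <- sweep(sweep(X, 2, mu), 2, s, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- s
  out
}

#' PCA with automatic component count
#'
#' Fits a full PCA on (already standardized) data and keeps the smallest
#' number of components whose cumulative explained-variance ratio strictly
#' exceeds `threshold`.
#'
#' @param X Standardized numeric matrix.
#' @param threshold Cumulative explained-variance threshold in \[0, 1);
#'   default 0.8.
#' @return Object of class `pca_projection`: `n_components`, `coordinates`
#'   (n x n_components), `explained_variance_ratio` (all components),
#'   `rotation`, `threshold`.
#' @export
fit_pca_auto <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  stopifnot(threshold >= 0, threshold < 1)
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(evr)
  n_comp <- which(cum > threshold)[1]
  if (is.na(n_comp)) {
    warning("cumulative explained variance never exceeds threshold; using all components",
            call. = FALSE)
    n_comp <- length(evr)
  }
  structure(list(n_components = n_comp,
                 coordinates = pc$x[, seq_len(n_comp), drop = FALSE],
                 explained_variance_ratio = evr,
                 rotation = pc$rotation[, seq_len(n_comp), drop = FALSE],
                 threshold = threshold),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d components (cumulative EVR %.3f > %.2f)\n",
              x$n_components,
              sum(x$explained_variance_ratio[seq_len(x$n_components)]),
              x$threshold))
  invisible(x)
}

#' WCSS curve over candidate cluster counts
#'
#' @param X Numeric matrix (e.g. PCA coordinates).
#' @param k_max Largest k to evaluate (>= 3).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Restarts per k.
#' @return Named numeric vector: WCSS at k = 1..k_max.
#' @export
wcss_curve <- function(X, k_max = 10L, seed = 0L, nstart = 10L) {
  X <- as.matrix(X)
  k_max <- min(as.integer(k_max), nrow(unique(X)))
  stopifnot(k_max >= 3)
  vapply(seq_len(k_max), function(k) {
    kmeans_cluster(X, k, seed = seed, nstart = nstart)$wcss
  }, 0)
}

#' Choose k by the elbow rule
#'
#' The elbow is the k at maximum perpendicular distance from the straight
#' line joining (1, WCSS_1) and (k_max, WCSS_kmax). A numerically straight
#' curve has no elbow; 1 is returned with a warning.
#'
#' @param wcss Numeric WCSS values at k = 1..k_max (`k_max >= 3`).
#' @return The chosen k.
#' @export
choose_k_elbow <- function(wcss) {
  k_max <- length(wcss)
  stopifnot(k_max >= 3)
  k <- seq_len(k_max)
  # line through the endpoints: a*x + b*y + c = 0
  x1 <- 1; y1 <- wcss[1]; x2 <- k_max; y2 <- wcss[k_max]
  a <- y2 - y1; b <- x1 - x2; c <- x2 * y1 - x1 * y2
  dist <- abs(a * k + b * wcss + c) / sqrt(a^2 + b^2)
  if (max(dist) < 1e-8 * max(abs(wcss), 1)) {
    warning("WCSS curve has no elbow (straight line); returning k = 1",
            call. = FALSE)
    return(1L)
  }
  which.max(dist)
}

#' K-means clustering with canonical labels
#'
#' Lloyd's algorithm with multiple seeded restarts; labels are relabelled
#' in order of decreasing cluster size (label 0 = largest cluster) so a
#' clustering is comparable across runs.
#'
#' @param X Numeric matrix (e.g. PCA coordinates).
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param nstart Restarts.
#' @return Object of class `cluster_assignment`: `k`, `labels` (0-based
#'   integers), `centers`, `wcss`, `seed`.
#' @export
kmeans_cluster <- function(X, k, seed = 0L, nstart = 10L) {
  X <- as.matrix(X)
  stopifnot(k >= 1)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) stopf("k = %d exceeds the %d distinct rows", k, n_distinct)
  if (k == n_distinct) {
    # every distinct row is its own cluster; stats::kmeans needs k < n
    key <- apply(X, 1, paste, collapse = "\r")
    labels1 <- match(key, unique(key))
    km <- list(cluster = labels1, centers = X[!duplicated(key), , drop = FALSE],
               size = tabulate(labels1, k), tot.withinss = 0)
  } else {
    km <- withr::with_seed(seed, kmeans(X, centers = k, nstart = nstart,
                                        iter.max = 50L))
  }
  size_order <- order(-km$size, seq_len(k))
  relabel <- match(seq_len(k), size_order) - 1L
  structure(list(k = as.integer(k), labels = relabel[km$cluster],
                 centers = km$centers[size_order, , drop = FALSE],
                 wcss = km$tot.withinss, seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' Standardize, project, and cluster in one call
#'
#' @param X Raw numeric matrix (rows = variants; columns = features, e.g.
#'   an encoded matrix or a per-contributor prediction table).
#' @param threshold Explained-variance threshold for [fit_pca_auto()].
#' @param k Cluster count; `NULL` (default) chooses by [choose_k_elbow()].
#' @param k_max Largest k scanned for the elbow.
#' @param seed RNG seed.
#' @return List with `projection`, `wcss`, `k`, `assignment`.
#' @export
embed_and_cluster <- function(X, threshold = 0.8, k = NULL, k_max = 10L,
                              seed = 0L) {
  Xs <- standardize(X)
  proj <- fit_pca_auto(Xs, threshold = threshold)
  wcss <- wcss_curve(proj$coordinates, k_max = k_max, seed = seed)
  if (is.null(k)) k <- choose_k_elbow(wcss)
  list(projection = proj, wcss = wcss, k = k,
       assignment = kmeans_cluster(proj$coordinates, k, seed = seed))
}
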