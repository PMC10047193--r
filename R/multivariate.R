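#' Sample-level similarity matrices
#'
#' Treats each sample as a vector over proteins and returns either the
#' Euclidean distance matrix or the Pearson correlation matrix between
#' samples (the quantities behind sample-correlation heatmaps and
#' sample-level dendrograms).
#'
#' @param dataset an imputed [abundance_dataset()] with no missing values.
#' @param method `"euclidean"` or `"pearson"`.
#' @return a samples x samples numeric matrix.
#' @export
sample_similarity <- function(dataset, method = c("euclidean", "pearson")) {
  method <- match.arg(method)
  if (anyNA(dataset$values))
    stop("similarity error: dataset contains missing values", call. = FALSE)
  x <- t(dataset$values)  # samples in rows
  if (method == "euclidean") {
    as.matrix(stats::dist(x, method = "euclidean"))
  } else {
    if (any(apply(x, 1, stats::sd) == 0))
      stop("undefined-correlation error: zero-variance sample", call. = FALSE)
    stats::cor(t(x), method = "pearson")
  }
}

#' Hierarchical clustering of a distance matrix
#'
#' @param distance_matrix symmetric non-negative matrix with zero diagonal
#'   (e.g. from [sample_similarity()] with `method = "euclidean"`).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return an `hclust` merge tree.
#' @export
hierarchical_clustering <- function(distance_matrix,
                                    linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(distance_matrix) ||
      !isTRUE(all.equal(distance_matrix, t(distance_matrix),
                        tolerance = 1e-10)))
    stop("matrix error: distance matrix must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(distance_matrix), method = linkage)
}

#' k-means clustering followed by PCA on sample vectors
#'
#' Runs seeded k-means (Euclidean, best of `nstart` restarts on
#' within-cluster sum of squares) on the sample x protein matrix, then PCA
#' on the mean-centered (unscaled) matrix. Used as a quality-control
#' ordination: well-separated groups should split along the leading
#' components and agree with the k-means partition.
#'
#' @param dataset an imputed [abundance_dataset()].
#' @param k number of clusters (default 2).
#' @param n_components number of principal components to report (default 2).
#' @param seed integer RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @param scale. logical, scale proteins to unit variance before PCA
#'   (default FALSE; abundances share a common log scale).
#' @return list with `pc_scores` (samples x `n_components`),
#'   `explained_variance_fraction`, `kmeans_labels` (named integer vector),
#'   `distance_matrix`, `correlation_matrix`, `dendrogram` (hclust), and the
#'   full `prcomp` fit as `pca`.
#' @export
kmeans_pca <- function(dataset, k = 2L, n_components = 2L, seed = 1L,
                       nstart = 10L, scale. = FALSE) {
  x <- t(dataset$values)
  if (k > nrow(x))
    stop("parameter error: k (", k, ") exceeds the number of samples (",
         nrow(x), ")", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  pca <- stats::prcomp(x, center = TRUE, scale. = scale.)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  n_components <- min(n_components, ncol(pca$x))
  dmat <- sample_similarity(dataset, "euclidean")
  list(pc_scores = pca$x[, seq_len(n_components), drop = FALSE],
       explained_variance_fraction = expl[seq_len(n_components)],
       kmeans_labels = stats::setNames(km$cluster, dataset$sample_ids),
       distance_matrix = dmat,
       correlation_matrix = sample_similarity(dataset, "pearson"),
       dendrogram = hierarchical_clustering(dmat),
       pca = pca)
}
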