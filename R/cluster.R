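#' Replace missing calls with the heterozygote placeholder
#'
#' K-means cannot handle missing values, so prior to clustering every
#' missing call is replaced by 1 (the heterozygote, the midpoint of the
#' 0/1/2 scale). The imputation engine itself never sees these
#' placeholders.
#'
#' @param gm a [geno_matrix()].
#' @return a numeric individuals x markers matrix with no missing values.
#' @export
fill_for_clustering <- function(gm) {
  validate_geno_matrix(gm)
  X <- gm$calls
  X[is.na(X)] <- 1L
  storage.mode(X) <- "double"
  X
}

#' K-means on a complete genotype matrix
#'
#' Lloyd-type K-means (via [stats::kmeans()]) with Euclidean distance on the
#' raw 0/1/2 coordinates, best of `nstart` random initialisations by
#' within-cluster sum of squares.
#'
#' @param X complete numeric matrix (individuals x markers).
#' @param k number of clusters (`1 <= k <=` individuals).
#' @param nstart random restarts.
#' @param seed random seed.
#' @return a list: `labels` (integer in `1..k`), `centers`, `inertia`
#'   (total within-cluster sum of squares).
#' @export
kmeans_fit <- function(X, k, nstart = 25, seed) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("kmeans_fit() needs a complete matrix; see fill_for_clustering()")
  if (k < 1 || k > nrow(X)) stopf("k must be in [1, %d]", nrow(X))
  if (!missing(seed)) set.seed(seed)
  if (k == 1) {
    ctr <- matrix(colMeans(X), 1)
    return(list(labels = rep(1L, nrow(X)), centers = ctr,
                inertia = sum(sweep(X, 2, ctr[1, ])^2)))
  }
  km <- suppressWarnings(kmeans(X, centers = k, nstart = nstart,
                                iter.max = 500))
  list(labels = as.integer(km$cluster), centers = km$centers,
       inertia = km$tot.withinss)
}

#' Mean silhouette coefficient of a clustering
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distance, averaged over individuals; members of singleton
#' clusters contribute 0. Computed through [cluster::silhouette()].
#'
#' @param X complete numeric matrix, or a precomputed `dist` object.
#' @param labels integer cluster labels (>= 2 distinct, all non-empty).
#' @return the mean silhouette coefficient in `[-1, 1]`.
#' @export
mean_silhouette <- function(X, labels) {
  if (length(unique(labels)) < 2)
    stopf("silhouette is undefined for a single cluster")
  d <- if (inherits(X, "dist")) X else dist(as.matrix(X))
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Silhouette-guided selection of the cluster count
#'
#' Runs K-means for each k in `k_range`, scores every solution by the mean
#' silhouette coefficient, and returns the assignment at the maximising k
#' (ties broken toward smaller k, favouring larger clusters and hence
#' richer per-cluster haplotype panels). Clusters smaller than
#' `min_cluster` individuals are merged into the cluster with the nearest
#' centroid: a haplotype reference panel needs at least two other
#' individuals to copy from.
#'
#' For pairwise-distance tractability the silhouette is evaluated on a
#' random subsample of at most `max_sil_ind` individuals and
#' `max_sil_markers` markers when the input is larger.
#'
#' @param X complete numeric matrix (individuals x markers).
#' @param k_range candidate cluster counts (default 2..10).
#' @param nstart K-means restarts per k (default 25).
#' @param seed random seed.
#' @param min_cluster minimum cluster size before merging (default 3).
#' @param max_sil_ind,max_sil_markers silhouette subsampling thresholds.
#' @return a list of class `cluster_assignment`: `labels` (1..K), `K`,
#'   `silhouette_by_k` (named vector over the searched k), `centers`.
#' @export
select_k <- function(X, k_range = 2:10, nstart = 25, seed,
                     min_cluster = 3, max_sil_ind = 2000,
                     max_sil_markers = 5000) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) {
    warnf("fewer than 3 individuals; clustering skipped (single cluster)")
    return(structure(list(labels = rep(1L, n), K = 1L,
                          silhouette_by_k = setNames(numeric(0), character(0)),
                          centers = matrix(colMeans(X), 1)),
                     class = "cluster_assignment"))
  }
  n_distinct <- nrow(unique(X))
  k_range <- k_range[k_range >= 2 & k_range <= min(n - 1L, n_distinct)]
  if (!length(k_range)) k_range <- 2L
  # silhouette subsample (distance matrices are quadratic)
  set.seed(child_seed(seed, 0L))
  sil_ind <- seq_len(n)
  if (n > max_sil_ind) sil_ind <- sort(sample.int(n, max_sil_ind))
  sil_cols <- seq_len(ncol(X))
  if (ncol(X) > max_sil_markers)
    sil_cols <- sort(sample.int(ncol(X), max_sil_markers))
  d <- dist(X[sil_ind, sil_cols, drop = FALSE])
  fits <- vector("list", length(k_range))
  sil <- setNames(rep(NA_real_, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- kmeans_fit(X, k, nstart = nstart, seed = child_seed(seed, k))
    labs <- fits[[i]]$labels[sil_ind]
    sil[i] <- if (length(unique(labs)) < 2) -Inf else mean_silhouette(d, labs)
  }
  best <- which.max(sil)  # first maximum -> smallest k on ties
  fit <- fits[[best]]
  out <- merge_small_clusters(X, fit$labels, fit$centers, min_cluster)
  structure(list(labels = out$labels, K = out$K,
                 silhouette_by_k = sil, centers = out$centers),
            class = "cluster_assignment")
}

# merge clusters smaller than min_cluster into nearest-centroid neighbours
merge_small_clusters <- function(X, labels, centers, min_cluster) {
  repeat {
    sizes <- tabulate(labels, nbins = max(labels))
    keep <- which(sizes > 0)
    small <- keep[sizes[keep] < min_cluster]
    if (!length(small) || length(keep) == 1) break
    s <- small[which.min(sizes[small])]
    others <- setdiff(keep, s)
    dc <- colSums((t(centers[others, , drop = FALSE]) - centers[s, ])^2)
    tgt <- others[which.min(dc)]
    labels[labels == s] <- tgt
    for (g in unique(labels))
      centers[g, ] <- colMeans(X[labels == g, , drop = FALSE])
  }
  relab <- as.integer(factor(labels, levels = sort(unique(labels))))
  K <- max(relab)
  ctr <- matrix(0, K, ncol(X))
  for (g in seq_len(K)) ctr[g, ] <- colMeans(X[relab == g, , drop = FALSE])
  list(labels = relab, K = K, centers = ctr)
}
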