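#' Shared-nearest-neighbor graph in PC space
#'
#' Each cell's neighbor set is itself plus its `k` Euclidean nearest
#' neighbors in the embedding. Cells i and j are connected when either is
#' in the other's neighbor set; the edge weight is the Jaccard overlap of
#' the two sets, and zero-weight edges are dropped.
#'
#' @param embedding an [pca_embed()] result, or a cells x dims matrix.
#' @param k number of nearest neighbors (0 < k < n_cells).
#' @return An undirected weighted [igraph::graph] with one vertex per cell.
#' @export
build_knn_graph <- function(embedding, k = 20) {
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  n <- nrow(coords)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d2 <- euclidean_dist2(coords)
  # neighbor sets: self + k nearest others
  nb <- matrix(0L, n, k + 1L)
  for (i in seq_len(n)) {
    o <- order(d2[i, ])
    o <- o[o != i][seq_len(k)]
    nb[i, ] <- c(i, o)
  }
  # reverse neighbor lists: who has i in its set
  rev_of <- split(rep(seq_len(n), k + 1L), as.vector(nb))
  rev_list <- vector("list", n)
  rev_list[as.integer(names(rev_of))] <- rev_of
  ei <- vector("list", n); ew <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- unique(c(nb[i, ], rev_list[[i]]))
    cand <- cand[cand > i]
    if (!length(cand)) next
    inter <- vapply(cand, function(j) sum(nb[j, ] %in% nb[i, ]), numeric(1))
    w <- inter / (2 * (k + 1L) - inter)
    keep <- w > 0
    if (any(keep)) {
      ei[[i]] <- rbind(i, cand[keep])
      ew[[i]] <- w[keep]
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  edges <- unlist(ei)
  if (length(edges))
    g <- igraph::add_edges(g, edges, weight = unlist(ew))
  if (!is.null(rownames(coords)))
    igraph::V(g)$name <- rownames(coords)
  g
}

euclidean_dist2 <- function(coords) {
  ss <- rowSums(coords^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Louvain community detection at a given resolution
#'
#' Runs modularity maximization with a resolution parameter on the SNN
#' graph; deterministic for a fixed seed.
#'
#' @param graph weighted undirected graph from [build_knn_graph()].
#' @param resolution resolution parameter (> 0).
#' @param seed RNG seed.
#' @return list of class `cluster_labels`: `labels` (integer, contiguous
#'   from 0, named by cell), `resolution`, `n_clusters`, `seed`.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 0L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  stopifnot(resolution > 0)
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  lab <- as.integer(igraph::membership(comm)) - 1L
  lab <- match(lab, sort(unique(lab))) - 1L
  names(lab) <- igraph::V(graph)$name
  structure(list(labels = lab, resolution = resolution,
                 n_clusters = length(unique(lab)), seed = seed),
            class = "cluster_labels")
}

#' Mean silhouette width of a labelling
#'
#' Euclidean silhouette in embedding space: for each cell, a is the mean
#' distance to its own cluster (excluding itself), b the smallest mean
#' distance to another cluster, and s = (b - a) / max(a, b). Cells in
#' singleton clusters score 0. Returns the mean over cells; a single
#' cluster scores the -1 sentinel.
#'
#' @param coords cells x dims matrix.
#' @param labels integer cluster labels (one per cell).
#' @param D optional precomputed cells x cells Euclidean distance matrix.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(coords, labels, D = NULL) {
  coords <- as.matrix(coords)
  labels <- as.integer(labels)
  n <- nrow(coords)
  stopifnot(length(labels) == n)
  cl <- sort(unique(labels))
  if (length(cl) < 2) return(-1)
  if (is.null(D)) D <- sqrt(euclidean_dist2(coords))
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each cell to each cluster
  agg <- vapply(cl, function(g)
    rowSums(D[, labels == g, drop = FALSE]), numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    gi <- match(labels[i], cl)
    ni <- sizes[gi]
    if (ni == 1) { s[i] <- 0; next }
    a <- agg[i, gi] / (ni - 1)
    b <- min(agg[i, -gi] / sizes[-gi])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Scan resolutions and keep the best-silhouette partition
#'
#' Clusters the graph at every resolution in `grid`, scores each partition
#' by mean silhouette in the embedding (single-cluster partitions score the
#' -1 sentinel), and returns the scan plus the labels at the chosen
#' resolution: the argmax, ties broken toward the smallest resolution. For
#' embeddings larger than `subsample_above` cells the silhouette is
#' computed on a fixed-seed subsample of that size.
#'
#' @param embedding an [pca_embed()] result (or coordinate matrix).
#' @param graph SNN graph over the same cells.
#' @param grid resolutions to scan (default 0.1 to 1.5 by 0.1).
#' @param seed RNG seed for Louvain (and subsampling).
#' @param subsample_above silhouette subsample threshold (default 5000).
#' @return list of class `resolution_scan`: `scan` (data.frame resolution,
#'   n_clusters, mean_silhouette), `chosen_resolution`, `labels`
#'   (a `cluster_labels`).
#' @export
select_resolution <- function(embedding, graph,
                              grid = seq(0.1, 1.5, by = 0.1), seed = 0L,
                              subsample_above = 5000) {
  if (!length(grid)) stop("resolution grid is empty")
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  n <- nrow(coords)
  sub <- seq_len(n)
  if (n > subsample_above) {
    set.seed(seed)
    sub <- sort(sample.int(n, subsample_above))
  }
  fits <- lapply(grid, function(r) louvain_cluster(graph, r, seed = seed))
  Dsub <- sqrt(euclidean_dist2(coords[sub, , drop = FALSE]))
  sil <- vapply(seq_along(grid), function(i) {
    lab <- fits[[i]]$labels
    if (length(unique(lab)) < 2) return(-1)
    mean_silhouette(coords[sub, , drop = FALSE], lab[sub], D = Dsub)
  }, numeric(1))
  scan <- data.frame(resolution = grid,
                     n_clusters = vapply(fits, `[[`, 0L, "n_clusters"),
                     mean_silhouette = sil)
  if (all(scan$n_clusters == 1))
    warning("every resolution yields a single cluster")
  best <- which(sil == max(sil))
  best <- best[which.min(grid[best])]
  structure(list(scan = scan, chosen_resolution = grid[best],
                 labels = fits[[best]]),
            class = "resolution_scan")
}

#' Adjusted Rand index between two labellings
#'
#' Hubert-Arabie adjusted Rand index, used to score recovery of planted
#' cell types.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
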