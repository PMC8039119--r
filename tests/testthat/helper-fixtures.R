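# Shared fixture builders. Everything is generated in code at test time.

# small dense count matrix with named genes/cells
toy_counts <- function(m, genes = NULL, cells = NULL, region = "midbrain") {
  m <- as.matrix(m)
  if (!is.null(genes)) rownames(m) <- genes
  else if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (!is.null(cells)) colnames(m) <- cells
  else if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  count_matrix(m, region)
}

make_de_fixture <- function(n = 120, G = 30, seed = 31, planted = NULL) {
  set.seed(seed)
  mu <- rexp(G, 1) + 0.2
  m <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 2), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:n)))
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  if (!is.null(planted))
    m[planted, grp] <- rnbinom(n / 2, mu = 4 * mu[match(planted, rownames(m))],
                               size = 2)
  zero <- colSums(m) == 0
  m[1, zero] <- 1
  list(x = lognormalize(count_matrix(m, "m")), grp = grp)
}

# random count fixture for QC oracle comparisons
random_qc_fixture <- function(n_cells, n_genes = 60, seed = 1) {
  set.seed(seed)
  mu <- rexp(n_genes, 1)
  m <- matrix(rnbinom(n_genes * n_cells, mu = rep(mu, n_cells), size = 1),
              n_genes, n_cells)
  rownames(m) <- c(sprintf("mt-G%d", 1:4), sprintf("Rps%d", 1:3),
                   sprintf("g%03d", seq_len(n_genes - 7)))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  count_matrix(m, sample(c("midbrain", "striatum"), n_cells, replace = TRUE))
}

# well-separated K-type spec: shared baseline plus `per_type` dedicated
# genes per type at `fold`-fold enrichment, no artifacts
separated_spec <- function(K = 3, cells_per_type = 300, n_genes = 1000,
                           fold = 4, per_type = 50, seed = 1,
                           artifact_fractions = c(empty = 0, high_mito = 0,
                                                  contaminated = 0)) {
  set.seed(seed + 10000L)
  baseline <- rexp(n_genes, rate = 2)
  start <- 21L  # leave the mito/ribo prefix genes at baseline
  stopifnot(start + K * per_type <= n_genes)
  types <- lapply(seq_len(K), function(k) {
    p <- baseline
    idx <- start + (k - 1L) * per_type + seq_len(per_type)
    p[idx] <- fold * pmax(baseline[idx], 0.5)
    list(name = paste0("type", k),
         n_cells = c(midbrain = ceiling(cells_per_type / 2),
                     striatum = floor(cells_per_type / 2)),
         profile = p)
  })
  sim_spec(n_genes, types, dispersion = 2, depth_lognormal = c(0, 0.25),
           artifact_fractions = artifact_fractions, seed = seed)
}

# run normalize/embed/cluster on a container, return scan + labels
cluster_pipeline <- function(x, n_pcs = 20, k = 20, seed = 0L,
                             grid = seq(0.1, 1.5, by = 0.1)) {
  x <- lognormalize(gene_filter(x))
  emb <- pca_embed(x, select_hvg(x, 5000), n_pcs)
  g <- build_knn_graph(emb, k = k)
  select_resolution(emb, g, grid = grid, seed = seed)
}

# literal O(n^2) silhouette oracle (independent of the package version)
silhouette_oracle <- function(coords, labels) {
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(coords) - coords[i, ])^2))
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(di[own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(di[labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force evaluation of the 2-of-3 MAD rule, one region at a time
qc_oracle <- function(x, params = qc_params()) {
  m <- as.matrix(miglia:::raw_counts(x))
  mito <- grepl("^mt-", rownames(m), ignore.case = TRUE)
  reg <- regions(x)
  low <- logical(ncol(m))
  for (r in unique(reg)) {
    idx <- which(reg == r)
    ng <- tot <- pm <- numeric(length(idx))
    for (j in seq_along(idx)) {
      cellv <- m[, idx[j]]
      ng[j] <- sum(cellv > 0)
      tot[j] <- sum(cellv)
      pm[j] <- if (tot[j] > 0) 100 * sum(cellv[mito]) / tot[j] else 0
    }
    if (length(idx) < 3) next
    madu <- function(v) median(abs(v - median(v)))
    for (j in seq_along(idx)) {
      f1 <- ng[j] < params$min_genes ||
        ng[j] > median(ng) + params$mad_genes * madu(ng)
      f2 <- abs(tot[j] - median(tot)) > params$mad_counts * madu(tot)
      f3 <- pm[j] > median(pm) + params$mad_mito * madu(pm)
      low[idx[j]] <- (f1 + f2 + f3) >= params$min_fail
    }
  }
  low
}
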