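#' Library-size log-normalization
#'
#' Each count is divided by the cell's total counts, multiplied by
#' `scale_factor` and transformed with `log1p`; the result is stored as the
#' `"lognorm"` assay, with the raw layer retained alongside. Consequently,
#' for every cell the `expm1` of its normalized values sums exactly to
#' `scale_factor`.
#'
#' @param x count matrix container (raw layer; no zero-total cells).
#' @param scale_factor library-size scale (default 10,000).
#' @return The container with a `lognorm` assay added.
#' @export
lognormalize <- function(x, scale_factor = 10000) {
  m <- raw_counts(x)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(colnames(m)[totals == 0][1:min(5, sum(totals == 0))],
               collapse = ", "))
  ln <- m
  ln@x <- log1p(ln@x / rep.int(totals, diff(ln@p)) * scale_factor)
  SummarizedExperiment::assay(x, "lognorm") <- ln
  x
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a degree-2 polynomial trend of
#' log10 variance on log10 mean is fitted over genes with positive
#' variance of the raw counts, counts are standardized per gene by the
#' trend-expected standard deviation, clipped at `sqrt(n_cells)`, and the
#' variance of the clipped values is the ranking statistic. Ties break by
#' gene order.
#'
#' @param x count matrix container with a `lognorm` layer (normalization is
#'   a precondition; the variance trend itself is fitted on raw counts).
#' @param n_top number of genes to return (capped at the gene universe).
#' @return Character vector of gene symbols, highest standardized variance
#'   first.
#' @export
select_hvg <- function(x, n_top = 5000) {
  if (n_top <= 0) stop("n_top must be positive")
  lognorm_values(x)  # enforce precondition
  m <- raw_counts(x)
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowSums((m - mu)^2) / max(1, n - 1)
  sd_exp <- rep(0, length(mu))
  fit_on <- v > 0 & mu > 0
  if (sum(fit_on) >= 3 && length(unique(mu[fit_on])) >= 3) {
    lm10 <- log10(mu[fit_on])
    fit <- stats::lm(log10(v[fit_on]) ~ lm10 + I(lm10^2))
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      sd_exp[fit_on] <- sqrt(mean(v[fit_on]))
    } else {
      pred <- cbind(1, lm10, lm10^2) %*% cf
      sd_exp[fit_on] <- sqrt(10^as.vector(pred))
    }
  } else {
    # degenerate trend (too few distinct means): flat expected variance,
    # so observed variance ranks the genes directly
    sd_exp[fit_on] <- sqrt(mean(v[fit_on]))
  }
  clip <- sqrt(n)
  std_var <- numeric(length(mu))
  dm <- as.matrix(m)
  for (g in which(sd_exp > 0)) {
    z <- (dm[g, ] - mu[g]) / sd_exp[g]
    z <- pmin(pmax(z, -clip), clip)
    std_var[g] <- sum((z - mean(z))^2) / max(1, n - 1)
  }
  ord <- order(-std_var, seq_along(std_var))
  rownames(m)[ord][seq_len(min(n_top, length(ord)))]
}

#' PCA embedding on highly variable genes
#'
#' The lognorm submatrix of the selected genes is per-gene centered and
#' scaled to unit variance (zero-variance genes contribute zeros), scaled
#' values are clipped at +/-10, and the exact decomposition of the result
#' gives the embedding. Component signs are canonicalized so that each
#' component's largest-magnitude gene loading is positive.
#'
#' @param x count matrix container with a `lognorm` layer.
#' @param hvg character vector of genes to use (subset of the universe).
#' @param n_components number of components to keep.
#' @return list of class `embedding`: `coordinates` (cells x components,
#'   barcodes as rownames), `explained_variance_ratio`, `hvg_list`,
#'   `n_components`, `loadings`.
#' @export
pca_embed <- function(x, hvg, n_components = 20) {
  if (!length(hvg) || !all(hvg %in% rownames(x)))
    stop("hvg genes missing from the universe")
  ln <- as.matrix(lognorm_values(x)[hvg, , drop = FALSE])
  X <- t(ln)                                   # cells x genes
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, mu)
  pos <- sdv > 0
  X[, pos] <- sweep(X[, pos, drop = FALSE], 2, sdv[pos], "/")
  X[, !pos] <- 0
  X <- pmin(pmax(X, -10), 10)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(cells, genes)")
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loads <- sv$v
  flip <- vapply(seq_len(n_components), function(j)
    loads[which.max(abs(loads[, j])), j] < 0, logical(1))
  scores[, flip] <- -scores[, flip]
  loads[, flip] <- -loads[, flip]
  total_var <- sum(apply(X, 2, stats::var))
  evr <- (sv$d^2 / (nrow(X) - 1)) / total_var
  rownames(scores) <- colnames(ln)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(loads) <- hvg
  structure(list(coordinates = scores,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 hvg_list = hvg, n_components = n_components,
                 loadings = loads),
            class = "embedding")
}
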