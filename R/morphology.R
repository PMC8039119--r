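#' Construct a cell skeleton
#'
#' A rooted 3D tree representing one microglial cell: one node per sample
#' point with micrometre coordinates and a parent link; the single node
#' with parent -1 is the root (soma). The node table follows SWC column
#' conventions (id, type, x, y, z, radius, parent).
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return list of class `skeleton`.
#' @export
skeleton <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("nodes must have SWC columns")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) stop("skeleton must have exactly one root")
  nonroot <- nodes$parent[nodes$parent != -1]
  if (!all(nonroot %in% nodes$id)) stop("parent id not present in node table")
  s <- structure(list(nodes = nodes), class = "skeleton")
  # reject cycles / disconnection: every node must reach the root
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); j <- i
    while (nodes$parent[j] != -1) {
      if (j %in% seen) stop("cycle detected in skeleton")
      seen <- c(seen, j)
      j <- idx[[as.character(nodes$parent[j])]]
    }
  }
  s
}

#' Read/write SWC skeleton files
#'
#' Standard SWC: whitespace-separated columns id, type, x, y, z, radius,
#' parent; `#` lines are comments; parent -1 marks the root.
#'
#' @param path SWC file path.
#' @return `read_swc`: a `skeleton`.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  skeleton(tab)
}

#' @rdname read_swc
#' @param s a `skeleton`.
#' @export
write_swc <- function(s, path) {
  utils::write.table(s$nodes, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Skeleton morphometrics: process length, branch points, segments
#'
#' Total process length is the sum of Euclidean parent-child edge lengths.
#' Branch points are non-root nodes with at least two children, plus the
#' root when it has at least three children (a bipolar soma is not a
#' process bifurcation). Segments are the maximal unbranched paths between
#' critical points (root, branch points, tips); equivalently, one segment
#' per non-root critical node. A single-node skeleton counts as one
#' (zero-length) segment.
#'
#' @param s a `skeleton`.
#' @return list of class `morph_metrics`: `total_process_length` (um),
#'   `n_branch_points`, `n_segments`.
#' @export
skeleton_morphometrics <- function(s) {
  stopifnot(inherits(s, "skeleton"))
  nd <- s$nodes
  if (nrow(nd) == 1)
    return(structure(list(total_process_length = 0, n_branch_points = 0L,
                          n_segments = 1L), class = "morph_metrics"))
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  child <- nd$parent != -1
  pi <- idx[as.character(nd$parent[child])]
  ci <- which(child)
  seg_len <- sqrt((nd$x[ci] - nd$x[pi])^2 + (nd$y[ci] - nd$y[pi])^2 +
                  (nd$z[ci] - nd$z[pi])^2)
  total <- sum(seg_len)
  n_children <- table(factor(nd$parent[child], levels = nd$id))
  is_root <- nd$parent == -1
  branch <- (!is_root & n_children >= 2) | (is_root & n_children >= 3)
  tip <- n_children == 0
  critical <- branch | tip | is_root
  n_segments <- sum(critical & !is_root)
  structure(list(total_process_length = total,
                 n_branch_points = sum(branch),
                 n_segments = as.integer(n_segments)),
            class = "morph_metrics")
}

#' Cell density per square millimetre
#'
#' @param n_cells cell count (>= 0).
#' @param area field area in mm^2 (> 0).
#' @return Cells per mm^2.
#' @export
cell_density <- function(n_cells, area) {
  if (any(area <= 0)) stop("area must be positive")
  stopifnot(all(n_cells >= 0))
  n_cells / area
}

#' Group statistics for morphometric comparisons
#'
#' Parametric mode: one-way ANOVA with Tukey HSD pairwise comparisons
#' (used for cell density and process length). Nonparametric mode:
#' Kruskal-Wallis (tie-corrected) with Dunn's pairwise z tests,
#' Bonferroni-adjusted (used for branch-point and segment counts).
#' When every group is constant at the same value the omnibus p is
#' reported as 1 with a flag.
#'
#' @param values list of numeric vectors, one per group (named).
#' @param mode `"parametric"` or `"nonparametric"`.
#' @return list of class `group_stats`: `test`, `statistic`, `p`,
#'   `pairwise` (data.frame group1, group2, p_adj), `flag`.
#' @export
group_stats <- function(values, mode = c("parametric", "nonparametric")) {
  mode <- match.arg(mode)
  stopifnot(length(values) >= 2, all(lengths(values) >= 2))
  if (is.null(names(values)))
    names(values) <- paste0("g", seq_along(values))
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  if (stats::var(y) == 0) {
    pairs <- t(utils::combn(names(values), 2))
    return(structure(list(
      test = if (mode == "parametric") "anova_tukey" else "kruskal_dunn",
      statistic = NA_real_, p = 1,
      pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                            p_adj = 1),
      flag = "zero_variance"), class = "group_stats"))
  }
  if (mode == "parametric") {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    structure(list(test = "anova_tukey",
                   statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                   pairwise = data.frame(group1 = pairs[, 2],
                                         group2 = pairs[, 1],
                                         p_adj = tk[, "p adj"],
                                         row.names = NULL),
                   flag = ""),
              class = "group_stats")
  } else {
    kw <- stats::kruskal.test(y, g)
    structure(list(test = "kruskal_dunn",
                   statistic = unname(kw$statistic), p = kw$p.value,
                   pairwise = dunn_pairwise(y, g),
                   flag = ""),
              class = "group_stats")
  }
}

#' Dunn's pairwise z tests after Kruskal-Wallis
#'
#' Rank-based pairwise comparisons on the pooled ranks with the standard
#' tie correction; two-sided normal p-values, Bonferroni-adjusted over all
#' group pairs.
#'
#' @param y pooled observations.
#' @param g group factor aligned with `y`.
#' @return data.frame `group1`, `group2`, `z`, `p_adj`.
#' @export
dunn_pairwise <- function(y, g) {
  g <- droplevels(as.factor(g))
  r <- rank(y)
  N <- length(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_adj = pmin(1, p * ncol(pairs)), row.names = NULL)
}
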