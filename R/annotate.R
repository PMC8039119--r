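#' Bundled brain cell-type marker panel
#'
#' The curated mouse-brain marker panel used to annotate clusters:
#' microglia, astrocytes, oligodendrocytes, endothelial cells, ependymal
#' cells, choroid plexus, neurons/neural stem cells, pericytes and a hybrid
#' (mixed neuronal / oligodendrocyte-precursor) class.
#'
#' @return Named list mapping cell-type name to marker gene symbols.
#' @export
default_marker_panel <- function() {
  list(
    microglia        = c("P2ry12", "Hexb", "Cx3cr1", "Siglech"),
    astrocytes       = c("Gja1", "Plpp3", "Slc1a2", "Aqp4"),
    oligodendrocytes = c("Plp1", "Mbp", "Mobp", "Trf"),
    endothelial      = c("Ly6c1", "Cldn5", "Pltp", "Pecam1"),
    ependymal        = c("Ccdc153", "Tmem212", "Dynlrb2", "Rsph4a"),
    choroid_plexus   = c("Kcnj13", "Flor1", "Clic6", "Kl"),
    neurons_nsc      = c("Meg3", "Snhg11", "Ndrg4", "Snap25"),
    pericytes        = c("Cald1", "Vtn", "Notch3"),
    hybrid           = c("Scn7a", "Map2", "C1ql1", "Pdgfra")
  )
}

#' Score clusters against a marker panel and assign identities
#'
#' For every marker gene the cluster means of lognorm expression are
#' z-scored across clusters; a cluster's score for a cell type is the mean
#' z-score over that type's markers present in the gene universe. Each
#' cluster is assigned the argmax type; when the top two scores differ by
#' less than `delta` the cluster is flagged ambiguous.
#'
#' @param x count matrix container with a `lognorm` layer.
#' @param labels a `cluster_labels` (or integer vector, one per cell).
#' @param panel named list of marker symbol vectors
#'   (default [default_marker_panel()]).
#' @param delta ambiguity margin on the top-two score gap.
#' @return list of class `annotation_result`: `assignments` data.frame
#'   (cluster, label, ambiguous, top_score, runner_up), `scores` matrix
#'   (clusters x types).
#' @export
score_marker_panels <- function(x, labels, panel = default_marker_panel(),
                                delta = 0.1) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else
    as.integer(labels)
  ln <- lognorm_values(x)
  present <- lapply(panel, intersect, rownames(ln))
  missing <- mapply(setdiff, panel, present, SIMPLIFY = FALSE)
  if (any(lengths(missing) > 0))
    message("markers absent from the gene universe: ",
            paste(unlist(missing), collapse = ", "))
  if (all(lengths(present) == 0))
    stop("no marker of any cell type is present in the gene universe")
  panel <- present[lengths(present) > 0]
  cl <- sort(unique(lab))
  genes <- unique(unlist(panel))
  cmeans <- vapply(cl, function(g)
    Matrix::rowMeans(ln[genes, lab == g, drop = FALSE]), numeric(length(genes)))
  cmeans <- matrix(cmeans, nrow = length(genes),
                   dimnames = list(genes, paste0("c", cl)))
  zs <- t(apply(cmeans, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (length(cl) == 1) zs <- matrix(0, length(genes), 1,
                                    dimnames = list(genes, paste0("c", cl)))
  scores <- t(vapply(names(panel), function(ty)
    colMeans(zs[panel[[ty]], , drop = FALSE]), numeric(length(cl))))
  scores <- matrix(scores, nrow = length(panel),
                   dimnames = list(names(panel), paste0("c", cl)))
  assign <- lapply(seq_along(cl), function(j) {
    s <- sort(scores[, j], decreasing = TRUE)
    data.frame(cluster = cl[j], label = names(s)[1],
               ambiguous = length(s) > 1 && (s[1] - s[2]) < delta,
               top_score = s[1],
               runner_up = if (length(s) > 1) s[2] else NA_real_)
  })
  structure(list(assignments = do.call(rbind, assign), scores = t(scores)),
            class = "annotation_result")
}

#' Per-group expression summary (dot-plot statistics)
#'
#' For each requested gene and each group: the percentage of cells with a
#' raw count above zero and the mean lognorm expression.
#'
#' @param x count matrix container with raw and `lognorm` layers.
#' @param grouping per-cell group labels.
#' @param genes gene symbols (must be present in the universe).
#' @return data.frame with columns `gene`, `group`, `pct_expressing`,
#'   `mean_lognorm`.
#' @export
group_expression_summary <- function(x, grouping, genes) {
  if (!all(genes %in% rownames(x)))
    stop("genes absent from the universe: ",
         paste(setdiff(genes, rownames(x)), collapse = ", "))
  stopifnot(length(grouping) == ncol(x))
  groups <- if (is.factor(grouping)) levels(grouping) else
    unique(as.character(grouping))
  grouping <- as.character(grouping)
  raw <- raw_counts(x)[genes, , drop = FALSE]
  ln <- lognorm_values(x)[genes, , drop = FALSE]
  out <- list()
  for (g in groups) {
    sel <- grouping == g
    if (!any(sel)) stop("empty group: ", g)
    out[[g]] <- data.frame(
      gene = genes, group = g,
      pct_expressing = 100 * Matrix::rowSums(raw[, sel, drop = FALSE] > 0) /
        sum(sel),
      mean_lognorm = Matrix::rowMeans(ln[, sel, drop = FALSE]),
      row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Purge contaminant-expressing cells from a target cluster
#'
#' Returns the cells of the target cluster with contaminated cells
#' removed: a cell is contaminated when at least `min_markers` of the
#' contaminant marker genes have a raw count above zero.
#'
#' @param x count matrix container.
#' @param labels a `cluster_labels` (or integer vector).
#' @param target_label cluster label of the population to purify.
#' @param contaminant_markers marker symbols indicating contamination
#'   (default the oligodendrocyte trio Mbp, Mag, Plp1).
#' @param min_markers how many detected markers condemn a cell (default 2).
#' @return The purified subset container (region labels intact).
#' @export
purify_subset <- function(x, labels, target_label,
                          contaminant_markers = c("Mbp", "Mag", "Plp1"),
                          min_markers = 2) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else
    as.integer(labels)
  stopifnot(length(lab) == ncol(x))
  in_target <- lab == target_label
  if (!any(in_target)) stop("no cells carry label ", target_label)
  sub <- x[, in_target]
  present <- intersect(contaminant_markers, rownames(sub))
  n_detected <- if (length(present))
    Matrix::colSums(raw_counts(sub)[present, , drop = FALSE] > 0)
  else rep(0, ncol(sub))
  bad <- n_detected >= min_markers
  if (all(bad)) stop("every target cell flagged as contaminated")
  message(sum(bad), " of ", ncol(sub), " target cells removed as contaminated")
  sub[, !bad]
}
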