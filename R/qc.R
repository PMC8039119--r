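#' Quality-control parameters
#'
#' Defaults follow the study design: a cell is flagged on the gene
#' criterion when it expresses fewer than 200 genes or more than 2 unscaled
#' MADs above the median; on the depth criterion when its total counts lie
#' more than 2 MADs above or below the median; on the mitochondrial
#' criterion when its mito percentage exceeds the median by more than 1.5
#' MADs. Cells failing at least `min_fail` (default 2) of the three
#' criteria are low quality. Genes expressed in fewer than
#' `min_cells_per_gene` (default 5) cells, and all mitochondrial/ribosomal
#' genes, are dropped.
#'
#' @param min_genes absolute floor on expressed genes per cell.
#' @param mad_genes,mad_counts,mad_mito MAD multipliers per criterion.
#' @param min_fail number of failed criteria that marks a cell low quality.
#' @param min_cells_per_gene gene-level detection floor.
#' @param mito_prefixes,ribo_prefixes case-insensitive symbol prefixes.
#' @param mad_constant scale factor applied to the MAD; 1 = unscaled
#'   (median absolute deviation from the median), 1.4826 = normal-consistent.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200, mad_genes = 2, mad_counts = 2,
                      mad_mito = 1.5, min_fail = 2, min_cells_per_gene = 5,
                      mito_prefixes = c("mt-"),
                      ribo_prefixes = c("Rps", "Rpl"),
                      mad_constant = 1) {
  stopifnot(min_genes > 0, mad_genes > 0, mad_counts > 0, mad_mito > 0,
            min_fail %in% 1:3, min_cells_per_gene > 0, mad_constant > 0)
  structure(list(min_genes = min_genes, mad_genes = mad_genes,
                 mad_counts = mad_counts, mad_mito = mad_mito,
                 min_fail = min_fail, min_cells_per_gene = min_cells_per_gene,
                 mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes,
                 mad_constant = mad_constant),
            class = "qc_params")
}

unscaled_mad <- function(x, constant = 1) {
  constant * stats::median(abs(x - stats::median(x)))
}

prefix_match <- function(symbols, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(symbols)))
  pat <- paste0("^(", paste(sapply(prefixes, function(p)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)), collapse = "|"), ")")
  grepl(pat, symbols, ignore.case = TRUE)
}

#' Select cell-containing barcodes at the knee of the barcode-rank curve
#'
#' Barcodes are sorted by total counts (descending); on the cumulative
#' count curve over log10 rank (both axes rescaled to the unit square) the
#' knee is the rank with maximal perpendicular distance to the chord
#' joining the curve's endpoints. Barcodes up to the knee are kept, capped
#' at `max_cells` if given.
#'
#' @param x count matrix container (raw layer).
#' @param max_cells optional hard cap on the number of selected barcodes.
#' @return The container restricted to selected barcodes, in rank order.
#' @export
knee_select <- function(x, max_cells = NULL) {
  totals <- Matrix::colSums(raw_counts(x))
  n <- length(totals)
  if (n < 3) stop("knee selection needs at least 3 barcodes")
  ord <- order(totals, decreasing = TRUE)
  sorted <- totals[ord]
  if (max(sorted) == min(sorted)) {
    warning("all barcodes have equal totals; no knee, returning all")
    keep <- ord
  } else {
    k <- knee_index(sorted)
    keep <- ord[seq_len(k)]
  }
  if (!is.null(max_cells)) keep <- keep[seq_len(min(max_cells, length(keep)))]
  x[, keep]
}

#' @rdname knee_select
#' @param sorted_totals totals sorted in decreasing order.
#' @return `knee_index`: the rank (1-based) of the knee.
#' @export
knee_index <- function(sorted_totals) {
  n <- length(sorted_totals)
  xs <- log10(seq_len(n))
  ys <- cumsum(as.numeric(sorted_totals))
  xs <- (xs - xs[1]) / (xs[n] - xs[1])
  ys <- (ys - ys[1]) / (ys[n] - ys[1])
  # signed distance from (xs, ys) to the chord from (0,0) to (1,1) is
  # (ys - xs) / sqrt(2); the knee sits where the concave cumulative curve
  # rises farthest above the chord
  which.max(ys - xs)
}

#' Per-cell quality metrics
#'
#' @param x count matrix container (raw layer).
#' @param params a [qc_params()].
#' @return data.frame with one row per cell: `barcode`, `region`,
#'   `n_genes_expressed`, `total_counts`, `pct_mito` (0 when the cell has
#'   zero total counts).
#' @export
qc_metrics <- function(x, params = qc_params()) {
  m <- raw_counts(x)
  mito <- prefix_match(rownames(m), params$mito_prefixes)
  total <- Matrix::colSums(m)
  mito_counts <- if (any(mito))
    Matrix::colSums(m[mito, , drop = FALSE]) else numeric(ncol(m))
  data.frame(
    barcode = colnames(m),
    region = regions(x),
    n_genes_expressed = Matrix::colSums(m > 0),
    total_counts = as.numeric(total),
    pct_mito = ifelse(total > 0, 100 * mito_counts / total, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

qc_flag_one_dataset <- function(met, params) {
  med_g <- stats::median(met$n_genes_expressed)
  mad_g <- unscaled_mad(met$n_genes_expressed, params$mad_constant)
  med_c <- stats::median(met$total_counts)
  mad_c <- unscaled_mad(met$total_counts, params$mad_constant)
  med_m <- stats::median(met$pct_mito)
  mad_m <- unscaled_mad(met$pct_mito, params$mad_constant)
  met$flag_genes <- met$n_genes_expressed < params$min_genes |
    met$n_genes_expressed > med_g + params$mad_genes * mad_g
  met$flag_counts <- abs(met$total_counts - med_c) > params$mad_counts * mad_c
  met$flag_mito <- met$pct_mito > med_m + params$mad_mito * mad_m
  met$low_quality <-
    (met$flag_genes + met$flag_counts + met$flag_mito) >= params$min_fail
  met
}

#' Flag and remove low-quality cells (2-of-3 MAD rule)
#'
#' The three criteria are evaluated separately within each region dataset;
#' a cell is low quality when at least `min_fail` criteria fail. Datasets
#' with fewer than 3 cells are passed through unfiltered with a warning.
#'
#' @param x count matrix container (raw layer).
#' @param params a [qc_params()].
#' @return `list(matrix = filtered container, qc = per-cell QC table with
#'   flag_genes/flag_counts/flag_mito/low_quality columns)`; the QC table
#'   covers all input cells.
#' @export
qc_filter <- function(x, params = qc_params()) {
  met <- qc_metrics(x, params)
  met$flag_genes <- met$flag_counts <- met$flag_mito <- FALSE
  met$low_quality <- FALSE
  parts <- split(seq_len(nrow(met)), met$region)
  for (idx in parts) {
    if (length(idx) < 3) {
      warning("fewer than 3 cells in dataset '", met$region[idx[1]],
              "'; QC filtering skipped for it")
    } else {
      met[idx, ] <- qc_flag_one_dataset(met[idx, , drop = FALSE], params)
    }
  }
  list(matrix = x[, !met$low_quality], qc = met)
}

#' Filter genes by detection and symbol prefix
#'
#' Keeps genes expressed (count > 0) in at least `min_cells_per_gene`
#' cells whose symbols match neither the mitochondrial nor the ribosomal
#' prefixes (case-insensitive).
#'
#' @param x count matrix container (cell filtering already applied).
#' @param params a [qc_params()].
#' @return The container restricted to kept genes.
#' @export
gene_filter <- function(x, params = qc_params()) {
  m <- raw_counts(x)
  n_cells_expr <- Matrix::rowSums(m > 0)
  drop_prefix <- prefix_match(rownames(m), params$mito_prefixes) |
    prefix_match(rownames(m), params$ribo_prefixes)
  keep <- n_cells_expr >= params$min_cells_per_gene & !drop_prefix
  if (!any(keep)) stop("gene filter removed every gene")
  x[keep, ]
}
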