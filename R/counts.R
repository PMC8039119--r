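#' Construct a count matrix container
#'
#' Wraps a genes x cells matrix of non-negative integer UMI counts in a
#' [SingleCellExperiment::SingleCellExperiment] with a per-cell `region`
#' label. The raw counts live in the `"counts"` assay; [lognormalize()]
#' adds a `"lognorm"` assay alongside.
#'
#' @param counts genes x cells matrix (base or [Matrix::Matrix]) of
#'   non-negative integers, with unique rownames (gene symbols) and unique
#'   colnames (cell barcodes).
#' @param region character scalar or per-cell vector of region labels
#'   (e.g. `"midbrain"`, `"striatum"`).
#' @return A `SingleCellExperiment` with assay `counts` and
#'   `colData(x)$region`.
#' @export
count_matrix <- function(counts, region) {
  if (!methods::is(counts, "CsparseMatrix"))
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  counts <- methods::as(counts, "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene symbols as rownames and barcodes as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell barcodes")
  v <- counts@x
  if (anyNA(v)) stop("counts contain missing values")
  if (length(v) && (any(v < 0) || any(v != trunc(v))))
    stop("counts must be non-negative integers")
  if (length(region) == 1L) region <- rep(region, ncol(counts))
  if (length(region) != ncol(counts))
    stop("region must be length 1 or one label per cell")
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(region = as.character(region),
                                   row.names = colnames(counts))
  )
}

#' @rdname count_matrix
#' @param x a count matrix container.
#' @export
regions <- function(x) SummarizedExperiment::colData(x)$region

raw_counts <- function(x) SummarizedExperiment::assay(x, "counts")

lognorm_values <- function(x) {
  if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
    stop("no lognorm layer; run lognormalize() first")
  SummarizedExperiment::assay(x, "lognorm")
}

#' Read a count matrix from disk
#'
#' Supports the two interchange formats used downstream of droplet
#' pipelines: a dense digital-gene-expression (DGE) TSV (genes in rows,
#' first column gene symbols, header row of cell barcodes) and a
#' MatrixMarket sparse triplet (`matrix.mtx` genes x cells) with
#' `barcodes.tsv` / `features.tsv` sidecars.
#'
#' @param path file path (`dge_tsv`) or directory containing
#'   `matrix.mtx`, `barcodes.tsv` and `features.tsv` (`mtx`).
#' @param format `"dge_tsv"` or `"mtx"`.
#' @param region_label region label attached to every cell.
#' @return A count matrix container (see [count_matrix()]), layer `counts`.
#' @export
load_counts <- function(path, format = c("dge_tsv", "mtx"), region_label) {
  format <- match.arg(format)
  if (format == "dge_tsv") {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0) stop("empty file: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("DGE TSV needs a gene column and >=1 cell column")
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in DGE TSV")
    rownames(m) <- genes
  } else {
    mtx <- file.path(path, "matrix.mtx")
    bc  <- file.path(path, "barcodes.tsv")
    ft  <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) if (!file.exists(f)) stop("no such file: ", f)
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    barcodes <- readLines(bc)
    features <- vapply(strsplit(readLines(ft), "\t"), `[`, "", 1L)
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
      stop("dimension mismatch between matrix.mtx and its sidecars")
    rownames(m) <- features
    colnames(m) <- barcodes
  }
  count_matrix(m, region_label)
}

#' Write a count matrix to disk
#'
#' Writes both interchange formats: a MatrixMarket triplet with sidecars
#' into `dir`, and a dense DGE TSV (genes x cells) when `dense = TRUE`.
#'
#' @param x count matrix container.
#' @param dir output directory (created if missing).
#' @param dense also write `dge.tsv` alongside the sparse triplet.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir, dense = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- raw_counts(x)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  if (dense) {
    dm <- as.matrix(m)
    df <- data.frame(gene = rownames(dm), dm, check.names = FALSE)
    utils::write.table(df, file.path(dir, "dge.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(
    data.frame(barcode = colnames(m), region = regions(x)),
    file.path(dir, "regions.csv"), row.names = FALSE)
  invisible(dir)
}

#' Concatenate per-region count matrices
#'
#' Stacks cells over the intersection of the gene universes, with gene
#' order canonicalized lexicographically. Barcodes duplicated across
#' inputs are suffixed with their region label.
#'
#' @param matrices list of count matrix containers (raw layer).
#' @return One combined container.
#' @export
concatenate_counts <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1L) return(matrices[[1L]])
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0) stop("empty gene intersection")
  genes <- sort(genes)
  parts <- lapply(matrices, function(m) raw_counts(m)[genes, , drop = FALSE])
  bcs <- unlist(lapply(parts, colnames), use.names = FALSE)
  reg <- unlist(lapply(matrices, regions), use.names = FALSE)
  dup <- duplicated(bcs) | duplicated(bcs, fromLast = TRUE)
  if (any(dup)) bcs[dup] <- paste(bcs[dup], reg[dup], sep = "_")
  combined <- do.call(cbind, parts)
  colnames(combined) <- bcs
  count_matrix(combined, reg)
}
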