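#' Construct a gene signature
#'
#' A named gene set with a direction of change (+1 up, -1 down) per gene.
#'
#' @param name signature name.
#' @param genes unique gene symbols.
#' @param direction per-gene +1/-1 (or a single value recycled).
#' @param source optional provenance tag.
#' @return list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, direction, source = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("empty signature: ", name)
  if (anyDuplicated(genes)) stop("duplicate symbols in signature ", name)
  if (length(direction) == 1L) direction <- rep(direction, length(genes))
  if (length(direction) != length(genes) || !all(direction %in% c(-1, 1)))
    stop("direction must be +1/-1 for every gene")
  structure(list(name = name, genes = genes,
                 direction = stats::setNames(as.integer(direction), genes),
                 source = source),
            class = "gene_signature")
}

#' Read/write a signature as two-column TSV (gene, direction)
#'
#' @param path TSV path.
#' @param name,source metadata for the loaded signature.
#' @return `read_signature`: a `gene_signature`.
#' @export
read_signature <- function(path, name = basename(path), source = path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  gene_signature(name, tab[[1]], tab[[2]], source)
}

#' @rdname read_signature
#' @param sig a `gene_signature`.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(
    data.frame(gene = sig$genes, direction = unname(sig$direction)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Signature overlap (Venn counts)
#'
#' Case-sensitive symbol intersection of two signatures; `case_fold = TRUE`
#' matches case-insensitively (public gene lists mix cases).
#'
#' @param a,b `gene_signature` objects.
#' @param case_fold match symbols case-insensitively.
#' @return list of class `overlap_result`: `n_a`, `n_b`, `n_shared`,
#'   `pct_shared_of_a` (100 * n_shared / n_a), `shared` (symbols as spelled
#'   in `a`), plus NA concordance fields until
#'   [direction_concordance()] fills them.
#' @export
signature_overlap <- function(a, b, case_fold = FALSE) {
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  ga <- a$genes; gb <- b$genes
  shared <- if (case_fold) ga[tolower(ga) %in% tolower(gb)] else
    intersect(ga, gb)
  structure(list(n_a = length(ga), n_b = length(gb),
                 n_shared = length(shared),
                 pct_shared_of_a = 100 * length(shared) / length(ga),
                 shared = shared,
                 n_concordant = NA_integer_, pct_concordant = NA_real_),
            class = "overlap_result")
}

#' Direction concordance over shared genes
#'
#' A shared gene is concordant when its direction of change is the same in
#' both signatures; the percentage is relative to the shared count.
#'
#' @param a,b `gene_signature` objects.
#' @param shared shared symbols (default: recomputed via
#'   [signature_overlap()]).
#' @param case_fold match symbols case-insensitively.
#' @return An `overlap_result` with `n_concordant` and `pct_concordant`
#'   filled in.
#' @export
direction_concordance <- function(a, b, shared = NULL, case_fold = FALSE) {
  ov <- signature_overlap(a, b, case_fold)
  if (is.null(shared)) shared <- ov$shared
  if (!length(shared)) stop("shared gene set is empty")
  da <- a$direction[shared]
  db <- if (case_fold)
    b$direction[match(tolower(shared), tolower(b$genes))]
  else b$direction[shared]
  if (any(is.na(da)) || any(is.na(db)))
    stop("gene missing a direction in one of the signatures")
  conc <- sum(da == db)
  ov$n_shared <- length(shared)
  ov$n_concordant <- conc
  ov$pct_concordant <- 100 * conc / length(shared)
  ov
}

#' Relative qPCR expression (2^-dCT)
#'
#' The difference in threshold cycles between the target gene and the
#' reference gene gives the standardized expression level dCT; relative
#' expression is `2^-dCT`.
#'
#' @param ct_target,ct_reference threshold cycles (finite; vectorized).
#' @return `2^-(ct_target - ct_reference)`.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("threshold cycles must be finite")
  2^(-(ct_target - ct_reference))
}
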