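#' Multiple-testing adjustment
#'
#' Bonferroni: `min(1, m * p)`. Benjamini-Hochberg: step-up with enforced
#' monotonicity, capped at 1.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  ord <- order(p, decreasing = TRUE)
  ranked <- m / (m - seq_len(m) + 1) * p[ord]   # m/k * p_(k), largest first
  adj <- pmin(1, cummin(ranked))
  out <- numeric(m)
  out[ord] <- adj
  out
}

log_safe <- function(v) log(pmax(v, 1e-8))

#' Hurdle differential expression for one two-group comparison
#'
#' Two-part test per gene, with the per-cell total transcript count as a
#' covariate: a logistic regression of detection (raw count > 0) on group +
#' log(total counts), and a Gaussian linear model of lognorm expression
#' among detected cells on the same design. Each part contributes a
#' likelihood-ratio statistic against the covariate-only reduced model; the
#' p-value is the chi-square tail of the summed statistics at the summed
#' degrees of freedom. Log fold change is the natural-log difference of
#' group means of lognorm values (group minus rest); pct_1/pct_2 are
#' percent-expressing per group.
#'
#' @param x count matrix container with raw and `lognorm` layers.
#' @param group_mask logical per cell: TRUE = group of interest.
#' @param covariate per-cell total transcript counts (defaults to column
#'   sums of the raw layer).
#' @return data.frame, one row per gene: `gene`, `log_fc`, `pct_1`,
#'   `pct_2`, `p_raw`, `flag` (`""`, `"low_detection"`, or
#'   `"fisher_fallback"`).
#' @export
hurdle_de <- function(x, group_mask, covariate = NULL) {
  stopifnot(is.logical(group_mask), length(group_mask) == ncol(x))
  if (!any(group_mask) || all(group_mask))
    stop("both groups must be non-empty")
  raw <- as.matrix(raw_counts(x))
  ln <- as.matrix(lognorm_values(x))
  if (is.null(covariate)) covariate <- colSums(raw)
  stopifnot(length(covariate) == ncol(x))
  lcov <- log_safe(covariate)
  grp <- as.numeric(group_mask)
  n1 <- sum(group_mask); n2 <- sum(!group_mask)
  genes <- rownames(raw)
  out <- data.frame(gene = genes, log_fc = NA_real_, pct_1 = NA_real_,
                    pct_2 = NA_real_, p_raw = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    y <- ln[gi, ]
    det <- raw[gi, ] > 0
    out$log_fc[gi] <- mean(y[group_mask]) - mean(y[!group_mask])
    out$pct_1[gi] <- 100 * sum(det & group_mask) / n1
    out$pct_2[gi] <- 100 * sum(det & !group_mask) / n2
    if (sum(det) < 3) {
      out$p_raw[gi] <- 1
      out$flag[gi] <- "low_detection"
      next
    }
    res <- hurdle_test_one(y, det, grp, lcov)
    out$p_raw[gi] <- res$p
    out$flag[gi] <- res$flag
  }
  out
}

hurdle_test_one <- function(y, det, grp, lcov) {
  flag <- ""
  lr <- 0; df <- 0
  # discrete part: detection ~ group + log(covariate)
  dfull <- tryCatch(
    suppressWarnings(stats::glm(det ~ grp + lcov, family = stats::binomial())),
    error = function(e) NULL)
  dred <- tryCatch(
    suppressWarnings(stats::glm(det ~ lcov, family = stats::binomial())),
    error = function(e) NULL)
  separated <- is.null(dfull) || !dfull$converged ||
    any(abs(stats::coef(dfull)["grp"]) > 15, na.rm = TRUE)
  if (separated) {
    # complete separation: fall back to Fisher's exact on detection
    p <- stats::fisher.test(table(factor(det, c(FALSE, TRUE)),
                                  factor(grp, c(0, 1))))$p.value
    return(list(p = p, flag = "fisher_fallback"))
  }
  if (!all(det) && any(det)) {
    lr <- lr + max(0, dred$deviance - dfull$deviance)
    df <- df + 1
  }
  # continuous part among detected cells, needs both groups represented;
  # the LR contribution is taken as the chi-square deviate of the exact
  # F test, which keeps genes with few detected cells calibrated
  di <- which(det)
  if (length(unique(grp[di])) == 2 && length(di) >= 4) {
    f_full <- stats::lm(y[di] ~ grp[di] + lcov[di])
    f_red <- stats::lm(y[di] ~ lcov[di])
    if (sum(stats::resid(f_full)^2) > 0) {
      pF <- stats::anova(f_red, f_full)[2, "Pr(>F)"]
      if (is.finite(pF)) {
        lr <- lr + stats::qchisq(max(pF, 1e-300), 1, lower.tail = FALSE)
        df <- df + 1
      }
    }
  }
  if (df == 0) return(list(p = 1, flag = "degenerate"))
  list(p = stats::pchisq(lr, df, lower.tail = FALSE), flag = flag)
}

#' One-vs-rest marker detection across all clusters
#'
#' Runs [hurdle_de()] of each cluster against all other cells, with no
#' gene pre-filtering (log-FC threshold 0, minimum percent 0), and applies
#' Bonferroni correction over genes within each comparison. Singleton
#' clusters are skipped with a warning.
#'
#' @param x count matrix container with raw and `lognorm` layers.
#' @param labels a `cluster_labels` (or integer vector, one per cell).
#' @param covariate per-cell total transcript counts (default: raw column
#'   sums).
#' @return data.frame with one row per (cluster, gene): columns of
#'   [hurdle_de()] plus `group` and `p_adj`.
#' @export
find_all_markers <- function(x, labels, covariate = NULL) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else
    as.integer(labels)
  stopifnot(length(lab) == ncol(x))
  cl <- sort(unique(lab))
  if (length(cl) < 2) stop("need at least 2 clusters")
  out <- list()
  for (g in cl) {
    mask <- lab == g
    if (sum(mask) < 2) {
      warning("cluster ", g, " is a singleton; skipped")
      next
    }
    tab <- hurdle_de(x, mask, covariate)
    tab$group <- g
    tab$p_adj <- adjust_pvalues(tab$p_raw, "bonferroni")
    out[[as.character(g)]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Negative-binomial GLM differential expression across subsets
#'
#' Per gene, a log-link negative-binomial GLM of raw counts on the subset
#' factor plus log(total transcripts), tested against the covariate-only
#' reduced model by a likelihood-ratio chi-square. The per-gene NB size is
#' estimated by method of moments on the residuals of a full-model Poisson
#' fit (dispersion floored at 1e-8, i.e. near-Poisson when the data are
#' underdispersed). Genes whose fit fails fall
#' back to a Poisson GLM and are flagged. BH q-values are computed across
#' genes.
#'
#' @param x count matrix container (raw layer).
#' @param subset_labels per-cell subset labels (>= 2 distinct).
#' @param covariate per-cell total transcript counts (default: raw column
#'   sums).
#' @return data.frame per gene: `gene`, `p_raw`, `q_value`, `flag`.
#' @export
nb_glm_de <- function(x, subset_labels, covariate = NULL) {
  raw <- as.matrix(raw_counts(x))
  fac <- factor(subset_labels)
  stopifnot(length(fac) == ncol(x))
  if (nlevels(fac) < 2) stop("need at least 2 subset labels")
  if (is.null(covariate)) covariate <- colSums(raw)
  lcov <- log_safe(covariate)
  genes <- rownames(raw)
  p <- rep(NA_real_, length(genes))
  flag <- character(length(genes))
  df <- nlevels(fac) - 1
  for (gi in seq_along(genes)) {
    yv <- as.numeric(raw[gi, ])
    if (sum(yv > 0) < 3) { p[gi] <- 1; flag[gi] <- "low_detection"; next }
    # moments taken on the full-model Poisson residuals, so that covariate-
    # and group-driven variance is not mistaken for overdispersion
    size <- tryCatch({
      pois <- suppressWarnings(stats::glm(yv ~ fac + lcov,
                                          family = stats::poisson()))
      suppressWarnings(MASS::theta.mm(yv, stats::fitted(pois),
                                      pois$df.residual))
    }, error = function(e) NA_real_)
    if (!is.finite(size) || size <= 0) size <- 1e8
    size <- min(max(size, 1e-8), 1e8)
    fam <- MASS::negative.binomial(theta = size)
    fit <- tryCatch({
      full <- suppressWarnings(stats::glm(yv ~ fac + lcov, family = fam))
      red <- suppressWarnings(stats::glm(yv ~ lcov, family = fam))
      if (!full$converged || !red$converged) stop("no convergence")
      list(full = full, red = red, fb = "")
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        full <- suppressWarnings(stats::glm(yv ~ fac + lcov,
                                            family = stats::poisson()))
        red <- suppressWarnings(stats::glm(yv ~ lcov,
                                           family = stats::poisson()))
        list(full = full, red = red, fb = "poisson_fallback")
      }, error = function(e) NULL)
    }
    if (is.null(fit)) { p[gi] <- 1; flag[gi] <- "fit_failed"; next }
    lr <- max(0, fit$red$deviance - fit$full$deviance)
    p[gi] <- stats::pchisq(lr, df, lower.tail = FALSE)
    flag[gi] <- fit$fb
  }
  data.frame(gene = genes, p_raw = p,
             q_value = adjust_pvalues(p, "bh"),
             flag = flag, stringsAsFactors = FALSE)
}
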