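#' Specify a synthetic droplet dataset
#'
#' A `sim_spec` captures everything [simulate_dataset()] needs: gene panel
#' size and naming, per-type negative-binomial expression profiles, the
#' per-cell depth model, planted expression programs (sub-states), and the
#' fractions of artifact barcodes (empty droplets, high-mitochondrial
#' cells, contaminated cells).
#'
#' @param n_genes number of genes in the panel.
#' @param cell_types list of `list(name=, n_cells=c(region = count, ...),
#'   profile = numeric(n_genes))` where `profile` holds per-gene NB means at
#'   unit depth.
#' @param dispersion NB size (inverse-dispersion) parameter, shared across
#'   genes; larger is closer to Poisson.
#' @param depth_lognormal `c(meanlog, sdlog)` of the per-cell library-size
#'   factor.
#' @param signature_plants list of `list(cell_type=, genes=, log2fc=,
#'   substate=, fraction=)`: a random `fraction` of that type's cells gets
#'   the named genes scaled by `2^log2fc` and is labelled with `substate`.
#' @param artifact_fractions `c(empty=, high_mito=, contaminated=)`,
#'   fractions of the ordinary cell count appended as artifact barcodes.
#' @param mito_gene_count,ribo_gene_count how many panel genes carry
#'   mitochondrial (`mt-`) and ribosomal (`Rps`/`Rpl`) prefixes.
#' @param gene_names optional length-`n_genes` character vector; by default
#'   mito/ribo prefixes are assigned to the leading genes and the rest are
#'   `g0001`, `g0002`, ...
#' @param seed integer RNG seed; all randomness in [simulate_dataset()]
#'   derives from it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes, cell_types, dispersion = 2,
                     depth_lognormal = c(0, 0.25),
                     signature_plants = list(),
                     artifact_fractions = c(empty = 0, high_mito = 0,
                                            contaminated = 0),
                     mito_gene_count = 10, ribo_gene_count = 10,
                     gene_names = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, dispersion > 0, length(depth_lognormal) == 2,
            mito_gene_count >= 0, ribo_gene_count >= 0,
            mito_gene_count + ribo_gene_count <= n_genes)
  if (length(cell_types) == 0) stop("at least one cell type is required")
  af <- artifact_fractions
  for (nm in c("empty", "high_mito", "contaminated"))
    if (!nm %in% names(af)) af[nm] <- 0
  af <- af[c("empty", "high_mito", "contaminated")]
  if (any(af < 0 | af > 1)) stop("artifact fractions must lie in [0, 1]")
  if (is.null(gene_names)) {
    gene_names <- sprintf("g%04d", seq_len(n_genes))
    if (mito_gene_count > 0)
      gene_names[seq_len(mito_gene_count)] <-
        sprintf("mt-Sim%d", seq_len(mito_gene_count))
    if (ribo_gene_count > 0) {
      idx <- mito_gene_count + seq_len(ribo_gene_count)
      pre <- rep(c("Rps", "Rpl"), length.out = ribo_gene_count)
      gene_names[idx] <- sprintf("%sSim%d", pre, seq_len(ribo_gene_count))
    }
  }
  if (length(gene_names) != n_genes || anyDuplicated(gene_names))
    stop("gene_names must be ", n_genes, " unique symbols")
  for (ct in cell_types) {
    if (is.null(ct$name) || is.null(ct$n_cells) || is.null(ct$profile))
      stop("each cell type needs name, n_cells and profile")
    if (length(ct$profile) != n_genes)
      stop("profile length != n_genes for type ", ct$name)
    if (any(ct$profile < 0)) stop("profiles must be non-negative")
    if (any(ct$n_cells < 0)) stop("cell counts must be non-negative")
  }
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 dispersion = dispersion, depth_lognormal = depth_lognormal,
                 signature_plants = signature_plants,
                 artifact_fractions = af,
                 mito_gene_count = mito_gene_count,
                 ribo_gene_count = ribo_gene_count,
                 gene_names = gene_names, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Study-like default simulation spec
#'
#' Emulates a dissociated midbrain/striatum suspension: four major brain
#' cell types carrying the bundled marker panel at strong (default 6-fold)
#' enrichment, microglia split into homeostatic and immune-alerted
#' sub-states (inflammatory genes up, homeostatic genes down), plus empty
#' droplets, high-mitochondrial cells and oligodendrocyte-contaminated
#' microglia at the given fractions.
#'
#' @param n_genes panel size.
#' @param cells_per_type per-region cell count for each of the four types.
#' @param marker_fold fold-change of each type's marker genes over baseline.
#' @param alerted_fraction fraction of microglia planted as immune-alerted.
#' @param artifact_fractions see [sim_spec()].
#' @param seed RNG seed (profiles and simulation both derive from it).
#' @return A `sim_spec`.
#' @export
brain_sim_spec <- function(n_genes = 1500,
                           cells_per_type = c(midbrain = 120, striatum = 120),
                           marker_fold = 6,
                           alerted_fraction = 0.3,
                           artifact_fractions = c(empty = 0.15,
                                                  high_mito = 0.05,
                                                  contaminated = 0.05),
                           seed = 1L) {
  panel <- default_marker_panel()[c("microglia", "astrocytes",
                                    "oligodendrocytes", "endothelial")]
  alerted_up <- c("Cd83", "Il1b", "Cd74", "Cd14", "Gpr84", "Socs3", "Ccl4",
                  "Nfkbiz", "Icam1", "Fth1")
  contam <- c("Mbp", "Mag", "Plp1")
  mito_n <- 10L; ribo_n <- 10L
  named <- unique(c(unlist(panel, use.names = FALSE), alerted_up, contam))
  stopifnot(n_genes >= mito_n + ribo_n + length(named) + 50)
  gene_names <- sprintf("g%04d", seq_len(n_genes))
  gene_names[seq_len(mito_n)] <- sprintf("mt-Sim%d", seq_len(mito_n))
  gene_names[mito_n + seq_len(ribo_n)] <-
    sprintf("%sSim%d", rep(c("Rps", "Rpl"), length.out = ribo_n), seq_len(ribo_n))
  gene_names[mito_n + ribo_n + seq_along(named)] <- named

  set.seed(seed)
  baseline <- stats::rexp(n_genes, rate = 2)          # mean 0.5 per gene
  baseline[seq_len(mito_n)] <- 2.5                    # ~5% mito at baseline
  # oligodendrocyte markers are (near) silent outside their own lineage
  baseline[match(contam, gene_names)] <- 0.02
  # each type expresses its markers plus a dedicated ~50-gene program
  prog_n <- 50L
  free <- setdiff(seq_len(n_genes),
                  c(seq_len(mito_n + ribo_n),
                    match(named, gene_names)))
  profiles <- lapply(seq_along(panel), function(ti) {
    ty <- names(panel)[ti]
    p <- baseline
    mk <- match(panel[[ty]], gene_names)
    prog <- free[(ti - 1L) * prog_n + seq_len(max(0L, prog_n - length(mk)))]
    up <- c(mk, prog)
    p[up] <- marker_fold * pmax(baseline[up], 0.5)
    p
  })
  names(profiles) <- names(panel)
  # oligodendrocyte contaminant markers are dependable in their own type
  profiles$oligodendrocytes[match(contam, gene_names)] <-
    pmax(profiles$oligodendrocytes[match(contam, gene_names)], 5)

  cts <- lapply(names(panel), function(ty)
    list(name = ty, n_cells = cells_per_type, profile = profiles[[ty]]))
  plants <- list(list(cell_type = "microglia", genes = alerted_up,
                      log2fc = 2, substate = "immune_alerted",
                      fraction = alerted_fraction))
  sim_spec(n_genes, cts, dispersion = 2, depth_lognormal = c(0, 0.25),
           signature_plants = plants, artifact_fractions = artifact_fractions,
           mito_gene_count = mito_n, ribo_gene_count = ribo_n,
           gene_names = gene_names, seed = seed)
}

#' Simulate a droplet count matrix with planted ground truth
#'
#' Counts are gamma-Poisson: gene g in cell i is NB with mean
#' `profile[g] * depth[i]` and shared size (inverse-dispersion). Artifact
#' barcodes are appended and the whole column order shuffled; the returned
#' truth table carries the permutation.
#'
#' Artifact construction: empty droplets draw a multinomial over the mean
#' (ambient) profile with totals at most 5% of the median real-cell depth;
#' high-mito cells are low-depth cells whose mitochondrial counts are
#' resampled so their mito fraction exceeds the clean-cohort median by at
#' least 3 unscaled MADs (these cells violate both the depth and the mito
#' quality criteria); contaminated cells are microglia with a scaled
#' oligodendrocyte profile added on top, guaranteeing non-zero
#' Mbp/Mag/Plp1-analog counts in expectation.
#'
#' @param spec a [sim_spec()].
#' @return `list(matrix = <count matrix container>, truth = <data.frame>)`;
#'   truth has one row per barcode in matrix column order with columns
#'   `barcode`, `cell_type`, `region`, `artifact`
#'   (`none|empty|high_mito|contaminated`) and `substate`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  mito_idx <- grep("^mt-", spec$gene_names, ignore.case = TRUE)

  blocks <- list(); meta <- list()
  for (ct in spec$cell_types) {
    for (rg in names(ct$n_cells)) {
      n <- ct$n_cells[[rg]]
      if (n == 0) next
      depth <- stats::rlnorm(n, spec$depth_lognormal[1], spec$depth_lognormal[2])
      mu <- outer(ct$profile, depth)
      cnt <- matrix(stats::rnbinom(G * n, mu = mu, size = spec$dispersion), G, n)
      sub <- rep("base", n)
      for (pl in spec$signature_plants) {
        if (!identical(pl$cell_type, ct$name)) next
        frac <- if (is.null(pl$fraction)) 0.5 else pl$fraction
        hit <- which(stats::runif(n) < frac)
        gi <- if (is.character(pl$genes)) match(pl$genes, spec$gene_names) else pl$genes
        gi <- gi[!is.na(gi)]
        if (length(hit) && length(gi)) {
          mu2 <- outer(ct$profile[gi] * 2^pl$log2fc, depth[hit])
          cnt[gi, hit] <- stats::rnbinom(length(mu2), mu = mu2,
                                         size = spec$dispersion)
          sub[hit] <- if (is.null(pl$substate)) "planted" else pl$substate
        }
      }
      blocks[[length(blocks) + 1]] <- cnt
      meta[[length(meta) + 1]] <- data.frame(
        cell_type = ct$name, region = rg, artifact = "none", substate = sub,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  truth <- do.call(rbind, meta)
  n_real <- ncol(counts)
  real_totals <- colSums(counts)
  med_total <- stats::median(real_totals)
  region_pool <- unique(truth$region)

  af <- spec$artifact_fractions
  n_empty <- round(af[["empty"]] * n_real)
  n_hm    <- round(af[["high_mito"]] * n_real)
  n_cont  <- round(af[["contaminated"]] * n_real)

  prof_mat <- vapply(spec$cell_types, `[[`, numeric(G), "profile")
  ambient <- rowMeans(prof_mat)
  micro_i <- which(vapply(spec$cell_types, `[[`, "", "name") == "microglia")
  if (!length(micro_i)) micro_i <- 1L
  oligo_i <- which(vapply(spec$cell_types, `[[`, "", "name") == "oligodendrocytes")

  add_block <- function(cnt, kind, base_type) {
    n <- ncol(cnt)
    counts <<- cbind(counts, cnt)
    truth <<- rbind(truth, data.frame(
      cell_type = base_type, region = sample(region_pool, n, replace = TRUE),
      artifact = kind, substate = "base", stringsAsFactors = FALSE))
  }

  if (n_empty > 0) {
    tot <- pmax(1, round(stats::runif(n_empty, 0.005, 0.05) * med_total))
    cnt <- vapply(tot, function(t)
      as.vector(stats::rmultinom(1, t, prob = ambient + 1e-9)), numeric(G))
    add_block(cnt, "empty", "ambient")
  }

  if (n_hm > 0) {
    base_prof <- spec$cell_types[[micro_i]]$profile
    depth <- 0.15 * stats::rlnorm(n_hm, spec$depth_lognormal[1],
                                  spec$depth_lognormal[2])
    cnt <- matrix(stats::rnbinom(G * n_hm, mu = outer(base_prof, depth),
                                 size = spec$dispersion), G, n_hm)
    if (length(mito_idx)) {
      pm <- 100 * colSums(counts[mito_idx, , drop = FALSE]) /
        pmax(1, colSums(counts))
      thr <- stats::median(pm) + 4 * stats::median(abs(pm - stats::median(pm)))
      target <- pmin(95, pmax(thr, stats::median(pm) + 25)) / 100
      for (j in seq_len(n_hm)) {
        non_mito <- sum(cnt[-mito_idx, j])
        need <- max(1, round(target[1] / (1 - target[1]) * max(non_mito, 10)))
        pr <- base_prof[mito_idx] + 1e-9
        cnt[mito_idx, j] <- as.vector(stats::rmultinom(1, need, prob = pr))
      }
    }
    add_block(cnt, "high_mito", spec$cell_types[[micro_i]]$name)
  }

  if (n_cont > 0) {
    mg_prof <- spec$cell_types[[micro_i]]$profile
    ol_prof <- if (length(oligo_i)) spec$cell_types[[oligo_i]]$profile else {
      p <- numeric(G)
      gi <- match(c("Mbp", "Mag", "Plp1"), spec$gene_names)
      gi <- gi[!is.na(gi)]
      if (!length(gi)) gi <- seq_len(min(3, G))
      p[gi] <- 10
      p
    }
    depth <- stats::rlnorm(n_cont, spec$depth_lognormal[1],
                           spec$depth_lognormal[2])
    prof <- mg_prof + 0.15 * ol_prof
    ci <- match(c("Mbp", "Mag", "Plp1"), spec$gene_names)
    ci <- ci[!is.na(ci)]
    # contaminant transcripts are reliably present without dragging the
    # cell out of the microglia neighborhood
    if (length(ci)) prof[ci] <- pmax(prof[ci], 5)
    mu <- outer(prof, depth)
    cnt <- matrix(stats::rnbinom(G * n_cont, mu = mu, size = spec$dispersion),
                  G, n_cont)
    add_block(cnt, "contaminated", spec$cell_types[[micro_i]]$name)
  }

  n_all <- ncol(counts)
  perm <- sample.int(n_all)
  counts <- counts[, perm, drop = FALSE]
  truth <- truth[perm, , drop = FALSE]
  truth$barcode <- sprintf("BC%05d", seq_len(n_all))
  truth <- truth[, c("barcode", "cell_type", "region", "artifact", "substate")]
  rownames(truth) <- NULL
  rownames(counts) <- spec$gene_names
  colnames(counts) <- truth$barcode
  list(matrix = count_matrix(counts, truth$region), truth = truth)
}

#' Simulate a microglia skeleton with known morphometrics
#'
#' Grows a rooted binary tree: one trunk process from the soma, then
#' `n_branch_events` bifurcations at randomly chosen tips, every segment a
#' straight edge of `segment_length` micrometres in a random 3D direction.
#' By construction the tree has total length
#' `(2 * n_branch_events + 1) * segment_length`, `n_branch_events` branch
#' points and `2 * n_branch_events + 1` segments.
#'
#' @param n_branch_events number of bifurcations (>= 0).
#' @param segment_length edge length in micrometres (> 0).
#' @param seed RNG seed.
#' @return A `skeleton` (see [skeleton()]).
#' @export
simulate_skeleton <- function(n_branch_events, segment_length, seed = 1L) {
  stopifnot(n_branch_events >= 0)
  if (segment_length <= 0) stop("segment_length must be positive")
  set.seed(seed)
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 2, parent = -1L)
  add_node <- function(parent_id, pos) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, 3L, pos[1], pos[2], pos[3], 0.5, parent_id)
    id
  }
  tip <- add_node(1L, rand_dir() * segment_length)
  tips <- tip
  for (e in seq_len(n_branch_events)) {
    pick <- if (length(tips) == 1L) 1L else sample.int(length(tips), 1L)
    pid <- tips[pick]
    base <- as.numeric(nodes[pid, c("x", "y", "z")])
    kids <- c(add_node(pid, base + rand_dir() * segment_length),
              add_node(pid, base + rand_dir() * segment_length))
    tips <- c(tips[-pick], kids)
  }
  skeleton(nodes)
}
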