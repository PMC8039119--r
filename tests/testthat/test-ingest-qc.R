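test_that("DGE TSV loading matches a hand parse", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tAAAC\tGGGT",
               "Actb\t3\t0",
               "Hexb\t1\t2",
               "Gja1\t0\t5"), f)
  x <- load_counts(f, "dge_tsv", region_label = "midbrain")
  expect_equal(dim(x), c(3L, 2L))
  m <- as.matrix(miglia:::raw_counts(x))
  expect_equal(unname(m),
               matrix(c(3, 1, 0, 0, 2, 5), 3, 2))
  expect_equal(rownames(m), c("Actb", "Hexb", "Gja1"))
  expect_equal(colnames(m), c("AAAC", "GGGT"))
  expect_equal(unique(regions(x)), "midbrain")
})

test_that("empty files and malformed inputs error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_error(load_counts(f, "dge_tsv", "m"), "empty file")
  expect_error(load_counts(tempfile(), "dge_tsv", "m"), "no such file")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1", "a\t1", "a\t2"), g)
  expect_error(load_counts(g, "dge_tsv", "m"), "duplicate")
})

test_that("MTX write/read round-trips any simulated matrix", {
  spc <- separated_spec(K = 2, cells_per_type = 30, n_genes = 150, seed = 4)
  sim <- simulate_dataset(spc)
  d <- withr::local_tempdir()
  write_counts(sim$matrix, d)
  back <- load_counts(d, "mtx", region_label = "midbrain")
  expect_equal(as.matrix(miglia:::raw_counts(back)),
               as.matrix(miglia:::raw_counts(sim$matrix)))
  # the dense form round-trips through the DGE dialect too
  back2 <- load_counts(file.path(d, "dge.tsv"), "dge_tsv", "midbrain")
  expect_equal(as.matrix(miglia:::raw_counts(back2)),
               as.matrix(miglia:::raw_counts(sim$matrix)))
})

test_that("knee selection isolates a planted high-count population", {
  set.seed(2)
  m <- cbind(matrix(rpois(20 * 50, 20), 20),    # 50 cells, total ~400
             matrix(rpois(20 * 950, 0.5), 20))  # 950 ambient barcodes
  x <- toy_counts(m, cells = sprintf("b%04d", 1:1000))
  sel <- knee_select(x)
  tot <- Matrix::colSums(miglia:::raw_counts(x))
  # brute-force distance-to-chord over all ranks
  ord <- order(tot, decreasing = TRUE)
  ys <- cumsum(as.numeric(tot[ord])); xs <- log10(seq_along(ys))
  xs <- (xs - xs[1]) / (xs[length(xs)] - xs[1])
  ys <- (ys - ys[1]) / (ys[length(ys)] - ys[1])
  expect_equal(ncol(sel), which.max(ys - xs))
  # the 50 planted cells are exactly the selected ones
  expect_setequal(colnames(sel), sprintf("b%04d", 1:50))
})

test_that("degenerate and capped knee selection honor their contracts", {
  x <- toy_counts(matrix(5, 4, 30))
  expect_warning(sel <- knee_select(x), "equal totals")
  expect_equal(ncol(sel), 30)
  set.seed(1)
  y <- toy_counts(matrix(rpois(4 * 30, 3), 4, 30))
  expect_lte(ncol(knee_select(y, max_cells = 10)), 10)
})

test_that("qc metrics follow direct arithmetic", {
  m <- matrix(c(0, 2, 3, 0, 5), 5, 1)
  x <- toy_counts(m, genes = c("a", "b", "c", "d", "mt-Nd1"))
  met <- qc_metrics(x)
  expect_equal(met$n_genes_expressed, 3)
  expect_equal(met$total_counts, 10)
  expect_equal(met$pct_mito, 50)

  # no mito-prefixed genes -> pct_mito 0 everywhere
  y <- toy_counts(matrix(1:6, 3, 2))
  expect_equal(qc_metrics(y)$pct_mito, c(0, 0))

  # zero-total cell: pct_mito defined as 0
  z <- toy_counts(matrix(c(2, 1, 0, 0), 2, 2), genes = c("mt-a", "g1"))
  expect_equal(qc_metrics(z)$pct_mito, c(200 / 3, 0))
})

test_that("qc metrics equal a brute-force per-cell loop on a 20-cell fixture", {
  x <- random_qc_fixture(20, seed = 6)
  met <- qc_metrics(x)
  m <- as.matrix(miglia:::raw_counts(x))
  mito <- grepl("^mt-", rownames(m))
  for (j in 1:20) {
    expect_equal(met$n_genes_expressed[j], sum(m[, j] > 0))
    expect_equal(met$total_counts[j], sum(m[, j]))
    expect_equal(met$pct_mito[j],
                 if (sum(m[, j]) > 0) 100 * sum(m[mito, j]) / sum(m[, j]) else 0)
  }
})

test_that("2-of-3 rule: single violations are retained, doubles removed", {
  # homogeneous cohort: zero MADs, nothing removed
  base <- matrix(1, 250, 30)
  x <- toy_counts(base)
  res <- qc_filter(x)
  expect_false(any(res$qc$low_quality))
  expect_equal(ncol(res$matrix), 30)

  # cell 31 violates only the mito criterion -> retained: the mito bump is
  # offset by zeroing another gene so total counts stay on the median
  cells <- matrix(1, 251, 31)
  rownames(cells) <- c("mt-a", sprintf("g%03d", 1:250))
  cells["mt-a", 31] <- 2
  cells["g001", 31] <- 0        # total back to 251, n_genes 250 (floor is 200)
  x2 <- toy_counts(cells)
  res2 <- qc_filter(x2)
  expect_true(res2$qc$flag_mito[31])
  expect_false(res2$qc$flag_counts[31])
  expect_false(res2$qc$flag_genes[31])
  expect_false(res2$qc$low_quality[31])

  # a cell violating depth and mito together is removed
  cells3 <- matrix(1, 251, 31)
  rownames(cells3) <- rownames(cells)
  cells3["mt-a", 31] <- 100     # mito and total both blow up
  x3 <- toy_counts(cells3)
  res3 <- qc_filter(x3)
  expect_true(res3$qc$flag_mito[31] && res3$qc$flag_counts[31])
  expect_true(res3$qc$low_quality[31])
  expect_equal(ncol(res3$matrix), 30)
})

test_that("qc_filter equals the brute-force oracle on random fixtures", {
  for (s in 1:10) {
    x <- random_qc_fixture(80, seed = 100 + s)
    res <- qc_filter(x)
    expect_identical(res$qc$low_quality, qc_oracle(x), label = paste("seed", s))
  }
})

test_that("filtering is applied separately per region dataset", {
  set.seed(8)
  # midbrain cells much deeper than striatum; joint filtering would flag
  # whole regions, per-dataset filtering flags within-region outliers only
  deep <- matrix(rpois(100 * 20, 50), 100, 20)
  shallow <- matrix(rpois(100 * 20, 5), 100, 20)
  m <- cbind(deep, shallow)
  rownames(m) <- sprintf("g%03d", 1:100)
  colnames(m) <- sprintf("c%03d", 1:40)
  x <- count_matrix(m, rep(c("midbrain", "striatum"), each = 20))
  res <- qc_filter(x, qc_params(min_genes = 5))
  kept <- table(regions(res$matrix))
  expect_gt(kept[["midbrain"]], 10)
  expect_gt(kept[["striatum"]], 10)
})

test_that("tiny datasets skip filtering with a warning", {
  x <- toy_counts(matrix(1:4, 2, 2))
  expect_warning(res <- qc_filter(x), "fewer than 3 cells")
  expect_equal(ncol(res$matrix), 2)
})

test_that("gene filter applies the 5-cell floor and prefix exclusions", {
  m <- rbind(
    in4  = c(1, 1, 1, 1, 0, 0),
    in5  = c(1, 1, 1, 1, 1, 0),
    zero = rep(0, 6),
    ubiq = rep(2, 6)
  )
  m <- rbind(m, "mt-Nd1" = rep(3, 6), "RpsX" = rep(1, 6), "rplY" = rep(1, 6))
  x <- toy_counts(m, genes = rownames(m))
  out <- gene_filter(x)
  expect_setequal(rownames(out), c("in5", "ubiq"))
  # idempotent
  expect_equal(rownames(gene_filter(out)), rownames(out))
  # removing everything errors
  y <- toy_counts(matrix(c(1, 0, 0, 0, 0, 0), 1, 6), genes = "solo")
  expect_error(gene_filter(y), "every gene")
})

test_that("concatenation stacks cells over the gene intersection", {
  a <- toy_counts(matrix(1, 3, 100), genes = c("a", "b", "c"),
                  cells = sprintf("x%03d", 1:100), region = "midbrain")
  b <- toy_counts(matrix(2, 3, 200), genes = c("b", "c", "d"),
                  cells = sprintf("y%03d", 1:200), region = "striatum")
  ab <- concatenate_counts(list(a, b))
  expect_equal(ncol(ab), 300)
  expect_equal(rownames(ab), c("b", "c"))
  # split by region recovers the originals up to gene-order permutation
  back_a <- ab[, regions(ab) == "midbrain"]
  expect_equal(as.matrix(miglia:::raw_counts(back_a)),
               as.matrix(miglia:::raw_counts(a))[c("b", "c"), ])
  # duplicate barcodes get region suffixes
  c2 <- toy_counts(matrix(1, 2, 3), genes = c("b", "c"),
                   cells = c("x001", "q1", "q2"), region = "striatum")
  ac <- concatenate_counts(list(a, c2))
  expect_true(all(c("x001_midbrain", "x001_striatum") %in% colnames(ac)))
})
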