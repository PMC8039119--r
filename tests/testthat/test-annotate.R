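make_annot_fixture <- function() {
  # 3 clusters x 20 cells, microglia markers exclusive to cluster 0,
  # astrocyte markers to cluster 1; cluster 2 expresses only background
  genes <- c("P2ry12", "Hexb", "Cx3cr1", "Siglech",
             "Gja1", "Plpp3", "Slc1a2", "Aqp4", "bg1", "bg2")
  m <- matrix(0, length(genes), 60, dimnames = list(genes, sprintf("c%02d", 1:60)))
  m[1:4, 1:20] <- 5
  m[5:8, 21:40] <- 5
  m[9:10, ] <- 2
  x <- lognormalize(count_matrix(m, "midbrain"))
  list(x = x, labels = rep(0:2, each = 20))
}

test_that("marker scoring labels the exclusive microglia cluster", {
  fx <- make_annot_fixture()
  ann <- suppressMessages(score_marker_panels(fx$x, fx$labels))
  asg <- ann$assignments
  expect_equal(asg$label[asg$cluster == 0], "microglia")
  expect_equal(asg$label[asg$cluster == 1], "astrocytes")
  expect_false(asg$ambiguous[asg$cluster == 0])
})

test_that("identical expression everywhere makes every cluster ambiguous", {
  m <- matrix(3, 8, 30, dimnames = list(
    c("P2ry12", "Hexb", "Cx3cr1", "Siglech", "Gja1", "Plpp3", "Slc1a2", "Aqp4"),
    sprintf("c%02d", 1:30)))
  x <- lognormalize(count_matrix(m, "m"))
  ann <- suppressMessages(score_marker_panels(x, rep(0:2, each = 10)))
  expect_true(all(ann$assignments$ambiguous))
  expect_true(all(ann$scores == 0))
})

test_that("scores equal hand-computed z-score means on a 2x2 toy", {
  # 2 clusters, 2 types with one marker each; hand-set means
  m <- matrix(0, 2, 20, dimnames = list(c("mkA", "mkB"), sprintf("c%02d", 1:20)))
  m["mkA", 1:10] <- 4; m["mkA", 11:20] <- 1
  m["mkB", 1:10] <- 2; m["mkB", 11:20] <- 6
  x <- lognormalize(count_matrix(m, "m"))
  labels <- rep(0:1, each = 10)
  panel <- list(typeA = "mkA", typeB = "mkB")
  ann <- score_marker_panels(x, labels, panel)
  ln <- as.matrix(miglia:::lognorm_values(x))
  hand_z <- function(gene) {
    mu <- c(mean(ln[gene, 1:10]), mean(ln[gene, 11:20]))
    (mu - mean(mu)) / sd(mu)
  }
  expect_equal(unname(ann$scores[, "typeA"]), hand_z("mkA"), tolerance = 1e-12)
  expect_equal(unname(ann$scores[, "typeB"]), hand_z("mkB"), tolerance = 1e-12)
  expect_equal(ann$assignments$label, c("typeA", "typeB"))
})

test_that("annotation is invariant to cluster relabeling and cell order", {
  fx <- make_annot_fixture()
  a1 <- suppressMessages(score_marker_panels(fx$x, fx$labels))
  relab <- c(5L, 0L, 9L)[fx$labels + 1]      # arbitrary relabeling
  a2 <- suppressMessages(score_marker_panels(fx$x, relab))
  m1 <- setNames(a1$assignments$label, c(5, 0, 9)[a1$assignments$cluster + 1])
  m2 <- setNames(a2$assignments$label, a2$assignments$cluster)
  expect_equal(m1[order(names(m1))], m2[order(names(m2))])
  set.seed(2)
  perm <- sample(60)
  a3 <- suppressMessages(score_marker_panels(fx$x[, perm], fx$labels[perm]))
  expect_equal(a3$assignments, a1$assignments)
})

test_that("missing markers are skipped; all missing is an error", {
  fx <- make_annot_fixture()
  expect_message(score_marker_panels(fx$x, fx$labels), "absent")
  expect_error(score_marker_panels(fx$x, fx$labels,
                                   panel = list(t = "NotAGene")),
               "no marker")
})

test_that("group expression summary matches a brute-force loop", {
  set.seed(22)
  m <- matrix(rpois(10 * 30, 1.5), 10, 30)
  x <- lognormalize(toy_counts(m))
  grouping <- rep(c("a", "b", "c"), each = 10)
  genes <- rownames(miglia:::raw_counts(x))[1:4]
  tab <- group_expression_summary(x, grouping, genes)
  ln <- as.matrix(miglia:::lognorm_values(x))
  mr <- as.matrix(miglia:::raw_counts(x))
  for (g in c("a", "b", "c")) for (gn in genes) {
    sel <- grouping == g
    row <- tab[tab$group == g & tab$gene == gn, ]
    expect_equal(row$pct_expressing, 100 * sum(mr[gn, sel] > 0) / sum(sel))
    expect_equal(row$mean_lognorm, mean(ln[gn, sel]))
  }
})

test_that("summary saturates at 0% and 100%", {
  m <- rbind(allon = rep(3, 12), alloff = c(rep(0, 6), rep(1, 6)))
  x <- lognormalize(toy_counts(m, genes = rownames(m)))
  grouping <- rep(c("g1", "g2"), each = 6)
  tab <- group_expression_summary(x, grouping, c("allon", "alloff"))
  expect_equal(tab$pct_expressing[tab$gene == "allon"], c(100, 100))
  g1off <- tab[tab$gene == "alloff" & tab$group == "g1", ]
  expect_equal(g1off$pct_expressing, 0)
  expect_equal(g1off$mean_lognorm, 0)
  expect_error(group_expression_summary(x, grouping, "nope"), "absent")
  expect_error(group_expression_summary(
    x, factor(grouping, levels = c("g1", "g2", "ghost")), "allon"),
    "ghost")
})

test_that("purification removes marker-positive cells and keeps the rest", {
  genes <- c("Mbp", "Mag", "Plp1", "P2ry12", "bg")
  m <- matrix(0, 5, 8, dimnames = list(genes, paste0("c", 1:8)))
  m["P2ry12", ] <- 5; m["bg", ] <- 2
  m["Mbp", 1] <- 3; m["Plp1", 1] <- 2          # two markers -> removed
  m["Mbp", 2] <- 4                             # one marker -> kept
  x <- count_matrix(m, "m")
  labels <- rep(0L, 8)
  out <- suppressMessages(purify_subset(x, labels, 0L))
  expect_false("c1" %in% colnames(out))
  expect_true(all(paste0("c", 2:8) %in% colnames(out)))
  expect_error(purify_subset(x, labels, 3L), "no cells")
  m2 <- m; m2["Mbp", ] <- 5; m2["Mag", ] <- 5
  expect_error(suppressMessages(
    purify_subset(count_matrix(m2, "m"), labels, 0L)), "every target cell")
})
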