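swc_df <- function(...) {
  d <- as.data.frame(rbind(...))
  names(d) <- c("id", "type", "x", "y", "z", "radius", "parent")
  d
}

test_that("morphometrics follow the critical-point definitions", {
  # single edge of length 1
  s <- skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1), c(2, 3, 1, 0, 0, 1, 1)))
  m <- skeleton_morphometrics(s)
  expect_equal(m$total_process_length, 1)
  expect_equal(m$n_branch_points, 0)
  expect_equal(m$n_segments, 1)

  # Y: three unit edges from one bifurcation
  y <- skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1),
                       c(2, 3, 0, 0, 1, 1, 1),
                       c(3, 3, 1, 0, 1, 1, 2),
                       c(4, 3, -1, 0, 1, 1, 2)))
  my <- skeleton_morphometrics(y)
  expect_equal(my$total_process_length, 3)
  expect_equal(my$n_branch_points, 1)
  expect_equal(my$n_segments, 3)

  # chain of 3 unit edges: unbranched nodes collapse into one segment
  ch <- skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1),
                        c(2, 3, 1, 0, 0, 1, 1),
                        c(3, 3, 2, 0, 0, 1, 2),
                        c(4, 3, 3, 0, 0, 1, 3)))
  mc <- skeleton_morphometrics(ch)
  expect_equal(mc$total_process_length, 3)
  expect_equal(mc$n_branch_points, 0)
  expect_equal(mc$n_segments, 1)
})

test_that("soma convention: bipolar root is no branch point, tripolar is", {
  bi <- skeleton(swc_df(c(1, 1, 0, 0, 0, 2, -1),
                        c(2, 3, 1, 0, 0, 1, 1),
                        c(3, 3, -1, 0, 0, 1, 1)))
  mb <- skeleton_morphometrics(bi)
  expect_equal(mb$n_branch_points, 0)
  expect_equal(mb$n_segments, 2)
  tri <- skeleton(swc_df(c(1, 1, 0, 0, 0, 2, -1),
                         c(2, 3, 1, 0, 0, 1, 1),
                         c(3, 3, -1, 0, 0, 1, 1),
                         c(4, 3, 0, 1, 0, 1, 1)))
  mt <- skeleton_morphometrics(tri)
  expect_equal(mt$n_branch_points, 1)
  expect_equal(mt$n_segments, 3)
})

test_that("invalid skeletons are rejected", {
  expect_error(skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1),
                               c(2, 3, 1, 0, 0, 1, -1))),
               "exactly one root")
  expect_error(skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1),
                               c(2, 3, 1, 0, 0, 1, 9))),
               "parent id")
  # two nodes pointing at each other, disconnected from the root: a cycle
  expect_error(skeleton(swc_df(c(1, 1, 0, 0, 0, 1, -1),
                               c(2, 3, 1, 0, 0, 1, 3),
                               c(3, 3, 2, 0, 0, 1, 2))),
               "cycle")
  expect_error(skeleton(swc_df(c(1, 1, NA, 0, 0, 1, -1))), "finite")
})

test_that("morphometrics are invariant under rigid motion", {
  s <- simulate_skeleton(6, 4.5, seed = 33)
  m0 <- skeleton_morphometrics(s)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  nd <- s$nodes
  xyz <- as.matrix(nd[, c("x", "y", "z")]) %*% R
  nd$x <- xyz[, 1] + 100; nd$y <- xyz[, 2] - 7; nd$z <- xyz[, 3] + 0.5
  m1 <- skeleton_morphometrics(skeleton(nd))
  expect_equal(m1$total_process_length, m0$total_process_length,
               tolerance = 1e-9)
  expect_equal(m1$n_branch_points, m0$n_branch_points)
  expect_equal(m1$n_segments, m0$n_segments)
})

test_that("SWC files round-trip", {
  s <- simulate_skeleton(4, 3, seed = 8)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(s, f)
  s2 <- read_swc(f)
  expect_equal(s2$nodes$parent, s$nodes$parent)
  expect_equal(s2$nodes$x, s$nodes$x, tolerance = 1e-12)
  m1 <- skeleton_morphometrics(s); m2 <- skeleton_morphometrics(s2)
  expect_equal(m2$total_process_length, m1$total_process_length,
               tolerance = 1e-9)
})

test_that("cell density is a plain ratio with guards", {
  expect_equal(cell_density(50, 0.5), 100)
  expect_equal(cell_density(0, 2), 0)
  # additivity over equal-density fields
  expect_equal(cell_density(50 + 100, 0.5 + 1), 100)
  expect_error(cell_density(5, 0), "positive")
})

test_that("group stats run both modes and cover all pairs", {
  set.seed(71)
  v <- list(ctx = rnorm(12, 10), crb = rnorm(12, 10), mb = rnorm(12, 14))
  gp <- group_stats(v, "parametric")
  expect_equal(gp$test, "anova_tukey")
  expect_equal(nrow(gp$pairwise), 3)
  expect_setequal(paste(gp$pairwise$group1, gp$pairwise$group2),
                  c("ctx crb", "ctx mb", "crb mb"))
  gn <- group_stats(v, "nonparametric")
  expect_equal(gn$test, "kruskal_dunn")
  expect_equal(nrow(gn$pairwise), 3)
  expect_lt(gn$p, 0.05)
  # strong separation is significant in both modes
  v2 <- list(a = rnorm(12), b = rnorm(12) + 10)
  expect_lt(group_stats(v2, "parametric")$p, 1e-3)
  expect_lt(group_stats(v2, "nonparametric")$p, 1e-3)
})

test_that("all-constant groups report p = 1 with a flag", {
  v <- list(a = rep(2, 5), b = rep(2, 5), c = rep(2, 5))
  gs <- group_stats(v, "parametric")
  expect_equal(gs$p, 1)
  expect_equal(gs$flag, "zero_variance")
})

test_that("Dunn z tests agree with a direct rank computation", {
  set.seed(72)
  y <- c(rnorm(8), rnorm(8, 2))
  g <- factor(rep(c("a", "b"), each = 8))
  dp <- dunn_pairwise(y, g)
  r <- rank(y)
  N <- 16
  se <- sqrt((N * (N + 1) / 12) * (1 / 8 + 1 / 8))
  z_hand <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(dp$z, z_hand, tolerance = 1e-12)
  # with only one pair, Bonferroni leaves p unchanged
  expect_equal(dp$p_adj, min(1, 2 * pnorm(-abs(z_hand))), tolerance = 1e-12)
})
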