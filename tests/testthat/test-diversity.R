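test_that("rarefaction subsamples without replacement to the exact depth", {
  ct <- tiny_counts()  # libraries (6, 3)
  r <- rarefy(ct, 3, seed = 1)
  expect_equal(unname(library_sizes(r)), c(3, 3))
  expect_true(all(r$counts <= ct$counts))
  # depth = library size leaves the sample unchanged (multiset identity)
  r2 <- rarefy(ct, 3, seed = 1)
  expect_identical(r2$counts[, "s2"], ct$counts[, "s2"])
  expect_error(rarefy(ct, 5), "s2")

  # forced outcome: a sample (10, 0) rarefied to 5 is always (5, 0)
  m <- count_table(matrix(c(10L, 0L, 10L, 0L), 2, 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  rr <- rarefy(m, 5, seed = 3)
  expect_equal(unname(rr$counts[, "x"]), c(5L, 0L))

  # hypergeometric oracle: (6, 3) to depth 3 has E[taxon 1] = 3*6/9 = 2
  m2 <- count_table(matrix(c(6L, 6L, 3L, 3L), 2, 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  set.seed(5)
  draws <- vapply(1:10000, function(i)
    rarefy(m2, 3, seed = sample.int(1e8, 1))$counts["a", "x"], numeric(1))
  expect_equal(mean(draws), 2.0, tolerance = 0.02)
})

test_that("chao1 matches hand evaluation and dominates observed richness", {
  expect_equal(chao1(c(5, 5, 5)), 3.0)
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1(c(1, 1, 1)), 6.0)
  expect_error(chao1(c(0, 0)), "all-zero")
  set.seed(8)
  for (i in 1:50) {
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    s_obs <- sum(x > 0)
    expect_gte(chao1(x), s_obs)
    if (sum(x == 1) == 0) expect_equal(chao1(x), s_obs)
    else expect_gt(chao1(x), s_obs)
  }
})

test_that("shannon matches hand evaluation and its invariances", {
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(c(3, 3, 3, 3)), log(4))
  expect_equal(shannon(c(1, 3)), 0.5623, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(9)
  for (i in 1:25) {
    x <- rpois(12, 5) + 1
    expect_equal(shannon(x), shannon(sample(x)))
    expect_lte(shannon(x), log(12) + 1e-12)
    # transferring mass from a rich to a poor taxon raises evenness
    j <- which.max(x); k <- which.min(x)
    if (x[j] - x[k] >= 2) {
      y <- x; y[j] <- y[j] - 1; y[k] <- y[k] + 1
      expect_gt(shannon(y), shannon(x))
    }
  }
})

test_that("percent change helpers reproduce the worked examples", {
  expect_equal(percent_increase(3091.09, 2792.47), 10.69)
  expect_equal(percent_increase(459.65, 383.44), 19.88)
  expect_equal(percent_increase(5, 5), 0)
  expect_error(percent_increase(1, 0), "> 0")
  expect_equal(percent_decrease(0.7, 1.0), 30.0)
  expect_equal(percent_decrease(0.4058, 1.0), 59.42)
  expect_equal(percent_decrease(2, 2), 0)
})

test_that("bray_curtis matches hand values and vegan", {
  m <- count_table(matrix(c(3L, 3L, 5L, 5L, 0L, 2L), 3, 2,
                          dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  d <- bray_curtis(m)
  expect_equal(unname(diag(unclass(d))), c(0, 0))
  ident <- count_table(matrix(c(2L, 1L, 4L, 2L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unclass(bray_curtis(ident))["s1", "s2"], 0)
  disj <- count_table(matrix(c(3L, 0L, 0L, 7L), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unclass(bray_curtis(disj))["s1", "s2"], 1)
  # relative abundances (.5, .5) vs (1, 0)
  half <- count_table(matrix(c(1L, 1L, 2L, 0L), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unclass(bray_curtis(half))["s1", "s2"], 0.5)

  ct <- random_counts(12, 15, seed = 44)
  d1 <- unclass(bray_curtis(ct))
  d2 <- as.matrix(vegan::vegdist(t(relative_abundance(ct)), method = "bray"))
  expect_equal(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 0,
               tolerance = 1e-12)
  expect_true(all(d1 >= 0 & d1 <= 1))
  expect_equal(d1, t(d1))
})

test_that("pcoa performs classical scaling", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  p3 <- pcoa(distance_matrix(d3))
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-10]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2])

  # points on a line embed exactly on the first axis
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("p", 1:4), paste0("p", 1:4))
  pl <- pcoa(distance_matrix(dl))
  expect_equal(abs(cor(pl$coordinates[, 1], x)), 1, tolerance = 1e-10)
  expect_equal(as.matrix(dist(pl$coordinates[, 1])), unname(dl),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(pl$negative_fraction, 0, tolerance = 1e-10)

  # a non-Euclidean four-point configuration reports negative eigenvalues
  dn <- matrix(1, 4, 4, dimnames = list(paste0("q", 1:4), paste0("q", 1:4)))
  diag(dn) <- 0
  dn[1, 2] <- dn[2, 1] <- dn[3, 4] <- dn[4, 3] <- 1.9
  pn <- pcoa(distance_matrix(dn))
  expect_gt(pn$negative_fraction, 0)

  # agreement with classical scaling in stats
  ct <- random_counts(10, 12, seed = 5)
  d <- bray_curtis(ct)
  mine <- pcoa(d)
  ref <- stats::cmdscale(stats::as.dist(unclass(d)), k = 3, eig = TRUE)
  expect_equal(mine$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(mine$coordinates[, k]), abs(ref$points[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("permanova matches vegan and behaves at the extremes", {
  ct <- random_counts(12, 20, seed = 77)
  d <- bray_curtis(ct)
  g <- factor(rep(c("a", "b"), each = 10))
  mine <- miconet::permanova(d, g, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ g, permutations = 199)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)

  # two perfectly separated clusters: no permutation beats the observed F
  # (20 samples, so permutations reproducing the split are vanishingly rare)
  sep <- matrix(1, 20, 20); diag(sep) <- 0
  sep[1:10, 1:10][lower.tri(sep[1:10, 1:10])] <- .05
  sep[11:20, 11:20][lower.tri(sep[11:20, 11:20])] <- .05
  sep[upper.tri(sep)] <- t(sep)[upper.tri(sep)]
  dimnames(sep) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g2 <- factor(rep(c("a", "b"), each = 10))
  res <- miconet::permanova(distance_matrix(sep), g2, n_perm = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)

  # all pairwise distances equal: R^2 is the analytic 1 - (n-a)/(n-1)
  eq <- matrix(1, 9, 9); diag(eq) <- 0
  dimnames(eq) <- list(paste0("s", 1:9), paste0("s", 1:9))
  g3 <- factor(rep(c("a", "b", "c"), each = 3))
  req <- miconet::permanova(distance_matrix(eq), g3, n_perm = 99, seed = 3)
  expect_equal(req$r_squared, 1 - (9 - 3) / (9 - 1), tolerance = 1e-12)

  expect_error(miconet::permanova(d, factor(c("a", rep("b", 19)))),
               "fewer than 2")
})

test_that("anosim matches vegan, brute force, and its extremes", {
  ct <- random_counts(12, 16, seed = 78)
  d <- bray_curtis(ct)
  g <- factor(rep(c("a", "b"), each = 8))
  mine <- miconet::anosim(d, g, n_perm = 99, seed = 1)
  ref <- vegan::anosim(stats::as.dist(unclass(d)), g, permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_gte(mine$p_value, 1 / 100)
  expect_lte(abs(mine$statistic), 1)

  # all within-distances below all between-distances: R = 1
  sep <- matrix(1, 6, 6); diag(sep) <- 0
  sep[1:3, 1:3][lower.tri(sep[1:3, 1:3])] <- .1
  sep[4:6, 4:6][lower.tri(sep[4:6, 4:6])] <- .1
  sep[upper.tri(sep)] <- t(sep)[upper.tri(sep)]
  dimnames(sep) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g2 <- factor(rep(c("a", "b"), each = 3))
  expect_equal(miconet::anosim(distance_matrix(sep), g2, n_perm = 99,
                               seed = 2)$statistic, 1)

  # brute-force rank oracle on a 5-sample case
  set.seed(10)
  d5 <- matrix(0, 5, 5)
  d5[lower.tri(d5)] <- runif(10)
  d5 <- d5 + t(d5)
  dimnames(d5) <- list(paste0("s", 1:5), paste0("s", 1:5))
  g5 <- factor(c("a", "a", "a", "b", "b"))
  rk <- rank(d5[lower.tri(d5)])
  same <- outer(g5, g5, "==")[lower.tri(d5)]
  r_manual <- (mean(rk[!same]) - mean(rk[same])) / (10 / 2)
  expect_equal(miconet::anosim(distance_matrix(d5), g5, n_perm = 99,
                               seed = 1)$statistic, r_manual)

  # null expectation of R is ~0 over random label draws
  set.seed(11)
  rs <- vapply(1:200, function(i) {
    gi <- factor(sample(rep(c("a", "b"), each = 8)))
    miconet::anosim(d, gi, n_perm = 99, seed = i)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("alpha_diversity composes rarefaction and the indices", {
  ct <- random_counts(25, 6, seed = 12, lambda = 8)
  al <- alpha_diversity(ct, depth = NULL, seed = 2)
  expect_equal(nrow(al), 6L)
  expect_true(all(al$chao1 >= al$s_obs))
  expect_true(all(al$shannon <= log(al$s_obs)))
  expect_equal(unique(al$depth), min(library_sizes(ct)))
})
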