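test_that("filter_taxa applies a strict mean relative-abundance gate", {
  m <- matrix(c(999L, 999L, 999L, 999L,
                1L, 1L, 1L, 1L,
                2L, 2L, 2L, 2L), 3, 4, byrow = TRUE,
              dimnames = list(c("big", "tiny", "edge"),
                              paste0("s", 1:4)))
  # library 1002 per sample: tiny = 0.000998 (< 0.1%), edge = 0.001996
  ct <- count_table(m)
  kept <- filter_taxa(ct, 0.001)
  expect_setequal(kept$taxa, c("big", "edge"))
  # exact threshold is dropped (strict >)
  exact <- count_table(matrix(c(999L, 1L) , 2, 4, byrow = FALSE,
                              dimnames = list(c("a", "b"), paste0("s", 1:4))))
  expect_setequal(filter_taxa(exact, 0.001)$taxa, "a")
  expect_identical(filter_taxa(ct, 0)$taxa, ct$taxa)
  expect_error(filter_taxa(ct, 1.5), "fraction")
  expect_error(filter_taxa(ct, -0.1), "fraction")
})

test_that("pairwise measures reproduce exact and brute-force values", {
  # equal column sums make relative profiles proportional to the raw rows
  ct <- profile_counts(list(c(1L, 2L, 3L, 4L), c(2L, 4L, 6L, 8L)))
  as <- pairwise_measures(ct)
  expect_equal(as$stats$pearson["t1", "t2"], 1)
  expect_equal(as$stats$spearman["t1", "t2"], 1)

  anti <- profile_counts(list(c(1L, 2L, 3L, 4L), c(8L, 6L, 4L, 2L)))
  as2 <- pairwise_measures(anti)
  expect_equal(as2$stats$spearman["t1", "t2"], -1)

  # identical profiles: spearman 1, KL 0, BC 0
  same <- profile_counts(list(c(3L, 5L, 9L, 2L), c(3L, 5L, 9L, 2L)))
  as3 <- pairwise_measures(same)
  expect_equal(as3$stats$spearman["t1", "t2"], 1)
  expect_equal(as3$stats$kl["t1", "t2"], 0)
  expect_equal(as3$stats$bray_curtis["t1", "t2"], 0)

  # brute-force oracles on a random table (incl. binned plug-in MI)
  ct4 <- random_counts(8, 25, seed = 31)
  as4 <- pairwise_measures(ct4)
  R <- relative_abundance(ct4)
  P <- (ct4$counts + 0.5) / rowSums(ct4$counts + 0.5)
  nb <- floor(sqrt(25))
  bin <- function(x) floor((rank(x, ties.method = "first") - 1) * nb / 25)
  for (pr in list(c(1, 2), c(3, 7), c(4, 8))) {
    i <- pr[1]; j <- pr[2]
    expect_equal(as4$stats$spearman[i, j],
                 cor(R[i, ], R[j, ], method = "spearman"))
    expect_equal(as4$stats$pearson[i, j], cor(R[i, ], R[j, ]))
    expect_equal(as4$stats$kl[i, j],
                 sum(P[i, ] * log(P[i, ] / P[j, ])) +
                   sum(P[j, ] * log(P[j, ] / P[i, ])))
    expect_equal(as4$stats$bray_curtis[i, j],
                 sum(abs(R[i, ] - R[j, ])) / sum(R[i, ] + R[j, ]))
    tab <- table(factor(bin(R[i, ]), 0:(nb - 1)),
                 factor(bin(R[j, ]), 0:(nb - 1))) / 25
    mi <- sum(ifelse(tab > 0,
                     tab * log(tab / outer(rowSums(tab), colSums(tab))), 0))
    expect_equal(as4$stats$mutual_information[i, j], mi)
  }

  # constant profile: Spearman/Pearson recorded missing with a warning
  m <- rbind(t1 = c(5L, 5L, 5L, 5L), t2 = c(1L, 2L, 3L, 4L),
             t3 = c(9L, 8L, 7L, 6L))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(asc <- pairwise_measures(count_table(m)), "constant")
  expect_true(is.na(asc$stats$spearman["t1", "t2"]))
  expect_false(is.na(asc$stats$kl["t1", "t2"]))
})

test_that("permutation p-values obey the add-one estimator and the null", {
  ct <- random_counts(6, 20, seed = 3)
  expect_error(permutation_pvalues(ct, B = 50), ">= 99")

  # a perfectly monotone pair is more extreme than every permutation
  strong <- profile_counts(list(1:12, 1:12 * 2L))
  as <- permutation_pvalues(strong, B = 99, seed = 5)
  expect_equal(as$pvalues$spearman["t1", "t2"], 0.01)

  # independent taxa: pooled spearman p-values look uniform
  null <- random_counts(8, 40, seed = 21, lambda = 50)
  asn <- permutation_pvalues(null, B = 499, seed = 9)
  pv <- asn$pvalues$spearman[upper.tri(asn$pvalues$spearman)]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  for (m in names(asn$pvalues))
    expect_true(all(asn$pvalues[[m]] > 0 & asn$pvalues[[m]] <= 1,
                    na.rm = TRUE))
})

test_that("planted pairs at the default profile reach p <= 0.01", {
  hits <- vapply(1:20, function(s) {
    cfg <- uniform_config(6, means = c(.15, .15, .175, .175, .175, .175),
                          log_noise_sd = 0.15,
                          blocks = list(list(taxa = c("t1", "t2"),
                                             loadings = c(0.9, 0.9))))
    ds <- generate_dataset(cfg, seed = 600 + s)
    as <- permutation_pvalues(ds$counts, B = 199, seed = s)
    as$pvalues$spearman["t1", "t2"] <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("brown_combine reduces to Fisher and handles degeneracy", {
  p <- c(0.05, 0.05)
  fisher <- pchisq(-2 * sum(log(p)), df = 4, lower.tail = FALSE)
  expect_equal(miconet:::combine_brown(p, E = 4, V = 8), fisher)
  expect_equal(fisher, 0.017479, tolerance = 1e-4)

  # perfectly dependent identical p-values collapse to the common p
  for (pp in c(0.001, 0.05, 0.3)) {
    k <- 5
    expect_equal(miconet:::combine_brown(rep(pp, k), E = 2 * k, V = 4 * k^2),
                 pp, tolerance = 1e-12)
  }
  # all p = 1 combine to 1
  expect_equal(miconet:::combine_brown(rep(1, 5), E = 10, V = 20), 1)

  # through the pipeline: requires permutation p-values first
  ct <- random_counts(5, 12, seed = 2)
  expect_error(brown_combine(pairwise_measures(ct)), "permutation_pvalues")
  as <- brown_combine(permutation_pvalues(ct, B = 199, seed = 3))
  bp <- as$brown_p[upper.tri(as$brown_p)]
  expect_true(all(bp > 0 & bp <= 1))
})

test_that("empirical Brown tracks Fisher on independent p-values", {
  # simulate independent -2 log p transforms; the empirical covariance is
  # then near zero and the combined p must match Fisher within 5% relative
  set.seed(123)
  B <- 20000
  W <- matrix(-2 * log(runif(B * 5)), B, 5)
  E <- sum(colMeans(W))
  V <- sum(cov(W))
  for (ptarget in c(0.001, 0.01, 0.1, 0.5)) {
    pvec <- rep(ptarget^(1 / 5), 5)  # Fisher stat matching a joint level
    fisher <- pchisq(-2 * sum(log(pvec)), df = 10, lower.tail = FALSE)
    brown <- miconet:::combine_brown(pvec, E = E, V = V)
    expect_lt(abs(brown - fisher) / fisher, 0.05)
  }
})

test_that("build_network gates edges on score and combined p", {
  ct <- random_counts(6, 16, seed = 13)
  as <- brown_combine(permutation_pvalues(ct, B = 199, seed = 1))
  # override evidence to force decisions
  as$stats$spearman[] <- 0
  as$brown_p[] <- 1
  as$stats$spearman["t1", "t2"] <- as$stats$spearman["t2", "t1"] <- 0.9
  as$brown_p["t1", "t2"] <- as$brown_p["t2", "t1"] <- 0.001
  as$stats$spearman["t3", "t4"] <- as$stats$spearman["t4", "t3"] <- 0.9
  as$brown_p["t3", "t4"] <- as$brown_p["t4", "t3"] <- 0.2
  as$stats$spearman["t5", "t6"] <- as$stats$spearman["t6", "t5"] <- -0.7
  as$brown_p["t5", "t6"] <- as$brown_p["t6", "t5"] <- 0.01
  net <- build_network(as)
  expect_equal(nrow(net$edges), 2L)
  key <- pair_key(net$edges$from, net$edges$to)
  expect_setequal(key, c(pair_key("t1", "t2"), pair_key("t5", "t6")))
  expect_equal(net$edges$sign[key == pair_key("t1", "t2")], 1L)
  expect_equal(net$edges$sign[key == pair_key("t5", "t6")], -1L)
  expect_setequal(net$nodes$taxon, c("t1", "t2", "t5", "t6"))
})

test_that("tightening either gate never adds edges", {
  ds <- generate_dataset(default_soil_profile(), seed = 21)
  ba <- kingdom_subset(ds$counts, ds$taxonomy, "Bacteria")
  sel <- ds$design$sample[ds$design$ismb %in% c("M", "H")]
  tb <- filter_taxa(count_table(ba$counts[, sel]), 0.001)
  as <- suppressWarnings(brown_combine(permutation_pvalues(tb, B = 199, seed = 2)))
  base <- build_network(as)
  basekey <- pair_key(base$edges$from, base$edges$to)
  for (thr in c(0.7, 0.8)) {
    sub <- build_network(as, score_threshold = thr)
    expect_true(all(pair_key(sub$edges$from, sub$edges$to) %in% basekey))
  }
  for (pt in c(0.01, 0.001)) {
    sub <- build_network(as, p_threshold = pt)
    expect_true(all(pair_key(sub$edges$from, sub$edges$to) %in% basekey))
  }
})

test_that("edge calling is invariant to taxon order; scores to sample order", {
  set.seed(55)
  ct <- random_counts(8, 24, seed = 4)
  as1 <- permutation_pvalues(ct, B = 199, seed = 7)
  perm_t <- sample(ct$taxa)
  ct2 <- count_table(ct$counts[perm_t, ])
  as2 <- permutation_pvalues(ct2, B = 199, seed = 7)
  expect_equal(as2$stats$spearman[ct$taxa, ct$taxa], as1$stats$spearman)
  net1 <- build_network(brown_combine(as1))
  net2 <- build_network(brown_combine(as2))
  expect_setequal(pair_key(net1$edges$from, net1$edges$to),
                  pair_key(net2$edges$from, net2$edges$to))

  perm_s <- sample(ct$samples)
  as3 <- pairwise_measures(count_table(ct$counts[, perm_s]))
  for (m in names(as3$stats))
    expect_equal(as3$stats[[m]], pairwise_measures(ct)$stats[[m]])
})

test_that("topology reproduces forced values and matches igraph", {
  # printed-scale check: 44 nodes and 566 edges give density 0.60
  tp <- topology(random_network(44, 566, seed = 2))
  expect_equal(tp$network_density, 2 * 566 / (44 * 43), tolerance = 1e-12)
  expect_equal(round(tp$network_density, 2), 0.60)

  tri <- mk_network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                               sign = 1L))
  tt <- topology(tri)
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$average_path_length, 1)
  expect_equal(tt$network_density, 1)
  expect_equal(tt$positive_pct, 100)

  path4 <- mk_network(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "d"), sign = 1L))
  tp4 <- topology(path4)
  expect_equal(tp4$clustering_coefficient, 0)
  expect_equal(tp4$average_path_length, 5 / 3)

  for (seed in 1:4) {
    net <- random_network(15, 22, seed = seed, p_negative = 0.4)
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = net$nodes$taxon)
    tpo <- topology(net)
    expect_equal(tpo$clustering_coefficient,
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"))
    expect_equal(tpo$average_path_length, igraph::mean_distance(g))
    expect_equal(tpo$positive_pct + tpo$negative_pct, 100)
  }
  expect_error(topology(mk_network(data.frame(from = character(0),
                                              to = character(0),
                                              sign = integer(0)))),
               "2 nodes")
})

test_that("hub detection uses normalized degree with an inclusive cutoff", {
  star <- mk_network(data.frame(from = "hub", to = paste0("leaf", 1:5),
                                sign = 1L))
  hubs <- detect_hubs(star, cutoff = 0.2)
  expect_equal(hubs$taxon[1], "hub")
  expect_equal(hubs$centrality[1], 1)
  # leaves sit exactly at 1/5 = 0.2 and are flagged by the >= rule
  expect_setequal(hubs$taxon, c("hub", paste0("leaf", 1:5)))
  expect_equal(nrow(detect_hubs(star, cutoff = 0.21)), 1L)
  empty <- mk_network(data.frame(from = character(0), to = character(0),
                                 sign = integer(0)))
  expect_equal(nrow(detect_hubs(empty)), 0L)
})

test_that("planted module members dominate the hub list", {
  ds <- generate_dataset(default_soil_profile(), seed = 31)
  ba <- kingdom_subset(ds$counts, ds$taxonomy, "Bacteria")
  sel <- ds$design$sample[ds$design$ismb %in% c("M", "H")]
  res <- suppressMessages(suppressWarnings(
    infer_network(count_table(ba$counts[, sel]), B = 499, seed = 32)))
  block_taxa <- unique(c(ds$truth$edges$taxon_a, ds$truth$edges$taxon_b))
  deg <- table(factor(c(res$network$edges$from, res$network$edges$to),
                      levels = res$network$nodes$taxon))
  in_block <- names(deg) %in% block_taxa
  nonblock_mean <- if (any(!in_block)) mean(deg[!in_block]) else 0
  expect_gt(mean(deg[in_block]), 2 * max(nonblock_mean, 0.1))
  hubs <- detect_hubs(res$network)
  expect_gt(mean(hubs$taxon %in% block_taxa), 0.8)
})
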