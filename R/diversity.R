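#' Rarefy a count table by subsampling without replacement
#'
#' Each sample is subsampled to exactly `depth` reads without replacement
#' (multivariate hypergeometric). Taxa whose rows become all zero are kept
#' unless `drop_empty = TRUE`.
#'
#' @param table a [count_table()]
#' @param depth target library size; must not exceed any sample's library size
#' @param seed integer seed
#' @param drop_empty drop taxa with all-zero rows after rarefaction
#' @return a rarefied [count_table()]
#' @export
rarefy <- function(table, depth, seed = 1L, drop_empty = FALSE) {
  ls <- library_sizes(table)
  if (any(ls < depth))
    stop_fmt("depth %d exceeds library size of sample '%s' (%d)",
             depth, names(ls)[ls < depth][1L], min(ls[ls < depth]))
  set.seed(seed)
  T <- nrow(table$counts)
  out <- apply(table$counts, 2L, function(col) {
    picked <- sample.int(sum(col), depth)
    tabulate(findInterval(picked - 1L, cumsum(col), left.open = FALSE) + 1L,
             nbins = T)
  })
  rownames(out) <- table$taxa
  if (drop_empty) out <- out[rowSums(out) > 0, , drop = FALSE]
  count_table(out)
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with `F1`/`F2` the singleton and
#' doubleton counts. The `+1` denominator keeps the estimate finite when no
#' doubletons are present.
#'
#' @param sample_counts non-negative integer vector of one sample's counts
#' @return the Chao1 estimate (>= observed richness)
#' @export
chao1 <- function(sample_counts) {
  if (any(sample_counts < 0)) stop_fmt("negative counts")
  if (sum(sample_counts) == 0) stop_fmt("chao1 undefined for an all-zero sample")
  s_obs <- sum(sample_counts > 0)
  f1 <- sum(sample_counts == 1)
  f2 <- sum(sample_counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index (natural log)
#'
#' `-sum(p_i * log(p_i))` over taxa with positive abundance.
#'
#' @param sample_counts non-negative vector with positive sum
#' @return Shannon entropy in nats, in `[0, log(S_obs)]`
#' @export
shannon <- function(sample_counts) {
  if (any(sample_counts < 0)) stop_fmt("negative counts")
  tot <- sum(sample_counts)
  if (tot == 0) stop_fmt("shannon undefined for an all-zero sample")
  p <- sample_counts[sample_counts > 0] / tot
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' Observed richness, Chao1 and Shannon per sample, optionally after
#' rarefying every sample to a common depth (defaults to the minimum
#' library size when `depth = NULL`).
#'
#' @param table a [count_table()]
#' @param depth rarefaction depth, `NA` to skip rarefaction, `NULL` for the
#'   minimum library size
#' @param seed seed for the rarefaction draw
#' @return data.frame (class `alpha_result`): `sample`, `s_obs`, `chao1`,
#'   `shannon`, `depth`
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1L) {
  if (is.null(depth)) depth <- min(library_sizes(table))
  used <- table
  if (!is.na(depth)) used <- rarefy(table, depth, seed = seed)
  res <- data.frame(
    sample = used$samples,
    s_obs = apply(used$counts, 2L, function(x) sum(x > 0)),
    chao1 = apply(used$counts, 2L, chao1),
    shannon = apply(used$counts, 2L, shannon),
    depth = if (is.na(depth)) NA_integer_ else as.integer(depth),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("alpha_result", "data.frame")
  res
}

#' Percent increase / decrease of `a` relative to baseline `b`
#'
#' `percent_increase` returns `100 * (a - b) / b`; `percent_decrease`
#' returns `100 * (b - a) / b`. Both report two decimals.
#'
#' @param a value of interest
#' @param b positive baseline
#' @return signed percent change, rounded to 2 decimals
#' @export
percent_increase <- function(a, b) {
  if (any(b <= 0)) stop_fmt("baseline must be > 0")
  round(100 * (a - b) / b, 2)
}

#' @rdname percent_increase
#' @export
percent_decrease <- function(a, b) {
  if (any(b <= 0)) stop_fmt("baseline must be > 0")
  round(100 * (b - a) / b, 2)
}

#' Construct / validate a distance matrix
#' @param m symmetric numeric matrix with zero diagonal and dimnames
#' @return object of class `distance_matrix`
#' @export
distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop_fmt("distance matrix needs sample names")
  if (!isSymmetric(unname(m), tol = 1e-10)) stop_fmt("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop_fmt("distance matrix diagonal must be zero")
  structure(m, class = c("distance_matrix", "matrix"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j, k) = sum |x_ij - x_ik| / sum (x_ij + x_ik)` computed on per-sample
#' relative abundances, so entries lie in `[0, 1]`.
#'
#' @param table a [count_table()] with >= 2 samples
#' @return a [distance_matrix()]
#' @export
bray_curtis <- function(table) {
  R <- relative_abundance(table)
  n <- ncol(R)
  d <- matrix(0, n, n, dimnames = list(colnames(R), colnames(R)))
  for (j in seq_len(n - 1L)) {
    diffs <- abs(R[, (j + 1L):n, drop = FALSE] - R[, j])
    sums <- R[, (j + 1L):n, drop = FALSE] + R[, j]
    d[j, (j + 1L):n] <- colSums(diffs) / colSums(sums)
  }
  distance_matrix(d + t(d))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2` and eigen-decomposes it. Axes with positive
#' eigenvalues are returned, scaled by `sqrt(lambda)`; the summed magnitude
#' of negative eigenvalues is reported as the non-Euclidean fraction
#' `sum(|lambda-|) / sum(|lambda|)`.
#'
#' @param dist a [distance_matrix()]
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `explained` (proportions over positive eigenvalues) and
#'   `negative_fraction`
#' @export
pcoa <- function(dist) {
  dist <- distance_matrix(dist)
  n <- nrow(dist)
  A <- -0.5 * unclass(dist)^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- e$values
  pos <- which(lam > max(lam) * 1e-10 & lam > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), length(pos))
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = lam,
       explained = lam[pos] / sum(lam[pos]),
       negative_fraction = sum(abs(lam[lam < 0])) / sum(abs(lam)))
}

check_groups <- function(dist, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(dist))
    stop_fmt("groups length (%d) != number of samples (%d)",
             length(groups), nrow(dist))
  groups <- droplevels(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop_fmt("need >= 2 groups")
  if (any(tab < 2L))
    stop_fmt("group '%s' has fewer than 2 samples", names(tab)[tab < 2][1L])
  groups
}

perm_result <- function(statistic, r2, p, n_perm, seed) {
  structure(list(statistic = statistic, r_squared = r2, p_value = p,
                 permutations = n_perm, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4f%s, p = %.4g (%d permutations)\n",
              x$statistic,
              if (!is.null(x$r_squared) && !is.na(x$r_squared))
                sprintf(", R2 = %.3f", x$r_squared) else "",
              x$p_value, x$permutations))
  invisible(x)
}

permanova_f <- function(d2, groups, n) {
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    sel <- groups == g
    ng <- sum(sel)
    dg <- d2[sel, sel]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]) / ng
  }
  ss_between <- ss_total - ss_within
  a <- nlevels(groups)
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: pseudo-F from within- vs
#' between-group sums of squared distances, `R^2 = SS_between / SS_total`,
#' and a permutation p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)` under
#' random relabeling.
#'
#' @param dist a [distance_matrix()]
#' @param groups group label per sample (>= 2 groups, each >= 2 samples)
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return a `perm_test_result` with pseudo-F, R^2 and p
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L) {
  dist <- distance_matrix(dist)
  groups <- check_groups(dist, groups)
  n <- nrow(dist)
  d2 <- unclass(dist)^2
  obs <- permanova_f(d2, groups, n)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    fp <- permanova_f(d2, groups[sample.int(n)], n)["f"]
    if (fp >= obs["f"]) ge <- ge + 1L
  }
  perm_result(unname(obs["f"]), unname(obs["r2"]),
              (1 + ge) / (n_perm + 1), n_perm, seed)
}

anosim_r <- function(rk, within, M) {
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` over
#' the ranks of all `M = n (n - 1) / 2` pairwise distances, with a
#' permutation p-value as in [permanova()].
#'
#' @inheritParams permanova
#' @return a `perm_test_result` with the R statistic and p
#' @export
anosim <- function(dist, groups, n_perm = 999L, seed = 1L) {
  dist <- distance_matrix(dist)
  groups <- check_groups(dist, groups)
  n <- nrow(dist)
  lt <- lower.tri(dist)
  rk <- rank(unclass(dist)[lt])
  M <- n * (n - 1) / 2
  same <- function(g) {
    m <- outer(g, g, "==")
    m[lt]
  }
  obs <- anosim_r(rk, same(groups), M)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (anosim_r(rk, same(groups[sample.int(n)]), M) >= obs) ge <- ge + 1L
  }
  perm_result(obs, NA_real_, (1 + ge) / (n_perm + 1), n_perm, seed)
}
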