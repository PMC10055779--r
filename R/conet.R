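#' Filter taxa by mean relative abundance
#'
#' Retains taxa whose mean per-sample relative abundance strictly exceeds the
#' threshold. Networks are typically built at the genus level with a 0.1%
#' (`0.001`) filter for bacteria and at the family level with a 0.001%
#' (`1e-5`) filter for fungi.
#'
#' @param table a [count_table()]
#' @param min_mean_rel_abund threshold as a fraction in `[0, 1)`
#' @return the filtered [count_table()]
#' @export
filter_taxa <- function(table, min_mean_rel_abund) {
  if (!is.numeric(min_mean_rel_abund) || length(min_mean_rel_abund) != 1 ||
      min_mean_rel_abund < 0 || min_mean_rel_abund >= 1)
    stop_fmt("abundance threshold must be a fraction in [0, 1)")
  keep <- rowMeans(relative_abundance(table)) > min_mean_rel_abund
  if (!any(keep)) stop_fmt("no taxa pass the %.4g abundance filter", min_mean_rel_abund)
  count_table(table$counts[keep, , drop = FALSE])
}

# shared preprocessing for the C++ engine
assoc_inputs <- function(table) {
  Rl <- relative_abundance(table)
  n <- ncol(Rl)
  if (n < 4L) stop_fmt("need >= 4 samples for pairwise association measures")
  if (nrow(Rl) < 2L) stop_fmt("need >= 2 taxa for pairwise association measures")
  rmean <- rowMeans(Rl)
  rsd <- apply(Rl, 1L, sd)
  valid <- rsd > 0
  std_rows <- function(m) {
    c0 <- m - rowMeans(m)
    nrm <- sqrt(rowSums(c0^2))
    nrm[nrm == 0] <- 1
    c0 / nrm
  }
  ranks <- t(apply(Rl, 1L, rank))
  Zs <- std_rows(ranks)
  Zp <- std_rows(Rl)
  # KL profiles: pseudocount then per-taxon normalization
  Pk <- table$counts + 0.5
  Pk <- Pk / rowSums(Pk)
  Lk <- log(Pk)
  h <- rowSums(Pk * Lk)
  # equal-frequency bins, ties broken by stable rank order
  nbins <- max(2L, floor(sqrt(n)))
  bins <- t(apply(Rl, 1L, function(x)
    as.integer(floor((rank(x, ties.method = "first") - 1) * nbins / n))))
  list(Zs = Zs, Zp = Zp, Rl = Rl, Pk = Pk, Lk = Lk, h = h,
       bins = bins, nbins = nbins, valid = valid, n = n)
}

pair_index <- function(taxa) {
  T <- length(taxa)
  i <- rep.int(seq_len(T - 1L), times = (T - 1L):1L)
  j <- unlist(lapply(seq_len(T - 1L), function(k) (k + 1L):T))
  data.frame(i = i, j = j, taxon_a = taxa[i], taxon_b = taxa[j],
             stringsAsFactors = FALSE)
}

pair_to_matrix <- function(v, taxa) {
  T <- length(taxa)
  m <- matrix(NA_real_, T, T, dimnames = list(taxa, taxa))
  m[lower.tri(m)] <- NA  # filled below
  idx <- pair_index(taxa)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}

run_engine <- function(table, perms) {
  inp <- assoc_inputs(table)
  res <- assoc_engine_cpp(inp$Zs, inp$Zp, inp$Rl, inp$Pk, inp$Lk, inp$h,
                          inp$bins, inp$nbins, perms, inp$valid)
  taxa <- table$taxa
  if (any(!inp$valid))
    warning(sprintf("constant profile, Spearman/Pearson undefined for: %s",
                    paste(taxa[!inp$valid], collapse = ", ")), call. = FALSE)
  stats <- lapply(seq_along(measure_names), function(m)
    pair_to_matrix(res$obs[, m], taxa))
  names(stats) <- measure_names
  pvalues <- lapply(seq_along(measure_names), function(m)
    pair_to_matrix(res$pval[, m], taxa))
  names(pvalues) <- measure_names
  structure(list(taxa = taxa, n_samples = inp$n, B = res$B,
                 pairs = pair_index(taxa), stats = stats,
                 pvalues = pvalues, w_mean = res$w_mean, w_cov = res$w_cov,
                 stat_cor = res$stat_cor, brown_p = NULL),
            class = "conet_assoc")
}

#' Pairwise ensemble association measures
#'
#' Computes, for every unordered taxon pair, Spearman and Pearson correlation
#' of the relative-abundance profiles, symmetrized Kullback-Leibler
#' dissimilarity of the pseudocounted per-taxon profiles, Bray-Curtis
#' dissimilarity, and mutual information with equal-frequency binning
#' (`floor(sqrt(n))` bins). Pairs involving a constant profile get `NA`
#' Spearman/Pearson with a warning.
#'
#' @param table a [count_table()] (typically after [filter_taxa()])
#' @return a `conet_assoc` object holding symmetric score matrices in
#'   `$stats`; p-value slots are empty until [permutation_pvalues()]
#' @export
pairwise_measures <- function(table) {
  run_engine(table, matrix(0L, 0L, ncol(table$counts)))
}

#' Permutation p-values for all measures
#'
#' The null model shuffles one profile's sample assignment `B` times and
#' recomputes all five measures. P-values use the add-one estimator
#' `(1 + #extreme) / (B + 1)`: two-sided on `|T|` for the signed
#' correlations, upper tail for mutual information, and two-sided (doubled
#' smaller tail: unusually small = co-presence, unusually large = exclusion)
#' for the dissimilarities. Per-replicate empirical p-values also yield the
#' mean and covariance of the `-2*log(p)` transforms used by
#' [brown_combine()].
#'
#' @param table a [count_table()]
#' @param B number of permutations (>= 99; default 1000)
#' @param seed integer seed for the permutations
#' @return a `conet_assoc` with `$stats`, `$pvalues` and Brown inputs filled
#' @export
permutation_pvalues <- function(table, B = 1000L, seed = 1L) {
  if (B < 99L) stop_fmt("B must be >= 99 (p-value resolution)")
  n <- ncol(table$counts)
  set.seed(seed)
  perms <- t(replicate(B, sample.int(n) - 1L))
  assoc <- run_engine(table, perms)
  assoc$seed <- seed
  assoc
}

# Brown's chi-square scaling from the mean vector and covariance matrix of
# the -2*log(p) transforms; zero covariance reduces to Fisher's method.
brown_params <- function(E, V, k) {
  if (!is.finite(V) || V <= 0) return(list(c = 1, f = 2 * k))
  list(c = V / (2 * E), f = 2 * E^2 / V)
}

combine_brown <- function(p, E, V) {
  k <- length(p)
  X <- -2 * sum(log(p))
  par <- brown_params(E, V, k)
  max(pchisq(X / par$c, df = par$f, lower.tail = FALSE), 5e-324)
}

kost_cov <- function(r) 3.263 * r + 0.710 * r^2 + 0.027 * r^3

#' Combine per-measure p-values with the empirical Brown method
#'
#' Models the Fisher statistic `X = -2 * sum(log(p_i))` as `c * chisq(f)`.
#' With `method = "empirical"`, `c` and `f` come from the mean and covariance
#' of the `-2*log(p)` transforms estimated across the permutation replicates;
#' with zero covariance this reduces exactly to Fisher's method. With
#' `method = "kost"` the covariance is the Kost-McDermott polynomial of the
#' permutation correlation between the raw measure statistics. Pairs with
#' fewer than two valid per-measure p-values are skipped (`NA`) with a
#' message.
#'
#' @param assoc a `conet_assoc` from [permutation_pvalues()]
#' @param method `"empirical"` (default) or `"kost"`
#' @return the `conet_assoc` with `$brown_p` (symmetric matrix) filled
#' @export
brown_combine <- function(assoc, method = c("empirical", "kost")) {
  method <- match.arg(method)
  if (is.null(assoc$B) || assoc$B < 1L)
    stop_fmt("run permutation_pvalues() before brown_combine()")
  M <- length(measure_names)
  idx <- assoc$pairs
  P <- nrow(idx)
  pv <- vapply(measure_names, function(m)
    assoc$pvalues[[m]][cbind(idx$i, idx$j)], numeric(P))
  out <- rep(NA_real_, P)
  skipped <- 0L
  for (p in seq_len(P)) {
    ok <- which(!is.na(pv[p, ]))
    k <- length(ok)
    if (k < 2L) { skipped <- skipped + 1L; next }
    if (method == "empirical") {
      E <- sum(assoc$w_mean[p, ok])
      V <- sum(matrix(assoc$w_cov[p, ], M, M)[ok, ok])
    } else {
      r <- matrix(assoc$stat_cor[p, ], M, M)[ok, ok]
      E <- 2 * k
      V <- 4 * k + 2 * sum(kost_cov(r[upper.tri(r)]))
    }
    out[p] <- combine_brown(pv[p, ok], E, V)
  }
  if (skipped > 0)
    message(sprintf("%d pair(s) skipped: fewer than 2 valid p-values", skipped))
  assoc$brown_p <- pair_to_matrix(out, assoc$taxa)
  assoc
}

#' Construct a validated co-occurrence network
#'
#' @param nodes data.frame with columns `taxon`, `abundance`, `hub`
#' @param edges data.frame with columns `from`, `to`, `sign`, `brown_p`,
#'   `spearman`
#' @return object of class `conet_network`
#' @export
conet_network <- function(nodes, edges) {
  stopifnot(all(c("taxon", "abundance", "hub") %in% names(nodes)),
            all(c("from", "to", "sign", "brown_p", "spearman") %in% names(edges)))
  if (anyDuplicated(nodes$taxon)) stop_fmt("duplicate network node")
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) stop_fmt("self-loop in network")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop_fmt("parallel edge in network")
    if (!all(c(edges$from, edges$to) %in% nodes$taxon))
      stop_fmt("edge endpoint missing from node set")
    orphan <- setdiff(nodes$taxon, c(edges$from, edges$to))
    if (length(orphan))
      stop_fmt("node without incident edge: %s", orphan[1L])
    if (!all(edges$sign %in% c(-1L, 1L))) stop_fmt("edge sign must be +/-1")
  } else if (nrow(nodes) > 0) {
    stop_fmt("network without edges must be empty")
  }
  structure(list(nodes = nodes, edges = edges), class = "conet_network")
}

#' @export
print.conet_network <- function(x, ...) {
  cat(sprintf("conet_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Call network edges from combined association evidence
#'
#' An edge is retained iff the association score exceeds `score_threshold`
#' in absolute value and the combined Brown p-value is below `p_threshold`
#' (defaults 0.6 and 0.05). The score is `|Spearman|`; with
#' `use_max_cor = TRUE` it is `max(|Spearman|, |Pearson|)`. Edge sign is the
#' sign of the Spearman correlation. Nodes are the taxa incident to at least
#' one retained edge; hub flags use [detect_hubs()] at `hub_cutoff`.
#'
#' @param assoc a `conet_assoc` with `$brown_p` filled ([brown_combine()])
#' @param score_threshold correlation gate (default 0.6)
#' @param p_threshold combined p-value gate (default 0.05)
#' @param abundance optional named vector of mean relative abundances
#' @param use_max_cor use `max(|Spearman|, |Pearson|)` as the score gate
#' @param hub_cutoff normalized-degree cutoff for hub flags (default 0.2)
#' @return a [conet_network()]
#' @export
build_network <- function(assoc, score_threshold = 0.6, p_threshold = 0.05,
                          abundance = NULL, use_max_cor = FALSE,
                          hub_cutoff = 0.2) {
  if (is.null(assoc$brown_p)) stop_fmt("run brown_combine() first")
  idx <- assoc$pairs
  sp <- assoc$stats$spearman[cbind(idx$i, idx$j)]
  pe <- assoc$stats$pearson[cbind(idx$i, idx$j)]
  bp <- assoc$brown_p[cbind(idx$i, idx$j)]
  score <- if (use_max_cor) pmax(abs(sp), abs(pe), na.rm = TRUE) else abs(sp)
  keep <- !is.na(sp) & !is.na(bp) & score > score_threshold & bp < p_threshold
  edges <- data.frame(from = idx$taxon_a[keep], to = idx$taxon_b[keep],
                      sign = ifelse(sp[keep] >= 0, 1L, -1L),
                      brown_p = bp[keep], spearman = sp[keep],
                      stringsAsFactors = FALSE)
  taxa <- sort(unique(c(edges$from, edges$to)))
  ab <- if (is.null(abundance)) setNames(rep(NA_real_, length(taxa)), taxa)
        else abundance[taxa]
  nodes <- data.frame(taxon = taxa, abundance = unname(ab),
                      hub = logical(length(taxa)), stringsAsFactors = FALSE)
  net <- conet_network(nodes, edges)
  if (nrow(nodes) >= 2) {
    hubs <- detect_hubs(net, cutoff = hub_cutoff)
    net$nodes$hub <- net$nodes$taxon %in% hubs$taxon
  }
  net
}

adjacency_list <- function(net) {
  taxa <- net$nodes$taxon
  adj <- vector("list", length(taxa))
  names(adj) <- taxa
  for (t in taxa) adj[[t]] <- integer(0)
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, taxa)
    ti <- match(net$edges$to, taxa)
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  adj
}

#' Topology indices of a co-occurrence network
#'
#' Reports node and edge counts, density `2E / (N (N - 1))`, mean local
#' clustering coefficient (nodes of degree < 2 contribute 0), average
#' shortest-path length over all connected pairs (disconnected pairs are
#' excluded; the component count is reported), and the percentage of
#' positive and negative edges.
#'
#' @param net a [conet_network()] with at least 2 nodes
#' @return object of class `topology_indices` (a one-row data.frame)
#' @export
topology <- function(net) {
  N <- nrow(net$nodes)
  if (N < 2L) stop_fmt("topology needs at least 2 nodes (density undefined)")
  E <- nrow(net$edges)
  adj <- adjacency_list(net)
  deg <- lengths(adj)

  local_cc <- vapply(seq_len(N), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    nbset <- nb
    for (u in nb) links <- links + sum(adj[[u]] %in% nbset)
    (links / 2) / (k * (k - 1) / 2)
  }, numeric(1))

  # BFS average shortest-path length over connected pairs
  tot <- 0; npairs <- 0
  comp <- rep(NA_integer_, N); ncomp <- 0L
  for (s in seq_len(N)) {
    if (is.na(comp[s])) { ncomp <- ncomp + 1L }
    dist <- rep(NA_integer_, N)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
    if (is.na(comp[s])) comp[which(!is.na(dist))] <- ncomp
    reach <- dist[!is.na(dist)]
    tot <- tot + sum(reach)
    npairs <- npairs + (length(reach) - 1L)
  }
  apl <- if (npairs > 0) tot / npairs else NA_real_

  structure(data.frame(
    clustering_coefficient = mean(local_cc),
    network_density = 2 * E / (N * (N - 1)),
    n_nodes = N, n_edges = E,
    average_path_length = apl,
    positive_pct = if (E) 100 * sum(net$edges$sign > 0) / E else NA_real_,
    negative_pct = if (E) 100 * sum(net$edges$sign < 0) / E else NA_real_,
    n_components = ncomp),
    class = c("topology_indices", "data.frame"))
}

#' Detect hub taxa by normalized degree centrality
#'
#' A taxon is a hub when `degree / (N - 1) >= cutoff` (default 0.2).
#'
#' @param net a [conet_network()]
#' @param cutoff centrality cutoff in `[0, 1]`
#' @return data.frame (`taxon`, `degree`, `centrality`), ranked descending
#' @export
detect_hubs <- function(net, cutoff = 0.2) {
  N <- nrow(net$nodes)
  empty <- data.frame(taxon = character(0), degree = integer(0),
                      centrality = numeric(0), stringsAsFactors = FALSE)
  if (N < 2L) return(empty)
  deg <- lengths(adjacency_list(net))
  cen <- deg / (N - 1)
  keep <- cen >= cutoff
  out <- data.frame(taxon = net$nodes$taxon[keep],
                    degree = as.integer(deg[keep]),
                    centrality = cen[keep], stringsAsFactors = FALSE)
  out[order(-out$centrality, out$taxon), , drop = FALSE]
}

#' One-call co-occurrence network inference
#'
#' Abundance filter, ensemble measures, permutation null, Brown combination
#' and edge calling in one step.
#'
#' @inheritParams permutation_pvalues
#' @inheritParams build_network
#' @param min_mean_rel_abund abundance filter passed to [filter_taxa()]
#' @param brown_method passed to [brown_combine()]
#' @return list with `network`, `assoc` and the filtered `table`
#' @export
infer_network <- function(table, min_mean_rel_abund = 0.001, B = 1000L,
                          seed = 1L, score_threshold = 0.6,
                          p_threshold = 0.05, hub_cutoff = 0.2,
                          use_max_cor = FALSE,
                          brown_method = c("empirical", "kost")) {
  ft <- filter_taxa(table, min_mean_rel_abund)
  assoc <- permutation_pvalues(ft, B = B, seed = seed)
  assoc <- brown_combine(assoc, method = match.arg(brown_method))
  net <- build_network(assoc, score_threshold = score_threshold,
                       p_threshold = p_threshold,
                       abundance = rowMeans(relative_abundance(ft)),
                       use_max_cor = use_max_cor, hub_cutoff = hub_cutoff)
  list(network = net, assoc = assoc, table = ft)
}
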