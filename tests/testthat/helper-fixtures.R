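# shared fixtures: everything is generated in code, nothing read from disk

tiny_counts <- function() {
  count_table(matrix(c(5L, 0L, 1L, 3L), 2, 2, byrow = TRUE,
                     dimnames = list(c("t1", "t2"), c("s1", "s2"))))
}

random_counts <- function(n_taxa = 10, n_samples = 20, seed = 1, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda) + 1L, n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  count_table(m)
}

# counts whose column sums are equal, so relative-abundance profiles are
# proportional to the raw rows (needed for exact-correlation examples)
profile_counts <- function(rows) {
  m <- do.call(rbind, rows)
  filler <- max(colSums(m)) + 10L - colSums(m)
  m <- rbind(m, filler)
  rownames(m) <- c(paste0("t", seq_along(rows)), "filler")
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_table(m)
}

# a conet_network from an edge data.frame (from, to, sign)
mk_network <- function(edges, spearman = 0.8, brown_p = 0.01) {
  if (nrow(edges) == 0)
    return(conet_network(
      data.frame(taxon = character(0), abundance = numeric(0), hub = logical(0)),
      data.frame(from = character(0), to = character(0), sign = integer(0),
                 brown_p = numeric(0), spearman = numeric(0))))
  edges$sign <- as.integer(edges$sign)
  edges$brown_p <- brown_p
  edges$spearman <- spearman * edges$sign
  taxa <- sort(unique(c(edges$from, edges$to)))
  conet_network(data.frame(taxon = taxa, abundance = NA_real_, hub = FALSE,
                           stringsAsFactors = FALSE),
                edges)
}

# random simple graph with exactly N nodes (all incident) and E edges
random_network <- function(N, E, seed = 1, p_negative = 0) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnm(N, E)
    if (min(igraph::degree(g)) > 0) break
  }
  el <- igraph::as_edgelist(g)
  taxa <- paste0("x", seq_len(N))
  sgn <- ifelse(runif(E) < p_negative, -1L, 1L)
  mk_network(data.frame(from = taxa[el[, 1]], to = taxa[el[, 2]], sign = sgn,
                        stringsAsFactors = FALSE))
}

# a small uniform simulation config (all cells identical composition)
uniform_config <- function(n_taxa = 10, blocks = list(), log_noise_sd = 0.3,
                           library_size_mean = 10000, n_replicates = 3L,
                           means = NULL) {
  taxa <- data.frame(taxon = paste0("t", seq_len(n_taxa)),
                     kingdom = "Bacteria",
                     lineage = paste0("k__Bacteria;p__P;c__;o__;f__;g__t",
                                      seq_len(n_taxa)),
                     stringsAsFactors = FALSE)
  if (is.null(means)) means <- rep(1 / n_taxa, n_taxa)
  cm <- matrix(means, n_taxa, 19,
               dimnames = list(taxa$taxon, miconet:::simulation_cells()))
  simulation_config(taxa, cm, blocks = blocks, log_noise_sd = log_noise_sd,
                    library_size_mean = library_size_mean,
                    n_replicates = n_replicates)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# planted-edge recovery on the pooled moderate+high bacterial samples
recovery_run <- function(seed, B = 1000) {
  ds <- generate_dataset(default_soil_profile(), seed = seed)
  ba <- kingdom_subset(ds$counts, ds$taxonomy, "Bacteria")
  sel <- ds$design$sample[ds$design$ismb %in% c("M", "H")]
  tb <- count_table(ba$counts[, sel, drop = FALSE])
  res <- suppressMessages(suppressWarnings(
    infer_network(tb, min_mean_rel_abund = 0.001, B = B, seed = seed + 1)))
  truth <- ds$truth$edges
  bt <- truth[truth$taxon_a %in% ba$taxa, ]
  pred <- pair_key(res$network$edges$from, res$network$edges$to)
  tk <- pair_key(bt$taxon_a, bt$taxon_b)
  list(tp = sum(pred %in% tk), n_pred = length(pred), n_truth = length(tk),
       network = res$network)
}
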