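#' Construct a validated taxon count table
#'
#' The basic data container of the package: a non-negative integer matrix of
#' read counts with taxa as rows and samples as columns. All downstream
#' stages (diversity, networks, guild scoring) consume this type. Relative
#' abundances are always derived on demand with [relative_abundance()] and
#' never stored.
#'
#' @param counts integer-like matrix, taxa x samples, with unique non-empty
#'   `rownames` (taxon identifiers) and `colnames` (sample identifiers).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `taxa` and `samples`.
#' @examples
#' ct <- count_table(matrix(c(5, 0, 1, 3), 2, 2, byrow = TRUE,
#'                          dimnames = list(c("t1", "t2"), c("s1", "s2"))))
#' library_sizes(ct)
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("count table needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate taxon identifier: %s",
             rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample identifier: %s",
             colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts) || anyNA(counts))
    stop_fmt("counts must be numeric and non-missing")
  if (any(counts < 0))
    stop_fmt("negative count at taxon '%s'",
             rownames(counts)[which(counts < 0, arr.ind = TRUE)[1L, 1L]])
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_fmt("non-integer count at taxon '%s'",
             rownames(counts)[which(abs(counts - round(counts)) > 1e-8,
                                    arr.ind = TRUE)[1L, 1L]])
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop_fmt("count table needs at least 1 taxon and 2 samples")
  cs <- colSums(counts)
  if (any(cs == 0))
    stop_fmt("sample '%s' has zero library size", colnames(counts)[cs == 0][1L])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 taxa = rownames(counts),
                 samples = colnames(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, total reads %s\n",
              length(x$taxa), length(x$samples),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Per-sample library sizes (column sums)
#' @param table a [count_table()]
#' @return named numeric vector of reads per sample
#' @export
library_sizes <- function(table) colSums(table$counts)

#' Per-sample relative abundances
#'
#' Each column is divided by its library size, so columns sum to one.
#'
#' @param table a [count_table()]
#' @return numeric matrix, taxa x samples
#' @export
relative_abundance <- function(table) {
  sweep(table$counts, 2L, colSums(table$counts), "/")
}

#' Read a tab-separated taxon count table
#'
#' Expects a header row of sample identifiers and a first column of taxon
#' identifiers; the remaining cells are read counts.
#'
#' @param path file path
#' @return a [count_table()]
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_fmt("'%s': need a taxon column and >= 2 samples", path)
  taxa <- as.character(df[[1L]])
  hdr <- names(df)[-1L]  # keep duplicates: `[.data.frame` would repair them
  m <- as.matrix(df[, -1L, drop = FALSE])
  colnames(m) <- hdr
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_fmt("'%s': non-numeric count at row %d ('%s'), column '%s'",
               path, bad[1L, 1L], taxa[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
    stop_fmt("'%s': counts are not numeric", path)
  }
  rownames(m) <- taxa
  count_table(m)
}

#' Write a count table as TSV
#' @param table a [count_table()]
#' @param path file path
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon = table$taxa, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixed rank order for all taxonomy operations. "domain" holds Bacteria or
# Fungi (amplicon tables mix the k__/d__ conventions).
tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomy map
#'
#' One row per taxon with the six fixed ranks domain..genus. Unknown ranks
#' are `NA`. Names such as `unclassified_f__Nectriaceae` or
#' `norank_c__Gemmatimonadetes` are kept verbatim as rank values.
#'
#' @param df data.frame with a `taxon` column and any of the rank columns
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus`.
#' @return object of class `taxonomy_map` (a data.frame)
#' @export
taxonomy_map <- function(df) {
  if (!"taxon" %in% names(df)) stop_fmt("taxonomy needs a 'taxon' column")
  if (anyDuplicated(df$taxon))
    stop_fmt("duplicate taxon in taxonomy: %s", df$taxon[duplicated(df$taxon)][1L])
  for (r in tax_ranks) if (!r %in% names(df)) df[[r]] <- NA_character_
  df <- df[, c("taxon", tax_ranks)]
  df[] <- lapply(df, as.character)
  df$taxon <- as.character(df$taxon)
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy table (taxon, ranked lineage string)
#'
#' Lineage segments are separated by `;` and assigned positionally to the
#' ranks domain, phylum, class, order, family, genus. Conventional rank
#' prefixes (`k__`, `d__`, `p__`, `c__`, `o__`, `f__`, `g__`) are stripped
#' when they match the positional rank; placeholder names such as
#' `unclassified_f__Nectriaceae` are preserved verbatim.
#'
#' @param path file path to a two-column TSV (taxon, lineage)
#' @return a [taxonomy_map()]
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fmt("'%s': need taxon and lineage columns", path)
  lineage <- as.character(df[[2L]])
  if (anyNA(lineage) || any(!nzchar(lineage)))
    stop_fmt("'%s': taxon '%s' has no lineage", path,
             df[[1L]][which(is.na(lineage) | !nzchar(lineage))[1L]])
  parsed <- t(vapply(lineage, parse_lineage, character(length(tax_ranks))))
  out <- data.frame(taxon = as.character(df[[1L]]), parsed,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("taxon", tax_ranks)
  taxonomy_map(out)
}

parse_lineage <- function(lineage) {
  seg <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  seg <- seg[nzchar(seg)]
  out <- rep(NA_character_, length(tax_ranks))
  prefixes <- c(domain = "[kd]__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  for (i in seq_along(seg)) {
    if (i > length(tax_ranks)) break
    s <- seg[i]
    pat <- paste0("^", prefixes[i])
    # strip the positional prefix only; unclassified_/norank_ names intact
    if (grepl(pat, s)) s <- sub(pat, "", s)
    out[i] <- if (nzchar(s)) s else NA_character_
  }
  out
}

#' Write a taxonomy map as a two-column lineage TSV
#' @param tax a [taxonomy_map()]
#' @param path file path
#' @export
write_taxonomy <- function(tax, path) {
  prefixes <- c(domain = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  lineage <- vapply(seq_len(nrow(tax)), function(i) {
    vals <- unlist(tax[i, tax_ranks])
    keep <- !is.na(vals)
    if (!any(keep)) return("k__")
    upto <- max(which(keep))
    vals <- vals[seq_len(upto)]
    vals[is.na(vals)] <- ""
    # re-attach the conventional prefix unless the name embeds its own
    pref <- ifelse(grepl("__", vals, fixed = TRUE), "", prefixes[seq_len(upto)])
    paste0(pref, vals, collapse = ";")
  }, character(1))
  write.table(data.frame(taxon = tax$taxon, lineage = lineage),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_factors <- list(ismb = c("L", "M", "H", "native"),
                       fertilizer = c("N", "C", "O", "native"),
                       habitat = c("SB", "SR", "native"))

#' Construct per-sample design metadata
#'
#' Treatment factors of the factorial design: indigenous soil microbial
#' biomass level (`L`, `M`, `H`), fertilizer (`N` none, `C` chemical,
#' `O` organic/biogas residue), soil habitat (`SB` bulk, `SR` rhizosphere),
#' plus replicate number and optional physicochemical/yield covariates.
#' Native (untreated) soil carries the level `"native"` for all three factors.
#'
#' @param df data.frame with columns `sample`, `ismb`, `fertilizer`,
#'   `habitat`, `replicate`; further numeric columns are kept as covariates.
#' @return object of class `sample_design` (a data.frame)
#' @export
sample_design <- function(df) {
  need <- c("sample", "ismb", "fertilizer", "habitat", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("design lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop_fmt("duplicate sample in design: %s", df$sample[duplicated(df$sample)][1L])
  for (f in names(design_factors)) {
    bad <- setdiff(unique(as.character(df[[f]])), design_factors[[f]])
    if (length(bad)) stop_fmt("invalid %s level: %s", f, bad[1L])
    df[[f]] <- factor(df[[f]], levels = design_factors[[f]])
  }
  nat <- df$ismb == "native" | df$fertilizer == "native" | df$habitat == "native"
  if (any(nat & !(df$ismb == "native" & df$fertilizer == "native" & df$habitat == "native")))
    stop_fmt("native samples must be native for all three factors")
  df$replicate <- as.integer(df$replicate)
  covars <- setdiff(names(df), need)
  for (cv in covars) {
    if (!is.numeric(df[[cv]]))
      stop_fmt("covariate '%s' must be numeric", cv)
    if (any(!is.finite(df[[cv]]) & !is.na(df[[cv]])))
      stop_fmt("covariate '%s' has non-finite values", cv)
  }
  df$sample <- as.character(df$sample)
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Treatment code of each sample (e.g. `OH_SR`, or `native`)
#' @param design a [sample_design()]
#' @return character vector, fertilizer + ISMB level + habitat
#' @export
treatment_code <- function(design) {
  ifelse(design$ismb == "native", "native",
         paste0(design$fertilizer, design$ismb, "_", design$habitat))
}

#' Read / write sample design TSVs
#' @param path file path
#' @return a [sample_design()]
#' @export
read_sample_design <- function(path) {
  sample_design(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' @rdname read_sample_design
#' @param design a [sample_design()]
#' @export
write_sample_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network as GraphML
#'
#' Nodes carry the taxon name, mean relative abundance and hub flag; edges
#' carry the consensus sign, combined Brown p-value and Spearman score. The
#' file re-imports losslessly with [read_network_graphml()].
#'
#' @param network a `conet_network` (see [build_network()])
#' @param path output path
#' @export
write_network_graphml <- function(network, path) {
  g <- network_to_igraph(network)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_fmt("cannot write '%s': %s", path, conditionMessage(e)))
  close(con)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

network_to_igraph <- function(network) {
  stopifnot(inherits(network, "conet_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(network$nodes),
                            name = network$nodes$taxon,
                            abundance = network$nodes$abundance,
                            hub = network$nodes$hub)
  if (nrow(network$edges) > 0) {
    idx <- rbind(match(network$edges$from, network$nodes$taxon),
                 match(network$edges$to, network$nodes$taxon))
    g <- igraph::add_edges(g, as.vector(idx),
                           sign = network$edges$sign,
                           brown_p = network$edges$brown_p,
                           spearman = network$edges$spearman)
  }
  g
}

#' Re-import a GraphML network written by [write_network_graphml()]
#' @param path file path
#' @return a `conet_network`
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  nodes <- data.frame(
    taxon = if (n) igraph::V(g)$name else character(0),
    abundance = if (n) igraph::V(g)$abundance else numeric(0),
    hub = if (n) as.logical(igraph::V(g)$hub) else logical(0),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(
    from = as.character(el[, 1]), to = as.character(el[, 2]),
    sign = if (nrow(el)) as.integer(igraph::E(g)$sign) else integer(0),
    brown_p = if (nrow(el)) igraph::E(g)$brown_p else numeric(0),
    spearman = if (nrow(el)) igraph::E(g)$spearman else numeric(0),
    stringsAsFactors = FALSE)
  conet_network(nodes, edges)
}

#' Export the edge list of a network as TSV
#' @param network a `conet_network`
#' @param path output path
#' @export
write_network_edgelist <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
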