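#' Simulation configuration for a factorial soil-community experiment
#'
#' Describes a stated world: per-taxon target relative abundances for every
#' treatment cell (3 biomass levels x 3 fertilizers x 2 habitats, plus a
#' native-soil cell), planted taxon-taxon association blocks realized through
#' shared latent Gaussian factors, a Dirichlet-multinomial count layer, and
#' treatment-structured covariates. Identical config + seed always yields
#' identical output.
#'
#' @param taxa data.frame with columns `taxon`, `kingdom` (`"Bacteria"` or
#'   `"Fungi"`) and `lineage` (rank-prefixed string for the taxonomy table)
#' @param cell_means taxa x cells matrix of target within-kingdom relative
#'   abundances; columns are treatment codes (`NL_SB`, ..., `OH_SR`,
#'   `native`); per-kingdom column sums must be in (0, 1]; any deficit is
#'   spread evenly over that kingdom's taxa
#' @param blocks list of association blocks, each
#'   `list(taxa = c(...), loadings = c(...))`; loadings are signed latent
#'   factor loadings (same kingdom per block)
#' @param library_size_mean,library_size_dispersion negative-binomial reads
#'   per sample and kingdom (mean 10,000 by default, a desk-scale stand-in)
#' @param overdispersion Dirichlet-multinomial overdispersion (default 0.02,
#'   i.e. concentration 50)
#' @param log_noise_sd per-taxon log-normal noise sd (default 0.30)
#' @param n_replicates replicates per cell (default 3; 19 cells x 3 = 57)
#' @param covariate_means covariates x cells matrix of covariate means
#' @param covariate_sd named vector of covariate noise sd
#' @param covariate_links list of `list(covariate =, taxon =, coef =)`
#'   entries tying a covariate to a taxon's latent log-abundance deviation
#' @param pathogen_taxa character vector of pathogen taxon names
#' @param seed default seed for [generate_dataset()] (default 20170001)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(taxa, cell_means, blocks = list(),
                              library_size_mean = 10000,
                              library_size_dispersion = 8,
                              overdispersion = 0.02,
                              log_noise_sd = 0.30,
                              n_replicates = 3L,
                              covariate_means = NULL,
                              covariate_sd = NULL,
                              covariate_links = list(),
                              pathogen_taxa = character(0),
                              seed = 20170001L) {
  stopifnot(is.data.frame(taxa),
            all(c("taxon", "kingdom", "lineage") %in% names(taxa)))
  if (nrow(taxa) == 0L) stop_fmt("config error: zero taxa")
  if (n_replicates < 1L) stop_fmt("config error: zero replicates")
  if (anyDuplicated(taxa$taxon)) stop_fmt("duplicate taxon in config")
  if (!all(taxa$kingdom %in% c("Bacteria", "Fungi")))
    stop_fmt("kingdom must be Bacteria or Fungi")
  cells <- simulation_cells()
  cell_means <- as.matrix(cell_means)
  if (!setequal(colnames(cell_means), cells))
    stop_fmt("cell_means must have one column per treatment cell (%d cells)",
             length(cells))
  cell_means <- cell_means[taxa$taxon, cells, drop = FALSE]
  if (any(cell_means < 0)) stop_fmt("negative target abundance")
  for (kg in unique(taxa$kingdom)) {
    rows <- taxa$kingdom == kg
    cs <- colSums(cell_means[rows, , drop = FALSE])
    if (any(cs > 1 + 1e-8))
      stop_fmt("%s target abundances exceed 1 in cell %s", kg,
               cells[cs > 1 + 1e-8][1L])
    if (any(cs <= 0)) stop_fmt("%s has zero total abundance in a cell", kg)
    # spread any unallocated mass evenly
    deficit <- pmax(0, 1 - cs)
    cell_means[rows, ] <- sweep(cell_means[rows, , drop = FALSE], 2L,
                                deficit / sum(rows), "+")
  }
  for (b in blocks) {
    stopifnot(all(c("taxa", "loadings") %in% names(b)),
              length(b$taxa) == length(b$loadings))
    if (!all(is.finite(b$loadings))) stop_fmt("non-finite loading")
    miss <- setdiff(b$taxa, taxa$taxon)
    if (length(miss)) stop_fmt("block references unknown taxon '%s'", miss[1L])
  }
  if (!is.null(covariate_means)) {
    covariate_means <- as.matrix(covariate_means)
    covariate_means <- covariate_means[, cells, drop = FALSE]
    stopifnot(!is.null(rownames(covariate_means)))
    if (is.null(covariate_sd))
      covariate_sd <- setNames(rep(1, nrow(covariate_means)),
                               rownames(covariate_means))
  }
  structure(list(taxa = taxa, cells = cells, cell_means = cell_means,
                 blocks = blocks,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 overdispersion = overdispersion,
                 log_noise_sd = log_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 covariate_means = covariate_means,
                 covariate_sd = covariate_sd,
                 covariate_links = covariate_links,
                 pathogen_taxa = pathogen_taxa,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

simulation_cells <- function() {
  grid <- expand.grid(habitat = c("SB", "SR"), ismb = c("L", "M", "H"),
                      fertilizer = c("N", "C", "O"),
                      stringsAsFactors = FALSE)
  c(paste0(grid$fertilizer, grid$ismb, "_", grid$habitat), "native")
}

cell_factors <- function(code) {
  if (code == "native")
    return(list(ismb = "native", fertilizer = "native", habitat = "native"))
  list(ismb = substr(code, 2L, 2L), fertilizer = substr(code, 1L, 1L),
       habitat = sub("^.._", "", code))
}

#' Generate a synthetic factorial community dataset
#'
#' Draws, for every sample: latent Gaussian factors (one per association
#' block), per-taxon log-normal abundances centered on the cell's target
#' composition (mean-corrected so targets are unbiased), then per-kingdom
#' Dirichlet-multinomial counts at a negative-binomial library size.
#' Covariates follow their cell means plus configured links to taxon
#' latent deviations.
#'
#' @param config a [simulation_config()]
#' @param seed integer seed (defaults to the config's seed)
#' @return list of class `synthetic_dataset`: `counts` ([count_table()],
#'   both kingdoms stacked), `taxonomy` ([taxonomy_map()]), `design`
#'   ([sample_design()] with covariates), `truth` (planted edges, factor
#'   effects and the target cell means)
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  taxa <- config$taxa$taxon
  Tn <- length(taxa)
  kingdoms <- config$taxa$kingdom
  nb <- length(config$blocks)

  # per-taxon loading vectors
  Lmat <- matrix(0, Tn, max(nb, 1L), dimnames = list(taxa, NULL))
  for (b in seq_len(nb)) {
    bl <- config$blocks[[b]]
    Lmat[bl$taxa, b] <- bl$loadings
  }
  sig <- config$log_noise_sd

  MU <- calibrate_cell_means(config, Lmat)
  set.seed(seed)

  cells <- rep(config$cells, each = config$n_replicates)
  reps <- rep(seq_len(config$n_replicates), times = length(config$cells))
  samples <- paste0(cells, "_", reps)
  ns <- length(samples)

  counts <- matrix(0L, Tn, ns, dimnames = list(taxa, samples))
  dev <- matrix(0, Tn, ns, dimnames = list(taxa, samples))

  for (s in seq_len(ns)) {
    f <- rnorm(max(nb, 1L))
    eps <- rnorm(Tn, 0, sig)
    noise <- drop(Lmat %*% f) + eps
    dev[, s] <- noise
    eta <- MU[, cells[s]] + noise
    for (kg in unique(kingdoms)) {
      rows <- which(kingdoms == kg)
      w <- exp(eta[rows])
      p <- w / sum(w)
      g <- rgamma(length(rows), shape = p / config$overdispersion)
      pdir <- if (sum(g) > 0) g / sum(g) else p
      depth <- max(500L, rnbinom(1L, mu = config$library_size_mean,
                                 size = config$library_size_dispersion))
      counts[rows, s] <- rmultinom(1L, depth, pdir)[, 1L]
    }
  }

  fac <- lapply(cells, cell_factors)
  design_df <- data.frame(
    sample = samples,
    ismb = vapply(fac, `[[`, "", "ismb"),
    fertilizer = vapply(fac, `[[`, "", "fertilizer"),
    habitat = vapply(fac, `[[`, "", "habitat"),
    replicate = reps, stringsAsFactors = FALSE)
  if (!is.null(config$covariate_means)) {
    for (cv in rownames(config$covariate_means)) {
      base <- config$covariate_means[cv, cells]
      val <- base + rnorm(ns, 0, config$covariate_sd[[cv]])
      for (lk in config$covariate_links) {
        if (lk$covariate == cv) val <- val + lk$coef * dev[lk$taxon, ]
      }
      design_df[[cv]] <- unname(val)
    }
  }

  parsed <- t(vapply(config$taxa$lineage, parse_lineage,
                     character(length(tax_ranks))))
  taxmap <- data.frame(taxon = taxa, parsed, stringsAsFactors = FALSE,
                       row.names = NULL)
  names(taxmap) <- c("taxon", tax_ranks)

  truth <- list(
    edges = planted_edges(config),
    factor_effects = planted_factor_effects(config),
    cell_means = config$cell_means,
    pathogen_taxa = config$pathogen_taxa)

  structure(list(counts = count_table(counts),
                 taxonomy = taxonomy_map(taxmap),
                 design = sample_design(design_df),
                 truth = truth, seed = seed),
            class = "synthetic_dataset")
}

# Softmax normalization and the count layer are nonlinear, so raw
# log(target) means are biased (Jensen / compositional saturation,
# noticeable for block taxa and dominant taxa). Calibrate per-cell log-mean
# offsets against a fixed deterministic Monte-Carlo noise panel so that
# expected within-kingdom relative abundances hit the configured targets.
calibrate_cell_means <- function(config, Lmat, n_draws = 6000L, n_iter = 4L) {
  taxa <- config$taxa$taxon
  Tn <- length(taxa)
  sig <- config$log_noise_sd
  nb <- ncol(Lmat)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(987654321L)
  Fp <- matrix(rnorm(nb * n_draws), nb, n_draws)
  Ep <- matrix(rnorm(Tn * n_draws, 0, sig), Tn, n_draws)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  noise <- Lmat %*% Fp + Ep

  MU <- log(pmax(config$cell_means, 1e-8))
  key <- apply(config$cell_means, 2L, paste, collapse = ",")
  for (cell in config$cells[!duplicated(key)]) {
    mu <- MU[, cell]
    tgt <- config$cell_means[, cell]
    for (it in seq_len(n_iter)) {
      w <- exp(mu + noise)
      for (kg in unique(config$taxa$kingdom)) {
        rows <- config$taxa$kingdom == kg
        wk <- w[rows, , drop = FALSE]
        share <- rowMeans(sweep(wk, 2L, colSums(wk), "/"))
        mu[rows] <- mu[rows] + log(pmax(tgt[rows], 1e-8) / pmax(share, 1e-12))
      }
    }
    MU[, key == key[[cell]]] <- mu
  }
  MU
}

planted_edges <- function(config) {
  out <- list()
  for (bl in config$blocks) {
    k <- length(bl$taxa)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      out[[length(out) + 1L]] <- data.frame(
        taxon_a = bl$taxa[i], taxon_b = bl$taxa[j],
        sign = ifelse(bl$loadings[i] * bl$loadings[j] >= 0, 1L, -1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      sign = integer(0)))
  do.call(rbind, out)
}

planted_factor_effects <- function(config) {
  cells <- setdiff(config$cells, "native")
  info <- lapply(cells, cell_factors)
  out <- list()
  for (f in c("ismb", "fertilizer", "habitat")) {
    lev <- vapply(info, `[[`, "", f)
    bycell <- config$cell_means[, cells, drop = FALSE]
    levmean <- vapply(unique(lev), function(l)
      rowMeans(bycell[, lev == l, drop = FALSE]), numeric(nrow(bycell)))
    rng <- apply(levmean, 1L, function(x) max(x) - min(x))
    rel <- rng / pmax(apply(levmean, 1L, max), 1e-12)
    affected <- rownames(bycell)[rel > 0.2]
    out[[f]] <- data.frame(taxon = affected,
                           effect_size = rel[rel > 0.2],
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Subset a count table to one kingdom
#'
#' @param table a [count_table()]
#' @param taxonomy a [taxonomy_map()] covering the table's taxa
#' @param kingdom `"Bacteria"` or `"Fungi"` (matched against the domain rank)
#' @return a [count_table()] restricted to that kingdom's taxa
#' @export
kingdom_subset <- function(table, taxonomy, kingdom) {
  keep <- taxonomy$taxon[!is.na(taxonomy$domain) & taxonomy$domain == kingdom]
  keep <- intersect(table$taxa, keep)
  if (!length(keep)) stop_fmt("no taxa for kingdom '%s'", kingdom)
  count_table(table$counts[keep, , drop = FALSE])
}

# ---- bundled default profile ------------------------------------------------

# 30 bacterial genera with per-genus target shares under the "rich"
# composition (moderate/high biomass and native soil: seven abundant phyla,
# fairly even) and the "low" composition (sterilized soil: mass concentrated
# on Proteobacteria / Firmicutes / Bacteroidetes survivors).
bact_genera <- data.frame(
  genus = c("Massilia", "Rhizobium", "Devosia", "Ensifer", "Bdellovibrio",
            "Brevundimonas",
            "Bacillus", "Tumebacillus", "Paenibacillus", "Paenisporosarcina",
            "Sporosarcina",
            "Adhaeribacter", "Flavisolibacter", "Pedobacter",
            "norank_f__Chitinophagaceae", "norank_f__Cytophagaceae",
            "Pseudarthrobacter", "norank_o__Acidimicrobiales", "Streptomyces",
            "Nocardioides",
            "norank_o__AKYG1722", "norank_c__Anaerolineae", "Roseiflexus",
            "Microcoleus", "Nostoc",
            "norank_c__Acidobacteria", "Blastocatella",
            "norank_c__Gemmatimonadetes", "Nitrospira", "Chthoniobacter"),
  phylum = c(rep("Proteobacteria", 6), rep("Firmicutes", 5),
             rep("Bacteroidetes", 5), rep("Actinobacteria", 4),
             rep("Chloroflexi", 3), rep("Cyanobacteria", 2),
             rep("Acidobacteria", 2), "Gemmatimonadetes", "Nitrospirae",
             "Verrucomicrobia"),
  rich = c(.06, .03, .03, .02, .02, .02,
           .06, .03, .02, .02, .02,
           .03, .06, .06, .03, .02,
           .06, .03, .02, .02,
           .03, .03, .02,
           .06, .02,
           .03, .02,
           .06, .06, .01),
  # sterilized soil: survivor phyla dominate and most minor lineages drop to
  # trace frequencies (~1 read expected at the default depth), so observed
  # richness and evenness are clearly reduced
  low = c(.22, .03, .03, .02, .02, .02,
          .10, .03, .015, .01, .009,
          .18, .10, .08, .06, .04,
          .02, 1e-4, 1e-4, 1e-4,
          1e-4, 1e-4, 1e-4,
          .01, 1e-4,
          .005, 1e-4,
          1e-4, 1e-4, 1e-4),
  stringsAsFactors = FALSE)
bact_genera$rich <- bact_genera$rich / sum(bact_genera$rich)
bact_genera$low <- bact_genera$low / sum(bact_genera$low)

fungal_families <- c("Cystofilobasidiaceae", "Chaetomiaceae", "Microascaceae",
                     "Lasiosphaeriaceae", "Trichocomaceae", "Mortierellaceae",
                     "Rhizophlyctidaceae", "unclassified_k__Fungi",
                     "unclassified_p__Ascomycota", "Hypocreaceae",
                     "Aspergillaceae", "Sporormiaceae", "Pleosporaceae",
                     "Davidiellaceae", "Tremellaceae", "Filobasidiaceae",
                     "Piskurozymaceae", "Ceratobasidiaceae")

# rhizosphere Fusarium / unclassified_f__Nectriaceae target shares per cell
fusarium_sr_shares <- list(
  NL_SR = c(.8741, .0186), CL_SR = c(.1602, .7626), OL_SR = c(.0503, .0434),
  NM_SR = c(.0827, .6222), CM_SR = c(.0928, .0877), OM_SR = c(.1507, .6986),
  NH_SR = c(.0236, .2637), CH_SR = c(.1628, .1324), OH_SR = c(.0384, .1304),
  native = c(.0159, .0014))

#' Bundled default simulation profile
#'
#' A ready-made [simulation_config()] emulating the design of a
#' 3 biomass-level x 3 fertilizer x 2 habitat microcosm experiment with one
#' native-soil cell and three replicates per cell (57 samples): low-biomass
#' cells concentrate bacterial mass on three dominant phyla while
#' moderate/high cells spread it over seven; rhizosphere cells carry
#' treatment-dependent Fusarium-type pathogen shares (e.g. 87.41% in the
#' unfertilized low-biomass rhizosphere, 5.03% under organic fertilizer,
#' 1.59% in native soil); three bacterial and one fungal association blocks
#' are planted via shared latent factors; covariates follow the factorial
#' structure with yield ratios favouring organic fertilizer at high biomass.
#'
#' @return a [simulation_config()]
#' @export
default_soil_profile <- function() {
  cells <- simulation_cells()

  bact <- data.frame(taxon = bact_genera$genus, kingdom = "Bacteria",
                     lineage = paste0("k__Bacteria;p__", bact_genera$phylum,
                                      ";c__;o__;f__;g__", bact_genera$genus),
                     stringsAsFactors = FALSE)
  fung <- data.frame(
    taxon = c("Fusarium", "unclassified_f__Nectriaceae", fungal_families),
    kingdom = "Fungi",
    lineage = c(
      "k__Fungi;p__Ascomycota;c__Sordariomycetes;o__Hypocreales;f__Nectriaceae;g__Fusarium",
      "k__Fungi;p__Ascomycota;c__Sordariomycetes;o__Hypocreales;f__Nectriaceae;g__unclassified_f__Nectriaceae",
      paste0("k__Fungi;p__;c__;o__;f__", fungal_families)),
    stringsAsFactors = FALSE)
  taxa <- rbind(bact, fung)

  cm <- matrix(0, nrow(taxa), length(cells),
               dimnames = list(taxa$taxon, cells))
  for (cell in cells) {
    lev <- cell_factors(cell)$ismb
    cm[bact_genera$genus, cell] <-
      if (lev == "L") bact_genera$low else bact_genera$rich
  }

  even_w <- setNames(c(.08, .08, .07, .10, .10, .10, .10, .07, .06,
                       rep(.24 / 9, 9)), fungal_families)
  nl_sb_w <- setNames(c(.02, .50, .25, .01, .01, .01, .01, .02, .15,
                        rep(.02 / 9, 9)), fungal_families)
  ol_sb_w <- setNames(c(.02, .02, .02, .02, .02, .10, .02, .70, .02,
                        rep(.06 / 9, 9)), fungal_families)
  for (cell in cells) {
    fac <- cell_factors(cell)
    path <- if (cell %in% names(fusarium_sr_shares) &&
                (fac$habitat %in% c("SR", "native")))
      fusarium_sr_shares[[cell]] else c(.02, .01)
    w <- even_w
    if (cell == "NL_SB") w <- nl_sb_w
    if (cell == "OL_SB") w <- ol_sb_w
    cm["Fusarium", cell] <- path[1L]
    cm["unclassified_f__Nectriaceae", cell] <- path[2L]
    cm[fungal_families, cell] <- (1 - sum(path)) * w / sum(w)
  }

  # mirrored "competition" modules: equal positive and negative loadings on
  # equal-mass taxa, so the module's first-order mass effect cancels and the
  # compositional common-mode stays small
  blocks <- list(
    list(taxa = c("Nitrospira", "norank_c__Gemmatimonadetes",
                  "Massilia", "Bacillus"),
         loadings = c(1.35, 1.35, -1.35, -1.35)),
    list(taxa = c("Pseudarthrobacter", "Microcoleus",
                  "Pedobacter", "Flavisolibacter"),
         loadings = c(1.35, 1.35, -1.35, -1.35)),
    list(taxa = c("Rhizophlyctidaceae", "Lasiosphaeriaceae",
                  "Trichocomaceae", "Mortierellaceae"),
         loadings = c(1.35, 1.35, -1.35, -1.35)))

  covs <- c("TN", "TC", "NH4", "NO3", "AP", "AK", "dry_matter", "stem_length")
  cvm <- matrix(0, length(covs), length(cells),
                dimnames = list(covs, cells))
  dm_tab <- list(N = c(L = 3.0, M = 3.5, H = 4.0),
                 C = c(L = 4.0, M = 4.5, H = 4.43),
                 O = c(L = 4.6, M = 5.75, H = 6.70))
  for (cell in cells) {
    fac <- cell_factors(cell)
    if (cell == "native") {
      cvm[, cell] <- c(0.45, 31.6, 0.10, 2.65, 27.4, 197.2, 3.2, 20)
      next
    }
    tn <- c(L = .45, M = .49, H = .50)[[fac$ismb]] +
      c(N = 0, C = .02, O = -.01)[[fac$fertilizer]]
    tc <- c(L = 28.7, M = 37.2, H = 30.7)[[fac$ismb]] +
      c(N = 0, C = -1, O = 3)[[fac$fertilizer]]
    nh4 <- 0.10 + c(N = 0, C = .6, O = .3)[[fac$fertilizer]] +
      ifelse(fac$habitat == "SR", -.05, 0)
    no3 <- 2.65 + c(N = 0, C = .5, O = 1)[[fac$fertilizer]] +
      ifelse(fac$habitat == "SR", .2, 0)
    ap <- c(N = 27, C = 40, O = 80)[[fac$fertilizer]] +
      ifelse(fac$fertilizer == "O" && fac$ismb == "H", 20, 0)
    ak <- c(L = 221.0, M = 217.6, H = 218.4)[[fac$ismb]] +
      ifelse(fac$habitat == "SR", -5, 0)
    dm <- dm_tab[[fac$fertilizer]][[fac$ismb]]
    sl <- 20 + c(L = 0, M = 2, H = 4)[[fac$ismb]] +
      c(N = 0, C = 2, O = 3)[[fac$fertilizer]]
    cvm[, cell] <- c(tn, tc, nh4, no3, ap, ak, dm, sl)
  }
  cvs <- c(TN = .01, TC = 1, NH4 = .02, NO3 = .10, AP = 3, AK = 4,
           dry_matter = .15, stem_length = 1)
  links <- list(
    list(covariate = "NO3", taxon = "Fusarium", coef = -0.15),
    list(covariate = "TC", taxon = "unclassified_f__Nectriaceae", coef = -1.2),
    list(covariate = "AK", taxon = "Fusarium", coef = -5))

  simulation_config(taxa = taxa, cell_means = cm, blocks = blocks,
                    covariate_means = cvm, covariate_sd = cvs,
                    covariate_links = links,
                    pathogen_taxa = c("Fusarium", "unclassified_f__Nectriaceae"),
                    seed = 20170001L)
}
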