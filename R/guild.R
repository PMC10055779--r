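#' Read a trophic-guild lookup table
#'
#' TSV with columns `taxon`, `rank` (`genus` or `family`), `trophic_mode`,
#' `guild`, `confidence` (`Possible`, `Probable`, `Highly Probable`).
#' Multiple guilds may be separated by `-` inside `guild`. The same format
#' as full community-curated guild databases, so a complete table can be
#' dropped in.
#'
#' @param path file path
#' @return object of class `guild_table` (a data.frame)
#' @export
read_guild_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon", "rank", "trophic_mode", "guild", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("guild table lacks column(s): %s",
                             paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_fmt("empty guild table")
  if (!all(df$rank %in% c("genus", "family")))
    stop_fmt("guild rank must be 'genus' or 'family'")
  key <- paste(df$rank, df$taxon)
  if (anyDuplicated(key))
    stop_fmt("duplicate guild entry: %s", key[duplicated(key)][1L])
  if (!all(df$confidence %in% names(confidence_levels)))
    stop_fmt("invalid confidence value '%s'",
             setdiff(df$confidence, names(confidence_levels))[1L])
  class(df) <- c("guild_table", "data.frame")
  df
}

confidence_levels <- c("Possible" = 1L, "Probable" = 2L, "Highly Probable" = 3L)

#' Bundled mini guild table
#'
#' A small hand-curated genus/family lookup shipped with the package
#' (a stand-in for a full external guild database, which is not bundled).
#'
#' @return a `guild_table`
#' @export
default_guild_table <- function() {
  read_guild_table(system.file("extdata", "guild_table_mini.tsv",
                               package = "miconet", mustWork = TRUE))
}

#' Assign fungal taxa to trophic guilds
#'
#' Looks each taxon up by its genus first, then by its family (the most
#' specific matching rank wins); unmatched taxa become `unassigned`.
#'
#' @param tax a [taxonomy_map()] with genus and/or family ranks
#' @param guilds a `guild_table` (default the bundled mini table)
#' @return data.frame (class `guild_assignment`): `taxon`, `trophic_mode`,
#'   `guild`, `confidence`, `matched_rank`
#' @export
assign_guilds <- function(tax, guilds = default_guild_table()) {
  if (!inherits(guilds, "guild_table") || nrow(guilds) == 0L)
    stop_fmt("empty or invalid guild table")
  gg <- guilds[guilds$rank == "genus", ]
  gf <- guilds[guilds$rank == "family", ]
  out <- data.frame(taxon = tax$taxon,
                    trophic_mode = "unassigned", guild = "unassigned",
                    confidence = NA_character_,
                    matched_rank = NA_character_,
                    stringsAsFactors = FALSE)
  mg <- match(tax$genus, gg$taxon)
  mf <- match(tax$family, gf$taxon)
  use_f <- is.na(mg) & !is.na(mf)
  use_g <- !is.na(mg)
  out$trophic_mode[use_g] <- gg$trophic_mode[mg[use_g]]
  out$guild[use_g] <- gg$guild[mg[use_g]]
  out$confidence[use_g] <- gg$confidence[mg[use_g]]
  out$matched_rank[use_g] <- "genus"
  out$trophic_mode[use_f] <- gf$trophic_mode[mf[use_f]]
  out$guild[use_f] <- gf$guild[mf[use_f]]
  out$confidence[use_f] <- gf$confidence[mf[use_f]]
  out$matched_rank[use_f] <- "family"
  class(out) <- c("guild_assignment", "data.frame")
  out
}

#' Per-sample relative abundance of potential pathogens
#'
#' Sums, per sample, the relative abundances of taxa whose trophic mode
#' includes `Pathotroph`, whose guild matches any pattern in `guild_filter`,
#' and whose assignment confidence is at least `min_confidence`.
#'
#' @param table a [count_table()]
#' @param assignment a `guild_assignment` from [assign_guilds()] covering
#'   the table's taxa
#' @param guild_filter character patterns matched against the guild label
#'   (default plant and animal pathogens)
#' @param min_confidence minimal confidence contributing to the sum
#'   (default `"Probable"`)
#' @return named numeric vector in `[0, 1]`, one value per sample
#' @export
pathogen_abundance <- function(table, assignment,
                               guild_filter = c("Plant Pathogen",
                                                "Animal Pathogen"),
                               min_confidence = "Probable") {
  miss <- setdiff(table$taxa, assignment$taxon)
  if (length(miss))
    stop_fmt("assignment does not cover taxon '%s'", miss[1L])
  a <- assignment[match(table$taxa, assignment$taxon), ]
  conf_ok <- !is.na(a$confidence) &
    confidence_levels[a$confidence] >= confidence_levels[[min_confidence]]
  guild_ok <- Reduce(`|`, lapply(guild_filter, function(g)
    grepl(g, a$guild, fixed = TRUE)), rep(FALSE, nrow(a)))
  sel <- grepl("Pathotroph", a$trophic_mode, fixed = TRUE) & guild_ok & conf_ok
  colSums(relative_abundance(table)[sel, , drop = FALSE])
}
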