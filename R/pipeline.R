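#' Pipeline configuration
#'
#' Collects every path, threshold and seed of the end-to-end pipeline
#' (generate -> diversity -> network -> guilds -> stats). When `counts`,
#' `taxonomy` or `design` are `NULL` the generate stage simulates a dataset
#' from [default_soil_profile()].
#'
#' @param out_dir output directory (created if needed)
#' @param counts,taxonomy,design optional input TSV paths
#' @param bacteria_filter,fungi_filter abundance filters for the network
#'   stage (defaults 0.1% and 0.001%)
#' @param score_threshold,p_threshold,hub_cutoff edge and hub gates
#' @param B association permutations; `n_perm` diversity-test permutations
#' @param network_group factor defining one network per level
#'   (`"ismb"`, `"fertilizer"` or `"habitat"`)
#' @param depth rarefaction depth (`NULL` = minimum library size)
#' @param seed master seed; stage seeds are derived from it
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, counts = NULL, taxonomy = NULL,
                            design = NULL, bacteria_filter = 0.001,
                            fungi_filter = 1e-5, score_threshold = 0.6,
                            p_threshold = 0.05, hub_cutoff = 0.2,
                            B = 1000L, n_perm = 999L,
                            network_group = "ismb", depth = NULL,
                            seed = 20170001L) {
  stopifnot(score_threshold >= 0, score_threshold < 1,
            p_threshold > 0, p_threshold <= 1,
            hub_cutoff >= 0, hub_cutoff <= 1,
            network_group %in% c("ismb", "fertilizer", "habitat"))
  structure(list(out_dir = out_dir, counts = counts, taxonomy = taxonomy,
                 design = design, bacteria_filter = bacteria_filter,
                 fungi_filter = fungi_filter,
                 score_threshold = score_threshold,
                 p_threshold = p_threshold, hub_cutoff = hub_cutoff,
                 B = as.integer(B), n_perm = as.integer(n_perm),
                 network_group = network_group, depth = depth,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages, writes all outputs under
#' `config$out_dir`, and records a manifest (package version, seeds,
#' thresholds and per-output MD5 checksums) in `manifest.json`. Reruns with
#' the same config reproduce identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param stages subset of
#'   `c("generate", "diversity", "network", "guilds", "stats")`
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config,
                         stages = c("generate", "diversity", "network",
                                    "guilds", "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  done <- character(0)
  pth <- function(...) file.path(config$out_dir, ...)
  emit <- function(p) outputs <<- c(outputs, p)

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e)
      stop_fmt("stage '%s' failed: %s (outputs so far are partial)",
               name, conditionMessage(e)))
    done <<- c(done, name)
    stage_log(name, sprintf("done in %.1fs",
                            as.numeric(Sys.time() - t0, units = "secs")))
  }

  ds <- NULL
  load_inputs <- function() {
    if (!is.null(ds)) return(ds)
    if (is.null(config$counts)) {
      stop_fmt("no input paths and generate stage not run")
    }
    list(counts = read_count_table(config$counts),
         taxonomy = read_taxonomy(config$taxonomy),
         design = read_sample_design(config$design))
  }

  run_stage("generate", function() {
    if (is.null(config$counts)) {
      ds <<- generate_dataset(default_soil_profile(), seed = config$seed)
    } else {
      ds <<- load_inputs()
      ds$truth <- NULL
    }
    emit(write_count_table(ds$counts, pth("counts.tsv")))
    emit(write_taxonomy(ds$taxonomy, pth("taxonomy.tsv")))
    emit(write_sample_design(ds$design, pth("design.tsv")))
    if (!is.null(ds$truth)) {
      emit(pth("truth_edges.tsv"))
      write.table(ds$truth$edges, pth("truth_edges.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  if (is.null(ds)) ds <- load_inputs()

  kingdom_tables <- function() {
    lapply(c(Bacteria = "Bacteria", Fungi = "Fungi"), function(kg)
      tryCatch(kingdom_subset(ds$counts, ds$taxonomy, kg),
               error = function(e) NULL))
  }

  run_stage("diversity", function() {
    kt <- kingdom_tables()
    for (kg in names(kt)) {
      if (is.null(kt[[kg]])) next
      tb <- kt[[kg]]
      depth <- config$depth %||% min(library_sizes(tb))
      al <- alpha_diversity(tb, depth = depth, seed = config$seed + 1L)
      emit(pth(sprintf("alpha_%s.tsv", tolower(kg))))
      write.table(al, pth(sprintf("alpha_%s.tsv", tolower(kg))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      d <- bray_curtis(tb)
      emit(pth(sprintf("braycurtis_%s.tsv", tolower(kg))))
      write.table(data.frame(sample = rownames(d), unclass(d),
                             check.names = FALSE),
                  pth(sprintf("braycurtis_%s.tsv", tolower(kg))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ord <- pcoa(d)
      emit(pth(sprintf("pcoa_%s.tsv", tolower(kg))))
      write.table(data.frame(sample = rownames(ord$coordinates),
                             ord$coordinates[, seq_len(min(3, ncol(ord$coordinates))),
                                             drop = FALSE]),
                  pth(sprintf("pcoa_%s.tsv", tolower(kg))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      nonnat <- ds$design$ismb != "native"
      dn <- distance_matrix(unclass(d)[nonnat, nonnat])
      rows <- list()
      for (f in c("ismb", "fertilizer", "habitat")) {
        g <- droplevels(ds$design[[f]][nonnat])
        pm <- permanova(dn, g, n_perm = config$n_perm, seed = config$seed + 2L)
        an <- anosim(dn, g, n_perm = config$n_perm, seed = config$seed + 3L)
        rows[[f]] <- data.frame(kingdom = kg, factor = f,
                                pseudo_f = pm$statistic, r_squared = pm$r_squared,
                                permanova_p = pm$p_value,
                                anosim_r = an$statistic, anosim_p = an$p_value)
      }
      emit(pth(sprintf("beta_tests_%s.tsv", tolower(kg))))
      write.table(do.call(rbind, rows),
                  pth(sprintf("beta_tests_%s.tsv", tolower(kg))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  run_stage("network", function() {
    kt <- kingdom_tables()
    topo <- list()
    lv <- setdiff(levels(droplevels(ds$design[[config$network_group]])), "native")
    for (kg in names(kt)) {
      if (is.null(kt[[kg]])) next
      filt <- if (kg == "Bacteria") config$bacteria_filter else config$fungi_filter
      for (l in lv) {
        sel <- ds$design$sample[ds$design[[config$network_group]] == l]
        tb <- count_table(kt[[kg]]$counts[, sel, drop = FALSE])
        res <- infer_network(tb, min_mean_rel_abund = filt, B = config$B,
                             seed = config$seed + 4L,
                             score_threshold = config$score_threshold,
                             p_threshold = config$p_threshold,
                             hub_cutoff = config$hub_cutoff)
        tag <- sprintf("%s_%s_%s", tolower(kg), config$network_group, l)
        emit(write_network_graphml(res$network, pth(paste0("network_", tag, ".graphml"))))
        if (nrow(res$network$nodes) >= 2)
          topo[[tag]] <- cbind(network = tag, topology(res$network))
      }
    }
    emit(pth("topology.tsv"))
    write.table(if (length(topo)) do.call(rbind, topo) else
                  data.frame(network = character(0)),
                pth("topology.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("guilds", function() {
    kt <- kingdom_tables()
    if (is.null(kt$Fungi)) return(invisible())
    assign <- assign_guilds(ds$taxonomy, default_guild_table())
    pa <- pathogen_abundance(kt$Fungi, assign)
    emit(pth("pathogen_abundance.tsv"))
    write.table(data.frame(sample = names(pa), pathogen_rel_abund = unname(pa)),
                pth("pathogen_abundance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  run_stage("stats", function() {
    kt <- kingdom_tables()
    rows <- list()
    for (kg in names(kt)) {
      if (is.null(kt[[kg]])) next
      al <- alpha_diversity(kt[[kg]], depth = NA, seed = config$seed)
      for (idx in c("chao1", "shannon")) {
        an <- factorial_anova(al[[idx]][match(ds$design$sample, al$sample)],
                              ds$design)
        rows[[paste(kg, idx)]] <- cbind(kingdom = kg, response = idx, an)
      }
    }
    covs <- setdiff(names(ds$design),
                    c("sample", "ismb", "fertilizer", "habitat", "replicate"))
    for (cv in covs) {
      an <- factorial_anova(cv, ds$design)
      rows[[paste("covariate", cv)]] <- cbind(kingdom = "covariate",
                                              response = cv, an)
    }
    emit(pth("anova.tsv"))
    write.table(do.call(rbind, rows), pth("anova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(covs) && !is.null(kt$Fungi)) {
      ra <- t(relative_abundance(kt$Fungi))
      scr <- correlation_screen(as.data.frame(ds$design)[, covs, drop = FALSE],
                                ra[ds$design$sample, , drop = FALSE],
                                method = "spearman")
      emit(pth("correlation_screen.tsv"))
      write.table(scr, pth("correlation_screen.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })

  manifest <- list(
    package = "miconet",
    version = as.character(utils::packageVersion("miconet")),
    seed = config$seed,
    thresholds = list(score = config$score_threshold, p = config$p_threshold,
                      hub = config$hub_cutoff,
                      bacteria_filter = config$bacteria_filter,
                      fungi_filter = config$fungi_filter),
    B = config$B, n_perm = config$n_perm,
    stages = done,
    checksums = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Parses `generate | diversity | network | guilds | stats | run-all`
#' subcommands with `--out-dir`, `--seed`, `--counts`, `--taxonomy`,
#' `--design`, `--b`, `--n-perm`, `--group` flags and dispatches to
#' [run_pipeline()]. Used by the `inst/cli/miconet.R` script.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status (0 on success)
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: miconet.R <generate|diversity|network|guilds|stats|run-all>",
    "--out-dir DIR [--seed N] [--counts F --taxonomy F --design F]",
    "[--b N] [--n-perm N] [--group ismb|fertilizer|habitat]")
  if (length(args) < 1L) { message(usage); return(1L) }
  cmd <- args[[1L]]
  known <- c("generate", "diversity", "network", "guilds", "stats", "run-all")
  if (!cmd %in% known) { message("unknown subcommand: ", cmd); return(1L) }
  opt <- list(`out-dir` = NULL, seed = "20170001", counts = NULL,
              taxonomy = NULL, design = NULL, b = "1000", `n-perm` = "999",
              group = "ismb")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt) || i == length(args)) {
      message("bad option: ", args[[i]]); return(1L)
    }
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  if (is.null(opt$`out-dir`)) { message(usage); return(1L) }
  cfg <- pipeline_config(out_dir = opt$`out-dir`, counts = opt$counts,
                         taxonomy = opt$taxonomy, design = opt$design,
                         B = as.integer(opt$b),
                         n_perm = as.integer(opt$`n-perm`),
                         network_group = opt$group,
                         seed = as.integer(opt$seed))
  stages <- if (cmd == "run-all") c("generate", "diversity", "network",
                                    "guilds", "stats")
            else unique(c(if (is.null(opt$counts)) "generate", cmd))
  status <- tryCatch({ run_pipeline(cfg, stages = stages); 0L },
                     error = function(e) { message(conditionMessage(e)); 1L })
  status
}
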