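# End-to-end orchestration: simulate or ingest inputs, call hits per screen,
# merge, map orthologs, build and augment networks in both species, and
# report the cross-species overlap. Every run writes a manifest (config,
# seed, per-file md5 checksums, stage counts) so identical config + seed
# gives an identical manifest.

#' Build a pipeline configuration
#'
#' All thresholds of the workflow live here: the hit-calling cutoff
#' (`alpha = 0.05`, raw p), the interaction-confidence threshold
#' (`min_conf = 0.900`, the "highest confidence" preset), the modifier
#' degree filter (`degree_k = 2`) and the ortholog consensus policy.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param alpha Hit-calling p-value cutoff in (0, 1].
#' @param min_conf Edge-confidence threshold in [0, 1].
#' @param degree_k Minimum within-hit-network degree for the filtered view.
#' @param policy Ortholog policy, `"union"` or `"majority"`.
#' @param replicate_exclusion Apply CV replicate exclusion before scoring?
#' @param day Imaging day passed to [collect_measurements()] (`NULL` = the
#'   single day present).
#' @param simulate List of arguments for the input generators (see
#'   [screen_sim_config()]); used when no input paths are given.
#' @param paths Named list of input file paths (`colony_wt`, `colony_mut`,
#'   `strain_map_wt`, `strain_map_mut`, `pombe_edges`, `human_edges`,
#'   `orthologs`) to ingest instead of simulating. Simulation fills any
#'   that are missing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, min_conf = 0.900,
                            degree_k = 2L, policy = c("union", "majority"),
                            replicate_exclusion = FALSE, day = NULL,
                            simulate = list(), paths = list()) {
  policy <- match.arg(policy)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (min_conf < 0 || min_conf > 1) stop("min_conf must be in [0, 1]")
  if (degree_k < 0) stop("degree_k must be non-negative")
  structure(list(seed = as.integer(seed), alpha = alpha, min_conf = min_conf,
                 degree_k = as.integer(degree_k), policy = policy,
                 replicate_exclusion = isTRUE(replicate_exclusion), day = day,
                 simulate = simulate, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema is flat and mirrors the arguments of
#' [pipeline_config()]; `simulate:` and `paths:` are nested maps.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "alpha", "min_conf", "degree_k", "policy",
             "replicate_exclusion", "day", "simulate", "paths")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

.stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stages: (1) simulate or ingest inputs; (2) normalize, score and call hits
#' for the wt and mut screens; (3) merge into the unique modifier set;
#' (4) map orthologs and report coverage; (5) build the yeast primary,
#' degree-filtered and neighbor-extended networks plus the human primary
#' network, apply orphan rescue, export graphs; (6) cross-species overlap.
#' Any stage failure halts with the stage name. Gene/node/edge counts are
#' logged at stage boundaries and recorded in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- "inputs"
  res <- tryCatch({
    inp <- .pipeline_inputs(config, out_dir)
    counts$n_genes_wt <- length(unique(inp$wt$strain_map$gene_id))
    counts$n_genes_mut <- length(unique(inp$mut$strain_map$gene_id))
    .stage_msg(stage, "wt: %d genes, mut: %d genes",
               counts$n_genes_wt, counts$n_genes_mut)

    stage <- "call-hits"
    hits_by_screen <- list()
    for (scr in c("wt", "mut")) {
      meas <- collect_measurements(inp[[scr]]$grids, inp[[scr]]$strain_map,
                                   day = config$day, screen = scr)
      scores <- score_screen(meas,
                             replicate_exclusion = config$replicate_exclusion)
      write_scores(scores, file.path(out_dir, paste0("scores_", scr, ".tsv")))
      ht <- call_hits(scores, alpha = config$alpha)
      write_hit_table(ht, file.path(out_dir, paste0("hits_", scr, ".tsv")))
      hits_by_screen[[scr]] <- ht
      counts[[paste0("n_hits_", scr)]] <- nrow(ht)
      .stage_msg(stage, "%s screen: %d hits (SL %d, SS %d)", scr, nrow(ht),
                 sum(ht$category == "SL"), sum(ht$category == "SS"))
    }

    stage <- "merge"
    modifiers <- merge_hit_tables(hits_by_screen$wt, hits_by_screen$mut)
    writeLines(modifiers, file.path(out_dir, "modifiers.txt"))
    counts$n_modifiers <- length(modifiers)
    .stage_msg(stage, "%d unique modifiers", length(modifiers))

    stage <- "map-orthologs"
    tables <- inp$ortholog_tables
    frac <- if (length(modifiers))
      ortholog_fraction(modifiers, tables, config$policy)
    else list(count_mapped = 0L, percent = NA_real_)
    human_hits <- humanize(modifiers, tables, config$policy)
    writeLines(human_hits, file.path(out_dir, "human_hits.txt"))
    counts$n_mapped <- frac$count_mapped
    counts$percent_mapped <- frac$percent
    .stage_msg(stage, "%d of %d modifiers orthologous (%.1f%%); %d human symbols",
               frac$count_mapped, length(modifiers),
               ifelse(is.na(frac$percent), 0, frac$percent), length(human_hits))

    stage <- "network"
    pombe_full <- load_edges(inp$paths$pombe_edges, min_conf = config$min_conf,
                             species = "pombe")
    human_full <- load_edges(inp$paths$human_edges, min_conf = config$min_conf,
                             species = "human")
    pombe_primary <- primary_network(modifiers, pombe_full)
    pombe_filtered <- degree_filter(modifiers, pombe_full, k = config$degree_k)
    pombe_extended <- extend_with_neighbors(modifiers, pombe_full)
    rescued <- rescue_orphans(modifiers, pombe_primary, pombe_extended)
    human_primary <- primary_network(human_hits, human_full)
    human_filtered <- degree_filter(human_hits, human_full, k = config$degree_k)
    export_graph(pombe_primary, file.path(out_dir, "pombe_primary.graphml"), "GraphML")
    export_graph(pombe_extended, file.path(out_dir, "pombe_extended.graphml"), "GraphML")
    export_graph(human_primary, file.path(out_dir, "human_primary.graphml"), "GraphML")
    export_graph(pombe_extended, file.path(out_dir, "pombe_extended.sif"), "SIF")
    .write_cluster_report(clusters(pombe_extended),
                          file.path(out_dir, "pombe_extended_clusters.tsv"))
    .write_cluster_report(clusters(human_primary),
                          file.path(out_dir, "human_primary_clusters.tsv"))
    .write_rescue_report(rescued, file.path(out_dir, "rescued.tsv"))
    counts$n_pombe_clusters <- length(clusters(pombe_primary))
    counts$n_pombe_clusters_filtered <- length(clusters(pombe_filtered))
    counts$n_human_clusters <- length(clusters(human_primary))
    counts$n_human_clusters_filtered <- length(clusters(human_filtered))
    counts$n_rescued <- length(rescued)
    .stage_msg(stage,
               "pombe clusters %d (degree>=%d: %d); human clusters %d (degree>=%d: %d); %d rescued nodes",
               counts$n_pombe_clusters, config$degree_k,
               counts$n_pombe_clusters_filtered, counts$n_human_clusters,
               config$degree_k, counts$n_human_clusters_filtered,
               counts$n_rescued)

    stage <- "overlap"
    overlap <- cross_species_overlap(pombe_extended, human_primary, tables,
                                     policy = config$policy,
                                     rescued = names(rescued))
    write.table(as.data.frame(overlap), file.path(out_dir, "overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$n_overlap <- nrow(overlap)
    .stage_msg(stage, "%d shared human symbols", nrow(overlap))
    list(overlap = overlap, rescued = rescued, counts = counts)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    config = unclass(config)[c("seed", "alpha", "min_conf", "degree_k",
                               "policy", "replicate_exclusion")],
    counts = res$counts, checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Resolve inputs: anything not supplied as a path is simulated into out_dir,
# then *read back* through the standard readers so simulated and ingested
# runs exercise the same code path.
.pipeline_inputs <- function(config, out_dir) {
  p <- config$paths
  sim <- config$simulate
  sim_dir <- file.path(out_dir, "inputs")
  dir.create(sim_dir, showWarnings = FALSE)
  need_screen <- is.null(p$colony_wt) || is.null(p$colony_mut)
  if (need_screen) {
    sim_args <- sim[setdiff(names(sim), c("n_ppi_nodes", "frac_mapped"))]
    for (scr in c("wt", "mut")) {
      args <- sim_args
      args$seed <- config$seed + if (scr == "wt") 101L else 202L
      if (scr == "mut" && is.null(args$global_induction_cost))
        args$global_induction_cost <- 1  # the mutant query carries no growth cost
      sc <- do.call(screen_sim_config, args)
      out <- simulate_screen(sc, screen = scr)
      p[[paste0("colony_", scr)]] <-
        write_colony_table(out$grids, file.path(sim_dir, paste0("colony_", scr, ".csv")))
      p[[paste0("strain_map_", scr)]] <-
        write_strain_map(out$strain_map, file.path(sim_dir, paste0("strain_map_", scr, ".tsv")))
    }
  }
  wt_map <- read_strain_map(p$strain_map_wt, query = "wt")
  mut_map <- read_strain_map(p$strain_map_mut, query = "mut")
  genes <- sort(unique(c(wt_map$gene_id, mut_map$gene_id)))
  if (is.null(p$pombe_edges)) {
    n_nodes <- length(genes)
    ed <- simulate_ppi(n_nodes, frac_above_threshold = 0.05,
                       seed = config$seed + 303L)
    # relabel generator nodes into the screen's gene namespace
    lut <- setNames(genes, sprintf("N%04d", seq_len(n_nodes)))
    ed$geneA <- unname(lut[ed$geneA]); ed$geneB <- unname(lut[ed$geneB])
    p$pombe_edges <- write_edge_table(ed, file.path(sim_dir, "pombe_edges.tsv"))
  }
  if (is.null(p$orthologs)) {
    tabs <- simulate_orthologs(genes, seed = config$seed + 404L)
    p$orthologs <- write_ortholog_tables(tabs, file.path(sim_dir, "orthologs.tsv"))
  }
  tables <- read_ortholog_tables(p$orthologs)
  if (is.null(p$human_edges)) {
    truth <- do.call(rbind, lapply(tables, function(t)
      data.frame(sym = unlist(t$map, use.names = FALSE))))
    syms <- sort(unique(truth$sym))
    ed <- simulate_ppi(length(syms), frac_above_threshold = 0.05,
                       seed = config$seed + 505L)
    lut <- setNames(syms, sprintf("N%04d", seq_along(syms)))
    ed$geneA <- unname(lut[ed$geneA]); ed$geneB <- unname(lut[ed$geneB])
    p$human_edges <- write_edge_table(ed, file.path(sim_dir, "human_edges.tsv"))
  }
  list(
    wt = list(grids = read_colony_table(p$colony_wt), strain_map = wt_map),
    mut = list(grids = read_colony_table(p$colony_mut), strain_map = mut_map),
    ortholog_tables = tables,
    paths = p)
}

.write_cluster_report <- function(cls, path) {
  rows <- lapply(seq_along(cls), function(i)
    data.frame(cluster_id = i, member = cls[[i]]$members,
               role = unname(cls[[i]]$roles), stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), member = character(0), role = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_rescue_report <- function(rescued, path) {
  df <- if (length(rescued))
    data.frame(rescued_node = names(rescued),
               orphans = vapply(rescued, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  else data.frame(rescued_node = character(0), orphans = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
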