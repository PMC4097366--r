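# Seeded generators for every pipeline input.
#
# Each generator is a pure function of its configuration and seed: the RNG
# state is saved and restored, so generators neither depend on nor perturb
# the caller's random stream, and identical seeds give bit-identical output.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Configuration for the colony-screen simulator
#'
#' Sizes are built multiplicatively:
#' `base 200 x plate_effect x gradient(row, col) x condition_factor x
#'  gene_effect x exp(N(0, noise_sigma^2))`.
#' The condition factor applies the genome-wide growth cost of inducing the
#' query gene to every strain on inducing plates; planted SL/SS genes get an
#' additional multiplier on inducing plates only. Log-normal noise makes the
#' log growth ratio exactly normal under the null.
#'
#' @param n_genes Number of deletion strains (each occupies a quadruplicate
#'   2x2 block; 384 genes fill one 1536-format plate).
#' @param planted_sl,planted_ss Disjoint sets of gene IDs (from the generated
#'   `G%04d` namespace) carrying true effects.
#' @param effect_multiplier_sl Inducing-condition size multiplier for SL
#'   genes, in (0,1); default 0.5 (a 50% growth reduction).
#' @param effect_multiplier_ss Multiplier for SS genes, > 1; default 1.5.
#' @param noise_sigma SD of log-normal colony noise on the natural-log scale
#'   (default 0.1).
#' @param plate_effect_sigma SD of the per-plate log-normal multiplicative
#'   effect, drawn independently per physical plate (default 0.15).
#' @param gradient_amplitude Amplitude of a linear row+column spatial trend
#'   across each plate (default 0.1, i.e. +/-10% corner to corner).
#' @param global_induction_cost Multiplier applied to *all* strains on
#'   inducing plates, in (0,1]; default 0.8.
#' @param day Imaging day recorded on the grids (default 3).
#' @param seed Integer seed.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 384L, planted_sl = character(0),
                              planted_ss = character(0),
                              effect_multiplier_sl = 0.5,
                              effect_multiplier_ss = 1.5,
                              noise_sigma = 0.1, plate_effect_sigma = 0.15,
                              gradient_amplitude = 0.1,
                              global_induction_cost = 0.8,
                              day = 3L, seed = 1L) {
  if (length(intersect(planted_sl, planted_ss)))
    stop("planted SL and SS sets must be disjoint")
  if (effect_multiplier_sl <= 0 || effect_multiplier_sl >= 1)
    stop("effect_multiplier_sl must lie in (0, 1)")
  if (effect_multiplier_ss <= 1) stop("effect_multiplier_ss must exceed 1")
  if (global_induction_cost <= 0 || global_induction_cost > 1)
    stop("global_induction_cost must lie in (0, 1]")
  if (noise_sigma < 0 || plate_effect_sigma < 0)
    stop("sigmas must be non-negative")
  structure(list(n_genes = as.integer(n_genes), planted_sl = planted_sl,
                 planted_ss = planted_ss,
                 effect_multiplier_sl = effect_multiplier_sl,
                 effect_multiplier_ss = effect_multiplier_ss,
                 noise_sigma = noise_sigma,
                 plate_effect_sigma = plate_effect_sigma,
                 gradient_amplitude = gradient_amplitude,
                 global_induction_cost = global_induction_cost,
                 day = as.integer(day), seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Gene IDs of the simulated deletion library
#' @param n_genes Number of genes.
#' @return Character vector `G0001 ... G<n>`.
#' @export
sim_gene_ids <- function(n_genes) sprintf("G%04d", seq_len(n_genes))

#' Simulate a quadruplicate 1536-format colony screen
#'
#' Lays `n_genes` deletion strains out in 2x2 quadruplicate blocks on as many
#' 1536-format plates as needed (384 genes per plate), then generates paired
#' inducing / non-inducing grids under the model described in
#' [screen_sim_config()]. Gradient and noise are drawn independently per
#' condition plate; plate effects are drawn per (plate, condition) since the
#' two conditions live on different physical plates.
#'
#' @param config A [screen_sim_config()].
#' @param screen Screen label for the strain map ("wt" or "mut").
#' @return A list: `grids` (colony grids for both conditions),
#'   `strain_map`, and `truth` (data frame `gene_id`, `category` in
#'   SL/SS/null, plus attribute `plate_effects`).
#' @export
simulate_screen <- function(config, screen = "wt") {
  stopifnot(inherits(config, "screen_sim_config"))
  n <- config$n_genes
  per_plate <- 384L
  n_plates <- ceiling(n / per_plate)
  if (n < 1L) stop("n_genes must be positive")
  genes <- sim_gene_ids(n)
  bad <- setdiff(c(config$planted_sl, config$planted_ss), genes)
  if (length(bad)) stop("planted gene(s) outside the library: ", paste(bad, collapse = ", "))

  idx <- seq_len(n) - 1L
  plate <- idx %/% per_plate + 1L
  block <- idx %% per_plate
  brow <- block %/% 24L + 1L
  bcol <- block %% 24L + 1L
  # quadruplicate 2x2 block per gene
  pos <- data.frame(
    plate = sprintf("P%02d", rep(plate, each = 4L)),
    row = as.vector(rbind(2L * brow - 1L, 2L * brow - 1L, 2L * brow, 2L * brow)),
    col = as.vector(rbind(2L * bcol - 1L, 2L * bcol, 2L * bcol - 1L, 2L * bcol)),
    gene_id = rep(genes, each = 4L), stringsAsFactors = FALSE)
  map <- strain_map(pos, query = if (screen == "wt") "wt" else "mut")

  effect <- setNames(rep(1, n), genes)
  effect[config$planted_sl] <- config$effect_multiplier_sl
  effect[config$planted_ss] <- config$effect_multiplier_ss
  category <- setNames(rep("null", n), genes)
  category[config$planted_sl] <- "SL"
  category[config$planted_ss] <- "SS"

  .with_seed(config$seed, {
    grids <- list()
    pe <- expand.grid(plate = sprintf("P%02d", seq_len(n_plates)),
                      condition = c("non_inducing", "inducing"),
                      stringsAsFactors = FALSE)
    pe$effect <- exp(rnorm(nrow(pe), 0, config$plate_effect_sigma))
    grad <- function(nr, nc)
      1 + config$gradient_amplitude *
        (outer((seq_len(nr) - 1) / (nr - 1), (seq_len(nc) - 1) / (nc - 1), `+`) - 1)
    for (i in seq_len(nrow(pe))) {
      p <- pe$plate[i]; cond <- pe$condition[i]
      m <- matrix(0, 32L, 48L)
      on_plate <- pos[pos$plate == p, ]
      ge <- effect[on_plate$gene_id]
      cond_factor <- if (cond == "inducing") config$global_induction_cost else 1
      gene_factor <- if (cond == "inducing") ge else rep(1, nrow(on_plate))
      mu <- 200 * pe$effect[i] *
        grad(32L, 48L)[cbind(on_plate$row, on_plate$col)] *
        cond_factor * gene_factor
      m[cbind(on_plate$row, on_plate$col)] <-
        mu * exp(rnorm(nrow(on_plate), 0, config$noise_sigma))
      grids[[length(grids) + 1L]] <- colony_grid(p, cond, config$day, m)
    }
    truth <- data.frame(gene_id = genes, category = unname(category),
                        stringsAsFactors = FALSE)
    attr(truth, "plate_effects") <- pe
    list(grids = grids, strain_map = map, truth = truth)
  })
}

#' Simulate a STRING-style weighted PPI edge list
#'
#' Generates a preferential-attachment random graph on `n_nodes` labelled
#' nodes, assigns each background edge a confidence score drawn above the
#' 0.900 threshold with probability `frac_above_threshold` (uniform in
#' 900-1000) and below it otherwise (uniform in 150-899), then plants the
#' given modules as cliques whose within-module edges all score >= 900.
#'
#' @param n_nodes Number of nodes (labelled `N0001 ...`).
#' @param attachment Edges added per node in the preferential-attachment
#'   process (default 2).
#' @param frac_above_threshold Probability a background edge scores >= 900.
#' @param planted_modules List of integer vectors of node indices in
#'   `1..n_nodes`; modules must be disjoint.
#' @param seed Integer seed.
#' @return Data frame `geneA`, `geneB`, `score` (integer 0-1000) with
#'   lexicographically ordered, deduplicated rows; write it with
#'   [write_edge_table()].
#' @export
simulate_ppi <- function(n_nodes, attachment = 2L, frac_above_threshold = 0.05,
                         planted_modules = list(), seed = 1L) {
  mod_nodes <- unlist(planted_modules)
  if (length(mod_nodes) && (any(mod_nodes < 1) || any(mod_nodes > n_nodes)))
    stop("planted module node outside 1..n_nodes")
  if (anyDuplicated(mod_nodes)) stop("planted modules must be disjoint")
  nm <- sprintf("N%04d", seq_len(n_nodes))
  .with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
    ed <- igraph::as_edgelist(g)
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    a <- pmin(ed[, 1], ed[, 2]); b <- pmax(ed[, 1], ed[, 2])
    key <- paste(a, b)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    above <- runif(length(a)) < frac_above_threshold
    score <- ifelse(above, sample(900:1000, length(a), replace = TRUE),
                    sample(150:899, length(a), replace = TRUE))
    df <- data.frame(a = a, b = b, score = score)
    for (mod in planted_modules) {
      if (length(mod) < 2) next
      prs <- utils::combn(sort(mod), 2)
      mdf <- data.frame(a = prs[1, ], b = prs[2, ],
                        score = sample(900:1000, ncol(prs), replace = TRUE))
      df <- df[!(paste(df$a, df$b) %in% paste(mdf$a, mdf$b)), ]
      df <- rbind(df, mdf)
    }
    out <- data.frame(geneA = nm[df$a], geneB = nm[df$b], score = as.integer(df$score))
    out <- out[order(out$geneA, out$geneB), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate multi-source ortholog tables
#'
#' Each gene is mapped with probability `frac_mapped` (default 0.838, a
#' realistic conserved-core coverage for fission yeast vs human); mapped
#' genes gain a second human symbol with probability `one_to_many_rate`.
#' Every mapped pair is guaranteed to appear in at least one source and
#' appears in each further source independently with probability
#' `1 - source_dropout`, emulating incomplete agreement between curated
#' databases.
#'
#' @param genes Character vector of yeast gene IDs.
#' @param frac_mapped Per-gene mapping probability.
#' @param one_to_many_rate Probability of a second symbol for a mapped gene.
#' @param n_sources Number of source tables (default 4).
#' @param source_dropout Per-source omission probability for a pair.
#' @param seed Integer seed.
#' @return A named list of [ortholog_table()] objects (`source1`, ...), with
#'   attribute `truth`: data frame `yeast_id`, `human_symbol` of all planted
#'   pairs.
#' @export
simulate_orthologs <- function(genes, frac_mapped = 0.838,
                               one_to_many_rate = 0.1, n_sources = 4L,
                               source_dropout = 0.2, seed = 1L) {
  stopifnot(frac_mapped >= 0, frac_mapped <= 1,
            one_to_many_rate >= 0, one_to_many_rate <= 1,
            source_dropout >= 0, source_dropout <= 1, n_sources >= 1)
  .with_seed(seed, {
    mapped <- runif(length(genes)) < frac_mapped
    pairs <- list()
    for (i in which(mapped)) {
      syms <- sprintf("HSY%04d", i)
      if (runif(1) < one_to_many_rate) syms <- c(syms, sprintf("HSY%04dB", i))
      pairs[[genes[i]]] <- syms
    }
    truth <- data.frame(
      yeast_id = rep(names(pairs), lengths(pairs)),
      human_symbol = unlist(pairs, use.names = FALSE),
      stringsAsFactors = FALSE)
    src_rows <- replicate(n_sources, list(yeast_id = character(0),
                                          human_symbol = character(0)),
                          simplify = FALSE)
    for (j in seq_len(nrow(truth))) {
      present <- runif(n_sources) < (1 - source_dropout)
      if (!any(present)) present[sample.int(n_sources, 1)] <- TRUE
      for (s in which(present)) {
        src_rows[[s]]$yeast_id <- c(src_rows[[s]]$yeast_id, truth$yeast_id[j])
        src_rows[[s]]$human_symbol <- c(src_rows[[s]]$human_symbol, truth$human_symbol[j])
      }
    }
    tabs <- lapply(seq_len(n_sources), function(s)
      ortholog_table(sprintf("source%d", s), as.data.frame(src_rows[[s]],
                                                           stringsAsFactors = FALSE)))
    names(tabs) <- vapply(tabs, `[[`, character(1), "source")
    attr(tabs, "truth") <- truth
    tabs
  })
}

#' Simulate embryo severity scores
#'
#' For each group and experiment, embryo categories are drawn from the
#' group's category-probability profile, and each embryo's abnormal-axon
#' count is drawn uniformly from the configured bin of its category (the
#' inverse of [classify_embryo()]).
#'
#' @param group_profiles Named list: group -> named probability vector over
#'   the severity categories (must sum to 1 within 1e-9).
#' @param n_experiments Experiments per group (default 4).
#' @param n_per_experiment Embryos per experiment (default 25).
#' @param bins Severity bins, see [default_severity_bins()].
#' @param seed Integer seed.
#' @return Data frame `embryo_id`, `group`, `experiment_id`,
#'   `n_abnormal_axons`, `true_category`.
#' @export
simulate_embryos <- function(group_profiles, n_experiments = 4L,
                             n_per_experiment = 25L,
                             bins = default_severity_bins(), seed = 1L) {
  .check_bins(bins)
  for (g in names(group_profiles)) {
    pr <- group_profiles[[g]]
    if (abs(sum(pr) - 1) > 1e-9) stop("profile for group ", g, " does not sum to 1")
    if (!all(names(pr) %in% names(bins)))
      stop("profile categories must be among: ", paste(names(bins), collapse = ", "))
  }
  .with_seed(seed, {
    rows <- list()
    for (g in names(group_profiles)) {
      pr <- group_profiles[[g]]
      for (e in seq_len(n_experiments)) {
        cat_draw <- sample(names(pr), n_per_experiment, replace = TRUE, prob = pr)
        n_ax <- vapply(cat_draw, function(cc) {
          b <- bins[[cc]]
          # sample() on a length-1 vector would sample 1:x; index explicitly
          as.integer(b[1] + sample.int(b[2] - b[1] + 1L, 1L) - 1L)
        }, integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          embryo_id = sprintf("%s_e%d_%02d", gsub("[^A-Za-z0-9]", "", g), e,
                              seq_len(n_per_experiment)),
          group = g, experiment_id = e, n_abnormal_axons = n_ax,
          true_category = cat_draw, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
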