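# Confidence-thresholded PPI subnetworks, neighbor augmentation, orphan
# rescue and cross-species overlap.
#
# Graph machinery is igraph; this file owns the screen-specific semantics:
# which nodes enter a graph, what "orphan" and "rescued" mean, and how the
# two species' networks are compared. Species-specific ID spaces never mix
# inside one graph — crossing happens only through humanize().

#' Construct a PPI network object
#'
#' @param graph An undirected simple `igraph` with vertex attribute `name`
#'   and edge attribute `confidence` in `[0, 1]`.
#' @param species `"pombe"` or `"human"`.
#' @param min_conf Confidence threshold the edges satisfy.
#' @param channel Evidence channel label (only `"experiments"` is used).
#' @return An object of class `ppi_network`.
#' @export
ppi_network <- function(graph, species = c("pombe", "human"),
                        min_conf = 0.900, channel = "experiments") {
  species <- match.arg(species)
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  if (igraph::ecount(graph) > 0) {
    conf <- igraph::E(graph)$confidence
    if (is.null(conf) || any(conf < min_conf - 1e-12) || any(conf > 1))
      stop("every edge must carry a confidence in [min_conf, 1]")
  }
  if (any(igraph::which_loop(graph))) stop("self-loops are not allowed")
  if (any(igraph::count_multiple(graph) > 1)) stop("duplicate edges are not allowed")
  structure(list(graph = graph, species = species,
                 min_conf = min_conf, channel = channel),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %s, %d nodes, %d edges, confidence >= %.3f (%s channel)\n",
              x$species, igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$min_conf, x$channel))
  invisible(x)
}

#' Node names of a PPI network
#' @param network A `ppi_network`.
#' @return Character vector of node IDs.
#' @export
network_nodes <- function(network) {
  igraph::V(network$graph)$name
}

#' Load a STRING-style edge list at a confidence threshold
#'
#' Reads a TSV of `geneA`, `geneB`, `score` with integer scores on the 0-1000
#' STRING convention (divided by 1000 on load). Symmetric duplicate edges are
#' collapsed keeping the maximum confidence; only edges with confidence
#' >= `min_conf` (inclusive, matching the "highest confidence (0.900)"
#' preset) are retained. Nodes only ever seen on sub-threshold edges are not
#' part of the returned network.
#'
#' @param path Edge TSV path.
#' @param min_conf Inclusive confidence threshold, default 0.900.
#' @param species Species tag for the resulting network.
#' @return A [ppi_network()].
#' @export
load_edges <- function(path, min_conf = 0.900, species = "pombe") {
  if (!file.exists(path)) stop("edge file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("geneA", "geneB", "score")
  if (!all(need %in% names(df)))
    stop("edge TSV must have header: ", paste(need, collapse = "\t"))
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1000)
  if (length(bad))
    stop(sprintf("score outside [0, 1000] at data line %d", bad[1]))
  df <- df[df$geneA != df$geneB, , drop = FALSE]   # drop self-loops
  a <- pmin(df$geneA, df$geneB); b <- pmax(df$geneA, df$geneB)
  conf <- tapply(df$score / 1000, paste(a, b, sep = "\r"), max)
  keep <- conf >= min_conf
  ends <- strsplit(names(conf)[keep], "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(ends, `[`, "", 1L),
                      to = vapply(ends, `[`, "", 2L),
                      confidence = as.numeric(conf[keep]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  ppi_network(g, species = species, min_conf = min_conf)
}

#' Write an edge list in the STRING-style TSV dialect
#' @param edges Data frame `geneA`, `geneB`, `score` (integer 0-1000).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(all(c("geneA", "geneB", "score") %in% names(edges)))
  write.table(edges[, c("geneA", "geneB", "score")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hit-induced primary network
#'
#' Induces the subgraph of `network` on the hit set. Hits absent from the
#' thresholded interaction data, or with no qualifying edge to another hit,
#' are retained as degree-0 nodes and flagged as *orphans* (vertex attribute
#' `role` is `"hit"` for all nodes; orphanhood is a degree property queried
#' by [rescue_orphans()]).
#'
#' @param hits Character vector of gene IDs.
#' @param network A whole-genome [ppi_network()] at threshold.
#' @return A `ppi_network` whose node set is exactly `hits`.
#' @export
primary_network <- function(hits, network) {
  stopifnot(inherits(network, "ppi_network"))
  hits <- sort(unique(hits))
  present <- intersect(hits, network_nodes(network))
  g <- igraph::induced_subgraph(network$graph, present)
  missing <- setdiff(hits, present)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  igraph::V(g)$role <- "hit"
  ppi_network(g, species = network$species, min_conf = network$min_conf,
              channel = network$channel)
}

#' Connected-component clusters of a network
#'
#' @param network A `ppi_network`.
#' @param min_size Minimum component size to report (default 2, so isolated
#'   nodes — orphans — are never clusters).
#' @return A list of `network_cluster` objects, sorted by size descending
#'   then by lexicographically smallest member; each has `members`, `roles`
#'   and `species`.
#' @export
clusters <- function(network, min_size = 2L) {
  stopifnot(inherits(network, "ppi_network"))
  comp <- igraph::components(network$graph)
  roles <- igraph::V(network$graph)$role
  if (is.null(roles)) roles <- rep("hit", igraph::vcount(network$graph))
  names(roles) <- network_nodes(network)
  out <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == k])
    if (length(members) < min_size) next
    out[[length(out) + 1L]] <- structure(
      list(members = members, roles = roles[members], species = network$species),
      class = "network_cluster")
  }
  sizes <- vapply(out, function(cl) length(cl$members), integer(1))
  first <- vapply(out, function(cl) cl$members[1], character(1))
  out[order(-sizes, first)]
}

#' @export
print.network_cluster <- function(x, ...) {
  cat(sprintf("<network_cluster> %s, %d members: %s\n", x$species,
              length(x$members), paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Filter hits by within-hit-network degree
#'
#' Keeps the modifiers that interact with at least `k` other modifiers:
#' degrees are measured once against the *unfiltered* hit-induced subgraph
#' and survivors are re-induced in a single pass. This is deliberately not an
#' iterative k-core — the selection criterion is "shares >= k interactions
#' with other screen hits", judged against the full hit set.
#'
#' @param hits Character vector of gene IDs.
#' @param network Whole-genome `ppi_network` (the hit-induced subgraph is
#'   built internally via [primary_network()]).
#' @param k Minimum degree, default 2; `k = 0` leaves the primary network
#'   unchanged.
#' @return A `ppi_network` on the surviving hits.
#' @export
degree_filter <- function(hits, network, k = 2L) {
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be a non-negative integer")
  primary <- primary_network(hits, network)
  if (k == 0) return(primary)
  deg <- igraph::degree(primary$graph)
  survivors <- names(deg)[deg >= k]
  g <- igraph::induced_subgraph(primary$graph, survivors)
  ppi_network(g, species = network$species, min_conf = network$min_conf,
              channel = network$channel)
}

#' Extend a hit set with first-degree neighbors
#'
#' Node set = hits plus every node of the whole-genome network adjacent to a
#' hit; edges are *all* qualifying edges among that node set (including
#' neighbor-neighbor edges). The rationale for augmentation: a true network
#' member may be missing from the screen because its deletion is inviable
#' (essential genes are absent from the deletion library) or for other
#' reasons, yet it can still connect hits. Vertex attribute `role` records
#' `"hit"` vs `"neighbor"`.
#'
#' @param hits Character vector of gene IDs.
#' @param full Whole-genome `ppi_network` at threshold.
#' @return A `ppi_network` containing all hits (even edgeless ones).
#' @export
extend_with_neighbors <- function(hits, full) {
  stopifnot(inherits(full, "ppi_network"))
  hits <- sort(unique(hits))
  present <- intersect(hits, network_nodes(full))
  nbrs <- character(0)
  if (length(present)) {
    adj <- igraph::adjacent_vertices(full$graph, present)
    nbrs <- unique(unlist(lapply(adj, function(v) v$name), use.names = FALSE))
  }
  node_set <- sort(unique(c(hits, nbrs)))
  g <- igraph::induced_subgraph(full$graph, intersect(node_set, network_nodes(full)))
  missing <- setdiff(node_set, network_nodes(full))
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  igraph::V(g)$role <- ifelse(igraph::V(g)$name %in% hits, "hit", "neighbor")
  ppi_network(g, species = full$species, min_conf = full$min_conf,
              channel = full$channel)
}

#' Rescue orphan hits through shared first-degree neighbors
#'
#' Orphans are hits with zero edges to other hits in the thresholded primary
#' network. A non-hit node of the extended network that is adjacent to at
#' least two orphans "rescues" them: it joins previously unmapped hits into a
#' cluster, and is itself promoted into the analysis as a new candidate.
#'
#' @param hits Character vector of gene IDs.
#' @param primary The hit-induced [primary_network()].
#' @param extended The [extend_with_neighbors()] network built from the same
#'   hit set and threshold.
#' @return A named list mapping each rescued node to the sorted character
#'   vector of orphans it rescues (empty list if none).
#' @export
rescue_orphans <- function(hits, primary, extended) {
  stopifnot(inherits(primary, "ppi_network"), inherits(extended, "ppi_network"))
  hits <- sort(unique(hits))
  if (!all(hits %in% network_nodes(primary)))
    stop("primary network does not cover the hit set")
  deg <- igraph::degree(primary$graph)
  orphans <- intersect(hits, names(deg)[deg == 0])
  if (length(orphans) == 0L) return(list())
  non_hits <- setdiff(network_nodes(extended), hits)
  out <- list()
  for (v in sort(non_hits)) {
    nb <- names(igraph::neighbors(extended$graph, v))
    saved <- sort(intersect(nb, orphans))
    if (length(saved) >= 2L) out[[v]] <- saved
  }
  out
}

#' Cross-species network overlap
#'
#' Humanizes every node of the (extended) yeast network through the ortholog
#' tables and intersects the resulting symbol set with the nodes of the human
#' primary network. Each shared symbol is reported with its yeast provenance:
#' which yeast gene(s) map to it and their role (`hit`, `rescued` or
#' `neighbor`) on the yeast side.
#'
#' @param pombe_extended Yeast `ppi_network` with a `role` vertex attribute.
#' @param human_primary Human `ppi_network`.
#' @param tables Ortholog tables (see [read_ortholog_tables()]).
#' @param policy Mapping policy, see [consensus_map()].
#' @param rescued Optional character vector of rescued node names (from
#'   [rescue_orphans()]); these report role `"rescued"` instead of
#'   `"neighbor"`.
#' @return An object of class `overlap_report`: data frame with columns
#'   `human_symbol`, `yeast_genes` (comma-joined), `yeast_roles`.
#' @export
cross_species_overlap <- function(pombe_extended, human_primary, tables,
                                  policy = "union", rescued = character(0)) {
  stopifnot(inherits(pombe_extended, "ppi_network"),
            inherits(human_primary, "ppi_network"))
  if (pombe_extended$species == human_primary$species)
    stop("overlap requires networks from two different species")
  ynodes <- network_nodes(pombe_extended)
  roles <- igraph::V(pombe_extended$graph)$role
  if (is.null(roles)) roles <- rep("hit", length(ynodes))
  roles[ynodes %in% rescued] <- "rescued"
  names(roles) <- ynodes
  hnodes <- network_nodes(human_primary)
  rows <- list()
  for (g in ynodes) {
    syms <- consensus_map(g, tables, policy)$human_symbols
    for (s in intersect(syms, hnodes)) {
      if (is.null(rows[[s]])) rows[[s]] <- character(0)
      rows[[s]] <- c(rows[[s]], g)
    }
  }
  shared <- sort(names(rows))
  df <- data.frame(
    human_symbol = shared,
    yeast_genes = vapply(shared, function(s) paste(sort(rows[[s]]), collapse = ","), ""),
    yeast_roles = vapply(shared, function(s)
      paste(roles[sort(rows[[s]])], collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("overlap_report", "data.frame"))
}

#' Export a network to SIF or GraphML
#'
#' SIF lines are `A pp B` with lexicographically ordered endpoints and rows;
#' GraphML carries node attributes `species` and `role` and the edge
#' attribute `confidence`. Output is deterministic: two exports of the same
#' network are byte-identical.
#'
#' @param network A `ppi_network`.
#' @param path Output file path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("SIF", "GraphML")) {
  stopifnot(inherits(network, "ppi_network"))
  format <- match.arg(format)
  g <- network$graph
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  if (is.null(igraph::V(g)$role)) igraph::V(g)$role <- "hit"
  igraph::V(g)$species <- network$species
  if (format == "SIF") {
    ed <- igraph::as_edgelist(g)
    lines <- character(0)
    if (nrow(ed)) {
      a <- pmin(ed[, 1], ed[, 2]); b <- pmax(ed[, 1], ed[, 2])
      lines <- sort(paste(a, "pp", b))
    }
    writeLines(lines, path)
  } else {
    ord <- igraph::V(g)$name
    ed <- igraph::as_edgelist(g)
    conf <- if (igraph::ecount(g)) igraph::E(g)$confidence else numeric(0)
    eord <- if (nrow(ed)) order(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])) else integer(0)
    con <- file(path, open = "wt")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="species" for="node" attr.name="species" attr.type="string"/>')
    w('  <key id="role" for="node" attr.name="role" attr.type="string"/>')
    w('  <key id="confidence" for="edge" attr.name="confidence" attr.type="double"/>')
    w('  <graph id="G" edgedefault="undirected">')
    for (i in seq_along(ord)) {
      w('    <node id="%s"><data key="species">%s</data><data key="role">%s</data></node>',
        ord[i], igraph::V(g)$species[i], igraph::V(g)$role[i])
    }
    for (i in eord) {
      w('    <edge source="%s" target="%s"><data key="confidence">%.17g</data></edge>',
        min(ed[i, 1], ed[i, 2]), max(ed[i, 1], ed[i, 2]), conf[i])
    }
    w('  </graph>')
    w('</graphml>')
  }
  invisible(path)
}

#' Import a GraphML file written by [export_graph()]
#'
#' @param path GraphML file path.
#' @param min_conf Confidence threshold recorded on the result.
#' @return A `ppi_network`.
#' @export
import_graphml <- function(path, min_conf = 0.900) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- igraph::V(g)$id
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  species <- unique(igraph::V(g)$species)
  if (length(species) == 0L) species <- "pombe"
  ppi_network(igraph::as_undirected(g, mode = "collapse"),
              species = species[1], min_conf = min_conf)
}
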