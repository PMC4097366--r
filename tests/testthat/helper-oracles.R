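# Shared fixtures and independent oracles for the network tests.

# Build a ppi_network from an in-memory edge data frame (geneA, geneB, score)
# through the standard TSV reader, so tests exercise the real load path.
make_net <- function(edges, min_conf = 0.900, species = "pombe") {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_edge_table(edges, f)
  load_edges(f, min_conf = min_conf, species = species)
}

edge_df <- function(a, b, score) {
  data.frame(geneA = a, geneB = b, score = as.integer(score),
             stringsAsFactors = FALSE)
}

# Brute-force orphan-rescue oracle: plain loops over an explicit edge list,
# no graph library. `edges` is a two-column character matrix of the
# *thresholded* edges of the full network.
brute_rescue <- function(hits, edges) {
  adj_of <- function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  }
  orphans <- character(0)
  for (h in hits) {
    if (!any(adj_of(h) %in% hits)) orphans <- c(orphans, h)
  }
  extended_nodes <- unique(c(hits, unlist(lapply(hits, adj_of))))
  out <- list()
  for (v in sort(setdiff(extended_nodes, hits))) {
    saved <- sort(intersect(adj_of(v), orphans))
    if (length(saved) >= 2) out[[v]] <- saved
  }
  out
}

sort_rescue <- function(x) if (length(x)) x[order(names(x))] else list()

# Union-find connected-components oracle (independent of igraph).
brute_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, character(1)))
}

# Random test instance: n nodes, each possible edge present with prob p_edge
# and scored above threshold with prob p_conf; a random subset are hits.
random_instance <- function(n, seed) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  prs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(prs)) < 0.25
  prs <- prs[keep, , drop = FALSE]
  hits <- sample(nodes, max(2, rbinom(1, n, 0.4)))
  list(nodes = nodes, edges = prs, hits = sort(hits))
}
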