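test_that("edge loading thresholds inclusively and collapses duplicates", {
  net <- make_net(edge_df(c("A", "B", "C"), c("B", "A", "D"), c(950, 920, 900)))
  # A-B and B-A collapse keeping max; C-D sits exactly on the threshold
  expect_setequal(network_nodes(net), c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(net$graph), 2L)
  eid <- igraph::get_edge_ids(net$graph, c("A", "B"))
  expect_equal(igraph::E(net$graph)$confidence[eid], 0.95)
  sub <- make_net(edge_df("A", "B", 899))
  expect_equal(igraph::ecount(sub$graph), 0L)
  expect_error(make_net(edge_df("A", "B", 1500)), "outside")
})

test_that("raising the confidence threshold never adds an edge", {
  set.seed(8)
  ed <- edge_df(sprintf("n%02d", sample(20, 60, TRUE)),
                sprintf("n%02d", sample(20, 60, TRUE)),
                sample(0:1000, 60, TRUE))
  ed <- ed[ed$geneA != ed$geneB, ]
  sif_edges <- function(net) {
    if (igraph::ecount(net$graph) == 0) return(character(0))
    el <- igraph::as_edgelist(net$graph)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  prev <- NULL
  for (t in c(0.3, 0.6, 0.9)) {
    cur <- sif_edges(make_net(ed, min_conf = t))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the primary network induces on hits and keeps orphans", {
  full <- make_net(edge_df(c("A", "B", "E"), c("B", "C", "F"), c(950, 930, 960)))
  prim <- primary_network(c("A", "B", "C", "D"), full)
  expect_setequal(network_nodes(prim), c("A", "B", "C", "D"))
  expect_equal(igraph::degree(prim$graph)[["D"]], 0)
  cl <- clusters(prim)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("A", "B", "C"))
  # hits with no qualifying edges at all: edgeless network, all orphans
  lonely <- primary_network(c("X", "Y"), full)
  expect_equal(igraph::ecount(lonely$graph), 0L)
  expect_setequal(network_nodes(lonely), c("X", "Y"))
  # induced subgraph of an induced subgraph is the same induced subgraph
  again <- primary_network(c("A", "B", "C", "D"), prim)
  expect_equal(igraph::ecount(again$graph), igraph::ecount(prim$graph))
  expect_setequal(network_nodes(again), network_nodes(prim))
})

test_that("clusters are connected components above the size threshold", {
  net <- make_net(edge_df(c("a", "b", "d", "f"), c("b", "c", "e", "g"),
                          c(950, 950, 950, 950)))
  prim <- primary_network(c("a", "b", "c", "d", "e", "f", "g"), net)
  cl <- clusters(prim)
  expect_length(cl, 3L)
  expect_equal(vapply(cl, function(x) length(x$members), integer(1)), c(3L, 2L, 2L))
  expect_equal(cl[[1]]$members, c("a", "b", "c"))
  # matches a union-find oracle
  oracle <- brute_components(network_nodes(prim),
                             igraph::as_edgelist(prim$graph))
  oracle <- Filter(function(x) length(x) >= 2, oracle)
  expect_setequal(vapply(cl, function(x) paste(x$members, collapse = "+"), ""),
                  vapply(oracle, function(x) paste(sort(unname(x)), collapse = "+"), ""))
  # edgeless graph: nothing at min_size 2; cluster + orphan sizes partition nodes
  edgeless <- primary_network(c("x", "y"), net)
  expect_length(clusters(edgeless), 0L)
  deg <- igraph::degree(prim$graph)
  expect_equal(sum(vapply(cl, function(x) length(x$members), integer(1))) +
                 sum(deg == 0), length(network_nodes(prim)))
})

test_that("the degree filter is one pass, not an iterative core", {
  full <- make_net(edge_df(c("A", "B"), c("B", "C"), c(950, 950)))
  # path A-B-C with k=2: only B passes the degree test, leaving an edgeless graph
  filt <- degree_filter(c("A", "B", "C"), full, k = 2)
  expect_equal(network_nodes(filt), "B")
  expect_length(clusters(filt), 0L)
  tri <- make_net(edge_df(c("A", "B", "C"), c("B", "C", "A"), c(950, 950, 950)))
  filt2 <- degree_filter(c("A", "B", "C"), tri, k = 2)
  expect_setequal(network_nodes(filt2), c("A", "B", "C"))
  expect_length(clusters(filt2), 1L)
  # k = 0 leaves the primary network unchanged
  filt0 <- degree_filter(c("A", "B", "C", "D"), full, k = 0)
  expect_setequal(network_nodes(filt0), c("A", "B", "C", "D"))
  expect_error(degree_filter(c("A"), full, k = -1), "non-negative")
})

test_that("neighbor extension includes all qualifying edges among the node set", {
  full <- make_net(edge_df(c("A", "N", "D", "Q"), c("N", "D", "E", "R"),
                           c(950, 930, 940, 970)))
  ext <- extend_with_neighbors(c("A", "D"), full)
  expect_setequal(network_nodes(ext), c("A", "D", "N", "E"))
  expect_equal(igraph::ecount(ext$graph), 3L)
  roles <- setNames(igraph::V(ext$graph)$role, network_nodes(ext))
  expect_equal(roles[["A"]], "hit")
  expect_equal(roles[["N"]], "neighbor")
  # a hit with no neighbors still appears
  ext2 <- extend_with_neighbors(c("A", "Z"), full)
  expect_true(all(c("A", "Z") %in% network_nodes(ext2)))
})

test_that("orphan rescue finds non-hits adjacent to at least two orphans", {
  full <- make_net(edge_df(c("A", "N", "D", "A2"), c("N", "D", "E", "B2"),
                           c(950, 930, 940, 950)))
  hits <- c("A", "D", "A2", "B2")
  prim <- primary_network(hits, full)
  ext <- extend_with_neighbors(hits, full)
  res <- rescue_orphans(hits, prim, ext)
  # A and D are orphans (A2-B2 interact, so they are not); N touches both
  expect_equal(names(res), "N")
  expect_equal(res$N, c("A", "D"))
  # no orphans -> empty result
  res2 <- rescue_orphans(c("A2", "B2"),
                         primary_network(c("A2", "B2"), full),
                         extend_with_neighbors(c("A2", "B2"), full))
  expect_length(res2, 0L)
})

test_that("orphan rescue agrees with brute-force enumeration on random graphs", {
  for (seed in 1:40) {
    inst <- random_instance(n = 5L + (seed %% 8L), seed = seed)
    ed <- edge_df(inst$edges[, 1], inst$edges[, 2],
                  rep(950, nrow(inst$edges)))
    if (nrow(ed) == 0) next
    full <- make_net(ed)
    prim <- primary_network(inst$hits, full)
    ext <- extend_with_neighbors(inst$hits, full)
    got <- rescue_orphans(inst$hits, prim, ext)
    want <- brute_rescue(inst$hits, inst$edges)
    expect_equal(sort_rescue(got), sort_rescue(want),
                 info = paste("seed", seed))
  }
})

test_that("cross-species overlap intersects humanized yeast nodes with human nodes", {
  tabs <- list(ortholog_table("db", data.frame(
    yeast_id = c("y1", "y2", "nb"), human_symbol = c("CUL3", "GSK3B", "COPS5"))))
  yeast_full <- make_net(edge_df(c("y1", "y3"), c("nb", "nb"), c(950, 930)))
  ext <- extend_with_neighbors(c("y1", "y2", "y3"), yeast_full)
  human <- make_net(edge_df("CUL3", "COPS5", 950), species = "human")
  hum_prim <- primary_network(c("CUL3", "COPS5"), human)
  rep <- cross_species_overlap(ext, hum_prim, tabs, rescued = "nb")
  expect_setequal(rep$human_symbol, c("CUL3", "COPS5"))
  expect_equal(rep$yeast_genes[rep$human_symbol == "CUL3"], "y1")
  expect_equal(rep$yeast_roles[rep$human_symbol == "COPS5"], "rescued")
  expect_true(all(rep$human_symbol %in% network_nodes(hum_prim)))
  # empty ortholog table -> empty overlap
  none <- cross_species_overlap(ext, hum_prim,
    list(ortholog_table("e", data.frame(yeast_id = character(0),
                                        human_symbol = character(0)))))
  expect_equal(nrow(none), 0L)
  expect_error(cross_species_overlap(ext, ext, tabs), "different species")
})

test_that("graph exports are deterministic and GraphML round-trips", {
  net <- make_net(edge_df(c("b", "a", "c"), c("a", "c", "d"), c(950, 930, 920)))
  prim <- primary_network(c("a", "b", "c", "d", "e"), net)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(prim, sif, "SIF")
  expect_equal(readLines(sif), c("a pp b", "a pp c", "c pp d"))
  gml1 <- withr::local_tempfile(fileext = ".graphml")
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(prim, gml1, "GraphML")
  export_graph(prim, gml2, "GraphML")
  expect_identical(readLines(gml1), readLines(gml2))
  back <- import_graphml(gml1)
  expect_equal(network_nodes(back), network_nodes(prim))
  expect_equal(igraph::as_edgelist(back$graph), igraph::as_edgelist(prim$graph))
  expect_equal(igraph::E(back$graph)$confidence, igraph::E(prim$graph)$confidence)
  # empty network exports a valid (empty) document
  empty <- primary_network(character(0), net)
  sif0 <- withr::local_tempfile(fileext = ".sif")
  export_graph(empty, sif0, "SIF")
  expect_equal(readLines(sif0), character(0))
  expect_error(export_graph(prim, sif, "DOT"), "arg")
})
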