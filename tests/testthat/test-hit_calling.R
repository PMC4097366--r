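# Helper: build a gene_measurements frame directly from per-gene replicate
# vectors (bypassing grids) for focused scoring tests.
meas_df <- function(ind, non, screen = "wt") {
  out <- data.frame(gene_id = names(ind), screen = screen,
                    stringsAsFactors = FALSE)
  out$sizes_inducing <- unname(ind)
  out$sizes_non_inducing <- unname(non)
  class(out) <- c("gene_measurements", "data.frame")
  out
}

# Null measurements: n genes, 4 replicates per condition, multiplicative
# log-normal noise, optional per-gene inducing multiplier.
null_meas <- function(n, sigma = 0.1, multiplier = rep(1, n), seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n))
  ind <- lapply(seq_len(n), function(i)
    multiplier[i] * exp(rnorm(4, 0, sigma)))
  non <- lapply(seq_len(n), function(i) exp(rnorm(4, 0, sigma)))
  meas_df(setNames(ind, ids), setNames(non, ids))
}

test_that("plate-median normalization rescales nonzero sizes and is idempotent", {
  g <- colony_grid("P1", "inducing", 1, matrix(200, 16, 24))
  expect_true(all(normalize_grid(g)$sizes == 1))
  m <- matrix(0, 16, 24); m[1, 1:4] <- c(100, 200, 300, 0)
  g2 <- normalize_grid(colony_grid("P1", "inducing", 1, m))
  expect_equal(g2$sizes[1, 1:4], c(0.5, 1.0, 1.5, 0))
  expect_equal(normalize_grid(g2)$sizes, g2$sizes)
  expect_equal(median(g2$sizes[g2$sizes > 0]), 1)
  expect_error(normalize_grid(colony_grid("P0", "inducing", 1, matrix(0, 16, 24))),
               "all-zero")
})

test_that("CV replicate exclusion removes at most one aberrant value", {
  expect_equal(exclude_replicates(c(1, 1, 1, 1)), c(1, 1, 1, 1))
  expect_equal(exclude_replicates(c(1.0, 1.1, 0.9, 3.0)), c(1.0, 1.1, 0.9))
  # no single removal reaches CV < 0.35: everything retained
  expect_equal(exclude_replicates(c(1, 3, 5, 7)), c(1, 3, 5, 7))
  # fewer than 3 values: untouched
  expect_equal(exclude_replicates(c(0.1, 9)), c(0.1, 9))
})

test_that("log growth ratio has the closed form and is antisymmetric", {
  expect_equal(log_growth_ratio(1, 1), 0)
  expect_equal(log_growth_ratio(1, 0.5), log(2))
  for (pair in list(c(0.3, 1.7), c(2, 5), c(1, 4))) {
    expect_equal(log_growth_ratio(pair[1], pair[2]),
                 -log_growth_ratio(pair[2], pair[1]))
  }
  expect_error(log_growth_ratio(0, 1), "positive")
})

test_that("screen scoring standardizes against the population", {
  m <- null_meas(200, seed = 11)
  sc <- score_screen(m)
  expect_equal(mean(sc$z), 0, tolerance = 1e-12)
  expect_equal(sd(sc$z), 1, tolerance = 1e-12)
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  # a strong planted gene sits far in the tail on the SL side
  m2 <- null_meas(200, multiplier = c(0.3, rep(1, 199)), seed = 12)
  sc2 <- score_screen(m2)
  top <- sc2[sc2$gene_id == "g0001", ]
  expect_lt(top$p, 1e-5)
  expect_gt(top$z, 0)
})

test_that("degenerate screens are rejected", {
  m <- meas_df(setNames(rep(list(c(1, 1, 1, 1)), 25), sprintf("g%02d", 1:25)),
               setNames(rep(list(c(1, 1, 1, 1)), 25), sprintf("g%02d", 1:25)))
  expect_error(score_screen(m), "zero population SD")
  expect_error(score_screen(null_meas(10)), "fewer than 20")
})

test_that("zero-size genes are capped or dropped, never infinite", {
  set.seed(2)
  ind <- setNames(lapply(1:30, function(i) exp(rnorm(4, 0, 0.05))), sprintf("g%02d", 1:30))
  non <- setNames(lapply(1:30, function(i) exp(rnorm(4, 0, 0.05))), sprintf("g%02d", 1:30))
  ind[["g01"]] <- numeric(0)        # dead only when induced -> capped SL candidate
  ind[["g02"]] <- numeric(0)
  non[["g02"]] <- numeric(0)        # dead in both -> dropped
  non[["g03"]] <- 1.1               # single replicate -> dropped, low support
  sc <- score_screen(meas_df(ind, non))
  expect_true(all(is.finite(sc$lgr)))
  expect_false("g02" %in% sc$gene_id)
  expect_false("g03" %in% sc$gene_id)
  expect_named(attr(sc, "dropped"))
  g1 <- sc[sc$gene_id == "g01", ]
  expect_true(g1$flagged)
  expect_equal(g1$lgr, max(sc$lgr))  # strongest SL candidate on the screen
})

test_that("scoring and hit calls are invariant to rescaling raw plate sizes", {
  cfg <- screen_sim_config(n_genes = 96, planted_sl = sim_gene_ids(96)[1:3],
                           noise_sigma = 0.05, seed = 77)
  out <- simulate_screen(cfg)
  sc1 <- score_screen(collect_measurements(out$grids, out$strain_map))
  scaled <- lapply(out$grids, function(g) { g$sizes <- g$sizes * 37.5; g })
  sc2 <- score_screen(collect_measurements(scaled, out$strain_map))
  expect_equal(sc1$z, sc2$z, tolerance = 1e-12)
  expect_equal(as.data.frame(call_hits(sc1)), as.data.frame(call_hits(sc2)))
})

test_that("hit calling splits by sign, ranks by p and respects alpha", {
  m <- null_meas(300, multiplier = c(rep(0.5, 5), rep(2, 5), rep(1, 290)), seed = 9)
  sc <- score_screen(m)
  hits <- call_hits(sc, alpha = 0.05)
  sl <- hits[hits$category == "SL", ]; ss <- hits[hits$category == "SS", ]
  expect_true(all(sprintf("g%04d", 1:5) %in% sl$gene_id))
  expect_true(all(sprintf("g%04d", 6:10) %in% ss$gene_id))
  expect_true(all(sl$statistic > 0) && all(ss$statistic < 0))
  expect_true(all(diff(sl$p_value) >= 0))
  expect_true(all(hits$p_value <= 0.05))
  expect_error(call_hits(sc, alpha = 0), "alpha")
  expect_error(call_hits(sc, alpha = 1.5), "alpha")
  # shrinking alpha never adds a hit
  for (a in c(0.05, 0.01, 0.001, 1e-6)) {
    expect_true(all(call_hits(sc, alpha = a)$gene_id %in% hits$gene_id))
  }
  expect_equal(nrow(call_hits(sc, alpha = 1e-300)), 0L)
})

test_that("tied p-values are broken by |z| then gene id", {
  sc <- structure(
    data.frame(gene_id = c("b", "a", "c"), lgr = c(1, 1, 2),
               z = c(2.5, 2.5, 3.0), p = c(0.01, 0.01, 0.01),
               flagged = FALSE, stringsAsFactors = FALSE),
    mu = 0, sigma = 1, screen = "wt", dropped = character(0),
    class = c("screen_scores", "data.frame"))
  hits <- call_hits(sc)
  expect_equal(hits$gene_id, c("c", "a", "b"))
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  m <- null_meas(500, seed = 21)
  sc <- score_screen(m)
  raw <- call_hits(sc, alpha = 0.05)
  bh <- call_hits(sc, alpha = 0.05, adjust = "BH")
  expect_lte(nrow(bh), nrow(raw))
})

test_that("merging hit tables takes the set union of the four lists", {
  t1 <- hit_table(data.frame(screen = "wt", category = rep(c("SL", "SS"), c(2, 1)),
                             rank = c(1, 2, 1), gene_id = c("a", "b", "c")))
  t2 <- hit_table(data.frame(screen = "mut", category = rep(c("SL", "SS"), c(2, 1)),
                             rank = c(1, 2, 1), gene_id = c("b", "d", "e")))
  expect_equal(merge_hit_tables(t1, t2), c("a", "b", "c", "d", "e"))
  expect_lte(length(merge_hit_tables(t1, t2)), nrow(t1) + nrow(t2))
  disj <- hit_table(data.frame(screen = "mut", category = "SL", rank = 1:3,
                               gene_id = c("x", "y", "z")))
  expect_length(merge_hit_tables(t1, disj), nrow(t1) + 3L)
})
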