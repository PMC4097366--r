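# Hit calling: plate-median normalization, quadruplicate aggregation,
# log-growth-ratio z scoring and SL/SS list assembly.
#
# The statistic is the standard colony-screen one: per gene,
# lgr = ln(mean size non-inducing / mean size inducing), standardized against
# the population of all scoreable genes on the screen. Centering on the
# population absorbs the genome-wide growth cost of inducing the query gene,
# so z measures a gene's *differential* response, not the global slowdown.

#' Normalize a colony grid by its plate median
#'
#' Divides every nonzero colony size by the median of the nonzero sizes on the
#' plate, so the median normalized nonzero size is exactly 1. Zeros (missing /
#' dead positions) are left at zero. This removes multiplicative plate effects
#' (media batch, pinning pressure, incubation) before conditions are compared.
#'
#' @param grid A [colony_grid()].
#' @return A `colony_grid` with normalized sizes. Idempotent.
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "colony_grid"))
  nz <- grid$sizes[grid$sizes > 0]
  if (length(nz) == 0L)
    stop("cannot normalize an all-zero plate: ", grid$plate_id)
  grid$sizes <- grid$sizes / median(nz)
  grid
}

#' Coefficient-of-variation replicate exclusion
#'
#' Quadruplicate pinning occasionally produces one aberrant colony. If the CV
#' (sd/mean) of the replicate sizes exceeds `cv_threshold` and removing the
#' single value farthest from the median brings the CV below the threshold,
#' that value is dropped. At most one value is ever excluded; with fewer than
#' three values no exclusion is attempted.
#'
#' @param sizes Numeric vector of up to 4 replicate sizes.
#' @param cv_threshold CV above which exclusion is attempted (default 0.35).
#' @return The retained sizes.
#' @export
#' @examples
#' exclude_replicates(c(1.0, 1.1, 0.9, 3.0))  # drops 3.0
exclude_replicates <- function(sizes, cv_threshold = 0.35) {
  if (length(sizes) < 3L) return(sizes)
  cv <- sd(sizes) / mean(sizes)
  if (!is.finite(cv) || cv <= cv_threshold) return(sizes)
  drop <- which.max(abs(sizes - median(sizes)))
  kept <- sizes[-drop]
  cv_after <- sd(kept) / mean(kept)
  if (is.finite(cv_after) && cv_after < cv_threshold) kept else sizes
}

#' Log growth ratio between conditions
#'
#' `ln(mean_non_inducing / mean_inducing)`: positive values mean the strain
#' grows *slower* when the query gene is induced (the synthetic-lethal
#' direction); negative values mean induction is tolerated better than the
#' population (the suppressor direction).
#'
#' @param mean_non_inducing,mean_inducing Positive mean normalized sizes.
#' @return A real number; antisymmetric in its arguments.
#' @export
log_growth_ratio <- function(mean_non_inducing, mean_inducing) {
  if (any(mean_non_inducing <= 0) || any(mean_inducing <= 0))
    stop("log_growth_ratio requires positive means; zero-size genes are handled in score_screen()")
  log(mean_non_inducing / mean_inducing)
}

#' Assemble per-gene quadruplicate measurements from grids
#'
#' Normalizes every grid by its plate median, then collects for each gene of
#' the strain map its replicate sizes under the inducing and non-inducing
#' conditions. Zero sizes are treated as missing and dropped from the
#' replicate vectors (their count is recorded).
#'
#' @param grids List of [colony_grid()] covering both conditions.
#' @param map A [strain_map()].
#' @param day Imaging day to use; `NULL` (default) requires the grids to hold
#'   a single day and uses it. The screen documents plates on several
#'   consecutive days, so the caller chooses which day enters scoring.
#' @param screen Screen label stored on the result ("wt" or "mut").
#' @return A data frame of class `gene_measurements` with list-columns
#'   `sizes_inducing` and `sizes_non_inducing`.
#' @export
collect_measurements <- function(grids, map, day = NULL, screen = "wt") {
  stopifnot(inherits(map, "strain_map"))
  days <- unique(vapply(grids, `[[`, integer(1), "day"))
  if (is.null(day)) {
    if (length(days) != 1L)
      stop("grids span days ", paste(sort(days), collapse = ", "),
           "; pass `day` to select one")
    day <- days
  }
  grids <- Filter(function(g) g$day == day, grids)
  if (length(grids) == 0L) stop("no grids for day ", day)
  grids <- lapply(grids, normalize_grid)
  lookup <- list()
  for (g in grids) lookup[[paste(g$plate_id, g$condition)]] <- g
  pull <- function(rows, condition) {
    out <- numeric(0)
    for (i in seq_len(nrow(rows))) {
      g <- lookup[[paste(rows$plate[i], condition)]]
      if (is.null(g))
        stop("strain map references plate ", rows$plate[i],
             " with no ", condition, " grid on day ", day)
      out <- c(out, g$sizes[rows$row[i], rows$col[i]])
    }
    out[out > 0]
  }
  by_gene <- split(seq_len(nrow(map)), map$gene_id)
  genes <- names(by_gene)
  ind <- vector("list", length(genes)); non <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    rows <- map[by_gene[[j]], , drop = FALSE]
    ind[[j]] <- pull(rows, "inducing")
    non[[j]] <- pull(rows, "non_inducing")
  }
  out <- data.frame(gene_id = genes, screen = screen, stringsAsFactors = FALSE)
  out$sizes_inducing <- ind
  out$sizes_non_inducing <- non
  structure(out, class = c("gene_measurements", "data.frame"))
}

#' Score a screen: per-gene log growth ratio, z and p
#'
#' For each gene, mean replicate sizes per condition (optionally after CV
#' [exclude_replicates()]) give `lgr = ln(mean_non_inducing / mean_inducing)`.
#' Genes are standardized against the population:
#' `z = (lgr - mean(lgr)) / sd(lgr)`, with a two-tailed normal p-value.
#'
#' Degenerate genes are handled explicitly rather than producing infinities:
#' a gene dead in the non-inducing condition is dropped (dead independent of
#' induction); a gene dead *only* under induction is the strongest possible
#' SL candidate and is assigned the largest finite lgr on the screen plus one
#' population SD, flagged in the output. A gene with a single surviving
#' replicate in a condition is dropped for lack of support.
#'
#' @param measurements A `gene_measurements` data frame
#'   (see [collect_measurements()]).
#' @param replicate_exclusion Apply the CV rule before averaging?
#'   Default `FALSE`; both modes are first-class.
#' @param cv_threshold Threshold for [exclude_replicates()].
#' @param min_genes Minimum scoreable genes for population statistics
#'   (default 20).
#' @return An object of class `screen_scores`: a data frame
#'   (`gene_id`, `lgr`, `z`, `p`, `flagged`) with attributes `mu`, `sigma`,
#'   `screen` and `dropped` (gene IDs removed with reasons).
#' @export
score_screen <- function(measurements, replicate_exclusion = FALSE,
                         cv_threshold = 0.35, min_genes = 20L) {
  stopifnot(is.data.frame(measurements))
  prep <- function(v) {
    if (replicate_exclusion) v <- exclude_replicates(v, cv_threshold) else v
  }
  n <- nrow(measurements)
  m_ind <- numeric(n); m_non <- numeric(n); status <- character(n)
  for (i in seq_len(n)) {
    si <- prep(measurements$sizes_inducing[[i]])
    sn <- prep(measurements$sizes_non_inducing[[i]])
    m_ind[i] <- if (length(si)) mean(si) else 0
    m_non[i] <- if (length(sn)) mean(sn) else 0
    status[i] <-
      if (length(sn) == 0L) "dead_non_inducing"       # dead regardless of induction
      else if (length(sn) == 1L) "low_support"
      else if (length(si) == 0L) "dead_inducing"      # strongest SL candidate
      else if (length(si) == 1L) "low_support"
      else "ok"
  }
  keep <- status %in% c("ok", "dead_inducing")
  dropped <- setNames(status[!keep], measurements$gene_id[!keep])
  gene_id <- measurements$gene_id[keep]
  st <- status[keep]
  lgr <- rep(NA_real_, length(gene_id))
  lgr[st == "ok"] <- log_growth_ratio(m_non[keep][st == "ok"], m_ind[keep][st == "ok"])
  if (sum(st == "ok") < min_genes)
    stop("fewer than ", min_genes, " scoreable genes; population statistics unsupported")
  sd_fin <- sd(lgr[st == "ok"])
  if (!is.finite(sd_fin) || sd_fin == 0)
    stop("zero population SD of log growth ratios; degenerate screen")
  lgr[st == "dead_inducing"] <- max(lgr[st == "ok"]) + sd_fin
  mu <- mean(lgr); sigma <- sd(lgr)
  if (sigma == 0) stop("zero population SD of log growth ratios; degenerate screen")
  z <- (lgr - mu) / sigma
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(gene_id = gene_id, lgr = lgr, z = z, p = p,
                    flagged = st == "dead_inducing", stringsAsFactors = FALSE)
  structure(res, mu = mu, sigma = sigma,
            screen = unique(measurements$screen)[1], dropped = dropped,
            class = c("screen_scores", "data.frame"))
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("<screen_scores> %s screen: %d genes (mu = %.4f, sigma = %.4f), %d flagged, %d dropped\n",
              attr(x, "screen"), nrow(x), attr(x, "mu"), attr(x, "sigma"),
              sum(x$flagged), length(attr(x, "dropped"))))
  invisible(x)
}

#' Write a per-gene score audit TSV (`gene_id`, `screen`, `lgr`, `z`, `p`)
#' @param scores A `screen_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(gene_id = scores$gene_id, screen = attr(scores, "screen"),
                   lgr = scores$lgr, z = scores$z, p = scores$p)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call SL/SS hits from screen scores
#'
#' Genes with `p <= alpha` are split by sign — `z > 0` (slower growth under
#' induction) is synthetic lethal, `z < 0` synthetic suppressor — and ranked
#' by ascending p; ties are broken by `|z|` descending, then gene ID. The
#' published screens rank at raw P <= 0.05 with no multiple-testing
#' correction; a Benjamini-Hochberg option is available behind `adjust` and
#' off by default for fidelity to that convention.
#'
#' @param scores A `screen_scores` object.
#' @param alpha Significance cutoff in (0, 1] (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A [hit_table()] for this screen (two lists: SL and SS).
#' @export
call_hits <- function(scores, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(scores, "screen_scores"))
  adjust <- match.arg(adjust)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  p_eff <- if (adjust == "BH") p.adjust(scores$p, "BH") else scores$p
  screen <- attr(scores, "screen")
  pieces <- lapply(c(SL = 1, SS = -1), function(sgn) {
    idx <- which(p_eff <= alpha & sign(scores$z) == sgn)
    if (length(idx) == 0L)
      return(data.frame(screen = character(0), category = character(0),
                        rank = integer(0), gene_id = character(0),
                        statistic = numeric(0), p_value = numeric(0)))
    ord <- idx[order(p_eff[idx], -abs(scores$z[idx]), scores$gene_id[idx])]
    data.frame(screen = screen,
               category = if (sgn > 0) "SL" else "SS",
               rank = seq_along(ord), gene_id = scores$gene_id[ord],
               statistic = scores$z[ord], p_value = p_eff[ord])
  })
  hit_table(do.call(rbind, pieces))
}

#' Merge hit tables into the unique modifier set
#'
#' The set union of gene IDs across all (screen, category) lists of the given
#' hit tables — the screen's headline "modifier" count.
#'
#' @param ... One or more `hit_table` objects (e.g. the wt and mut screens,
#'   or the single packaged fixture holding all four lists).
#' @return Sorted character vector of unique gene IDs.
#' @export
#' @examples
#' length(merge_hit_tables(read_table1_fixture()))  # 173
merge_hit_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) > 0L, all(vapply(tabs, inherits, logical(1), "hit_table")))
  sort(unique(unlist(lapply(tabs, `[[`, "gene_id"), use.names = FALSE)))
}
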