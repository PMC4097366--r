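# Categorical motor-axon severity summaries for zebrafish embryo scoring.
#
# Each embryo contributes a count of abnormal axons out of 20 scored
# (myotomes 6-15, both sides); embryos are binned into severity categories,
# percentages are computed per independent experiment, and groups are
# summarized as mean +/- SEM *across experiments* (not across embryos),
# matching how replicated injection experiments are conventionally reported.

.SEVERITY_LEVELS <- c("severe", "moderate", "mild", "none")

#' Default severity bins
#'
#' The published classification ("severe, moderate, mild, or no defects")
#' does not print its bin edges, so the bins are configuration with these
#' documented defaults over the 0-20 abnormal-axon range: none = 0,
#' mild = 1-3, moderate = 4-7, severe = 8-20.
#'
#' @param n_scored Total axons scored per embryo (default 20).
#' @return Named list of `c(lo, hi)` integer ranges partitioning
#'   `0:n_scored`.
#' @export
default_severity_bins <- function(n_scored = 20L) {
  list(none = c(0L, 0L), mild = c(1L, 3L), moderate = c(4L, 7L),
       severe = c(8L, n_scored))
}

.check_bins <- function(bins, n_scored = 20L) {
  covered <- sort(as.integer(unlist(lapply(bins, function(b) seq(b[1], b[2])),
                                    use.names = FALSE)))
  if (!identical(covered, 0:n_scored))
    stop("severity bins must partition 0..", n_scored,
         " with no gaps or overlaps")
  invisible(bins)
}

#' Classify an embryo by its abnormal-axon count
#'
#' @param n_abnormal_axons Integer count(s) in `0..n_scored`.
#' @param bins Named list of inclusive `c(lo, hi)` ranges that partition
#'   `0:n_scored`; see [default_severity_bins()].
#' @param n_scored Total axons scored per embryo.
#' @return Character vector of category names (vectorized).
#' @export
#' @examples
#' classify_embryo(5)  # "moderate"
classify_embryo <- function(n_abnormal_axons, bins = default_severity_bins(),
                            n_scored = 20L) {
  .check_bins(bins, n_scored)
  if (any(n_abnormal_axons < 0 | n_abnormal_axons > n_scored))
    stop("abnormal-axon counts must lie in 0..", n_scored)
  vapply(n_abnormal_axons, function(n) {
    for (nm in names(bins)) if (n >= bins[[nm]][1] && n <= bins[[nm]][2]) return(nm)
    stop("unreachable: bins validated as a partition")
  }, character(1))
}

.check_embryo_df <- function(scores) {
  need <- c("embryo_id", "group", "experiment_id", "n_abnormal_axons")
  if (!all(need %in% names(scores)))
    stop("embryo scores need columns: ", paste(need, collapse = ", "))
  invisible(scores)
}

#' Per-group severity summary across experiments
#'
#' Computes, per group and experiment, the percentage of embryos in each
#' severity category (summing to 100 exactly), then the mean and SEM of those
#' percentages across experiments. With a single experiment the mean is
#' reported and the SEM flagged undefined (`NA`).
#'
#' @param scores Data frame of embryo scores (`embryo_id`, `group`,
#'   `experiment_id`, `n_abnormal_axons`).
#' @param bins Severity bins, see [default_severity_bins()].
#' @param n_scored Total axons scored per embryo.
#' @return An object of class `group_summary`: a data frame with one row per
#'   group x category holding `mean_percent` and `sem`, plus attribute
#'   `n_per_experiment` (embryo counts per group and experiment).
#' @export
group_summary <- function(scores, bins = default_severity_bins(), n_scored = 20L) {
  .check_embryo_df(scores)
  scores$category <- factor(
    classify_embryo(scores$n_abnormal_axons, bins, n_scored),
    levels = intersect(.SEVERITY_LEVELS, names(bins)))
  rows <- list(); npe <- list()
  for (grp in unique(scores$group)) {
    sub <- scores[scores$group == grp, ]
    exps <- sort(unique(sub$experiment_id))
    pct <- sapply(exps, function(e) {
      cnt <- table(sub$category[sub$experiment_id == e])
      if (sum(cnt) == 0L) stop("experiment ", e, " of group ", grp, " has no embryos")
      100 * as.numeric(cnt) / sum(cnt)
    })  # categories x experiments
    pct <- matrix(pct, nrow = nlevels(scores$category),
                  dimnames = list(levels(scores$category), exps))
    rows[[grp]] <- data.frame(
      group = grp, category = rownames(pct),
      mean_percent = rowMeans(pct),
      sem = if (ncol(pct) >= 2) apply(pct, 1, sd) / sqrt(ncol(pct)) else NA_real_,
      n_experiments = ncol(pct), stringsAsFactors = FALSE)
    npe[[grp]] <- vapply(exps, function(e) sum(sub$experiment_id == e), integer(1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_per_experiment = npe,
            class = c("group_summary", "data.frame"))
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> mean percent (+/- SEM across experiments)\n")
  for (grp in unique(x$group)) {
    sub <- x[x$group == grp, ]
    cat(sprintf("  %s [n per exp: %s]\n", grp,
                paste(attr(x, "n_per_experiment")[[grp]], collapse = "/")))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-9s %5.1f (+/- %s)\n", sub$category[i], sub$mean_percent[i],
                  ifelse(is.na(sub$sem[i]), "NA", sprintf("%.1f", sub$sem[i]))))
  }
  invisible(x)
}

#' Write a group summary TSV (group, category, mean_percent, sem, n_experiments)
#' @param summary A `group_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(summary, path) {
  write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Compare the severity distributions of two groups
#'
#' Pools embryos across experiments into a category x group contingency table
#' and applies a chi-square test of homogeneity, falling back to Fisher's
#' exact test when any expected cell count is below 5. The test identity is
#' always part of the return value, since categorical phenotype comparisons
#' are reported with many different tests in the literature.
#'
#' @param g1,g2 Embryo-score data frames (same columns as [group_summary()]).
#' @param bins Severity bins.
#' @param n_scored Total axons scored per embryo.
#' @return A list: `method`, `statistic` (NA for the exact test), `p_value`,
#'   and the pooled `table`.
#' @export
compare_groups <- function(g1, g2, bins = default_severity_bins(), n_scored = 20L) {
  .check_embryo_df(g1); .check_embryo_df(g2)
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("both groups need at least one embryo")
  lev <- intersect(.SEVERITY_LEVELS, names(bins))
  cnt <- function(df) table(factor(classify_embryo(df$n_abnormal_axons, bins, n_scored),
                                   levels = lev))
  tab <- rbind(g1 = cnt(g1), g2 = cnt(g2))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2)
    return(list(method = "chi-square (degenerate: one category observed)",
                statistic = 0, p_value = 1, table = tab))
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(cs$expected < 5)) {
    ft <- fisher.test(tab, workspace = 2e7)
    list(method = "Fisher exact", statistic = NA_real_,
         p_value = ft$p.value, table = tab)
  } else {
    list(method = "chi-square", statistic = unname(cs$statistic),
         p_value = cs$p.value, table = tab)
  }
}
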