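# Data model and file I/O for colony-size screens.
#
# All on-disk coordinates are 1-based (plate-scanner convention). Matrices in
# R are naturally 1-indexed so no offset conversion is needed beyond input
# validation; positions are stored as (row, col) into the sizes matrix.

.GRID_FORMATS <- list(`1536` = c(32L, 48L), `384` = c(16L, 24L))

#' Construct a colony grid
#'
#' A colony grid is one plate x condition x day matrix of colony sizes in
#' arbitrary area units. A size of 0 encodes "no growth or missing"; zeros are
#' excluded from downstream statistics rather than imputed, because a pinning
#' failure cannot be distinguished from lethality except through the
#' inducing / non-inducing contrast itself.
#'
#' @param plate_id Plate identifier (character scalar).
#' @param condition `"inducing"` or `"non_inducing"`.
#' @param day Non-negative integer imaging day.
#' @param sizes Numeric matrix of non-negative colony sizes. Dimensions must
#'   match a supported plate format: 32 x 48 (1536 format) or 16 x 24
#'   (384 format).
#' @return An object of class `colony_grid`.
#' @export
#' @examples
#' g <- colony_grid("P1", "inducing", 1, matrix(200, 32, 48))
#' dim(g$sizes)
colony_grid <- function(plate_id, condition, day, sizes) {
  condition <- match.arg(condition, c("inducing", "non_inducing"))
  stopifnot(is.matrix(sizes), is.numeric(sizes))
  if (length(day) != 1L || is.na(day) || day < 0 || day != floor(day))
    stop("`day` must be a single non-negative integer")
  if (any(sizes < 0, na.rm = TRUE)) stop("colony sizes must be non-negative")
  fmt <- .match_format(nrow(sizes), ncol(sizes))
  structure(
    list(plate_id = as.character(plate_id), condition = condition,
         day = as.integer(day), n_rows = nrow(sizes), n_cols = ncol(sizes),
         format = fmt, sizes = sizes),
    class = "colony_grid")
}

.match_format <- function(n_rows, n_cols) {
  for (fmt in names(.GRID_FORMATS)) {
    d <- .GRID_FORMATS[[fmt]]
    if (n_rows == d[1] && n_cols == d[2]) return(fmt)
  }
  stop(sprintf(
    "grid dimensions %d x %d match no supported plate format (1536 = 32x48, 384 = 16x24)",
    n_rows, n_cols))
}

#' @export
print.colony_grid <- function(x, ...) {
  cat(sprintf("<colony_grid> plate %s, %s, day %d, %s format (%d x %d), %d empty positions\n",
              x$plate_id, x$condition, x$day, x$format, x$n_rows, x$n_cols,
              sum(x$sizes == 0)))
  invisible(x)
}

#' Read colony grids from a long-format CSV
#'
#' Expects a header `plate,condition,day,row,col,size` with 1-based
#' coordinates. One grid is returned per distinct (plate, condition, day);
#' positions absent from the file are set to size 0. Grid dimensions are the
#' smallest supported plate format containing all listed coordinates.
#'
#' @param path CSV file path.
#' @return A list of [colony_grid()] objects, ordered by plate, condition, day.
#' @export
read_colony_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "condition", "day", "row", "col", "size")
  if (!all(need %in% names(df)))
    stop("colony CSV must have header: ", paste(need, collapse = ","))
  if (nrow(df) == 0L) return(list())
  .check_colony_rows(df)
  keys <- unique(df[, c("plate", "condition", "day")])
  keys <- keys[order(keys$plate, keys$condition, keys$day), , drop = FALSE]
  grids <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$plate == keys$plate[i] & df$condition == keys$condition[i] &
                df$day == keys$day[i], , drop = FALSE]
    dims <- .infer_dims(max(sub$row), max(sub$col))
    m <- matrix(0, dims[1], dims[2])
    m[cbind(sub$row, sub$col)] <- sub$size
    grids[[i]] <- colony_grid(keys$plate[i], keys$condition[i], keys$day[i], m)
  }
  grids
}

.check_colony_rows <- function(df) {
  bad <- which(is.na(df$row) | is.na(df$col) | is.na(df$size) | is.na(df$day) |
                 df$row < 1 | df$col < 1 | df$size < 0 |
                 df$row != floor(df$row) | df$col != floor(df$col))
  if (length(bad))
    stop(sprintf("malformed colony row at data line %d (coordinates 1-based, sizes >= 0)",
                 bad[1]))
  big <- which(df$row > 32 | df$col > 48)
  if (length(big))
    stop(sprintf("out-of-range coordinate at data line %d (max supported 32 x 48)", big[1]))
  invisible(df)
}

.infer_dims <- function(max_row, max_col) {
  if (max_row <= 16 && max_col <= 24) return(.GRID_FORMATS[["384"]])
  .GRID_FORMATS[["1536"]]
}

#' Write colony grids to a long-format CSV
#'
#' Inverse of [read_colony_table()]. All positions, including zeros, are
#' written so a round trip reproduces the grids exactly.
#'
#' @param grids A list of [colony_grid()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(grids, path) {
  rows <- lapply(grids, function(g) {
    idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
    data.frame(plate = g$plate_id, condition = g$condition, day = g$day,
               row = idx$row, col = idx$col, size = g$sizes[cbind(idx$row, idx$col)])
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a strain map
#'
#' Maps plate positions to deletion-strain gene IDs. Each gene must occupy
#' exactly four positions (the quadruplicate 2x2 pinning block of a 384-format
#' source plate replicated into 1536 format).
#'
#' @param positions Data frame with columns `plate`, `row`, `col`, `gene_id`.
#' @param query Which query strain the plates carry: `"wt"`, `"mut"` or
#'   `"control"`.
#' @return An object of class `strain_map` (a validated data frame).
#' @export
strain_map <- function(positions, query = c("wt", "mut", "control")) {
  query <- match.arg(query)
  need <- c("plate", "row", "col", "gene_id")
  if (!all(need %in% names(positions)))
    stop("strain map needs columns: ", paste(need, collapse = ", "))
  positions <- positions[, need]
  cnt <- table(positions$gene_id)
  if (any(cnt != 4L))
    stop("every gene must map to exactly 4 positions; offending gene(s): ",
         paste(head(names(cnt)[cnt != 4L], 3), collapse = ", "))
  key <- paste(positions$plate, positions$row, positions$col)
  if (anyDuplicated(key)) stop("duplicate plate position in strain map")
  structure(positions, query = query, class = c("strain_map", "data.frame"))
}

#' Read a strain map TSV (`plate`, `row`, `col`, `gene_id`)
#' @param path TSV file path.
#' @param query Query strain label, see [strain_map()].
#' @return A `strain_map`.
#' @export
read_strain_map <- function(path, query = "wt") {
  strain_map(read.delim(path, stringsAsFactors = FALSE), query = query)
}

#' Write a strain map TSV
#' @param map A `strain_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a hit table
#'
#' A hit table holds the four ordered SL/SS lists keyed by (screen, category):
#' wt-SL, wt-SS, mut-SL, mut-SS. SL (synthetic lethal) genes grow slower when
#' the query gene is induced; SS (synthetic suppressor) genes grow faster.
#'
#' @param df Data frame with columns `screen` ("wt"/"mut"), `category`
#'   ("SL"/"SS"), `rank` (positive integer within each list), `gene_id`, and
#'   optionally `statistic` (z-score) and `p_value`.
#' @return An object of class `hit_table`.
#' @export
hit_table <- function(df) {
  need <- c("screen", "category", "rank", "gene_id")
  if (!all(need %in% names(df))) stop("hit table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$screen %in% c("wt", "mut"))) stop("screen must be 'wt' or 'mut'")
  if (!all(df$category %in% c("SL", "SS"))) stop("category must be 'SL' or 'SS'")
  if (!"statistic" %in% names(df)) df$statistic <- NA_real_
  if (!"p_value" %in% names(df)) df$p_value <- NA_real_
  if (any(!is.na(df$p_value) & (df$p_value < 0 | df$p_value > 1)))
    stop("p_value outside [0, 1]")
  key <- interaction(df$screen, df$category, drop = TRUE)
  for (lv in levels(key)) {
    sub <- df[key == lv, ]
    if (anyDuplicated(sub$gene_id))
      stop("duplicate gene within list ", lv)
    if (!identical(sort(as.integer(sub$rank)), seq_len(nrow(sub))))
      stop("ranks within list ", lv, " must be 1..n")
  }
  df <- df[order(df$screen, df$category, df$rank), ]
  rownames(df) <- NULL
  structure(df[, c("screen", "category", "rank", "gene_id", "statistic", "p_value")],
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  tab <- table(paste(x$screen, x$category, sep = "-"))
  cat("<hit_table> ", nrow(x), " entries: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one ordered list from a hit table
#' @param hits A `hit_table`.
#' @param screen `"wt"` or `"mut"`.
#' @param category `"SL"` or `"SS"`.
#' @return Character vector of gene IDs in rank order.
#' @export
hit_list <- function(hits, screen, category) {
  sub <- hits[hits$screen == screen & hits$category == category, ]
  sub$gene_id[order(sub$rank)]
}

#' Read / write hit-table TSVs
#'
#' TSV columns: `screen`, `category`, `rank`, `gene_id`, `statistic`,
#' `p_value` (the last two may be `NA` when not available, as for the
#' published top-hit lists which print IDs only).
#'
#' @param path File path.
#' @return `read_hit_table()`: a `hit_table`; `write_hit_table()`: `path`,
#'   invisibly.
#' @export
read_hit_table <- function(path) {
  hit_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_hit_table
#' @param hits A `hit_table`.
#' @export
write_hit_table <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.TABLE1_MD5 <- "d40c9802d8907719a37f925147795546"

#' Load the packaged SGA top-hit lists
#'
#' Returns the transcribed top-hit table of the UBA1 / mutUBA1 fission-yeast
#' SGA screen: four ordered lists of S. pombe systematic IDs (57 wt-SL,
#' 48 wt-SS, 54 mut-SL, 45 mut-SS; 173 unique genes in total). Statistics and
#' p-values are `NA` because the published lists print gene IDs only. The
#' fixture is checksummed; a mismatch signals a corrupted installation.
#'
#' @return A `hit_table`.
#' @export
#' @examples
#' length(merge_hit_tables(read_table1_fixture()))
read_table1_fixture <- function() {
  path <- system.file("extdata", "table1_hits.tsv", package = "yana")
  if (path == "" || !file.exists(path))
    stop("packaged top-hit fixture not found; reinstall the package")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .TABLE1_MD5))
    stop("top-hit fixture checksum mismatch (", md5, "); the fixture must never be edited")
  read_hit_table(path)
}
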