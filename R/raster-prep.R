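# Raster preparation: block aggregation, 5x5 tiling, temporal stacking,
# spatially blocked four-fold partitioning, and prediction-map assembly.
# Conventions used throughout: 0-based row-major tile coordinates; a tile
# with indices (i, j) covers pixel rows [size*i, size*i + size) and columns
# [size*j, size*j + size), half-open; trailing partial blocks are dropped.

#' Block-aggregate a raster
#'
#' Downsamples by an integer factor, e.g. from the 5 cm sensor grid to the
#' 50 cm analysis grid (factor 10).  Each output cell is the mean of the
#' valid (non-`NA`) cells in its factor x factor block; a cell is invalid
#' only if the whole block is.  Trailing rows/columns that do not fill a
#' block are dropped.
#'
#' @param x A numeric matrix (`NA` = invalid), or a `yield_raster`.
#' @param factor Positive integer aggregation factor; 1 is the identity.
#' @return Same type as `x`, aggregated.
#' @export
#' @examples
#' aggregate_raster(matrix(1, 10, 10), 10)   # 1 x 1 cell, value 1
aggregate_raster <- function(x, factor) {
  UseMethod("aggregate_raster")
}

#' @export
aggregate_raster.matrix <- function(x, factor) {
  f <- check_count(factor, "factor")
  if (nrow(x) < f || ncol(x) < f)
    stop_input("raster dimensions must be at least the aggregation factor")
  if (f == 1L) return(x)
  h <- (nrow(x) %/% f) * f
  w <- (ncol(x) %/% f) * f
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  blocks <- aperm(array(x, c(f, h %/% f, f, w %/% f)), c(1, 3, 2, 4))
  v <- matrix(blocks, nrow = f * f)
  cnt <- colSums(!is.na(v))
  s <- colSums(v, na.rm = TRUE)
  out <- ifelse(cnt == 0, NA_real_, s / cnt)
  matrix(out, h %/% f, w %/% f)
}

#' @export
aggregate_raster.yield_raster <- function(x, factor) {
  values <- aggregate_raster(x$values, factor)
  structure(list(values = values, mask = !is.na(values),
                 resolution = x$resolution * factor),
            class = "yield_raster")
}

#' Split co-registered features and yield into 5x5 tiles
#'
#' Cuts the tile grid (floor division; trailing pixels are never tiled) and
#' retains only complete tiles: those with no missing value in any feature
#' layer or yield cell.  Retained tiles carry their 0-based row-major grid
#' coordinates so folds and maps can be reconstructed.
#'
#' @param features A `feature_raster`.
#' @param yield A `yield_raster` with the same pixel grid.
#' @param size Tile edge in pixels (default 5).
#' @return A `tile_set`: `features` (n x size x size x 7 array), `yield`
#'   (n x size x size), integer vectors `row_idx`/`col_idx`, `tile_grid`
#'   (tile rows, tile cols), `size`, `dates`, `n_dates = 1`.
#' @export
tile_field <- function(features, yield, size = 5L) {
  if (!inherits(features, "feature_raster"))
    stop_input("'features' must be a feature_raster")
  if (!inherits(yield, "yield_raster"))
    stop_input("'yield' must be a yield_raster")
  size <- check_count(size, "size")
  dims <- dim(features$features)[1:2]
  if (!identical(dims, dim(yield$values)))
    stop_input("feature and yield rasters have different shapes")
  n_tr <- dims[1] %/% size
  n_tc <- dims[2] %/% size
  if (n_tr < 1L || n_tc < 1L)
    stop_input("raster smaller than one tile")

  ok <- features$mask & yield$mask
  # a tile is retained iff every pixel in its extent is valid
  ok_cropped <- ok[seq_len(n_tr * size), seq_len(n_tc * size), drop = FALSE]
  blocks <- aperm(array(ok_cropped, c(size, n_tr, size, n_tc)), c(1, 3, 2, 4))
  complete <- matrix(colSums(matrix(blocks, nrow = size * size)) == size^2,
                     n_tr, n_tc)

  keep <- which(complete, arr.ind = TRUE)   # 1-based (tile row, tile col)
  n <- nrow(keep)
  feats <- array(NA_real_, c(n, size, size, 7L),
                 dimnames = list(NULL, NULL, NULL, feature_names()))
  yl <- array(NA_real_, c(n, size, size))
  for (k in seq_len(n)) {
    rr <- (keep[k, 1] - 1L) * size + seq_len(size)
    cc <- (keep[k, 2] - 1L) * size + seq_len(size)
    feats[k, , , ] <- features$features[rr, cc, ]
    yl[k, , ] <- yield$values[rr, cc]
  }
  structure(list(features = feats, yield = yl,
                 row_idx = as.integer(keep[, 1] - 1L),
                 col_idx = as.integer(keep[, 2] - 1L),
                 tile_grid = c(n_tr, n_tc), size = size,
                 dates = features$date_label %||% NA_character_,
                 n_dates = 1L),
            class = "tile_set")
}

#' Stack single-date tile sets across time
#'
#' Combines tile sets from successive flyover dates (oldest first) into
#' temporal tiles of shape size x size x n_dates x 7.  A tile is retained
#' only if it is complete at every date; yield labels are taken from the
#' first set (all sets of one field share the yield raster).
#'
#' @param tile_sets List of single-date `tile_set`s on the same tile grid.
#' @return A `tile_set` with `n_dates = length(tile_sets)`.
#' @export
stack_time <- function(tile_sets) {
  stopifnot(length(tile_sets) >= 1L)
  for (ts in tile_sets) {
    if (!inherits(ts, "tile_set") || ts$n_dates != 1L)
      stop_input("stack_time expects single-date tile_set objects")
    if (!identical(ts$tile_grid, tile_sets[[1]]$tile_grid) ||
        ts$size != tile_sets[[1]]$size)
      stop_input("tile sets are on different tile grids")
  }
  base <- tile_sets[[1]]
  keys <- lapply(tile_sets, function(ts) ts$row_idx * base$tile_grid[2] + ts$col_idx)
  common <- Reduce(intersect, keys)
  n <- length(common)
  size <- base$size
  nd <- length(tile_sets)
  feats <- array(NA_real_, c(n, size, size, nd, 7L),
                 dimnames = list(NULL, NULL, NULL, NULL, feature_names()))
  for (d in seq_len(nd)) {
    pos <- match(common, keys[[d]])
    feats[, , , d, ] <- tile_sets[[d]]$features[pos, , , , drop = FALSE]
  }
  pos1 <- match(common, keys[[1]])
  structure(list(features = feats,
                 yield = base$yield[pos1, , , drop = FALSE],
                 row_idx = base$row_idx[pos1], col_idx = base$col_idx[pos1],
                 tile_grid = base$tile_grid, size = size,
                 dates = vapply(tile_sets, function(ts) ts$dates[1],
                                character(1)),
                 n_dates = nd),
            class = "tile_set")
}

# map tile indices to one of four nearly equal contiguous chunks (0..3)
fold_chunk <- function(idx, n) pmin((idx * 4L) %/% n, 3L)

#' Partition tiles into four spatially blocked folds
#'
#' Splits the tile grid into a 4 x 4 lattice of contiguous rectangular
#' blocks and, for each of the four folds, assigns whole blocks to roles
#' along broken diagonals: fold k tests the blocks with
#' `(block_col - block_row) mod 4 == k`, validates the next diagonal, and
#' trains on the remaining two.  Each block is a test block in exactly one
#' fold, every role is a union of rectangles (so test pixels are never
#' scattered among training pixels), and realized fractions approach
#' 50/25/25 train/validation/test as the grid grows.
#'
#' @param tile_set A `tile_set`.
#' @param scheme Partitioning scheme; only `"diagonal4x4"` is defined.
#' @return A list of four `fold_spec` objects (folds A-D), each with
#'   `fold_id`, a `roles` factor over the retained tiles with levels
#'   train/validation/test, and the block geometry.
#' @export
partition_folds <- function(tile_set, scheme = "diagonal4x4") {
  stopifnot(inherits(tile_set, "tile_set"))
  scheme <- match.arg(scheme)
  n_tr <- tile_set$tile_grid[1]
  n_tc <- tile_set$tile_grid[2]
  if (n_tr < 4L || n_tc < 4L)
    stop_input("tile grid too small for 4 x 4 fold blocks (need >= 4 x 4 tiles)")
  br <- fold_chunk(tile_set$row_idx, n_tr)
  bc <- fold_chunk(tile_set$col_idx, n_tc)
  diagonal <- (bc - br) %% 4L
  lapply(0:3, function(k) {
    roles <- rep("train", length(diagonal))
    roles[diagonal == k] <- "test"
    roles[diagonal == (k + 1L) %% 4L] <- "validation"
    structure(list(fold_id = LETTERS[k + 1L],
                   roles = factor(roles,
                                  levels = c("train", "validation", "test")),
                   scheme = scheme,
                   block_row = br, block_col = bc),
              class = "fold_spec")
  })
}

#' @export
print.fold_spec <- function(x, ...) {
  tab <- table(x$roles)
  cat(sprintf("<fold_spec> fold %s (%s): %d train / %d validation / %d test tiles\n",
              x$fold_id, x$scheme, tab[["train"]], tab[["validation"]],
              tab[["test"]]))
  invisible(x)
}

#' Subset a tile set
#'
#' @param x A `tile_set`.
#' @param i Logical or integer index over retained tiles.
#' @param ... Unused.
#' @return The subsetted `tile_set`.
#' @export
`[.tile_set` <- function(x, i, ...) {
  out <- x
  if (x$n_dates == 1L) {
    out$features <- x$features[i, , , , drop = FALSE]
  } else {
    out$features <- x$features[i, , , , , drop = FALSE]
  }
  out$yield <- x$yield[i, , , drop = FALSE]
  out$row_idx <- x$row_idx[i]
  out$col_idx <- x$col_idx[i]
  out
}

#' Number of tiles in a tile set
#' @param x A `tile_set`.
#' @return Integer count of retained tiles.
#' @export
n_tiles <- function(x) length(x$row_idx)

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles of %d x %d px on a %d x %d grid, %d date(s)\n",
              n_tiles(x), x$size, x$size, x$tile_grid[1], x$tile_grid[2],
              x$n_dates))
  invisible(x)
}

#' Reassemble tile patches into a field raster
#'
#' Places per-tile 5x5 patches (predictions, or the labels themselves) back
#' at their pixel extents; everything outside retained tiles is nodata.
#' With `values = tile_set$yield` this inverts [tile_field()] on the
#' retained extents exactly.
#'
#' @param tile_set A `tile_set`.
#' @param values n x size x size array of patch values; defaults to the
#'   yield labels.
#' @param dims Output raster dimensions; defaults to the full tile grid.
#' @return A `yield_raster` (`NA` outside retained tiles).
#' @export
assemble_map <- function(tile_set, values = tile_set$yield,
                         dims = tile_set$tile_grid * tile_set$size) {
  stopifnot(inherits(tile_set, "tile_set"))
  n <- n_tiles(tile_set)
  if (is.null(dim(values)) || dim(values)[1] != n)
    stop_input("'values' must supply one ", tile_set$size, "x",
               tile_set$size, " patch per retained tile (", n, ")")
  size <- tile_set$size
  out <- matrix(NA_real_, dims[1], dims[2])
  for (k in seq_len(n)) {
    rr <- tile_set$row_idx[k] * size + seq_len(size)
    cc <- tile_set$col_idx[k] * size + seq_len(size)
    out[rr, cc] <- values[k, , ]
  }
  structure(list(values = out, mask = !is.na(out), resolution = NA_real_),
            class = "yield_raster")
}

#' Pixel table of a tile set
#'
#' One row per pixel (and per date for temporal sets): tile coordinates,
#' within-tile offsets, the seven features and the yield label.  This is
#' the representation consumed by the per-pixel models (null, linear,
#' boosted trees).
#'
#' @param x A `tile_set`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return A `data.frame`.
#' @export
as.data.frame.tile_set <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  n <- n_tiles(x)
  size <- x$size
  px <- size * size
  base <- data.frame(
    tile = rep(seq_len(n), each = px),
    row_idx = rep(x$row_idx, each = px),
    col_idx = rep(x$col_idx, each = px),
    row_off = rep(rep(0:(size - 1), each = size), times = n),
    col_off = rep(rep(0:(size - 1), times = size), times = n))
  if (x$n_dates == 1L) {
    fm <- t(tiles_to_matrix(x))        # (n*px) x 7, C-order positions
    colnames(fm) <- feature_names()
    out <- cbind(base, as.data.frame(fm))
    out$yield <- as.vector(aperm(x$yield, c(3, 2, 1)))
    out
  } else {
    reps <- do.call(rbind, rep(list(base), x$n_dates))
    reps$date <- rep(x$dates, each = n * px)
    ord <- order(reps$tile, reps$date, reps$row_off, reps$col_off)
    reps <- reps[ord, ]
    feat <- matrix(NA_real_, nrow(reps), 7L,
                   dimnames = list(NULL, feature_names()))
    r <- 1L
    for (k in seq_len(n)) for (d in seq_len(x$n_dates))
      for (i in seq_len(size)) for (j in seq_len(size)) {
        feat[r, ] <- x$features[k, i, j, d, ]
        r <- r + 1L
      }
    out <- cbind(reps, as.data.frame(feat))
    out$yield <- x$yield[cbind(out$tile, out$row_off + 1L, out$col_off + 1L)]
    rownames(out) <- NULL
    out
  }
}
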