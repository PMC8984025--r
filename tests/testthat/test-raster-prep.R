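# Aggregation, tiling, temporal stacking, fold partitioning, and map
# assembly.

test_that("aggregation matches a brute-force block-mean oracle", {
  m <- matrix(0:399, 20, 20, byrow = TRUE)
  got <- aggregate_raster(m, 10)
  oracle <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    acc <- 0
    for (r in 1:10) for (cc in 1:10)
      acc <- acc + m[(i - 1) * 10 + r, (j - 1) * 10 + cc]
    oracle[i, j] <- acc / 100
  }
  expect_equal(got, oracle)

  expect_equal(aggregate_raster(matrix(1, 10, 10), 10), matrix(1, 1, 1))
  expect_identical(aggregate_raster(m, 1), m)
})

test_that("aggregation ignores missing cells and drops partial blocks", {
  m <- matrix(1, 10, 10)
  m[1, 1] <- NA
  expect_equal(aggregate_raster(m, 10)[1, 1], 1)
  m[1:5, 1:10] <- NA
  m[6:10, 1:10] <- NA
  expect_true(is.na(aggregate_raster(m, 10)[1, 1]))
  # 23 x 21 at factor 10 -> 2 x 2
  expect_equal(dim(aggregate_raster(matrix(0, 23, 21), 10)), c(2, 2))
  expect_error(aggregate_raster(matrix(0, 10, 10), 2.5), "integer")
})

test_that("aggregation commutes with affine transforms", {
  set.seed(21)
  m <- matrix(rnorm(400), 20, 20)
  m[sample(400, 30)] <- NA
  expect_equal(aggregate_raster(3 * m + 7, 5),
               3 * aggregate_raster(m, 5) + 7)
})

fake_features <- function(values, mask = NULL) {
  dims <- dim(values)
  feats <- array(rep(values, 7), c(dims, 7),
                 dimnames = list(NULL, NULL, feature_names()))
  m <- if (is.null(mask)) !is.na(values) else mask
  for (f in 1:7) feats[, , f][!m] <- NA
  structure(list(features = feats, mask = m, date_label = "d1",
                 stage = "booting"), class = "feature_raster")
}

fake_yield <- function(values) {
  structure(list(values = values, mask = !is.na(values), resolution = 0.5),
            class = "yield_raster")
}

test_that("tiling counts and exclusion rules are exact", {
  v <- matrix(seq_len(400), 20, 20)
  ts <- tile_field(fake_features(v), fake_yield(v))
  expect_equal(n_tiles(ts), 16)
  expect_equal(ts$tile_grid, c(4, 4))

  v2 <- v; v2[3, 3] <- NA                        # one bad pixel, tile (0,0)
  ts2 <- tile_field(fake_features(v2), fake_yield(v))
  expect_equal(n_tiles(ts2), 15)
  expect_false(any(ts2$row_idx == 0 & ts2$col_idx == 0))

  v3 <- matrix(1, 23, 21)
  ts3 <- tile_field(fake_features(v3), fake_yield(v3))
  expect_equal(ts3$tile_grid, c(4, 4))

  expect_error(tile_field(fake_features(v), fake_yield(matrix(1, 10, 10))),
               "different shapes")
})

test_that("tile then assemble is the identity on retained extents", {
  set.seed(22)
  v <- matrix(rnorm(400, 9), 20, 20)
  v[1, 1] <- NA                                   # excludes tile (0,0)
  ts <- tile_field(fake_features(v, mask = matrix(TRUE, 20, 20)),
                   fake_yield(v))
  back <- assemble_map(ts)
  expect_true(all(is.na(back$values[1:5, 1:5])))  # excluded tile -> nodata
  retained <- !is.na(back$values)
  expect_identical(back$values[retained], v[retained])

  # single retained tile: nodata everywhere else
  one <- ts[1]
  m1 <- assemble_map(one)
  expect_equal(sum(!is.na(m1$values)), 25)

  # difference map convention: observed - predicted
  pred <- ts$yield + 0.5
  dm <- difference_map(ts, pred)
  expect_equal(unique(round(dm$values[!is.na(dm$values)], 10)), -0.5)

  expect_error(assemble_map(ts, values = ts$yield[1:3, , , drop = FALSE]),
               "per retained tile")
})

test_that("temporal stacking intersects tiles across dates", {
  v <- matrix(rnorm(400, 9), 20, 20)
  f1 <- fake_features(v)
  y <- fake_yield(v)
  single <- tile_field(f1, y)
  sets <- replicate(5, single, simplify = FALSE)
  temporal <- stack_time(sets)
  expect_equal(temporal$n_dates, 5L)
  expect_equal(dim(temporal$features), c(16, 5, 5, 5, 7))
  # identical sets -> features constant along the date axis
  expect_equal(temporal$features[, , , 1, ], temporal$features[, , , 4, ])

  # a tile missing at one date is excluded from the temporal set
  v2 <- v; v2[8, 8] <- NA                        # kills tile (1,1)
  sets2 <- sets; sets2[[3]] <- tile_field(fake_features(v2), y)
  temporal2 <- stack_time(sets2)
  expect_equal(n_tiles(temporal2), 15)

  # n_dates = 1 is the input up to axis insertion
  t1 <- stack_time(list(single))
  expect_equal(drop(t1$features[, , , 1, ]), drop(single$features))
  expect_identical(t1$row_idx, single$row_idx)
})

test_that("fold partitioning is deterministic, disjoint, and near 50/25/25", {
  v <- matrix(1, 100, 100)                        # 20 x 20 tile grid
  ts <- tile_field(fake_features(v), fake_yield(v))
  folds <- partition_folds(ts)
  expect_length(folds, 4)
  expect_identical(vapply(folds, `[[`, "", "fold_id"), LETTERS[1:4])

  for (f in folds) {
    tab <- table(f$roles)
    expect_equal(unname(tab[["train"]]), 200, tolerance = 0.1)
    expect_true(abs(tab[["validation"]] - 100) <= 20)
    expect_true(abs(tab[["test"]] - 100) <= 20)
    # fractions within 5 points of 50/25/25
    fr <- tab / sum(tab)
    expect_lt(abs(fr[["train"]] - 0.5), 0.05)
    expect_lt(abs(fr[["validation"]] - 0.25), 0.05)
    expect_lt(abs(fr[["test"]] - 0.25), 0.05)
    # roles partition the tiles
    expect_equal(sum(tab), n_tiles(ts))
  }

  # deterministic
  folds2 <- partition_folds(ts)
  for (k in 1:4) expect_identical(folds[[k]]$roles, folds2[[k]]$roles)

  # every tile serves as test in exactly one fold
  test_count <- Reduce(`+`, lapply(folds, function(f) f$roles == "test"))
  expect_true(all(test_count == 1))

  # too-small grids are a configuration error
  tiny <- tile_field(fake_features(matrix(1, 15, 15)),
                     fake_yield(matrix(1, 15, 15)))
  expect_error(partition_folds(tiny), "too small")
})

test_that("fold roles are spatially coherent rectangles", {
  v <- matrix(1, 100, 100)
  ts <- tile_field(fake_features(v), fake_yield(v))
  fold <- partition_folds(ts)[[1]]
  # within each 5x5-tile block every tile has the same role
  block <- paste(fold$block_row, fold$block_col)
  role_per_block <- tapply(as.character(fold$roles), block,
                           function(r) length(unique(r)))
  expect_true(all(role_per_block == 1))
})

test_that("tile pixel tables round-trip through CSV", {
  ts <- small_tiles()
  df <- as.data.frame(ts)
  expect_equal(nrow(df), n_tiles(ts) * 25)
  expect_true(all(feature_names() %in% names(df)))

  path <- tempfile(fileext = ".csv")
  write_tiles_csv(ts, path)
  back <- read_tiles_csv(path, tile_grid = ts$tile_grid,
                         date_label = ts$dates)
  expect_equal(back$features, ts$features, tolerance = 1e-12)
  expect_equal(back$yield, ts$yield, tolerance = 1e-12)
  expect_identical(back$row_idx, ts$row_idx)
})
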