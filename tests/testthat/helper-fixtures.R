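# Shared fixtures built in code.  Heavy artifacts (trained networks) are
# memoized in this environment so several tests can share one training run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small single-date field fixture: 120 x 120 cells, booting stage
small_field_config <- function(seed = 5, ...) {
  field_config(height_px = 120L, width_px = 120L, buffer_cells = 10L,
               stage_labels = "booting", seed = seed, ...)
}

small_tiles <- function(seed = 5, ...) {
  memo(paste0("tiles_", seed, "_", paste(c(...), collapse = "_")), {
    field <- simulate_field(small_field_config(seed = seed, ...))
    feats <- build_feature_stack(field$stacks$booting)
    tile_field(feats, field$yield)
  })
}

# toy reflectance stack with hand-set band values
toy_stack <- function(nir = 0.5, red = 0.1, green = 0.2, blue = 0.15,
                      rededge = 0.3, thermal = 25, n = 2) {
  m <- function(v) matrix(v, n, n)
  structure(list(bands = list(blue = m(blue), green = m(green), red = m(red),
                              rededge = m(rededge), nir = m(nir)),
                 thermal = m(thermal), mask = matrix(TRUE, n, n),
                 date_label = "toy", stage = "booting"),
            class = "reflectance_stack")
}

# hand-built tile_set with given per-tile constant yields and features
# drawn from a function(feature index) -> n x 5 x 5 values
synthetic_tile_set <- function(n_side = 10, yield_fun, feature_fun,
                               seed = 1) {
  n <- n_side^2
  set.seed(seed)
  feats <- array(0, c(n, 5, 5, 7),
                 dimnames = list(NULL, NULL, NULL, feature_names()))
  yl <- array(0, c(n, 5, 5))
  idx <- expand.grid(col = 0:(n_side - 1), row = 0:(n_side - 1))
  for (k in seq_len(n)) {
    yl[k, , ] <- yield_fun(k)
    for (f in 1:7) feats[k, , , f] <- feature_fun(k, f)
  }
  structure(list(features = feats, yield = yl,
                 row_idx = as.integer(idx$row), col_idx = as.integer(idx$col),
                 tile_grid = c(n_side, n_side), size = 5L,
                 dates = "synthetic", n_dates = 1L),
            class = "tile_set")
}
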