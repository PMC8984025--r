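# Raster and tile serialization.  Rasters are written as single-channel
# 32-bit TIFF images; because the TIFF writer stores values in [0, 1], each
# layer is affinely rescaled on write and the scale, offset, nodata flag
# and band metadata are recorded in a JSON sidecar next to the file, which
# the reader uses to restore the original values.

raster_sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster layer to TIFF with a JSON sidecar
#'
#' @param values Numeric matrix (`NA` = nodata).
#' @param path Output `.tif` path; `<path>.json` is written alongside.
#' @param meta Named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(values, path, meta = list()) {
  nodata <- -9999
  v <- values
  v[is.na(v)] <- nodata
  lo <- min(v)
  hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L)
  side <- c(list(offset = lo, scale = scale, nodata = nodata,
                 nrow = nrow(values), ncol = ncol(values)), meta)
  jsonlite::write_json(side, raster_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster layer written by [write_raster_tiff()]
#'
#' @param path The `.tif` path.
#' @return A numeric matrix with `NA` at nodata cells; sidecar metadata is
#'   attached as the `"meta"` attribute.
#' @export
read_raster_tiff <- function(path) {
  side <- jsonlite::read_json(raster_sidecar_path(path), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * side$scale + side$offset
  v[abs(v - side$nodata) < 1e-3 * max(1, abs(side$nodata))] <- NA_real_
  attr(v, "meta") <- side[setdiff(names(side),
                                  c("offset", "scale", "nodata"))]
  v
}

#' Write a simulated field to a directory
#'
#' One TIFF per band per date plus the yield raster, and a `config.json`
#' sidecar recording the full field configuration and seed.
#'
#' @param field A `paddy_field` from [simulate_field()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "paddy_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster_tiff(field$yield$values, file.path(dir, "yield.tif"),
                    meta = list(layer = "yield", units = "Mg/ha"))
  for (d in names(field$stacks)) {
    st <- field$stacks[[d]]
    for (b in names(st$bands))
      write_raster_tiff(st$bands[[b]],
                        file.path(dir, sprintf("%s_%s.tif", d, b)),
                        meta = list(layer = b, date_label = d,
                                    stage = st$stage))
    write_raster_tiff(st$thermal, file.path(dir, sprintf("%s_thermal.tif", d)),
                      meta = list(layer = "thermal", date_label = d,
                                  stage = st$stage, units = "degC"))
  }
  cfg <- unclass(field$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reflectance stack for one date from a field directory
#'
#' @param dir Directory written by [write_field()] (or user-supplied TIFFs
#'   following the same `<date>_<band>.tif` naming).
#' @param date_label The date to read.
#' @return A `reflectance_stack`.
#' @export
read_reflectance_stack <- function(dir, date_label) {
  band_names <- c("blue", "green", "red", "rededge", "nir")
  bands <- lapply(band_names, function(b) {
    p <- file.path(dir, sprintf("%s_%s.tif", date_label, b))
    if (!file.exists(p)) stop_input("missing raster: ", p)
    read_raster_tiff(p)
  })
  names(bands) <- band_names
  tp <- file.path(dir, sprintf("%s_thermal.tif", date_label))
  if (!file.exists(tp)) stop_input("missing layer: thermal (", tp, ")")
  thermal <- read_raster_tiff(tp)
  stage <- attr(thermal, "meta")$stage %||% NA_character_
  mask <- Reduce(`&`, lapply(c(bands, list(thermal)), function(m) !is.na(m)))
  structure(list(bands = lapply(bands, function(m) { m[!mask] <- NA; m }),
                 thermal = { thermal[!mask] <- NA; thermal },
                 mask = mask, date_label = date_label, stage = stage),
            class = "reflectance_stack")
}

#' Read the yield raster from a field directory
#' @param dir Directory written by [write_field()].
#' @param resolution Cell size in meters recorded on the result.
#' @return A `yield_raster`.
#' @export
read_yield_raster <- function(dir, resolution = 0.5) {
  v <- read_raster_tiff(file.path(dir, "yield.tif"))
  attr(v, "meta") <- NULL
  structure(list(values = v, mask = !is.na(v), resolution = resolution),
            class = "yield_raster")
}

#' Serialize tiles to CSV
#'
#' One row per pixel (tile ids, pixel offsets, date for temporal sets, the
#' seven features, yield), the plain-text mirror of the tile arrays.
#'
#' @param tiles A `tile_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tiles_csv <- function(tiles, path) {
  utils::write.csv(as.data.frame(tiles), path, row.names = FALSE)
  invisible(path)
}

#' Read a single-date tile CSV back into a tile_set
#'
#' @param path CSV written by [write_tiles_csv()].
#' @param tile_grid Tile-grid dimensions (rows, cols).
#' @param size Tile edge in pixels.
#' @param date_label Date label to record.
#' @return A `tile_set`.
#' @export
read_tiles_csv <- function(path, tile_grid, size = 5L,
                           date_label = NA_character_) {
  df <- utils::read.csv(path)
  if ("date" %in% names(df))
    stop_input("temporal tile CSVs cannot be read back; rebuild with stack_time()")
  ids <- unique(df[c("tile", "row_idx", "col_idx")])
  ids <- ids[order(ids$tile), ]
  n <- nrow(ids)
  feats <- array(NA_real_, c(n, size, size, 7L),
                 dimnames = list(NULL, NULL, NULL, feature_names()))
  yl <- array(NA_real_, c(n, size, size))
  idx <- cbind(df$tile, df$row_off + 1L, df$col_off + 1L)
  for (f in seq_along(feature_names()))
    feats[cbind(idx, f)] <- df[[feature_names()[f]]]
  yl[idx] <- df$yield
  structure(list(features = feats, yield = yl,
                 row_idx = as.integer(ids$row_idx),
                 col_idx = as.integer(ids$col_idx),
                 tile_grid = as.integer(tile_grid), size = as.integer(size),
                 dates = date_label, n_dates = 1L),
            class = "tile_set")
}
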