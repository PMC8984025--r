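# Vegetation indices computed from named reflectance bands.  The seven
# model features are the six indices plus the raw thermal layer, in a fixed
# canonical order (alphabetical indices, then thermal) so every model sees
# the same feature layout.

#' Canonical feature names
#'
#' The fixed layer order used throughout the pipeline: the six vegetation
#' indices alphabetically, then the thermal band.
#'
#' @return Character vector of length 7.
#' @export
feature_names <- function() {
  c("CIgreen", "GNDVI", "NAVI", "NDVI", "RENDVI", "TGI", "thermal")
}

#' Names of the supported vegetation indices
#' @return Character vector of length 6.
#' @export
vi_names <- function() feature_names()[1:6]

# index formulas, elementwise on reflectance matrices; zero denominators
# yield NA (masked, not clipped)
vi_formulas <- list(
  NDVI = function(b) safe_div(b$nir - b$red, b$nir + b$red),
  CIgreen = function(b) safe_div(b$nir, b$green) - 1,
  RENDVI = function(b) safe_div(b$nir - b$rededge, b$nir + b$rededge),
  GNDVI = function(b) safe_div(b$nir - b$green, b$nir + b$green),
  NAVI = function(b) 1 - safe_div(b$red, b$nir),
  # TGI embeds the band center wavelengths 670/550/480 nm as constants
  TGI = function(b) -0.5 * ((670 - 480) * (b$red - b$green) -
                            (670 - 550) * (b$red - b$blue))
)

safe_div <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

required_bands <- list(
  NDVI = c("nir", "red"), CIgreen = c("nir", "green"),
  RENDVI = c("nir", "rededge"), GNDVI = c("nir", "green"),
  NAVI = c("red", "nir"), TGI = c("red", "green", "blue"))

#' Compute one vegetation index
#'
#' Applies the index formula elementwise to the named bands of a
#' reflectance stack.  Cells whose denominator is zero (band sums for the
#' normalized-difference indices, green for CIgreen, NIR for NAVI) are
#' masked `NA` rather than clipped.  Reflectance values outside `[0, 1]`
#' trigger a warning but are used as-is.
#'
#' The formulas are: NDVI `(nir-red)/(nir+red)`; CIgreen `nir/green - 1`;
#' RENDVI `(nir-rededge)/(nir+rededge)`; GNDVI `(nir-green)/(nir+green)`;
#' NAVI `1 - red/nir`; TGI `-0.5*[(670-480)*(red-green) -
#' (670-550)*(red-blue)]`.
#'
#' @param name One of `vi_names()`.
#' @param stack A `reflectance_stack` (or a named list of band matrices
#'   with elements among blue, green, red, rededge, nir).
#' @return A matrix of index values with `NA` at invalid cells.
#' @export
#' @examples
#' b <- list(nir = matrix(0.5), red = matrix(0.1))
#' compute_index("NDVI", b)   # 0.4 / 0.6
compute_index <- function(name, stack) {
  if (length(name) != 1L || !name %in% vi_names())
    stop_input("unknown index '", paste(name, collapse = ","),
               "'; supported: ", paste(vi_names(), collapse = ", "))
  bands <- if (inherits(stack, "reflectance_stack")) stack$bands else stack
  need <- required_bands[[name]]
  missing_b <- setdiff(need, names(bands))
  if (length(missing_b))
    stop_input("missing band(s) for ", name, ": ",
               paste(missing_b, collapse = ", "))
  vals <- unlist(lapply(bands[need], as.vector))
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    warning("reflectance values outside [0, 1] in bands used for ", name,
            call. = FALSE)
  vi_formulas[[name]](bands)
}

#' Assemble the 7-layer feature raster
#'
#' Computes the six vegetation indices from a reflectance stack and stacks
#' them with the thermal layer in the canonical order
#' (CIgreen, GNDVI, NAVI, NDVI, RENDVI, TGI, thermal).  The validity mask
#' is the intersection of the stack mask and per-index validity (zero
#' denominators); masked cells are `NA` in every layer.
#'
#' @param stack A `reflectance_stack` with all five bands and thermal.
#' @return A `feature_raster`: list with `features` (height x width x 7
#'   array, dimnames on layer axis), `mask`, `date_label`, `stage`.
#' @export
build_feature_stack <- function(stack) {
  if (!inherits(stack, "reflectance_stack"))
    stop_input("'stack' must be a reflectance_stack")
  need <- c("blue", "green", "red", "rededge", "nir")
  missing_b <- setdiff(need, names(stack$bands))
  if (length(missing_b))
    stop_input("missing reflectance layer(s): ",
               paste(missing_b, collapse = ", "))
  if (is.null(stack$thermal))
    stop_input("missing layer: thermal")
  dims <- dim(stack$thermal)
  for (b in need)
    if (!identical(dim(stack$bands[[b]]), dims))
      stop_input("band '", b, "' shape differs from thermal layer")

  layers <- lapply(vi_names(), compute_index, stack = stack)
  layers <- c(layers, list(stack$thermal))
  features <- array(NA_real_, c(dims, 7L),
                    dimnames = list(NULL, NULL, feature_names()))
  mask <- stack$mask
  for (i in seq_along(layers)) mask <- mask & is.finite(layers[[i]])
  for (i in seq_along(layers)) {
    li <- layers[[i]]
    li[!mask] <- NA_real_
    features[, , i] <- li
  }
  structure(list(features = features, mask = mask,
                 date_label = stack$date_label, stage = stack$stage),
            class = "feature_raster")
}

#' @export
print.feature_raster <- function(x, ...) {
  cat(sprintf("<feature_raster> '%s', %d x %d cells x 7 layers, %d valid\n",
              x$date_label %||% "?", dim(x$features)[1], dim(x$features)[2],
              sum(x$mask)))
  invisible(x)
}
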