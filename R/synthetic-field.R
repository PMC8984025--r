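# Synthetic field generator: spatially autocorrelated latent vigor, yield
# with harvester label noise, and stage-dependent multispectral/thermal
# reflectance, all pure functions of (config, seed).

# Stationary zero-mean unit-variance Gaussian random field with
# squared-exponential covariance cov(h) = exp(-(h/L)^2), sampled exactly by
# circulant embedding: the grid is embedded in a torus large enough that
# wrap-around covariance is negligible, the covariance eigenvalues are
# obtained by FFT, and one complex white-noise FFT yields the field in
# O(N log N).
grf_sample <- function(n_row, n_col, corr_cells, seed) {
  embed_dim <- function(n) {
    pad <- ceiling(6 * min(corr_cells, n))
    stats::nextn(max(2L * n, n + pad))
  }
  m1 <- embed_dim(n_row)
  m2 <- embed_dim(n_col)
  torus_dist <- function(m) pmin(0:(m - 1), m - (0:(m - 1)))
  d1 <- torus_dist(m1)
  d2 <- torus_dist(m2)
  covmat <- exp(-outer(d1^2, d2^2, "+") / corr_cells^2)
  lam <- Re(stats::fft(covmat))
  lam[lam < 0] <- 0            # clamp tiny negative embedding eigenvalues
  with_seed(seed, {
    w <- complex(real = stats::rnorm(m1 * m2),
                 imaginary = stats::rnorm(m1 * m2))
    z <- stats::fft(sqrt(lam) * matrix(w, m1, m2))
    Re(z)[seq_len(n_row), seq_len(n_col), drop = FALSE] / sqrt(m1 * m2)
  })
}

#' Simulate the latent vigor field
#'
#' Draws a stationary, spatially autocorrelated Gaussian field (zero mean,
#' unit variance, squared-exponential covariance) standing in for the soil
#' and water heterogeneity that drives intra-field yield variation.  The
#' autocorrelation at a lag of one correlation length is `exp(-1)`.
#'
#' @param config A [field_config()].
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return A `latent_field`: list with `values` (height x width matrix) and
#'   the correlation length in cells.
#' @export
#' @examples
#' cfg <- field_config(height_px = 60, width_px = 60, buffer_cells = 5)
#' lat <- simulate_latent(cfg)
#' sd(lat$values)
simulate_latent <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  corr_cells <- config$correlation_length / config$resolution
  values <- grf_sample(config$height_px, config$width_px, corr_cells, seed)
  structure(list(values = values, correlation_length_cells = corr_cells),
            class = "latent_field")
}

# curvilinear harvester-track artifact: periodic stripes whose phase is
# offset by a slow sinusoid in the row direction, giving the smoothly
# curving pattern a combine leaves when driving the field
harvester_tracks <- function(n_row, n_col, amplitude, spacing) {
  r <- matrix(0:(n_row - 1), n_row, n_col)
  cc <- matrix(0:(n_col - 1), n_row, n_col, byrow = TRUE)
  offset <- 2 * spacing * sin(2 * pi * r / (12 * spacing))
  amplitude * sin(2 * pi * (cc + offset) / spacing)
}

buffer_mask <- function(n_row, n_col, buffer) {
  mask <- matrix(TRUE, n_row, n_col)
  if (buffer > 0) {
    if (2 * buffer >= n_row || 2 * buffer >= n_col) {
      mask[] <- FALSE
    } else {
      idx_r <- c(seq_len(buffer), n_row - seq_len(buffer) + 1L)
      idx_c <- c(seq_len(buffer), n_col - seq_len(buffer) + 1L)
      mask[idx_r, ] <- FALSE
      mask[, idx_c] <- FALSE
    }
  }
  mask
}

#' Simulate the yield raster
#'
#' Yield is an affine transform of the latent vigor field,
#' `yield_mean + yield_sd * vigor`, plus an optional additive curvilinear
#' track artifact emulating combine-harvester label noise.  Yields are
#' clipped at zero (physical non-negativity) and cells within
#' `buffer_cells` of the field edge are masked invalid, mirroring the
#' edge-buffer exclusion applied to yield-monitor data.
#'
#' @param latent A `latent_field` from [simulate_latent()].
#' @param config The matching [field_config()].
#' @return A `yield_raster`: list with `values` (Mg/ha, `NA` outside the
#'   mask), logical `mask`, and `resolution` (m).
#' @export
simulate_yield <- function(latent, config) {
  stopifnot(inherits(latent, "latent_field"), inherits(config, "field_config"))
  v <- config$yield_mean + config$yield_sd * latent$values
  if (config$track_amplitude > 0)
    v <- v + harvester_tracks(nrow(v), ncol(v), config$track_amplitude,
                              config$track_spacing)
  v <- pmax(v, 0)
  mask <- buffer_mask(nrow(v), ncol(v), config$buffer_cells)
  v[!mask] <- NA_real_
  structure(list(values = v, mask = mask, resolution = config$resolution),
            class = "yield_raster")
}

# deterministic soil-texture field shared by all dates of one field
soil_texture <- function(config) {
  corr_cells <- config$soil_correlation_length / config$resolution
  grf_sample(config$height_px, config$width_px, corr_cells,
             config$seed + 101L)
}

# band link parameters: baseline reflectance of the scene and the
# logit-scale response of each band to canopy vigor.  NIR rises with vigor;
# red, green, blue and red-edge fall as a denser canopy absorbs more
# visible light.
band_links <- function() {
  list(base = c(blue = 0.08, green = 0.12, red = 0.10,
                rededge = 0.25, nir = 0.45),
       vigor = c(blue = -0.20, green = -0.50, red = -0.80,
                 rededge = -0.35, nir = 0.80))
}

# reflectance sensor floor: real radiometric products bottom out at the
# noise floor of the sensor, never at exactly zero, which keeps ratio
# indices (CIgreen, NAVI) defined everywhere
REFLECTANCE_FLOOR <- 0.005

#' Simulate one flyover's reflectance stack
#'
#' Generates the five reflectance bands (blue, green, red, red-edge, NIR,
#' unitless in `[0, 1]`) and the thermal layer (degrees C) for a given
#' growth stage.  Each band is a monotone (logistic-squashed affine)
#' function of latent vigor whose gain depends on the stage: near zero
#' before emergence, maximal at booting/flowering, attenuated at
#' maturation.  NIR increases and red decreases with vigor; thermal
#' decreases with vigor (evaporative cooling of a transpiring canopy).  A
#' fine-grained soil texture, attenuated as the canopy closes, keeps
#' bare-soil scenes from being featureless, and i.i.d. sensor noise is
#' added per band.
#'
#' @param latent A `latent_field`.
#' @param stage A growth-stage label (a name of [stage_gains()]).
#' @param config The matching [field_config()].
#' @param date_label Identifier for the acquisition; defaults to the stage.
#' @param seed Seed for the sensor noise of this date.
#' @param mask Optional validity mask to apply (defaults to all valid).
#' @return A `reflectance_stack`: named band matrices, `thermal`, `mask`,
#'   `date_label` and `stage`.
#' @export
simulate_reflectance <- function(latent, stage, config, date_label = stage,
                                 seed = config$seed + 211L, mask = NULL) {
  stopifnot(inherits(latent, "latent_field"), inherits(config, "field_config"))
  gains <- stage_gains()
  if (!stage %in% names(gains))
    stop_input("unknown growth stage '", stage, "'; known stages: ",
               paste(names(gains), collapse = ", "))
  g <- gains[[stage]]
  links <- band_links()
  soil <- if (config$soil_texture_sd > 0 && g < 1)
    soil_texture(config) else 0
  n1 <- nrow(latent$values); n2 <- ncol(latent$values)
  if (is.null(mask)) mask <- matrix(TRUE, n1, n2)

  bands <- with_seed(seed, {
    out <- lapply(names(links$base), function(b) {
      lin <- stats::qlogis(links$base[[b]]) +
        links$vigor[[b]] * g * latent$values +
        (1 - g) * config$soil_texture_sd * soil
      v <- stats::plogis(lin)
      if (config$sensor_noise_sd > 0)
        v <- v + matrix(stats::rnorm(n1 * n2, sd = config$sensor_noise_sd),
                        n1, n2)
      pmin(pmax(v, REFLECTANCE_FLOOR), 1)
    })
    names(out) <- names(links$base)
    thermal <- 30 - 4 * g * latent$values + (1 - g) * 1.5 * soil
    if (config$thermal_noise_sd > 0)
      thermal <- thermal +
        matrix(stats::rnorm(n1 * n2, sd = config$thermal_noise_sd), n1, n2)
    c(out, list(thermal = thermal))
  })
  thermal <- bands$thermal
  bands$thermal <- NULL
  for (b in names(bands)) bands[[b]][!mask] <- NA_real_
  thermal[!mask] <- NA_real_
  structure(list(bands = bands, thermal = thermal, mask = mask,
                 date_label = date_label, stage = stage),
            class = "reflectance_stack")
}

#' Simulate a complete multi-date field
#'
#' Draws the latent vigor field once, derives the yield raster and one
#' reflectance stack per configured flyover date, and co-masks everything
#' on the edge-buffer mask so no valid feature pixel exists where yield is
#' masked.
#'
#' @param config A [field_config()].
#' @return A `paddy_field`: list with `config`, `latent`, `yield`
#'   (a `yield_raster`) and `stacks` (named list of `reflectance_stack`,
#'   one per date in `config$stage_labels`).
#' @export
#' @examples
#' cfg <- field_config(height_px = 60, width_px = 60, buffer_cells = 5,
#'                     stage_labels = "booting")
#' field <- simulate_field(cfg)
#' field$yield
simulate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  latent <- simulate_latent(config)
  yield <- simulate_yield(latent, config)
  stacks <- lapply(seq_along(config$stage_labels), function(i) {
    simulate_reflectance(latent, config$stage_labels[[i]], config,
                         date_label = config$stage_labels[[i]],
                         seed = config$seed + 211L + 37L * i,
                         mask = yield$mask)
  })
  names(stacks) <- config$stage_labels
  structure(list(config = config, latent = latent, yield = yield,
                 stacks = stacks),
            class = "paddy_field")
}

#' @export
print.yield_raster <- function(x, ...) {
  ok <- x$values[x$mask]
  cat(sprintf("<yield_raster> %d x %d cells, %d valid\n", nrow(x$values),
              ncol(x$values), sum(x$mask)))
  if (length(ok))
    cat(sprintf("  yield: mean %.2f, sd %.2f Mg/ha\n", mean(ok),
                stats::sd(ok)))
  invisible(x)
}

#' @export
print.reflectance_stack <- function(x, ...) {
  cat(sprintf("<reflectance_stack> '%s' (%s), %d x %d cells, %d valid\n",
              x$date_label, x$stage, nrow(x$thermal), ncol(x$thermal),
              sum(x$mask)))
  invisible(x)
}

#' @export
print.paddy_field <- function(x, ...) {
  cat(sprintf("<paddy_field> %d x %d cells, %d date(s): %s\n",
              x$config$height_px, x$config$width_px, x$config$n_dates,
              paste(names(x$stacks), collapse = ", ")))
  invisible(x)
}
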