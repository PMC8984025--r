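#' Growth stages with a defined canopy signal gain
#'
#' The simulator couples reflectance to the latent vigor field with a
#' stage-specific gain: essentially zero before emergence (the sensor sees
#' bare soil), rising through tillering, maximal around booting/flowering
#' when canopy contrast between high- and low-yielding areas peaks, and
#' attenuated during grain fill and maturation as leaves senesce.
#'
#' @return Named numeric vector of gains in `[0, 1]`, one per known stage.
#' @export
#' @examples
#' stage_gains()
stage_gains <- function() {
  c(pre_emergence      = 0,
    tillering          = 0.35,
    panicle_initiation = 0.70,
    booting            = 1.00,
    flowering          = 0.95,
    grain_fill         = 0.60,
    maturation         = 0.40)
}

#' Configuration for a synthetic rice field
#'
#' Describes one simulated field on a 50 cm analysis grid: its size, the
#' first and second moments of grain yield, the spatial autocorrelation
#' scale of the latent vigor field that drives both yield and canopy
#' reflectance, the flyover dates (as growth-stage labels), sensor and
#' label noise, and the edge buffer excluded from analysis.
#'
#' Defaults emulate the field statistics the pipeline was designed around:
#' yield 9.06 +/- 0.9 Mg/ha, a 10 m edge buffer (20 cells at 50 cm), and
#' harvester track artifacts spaced one 8.5 m header width apart
#' (17 cells).
#'
#' @param height_px,width_px Grid size in 50 cm cells.
#' @param yield_mean,yield_sd Target yield moments, Mg/ha. `yield_sd = 0`
#'   gives a constant field (useful for degenerate-case checks).
#' @param correlation_length Autocorrelation scale of the latent vigor
#'   field, in meters: the lag at which autocorrelation drops to `exp(-1)`.
#' @param resolution Cell size in meters (0.5 for the 50 cm grid).
#' @param stage_labels Ordered growth-stage labels, one per flyover date;
#'   must be names of [stage_gains()].
#' @param sensor_noise_sd I.i.d. additive reflectance noise per band,
#'   reflectance units.
#' @param thermal_noise_sd I.i.d. additive thermal noise, degrees C.
#' @param track_amplitude Amplitude (Mg/ha) of the curvilinear
#'   combine-harvester label-noise artifact; 0 disables it.
#' @param track_spacing Spacing of harvester tracks in cells (17 cells =
#'   one 8.5 m header width).
#' @param buffer_cells Width of the masked edge buffer in cells.
#' @param soil_texture_sd Logit-scale amplitude of the fine-grained soil
#'   background texture visible before canopy closure.
#' @param soil_correlation_length Autocorrelation scale of the soil
#'   texture, meters.
#' @param seed Integer seed; all generation is a pure function of
#'   (config, seed).
#' @return An object of class `field_config`.
#' @export
#' @examples
#' cfg <- field_config(height_px = 100, width_px = 100, buffer_cells = 5)
#' cfg
field_config <- function(height_px = 400L, width_px = 400L,
                         yield_mean = 9.06, yield_sd = 0.9,
                         correlation_length = 10, resolution = 0.5,
                         stage_labels = c("tillering", "panicle_initiation",
                                          "booting", "flowering",
                                          "grain_fill"),
                         sensor_noise_sd = 0.05, thermal_noise_sd = 1.0,
                         track_amplitude = 0.25, track_spacing = 17,
                         buffer_cells = 20L,
                         soil_texture_sd = 0.15,
                         soil_correlation_length = 1,
                         seed = 1L) {
  cfg <- list(
    height_px = check_count(height_px, "height_px"),
    width_px = check_count(width_px, "width_px"),
    yield_mean = check_number(yield_mean, "yield_mean", min = 0),
    yield_sd = check_number(yield_sd, "yield_sd", min = 0),
    correlation_length = check_number(correlation_length,
                                      "correlation_length", 0, strict = TRUE),
    resolution = check_number(resolution, "resolution", 0, strict = TRUE),
    stage_labels = as.character(stage_labels),
    sensor_noise_sd = check_number(sensor_noise_sd, "sensor_noise_sd", 0),
    thermal_noise_sd = check_number(thermal_noise_sd, "thermal_noise_sd", 0),
    track_amplitude = check_number(track_amplitude, "track_amplitude", 0),
    track_spacing = check_number(track_spacing, "track_spacing", 0,
                                 strict = TRUE),
    buffer_cells = check_count(buffer_cells, "buffer_cells", min = 0L),
    soil_texture_sd = check_number(soil_texture_sd, "soil_texture_sd", 0),
    soil_correlation_length = check_number(soil_correlation_length,
                                           "soil_correlation_length", 0,
                                           strict = TRUE),
    seed = check_count(seed, "seed", min = 0L))
  if (length(cfg$stage_labels) < 1L)
    stop_input("at least one stage label is required")
  unknown <- setdiff(cfg$stage_labels, names(stage_gains()))
  if (length(unknown))
    stop_input("unknown growth stage(s): ", paste(unknown, collapse = ", "),
               "; known stages: ", paste(names(stage_gains()), collapse = ", "))
  cfg$n_dates <- length(cfg$stage_labels)
  structure(cfg, class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  cat("<field_config>\n")
  cat(sprintf("  grid: %d x %d cells at %.2g m (%.1f ha)\n", x$height_px,
              x$width_px, x$resolution,
              x$height_px * x$width_px * x$resolution^2 / 1e4))
  cat(sprintf("  yield: %.2f +/- %.2f Mg/ha, correlation length %.3g m\n",
              x$yield_mean, x$yield_sd, x$correlation_length))
  cat(sprintf("  dates: %s\n", paste(x$stage_labels, collapse = ", ")))
  cat(sprintf("  noise: sensor %.3g, thermal %.3g C, tracks %.3g Mg/ha / %g cells\n",
              x$sensor_noise_sd, x$thermal_noise_sd, x$track_amplitude,
              x$track_spacing))
  cat(sprintf("  buffer: %d cells; seed %d\n", x$buffer_cells, x$seed))
  invisible(x)
}
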