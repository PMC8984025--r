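# Synthetic field generator: determinism, spatial structure, yield moments,
# reflectance-vigor coupling.

test_that("generation is a pure function of (config, seed)", {
  cfg <- field_config(height_px = 60, width_px = 60, buffer_cells = 5,
                      stage_labels = "booting", seed = 42)
  f1 <- simulate_field(cfg)
  f2 <- simulate_field(cfg)
  expect_identical(f1$latent$values, f2$latent$values)
  expect_identical(f1$yield$values, f2$yield$values)
  expect_identical(f1$stacks$booting$bands$nir, f2$stacks$booting$bands$nir)
  expect_identical(f1$stacks$booting$thermal, f2$stacks$booting$thermal)
  # a different seed gives a different realization
  f3 <- simulate_field(field_config(height_px = 60, width_px = 60,
                                    buffer_cells = 5,
                                    stage_labels = "booting", seed = 43))
  expect_false(identical(f1$latent$values, f3$latent$values))
})

test_that("latent field is standardized and spatially correlated at the configured scale", {
  cfg <- field_config(height_px = 400, width_px = 400,
                      correlation_length = 10, seed = 3)  # 20 cells
  lat <- simulate_latent(cfg)
  expect_equal(dim(lat$values), c(400, 400))
  expect_lt(abs(stats::var(as.vector(lat$values)) - 1), 0.2)
  expect_lt(abs(mean(lat$values)), 0.3)

  lag20 <- cor(as.vector(lat$values[, 1:380]), as.vector(lat$values[, 21:400]))
  expect_gt(lag20, 0.22)
  expect_lt(lag20, 0.52)

  # oracle: direct covariance-matrix Cholesky sampling on a 50 x 50 subgrid.
  # Small-domain empirical autocorrelation is biased low, so the FFT field
  # is measured on 50 x 50 subgrids too and the two estimators (same
  # domain size, same statistic) are compared.
  n <- 50; L <- 20
  subgrid_acf <- function(z)
    cor(as.vector(z[, 1:(n - 20)]), as.vector(z[, 21:n]))
  coords <- expand.grid(r = 1:n, c = 1:n)
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / L^2)
  Cf <- chol(K + diag(1e-8, n^2))
  set.seed(99)
  oracle_acf <- replicate(16, {
    z <- matrix(drop(crossprod(Cf, rnorm(n^2))), n, n)
    subgrid_acf(z)
  })
  offs <- seq(0, 350, by = 50)
  fft_acf <- as.vector(outer(offs, offs, Vectorize(function(i, j)
    subgrid_acf(lat$values[i + 1:n, j + 1:n]))))
  expect_lt(abs(mean(oracle_acf) - mean(fft_acf)), 0.15)
})

test_that("perfect-correlation limit collapses to a spatial constant", {
  cfg <- field_config(height_px = 100, width_px = 100,
                      correlation_length = 5e5, seed = 4)
  lat <- simulate_latent(cfg)
  expect_lt(stats::sd(lat$values), 0.01)
})

test_that("simulated yield hits the configured moments", {
  means <- sds <- numeric(5)
  for (i in 1:5) {
    cfg <- field_config(seed = 100 + i)        # default 400 x 400, 9.06/0.9
    lat <- simulate_latent(cfg)
    y <- simulate_yield(lat, cfg)
    ok <- y$values[y$mask]
    means[i] <- mean(ok)
    sds[i] <- stats::sd(ok)
  }
  expect_gt(mean(means), 8.96)
  expect_lt(mean(means), 9.16)
  expect_gt(mean(sds), 0.8)
  expect_lt(mean(sds), 1.0)
})

test_that("degenerate variance gives a constant raster and buffers count cells", {
  cfg <- field_config(height_px = 10, width_px = 10, yield_sd = 0,
                      track_amplitude = 0, buffer_cells = 2, seed = 1)
  y <- simulate_yield(simulate_latent(cfg), cfg)
  expect_equal(sum(y$mask), 36)                 # (10 - 2*2)^2
  expect_true(all(y$values[y$mask] == cfg$yield_mean))
  expect_true(all(is.na(y$values[!y$mask])))
})

test_that("yields are clipped at zero", {
  cfg <- field_config(height_px = 80, width_px = 80, yield_mean = 0.5,
                      yield_sd = 5, buffer_cells = 0, track_amplitude = 0,
                      seed = 2)
  y <- simulate_yield(simulate_latent(cfg), cfg)
  expect_gte(min(y$values), 0)
  expect_gt(mean(y$values == 0), 0)             # clipping actually engaged
})

test_that("reflectance couples to vigor with stage-dependent gain", {
  cfg <- field_config(height_px = 400, width_px = 400, sensor_noise_sd = 0,
                      thermal_noise_sd = 0, track_amplitude = 0,
                      buffer_cells = 0, seed = 6,
                      stage_labels = c("pre_emergence", "booting"))
  lat <- simulate_latent(cfg)
  y <- simulate_yield(lat, cfg)
  boot <- simulate_reflectance(lat, "booting", cfg)
  expect_gt(cor(as.vector(boot$bands$nir), as.vector(y$values)), 0.9)
  expect_lt(cor(as.vector(boot$thermal), as.vector(y$values)), -0.9)
  expect_lt(cor(as.vector(boot$bands$red), as.vector(y$values)), -0.9)

  pre <- simulate_reflectance(lat, "pre_emergence", cfg)
  expect_lt(abs(cor(as.vector(pre$bands$nir), as.vector(y$values))), 0.05)

  # all bands in range
  for (b in pre$bands) expect_true(all(b >= 0 & b <= 1))
})

test_that("equal vigor cells give identical band vectors without noise", {
  cfg <- field_config(height_px = 4, width_px = 4, sensor_noise_sd = 0,
                      thermal_noise_sd = 0, seed = 1)
  lat <- structure(list(values = matrix(c(0.7, -1, 0.2, 0.7), 2, 2),
                        correlation_length_cells = 1),
                   class = "latent_field")
  st <- simulate_reflectance(lat, "booting", cfg)   # gain 1: soil term off
  for (b in st$bands) expect_identical(b[1, 1], b[2, 2])
  expect_identical(st$thermal[1, 1], st$thermal[2, 2])
})

test_that("CIgreen contrast between yield deciles peaks at booting, not pre-emergence", {
  cfg <- field_config(height_px = 200, width_px = 200, buffer_cells = 0,
                      track_amplitude = 0, seed = 8,
                      stage_labels = c("pre_emergence", "booting"))
  field <- simulate_field(cfg)
  y <- as.vector(field$yield$values)
  contrast <- function(stage) {
    cig <- compute_index("CIgreen", field$stacks[[stage]])
    hi <- y >= stats::quantile(y, 0.9)
    lo <- y <= stats::quantile(y, 0.1)
    mean(cig[hi]) - mean(cig[lo])
  }
  expect_gt(contrast("booting"), contrast("pre_emergence") + 0.5)
})

test_that("masks propagate: no valid feature pixel where yield is masked", {
  field <- simulate_field(small_field_config())
  feats <- build_feature_stack(field$stacks$booting)
  expect_true(all(is.na(feats$features[, , 1][!field$yield$mask])))
  expect_true(!any(feats$mask & !field$yield$mask))
})

test_that("invalid configurations are rejected", {
  expect_error(field_config(height_px = 0), "height_px")
  expect_error(field_config(correlation_length = 0), "correlation_length")
  expect_error(field_config(buffer_cells = -1), "buffer_cells")
  expect_error(field_config(stage_labels = "ripening"), "unknown growth stage")
  cfg <- field_config(height_px = 20, width_px = 20)
  expect_error(simulate_reflectance(simulate_latent(cfg), "harvest", cfg),
               "unknown growth stage")
})
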