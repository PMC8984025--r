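# Shared heavy fixture for the model-ranking, denoising and reduced-data
# checks: one simulated field per seed (booting stage, spatially correlated
# yield, harvester label noise, default sensor noise), fold B, with the
# null / linear / 2D-CNN models trained under the full 50-epoch protocol.
# Memoized so the ranking, map-smoothness and reduced-training tests reuse
# the same trained networks.

ranking_run <- function(seed) {
  memo(paste0("ranking_", seed), {
    cfg <- field_config(height_px = 200L, width_px = 200L,
                        buffer_cells = 10L, stage_labels = "booting",
                        seed = seed)
    field <- simulate_field(cfg)
    feats <- build_feature_stack(field$stacks$booting)
    tiles <- tile_field(feats, field$yield)
    fold <- partition_folds(tiles)[[2]]
    null <- yield_model(tiles, "null", fold = fold)
    linear <- yield_model(tiles, "linear", fold = fold)
    cnn <- yield_model(tiles, "cnn2d", fold = fold, epochs = 50,
                       seed = seed)
    test <- tiles[fold$roles == "test"]
    list(tiles = tiles, fold = fold, test = test,
         null = null, linear = linear, cnn = cnn,
         rmse = c(null = evaluate_model(null, test)$rmse,
                  linear = evaluate_model(linear, test)$rmse,
                  cnn = evaluate_model(cnn, test)$rmse))
  })
}

ranking_seeds <- c(5L, 11L, 23L)

# mean squared difference between adjacent predicted pixels of a map
high_freq_energy <- function(map) {
  v <- map$values
  dh <- (v[, -1] - v[, -ncol(v)])^2
  dv <- (v[-1, ] - v[-nrow(v), ])^2
  mean(c(dh[!is.na(dh)], dv[!is.na(dv)]))
}
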