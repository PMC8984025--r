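# The five model kinds: closed-form behaviors, hyperparameter contracts,
# architecture conformance, and the training engine's checkpointing.

test_that("null model predicts the training mean and its training RMSE is the population sd", {
  ts <- synthetic_tile_set(4, yield_fun = function(k) k %% 2 * 2 + 8,
                           feature_fun = function(k, f) 0)
  m <- yield_model(ts, "null")
  expect_equal(unname(coef(m)), 9)               # yields alternate 8, 10
  p <- predict(m, ts)
  expect_true(all(p == 9))

  y <- as.vector(ts$yield)
  rep <- evaluate_model(m, ts)
  pop_sd <- sqrt(mean((y - mean(y))^2))
  expect_equal(rep$rmse, pop_sd)
  expect_false(rep$r2_defined)                   # constant predictions: n.d.
})

test_that("OLS recovers exact coefficients and flags aliased columns", {
  ndvi_i <- match("NDVI", feature_names())
  set.seed(41)
  ts <- synthetic_tile_set(6,
    yield_fun = function(k) 0,
    feature_fun = function(k, f) if (f == ndvi_i) matrix(runif(25), 5) else 0)
  ts$yield <- 2 + 3 * ts$features[, , , ndvi_i]
  expect_warning(m <- yield_model(ts, "linear"), "aliased")
  co <- coef(m)
  expect_equal(unname(co["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["NDVI"]), 3, tolerance = 1e-8)
  expect_true(all(is.na(co[setdiff(feature_names(), "NDVI")])))
  expect_setequal(m$aliased, setdiff(feature_names(), "NDVI"))

  # predictions equal the per-pixel dot-product oracle
  p <- predict(m, ts)
  oracle <- 2 + 3 * ts$features[, , , ndvi_i]
  expect_equal(p, oracle, tolerance = 1e-8)
})

test_that("OLS coefficient recovery under noise stays within 3 standard errors", {
  set.seed(42)
  beta <- c(0.5, -0.3, 0.2, 0.8, -0.6, 0.1, 0.05)
  ts <- synthetic_tile_set(20,                   # 400 tiles = 10,000 px
    yield_fun = function(k) 0,
    feature_fun = function(k, f) matrix(rnorm(25), 5))
  df <- as.data.frame(ts)
  df$yield <- 9 + as.matrix(df[feature_names()]) %*% beta +
    rnorm(nrow(df), 0, 0.1)
  ts$yield[cbind(df$tile, df$row_off + 1, df$col_off + 1)] <- df$yield
  m <- yield_model(ts, "linear")
  est <- summary(m$fit)$coefficients
  for (i in seq_along(beta)) {
    row <- est[feature_names()[i], ]
    expect_lt(abs(row["Estimate"] - beta[i]), 3 * row["Std. Error"])
  }
})

test_that("boosted trees fit steps better than lines and honor their hyperparameters", {
  ndvi_i <- match("NDVI", feature_names())
  set.seed(43)
  ts <- synthetic_tile_set(8,
    yield_fun = function(k) 0,
    feature_fun = function(k, f) if (f == ndvi_i) matrix(runif(25), 5) else
      matrix(rnorm(25), 5))
  ts$yield <- 8 + 2 * (ts$features[, , , ndvi_i] > 0.5)   # step function

  mx <- yield_model(ts, "xgboost")
  ml <- yield_model(ts, "linear")
  expect_lt(evaluate_model(mx, ts)$rmse, evaluate_model(ml, ts)$rmse)

  # depth-2 constraint: no path tests more than 2 features
  dt <- xgboost::xgb.model.dt.tree(model = mx$fit)
  depth_of <- function(tree) {
    d <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$ID)
    d[tree$ID[1]] <- 0L
    for (i in seq_len(nrow(tree))) {
      if (tree$Feature[i] != "Leaf") {
        d[tree$Yes[i]] <- d[tree$ID[i]] + 1L
        d[tree$No[i]] <- d[tree$ID[i]] + 1L
      }
    }
    max(d[tree$ID[tree$Feature != "Leaf"]], na.rm = TRUE)
  }
  depths <- vapply(split(as.data.frame(dt), dt$Tree), depth_of, numeric(1))
  expect_true(all(depths <= 1))   # root depth 0, so interior nodes <= depth 1
  expect_equal(max(dt$Tree) + 1, 200)     # all 200 boosting rounds present

  # nrounds = 0 predicts the base score (training mean)
  m0 <- yield_model(ts, "xgboost", nrounds = 0)
  expect_true(all(predict(m0, ts) == mean(ts$yield)))
})

test_that("CNN architectures conform to the published layer table", {
  s2 <- build_cnn2d()
  s3 <- build_cnn3d()
  expect_equal(s2$n_params, 3558529)
  expect_equal(s3$n_params, 3763201)

  # encoder output before flatten is 5 x 5 x 256 for both networks
  expect_equal(s2$layers[[3]]$out_dim, c(5, 5))
  expect_equal(s2$layers[[3]]$cout, 256)
  expect_equal(s3$layers[[3]]$out_dim, c(5, 5, 1))   # (1,1,5) valid collapse
  expect_equal(s3$layers[[3]]$pout, 25)
  expect_equal(s3$layers[[3]]$cout, 256)

  # dense bottleneck: 6,400 units feed the (5,5,256) reshape
  expect_equal(s2$layers[[5]]$cin, 6400)
  expect_equal(s2$layers[[6]]$cout, 6400)
  expect_equal(s2$layers[[7]]$pout * s2$layers[[7]]$cin, 6400)

  # kernels as printed
  expect_equal(s2$layers[[1]]$kernel, c(3L, 3L))
  expect_equal(s3$layers[[1]]$kernel, c(3L, 3L, 3L))
  expect_equal(s3$layers[[2]]$kernel, c(2L, 2L, 3L))
  expect_equal(s3$layers[[3]]$kernel, c(1L, 1L, 5L))

  # final layer linear, all others relu
  relus <- vapply(s2$layers, `[[`, TRUE, "relu")
  expect_false(relus[[length(relus)]])
  expect_true(all(relus[vapply(s2$layers, function(l)
    l$type %in% c("conv", "dense"), TRUE)][1:7]))
})

test_that("an untrained network with zero output bias maps zeros to zeros", {
  ts <- synthetic_tile_set(4, yield_fun = function(k) 0,
                           feature_fun = function(k, f) 0)
  fold <- list(roles = factor(rep(c("train", "validation", "test"),
                                  length.out = 16),
                              levels = c("train", "validation", "test")),
               fold_id = "A")
  class(fold) <- "fold_spec"
  m <- yield_model(ts, "cnn2d", fold = fold, epochs = 0)
  # training mean is 0, so the output bias is 0 and zero input stays zero
  p <- predict(m, ts)
  expect_equal(max(abs(p)), 0)
})

test_that("CNN training checkpoints the best validation epoch and learns a constant", {
  set.seed(44)
  ts <- synthetic_tile_set(8, yield_fun = function(k) 9,
                           feature_fun = function(k, f) matrix(rnorm(25), 5))
  fold <- partition_folds(ts)[[1]]
  m <- yield_model(ts, "cnn2d", fold = fold, epochs = 15, seed = 3)
  expect_equal(nrow(m$history), 15)
  expect_equal(m$best_val_loss, min(m$history$val_mse))
  expect_equal(m$history$val_mse[m$best_epoch], m$best_val_loss)

  # constant labels are trivially learnable: val RMSE < 5% of the constant
  expect_lt(sqrt(m$best_val_loss), 0.05 * 9)

  # prediction is deterministic
  p1 <- predict(m, ts)
  p2 <- predict(m, ts)
  expect_identical(p1, p2)

  # retraining with the same seed reproduces the weights bit for bit
  m2 <- yield_model(ts, "cnn2d", fold = fold, epochs = 15, seed = 3)
  expect_identical(m$weights, m2$weights)
  expect_false(identical(
    m$weights,
    yield_model(ts, "cnn2d", fold = fold, epochs = 15, seed = 4)$weights))
})

test_that("a trained 2D-CNN beats the null model on simulator output", {
  ts <- small_tiles(seed = 5)
  fold <- partition_folds(ts)[[2]]
  null <- yield_model(ts, "null", fold = fold)
  cnn <- memo("cnn_small_5", yield_model(ts, "cnn2d", fold = fold,
                                         epochs = 15, seed = 5))
  e_null <- evaluate_model(null, ts, roles = fold$roles)
  e_cnn <- evaluate_model(cnn, ts, roles = fold$roles)
  expect_lt(e_cnn$rmse, e_null$rmse)
})

test_that("model-kind and tile-shape mismatches are rejected", {
  ts <- small_tiles()
  expect_error(yield_model(ts, "cnn3d"), "5 dates")
  temporal <- stack_time(replicate(5, ts, simplify = FALSE))
  expect_error(yield_model(temporal, "linear"), "single-date")
  expect_error(yield_model(temporal, "cnn2d"), "single-date")
  fold <- partition_folds(ts)[[1]]
  m <- yield_model(ts, "null", fold = fold)
  expect_error(predict(yield_model(ts, "linear", fold = fold), temporal),
               "single-date")
})
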