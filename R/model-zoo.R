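# The five competing yield models behind one fitting interface.  The
# per-pixel models (null, linear, boosted trees) see each 50 cm pixel's
# seven features independently; the convolutional autoencoders map a whole
# 5x5 patch (optionally across five dates) to a 5x5 yield patch.

#' Fit a yield prediction model
#'
#' Fits one of the five competing models to the training tiles of a fold:
#'
#' * `"null"` - predicts the mean yield over all training pixels.
#' * `"linear"` - ordinary least squares on the seven per-pixel features,
#'   via [stats::lm()]; aliased (rank-deficient) columns are reported and
#'   dropped.
#' * `"xgboost"` - gradient boosted regression trees on the same per-pixel
#'   features (squared-error objective, `eta = 0.2`, `max_depth = 2`,
#'   `nrounds = 200`, base score = training mean, no subsampling).
#' * `"cnn2d"` / `"cnn3d"` - the convolutional autoencoders of
#'   [build_cnn2d()]/[build_cnn3d()], trained for `epochs` epochs of
#'   mean-squared-error loss with the adaptive-moment (Adam) optimizer;
#'   after every epoch the validation loss is recorded and the returned
#'   weights are those of the best validation epoch.  Features are
#'   standardized (mean/sd fitted on the training fold only) and the
#'   output bias starts at the training-mean yield.
#'
#' @param tiles A `tile_set` (single-date for all kinds but `"cnn3d"`,
#'   which needs a 5-date temporal set).
#' @param kind Model kind.
#' @param fold A `fold_spec` from [partition_folds()], or `NULL` to train
#'   on all tiles (not available for the CNNs, which need a validation
#'   split).
#' @param epochs,batch_size,learning_rate CNN training protocol (defaults
#'   50 / 32 / 1e-3).
#' @param eta,max_depth,nrounds Boosted-trees hyperparameters.
#' @param seed Seed for all stochastic parts (weight initialisation, batch
#'   shuffling).
#' @param ... Unused.
#' @return An object of class `c("yield_<kind>", "yield_model")` with the
#'   fitted parameters, the feature normalizer, per-epoch training history
#'   (CNNs), and provenance (`fold_id`, `dates`, `seed`).
#' @seealso [predict.yield_model()], [evaluate_model()],
#'   [feature_importance()]
#' @export
#' @examples
#' cfg <- field_config(height_px = 60, width_px = 60, buffer_cells = 2,
#'                     stage_labels = "booting", seed = 7)
#' field <- simulate_field(cfg)
#' feats <- build_feature_stack(field$stacks$booting)
#' tiles <- tile_field(feats, field$yield)
#' m <- yield_model(tiles, "null")
#' predict(m, tiles[1])[1, 1, 1]
yield_model <- function(tiles,
                        kind = c("null", "linear", "xgboost", "cnn2d",
                                 "cnn3d"),
                        fold = NULL, epochs = 50L, batch_size = 32L,
                        learning_rate = 1e-3, eta = 0.2, max_depth = 2L,
                        nrounds = 200L, seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(tiles, "tile_set"))
  if (!is.null(fold)) {
    if (!inherits(fold, "fold_spec"))
      stop_input("'fold' must be a fold_spec")
    if (length(fold$roles) != n_tiles(tiles))
      stop_input("fold roles do not match the number of tiles")
  }
  if (kind == "cnn3d") {
    if (tiles$n_dates != 5L)
      stop_input("cnn3d requires a temporal tile_set with exactly 5 dates")
  } else if (kind %in% c("cnn2d") && tiles$n_dates != 1L) {
    stop_input("cnn2d requires a single-date tile_set")
  } else if (kind %in% c("linear", "xgboost", "null") && tiles$n_dates != 1L) {
    stop_input("per-pixel models require a single-date tile_set")
  }

  roles <- if (is.null(fold)) factor(rep("train", n_tiles(tiles)),
                                     levels = c("train", "validation", "test"))
           else fold$roles
  train <- tiles[roles == "train"]
  if (n_tiles(train) == 0L) stop_input("no training tiles")

  obj <- list(kind = kind, fold_id = if (is.null(fold)) NA_character_
              else fold$fold_id,
              dates = tiles$dates, n_dates = tiles$n_dates, seed = seed,
              features = feature_names(), call = match.call())

  if (kind == "null") {
    obj$train_mean <- mean(train$yield)
    obj$n_train_px <- length(train$yield)
  } else if (kind == "linear") {
    df <- pixel_frame(train)
    fit <- stats::lm(stats::reformulate(feature_names(), "yield"), data = df)
    aliased <- names(which(is.na(stats::coef(fit))))
    if (length(aliased))
      warning("aliased (dropped) linear-model columns: ",
              paste(aliased, collapse = ", "), call. = FALSE)
    obj$fit <- fit
    obj$aliased <- aliased
  } else if (kind == "xgboost") {
    df <- pixel_frame(train)
    X <- as.matrix(df[feature_names()])
    base <- mean(df$yield)
    obj$base_score <- base
    obj$nrounds <- nrounds
    if (nrounds > 0) {
      dtrain <- xgboost::xgb.DMatrix(X, label = df$yield, nthread = 1)
      obj$fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = eta,
                      max_depth = max_depth, base_score = base,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0)
    }
  } else {
    val <- tiles[roles == "validation"]
    if (n_tiles(val) == 0L)
      stop_input("CNN training needs a fold with validation tiles")
    spec <- if (kind == "cnn2d") build_cnn2d() else build_cnn3d()
    norm <- fit_normalizer(train)
    Xtr <- normalize_input(tiles_to_matrix(train), norm)
    Xval <- normalize_input(tiles_to_matrix(val), norm)
    fit <- cpp_cnn_train(Xtr, tiles_to_labels(train), Xval,
                         tiles_to_labels(val), engine_spec(spec),
                         as.integer(epochs), as.integer(batch_size),
                         learning_rate, 0.9, 0.999, 1e-7,
                         as.integer(seed), mean(train$yield))
    obj$spec <- spec
    obj$weights <- fit$weights
    obj$normalizer <- norm
    obj$best_epoch <- fit$best_epoch
    obj$best_val_loss <- fit$best_val
    obj$history <- if (nrow(fit$history))
      data.frame(epoch = seq_len(nrow(fit$history)),
                 train_mse = fit$history[, 1], val_mse = fit$history[, 2])
      else data.frame(epoch = integer(), train_mse = numeric(),
                      val_mse = numeric())
  }
  obj$n_train_tiles <- n_tiles(train)
  class(obj) <- c(paste0("yield_", kind), "yield_model")
  obj
}

pixel_frame <- function(tiles) {
  fm <- tiles_to_matrix(tiles)
  df <- as.data.frame(t(fm))
  names(df) <- feature_names()
  df$yield <- tiles_to_labels(tiles)
  df
}

fit_normalizer <- function(tiles) {
  fm <- tiles_to_matrix(tiles)
  mu <- rowMeans(fm)
  sd <- apply(fm, 1, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

normalize_input <- function(fm, norm) (fm - norm$mean) / norm$sd

# strip R-side metadata down to what the C++ engine reads
engine_spec <- function(spec) {
  lapply(spec$layers, function(L) {
    out <- L[intersect(names(L), c("type", "relu", "cin", "cout", "pin",
                                   "pout", "idx"))]
    out
  })
}

#' Predict yield patches from a fitted model
#'
#' Applies a fitted [yield_model()] to tiles: per-pixel models are applied
#' elementwise to each pixel's features, CNNs to whole patches.  Output is
#' deterministic given the fitted parameters.
#'
#' @param object A `yield_model`.
#' @param tiles A `tile_set` with the feature shape the model was trained
#'   on.
#' @param ... Unused.
#' @return An `n_tiles x size x size` array of predicted yields (Mg/ha).
#' @export
predict.yield_model <- function(object, tiles, ...) {
  stopifnot(inherits(tiles, "tile_set"))
  n <- n_tiles(tiles)
  size <- tiles$size
  switch(object$kind,
    null = array(object$train_mean, c(n, size, size)),
    linear = {
      check_pixel_tiles(tiles)
      df <- pixel_frame(tiles)
      predictions_to_patches(stats::predict(object$fit, newdata = df), n,
                             size)
    },
    xgboost = {
      check_pixel_tiles(tiles)
      if (is.null(object$fit))
        return(array(object$base_score, c(n, size, size)))
      X <- t(tiles_to_matrix(tiles))
      colnames(X) <- feature_names()
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))
      predictions_to_patches(p, n, size)
    },
    {
      want_dates <- if (object$kind == "cnn3d") 5L else 1L
      if (tiles$n_dates != want_dates)
        stop_input(object$kind, " expects tiles with ", want_dates,
                   " date(s)")
      X <- normalize_input(tiles_to_matrix(tiles), object$normalizer)
      p <- cpp_cnn_predict(X, engine_spec(object$spec), object$weights)
      predictions_to_patches(p, n, size)
    })
}

check_pixel_tiles <- function(tiles) {
  if (tiles$n_dates != 1L)
    stop_input("per-pixel models expect a single-date tile_set")
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("<yield_model> kind '%s', fold %s, date(s): %s\n", x$kind,
              x$fold_id, paste(x$dates, collapse = ", ")))
  cat(sprintf("  trained on %d tiles\n", x$n_train_tiles))
  if (x$kind == "null")
    cat(sprintf("  constant prediction: %.3f Mg/ha\n", x$train_mean))
  if (!is.null(x$spec))
    cat(sprintf("  %s parameters; best validation epoch %d (MSE %.4f)\n",
                format(x$spec$n_params, big.mark = ","), x$best_epoch,
                x$best_val_loss))
  invisible(x)
}

#' @export
summary.yield_model <- function(object, ...) {
  out <- list(kind = object$kind, fold_id = object$fold_id,
              dates = object$dates, n_train_tiles = object$n_train_tiles,
              seed = object$seed)
  if (object$kind == "linear") out$lm_summary <- summary(object$fit)
  if (!is.null(object$history) && nrow(object$history)) {
    out$best_epoch <- object$best_epoch
    out$best_val_loss <- object$best_val_loss
    out$final_train_mse <- utils::tail(object$history$train_mse, 1)
  }
  structure(out, class = "summary.yield_model")
}

#' @export
print.summary.yield_model <- function(x, ...) {
  cat(sprintf("Yield model '%s' (fold %s, %s), %d training tiles, seed %d\n",
              x$kind, x$fold_id, paste(x$dates, collapse = ", "),
              x$n_train_tiles, x$seed))
  if (!is.null(x$best_epoch))
    cat(sprintf("  best validation epoch %d (MSE %.4f); final train MSE %.4f\n",
                x$best_epoch, x$best_val_loss, x$final_train_mse))
  if (!is.null(x$lm_summary)) print(x$lm_summary)
  invisible(x)
}

#' @export
coef.yield_model <- function(object, ...) {
  switch(object$kind,
         linear = stats::coef(object$fit),
         null = c(`(mean yield)` = object$train_mean),
         NULL)
}

#' Residuals of a yield model on a tile set
#'
#' @param object A `yield_model`.
#' @param tiles The `tile_set` to evaluate on.
#' @param ... Unused.
#' @return Array of observed minus predicted yield, one value per pixel.
#' @export
residuals.yield_model <- function(object, tiles, ...) {
  tiles$yield - predict(object, tiles)
}

#' Plot CNN training history
#'
#' For CNN models, draws per-epoch training and validation loss with the
#' checkpointed epoch marked; other kinds have no history and produce an
#' informative message.
#'
#' @param x A `yield_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.yield_model <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) {
    message("no training history for kind '", x$kind, "'")
    return(invisible(x))
  }
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_mse, x$history$val_mse),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
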