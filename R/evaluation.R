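# Evaluation metrics, feature-blanking importance, and cross-fold
# summaries.

#' Compute the four evaluation metrics
#'
#' Given per-pixel observed and predicted yields, computes:
#' RMSE `sqrt(mean((Y - Yhat)^2))`; MAE `mean(|Yhat - Y|)`;
#' MBE `mean(Yhat - Y)` (positive = overprediction); and R2 as the squared
#' product-moment correlation
#' `[sum((Y - mean(Y)) * (Yhat - mean(Yhat)))]^2 /
#' [sum((Y - mean(Y))^2) * sum((Yhat - mean(Yhat))^2)]`.
#' R2 is reported as not defined (`NA` with `r2_defined = FALSE`) when
#' either series has zero variance - e.g. for the constant-prediction null
#' model.  Relative RMSE (`rrmse`, %) is RMSE divided by the mean observed
#' yield.  Pixel pairs with a missing value in either series are dropped.
#'
#' @param observed,predicted Equal-length numeric vectors (or arrays) of
#'   yields, Mg/ha.
#' @param model,fold_id,dates Optional provenance recorded in the report.
#' @return An `eval_report`: list with `n`, `rmse`, `mae`, `mbe`, `r2`,
#'   `r2_defined`, `rrmse` and the provenance fields.
#' @export
#' @examples
#' compute_metrics(c(8, 9, 10), c(8.2, 9.1, 9.7))
compute_metrics <- function(observed, predicted, model = NA_character_,
                            fold_id = NA_character_, dates = NA_character_) {
  observed <- as.vector(observed)
  predicted <- as.vector(predicted)
  if (length(observed) != length(predicted))
    stop_input("observed and predicted lengths differ")
  keep <- is.finite(observed) & is.finite(predicted)
  y <- observed[keep]
  yhat <- predicted[keep]
  n <- length(y)
  if (n < 1L) stop_input("no overlapping valid pixels")
  err <- yhat - y
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  mbe <- mean(err)
  dy <- y - mean(y)
  dyh <- yhat - mean(yhat)
  ss_y <- sum(dy^2)
  ss_yh <- sum(dyh^2)
  r2_defined <- ss_y > 0 && ss_yh > 0
  r2 <- if (r2_defined) sum(dy * dyh)^2 / (ss_y * ss_yh) else NA_real_
  structure(list(n = n, rmse = rmse, mae = mae, mbe = mbe, r2 = r2,
                 r2_defined = r2_defined,
                 rrmse = 100 * rmse / mean(y),
                 model = model, fold_id = fold_id,
                 dates = paste(dates, collapse = ",")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  r2 <- if (x$r2_defined) sprintf("%.3f", x$r2) else "n.d."
  cat(sprintf(
    "<eval_report> %s fold %s (%s): n = %d px\n  RMSE %.3f | MAE %.3f | MBE %+.3f Mg/ha | R2 %s | rRMSE %.1f%%\n",
    x$model, x$fold_id, x$dates, x$n, x$rmse, x$mae, x$mbe, r2, x$rrmse))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(model = x$model, fold_id = x$fold_id, dates = x$dates,
             n = x$n, rmse = x$rmse, mae = x$mae, mbe = x$mbe, r2 = x$r2,
             r2_defined = x$r2_defined, rrmse = x$rrmse,
             stringsAsFactors = FALSE)
}

#' Evaluate a fitted model on a tile subset
#'
#' Predicts the given tiles and scores them with [compute_metrics()].
#'
#' @param model A [yield_model()].
#' @param tiles A `tile_set`.
#' @param roles Optional role factor (from a `fold_spec`) and
#' @param role the role to evaluate (default `"test"`); with `roles = NULL`
#'   all tiles are scored.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, tiles, roles = NULL, role = "test") {
  if (!is.null(roles)) tiles <- tiles[roles == role]
  if (n_tiles(tiles) == 0L) stop_input("no tiles to evaluate")
  pred <- predict(model, tiles)
  compute_metrics(tiles$yield, pred, model = model$kind,
                  fold_id = model$fold_id, dates = tiles$dates)
}

#' Blank one feature across a tile set
#'
#' Replaces every value of one feature layer by the mean of that feature
#' over all pixels of the tile set (the raw, unnormalized scale; a model's
#' own normalizer is applied afterwards at prediction time).  All other
#' layers are untouched.  Blanking an already-constant layer is a no-op.
#'
#' @param tiles A `tile_set`.
#' @param feature One of [feature_names()].
#' @return The modified `tile_set`.
#' @export
blank_feature <- function(tiles, feature) {
  stopifnot(inherits(tiles, "tile_set"))
  if (length(feature) != 1L || !feature %in% feature_names())
    stop_input("unknown feature '", paste(feature, collapse = ","),
               "'; features: ", paste(feature_names(), collapse = ", "))
  fi <- match(feature, feature_names())
  if (tiles$n_dates == 1L) {
    tiles$features[, , , fi] <- mean(tiles$features[, , , fi])
  } else {
    tiles$features[, , , , fi] <- mean(tiles$features[, , , , fi])
  }
  tiles
}

#' Feature importance by blanking
#'
#' For each of the seven features in turn, replaces its observed variation
#' with the test-set mean, re-evaluates the model, and reports the RMSE
#' increase: `delta_rmse = RMSE(blanked) - RMSE(original)`, also expressed
#' relative to mean observed yield (`delta_rrmse`, percentage points).
#' Larger positive values indicate more important features; values can be
#' negative when removing a feature's variation happens to help.
#'
#' @param model A fitted [yield_model()].
#' @param tiles Test-set `tile_set`.
#' @return A `data.frame` with one row per feature: `feature`,
#'   `rmse_blanked`, `delta_rmse` (Mg/ha), `delta_rrmse` (points),
#'   `fold_id`.
#' @export
feature_importance <- function(model, tiles) {
  base <- evaluate_model(model, tiles)
  rows <- lapply(feature_names(), function(f) {
    rep <- evaluate_model(model, blank_feature(tiles, f))
    data.frame(feature = f, rmse_blanked = rep$rmse,
               delta_rmse = rep$rmse - base$rmse,
               delta_rrmse = rep$rrmse - base$rrmse,
               fold_id = model$fold_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rmse_original") <- base$rmse
  out
}

#' Summarize evaluation reports across folds
#'
#' Per-model mean and standard deviation of each metric across the
#' supplied fold reports (undefined R2 values are dropped from the R2
#' average, mirroring "n.d." entries).
#'
#' @param reports A list of `eval_report`s, or a `data.frame` of rows from
#'   [as.data.frame.eval_report()].
#' @return A `data.frame`, one row per model, with `n_folds` and
#'   `<metric>_mean`/`<metric>_sd` columns for rmse, mae, mbe, r2 and
#'   rrmse.
#' @export
cross_fold_summary <- function(reports) {
  df <- if (is.data.frame(reports)) reports
        else do.call(rbind, lapply(reports, as.data.frame))
  if (!nrow(df)) stop_input("no reports to summarize")
  found_folds <- sort(unique(df$fold_id))
  if (length(found_folds) < 4L)
    warning("summary computed over fold(s) ",
            paste(found_folds, collapse = ", "), " only", call. = FALSE)
  metrics <- c("rmse", "mae", "mbe", "r2", "rrmse")
  out <- lapply(split(df, df$model), function(d) {
    row <- data.frame(model = d$model[1], n_folds = length(unique(d$fold_id)))
    for (m in metrics) {
      v <- d[[m]]
      if (m == "r2") v <- v[d$r2_defined]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Observed-minus-predicted difference map
#'
#' Assembles a field-scale difference raster (observed yield minus
#' predicted yield; positive where the model underpredicts).
#'
#' @param tile_set Test or full `tile_set` with labels.
#' @param predictions n x size x size prediction array for those tiles.
#' @param dims Output dimensions, as in [assemble_map()].
#' @return A `yield_raster` of differences.
#' @export
difference_map <- function(tile_set, predictions,
                           dims = tile_set$tile_grid * tile_set$size) {
  assemble_map(tile_set, tile_set$yield - predictions, dims = dims)
}
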