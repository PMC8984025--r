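# Network specifications for the patch-regression convolutional
# autoencoders, plus converters between tile arrays and the engine's
# channel x (sample*position) matrix layout.  Positions are enumerated in C
# order (last axis fastest) so the Flatten between encoder and bottleneck
# is a pure reshape.

# im2col index table for an n-dimensional convolution at stride 1.
# Returns a (n_out_positions x n_taps) integer matrix of 0-based input
# positions, -1 where the tap falls in zero padding.  "same" padding uses
# the asymmetric convention of the common deep-learning frameworks
# (floor((k-1)/2) before, remainder after), which matters for even kernels.
conv_index <- function(in_dim, kernel, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  nd <- length(in_dim)
  stopifnot(length(kernel) == nd)
  pad_begin <- if (padding == "same") (kernel - 1L) %/% 2L else rep(0L, nd)
  out_dim <- if (padding == "same") in_dim else in_dim - kernel + 1L
  if (any(out_dim < 1L)) stop_input("kernel larger than input")
  grid_c <- function(dims) {
    g <- expand.grid(rev(lapply(dims, function(n) 0:(n - 1))),
                     KEEP.OUT.ATTRS = FALSE)
    as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
  }
  outs <- grid_c(out_dim)
  taps <- grid_c(kernel)
  idx <- matrix(-1L, nrow(outs), nrow(taps))
  for (t in seq_len(nrow(taps))) {
    coord <- sweep(outs, 2, pad_begin, "-")
    coord <- sweep(coord, 2, taps[t, ], "+")
    ok <- rowSums(coord < 0) == 0 &
      rowSums(sweep(coord, 2, in_dim, ">=")) == 0
    lin <- rep(0L, nrow(coord))
    for (a in seq_len(nd)) lin <- lin * in_dim[a] + coord[, a]
    idx[ok, t] <- as.integer(lin[ok])
  }
  list(idx = idx, out_dim = out_dim)
}

conv_layer <- function(in_dim, kernel, padding, cin, cout, relu) {
  ci <- conv_index(in_dim, kernel, padding)
  list(type = "conv", relu = relu, cin = cin, cout = cout,
       pin = prod(in_dim), pout = nrow(ci$idx), idx = ci$idx,
       kernel = kernel, padding = padding, in_dim = in_dim,
       out_dim = ci$out_dim)
}

dense_layer <- function(din, dout, relu) {
  list(type = "dense", relu = relu, cin = din, cout = dout)
}

# shared bottleneck + decoder: flatten -> dense 256 -> dense 6400 ->
# reshape (5,5,256) -> three decoding convolutions down to one yield layer
cnn_tail <- function() {
  list(
    list(type = "flatten", relu = FALSE, cin = 256L, cout = 256L, pin = 25L),
    dense_layer(6400L, 256L, relu = TRUE),
    dense_layer(256L, 6400L, relu = TRUE),
    list(type = "unflatten", relu = FALSE, cin = 256L, cout = 256L,
         pout = 25L),
    conv_layer(c(5L, 5L), c(2L, 2L), "same", 256L, 128L, relu = TRUE),
    conv_layer(c(5L, 5L), c(3L, 3L), "same", 128L, 64L, relu = TRUE),
    conv_layer(c(5L, 5L), c(1L, 1L), "same", 64L, 1L, relu = FALSE))
}

#' Architecture of the 2D convolutional autoencoder
#'
#' Builds the layer specification of the spatial patch-regression network:
#' a three-convolution encoder (64 filters 3x3 same, 128 filters 2x2 same,
#' 256 filters 1x1 valid) over a 5 x 5 x 7 input, a flatten into a
#' 6,400-unit vector, dense layers of 256 and 6,400 units, a reshape back
#' to 5 x 5 x 256, and a three-convolution decoder (128 filters 2x2, 64
#' filters 3x3, 1 filter 1x1) emitting a 5 x 5 yield patch.  Every layer is
#' rectified-linear except the final, linear one.  The second dense layer
#' has 6,400 units: a width of 5,400 is sometimes quoted for this
#' architecture, but the following reshape to (5, 5, 256) requires exactly
#' 5 * 5 * 256 = 6,400.
#'
#' @return A `cnn_spec` (layer list plus metadata).
#' @export
#' @examples
#' build_cnn2d()
build_cnn2d <- function() {
  layers <- c(list(
    conv_layer(c(5L, 5L), c(3L, 3L), "same", 7L, 64L, relu = TRUE),
    conv_layer(c(5L, 5L), c(2L, 2L), "same", 64L, 128L, relu = TRUE),
    conv_layer(c(5L, 5L), c(1L, 1L), "valid", 128L, 256L, relu = TRUE)),
    cnn_tail())
  structure(list(kind = "cnn2d", input_shape = c(5L, 5L, 7L),
                 layers = layers, n_params = count_params(layers)),
            class = "cnn_spec")
}

#' Architecture of the 3D spatio-temporal convolutional autoencoder
#'
#' As [build_cnn2d()], but the encoder convolves over space and time on a
#' 5 x 5 x 5 x 7 input (five dates): kernels (3,3,3) same, (2,2,3) same,
#' and (1,1,5) valid - the last collapses the five-date axis to one, after
#' which the bottleneck and decoder are identical to the 2D network.
#'
#' @return A `cnn_spec`.
#' @export
build_cnn3d <- function() {
  layers <- c(list(
    conv_layer(c(5L, 5L, 5L), c(3L, 3L, 3L), "same", 7L, 64L, relu = TRUE),
    conv_layer(c(5L, 5L, 5L), c(2L, 2L, 3L), "same", 64L, 128L, relu = TRUE),
    conv_layer(c(5L, 5L, 5L), c(1L, 1L, 5L), "valid", 128L, 256L,
               relu = TRUE)),
    cnn_tail())
  structure(list(kind = "cnn3d", input_shape = c(5L, 5L, 5L, 7L),
                 layers = layers, n_params = count_params(layers)),
            class = "cnn_spec")
}

count_params <- function(layers) {
  sum(vapply(layers, function(L) {
    switch(L$type,
           conv = ncol(L$idx) * L$cin * L$cout + L$cout,
           dense = L$cin * L$cout + L$cout,
           0L)
  }, numeric(1)))
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %s: input (%s), %s parameters\n", x$kind,
              paste(x$input_shape, collapse = ","),
              format(x$n_params, big.mark = ",")))
  for (L in x$layers) {
    desc <- switch(L$type,
      conv = sprintf("conv %s -> %d filters, kernel (%s), %s%s",
                     paste0(L$cin, "ch"), L$cout,
                     paste(L$kernel, collapse = ","), L$padding,
                     if (L$relu) ", relu" else ", linear"),
      dense = sprintf("dense %d -> %d%s", L$cin, L$cout,
                      if (L$relu) ", relu" else ", linear"),
      flatten = sprintf("flatten (%d positions x %d ch)", L$pin, L$cin),
      unflatten = sprintf("reshape -> (%d positions x %d ch)", L$pout, L$cin))
    cat("  ", desc, "\n", sep = "")
  }
  invisible(x)
}

# tile features -> engine input matrix (7 x N*positions), positions in C
# order over (row, col[, date])
tiles_to_matrix <- function(tiles) {
  if (tiles$n_dates == 1L) {
    a <- aperm(tiles$features, c(4, 3, 2, 1))     # (feat, col, row, tile)
    matrix(a, nrow = 7L)
  } else {
    a <- aperm(tiles$features, c(5, 4, 3, 2, 1))  # (feat, date, col, row, tile)
    matrix(a, nrow = 7L)
  }
}

# yield patches -> label vector in the same sample-position order
tiles_to_labels <- function(tiles) {
  as.vector(aperm(tiles$yield, c(3, 2, 1)))
}

# engine predictions (length N*25) -> n x 5 x 5 patch array
predictions_to_patches <- function(pred, n, size = 5L) {
  aperm(array(pred, c(size, size, n)), c(3, 2, 1))
}
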