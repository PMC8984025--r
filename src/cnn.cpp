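// Single-precision backpropagation engine for the patch-regression
// convolutional autoencoders.  Activations are stored column-major as
// (channels x N*positions) matrices, one column per sample-position, with
// positions enumerated in C order (last spatial axis fastest).  With that
// layout the Flatten/Reshape steps between the convolutional sub-networks
// and the dense bottleneck are pure memory reinterpretations, and every
// convolution reduces to one GEMM on an im2col matrix.  All randomness
// (weight initialisation, epoch shuffling) comes from one std::mt19937 so a
// run is a pure function of its seed.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Layer {
  int type;                 // 0 conv, 1 dense, 2 flatten, 3 unflatten
  bool relu;
  int cin, cout;            // channels (conv) or widths (dense)
  int pin, pout, taps;      // conv geometry; flatten: pin = positions, cin = channels
  imat idx;                 // pout x taps, 0-based input position, -1 = zero pad
  fmat W; fvec b;
  fmat mW, vW; fvec mb, vb; // Adam state
  fmat X, Xcol, Z;          // caches for backward
};

std::vector<Layer> build_layers(Rcpp::List spec) {
  std::vector<Layer> layers;
  for (int i = 0; i < spec.size(); ++i) {
    Rcpp::List ls = spec[i];
    Layer L;
    std::string ty = Rcpp::as<std::string>(ls["type"]);
    L.relu = Rcpp::as<bool>(ls["relu"]);
    L.cin = Rcpp::as<int>(ls["cin"]);
    L.cout = Rcpp::as<int>(ls["cout"]);
    if (ty == "conv") {
      L.type = 0;
      L.idx = Rcpp::as<imat>(ls["idx"]);
      L.pout = L.idx.n_rows;
      L.taps = L.idx.n_cols;
      L.pin = Rcpp::as<int>(ls["pin"]);
    } else if (ty == "dense") {
      L.type = 1; L.pin = 1; L.pout = 1; L.taps = 0;
    } else if (ty == "flatten") {
      L.type = 2; L.pin = Rcpp::as<int>(ls["pin"]); L.pout = 1; L.taps = 0;
    } else if (ty == "unflatten") {
      L.type = 3; L.pin = 1; L.pout = Rcpp::as<int>(ls["pout"]); L.taps = 0;
    } else {
      Rcpp::stop("unknown layer type '%s'", ty);
    }
    layers.push_back(std::move(L));
  }
  return layers;
}

// Glorot (fan-based) uniform initialisation; biases zero except the final
// layer's, which is set to the training-set mean yield so the network starts
// at the null model.
void init_weights(std::vector<Layer>& layers, std::mt19937& rng,
                  double out_bias_init) {
  int last_param = -1;
  for (size_t i = 0; i < layers.size(); ++i)
    if (layers[i].type <= 1) last_param = (int)i;
  for (size_t i = 0; i < layers.size(); ++i) {
    Layer& L = layers[i];
    if (L.type > 1) continue;
    int fan_in  = (L.type == 0) ? L.taps * L.cin  : L.cin;
    int fan_out = (L.type == 0) ? L.taps * L.cout : L.cout;
    float limit = std::sqrt(6.0f / (float)(fan_in + fan_out));
    std::uniform_real_distribution<float> U(-limit, limit);
    L.W.set_size(L.cout, fan_in);
    for (uword k = 0; k < L.W.n_elem; ++k) L.W(k) = U(rng);
    L.b.zeros(L.cout);
    if ((int)i == last_param) L.b.fill((float)out_bias_init);
    L.mW.zeros(size(L.W)); L.vW.zeros(size(L.W));
    L.mb.zeros(L.cout);    L.vb.zeros(L.cout);
  }
}

fmat layer_forward(Layer& L, const fmat& A, bool cache) {
  if (L.type == 2) {                       // flatten: (c, N*p) -> (c*p, N)
    return reshape(A, (uword)L.cin * L.pin, A.n_cols / L.pin);
  }
  if (L.type == 3) {                       // unflatten: (c*p, N) -> (c, N*p)
    return reshape(A, (uword)L.cin, A.n_cols * L.pout);
  }
  fmat Z;
  if (L.type == 0) {
    int N = (int)(A.n_cols / L.pin);
    fmat Xcol((uword)L.taps * L.cin, (uword)N * L.pout, fill::zeros);
    for (int t = 0; t < L.taps; ++t) {
      for (int p = 0; p < L.pout; ++p) {
        sword q = L.idx(p, t);
        if (q < 0) continue;
        for (int s = 0; s < N; ++s) {
          std::memcpy(Xcol.colptr((uword)s * L.pout + p) + (uword)t * L.cin,
                      A.colptr((uword)s * L.pin + q),
                      sizeof(float) * L.cin);
        }
      }
    }
    Z = L.W * Xcol;
    Z.each_col() += L.b;
    if (cache) L.Xcol = std::move(Xcol);
  } else {                                 // dense
    Z = L.W * A;
    Z.each_col() += L.b;
    if (cache) L.X = A;
  }
  if (cache) L.Z = Z;
  if (L.relu) Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  return Z;
}

// fused single-pass Adam update (no expression temporaries)
void adam_step(float* W, float* m, float* v, const float* g, uword n,
               float lr, float b1, float b2, float eps, float c1, float c2) {
  const float omb1 = 1.0f - b1, omb2 = 1.0f - b2;
  for (uword k = 0; k < n; ++k) {
    const float gk = g[k];
    m[k] = b1 * m[k] + omb1 * gk;
    v[k] = b2 * v[k] + omb2 * gk * gk;
    W[k] -= lr * (m[k] / c1) / (std::sqrt(v[k] / c2) + eps);
  }
}

fmat layer_backward(Layer& L, fmat dA, float lr, float b1, float b2,
                    float eps, int tstep, bool need_dx) {
  if (L.type == 2) return reshape(dA, (uword)L.cin, dA.n_cols * L.pin);
  if (L.type == 3) return reshape(dA, (uword)L.cin * L.pout, dA.n_cols / L.pout);
  if (L.relu) {
    const fmat& Z = L.Z;
    for (uword k = 0; k < dA.n_elem; ++k) if (Z(k) <= 0.0f) dA(k) = 0.0f;
  }
  float c1 = 1.0f - std::pow(b1, (float)tstep);
  float c2 = 1.0f - std::pow(b2, (float)tstep);
  fmat dX;
  if (L.type == 0) {
    fmat dW = dA * L.Xcol.t();
    fvec db = sum(dA, 1);
    if (need_dx) {
      fmat dXcol = L.W.t() * dA;
      int N = (int)(dA.n_cols / L.pout);
      dX.zeros((uword)L.cin, (uword)N * L.pin);
      for (int t = 0; t < L.taps; ++t) {
        for (int p = 0; p < L.pout; ++p) {
          sword q = L.idx(p, t);
          if (q < 0) continue;
          for (int s = 0; s < N; ++s) {
            const float* src = dXcol.colptr((uword)s * L.pout + p) + (uword)t * L.cin;
            float* dst = dX.colptr((uword)s * L.pin + q);
            for (int c = 0; c < L.cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
    adam_step(L.W.memptr(), L.mW.memptr(), L.vW.memptr(), dW.memptr(),
              dW.n_elem, lr, b1, b2, eps, c1, c2);
    adam_step(L.b.memptr(), L.mb.memptr(), L.vb.memptr(), db.memptr(),
              db.n_elem, lr, b1, b2, eps, c1, c2);
  } else {
    fmat dW = dA * L.X.t();
    fvec db = sum(dA, 1);
    if (need_dx) dX = L.W.t() * dA;
    adam_step(L.W.memptr(), L.mW.memptr(), L.vW.memptr(), dW.memptr(),
              dW.n_elem, lr, b1, b2, eps, c1, c2);
    adam_step(L.b.memptr(), L.mb.memptr(), L.vb.memptr(), db.memptr(),
              db.n_elem, lr, b1, b2, eps, c1, c2);
  }
  return dX;
}

fmat net_forward(std::vector<Layer>& layers, fmat A, bool cache) {
  for (size_t i = 0; i < layers.size(); ++i)
    A = layer_forward(layers[i], A, cache);
  return A;
}

// chunked forward pass (no caches) returning predictions for all samples
fvec net_predict(std::vector<Layer>& layers, const fmat& X,
                 int pin0, int pout_last, int chunk) {
  int N = (int)(X.n_cols / pin0);
  fvec out((uword)N * pout_last);
  for (int s0 = 0; s0 < N; s0 += chunk) {
    int nb = std::min(chunk, N - s0);
    fmat Xb = X.cols((uword)s0 * pin0, (uword)(s0 + nb) * pin0 - 1);
    fmat P = net_forward(layers, Xb, false);
    std::memcpy(out.memptr() + (uword)s0 * pout_last, P.memptr(),
                sizeof(float) * (uword)nb * pout_last);
  }
  return out;
}

Rcpp::List export_weights(const std::vector<Layer>& layers) {
  Rcpp::List out;
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& L = layers[i];
    if (L.type > 1) { out.push_back(R_NilValue); continue; }
    out.push_back(Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(L.W)),
        Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(L.b))));
  }
  return out;
}

void import_weights(std::vector<Layer>& layers, Rcpp::List weights) {
  for (size_t i = 0; i < layers.size(); ++i) {
    Layer& L = layers[i];
    if (L.type > 1) continue;
    Rcpp::List wl = weights[i];
    L.W = conv_to<fmat>::from(Rcpp::as<mat>(wl["W"]));
    L.b = conv_to<fvec>::from(Rcpp::as<vec>(wl["b"]));
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_cnn_train")]]
Rcpp::List cpp_cnn_train(const arma::mat& X, const arma::vec& y,
                         const arma::mat& Xval, const arma::vec& yval,
                         Rcpp::List layerspec, int epochs, int batch,
                         double lr, double beta1, double beta2, double eps,
                         int seed, double out_bias_init) {
  std::vector<Layer> layers = build_layers(layerspec);
  int pin0 = layers.front().pin;
  int pout_last = layers.back().pout > 1 ? layers.back().pout
                                         : (int)(y.n_elem / (X.n_cols / pin0));
  int N = (int)(X.n_cols / pin0);
  int Nv = (int)(Xval.n_cols / pin0);
  if ((int)y.n_elem != N * pout_last) Rcpp::stop("label length mismatch");

  std::mt19937 rng((unsigned)seed);
  init_weights(layers, rng, out_bias_init);

  fmat Xf = conv_to<fmat>::from(X);
  fvec yf = conv_to<fvec>::from(y);
  fmat Xvf = conv_to<fmat>::from(Xval);
  fvec yvf = conv_to<fvec>::from(yval);

  mat history(epochs, 2);
  double best_val = datum::inf;
  int best_epoch = 0;
  Rcpp::List best_weights = export_weights(layers);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  int tstep = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; int nb_batches = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int nb = std::min(batch, N - b0);
      fmat Xb((uword)layers.front().cin, (uword)nb * pin0);
      fvec yb((uword)nb * pout_last);
      for (int j = 0; j < nb; ++j) {
        int s = order[b0 + j];
        std::memcpy(Xb.colptr((uword)j * pin0), Xf.colptr((uword)s * pin0),
                    sizeof(float) * Xb.n_rows * pin0);
        std::memcpy(yb.memptr() + (uword)j * pout_last,
                    yf.memptr() + (uword)s * pout_last,
                    sizeof(float) * pout_last);
      }
      fmat P = net_forward(layers, Xb, true);
      fmat R = P - yb.t();                   // (1, nb*pout)
      double loss = accu(conv_to<mat>::from(square(R))) / R.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d; lower the learning rate", ep + 1);
      ep_loss += loss; ++nb_batches;
      fmat dA = (2.0f / (float)R.n_elem) * R;
      ++tstep;
      for (int li = (int)layers.size() - 1; li >= 0; --li)
        dA = layer_backward(layers[li], std::move(dA),
                            (float)lr, (float)beta1, (float)beta2,
                            (float)eps, tstep, li > 0);
    }
    // validation loss with current weights
    fvec pv = net_predict(layers, Xvf, pin0, pout_last, 256);
    double vloss = accu(conv_to<mat>::from(square(pv - yvf))) / pv.n_elem;
    history(ep, 0) = ep_loss / std::max(nb_batches, 1);
    history(ep, 1) = vloss;
    if (vloss < best_val) {
      best_val = vloss;
      best_epoch = ep + 1;
      best_weights = export_weights(layers);
    }
    Rcpp::checkUserInterrupt();
  }
  if (epochs == 0) {                        // untrained network: keep init
    fvec pv = Nv > 0 ? net_predict(layers, Xvf, pin0, pout_last, 256) : fvec();
    best_val = Nv > 0 ? accu(conv_to<mat>::from(square(pv - yvf))) / pv.n_elem
                      : NA_REAL;
    best_epoch = 0;
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = best_weights,
      Rcpp::Named("history") = history,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val") = best_val);
}

//' @noRd
// [[Rcpp::export(name = "cpp_cnn_predict")]]
arma::vec cpp_cnn_predict(const arma::mat& X, Rcpp::List layerspec,
                          Rcpp::List weights) {
  std::vector<Layer> layers = build_layers(layerspec);
  import_weights(layers, weights);
  int pin0 = layers.front().pin;
  int pout_last = 1;
  for (size_t i = 0; i < layers.size(); ++i)
    if (layers[i].type == 0) pout_last = layers[i].pout;
  fmat Xf = conv_to<fmat>::from(X);
  fvec out = net_predict(layers, Xf, pin0, pout_last, 256);
  return conv_to<vec>::from(out);
}
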