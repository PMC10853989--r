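// Dense feedforward training loop (autoencoders and MLP classifiers).
//
// Hidden layers are rectifiers; the output layer is identity (MSE loss)
// or softmax (cross-entropy). Optimizers: Adam and plain SGD, minibatch
// with per-epoch reshuffling. All randomness (weight initialisation,
// shuffles) is drawn from R's RNG, so set.seed() on the R side makes
// training fully reproducible. The per-epoch loss recorded in the history
// is the full-training-set loss; early stopping triggers once it has not
// improved by more than minDelta for `patience` consecutive epochs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

namespace {

struct Layer {
  mat W;
  rowvec b;
  mat mW, vW;     // Adam first/second moments
  rowvec mb, vb;
};

inline void relu_inplace(mat& Z) {
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

inline void softmax_inplace(mat& Z) {
  Z.each_col() -= arma::max(Z, 1);  // row-wise stabilisation
  Z = arma::exp(Z);
  Z.each_col() /= arma::sum(Z, 1);
}

// forward pass; if acts is non-null, stores activations per layer.
// rectify[i] says whether layer i's output is passed through the
// rectifier (the bottleneck code layer of an autoencoder is linear).
mat forward(const std::vector<Layer>& layers, const mat& X, bool softmax,
            const std::vector<bool>& rectify, std::vector<mat>* acts) {
  mat A = X;
  if (acts) (*acts)[0] = A;
  const size_t L = layers.size();
  for (size_t i = 0; i < L; ++i) {
    mat Z = A * layers[i].W;
    Z.each_row() += layers[i].b;
    if (i + 1 < L) {
      if (rectify[i]) relu_inplace(Z);
    } else if (softmax) {
      softmax_inplace(Z);
    }
    A = std::move(Z);
    if (acts) (*acts)[i + 1] = A;
  }
  return A;
}

double full_loss(const std::vector<Layer>& layers, const mat& X, const mat& Y,
                 bool softmax, const std::vector<bool>& rectify) {
  mat P = forward(layers, X, softmax, rectify, nullptr);
  if (!softmax) {
    mat D = P - Y;
    return arma::accu(arma::square(D)) / D.n_elem;
  }
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return -arma::accu(Y % arma::log(P)) / static_cast<double>(X.n_rows);
}

}  // namespace

// [[Rcpp::export(name = ".cppNnTrain")]]
List cppNnTrain(const arma::mat& X, const arma::mat& Y,
                IntegerVector widths, bool softmax,
                LogicalVector rectifyHidden,
                int batchSize, double learningRate, std::string solver,
                int maxEpochs, int patience, double minDelta) {
  const int n = X.n_rows;
  if (n < 2) stop("need at least 2 rows to train");
  const size_t L = widths.size() - 1;
  const bool adam = (solver == "adam");
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  RNGScope rngScope;  // weight init + shuffles come from R's RNG

  std::vector<bool> rectify(L, true);
  for (size_t i = 0; i < L && i < static_cast<size_t>(rectifyHidden.size()); ++i) {
    rectify[i] = rectifyHidden[i];
  }

  std::vector<Layer> layers(L);
  for (size_t i = 0; i < L; ++i) {
    const int fanIn = widths[i], fanOut = widths[i + 1];
    layers[i].W.set_size(fanIn, fanOut);
    const double sd = std::sqrt(2.0 / fanIn);
    // column-major fill matches an R matrix(rnorm(...), fanIn, fanOut)
    for (int c = 0; c < fanOut; ++c)
      for (int r = 0; r < fanIn; ++r)
        layers[i].W(r, c) = norm_rand() * sd;
    layers[i].b.zeros(fanOut);
    if (adam) {
      layers[i].mW.zeros(fanIn, fanOut);
      layers[i].vW.zeros(fanIn, fanOut);
      layers[i].mb.zeros(fanOut);
      layers[i].vb.zeros(fanOut);
    }
  }

  std::vector<mat> acts(L + 1);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<double> history;
  history.reserve(maxEpochs);
  double best = R_PosInf;
  int wait = 0;
  long tstep = 0;

  for (int epoch = 0; epoch < maxEpochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int s = 0; s < n; s += batchSize) {
      const int e = std::min(s + batchSize, n) - 1;
      arma::uvec idx(e - s + 1);
      for (int i = s; i <= e; ++i) idx[i - s] = perm[i];
      const mat Xb = X.rows(idx);
      const mat Yb = Y.rows(idx);

      forward(layers, Xb, softmax, rectify, &acts);
      mat delta;
      if (!softmax) {
        delta = 2.0 * (acts[L] - Yb) / static_cast<double>(Yb.n_elem);
      } else {
        delta = (acts[L] - Yb) / static_cast<double>(Yb.n_rows);
      }
      ++tstep;
      const double c1 = adam ? 1.0 - std::pow(b1, tstep) : 1.0;
      const double c2 = adam ? 1.0 - std::pow(b2, tstep) : 1.0;
      for (int i = static_cast<int>(L) - 1; i >= 0; --i) {
        mat gW = acts[i].t() * delta;
        rowvec gb = arma::sum(delta, 0);
        if (i > 0) {
          delta = delta * layers[i].W.t();
          if (rectify[i - 1]) {
            // rectifier derivative: zero where the activation was clipped
            delta %= arma::conv_to<mat>::from(acts[i] > 0.0);
          }
        }
        Layer& ly = layers[i];
        if (adam) {
          ly.mW = b1 * ly.mW + (1.0 - b1) * gW;
          ly.vW = b2 * ly.vW + (1.0 - b2) * arma::square(gW);
          ly.mb = b1 * ly.mb + (1.0 - b1) * gb;
          ly.vb = b2 * ly.vb + (1.0 - b2) * arma::square(gb);
          ly.W -= learningRate * (ly.mW / c1) / (arma::sqrt(ly.vW / c2) + eps);
          ly.b -= learningRate * (ly.mb / c1) / (arma::sqrt(ly.vb / c2) + eps);
        } else {
          ly.W -= learningRate * gW;
          ly.b -= learningRate * gb;
        }
      }
    }
    const double loss = full_loss(layers, X, Y, softmax, rectify);
    history.push_back(loss);
    if (loss < best - minDelta) {
      best = loss;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  List outLayers(L);
  for (size_t i = 0; i < L; ++i) {
    outLayers[i] = List::create(Named("W") = wrap(layers[i].W),
                                Named("b") = NumericVector(layers[i].b.begin(),
                                                           layers[i].b.end()));
  }
  return List::create(Named("layers") = outLayers,
                      Named("history") = wrap(history));
}
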