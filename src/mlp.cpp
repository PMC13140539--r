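// Small fully connected regressor (ReLU hidden layers, linear output)
// trained with Adam on mean squared error. Deterministic for a fixed seed:
// initialisation and minibatch shuffling use a private mt19937, training is
// single-threaded.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

static arma::mat relu(const arma::mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct Net {
  std::vector<arma::mat> W;  // W[l]: (n_out x n_in)
  std::vector<arma::vec> b;
};

static Net init_net(const std::vector<int>& dims, std::mt19937& rng) {
  Net net;
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    arma::mat W(dims[l + 1], dims[l]);
    double scale = std::sqrt(2.0 / dims[l]);  // He initialisation for ReLU
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = gauss(rng) * scale;
    net.W.push_back(W);
    net.b.push_back(arma::vec(dims[l + 1], arma::fill::zeros));
  }
  return net;
}

// forward pass on a batch (columns = samples); keeps activations for backprop
static arma::mat forward(const Net& net, const arma::mat& X,
                         std::vector<arma::mat>* acts = nullptr) {
  arma::mat a = X;
  if (acts) acts->push_back(a);
  for (size_t l = 0; l < net.W.size(); ++l) {
    arma::mat z = net.W[l] * a;
    z.each_col() += net.b[l];
    a = (l + 1 == net.W.size()) ? z : relu(z);
    if (acts) acts->push_back(a);
  }
  return a;
}

static double mse(const Net& net, const arma::mat& X, const arma::mat& Y) {
  arma::mat e = forward(net, X) - Y;
  return arma::accu(arma::square(e)) / e.n_elem;
}

// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                   IntegerVector hidden, int epochs, int batch_size,
                   double lr, int seed) {
  // X: n x p, Y: n x q (row-major samples as passed from R)
  arma::mat Xt = X.t(), Yt = Y.t();  // columns = samples
  std::vector<int> dims;
  dims.push_back(Xt.n_rows);
  for (int h : hidden) dims.push_back(h);
  dims.push_back(Yt.n_rows);

  std::mt19937 rng(static_cast<unsigned>(seed));
  Net net = init_net(dims, rng);
  const size_t L = net.W.size();
  double loss0 = mse(net, Xt, Yt);

  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  const arma::uword n = Xt.n_cols;
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword end = std::min<arma::uword>(start + batch_size, n);
      arma::uvec cols(end - start);
      for (arma::uword i = start; i < end; ++i) cols[i - start] = idx[i];
      arma::mat Xb = Xt.cols(cols), Yb = Yt.cols(cols);

      std::vector<arma::mat> acts;
      arma::mat out = forward(net, Xb, &acts);
      arma::mat delta = 2.0 * (out - Yb) / (out.n_elem);  // dMSE/dout

      ++step;
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        arma::mat gW = delta * acts[l].t();
        arma::vec gb = arma::sum(delta, 1);
        if (l > 0) {
          arma::mat da = net.W[l].t() * delta;
          delta = da % arma::conv_to<arma::mat>::from(acts[l] > 0.0);
        }
        double c1 = 1.0 - std::pow(b1, step), c2 = 1.0 - std::pow(b2, step);
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW);
        net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb);
        net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
  }
  double loss1 = mse(net, Xt, Yt);
  if (!std::isfinite(loss1)) stop("non-finite training loss");

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) { Wl[l] = net.W[l]; bl[l] = net.b[l]; }
  return List::create(_["W"] = Wl, _["b"] = bl,
                      _["loss_init"] = loss0, _["loss_final"] = loss1);
}

// [[Rcpp::export(name = ".mlp_predict")]]
arma::mat mlp_predict_cpp(List weights, const arma::mat& X) {
  List Wl = weights["W"], bl = weights["b"];
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(as<arma::mat>(Wl[l]));
    net.b.push_back(as<arma::vec>(bl[l]));
  }
  return forward(net, X.t()).t();
}
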