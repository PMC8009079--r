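// Compiled backend for the convolutional activity classifier.
//
// Forward pass: same-padded stride-1 cross-correlation (im2col + GEMM),
// ReLU, k x k max pooling per layer; flatten (filter-major, then rows,
// then columns -- the same order as the R reference ops); fully
// connected ReLU layers with inverted dropout during training; softmax.
// Training: mini-batch Adam on the sparse categorical cross-entropy.
//
// Conventions shared with the R side:
//  - images arrive as an R array (H, W, C, N), column-major;
//  - conv weights as (a, b, C_in, F) arrays, dense weights as
//    (out x in) matrices;
//  - feature maps are held as (F x H*W) matrices with pixel index
//    p = i*W + j (row-major pixels), so concatenating rows reproduces
//    flatten_concat() exactly;
//  - "same" padding puts the extra zero row/column at the bottom/right
//    when the kernel size is even.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvLayer {
  arma::mat Wm;    // F x (C*a*b)
  arma::vec bias;  // F
  int a, b, cin, f;
};

struct DenseLayer {
  arma::mat W;  // out x in
  arma::vec b;
};

// row index inside an im2col column for (channel c, kernel row p, col q)
inline int colrow(int c, int p, int q, int a, int b) {
  return (c * a + p) * b + q;
}

// X: (C x H*W) with pixel index i*W+j.  M: (C*a*b x H*W), zero padded.
void im2col_same(const arma::mat& X, int H, int W, int a, int b,
                 arma::mat& M) {
  const int C = X.n_rows;
  const int pt = (a - 1) / 2, pl = (b - 1) / 2;
  M.zeros();
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int px = i * W + j;
      for (int c = 0; c < C; ++c) {
        for (int p = 0; p < a; ++p) {
          const int ii = i + p - pt;
          if (ii < 0 || ii >= H) continue;
          for (int q = 0; q < b; ++q) {
            const int jj = j + q - pl;
            if (jj < 0 || jj >= W) continue;
            M(colrow(c, p, q, a, b), px) = X(c, ii * W + jj);
          }
        }
      }
    }
  }
}

// scatter-add of dM back onto the input (inverse of im2col_same)
void col2im_same(const arma::mat& dM, int H, int W, int a, int b,
                 arma::mat& dX) {
  const int C = dX.n_rows;
  const int pt = (a - 1) / 2, pl = (b - 1) / 2;
  dX.zeros();
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int px = i * W + j;
      for (int c = 0; c < C; ++c) {
        for (int p = 0; p < a; ++p) {
          const int ii = i + p - pt;
          if (ii < 0 || ii >= H) continue;
          for (int q = 0; q < b; ++q) {
            const int jj = j + q - pl;
            if (jj < 0 || jj >= W) continue;
            dX(c, ii * W + jj) += dM(colrow(c, p, q, a, b), px);
          }
        }
      }
    }
  }
}

// k x k max pooling of Y (F x H*W) -> P (F x (H/k)*(W/k)); arg holds the
// winning input pixel index for the backward pass. Ties go to the first
// (row-major smallest) pixel scanned.
void maxpool_fwd(const arma::mat& Y, int H, int W, int k,
                 arma::mat& P, arma::imat& arg) {
  const int F = Y.n_rows, ph = H / k, pw = W / k;
  for (int f = 0; f < F; ++f) {
    for (int oi = 0; oi < ph; ++oi) {
      for (int oj = 0; oj < pw; ++oj) {
        double best = -std::numeric_limits<double>::infinity();
        int bestpx = -1;
        for (int di = 0; di < k; ++di) {
          for (int dj = 0; dj < k; ++dj) {
            const int px = (oi * k + di) * W + (oj * k + dj);
            const double v = Y(f, px);
            if (v > best) { best = v; bestpx = px; }
          }
        }
        P(f, oi * pw + oj) = best;
        arg(f, oi * pw + oj) = bestpx;
      }
    }
  }
}

struct Workspace {
  // per conv layer
  std::vector<arma::mat> X;     // input maps (C x H*W)
  std::vector<arma::mat> M;     // im2col buffer
  std::vector<arma::mat> Ypre;  // pre-activation (F x H*W)
  std::vector<arma::mat> P;     // pooled output
  std::vector<arma::imat> Parg;
  std::vector<int> H, W, pH, pW;
  // dense
  arma::vec flat;
  std::vector<arma::vec> hpre, h, mask;
  arma::vec prob;
};

void make_workspace(const std::vector<ConvLayer>& conv,
                    const std::vector<DenseLayer>& dense,
                    const IntegerVector& pool, int H0, int W0, int C0,
                    Workspace& ws) {
  const size_t L = conv.size();
  ws.X.resize(L); ws.M.resize(L); ws.Ypre.resize(L);
  ws.P.resize(L); ws.Parg.resize(L);
  ws.H.resize(L); ws.W.resize(L); ws.pH.resize(L); ws.pW.resize(L);
  int h = H0, w = W0, c = C0;
  for (size_t l = 0; l < L; ++l) {
    ws.H[l] = h; ws.W[l] = w;
    ws.X[l].set_size(c, h * w);
    ws.M[l].set_size(c * conv[l].a * conv[l].b, h * w);
    ws.Ypre[l].set_size(conv[l].f, h * w);
    const int k = pool[l];
    ws.pH[l] = h / k; ws.pW[l] = w / k;
    ws.P[l].set_size(conv[l].f, ws.pH[l] * ws.pW[l]);
    ws.Parg[l].set_size(conv[l].f, ws.pH[l] * ws.pW[l]);
    h = ws.pH[l]; w = ws.pW[l]; c = conv[l].f;
  }
  ws.flat.set_size(c * h * w);
  ws.hpre.resize(dense.size());
  ws.h.resize(dense.size());
  ws.mask.resize(dense.size());
  for (size_t z = 0; z < dense.size(); ++z) {
    ws.hpre[z].set_size(dense[z].W.n_rows);
    ws.h[z].set_size(dense[z].W.n_rows);
    ws.mask[z].set_size(dense[z].W.n_rows);
  }
}

// copy image n of the R array (H,W,C,N) into (C x H*W) row-major-pixel
void load_image(const double* img, int H, int W, int C, long n,
                arma::mat& X) {
  const long base = n * (long)H * W * C;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        X(c, i * W + j) = img[base + i + (long)H * j + (long)H * W * c];
}

// forward one image; returns probabilities in ws.prob
void forward(const double* img, long n, int H0, int W0, int C0,
             const std::vector<ConvLayer>& conv,
             const std::vector<DenseLayer>& dense,
             const IntegerVector& pool, double dropout, bool training,
             std::mt19937_64* rng, Workspace& ws) {
  load_image(img, H0, W0, C0, n, ws.X[0]);
  const size_t L = conv.size();
  for (size_t l = 0; l < L; ++l) {
    im2col_same(ws.X[l], ws.H[l], ws.W[l], conv[l].a, conv[l].b, ws.M[l]);
    ws.Ypre[l] = conv[l].Wm * ws.M[l];
    ws.Ypre[l].each_col() += conv[l].bias;
    arma::mat Yact = arma::clamp(ws.Ypre[l], 0.0,
                                 std::numeric_limits<double>::infinity());
    maxpool_fwd(Yact, ws.H[l], ws.W[l], pool[l], ws.P[l], ws.Parg[l]);
    if (l + 1 < L) ws.X[l + 1] = ws.P[l];
  }
  // flatten: filter-major, pixels row-major
  const arma::mat& Pl = ws.P[L - 1];
  const int pix = Pl.n_cols;
  for (arma::uword f = 0; f < Pl.n_rows; ++f)
    for (int p = 0; p < pix; ++p)
      ws.flat[f * pix + p] = Pl(f, p);
  // dense stack; ReLU + dropout on hidden layers, identity on the last
  const arma::vec* in = &ws.flat;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t z = 0; z < dense.size(); ++z) {
    ws.hpre[z] = dense[z].W * (*in) + dense[z].b;
    if (z + 1 < dense.size()) {
      ws.h[z] = arma::clamp(ws.hpre[z], 0.0,
                            std::numeric_limits<double>::infinity());
      if (training && dropout > 0.0) {
        for (arma::uword i = 0; i < ws.h[z].n_elem; ++i)
          ws.mask[z][i] = (unif(*rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        ws.h[z] %= ws.mask[z];
      } else {
        ws.mask[z].ones();
      }
    } else {
      ws.h[z] = ws.hpre[z];  // logits
    }
    in = &ws.h[z];
  }
  const arma::vec& logits = ws.h.back();
  ws.prob = arma::exp(logits - logits.max());
  ws.prob /= arma::accu(ws.prob);
}

struct Grads {
  std::vector<arma::mat> convW;
  std::vector<arma::vec> convB;
  std::vector<arma::mat> denseW;
  std::vector<arma::vec> denseB;
  void zero() {
    for (auto& g : convW) g.zeros();
    for (auto& g : convB) g.zeros();
    for (auto& g : denseW) g.zeros();
    for (auto& g : denseB) g.zeros();
  }
};

void backward(int label, const std::vector<ConvLayer>& conv,
              const std::vector<DenseLayer>& dense,
              const IntegerVector& pool, Workspace& ws, Grads& g) {
  const size_t nz = dense.size();
  arma::vec delta = ws.prob;           // dL/dlogits = p - onehot
  delta[label] -= 1.0;
  for (size_t zi = nz; zi-- > 0;) {
    const arma::vec& input = (zi == 0) ? ws.flat : ws.h[zi - 1];
    g.denseW[zi] += delta * input.t();
    g.denseB[zi] += delta;
    if (zi == 0) { delta = dense[zi].W.t() * delta; break; }
    arma::vec d = dense[zi].W.t() * delta;
    d %= ws.mask[zi - 1];                       // dropout
    for (arma::uword i = 0; i < d.n_elem; ++i)  // ReLU
      if (ws.hpre[zi - 1][i] <= 0.0) d[i] = 0.0;
    delta = d;
  }
  // delta is now dL/dflat; walk the conv stack backwards
  const size_t L = conv.size();
  arma::mat dP;
  for (size_t l = L; l-- > 0;) {
    const int pix = ws.P[l].n_cols;
    if (l == L - 1) {
      dP.set_size(conv[l].f, pix);
      for (int f = 0; f < conv[l].f; ++f)
        for (int p = 0; p < pix; ++p)
          dP(f, p) = delta[f * (long)pix + p];
    }
    // pool backward + ReLU backward into dY (F x H*W)
    arma::mat dY(conv[l].f, ws.H[l] * ws.W[l], arma::fill::zeros);
    for (int f = 0; f < conv[l].f; ++f)
      for (int p = 0; p < pix; ++p)
        dY(f, ws.Parg[l](f, p)) += dP(f, p);
    dY.elem(arma::find(ws.Ypre[l] <= 0.0)).zeros();
    g.convW[l] += dY * ws.M[l].t();
    g.convB[l] += arma::sum(dY, 1);
    if (l > 0) {
      arma::mat dM = conv[l].Wm.t() * dY;
      dP.set_size(ws.X[l].n_rows, ws.X[l].n_cols);
      col2im_same(dM, ws.H[l], ws.W[l], conv[l].a, conv[l].b, dP);
    }
  }
}

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::vec> mB, vB;
  double lr, b1, b2, eps;
  long t = 0;
  template <typename T>
  void step_one(T& param, const T& grad, T& m, T& v) {
    m = b1 * m + (1.0 - b1) * grad;
    v = b2 * v + (1.0 - b2) * (grad % grad);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    param -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

std::vector<ConvLayer> read_conv(const List& conv_w) {
  std::vector<ConvLayer> conv;
  for (int l = 0; l < conv_w.size(); ++l) {
    List cw = conv_w[l];
    NumericVector W = cw["W"];
    NumericVector bias = cw["b"];
    IntegerVector d = W.attr("dim");  // a, b, cin, f
    ConvLayer cl;
    cl.a = d[0]; cl.b = d[1]; cl.cin = d[2]; cl.f = d[3];
    cl.Wm.set_size(cl.f, cl.cin * cl.a * cl.b);
    for (int f = 0; f < cl.f; ++f)
      for (int c = 0; c < cl.cin; ++c)
        for (int p = 0; p < cl.a; ++p)
          for (int q = 0; q < cl.b; ++q)
            cl.Wm(f, colrow(c, p, q, cl.a, cl.b)) =
              W[p + cl.a * (q + cl.b * (c + cl.cin * f))];
    cl.bias = arma::vec(bias.begin(), bias.size());
    conv.push_back(std::move(cl));
  }
  return conv;
}

std::vector<DenseLayer> read_dense(const List& dense_w) {
  std::vector<DenseLayer> dense;
  for (int z = 0; z < dense_w.size(); ++z) {
    List dw = dense_w[z];
    NumericMatrix W = dw["W"];
    NumericVector b = dw["b"];
    DenseLayer dl;
    dl.W = arma::mat(W.begin(), W.nrow(), W.ncol());
    dl.b = arma::vec(b.begin(), b.size());
    dense.push_back(std::move(dl));
  }
  return dense;
}

List write_conv(const std::vector<ConvLayer>& conv) {
  List out(conv.size());
  for (size_t l = 0; l < conv.size(); ++l) {
    const ConvLayer& cl = conv[l];
    NumericVector W(cl.a * cl.b * cl.cin * cl.f);
    for (int f = 0; f < cl.f; ++f)
      for (int c = 0; c < cl.cin; ++c)
        for (int p = 0; p < cl.a; ++p)
          for (int q = 0; q < cl.b; ++q)
            W[p + cl.a * (q + cl.b * (c + cl.cin * f))] =
              cl.Wm(f, colrow(c, p, q, cl.a, cl.b));
    out[l] = List::create(Named("W") = W,
                          Named("b") = NumericVector(cl.bias.begin(),
                                                     cl.bias.end()));
  }
  return out;
}

List write_dense(const std::vector<DenseLayer>& dense) {
  List out(dense.size());
  for (size_t z = 0; z < dense.size(); ++z) {
    NumericMatrix W(dense[z].W.n_rows, dense[z].W.n_cols);
    std::copy(dense[z].W.begin(), dense[z].W.end(), W.begin());
    out[z] = List::create(Named("W") = W,
                          Named("b") = NumericVector(dense[z].b.begin(),
                                                     dense[z].b.end()));
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_dcnn_train(NumericVector images, IntegerVector labels,
                    List conv_w, List dense_w, IntegerVector pool,
                    double dropout, int epochs, int batch_size,
                    double lr, double beta1, double beta2, double eps,
                    int seed, int n_classes) {
  IntegerVector dims = images.attr("dim");
  const int H0 = dims[0], W0 = dims[1], C0 = dims[2];
  const long N = dims[3];
  if (N == 0) stop("empty training set");
  for (long i = 0; i < N; ++i)
    if (labels[i] < 0 || labels[i] >= n_classes)
      stop("label %d outside [0, %d)", labels[i], n_classes);

  std::vector<ConvLayer> conv = read_conv(conv_w);
  std::vector<DenseLayer> dense = read_dense(dense_w);
  Workspace ws;
  make_workspace(conv, dense, pool, H0, W0, C0, ws);

  Grads g;
  Adam opt;
  opt.lr = lr; opt.b1 = beta1; opt.b2 = beta2; opt.eps = eps;
  for (const auto& cl : conv) {
    g.convW.emplace_back(arma::size(cl.Wm), arma::fill::zeros);
    g.convB.emplace_back(cl.bias.n_elem, arma::fill::zeros);
    opt.mW.emplace_back(arma::size(cl.Wm), arma::fill::zeros);
    opt.vW.emplace_back(arma::size(cl.Wm), arma::fill::zeros);
    opt.mB.emplace_back(cl.bias.n_elem, arma::fill::zeros);
    opt.vB.emplace_back(cl.bias.n_elem, arma::fill::zeros);
  }
  std::vector<arma::mat> dmW, dvW;
  std::vector<arma::vec> dmB, dvB;
  for (const auto& dl : dense) {
    g.denseW.emplace_back(arma::size(dl.W), arma::fill::zeros);
    g.denseB.emplace_back(dl.b.n_elem, arma::fill::zeros);
    dmW.emplace_back(arma::size(dl.W), arma::fill::zeros);
    dvW.emplace_back(arma::size(dl.W), arma::fill::zeros);
    dmB.emplace_back(dl.b.n_elem, arma::fill::zeros);
    dvB.emplace_back(dl.b.n_elem, arma::fill::zeros);
  }

  std::mt19937_64 rng((unsigned long long)seed);
  std::vector<long> order(N);
  for (long i = 0; i < N; ++i) order[i] = i;

  NumericVector hist_loss(epochs), hist_acc(epochs);
  const double* img = images.begin();

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    long correct = 0;
    for (long start = 0; start < N; start += batch_size) {
      const long end = std::min(N, start + (long)batch_size);
      const double scale = 1.0 / (double)(end - start);
      g.zero();
      for (long bi = start; bi < end; ++bi) {
        const long n = order[bi];
        forward(img, n, H0, W0, C0, conv, dense, pool, dropout, true,
                &rng, ws);
        const double p = std::max(ws.prob[labels[n]], 1e-12);
        loss_sum += -std::log(p);
        if ((int)ws.prob.index_max() == labels[n]) ++correct;
        backward(labels[n], conv, dense, pool, ws, g);
      }
      ++opt.t;
      for (size_t l = 0; l < conv.size(); ++l) {
        arma::mat gw = g.convW[l] * scale;
        arma::vec gb = g.convB[l] * scale;
        opt.step_one(conv[l].Wm, gw, opt.mW[l], opt.vW[l]);
        opt.step_one(conv[l].bias, gb, opt.mB[l], opt.vB[l]);
      }
      for (size_t z = 0; z < dense.size(); ++z) {
        arma::mat gw = g.denseW[z] * scale;
        arma::vec gb = g.denseB[z] * scale;
        opt.step_one(dense[z].W, gw, dmW[z], dvW[z]);
        opt.step_one(dense[z].b, gb, dmB[z], dvB[z]);
      }
      if (start % 16384 == 0) Rcpp::checkUserInterrupt();
    }
    hist_loss[e] = loss_sum / (double)N;
    hist_acc[e] = (double)correct / (double)N;
  }

  return List::create(Named("conv") = write_conv(conv),
                      Named("dense") = write_dense(dense),
                      Named("loss") = hist_loss,
                      Named("accuracy") = hist_acc);
}

// [[Rcpp::export]]
NumericMatrix cpp_dcnn_predict(NumericVector images, List conv_w,
                               List dense_w, IntegerVector pool,
                               int n_classes) {
  IntegerVector dims = images.attr("dim");
  const int H0 = dims[0], W0 = dims[1], C0 = dims[2];
  const long N = dims[3];
  std::vector<ConvLayer> conv = read_conv(conv_w);
  std::vector<DenseLayer> dense = read_dense(dense_w);
  Workspace ws;
  make_workspace(conv, dense, pool, H0, W0, C0, ws);
  NumericMatrix probs(N, n_classes);
  const double* img = images.begin();
  for (long n = 0; n < N; ++n) {
    forward(img, n, H0, W0, C0, conv, dense, pool, 0.0, false, nullptr, ws);
    for (int j = 0; j < n_classes; ++j) probs(n, j) = ws.prob[j];
    if (n % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return probs;
}

// First-layer pre-activation maps for one image: used by the test suite
// to check the compiled convolution against the reference operations.
// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector image, List conv_w) {
  IntegerVector dims = image.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  std::vector<ConvLayer> conv = read_conv(conv_w);
  const ConvLayer& cl = conv[0];
  arma::mat X(C, H * W), M(C * cl.a * cl.b, H * W);
  const double* img = image.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        X(c, i * W + j) = img[i + (long)H * j + (long)H * W * c];
  im2col_same(X, H, W, cl.a, cl.b, M);
  arma::mat Y = cl.Wm * M;
  Y.each_col() += cl.bias;
  NumericVector out(H * W * cl.f);
  out.attr("dim") = IntegerVector::create(H, W, cl.f);
  for (int f = 0; f < cl.f; ++f)
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j)
        out[i + (long)H * j + (long)H * W * f] = Y(f, i * W + j);
  return out;
}
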