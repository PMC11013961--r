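// Convolutional local-count regressor and connected-component labeling.
//
// Activations for a batch of N feature maps of size H x W x C are stored as an
// arma::mat with N*H*W rows (sample-major, then row, then column: row index
// n*H*W + i*W + j) and C columns. This layout makes 3x3 convolution a single
// im2col + GEMM, and batch normalization a per-column moment computation.
//
// All randomness (weight init, epoch shuffling, dropout masks) is drawn from
// R's RNG so that results are reproducible under set.seed().

#include <RcppArmadillo.h>
#include <functional>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// Reorder flattened patches from R's array order (i + ps*j + ps*ps*c per
// sample) into the activation layout described above.
static mat patchesToActivations(const mat& X, int ps) {
  int N = X.n_rows;
  mat A(N * ps * ps, 3);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < 3; ++c)
      for (int j = 0; j < ps; ++j)
        for (int i = 0; i < ps; ++i)
          A(n * ps * ps + i * ps + j, c) = X(n, i + ps * j + ps * ps * c);
  return A;
}

// im2col for a 3x3 kernel with zero padding 1.
static mat im2col3(const mat& A, int N, int H, int W) {
  int C = A.n_cols;
  mat out(A.n_rows, 9 * C, arma::fill::zeros);
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      int k = (di + 1) * 3 + (dj + 1);
      int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      int len = j1 - j0;
      if (len <= 0) continue;
      for (int n = 0; n < N; ++n) {
        int base = n * H * W;
        for (int i = i0; i < i1; ++i) {
          int src = base + (i + di) * W + (j0 + dj);
          int dst = base + i * W + j0;
          out.submat(dst, k * C, dst + len - 1, k * C + C - 1) =
              A.submat(src, 0, src + len - 1, C - 1);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add the column gradient back onto the input.
static mat col2im3(const mat& dCols, int N, int H, int W, int C) {
  mat dA(N * H * W, C, arma::fill::zeros);
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      int k = (di + 1) * 3 + (dj + 1);
      int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      int len = j1 - j0;
      if (len <= 0) continue;
      for (int n = 0; n < N; ++n) {
        int base = n * H * W;
        for (int i = i0; i < i1; ++i) {
          int src = base + (i + di) * W + (j0 + dj);
          int dst = base + i * W + j0;
          dA.submat(src, 0, src + len - 1, C - 1) +=
              dCols.submat(dst, k * C, dst + len - 1, k * C + C - 1);
        }
      }
    }
  }
  return dA;
}

static mat maxpool2(const mat& A, int N, int H, int W, arma::umat& argmax) {
  int C = A.n_cols, Ho = H / 2, Wo = W / 2;
  mat out(N * Ho * Wo, C);
  argmax.set_size(N * Ho * Wo, C);
  for (int n = 0; n < N; ++n) {
    for (int i = 0; i < Ho; ++i) {
      for (int j = 0; j < Wo; ++j) {
        int orow = n * Ho * Wo + i * Wo + j;
        int r00 = n * H * W + (2 * i) * W + 2 * j;
        int rows[4] = {r00, r00 + 1, r00 + W, r00 + W + 1};
        for (int c = 0; c < C; ++c) {
          double best = A(rows[0], c);
          int bi = rows[0];
          for (int q = 1; q < 4; ++q) {
            double v = A(rows[q], c);
            if (v > best) { best = v; bi = rows[q]; }
          }
          out(orow, c) = best;
          argmax(orow, c) = bi;
        }
      }
    }
  }
  return out;
}

static mat maxpool2_backward(const mat& dOut, const arma::umat& argmax,
                             int nrowIn) {
  mat dA(nrowIn, dOut.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < dOut.n_rows; ++r)
    for (arma::uword c = 0; c < dOut.n_cols; ++c)
      dA(argmax(r, c), c) += dOut(r, c);
  return dA;
}

struct ConvBlock {
  mat W;             // (9*Cin) x Cout
  rowvec gamma, beta, rmean, rvar;
};

struct Net {
  std::vector<ConvBlock> blocks;
  vec headW;
  double headB;
};

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mG, vG, mB, vB;
  vec mHw, vHw;
  double mHb, vHb;
  long t;
};

// Per-batch caches needed for the backward pass.
struct BlockCache {
  mat cols;        // im2col of the block input
  mat xhat;        // normalized pre-activation
  rowvec invstd;
  mat reluIn;      // post-BN (input to ReLU)
  arma::umat poolArg;
  int nrowPre;     // rows before pooling
  mat dropMask;    // empty when dropout off
};

static void initNet(Net& net, const IntegerVector& widths, int ps,
                    double headBias) {
  int cin = 3;
  net.blocks.clear();
  for (int b = 0; b < widths.size(); ++b) {
    int cout = widths[b];
    ConvBlock blk;
    blk.W.set_size(9 * cin, cout);
    double sd = std::sqrt(2.0 / (9.0 * cin));
    for (arma::uword k = 0; k < blk.W.n_elem; ++k) blk.W(k) = norm_rand() * sd;
    blk.gamma = rowvec(cout, arma::fill::ones);
    blk.beta = rowvec(cout, arma::fill::zeros);
    blk.rmean = rowvec(cout, arma::fill::zeros);
    blk.rvar = rowvec(cout, arma::fill::ones);
    net.blocks.push_back(blk);
    cin = cout;
  }
  int npool = (int)widths.size() - 1;
  int side = ps >> npool;
  int D = side * side * cin;
  net.headW.set_size(D);
  // damped head init: the network starts close to the constant predictor
  // (headBias is set to the mean training target by the caller)
  double sd = 0.1 * std::sqrt(2.0 / D);
  for (int k = 0; k < D; ++k) net.headW(k) = norm_rand() * sd;
  net.headB = headBias;
}

// Forward pass. When training, batch statistics are used for BN (and running
// stats updated); otherwise the stored running statistics are used.
static vec forward(Net& net, const mat& A0, int N, int ps, bool training,
                   double dropout, std::vector<BlockCache>* caches,
                   mat* flatOut) {
  mat A = A0;
  int H = ps, W = ps;
  int nb = (int)net.blocks.size();
  for (int b = 0; b < nb; ++b) {
    ConvBlock& blk = net.blocks[b];
    BlockCache cache;
    mat cols = im2col3(A, N, H, W);
    mat Z = cols * blk.W;
    rowvec mu, invstd;
    if (training) {
      mu = arma::mean(Z, 0);
      rowvec var = arma::mean(arma::square(Z.each_row() - mu), 0);
      invstd = 1.0 / arma::sqrt(var + BN_EPS);
      blk.rmean = (1.0 - BN_MOMENTUM) * blk.rmean + BN_MOMENTUM * mu;
      blk.rvar = (1.0 - BN_MOMENTUM) * blk.rvar + BN_MOMENTUM * var;
    } else {
      mu = blk.rmean;
      invstd = 1.0 / arma::sqrt(blk.rvar + BN_EPS);
    }
    mat xhat = (Z.each_row() - mu).each_row() % invstd;
    mat Y = (xhat.each_row() % blk.gamma).each_row() + blk.beta;
    if (caches) {
      cache.cols = std::move(cols);
      cache.xhat = xhat;
      cache.invstd = invstd;
      cache.reluIn = Y;
    }
    Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (b < nb - 1) {
      arma::umat arg;
      int nrowPre = N * H * W;
      Y = maxpool2(Y, N, H, W, arg);
      H /= 2; W /= 2;
      if (caches) { cache.poolArg = std::move(arg); cache.nrowPre = nrowPre; }
    } else if (caches) {
      cache.nrowPre = -1;
    }
    // dropout only after the last block: placed before any batch norm it
    // would inflate the batch variance at train time and bias the running
    // statistics used at evaluation
    if (training && dropout > 0.0 && b == nb - 1) {
      mat msk(Y.n_rows, Y.n_cols);
      double scale = 1.0 / (1.0 - dropout);
      for (arma::uword k = 0; k < msk.n_elem; ++k)
        msk(k) = (unif_rand() < dropout) ? 0.0 : scale;
      Y %= msk;
      if (caches) cache.dropMask = std::move(msk);
    }
    if (caches) (*caches)[b] = std::move(cache);
    A = std::move(Y);
  }
  // Flatten (position, channel) rows per sample into one row per sample.
  int P = H * W, C = A.n_cols;
  mat Xf(N, P * C);
  for (int n = 0; n < N; ++n)
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < C; ++c)
        Xf(n, p * C + c) = A(n * P + p, c);
  if (flatOut) *flatOut = Xf;
  return Xf * net.headW + net.headB;
}

struct Grads {
  std::vector<mat> dW;
  std::vector<rowvec> dGamma, dBeta;
  vec dHw;
  double dHb;
};

static void backward(Net& net, std::vector<BlockCache>& caches,
                     const mat& flat, const vec& dyhat, int N, int ps,
                     Grads& g) {
  int nb = (int)net.blocks.size();
  g.dW.assign(nb, mat());
  g.dGamma.assign(nb, rowvec());
  g.dBeta.assign(nb, rowvec());
  g.dHw = flat.t() * dyhat;
  g.dHb = arma::accu(dyhat);
  // dimensions at the output of each block
  std::vector<int> Hs(nb + 1), Ws(nb + 1);
  Hs[0] = ps; Ws[0] = ps;
  for (int b = 0; b < nb; ++b) {
    Hs[b + 1] = (b < nb - 1) ? Hs[b] / 2 : Hs[b];
    Ws[b + 1] = (b < nb - 1) ? Ws[b] / 2 : Ws[b];
  }
  int P = Hs[nb] * Ws[nb];
  int C = net.blocks[nb - 1].W.n_cols;
  mat dA(N * P, C);
  for (int n = 0; n < N; ++n)
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < C; ++c)
        dA(n * P + p, c) = dyhat(n) * net.headW(p * C + c);
  for (int b = nb - 1; b >= 0; --b) {
    BlockCache& cache = caches[b];
    ConvBlock& blk = net.blocks[b];
    if (cache.dropMask.n_elem > 0) dA %= cache.dropMask;
    if (cache.nrowPre >= 0)
      dA = maxpool2_backward(dA, cache.poolArg, cache.nrowPre);
    // ReLU
    dA %= arma::conv_to<mat>::from(cache.reluIn > 0.0);
    // BatchNorm backward (batch statistics)
    double M = (double)dA.n_rows;
    g.dGamma[b] = arma::sum(dA % cache.xhat, 0);
    g.dBeta[b] = arma::sum(dA, 0);
    mat dxhat = dA.each_row() % blk.gamma;
    rowvec sum_dxhat = arma::sum(dxhat, 0);
    rowvec sum_dxhat_xhat = arma::sum(dxhat % cache.xhat, 0);
    mat dZ = (dxhat * M - (cache.xhat.each_row() % sum_dxhat_xhat));
    dZ.each_row() -= sum_dxhat;
    dZ.each_row() %= (cache.invstd / M);
    g.dW[b] = cache.cols.t() * dZ;
    if (b > 0) {
      mat dCols = dZ * blk.W.t();
      int Cin = net.blocks[b - 1].W.n_cols;
      dA = col2im3(dCols, N, Hs[b], Ws[b], Cin);
    }
  }
}

static void adamInit(AdamState& st, const Net& net) {
  int nb = (int)net.blocks.size();
  st.mW.clear(); st.vW.clear();
  st.mG.clear(); st.vG.clear(); st.mB.clear(); st.vB.clear();
  for (int b = 0; b < nb; ++b) {
    st.mW.push_back(mat(arma::size(net.blocks[b].W), arma::fill::zeros));
    st.vW.push_back(mat(arma::size(net.blocks[b].W), arma::fill::zeros));
    st.mG.push_back(rowvec(net.blocks[b].gamma.n_elem, arma::fill::zeros));
    st.vG.push_back(rowvec(net.blocks[b].gamma.n_elem, arma::fill::zeros));
    st.mB.push_back(rowvec(net.blocks[b].beta.n_elem, arma::fill::zeros));
    st.vB.push_back(rowvec(net.blocks[b].beta.n_elem, arma::fill::zeros));
  }
  st.mHw = vec(net.headW.n_elem, arma::fill::zeros);
  st.vHw = vec(net.headW.n_elem, arma::fill::zeros);
  st.mHb = 0.0; st.vHb = 0.0;
  st.t = 0;
}

template <typename T>
static void adamUpdate(T& param, T& m, T& v, const T& grad, double lr,
                       double bc1, double bc2) {
  m = 0.9 * m + 0.1 * grad;
  v = 0.999 * v + 0.001 * (grad % grad);
  param -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

static void adamStep(Net& net, AdamState& st, const Grads& g, double lr) {
  st.t += 1;
  double bc1 = 1.0 - std::pow(0.9, (double)st.t);
  double bc2 = 1.0 - std::pow(0.999, (double)st.t);
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    adamUpdate(net.blocks[b].W, st.mW[b], st.vW[b], g.dW[b], lr, bc1, bc2);
    adamUpdate(net.blocks[b].gamma, st.mG[b], st.vG[b], g.dGamma[b], lr, bc1, bc2);
    adamUpdate(net.blocks[b].beta, st.mB[b], st.vB[b], g.dBeta[b], lr, bc1, bc2);
  }
  adamUpdate(net.headW, st.mHw, st.vHw, g.dHw, lr, bc1, bc2);
  st.mHb = 0.9 * st.mHb + 0.1 * g.dHb;
  st.vHb = 0.999 * st.vHb + 0.001 * g.dHb * g.dHb;
  net.headB -= lr * (st.mHb / bc1) / (std::sqrt(st.vHb / bc2) + 1e-8);
}

static List netToList(const Net& net) {
  List blocks(net.blocks.size());
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    const ConvBlock& blk = net.blocks[b];
    blocks[b] = List::create(
        Named("W") = wrap(blk.W), Named("gamma") = wrap(blk.gamma),
        Named("beta") = wrap(blk.beta), Named("rmean") = wrap(blk.rmean),
        Named("rvar") = wrap(blk.rvar));
  }
  return List::create(Named("blocks") = blocks,
                      Named("head_w") = wrap(net.headW),
                      Named("head_b") = net.headB);
}

static Net netFromList(List params) {
  Net net;
  List blocks = params["blocks"];
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    ConvBlock cb;
    cb.W = as<mat>(blk["W"]);
    cb.gamma = as<rowvec>(blk["gamma"]);
    cb.beta = as<rowvec>(blk["beta"]);
    cb.rmean = as<rowvec>(blk["rmean"]);
    cb.rvar = as<rowvec>(blk["rvar"]);
    net.blocks.push_back(cb);
  }
  net.headW = as<vec>(params["head_w"]);
  net.headB = as<double>(params["head_b"]);
  return net;
}

static double evalL1(Net& net, const mat& X, const vec& y, int ps, int chunk) {
  int N = X.n_rows;
  double acc = 0.0;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    mat Xc = X.rows(s, e - 1);
    mat A0 = patchesToActivations(Xc, ps);
    vec yh = forward(net, A0, e - s, ps, false, 0.0, nullptr, nullptr);
    acc += arma::accu(arma::abs(yh - y.subvec(s, e - 1)));
  }
  return acc / N;
}

// [[Rcpp::export]]
List cnnTrainCpp(const arma::mat& Xtr, const arma::vec& ytr,
                 const arma::mat& Xval, const arma::vec& yval,
                 IntegerVector widths, int patchSize, double lr,
                 int maxEpochs, int patience, int batchSize, double dropout,
                 bool verbose) {
  int N = Xtr.n_rows;
  Net net;
  initNet(net, widths, patchSize, arma::mean(ytr));
  AdamState st;
  adamInit(st, net);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> trainLoss, valLoss;
  double bestVal = R_PosInf;
  int bestEpoch = 0, wait = 0;
  List bestParams = netToList(net);
  int nb = widths.size();
  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epochLoss = 0.0;
    long seen = 0;
    for (int s = 0; s < N; s += batchSize) {
      int e = std::min(N, s + batchSize);
      int M = e - s;
      if (M < 2) continue;  // batch statistics need >= 2 rows
      arma::uvec idx(M);
      for (int k = 0; k < M; ++k) idx[k] = order[s + k];
      mat Xb = Xtr.rows(idx);
      vec yb = ytr.elem(idx);
      mat A0 = patchesToActivations(Xb, patchSize);
      std::vector<BlockCache> caches(nb);
      mat flat;
      vec yh = forward(net, A0, M, patchSize, true, dropout, &caches, &flat);
      vec resid = yh - yb;
      epochLoss += arma::accu(arma::abs(resid));
      seen += M;
      vec dy = arma::sign(resid) / (double)M;
      Grads g;
      backward(net, caches, flat, dy, M, patchSize, g);
      adamStep(net, st, g, lr);
    }
    double tl = seen > 0 ? epochLoss / seen : NA_REAL;
    double vl = evalL1(net, Xval, yval, patchSize, 512);
    trainLoss.push_back(tl);
    valLoss.push_back(vl);
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch << " train L1 " << tl << " val L1 "
                  << vl << std::endl;
    if (vl < bestVal - 1e-12) {
      bestVal = vl;
      bestEpoch = epoch;
      bestParams = netToList(net);
      wait = 0;
    } else {
      wait += 1;
      if (wait >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("params") = bestParams,
                      Named("train_loss") = wrap(trainLoss),
                      Named("val_loss") = wrap(valLoss),
                      Named("best_epoch") = bestEpoch,
                      Named("best_val_loss") = bestVal);
}

// [[Rcpp::export]]
arma::vec cnnPredictCpp(List params, const arma::mat& X, int patchSize,
                        int chunk) {
  Net net = netFromList(params);
  int N = X.n_rows;
  vec out(N);
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    mat Xc = X.rows(s, e - 1);
    mat A0 = patchesToActivations(Xc, patchSize);
    vec yh = forward(net, A0, e - s, patchSize, false, 0.0, nullptr, nullptr);
    out.subvec(s, e - 1) = yh;
  }
  return out;
}

// 8-connected component labeling of a logical mask (union-find).
// [[Rcpp::export]]
IntegerMatrix labelComponents8(const LogicalMatrix& keep) {
  int H = keep.nrow(), W = keep.ncol();
  std::vector<int> parent(H * W, -1);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!keep(i, j)) continue;
      int id = i * W + j;
      parent[id] = id;
      // neighbours already visited in raster order: W, NW, N, NE
      if (j > 0 && keep(i, j - 1)) unite(id, i * W + j - 1);
      if (i > 0) {
        if (j > 0 && keep(i - 1, j - 1)) unite(id, (i - 1) * W + j - 1);
        if (keep(i - 1, j)) unite(id, (i - 1) * W + j);
        if (j < W - 1 && keep(i - 1, j + 1)) unite(id, (i - 1) * W + j + 1);
      }
    }
  }
  IntegerMatrix lab(H, W);
  std::map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!keep(i, j)) { lab(i, j) = 0; continue; }
      int root = find(i * W + j);
      auto it = relabel.find(root);
      if (it == relabel.end()) { relabel[root] = ++next; lab(i, j) = next; }
      else lab(i, j) = it->second;
    }
  }
  return lab;
}
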