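// Core numerical engine for the 4-layer 2D CNN: im2col convolution (stride 2,
// "same" padding), 2x2 max pooling, dense layers, sigmoid output, weighted
// binary cross-entropy, and SGD with momentum and time-based learning-rate
// decay.  All arithmetic is single precision, single path, so that training
// is bit-reproducible given the same initial weights and shuffle schedule
// (both supplied from R, where the seeded RNG lives).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvDims {
  int Hin, Win, Cin, F;
  int Hout, Wout;      // after conv (stride 2, same padding)
  int Hp, Wp;          // after 2x2 max pool
  int pad_top, pad_left;
};

// Keras-style "same" padding for stride s, kernel k: out = ceil(in/s),
// total pad = max((out-1)*s + k - in, 0), split with the extra pixel after.
inline void same_pad(int in, int k, int s, int& out, int& pad_before) {
  out = (in + s - 1) / s;
  int total = std::max((out - 1) * s + k - in, 0);
  pad_before = total / 2;
}

ConvDims conv_dims(int Hin, int Win, int Cin, int F, int k, int s) {
  ConvDims d;
  d.Hin = Hin; d.Win = Win; d.Cin = Cin; d.F = F;
  same_pad(Hin, k, s, d.Hout, d.pad_top);
  same_pad(Win, k, s, d.Wout, d.pad_left);
  d.Hp = d.Hout / 2;
  d.Wp = d.Wout / 2;
  return d;
}

// Patch matrix for one sample: rows = output positions (row-major over
// (i,j) with i fastest, matching arma column ordering of the output cube),
// cols = kernel taps ordered dy + k*dx + k*k*c.
void im2col(const fcube& x, const ConvDims& d, int k, int s, fmat& P) {
  P.set_size(d.Hout * d.Wout, k * k * d.Cin);
  for (int c = 0; c < d.Cin; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * dx + k * k * c;
        float* dst = P.colptr(col);
        for (int j = 0; j < d.Wout; ++j) {
          const int sx = j * s + dx - d.pad_left;
          const bool xin = sx >= 0 && sx < d.Win;
          for (int i = 0; i < d.Hout; ++i) {
            const int sy = i * s + dy - d.pad_top;
            float v = 0.0f;
            if (xin && sy >= 0 && sy < d.Hin) v = x(sy, sx, c);
            dst[i + d.Hout * j] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-matrix gradient back onto the input cube.
void col2im(const fmat& dP, const ConvDims& d, int k, int s, fcube& dx) {
  dx.zeros(d.Hin, d.Win, d.Cin);
  for (int c = 0; c < d.Cin; ++c) {
    for (int ddx = 0; ddx < k; ++ddx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * ddx + k * k * c;
        const float* src = dP.colptr(col);
        for (int j = 0; j < d.Wout; ++j) {
          const int sx = j * s + ddx - d.pad_left;
          if (sx < 0 || sx >= d.Win) continue;
          for (int i = 0; i < d.Hout; ++i) {
            const int sy = i * s + dy - d.pad_top;
            if (sy < 0 || sy >= d.Hin) continue;
            dx(sy, sx, c) += src[i + d.Hout * j];
          }
        }
      }
    }
  }
}

// 2x2/2 max pool over each slice; argmax linear index (within the HoutxWout
// plane) recorded for the backward pass.
void maxpool(const fcube& a, const ConvDims& d, fcube& out, umat& amax) {
  out.set_size(d.Hp, d.Wp, d.F);
  amax.set_size(d.Hp * d.Wp, d.F);
  for (int f = 0; f < d.F; ++f) {
    for (int j = 0; j < d.Wp; ++j) {
      for (int i = 0; i < d.Hp; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        float best = a(i0, j0, f);
        int bi = i0, bj = j0;
        if (a(i0 + 1, j0, f) > best) { best = a(i0 + 1, j0, f); bi = i0 + 1; bj = j0; }
        if (a(i0, j0 + 1, f) > best) { best = a(i0, j0 + 1, f); bi = i0; bj = j0 + 1; }
        if (a(i0 + 1, j0 + 1, f) > best) { best = a(i0 + 1, j0 + 1, f); bi = i0 + 1; bj = j0 + 1; }
        out(i, j, f) = best;
        amax(i + d.Hp * j, f) = bi + d.Hout * bj;
      }
    }
  }
}

struct Net {
  int k = 3, stride = 2;
  int n_conv = 0;
  std::vector<fmat> Wc;      // (k*k*Cin) x F
  std::vector<frowvec> bc;
  std::vector<fmat> Wd;      // dense, in x out (last is output layer)
  std::vector<frowvec> bd;
  std::vector<ConvDims> dims;
  int flat = 0;
};

Net unpack(const Rcpp::List& weights, int H, int W, int C) {
  Net net;
  const Rcpp::List conv = weights["conv"];
  const Rcpp::List dense = weights["dense"];
  net.n_conv = conv.size();
  int h = H, w = W, c = C;
  for (int l = 0; l < net.n_conv; ++l) {
    const Rcpp::List layer = conv[l];
    const Rcpp::NumericMatrix Wm = layer["W"];
    const Rcpp::NumericVector bv = layer["b"];
    const int F = Wm.ncol();
    if (Wm.nrow() != net.k * net.k * c)
      Rcpp::stop("conv layer %d: weight rows %d != k*k*Cin = %d", l + 1,
                 (int)Wm.nrow(), net.k * net.k * c);
    fmat Wf(Wm.nrow(), Wm.ncol());
    for (int jj = 0; jj < Wm.ncol(); ++jj)
      for (int ii = 0; ii < Wm.nrow(); ++ii) Wf(ii, jj) = (float)Wm(ii, jj);
    frowvec bf(F);
    for (int ii = 0; ii < F; ++ii) bf(ii) = (float)bv[ii];
    net.Wc.push_back(std::move(Wf));
    net.bc.push_back(std::move(bf));
    ConvDims d = conv_dims(h, w, c, F, net.k, net.stride);
    net.dims.push_back(d);
    h = d.Hp; w = d.Wp; c = F;
  }
  if (h != 1 || w != 1)
    Rcpp::stop("conv/pool cascade does not reduce input to 1x1 (got %dx%d)", h, w);
  net.flat = c;
  int nin = c;
  for (int l = 0; l < dense.size(); ++l) {
    const Rcpp::List layer = dense[l];
    const Rcpp::NumericMatrix Wm = layer["W"];
    const Rcpp::NumericVector bv = layer["b"];
    if (Wm.nrow() != nin)
      Rcpp::stop("dense layer %d: weight rows %d != inputs %d", l + 1,
                 (int)Wm.nrow(), nin);
    fmat Wf(Wm.nrow(), Wm.ncol());
    for (int jj = 0; jj < Wm.ncol(); ++jj)
      for (int ii = 0; ii < Wm.nrow(); ++ii) Wf(ii, jj) = (float)Wm(ii, jj);
    frowvec bf(Wm.ncol());
    for (int ii = 0; ii < Wm.ncol(); ++ii) bf(ii) = (float)bv[ii];
    net.Wd.push_back(std::move(Wf));
    net.bd.push_back(std::move(bf));
    nin = Wm.ncol();
  }
  if (nin != 1) Rcpp::stop("final dense layer must have 1 output");
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List conv(net.n_conv), dense(net.Wd.size());
  for (int l = 0; l < net.n_conv; ++l) {
    Rcpp::NumericMatrix Wm(net.Wc[l].n_rows, net.Wc[l].n_cols);
    for (uword jj = 0; jj < net.Wc[l].n_cols; ++jj)
      for (uword ii = 0; ii < net.Wc[l].n_rows; ++ii) Wm(ii, jj) = net.Wc[l](ii, jj);
    Rcpp::NumericVector bv(net.bc[l].n_elem);
    for (uword ii = 0; ii < net.bc[l].n_elem; ++ii) bv[ii] = net.bc[l](ii);
    conv[l] = Rcpp::List::create(Rcpp::Named("W") = Wm, Rcpp::Named("b") = bv);
  }
  for (size_t l = 0; l < net.Wd.size(); ++l) {
    Rcpp::NumericMatrix Wm(net.Wd[l].n_rows, net.Wd[l].n_cols);
    for (uword jj = 0; jj < net.Wd[l].n_cols; ++jj)
      for (uword ii = 0; ii < net.Wd[l].n_rows; ++ii) Wm(ii, jj) = net.Wd[l](ii, jj);
    Rcpp::NumericVector bv(net.bd[l].n_elem);
    for (uword ii = 0; ii < net.bd[l].n_elem; ++ii) bv[ii] = net.bd[l](ii);
    dense[l] = Rcpp::List::create(Rcpp::Named("W") = Wm, Rcpp::Named("b") = bv);
  }
  return Rcpp::List::create(Rcpp::Named("conv") = conv, Rcpp::Named("dense") = dense);
}

// Per-sample forward caches (needed for backprop).
struct Cache {
  std::vector<fmat> P;        // patch matrices per conv layer
  std::vector<fmat> convact;  // post-ReLU conv activations (Hout*Wout x F)
  std::vector<umat> amax;     // pool argmax
  std::vector<frowvec> hid;   // dense activations (post-ReLU), incl. flatten
  float p = 0.0f;             // sigmoid output
};

fcube sample_cube(const float* X, int H, int W, int C, int n) {
  // X stored as (H, W, C, N) column-major
  fcube x(H, W, C);
  const size_t per = (size_t)H * W * C;
  std::memcpy(x.memptr(), X + per * n, per * sizeof(float));
  return x;
}

float forward(const Net& net, const fcube& x0, Cache* cache) {
  fcube x = x0;
  Cache local;
  Cache& cc = cache ? *cache : local;
  cc.P.resize(net.n_conv);
  cc.convact.resize(net.n_conv);
  cc.amax.resize(net.n_conv);
  for (int l = 0; l < net.n_conv; ++l) {
    const ConvDims& d = net.dims[l];
    fmat P;
    im2col(x, d, net.k, net.stride, P);
    fmat A = P * net.Wc[l];
    A.each_row() += net.bc[l];
    A.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
    fcube Ac(A.memptr(), d.Hout, d.Wout, d.F);
    fcube pooled;
    umat amax;
    maxpool(Ac, d, pooled, amax);
    if (cache) {
      cc.P[l] = std::move(P);
      cc.convact[l] = std::move(A);
      cc.amax[l] = std::move(amax);
    }
    x = std::move(pooled);
  }
  frowvec h(x.memptr(), net.flat);  // flatten: 1x1xF -> F
  cc.hid.clear();
  cc.hid.push_back(h);
  const int nd = net.Wd.size();
  for (int l = 0; l < nd; ++l) {
    frowvec z = cc.hid.back() * net.Wd[l] + net.bd[l];
    if (l < nd - 1) z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cc.hid.push_back(std::move(z));
  }
  const float zout = cc.hid.back()(0);
  const float p = 1.0f / (1.0f + std::exp(-zout));
  cc.p = p;
  return p;
}

struct Grads {
  std::vector<fmat> Wc;
  std::vector<frowvec> bc;
  std::vector<fmat> Wd;
  std::vector<frowvec> bd;
  void zero_like(const Net& net) {
    Wc.resize(net.n_conv); bc.resize(net.n_conv);
    Wd.resize(net.Wd.size()); bd.resize(net.Wd.size());
    for (int l = 0; l < net.n_conv; ++l) {
      Wc[l].zeros(net.Wc[l].n_rows, net.Wc[l].n_cols);
      bc[l].zeros(net.bc[l].n_elem);
    }
    for (size_t l = 0; l < net.Wd.size(); ++l) {
      Wd[l].zeros(net.Wd[l].n_rows, net.Wd[l].n_cols);
      bd[l].zeros(net.bd[l].n_elem);
    }
  }
};

// Backprop one sample; dz = dLoss/dlogit (already includes sample weight /
// batch normalisation).  Accumulates into g.
void backward(const Net& net, const Cache& cc, float dz, Grads& g) {
  const int nd = net.Wd.size();
  frowvec delta(1);
  delta(0) = dz;
  for (int l = nd - 1; l >= 0; --l) {
    g.Wd[l] += cc.hid[l].t() * delta;
    g.bd[l] += delta;
    if (l > 0) {
      frowvec prev = delta * net.Wd[l].t();
      // ReLU gate on the hidden activation
      const frowvec& act = cc.hid[l];
      for (uword i = 0; i < prev.n_elem; ++i)
        if (act(i) <= 0.0f) prev(i) = 0.0f;
      delta = std::move(prev);
    } else {
      delta = delta * net.Wd[l].t();  // gradient wrt flatten vector
    }
  }
  // delta now has net.flat elements = gradient wrt last pooled cube (1x1xF)
  fcube dpool(1, 1, net.flat);
  for (int f = 0; f < net.flat; ++f) dpool(0, 0, f) = delta(f);

  for (int l = net.n_conv - 1; l >= 0; --l) {
    const ConvDims& d = net.dims[l];
    // pool backward: scatter into conv activation grad
    fmat dA(d.Hout * d.Wout, d.F, fill::zeros);
    for (int f = 0; f < d.F; ++f) {
      const float* dp = dpool.slice_memptr(f);
      for (int idx = 0; idx < d.Hp * d.Wp; ++idx) {
        const float v = dp[idx];
        if (v != 0.0f) dA(cc.amax[l](idx, f), f) += v;
      }
    }
    // ReLU gate
    const fmat& act = cc.convact[l];
    for (uword jj = 0; jj < dA.n_cols; ++jj) {
      float* dcol = dA.colptr(jj);
      const float* acol = act.colptr(jj);
      for (uword ii = 0; ii < dA.n_rows; ++ii)
        if (acol[ii] <= 0.0f) dcol[ii] = 0.0f;
    }
    g.Wc[l] += cc.P[l].t() * dA;
    g.bc[l] += sum(dA, 0);
    if (l > 0) {
      fmat dP = dA * net.Wc[l].t();
      fcube dx;
      col2im(dP, d, net.k, net.stride, dx);
      dpool = std::move(dx);
    }
  }
}

double bce(double p, double y, double eps = 1e-7) {
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

// Mann-Whitney AUC of probabilities vs binary labels (ties counted 1/2).
double auc_probs(const std::vector<double>& p, const std::vector<int>& y) {
  double npos = 0, nneg = 0, u = 0;
  for (size_t i = 0; i < p.size(); ++i) {
    if (y[i] == 1) {
      ++npos;
      for (size_t j = 0; j < p.size(); ++j) {
        if (y[j] == 0) {
          if (p[i] > p[j]) u += 1.0;
          else if (p[i] == p[j]) u += 0.5;
        }
      }
    } else {
      ++nneg;
    }
  }
  if (npos == 0 || nneg == 0) return NA_REAL;
  return u / (npos * nneg);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::List weights, Rcpp::NumericVector X) {
  Rcpp::IntegerVector dm = X.attr("dim");
  if (dm.size() != 4) Rcpp::stop("X must be a 4-d array (H, W, C, N)");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  Net net = unpack(weights, H, W, C);
  std::vector<float> Xf(X.size());
  for (R_xlen_t i = 0; i < X.size(); ++i) Xf[i] = (float)X[i];
  Rcpp::NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    fcube x = sample_cube(Xf.data(), H, W, C, n);
    out[n] = forward(net, x, nullptr);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::List weights,
                         Rcpp::NumericVector X, Rcpp::IntegerVector y,
                         Rcpp::NumericVector Xval, Rcpp::IntegerVector yval,
                         Rcpp::IntegerMatrix shuffle,  // epochs x N, 1-based
                         int batch_size, double lr, double decay,
                         double momentum, double w0, double w1,
                         double l2_out, std::string metric) {
  Rcpp::IntegerVector dm = X.attr("dim");
  if (dm.size() != 4) Rcpp::stop("X must be a 4-d array (H, W, C, N)");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int epochs = shuffle.nrow();
  if (shuffle.ncol() != N) Rcpp::stop("shuffle schedule has %d columns, need %d",
                                      (int)shuffle.ncol(), N);
  Net net = unpack(weights, H, W, C);

  std::vector<float> Xf(X.size());
  for (R_xlen_t i = 0; i < X.size(); ++i) Xf[i] = (float)X[i];
  const int Nval = Xval.size() > 0 ? ((Rcpp::IntegerVector)Xval.attr("dim"))[3] : 0;
  std::vector<float> Xvf(Xval.size());
  for (R_xlen_t i = 0; i < Xval.size(); ++i) Xvf[i] = (float)Xval[i];

  Grads vel;  // momentum buffers
  vel.zero_like(net);
  Grads g;
  long iter = 0;

  Rcpp::NumericMatrix history(epochs, 4);  // loss, metric, val_loss, val_metric
  Rcpp::colnames(history) = Rcpp::CharacterVector::create(
      "loss", "metric", "val_loss", "val_metric");

  const int nbatch = (N + batch_size - 1) / batch_size;

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    std::vector<double> train_p(N);
    std::vector<int> train_y(N);
    for (int b = 0; b < nbatch; ++b) {
      const int lo = b * batch_size;
      const int hi = std::min(lo + batch_size, N);
      const int B = hi - lo;
      g.zero_like(net);
      double batch_loss = 0.0;
      for (int s = lo; s < hi; ++s) {
        const int n = shuffle(e, s) - 1;
        fcube x = sample_cube(Xf.data(), H, W, C, n);
        Cache cc;
        const float p = forward(net, x, &cc);
        const double yy = y[n];
        const double wgt = yy == 1.0 ? w1 : w0;
        batch_loss += wgt * bce(p, yy);
        train_p[s] = p;
        train_y[s] = y[n];
        const float dz = (float)(wgt * ((double)p - yy) / B);
        backward(net, cc, dz, g);
      }
      // L2 penalty on the output layer kernel only
      const int lo_l = net.Wd.size() - 1;
      double reg = l2_out * accu(square(net.Wd[lo_l]));
      batch_loss = batch_loss / B + reg;
      g.Wd[lo_l] += (float)(2.0 * l2_out) * net.Wd[lo_l];
      // SGD with momentum + time-based decay (lr_t = lr / (1 + decay * t))
      const double lr_t = lr / (1.0 + decay * (double)iter);
      for (int l = 0; l < net.n_conv; ++l) {
        vel.Wc[l] = (float)momentum * vel.Wc[l] - (float)lr_t * g.Wc[l];
        net.Wc[l] += vel.Wc[l];
        vel.bc[l] = (float)momentum * vel.bc[l] - (float)lr_t * g.bc[l];
        net.bc[l] += vel.bc[l];
      }
      for (size_t l = 0; l < net.Wd.size(); ++l) {
        vel.Wd[l] = (float)momentum * vel.Wd[l] - (float)lr_t * g.Wd[l];
        net.Wd[l] += vel.Wd[l];
        vel.bd[l] = (float)momentum * vel.bd[l] - (float)lr_t * g.bd[l];
        net.bd[l] += vel.bd[l];
      }
      ++iter;
      epoch_loss += batch_loss;
    }
    history(e, 0) = epoch_loss / nbatch;
    // monitored metric on the (pre-update, running) training predictions
    if (metric == "acc") {
      double ok = 0;
      for (int s = 0; s < N; ++s) ok += (train_p[s] > 0.5 ? 1 : 0) == train_y[s];
      history(e, 1) = ok / N;
    } else {
      history(e, 1) = auc_probs(train_p, train_y);
    }
    if (Nval > 0) {
      std::vector<double> vp(Nval);
      std::vector<int> vy(Nval);
      double vloss = 0.0;
      for (int n = 0; n < Nval; ++n) {
        fcube x = sample_cube(Xvf.data(), H, W, C, n);
        vp[n] = forward(net, x, nullptr);
        vy[n] = yval[n];
        vloss += bce(vp[n], (double)yval[n]);
      }
      const int lo_l = net.Wd.size() - 1;
      history(e, 2) = vloss / Nval + l2_out * accu(square(net.Wd[lo_l]));
      if (metric == "acc") {
        double ok = 0;
        for (int n = 0; n < Nval; ++n) ok += (vp[n] > 0.5 ? 1 : 0) == vy[n];
        history(e, 3) = ok / Nval;
      } else {
        history(e, 3) = auc_probs(vp, vy);
      }
    } else {
      history(e, 2) = NA_REAL;
      history(e, 3) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("weights") = pack(net),
                            Rcpp::Named("history") = history);
}
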