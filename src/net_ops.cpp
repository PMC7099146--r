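// Dual-pathway patch CNN: conv/LRN/maxpool primitives, full forward/backward,
// SGD with momentum + weight decay, and batched inference. Single precision;
// all loops deterministic and single-threaded (randomness lives in R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;
using arma::uword;

// ---------- low-level layer helpers (float) ----------

// valid convolution, stride 1. Column j of the output corresponds to output
// position (oi, oj) with j = oi + oh*oj; row index = ch*k*k + kj*k + ki.
static fmat im2col(const fcube& x, int k) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = h - k + 1, ow = w - k + 1;
  fmat col(c * k * k, oh * ow);
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = ch * k * k + kj * k + ki;
        for (int oj = 0; oj < ow; ++oj)
          for (int oi = 0; oi < oh; ++oi)
            col(r, oi + oh * oj) = x(oi + ki, oj + kj, ch);
      }
  return col;
}

static void col2im_add(fcube& dx, const fmat& dcol, int k) {
  const int h = dx.n_rows, w = dx.n_cols, c = dx.n_slices;
  const int oh = h - k + 1, ow = w - k + 1;
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = ch * k * k + kj * k + ki;
        for (int oj = 0; oj < ow; ++oj)
          for (int oi = 0; oi < oh; ++oi)
            dx(oi + ki, oj + kj, ch) += dcol(r, oi + oh * oj);
      }
}

static fcube conv_fwd(const fcube& x, const fmat& W, const fvec& b, int k,
                      fmat* col_out) {
  const int oh = x.n_rows - k + 1, ow = x.n_cols - k + 1;
  fmat col = im2col(x, k);
  fmat y = W * col;
  y.each_col() += b;
  if (col_out) *col_out = std::move(col);
  fcube out(oh, ow, W.n_rows);
  for (uword ch = 0; ch < W.n_rows; ++ch)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi)
        out(oi, oj, ch) = y(ch, oi + oh * oj);
  return out;
}

// gradient wrt weights/bias/input; dx has the shape of the conv input
static void conv_bwd(const fcube& dy, const fmat& col, const fmat& W, int k,
                     fmat& dW, fvec& db, fcube* dx) {
  const int oh = dy.n_rows, ow = dy.n_cols, co = dy.n_slices;
  fmat dyM(co, oh * ow);
  for (int ch = 0; ch < co; ++ch)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi)
        dyM(ch, oi + oh * oj) = dy(oi, oj, ch);
  dW += dyM * col.t();
  db += arma::sum(dyM, 1);
  if (dx) {
    fmat dcol = W.t() * dyM;
    dx->zeros();
    col2im_add(*dx, dcol, k);
  }
}

static fcube relu_fwd(const fcube& x) { return arma::clamp(x, 0.0f, arma::datum::inf); }

static fcube relu_bwd(const fcube& dy, const fcube& x_pre) {
  fcube dx = dy;
  for (uword i = 0; i < x_pre.n_elem; ++i) if (x_pre(i) <= 0.0f) dx(i) = 0.0f;
  return dx;
}

// LRN across channels: scale_i = k0 + (alpha/n) * sum_{|j-i|<=(n-1)/2} x_j^2,
// y_i = x_i * scale_i^{-beta}
struct LrnCache { fcube x, y, scale; };

static fcube lrn_fwd(const fcube& x, int n, float alpha, float beta, float k0,
                     LrnCache& cache) {
  const int C = x.n_slices, half = (n - 1) / 2;
  fcube scale(arma::size(x));
  for (int c = 0; c < C; ++c) {
    fmat s(x.n_rows, x.n_cols, arma::fill::value(k0));
    for (int j = std::max(0, c - half); j <= std::min(C - 1, c + half); ++j)
      s += (alpha / n) * arma::square(x.slice(j));
    scale.slice(c) = s;
  }
  fcube y = x % arma::pow(scale, -beta);
  cache.x = x; cache.y = y; cache.scale = scale;
  return y;
}

static fcube lrn_bwd(const fcube& dy, const LrnCache& cc, int n, float alpha,
                     float beta) {
  const int C = cc.x.n_slices, half = (n - 1) / 2;
  fcube ratio = dy % cc.y / cc.scale;  // dy_j * y_j / scale_j
  fcube dx(arma::size(dy));
  for (int c = 0; c < C; ++c) {
    fmat acc(dy.n_rows, dy.n_cols, arma::fill::zeros);
    for (int j = std::max(0, c - half); j <= std::min(C - 1, c + half); ++j)
      acc += ratio.slice(j);
    dx.slice(c) = dy.slice(c) % arma::pow(cc.scale.slice(c), -beta)
      - (2.0f * alpha * beta / n) * cc.x.slice(c) % acc;
  }
  return dx;
}

struct PoolCache { arma::ucube argmax; int in_h, in_w; };

static fcube pool_fwd(const fcube& x, int k, int s, PoolCache& cache) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  const int oh = (h - k) / s + 1, ow = (w - k) / s + 1;
  fcube y(oh, ow, C);
  cache.argmax.set_size(oh, ow, C);
  cache.in_h = h; cache.in_w = w;
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        float best = -arma::datum::inf; uword arg = 0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const int i = oi * s + ki, j = oj * s + kj;
            const float v = x(i, j, c);
            if (v > best) { best = v; arg = i + (uword)h * j; }
          }
        y(oi, oj, c) = best;
        cache.argmax(oi, oj, c) = arg;
      }
  return y;
}

static fcube pool_bwd(const fcube& dy, const PoolCache& cc) {
  fcube dx(cc.in_h, cc.in_w, dy.n_slices, arma::fill::zeros);
  for (uword c = 0; c < dy.n_slices; ++c)
    for (uword oj = 0; oj < dy.n_cols; ++oj)
      for (uword oi = 0; oi < dy.n_rows; ++oi) {
        const uword arg = cc.argmax(oi, oj, c);
        dx(arg % cc.in_h, arg / cc.in_h, c) += dy(oi, oj, c);
      }
  return dx;
}

// ---------- the dual-pathway network ----------

// weight indices: 0-2 small pathway convs, 3-5 large pathway convs,
// 6 cascade conv, 7 fcA (concat maps tap), 8 fcB (cascade tap),
// 9 fcJoin, 10 fcOut
#define NW 11

struct NetSpec {
  int p;                // input spatial size (both pathways)
  int c1, c2, c3;       // pathway channel progression
  int cascade;          // cascade conv channels
  int fc_tap, fc_join;  // fully connected widths
  int classes;
  int k, pool_k, pool_s;
  int lrn_n; float lrn_alpha, lrn_beta, lrn_k;
  float dropout;
};

struct PathCache {
  fmat col1, col2, col3;
  fcube a1, a2, a3;        // pre-activation conv outputs
  LrnCache l1, l2;
  PoolCache p1, p2;
  fcube r1, r2;            // post-relu (lrn inputs)
  fcube pool1_out;
};

struct Net {
  NetSpec s;
  std::vector<fmat> W, vW, gW;
  std::vector<fvec> b, vb, gb;
  Net(const NetSpec& spec) : s(spec), W(NW), vW(NW), gW(NW), b(NW), vb(NW), gb(NW) {}

  fcube path_fwd(const fmat& x, int base, PathCache& c) const {
    fcube x0(x.n_rows, x.n_cols, 1); x0.slice(0) = x;
    c.a1 = conv_fwd(x0, W[base], b[base], s.k, &c.col1);
    c.r1 = relu_fwd(c.a1);
    fcube l1 = lrn_fwd(c.r1, s.lrn_n, s.lrn_alpha, s.lrn_beta, s.lrn_k, c.l1);
    c.pool1_out = pool_fwd(l1, s.pool_k, s.pool_s, c.p1);
    c.a2 = conv_fwd(c.pool1_out, W[base + 1], b[base + 1], s.k, &c.col2);
    c.r2 = relu_fwd(c.a2);
    fcube l2 = lrn_fwd(c.r2, s.lrn_n, s.lrn_alpha, s.lrn_beta, s.lrn_k, c.l2);
    fcube p2 = pool_fwd(l2, s.pool_k, s.pool_s, c.p2);
    c.a3 = conv_fwd(p2, W[base + 2], b[base + 2], s.k, &c.col3);
    return relu_fwd(c.a3);
  }

  void path_bwd(const fcube& dout, int base, const PathCache& c) {
    fcube d3 = relu_bwd(dout, c.a3);
    // conv3's input is the pool2 output: its grid is the argmax grid of p2
    fcube dpool2(c.p2.argmax.n_rows, c.p2.argmax.n_cols, c.p2.argmax.n_slices);
    conv_bwd(d3, c.col3, W[base + 2], s.k, gW[base + 2], gb[base + 2], &dpool2);
    fcube dl2 = pool_bwd(dpool2, c.p2);
    fcube dr2 = lrn_bwd(dl2, c.l2, s.lrn_n, s.lrn_alpha, s.lrn_beta);
    fcube da2 = relu_bwd(dr2, c.a2);
    fcube dpool1(c.pool1_out.n_rows, c.pool1_out.n_cols, c.pool1_out.n_slices);
    conv_bwd(da2, c.col2, W[base + 1], s.k, gW[base + 1], gb[base + 1], &dpool1);
    fcube dl1 = pool_bwd(dpool1, c.p1);
    fcube dr1 = lrn_bwd(dl1, c.l1, s.lrn_n, s.lrn_alpha, s.lrn_beta);
    fcube da1 = relu_bwd(dr1, c.a1);
    conv_bwd(da1, c.col1, W[base], s.k, gW[base], gb[base], nullptr);
  }

  // forward one sample; returns class probabilities; when drop != nullptr the
  // fc_join activations are masked (inverted dropout) and caches are filled
  fvec forward(const fmat& xs, const fmat& xl, const float* drop,
               PathCache& cs, PathCache& cl, fcube& concat, fmat& casc_col,
               fvec& casc_pre, fvec& tapA_pre, fvec& tapB_pre, fvec& join_pre,
               fvec& h_drop) const {
    fcube os = path_fwd(xs, 0, cs);
    fcube ol = path_fwd(xl, 3, cl);
    concat.set_size(os.n_rows, os.n_cols, os.n_slices + ol.n_slices);
    concat.slices(0, os.n_slices - 1) = os;
    concat.slices(os.n_slices, concat.n_slices - 1) = ol;
    fcube cascade = conv_fwd(concat, W[6], b[6], s.k, &casc_col); // 1x1xCasc
    casc_pre = fvec(cascade.memptr(), cascade.n_elem);
    fvec cascade_r = arma::clamp(casc_pre, 0.0f, arma::datum::inf);
    fvec flat(concat.memptr(), concat.n_elem);
    tapA_pre = W[7] * flat + b[7];
    fvec tapA = arma::clamp(tapA_pre, 0.0f, arma::datum::inf);
    tapB_pre = W[8] * cascade_r + b[8];
    fvec tapB = arma::clamp(tapB_pre, 0.0f, arma::datum::inf);
    fvec j = arma::join_cols(tapA, tapB);
    join_pre = W[9] * j + b[9];
    fvec h = arma::clamp(join_pre, 0.0f, arma::datum::inf);
    if (drop) {
      const float keep = 1.0f - s.dropout;
      for (uword i = 0; i < h.n_elem; ++i) h(i) *= drop[i] / keep;
    }
    h_drop = h;
    fvec z = W[10] * h + b[10];
    const float m = z.max();
    fvec e = arma::exp(z - m);
    return e / arma::accu(e);
  }

  // backward one sample from dz (= sigma - onehot(y)); drop as in forward
  void backward(const fvec& dz, const float* drop, const PathCache& cs,
                const PathCache& cl, const fcube& concat, const fmat& casc_col,
                const fvec& casc_pre, const fvec& tapA_pre, const fvec& tapB_pre,
                const fvec& join_pre, const fvec& h_drop) {
    gW[10] += dz * h_drop.t();
    gb[10] += dz;
    fvec dh = W[10].t() * dz;
    if (drop) {
      const float keep = 1.0f - s.dropout;
      for (uword i = 0; i < dh.n_elem; ++i) dh(i) *= drop[i] / keep;
    }
    for (uword i = 0; i < dh.n_elem; ++i) if (join_pre(i) <= 0.0f) dh(i) = 0.0f;
    fvec tapA = arma::clamp(tapA_pre, 0.0f, arma::datum::inf);
    fvec tapB = arma::clamp(tapB_pre, 0.0f, arma::datum::inf);
    fvec j = arma::join_cols(tapA, tapB);
    gW[9] += dh * j.t();
    gb[9] += dh;
    fvec dj = W[9].t() * dh;
    fvec dA = dj.subvec(0, tapA.n_elem - 1);
    fvec dB = dj.subvec(tapA.n_elem, dj.n_elem - 1);
    for (uword i = 0; i < dA.n_elem; ++i) if (tapA_pre(i) <= 0.0f) dA(i) = 0.0f;
    for (uword i = 0; i < dB.n_elem; ++i) if (tapB_pre(i) <= 0.0f) dB(i) = 0.0f;
    fvec flat(const_cast<float*>(concat.memptr()), concat.n_elem, false);
    gW[7] += dA * flat.t();
    gb[7] += dA;
    fvec dflat = W[7].t() * dA;
    fvec cascade_r = arma::clamp(casc_pre, 0.0f, arma::datum::inf);
    gW[8] += dB * cascade_r.t();
    gb[8] += dB;
    fvec dcasc = W[8].t() * dB;
    for (uword i = 0; i < dcasc.n_elem; ++i) if (casc_pre(i) <= 0.0f) dcasc(i) = 0.0f;
    // cascade conv backward (output is 1x1xCasc)
    fcube dcasc_cube(1, 1, dcasc.n_elem);
    for (uword i = 0; i < dcasc.n_elem; ++i) dcasc_cube(0, 0, i) = dcasc(i);
    fcube dconcat(concat.n_rows, concat.n_cols, concat.n_slices);
    conv_bwd(dcasc_cube, casc_col, W[6], s.k, gW[6], gb[6], &dconcat);
    // add the fcA tap gradient
    fvec dconcat_flat(dconcat.memptr(), dconcat.n_elem, false);
    dconcat_flat += dflat;
    const uword c3 = concat.n_slices / 2;
    path_bwd(dconcat.slices(0, c3 - 1), 0, cs);
    path_bwd(dconcat.slices(c3, concat.n_slices - 1), 3, cl);
  }

  void zero_grad() {
    for (int i = 0; i < NW; ++i) {
      gW[i].zeros(W[i].n_rows, W[i].n_cols);
      gb[i].zeros(b[i].n_elem);
    }
  }

  void sgd_step(float lr, float momentum, float wd, int batch) {
    for (int i = 0; i < NW; ++i) {
      if (vW[i].n_elem == 0) { vW[i].zeros(W[i].n_rows, W[i].n_cols); vb[i].zeros(b[i].n_elem); }
      vW[i] = momentum * vW[i] - lr * (gW[i] / (float)batch + wd * W[i]);
      vb[i] = momentum * vb[i] - lr * (gb[i] / (float)batch + wd * b[i]);
      W[i] += vW[i];
      b[i] += vb[i];
    }
  }
};

static NetSpec spec_from_list(const List& sp) {
  NetSpec s;
  s.p = as<int>(sp["input_size"]);
  IntegerVector ch = sp["channels"];
  s.c1 = ch[0]; s.c2 = ch[1]; s.c3 = ch[2];
  s.cascade = as<int>(sp["cascade"]);
  s.fc_tap = as<int>(sp["fc_tap"]);
  s.fc_join = as<int>(sp["fc_join"]);
  s.classes = as<int>(sp["classes"]);
  s.k = as<int>(sp["kernel"]);
  s.pool_k = as<int>(sp["pool_size"]);
  s.pool_s = as<int>(sp["pool_stride"]);
  List lrn = sp["lrn"];
  s.lrn_n = as<int>(lrn["size"]);
  s.lrn_alpha = as<double>(lrn["alpha"]);
  s.lrn_beta = as<double>(lrn["beta"]);
  s.lrn_k = as<double>(lrn["k"]);
  s.dropout = as<double>(sp["dropout"]);
  return s;
}

static fcube cube_from_R(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  fcube x(d[0], d[1], d[2]);
  for (uword i = 0; i < x.n_elem; ++i) x(i) = (float)a[i];
  return x;
}

// [[Rcpp::export]]
SEXP cpp_net_create(List weights, List biases, List spec) {
  NetSpec s = spec_from_list(spec);
  Net* net = new Net(s);
  for (int i = 0; i < NW; ++i) {
    NumericMatrix w = weights[i];
    NumericVector bv = biases[i];
    net->W[i] = fmat(w.nrow(), w.ncol());
    for (int jj = 0; jj < w.ncol(); ++jj)
      for (int ii = 0; ii < w.nrow(); ++ii)
        net->W[i](ii, jj) = (float)w(ii, jj);
    net->b[i] = fvec(bv.size());
    for (int ii = 0; ii < bv.size(); ++ii) net->b[i](ii) = (float)bv[ii];
  }
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_net_weights(SEXP net_ptr) {
  XPtr<Net> net(net_ptr);
  List Ws(NW), Bs(NW);
  for (int i = 0; i < NW; ++i) {
    const fmat& w = net->W[i];
    NumericMatrix out(w.n_rows, w.n_cols);
    for (uword jj = 0; jj < w.n_cols; ++jj)
      for (uword ii = 0; ii < w.n_rows; ++ii) out(ii, jj) = w(ii, jj);
    Ws[i] = out;
    Bs[i] = NumericVector(net->b[i].begin(), net->b[i].end());
  }
  return List::create(_["weights"] = Ws, _["biases"] = Bs);
}

// train on one mini-batch; xs/xl are p x p x n arrays (already scaled to
// [0,1]-ish), y in {0,1,...}, drop is n x fc_join 0/1 matrix.
// Returns mean loss over the batch. update=false accumulates nothing into the
// parameters (used for gradient checking via cpp_net_gradients).
// [[Rcpp::export]]
double cpp_net_train_batch(SEXP net_ptr, NumericVector xs, NumericVector xl,
                           IntegerVector y, NumericMatrix drop, double lr,
                           double momentum, double weight_decay,
                           bool update = true) {
  XPtr<Net> net(net_ptr);
  fcube Xs = cube_from_R(xs), Xl = cube_from_R(xl);
  const int n = Xs.n_slices;
  net->zero_grad();
  double loss = 0.0;
  std::vector<float> dmask(net->s.fc_join);
  for (int i = 0; i < n; ++i) {
    for (int jj = 0; jj < net->s.fc_join; ++jj) dmask[jj] = (float)drop(i, jj);
    PathCache cs, cl; fcube concat; fmat ccol;
    fvec casc_pre, tA, tB, jpre, hd;
    fvec sig = net->forward(Xs.slice(i), Xl.slice(i), dmask.data(), cs, cl,
                            concat, ccol, casc_pre, tA, tB, jpre, hd);
    const int yi = y[i];
    loss += -std::log(std::max(sig(yi), 1e-12f));
    fvec dz = sig;
    dz(yi) -= 1.0f;
    net->backward(dz, dmask.data(), cs, cl, concat, ccol, casc_pre, tA, tB,
                  jpre, hd);
  }
  if (update) net->sgd_step(lr, momentum, weight_decay, n);
  if (!std::isfinite(loss)) stop("training diverged: non-finite batch loss");
  return loss / n;
}

// [[Rcpp::export]]
List cpp_net_gradients(SEXP net_ptr) {
  XPtr<Net> net(net_ptr);
  List Ws(NW), Bs(NW);
  for (int i = 0; i < NW; ++i) {
    const fmat& w = net->gW[i];
    NumericMatrix out(w.n_rows, w.n_cols);
    for (uword jj = 0; jj < w.n_cols; ++jj)
      for (uword ii = 0; ii < w.n_rows; ++ii) out(ii, jj) = w(ii, jj);
    Ws[i] = out;
    Bs[i] = NumericVector(net->gb[i].begin(), net->gb[i].end());
  }
  return List::create(_["weights"] = Ws, _["biases"] = Bs);
}

// inference (dropout off); returns n x classes probability matrix
// [[Rcpp::export]]
NumericMatrix cpp_net_predict(SEXP net_ptr, NumericVector xs, NumericVector xl) {
  XPtr<Net> net(net_ptr);
  fcube Xs = cube_from_R(xs), Xl = cube_from_R(xl);
  const int n = Xs.n_slices;
  NumericMatrix out(n, net->s.classes);
  for (int i = 0; i < n; ++i) {
    PathCache cs, cl; fcube concat; fmat ccol;
    fvec casc_pre, tA, tB, jpre, hd;
    fvec sig = net->forward(Xs.slice(i), Xl.slice(i), nullptr, cs, cl, concat,
                            ccol, casc_pre, tA, tB, jpre, hd);
    for (int c = 0; c < net->s.classes; ++c) out(i, c) = sig(c);
  }
  return out;
}

// ---------- generic double-precision layer primitives ----------
// Standalone valid conv / maxpool on h x w x c arrays; used for brute-force
// shape and semantics checks against the closed-form layer arithmetic.

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix W,
                                 NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], co = W.nrow();
  if (h < k || w < k) stop("input smaller than kernel");
  if (W.ncol() != c * k * k) stop("weight shape mismatch");
  const int oh = h - k + 1, ow = w - k + 1;
  NumericVector out(oh * ow * co);
  out.attr("dim") = IntegerVector::create(oh, ow, co);
  for (int o = 0; o < co; ++o)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        double acc = b[o];
        for (int ch = 0; ch < c; ++ch)
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              acc += W(o, ch * k * k + kj * k + ki) *
                     x[(oi + ki) + h * ((oj + kj) + (double)0 + w * ch)];
        out[oi + oh * (oj + (double)0 + ow * o)] = acc;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d(NumericVector x, int k, int s) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2];
  if (h < k || w < k) stop("input smaller than pooling window");
  const int oh = (h - k) / s + 1, ow = (w - k) / s + 1;
  NumericVector out(oh * ow * c);
  out.attr("dim") = IntegerVector::create(oh, ow, c);
  for (int ch = 0; ch < c; ++ch)
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        double best = R_NegInf;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            best = std::max(best,
                            x[(oi * s + ki) + h * ((oj * s + kj) + (double)0 + w * ch)]);
        out[oi + oh * (oj + (double)0 + ow * ch)] = best;
      }
  return out;
}

// ---------- patch extraction ----------

static inline int reflect_idx(int i, int n) {
  // np.pad 'reflect' convention (edge not duplicated); n >= 2
  const int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return i < n ? i : period - i;
}

// Extract co-centred small (p x p) and large (q x q, bilinearly resampled to
// p x p) patches around 1-based (row, col) centers with reflection padding.
// [[Rcpp::export]]
List cpp_extract_patch_pairs(NumericMatrix image, IntegerMatrix centers,
                             int p, int q) {
  const int h = image.nrow(), w = image.ncol(), n = centers.nrow();
  const int hp = (p - 1) / 2, hq = (q - 1) / 2;
  NumericVector small(p * p * (double)n), large(p * p * (double)n);
  small.attr("dim") = IntegerVector::create(p, p, n);
  large.attr("dim") = IntegerVector::create(p, p, n);
  std::vector<double> big(q * q);
  for (int s = 0; s < n; ++s) {
    const int cr = centers(s, 0) - 1, cc = centers(s, 1) - 1;
    double* sm = &small[(double)s * p * p];
    for (int j = 0; j < p; ++j) {
      const int jj = reflect_idx(cc - hp + j, w);
      for (int i = 0; i < p; ++i)
        sm[i + p * j] = image(reflect_idx(cr - hp + i, h), jj);
    }
    for (int j = 0; j < q; ++j) {
      const int jj = reflect_idx(cc - hq + j, w);
      for (int i = 0; i < q; ++i)
        big[i + q * j] = image(reflect_idx(cr - hq + i, h), jj);
    }
    double* lg = &large[(double)s * p * p];
    const double scale = (double)(q - 1) / (double)(p - 1);
    for (int j = 0; j < p; ++j) {
      const double v = j * scale;
      const int j0 = std::min((int)v, q - 2);
      const double fj = v - j0;
      for (int i = 0; i < p; ++i) {
        const double u = i * scale;
        const int i0 = std::min((int)u, q - 2);
        const double fi = u - i0;
        lg[i + p * j] =
          (1 - fi) * (1 - fj) * big[i0 + q * j0] +
          fi * (1 - fj) * big[i0 + 1 + q * j0] +
          (1 - fi) * fj * big[i0 + q * (j0 + 1)] +
          fi * fj * big[i0 + 1 + q * (j0 + 1)];
      }
    }
  }
  return List::create(_["small"] = small, _["large"] = large);
}

// Multi-source BFS fill (8-connectivity): propagate each seed's value to the
// nearest pixels; used to fill unvisited mask pixels from the stride grid.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_fill(int nrow, int ncol, IntegerVector seed_row,
                           IntegerVector seed_col, NumericVector seed_val) {
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> q;
  q.reserve((size_t)nrow * ncol);
  for (int i = 0; i < seed_row.size(); ++i) {
    const int r = seed_row[i] - 1, c = seed_col[i] - 1;
    out(r, c) = seed_val[i];
    q.push_back(r + nrow * c);
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  size_t head = 0;
  while (head < q.size()) {
    const int idx = q[head++];
    const int r = idx % nrow, c = idx / nrow;
    const double v = out(r, c);
    for (int d = 0; d < 8; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      if (ISNA(out(rr, cc))) { out(rr, cc) = v; q.push_back(rr + nrow * cc); }
    }
  }
  return out;
}
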