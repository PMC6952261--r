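// Compact CPU engine for small spatiotemporal (3D) convolutional networks.
//
// Activations are stored per sample as contiguous (C, T, H, W) blocks with W
// fastest. 3D convolution is evaluated as im2col followed by a single sgemm
// per sample; the im2col buffer is rebuilt during the backward pass instead
// of being cached, trading ~30% extra time for a much smaller peak footprint.
// All arithmetic is single precision; batch-norm statistics accumulate in
// double.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

struct Dims {
  int C, T, H, W;
  long size() const { return (long)C * T * H * W; }
};

struct ConvGeom {
  int kt, kh, kw, st, sh, sw, pt, ph, pw, cin, cout;
  int To, Ho, Wo;  // output spatial dims, set by out_dims()
  long woff, boff;
  void out_dims(const Dims &in) {
    To = (in.T + 2 * pt - kt) / st + 1;
    Ho = (in.H + 2 * ph - kh) / sh + 1;
    Wo = (in.W + 2 * pw - kw) / sw + 1;
  }
};

// col is P x K with P = To*Ho*Wo (w fastest), K = cin*kt*kh*kw.
// Column r = ((c*kt + it)*kh + ih)*kw + iw is contiguous over positions.
static void im2col(const float *in, const Dims &d, const ConvGeom &g, fmat &col) {
  const long P = (long)g.To * g.Ho * g.Wo;
  for (int c = 0; c < g.cin; ++c) {
    const float *ch = in + (long)c * d.T * d.H * d.W;
    for (int it = 0; it < g.kt; ++it)
      for (int ih = 0; ih < g.kh; ++ih)
        for (int iw = 0; iw < g.kw; ++iw) {
          long r = (((long)c * g.kt + it) * g.kh + ih) * g.kw + iw;
          float *dst = col.colptr(r);
          long p = 0;
          for (int t = 0; t < g.To; ++t) {
            int tin = t * g.st + it - g.pt;
            if (tin < 0 || tin >= d.T) {
              std::fill(dst + p, dst + p + (long)g.Ho * g.Wo, 0.0f);
              p += (long)g.Ho * g.Wo;
              continue;
            }
            for (int h = 0; h < g.Ho; ++h) {
              int hin = h * g.sh + ih - g.ph;
              if (hin < 0 || hin >= d.H) {
                std::fill(dst + p, dst + p + g.Wo, 0.0f);
                p += g.Wo;
                continue;
              }
              const float *row = ch + ((long)tin * d.H + hin) * d.W;
              if (g.sw == 1) {
                int w0 = iw - g.pw;           // input w for output w = 0
                int a = std::max(0, -w0);     // first valid output w
                int b = std::min(g.Wo, d.W - w0);  // one past last valid
                if (a > 0) std::fill(dst + p, dst + p + std::min(a, g.Wo), 0.0f);
                if (b > a) std::copy(row + w0 + a, row + w0 + b, dst + p + a);
                if (b < g.Wo) std::fill(dst + p + std::max(b, 0), dst + p + g.Wo, 0.0f);
                p += g.Wo;
              } else {
                for (int w = 0; w < g.Wo; ++w, ++p) {
                  int win = w * g.sw + iw - g.pw;
                  dst[p] = (win < 0 || win >= d.W) ? 0.0f : row[win];
                }
              }
            }
          }
          (void)P;
        }
  }
}

static void col2im_add(const fmat &dcol, float *din, const Dims &d, const ConvGeom &g) {
  for (int c = 0; c < g.cin; ++c) {
    float *ch = din + (long)c * d.T * d.H * d.W;
    for (int it = 0; it < g.kt; ++it)
      for (int ih = 0; ih < g.kh; ++ih)
        for (int iw = 0; iw < g.kw; ++iw) {
          long r = (((long)c * g.kt + it) * g.kh + ih) * g.kw + iw;
          const float *src = dcol.colptr(r);
          long p = 0;
          for (int t = 0; t < g.To; ++t) {
            int tin = t * g.st + it - g.pt;
            if (tin < 0 || tin >= d.T) { p += (long)g.Ho * g.Wo; continue; }
            for (int h = 0; h < g.Ho; ++h) {
              int hin = h * g.sh + ih - g.ph;
              if (hin < 0 || hin >= d.H) { p += g.Wo; continue; }
              float *row = ch + ((long)tin * d.H + hin) * d.W;
              for (int w = 0; w < g.Wo; ++w, ++p) {
                int win = w * g.sw + iw - g.pw;
                if (win >= 0 && win < d.W) row[win] += src[p];
              }
            }
          }
        }
  }
}

static ConvGeom conv_geom(const List &op, const Dims &in) {
  ConvGeom g;
  g.kt = op["kt"]; g.kh = op["kh"]; g.kw = op["kw"];
  g.st = op["st"]; g.sh = op["sh"]; g.sw = op["sw"];
  g.pt = op["pt"]; g.ph = op["ph"]; g.pw = op["pw"];
  g.cin = op["cin"]; g.cout = op["cout"];
  g.woff = (long)(double)op["woff"]; g.boff = (long)(double)op["boff"];
  g.out_dims(in);
  return g;
}

// weights are stored as a (K x cout) matrix, column-major, at woff.
static void conv_forward(const fvec &pv, const ConvGeom &g, const float *in,
                         const Dims &din, float *out, int B, fmat &col) {
  const long K = (long)g.cin * g.kt * g.kh * g.kw;
  const long P = (long)g.To * g.Ho * g.Wo;
  const fmat Wm(const_cast<float *>(pv.memptr()) + g.woff, K, g.cout, false, true);
  col.set_size(P, K);
  fmat O(P, g.cout);
  for (int b = 0; b < B; ++b) {
    im2col(in + (long)b * din.size(), din, g, col);
    O = col * Wm;
    float *ob = out + (long)b * g.cout * P;
    for (int c = 0; c < g.cout; ++c) {
      const float bias = pv[g.boff + c];
      const float *src = O.colptr(c);
      float *dst = ob + (long)c * P;
      for (long p = 0; p < P; ++p) dst[p] = src[p] + bias;
    }
  }
}

static void conv_backward(const fvec &pv, fvec &gv, const ConvGeom &g,
                          const float *in, const Dims &din, const float *dout,
                          float *din_grad, int B, fmat &col) {
  const long K = (long)g.cin * g.kt * g.kh * g.kw;
  const long P = (long)g.To * g.Ho * g.Wo;
  const fmat Wm(const_cast<float *>(pv.memptr()) + g.woff, K, g.cout, false, true);
  fmat dWm(gv.memptr() + g.woff, K, g.cout, false, true);
  col.set_size(P, K);
  fmat dO(P, g.cout), dcol(P, K);
  for (int b = 0; b < B; ++b) {
    const float *db = dout + (long)b * g.cout * P;
    for (int c = 0; c < g.cout; ++c) {
      std::copy(db + (long)c * P, db + (long)(c + 1) * P, dO.colptr(c));
      double s = 0;
      for (long p = 0; p < P; ++p) s += db[(long)c * P + p];
      gv[g.boff + c] += (float)s;
    }
    im2col(in + (long)b * din.size(), din, g, col);
    dWm += col.t() * dO;
    if (din_grad) {
      dcol = dO * Wm.t();
      col2im_add(dcol, din_grad + (long)b * din.size(), din, g);
    }
  }
}

struct BnRef {
  int c; long goff, boff, rmoff, rvoff;
};

static BnRef bn_ref(const List &op) {
  BnRef r;
  r.c = op["c"];
  r.goff = (long)(double)op["goff"]; r.boff = (long)(double)op["betaoff"];
  r.rmoff = (long)(double)op["rmoff"]; r.rvoff = (long)(double)op["rvoff"];
  return r;
}

static void bn_forward(const fvec &pv, fvec &bv, const BnRef &r, const float *in,
                       float *out, int B, long S, bool training,
                       fvec &mean_save, fvec &invstd_save) {
  mean_save.set_size(r.c);
  invstd_save.set_size(r.c);
  for (int c = 0; c < r.c; ++c) {
    float mean, invstd;
    if (training) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const float *p = in + ((long)b * r.c + c) * S;
        for (long i = 0; i < S; ++i) { s += p[i]; s2 += (double)p[i] * p[i]; }
      }
      const double n = (double)B * S;
      const double m = s / n;
      const double var = std::max(0.0, s2 / n - m * m);
      mean = (float)m;
      invstd = (float)(1.0 / std::sqrt(var + BN_EPS));
      bv[r.rmoff + c] = (1.0f - BN_MOMENTUM) * bv[r.rmoff + c] + BN_MOMENTUM * mean;
      bv[r.rvoff + c] = (1.0f - BN_MOMENTUM) * bv[r.rvoff + c] + BN_MOMENTUM * (float)var;
    } else {
      mean = bv[r.rmoff + c];
      invstd = 1.0f / std::sqrt(bv[r.rvoff + c] + BN_EPS);
    }
    mean_save[c] = mean;
    invstd_save[c] = invstd;
    const float gamma = pv[r.goff + c], beta = pv[r.boff + c];
    const float a = gamma * invstd, bconst = beta - gamma * invstd * mean;
    for (int b = 0; b < B; ++b) {
      const float *p = in + ((long)b * r.c + c) * S;
      float *q = out + ((long)b * r.c + c) * S;
      for (long i = 0; i < S; ++i) q[i] = a * p[i] + bconst;
    }
  }
}

static void bn_backward(const fvec &pv, fvec &gv, const BnRef &r, const float *in,
                        const float *dout, float *din_grad, int B, long S,
                        const fvec &mean_save, const fvec &invstd_save) {
  const double n = (double)B * S;
  for (int c = 0; c < r.c; ++c) {
    const float mean = mean_save[c], invstd = invstd_save[c];
    double s1 = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const float *x = in + ((long)b * r.c + c) * S;
      const float *dy = dout + ((long)b * r.c + c) * S;
      for (long i = 0; i < S; ++i) {
        s1 += dy[i];
        s2 += (double)dy[i] * ((x[i] - mean) * invstd);
      }
    }
    gv[r.goff + c] += (float)s2;
    gv[r.boff + c] += (float)s1;
    const float gamma = pv[r.goff + c];
    const float k1 = (float)(s1 / n), k2 = (float)(s2 / n);
    for (int b = 0; b < B; ++b) {
      const float *x = in + ((long)b * r.c + c) * S;
      const float *dy = dout + ((long)b * r.c + c) * S;
      float *dx = din_grad + ((long)b * r.c + c) * S;
      for (long i = 0; i < S; ++i) {
        const float xh = (x[i] - mean) * invstd;
        dx[i] += gamma * invstd * (dy[i] - k1 - xh * k2);
      }
    }
  }
}

// [[Rcpp::export]]
List nn_run(NumericVector params, NumericVector buffers, List ops, RawVector x,
            IntegerVector xdim, bool training, IntegerVector labels,
            NumericVector class_w, bool want_grad, int dropout_seed) {
  const int B = xdim[0];
  Dims d0;
  d0.C = xdim[1]; d0.T = xdim[2]; d0.H = xdim[3]; d0.W = xdim[4];
  const int nops = ops.size();

  fvec pv(params.size());
  for (long i = 0; i < (long)params.size(); ++i) pv[i] = (float)params[i];
  fvec bv(buffers.size());
  for (long i = 0; i < (long)buffers.size(); ++i) bv[i] = (float)buffers[i];

  // input: R array (T, H, W, C) per chunk, uint8 -> (C, T, H, W) float in [0,1]
  fvec xin((long)B * d0.size());
  {
    const Rbyte *src = x.begin();
    for (int b = 0; b < B; ++b) {
      float *blk = xin.memptr() + (long)b * d0.size();
      long s = (long)b * d0.size();
      for (int c = 0; c < d0.C; ++c)
        for (int w = 0; w < d0.W; ++w)
          for (int h = 0; h < d0.H; ++h)
            for (int t = 0; t < d0.T; ++t)
              blk[(((long)c * d0.T + t) * d0.H + h) * d0.W + w] = src[s++] / 255.0f;
    }
  }

  std::vector<fvec> outs(nops);
  std::vector<Dims> odims(nops);
  std::vector<fvec> sv_a(nops), sv_b(nops), sv_c(nops);  // bn stats, dropout masks, proj outs
  std::vector<arma::uvec> sv_idx(nops);                  // pool argmax
  std::vector<int> pushstack;
  fmat colbuf;
  std::mt19937 rng((unsigned)dropout_seed);

  Dims cur = d0;
  for (int i = 0; i < nops; ++i) {
    List op = ops[i];
    std::string type = as<std::string>(op["type"]);
    const float *in = (i == 0) ? xin.memptr() : outs[i - 1].memptr();
    const Dims din = (i == 0) ? d0 : odims[i - 1];

    if (type == "conv") {
      ConvGeom g = conv_geom(op, din);
      cur.C = g.cout; cur.T = g.To; cur.H = g.Ho; cur.W = g.Wo;
      outs[i].set_size((long)B * cur.size());
      conv_forward(pv, g, in, din, outs[i].memptr(), B, colbuf);
    } else if (type == "bn") {
      BnRef r = bn_ref(op);
      cur = din;
      outs[i].set_size((long)B * cur.size());
      bn_forward(pv, bv, r, in, outs[i].memptr(), B, (long)din.T * din.H * din.W,
                 training, sv_a[i], sv_b[i]);
    } else if (type == "relu") {
      cur = din;
      outs[i].set_size((long)B * cur.size());
      const long n = (long)B * cur.size();
      for (long j = 0; j < n; ++j) outs[i][j] = in[j] > 0.0f ? in[j] : 0.0f;
    } else if (type == "pool") {
      int kt = op["kt"], kh = op["kh"], kw = op["kw"];
      int st = op["st"], sh = op["sh"], sw = op["sw"];
      cur.C = din.C;
      cur.T = (din.T - kt) / st + 1;
      cur.H = (din.H - kh) / sh + 1;
      cur.W = (din.W - kw) / sw + 1;
      outs[i].set_size((long)B * cur.size());
      sv_idx[i].set_size((long)B * cur.size());
      long o = 0;
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < din.C; ++c) {
          const float *blk = in + ((long)b * din.C + c) * din.T * din.H * din.W;
          const long base = ((long)b * din.C + c) * din.T * din.H * din.W;
          for (int t = 0; t < cur.T; ++t)
            for (int h = 0; h < cur.H; ++h)
              for (int w = 0; w < cur.W; ++w, ++o) {
                float best = -std::numeric_limits<float>::infinity();
                long besti = 0;
                for (int it = 0; it < kt; ++it)
                  for (int ih = 0; ih < kh; ++ih)
                    for (int iw = 0; iw < kw; ++iw) {
                      long idx = ((long)(t * st + it) * din.H + (h * sh + ih)) * din.W +
                                 (w * sw + iw);
                      if (blk[idx] > best) { best = blk[idx]; besti = idx; }
                    }
                outs[i][o] = best;
                sv_idx[i][o] = base + besti;
              }
        }
    } else if (type == "push") {
      cur = din;
      outs[i] = (i == 0) ? xin : outs[i - 1];
      pushstack.push_back(i);
    } else if (type == "addid") {
      int src = pushstack.back(); pushstack.pop_back();
      cur = din;
      outs[i] = outs[i - 1] + outs[src];
      op["srcop"] = src;  // remembered for backward
      ops[i] = op;
    } else if (type == "addproj") {
      int src = pushstack.back(); pushstack.pop_back();
      ConvGeom g = conv_geom(op, odims[src]);
      cur = din;  // main branch dims == projection output dims
      sv_c[i].set_size((long)B * cur.size());
      conv_forward(pv, g, outs[src].memptr(), odims[src], sv_c[i].memptr(), B, colbuf);
      BnRef r = bn_ref(op);
      fvec bnout((long)B * cur.size());
      bn_forward(pv, bv, r, sv_c[i].memptr(), bnout.memptr(), B,
                 (long)cur.T * cur.H * cur.W, training, sv_a[i], sv_b[i]);
      outs[i] = outs[i - 1] + bnout;
      op["srcop"] = src;
      ops[i] = op;
    } else if (type == "gap") {
      cur.C = din.C; cur.T = 1; cur.H = 1; cur.W = 1;
      outs[i].set_size((long)B * din.C);
      const long S = (long)din.T * din.H * din.W;
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < din.C; ++c) {
          const float *p = in + ((long)b * din.C + c) * S;
          double s = 0;
          for (long j = 0; j < S; ++j) s += p[j];
          outs[i][(long)b * din.C + c] = (float)(s / S);
        }
    } else if (type == "flatten") {
      cur.C = (int)din.size(); cur.T = 1; cur.H = 1; cur.W = 1;
      outs[i] = (i == 0) ? xin : outs[i - 1];
    } else if (type == "fc") {
      int cin = op["cin"], cout = op["cout"];
      long woff = (long)(double)op["woff"], boff = (long)(double)op["boff"];
      const fmat Wm(const_cast<float *>(pv.memptr()) + woff, cin, cout, false, true);
      const fmat X(const_cast<float *>(in), cin, B, false, true);
      fmat O = Wm.t() * X;  // cout x B
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < cout; ++c) O(c, b) += pv[boff + c];
      cur.C = cout; cur.T = 1; cur.H = 1; cur.W = 1;
      outs[i] = fvec(O.memptr(), (long)B * cout);
    } else if (type == "dropout") {
      double rate = op["rate"];
      cur = din;
      const long n = (long)B * cur.size();
      outs[i].set_size(n);
      if (training && rate > 0) {
        sv_b[i].set_size(n);
        std::uniform_real_distribution<float> U(0.0f, 1.0f);
        const float scale = 1.0f / (1.0f - (float)rate);
        for (long j = 0; j < n; ++j) {
          sv_b[i][j] = (U(rng) < rate) ? 0.0f : scale;
          outs[i][j] = in[j] * sv_b[i][j];
        }
      } else {
        std::copy(in, in + n, outs[i].memptr());
      }
    } else {
      stop("unknown op type: " + type);
    }
    odims[i] = cur;
  }

  // scores: final activation must be (K, 1, 1, 1)
  const int K = odims[nops - 1].C;
  NumericMatrix scores(B, K);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) scores(b, k) = outs[nops - 1][(long)b * K + k];

  double loss = NA_REAL;
  fmat dsc;  // gradient w.r.t. scores, K x B (fmat for layout convenience)
  if (labels.size() == B) {
    loss = 0.0;
    dsc.zeros(K, B);
    for (int b = 0; b < B; ++b) {
      double mx = scores(b, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, scores(b, k));
      double Z = 0;
      for (int k = 0; k < K; ++k) Z += std::exp(scores(b, k) - mx);
      const int y = labels[b] - 1;
      const double w = class_w[y];
      double qy = std::exp(scores(b, y) - mx) / Z;
      loss += -w * std::log(std::max(qy, 1e-12));
      if (want_grad) {
        for (int k = 0; k < K; ++k) {
          double q = std::exp(scores(b, k) - mx) / Z;
          dsc(k, b) = (float)(w * (q - (k == y ? 1.0 : 0.0)) / B);
        }
      }
    }
  }

  NumericVector grad;
  if (want_grad) {
    fvec gv(params.size(), arma::fill::zeros);
    std::vector<fvec> gshort;        // gradients waiting for their push op
    std::vector<int> gshort_src;     // producing op index recorded at add*
    fvec g(dsc.memptr(), (long)B * K);  // gradient w.r.t. current op output
    for (int i = nops - 1; i >= 0; --i) {
      List op = ops[i];
      std::string type = as<std::string>(op["type"]);
      const float *in = (i == 0) ? xin.memptr() : outs[i - 1].memptr();
      const Dims din = (i == 0) ? d0 : odims[i - 1];
      const bool need_din = (i > 0);
      fvec gin;
      if (need_din) gin.zeros((long)B * din.size());

      if (type == "conv") {
        ConvGeom g2 = conv_geom(op, din);
        conv_backward(pv, gv, g2, in, din, g.memptr(),
                      need_din ? gin.memptr() : nullptr, B, colbuf);
      } else if (type == "bn") {
        BnRef r = bn_ref(op);
        bn_backward(pv, gv, r, in, g.memptr(), gin.memptr(), B,
                    (long)din.T * din.H * din.W, sv_a[i], sv_b[i]);
      } else if (type == "relu") {
        for (long j = 0; j < (long)g.n_elem; ++j)
          gin[j] = outs[i][j] > 0.0f ? g[j] : 0.0f;
      } else if (type == "pool") {
        for (long o = 0; o < (long)g.n_elem; ++o) gin[sv_idx[i][o]] += g[o];
      } else if (type == "push") {
        gin = g;
        // add the shortcut gradient recorded by the matching add op
        for (size_t k = 0; k < gshort_src.size(); ++k)
          if (gshort_src[k] == i) {
            gin += gshort[k];
            gshort.erase(gshort.begin() + k);
            gshort_src.erase(gshort_src.begin() + k);
            break;
          }
      } else if (type == "addid") {
        gin = g;
        gshort.push_back(g);
        gshort_src.push_back((int)(as<int>(op["srcop"])));
      } else if (type == "addproj") {
        gin = g;
        const int src = as<int>(op["srcop"]);
        const Dims dsrc = odims[src];
        const Dims dout = odims[i];
        fvec gproj;
        gproj.zeros((long)B * dout.size());
        BnRef r = bn_ref(op);
        bn_backward(pv, gv, r, sv_c[i].memptr(), g.memptr(), gproj.memptr(), B,
                    (long)dout.T * dout.H * dout.W, sv_a[i], sv_b[i]);
        ConvGeom g2 = conv_geom(op, dsrc);
        fvec gsrc;
        gsrc.zeros((long)B * dsrc.size());
        conv_backward(pv, gv, g2, outs[src].memptr(), dsrc, gproj.memptr(),
                      gsrc.memptr(), B, colbuf);
        gshort.push_back(gsrc);
        gshort_src.push_back(src);
      } else if (type == "gap") {
        const long S = (long)din.T * din.H * din.W;
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < din.C; ++c) {
            const float gval = g[(long)b * din.C + c] / S;
            float *dst = gin.memptr() + ((long)b * din.C + c) * S;
            for (long j = 0; j < S; ++j) dst[j] += gval;
          }
      } else if (type == "flatten") {
        if (need_din) gin = g;
      } else if (type == "fc") {
        int cin = op["cin"], cout = op["cout"];
        long woff = (long)(double)op["woff"], boff = (long)(double)op["boff"];
        const fmat Wm(const_cast<float *>(pv.memptr()) + woff, cin, cout, false, true);
        fmat dWm(gv.memptr() + woff, cin, cout, false, true);
        const fmat X(const_cast<float *>(in), cin, B, false, true);
        const fmat dO(const_cast<float *>(g.memptr()), cout, B, false, true);
        dWm += X * dO.t();
        for (int c = 0; c < cout; ++c) {
          double s = 0;
          for (int b = 0; b < B; ++b) s += dO(c, b);
          gv[boff + c] += (float)s;
        }
        if (need_din) {
          fmat dX(gin.memptr(), cin, B, false, true);
          dX += Wm * dO;
        }
      } else if (type == "dropout") {
        if (training && sv_b[i].n_elem == g.n_elem) {
          for (long j = 0; j < (long)g.n_elem; ++j) gin[j] = g[j] * sv_b[i][j];
        } else {
          gin = g;
        }
      }

      outs[i].reset();
      if (i > 0) g = std::move(gin);
    }
    grad = NumericVector(gv.n_elem);
    for (long i = 0; i < (long)gv.n_elem; ++i) grad[i] = gv[i];
  }

  NumericVector newbuf(bv.n_elem);
  for (long i = 0; i < (long)bv.n_elem; ++i) newbuf[i] = bv[i];

  return List::create(_["scores"] = scores, _["loss"] = loss, _["grad"] = grad,
                      _["buffers"] = newbuf);
}
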