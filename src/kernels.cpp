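// Numeric kernels for the segmentation network and metrics.
// Layout convention: feature tensors are R arrays [H, W, C, N] (column-major),
// conv weights [k, k, Cin, Cout], transposed-conv weights [2, 2, Cin, Cout].

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double *x, int H, int W, int Cin, int k) {
  // rows: H*W output positions; cols: k*k*Cin (ki fastest, then kj, then ci)
  const int p = (k - 1) / 2;
  arma::mat M(H * W, k * k * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ci * k * k + kj * k + ki;
        double *Mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - p;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - p;
            if (sh < 0 || sh >= H) continue;
            Mcol[h + H * w] = xc[sh + H * sw];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector Wt, IntegerVector wdim,
                            NumericVector b) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  NumericVector out((size_t)H * W * Cout * N);
  arma::mat Wm(Wt.begin(), k * k * Cin, Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k);
    arma::mat O(out.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
    O = M * Wm;
    for (int c = 0; c < Cout; ++c) O.col(c) += b[c];
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector Wt, IntegerVector wdim,
                   NumericVector dout) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  const int p = (k - 1) / 2;
  NumericVector dx((size_t)H * W * Cin * N);
  NumericVector dW((size_t)k * k * Cin * Cout);
  NumericVector db(Cout);
  arma::mat Wm(Wt.begin(), k * k * Cin, Cout, false);
  arma::mat dWm(dW.begin(), k * k * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k);
    arma::mat D(dout.begin() + (size_t)H * W * Cout * n, H * W, Cout, false);
    dWm += M.t() * D;
    dbv += arma::sum(D, 0).t();
    arma::mat dM = D * Wm.t();
    // col2im scatter-add
    double *dxn = dx.begin() + (size_t)H * W * Cin * n;
    for (int ci = 0; ci < Cin; ++ci) {
      double *dxc = dxn + (size_t)H * W * ci;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int col = ci * k * k + kj * k + ki;
          const double *Mcol = dM.colptr(col);
          for (int w = 0; w < W; ++w) {
            const int sw = w + kj - p;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + ki - p;
              if (sh < 0 || sh >= H) continue;
              dxc[sh + H * sw] += Mcol[h + H * w];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dW.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          size_t best = base + (2 * h) + (size_t)H * (2 * w);
          double bv = xp[best];
          const int hs[2] = {2 * h, 2 * h + 1}, ws[2] = {2 * w, 2 * w + 1};
          for (int a = 0; a < 2; ++a)
            for (int bq = 0; bq < 2; ++bq) {
              size_t ii = base + hs[a] + (size_t)H * ws[bq];
              if (xp[ii] > bv) { bv = xp[ii]; best = ii; }
            }
          out[obase + h + (size_t)Ho * w] = bv;
          idx[obase + h + (size_t)Ho * w] = (int)best;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dout,
                             IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i]] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Transposed conv 2x2 stride 2: out[2i+di, 2j+dj, co] = sum_ci x[i,j,ci] * W[di,dj,ci,co]
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, IntegerVector xdim,
                            NumericVector Wt, NumericVector b) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  IntegerVector wd = Wt.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                H * W, Cin, false);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        // weight slice [Cin, Cout] at (di, dj)
        arma::mat Ws(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Ws(ci, co) = Wt[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))];
        arma::mat O = X * Ws;  // HW x Cout
        double *op = out.begin() + (size_t)Ho * Wo * Cout * n;
        for (int co = 0; co < Cout; ++co) {
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              op[(2 * h + di) + (size_t)Ho * ((2 * w + dj) + (size_t)Wo * co)] =
                O(h + H * w, co) + b[co];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, IntegerVector xdim,
                   NumericVector Wt, NumericVector dout) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  IntegerVector wd = Wt.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * Cin * N);
  NumericVector dW((size_t)4 * Cin * Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                H * W, Cin, false);
    arma::mat dX(dx.begin() + (size_t)H * W * Cin * n, H * W, Cin, false, true);
    const double *dp = dout.begin() + (size_t)Ho * Wo * Cout * n;
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        arma::mat D(H * W, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              D(h + H * w, co) =
                dp[(2 * h + di) + (size_t)Ho * ((2 * w + dj) + (size_t)Wo * co)];
        arma::mat Ws(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Ws(ci, co) = Wt[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))];
        dX += D * Ws.t();
        arma::mat dWs = X.t() * D;  // Cin x Cout
        for (int co = 0; co < Cout; ++co) {
          for (int ci = 0; ci < Cin; ++ci)
            dW[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))] += dWs(ci, co);
          db[co] += arma::accu(D.col(co));
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dW.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 3D connected components, 6-connectivity, on a logical/integer mask.
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int H = dims[0], W = dims[1], Z = dims.size() > 2 ? dims[2] : 1;
  IntegerVector lab((size_t)H * W * Z);
  std::vector<int> sizes;
  int cur = 0;
  std::queue<size_t> q;
  const size_t n = (size_t)H * W * Z;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    int sz = 0;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      size_t v = q.front(); q.pop(); ++sz;
      const int z = (int)(v / ((size_t)H * W));
      const int r = (int)(v % ((size_t)H * W));
      const int w = r / H, h = r % H;
      const int dh[6] = {-1, 1, 0, 0, 0, 0};
      const int dw[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int hh = h + dh[d], ww = w + dw[d], zz = z + dz[d];
        if (hh < 0 || hh >= H || ww < 0 || ww >= W || zz < 0 || zz >= Z) continue;
        const size_t u = (size_t)hh + (size_t)H * (ww + (size_t)W * zz);
        if (mask[u] && lab[u] == 0) { lab[u] = cur; q.push(u); }
      }
    }
    sizes.push_back(sz);
  }
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// For each row of A (coordinates in mm), distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        const double t = A(i, k) - B(j, k);
        s += t * t;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-channel mean and population variance over (H, W, N) of [H, W, C, N].
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t hw = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = gamma * (x - mean) * invstd + beta, per channel of [H, W, C, N].
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, IntegerVector dims,
                           NumericVector mean, NumericVector invstd,
                           NumericVector gamma, NumericVector beta) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t hw = (size_t)H * W;
  NumericVector out(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + hw * (c + (size_t)C * n);
      double *o = out.begin() + hw * (c + (size_t)C * n);
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - a * mean[c];
      for (size_t i = 0; i < hw; ++i) o[i] = a * p[i] + b;
    }
  out.attr("dim") = dims;
  return out;
}

// Backward of batch norm. In training mode uses the batch-statistics
// formula; in eval mode dx = dout * gamma * invstd.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector dims, NumericVector mean,
               NumericVector invstd, NumericVector gamma,
               NumericVector dout, bool training) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t hw = (size_t)H * W;
  const double cnt = (double)hw * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sd = 0, sdx = 0;  // sum(dout), sum(dout * xhat)
    for (int n = 0; n < N; ++n) {
      const double *px = x.begin() + hw * (c + (size_t)C * n);
      const double *pd = dout.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (px[i] - mean[c]) * invstd[c];
        sd += pd[i];
        sdx += pd[i] * xh;
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double *px = x.begin() + hw * (c + (size_t)C * n);
      const double *pd = dout.begin() + hw * (c + (size_t)C * n);
      double *pdx = dx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        if (training) {
          const double xh = (px[i] - mean[c]) * invstd[c];
          pdx[i] = g * invstd[c] * (pd[i] - sd / cnt - xh * sdx / cnt);
        } else {
          pdx[i] = g * invstd[c] * pd[i];
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Per-pixel softmax over the class axis of [H, W, C, N].
// [[Rcpp::export]]
NumericVector cpp_softmax(NumericVector logits, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t hw = (size_t)H * W;
  NumericVector out(logits.size());
  std::vector<double> buf(C);
  for (int n = 0; n < N; ++n) {
    const double *base = logits.begin() + hw * (size_t)C * n;
    double *obase = out.begin() + hw * (size_t)C * n;
    for (size_t i = 0; i < hw; ++i) {
      double m = base[i];
      for (int c = 1; c < C; ++c)
        m = std::max(m, base[i + hw * c]);
      double s = 0;
      for (int c = 0; c < C; ++c) {
        buf[c] = std::exp(base[i + hw * c] - m);
        s += buf[c];
      }
      for (int c = 0; c < C; ++c) obase[i + hw * c] = buf[c] / s;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ReLU forward in place-ish (returns new vector) plus mask-free backward
// support: backward recomputes from the forward output (out > 0).
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[i] = out[i] > 0 ? dout[i] : 0.0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}
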