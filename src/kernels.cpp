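// Hot inner loops of the autodiff engine: row gather/scatter and
// group-wise softmax over edge lists. These dominate training time for
// the attention and message-passing layers.

#include <Rcpp.h>
using namespace Rcpp;

// out[k, ] = X[idx[k] - 1, ]
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(const NumericMatrix& X,
                              const IntegerVector& idx) {
  const int n = idx.size(), p = X.ncol(), nr = X.nrow();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double* oj = &out(0, j);
    for (int k = 0; k < n; ++k) oj[k] = xj[idx[k] - 1];
  }
  (void)nr;
  return out;
}

// out[idx[k] - 1, ] += G[k, ], out has `n` rows
// [[Rcpp::export]]
NumericMatrix cpp_scatter_rows(const NumericMatrix& G,
                               const IntegerVector& idx, const int n) {
  const int m = idx.size(), p = G.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* gj = &G(0, j);
    double* oj = &out(0, j);
    for (int k = 0; k < m; ++k) oj[idx[k] - 1] += gj[k];
  }
  return out;
}

// Column-wise softmax within row groups. group is 1-based with values in
// 1..ngroups; rows sharing a group form one softmax support per column.
// [[Rcpp::export]]
NumericMatrix cpp_group_softmax(const NumericMatrix& S,
                                const IntegerVector& group,
                                const int ngroups) {
  const int m = S.nrow(), p = S.ncol();
  NumericMatrix out(m, p);
  std::vector<double> gmax(ngroups), gsum(ngroups);
  for (int j = 0; j < p; ++j) {
    const double* sj = &S(0, j);
    double* oj = &out(0, j);
    std::fill(gmax.begin(), gmax.end(), R_NegInf);
    for (int k = 0; k < m; ++k) {
      const int g = group[k] - 1;
      if (sj[k] > gmax[g]) gmax[g] = sj[k];
    }
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      const double e = std::exp(sj[k] - gmax[group[k] - 1]);
      oj[k] = e;
      gsum[group[k] - 1] += e;
    }
    for (int k = 0; k < m; ++k) {
      const double d = gsum[group[k] - 1];
      oj[k] = d > 0 ? oj[k] / d : 0.0;
    }
  }
  return out;
}

// Backward of group softmax: dS = A * (G - sum_group(A * G)).
// [[Rcpp::export]]
NumericMatrix cpp_group_softmax_bwd(const NumericMatrix& A,
                                    const NumericMatrix& G,
                                    const IntegerVector& group,
                                    const int ngroups) {
  const int m = A.nrow(), p = A.ncol();
  NumericMatrix out(m, p);
  std::vector<double> dot(ngroups);
  for (int j = 0; j < p; ++j) {
    const double* aj = &A(0, j);
    const double* gj = &G(0, j);
    double* oj = &out(0, j);
    std::fill(dot.begin(), dot.end(), 0.0);
    for (int k = 0; k < m; ++k) dot[group[k] - 1] += aj[k] * gj[k];
    for (int k = 0; k < m; ++k)
      oj[k] = aj[k] * (gj[k] - dot[group[k] - 1]);
  }
  return out;
}

// out[k, ] = X[k, colidx[k-th target col]] pattern: column gather,
// colidx is 1-based into X's columns, out has colidx.size() columns.
// [[Rcpp::export]]
NumericMatrix cpp_gather_cols(const NumericMatrix& X,
                              const IntegerVector& colidx) {
  const int n = X.nrow(), p = colidx.size();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, colidx[j] - 1);
    std::copy(xj, xj + n, &out(0, j));
  }
  return out;
}

// Backward of column gather: out[, colidx[j]] += G[, j], out has `p` cols.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_cols(const NumericMatrix& G,
                               const IntegerVector& colidx, const int p) {
  const int n = G.nrow(), m = colidx.size();
  NumericMatrix out(n, p);
  for (int j = 0; j < m; ++j) {
    const double* gj = &G(0, j);
    double* oj = &out(0, colidx[j] - 1);
    for (int k = 0; k < n; ++k) oj[k] += gj[k];
  }
  return out;
}

// Elementwise product of two gathered row sets followed by a head-block
// column sum: scores[k, h] = sum_{c in head h} Q[qidx[k]-1, c] *
// K[kidx[k]-1, c] * scale. Fuses the two big gathers and the product for
// attention scores.
// [[Rcpp::export]]
NumericMatrix cpp_edge_scores(const NumericMatrix& Q, const NumericMatrix& K,
                              const IntegerVector& qidx,
                              const IntegerVector& kidx,
                              const int nheads, const double scale) {
  const int m = qidx.size(), d = Q.ncol();
  const int hd = d / nheads;
  NumericMatrix out(m, nheads);
  for (int k = 0; k < m; ++k) {
    const int qr = qidx[k] - 1, kr = kidx[k] - 1;
    for (int h = 0; h < nheads; ++h) {
      double s = 0.0;
      for (int c = h * hd; c < (h + 1) * hd; ++c)
        s += Q(qr, c) * K(kr, c);
      out(k, h) = s * scale;
    }
  }
  return out;
}

// Gradient of edge scores wrt Q and K: dQ[qidx[k]-1, c] += G[k, h] *
// K[kidx[k]-1, c] * scale (and symmetrically for K).
// [[Rcpp::export]]
List cpp_edge_scores_bwd(const NumericMatrix& G, const NumericMatrix& Q,
                         const NumericMatrix& K, const IntegerVector& qidx,
                         const IntegerVector& kidx, const double scale) {
  const int m = qidx.size(), d = Q.ncol(), H = G.ncol();
  const int hd = d / H;
  NumericMatrix dQ(Q.nrow(), d), dK(K.nrow(), d);
  for (int k = 0; k < m; ++k) {
    const int qr = qidx[k] - 1, kr = kidx[k] - 1;
    for (int h = 0; h < H; ++h) {
      const double g = G(k, h) * scale;
      if (g == 0.0) continue;
      for (int c = h * hd; c < (h + 1) * hd; ++c) {
        dQ(qr, c) += g * K(kr, c);
        dK(kr, c) += g * Q(qr, c);
      }
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK);
}

// Attention-weighted aggregation: out[src[k]-1, c] += A[k, h(c)] *
// V[dst[k]-1, c], where h(c) = c / (d / H).
// [[Rcpp::export]]
NumericMatrix cpp_attn_out(const NumericMatrix& A, const NumericMatrix& V,
                           const IntegerVector& dst,
                           const IntegerVector& src, const int ntok) {
  const int m = src.size(), d = V.ncol(), H = A.ncol();
  const int hd = d / H;
  NumericMatrix out(ntok, d);
  for (int k = 0; k < m; ++k) {
    const int sr = src[k] - 1, dr = dst[k] - 1;
    for (int h = 0; h < H; ++h) {
      const double a = A(k, h);
      if (a == 0.0) continue;
      for (int c = h * hd; c < (h + 1) * hd; ++c)
        out(sr, c) += a * V(dr, c);
    }
  }
  return out;
}

// Gradients of cpp_attn_out wrt A and V.
// [[Rcpp::export]]
List cpp_attn_out_bwd(const NumericMatrix& G, const NumericMatrix& A,
                      const NumericMatrix& V, const IntegerVector& dst,
                      const IntegerVector& src, const int nv) {
  const int m = src.size(), d = V.ncol(), H = A.ncol();
  const int hd = d / H;
  NumericMatrix dA(m, H), dV(nv, d);
  for (int k = 0; k < m; ++k) {
    const int sr = src[k] - 1, dr = dst[k] - 1;
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      const double a = A(k, h);
      for (int c = h * hd; c < (h + 1) * hd; ++c) {
        const double g = G(sr, c);
        acc += g * V(dr, c);
        dV(dr, c) += a * g;
      }
      dA(k, h) = acc;
    }
  }
  return List::create(Named("dA") = dA, Named("dV") = dV);
}

// B-spline basis (or first-derivative basis) on an extended knot vector:
// direct port of the Cox-de Boor recursion used by bspline_basis(). `ext`
// contains the grid extended by `order` knots each side; x must already
// be clamped to [lo, hi]; the last base interval is right-closed.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_basis(const NumericVector& x,
                                const NumericVector& ext, const int order,
                                const int n_grid, const bool derivative) {
  const int npt = x.size();
  const int nb = n_grid - 1 + order;     // basis count at full degree
  const double hi = ext[order + n_grid - 1];
  const int last_base = order + n_grid - 2;  // 0-based last base interval
  const int deg_target = derivative ? order - 1 : order;
  const int m0 = ext.size() - 1;
  std::vector<double> B(m0), Bn(m0);
  NumericMatrix out(npt, nb);
  for (int k = 0; k < npt; ++k) {
    const double xv = x[k];
    int m = m0;
    if (xv == hi) {
      std::fill(B.begin(), B.end(), 0.0);
      B[last_base] = 1.0;
    } else {
      for (int i = 0; i < m; ++i)
        B[i] = (xv >= ext[i] && xv < ext[i + 1]) ? 1.0 : 0.0;
    }
    for (int d = 1; d <= deg_target; ++d) {
      m -= 1;
      for (int i = 0; i < m; ++i) {
        const double d1 = ext[i + d] - ext[i];
        const double d2 = ext[i + d + 1] - ext[i + 1];
        double v = 0.0;
        if (d1 > 0) v += (xv - ext[i]) / d1 * B[i];
        if (d2 > 0) v += (ext[i + d + 1] - xv) / d2 * B[i + 1];
        Bn[i] = v;
      }
      std::copy(Bn.begin(), Bn.begin() + m, B.begin());
    }
    if (!derivative) {
      for (int i = 0; i < nb; ++i) out(k, i) = B[i];
    } else {
      for (int i = 0; i < nb; ++i) {
        const double d1 = ext[i + order] - ext[i];
        const double d2 = ext[i + order + 1] - ext[i + 1];
        double v = 0.0;
        if (d1 > 0) v += B[i] / d1;
        if (d2 > 0) v -= B[i + 1] / d2;
        out(k, i) = order * v;
      }
    }
  }
  return out;
}
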