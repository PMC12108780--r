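// Batched 1-D convolution primitives shared by every network layer that
// slides a kernel along the time axis, plus a CRC-32 used by the NPZ
// container writer.  Convolutions use "same" zero padding and odd kernels so
// padding is symmetric.  Two code paths: Cin == 1 (the temporal convolution,
// where per-slice GEMMs would be overhead-bound) runs as scaled adds on one
// big (T x slices) matrix; the general path runs one small GEMM per kernel
// tap per slice.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: (T, Cin, n) cube, W: (K, Cin, Cout) cube, b: length-Cout vector.
// Returns Y: (T, Cout, n).
// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::cube& W,
                      const arma::vec& b) {
  const uword T = X.n_rows, Cin = X.n_cols, n = X.n_slices;
  const uword K = W.n_rows, Cout = W.n_slices;
  if (W.n_cols != Cin) Rcpp::stop("conv1d: weight Cin mismatch");
  if (K % 2 == 0) Rcpp::stop("conv1d: kernel length must be odd");
  const int pad = (int(K) - 1) / 2;
  cube Y(T, Cout, n);

  if (Cin == 1) {
    // processed in column blocks so each block stays cache-resident across
    // all kernel taps
    const mat Xm(const_cast<double*>(X.memptr()), T, n, false, true);
    const uword bs = 32;
    mat Yf(T, bs);
    for (uword c0 = 0; c0 < n; c0 += bs) {
      const uword c1 = std::min(c0 + bs, n) - 1;
      for (uword co = 0; co < Cout; ++co) {
        mat Yb = Yf.cols(0, c1 - c0);
        Yb.fill(b(co));
        for (uword k = 0; k < K; ++k) {
          int o = int(k) - pad;
          uword r0 = (o < 0) ? uword(-o) : 0;
          uword r1 = (o > 0) ? T - 1 - uword(o) : T - 1;
          if (r1 >= T || r0 > r1) continue;
          Yb.rows(r0, r1) += W(k, 0, co) * Xm.submat(r0 + o, c0, r1 + o, c1);
        }
        for (uword i = c0; i <= c1; ++i) Y.slice(i).col(co) = Yb.col(i - c0);
      }
    }
    return Y;
  }

  std::vector<mat> Wk(K);  // tap weight matrices (Cin, Cout)
  for (uword k = 0; k < K; ++k) {
    mat wk(Cin, Cout);
    for (uword co = 0; co < Cout; ++co) wk.col(co) = W.slice(co).row(k).t();
    Wk[k] = wk;
  }
  for (uword i = 0; i < n; ++i) {
    mat& Yi = Y.slice(i);
    Yi = repmat(b.t(), T, 1);
    const mat& Xi = X.slice(i);
    for (uword k = 0; k < K; ++k) {
      int o = int(k) - pad;
      uword r0 = (o < 0) ? uword(-o) : 0;
      uword r1 = (o > 0) ? T - 1 - uword(o) : T - 1;
      if (r1 >= T || r0 > r1) continue;
      Yi.rows(r0, r1) += Xi.rows(r0 + o, r1 + o) * Wk[k];
    }
  }
  return Y;
}

// Gradients of conv1d_fwd.  dY: (T, Cout, n).  Returns list(dX, dW, db).
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::cube& W,
                      const arma::cube& dY) {
  const uword T = X.n_rows, Cin = X.n_cols, n = X.n_slices;
  const uword K = W.n_rows, Cout = W.n_slices;
  const int pad = (int(K) - 1) / 2;
  cube dX(T, Cin, n, fill::zeros);
  cube dW(K, Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);

  if (Cin == 1) {
    const mat Xm(const_cast<double*>(X.memptr()), T, n, false, true);
    mat dXm(dX.memptr(), T, n, false, true);
    const uword bs = 32;
    mat dYf(T, bs);
    for (uword c0 = 0; c0 < n; c0 += bs) {
      const uword c1 = std::min(c0 + bs, n) - 1;
      for (uword co = 0; co < Cout; ++co) {
        mat dYb = dYf.cols(0, c1 - c0);
        for (uword i = c0; i <= c1; ++i) dYb.col(i - c0) = dY.slice(i).col(co);
        db(co) += accu(dYb);
        for (uword k = 0; k < K; ++k) {
          int o = int(k) - pad;
          uword r0 = (o < 0) ? uword(-o) : 0;
          uword r1 = (o > 0) ? T - 1 - uword(o) : T - 1;
          if (r1 >= T || r0 > r1) continue;
          dW(k, 0, co) += accu(Xm.submat(r0 + o, c0, r1 + o, c1) %
                               dYb.rows(r0, r1));
          dXm.submat(r0 + o, c0, r1 + o, c1) += W(k, 0, co) * dYb.rows(r0, r1);
        }
      }
    }
    return Rcpp::List::create(Rcpp::Named("dX") = dX,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }

  std::vector<mat> Wk(K), dWk(K, mat(Cin, Cout, fill::zeros));
  for (uword k = 0; k < K; ++k) {
    mat wk(Cin, Cout);
    for (uword co = 0; co < Cout; ++co) wk.col(co) = W.slice(co).row(k).t();
    Wk[k] = wk;
  }
  for (uword i = 0; i < n; ++i) {
    const mat& Xi = X.slice(i);
    const mat& dYi = dY.slice(i);
    db += sum(dYi, 0).t();
    mat& dXi = dX.slice(i);
    for (uword k = 0; k < K; ++k) {
      int o = int(k) - pad;
      uword r0 = (o < 0) ? uword(-o) : 0;
      uword r1 = (o > 0) ? T - 1 - uword(o) : T - 1;
      if (r1 >= T || r0 > r1) continue;
      dWk[k] += Xi.rows(r0 + o, r1 + o).t() * dYi.rows(r0, r1);
      dXi.rows(r0 + o, r1 + o) += dYi.rows(r0, r1) * Wk[k].t();
    }
  }
  for (uword k = 0; k < K; ++k)
    for (uword co = 0; co < Cout; ++co)
      dW.slice(co).row(k) = dWk[k].col(co).t();
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
double crc32_raw(const Rcpp::RawVector& data, double init) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = ~uint32_t(init);
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return double(~crc);
}

// ---- batch normalization over channels (dim 2 of a (T, C, S) cube) --------
// The cube is addressed as a (T*C, S) matrix whose row-block c*T..(c+1)*T-1
// holds channel c, so per-channel statistics are contiguous row-block
// reductions (no per-slice copies).

// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::cube& X, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, double momentum, double eps,
                      bool train) {
  const uword T = X.n_rows, C = X.n_cols, S = X.n_slices;
  const double m = double(T) * double(S);
  const mat M(const_cast<double*>(X.memptr()), T * C, S, false, true);
  vec mu(C), v(C);
  if (train) {
    for (uword c = 0; c < C; ++c) {
      auto sub = M.rows(c * T, (c + 1) * T - 1);
      mu(c) = accu(sub) / m;
      v(c) = accu(square(sub - mu(c))) / m;
    }
  } else {
    mu = run_mean; v = run_var;
  }
  vec istd = 1.0 / sqrt(v + eps);
  cube Xhat(T, C, S), out(T, C, S);
  mat Xh(Xhat.memptr(), T * C, S, false, true);
  mat O(out.memptr(), T * C, S, false, true);
  for (uword c = 0; c < C; ++c) {
    const uword r0 = c * T, r1 = (c + 1) * T - 1;
    Xh.rows(r0, r1) = (M.rows(r0, r1) - mu(c)) * istd(c);
    O.rows(r0, r1) = Xh.rows(r0, r1) * gamma(c) + beta(c);
  }
  vec nm = run_mean, nv = run_var;
  if (train) {
    nm = (1 - momentum) * run_mean + momentum * mu;
    nv = (1 - momentum) * run_var + momentum * v * m / std::max(1.0, m - 1);
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = out, Rcpp::Named("Xhat") = Xhat,
    Rcpp::Named("istd") = istd, Rcpp::Named("run_mean") = nm,
    Rcpp::Named("run_var") = nv);
}

// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::cube& dY, const arma::cube& Xhat,
                      const arma::vec& istd, const arma::vec& gamma,
                      bool train) {
  const uword T = dY.n_rows, C = dY.n_cols, S = dY.n_slices;
  const double m = double(T) * double(S);
  const mat dYm(const_cast<double*>(dY.memptr()), T * C, S, false, true);
  const mat Xh(const_cast<double*>(Xhat.memptr()), T * C, S, false, true);
  vec dgamma(C), dbeta(C);
  cube dX(T, C, S);
  mat dXm(dX.memptr(), T * C, S, false, true);
  for (uword c = 0; c < C; ++c) {
    const uword r0 = c * T, r1 = (c + 1) * T - 1;
    dgamma(c) = accu(dYm.rows(r0, r1) % Xh.rows(r0, r1));
    dbeta(c) = accu(dYm.rows(r0, r1));
    const double gi = gamma(c) * istd(c);
    if (!train) {
      dXm.rows(r0, r1) = dYm.rows(r0, r1) * gi;
    } else {
      dXm.rows(r0, r1) =
        (dYm.rows(r0, r1) - dbeta(c) / m -
         Xh.rows(r0, r1) * (dgamma(c) / m)) * gi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// ---- depthwise spatial convolution (depth multiplier 1) -------------------

// X viewed as (T*F1, C, n); W: (C, F1).  Y: (T, F1, n) with
// Y(t, f, i) = sum_c X(f*T + t, c, i) * W(c, f).
// [[Rcpp::export]]
arma::cube dw_fwd_cpp(const arma::cube& X, const arma::mat& W, int T_) {
  const uword T = uword(T_), C = X.n_cols, n = X.n_slices;
  const uword F1 = X.n_rows / T;
  cube Y(T, F1, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    mat M = X.slice(i) * W;          // (T*F1, F1)
    for (uword f = 0; f < F1; ++f)
      Y.slice(i).col(f) = M.submat(f * T, f, (f + 1) * T - 1, f);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List dw_bwd_cpp(const arma::cube& X, const arma::mat& W,
                      const arma::cube& dY, int T_) {
  const uword T = uword(T_), C = X.n_cols, n = X.n_slices;
  const uword F1 = X.n_rows / T;
  cube dX(T * F1, C, n);
  mat dW(C, F1, fill::zeros);
  mat B(T * F1, F1);
  for (uword i = 0; i < n; ++i) {
    B.zeros();
    for (uword f = 0; f < F1; ++f)
      B.submat(f * T, f, (f + 1) * T - 1, f) = dY.slice(i).col(f);
    dX.slice(i) = B * W.t();
    dW += X.slice(i).t() * B;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW);
}
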