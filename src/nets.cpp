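// Mini-batch Adam training loops for the three neural regressors
// (multilayer perceptron, 1-D convolutional network, LSTM).  Inputs are
// standardized features (n x 4) and targets (n x 2); all randomness
// (initialisation, shuffling, dropout) is drawn from a std::mt19937
// seeded explicitly, so training is bit-reproducible for a given seed.
// The CNN and LSTM cores use flat buffers and explicit loops: the
// networks are tiny (tens of weights) and mini-batches small, so
// per-call linear-algebra overhead would otherwise dominate.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  std::vector<double> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(size_t n) { m.assign(n, 0.0); v.assign(n, 0.0); }
  void step(double* w, const double* g, size_t n, double lr, int t) {
    const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    for (size_t k = 0; k < n; ++k) {
      m[k] = b1 * m[k] + (1 - b1) * g[k];
      v[k] = b2 * v[k] + (1 - b2) * g[k] * g[k];
      w[k] -= lr * (m[k] / c1) / (std::sqrt(v[k] / c2) + eps);
    }
  }
};

void glorot_fill(std::vector<double>& w, int fan_in, int fan_out,
                 std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> un(-lim, lim);
  for (auto& x : w) x = un(rng);
}

std::vector<std::vector<int>> make_batches(int n, int batch,
                                           std::mt19937& rng) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  std::vector<std::vector<int>> out;
  for (int s = 0; s < n; s += batch)
    out.emplace_back(idx.begin() + s,
                     idx.begin() + std::min(s + batch, n));
  return out;
}

inline double sigm1(double z) { return 1.0 / (1.0 + std::exp(-z)); }

} // namespace

// ---------------------------------------------------------------- MLP ----

// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat& X, const arma::mat& Y,
                         const arma::ivec& widths, int epochs, int batch,
                         double lr, double dropout, std::string loss,
                         int seed) {
  bool mae = (loss == "mae");
  std::mt19937 rng(static_cast<unsigned>(seed));
  int L = widths.n_elem + 1;
  std::vector<int> sizes;
  sizes.push_back(X.n_cols);
  for (uword i = 0; i < widths.n_elem; ++i) sizes.push_back(widths[i]);
  sizes.push_back(Y.n_cols);

  // weights row-major [in][out], biases [out]
  std::vector<std::vector<double>> W(L), b(L);
  std::vector<Adam> aW(L), ab(L);
  for (int l = 0; l < L; ++l) {
    W[l].assign(sizes[l] * sizes[l + 1], 0.0);
    glorot_fill(W[l], sizes[l], sizes[l + 1], rng);
    b[l].assign(sizes[l + 1], 0.0);
    aW[l].init(W[l].size());
    ab[l].init(b[l].size());
  }
  std::uniform_real_distribution<double> un01(0.0, 1.0);
  int maxw = 0;
  for (int s : sizes) maxw = std::max(maxw, s);
  int B0 = std::min<int>(batch, X.n_rows);

  // activation/grad buffers per layer, layout [sample][unit]
  std::vector<std::vector<double>> act(L + 1), pre(L), dact(L + 1);
  std::vector<std::vector<double>> mask(L);
  for (int l = 0; l <= L; ++l) {
    act[l].assign(B0 * maxw, 0.0);
    dact[l].assign(B0 * maxw, 0.0);
    if (l < L) { pre[l].assign(B0 * maxw, 0.0); mask[l].assign(B0 * maxw, 1.0); }
  }
  std::vector<double> gW(maxw * maxw), gb(maxw);

  vec history(epochs, fill::zeros);
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    auto batches = make_batches(X.n_rows, batch, rng);
    double acc = 0; int nb = 0;
    for (auto& idx : batches) {
      int B = idx.size();
      for (int i = 0; i < B; ++i)
        for (int j = 0; j < sizes[0]; ++j)
          act[0][i * sizes[0] + j] = X(idx[i], j);
      // forward
      for (int l = 0; l < L; ++l) {
        int ni = sizes[l], no = sizes[l + 1];
        for (int i = 0; i < B; ++i) {
          const double* a = &act[l][i * ni];
          double* z = &pre[l][i * no];
          for (int o = 0; o < no; ++o) z[o] = b[l][o];
          for (int j = 0; j < ni; ++j) {
            const double aj = a[j];
            const double* wrow = &W[l][j * no];
            for (int o = 0; o < no; ++o) z[o] += aj * wrow[o];
          }
          double* out = &act[l + 1][i * no];
          if (l < L - 1) {
            for (int o = 0; o < no; ++o) {
              double r = z[o] > 0 ? z[o] : 0.0;
              double mk = 1.0;
              if (l == 0 && dropout > 0)
                mk = (un01(rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
              mask[l][i * no + o] = mk;
              out[o] = r * mk;
            }
          } else {
            for (int o = 0; o < no; ++o) out[o] = z[o];
          }
        }
      }
      // loss and output gradient
      int no = sizes[L];
      double lval = 0;
      for (int i = 0; i < B; ++i)
        for (int o = 0; o < no; ++o) {
          double d = act[L][i * no + o] - Y(idx[i], o);
          lval += mae ? std::fabs(d) : d * d;
          dact[L][i * no + o] =
              (mae ? (d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0)) : 2.0 * d) /
              (B * no);
        }
      lval /= B * no;
      if (!std::isfinite(lval)) Rcpp::stop("NaN loss during MLP training");
      acc += lval; nb++;
      // backward
      ++t;
      for (int l = L - 1; l >= 0; --l) {
        int ni = sizes[l], nu = sizes[l + 1];
        // dZ in dact[l+1] (apply relu/dropout mask for hidden layers)
        if (l < L - 1)
          for (int i = 0; i < B; ++i)
            for (int o = 0; o < nu; ++o) {
              double dz = dact[l + 1][i * nu + o] * mask[l][i * nu + o];
              dact[l + 1][i * nu + o] = pre[l][i * nu + o] > 0 ? dz : 0.0;
            }
        std::fill(gW.begin(), gW.begin() + ni * nu, 0.0);
        std::fill(gb.begin(), gb.begin() + nu, 0.0);
        for (int i = 0; i < B; ++i) {
          const double* a = &act[l][i * ni];
          const double* dz = &dact[l + 1][i * nu];
          double* da = &dact[l][i * ni];
          for (int j = 0; j < ni; ++j) da[j] = 0.0;
          for (int o = 0; o < nu; ++o) gb[o] += dz[o];
          for (int j = 0; j < ni; ++j) {
            const double aj = a[j];
            const double* wrow = &W[l][j * nu];
            double accd = 0;
            double* grow = &gW[j * nu];
            for (int o = 0; o < nu; ++o) {
              grow[o] += aj * dz[o];
              accd += wrow[o] * dz[o];
            }
            da[j] = accd;
          }
        }
        aW[l].step(W[l].data(), gW.data(), ni * nu, lr, t);
        ab[l].step(b[l].data(), gb.data(), nu, lr, t);
      }
    }
    history[ep] = acc / std::max(nb, 1);
  }
  // export weights as R matrices (in x out) and bias vectors
  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    int ni = sizes[l], no = sizes[l + 1];
    mat Wm(ni, no);
    for (int j = 0; j < ni; ++j)
      for (int o = 0; o < no; ++o) Wm(j, o) = W[l][j * no + o];
    Wout[l] = Wm;
    bout[l] = Rcpp::NumericVector(b[l].begin(), b[l].end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("history") = history);
}

// ---------------------------------------------------------------- CNN ----
// 1-D convolutions over the length-4 feature sequence (one input
// channel): conv(k=3, pad 1, ReLU) -> maxpool(2) -> conv -> conv ->
// flatten -> dense linear head.  Buffers layout: [sample][pos][channel].

namespace {

// conv with kernel 3, pad 1; W layout [dk][cin][cout], b [cout]
void conv3_fwd(const double* in, int B, int L, int Cin, const double* W,
               const double* b, int Cout, double* out) {
  for (int i = 0; i < B; ++i)
    for (int p = 0; p < L; ++p) {
      double* o = out + (i * L + p) * Cout;
      for (int c = 0; c < Cout; ++c) o[c] = b[c];
      for (int dk = 0; dk < 3; ++dk) {
        int q = p + dk - 1;
        if (q < 0 || q >= L) continue;
        const double* a = in + (i * L + q) * Cin;
        const double* w = W + dk * Cin * Cout;
        for (int ci = 0; ci < Cin; ++ci) {
          const double av = a[ci];
          const double* wr = w + ci * Cout;
          for (int c = 0; c < Cout; ++c) o[c] += av * wr[c];
        }
      }
    }
}

void conv3_bwd(const double* in, const double* dout, int B, int L, int Cin,
               const double* W, int Cout, double* din, double* gW,
               double* gb) {
  std::fill(din, din + B * L * Cin, 0.0);
  std::fill(gW, gW + 3 * Cin * Cout, 0.0);
  std::fill(gb, gb + Cout, 0.0);
  for (int i = 0; i < B; ++i)
    for (int p = 0; p < L; ++p) {
      const double* dz = dout + (i * L + p) * Cout;
      for (int c = 0; c < Cout; ++c) gb[c] += dz[c];
      for (int dk = 0; dk < 3; ++dk) {
        int q = p + dk - 1;
        if (q < 0 || q >= L) continue;
        const double* a = in + (i * L + q) * Cin;
        double* da = din + (i * L + q) * Cin;
        const double* w = W + dk * Cin * Cout;
        double* gw = gW + dk * Cin * Cout;
        for (int ci = 0; ci < Cin; ++ci) {
          double accd = 0;
          const double av = a[ci];
          const double* wr = w + ci * Cout;
          double* gr = gw + ci * Cout;
          for (int c = 0; c < Cout; ++c) {
            gr[c] += av * dz[c];
            accd += wr[c] * dz[c];
          }
          da[ci] += accd;
        }
      }
    }
}

inline void relu_fwd(double* z, int n, unsigned char* on) {
  for (int k = 0; k < n; ++k) {
    on[k] = z[k] > 0;
    if (!on[k]) z[k] = 0;
  }
}

inline void relu_bwd(double* dz, int n, const unsigned char* on) {
  for (int k = 0; k < n; ++k)
    if (!on[k]) dz[k] = 0;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_cnn(const arma::mat& X, const arma::mat& Y,
                         int f1, int f2, int f3, int epochs, int batch,
                         double lr, std::string loss, int seed) {
  bool mae = (loss == "mae");
  std::mt19937 rng(static_cast<unsigned>(seed));
  const int Lseq = X.n_cols, Lp = Lseq / 2, O = Y.n_cols;
  std::vector<double> W1(3 * 1 * f1), b1(f1, 0.0);
  std::vector<double> W2(3 * f1 * f2), b2(f2, 0.0);
  std::vector<double> W3(3 * f2 * f3), b3(f3, 0.0);
  std::vector<double> Wd(Lp * f3 * O), bd(O, 0.0);
  glorot_fill(W1, 3, f1, rng);
  glorot_fill(W2, 3 * f1, f2, rng);
  glorot_fill(W3, 3 * f2, f3, rng);
  glorot_fill(Wd, Lp * f3, O, rng);
  Adam aW1, aW2, aW3, aWd, ab1, ab2, ab3, abd;
  aW1.init(W1.size()); aW2.init(W2.size()); aW3.init(W3.size());
  aWd.init(Wd.size());
  ab1.init(f1); ab2.init(f2); ab3.init(f3); abd.init(O);

  int B0 = std::min<int>(batch, X.n_rows);
  std::vector<double> A0(B0 * Lseq), Z1(B0 * Lseq * f1), P1(B0 * Lp * f1),
      Z2(B0 * Lp * f2), Z3(B0 * Lp * f3), P(B0 * O);
  std::vector<unsigned char> on1(B0 * Lseq * f1), on2(B0 * Lp * f2),
      on3(B0 * Lp * f3);
  std::vector<int> amax(B0 * Lp * f1);
  std::vector<double> dZ1(B0 * Lseq * f1), dP1(B0 * Lp * f1),
      dZ2(B0 * Lp * f2), dZ3(B0 * Lp * f3), dP(B0 * O), dA0(B0 * Lseq);
  std::vector<double> gW1(W1.size()), gW2(W2.size()), gW3(W3.size()),
      gWd(Wd.size()), gb1(f1), gb2(f2), gb3(f3), gbd(O);

  vec history(epochs, fill::zeros);
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    auto batches = make_batches(X.n_rows, batch, rng);
    double acc = 0; int nb = 0;
    for (auto& idx : batches) {
      int B = idx.size();
      for (int i = 0; i < B; ++i)
        for (int p = 0; p < Lseq; ++p) A0[i * Lseq + p] = X(idx[i], p);
      conv3_fwd(A0.data(), B, Lseq, 1, W1.data(), b1.data(), f1, Z1.data());
      relu_fwd(Z1.data(), B * Lseq * f1, on1.data());
      // maxpool(2) over positions
      for (int i = 0; i < B; ++i)
        for (int p = 0; p < Lp; ++p)
          for (int c = 0; c < f1; ++c) {
            double v0 = Z1[(i * Lseq + 2 * p) * f1 + c];
            double v1 = Z1[(i * Lseq + 2 * p + 1) * f1 + c];
            int a = v0 >= v1 ? 0 : 1;
            amax[(i * Lp + p) * f1 + c] = a;
            P1[(i * Lp + p) * f1 + c] = a ? v1 : v0;
          }
      conv3_fwd(P1.data(), B, Lp, f1, W2.data(), b2.data(), f2, Z2.data());
      relu_fwd(Z2.data(), B * Lp * f2, on2.data());
      conv3_fwd(Z2.data(), B, Lp, f2, W3.data(), b3.data(), f3, Z3.data());
      relu_fwd(Z3.data(), B * Lp * f3, on3.data());
      // dense head on the flattened [pos][chan] block
      const int F = Lp * f3;
      double lval = 0;
      for (int i = 0; i < B; ++i) {
        const double* a = &Z3[i * F];
        for (int o = 0; o < O; ++o) {
          double z = bd[o];
          for (int j = 0; j < F; ++j) z += a[j] * Wd[j * O + o];
          P[i * O + o] = z;
          double d = z - Y(idx[i], o);
          lval += mae ? std::fabs(d) : d * d;
          dP[i * O + o] =
              (mae ? (d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0)) : 2.0 * d) /
              (B * O);
        }
      }
      lval /= B * O;
      if (!std::isfinite(lval)) Rcpp::stop("NaN loss during CNN training");
      acc += lval; nb++;
      // backward
      std::fill(gWd.begin(), gWd.end(), 0.0);
      std::fill(gbd.begin(), gbd.end(), 0.0);
      for (int i = 0; i < B; ++i) {
        const double* a = &Z3[i * F];
        const double* dp = &dP[i * O];
        double* dz3 = &dZ3[i * F];
        for (int o = 0; o < O; ++o) gbd[o] += dp[o];
        for (int j = 0; j < F; ++j) {
          double accd = 0;
          for (int o = 0; o < O; ++o) {
            gWd[j * O + o] += a[j] * dp[o];
            accd += Wd[j * O + o] * dp[o];
          }
          dz3[j] = accd;
        }
      }
      relu_bwd(dZ3.data(), B * F, on3.data());
      conv3_bwd(Z2.data(), dZ3.data(), B, Lp, f2, W3.data(), f3,
                dZ2.data(), gW3.data(), gb3.data());
      relu_bwd(dZ2.data(), B * Lp * f2, on2.data());
      conv3_bwd(P1.data(), dZ2.data(), B, Lp, f1, W2.data(), f2,
                dP1.data(), gW2.data(), gb2.data());
      // un-pool
      std::fill(dZ1.begin(), dZ1.begin() + B * Lseq * f1, 0.0);
      for (int i = 0; i < B; ++i)
        for (int p = 0; p < Lp; ++p)
          for (int c = 0; c < f1; ++c) {
            int a = amax[(i * Lp + p) * f1 + c];
            dZ1[(i * Lseq + 2 * p + a) * f1 + c] = dP1[(i * Lp + p) * f1 + c];
          }
      relu_bwd(dZ1.data(), B * Lseq * f1, on1.data());
      conv3_bwd(A0.data(), dZ1.data(), B, Lseq, 1, W1.data(), f1,
                dA0.data(), gW1.data(), gb1.data());
      ++t;
      aW1.step(W1.data(), gW1.data(), W1.size(), lr, t);
      aW2.step(W2.data(), gW2.data(), W2.size(), lr, t);
      aW3.step(W3.data(), gW3.data(), W3.size(), lr, t);
      aWd.step(Wd.data(), gWd.data(), Wd.size(), lr, t);
      ab1.step(b1.data(), gb1.data(), f1, lr, t);
      ab2.step(b2.data(), gb2.data(), f2, lr, t);
      ab3.step(b3.data(), gb3.data(), f3, lr, t);
      abd.step(bd.data(), gbd.data(), O, lr, t);
    }
    history[ep] = acc / std::max(nb, 1);
  }
  // export: conv weights as (k, cin, cout) arrays, dense as (F x O)
  auto conv2r = [](const std::vector<double>& W, int cin, int cout) {
    Rcpp::NumericVector v(3 * cin * cout);
    // stored [dk][cin][cout]; export with dim (dk, cin, cout)
    for (int dk = 0; dk < 3; ++dk)
      for (int ci = 0; ci < cin; ++ci)
        for (int c = 0; c < cout; ++c)
          v[dk + 3 * ci + 3 * cin * c] = W[(dk * cin + ci) * cout + c];
    v.attr("dim") = Rcpp::IntegerVector::create(3, cin, cout);
    return v;
  };
  const int F = Lp * f3;
  mat Wdm(F, O);
  for (int j = 0; j < F; ++j)
    for (int o = 0; o < O; ++o) Wdm(j, o) = Wd[j * O + o];
  return Rcpp::List::create(
      Rcpp::Named("W1") = conv2r(W1, 1, f1),
      Rcpp::Named("b1") = Rcpp::NumericVector(b1.begin(), b1.end()),
      Rcpp::Named("W2") = conv2r(W2, f1, f2),
      Rcpp::Named("b2") = Rcpp::NumericVector(b2.begin(), b2.end()),
      Rcpp::Named("W3") = conv2r(W3, f2, f3),
      Rcpp::Named("b3") = Rcpp::NumericVector(b3.begin(), b3.end()),
      Rcpp::Named("Wd") = Wdm,
      Rcpp::Named("bd") = Rcpp::NumericVector(bd.begin(), bd.end()),
      Rcpp::Named("history") = history);
}

// --------------------------------------------------------------- LSTM ----
// The four features enter as a length-4 sequence of scalars; gate
// equations: i = s(Wi [h, x] + bi), f = s(Wf [h, x] + bf),
// g = tanh(Wc [h, x] + bc), c = f*c_prev + i*g, o = s(Wo [h, x] + bo),
// h = o * tanh(c).  The last hidden state feeds a ReLU dense layer and a
// linear output layer.  Gate weights are stored [in][out] with
// in = H (recurrent) + 1 (input scalar).

// [[Rcpp::export]]
Rcpp::List cpp_train_lstm(const arma::mat& X, const arma::mat& Y,
                          int hidden, int epochs, int batch, double lr,
                          std::string loss, int seed) {
  bool mae = (loss == "mae");
  std::mt19937 rng(static_cast<unsigned>(seed));
  const int T = X.n_cols, H = hidden, O = Y.n_cols, Zn = H + 1;
  if (H > 64) Rcpp::stop("LSTM hidden size is limited to 64");
  std::vector<double> Wi(Zn * H), Wf(Zn * H), Wc(Zn * H), Wo(Zn * H);
  std::vector<double> bi(H, 0.0), bf(H, 1.0), bc(H, 0.0), bo(H, 0.0);
  std::vector<double> Wd1(H * H), bd1(H, 0.0), Wd2(H * O), bd2(O, 0.0);
  glorot_fill(Wi, Zn, H, rng); glorot_fill(Wf, Zn, H, rng);
  glorot_fill(Wc, Zn, H, rng); glorot_fill(Wo, Zn, H, rng);
  glorot_fill(Wd1, H, H, rng); glorot_fill(Wd2, H, O, rng);
  Adam aWi, aWf, aWc, aWo, aWd1, aWd2, abi, abf, abc, abo, abd1, abd2;
  aWi.init(Wi.size()); aWf.init(Wf.size()); aWc.init(Wc.size());
  aWo.init(Wo.size()); aWd1.init(Wd1.size()); aWd2.init(Wd2.size());
  abi.init(H); abf.init(H); abc.init(H); abo.init(H); abd1.init(H);
  abd2.init(O);

  int B0 = std::min<int>(batch, X.n_rows);
  // per-timestep state buffers [t][sample][unit]
  auto buf = [&](int units) { return std::vector<double>((T + 1) * B0 * units, 0.0); };
  std::vector<double> hs = buf(H), cs = buf(H);
  std::vector<double> ig(T * B0 * H), fg(T * B0 * H), gg(T * B0 * H),
      og(T * B0 * H), tc(T * B0 * H);
  std::vector<double> Z1(B0 * H), A1(B0 * H), P(B0 * O), dP(B0 * O),
      dZ1(B0 * H), dh(B0 * H), dc(B0 * H);
  std::vector<unsigned char> on1(B0 * H);
  std::vector<double> gWi(Wi.size()), gWf(Wf.size()), gWc(Wc.size()),
      gWo(Wo.size()), gWd1(Wd1.size()), gWd2(Wd2.size());
  std::vector<double> gbi(H), gbf(H), gbc(H), gbo(H), gbd1(H), gbd2(O);

  vec history(epochs, fill::zeros);
  int t_adam = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    auto batches = make_batches(X.n_rows, batch, rng);
    double acc = 0; int nb = 0;
    for (auto& idx : batches) {
      int B = idx.size();
      std::fill(hs.begin(), hs.begin() + B * H, 0.0);
      std::fill(cs.begin(), cs.begin() + B * H, 0.0);
      // forward through time
      for (int s = 0; s < T; ++s) {
        const double* hp = &hs[s * B0 * H];
        const double* cp = &cs[s * B0 * H];
        double* hn = &hs[(s + 1) * B0 * H];
        double* cn = &cs[(s + 1) * B0 * H];
        for (int i = 0; i < B; ++i) {
          const double xv = X(idx[i], s);
          const double* h = hp + i * H;
          for (int u = 0; u < H; ++u) {
            // gate weights are output-major: row u holds [recurrent, input]
            const double *wi = &Wi[u * Zn], *wf = &Wf[u * Zn],
                         *wc = &Wc[u * Zn], *wo = &Wo[u * Zn];
            double zi = bi[u] + xv * wi[H];
            double zf = bf[u] + xv * wf[H];
            double zg = bc[u] + xv * wc[H];
            double zo = bo[u] + xv * wo[H];
            for (int j = 0; j < H; ++j) {
              const double hj = h[j];
              zi += hj * wi[j];
              zf += hj * wf[j];
              zg += hj * wc[j];
              zo += hj * wo[j];
            }
            const int k = (s * B0 + i) * H + u;
            double iv = sigm1(zi), fv = sigm1(zf), gv = std::tanh(zg),
                   ov = sigm1(zo);
            double cv = fv * cp[i * H + u] + iv * gv;
            double th = std::tanh(cv);
            ig[k] = iv; fg[k] = fv; gg[k] = gv; og[k] = ov; tc[k] = th;
            cn[i * H + u] = cv;
            hn[i * H + u] = ov * th;
          }
        }
      }
      // dense head: ReLU(H) then linear O
      const double* hT = &hs[T * B0 * H];
      double lval = 0;
      for (int i = 0; i < B; ++i) {
        for (int u = 0; u < H; ++u) {
          double z = bd1[u];
          for (int j = 0; j < H; ++j) z += hT[i * H + j] * Wd1[j * H + u];
          Z1[i * H + u] = z;
          on1[i * H + u] = z > 0;
          A1[i * H + u] = z > 0 ? z : 0.0;
        }
        for (int o = 0; o < O; ++o) {
          double z = bd2[o];
          for (int j = 0; j < H; ++j) z += A1[i * H + j] * Wd2[j * O + o];
          P[i * O + o] = z;
          double d = z - Y(idx[i], o);
          lval += mae ? std::fabs(d) : d * d;
          dP[i * O + o] =
              (mae ? (d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0)) : 2.0 * d) /
              (B * O);
        }
      }
      lval /= B * O;
      if (!std::isfinite(lval)) Rcpp::stop("NaN loss during LSTM training");
      acc += lval; nb++;
      // backward: head
      std::fill(gWd1.begin(), gWd1.end(), 0.0);
      std::fill(gWd2.begin(), gWd2.end(), 0.0);
      std::fill(gbd1.begin(), gbd1.end(), 0.0);
      std::fill(gbd2.begin(), gbd2.end(), 0.0);
      std::fill(gWi.begin(), gWi.end(), 0.0);
      std::fill(gWf.begin(), gWf.end(), 0.0);
      std::fill(gWc.begin(), gWc.end(), 0.0);
      std::fill(gWo.begin(), gWo.end(), 0.0);
      std::fill(gbi.begin(), gbi.end(), 0.0);
      std::fill(gbf.begin(), gbf.end(), 0.0);
      std::fill(gbc.begin(), gbc.end(), 0.0);
      std::fill(gbo.begin(), gbo.end(), 0.0);
      for (int i = 0; i < B; ++i) {
        const double* dp = &dP[i * O];
        double* dz1 = &dZ1[i * H];
        for (int o = 0; o < O; ++o) gbd2[o] += dp[o];
        for (int j = 0; j < H; ++j) {
          double accd = 0;
          for (int o = 0; o < O; ++o) {
            gWd2[j * O + o] += A1[i * H + j] * dp[o];
            accd += Wd2[j * O + o] * dp[o];
          }
          dz1[j] = on1[i * H + j] ? accd : 0.0;
        }
        for (int u = 0; u < H; ++u) gbd1[u] += dz1[u];
        double* dhi = &dh[i * H];
        for (int j = 0; j < H; ++j) {
          double accd = 0;
          for (int u = 0; u < H; ++u) {
            gWd1[j * H + u] += hT[i * H + j] * dz1[u];
            accd += Wd1[j * H + u] * dz1[u];
          }
          dhi[j] = accd;
        }
      }
      std::fill(dc.begin(), dc.begin() + B * H, 0.0);
      // backward through time
      for (int s = T - 1; s >= 0; --s) {
        const double* hp = &hs[s * B0 * H];
        const double* cp = &cs[s * B0 * H];
        for (int i = 0; i < B; ++i) {
          const double xv = X(idx[i], s);
          double* dhi = &dh[i * H];
          double* dci = &dc[i * H];
          double dznext[64];  // H <= 64 assumed (widths are ~10)
          for (int j = 0; j < H; ++j) dznext[j] = 0.0;
          for (int u = 0; u < H; ++u) {
            const int k = (s * B0 + i) * H + u;
            const double iv = ig[k], fv = fg[k], gv = gg[k], ov = og[k],
                         th = tc[k];
            double dcv = dci[u] + dhi[u] * ov * (1 - th * th);
            double dog = dhi[u] * th;
            double dig = dcv * gv;
            double dgg = dcv * iv;
            double dfg = dcv * cp[i * H + u];
            double dzi = dig * iv * (1 - iv);
            double dzf = dfg * fv * (1 - fv);
            double dzg = dgg * (1 - gv * gv);
            double dzo = dog * ov * (1 - ov);
            gbi[u] += dzi; gbf[u] += dzf; gbc[u] += dzg; gbo[u] += dzo;
            double *gi = &gWi[u * Zn], *gf = &gWf[u * Zn],
                   *gc = &gWc[u * Zn], *go = &gWo[u * Zn];
            const double *wi = &Wi[u * Zn], *wf = &Wf[u * Zn],
                         *wc = &Wc[u * Zn], *wo = &Wo[u * Zn];
            gi[H] += xv * dzi; gf[H] += xv * dzf;
            gc[H] += xv * dzg; go[H] += xv * dzo;
            const double* hrow = hp + i * H;
            for (int j = 0; j < H; ++j) {
              const double hj = hrow[j];
              gi[j] += hj * dzi;
              gf[j] += hj * dzf;
              gc[j] += hj * dzg;
              go[j] += hj * dzo;
              dznext[j] += wi[j] * dzi + wf[j] * dzf +
                           wc[j] * dzg + wo[j] * dzo;
            }
            dci[u] = dcv * fv;
          }
          for (int j = 0; j < H; ++j) dhi[j] = dznext[j];
        }
      }
      ++t_adam;
      aWi.step(Wi.data(), gWi.data(), Wi.size(), lr, t_adam);
      aWf.step(Wf.data(), gWf.data(), Wf.size(), lr, t_adam);
      aWc.step(Wc.data(), gWc.data(), Wc.size(), lr, t_adam);
      aWo.step(Wo.data(), gWo.data(), Wo.size(), lr, t_adam);
      aWd1.step(Wd1.data(), gWd1.data(), Wd1.size(), lr, t_adam);
      aWd2.step(Wd2.data(), gWd2.data(), Wd2.size(), lr, t_adam);
      abi.step(bi.data(), gbi.data(), H, lr, t_adam);
      abf.step(bf.data(), gbf.data(), H, lr, t_adam);
      abc.step(bc.data(), gbc.data(), H, lr, t_adam);
      abo.step(bo.data(), gbo.data(), H, lr, t_adam);
      abd1.step(bd1.data(), gbd1.data(), H, lr, t_adam);
      abd2.step(bd2.data(), gbd2.data(), O, lr, t_adam);
    }
    history[ep] = acc / std::max(nb, 1);
  }
  auto gate2r = [&](const std::vector<double>& W) {
    mat M(Zn, H);  // (recurrent+input) x units, matching [h, x] %*% W
    for (int u = 0; u < H; ++u)
      for (int j = 0; j < Zn; ++j) M(j, u) = W[u * Zn + j];
    return M;
  };
  auto wmat = [](const std::vector<double>& W, int ni, int no) {
    mat M(ni, no);
    for (int j = 0; j < ni; ++j)
      for (int o = 0; o < no; ++o) M(j, o) = W[j * no + o];
    return M;
  };
  auto wvec = [](const std::vector<double>& b) {
    return Rcpp::NumericVector(b.begin(), b.end());
  };
  return Rcpp::List::create(
      Rcpp::Named("Wi") = gate2r(Wi), Rcpp::Named("bi") = wvec(bi),
      Rcpp::Named("Wf") = gate2r(Wf), Rcpp::Named("bf") = wvec(bf),
      Rcpp::Named("Wc") = gate2r(Wc), Rcpp::Named("bc") = wvec(bc),
      Rcpp::Named("Wo") = gate2r(Wo), Rcpp::Named("bo") = wvec(bo),
      Rcpp::Named("Wd1") = wmat(Wd1, H, H), Rcpp::Named("bd1") = wvec(bd1),
      Rcpp::Named("Wd2") = wmat(Wd2, H, O), Rcpp::Named("bd2") = wvec(bd2),
      Rcpp::Named("history") = history);
}
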