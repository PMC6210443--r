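// Batched forward and backward passes of the channel-isolated CNN.
// Layout contracts (column-major, matching the R arrays):
//   x        : C x W0 x B          input windows
//   conv1_w  : f1 x k1 x banks     per-channel filter bank (banks = 1 if shared)
//   conv1_b  : f1 x banks
//   conv2_w  : f2 x f1 x k2 x banks
//   conv2_b  : f2 x banks
//   pl1_w    : pl1 x fd            fd = C * (f2/pool) * W2
//   pl2_w    : ncls x pl1
// Per-channel feature order inside fd: pooled map fastest, then time, then
// channel -- identical to the R reference implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Geom {
  int C, W0, B, k1, k2, f1, f2, pool, npool;
  int W1, W2, p1l, p2l, fd, rows_per_ch;
  bool shared;
};

Geom make_geom(const Rcpp::List& cfg, int B) {
  Geom g;
  g.C = Rcpp::as<int>(cfg["n_channels"]);
  g.W0 = Rcpp::as<int>(cfg["W"]);
  g.B = B;
  g.f1 = Rcpp::as<int>(cfg["conv1_filters"]);
  g.k1 = Rcpp::as<int>(cfg["conv1_size"]);
  g.f2 = Rcpp::as<int>(cfg["conv2_filters"]);
  g.k2 = Rcpp::as<int>(cfg["conv2_size"]);
  g.pool = Rcpp::as<int>(cfg["pool_size"]);
  g.npool = g.f2 / g.pool;
  g.shared = Rcpp::as<bool>(cfg["shared_filters"]);
  const bool same = Rcpp::as<std::string>(cfg["padding"]) == "same";
  g.p1l = same ? (g.k1 - 1) / 2 : 0;
  g.p2l = same ? (g.k2 - 1) / 2 : 0;
  g.W1 = same ? g.W0 : g.W0 - g.k1 + 1;
  g.W2 = same ? g.W1 : g.W1 - g.k2 + 1;
  g.rows_per_ch = g.npool * g.W2;
  g.fd = g.C * g.rows_per_ch;
  return g;
}

// im2col for one channel of the input: X1 is k1 x (W1 * B)
void im2col_input(const double* x, int c, const Geom& g, mat& X1) {
  for (int b = 0; b < g.B; ++b) {
    for (int t = 0; t < g.W1; ++t) {
      const int col = b * g.W1 + t;
      for (int j = 0; j < g.k1; ++j) {
        const int s = t + j - g.p1l;
        X1(j, col) = (s >= 0 && s < g.W0)
          ? x[c + (std::size_t)g.C * (s + (std::size_t)g.W0 * b)]
          : 0.0;
      }
    }
  }
}

// im2col over conv1 maps: X2 is (f1 * k2) x (W2 * B), row index m + f1 * j
void im2col_maps(const mat& F1, const Geom& g, mat& X2) {
  X2.zeros();
  for (int b = 0; b < g.B; ++b) {
    for (int t = 0; t < g.W2; ++t) {
      const int col = b * g.W2 + t;
      for (int j = 0; j < g.k2; ++j) {
        const int s = t + j - g.p2l;
        if (s >= 0 && s < g.W1) {
          X2.col(col).subvec(g.f1 * j, g.f1 * (j + 1) - 1) = F1.col(b * g.W1 + s);
        }
      }
    }
  }
}

// forward through one channel; fills the channel's rows of feat and,
// if caches are given, stores X1, X2, F2
void channel_forward(const double* x, int c, const Geom& g,
                     const cube& c1w, const mat& c1b,
                     const mat& c2w_flat, const mat& c2b,
                     mat& feat, mat& X1, mat& X2, mat& F2) {
  const int cw = g.shared ? 0 : c;
  im2col_input(x, c, g, X1);
  mat F1 = c1w.slice(cw) * X1;
  F1.each_col() += c1b.col(cw);
  im2col_maps(F1, g, X2);
  F2 = c2w_flat.rows(g.f2 * cw, g.f2 * (cw + 1) - 1) * X2;
  F2.each_col() += c2b.col(cw);
  // pair-max pool over the map axis, then ReLU, straight into feat
  for (int col = 0; col < g.W2 * g.B; ++col) {
    const int b = col / g.W2;
    const int t = col % g.W2;
    for (int m = 0; m < g.npool; ++m) {
      double v = F2(m * g.pool, col);
      for (int j = 1; j < g.pool; ++j) v = std::max(v, F2(m * g.pool + j, col));
      feat(c * g.rows_per_ch + t * g.npool + m, b) = std::max(v, 0.0);
    }
  }
}

} // namespace

// Full forward pass; returns class probabilities (ncls x B) plus the dense
// intermediates. Used by prediction and by the single-window forward.
// [[Rcpp::export(name = ".cpp_forward")]]
Rcpp::List cpp_forward(Rcpp::List weights, Rcpp::NumericVector x, Rcpp::List cfg) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const Geom g = make_geom(cfg, xd[2]);

  Rcpp::NumericVector c1wR = weights["conv1_w"], c1bR = weights["conv1_b"],
    c2wR = weights["conv2_w"], c2bR = weights["conv2_b"];
  const int banks = g.shared ? 1 : g.C;
  const cube c1w(c1wR.begin(), g.f1, g.k1, banks, false);
  const mat c1b(c1bR.begin(), g.f1, banks, false);
  // conv2_w (f2, f1, k2, banks) viewed as (f2 * banks) x (f1 * k2) blocks:
  // rearrange once into a banks-stacked matrix with row blocks per bank
  const mat c2b(c2bR.begin(), g.f2, banks, false);
  const cube c2w(c2wR.begin(), g.f2, g.f1, g.k2 * banks, false);
  mat c2w_flat(g.f2 * banks, g.f1 * g.k2);
  for (int cw = 0; cw < banks; ++cw)
    for (int j = 0; j < g.k2; ++j)
      c2w_flat.submat(g.f2 * cw, g.f1 * j, g.f2 * (cw + 1) - 1, g.f1 * (j + 1) - 1) =
        c2w.slice(cw * g.k2 + j);

  Rcpp::NumericVector pl1wR = weights["pl1_w"], pl2wR = weights["pl2_w"];
  const mat pl1w(pl1wR.begin(), Rcpp::as<int>(cfg["pl1_outputs"]), g.fd, false);
  const vec pl1b = Rcpp::as<vec>(weights["pl1_b"]);
  const mat pl2w(pl2wR.begin(), Rcpp::as<int>(cfg["n_classes"]), pl1w.n_rows, false);
  const vec pl2b = Rcpp::as<vec>(weights["pl2_b"]);

  mat feat(g.fd, g.B);
  mat X1(g.k1, g.W1 * g.B), X2(g.f1 * g.k2, g.W2 * g.B), F2;
  for (int c = 0; c < g.C; ++c) {
    channel_forward(x.begin(), c, g, c1w, c1b, c2w_flat, c2b, feat, X1, X2, F2);
  }
  mat z1 = pl1w * feat;
  z1.each_col() += pl1b;
  const mat H = 1.0 / (1.0 + exp(-z1));
  mat scores = pl2w * H;
  scores.each_col() += pl2b;
  const rowvec mx = max(scores, 0);
  mat es = exp(scores.each_row() - mx);
  const mat probs = es.each_row() / sum(es, 0);
  return Rcpp::List::create(
    Rcpp::Named("probs") = probs,
    Rcpp::Named("scores") = scores,
    Rcpp::Named("H") = H,
    Rcpp::Named("feat") = feat
  );
}

// Mean softmax cross-entropy and exact gradients for a labelled batch.
// labels are 1-based softmax positions.
// [[Rcpp::export(name = ".cpp_loss_grad")]]
Rcpp::List cpp_loss_grad(Rcpp::List weights, Rcpp::NumericVector x,
                         Rcpp::IntegerVector labels, Rcpp::List cfg) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const Geom g = make_geom(cfg, xd[2]);
  const int banks = g.shared ? 1 : g.C;

  Rcpp::NumericVector c1wR = weights["conv1_w"], c1bR = weights["conv1_b"],
    c2wR = weights["conv2_w"], c2bR = weights["conv2_b"];
  const cube c1w(c1wR.begin(), g.f1, g.k1, banks, false);
  const mat c1b(c1bR.begin(), g.f1, banks, false);
  const mat c2b(c2bR.begin(), g.f2, banks, false);
  const cube c2w(c2wR.begin(), g.f2, g.f1, g.k2 * banks, false);
  mat c2w_flat(g.f2 * banks, g.f1 * g.k2);
  for (int cw = 0; cw < banks; ++cw)
    for (int j = 0; j < g.k2; ++j)
      c2w_flat.submat(g.f2 * cw, g.f1 * j, g.f2 * (cw + 1) - 1, g.f1 * (j + 1) - 1) =
        c2w.slice(cw * g.k2 + j);
  Rcpp::NumericVector pl1wR = weights["pl1_w"], pl2wR = weights["pl2_w"];
  const mat pl1w(pl1wR.begin(), Rcpp::as<int>(cfg["pl1_outputs"]), g.fd, false);
  const vec pl1b = Rcpp::as<vec>(weights["pl1_b"]);
  const mat pl2w(pl2wR.begin(), Rcpp::as<int>(cfg["n_classes"]), pl1w.n_rows, false);
  const vec pl2b = Rcpp::as<vec>(weights["pl2_b"]);

  // forward with caches
  std::vector<mat> X1c(g.C), X2c(g.C), F2c(g.C);
  mat feat(g.fd, g.B);
  for (int c = 0; c < g.C; ++c) {
    X1c[c].set_size(g.k1, g.W1 * g.B);
    X2c[c].set_size(g.f1 * g.k2, g.W2 * g.B);
    channel_forward(x.begin(), c, g, c1w, c1b, c2w_flat, c2b,
                    feat, X1c[c], X2c[c], F2c[c]);
  }
  mat z1 = pl1w * feat;
  z1.each_col() += pl1b;
  const mat H = 1.0 / (1.0 + exp(-z1));
  mat scores = pl2w * H;
  scores.each_col() += pl2b;
  const rowvec mx = max(scores, 0);
  const rowvec lse = log(sum(exp(scores.each_row() - mx), 0)) + mx;
  double loss = 0.0;
  for (int b = 0; b < g.B; ++b) loss += lse(b) - scores(labels[b] - 1, b);
  loss /= g.B;

  mat G = exp(scores.each_row() - lse); // softmax probabilities
  for (int b = 0; b < g.B; ++b) G(labels[b] - 1, b) -= 1.0;
  G /= g.B;

  mat d_pl2w = G * H.t();
  vec d_pl2b = sum(G, 1);
  mat dH = pl2w.t() * G;
  mat dz1 = dH % H % (1.0 - H);
  mat d_pl1w = dz1 * feat.t();
  vec d_pl1b = sum(dz1, 1);
  mat dfeat = pl1w.t() * dz1;

  cube d_c1w(g.f1, g.k1, banks, fill::zeros);
  mat d_c1b(g.f1, banks, fill::zeros);
  cube d_c2w(g.f2, g.f1, g.k2 * banks, fill::zeros);
  mat d_c2b(g.f2, banks, fill::zeros);

  mat dF2(g.f2, g.W2 * g.B), dF1(g.f1, g.W1 * g.B);
  for (int c = 0; c < g.C; ++c) {
    const int cw = g.shared ? 0 : c;
    const mat& F2 = F2c[c];
    // ReLU gate + un-pool: gradient goes to the first map attaining the max
    dF2.zeros();
    for (int col = 0; col < g.W2 * g.B; ++col) {
      const int b = col / g.W2;
      const int t = col % g.W2;
      for (int m = 0; m < g.npool; ++m) {
        int arg = m * g.pool;
        double v = F2(arg, col);
        for (int j = 1; j < g.pool; ++j) {
          const double cand = F2(m * g.pool + j, col);
          if (cand > v) { v = cand; arg = m * g.pool + j; }
        }
        if (v > 0.0) {
          dF2(arg, col) = dfeat(c * g.rows_per_ch + t * g.npool + m, b);
        }
      }
    }
    d_c2b.col(cw) += sum(dF2, 1);
    const mat dA2 = dF2 * X2c[c].t(); // f2 x (f1 * k2)
    for (int j = 0; j < g.k2; ++j) {
      d_c2w.slice(cw * g.k2 + j) += dA2.cols(g.f1 * j, g.f1 * (j + 1) - 1);
    }
    const mat dX2 = c2w_flat.rows(g.f2 * cw, g.f2 * (cw + 1) - 1).t() * dF2;
    // col2im: accumulate back onto the conv1 output grid
    dF1.zeros();
    for (int b = 0; b < g.B; ++b) {
      for (int t = 0; t < g.W2; ++t) {
        const int col = b * g.W2 + t;
        for (int j = 0; j < g.k2; ++j) {
          const int s = t + j - g.p2l;
          if (s >= 0 && s < g.W1) {
            dF1.col(b * g.W1 + s) +=
              dX2.col(col).subvec(g.f1 * j, g.f1 * (j + 1) - 1);
          }
        }
      }
    }
    d_c1b.col(cw) += sum(dF1, 1);
    d_c1w.slice(cw) += dF1 * X1c[c].t();
  }

  Rcpp::NumericVector g1(d_c1w.begin(), d_c1w.end());
  g1.attr("dim") = Rcpp::IntegerVector::create(g.f1, g.k1, banks);
  Rcpp::NumericVector g2(d_c2w.begin(), d_c2w.end());
  g2.attr("dim") = Rcpp::IntegerVector::create(g.f2, g.f1, g.k2, banks);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("conv1_w") = g1,
      Rcpp::Named("conv1_b") = Rcpp::wrap(d_c1b),
      Rcpp::Named("conv2_w") = g2,
      Rcpp::Named("conv2_b") = Rcpp::wrap(d_c2b),
      Rcpp::Named("pl1_w") = Rcpp::wrap(d_pl1w),
      Rcpp::Named("pl1_b") = Rcpp::NumericVector(d_pl1b.begin(), d_pl1b.end()),
      Rcpp::Named("pl2_w") = Rcpp::wrap(d_pl2w),
      Rcpp::Named("pl2_b") = Rcpp::NumericVector(d_pl2b.begin(), d_pl2b.end())
    )
  );
}
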