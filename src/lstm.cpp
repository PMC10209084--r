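// Causal LSTM sequence-to-sequence regressor.
//
// Single LSTM layer (gate order i, f, g, o) with a linear readout,
// trained by full backpropagation through time with Adam on
// mini-batches of whole sequences. Prediction unrolls strictly
// stepwise, so the output at bin t depends only on inputs at bins <= t.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;
using Rcpp::List;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// deterministic uniform(-r, r) from a raw mt19937 stream
static void fill_uniform(mat& m, std::mt19937& gen, double r) {
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = r * (2.0 * (gen() * (1.0 / 4294967296.0)) - 1.0);
}

struct Params {
  mat W, U;      // 4H x n_in, 4H x H
  vec b, w_out;  // 4H, H
  double b_out;
};

static Params init_params(int n_in, int hidden, int seed) {
  std::mt19937 gen(static_cast<unsigned>(seed));
  Params p;
  double r_in = 1.0 / std::sqrt((double)n_in);
  double r_h  = 1.0 / std::sqrt((double)hidden);
  p.W.set_size(4 * hidden, n_in);  fill_uniform(p.W, gen, r_in);
  p.U.set_size(4 * hidden, hidden); fill_uniform(p.U, gen, r_h);
  p.b = zeros<vec>(4 * hidden);
  p.b.subvec(hidden, 2 * hidden - 1).fill(1.0);  // forget-gate bias
  p.w_out.set_size(hidden);
  mat tmp(hidden, 1); fill_uniform(tmp, gen, r_h); p.w_out = tmp.col(0);
  p.b_out = 0.0;
  return p;
}

struct Grads {
  mat W, U; vec b, w_out; double b_out;
  void zero(const Params& p) {
    W = zeros<mat>(p.W.n_rows, p.W.n_cols);
    U = zeros<mat>(p.U.n_rows, p.U.n_cols);
    b = zeros<vec>(p.b.n_elem);
    w_out = zeros<vec>(p.w_out.n_elem);
    b_out = 0.0;
  }
};

// Forward + BPTT over one padded batch. X: n_in x B x T (cube),
// Y, M (mask): B x T. Returns masked sum of squared errors; grads
// accumulated into g (already zeroed), scaled by 1/sum(mask).
static double batch_loss_grad(const Params& p, const cube& X, const mat& Y,
                              const mat& M, Grads& g, bool want_grad) {
  const int H = p.w_out.n_elem;
  const int B = Y.n_rows, T = Y.n_cols;
  cube gates(4 * H, B, T);  // post-nonlinearity
  cube cs(H, B, T), hs(H, B, T);
  mat h = zeros<mat>(H, B), c = zeros<mat>(H, B);
  mat dy(B, T);
  double sse = 0.0, denom = accu(M);
  if (denom <= 0) return 0.0;

  for (int t = 0; t < T; ++t) {
    mat z = p.W * X.slice(t) + p.U * h;
    z.each_col() += p.b;
    mat i = sigm(z.rows(0, H - 1));
    mat f = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = sigm(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % gg;
    h = o % tanh(c);
    gates.slice(t) = join_cols(join_cols(i, f), join_cols(gg, o));
    cs.slice(t) = c; hs.slice(t) = h;
    rowvec y = p.w_out.t() * h + p.b_out;
    rowvec err = (y - Y.col(t).t()) % M.col(t).t();
    dy.col(t) = (2.0 / denom) * err.t();
    sse += accu(square(err));
  }
  if (!want_grad) return sse / denom;

  mat dh_next = zeros<mat>(H, B), dc_next = zeros<mat>(H, B);
  mat f_next;  // forget gates at t+1
  for (int t = T - 1; t >= 0; --t) {
    const mat i = gates.slice(t).rows(0, H - 1);
    const mat f = gates.slice(t).rows(H, 2 * H - 1);
    const mat gg = gates.slice(t).rows(2 * H, 3 * H - 1);
    const mat o = gates.slice(t).rows(3 * H, 4 * H - 1);
    const mat tc = tanh(cs.slice(t));
    mat dh = p.w_out * dy.col(t).t() + dh_next;
    g.w_out += hs.slice(t) * dy.col(t);
    g.b_out += accu(dy.col(t));
    mat dc = dh % o % (1.0 - square(tc)) + dc_next;
    mat c_prev = (t > 0) ? cs.slice(t - 1) : zeros<mat>(H, B);
    mat di = dc % gg % i % (1.0 - i);
    mat df = dc % c_prev % f % (1.0 - f);
    mat dg = dc % i % (1.0 - square(gg));
    mat do_ = dh % tc % o % (1.0 - o);
    mat dz = join_cols(join_cols(di, df), join_cols(dg, do_));
    g.W += dz * X.slice(t).t();
    if (t > 0) g.U += dz * hs.slice(t - 1).t();
    g.b += sum(dz, 1);
    dh_next = p.U.t() * dz;
    dc_next = dc % f;
  }
  return sse / denom;
}

static List pack_params(const Params& p) {
  return List::create(Rcpp::Named("W") = p.W, Rcpp::Named("U") = p.U,
                      Rcpp::Named("b") = p.b, Rcpp::Named("w_out") = p.w_out,
                      Rcpp::Named("b_out") = p.b_out);
}

static Params unpack_params(const Rcpp::List& w) {
  Params p;
  p.W = Rcpp::as<mat>(w["W"]); p.U = Rcpp::as<mat>(w["U"]);
  p.b = Rcpp::as<vec>(w["b"]); p.w_out = Rcpp::as<vec>(w["w_out"]);
  p.b_out = Rcpp::as<double>(w["b_out"]);
  return p;
}

// Build a padded batch (cube + target + mask) from sequence indices.
static void make_batch(const std::vector<mat>& Xs, const std::vector<vec>& ys,
                       const std::vector<int>& idx, cube& X, mat& Y, mat& M) {
  int B = idx.size();
  int n_in = Xs[0].n_rows;
  int T = 0;
  for (int b = 0; b < B; ++b) T = std::max(T, (int)Xs[idx[b]].n_cols);
  X = zeros<cube>(n_in, B, T);
  Y = zeros<mat>(B, T);
  M = zeros<mat>(B, T);
  for (int b = 0; b < B; ++b) {
    const mat& x = Xs[idx[b]];
    int Tb = x.n_cols;
    for (int t = 0; t < Tb; ++t) X.slice(t).col(b) = x.col(t);
    Y.row(b).cols(0, Tb - 1) = ys[idx[b]].t();
    M.row(b).cols(0, Tb - 1).fill(1.0);
  }
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List x_list, Rcpp::List y_list, int hidden,
                          int epochs, double lr, int batch_size,
                          double clip, double weight_decay, int seed,
                          Rcpp::List xv_list, Rcpp::List yv_list) {
  int n_seq = x_list.size();
  std::vector<mat> Xs(n_seq);
  std::vector<vec> ys(n_seq);
  for (int i = 0; i < n_seq; ++i) {
    Xs[i] = Rcpp::as<mat>(x_list[i]);
    ys[i] = Rcpp::as<vec>(y_list[i]);
    if ((int)ys[i].n_elem != (int)Xs[i].n_cols)
      Rcpp::stop("sequence %d: target length != input length", i + 1);
  }
  int n_val = xv_list.size();
  std::vector<mat> Xv(n_val);
  std::vector<vec> yv(n_val);
  for (int i = 0; i < n_val; ++i) {
    Xv[i] = Rcpp::as<mat>(xv_list[i]);
    yv[i] = Rcpp::as<vec>(yv_list[i]);
  }
  int n_in = Xs[0].n_rows;
  Params p = init_params(n_in, hidden, seed);
  // validation loss of the untrained net = early-stopping baseline
  Params best = p;
  double best_val = datum::inf;
  std::vector<double> val_hist;
  auto val_loss = [&](const Params& pp) {
    if (n_val == 0) return datum::nan;
    double sse = 0.0; long n = 0;
    for (int i = 0; i < n_val; ++i) {
      vec yh = zeros<vec>(Xv[i].n_cols);
      { // stepwise forward
        const int H = pp.w_out.n_elem;
        vec h = zeros<vec>(H), c = zeros<vec>(H);
        for (uword t = 0; t < Xv[i].n_cols; ++t) {
          vec z = pp.W * Xv[i].col(t) + pp.U * h + pp.b;
          vec ii = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
          vec ff = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
          vec gg = tanh(z.subvec(2 * H, 3 * H - 1));
          vec oo = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
          c = ff % c + ii % gg;
          h = oo % tanh(c);
          yh(t) = dot(pp.w_out, h) + pp.b_out;
        }
      }
      sse += accu(square(yh - yv[i]));
      n += yv[i].n_elem;
    }
    return sse / (double)n;
  };
  if (n_val > 0) { best_val = val_loss(p); val_hist.push_back(best_val); }

  Grads m_st, v_st;  // Adam first/second moments
  m_st.zero(p); v_st.zero(p);
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  std::mt19937 order_gen(static_cast<unsigned>(seed) + 7u);
  std::vector<int> order(n_seq);
  for (int i = 0; i < n_seq; ++i) order[i] = i;
  std::vector<double> loss_hist;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), order_gen);
    double ep_loss = 0.0; int n_batches = 0;
    for (int start = 0; start < n_seq; start += batch_size) {
      std::vector<int> idx(order.begin() + start,
                           order.begin() + std::min(start + batch_size, n_seq));
      cube X; mat Y, M;
      make_batch(Xs, ys, idx, X, Y, M);
      Grads g; g.zero(p);
      ep_loss += batch_loss_grad(p, X, Y, M, g, true);
      ++n_batches;
      // global gradient-norm clipping
      double nrm = std::sqrt(accu(square(g.W)) + accu(square(g.U)) +
                             accu(square(g.b)) + accu(square(g.w_out)) +
                             g.b_out * g.b_out);
      if (clip > 0 && nrm > clip) {
        double s = clip / nrm;
        g.W *= s; g.U *= s; g.b *= s; g.w_out *= s; g.b_out *= s;
      }
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      auto adam = [&](mat& th, mat& mm, mat& vv, const mat& gr) {
        mm = beta1 * mm + (1 - beta1) * gr;
        vv = beta2 * vv + (1 - beta2) * square(gr);
        th -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
      };
      adam(p.W, m_st.W, v_st.W, g.W);
      adam(p.U, m_st.U, v_st.U, g.U);
      if (weight_decay > 0) {  // decoupled decay on weight matrices only
        p.W *= (1.0 - lr * weight_decay);
        p.U *= (1.0 - lr * weight_decay);
        p.w_out *= (1.0 - lr * weight_decay);
      }
      { // vectors and scalar
        m_st.b = beta1 * m_st.b + (1 - beta1) * g.b;
        v_st.b = beta2 * v_st.b + (1 - beta2) * square(g.b);
        p.b -= lr * (m_st.b / bc1) / (sqrt(v_st.b / bc2) + eps);
        m_st.w_out = beta1 * m_st.w_out + (1 - beta1) * g.w_out;
        v_st.w_out = beta2 * v_st.w_out + (1 - beta2) * square(g.w_out);
        p.w_out -= lr * (m_st.w_out / bc1) / (sqrt(v_st.w_out / bc2) + eps);
        m_st.b_out = beta1 * m_st.b_out + (1 - beta1) * g.b_out;
        v_st.b_out = beta2 * v_st.b_out + (1 - beta2) * g.b_out * g.b_out;
        p.b_out -= lr * (m_st.b_out / bc1) /
          (std::sqrt(v_st.b_out / bc2) + eps);
      }
    }
    loss_hist.push_back(ep_loss / n_batches);
    if (n_val > 0) {
      double vl = val_loss(p);
      val_hist.push_back(vl);
      if (vl < best_val) { best_val = vl; best = p; }
    }
  }
  if (n_val == 0) best = p;
  return List::create(Rcpp::Named("weights") = pack_params(best),
                      Rcpp::Named("final_weights") = pack_params(p),
                      Rcpp::Named("loss") = loss_hist,
                      Rcpp::Named("val_loss") = val_hist);
}

// [[Rcpp::export]]
arma::vec lstm_forward_cpp(Rcpp::List weights, const arma::mat& X) {
  Params p = unpack_params(weights);
  const int H = p.w_out.n_elem;
  const int T = X.n_cols;
  vec h = zeros<vec>(H), c = zeros<vec>(H), out(T);
  for (int t = 0; t < T; ++t) {
    vec z = p.W * X.col(t) + p.U * h + p.b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    out(t) = dot(p.w_out, h) + p.b_out;
  }
  return out;
}

// Loss and analytic gradients for one batch of sequences (used by the
// finite-difference gradient checks).
// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(Rcpp::List weights, Rcpp::List x_list,
                         Rcpp::List y_list) {
  Params p = unpack_params(weights);
  int n_seq = x_list.size();
  std::vector<mat> Xs(n_seq);
  std::vector<vec> ys(n_seq);
  std::vector<int> idx(n_seq);
  for (int i = 0; i < n_seq; ++i) {
    Xs[i] = Rcpp::as<mat>(x_list[i]);
    ys[i] = Rcpp::as<vec>(y_list[i]);
    idx[i] = i;
  }
  cube X; mat Y, M;
  make_batch(Xs, ys, idx, X, Y, M);
  Grads g; g.zero(p);
  double loss = batch_loss_grad(p, X, Y, M, g, true);
  return List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = List::create(
      Rcpp::Named("W") = g.W, Rcpp::Named("U") = g.U,
      Rcpp::Named("b") = g.b, Rcpp::Named("w_out") = g.w_out,
      Rcpp::Named("b_out") = g.b_out));
}

// [[Rcpp::export]]
Rcpp::List lstm_init_cpp(int n_in, int hidden, int seed) {
  return pack_params(init_params(n_in, hidden, seed));
}
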