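// Single-layer LSTM sequence-to-sequence regressor with a linear output
// head (two outputs: HS and TO confidence), trained with MSE loss and
// Adam.  The training epoch loop lives here so that desk-scale training of
// the event-detection models completes in minutes on one CPU.  All
// randomness (weight init, minibatch shuffling) is drawn in R and passed
// in, so results are reproducible from the R-side seed alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Weights {
  mat Wx;  // 4H x 1
  mat Wh;  // 4H x H
  vec b;   // 4H
  mat Wy;  // 2 x H
  vec by;  // 2
};

Weights unpack(const Rcpp::List& w) {
  Weights out;
  out.Wx = Rcpp::as<mat>(w["Wx"]);
  out.Wh = Rcpp::as<mat>(w["Wh"]);
  out.b  = Rcpp::as<vec>(w["b"]);
  out.Wy = Rcpp::as<mat>(w["Wy"]);
  out.by = Rcpp::as<vec>(w["by"]);
  return out;
}

Rcpp::List pack(const Weights& w) {
  return Rcpp::List::create(Rcpp::Named("Wx") = w.Wx, Rcpp::Named("Wh") = w.Wh,
                            Rcpp::Named("b") = w.b, Rcpp::Named("Wy") = w.Wy,
                            Rcpp::Named("by") = w.by);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

}  // namespace

// Forward pass over a batch of equal-length sequences.
// x: T x B input matrix (one feature).  Returns list(hs = T x B, to = T x B).
// [[Rcpp::export(name = ".lstm_forward")]]
Rcpp::List lstm_forward(Rcpp::List weights, const arma::mat& x) {
  Weights w = unpack(weights);
  const uword H = w.Wh.n_cols, T = x.n_rows, B = x.n_cols;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  mat out_hs(T, B), out_to(T, B);
  for (uword t = 0; t < T; ++t) {
    mat z = w.Wx * x.row(t) + w.Wh * h;
    z.each_col() += w.b;
    mat i = sigmoid(z.rows(0, H - 1));
    mat f = sigmoid(z.rows(H, 2 * H - 1));
    mat g = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = sigmoid(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    mat y = w.Wy * h;
    y.each_col() += w.by;
    out_hs.row(t) = y.row(0);
    out_to.row(t) = y.row(1);
  }
  return Rcpp::List::create(Rcpp::Named("hs") = out_hs,
                            Rcpp::Named("to") = out_to);
}

// Train on one sequence (pre-chunked): x, y_hs, y_to are T x C matrices
// whose columns are the chunks.  `order` is an epochs x C matrix of
// 1-based chunk permutations drawn in R; chunks are taken `minibatch` at a
// time.  The learning rate within this call is
// lr0 * decay^floor(epoch / decay_every) (epoch 0-based).  Adam moments
// and step counter are received and returned so the caller controls
// whether they persist across increments.  Gradients are clipped to a
// global L2 norm of `clip` (0 disables).
// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train(Rcpp::List weights, const arma::mat& x,
                      const arma::mat& y_hs, const arma::mat& y_to,
                      const arma::imat& order, int minibatch,
                      double lr0, double decay, int decay_every,
                      Rcpp::List adam, double clip) {
  Weights w = unpack(weights);
  const uword H = w.Wh.n_cols, T = x.n_rows, C = x.n_cols;
  const int epochs = order.n_rows;
  if (y_hs.n_rows != T || y_to.n_rows != T || y_hs.n_cols != C || y_to.n_cols != C)
    Rcpp::stop("input/target chunk matrices must agree in shape");
  if (minibatch < 1) Rcpp::stop("minibatch must be >= 1");

  // Adam state: one moment pair per parameter block
  Weights m = unpack(adam["m"]), v = unpack(adam["v"]);
  int adam_t = Rcpp::as<int>(adam["t"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<double> epoch_loss(epochs);

  cube I(H, 0, 0), F(H, 0, 0), G(H, 0, 0), O(H, 0, 0), Cc(H, 0, 0), Hh(H, 0, 0);

  for (int e = 0; e < epochs; ++e) {
    double lr = lr0 * std::pow(decay, e / decay_every);
    double loss_sum = 0.0;
    uword n_batches = 0;
    for (uword start = 0; start < C; start += minibatch) {
      uword stop = std::min<uword>(start + minibatch, C) - 1;
      uword B = stop - start + 1;
      mat xb(T, B), yhb(T, B), ytb(T, B);
      for (uword j = 0; j < B; ++j) {
        uword col = static_cast<uword>(order(e, start + j)) - 1;
        xb.col(j) = x.col(col);
        yhb.col(j) = y_hs.col(col);
        ytb.col(j) = y_to.col(col);
      }

      // forward with caches
      I.set_size(H, B, T); F.set_size(H, B, T); G.set_size(H, B, T);
      O.set_size(H, B, T); Cc.set_size(H, B, T); Hh.set_size(H, B, T);
      mat h(H, B, fill::zeros), c(H, B, fill::zeros);
      mat err_hs(T, B), err_to(T, B);
      for (uword t = 0; t < T; ++t) {
        mat z = w.Wx * xb.row(t) + w.Wh * h;
        z.each_col() += w.b;
        mat ig = sigmoid(z.rows(0, H - 1));
        mat fg = sigmoid(z.rows(H, 2 * H - 1));
        mat gg = tanh(z.rows(2 * H, 3 * H - 1));
        mat og = sigmoid(z.rows(3 * H, 4 * H - 1));
        c = fg % c + ig % gg;
        h = og % tanh(c);
        I.slice(t) = ig; F.slice(t) = fg; G.slice(t) = gg; O.slice(t) = og;
        Cc.slice(t) = c; Hh.slice(t) = h;
        mat y = w.Wy * h;
        y.each_col() += w.by;
        err_hs.row(t) = y.row(0) - yhb.row(t);
        err_to.row(t) = y.row(1) - ytb.row(t);
      }
      double loss = (accu(square(err_hs)) + accu(square(err_to))) /
                    (2.0 * T * B);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
      loss_sum += loss;
      ++n_batches;

      // backward (BPTT)
      Weights g{mat(size(w.Wx), fill::zeros), mat(size(w.Wh), fill::zeros),
                vec(size(w.b), fill::zeros), mat(size(w.Wy), fill::zeros),
                vec(size(w.by), fill::zeros)};
      mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
      const double scale = 1.0 / (static_cast<double>(T) * B);
      for (uword t = T; t-- > 0;) {
        mat dy(2, B);
        dy.row(0) = err_hs.row(t) * scale;
        dy.row(1) = err_to.row(t) * scale;
        g.Wy += dy * Hh.slice(t).t();
        g.by += sum(dy, 1);
        mat dh = w.Wy.t() * dy + dh_next;
        const mat& ct = Cc.slice(t);
        mat tc = tanh(ct);
        const mat& ig = I.slice(t); const mat& fg = F.slice(t);
        const mat& gg = G.slice(t); const mat& og = O.slice(t);
        mat dzo = dh % tc % og % (1.0 - og);
        mat dc = dh % og % (1.0 - square(tc)) + dc_next;
        mat dzi = dc % gg % ig % (1.0 - ig);
        mat dzg = dc % ig % (1.0 - square(gg));
        mat c_prev = (t > 0) ? Cc.slice(t - 1) : mat(H, B, fill::zeros);
        mat dzf = dc % c_prev % fg % (1.0 - fg);
        dc_next = dc % fg;
        mat dz = join_cols(dzi, dzf, dzg, dzo);  // 4H x B
        g.Wx += dz * xb.row(t).t();
        mat h_prev = (t > 0) ? Hh.slice(t - 1) : mat(H, B, fill::zeros);
        g.Wh += dz * h_prev.t();
        g.b += sum(dz, 1);
        dh_next = w.Wh.t() * dz;
      }

      if (clip > 0) {
        double nrm = std::sqrt(accu(square(g.Wx)) + accu(square(g.Wh)) +
                               accu(square(g.b)) + accu(square(g.Wy)) +
                               accu(square(g.by)));
        if (nrm > clip) {
          double s = clip / nrm;
          g.Wx *= s; g.Wh *= s; g.b *= s; g.Wy *= s; g.by *= s;
        }
      }

      // Adam update
      ++adam_t;
      double bc1 = 1.0 - std::pow(b1, adam_t), bc2 = 1.0 - std::pow(b2, adam_t);
      auto upd = [&](mat& th, mat& mm, mat& vv, const mat& gr) {
        mm = b1 * mm + (1.0 - b1) * gr;
        vv = b2 * vv + (1.0 - b2) * square(gr);
        th -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
      };
      auto updv = [&](vec& th, vec& mm, vec& vv, const vec& gr) {
        mm = b1 * mm + (1.0 - b1) * gr;
        vv = b2 * vv + (1.0 - b2) * square(gr);
        th -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
      };
      upd(w.Wx, m.Wx, v.Wx, g.Wx);
      upd(w.Wh, m.Wh, v.Wh, g.Wh);
      updv(w.b, m.b, v.b, g.b);
      upd(w.Wy, m.Wy, v.Wy, g.Wy);
      updv(w.by, m.by, v.by, g.by);
    }
    epoch_loss[e] = loss_sum / n_batches;
    if (e % 20 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = pack(w),
      Rcpp::Named("adam") = Rcpp::List::create(
          Rcpp::Named("m") = pack(m), Rcpp::Named("v") = pack(v),
          Rcpp::Named("t") = adam_t),
      Rcpp::Named("loss") = epoch_loss);
}
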