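// Minimal LSTM stack with backpropagation through time.
//
// Layer spec (from R): list(type = "lstm"|"dense", units, activation
// ("relu"|"linear", dense only), dropout (prob, applied to the layer
// output during training), append (number of auxiliary input rows,
// taken from the tail of the input tensor, concatenated to this layer's
// input — lets side channels such as the gait phase and current angle
// bypass the feature-extractor stage).
//
// Sequence tensors are cubes of dimension (features, batch, time); the
// first layer consumes the leading rows not claimed by any append; the
// loss is evaluated at the last timestep only (many-to-one).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LayerDef {
  bool lstm;
  int units;
  bool relu;
  double dropout;
  int append;
};

static std::vector<LayerDef> parse_layers(const List& layers) {
  std::vector<LayerDef> defs;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerDef d;
    std::string type = as<std::string>(l["type"]);
    d.lstm = (type == "lstm");
    d.units = as<int>(l["units"]);
    d.relu = false;
    if (!d.lstm && l.containsElementNamed("activation"))
      d.relu = (as<std::string>(l["activation"]) == "relu");
    d.dropout = l.containsElementNamed("dropout") ?
      as<double>(l["dropout"]) : 0.0;
    d.append = l.containsElementNamed("append") ?
      as<int>(l["append"]) : 0;
    defs.push_back(d);
  }
  return defs;
}

// [[Rcpp::export]]
List nn_init(List layers, int input_dim, int seed) {
  std::vector<LayerDef> defs = parse_layers(layers);
  std::mt19937 rng(seed);
  List out(defs.size());
  int total_append = 0;
  for (auto& d : defs) total_append += d.append;
  int d_in = input_dim - total_append;
  for (size_t i = 0; i < defs.size(); ++i) {
    int H = defs[i].units;
    d_in += defs[i].append;
    if (defs[i].lstm) {
      double kx = 1.0 / std::sqrt((double)d_in);
      double kh = 1.0 / std::sqrt((double)H);
      std::uniform_real_distribution<double> ux(-kx, kx), uh(-kh, kh);
      mat Wx(4 * H, d_in), Wh(4 * H, H);
      for (auto& v : Wx) v = ux(rng);
      for (auto& v : Wh) v = uh(rng);
      vec b(4 * H, arma::fill::zeros);
      b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias
      out[i] = List::create(_["Wx"] = Wx, _["Wh"] = Wh, _["b"] = b);
    } else {
      double k = 1.0 / std::sqrt((double)d_in);
      std::uniform_real_distribution<double> uw(-k, k);
      mat W(H, d_in);
      for (auto& v : W) v = uw(rng);
      vec b(H, arma::fill::zeros);
      out[i] = List::create(_["W"] = W, _["b"] = b);
    }
    d_in = H;
  }
  return out;
}

struct LstmCache {
  cube i, f, o, g, c, h;  // H x B x T each
};

struct NetState {
  std::vector<LayerDef> defs;
  // weights per layer: lstm -> Wx, Wh, b ; dense -> W, b
  std::vector<mat> Wx, Wh, W;
  std::vector<vec> b;
};

static NetState unpack(const List& layers, const List& weights) {
  NetState s;
  s.defs = parse_layers(layers);
  size_t n = s.defs.size();
  s.Wx.resize(n); s.Wh.resize(n); s.W.resize(n); s.b.resize(n);
  for (size_t i = 0; i < n; ++i) {
    List w = weights[i];
    if (s.defs[i].lstm) {
      s.Wx[i] = as<mat>(w["Wx"]);
      s.Wh[i] = as<mat>(w["Wh"]);
      s.b[i] = as<vec>(w["b"]);
    } else {
      s.W[i] = as<mat>(w["W"]);
      s.b[i] = as<vec>(w["b"]);
    }
  }
  return s;
}

static List pack(const NetState& s) {
  List out(s.defs.size());
  for (size_t i = 0; i < s.defs.size(); ++i) {
    if (s.defs[i].lstm)
      out[i] = List::create(_["Wx"] = s.Wx[i], _["Wh"] = s.Wh[i],
                            _["b"] = s.b[i]);
    else
      out[i] = List::create(_["W"] = s.W[i], _["b"] = s.b[i]);
  }
  return out;
}

// Forward pass. If train, dropout masks are sampled and caches kept.
static cube forward(const NetState& s, const cube& X, bool train,
                    std::vector<LstmCache>& caches,
                    std::vector<cube>& inputs,
                    std::vector<cube>& masks,
                    std::mt19937& rng) {
  int T = X.n_slices, B = X.n_cols;
  int total_append = 0;
  for (auto& d : s.defs) total_append += d.append;
  int main_dim = X.n_rows - total_append;
  cube cur = X.rows(0, main_dim - 1);
  int aux_at = main_dim;
  caches.assign(s.defs.size(), LstmCache());
  inputs.assign(s.defs.size(), cube());
  masks.assign(s.defs.size(), cube());
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t li = 0; li < s.defs.size(); ++li) {
    const LayerDef& d = s.defs[li];
    if (d.append > 0) {
      cube joined(cur.n_rows + d.append, B, T);
      joined.rows(0, cur.n_rows - 1) = cur;
      joined.rows(cur.n_rows, joined.n_rows - 1) =
        X.rows(aux_at, aux_at + d.append - 1);
      aux_at += d.append;
      cur = joined;
    }
    if (train) inputs[li] = cur;
    int H = d.units;
    if (d.lstm) {
      LstmCache cc;
      cc.i.set_size(H, B, T); cc.f.set_size(H, B, T);
      cc.o.set_size(H, B, T); cc.g.set_size(H, B, T);
      cc.c.set_size(H, B, T); cc.h.set_size(H, B, T);
      mat h_prev(H, B, arma::fill::zeros), c_prev(H, B, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        mat a = s.Wx[li] * cur.slice(t) + s.Wh[li] * h_prev;
        a.each_col() += s.b[li];
        mat ig = sigm(a.rows(0, H - 1));
        mat fg = sigm(a.rows(H, 2 * H - 1));
        mat og = sigm(a.rows(2 * H, 3 * H - 1));
        mat gg = arma::tanh(a.rows(3 * H, 4 * H - 1));
        mat ct = fg % c_prev + ig % gg;
        mat ht = og % arma::tanh(ct);
        cc.i.slice(t) = ig; cc.f.slice(t) = fg;
        cc.o.slice(t) = og; cc.g.slice(t) = gg;
        cc.c.slice(t) = ct; cc.h.slice(t) = ht;
        h_prev = ht; c_prev = ct;
      }
      if (train) caches[li] = cc;
      cur = cc.h;
    } else {
      cube out(H, B, T);
      for (int t = 0; t < T; ++t) {
        mat z = s.W[li] * cur.slice(t);
        z.each_col() += s.b[li];
        if (d.relu) z = arma::clamp(z, 0.0, arma::datum::inf);
        out.slice(t) = z;
      }
      cur = out;
    }
    if (train && d.dropout > 0.0) {
      cube msk(H, B, T);
      for (auto& v : msk)
        v = (unif(rng) < d.dropout) ? 0.0 : 1.0 / (1.0 - d.dropout);
      masks[li] = msk;
      cur %= msk;
    }
  }
  return cur;
}

struct Grads {
  std::vector<mat> Wx, Wh, W;
  std::vector<vec> b;
};

static void backward(const NetState& s, const cube& dTop,
                     const std::vector<LstmCache>& caches,
                     const std::vector<cube>& inputs,
                     const std::vector<cube>& masks,
                     const std::vector<cube>& outputs_dropped,
                     Grads& g) {
  int T = dTop.n_slices;
  size_t n = s.defs.size();
  g.Wx.assign(n, mat()); g.Wh.assign(n, mat());
  g.W.assign(n, mat()); g.b.assign(n, vec());
  cube dCur = dTop;
  for (int li = (int)n - 1; li >= 0; --li) {
    const LayerDef& d = s.defs[li];
    if (d.dropout > 0.0) dCur %= masks[li];
    const cube& xin = inputs[li];
    if (d.lstm) {
      const LstmCache& cc = caches[li];
      int H = d.units, B = dCur.n_cols;
      mat dWx(s.Wx[li].n_rows, s.Wx[li].n_cols, arma::fill::zeros);
      mat dWh(s.Wh[li].n_rows, s.Wh[li].n_cols, arma::fill::zeros);
      vec db(4 * H, arma::fill::zeros);
      cube dX(xin.n_rows, B, T);
      mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        mat dh = dCur.slice(t) + dh_next;
        mat tc = arma::tanh(cc.c.slice(t));
        mat do_ = dh % tc;
        mat dc = dc_next + dh % cc.o.slice(t) % (1.0 - tc % tc);
        mat c_prev = (t > 0) ? cc.c.slice(t - 1)
                             : mat(H, B, arma::fill::zeros);
        mat di = dc % cc.g.slice(t);
        mat df = dc % c_prev;
        mat dg = dc % cc.i.slice(t);
        dc_next = dc % cc.f.slice(t);
        mat dai = di % cc.i.slice(t) % (1.0 - cc.i.slice(t));
        mat daf = df % cc.f.slice(t) % (1.0 - cc.f.slice(t));
        mat dao = do_ % cc.o.slice(t) % (1.0 - cc.o.slice(t));
        mat dag = dg % (1.0 - cc.g.slice(t) % cc.g.slice(t));
        mat da = arma::join_cols(arma::join_cols(dai, daf),
                                 arma::join_cols(dao, dag));
        mat h_prev = (t > 0) ? cc.h.slice(t - 1)
                             : mat(H, B, arma::fill::zeros);
        dWx += da * xin.slice(t).t();
        dWh += da * h_prev.t();
        db += arma::sum(da, 1);
        dX.slice(t) = s.Wx[li].t() * da;
        dh_next = s.Wh[li].t() * da;
      }
      g.Wx[li] = dWx; g.Wh[li] = dWh; g.b[li] = db;
      if (d.append > 0) {
        cube stripped = dX.rows(0, dX.n_rows - d.append - 1);
        dCur = stripped;
      } else {
        dCur = dX;
      }
    } else {
      int B = dCur.n_cols;
      mat dW(s.W[li].n_rows, s.W[li].n_cols, arma::fill::zeros);
      vec db(d.units, arma::fill::zeros);
      cube dX(xin.n_rows, B, T);
      for (int t = 0; t < T; ++t) {
        mat dz = dCur.slice(t);
        if (d.relu) {
          // the layer's own output rows (the next layer's input may carry
          // appended auxiliary rows) hold the relu mask
          mat outs = outputs_dropped[li].slice(t).rows(0, d.units - 1);
          dz %= arma::conv_to<mat>::from(outs > 0.0);
        }
        dW += dz * xin.slice(t).t();
        db += arma::sum(dz, 1);
        dX.slice(t) = s.W[li].t() * dz;
      }
      g.W[li] = dW; g.b[li] = db;
      if (d.append > 0) {
        cube stripped = dX.rows(0, dX.n_rows - d.append - 1);
        dCur = stripped;
      } else {
        dCur = dX;
      }
    }
  }
}

// Loss head at the last timestep. Fills dOut; returns the loss.
static double loss_head(const mat& out, const mat& Y, bool softmax,
                        mat& dOut) {
  int B = out.n_cols;
  if (softmax) {
    mat z = out;
    arma::rowvec mx = arma::max(z, 0);
    z.each_row() -= mx;
    mat e = arma::exp(z);
    arma::rowvec sums = arma::sum(e, 0);
    mat P = e;
    P.each_row() /= sums;
    dOut = (P - Y) / (double)B;
    double loss = -arma::accu(Y % arma::log(P + 1e-12)) / (double)B;
    return loss;
  }
  mat diff = out - Y;
  dOut = 2.0 * diff / (double)(B * out.n_rows);
  return arma::accu(diff % diff) / (double)(B * out.n_rows);
}

// [[Rcpp::export]]
List nn_train_cpp(List layers, List weights, const arma::cube& X,
                  const arma::mat& Y, std::string loss, List opts) {
  NetState s = unpack(layers, weights);
  bool softmax = (loss == "softmax");
  int epochs = as<int>(opts["epochs"]);
  int batch = as<int>(opts["batch"]);
  double lr = as<double>(opts["lr"]);
  int seed = as<int>(opts["seed"]);
  int patience = opts.containsElementNamed("patience") ?
    as<int>(opts["patience"]) : 0;
  double wd = opts.containsElementNamed("weight_decay") ?
    as<double>(opts["weight_decay"]) : 0.0;
  double val_frac = opts.containsElementNamed("val_frac") ?
    as<double>(opts["val_frac"]) : 0.0;
  double clip = 5.0;
  std::mt19937 rng(seed);

  // validation split is the time-ordered tail: sequences are handed over
  // in temporal order, and a randomly interleaved split would correlate
  // with the training set and mask temporal overfitting
  int N = X.n_cols;
  int n_val = (patience > 0 && val_frac > 0.0) ?
    (int)std::floor(val_frac * N) : 0;
  if (n_val < 2) n_val = 0;
  std::vector<int> val_idx, tr_idx;
  for (int i = 0; i < N - n_val; ++i) tr_idx.push_back(i);
  for (int i = N - n_val; i < N; ++i) val_idx.push_back(i);
  int Ntr = tr_idx.size();

  // Adam state
  size_t nl = s.defs.size();
  std::vector<mat> mWx(nl), vWx(nl), mWh(nl), vWh(nl), mW(nl), vW(nl);
  std::vector<vec> mb(nl), vb(nl);
  for (size_t i = 0; i < nl; ++i) {
    if (s.defs[i].lstm) {
      mWx[i] = arma::zeros<mat>(arma::size(s.Wx[i])); vWx[i] = mWx[i];
      mWh[i] = arma::zeros<mat>(arma::size(s.Wh[i])); vWh[i] = mWh[i];
      mb[i] = arma::zeros<vec>(s.b[i].n_elem); vb[i] = mb[i];
    } else {
      mW[i] = arma::zeros<mat>(arma::size(s.W[i])); vW[i] = mW[i];
      mb[i] = arma::zeros<vec>(s.b[i].n_elem); vb[i] = mb[i];
    }
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<double> hist, val_hist;
  double best_val = arma::datum::inf;
  int bad = 0;
  List best_weights = pack(s);

  std::vector<LstmCache> caches;
  std::vector<cube> inputs, masks, outdrops;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int b0 = 0; b0 < Ntr; b0 += batch) {
      int b1i = std::min(b0 + batch, Ntr);
      int B = b1i - b0;
      arma::uvec idx(B);
      for (int k = 0; k < B; ++k) idx[k] = tr_idx[b0 + k];
      cube Xb(X.n_rows, B, X.n_slices);
      for (arma::uword t = 0; t < X.n_slices; ++t)
        Xb.slice(t) = X.slice(t).cols(idx);
      mat Yb = Y.cols(idx);

      cube out = forward(s, Xb, true, caches, inputs, masks, rng);
      // keep per-layer outputs (post-relu, pre-dropout-dividing kept via
      // masks) for relu masks: recompute from inputs of next layer is
      // awkward; store outputs by re-deriving: the input of layer li+1 is
      // the (dropped) output of layer li.
      outdrops.assign(s.defs.size(), cube());
      for (size_t li = 0; li + 1 < s.defs.size(); ++li)
        outdrops[li] = inputs[li + 1];
      outdrops[s.defs.size() - 1] = out;

      mat dOut;
      double l = loss_head(out.slice(out.n_slices - 1), Yb, softmax, dOut);
      ep_loss += l; ++n_batches;
      cube dTop(out.n_rows, B, out.n_slices, arma::fill::zeros);
      dTop.slice(out.n_slices - 1) = dOut;

      Grads g;
      backward(s, dTop, caches, inputs, masks, outdrops, g);

      // global-norm clip
      double nrm2 = 0.0;
      for (size_t i = 0; i < nl; ++i) {
        if (s.defs[i].lstm) {
          nrm2 += arma::accu(g.Wx[i] % g.Wx[i]) +
                  arma::accu(g.Wh[i] % g.Wh[i]);
        } else {
          nrm2 += arma::accu(g.W[i] % g.W[i]);
        }
        nrm2 += arma::accu(g.b[i] % g.b[i]);
      }
      double scale = 1.0;
      double nrm = std::sqrt(nrm2);
      if (nrm > clip) scale = clip / nrm;

      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
        (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < nl; ++i) {
        if (s.defs[i].lstm) {
          mat gx = g.Wx[i] * scale, gh = g.Wh[i] * scale;
          mWx[i] = b1 * mWx[i] + (1 - b1) * gx;
          vWx[i] = b2 * vWx[i] + (1 - b2) * (gx % gx);
          s.Wx[i] -= corr * mWx[i] / (arma::sqrt(vWx[i]) + eps) +
            lr * wd * s.Wx[i];
          mWh[i] = b1 * mWh[i] + (1 - b1) * gh;
          vWh[i] = b2 * vWh[i] + (1 - b2) * (gh % gh);
          s.Wh[i] -= corr * mWh[i] / (arma::sqrt(vWh[i]) + eps) +
            lr * wd * s.Wh[i];
        } else {
          mat gw = g.W[i] * scale;
          mW[i] = b1 * mW[i] + (1 - b1) * gw;
          vW[i] = b2 * vW[i] + (1 - b2) * (gw % gw);
          s.W[i] -= corr * mW[i] / (arma::sqrt(vW[i]) + eps) +
            lr * wd * s.W[i];
        }
        vec gb = g.b[i] * scale;
        mb[i] = b1 * mb[i] + (1 - b1) * gb;
        vb[i] = b2 * vb[i] + (1 - b2) * (gb % gb);
        s.b[i] -= corr * mb[i] / (arma::sqrt(vb[i]) + eps);
      }
    }
    hist.push_back(ep_loss / std::max(n_batches, 1));

    if (n_val > 0) {
      arma::uvec idx(n_val);
      for (int k = 0; k < n_val; ++k) idx[k] = val_idx[k];
      cube Xv(X.n_rows, n_val, X.n_slices);
      for (arma::uword t = 0; t < X.n_slices; ++t)
        Xv.slice(t) = X.slice(t).cols(idx);
      mat Yv = Y.cols(idx);
      std::vector<LstmCache> c2; std::vector<cube> i2, m2;
      cube outv = forward(s, Xv, false, c2, i2, m2, rng);
      mat dummy;
      double vl = loss_head(outv.slice(outv.n_slices - 1), Yv, softmax,
                            dummy);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-6) {
        best_val = vl; bad = 0;
        best_weights = pack(s);
      } else if (++bad >= patience) {
        return List::create(_["weights"] = best_weights,
                            _["history"] = hist,
                            _["val_history"] = val_hist,
                            _["stopped_epoch"] = ep + 1);
      }
    }
  }
  List w = (n_val > 0) ? best_weights : pack(s);
  return List::create(_["weights"] = w, _["history"] = hist,
                      _["val_history"] = val_hist,
                      _["stopped_epoch"] = epochs);
}

// Loss and analytic gradients for one batch (no dropout); used to verify
// the backward pass against finite differences.
// [[Rcpp::export]]
List nn_loss_grad_cpp(List layers, List weights, const arma::cube& X,
                      const arma::mat& Y, std::string loss) {
  NetState s = unpack(layers, weights);
  bool softmax = (loss == "softmax");
  std::mt19937 rng(0);
  std::vector<LstmCache> caches;
  std::vector<cube> inputs, masks, outdrops;
  cube out = forward(s, X, true, caches, inputs, masks, rng);
  outdrops.assign(s.defs.size(), cube());
  for (size_t li = 0; li + 1 < s.defs.size(); ++li)
    outdrops[li] = inputs[li + 1];
  outdrops[s.defs.size() - 1] = out;
  mat dOut;
  double l = loss_head(out.slice(out.n_slices - 1), Y, softmax, dOut);
  cube dTop(out.n_rows, out.n_cols, out.n_slices, arma::fill::zeros);
  dTop.slice(out.n_slices - 1) = dOut;
  Grads g;
  backward(s, dTop, caches, inputs, masks, outdrops, g);
  List gl(s.defs.size());
  for (size_t i = 0; i < s.defs.size(); ++i) {
    if (s.defs[i].lstm)
      gl[i] = List::create(_["Wx"] = g.Wx[i], _["Wh"] = g.Wh[i],
                           _["b"] = g.b[i]);
    else
      gl[i] = List::create(_["W"] = g.W[i], _["b"] = g.b[i]);
  }
  return List::create(_["loss"] = l, _["grads"] = gl);
}

// [[Rcpp::export]]
arma::mat nn_forward_cpp(List layers, List weights, const arma::cube& X) {
  NetState s = unpack(layers, weights);
  std::mt19937 rng(0);
  std::vector<LstmCache> caches;
  std::vector<cube> inputs, masks;
  cube out = forward(s, X, false, caches, inputs, masks, rng);
  return out.slice(out.n_slices - 1);
}
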