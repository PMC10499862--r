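// Encoder -> (bidirectional) LSTM -> decoder regressor for per-residue
// B-factor prediction. Parameters live in one flat vector; the packing
// order is defined solely by net_shapes() below and mirrored nowhere else.
//
// Packing order:
//   encoder layer l:        W (out x in), b (out)
//   lstm layer l, dir d:    W (4H x in_l), U (4H x H), b (4H)
//                           gate row blocks ordered [input; forget; cell; output]
//                           dir order: forward, then backward when bidirectional
//   decoder layer l:        W (out x in), b (out)   (last layer linear, out = 1)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Cfg {
  int D;                      // input feature width
  std::vector<int> enc;       // encoder layer widths (possibly empty)
  bool use_lstm;
  int H, L;                   // lstm hidden size, layer count
  bool bidir;
  std::vector<int> dec;       // decoder widths, last must be 1
  int act;                    // 0 = tanh, 1 = relu
};

static Cfg parse_cfg(const Rcpp::List& c) {
  Cfg g;
  g.D = Rcpp::as<int>(c["input_dim"]);
  g.enc = Rcpp::as<std::vector<int>>(c["encoder_widths"]);
  g.use_lstm = Rcpp::as<bool>(c["use_lstm"]);
  g.H = g.use_lstm ? Rcpp::as<int>(c["lstm_hidden"]) : 0;
  g.L = g.use_lstm ? Rcpp::as<int>(c["lstm_layers"]) : 0;
  g.bidir = Rcpp::as<bool>(c["bidirectional"]);
  g.dec = Rcpp::as<std::vector<int>>(c["decoder_widths"]);
  std::string a = Rcpp::as<std::string>(c["activation"]);
  g.act = (a == "relu") ? 1 : 0;
  if (g.dec.empty() || g.dec.back() != 1)
    Rcpp::stop("decoder_widths must end at width 1");
  return g;
}

static int enc_out_width(const Cfg& g) {
  return g.enc.empty() ? g.D : g.enc.back();
}
static int ndir(const Cfg& g) { return g.bidir ? 2 : 1; }
static int lstm_out_width(const Cfg& g) { return g.H * ndir(g); }
static int dec_in_width(const Cfg& g) {
  return g.use_lstm ? lstm_out_width(g) : enc_out_width(g);
}

struct Shape { int r, c; std::string kind; };

static std::vector<Shape> net_shapes(const Cfg& g) {
  std::vector<Shape> s;
  int in = g.D;
  for (int w : g.enc) {
    s.push_back({w, in, "enc_w"});
    s.push_back({w, 1, "enc_b"});
    in = w;
  }
  if (g.use_lstm) {
    int lin = enc_out_width(g);
    for (int l = 0; l < g.L; ++l) {
      for (int d = 0; d < ndir(g); ++d) {
        s.push_back({4 * g.H, lin, "lstm_w"});
        s.push_back({4 * g.H, g.H, "lstm_u"});
        s.push_back({4 * g.H, 1, "lstm_b"});
      }
      lin = lstm_out_width(g);
    }
  }
  in = dec_in_width(g);
  for (int w : g.dec) {
    s.push_back({w, in, "dec_w"});
    s.push_back({w, 1, "dec_b"});
    in = w;
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::List nn_shapes_cpp(Rcpp::List cfg) {
  Cfg g = parse_cfg(cfg);
  std::vector<Shape> s = net_shapes(g);
  Rcpp::List out(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    out[i] = Rcpp::List::create(Rcpp::Named("rows") = s[i].r,
                                Rcpp::Named("cols") = s[i].c,
                                Rcpp::Named("kind") = s[i].kind);
  return out;
}

struct Net {
  std::vector<mat> encW; std::vector<vec> encb;
  std::vector<std::vector<mat>> W, U;    // [layer][dir]
  std::vector<std::vector<vec>> b;
  std::vector<mat> decW; std::vector<vec> decb;
};

static Net unpack(const vec& par, const Cfg& g, bool zeros = false) {
  Net n;
  std::vector<Shape> s = net_shapes(g);
  size_t off = 0, k = 0;
  auto take_mat = [&](int r, int c) {
    mat m = zeros ? mat(r, c, fill::zeros)
                  : mat(par.memptr() + off, r, c);  // column-major copy
    off += (size_t)r * c;
    return m;
  };
  for (size_t i = 0; i < g.enc.size(); ++i) {
    n.encW.push_back(take_mat(s[k].r, s[k].c)); ++k;
    n.encb.push_back(vec(take_mat(s[k].r, 1))); ++k;
  }
  if (g.use_lstm) {
    n.W.resize(g.L); n.U.resize(g.L); n.b.resize(g.L);
    for (int l = 0; l < g.L; ++l)
      for (int d = 0; d < ndir(g); ++d) {
        n.W[l].push_back(take_mat(s[k].r, s[k].c)); ++k;
        n.U[l].push_back(take_mat(s[k].r, s[k].c)); ++k;
        n.b[l].push_back(vec(take_mat(s[k].r, 1))); ++k;
      }
  }
  for (size_t i = 0; i < g.dec.size(); ++i) {
    n.decW.push_back(take_mat(s[k].r, s[k].c)); ++k;
    n.decb.push_back(vec(take_mat(s[k].r, 1))); ++k;
  }
  if (!zeros && off != par.n_elem)
    Rcpp::stop("parameter vector length does not match the configuration");
  return n;
}

static size_t n_params(const Cfg& g) {
  size_t n = 0;
  for (const Shape& s : net_shapes(g)) n += (size_t)s.r * s.c;
  return n;
}

static vec pack(const Net& n, const Cfg& g) {
  vec out(n_params(g));
  size_t off = 0;
  auto put = [&](const mat& m) {
    std::copy(m.memptr(), m.memptr() + m.n_elem, out.memptr() + off);
    off += m.n_elem;
  };
  for (size_t i = 0; i < n.encW.size(); ++i) { put(n.encW[i]); put(n.encb[i]); }
  for (size_t l = 0; l < n.W.size(); ++l)
    for (size_t d = 0; d < n.W[l].size(); ++d) {
      put(n.W[l][d]); put(n.U[l][d]); put(n.b[l][d]);
    }
  for (size_t i = 0; i < n.decW.size(); ++i) { put(n.decW[i]); put(n.decb[i]); }
  return out;
}

static mat act_fwd(const mat& z, int act) {
  if (act == 1) return clamp(z, 0.0, datum::inf);
  return tanh(z);
}
// derivative expressed through the activation value a
static mat act_bwd(const mat& a, int act) {
  if (act == 1) return conv_to<mat>::from(a > 0);
  return 1.0 - square(a);
}

static vec sigm(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

// ---------------------------------------------------------------- forward

struct LstmCache {
  mat In;                 // layer input, N x F
  mat I, F, G, O, C, Ct, Hs;  // per-position gate/cell values, N x H
};

struct Caches {
  std::vector<mat> encA;                 // encA[0] = X, then activations
  std::vector<std::vector<LstmCache>> lstm;  // [layer][dir]
  std::vector<mat> decA;                 // decA[0] = dec input
};

static void lstm_dir_forward(const mat& In, const mat& W, const mat& U,
                             const vec& b, int H, bool backward_dir,
                             LstmCache& cc) {
  int N = In.n_rows;
  cc.In = In;
  cc.I.set_size(N, H); cc.F.set_size(N, H); cc.G.set_size(N, H);
  cc.O.set_size(N, H); cc.C.set_size(N, H); cc.Ct.set_size(N, H);
  cc.Hs.set_size(N, H);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int s = 0; s < N; ++s) {
    int t = backward_dir ? (N - 1 - s) : s;
    vec a4 = W * In.row(t).t() + U * h + b;
    vec i = sigm(a4.rows(0, H - 1));
    vec f = sigm(a4.rows(H, 2 * H - 1));
    vec g = tanh(a4.rows(2 * H, 3 * H - 1));
    vec o = sigm(a4.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    vec ct = tanh(c);
    h = o % ct;
    cc.I.row(t) = i.t(); cc.F.row(t) = f.t(); cc.G.row(t) = g.t();
    cc.O.row(t) = o.t(); cc.C.row(t) = c.t(); cc.Ct.row(t) = ct.t();
    cc.Hs.row(t) = h.t();
  }
}

static vec forward_full(const Net& n, const Cfg& g, const mat& X, Caches* cc) {
  mat A = X;
  if (cc) cc->encA.push_back(A);
  for (size_t l = 0; l < n.encW.size(); ++l) {
    A = act_fwd(A * n.encW[l].t() + repmat(n.encb[l].t(), A.n_rows, 1), g.act);
    if (cc) cc->encA.push_back(A);
  }
  if (g.use_lstm) {
    if (cc) cc->lstm.resize(g.L);
    for (int l = 0; l < g.L; ++l) {
      std::vector<LstmCache> local(ndir(g));
      for (int d = 0; d < ndir(g); ++d)
        lstm_dir_forward(A, n.W[l][d], n.U[l][d], n.b[l][d], g.H, d == 1,
                         local[d]);
      A = g.bidir ? join_rows(local[0].Hs, local[1].Hs) : local[0].Hs;
      if (cc) cc->lstm[l] = std::move(local);
    }
  }
  if (cc) cc->decA.push_back(A);
  for (size_t l = 0; l < n.decW.size(); ++l) {
    mat Z = A * n.decW[l].t() + repmat(n.decb[l].t(), A.n_rows, 1);
    A = (l + 1 == n.decW.size()) ? Z : act_fwd(Z, g.act);
    if (cc) cc->decA.push_back(A);
  }
  return vec(A.col(0));
}

// ---------------------------------------------------------------- backward

static mat lstm_dir_backward(const LstmCache& cc, const mat& W, const mat& U,
                             int H, bool backward_dir, const mat& dH,
                             mat& gW, mat& gU, vec& gb) {
  int N = cc.In.n_rows;
  mat dIn(N, cc.In.n_cols, fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int s = N - 1; s >= 0; --s) {
    int t = backward_dir ? (N - 1 - s) : s;
    int tprev = backward_dir ? (t + 1) : (t - 1);
    vec i = cc.I.row(t).t(), f = cc.F.row(t).t(), gg = cc.G.row(t).t(),
        o = cc.O.row(t).t(), ct = cc.Ct.row(t).t();
    vec cprev = (s > 0) ? vec(cc.C.row(tprev).t()) : vec(H, fill::zeros);
    vec hprev = (s > 0) ? vec(cc.Hs.row(tprev).t()) : vec(H, fill::zeros);
    vec dh = dH.row(t).t() + dh_next;
    vec do_ = dh % ct;
    vec dc = dh % o % (1.0 - ct % ct) + dc_next;
    vec dai = (dc % gg) % i % (1.0 - i);
    vec daf = (dc % cprev) % f % (1.0 - f);
    vec dag = (dc % i) % (1.0 - gg % gg);
    vec dao = do_ % o % (1.0 - o);
    vec da = join_cols(join_cols(dai, daf), join_cols(dag, dao));
    gW += da * cc.In.row(t);
    gU += da * hprev.t();
    gb += da;
    dIn.row(t) += (W.t() * da).t();
    dh_next = U.t() * da;
    dc_next = dc % f;
  }
  return dIn;
}

static void backward_full(const Net& n, const Cfg& g, const Caches& cc,
                          const vec& dpred, Net& grad) {
  // decoder
  size_t nd = n.decW.size();
  mat dA = mat(dpred);
  for (size_t l = nd; l-- > 0;) {
    mat dZ = (l + 1 == nd) ? dA : dA % act_bwd(cc.decA[l + 1], g.act);
    grad.decW[l] += dZ.t() * cc.decA[l];
    grad.decb[l] += sum(dZ, 0).t();
    dA = dZ * n.decW[l];
  }
  // lstm stack
  if (g.use_lstm) {
    for (int l = g.L; l-- > 0;) {
      mat dIn;
      for (int d = 0; d < ndir(g); ++d) {
        mat dH = g.bidir
                     ? mat(dA.cols(d * g.H, (d + 1) * g.H - 1))
                     : dA;
        mat dd = lstm_dir_backward(cc.lstm[l][d], n.W[l][d], n.U[l][d], g.H,
                                   d == 1, dH, grad.W[l][d], grad.U[l][d],
                                   grad.b[l][d]);
        if (d == 0) dIn = dd; else dIn += dd;
      }
      dA = dIn;
    }
  }
  // encoder
  for (size_t l = n.encW.size(); l-- > 0;) {
    mat dZ = dA % act_bwd(cc.encA[l + 1], g.act);
    grad.encW[l] += dZ.t() * cc.encA[l];
    grad.encb[l] += sum(dZ, 0).t();
    dA = dZ * n.encW[l];
  }
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
arma::vec nn_forward_cpp(const arma::vec& par, Rcpp::List cfg,
                         const arma::mat& X) {
  Cfg g = parse_cfg(cfg);
  if ((int)X.n_cols != g.D) Rcpp::stop("feature matrix width mismatch");
  Net n = unpack(par, g);
  return forward_full(n, g, X, nullptr);
}

// Mean over proteins of the per-protein mean squared error, plus its
// gradient with respect to the flat parameter vector.
// [[Rcpp::export]]
Rcpp::List nn_loss_grad_cpp(const arma::vec& par, Rcpp::List cfg,
                            Rcpp::List X_list, Rcpp::List y_list) {
  Cfg g = parse_cfg(cfg);
  Net n = unpack(par, g);
  Net grad = unpack(par, g, true);
  int B = X_list.size();
  if (B == 0) Rcpp::stop("empty batch");
  double loss = 0.0;
  for (int p = 0; p < B; ++p) {
    mat X = Rcpp::as<mat>(X_list[p]);
    vec y = Rcpp::as<vec>(y_list[p]);
    if ((int)X.n_cols != g.D) Rcpp::stop("feature matrix width mismatch");
    if (X.n_rows != y.n_elem) Rcpp::stop("target length mismatch");
    Caches cc;
    vec pred = forward_full(n, g, X, &cc);
    vec r = pred - y;
    double N = (double)r.n_elem;
    loss += dot(r, r) / N;
    vec dpred = (2.0 / (N * B)) * r;
    backward_full(n, g, cc, dpred, grad);
  }
  loss /= B;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = pack(grad, g));
}
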