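// Point-set regression network: shared per-point MLP stack with batch
// normalization, channel-wise max pooling to a global feature vector, a
// dense head, and an optional input transform sub-network (T-Net) that
// predicts a 3x3 linear alignment of the input points. Forward, backward
// and the Adam training loop live here; all workspaces are allocated once
// per call and reused across batches, so the steady-state cost is the BLAS
// matrix products. All randomness (shuffling, jitter) is drawn from R's RNG
// so a single R-side seed makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;
using arma::uword;

static const double BN_EPS = 1e-5;

struct AdamOpt {
  double lr, b1, b2, eps;
  long t = 0;
};

struct Dense {
  mat W;
  vec b;
  bool has_b = false;
  mat gW, mW, vW;
  vec gb, mb, vb;
  void prep() {
    gW.zeros(arma::size(W)); mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    if (has_b) {
      gb.zeros(b.n_elem); mb.zeros(b.n_elem); vb.zeros(b.n_elem);
    }
  }
};

struct BNorm {
  rowvec gam, bet, rmean, rvar;
  rowvec mu, istd;                  // cached by the training-mode forward
  rowvec ggam, gbet, m_g, v_g, m_b, v_b;
  void prep() {
    uword c = gam.n_elem;
    mu.zeros(c); istd.zeros(c);
    ggam.zeros(c); gbet.zeros(c);
    m_g.zeros(c); v_g.zeros(c); m_b.zeros(c); v_b.zeros(c);
  }
};

struct Block {  // dense (no bias) -> batch norm -> ReLU
  Dense d;
  BNorm bn;
};

// ---------------------------------------------------------------------------

static void block_fwd(Block& bl, const mat& X, mat& S, mat& A, bool train,
                      double mom) {
  S = X * bl.d.W;  // gemm straight into the preallocated view
  const uword m = S.n_rows, C = S.n_cols;
  for (uword j = 0; j < C; ++j) {
    const double* s = S.colptr(j);
    double* a = A.colptr(j);
    double mu_j, istd_j;
    if (train) {
      double s1 = 0.0, s2 = 0.0;
      for (uword i = 0; i < m; ++i) { s1 += s[i]; s2 += s[i] * s[i]; }
      mu_j = s1 / m;
      double var_j = s2 / m - mu_j * mu_j;
      if (var_j < 0) var_j = 0;
      istd_j = 1.0 / std::sqrt(var_j + BN_EPS);
      bl.bn.mu[j] = mu_j;
      bl.bn.istd[j] = istd_j;
      bl.bn.rmean[j] = mom * bl.bn.rmean[j] + (1.0 - mom) * mu_j;
      bl.bn.rvar[j] = mom * bl.bn.rvar[j] + (1.0 - mom) * var_j;
    } else {
      mu_j = bl.bn.rmean[j];
      istd_j = 1.0 / std::sqrt(bl.bn.rvar[j] + BN_EPS);
    }
    const double sc = bl.bn.gam[j] * istd_j;
    const double sh = bl.bn.bet[j] - mu_j * sc;
    for (uword i = 0; i < m; ++i) {
      const double h = s[i] * sc + sh;
      a[i] = h > 0 ? h : 0.0;
    }
  }
}

// D carries dA on entry and dS on exit (in place); Dprev <- dXin if wanted.
static void block_bwd(Block& bl, const mat& Xin, const mat& S, const mat& A,
                      mat& D, mat* Dprev) {
  const uword m = S.n_rows, C = S.n_cols;
  for (uword j = 0; j < C; ++j) {
    double* dh = D.colptr(j);
    const double* s = S.colptr(j);
    const double* a = A.colptr(j);
    const double mu_j = bl.bn.mu[j], istd_j = bl.bn.istd[j];
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < m; ++i) {
      if (a[i] <= 0) dh[i] = 0.0;  // ReLU mask
      const double xh = (s[i] - mu_j) * istd_j;
      s1 += dh[i];
      s2 += dh[i] * xh;
    }
    bl.bn.ggam[j] = s2;
    bl.bn.gbet[j] = s1;
    const double c1 = s1 / m, c2 = s2 / m;
    const double gi = bl.bn.gam[j] * istd_j;
    for (uword i = 0; i < m; ++i) {
      const double xh = (s[i] - mu_j) * istd_j;
      dh[i] = gi * (dh[i] - c1 - xh * c2);
    }
  }
  bl.d.gW = Xin.t() * D;
  if (Dprev) *Dprev = D * bl.d.W.t();
}

static void pool_fwd(const mat& A, uword n, uword B, mat& P, umat& AMX) {
  const uword C = A.n_cols;
  for (uword j = 0; j < C; ++j) {
    const double* a = A.colptr(j);
    for (uword b = 0; b < B; ++b) {
      const double* p = a + b * n;
      double mx = p[0];
      uword am = 0;
      for (uword i = 1; i < n; ++i)
        if (p[i] > mx) { mx = p[i]; am = i; }
      P(b, j) = mx;
      AMX(b, j) = am + b * n;
    }
  }
}

static void pool_bwd(const mat& dP, const umat& AMX, mat& D) {
  D.zeros();
  const uword B = dP.n_rows, C = dP.n_cols;
  for (uword j = 0; j < C; ++j)
    for (uword b = 0; b < B; ++b)
      D(AMX(b, j), j) += dP(b, j);
}

// ---------------------------------------------------------------------------

struct Stack {
  std::vector<Block> conv, fc;
  Dense out;
  uword in_dim = 3, odim = 1;

  // full-size workspaces (Rmax point rows, Bmax cloud rows)
  std::vector<mat> Sc_buf, Ac_buf, Sf_buf, Af_buf;
  mat P_buf, Z_buf;
  umat AMX_buf;
  mat D1_buf, D2_buf;  // point-level gradient ping-pong
  mat E1_buf, E2_buf;  // cloud-level gradient ping-pong

  void alloc(uword Rmax, uword Bmax) {
    Sc_buf.clear(); Ac_buf.clear(); Sf_buf.clear(); Af_buf.clear();
    uword maxcw = in_dim;
    for (auto& b : conv) {
      uword w = b.d.W.n_cols;
      Sc_buf.emplace_back(Rmax, w);
      Ac_buf.emplace_back(Rmax, w);
      if (w > maxcw) maxcw = w;
    }
    uword lastc = conv.back().d.W.n_cols;
    uword maxfw = std::max(lastc, odim);
    for (auto& b : fc) {
      uword w = b.d.W.n_cols;
      Sf_buf.emplace_back(Bmax, w);
      Af_buf.emplace_back(Bmax, w);
      if (w > maxfw) maxfw = w;
    }
    P_buf.set_size(Bmax, lastc);
    AMX_buf.set_size(Bmax, lastc);
    Z_buf.set_size(Bmax, odim);
    D1_buf.set_size(Rmax, maxcw);
    D2_buf.set_size(Rmax, maxcw);
    E1_buf.set_size(Bmax, maxfw);
    E2_buf.set_size(Bmax, maxfw);
  }
};

// per-batch alias views over a stack's buffers (no copies, no allocation)
struct StackViews {
  std::vector<mat> Sc, Ac, Sf, Af;
  mat P, Z;
  umat AMX;
  StackViews(Stack& st, uword r, uword B) {
    Sc.reserve(st.conv.size()); Ac.reserve(st.conv.size());
    for (size_t i = 0; i < st.conv.size(); ++i) {
      uword w = st.conv[i].d.W.n_cols;
      Sc.emplace_back(st.Sc_buf[i].memptr(), r, w, false, true);
      Ac.emplace_back(st.Ac_buf[i].memptr(), r, w, false, true);
    }
    Sf.reserve(st.fc.size()); Af.reserve(st.fc.size());
    for (size_t i = 0; i < st.fc.size(); ++i) {
      uword w = st.fc[i].d.W.n_cols;
      Sf.emplace_back(st.Sf_buf[i].memptr(), B, w, false, true);
      Af.emplace_back(st.Af_buf[i].memptr(), B, w, false, true);
    }
    uword lastc = st.conv.back().d.W.n_cols;
    P = mat(st.P_buf.memptr(), B, lastc, false, true);
    AMX = umat(st.AMX_buf.memptr(), B, lastc, false, true);
    Z = mat(st.Z_buf.memptr(), B, st.odim, false, true);
  }
};

static void stack_fwd(Stack& st, StackViews& v, const mat& X, uword n,
                      uword B, bool train, double mom) {
  const mat* cur = &X;
  for (size_t i = 0; i < st.conv.size(); ++i) {
    block_fwd(st.conv[i], *cur, v.Sc[i], v.Ac[i], train, mom);
    cur = &v.Ac[i];
  }
  pool_fwd(*cur, n, B, v.P, v.AMX);
  cur = &v.P;
  for (size_t i = 0; i < st.fc.size(); ++i) {
    block_fwd(st.fc[i], *cur, v.Sf[i], v.Af[i], train, mom);
    cur = &v.Af[i];
  }
  v.Z = (*cur) * st.out.W;
  v.Z.each_row() += st.out.b.t();
}

// dZ is consumed; on exit, if dX != nullptr it holds the input gradient.
static void stack_bwd(Stack& st, StackViews& v, const mat& X, mat& dZ,
                      uword r, uword B, mat* dX) {
  const mat& Alast = st.fc.empty() ? v.P : v.Af.back();
  st.out.gb = arma::sum(dZ, 0).t();
  st.out.gW = Alast.t() * dZ;

  mat E1(st.E1_buf.memptr(), B, st.E1_buf.n_cols, false, true);
  mat E2(st.E2_buf.memptr(), B, st.E2_buf.n_cols, false, true);
  mat curE(E1.memptr(), B, st.out.W.n_rows, false, true);
  curE = dZ * st.out.W.t();
  bool in1 = true;
  for (size_t k = st.fc.size(); k-- > 0;) {
    const mat& Xin = (k == 0) ? v.P : v.Af[k - 1];
    uword din = st.fc[k].d.W.n_rows;
    mat prevE((in1 ? E2 : E1).memptr(), B, din, false, true);
    mat curv((in1 ? E1 : E2).memptr(), B, st.fc[k].d.W.n_cols, false, true);
    block_bwd(st.fc[k], Xin, v.Sf[k], v.Af[k], curv, &prevE);
    in1 = !in1;
  }
  // gradient w.r.t. the pooled features now sits in (in1 ? E1 : E2)
  mat dP((in1 ? E1 : E2).memptr(), B, v.P.n_cols, false, true);

  mat D1(st.D1_buf.memptr(), r, v.P.n_cols, false, true);
  pool_bwd(dP, v.AMX, D1);
  bool d_in1 = true;
  for (size_t k = st.conv.size(); k-- > 0;) {
    const mat& Xin = (k == 0) ? X : v.Ac[k - 1];
    uword din = st.conv[k].d.W.n_rows;
    mat curD((d_in1 ? st.D1_buf : st.D2_buf).memptr(), r,
             st.conv[k].d.W.n_cols, false, true);
    bool want_dx = (k > 0) || (dX != nullptr);
    mat prevD((d_in1 ? st.D2_buf : st.D1_buf).memptr(), r, din, false, true);
    block_bwd(st.conv[k], Xin, v.Sc[k], v.Ac[k], curD,
              want_dx ? &prevD : nullptr);
    d_in1 = !d_in1;
  }
  if (dX) *dX = mat((d_in1 ? st.D1_buf : st.D2_buf).memptr(), r, 3, false, true);
}

// ---------------------------------------------------------------------------

struct Net {
  uword n_pts, Bmax, Rmax;
  bool use_tnet;
  double L, bn_mom;
  Stack tnet, main_s;
  mat X0_buf, Xt_buf, dXt_buf;

  std::vector<std::pair<double*, uword>> state_refs;  // all learnable + BN stats
  struct OptRef { double* p; double* g; double* m; double* v; uword n; };
  std::vector<OptRef> opt_refs;

  void register_stack(Stack& st) {
    auto add_dense = [&](Dense& d) {
      d.prep();
      state_refs.push_back({d.W.memptr(), d.W.n_elem});
      opt_refs.push_back({d.W.memptr(), d.gW.memptr(), d.mW.memptr(),
                          d.vW.memptr(), d.W.n_elem});
      if (d.has_b) {
        state_refs.push_back({d.b.memptr(), d.b.n_elem});
        opt_refs.push_back({d.b.memptr(), d.gb.memptr(), d.mb.memptr(),
                            d.vb.memptr(), d.b.n_elem});
      }
    };
    auto add_bn = [&](BNorm& bn) {
      bn.prep();
      state_refs.push_back({bn.gam.memptr(), bn.gam.n_elem});
      state_refs.push_back({bn.bet.memptr(), bn.bet.n_elem});
      state_refs.push_back({bn.rmean.memptr(), bn.rmean.n_elem});
      state_refs.push_back({bn.rvar.memptr(), bn.rvar.n_elem});
      opt_refs.push_back({bn.gam.memptr(), bn.ggam.memptr(), bn.m_g.memptr(),
                          bn.v_g.memptr(), bn.gam.n_elem});
      opt_refs.push_back({bn.bet.memptr(), bn.gbet.memptr(), bn.m_b.memptr(),
                          bn.v_b.memptr(), bn.bet.n_elem});
    };
    for (auto& b : st.conv) { add_dense(b.d); add_bn(b.bn); }
    for (auto& b : st.fc) { add_dense(b.d); add_bn(b.bn); }
    add_dense(st.out);
  }

  void finalize(uword batch_max) {
    Bmax = batch_max;
    Rmax = Bmax * n_pts;
    if (use_tnet) { tnet.alloc(Rmax, Bmax); register_stack(tnet); }
    main_s.alloc(Rmax, Bmax);
    register_stack(main_s);
    X0_buf.set_size(Rmax, 3);
    Xt_buf.set_size(Rmax, 3);
    dXt_buf.set_size(Rmax, 3);
  }

  std::vector<vec> snapshot() const {
    std::vector<vec> out;
    out.reserve(state_refs.size());
    for (auto& s : state_refs) out.emplace_back(vec(s.first, s.second));
    return out;
  }
  void restore(const std::vector<vec>& snap) {
    for (size_t i = 0; i < state_refs.size(); ++i)
      std::memcpy(state_refs[i].first, snap[i].memptr(),
                  state_refs[i].second * sizeof(double));
  }
};

static void adam_step(Net& net, AdamOpt& opt) {
  ++opt.t;
  const double c1 = 1.0 - std::pow(opt.b1, (double)opt.t);
  const double c2 = 1.0 - std::pow(opt.b2, (double)opt.t);
  for (auto& r : net.opt_refs) {
    double* p = r.p; double* g = r.g; double* m = r.m; double* v = r.v;
    for (uword i = 0; i < r.n; ++i) {
      m[i] = opt.b1 * m[i] + (1.0 - opt.b1) * g[i];
      v[i] = opt.b2 * v[i] + (1.0 - opt.b2) * g[i] * g[i];
      p[i] -= opt.lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + opt.eps);
    }
  }
}

// ---------------------------------------------------------------------------
// parameter (un)packing: flat R list in fixed order; see R/pointnet.R

struct Cursor {
  const List& src;
  int i = 0;
  explicit Cursor(const List& s) : src(s) {}
  mat next_mat() { return as<mat>(src[i++]); }
  rowvec next_rowvec() {
    NumericVector v = src[i++];
    return rowvec(v.begin(), v.size());
  }
  vec next_vec() {
    NumericVector v = src[i++];
    return vec(v.begin(), v.size());
  }
};

static void load_block(Cursor& c, Block& bl) {
  bl.d.W = c.next_mat();
  bl.bn.gam = c.next_rowvec();
  bl.bn.bet = c.next_rowvec();
  bl.bn.rmean = c.next_rowvec();
  bl.bn.rvar = c.next_rowvec();
}

static void load_stack(Cursor& c, Stack& st, int n_conv, int n_fc, uword odim) {
  st.conv.resize(n_conv);
  st.fc.resize(n_fc);
  for (auto& b : st.conv) load_block(c, b);
  for (auto& b : st.fc) load_block(c, b);
  st.out.W = c.next_mat();
  st.out.b = c.next_vec();
  st.out.has_b = true;
  st.odim = odim;
}

struct OutCursor {
  List dst;
  int i = 0;
  explicit OutCursor(const List& tmpl) : dst(clone(tmpl)) {}
  void put_mat(const mat& m) {
    NumericMatrix r(m.n_rows, m.n_cols);
    std::memcpy(r.begin(), m.memptr(), m.n_elem * sizeof(double));
    dst[i++] = r;
  }
  void put_row(const rowvec& v) {
    dst[i++] = NumericVector(v.begin(), v.end());
  }
  void put_vec(const vec& v) {
    dst[i++] = NumericVector(v.begin(), v.end());
  }
};

static void dump_block(OutCursor& c, const Block& bl) {
  c.put_mat(bl.d.W);
  c.put_row(bl.bn.gam);
  c.put_row(bl.bn.bet);
  c.put_row(bl.bn.rmean);
  c.put_row(bl.bn.rvar);
}

static void dump_stack(OutCursor& c, const Stack& st) {
  for (auto& b : st.conv) dump_block(c, b);
  for (auto& b : st.fc) dump_block(c, b);
  c.put_mat(st.out.W);
  c.put_vec(st.out.b);
}

// heap-allocated: Net::state_refs points into member matrices, so the
// object must never be moved or copied after finalize()
static std::unique_ptr<Net> build_net(const List& params, const List& cfg,
                                      uword batch_max) {
  std::unique_ptr<Net> net(new Net());
  net->n_pts = as<int>(cfg["n_points"]);
  net->L = as<double>(cfg["plane_distance"]);
  net->use_tnet = as<bool>(cfg["use_input_transform"]);
  net->bn_mom = as<double>(cfg["bn_momentum"]);
  IntegerVector tc = cfg["tnet_conv"], tf = cfg["tnet_fc"];
  IntegerVector mc = cfg["conv"], hd = cfg["head"];
  Cursor cur(params);
  if (net->use_tnet) load_stack(cur, net->tnet, tc.size(), tf.size(), 9);
  load_stack(cur, net->main_s, mc.size(), hd.size(), 1);
  net->finalize(batch_max);
  return net;
}

// featurize one cloud into rows [row0, row0+n) of X0: centre x and y at the
// cloud centroid, express z as height above the floor plane (L - z);
// optionally jitter every raw coordinate by U(-amp, amp) first.
static void featurize(const mat& cl, double L, double amp, bool jit,
                      mat& X0, uword row0) {
  const uword n = cl.n_rows;
  double* x = X0.colptr(0) + row0;
  double* y = X0.colptr(1) + row0;
  double* z = X0.colptr(2) + row0;
  double sx = 0, sy = 0;
  const double* cx = cl.colptr(0);
  const double* cy = cl.colptr(1);
  const double* cz = cl.colptr(2);
  for (uword i = 0; i < n; ++i) {
    x[i] = cx[i] + (jit ? amp * (2.0 * unif_rand() - 1.0) : 0.0);
    sx += x[i];
  }
  for (uword i = 0; i < n; ++i) {
    y[i] = cy[i] + (jit ? amp * (2.0 * unif_rand() - 1.0) : 0.0);
    sy += y[i];
  }
  for (uword i = 0; i < n; ++i)
    z[i] = L - (cz[i] + (jit ? amp * (2.0 * unif_rand() - 1.0) : 0.0));
  const double mx = sx / n, my = sy / n;
  for (uword i = 0; i < n; ++i) { x[i] -= mx; y[i] -= my; }
}

// forward pass over one assembled batch; returns predictions (B x 1 view
// into the main stack's Z buffer, post-ReLU values copied into preds).
static void net_fwd(Net& net, StackViews* tv, StackViews& mv, uword B,
                    bool train, std::vector<mat>& Tmats) {
  const uword n = net.n_pts, r = B * n;
  mat X0(net.X0_buf.memptr(), r, 3, false, true);
  if (net.use_tnet) {
    stack_fwd(net.tnet, *tv, X0, n, B, train, net.bn_mom);
    mat Xt(net.Xt_buf.memptr(), r, 3, false, true);
    Tmats.resize(B);
    for (uword b = 0; b < B; ++b) {
      mat T(3, 3);
      for (uword jj = 0; jj < 3; ++jj)
        for (uword ii = 0; ii < 3; ++ii)
          T(ii, jj) = tv->Z(b, ii + 3 * jj);
      Tmats[b] = T;
      Xt.rows(b * n, (b + 1) * n - 1) = X0.rows(b * n, (b + 1) * n - 1) * T;
    }
    stack_fwd(net.main_s, mv, Xt, n, B, train, net.bn_mom);
  } else {
    stack_fwd(net.main_s, mv, X0, n, B, train, net.bn_mom);
  }
}

static void net_bwd(Net& net, StackViews* tv, StackViews& mv, mat& dZ,
                    uword B, std::vector<mat>& Tmats) {
  const uword n = net.n_pts, r = B * n;
  mat X0(net.X0_buf.memptr(), r, 3, false, true);
  if (net.use_tnet) {
    mat Xt(net.Xt_buf.memptr(), r, 3, false, true);
    mat dXt(net.dXt_buf.memptr(), r, 3, false, true);
    stack_bwd(net.main_s, mv, Xt, dZ, r, B, &dXt);
    mat dG(B, 9);
    for (uword b = 0; b < B; ++b) {
      mat dT = X0.rows(b * n, (b + 1) * n - 1).t() *
               dXt.rows(b * n, (b + 1) * n - 1);
      for (uword jj = 0; jj < 3; ++jj)
        for (uword ii = 0; ii < 3; ++ii)
          dG(b, ii + 3 * jj) = dT(ii, jj);
    }
    stack_bwd(net.tnet, *tv, X0, dG, r, B, nullptr);
  } else {
    stack_bwd(net.main_s, mv, X0, dZ, r, B, nullptr);
  }
}

// [[Rcpp::export]]
List cpp_pn_train(List params, List cfg, List ctrl, List train_clouds,
                  NumericVector train_y, List val_clouds,
                  NumericVector val_y) {
  const int batch_size = as<int>(ctrl["batch_size"]);
  const int max_epochs = as<int>(ctrl["max_epochs"]);
  int patience = as<int>(ctrl["patience"]);
  if (patience <= 0) patience = INT_MAX;
  const double jitter = as<double>(ctrl["jitter"]);
  AdamOpt opt{as<double>(ctrl["learning_rate"]), as<double>(ctrl["beta1"]),
              as<double>(ctrl["beta2"]), as<double>(ctrl["adam_eps"])};

  const int Ntr = train_clouds.size(), Nva = val_clouds.size();
  const int Bmax = std::min(batch_size, std::max(Ntr, Nva));
  std::unique_ptr<Net> net_p = build_net(params, cfg, (uword)Bmax);
  Net& net = *net_p;
  const uword n = net.n_pts;

  std::vector<mat> tr(Ntr), vaF(Nva);
  for (int i = 0; i < Ntr; ++i) tr[i] = as<mat>(train_clouds[i]);
  {  // validation features are fixed: featurize once, without jitter
    for (int i = 0; i < Nva; ++i) {
      vaF[i].set_size(n, 3);
      featurize(as<mat>(val_clouds[i]), net.L, 0.0, false, vaF[i], 0);
    }
  }

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;
  std::vector<double> hist_tr, hist_va;
  double best = R_PosInf;
  int best_epoch = 0, wait = 0, stopped = max_epochs;
  std::vector<vec> best_snap;
  std::vector<mat> Tmats;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    checkUserInterrupt();
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = Ntr - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double sse = 0.0;
    for (int start = 0; start < Ntr; start += batch_size) {
      const int B = std::min(batch_size, Ntr - start);
      const uword r = (uword)B * n;
      mat X0(net.X0_buf.memptr(), r, 3, false, true);
      for (int b = 0; b < B; ++b)
        featurize(tr[order[start + b]], net.L, jitter, jitter > 0, X0,
                  (uword)b * n);
      std::unique_ptr<StackViews> tv;
      if (net.use_tnet) tv.reset(new StackViews(net.tnet, r, B));
      StackViews mv(net.main_s, r, B);
      net_fwd(net, tv.get(), mv, B, true, Tmats);
      mat dZ(B, 1);
      for (int b = 0; b < B; ++b) {
        const double z = mv.Z(b, 0);
        const double p = z > 0 ? z : 0.0;
        const double err = p - train_y[order[start + b]];
        sse += err * err;
        dZ(b, 0) = z > 0 ? 2.0 * err / B : 0.0;
      }
      net_bwd(net, tv.get(), mv, dZ, B, Tmats);
      adam_step(net, opt);
    }
    const double tr_rmse = std::sqrt(sse / Ntr);
    if (!std::isfinite(tr_rmse))
      stop("training diverged (non-finite loss) at epoch %d", epoch);
    hist_tr.push_back(tr_rmse);

    double vsse = 0.0;
    for (int start = 0; start < Nva; start += Bmax) {
      const int B = std::min(Bmax, Nva - start);
      const uword r = (uword)B * n;
      mat X0(net.X0_buf.memptr(), r, 3, false, true);
      for (int b = 0; b < B; ++b)
        X0.rows((uword)b * n, (uword)(b + 1) * n - 1) = vaF[start + b];
      std::unique_ptr<StackViews> tv;
      if (net.use_tnet) tv.reset(new StackViews(net.tnet, r, B));
      StackViews mv(net.main_s, r, B);
      net_fwd(net, tv.get(), mv, B, false, Tmats);
      for (int b = 0; b < B; ++b) {
        const double z = mv.Z(b, 0);
        const double err = (z > 0 ? z : 0.0) - val_y[start + b];
        vsse += err * err;
      }
    }
    const double va_rmse = std::sqrt(vsse / Nva);
    hist_va.push_back(va_rmse);

    if (va_rmse < best) {
      best = va_rmse;
      best_epoch = epoch;
      best_snap = net.snapshot();
      wait = 0;
    } else if (++wait >= patience) {
      stopped = epoch;
      break;
    }
    if (epoch == max_epochs) stopped = epoch;
  }
  if (!best_snap.empty()) net.restore(best_snap);

  OutCursor oc(params);
  if (net.use_tnet) dump_stack(oc, net.tnet);
  dump_stack(oc, net.main_s);
  return List::create(_["params"] = oc.dst,
                      _["train_rmse"] = NumericVector(hist_tr.begin(), hist_tr.end()),
                      _["val_rmse"] = NumericVector(hist_va.begin(), hist_va.end()),
                      _["best_epoch"] = best_epoch,
                      _["stopped_epoch"] = stopped,
                      _["best_val_rmse"] = best);
}

// [[Rcpp::export]]
NumericVector cpp_pn_predict(List params, List cfg, List clouds) {
  const int N = clouds.size();
  if (N == 0) return NumericVector(0);
  const int Bmax = std::min(32, N);
  std::unique_ptr<Net> net_p = build_net(params, cfg, (uword)Bmax);
  Net& net = *net_p;
  const uword n = net.n_pts;
  NumericVector out(N);
  std::vector<mat> Tmats;
  for (int start = 0; start < N; start += Bmax) {
    const int B = std::min(Bmax, N - start);
    const uword r = (uword)B * n;
    mat X0(net.X0_buf.memptr(), r, 3, false, true);
    for (int b = 0; b < B; ++b)
      featurize(as<mat>(clouds[start + b]), net.L, 0.0, false, X0,
                (uword)b * n);
    std::unique_ptr<StackViews> tv;
    if (net.use_tnet) tv.reset(new StackViews(net.tnet, r, B));
    StackViews mv(net.main_s, r, B);
    net_fwd(net, tv.get(), mv, B, false, Tmats);
    for (int b = 0; b < B; ++b) {
      const double z = mv.Z(b, 0);
      out[start + b] = z > 0 ? z : 0.0;
    }
  }
  return out;
}
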