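// Numeric core of the spectral-spatial factorized-attention transformer.
// Layout contract (shared with the R wrappers): token rows are ordered
// (sample, band, position) with position fastest; the S class-token rows
// sit at the end of the stacked matrix. All matrices are column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Dims {
  int S, N, B, D, heads, depth, p2, n_classes;
  bool band_pos;
  int n_tok() const { return S * B * N; }
  int n_rows() const { return S * B * N + S; }
  int dh() const { return D / heads; }
};

Dims read_dims(const List& d) {
  Dims out;
  out.S = d["S"]; out.N = d["N"]; out.B = d["B"]; out.D = d["D"];
  out.heads = d["heads"]; out.depth = d["depth"]; out.p2 = d["p2"];
  out.n_classes = d["n_classes"];
  out.band_pos = d["band_pos"];
  return out;
}

mat as_mat(SEXP s) {
  Rcpp::NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
vec as_vec(SEXP s) {
  Rcpp::NumericVector v(s);
  return vec(v.begin(), v.size(), false, true);
}

struct Lin { mat W; vec b; };
Lin read_lin(const List& l) {
  return Lin{ as_mat(l["W"]), as_vec(l["b"]) };
}

struct Blk {
  vec ln1_g, ln1_b, ln2_g, ln2_b, ln3_g, ln3_b;
  Lin sq, sk, sv, so, pq, pk, pv, po, m1, m2;
};

Blk read_blk(const List& l) {
  Blk b;
  b.ln1_g = as_vec(l["ln1_g"]); b.ln1_b = as_vec(l["ln1_b"]);
  b.ln2_g = as_vec(l["ln2_g"]); b.ln2_b = as_vec(l["ln2_b"]);
  b.ln3_g = as_vec(l["ln3_g"]); b.ln3_b = as_vec(l["ln3_b"]);
  b.sq = read_lin(l["spe_q"]); b.sk = read_lin(l["spe_k"]);
  b.sv = read_lin(l["spe_v"]); b.so = read_lin(l["spe_o"]);
  b.pq = read_lin(l["spa_q"]); b.pk = read_lin(l["spa_k"]);
  b.pv = read_lin(l["spa_v"]); b.po = read_lin(l["spa_o"]);
  b.m1 = read_lin(l["mlp1"]); b.m2 = read_lin(l["mlp2"]);
  return b;
}

struct LNCache { mat xhat, Y; vec inv_sd; };

void ln_fwd(const mat& X, const vec& g, const vec& b, LNCache& c) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  c.inv_sd = 1.0 / sqrt(mean(square(xc), 1) + 1e-6);
  xc.each_col() %= c.inv_sd;
  c.xhat = std::move(xc);
  c.Y = c.xhat.each_row() % g.t();
  c.Y.each_row() += b.t();
}

// returns dX; accumulates dg, db
mat ln_bwd(const mat& dY, const LNCache& c, const vec& g, vec& dg, vec& db) {
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % c.xhat, 1);
  dg = sum(dY % c.xhat, 0).t();
  db = sum(dY, 0).t();
  mat dX = dxhat.each_col() - m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv_sd;
  return dX;
}

// rowwise softmax in place (global-max shift, exact per row)
void softmax_rows(mat& s) {
  s -= s.max();
  s = exp(s);
  s.each_col() /= sum(s, 1);
}

// GELU, sigmoid approximation: x * sigmoid(1.702 x). Returns activation,
// stores the sigmoid for the backward pass.
void gelu_fwd(const mat& X, mat& H, mat& Sig) {
  Sig = 1.0 / (1.0 + exp(-1.702 * X));
  H = X % Sig;
}
mat gelu_bwd(const mat& dH, const mat& X, const mat& Sig) {
  return dH % (Sig + 1.702 * X % Sig % (1.0 - Sig));
}

struct AttnCache {
  mat Q, K, V, O;
  cube A;          // spectral: (B,B,slice per s,n,h); spatial: (N+1,N+1,...)
};

struct BlkCache {
  LNCache ln1, ln2, ln3;
  AttnCache at1, at2;
  mat Hpre, Sig, H;
  mat m1, m2, m3;  // dropout masks (possibly empty)
};

void project_qkv(const mat& Y, const Lin& lq, const Lin& lk, const Lin& lv,
                 AttnCache& c) {
  c.Q = Y * lq.W; c.Q.each_row() += lq.b.t();
  c.K = Y * lk.W; c.K.each_row() += lk.b.t();
  c.V = Y * lv.W; c.V.each_row() += lv.b.t();
}

// ---- spectral attention: tokens at one (sample, position) attend across
// bands; class tokens bypass this stream.
void spectral_fwd(const Dims& dm, const Lin& lq, const Lin& lk,
                  const Lin& lv, const Lin& lo, const mat& Y,
                  AttnCache& c, mat& delta) {
  const int B = dm.B, N = dm.N, dh = dm.dh();
  const double scale = 1.0 / std::sqrt((double)dh);
  project_qkv(Y, lq, lk, lv, c);
  c.O.zeros(dm.n_rows(), dm.D);
  c.A.set_size(B, B, (size_t)dm.S * N * dm.heads);
  mat qm(B, dh), km(B, dh), vm(B, dh);
  size_t slice = 0;
  for (int h = 0; h < dm.heads; ++h) {
    const int off = h * dh;
    for (int s = 0; s < dm.S; ++s) {
      const int base = s * B * N;
      for (int n = 0; n < N; ++n) {
        for (int b = 0; b < B; ++b)
          for (int d = 0; d < dh; ++d) {
            qm(b, d) = c.Q(base + b * N + n, off + d);
            km(b, d) = c.K(base + b * N + n, off + d);
            vm(b, d) = c.V(base + b * N + n, off + d);
          }
        mat A = qm * km.t() * scale;
        softmax_rows(A);
        mat om = A * vm;
        c.A.slice(slice++) = A;
        for (int b = 0; b < B; ++b)
          for (int d = 0; d < dh; ++d)
            c.O(base + b * N + n, off + d) = om(b, d);
      }
    }
  }
  delta = c.O * lo.W;
  delta.each_row() += lo.b.t();
  delta.rows(dm.n_tok(), dm.n_rows() - 1).zeros();
}

void spectral_bwd(const Dims& dm, const Lin& lq, const Lin& lk,
                  const Lin& lv, const Lin& lo, const mat& Y,
                  const AttnCache& c, mat dDelta, mat& dY,
                  List& g_q, List& g_k, List& g_v, List& g_o) {
  const int B = dm.B, N = dm.N, dh = dm.dh();
  const double scale = 1.0 / std::sqrt((double)dh);
  dDelta.rows(dm.n_tok(), dm.n_rows() - 1).zeros();
  mat dO = dDelta * lo.W.t();
  mat goW = c.O.t() * dDelta;
  vec gob = sum(dDelta.rows(0, dm.n_tok() - 1), 0).t();
  mat dQ(size(c.Q), fill::zeros), dK(size(c.K), fill::zeros),
      dV(size(c.V), fill::zeros);
  mat qm(B, dh), km(B, dh), vm(B, dh), dom(B, dh);
  size_t slice = 0;
  for (int h = 0; h < dm.heads; ++h) {
    const int off = h * dh;
    for (int s = 0; s < dm.S; ++s) {
      const int base = s * B * N;
      for (int n = 0; n < N; ++n) {
        for (int b = 0; b < B; ++b)
          for (int d = 0; d < dh; ++d) {
            qm(b, d) = c.Q(base + b * N + n, off + d);
            km(b, d) = c.K(base + b * N + n, off + d);
            vm(b, d) = c.V(base + b * N + n, off + d);
            dom(b, d) = dO(base + b * N + n, off + d);
          }
        const mat& A = c.A.slice(slice++);
        mat dVm = A.t() * dom;
        mat dA = dom * vm.t();
        mat dS = A % (dA.each_col() - sum(dA % A, 1)) * scale;
        mat dQm = dS * km;
        mat dKm = dS.t() * qm;
        for (int b = 0; b < B; ++b)
          for (int d = 0; d < dh; ++d) {
            dQ(base + b * N + n, off + d) = dQm(b, d);
            dK(base + b * N + n, off + d) = dKm(b, d);
            dV(base + b * N + n, off + d) = dVm(b, d);
          }
      }
    }
  }
  dY = dQ * lq.W.t() + dK * lk.W.t() + dV * lv.W.t();
  g_q = List::create(Named("W") = Y.t() * dQ, Named("b") = sum(dQ, 0).t());
  g_k = List::create(Named("W") = Y.t() * dK, Named("b") = sum(dK, 0).t());
  g_v = List::create(Named("W") = Y.t() * dV, Named("b") = sum(dV, 0).t());
  g_o = List::create(Named("W") = goW, Named("b") = gob);
}

// ---- spatial attention: per (sample, band) the sequence is [class token,
// N position tokens]; each sample's class-token outputs are averaged over
// its bands.
void spatial_fwd(const Dims& dm, const Lin& lq, const Lin& lk,
                 const Lin& lv, const Lin& lo, const mat& Y,
                 AttnCache& c, mat& delta) {
  const int B = dm.B, N = dm.N, dh = dm.dh();
  const double scale = 1.0 / std::sqrt((double)dh);
  project_qkv(Y, lq, lk, lv, c);
  c.O.zeros(dm.n_rows(), dm.D);
  c.A.set_size(N + 1, N + 1, (size_t)dm.S * B * dm.heads);
  mat qm(N + 1, dh), km(N + 1, dh), vm(N + 1, dh);
  size_t slice = 0;
  for (int h = 0; h < dm.heads; ++h) {
    const int off = h * dh;
    for (int s = 0; s < dm.S; ++s) {
      const int crow = dm.n_tok() + s;
      for (int b = 0; b < B; ++b) {
        const int base = (s * B + b) * N;
        qm.row(0) = c.Q.row(crow).cols(off, off + dh - 1);
        km.row(0) = c.K.row(crow).cols(off, off + dh - 1);
        vm.row(0) = c.V.row(crow).cols(off, off + dh - 1);
        qm.rows(1, N) = c.Q.submat(base, off, base + N - 1, off + dh - 1);
        km.rows(1, N) = c.K.submat(base, off, base + N - 1, off + dh - 1);
        vm.rows(1, N) = c.V.submat(base, off, base + N - 1, off + dh - 1);
        mat A = qm * km.t() * scale;
        softmax_rows(A);
        mat om = A * vm;
        c.A.slice(slice++) = A;
        c.O.submat(base, off, base + N - 1, off + dh - 1) = om.rows(1, N);
        c.O.row(crow).cols(off, off + dh - 1) += om.row(0) / B;
      }
    }
  }
  delta = c.O * lo.W;
  delta.each_row() += lo.b.t();
}

void spatial_bwd(const Dims& dm, const Lin& lq, const Lin& lk,
                 const Lin& lv, const Lin& lo, const mat& Y,
                 const AttnCache& c, const mat& dDelta, mat& dY,
                 List& g_q, List& g_k, List& g_v, List& g_o) {
  const int B = dm.B, N = dm.N, dh = dm.dh();
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dO = dDelta * lo.W.t();
  mat goW = c.O.t() * dDelta;
  vec gob = sum(dDelta, 0).t();
  mat dQ(size(c.Q), fill::zeros), dK(size(c.K), fill::zeros),
      dV(size(c.V), fill::zeros);
  mat qm(N + 1, dh), km(N + 1, dh), vm(N + 1, dh), dom(N + 1, dh);
  size_t slice = 0;
  for (int h = 0; h < dm.heads; ++h) {
    const int off = h * dh;
    for (int s = 0; s < dm.S; ++s) {
      const int crow = dm.n_tok() + s;
      for (int b = 0; b < B; ++b) {
        const int base = (s * B + b) * N;
        qm.row(0) = c.Q.row(crow).cols(off, off + dh - 1);
        km.row(0) = c.K.row(crow).cols(off, off + dh - 1);
        vm.row(0) = c.V.row(crow).cols(off, off + dh - 1);
        qm.rows(1, N) = c.Q.submat(base, off, base + N - 1, off + dh - 1);
        km.rows(1, N) = c.K.submat(base, off, base + N - 1, off + dh - 1);
        vm.rows(1, N) = c.V.submat(base, off, base + N - 1, off + dh - 1);
        dom.row(0) = dO.row(crow).cols(off, off + dh - 1) / B;
        dom.rows(1, N) = dO.submat(base, off, base + N - 1, off + dh - 1);
        const mat& A = c.A.slice(slice++);
        mat dVm = A.t() * dom;
        mat dA = dom * vm.t();
        mat dS = A % (dA.each_col() - sum(dA % A, 1)) * scale;
        mat dQm = dS * km;
        mat dKm = dS.t() * qm;
        dQ.submat(base, off, base + N - 1, off + dh - 1) += dQm.rows(1, N);
        dK.submat(base, off, base + N - 1, off + dh - 1) += dKm.rows(1, N);
        dV.submat(base, off, base + N - 1, off + dh - 1) += dVm.rows(1, N);
        dQ.row(crow).cols(off, off + dh - 1) += dQm.row(0);
        dK.row(crow).cols(off, off + dh - 1) += dKm.row(0);
        dV.row(crow).cols(off, off + dh - 1) += dVm.row(0);
      }
    }
  }
  dY = dQ * lq.W.t() + dK * lk.W.t() + dV * lv.W.t();
  g_q = List::create(Named("W") = Y.t() * dQ, Named("b") = sum(dQ, 0).t());
  g_k = List::create(Named("W") = Y.t() * dK, Named("b") = sum(dK, 0).t());
  g_v = List::create(Named("W") = Y.t() * dV, Named("b") = sum(dV, 0).t());
  g_o = List::create(Named("W") = goW, Named("b") = gob);
}

void block_fwd(const Dims& dm, const Blk& blk, mat& X, BlkCache& c,
               const List* masks) {
  ln_fwd(X, blk.ln1_g, blk.ln1_b, c.ln1);
  mat d1;
  spectral_fwd(dm, blk.sq, blk.sk, blk.sv, blk.so, c.ln1.Y, c.at1, d1);
  if (masks) { c.m1 = as_mat((*masks)["m1"]); d1 %= c.m1; }
  X += d1;
  ln_fwd(X, blk.ln2_g, blk.ln2_b, c.ln2);
  mat d2;
  spatial_fwd(dm, blk.pq, blk.pk, blk.pv, blk.po, c.ln2.Y, c.at2, d2);
  if (masks) { c.m2 = as_mat((*masks)["m2"]); d2 %= c.m2; }
  X += d2;
  ln_fwd(X, blk.ln3_g, blk.ln3_b, c.ln3);
  c.Hpre = c.ln3.Y * blk.m1.W;
  c.Hpre.each_row() += blk.m1.b.t();
  gelu_fwd(c.Hpre, c.H, c.Sig);
  mat d3 = c.H * blk.m2.W;
  d3.each_row() += blk.m2.b.t();
  if (masks) { c.m3 = as_mat((*masks)["m3"]); d3 %= c.m3; }
  X += d3;
}

List block_bwd(const Dims& dm, const Blk& blk, const BlkCache& c, mat& dX) {
  List g;
  mat dd3 = c.m3.n_elem ? mat(dX % c.m3) : dX;
  g["mlp2"] = List::create(Named("W") = c.H.t() * dd3,
                           Named("b") = vec(sum(dd3, 0).t()));
  mat dH = dd3 * blk.m2.W.t();
  mat dHpre = gelu_bwd(dH, c.Hpre, c.Sig);
  g["mlp1"] = List::create(Named("W") = c.ln3.Y.t() * dHpre,
                           Named("b") = vec(sum(dHpre, 0).t()));
  mat dY3 = dHpre * blk.m1.W.t();
  vec dg, db;
  mat dX2 = ln_bwd(dY3, c.ln3, blk.ln3_g, dg, db);
  g["ln3_g"] = dg; g["ln3_b"] = db;
  dX2 += dX;

  mat dd2 = c.m2.n_elem ? mat(dX2 % c.m2) : dX2;
  mat dY2;
  List gq, gk, gv, go;
  spatial_bwd(dm, blk.pq, blk.pk, blk.pv, blk.po, c.ln2.Y, c.at2, dd2, dY2,
              gq, gk, gv, go);
  g["spa_q"] = gq; g["spa_k"] = gk; g["spa_v"] = gv; g["spa_o"] = go;
  mat dX1 = ln_bwd(dY2, c.ln2, blk.ln2_g, dg, db);
  g["ln2_g"] = dg; g["ln2_b"] = db;
  dX1 += dX2;

  mat dd1 = c.m1.n_elem ? mat(dX1 % c.m1) : dX1;
  mat dY1;
  spectral_bwd(dm, blk.sq, blk.sk, blk.sv, blk.so, c.ln1.Y, c.at1, dd1, dY1,
               gq, gk, gv, go);
  g["spe_q"] = gq; g["spe_k"] = gk; g["spe_v"] = gv; g["spe_o"] = go;
  mat dX0 = ln_bwd(dY1, c.ln1, blk.ln1_g, dg, db);
  g["ln1_g"] = dg; g["ln1_b"] = db;
  dX = dX1 + dX0;
  return g;
}

// stacked patch matrix -> token matrix with positional/class embeddings
mat embed(const Dims& dm, const List& params, const mat& P) {
  mat X(dm.n_rows(), dm.D);
  X.rows(0, dm.n_tok() - 1) = P * as_mat(params["embed_W"]);
  vec eb = as_vec(params["embed_b"]);
  X.rows(0, dm.n_tok() - 1).each_row() += eb.t();
  mat pos = as_mat(params["pos_spatial"]);
  for (int s = 0; s < dm.S; ++s)
    for (int b = 0; b < dm.B; ++b)
      X.rows((s * dm.B + b) * dm.N, (s * dm.B + b + 1) * dm.N - 1) += pos;
  if (dm.band_pos) {
    mat pb = as_mat(params["pos_band"]);
    for (int s = 0; s < dm.S; ++s)
      for (int b = 0; b < dm.B; ++b)
        X.rows((s * dm.B + b) * dm.N, (s * dm.B + b + 1) * dm.N - 1)
            .each_row() += pb.row(b);
  }
  vec cls = as_vec(params["cls"]);
  for (int s = 0; s < dm.S; ++s) X.row(dm.n_tok() + s) = cls.t();
  return X;
}

struct ForwardState {
  mat X;
  std::vector<BlkCache> caches;
  LNCache lnf;
  mat logits, probs;
};

void run_forward(const Dims& dm, const List& params, const mat& P,
                 const Rcpp::Nullable<List>& masks, ForwardState& st) {
  st.X = embed(dm, params, P);
  List blocks = params["blocks"];
  st.caches.resize(dm.depth);
  List mlist;
  bool has_masks = masks.isNotNull();
  if (has_masks) mlist = masks.get();
  for (int l = 0; l < dm.depth; ++l) {
    Blk blk = read_blk(blocks[l]);
    List ml;
    if (has_masks) ml = List(mlist[l]);
    block_fwd(dm, blk, st.X, st.caches[l], has_masks ? &ml : nullptr);
    if (!st.X.is_finite())
      Rcpp::stop("non-finite activations after block %d", l + 1);
  }
  mat cls_rows = st.X.rows(dm.n_tok(), dm.n_rows() - 1);
  ln_fwd(cls_rows, as_vec(params["lnf_g"]), as_vec(params["lnf_b"]), st.lnf);
  st.logits = st.lnf.Y * as_mat(params["head_W"]);
  st.logits.each_row() += as_vec(params["head_b"]).t();
  st.probs = st.logits;
  softmax_rows(st.probs);
}

} // namespace

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(const arma::mat& P, List params, List dims,
                 Rcpp::Nullable<List> masks, bool capture) {
  Dims dm = read_dims(dims);
  ForwardState st;
  run_forward(dm, params, P, masks, st);
  List out = List::create(Named("logits") = st.logits,
                          Named("probs") = st.probs);
  if (capture) {
    if (dm.S != 1) Rcpp::stop("attention capture requires a single sample");
    List spat(dm.depth), spec(dm.depth);
    for (int l = 0; l < dm.depth; ++l) {
      // spatial: per band, (N+1) x (N+1) x heads (slices ordered h,s,b)
      List sb(dm.B);
      for (int b = 0; b < dm.B; ++b) {
        cube ab(dm.N + 1, dm.N + 1, dm.heads);
        for (int h = 0; h < dm.heads; ++h)
          ab.slice(h) = st.caches[l].at2.A.slice((size_t)h * dm.B + b);
        sb[b] = ab;
      }
      spat[l] = sb;
      // spectral: per position, B x B x heads
      List sn(dm.N);
      for (int n = 0; n < dm.N; ++n) {
        cube an(dm.B, dm.B, dm.heads);
        for (int h = 0; h < dm.heads; ++h)
          an.slice(h) = st.caches[l].at1.A.slice((size_t)h * dm.N + n);
        sn[n] = an;
      }
      spec[l] = sn;
    }
    out["attn"] = List::create(Named("spatial") = spat,
                               Named("spectral") = spec);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_backward")]]
List cpp_backward(const arma::mat& P, List params, List dims,
                  const arma::ivec& ys, Rcpp::Nullable<List> masks) {
  Dims dm = read_dims(dims);
  ForwardState st;
  run_forward(dm, params, P, masks, st);
  double loss = 0;
  mat dlogits = st.probs;
  for (int s = 0; s < dm.S; ++s) {
    double p = std::max(st.probs(s, ys(s) - 1), 1e-12);
    loss -= std::log(p);
    dlogits(s, ys(s) - 1) -= 1.0;
  }
  loss /= dm.S;
  dlogits /= dm.S;
  List g;
  g["head_W"] = mat(st.lnf.Y.t() * dlogits);
  g["head_b"] = vec(sum(dlogits, 0).t());
  mat dh = dlogits * as_mat(params["head_W"]).t();
  vec dg, db;
  mat dcls = ln_bwd(dh, st.lnf, as_vec(params["lnf_g"]), dg, db);
  g["lnf_g"] = dg; g["lnf_b"] = db;
  mat dX(dm.n_rows(), dm.D, fill::zeros);
  dX.rows(dm.n_tok(), dm.n_rows() - 1) = dcls;
  List blocks = params["blocks"];
  List gblocks(dm.depth);
  for (int l = dm.depth - 1; l >= 0; --l) {
    Blk blk = read_blk(blocks[l]);
    gblocks[l] = block_bwd(dm, blk, st.caches[l], dX);
  }
  g["blocks"] = gblocks;
  mat dtok = dX.rows(0, dm.n_tok() - 1);
  vec gcls(dm.D, fill::zeros);
  for (int s = 0; s < dm.S; ++s)
    gcls += dX.row(dm.n_tok() + s).t();
  g["cls"] = gcls;
  mat gpos(dm.N, dm.D, fill::zeros);
  for (int s = 0; s < dm.S; ++s)
    for (int b = 0; b < dm.B; ++b)
      gpos += dtok.rows((s * dm.B + b) * dm.N, (s * dm.B + b + 1) * dm.N - 1);
  g["pos_spatial"] = gpos;
  if (dm.band_pos) {
    mat gpb(dm.B, dm.D, fill::zeros);
    for (int s = 0; s < dm.S; ++s)
      for (int b = 0; b < dm.B; ++b)
        gpb.row(b) += sum(
            dtok.rows((s * dm.B + b) * dm.N, (s * dm.B + b + 1) * dm.N - 1), 0);
    g["pos_band"] = gpb;
  }
  g["embed_W"] = mat(P.t() * dtok);
  g["embed_b"] = vec(sum(dtok, 0).t());
  return List::create(Named("loss") = loss, Named("probs") = st.probs,
                      Named("grads") = g);
}

// [[Rcpp::export(name = ".cpp_block_forward")]]
arma::mat cpp_block_forward(const arma::mat& X, List blk_params, List dims) {
  Dims dm = read_dims(dims);
  Blk blk = read_blk(blk_params);
  mat Xw = X;
  BlkCache c;
  block_fwd(dm, blk, Xw, c, nullptr);
  return Xw;
}
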