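// Compiled kernel for the message-passing network: one call runs the
// full forward pass (and optionally the exact reverse-mode gradients)
// for a collated batch.  Mirrors the reference R implementation in
// R/gnn.R exactly; the test suite asserts numerical agreement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct MLP {
  mat W1, W2;
  rowvec b1, b2;
};

MLP get_mlp(const Rcpp::List& p) {
  MLP m;
  m.W1 = Rcpp::as<mat>(p["W1"]);
  m.b1 = Rcpp::as<rowvec>(p["b1"]);
  m.W2 = Rcpp::as<mat>(p["W2"]);
  m.b2 = Rcpp::as<rowvec>(p["b2"]);
  return m;
}

struct MLPCache {
  mat X, H1;
};

mat mlp_fwd(const MLP& p, const mat& X, MLPCache& c) {
  c.X = X;
  c.H1 = X * p.W1;
  c.H1.each_row() += p.b1;
  c.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  mat out = c.H1 * p.W2;
  out.each_row() += p.b2;
  return out;
}

struct MLPGrad {
  mat dW1, dW2;
  rowvec db1, db2;
};

mat mlp_bwd(const MLP& p, const MLPCache& c, const mat& dout, MLPGrad& g) {
  g.dW2 = c.H1.t() * dout;
  g.db2 = sum(dout, 0);
  mat dH1 = dout * p.W2.t();
  dH1.elem(find(c.H1 == 0)).zeros();
  g.dW1 = c.X.t() * dH1;
  g.db1 = sum(dH1, 0);
  return dH1 * p.W1.t();
}

Rcpp::List wrap_grad(const MLPGrad& g) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = g.dW1,
      Rcpp::Named("b1") = Rcpp::NumericVector(g.db1.begin(), g.db1.end()),
      Rcpp::Named("W2") = g.dW2,
      Rcpp::Named("b2") = Rcpp::NumericVector(g.db2.begin(), g.db2.end()));
}

mat mean_scatter(const mat& X, const ivec& g, int ng, const vec& cnt) {
  mat out(ng, X.n_cols, fill::zeros);
  for (uword i = 0; i < X.n_rows; ++i) out.row(g[i]) += X.row(i);
  for (int j = 0; j < ng; ++j)
    if (cnt[j] > 0) out.row(j) /= cnt[j];
  return out;
}

mat sum_scatter(const mat& X, const ivec& g, int ng) {
  mat out(ng, X.n_cols, fill::zeros);
  for (uword i = 0; i < X.n_rows; ++i) out.row(g[i]) += X.row(i);
  return out;
}

mat mean_unscatter(const mat& d, const ivec& g, const vec& cnt) {
  mat out(g.n_elem, d.n_cols);
  for (uword i = 0; i < g.n_elem; ++i) out.row(i) = d.row(g[i]) / cnt[g[i]];
  return out;
}

mat gather(const mat& X, const ivec& idx) {
  mat out(idx.n_elem, X.n_cols);
  for (uword i = 0; i < idx.n_elem; ++i) out.row(i) = X.row(idx[i]);
  return out;
}

struct RoundCache {
  MLPCache ce, cv, cu;
};

}  // namespace

// Forward pass, and when `want_grad` the exact gradients of the masked
// loss w.r.t. every parameter.  Index vectors in `batch` are 1-based.
// [[Rcpp::export(name = ".cpp_gnn_pass")]]
Rcpp::List cpp_gnn_pass(Rcpp::List params, Rcpp::List batch, int M,
                        bool share, std::string loss_name, bool want_grad,
                        Rcpp::NumericVector targets_std,
                        Rcpp::LogicalVector mask) {
  mat V = Rcpp::as<mat>(batch["V"]);
  mat E = Rcpp::as<mat>(batch["E"]);
  ivec s = Rcpp::as<ivec>(batch["s"]) - 1;
  ivec r = Rcpp::as<ivec>(batch["r"]) - 1;
  ivec gn = Rcpp::as<ivec>(batch["gn"]) - 1;
  ivec ge = Rcpp::as<ivec>(batch["ge"]) - 1;
  int B = Rcpp::as<int>(batch["B"]);
  int N = V.n_rows, Mq = E.n_rows;

  vec cnt_in(N, fill::zeros);
  for (int i = 0; i < Mq; ++i) cnt_in[r[i]] += 1.0;
  vec cnt_gn(B, fill::zeros);
  for (int i = 0; i < N; ++i) cnt_gn[gn[i]] += 1.0;
  vec cnt_ge(B, fill::zeros);
  for (int i = 0; i < Mq; ++i) cnt_ge[ge[i]] += 1.0;

  MLP encV = get_mlp(params["encV"]);
  MLP encE = get_mlp(params["encE"]);
  MLP readout = get_mlp(params["readout"]);
  Rcpp::List blocks_in = params["blocks"];
  int n_blocks = share ? 1 : M;
  std::vector<MLP> bedge(n_blocks), bnode(n_blocks), bglob(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    Rcpp::List bl = blocks_in[i];
    bedge[i] = get_mlp(bl["edge"]);
    bnode[i] = get_mlp(bl["node"]);
    bglob[i] = get_mlp(bl["global"]);
  }
  int h = encV.W2.n_cols;

  // ---- forward ----
  MLPCache cV, cE, cR;
  mat Vh = mlp_fwd(encV, V, cV);
  mat Eh = Mq > 0 ? mlp_fwd(encE, E, cE) : mat(0, h);
  mat U(B, h, fill::zeros);
  std::vector<RoundCache> rc(M);
  for (int t = 0; t < M; ++t) {
    int bi = share ? 0 : t;
    mat Xe = join_rows(join_rows(Eh, gather(Vh, s)),
                       join_rows(gather(Vh, r), gather(U, ge)));
    mat Enew = Mq > 0 ? mlp_fwd(bedge[bi], Xe, rc[t].ce) : mat(0, h);
    mat Ae = mean_scatter(Enew, r, N, cnt_in);
    mat Xv = join_rows(join_rows(Ae, Vh), gather(U, gn));
    mat Vnew = mlp_fwd(bnode[bi], Xv, rc[t].cv);
    mat AEg = mean_scatter(Enew, ge, B, cnt_ge);
    mat AVg = mean_scatter(Vnew, gn, B, cnt_gn);
    mat Xu = join_rows(join_rows(AEg, AVg), U);
    mat Unew = mlp_fwd(bglob[bi], Xu, rc[t].cu);
    Vh = Vnew; Eh = Enew; U = Unew;
  }
  mat pred_m = mlp_fwd(readout, Vh, cR);
  vec pred = pred_m.col(0);

  if (!want_grad) {
    return Rcpp::List::create(
        Rcpp::Named("pred") = Rcpp::NumericVector(pred.begin(), pred.end()));
  }

  // ---- loss ----
  vec tg = Rcpp::as<vec>(targets_std);
  std::vector<uword> midx;
  for (int i = 0; i < N; ++i)
    if (mask[i] == TRUE) midx.push_back(i);
  uvec idx(midx.size());
  for (size_t i = 0; i < midx.size(); ++i) idx[i] = midx[i];
  vec diff = pred.elem(idx) - tg.elem(idx);
  double nm = static_cast<double>(idx.n_elem);
  double loss;
  vec d_pred(N, fill::zeros);
  if (loss_name == "mae") {
    loss = mean(abs(diff));
    vec dsub = sign(diff) / nm;
    d_pred.elem(idx) = dsub;
  } else {
    loss = mean(square(diff));
    d_pred.elem(idx) = 2.0 * diff / nm;
  }

  // ---- backward ----
  MLPGrad gR;
  mat dV = mlp_bwd(readout, cR, mat(d_pred), gR);
  mat dE(Mq, h, fill::zeros);
  mat dU(B, h, fill::zeros);
  std::vector<MLPGrad> gedge(n_blocks), gnode(n_blocks), gglob(n_blocks);
  std::vector<bool> seen(n_blocks, false);
  auto acc = [](MLPGrad& a, const MLPGrad& g, bool first) {
    if (first) { a = g; return; }
    a.dW1 += g.dW1; a.db1 += g.db1; a.dW2 += g.dW2; a.db2 += g.db2;
  };
  for (int t = M - 1; t >= 0; --t) {
    int bi = share ? 0 : t;
    MLPGrad gu, gv, gs;
    mat dXu = mlp_bwd(bglob[bi], rc[t].cu, dU, gu);
    mat dAEg = dXu.cols(0, h - 1);
    mat dAVg = dXu.cols(h, 2 * h - 1);
    mat dUprev = dXu.cols(2 * h, 3 * h - 1);
    dV += mean_unscatter(dAVg, gn, cnt_gn);
    mat dXv = mlp_bwd(bnode[bi], rc[t].cv, dV, gv);
    mat dAe = dXv.cols(0, h - 1);
    mat dVprev = dXv.cols(h, 2 * h - 1);
    dUprev += sum_scatter(dXv.cols(2 * h, 3 * h - 1), gn, B);
    MLPGrad ge_g;
    mat dEprev(Mq, h, fill::zeros);
    if (Mq > 0) {
      dE += mean_unscatter(dAe, r, cnt_in) + mean_unscatter(dAEg, ge, cnt_ge);
      mat dXe = mlp_bwd(bedge[bi], rc[t].ce, dE, ge_g);
      dEprev = dXe.cols(0, h - 1);
      dVprev += sum_scatter(dXe.cols(h, 2 * h - 1), s, N) +
                sum_scatter(dXe.cols(2 * h, 3 * h - 1), r, N);
      dUprev += sum_scatter(dXe.cols(3 * h, 4 * h - 1), ge, B);
    } else {
      ge_g.dW1 = mat(size(bedge[bi].W1), fill::zeros);
      ge_g.db1 = rowvec(bedge[bi].b1.n_elem, fill::zeros);
      ge_g.dW2 = mat(size(bedge[bi].W2), fill::zeros);
      ge_g.db2 = rowvec(bedge[bi].b2.n_elem, fill::zeros);
    }
    acc(gedge[bi], ge_g, !seen[bi]);
    acc(gnode[bi], gv, !seen[bi]);
    acc(gglob[bi], gu, !seen[bi]);
    seen[bi] = true;
    dV = dVprev; dE = dEprev; dU = dUprev;
  }
  MLPGrad gV, gE;
  mlp_bwd(encV, cV, dV, gV);
  if (Mq > 0) {
    mlp_bwd(encE, cE, dE, gE);
  } else {
    gE.dW1 = mat(size(encE.W1), fill::zeros);
    gE.db1 = rowvec(encE.b1.n_elem, fill::zeros);
    gE.dW2 = mat(size(encE.W2), fill::zeros);
    gE.db2 = rowvec(encE.b2.n_elem, fill::zeros);
  }

  Rcpp::List blocks_out(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    blocks_out[i] = Rcpp::List::create(
        Rcpp::Named("edge") = wrap_grad(gedge[i]),
        Rcpp::Named("node") = wrap_grad(gnode[i]),
        Rcpp::Named("global") = wrap_grad(gglob[i]));
  }
  return Rcpp::List::create(
      Rcpp::Named("pred") = Rcpp::NumericVector(pred.begin(), pred.end()),
      Rcpp::Named("loss") = loss,
      Rcpp::Named("n") = nm,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("encV") = wrap_grad(gV),
          Rcpp::Named("encE") = wrap_grad(gE),
          Rcpp::Named("blocks") = blocks_out,
          Rcpp::Named("readout") = wrap_grad(gR)));
}
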