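// Compiled core of the SE(3)-invariant attention backbone.
//
// This is a line-for-line port of the reference R implementation in
// R/backbone.R (backbone_pass / backbone_bwd); the two are cross-checked
// numerically in the test suite.  All conventions (row 0 = virtual node,
// RMS normalization with eps = 1e-6, bias construction order) match the R
// code exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

// Read-only, zero-copy views onto R objects (never resized or written).
static mat vmat(SEXP x) {
  NumericMatrix m(x);
  return mat(m.begin(), m.nrow(), m.ncol(), false);
}
static vec vvec(SEXP x) {
  NumericVector v(x);
  return vec(v.begin(), v.size(), false);
}
static rowvec vrow(SEXP x) {
  NumericVector v(x);
  return rowvec(v.begin(), v.size(), false);
}
static arma::cube vcube(SEXP x) {
  NumericVector v(x);
  IntegerVector d = v.attr("dim");
  return arma::cube(v.begin(), d[0], d[1], d[2], false);
}

static mat relu_of(const mat& X) {
  mat Y = X;
  Y.elem(arma::find(Y < 0)).zeros();
  return Y;
}

static mat add_rowvec(mat X, const rowvec& b) {
  X.each_row() += b;
  return X;
}

static mat rms_fwd(const mat& X, const rowvec& g, vec& r_out) {
  vec r = arma::sqrt(arma::mean(arma::square(X), 1) + 1e-6);
  mat Y = X.each_col() / r;
  Y.each_row() %= g;
  r_out = r;
  return Y;
}

static mat rms_bwd(const mat& dY, const mat& X, const rowvec& g, const vec& r,
                   rowvec& dg_out) {
  const double W = (double)X.n_cols;
  mat gd = dY;
  gd.each_row() %= g;
  vec s = arma::sum(gd % X, 1);
  mat dX = gd.each_col() / r;
  dX -= X.each_col() % (s / (W * arma::pow(r, 3)));
  dg_out = arma::sum(dY % (X.each_col() / r), 0);
  return dX;
}

static void pair_geometry(const mat& coords, const vec& centers, double sigma,
                          mat& G, mat& Ux, mat& Uy, mat& Uz) {
  const arma::uword n = coords.n_rows;
  mat D(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = i + 1; j < n; ++j) {
      double d = arma::norm(coords.row(i) - coords.row(j), 2);
      D(i, j) = d; D(j, i) = d;
    }
  const arma::uword K = centers.n_elem;
  G.set_size(n * n, K);
  const double denom = 2.0 * sigma * sigma;
  for (arma::uword k = 0; k < K; ++k) {
    mat E = arma::exp(-arma::square(D - centers(k)) / denom);
    E.diag().zeros();
    G.col(k) = arma::vectorise(E);
  }
  mat Dsafe = D;
  Dsafe.diag().ones();
  Ux.set_size(n, n); Uy.set_size(n, n); Uz.set_size(n, n);
  for (arma::uword j = 0; j < n; ++j)
    for (arma::uword i = 0; i < n; ++i) {
      Ux(i, j) = (coords(i, 0) - coords(j, 0)) / Dsafe(i, j);
      Uy(i, j) = (coords(i, 1) - coords(j, 1)) / Dsafe(i, j);
      Uz(i, j) = (coords(i, 2) - coords(j, 2)) / Dsafe(i, j);
    }
  Ux.diag().zeros(); Uy.diag().zeros(); Uz.diag().zeros();
}

static mat softmax_rows(mat S) {
  vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
  return S;
}

// [[Rcpp::export(name = ".cpp_backbone_pass")]]
List cpp_backbone_pass(IntegerVector el_idx, IntegerVector deg,
                       IntegerVector ring, NumericVector fvec,
                       IntegerMatrix sp_idx, NumericMatrix coords_in,
                       List params, List config, Nullable<NumericVector> vextra,
                       bool keep_cache) {
  const int n = coords_in.nrow();
  const int W = as<int>(config["width"]);
  const int L = as<int>(config["layers"]);
  const int nh = as<int>(config["heads"]);
  const int dh = W / nh;
  const double sdh = std::sqrt((double)dh);
  List pair = config["pair"];
  vec centers = vvec(pair["centers"]);
  double sigma = as<double>(pair["sigma"]);
  const int M = n + 1;

  mat coords(coords_in.begin(), n, 3);
  mat G, Ux, Uy, Uz;
  pair_geometry(coords, centers, sigma, G, Ux, Uy, Uz);

  mat emb_el = vmat(params["emb_el"]);
  mat emb_deg = vmat(params["emb_deg"]);
  mat emb_ring = vmat(params["emb_ring"]);
  mat virt_W = vmat(params["virt_W"]);
  vec virt_b = vvec(params["virt_b"]);
  vec fv = vvec(fvec);

  // per-atom radial distribution over the Gaussian basis
  mat W_rdf = vmat(params["W_rdf"]);
  mat rdf(n, G.n_cols, arma::fill::zeros);
  for (arma::uword k = 0; k < G.n_cols; ++k) {
    mat Gk(G.colptr(k), n, n);
    rdf.col(k) = arma::sum(Gk, 1);
  }
  mat Hrdf = rdf * W_rdf;

  mat H(M, W);
  H.row(0) = virt_b.t() + fv.t() * virt_W;
  if (vextra.isNotNull()) H.row(0) += as<vec>(vextra.get()).t();
  for (int i = 0; i < n; ++i)
    H.row(i + 1) = emb_el.row(el_idx[i] - 1) + emb_deg.row(deg[i]) +
      emb_ring.row(ring[i]) + Hrdf.row(i);

  List layer_params = params["layers"];
  List caches(L);
  for (int l = 0; l < L; ++l) {
    List p = layer_params[l];
    rowvec g1 = vrow(p["g1"]), g2 = vrow(p["g2"]);
    mat Wq = vmat(p["Wq"]), Wk = vmat(p["Wk"]), Wv = vmat(p["Wv"]);
    rowvec bq = vrow(p["bq"]), bk = vrow(p["bk"]),
      bv = vrow(p["bv"]);
    mat Wo = vmat(p["Wo"]);
    rowvec bo = vrow(p["bo"]);
    mat Wg = vmat(p["Wg"]);
    mat sp_emb = vmat(p["sp_emb"]);
    vec vb_from = vvec(p["vb_from"]), vb_to = vvec(p["vb_to"]);
    mat Wf1 = vmat(p["Wf1"]), Wf2 = vmat(p["Wf2"]);
    rowvec bf1 = vrow(p["bf1"]), bf2 = vrow(p["bf2"]);

    vec r1;
    mat Hn = rms_fwd(H, g1, r1);
    mat Q = add_rowvec(Hn * Wq, bq);
    mat Km = add_rowvec(Hn * Wk, bk);
    mat Vm = add_rowvec(Hn * Wv, bv);
    mat GB = G * Wg;                     // (n*n) x nh
    mat O(M, W);
    arma::cube Pcube(M, M, nh);
    for (int h = 0; h < nh; ++h) {
      mat B(M, M, arma::fill::zeros);
      mat Breal(GB.colptr(h), n, n);     // view on column h
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          B(i + 1, j + 1) = Breal(i, j) + sp_emb(sp_idx(i, j) - 1, h);
      for (int j = 1; j < M; ++j) B(0, j) = vb_from(h);
      for (int i = 0; i < M; ++i) B(i, 0) = vb_to(h);
      mat Qh = Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = Km.cols(h * dh, (h + 1) * dh - 1);
      mat S = Qh * Kh.t() / sdh + B;
      mat P = softmax_rows(S);
      O.cols(h * dh, (h + 1) * dh - 1) = P * Vm.cols(h * dh, (h + 1) * dh - 1);
      Pcube.slice(h) = P;
    }
    mat attn = add_rowvec(O * Wo, bo);
    mat H1 = H + attn;
    vec r2;
    mat Hn2 = rms_fwd(H1, g2, r2);
    mat Fpre = add_rowvec(Hn2 * Wf1, bf1);
    mat Fh = relu_of(Fpre);
    mat H2 = H1 + add_rowvec(Fh * Wf2, bf2);
    if (!H2.is_finite())
      stop("non-finite activation in backbone layer %d", l + 1);
    if (keep_cache)
      caches[l] = List::create(_["Hin"] = H, _["Hn"] = Hn, _["r1"] = r1,
                               _["Q"] = Q, _["K"] = Km, _["V"] = Vm,
                               _["P"] = Pcube, _["O"] = O, _["H1"] = H1,
                               _["Hn2"] = Hn2, _["r2"] = r2,
                               _["Fpre"] = Fpre, _["Fh"] = Fh);
    H = H2;
  }

  rowvec gf = vrow(params["gf"]);
  vec rF;
  mat HF = rms_fwd(H, gf, rF);
  vec virtual_emb = HF.row(0).t();
  mat atom_emb = HF.rows(1, M - 1);

  mat disp(n, 3, arma::fill::zeros);
  mat Cpre, Crelu;
  if (n > 1) {
    mat Wc_a = vmat(params["Wc_a"]), Wc_b = vmat(params["Wc_b"]),
      Wc_g = vmat(params["Wc_g"]);
    rowvec bc = vrow(params["bc"]);
    vec wc2 = vvec(params["wc2"]);
    mat Ap = atom_emb * Wc_a;
    mat Bp = atom_emb * Wc_b;
    mat Gp = G * Wc_g;
    const int dc = Ap.n_cols;
    Cpre.set_size(n * n, dc);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        Cpre.row(i + j * n) = Ap.row(i) + Bp.row(j) + Gp.row(i + j * n) + bc;
    Crelu = relu_of(Cpre);
    vec cv = Crelu * wc2;
    mat Cm(cv.memptr(), n, n);
    Cm.diag().zeros();
    disp.col(0) = arma::sum(Cm % Ux, 1);
    disp.col(1) = arma::sum(Cm % Uy, 1);
    disp.col(2) = arma::sum(Cm % Uz, 1);
  }

  List out = List::create(_["virtual"] = virtual_emb, _["atom_emb"] = atom_emb,
                          _["displacement"] = disp);
  if (keep_cache)
    out["cache"] = List::create(_["G"] = G, _["rdf"] = rdf,
                                _["Ux"] = Ux, _["Uy"] = Uy,
                                _["Uz"] = Uz, _["layers"] = caches,
                                _["Hlast"] = H, _["rF"] = rF, _["HF"] = HF,
                                _["Cpre"] = Cpre, _["Crelu"] = Crelu,
                                _["sp_idx"] = sp_idx, _["n"] = n);
  return out;
}

// [[Rcpp::export(name = ".cpp_backbone_bwd")]]
List cpp_backbone_bwd(Nullable<NumericVector> dvirtual_in,
                      Nullable<NumericMatrix> datom_in,
                      Nullable<NumericMatrix> ddisp_in, List cache,
                      IntegerVector el_idx, IntegerVector deg,
                      IntegerVector ring, NumericVector fvec, List params,
                      List config) {
  const int n = as<int>(cache["n"]);
  const int W = as<int>(config["width"]);
  const int L = as<int>(config["layers"]);
  const int nh = as<int>(config["heads"]);
  const int dh = W / nh;
  const double sdh = std::sqrt((double)dh);
  const int M = n + 1;
  const int nspb = as<int>(config["sp_buckets"]);

  mat G = vmat(cache["G"]);
  mat HF = vmat(cache["HF"]);
  mat Hlast = vmat(cache["Hlast"]);
  vec rF = vvec(cache["rF"]);
  IntegerMatrix sp_idx = as<IntegerMatrix>(cache["sp_idx"]);

  mat dAtom(n, W, arma::fill::zeros);
  // explicit deep copy: dAtom is accumulated into below and must never
  // alias the caller's R matrix
  if (datom_in.isNotNull()) dAtom = as<mat>(datom_in.get());

  List gcoord = List::create(
    _["Wc_a"] = NumericMatrix(W, vmat(params["Wc_a"]).n_cols),
    _["Wc_b"] = NumericMatrix(W, vmat(params["Wc_b"]).n_cols),
    _["Wc_g"] = NumericMatrix(G.n_cols, vmat(params["Wc_g"]).n_cols),
    _["bc"] = NumericVector(vrow(params["bc"]).n_elem),
    _["wc2"] = NumericVector(as<vec>(params["wc2"]).n_elem));

  if (ddisp_in.isNotNull() && n > 1) {
    mat ddisp = vmat(ddisp_in.get());
    if (arma::any(arma::vectorise(ddisp) != 0)) {
      mat Ux = vmat(cache["Ux"]), Uy = vmat(cache["Uy"]),
        Uz = vmat(cache["Uz"]);
      mat Cpre = vmat(cache["Cpre"]), Crelu = vmat(cache["Crelu"]);
      vec wc2 = vvec(params["wc2"]);
      mat Wc_a = vmat(params["Wc_a"]), Wc_b = vmat(params["Wc_b"]);
      mat dC = Ux.each_col() % ddisp.col(0);
      dC += Uy.each_col() % ddisp.col(1);
      dC += Uz.each_col() % ddisp.col(2);
      dC.diag().zeros();
      vec dcv = arma::vectorise(dC);
      vec gwc2 = Crelu.t() * dcv;
      mat dCpre = dcv * wc2.t();
      dCpre.elem(arma::find(Cpre <= 0)).zeros();
      rowvec gbc = arma::sum(dCpre, 0);
      mat gWc_g = G.t() * dCpre;
      const int dc = dCpre.n_cols;
      mat dAp(n, dc, arma::fill::zeros), dBp(n, dc, arma::fill::zeros);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          dAp.row(i) += dCpre.row(i + j * n);
          dBp.row(j) += dCpre.row(i + j * n);
        }
      mat atom_emb = HF.rows(1, M - 1);
      gcoord["Wc_a"] = wrap(mat(atom_emb.t() * dAp));
      gcoord["Wc_b"] = wrap(mat(atom_emb.t() * dBp));
      gcoord["Wc_g"] = wrap(gWc_g);
      gcoord["bc"] = wrap(gbc);
      gcoord["wc2"] = wrap(gwc2);
      dAtom += dAp * Wc_a.t() + dBp * Wc_b.t();
    }
  }

  mat dHF(M, W, arma::fill::zeros);
  if (dvirtual_in.isNotNull()) dHF.row(0) = as<vec>(dvirtual_in.get()).t();
  dHF.rows(1, M - 1) = dAtom;
  rowvec gf = vrow(params["gf"]);
  rowvec dgf;
  mat dH = rms_bwd(dHF, Hlast, gf, rF, dgf);

  List layer_params = params["layers"];
  List layer_caches = cache["layers"];
  List glayers(L);
  for (int l = L - 1; l >= 0; --l) {
    List p = layer_params[l];
    List lc = layer_caches[l];
    mat Wq = vmat(p["Wq"]), Wk = vmat(p["Wk"]), Wv = vmat(p["Wv"]);
    mat Wo = vmat(p["Wo"]);
    mat Wf1 = vmat(p["Wf1"]), Wf2 = vmat(p["Wf2"]);
    rowvec g1 = vrow(p["g1"]), g2 = vrow(p["g2"]);
    mat Hin = vmat(lc["Hin"]), Hn = vmat(lc["Hn"]);
    vec r1 = vvec(lc["r1"]), r2 = vvec(lc["r2"]);
    mat Q = vmat(lc["Q"]), Km = vmat(lc["K"]), Vm = vmat(lc["V"]);
    arma::cube Pcube = vcube(lc["P"]);
    mat O = vmat(lc["O"]), H1 = vmat(lc["H1"]), Hn2 = vmat(lc["Hn2"]);
    mat Fpre = vmat(lc["Fpre"]), Fh = vmat(lc["Fh"]);

    mat dFh = dH * Wf2.t();
    mat gWf2 = Fh.t() * dH;
    rowvec gbf2 = arma::sum(dH, 0);
    mat dFpre = dFh;
    dFpre.elem(arma::find(Fpre <= 0)).zeros();
    mat gWf1 = Hn2.t() * dFpre;
    rowvec gbf1 = arma::sum(dFpre, 0);
    mat dHn2 = dFpre * Wf1.t();
    rowvec gg2;
    mat dH1 = dH + rms_bwd(dHn2, H1, g2, r2, gg2);

    mat dO = dH1 * Wo.t();
    mat gWo = O.t() * dH1;
    rowvec gbo = arma::sum(dH1, 0);
    mat dQ(M, W, arma::fill::zeros), dK(M, W, arma::fill::zeros),
      dV(M, W, arma::fill::zeros);
    mat dGB(n * n, nh, arma::fill::zeros);
    mat gsp(nspb, nh, arma::fill::zeros);
    vec gvb_from(nh, arma::fill::zeros), gvb_to(nh, arma::fill::zeros);
    for (int h = 0; h < nh; ++h) {
      mat P = Pcube.slice(h);
      mat dOh = dO.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = Vm.cols(h * dh, (h + 1) * dh - 1);
      mat dP = dOh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = P.t() * dOh;
      vec rs = arma::sum(dP % P, 1);
      mat dPc = dP;
      dPc.each_col() -= rs;
      mat dS = P % dPc;
      dQ.cols(h * dh, (h + 1) * dh - 1) =
        dS * Km.cols(h * dh, (h + 1) * dh - 1) / sdh;
      dK.cols(h * dh, (h + 1) * dh - 1) =
        dS.t() * Q.cols(h * dh, (h + 1) * dh - 1) / sdh;
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          double v = dS(i + 1, j + 1);
          dGB(i + j * n, h) = v;
          gsp(sp_idx(i, j) - 1, h) += v;
        }
      double sfrom = 0;
      for (int j = 1; j < M; ++j) sfrom += dS(0, j);
      gvb_from(h) = sfrom;
      gvb_to(h) = arma::accu(dS.col(0));
    }
    mat gWg = G.t() * dGB;
    mat dHn = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    rowvec gg1;
    mat dHn_b = rms_bwd(dHn, Hin, g1, r1, gg1);
    glayers[l] = List::create(
      _["g1"] = wrap(gg1), _["g2"] = wrap(gg2),
      _["Wq"] = wrap(mat(Hn.t() * dQ)), _["bq"] = wrap(rowvec(arma::sum(dQ, 0))),
      _["Wk"] = wrap(mat(Hn.t() * dK)), _["bk"] = wrap(rowvec(arma::sum(dK, 0))),
      _["Wv"] = wrap(mat(Hn.t() * dV)), _["bv"] = wrap(rowvec(arma::sum(dV, 0))),
      _["Wo"] = wrap(gWo), _["bo"] = wrap(gbo),
      _["Wg"] = wrap(gWg), _["sp_emb"] = wrap(gsp),
      _["vb_from"] = wrap(gvb_from), _["vb_to"] = wrap(gvb_to),
      _["Wf1"] = wrap(gWf1), _["bf1"] = wrap(gbf1),
      _["Wf2"] = wrap(gWf2), _["bf2"] = wrap(gbf2));
    dH = dH1 + dHn_b;
  }

  vec fv = vvec(fvec);
  mat rdf = vmat(cache["rdf"]);
  rowvec dvirt = dH.row(0);
  mat gvirt_W = fv * dvirt;
  mat gemb_el(vmat(params["emb_el"]).n_rows, W, arma::fill::zeros);
  mat gemb_deg(7, W, arma::fill::zeros);
  mat gemb_ring(2, W, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    gemb_el.row(el_idx[i] - 1) += dH.row(i + 1);
    gemb_deg.row(deg[i]) += dH.row(i + 1);
    gemb_ring.row(ring[i]) += dH.row(i + 1);
  }
  mat gW_rdf = rdf.t() * dH.rows(1, M - 1);

  List grads = List::create(
    _["emb_el"] = wrap(gemb_el), _["emb_deg"] = wrap(gemb_deg),
    _["emb_ring"] = wrap(gemb_ring), _["W_rdf"] = wrap(gW_rdf),
    _["virt_W"] = wrap(gvirt_W),
    _["virt_b"] = wrap(vec(dvirt.t())), _["layers"] = glayers,
    _["gf"] = wrap(dgf), _["Wc_a"] = gcoord["Wc_a"],
    _["Wc_b"] = gcoord["Wc_b"], _["Wc_g"] = gcoord["Wc_g"],
    _["bc"] = gcoord["bc"], _["wc2"] = gcoord["wc2"]);
  return List::create(_["grads"] = grads,
                      _["dvirtual_extra"] = wrap(vec(dvirt.t())));
}
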