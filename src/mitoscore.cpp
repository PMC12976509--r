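// Core numerics: 8-connected component labeling, Moore boundary tracing,
// and a compact residual CNN (im2col convolutions, Adam-ready gradients).
// The CNN is deliberately small: single-channel microscopy patches are
// low-entropy compared to natural images, and desk-scale training runs on
// one CPU core.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 8-connected component labeling (union-find)
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const NumericMatrix &img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) == 0) continue;
      // neighbors already visited in column-major order:
      // (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int r = nb[k][0], c = nb[k][1];
        if (r < 0 || r >= nr || c < 0) continue;
        int l = lab(r, c);
        if (l > 0) lmin = (lmin == 0) ? l : std::min(lmin, l);
      }
      if (lmin == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k) {
          int r = nb[k][0], c = nb[k][1];
          if (r < 0 || r >= nr || c < 0) continue;
          if (lab(r, c) > 0) uf_union(parent, lmin, lab(r, c));
        }
      }
    }
  }
  // flatten labels to 1..K
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = uf_find(parent, lab(i, j));
        if (remap[r] == 0) remap[r] = ++k;
        lab(i, j) = remap[r];
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Moore-neighbor boundary tracing of a single binary object.
// Returns 0-based (row, col) boundary pixel chain, clockwise.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".boundary_chain")]]
IntegerMatrix boundary_chain(const IntegerMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return mask(i, j) != 0;
  };
  // find start: first foreground pixel in column-major scan
  int si = -1, sj = -1;
  for (int j = 0; j < nc && si < 0; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) != 0) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // Moore neighborhood, clockwise starting from W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> rows, cols;
  int ci = si, cj = sj;
  int backtrack = 0;  // came from W (scan direction guarantees W is background)
  rows.push_back(ci); cols.push_back(cj);
  for (int guard = 0; guard < 4 * nr * nc + 8; ++guard) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int dir = (backtrack + k) % 8;
      int ni = ci + dr[dir], nj = cj + dc[dir];
      if (at(ni, nj)) { found = dir; ci = ni; cj = nj; break; }
    }
    if (found < 0) break;  // isolated pixel
    if (ci == si && cj == sj) break;
    rows.push_back(ci); cols.push_back(cj);
    // new backtrack: direction pointing to the previous pixel, advanced by one
    backtrack = (found + 5) % 8;
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Compact residual CNN
//
// Architecture (input S x S x 1, S divisible by 8, base width w, K classes):
//   stem : conv3x3(1 -> w), relu, maxpool2          -> S/2
//   res A: conv3x3(w -> w), relu, conv3x3(w -> w), +identity, relu, maxpool2
//   res B: conv3x3(w -> 2w), relu, conv3x3(2w -> 2w), +conv1x1(w -> 2w), relu,
//          maxpool2
//   head : global average pool -> dense(2w -> K) -> softmax
// ---------------------------------------------------------------------------

static arma::mat im2col3(const arma::cube &X) {
  // 3x3, stride 1, zero pad 1. X: H x W x C -> (9C) x (H*W)
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::mat col(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat &x = X.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ki;
            if (si < 0 || si >= H) continue;
            col(krow, j * H + i) = x(si, sj);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im3(const arma::mat &col, int H, int W, int C) {
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat &x = X.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ki;
            if (si < 0 || si >= H) continue;
            x(si, sj) += col(krow, j * H + i);
          }
        }
      }
    }
  }
  return X;
}

static arma::cube conv3(const arma::cube &X, const arma::mat &Wt,
                        const arma::vec &b, arma::mat &col_out) {
  const int H = X.n_rows, W = X.n_cols;
  col_out = im2col3(X);
  arma::mat Y = Wt * col_out;          // F x (H*W)
  Y.each_col() += b;
  arma::cube out(H, W, Wt.n_rows);
  for (arma::uword f = 0; f < Wt.n_rows; ++f)
    out.slice(f) = arma::reshape(Y.row(f), H, W);
  return out;
}

static arma::cube pool2(const arma::cube &X, arma::ucube &argmax) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  arma::cube Y(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300; unsigned bk = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = X(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bk = dj * 2 + di; }
          }
        Y(i, j, c) = best;
        argmax(i, j, c) = bk;
      }
  return Y;
}

static arma::cube unpool2(const arma::cube &dY, const arma::ucube &argmax,
                          int H, int W) {
  const int C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned j = 0; j < dY.n_cols; ++j)
      for (unsigned i = 0; i < dY.n_rows; ++i) {
        unsigned bk = argmax(i, j, c);
        dX(2 * i + bk % 2, 2 * j + bk / 2, c) = dY(i, j, c);
      }
  return dX;
}

static arma::mat cube_to_mat(const arma::cube &X) {
  // C x (H*W)
  arma::mat M(X.n_slices, X.n_rows * X.n_cols);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    M.row(c) = arma::vectorise(X.slice(c)).t();
  return M;
}

static arma::cube mat_to_cube(const arma::mat &M, int H, int W) {
  arma::cube X(H, W, M.n_rows);
  for (arma::uword c = 0; c < M.n_rows; ++c)
    X.slice(c) = arma::reshape(M.row(c), H, W);
  return X;
}

struct CNNWeights {
  arma::mat W1, Wa1, Wa2, Wb1, Wb2, Wsc, Wfc;
  arma::vec b1, ba1, ba2, bb1, bb2, bsc, bfc;
};

static CNNWeights unpack(const List &w) {
  CNNWeights W;
  W.W1 = as<arma::mat>(w["W1"]);   W.b1 = as<arma::vec>(w["b1"]);
  W.Wa1 = as<arma::mat>(w["Wa1"]); W.ba1 = as<arma::vec>(w["ba1"]);
  W.Wa2 = as<arma::mat>(w["Wa2"]); W.ba2 = as<arma::vec>(w["ba2"]);
  W.Wb1 = as<arma::mat>(w["Wb1"]); W.bb1 = as<arma::vec>(w["bb1"]);
  W.Wb2 = as<arma::mat>(w["Wb2"]); W.bb2 = as<arma::vec>(w["bb2"]);
  W.Wsc = as<arma::mat>(w["Wsc"]); W.bsc = as<arma::vec>(w["bsc"]);
  W.Wfc = as<arma::mat>(w["Wfc"]); W.bfc = as<arma::vec>(w["bfc"]);
  return W;
}

struct FwdState {
  arma::cube x0, c1, p1, a1r, r1, p2, b1r, b2, sc, r2;
  arma::mat col1, cola1, cola2, colb1, colb2, p2mat;
  arma::ucube am1, am2, am3;
  arma::vec feat, probs;
};

static void forward_one(const CNNWeights &W, const arma::mat &img,
                        FwdState &S) {
  const int sz = img.n_rows;
  S.x0 = arma::cube(sz, sz, 1);
  S.x0.slice(0) = img;
  S.c1 = conv3(S.x0, W.W1, W.b1, S.col1);
  S.c1.transform([](double v) { return v > 0 ? v : 0.0; });
  S.p1 = pool2(S.c1, S.am1);
  // residual block A
  S.a1r = conv3(S.p1, W.Wa1, W.ba1, S.cola1);
  S.a1r.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::cube a2 = conv3(S.a1r, W.Wa2, W.ba2, S.cola2);
  S.r1 = a2 + S.p1;
  S.r1.transform([](double v) { return v > 0 ? v : 0.0; });
  S.p2 = pool2(S.r1, S.am2);
  // residual block B (widening, 1x1 shortcut)
  S.b1r = conv3(S.p2, W.Wb1, W.bb1, S.colb1);
  S.b1r.transform([](double v) { return v > 0 ? v : 0.0; });
  S.b2 = conv3(S.b1r, W.Wb2, W.bb2, S.colb2);
  S.p2mat = cube_to_mat(S.p2);
  arma::mat scm = W.Wsc * S.p2mat;
  scm.each_col() += W.bsc;
  S.sc = mat_to_cube(scm, S.p2.n_rows, S.p2.n_cols);
  S.r2 = S.b2 + S.sc;
  S.r2.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::ucube am3;
  arma::cube p3 = pool2(S.r2, S.am3);
  // global average pool
  S.feat.set_size(p3.n_slices);
  for (arma::uword c = 0; c < p3.n_slices; ++c)
    S.feat(c) = arma::accu(p3.slice(c)) / (p3.n_rows * p3.n_cols);
  arma::vec logits = W.Wfc * S.feat + W.bfc;
  logits -= logits.max();
  S.probs = arma::exp(logits);
  S.probs /= arma::accu(S.probs);
}

// [[Rcpp::export(name = ".cnn_forward")]]
NumericMatrix cnn_forward(const List &weights, const arma::cube &X) {
  CNNWeights W = unpack(weights);
  const int n = X.n_slices;
  FwdState S;
  NumericMatrix out(n, W.Wfc.n_rows);
  for (int s = 0; s < n; ++s) {
    forward_one(W, X.slice(s), S);
    for (arma::uword k = 0; k < S.probs.n_elem; ++k) out(s, k) = S.probs(k);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_grad")]]
List cnn_grad(const List &weights, const arma::cube &X,
              const IntegerVector &y) {
  CNNWeights W = unpack(weights);
  const int n = X.n_slices;
  CNNWeights G;
  G.W1.zeros(arma::size(W.W1));   G.b1.zeros(arma::size(W.b1));
  G.Wa1.zeros(arma::size(W.Wa1)); G.ba1.zeros(arma::size(W.ba1));
  G.Wa2.zeros(arma::size(W.Wa2)); G.ba2.zeros(arma::size(W.ba2));
  G.Wb1.zeros(arma::size(W.Wb1)); G.bb1.zeros(arma::size(W.bb1));
  G.Wb2.zeros(arma::size(W.Wb2)); G.bb2.zeros(arma::size(W.bb2));
  G.Wsc.zeros(arma::size(W.Wsc)); G.bsc.zeros(arma::size(W.bsc));
  G.Wfc.zeros(arma::size(W.Wfc)); G.bfc.zeros(arma::size(W.bfc));
  double loss = 0; int ncorrect = 0;
  FwdState S;
  for (int s = 0; s < n; ++s) {
    forward_one(W, X.slice(s), S);
    const int yi = y[s];
    loss += -std::log(std::max(S.probs(yi), 1e-12));
    if ((int)S.probs.index_max() == yi) ++ncorrect;
    // dLogits
    arma::vec dlog = S.probs;
    dlog(yi) -= 1.0;
    G.Wfc += dlog * S.feat.t();
    G.bfc += dlog;
    arma::vec dfeat = W.Wfc.t() * dlog;
    // back through GAP + pool3
    const int H3 = S.r2.n_rows / 2, W3 = S.r2.n_cols / 2;
    arma::cube dp3(H3, W3, dfeat.n_elem);
    for (arma::uword c = 0; c < dfeat.n_elem; ++c)
      dp3.slice(c).fill(dfeat(c) / (H3 * W3));
    arma::cube dr2 = unpool2(dp3, S.am3, S.r2.n_rows, S.r2.n_cols);
    for (arma::uword e = 0; e < dr2.n_elem; ++e)
      if (S.r2(e) <= 0) dr2(e) = 0;
    // r2 = b2 + sc
    // shortcut path
    arma::mat dr2m = cube_to_mat(dr2);
    G.Wsc += dr2m * S.p2mat.t();
    G.bsc += arma::sum(dr2m, 1);
    arma::mat dp2m_sc = W.Wsc.t() * dr2m;
    // main path: b2 = conv3(b1r, Wb2)
    G.Wb2 += dr2m * S.colb2.t();
    G.bb2 += arma::sum(dr2m, 1);
    arma::mat dcolb2 = W.Wb2.t() * dr2m;
    arma::cube db1r = col2im3(dcolb2, S.b1r.n_rows, S.b1r.n_cols,
                              S.b1r.n_slices);
    for (arma::uword e = 0; e < db1r.n_elem; ++e)
      if (S.b1r(e) <= 0) db1r(e) = 0;
    arma::mat db1m = cube_to_mat(db1r);
    G.Wb1 += db1m * S.colb1.t();
    G.bb1 += arma::sum(db1m, 1);
    arma::mat dcolb1 = W.Wb1.t() * db1m;
    arma::cube dp2 = col2im3(dcolb1, S.p2.n_rows, S.p2.n_cols, S.p2.n_slices);
    dp2 += mat_to_cube(dp2m_sc, S.p2.n_rows, S.p2.n_cols);
    // through pool2 and residual block A
    arma::cube dr1 = unpool2(dp2, S.am2, S.r1.n_rows, S.r1.n_cols);
    for (arma::uword e = 0; e < dr1.n_elem; ++e)
      if (S.r1(e) <= 0) dr1(e) = 0;
    // r1 = a2 + p1 (identity shortcut): dp1 gets dr1 directly plus conv path
    arma::mat dr1m = cube_to_mat(dr1);
    G.Wa2 += dr1m * S.cola2.t();
    G.ba2 += arma::sum(dr1m, 1);
    arma::mat dcola2 = W.Wa2.t() * dr1m;
    arma::cube da1 = col2im3(dcola2, S.a1r.n_rows, S.a1r.n_cols,
                             S.a1r.n_slices);
    for (arma::uword e = 0; e < da1.n_elem; ++e)
      if (S.a1r(e) <= 0) da1(e) = 0;
    arma::mat da1m = cube_to_mat(da1);
    G.Wa1 += da1m * S.cola1.t();
    G.ba1 += arma::sum(da1m, 1);
    arma::mat dcola1 = W.Wa1.t() * da1m;
    arma::cube dp1 = col2im3(dcola1, S.p1.n_rows, S.p1.n_cols, S.p1.n_slices);
    dp1 += dr1;  // identity shortcut
    // stem
    arma::cube dc1 = unpool2(dp1, S.am1, S.c1.n_rows, S.c1.n_cols);
    for (arma::uword e = 0; e < dc1.n_elem; ++e)
      if (S.c1(e) <= 0) dc1(e) = 0;
    arma::mat dc1m = cube_to_mat(dc1);
    G.W1 += dc1m * S.col1.t();
    G.b1 += arma::sum(dc1m, 1);
  }
  const double inv = 1.0 / n;
  return List::create(
      _["loss"] = loss * inv, _["acc"] = (double)ncorrect * inv,
      _["grads"] = List::create(
          _["W1"] = G.W1 * inv, _["b1"] = G.b1 * inv,
          _["Wa1"] = G.Wa1 * inv, _["ba1"] = G.ba1 * inv,
          _["Wa2"] = G.Wa2 * inv, _["ba2"] = G.ba2 * inv,
          _["Wb1"] = G.Wb1 * inv, _["bb1"] = G.bb1 * inv,
          _["Wb2"] = G.Wb2 * inv, _["bb2"] = G.bb2 * inv,
          _["Wsc"] = G.Wsc * inv, _["bsc"] = G.bsc * inv,
          _["Wfc"] = G.Wfc * inv, _["bfc"] = G.bfc * inv));
}
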