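// Compiled kernels for plumfw: binary morphology, connected-component
// labelling, and an SMO solver for the epsilon-SVR dual.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Binary erosion/dilation of a logical matrix with an arbitrary structuring
// element given as integer offsets (dy, dx) relative to the origin.
// op = 0: erode, op = 1: dilate. Pixels outside the frame count as background.
// [[Rcpp::export(name = ".cpp_binary_morph")]]
LogicalMatrix cpp_binary_morph(const LogicalMatrix& mask,
                               const IntegerMatrix& offsets,
                               int op) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool val = (op == 0);
      for (int s = 0; s < k; ++s) {
        const int ii = i + offsets(s, 0), jj = j + offsets(s, 1);
        const bool in = (ii >= 0 && ii < nr && jj >= 0 && jj < nc);
        const bool fg = in && mask(ii, jj);
        if (op == 0) {          // erosion: every offset must be foreground
          if (!fg) { val = false; break; }
        } else {                // dilation: any offset foreground suffices
          if (fg) { val = true; break; }
        }
      }
      out(i, j) = val;
    }
  }
  return out;
}

// Connected-component labelling (BFS), connectivity 4 or 8.
// Returns an integer matrix with 0 = background, components numbered 1..K.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int s = 0; s < nn; ++s) {
          const int ii = ci + dy[s], jj = cj + dx[s];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// SMO solver for the epsilon-insensitive SVR dual, LIBSVM-style 2n
// formulation.  Variables x[t], t = 0..2n-1: t < n are the alpha block
// (sign +1), t >= n the alpha* block (sign -1); beta_i = x[i] - x[n+i].
//
//   min  1/2 sum_{t,u} s_t s_u x_t x_u K_{p(t)p(u)} + sum_t p_t x_t
//   s.t. sum_t s_t x_t = 0,  0 <= x_t <= C
//
// with p_t = eps - y_t (alpha block), eps + y_t (alpha* block).
// Working-set selection: maximal violating pair; stop when the KKT gap
// m(x) - M(x) < tol.
// [[Rcpp::export(name = ".cpp_svr_smo")]]
List cpp_svr_smo(const NumericMatrix& K, const NumericVector& y,
                 double C, double eps, double tol, int max_iter) {
  const int n = K.nrow();
  const int N = 2 * n;
  const double TAU = 1e-12;
  std::vector<double> x(N, 0.0), G(N), s(N), p(N);
  for (int i = 0; i < n; ++i) {
    s[i] = 1.0;  s[n + i] = -1.0;
    p[i] = eps - y[i];
    p[n + i] = eps + y[i];
    G[i] = p[i];
    G[n + i] = p[n + i];
  }
  // Q(t, u) = s_t s_u K(p(t), p(u)); QD = diagonal.
  std::vector<double> QD(N);
  for (int i = 0; i < n; ++i) { QD[i] = K(i, i); QD[n + i] = K(i, i); }

  int iter = 0;
  double gap = R_PosInf;
  while (iter < max_iter) {
    // select maximal violating pair
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < N; ++t) {
      const bool up  = (s[t] > 0) ? (x[t] < C) : (x[t] > 0);
      const bool low = (s[t] > 0) ? (x[t] > 0) : (x[t] < C);
      const double v = -s[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (gap < tol) break;
    ++iter;

    const int pi = i % n, pj = j % n;
    const double Kij = K(pi, pj);
    const double old_xi = x[i], old_xj = x[j];
    if (s[i] != s[j]) {
      double quad = QD[i] + QD[j] + 2.0 * Kij;   // Q_ij = s_i s_j K = -K here
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = x[i] - x[j];
      x[i] += delta; x[j] += delta;
      if (diff > 0) {
        if (x[j] < 0) { x[j] = 0; x[i] = diff; }
      } else {
        if (x[i] < 0) { x[i] = 0; x[j] = -diff; }
      }
      if (diff > 0) {
        if (x[i] > C) { x[i] = C; x[j] = C - diff; }
      } else {
        if (x[j] > C) { x[j] = C; x[i] = C + diff; }
      }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = x[i] + x[j];
      x[i] -= delta; x[j] += delta;
      if (sum > C) {
        if (x[i] > C) { x[i] = C; x[j] = sum - C; }
      } else {
        if (x[j] < 0) { x[j] = 0; x[i] = sum; }
      }
      if (sum > C) {
        if (x[j] > C) { x[j] = C; x[i] = sum - C; }
      } else {
        if (x[i] < 0) { x[i] = 0; x[j] = sum; }
      }
    }
    const double dxi = x[i] - old_xi, dxj = x[j] - old_xj;
    // G_t += Q(t,i) dxi + Q(t,j) dxj with Q(t,i) = s_t s_i K(p(t), p(i))
    for (int t = 0; t < N; ++t) {
      const int pt = t % n;
      G[t] += s[t] * (s[i] * K(pt, pi) * dxi + s[j] * K(pt, pj) * dxj);
    }
  }

  // bias: -s_t G_t = b for free variables; else midpoint of the KKT bounds
  double bsum = 0.0; int nfree = 0;
  double ub = R_PosInf, lb = -R_PosInf;
  for (int t = 0; t < N; ++t) {
    const bool up  = (s[t] > 0) ? (x[t] < C) : (x[t] > 0);
    const bool low = (s[t] > 0) ? (x[t] > 0) : (x[t] < C);
    const double v = -s[t] * G[t];
    if (x[t] > 0 && x[t] < C) { bsum += v; ++nfree; }
    if (up && v > lb) lb = v;
    if (low && v < ub) ub = v;
  }
  const double bias = (nfree > 0) ? bsum / nfree : (lb + ub) / 2.0;

  NumericVector beta(n), alpha(n), alpha_star(n);
  for (int i = 0; i < n; ++i) {
    alpha[i] = x[i];
    alpha_star[i] = x[n + i];
    beta[i] = x[i] - x[n + i];
  }
  // dual objective 1/2 b'Kb + eps * sum(a + a*) - y'b
  double quad = 0.0, lin = 0.0;
  for (int i = 0; i < n; ++i) {
    double Kb = 0.0;
    for (int j2 = 0; j2 < n; ++j2) Kb += K(i, j2) * beta[j2];
    quad += beta[i] * Kb;
    lin += eps * (alpha[i] + alpha_star[i]) - y[i] * beta[i];
  }
  return List::create(_["beta"] = beta, _["alpha"] = alpha,
                      _["alpha_star"] = alpha_star, _["bias"] = bias,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["objective"] = 0.5 * quad + lin,
                      _["converged"] = (gap < tol));
}
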