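// Undated DTL reconciliation likelihood.
//
// Species-tree branches are identified with nodes (the edge above each
// node), so a rooted tree on L leaves has M = 2L-1 branches including the
// stem above the root. Branch ids are assigned in postorder by the R
// constructor, so children always precede parents and sweeps run
// sequentially over 1..M (the root/stem is branch M). Event probabilities
// per opportunity are p_D = delta/W, p_T = tau/W, p_L = lambda/W,
// p_S = 1/W with W = delta + tau + lambda + 1.
//
// Extinction E_e: probability a single copy entering branch e leaves no
// observed descendant. Jacobi iteration of
//   leaf e (species s):  E_e = pL + pD E_e^2 + pT Ebar_-e E_e + pS m_s
//   internal e (kids f,g): E_e = pL + pD E_e^2 + pT Ebar_-e E_e + pS E_f E_g
// from all zeros, where Ebar_-e is the mean of E over branches != e.
//
// Observation DP: for each directed gene subtree u and branch e,
//   A(u,e) = [u leaf: pS (1-m_s) 1{e = terminal branch of species(u)}]
//          + [u internal, kids v,w:
//               pD P(v,e) P(w,e)
//             + pT (P(v,e) Pbar_-e(w) + P(w,e) Pbar_-e(v))
//             + (e internal, kids f,g) pS (P(v,f)P(w,g) + P(v,g)P(w,f))]
//          + (e internal) pS (P(u,f) E_g + P(u,g) E_f)
//          + pT E_e Pbar_-e(u)
//   P(u,e) = A(u,e) / (1 - 2 pD E_e - pT Ebar_-e)
// Given the children's vectors, this system is LINEAR in P(u,.): lower
// triangular in postorder (the speciation-loss term only references child
// branches) plus a rank-one coupling through the branch mean Pbar. It is
// solved exactly: with S = sum_e P(u,e),
//   P(e) [denom(e) + pT E_e/(M-1)] =
//        A0(e) + pS (P(f) E_g + P(g) E_f) + pT E_e S / (M-1)
// so P = u + v S where u, v each solve one triangular sweep (v is
// gene-node independent), and S = sum(u) / (1 - sum(v)). Each subtree's P
// vector carries a log scale factor so families with hundreds of leaves
// stay in range.
//
// Family likelihood: sum over gene-tree rootings rho (undirected edges)
// and origination branches e of P(rho,e), divided by the number of
// origination branches and by (1 - mean extinction over them).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

struct Probs { double pD, pT, pL, pS; };

static Probs event_probs_c(double delta, double tau, double lambda) {
  double W = delta + tau + lambda + 1.0;
  Probs p;
  p.pD = delta / W; p.pT = tau / W; p.pL = lambda / W; p.pS = 1.0 / W;
  return p;
}

// Fixed point for extinction, iterated from all zeros with Gauss-Seidel
// sweeps in postorder (children first; the running sum keeps Ebar
// current). Returns iterations used (negative if not converged).
static int extinction_fp(int M, const int* child1, const int* child2,
                         const double* m, const Probs& p, double tol,
                         int maxit, std::vector<double>& E,
                         double* residual) {
  std::fill(E.begin(), E.end(), 0.0);
  double inv_M1 = (M > 1) ? 1.0 / (M - 1) : 0.0;
  double diff = 0.0, sumE = 0.0;
  for (int it = 1; it <= maxit; ++it) {
    diff = 0.0;
    for (int e = 0; e < M; ++e) {
      double ebar = (sumE - E[e]) * inv_M1;
      double tail = (child1[e] == 0) ? p.pS * m[e]
                    : p.pS * E[child1[e] - 1] * E[child2[e] - 1];
      double nv = p.pL + p.pD * E[e] * E[e] + p.pT * ebar * E[e] + tail;
      double d = std::fabs(nv - E[e]);
      if (d > diff) diff = d;
      sumE += nv - E[e];
      E[e] = nv;
    }
    if (diff < tol) { *residual = diff; return it; }
  }
  *residual = diff;
  return -maxit;
}

// [[Rcpp::export]]
List dtl_extinction_cpp(int M, IntegerVector child1, IntegerVector child2,
                        NumericVector m, double delta, double tau,
                        double lambda, double tol = 1e-12,
                        int maxit = 10000) {
  if (delta < 0 || tau < 0 || lambda < 0) stop("rates must be >= 0");
  Probs p = event_probs_c(delta, tau, lambda);
  std::vector<double> E(M);
  double resid;
  int it = extinction_fp(M, child1.begin(), child2.begin(), m.begin(), p,
                         tol, maxit, E, &resid);
  if (it < 0)
    stop("extinction fixed point did not converge in %d sweeps (residual %g)",
         maxit, resid);
  return List::create(_["E"] = NumericVector(E.begin(), E.end()),
                      _["iterations"] = it, _["residual"] = resid);
}

// Solve the closure system for one gene node's P vector over all branches
// (exact: triangular sweep for u, then the rank-one mean coupling in
// closed form). A0 holds the terms that do not involve P(u,.);
// invdenom2[e] = 1 / (denom(e) + pT E_e / (M-1)), v and vsum are the
// gene-node-independent homogeneous solution. Returns false when the mean
// coupling is non-contractive (infeasible rates).
static bool solve_node(int M, const int* child1, const int* child2,
                       const std::vector<double>& E,
                       const std::vector<double>& invdenom2,
                       const std::vector<double>& v, double vsum,
                       const Probs& p, const std::vector<double>& A0,
                       std::vector<double>& P) {
  double usum = 0.0;
  for (int e = 0; e < M; ++e) {
    double a = A0[e];
    if (child1[e] != 0) {
      int f = child1[e] - 1, g = child2[e] - 1;
      a += p.pS * (P[f] * E[g] + P[g] * E[f]);
    }
    double u = a * invdenom2[e];
    P[e] = u;
    usum += u;
  }
  if (vsum >= 1.0) return false;
  double S = usum / (1.0 - vsum);
  for (int e = 0; e < M; ++e) P[e] += v[e] * S;
  return true;
}

struct DtlWork {           // scratch reused across likelihood evaluations
  std::vector<double> E, invdenom2, v, A0, Pr;
  std::vector<std::vector<double> > P;
  std::vector<double> lsc, sums, logterms;
};

// core likelihood; returns loglik or -Inf (infeasible)
static double loglik_core(int M, const int* child1, const int* child2,
                          const double* m, int root,
                          int D, const int* g_kind, const int* g_species,
                          const int* g_childA, const int* g_childB,
                          int R, const int* rootA, const int* rootB,
                          double delta, double tau, double lambda,
                          bool orig_stem, double e_tol, int e_maxit,
                          double p_tol, int p_maxsweep, DtlWork& W) {
  Probs p = event_probs_c(delta, tau, lambda);
  W.E.resize(M);
  double resid;
  int it = extinction_fp(M, child1, child2, m, p, e_tol, e_maxit, W.E, &resid);
  if (it < 0)
    stop("extinction fixed point did not converge in %d sweeps (residual %g)",
         e_maxit, resid);
  std::vector<double>& E = W.E;

  double inv_M1 = (M > 1) ? 1.0 / (M - 1) : 0.0;
  W.invdenom2.resize(M); W.v.resize(M);
  double sumE = 0.0;
  for (int i = 0; i < M; ++i) sumE += E[i];
  for (int e = 0; e < M; ++e) {
    double de = 1.0 - 2.0 * p.pD * E[e] - p.pT * (sumE - E[e]) * inv_M1;
    if (de <= 1e-12) return R_NegInf;
    W.invdenom2[e] = 1.0 / (de + p.pT * E[e] * inv_M1);
  }
  // homogeneous solution of the mean coupling (gene-node independent)
  double vsum = 0.0;
  for (int e = 0; e < M; ++e) {
    double a = p.pT * E[e] * inv_M1;
    if (child1[e] != 0) {
      int f = child1[e] - 1, g = child2[e] - 1;
      a += p.pS * (W.v[f] * E[g] + W.v[g] * E[f]);
    }
    W.v[e] = a * W.invdenom2[e];
    vsum += W.v[e];
  }
  if (vsum >= 1.0) return R_NegInf;

  W.P.resize(D); W.lsc.assign(D, 0.0); W.sums.assign(D, 0.0);
  W.A0.resize(M);
  for (int d = 0; d < D; ++d) {
    W.P[d].assign(M, 0.0);
    if (g_kind[d] == 0) {
      std::fill(W.A0.begin(), W.A0.end(), 0.0);
      int e = g_species[d] - 1;
      W.A0[e] = p.pS * (1.0 - m[e]);
      W.lsc[d] = 0.0;
    } else {
      int va = g_childA[d] - 1, vb = g_childB[d] - 1;
      const std::vector<double>& Pa = W.P[va];
      const std::vector<double>& Pb = W.P[vb];
      double sa = W.sums[va], sb = W.sums[vb];
      for (int e = 0; e < M; ++e) {
        double a = p.pD * Pa[e] * Pb[e]
                 + p.pT * (Pa[e] * (sb - Pb[e]) + Pb[e] * (sa - Pa[e])) * inv_M1;
        if (child1[e] != 0) {
          int f = child1[e] - 1, g = child2[e] - 1;
          a += p.pS * (Pa[f] * Pb[g] + Pa[g] * Pb[f]);
        }
        W.A0[e] = a;
      }
      W.lsc[d] = W.lsc[va] + W.lsc[vb];
    }
    if (!solve_node(M, child1, child2, E, W.invdenom2, W.v, vsum, p, W.A0,
                    W.P[d])) return R_NegInf;
    double mx = 0.0;
    for (int e = 0; e < M; ++e) if (W.P[d][e] > mx) mx = W.P[d][e];
    if (mx > 0.0) {
      for (int e = 0; e < M; ++e) W.P[d][e] /= mx;
      W.lsc[d] += std::log(mx);
    }
    double s = 0.0;
    for (int e = 0; e < M; ++e) s += W.P[d][e];
    W.sums[d] = s;
  }

  int n_orig = orig_stem ? M : M - 1;     // stem is branch `root`
  double meanE = 0.0;
  for (int e = 0; e < M; ++e)
    if (orig_stem || e != root - 1) meanE += E[e];
  meanE /= n_orig;
  if (meanE >= 1.0 - 1e-15) return R_NegInf;

  W.logterms.clear();
  W.Pr.resize(M);
  for (int r = 0; r < R; ++r) {
    int va = rootA[r] - 1, vb = rootB[r] - 1;
    const std::vector<double>& Pa = W.P[va];
    const std::vector<double>& Pb = W.P[vb];
    double sa = W.sums[va], sb = W.sums[vb];
    for (int e = 0; e < M; ++e) {
      double a = p.pD * Pa[e] * Pb[e]
               + p.pT * (Pa[e] * (sb - Pb[e]) + Pb[e] * (sa - Pa[e])) * inv_M1;
      if (child1[e] != 0) {
        int f = child1[e] - 1, g = child2[e] - 1;
        a += p.pS * (Pa[f] * Pb[g] + Pa[g] * Pb[f]);
      }
      W.A0[e] = a;
    }
    if (!solve_node(M, child1, child2, E, W.invdenom2, W.v, vsum, p, W.A0,
                    W.Pr)) return R_NegInf;
    double tot = 0.0;
    for (int e = 0; e < M; ++e)
      if (orig_stem || e != root - 1) tot += W.Pr[e];
    if (tot > 0.0)
      W.logterms.push_back(std::log(tot) + W.lsc[va] + W.lsc[vb]);
  }
  if (W.logterms.empty()) return R_NegInf;
  double mx = W.logterms[0];
  for (size_t i = 1; i < W.logterms.size(); ++i)
    if (W.logterms[i] > mx) mx = W.logterms[i];
  double acc = 0.0;
  for (size_t i = 0; i < W.logterms.size(); ++i)
    acc += std::exp(W.logterms[i] - mx);
  return mx + std::log(acc) - std::log((double) n_orig) - std::log1p(-meanE);
}

// [[Rcpp::export]]
List dtl_loglik_cpp(int M, IntegerVector child1, IntegerVector child2,
                    NumericVector m, int root,
                    IntegerVector g_kind, IntegerVector g_species,
                    IntegerVector g_childA, IntegerVector g_childB,
                    IntegerVector rootA, IntegerVector rootB,
                    double delta, double tau, double lambda,
                    bool orig_stem = true,
                    double e_tol = 1e-12, int e_maxit = 10000,
                    double p_tol = 1e-10, int p_maxsweep = 100) {
  if (delta < 0 || tau < 0 || lambda < 0) stop("rates must be >= 0");
  DtlWork W;
  double ll = loglik_core(M, child1.begin(), child2.begin(), m.begin(), root,
                          g_kind.size(), g_kind.begin(), g_species.begin(),
                          g_childA.begin(), g_childB.begin(),
                          rootA.size(), rootA.begin(), rootB.begin(),
                          delta, tau, lambda, orig_stem,
                          e_tol, e_maxit, p_tol, p_maxsweep, W);
  bool feas = R_finite(ll);
  return List::create(_["loglik"] = ll, _["feasible"] = feas,
                      _["reason"] = feas ? "" : "zero probability under these rates");
}

// ---- free-mode rate optimization: Nelder-Mead in log10-rate space -------
//
// Maximizes the likelihood over (delta, tau, lambda), parameters clamped
// to [1e-10, 10]. Standard simplex moves (reflect 1, expand 2, contract
// 0.5, shrink 0.5); convergence when the simplex function spread drops
// below reltol * (|best| + reltol); one restart from the best point with
// half the initial step. Deterministic.

struct FitCtx {
  int M; const int *c1, *c2; const double* m; int root;
  int D; const int *gk, *gs, *ga, *gb;
  int R; const int *ra, *rb;
  bool orig_stem; double e_tol; int e_maxit; double p_tol; int p_maxsweep;
  DtlWork W; int evals;
};

static double neg_ll(FitCtx& ctx, const double* x) {
  double r[3];
  for (int i = 0; i < 3; ++i) {
    double xi = x[i];
    if (xi < -10.0) xi = -10.0;
    if (xi > 1.0) xi = 1.0;
    r[i] = std::pow(10.0, xi);
  }
  ctx.evals++;
  double ll = loglik_core(ctx.M, ctx.c1, ctx.c2, ctx.m, ctx.root,
                          ctx.D, ctx.gk, ctx.gs, ctx.ga, ctx.gb,
                          ctx.R, ctx.ra, ctx.rb, r[0], r[1], r[2],
                          ctx.orig_stem, ctx.e_tol, ctx.e_maxit,
                          ctx.p_tol, ctx.p_maxsweep, ctx.W);
  if (!R_finite(ll)) return 1e300;
  return -ll;
}

static void nm_run(FitCtx& ctx, double* x0, double step, double reltol,
                   int maxit, double* fbest) {
  const int n = 3;
  double S[4][3], f[4];
  for (int i = 0; i < n; ++i) S[0][i] = x0[i];
  f[0] = neg_ll(ctx, S[0]);
  for (int v = 1; v <= n; ++v) {
    for (int i = 0; i < n; ++i) S[v][i] = x0[i] + (i == v - 1 ? step : 0.0);
    f[v] = neg_ll(ctx, S[v]);
  }
  int iter = 0;
  while (iter++ < maxit) {
    // order: lo = best, hi = worst, nh = next worst
    int lo = 0, hi = 0, nh = 0;
    for (int v = 1; v <= n; ++v) {
      if (f[v] < f[lo]) lo = v;
      if (f[v] > f[hi]) { nh = hi; hi = v; }
      else if (f[v] > f[nh] && v != hi) nh = v;
    }
    if (f[hi] - f[lo] <= reltol * (std::fabs(f[lo]) + reltol)) break;
    double cen[3] = {0, 0, 0};
    for (int v = 0; v <= n; ++v) if (v != hi)
      for (int i = 0; i < n; ++i) cen[i] += S[v][i];
    for (int i = 0; i < n; ++i) cen[i] /= n;
    double xr[3], xe[3], xc[3];
    for (int i = 0; i < n; ++i) xr[i] = cen[i] + (cen[i] - S[hi][i]);
    double fr = neg_ll(ctx, xr);
    if (fr < f[lo]) {
      for (int i = 0; i < n; ++i) xe[i] = cen[i] + 2.0 * (cen[i] - S[hi][i]);
      double fe = neg_ll(ctx, xe);
      if (fe < fr) { std::copy(xe, xe + n, S[hi]); f[hi] = fe; }
      else { std::copy(xr, xr + n, S[hi]); f[hi] = fr; }
    } else if (fr < f[nh]) {
      std::copy(xr, xr + n, S[hi]); f[hi] = fr;
    } else {
      for (int i = 0; i < n; ++i) xc[i] = cen[i] + 0.5 * (S[hi][i] - cen[i]);
      double fc = neg_ll(ctx, xc);
      if (fc < f[hi]) { std::copy(xc, xc + n, S[hi]); f[hi] = fc; }
      else {
        for (int v = 0; v <= n; ++v) if (v != lo) {
          for (int i = 0; i < n; ++i)
            S[v][i] = S[lo][i] + 0.5 * (S[v][i] - S[lo][i]);
          f[v] = neg_ll(ctx, S[v]);
        }
      }
    }
  }
  int lo = 0;
  for (int v = 1; v <= n; ++v) if (f[v] < f[lo]) lo = v;
  for (int i = 0; i < n; ++i) x0[i] = S[lo][i];
  *fbest = f[lo];
}

// [[Rcpp::export]]
List dtl_fit_free_cpp(int M, IntegerVector child1, IntegerVector child2,
                      NumericVector m, int root,
                      IntegerVector g_kind, IntegerVector g_species,
                      IntegerVector g_childA, IntegerVector g_childB,
                      IntegerVector rootA, IntegerVector rootB,
                      NumericVector init_log10, double step = 0.5,
                      double reltol = 1e-8, int maxit = 500,
                      bool restart = true, bool orig_stem = true,
                      double e_tol = 1e-12, int e_maxit = 10000,
                      double p_tol = 1e-10, int p_maxsweep = 100) {
  if (init_log10.size() != 3) stop("init_log10 must have length 3");
  FitCtx ctx;
  ctx.M = M; ctx.c1 = child1.begin(); ctx.c2 = child2.begin();
  ctx.m = m.begin(); ctx.root = root;
  ctx.D = g_kind.size(); ctx.gk = g_kind.begin(); ctx.gs = g_species.begin();
  ctx.ga = g_childA.begin(); ctx.gb = g_childB.begin();
  ctx.R = rootA.size(); ctx.ra = rootA.begin(); ctx.rb = rootB.begin();
  ctx.orig_stem = orig_stem; ctx.e_tol = e_tol; ctx.e_maxit = e_maxit;
  ctx.p_tol = p_tol; ctx.p_maxsweep = p_maxsweep; ctx.evals = 0;
  double x[3];
  for (int i = 0; i < 3; ++i) {
    x[i] = init_log10[i];
    if (x[i] < -10.0) x[i] = -10.0;
    if (x[i] > 1.0) x[i] = 1.0;
  }
  double fbest;
  nm_run(ctx, x, step, reltol, maxit, &fbest);
  if (restart) nm_run(ctx, x, step * 0.5, reltol, maxit, &fbest);
  NumericVector rates(3);
  for (int i = 0; i < 3; ++i) {
    double xi = x[i];
    if (xi < -10.0) xi = -10.0;
    if (xi > 1.0) xi = 1.0;
    rates[i] = std::pow(10.0, xi);
  }
  return List::create(_["rates"] = rates, _["loglik"] = -fbest,
                      _["evals"] = ctx.evals);
}

// ---- batched loss-rate optimization over many families ------------------
//
// For a fixed rooted species tree and per-family fixed (delta, tau), fits
// lambda for every family by Brent search on log10 lambda in [xlo, xhi].
// Family encodings are concatenated with local 1-based child/rooting
// indices. This is the inner loop of a root scan, so it avoids any R
// round-trips.

static double brent_max(std::function<double(double)> f, double a, double b,
                        double tol, double* fmax) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double pp = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) pp = -pp;
      q = std::fabs(q);
      double etemp = e; e = d;
      if (std::fabs(pp) < std::fabs(0.5 * q * etemp) &&
          pp > q * (a - x) && pp < q * (b - x)) {
        d = pp / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmax = fx;
  return x;
}

// [[Rcpp::export]]
List dtl_fit_lambda_batch_cpp(int M, IntegerVector child1,
                              IntegerVector child2, NumericVector m,
                              int root, IntegerVector fam_D,
                              IntegerVector fam_R, IntegerVector g_kind,
                              IntegerVector g_species,
                              IntegerVector g_childA, IntegerVector g_childB,
                              IntegerVector rootA, IntegerVector rootB,
                              NumericVector delta0, NumericVector tau0,
                              NumericVector lambda0 = NumericVector(0),
                              double xlo = -10.0, double xhi = 1.0,
                              double window = 3.0,
                              double xtol = 1e-6, bool orig_stem = true,
                              double e_tol = 1e-12, int e_maxit = 10000,
                              double p_tol = 1e-10, int p_maxsweep = 100) {
  int N = fam_D.size();
  if (fam_R.size() != N || delta0.size() != N || tau0.size() != N)
    stop("family argument lengths disagree");
  NumericVector lambda(N), loglik(N);
  DtlWork W;
  int offD = 0, offR = 0;
  for (int i = 0; i < N; ++i) {
    int D = fam_D[i], R = fam_R[i];
    const int* gk = g_kind.begin() + offD;
    const int* gs = g_species.begin() + offD;
    const int* ga = g_childA.begin() + offD;
    const int* gb = g_childB.begin() + offD;
    const int* ra = rootA.begin() + offR;
    const int* rb = rootB.begin() + offR;
    double de = delta0[i], ta = tau0[i];
    double lo = xlo, hi = xhi;
    if (lambda0.size() == N) {
      // bracket the search around the family's reference-root loss rate;
      // the per-root optimum rarely drifts more than `window` decades
      double c0 = std::log10(std::max(lambda0[i], 1e-10));
      lo = std::max(xlo, c0 - window);
      hi = std::min(xhi, c0 + window);
      if (hi - lo < 1.0) { lo = std::max(xlo, hi - 1.0); hi = std::min(xhi, lo + 1.0); }
    }
    auto obj = [&](double x) -> double {
      double ll = loglik_core(M, child1.begin(), child2.begin(), m.begin(),
                              root, D, gk, gs, ga, gb, R, ra, rb,
                              de, ta, std::pow(10.0, x), orig_stem,
                              e_tol, e_maxit, p_tol, p_maxsweep, W);
      return R_finite(ll) ? ll : -1e300;
    };
    double fbest;
    double xbest = brent_max(obj, lo, hi, xtol, &fbest);
    lambda[i] = std::pow(10.0, xbest);
    loglik[i] = fbest;
    offD += D; offR += R;
  }
  return List::create(_["lambda"] = lambda, _["loglik"] = loglik);
}
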