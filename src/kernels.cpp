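#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Mass-action reactant factor for reaction r at state x: the hazard is
// theta_r * base_factor. conv 0 = binomial choose(x_a, u_ra), conv 1 =
// falling factorial x_a (x_a - 1) ... (x_a - u_ra + 1). Zero when any
// reactant count is below its stoichiometry.
static double base_factor(const std::vector<int>& x, const IntegerMatrix& U,
                          int r, int conv) {
  double f = 1.0;
  const int K = U.ncol();
  for (int a = 0; a < K; ++a) {
    const int u = U(r, a);
    if (u == 0) continue;
    const int xa = x[a];
    if (xa < u) return 0.0;
    double g = 1.0;
    for (int i = 0; i < u; ++i) g *= (double)(xa - i);
    if (conv == 0) for (int i = 2; i <= u; ++i) g /= (double)i;
    f *= g;
  }
  return f;
}

// [[Rcpp::export]]
NumericVector hazards_mass_action_cpp(IntegerVector x, IntegerMatrix U,
                                      NumericVector theta, int conv) {
  const int M = U.nrow();
  std::vector<int> xs(x.begin(), x.end());
  NumericVector h(M);
  for (int r = 0; r < M; ++r) h[r] = theta[r] * base_factor(xs, U, r, conv);
  return h;
}

// Replay a path, accumulating the complete-data log-likelihood and the
// theta-free integrated propensities G_r = int h_r(X(t)) / theta_r dt.
// Validity requires every fired reaction to have positive hazard at its
// firing state (which for mass action implies non-negative counts
// throughout). Returns false on an invalid path; ll is then meaningless.
static bool eval_path(const std::vector<double>& tt, const std::vector<int>& ty,
                      const std::vector<int>& x0, double t0, double t1,
                      const IntegerMatrix& U, const IntegerMatrix& A,
                      const NumericVector& theta, int conv,
                      double& ll, std::vector<double>& G,
                      std::vector<int>* xend = NULL) {
  const int M = U.nrow(), K = U.ncol();
  std::vector<int> x = x0;
  std::fill(G.begin(), G.end(), 0.0);
  ll = 0.0;
  double tprev = t0;
  const int J = (int)tt.size();
  for (int j = 0; j <= J; ++j) {
    const double tnext = (j < J) ? tt[j] : t1;
    const double dt = tnext - tprev;
    double h0 = 0.0;
    for (int r = 0; r < M; ++r) {
      const double b = base_factor(x, U, r, conv);
      G[r] += b * dt;
      h0 += theta[r] * b;
    }
    ll -= h0 * dt;
    if (j < J) {
      const int r = ty[j];
      const double b = base_factor(x, U, r, conv);
      if (b <= 0.0) return false;
      ll += std::log(theta[r] * b);
      for (int a = 0; a < K; ++a) {
        x[a] += A(r, a);
        if (x[a] < 0) return false;
      }
      tprev = tnext;
    }
  }
  if (xend) *xend = x;
  return true;
}

// [[Rcpp::export]]
List eval_path_cpp(NumericVector times, IntegerVector types, IntegerVector x0,
                   double t0, double t1, IntegerMatrix U, IntegerMatrix A,
                   NumericVector theta, int conv) {
  const int M = U.nrow();
  std::vector<double> tt(times.begin(), times.end());
  std::vector<int> ty(types.size());
  for (int j = 0; j < types.size(); ++j) ty[j] = types[j] - 1;
  std::vector<int> xs(x0.begin(), x0.end());
  std::vector<double> G(M);
  std::vector<int> xend;
  double ll;
  bool ok = eval_path(tt, ty, xs, t0, t1, U, A, theta, conv, ll, G, &xend);
  IntegerVector n(M);
  for (int j = 0; j < types.size(); ++j) n[types[j] - 1]++;
  return List::create(_["valid"] = ok,
                      _["loglik"] = ok ? ll : R_NegInf,
                      _["n"] = n,
                      _["G"] = NumericVector(G.begin(), G.end()),
                      _["x_end"] = ok ? IntegerVector(wrap(xend))
                                      : IntegerVector(0));
}

// [[Rcpp::export]]
List ssa_cpp(IntegerVector x0, IntegerMatrix U, IntegerMatrix A,
             NumericVector theta, int conv, double t0, double t_end,
             int max_events) {
  const int M = U.nrow(), K = U.ncol();
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> times;
  std::vector<int> types;
  std::vector<double> h(M);
  double t = t0;
  for (;;) {
    double h0 = 0.0;
    for (int r = 0; r < M; ++r) {
      h[r] = theta[r] * base_factor(x, U, r, conv);
      h0 += h[r];
    }
    if (h0 <= 0.0) break;
    t += exp_rand() / h0;
    if (t >= t_end) break;
    if ((int)times.size() >= max_events)
      stop("SSA event cap (%d) exceeded: hazards may be exploding", max_events);
    double u = unif_rand() * h0;
    int r = 0;
    double c = h[0];
    while (u > c && r < M - 1) c += h[++r];
    times.push_back(t);
    types.push_back(r + 1);
    for (int a = 0; a < K; ++a) x[a] += A(r, a);
  }
  return List::create(_["times"] = wrap(times), _["types"] = wrap(types),
                      _["x_end"] = wrap(x));
}

// Endpoint-conditioned rejection sampler: run unconstrained SSA over the
// interval, keep realizations whose final state matches x_end exactly.
// Returns the total event count of each accepted run (validation oracle).
// [[Rcpp::export]]
List rejection_counts_cpp(IntegerVector x0, IntegerVector x_end,
                          IntegerMatrix U, IntegerMatrix A, NumericVector theta,
                          int conv, double tau, int n_target, int max_tries) {
  const int M = U.nrow(), K = U.ncol();
  std::vector<int> counts;
  std::vector<double> h(M);
  int tries = 0;
  while ((int)counts.size() < n_target && tries < max_tries) {
    ++tries;
    std::vector<int> x(x0.begin(), x0.end());
    double t = 0.0;
    int J = 0;
    for (;;) {
      double h0 = 0.0;
      for (int r = 0; r < M; ++r) {
        h[r] = theta[r] * base_factor(x, U, r, conv);
        h0 += h[r];
      }
      if (h0 <= 0.0) break;
      t += exp_rand() / h0;
      if (t >= tau) break;
      double u = unif_rand() * h0;
      int r = 0;
      double c = h[0];
      while (u > c && r < M - 1) c += h[++r];
      ++J;
      if (J > 100000) break;
      for (int a = 0; a < K; ++a) x[a] += A(r, a);
    }
    bool match = true;
    for (int a = 0; a < K; ++a)
      if (x[a] != x_end[a]) { match = false; break; }
    if (match) counts.push_back(J);
  }
  return List::create(_["counts"] = wrap(counts), _["tries"] = tries);
}

// ---------------------------------------------------------------------------
// Exact minimal reaction-count search (iterative-deepening branch and bound).
// Finds the non-negative integer r minimizing sum(r) subject to
// t(Atil) %*% r == delta, where Atil is M x Gm. Admissible bound: each
// remaining unit of budget can change species a by at most the largest
// |Atil(r, a)| among unassigned reactions.
// ---------------------------------------------------------------------------
struct CountSearch {
  const IntegerMatrix& Atil;
  int M, Gm;
  std::vector<std::vector<int> > maxeff; // maxeff[idx][a] over r >= idx
  std::vector<int> r;

  CountSearch(const IntegerMatrix& Atil_) : Atil(Atil_) {
    M = Atil.nrow();
    Gm = Atil.ncol();
    maxeff.assign(M + 1, std::vector<int>(Gm, 0));
    for (int idx = M - 1; idx >= 0; --idx)
      for (int a = 0; a < Gm; ++a) {
        int e = std::abs(Atil(idx, a));
        maxeff[idx][a] = std::max(e, maxeff[idx + 1][a]);
      }
    r.assign(M, 0);
  }

  // lower bound on events needed to cancel res using reactions idx..M-1;
  // -1 means infeasible
  int bound(const std::vector<int>& res, int idx) const {
    int b = 0;
    for (int a = 0; a < Gm; ++a) {
      if (res[a] == 0) continue;
      const int e = maxeff[idx][a];
      if (e == 0) return -1;
      const int need = (std::abs(res[a]) + e - 1) / e;
      if (need > b) b = need;
    }
    return b;
  }

  bool dfs(int idx, std::vector<int>& res, int budget) {
    const int lb = bound(res, idx);
    if (lb < 0 || lb > budget) return false;
    if (idx == M) return budget == 0; // res == 0 guaranteed by lb == 0
    for (int c = 0; c <= budget; ++c) {
      if (c > 0)
        for (int a = 0; a < Gm; ++a) res[a] -= Atil(idx, a);
      r[idx] = c;
      if (dfs(idx + 1, res, budget - c)) return true;
    }
    for (int a = 0; a < Gm; ++a) res[a] += budget * Atil(idx, a);
    r[idx] = 0;
    return false;
  }
};

// [[Rcpp::export]]
IntegerVector find_counts_cpp(IntegerMatrix Atil, IntegerVector delta,
                              int max_total) {
  CountSearch cs(Atil);
  std::vector<int> res(delta.begin(), delta.end());
  for (int S = 0; S <= max_total; ++S) {
    std::vector<int> res0 = res;
    if (cs.dfs(0, res0, S))
      return IntegerVector(cs.r.begin(), cs.r.end());
  }
  return IntegerVector(0); // infeasible within cap
}

// ---------------------------------------------------------------------------
// RJMCMC samplers. Paths are stored per inter-observation interval; move
// types: 1 = add one elementary mode with uniform times, 2 = delete a
// uniformly chosen combination matching a mode, 3 = redraw all event times
// (type order kept). Acceptance ratios follow from detailed balance:
//   log AR_add = dll + log(a2/a1) + Q log tau + sum_j [lg(c_j+1)-lg(c_j+q_j+1)]
//   log AR_del = dll + log(a1/a2) - Q log tau + sum_j [lg(c_j+1)-lg(c_j-q_j+1)]
//   log AR_shuffle = dll
// where c_j are current per-type counts on the interval being modified.
// ---------------------------------------------------------------------------
struct IPath {
  std::vector<double> t;
  std::vector<int> ty; // 0-based
  std::vector<int> cnt;
  double ll;
  std::vector<double> G;
};

static void sort_events(std::vector<double>& t, std::vector<int>& ty) {
  const int n = (int)t.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return t[a] < t[b]; });
  std::vector<double> t2(n);
  std::vector<int> ty2(n);
  for (int i = 0; i < n; ++i) { t2[i] = t[ord[i]]; ty2[i] = ty[ord[i]]; }
  t.swap(t2);
  ty.swap(ty2);
}

// candidate = current path plus one copy of mode k at uniform times
static void add_mode_events(const IPath& p, const IntegerMatrix& modes, int k,
                            double t0, double t1, std::vector<double>& nt,
                            std::vector<int>& nty) {
  nt = p.t;
  nty = p.ty;
  const int M = modes.ncol();
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < modes(k, j); ++c) {
      nt.push_back(t0 + unif_rand() * (t1 - t0));
      nty.push_back(j);
    }
  sort_events(nt, nty);
}

// candidate = current path minus a uniformly chosen combination matching
// mode k; false when the path lacks the required events
static bool del_mode_events(const IPath& p, const IntegerMatrix& modes, int k,
                            std::vector<double>& nt, std::vector<int>& nty) {
  const int M = modes.ncol();
  const int n = (int)p.t.size();
  std::vector<char> rem(n, 0);
  for (int j = 0; j < M; ++j) {
    const int q = modes(k, j);
    if (q == 0) continue;
    if (p.cnt[j] < q) return false;
    std::vector<int> pos;
    pos.reserve(p.cnt[j]);
    for (int i = 0; i < n; ++i)
      if (p.ty[i] == j) pos.push_back(i);
    for (int c = 0; c < q; ++c) {
      int pick = c + (int)(unif_rand() * (double)(pos.size() - c));
      if (pick >= (int)pos.size()) pick = (int)pos.size() - 1;
      std::swap(pos[c], pos[pick]);
      rem[pos[c]] = 1;
    }
  }
  nt.clear();
  nty.clear();
  for (int i = 0; i < n; ++i)
    if (!rem[i]) { nt.push_back(p.t[i]); nty.push_back(p.ty[i]); }
  return true;
}

static double lg(double x) { return R::lgammafn(x); }

// proposal-density correction for adding mode k to a path with counts cnt
// on an interval of length tau (excluding the alpha ratio)
static double add_corr(const std::vector<int>& cnt, const IntegerMatrix& modes,
                       int k, double tau) {
  double corr = 0.0;
  int Q = 0;
  const int M = modes.ncol();
  for (int j = 0; j < M; ++j) {
    const int q = modes(k, j);
    if (q == 0) continue;
    Q += q;
    corr += lg(cnt[j] + 1.0) - lg(cnt[j] + q + 1.0);
  }
  return corr + Q * std::log(tau);
}

static double del_corr(const std::vector<int>& cnt, const IntegerMatrix& modes,
                       int k, double tau) {
  double corr = 0.0;
  int Q = 0;
  const int M = modes.ncol();
  for (int j = 0; j < M; ++j) {
    const int q = modes(k, j);
    if (q == 0) continue;
    Q += q;
    corr += lg(cnt[j] + 1.0) - lg(cnt[j] - q + 1.0);
  }
  return corr - Q * std::log(tau);
}

static IPath make_ipath(const NumericVector& times, const IntegerVector& types,
                        const std::vector<int>& x0, double t0, double t1,
                        const IntegerMatrix& U, const IntegerMatrix& A,
                        const NumericVector& theta, int conv, int interval) {
  const int M = U.nrow();
  IPath p;
  p.t.assign(times.begin(), times.end());
  p.ty.resize(types.size());
  p.cnt.assign(M, 0);
  for (int j = 0; j < types.size(); ++j) {
    p.ty[j] = types[j] - 1;
    p.cnt[p.ty[j]]++;
  }
  p.G.resize(M);
  if (!eval_path(p.t, p.ty, x0, t0, t1, U, A, theta, conv, p.ll, p.G))
    stop("initial path for interval %d is invalid", interval + 1);
  return p;
}

static List pack_paths(const std::vector<IPath>& paths) {
  List out(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    IntegerVector ty(paths[i].ty.size());
    for (size_t j = 0; j < paths[i].ty.size(); ++j) ty[j] = paths[i].ty[j] + 1;
    out[i] = List::create(_["times"] = wrap(paths[i].t), _["types"] = ty);
  }
  return out;
}

// [[Rcpp::export]]
List rjmcmc_full_cpp(IntegerMatrix states, NumericVector obstimes, List paths0,
                     IntegerMatrix modes, NumericVector theta, IntegerMatrix U,
                     IntegerMatrix A, int conv, double alpha1, double alpha2,
                     int n_samples, int burn_in, int thin,
                     bool record_intervals) {
  const int M = U.nrow(), K = U.ncol();
  const int m = states.nrow();
  const int nI = m - 1;
  const int Kp = modes.nrow();
  if (Kp == 0) stop("empty null set: no reversible-jump moves exist");

  std::vector<std::vector<int> > x0s(nI, std::vector<int>(K));
  for (int i = 0; i < nI; ++i)
    for (int a = 0; a < K; ++a) x0s[i][a] = states(i, a);

  std::vector<IPath> paths(nI);
  for (int i = 0; i < nI; ++i) {
    List pi = paths0[i];
    paths[i] = make_ipath(pi["times"], pi["types"], x0s[i], obstimes[i],
                          obstimes[i + 1], U, A, theta, conv, i);
  }

  const int n_iter = burn_in + n_samples * thin;
  IntegerMatrix n_mat(n_samples, M);
  NumericMatrix G_mat(n_samples, M);
  IntegerVector J_tot(n_samples);
  IntegerMatrix J_int(record_intervals ? n_samples : 0, record_intervals ? nI : 0);
  IntegerVector prop(3), acc(3);

  std::vector<double> nt;
  std::vector<int> nty;
  std::vector<double> candG(M);

  int srow = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < nI; ++i) {
      const double t0 = obstimes[i], t1 = obstimes[i + 1];
      const double tau = t1 - t0;
      const int k = std::min((int)(unif_rand() * Kp), Kp - 1);
      const double u = unif_rand();
      int move = (u < alpha1) ? 1 : (u < alpha1 + alpha2) ? 2 : 3;
      prop[move - 1]++;
      double corr = 0.0;
      bool feasible = true;
      if (move == 1) {
        corr = std::log(alpha2 / alpha1) + add_corr(paths[i].cnt, modes, k, tau);
        add_mode_events(paths[i], modes, k, t0, t1, nt, nty);
      } else if (move == 2) {
        feasible = del_mode_events(paths[i], modes, k, nt, nty);
        if (feasible)
          corr = std::log(alpha1 / alpha2) + del_corr(paths[i].cnt, modes, k, tau);
      } else {
        nty = paths[i].ty;
        nt.resize(nty.size());
        for (size_t j = 0; j < nt.size(); ++j) nt[j] = t0 + unif_rand() * tau;
        std::sort(nt.begin(), nt.end());
      }
      if (!feasible) continue;
      double cll;
      if (!eval_path(nt, nty, x0s[i], t0, t1, U, A, theta, conv, cll, candG))
        continue;
      const double logar = (cll - paths[i].ll) + corr;
      if (logar >= 0.0 || std::log(unif_rand()) < logar) {
        acc[move - 1]++;
        paths[i].t = nt;
        paths[i].ty = nty;
        paths[i].ll = cll;
        paths[i].G = candG;
        std::fill(paths[i].cnt.begin(), paths[i].cnt.end(), 0);
        for (size_t j = 0; j < nty.size(); ++j) paths[i].cnt[nty[j]]++;
      }
    }
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int Jt = 0;
      for (int i = 0; i < nI; ++i) {
        const int Ji = (int)paths[i].t.size();
        Jt += Ji;
        if (record_intervals) J_int(srow, i) = Ji;
        for (int r = 0; r < M; ++r) {
          n_mat(srow, r) += paths[i].cnt[r];
          G_mat(srow, r) += paths[i].G[r];
        }
      }
      J_tot[srow] = Jt;
      ++srow;
      if (srow >= n_samples) break;
    }
  }

  return List::create(_["n"] = n_mat, _["G"] = G_mat, _["J"] = J_tot,
                      _["J_interval"] = J_int, _["proposed"] = prop,
                      _["accepted"] = acc, _["paths"] = pack_paths(paths),
                      _["states"] = states);
}

// [[Rcpp::export]]
List rjmcmc_partial_cpp(IntegerMatrix states0, NumericVector obstimes,
                        List paths0, IntegerMatrix modes, NumericVector theta,
                        IntegerMatrix U, IntegerMatrix A, int conv,
                        double alpha1, double alpha2, int n_samples,
                        int burn_in, int thin, bool record_intervals,
                        bool record_states) {
  const int M = U.nrow(), K = U.ncol();
  const int m = states0.nrow();
  const int nI = m - 1;
  const int Kp = modes.nrow();
  if (Kp == 0) stop("empty null set: no reversible-jump moves exist");

  // net effect of each mode on the full state
  std::vector<std::vector<int> > md(Kp, std::vector<int>(K, 0));
  std::vector<char> mzero(Kp, 1);
  for (int k = 0; k < Kp; ++k) {
    for (int j = 0; j < M; ++j)
      if (modes(k, j) > 0)
        for (int a = 0; a < K; ++a) md[k][a] += modes(k, j) * A(j, a);
    for (int a = 0; a < K; ++a)
      if (md[k][a] != 0) { mzero[k] = 0; break; }
  }

  std::vector<std::vector<int> > st(m, std::vector<int>(K));
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < K; ++a) st[i][a] = states0(i, a);

  std::vector<IPath> paths(nI);
  for (int i = 0; i < nI; ++i) {
    List pi = paths0[i];
    paths[i] = make_ipath(pi["times"], pi["types"], st[i], obstimes[i],
                          obstimes[i + 1], U, A, theta, conv, i);
  }

  const int n_iter = burn_in + n_samples * thin;
  IntegerMatrix n_mat(n_samples, M);
  NumericMatrix G_mat(n_samples, M);
  IntegerVector J_tot(n_samples);
  IntegerMatrix J_int(record_intervals ? n_samples : 0, record_intervals ? nI : 0);
  IntegerMatrix S_rec(record_states ? n_samples : 0, record_states ? m * K : 0);
  IntegerVector prop(3), acc(3);

  std::vector<double> nt, nt2;
  std::vector<int> nty, nty2;
  std::vector<double> candG(M), candG2(M);

  auto refresh = [&](IPath& p, std::vector<double>& t, std::vector<int>& ty,
                     double ll, std::vector<double>& G) {
    p.t = t;
    p.ty = ty;
    p.ll = ll;
    p.G = G;
    std::fill(p.cnt.begin(), p.cnt.end(), 0);
    for (size_t j = 0; j < ty.size(); ++j) p.cnt[ty[j]]++;
  };

  int srow = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- update of the start state at t_1: modify interval 1 while holding
    // its end state fixed and shifting the (hidden) start state
    {
      const double t0 = obstimes[0], t1 = obstimes[1];
      const double tau = t1 - t0;
      const int k = std::min((int)(unif_rand() * Kp), Kp - 1);
      const double u = unif_rand();
      if (u < alpha1 + alpha2) {
        const int move = (u < alpha1) ? 1 : 2;
        bool feasible = true;
        double corr = 0.0;
        std::vector<int> news0 = st[0];
        if (move == 1) {
          for (int a = 0; a < K; ++a) {
            news0[a] -= md[k][a];
            if (news0[a] < 0) feasible = false;
          }
          if (feasible) {
            corr = std::log(alpha2 / alpha1) +
                   add_corr(paths[0].cnt, modes, k, tau);
            add_mode_events(paths[0], modes, k, t0, t1, nt, nty);
          }
        } else {
          feasible = del_mode_events(paths[0], modes, k, nt, nty);
          if (feasible) {
            for (int a = 0; a < K; ++a) {
              news0[a] += md[k][a];
              if (news0[a] < 0) feasible = false;
            }
          }
          if (feasible)
            corr = std::log(alpha1 / alpha2) +
                   del_corr(paths[0].cnt, modes, k, tau);
        }
        double cll;
        if (feasible &&
            eval_path(nt, nty, news0, t0, t1, U, A, theta, conv, cll, candG)) {
          const double logar = (cll - paths[0].ll) + corr;
          if (logar >= 0.0 || std::log(unif_rand()) < logar) {
            refresh(paths[0], nt, nty, cll, candG);
            st[0] = news0;
          }
        }
      }
    }

    // --- sweep over intervals with complementary paired moves
    for (int i = 0; i < nI; ++i) {
      const double t0 = obstimes[i], t1 = obstimes[i + 1];
      const double tau = t1 - t0;
      const int k = std::min((int)(unif_rand() * Kp), Kp - 1);
      const double u = unif_rand();
      const int move = (u < alpha1) ? 1 : (u < alpha1 + alpha2) ? 2 : 3;
      prop[move - 1]++;

      if (move == 3) {
        nty = paths[i].ty;
        nt.resize(nty.size());
        for (size_t j = 0; j < nt.size(); ++j) nt[j] = t0 + unif_rand() * tau;
        std::sort(nt.begin(), nt.end());
        double cll;
        if (eval_path(nt, nty, st[i], t0, t1, U, A, theta, conv, cll, candG)) {
          const double logar = cll - paths[i].ll;
          if (logar >= 0.0 || std::log(unif_rand()) < logar) {
            acc[2]++;
            refresh(paths[i], nt, nty, cll, candG);
          }
        }
        continue;
      }

      const int sgn = (move == 1) ? 1 : -1; // state shift at t_{i+1} is sgn*d
      bool feasible = true;
      double corr = 0.0;
      if (move == 1) {
        corr = std::log(alpha2 / alpha1) + add_corr(paths[i].cnt, modes, k, tau);
        add_mode_events(paths[i], modes, k, t0, t1, nt, nty);
      } else {
        feasible = del_mode_events(paths[i], modes, k, nt, nty);
        if (feasible)
          corr = std::log(alpha1 / alpha2) + del_corr(paths[i].cnt, modes, k, tau);
      }
      if (!feasible) continue;

      if (mzero[k]) {
        // mode nulls every species: single-interval update
        double cll;
        if (!eval_path(nt, nty, st[i], t0, t1, U, A, theta, conv, cll, candG))
          continue;
        const double logar = (cll - paths[i].ll) + corr;
        if (logar >= 0.0 || std::log(unif_rand()) < logar) {
          acc[move - 1]++;
          refresh(paths[i], nt, nty, cll, candG);
        }
        continue;
      }

      std::vector<int> news = st[i + 1];
      for (int a = 0; a < K; ++a) {
        news[a] += sgn * md[k][a];
        if (news[a] < 0) { feasible = false; break; }
      }
      if (!feasible) continue;

      if (i == nI - 1) {
        // final interval: the hidden state at t_m is unconstrained
        double cll;
        if (!eval_path(nt, nty, st[i], t0, t1, U, A, theta, conv, cll, candG))
          continue;
        const double logar = (cll - paths[i].ll) + corr;
        if (logar >= 0.0 || std::log(unif_rand()) < logar) {
          acc[move - 1]++;
          refresh(paths[i], nt, nty, cll, candG);
          st[i + 1] = news;
        }
        continue;
      }

      // paired move: complementary delete/add of the same mode on interval
      // i+1 restores the state at t_{i+2}
      const double t2 = obstimes[i + 2];
      const double tau2 = t2 - t1;
      if (move == 1) {
        if (!del_mode_events(paths[i + 1], modes, k, nt2, nty2)) continue;
        corr += del_corr(paths[i + 1].cnt, modes, k, tau2);
      } else {
        add_mode_events(paths[i + 1], modes, k, t1, t2, nt2, nty2);
        corr += add_corr(paths[i + 1].cnt, modes, k, tau2);
      }
      double cll, cll2;
      if (!eval_path(nt, nty, st[i], t0, t1, U, A, theta, conv, cll, candG))
        continue;
      if (!eval_path(nt2, nty2, news, t1, t2, U, A, theta, conv, cll2, candG2))
        continue;
      const double logar = (cll - paths[i].ll) + (cll2 - paths[i + 1].ll) + corr;
      if (logar >= 0.0 || std::log(unif_rand()) < logar) {
        acc[move - 1]++;
        refresh(paths[i], nt, nty, cll, candG);
        refresh(paths[i + 1], nt2, nty2, cll2, candG2);
        st[i + 1] = news;
      }
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int Jt = 0;
      for (int i = 0; i < nI; ++i) {
        const int Ji = (int)paths[i].t.size();
        Jt += Ji;
        if (record_intervals) J_int(srow, i) = Ji;
        for (int r = 0; r < M; ++r) {
          n_mat(srow, r) += paths[i].cnt[r];
          G_mat(srow, r) += paths[i].G[r];
        }
      }
      J_tot[srow] = Jt;
      if (record_states)
        for (int i = 0; i < m; ++i)
          for (int a = 0; a < K; ++a) S_rec(srow, i * K + a) = st[i][a];
      ++srow;
      if (srow >= n_samples) break;
    }
  }

  IntegerMatrix states_out(m, K);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < K; ++a) states_out(i, a) = st[i][a];

  return List::create(_["n"] = n_mat, _["G"] = G_mat, _["J"] = J_tot,
                      _["J_interval"] = J_int, _["state_samples"] = S_rec,
                      _["proposed"] = prop, _["accepted"] = acc,
                      _["paths"] = pack_paths(paths),
                      _["states"] = states_out);
}
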